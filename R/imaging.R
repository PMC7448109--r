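# Lesion quantification: grayscale conversion, Gaussian smoothing,
# 2x2 finite-difference gradient, non-maximum suppression, hysteresis
# thresholding, Moore boundary tracing with eight-direction Freeman chain
# codes, and region area via the discrete Green's theorem.
#
# Coordinate convention throughout: (row, col) with row 1 at the top;
# x = col, y = row, y increases downward. Freeman codes: 0 = +x,
# 1 = (+x,-y), 2 = -y, 3 = (-x,-y), 4 = -x, 5 = (-x,+y), 6 = +y,
# 7 = (+x,+y) -- i.e. 0 is East and codes advance counter-clockwise on
# screen is FALSE: with y down, codes 1..3 step upward, 5..7 downward.

# (dr, dc) displacement for Freeman codes 0..7, in code order.
.freeman_steps <- matrix(c(
   0L,  1L,   # 0: +x
  -1L,  1L,   # 1: +x,-y
  -1L,  0L,   # 2: -y
  -1L, -1L,   # 3: -x,-y
   0L, -1L,   # 4: -x
   1L, -1L,   # 5: -x,+y
   1L,  0L,   # 6: +y
   1L,  1L    # 7: +x,+y
), ncol = 2, byrow = TRUE)

#' Default grayscale channel weights
#'
#' The channel weights (alpha for R, beta for G, gamma for B) must lie in
#' alpha in \[0.25, 0.35\], beta in \[0.55, 0.65\], gamma in \[0.1, 0.2\].
#' The defaults (0.30, 0.59, 0.11) sit inside all three ranges and sum to 1,
#' so uniform-channel (already gray) pixels map to themselves.
#'
#' @return Named numeric vector `c(alpha, beta, gamma)`.
#' @export
grayscale_weights <- function(alpha = 0.30, beta = 0.59, gamma = 0.11) {
  if (alpha < 0.25 || alpha > 0.35) stop("alpha must be in [0.25, 0.35]")
  if (beta < 0.55 || beta > 0.65) stop("beta must be in [0.55, 0.65]")
  if (gamma < 0.1 || gamma > 0.2) stop("gamma must be in [0.1, 0.2]")
  c(alpha = alpha, beta = beta, gamma = gamma)
}

#' Convert an RGB image to grayscale
#'
#' Computes `alpha*R + beta*G + gamma*B` per pixel and clips to \[0, 255\].
#' A plain matrix input is treated as an image with three equal channels,
#' so it passes through unchanged whenever the weights sum to 1.
#'
#' @param img h-by-w-by-3 numeric array, or a numeric matrix.
#' @param w Weights from [grayscale_weights()].
#' @return Numeric matrix of gray intensities in \[0, 255\].
#' @export
to_grayscale <- function(img, w = grayscale_weights()) {
  if (is.matrix(img)) {
    if (length(img) == 0) stop("empty image")
    g <- img * sum(w)
  } else if (is.array(img) && length(dim(img)) == 3 && dim(img)[3] == 3) {
    if (dim(img)[1] < 1 || dim(img)[2] < 1) stop("empty image")
    ch <- function(k) matrix(img[, , k], dim(img)[1], dim(img)[2])
    g <- ch(1) * w[[1]] + ch(2) * w[[2]] + ch(3) * w[[3]]
  } else stop("img must be a matrix or an h-by-w-by-3 array")
  pmin(pmax(g, 0), 255)
}

#' Gaussian smoothing kernel
#'
#' Square kernel of side `2*radius + 1` with entries proportional to
#' `exp(-(x^2 + y^2) / (2*sigma^2))`, renormalised to sum exactly 1.
#'
#' @param sigma Positive standard deviation (pixels).
#' @param radius Kernel radius (>= 1).
#' @return Numeric matrix summing to 1.
#' @export
gaussian_kernel <- function(sigma, radius = 2L) {
  if (!is.numeric(sigma) || sigma <= 0) stop("sigma must be > 0")
  if (radius < 1) stop("radius must be >= 1")
  d <- seq(-radius, radius)
  k <- exp(-outer(d^2, d^2, "+") / (2 * sigma^2))
  k / sum(k)
}

#' Smooth an image by 2-d convolution
#'
#' Discrete convolution with reflect padding at the borders. With a
#' unit-sum kernel, constant images are fixed points and the output range
#' never exceeds the input range.
#'
#' @param g Numeric matrix.
#' @param kernel Square kernel, e.g. from [gaussian_kernel()].
#' @return Smoothed matrix, same dimensions as `g`.
#' @export
smooth_image <- function(g, kernel) {
  stopifnot(is.matrix(g), is.matrix(kernel))
  kh <- nrow(kernel); kw <- ncol(kernel)
  if (kh > nrow(g) || kw > ncol(g)) stop("kernel larger than image")
  rr <- (kh - 1L) %/% 2L; rc <- (kw - 1L) %/% 2L
  # reflect padding (edge mirror without repeating the border pixel would be
  # "reflect" in scipy terms; we mirror including the border: a b c -> b a|a b c|c b)
  ridx <- c(rev(seq_len(rr)), seq_len(nrow(g)), nrow(g) + 1 - seq_len(rr))
  cidx <- c(rev(seq_len(rc)), seq_len(ncol(g)), ncol(g) + 1 - seq_len(rc))
  pad <- g[ridx, cidx, drop = FALSE]
  out <- matrix(0, nrow(g), ncol(g))
  for (i in seq_len(kh)) {
    for (j in seq_len(kw)) {
      # convolution flips the kernel relative to cross-correlation
      out <- out + kernel[kh - i + 1L, kw - j + 1L] *
        pad[(i - 1L) + seq_len(nrow(g)), (j - 1L) + seq_len(ncol(g)), drop = FALSE]
    }
  }
  out
}

#' First-order 2x2 finite-difference gradient field
#'
#' For an h-by-w image the field lives on the (h-1)-by-(w-1) grid of 2x2
#' blocks:
#' `Gx = (f(x+1,y) - f(x,y) + f(x+1,y+1) - f(x,y+1)) / 2`,
#' `Gy = (f(x,y+1) - f(x,y) + f(x+1,y+1) - f(x+1,y)) / 2`,
#' magnitude `sqrt(Gx^2 + Gy^2)` and direction `atan2(Gy, Gx)`.
#'
#' @param g Numeric matrix, at least 2x2.
#' @return List of class `"gradient_field"` with `gx`, `gy`, `magnitude`,
#'   `direction` matrices.
#' @export
image_gradient <- function(g) {
  stopifnot(is.matrix(g))
  h <- nrow(g); w <- ncol(g)
  if (h < 2 || w < 2) stop("image must be at least 2x2")
  A <- g[1:(h - 1), 1:(w - 1), drop = FALSE]   # f(x,   y)
  B <- g[1:(h - 1), 2:w,       drop = FALSE]   # f(x+1, y)
  C <- g[2:h,       1:(w - 1), drop = FALSE]   # f(x,   y+1)
  D <- g[2:h,       2:w,       drop = FALSE]   # f(x+1, y+1)
  gx <- (B - A + D - C) / 2
  gy <- (C - A + D - B) / 2
  structure(list(gx = gx, gy = gy,
                 magnitude = sqrt(gx^2 + gy^2),
                 direction = atan2(gy, gx)),
            class = "gradient_field")
}

#' Non-maximum suppression of gradient magnitude
#'
#' Quantises each gradient direction to one of four sectors (0, 45, 90,
#' 135 degrees) and keeps a pixel's magnitude only if it is >= both
#' neighbours along that direction (ties keep the pixel, so plateaus
#' retain a connected ridge). No sub-pixel interpolation.
#'
#' @param field A `"gradient_field"` from [image_gradient()].
#' @return Thinned magnitude matrix (zeros at suppressed pixels).
#' @export
nonmax_suppress <- function(field) {
  stopifnot(inherits(field, "gradient_field"))
  m <- field$magnitude
  h <- nrow(m); w <- ncol(m)
  # sector 0: gradient ~ horizontal -> compare left/right neighbours
  # sector 1: 45 deg (+x,+y)        -> compare down-right/up-left
  # sector 2: vertical              -> compare up/down
  # sector 3: 135 deg (-x,+y)       -> compare down-left/up-right
  theta <- field$direction %% pi
  sector <- as.integer(round(theta / (pi / 4))) %% 4L
  pad <- matrix(0, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- m
  shift <- function(dr, dc) pad[(2 + dr):(h + 1 + dr), (2 + dc):(w + 1 + dc)]
  n1 <- matrix(0, h, w); n2 <- matrix(0, h, w)
  sel <- sector == 0L; n1[sel] <- shift(0, 1)[sel];   n2[sel] <- shift(0, -1)[sel]
  sel <- sector == 1L; n1[sel] <- shift(1, 1)[sel];   n2[sel] <- shift(-1, -1)[sel]
  sel <- sector == 2L; n1[sel] <- shift(1, 0)[sel];   n2[sel] <- shift(-1, 0)[sel]
  sel <- sector == 3L; n1[sel] <- shift(1, -1)[sel];  n2[sel] <- shift(-1, 1)[sel]
  out <- m
  out[m < n1 | m < n2] <- 0
  out
}

# Binary dilation by the 8-neighbourhood, restricted to `allowed`.
.grow8 <- function(seed, allowed) {
  h <- nrow(seed); w <- ncol(seed)
  pad <- matrix(FALSE, h + 2, w + 2)
  repeat {
    pad[2:(h + 1), 2:(w + 1)] <- seed
    grown <- seed
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      grown <- grown | pad[(2 + dr):(h + 1 + dr), (2 + dc):(w + 1 + dc)]
    }
    grown <- grown & allowed
    new <- grown | seed
    if (identical(new, seed)) return(seed)
    seed <- new
  }
}

#' Double (hysteresis) thresholding of a thinned magnitude raster
#'
#' Pixels with magnitude >= `t_high` are strong edges; pixels in
#' \[`t_low`, `t_high`) are kept only when 8-connected (transitively)
#' to a strong pixel.
#'
#' @param thinned Magnitude matrix (e.g. from [nonmax_suppress()]).
#' @param t_low,t_high Thresholds, `0 <= t_low <= t_high`.
#' @return Binary (0/1) integer matrix.
#' @export
hysteresis_threshold <- function(thinned, t_low, t_high) {
  stopifnot(is.matrix(thinned))
  if (t_low > t_high) stop("t_low must be <= t_high")
  if (t_low < 0) stop("thresholds must be non-negative")
  strong <- thinned >= t_high
  candidate <- thinned >= t_low
  keep <- .grow8(strong, candidate)
  matrix(as.integer(keep), nrow(thinned), ncol(thinned))
}

# Connected-component labelling (8-connectivity). Returns an integer label
# matrix (0 = background) and component sizes.
.label_components <- function(mask) {
  mask <- mask > 0
  labels <- matrix(0L, nrow(mask), ncol(mask))
  sizes <- integer(0)
  lab <- 0L
  remaining <- mask
  while (any(remaining)) {
    lab <- lab + 1L
    idx <- which(remaining)[1]
    seed <- matrix(FALSE, nrow(mask), ncol(mask))
    seed[idx] <- TRUE
    comp <- .grow8(seed, remaining)
    labels[comp] <- lab
    sizes[lab] <- sum(comp)
    remaining <- remaining & !comp
  }
  list(labels = labels, sizes = sizes)
}

#' Largest 8-connected foreground component
#'
#' @param mask Logical or 0/1 matrix.
#' @return Logical matrix selecting the largest component (all-FALSE when
#'   the mask is empty).
#' @export
largest_component <- function(mask) {
  cc <- .label_components(mask)
  if (length(cc$sizes) == 0) return(matrix(FALSE, nrow(mask), ncol(mask)))
  cc$labels == which.max(cc$sizes)
}

#' Fill the interior of a closed edge contour
#'
#' Flood-fills background from the image border through non-edge pixels
#' (4-connectivity); everything not reached -- the edge ring and its
#' interior -- is the filled region.
#'
#' @param edges Binary matrix (edge pixels = 1).
#' @return Logical matrix of the filled region.
#' @export
fill_edge_map <- function(edges) {
  stopifnot(is.matrix(edges))
  h <- nrow(edges); w <- ncol(edges)
  open <- !(edges > 0)
  seed <- matrix(FALSE, h, w)
  seed[1, ] <- open[1, ]; seed[h, ] <- open[h, ]
  seed[, 1] <- open[, 1]; seed[, w] <- open[, w]
  # 4-connected flood of the outside
  pad <- matrix(FALSE, h + 2, w + 2)
  repeat {
    pad[2:(h + 1), 2:(w + 1)] <- seed
    grown <- seed |
      pad[1:h, 2:(w + 1)] | pad[3:(h + 2), 2:(w + 1)] |
      pad[2:(h + 1), 1:w] | pad[2:(h + 1), 3:(w + 2)]
    grown <- grown & open
    if (identical(grown, seed)) break
    seed <- grown
  }
  !seed
}

#' Trace the boundary of a single connected region
#'
#' Moore-neighbour tracing, clockwise on screen, starting from the
#' topmost-then-leftmost foreground pixel. Returns the ordered boundary
#' pixels and the eight-direction Freeman chain code; the chain is closed
#' (net displacement zero).
#'
#' @param mask Logical or 0/1 matrix containing exactly one 8-connected
#'   foreground component.
#' @return List of class `"boundary_chain"`: `start` (row, col), `points`
#'   (N-by-2 matrix, row/col), `codes` (integer vector in 0..7, length N;
#'   empty for a single-pixel region).
#' @export
trace_boundary <- function(mask) {
  mask <- mask > 0
  if (!any(mask)) stop("empty region")
  cc <- .label_components(mask)
  if (length(cc$sizes) > 1)
    stop("region has ", length(cc$sizes),
         " components; select the largest first")
  h <- nrow(mask); w <- ncol(mask)
  at <- function(r, c) r >= 1 && r <= h && c >= 1 && c <= w && mask[r, c]
  # topmost, then leftmost
  rows <- row(mask)[mask]; cols <- col(mask)[mask]
  r0 <- min(rows); c0 <- min(cols[rows == r0])
  # clockwise neighbour order on screen (y down): E SE S SW W NW N NE
  nb <- matrix(c(0, 1, 1, 1, 1, 0, 1, -1, 0, -1, -1, -1, -1, 0, -1, 1),
               ncol = 2, byrow = TRUE)
  if (sum(mask) == 1) {
    return(structure(list(start = c(r0, c0),
                          points = matrix(c(r0, c0), ncol = 2),
                          codes = integer(0)),
                     class = "boundary_chain"))
  }
  # backtrack starts at the West neighbour (background by start choice)
  cur <- c(r0, c0); back <- c(r0, c0 - 1L)
  pts <- matrix(0L, nrow = 4L * sum(mask) + 8L, ncol = 2)
  pts[1, ] <- cur; n <- 1L
  limit <- nrow(pts)
  repeat {
    # index of back in cur's clockwise neighbourhood
    d <- c(back[1] - cur[1], back[2] - cur[2])
    bi <- which(nb[, 1] == d[1] & nb[, 2] == d[2])
    found <- FALSE
    for (k in 1:8) {
      i <- ((bi - 1L + k) %% 8L) + 1L
      r <- cur[1] + nb[i, 1]; c <- cur[2] + nb[i, 2]
      if (at(r, c)) {
        prev <- ((bi - 1L + k - 1L) %% 8L) + 1L
        back <- c(cur[1] + nb[prev, 1], cur[2] + nb[prev, 2])
        cur <- c(r, c)
        found <- TRUE
        break
      }
    }
    if (!found) stop("tracing failed: isolated pixel inside multi-pixel region")
    if (cur[1] == r0 && cur[2] == c0) break
    n <- n + 1L
    if (n > limit) stop("tracing failed to close")
    pts[n, ] <- cur
  }
  pts <- pts[seq_len(n), , drop = FALSE]
  nxt <- rbind(pts[-1, , drop = FALSE], pts[1, , drop = FALSE])
  dr <- nxt[, 1] - pts[, 1]; dc <- nxt[, 2] - pts[, 2]
  codes <- integer(n)
  for (i in seq_len(n)) {
    j <- which(.freeman_steps[, 1] == dr[i] & .freeman_steps[, 2] == dc[i])
    if (length(j) != 1) stop("non-adjacent step in traced boundary")
    codes[i] <- j - 1L
  }
  structure(list(start = c(r0, c0), points = pts, codes = codes),
            class = "boundary_chain")
}

#' Vertical-step labels of a Freeman chain
#'
#' Maps each code to the sign of its row step (downward positive):
#' codes 1, 2, 3 -> -1; codes 0, 4 -> 0; codes 5, 6, 7 -> +1.
#'
#' @param chain A `"boundary_chain"` or an integer vector of codes.
#' @return Integer vector of labels in \{-1, 0, 1\}.
#' @export
label_chain <- function(chain) {
  codes <- if (inherits(chain, "boundary_chain")) chain$codes else chain
  if (length(codes) == 0) return(integer(0))
  if (any(codes < 0 | codes > 7 | codes != floor(codes)))
    stop("chain codes must be integers in 0..7")
  .freeman_steps[codes + 1L, 1]
}

# Signed-area magnitude of the polygon through the chain's pixel centres
# (discrete Green's theorem along the closed contour).
.chain_polygon_area <- function(chain) {
  n <- length(chain$codes)
  if (n == 0) return(0)
  pts <- chain$points
  nxt <- rbind(pts[-1, , drop = FALSE], pts[1, , drop = FALSE])
  if (any(abs(nxt - pts) > 1)) stop("chain is not closed unit-step")
  s <- nxt[, 1] - pts[, 1]                 # row steps = labels
  abs(sum((pts[, 2] + nxt[, 2]) / 2 * s))
}

#' Enclosed pixel count of a closed boundary chain
#'
#' Discrete Green's theorem plus the Pick correction: with boundary points
#' p_i = (x_i, y_i) and vertical steps s_i = y_{i+1} - y_i, the polygon
#' through the pixel centres has area `A = |sum (x_i + x_{i+1})/2 * s_i|`
#' and the enclosed pixel count (boundary included) is `A + N/2 + 1`.
#' A single-pixel region (N = 0) has area 1.
#'
#' @param chain A `"boundary_chain"` from [trace_boundary()].
#' @return Integer pixel count.
#' @export
chain_area <- function(chain) {
  stopifnot(inherits(chain, "boundary_chain"))
  n <- length(chain$codes)
  if (n == 0) return(1L)
  as.integer(round(.chain_polygon_area(chain) + n / 2 + 1))
}

#' Mean gray level over a region
#'
#' @param g Grayscale matrix.
#' @param mask Logical/0-1 matrix of the same size.
#' @return Arithmetic mean of `g` over the mask.
#' @export
mean_gray_level <- function(g, mask) {
  stopifnot(is.matrix(g))
  mask <- mask > 0
  if (!any(mask)) stop("empty mask")
  mean(g[mask])
}

#' Preprocessing parameters for lesion extraction
#'
#' @param weights Grayscale weights, see [grayscale_weights()].
#' @param sigma,radius Gaussian smoothing parameters.
#' @param t_high_quantile Quantile of the non-zero thinned magnitudes used
#'   as the strong threshold.
#' @param t_low_fraction Weak threshold as a fraction of the strong one.
#' @param min_area Minimum lesion pixel area for the image to count as
#'   informative. The default is the pixel area of a circle of diameter
#'   15 (the normal-lesion bound, in mm, at 1 px/mm spacing).
#' @param min_gray Minimum mean gray level for informativeness (180 is the
#'   upper normal bound).
#' @param pixel_spacing_mm Optional mm-per-pixel spacing; when given,
#'   `min_area` is derived from a 15 mm equivalent-circle diameter.
#' @return Named list of parameters.
#' @export
imaging_params <- function(weights = grayscale_weights(), sigma = 1.4,
                           radius = 2L, t_high_quantile = 0.9,
                           t_low_fraction = 0.4,
                           min_area = NULL, min_gray = 180,
                           pixel_spacing_mm = NULL) {
  if (is.null(min_area)) {
    d_px <- if (is.null(pixel_spacing_mm)) 15 else 15 / pixel_spacing_mm
    min_area <- pi * (d_px / 2)^2
  }
  list(weights = weights, sigma = sigma, radius = radius,
       t_high_quantile = t_high_quantile, t_low_fraction = t_low_fraction,
       min_area = min_area, min_gray = min_gray,
       pixel_spacing_mm = pixel_spacing_mm)
}

#' Extract lesion area and mean gray level from an image
#'
#' Full pipeline: grayscale -> Gaussian smoothing -> 2x2 gradient ->
#' non-maximum suppression -> hysteresis thresholding -> fill + largest
#' component -> boundary trace -> chain-code area and mean gray level.
#' The `informative` flag marks images whose lesion passes both the area
#' and the gray-level screening bounds.
#'
#' @param img RGB array or grayscale matrix.
#' @param params From [imaging_params()].
#' @return List of class `"lesion_metrics"`: `area_px`, `mean_gray`,
#'   `n_pixels`, `informative`.
#' @export
extract_lesion_metrics <- function(img, params = imaging_params()) {
  g <- to_grayscale(img, params$weights)
  gs <- smooth_image(g, gaussian_kernel(params$sigma, params$radius))
  field <- image_gradient(gs)
  thin <- nonmax_suppress(field)
  nz <- thin[thin > 0]
  empty <- structure(list(area_px = 0L, mean_gray = NA_real_,
                          n_pixels = 0L, informative = FALSE),
                     class = "lesion_metrics")
  if (length(nz) == 0) return(empty)
  t_high <- stats::quantile(nz, params$t_high_quantile, names = FALSE)
  t_low <- params$t_low_fraction * t_high
  edges <- hysteresis_threshold(thin, t_low, t_high)
  if (!any(edges > 0)) return(empty)
  filled <- fill_edge_map(edges)
  comp <- largest_component(filled)
  if (!any(comp)) return(empty)
  chain <- trace_boundary(comp)
  # The traced chain follows the detected edge ridge, which straddles the
  # true lesion boundary; the unbiased region estimate is the discrete
  # Green's-theorem area enclosed by the contour itself (+1 so a
  # degenerate single-pixel chain still counts one pixel), not the
  # boundary-inclusive pixel count chain_area() reports for filled masks.
  area <- as.integer(round(.chain_polygon_area(chain) + 1))
  # the gradient grid is offset by half a pixel; index g on the same grid
  gsub <- g[seq_len(nrow(comp)), seq_len(ncol(comp)), drop = FALSE]
  mg <- mean_gray_level(gsub, comp)
  structure(list(area_px = area, mean_gray = mg, n_pixels = area,
                 informative = area >= params$min_area && mg >= params$min_gray),
            class = "lesion_metrics")
}

#' @export
print.lesion_metrics <- function(x, ...) {
  cat(sprintf("Lesion metrics: area = %d px, mean gray = %s, informative = %s\n",
              x$area_px,
              if (is.na(x$mean_gray)) "NA" else sprintf("%.2f", x$mean_gray),
              x$informative))
  invisible(x)
}
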