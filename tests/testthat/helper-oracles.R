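# Independent oracles used by the unit and acceptance tests. These are
# deliberately naive (queue-based BFS, brute-force rasterisation, central
# finite differences) and share no code with the package internals.

# Pixel count of a mask by literal flood fill (8-connectivity) from the
# first foreground pixel; equals sum(mask) only for a single component,
# which is exactly what the callers assert.
flood_fill_count <- function(mask) {
  mask <- mask > 0
  if (!any(mask)) return(0L)
  h <- nrow(mask); w <- ncol(mask)
  seen <- matrix(FALSE, h, w)
  start <- which(mask)[1]
  queue <- c(start)
  seen[start] <- TRUE
  count <- 0L
  while (length(queue)) {
    idx <- queue[length(queue)]; queue <- queue[-length(queue)]
    count <- count + 1L
    r <- ((idx - 1L) %% h) + 1L; c <- ((idx - 1L) %/% h) + 1L
    for (dr in -1:1) for (dc in -1:1) {
      rr <- r + dr; cc <- c + dc
      if (rr >= 1 && rr <= h && cc >= 1 && cc <= w &&
          mask[rr, cc] && !seen[rr, cc]) {
        seen[rr, cc] <- TRUE
        queue <- c(queue, (cc - 1L) * h + rr)
      }
    }
  }
  count
}

# Brute-force hysteresis: strong pixels plus weak pixels 8-connected to a
# strong one, by repeated single-pixel sweeps until no change.
hysteresis_oracle <- function(m, t_low, t_high) {
  h <- nrow(m); w <- ncol(m)
  keep <- m >= t_high
  cand <- m >= t_low
  repeat {
    changed <- FALSE
    for (r in 1:h) for (c in 1:w) {
      if (cand[r, c] && !keep[r, c]) {
        for (dr in -1:1) for (dc in -1:1) {
          rr <- r + dr; cc <- c + dc
          if (rr >= 1 && rr <= h && cc >= 1 && cc <= w && keep[rr, cc]) {
            keep[r, c] <- TRUE; changed <- TRUE
          }
        }
      }
    }
    if (!changed) break
  }
  matrix(as.integer(keep), h, w)
}

# Rasterise a random convex shape (ellipse or convex polygon) on an
# n-by-n grid; returns a logical mask guaranteed single-component.
random_convex_mask <- function(n = 48) {
  cols <- matrix(rep(1:n, each = n), n, byrow = TRUE)
  rows <- t(cols)
  if (runif(1) < 0.5) {
    a <- runif(1, 2.5, n / 3); b <- runif(1, 2.5, n / 3)
    cx <- runif(1, n / 3, 2 * n / 3); cy <- runif(1, n / 3, 2 * n / 3)
    mask <- ((cols - cx) / a)^2 + ((rows - cy) / b)^2 <= 1
  } else {
    k <- sample(3:7, 1)
    ang <- sort(runif(k, 0, 2 * pi))
    rad <- runif(k, n / 6, n / 2.5)
    cx <- n / 2 + runif(1, -n / 8, n / 8); cy <- n / 2 + runif(1, -n / 8, n / 8)
    px <- cx + rad * cos(ang); py <- cy + rad * sin(ang)
    # point-in-convex-hull test via half-planes of the hull
    hull <- chull(px, py)
    hx <- px[hull]; hy <- py[hull]
    mask <- matrix(TRUE, n, n)
    m <- length(hx)
    for (i in seq_len(m)) {
      j <- (i %% m) + 1
      side <- (hx[j] - hx[i]) * (rows - hy[i]) - (hy[j] - hy[i]) * (cols - hx[i])
      mask <- mask & (side <= 0)
    }
  }
  if (sum(mask) < 1) mask[round(n / 2), round(n / 2)] <- TRUE
  # thin slivers can rasterise into several components; redraw until the
  # independent flood fill confirms a single one
  if (flood_fill_count(mask) != sum(mask)) return(random_convex_mask(n))
  mask
}

# Central finite-difference gradient of the batch loss for every weight
# and bias of a network.
finite_diff_grads <- function(net, x, d, eps = 1e-6) {
  lossat <- function(nn) net_loss(net_forward(nn, x)$output, d)
  dW <- net$weights; db <- net$biases
  for (m in seq_along(net$weights)) {
    for (i in seq_along(net$weights[[m]])) {
      np <- net; np$weights[[m]][i] <- np$weights[[m]][i] + eps
      nm <- net; nm$weights[[m]][i] <- nm$weights[[m]][i] - eps
      dW[[m]][i] <- (lossat(np) - lossat(nm)) / (2 * eps)
    }
    for (i in seq_along(net$biases[[m]])) {
      np <- net; np$biases[[m]][i] <- np$biases[[m]][i] + eps
      nm <- net; nm$biases[[m]][i] <- nm$biases[[m]][i] - eps
      db[[m]][i] <- (lossat(np) - lossat(nm)) / (2 * eps)
    }
  }
  list(dW = dW, db = db)
}

# Relative agreement used by the gradient checks.
max_rel_err <- function(a, b) {
  denom <- pmax(abs(a) + abs(b), 1e-8)
  max(abs(a - b) / denom)
}

# Small AND-gate fixture shared by perceptron and CLI tests.
and_fixture <- function() {
  list(x = matrix(c(0, 0, 0, 1, 1, 0, 1, 1), ncol = 2, byrow = TRUE),
       d = c(0.1, 0.1, 0.1, 0.9))
}
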