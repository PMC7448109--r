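# Reproducible synthetic cohorts: stage-conditioned serum marker panels
# (log-normal, TPSA rising and FPSA/TPSA falling with stage) and lesion
# images (one bright filled ellipse on a noisy dark background) with
# exact rasterised ground truth.

#' Default per-stage marker distribution parameters
#'
#' All markers are log-normal (positive support, right-skewed lab
#' values). Anchors: TPSA < 4 ng/ml is normal, > 10 raises suspicion and
#' mean levels above 50 indicate likely cancer, so the stage medians
#' default to 5, 12, 30, 60 ng/ml; the FPSA/TPSA ratio declines with
#' stage and falls below 0.1 in stage IV (median ratios 0.20, 0.15, 0.11,
#' 0.07); haemoglobin and red-cell measures decline mildly; PAP and PSMA
#' rise. These are documented defaults, not literature claims.
#'
#' @return Nested list: per marker, `median` (length 4, stages I-IV) and
#'   `sdlog`.
#' @export
default_marker_params <- function() {
  list(
    tpsa = list(median = c(5, 12, 30, 60), sdlog = 0.30),
    fpsa_ratio = list(median = c(0.20, 0.15, 0.11, 0.07), sdlog = 0.20),
    hb = list(median = c(140, 135, 128, 118), sdlog = 0.04),
    rbc = list(median = c(13.5, 13.2, 12.8, 12.2), sdlog = 0.04),
    pap = list(median = c(1.5, 3, 8, 20), sdlog = 0.35),
    psma = list(median = c(2, 4, 9, 20), sdlog = 0.35)
  )
}

#' Default per-stage lesion rendering parameters
#'
#' Semi-axis ranges (pixels) grow with stage, as does lesion intensity
#' (late lesions are larger and brighter on the gray scale); the
#' background sits well below the 180 gray screening bound.
#'
#' @param image_size Side of the square image in pixels.
#' @param noise_sd Standard deviation of the additive Gaussian pixel noise.
#' @return Named list of rendering parameters.
#' @export
default_lesion_params <- function(image_size = 128L, noise_sd = 8) {
  list(image_size = as.integer(image_size),
       axis_range = list(c(5, 9), c(10, 14), c(15, 19), c(20, 25)),
       lesion_intensity = c(185, 195, 205, 215),
       background = 80,
       noise_sd = noise_sd)
}

.stage_index <- function(stage) {
  if (is.character(stage)) stage <- match(stage, c("I", "II", "III", "IV"))
  stage <- as.integer(stage)
  if (length(stage) != 1 || is.na(stage) || stage < 1 || stage > 4)
    stop("stage must be I-IV (or 1-4)")
  stage
}

#' Sample one stage-conditioned marker panel
#'
#' Draws the six markers from the per-stage log-normal distributions
#' (FPSA as ratio times TPSA) and clips to the plausibility caps, so a
#' generated panel always passes validation. Uses the current RNG state;
#' seed with `set.seed()` for reproducibility.
#'
#' @param stage Stage `"I"`..`"IV"` or 1..4.
#' @param params See [default_marker_params()].
#' @param ranges Reference ranges supplying the caps.
#' @return A [marker_panel()].
#' @export
sample_marker_panel <- function(stage, params = default_marker_params(),
                                ranges = default_ranges()) {
  s <- .stage_index(stage)
  draw <- function(p) stats::rlnorm(1, meanlog = log(p$median[s]), sdlog = p$sdlog)
  cap <- function(name, v) min(v, .range_row(ranges, name)$cap)
  tpsa <- cap("tpsa", draw(params$tpsa))
  fpsa <- cap("fpsa", tpsa * draw(params$fpsa_ratio))
  marker_panel(
    tpsa = tpsa,
    rbc = cap("rbc", draw(params$rbc)),
    hb = cap("hb", draw(params$hb)),
    fpsa = fpsa,
    pap = cap("pap", draw(params$pap)),
    psma = cap("psma", draw(params$psma))
  )
}

#' Render one synthetic lesion image with ground truth
#'
#' One filled ellipse with stage-dependent semi-axes and intensity,
#' centred in the image, on a uniform background with additive Gaussian
#' noise; pixel values are clipped to \[0, 255\]. The returned
#' `true_area_px` is the exact rasterised pixel count
#' (pixels with `((c-cx)/a)^2 + ((r-cy)/b)^2 <= 1`) and `true_mean_gray`
#' the mean rendered intensity over those pixels.
#'
#' @param stage Stage `"I"`..`"IV"` or 1..4.
#' @param params See [default_lesion_params()].
#' @return List: `image` (h-by-w-by-3 array), `gray` (matrix),
#'   `true_area_px`, `true_mean_gray`.
#' @export
render_lesion_image <- function(stage, params = default_lesion_params()) {
  s <- .stage_index(stage)
  n <- params$image_size
  ar <- params$axis_range[[s]]
  a <- stats::runif(1, ar[1], ar[2])
  b <- stats::runif(1, ar[1], ar[2])
  cx <- (n + 1) / 2; cy <- (n + 1) / 2
  if (cx - a < 1 || cx + a > n || cy - b < 1 || cy + b > n)
    stop("ellipse exceeds image bounds")
  cols <- matrix(rep(seq_len(n), each = n), nrow = n, byrow = TRUE)
  rows <- t(cols)
  inside <- ((cols - cx) / a)^2 + ((rows - cy) / b)^2 <= 1
  g <- matrix(params$background, n, n)
  g[inside] <- params$lesion_intensity[s]
  if (params$noise_sd > 0)
    g <- g + matrix(stats::rnorm(n * n, 0, params$noise_sd), n, n)
  g <- pmin(pmax(g, 0), 255)
  list(image = gray_to_rgb(g), gray = g,
       true_area_px = sum(inside),
       true_mean_gray = mean(g[inside]))
}

#' Specification of a synthetic cohort
#'
#' @param n Number of patients.
#' @param stage_mix Proportions of stages I-IV (must sum to 1).
#' @param seed Root integer seed; marker, geometry and assignment draws
#'   flow from named sub-seeds derived from it.
#' @param marker_params,lesion_params See [default_marker_params()] /
#'   [default_lesion_params()].
#' @return Named list of class `"cohort_spec"`.
#' @export
cohort_spec <- function(n, stage_mix = rep(0.25, 4), seed = 1L,
                        marker_params = default_marker_params(),
                        lesion_params = default_lesion_params()) {
  if (n < 1) stop("n must be >= 1")
  if (length(stage_mix) != 4 || any(stage_mix < 0) ||
      abs(sum(stage_mix) - 1) > 1e-8)
    stop("stage_mix must be 4 non-negative proportions summing to 1")
  structure(list(n = as.integer(n), stage_mix = stage_mix,
                 seed = as.integer(seed), marker_params = marker_params,
                 lesion_params = lesion_params),
            class = "cohort_spec")
}

# Named sub-seeds derived from the root seed, kept below 2^31.
.sub_seed <- function(seed, stream) {
  offs <- c(stages = 101L, markers = 202L, geometry = 303L)
  (as.integer(seed) * 7919L + offs[[stream]]) %% 2147483647L
}

#' Generate a reproducible synthetic cohort
#'
#' Stages are drawn from `stage_mix`; each patient gets a marker panel
#' and a lesion image with ground truth. The cohort table follows the
#' input-model CSV schema with `area` / `gray_level` set to the rendered
#' ground truth, plus `stage` (true stage) and `true_area_px`.
#'
#' @param spec A [cohort_spec()].
#' @param out_dir Optional directory: writes `cohort.csv`, `spec.json`
#'   and, with `write_images = TRUE`, one `<patient_id>.pgm` per patient.
#' @param keep_images Keep the rendered images in the returned list.
#' @param write_images Write PGM files under `out_dir`.
#' @return List with `cohort` (data frame) and, if requested, `images`
#'   (named list of grayscale matrices).
#' @export
generate_cohort <- function(spec, out_dir = NULL, keep_images = FALSE,
                            write_images = FALSE) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(.sub_seed(spec$seed, "stages"))
  stages <- sample(1:4, spec$n, replace = TRUE, prob = spec$stage_mix)
  set.seed(.sub_seed(spec$seed, "markers"))
  panels <- lapply(stages, sample_marker_panel, params = spec$marker_params)
  set.seed(.sub_seed(spec$seed, "geometry"))
  lesions <- lapply(stages, render_lesion_image, params = spec$lesion_params)
  ids <- sprintf("P%04d", seq_len(spec$n))
  cohort <- data.frame(
    patient_id = ids,
    tpsa = vapply(panels, `[[`, numeric(1), "tpsa"),
    rbc = vapply(panels, `[[`, numeric(1), "rbc"),
    hb = vapply(panels, `[[`, numeric(1), "hb"),
    fpsa = vapply(panels, `[[`, numeric(1), "fpsa"),
    pap = vapply(panels, `[[`, numeric(1), "pap"),
    psma = vapply(panels, `[[`, numeric(1), "psma"),
    area = vapply(lesions, `[[`, numeric(1), "true_area_px"),
    gray_level = vapply(lesions, `[[`, numeric(1), "true_mean_gray"),
    stage = c("I", "II", "III", "IV")[stages],
    true_area_px = vapply(lesions, `[[`, numeric(1), "true_area_px"),
    stringsAsFactors = FALSE
  )
  out <- list(cohort = cohort)
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (keep_images || write_images) {
    images <- lapply(lesions, `[[`, "gray")
    names(images) <- ids
    if (keep_images) out$images <- images
    if (write_images) {
      if (is.null(out_dir)) stop("out_dir required to write images")
      for (id in ids) write_image(images[[id]], file.path(out_dir, paste0(id, ".pgm")))
    }
  }
  if (!is.null(out_dir)) {
    write_cohort(cohort, file.path(out_dir, "cohort.csv"))
    jsonlite::write_json(list(n = spec$n, stage_mix = spec$stage_mix,
                              seed = spec$seed),
                         file.path(out_dir, "spec.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}

#' Stage-midpoint training target
#'
#' Desired network outputs sit at the midpoints of the four DPC bands so
#' that sub-model scores live directly on the DPC scale:
#' I -> 0.125, II -> 0.375, III -> 0.625, IV -> 0.875.
#'
#' @param stage Character or integer stage vector.
#' @return Numeric targets in (0, 1).
#' @export
stage_target <- function(stage) {
  idx <- if (is.character(stage)) match(stage, c("I", "II", "III", "IV"))
         else as.integer(stage)
  if (any(is.na(idx)) || any(idx < 1 | idx > 4)) stop("invalid stage")
  c(0.125, 0.375, 0.625, 0.875)[idx]
}
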