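# Run configuration: one nested list binding together the imaging
# parameters, reference ranges, the two network configurations, the
# fusion weight table and evaluation settings; JSON round-trip with
# unknown-key rejection and an md5 provenance hash.

#' Default run configuration
#'
#' @param seed Root seed used to derive the two network seeds.
#' @return Nested named list of class `"run_config"`.
#' @export
default_run_config <- function(seed = 1L) {
  seed <- as.integer(seed)
  list(
    seed = seed,
    imaging = list(alpha = 0.30, beta = 0.59, gamma = 0.11, sigma = 1.4,
                   radius = 2L, t_high_quantile = 0.9, t_low_fraction = 0.4,
                   min_area = pi * 7.5^2, min_gray = 180),
    ranges = default_ranges(),
    marker_net = list(layer_sizes = c(6L, 4L, 1L), eta_w = 0.9, eta_b = 0.9,
                      momentum = 0.7, tolerance = 1e-4, init_low = 0,
                      init_high = 0.5, max_epochs = 4000L, rate_floor = 1e-4,
                      seed = (seed * 13L + 1L) %% 2147483647L),
    image_net = list(layer_sizes = c(2L, 3L, 1L), eta_w = 0.9, eta_b = 0.9,
                     momentum = 0.7, tolerance = 1e-4, init_low = 0,
                     init_high = 0.5, max_epochs = 4000L, rate_floor = 1e-4,
                     seed = (seed * 13L + 2L) %% 2147483647L),
    fusion = list(early_early = 0.6, late_late = 0.4, late_early = 0.8,
                  early_late = 0.2),
    evaluation = list(positive_stages = c("III", "IV"))
  )
}

.config_imaging_params <- function(config) {
  im <- config$imaging
  imaging_params(weights = grayscale_weights(im$alpha, im$beta, im$gamma),
                 sigma = im$sigma, radius = im$radius,
                 t_high_quantile = im$t_high_quantile,
                 t_low_fraction = im$t_low_fraction,
                 min_area = im$min_area, min_gray = im$min_gray)
}

.config_net <- function(nc) {
  do.call(network_config, nc)
}

.config_ranges <- function(config) {
  r <- config$ranges
  data.frame(indicator = as.character(r$indicator),
             lower = as.numeric(r$lower), upper = as.numeric(r$upper),
             cap = as.numeric(r$cap), stringsAsFactors = FALSE)
}

.config_fusion <- function(config) do.call(fusion_table, config$fusion)

#' Save / load a run configuration as JSON
#'
#' `load_run_config()` rejects files containing keys the package does not
#' know, so typos never silently fall back to defaults.
#'
#' @param config A run-config list (see [default_run_config()]).
#' @param path JSON path.
#' @return `path` invisibly (`save_run_config`); the config list
#'   (`load_run_config`).
#' @export
save_run_config <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname save_run_config
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  ref <- default_run_config()
  check_keys <- function(got, want, where) {
    unknown <- setdiff(names(got), names(want))
    if (length(unknown))
      stop("unknown config key(s) in ", where, ": ",
           paste(unknown, collapse = ", "))
  }
  check_keys(cfg, ref, "top level")
  for (sect in c("imaging", "marker_net", "image_net", "fusion", "evaluation"))
    if (!is.null(cfg[[sect]])) check_keys(cfg[[sect]], ref[[sect]], sect)
  out <- utils::modifyList(ref, cfg)
  out$ranges <- .config_ranges(out)
  for (nn in c("marker_net", "image_net")) {
    out[[nn]]$layer_sizes <- as.integer(out[[nn]]$layer_sizes)
    out[[nn]]$max_epochs <- as.integer(out[[nn]]$max_epochs)
    out[[nn]]$seed <- as.integer(out[[nn]]$seed)
  }
  out
}

#' md5 hash of a configuration (provenance)
#'
#' @param config A run-config list.
#' @return Character md5 digest of the canonical JSON serialisation.
#' @export
config_hash <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  save_run_config(config, tf)
  unname(tools::md5sum(tf))
}
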