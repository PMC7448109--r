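# Serum-marker panel assembly, validation against the normal reference
# ranges, and min-max scaling of the combined marker + image feature vector.

.FEATURES <- c("tpsa", "rbc", "hb", "fpsa", "pap", "psma", "area", "gray_level")
.MARKERS <- .FEATURES[1:6]

#' A six-marker serum panel
#'
#' Units: TPSA ng/ml, RBC g/100 ml (as printed in the reference table, and
#' carried opaquely), HB g/L, FPSA ug/L, PAP ng/ml, PSMA ng/ml.
#'
#' @param tpsa,rbc,hb,fpsa,pap,psma Marker values; `NA` marks missingness.
#' @return Named list of class `"marker_panel"`.
#' @export
marker_panel <- function(tpsa = NA_real_, rbc = NA_real_, hb = NA_real_,
                         fpsa = NA_real_, pap = NA_real_, psma = NA_real_) {
  structure(list(tpsa = tpsa, rbc = rbc, hb = hb, fpsa = fpsa,
                 pap = pap, psma = psma), class = "marker_panel")
}

#' Default reference ranges
#'
#' One row per indicator with the normal range (`lower`, `upper`) and a
#' plausibility `cap` above which a value is treated as a recording error
#' rather than disease signal. Normal ranges: TPSA 0-4 ng/ml, FPSA 4-20
#' ug/L, HB 120-165 g/L, RBC 12-15 g/100 ml, PAP 0-3.5 ng/ml, PSMA 0-4
#' ng/ml, lesion area < 15 mm (equivalent-circle diameter), gray level
#' < 180. Caps are configurable plumbing, not clinical claims.
#'
#' @param image_px Pixel count of the image (cap for the area feature).
#' @return Data frame with columns `indicator`, `lower`, `upper`, `cap`.
#' @export
default_ranges <- function(image_px = 128 * 128) {
  data.frame(
    indicator = .FEATURES,
    lower = c(0, 12, 120, 4, 0, 0, 0, 0),
    upper = c(4, 15, 165, 20, 3.5, 4, pi * 7.5^2, 180),
    cap   = c(1000, 25, 250, 500, 100, 100, image_px, 255),
    stringsAsFactors = FALSE
  )
}

.range_row <- function(ranges, name) {
  i <- match(name, ranges$indicator)
  if (is.na(i)) stop("unknown indicator: ", name)
  ranges[i, ]
}

#' Upper bound of an indicator's normal range
#'
#' The largest value the validator still classifies as normal.
#'
#' @param indicator Indicator name (e.g. `"tpsa"`, case-insensitive).
#' @param ranges Reference ranges, see [default_ranges()].
#' @return Numeric upper bound.
#' @export
largest_normal <- function(indicator, ranges = default_ranges()) {
  .range_row(ranges, tolower(indicator))$upper
}

#' Validate a marker panel against plausibility bounds
#'
#' A field is `missing` when absent or `NA`, `nonnumeric` when not a
#' number, `out_of_range` when negative or above the plausibility cap, and
#' `ok` otherwise. Values above the normal range but below the cap are
#' accepted: they are disease signal, not errors. The panel is `accepted`
#' iff every field is `ok`.
#'
#' @param panel A [marker_panel()] (or named list with the six markers).
#' @param ranges Reference ranges.
#' @param id Optional record identifier carried into the report.
#' @return List of class `"validation_report"` with `id`, `field_status`
#'   (named character), `accepted`.
#' @export
validate_record <- function(panel, ranges = default_ranges(), id = NA) {
  status <- vapply(.MARKERS, function(m) {
    v <- panel[[m]]
    if (is.null(v) || length(v) == 0 || all(is.na(v)))
      return("missing")
    if (is.character(v)) {
      vn <- suppressWarnings(as.numeric(v))
      if (is.na(vn)) return("nonnumeric")
      v <- vn
    }
    if (!is.numeric(v) || !is.finite(v)) return("nonnumeric")
    cap <- .range_row(ranges, m)$cap
    if (v < 0 || v > cap) return("out_of_range")
    "ok"
  }, character(1))
  structure(list(id = id, field_status = status,
                 accepted = all(status == "ok")),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("Record %s: %s\n", as.character(x$id),
              if (x$accepted) "accepted" else "rejected"))
  bad <- x$field_status[x$field_status != "ok"]
  if (length(bad))
    cat(paste(sprintf("  %s: %s", names(bad), bad), collapse = "\n"), "\n")
  invisible(x)
}

#' Min-max scale the eight features to \[0, 1\]
#'
#' Each feature is mapped by `(value - lower) / (cap - lower)` and clipped
#' to \[0, 1\]. Output order is fixed: tpsa, rbc, hb, fpsa, pap, psma,
#' area, gray_level.
#'
#' @param panel A validated [marker_panel()].
#' @param feats Named list/vector with `area` and `gray_level`.
#' @param ranges Reference ranges.
#' @return Named numeric vector of length 8 in \[0, 1\].
#' @export
scale_inputs <- function(panel, feats, ranges = default_ranges()) {
  rep_ <- validate_record(panel, ranges)
  if (!rep_$accepted)
    stop("panel rejected by validation: ",
         paste(names(rep_$field_status)[rep_$field_status != "ok"], collapse = ", "))
  vals <- c(vapply(.MARKERS, function(m) as.numeric(panel[[m]]), numeric(1)),
            area = as.numeric(feats[["area"]]),
            gray_level = as.numeric(feats[["gray_level"]]))
  out <- vapply(seq_along(.FEATURES), function(i) {
    r <- .range_row(ranges, .FEATURES[i])
    min(1, max(0, (vals[[i]] - r$lower) / (r$cap - r$lower)))
  }, numeric(1))
  names(out) <- .FEATURES
  out
}

#' Split the scaled feature vector into its two channels
#'
#' `assemble_acp()` returns the six scaled serum markers (the disease
#' channel); `assemble_ahp()` the two scaled image features. Their
#' concatenation round-trips the input exactly.
#'
#' @param scaled Length-8 vector from [scale_inputs()].
#' @return Numeric vector of length 6 (ACP) or 2 (AHP).
#' @export
assemble_acp <- function(scaled) {
  if (length(scaled) != 8) stop("scaled vector must have length 8")
  scaled[1:6]
}

#' @rdname assemble_acp
#' @export
assemble_ahp <- function(scaled) {
  if (length(scaled) != 8) stop("scaled vector must have length 8")
  scaled[7:8]
}

#' Read a cohort CSV
#'
#' Expected header: `patient_id,tpsa,rbc,hb,fpsa,pap,psma[,area,gray_level][,stage]`.
#'
#' @param path CSV path.
#' @return Data frame.
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", .MARKERS)
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("cohort CSV missing columns: ", paste(miss, collapse = ", "))
  df
}

#' Write a cohort data frame as CSV
#'
#' @param df Cohort data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
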