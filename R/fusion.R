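# Rule-based fusion of the marker-channel and image-channel scores into
# the DPC decision score, the clinical stage, and a treatment
# recommendation; plus confusion-matrix / ROC evaluation.

.STAGES <- c("I", "II", "III", "IV")

.TREATMENT <- c(
  I   = "Pay attention to physical changes and observe carefully",
  II  = "Prostatectomy, radioactive implantation",
  III = "Endocrine therapy, orchiectomy (nonsteroidal antiandrogen intermittent therapy)",
  IV  = "Chemotherapy (CTX, 5-FU, ADM, VLB, and PTX)"
)

#' Clinical stage of a DPC score
#'
#' Half-open bands, boundary values belonging to the lower stage:
#' (0, 0.25\] -> I, (0.25, 0.50\] -> II, (0.50, 0.75\] -> III,
#' (0.75, 1.00\] -> IV. Scores outside (0, 1\] are rejected (a sigmoid
#' output can never be exactly 0).
#'
#' @param score Numeric vector of DPC scores in (0, 1\].
#' @return Character vector of stages `"I"`..`"IV"`.
#' @export
stage_of_score <- function(score) {
  if (any(!is.finite(score)) || any(score <= 0) || any(score > 1))
    stop("DPC score must lie in (0, 1]")
  out <- character(length(score))
  out[score <= 0.25] <- "I"
  out[score > 0.25 & score <= 0.50] <- "II"
  out[score > 0.50 & score <= 0.75] <- "III"
  out[score > 0.75] <- "IV"
  out
}

#' Early/late band of a stage
#'
#' Stages I and II are `"early"`, III and IV `"late"` (image findings are
#' markedly more conspicuous in late disease, which drives the rule
#' table).
#'
#' @param stage Character vector of stages.
#' @return Character vector, `"early"` or `"late"`.
#' @export
band_of <- function(stage) {
  if (!all(stage %in% .STAGES)) stop("invalid stage")
  ifelse(stage %in% c("I", "II"), "early", "late")
}

#' Four-case fusion weight table
#'
#' Disease-channel weights keyed by (disease band, image band). The
#' orderings come from the rule table: when both channels agree early the
#' disease weight is slightly above 1/2; when both agree late, slightly
#' below; on disagreement the early-looking image (late disease) case
#' trusts the markers strongly (>= 0.75) and the late-looking image
#' (early disease) case trusts the image strongly (<= 0.25). The image
#' weight is always `1 - w_disease`.
#'
#' @param early_early,late_late,late_early,early_late Disease weights for
#'   the cases (disease band, image band).
#' @return Named list of class `"fusion_table"`.
#' @export
fusion_table <- function(early_early = 0.6, late_late = 0.4,
                         late_early = 0.8, early_late = 0.2) {
  w <- c(early_early = early_early, late_late = late_late,
         late_early = late_early, early_late = early_late)
  if (any(w <= 0 | w >= 1)) stop("weights must lie in (0, 1)")
  if (early_early <= 0.5) stop("early/early disease weight must exceed 0.5")
  if (late_late >= 0.5) stop("late/late disease weight must be below 0.5")
  if (late_early < 0.75) stop("late-disease/early-image weight must be >= 0.75")
  if (early_late > 0.25) stop("early-disease/late-image weight must be <= 0.25")
  structure(as.list(w), class = "fusion_table")
}

#' Select fusion weights for a band pair
#'
#' Exactly one rule fires for each (disease band, image band) pair; the
#' image weight is `1 - w_disease`.
#'
#' @param disease_band,image_band `"early"` or `"late"`.
#' @param table A [fusion_table()].
#' @return Named numeric vector `c(w_disease, w_image)`.
#' @export
select_weights <- function(disease_band, image_band, table = fusion_table()) {
  stopifnot(inherits(table, "fusion_table"))
  if (!disease_band %in% c("early", "late") ||
      !image_band %in% c("early", "late")) stop("invalid band")
  key <- paste(disease_band, image_band, sep = "_")
  w <- switch(key,
              early_early = table$early_early,
              late_late = table$late_late,
              late_early = table$late_early,
              early_late = table$early_late)
  c(w_disease = w, w_image = 1 - w)
}

#' Fuse the two channel scores into a DPC result
#'
#' `dpc = w_disease * disease_score + w_image * image_score`; the fused
#' score always lies between the two channel scores, and the stage is the
#' band of the fused score.
#'
#' @param disease_score,image_score Sub-model outputs in (0, 1).
#' @param weights Length-2 vector `c(w_disease, w_image)` from
#'   [select_weights()], or `NULL` to derive it from the channel bands
#'   with `table`.
#' @param table [fusion_table()] used when `weights` is `NULL`.
#' @return List of class `"dpc_result"`: `dpc`, `stage`, `w_disease`,
#'   `w_image`, `disease_score`, `image_score`.
#' @export
combine_dpc <- function(disease_score, image_score, weights = NULL,
                        table = fusion_table()) {
  if (!is.finite(disease_score) || disease_score <= 0 || disease_score >= 1 ||
      !is.finite(image_score) || image_score <= 0 || image_score >= 1)
    stop("channel scores must lie in (0, 1)")
  if (is.null(weights)) {
    weights <- select_weights(band_of(stage_of_score(disease_score)),
                              band_of(stage_of_score(image_score)), table)
  }
  if (abs(sum(weights) - 1) > 1e-12) stop("weights must sum to 1")
  dpc <- weights[[1]] * disease_score + weights[[2]] * image_score
  structure(list(dpc = dpc, stage = stage_of_score(dpc),
                 w_disease = weights[[1]], w_image = weights[[2]],
                 disease_score = disease_score, image_score = image_score),
            class = "dpc_result")
}

#' Treatment recommendation for a stage
#'
#' Stage I: watchful observation; II: prostatectomy with radioactive
#' implantation; III: endocrine therapy / orchiectomy; IV: chemotherapy
#' (CTX, 5-FU, ADM, VLB, PTX).
#'
#' @param stage `"I"`, `"II"`, `"III"` or `"IV"`.
#' @return List of class `"treatment_plan"` with `stage` and `advice`.
#' @export
recommend_treatment <- function(stage) {
  if (length(stage) != 1 || !stage %in% .STAGES) stop("invalid stage")
  structure(list(stage = stage, advice = unname(.TREATMENT[stage])),
            class = "treatment_plan")
}

#' Diagnose one patient from panel + image features
#'
#' Full chain: validate the marker panel, min-max scale all eight
#' features, run the two trained networks, band both sub-scores, select
#' the fusion weights, fuse into DPC, stage and recommend.
#'
#' @param panel A [marker_panel()].
#' @param feats Named list/vector with `area` and `gray_level` (e.g. from
#'   [extract_lesion_metrics()]).
#' @param marker_net,image_net Trained `"perceptron"` networks (6 and 2
#'   inputs).
#' @param ranges Reference ranges for validation/scaling.
#' @param table [fusion_table()].
#' @param id Optional patient identifier.
#' @return List of class `"diagnosis"`: `patient_id`, `disease_score`,
#'   `image_score`, `w_disease`, `w_image`, `dpc`, `stage`, `advice`.
#' @export
diagnose_patient <- function(panel, feats, marker_net, image_net,
                             ranges = default_ranges(),
                             table = fusion_table(), id = NA) {
  rep_ <- validate_record(panel, ranges, id = id)
  if (!rep_$accepted) {
    bad <- rep_$field_status[rep_$field_status != "ok"]
    stop("record ", as.character(id), " rejected: ",
         paste(sprintf("%s (%s)", names(bad), bad), collapse = ", "))
  }
  scaled <- scale_inputs(panel, feats, ranges)
  d <- predict_score(marker_net, assemble_acp(scaled))
  i <- predict_score(image_net, assemble_ahp(scaled))
  res <- combine_dpc(d, i, table = table)
  plan <- recommend_treatment(res$stage)
  structure(list(patient_id = id, disease_score = d, image_score = i,
                 w_disease = res$w_disease, w_image = res$w_image,
                 dpc = res$dpc, stage = res$stage, advice = plan$advice),
            class = "diagnosis")
}

#' @export
print.diagnosis <- function(x, ...) {
  cat(sprintf("Patient %s: DPC = %.4f -> stage %s\n", as.character(x$patient_id),
              x$dpc, x$stage))
  cat(sprintf("  disease score %.4f (w = %.2f), image score %.4f (w = %.2f)\n",
              x$disease_score, x$w_disease, x$image_score, x$w_image))
  cat("  advice:", x$advice, "\n")
  invisible(x)
}

#' Diagnose a cohort data frame
#'
#' Applies [diagnose_patient()] to every row; rejected records are
#' reported, not silently dropped.
#'
#' @param df Cohort data frame with the marker columns plus `area` and
#'   `gray_level`.
#' @inheritParams diagnose_patient
#' @return List with `reports` (data frame, one row per accepted record)
#'   and `rejects` (data frame `patient_id`, `reason`).
#' @export
diagnose_cohort <- function(df, marker_net, image_net,
                            ranges = default_ranges(),
                            table = fusion_table()) {
  reports <- list(); rejects <- list()
  for (k in seq_len(nrow(df))) {
    row <- df[k, ]
    panel <- marker_panel(tpsa = row$tpsa, rbc = row$rbc, hb = row$hb,
                          fpsa = row$fpsa, pap = row$pap, psma = row$psma)
    res <- tryCatch(
      diagnose_patient(panel, list(area = row$area, gray_level = row$gray_level),
                       marker_net, image_net, ranges, table,
                       id = row$patient_id),
      error = function(e) e)
    if (inherits(res, "error")) {
      rejects[[length(rejects) + 1L]] <-
        data.frame(patient_id = row$patient_id, reason = conditionMessage(res),
                   stringsAsFactors = FALSE)
    } else {
      reports[[length(reports) + 1L]] <-
        data.frame(patient_id = res$patient_id,
                   disease_score = res$disease_score,
                   image_score = res$image_score,
                   w_disease = res$w_disease, w_image = res$w_image,
                   dpc = res$dpc, stage = res$stage, advice = res$advice,
                   stringsAsFactors = FALSE)
    }
  }
  list(reports = if (length(reports)) do.call(rbind, reports) else
         data.frame(patient_id = character(0)),
       rejects = if (length(rejects)) do.call(rbind, rejects) else
         data.frame(patient_id = character(0), reason = character(0)))
}

#' Confusion counts, TPR/FPR and an ROC sweep
#'
#' The positive class defaults to late-stage disease (stage III or IV).
#' `TPR = TP / (TP + FN)`, `FPR = FP / (FP + TN)`; an undefined rate
#' (zero denominator) is `NA`, never 0. When DPC scores are supplied, an
#' ROC curve is computed by sweeping a binarisation threshold over (0, 1).
#'
#' @param predicted,truth Equal-length stage vectors (`"I"`..`"IV"`).
#' @param positive_stages Stages counting as positive.
#' @param dpc Optional numeric DPC scores (same length) for the ROC sweep.
#' @param n_thresholds Number of ROC thresholds.
#' @return List of class `"classifier_eval"`: `tp`, `fp`, `fn`, `tn`,
#'   `tpr`, `fpr`, and (with `dpc`) `roc` data frame with columns
#'   `threshold`, `fpr`, `tpr`.
#' @export
evaluate_classifier <- function(predicted, truth,
                                positive_stages = c("III", "IV"),
                                dpc = NULL, n_thresholds = 101L) {
  if (length(predicted) == 0) stop("empty input")
  if (length(predicted) != length(truth)) stop("length mismatch")
  pp <- predicted %in% positive_stages
  tp_ <- truth %in% positive_stages
  tp <- sum(pp & tp_); fp <- sum(pp & !tp_)
  fn <- sum(!pp & tp_); tn <- sum(!pp & !tp_)
  rate <- function(num, den) if (den == 0) NA_real_ else num / den
  out <- list(tp = tp, fp = fp, fn = fn, tn = tn,
              tpr = rate(tp, tp + fn), fpr = rate(fp, fp + tn))
  if (!is.null(dpc)) {
    if (length(dpc) != length(truth)) stop("dpc length mismatch")
    th <- seq(0, 1, length.out = n_thresholds)
    roc <- t(vapply(th, function(t0) {
      pos <- dpc > t0
      c(fpr = rate(sum(pos & !tp_), sum(!tp_)),
        tpr = rate(sum(pos & tp_), sum(tp_)))
    }, numeric(2)))
    out$roc <- data.frame(threshold = th, fpr = roc[, "fpr"],
                          tpr = roc[, "tpr"])
  }
  structure(out, class = "classifier_eval")
}

#' @export
print.classifier_eval <- function(x, ...) {
  cat(sprintf("TP %d  FP %d  FN %d  TN %d | TPR %s  FPR %s\n",
              x$tp, x$fp, x$fn, x$tn,
              format(x$tpr, digits = 4), format(x$fpr, digits = 4)))
  invisible(x)
}
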