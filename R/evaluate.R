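#' Rank-based AUC
#'
#' Area under the ROC curve computed as the Mann-Whitney concordance
#' probability: the probability a random cancer sample scores above a random
#' control, with ties counted 0.5. Invariant under strictly monotone
#' transforms of the scores.
#'
#' @param scores Numeric scores (higher = more cancer-like).
#' @param labels `"cancer"` / `"control"` labels aligned with `scores`.
#' @return AUC in `[0, 1]`.
#' @export
rank_auc <- function(scores, labels) {
  is1 <- labels == "cancer"
  n1 <- sum(is1)
  n0 <- sum(!is1)
  stopifnot(n1 > 0L, n0 > 0L)
  r <- rank(scores)
  (sum(r[is1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Default colon-segment grouping
#'
#' Maps colon segments to the proximal/distal dichotomy at the splenic
#' flexure.
#'
#' @return Named character vector, segment -> group.
#' @export
default_location_groups <- function() {
  c("cecum" = "proximal", "ileocecal valve" = "proximal",
    "ascending colon" = "proximal", "hepatic flexure" = "proximal",
    "transverse colon" = "proximal",
    "splenic flexure" = "distal", "descending colon" = "distal",
    "sigmoid colon" = "distal", "rectosigmoid" = "distal",
    "rectum" = "distal")
}

#' Classification metrics panel
#'
#' Classifies each scored sample as cancer when its posterior is at or above
#' `threshold`, then reports the confusion counts, overall sensitivity and
#' specificity, sensitivity per tumor stage and per location group, combined
#' early-stage (I + IIA) sensitivity, rank-based AUC, and the ROC points.
#'
#' @param scores A tibble from [score_samples()] (`sample_id`, `posterior`).
#' @param manifest Manifest rows for the scored samples (labels required;
#'   stage/location used for the breakdowns).
#' @param threshold Posterior decision threshold.
#' @param location_groups Named map segment -> group; see
#'   [default_location_groups()].
#' @return An object of class `fragcnv_metrics`.
#' @export
evaluate_classifier <- function(scores, manifest, threshold = 0.5,
                                location_groups = default_location_groups()) {
  if (nrow(scores) == 0L) {
    abort("empty evaluation split", class = "fragcnv_validation_error")
  }
  m <- manifest[match(scores$sample_id, manifest$sample_id), ]
  if (anyNA(m$label)) {
    abort(paste0("scored sample(s) missing from manifest: ",
                 paste(scores$sample_id[is.na(m$label)], collapse = ", ")),
          class = "fragcnv_validation_error")
  }
  truth <- m$label
  pred <- ifelse(scores$posterior >= threshold, "cancer", "control")

  tp <- sum(pred == "cancer" & truth == "cancer")
  fn <- sum(pred == "control" & truth == "cancer")
  tn <- sum(pred == "control" & truth == "control")
  fp <- sum(pred == "cancer" & truth == "control")

  pct <- function(num, den) if (den == 0) NA_real_ else round(100 * num / den, 1)

  correct_cancer <- pred == "cancer" & truth == "cancer"
  per_stage <- tibble::tibble(stage = m$stage, hit = correct_cancer,
                              cancer = truth == "cancer") |>
    dplyr::filter(.data$cancer, !is.na(.data$stage)) |>
    dplyr::group_by(.data$stage) |>
    dplyr::summarise(n = dplyr::n(), tp = sum(.data$hit),
                     sensitivity = pct(sum(.data$hit), dplyr::n()),
                     .groups = "drop")

  group <- unname(location_groups[m$location])
  per_location <- tibble::tibble(group = group, hit = correct_cancer,
                                 cancer = truth == "cancer") |>
    dplyr::filter(.data$cancer, !is.na(.data$group)) |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(n = dplyr::n(), tp = sum(.data$hit),
                     sensitivity = pct(sum(.data$hit), dplyr::n()),
                     .groups = "drop")

  early <- truth == "cancer" & !is.na(m$stage) & m$stage %in% c("I", "IIA")
  early_sens <- pct(sum(correct_cancer & early), sum(early))

  auc <- rank_auc(scores$posterior, truth)
  thr <- c(Inf, sort(unique(scores$posterior), decreasing = TRUE))
  roc <- purrr::map_dfr(thr, function(t) {
    p <- scores$posterior >= t
    tibble::tibble(threshold = t,
                   fpr = sum(p & truth == "control") / max(1, tn + fp),
                   tpr = sum(p & truth == "cancer") / max(1, tp + fn))
  })

  structure(
    list(confusion = c(TP = tp, FN = fn, TN = tn, FP = fp),
         sensitivity = pct(tp, tp + fn),
         specificity = pct(tn, tn + fp),
         early_stage_sensitivity = early_sens,
         per_stage = per_stage,
         per_location = per_location,
         auc = auc, threshold = threshold, roc = roc,
         n = nrow(scores)),
    class = "fragcnv_metrics"
  )
}

#' @export
print.fragcnv_metrics <- function(x, ...) {
  cat("<fragcnv classification metrics>\n")
  cat(sprintf("  n = %d  (TP %d, FN %d, TN %d, FP %d) at threshold %.2f\n",
              x$n, x$confusion[["TP"]], x$confusion[["FN"]],
              x$confusion[["TN"]], x$confusion[["FP"]], x$threshold))
  cat(sprintf("  sensitivity %.1f%%  specificity %.1f%%  AUC %.3f\n",
              x$sensitivity, x$specificity, x$auc))
  if (!is.na(x$early_stage_sensitivity)) {
    cat(sprintf("  early-stage (I+IIA) sensitivity %.1f%%\n",
                x$early_stage_sensitivity))
  }
  if (nrow(x$per_stage) > 0L) {
    cat("  per stage:",
        paste(sprintf("%s %.0f%% (%d/%d)", x$per_stage$stage,
                      x$per_stage$sensitivity, x$per_stage$tp,
                      x$per_stage$n), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @exportS3Method generics::glance
glance.fragcnv_metrics <- function(x, ...) {
  tibble::tibble(n = x$n, tp = x$confusion[["TP"]], fn = x$confusion[["FN"]],
                 tn = x$confusion[["TN"]], fp = x$confusion[["FP"]],
                 sensitivity = x$sensitivity, specificity = x$specificity,
                 early_stage_sensitivity = x$early_stage_sensitivity,
                 auc = x$auc, threshold = x$threshold)
}

#' @exportS3Method generics::tidy
tidy.fragcnv_metrics <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(group = "overall", n = x$n,
                   tp = x$confusion[["TP"]], sensitivity = x$sensitivity),
    dplyr::transmute(x$per_stage, group = paste0("stage ", .data$stage),
                     n = .data$n, tp = .data$tp,
                     sensitivity = .data$sensitivity),
    dplyr::transmute(x$per_location, group = paste0("location ", .data$group),
                     n = .data$n, tp = .data$tp,
                     sensitivity = .data$sensitivity)
  )
}

#' ROC curve of a metrics panel
#'
#' @param object A `fragcnv_metrics` object.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.fragcnv_metrics <- function(object, ...) {
  ggplot2::ggplot(object$roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step(linewidth = 0.8, color = "#2166ac") +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         color = "grey60") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate (1 - specificity)",
      y = "True positive rate (sensitivity)",
      title = sprintf("ROC, AUC = %.3f", object$auc)
    ) +
    ggplot2::theme_minimal()
}
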