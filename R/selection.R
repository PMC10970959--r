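#' Batch-wise correlation filtering of region features
#'
#' Redundant (mutually correlated) region features carry no independent
#' information for the downstream classifier, so they are removed before
#' model fitting. Features are partitioned into consecutive batches of
#' `batch_size` (genomic order; the last batch may be smaller). Within each
#' batch, the Pearson correlation matrix across training samples is computed;
#' each feature's score is the mean of `|r|` with all other features in its
#' batch, and features scoring strictly above `threshold` are removed in one
#' simultaneous pass. Constant (zero-variance) features get score 0 and are
#' kept.
#'
#' @param features A `fragcnv_features` tibble restricted to training
#'   samples, or any tibble with `sample_id` plus numeric feature columns.
#' @param batch_size Number of consecutive features per batch.
#' @param threshold Removal cutoff on mean absolute correlation.
#' @param iterative If `TRUE`, use greedy elimination instead: repeatedly
#'   drop the worst-scoring feature above threshold and rescore. Off by
#'   default; the single-pass rule is the reference behavior.
#' @return An object of class `fragcnv_selection`: list with a per-feature
#'   `table` tibble (`feature_id`, `batch`, `mean_abs_r`, `kept`),
#'   `kept_feature_ids`, `removed_feature_ids`, `batch_size`, `threshold`.
#' @export
correlation_filter <- function(features, batch_size = 1000, threshold = 0.7,
                               iterative = FALSE) {
  x <- feature_matrix(features)
  if (ncol(x) < 2L) {
    abort("need at least 2 features", class = "fragcnv_validation_error")
  }
  if (nrow(x) < 3L) {
    abort("need at least 3 samples", class = "fragcnv_validation_error")
  }
  if (!all(is.finite(x))) {
    abort("non-finite feature values", class = "fragcnv_validation_error")
  }
  p <- ncol(x)
  batch <- ceiling(seq_len(p) / batch_size)

  score_batch <- function(xb) {
    m <- ncol(xb)
    if (m == 1L) return(0)
    sds <- apply(xb, 2L, sd)
    nonconst <- sds > 0
    absr <- matrix(0, m, m)
    if (sum(nonconst) >= 2L) {
      absr[nonconst, nonconst] <- abs(cor(xb[, nonconst, drop = FALSE]))
    }
    diag(absr) <- 0
    colSums(absr) / (m - 1)
  }

  tab <- purrr::map_dfr(unique(batch), function(b) {
    cols <- which(batch == b)
    xb <- x[, cols, drop = FALSE]
    if (!iterative) {
      score <- score_batch(xb)
      kept <- score <= threshold
    } else {
      alive <- rep(TRUE, length(cols))
      score <- score_batch(xb)
      repeat {
        s <- score_batch(xb[, alive, drop = FALSE])
        score[alive] <- s
        if (sum(alive) < 2L || max(s) <= threshold) break
        worst <- which(alive)[which.max(s)]
        alive[worst] <- FALSE
      }
      kept <- alive
    }
    tibble::tibble(feature_id = colnames(x)[cols], batch = b,
                   mean_abs_r = score, kept = kept)
  })

  structure(
    list(table = tab,
         kept_feature_ids = tab$feature_id[tab$kept],
         removed_feature_ids = tab$feature_id[!tab$kept],
         batch_size = batch_size, threshold = threshold,
         iterative = iterative),
    class = "fragcnv_selection"
  )
}

#' @export
print.fragcnv_selection <- function(x, ...) {
  cat("<fragcnv correlation filter>\n")
  cat("  batch size:", x$batch_size, " threshold:", x$threshold,
      if (x$iterative) " (iterative)" else " (single pass)", "\n")
  cat("  kept", length(x$kept_feature_ids), "of",
      nrow(x$table), "features\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.fragcnv_selection <- function(x, ...) x$table

#' Per-feature cancer-versus-control rank test
#'
#' Two-sided Wilcoxon rank-sum (Mann-Whitney) test of each feature between
#' cancer and control samples. Used as an optional differential-signal
#' post-filter after correlation filtering, and to locate the most
#' discriminative region.
#'
#' @param features A feature tibble (training samples).
#' @param labels Character vector of `"cancer"` / `"control"` labels aligned
#'   with the feature rows (or a manifest to join on `sample_id`).
#' @return A tibble `feature_id`, `statistic` (rank-sum W of the cancer
#'   group), `p_value`, sorted as the input features.
#' @export
differential_test <- function(features, labels) {
  if (is.data.frame(labels)) {
    labels <- labels$label[match(features$sample_id, labels$sample_id)]
  }
  x <- feature_matrix(features)
  stopifnot(length(labels) == nrow(x))
  n1 <- sum(labels == "cancer")
  n0 <- sum(labels == "control")
  if (n1 < 2L || n0 < 2L) {
    abort("each label needs at least 2 samples",
          class = "fragcnv_validation_error")
  }
  res <- apply(x, 2L, function(v) {
    wt <- suppressWarnings(
      wilcox.test(v[labels == "cancer"], v[labels == "control"],
                  alternative = "two.sided")
    )
    p <- wt$p.value
    if (!is.finite(p)) p <- 1 # all values tied: no evidence against the null
    c(unname(wt$statistic), p)
  })
  tibble::tibble(feature_id = colnames(x),
                 statistic = unname(res[1L, ]), p_value = unname(res[2L, ]))
}
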