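#' Fit a shrinkage linear discriminant classifier
#'
#' Gaussian LDA with a pooled within-class covariance shrunk toward its
#' diagonal: `Sigma = (1 - alpha) * S + alpha * diag(S)`. Shrinkage is
#' required in the regime typical of region features (thousands of bins,
#' tens of plasma samples), where the sample covariance is singular. With
#' `shrinkage = NULL` the intensity is estimated from the data by the
#' Schafer-Strimmer analytic formula (variance of the off-diagonal sample
#' covariances over their squared magnitude), clamped to `[0, 1]`.
#'
#' @param features A feature tibble (training samples, selected features
#'   only) or a numeric samples-by-features matrix.
#' @param labels `"cancer"` / `"control"` labels aligned with rows (or a
#'   manifest to join on `sample_id`).
#' @param shrinkage Shrinkage intensity in `[0, 1]`, or `NULL` to
#'   auto-estimate.
#' @param priors Named class priors `c(cancer = , control = )`; default the
#'   observed training frequencies.
#' @return An object of class `fragcnv_lda`: class means, shrunk covariance
#'   factors, discriminant direction `beta = Sigma^{-1} (mu_cancer -
#'   mu_control)`, intercept, priors, `alpha`, and `feature_ids`.
#' @export
fit_lda <- function(features, labels, shrinkage = NULL, priors = NULL) {
  if (is.data.frame(labels)) {
    labels <- labels$label[match(features$sample_id, labels$sample_id)]
  }
  x <- if (is.matrix(features)) features else feature_matrix(features)
  n <- nrow(x)
  p <- ncol(x)
  stopifnot(length(labels) == n)
  if (n < 4L) {
    abort("need at least 4 training samples", class = "fragcnv_validation_error")
  }
  if (!all(c("cancer", "control") %in% labels)) {
    abort("both classes must be present in training data",
          class = "fragcnv_validation_error")
  }
  idx1 <- labels == "cancer"
  mu1 <- colMeans(x[idx1, , drop = FALSE])
  mu0 <- colMeans(x[!idx1, , drop = FALSE])
  xc <- x
  xc[idx1, ] <- sweep(x[idx1, , drop = FALSE], 2L, mu1)
  xc[!idx1, ] <- sweep(x[!idx1, , drop = FALSE], 2L, mu0)
  # maximum-likelihood pooled covariance (divide by n, not n - 2) so the fit
  # is invariant to duplicating the training set at fixed shrinkage
  s <- crossprod(xc) / n

  alpha <- shrinkage
  if (is.null(alpha)) {
    alpha <- estimate_shrinkage(xc, n)
  }
  if (alpha < 0 || alpha > 1) {
    abort("shrinkage must lie in [0, 1]", class = "fragcnv_validation_error")
  }
  if (alpha == 0 && p >= n) {
    abort(paste0("pooled covariance is singular (", p, " features, ", n,
                 " samples); use shrinkage > 0 or shrinkage = NULL"),
          class = "fragcnv_validation_error")
  }
  sigma <- (1 - alpha) * s
  diag(sigma) <- diag(s) # (1-a)*s_ii + a*s_ii

  beta <- tryCatch(
    drop(solve(sigma, mu1 - mu0)),
    error = function(e) {
      abort(paste0("pooled covariance is singular; increase shrinkage (",
                   conditionMessage(e), ")"),
            class = "fragcnv_validation_error")
    }
  )
  if (is.null(priors)) {
    priors <- c(cancer = mean(idx1), control = mean(!idx1))
  }
  priors <- priors / sum(priors)
  intercept <- -sum((mu1 + mu0) / 2 * beta) + log(priors[["cancer"]] /
                                                    priors[["control"]])
  structure(
    list(mu_cancer = mu1, mu_control = mu0, beta = beta,
         intercept = unname(intercept), alpha = alpha, priors = priors,
         feature_ids = colnames(x), n_train = n),
    class = "fragcnv_lda"
  )
}

# Schafer-Strimmer shrinkage intensity toward the diagonal target, computed
# from within-class centered data (pooled estimate).
estimate_shrinkage <- function(xc, n) {
  m <- nrow(xc)
  s <- crossprod(xc) / n
  x2 <- xc^2
  # var of covariance entries: (m/(m-1)^3) * sum_k (w_kij - mean_ij)^2
  vs <- (crossprod(x2) - crossprod(xc)^2 / m) * m / ((m - 1)^3)
  diag(vs) <- 0
  s_off <- s
  diag(s_off) <- 0
  denom <- sum(s_off^2)
  if (denom <= 0) return(0)
  min(1, max(0, sum(vs) / denom))
}

#' Posterior cancer probability under a fitted LDA model
#'
#' @param model A `fragcnv_lda` fit.
#' @param features A feature tibble or matrix containing the model's
#'   `feature_ids`.
#' @return A tibble `sample_id`, `ld` (linear discriminant value), and
#'   `posterior` (probability of cancer, strictly monotone in `ld`).
#' @export
score_samples <- function(model, features) {
  x <- if (is.matrix(features)) {
    missing_ids <- setdiff(model$feature_ids, colnames(features))
    if (length(missing_ids) > 0L) {
      abort(paste0("missing feature(s): ",
                   paste(head(missing_ids, 5L), collapse = ", ")),
            class = "fragcnv_validation_error")
    }
    features[, model$feature_ids, drop = FALSE]
  } else {
    feature_matrix(features, model$feature_ids)
  }
  ld <- drop(x %*% model$beta) + model$intercept
  tibble::tibble(
    sample_id = rownames(x) %||% as.character(seq_len(nrow(x))),
    ld = unname(ld),
    posterior = unname(plogis(ld))
  )
}

#' @export
print.fragcnv_lda <- function(x, ...) {
  cat("<fragcnv shrinkage LDA>\n")
  cat("  features:", length(x$feature_ids),
      " training samples:", x$n_train, "\n")
  cat(sprintf("  shrinkage alpha: %.4f\n", x$alpha))
  cat(sprintf("  priors: cancer %.3f / control %.3f\n",
              x$priors[["cancer"]], x$priors[["control"]]))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.fragcnv_lda <- function(x, ...) {
  tibble::tibble(feature_id = x$feature_ids,
                 coefficient = unname(x$beta),
                 mean_cancer = unname(x$mu_cancer),
                 mean_control = unname(x$mu_control))
}

#' @exportS3Method generics::glance
glance.fragcnv_lda <- function(x, ...) {
  tibble::tibble(n_features = length(x$feature_ids), n_train = x$n_train,
                 alpha = x$alpha, intercept = x$intercept,
                 prior_cancer = x$priors[["cancer"]])
}
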