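mk_feat <- function(x, ids = paste0("s", seq_len(nrow(x)))) {
  colnames(x) <- colnames(x) %||% paste0("f", seq_len(ncol(x)))
  dplyr::bind_cols(tibble::tibble(sample_id = ids), tibble::as_tibble(x))
}

test_that("symmetric one-dimensional classes split at zero", {
  x <- matrix(c(-1.5, -1, -0.5, 0.5, 1, 1.5), ncol = 1)
  labels <- c(rep("control", 3), rep("cancer", 3))
  fit <- fit_lda(mk_feat(x), labels, shrinkage = 0)
  sc <- score_samples(fit, mk_feat(matrix(c(-0.01, 0.01, 0), ncol = 1)))
  expect_lt(sc$posterior[1], 0.5)
  expect_gt(sc$posterior[2], 0.5)
  expect_equal(sc$posterior[3], 0.5) # midpoint of class means
  # class means score confidently for their own class
  m <- score_samples(fit, mk_feat(matrix(c(1, -1), ncol = 1)))
  expect_gt(m$posterior[1], 0.5)
  expect_lt(m$posterior[2], 0.5)
})

test_that("duplicating the training set leaves the model unchanged", {
  x <- with_local_seed(8, matrix(rnorm(40), 10, 4))
  labels <- rep(c("cancer", "control"), 5)
  f1 <- fit_lda(mk_feat(x), labels, shrinkage = 0.3)
  f2 <- fit_lda(mk_feat(rbind(x, x), ids = paste0("s", 1:20)),
                rep(labels, 2), shrinkage = 0.3)
  expect_equal(f1$beta, f2$beta, tolerance = 1e-8)
  expect_equal(f1$intercept, f2$intercept, tolerance = 1e-8)
})

test_that("estimated discriminant direction approaches the analytic one", {
  sigma <- matrix(c(1, 0.6, 0.6, 2), 2, 2)
  mu0 <- c(0, 0)
  mu1 <- c(1, 0.5)
  ch <- chol(sigma)
  x <- with_local_seed(15, {
    z <- matrix(rnorm(400 * 2), 400, 2) %*% ch
    z[201:400, ] <- sweep(z[201:400, ], 2, mu1, "+")
    z
  })
  labels <- rep(c("control", "cancer"), each = 200)
  fit <- fit_lda(mk_feat(x), labels, shrinkage = 0)
  analytic <- solve(sigma, mu1 - mu0)
  angle <- acos(sum(fit$beta * analytic) /
                  sqrt(sum(fit$beta^2) * sum(analytic^2))) * 180 / pi
  expect_lt(angle, 5)
  # cross-check against an independent LDA implementation
  mass_fit <- MASS::lda(x, grouping = labels)
  mass_dir <- drop(mass_fit$scaling)
  cosang <- abs(sum(fit$beta * mass_dir) /
                  sqrt(sum(fit$beta^2) * sum(mass_dir^2)))
  expect_gt(cosang, 0.999)
})

test_that("singular covariance without shrinkage is refused with advice", {
  x <- with_local_seed(9, matrix(rnorm(6 * 10), 6, 10))
  labels <- rep(c("cancer", "control"), 3)
  expect_error(fit_lda(mk_feat(x), labels, shrinkage = 0), "shrinkage",
               class = "fragcnv_validation_error")
  # auto shrinkage handles p >> n
  fit <- fit_lda(mk_feat(x), labels)
  expect_true(fit$alpha > 0 && fit$alpha <= 1)
  expect_error(fit_lda(mk_feat(x[1:3, ]), labels[1:3]), "4 training",
               class = "fragcnv_validation_error")
  expect_error(fit_lda(mk_feat(x), rep("cancer", 6)), "both classes",
               class = "fragcnv_validation_error")
})

test_that("scoring requires the model's features", {
  x <- with_local_seed(10, matrix(rnorm(24), 6, 4))
  fit <- fit_lda(mk_feat(x), rep(c("cancer", "control"), 3), shrinkage = 0.5)
  expect_error(score_samples(fit, mk_feat(x[, 1:2, drop = FALSE])),
               "f3", class = "fragcnv_validation_error")
})

test_that("rank AUC equals brute-force pairwise concordance", {
  for (s in 1:6) {
    n1 <- 5 + s
    n0 <- 9 - (s %% 3)
    scores <- with_local_seed(s, round(rnorm(n1 + n0), 1)) # ties likely
    labels <- c(rep("cancer", n1), rep("control", n0))
    oracle <- 0
    for (i in seq_len(n1)) {
      for (j in seq_len(n0)) {
        d <- scores[i] - scores[n1 + j]
        oracle <- oracle + (d > 0) + 0.5 * (d == 0)
      }
    }
    oracle <- oracle / (n1 * n0)
    expect_equal(rank_auc(scores, labels), oracle)
    # invariance under strictly monotone transforms
    expect_equal(rank_auc(plogis(3 * scores + 2), labels), oracle)
    proc_auc <- as.numeric(suppressMessages(
      pROC::auc(pROC::roc(labels, scores, levels = c("control", "cancer"),
                          direction = "<", quiet = TRUE))
    ))
    expect_equal(oracle, proc_auc)
  }
})

test_that("label-permuted scores center the AUC on one half", {
  scores <- with_local_seed(20, rnorm(24))
  labels <- rep(c("cancer", "control"), each = 12)
  aucs <- with_local_seed(21, {
    vapply(1:10000, function(i) rank_auc(scores, sample(labels)), 0)
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.02)
})

test_that("the metrics panel reproduces hand-computed rates", {
  # 12 cancers (10 called) + 12 controls (11 called correctly)
  manifest <- tibble::tibble(
    sample_id = paste0("s", 1:24),
    label = rep(c("cancer", "control"), each = 12),
    stage = c(rep("I", 4), rep("IIA", 4), rep("III", 4), rep(NA, 12)),
    location = c(rep("cecum", 6), rep("rectum", 6), rep(NA, 12)),
    chemistry = "WGES", split = "test", fragments_path = "x.bed"
  )
  post <- c(
    0.9, 0.8, 0.7, 0.3,   # stage I: 3/4 called
    0.95, 0.85, 0.75, 0.65, # stage IIA: 4/4
    0.9, 0.8, 0.7, 0.4,   # stage III: 3/4
    rep(0.2, 11), 0.8     # controls: one false positive
  )
  scores <- tibble::tibble(sample_id = manifest$sample_id, posterior = post)
  m <- evaluate_classifier(scores, manifest)
  expect_equal(unname(m$confusion), c(10, 2, 11, 1))
  expect_equal(m$sensitivity, 83.3)
  expect_equal(m$specificity, 91.7)
  expect_equal(m$per_stage$sensitivity[m$per_stage$stage == "I"], 75)
  expect_equal(m$per_stage$sensitivity[m$per_stage$stage == "IIA"], 100)
  expect_equal(m$early_stage_sensitivity, 87.5)
  expect_equal(sum(m$per_stage$tp), m$confusion[["TP"]])
  loc <- m$per_location
  expect_equal(loc$sensitivity[loc$group == "proximal"],
               round(100 * sum(post[1:6] >= 0.5) / 6, 1))
  # perfectly separated scores
  sep <- tibble::tibble(sample_id = manifest$sample_id,
                        posterior = c(rep(0.9, 12), rep(0.1, 12)))
  expect_equal(evaluate_classifier(sep, manifest)$auc, 1.0)
  expect_error(evaluate_classifier(scores[0, ], manifest), "empty",
               class = "fragcnv_validation_error")
})
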