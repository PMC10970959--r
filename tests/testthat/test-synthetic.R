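test_that("genome construction is deterministic and tiles the region", {
  region <- genomic_region("chr18", 0, 1e7)
  g1 <- build_genome(region, bin_width = 5000, seed = 3)
  g2 <- build_genome(region, bin_width = 5000, seed = 3)
  expect_equal(nrow(g1$bins), 2000L)
  expect_identical(g1$bins, g2$bins)
  expect_error(build_genome(genomic_region("chr18", 0, 100), bin_width = 5000),
               "shorter", class = "fragcnv_validation_error")
})

test_that("genome GC track populates every 5% gate from 15% to 65%", {
  g <- small_genome()
  gates <- table(fragcnv:::gc_gate(g$bins$gc))
  expect_equal(length(gates), 10L)
  expect_true(all(gates > 0))
  expect_true(min(g$bins$gc) >= 0.15 && max(g$bins$gc) <= 0.65)
})

test_that("neutral WGS sample spreads uniformly over uniform-weight bins", {
  g <- flat_genome()
  fr <- simulate_sample(g, tumor_fraction = 0, chemistry = "WGS",
                        n_fragments = 1e5, seed = 21)
  counts <- count_by_class(fr, g$bins[, c("bin", "chrom", "start", "end")],
                           size_classes(c(50, 5000), c(5001, 5002)))
  # every fragment qualifies as "short": per-bin totals ~ uniform multinomial
  expect_equal(sum(counts$short), 1e5)
  gof <- suppressWarnings(stats::chisq.test(counts$short))
  expect_gt(gof$p.value, 0.001)
})

test_that("copy-number alteration inflates the altered bin by the stated factor", {
  g <- flat_genome()
  cnv <- 37L
  fr <- simulate_sample(g, tumor_fraction = 0.2, cnv_bins = cnv,
                        cnv_copy_ratio = 3, chemistry = "WGS",
                        n_fragments = 4e5, seed = 9)
  counts <- count_by_class(fr, g$bins[, c("bin", "chrom", "start", "end")],
                           size_classes(c(50, 5000), c(5001, 5002)))
  other <- mean(counts$short[-cnv])
  ratio <- counts$short[cnv] / other
  # expected (0.8 + 0.2 * 3) / 1 = 1.4
  expect_gt(ratio, 1.25)
  expect_lt(ratio, 1.55)
})

test_that("expected CNV-bin count is non-decreasing in tumor fraction", {
  g <- flat_genome()
  cnv <- 10L
  counts <- vapply(c(0, 0.25, 0.5, 1), function(tf) {
    fr <- simulate_sample(g, tumor_fraction = tf, cnv_bins = cnv,
                          cnv_copy_ratio = 4, chemistry = "WGS",
                          n_fragments = 2e5, seed = 31)
    sum(floor((fr$start + fr$end) / 2) %/% 5000 + 1 == cnv)
  }, 0)
  # allow small Monte-Carlo wiggle around monotone expectation
  expect_true(all(diff(counts) > -3 * sqrt(counts[-length(counts)])))
  expect_gt(counts[4], counts[1] * 2)
})

test_that("every simulated fragment lies inside the genome region", {
  g <- small_genome()
  fr <- simulate_sample(g, chemistry = "WGBS", n_fragments = 2e4, seed = 2)
  expect_true(all(fr$start >= g$region$start))
  expect_true(all(fr$end <= g$region$end))
  expect_true(all(fr$length == fr$end - fr$start))
})

test_that("bisulfite chemistry depletes long fragments relative to WGS", {
  g <- small_genome()
  fb <- simulate_sample(g, chemistry = chemistry_model("WGBS"),
                        n_fragments = 1e5, seed = 13, lambda_multiplier = 1)
  fs <- simulate_sample(g, chemistry = "WGS", n_fragments = 1e5, seed = 13)
  expect_lt(mean(fb$length > 400), mean(fs$length > 400))
})

test_that("chemistry ordering: WGBS shorter than WGES which matches WGS", {
  g <- small_genome()
  fb <- simulate_sample(g, chemistry = "WGBS", n_fragments = 5e4, seed = 3,
                        lambda_multiplier = 1)
  fe <- simulate_sample(g, chemistry = "WGES", n_fragments = 5e4, seed = 3,
                        lambda_multiplier = 1)
  fs <- simulate_sample(g, chemistry = "WGS", n_fragments = 5e4, seed = 3)
  expect_lt(mean(fb$length), mean(fe$length))
  expect_lt(abs(mean(fe$length) - mean(fs$length)), 3)
  sc <- gate_scheme(preset = "electropherogram")
  g1 <- function(fr) gate_percentages(fr, sc)$pct[1L]
  expect_gt(g1(fb), g1(fe))
})

test_that("WGBS flattens the coverage-GC correlation relative to WGS", {
  g <- small_genome()
  cov_cor <- function(chem) {
    fr <- simulate_sample(g, chemistry = chem, n_fragments = 1e5, seed = 17,
                          lambda_multiplier = 1)
    mid_bin <- floor((fr$start + fr$end) / 2) %/% 5000 + 1
    cor(tabulate(mid_bin, nbins = nrow(g$bins)), g$bins$gc)
  }
  expect_gt(cov_cor("WGS"), cov_cor("WGBS"))
})

test_that("degenerate chemistry is refused", {
  g <- flat_genome()
  dead <- chemistry_model(lambda_len = 10, lambda_gc = 50, len_onset = 0)
  expect_error(simulate_sample(g, chemistry = dead, n_fragments = 100),
               "degenerate chemistry", class = "fragcnv_validation_error")
})

test_that("cohort simulation writes the requested design, reproducibly", {
  g <- small_genome()
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  man1 <- simulate_cohort(g, dir1, n_train = c(cancer = 3, control = 3),
                          n_test = c(cancer = 2, control = 2),
                          n_fragments = 2000, seed = 77)
  man2 <- simulate_cohort(g, dir2, n_train = c(cancer = 3, control = 3),
                          n_test = c(cancer = 2, control = 2),
                          n_fragments = 2000, seed = 77)
  expect_equal(nrow(man1), 10L)
  expect_equal(sum(man1$split == "train" & man1$label == "cancer"), 3L)
  expect_equal(sum(man1$split == "test" & man1$label == "control"), 2L)
  expect_true(all(file.exists(man1$fragments_path)))
  expect_true(all(!is.na(man1$stage[man1$label == "cancer"])))

  # byte-identical across reruns with the same seed
  f1 <- sort(list.files(dir1))
  expect_equal(f1, sort(list.files(dir2)))
  for (f in f1) {
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)))
  }

  expect_error(
    simulate_cohort(g, dir1, n_train = c(cancer = 0, control = 3),
                    n_test = c(cancer = 1, control = 1)),
    "at least one", class = "fragcnv_validation_error"
  )
})
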