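test_that("FASTA windows report GC over unambiguous bases only", {
  fa <- withr::local_tempfile(fileext = ".fa")
  seq50 <- paste(rep("GGCCAATTGGCCAATT", 40), collapse = "") # gc = 0.5
  allA <- paste(rep("A", 160), collapse = "")
  withN <- paste0(paste(rep("N", 80), collapse = ""),
                  paste(rep("GC", 40), collapse = "")) # gc = 1 over calls
  allN <- paste(rep("N", 160), collapse = "")
  writeLines(c(">chrT description", seq50, allA, withN, allN), fa)
  expect_message(
    win <- gc_windows(fa, genomic_region("chrT", 0, 1120), width = 160),
    "ambiguous"
  )
  expect_equal(nrow(win), 6L) # the all-N window is dropped
  expect_equal(win$gc[1:4], rep(0.5, 4))
  expect_equal(win$gc[5], 0) # all-A window
  expect_equal(win$gc[6], 1) # N's excluded from numerator and denominator
  expect_equal(win$end - win$start, rep(160, 6))
})

test_that("synthetic-genome windows inherit the configured GC profile", {
  g <- small_genome()
  win <- gc_windows(g, width = 150)
  expect_true(all(win$end - win$start <= 150))
  # occupancy per gate mirrors the genome's own (uniform) gate histogram
  bin_tab <- table(fragcnv:::gc_gate(g$bins$gc))
  win_tab <- table(win$gate)
  expect_equal(names(win_tab), names(bin_tab))
  expect_equal(as.numeric(win_tab / sum(win_tab)),
               as.numeric(bin_tab / sum(bin_tab)), tolerance = 0.02)
})

test_that("stratified sampling allocates windows equally across GC gates", {
  g <- small_genome()
  win <- gc_windows(g, width = 150)
  sub <- stratified_gc_sample(win, n_total = 3000, seed = 4)
  occupancy <- table(sub$gate)
  expect_equal(as.numeric(occupancy), rep(300, 10))
  sub2 <- stratified_gc_sample(win, n_total = 3000, seed = 4)
  expect_identical(sub, sub2)
  # remainder goes to the lowest gates
  sub3 <- stratified_gc_sample(win, n_total = 1003, seed = 4)
  expect_equal(as.numeric(table(sub3$gate)), c(101, 101, 101, rep(100, 7)))
  # a gate with no windows is an error in strict mode
  narrow <- win[win$gc > 0.3, ]
  expect_error(stratified_gc_sample(narrow, 1000, seed = 1), "gate",
               class = "fragcnv_validation_error")
  relaxed <- stratified_gc_sample(narrow, 1000, seed = 1, strict = FALSE)
  expect_lt(nrow(relaxed), 1000)
})

test_that("regression recovers an exactly linear coverage profile", {
  # windows with gc = 0.0 .. 0.9 and coverage constructed as 2 + 10 * gc
  gc_vals <- seq(0, 0.9, by = 0.1)
  win <- tibble::tibble(
    chrom = "chr18",
    start = seq(0, by = 1000, length.out = 10),
    end = seq(150, by = 1000, length.out = 10),
    gc = gc_vals
  )
  frags <- purrr::map_dfr(seq_len(10), function(i) {
    k <- 2 + 10 * gc_vals[i]
    tibble::tibble(chrom = "chr18",
                   start = rep(win$start[i], k),
                   end = rep(win$start[i] + 100, k))
  })
  frags <- validate_fragments(frags)
  fit <- coverage_vs_gc(frags, win)
  expect_equal(fit$slope, 10, tolerance = 1e-9)
  expect_equal(fit$intercept, 2, tolerance = 1e-9)
  expect_equal(fit$pearson_r, 1, tolerance = 1e-9)
  expect_equal(sign(fit$slope), sign(fit$pearson_r))

  # doubling coverage doubles the slope, leaves r unchanged
  fit2 <- coverage_vs_gc(dplyr::bind_rows(frags, frags), win)
  expect_equal(fit2$slope, 2 * fit$slope, tolerance = 1e-9)
  expect_equal(fit2$pearson_r, fit$pearson_r, tolerance = 1e-9)
})

test_that("OLS slope and r match closed-form formulas on random instances", {
  for (s in 1:5) {
    dat <- with_local_seed(s, {
      gc <- runif(40, 0.15, 0.65)
      cov <- rpois(40, 20 + 15 * gc)
      list(gc = gc, cov = cov)
    })
    win <- tibble::tibble(chrom = "chr18",
                          start = seq(0, by = 500, length.out = 40),
                          end = seq(150, by = 500, length.out = 40),
                          gc = dat$gc)
    frags <- purrr::map_dfr(1:40, function(i) {
      if (dat$cov[i] == 0) return(NULL)
      tibble::tibble(chrom = "chr18", start = rep(win$start[i], dat$cov[i]),
                     end = rep(win$start[i] + 80, dat$cov[i]))
    })
    fit <- coverage_vs_gc(validate_fragments(frags), win)
    sxy <- sum((dat$gc - mean(dat$gc)) * (dat$cov - mean(dat$cov)))
    sxx <- sum((dat$gc - mean(dat$gc))^2)
    syy <- sum((dat$cov - mean(dat$cov))^2)
    expect_equal(fit$slope, sxy / sxx, tolerance = 1e-9)
    expect_equal(fit$intercept, mean(dat$cov) - fit$slope * mean(dat$gc),
                 tolerance = 1e-9)
    expect_equal(fit$pearson_r, sxy / sqrt(sxx * syy), tolerance = 1e-9)
  }
})

test_that("GC-independent coverage shows no correlation at n = 3000", {
  g <- small_genome()
  win <- gc_windows(g, width = 150)
  sub <- stratified_gc_sample(win, n_total = 3000, seed = 8)
  # break any GC-coverage link by permuting the GC labels
  sub_perm <- sub
  sub_perm$gc <- with_local_seed(88, sample(sub$gc))
  fr <- simulate_sample(g, chemistry = "WGS", n_fragments = 1e5, seed = 6)
  fit <- coverage_vs_gc(fr, sub_perm)
  expect_lt(abs(fit$pearson_r), 0.1)
})

test_that("bisulfite libraries flatten the coverage-GC regression", {
  g <- small_genome()
  win <- gc_windows(g, width = 150)
  sub <- stratified_gc_sample(win, n_total = 3000, seed = 8)
  fs <- simulate_sample(g, chemistry = "WGS", n_fragments = 2e5, seed = 61)
  fb <- simulate_sample(g, chemistry = "WGBS", n_fragments = 2e5, seed = 61,
                        lambda_multiplier = 1)
  fit_s <- coverage_vs_gc(fs, sub)
  fit_b <- coverage_vs_gc(fb, sub)
  expect_gt(fit_s$pearson_r, fit_b$pearson_r)
})

test_that("degenerate regression designs are refused", {
  win <- tibble::tibble(chrom = "chr18", start = c(0, 1000, 2000),
                        end = c(150, 1150, 2150), gc = rep(0.5, 3))
  fr <- validate_fragments(tibble::tibble(chrom = "chr18", start = 10, end = 110))
  expect_error(coverage_vs_gc(fr, win), "degenerate",
               class = "fragcnv_validation_error")
  expect_error(coverage_vs_gc(fr, win[1:2, ]), "3 windows",
               class = "fragcnv_validation_error")
})
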