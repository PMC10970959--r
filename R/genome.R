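# Run code with a locally set RNG seed, restoring global RNG state after.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Build a synthetic single-chromosome genome
#'
#' Creates the binned reference a synthetic cohort is simulated on: a region
#' tiled into uniform bins, each with a GC fraction and a baseline fragment
#' emission weight. The GC track is a smooth random field rank-mapped onto
#' `[0.15, 0.65]`, so every 5% GC gate between 15% and 65% is populated.
#' Baseline weights are log-linearly coupled to GC (`gc_coupling`), emulating
#' the positive coverage-GC association of real sequencing data, plus
#' log-normal bin-to-bin noise.
#'
#' @param region A region tibble (see [genomic_region()], [region_preset()]).
#' @param bin_width Bin width, bp (>= 150).
#' @param gc_smoothness Width, in bins, of the smoothing window of the GC
#'   random field; larger values give longer-range GC autocorrelation.
#' @param gc_coupling Log-linear slope of baseline weight on centered GC.
#'   Set to 0 (with `weight_noise_sd = 0`) for uniform weights.
#' @param weight_noise_sd Standard deviation of log-normal weight noise.
#' @param seed Integer seed; the genome is deterministic given it.
#' @return An object of class `fragcnv_genome`: list with `region`,
#'   `bin_width`, and a `bins` tibble (`bin`, `chrom`, `start`, `end`, `gc`,
#'   `weight`).
#' @export
#' @examples
#' g <- build_genome(genomic_region("chr18", 0, 1e6), bin_width = 5000, seed = 1)
#' nrow(g$bins)
build_genome <- function(region, bin_width = 5000, gc_smoothness = 20,
                         gc_coupling = 1.5, weight_noise_sd = 0.1,
                         seed = 1L) {
  stopifnot(bin_width >= 150)
  region_len <- region$end - region$start
  if (region_len < bin_width) {
    abort("region shorter than one bin", class = "fragcnv_validation_error")
  }
  bins <- make_bins(region, bin_width)
  n <- nrow(bins)
  with_seed(seed, {
    # smooth random field -> rank map onto [0.15, 0.65]
    x <- cumsum(rnorm(n))
    k <- max(1L, min(as.integer(gc_smoothness), n))
    if (k > 1L) {
      x <- stats::filter(x, rep(1 / k, k), sides = 2)
      x[is.na(x)] <- x[!is.na(x)][1L]
    }
    gc <- if (n == 1L) 0.40 else 0.15 + 0.5 * (rank(x, ties.method = "first") - 1) / (n - 1)
    log_w <- gc_coupling * (gc - mean(gc)) +
      if (weight_noise_sd > 0) rnorm(n, 0, weight_noise_sd) else 0
    weight <- exp(log_w)
  })
  bins$gc <- as.numeric(gc)
  bins$weight <- as.numeric(weight)
  structure(
    list(region = region, bin_width = bin_width, bins = bins, seed = seed),
    class = "fragcnv_genome"
  )
}

#' @export
print.fragcnv_genome <- function(x, ...) {
  cat("<fragcnv synthetic genome>\n")
  cat("  region:", x$region$chrom,
      sprintf("%d-%d", as.integer(x$region$start), as.integer(x$region$end)), "\n")
  cat("  bins:", nrow(x$bins), "of width", x$bin_width, "bp\n")
  cat(sprintf("  GC range: %.3f-%.3f\n", min(x$bins$gc), max(x$bins$gc)))
  invisible(x)
}

#' Default contiguous copy-number-altered bin block
#'
#' Picks a contiguous run of bins covering `fraction` of the genome, centered
#' at `at` (fraction of the genome from its left edge). Used as the default
#' location of the simulated chromosome-18q copy-number signal.
#'
#' @param genome A `fragcnv_genome`.
#' @param fraction Fraction of bins in the block.
#' @param at Center of the block as a fraction of the genome length.
#' @return Integer vector of bin indices.
#' @export
default_cnv_bins <- function(genome, fraction = 0.05, at = 0.4) {
  n <- nrow(genome$bins)
  width <- max(1L, round(fraction * n))
  center <- round(at * n)
  start <- min(max(1L, center - width %/% 2L), n - width + 1L)
  seq.int(start, start + width - 1L)
}
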