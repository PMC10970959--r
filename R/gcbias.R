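#' Tile a region into fixed-width GC windows
#'
#' Produces the non-overlapping 150 bp windows used to quantify
#' conversion-chemistry coverage bias, each annotated with its GC fraction
#' and its 5% GC gate label (gates span 15% to 65% GC; windows outside get
#' `NA`). GC can come from a FASTA reference (via Biostrings; ambiguous
#' bases are excluded from both numerator and denominator, and all-ambiguous
#' windows are dropped with a message) or from a synthetic genome, whose
#' windows inherit the GC of the bin containing their midpoint.
#'
#' @param x A `fragcnv_genome`, or a FASTA file path.
#' @param region Region tibble; defaults to a synthetic genome's own region.
#'   For FASTA input, `chrom` must name a sequence in the file and
#'   coordinates are 0-based half-open within it.
#' @param width Window width, bp.
#' @return A tibble `chrom`, `start`, `end`, `gc`, `gate` (ordered factor of
#'   gate labels such as `"15-20"`).
#' @export
gc_windows <- function(x, region = NULL, width = 150) {
  stopifnot(width > 0)
  if (inherits(x, "fragcnv_genome")) {
    region <- region %||% x$region
    win <- make_bins(region, width)
    bins <- x$bins
    bin_idx <- bin_of_midpoint(
      tibble::tibble(chrom = win$chrom, start = win$start, end = win$end),
      bins
    )
    win$gc <- bins$gc[bin_idx]
    dropped <- sum(is.na(win$gc))
    if (dropped > 0L) {
      inform(paste0("dropped ", dropped, " window(s) outside the genome bins"))
      win <- win[!is.na(win$gc), ]
    }
  } else if (is.character(x) && length(x) == 1L) {
    if (!requireNamespace("Biostrings", quietly = TRUE)) {
      abort("FASTA input requires the Biostrings package",
            class = "fragcnv_validation_error")
    }
    seqs <- Biostrings::readDNAStringSet(x)
    names(seqs) <- sub("\\s.*$", "", names(seqs))
    if (is.null(region)) {
      region <- genomic_region(names(seqs)[1L], 0, Biostrings::width(seqs)[1L])
    }
    if (!region$chrom %in% names(seqs)) {
      abort(paste0("sequence not found in FASTA: ", region$chrom),
            class = "fragcnv_validation_error")
    }
    win <- make_bins(region, width)
    views <- Biostrings::Views(seqs[[region$chrom]],
                               start = win$start + 1L, end = win$end)
    freq <- Biostrings::letterFrequency(views, c("G", "C", "A", "T"))
    unambig <- rowSums(freq)
    gc <- ifelse(unambig > 0, (freq[, "G"] + freq[, "C"]) / unambig, NA_real_)
    dropped <- sum(is.na(gc))
    if (dropped > 0L) {
      inform(paste0("dropped ", dropped, " all-ambiguous window(s)"))
    }
    win$gc <- gc
    win <- win[!is.na(win$gc), ]
  } else {
    abort("x must be a fragcnv_genome or a FASTA path",
          class = "fragcnv_validation_error")
  }
  win$gate <- gc_gate(win$gc)
  win[, c("chrom", "start", "end", "gc", "gate")]
}

# 5%-wide GC gate label over [0.15, 0.65); NA outside
gc_gate <- function(gc, lo = 0.15, hi = 0.65, step = 0.05) {
  edges <- seq(lo, hi, by = step)
  labels <- paste0(round(100 * edges[-length(edges)]), "-",
                   round(100 * edges[-1]))
  idx <- findInterval(gc, edges)
  idx[gc < lo | gc >= hi] <- NA_integer_
  factor(labels[idx], levels = labels, ordered = TRUE)
}

#' GC-stratified window sample
#'
#' Randomly selects windows without replacement, allocated equally across the
#' ten 5% GC gates between 15% and 65% (remainder, if any, to the lowest
#' gates), so the regression design spans a wide GC range regardless of the
#' genome's own GC composition.
#'
#' @param windows A window tibble from [gc_windows()].
#' @param n_total Total windows to select.
#' @param seed Integer seed; the subset is deterministic given it.
#' @param strict If `TRUE` (default), a gate with fewer windows than its
#'   allocation is an error; if `FALSE`, all its windows are taken.
#' @return The selected subset of `windows` (gate order, then genomic order).
#' @export
stratified_gc_sample <- function(windows, n_total = 3000, seed = 1L,
                                 strict = TRUE) {
  windows <- windows[!is.na(windows$gate), ]
  gates <- levels(windows$gate)
  n_gates <- length(gates)
  base <- n_total %/% n_gates
  alloc <- rep(base, n_gates)
  extra <- n_total - base * n_gates
  if (extra > 0L) alloc[seq_len(extra)] <- alloc[seq_len(extra)] + 1L
  with_seed(seed, {
    picked <- purrr::map(seq_along(gates), function(i) {
      pool <- which(windows$gate == gates[i])
      if (length(pool) < alloc[i]) {
        if (strict) {
          abort(paste0("GC gate ", gates[i], " has only ", length(pool),
                       " window(s), need ", alloc[i]),
                class = "fragcnv_validation_error")
        }
        return(pool)
      }
      sort(sample(pool, alloc[i]))
    })
  })
  windows[unlist(picked), ]
}

#' Regress fragment coverage on GC content
#'
#' Per-window coverage is the number of fragments whose midpoint falls in the
#' window; an ordinary least-squares line of coverage on GC fraction is
#' fitted over the (typically GC-stratified) window set. Under bisulfite
#' conversion, GC-rich fragments are chemically depleted, flattening the
#' coverage-GC relationship relative to unconverted or enzymatically
#' converted libraries.
#'
#' @param fragments A fragment tibble.
#' @param windows A window tibble (`chrom`, `start`, `end`, `gc`), e.g. from
#'   [stratified_gc_sample()].
#' @return An object of class `fragcnv_gcfit`: `slope` (coverage per unit GC
#'   fraction), `intercept`, `pearson_r`, `n_windows`, and the per-window
#'   `data` tibble.
#' @export
coverage_vs_gc <- function(fragments, windows) {
  if (nrow(windows) < 3L) {
    abort("need at least 3 windows", class = "fragcnv_validation_error")
  }
  if (sd(windows$gc) == 0) {
    abort("degenerate design: zero GC variance in window set",
          class = "fragcnv_validation_error")
  }
  ord <- order(windows$start)
  w <- windows[ord, ]
  mid <- floor((fragments$start + fragments$end) / 2)
  mid <- mid[fragments$chrom == w$chrom[1L]]
  idx <- findInterval(mid, w$start)
  hit <- idx >= 1L & idx <= nrow(w) & mid < w$end[pmax(idx, 1L)]
  coverage <- tabulate(idx[hit], nbins = nrow(w))
  fit <- lm(coverage ~ gc, data = tibble::tibble(gc = w$gc, coverage = coverage))
  r <- cor(w$gc, coverage)
  structure(
    list(slope = unname(coef(fit)[2L]), intercept = unname(coef(fit)[1L]),
         pearson_r = r, n_windows = nrow(w),
         data = tibble::tibble(chrom = w$chrom, start = w$start, end = w$end,
                               gc = w$gc, coverage = coverage)),
    class = "fragcnv_gcfit"
  )
}

#' @export
print.fragcnv_gcfit <- function(x, ...) {
  cat("<fragcnv GC-coverage regression>\n")
  cat(sprintf("  slope %.3f  intercept %.3f  Pearson r %.3f  (n = %d windows)\n",
              x$slope, x$intercept, x$pearson_r, x$n_windows))
  invisible(x)
}

#' @exportS3Method generics::glance
glance.fragcnv_gcfit <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept,
                 pearson_r = x$pearson_r, n_windows = x$n_windows)
}

#' Coverage-versus-GC scatter with the fitted line
#'
#' @param object A `fragcnv_gcfit`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.fragcnv_gcfit <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$gc, y = .data$coverage)) +
    ggplot2::geom_point(alpha = 0.25, size = 0.7, color = "#555555") +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         color = "#b2182b", linewidth = 0.9) +
    ggplot2::labs(
      x = "GC fraction", y = "Fragment coverage",
      title = sprintf("slope %.3f, r = %.3f", object$slope, object$pearson_r)
    ) +
    ggplot2::theme_minimal()
}
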