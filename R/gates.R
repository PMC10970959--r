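#' Nucleosome-wrapping size-gate scheme
#'
#' Four half-open fragment-length gates `[b0,b1), [b1,b2), [b2,b3), [b3,b4)`
#' corresponding to DNA wrapped around 1, 2, 3, or more nucleosomes. The
#' default boundaries (100, 400, 585, 825, 5500 bp) are electropherogram
#' gates defined on adapter-ligated library molecules; to apply them to
#' aligned insert sizes, set `adapter_offset` to the total adapter/primer
#' length added during library preparation (the `"electropherogram"` preset
#' uses 130 bp).
#'
#' @param boundaries Five strictly increasing cut points, bp.
#' @param adapter_offset Offset (bp) added to insert lengths before gate
#'   lookup, expressing library-molecule gates on the insert-size axis.
#' @param preset `"sequencing"` (offset 0) or `"electropherogram"`
#'   (offset 130); ignored when `adapter_offset` is given.
#' @return An object of class `fragcnv_gates`.
#' @export
gate_scheme <- function(boundaries = c(100, 400, 585, 825, 5500),
                        adapter_offset = NULL,
                        preset = c("sequencing", "electropherogram")) {
  preset <- match.arg(preset)
  if (is.null(adapter_offset)) {
    adapter_offset <- if (preset == "electropherogram") 130 else 0
  }
  if (length(boundaries) != 5L || any(diff(boundaries) <= 0)) {
    abort("gate boundaries must be 5 strictly increasing cut points",
          class = "fragcnv_validation_error")
  }
  structure(list(boundaries = as.numeric(boundaries),
                 adapter_offset = as.numeric(adapter_offset)),
            class = "fragcnv_gates")
}

#' Assign fragment lengths to size gates
#'
#' Gate `g` holds lengths with `b[g] <= length + adapter_offset < b[g+1]`
#' (half-open, lower-inclusive). Lengths outside `[b0, b4)` map to `NA`.
#'
#' @param length Positive fragment length(s), bp (insert sizes).
#' @param scheme A [gate_scheme()].
#' @return Integer gate indices in 1..4, or `NA` for out-of-gate lengths.
#' @export
#' @examples
#' assign_gate(c(350, 400, 167), gate_scheme())
assign_gate <- function(length, scheme = gate_scheme()) {
  if (any(length <= 0)) {
    abort("fragment lengths must be positive",
          class = "fragcnv_validation_error")
  }
  adjusted <- length + scheme$adapter_offset
  idx <- findInterval(adjusted, scheme$boundaries)
  idx[idx < 1L | idx > 4L] <- NA_integer_
  as.integer(idx)
}

#' Per-sample gate percentage profile
#'
#' Percentage of fragments in each size gate, relative to all input
#' fragments; fragments outside every gate are excluded from the numerators
#' but kept in the denominator, so the four percentages sum to at most 100
#' (as in Fragment Analyzer percentage exports).
#'
#' @param fragments A fragment tibble (or anything with a `length` column),
#'   or a numeric vector of lengths.
#' @param scheme A [gate_scheme()].
#' @param sample_id Optional sample label attached to the output.
#' @return A tibble with one row per gate: `sample_id`, `gate`, `lower`,
#'   `upper` (on the adjusted axis), `n`, `pct`. Attribute `n_total` carries
#'   the denominator.
#' @export
gate_percentages <- function(fragments, scheme = gate_scheme(),
                             sample_id = NA_character_) {
  lengths <- if (is.numeric(fragments)) fragments else fragments$length
  if (length(lengths) == 0L) {
    abort("no fragments", class = "fragcnv_validation_error")
  }
  g <- assign_gate(lengths, scheme)
  n_total <- length(lengths)
  counts <- tabulate(g, nbins = 4L)
  out <- tibble::tibble(
    sample_id = sample_id,
    gate = 1:4,
    lower = scheme$boundaries[1:4],
    upper = scheme$boundaries[2:5],
    n = counts,
    pct = 100 * counts / n_total
  )
  attr(out, "n_total") <- n_total
  out
}

#' Gate profiles for every sample in a manifest
#'
#' @param manifest A manifest tibble (see [read_manifest()]).
#' @param scheme A [gate_scheme()].
#' @return A long tibble of per-sample gate percentages with the manifest's
#'   `label`, `chemistry` and `split` columns joined on.
#' @export
gate_profile_table <- function(manifest, scheme = gate_scheme()) {
  manifest <- validate_manifest(manifest)
  purrr::map_dfr(seq_len(nrow(manifest)), function(i) {
    frags <- read_fragments(manifest$fragments_path[i])
    prof <- gate_percentages(frags, scheme, sample_id = manifest$sample_id[i])
    prof$label <- manifest$label[i]
    prof$chemistry <- manifest$chemistry[i]
    prof$split <- manifest$split[i]
    prof
  })
}

#' Paired comparison of gate profiles between two chemistries
#'
#' For each gate, runs a two-sided paired Wilcoxon signed-rank test on the
#' per-sample percentage differences (B minus A) across samples matched by
#' `sample_id`, and reports the direction of the median difference. This is
#' the test behind the bisulfite-versus-enzymatic gate-shift comparison:
#' bisulfite conversion degrades multi-nucleosome fragments, inflating gate 1
#' at the expense of gates 2-4.
#'
#' @param profiles_a,profiles_b Long gate-profile tibbles (`sample_id`,
#'   `gate`, `pct`) with identical `sample_id` sets.
#' @return A tibble with one row per gate: `gate`, `median_diff` (B - A),
#'   `direction` (-1, 0, 1), `statistic` (signed-rank V), `p_value`.
#' @export
compare_paired_gates <- function(profiles_a, profiles_b) {
  ids_a <- unique(profiles_a$sample_id)
  ids_b <- unique(profiles_b$sample_id)
  orphans <- c(setdiff(ids_a, ids_b), setdiff(ids_b, ids_a))
  if (length(orphans) > 0L) {
    abort(paste0("unmatched sample_id(s): ", paste(orphans, collapse = ", ")),
          class = "fragcnv_validation_error")
  }
  if (length(ids_a) < 6L) {
    abort("need at least 6 matched pairs", class = "fragcnv_validation_error")
  }
  purrr::map_dfr(sort(unique(profiles_a$gate)), function(g) {
    a <- profiles_a[profiles_a$gate == g, ]
    b <- profiles_b[profiles_b$gate == g, ]
    d <- b$pct[match(ids_a, b$sample_id)] - a$pct[match(ids_a, a$sample_id)]
    med <- median(d)
    if (all(d == 0)) {
      return(tibble::tibble(gate = g, median_diff = 0, direction = 0L,
                            statistic = NA_real_, p_value = 1))
    }
    wt <- suppressWarnings(wilcox.test(d, alternative = "two.sided"))
    tibble::tibble(gate = g, median_diff = med,
                   direction = as.integer(sign(med)),
                   statistic = unname(wt$statistic), p_value = wt$p.value)
  })
}
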