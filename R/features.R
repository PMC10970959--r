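#' Tile a region into uniform windows
#'
#' Bins tile the region left to right without gaps or overlaps; the last bin
#' is truncated at the region end.
#'
#' @param region A one-row region tibble.
#' @param bin_width Window width, bp.
#' @return A tibble with columns `bin`, `chrom`, `start`, `end`.
#' @export
#' @examples
#' make_bins(genomic_region("chr18", 0, 10000), 3000)
make_bins <- function(region, bin_width) {
  if (bin_width <= 0) {
    abort("bin_width must be positive", class = "fragcnv_validation_error")
  }
  len <- region$end - region$start
  n <- ceiling(len / bin_width)
  start <- region$start + (seq_len(n) - 1) * bin_width
  end <- pmin(start + bin_width, region$end)
  tibble::tibble(bin = seq_len(n), chrom = region$chrom,
                 start = start, end = end)
}

#' Fragment size-class scheme
#'
#' Inclusive length windows for the "short" and "medium" mono-nucleosome
#' sub-populations counted per bin. Defaults (short 100-150 bp, medium
#' 151-220 bp, insert sizes) follow the fragmentomics convention that
#' tumor-derived cfDNA is enriched below the ~167 bp mono-nucleosome mode.
#'
#' @param short Inclusive `c(lo, hi)` bounds of the short class, bp.
#' @param medium Inclusive bounds of the medium class; must start above
#'   `short[2]`.
#' @return An object of class `fragcnv_size_classes`.
#' @export
size_classes <- function(short = c(100, 150), medium = c(151, 220)) {
  stopifnot(length(short) == 2L, length(medium) == 2L,
            short[1] <= short[2], medium[1] <= medium[2])
  if (short[2] >= medium[1]) {
    abort("size classes must be disjoint and ordered (short below medium)",
          class = "fragcnv_validation_error")
  }
  structure(list(short = as.numeric(short), medium = as.numeric(medium)),
            class = "fragcnv_size_classes")
}

# bin index of each fragment midpoint, NA when outside the binned region or
# on another chromosome
bin_of_midpoint <- function(fragments, bins) {
  mid <- floor((fragments$start + fragments$end) / 2)
  region_start <- bins$start[1L]
  region_end <- bins$end[nrow(bins)]
  width <- if (nrow(bins) >= 2L) bins$start[2L] - bins$start[1L] else
    bins$end[1L] - bins$start[1L]
  idx <- floor((mid - region_start) / width) + 1
  ok <- fragments$chrom == bins$chrom[1L] & mid >= region_start & mid < region_end
  idx[!ok] <- NA_real_
  as.integer(idx)
}

#' Count short and medium fragments per bin
#'
#' A fragment contributes to the bin containing its midpoint
#' `floor((start + end) / 2)` and to the size class containing its length;
#' fragments outside both classes or outside the binned region are excluded
#' (tallied in the `excluded` attribute).
#'
#' @param fragments A fragment tibble.
#' @param bins A bin tibble from [make_bins()].
#' @param classes A [size_classes()] scheme.
#' @return A tibble with one row per bin: `bin`, `short`, `medium`.
#' @export
count_by_class <- function(fragments, bins, classes = size_classes()) {
  idx <- bin_of_midpoint(fragments, bins)
  len <- fragments$length
  is_short <- len >= classes$short[1] & len <= classes$short[2]
  is_medium <- len >= classes$medium[1] & len <= classes$medium[2]
  in_bin <- !is.na(idx)
  n_bins <- nrow(bins)
  out <- tibble::tibble(
    bin = bins$bin,
    short = tabulate(idx[in_bin & is_short], nbins = n_bins),
    medium = tabulate(idx[in_bin & is_medium], nbins = n_bins)
  )
  attr(out, "excluded") <- c(
    out_of_region = sum(!in_bin),
    out_of_class = sum(in_bin & !is_short & !is_medium)
  )
  out
}

#' Build the samples-by-bins feature matrix
#'
#' Reads every sample's fragment file, counts short and medium fragments per
#' uniform window, and assembles the feature matrix fed to region selection
#' and the LDA classifier. The default feature is the combined short+medium
#' count per bin, normalized to counts per million in-region class-qualifying
#' fragments (CPM) so samples are comparable at unequal depths.
#'
#' @param manifest A manifest tibble.
#' @param bins A bin tibble from [make_bins()].
#' @param classes A [size_classes()] scheme.
#' @param layout `"combined"` (short+medium summed per bin), `"separate"`
#'   (short and medium as distinct features), or `"ratio"`
#'   (`(short + 0.5) / (medium + 0.5)` per bin, no CPM scaling).
#' @param normalization `"cpm"` or `"none"` (ignored for `"ratio"`).
#' @return An object of class `fragcnv_features`: a tibble with `sample_id`
#'   followed by one column per feature (ids `chrom:start-end:class`), plus
#'   attributes `feature_info` (tibble) and `normalization`.
#' @export
build_feature_matrix <- function(manifest, bins, classes = size_classes(),
                                 layout = c("combined", "separate", "ratio"),
                                 normalization = c("cpm", "none")) {
  layout <- match.arg(layout)
  normalization <- match.arg(normalization)
  manifest <- validate_manifest(manifest)

  rows <- purrr::map(seq_len(nrow(manifest)), function(i) {
    frags <- read_fragments(manifest$fragments_path[i])
    counts <- count_by_class(frags, bins, classes)
    total <- sum(counts$short) + sum(counts$medium)
    if (total == 0L) {
      abort(paste0("sample has zero in-region class-qualifying fragments: ",
                   manifest$sample_id[i]),
            class = "fragcnv_validation_error")
    }
    vals <- switch(
      layout,
      combined = counts$short + counts$medium,
      separate = c(counts$short, counts$medium),
      ratio = (counts$short + 0.5) / (counts$medium + 0.5)
    )
    if (layout != "ratio" && normalization == "cpm") {
      vals <- 1e6 * vals / total
    }
    vals
  })

  base_ids <- sprintf("%s:%d-%d", bins$chrom,
                      as.integer(bins$start), as.integer(bins$end))
  feature_info <- switch(
    layout,
    combined = tibble::tibble(feature_id = paste0(base_ids, ":cnt"),
                              bin = bins$bin, chrom = bins$chrom,
                              start = bins$start, end = bins$end,
                              class = "combined"),
    separate = tibble::tibble(
      feature_id = c(paste0(base_ids, ":short"), paste0(base_ids, ":medium")),
      bin = c(bins$bin, bins$bin), chrom = c(bins$chrom, bins$chrom),
      start = c(bins$start, bins$start), end = c(bins$end, bins$end),
      class = rep(c("short", "medium"), each = nrow(bins))
    ),
    ratio = tibble::tibble(feature_id = paste0(base_ids, ":ratio"),
                           bin = bins$bin, chrom = bins$chrom,
                           start = bins$start, end = bins$end,
                           class = "ratio")
  )

  mat <- do.call(rbind, rows)
  colnames(mat) <- feature_info$feature_id
  out <- dplyr::bind_cols(
    tibble::tibble(sample_id = manifest$sample_id),
    tibble::as_tibble(mat)
  )
  structure(out,
            feature_info = feature_info,
            normalization = if (layout == "ratio") "ratio" else normalization,
            class = c("fragcnv_features", class(out)))
}

# numeric matrix view of a feature tibble (samples x features)
feature_matrix <- function(features, feature_ids = NULL) {
  stopifnot(is.data.frame(features), "sample_id" %in% names(features))
  cols <- setdiff(names(features), "sample_id")
  if (!is.null(feature_ids)) {
    missing_ids <- setdiff(feature_ids, cols)
    if (length(missing_ids) > 0L) {
      abort(paste0("missing feature(s): ",
                   paste(head(missing_ids, 5L), collapse = ", "),
                   if (length(missing_ids) > 5L) " ..."),
            class = "fragcnv_validation_error")
    }
    cols <- feature_ids
  }
  m <- as.matrix(features[, cols, drop = FALSE])
  rownames(m) <- features$sample_id
  m
}
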