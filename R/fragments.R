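#' Read cfDNA fragment intervals from a BED file
#'
#' Fragments are aligned, deduplicated cfDNA molecules represented as BED3
#' intervals (0-based, half-open). Columns beyond the third are ignored.
#' Strand is not used anywhere in the package: cfDNA fragment counting is
#' strand-agnostic.
#'
#' @param path Path to a tab-separated BED file without header.
#' @return A tibble with columns `chrom` (character), `start`, `end`
#'   (integer-valued doubles, 0-based half-open) and `length` (`end - start`),
#'   one row per input line, in file order.
#' @seealso [write_fragments()], [read_manifest()]
#' @export
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines("chr18\t100\t267", bed)
#' read_fragments(bed)
read_fragments <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("fragment file not found: ", path), class = "fragcnv_io_error")
  }
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(tibble::tibble(
      chrom = character(), start = double(), end = double(), length = double()
    ))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    bad <- which(nf < 3L)[1L]
    abort(
      paste0("malformed BED line ", bad, ": fewer than 3 tab-separated fields"),
      class = "fragcnv_parse_error"
    )
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  bad <- which(!is.finite(start) | !is.finite(end) | start < 0 | end < 0 |
                 start != floor(start) | end != floor(end))
  if (length(bad) > 0L) {
    abort(
      paste0("malformed BED line ", bad[1L],
             ": columns 2-3 must be non-negative integers"),
      class = "fragcnv_parse_error"
    )
  }
  bad <- which(end <= start)
  if (length(bad) > 0L) {
    abort(
      paste0("end <= start at line ", bad[1L]),
      class = "fragcnv_validation_error"
    )
  }
  tibble::tibble(chrom = chrom, start = start, end = end, length = end - start)
}

#' Write fragment intervals to a BED3 file
#'
#' Inverse of [read_fragments()]: `read_fragments(write_fragments(x, p))`
#' recovers `x` exactly.
#'
#' @param fragments A tibble with columns `chrom`, `start`, `end`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fragments <- function(fragments, path) {
  fragments <- validate_fragments(fragments)
  lines <- sprintf("%s\t%d\t%d", fragments$chrom,
                   as.integer(fragments$start), as.integer(fragments$end))
  tryCatch(
    readr::write_lines(lines, path),
    error = function(e) {
      abort(paste0("cannot write fragment file: ", path,
                   " (", conditionMessage(e), ")"),
            class = "fragcnv_io_error")
    }
  )
  invisible(path)
}

#' Validate a fragment tibble
#'
#' Checks the interval invariants (`end > start`, non-negative coordinates)
#' and recomputes `length`.
#'
#' @param fragments A data frame with columns `chrom`, `start`, `end`.
#' @return The validated tibble with a `length` column.
#' @export
validate_fragments <- function(fragments) {
  req <- c("chrom", "start", "end")
  missing_cols <- setdiff(req, names(fragments))
  if (length(missing_cols) > 0L) {
    abort(paste0("fragment table missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "fragcnv_schema_error")
  }
  fragments <- tibble::as_tibble(fragments)
  if (nrow(fragments) > 0L) {
    if (any(fragments$start < 0)) {
      abort("fragment start coordinates must be non-negative",
            class = "fragcnv_validation_error")
    }
    bad <- which(fragments$end <= fragments$start)
    if (length(bad) > 0L) {
      abort(paste0("end <= start for fragment row ", bad[1L]),
            class = "fragcnv_validation_error")
    }
  }
  fragments$length <- fragments$end - fragments$start
  fragments
}

#' Define a genomic region
#'
#' @param chrom Chromosome name.
#' @param start 0-based inclusive start.
#' @param end 0-based exclusive end; must exceed `start`.
#' @return A one-row tibble with columns `chrom`, `start`, `end`.
#' @export
#' @examples
#' genomic_region("chr18", 18500000, 80373285)
genomic_region <- function(chrom, start, end) {
  if (end <= start) {
    abort("region end must be greater than start",
          class = "fragcnv_validation_error")
  }
  tibble::tibble(chrom = as.character(chrom),
                 start = as.numeric(start), end = as.numeric(end))
}

#' Built-in target region preset
#'
#' The q-arm of chromosome 18 on an hg38-like build, the region recurrently
#' deleted (18q loss of heterozygosity) in colorectal cancer. The genome
#' build underlying the coordinates is a convention of this package, exposed
#' as a named preset rather than a constant.
#'
#' @param name Preset name; currently only `"chr18q"`.
#' @return A one-row region tibble (see [genomic_region()]).
#' @export
region_preset <- function(name = "chr18q") {
  presets <- list(
    chr18q = genomic_region("chr18", 18500000, 80373285)
  )
  if (!name %in% names(presets)) {
    abort(paste0("unknown region preset: ", name,
                 " (available: ", paste(names(presets), collapse = ", "), ")"),
          class = "fragcnv_validation_error")
  }
  presets[[name]]
}
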