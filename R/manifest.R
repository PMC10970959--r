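MANIFEST_COLUMNS <- c("sample_id", "label", "stage", "location",
                      "chemistry", "split", "fragments_path")
LABEL_LEVELS <- c("cancer", "control")
STAGE_LEVELS <- c("0", "I", "IIA", "III", "IIIA", "IIIB", "IV")
CHEMISTRY_LEVELS <- c("WGES", "WGBS", "WGS")
SPLIT_LEVELS <- c("train", "test")

#' Read a cohort manifest
#'
#' A manifest is a tab-separated table with one row per plasma sample,
#' carrying the class label (cancer/control), tumor stage, tumor location,
#' conversion chemistry (enzymatic WGES, bisulfite WGBS, or unconverted WGS),
#' the train/test split and the path to the sample's fragment BED file.
#'
#' @param path Path to a TSV file with a header containing at least the
#'   columns `sample_id`, `label`, `stage`, `location`, `chemistry`, `split`,
#'   `fragments_path`.
#' @param base_dir Directory against which relative `fragments_path` entries
#'   are resolved; defaults to the manifest's own directory.
#' @return A validated manifest tibble.
#' @export
read_manifest <- function(path, base_dir = dirname(path)) {
  if (!file.exists(path)) {
    abort(paste0("manifest not found: ", path), class = "fragcnv_io_error")
  }
  m <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                       progress = FALSE)
  missing_cols <- setdiff(MANIFEST_COLUMNS, names(m))
  if (length(missing_cols) > 0L) {
    abort(paste0("manifest missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "fragcnv_schema_error")
  }
  rel <- !grepl("^(/|[A-Za-z]:)", m$fragments_path) & !is.na(m$fragments_path)
  m$fragments_path[rel] <- file.path(base_dir, m$fragments_path[rel])
  validate_manifest(m)
}

#' Write a cohort manifest to TSV
#'
#' @param manifest A manifest tibble (see [read_manifest()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  manifest <- validate_manifest(manifest)
  readr::write_tsv(manifest[, MANIFEST_COLUMNS], path, na = "NA",
                   progress = FALSE)
  invisible(path)
}

#' Validate a cohort manifest
#'
#' Enforces the manifest schema: known enum values, unique sample ids, and
#' the rule that control samples carry no tumor stage.
#'
#' @param manifest A data frame with the manifest columns.
#' @return The validated manifest tibble.
#' @export
validate_manifest <- function(manifest) {
  missing_cols <- setdiff(MANIFEST_COLUMNS, names(manifest))
  if (length(missing_cols) > 0L) {
    abort(paste0("manifest missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "fragcnv_schema_error")
  }
  m <- tibble::as_tibble(manifest)
  m$stage[m$stage %in% c("NA", "")] <- NA_character_
  m$location[m$location %in% c("NA", "")] <- NA_character_

  dup <- m$sample_id[duplicated(m$sample_id)]
  if (length(dup) > 0L) {
    abort(paste0("duplicate sample_id in manifest: ",
                 paste(unique(dup), collapse = ", ")),
          class = "fragcnv_validation_error")
  }
  check_enum <- function(values, levels, field, allow_na = FALSE) {
    bad <- if (allow_na) {
      !is.na(values) & !values %in% levels
    } else {
      is.na(values) | !values %in% levels
    }
    if (any(bad)) {
      abort(paste0("invalid ", field, " value(s): ",
                   paste(unique(values[bad]), collapse = ", "),
                   " (allowed: ", paste(levels, collapse = ", "), ")"),
            class = "fragcnv_validation_error")
    }
  }
  check_enum(m$label, LABEL_LEVELS, "label")
  check_enum(m$stage, STAGE_LEVELS, "stage", allow_na = TRUE)
  check_enum(m$chemistry, CHEMISTRY_LEVELS, "chemistry")
  check_enum(m$split, SPLIT_LEVELS, "split")

  bad <- m$label == "control" & !is.na(m$stage)
  if (any(bad)) {
    abort(paste0("control sample(s) with a tumor stage: ",
                 paste(m$sample_id[bad], collapse = ", ")),
          class = "fragcnv_validation_error")
  }
  m
}

# Both classes must be present in a split used for model fitting.
check_split_has_both_classes <- function(manifest, split) {
  sub <- manifest[manifest$split == split, ]
  if (!all(LABEL_LEVELS %in% sub$label)) {
    abort(paste0("split '", split,
                 "' must contain at least one cancer and one control sample"),
          class = "fragcnv_validation_error")
  }
  invisible(sub)
}
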