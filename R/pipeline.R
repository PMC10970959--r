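#' Assemble a pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis in one validated list.
#' All stochastic stages derive their seeds from the single `seed`.
#'
#' @param manifest_path Path to the cohort manifest TSV (ignored when a
#'   manifest tibble is passed to [run_pipeline()] directly).
#' @param region Target region tibble; default the chr18q preset.
#' @param bin_width Feature window width, bp.
#' @param classes A [size_classes()] scheme.
#' @param gates A [gate_scheme()].
#' @param layout Feature layout (see [build_feature_matrix()]).
#' @param batch_size,cor_threshold Correlation-filter parameters.
#' @param differential_filter Apply the per-region rank test after the
#'   correlation filter and keep features with `p < differential_alpha`.
#' @param differential_alpha Significance cutoff of the optional post-filter.
#' @param shrinkage LDA shrinkage intensity, `NULL` for auto.
#' @param decision_threshold Posterior classification threshold.
#' @param gc_width,gc_n_total GC-bias window width and stratified sample size.
#' @param seed Integer master seed.
#' @return A `fragcnv_config` list.
#' @export
pipeline_config <- function(manifest_path = NULL,
                            region = region_preset("chr18q"),
                            bin_width = 5000,
                            classes = size_classes(),
                            gates = gate_scheme(),
                            layout = "combined",
                            batch_size = 1000,
                            cor_threshold = 0.7,
                            differential_filter = FALSE,
                            differential_alpha = 0.05,
                            shrinkage = NULL,
                            decision_threshold = 0.5,
                            gc_width = 150,
                            gc_n_total = 3000,
                            seed = 1L) {
  stopifnot(bin_width > 0, batch_size >= 1, cor_threshold >= 0,
            cor_threshold <= 1, decision_threshold > 0,
            decision_threshold < 1, gc_width > 0, gc_n_total >= 10)
  structure(
    list(manifest_path = manifest_path, region = region,
         bin_width = bin_width, classes = classes, gates = gates,
         layout = layout, batch_size = batch_size,
         cor_threshold = cor_threshold,
         differential_filter = differential_filter,
         differential_alpha = differential_alpha,
         shrinkage = shrinkage, decision_threshold = decision_threshold,
         gc_width = gc_width, gc_n_total = gc_n_total,
         seed = as.integer(seed)),
    class = "fragcnv_config"
  )
}

#' Run the full fragmentation / copy-number classification pipeline
#'
#' Executes the stages in order: feature matrix over uniform windows,
#' correlation-based region selection on the training split only, shrinkage
#' LDA fit on the training split, scoring and metric panel on the held-out
#' test split, and (when a synthetic genome is supplied) the GC-bias
#' regression. Train and test splits must be disjoint by `sample_id`; the
#' test labels are never consulted before evaluation.
#'
#' @param manifest A manifest tibble, or `NULL` to read
#'   `config$manifest_path`.
#' @param config A [pipeline_config()].
#' @param genome Optional `fragcnv_genome` for the GC-bias stage.
#' @param out_dir Optional directory; when given, features, the selection
#'   table, model coefficients, metrics and a run log are written there.
#' @return A list with `features`, `selection`, `model`, `scores`, `metrics`,
#'   `gc_fit` (or `NULL`), and `config`.
#' @export
run_pipeline <- function(manifest = NULL, config = pipeline_config(),
                         genome = NULL, out_dir = NULL) {
  if (is.null(manifest)) {
    if (is.null(config$manifest_path)) {
      abort("no manifest given and no manifest_path in config",
            class = "fragcnv_validation_error")
    }
    manifest <- read_manifest(config$manifest_path)
  }
  manifest <- validate_manifest(manifest)
  train_ids <- manifest$sample_id[manifest$split == "train"]
  test_ids <- manifest$sample_id[manifest$split == "test"]
  overlap <- intersect(train_ids, test_ids)
  if (length(overlap) > 0L) {
    abort(paste0("train/test leakage, sample(s) in both splits: ",
                 paste(overlap, collapse = ", ")),
          class = "fragcnv_validation_error")
  }
  check_split_has_both_classes(manifest, "train")
  missing_files <- manifest$fragments_path[!file.exists(manifest$fragments_path)]
  if (length(missing_files) > 0L) {
    abort(paste0("missing fragment file(s): ",
                 paste(head(missing_files, 3L), collapse = ", ")),
          class = "fragcnv_io_error")
  }

  bins <- make_bins(config$region, config$bin_width)
  features <- build_feature_matrix(manifest, bins, config$classes,
                                   layout = config$layout)
  train_feat <- features[features$sample_id %in% train_ids, ]
  test_feat <- features[features$sample_id %in% test_ids, ]

  selection <- correlation_filter(train_feat, batch_size = config$batch_size,
                                  threshold = config$cor_threshold)
  kept <- selection$kept_feature_ids
  if (isTRUE(config$differential_filter)) {
    dt <- differential_test(train_feat[, c("sample_id", kept)], manifest)
    kept <- dt$feature_id[dt$p_value < config$differential_alpha]
    if (length(kept) < 2L) {
      abort("differential post-filter left fewer than 2 features",
            class = "fragcnv_validation_error")
    }
  }

  model <- fit_lda(train_feat[, c("sample_id", kept)], manifest,
                   shrinkage = config$shrinkage)
  scores <- score_samples(model, test_feat)
  metrics <- evaluate_classifier(scores, manifest,
                                 threshold = config$decision_threshold)

  gc_fit <- NULL
  if (!is.null(genome)) {
    windows <- gc_windows(genome, width = config$gc_width)
    subset <- stratified_gc_sample(windows, n_total = config$gc_n_total,
                                   seed = config$seed)
    # pool test-split fragments for the chemistry-level coverage profile
    pooled <- purrr::map_dfr(manifest$fragments_path[manifest$split == "test"],
                             read_fragments)
    gc_fit <- coverage_vs_gc(pooled, subset)
  }

  result <- list(features = features, selection = selection, model = model,
                 scores = scores, metrics = metrics, gc_fit = gc_fit,
                 config = config)
  if (!is.null(out_dir)) write_run_outputs(result, manifest, out_dir)
  result
}

write_run_outputs <- function(result, manifest, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(result$features, file.path(out_dir, "features.tsv"),
                   progress = FALSE)
  readr::write_tsv(result$selection$table, file.path(out_dir, "selection.tsv"),
                   progress = FALSE)
  readr::write_tsv(tidy(result$model), file.path(out_dir, "model.tsv"),
                   progress = FALSE)
  readr::write_csv(result$metrics$roc, file.path(out_dir, "roc.csv"),
                   progress = FALSE)
  jsonlite::write_json(
    list(
      confusion = as.list(result$metrics$confusion),
      sensitivity = result$metrics$sensitivity,
      specificity = result$metrics$specificity,
      early_stage_sensitivity = result$metrics$early_stage_sensitivity,
      auc = result$metrics$auc,
      per_stage = result$metrics$per_stage,
      per_location = result$metrics$per_location
    ),
    file.path(out_dir, "metrics.json"), auto_unbox = TRUE, digits = NA
  )
  if (!is.null(result$gc_fit)) {
    jsonlite::write_json(as.list(glance(result$gc_fit)),
                         file.path(out_dir, "gc_bias.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  cfg <- result$config
  log <- list(
    config_hash = rlang::hash(cfg),
    seed = cfg$seed,
    n_train = sum(manifest$split == "train"),
    n_test = sum(manifest$split == "test"),
    n_features = nrow(result$selection$table),
    n_selected = length(result$model$feature_ids),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)
  )
  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Gate-percentage comparison plot
#'
#' Boxplots of per-sample gate percentages split by a grouping column
#' (typically `chemistry`), one panel per gate.
#'
#' @param profiles A long gate-profile tibble from [gate_profile_table()].
#' @param by Grouping column name.
#' @return A ggplot.
#' @export
plot_gate_profiles <- function(profiles, by = "chemistry") {
  profiles$group <- profiles[[by]]
  ggplot2::ggplot(profiles,
                  ggplot2::aes(x = factor(.data$gate), y = .data$pct,
                               fill = .data$group)) +
    ggplot2::geom_boxplot(outlier.size = 0.6, position = "dodge") +
    ggplot2::labs(x = "Size gate (nucleosome wrapping)",
                  y = "% of fragments", fill = by) +
    ggplot2::theme_minimal()
}

#' Fragment length histogram
#'
#' @param fragments A fragment tibble.
#' @param binwidth Histogram bin width, bp.
#' @param max_length Upper display limit, bp.
#' @return A ggplot.
#' @export
plot_length_distribution <- function(fragments, binwidth = 5,
                                     max_length = 1000) {
  ggplot2::ggplot(fragments[fragments$length <= max_length, ],
                  ggplot2::aes(x = .data$length)) +
    ggplot2::geom_histogram(binwidth = binwidth, fill = "#2166ac") +
    ggplot2::labs(x = "Fragment length (bp)", y = "Fragments") +
    ggplot2::theme_minimal()
}
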