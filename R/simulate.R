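#' Simulate one cfDNA sample
#'
#' Draws aligned cfDNA fragments from a synthetic genome under a conversion
#' chemistry. The generative model:
#'
#' 1. A candidate fragment picks a bin with probability proportional to
#'    `weight_b * cn_b`, where `cn_b = (1 - tumor_fraction) +
#'    tumor_fraction * cnv_copy_ratio` in copy-number-altered bins and 1
#'    elsewhere.
#' 2. Its length is drawn from the chemistry's nucleosome-peak mixture; with
#'    probability `tumor_fraction` the fragment is tumor-derived and its
#'    length is shifted by the chemistry's `tumor_length_shift`.
#' 3. The candidate is retained with probability
#'    `survival(length, gc of its bin)`; candidates are drawn until
#'    `n_fragments` are retained.
#'
#' The expected retained-fragment allocation across bins is therefore
#' proportional to `weight_b * cn_b * mean-survival_b`.
#'
#' @param genome A `fragcnv_genome` (see [build_genome()]).
#' @param tumor_fraction Proportion of plasma cfDNA that is tumor-derived,
#'   in `[0, 1]`; 0 for controls.
#' @param cnv_bins Integer indices of copy-number-altered bins.
#' @param cnv_copy_ratio Tumor-cell copies divided by 2; values above 1 model
#'   the elevated coverage seen in colorectal-cancer plasma on 18q gains (or,
#'   with the altered block read as the retained complement of a loss
#'   elsewhere, relative gain).
#' @param chemistry Chemistry preset name (`"WGS"`, `"WGES"`, `"WGBS"`) or a
#'   [chemistry_model()].
#' @param n_fragments Number of fragments to emit.
#' @param seed Integer seed; output is deterministic given it.
#' @param min_length Smallest emitted fragment length, bp.
#' @param lambda_multiplier Per-sample multiplier on the chemistry's
#'   degradation rates; `NULL` (default) draws it from the chemistry's
#'   `lambda_sd` (log-normal), 1 disables the sample effect.
#' @return A fragment tibble (`chrom`, `start`, `end`, `length`), sorted by
#'   `start`.
#' @export
simulate_sample <- function(genome, tumor_fraction = 0, cnv_bins = integer(),
                            cnv_copy_ratio = 1, chemistry = "WGES",
                            n_fragments = 20000, seed = 1L,
                            min_length = 50, lambda_multiplier = NULL) {
  chem <- as_chemistry(chemistry)
  stopifnot(tumor_fraction >= 0, tumor_fraction <= 1,
            cnv_copy_ratio > 0, n_fragments > 0)
  bins <- genome$bins
  n_bins <- nrow(bins)
  cn <- rep(1, n_bins)
  if (length(cnv_bins) > 0L) {
    stopifnot(all(cnv_bins >= 1L), all(cnv_bins <= n_bins))
    cn[cnv_bins] <- (1 - tumor_fraction) + tumor_fraction * cnv_copy_ratio
  }
  bin_prob <- bins$weight * cn

  # upper bound on achievable survival anywhere on the genome
  best <- survival_prob(chem, min_length, min(bins$gc))
  if (best < 1e-12) {
    abort("degenerate chemistry: survival is zero over the whole genome",
          class = "fragcnv_validation_error")
  }

  region_start <- genome$region$start
  region_end <- genome$region$end

  out_bin <- integer(0)
  out_len <- numeric(0)
  with_seed(seed, {
    mult <- lambda_multiplier %||%
      (if (chem$lambda_sd > 0) exp(rnorm(1L, 0, chem$lambda_sd)) else 1)
    eff <- scale_chemistry(chem, mult)
    acc_rate <- 0.5
    rounds <- 0L
    while (length(out_bin) < n_fragments) {
      rounds <- rounds + 1L
      if (rounds > 200L) {
        abort("degenerate chemistry: acceptance rate too low to simulate",
              class = "fragcnv_validation_error")
      }
      need <- n_fragments - length(out_bin)
      m <- ceiling(need / max(acc_rate, 1e-3) * 1.1) + 100L
      b <- sample.int(n_bins, m, replace = TRUE, prob = bin_prob)
      is_tumor <- runif(m) < tumor_fraction
      peak <- sample.int(length(chem$peak_centers), m, replace = TRUE,
                         prob = chem$peak_weights)
      len <- round(rnorm(m, chem$peak_centers[peak] +
                           ifelse(is_tumor, chem$tumor_length_shift, 0),
                         chem$peak_sd))
      len <- pmax(len, min_length)
      keep <- runif(m) < survival_prob(eff, len, bins$gc[b])
      acc_rate <- max(mean(keep), 1e-3)
      out_bin <- c(out_bin, b[keep])
      out_len <- c(out_len, len[keep])
    }
    out_bin <- out_bin[seq_len(n_fragments)]
    out_len <- out_len[seq_len(n_fragments)]
    # place the fragment midpoint uniformly within its bin, then shift the
    # whole fragment back inside the region if it overhangs an edge
    mid <- floor(bins$start[out_bin] +
                   runif(n_fragments) * (bins$end[out_bin] - bins$start[out_bin]))
    start <- mid - out_len %/% 2
    start <- pmax(region_start, pmin(start, region_end - out_len))
    end <- start + out_len
  })
  frags <- tibble::tibble(
    chrom = genome$region$chrom,
    start = as.numeric(start),
    end = as.numeric(end),
    length = as.numeric(out_len)
  )
  dplyr::arrange(frags, .data$start, .data$end)
}

# Monte-Carlo estimate of the population mean survival probability of a
# candidate fragment, used to translate an input-molecule budget into a
# retained (sequenced) fragment count.
expected_survival <- function(genome, chem, tumor_fraction = 0,
                              n_mc = 4000, seed = 1L, min_length = 50) {
  bins <- genome$bins
  with_seed(seed, {
    b <- sample.int(nrow(bins), n_mc, replace = TRUE, prob = bins$weight)
    is_tumor <- runif(n_mc) < tumor_fraction
    peak <- sample.int(length(chem$peak_centers), n_mc, replace = TRUE,
                       prob = chem$peak_weights)
    len <- pmax(round(rnorm(n_mc, chem$peak_centers[peak] +
                              ifelse(is_tumor, chem$tumor_length_shift, 0),
                            chem$peak_sd)), min_length)
    out <- mean(survival_prob(chem, len, bins$gc[b]))
  })
  out
}

#' Simulate a full cfDNA cohort to disk
#'
#' Writes one BED fragment file per sample plus a manifest TSV readable by
#' [read_manifest()]. Cancer samples receive a tumor fraction, a shared
#' copy-number-altered bin block, and a stage/location drawn from
#' configurable label distributions, so per-stage and per-location metric
#' reporting is exercisable downstream.
#'
#' @param genome A `fragcnv_genome`.
#' @param out_dir Output directory (created if needed).
#' @param n_train Named vector `c(cancer = , control = )` of training counts.
#' @param n_test Named vector of test counts.
#' @param chemistry Chemistry preset or model applied to every sample.
#' @param tumor_fraction Tumor fraction of cancer samples: a single value or
#'   a `c(lo, hi)` range sampled uniformly per sample.
#' @param cnv_bins Copy-number-altered bin indices; default a contiguous 5%
#'   block via [default_cnv_bins()].
#' @param cnv_copy_ratio Copy ratio in altered bins (tumor copies / 2).
#' @param n_fragments Input cfDNA molecules per sample. With
#'   `conversion_depth_loss = TRUE` (default) the sequenced fragment count is
#'   `n_fragments` times the sample's expected conversion survival, so lossy
#'   chemistries yield shallower libraries at matched plasma input — the
#'   depth cost of bisulfite conversion. With `FALSE`, every sample retains
#'   exactly `n_fragments` fragments.
#' @param conversion_depth_loss Scale sequenced depth by conversion survival
#'   (see `n_fragments`).
#' @param stage_probs Named probability weights over tumor stages for cancer
#'   samples; defaults reflect an early-stage-enriched screening cohort.
#' @param location_probs Named probability weights over colon segments.
#' @param seed Integer seed; all files are byte-identical across reruns.
#' @param prefix Sample-id prefix.
#' @return The manifest tibble (also written to `out_dir/manifest.tsv`).
#' @export
simulate_cohort <- function(genome, out_dir,
                            n_train = c(cancer = 24, control = 24),
                            n_test = c(cancer = 12, control = 12),
                            chemistry = "WGES",
                            tumor_fraction = 0.2,
                            cnv_bins = NULL,
                            cnv_copy_ratio = 3,
                            n_fragments = 20000,
                            conversion_depth_loss = TRUE,
                            stage_probs = c("0" = 3, "I" = 14, "IIA" = 9,
                                            "III" = 7, "IIIA" = 2, "IIIB" = 1),
                            location_probs = NULL,
                            seed = 1L,
                            prefix = NULL) {
  chem <- as_chemistry(chemistry)
  counts <- c(train_cancer = unname(n_train["cancer"]),
              train_control = unname(n_train["control"]),
              test_cancer = unname(n_test["cancer"]),
              test_control = unname(n_test["control"]))
  if (any(is.na(counts)) || any(counts < 1)) {
    abort("each split needs at least one cancer and one control sample",
          class = "fragcnv_validation_error")
  }
  if (is.null(cnv_bins)) cnv_bins <- default_cnv_bins(genome)
  if (is.null(location_probs)) {
    location_probs <- setNames(rep(1, 8), c(
      "cecum", "ileocecal valve", "hepatic flexure", "transverse colon",
      "descending colon", "sigmoid colon", "rectosigmoid", "rectum"
    ))
  }
  if (is.null(prefix)) prefix <- tolower(chem$name)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  plan <- tibble::tibble(
    split = rep(c("train", "train", "test", "test"), counts),
    label = rep(c("cancer", "control", "cancer", "control"), counts)
  )
  n <- nrow(plan)
  plan$sample_id <- sprintf("%s_%s_%s_%02d", prefix, plan$split, plan$label,
                            stats::ave(seq_len(n),
                                       paste(plan$split, plan$label),
                                       FUN = seq_along))
  is_cancer <- plan$label == "cancer"
  with_seed(seed, {
    tf <- numeric(n)
    tf[is_cancer] <- if (length(tumor_fraction) == 2L) {
      runif(sum(is_cancer), tumor_fraction[1L], tumor_fraction[2L])
    } else {
      rep(tumor_fraction, sum(is_cancer))
    }
    stage <- rep(NA_character_, n)
    stage[is_cancer] <- sample(names(stage_probs), sum(is_cancer),
                               replace = TRUE, prob = stage_probs)
    location <- rep(NA_character_, n)
    location[is_cancer] <- sample(names(location_probs), sum(is_cancer),
                                  replace = TRUE, prob = location_probs)
    mult <- if (chem$lambda_sd > 0) exp(rnorm(n, 0, chem$lambda_sd)) else rep(1, n)
  })
  plan$tumor_fraction <- tf
  plan$stage <- stage
  plan$location <- location
  plan$fragments_path <- paste0(plan$sample_id, ".bed")

  for (i in seq_len(n)) {
    n_i <- n_fragments
    if (isTRUE(conversion_depth_loss)) {
      acc <- expected_survival(genome, scale_chemistry(chem, mult[i]),
                               tumor_fraction = plan$tumor_fraction[i],
                               seed = seed + i + 500000L)
      n_i <- max(200L, round(n_fragments * acc))
    }
    frags <- simulate_sample(
      genome,
      tumor_fraction = plan$tumor_fraction[i],
      cnv_bins = if (is_cancer[i]) cnv_bins else integer(),
      cnv_copy_ratio = cnv_copy_ratio,
      chemistry = chem,
      n_fragments = n_i,
      seed = seed + i,
      lambda_multiplier = mult[i]
    )
    write_fragments(frags, file.path(out_dir, plan$fragments_path[i]))
  }

  manifest <- tibble::tibble(
    sample_id = plan$sample_id,
    label = plan$label,
    stage = plan$stage,
    location = plan$location,
    chemistry = chem$name,
    split = plan$split,
    fragments_path = plan$fragments_path
  )
  write_manifest(manifest, file.path(out_dir, "manifest.tsv"))
  manifest$fragments_path <- file.path(out_dir, manifest$fragments_path)
  validate_manifest(manifest)
}
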