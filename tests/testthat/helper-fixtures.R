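# Shared fixtures built in code. The small genome and cohorts are cached per
# test run so several test files can reuse them without re-simulating.

fixture_env <- new.env(parent = emptyenv())

`%||%` <- function(a, b) if (is.null(a)) b else a

small_genome <- function() {
  if (is.null(fixture_env$genome)) {
    fixture_env$genome <- build_genome(
      genomic_region("chr18", 0, 1e7), bin_width = 5000, seed = 11
    )
  }
  fixture_env$genome
}

# uniform-weight genome for multinomial checks
flat_genome <- function(n_mb = 2) {
  build_genome(genomic_region("chr18", 0, n_mb * 1e6), bin_width = 5000,
               gc_coupling = 0, weight_noise_sd = 0, seed = 5)
}

random_fragments <- function(n, chrom = "chr18", max_pos = 1e6, seed = 1) {
  with_local_seed(seed, {
    start <- sort(sample.int(max_pos, n, replace = TRUE)) - 1
    len <- sample(60:600, n, replace = TRUE)
    tibble::tibble(chrom = chrom, start = start, end = start + len,
                   length = len)
  })
}

with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

make_manifest_tsv <- function(path, rows) {
  header <- paste(c("sample_id", "label", "stage", "location", "chemistry",
                    "split", "fragments_path"), collapse = "\t")
  writeLines(c(header, rows), path)
  path
}

manifest_row <- function(id, label, stage = "NA", location = "NA",
                         chemistry = "WGES", split = "test",
                         path = "x.bed") {
  paste(id, label, stage, location, chemistry, split, path, sep = "\t")
}

# cached demo cohort: small genome, WGES chemistry, default study conditions
demo_cohort <- function() {
  if (is.null(fixture_env$cohort)) {
    dir <- file.path(tempdir(), "fragcnv_demo_cohort")
    fixture_env$cohort <- simulate_cohort(small_genome(), dir,
                                          chemistry = "WGES", seed = 101)
  }
  fixture_env$cohort
}

demo_config <- function() pipeline_config(region = small_genome()$region,
                                          seed = 7)

# one canonical orchestrated run, reused across pipeline tests
demo_run <- function() {
  if (is.null(fixture_env$run)) {
    dir <- file.path(tempdir(), "fragcnv_demo_run")
    fixture_env$run <- run_pipeline(demo_cohort(), demo_config(),
                                    genome = small_genome(), out_dir = dir)
    fixture_env$run_dir <- dir
  }
  fixture_env$run
}

demo_run_dir <- function() {
  demo_run()
  fixture_env$run_dir
}

# ten seeded cohort replicates per chemistry, cached so the recovery and
# chemistry-comparison properties evaluate the same runs
acceptance_runs <- function(chemistry) {
  key <- paste0("acc_", chemistry)
  if (is.null(fixture_env[[key]])) {
    g <- small_genome()
    cfg <- pipeline_config(region = g$region, seed = 1)
    fixture_env[[key]] <- purrr::map(1:10, function(i) {
      dir <- file.path(tempdir(), sprintf("acc_%s_%02d", chemistry, i))
      man <- simulate_cohort(g, dir, chemistry = chemistry, seed = 4000L + i)
      generics::glance(run_pipeline(man, cfg, genome = g)$metrics)
    })
  }
  fixture_env[[key]]
}
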