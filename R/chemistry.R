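#' Conversion-chemistry fragment model
#'
#' Describes how a library-preparation chemistry shapes the cfDNA fragment
#' population: a mixture of nucleosome-periodic length peaks (mono- to
#' tetra-nucleosome), a length shift for tumor-derived fragments, and a
#' per-fragment survival probability capturing chemical degradation.
#'
#' Survival is `exp(-(lambda_len * max(0, length - len_onset) + lambda_gc * gc))`:
#' bisulfite conversion destroys long fragments (multi-nucleosome peaks) and
#' depletes GC-rich fragments, while enzymatic conversion (WGES) and plain
#' WGS are near-lossless and lossless respectively.
#'
#' @param peak_centers Nucleosome peak centers, bp (insert-size axis).
#' @param peak_weights Mixture weights over the peaks; normalized internally.
#' @param peak_sd Within-peak standard deviation, bp.
#' @param tumor_length_shift Shift applied to tumor-derived fragment lengths,
#'   bp (negative: ctDNA fragments run shorter than background cfDNA).
#' @param lambda_len Degradation rate per bp of length above `len_onset`.
#' @param lambda_gc Degradation rate per unit GC fraction.
#' @param len_onset Length (bp) above which length-dependent degradation acts.
#' @param lambda_sd Standard deviation of the per-sample log-normal
#'   multiplier on both degradation rates, modelling sample-to-sample
#'   variability in conversion efficiency (a hallmark of bisulfite batches;
#'   0 for deterministic chemistry).
#' @param name Optional label for the model.
#' @return An object of class `fragcnv_chemistry`.
#' @export
#' @examples
#' chemistry_model("WGBS")
#' m <- chemistry_model("WGS")
#' survival_prob(m, length = 500, gc = 0.5) # 1 for WGS
chemistry_model <- function(peak_centers = c(167, 334, 501, 668),
                            peak_weights = 0.28^(0:3),
                            peak_sd = 25,
                            tumor_length_shift = -20,
                            lambda_len = 0,
                            lambda_gc = 0,
                            len_onset = 250,
                            lambda_sd = 0,
                            name = "custom") {
  if (is.character(peak_centers) && length(peak_centers) == 1L) {
    return(chemistry_preset(peak_centers))
  }
  stopifnot(length(peak_centers) >= 1L,
            length(peak_weights) == length(peak_centers),
            all(peak_weights >= 0), sum(peak_weights) > 0,
            peak_sd > 0, lambda_len >= 0, lambda_gc >= 0, lambda_sd >= 0)
  structure(
    list(
      peak_centers = as.numeric(peak_centers),
      peak_weights = as.numeric(peak_weights) / sum(peak_weights),
      peak_sd = peak_sd,
      tumor_length_shift = tumor_length_shift,
      lambda_len = lambda_len,
      lambda_gc = lambda_gc,
      len_onset = len_onset,
      lambda_sd = lambda_sd,
      name = name
    ),
    class = "fragcnv_chemistry"
  )
}

chemistry_preset <- function(name) {
  switch(
    name,
    WGS = chemistry_model(lambda_len = 0, lambda_gc = 0, name = "WGS"),
    WGES = chemistry_model(lambda_len = 2e-4, lambda_gc = 0.1,
                           lambda_sd = 0.1, name = "WGES"),
    WGBS = chemistry_model(lambda_len = 4e-3, lambda_gc = 1.5,
                           lambda_sd = 0.5, name = "WGBS"),
    abort(paste0("unknown chemistry preset: ", name,
                 " (available: WGS, WGES, WGBS)"),
          class = "fragcnv_validation_error")
  )
}

# chemistry with degradation rates scaled by a per-sample multiplier
scale_chemistry <- function(chem, multiplier) {
  chem$lambda_len <- chem$lambda_len * multiplier
  chem$lambda_gc <- chem$lambda_gc * multiplier
  chem
}

as_chemistry <- function(x) {
  if (inherits(x, "fragcnv_chemistry")) return(x)
  if (is.character(x) && length(x) == 1L) return(chemistry_preset(x))
  abort("chemistry must be a preset name or a chemistry_model()",
        class = "fragcnv_validation_error")
}

#' Per-fragment survival probability under a chemistry
#'
#' @param model A `fragcnv_chemistry` object or preset name.
#' @param length Fragment length(s), bp.
#' @param gc GC fraction(s) in `[0, 1]` at the fragment's location.
#' @return Retention probabilities in `[0, 1]`, vectorized over inputs.
#' @export
survival_prob <- function(model, length, gc) {
  model <- as_chemistry(model)
  exp(-(model$lambda_len * pmax(0, length - model$len_onset) +
          model$lambda_gc * gc))
}

#' @export
print.fragcnv_chemistry <- function(x, ...) {
  cat("<fragcnv chemistry:", x$name, ">\n")
  cat("  peaks (bp):", paste(x$peak_centers, collapse = ", "),
      " sd:", x$peak_sd, "\n")
  cat("  weights:", paste(signif(x$peak_weights, 3), collapse = ", "), "\n")
  cat("  tumor length shift:", x$tumor_length_shift, "bp\n")
  cat("  degradation: lambda_len =", x$lambda_len,
      " lambda_gc =", x$lambda_gc, " onset =", x$len_onset,
      "bp  per-sample sd =", x$lambda_sd, "\n")
  invisible(x)
}
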