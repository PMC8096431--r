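#' Pipeline configuration
#'
#' Collects the tolerances and thresholds shared across the analysis stages.
#' Defaults are the study constants: +/-5 ppm mass accuracy, +/-0.1 min
#' adduct co-elution window, peak intensity > 1e6 for presence/absence,
#' Bliss-excess threshold 0.08 at alpha 0.05.
#'
#' @param ppm_tol Mass accuracy tolerance in ppm (inclusive bound).
#' @param rt_tol_min Retention-time co-elution window in minutes (inclusive).
#' @param intensity_threshold Strict lower bound for calling a feature
#'   present in a sample (arbitrary intensity units).
#' @param b_threshold Bliss-excess classification threshold.
#' @param alpha Significance level for interaction and group tests.
#' @param entanglement_L Exponent of the entanglement score.
#' @param adducts Adduct table, see [default_adducts()].
#' @param seed Optional integer seed recorded with the run.
#' @return A named list of class `chem_config`.
#' @export
chem_config <- function(ppm_tol = 5, rt_tol_min = 0.1,
                        intensity_threshold = 1e6, b_threshold = 0.08,
                        alpha = 0.05, entanglement_L = 1.5,
                        adducts = default_adducts(), seed = NULL) {
  stopifnot(ppm_tol > 0, rt_tol_min > 0, intensity_threshold > 0,
            b_threshold > 0, alpha > 0, alpha < 1, entanglement_L > 0)
  structure(list(ppm_tol = ppm_tol, rt_tol_min = rt_tol_min,
                 intensity_threshold = intensity_threshold,
                 b_threshold = b_threshold, alpha = alpha,
                 entanglement_L = entanglement_L, adducts = adducts,
                 seed = seed),
            class = "chem_config")
}

# Derive a per-generator substream seed from one root seed, so that adding a
# generator call does not shift the draws of the others. Kept below 2^31.
substream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((abs(seed) * 7919 + h * 104729) %% .Machine$integer.max)
}

# Evaluate expr under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}
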