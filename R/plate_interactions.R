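# Bliss-independence interaction analysis of resazurin microdilution plates.
#
# A plate table holds well-level fluorescence for treatments (single
# compounds and pairwise combinations), inoculum controls (spores + medium),
# medium sterility controls, and optional solvent controls. Fractional
# inhibition normalises treatment fluorescence against the inoculum- and
# medium-control means; the Bliss Independence model supplies the expected
# combined inhibition under independent action, and the Bliss excess
# b = E_bliss - FI_AB together with a Welch t-test classifies each pair as
# synergistic, additive, antagonistic or indeterminate.

#' Fractional inhibition from plate fluorescence
#'
#' Normalises a treatment fluorescence reading against the mean fluorescence
#' of the inoculum control (uninhibited growth, FI = 0) and the medium
#' sterility control (no growth, FI = 1):
#' \deqn{FI = 1 - (T_F - MC_F) / (IC_F - MC_F)}
#' Values are deliberately not clipped to \[0, 1\]: FI < 0 indicates growth
#' stimulation and FI > 1 fluorescence below the sterile-medium baseline;
#' both propagate unchanged into downstream means and the Bliss excess,
#' since clipping would bias interaction calls.
#'
#' @param t_f Treatment fluorescence (vectorised).
#' @param mc_f_mean Mean fluorescence of the medium sterility control wells.
#' @param ic_f_mean Mean fluorescence of the inoculum control wells.
#' @return Dimensionless fractional inhibition, same length as `t_f`.
#' @export
#' @examples
#' compute_fi(400, mc_f_mean = 100, ic_f_mean = 1100) # 0.7
compute_fi <- function(t_f, mc_f_mean, ic_f_mean) {
  stopifnot(is.numeric(t_f), length(mc_f_mean) == 1L, length(ic_f_mean) == 1L)
  if (!is.finite(mc_f_mean) || !is.finite(ic_f_mean)) {
    stop("control means must be finite")
  }
  if (ic_f_mean == mc_f_mean) {
    stop("degenerate controls: inoculum-control mean equals medium-control mean (",
         format(ic_f_mean), "); fractional inhibition is undefined")
  }
  1 - (t_f - mc_f_mean) / (ic_f_mean - mc_f_mean)
}

#' Percent inhibition
#'
#' @param fi Fractional inhibition (dimensionless).
#' @return `fi * 100`, in percent.
#' @export
percent_inhibition <- function(fi) {
  stopifnot(is.numeric(fi), all(is.finite(fi)))
  fi * 100
}

#' Bliss expected combined inhibition
#'
#' Expected fractional inhibition of a pair of independently acting
#' inhibitors: \eqn{E = FI_A + FI_B - FI_A FI_B}. Vectorised and symmetric.
#'
#' @param fi_a,fi_b Fractional inhibitions of the single compounds.
#' @return Expected combined fractional inhibition.
#' @export
bliss_expected <- function(fi_a, fi_b) {
  stopifnot(is.numeric(fi_a), is.numeric(fi_b),
            all(is.finite(fi_a)), all(is.finite(fi_b)))
  fi_a + fi_b - fi_a * fi_b
}

#' Bliss expected values over all replicate combinations
#'
#' The expected-value distribution is built from the single-compound
#' replicates in all possible combinations (Cartesian product), giving
#' `length(fi_reps_a) * length(fi_reps_b)` values in row-major order:
#' the first replicate of A paired with every replicate of B, then the
#' second, and so on.
#'
#' @param fi_reps_a,fi_reps_b Replicate FI values of each single compound.
#' @return Numeric vector of Bliss expected values, length `n_a * n_b`.
#' @export
all_pairs_expected <- function(fi_reps_a, fi_reps_b) {
  if (length(fi_reps_a) == 0L || length(fi_reps_b) == 0L) {
    stop("all_pairs_expected requires non-empty replicate vectors")
  }
  # a-outer, b-inner ordering
  as.vector(t(outer(fi_reps_a, fi_reps_b, bliss_expected)))
}

#' Bliss excess
#'
#' `b = e_bliss_mean - fi_ab_mean`: the mean expected combined inhibition
#' minus the mean observed combined inhibition. Under the classification
#' convention used here, `b >= b_threshold` with p <= alpha is called
#' synergistic and `b <= -b_threshold` antagonistic.
#'
#' @param e_bliss_mean Mean of the Bliss expected values.
#' @param fi_ab_mean Mean observed FI of the combination wells.
#' @return The Bliss excess `b`.
#' @export
bliss_excess <- function(e_bliss_mean, fi_ab_mean) {
  stopifnot(is.finite(e_bliss_mean), is.finite(fi_ab_mean))
  e_bliss_mean - fi_ab_mean
}

#' Welch t-test between Bliss expected values and observed combination FIs
#'
#' Two-sided Welch (unequal variance) two-sample t-test comparing the mean
#' of the expected-value distribution with the mean observed combination FI.
#' Degenerate zero-variance inputs are handled explicitly: if both samples
#' are constant and equal (to relative machine epsilon) the test is a
#' perfect null (t = 0, p = 1); if both are constant but clearly different
#' the difference is infinitely significant (t = +/-Inf, p = 0), which keeps
#' noiseless simulated plates classifiable.
#'
#' @param e_bliss_values Bliss expected values (length >= 2).
#' @param fi_ab_reps Observed combination FI replicates (length >= 2).
#' @return List with elements `t_stat`, `p_value`, `df`.
#' @export
interaction_test <- function(e_bliss_values, fi_ab_reps) {
  if (length(e_bliss_values) < 2L || length(fi_ab_reps) < 2L) {
    stop("interaction_test requires >= 2 values in each sample")
  }
  welch_test(e_bliss_values, fi_ab_reps)
}

# Shared Welch machinery (also used by the competition-assay module).
welch_test <- function(x, y) {
  vx <- stats::var(x)
  vy <- stats::var(y)
  if (vx == 0 && vy == 0) {
    d <- mean(x) - mean(y)
    scale <- max(abs(mean(x)), abs(mean(y)), 1)
    if (abs(d) <= .Machine$double.eps * 8 * scale) {
      return(list(t_stat = 0, p_value = 1, df = NA_real_))
    }
    return(list(t_stat = sign(d) * Inf, p_value = 0, df = NA_real_))
  }
  ht <- stats::t.test(x, y, var.equal = FALSE, alternative = "two.sided")
  list(t_stat = unname(ht$statistic), p_value = ht$p.value,
       df = unname(ht$parameter))
}

#' Classify a compound-pair interaction
#'
#' Applies the threshold rule on the Bliss excess `b` and the t-test
#' p-value: when p <= alpha, `b >= b_threshold` is synergistic,
#' `b <= -b_threshold` antagonistic, and values between the thresholds
#' additive. When p > alpha the pair is additive if `|b| <= b_threshold`
#' and indeterminate otherwise (a large excess that the test cannot
#' distinguish from noise is left uncalled rather than silently labelled
#' additive).
#'
#' @param b Bliss excess.
#' @param p Two-sided p-value from [interaction_test()].
#' @param b_threshold Classification threshold on `|b|` (default 0.08).
#' @param alpha Significance level (default 0.05).
#' @return One of `"synergistic"`, `"additive"`, `"antagonistic"`,
#'   `"indeterminate"`.
#' @export
classify_interaction <- function(b, p, b_threshold = 0.08, alpha = 0.05) {
  stopifnot(is.finite(b), p >= 0, p <= 1, b_threshold > 0,
            alpha > 0, alpha < 1)
  if (p > alpha) {
    if (abs(b) <= b_threshold) "additive" else "indeterminate"
  } else if (b >= b_threshold) {
    "synergistic"
  } else if (b <= -b_threshold) {
    "antagonistic"
  } else {
    "additive"
  }
}

# --- plate-table plumbing ---------------------------------------------------

plate_roles <- c("treatment", "inoculum_control", "medium_control",
                 "solvent_control")

#' Validate a plate table
#'
#' Checks the structural invariants of a well-level fluorescence table:
#' required columns, known roles, nonnegative fluorescence, at least one
#' inoculum and one medium control, compounds named on every treatment row,
#' and >= 2 replicates per treatment group.
#'
#' @param plate A data frame with columns `well_id`, `role`, `compound_a`,
#'   `conc_a`, `compound_b`, `conc_b`, `replicate`, `fluorescence`.
#' @return The validated table, invisibly coerced to a tibble.
#' @export
validate_plate_table <- function(plate) {
  req <- c("well_id", "role", "compound_a", "conc_a", "compound_b",
           "conc_b", "replicate", "fluorescence")
  missing_cols <- setdiff(req, names(plate))
  if (length(missing_cols)) {
    stop("plate table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  plate <- tibble::as_tibble(plate)
  bad_role <- setdiff(unique(plate$role), plate_roles)
  if (length(bad_role)) {
    stop("unknown role(s): ", paste(bad_role, collapse = ", "))
  }
  if (any(!is.finite(plate$fluorescence)) || any(plate$fluorescence < 0)) {
    stop("fluorescence must be finite and nonnegative")
  }
  missing_roles <- setdiff(c("inoculum_control", "medium_control"),
                           unique(plate$role))
  if (length(missing_roles)) {
    stop("plate table lacks required control role(s): ",
         paste(missing_roles, collapse = ", "))
  }
  trt <- plate[plate$role == "treatment", ]
  if (nrow(trt)) {
    no_compound <- is.na(trt$compound_a) | trt$compound_a == ""
    if (any(no_compound)) {
      stop("treatment row(s) without a compound: ",
           paste(trt$well_id[no_compound], collapse = ", "))
    }
    key <- treatment_key(trt)
    n_rep <- table(key)
    if (any(n_rep < 2L)) {
      stop("treatment group(s) with < 2 replicates: ",
           paste(names(n_rep)[n_rep < 2L], collapse = "; "))
    }
  }
  invisible(plate)
}

# Canonical group key for a treatment row: compound(s) and concentration(s).
treatment_key <- function(rows) {
  b <- ifelse(is.na(rows$compound_b) | rows$compound_b == "", "",
              paste0(" + ", rows$compound_b, "@", rows$conc_b))
  paste0(rows$compound_a, "@", rows$conc_a, b)
}

#' Per-well fractional inhibition for a whole plate
#'
#' Computes the control means (medium sterility, and inoculum or solvent
#' control) and the FI of every treatment well. With
#' `use_solvent_control = TRUE` the solvent-control wells (spores + medium +
#' solvent) replace the plain inoculum control as the 0-inhibition baseline,
#' which corrects for any solvent effect.
#'
#' @param plate A validated plate table.
#' @param use_solvent_control Use solvent-control wells as the growth
#'   baseline instead of the inoculum control.
#' @return Tibble of treatment rows with columns `group`, `compound_a`,
#'   `conc_a`, `compound_b`, `conc_b`, `replicate`, `fi`, plus attributes
#'   `ic_mean`, `mc_mean` and `solvent_fi` (mean FI of solvent wells, as a
#'   QC quantity, when present).
#' @export
plate_fi <- function(plate, use_solvent_control = FALSE) {
  plate <- validate_plate_table(plate)
  mc <- plate$fluorescence[plate$role == "medium_control"]
  baseline_role <- if (use_solvent_control) "solvent_control" else
    "inoculum_control"
  ic <- plate$fluorescence[plate$role == baseline_role]
  if (use_solvent_control && !length(ic)) {
    stop("use_solvent_control = TRUE but the plate has no solvent_control rows")
  }
  mc_mean <- mean(mc)
  ic_mean <- mean(ic)
  trt <- plate[plate$role == "treatment", ]
  out <- tibble::tibble(
    group = treatment_key(trt),
    compound_a = trt$compound_a, conc_a = trt$conc_a,
    compound_b = trt$compound_b, conc_b = trt$conc_b,
    replicate = trt$replicate,
    fi = compute_fi(trt$fluorescence, mc_mean, ic_mean)
  )
  attr(out, "ic_mean") <- ic_mean
  attr(out, "mc_mean") <- mc_mean
  sv <- plate$fluorescence[plate$role == "solvent_control"]
  if (length(sv)) {
    attr(out, "solvent_fi") <- mean(compute_fi(sv, mc_mean, ic_mean))
  }
  out
}

#' Run the full plate interaction pipeline
#'
#' For every pairwise combination present in the plate, computes the
#' single-compound FI replicate sets, the Bliss expected-value distribution
#' (all replicate combinations, or per-replicate-index pairing in the
#' conservative mode), the Bliss excess, the Welch t-test, and the
#' interaction class. Solvent-control wells contribute a QC mean FI but
#' never enter pair classification.
#'
#' @param plate Plate table (see [validate_plate_table()]).
#' @param config A [chem_config()] list; `b_threshold` and `alpha` are used.
#' @param expected_mode `"all_pairs"` (default; the n_a x n_b cross of
#'   single-compound replicates) or `"paired"` (replicate i of A with
#'   replicate i of B only; conservative, avoids pseudo-replication).
#' @param use_solvent_control Passed to [plate_fi()].
#' @return Tibble with one row per (pair, concentration combination):
#'   compounds, concentrations, `fi_a_mean`, `fi_b_mean`, `fi_ab_mean`,
#'   `e_bliss_mean`, `bliss_excess`, `t_stat`, `p_value`, `n_expected`,
#'   `n_observed`, `label`. The per-pair expected-value vectors are kept in
#'   the attribute `e_bliss_values` (named list).
#' @export
run_interaction_pipeline <- function(plate, config = chem_config(),
                                     expected_mode = c("all_pairs", "paired"),
                                     use_solvent_control = FALSE) {
  expected_mode <- match.arg(expected_mode)
  fi_tab <- plate_fi(plate, use_solvent_control = use_solvent_control)
  is_pair <- !(is.na(fi_tab$compound_b) | fi_tab$compound_b == "")
  singles <- split(fi_tab$fi[!is_pair], fi_tab$group[!is_pair])
  pairs <- fi_tab[is_pair, ]
  if (!nrow(pairs)) {
    stop("plate contains no pairwise-combination treatment rows")
  }
  res <- list()
  e_store <- list()
  for (g in unique(pairs$group)) {
    rows <- pairs[pairs$group == g, ]
    key_a <- paste0(rows$compound_a[1], "@", rows$conc_a[1])
    key_b <- paste0(rows$compound_b[1], "@", rows$conc_b[1])
    for (k in c(key_a, key_b)) {
      if (is.null(singles[[k]])) {
        stop("combination '", g, "' lacks single-compound wells for '", k, "'")
      }
    }
    fi_a <- singles[[key_a]]
    fi_b <- singles[[key_b]]
    e_vals <- if (expected_mode == "all_pairs") {
      all_pairs_expected(fi_a, fi_b)
    } else {
      n <- min(length(fi_a), length(fi_b))
      bliss_expected(fi_a[seq_len(n)], fi_b[seq_len(n)])
    }
    fi_ab <- rows$fi
    b <- bliss_excess(mean(e_vals), mean(fi_ab))
    tst <- interaction_test(e_vals, fi_ab)
    res[[g]] <- tibble::tibble(
      pair = g,
      compound_a = rows$compound_a[1], conc_a = rows$conc_a[1],
      compound_b = rows$compound_b[1], conc_b = rows$conc_b[1],
      fi_a_mean = mean(fi_a), fi_b_mean = mean(fi_b),
      fi_ab_mean = mean(fi_ab), e_bliss_mean = mean(e_vals),
      bliss_excess = b, t_stat = tst$t_stat, p_value = tst$p_value,
      n_expected = length(e_vals), n_observed = length(fi_ab),
      label = classify_interaction(b, tst$p_value,
                                   b_threshold = config$b_threshold,
                                   alpha = config$alpha)
    )
    e_store[[g]] <- e_vals
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "e_bliss_values") <- e_store
  attr(out, "solvent_fi") <- attr(fi_tab, "solvent_fi")
  out
}
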