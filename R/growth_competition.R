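# Fold-change statistics for the frass competition assay: CFU counts at
# inoculation and after incubation, per organism per treatment, compared by
# Welch t-test (two groups) or one-way ANOVA with Tukey HSD (more groups).

#' Growth fold change from CFU counts
#'
#' `cfu_final / cfu_initial`; 0 marks extinction (final count below the
#' plating detection limit is recorded as 0 and enters the fold change as
#' 0 rather than being excluded). Vectorised.
#'
#' @param cfu_initial Initial colony counts, strictly positive.
#' @param cfu_final Final colony counts, nonnegative.
#' @return Dimensionless fold changes.
#' @export
fold_change <- function(cfu_initial, cfu_final) {
  stopifnot(length(cfu_initial) == length(cfu_final))
  bad <- which(!(cfu_initial > 0))
  if (length(bad)) {
    stop("nonpositive initial CFU count in row(s): ",
         paste(bad, collapse = ", "))
  }
  if (any(cfu_final < 0)) stop("negative final CFU count")
  cfu_final / cfu_initial
}

#' Compare fold changes of two treatment groups
#'
#' Two-sided Welch t-test on the natural scale (as the assay reports fold
#' changes); set `log10_mode = TRUE` to test log10 fold changes instead,
#' which is more robust when dispersions are multiplicative.
#'
#' @param fc_a,fc_b Fold-change vectors, length >= 2 each.
#' @param log10_mode Test log10-transformed values (requires all > 0).
#' @return List with `t_stat`, `p_value`, `df`.
#' @export
compare_two_groups <- function(fc_a, fc_b, log10_mode = FALSE) {
  if (length(fc_a) < 2L || length(fc_b) < 2L) {
    stop("compare_two_groups requires >= 2 values per group")
  }
  if (log10_mode) {
    if (any(fc_a <= 0) || any(fc_b <= 0)) {
      stop("log10 mode requires strictly positive fold changes")
    }
    fc_a <- log10(fc_a)
    fc_b <- log10(fc_b)
  }
  welch_test(fc_a, fc_b)
}

#' Compare fold changes of three or more treatment groups
#'
#' One-way ANOVA followed by Tukey's HSD; pairwise p-values are adjusted
#' with the studentized-range distribution.
#'
#' @param groups Named list of fold-change vectors (>= 3 groups, each
#'   >= 2 values).
#' @param log10_mode Analyse log10 fold changes.
#' @return List with `anova_F`, `anova_p`, `df_between`, `df_within`, and
#'   `tukey` (tibble: `contrast`, `diff`, `lwr`, `upr`, `p_adj`).
#' @export
compare_many_groups <- function(groups, log10_mode = FALSE) {
  if (length(groups) < 3L) {
    stop("fewer than 3 groups; use compare_two_groups()")
  }
  if (any(vapply(groups, length, 0L) < 2L)) {
    stop("every group needs >= 2 replicates")
  }
  y <- unlist(groups, use.names = FALSE)
  if (log10_mode) {
    if (any(y <= 0)) stop("log10 mode requires strictly positive fold changes")
    y <- log10(y)
  }
  g <- factor(rep(names(groups), vapply(groups, length, 0L)))
  fit <- stats::aov(y ~ g)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$g
  list(
    anova_F = an[["F value"]][1],
    anova_p = an[["Pr(>F)"]][1],
    df_between = an[["Df"]][1],
    df_within = an[["Df"]][2],
    tukey = tibble::tibble(
      contrast = rownames(tk),
      diff = tk[, "diff"], lwr = tk[, "lwr"], upr = tk[, "upr"],
      p_adj = tk[, "p adj"]
    )
  )
}

#' Fold-change analysis of a CFU table
#'
#' Computes per-row fold changes and, per organism, compares treatments:
#' Welch t-test for two treatments, ANOVA + Tukey for more.
#'
#' @param cfu CFU table: `organism`, `treatment`, `replicate`,
#'   `cfu_initial`, `cfu_final`.
#' @param log10_mode Analyse log10 fold changes.
#' @return List per organism with `fold_changes` (tibble) and `test`.
#' @export
analyze_cfu <- function(cfu, log10_mode = FALSE) {
  req <- c("organism", "treatment", "replicate", "cfu_initial", "cfu_final")
  missing_cols <- setdiff(req, names(cfu))
  if (length(missing_cols)) {
    stop("CFU table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  cfu$fold_change <- fold_change(cfu$cfu_initial, cfu$cfu_final)
  out <- list()
  for (org in unique(cfu$organism)) {
    sub <- cfu[cfu$organism == org, ]
    groups <- split(sub$fold_change, sub$treatment)
    if (any(vapply(groups, length, 0L) < 2L)) {
      stop("organism '", org, "' has a treatment with < 2 replicates")
    }
    test <- if (length(groups) == 2L) {
      c(list(method = "welch_t"),
        compare_two_groups(groups[[1]], groups[[2]], log10_mode = log10_mode))
    } else if (length(groups) >= 3L) {
      c(list(method = "anova_tukey"),
        compare_many_groups(groups, log10_mode = log10_mode))
    } else {
      list(method = "none")
    }
    out[[org]] <- list(fold_changes = tibble::as_tibble(sub), test = test)
  }
  out
}
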