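# Synthetic-data generators with known ground truth for every analysis
# stage: resazurin plates with configurable true inhibitions and Bliss
# excess, LC-MS feature tables with spiked compounds, adduct series, decoys
# and blank contaminants, leaf-matched dendrogram pairs with controlled
# discordance, and CFU tables with configurable fold changes. Each
# generator derives its own substream from the root seed, so adding one
# call never shifts the draws of another, and reruns under the same seed
# are byte-identical.

#' Simulate a resazurin interaction plate
#'
#' Inverse model of the fractional-inhibition formula: a well with true
#' inhibition f fluoresces `Normal(ic_mean - f * (ic_mean - mc_mean),
#' noise_sd * (ic_mean - mc_mean))` — noise scales with the control dynamic
#' range so FI noise is comparable across plates. Combination wells use
#' `fi_ab_true = bliss_expected(fi_a_true, fi_b_true) - b_true`, so the
#' pipeline's recovered Bliss excess estimates `b_true`. Inoculum-,
#' medium- and solvent-control wells are included.
#'
#' @param fi_a_true,fi_b_true True single-compound fractional inhibitions.
#' @param b_true True Bliss excess (0 = exact independence).
#' @param n_replicates Biological replicates per arm (default 7).
#' @param noise_sd Noise as a fraction of the control dynamic range.
#' @param ic_mean,mc_mean True inoculum- and medium-control fluorescence.
#' @param compound_a,compound_b,conc_a,conc_b Labels and concentrations
#'   (ug/mL) written into the table.
#' @param seed Integer seed.
#' @return A plate table (see [validate_plate_table()]) with the true FI
#'   values in attribute `"truth"`.
#' @export
simulate_plate <- function(fi_a_true = 0.4, fi_b_true = 0.4, b_true = 0,
                           n_replicates = 7L, noise_sd = 0.02,
                           ic_mean = 20000, mc_mean = 2000,
                           compound_a = "cmpdA", compound_b = "cmpdB",
                           conc_a = 15, conc_b = 15, seed = 1L) {
  stopifnot(mc_mean < ic_mean, n_replicates >= 2L, noise_sd >= 0)
  rng <- ic_mean - mc_mean
  fi_ab_true <- bliss_expected(fi_a_true, fi_b_true) - b_true
  for (f in c(fi_a_true, fi_b_true, fi_ab_true)) {
    if (ic_mean - f * rng < 0) {
      stop("true FI ", format(f), " implies negative fluorescence; ",
           "use a smaller FI/excess or a larger medium-control mean")
    }
  }
  with_seed(substream_seed(seed, "plate"), {
    draw <- function(f, n) stats::rnorm(n, ic_mean - f * rng, noise_sd * rng)
    n <- n_replicates
    rows <- list(
      tibble::tibble(role = "treatment", compound_a = compound_a,
                     conc_a = conc_a, compound_b = "", conc_b = NA_real_,
                     replicate = seq_len(n), fluorescence = draw(fi_a_true, n)),
      tibble::tibble(role = "treatment", compound_a = compound_b,
                     conc_a = conc_b, compound_b = "", conc_b = NA_real_,
                     replicate = seq_len(n), fluorescence = draw(fi_b_true, n)),
      tibble::tibble(role = "treatment", compound_a = compound_a,
                     conc_a = conc_a, compound_b = compound_b, conc_b = conc_b,
                     replicate = seq_len(n), fluorescence = draw(fi_ab_true, n)),
      tibble::tibble(role = "inoculum_control", compound_a = "", conc_a = NA,
                     compound_b = "", conc_b = NA, replicate = seq_len(n),
                     fluorescence = draw(0, n)),
      tibble::tibble(role = "medium_control", compound_a = "", conc_a = NA,
                     compound_b = "", conc_b = NA, replicate = seq_len(n),
                     fluorescence = draw(1, n)),
      tibble::tibble(role = "solvent_control", compound_a = "", conc_a = NA,
                     compound_b = "", conc_b = NA, replicate = seq_len(n),
                     fluorescence = draw(0, n))
    )
    plate <- do.call(rbind, rows)
    plate <- cbind(tibble::tibble(well_id = sprintf("W%03d",
                                                    seq_len(nrow(plate)))),
                   plate)
    plate <- tibble::as_tibble(plate)
    attr(plate, "truth") <- list(fi_a = fi_a_true, fi_b = fi_b_true,
                                 fi_ab = fi_ab_true, b = b_true)
    plate
  })
}

#' Reference compound library of the gallery system
#'
#' A small synthetic stand-in for the dereplication library: one
#' representative per family detected in the system (actinomycins,
#' angucyclinones, nactins, polyene macrolides, cycloheximide, piericidins,
#' alteramides), with real monoisotopic masses, synthetic reference
#' retention times and synthetic stick MS2 spectra.
#'
#' @return List with `library` (tibble: `name`, `family`,
#'   `monoisotopic_mass`, `is_polyene`, `reference_rt`,
#'   `standard_available`) and `ref_spectra` (named list of
#'   `list(spectrum, source)`).
#' @export
default_compound_library <- function() {
  lib <- tibble::tibble(
    name = c("actinomycin X2", "actinomycin D", "STA-21", "cycloheximide",
             "monactin", "filipin III", "piericidin A", "alteramide A"),
    family = c("actinomycins", "actinomycins", "angucyclinones",
               "cycloheximide", "nactins", "polyene macrolides",
               "piericidins", "PTMs"),
    monoisotopic_mass = c(1268.600, 1254.628, 322.084, 281.163,
                          750.442, 654.397, 415.272, 510.298),
    is_polyene = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE),
    reference_rt = c(8.2, 8.0, 5.1, 3.4, 9.6, 7.3, 10.2, 6.8),
    standard_available = c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE, FALSE, FALSE)
  )
  # deterministic synthetic stick spectra: 8 fragments per compound
  ref_spectra <- lapply(seq_len(nrow(lib)), function(i) {
    m <- lib$monoisotopic_mass[i]
    frags <- round(m * seq(0.15, 0.92, length.out = 8) + (i * 7) %% 13, 3)
    inten <- 100 * (0.35 + 0.65 * abs(sin(seq_len(8) + i)))
    list(spectrum = cbind(mz = frags, intensity = inten),
         source = if (lib$standard_available[i]) "standard" else "library")
  })
  names(ref_spectra) <- lib$name
  list(library = lib, ref_spectra = ref_spectra)
}

#' Simulate an LC-MS feature table with known ground truth
#'
#' Spikes each library compound into the environmental samples as a
#' co-eluting adduct series ([M+H]+, [M+Na]+, [M+NH4]+) with truncated
#' Gaussian mass error (sd `ppm_error_sd`, clamped at `ppm_error_max`) and
#' truncated Gaussian retention-time jitter, detected in the LC-MS/MS run
#' and all technical replicates; attaches the reference MS2 spectrum to the
#' protonated feature in the MS/MS run. Adds decoy features at least
#' `decoy_min_ppm` away from every theoretical library m/z, and blank
#' contaminants detected in the blank runs.
#'
#' @param library_set As from [default_compound_library()].
#' @param samples Environmental sample ids.
#' @param n_technical_replicates LC-MS technical replicates per sample.
#' @param ppm_error_sd,ppm_error_max Spike mass-error model (ppm).
#' @param rt_jitter_sd,rt_jitter_max Spike RT-jitter model (minutes).
#' @param n_decoys,decoy_min_ppm Decoy features and their minimum distance
#'   from any library adduct m/z.
#' @param n_blank_contaminants Features spiked into the blank runs.
#' @param base_intensity Spike intensity scale (arbitrary units).
#' @param adducts Adduct labels used for the spike series.
#' @param seed Integer seed.
#' @return List: `features` (feature table), `spectra` (query MS2 list),
#'   `sample_groups` (for [annotate_features()]), `blank_ids`, `truth`
#'   (tibble of spiked feature/compound/adduct/sample), and `library_set`.
#' @export
simulate_features <- function(library_set = default_compound_library(),
                              samples = c("envA", "envB"),
                              n_technical_replicates = 3L,
                              ppm_error_sd = 1, ppm_error_max = 3,
                              rt_jitter_sd = 0.01, rt_jitter_max = 0.03,
                              n_decoys = 500L, decoy_min_ppm = 20,
                              n_blank_contaminants = 25L,
                              base_intensity = 5e6,
                              adducts = c("[M+H]+", "[M+Na]+", "[M+NH4]+"),
                              seed = 1L) {
  lib <- library_set$library
  adduct_tab <- default_adducts()
  adduct_tab <- adduct_tab[adduct_tab$label %in% adducts, ]
  stopifnot(nrow(adduct_tab) == length(adducts))
  run_ids <- c(
    unlist(lapply(samples, function(s)
      c(paste0(s, "_msms"), paste0(s, "_r", seq_len(n_technical_replicates))))),
    "blank_meoh", "blank_medium"
  )
  blank_ids <- c("blank_meoh", "blank_medium")
  sample_groups <- stats::setNames(lapply(samples, function(s) {
    list(msms = paste0(s, "_msms"),
         lcms = paste0(s, "_r", seq_len(n_technical_replicates)))
  }), samples)

  with_seed(substream_seed(seed, "features"), {
    rtrunc_norm <- function(n, sd, lim) {
      if (sd == 0) return(rep(0, n))
      x <- stats::rnorm(n, 0, sd)
      pmax(pmin(x, lim), -lim)
    }
    feats <- list()
    spectra <- list()
    truth <- list()
    fid <- 0L
    new_fid <- function() {
      fid <<- fid + 1L
      sprintf("F%05d", fid)
    }
    zero_row <- stats::setNames(as.list(rep(0, 2 * length(run_ids))),
                                c(paste0("intensity_", run_ids),
                                  paste0("has_ms2_", run_ids)))
    add_feature <- function(mz, rt, present_runs, inten, ms2_runs = character()) {
      id <- new_fid()
      row <- c(list(feature_id = id, mz = mz, rt = rt), zero_row)
      for (r in present_runs) {
        row[[paste0("intensity_", r)]] <-
          inten * exp(stats::rnorm(1, 0, 0.1))
      }
      for (r in ms2_runs) row[[paste0("has_ms2_", r)]] <- 1
      feats[[length(feats) + 1L]] <<- tibble::as_tibble(row)
      id
    }

    theo_all <- unlist(lapply(lib$monoisotopic_mass, function(m)
      theoretical_mz(m, default_adducts()$mass_shift,
                     default_adducts()$charge)))

    # spiked compounds: full adduct series in every environmental sample
    for (ci in seq_len(nrow(lib))) {
      for (s in samples) {
        grp <- sample_groups[[s]]
        runs <- c(grp$msms, grp$lcms)
        for (ai in seq_len(nrow(adduct_tab))) {
          theo <- theoretical_mz(lib$monoisotopic_mass[ci],
                                 adduct_tab$mass_shift[ai],
                                 adduct_tab$charge[ai])
          mz <- theo * (1 + rtrunc_norm(1, ppm_error_sd, ppm_error_max) * 1e-6)
          rt <- lib$reference_rt[ci] +
            rtrunc_norm(1, rt_jitter_sd, rt_jitter_max)
          is_primary <- adduct_tab$label[ai] == "[M+H]+"
          id <- add_feature(mz, rt, runs,
                            base_intensity * (if (is_primary) 1 else 0.4),
                            ms2_runs = if (is_primary) grp$msms else character())
          if (is_primary) {
            spectra[[id]] <- library_set$ref_spectra[[lib$name[ci]]]$spectrum
          }
          truth[[length(truth) + 1L]] <- tibble::tibble(
            feature_id = id, compound = lib$name[ci],
            adduct = adduct_tab$label[ai], sample = s)
        }
      }
    }

    # decoys: random masses kept >= decoy_min_ppm from every library m/z
    n_kept <- 0L
    while (n_kept < n_decoys) {
      mz <- stats::runif(1, 150, 1500)
      if (all(abs(ppm_error(mz, theo_all)) >= decoy_min_ppm)) {
        n_runs <- sample(2:length(run_ids), 1)
        add_feature(mz, stats::runif(1, 0.5, 12),
                    sample(run_ids, n_runs), base_intensity * 0.5)
        n_kept <- n_kept + 1L
      }
    }

    # blank contaminants: present in blanks (and possibly samples)
    for (k in seq_len(n_blank_contaminants)) {
      mz <- stats::runif(1, 150, 1500)
      runs <- unique(c(blank_ids, sample(run_ids, sample(0:3, 1))))
      add_feature(mz, stats::runif(1, 0.5, 12), runs, base_intensity)
    }

    features <- do.call(rbind, feats)
    list(features = features, spectra = spectra,
         sample_groups = sample_groups, blank_ids = blank_ids,
         truth = do.call(rbind, truth), library_set = library_set)
  })
}

#' Simulate a leaf-matched pair of dendrograms with controlled discordance
#'
#' Draws a random binary chemotype profile, clusters it with Jaccard/UPGMA
#' (first tree), applies `round(discordance * n_leaves)` random leaf
#' transpositions to the profile's row labels and clusters again (second
#' tree). `discordance = 0` yields topologically identical trees.
#'
#' @param n_leaves Number of strains (>= 4).
#' @param discordance Fraction in \[0, 1\] controlling the number of leaf
#'   transpositions.
#' @param n_items Number of profile items (features).
#' @param p_present Bernoulli presence probability per item.
#' @param seed Integer seed.
#' @return List: `tree_left`, `tree_right` (`chem_dendro`), and `truth`
#'   (matrix of applied transpositions, 0 rows when none).
#' @export
simulate_tree_pair <- function(n_leaves = 12L, discordance = 0,
                               n_items = 80L, p_present = 0.3, seed = 1L) {
  stopifnot(n_leaves >= 4L, discordance >= 0, discordance <= 1)
  with_seed(substream_seed(seed, "trees"), {
    labels <- sprintf("S%02d", seq_len(n_leaves))
    profile <- matrix(stats::rbinom(n_leaves * n_items, 1, p_present),
                      nrow = n_leaves,
                      dimnames = list(labels, sprintf("I%03d",
                                                      seq_len(n_items))))
    tree_left <- upgma(jaccard_matrix(profile))
    n_swap <- round(discordance * n_leaves)
    swapped <- profile
    swaps <- matrix(integer(0), ncol = 2)
    if (n_swap > 0) {
      swaps <- t(replicate(n_swap, sample(n_leaves, 2)))
      for (k in seq_len(n_swap)) {
        i <- swaps[k, 1]; j <- swaps[k, 2]
        tmp <- swapped[i, ]
        swapped[i, ] <- swapped[j, ]
        swapped[j, ] <- tmp
      }
    }
    tree_right <- upgma(jaccard_matrix(swapped))
    list(tree_left = tree_left, tree_right = tree_right, truth = swaps)
  })
}

#' Simulate a CFU table for the frass competition assay
#'
#' Initial counts are lognormal around `initial_mean`; final counts are
#' lognormal around `initial * fold_change` (mean-preserving), so
#' `dispersion = 0` recovers every true fold change exactly and a true
#' fold change of 0 yields extinction.
#'
#' @param plans Named list: organism -> named numeric vector of true fold
#'   changes per treatment.
#' @param n_replicates Biological replicates per group (default 8).
#' @param dispersion Lognormal sdlog of counts (default 0.15).
#' @param initial_mean Mean initial inoculum (CFU).
#' @param seed Integer seed.
#' @return A CFU table (see [analyze_cfu()]) with `plans` in attribute
#'   `"truth"`.
#' @export
simulate_cfu <- function(plans, n_replicates = 8L, dispersion = 0.15,
                         initial_mean = 1000, seed = 1L) {
  stopifnot(n_replicates >= 2L, dispersion >= 0, initial_mean > 0)
  with_seed(substream_seed(seed, "cfu"), {
    rln <- function(n, mean) {
      if (dispersion == 0) return(rep(mean, n))
      mean * exp(stats::rnorm(n, -dispersion^2 / 2, dispersion))
    }
    rows <- list()
    for (org in names(plans)) {
      fcs <- plans[[org]]
      stopifnot(all(fcs >= 0))
      for (trt in names(fcs)) {
        init <- rln(n_replicates, initial_mean)
        fin <- if (fcs[[trt]] == 0) rep(0, n_replicates) else
          rln(n_replicates, 1) * init * fcs[[trt]]
        rows[[length(rows) + 1L]] <- tibble::tibble(
          organism = org, treatment = trt, replicate = seq_len(n_replicates),
          cfu_initial = init, cfu_final = fin)
      }
    }
    out <- do.call(rbind, rows)
    attr(out, "truth") <- plans
    out
  })
}
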