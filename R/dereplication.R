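# Rule-based dereplication of LC-MS feature tables against a compound
# library: exact-mass matching under a ppm tolerance, adduct co-elution,
# MS2 spectral similarity, replicate-presence validation for environmental
# samples, a dedicated rule for unstable polyene macrolides, and
# identification levels 1-3.

PROTON_MASS <- 1.007276466

#' Default positive-mode adduct table
#'
#' The adducts screened during annotation: protonated, sodiated,
#' ammoniated, potassiated and doubly protonated species. `mass_shift` is
#' the total mass added before dividing by `charge`.
#'
#' @return Tibble with columns `label`, `mass_shift` (Da), `charge`.
#' @export
default_adducts <- function() {
  tibble::tibble(
    label = c("[M+H]+", "[M+Na]+", "[M+NH4]+", "[M+K]+", "[M+2H]2+"),
    mass_shift = c(PROTON_MASS, 22.989218, 18.033823, 38.963158,
                   2 * PROTON_MASS),
    charge = c(1L, 1L, 1L, 1L, 2L)
  )
}

#' Theoretical m/z of an adduct
#'
#' @param mass Neutral monoisotopic mass in Da.
#' @param mass_shift Signed total mass shift of the adduct in Da.
#' @param charge Positive integer charge.
#' @return `(mass + mass_shift) / charge`.
#' @export
theoretical_mz <- function(mass, mass_shift, charge = 1L) {
  stopifnot(all(mass > 0), all(charge >= 1))
  mz <- (mass + mass_shift) / charge
  if (any(mz <= 0)) stop("nonpositive theoretical m/z")
  mz
}

#' Signed relative mass error in ppm
#'
#' @param observed_mz,theo_mz Observed and theoretical m/z in Da.
#' @return `(observed - theoretical) / theoretical * 1e6`.
#' @export
ppm_error <- function(observed_mz, theo_mz) {
  stopifnot(all(theo_mz > 0))
  (observed_mz - theo_mz) / theo_mz * 1e6
}

#' Match features against a compound library
#'
#' Enumerates every (feature, compound, adduct) triple whose observed m/z
#' lies within `ppm_tol` (inclusive) of the theoretical adduct m/z.
#'
#' @param features Feature table with columns `feature_id`, `mz`, `rt`.
#' @param library Compound library with columns `name`, `monoisotopic_mass`.
#' @param adducts Adduct table as from [default_adducts()].
#' @param ppm_tol Inclusive ppm tolerance (default 5).
#' @return Tibble of candidates: `feature_id`, `compound`, `adduct`,
#'   `observed_mz`, `theo_mz`, `ppm_error`, `rt`.
#' @export
match_features <- function(features, library, adducts = default_adducts(),
                           ppm_tol = 5) {
  stopifnot(nrow(library) > 0, ppm_tol > 0)
  theo <- expand.grid(ci = seq_len(nrow(library)),
                      ai = seq_len(nrow(adducts)))
  theo$mz <- theoretical_mz(library$monoisotopic_mass[theo$ci],
                            adducts$mass_shift[theo$ai],
                            adducts$charge[theo$ai])
  out <- vector("list", nrow(features))
  for (i in seq_len(nrow(features))) {
    err <- ppm_error(features$mz[i], theo$mz)
    hit <- which(abs(err) <= ppm_tol)
    if (length(hit)) {
      out[[i]] <- tibble::tibble(
        feature_id = features$feature_id[i],
        compound = library$name[theo$ci[hit]],
        adduct = adducts$label[theo$ai[hit]],
        observed_mz = features$mz[i],
        theo_mz = theo$mz[hit],
        ppm_error = err[hit],
        rt = features$rt[i]
      )
    }
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) {
    return(tibble::tibble(feature_id = character(), compound = character(),
                          adduct = character(), observed_mz = numeric(),
                          theo_mz = numeric(), ppm_error = numeric(),
                          rt = numeric()))
  }
  do.call(rbind, out)
}

#' Co-eluting adducts of a candidate hit
#'
#' Distinct adduct labels of the candidate's compound whose matched
#' features elute within `rt_tol` minutes (inclusive) of the candidate.
#' The candidate's own adduct is counted as one of them.
#'
#' @param candidate One row of the [match_features()] output.
#' @param candidates Full candidate table from [match_features()].
#' @param rt_tol Retention-time window in minutes (default 0.1).
#' @return Character vector of adduct labels.
#' @export
coeluting_adducts <- function(candidate, candidates, rt_tol = 0.1) {
  same <- candidates[candidates$compound == candidate$compound &
                       abs(candidates$rt - candidate$rt) <= rt_tol, ]
  unique(same$adduct)
}

#' Greedy cosine similarity between two stick spectra
#'
#' Fragment intensities are square-root scaled; fragment pairs within
#' `frag_tol` Da are matched greedily in order of decreasing intensity
#' product, each peak used at most once; the score is the cosine of the
#' matched intensity vectors against the full spectrum norms. Symmetric in
#' its arguments; 1 for identical spectra, 0 when no fragments match.
#'
#' @param spec_a,spec_b Two-column matrices (`mz`, `intensity`), rows > 0.
#' @param frag_tol Fragment m/z tolerance in Da.
#' @return Similarity in \[0, 1\] with attribute `n_matched`.
#' @export
spectral_similarity <- function(spec_a, spec_b, frag_tol = 0.02) {
  spec_a <- as_spectrum(spec_a)
  spec_b <- as_spectrum(spec_b)
  wa <- sqrt(spec_a[, 2])
  wb <- sqrt(spec_b[, 2])
  pairs <- which(abs(outer(spec_a[, 1], spec_b[, 1], "-")) <= frag_tol,
                 arr.ind = TRUE)
  score <- 0
  n_matched <- 0L
  if (nrow(pairs)) {
    prod <- wa[pairs[, 1]] * wb[pairs[, 2]]
    ord <- order(prod, decreasing = TRUE)
    used_a <- logical(length(wa))
    used_b <- logical(length(wb))
    for (k in ord) {
      i <- pairs[k, 1]; j <- pairs[k, 2]
      if (!used_a[i] && !used_b[j]) {
        used_a[i] <- TRUE
        used_b[j] <- TRUE
        score <- score + prod[k]
        n_matched <- n_matched + 1L
      }
    }
  }
  sim <- score / (sqrt(sum(wa^2)) * sqrt(sum(wb^2)))
  attr(sim, "n_matched") <- n_matched
  sim
}

as_spectrum <- function(x) {
  x <- as.matrix(x)
  if (!nrow(x) || ncol(x) < 2) stop("spectrum must have >= 1 fragment row")
  if (any(x[, 2] < 0)) stop("negative fragment intensity")
  x[order(x[, 1]), , drop = FALSE]
}

#' Assign an identification level from the available evidence
#'
#' Level 1: retention time and fragmentation pattern both match a commercial
#' standard of the compound. Level 2: MS2 spectrum matches a literature or
#' library spectrum. Level 3: MS2 spectral similarity to a standard of an
#' analog compound. With no qualifying MS2 evidence the candidate falls
#' through to `"rejected"` here; context-specific no-MS2 rules
#' ([validate_environmental()], [validate_polyene()]) may still accept it.
#'
#' @param evidence List with logical elements `rt_match`,
#'   `ms2_match_standard`, `ms2_match_library`, `ms2_match_analog`.
#' @return One of `"1"`, `"2"`, `"3"`, `"rejected"`.
#' @export
assign_id_level <- function(evidence) {
  pick <- function(nm) isTRUE(evidence[[nm]])
  if (pick("rt_match") && pick("ms2_match_standard")) "1"
  else if (pick("ms2_match_library")) "2"
  else if (pick("ms2_match_analog")) "3"
  else "rejected"
}

#' Validate a candidate hit in an environmental sample
#'
#' A hit in an environmental extract is real only if the feature is present
#' in the sample's MS/MS run and in all three LC-MS technical replicates.
#' When the MS2 spectrum is missing in this sample but was observed in at
#' least one environmental sample, the hit is still accepted provided its
#' retention time and mass error are within tolerance and either at least
#' two adducts co-elute or another member of the compound family was
#' detected in the same sample. A compound whose MS2 was never observed in
#' any environmental sample is rejected regardless of mass, retention time
#' or adduct evidence.
#'
#' @param in_msms_run Feature detected in the sample's LC-MS/MS run.
#' @param n_lcms_replicates Number of LC-MS technical replicates in which
#'   the feature was detected.
#' @param ms2_here MS2 recorded for this compound in this sample.
#' @param ms2_anywhere MS2 recorded in at least one environmental sample.
#' @param rt_ppm_ok Retention time and ppm error within tolerance.
#' @param n_adducts Number of co-eluting adducts (the primary ion counts).
#' @param family_member_present Another accepted member of the same
#'   compound family detected in this sample.
#' @param n_replicates_total Number of technical replicates acquired; the
#'   protocol uses 3, any other value requires `allow_replicate_override`.
#' @param allow_replicate_override Permit `n_replicates_total != 3`.
#' @return Logical: is the hit accepted?
#' @export
validate_environmental <- function(in_msms_run, n_lcms_replicates,
                                   ms2_here, ms2_anywhere, rt_ppm_ok,
                                   n_adducts, family_member_present,
                                   n_replicates_total = 3L,
                                   allow_replicate_override = FALSE) {
  if (n_replicates_total != 3L && !allow_replicate_override) {
    stop("environmental validation expects 3 technical replicates, got ",
         n_replicates_total,
         " (set allow_replicate_override = TRUE to proceed)")
  }
  if (!isTRUE(ms2_anywhere)) return(FALSE)
  present <- isTRUE(in_msms_run) &&
    n_lcms_replicates >= n_replicates_total
  if (!present) return(FALSE)
  if (isTRUE(ms2_here)) return(TRUE)
  isTRUE(rt_ppm_ok) && (n_adducts >= 2L || isTRUE(family_member_present))
}

#' Validate a polyene macrolide hit
#'
#' Polyene macrolides are unstable and elute with low peak heights, so
#' their environmental annotation uses a replicate-based adduct rule in
#' place of the MS2 requirement: retention time and mass error within
#' tolerance, at least two adducts in one technical replicate, and at
#' least one adduct in two other technical replicates.
#'
#' @param rt_ppm_ok Retention time and ppm error within tolerance.
#' @param adducts_per_replicate Integer vector: number of adducts observed
#'   in each technical replicate.
#' @return Logical: is the hit accepted?
#' @export
validate_polyene <- function(rt_ppm_ok, adducts_per_replicate) {
  a <- as.integer(adducts_per_replicate)
  if (!isTRUE(rt_ppm_ok) || !length(a)) return(FALSE)
  for (i in seq_along(a)) {
    if (a[i] >= 2L && sum(a[-i] >= 1L) >= 2L) return(TRUE)
  }
  FALSE
}

# MS2 match decision against one reference spectrum. Thresholds follow the
# package defaults: similarity >= 0.7 with >= 4 matched fragments for a
# standard or library spectrum, >= 0.5 for an analog standard.
ms2_matches <- function(query, reference, analog = FALSE, frag_tol = 0.02,
                        min_similarity = if (analog) 0.5 else 0.7,
                        min_fragments = if (analog) 1L else 4L) {
  if (is.null(query) || is.null(reference)) return(FALSE)
  sim <- spectral_similarity(query, reference, frag_tol = frag_tol)
  as.numeric(sim) >= min_similarity &&
    attr(sim, "n_matched") >= min_fragments
}

#' Annotate an LC-MS feature table against a compound library
#'
#' End-to-end dereplication: exact-mass candidate matching under the ppm
#' tolerance, adduct co-elution grouping, MS2-based identification levels,
#' and context-dependent validation. In `"culture_extract"` context a
#' candidate is accepted when it carries MS2 evidence or at least two
#' co-eluting adducts. In `"environmental"` context each sample group
#' (one LC-MS/MS run plus three LC-MS technical replicates) is validated
#' with the replicate-presence rules; polyene macrolides use the dedicated
#' adduct-per-replicate rule. Family-member co-detection counts only hits
#' already accepted in the same sample, evaluated in decreasing evidence
#' order in a single pass.
#'
#' @param features Feature table: `feature_id`, `mz`, `rt`, one
#'   `intensity_<run>` column per run, one `has_ms2_<run>` column per run.
#' @param library Compound library: `name`, `family`, `monoisotopic_mass`,
#'   `is_polyene`, `reference_rt` (NA if no standard), `standard_available`.
#' @param config A [chem_config()]; supplies ppm and RT tolerances and the
#'   adduct table.
#' @param context `"culture_extract"` or `"environmental"`.
#' @param sample_groups For environmental context: named list, one element
#'   per environmental sample, each `list(msms = <run id>, lcms = <run
#'   ids>)`.
#' @param spectra Named list of query MS2 spectra keyed by `feature_id`.
#' @param ref_spectra Named list keyed by compound name; each element
#'   `list(spectrum = <matrix>, source = "standard"|"library"|"analog")`.
#' @param detection_threshold Intensity above which a feature counts as
#'   detected in a run (default 0, i.e. any positive intensity).
#' @param allow_replicate_override Passed to [validate_environmental()].
#' @return Tibble of annotation hits: `feature_id`, `compound`, `family`,
#'   `adduct` (primary, smallest |ppm|), `ppm_error`, `rt`,
#'   `n_adducts`, `matched_adducts`, `id_level`, `accepted`, `context`.
#' @export
annotate_features <- function(features, library, config = chem_config(),
                              context = c("culture_extract", "environmental"),
                              sample_groups = NULL, spectra = NULL,
                              ref_spectra = NULL, detection_threshold = 0,
                              allow_replicate_override = FALSE) {
  context <- match.arg(context)
  cands <- match_features(features, library, adducts = config$adducts,
                          ppm_tol = config$ppm_tol)
  empty <- tibble::tibble(
    feature_id = character(), compound = character(), family = character(),
    adduct = character(), ppm_error = numeric(), rt = numeric(),
    n_adducts = integer(), matched_adducts = character(),
    id_level = character(), accepted = logical(), context = character())
  if (!nrow(cands)) return(empty)
  if (context == "environmental" && is.null(sample_groups)) {
    stop("environmental context requires sample_groups")
  }

  run_ids <- sub("^intensity_", "", grep("^intensity_", names(features),
                                         value = TRUE))
  detected <- function(fid, run) {
    col <- paste0("intensity_", run)
    if (!col %in% names(features)) stop("unknown run id: ", run)
    features[[col]][features$feature_id == fid] > detection_threshold
  }
  ms2_in_run <- function(fid, run) {
    col <- paste0("has_ms2_", run)
    col %in% names(features) &&
      isTRUE(features[[col]][features$feature_id == fid] > 0)
  }

  # one working row per (feature, compound): primary adduct = smallest |ppm|
  key <- paste(cands$feature_id, cands$compound, sep = "\r")
  rows <- lapply(split(seq_len(nrow(cands)), key), function(idx) {
    sub <- cands[idx, ]
    sub[which.min(abs(sub$ppm_error)), ]
  })
  hits <- do.call(rbind, rows)

  # evidence per hit
  hits$family <- library$family[match(hits$compound, library$name)]
  is_poly <- library$is_polyene[match(hits$compound, library$name)]
  ref_rt <- library$reference_rt[match(hits$compound, library$name)]
  adduct_lists <- vector("list", nrow(hits))
  lvl <- character(nrow(hits))
  best_sim <- numeric(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    adduct_lists[[i]] <- coeluting_adducts(hits[i, ], cands,
                                           rt_tol = config$rt_tol_min)
    q <- spectra[[hits$feature_id[i]]]
    ref <- ref_spectra[[hits$compound[i]]]
    ev <- list(
      rt_match = is.finite(ref_rt[i]) &&
        abs(hits$rt[i] - ref_rt[i]) <= config$rt_tol_min,
      ms2_match_standard = !is.null(ref) && ref$source == "standard" &&
        ms2_matches(q, ref$spectrum),
      ms2_match_library = !is.null(ref) && ref$source == "library" &&
        ms2_matches(q, ref$spectrum),
      ms2_match_analog = !is.null(ref) && ref$source == "analog" &&
        ms2_matches(q, ref$spectrum, analog = TRUE)
    )
    lvl[i] <- assign_id_level(ev)
    best_sim[i] <- if (!is.null(q) && !is.null(ref))
      as.numeric(spectral_similarity(q, ref$spectrum)) else 0
  }
  hits$n_adducts <- lengths(adduct_lists)
  hits$matched_adducts <- vapply(adduct_lists, paste, "", collapse = ";")
  hits$id_level <- lvl

  ms2_any <- vapply(seq_len(nrow(hits)), function(i) {
    any(vapply(run_ids, function(r) ms2_in_run(hits$feature_id[i], r),
               logical(1)))
  }, logical(1))

  if (context == "culture_extract") {
    # adduct-only evidence without MS2 supports at most a level-3 call
    hits$accepted <- hits$id_level != "rejected" | hits$n_adducts >= 2L
    hits$id_level[hits$id_level == "rejected" & hits$accepted] <- "3"
  } else {
    # evaluate in decreasing evidence order so that family co-detection
    # never bootstraps off a weaker, not-yet-accepted hit
    ord <- order(hits$id_level != "1", hits$id_level != "2",
                 -hits$n_adducts, -best_sim)
    accepted <- logical(nrow(hits))
    accepted_fam_by_sample <- list()
    ms2_anywhere_by_compound <- tapply(ms2_any, hits$compound, any)
    for (i in ord) {
      fid <- hits$feature_id[i]
      ok_any <- FALSE
      for (s in names(sample_groups)) {
        grp <- sample_groups[[s]]
        n_rep <- sum(vapply(grp$lcms, function(r) detected(fid, r),
                            logical(1)))
        in_msms <- detected(fid, grp$msms)
        ms2_here <- ms2_in_run(fid, grp$msms)
        rt_ppm_ok <- abs(hits$ppm_error[i]) <= config$ppm_tol
        fam_here <- hits$family[i] %in% accepted_fam_by_sample[[s]]
        ok <- if (isTRUE(is_poly[i])) {
          adducts_per_rep <- vapply(grp$lcms, function(r) {
            sub <- cands[cands$compound == hits$compound[i] &
                           abs(cands$rt - hits$rt[i]) <= config$rt_tol_min, ]
            sum(vapply(seq_len(nrow(sub)), function(k)
              isTRUE(detected(sub$feature_id[k], r)), logical(1)))
          }, integer(1))
          validate_polyene(rt_ppm_ok, adducts_per_rep)
        } else {
          validate_environmental(
            in_msms_run = in_msms, n_lcms_replicates = n_rep,
            ms2_here = ms2_here,
            ms2_anywhere = isTRUE(ms2_anywhere_by_compound[[hits$compound[i]]]),
            rt_ppm_ok = rt_ppm_ok, n_adducts = hits$n_adducts[i],
            family_member_present = fam_here,
            n_replicates_total = length(grp$lcms),
            allow_replicate_override = allow_replicate_override)
        }
        if (ok) {
          ok_any <- TRUE
          accepted_fam_by_sample[[s]] <-
            union(accepted_fam_by_sample[[s]], hits$family[i])
        }
      }
      accepted[i] <- ok_any
    }
    hits$accepted <- accepted
    hits$id_level[!hits$accepted] <- "rejected"
    # accepted without a direct MS2 tier: adduct/family evidence, level 3
    hits$id_level[hits$accepted & hits$id_level == "rejected"] <- "3"
  }
  hits$context <- context
  out <- hits[, c("feature_id", "compound", "family", "adduct", "ppm_error",
                  "rt", "n_adducts", "matched_adducts", "id_level",
                  "accepted", "context")]
  rownames(out) <- NULL
  tibble::as_tibble(out)
}
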