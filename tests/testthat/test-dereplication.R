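test_that("adduct m/z arithmetic and ppm errors are exact", {
  expect_equal(theoretical_mz(500, 0, 1), 500)
  expect_equal(theoretical_mz(500, 1.007276466, 1), 501.007276466)
  expect_equal(theoretical_mz(500, 2 * 1.007276466, 2),
               (500 + 2 * 1.007276466) / 2)
  expect_error(theoretical_mz(1, -2, 1), "nonpositive")
  expect_equal(ppm_error(500.0025, 500), 5)
  expect_equal(ppm_error(499.9975, 500), -5)
  expect_equal(ppm_error(500, 500), 0)
})

test_that("feature matching respects the inclusive ppm tolerance", {
  lib <- tibble::tibble(name = "X", family = "f", monoisotopic_mass = 500,
                        is_polyene = FALSE, reference_rt = 5,
                        standard_available = TRUE)
  mh <- theoretical_mz(500, 1.007276466, 1)
  feats <- tibble::tibble(
    feature_id = c("exact", "at5ppm", "out6ppm"),
    mz = c(mh, mh * (1 + 5e-6), mh * (1 + 6e-6)),
    rt = c(5, 5, 5))
  # the bound is inclusive: a feature sitting exactly at the tolerance of
  # its computed error is matched
  boundary_err <- abs(ppm_error(feats$mz[2], mh))
  hits <- match_features(feats, lib, ppm_tol = boundary_err)
  expect_true("at5ppm" %in% hits$feature_id)
  hits <- match_features(feats, lib)
  expect_setequal(setdiff(hits$feature_id, "at5ppm"), "exact")
  expect_false("out6ppm" %in% hits$feature_id)
  expect_equal(hits$ppm_error[hits$feature_id == "exact"], 0)
  expect_equal(hits$adduct[hits$feature_id == "exact"], "[M+H]+")
  # monotone in tolerance: widening never loses a hit
  wider <- match_features(feats, lib, ppm_tol = 10)
  expect_true(all(paste(hits$feature_id, hits$adduct) %in%
                    paste(wider$feature_id, wider$adduct)))
})

test_that("co-eluting adducts honour the inclusive RT window", {
  lib <- tibble::tibble(name = "X", family = "f", monoisotopic_mass = 500,
                        is_polyene = FALSE, reference_rt = 5,
                        standard_available = TRUE)
  ad <- default_adducts()
  feats <- tibble::tibble(
    feature_id = c("h", "na", "k"),
    mz = c(theoretical_mz(500, ad$mass_shift[ad$label == "[M+H]+"], 1),
           theoretical_mz(500, ad$mass_shift[ad$label == "[M+Na]+"], 1),
           theoretical_mz(500, ad$mass_shift[ad$label == "[M+K]+"], 1)),
    rt = c(5.00, 5.05, 5.15))
  cands <- match_features(feats, lib)
  primary <- cands[cands$feature_id == "h", ]
  got <- coeluting_adducts(primary, cands, rt_tol = 0.1)
  expect_setequal(got, c("[M+H]+", "[M+Na]+")) # K at drt 0.15 excluded
  expect_setequal(coeluting_adducts(primary, cands, rt_tol = 0.2),
                  c("[M+H]+", "[M+Na]+", "[M+K]+"))
})

test_that("spectral similarity is a symmetric bounded greedy cosine", {
  sp <- cbind(mz = c(100.1, 250.2, 390.3), intensity = c(20, 100, 60))
  self <- spectral_similarity(sp, sp)
  expect_equal(as.numeric(self), 1, tolerance = 1e-12)
  expect_equal(attr(self, "n_matched"), 3L)
  far <- cbind(mz = c(111, 222), intensity = c(50, 50))
  expect_equal(as.numeric(spectral_similarity(sp, far)), 0)
  # symmetry and agreement with the exact one-to-one cosine when peaks are
  # separated by more than the tolerance (unambiguous matching)
  for (k in 1:20) {
    na <- sample(3:6, 1); nb <- sample(3:6, 1)
    a <- cbind(mz = sort(sample(seq(100, 900, by = 1), na)) + runif(na, 0, 0.005),
               intensity = runif(na, 1, 100))
    b <- cbind(mz = sort(sample(seq(100, 900, by = 1), nb)) + runif(nb, 0, 0.005),
               intensity = runif(nb, 1, 100))
    s_ab <- as.numeric(spectral_similarity(a, b))
    s_ba <- as.numeric(spectral_similarity(b, a))
    expect_equal(s_ab, s_ba, tolerance = 1e-12)
    # exact oracle: unique pairing within tolerance
    wa <- sqrt(a[, 2]); wb <- sqrt(b[, 2])
    num <- 0
    for (i in seq_len(na)) {
      j <- which(abs(b[, 1] - a[i, 1]) <= 0.02)
      if (length(j) == 1) num <- num + wa[i] * wb[j]
    }
    expect_equal(s_ab, num / sqrt(sum(wa^2)) / sqrt(sum(wb^2)),
                 tolerance = 1e-9)
  }
  expect_error(spectral_similarity(sp[0, , drop = FALSE], sp), "fragment")
})

test_that("identification levels follow the evidence hierarchy", {
  expect_equal(assign_id_level(list(rt_match = TRUE,
                                    ms2_match_standard = TRUE)), "1")
  expect_equal(assign_id_level(list(rt_match = FALSE,
                                    ms2_match_standard = TRUE,
                                    ms2_match_library = TRUE)), "2")
  expect_equal(assign_id_level(list(ms2_match_library = TRUE)), "2")
  expect_equal(assign_id_level(list(ms2_match_analog = TRUE)), "3")
  expect_equal(assign_id_level(list(rt_match = TRUE)), "rejected")
})

test_that("environmental validation enforces the replicate and MS2 rules", {
  ok <- function(...) validate_environmental(...)
  # MS2 present in this sample, full replicate presence
  expect_true(ok(TRUE, 3, TRUE, TRUE, TRUE, 1, FALSE))
  # missing one technical replicate
  expect_false(ok(TRUE, 2, TRUE, TRUE, TRUE, 3, TRUE))
  # not in the MS/MS run
  expect_false(ok(FALSE, 3, TRUE, TRUE, TRUE, 3, TRUE))
  # no MS2 anywhere: rejected no matter how good the rest is
  expect_false(ok(TRUE, 3, FALSE, FALSE, TRUE, 3, TRUE))
  # MS2 elsewhere only: needs rt/ppm plus 2 adducts or a family member
  expect_true(ok(TRUE, 3, FALSE, TRUE, TRUE, 2, FALSE))
  expect_true(ok(TRUE, 3, FALSE, TRUE, TRUE, 1, TRUE))
  expect_false(ok(TRUE, 3, FALSE, TRUE, TRUE, 1, FALSE))
  expect_false(ok(TRUE, 3, FALSE, TRUE, FALSE, 3, TRUE))
  # protocol uses 3 technical replicates
  expect_error(ok(TRUE, 2, TRUE, TRUE, TRUE, 2, FALSE,
                  n_replicates_total = 2), "3 technical replicates")
  expect_false(ok(FALSE, 2, TRUE, TRUE, TRUE, 2, FALSE,
                  n_replicates_total = 2, allow_replicate_override = TRUE))
})

test_that("polyene rule needs 2 adducts in one and 1 in two other replicates", {
  expect_true(validate_polyene(TRUE, c(2, 1, 1)))
  expect_false(validate_polyene(TRUE, c(2, 1, 0)))
  expect_false(validate_polyene(TRUE, c(1, 1, 1)))
  expect_true(validate_polyene(TRUE, c(3, 2, 2)))
  expect_false(validate_polyene(FALSE, c(2, 1, 1)))
  # every accepted pattern implies >= 4 adduct observations in total
  for (k in 1:200) {
    a <- sample(0:3, 3, replace = TRUE)
    if (validate_polyene(TRUE, a)) expect_gte(sum(a), 4)
  }
})

test_that("annotation recovers every spike and no decoys, deterministically", {
  sim <- simulate_features(seed = 7)
  ann <- annotate_features(sim$features, sim$library_set$library,
                           context = "environmental",
                           sample_groups = sim$sample_groups,
                           spectra = sim$spectra,
                           ref_spectra = sim$library_set$ref_spectra)
  accepted <- ann[ann$accepted, ]
  # recall: every spiked (feature, compound) accepted
  expect_true(all(sim$truth$feature_id %in% accepted$feature_id))
  # no decoy or contaminant feature is ever annotated
  expect_equal(setdiff(accepted$feature_id, sim$truth$feature_id),
               character(0))
  expect_true(all(accepted$id_level %in% c("1", "2", "3")))
  # standards spiked with their own spectra and matching RT reach level 1
  lvl1 <- unique(accepted$compound[accepted$id_level == "1"])
  expect_true("actinomycin X2" %in% lvl1)
  # determinism: identical inputs, identical hits
  ann2 <- annotate_features(sim$features, sim$library_set$library,
                            context = "environmental",
                            sample_groups = sim$sample_groups,
                            spectra = sim$spectra,
                            ref_spectra = sim$library_set$ref_spectra)
  expect_identical(ann, ann2)
})
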