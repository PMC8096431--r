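#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study datasets that the downstream
# analyses consume, with known ground truth. Writes plain-text inputs under
# results/simdata/. All stages share one root seed; each generator draws
# from its own substream.

suppressPackageStartupMessages(library(frasschem))
SEED <- 1L
out <- "results/simdata"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

# Four compound pairs emulating the tested combinations: two synergistic,
# two antagonistic (true Bliss excess +/-0.2), single-compound inhibitions
# around 0.4, seven biological replicates, noise 2% of the control range.
pairs <- list(
  list(a = "actinomycin_X2", b = "filipins",   ca = 15, cb = 2,  b_true =  0.2),
  list(a = "actinomycin_X2", b = "STA-21",     ca = 15, cb = 15, b_true =  0.2),
  list(a = "actinomycin_X2", b = "nactins",    ca = 15, cb = 15, b_true = -0.2),
  list(a = "filipins",       b = "STA-21",     ca = 4,  cb = 20, b_true = -0.2)
)
for (i in seq_along(pairs)) {
  p <- pairs[[i]]
  plate <- simulate_plate(fi_a_true = 0.4, fi_b_true = 0.4, b_true = p$b_true,
                          compound_a = p$a, compound_b = p$b,
                          conc_a = p$ca, conc_b = p$cb, seed = SEED + i)
  utils::write.csv(plate, file.path(out, sprintf("plate_%02d.csv", i)),
                   row.names = FALSE)
}
message("wrote ", length(pairs), " interaction plates")

# LC-MS feature table with the full spiked library, 500 decoys, blank
# contaminants and 3 technical replicates per environmental sample.
sim <- simulate_features(seed = SEED)
utils::write.csv(sim$features, file.path(out, "features.csv"),
                 row.names = FALSE)
utils::write.csv(sim$truth, file.path(out, "features_truth.csv"),
                 row.names = FALSE)
utils::write.csv(sim$library_set$library, file.path(out, "library.csv"),
                 row.names = FALSE)
write_mgf(sim$spectra, file.path(out, "spectra.mgf"))
jsonlite::write_json(sim$sample_groups, file.path(out, "sample_groups.json"),
                     auto_unbox = TRUE, pretty = TRUE)
message("wrote feature table: ", nrow(sim$features), " features (",
        nrow(sim$truth), " spiked)")

# Leaf-matched dendrogram pair at moderate discordance, as newick.
trees <- simulate_tree_pair(n_leaves = 12, discordance = 0.4, seed = SEED)
write_newick(trees$tree_left, file.path(out, "tree_chemistry.nwk"))
write_newick(trees$tree_right, file.path(out, "tree_phylogeny.nwk"))
message("wrote tree pair (", nrow(trees$truth), " leaf transpositions)")

# Frass competition CFU table: the entomopathogen grows ~15-fold alone and
# is held near 1-fold by each streptomycete; a streptomycete pair competes
# mildly. Eight biological replicates per group.
cfu <- simulate_cfu(list(
  M_anisopliae = c(alone = 15, plus_S_padanus = 1, plus_S_californicus = 1.3,
                   no_frass = 1),
  S_padanus = c(alone = 8, plus_S_californicus = 5)
), seed = SEED)
utils::write.csv(cfu, file.path(out, "cfu.csv"), row.names = FALSE)
message("wrote CFU table: ", nrow(cfu), " rows")
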