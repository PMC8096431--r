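---
title: "Models, rules and design choices behind frasschem"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, rules and design choices behind frasschem}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(frasschem)
```

frasschem analyses the chemical ecology of beetle-gallery *Streptomyces*:
how pairs of their antimicrobials interact against a fungal entomopathogen,
which known compounds are detectable in culture and environmental extracts,
how strain chemotypes cluster relative to a phylogeny, and how competitors
change each other's growth on frass. This vignette explains each model, its
assumptions, the tunable parameters, and the choices made where the design
was genuinely open. Nothing here reports an empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

## Plate interactions under Bliss Independence

A resazurin microdilution plate yields one fluorescence reading per well;
metabolically active fungus reduces resazurin to a fluorescent product, so
fluorescence is a growth proxy. Fractional inhibition normalises a
treatment well against the plate's own controls,

$$FI = 1 - \frac{T_F - \overline{MC_F}}{\overline{IC_F} - \overline{MC_F}},$$

so an uninhibited well (inoculum-control level) has FI 0 and a sterile well
(medium-control level) FI 1. The control means are taken over the replicate
control wells of the same plate; a `use_solvent_control` switch substitutes
the solvent-control wells (spores + medium + DMSO) as the zero-inhibition
baseline, since both controls are run. **FI is never clipped to [0, 1]**:
growth stimulation (FI < 0) and readings below the sterile baseline
(FI > 1) propagate into all downstream means. Clipping would shift means
toward inhibition asymmetrically and bias the Bliss excess toward synergy.

Two independently acting inhibitors are expected to combine as
$E_{AB} = FI_A + FI_B - FI_A FI_B$. The expected-value *distribution* is
built from the single-compound replicates in all $n_A \times n_B$
cross-combinations (with seven replicates per arm, 49 values); the Bliss
excess is computed from averages, $b = \overline{E_{AB}} -
\overline{FI_{AB}}$, and a t-test compares the two samples. A pair is
synergistic when $b \ge 0.08$ and $p \le 0.05$, antagonistic when
$b \le -0.08$ and $p \le 0.05$, additive otherwise — thresholds are config
values (`chem_config`) with these defaults. Sign convention: $b$ is
*expected minus observed* combined inhibition, and $b \ge 0.08$ is the
synergy call; the classification is applied exactly as stated, and the
round-trip identity with the generator (which plants
$FI_{AB} = E_{AB} - b_{true}$) makes the convention self-consistent
end to end.

Open choices, resolved as follows:

* **t-test variant.** Welch (unequal variance), two-sided. The two samples
  have very different sizes (49 vs 7) and no variance-equality argument is
  available.
* **Pseudo-replication.** Comparing 49 cross-combination values against 7
  observed values inflates the nominal sample size of the expected arm.
  The default reproduces that design faithfully; an optional
  `expected_mode = "paired"` pairs replicate *i* of A with replicate *i* of
  B (7 expected values) for a conservative re-analysis.
* **Insignificant but large excess.** When $p > \alpha$ and
  $|b| > 0.08$ the pair is labelled *indeterminate* rather than additive:
  calling it additive would assert an absence of interaction the test
  cannot support.
* **Zero variance.** Two constant equal samples give $t = 0, p = 1$; two
  constant samples that differ by more than relative machine epsilon give
  $t = \pm\infty, p = 0$ (an exact, noiseless difference), which keeps
  noiseless simulations classifiable; constant samples differing by less
  than machine epsilon raise an error rather than guess.

## Dereplication rules

Annotation evidence is assembled in tiers. Candidates are every (feature,
compound, adduct) triple whose m/z lies within the **inclusive** ±5 ppm
tolerance of the theoretical adduct m/z — inclusive because that is what a
"±" tolerance means. The default positive-mode adduct list is [M+H]+,
[M+Na]+, [M+NH4]+, [M+K]+ and [M+2H]2+ (configurable; the proton mass is
fixed at 1.007276466 Da). Adducts of the same compound co-elute if their
retention times agree within ±0.1 min, again inclusive, and the primary ion
counts as one of the "at least two adducts" (the stricter reading — two
adducts *besides* the primary — can be recovered by requiring
`n_adducts >= 3`).

Identification levels follow the usual metabolomics tiers: level 1 needs a
retention-time match *and* an MS2 match against the compound's own
commercial standard; level 2 an MS2 match against a literature or library
spectrum; level 3 MS2 similarity to a standard of an analog. MS2 "match"
is nowhere quantified in practice — it is expert judgment — so the package
uses a reproducible surrogate: greedy cosine similarity on square-root
scaled stick spectra, requiring similarity ≥ 0.7 with ≥ 4 matched fragments
for levels 1–2 and ≥ 0.5 for the analog tier, all config-exposed. With
centroided spectra whose peaks are separated by more than the fragment
tolerance the greedy matching is provably the exact one-to-one optimum,
which is what the tests verify.

Environmental hits face stricter rules than culture extracts: a feature
must appear in the sample's LC-MS/MS run *and* in all three LC-MS technical
replicates; if its MS2 is missing in this sample but present in another
environmental sample, mass and retention time must be within tolerance and
either ≥ 2 adducts must co-elute or another already-accepted member of the
same compound family must be present in the same sample (hits are evaluated
in decreasing evidence order in a single pass, so family support never
bootstraps off weaker hits); and a compound whose MS2 was never observed in
any environmental sample is rejected outright. Polyene macrolides, which
fragment poorly and elute with low peak heights, replace the MS2
requirement with an adduct-replicate pattern: ≥ 2 adducts in one technical
replicate and ≥ 1 adduct in two others — so [2,1,1] is accepted while
[2,1,0] and [1,1,1] are not, and any accepted polyene carries at least four
adduct observations in total.

## Chemotype clustering and tanglegrams

Features detected in any blank run (solvent or medium extraction control)
are removed entirely; the survivors are binarised at peak intensity
**strictly greater than** 1×10⁶ (an intensity exactly at the threshold is
absent — "higher than" is read literally). Strain profiles are compared by
Jaccard distance; two empty profiles are defined to be at distance 0 with a
warning, so an all-blank strain degrades gracefully instead of producing
NaN. UPGMA then agglomerates with size-weighted average linkage. Two
conventions were open:

* **Merge heights.** A node's height equals the merging distance $d$, not
  $d/2$ — the convention of `hclust(method = "average")`, which the
  clustering is verified against on random matrices.
* **Ties.** Equal minimal distances are resolved toward the
  lexicographically smallest pair of cluster labels (a cluster is labelled
  by its smallest member), making the dendrogram a pure function of the
  distance matrix.

Tanglegram entanglement between two leaf orderings is
$\sum_i |pos_L(i) - pos_R(i)|^L$ normalised by the value attained when one
ordering is the reversal of the other, so it is 0 for identical orderings
and 1 for a reversal. The exponent defaults to $L = 1.5$ (configurable),
a middle ground between the robust $L = 1$ and the displacement-punishing
$L = 2$. Untangling starts from both trees ladderized and alternately fixes
one tree's leaf order while rotating the other's internal nodes to minimise
entanglement. Each one-sided step is solved *exactly* by dynamic
programming — once ancestor flips are fixed, a subtree's leaves occupy a
contiguous position block, so the optimal flip decomposes recursively — and
both alternation orders are tried. Coordinate descent of this kind can
still stall in a joint local optimum on very small trees, so for trees with
≤ 8 leaves the joint optimum over all rotations of both trees is computed
exactly (enumerate one side, best-respond on the other). The returned
entanglement therefore never exceeds that of the ladderized start, and on
small trees equals the exhaustive-rotation optimum.

## Competition-assay statistics

Growth is summarised as the fold change `cfu_final / cfu_initial` per
replicate tube. Counts below the plating detection limit are recorded as 0
and enter the fold change as 0 — excluding extinctions would bias growth
upward. Fold changes are analysed on the natural scale by default, matching
how such assays are reported; `log10_mode` offers a variance-stabilised
alternative since the raw-vs-log choice is not standardised. Two treatments
are compared by the same Welch machinery as the plate module; three or more
by one-way ANOVA with Tukey HSD, whose adjusted p-values come from the
studentized-range distribution and are never smaller than the unadjusted
pairwise t-test on the same contrast.

## What the generators emulate — and what they do not

Each generator inverts the corresponding analysis under known truth, with
substreams derived from one root seed so adding a call never shifts another
generator's draws:

* `simulate_plate` draws well fluorescence
  $\mathcal{N}(IC - f (IC - MC),\; \sigma (IC - MC))$ — noise proportional
  to the control dynamic range, keeping FI noise comparable across plates —
  with the combination well at $f = E_{AB} - b_{true}$. Defaults: 7
  biological replicates and $\sigma = 0.02$, i.e. FI noise of 2 points.
* `simulate_features` spikes every library compound into each environmental
  sample as a co-eluting three-adduct series with truncated-Gaussian mass
  error (sd 1 ppm, clamped at ±3 ppm) and RT jitter (sd 0.01 min, clamped
  at ±0.03 min), detected in the MS/MS run and all 3 technical replicates,
  plus 500 decoys kept ≥ 20 ppm from every library m/z and 25 blank
  contaminants. The truncation keeps every planted spike inside the ±5
  ppm/±0.1 min windows, which is what makes "recall = 100%" a meaningful
  round-trip identity rather than a statement about tail risk.
* `simulate_tree_pair` clusters a random binary chemotype profile
  (12 strains × 80 items, presence probability 0.3 by default), then
  re-clusters after `round(discordance × n)` random leaf transpositions —
  discordance 0 gives topologically identical trees.
* `simulate_cfu` draws initial counts lognormally around the planned
  inoculum and final counts lognormally (mean-preserving, sdlog 0.15
  default) around `initial × fold_change`, with 8 replicates per group;
  zero dispersion recovers fold changes exactly and a planted fold change
  of 0 yields extinction.

Passing these tests shows the *rules and statistics are implemented
correctly*, not that real data would behave: real plates have positional
and edge effects and non-Gaussian fluorescence error; real feature tables
have correlated intensities, isotope clusters, in-source fragments and
heavy-tailed mass errors; real chemotypes are not i.i.d. Bernoulli; real
CFU counts are overdispersed beyond lognormal. None of those are simulated.

## Problem sizes and numerical choices

The test suite and acceptance script use 1,000 simulated null pairs and
2 × 250 effect pairs for the false-call/power properties, 100 random 8-leaf
matrices for the UPGMA oracle, 15 six-leaf tree pairs for exhaustive
untangling optimality, 20 seeds × 4 discordance levels for the entanglement
sweep, and 10,000 permutation draws for the t-test cross-check — sizes
chosen so each property is measured with comfortable margin while the whole
suite runs in minutes on a laptop. Oracle equalities are asserted at 1e-9;
internal tie and convergence tolerances sit at 1e-12–1e-15, far below any
data scale. Degenerate inputs (equal control means, zero-variance samples,
empty profiles, single-leaf trees, nonpositive initial CFU) raise errors
naming the offending group rather than propagating NaN.

## Known limitations

Dose–response fitting (IC50s, FIC checkerboards) and Loewe additivity are
out of scope, as are raw-file peak picking, molecular networking,
isotope-pattern scoring, negative-mode adducts, phylogenetic inference and
bootstrap support. The dereplication surface assumes centroided stick
spectra and one reference spectrum per compound; the untangling heuristic
is exact only below nine leaves and otherwise inherits the usual local
optimality caveat of alternating optimisation.
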