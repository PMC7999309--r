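---
title: "Methods: differential urinary-exosome proteomics with pi-score ranking and cytokine inference"
author: "cytopi"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential proteomics and cytokine inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cytopi)
```

# The analysis

`cytopi` implements a complete case/control analysis of a label-free
proteomics experiment, of the kind used to compare urinary-exosome
proteomes of patients with vancomycin-associated acute kidney injury
(V-AKI) against healthy controls. The input is a protein x sample matrix
of summed MS1 peak-area abundances with missing measurements, a binary
sample grouping, and (optionally) a STRING-style scored interaction
network over the proteins and a cytokine panel. Four stages follow:

1. **Two-step normalization** of abundances,
2. **Differential testing** with Welch's t-test and pi-score ranking,
3. **Ordination**: Bray-Curtis distances, PCoA, PERMANOVA,
4. **Cytokine inference**: connection-enrichment scores on the network.

A synthetic-data generator with known ground truth accompanies the
pipeline so that every stage can be validated end to end without any
external download.

# Normalization

Raw abundances `a_ij` (protein `i`, sample `j`) are normalized in two
median-anchored steps:

* Step 1 (protein scaling): `f_i = mean_i / median_i(mean_i)` and
  `a'_ij = a_ij / f_i`, where `mean_i` is protein `i`'s average across
  the experiment. Afterwards every protein's mean equals the original
  median of protein means — an algebraic identity the tests assert at a
  relative tolerance of 1e-9.
* Step 2 (sample scaling): `g_j = median_j / median(all a')` and
  `a''_ij = a'_ij / g_j`, equalizing per-sample medians and thereby
  removing run-to-run intensity drift.

Three numerical conventions matter and are deliberate choices, since the
procedure's prose description does not fix them:

* **Means and medians skip missing values.** Abundance tables encode a
  missing measurement as an absent value (`NA`), never as zero; factors
  computed over zero-imputed cells would be biased downward for proteins
  with many absences. No imputation is performed at any stage.
* **Zeros are retained as values.** A measured zero enters the means and
  medians; only a protein that is entirely missing/zero (step 1) or a
  sample with a zero median (step 2) is an error, reported by
  identifier — degenerate input fails loudly rather than being dropped.
* **Even-length medians** are the midpoint of the two central values
  (the conventional definition); factor values depend on this.

Both steps are equivariant under global rescaling of the input, so the
normalization has no preferred intensity unit.

# Differential testing and the pi-score

Each protein is tested with Welch's unequal-variance two-sided t-test on
its normalized abundances (at least two present values per group;
proteins failing that are reported as skipped, not silently dropped).
Testing is done on the abundance scale itself, matching the convention
of running an independent t-test directly on normalized label-free
intensities; the simulation study below shows that on log-normal data
this gives virtually the same ranking as testing log2 intensities.

Effect size is the log2 ratio of group arithmetic means,
`log2((mean_case + c) / (mean_control + c))` with pseudocount `c = 0` by
default — ratio-of-means is the common label-free convention, and the
pseudocount is exposed for matrices containing exact zeros.

The two are combined into the **pi-score**

> pi = log2FC x (-log10 p),

a signed score whose magnitude grows with both significance and effect
size. Significance is called at **|pi| > 1, strictly**: a protein with
pi exactly 1 is *not* significant. Positive pi-scores are
case-associated, negative control-associated. Two degenerate cases are
defined explicitly: two constant equal groups give `t = 0, p = 1`
(pi = 0), and two constant unequal groups clamp `p` to the smallest
positive double with a warning. No multiple-testing correction enters
the classification — the pi-score deliberately uses the raw p-value —
but a Benjamini-Hochberg `bh_q` column is emitted for reference.

The volcano export flags the top-k (default 10) proteins per class by
|pi|, with ties broken by smaller p-value and then input order, so the
flagging is deterministic.

# Ordination and PERMANOVA

Between-sample structure uses the Bray-Curtis dissimilarity
`d(u, v) = sum|u_i - v_i| / sum(u_i + v_i)`, computed with missing
values as zeros — Bray-Curtis requires complete non-negative vectors,
and absence-as-zero is how community-ecology tooling treats such data.
This is the only stage that reads missing values as zeros; the policy is
an explicit argument (`as_zero`) so the choice is visible at the call
site.

PCoA is classical scaling: Gower double-centering of `-d^2/2`, a
symmetric eigendecomposition, and coordinates scaled by the square roots
of positive eigenvalues. Bray-Curtis matrices are generally
non-Euclidean, so negative eigenvalues occur; they are reported
unmodified and given no axes — no Cailliez or Lingoes correction — and
explained proportions are taken over the positive-eigenvalue total. On
Euclidean-consistent input the coordinates reproduce the distances to
1e-8, which the tests assert.

PERMANOVA uses the one-way pseudo-F computed directly from pairwise
distances (`SS_total` from all pairs divided by n, `SS_within` from
within-group pairs divided by group size, `SS_between` by subtraction).
The null distribution permutes group labels. Two regimes:

* **Exhaustive**: when the number of distinct relabelings is within the
  permutation budget (e.g. 792 for 5 + 7 samples against the default
  budget of 999), all relabelings are enumerated and the p-value is
  exact — the fraction of relabelings, observed included, with
  `F >= F_obs`.
* **Sampled**: otherwise labels are shuffled uniformly with replacement
  and `p = (1 + #{F_perm >= F_obs}) / (1 + n_permutations)`, which never
  returns zero.

The tests verify the sampled/exhaustive switch against brute-force
enumeration and calibrate the type-I error on 400 null datasets of 12
samples (50 proteins each, 199 permutations): the rejection rate at
alpha = 0.05 must lie in [0.02, 0.09], a four-sigma binomial band around
the nominal level.

# Cytokine inference

The cytokine panel is written as range strings — TGFb, TNF, IFN, IL1-40,
CXCL1-16, CCL1-27 — which expand to 86 identifiers. "IFN" is treated as
a single identifier rather than an interferon family, and identifier
matching is exact-string, case-insensitive, with an optional alias table
(e.g. `TGFB1 -> TGFb`) because interaction databases and panels rarely
share a naming dialect.

Edges are kept when their combined confidence score is **strictly**
above 0.4, and a cytokine becomes *eligible* with **at least five**
(inclusive) filtered connections to significantly altered proteins.
Both boundaries are asserted in the tests.

For an eligible cytokine `c` with `k_case` and `k_control` filtered
edges to case- and control-associated proteins, the enrichment score per
class `d` is the double ratio

> e_d(c) = (k_d(c) / T_d) / (k_total(c) / T_total),

i.e. the cytokine's connection share into class `d`, normalized by the
class's share of the network, normalized again by the cytokine's overall
connectivity to significant proteins. The **fold-connection ratio**
`e_case / e_control` summarizes the leaning; it is reported as `Inf`
when a cytokine touches no control-associated protein, never silently
capped. The class total `T_d` has two defensible readings, both
implemented behind one switch:

* `protein_count` (default): `T_d` = number of significant proteins in
  class `d`. This reads "fold more connections than" as a
  class-size-normalized connection ratio and makes the score invariant
  under class swap (`fold -> 1/fold`), which the tests assert.
* `edge_count`: `T_d` = number of filtered protein-protein edges
  incident to class-`d` proteins (cytokine edges excluded), for networks
  where within-class wiring density differs.

The exported network sizes each significant protein by |pi|, colors
proteins by their contact with enriched cytokines (pro-inflammatory
contact takes precedence over anti-inflammatory; a protein touching
both is colored "pro"), and ships as GraphML and as a SIF plus
node-attribute pair for Cytoscape. The default inflammation table is
deliberately minimal — IL6 and TNF pro-inflammatory, IL10
anti-inflammatory, everything else unclassified — and is a plain
data.frame the user replaces wholesale.

# The synthetic-data generator

The generator is first-class, tested code: it defines the conditions
under which the pipeline's statistical behavior is validated.

Log2 abundances follow
`log2(a_ij) = base + b_i + e_i g_j + eps_ij` with protein baselines
`b_i ~ N(0, protein_sd^2)`, case indicator `g_j`, signed planted effects
`e_i`, and noise `eps_ij ~ N(0, noise_sd^2)`. Defaults emulate a small
clinical exosome study: 2000 proteins, 5 case vs 7 control samples, 5%
differential proteins at |log2FC| = 2, `base_log2_mean = 20` (about 1e6
on the raw scale, a typical summed MS1 peak area), `protein_sd = 2`
(about four orders of magnitude of dynamic range across proteins),
`noise_sd = 0.5` (roughly 35% CV, mid-range for label-free
quantification), and 10% missing cells. Exactly
`round(frac_diff x n_proteins)` proteins carry the effect, half up in
cases and half down, the odd one up. Missingness is either completely
at random or intensity-dependent — a logistic function of log2
abundance with its midpoint calibrated by root-finding so the marginal
rate equals `missing_rate`, emulating the left-censored missingness of
LC-MS data. Missing cells are `NA`, never zero, so the normalization
medians skip them.

The network generator draws cytokine-protein edges independently:
probability `p_planted` for (planted cytokine, case protein) pairs,
`p_base` otherwise, with uniform scores over the full confidence range
(0, 1) by default and an optional protein-protein background. Identical
seeds reproduce every output byte for byte.

What the generator does *not* emulate — correlated protein modules,
shared-peptide quantification artifacts, batch structure, heavy-tailed
contaminant proteins — bounds what the recovery tests show: they
demonstrate that the pipeline's statistics behave correctly under a
clean log-normal model, not that any particular clinical dataset will
yield a given protein list.

# Validation sizes and recorded behavior

The test suite checks every stage against an independent oracle (hand
formulas, vegan and cmdscale cross-checks, brute-force enumeration) and
runs the following study-condition benchmarks, sized to keep the whole
suite under a minute:

* Planted-protein recovery at 1000 proteins, 5 vs 7 samples, 50 planted
  at |log2FC| = 2, `noise_sd = 0.5`, no missingness, seed 1: recall of
  planted proteins among |pi| > 1 calls at least 0.7 and
  false-discovery proportion at most 0.3. (The fixed-seed run records
  recall 1.0 and FDP about 0.26; the FDP reflects the deliberate absence
  of multiple-testing correction in the pi-score convention.)
* PERMANOVA on the planted dataset against a matched effect-free dataset
  at the same seed: the planted p-value must be smaller.
* Cytokine recovery on a planted network (`p_planted = 0.8`,
  `p_base = 0.05`, seed 1): every eligible planted cytokine has
  fold-connection above 1 and planted cytokines outrank non-planted.
* Type-I calibration: 400 null datasets as described above.
* End-to-end determinism: two pipeline runs at the generator defaults
  produce byte-identical output files.

`scripts/acceptance.R` re-runs these benchmarks from scratch at any seed
and writes the resulting quantities as JSON.

# Known limitations

* The pi-score uses raw p-values by design; with ~2000 tests the
  false-discovery proportion among calls is expected to be in the
  0.2-0.3 range under the default simulation conditions. Users wanting
  FDR control should gate on the provided `bh_q` column instead.
* Bray-Curtis treats absence-as-zero, so differing missingness between
  groups can itself separate samples in distance space.
* The enrichment double ratio is one reading of an ambiguous verbal
  definition; the alternative (`edge_count`) reading is provided, and
  conclusions that differ between the two should be treated with
  caution.
* PERMANOVA assumes exchangeable samples under the null; with 5 + 7
  samples the exact enumeration bounds the attainable p-value at
  1/792 from below.
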