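---
title: "Methods: interactome scoring, TMT threshold calibration and network enrichment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: interactome scoring, TMT threshold calibration and network enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proteodiff)
```

proteodiff implements three related protein-level analyses that together
take a tagged-bait affinity purification and a multiplexed quantitative
comparison from raw tables to a ranked interactome, a differential
proteome, and a functional-network summary. This vignette documents the
models behind each stage, the tunable parameters and their defaults, what
the synthetic-data generators do and do not emulate, and the numerical and
design choices a maintainer would want spelled out.

## 1. AP-MS candidate filtering and enrichment-index ranking

An affinity purification of a tagged bait co-purifies genuine partners,
abundant sticky background, and everything in between. The screen
implemented in `score_apms()` is a filter cascade followed by an
abundance-normalized ranking:

1. **Evidence floor.** A protein must carry at least 2 unique peptides and
   at least 10 spectral counts (SpC) in the bait purification. Both bounds
   are inclusive and configurable (`apms_config()`).
2. **Specificity.** The protein must be absent from the control
   purification (`control_spc == 0`, the *bait-unique* branch) **or** be at
   least 4-fold enriched (`bait_spc / control_spc >= 4`, inclusive). The
   bait-unique branch is an explicit disjunct, not a pseudocount trick:
   control-zero proteins never enter a division.
3. **Compartment plausibility.** For a nuclear bait only candidates with
   nuclear or unknown subcellular localization are retained; "unknown" is
   kept deliberately, since discarding unannotated proteins would bias the
   screen toward well-studied ones.
4. **Ranking.** Each candidate's relative abundance within the purification
   is its normalized spectral abundance factor,

   $$\mathrm{NSAF}_i = \frac{\mathrm{SpC}_i / L_i}{\sum_j \mathrm{SpC}_j / L_j},$$

   with $L_i$ the protein length in amino acids and the denominator running
   over **all** bait-detected proteins — the NSAF is a property of the
   purification, so it is computed before any filtering and later filters
   cannot change a retained protein's value. The enrichment index divides
   by the whole-cell abundance estimate $A_i$ (ppm, PAX-style):
   $\mathrm{EI}_i = \mathrm{NSAF}_i / A_i$. A high index flags a protein
   captured far above its cellular baseline — exactly the signature of a
   specific, possibly low-abundance partner that total-abundance ranking
   would bury. The top 50 candidates by index are reported; ties break by
   accession so output is reproducible.

**Missing whole-cell abundance.** Proteins without a positive abundance
estimate are a real dilemma: they are disproportionately the poorly
characterized, low-abundance proteins the index exists to surface.
The default policy imputes the dataset's minimum positive abundance
(the most favorable defensible value) and flags the row
(`abundance_imputed`); `missing_abundance_policy = "exclude"` drops them
instead. An abundance recorded as exactly 0 is treated as missing for the
division, though 0 remains a legal stored value in the metadata table.

## 2. TMT threshold calibration and concordant-replicate calls

The comparison design is two biological duplicates per group (control,
mutant) quantified in one TMT multiplex. The stage is deliberately a pure
fold-threshold classifier — no moderated statistics — because with n = 2
per group the honest basis for a cutoff is the replicate noise itself:

1. **Normalization** (`normalize_channels()`): each reporter channel is
   rescaled so its column total equals the mean original total
   (`total_sum`). The method is configurable because published abundance
   tables are often already normalized; `none` is then correct.
2. **Concordance** (`replicate_concordance()`): squared Pearson correlation
   of log10 abundances between duplicates. Under the package's default
   noise model this is ≈ 0.99; values far below that flag a failed
   replicate before any calling is done.
3. **Noise fit** (`fit_ratio_distribution()`): within-group replicate log2
   ratios are binned with Freedman–Diaconis breaks and a Gaussian
   $a\,e^{-(x-\mu)^2/2\sigma^2}$ is fitted to the histogram by nonlinear
   least squares (Levenberg–Marquardt). A histogram fit, rather than a
   direct moment estimate, keeps the estimate insensitive to the handful of
   genuinely differential proteins in the tails. If the fit fails or the
   input is degenerate (e.g. all ratios identical) the estimator falls back
   to (median, 1.4826·MAD) and sets a `fallback` flag.
4. **Threshold** (`derive_threshold()`): the fold window containing a
   central coverage $c$ of the fitted ratio distribution is
   $\tau = 2^{z_{(1+c)/2}\,\sigma_{\log_2}}$. With
   $\sigma_{\log_2} = \log_2(1.3)/1.6449$ — the spread at which 90% of
   replicate ratios lie within ±1.3-fold — coverage 0.90 returns exactly
   $\tau = 1.30$: the familiar "±30%" rule is the 90% point of the
   replicate-noise distribution, and the identity is tested analytically.
5. **Calls** (`call_differential()`): with per-replicate ratios
   $r_i = \mathrm{mutant}_i/\mathrm{control}_i$, a protein is **up** iff
   $r_1 \ge \tau$ and $r_2 \ge \tau$, **down** iff both
   $r_i \le 1/\tau$ — symmetric on the log scale, inclusive, and requiring
   the *same* direction in both replicates. Proteins with a zero reporter
   abundance in any channel are marked not evaluable and excluded from the
   summary counts; TMT zeros are rare missingness, not biology, so they are
   neither imputed nor allowed to create infinite ratios.

Requiring concordant duplicates squares the false-positive rate: if a null
protein exceeds $\tau$ in one replicate with probability $p$ (0.05 at the
calibrated threshold), the chance of a false call in a given direction is
$p^2$ = 0.0025. This identity is verified by Monte Carlo in the test
suite. Replicate pairing is by index (`mutant_1/control_1`,
`mutant_2/control_2`); all-four-cross-ratios (`pairing = "cross"`) and
classification on the ratio of group means (`pairing = "average"`) are
available as stricter and looser variants, off by default because the
two-duplicate design gives no basis for preferring them.

## 3. Functional network and over-representation

`build_network()` induces the subgraph of a STRING-dialect edge table on
the query set, keeping edges with combined score **strictly** greater than
0.4 (the conventional medium-confidence floor; flat files scored 0–1000
are auto-rescaled on read). Query proteins absent from the edge vocabulary
are reported as unmapped rather than silently dropped. Because "average
connectivity" is ambiguous when isolated nodes exist,
`connectivity_summary()` reports the mean degree with both denominators
(all mapped nodes, and connected nodes only).

`cluster_network()` uses deterministic greedy modularity maximization on
the unweighted thresholded graph (nodes pre-sorted lexicographically,
multi-edges and self-loops removed); communities reaching
`min_cluster_size = 3` are reported as clusters, renumbered by decreasing
size. Published cardiac-interactome analyses of this kind ran a Cytoscape
plug-in whose algorithm and database snapshot are not recoverable, so the
package does not chase any specific historical clustering; correctness is
instead defined by planted-partition recovery (adjusted Rand index > 0.8
at `p_within = 0.9`, `p_between = 0.05`), which any sound community
detector should achieve.

`go_overrepresentation()` is the one-sided hypergeometric upper tail
$P(X \ge k)$ per term against a background of all quantified proteins (not
the whole annotation universe — standard over-representation practice, and
configurable simply by passing a different `background`). Terms are flagged
at raw p < 0.05, matching the conventional display rule for such figures;
Benjamini–Hochberg q-values are attached for reporting but never used for
thresholding, so modern practice is surfaced without changing behavior.
Annotations are a flat term→protein table; ontology-graph propagation to
ancestor terms belongs upstream and is out of scope.

## 4. What the generators emulate — and what they do not

`simulate_apms()` draws background bait/control counts from a negative
binomial (real spectral counts are overdispersed relative to Poisson; the
`dispersion` size parameter defaults to 4, reflecting counts already
aggregated over duplicate runs and gel fractions, which sums the
per-run size). Planted interactors get their bait mean multiplied by
`enrichment_factor` (default 8, twice the filter's 4-fold floor: a planted
truth sitting exactly on the decision boundary would make recovery a coin
flip rather than a test); half of them (`unique_fraction = 0.5`) are drawn
with control mean 0, since a control purification lacking the bait should
show no trace of genuinely bait-dependent partners. Planted interactors
receive nuclear/unknown localization — a nuclear bait's true partners are
nuclear — and low whole-cell abundance (log-uniform 0.1–10 ppm versus
0.1–1000 ppm background), emulating the low-abundance specific partners
the enrichment index is designed to surface.

`simulate_tmt()` draws per-protein base log2 abundance from N(10, 2) (a
typical reporter-intensity dynamic range) and adds independent
N(0, $\sigma/\sqrt{2}$) noise per channel, so within-group replicate log2
ratios have standard deviation exactly $\sigma$ (`tmt_sigma_ratio`,
default $\log_2(1.3)/1.6449 \approx 0.2301$). Planted up/down proteins
(defaults 50 + 50 of 3000, $|\log_2 \mathrm{FC}| = 1$) shift both mutant
channels. The generators are pure functions of (config, seed) and the
planted truth is returned alongside the data, so recovery tests need no
re-derivation.

Not emulated, deliberately: peptide-to-protein inference, isotopic
impurity, TMT ratio compression, correlated (batch) channel noise,
abundance-dependent count variance, and contaminant structure in AP-MS
background. Passing recovery tests therefore demonstrates that the
*decision rules* behave as designed under their own statistical
assumptions — not that those assumptions capture every pathology of real
data. One consequence worth stating plainly: with 100 planted effects in
3000 proteins and a threshold calibrated to a 5% per-replicate tail, the
expected false-discovery proportion among calls is
$2900 \cdot 2 p^2 / (2900 \cdot 2 p^2 + \approx 99) \approx 0.13$. A pure
fold-rule has no p-value machinery to push this lower at fixed τ; that is
its honest operating point under these conditions, and the package reports
it rather than masking it.

## 5. Numerical choices and problem sizes

* Inclusive thresholds everywhere (≥ 10 SpC, ≥ 4-fold, ≥ τ, ≤ 1/τ); the
  one strict inequality is the network score bound (> 0.4), mirroring the
  field's convention.
* All orderings are total: candidate ranking breaks enrichment-index ties
  by accession; cluster ids order by size then first member; output tables
  are sorted so identical runs are byte-identical.
* Seeds: every generator takes an explicit integer seed and restores RNG
  state on exit (`withr::local_seed`), so library calls never perturb a
  caller's RNG stream.
* Test and verification sizes were chosen as the smallest that make the
  Monte-Carlo error comfortably smaller than the margins being tested:
  3000 proteins for TMT calibration (σ recovered within 5%), 200 × 3000
  null calls for the $p^2$ identity, 20 seeds for each recovery experiment,
  exhaustive enumeration for hypergeometric tails at N ≤ 60.

## 6. Known limitations

* The TMT stage assumes exactly two replicates per group for ratio-based
  calling; the containers accept more, but the concordance and fit
  operations are duplicate-specific by design.
* Histogram-Gaussian σ estimation is mildly binning-dependent; at n ≥ 3000
  ratios the effect is within the 5% tolerance the tests enforce, but at a
  few hundred ratios the robust fallback is often the better estimator.
* The enrichment stage tests each term marginally; strongly overlapping
  terms will co-fire, and no term-grouping heuristic is applied.
* The localization filter trusts its input categories; mapping real
  annotation sources into {nuclear, unknown, other} is the caller's
  responsibility and is where most real-data ambiguity lives.
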