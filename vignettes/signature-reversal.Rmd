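---
title: "Signature reversal scoring: model, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Signature reversal scoring: model, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Signature-reversal drug repurposing starts from a simple hypothesis: if a
disease pushes a set of genes up and another set down, a compound whose
induced expression changes run in the *opposite* direction is a candidate
therapeutic. `rgescore` implements the full desk pipeline around that
hypothesis for L1000-style perturbation compendia:

1. build a directed disease signature from a differential-expression table,
2. score every drug profile with a rank-based Reverse Gene Expression Score
   (RGES),
3. normalize and summarize the per-profile scores into one sRGES per
   compound, and
4. identify the individual signature genes that effective compounds
   specifically reverse.

A synthetic-study generator with recorded ground truth makes every stage
testable without any external download.

# Disease signatures

A gene enters the signature when `|log2fc| > 1.5` and adjusted `P < 0.001`
(both strict), with the sign of the fold change assigning the direction.
The fold-change cut is applied to the *absolute* value and split by sign:
a single printed threshold produces both directed sets, which is how such
signatures are reported in practice. Genes with missing adjusted `P` are
excluded, never imputed. Scoring is restricted to the landmark gene
universe — the directly measured genes of L1000-style platforms (978 in the
standard panel) — because scores computed on directly measured genes behave
better than scores that mix in model-imputed expression. Signatures of 50
or fewer genes trigger a warning: rank statistics on very small sets are
noisy, and reversal screens conventionally require more than 50
differentially expressed genes per disease.

# The RGES statistic

For one profile, genes are ranked by their differential-expression value,
rank 1 being the most upregulated; ties break by ascending gene identifier
so the ranking is deterministic. For a gene set of size $m$ in a ranking of
$n$ genes with sorted positions $V(1) \le \dots \le V(m)$, the two
Kolmogorov–Smirnov-type deviations are

$$a = \max_{j} \left( \tfrac{j}{m} - \tfrac{V(j)}{n} \right), \qquad
  b = \max_{j} \left( \tfrac{V(j)}{n} - \tfrac{j-1}{m} \right),$$

and the enrichment score is $es = a$ if $a > b$, otherwise $-b$. Computing
$es_{up}$ and $es_{down}$ for the signature's two sets gives

$$\mathrm{RGES} = es_{up} - es_{down} \in [-2, 2],$$

with *no* zero-clamping when the two components share a sign. The classic
connectivity score sets such cases to zero, which piles a point mass at 0
and destroys the correlation structure against compound efficacy; keeping
the raw difference preserves it. Strongly negative RGES means reversal:
disease-up genes pushed to the bottom of the ranking and disease-down genes
pulled to the top.

Because the score depends on the data only through ranks, it is exactly
invariant under strictly monotone transforms of the profile values, and
swapping the signature's two sets negates it exactly — both properties are
enforced in the test suite over randomized cases, and the $a$/$b$ maxima
are checked against an independent brute-force loop on all small universes.

Spearman, Pearson and cosine similarity between the profile values and the
signature's fold changes are provided as comparison scores, and a gene-set
permutation P value (random up/down sets of the observed sizes, two-sided
on $|\mathrm{RGES}|$, with the add-one correction) quantifies how extreme a
single profile's score is. The permutation null is a pragmatic choice — the
natural null for "is this score larger than chance for sets of this size" —
not a claim about any particular screening compendium.

# Summarization to sRGES

One compound is typically profiled many times: several cell lines, doses
from nanomolar to tens of micromolar, 6 h and 24 h treatments. Reversal
strength grows with dose and duration, so raw scores from different
conditions are not comparable. Conditions are grouped into a 2×2 grid of
bins at 10 µM and 24 h — the reference condition (10 µM, 24 h) is the most
common assay condition in LINCS-style screens, and both boundaries fall on
the reference side so the reference maps to its own bin.

For each non-reference bin, compounds profiled in the *same cell line* under
both the reference and that bin provide paired observations; the bin's
additive offset is the mean over pairs of (mean reference RGES − mean
target-bin RGES). Bins supported by fewer than `min_pairs` pairs (default
10) fall back to offset 0 with a warning. This paired-mean model is the
simplest one consistent with the assumption that the condition effect
depends mainly on dose and time; it estimates each bin freely rather than
imposing a functional form on f(dose, time), and with ≥300 pairs at noise
sd 0.05 it recovers planted additive offsets to within ±0.02.

Profiles are further weighted by how transcriptionally similar their cell
line is to the tumours of interest: the raw score of a cell line is its
average Spearman correlation to individual tumour samples over shared
genes; negative averages clamp to 0 (a weight is a non-negative multiplier)
and scores are divided by their maximum, so the best-matched line has
weight exactly 1. The summary is then the weighted mean of offset-adjusted
scores,

$$\mathrm{sRGES}(c) \;=\;
  \frac{\sum_{i \in c} w(\mathrm{cell}_i)\,
        \bigl(\mathrm{RGES}_i + \mathrm{offset}(\mathrm{bin}_i)\bigr)}
       {\sum_{i \in c} w(\mathrm{cell}_i)},$$

with the weight sum as the denominator so that weights rescale rather than
dilute. This concrete form — reference normalization plus correlation
weighting inside a weighted mean — is this package's design choice among
the summaries consistent with that description; the obvious alternatives
(best, lower-middle median, or plain mean of raw RGES per compound) are
provided as named strategies for benchmarking, and on synthetic studies the
weighted form correlates with planted efficacy at least as well as the
best-profile strategy. Output tables are sorted ascending by sRGES, most
reversing first, matching how such rankings are consumed.

# Reversal genes

To move from compound ranking to gene-level claims, each compound is
reduced to one profile and one potency: the lower-middle-median IC50 across
measurements, and the profile holding the lower-middle-median RGES (ties by
smallest profile id). Compounds split into effective (median IC50 < 10 µM,
strictly) and ineffective (≥ 10 µM) — 10 µM is the conventional primary
screening activity bound. Each signature gene's normalized position
(rank/n, rank 1 on top) is compared between groups with a one-sided
Mann–Whitney–Wilcoxon test:

* **up** genes: reversal means effective compounds push them toward the
  *bottom*, i.e. positions stochastically **greater** in the effective group;
* **down** genes: positions stochastically **smaller**.

This sign convention is the most error-prone point in the module: "ranked
lower" means *toward the bottom*, which under the rank-1-on-top convention
is a *larger* normalized position.

P values are exact (from the null Wilcoxon distribution) when the pooled
group size is at most 20 and tie-free, and otherwise use the normal
approximation with the mid-rank tie correction and no continuity
correction — without the continuity term the attained level tracks the
nominal one closely (the test suite verifies calibration under label
permutation). Benjamini–Hochberg adjustment across all tested genes with an
adjusted-P cut of 0.25 flags reversal genes; BH is the field's default for
FDR-style cuts at this level. Robustness is assessed by leave-one-compound-out:
the test is repeated with each compound (from either group) removed, and
only genes flagged in the full set *and* every trial are `robust`. The
robust set is by construction a subset of the full-set flags.

One behaviour worth knowing: selecting the median-RGES representative
conditions, for ineffective compounds, on the very genes being tested,
which mildly concentrates their null positions and can push the realized
false-discovery proportion of the *full-set* flags slightly around the
nominal level. The LOCO-robust list, which is the intended deliverable, is
distinctly more conservative.

# The synthetic generator

`simulate_study()` emulates the statistical structure the method assumes,
with every planted quantity recorded:

* a universe of 978 genes with a 50+50-gene signature whose planted genes
  pass the signature filter by construction;
* 30 effective and 30 ineffective compounds; effective compounds carry a
  per-compound reversal strength of 0.3 × U(0.7, 1.3) (mean 0.3) in
  normalized rank units, ineffective compounds 0.3 × U(0, 0.1);
* one profile per compound × 3 cell lines × 4 condition bins; planted genes
  receive a background-uniform position displaced by the compound's
  strength (up-genes toward the bottom, down-genes toward the top), mapped
  back to values through the normal quantile so planted and background
  values are distributionally compatible, with per-profile shift jitter of
  sd 0.05 and positions clipped into (0, 1);
* non-reference bins attenuate the planted shift by 0.10–0.20 rank units
  (lower dose and shorter treatment weaken reversal), and 5% of profiles
  are flagged low-quality;
* IC50 follows the lognormal link `exp(3 − 8·strength + ε)`, sd(ε) = 0.5,
  chosen so the 10 µM threshold separates the groups without being
  deterministic — some ineffective compounds stray under it, as in real
  screens;
* cell lines mix a shared tumour factor with independent noise as
  `ρ·F + √(1−ρ²)·e` (ρ = 0.9/0.7/0.5 by default), so expected correlation
  to tumours is ρ and expected weights are ρ/max(ρ); tumours add noise of
  sd 0.3 on top of the factor.

Because profile *values* are the generator's output and RGES is computed
downstream, condition effects inside `simulate_study()` live on the
rank-shift scale, not the RGES scale. Exactly additive RGES bin effects —
what the offset estimator assumes — are planted by the dedicated
`simulate_offset_training()` generator, which is what the offset-recovery
validation uses.

What the generator does **not** emulate: L1000 plate and batch effects,
dose–response curvature within a bin, compound polypharmacology,
correlated gene modules (background values are i.i.d.), or imputed-gene
noise. Passing the recovery suite therefore shows the *machinery* is
correct and well-calibrated under the assumed structure, not that any
particular real compendium satisfies that structure.

# Numerical and validation choices

* Deterministic tie-breaks everywhere: gene-id order in rankings, smallest
  profile id among equal medians, lower-middle medians (always an observed
  value, bit-reproducible).
* `min_overlap = 3` signature genes per direction is required for a score;
  smaller overlaps give degenerate KS statistics.
* Doubles are serialized at 17 significant digits so signatures and score
  tables round-trip exactly; all outputs are written atomically.
* Validation problem sizes: the enrichment oracle sweeps ≥1000 random
  rankings over universes up to n = 12 with set sizes up to 3 (where
  brute-force enumeration is exact and instant); algebraic properties run
  on ≥1000 randomized cases; recovery experiments use 20 fixed seeds at the
  generator defaults above, with null calibration from 200 label
  permutations of a strength-0 study. These sizes make the whole suite run
  in a couple of minutes while keeping every Monte-Carlo margin wide
  relative to its tolerance.
* For the reversal-gene recovery experiment the study is generated with
  condition attenuation set to zero so the representative profiles carry
  the nominal 0.3 shift being tested; with attenuation on, the
  median-RGES selection lands on attenuated profiles and the experiment
  would measure a much smaller (and unintended) effect.

# Limitations

* The summarization form (weighted mean with Σw denominator; paired-mean
  offsets on a 2×2 bin grid) is one defensible choice within the described
  components, not a canonical formula; the named strategies exist to make
  such comparisons easy.
* Offsets are additive and shared across compounds; a compound whose
  condition response deviates wildly from the average is mis-normalized.
* Cell-line weights use shared landmark genes by default; weighting on a
  most-variable-gene subset is not implemented.
* The gene-set permutation P value for a single RGES is exchangeable-null
  only; it does not model inter-gene correlation.
* No IC50 harmonization across assays is attempted: the efficacy table is
  taken at face value and summarized by the lower-middle median.

# A worked run

```{r, eval = FALSE}
library(rgescore)

study <- simulate_study(sim_config(seed = 1))
scores <- batch_score(study$profiles, study$signature)
offsets <- estimate_offsets(scores)
weights <- compute_cell_weights(study$cell_expr, study$tumour_expr)
srges <- summarize_srges(scores, offsets, weights)
head(srges)

groups <- summarize_efficacy(study$efficacy)
reps <- select_representative_profiles(scores)
pos <- normalized_positions(study$profiles, study$signature, reps)
genes <- loco_reversal_genes(pos, groups, study$signature)
subset(genes, robust)
```

The same pipeline is available from a shell through the `rges` script
(`exec/rges` in the installed package) with the subcommands `simulate`,
`signature`, `score`, `srges` and `reversal`.
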