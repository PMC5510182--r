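# rgescore

Reverse Gene Expression Scoring for signature-based drug repurposing.

## What it does

Given (a) a disease gene-expression signature — the genes significantly up-
and downregulated in tumours versus adjacent normal tissue — and (b) a
compendium of drug-perturbation expression profiles over a landmark gene
panel (L1000-style), `rgescore` ranks compounds by how strongly they
*reverse* the disease signature, and then asks which individual signature
genes the effective compounds specifically flip.

For one profile ranked by differential expression (rank 1 = most
upregulated), each directed gene set of size *m* in a ranking of *n* genes
gets a Kolmogorov–Smirnov-type enrichment score from

  a = max_j ( j/m − V(j)/n ),  b = max_j ( V(j)/n − (j−1)/m ),
  es = a if a > b, else −b,

where V(1) ≤ … ≤ V(m) are the set's sorted positions. The Reverse Gene
Expression Score is

  **RGES = es_up − es_down**,

kept as a raw difference (no zero-clamping when the components share a
sign). Negative RGES = reversal. Because one compound is profiled under
many cell lines, doses and durations, per-profile scores are normalized to
the reference assay condition (10 µM, 24 h) by additive per-bin offsets
learned from compounds profiled under both conditions in the same cell
line, weighted by each cell line's rank correlation to the tumours
(clamped at 0, max-normalized to 1), and summarized per compound as

  **sRGES = Σᵢ wᵢ (RGESᵢ + offset(binᵢ)) / Σᵢ wᵢ.**

Gene-level reversal is tested by splitting compounds at a median IC50 of
10 µM into effective/ineffective, reducing each compound to its
median-RGES profile, and comparing each signature gene's normalized rank
between groups with a one-sided Mann–Whitney–Wilcoxon test
(Benjamini–Hochberg, adjusted P < 0.25), with a leave-one-compound-out
filter marking genes significant in *every* trial as robust.

A synthetic-study generator (`simulate_study()`) plants all of this
structure — reversal strengths, condition effects, cell–tumour similarity,
an IC50 link — with recorded ground truth, so the whole pipeline is
testable offline.

## Worked example

```r
library(rgescore)

study   <- simulate_study(sim_config(seed = 1))   # 978 genes, 60 compounds
scores  <- batch_score(study$profiles, study$signature)
offsets <- estimate_offsets(scores)
weights <- compute_cell_weights(study$cell_expr, study$tumour_expr)
srges   <- summarize_srges(scores, offsets, weights)
head(srges, 5)
#>   compound_id      srges n_profiles n_cell_lines
#> 1      eff024 -0.8315289         12            3
#> 2      eff001 -0.8258736         12            3
#> 3      eff016 -0.8133444         12            3
#> 4      eff014 -0.8091463         12            3
#> 5      eff011 -0.7920901         12            3
```

The most reversing compounds (sRGES near −0.83) are all planted effective
compounds. The learned normalization state is interpretable on its own:

```r
offsets
#>         bin     offset support
#>   high_long  0.0000000       0
#>  high_short -0.1876808     157
#>    low_long -0.1049640     160
#>   low_short -0.2412826     161
weights
#>  cell_line   raw_cor    weight
#>        CL1 0.8582764 1.0000000
#>        CL2 0.6449320 0.7514269
#>        CL3 0.4494687 0.5236875
```

Lower doses and shorter treatments weaken reversal, so their scores need a
negative adjustment toward the 10 µM / 24 h reference; the cell line most
correlated with the tumours carries weight 1. Here Spearman correlation
between sRGES and log median IC50 is 0.84 — compounds that reverse the
signature hardest are the most potent, which is the premise the method
screens on. Gene-level discovery then flags the planted reversal genes:

```r
groups <- summarize_efficacy(study$efficacy)
reps   <- select_representative_profiles(scores)
pos    <- normalized_positions(study$profiles, study$signature, reps)
genes  <- loco_reversal_genes(pos, groups, study$signature)
head(subset(genes, robust), 5)
#>    gene direction u_stat           p       padj reversal robust
#> 1 g0001        up  596.0 0.015110458 0.03976436     TRUE   TRUE
#> 3 g0003        up  567.0 0.041091310 0.06848552     TRUE   TRUE
#> 4 g0004        up  590.0 0.018827168 0.04380574     TRUE   TRUE
#> 5 g0005        up  629.0 0.003959965 0.02177424     TRUE   TRUE
#> 7 g0007        up  597.5 0.014283787 0.03933961     TRUE   TRUE
```

The same pipeline runs from a shell via the installed `exec/rges` script:
`rges simulate | signature | score | srges | reversal` (see `rges --help`).
Real data come in as tab-separated tables (DE table, profile matrix +
metadata sidecar or GCT v1.3 text, efficacy table); see the vignette in
`vignettes/signature-reversal.Rmd` for formats, model details and design
choices.

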