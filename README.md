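# ploidyExpress

Expression-state classification for ovule transcriptomes across a
sexual–apomictic ploidy series.

## What it is for

Apomictic (asexually seeding) hexaploids of the *Ranunculus auricomus*
complex are allopolyploid hybrids of a diploid and a tetraploid sexual
parent. When their ovule transcriptomes are compared with the sexual
parents across four developmental stages, expression differences can stem
from genome dosage, from inheritance of one parent's expression level, or
from hybridization itself. `ploidyExpress` implements the full analysis
chain for microarray-style designs of this kind — including the awkward
reality that the tetraploid parent is a single genotype with no biological
replication — together with a synthetic-data generator that plants known
expression classes for end-to-end validation.

The pipeline: median-polish probe summarization and quantile normalization
(the algorithmic core of RMA), a σ/σmax variance filter, PCA sample QC,
stage-wise Welch t tests gated by p < 0.01, |log2 FC| > 2 and BH q < 0.05,
Venn-style stage summaries, the expression-state classification, STEM-style
profile analysis with permutation significance for heterochrony detection,
a SNP parental-origin screen, and ΔΔCt qPCR validation.

## The classification at its core

For gene *g* at stage *s*, with diploid mean/SD (x̄₂ₓ, s₂ₓ), hexaploid
mean/SD (x̄₆ₓ, s₆ₓ), tetraploid point value x₄ₓ and band half-width k = 2,
genes DE between 6x and 2x are classified first-match-wins:

1. **transgressive**: |x₄ₓ − x̄₂ₓ| ≤ k·s₂ₓ and |x̄₆ₓ − x̄₂ₓ| > k·s₂ₓ and
   |x̄₆ₓ − x₄ₓ| > k·s₆ₓ (parents agree, hybrid outside both);
2. **po_4x** (expression-level dominance toward the tetraploid):
   |x₄ₓ − x̄₆ₓ| ≤ k·s₆ₓ and |x₄ₓ − x̄₂ₓ| > k·s₂ₓ;
3. **ploidy** (additivity): x̄₂ₓ < x₄ₓ < x̄₆ₓ (or strictly reversed) with
   both polyploids outside the diploid band;
4. otherwise unclassified.

Non-DE genes are screened secondarily: **po_2x** when |x₄ₓ − x̄₆ₓ| > k·s₆ₓ
(the hybrid tracks its diploid parent; the tetraploid is the outlier).

See `vignettes/expression-states.Rmd` for the model, its conventions and
their rationale.

## Worked example

```r
library(ploidyExpress)

design <- generate_design(3, 1, 3, 4)          # 7 genotypes x 4 stages
truth  <- plant_truth(2000, effect_size = 3, seed = 1)
probes <- simulate_expression(truth, design, noise_sd = 0.3, seed = 1001)
expr   <- summarize_probes(probes)             # log2 + median polish
de     <- de_all_stages(expr, design)          # Welch t, 3 gates per stage
ct     <- classify_expression(expr, design, de)
planted_class_recovery(truth, ct)
```

```
          class n_planted n_recovered recovery_pct
1        ploidy       196         196          100
2         po_4x       197         197          100
3         po_2x       106         106          100
4 transgressive       106         106          100
```

Every planted class is recovered at ≥ 99% across seeds under realistic
noise (100% exactly when `noise_sd = 0`). A single `run_pipeline(pipeline_config())`
call executes the whole chain — including heterochrony profiles, the SNP
origin screen and qPCR concordance — and writes all tables with an
md5-hashed manifest; reruns under the same seed are byte-identical.

Summarizing a classification table reproduces stage-by-class marginals:

```r
s <- summarize_classes(ct, stages = stage_labels(4))
s[s$stage == "Total", c("direction", "transgressive", "parent_of_origin",
                        "ploidy", "total")]
```

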