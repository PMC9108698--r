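# trbserial

Serial analysis of the T-cell receptor β-chain (TRB) repertoire from
AIRR-seq rearrangement tables.

Chronic HIV infection depletes and distorts the peripheral T-cell
compartment: repertoires become dominated by large, mostly private clonal
expansions, diversity falls, and the network structure of CDR3 sequences
shifts from the dense many-to-many neighborhoods of naive repertoires to
sparse hub-like architectures typical of antigen-experienced ones.
`trbserial` implements the quantitative toolkit needed to follow such
repertoires longitudinally — in people living with HIV sampled before and
after antiretroviral therapy (ART) initiation and in healthy controls —
starting from standard immunoSEQ-style or AIRR rearrangement tables. It is
aimed at immunogenomics analysts working with serial bulk TRB CDR3 data.

## What it computes

Each blood sample yields a table of unique CDR3 nucleotide rearrangements
with template counts. After excluding samples with fewer than 5000 total
sequences and discarding CDR3s shorter than 7 amino acids, repertoires are
depth-normalized by repeated downsampling (without replacement) to 5000
sequences, and summary statistics are averaged over 100 iterations:

- **Clonality** `1 − H/ln R`, where `H = −Σ pᵢ ln pᵢ` is the Shannon
  entropy of the productive amino-acid clonotype frequencies and `R` the
  number of clonotypes: 0 for a perfectly even repertoire, 1 for a
  monoclonal one.
- **Gini coefficient** `G = Σᵢⱼ |xᵢ − xⱼ| / (2 n Σ xᵢ)` of the clone-size
  distribution.
- **TRB sequence production efficiency** — mean number of distinct
  nucleotide rearrangements encoding one CDR3 amino-acid sequence
  (convergent recombination).
- **CDR3 length spectra**, **maximum clone frequency**, and **cumulative
  top-10/100/1000 clone frequencies**.
- **Pairwise repertoire similarity** `|shared AA| / (|A| + |B|)` over
  unique productive sequences (0.5 for identical repertoires), decomposed
  into within-participant and across-participant pairs.
- **Edit-distance-1 networks** over the 5000 most frequent CDR3 amino-acid
  sequences per repertoire, with pooled degree distributions per sample
  group and a GAM-style trend curve.
- **Longitudinal tracking** of the 50 most abundant clones per participant
  around the ART date, **annotation** against VDJdb/McPAS-TCR style
  databases filtered by the participant's MHC genotype, propagation of
  annotations through GLIPH2-style specificity groups, and discovery of
  **candidate public clonotypes** shared by two or more participants.
- **Group comparisons** (pre-ART vs post-ART vs control) with two-sided
  Wilcoxon tests and Holm-Bonferroni correction.

A synthetic cohort generator (`generator_config()`, `generate_cohort()`,
`spike_public_clonotypes()`) reproduces the statistical structure of all
three sample groups — heavy-tailed clone sizes with a persistent dominant
expansion, post-ART diversification, convergent recombination, realistic
CDR3 length spectra, edit-distance-1 neighborhoods, viral-load and CD4
trajectories — so the entire pipeline runs and is validated with no
external data.

## Worked example

```r
library(trbserial)

plhiv <- generate_cohort(generator_config("plhiv", n_participants = 4,
  n_clones = 2000, samples_per_participant = c(5, 6), art_sample_index = 3,
  total_count_per_sample = 20000, seed = 2024))
ctrl  <- generate_cohort(generator_config("control", n_participants = 4,
  n_clones = 4000, total_count_per_sample = 20000, seed = 2025))
coh <- combine_cohorts(plhiv, ctrl)
coh
#> TRB cohort: 8 participants, 26 repertoires
#> control    post     pre
#>       4      14       8

m <- cohort_metrics(coh, analysis_config(downsample_iterations = 10, rng_seed = 1))
round(tapply(m$clonality, m$group, mean), 3)
#> control    post     pre
#>   0.033   0.163   0.263

cmp <- compare_groups(m, c("clonality", "gini"))
cmp[, c("metric", "group_a", "group_b", "test", "p_value", "p_adjusted")]
#>      metric group_a group_b     test  p_value p_adjusted
#> 1 clonality control    post rank_sum 6.54e-04   2.61e-03
#> 2 clonality control     pre rank_sum 4.04e-03   8.08e-03
#> 3 clonality    post     pre rank_sum 7.51e-05   3.75e-04
#> 4      gini control    post rank_sum 6.54e-04   2.61e-03
#> 5      gini control     pre rank_sum 4.04e-03   8.08e-03
#> 6      gini    post     pre rank_sum 6.25e-06   3.75e-05

nw <- build_network(top_n_clonotypes(filter_cdr3(coh$repertoires[["5001_T01"]]), 2000))
nw
#> Edit-distance-1 CDR3 network: 2000 nodes, 401 edges
#>   mean degree 0.401, max degree 4
```

Depth-normalized clonality falls from pre-ART to post-ART repertoires but
stays far above the control level, and every pairwise contrast survives
Holm correction — the diversity recovery pattern the package is designed
to quantify. The control-profile network shows the dense edit-distance-1
neighborhoods expected of a naive-like repertoire.

`run_pipeline(cohort, out_dir, config)` executes the whole chain (QC →
metrics → similarity → networks → tracking/annotation → comparisons) and
writes TSV outputs plus a JSON manifest; identical inputs and seeds give
byte-identical outputs.

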