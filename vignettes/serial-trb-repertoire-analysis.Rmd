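---
title: "Serial TRB repertoire analysis: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Serial TRB repertoire analysis: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`trbserial` analyses serial bulk TRB CDR3 repertoires — typically from
people living with HIV (PLHIV) sampled before and after antiretroviral
therapy (ART) initiation, against single-timepoint healthy controls. This
vignette explains the statistical machinery, the tunable parameters and
their defaults, the synthetic-data model used for validation, and the
design decisions taken where the methodology left genuine freedom.

## Data model

The unit of analysis is a *repertoire*: the unique TRB CDR3 nucleotide
rearrangements detected in one blood sample, each with an amino-acid
translation, V/J gene calls, a productive/nonproductive frame flag, and a
template count. Nucleotide identity is the clonal key: rows sharing a
CDR3 nucleotide sequence are merged by summing counts at load time, and
clone tracking across timepoints uses the same key. Diversity statistics,
similarity, networks and annotation all operate at the amino-acid level
over productive sequences, since the amino-acid sequence is the unit of
antigen specificity; `unique_nt` and the nucleotide-level Gini are exposed
alongside for completeness, because the source material does not pin down
which level the inequality statistic used.

Two tabular dialects are read and written: the immunoSEQ export layout
(`nucleotide` / `aminoAcid` / `count (templates/reads)` / `vGeneName` /
`jGeneName` / `sequenceStatus`) and the AIRR rearrangement layout
(`junction` / `junction_aa` / `duplicate_count` / `v_call` / `j_call` /
`productive`). The frame flag is taken from the file when present and
otherwise computed as "no stop codon and nucleotide length divisible by
3". Where an export carries both template and read counts, the reader
defaults to templates (`count_source` switches this), since template
counts estimate input cell numbers.

## Depth normalization and summary statistics

Sequencing depth varies widely between samples, and every diversity
statistic is depth-sensitive. The pipeline therefore:

1. excludes samples with total count strictly below 5000 (a sample with
   exactly 5000 is kept — the threshold is "fewer than 5000");
2. repeatedly draws exactly 5000 reads *without replacement* from each
   retained repertoire (multivariate hypergeometric over clones), rather
   than multinomially: the draw is from an observed finite read pool, and
   at depths close to the total count the multinomial would overdisperse;
3. discards CDR3s shorter than 7 amino acids (sequences without a
   plausible conserved-cysteine-to-phenylalanine loop);
4. computes all statistics on each downsampled repertoire and reports the
   arithmetic mean over 100 iterations. The averaging applies to *every*
   statistic, including unique-sequence counts, which are therefore not
   integers.

Clonality is `1 − H/ln R` with `H` the Shannon entropy of the productive
amino-acid clonotype frequencies. The base of the logarithm cancels in
`H/ln R`. A monoclonal repertoire has `R = 1` and `ln R = 0`; the package
returns clonality 1 by convention, the limit of maximal dominance. For the
same repertoire the Gini coefficient
`G = Σᵢⱼ |xᵢ − xⱼ| / (2 n Σ x)` over the clone-count vector is 0 — a
single clone exhibits no *between-clone* inequality under this formula,
which is the definition the package follows consistently even though
one could alternatively spread the monoclonal mass over the read-level
support and obtain `(n−1)/n`.

The full-repertoire (not downsampled) unique productive amino-acid count
is reported separately (`unique_productive_aa_full`): cohort-level
descriptive tables are conventionally quoted on full repertoires, while
the downsampled means support cross-sample comparison.

## Similarity

The pairwise similarity of two repertoires is the number of shared unique
productive amino-acid sequences divided by the **sum** of the two unique
counts, so identical repertoires score 0.5. The defining phrase ("the
total number of sequences in both repertoires") could also be read as the
union (Jaccard); the sum reading is the package default because it is the
literal arithmetic of the phrase, and `similarity_denominator = "union"`
is provided for sensitivity analysis. Membership is binary — frequencies
do not weight the overlap.

## Edit-distance-1 networks

Per repertoire, the 5000 most frequent productive amino-acid clonotypes
become nodes, and two nodes are joined when their Levenshtein distance is
exactly 1. Distance is full Levenshtein (substitution, insertion,
deletion at unit cost) because CDR3s of different lengths coexist in one
network. The implementation uses length-bucketed deletion-neighborhood
hashing — substitution pairs share a position-marked deletion key, indel
pairs arise when a sequence equals a single-deletion variant of a longer
one — and is required by the test suite to match the quadratic
dynamic-programming oracle (`utils::adist`) edge-for-edge.

Degrees are pooled across the networks of a sample group (edges never
cross repertoires); the package reports both the per-degree frequency and
the complementary cumulative fraction P(degree ≥ k), since "cumulative
frequency of nodes of a given degree" is ambiguous between the two; the
tail-comparison utility (`compare_degree_tails()`) uses the ccdf with a
bootstrap over repertoires. The trend curve is a penalized spline on log
frequencies with the smoothing parameter chosen by generalized cross
validation (`mgcv::gam`), standing in for a GAM regression line without
further tuning; it is skipped below four distinct degrees. Whether
networks should include nonproductive sequences was open; the package
uses productive only, consistent with every other amino-acid-level
analysis.

## Tracking, annotation, and public clonotypes

For each treated participant with at least two timepoints, the package
selects the `n = 50` clonotypes with the highest *maximum* frequency
across timepoints — yielding exactly 50 trajectories, the quantity an
alluvial plot displays — rather than the union of per-timepoint top-50
sets, which would yield a variable number. Trajectories carry zeros, and
a clone is `pre_art` iff its earliest nonzero frequency precedes the ART
date. Presence is assessed on full repertoires: downsampling is tied to
summary statistics, and detection sensitivity should not depend on it.

Annotation matches CDR3 amino-acid strings exactly against VDJdb and
McPAS-TCR style tables (V/J-restricted matching was considered and left
out of the default because the reference databases are themselves indexed
by CDR3). A match only labels a clone when the participant's MHC genotype
carries the record's restricting allele, compared at two-field resolution
with family-only database entries (e.g. "HLA-B*44") matching any allele
of the family — the rule that lets a B*44-annotated record label a
participant typed as B*44:03:01. When one CDR3 is annotated to several
pathogens, the source with the most MHC-consistent records wins and ties
fall to `other_public`.

Specificity groups (GLIPH2-style clusters) propagate annotation: a group
seeded by at least one annotated member, whose predicted MHC restriction
is compatible with the seed record's allele *and* carried by the
participant, transfers `likely_<source>` labels to its unseeded members.
Groups without a predicted restriction do not propagate — the restriction
filter is the step that controls false transfer, so its absence is
treated as failure, not as a pass.

Candidate public clonotypes are productive sequences observed in two or
more treated participants and absent from both databases; any nonzero
template count constitutes "observed" by default (`min_count` raises
this). Label precedence is deterministic: direct match > likely label >
candidate_public > private.

## Group comparisons

The headline contrasts (pre-ART vs post-ART vs control) involve unpaired
groups of unequal sizes, for which the signed-rank test is not defined;
the package uses the rank-sum (Mann-Whitney) form for unpaired pairs and
reserves the signed-rank form for the within-participant pre/post
contrast (each participant's pre and post samples nearest the ART date),
recording per row which test was used. Tests are two-sided; the exact
null distribution is used for groups up to 25 observations without ties
and the normal approximation with continuity correction otherwise. All
metric × pair tests of one call form a single Holm-Bonferroni family, and
adjusted p < 0.05 is called significant.

## The synthetic cohort model

The generator exists so that every downstream stage can be validated in
closed loop. Per participant it builds a clone pool and evolves it across
timepoints:

- **Clone sizes.** `clone_law` is uniform, symmetric Dirichlet, or a
  power law parameterized by the clone-*size* distribution exponent α
  (rank weights `i^(−1/(α−1))`, so α = 2 gives the classic Zipf rank
  law). The size-distribution parameterization was chosen because a
  literal rank exponent of 2 would hand one clone the majority of the
  repertoire, which is not what heavy-tailed repertoires look like; α
  defaults to 2 as a modeling choice, not an empirical claim. An optional
  dominant clone holds `dominant_clone_freq` of the repertoire (default
  0.12 for the PLHIV profile), mirroring the single conspicuous expansion
  many PLHIV repertoires carry.
- **Persistence.** Clone log-frequencies carry AR(1) noise with
  autocorrelation `persistence` (default 0.9; 1 freezes the composition)
  and stationary SD `freq_log_sd` (0.4). After the ART timepoint,
  log-weight deviations from the pool mean shrink by
  `post_art_contraction` (0.08) per timepoint — expansions contract
  gradually while remaining dominant — and `post_art_diversification`
  (0.05) × `n_clones` new naive-like clones enter per timepoint. Together
  these produce the observed ordering of depth-normalized clonality:
  pre-ART > post-ART > control.
- **Sequences.** CDR3 amino-acid lengths follow a discretized normal
  truncated to [6, 27] (control: mean 15, sd 2 — median 15; PLHIV: mean
  14.3, sd 1.6 — the shorter, narrower spectrum of antigen-experienced
  repertoires). Sequences run from the conserved cysteine to the
  conserved phenylalanine. A fraction `neighbor_rate` of clones (control
  0.35, PLHIV 0.15) is created as single-substitution variants of earlier
  clones: without this, independently random CDR3s would have essentially
  no edit-distance-1 neighbors and the network module would be
  vacuous. Each clonotype carries `1 + Poisson(convergence_rate − 1)`
  synonymous nucleotide variants produced by random back-translation
  through the standard genetic code (control 1.3, PLHIV 1.1 — controls
  show higher production efficiency).
- **Sampling.** Template counts are multinomial at
  `total_count_per_sample` (default 50,000, matching a typical targeted
  depth of 40,000–50,000 T-cell genomes).
- **Clinical trajectories.** Pre-ART viral load is uniform on
  10^4.5–10^5.5 copies/mL and steps down to the suppressed level
  (10^1.6) immediately at ART; CD4 recovers along a saturating
  exponential from 250 cells/µL toward a 650 cells/µL plateau at 0.35/yr
  — deliberately below the 700–1800 cells/µL normal range, since
  long-term cohorts frequently do not re-enter it.
- **Spiking.** `spike_public_clonotypes()` inserts annotated public
  clonotypes at a configurable frequency (default 10⁻³) into every
  repertoire of participants carrying the record's restricting allele,
  recording the ground-truth carrier map for closed-loop recovery tests.

The generator is deterministic: every draw derives from the master seed
via per-participant substreams, and a repertoire is bit-identical whether
generated standalone or inside a cohort (the per-participant stream
always draws the full maximum number of timepoints, so early timepoints
do not depend on how many are requested).

What the generator does **not** emulate: V(D)J recombination biases and
gene-segment-correlated sequence content (V/J calls are uniform draws),
HIV sequence evolution, cross-participant sequence sharing other than
explicit spikes (real public clonotypes arise spontaneously from
recombination convergence), sequencing error, and nonproductive
rearrangements (the readers and filters handle them; the generator emits
productive sequences only). Passing tests on synthetic cohorts therefore
demonstrates the correctness of the statistical machinery under the
stated model, not the biological fidelity of the model itself.

## Numerical and degenerate-input conventions

- All orderings (top-N selection, tie-breaks, table output) use
  radix/C-locale ordering with lexicographic tie-breaks, so results are
  platform- and locale-independent.
- `downsample()` at depth equal to the total count returns the input
  unchanged; a depth above the total is an error rather than a silent
  resample.
- Empty frequency vectors, all-zero counts, and repertoires without
  productive sequences raise errors rather than NaN.
- Unparseable HLA strings in annotation databases are kept with an empty
  allele and a warning (they can still match by sequence, but never pass
  the MHC filter); an unparseable allele in a *spike* record is an error,
  since the spike is defined by its restriction.
- Problem sizes in the test suite are scaled-down versions of the default
  profiles (hundreds to a few thousand clones, 10–20 repertoires per
  check); the defaults themselves (30 participants, 20,000–40,000
  clones, 50,000 templates) are the cohort conditions the generator is
  calibrated to, and the acceptance script exercises the control defaults
  at full depth with 20 repertoires.

## Known limitations

- The similarity score depends on repertoire richness; comparing
  repertoires summarized at different depths without the downsampling
  step will bias it. The pipeline always filters and, for summary
  statistics, depth-normalizes first.
- The degree-trend smoother is descriptive; no power-law vs exponential
  hypothesis test is performed, deliberately.
- The paired pre/post contrast uses one pre and one post sample per
  participant; it does not model within-participant correlation beyond
  pairing (no mixed-effects longitudinal model, by design).
- Candidate-public discovery is exact-match; convergent near-matches
  (one substitution away) are visible in the network module but are not
  merged into candidates.
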