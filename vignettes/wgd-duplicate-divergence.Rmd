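---
title: "Detecting retained WGD paralog pairs and quantifying their divergence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting retained WGD paralog pairs and quantifying their divergence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`wgdpairs` identifies paralog pairs retained from a whole-genome duplication
(WGD) in a transcriptome assembly and quantifies how the two copies of each
pair have diverged, in their coding sequences and in their expression. This
vignette is the package's account of the underlying methods: the models and
rules each stage implements, the assumptions they make, the tunable
parameters and their defaults, what the synthetic-data generator does and
does not emulate, and the numerical conventions adopted where the design was
genuinely open.

```{r setup}
library(wgdpairs)
```

## The pipeline and its assumptions

The analysis consumes four tabular inputs — coding sequences, an all-vs-all
protein similarity table, genomic placements of the genes on a reference,
and per-sample read counts with effective lengths — and proceeds through
stages that are each exposed as an ordinary function returning a tibble, so
any stage can be run, inspected, or replaced in isolation.
`run_wgd_pipeline()` chains them.

### Contig filtering

Assemblies contain fragments and noise, so contigs pass three pure
predicates before any pairing: length at least `min_len` (default 500 bp,
inclusive), expression of at least `min_fpkm` (default FPKM ≥ 1), and a
callable open reading frame of at least `min_codons` (default 100) in one of
the six frames. FPKM is `count · 1e9 / (length · total fragments)`.

Three conventions here were genuinely open:

* **Which samples the FPKM rule aggregates over.** "Expressed somewhere" can
  mean one sample, all samples, or the average. The default is the most
  permissive reading — FPKM ≥ 1 in *at least one* sample — because a gene
  expressed in a single tissue is still an expressed gene; `fpkm_rule =
  "all"` or `"mean"` select the stricter readings.
* **The ORF minimum.** 100 codons is the conventional default of standard
  transcript ORF callers. The finder is minimal by design: it reports the
  longest ATG-to-stop frame and does not score coding potential, so very
  short genuine genes and stopless fragments are out of scope.
* Filters are pure predicates, so the *retained set* is order-independent;
  only the per-stage counts in the report depend on the fixed order
  (length → expression → ORF).

### Duplicate detection: reciprocal second-best hits

In an all-vs-all search of a genome against itself, each gene's best hit is
itself, and — if the gene kept its WGD copy — the second-best hit is that
copy. Genes A and B are therefore paired when each is the other's best
*non-self* hit and both e-values are strictly below `evalue_max` (default
1e-10). Self hits are removed by identifier equality rather than by rank, so
the rule is unaffected by search tools that suppress self hits. Reciprocity
makes the output a matching: no gene appears in two pairs, which also means
members of larger gene families are paired with their closest relative only.
Ties in e-value are broken by descending bitscore and then by subject
identifier, and multiple HSPs for one query–subject combination collapse to
the lowest-e-value row, so the output is deterministic.

### Codon alignments and fourfold-degenerate sites

Peptides are aligned with Needleman–Wunsch global alignment under BLOSUM62
with affine gap penalties (`gap_open = 10`, `gap_extend = 1`; a gap run of
length L costs 10 + L). For a *pair* of sequences, progressive multiple
alignment reduces to exactly this pairwise problem, and a deterministic
dynamic program can be verified against an exhaustive enumeration oracle,
which the test suite does. The alignment is then back-translated: each
residue column is replaced by its source codon, each gap by `---`, after
verifying that every CDS translates exactly to its ungapped peptide
(terminal stop codons are stripped first, following the usual
back-translation convention).

A column yields a fourfold-degenerate (4D) site when both codons are
ungapped, their first two bases are identical, and that prefix is one of the
eight 4D families of the standard code (CTN, GTN, TCN, CCN, ACN, GCN, CGN,
GGN). Requiring the *shared* prefix is what makes "transversion per 4D site"
well defined for diverged pairs: if the prefixes differ, the degeneracy
class of the third position is ambiguous. Only the column itself must be
ungapped; no masking of neighbouring columns is applied.

### 4DTV and the multiple-hit correction

The raw 4DTV of a pair is the proportion *q* of its 4D sites whose third
bases differ by a transversion (purine ↔ pyrimidine). Transversions are the
minority of substitutions, so back-mutations at these sites are rare and the
statistic remains informative at ages where total synonymous divergence
saturates. The raw proportion is corrected for multiple hits with the
two-state Kimura form

$$\mathrm{4DTV} = -\tfrac{1}{2}\,\ln(1 - 2q),$$

the purine/pyrimidine analogue of the Jukes–Cantor correction: monotone,
at least `q`, tending to `q` as `q → 0`, and undefined at `q ≥ 0.5`
(such pairs are flagged `saturated` and never classified as WGD-retained).
The correction sits behind a single function (`correct_4dtv()`, with inverse
`uncorrect_4dtv()`), and `pair_divergence(correction = ...)` accepts any
replacement, so a different multiple-hit model can be swapped in without
touching the rest of the pipeline.

### Classification: the 4DTV window and the tandem rule

WGD events leave a peak in the 4DTV distribution; pairs inside a window
around the peak (default [0.04, 0.2], endpoints inclusive) are taken as
candidates from that WGD. Peak detection is deliberately **not** automated:
the window is a parameter, and `dtv_histogram()` / `plot_dtv_distribution()`
exist precisely so users choose it from their own distribution.

Pairs whose members lie close together on one chromosome are more likely
tandem duplicates than WGD remnants. The rule: same chromosome and an
interval gap (end of the upstream gene to start of the downstream gene)
strictly below `tandem_max_dist` (default 100 kb). The gap — rather than a
midpoint or start-to-start distance — is the conservative reading of
"within 100 kb of each other": it is the smallest of the candidate distance
definitions, so it flags a superset of what the others would flag. Pairs
with unplaced members cannot be tested and are noted `unplaced` (not
tandem); they are likewise excluded from the denominator of the
chromosome-pairing summary.

The cascade is count-conserving — candidates = out-of-window + saturated +
in-window, and in-window = tandem + WGD-retained — which the tests assert
exactly.

### Ka/Ks by the NG86 counting method

Selective constraint is estimated with the Nei–Gojobori (1986) counting
estimator rather than a maximum-likelihood codon model. The choice is
deliberate: NG86 is fully specified by elementary rules, deterministic, and
checkable against a brute-force oracle, and the scientific inference it
supports here (ω ≪ 1 ⇒ purifying selection) is robust to the estimator.
Conventions, all verified against an independent pathway-enumeration oracle
in the tests:

* Site counts: for each codon position, the three single-nucleotide
  neighbours are enumerated; mutations to stop codons are excluded from both
  numerator and denominator, and each position contributes one site split
  between synonymous and nonsynonymous fractions. Site totals are averaged
  over the two sequences.
* Differences: for codons differing at 2 or 3 positions, all substitution
  orderings are enumerated, orderings passing through a stop codon are
  dropped, and synonymous/nonsynonymous step counts are averaged over the
  rest with equal weight. In the degenerate case where *every* ordering is
  blocked by stops, each differing position is classified against the first
  codon's background, with a warning.
* Correction: Jukes–Cantor, `d = −¾ ln(1 − 4p/3)`; proportions at or above
  3/4 are flagged `saturated`. ω is `NA` when Ks is 0 or undefined —
  an honest "no information" rather than an infinity.

On a one-codon alignment a single synonymous difference gives a synonymous
proportion above 3/4, so Ks saturates by construction; such degenerate
inputs are flagged, not silently dropped.

### Expression divergence

TPM is computed from counts and effective lengths
(`tpm = (count/len) / Σ(count/len) · 1e6`; per-sample sums are exactly one
million). A copy is *expressed* in a tissue × genotype condition when its
mean TPM over that condition's replicates is strictly above
`tpm_threshold = 1`. Each pair's two tissue sets then determine its
partitioning class (both tissues, one shared tissue, confined together to
one tissue, reciprocally partitioned, one silent, both silent) — the
expression analogue of subfunctionalization.

Copy-vs-copy differential expression is tested per condition with an exact
conditional negative-binomial test, the two copies playing the role of the
two groups: counts are normalized to a common (geometric-mean) library size,
a single common dispersion is estimated across all pairs and conditions by
conditional maximum likelihood (or fixed via `dispersion`, which makes runs
exactly reproducible), the two group sums are conditioned on their total,
and the p-value is the total probability of all splits at most as probable
as the observed one. As dispersion → 0 this reduces to an exact binomial
split test, which is the oracle the tests use; at positive dispersion it
matches the small-p exact test of the standard count-data DE framework,
cross-checked in the suite. Multiple testing is controlled per condition
with Benjamini–Hochberg (FDR ≤ 0.05) — the default FDR procedure, applied
across pairs within one tissue × genotype. Fold changes are
`log2((mean_b + 0.5)/(mean_a + 0.5))` on normalized means; the 0.5
pseudo-count avoids division by zero and is configurable. |log2 FC| is
binned at 0.4 / 2 / 8 with left-closed intervals ([0, 0.4) low, [0.4, 2)
mid, [2, 8) high, [8, ∞) extreme); the cut points are the conventional
descriptive boundaries and the left-closed choice is this package's fixed
convention at the boundaries.

### Association and GO enrichment

Spearman rank correlation (average ranks for ties) relates a per-pair
expression-divergence metric — |log2 FC| by default; the FDR or signed FC by
option, since which quantity best represents "differential expression" is a
user choice — to each sequence-divergence measure per condition. P-values
use the exact null distribution where available (no ties) and the
large-sample approximation otherwise.

Annotations are transferred from a reference proteome by single best hit
with e-value < 1e-10 *and* bitscore > 40 (both strict), ties broken by
bitscore then subject id. Enrichment per GO term uses the one-sided Fisher
exact test (hypergeometric upper tail) with BH correction across terms, and
`overrepresented` means adjusted p ≤ 0.05. The 2×2 margin is test set vs
reference *minus* test set by default: disjoint margins keep the table
well-defined; `mode = "inclusive"` keeps the test genes in the reference
margin for compatibility with tools that do. Genes (copies) are the unit of
enrichment, since annotation is per gene; a pair contributes both copies.
No GO-graph ancestor propagation is performed — term sets are used exactly
as given.

## The synthetic-data generator

Every stage above is verified against planted ground truth produced by
`simulate_study()`. The generator emulates the *inputs* of a WGD
retention study, not its raw data: no reads, no assembly.

**Sequences.** Each pair starts from a random ancestral CDS (ATG start, no
internal stops, terminal stop; length uniform in `n_codons_range`). Codon
prefixes (positions 1–2) and non-4D third positions evolve independently in
each copy under a kappa-weighted single-nucleotide process: a proposal is a
transition with probability κ/(κ+2), otherwise one of the two transversions;
proposals creating stops are always rejected; nonsynonymous proposals are
accepted with probability `nonsyn_rate_scale`, which is what gives planted
pairs a tunable true Ka/Ks. Third positions of columns that retain an
identical 4D prefix in both copies are handled differently: the generator
plants **exactly** `round(rate · n4D)` transversions (and `round(rate·κ/2 ·
n4D)` transitions) at randomly chosen sites, each in a randomly chosen copy.
Planting a fixed count rather than per-site Bernoulli events removes the
binomial noise (standard deviation ≈ 0.02–0.04 at realistic gene lengths)
that would otherwise scatter measured 4DTV around its target; with exact
planting, each pair's raw 4DTV equals its target up to `0.5/n4D`, so pairs
planted inside the classification window are *recoverable* — the property
the generator exists to provide. All planted third-position changes in 4D
families are synonymous and cannot create stops.

**Placement.** WGD pair members go to two distinct chromosomes (19 by
default, the willow/poplar karyotype); tandem members to one chromosome at
an interval gap of `tandem_distance_bp` (default 50 kb, inside the 100 kb
rule); singletons anywhere. Genes never overlap.

**Counts.** Per gene and replicate, counts are negative-binomial with mean
`mean_expression · (length/1 kb) · baseline · 2^(±fc/2)`, where the
lognormal baseline is shared by the two copies of a pair (so `fc = 0` pairs
have identical expected counts) and the planted log2 fold change `fc` is
split evenly between the copies. Effective length equals CDS length —
fragment-length corrections belong to quantification tools, not to this
model, and TPM algebra is unaffected. A fraction `fraction_de_pairs` of
pairs receives a nonzero effect, |fc| ~ N(`fc_log2_mean`, `fc_log2_sd`) with
random sign.

**Hits, annotations, truth.** The hit table contains a top-scoring self hit
per gene and mutual sub-self hits for pair members far below the pairing
threshold; optional decoys at e-value 1e-5 exercise the threshold. Both
copies of a pair share one random GO term set (the annotation symmetry seen
in low-divergence duplicates); annotation is independent of expression
effects, so enrichment analyses on simulated data have a true null. A fixed
`seed` makes every output byte-identical.

### Defaults as study conditions

The defaults describe a plausible two-tissue, two-genotype study of a
post-WGD plant transcriptome and are fixed once:

| parameter | default | rationale |
|---|---|---|
| `branch_transversion_rate` | 0.10 | centre of the classic WGD 4DTV peak |
| `ts_tv_ratio` (κ) | 2 | typical plant nuclear transition bias |
| `nonsyn_rate_scale` | 0.23 | matches the mean Ka/Ks reported for retained WGD pairs |
| `n_codons_range` | 200–500 | 0.6–1.5 kb CDS, the realistic plant range |
| `n_chromosomes` | 19 | willow/poplar karyotype |
| `tandem_distance_bp` | 50,000 | comfortably inside the 100 kb rule |
| `conditions` | leaf/root × two genotypes, 5/5/4/4 replicates | the sequenced design of a two-genotype leaf/root study |
| `nb_dispersion` | 0.05 | conventional for biological replicates of clonal genotypes; no empirical estimate exists for this design |
| `mean_expression` | 500 | comfortably measurable counts per kb |
| `fraction_de_pairs`, fc | 0.74, \|fc\| ~ N(1.2, 0.6) | most pairs differentially expressed, mostly at modest fold changes |

Two estimator-side notes. First, NG86 assumes no transition/transversion
bias when counting sites, so under κ > 1 it is known to push ω below 1 even
for neutral evolution; the neutrality-recovery property test therefore runs
the generator at κ = 1 (testing the estimator under its own model), while
the default κ stays 2 (realistic data). Consequently the mean ω recovered
from default simulations (≈ 0.19) sits slightly below the planted
acceptance scale of 0.23 — an expected, documented estimator bias, not a
defect. Second, `branch_transversion_rate` is specified on the *raw* scale;
to plant pairs whose **corrected** 4DTV hits a target, pass
`uncorrect_4dtv(target)`, which is how the test suite plants pairs across
the full window-age span.

### What passing tests do and do not show

The generator produces clean, gapless orthologous structure: no indels, no
assembly chimeras or fragmented contigs, no isoforms, no allele-specific
expression, no gene families beyond pairs, no GC or codon-usage bias, and a
single common count dispersion. Tests passing on it therefore demonstrate
that the *rules and estimators are implemented correctly* — recovery is
exact where it should be exact, calibrated where it should be calibrated —
not that real assemblies will behave as cleanly. On real data, fragmented
contigs weaken the reciprocal-best matching, alignment error adds noise to
4DTV, and tagwise dispersion variation makes the common-dispersion DE test
anticonservative for high-dispersion genes.

## Numerical conventions and degenerate inputs

* Coordinates are uniformly 0-based half-open internally; GFF3 input is
  converted on read. A single convention avoids off-by-one errors in the
  100 kb rule.
* Window endpoints are inclusive; "within 100 kb" is strict. Both documented
  and configurable.
* Alignment ties among co-optimal alignments are resolved by the dynamic
  program deterministically; only the score is contractual (and
  oracle-tested), not the realized gap placement.
* Zero 4D sites → 4DTV undefined (flagged, not 0). Raw 4DTV ≥ 0.5 →
  correction undefined, pair flagged `saturated`. Zero counts for both
  copies → p = 1, log2 FC = 0. All-zero samples → TPM `NA` with a warning.
* The exact NB test compares split probabilities with a 1e-10 relative
  tolerance when collecting "at most as probable" outcomes, guarding against
  ties lost to floating-point rounding.
* The common-dispersion search is a one-dimensional conditional-likelihood
  optimization on log scale over [1e-6, 5].

## Limitations

* Pairing cannot see families: a gene with two surviving WGD copies is
  paired with the closer one only.
* The 4DTV window is a user decision guided by the histogram; nothing dates
  the peak formally (no mixture model).
* NG86 with equal pathway weighting underestimates ω under strong transition
  bias; for publication-grade selection inference on real data, confirm with
  an ML codon model. A hook for ingesting externally computed estimates is
  the `correction`/tibble-in, tibble-out design of `pair_divergence()` — any
  per-pair table with the same columns can replace it downstream.
* The DE test uses one common dispersion; no tagwise/trended shrinkage, no
  GLM designs.
* GO enrichment treats term sets as flat labels (no DAG propagation).

## Problem sizes used in the checks

The shipped verification suite runs entirely on synthetic data at sizes
chosen to exercise every rule while staying quick on one CPU: 500 random
50-codon pairs for the Ka/Ks oracle equivalence, 200 pairs of ~300 codons
for 4DTV recovery (plus 34-pair batches planted across the window span),
one 100/20/200-gene end-to-end study, 200 short-peptide alignment oracle
comparisons, and 2,000 null plus 100 powered pairs for DE calibration. The
acceptance script (`scripts/acceptance.R`) re-runs the same computations
from scratch under a user-supplied seed.
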