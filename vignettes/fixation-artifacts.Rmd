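---
title: "Models and methods: fixation artifacts in matched tumour sequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: fixation artifacts in matched tumour sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

fixsig analyses matched tumour samples — the same lesion split and
preserved as snap-frozen (SF), methanol-fixed (UMFIX) and formalin-fixed
(NBF) material — to separate genuine somatic mutation from
fixation-induced sequencing artefact. This vignette is the package's
methods account: the models, their assumptions, every tunable that
matters, and the numerical choices behind the implementation.

## 1. Mutation catalogs

The unit of observation is a *non-reference base change*: any
read-supported substitution at a reference position, artefacts included.
Presence in a sample means at least one row for that (chrom, pos, ref,
alt) key; no VAF or depth gate is applied (a minimum-support option exists
but defaults to off). Counting keeps multiplicity — one input row is one
observed change event — while the common/unique partition works on
distinct keys per sample, since the raw data leave open whether
occurrences or loci were tallied upstream.

Changes matching a germline blacklist key are removed first. Each
remaining change is annotated with its reference trinucleotide; changes at
a contig edge or with a non-ACGT base in the window cannot be annotated
and are dropped and counted. Purine-centred changes are
reverse-complemented so that every change lands in one of 96 channels (6
pyrimidine substitution classes x 16 flank pairs, lexicographic within
class). The channel order is frozen so catalogs are byte-comparable.

Per patient, a change key seen in *every* sample is `common`; seen in
exactly *one* sample it is unique to that sample's fixative; keys in a
strict subset of two or more samples are `unassigned` and excluded from
category analyses — the category scheme models only the two clean
hypotheses (true somatic vs single-fixative artefact). Biopsy and surgical
samples of one fixative count as separate samples in this partition.

## 2. Signature deconvolution

Catalogs are factorized as `V ~ W H` with `W >= 0` column-normalized and
`H >= 0`, minimizing the generalized Kullback–Leibler divergence
`D(V||WH) = sum(v log(v/x) - v + x)` — the Poisson log-likelihood, the
natural objective for count catalogs (a Frobenius option is deliberately
not offered; counts here are small and skewed). Multiplicative updates are
used with `0 log 0 = 0` handled natively (no pseudo-count); zeros in `V`
propagate to structural zeros in the factors within one update, so
channels absent everywhere get exactly zero weight. Denominators are
guarded at `1e-16`. The divergence trace is recorded every iteration; the
updates are monotone and the test suite asserts non-increase on every
fitted matrix. Defaults: `n_restarts = 20` random initializations
(distinct sub-seeds), `max_iter = 5000`, relative-change tolerance
`1e-8`; the best restart by final divergence wins, and components are
ordered by descending total exposure for reproducible reports.

**Rank selection.** For each candidate K the catalog columns are
bootstrap-resampled (multinomial per column, preserving column totals),
each replicate factorized from a *single* random start, all bootstrap
signatures pooled and clustered into K groups by cosine distance
(partitioning around medoids). The stability of K is the **minimum**
cluster-average silhouette, not the pooled mean: a rank is only as stable
as its least reproducible signature, and on rank-3 data the pooled mean
stays above 0.85 at K = 4–5 because three strong clusters mask one
irreproducible component. Single-start bootstrap fits are likewise
deliberate — extra restarts would let an overfitted component converge to
the same residual direction of the one observed catalog in every
replicate, hiding its irreproducibility (and cost more). K = 1 is defined
as perfectly stable. The selected rank is the largest K with stability at
or above the threshold (default 0.8); if none qualifies, the most stable K
wins, smaller on ties. Reconstruction divergence per K is reported
alongside.

**Matching and refitting.** Fitted signatures are matched to reference
profiles by maximizing total cosine similarity over one-to-one
assignments (Hungarian algorithm, implemented natively; a brute-force
permutation oracle checks it in the tests). The packaged reference TSV
contains *synthetic* profiles — a CpG C>T deamination-like probability
vector and a flat background — constructed in-repo as stand-ins, not
measured human signatures; users supply their own for real work. Category
catalogs are decomposed against a fixed `W` by H-only multiplicative
updates, reported as counts and per-column proportions.

## 3. Copy number

Bin counts are median-normalized: `logratio = log2(count/median)` over
un-masked bins, zero-count bins masked and the median recomputed.
Concordance between two samples is Spearman's rho on jointly un-masked
*bin-level* log-ratios (bin level is stricter than segment level and
matches profile-vs-profile comparison; segment-level rho can be computed
from the segment tables if wanted). The headline comparison counts, per
patient and sample type, whether rho(UMFIX, SF) exceeds rho(NBF, SF);
ties count as non-superior and are reported separately.

Segmentation is recursive binary splitting on the maximal two-sample t
statistic, accepted when a permutation p-value (default 1000 permutations,
seeded) is below `alpha = 0.01`, then segments shorter than `min_bins = 3`
are merged into the neighbour with the closer mean. Two numerical choices
matter:

* *Degenerate splits.* A split with (numerically) zero within-segment
  variance on both sides and distinct means has an infinite t statistic
  and is accepted without the permutation gate. On a handful of bins no
  permutation test can reach a useful level (a perfect 3|3 step has a
  minimal achievable two-sided p of 0.1), yet the split is certain; this
  rule makes noiseless recovery exact, which the tests verify exhaustively
  for all step positions up to 30 bins. The degeneracy threshold is
  relative to the data's mean-square scale, because catastrophic
  cancellation in the cumulative sums can otherwise turn an exact step
  into a merely large finite statistic that the permutation gate then
  wrongly rejects.
* *Per-segment variance* is the unbiased variance of the member bins'
  log-ratios within each sample's own segmentation — the most direct
  reading of "variance per copy-number segment"; variance around the
  matched SF segment means would answer a subtly different question.

No GC/mappability correction is applied (the synthetic data has neither);
the normalization accepts per-bin weights so real-data corrections can
plug in upstream.

## 4. SNV evaluation

With a finite assayed panel the confusion matrix is well defined per
position: TP = call matching a true variant in position and alleles, FN =
missed true variant, and specificity is per assayed position —
`TN = |assayed non-variant positions| - FP` with every non-matching call
charged against that denominator, so the identities `TP + FN = |truth|`
and `FP + TN = |non-variant positions|` hold on any input (fuzz-tested).
Group summaries are means of per-sample proportions with
`mean ± t(0.975, n-1) sd/sqrt(n)` intervals — an interval on the *mean
across samples*, chosen over pooled binomial intervals because samples,
not positions, are the replication unit; single-sample groups report the
point estimate with the CI flagged unavailable.

## 5. qPCR quality metrics

ΔCq = sample Cq − control Cq for the 90 bp amplicon measures amplifiable
yield (reports may display the negated value; storage never negates).
DNA integrity is the Q-ratio `(1+E)^(Cq_41 - Cq_long)` for 129 and 305 bp
amplicons; amplification efficiency `E` defaults to 1 (kit standard
curves are typically unavailable; the ordering of groups is unaffected,
only the absolute scale). Group comparisons use the Wilcoxon rank-sum
test, unpaired, two-sided, with significance stars at 0.05/0.005/0.0005.
The rank-sum statistic is the sum of x-ranks with average-rank ties; the
p-value is exact — from the full null distribution computed by the
classical shift algorithm — when the pooled sample has at most 12
observations and no ties, otherwise a normal approximation with tie and
continuity corrections. Exhaustively at the first size past the exact
branch (n = 13), the approximation deviates from enumeration by at most
0.0135. Null calibration at nominal 0.05 sits in the conservative half of
[0.03, 0.07] (the continuity correction costs a little power).

## 6. The synthetic cohort generator

The generator emulates the matched-triplet study design with planted,
recoverable ground truth. The default preset:

| parameter | default | rationale |
|---|---|---|
| patients / sample types | 12, biopsy + surgical | matched design, 72 samples |
| fixatives | SF, UMFIX, NBF | ordered by expected quality |
| planted signatures | 2 noise + 1 CpG-deamination-like | disjoint supports, see below |
| noise mixture per fixative | SF 0.9/0.1, UMFIX 0.5/0.5, NBF 0.1/0.9 | identifiability, see below |
| burden (common, unique) | 1000, 1000 expected changes | ~2000 changes per catalog column |
| burden dispersion | log-normal, sdlog 1.0, mean-preserving | realistic burden spread |
| reference | 500 kb random, all 32 contexts guaranteed | desk-scale stand-in for a genome |
| CN bins / segments / states | 250 / 6 / 1–4 | desk-scale stand-in for genome-wide sWGS |
| CN noise sd (log2) | SF 0.10, UMFIX 0.15, NBF 0.30 | the fixative ordering under study |
| read depth per neutral bin | 500 | Poisson noise well below the planted sds |
| qPCR means | see `sim_config()` | SF ≈ UMFIX at 90 bp; NBF worst, gap growing with length |
| SNV sensitivity / FP rate | 0.95/0.95/0.85, 0.002/0.002/0.01 | NBF-depressed calling |

Changes are placed by rejection sampling from a precomputed index of
reference positions per trinucleotide context, so every emitted change
re-annotates to exactly the channel it was drawn from; positions are
unique within a patient, making the ground-truth labels exact (a common
change is in all of a patient's samples, a unique change in exactly one).
Counts are Poisson around the (dispersed) burdens. Copy-number counts are
Poisson around `depth x state/2 x 2^eps` with Gaussian log2-ratio noise
`eps`; a fixative with sd exactly 0 emits deterministic expected counts —
the exact noiseless limit used by the validation tests.

Two generator choices deserve their reasoning spelled out, because they
are what make planted-signature recovery *possible*, not merely convenient:

* *Near-extreme noise mixtures.* With two noise signatures, every
  fixative's mixture lies on the same line segment between them. If all
  three mixtures are interior (e.g. 0.3/0.7-style), the extreme rays of
  the nonnegative cone spanned by the data are the fixative *blends*, and
  no exact NMF of any rank can return the planted profiles — recovery is
  unidentifiable in principle, not merely hard. Near-extreme weights mean
  each noise process appears nearly pure in one fixative, which is the
  identifiable regime. Scientifically this asserts that each fixative's
  artefact load is dominated by its own chemistry, the hypothesis the
  category analysis is designed to expose.
* *Burden dispersion.* With flat burdens every catalog column has the
  same ~50/50 common/noise composition, and the same unidentifiability
  reappears through the back door (every column contains the common
  signature in the same proportion). Real cohorts show order-of-magnitude
  spread in mutation burden and artefact load; the mean-preserving
  log-normal multipliers (sdlog 1) reproduce that spread and give the
  factorization the near-pure columns separability requires.

What the generator does **not** model — and what passing tests therefore
do not establish about real data: overlapping signature supports (real
signatures share channels heavily; recovery there is harder than here),
sequencing-error base-quality structure, read-level artefacts (no
FASTQ/BAM), tumour purity and subclonality, GC/mappability waves in
coverage, overdispersion beyond Poisson in bin counts, and qPCR
efficiency drift. The blacklist is built from known keys plus decoys, so
filtering is exercised with exact ground truth rather than population
allele frequencies.

## 7. Problem sizes used by the tests and acceptance script

The checked-in suite runs the full preset where the claim depends on it
and scales the algorithmic knobs, not the study conditions: signature
recovery and rank selection use 10 cohorts at the default preset with 4
NMF restarts (12 single-start bootstraps, K in 1..5) — the recovery
statistic is the per-cohort *minimum* matched cosine, summarized by its
median; copy-number claims use 20 cohorts of 20 patients (segment
variances pooled from 5 of them, 150 permutations per split); Wilcoxon
exactness is exhaustive for all pooled sizes up to 8 and the type-I rate
uses 2000 null replicates; the segmentation oracle is exhaustive over all
step positions up to 30 bins. `scripts/acceptance.R` recomputes the same
quantities from scratch at a caller-supplied seed.

## 8. Known limitations

Rank selection clusters bootstrap signatures from a single observed
catalog, so it measures reproducibility against resampling noise, not
against fresh cohorts; the minimum-silhouette statistic guards the common
failure (a stable-looking mean hiding one unstable component) but cannot
rescue a preset whose signatures genuinely overlap. The Hungarian matcher
assumes signatures are comparable by cosine alone. The CBS variant here
is plain (non-circular) recursive splitting; on profiles whose first and
last segments share a state, a circular test would have slightly more
power. Exposure refitting against a misspecified `W` redistributes mass
silently — proportions should be read jointly with the reconstruction
divergence the fit reports.
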