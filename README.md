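# fixsig

Quantifying how tissue fixation distorts tumour DNA sequencing, from
matched per-patient samples.

## The problem

Precision-oncology workflows need high-quality tumour DNA, but the routine
pathology archive is formalin-fixed (NBF), which fragments DNA and induces
artefactual base changes (classically C>T from cytosine deamination).
Methanol-based fixation (UMFIX) is a proposed middle ground between
snap-frozen tissue (SF, the gold standard) and formalin. To compare
fixatives rigorously one profiles *matched* samples — the same tumour
split three ways — and asks, per assay:

* **Sequencing noise.** Collect every non-reference base change observed in
  the data (not just called variants), remove known germline positions,
  annotate each change with its reference trinucleotide context, collapse
  to the 96 pyrimidine-centric channels, and deconvolve the resulting
  catalogs by non-negative matrix factorization (NMF):

  `V (96 x n) ~ W (96 x K) . H (K x n)`,  W, H >= 0,

  minimizing the generalized Kullback–Leibler divergence (the Poisson
  likelihood for count catalogs). Columns of `W` are *signatures*
  (probability vectors over channels), `H` holds *exposures* (expected
  change counts). Partitioning changes into those **common** to all of a
  patient's samples versus **unique** to one fixative separates true
  somatic mutation (CpG C>T deamination-like) from fixation/processing
  noise.
* **Copy number.** Shallow WGS read counts per genomic bin are
  median-normalized to `log2` ratios, segmented (recursive binary splitting
  on the two-sample t statistic with a permutation gate), and compared
  against the matched SF profile by Spearman's rho; per-segment variance
  measures noise.
* **SNV calling.** Call sets from an amplicon panel are scored against a
  curated truth set — sensitivity `TP/(TP+FN)` and per-assayed-position
  specificity `TN/(TN+FP)` — summarized per fixative with t-based 95%
  confidence intervals.
* **DNA quality.** qPCR quantification cycles for 41/90/129/305 bp
  amplicons give the yield metric ΔCq (sample − control) and the integrity
  Q-ratio `(1+E)^(Cq_41 − Cq_long)`; groups are compared with Wilcoxon
  rank-sum tests (exact by enumeration for small samples).

Because the patient data behind this design are not publicly deposited,
the package ships a first-class synthetic-cohort generator that emulates
the study: matched biopsy/surgical triplets per patient, shared somatic
changes drawn from a planted CpG-deamination-like signature, fixative-
specific noise from planted artefact signatures, a shared copy-number
truth observed with fixative-ordered noise (SF < UMFIX < NBF), and Cq
tables encoding fragment-length-dependent loss. Every analysis stage can
therefore be validated against known ground truth.

## Worked example

```r
library(fixsig)

cohort  <- simulate_cohort(sim_config(seed = 1))
kept    <- filter_blacklist(cohort$changes, cohort$blacklist)
catalog <- build_catalog(kept, cohort$reference)
dim(catalog)
#> [1] 96 72

fit <- nmf_factorize(catalog, K = 3, n_restarts = 4, max_iter = 3000,
                     tol = 1e-7, seed = 1)
fit
#> KL-NMF signature fit: K = 3 | divergence = 1957.68 | 1782 iterations (converged)

match_signatures(fit$W, reference_signatures())$assignment
#> # A tibble: 2 × 3
#>   signature reference            cosine
#> 1 S1        cpg_deamination_like  0.966
#> 2 S2        flat_background       0.443
```

The dominant fitted signature is the CpG C>T deamination-like profile.
Decomposing the per-category catalogs (changes common to all of a
patient's samples vs unique to one fixative) shows the deamination
signature confined to the common category, while the fixative-unique
categories are mixtures of the two noise signatures:

```r
catc <- build_category_catalog(cohort$changes, cohort$reference, cohort$blacklist)
round(estimate_exposures(catc, fit$W, seed = 1)$proportions, 3)
#>    common NBF-unique SF-unique UMFIX-unique
#> S1      1      0.000     0.000         0.00
#> S2      0      0.083     0.939         0.51
#> S3      0      0.917     0.061         0.49

concordance_summary(cohort$cn$counts)$summary
#> # A tibble: 2 × 4
#>   sample_type n_pairs umfix_superior  ties
#> 1 biopsy           12              9     0
#> 2 surgical         12             12     0
```

So in 9 of 12 biopsies and 12 of 12 surgical samples the UMFIX profile
correlates better with the matched snap-frozen profile than the NBF one
does. DNA-integrity Q-ratios for the 305 bp amplicon separate all three
fixatives sharply, and SNV sensitivity is depressed for NBF only:

```r
qc <- qc_report(cohort$qpcr, cohort$config$qpcr_control_cq)
qc$tests[qc$tests$metric == "q_ratio_305_41", ]
#>   metric         group_a group_b statistic       p_value stars
#> 1 q_ratio_305_41 SF      UMFIX         866 0.0000000105  ***
#> 2 q_ratio_305_41 SF      NBF           876 0.00000000306 ***
#> 3 q_ratio_305_41 UMFIX   NBF           876 0.00000000306 ***

ev <- evaluate_cohort_calls(cohort$snv$calls, cohort$snv$panel, cohort$snv$truth)
summarize_by_fixative(ev)[, c("fixative", "metric", "mean", "ci_lo", "ci_hi")]
#>   fixative metric       mean ci_lo ci_hi
#> 1 NBF      sensitivity 0.858 0.810 0.906
#> 2 NBF      specificity 0.991 0.989 0.994
#> 3 SF       sensitivity 0.971 0.951 0.990
#> 4 SF       specificity 0.997 0.996 0.998
#> 5 UMFIX    sensitivity 0.962 0.935 0.990
#> 6 UMFIX    specificity 0.998 0.997 0.999
```

`plot_signatures()`, `plot_exposures()`, `plot_cn_profile()`,
`plot_qc_metrics()` and `plot_eval_summary()` produce the corresponding
ggplot figures; fitted objects support `tidy()` and `glance()`.

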