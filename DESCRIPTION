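Package: fixsig
Title: Fixation-Artifact Analysis for Matched Tumour Sequencing Samples
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify how tissue fixation (snap-frozen, methanol-based
    UMFIX, neutral-buffered formalin) distorts DNA sequencing results in matched
    tumour samples. Builds blacklist-filtered, strand-collapsed 96-channel
    trinucleotide mutation catalogs from observed non-reference base changes,
    deconvolves them into noise signatures by Kullback-Leibler non-negative
    matrix factorization with bootstrap rank selection and Hungarian matching
    to reference profiles, scores shallow whole-genome copy-number concordance
    against the snap-frozen gold standard via median-normalized log-ratios,
    native circular binary segmentation and Spearman correlation, evaluates SNV
    call sets against curated truth sets (sensitivity/specificity with t-based
    confidence intervals), and computes qPCR DNA-quality metrics (delta-Cq,
    amplicon-length Q-ratios) with exact/approximate Wilcoxon rank-sum tests.
    A deterministic synthetic-cohort generator emulates matched per-patient
    fixative triplets with planted trinucleotide signatures, shared copy-number
    truth with fixative-ordered noise, and fragment-length-dependent qPCR yield.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    cluster,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
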