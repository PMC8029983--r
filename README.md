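# melatomics

Pan-cancer multi-omics integration of the melatonergic gene panel.

Melatonin signalling is carried by a 12-gene panel — membrane receptors
(*MTNR1A*, *MTNR1B*, *GPR50*), nuclear receptors (*RORA*, *RORB*,
*RORC*), intracellular binders (*CALM1*, *NQO2*), synthesis (*ASMT*) and
metabolism (*CYP1A1*, *CYP1A2*, *CYP1B1*) — and its disturbance in
tumors is usually assessed separately on microarray and RNA-seq cohorts,
which do not always agree. `melatomics` is for analysts who want a
single, reproducible pipeline that scores tumor-versus-normal
differential expression on **both** platforms, integrates the calls into
one consensus status, and relates that status to methylation, mutation,
copy-number, survival, progression and pathway layers. A seeded
synthetic multi-omics cohort generator makes every stage testable
without access to controlled consortium data.

## The core score

Each platform yields a signed status per gene: ±1 for a significant
call (BH FDR < 0.05; pooled-variance *t* on log2 array intensities, a
conditional negative-binomial exact test on TMM-normalized counts) and
±0.5 for a non-significant trend in that direction. The integrated
status is the sign-gated sum

    S = s_array + s_seq   if sgn(s_array) = sgn(s_seq)
    S = 0                 otherwise

so S ∈ {−2, −1.5, −1, 0, 1, 1.5, 2}: |S| = 2 means both platforms
significant and concordant; |S| = 1.5 is one significant call backed by
a same-direction trend; any direction conflict collapses to 0.

Around the score, the package provides gene-level methylation
consistency calls (all CpG sites significant in one direction; mixed
directions exclude the gene), alteration-frequency summaries with
expression-consistency flags, Kaplan-Meier / log-rank / Cox (Efron
ties) survival stratification including mutation-by-expression
subgroups, metastasis (N+M+ vs N0M0) and stage (ANOVA + Tukey,
early-vs-late) comparisons, and anchor-gene Pearson screening with
hypergeometric pathway enrichment. See the methods vignette
(`vignettes/melatomics-methods.Rmd`) for models, assumptions and every
tunable parameter.

## Worked example

Simulate a cohort at the default study conditions (30 tumor / 30 normal,
2000 genes here reduced to 500, 10% planted effects of 2 log2 units, a
planted hazard ratio of 2 on *RORA*), then score the panel:

```r
library(melatomics)

cfg <- cohort_config(n_tumor = 30, n_normal = 30, n_genes = 500,
                     hr_genes = c(RORA = log(2)), seed = 42)
co  <- simulate_cohort(cfg)

nf   <- tmm_factors(co$expression$counts)
de_a <- array_ttest_de(co$expression$array, co$expression$groups)
de_s <- count_nb_de(co$expression$counts, nf, co$expression$groups)
status_table(de_a, de_s,
             genes = intersect(unname(melatonergic_genes()), de_a$gene))
#>      gene s_array s_seq  S
#> 1  MTNR1A     0.5   0.5  1
#> 2  MTNR1B     0.5   0.5  1
#> 3   GPR50    -0.5   0.5  0
#> 4    RORA     0.5   0.5  1
#> 5    RORB    -0.5   0.5  0
#> 6    RORC    -0.5  -0.5 -1
#> 7   CALM1     1.0   1.0  2
#> 8    NQO2    -0.5  -0.5 -1
#> 9    ASMT    -0.5   0.5  0
#> 10 CYP1A2     0.5   0.5  1
#> ...
```

In this cohort only *CALM1* carries a planted effect among the panel
genes (direction +1 on both platforms), and it is the one gene reaching
S = 2 — both platforms significant and concordant. Genes such as
*GPR50* or *CYP1A1* show opposite noise trends on the two platforms and
are zeroed out by the sign gate; the remaining ±1 values are concordant
trends that never reach significance on either platform.

Survival on the planted prognostic gene:

```r
cl  <- co$clinical[co$clinical$group == "tumor", ]
x   <- as.numeric(scale(co$expression$array["RORA", cl$sample_id]))
cox_fit(matrix(x, ncol = 1, dimnames = list(NULL, "RORA")),
        cl$os_time, cl$os_event)[, c("hr", "lower", "upper", "p")]
#>      hr lower upper     p
#> 1 2.665 1.516 4.686 0.001

logrank(cl$os_time, cl$os_event,
        median_dichotomize(co$expression$array["RORA", cl$sample_id]))$p
#> [1] 0.0056
```

The univariate hazard ratio per standardized expression unit is
estimated at 2.67 (95% CI 1.52-4.69) against a planted value of 2 — at
n = 30 the interval is wide but covers the truth — and the median-split
log-rank confirms the stratification (p = 0.0056).

The same analyses, plus methylation, multi-omics consistency,
progression, enrichment and miRNA stages, run end-to-end from a config:

```r
run_pipeline(list(simulate = list(n_tumor = 30, n_normal = 30,
                                  n_genes = 500,
                                  hr_genes = list(RORA = log(2)))),
             seed = 42, out = "results")
```

which writes one TSV per result table plus a `manifest.yaml` recording
versions, seed and parameters; the same config and seed reproduce
byte-identical tables.

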