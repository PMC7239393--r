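# stipper

Localization and dosage analysis of a sex-linked nested tandem copy
number variant (CNV) from cohort short-read data.

## What this solves

The pigeon *Stipper* (*St*) locus on the Z chromosome controls a series
of depigmentation phenotypes (Almond and its milder relatives). The
causal lesion is a *nested tandem CNV*: an outer ~77-kb segment of the
locus is tandemly repeated, with a nested ~25-kb inner segment further
duplicated inside each unit — 7 outer and 14 inner copies per expanded
chromosome for the canonical allele. Because birds are ZW/ZZ, females
carry 1 Z (hemizygous baseline) and males 2, so dosage arithmetic,
depth normalization and association tests must all be sex-aware.

`stipper` provides the full analysis chain as composable R functions:

| stage | functions |
|---|---|
| case/control differentiation scan | `lrt_site`, `genome_scan`, `significance_threshold`, `candidate_region`, `fixed_difference_scan` |
| read-depth CNV calling | `normalize_depth`, `segment_track`, `copy_number`, `detect_breakpoints`, `assemble_call` |
| tandem structure & gene effects | `infer_structure`, `predict_gene_effects` |
| paralog-aware low-fraction variant scan | `filter_allelic_fraction`, `biallelic_private_alleles`, `recurrence_scan`, `control_cross_check`, `paralog_scan` |
| dosage & expression statistics | `quantify_copies`, `phenotype_association`, `relative_expression`, `group_comparison` |
| synthetic cohorts with known truth | `sim_config`, `simulate_cohort`, `simulate_depth`, `simulate_clip_piles`, `simulate_allele_depths`, `simulate_differentiated_genotypes`, `simulate_assay`, `simulate_expression` |

The scan statistic is a two-binomial likelihood ratio
`G = 2[l(p1) + l(p2) − l(p0, cases) − l(p0, controls)]` with a χ²(1)
p-value and Bonferroni genome-wide threshold; copy number is the rounded
median normalized read depth times the sex baseline; tandem structure
with outer multiplicity *o* and inner count *i = o·r* implies junction
counts 1/2 = o, 2/2 = o(r−1), 2/3 = o, 3/1 = o−1, which drive gene
amplification/truncation/fusion predictions; copy-number assays are
quantified as `c0 · 2^(−ΔΔCt)`. The methods vignette
(`vignettes/stipper-methods.Rmd`) derives and justifies each piece.

## Worked example

Simulate the study-scale cohort (12 cases vs 109 controls), map the
locus, call the CNV in a hemizygous female, infer its structure, and
associate copy number with phenotype:

```r
library(stipper)
cfg    <- sim_config(seed = 11)
cohort <- simulate_cohort(cfg)

## 1. differentiation scan over 2,025 sites
geno <- simulate_differentiated_genotypes(cohort, cfg, n_sites = 2000,
                                          n_causal = 25, seed = 12)
scan <- genome_scan(geno, cohort$samples)
candidate_region(scan)[1, ]
#>      scaffold  start    end n_sites peak_minus_log10_p peak_pos
#> 1 ScoHet5_227 103242 126242      25           22.35668   103242

## 2. read-depth pipeline on one case female
ctrl  <- genomic_interval(cfg$scaffold, 1, cfg$outer$start - 1)
track <- normalize_depth(simulate_depth(cohort$truth$case_01, cfg, seed = 13), ctrl)
piles <- simulate_clip_piles(cohort$truth$case_01, cfg, seed = 14)
call  <- assemble_call(segment_track(track), detect_breakpoints(piles), baseline = 1)
call
#> cnv_call: outer 77 kb CN 7 | inner 25 kb CN 14
call$breakpoints
#>  outer_left  inner_left inner_right outer_right
#>       81467      101091      126635      159256

## 3. tandem structure and gene effects
st <- infer_structure(call)
st
#> tandem_structure: o=7, r=2; junctions 1/2=7 2/2=7 2/3=7 3/1=6
eff <- predict_gene_effects(st, example_gene_models(cfg), call)
eff[, c("gene", "effect", "copies_per_chromosome")]
#>              gene                effect copies_per_chromosome
#> Mlana       Mlana        amplified_full                    14
#> Slc16a13 Slc16a13 truncated_at_junction                     7
#> Ermp1       Ermp1        fusion_partner                     1
#> Kiaa2026 Kiaa2026        fusion_partner                     1
#> Ric1         Ric1             unchanged                     1
attr(eff, "fusion")
#>   gene_5prime gene_3prime copies
#> 1       Ermp1    Kiaa2026      6

## 4. copy-number assay association
est <- quantify_copies(simulate_assay(cohort, cfg, seed = 15))
aggregate(cn_integer ~ phenotype, est, function(x) round(mean(x), 1))
#>    phenotype cn_integer
#> 1     Almond       13.2
#> 2 non-Almond        1.5
phenotype_association(est)$p_bonferroni["Almond", "non-Almond"]
#> [1] 1.45328e-08
```

Reading: the scan's top candidate region overlaps the simulated causal
interval; the depth pipeline recovers the 7-copy outer / 14-copy inner
configuration with all four breakpoints at their exact simulated
positions; the inferred arrangement predicts the inner gene amplified to
14 copies per chromosome, 7 full + 7 truncated copies of the
inner-boundary gene, and 6 copies of the outer-junction fusion; and the
TaqMan-style assay cleanly separates expanded from wild-type birds.

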