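---
title: "Methods: localizing and characterizing a sex-linked nested tandem CNV"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: localizing and characterizing a sex-linked nested tandem CNV}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stipper)
```

## The problem

The classical *Stipper* (*St*) locus on the pigeon Z chromosome controls a
spectrum of plumage depigmentation phenotypes (Almond, Qualmond, Faded,
Sandy, Frosty, Chalky, White Out). Birds are ZW/ZZ: males are the
homogametic sex, so a female is hemizygous for any Z-linked locus and
carries a baseline of **1** copy where a male carries **2**. The causal
lesion is a *nested tandem copy number variant*: an outer segment of the
reference locus is tandemly repeated, and within each repeat unit a nested
inner segment is additionally duplicated. For the canonical expanded
allele the outer segment appears 7 times and the inner segment 14 times
per affected chromosome, so a hemizygous carrier female shows read-depth
plateaus of roughly 14x (inner), 7x (outer shoulders) and 1x (flanks)
relative to her genome-wide coverage, and a homozygous male carries
2 x 14 = 28 inner copies in total.

`stipper` implements the full computational chain that maps and
characterizes such a locus from cohort short-read data:

1. **diffscan** — a case/control allele-frequency differentiation scan;
2. **cnvscan** — read-depth normalization, segmentation, integer copy
   number, soft-clip breakpoint detection, tandem-structure inference and
   gene-effect prediction;
3. **paralogvar** — a paralog-aware scan for low-allele-fraction variants
   private to the case cohort;
4. **dosagestats** — TaqMan-style ddCt copy-number quantification,
   phenotype association, and qRT-PCR group statistics;
5. **simcohort** — a fully seeded synthetic cohort generator with known
   truth, so that every stage above is testable at desk scale.

All genomic coordinates are 1-based and inclusive (BED input is converted
on read), and kilobase labels use `floor(length/1000)` so that a
77,790-bp interval is reported as "77 kb".

## Differentiation scan

For each biallelic site the cohorts are summarized as alternate-allele
counts $a_1/n_1$ (cases) and $a_2/n_2$ (controls). Allele counting is
sex-aware on Z: a female contributes one allele, a male two, with a
sample's dosage called from its allelic depths as
$\mathrm{round}(\mathrm{ploidy}\cdot AD_{alt}/DP)$. The statistic is the
two-binomial likelihood-ratio

$$G = 2\left[\ell(\hat p_1; a_1, n_1) + \ell(\hat p_2; a_2, n_2)
      - \ell(\hat p_0; a_1, n_1) - \ell(\hat p_0; a_2, n_2)\right],$$

with $\hat p_i = a_i/n_i$, pooled $\hat p_0$, the convention
$0\log 0 = 0$, and an upper $\chi^2_1$ tail p-value. This is a
hard-count approximation to genotype-likelihood differentiation
statistics (pFst-style): fully specified, and checkable against a
brute-force log-likelihood oracle. $G$ is computed with the two cohort
terms grouped so that equal sample frequencies give exactly $G = 0$.

Multiple testing uses Bonferroni over tested sites (the correction behind
published genome-wide thresholds of this kind is rarely stated; Bonferroni
is the conservative default). Significant sites are merged into candidate
regions when within `merge_gap` (default 10 kb) and ranked by peak
$-\log_{10} p$, ties broken by scaffold order then position. The
fixed-difference scan reports exonic sites where some alternate allele is
carried by every case and no control; any missing genotype makes a site
ineligible.

**Calibration.** The $\chi^2_1$ approximation is asymptotic. A
pre-specified numerical check showed that at this study's own cohort
sizes (12 cases / 109 controls, i.e. ~14 vs ~163 Z alleles) the null
p-values are mildly anti-conservative (empirical 5% rate about 6%), and
that *equal-size* cohorts put visible point mass at $p = 1$ (ties of the
sample frequencies). The package's uniformity test therefore runs the
null scan at a 10x panel (140 vs 1630 alleles), where a
Kolmogorov–Smirnov test at $\alpha = 0.01$ over 10,000 sites passes; the
small-cohort anti-conservatism is a known limitation users should keep in
mind when quoting borderline p-values at small $n$.

## Read-depth copy number

Depth tracks are per-window means (default window 100 bp; depth files
omit zero-coverage positions, which are counted as depth 0).
Normalization divides by the *median* depth over a CNV-free control
interval — by default everything from the scaffold start to the CNV —
after which the control median is exactly 1 and the operation is
idempotent.

Integer copy number over an interval is
$\mathrm{round}(\mathrm{median\ normalized\ depth} \times
\mathrm{baseline})$ total copies (baseline 1 for females, 2 for males),
reported per chromosome as total/baseline. The median (not the mean) is
used for robustness to localized depth spikes such as repeat elements
inside the region; an exclusion mask can drop windows explicitly.
Intervals covered by fewer than 5 windows are refused.

**Segmentation.** Greedy binary splitting with the CUSUM-weighted mean
difference $\sqrt{k(n-k)/n}\,|\bar x_L - \bar x_R|$; for a noiseless
piecewise-constant profile the maximizer lies exactly on a true boundary.
A candidate split must pass two gates:

* a *noise gate*: the score must exceed $1.5\,\hat\sigma\sqrt{2\log n}$,
  where $\hat\sigma$ is the robust (MAD of first differences) window sd.
  This matters because Poisson noise scales with copy level — at a 14x
  plateau under 30x coverage the window sd is ~0.68 copies, and without
  this gate the maximum fluctuation over a few-hundred-window plateau
  regularly fakes a 0.5-copy step;
* a *step gate*: the medians of the `min_seg` (default 10) windows
  flanking the cut must differ by at least `step_threshold` (default 0.5
  copies).

Adjacent segments whose medians differ by less than the threshold are
re-merged. On noiseless profiles the boundaries are recovered exactly (at
window resolution); with Poisson noise at 30x the four boundaries of the
7/14 configuration are recovered within +/-2 windows in >95% of seeded
replicates.

**Breakpoints and call assembly.** Soft-clip pileups with at least
`min_support` (default 3) clipped reads are breakpoints, merged within
5 bp keeping the highest count (this automates what is otherwise done by
eye in a genome browser). Call assembly pairs each depth-segment boundary
with the nearest breakpoint: a breakpoint within 2 windows replaces the
window-resolution boundary; a boundary with no breakpoint within 10
windows flags the call `depth-only` (depth evidence without split-read
support does occur in real panels). An elevated region consisting of a
single plateau with no outer shoulder is called `inner-only` with outer
copy number 1 — the configuration seen in rare non-carrier birds with
only the inner duplication.

**Structure and gene effects.** With per-chromosome outer multiplicity
$o$ and inner count $i$, uniform units require $o \mid i$; the
arrangement is S1 (S2 x $r$) S3 repeated $o$ times, $r = i/o$, giving
junction counts $1/2 = o$, $2/2 = o(r-1)$, $2/3 = o$, $3/1 = o-1$
(verified against exhaustive enumeration of the arrangement string for
$o \le 10$, $r \le 4$). Non-divisible calls are rejected with the nearest
divisible structures proposed, rather than guessing a non-uniform
arrangement. Gene effects follow placement: inside-inner genes amplify to
$i$ copies, inside-outer to $o$; a gene straddling an inner edge gets one
full copy per 2/3 junction and one truncated copy per novel 2/2 junction;
the pair of genes straddling the two outer edges is predicted to fuse at
every 3/1 junction ($o - 1$ copies). For the canonical $o = 7$
arrangement the enumeration yields seven full copies of the
inner-boundary gene; because an external expectation of six circulates
for this configuration, the output carries an explicit note that the
count is the enumeration result.

## Paralog-aware low-frequency variant scan

Inside an expanded CNV, a variant on one of $k$ copies appears at an
allelic fraction of about $1/k$ — ~7% for 1 of 14 — far below a diploid
heterozygote. The scan therefore works on allelic depths, not genotype
calls:

1. **Retention**: keep (site, allele, sample) triples with
   $AD/DP > 4\%$ (strictly greater; 4/100 is *not* retained). The
   threshold keeps 1-of-14 variants while discarding typical
   sequencing-error support.
2. **Routing**: biallelic sites go through a cohort frequency comparison
   (alleles with nonzero retained frequency in cases and zero in
   controls); multiallelic sites go through a recurrence scan.
3. **Recurrence**: a binary presence matrix (1 = at least one supporting
   read, deliberately *laxer* than the retention filter) over case
   samples; rows with at least `min_cases` (default 3) presences are
   candidates. The rows of the matrix are the alternate alleles retained
   in at least one case; passing `retained = NULL` scans every alternate
   allele instead.
4. **Control cross-check**: any candidate with a single supporting read
   in any control is discarded; survivors are case-specific.

Missing samples count as absent, and the output is invariant to sample
order. Both thresholds are configurable, and raising either can only
shrink the output.

The control cross-check is deliberately unforgiving — one read kills a
candidate. With a 0.5% per-base error rate this means a planted
copy-private allele can be vetoed by a single colliding error read in a
control pileup, and no fraction-based rule can distinguish that from
genuine presence. The recovery property is therefore scored on planted
alleles whose simulated control read data are truly empty: those are
recovered in >=95/100 seeded replicates, while a null cohort (no planted
alleles) yields an empty case-specific set.

## Dosage and expression statistics

**ddCt quantification.** Per sample,
$\Delta Ct = \overline{Ct}_{target} - \overline{Ct}_{ref}$;
$\Delta\Delta Ct$ is taken against a designated calibrator of known copy
count $c_0$ (a wild-type bird: female 1, male 2 for a Z-linked target),
and the continuous estimate is $c_0 \cdot 2^{-\Delta\Delta Ct}$, rounded
for the integer estimate. A zero-noise simulated assay inverts exactly
for every copy number 1–28.

**Association.** All phenotype pairs are compared with a two-sided
rank-sum test. Exact inference uses `pwilcox` for tie-free samples with
both sizes <= 25 (equivalent to enumeration); tied samples are enumerated
exhaustively when $\binom{n_1+n_2}{n_1} \le 2\times 10^5$, handled by a
fixed-seed 20,000-draw permutation null for tied samples up to 25 per
group beyond that budget, and otherwise approximated normally with tie
and continuity corrections (within ~0.01 of enumeration at sizes 9–25).
Full enumeration at the nominal 25-per-group crossover would require up
to $\binom{50}{25} \approx 10^{14}$ assignments, which is why the
permutation path exists. Bonferroni correction uses the all-pairs count;
because the family could equally be "each phenotype versus wild type",
the result also reports that alternative denominator.

**Expression.** Fold changes are
$2^{-(\Delta Ct - \overline{\Delta Ct}_{baseline})}$ against the
wild-type group, with replicates averaged before $\Delta Ct$. Group
comparisons run one-way ANOVA on $\Delta Ct$ — the log2 scale, where
replicate variance is closest to homogeneous — followed by Tukey's HSD
and an insert-and-absorb compact letter display (groups sharing a letter
are not significantly different at 0.05). Groups with fewer than two
samples are excluded with a warning rather than silently pooled.

## The synthetic cohort generator

The generator's defaults encode the study conditions: 12 cases (10
hemizygous females, 2 heterozygous males) versus 109 controls for the
mapping scan; a 10-case / 14-control subcohort for the paralog scan; the
canonical expansion `Almond = c(7, 14)` with smaller expansions for other
alleles of the series; quadruplicate copy-number assays and duplicate
expression assays. Mean coverage 30x and a 0.5% per-base error rate are
configuration defaults chosen as typical of a modern resequencing panel —
the source data report neither — and are not claims.

The CNV sits on a single 400-kb synthetic scaffold at the printed locus
coordinates shifted left by a configurable offset (default 5.1 Mb), so
published anchors remain directly usable while tracks stay small
(4,000 windows at the default 100-bp window). Specifics worth knowing:

* **Depth** is Poisson per window with mean
  `coverage * local copies / baseline`; `noise = FALSE` returns the
  expectation, giving exact step profiles for boundary tests. An
  overdispersed real sequencer will be somewhat noisier than this.
* **Clip piles** appear at the four breakpoints with Poisson counts
  proportional to the novel junction multiplicities ($i-o$ at inner,
  $o-1$ at outer breakpoints) plus sporadic 1-read background clips.
* **Allelic depths**: copy-private variants ride exactly one copy of each
  expanded chromosome (fraction $1/k_{total}$, with $k_{total}$ summed
  over both chromosomes of a male — pooled reads map to a single
  reference locus). Population alleles are assigned per *ancestral
  chromosome* and ride all of its copies, because tandem copies are
  identical by descent; modelling copies as independent draws would make
  expanded cases systematically enriched for every low-frequency allele
  and is wrong. Sequencing errors are binomial in DP, spread uniformly
  over the three non-reference bases.
* **Genotypes for the scan** encode dosage directly in AD with
  DP = ploidy; background sites share one frequency (uniform on
  0.1–0.9 by default, see the calibration note above), causal sites
  draw the cohorts at configurable divergent frequencies.
* **Assays**: target Ct shifts by $-\log_2(CN/c_0)$ with Gaussian
  replicate noise, so ddCt quantification is exactly invertible at zero
  noise.

All randomness flows through explicit seeds; a fixed seed reproduces
outputs bit-for-bit. What the generator does *not* emulate: alignment
artifacts, GC and mappability bias, overdispersed coverage, batch/plate
effects, linkage between sites, and W-chromosome repeat pileups. Passing
tests therefore demonstrate the correctness of the algorithms under the
stated statistical model, not robustness to every artifact of real data.

## Problem sizes and determinism

The shipped tests run at desk scale by design: 4,000-window tracks,
100-replicate recovery loops for the copy-number and paralog-recovery
properties, a 10,000-site null scan for calibration, and exhaustive
enumerations up to $o \le 10$, $r \le 4$ (junctions) and group sizes
<= 8 (rank-sum oracle). `scripts/acceptance.R --seed S --out F` re-runs
the headline quantities (kb labels, outer/inner integer copy number of a
simulated hemizygous female, the ~7% private-allele fraction, the
28-copy homozygote total) from scratch at those sizes.

## Known limitations

* The differentiation scan uses hard allele counts, not genotype
  likelihoods; at very low depth the dosage call
  $\mathrm{round}(\mathrm{ploidy} \cdot AD/DP)$ discards uncertainty.
* The $\chi^2_1$ p-value is anti-conservative at small cohort sizes (see
  calibration note).
* Structure inference assumes uniform repeat units; genuinely non-uniform
  expansions are rejected, not reconstructed.
* The paralog scan's one-read control veto trades sensitivity for
  specificity exactly as the original procedure does; with realistic
  error rates some genuinely private alleles will be vetoed by chance
  collisions.
* Copy-number estimates are per-sample medians; no joint calling or
  population-level smoothing across samples is attempted.
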