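---
title: "Methods: multi-region heterogeneity analysis in clonehet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-region heterogeneity analysis in clonehet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonehet)
```

clonehet analyses multi-region tumor sequencing cohorts: several spatially
distinct samples per patient (a primary tumor and its intrathoracic
metastases, in the motivating setting of inoperable lung cancer sampled by
endoscopic needle aspiration), each with somatic variant calls, a germline
control, a cytology-based tumor-cellularity estimate, and copy-number
segment tables. This vignette describes the models behind each stage, the
parameters that matter, the synthetic-data generator that stands in for
controlled-access sequencing data, and the package's numerical choices and
limitations.

## Clonal partition and the clone tree

Presence of a variant in a region is called from read counts:
`unknown` below 10 total reads, `present` with ≥ 3 alt reads and VAF ≥ 0.05,
otherwise `absent`. These defaults are conservative for ~150× tumor
sequencing and are arguments of `call_presence()`; at much lower depth the
depth floor should be lowered with corresponding loss of confidence.
Unknown calls are tolerated but never imputed: a variant is *truncal* when
no region calls it absent (and at least one calls it present), *private*
when present in exactly one region, *shared* otherwise. Variants present
nowhere are dropped and counted. This is a deliberately discrete
presence-pattern clustering; VAF is not used for subclonal deconvolution
(no cancer-cell-fraction clustering), which keeps the partition exact and
auditable at the cost of not resolving subclones that share a region set.

`build_tree()` reconstructs a perfect phylogeny over the observed presence
subsets: the trunk carries the full region set (the last common ancestor);
every other subset attaches to its smallest observed strict superset, or
to the trunk. Real data violate the perfect-phylogeny assumption; when two
subsets overlap without nesting, the higher-count pattern is kept as a
clade and the other is attached directly to the trunk, with lexicographic
region order breaking ties. Every region is emitted as a leaf even when it
has no private variants, so branch counts always cover all regions and sum
exactly to the number of classified variants. Trees export as Newick
(branch lengths = mutation counts) and as TSV edge lists.

## Mutational signatures

SNVs are binned into the 96 canonical channels: substitution classes
C>A, C>G, C>T, T>A, T>C, T>G crossed with the 16 flanking contexts ordered
lexicographically by the 5' then the 3' base, with purine-reference
variants reverse-complemented onto the pyrimidine strand. Indels and
variants at the first/last reference position have no complete context and
are excluded (and tallied).

Exposure fitting is supervised non-negative least squares against a fixed
catalog rather than de novo factorisation: with spectrum counts $x$
(total $N$) and catalog matrix $M \in \mathbb{R}^{S\times 96}$,

$$ e^{*} = \arg\min_{e \ge 0} \left\lVert \frac{x}{N} - M^{\top} e \right\rVert_2 , $$

solved by a hand-implemented Lawson–Hanson active-set iteration
(tolerance $10^{-9}$; the unconstrained subproblems are QR solves, which is
ample for a 96 × 6 system). Fractions are $e/\sum e$ and exposures are
rescaled to mutation counts. Supervised fitting was chosen because the
analyses the package supports report fractions for *named* processes
(tobacco, APOBEC, 5-methyl-cytosine deamination "clock", homologous
recombination deficiency, polymerase η) — a supervised fit reproduces
those deterministically and testably, whereas de novo NMF is
non-deterministic and needs post-hoc signature matching. The residual norm
is non-increasing in catalog size (nested models), which the tests verify.

The bundled catalog is **synthetic**: six parametric shapes
(`tobacco`: C>A-dominated; `clock`: C>T at NpCpG; `apobec`: C>T/C>G at
TpCpN; `hrd`: broad and structured; `poleta`: T>A/T>C with A/T 5'
preference; `background`: flat), rows normalised to 1, full rank. It is a
stand-in for a reference catalog such as COSMIC — fitted fractions on real
tumors are not expected to match published per-case percentages, and users
with real data should load their preferred catalog via `load_catalog()`
(TSV, rows = signatures, 96 canonical columns).

Per-branch attribution simply refits each branch's own spectrum. Branches
with fewer than 50 SNVs are fitted but flagged low-confidence (multinomial
noise at that size makes fractions unstable); empty branches get no fit.
Smoking metrics report the tobacco-signature fraction, the implied count
`round(fraction × N)`, and the count per pack-year; never-smokers (0
pack-years) keep their fraction but have an undefined per-pack-year rate.

## LOH from VAF and cellularity

A tumor sample is modelled as a mixture of tumor cells (fraction $p$) and
diploid normal cells. A locus with $g$ alt copies in normal cells and
$c_{alt}$ of $c_{tot}$ copies in tumor cells has expected VAF

$$ \mathrm{VAF}(p, g, c_{alt}, c_{tot}) =
   \frac{(1-p)\,g + p\,c_{alt}}{2(1-p) + p\,c_{tot}} . $$

At $p = 0$ this is $g/2$ regardless of tumor state; at $p = 1$ with the
alt allele lost it is 0. Germline-heterozygous sites ($g = 1$, retained
expectation exactly 0.5 at any purity) are scored by the binomial
log-likelihood ratio of the best loss model — hemizygous loss of the alt
allele $(c_{alt}{=}0, c_{tot}{=}1)$ or copy-neutral loss of the reference
allele $(c_{alt}{=}2, c_{tot}{=}2)$, which between them cover VAF shifts in
either direction — against the retained model. A site is LOH when the
ratio exceeds 3 (about an $e^3$ likelihood ratio), indeterminate below 20
total reads. The threshold and floor are arguments; the defaults are
calibrated for ~150× data, where the simulated operating characteristics
are ≥ 0.95 sensitivity for hemizygous loss at 0.6 cellularity and ≥ 0.99
specificity for retained sites up to 0.8 cellularity. The model set
deliberately excludes full allele-specific copy-number inference (a
purity/ploidy caller's job); subclonal LOH and extreme amplification of
the retained allele will reduce sensitivity.

## Copy-number heterogeneity

Candidate extreme CNVs keep segments with total copy number 0 or > 6 and
size strictly > 20 kb (1-based inclusive coordinates; a `bed0` flag
converts standard BED half-open input). Inter-region heterogeneity
rasterises each region's profile onto fixed bins (default 1 Mb; a bin takes
the copy number of the segment covering its midpoint) and scores pairs by
the mean absolute log2 ratio of pseudocount-shifted copy numbers,
$\mathrm{mean}\,|\log_2((cn_a + 0.5)/(cn_b + 0.5))|$, over bins covered in
both regions. The pseudocount 0.5 keeps homozygous deletions finite; the
measure is symmetric, zero on identical profiles, invariant to splitting a
segment into equal-copy pieces, and undefined (NA) for pairs with no
shared covered bin. It is a package-defined distance for comparing regions
within a patient, not a published metric, so absolute values are only
comparable within one analysis.

## Filtration cascades

Three rule sets, vectorised over variant tables, each returning per-rule
failure labels so decisions are auditable:

* **Somatic driver**: gene on the driver list, caller quality
  (Strelka-style QSS for SNVs / QSI for indels, one `qss` field) strictly
  > 15, population allele frequency < 1 %, CADD scaled score > 2, impact
  HIGH or MODERATE.
* **Somatic LOF + LOH**: all genes queried (no list), same
  quality/AF/CADD thresholds, impact HIGH only, and somatic LOH evidence
  required.
* **Germline DNA repair**: gene on the repair list, population AF < 2 %,
  and HIGH impact or a missense satisfying (ClinVar
  pathogenic/likely-pathogenic) OR (Pfam domain AND ≥ 1 damaging of
  PROVEAN/SIFT/PolyPhen) OR (≥ 2 damaging of the three).

Missing CADD and missing population AF pass their rules (absence of
evidence is not exclusion — these scores are only available for a subset
of variants); missing caller quality fails, and missing predictor calls
count as not damaging. One predictor call per variant is assumed
(transcript-level conflicts must be collapsed upstream). Mutation burden
is variants per callable megabase with hypermutation strictly above
10/Mb.

## Group statistics

Welch's t (unequal variances, Welch–Satterthwaite degrees of freedom) and
the pooled-variance Student t are implemented from their formulas, with
two-tailed p-values via $I_{\nu/(\nu+t^2)}(\nu/2, 1/2)$ evaluated by the
standard continued-fraction expansion of the regularised incomplete beta
(modified Lentz). They agree with `stats::t.test()` to ~1e-10 in the
tests, coincide exactly for equal variances and sizes, and are calibrated
(type-I error 0.05 ± 0.01 at $n = 10 + 10$ over 10,000 null simulations).
`compare_by_germline_status()` groups patients by whether any germline
repair variant passed the cascade, excludes patients with an undefined
metric (e.g. per-pack-year rates in never-smokers) with a logged count,
and signals insufficient data below two patients per group. No
multiple-testing correction is applied across the three metrics by
default, matching the single-test reporting convention of the analyses
this reproduces. Cohort-level smoking-metric comparisons are run among
ever-smokers — a germline effect on tobacco-induced damage is only
observable given exposure — while burden comparisons use all patients.

## The synthetic cohort generator

`simulate_cohort()` emulates the study design the package targets. Its
defaults are the study conditions, chosen once:

* 11 patients × 3 regions, tumor depth Poisson around 150×, germline 35×,
  per-region cellularity uniform on [0.4, 0.9] (cytology-screened samples
  well above the ~15–20 % informativeness floor).
* 2,000 somatic variants per patient before a smoking-status multiplier
  (current 1.5×, former 1×, never 0.3×), of which
  `round(truncal_fraction × n)` (default 0.8) are truncal — multi-region
  studies of metastatic disease find most of the burden in the last common
  ancestor — and the rest are spread uniformly over region-private
  branches. Smoking status is drawn current/former/never with
  probabilities 0.2/0.65/0.15; ever-smokers get 10–60 pack-years.
* Branch spectra: the truncal tobacco fraction of an ever-smoker is drawn
  N(0.5, 0.1) for germline-mutant patients and N(0.2, 0.1) for wild-type
  (truncated to [0, 1]; near zero for never-smokers) — the
  gene-by-environment effect downstream stages must recover; each private
  branch is dominated (0.7) by a rotating non-tobacco process. Positions
  are sampled uniformly without replacement over the reference interior so
  every variant has a full trinucleotide context.
* Read counts: total reads Poisson around the mean depth; alt reads
  binomial at the expected VAF for carried variants and at the sequencing
  error rate (default 0.001 — a simulator choice for post-calling noise,
  not an estimate from any dataset) for absent ones.
* Germline: mutant patients (probability 0.6) receive 1–3 repair-gene
  records constructed to pass the germline cascade through each of its
  three disjuncts in rotation; all patients receive benign decoys.
  Heterozygous SNP sites (default 120) are simulated with truncal LOH in a
  configurable fraction (0.3), losing the reference or alternate allele
  hemizygously or copy-neutrally with equal probability.
* CNVs: per-region segment tables over a separate 100 Mb virtual genome, a
  shared truncal aberration profile plus private deviations. The CNV
  tables and the LOH het sites are deliberately decoupled (LOH truth is
  per-site, not derived from the segment tables): the CNV module is
  exercised on realistic segment geometry while LOH detection is tested
  against its own generative model.
* The burden denominator (`callable_mb`, default 100) is scaled with the
  simulated variant counts so burdens fall in the 1–30/Mb range real
  tumors span.

Everything is deterministic given the seed; with identical configuration
the emitted VCF bodies are byte-identical. The generator does **not**
emulate: read-level artefacts (no FASTQ/BAM), caller-specific error modes,
indel realism (indels are 1-bp insertions for counting only), subclonal
structure within a region, structural variants or fusions, or linkage
between the CNV tables and somatic VAFs. Passing tests therefore
demonstrate correctness of the algorithms under the stated generative
model — binomial read sampling, exact presence patterns, known mixtures —
not robustness to the full error structure of real sequencing.

## Problem sizes and numerical choices

The test suite and the acceptance script use desk-scale sizes chosen as
the package's own validation conditions: 100 kb references, 5,000-SNV
spectra over 20 seeds for signature recovery (tolerance 0.05 max absolute
error; exact mixtures recover to 1e-6), 1,000-variant 3-region patients
for clonal recovery (truncal fraction within 0.02), 1,000 simulated sites
per arm for LOH operating characteristics, 10,000 null replicates for
test calibration, and a 20-patient end-to-end cohort. Degenerate inputs
are signalled, not silently patched: empty spectra raise an undefined-fit
condition, sub-two-patient groups an insufficient-data condition, zero
depth flags VAF as missing, and a pure tumor with total copy number zero
has undefined VAF. Ties in tree construction are broken lexicographically
so all outputs are reproducible.

## Known limitations

Beyond the generator's non-goals above: the partition cannot separate
subclones sharing a presence pattern; the supervised signature fit is only
as good as the supplied catalog (a missing active process inflates the
residual and leaks into correlated signatures); LOH detection assumes a
known, accurate cellularity and clonal LOH; and the CNV distance is a
within-analysis comparison tool, not a calibrated evolutionary distance.
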