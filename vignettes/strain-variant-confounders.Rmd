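---
title: "Strain-variant confounders of mouse tumor CNV analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Strain-variant confounders of mouse tumor CNV analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lohconfound)
```

# The mechanism being modeled

Mouse cancer cohorts are usually mixed-background crosses of two inbred
strains. `lohconfound` models the smallest system in which the resulting
artifact arises: two founders, `REFSTRAIN` (defines the reference genome;
C57BL/6J analog) and `DONOR` (129S analog), differing at a dense set of
diagnostic SNPs (the donor carries the ALT allele at every such site with
probability 1) and at discrete deletion variants fixed in the donor strain.
An engineered driver allele sits on the donor haplotype 1.5 Mb from one such
deletion, producing tight genetic linkage: the recombination fraction
between them under the default map (0.5 cM/Mb) is about 0.75 %, so the two
loci co-segregate through any realistic number of cross generations.

In a tumor from a heterozygous carrier, selection against the wild-type
driver drives a copy-neutral LOH event that discards the `REFSTRAIN`
haplotype and duplicates the donor one. At the linked deletion the germline
had one physical copy (the `REFSTRAIN` one); the tumor now has zero. A
tumor/germline coverage comparison therefore shows a focal homozygous
deletion with breakpoints fixed by the germline variant — identical in every
affected tumor — even though the only somatic event was copy-neutral. In a
driver-homozygous germline both copies already lack the locus, the
comparison sees no change, and the variant is invisible. The analysis
modules exist to detect exactly these signatures.

# The synthetic genome

Defaults (all exposed in `default_config()`):

| parameter | default | meaning |
|---|---|---|
| chr11-like length | 122 Mb | carries driver (69.58 Mb) and 200 kb donor deletion (70.98–71.18 Mb) |
| chr4-like length | 156 Mb | carries suppressor locus (89.28 Mb) and 600 kb donor deletion (112.0–112.6 Mb) |
| map rate | 0.5 cM/Mb | uniform; chr11-like map length 61 cM |
| SNP spacing | 10 kb | regular grid, seeded jitter of ±25 % of the spacing |
| bin size | 20 kb | coverage bins |
| mean depth | 100 | per neutral diploid bin and per SNP |
| NB dispersion | 0.05 | bin-count variance `mu + 0.05 mu^2` |
| purity | 1.0 | primary cell cultures; mixing available |

The geometry mirrors real mouse chromosome scales and the published 1.5 Mb
driver–variant separation while remaining fully synthetic; no real assembly
coordinates are used. Coordinates are 0-based half-open (BED convention)
throughout.

One deliberate choice: diagnostic SNP positions are *excluded* from registry
deletion intervals. A site inside a region absent from the donor assembly
has no donor allele and therefore cannot be ascertained as a strain-
diagnostic SNP. Besides being what SNP discovery on real strains would
yield, this makes germline haplotype reconstruction behave like the real
analysis: a heterozygous carrier shows one uninterrupted heterozygous
segment spanning driver and variant, rather than a spurious
reference-homozygous island of VAF-0 sites inside the deletion.

# Breeding model

Meiosis follows the Haldane model: crossover count Poisson with mean equal
to the map length in Morgans, positions uniform, starting copy a fair coin,
no interference and no obligate chiasma. This is the simplest model whose
expectations support the claims the package tests (crossover rates, donor-
fraction decay, linkage persistence); interference would sharpen, not
change, the qualitative picture.

`backcross_scheme(n_generations = n)` performs `n` backcross meioses
starting from the F1, selecting each generation the first offspring that
carries the engineered allele (rejection sampling, as in genotype-driven
breeding). Two consequences the tests verify:

- On the carrier chromosome the allele-containing block is donor-origin on
  exactly one copy with probability 1 at every generation — backcrossing can
  never remove the linked variant, only shrink its flanking donor segment.
- On chromosomes not carrying the allele the expected donor fraction is
  `2^-(n+1)`: one quarter after the first backcross, halving each
  generation. The package states its generation count in backcross meioses
  from the F1; congenic nomenclature (N2 = first backcross offspring) is off
  by one from this and some informal statements of the halving rule differ
  accordingly. The tests pin the convention against an independent
  Monte-Carlo simulation of the unselected gamete lineage plus the analytic
  halving expectation rather than against any verbal convention.

The default cohort scheme is the F1 het-carrier (`"f1"`), the configuration
in which the artifact appears; `"driver_homozygous"` (intercross offspring
selected to driver homozygosity) produces the invisibility scenario, and
`"backcross"` produces congenic-like genomes. The real cohorts' exact
pedigrees are not modeled; the scheme is a config choice.

# Readout model

Coverage: per 20 kb bin, expected count `mean_depth x mean(physical
copies)/2`, drawn negative-binomial. *Physical copies* is the quantity
sequencing sees: per-haplotype somatic copy number, zeroed wherever that
haplotype's strain carries a registry deletion. Allele counts: per SNP,
depth Poisson at `mean_depth x physical_copies/2`, ALT count binomial with
probability = donor-origin fraction of surviving copies. Somatic events
compose in order, so a focal deletion followed by CN-LOH retaining the
deleted copy yields zero copies (the two-step suppressor scenario). aCGH
probes report `log2((test + 0.5)/(reference + 0.5))` plus Gaussian noise
(sd 0.15); probe spacing is a config parameter (default 10 kb — the real
array's local spacing is not modeled). Read-level effects (GC bias, capture
efficiency, mapping error) are not simulated; the min-depth filter in the
caller stands in for the read-quality filtering a real pipeline applies.

# Calling models

**Haplotype states.** Windows of 25 SNPs (depth ≥ 10) are classified by mean
VAF: heterozygous in [0.15, 0.85], donor-homozygous above, reference-
homozygous below or with no ALT evidence; adjacent same-state windows merge,
boundaries fall midway between flanking informative SNPs (ties toward the
lower coordinate). The published rule is a direct three-way frequency
classification, so a window threshold — not an HMM — is the faithful
implementation; an HMM would be a natural extension for noisier data. The
thresholds separate binomial(100, 0.5) from binomial(100, ~1) with
negligible error; the numeric values are package decisions, as only
approximate frequencies are published.

**LOH and mechanism.** LOH is defined only over germline heterozygosity.
Within germline-HET segments, tumor windows with mean VAF outside
[0.15, 0.85] merge into calls; the mechanism comes from the median
depth-normalized tumor/germline bin ratio over the call: copy-neutral in
[0.8, 1.2], deletion below 0.7, otherwise (or without coverage) UNKNOWN.

**Copy number.** Bin ratios are `log2((t + 0.5)/(g + 0.5))` after median
depth scaling, median-centered. Segmentation is *seeded binary
segmentation*: candidate changepoints are the best splits within a
deterministic multi-scale interval collection (dyadic scales, 50 % overlap)
plus the current segment; the best candidate is accepted when its
within-interval sum-of-squares reduction exceeds
`penalty x 4 x sigma^2 x log(n_bins)`, with `sigma^2` estimated robustly from
successive differences. Plain single-split binary segmentation was the
obvious first choice but fails a simple calculation: for a 10-bin deletion
at depth −6.6 on a 6,100-bin chromosome the best *single* split reduces the
sum of squares by ≈ 1.0, below the ≈ 2 ceiling that pure noise reaches,
so no threshold can both find the variant and avoid false splits. Focal
events need a candidate interval of their own scale; the seeded collection
supplies one deterministically (a stochastic interval sampler would break
the pipeline's reproducibility guarantee). With zero estimated noise any
positive reduction is accepted, so noise-free steps split exactly. Segment
calls: homozygous loss ≤ −2, heterozygous loss ≤ −0.35, gain ≥ +0.3 on the
mean log2 ratio.

**Cohort classification.** Homozygous-loss calls are clustered by
single-linkage overlap; breakpoint concordance is the fraction of member
pairs agreeing within one bin at both ends. Each call is then classified by
the deterministic conjunction of three evidence flags — reciprocal overlap
≥ 0.9 with a registry variant; cluster concordance ≥ 0.9 with ≥ 3 members;
containment in an LOH call whose interval includes a driver position. A
probabilistic score was deliberately avoided: the argument being encoded is
categorical, and a score would be an invention the data behind it could not
calibrate. Cut-offs are config-exposed defaults; the published contrast
("identical" vs "stepped") is qualitative.

# What the tests do and do not show

The simulation reproduces the mechanism's arithmetic, not real WES data.
Passing tests demonstrate that the pipeline recovers planted truth under
idealized noise (negative-binomial bins, binomial alleles, perfect SNP
ascertainment outside deletions, purity 1). They do not demonstrate
robustness to alignment artifacts, capture bias, subclonality, or imperfect
strain annotation — on real data the registry-matching flag in particular
inherits the quality of the strain-variant catalog used.

Problem sizes were chosen so the full suite and the acceptance run complete
comfortably on a single CPU: cohorts of 4–27 animals, 13,900 bins and
~27,700 SNPs per sample, 1,000 backcross replicates for the persistence
property and 600 + 4,000 (implementation + oracle) replicates for the
donor-fraction comparison. Monte-Carlo tolerances are stated as 3 standard
errors of the quantity being estimated.

# Known limitations

- No sex chromosomes, mutation, genotyping error, or crossover
  interference; no phenotype-based selection.
- Tumor purity is a single mixing fraction; no subclonal structure.
- CN-LOH extent is drawn from a simple telomeric model (uniform start
  upstream of the driver to the chromosome end); real segment-extent
  distributions are not published and interstitial events are config-only.
- The registry models deletions only; insertions relative to the reference
  would produce gain-like artifacts by an analogous mechanism and are left
  as an extension.
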