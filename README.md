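# lohconfound

Strain-specific germline variants masquerading as somatic deletions in mouse
cancer genomes — a simulator and detection toolkit.

## The problem

Mouse cancer cohorts are bred from crosses of inbred strains (for example a
129S-derived strain carrying an engineered driver allele, crossed onto
C57BL/6J). The strains differ not only at millions of diagnostic SNPs but
also at discrete structural variants: deletions fixed in one strain and
absent from the reference strain's genome. When such a germline deletion is
genetically linked to a driver allele that tumors select for — e.g. a
deletion 1.5 Mb from an engineered *Trp53*-like allele — a single somatic
copy-neutral loss of heterozygosity (CN-LOH) event that removes the
wild-type-driver haplotype also removes the only chromosome copy that still
carried DNA at the variant locus. In the standard tumor-versus-germline
comparison this surfaces as a focal, apparently somatic, homozygous
deletion. Because the deletion boundaries are fixed in the germline of the
donor strain, the artifact recurs with *identical* breakpoints across
unrelated tumors, models and laboratories — unlike genuine somatic
tumor-suppressor losses, whose overlaid breakpoints form a "stepped"
pattern. And in animals bred to homozygosity for the driver haplotype the
variant is invisible to tumor/germline comparison altogether, because the
germline already has zero copies.

`lohconfound` reproduces this mechanism end to end in simulation and
implements the detection logic that separates such artifacts from real
somatic candidates.

## What it does

**Simulation**

- `build_default_layout()` — synthetic two-founder genome: a chr11-like
  chromosome with an engineered driver 1.5 Mb from a 200 kb donor-strain
  deletion, and a chr4-like chromosome with a tumor-suppressor locus and a
  second donor-strain deletion; dense strain-diagnostic SNPs (donor carries
  ALT with probability 1).
- `meiosis()`, `cross()`, `backcross_scheme()` — Haldane-model meiosis
  (Poisson crossovers, no interference) and breeding with genotype selection
  for the engineered allele; genomes are haplotype mosaics of founder blocks.
- `simulate_kpc_tumor()`, `copy_state()`, `physical_copies()` — somatic
  CN-LOH and focal-deletion events composed in order, and the physical copy
  number that sequencing actually sees once strain-private germline
  deletions are accounted for.
- `simulate_coverage()`, `simulate_allele_counts()`, `simulate_acgh()` —
  WES-like binned read counts (negative binomial), per-SNP ref/alt counts
  (Poisson depth, binomial allele sampling) and aCGH-style probe log-ratios.

**Analysis**

- `call_haplotype_segments()` — three-way haplotype reconstruction from SNP
  allele frequencies (VAF ≈ 0.5 heterozygous, ≈ 1 pure donor, no ALT reads
  = reference strain).
- `call_loh()` — LOH calls within germline-heterozygous segments, with the
  mechanism read off the tumor/germline coverage ratio: ≈ 1 is copy-neutral
  LOH, ≈ 0.5 is deletion LOH.
- `compute_log_ratios()`, `segment_log_ratios()`, `call_segments()` —
  tumor/germline log2-ratio copy-number calling with deterministic seeded
  binary segmentation.
- `overlay_cohort()`, `classify_cnv()` — cohort overlay with breakpoint
  concordance, and the three-way evidence rule (registry match, identical
  breakpoints, linkage to driver LOH) classifying each homozygous-loss call
  as `GERMLINE_VARIANT_ARTIFACT`, `SOMATIC_CANDIDATE` or `AMBIGUOUS`.
- `run_cohort_pipeline()` — the whole chain for a cohort, deterministic
  given one master seed.

## Worked example

```r
library(lohconfound)
cfg <- default_config()
cfg$breeding$n_animals <- 4      # four F1 het-carrier animals
res <- run_cohort_pipeline(cfg, seed = 7)

res$calls[, c("tumor_id", "chrom", "start", "end", "log2_ratio",
              "classification", "distance_to_driver")]
#>    tumor_id chrom    start      end log2_ratio            classification
#> 1 animal_01 chr11 70980000 71180000  -6.530027 GERMLINE_VARIANT_ARTIFACT
#> 2 animal_02 chr11 70980000 71180000  -6.655066 GERMLINE_VARIANT_ARTIFACT
#> 3 animal_03 chr11 70980000 71180000  -6.512007 GERMLINE_VARIANT_ARTIFACT
#> 4 animal_04 chr11 70980000 71180000  -6.602803 GERMLINE_VARIANT_ARTIFACT
#>   distance_to_driver
#> 1            1500000
#> 2            1500000
#> 3            1500000
#> 4            1500000

res$variant_summary
#>      variant_id n_animals_with_call n_animals
#> 1 Nlrp1like_del                   4         4
#> 2 Skintlike_del                   0         4

res$overlays[[1]]$concordance
#> [1] 1

res$animals$animal_01$loh
#>   chrom    start      end mechanism retained coverage_ratio mean_vaf
#> 1 chr11 64249801 1.22e+08    CN_LOH      ALT      0.9896896        1
```

Every heterozygous-carrier tumor undergoes driver CN-LOH (coverage ratio
≈ 1, tumor VAF → 1 over the lost haplotype) and consequently shows a deep
homozygous-loss call (log2 ratio ≈ −6.6) whose breakpoints coincide exactly
with the registry deletion in every animal — breakpoint concordance 1.0 —
and sit 1.5 Mb from the driver. All calls are classified as germline-variant
artifacts, with all three evidence flags set. Switching
`cfg$breeding$scheme <- "driver_homozygous"` makes the same variant
disappear from every tumor/germline comparison (`n_animals_with_call` 0),
the invisibility half of the mechanism.

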