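test_that("copy_state applies events in order", {
  f1 <- make_f1(1)
  t0 <- tumor_genome(f1)
  expect_equal(unname(copy_state(t0, "chr11", c(1e6, 70e6))),
               matrix(1, 2, 2))

  ev <- somatic_event("CN_LOH", "chr11", 50e6, 122e6, "B")
  t1 <- tumor_genome(f1, ev)
  cs <- copy_state(t1, "chr11", c(49e6, 51e6))
  expect_equal(unname(cs[1, ]), c(1, 1))   # outside interval
  expect_equal(unname(cs[2, ]), c(2, 0))   # inside: retained copy doubled

  # deletion first, then CN-LOH retaining the deleted copy: nothing left
  ev2 <- rbind(somatic_event("FOCAL_DEL", "chr4", 88e6, 90e6, "A"),
               somatic_event("CN_LOH", "chr4", 80e6, 156e6, "B"))
  t2 <- tumor_genome(f1, ev2)
  cs2 <- copy_state(t2, "chr4", c(89e6, 95e6, 10e6))
  expect_equal(unname(cs2[1, ]), c(0, 0))  # inside both events
  expect_equal(unname(cs2[2, ]), c(2, 0))  # CN-LOH only
  expect_equal(unname(cs2[3, ]), c(1, 1))  # untouched
  expect_error(copy_state(t2, "chr4", 200e6), "out of range")
})

test_that("physical copies account for strain-private deletions", {
  v11 <- registry[registry$chrom == "chr11", ]
  vpos <- (v11$start + v11$end) / 2
  f1 <- make_f1(2)  # donor variant on copy A, REFSTRAIN copy B
  expect_equal(physical_copies(f1, registry, "chr11", vpos), 1)
  expect_equal(physical_copies(f1, registry, "chr11", 1e6), 2)

  # tumor CN-LOH losing the REFSTRAIN copy: variant locus loses all DNA
  tum <- tumor_genome(f1, somatic_event("CN_LOH", "chr11", 50e6, 122e6, "B"))
  expect_equal(physical_copies(tum, registry, "chr11", vpos), 0)
  expect_equal(physical_copies(tum, registry, "chr11", 80e6), 2)

  # homozygous donor germline: zero physical copies in germline AND tumor
  expect_equal(physical_copies(donor_founder, registry, "chr11", vpos), 0)
  tum2 <- tumor_genome(donor_founder)
  expect_equal(physical_copies(tum2, registry, "chr11", vpos), 0)
})

test_that("coverage expectations follow physical copy number", {
  cov <- simulate_coverage(ref_founder, registry, layout, seed = 31)
  expect_true(all(cov$count >= 0))
  expect_equal(sum(cov$end - cov$start), sum(layout$chromosomes$length))
  # neutral diploid genome: mean bin count ~ mean_depth within 3 SE
  se <- stats::sd(cov$count) / sqrt(nrow(cov))
  expect_lt(abs(mean(cov$count) - 100), 3 * se)

  # bins fully inside a homozygous deletion get exactly zero counts
  v11 <- registry[registry$chrom == "chr11", ]
  cov_d <- simulate_coverage(donor_founder, registry, layout, seed = 32)
  inside <- cov_d$chrom == "chr11" & cov_d$start >= v11$start &
    cov_d$end <= v11$end
  expect_true(all(cov_d$count[inside] == 0))

  # germline-het variant bins: expected count mean_depth / 2
  f1 <- make_f1(3)
  counts <- unlist(lapply(1:30, function(s) {
    cv <- simulate_coverage(f1, registry, layout, seed = 100 + s)
    cv$count[cv$chrom == "chr11" & cv$start >= v11$start & cv$end <= v11$end]
  }))
  se <- stats::sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - 50), 3 * se)
})

test_that("allele counts read out haplotype state", {
  f1 <- make_f1(4)
  ac <- simulate_allele_counts(f1, registry, layout, seed = 41)
  vaf <- ac$alt_count / (ac$ref_count + ac$alt_count)
  se <- stats::sd(vaf) / sqrt(length(vaf))
  expect_lt(abs(mean(vaf) - 0.5), 3 * se)

  # pure donor: VAF 1 at every covered SNP, for several seeds
  for (s in 1:3) {
    ac_d <- simulate_allele_counts(donor_founder, registry, layout, seed = s)
    expect_true(all(ac_d$ref_count == 0))
    expect_gt(mean(ac_d$alt_count), 90)
  }
  # pure reference: not a single ALT read, ever
  for (s in 1:3) {
    ac_r <- simulate_allele_counts(ref_founder, registry, layout, seed = s)
    expect_true(all(ac_r$alt_count == 0))
  }
})

test_that("CN-LOH shifts allele frequency but conserves coverage", {
  f1 <- make_f1(5)
  tum <- tumor_genome(f1, somatic_event("CN_LOH", "chr11", 40e6, 122e6, "B"))
  gc_ <- simulate_coverage(f1, registry, layout, seed = 51)
  tc <- simulate_coverage(tum, registry, layout, seed = 52)
  v11 <- registry[registry$chrom == "chr11", ]
  in_loh <- gc_$chrom == "chr11" & gc_$start >= 40e6 &
    !(gc_$end > v11$start & gc_$start < v11$end)
  ratio <- mean(tc$count[in_loh]) / mean(gc_$count[in_loh])
  expect_lt(abs(ratio - 1), 0.02)

  ta <- simulate_allele_counts(tum, registry, layout, seed = 53)
  sel <- ta$chrom == "chr11" & ta$pos >= 41e6
  vaf <- ta$alt_count[sel] / (ta$ref_count[sel] + ta$alt_count[sel])
  expect_gt(mean(vaf, na.rm = TRUE), 0.99)

  # germline-cancels-germline: an event-free tumor matches its germline
  t0 <- tumor_genome(f1)
  tc0 <- simulate_coverage(t0, registry, layout, seed = 54)
  expect_lt(abs(mean(tc0$count) - mean(gc_$count)), 1.5)
})

test_that("tumor purity dilutes the somatic signal", {
  f1 <- make_f1(6)
  tum <- tumor_genome(f1, somatic_event("CN_LOH", "chr11", 40e6, 122e6, "B"))
  ta <- simulate_allele_counts(tum, registry, layout, seed = 61, purity = 0.6)
  sel <- ta$chrom == "chr11" & ta$pos >= 41e6
  vaf <- ta$alt_count[sel] / (ta$ref_count[sel] + ta$alt_count[sel])
  # expected VAF = (0.6 * 2 + 0.4 * 1) / 2 = 0.8
  expect_lt(abs(mean(vaf, na.rm = TRUE) - 0.8), 0.02)
})

test_that("driver-selected tumor simulation targets the wild-type haplotype", {
  f1 <- make_f1(7)  # driver on DONOR copy A
  for (s in 1:5) {
    tum <- simulate_kpc_tumor(f1, driver, s)
    ev <- tum$events
    expect_equal(nrow(ev), 1L)
    expect_identical(ev$type, "CN_LOH")
    expect_identical(ev$target_copy, "B")
    expect_true(ev$start <= driver$position && driver$position < ev$end)
  }
  # homozygous carrier: nothing to select against
  tum_h <- simulate_kpc_tumor(donor_founder, driver, 1)
  expect_equal(nrow(tum_h$events), 0L)
  expect_equal(unname(copy_state(tum_h, "chr11", 70e6)), matrix(1, 1, 2))
  # scenario with all events disabled
  tum_off <- simulate_kpc_tumor(f1, driver, 1,
                                scenario = list(driver_cnloh = FALSE))
  expect_equal(nrow(tum_off$events), 0L)
  expect_error(simulate_kpc_tumor(ref_founder, driver, 1), "engineered allele")
})

test_that("aCGH probe ratios reveal strain-private deletions", {
  probes <- make_probe_set(layout, spacing = 100000)
  f1 <- make_f1(8)
  t0 <- tumor_genome(f1)
  self <- simulate_acgh(t0, registry, probes, seed = 81)
  expect_lt(abs(mean(self$log2_ratio)), 0.01)
  expect_lt(stats::sd(self$log2_ratio), 0.2)

  # donor germline against the reference founder: deep negative ratios at the
  # variant locus (inter-strain hybridization design)
  v11 <- registry[registry$chrom == "chr11", ]
  acgh <- simulate_acgh(donor_founder, registry, probes, seed = 82,
                        reference = ref_founder)
  inside <- acgh$chrom == "chr11" & acgh$pos >= v11$start & acgh$pos < v11$end
  expect_true(any(inside))
  expect_lt(mean(acgh$log2_ratio[inside]), -1.5)
  expect_lt(abs(mean(acgh$log2_ratio[!inside & acgh$chrom == "chr11"])), 0.05)
})

test_that("readout tables round-trip through their TSV writers", {
  f1 <- make_f1(9)
  cov <- simulate_coverage(f1, registry, layout, seed = 91, sample_id = "m1")
  p1 <- withr::local_tempfile(fileext = ".tsv")
  write_coverage(cov, p1)
  cov2 <- read_coverage(p1, sample_id = "m1")
  expect_equal(cov2$count, cov$count)
  expect_equal(cov2$start, cov$start)

  ac <- simulate_allele_counts(f1, registry, layout, seed = 92, sample_id = "m1")
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_allele_counts(ac, p2)
  ac2 <- read_allele_counts(p2, sample_id = "m1")
  expect_equal(ac2$alt_count, ac$alt_count)

  p3 <- withr::local_tempfile(fileext = ".vcf")
  write_allele_counts_vcf(ac, p3)
  lines <- readLines(p3)
  expect_match(lines[1], "fileformat=VCFv4.2", fixed = TRUE)
  expect_equal(length(lines) - 3L, nrow(ac))
})
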