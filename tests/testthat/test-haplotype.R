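test_that("haplotype segmentation recovers founder and F1 states", {
  f1 <- make_f1(11)
  ac <- simulate_allele_counts(f1, registry, layout, seed = 111)
  segs <- call_haplotype_segments(ac, layout)
  # one HET segment per chromosome, spanning it fully (driver and variant
  # loci fall inside the same segment)
  expect_equal(nrow(segs), 2L)
  expect_true(all(segs$state == "HET"))
  expect_equal(segs$start, c(0, 0))
  expect_equal(sort(segs$end), sort(layout$chromosomes$length))

  ac_d <- simulate_allele_counts(donor_founder, registry, layout, seed = 112)
  segs_d <- call_haplotype_segments(ac_d, layout)
  expect_true(all(segs_d$state == "HOM_ALT"))
  expect_equal(nrow(segs_d), 2L)

  ac_r <- simulate_allele_counts(ref_founder, registry, layout, seed = 113)
  segs_r <- call_haplotype_segments(ac_r, layout)
  expect_true(all(segs_r$state == "HOM_REF"))

  empty <- ac[0, ]
  expect_equal(nrow(call_haplotype_segments(empty, layout)), 0L)
})

test_that("segment boundaries track true recombination breakpoints", {
  for (s in 1:3) {
    g <- make_f2(s)
    ac <- simulate_allele_counts(g, registry, layout, seed = 200 + s)
    segs <- call_haplotype_segments(ac, layout)
    conc <- haplotype_concordance(segs, g)
    expect_gte(conc, 0.95)
  }
})

test_that("concordance is 1 for perfect calls and 0 for inverted calls", {
  f1 <- make_f1(12)
  perfect <- data.frame(chrom = c("chr11", "chr4"), start = c(0, 0),
                        end = layout$chromosomes$length[
                          match(c("chr11", "chr4"), layout$chromosomes$name)],
                        state = "HET", n_snps = 1L, mean_vaf = 0.5)
  expect_equal(haplotype_concordance(perfect, f1), 1.0)
  wrong <- perfect
  wrong$state <- "HOM_REF"
  expect_equal(haplotype_concordance(wrong, f1), 0.0)
})

test_that("concordance does not degrade with deeper sequencing", {
  mean_conc <- function(depth) {
    mean(vapply(1:4, function(s) {
      g <- make_f2(100 + s)
      ac <- simulate_allele_counts(g, registry, layout, mean_depth = depth,
                                   seed = 300 + s)
      haplotype_concordance(call_haplotype_segments(ac, layout), g)
    }, double(1)))
  }
  c20 <- mean_conc(20)
  c50 <- mean_conc(50)
  c100 <- mean_conc(100)
  expect_lte(c20, c50 + 0.01)
  expect_lte(c50, c100 + 0.01)
})

test_that("CN-LOH is called with a copy-neutral mechanism", {
  f1 <- make_f1(13)
  tum <- simulate_kpc_tumor(f1, driver, 131)
  gc_ <- simulate_coverage(f1, registry, layout, seed = 132)
  tc <- simulate_coverage(tum, registry, layout, seed = 133)
  ga <- simulate_allele_counts(f1, registry, layout, seed = 134)
  ta <- simulate_allele_counts(tum, registry, layout, seed = 135)
  segs <- call_haplotype_segments(ga, layout)
  loh <- call_loh(segs, ta, tc, gc_, layout)
  hit <- loh[loh$chrom == "chr11" & loh$start <= driver$position &
               loh$end > driver$position, ]
  expect_equal(nrow(hit), 1L)
  expect_identical(hit$mechanism, "CN_LOH")
  expect_identical(hit$retained, "ALT")
  expect_gt(hit$coverage_ratio, 0.9)
  expect_lt(hit$coverage_ratio, 1.1)
  # call boundary tracks the true event start to within a SNP window
  true_start <- tum$events$start[1]
  expect_lt(abs(hit$start - true_start), 30 * 10000)
})

test_that("a tumor identical to its germline yields no LOH calls", {
  f1 <- make_f1(14)
  t0 <- tumor_genome(f1)
  gc_ <- simulate_coverage(f1, registry, layout, seed = 141)
  tc <- simulate_coverage(t0, registry, layout, seed = 142)
  ga <- simulate_allele_counts(f1, registry, layout, seed = 143)
  ta <- simulate_allele_counts(t0, registry, layout, seed = 144)
  segs <- call_haplotype_segments(ga, layout)
  expect_equal(nrow(call_loh(segs, ta, tc, gc_, layout)), 0L)
})

test_that("hemizygous focal deletions are labeled deletion-LOH", {
  f1 <- make_f1(15)
  tum <- tumor_genome(f1, somatic_event("FOCAL_DEL", "chr11", 30e6, 60e6, "B"))
  gc_ <- simulate_coverage(f1, registry, layout, seed = 151)
  tc <- simulate_coverage(tum, registry, layout, seed = 152)
  ga <- simulate_allele_counts(f1, registry, layout, seed = 153)
  ta <- simulate_allele_counts(tum, registry, layout, seed = 154)
  segs <- call_haplotype_segments(ga, layout)
  loh <- call_loh(segs, ta, tc, gc_, layout)
  hit <- loh[loh$chrom == "chr11" & loh$end > 30e6 & loh$start < 60e6, ]
  expect_equal(nrow(hit), 1L)
  expect_identical(hit$mechanism, "DELETION_LOH")
  expect_lt(hit$coverage_ratio, 0.7)
  expect_identical(hit$retained, "ALT")
})

test_that("LOH is never called over germline homozygosity", {
  # donor founder germline is HOM_ALT everywhere: no HET segments exist, so
  # even a genuine somatic CN-LOH event can produce no LOH call
  tum <- tumor_genome(donor_founder,
                      somatic_event("CN_LOH", "chr11", 40e6, 122e6, "B"))
  gc_ <- simulate_coverage(donor_founder, registry, layout, seed = 161)
  tc <- simulate_coverage(tum, registry, layout, seed = 162)
  ga <- simulate_allele_counts(donor_founder, registry, layout, seed = 163)
  ta <- simulate_allele_counts(tum, registry, layout, seed = 164)
  segs <- call_haplotype_segments(ga, layout)
  expect_false(any(segs$state == "HET"))
  expect_equal(nrow(call_loh(segs, ta, tc, gc_, layout)), 0L)
})

test_that("segment tables export as BED-dialect files", {
  f1 <- make_f1(16)
  ac <- simulate_allele_counts(f1, registry, layout, seed = 165)
  segs <- call_haplotype_segments(ac, layout)
  path <- withr::local_tempfile(fileext = ".bed")
  write_segments_bed(segs, path)
  lines <- readLines(path)
  expect_equal(length(lines), nrow(segs) + 1L)
  expect_match(lines[1], "^#chrom\tstart\tend")
})
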