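test_that("identical calls cluster with perfect breakpoint concordance", {
  calls <- data.frame(tumor_id = paste0("t", 1:4), chrom = "chr11",
                      start = 70980000, end = 71180000)
  ov <- overlay_cohort(calls)
  expect_equal(length(ov), 1L)
  expect_equal(nrow(ov[[1]]$members), 4L)
  expect_equal(ov[[1]]$concordance, 1.0)
  # recurrence mass conservation: profile integral equals summed lengths
  prof <- ov[[1]]$profile
  expect_equal(sum(prof$count * (prof$end - prof$start)),
               sum(calls$end - calls$start))
})

test_that("single calls carry no concordance and disjoint calls split", {
  one <- data.frame(tumor_id = "t1", chrom = "chr11", start = 1e6, end = 2e6)
  ov <- overlay_cohort(one)
  expect_equal(length(ov), 1L)
  expect_true(is.na(ov[[1]]$concordance))

  two <- data.frame(tumor_id = c("t1", "t2"), chrom = "chr11",
                    start = c(1e6, 5e6), end = c(2e6, 6e6))
  expect_equal(length(overlay_cohort(two)), 2L)
})

test_that("stepped deletions give near-zero concordance (pairwise oracle)", {
  # breakpoints uniform over +/- 2 Mb windows around a suppressor core
  sup <- 89280000
  n <- 10
  starts <- with_test_seed(42, floor(stats::runif(n, sup - 2e6, sup - 1e5)))
  ends <- with_test_seed(43, floor(stats::runif(n, sup + 1e5, sup + 2e6)))
  calls <- data.frame(tumor_id = paste0("t", 1:n), chrom = "chr4",
                      start = starts, end = ends)
  ov <- overlay_cohort(calls, tolerance_bins = 1, bin_size = 20000)
  expect_equal(length(ov), 1L)
  # brute-force pairwise agreement oracle
  agree <- 0; total <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    total <- total + 1
    if (abs(starts[i] - starts[j]) <= 20000 &&
        abs(ends[i] - ends[j]) <= 20000) agree <- agree + 1
  }
  expect_equal(ov[[1]]$concordance, agree / total)
  expect_lt(ov[[1]]$concordance, 0.2)
})

test_that("the three-way evidence rule classifies deterministically", {
  calls <- data.frame(tumor_id = paste0("t", 1:4), chrom = "chr11",
                      start = 70980000, end = 71180000)
  ov <- overlay_cohort(calls)
  loh <- data.frame(chrom = "chr11", start = 50e6, end = 122e6,
                    mechanism = "CN_LOH", retained = "ALT",
                    coverage_ratio = 1.0, mean_vaf = 0.99)
  verdict <- classify_cnv(calls[1, ], ov, registry, loh, drivers)
  expect_identical(verdict$classification, "GERMLINE_VARIANT_ARTIFACT")
  expect_true(verdict$matches_registry)
  expect_true(verdict$identical_breakpoints)
  expect_true(verdict$linked_driver_loh)
  expect_equal(verdict$distance_to_driver, 1.5e6)

  # no registry, only 2 members, no LOH: pure somatic candidate
  few <- data.frame(tumor_id = c("t1", "t2"), chrom = "chr4",
                    start = c(88e6, 88.8e6), end = c(90.4e6, 91e6))
  ov2 <- overlay_cohort(few)
  no_loh <- loh[0, ]
  verdict2 <- classify_cnv(few[1, ], ov2, registry, no_loh, drivers)
  expect_identical(verdict2$classification, "SOMATIC_CANDIDATE")
  expect_false(any(unlist(verdict2[c("matches_registry",
                                     "identical_breakpoints",
                                     "linked_driver_loh")])))

  # registry match without LOH context: ambiguous
  verdict3 <- classify_cnv(calls[1, ], ov, registry, no_loh, drivers)
  expect_identical(verdict3$classification, "AMBIGUOUS")

  # identical breakpoints alone (registry knockout) still flags the artifact
  verdict4 <- classify_cnv(calls[1, ], ov, strain_variant_registry(), loh,
                           drivers)
  expect_false(verdict4$matches_registry)
  expect_true(verdict4$identical_breakpoints)
  expect_identical(verdict4$classification, "GERMLINE_VARIANT_ARTIFACT")
})

test_that("het-carrier cohorts classify every variant-locus call as artifact", {
  cfg <- default_config()
  cfg$breeding$n_animals <- 4
  res <- run_cohort_pipeline(cfg, seed = 31)
  # mechanism guarantee: every tumor with driver CN-LOH shows the deletion
  cnloh_animals <- names(Filter(function(a) {
    any(a$events$type == "CN_LOH" & a$events$chrom == driver$chrom)
  }, res$animals))
  v11 <- registry[registry$chrom == "chr11", ]
  with_call <- unique(res$calls$tumor_id[
    res$calls$chrom == "chr11" & res$calls$end > v11$start &
      res$calls$start < v11$end])
  expect_setequal(with_call, cnloh_animals)
  expect_true(all(res$calls$classification == "GERMLINE_VARIANT_ARTIFACT"))

  # truth-based evaluation: artifact calls coincide with the germline variant
  # on the retained haplotype (sensitivity 1, no false positives)
  art <- res$calls[res$calls$classification == "GERMLINE_VARIANT_ARTIFACT", ]
  ro <- pmin((pmin(art$end, v11$end) - pmax(art$start, v11$start)) /
               (art$end - art$start),
             (pmin(art$end, v11$end) - pmax(art$start, v11$start)) /
               (v11$end - v11$start))
  expect_true(all(ro >= 0.9))
})

test_that("cohort runs are byte-identical under a fixed master seed", {
  cfg <- default_config()
  cfg$breeding$n_animals <- 2
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  r1 <- run_cohort_pipeline(cfg, seed = 99, outdir = d1)
  r2 <- run_cohort_pipeline(cfg, seed = 99, outdir = d2)
  f1 <- list.files(d1)
  expect_setequal(f1, list.files(d2))
  expect_gt(length(f1), 0)
  for (f in f1) {
    a <- file.path(d1, f); b <- file.path(d2, f)
    expect_identical(readBin(a, "raw", file.size(a)),
                     readBin(b, "raw", file.size(b)))
  }
  expect_equal(r1$summary, r2$summary)
  # manifest records config and seeds for reproducibility
  man <- jsonlite::read_json(file.path(d1, "manifest.json"))
  expect_equal(man$seed, 99)
  expect_equal(man$config$breeding$n_animals, 2)
})
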