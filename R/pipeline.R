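# End-to-end cohort pipeline: breeding -> tumors -> readouts -> calling ->
# cohort overlay -> artifact classification.

breed_animal <- function(scheme, donor, ref, driver, n_generations, seed,
                         max_attempts = 10000) {
  switch(
    scheme,
    f1 = cross(donor, ref, seed),
    driver_homozygous = {
      f1a <- cross(donor, ref, derive_seed(seed, 1))
      f1b <- cross(donor, ref, derive_seed(seed, 2))
      for (k in seq_len(max_attempts)) {
        off <- cross(f1a, f1b, derive_seed(seed, 2 + k))
        if (driver_zygosity(off, driver) == 2) return(off)
      }
      stop_config("failed to breed a driver-homozygous animal in %d attempts",
                  max_attempts)
    },
    backcross = backcross_scheme(donor, ref, n_generations, driver, seed),
    stop_config("breeding.scheme must be one of f1, driver_homozygous, backcross (got '%s')",
                scheme)
  )
}

# Run simulation + calling for one animal. Returns calls and light metadata;
# readout tables are written to `outdir` (if given) and then dropped.
run_animal <- function(animal_id, germline, tumor, registry, layout, drivers,
                       cfg, seed, outdir = NULL) {
  rd <- cfg$readout
  cal <- cfg$calling
  germ_cov <- simulate_coverage(germline, registry, layout, rd$bin_size,
                                rd$mean_depth, rd$dispersion,
                                derive_seed(seed, 102),
                                sample_id = paste0(animal_id, "_germline"))
  tum_cov <- simulate_coverage(tumor, registry, layout, rd$bin_size,
                               rd$mean_depth, rd$dispersion,
                               derive_seed(seed, 103), purity = rd$purity,
                               sample_id = paste0(animal_id, "_tumor"))
  germ_ac <- simulate_allele_counts(germline, registry, layout, rd$mean_depth,
                                    derive_seed(seed, 104),
                                    sample_id = paste0(animal_id, "_germline"))
  tum_ac <- simulate_allele_counts(tumor, registry, layout, rd$mean_depth,
                                   derive_seed(seed, 105), purity = rd$purity,
                                   sample_id = paste0(animal_id, "_tumor"))
  germ_segments <- call_haplotype_segments(germ_ac, layout, cal)
  ratios <- compute_log_ratios(tum_cov, germ_cov, cal$pseudocount)
  segs <- call_segments(segment_log_ratios(ratios, cal$penalty), cal)
  loh <- call_loh(germ_segments, tum_ac, tum_cov, germ_cov, layout, cal)
  if (!is.null(outdir)) {
    pre <- file.path(outdir, animal_id)
    write_coverage(germ_cov, paste0(pre, "_germline_coverage.tsv"))
    write_coverage(tum_cov, paste0(pre, "_tumor_coverage.tsv"))
    write_allele_counts(germ_ac, paste0(pre, "_germline_snv.tsv"))
    write_allele_counts(tum_ac, paste0(pre, "_tumor_snv.tsv"))
    write_segments_bed(germ_segments, paste0(pre, "_germline_haplotypes.bed"))
    write_segments_bed(loh, paste0(pre, "_loh.bed"))
    write_seg(segs, paste0(pre, "_cnv.seg"), sample_id = animal_id)
  }
  list(animal_id = animal_id,
       germline_truth = mosaics_to_bed(germline),
       events = tumor$events,
       germ_segments = germ_segments,
       segments = segs,
       loh = loh)
}

#' Run the full cohort simulation and confound-classification pipeline
#'
#' Breeds `n_animals` germlines under the configured scheme, simulates one
#' driver-selected tumor per animal, generates tumor and germline readouts,
#' reconstructs germline haplotypes, calls LOH and copy-number segments,
#' overlays homozygous-loss calls across the cohort, and classifies each call
#' as germline-variant artifact, somatic candidate, or ambiguous. Fully
#' deterministic given `config` and the master `seed` (per-animal seeds are
#' derived by fixed arithmetic).
#'
#' @param config Configuration list (see [default_config()]).
#' @param seed Master integer seed.
#' @param outdir Optional output directory; when given, per-animal readouts
#'   and calls, the cohort summary tables, and a reproducibility manifest
#'   (config + seeds) are written there.
#' @return A list with elements `layout`, `registry`, `drivers`, `animals`
#'   (per-animal results), `calls` (classified homozygous-loss calls),
#'   `overlays`, `summary` (classification counts), and `variant_summary`
#'   (per registry variant, number of animals with an overlapping
#'   homozygous-loss call).
#' @export
run_cohort_pipeline <- function(config = default_config(), seed, outdir = NULL) {
  built <- build_default_layout(config)
  layout <- built$layout
  registry <- built$registry
  drivers <- built$drivers
  eng <- drivers[drivers$engineered, , drop = FALSE]
  if (!nrow(eng)) stop_config("config$genome$drivers must include an engineered driver")
  driver <- eng[1, , drop = FALSE]

  scenario <- config$tumor
  if (isTRUE(scenario$suppressor_scenario)) {
    sup <- drivers[!drivers$engineered, , drop = FALSE]
    if (!nrow(sup)) stop_config("suppressor_scenario requires a non-engineered driver locus")
    scenario$suppressor <- sup[1, , drop = FALSE]
  }

  if (!is.null(outdir) && !dir.exists(outdir)) {
    dir.create(outdir, recursive = TRUE)
  }

  n <- config$breeding$n_animals
  donor <- founder_genome(layout, "DONOR")
  ref <- founder_genome(layout, "REFSTRAIN")
  animal_seeds <- vapply(seq_len(n), function(i) derive_seed(seed, i * 1000L),
                         integer(1))
  animals <- vector("list", n)
  all_calls <- list()
  for (i in seq_len(n)) {
    id <- sprintf("animal_%02d", i)
    s <- animal_seeds[i]
    germline <- breed_animal(config$breeding$scheme, donor, ref, driver,
                             config$breeding$n_generations, s)
    tumor <- simulate_kpc_tumor(germline, driver, derive_seed(s, 101), scenario)
    res <- run_animal(id, germline, tumor, registry, layout, drivers,
                      config, s, outdir)
    animals[[i]] <- res
    hom <- res$segments[res$segments$call == "HOM_LOSS", , drop = FALSE]
    if (nrow(hom)) {
      all_calls[[length(all_calls) + 1]] <-
        data.frame(tumor_id = id, chrom = hom$chrom, start = hom$start,
                   end = hom$end, log2_ratio = hom$log2_ratio)
    }
  }
  names(animals) <- vapply(animals, `[[`, character(1), "animal_id")
  calls <- if (length(all_calls)) do.call(rbind, all_calls) else
    data.frame(tumor_id = character(), chrom = character(), start = double(),
               end = double(), log2_ratio = double())

  overlays <- overlay_cohort(calls, config$calling$tolerance_bins,
                             config$readout$bin_size)
  verdicts <- do.call(rbind, lapply(seq_len(nrow(calls)), function(j) {
    call <- calls[j, , drop = FALSE]
    classify_cnv(call, overlays, registry, animals[[call$tumor_id]]$loh,
                 drivers, config$calling)
  }))
  if (is.null(verdicts)) {
    verdicts <- data.frame(tumor_id = character(), chrom = character(),
                           start = double(), end = double(),
                           log2_ratio = double(), classification = character(),
                           matches_registry = logical(),
                           identical_breakpoints = logical(),
                           linked_driver_loh = logical(),
                           distance_to_driver = double())
  }
  rownames(verdicts) <- NULL

  cls <- c("GERMLINE_VARIANT_ARTIFACT", "SOMATIC_CANDIDATE", "AMBIGUOUS")
  summary <- data.frame(
    classification = cls,
    n_calls = vapply(cls, function(x) sum(verdicts$classification == x),
                     double(1)))
  rownames(summary) <- NULL
  variant_summary <- do.call(rbind, lapply(seq_len(nrow(registry)), function(v) {
    hit <- verdicts$chrom == registry$chrom[v] &
      verdicts$end > registry$start[v] & verdicts$start < registry$end[v]
    data.frame(variant_id = registry$id[v],
               n_animals_with_call = length(unique(verdicts$tumor_id[hit])),
               n_animals = n)
  })) %||% data.frame(variant_id = character(), n_animals_with_call = double(),
                      n_animals = double())
  rownames(variant_summary) <- NULL

  result <- list(layout = layout, registry = registry, drivers = drivers,
                 animals = animals, calls = verdicts, overlays = overlays,
                 summary = summary, variant_summary = variant_summary,
                 seed = seed, animal_seeds = animal_seeds, config = config)

  if (!is.null(outdir)) {
    write_tsv_plain(verdicts, file.path(outdir, "cohort_calls.tsv"))
    write_tsv_plain(summary, file.path(outdir, "cohort_summary.tsv"))
    write_tsv_plain(variant_summary, file.path(outdir, "variant_summary.tsv"))
    manifest <- list(config = config, seed = seed, animal_seeds = animal_seeds,
                     n_animals = n)
    json <- jsonlite::toJSON(manifest, pretty = TRUE, auto_unbox = TRUE,
                             digits = NA)
    writeLines(json, file.path(outdir, "manifest.json"), useBytes = TRUE)
  }
  result
}

# Deterministic TSV writer (fixed formatting, LF endings, no quoting).
write_tsv_plain <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(names(df), collapse = "\t"), con, useBytes = TRUE)
  if (nrow(df)) {
    cols <- lapply(df, function(col) {
      if (is.numeric(col)) format(col, scientific = FALSE, trim = TRUE, digits = 10)
      else as.character(col)
    })
    writeLines(do.call(paste, c(cols, sep = "\t")), con, useBytes = TRUE)
  }
  invisible(path)
}
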