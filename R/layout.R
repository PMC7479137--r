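#' Default simulation configuration
#'
#' Returns the nested configuration list used throughout the package. The
#' synthetic genome emulates the geometry of the confounded loci in inbred
#' mouse crosses: a chr11-like chromosome carrying an engineered driver allele
#' (Trp53-like) 1.5 Mb from a 200 kb donor-strain deletion variant
#' (Nlrp1-like), and a chr4-like chromosome carrying a tumor-suppressor locus
#' (Cdkn2a-like) plus a second donor-strain deletion variant (Skint-like).
#'
#' Sections:
#' \describe{
#'   \item{genome}{chromosome names/lengths (bp), recombination rate
#'     (cM/Mb), diagnostic-SNP grid spacing and jitter, driver loci and
#'     strain-private deletion variants.}
#'   \item{breeding}{cohort scheme (\code{"f1"}, \code{"driver_homozygous"} or
#'     \code{"backcross"}), cohort size, backcross generations.}
#'   \item{tumor}{somatic-event scenario: driver CN-LOH and the optional
#'     two-step suppressor-deletion-then-CN-LOH scenario.}
#'   \item{readout}{coverage bin size, mean depths, negative-binomial
#'     dispersion, tumor purity, aCGH noise, log pseudo-copy epsilon.}
#'   \item{calling}{VAF thresholds, window size, coverage-ratio windows for
#'     LOH mechanism, segmentation penalty, copy-number call thresholds,
#'     cohort concordance parameters.}
#' }
#'
#' @return A nested named list.
#' @export
default_config <- function() {
  list(
    genome = list(
      chromosomes = list(
        list(name = "chr11", length = 122000000),
        list(name = "chr4", length = 156000000)
      ),
      map_rate = 0.5,          # cM per Mb, uniform (Haldane)
      snp_spacing = 10000,     # one diagnostic SNP per 10 kb
      snp_jitter = 0.25,       # jitter amplitude as fraction of spacing
      snp_seed = 20,           # seed for the grid jitter (layout is deterministic)
      drivers = list(
        list(id = "Trp53like", chrom = "chr11", position = 69580000,
             origin_strain = "DONOR", loh_selected = TRUE, engineered = TRUE),
        list(id = "Cdkn2alike", chrom = "chr4", position = 89280000,
             origin_strain = "DONOR", loh_selected = TRUE, engineered = FALSE)
      ),
      variants = list(
        list(id = "Nlrp1like_del", chrom = "chr11",
             start = 70980000, end = 71180000,
             carrier_strain = "DONOR", kind = "deletion"),
        list(id = "Skintlike_del", chrom = "chr4",
             start = 112000000, end = 112600000,
             carrier_strain = "DONOR", kind = "deletion")
      )
    ),
    breeding = list(
      scheme = "f1",
      n_animals = 8,
      n_generations = 10
    ),
    tumor = list(
      driver_cnloh = TRUE,
      cnloh_max_upstream = 20000000,  # CN-LOH start drawn uniformly this far upstream of the driver
      suppressor_scenario = FALSE,
      suppressor_del_window = 2000000, # focal-deletion breakpoints drawn in +/- this window
      suppressor_del_core = 100000     # minimal deleted flank either side of the suppressor
    ),
    readout = list(
      bin_size = 20000,
      mean_depth = 100,
      dispersion = 0.05,
      purity = 1.0,
      acgh_noise_sd = 0.15,
      epsilon = 0.5
    ),
    calling = list(
      window_snps = 25,
      min_depth = 10,
      t_lo = 0.15,
      t_hi = 0.85,
      r_lo = 0.8,
      r_hi = 1.2,
      r_del = 0.7,
      pseudocount = 0.5,
      penalty = 1.0,
      hom_loss = -2.0,
      het_loss = -0.35,
      gain = 0.3,
      tolerance_bins = 1,
      concordance_min = 0.9,
      min_members = 3,
      reciprocal_overlap = 0.9
    )
  )
}

#' Read a configuration file
#'
#' Reads a YAML (or JSON) configuration file and merges it over
#' [default_config()]: any field not present in the file keeps its default.
#'
#' @param path Path to a YAML/JSON config file.
#' @return A nested named list as from [default_config()].
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop_config("config file not found: %s", path)
  user <- yaml::read_yaml(path)
  merge_config(default_config(), user)
}

merge_config <- function(base, user) {
  if (!is.list(user)) return(user)
  for (nm in names(user)) {
    if (nm %in% names(base) && is.list(base[[nm]]) && !is.null(names(base[[nm]]))) {
      base[[nm]] <- merge_config(base[[nm]], user[[nm]])
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

#' Construct a genome layout
#'
#' A genome layout holds the chromosomes of the two-founder synthetic genome,
#' the uniform recombination rate, and the positions of strain-diagnostic SNPs
#' (sites where the donor strain carries ALT and the reference strain REF,
#' each with probability 1 — which is what makes SNP allele frequency a direct
#' haplotype readout).
#'
#' @param chromosomes data.frame with columns `name`, `length` (bp).
#' @param map_rate Recombination rate in cM per Mb (uniform along the genome).
#' @param snp_positions Named list (per chromosome) of strictly increasing
#'   0-based SNP positions in `[0, length)`.
#' @return An object of class `genome_layout`.
#' @export
genome_layout <- function(chromosomes, map_rate, snp_positions) {
  stopifnot(is.data.frame(chromosomes), all(c("name", "length") %in% names(chromosomes)))
  if (any(chromosomes$length <= 0)) stop_config("chromosome lengths must be > 0")
  if (anyDuplicated(chromosomes$name)) stop_config("duplicate chromosome names")
  if (!is.numeric(map_rate) || map_rate <= 0) stop_config("map_rate must be > 0")
  for (nm in names(snp_positions)) {
    p <- snp_positions[[nm]]
    len <- chromosomes$length[match(nm, chromosomes$name)]
    if (is.na(len)) stop_config("snp_positions for unknown chromosome '%s'", nm)
    if (length(p) && (is.unsorted(p, strictly = TRUE) || p[1] < 0 || p[length(p)] >= len)) {
      stop_config("snp_positions for '%s' must be strictly increasing within [0, length)", nm)
    }
  }
  structure(
    list(chromosomes = chromosomes, map_rate = map_rate,
         snp_positions = snp_positions),
    class = "genome_layout"
  )
}

chrom_length <- function(layout, chrom) {
  len <- layout$chromosomes$length[match(chrom, layout$chromosomes$name)]
  if (any(is.na(len))) stop_config("unknown chromosome '%s'", chrom[is.na(len)][1])
  len
}

#' @export
print.genome_layout <- function(x, ...) {
  cat("<genome_layout>", nrow(x$chromosomes), "chromosomes,",
      sum(lengths(x$snp_positions)), "diagnostic SNPs,",
      x$map_rate, "cM/Mb\n")
  invisible(x)
}

#' Build the default two-chromosome layout, variant registry and driver loci
#'
#' Constructs the synthetic genome from the `genome` section of the
#' configuration: a chr11-like chromosome where the engineered driver and the
#' midpoint of the donor-strain deletion variant are separated by 1.5 Mb
#' (tight genetic linkage), and a chr4-like chromosome with a tumor-suppressor
#' locus and a second donor-strain deletion. Diagnostic SNP positions are laid
#' on a regular grid (one per `snp_spacing` bp) and perturbed by seeded
#' uniform jitter of at most `snp_jitter * snp_spacing`, which keeps them
#' strictly increasing.
#'
#' @param config Configuration list as from [default_config()].
#' @return A list with elements `layout` ([genome_layout]), `registry`
#'   ([strain_variant_registry]) and `drivers` (data.frame of driver loci with
#'   columns id, chrom, position, origin_strain, loh_selected, engineered).
#' @export
build_default_layout <- function(config = default_config()) {
  g <- config$genome
  chroms <- do.call(rbind, lapply(g$chromosomes, function(ch) {
    data.frame(name = ch$name, length = as.double(ch$length))
  }))
  spacing <- g$snp_spacing
  if (!is.numeric(spacing) || spacing <= 0) stop_config("snp_spacing must be > 0")
  jit <- g$snp_jitter %||% 0.25
  if (jit < 0 || jit >= 0.5) stop_config("snp_jitter must be in [0, 0.5)")
  snp_positions <- with_seed(g$snp_seed %||% 20, {
    out <- list()
    for (i in seq_len(nrow(chroms))) {
      n <- floor(chroms$length[i] / spacing)
      centers <- spacing / 2 + (seq_len(n) - 1) * spacing
      u <- round(stats::runif(n, -jit * spacing, jit * spacing))
      out[[chroms$name[i]]] <- pmin(pmax(centers + u, 0), chroms$length[i] - 1)
    }
    out
  })
  variants <- if (length(g$variants)) {
    do.call(rbind, lapply(g$variants, function(v) {
      data.frame(chrom = v$chrom, start = as.double(v$start),
                 end = as.double(v$end), id = v$id,
                 carrier_strain = v$carrier_strain, kind = v$kind %||% "deletion")
    }))
  } else {
    empty_registry_df()
  }
  # Sites inside a strain-private deletion cannot be strain-diagnostic SNPs:
  # the carrier strain has no allele there. Drop grid positions falling
  # inside any registry variant interval.
  if (nrow(variants)) {
    for (nm in names(snp_positions)) {
      v <- variants[variants$chrom == nm, , drop = FALSE]
      p <- snp_positions[[nm]]
      for (j in seq_len(nrow(v))) {
        p <- p[p < v$start[j] | p >= v$end[j]]
      }
      snp_positions[[nm]] <- p
    }
  }
  layout <- genome_layout(chroms, g$map_rate, snp_positions)
  registry <- strain_variant_registry(variants, layout)

  drivers <- do.call(rbind, lapply(g$drivers, function(d) {
    data.frame(id = d$id, chrom = d$chrom, position = as.double(d$position),
               origin_strain = d$origin_strain,
               loh_selected = isTRUE(d$loh_selected),
               engineered = isTRUE(d$engineered))
  }))
  if (!is.null(drivers)) {
    len <- chrom_length(layout, drivers$chrom)
    if (any(drivers$position < 0 | drivers$position >= len)) {
      stop_config("driver position outside its chromosome")
    }
  }
  list(layout = layout, registry = registry, drivers = drivers)
}

empty_registry_df <- function() {
  data.frame(chrom = character(), start = double(), end = double(),
             id = character(), carrier_strain = character(), kind = character())
}

#' Construct a strain-variant registry
#'
#' The registry catalogs deletion variants private to one founder strain
#' relative to the reference strain's genome (the Nlrp1-like and Skint-like
#' analogs). On carrier haplotypes a registry deletion removes all diagnostic
#' SNPs and all sequencing coverage inside `[start, end)`.
#'
#' @param variants data.frame with columns chrom, start, end, id,
#'   carrier_strain, kind. Coordinates are 0-based half-open (BED convention).
#' @param layout Optional [genome_layout] used to validate coordinates.
#' @return data.frame of class `strain_registry`, sorted by (chrom, start).
#' @export
strain_variant_registry <- function(variants = empty_registry_df(), layout = NULL) {
  need <- c("chrom", "start", "end", "id", "carrier_strain", "kind")
  if (!all(need %in% names(variants))) {
    stop_config("registry requires columns: %s", paste(need, collapse = ", "))
  }
  variants <- variants[, need]
  if (nrow(variants)) {
    if (any(variants$start < 0 | variants$start >= variants$end)) {
      stop_config("registry variants must satisfy 0 <= start < end")
    }
    if (anyDuplicated(variants$id)) stop_config("registry variant ids must be unique")
    if (!is.null(layout)) {
      len <- chrom_length(layout, variants$chrom)
      if (any(variants$end > len)) stop_config("registry variant exceeds chromosome length")
    }
    variants <- variants[order(variants$chrom, variants$start), , drop = FALSE]
    rownames(variants) <- NULL
    # same-strain variants must not overlap on a chromosome
    for (key in unique(paste(variants$chrom, variants$carrier_strain))) {
      sel <- paste(variants$chrom, variants$carrier_strain) == key
      v <- variants[sel, , drop = FALSE]
      if (nrow(v) > 1 && any(v$start[-1] < v$end[-nrow(v)])) {
        stop_config("overlapping same-strain variants on %s", v$chrom[1])
      }
    }
  }
  class(variants) <- c("strain_registry", "data.frame")
  variants
}

#' Read a strain-variant registry from a BED-dialect file
#'
#' Expects a tab-separated BED6+ dialect with columns chrom, start, end, id,
#' carrier_strain, kind (0-based half-open coordinates). Lines starting with
#' `#` are treated as headers/comments. Round-trips byte-identically with
#' [write_registry()] for sorted input.
#'
#' @param path File path.
#' @param layout Optional [genome_layout] for coordinate validation.
#' @return A `strain_registry` data.frame.
#' @export
read_registry <- function(path, layout = NULL) {
  if (!file.exists(path)) stop_config("registry file not found: %s", path)
  lines <- readLines(path, encoding = "UTF-8")
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  rows <- which(keep)
  if (!length(rows)) return(strain_variant_registry(empty_registry_df(), layout))
  parts <- strsplit(lines[rows], "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 6)
  if (length(bad)) {
    stop_config("registry parse error at line %d: expected 6 tab-separated fields",
                rows[bad[1]])
  }
  m <- do.call(rbind, parts)
  start <- suppressWarnings(as.double(m[, 2]))
  end <- suppressWarnings(as.double(m[, 3]))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad)) {
    stop_config("registry parse error at line %d: malformed coordinates", rows[bad[1]])
  }
  bad <- which(start < 0 | start >= end)
  if (length(bad)) {
    stop_config("registry parse error at line %d: start must be < end and >= 0",
                rows[bad[1]])
  }
  df <- data.frame(chrom = m[, 1], start = start, end = end, id = m[, 4],
                   carrier_strain = m[, 5], kind = m[, 6])
  strain_variant_registry(df, layout)
}

#' Write a strain-variant registry to a BED-dialect file
#'
#' Tab-separated, sorted by (chrom, start), with a single `#`-prefixed header
#' line. An empty registry yields a header-only file.
#'
#' @param registry A `strain_registry` data.frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_registry <- function(registry, path) {
  registry <- strain_variant_registry(as.data.frame(registry))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines("#chrom\tstart\tend\tid\tcarrier_strain\tkind", con, useBytes = TRUE)
  if (nrow(registry)) {
    lines <- sprintf("%s\t%s\t%s\t%s\t%s\t%s",
                     registry$chrom,
                     format(registry$start, scientific = FALSE, trim = TRUE),
                     format(registry$end, scientific = FALSE, trim = TRUE),
                     registry$id, registry$carrier_strain, registry$kind)
    writeLines(enc2utf8(lines), con, useBytes = TRUE)
  }
  invisible(path)
}

# Registry variants carried by `strain` on `chrom` (possibly none).
registry_for <- function(registry, chrom, strain) {
  registry[registry$chrom == chrom & registry$carrier_strain == strain, , drop = FALSE]
}
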