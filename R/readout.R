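# WES-like observables: binned coverage, per-SNP allele counts, aCGH probes.

# Piecewise-constant expected physical copy number along one chromosome.
# Returns breakpoints `bp` (length k+1) and per-piece values `value` (length k).
expected_copies_piecewise <- function(genome, registry, chrom, purity = 1) {
  germ <- germline_of(genome)
  len <- chrom_length(germ$layout, chrom)
  h <- germ$haplotypes[[chrom]]
  bp <- c(0, len, h$A$start, h$A$end, h$B$start, h$B$end)
  if (inherits(genome, "tumor_genome")) {
    ev <- genome$events[genome$events$chrom == chrom, , drop = FALSE]
    bp <- c(bp, ev$start, ev$end)
  }
  v <- registry[registry$chrom == chrom, , drop = FALSE]
  bp <- c(bp, v$start, v$end)
  bp <- sort(unique(pmin(pmax(bp, 0), len)))
  mids <- (bp[-1] + bp[-length(bp)]) / 2
  pc <- physical_copies(genome, registry, chrom, mids)
  if (purity < 1) {
    pc_g <- physical_copies(germ, registry, chrom, mids)
    pc <- purity * pc + (1 - purity) * pc_g
  }
  list(bp = bp, value = pc)
}

# Mean of a piecewise-constant function over [starts, ends) intervals.
piecewise_mean <- function(pw, starts, ends) {
  cum <- c(0, cumsum(pw$value * diff(pw$bp)))
  f <- stats::approxfun(pw$bp, cum, rule = 2)
  (f(ends) - f(starts)) / (ends - starts)
}

chrom_bins <- function(len, bin_size) {
  starts <- seq(0, len - 1, by = bin_size)
  data.frame(start = starts, end = pmin(starts + bin_size, len))
}

#' Simulate a binned coverage profile
#'
#' Genome-wide binned read counts for one sample. Each bin's expected count is
#' `mean_depth * (mean physical copies over the bin) / 2`; counts are drawn
#' negative-binomial with the given dispersion (Poisson when `dispersion = 0`).
#' Tumor purity below 1 mixes the germline expectation in at fraction
#' `1 - purity`.
#'
#' @param genome A [diploid_genome] or [tumor_genome].
#' @param registry A `strain_registry`.
#' @param layout A [genome_layout].
#' @param bin_size Bin size in bp (a final short bin closes each chromosome).
#' @param mean_depth Expected count per diploid-neutral bin.
#' @param dispersion Negative-binomial dispersion (variance =
#'   `mu + dispersion * mu^2`).
#' @param seed Integer seed.
#' @param purity Tumor cell fraction in `[0, 1]`.
#' @param sample_id Sample identifier carried in the output.
#' @return data.frame of class `coverage_profile` with columns chrom, start,
#'   end, count; attributes `sample_id` and `bin_size`.
#' @export
simulate_coverage <- function(genome, registry, layout, bin_size = 20000,
                              mean_depth = 100, dispersion = 0.05, seed,
                              purity = 1, sample_id = "sample") {
  if (mean_depth <= 0) stop_config("mean_depth must be > 0")
  with_seed(seed, {
    out <- lapply(seq_len(nrow(layout$chromosomes)), function(i) {
      nm <- layout$chromosomes$name[i]
      len <- layout$chromosomes$length[i]
      bins <- chrom_bins(len, bin_size)
      pw <- expected_copies_piecewise(genome, registry, nm, purity)
      mu <- mean_depth * piecewise_mean(pw, bins$start, bins$end) / 2
      counts <- if (dispersion > 0) {
        stats::rnbinom(nrow(bins), size = 1 / dispersion, mu = mu)
      } else {
        stats::rpois(nrow(bins), mu)
      }
      data.frame(chrom = nm, start = bins$start, end = bins$end, count = counts)
    })
    prof <- do.call(rbind, out)
    rownames(prof) <- NULL
    structure(prof, sample_id = sample_id, bin_size = bin_size,
              class = c("coverage_profile", "data.frame"))
  })
}

#' Simulate per-SNP allele counts
#'
#' For each diagnostic SNP, total depth is Poisson with mean
#' `mean_depth * physical_copies / 2` and the ALT (donor-allele) count is
#' binomial with success probability equal to the fraction of surviving
#' copies that are donor-origin. SNPs inside a deletion on a haplotype
#' receive no reads from that haplotype; where no physical copies survive the
#' depth is zero.
#'
#' @inheritParams simulate_coverage
#' @param mean_depth Expected depth per SNP at neutral diploid state.
#' @param donor_strain Founder whose haplotypes carry the ALT allele.
#' @return data.frame of class `allele_count_table` with columns chrom, pos,
#'   ref_count, alt_count; attribute `sample_id`.
#' @export
simulate_allele_counts <- function(genome, registry, layout, mean_depth = 100,
                                   seed, purity = 1, sample_id = "sample",
                                   donor_strain = "DONOR") {
  if (mean_depth <= 0) stop_config("mean_depth must be > 0")
  germ <- germline_of(genome)
  with_seed(seed, {
    out <- lapply(names(layout$snp_positions), function(nm) {
      pos <- layout$snp_positions[[nm]]
      if (!length(pos)) return(NULL)
      d <- copy_detail(genome, registry, nm, pos)
      pc <- rowSums(d$copies)
      alt_copies <- rowSums(d$copies * (d$strains == donor_strain))
      if (purity < 1) {
        dg <- copy_detail(germ, registry, nm, pos)
        pc <- purity * pc + (1 - purity) * rowSums(dg$copies)
        alt_copies <- purity * alt_copies +
          (1 - purity) * rowSums(dg$copies * (dg$strains == donor_strain))
      }
      depth <- stats::rpois(length(pos), mean_depth * pc / 2)
      p_alt <- ifelse(pc > 0, alt_copies / pc, 0)
      alt <- stats::rbinom(length(pos), depth, p_alt)
      data.frame(chrom = nm, pos = pos, ref_count = depth - alt, alt_count = alt)
    })
    tab <- do.call(rbind, out)
    rownames(tab) <- NULL
    structure(tab, sample_id = sample_id,
              class = c("allele_count_table", "data.frame"))
  })
}

#' Build a regular aCGH-like probe set
#'
#' @param layout A [genome_layout].
#' @param spacing Probe spacing in bp.
#' @return data.frame with columns chrom, pos.
#' @export
make_probe_set <- function(layout, spacing = 10000) {
  out <- lapply(seq_len(nrow(layout$chromosomes)), function(i) {
    len <- layout$chromosomes$length[i]
    data.frame(chrom = layout$chromosomes$name[i],
               pos = seq(spacing / 2, len - 1, by = spacing))
  })
  do.call(rbind, out)
}

#' Simulate aCGH-like probe log2 ratios
#'
#' Per probe, `log2((test physical copies + eps) / (reference physical copies
#' + eps))` plus Gaussian noise. The reference can be the same animal's
#' germline (tumor/germline design) or any other genome such as the pure
#' reference-strain founder (inter-strain hybridization design, which is how
#' strain-private germline deletions are seen directly).
#'
#' @param tumor A [tumor_genome] or [diploid_genome] (test channel).
#' @param registry A `strain_registry`.
#' @param probes data.frame with columns chrom, pos (see [make_probe_set()]).
#' @param noise_sd Gaussian noise standard deviation on log2 ratios.
#' @param seed Integer seed.
#' @param reference `"germline"` or a [diploid_genome]/[tumor_genome].
#' @param epsilon Pseudo-copy added to both channels to avoid log of zero.
#' @return `probes` with an added `log2_ratio` column.
#' @export
simulate_acgh <- function(tumor, registry, probes, noise_sd = 0.15, seed,
                          reference = "germline", epsilon = 0.5) {
  ref <- if (identical(reference, "germline")) germline_of(tumor) else reference
  with_seed(seed, {
    ratios <- numeric(nrow(probes))
    for (nm in unique(probes$chrom)) {
      sel <- probes$chrom == nm
      pos <- probes$pos[sel]
      pc_t <- physical_copies(tumor, registry, nm, pos)
      pc_r <- physical_copies(ref, registry, nm, pos)
      ratios[sel] <- log2((pc_t + epsilon) / (pc_r + epsilon))
    }
    probes$log2_ratio <- ratios + stats::rnorm(nrow(probes), 0, noise_sd)
    probes
  })
}

#' Write a coverage profile as TSV
#'
#' Columns chrom, start, end, count, with a `#`-prefixed header.
#' @param profile A `coverage_profile`.
#' @param path Output path.
#' @export
write_coverage <- function(profile, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines("#chrom\tstart\tend\tcount", con, useBytes = TRUE)
  writeLines(sprintf("%s\t%s\t%s\t%d", profile$chrom,
                     format(profile$start, scientific = FALSE, trim = TRUE),
                     format(profile$end, scientific = FALSE, trim = TRUE),
                     profile$count), con, useBytes = TRUE)
  invisible(path)
}

#' Read a coverage profile written by [write_coverage()]
#' @param path File path.
#' @param sample_id Sample identifier to attach.
#' @export
read_coverage <- function(path, sample_id = "sample") {
  df <- utils::read.table(path, sep = "\t", comment.char = "#",
                          col.names = c("chrom", "start", "end", "count"),
                          colClasses = c("character", "double", "double", "integer"))
  structure(df, sample_id = sample_id,
            bin_size = if (nrow(df)) max(df$end - df$start) else NA_real_,
            class = c("coverage_profile", "data.frame"))
}

#' Write an allele count table as TSV
#' @param counts An `allele_count_table`.
#' @param path Output path.
#' @export
write_allele_counts <- function(counts, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines("#chrom\tpos\tref_count\talt_count", con, useBytes = TRUE)
  writeLines(sprintf("%s\t%s\t%d\t%d", counts$chrom,
                     format(counts$pos, scientific = FALSE, trim = TRUE),
                     counts$ref_count, counts$alt_count), con, useBytes = TRUE)
  invisible(path)
}

#' Read an allele count table written by [write_allele_counts()]
#' @param path File path.
#' @param sample_id Sample identifier to attach.
#' @export
read_allele_counts <- function(path, sample_id = "sample") {
  df <- utils::read.table(path, sep = "\t", comment.char = "#",
                          col.names = c("chrom", "pos", "ref_count", "alt_count"),
                          colClasses = c("character", "double", "integer", "integer"))
  structure(df, sample_id = sample_id,
            class = c("allele_count_table", "data.frame"))
}

#' Write an allele count table as a minimal VCF dialect
#'
#' Single-sample VCF 4.2 with GT unset (`./.`) and AD-style ref,alt counts.
#' @param counts An `allele_count_table`.
#' @param path Output path.
#' @export
write_allele_counts_vcf <- function(counts, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  sample_id <- attr(counts, "sample_id") %||% "sample"
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
               paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t", sample_id)),
             con, useBytes = TRUE)
  writeLines(sprintf("%s\t%s\t.\tN\t<ALT>\t.\t.\t.\tAD\t%d,%d",
                     counts$chrom,
                     format(counts$pos + 1, scientific = FALSE, trim = TRUE),
                     counts$ref_count, counts$alt_count), con, useBytes = TRUE)
  invisible(path)
}
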