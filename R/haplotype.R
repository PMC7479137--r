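# Haplotype-state reconstruction from SNP allele frequencies and LOH calling.

default_calling_params <- function() default_config()$calling

# Group indices 1..n into consecutive windows of `k` SNPs (last may be short).
snp_windows <- function(n, k) {
  if (n == 0) return(integer())
  rep(seq_len(ceiling(n / k)), each = k, length.out = n)
}

classify_vaf <- function(mean_vaf, any_alt, t_lo, t_hi) {
  ifelse(!any_alt | mean_vaf < t_lo, "HOM_REF",
         ifelse(mean_vaf > t_hi, "HOM_ALT", "HET"))
}

#' Reconstruct germline haplotype-state segments from SNP allele frequencies
#'
#' Implements the three-way frequency rule used to read haplotypes off
#' tumor/germline exome data in two-strain crosses: windows of diagnostic
#' SNPs with mean variant-allele frequency (VAF) near 0.5 are heterozygous
#' (two distinct strain haplotypes present), near 1.0 are pure donor strain,
#' and windows with (almost) no ALT reads match the reference strain.
#'
#' SNPs below `min_depth` are discarded (ambiguous/failed sites); the
#' remaining SNPs are grouped into consecutive windows of `window_snps`, each
#' window is classified, adjacent same-state windows are merged, and segment
#' boundaries are placed midway between the flanking SNPs of different-state
#' windows (ties toward the lower coordinate). The first and last segment of
#' each chromosome extend to the chromosome ends so segments tile the genome.
#'
#' @param counts An `allele_count_table`.
#' @param layout A [genome_layout] (for chromosome lengths).
#' @param params Calling parameters (see [default_config()] `calling`):
#'   `window_snps`, `min_depth`, `t_lo`, `t_hi`.
#' @return data.frame of class `haplotype_segments` with columns chrom,
#'   start, end, state, n_snps, mean_vaf.
#' @export
call_haplotype_segments <- function(counts, layout,
                                    params = default_calling_params()) {
  out <- list()
  if (is.null(counts) || !nrow(counts)) {
    return(structure(
      data.frame(chrom = character(), start = double(), end = double(),
                 state = character(), n_snps = integer(), mean_vaf = double()),
      class = c("haplotype_segments", "data.frame")))
  }
  for (nm in unique(counts$chrom)) {
    len <- chrom_length(layout, nm)
    x <- counts[counts$chrom == nm, , drop = FALSE]
    x <- x[order(x$pos), , drop = FALSE]
    depth <- x$ref_count + x$alt_count
    x <- x[depth >= params$min_depth, , drop = FALSE]
    if (!nrow(x)) next
    vaf <- x$alt_count / (x$ref_count + x$alt_count)
    w <- snp_windows(nrow(x), params$window_snps)
    wstate <- vapply(split(seq_len(nrow(x)), w), function(idx) {
      classify_vaf(mean(vaf[idx]), any(x$alt_count[idx] > 0),
                   params$t_lo, params$t_hi)
    }, character(1))
    first_pos <- vapply(split(x$pos, w), min, double(1))
    last_pos <- vapply(split(x$pos, w), max, double(1))
    runs <- rle(unname(wstate))
    ends_w <- cumsum(runs$lengths)
    starts_w <- c(1, utils::head(ends_w, -1) + 1)
    n_w <- length(wstate)
    prev_w <- pmax(starts_w - 1, 1)
    next_w <- pmin(ends_w + 1, n_w)
    seg_start <- midpoint(last_pos[prev_w], first_pos[starts_w])
    seg_start[starts_w == 1] <- 0
    seg_end <- midpoint(last_pos[ends_w], first_pos[next_w])
    seg_end[ends_w == n_w] <- len
    idx_by_run <- split(seq_len(nrow(x)), rep(seq_along(runs$lengths),
                                              runs$lengths)[w])
    out[[length(out) + 1]] <- data.frame(
      chrom = nm, start = seg_start, end = seg_end, state = runs$values,
      n_snps = vapply(idx_by_run, length, integer(1)),
      mean_vaf = vapply(idx_by_run, function(i) mean(vaf[i]), double(1)))
  }
  segs <- do.call(rbind, out)
  rownames(segs) <- NULL
  structure(segs, class = c("haplotype_segments", "data.frame"))
}

# Depth-normalized tumor/germline coverage ratio per bin over [start, end).
coverage_ratio_bins <- function(tumor_cov, germ_cov, chrom, start, end) {
  med_t <- stats::median(tumor_cov$count)
  med_g <- stats::median(germ_cov$count)
  sel <- tumor_cov$chrom == chrom & tumor_cov$end > start & tumor_cov$start < end
  t <- tumor_cov$count[sel]
  g <- germ_cov$count[germ_cov$chrom == chrom & germ_cov$end > start &
                        germ_cov$start < end]
  ok <- g > 0
  if (!length(t) || !any(ok)) return(numeric())
  (t[ok] / med_t) / (g[ok] / med_g)
}

#' Call LOH within germline-heterozygous segments and assign its mechanism
#'
#' Loss of heterozygosity is only defined over germline heterozygosity:
#' within each germline HET segment, tumor SNP windows whose mean VAF falls
#' outside `[t_lo, t_hi]` are flagged as LOH, contiguous flagged windows are
#' merged into calls, and the retained haplotype is ALT-like (donor) if the
#' call's VAF exceeds `t_hi`, REF-like otherwise. The mechanism is read off
#' the depth-normalized tumor/germline coverage ratio over the call:
#' copy-neutral LOH leaves total coverage unchanged (median ratio within
#' `[r_lo, r_hi]`), deletion LOH halves it (ratio below `r_del`); anything
#' else — including missing coverage — is recorded as UNKNOWN.
#'
#' @param germ_segments Germline `haplotype_segments`.
#' @param tumor_counts Tumor `allele_count_table`.
#' @param tumor_cov,germ_cov Tumor and germline `coverage_profile`s.
#' @param layout A [genome_layout].
#' @param params Calling parameters (`window_snps`, `min_depth`, `t_lo`,
#'   `t_hi`, `r_lo`, `r_hi`, `r_del`).
#' @return data.frame of class `loh_calls` with columns chrom, start, end,
#'   mechanism, retained, coverage_ratio, mean_vaf.
#' @export
call_loh <- function(germ_segments, tumor_counts, tumor_cov, germ_cov, layout,
                     params = default_calling_params()) {
  calls <- list()
  het <- germ_segments[germ_segments$state == "HET", , drop = FALSE]
  for (i in seq_len(nrow(het))) {
    nm <- het$chrom[i]
    x <- tumor_counts[tumor_counts$chrom == nm &
                        tumor_counts$pos >= het$start[i] &
                        tumor_counts$pos < het$end[i], , drop = FALSE]
    x <- x[order(x$pos), , drop = FALSE]
    depth <- x$ref_count + x$alt_count
    x <- x[depth >= params$min_depth, , drop = FALSE]
    if (!nrow(x)) next
    vaf <- x$alt_count / (x$ref_count + x$alt_count)
    w <- snp_windows(nrow(x), params$window_snps)
    wmean <- vapply(split(vaf, w), mean, double(1))
    flagged <- wmean < params$t_lo | wmean > params$t_hi
    if (!any(flagged)) next
    first_pos <- vapply(split(x$pos, w), min, double(1))
    last_pos <- vapply(split(x$pos, w), max, double(1))
    runs <- rle(unname(flagged))
    ends_w <- cumsum(runs$lengths)
    starts_w <- c(1, utils::head(ends_w, -1) + 1)
    for (r in which(runs$values)) {
      s_w <- starts_w[r]; e_w <- ends_w[r]
      call_start <- if (s_w == 1) het$start[i] else
        midpoint(last_pos[s_w - 1], first_pos[s_w])
      call_end <- if (e_w == length(flagged)) het$end[i] else
        midpoint(last_pos[e_w], first_pos[e_w + 1])
      idx <- which(w >= s_w & w <= e_w)
      mv <- mean(vaf[idx])
      ratios <- coverage_ratio_bins(tumor_cov, germ_cov, nm, call_start, call_end)
      if (!length(ratios)) {
        mech <- "UNKNOWN"; cr <- NA_real_
      } else {
        cr <- stats::median(ratios)
        mech <- if (cr >= params$r_lo && cr <= params$r_hi) "CN_LOH"
        else if (cr < params$r_del) "DELETION_LOH"
        else "UNKNOWN"
      }
      calls[[length(calls) + 1]] <- data.frame(
        chrom = nm, start = call_start, end = call_end, mechanism = mech,
        retained = if (mv > params$t_hi) "ALT" else "REF",
        coverage_ratio = cr, mean_vaf = mv)
    }
  }
  out <- if (length(calls)) do.call(rbind, calls) else
    data.frame(chrom = character(), start = double(), end = double(),
               mechanism = character(), retained = character(),
               coverage_ratio = double(), mean_vaf = double())
  rownames(out) <- NULL
  structure(out, class = c("loh_calls", "data.frame"))
}

# True haplotype state (HOM_REF / HET / HOM_ALT) piecewise along a chromosome
# of a diploid genome, relative to the donor strain.
truth_state_piecewise <- function(genome, chrom, donor_strain = "DONOR") {
  h <- genome$haplotypes[[chrom]]
  bp <- sort(unique(c(h$A$start, h$A$end, h$B$start, h$B$end)))
  mids <- (bp[-1] + bp[-length(bp)]) / 2
  sA <- mosaic_strain_at(h$A, mids) == donor_strain
  sB <- mosaic_strain_at(h$B, mids) == donor_strain
  state <- ifelse(sA & sB, "HOM_ALT", ifelse(!sA & !sB, "HOM_REF", "HET"))
  list(bp = bp, state = state)
}

#' Length-weighted concordance between called haplotype segments and truth
#'
#' Parameter-recovery metric for simulations: the fraction of total genome
#' length where the called state (HOM_REF/HET/HOM_ALT) matches the state
#' implied by the true haplotype mosaics. Genome not covered by any call
#' counts as discordant.
#'
#' @param called `haplotype_segments` from [call_haplotype_segments()].
#' @param truth A [diploid_genome] (simulation ground truth).
#' @param donor_strain Strain treated as the ALT-carrying donor.
#' @return Fraction in `[0, 1]`.
#' @export
haplotype_concordance <- function(called, truth, donor_strain = "DONOR") {
  total <- sum(truth$layout$chromosomes$length)
  agree <- 0
  for (nm in truth$layout$chromosomes$name) {
    tr <- truth_state_piecewise(truth, nm, donor_strain)
    segs <- called[called$chrom == nm, , drop = FALSE]
    for (i in seq_len(nrow(segs))) {
      ov_start <- pmax(segs$start[i], tr$bp[-length(tr$bp)])
      ov_end <- pmin(segs$end[i], tr$bp[-1])
      ov <- pmax(0, ov_end - ov_start)
      agree <- agree + sum(ov[tr$state == segs$state[i]])
    }
  }
  agree / total
}

#' Write haplotype segments or LOH calls as a BED-dialect file
#'
#' @param x A `haplotype_segments` or `loh_calls` data.frame.
#' @param path Output path.
#' @export
write_segments_bed <- function(x, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  extra <- setdiff(names(x), c("chrom", "start", "end"))
  writeLines(paste0("#chrom\tstart\tend\t", paste(extra, collapse = "\t")),
             con, useBytes = TRUE)
  if (nrow(x)) {
    vals <- do.call(paste, c(lapply(x[extra], function(col) {
      if (is.numeric(col)) format(col, scientific = FALSE, trim = TRUE, digits = 10)
      else as.character(col)
    }), sep = "\t"))
    writeLines(sprintf("%s\t%s\t%s\t%s", x$chrom,
                       format(x$start, scientific = FALSE, trim = TRUE),
                       format(x$end, scientific = FALSE, trim = TRUE), vals),
               con, useBytes = TRUE)
  }
  invisible(path)
}
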