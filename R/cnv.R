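# Tumor/germline copy-number calling from binned coverage log-ratios.

#' Compute per-bin tumor/germline coverage log2 ratios
#'
#' Tumor counts are first scaled by the ratio of genome-wide medians (so the
#' two samples are depth-matched), then each bin's ratio is
#' `log2((t + c) / (g + c))` with pseudocount `c`, and finally the ratios are
#' median-centered at 0 (robust to the small fraction of altered bins).
#'
#' @param tumor_cov,germ_cov `coverage_profile`s on identical bins.
#' @param pseudocount Pseudocount `c` added to both channels.
#' @param center Median-center the ratios (default TRUE).
#' @return data.frame of class `log_ratio_profile` with columns chrom, start,
#'   end, log2_ratio; attribute `bin_size`.
#' @export
compute_log_ratios <- function(tumor_cov, germ_cov, pseudocount = 0.5,
                               center = TRUE) {
  if (nrow(tumor_cov) != nrow(germ_cov) ||
      !all(tumor_cov$chrom == germ_cov$chrom) ||
      !all(tumor_cov$start == germ_cov$start) ||
      !all(tumor_cov$end == germ_cov$end)) {
    stop_config("tumor and germline coverage profiles must share identical bins")
  }
  scale <- stats::median(germ_cov$count) / stats::median(tumor_cov$count)
  r <- log2((tumor_cov$count * scale + pseudocount) /
              (germ_cov$count + pseudocount))
  if (center) r <- r - stats::median(r)
  structure(
    data.frame(chrom = tumor_cov$chrom, start = tumor_cov$start,
               end = tumor_cov$end, log2_ratio = r),
    bin_size = attr(tumor_cov, "bin_size"),
    class = c("log_ratio_profile", "data.frame"))
}

# Best split of x[lo..hi] by reduction in within-interval sum of squares,
# using precomputed cumulative sums cs = c(0, cumsum(x)), css likewise.
# Returns c(k, gain): left piece is lo..k.
best_split <- function(cs, css, lo, hi) {
  n <- hi - lo + 1
  if (n < 2) return(c(NA_real_, 0))
  ss <- function(l, h) {
    m <- h - l + 1
    (css[h + 1] - css[l]) - (cs[h + 1] - cs[l])^2 / m
  }
  k <- lo:(hi - 1)
  gain <- ss(lo, hi) - (ss(lo, k) + ss(k + 1, hi))
  best <- which.max(gain)
  c(k[best], gain[best])
}

# Deterministic multi-scale candidate intervals (seeded intervals): dyadic
# scales with 50% overlap, down to `min_len` bins. Focal events far shorter
# than the chromosome are only detectable inside an interval of comparable
# scale, which plain single-split binary segmentation lacks.
seeded_intervals <- function(n, min_len = 4) {
  if (n < min_len) return(matrix(numeric(), ncol = 2,
                                 dimnames = list(NULL, c("lo", "hi"))))
  out <- list()
  len <- n
  while (len >= min_len) {
    step <- max(1, floor(len / 2))
    lo <- unique(c(seq(1, max(1, n - len + 1), by = step), n - len + 1))
    out[[length(out) + 1]] <- cbind(lo = lo, hi = lo + len - 1)
    if (len == min_len) break
    len <- max(min_len, floor(len / 2))
  }
  do.call(rbind, out)
}

# Robust noise variance from successive differences (insensitive to the
# small fraction of bins inside true copy-number changes).
robust_sigma2 <- function(x) {
  if (length(x) < 3) return(0)
  (stats::median(abs(diff(x))) / (0.6744898 * sqrt(2)))^2
}

#' Segment log2 ratios by seeded binary segmentation
#'
#' Deterministic recursive segmentation. Candidate changepoints are the best
#' single splits within a fixed multi-scale collection of intervals (dyadic
#' scales, 50% overlap — "seeded" intervals) plus the current segment itself;
#' at each step the candidate with the largest reduction in within-interval
#' sum of squared deviations is accepted iff the reduction exceeds
#' `penalty * 4 * sigma2 * log(n_bins)`, where `sigma2` is a robust noise
#' variance estimated from successive differences and `n_bins` is the
#' chromosome's bin count; splitting then recurses into both halves. The
#' multi-scale candidates make short focal events (a few bins) detectable on
#' megabase-scale chromosomes, which a single whole-segment split statistic
#' cannot do. When the noise estimate is zero any strictly positive
#' reduction is accepted, so noise-free step signals split exactly at their
#' edges.
#'
#' @param ratios A `log_ratio_profile` from [compute_log_ratios()].
#' @param penalty Penalty multiplier (default 1.0).
#' @return data.frame of class `cnv_segments` with columns chrom, start, end,
#'   log2_ratio (segment mean), n_bins; attribute `bin_size`.
#' @export
segment_log_ratios <- function(ratios, penalty = 1.0) {
  if (any(!is.finite(ratios$log2_ratio))) stop_config("ratios must be finite")
  out <- list()
  for (nm in unique(ratios$chrom)) {
    sel <- ratios$chrom == nm
    x <- ratios$log2_ratio[sel]
    starts <- ratios$start[sel]
    ends <- ratios$end[sel]
    n <- length(x)
    cs <- c(0, cumsum(x))
    css <- c(0, cumsum(x^2))
    sigma2 <- robust_sigma2(x)
    thresh <- penalty * 4 * sigma2 * log(max(n, 2))
    iv <- seeded_intervals(n)
    iv_best <- matrix(NA_real_, nrow = nrow(iv), ncol = 2)
    for (i in seq_len(nrow(iv))) {
      iv_best[i, ] <- best_split(cs, css, iv[i, 1], iv[i, 2])
    }
    bounds <- c(0L, n)
    stack <- list(c(1L, n))
    while (length(stack)) {
      rng <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      if (rng[2] - rng[1] < 1) next
      inside <- iv[, 1] >= rng[1] & iv[, 2] <= rng[2]
      cand <- rbind(iv_best[inside, , drop = FALSE],
                    best_split(cs, css, rng[1], rng[2]))
      cand <- cand[is.finite(cand[, 1]), , drop = FALSE]
      if (!nrow(cand)) next
      best <- which.max(cand[, 2])
      gain <- cand[best, 2]
      accept <- if (sigma2 > 0) gain > thresh else gain > 0
      if (accept) {
        k <- as.integer(cand[best, 1])
        bounds <- c(bounds, k)
        stack[[length(stack) + 1]] <- c(rng[1], k)
        stack[[length(stack) + 1]] <- c(k + 1L, rng[2])
      }
    }
    bounds <- sort(unique(bounds))
    seg_lo <- utils::head(bounds, -1) + 1
    seg_hi <- bounds[-1]
    out[[length(out) + 1]] <- data.frame(
      chrom = nm,
      start = starts[seg_lo],
      end = ends[seg_hi],
      log2_ratio = vapply(seq_along(seg_lo),
                          function(i) mean(x[seg_lo[i]:seg_hi[i]]), double(1)),
      n_bins = seg_hi - seg_lo + 1L)
  }
  segs <- do.call(rbind, out)
  rownames(segs) <- NULL
  structure(segs, bin_size = attr(ratios, "bin_size"),
            class = c("cnv_segments", "data.frame"))
}

#' Assign copy-number calls to segments
#'
#' Threshold rule on segment mean log2 ratios: homozygous loss at or below
#' `hom_loss`, heterozygous loss at or below `het_loss`, gain at or above
#' `gain`, otherwise neutral.
#'
#' @param segments `cnv_segments` from [segment_log_ratios()].
#' @param thresholds Named list with `hom_loss`, `het_loss`, `gain`.
#' @return `segments` with an added `call` column
#'   (NEUTRAL/HET_LOSS/HOM_LOSS/GAIN).
#' @export
call_segments <- function(segments,
                          thresholds = default_config()$calling) {
  hom <- thresholds$hom_loss %||% -2.0
  het <- thresholds$het_loss %||% -0.35
  gain <- thresholds$gain %||% 0.3
  if (!(hom <= het && het < 0 && 0 < gain)) {
    stop_config("thresholds must satisfy hom <= het < 0 < gain")
  }
  r <- segments$log2_ratio
  segments$call <- ifelse(r <= hom, "HOM_LOSS",
                          ifelse(r <= het, "HET_LOSS",
                                 ifelse(r >= gain, "GAIN", "NEUTRAL")))
  segments
}

#' Write copy-number segments as a SEG-dialect file
#'
#' Tab-separated columns: sample, chrom, start, end, n_bins, seg_mean
#' (and call when present).
#'
#' @param segments `cnv_segments`.
#' @param path Output path.
#' @param sample_id Sample name for the first column.
#' @export
write_seg <- function(segments, path, sample_id = "sample") {
  con <- file(path, open = "wb")
  on.exit(close(con))
  has_call <- "call" %in% names(segments)
  hdr <- "sample\tchrom\tstart\tend\tn_bins\tseg_mean"
  if (has_call) hdr <- paste0(hdr, "\tcall")
  writeLines(hdr, con, useBytes = TRUE)
  if (nrow(segments)) {
    lines <- sprintf("%s\t%s\t%s\t%s\t%d\t%.6f", sample_id, segments$chrom,
                     format(segments$start, scientific = FALSE, trim = TRUE),
                     format(segments$end, scientific = FALSE, trim = TRUE),
                     segments$n_bins, segments$log2_ratio)
    if (has_call) lines <- paste0(lines, "\t", segments$call)
    writeLines(lines, con, useBytes = TRUE)
  }
  invisible(path)
}
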