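# Cohort overlay, breakpoint concordance and germline-artifact classification.

#' Overlay deletion calls across a tumor cohort
#'
#' Single-linkage clustering of overlapping calls (>= 1 bp overlap chains
#' members into one cluster, per chromosome). For each cluster with at least
#' two members, breakpoint concordance is the fraction of member pairs whose
#' start AND end each agree within `tolerance_bins * bin_size`; identical
#' germline-variant artifacts give concordance 1, genuinely somatic "stepped"
#' deletions give concordance near 0. A per-base recurrence profile (count of
#' members covering each base) is attached per cluster.
#'
#' @param calls data.frame of deletion calls across tumors with columns
#'   tumor_id, chrom, start, end.
#' @param tolerance_bins Breakpoint agreement tolerance in bins.
#' @param bin_size Bin size in bp.
#' @return List of clusters; each is a list with `cluster_id`, `members`
#'   (data.frame), `concordance` (NA for single-member clusters) and
#'   `profile` (data.frame chrom, start, end, count).
#' @export
overlay_cohort <- function(calls, tolerance_bins = 1, bin_size = 20000) {
  clusters <- list()
  if (is.null(calls) || !nrow(calls)) return(clusters)
  tol <- tolerance_bins * bin_size
  cid <- 0L
  for (nm in unique(calls$chrom)) {
    x <- calls[calls$chrom == nm, , drop = FALSE]
    x <- x[order(x$start, x$end), , drop = FALSE]
    run_max_end <- cummax(x$end)
    new_cluster <- c(TRUE, x$start[-1] >= utils::head(run_max_end, -1))
    grp <- cumsum(new_cluster)
    for (g in unique(grp)) {
      cid <- cid + 1L
      members <- x[grp == g, , drop = FALSE]
      rownames(members) <- NULL
      n <- nrow(members)
      conc <- NA_real_
      if (n >= 2) {
        pairs <- utils::combn(n, 2)
        agree <- abs(members$start[pairs[1, ]] - members$start[pairs[2, ]]) <= tol &
          abs(members$end[pairs[1, ]] - members$end[pairs[2, ]]) <= tol
        conc <- mean(agree)
      }
      bp <- sort(unique(c(members$start, members$end)))
      cnt <- vapply(seq_len(length(bp) - 1), function(i) {
        sum(members$start <= bp[i] & members$end >= bp[i + 1])
      }, double(1))
      profile <- data.frame(chrom = nm, start = utils::head(bp, -1),
                            end = bp[-1], count = cnt)
      clusters[[cid]] <- list(cluster_id = cid, members = members,
                              concordance = conc, profile = profile)
    }
  }
  clusters
}

reciprocal_overlap <- function(s1, e1, s2, e2) {
  ov <- pmax(0, pmin(e1, e2) - pmax(s1, s2))
  pmin(ov / (e1 - s1), ov / (e2 - s2))
}

#' Classify a deletion call as germline-variant artifact or somatic candidate
#'
#' Applies the three lines of evidence that distinguish strain-variant
#' artifacts from genuine somatic deletions, as a deterministic rule:
#' \describe{
#'   \item{matches_registry}{reciprocal overlap of at least
#'     `reciprocal_overlap` with a registry strain variant;}
#'   \item{identical_breakpoints}{the call belongs to a cohort cluster with
#'     breakpoint concordance of at least `concordance_min` and at least
#'     `min_members` members;}
#'   \item{linked_driver_loh}{the call lies within an LOH call of the same
#'     tumor whose interval contains a driver position (with the distance
#'     from call midpoint to that driver recorded).}
#' }
#' Classification: GERMLINE_VARIANT_ARTIFACT iff (matches_registry OR
#' identical_breakpoints) AND linked_driver_loh; SOMATIC_CANDIDATE iff no
#' evidence flag is set; AMBIGUOUS otherwise.
#'
#' @param call One-row data.frame (tumor_id, chrom, start, end).
#' @param overlays Output of [overlay_cohort()] for the cohort.
#' @param registry A `strain_registry`.
#' @param loh_calls `loh_calls` for the same tumor.
#' @param drivers Drivers data.frame (id, chrom, position, ...).
#' @param params List with `reciprocal_overlap`, `concordance_min`,
#'   `min_members`.
#' @return A one-row data.frame with the call columns plus classification,
#'   matches_registry, identical_breakpoints, linked_driver_loh,
#'   distance_to_driver.
#' @export
classify_cnv <- function(call, overlays, registry, loh_calls, drivers,
                         params = default_calling_params()) {
  stopifnot(nrow(call) == 1)
  ro_min <- params$reciprocal_overlap %||% 0.9
  conc_min <- params$concordance_min %||% 0.9
  min_members <- params$min_members %||% 3

  reg <- registry[registry$chrom == call$chrom, , drop = FALSE]
  matches_registry <- nrow(reg) > 0 &&
    any(reciprocal_overlap(call$start, call$end, reg$start, reg$end) >= ro_min)

  identical_breakpoints <- FALSE
  for (cl in overlays) {
    m <- cl$members
    hit <- m$chrom == call$chrom & m$start == call$start & m$end == call$end &
      (!("tumor_id" %in% names(m)) | m$tumor_id == call$tumor_id)
    if (any(hit)) {
      identical_breakpoints <- !is.na(cl$concordance) &&
        cl$concordance >= conc_min && nrow(m) >= min_members
      break
    }
  }

  linked_driver_loh <- FALSE
  distance_to_driver <- NA_real_
  loh <- loh_calls[loh_calls$chrom == call$chrom, , drop = FALSE]
  dr <- drivers[drivers$chrom == call$chrom, , drop = FALSE]
  mid <- (call$start + call$end) / 2
  for (i in seq_len(nrow(loh))) {
    if (loh$start[i] <= call$start && call$end <= loh$end[i]) {
      inside <- dr$position >= loh$start[i] & dr$position < loh$end[i]
      if (any(inside)) {
        linked_driver_loh <- TRUE
        d <- abs(mid - dr$position[inside])
        distance_to_driver <- min(d, distance_to_driver, na.rm = TRUE)
      }
    }
  }

  classification <- if ((matches_registry || identical_breakpoints) &&
                        linked_driver_loh) {
    "GERMLINE_VARIANT_ARTIFACT"
  } else if (!matches_registry && !identical_breakpoints && !linked_driver_loh) {
    "SOMATIC_CANDIDATE"
  } else {
    "AMBIGUOUS"
  }
  cbind(call,
        data.frame(classification = classification,
                   matches_registry = matches_registry,
                   identical_breakpoints = identical_breakpoints,
                   linked_driver_loh = linked_driver_loh,
                   distance_to_driver = distance_to_driver))
}
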