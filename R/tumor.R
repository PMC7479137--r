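#' Construct a somatic event table
#'
#' Events are applied in list order; later events read the copy state produced
#' by earlier events (needed for the deletion-then-CN-LOH two-step scenario).
#'
#' @param type `"CN_LOH"` or `"FOCAL_DEL"`.
#' @param chrom Chromosome name.
#' @param start,end Interval, 0-based half-open.
#' @param target_copy `"A"` or `"B"`: the haplotype copy lost by the event.
#' @return One-row data.frame.
#' @export
somatic_event <- function(type = c("CN_LOH", "FOCAL_DEL"), chrom, start, end,
                          target_copy = c("A", "B")) {
  type <- match.arg(type)
  target_copy <- match.arg(target_copy)
  if (!(start >= 0 && start < end)) stop_config("invalid event interval")
  data.frame(type = type, chrom = chrom, start = as.double(start),
             end = as.double(end), target_copy = target_copy)
}

#' Construct a tumor genome
#'
#' A germline diploid genome plus an ordered list of somatic events. With no
#' events the per-haplotype copy state is (1, 1) everywhere.
#'
#' @param germline A [diploid_genome].
#' @param events data.frame of [somatic_event] rows (possibly zero rows).
#' @return Object of class `tumor_genome`.
#' @export
tumor_genome <- function(germline, events = NULL) {
  if (is.null(events)) {
    events <- data.frame(type = character(), chrom = character(),
                         start = double(), end = double(),
                         target_copy = character())
  }
  if (nrow(events)) {
    len <- chrom_length(germline$layout, events$chrom)
    if (any(events$start < 0 | events$end > len | events$start >= events$end)) {
      stop_config("somatic event interval outside chromosome")
    }
  }
  structure(list(germline = germline, events = events), class = "tumor_genome")
}

#' Per-haplotype copy state of a tumor genome
#'
#' Applies events in order: a focal deletion on copy X zeroes X inside its
#' interval; CN-LOH targeting X zeroes X and duplicates the other copy (the
#' lost haplotype is replaced by a duplicate of the retained one, so total
#' copy number is preserved — unless the retained copy was itself already
#' deleted, in which case nothing is left to duplicate).
#'
#' @param tumor A [tumor_genome] (or a [diploid_genome], which is treated as
#'   event-free).
#' @param chrom Chromosome name.
#' @param pos Position(s), 0-based.
#' @return A matrix with columns `A` and `B` of per-haplotype copy numbers.
#' @export
copy_state <- function(tumor, chrom, pos) {
  n <- length(pos)
  cn <- matrix(1, nrow = n, ncol = 2, dimnames = list(NULL, c("A", "B")))
  if (inherits(tumor, "diploid_genome")) {
    len <- chrom_length(tumor$layout, chrom)
    if (any(pos < 0 | pos >= len)) stop_config("position out of range")
    return(cn)
  }
  len <- chrom_length(tumor$germline$layout, chrom)
  if (any(pos < 0 | pos >= len)) stop_config("position out of range")
  ev <- tumor$events[tumor$events$chrom == chrom, , drop = FALSE]
  for (i in seq_len(nrow(ev))) {
    inside <- pos >= ev$start[i] & pos < ev$end[i]
    if (!any(inside)) next
    tc <- ev$target_copy[i]
    oc <- setdiff(c("A", "B"), tc)
    if (ev$type[i] == "FOCAL_DEL") {
      cn[inside, tc] <- 0
    } else { # CN_LOH
      cn[inside, oc] <- 2 * cn[inside, oc]
      cn[inside, tc] <- 0
    }
  }
  cn
}

germline_of <- function(genome) {
  if (inherits(genome, "tumor_genome")) genome$germline else genome
}

# Per-copy surviving copy number and strain-of-origin at positions on one
# chromosome, accounting for registry deletions: a haplotype whose strain
# carries a registry deletion covering the position yields no DNA there.
copy_detail <- function(genome, registry, chrom, pos) {
  germ <- germline_of(genome)
  cn <- copy_state(genome, chrom, pos)
  strains <- cbind(A = strain_at(germ, chrom, pos, "A"),
                   B = strain_at(germ, chrom, pos, "B"))
  for (cp in c("A", "B")) {
    for (strain in unique(strains[, cp])) {
      v <- registry_for(registry, chrom, strain)
      if (!nrow(v)) next
      deleted <- rep(FALSE, length(pos))
      for (j in seq_len(nrow(v))) {
        deleted <- deleted | (pos >= v$start[j] & pos < v$end[j])
      }
      hit <- deleted & strains[, cp] == strain
      cn[hit, cp] <- 0
    }
  }
  list(copies = cn, strains = strains)
}

#' Physical DNA copy number at a position
#'
#' Sums per-haplotype copy numbers after zeroing any haplotype whose founder
#' strain carries a registry deletion covering the position. This is the
#' quantity sequencing depth actually reports: a strain-private germline
#' deletion contributes no reads from carrier haplotypes, so a single somatic
#' CN-LOH that retains the carrier haplotype drops physical copies to zero at
#' the variant locus.
#'
#' @param genome A [diploid_genome] or [tumor_genome].
#' @param registry A `strain_registry`.
#' @param chrom Chromosome name.
#' @param pos Position(s), 0-based.
#' @return Numeric vector of physical copy numbers.
#' @export
physical_copies <- function(genome, registry, chrom, pos) {
  d <- copy_detail(genome, registry, chrom, pos)
  unname(rowSums(d$copies))
}

#' Simulate somatic events for a driver-selected tumor
#'
#' Emulates tumor evolution in a driver-engineered model: if the germline is
#' heterozygous for the engineered driver allele, selective pressure to lose
#' the wild-type allele produces a CN-LOH event targeting the copy NOT
#' carrying the engineered allele, with an interval containing the driver
#' position (start drawn uniformly upstream of the driver, extending to the
#' chromosome end — telomeric CN-LOH — by default). If the germline is
#' already homozygous for the engineered haplotype there is nothing to select
#' against and no driver event is emitted.
#'
#' Optionally (scenario `suppressor_scenario`), a two-step event on a second
#' chromosome: a focal deletion of a tumor-suppressor locus with breakpoints
#' drawn uniformly in windows around the suppressor ("stepped" breakpoints),
#' followed by CN-LOH that retains the deleted copy.
#'
#' @param germline A [diploid_genome]; must carry the engineered allele on at
#'   least one copy.
#' @param driver Driver row (id, chrom, position, origin_strain, ...).
#' @param seed Integer seed.
#' @param scenario Scenario configuration (the `tumor` section of
#'   [default_config()]); for the suppressor scenario, `suppressor` must hold
#'   a driver row for the suppressor locus.
#' @return A [tumor_genome].
#' @export
simulate_kpc_tumor <- function(germline, driver, seed,
                               scenario = default_config()$tumor) {
  zyg <- driver_zygosity(germline, driver)
  if (zyg == 0) stop_config("germline does not carry the engineered allele")
  with_seed(seed, {
    events <- list()
    if (isTRUE(scenario$driver_cnloh %||% TRUE) && zyg == 1) {
      carrier_copy <- if (strain_at(germline, driver$chrom, driver$position, "A") ==
                          driver$origin_strain) "A" else "B"
      target <- setdiff(c("A", "B"), carrier_copy)
      len <- chrom_length(germline$layout, driver$chrom)
      max_up <- scenario$cnloh_max_upstream %||% 2e7
      start <- floor(stats::runif(1, max(0, driver$position - max_up), driver$position))
      events[[length(events) + 1]] <-
        somatic_event("CN_LOH", driver$chrom, start, len, target)
    }
    if (isTRUE(scenario$suppressor_scenario)) {
      sup <- scenario$suppressor
      if (is.null(sup)) stop_config("suppressor_scenario requires scenario$suppressor")
      w <- scenario$suppressor_del_window %||% 2e6
      core <- scenario$suppressor_del_core %||% 1e5
      len <- chrom_length(germline$layout, sup$chrom)
      # deletion hits the copy carrying the donor haplotype at the suppressor
      # (the variant-linked copy), matching the two-step scenario
      sA <- strain_at(germline, sup$chrom, sup$position, "A")
      del_copy <- if (sA == sup$origin_strain) "A" else "B"
      d_start <- floor(stats::runif(1, max(0, sup$position - w), sup$position - core))
      d_end <- floor(stats::runif(1, sup$position + core, min(len, sup$position + w)))
      events[[length(events) + 1]] <-
        somatic_event("FOCAL_DEL", sup$chrom, d_start, d_end, del_copy)
      max_up <- scenario$cnloh_max_upstream %||% 2e7
      l_start <- floor(stats::runif(1, max(0, sup$position - max_up), sup$position))
      events[[length(events) + 1]] <-
        somatic_event("CN_LOH", sup$chrom, l_start, len,
                      setdiff(c("A", "B"), del_copy))
    }
    tumor_genome(germline, if (length(events)) do.call(rbind, events) else NULL)
  })
}
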