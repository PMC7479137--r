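#' Construct a haplotype mosaic
#'
#' One chromosome copy represented as an ordered tiling of founder-strain
#' blocks — the substrate of inheritance: meiosis splices mosaics, and tumors
#' lose or duplicate whole mosaics. Adjacent blocks of the same strain are
#' merged so the representation is canonical.
#'
#' @param blocks data.frame with columns `start`, `end`, `strain`
#'   (0-based half-open, contiguous, first start 0, last end = `length`).
#' @param chrom Chromosome name.
#' @param length Chromosome length in bp.
#' @return Object of class `haplotype_mosaic` (a data.frame with attributes
#'   `chrom` and `chrom_length`).
#' @export
haplotype_mosaic <- function(blocks, chrom, length) {
  stopifnot(is.data.frame(blocks), all(c("start", "end", "strain") %in% names(blocks)))
  blocks <- blocks[blocks$end > blocks$start, c("start", "end", "strain"), drop = FALSE]
  if (!nrow(blocks)) stop_config("mosaic must contain at least one block")
  blocks <- blocks[order(blocks$start), , drop = FALSE]
  # merge adjacent same-strain blocks
  keep <- c(TRUE, blocks$strain[-1] != blocks$strain[-nrow(blocks)])
  grp <- cumsum(keep)
  merged <- data.frame(
    start = tapply(blocks$start, grp, min),
    end = tapply(blocks$end, grp, max),
    strain = blocks$strain[keep]
  )
  rownames(merged) <- NULL
  if (merged$start[1] != 0 || merged$end[nrow(merged)] != length ||
      (nrow(merged) > 1 && any(merged$start[-1] != merged$end[-nrow(merged)]))) {
    stop_config("mosaic blocks must tile [0, %s) contiguously", format(length, scientific = FALSE))
  }
  structure(merged, chrom = chrom, chrom_length = length,
            class = c("haplotype_mosaic", "data.frame"))
}

# Fast internal constructor: `start` sorted, pieces contiguous to `len`.
# Merges adjacent same-strain pieces without validation overhead.
new_mosaic <- function(start, strain, chrom, len) {
  n <- length(start)
  keep <- if (n > 1) c(TRUE, strain[-1] != strain[-n]) else TRUE
  s <- start[keep]
  df <- data.frame(start = s, end = c(s[-1], len), strain = strain[keep])
  structure(df, chrom = chrom, chrom_length = len,
            class = c("haplotype_mosaic", "data.frame"))
}

# Founder strain at positions `pos` along a mosaic.
mosaic_strain_at <- function(mosaic, pos) {
  idx <- findInterval(pos, mosaic$start)
  if (any(idx < 1) || any(pos >= attr(mosaic, "chrom_length"))) {
    stop_config("position out of range for chromosome %s", attr(mosaic, "chrom"))
  }
  mosaic$strain[idx]
}

# Extract the sub-blocks of a mosaic inside [from, to) (coordinates kept).
mosaic_slice <- function(mosaic, from, to) {
  sel <- mosaic$end > from & mosaic$start < to
  b <- mosaic[sel, , drop = FALSE]
  b$start <- pmax(b$start, from)
  b$end <- pmin(b$end, to)
  b
}

#' Construct a diploid genome
#'
#' @param layout A [genome_layout].
#' @param haplotypes Named list (per chromosome) of `list(A = , B = )`
#'   [haplotype_mosaic] pairs tiling the full chromosome.
#' @return Object of class `diploid_genome`.
#' @export
diploid_genome <- function(layout, haplotypes) {
  for (nm in layout$chromosomes$name) {
    h <- haplotypes[[nm]]
    if (is.null(h) || !all(c("A", "B") %in% names(h))) {
      stop_config("missing haplotype pair for chromosome %s", nm)
    }
  }
  structure(list(layout = layout, haplotypes = haplotypes),
            class = "diploid_genome")
}

#' Create a fully homozygous founder genome
#'
#' @param layout A [genome_layout].
#' @param strain Founder strain name (e.g. `"REFSTRAIN"` or `"DONOR"`).
#' @return A [diploid_genome] homozygous for `strain` everywhere.
#' @export
founder_genome <- function(layout, strain) {
  haps <- lapply(seq_len(nrow(layout$chromosomes)), function(i) {
    len <- layout$chromosomes$length[i]
    nm <- layout$chromosomes$name[i]
    m <- haplotype_mosaic(data.frame(start = 0, end = len, strain = strain), nm, len)
    list(A = m, B = m)
  })
  names(haps) <- layout$chromosomes$name
  diploid_genome(layout, haps)
}

#' Founder strain of origin at a genomic position
#'
#' @param genome A [diploid_genome].
#' @param chrom Chromosome name.
#' @param pos Position(s), 0-based.
#' @param copy `"A"` or `"B"`.
#' @return Character vector of founder strain names.
#' @export
strain_at <- function(genome, chrom, pos, copy = c("A", "B")) {
  copy <- match.arg(copy)
  h <- genome$haplotypes[[chrom]]
  if (is.null(h)) stop_config("unknown chromosome '%s'", chrom)
  mosaic_strain_at(h[[copy]], pos)
}

#' Does a germline genome carry a driver allele?
#'
#' A haplotype copy carries the engineered allele when its strain of origin at
#' the allele position is the allele's origin strain (the allele was
#' engineered on that founder background and travels with it).
#'
#' @param genome A [diploid_genome].
#' @param driver One row of a drivers data.frame (id, chrom, position,
#'   origin_strain, ...).
#' @return Integer 0, 1 or 2: number of copies carrying the allele.
#' @export
driver_zygosity <- function(genome, driver) {
  sum(vapply(c("A", "B"), function(cp) {
    strain_at(genome, driver$chrom, driver$position, cp) == driver$origin_strain
  }, logical(1)))
}

#' Simulate one meiosis for a chromosome (Haldane model)
#'
#' Crossover count is Poisson with mean equal to the map length in Morgans
#' (`length_bp * map_rate / 100 / 1e6`); crossover positions are uniform along
#' the chromosome (no interference, no obligate chiasma); the starting
#' parental copy is chosen by a fair coin. The gamete is the alternating
#' splice of the two parental copies at the crossover points, block-merged.
#'
#' @param parent A [diploid_genome].
#' @param chrom Chromosome name.
#' @param seed Integer seed.
#' @return A [haplotype_mosaic] gamete.
#' @export
meiosis <- function(parent, chrom, seed) {
  with_seed(seed, meiosis_(parent, chrom))
}

meiosis_ <- function(parent, chrom) {
  h <- parent$haplotypes[[chrom]]
  if (is.null(h)) stop_config("unknown chromosome '%s'", chrom)
  len <- chrom_length(parent$layout, chrom)
  morgans <- len * parent$layout$map_rate / 100 / 1e6
  n_xo <- stats::rpois(1, morgans)
  xo <- sort(unique(round(stats::runif(n_xo, 0, len))))
  xo <- xo[xo > 0 & xo < len]
  first <- if (stats::runif(1) < 0.5) "A" else "B"
  bounds <- c(0, xo, len)
  src <- rep(c(first, setdiff(c("A", "B"), first)), length.out = length(bounds) - 1)
  starts <- vector("list", length(src))
  strains <- vector("list", length(src))
  for (i in seq_along(src)) {
    m <- h[[src[i]]]
    idx <- which(m$end > bounds[i] & m$start < bounds[i + 1])
    s <- m$start[idx]
    s[1] <- bounds[i]
    starts[[i]] <- s
    strains[[i]] <- m$strain[idx]
  }
  new_mosaic(unlist(starts), unlist(strains), chrom, len)
}

#' Cross two parents
#'
#' One gamete from each parent per chromosome; the gamete from `p1` becomes
#' copy A and the gamete from `p2` copy B of the offspring.
#'
#' @param p1,p2 [diploid_genome] parents on the same layout.
#' @param seed Integer seed.
#' @return Offspring [diploid_genome].
#' @export
cross <- function(p1, p2, seed) {
  if (!identical(p1$layout$chromosomes, p2$layout$chromosomes)) {
    stop_config("parents have different genome layouts")
  }
  with_seed(seed, {
    haps <- lapply(p1$layout$chromosomes$name, function(nm) {
      list(A = meiosis_(p1, nm), B = meiosis_(p2, nm))
    })
    names(haps) <- p1$layout$chromosomes$name
    diploid_genome(p1$layout, haps)
  })
}

#' Backcross with selection for an engineered allele
#'
#' Starting from the F1 of `donor_founder` x `recurrent_founder`, each
#' generation crosses the current carrier to the recurrent founder and keeps
#' the first offspring that carries the engineered allele (genotype
#' selection, as in real congenic breeding where animals are genotyped for
#' the engineered allele). After any number of generations the returned
#' genome has a donor-origin block containing the allele position on exactly
#' one copy — the persistence of linked donor sequence near selected alleles.
#'
#' @param donor_founder,recurrent_founder Founder [diploid_genome]s.
#' @param n_generations Number of backcross generations (>= 1).
#' @param select_for Driver row (id, chrom, position, origin_strain, ...).
#' @param seed Integer seed.
#' @param max_attempts Offspring attempts per generation before aborting.
#' @return The generation-`n` carrier [diploid_genome].
#' @export
backcross_scheme <- function(donor_founder, recurrent_founder, n_generations,
                             select_for, seed, max_attempts = 10000) {
  if (n_generations < 1) stop_config("n_generations must be >= 1")
  carrier <- cross(donor_founder, recurrent_founder, derive_seed(seed, 0))
  k <- 1L
  for (gen in seq_len(n_generations)) {
    found <- FALSE
    for (attempt in seq_len(max_attempts)) {
      off <- cross(carrier, recurrent_founder, derive_seed(seed, k))
      k <- k + 1L
      if (driver_zygosity(off, select_for) >= 1) {
        carrier <- off
        found <- TRUE
        break
      }
    }
    if (!found) stop_config("selection failed after %d attempts in generation %d",
                            max_attempts, gen)
  }
  carrier
}

#' Genome-wide donor fraction
#'
#' Total length of DONOR-origin blocks over both copies divided by twice the
#' total length considered, optionally excluding an interval (e.g. the
#' selected region around an engineered allele) and optionally restricted to
#' a subset of chromosomes.
#'
#' @param genome A [diploid_genome].
#' @param donor_strain Strain counted as donor (default `"DONOR"`).
#' @param exclude Optional `list(chrom =, start =, end =)` interval to omit.
#' @param chroms Optional character vector of chromosomes to include.
#' @return Fraction in `[0, 1]`.
#' @export
donor_fraction <- function(genome, donor_strain = "DONOR", exclude = NULL,
                           chroms = NULL) {
  nms <- chroms %||% genome$layout$chromosomes$name
  tot <- 0
  donor <- 0
  for (nm in nms) {
    len <- chrom_length(genome$layout, nm)
    ex <- if (!is.null(exclude) && identical(exclude$chrom, nm)) exclude else NULL
    for (cp in c("A", "B")) {
      m <- genome$haplotypes[[nm]][[cp]]
      if (is.null(ex)) {
        l <- m$end - m$start
      } else {
        l <- interval_len_excluding(m$start, m$end, ex$start, ex$end)
      }
      donor <- donor + sum(l[m$strain == donor_strain])
      tot <- tot + sum(l)
    }
  }
  if (tot == 0) return(0)
  donor / tot
}

#' Export a diploid genome's haplotype mosaics as a BED-like table
#'
#' @param genome A [diploid_genome].
#' @return data.frame with columns chrom, start, end, strain, copy.
#' @export
mosaics_to_bed <- function(genome) {
  rows <- list()
  for (nm in genome$layout$chromosomes$name) {
    for (cp in c("A", "B")) {
      m <- genome$haplotypes[[nm]][[cp]]
      rows[[length(rows) + 1]] <- data.frame(
        chrom = nm, start = m$start, end = m$end, strain = m$strain, copy = cp)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
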