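# Shared fixtures, built once per test run.

built <- build_default_layout()
layout <- built$layout
registry <- built$registry
drivers <- built$drivers
driver <- drivers[drivers$engineered, , drop = FALSE][1, , drop = FALSE]
suppressor <- drivers[!drivers$engineered, , drop = FALSE][1, , drop = FALSE]

donor_founder <- founder_genome(layout, "DONOR")
ref_founder <- founder_genome(layout, "REFSTRAIN")

make_f1 <- function(seed) cross(donor_founder, ref_founder, seed)

# F2 intercross animal: non-trivial haplotype mosaic on both copies.
make_f2 <- function(seed) {
  cross(make_f1(derive_seed_t(seed, 1)), make_f1(derive_seed_t(seed, 2)),
        derive_seed_t(seed, 3))
}

# test-local seed derivation (independent of the package's internal one)
derive_seed_t <- function(seed, i) (seed * 1009 + i * 101) %% 1000003

with_test_seed <- function(seed, code) withr::with_seed(seed, code)

# Wrap a plain ratio vector as a log_ratio_profile on unit bins.
as_ratio_profile <- function(x, chrom = "chrT", bin_size = 1) {
  structure(
    data.frame(chrom = chrom, start = (seq_along(x) - 1) * bin_size,
               end = seq_along(x) * bin_size, log2_ratio = x),
    bin_size = bin_size, class = c("log_ratio_profile", "data.frame"))
}

# Exhaustive least-squares oracle: best 3-segment fit of a vector, searching
# all changepoint pairs (i < j). Returns c(i, j): segments 1..i, i+1..j, j+1..n.
exhaustive_two_changepoints <- function(x) {
  n <- length(x)
  cs <- c(0, cumsum(x))
  css <- c(0, cumsum(x^2))
  ss <- function(l, h) (css[h + 1] - css[l]) - (cs[h + 1] - cs[l])^2 / (h - l + 1)
  best <- c(NA, NA)
  best_sse <- Inf
  for (i in 1:(n - 2)) {
    for (j in (i + 1):(n - 1)) {
      sse <- ss(1, i) + ss(i + 1, j) + ss(j + 1, n)
      if (sse < best_sse) {
        best_sse <- sse
        best <- c(i, j)
      }
    }
  }
  best
}
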