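# Shared fixtures and independent oracles.  Expensive synthetic datasets
# are built once per test run and memoized.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, .fixture_cache)) assign(key, builder(), .fixture_cache)
  get(key, .fixture_cache)
}

# Small single-chromosome config for fast module tests.
tiny_cfg <- function(...) {
  args <- utils::modifyList(list(
    genome = data.frame(chrom = "chrS", length = 4.8e6,
                        stringsAsFactors = FALSE),
    n_domains_per_chrom = 8,
    domain_length_range = c(250e3, 400e3),
    rng_seed = 11
  ), list(...))
  do.call(sim_config, args)
}

tiny_ds <- function() memo("tiny_ds", function() generate_dataset(tiny_cfg()))

# Default study-scale dataset and pipeline run (seed 7, 60 domains,
# target correlation 0.6), shared across tests.
default_ds <- function() memo("default_ds", function()
  generate_dataset(sim_config()))

default_run <- function() memo("default_run", function()
  run_pipeline(default_ds()))

# Dense symmetric matrix -> contact_matrix (stores the upper triangle).
cm_from_dense <- function(D, chrom = "chrT", resolution = 10000) {
  idx <- which(upper.tri(D, diag = TRUE) & D != 0, arr.ind = TRUE)
  contact_matrix(idx[, 1], idx[, 2], D[idx], chrom, resolution, nrow(D))
}

# Random sparse symmetric O/E matrix as a dense array (independent of the
# package's sparse representation).
random_dense <- function(n, density = 0.3) {
  D <- matrix(0, n, n)
  up <- which(upper.tri(D, diag = TRUE))
  nz <- sample(up, max(1, round(density * length(up))))
  D[nz] <- round(stats::runif(length(nz), 0, 5), 6)
  D[lower.tri(D)] <- t(D)[lower.tri(D)]
  D
}

## ---- brute-force oracles (enumeration over the dense array) ----

oracle_domain_contacts <- function(D, bins) {
  s <- 0; np <- 0
  for (i in bins) for (j in bins) if (i < j) { s <- s + D[i, j]; np <- np + 1 }
  s / np
}

oracle_loop_contacts <- function(D, b1, b2) {
  s <- 0
  for (i in b1) for (j in b2) s <- s + D[i, j]
  s / (length(b1) * length(b2))
}

oracle_insulation <- function(D, b, ell, eps = 1e-6) {
  w <- (b - ell):(b + ell - 1)
  total <- 0; crossing <- 0
  for (i in w) for (j in w) if (i < j) {
    total <- total + D[i, j]
    if (i < b && j >= b) crossing <- crossing + D[i, j]
  }
  -log2((crossing + eps) / (total + eps))
}

oracle_apa <- function(D, centers, w) {
  size <- 2 * w + 1
  agg <- matrix(0, size, size)
  for (k in seq_len(nrow(centers))) {
    ci <- centers[k, 1]; cj <- centers[k, 2]
    agg <- agg + D[(ci - w):(ci + w), (cj - w):(cj + w)]
  }
  agg <- agg / nrow(centers)
  cw <- ceiling(w / 2)
  ll <- agg[(size - cw + 1):size, 1:cw, drop = FALSE]
  list(aggregate = agg, p2ll = agg[w + 1, w + 1] / mean(ll))
}

# Interval data.frame shorthand.
iv <- function(chrom, start, end) {
  data.frame(chrom = rep_len(chrom, length(start)), start = start, end = end,
             stringsAsFactors = FALSE)
}

iv_val <- function(chrom, start, end, value) {
  data.frame(chrom = chrom, start = start, end = end, value = value,
             stringsAsFactors = FALSE)
}

lp <- function(chrom, s1, e1, s2, e2) {
  data.frame(chrom = rep_len(chrom, length(s1)), start1 = s1, end1 = e1,
             start2 = s2, end2 = e2, stringsAsFactors = FALSE)
}
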