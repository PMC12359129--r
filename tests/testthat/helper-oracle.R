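# Independent oracles and shared fixtures.
#
# The 1-D k-means oracle exploits that optimal squared-error clusters of
# scalar data are contiguous in sorted order, so the global optimum is found
# by enumerating all C(m-1, k-1) contiguous partitions. It shares no code
# with tier_kmeans().
kmeans_oracle_1d <- function(x, k) {
  m <- length(x)
  ord <- order(x)
  xs <- x[ord]
  cuts <- utils::combn(m - 1L, k - 1L, simplify = FALSE)
  if (k == 1L) cuts <- list(integer(0))
  best_wcss <- Inf; best_bnd <- NULL
  for (cut in cuts) {
    bnd <- c(0L, cut, m)
    wcss <- 0
    for (s in seq_len(k)) {
      seg <- xs[(bnd[s] + 1L):bnd[s + 1L]]
      wcss <- wcss + sum((seg - mean(seg))^2)
    }
    if (wcss < best_wcss) { best_wcss <- wcss; best_bnd <- bnd }
  }
  # tier 1 = segment with the largest values (last in ascending order)
  tier <- integer(m)
  for (s in seq_len(k))
    tier[ord[(best_bnd[s] + 1L):best_bnd[s + 1L]]] <- k - s + 1L
  list(wcss = best_wcss, tier = stats::setNames(tier, names(x)))
}

# brute-force Shannon entropy weighting, written independently of R/entropy.R
entropy_oracle <- function(g) {
  m <- nrow(g)
  w <- numeric(ncol(g))
  for (j in seq_len(ncol(g))) {
    p <- g[, j] / sum(g[, j])
    h <- 0
    for (i in seq_len(m)) if (p[i] > 0) h <- h - p[i] * log(p[i])
    w[j] <- 1 - h / log(m)
  }
  w / sum(w)
}

# 3 alternatives x 2 benefit criteria toys with frozen pre-build oracle
# scores (hand/numpy evaluation of each method's published equations)
toy_sym <- function() matrix(c(10, 5, 2, 2, 5, 10), nrow = 3,
                             dimnames = list(c("A", "B", "C"), c("c1", "c2")))
toy_asym <- function() matrix(c(8, 6, 3, 3, 6, 9), nrow = 3,
                              dimnames = list(c("A", "B", "C"), c("c1", "c2")))

toy_oracle <- list(
  sym = list(
    weights = c(0.5, 0.5),
    topsis = c(0.5, 0.375, 0.5),
    edas   = c(0.5, 0.318182, 0.5),
    waspas = c(0.523607, 0.5, 0.523607),
    vikor  = c(0.5, 0.5, 0.5),
    cocoso = c(2.047810, 2.061999, 2.047810)),
  asym = list(
    weights = c(0.6, 0.4),
    topsis = c(0.573369, 0.563770, 0.426631),
    edas   = c(0.645833, 0.571429, 0.404762),
    waspas = c(0.688864, 0.716076, 0.590080),
    vikor  = c(0.222222, 0.100000, 1.000000),
    cocoso = c(2.039244, 2.475839, 1.700062),
    entropy = c(0.446038, 0.553962)))

# published EU-27 reference table, loaded once per test run
eu_ref <- eu_hes_results("scores")

# directory where workbook sheet exports enable the full data reproduction
supplementary_dir <- function()
  system.file("extdata", "ghsi-supplementary", package = "hespat")
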