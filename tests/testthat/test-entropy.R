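test_that("column shares follow their definition", {
  g <- decision_matrix(matrix(c(1, 3, 5, 5), 2, 2), bounds = c(0, 10))
  sh <- entropy_shares(g)
  expect_equal(unname(sh[, 1]), c(0.25, 0.75))
  expect_equal(unname(sh[, 2]), c(0.5, 0.5))
  expect_equal(unname(colSums(sh)), c(1, 1))

  expect_error(entropy_shares(matrix(c(-1, 2), 2, 1)), "nonnegative")
  expect_error(entropy_shares(matrix(c(0, 0, 1, 2), 2, 2)), "zero column sum")
})

test_that("entropy is 1 for uniform columns and matches hand values", {
  for (m in c(2, 5, 10)) {
    sh <- matrix(1 / m, m, 1)
    expect_equal(unname(entropy_values(sh)), 1)
  }
  # -(1/ln 2)(0.25 ln 0.25 + 0.75 ln 0.75)
  expect_equal(unname(entropy_values(matrix(c(0.25, 0.75), 2, 1))),
               0.811278, tolerance = 1e-6)
  expect_error(entropy_values(matrix(1, 1, 1)), "at least 2")
  # 0 ln 0 convention: a fully concentrated column has entropy 0
  expect_equal(unname(entropy_values(matrix(c(1, 0, 0), 3, 1))), 0)
})

test_that("divergence weighting excludes constant columns and normalizes", {
  expect_equal(unname(divergence_weights(c(1, 0.5))), c(0, 1))
  expect_error(divergence_weights(c(1, 1)), "no discriminating information")
  expect_equal(unname(divergence_weights(c(1, 1), uniform_fallback = TRUE)),
               c(0.5, 0.5))
  expect_error(divergence_weights(c(1.2, 0.5)), "0, 1")
})

test_that("end-to-end weights reproduce the hand-computed 2x2 example", {
  # columns with shares (0.25, 0.75) and (0.8, 0.2):
  # entropies 0.811278 / 0.721928, divergences normalize to 0.404 / 0.596
  g <- decision_matrix(matrix(c(25, 75, 80, 20), 2, 2))
  ew <- entropy_weights(g)
  expect_equal(unname(ew$entropies), c(0.811278, 0.721928), tolerance = 1e-6)
  expect_equal(unname(coef(ew)), c(0.404294, 0.595706), tolerance = 1e-6)
  expect_equal(sum(coef(ew)), 1)
})

test_that("printed per-indicator entropies yield the published weight row", {
  ent <- c(0.99328, 0.98508, 0.99159, 0.99344, 0.99825, 0.99829)
  w <- divergence_weights(ent)
  expect_lte(max(abs(unname(w) -
                       c(0.168, 0.372, 0.210, 0.164, 0.044, 0.043))), 1e-3)
})

test_that("a single varying column takes all the weight", {
  g <- decision_matrix(cbind(a = c(10, 60, 30), b = c(40, 40, 40)))
  ew <- suppressWarnings(entropy_weights(g))
  expect_equal(unname(coef(ew)), c(1, 0))
})

test_that("weights agree with the independent brute-force oracle", {
  set.seed(42)
  for (i in 1:20) {
    g <- matrix(runif(6 * 4, 1, 100), 6, 4)
    expect_equal(unname(coef(entropy_weights(decision_matrix(g)))),
                 entropy_oracle(g), tolerance = 1e-10)
  }
})

test_that("entropy weighting is scale-invariant and permutation-equivariant", {
  set.seed(7)
  for (i in 1:20) {
    g <- matrix(runif(8 * 5, 1, 100), 8, 5,
                dimnames = list(paste0("r", 1:8), paste0("c", 1:5)))
    ew <- entropy_weights(decision_matrix(g, bounds = range(g)))
    # multiply one column by c > 0: Eq-2 shares cancel the factor
    g2 <- g; g2[, 3] <- g2[, 3] * 17.5
    ew2 <- entropy_weights(decision_matrix(g2, bounds = range(g2)))
    expect_equal(coef(ew2), coef(ew), tolerance = 1e-12)
    expect_equal(ew2$shares, ew$shares, tolerance = 1e-12)
    # permuting rows and columns permutes outputs accordingly
    pr <- sample(8); pc <- sample(5)
    ew3 <- entropy_weights(decision_matrix(g[pr, pc], bounds = range(g)))
    expect_equal(coef(ew3), coef(ew)[pc], tolerance = 1e-12)
  }
})

test_that("concentrating a two-country column strictly lowers its entropy", {
  p <- seq(0.5, 0.95, by = 0.05)
  ent <- vapply(p, function(q)
    unname(entropy_values(matrix(c(q, 1 - q), 2, 1))), numeric(1))
  expect_true(all(diff(ent) < 0))
})
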