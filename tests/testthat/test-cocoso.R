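test_that("min-max normalization handles both orientations and degeneracy", {
  g <- decision_matrix(cbind(a = c(0, 5, 10), b = c(20, 30, 40)))
  n <- minmax_normalize(g)
  expect_equal(unname(n[, "a"]), c(0, 0.5, 1))
  expect_true(all(n >= 0 & n <= 1))

  nc <- minmax_normalize(decision_matrix(cbind(a = c(0, 10), b = c(1, 2))),
                         orientation = c("cost", "benefit"))
  expect_equal(unname(nc[, "a"]), c(1, 0))

  expect_warning(ncst <- minmax_normalize(cbind(a = c(5, 5), b = c(1, 2))),
                 "constant")
  expect_equal(unname(ncst[, "a"]), c(0, 0))
  ex <- attr(n, "column_extremes")
  expect_equal(unname(ex["max", "a"]), 10)
})

test_that("comparability sums follow Eq-style definitions", {
  norm <- matrix(1, 2, 3, dimnames = list(c("x", "y"), c("a", "b", "c")))
  cp <- comparability_sums(norm, c(0.2, 0.3, 0.5))
  expect_equal(unname(cp$CS), c(1, 1))
  expect_equal(unname(cp$P), c(3, 3))
  expect_error(comparability_sums(norm, c(-0.1, 0.6, 0.5)), "nonnegative")
  expect_error(comparability_sums(norm, c(0.2, 0.3)), "expected 3 weights")
  # 0^w = 0 for w > 0
  cp0 <- comparability_sums(matrix(c(0, 1), 2, 1,
                                   dimnames = list(NULL, "a")), 1)
  expect_equal(unname(cp0$P), c(0, 1))
})

test_that("appraisal scores reproduce the hand example and symmetry", {
  k <- appraisal_scores(CS = c(0.6, 0.4), P = c(1, 1), lambda = 0.5)
  expect_equal(unname(k$ka), c(8, 7) / 15, tolerance = 1e-12)
  expect_equal(unname(k$kb), c(2.5, 2))
  expect_equal(unname(k$kc), c(1, 0.875))

  # identical alternatives: full symmetry
  ki <- appraisal_scores(CS = rep(0.5, 4), P = rep(2, 4), lambda = 0.3)
  expect_equal(unname(ki$ka), rep(0.25, 4))
  expect_equal(unname(ki$kb), rep(2, 4))
  expect_equal(unname(ki$kc), rep(1, 4))

  expect_error(appraisal_scores(CS = c(0, 0.4), P = c(1, 1)), "degenerate")
  expect_error(appraisal_scores(CS = c(0.1, 0.4), P = c(1, 1), lambda = 2),
               "lambda")
})

test_that("composite index matches hand-derived values", {
  # published worked row: printed (ka, kb, kc) rounded at 3 dp give Ci
  # within 0.005 of the printed 6.123
  expect_equal(composite_index(0.038, 15.125, 0.851), 6.123,
               tolerance = 0.005 / 6.123)
  expect_equal(composite_index(c(8, 7) / 15, c(2.5, 2), c(1, 0.875)),
               c(2.4450869, 2.0486095), tolerance = 1e-6)
  expect_equal(composite_index(0.3, 5, 0.8), composite_index(0.3, 5, 0.8))
  expect_error(composite_index(0, 1, 1), "positive")
})

test_that("ranking is competition-style with flagged ties", {
  expect_equal(unname(rank_alternatives(c(2.445, 2.049))), c(1L, 2L))
  expect_warning(r <- rank_alternatives(c(3, 3, 1)), "tied")
  expect_equal(unname(r), c(1L, 1L, 3L))
})

test_that("the cocoso fit carries coherent components and methods", {
  g <- decision_matrix(toy_asym(), bounds = c(0, 10))
  fit <- cocoso(g, weights = c(0.6, 0.4))
  expect_s3_class(fit, "cocoso")
  expect_equal(unname(fit$Ci), toy_oracle$asym$cocoso, tolerance = 1e-6)
  expect_equal(sum(fit$ka), 1)
  expect_true(all(fit$kb >= 2))
  expect_true(all(fit$kc > 0 & fit$kc <= 1))
  expect_equal(sort(unname(fit$rank)), 1:3)
  expect_equal(unname(coef(fit)), c(0.6, 0.4))
  d <- as.data.frame(fit)
  expect_identical(names(d), c("country", "CS", "P", "ka", "kb", "kc",
                               "Ci", "rank"))
  expect_output(print(fit), "CoCoSo ranking")
  # entropy-weighted variant stores its weighting
  fe <- cocoso(g)
  expect_s3_class(fe$entropy, "entropy_weights")
  expect_equal(unname(coef(fe)), toy_oracle$asym$entropy, tolerance = 1e-6)
})

test_that("benefit-column affine maps leave scores and ranks unchanged", {
  set.seed(11)
  for (i in 1:10) {
    g <- matrix(runif(7 * 4, 10, 90), 7, 4,
                dimnames = list(paste0("r", 1:7), paste0("c", 1:4)))
    w <- c(0.4, 0.3, 0.2, 0.1)
    fit <- cocoso(decision_matrix(g, bounds = c(0, 100)), weights = w)
    g2 <- g; g2[, 2] <- 0.35 * g2[, 2] + 12
    fit2 <- cocoso(decision_matrix(g2, bounds = c(0, 100)), weights = w)
    expect_equal(fit2$norm, fit$norm, tolerance = 1e-12,
                 ignore_attr = TRUE)  # extremes shift; values must not
    expect_equal(fit2$Ci, fit$Ci, tolerance = 1e-10)
    expect_identical(fit2$rank, fit$rank)
  }
})

test_that("elementwise dominance implies a strictly better composite", {
  set.seed(23)
  for (i in 1:10) {
    base <- matrix(runif(6 * 4, 20, 80), 6, 4)
    base[2, ] <- base[1, ] + runif(4, 0.5, 5)   # row 2 dominates row 1
    w <- rep(0.25, 4)
    fit <- cocoso(decision_matrix(base, bounds = c(0, 100)), weights = w)
    expect_gt(fit$CS[2], fit$CS[1])
    expect_gte(fit$P[2], fit$P[1])
    expect_gt(fit$Ci[2], fit$Ci[1])
  }
})

test_that("lambda limits reduce kc to the single-strand ratios", {
  g <- decision_matrix(toy_asym(), bounds = c(0, 10))
  f0 <- cocoso(g, weights = c(0.6, 0.4), lambda = 0)
  f1 <- cocoso(g, weights = c(0.6, 0.4), lambda = 1)
  expect_equal(unname(f0$kc), unname(f0$P / max(f0$P)), tolerance = 1e-12)
  expect_equal(unname(f1$kc), unname(f1$CS / max(f1$CS)), tolerance = 1e-12)
})

test_that("epsilon regularization rescues an all-minimum alternative", {
  g <- decision_matrix(rbind(worst = c(10, 10), mid = c(50, 40),
                             best = c(90, 80)))
  expect_error(cocoso(g, weights = c(0.5, 0.5)), "worst")
  fit <- cocoso(g, weights = c(0.5, 0.5), epsilon = 1e-6)
  expect_equal(unname(fit$rank), c(3L, 2L, 1L))
})
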