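test_that("weight shifts are later minus earlier and conserve mass", {
  wa <- c(Prevention = 0.168, `Health system` = 0.164, Other = 0.668)
  wb <- c(Prevention = 0.162, `Health system` = 0.182, Other = 0.656)
  st <- weight_shift(wa, wb)
  expect_equal(st$shift[st$entity == "Health system"], 0.018)
  expect_equal(sum(st$shift), 0, tolerance = 1e-12)

  same <- weight_shift(wa, wa)
  expect_true(all(same$shift == 0))
  # alignment by name, not position
  st2 <- weight_shift(wa, wb[c(3, 1, 2)])
  expect_equal(st2$shift, st$shift)
  expect_error(weight_shift(wa, c(A = 0.5, B = 0.5)), "different indicators")
})

test_that("rank shifts are earlier minus later (positive = improvement)", {
  ra <- c(Poland = 20L, Lithuania = 13L, Malta = 27L)
  rb <- c(Poland = 14L, Lithuania = 9L, Malta = 27L)
  st <- rank_shift(ra, rb)
  expect_equal(st$shift[st$entity == "Poland"], 6)
  expect_equal(st$shift[st$entity == "Malta"], 0)

  # tier analogue: Lithuania moving from tier 2 to tier 1 is +1
  tt <- rank_shift(c(Lithuania = 2L), c(Lithuania = 1L))
  expect_equal(tt$shift, 1)

  # two full tie-free rankings: shifts cancel
  set.seed(1)
  p1 <- sample(10); p2 <- sample(10)
  names(p1) <- names(p2) <- paste0("c", 1:10)
  expect_equal(sum(rank_shift(p1, p2)$shift), 0)
  expect_error(rank_shift(ra, c(Malta = 1L, France = 2L, Spain = 3L)),
               "different countries")
})

test_that("shift summaries partition by sign with two-decimal percentages", {
  s <- shift_summary(c(1, -1))
  expect_equal(s$count, c(1L, 0L, 1L))
  expect_equal(s$percent, c(50, 0, 50))

  z <- shift_summary(rep(0, 5))
  expect_equal(z$count[z$status == "unchanged"], 5L)
  expect_equal(z$percent[z$status == "unchanged"], 100)
  expect_equal(sum(shift_summary(c(3, 0, -2, 1))$count), 4L)
  expect_equal(shift_summary(c(1, 0, 0))$percent[1], 33.33)
})

test_that("cluster profiles average indicators within tiers", {
  g <- decision_matrix(rbind(A = c(40, 10), B = c(60, 30), C = c(20, 50)))
  prof <- cluster_profile(g, c(A = 1, B = 1, C = 2))
  expect_equal(prof[[3]][prof$tier == "1"], 50)   # mean of 40, 60
  expect_equal(prof$n, c(2L, 1L))
  # singleton tier reproduces the country's own row
  expect_equal(unlist(prof[prof$tier == "2", c(3, 4)], use.names = FALSE),
               c(20, 50))
  # names aligned, not positional
  prof2 <- cluster_profile(g, c(C = 2, A = 1, B = 1))
  expect_equal(prof2, prof)
  expect_error(cluster_profile(g, c(A = 1, B = 1)), "no tier assigned.*C")
  # accepts a tier_kmeans fit directly
  fit <- tier_kmeans(c(A = 9, B = 8.5, C = 1), k = 2, restarts = 5, seed = 0)
  expect_s3_class(cluster_profile(g, fit), "data.frame")
})

test_that("regional weight comparison returns an aligned long table", {
  w1 <- c(Prevention = 0.3, Response = 0.7)
  w2 <- c(Response = 0.4, Prevention = 0.6)  # permuted order
  out <- regional_weight_comparison(list(EU = list(`2019` = w1, `2021` = w2)))
  expect_identical(names(out), c("region", "period", "indicator", "weight"))
  expect_equal(nrow(out), 4L)
  expect_equal(out$weight[out$period == "2021" & out$indicator == "Prevention"],
               0.6)
  # flat list passes through
  flat <- regional_weight_comparison(list(EU = w1))
  expect_equal(flat$weight, unname(w1))
  expect_error(regional_weight_comparison(
    list(EU = w1, Africa = c(Prevention = 0.5, Health = 0.5))),
    "differ across")
})
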