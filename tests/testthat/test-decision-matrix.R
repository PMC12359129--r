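test_that("construction enforces completeness, uniqueness and bounds", {
  g <- decision_matrix(rbind(A = c(50, 60), B = c(70, 80)), period = "2019")
  expect_s3_class(g, "decision_matrix")
  expect_identical(attr(g, "period"), "2019")

  expect_error(decision_matrix(rbind(A = c(50, NA), B = c(70, 80)),
                               indicators = c("Prevention", "Rapid response")),
               "A.*Rapid response")
  expect_error(decision_matrix(rbind(c(1, 2), c(3, 4)),
                               countries = c("X", "X")), "duplicate country")
  expect_error(decision_matrix(rbind(A = c(1, 2), B = c(3, 4)),
                               indicators = c("p", "p")), "duplicate indicator")
  expect_error(decision_matrix(rbind(A = c(50, 105), B = c(70, 80))),
               "outside bounds")
  expect_error(decision_matrix(matrix(1, 1, 2)), "at least 2 countries")
  # wider bounds admit the same score
  expect_silent(decision_matrix(rbind(A = c(50, 105), B = c(70, 80)),
                                bounds = c(0, 200)))
})

test_that("delimited reader preserves order and names offending cells", {
  f <- system.file("extdata", "toy_matrix.csv", package = "hespat")
  g <- read_decision_matrix(f)
  expect_equal(dim(g), c(5L, 3L))
  expect_identical(rownames(g)[1:2], c("Alba", "Brolland"))
  expect_identical(colnames(g)[1], "Prevention")
  expect_equal(g["Corvia", "Prevention"], 80.6)

  bad <- tempfile(fileext = ".csv")
  writeLines(c("country,Prevention,Response",
               "Austria,53.3,47.9", "Croatia,NA,37.0"), bad)
  expect_error(read_decision_matrix(bad), "Croatia.*Prevention")

  dup <- tempfile(fileext = ".csv")
  writeLines(c("country,Prevention", "Malta,50", "Malta,60"), dup)
  expect_error(read_decision_matrix(dup), "duplicate country")

  oob <- tempfile(fileext = ".csv")
  writeLines(c("country,Prevention", "Malta,150", "Cyprus,60"), oob)
  expect_error(read_decision_matrix(oob), "outside bounds")

  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("country\tPrevention\tResponse",
               "Malta\t50\t60", "Cyprus\t40\t70"), tsv)
  expect_equal(unname(read_decision_matrix(tsv)["Cyprus", "Response"]), 70)
})

test_that("validation reports constant columns, bounds and small m", {
  g <- decision_matrix(rbind(A = c(50, 50), B = c(50, 80)))
  rep_ <- validate_matrix(g)
  expect_true(rep_$ok)  # warnings only
  expect_identical(rep_$constant_columns, colnames(g)[1])
  expect_true(any(rep_$issues$severity == "warning"))
  expect_true(any(grepl("fewer than 3", rep_$issues$message)))

  # plain matrix with an out-of-bounds score is reported, not rejected
  raw <- rbind(A = c(105, 50), B = c(60, 70), C = c(55, 60))
  rep2 <- validate_matrix(raw, bounds = c(0, 100))
  expect_false(rep2$ok)
  expect_true(any(rep2$issues$severity == "error"))

  # degenerate 2x1 of equal scores
  rep3 <- validate_matrix(decision_matrix(matrix(c(50, 50), 2, 1)))
  expect_length(rep3$constant_columns, 1L)

  clean <- validate_matrix(decision_matrix(rbind(A = c(1, 2), B = c(3, 4),
                                                 C = c(5, 6))))
  expect_true(clean$ok)
  expect_identical(nrow(clean$issues), 0L)
})

test_that("write -> read round-trips a matrix up to the written precision", {
  g <- decision_matrix(matrix(runif(12, 10, 90), 4, 3,
                              dimnames = list(paste0("ctry", 1:4),
                                              c("Prevention", "Response", "Health system"))))
  f <- tempfile(fileext = ".csv")
  write_table(as.data.frame(g), f, digits = 6)
  g2 <- read_decision_matrix(f)
  expect_identical(rownames(g2), rownames(g))
  expect_identical(colnames(g2), colnames(g))
  expect_equal(unclass(g2), unclass(g), tolerance = 1e-6,
               ignore_attr = TRUE)

  expect_error(write_table(data.frame(), tempfile()), "empty")
  expect_error(write_table(data.frame(a = 1), "/nonexistent/dir/x.csv"),
               "cannot write")
})
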