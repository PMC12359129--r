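#' Min-max normalize a decision matrix
#'
#' Rescales every indicator column to \[0, 1\] against its own extremes:
#' benefit criteria as (g - min)/(max - min), cost criteria with the
#' direction reversed so 1 is always "best". A constant column is mapped to
#' all zeros by convention (with a warning); in the entropy-weighted
#' pipeline such a column carries weight 0, so the convention cannot affect
#' the composite index.
#'
#' @param matrix a [decision_matrix()] or numeric matrix.
#' @param orientation `"benefit"` or `"cost"`, length 1 or one per
#'   indicator. All six GHSI pillars are benefit criteria (the published
#'   index already scores a safer risk environment higher).
#' @return matrix in \[0, 1\] with attributes `orientation` and
#'   `column_extremes` (2 x n matrix of min/max).
#' @export
minmax_normalize <- function(matrix, orientation = "benefit") {
  g <- if (inherits(matrix, "decision_matrix")) unclass_matrix(matrix) else as.matrix(matrix)
  n <- ncol(g)
  orientation <- match.arg(rep_len(orientation, n), c("benefit", "cost"),
                           several.ok = TRUE)
  lo <- apply(g, 2L, min); hi <- apply(g, 2L, max)
  rng <- hi - lo
  constant <- rng == 0
  if (any(constant)) {
    warning("constant column(s) normalized to 0: ",
            paste(colnames(g)[constant], collapse = ", "), call. = FALSE)
    rng[constant] <- 1  # placeholder; numerator is 0 for these columns
  }
  norm <- sweep(sweep(g, 2L, lo, "-"), 2L, rng, "/")
  flip <- orientation == "cost"
  if (any(flip)) norm[, flip] <- 1 - norm[, flip, drop = FALSE]
  norm[, constant] <- 0
  structure(norm, orientation = orientation,
            column_extremes = rbind(min = lo, max = hi))
}

#' Weighted comparability sequences
#'
#' The two aggregation strands of CoCoSo: the weighted sum
#' \eqn{CS_i = \sum_j w_j n_{ij}} (in \[0, 1\]) and the power-weighted sum
#' \eqn{P_i = \sum_j n_{ij}^{w_j}} (in \[0, n\]), with \eqn{0^w = 0} for
#' w > 0.
#'
#' @param norm normalized matrix from [minmax_normalize()].
#' @param weights a weight vector or [entropy_weights()] object (length n,
#'   nonnegative, summing to 1).
#' @return list with numeric vectors `CS` and `P`, named by country.
#' @export
comparability_sums <- function(norm, weights) {
  w <- as_weight_vector(weights, colnames(norm))
  CS <- drop(norm %*% w)
  # R's 0^w is already 0 for w > 0 and 1 for w = 0 (zero-weight column:
  # the constant contributes equally to every country)
  P <- rowSums(sweep(norm, 2L, w, "^"))
  list(CS = stats::setNames(CS, rownames(norm)),
       P = stats::setNames(P, rownames(norm)))
}

#' CoCoSo appraisal scores
#'
#' Three compromise appraisal strategies built from the comparability sums:
#' \deqn{k_{ia} = (P_i + CS_i) / \sum_i (P_i + CS_i)}
#' \deqn{k_{ib} = CS_i/\min CS + P_i/\min P}
#' \deqn{k_{ic} = \frac{\lambda CS_i + (1-\lambda) P_i}{\lambda \max CS + (1-\lambda) \max P}}
#' `lambda` (the balance coefficient, 0.5 by default for parity) trades off
#' the additive against the multiplicative strand in \eqn{k_{ic}}.
#'
#' `min(CS) = 0` (a country at the minimum of every weighted criterion)
#' makes \eqn{k_{ib}} undefined and is surfaced as a hard error naming the
#' degenerate country; `epsilon` optionally shifts all normalized values
#' away from zero beforehand (off by default -- no regularization is applied
#' unless asked for).
#'
#' @param CS,P comparability sums from [comparability_sums()].
#' @param lambda balance coefficient in \[0, 1\].
#' @return list with numeric vectors `ka`, `kb`, `kc`.
#' @export
appraisal_scores <- function(CS, P, lambda = 0.5) {
  stopifnot(length(CS) == length(P))
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda < 0 || lambda > 1)
    stop("`lambda` must be a single number in [0, 1]", call. = FALSE)
  if (min(CS) <= 0 || min(P) <= 0) {
    deg <- names(CS)[which.min(CS)]
    if (min(P) <= 0) deg <- union(deg, names(P)[which.min(P)])
    stop("degenerate comparability sum (<= 0) for: ",
         paste(deg, collapse = ", "),
         "; a country at the column minimum of every criterion makes the ",
         "ratio appraisal undefined (consider `epsilon` in cocoso())",
         call. = FALSE)
  }
  tot <- CS + P
  ka <- tot / sum(tot)
  kb <- CS / min(CS) + P / min(P)
  kc <- (lambda * CS + (1 - lambda) * P) /
    (lambda * max(CS) + (1 - lambda) * max(P))
  list(ka = ka, kb = kb, kc = kc)
}

#' CoCoSo composite index
#'
#' Final aggregation of the three appraisal scores: the geometric mean plus
#' the arithmetic mean,
#' \deqn{C_i = (k_{ia} k_{ib} k_{ic})^{1/3} + (k_{ia} + k_{ib} + k_{ic})/3.}
#'
#' @param ka,kb,kc appraisal score vectors (positive, equal length).
#' @return numeric vector of composite indices.
#' @export
composite_index <- function(ka, kb, kc) {
  stopifnot(length(ka) == length(kb), length(kb) == length(kc))
  if (any(ka <= 0 | kb <= 0 | kc <= 0))
    stop("appraisal scores must be positive", call. = FALSE)
  (ka * kb * kc)^(1 / 3) + (ka + kb + kc) / 3
}

#' Rank alternatives by descending score
#'
#' Rank 1 is the largest value. Ties receive competition ranking (equal
#' rank, next rank skipped) and are flagged with a warning; the published
#' EU tables contain none, but synthetic data may.
#'
#' @param Ci numeric score vector (larger = better).
#' @return integer rank vector with the same names.
#' @export
rank_alternatives <- function(Ci) {
  if (anyDuplicated(Ci))
    warning("tied composite scores; competition ranking applied", call. = FALSE)
  r <- rank(-Ci, ties.method = "min")
  stats::setNames(as.integer(r), names(Ci))
}

#' Fit a CoCoSo ranking model
#'
#' The Combined Compromise Solution ranks alternatives by fusing a weighted
#' sum and a power-weighted sum of min-max normalized scores through three
#' appraisal strategies, aggregated into one composite index per country
#' (see [composite_index()]). With `weights = NULL` the indicator weights
#' are computed objectively from the data by the entropy method
#' ([entropy_weights()]), giving the entropy-CoCoSo model.
#'
#' @param x a [decision_matrix()] or numeric score matrix.
#' @param weights indicator weights (vector or [entropy_weights()] object),
#'   or `NULL` to use entropy weights.
#' @param lambda balance coefficient in \[0, 1\], default 0.5.
#' @param orientation per-indicator `"benefit"`/`"cost"` flags.
#' @param epsilon optional shift added to the normalized matrix to avoid a
#'   zero minimum comparability sum; 0 (off) by default.
#' @return an object of class `cocoso` with components `countries`,
#'   `weights`, `entropy` (the entropy_weights fit, when used), `norm`,
#'   `CS`, `P`, `ka`, `kb`, `kc`, `Ci`, `rank`, `lambda`, `ties`.
#'   Supports `print`, `summary`, `coef` (the weight vector), `plot`,
#'   and `as.data.frame`.
#' @examples
#' g <- decision_matrix(rbind(A = c(8, 3), B = c(6, 6), C = c(3, 9)),
#'                      bounds = c(0, 10))
#' fit <- cocoso(g, weights = c(0.6, 0.4))
#' fit
#' as.data.frame(fit)
#' @export
cocoso <- function(x, weights = NULL, lambda = 0.5, orientation = "benefit",
                   epsilon = 0) {
  if (!inherits(x, "decision_matrix") )
    x <- decision_matrix(x, bounds = range(x), period = NULL)
  ew <- NULL
  if (is.null(weights)) {
    ew <- entropy_weights(x)
    weights <- ew$weights
  }
  w <- as_weight_vector(weights, colnames(x))
  norm <- minmax_normalize(x, orientation)
  if (epsilon > 0) norm[] <- norm + epsilon
  cp <- comparability_sums(norm, w)
  k <- appraisal_scores(cp$CS, cp$P, lambda)
  Ci <- composite_index(k$ka, k$kb, k$kc)
  ties <- anyDuplicated(Ci) > 0L
  rk <- suppressWarnings(rank_alternatives(Ci))
  structure(list(countries = rownames(x), weights = w, entropy = ew,
                 norm = norm, CS = cp$CS, P = cp$P,
                 ka = k$ka, kb = k$kb, kc = k$kc, Ci = Ci, rank = rk,
                 lambda = lambda, ties = ties,
                 period = attr(x, "period"), call = match.call()),
            class = "cocoso")
}

#' @export
coef.cocoso <- function(object, ...) object$weights

#' @export
as.data.frame.cocoso <- function(x, ...) {
  data.frame(country = x$countries, CS = unname(x$CS), P = unname(x$P),
             ka = unname(x$ka), kb = unname(x$kb), kc = unname(x$kc),
             Ci = unname(x$Ci), rank = unname(x$rank), row.names = NULL)
}

#' @export
print.cocoso <- function(x, digits = 3, ...) {
  cat(sprintf("CoCoSo ranking of %d alternatives (lambda = %g%s)\n",
              length(x$Ci), x$lambda,
              if (is.null(x$entropy)) ", supplied weights" else ", entropy weights"))
  d <- as.data.frame(x)
  d <- d[order(d$rank), c("country", "Ci", "rank")]
  d$Ci <- round(d$Ci, digits)
  print(utils::head(d, 10L), row.names = FALSE)
  if (nrow(d) > 10L) cat("  ...", nrow(d) - 10L, "more\n")
  if (x$ties) cat("note: tied composite scores (competition ranking)\n")
  invisible(x)
}

#' @export
summary.cocoso <- function(object, digits = 3, ...) {
  cat("Weights:\n")
  print(round(object$weights, digits))
  cat("\n")
  d <- as.data.frame(object)
  d[-1] <- lapply(d[-1], round, digits)
  print(d[order(d$rank), ], row.names = FALSE)
  invisible(object)
}

#' @export
plot.cocoso <- function(x, ...) {
  ord <- order(x$Ci)
  graphics::barplot(x$Ci[ord], names.arg = x$countries[ord], horiz = TRUE,
                    las = 1, xlab = "composite index Ci",
                    main = "CoCoSo composite scores", ...)
  invisible(x)
}
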