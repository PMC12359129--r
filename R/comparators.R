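#' Rank a weighted decision matrix with a classical MCDM method
#'
#' Runs one of five entropy-compatible rankers on the same matrix and weight
#' vector, harmonized so that rank 1 is always the best alternative
#' regardless of whether the method's raw score is maximized (CoCoSo Ci,
#' TOPSIS closeness, EDAS appraisal, WASPAS joint score) or minimized
#' (VIKOR Q). The canonical published formulations are used:
#'
#' * **topsis** -- vector (root-sum-of-squares) normalization, weighted
#'   distances to the ideal and anti-ideal solutions, closeness coefficient
#'   D-/(D+ + D-).
#' * **edas** -- positive/negative distances from the per-criterion average
#'   solution, weighted, max-normalized, appraisal score (NSP + NSN)/2.
#' * **waspas** -- linear ratio normalization (g/max for benefit, min/g for
#'   cost), joint score `lambda_w` * WSM + (1 - `lambda_w`) * WPM.
#' * **vikor** -- min-max normalized group utility S and individual regret
#'   R, compromise Q with weight `v`; ranked by ascending Q (only the
#'   ranking, not the compromise-set conditions).
#' * **cocoso** -- delegates to [cocoso()].
#'
#' @param matrix a [decision_matrix()] or numeric matrix.
#' @param weights weight vector or [entropy_weights()] object.
#' @param method one of `"cocoso"`, `"topsis"`, `"edas"`, `"waspas"`,
#'   `"vikor"`.
#' @param orientation per-indicator `"benefit"`/`"cost"` flags.
#' @param lambda CoCoSo balance coefficient.
#' @param lambda_w WASPAS sum/product trade-off (default 0.5).
#' @param v VIKOR group-utility weight (default 0.5).
#' @param epsilon CoCoSo regularization shift (see [cocoso()]); relevant
#'   when an alternative sits at the minimum of every criterion.
#' @return an object of class `mcdm_ranking`: data frame with columns
#'   `country`, `score`, `rank`, plus attributes `method` and
#'   `higher_is_better`.
#' @export
run_comparator <- function(matrix, weights, method = c("cocoso", "topsis",
                                                       "edas", "waspas",
                                                       "vikor"),
                           orientation = "benefit", lambda = 0.5,
                           lambda_w = 0.5, v = 0.5, epsilon = 0) {
  method <- match.arg(method)
  g <- if (inherits(matrix, "decision_matrix")) unclass_matrix(matrix) else as.matrix(matrix)
  if (is.null(rownames(g))) rownames(g) <- paste0("alt", seq_len(nrow(g)))
  w <- as_weight_vector(weights, colnames(g))
  n <- ncol(g)
  orientation <- match.arg(rep_len(orientation, n), c("benefit", "cost"),
                           several.ok = TRUE)
  benefit <- orientation == "benefit"

  score <- switch(method,
    cocoso = cocoso(g, weights = w, lambda = lambda,
                    orientation = orientation, epsilon = epsilon)$Ci,
    topsis = topsis_score(g, w, benefit),
    edas = edas_score(g, w, benefit),
    waspas = waspas_score(g, w, benefit, lambda_w),
    vikor = vikor_score(g, w, benefit, v))
  higher <- method != "vikor"
  rk <- if (higher) rank(-score, ties.method = "min") else
    rank(score, ties.method = "min")
  structure(data.frame(country = rownames(g), score = unname(score),
                       rank = as.integer(unname(rk)), row.names = NULL),
            method = method, higher_is_better = higher,
            class = c("mcdm_ranking", "data.frame"))
}

topsis_score <- function(g, w, benefit) {
  denom <- sqrt(colSums(g^2))
  if (any(denom == 0)) denom[denom == 0] <- 1
  v <- sweep(sweep(g, 2L, denom, "/"), 2L, w, "*")
  ideal <- ifelse(benefit, apply(v, 2L, max), apply(v, 2L, min))
  anti  <- ifelse(benefit, apply(v, 2L, min), apply(v, 2L, max))
  dpos <- sqrt(rowSums(sweep(v, 2L, ideal, "-")^2))
  dneg <- sqrt(rowSums(sweep(v, 2L, anti, "-")^2))
  tot <- dpos + dneg
  out <- ifelse(tot == 0, 0.5, dneg / tot)  # identical alternatives: indifferent
  stats::setNames(out, rownames(g))
}

edas_score <- function(g, w, benefit) {
  av <- colMeans(g)
  if (any(av == 0))
    stop("EDAS requires nonzero criterion means", call. = FALSE)
  diffs <- sweep(g, 2L, av, "-")
  pda <- sweep(pmax(diffs, 0), 2L, av, "/")
  nda <- sweep(pmax(-diffs, 0), 2L, av, "/")
  if (any(!benefit)) {   # for cost criteria the roles of the distances swap
    tmp <- pda[, !benefit, drop = FALSE]
    pda[, !benefit] <- nda[, !benefit, drop = FALSE]
    nda[, !benefit] <- tmp
  }
  sp <- drop(pda %*% w); sn <- drop(nda %*% w)
  nsp <- if (max(sp) > 0) sp / max(sp) else rep(1, length(sp))
  nsn <- if (max(sn) > 0) 1 - sn / max(sn) else rep(1, length(sn))
  stats::setNames((nsp + nsn) / 2, rownames(g))
}

waspas_score <- function(g, w, benefit, lambda_w) {
  if (lambda_w < 0 || lambda_w > 1)
    stop("`lambda_w` must lie in [0, 1]", call. = FALSE)
  hi <- apply(g, 2L, max); lo <- apply(g, 2L, min)
  norm <- g
  for (j in seq_len(ncol(g))) {
    norm[, j] <- if (benefit[j]) {
      if (hi[j] == 0) 1 else g[, j] / hi[j]
    } else {
      if (any(g[, j] == 0))
        stop("WASPAS cost normalization undefined for zero scores", call. = FALSE)
      lo[j] / g[, j]
    }
  }
  wsm <- drop(norm %*% w)
  wpm <- apply(sweep(norm, 2L, w, "^"), 1L, prod)
  stats::setNames(lambda_w * wsm + (1 - lambda_w) * wpm, rownames(g))
}

vikor_score <- function(g, w, benefit, v) {
  if (nrow(g) < 2L) stop("VIKOR needs at least 2 alternatives", call. = FALSE)
  if (v < 0 || v > 1) stop("`v` must lie in [0, 1]", call. = FALSE)
  best <- ifelse(benefit, apply(g, 2L, max), apply(g, 2L, min))
  worst <- ifelse(benefit, apply(g, 2L, min), apply(g, 2L, max))
  rng <- best - worst
  keep <- rng != 0          # constant criteria contribute no regret
  d <- sweep(sweep(g, 2L, best, "-"), 2L, ifelse(keep, rng, 1), "/") * -1
  d[, !keep] <- 0
  wd <- sweep(d, 2L, w, "*")
  S <- rowSums(wd); R <- apply(wd, 1L, max)
  qs <- function(x) if (diff(range(x)) == 0) rep(0, length(x)) else
    (x - min(x)) / (max(x) - min(x))
  stats::setNames(v * qs(S) + (1 - v) * qs(R), rownames(g))
}

#' @export
print.mcdm_ranking <- function(x, digits = 4, ...) {
  cat(sprintf("%s ranking (%s score is better)\n", toupper(attr(x, "method")),
              if (attr(x, "higher_is_better")) "higher" else "lower"))
  d <- as.data.frame(x)
  d$score <- round(d$score, digits)
  print(d[order(d$rank), ], row.names = FALSE)
  invisible(x)
}

#' Spearman rank correlation of two rankings
#'
#' Average-rank tie correction (via [stats::cor()]); for tie-free rankings
#' this equals the classical 1 - 6 sum(d^2) / (m (m^2 - 1)). When both
#' vectors are named the second is aligned to the first by name.
#'
#' @param rank_a,rank_b rank (or score) vectors of equal length >= 2.
#' @return the correlation coefficient in \[-1, 1\].
#' @export
spearman_rho <- function(rank_a, rank_b) {
  if (length(rank_a) != length(rank_b))
    stop("rankings must have equal length", call. = FALSE)
  if (length(rank_a) < 2L) stop("need at least 2 ranked items", call. = FALSE)
  if (!is.null(names(rank_a)) && !is.null(names(rank_b))) {
    if (!setequal(names(rank_a), names(rank_b)))
      stop("rankings cover different items", call. = FALSE)
    rank_b <- rank_b[names(rank_a)]
  }
  stats::cor(rank_a, rank_b, method = "spearman")
}

#' Cross-method rank-agreement study
#'
#' For each period's matrix: entropy weights are computed, all requested
#' methods are ranked, and pairwise Spearman coefficients between the
#' method rankings are taken. The returned grid is the arithmetic mean of
#' the per-period coefficient matrices.
#'
#' @param matrices a [decision_matrix()] or a (named) list of them, one per
#'   period.
#' @param methods methods to compare (default all five).
#' @param weights optional fixed weight vector; default `NULL` recomputes
#'   entropy weights per period.
#' @inheritParams run_comparator
#' @return an object of class `agreement_matrix`: list with `methods`,
#'   `rho` (mean symmetric grid, unit diagonal), `per_period` (list of
#'   per-period grids) and `rankings` (per period, per method).
#' @export
agreement_study <- function(matrices, methods = c("cocoso", "topsis", "edas",
                                                  "waspas", "vikor"),
                            weights = NULL, orientation = "benefit",
                            lambda = 0.5, lambda_w = 0.5, v = 0.5,
                            epsilon = 0) {
  if (inherits(matrices, "decision_matrix") || !is.list(matrices))
    matrices <- list(matrices)
  if (length(matrices) < 1L) stop("need at least one period", call. = FALSE)
  methods <- match.arg(methods, c("cocoso", "topsis", "edas", "waspas",
                                  "vikor"), several.ok = TRUE)
  per_period <- vector("list", length(matrices))
  rankings <- vector("list", length(matrices))
  for (p in seq_along(matrices)) {
    m <- matrices[[p]]
    w <- if (is.null(weights)) entropy_weights(m) else weights
    rks <- lapply(methods, function(meth)
      run_comparator(m, w, method = meth, orientation = orientation,
                     lambda = lambda, lambda_w = lambda_w, v = v,
                     epsilon = epsilon))
    names(rks) <- methods
    rho <- diag(1, length(methods))
    dimnames(rho) <- list(methods, methods)
    for (i in seq_along(methods)) for (j in seq_along(methods)) if (i < j) {
      r <- spearman_rho(stats::setNames(rks[[i]]$rank, rks[[i]]$country),
                        stats::setNames(rks[[j]]$rank, rks[[j]]$country))
      rho[i, j] <- rho[j, i] <- r
    }
    per_period[[p]] <- rho
    rankings[[p]] <- rks
  }
  names(per_period) <- names(rankings) <- names(matrices)
  mean_rho <- Reduce(`+`, per_period) / length(per_period)
  structure(list(methods = methods, rho = mean_rho, per_period = per_period,
                 rankings = rankings),
            class = "agreement_matrix")
}

#' @export
print.agreement_matrix <- function(x, digits = 4, ...) {
  cat(sprintf("Mean Spearman rank agreement over %d period(s):\n",
              length(x$per_period)))
  print(round(x$rho, digits))
  invisible(x)
}

#' @export
as.data.frame.agreement_matrix <- function(x, ...) {
  data.frame(method = rownames(x$rho), as.data.frame(x$rho),
             check.names = FALSE, row.names = NULL)
}
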