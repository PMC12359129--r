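# run expr with a private, restored RNG stream
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' K-means performance clustering of composite scores
#'
#' Partitions countries into `k` clusters by Lloyd's algorithm on squared
#' Euclidean distance, minimizing the within-cluster sum of squares (WCSS).
#' Each restart initializes the centroids at `k` distinct data points drawn
#' uniformly without replacement; the best restart by WCSS is kept.
#' Deterministic given `seed`; the caller's RNG state is left untouched.
#'
#' Scores are usually the 1-D CoCoSo composite index `Ci`, but a matrix of
#' per-country features is accepted for multi-dimensional clustering.
#'
#' @param scores named numeric vector (or rows-as-countries matrix).
#' @param k number of clusters; must not exceed the number of distinct
#'   score values.
#' @param restarts number of random initializations (default 50; with 1-D
#'   data of a few dozen countries the global optimum is found reliably).
#' @param seed integer seed for the restart draws.
#' @param max_iter Lloyd iteration cap per restart.
#' @return an object of class `tier_kmeans`: list with `k`, `assignment`
#'   (cluster id per country, 1 = highest-centroid cluster), `centroids`
#'   (descending), `wcss`, `n_iter`, `tier` (same as assignment), `labels`
#'   (High/Intermediate/Dangerous when k = 3), `sizes`.
#' @examples
#' fit <- tier_kmeans(c(a = 1, b = 2, c = 10, d = 11), k = 2)
#' fit$wcss      # 1.0: both pairs cost 0.5
#' fit$tier      # a, b in tier 2; c, d in tier 1
#' @export
tier_kmeans <- function(scores, k = 3, restarts = 50, seed = 0,
                        max_iter = 300) {
  x <- if (is.matrix(scores)) scores else
    matrix(scores, ncol = 1L, dimnames = list(names(scores), "score"))
  if (is.null(rownames(x))) rownames(x) <- paste0("alt", seq_len(nrow(x)))
  distinct <- unique(x)
  if (k < 1L) stop("`k` must be at least 1", call. = FALSE)
  if (k > nrow(distinct))
    stop(sprintf("k = %d exceeds the %d distinct score value(s)",
                 k, nrow(distinct)), call. = FALSE)
  if (restarts < 1L) stop("`restarts` must be positive", call. = FALSE)

  if (k == 1L) {  # closed form; also sidesteps kmeans() reading a length-1
                  # `centers` as the cluster count
    mu <- matrix(colMeans(x), 1L, ncol(x), dimnames = list("tier1", colnames(x)))
    wcss <- sum(sweep(x, 2L, mu[1L, ], "-")^2)
    return(structure(list(k = 1L,
                          assignment = stats::setNames(rep(1L, nrow(x)), rownames(x)),
                          centroids = mu, wcss = wcss, n_iter = 1L,
                          tier = stats::setNames(rep(1L, nrow(x)), rownames(x)),
                          labels = stats::setNames("Tier 1", 1L),
                          sizes = nrow(x), restarts = restarts, seed = seed),
                     class = "tier_kmeans"))
  }
  best <- NULL
  with_local_seed(seed, {
    for (r in seq_len(restarts)) {
      centers <- distinct[sample.int(nrow(distinct), k), , drop = FALSE]
      fit <- tryCatch(
        stats::kmeans(x, centers = centers, iter.max = max_iter,
                      algorithm = "Lloyd"),
        error = function(e) NULL,   # e.g. a cluster emptied; try next restart
        warning = function(w) suppressWarnings(
          stats::kmeans(x, centers = centers, iter.max = max_iter,
                        algorithm = "Lloyd")))
      if (is.null(fit)) next
      if (is.null(best) || fit$tot.withinss < best$tot.withinss - 1e-12)
        best <- fit
    }
  })
  if (is.null(best))
    stop("k-means failed to produce a valid clustering in any restart",
         call. = FALSE)

  # order clusters by descending centroid so tier 1 is the top performers;
  # for matrix input the ordering key is the centroid row mean
  key <- if (ncol(x) == 1L) best$centers[, 1L] else rowMeans(best$centers)
  ord <- order(key, decreasing = TRUE)
  relabel <- match(seq_len(k), ord)
  tier <- stats::setNames(relabel[best$cluster], rownames(x))
  centroids <- best$centers[ord, , drop = FALSE]
  rownames(centroids) <- paste0("tier", seq_len(k))

  labels <- if (k == 3L) c("High", "Intermediate", "Dangerous") else
    paste("Tier", seq_len(k))
  structure(list(k = k, assignment = tier, centroids = centroids,
                 wcss = best$tot.withinss, n_iter = best$iter,
                 tier = tier, labels = stats::setNames(labels, seq_len(k)),
                 sizes = as.integer(table(factor(tier, levels = seq_len(k)))),
                 restarts = restarts, seed = seed),
            class = "tier_kmeans")
}

#' Tier labels of a clustering
#'
#' Clusters are ordered by descending centroid: tier 1 has the highest mean
#' composite score. With k = 3 the conventional qualitative labels High,
#' Intermediate and Dangerous are attached.
#'
#' @param result a [tier_kmeans()] fit.
#' @param as_label return the qualitative labels (factor) instead of tier
#'   numbers.
#' @return named integer vector of tiers, or a factor of labels.
#' @export
label_tiers <- function(result, as_label = FALSE) {
  stopifnot(inherits(result, "tier_kmeans"))
  if (!as_label) return(result$tier)
  factor(result$labels[as.character(result$tier)],
         levels = result$labels)
}

#' @export
print.tier_kmeans <- function(x, digits = 3, ...) {
  cat(sprintf("k-means tiers: k = %d, WCSS = %s, %d iteration(s), best of %d restart(s)\n",
              x$k, format(round(x$wcss, digits)), x$n_iter, x$restarts))
  for (t in seq_len(x$k))
    cat(sprintf("  tier %d (%s, centroid %s): %s\n", t, x$labels[t],
                paste(round(x$centroids[t, ], digits), collapse = ", "),
                paste(names(x$tier)[x$tier == t], collapse = ", ")))
  invisible(x)
}

#' @export
as.data.frame.tier_kmeans <- function(x, ...) {
  data.frame(country = names(x$tier), tier = unname(x$tier),
             label = unname(x$labels[as.character(x$tier)]), row.names = NULL)
}

#' WCSS elbow curve
#'
#' Best-of-restarts within-cluster sum of squares for k = 1..`k_max`, with a
#' curvature-based elbow suggestion: the k maximizing the second difference
#' of the WCSS sequence. The suggestion is a diagnostic, not a decision --
#' the curve should be inspected (the EU study fixed k = 3 visually). When
#' no k stands out (curvature nearly flat) the recommendation is flagged as
#' a weak elbow.
#'
#' @inheritParams tier_kmeans
#' @param k_max largest cluster count to evaluate.
#' @return an object of class `elbow_curve`: list with `ks`, `wcss_by_k`,
#'   `recommended_k`, `weak_elbow`.
#' @export
wcss_curve <- function(scores, k_max = 6, restarts = 50, seed = 0) {
  x <- if (is.matrix(scores)) scores else matrix(scores, ncol = 1L)
  k_max <- min(k_max, nrow(unique(x)))
  if (k_max < 1L) stop("`k_max` must be at least 1", call. = FALSE)
  wcss <- vapply(seq_len(k_max), function(k)
    tier_kmeans(scores, k = k, restarts = restarts, seed = seed)$wcss,
    numeric(1))
  recommended <- NA_integer_; weak <- TRUE
  if (k_max >= 3L) {
    curv <- wcss[1:(k_max - 2L)] - 2 * wcss[2:(k_max - 1L)] + wcss[3:k_max]
    recommended <- which.max(curv) + 1L
    # a genuine elbow leaves little dispersion unexplained at the bend; a
    # structureless curve (e.g. equally spaced points, WCSS ~ 1/k^2) does not
    weak <- wcss[1L] <= 0 || wcss[recommended] / wcss[1L] >= 0.1
  }
  structure(list(ks = seq_len(k_max), wcss_by_k = wcss,
                 recommended_k = recommended, weak_elbow = weak),
            class = "elbow_curve")
}

#' @export
print.elbow_curve <- function(x, digits = 3, ...) {
  cat("WCSS elbow curve:\n")
  print(data.frame(k = x$ks, wcss = round(x$wcss_by_k, digits)),
        row.names = FALSE)
  if (is.na(x$recommended_k)) {
    cat("no elbow recommendation (need k_max >= 3)\n")
  } else {
    cat(sprintf("suggested k = %d%s\n", x$recommended_k,
                if (x$weak_elbow) " (weak elbow: inspect the curve)" else ""))
  }
  invisible(x)
}

#' @export
plot.elbow_curve <- function(x, ...) {
  graphics::plot(x$ks, x$wcss_by_k, type = "b", xlab = "number of clusters k",
                 ylab = "WCSS", main = "Elbow diagnostic", ...)
  if (!is.na(x$recommended_k))
    graphics::abline(v = x$recommended_k, lty = 2)
  invisible(x)
}
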