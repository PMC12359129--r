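#' Column-normalized shares of a decision matrix
#'
#' Each score is divided by its column total, so that every indicator column
#' becomes a discrete probability distribution over countries. These shares
#' are the input to the Shannon entropy of an indicator; dividing by the
#' column sum also makes the whole weighting scale-invariant (multiplying a
#' column by any c > 0 cancels).
#'
#' @param matrix a [decision_matrix()] or nonnegative numeric matrix.
#' @return matrix of shares, same dimnames; every column sums to 1.
#' @export
entropy_shares <- function(matrix) {
  g <- if (inherits(matrix, "decision_matrix")) unclass_matrix(matrix) else as.matrix(matrix)
  if (any(g < 0))
    stop("entropy weighting requires nonnegative scores", call. = FALSE)
  csum <- colSums(g)
  if (any(csum == 0))
    stop("zero column sum for indicator(s): ",
         paste(colnames(g)[csum == 0], collapse = ", "),
         " (shares undefined)", call. = FALSE)
  sweep(g, 2L, csum, "/")
}

#' Shannon entropy of each indicator column
#'
#' For shares \eqn{n_{ij}} the entropy of indicator j is
#' \deqn{Ent_j = -\frac{1}{\ln m} \sum_{i=1}^m n_{ij} \ln n_{ij},}
#' with the information-theoretic convention \eqn{0 \ln 0 = 0}. The
#' \eqn{1/\ln m} factor scales entropy to \[0, 1\]: a uniform column (no
#' discriminating information) has entropy 1, a fully concentrated one
#' entropy 0. Natural logarithms throughout.
#'
#' @param shares share matrix from [entropy_shares()] (columns sum to 1).
#' @param m number of countries; defaults to `nrow(shares)`.
#' @return named numeric vector of per-indicator entropies in \[0, 1\].
#' @export
entropy_values <- function(shares, m = nrow(shares)) {
  if (m < 2L) stop("entropy scaling needs at least 2 countries (1/ln m undefined)",
                   call. = FALSE)
  plogp <- shares * log(shares)
  plogp[shares == 0] <- 0
  ent <- -colSums(plogp) / log(m)
  # clamp roundoff just past the theoretical range
  pmin(pmax(ent, 0), 1)
}

#' Divergence-normalized indicator weights
#'
#' The divergence 1 - entropy of an indicator measures its informational
#' significance: indicators whose scores differ more across countries get
#' larger weights. Weights are the divergences normalized to sum to 1; a
#' constant column (entropy 1) receives weight 0.
#'
#' @param entropies per-indicator entropies in \[0, 1\].
#' @param uniform_fallback if TRUE, an all-constant matrix (every entropy 1)
#'   yields uniform weights instead of an error. Off by default: uniform
#'   weights would silently hide that the data carry no information.
#' @return named numeric weight vector, nonnegative, summing to 1.
#' @export
divergence_weights <- function(entropies, uniform_fallback = FALSE) {
  if (any(entropies < 0 | entropies > 1))
    stop("entropies must lie in [0, 1]", call. = FALSE)
  div <- 1 - entropies
  if (sum(div) == 0) {
    if (uniform_fallback)
      return(stats::setNames(rep(1 / length(div), length(div)), names(div)))
    stop("every indicator column is constant: no discriminating information",
         call. = FALSE)
  }
  div / sum(div)
}

#' Entropy weights of a decision matrix
#'
#' End-to-end objective weighting: column shares, per-indicator Shannon
#' entropy, divergence (1 - entropy), and divergence-normalized weights.
#'
#' @inheritParams entropy_shares
#' @inheritParams divergence_weights
#' @return an object of class `entropy_weights`: list with `shares`,
#'   `entropies`, `divergences`, `weights` (all named by indicator),
#'   `m`, and `period` when the input carried one.
#' @examples
#' g <- decision_matrix(rbind(A = c(80, 20), B = c(40, 70), C = c(60, 50)))
#' ew <- entropy_weights(g)
#' coef(ew)
#' @export
entropy_weights <- function(matrix, uniform_fallback = FALSE) {
  shares <- entropy_shares(matrix)
  ent <- entropy_values(shares)
  w <- divergence_weights(ent, uniform_fallback = uniform_fallback)
  structure(list(shares = shares, entropies = ent, divergences = 1 - ent,
                 weights = w, m = nrow(shares),
                 period = attr(matrix, "period")),
            class = "entropy_weights")
}

#' @export
coef.entropy_weights <- function(object, ...) object$weights

#' @export
print.entropy_weights <- function(x, digits = 3, ...) {
  cat(sprintf("Entropy weights (%d countries, %d indicators)\n",
              x$m, length(x$weights)))
  print(round(rbind(entropy = x$entropies, divergence = x$divergences,
                    weight = x$weights), digits))
  invisible(x)
}

#' @export
as.data.frame.entropy_weights <- function(x, ...) {
  data.frame(indicator = names(x$weights), entropy = unname(x$entropies),
              divergence = unname(x$divergences), weight = unname(x$weights),
              row.names = NULL)
}

# accept an entropy_weights object, a named/plain numeric vector
as_weight_vector <- function(weights, indicators) {
  if (inherits(weights, "entropy_weights")) weights <- weights$weights
  if (!is.numeric(weights))
    stop("`weights` must be numeric or an entropy_weights object", call. = FALSE)
  n <- length(indicators)
  if (!is.null(names(weights)) && all(indicators %in% names(weights)))
    weights <- weights[indicators]
  if (length(weights) != n)
    stop(sprintf("expected %d weights, got %d", n, length(weights)), call. = FALSE)
  if (any(weights < 0)) stop("weights must be nonnegative", call. = FALSE)
  if (abs(sum(weights) - 1) > 1e-6)
    stop("weights must sum to 1 (got ", format(sum(weights)), ")", call. = FALSE)
  stats::setNames(as.numeric(weights), indicators)
}
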