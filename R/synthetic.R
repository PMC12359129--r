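#' Specification for a synthetic GHSI-like decision matrix
#'
#' Describes a bounded country-by-indicator score matrix with two planted,
#' recoverable structures: a per-indicator dispersion profile (so entropy
#' weights are controllable -- the indicator with the largest dispersion
#' multiplier should attract the largest weight) and additive performance
#' tiers (so clustering of composite scores can be checked against ground
#' truth).
#'
#' The defaults emulate the EU-27 study conditions: 27 countries, the six
#' GHSI pillars, three tiers of 11/12/4 countries at offsets +15/0/-20
#' score points, Gaussian noise with base spread 5 points scaled by
#' dispersion multipliers (4, 2, 1, 1, 0.5, 0.5), scores clipped to
#' \[0, 100\]. Mid-scale base means keep the Gaussian tails inside the
#' bounds so that clipping stays rare (< 1% of cells).
#'
#' @param m number of countries.
#' @param indicators indicator names.
#' @param base_mean per-indicator baseline score (recycled).
#' @param dispersion per-indicator dispersion multipliers (recycled, >= 0).
#' @param tiers data frame with columns `label`, `count`, `offset`;
#'   `count` must sum to `m` and `offset` must be strictly decreasing from
#'   best to worst tier.
#' @param noise_sd base noise standard deviation in score points.
#' @param bounds score range for clipping.
#' @param seed integer seed; generation is deterministic given the spec.
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(m = 27,
                           indicators = c("Prevention",
                                          "Detection and reporting",
                                          "Rapid response", "Health system",
                                          "Compliance with norms",
                                          "Risk environment"),
                           base_mean = 55,
                           dispersion = c(4, 2, 1, 1, 0.5, 0.5),
                           tiers = data.frame(
                             label = c("High", "Intermediate", "Dangerous"),
                             count = c(11, 12, 4),
                             offset = c(15, 0, -20)),
                           noise_sd = 5, bounds = c(0, 100), seed = 1) {
  n <- length(indicators)
  base_mean <- rep_len(base_mean, n)
  dispersion <- rep_len(dispersion, n)
  if (any(dispersion < 0)) stop("dispersion multipliers must be >= 0", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  if (!all(c("label", "count", "offset") %in% names(tiers)))
    stop("`tiers` needs columns label, count, offset", call. = FALSE)
  if (sum(tiers$count) != m)
    stop(sprintf("tier counts sum to %d but m = %d", sum(tiers$count), m),
         call. = FALSE)
  if (nrow(tiers) > 1L && any(diff(tiers$offset) >= 0))
    stop("tier offsets must be strictly decreasing from best to worst",
         call. = FALSE)
  if (!all(is.finite(c(base_mean, dispersion, noise_sd, tiers$offset))))
    stop("all spec parameters must be finite", call. = FALSE)
  structure(list(m = as.integer(m), indicators = as.character(indicators),
                 base_mean = base_mean, dispersion = dispersion,
                 tiers = tiers, noise_sd = noise_sd,
                 bounds = as.numeric(bounds), seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat(sprintf("Synthetic decision-matrix spec: %d countries x %d indicators, seed %d\n",
              x$m, length(x$indicators), x$seed))
  cat("tiers:", paste(sprintf("%s (n=%d, offset %+g)", x$tiers$label,
                              x$tiers$count, x$tiers$offset), collapse = ", "), "\n")
  cat("dispersion:", paste(x$dispersion, collapse = ", "),
      " noise_sd:", x$noise_sd, "\n")
  invisible(x)
}

#' Generate a synthetic decision matrix with known structure
#'
#' Scores are `base_mean[j] + tier_offset[i] + dispersion[j] * noise_sd * z`
#' with standard normal `z`, clipped to the bounds. The planted tier of
#' every country and the planted dispersion order of the indicators are
#' returned as ground truth for recovery tests. Deterministic given the
#' spec's seed; the caller's RNG state is untouched.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `matrix` (a [decision_matrix()]), `tiers` (named
#'   ground-truth tier per country), `dispersion_rank` (indicators ordered
#'   most- to least-dispersed), and `clip_fraction` (share of cells hit by
#'   clipping).
#' @export
generate_matrix <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  m <- spec$m; n <- length(spec$indicators)
  tier_of <- rep(seq_len(nrow(spec$tiers)), spec$tiers$count)
  offsets <- spec$tiers$offset[tier_of]
  raw <- with_local_seed(spec$seed, {
    z <- matrix(stats::rnorm(m * n), m, n)
    outer(offsets, spec$base_mean, "+") +
      sweep(z, 2L, spec$dispersion * spec$noise_sd, "*")
  })
  clipped <- pmin(pmax(raw, spec$bounds[1]), spec$bounds[2])
  countries <- sprintf("C%02d", seq_len(m))
  dm <- decision_matrix(clipped, countries = countries,
                        indicators = spec$indicators, bounds = spec$bounds,
                        period = paste0("synthetic-", spec$seed))
  list(matrix = dm,
       tiers = stats::setNames(tier_of, countries),
       dispersion_rank = spec$indicators[order(spec$dispersion,
                                               decreasing = TRUE)],
       clip_fraction = mean(raw != clipped))
}

#' Generate a multi-period panel of synthetic matrices
#'
#' All periods share the country set and base structure; `drift` adjusts
#' the tier offsets per period so rank and tier movements are known by
#' construction (a country demoted by drift must lose ranks). Each period
#' draws fresh noise from a sub-seed derived from the spec seed.
#'
#' @param spec a [synthetic_spec()].
#' @param n_periods number of periods (>= 1).
#' @param drift per-period additive adjustment to the tier offsets: either
#'   a single number per period (recycled over tiers), a list of per-tier
#'   vectors, or `NULL` for no drift. May also be a per-period *named*
#'   country-level offset via the `country_drift` argument.
#' @param country_drift optional list (one element per period) of named
#'   numeric vectors of per-country additive adjustments.
#' @return list of `generate_matrix()`-style results, one per period,
#'   named `period1..periodN`.
#' @export
generate_panel <- function(spec, n_periods = 2, drift = NULL,
                           country_drift = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (n_periods < 1L) stop("`n_periods` must be >= 1", call. = FALSE)
  out <- vector("list", n_periods)
  for (p in seq_len(n_periods)) {
    sp <- spec
    if (!is.null(drift)) {
      adj <- if (is.list(drift)) drift[[p]] else drift[p]
      sp$tiers$offset <- sp$tiers$offset + rep_len(adj, nrow(sp$tiers))
      # drift may reorder tiers; the spec invariant applies to the base spec
    }
    sp$seed <- spec$seed + (p - 1L) * 1000L
    res <- generate_matrix(sp)
    if (!is.null(country_drift) && !is.null(country_drift[[p]])) {
      cd <- country_drift[[p]]
      g <- unclass_matrix(res$matrix)
      g[names(cd), ] <- g[names(cd), , drop = FALSE] + cd
      g <- pmin(pmax(g, sp$bounds[1]), sp$bounds[2])
      res$matrix <- decision_matrix(g, bounds = sp$bounds,
                                    period = attr(res$matrix, "period"))
    }
    res$matrix <- `attr<-`(res$matrix, "period", paste0("period", p))
    out[[p]] <- res
  }
  names(out) <- paste0("period", seq_len(n_periods))
  out
}
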