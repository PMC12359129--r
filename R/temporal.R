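#' Temporal shift in indicator weights
#'
#' Shift = later weight minus earlier weight (2021 minus 2019 in the EU
#' study): positive means the indicator gained discriminating power.
#' Because both vectors are normalized, shifts sum to zero. Note the
#' opposite sign convention of [rank_shift()], where positive means the
#' country improved.
#'
#' @param weights_a earlier-period weights (vector or [entropy_weights()]).
#' @param weights_b later-period weights over the same indicators.
#' @return a `shift_table` data frame: `entity`, `value_a`, `value_b`,
#'   `shift`.
#' @export
weight_shift <- function(weights_a, weights_b) {
  a <- if (inherits(weights_a, "entropy_weights")) weights_a$weights else weights_a
  b <- if (inherits(weights_b, "entropy_weights")) weights_b$weights else weights_b
  if (!is.null(names(a)) && !is.null(names(b))) {
    if (!setequal(names(a), names(b)))
      stop("weight vectors cover different indicators", call. = FALSE)
    b <- b[names(a)]
  } else if (length(a) != length(b)) {
    stop("weight vectors differ in length", call. = FALSE)
  }
  structure(data.frame(entity = if (is.null(names(a)))
                         paste0("crit", seq_along(a)) else names(a),
                       value_a = unname(a), value_b = unname(b),
                       shift = unname(b - a), row.names = NULL),
            kind = "weight", class = c("shift_table", "data.frame"))
}

#' Temporal shift in country ranks or tiers
#'
#' Shift = earlier rank minus later rank, so a positive value is an
#' improvement (a move toward rank 1): a country going from rank 20 to 14
#' has shift +6. The same convention applies to tier shifts.
#'
#' @param ranks_a earlier-period ranks (named integer vector).
#' @param ranks_b later-period ranks over the same countries.
#' @return a `shift_table` data frame: `entity`, `value_a`, `value_b`,
#'   `shift`.
#' @export
rank_shift <- function(ranks_a, ranks_b) {
  if (!is.null(names(ranks_a)) && !is.null(names(ranks_b))) {
    if (!setequal(names(ranks_a), names(ranks_b)))
      stop("rankings cover different countries", call. = FALSE)
    ranks_b <- ranks_b[names(ranks_a)]
  } else if (length(ranks_a) != length(ranks_b)) {
    stop("rankings differ in length", call. = FALSE)
  }
  structure(data.frame(entity = if (is.null(names(ranks_a)))
                         paste0("alt", seq_along(ranks_a)) else names(ranks_a),
                       value_a = unname(ranks_a), value_b = unname(ranks_b),
                       shift = unname(ranks_a - ranks_b), row.names = NULL),
            kind = "rank", class = c("shift_table", "data.frame"))
}

#' Summarize a shift table
#'
#' Partitions entities by the sign of their shift into improved (> 0),
#' unchanged (= 0) and declined (< 0), with percentages of the total
#' reported to two decimals.
#'
#' @param shift_table a [rank_shift()] / [weight_shift()] table, or a plain
#'   numeric vector of shifts.
#' @return a `shift_summary` data frame: `status`, `count`, `percent`.
#' @export
shift_summary <- function(shift_table) {
  s <- if (is.data.frame(shift_table)) shift_table$shift else as.numeric(shift_table)
  counts <- c(improved = sum(s > 0), unchanged = sum(s == 0),
              declined = sum(s < 0))
  structure(data.frame(status = names(counts), count = as.integer(counts),
                       percent = round(100 * counts / length(s), 2),
                       row.names = NULL),
            class = c("shift_summary", "data.frame"))
}

#' Per-tier indicator profile
#'
#' Arithmetic mean of every indicator column within each performance tier.
#' Works for the six pillar indicators or any sub-indicator matrix sharing
#' the same country set.
#'
#' @param matrix a [decision_matrix()] or numeric matrix.
#' @param tiers named tier assignment covering every country in `matrix`
#'   (e.g. from [label_tiers()]).
#' @return data frame with `tier`, `n`, and one mean column per indicator.
#' @export
cluster_profile <- function(matrix, tiers) {
  g <- if (inherits(matrix, "decision_matrix")) unclass_matrix(matrix) else as.matrix(matrix)
  if (inherits(tiers, "tier_kmeans")) tiers <- tiers$tier
  if (!is.null(names(tiers))) {
    missing <- setdiff(rownames(g), names(tiers))
    if (length(missing))
      stop("no tier assigned for: ", paste(missing, collapse = ", "),
           call. = FALSE)
    tiers <- tiers[rownames(g)]
  } else if (length(tiers) != nrow(g)) {
    stop("`tiers` must cover every country in the matrix", call. = FALSE)
  }
  f <- factor(tiers)
  means <- apply(g, 2L, function(col) tapply(col, f, mean))
  if (is.null(dim(means)))  # single tier level
    means <- matrix(means, nrow = 1L, dimnames = list(levels(f), colnames(g)))
  data.frame(tier = levels(f), n = as.integer(table(f)), means,
             check.names = FALSE, row.names = NULL)
}

#' Long-format regional/period weight comparison
#'
#' Assembles entropy weights from several regions and/or periods into a
#' tidy (region, period, indicator, weight) table, aligned by indicator
#' name so permuted indicator orders are handled.
#'
#' @param results a named list. Either flat -- `list(EU = weights, ...)` --
#'   or nested by region then period --
#'   `list(EU = list("2019" = w1, "2021" = w2), ...)`. Each element is a
#'   weight vector or an [entropy_weights()] object.
#' @return data frame with columns `region`, `period`, `indicator`,
#'   `weight`.
#' @export
regional_weight_comparison <- function(results) {
  if (!is.list(results) || is.null(names(results)))
    stop("`results` must be a named list", call. = FALSE)
  get_w <- function(x) if (inherits(x, "entropy_weights")) x$weights else x
  rows <- list()
  for (region in names(results)) {
    el <- results[[region]]
    entries <- if (is.list(el) && !inherits(el, "entropy_weights")) el
               else list(el)
    periods <- if (is.null(names(entries))) rep(NA_character_, length(entries))
               else names(entries)
    for (i in seq_along(entries)) {
      w <- get_w(entries[[i]])
      rows[[length(rows) + 1L]] <-
        data.frame(region = region, period = periods[i],
                   indicator = names(w), weight = unname(w), row.names = NULL)
    }
  }
  out <- do.call(rbind, rows)
  ref <- sort(unique(out$indicator))
  by_case <- split(out$indicator, paste(out$region, out$period))
  ok <- vapply(by_case, function(ind) setequal(ind, ref), logical(1))
  if (!all(ok))
    stop("indicator sets differ across regions/periods: ",
         paste(names(by_case)[!ok], collapse = ", "), call. = FALSE)
  out
}
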