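#' Published EU-27 health-security reference results
#'
#' Summary results of the public entropy-CoCoSo assessment of the 27 EU
#' member states on the six GHSI pillars, bundled as plain-text tables for
#' validation, worked examples and regression tests:
#'
#' * `"scores"` -- per-country composite index `Ci`, rank `Ri` and k-means
#'   tier `Si` for the 2019, 2021 and aggregated 2017--2021 assessments,
#'   plus the 2019 to 2021 rank and tier shifts (positive = improvement).
#' * `"weights"` -- entropy indicator weights for the EU, African and
#'   Eastern Mediterranean regions over the three periods.
#' * `"weight_shifts"` -- per-region 2021 minus 2019 weight shifts.
#' * `"agreement"` -- mean Spearman rank agreement of entropy-CoCoSo with
#'   entropy-TOPSIS/EDAS/WASPAS/VIKOR over the three periods.
#'
#' Values are as printed in the published tables (3--6 decimals); the raw
#' country-by-indicator matrices behind them are distributed separately
#' (see the package README on reproduction).
#'
#' @param which which table to return.
#' @return a data frame.
#' @examples
#' head(eu_hes_results("scores"))
#' @export
eu_hes_results <- function(which = c("scores", "weights", "weight_shifts",
                                     "agreement")) {
  which <- match.arg(which)
  file <- c(scores = "eu_hes_results.csv",
            weights = "eu_regional_weights.csv",
            weight_shifts = "eu_weight_shifts.csv",
            agreement = "eu_method_agreement.csv")[[which]]
  path <- system.file("extdata", file, package = "hespat", mustWork = TRUE)
  utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8")
}
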