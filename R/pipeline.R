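#' Assemble a pipeline run configuration
#'
#' @param inputs named list of inputs, one per (region, period). Each
#'   element is a [decision_matrix()], a file path, or a list with fields
#'   `path` (plus optional `sheet`/`range` for workbooks), `region`,
#'   `period`. Inputs sharing a region are treated as consecutive periods
#'   for shift analysis, in the order given.
#' @param lambda CoCoSo balance coefficient in \[0, 1\].
#' @param k tier count for k-means clustering.
#' @param restarts,seed clustering restarts and seed.
#' @param orientation per-indicator benefit/cost flags.
#' @param comparators run the cross-method agreement study.
#' @param bounds score bounds for file inputs.
#' @param out_dir directory for CSV outputs and the JSON manifest, or
#'   `NULL` to return results without writing.
#' @param precision decimal places for serialized tables.
#' @return a `run_config` list.
#' @export
run_config <- function(inputs, lambda = 0.5, k = 3, restarts = 50, seed = 0,
                       orientation = "benefit", comparators = FALSE,
                       bounds = c(0, 100), out_dir = NULL, precision = 3) {
  if (length(inputs) < 1L) stop("at least one input is required", call. = FALSE)
  if (is.null(names(inputs)) || any(names(inputs) == ""))
    stop("`inputs` must be a fully named list", call. = FALSE)
  if (lambda < 0 || lambda > 1) stop("`lambda` must lie in [0, 1]", call. = FALSE)
  if (k < 1) stop("`k` must be >= 1", call. = FALSE)
  structure(list(inputs = inputs, lambda = lambda, k = k,
                 restarts = restarts, seed = seed, orientation = orientation,
                 comparators = isTRUE(comparators), bounds = bounds,
                 out_dir = out_dir, precision = precision),
            class = "run_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' The YAML mirrors the [run_config()] fields; `inputs` is a mapping from
#' input name to either a path string or a mapping with `path`, `region`,
#' `period`, `sheet`, `range`. Relative paths are resolved against the YAML
#' file's directory.
#'
#' @param path YAML file.
#' @return a `run_config`.
#' @export
load_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) if (grepl("^(/|[A-Za-z]:)", p)) p else file.path(base, p)
  y$inputs <- lapply(y$inputs, function(el) {
    if (is.character(el)) list(path = resolve(el))
    else { if (!is.null(el$path)) el$path <- resolve(el$path); el }
  })
  do.call(run_config, y)
}

resolve_input <- function(el, name, bounds) {
  if (inherits(el, "decision_matrix"))
    return(list(matrix = el, region = "all",
                period = attr(el, "period")))
  if (is.character(el)) el <- list(path = el)
  region <- if (is.null(el$region)) "all" else el$region
  period <- el$period
  dm <- if (!is.null(el$sheet))
    read_decision_workbook(el$path, sheet = el$sheet, range = el$range,
                           bounds = bounds, period = period)
  else
    read_decision_matrix(el$path, bounds = bounds, period = period)
  list(matrix = dm, region = region,
       period = if (is.null(period)) name else period)
}

#' Run the full assessment pipeline
#'
#' For every configured input: entropy weights, entropy-CoCoSo composite
#' scores and ranks, and k-means performance tiers. For consecutive period
#' pairs within a region: indicator weight shifts, country rank and tier
#' shifts, and an improved/unchanged/declined summary. Optionally the
#' five-method rank-agreement study over all inputs. All downstream stages
#' consume full-precision in-memory results; rounding happens only when
#' tables are serialized.
#'
#' Any stage error aborts the run with a stage-tagged message and removes
#' partially written outputs.
#'
#' @param config a [run_config()] (or a YAML path accepted by
#'   [load_run_config()]).
#' @return an object of class `hes_pipeline`: list with `results` (per
#'   input: `matrix`, `weights`, `cocoso`, `tiers`, `validation`),
#'   `shifts` (per region pair), `agreement` (or `NULL`) and `manifest`.
#' @examples
#' gen <- generate_matrix(synthetic_spec(seed = 7))
#' bundle <- run_pipeline(run_config(list(demo = gen$matrix), seed = 7))
#' bundle
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- load_run_config(config)
  stopifnot(inherits(config, "run_config"))
  written <- character()
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e) {
      unlink(written)
      stop(sprintf("[stage: %s] %s", what, conditionMessage(e)), call. = FALSE)
    })
  }

  results <- list()
  for (nm in names(config$inputs)) {
    inp <- stage(paste0("read/", nm),
                 resolve_input(config$inputs[[nm]], nm, config$bounds))
    val <- validate_matrix(inp$matrix)
    if (!val$ok)
      stage(paste0("validate/", nm),
            stop(paste(val$issues$message[val$issues$severity == "error"],
                       collapse = "; ")))
    for (cc in val$constant_columns)
      message(sprintf("[%s] constant column: %s", nm, cc))
    fit <- stage(paste0("cocoso/", nm),
                 cocoso(inp$matrix, lambda = config$lambda,
                        orientation = config$orientation))
    tiers <- stage(paste0("cluster/", nm),
                   tier_kmeans(fit$Ci, k = config$k,
                               restarts = config$restarts,
                               seed = config$seed))
    if (fit$ties) message(sprintf("[%s] tied composite scores", nm))
    results[[nm]] <- list(matrix = inp$matrix, region = inp$region,
                          period = inp$period, validation = val,
                          weights = fit$entropy, cocoso = fit, tiers = tiers)
  }

  shifts <- list()
  regions <- split(names(results), vapply(results, `[[`, "", "region"))
  for (reg in names(regions)) {
    nms <- regions[[reg]]
    if (length(nms) < 2L) next
    for (i in seq_len(length(nms) - 1L)) {
      a <- results[[nms[i]]]; b <- results[[nms[i + 1L]]]
      pair <- paste(nms[i], nms[i + 1L], sep = " -> ")
      shifts[[pair]] <- stage(paste0("shift/", pair), list(
        weights = weight_shift(a$cocoso$weights, b$cocoso$weights),
        ranks = rank_shift(a$cocoso$rank, b$cocoso$rank),
        tiers = rank_shift(a$tiers$tier, b$tiers$tier),
        summary = shift_summary(rank_shift(a$cocoso$rank, b$cocoso$rank))))
    }
  }

  agreement <- NULL
  if (config$comparators)
    agreement <- stage("agreement",
                       agreement_study(lapply(results, `[[`, "matrix"),
                                       orientation = config$orientation,
                                       lambda = config$lambda))

  manifest <- list(package = "hespat",
                   version = as.character(utils::packageVersion("hespat")),
                   lambda = config$lambda, k = config$k,
                   restarts = config$restarts, seed = config$seed,
                   orientation = config$orientation,
                   comparators = config$comparators,
                   precision = config$precision,
                   inputs = lapply(results, function(r)
                     list(region = r$region, period = r$period,
                          m = nrow(r$matrix), n = ncol(r$matrix))))

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(config$out_dir, f)
    stage("write", {
      wtab <- do.call(rbind, lapply(names(results), function(nm)
        data.frame(input = nm, as.data.frame(results[[nm]]$weights))))
      written <<- c(written, write_table(wtab, p("weights.csv"),
                                         digits = config$precision))
      ctab <- do.call(rbind, lapply(names(results), function(nm)
        data.frame(input = nm, as.data.frame(results[[nm]]$cocoso))))
      written <<- c(written, write_table(ctab, p("cocoso.csv"),
                                         digits = config$precision))
      ktab <- do.call(rbind, lapply(names(results), function(nm)
        data.frame(input = nm, as.data.frame(results[[nm]]$tiers))))
      written <<- c(written, write_table(ktab, p("clusters.csv"),
                                         digits = config$precision))
      if (length(shifts)) {
        stab <- do.call(rbind, lapply(names(shifts), function(pr) rbind(
          data.frame(pair = pr, kind = "weight", shifts[[pr]]$weights),
          data.frame(pair = pr, kind = "rank", shifts[[pr]]$ranks),
          data.frame(pair = pr, kind = "tier", shifts[[pr]]$tiers))))
        written <<- c(written, write_table(stab, p("shifts.csv"),
                                           digits = config$precision))
      }
      if (!is.null(agreement))
        written <<- c(written, write_table(as.data.frame(agreement),
                                           p("agreement.csv"),
                                           digits = 6))
      jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                           pretty = TRUE, digits = NA)
      written <<- c(written, p("manifest.json"))
    })
  }

  structure(list(results = results, shifts = shifts, agreement = agreement,
                 manifest = manifest),
            class = "hes_pipeline")
}

#' @export
print.hes_pipeline <- function(x, ...) {
  cat(sprintf("Health-security assessment pipeline: %d input(s)\n",
              length(x$results)))
  for (nm in names(x$results)) {
    r <- x$results[[nm]]
    top <- names(r$cocoso$rank)[which.min(r$cocoso$rank)]
    cat(sprintf("  %s [%s/%s]: %d x %d, top-ranked %s, tiers %s\n",
                nm, r$region, r$period, nrow(r$matrix), ncol(r$matrix), top,
                paste(r$tiers$sizes, collapse = "/")))
  }
  if (length(x$shifts))
    for (pr in names(x$shifts)) {
      s <- x$shifts[[pr]]$summary
      cat(sprintf("  shift %s: improved %d, unchanged %d, declined %d\n",
                  pr, s$count[1], s$count[2], s$count[3]))
    }
  if (!is.null(x$agreement))
    cat(sprintf("  mean cross-method Spearman rho: min %.3f\n",
                min(x$agreement$rho)))
  invisible(x)
}
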