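#' Construct a decision matrix
#'
#' A decision matrix holds the scores of `m` countries (rows, the
#' alternatives) on `n` indicators (columns, the criteria), each score lying
#' within declared bounds. The default bounds are the 0--100 convention used
#' by the Global Health Security Index; the MCDM mathematics downstream does
#' not depend on them, so they are configurable.
#'
#' Missing values are rejected rather than imputed: an incomplete score
#' matrix is a data problem, and imputation would invent information that the
#' entropy weighting would then mistake for dispersion.
#'
#' @param scores numeric matrix (or data frame of numerics), countries in
#'   rows, indicators in columns.
#' @param countries character vector of unique country identifiers; defaults
#'   to `rownames(scores)`.
#' @param indicators character vector of unique indicator names; defaults to
#'   `colnames(scores)`.
#' @param bounds length-2 numeric, inclusive score range.
#' @param period free-text label for the assessment period (e.g. `"2019"`).
#' @return an object of class `decision_matrix`: a numeric matrix with
#'   dimnames plus `bounds` and `period` attributes.
#' @seealso [read_decision_matrix()], [validate_matrix()]
#' @examples
#' g <- decision_matrix(rbind(A = c(70, 40), B = c(55, 62)),
#'                      indicators = c("Prevention", "Rapid response"),
#'                      period = "2019")
#' g
#' @export
decision_matrix <- function(scores, countries = rownames(scores),
                            indicators = colnames(scores),
                            bounds = c(0, 100), period = NULL) {
  if (is.data.frame(scores)) scores <- as.matrix(scores)
  if (!is.matrix(scores) || !is.numeric(scores))
    stop("`scores` must be a numeric matrix or data frame", call. = FALSE)
  m <- nrow(scores); n <- ncol(scores)
  if (m < 2L) stop("a decision matrix needs at least 2 countries (rows)", call. = FALSE)
  if (n < 1L) stop("a decision matrix needs at least 1 indicator (column)", call. = FALSE)
  if (is.null(countries)) countries <- paste0("alt", seq_len(m))
  if (is.null(indicators)) indicators <- paste0("crit", seq_len(n))
  countries <- as.character(countries); indicators <- as.character(indicators)
  if (length(countries) != m) stop("`countries` must have one entry per row", call. = FALSE)
  if (length(indicators) != n) stop("`indicators` must have one entry per column", call. = FALSE)
  if (anyDuplicated(countries))
    stop("duplicate country identifiers: ",
         paste(unique(countries[duplicated(countries)]), collapse = ", "), call. = FALSE)
  if (anyDuplicated(indicators))
    stop("duplicate indicator names: ",
         paste(unique(indicators[duplicated(indicators)]), collapse = ", "), call. = FALSE)
  if (!is.numeric(bounds) || length(bounds) != 2L || !all(is.finite(bounds)) ||
      bounds[1] >= bounds[2])
    stop("`bounds` must be two finite numbers, low < high", call. = FALSE)
  if (anyNA(scores)) {
    bad <- which(is.na(scores), arr.ind = TRUE)[1L, ]
    stop(sprintf("missing score at (%s, %s); complete matrices are required",
                 countries[bad[1L]], indicators[bad[2L]]), call. = FALSE)
  }
  off <- scores < bounds[1] | scores > bounds[2]
  if (any(off)) {
    idx <- which(off, arr.ind = TRUE)
    offenders <- apply(idx, 1L, function(ij)
      sprintf("(%s, %s) = %g", countries[ij[1L]], indicators[ij[2L]],
              scores[ij[1L], ij[2L]]))
    stop("scores outside bounds [", bounds[1], ", ", bounds[2], "]: ",
         paste(utils::head(offenders, 5L), collapse = "; "),
         if (length(offenders) > 5L) sprintf(" ... and %d more", length(offenders) - 5L),
         call. = FALSE)
  }
  dimnames(scores) <- list(countries, indicators)
  structure(scores, bounds = as.numeric(bounds),
            period = if (is.null(period)) NA_character_ else as.character(period),
            class = c("decision_matrix", "matrix", "array"))
}

#' Read a decision matrix from a delimited table
#'
#' Expects a header row of indicator names and a first column of country
#' identifiers; all remaining cells must parse as numbers. Row and column
#' order of the file is preserved.
#'
#' @param path file to read.
#' @param dialect `"csv"` or `"tsv"`; default inferred from the file
#'   extension (`.tsv`/`.tab` read as TSV, anything else as CSV).
#' @param bounds,period passed to [decision_matrix()].
#' @return a [decision_matrix()].
#' @examples
#' f <- system.file("extdata", "toy_matrix.csv", package = "hespat")
#' read_decision_matrix(f)
#' @export
read_decision_matrix <- function(path, dialect = NULL, bounds = c(0, 100),
                                 period = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(dialect))
    dialect <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "tsv" else "csv"
  dialect <- match.arg(dialect, c("csv", "tsv"))
  sep <- if (dialect == "tsv") "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                           stringsAsFactors = FALSE, colClasses = "character",
                           fileEncoding = "UTF-8", comment.char = "")
  if (ncol(raw) < 2L)
    stop("expected a country column plus at least one indicator column", call. = FALSE)
  countries <- raw[[1L]]
  indicators <- colnames(raw)[-1L]
  cells <- as.matrix(raw[, -1L, drop = FALSE])
  parsed <- suppressWarnings(array(as.numeric(cells), dim = dim(cells)))
  if (anyNA(parsed)) {
    bad <- which(is.na(parsed), arr.ind = TRUE)[1L, ]
    stop(sprintf("unparseable or missing cell at (%s, %s): \"%s\"",
                 countries[bad[1L]], indicators[bad[2L]],
                 cells[bad[1L], bad[2L]]), call. = FALSE)
  }
  decision_matrix(parsed, countries = countries, indicators = indicators,
                  bounds = bounds, period = period)
}

#' Read a decision matrix from a workbook sheet
#'
#' Loads a rectangular cell range of an `.xlsx` sheet and normalizes it to
#' the same [decision_matrix()] type as the delimited readers. The range must
#' include the indicator header row and the country column. Requires the
#' `readxl` package.
#'
#' @param path workbook file.
#' @param sheet sheet name or index.
#' @param range cell range such as `"A1:G28"`, or `NULL` for the whole sheet.
#' @param bounds,period passed to [decision_matrix()].
#' @return a [decision_matrix()].
#' @export
read_decision_workbook <- function(path, sheet, range = NULL,
                                   bounds = c(0, 100), period = NULL) {
  if (!requireNamespace("readxl", quietly = TRUE))
    stop("workbook ingestion requires the 'readxl' package", call. = FALSE)
  raw <- readxl::read_excel(path, sheet = sheet, range = range,
                            col_names = TRUE, .name_repair = "minimal")
  raw <- as.data.frame(raw, check.names = FALSE)
  countries <- as.character(raw[[1L]])
  parsed <- as.matrix(raw[, -1L, drop = FALSE])
  storage.mode(parsed) <- "double"
  if (anyNA(parsed)) {
    bad <- which(is.na(parsed), arr.ind = TRUE)[1L, ]
    stop(sprintf("unparseable or missing cell at (%s, %s)",
                 countries[bad[1L]], colnames(parsed)[bad[2L]]), call. = FALSE)
  }
  decision_matrix(parsed, countries = countries,
                  indicators = colnames(raw)[-1L], bounds = bounds,
                  period = period)
}

#' Validate a decision matrix
#'
#' Reports (rather than errors on) conditions that affect downstream stages:
#' out-of-bounds scores are errors, constant indicator columns are warnings
#' (they carry zero entropy weight and normalize degenerately), and fewer
#' than 3 countries is a warning because the default k = 3 tier clustering
#' is then infeasible.
#'
#' @param matrix a [decision_matrix()], or a plain numeric matrix (checked
#'   against `bounds` without the constructor's hard rejection, so that
#'   out-of-bounds data can be *reported* rather than refused).
#' @param bounds score range used when `matrix` is a plain matrix.
#' @return a `hes_validation` list with elements `ok` (TRUE iff no
#'   error-severity issue), `issues` (data frame of severity, location,
#'   message) and `constant_columns`.
#' @export
validate_matrix <- function(matrix, bounds = c(0, 100)) {
  if (inherits(matrix, "decision_matrix")) {
    bounds <- attr(matrix, "bounds")
  } else {
    if (is.data.frame(matrix)) matrix <- as.matrix(matrix)
    if (is.null(rownames(matrix))) rownames(matrix) <- paste0("alt", seq_len(nrow(matrix)))
    if (is.null(colnames(matrix))) colnames(matrix) <- paste0("crit", seq_len(ncol(matrix)))
  }
  issues <- list()
  add <- function(severity, location, message)
    issues[[length(issues) + 1L]] <<- data.frame(severity = severity,
                                                 location = location,
                                                 message = message)
  off <- matrix < bounds[1] | matrix > bounds[2]
  if (any(off)) {
    idx <- which(off, arr.ind = TRUE)
    for (r in seq_len(nrow(idx)))
      add("error",
          sprintf("(%s, %s)", rownames(matrix)[idx[r, 1L]],
                  colnames(matrix)[idx[r, 2L]]),
          sprintf("score %g outside bounds [%g, %g]",
                  matrix[idx[r, 1L], idx[r, 2L]], bounds[1], bounds[2]))
  }
  rng <- apply(matrix, 2L, function(x) diff(range(x)))
  constant <- colnames(matrix)[rng == 0]
  for (nm in constant)
    add("warning", nm, "constant column: zero entropy weight, degenerate normalization")
  if (nrow(matrix) < 3L)
    add("warning", "matrix", "fewer than 3 countries: k = 3 clustering infeasible")
  issues <- if (length(issues)) do.call(rbind, issues) else
    data.frame(severity = character(), location = character(), message = character())
  structure(list(ok = !any(issues$severity == "error"), issues = issues,
                 constant_columns = constant),
            class = "hes_validation")
}

#' @export
print.hes_validation <- function(x, ...) {
  cat("Decision-matrix validation:", if (x$ok) "OK" else "NOT OK", "\n")
  if (nrow(x$issues)) {
    cat(sprintf("%d issue(s):\n", nrow(x$issues)))
    for (i in seq_len(nrow(x$issues)))
      cat(sprintf("  [%s] %s: %s\n", x$issues$severity[i], x$issues$location[i],
                  x$issues$message[i]))
  } else cat("no issues\n")
  invisible(x)
}

#' @export
print.decision_matrix <- function(x, ...) {
  cat(sprintf("Decision matrix: %d countries x %d indicators, bounds [%g, %g]%s\n",
              nrow(x), ncol(x), attr(x, "bounds")[1], attr(x, "bounds")[2],
              if (is.na(attr(x, "period"))) "" else
                paste0(", period ", attr(x, "period"))))
  print(unclass_matrix(x), ...)
  invisible(x)
}

#' @export
as.data.frame.decision_matrix <- function(x, ...) {
  data.frame(country = rownames(x), unclass_matrix(x),
             check.names = FALSE, row.names = NULL)
}

# strip class/attributes for printing and arithmetic
unclass_matrix <- function(x) {
  attr(x, "bounds") <- NULL
  attr(x, "period") <- NULL
  class(x) <- NULL
  x
}

#' Write a result table to a delimited file
#'
#' Writes any tabular result (data frame, matrix, or a package result object
#' with an `as.data.frame` method) as UTF-8 CSV with a header row. Numeric
#' columns are rounded to `digits` decimals at serialization only; internal
#' computation is always at full precision.
#'
#' @param rows tabular result to write; must be non-empty.
#' @param path output file.
#' @param digits decimal places for numeric columns (default 3).
#' @param sep field separator (default `","`).
#' @return `path`, invisibly.
#' @export
write_table <- function(rows, path, digits = 3, sep = ",") {
  rows <- as.data.frame(rows)
  if (nrow(rows) == 0L) stop("refusing to write an empty table", call. = FALSE)
  num <- vapply(rows, is.numeric, logical(1))
  rows[num] <- lapply(rows[num], round, digits = digits)
  con <- tryCatch(suppressWarnings(file(path, "w", encoding = "UTF-8")),
                  error = function(e) stop("cannot write to ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  on.exit(close(con))
  utils::write.table(rows, con, sep = sep, row.names = FALSE, quote = TRUE)
  invisible(path)
}
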