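#' Per-area count table for disease mapping
#'
#' An `area_table` is the tabular backbone of an areal analysis: one row per
#' area with the observed disease count and the expected count under indirect
#' standardization. The implicit null is a relative risk of one in every area,
#' because the expected counts already absorb the age structure.
#'
#' Row order is significant: every per-area result produced by the package
#' (p-values, q-values, posterior probabilities, truth vectors) aligns to it,
#' and spatial adjacency is re-indexed against it.
#'
#' @param area_id character vector of unique area labels.
#' @param observed non-negative integer counts of cases, one per area.
#' @param expected positive expected counts under indirect standardization.
#' @return A data frame of class `area_table` with columns
#'   `area_id`, `observed`, `expected`.
#' @examples
#' tab <- area_table(c("A", "B", "C"), observed = c(10, 0, 5),
#'                   expected = c(8.2, 1, 5))
#' compute_smr(tab)
#' @seealso [read_area_table()], [compute_smr()], [adjacency_map()]
#' @export
area_table <- function(area_id, observed, expected) {
  area_id <- as.character(area_id)
  if (length(area_id) < 1L)
    stop("an area_table needs at least one area", call. = FALSE)
  if (length(observed) != length(area_id) ||
      length(expected) != length(area_id))
    stop("area_id, observed and expected must have equal length",
         call. = FALSE)
  if (anyDuplicated(area_id))
    stop("duplicated area_id: ",
         paste(unique(area_id[duplicated(area_id)]), collapse = ", "),
         call. = FALSE)
  observed <- as.numeric(observed)
  expected <- as.numeric(expected)
  bad <- which(!is.finite(observed) | observed < 0 |
                 abs(observed - round(observed)) > 1e-8)
  if (length(bad))
    stop("observed counts must be non-negative integers; offending row(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  bad <- which(!is.finite(expected) | expected <= 0)
  if (length(bad))
    stop("expected counts must be positive; offending row(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  out <- data.frame(area_id = area_id, observed = round(observed),
                    expected = expected, stringsAsFactors = FALSE)
  class(out) <- c("area_table", "data.frame")
  out
}

#' Read a per-area count table from delimited text
#'
#' Reads a comma- or tab-delimited file with a header row and builds a
#' validated [area_table()]. Column names are configurable so that files from
#' registries with their own conventions can be ingested without editing.
#'
#' @param file path to a delimited text file with a header row.
#' @param columns named character vector (or list) mapping the roles
#'   `id`, `observed`, `expected` to column names in the file.
#' @param sep field separator; `NULL` (default) auto-detects comma vs tab
#'   from the header line.
#' @return An [area_table()] preserving the file's row order.
#' @export
read_area_table <- function(file,
                            columns = c(id = "area_id",
                                        observed = "observed",
                                        expected = "expected"),
                            sep = NULL) {
  columns <- unlist(columns)
  for (role in c("id", "observed", "expected"))
    if (!role %in% names(columns))
      stop("column mapping must name a '", role, "' column", call. = FALSE)
  if (is.null(sep)) {
    header <- readLines(file, n = 1L)
    sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  }
  df <- utils::read.table(file, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(unname(columns), names(df))
  if (length(missing))
    stop("input file lacks required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  area_table(df[[columns[["id"]]]],
             df[[columns[["observed"]]]],
             df[[columns[["expected"]]]])
}

#' Write a per-area count table to delimited text
#'
#' Inverse of [read_area_table()]: writes the default `area_id, observed,
#' expected` columns so that reading the file back reproduces the table.
#'
#' @param table an [area_table()].
#' @param file output path.
#' @param sep field separator (default comma).
#' @return `file`, invisibly.
#' @export
write_area_table <- function(table, file, sep = ",") {
  stopifnot(inherits(table, "area_table"))
  df <- data.frame(area_id = table$area_id,
                   observed = table$observed,
                   # full double precision so that read-back is bit-exact
                   expected = sprintf("%.17g", table$expected),
                   stringsAsFactors = FALSE)
  utils::write.table(df, file, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Standardized mortality ratios and their precision
#'
#' The SMR `y/e` is the maximum-likelihood estimate of an area's relative
#' risk under indirect standardization; its variance on the ratio scale is
#' `1/e`, so the expected count itself acts as the precision. Small areas
#' therefore spread widely around the null value 1 while populous areas
#' hug it -- the geometry the funnel plot displays.
#'
#' @param table an [area_table()].
#' @return A data frame with columns `area_id`, `smr`, `variance`,
#'   `precision`, aligned to the table's row order.
#' @examples
#' compute_smr(area_table("A", 10, 5))  # smr 2, variance 0.2
#' @export
compute_smr <- function(table) {
  stopifnot(inherits(table, "area_table"))
  data.frame(area_id = table$area_id,
             smr = table$observed / table$expected,
             variance = 1 / table$expected,
             precision = table$expected,
             stringsAsFactors = FALSE)
}
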