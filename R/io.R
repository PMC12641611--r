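# Delimited-text input/output: abundance tables, the minimum-nonzero part
# filter, and CSV exports of coordinate systems and screening results.

.guess_sep <- function(path) {
  if (grepl("\\.(tsv|tab|txt)$", path, ignore.case = TRUE)) "\t" else ","
}

#' Read an abundance table
#'
#' Reads a delimited text file (comma- or tab-separated, chosen from the file
#' extension unless `sep` is given) into a composition matrix. The first
#' column holds identifiers: sample IDs when samples are in rows
#' (`orientation = "samples_rows"`), part IDs when parts are in rows
#' (`"parts_rows"`, in which case the table is transposed). Zeros are
#' permitted at load time and reported — they must be removed (see
#' [filter_min_nonzero()]) before any logratio transform, which will refuse
#' non-positive entries. Negative or non-numeric cells are an error naming
#' the offending cell.
#'
#' @param path file path.
#' @param orientation `"samples_rows"` (default) or `"parts_rows"`.
#' @param sep field separator; default from the extension.
#' @param response optional name of a column holding the response variable;
#'   it is split off before validation and returned as attribute `response`.
#' @return composition matrix (positivity not yet enforced) with attributes
#'   `zero_counts` (named integer vector of zero entries per part) and,
#'   if requested, `response`.
#' @export
read_abundance_table <- function(path,
                                 orientation = c("samples_rows", "parts_rows"),
                                 sep = NULL, response = NULL) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  if (is.null(sep)) sep <- .guess_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          colClasses = "character", quote = "\"",
                          comment.char = "")
  if (ncol(df) < 2L) stop("table needs an identifier column plus data columns",
                          call. = FALSE)
  ids <- df[[1L]]
  if (anyDuplicated(ids))
    stop(sprintf("duplicate identifiers in first column: '%s'",
                 ids[duplicated(ids)][1L]), call. = FALSE)
  if (anyDuplicated(names(df)[-1L]))
    stop(sprintf("duplicate column labels: '%s'",
                 names(df)[-1L][duplicated(names(df)[-1L])][1L]), call. = FALSE)
  M <- matrix(NA_real_, nrow(df), ncol(df) - 1L,
              dimnames = list(ids, names(df)[-1L]))
  for (j in seq_len(ncol(M))) {
    v <- suppressWarnings(as.numeric(df[[j + 1L]]))
    bad <- which(is.na(v) & !(df[[j + 1L]] %in% c("NA", "")))
    if (length(bad))
      stop(sprintf("non-numeric value '%s' at row %d, column '%s'",
                   df[[j + 1L]][bad[1L]], bad[1L], colnames(M)[j]),
           call. = FALSE)
    M[, j] <- v
  }
  if (anyNA(M)) {
    bad <- which(is.na(M), arr.ind = TRUE)[1L, ]
    stop(sprintf("missing value at row %d, column '%s'", bad[1L],
                 colnames(M)[bad[2L]]), call. = FALSE)
  }
  if (orientation == "parts_rows") M <- t(M)
  yvec <- NULL
  if (!is.null(response)) {
    ri <- match(response, colnames(M))
    if (is.na(ri))
      stop(sprintf("response column '%s' not found", response), call. = FALSE)
    yvec <- M[, ri]
    M <- M[, -ri, drop = FALSE]
  }
  if (any(M < 0)) {
    bad <- which(M < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("negative abundance %g at row '%s', part '%s'",
                 M[bad[1L], bad[2L]], rownames(M)[bad[1L]],
                 colnames(M)[bad[2L]]), call. = FALSE)
  }
  zeros <- colSums(M == 0)
  if (any(zeros > 0))
    message(sprintf("%d part(s) contain zeros (%d zero entries in total); filter before transforming",
                    sum(zeros > 0), sum(zeros)))
  X <- as_composition(M, require_positive = FALSE)
  attr(X, "zero_counts") <- zeros
  attr(X, "response") <- yvec
  X
}

#' Write an abundance table
#'
#' CSV writer matching [read_abundance_table()]; numbers are written with 17
#' significant digits so a write/read round trip reproduces doubles exactly.
#'
#' @param X composition matrix.
#' @param path output path.
#' @param sep field separator (default from the extension).
#' @param response optional response vector appended as a final column
#'   named `response`.
#' @export
write_abundance_table <- function(X, path, sep = NULL, response = NULL) {
  X <- unclass(X)
  if (is.null(sep)) sep <- .guess_sep(path)
  ids <- rownames(X)
  if (is.null(ids)) ids <- paste0("sample", seq_len(nrow(X)))
  fmt <- function(m) apply(m, 2L, function(col) formatC(col, digits = 17, format = "g"))
  body <- cbind(sample = ids, fmt(X))
  header <- c("sample", colnames(X))
  if (!is.null(response)) {
    body <- cbind(body, formatC(response, digits = 17, format = "g"))
    header <- c(header, "response")
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(header, collapse = sep), con)
  utils::write.table(body, con, sep = sep, quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Filter parts by minimum number of nonzero observations
#'
#' Keeps the parts with at least `min_nonzero` strictly positive entries —
#' the standard preparation for sparse count tables (e.g. requiring a
#' feature to be observed in roughly 10% of samples) before logratio
#' analysis.
#'
#' @param X composition matrix (zeros allowed).
#' @param min_nonzero required number of strictly positive entries per part;
#'   must not exceed the number of samples.
#' @return filtered composition matrix with attributes `kept_parts` and
#'   `dropped_parts` (character vectors). Dropping every part is an error.
#' @export
filter_min_nonzero <- function(X, min_nonzero) {
  M <- if (inherits(X, "composition_matrix")) unclass(X) else
    unclass(as_composition(X, require_positive = FALSE))
  if (min_nonzero > nrow(M))
    stop("min_nonzero cannot exceed the number of samples", call. = FALSE)
  nz <- colSums(M > 0)
  keep <- nz >= min_nonzero
  if (!any(keep)) stop("filter removed every part", call. = FALSE)
  out <- as_composition(M[, keep, drop = FALSE], require_positive = FALSE)
  attr(out, "kept_parts") <- colnames(M)[keep]
  attr(out, "dropped_parts") <- colnames(M)[!keep]
  out
}

#' Export a coordinate system as CSV
#'
#' Writes the SBP sign table (rows = coordinates, columns = parts, entries
#' -1/0/+1) and/or the real contrast matrix of a coordinate system. A
#' `# opals sbp v1` / `# opals contrast v1` header comment records the
#' schema.
#'
#' @param system a [coordinate_system()].
#' @param sbp_path,contrast_path output paths (either may be `NULL` to skip).
#' @export
write_system <- function(system, sbp_path = NULL, contrast_path = NULL) {
  stopifnot(inherits(system, "coordinate_system"))
  coord <- coordinate_names(system)
  emit <- function(m, path, tag, digits) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# opals %s v1 k=%s normalization=%s", tag,
                       ifelse(is.na(system$k), "NA", system$k),
                       system$normalization), con)
    df <- data.frame(coordinate = coord,
                     role = system$row_roles$role,
                     if (is.null(digits)) m else
                       apply(m, 2L, formatC, digits = digits, format = "g"),
                     check.names = FALSE)
    utils::write.table(df, con, sep = ",", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(sbp_path)) emit(system$sbp, sbp_path, "sbp", NULL)
  if (!is.null(contrast_path)) emit(system$contrast, contrast_path, "contrast", 17L)
  invisible(system)
}

#' Export screening records or part summaries as CSV
#'
#' @param x a `plr_records` or `part_summary` data frame.
#' @param path output path.
#' @export
write_results <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  tag <- if (inherits(x, "part_summary")) "part_summary" else "plr_records"
  writeLines(sprintf("# opals %s v1", tag), con)
  utils::write.table(as.data.frame(x), con, sep = ",", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
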