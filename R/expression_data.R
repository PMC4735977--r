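#' Construct an expression matrix
#'
#' An `expression_matrix` is the package's container for summarized microarray
#' (or any nonnegative) signal intensities: a numeric matrix of P probe sets
#' by n samples, with unique probe and sample identifiers and an optional
#' cell-type label. It is the unit over which all pairwise coexpression
#' statistics (Pearson r, mutual information, ranks) are computed.
#'
#' @param values numeric matrix, probes in rows, samples in columns; all
#'   entries must be finite and nonnegative.
#' @param probe_ids character vector of unique probe-set identifiers
#'   (defaults to `rownames(values)`).
#' @param sample_ids character vector of unique sample identifiers
#'   (defaults to `colnames(values)`).
#' @param cell_type free-text label for the cell type / condition group the
#'   samples belong to.
#' @return an object of class `expression_matrix`: the numeric matrix with
#'   `dimnames` set and a `cell_type` attribute.
#' @examples
#' m <- expression_matrix(matrix(runif(10), 2, 5,
#'   dimnames = list(c("a_at", "b_at"), paste0("S", 1:5))))
#' dim(m)
#' @export
expression_matrix <- function(values, probe_ids = rownames(values),
                              sample_ids = colnames(values),
                              cell_type = "unspecified") {
  if (!is.matrix(values) || !is.numeric(values)) {
    coexmi_error("coexmi_parse_error", "`values` must be a numeric matrix")
  }
  if (nrow(values) < 1L || ncol(values) < 1L) {
    coexmi_error("coexmi_empty_matrix_error", "expression matrix has no rows or no columns")
  }
  if (is.null(probe_ids) || is.null(sample_ids)) {
    coexmi_error("coexmi_parse_error", "probe and sample identifiers are required")
  }
  probe_ids <- as.character(probe_ids)
  sample_ids <- as.character(sample_ids)
  if (length(probe_ids) != nrow(values) || length(sample_ids) != ncol(values)) {
    coexmi_error("coexmi_parse_error", "identifier lengths do not match matrix dimensions")
  }
  if (anyDuplicated(probe_ids)) {
    coexmi_error("coexmi_duplicate_id_error", sprintf(
      "duplicated probe IDs: %s",
      paste(unique(probe_ids[duplicated(probe_ids)]), collapse = ", ")))
  }
  if (anyDuplicated(sample_ids)) {
    coexmi_error("coexmi_duplicate_id_error", sprintf(
      "duplicated sample IDs: %s",
      paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", ")))
  }
  if (anyNA(values) || any(!is.finite(values))) {
    coexmi_error("coexmi_parse_error", "expression values must all be finite (missing values are rejected, not imputed)")
  }
  if (any(values < 0)) {
    coexmi_error("coexmi_parse_error", "expression values must be nonnegative signal intensities")
  }
  dimnames(values) <- list(probe_ids, sample_ids)
  structure(values, cell_type = as.character(cell_type)[1],
            class = c("expression_matrix", class(values)))
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d probe sets x %d samples (cell type: %s)\n",
              nrow(x), ncol(x), attr(x, "cell_type")))
  invisible(x)
}

#' Read an expression matrix from a delimited text file
#'
#' Expects a header row of sample IDs and probe IDs in the first column;
#' every other cell is a nonnegative numeric signal value. This is the common
#' layout of summarized expression-matrix exports.
#'
#' @param path file path.
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @param cell_type optional cell-type label attached to the result.
#' @return an [expression_matrix()].
#' @export
read_expression_matrix <- function(path, dialect = c("tsv", "csv"),
                                   cell_type = "unspecified") {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "tsv") "\t" else ","
  if (!file.exists(path)) {
    coexmi_error("coexmi_io_error", sprintf("file not found: %s", path))
  }
  dt <- tryCatch(
    data.table::fread(path, sep = sep, header = TRUE, colClasses = list(character = 1)),
    error = function(e) coexmi_error("coexmi_parse_error",
                                     sprintf("failed to parse %s: %s", path, conditionMessage(e))))
  if (nrow(dt) < 1L || ncol(dt) < 2L) {
    coexmi_error("coexmi_empty_matrix_error", sprintf("no expression values in %s", path))
  }
  probe_ids <- dt[[1]]
  vals <- as.matrix(dt[, -1, with = FALSE])
  if (!is.numeric(vals)) {
    coexmi_error("coexmi_parse_error", sprintf("non-numeric expression cells in %s", path))
  }
  expression_matrix(vals, probe_ids = probe_ids,
                    sample_ids = colnames(dt)[-1], cell_type = cell_type)
}

#' Write an expression matrix to a delimited text file
#'
#' Inverse of [read_expression_matrix()]: the written file round-trips to an
#' identical matrix (values at full printed precision, IDs, ordering).
#'
#' @param mat an [expression_matrix()].
#' @param path output file path.
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(mat, path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(mat, "expression_matrix"))
  sep <- if (dialect == "tsv") "\t" else ","
  dt <- data.table::data.table(probe_id = rownames(mat))
  for (j in seq_len(ncol(mat))) dt[[colnames(mat)[j]]] <- unname(mat[, j])
  ok <- tryCatch({ data.table::fwrite(dt, path, sep = sep); TRUE },
                 error = function(e) FALSE)
  if (!ok) coexmi_error("coexmi_io_error", sprintf("cannot write %s", path))
  invisible(path)
}

#' Read a probe-to-gene-symbol annotation table
#'
#' Two-column delimited file (`probe_id`, `gene_symbol`); many probes may map
#' to one symbol but each probe maps to exactly one.
#'
#' @param path file path.
#' @param dialect `"tsv"` or `"csv"`.
#' @return named character vector: `annotation[probe_id] == gene_symbol`.
#' @export
read_probe_annotation <- function(path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "tsv") "\t" else ","
  dt <- data.table::fread(path, sep = sep, header = TRUE, colClasses = "character")
  if (ncol(dt) < 2L) coexmi_error("coexmi_parse_error", "annotation needs two columns (probe_id, gene_symbol)")
  if (anyDuplicated(dt[[1]])) {
    coexmi_error("coexmi_duplicate_id_error", "a probe maps to more than one gene symbol")
  }
  if (any(!nzchar(dt[[2]]))) coexmi_error("coexmi_parse_error", "empty gene symbols in annotation")
  stats::setNames(dt[[2]], dt[[1]])
}

#' Read a detection-call matrix
#'
#' Same layout as an expression matrix but entries are single characters:
#' `P` (present), `A` (absent), `M` (marginal), the usual convention for
#' microarray detection calls. Shape and IDs must match the companion
#' expression matrix when one is supplied.
#'
#' @param path file path.
#' @param dialect `"tsv"` or `"csv"`.
#' @param matrix optional companion [expression_matrix()] to validate against.
#' @return character matrix with probe/sample dimnames, class `detection_calls`.
#' @export
read_detection_calls <- function(path, dialect = c("tsv", "csv"), matrix = NULL) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "tsv") "\t" else ","
  dt <- data.table::fread(path, sep = sep, header = TRUE, colClasses = "character")
  if (nrow(dt) < 1L || ncol(dt) < 2L) {
    coexmi_error("coexmi_empty_matrix_error", sprintf("no calls in %s", path))
  }
  calls <- as.matrix(dt[, -1, with = FALSE])
  rownames(calls) <- dt[[1]]
  if (!all(calls %in% c("P", "A", "M"))) {
    coexmi_error("coexmi_parse_error", "detection calls must be single characters P/A/M")
  }
  if (!is.null(matrix)) {
    if (!identical(dim(calls), dim(unclass(matrix))) ||
        !identical(rownames(calls), rownames(matrix)) ||
        !identical(colnames(calls), colnames(matrix))) {
      coexmi_error("coexmi_shape_mismatch_error",
                   "detection-call matrix does not match its companion expression matrix")
    }
  }
  structure(calls, class = c("detection_calls", class(calls)))
}
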