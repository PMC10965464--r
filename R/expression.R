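#' Expression matrices
#'
#' Expression data are held as a plain numeric matrix (genes in rows, samples
#' or cells in columns) of class `expr_matrix`, carrying a declared unit
#' (`"counts"`, `"TPM"` or `"log2(TPM+1)"`) as an attribute. Values must be
#' finite, and nonnegative for counts/TPM; gene and sample identifiers must
#' be unique. The enrichment engine is rank-based, so the unit never changes
#' enrichment results; it matters for the CYT score and for bookkeeping.
#'
#' @name expression-matrices
NULL

.expr_units <- c("counts", "TPM", "log2(TPM+1)")

#' Construct a validated expression matrix
#'
#' @param values Numeric matrix, genes x samples, with rownames (gene symbols)
#'   and colnames (sample identifiers).
#' @param unit One of `"counts"`, `"TPM"`, `"log2(TPM+1)"`.
#' @return The matrix with class `expr_matrix` and a `unit` attribute.
#' @export
expression_matrix <- function(values, unit = c("TPM", "counts", "log2(TPM+1)")) {
  unit <- match.arg(unit)
  if (!is.matrix(values) || !is.numeric(values))
    stopf("`values` must be a numeric matrix")
  if (nrow(values) < 1L || ncol(values) < 1L)
    stopf("expression matrix must be at least 1 x 1")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stopf("expression matrix needs gene rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stopf("duplicate gene identifiers: %s", rownames(values)[duplicated(rownames(values))][1L])
  if (anyDuplicated(colnames(values)))
    stopf("duplicate sample identifiers: %s", colnames(values)[duplicated(colnames(values))][1L])
  if (any(!is.finite(values)))
    stopf("expression matrix contains non-finite values")
  if (unit %in% c("counts", "TPM") && any(values < 0))
    stopf("negative values are not allowed for unit '%s'", unit)
  structure(values, unit = unit, class = c("expr_matrix", class(values)))
}

#' Unit of an expression matrix
#' @param x An `expr_matrix`.
#' @return The unit string.
#' @export
expr_unit <- function(x) {
  u <- attr(x, "unit")
  if (is.null(u)) stopf("matrix carries no unit tag; build it with expression_matrix()")
  u
}

#' Read an expression matrix from TSV or MatrixMarket files
#'
#' TSV input has gene identifiers in the first column and one header column
#' per sample. MatrixMarket input (`.mtx`) needs companion `rows.txt` and
#' `cols.txt` files (one identifier per line) next to the matrix file, or
#' explicit paths. Duplicate gene rows are collapsed by their elementwise
#' maximum with a warning.
#'
#' @param path Path to the `.tsv`/`.txt` table or `.mtx` file.
#' @param unit Declared unit of the stored values.
#' @param rows_path,cols_path Optional identifier files for MatrixMarket input.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path, unit = c("TPM", "counts", "log2(TPM+1)"),
                            rows_path = NULL, cols_path = NULL) {
  unit <- match.arg(unit)
  if (!file.exists(path)) stopf("expression file not found: %s", path)
  if (grepl("\\.mtx$", path)) {
    m <- as.matrix(Matrix::readMM(path))
    if (is.null(rows_path)) rows_path <- file.path(dirname(path), "rows.txt")
    if (is.null(cols_path)) cols_path <- file.path(dirname(path), "cols.txt")
    if (!file.exists(rows_path) || !file.exists(cols_path))
      stopf("MatrixMarket input needs rows.txt and cols.txt beside %s", path)
    rownames(m) <- readLines(rows_path)
    colnames(m) <- readLines(cols_path)
  } else {
    tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                             check.names = FALSE, stringsAsFactors = FALSE)
    ids <- as.character(tab[[1L]])
    m <- as.matrix(tab[, -1L, drop = FALSE])
    if (!is.numeric(m)) {
      bad <- which(is.na(suppressWarnings(apply(m, 2, as.numeric))) & !is.na(m), arr.ind = TRUE)
      if (nrow(bad))
        stopf("non-numeric value at gene '%s', sample '%s'",
              ids[bad[1L, 1L]], colnames(m)[bad[1L, 2L]])
      stopf("expression table is not numeric")
    }
    rownames(m) <- ids
  }
  if (anyDuplicated(rownames(m))) {
    warnf("duplicate gene rows collapsed by maximum: %s, ...",
          rownames(m)[duplicated(rownames(m))][1L])
    m <- do.call(rbind, lapply(split(seq_len(nrow(m)), rownames(m)), function(ix)
      apply(m[ix, , drop = FALSE], 2, max)))
  }
  expression_matrix(m, unit = unit)
}

#' Write an expression matrix to TSV
#'
#' Values are written with 17 significant digits so that
#' `read_expression(write_expression(m))` round-trips bit-exactly.
#'
#' @param mat An [expression_matrix()] or numeric matrix with dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(mat, path) {
  vals <- matrix(sprintf("%.17g", unclass(mat)), nrow = nrow(mat),
                 dimnames = dimnames(mat))
  df <- data.frame(gene_id = rownames(mat), vals, check.names = FALSE)
  colnames(df) <- c("gene_id", colnames(mat))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
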