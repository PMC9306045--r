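#' Read a genes x cells count matrix
#'
#' Reads an expression count matrix from dense CSV/TSV or sparse MatrixMarket
#' format. Genes are rows and cells are columns throughout the package; a file
#' laid out cells-in-rows must be read with `transpose = TRUE` — orientation is
#' never guessed.
#'
#' For `format = "mtx"` the file is a coordinate MatrixMarket matrix
#' (1-based indices, genes x cells) accompanied by `genes.tsv` and
#' `barcodes.tsv` in the same directory (one identifier per line), mirroring
#' common single-cell tool output. Entries not listed in the file are zero.
#'
#' For CSV/TSV the first column holds gene identifiers and the first row cell
#' identifiers; UTF-8, `.` decimal separator.
#'
#' @param path Path to the matrix file.
#' @param format One of `"csv"`, `"tsv"`, `"mtx"`. Defaults to the file
#'   extension.
#' @param transpose Logical; set `TRUE` when a dense file stores cells as rows.
#' @return A base numeric matrix (genes x cells) with unique `rownames`
#'   (gene ids) and `colnames` (cell ids), all entries finite and >= 0.
#' @seealso [write_matrix()], [normalize_cpm()]
#' @export
#' @examples
#' tmp <- tempfile(fileext = ".csv")
#' writeLines(c("gene,c1,c2", "g1,1,0", "g2,2,3"), tmp)
#' read_counts(tmp)
read_counts <- function(path, format = c("auto", "csv", "tsv", "mtx"),
                        transpose = FALSE) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
      csv = "csv", tsv = "tsv", txt = "tsv", mtx = "mtx",
      stop("cannot infer format from extension of '", path,
           "'; pass format= explicitly", call. = FALSE))
  }
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  if (format == "mtx") {
    m <- .read_mtx(path)
    if (transpose) m <- t(m)
  } else {
    sep <- if (format == "csv") "," else "\t"
    df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                            check.names = FALSE, comment.char = "",
                            quote = "\"", encoding = "UTF-8")
    m <- as.matrix(df)
    storage.mode(m) <- "double"
    if (transpose) m <- t(m)
  }
  validate_counts(m)
  m
}

.read_mtx <- function(path) {
  dir <- dirname(path)
  gene_file <- file.path(dir, "genes.tsv")
  cell_file <- file.path(dir, "barcodes.tsv")
  for (f in c(gene_file, cell_file)) {
    if (!file.exists(f)) {
      stop("companion file missing for mtx input: ", f, call. = FALSE)
    }
  }
  sm <- Matrix::readMM(path)
  genes <- readLines(gene_file)
  cells <- readLines(cell_file)
  # name files may carry extra tab-separated columns (id \t symbol); keep col 1
  genes <- vapply(strsplit(genes, "\t", fixed = TRUE), `[`, "", 1L)
  cells <- vapply(strsplit(cells, "\t", fixed = TRUE), `[`, "", 1L)
  if (length(genes) != nrow(sm)) {
    stop("genes.tsv has ", length(genes), " entries but matrix has ",
         nrow(sm), " rows", call. = FALSE)
  }
  if (length(cells) != ncol(sm)) {
    stop("barcodes.tsv has ", length(cells), " entries but matrix has ",
         ncol(sm), " columns", call. = FALSE)
  }
  m <- as.matrix(sm)
  dimnames(m) <- list(genes, cells)
  m
}

#' Validate a genes x cells count matrix
#'
#' Checks the container contract shared by all matrix-valued inputs: numeric
#' matrix, finite non-negative entries, unique row (gene) and column (cell)
#' identifiers.
#'
#' @param m Matrix to validate.
#' @param allow_noninteger Allow fractional entries (normalized / log
#'   matrices); raw counts may be fractional too after upstream processing, so
#'   integrality is never enforced.
#' @return `m`, invisibly.
#' @export
validate_counts <- function(m, allow_noninteger = TRUE) {
  if (!is.matrix(m) || !is.numeric(m)) {
    stop("expected a numeric matrix", call. = FALSE)
  }
  if (length(m) && any(!is.finite(m))) {
    stop("matrix contains non-finite entries", call. = FALSE)
  }
  if (length(m) && any(m < 0)) {
    stop("matrix contains negative entries", call. = FALSE)
  }
  rn <- rownames(m)
  cn <- colnames(m)
  if (!is.null(rn) && anyDuplicated(rn)) {
    stop("duplicate gene identifiers", call. = FALSE)
  }
  if (!is.null(cn) && anyDuplicated(cn)) {
    stop("duplicate cell identifiers", call. = FALSE)
  }
  invisible(m)
}

#' Write a genes x cells matrix
#'
#' Inverse of [read_counts()]: dense CSV/TSV (gene ids in the first column,
#' cell ids in the header) or MatrixMarket with `genes.tsv` / `barcodes.tsv`
#' companions. Explicit zeros are stored as absent entries in mtx output.
#' A round trip through `write_matrix()` then `read_counts()` reproduces the
#' matrix to within float-formatting tolerance.
#'
#' @param m Genes x cells numeric matrix with dimnames.
#' @param path Output path.
#' @param format One of `"csv"`, `"tsv"`, `"mtx"`; default from extension.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path, format = c("auto", "csv", "tsv", "mtx")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
      csv = "csv", tsv = "tsv", txt = "tsv", mtx = "mtx",
      stop("cannot infer format from extension of '", path, "'",
           call. = FALSE))
  }
  if (!is.matrix(m)) m <- as.matrix(m)
  if (is.null(rownames(m)) && nrow(m) > 0) {
    rownames(m) <- paste0("g", seq_len(nrow(m)))
  }
  if (is.null(colnames(m)) && ncol(m) > 0) {
    colnames(m) <- paste0("c", seq_len(ncol(m)))
  }
  if (format == "mtx") {
    sm <- methods::as(methods::as(Matrix::Matrix(m, sparse = TRUE),
                                  "generalMatrix"), "CsparseMatrix")
    Matrix::writeMM(sm, path)
    dir <- dirname(path)
    writeLines(rownames(m), file.path(dir, "genes.tsv"))
    writeLines(colnames(m), file.path(dir, "barcodes.tsv"))
  } else {
    sep <- if (format == "csv") "," else "\t"
    # %.17g round-trips doubles exactly through text
    chr <- matrix(sprintf("%.17g", m), nrow(m), ncol(m))
    header <- paste(c("gene", colnames(m)), collapse = sep)
    rows <- if (nrow(m) > 0) {
      apply(cbind(rownames(m), chr), 1L, paste, collapse = sep)
    } else {
      character(0)
    }
    writeLines(c(header, rows), path)
  }
  invisible(path)
}

#' Drop genes expressed in no cell
#'
#' Removes every gene (row) whose counts are zero across all cells; row order
#' and all retained values are unchanged. May return a 0-gene matrix.
#'
#' @param m Genes x cells count matrix.
#' @return The filtered matrix.
#' @export
filter_unexpressed_genes <- function(m) {
  validate_counts(m)
  keep <- rowSums(m != 0) > 0
  m[keep, , drop = FALSE]
}

#' Counts-per-million normalization
#'
#' Divides each cell's counts by that cell's total and multiplies by a scale
#' factor (default 1e6), so every cell with a non-zero total sums exactly to
#' the scale factor. Cells with zero total are kept as all-zero columns (no
#' cell filtering is performed) with a warning.
#'
#' @param m Genes x cells count matrix.
#' @param scale Positive scale factor; default `1e6` (CPM).
#' @return Normalized matrix of the same shape.
#' @export
normalize_cpm <- function(m, scale = 1e6) {
  validate_counts(m)
  stopifnot(is.numeric(scale), length(scale) == 1L, scale > 0)
  totals <- colSums(m)
  zero <- totals == 0
  if (any(zero)) {
    warning(sum(zero), " cell(s) with zero total count kept as all-zero ",
            "columns", call. = FALSE)
    totals[zero] <- 1  # avoid 0/0; those columns are all zero anyway
  }
  sweep(m, 2L, totals / scale, `/`)
}

#' Log2(x + 1) transform
#'
#' Entrywise `log2(x + 1)` of a normalized matrix; zeros map to zero, so the
#' zero pattern of the input is preserved exactly.
#'
#' @param n Non-negative genes x cells matrix (typically CPM-normalized).
#' @return Log-transformed matrix.
#' @export
log_transform <- function(n) {
  if (!is.matrix(n) || !is.numeric(n)) {
    stop("expected a numeric matrix", call. = FALSE)
  }
  if (length(n) && any(n < 0)) {
    stop("negative entries cannot be log-transformed", call. = FALSE)
  }
  log2(n + 1)
}

#' Full preprocessing: filter, normalize, log-transform
#'
#' Convenience composition of [filter_unexpressed_genes()], [normalize_cpm()]
#' and [log_transform()] — the standard route from raw counts to the working
#' space in which imputation operates.
#'
#' @inheritParams normalize_cpm
#' @return Log-transformed CPM matrix with unexpressed genes removed.
#' @export
preprocess_counts <- function(m, scale = 1e6) {
  log_transform(normalize_cpm(filter_unexpressed_genes(m), scale = scale))
}
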