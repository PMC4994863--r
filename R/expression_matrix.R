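#' Construct an expression matrix
#'
#' The central data container: a dense genes x cells numeric matrix with
#' unique gene and cell identifiers, and optionally a per-cell collection-time
#' label (e.g. the hour at which each cell was harvested in a time-course
#' experiment). Values are assumed to be normalized expression measurements
#' (e.g. FPKM/TPM, possibly log-transformed); the package never re-normalizes
#' library sizes.
#'
#' @param values numeric matrix, genes in rows and cells in columns.
#' @param gene_ids character vector of unique gene identifiers (rows).
#' @param cell_ids character vector of unique cell identifiers (columns).
#' @param collection_time optional per-cell label (numeric or character) of
#'   length `ncol(values)`; used only by the evaluation functions.
#' @return an object of class `expression_matrix` with elements `values`
#'   (dimnamed matrix), `gene_ids`, `cell_ids` and `collection_time`.
#' @export
expression_matrix <- function(values, gene_ids = rownames(values),
                              cell_ids = colnames(values),
                              collection_time = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(gene_ids) || is.null(cell_ids)) {
    stop("gene_ids and cell_ids are required (or set as dimnames)")
  }
  gene_ids <- as.character(gene_ids)
  cell_ids <- as.character(cell_ids)
  if (length(gene_ids) != nrow(values)) {
    stop("gene_ids length (", length(gene_ids), ") != number of rows (",
         nrow(values), ")")
  }
  if (length(cell_ids) != ncol(values)) {
    stop("cell_ids length (", length(cell_ids), ") != number of columns (",
         ncol(values), ")")
  }
  dup <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup)) stop("duplicate gene identifier(s): ",
                        paste(utils::head(dup, 5), collapse = ", "))
  dup <- unique(cell_ids[duplicated(cell_ids)])
  if (length(dup)) stop("duplicate cell identifier(s): ",
                        paste(utils::head(dup, 5), collapse = ", "))
  if (anyNA(values) || any(!is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1, ]
    stop("non-finite expression value at gene '", gene_ids[bad[1]],
         "', cell '", cell_ids[bad[2]], "'")
  }
  if (!is.null(collection_time)) {
    if (length(collection_time) != length(cell_ids)) {
      stop("collection_time must have one label per cell")
    }
    names(collection_time) <- cell_ids
  }
  dimnames(values) <- list(gene_ids, cell_ids)
  structure(list(values = values, gene_ids = gene_ids, cell_ids = cell_ids,
                 collection_time = collection_time),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("expression_matrix: ", length(x$gene_ids), " genes x ",
      length(x$cell_ids), " cells",
      if (!is.null(x$collection_time)) " (with collection-time labels)",
      "\n", sep = "")
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Subset the cells of an expression matrix
#'
#' @param m an [expression_matrix()].
#' @param cells character vector of cell ids or integer/logical column index.
#' @return an `expression_matrix` restricted to the selected cells, in the
#'   order given; collection-time labels are carried along.
#' @export
subset_cells <- function(m, cells) {
  stopifnot(inherits(m, "expression_matrix"))
  if (is.character(cells)) {
    miss <- setdiff(cells, m$cell_ids)
    if (length(miss)) stop("unknown cell id(s): ",
                           paste(utils::head(miss, 5), collapse = ", "))
    idx <- match(cells, m$cell_ids)
  } else {
    idx <- seq_along(m$cell_ids)[cells]
  }
  expression_matrix(m$values[, idx, drop = FALSE],
                    gene_ids = m$gene_ids,
                    cell_ids = m$cell_ids[idx],
                    collection_time = if (!is.null(m$collection_time))
                      m$collection_time[idx])
}

#' Read an expression matrix from disk
#'
#' Dense TSV/CSV matrices have gene ids in the first column and a header row
#' of cell ids. Matrix Market (`mtx`) input is a 1-based coordinate triplet
#' file with companion one-name-per-line gene and cell name files; implicit
#' entries are materialized as exact zeros.
#'
#' @param path path to the matrix file.
#' @param format one of `"tsv"`, `"csv"`, `"mtx"`.
#' @param genes_path,cells_path companion name files (mtx only).
#' @param time_path optional TSV with columns `cell_id`, `time_label`
#'   providing collection-time labels.
#' @return an [expression_matrix()].
#' @export
load_expression <- function(path, format = c("tsv", "csv", "mtx"),
                            genes_path = NULL, cells_path = NULL,
                            time_path = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format %in% c("tsv", "csv")) {
    sep <- if (format == "tsv") "\t" else ","
    tab <- utils::read.table(path, sep = sep, header = TRUE, row.names = NULL,
                             check.names = FALSE, colClasses = "character",
                             quote = "", comment.char = "")
    gene_ids <- tab[[1]]
    cell_ids <- colnames(tab)[-1]
    raw <- as.matrix(tab[, -1, drop = FALSE])
    num <- suppressWarnings(matrix(as.numeric(raw), nrow = nrow(raw)))
    if (anyNA(num)) {
      bad <- which(is.na(num), arr.ind = TRUE)[1, ]
      stop("non-numeric entry '", raw[bad[1], bad[2]], "' at gene '",
           gene_ids[bad[1]], "', cell '", cell_ids[bad[2]], "'")
    }
    m <- expression_matrix(num, gene_ids = gene_ids, cell_ids = cell_ids)
  } else {
    if (is.null(genes_path) || is.null(cells_path)) {
      stop("mtx input requires genes_path and cells_path")
    }
    if (!file.exists(genes_path)) stop("file not found: ", genes_path)
    if (!file.exists(cells_path)) stop("file not found: ", cells_path)
    sp <- Matrix::readMM(path)
    gene_ids <- readLines(genes_path)
    cell_ids <- readLines(cells_path)
    if (nrow(sp) != length(gene_ids)) {
      stop("matrix has ", nrow(sp), " rows but ", length(gene_ids),
           " gene names")
    }
    if (ncol(sp) != length(cell_ids)) {
      stop("matrix has ", ncol(sp), " columns but ", length(cell_ids),
           " cell names")
    }
    m <- expression_matrix(as.matrix(sp), gene_ids = gene_ids,
                           cell_ids = cell_ids)
  }
  if (!is.null(time_path)) {
    m <- attach_collection_time(m, time_path)
  }
  m
}

#' Attach collection-time labels from a TSV file
#'
#' @param m an [expression_matrix()].
#' @param path TSV with header and columns `cell_id`, `time_label`.
#' @return `m` with `collection_time` filled in.
#' @export
attach_collection_time <- function(m, path) {
  stopifnot(inherits(m, "expression_matrix"))
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           check.names = FALSE, colClasses = "character")
  if (!all(c("cell_id", "time_label") %in% colnames(tab))) {
    stop("collection-time file must have columns cell_id and time_label")
  }
  miss <- setdiff(m$cell_ids, tab$cell_id)
  if (length(miss)) stop("no time label for cell(s): ",
                         paste(utils::head(miss, 5), collapse = ", "))
  lab <- tab$time_label[match(m$cell_ids, tab$cell_id)]
  num <- suppressWarnings(as.numeric(lab))
  m$collection_time <- if (!anyNA(num)) num else lab
  names(m$collection_time) <- m$cell_ids
  m
}

#' Write an expression matrix as TSV or CSV
#'
#' @param m an [expression_matrix()].
#' @param path output file.
#' @param format `"tsv"` or `"csv"`.
#' @export
write_expression <- function(m, path, format = c("tsv", "csv")) {
  stopifnot(inherits(m, "expression_matrix"))
  format <- match.arg(format)
  sep <- if (format == "tsv") "\t" else ","
  tab <- data.frame(gene_id = m$gene_ids, m$values, check.names = FALSE,
                    stringsAsFactors = FALSE)
  colnames(tab) <- c("gene_id", m$cell_ids)
  utils::write.table(tab, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Log-transform expression values
#'
#' Replaces every entry y by log_base(y + pseudocount), the conventional
#' variance-stabilizing transform for normalized expression units such as
#' TPM or FPKM.
#'
#' @param m an [expression_matrix()] with non-negative values.
#' @param pseudocount positive offset added before taking logs (default 1).
#' @param base logarithm base (default 2).
#' @return the transformed `expression_matrix`.
#' @export
log_transform <- function(m, pseudocount = 1, base = 2) {
  stopifnot(inherits(m, "expression_matrix"))
  if (pseudocount <= 0) stop("pseudocount must be > 0")
  if (any(m$values < 0)) {
    stop("negative expression values: input appears to be already ",
         "log-scaled or corrupt")
  }
  m$values <- log(m$values + pseudocount, base = base)
  m
}
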