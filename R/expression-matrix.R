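#' Construct an expression matrix
#'
#' The central container of the package: a gene x cell (or gene x spot)
#' numeric matrix with unique gene and cell identifiers and a layer tag that
#' records whether values are raw UMI counts or log-normalized expression.
#' Genes are always rows and cells always columns.
#'
#' @param values numeric matrix (base or `Matrix` sparse), genes x cells,
#'   finite and non-negative. For `layer = "raw_counts"` all values must be
#'   non-negative integers.
#' @param gene_ids character vector of unique gene identifiers, one per row.
#'   Defaults to the rownames of `values`.
#' @param cell_ids character vector of unique cell identifiers, one per
#'   column. Defaults to the colnames of `values`.
#' @param layer one of `"raw_counts"` or `"lognorm"`.
#'
#' @details Values are held sparsely (`dgCMatrix`) when fewer than half of
#' the entries are non-zero, densely otherwise; all operations go through the
#' accessors so the representation is an implementation detail.
#'
#' @return an object of class `ExpressionMatrix`.
#' @export
expression_matrix <- function(values, gene_ids = rownames(values),
                              cell_ids = colnames(values),
                              layer = c("raw_counts", "lognorm")) {
  layer <- match.arg(layer)
  if (is.null(gene_ids) || is.null(cell_ids)) {
    stop("gene_ids and cell_ids are required (or set dimnames on 'values')")
  }
  gene_ids <- as.character(gene_ids)
  cell_ids <- as.character(cell_ids)
  if (nrow(values) != length(gene_ids)) {
    stop("row count (", nrow(values), ") != number of gene ids (",
         length(gene_ids), ")")
  }
  if (ncol(values) != length(cell_ids)) {
    stop("column count (", ncol(values), ") != number of cell ids (",
         length(cell_ids), ")")
  }
  if (anyDuplicated(gene_ids)) {
    stop("duplicate gene ids: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  }
  if (anyDuplicated(cell_ids)) {
    stop("duplicate cell ids: ",
         paste(unique(cell_ids[duplicated(cell_ids)]), collapse = ", "))
  }
  vals_num <- if (methods::is(values, "sparseMatrix")) values@x else values
  if (length(vals_num) && (anyNA(vals_num) || any(!is.finite(vals_num)))) {
    stop("values must be finite (no NA/NaN/Inf)")
  }
  if (length(vals_num) && any(vals_num < 0)) {
    stop("values must be non-negative")
  }
  if (layer == "raw_counts" && length(vals_num) &&
      any(vals_num != round(vals_num))) {
    stop("raw_counts layer requires integer values")
  }
  nnz <- if (methods::is(values, "sparseMatrix")) {
    Matrix::nnzero(values)
  } else {
    sum(values != 0)
  }
  dense_frac <- if (length(values)) nnz / length(values) else 0
  values <- if (dense_frac < 0.5) {
    if (methods::is(values, "sparseMatrix")) {
      methods::as(values, "CsparseMatrix") * 1
    } else {
      Matrix::Matrix(values, sparse = TRUE) * 1
    }
  } else {
    as.matrix(values)
  }
  dimnames(values) <- list(gene_ids, cell_ids)
  structure(
    list(gene_ids = gene_ids, cell_ids = cell_ids, values = values,
         layer = layer),
    class = "ExpressionMatrix"
  )
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d cells [layer: %s, %s]\n",
              length(x$gene_ids), length(x$cell_ids), x$layer,
              if (methods::is(x$values, "sparseMatrix")) "sparse" else "dense"))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Dense numeric values of an expression matrix
#'
#' @param m an `ExpressionMatrix`.
#' @return a base dense matrix with gene rownames and cell colnames.
#' @export
em_values <- function(m) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  as.matrix(m$values)
}

#' Read a 10x-style MatrixMarket triplet directory
#'
#' Loads a directory holding `matrix.mtx` (optionally gzipped), a features
#' file (`features.tsv`, `features.tsv.gz` or `genes.tsv`) and a barcodes
#' file (`barcodes.tsv`, optionally gzipped), as produced by Cell Ranger.
#' Genes are rows, cells are columns; the result carries the raw-counts
#' layer. Duplicate feature names are disambiguated with `.1`, `.2`, ...
#' suffixes (escalating on collision, as [make.unique()]).
#'
#' @param directory_path path to the triplet directory.
#' @param feature_column which column of the features file to use as gene id
#'   (10x features files carry Ensembl id, symbol, type; the symbol column 2
#'   is the default when present).
#' @return an `ExpressionMatrix` with `layer = "raw_counts"`.
#' @export
read_10x_mtx <- function(directory_path, feature_column = 2L) {
  find_one <- function(candidates, what) {
    for (f in candidates) {
      p <- file.path(directory_path, f)
      if (file.exists(p)) return(p)
    }
    stop("missing ", what, " file in ", directory_path,
         " (looked for ", paste(candidates, collapse = ", "), ")")
  }
  mtx_path <- find_one(c("matrix.mtx", "matrix.mtx.gz"), "matrix")
  feat_path <- find_one(c("features.tsv", "features.tsv.gz",
                          "genes.tsv", "genes.tsv.gz"), "features")
  bc_path <- find_one(c("barcodes.tsv", "barcodes.tsv.gz"), "barcodes")

  mat <- Matrix::readMM(mtx_path)
  feats <- utils::read.table(feat_path, sep = "\t", header = FALSE,
                             quote = "", comment.char = "",
                             colClasses = "character")
  bcs <- utils::read.table(bc_path, sep = "\t", header = FALSE,
                           quote = "", comment.char = "",
                           colClasses = "character")[[1]]
  if (nrow(feats) != nrow(mat)) {
    stop("features file has ", nrow(feats), " rows but matrix header ",
         "declares ", nrow(mat), " genes")
  }
  if (length(bcs) != ncol(mat)) {
    stop("barcodes file has ", length(bcs), " rows but matrix header ",
         "declares ", ncol(mat), " cells")
  }
  col <- min(feature_column, ncol(feats))
  gene_ids <- make.unique(feats[[col]], sep = ".")
  expression_matrix(mat, gene_ids = gene_ids, cell_ids = bcs,
                    layer = "raw_counts")
}

#' Read a dense tab-separated expression matrix
#'
#' Expects a header row of cell ids (first field empty or a label) and one
#' row per gene whose first field is the gene id.
#'
#' @param file_path path to the TSV file.
#' @param layer layer tag for the values (`"raw_counts"` or `"lognorm"`).
#' @return an `ExpressionMatrix`.
#' @export
read_dense_tsv <- function(file_path, layer = c("raw_counts", "lognorm")) {
  layer <- match.arg(layer)
  if (!file.exists(file_path)) stop("no such file: ", file_path)
  lines <- readLines(file_path)
  if (!length(lines)) stop("empty file: ", file_path)
  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  cell_ids <- header[-1]
  n_cells <- length(cell_ids)
  body <- lines[-1]
  gene_ids <- character(length(body))
  values <- matrix(0, nrow = length(body), ncol = n_cells)
  for (i in seq_along(body)) {
    fields <- strsplit(body[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) != n_cells + 1L) {
      stop("format error at row ", i + 1L, ": expected ", n_cells + 1L,
           " fields, found ", length(fields))
    }
    gene_ids[i] <- fields[1L]
    row <- suppressWarnings(as.numeric(fields[-1L]))
    if (anyNA(row)) {
      j <- which(is.na(row))[1L]
      stop("format error at row ", i + 1L, ", column ", j + 1L,
           ": non-numeric value '", fields[j + 1L], "'")
    }
    values[i, ] <- row
  }
  expression_matrix(values, gene_ids = gene_ids, cell_ids = cell_ids,
                    layer = layer)
}

#' Write an expression matrix as dense TSV
#'
#' Values are printed with 17 significant digits so a write/read round trip
#' reproduces them exactly.
#'
#' @param m an `ExpressionMatrix`.
#' @param file_path output path.
#' @export
write_dense_tsv <- function(m, file_path) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  vals <- em_values(m)
  con <- file(file_path, open = "wt")
  on.exit(close(con))
  writeLines(paste(c("", m$cell_ids), collapse = "\t"), con)
  for (i in seq_along(m$gene_ids)) {
    writeLines(paste(c(m$gene_ids[i], sprintf("%.17g", vals[i, ])),
                     collapse = "\t"), con)
  }
  invisible(file_path)
}

#' Log-normalize raw counts
#'
#' Library-size normalization followed by a log transform: each count is
#' scaled by `scale_factor` over its cell's total count, then mapped through
#' `log(1 + x)`. This is the standard scRNA-seq "log-normalization" (scale
#' factor 10 000 by default) applied upstream of gene-gene distance
#' computation. Zeros map to zero exactly, so sparsity is preserved.
#'
#' @param m an `ExpressionMatrix` with `layer = "raw_counts"`.
#' @param scale_factor positive scale factor (default 1e4).
#' @return an `ExpressionMatrix` with `layer = "lognorm"` and identical ids.
#' @export
lognormalize <- function(m, scale_factor = 1e4) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (m$layer != "raw_counts") stop("lognormalize expects raw counts")
  if (!is.numeric(scale_factor) || length(scale_factor) != 1L ||
      scale_factor <= 0) {
    stop("scale_factor must be a positive number")
  }
  totals <- Matrix::colSums(m$values)
  if (any(totals == 0)) {
    stop("cells with zero total count: ",
         paste(m$cell_ids[totals == 0], collapse = ", "))
  }
  scaled <- m$values %*% Matrix::Diagonal(x = scale_factor / totals)
  out <- log1p(scaled)
  expression_matrix(out, gene_ids = m$gene_ids, cell_ids = m$cell_ids,
                    layer = "lognorm")
}
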