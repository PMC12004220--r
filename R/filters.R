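#' Filter modules by size
#'
#' Keeps modules with at least `min_size` genes. The benchmark analyses
#' discard modules of fewer than 10 genes. Ids are reassigned after
#' filtering and the decision is appended to the provenance.
#'
#' @param ms a `ModuleSet`.
#' @param min_size integer >= 1.
#' @return a filtered `ModuleSet`.
#' @export
filter_cluster_size <- function(ms, min_size = 10L) {
  stopifnot(inherits(ms, "ModuleSet"))
  min_size <- as.integer(min_size)
  keep <- vapply(ms$modules, length, 0L) >= min_size
  module_set(ms$modules[keep],
             provenance = c(ms$provenance,
                            list(filter_cluster_size = list(
                              min_size = min_size,
                              removed = sum(!keep)))))
}

#' Filter modules by number of supporting cells
#'
#' A cell supports a module when it expresses (value > 0) at least — or,
#' with `strict = TRUE`, more than — `min_frac` of the module's genes.
#' Modules supported by fewer than `min_cells` cells are discarded. The
#' benchmark analyses require five cells expressing 20% of a module's
#' genes; the PBMC analyses require two cells expressing more than 60%,
#' hence the strictness switch.
#'
#' @param ms a `ModuleSet`.
#' @param m_expr an `ExpressionMatrix` containing every module gene.
#' @param min_cells minimum number of supporting cells.
#' @param min_frac fraction of module genes a supporting cell must express.
#' @param strict if `TRUE` the fraction comparison is `>` rather than `>=`.
#' @return a filtered `ModuleSet`.
#' @export
filter_nb_supporting_cells <- function(ms, m_expr, min_cells = 5L,
                                       min_frac = 0.2, strict = FALSE) {
  stopifnot(inherits(ms, "ModuleSet"), inherits(m_expr, "ExpressionMatrix"))
  check_module_genes(ms, m_expr)
  keep <- vapply(seq_along(ms$modules), function(i) {
    genes <- ms$modules[[i]]
    frac <- Matrix::colSums(m_expr$values[genes, , drop = FALSE] > 0) /
      length(genes)
    supporting <- if (strict) sum(frac > min_frac) else sum(frac >= min_frac)
    supporting >= min_cells
  }, NA)
  module_set(ms$modules[keep],
             provenance = c(ms$provenance,
                            list(filter_nb_supporting_cells = list(
                              min_cells = as.integer(min_cells),
                              min_frac = min_frac, strict = strict,
                              removed = sum(!keep)))))
}

#' Filter modules by expression standard deviation
#'
#' The module statistic is the mean, over the module's genes, of each
#' gene's standard deviation across cells; modules below `min_sd` are
#' discarded. Intended for log-normalized values, where a near-zero
#' standard deviation flags a module of flat, uninformative genes.
#'
#' @param ms a `ModuleSet`.
#' @param m_expr an `ExpressionMatrix` containing every module gene.
#' @param min_sd non-negative threshold on the module statistic.
#' @return a filtered `ModuleSet`.
#' @export
filter_module_sd <- function(ms, m_expr, min_sd = 0.3) {
  stopifnot(inherits(ms, "ModuleSet"), inherits(m_expr, "ExpressionMatrix"))
  check_module_genes(ms, m_expr)
  vals <- em_values(m_expr)
  keep <- vapply(ms$modules, function(genes) {
    mean(apply(vals[genes, , drop = FALSE], 1L, stats::sd)) >= min_sd
  }, NA)
  module_set(ms$modules[keep],
             provenance = c(ms$provenance,
                            list(filter_module_sd = list(
                              min_sd = min_sd, removed = sum(!keep)))))
}

check_module_genes <- function(ms, m_expr) {
  for (id in names(ms$modules)) {
    missing <- setdiff(ms$modules[[id]], m_expr$gene_ids)
    if (length(missing)) {
      stop("module ", id, " contains gene(s) absent from the matrix: ",
           paste(missing, collapse = ", "))
    }
  }
  invisible(TRUE)
}

#' Most co-expressed genes of each module
#'
#' Ranks each module's genes by their mean Pearson correlation with the
#' other genes of the module (descending, ties by gene id) and returns the
#' first `n`. A gene with undefined correlations (zero variance, or a
#' single-gene module) scores 0.
#'
#' @param ms a `ModuleSet`.
#' @param m_expr an `ExpressionMatrix` containing every module gene.
#' @param n number of genes per module (default 20).
#' @return named list module id -> ordered character vector of genes.
#' @export
top_genes <- function(ms, m_expr, n = 20L) {
  stopifnot(inherits(ms, "ModuleSet"), inherits(m_expr, "ExpressionMatrix"))
  n <- as.integer(n)
  if (n < 1L) stop("n must be >= 1")
  check_module_genes(ms, m_expr)
  vals <- em_values(m_expr)
  lapply(ms$modules, function(genes) {
    if (length(genes) == 1L) return(genes)
    cc <- suppressWarnings(stats::cor(t(vals[genes, , drop = FALSE])))
    cc[!is.finite(cc)] <- 0
    diag(cc) <- 0
    score <- rowSums(cc) / (length(genes) - 1L)
    genes[order(-score, genes)][seq_len(min(n, length(genes)))]
  })
}

#' Per-cell module activity scores
#'
#' A rank-based recovery-curve score in the spirit of AUCell: for each
#' cell, genes are ranked by descending expression (ties broken by gene
#' id); the score of module M is the area under the step curve counting how
#' many of M's genes appear within the top `ceiling(top_fraction * n_genes)`
#' ranks, normalized by the maximal attainable area (all module genes at the
#' very top). Scores lie in `[0, 1]`: 1 when the module's genes are exactly
#' the cell's highest-expressed genes, 0 when none appears in the top
#' fraction. Semantics match the AUCell recovery-curve idea but values are
#' not numerically identical to that package's.
#'
#' @param ms a `ModuleSet`.
#' @param m_expr an `ExpressionMatrix` containing every module gene.
#' @param top_fraction fraction of top-ranked genes integrated (default
#'   0.05, the conventional AUCell setting).
#' @return a `ModuleScoreMatrix`: modules x cells numeric matrix (with a
#'   `top_fraction` attribute).
#' @export
module_activity_scores <- function(ms, m_expr, top_fraction = 0.05) {
  stopifnot(inherits(ms, "ModuleSet"), inherits(m_expr, "ExpressionMatrix"))
  if (!is.numeric(top_fraction) || top_fraction <= 0 || top_fraction > 1) {
    stop("top_fraction must lie in (0, 1]")
  }
  check_module_genes(ms, m_expr)
  vals <- em_values(m_expr)
  n_genes <- nrow(vals)
  n_top <- as.integer(ceiling(top_fraction * n_genes))
  id_order <- order(m_expr$gene_ids)
  scores <- matrix(0, nrow = length(ms$modules), ncol = ncol(vals),
                   dimnames = list(names(ms$modules), m_expr$cell_ids))
  for (c_idx in seq_len(ncol(vals))) {
    # descending expression, ties by gene id
    ord <- order(-vals[, c_idx], match(seq_len(n_genes), id_order))
    rank_of_gene <- integer(n_genes)
    rank_of_gene[ord] <- seq_len(n_genes)
    names(rank_of_gene) <- m_expr$gene_ids
    for (m_idx in seq_along(ms$modules)) {
      genes <- ms$modules[[m_idx]]
      r <- sort(rank_of_gene[genes])
      r <- r[r <= n_top]
      # area under the recovery step curve over ranks 1..n_top
      auc <- if (length(r)) sum(n_top - r + 1L) else 0
      max_auc <- sum(n_top - seq_len(min(length(genes), n_top)) + 1L)
      scores[m_idx, c_idx] <- auc / max_auc
    }
  }
  structure(scores, top_fraction = top_fraction, class = c("ModuleScoreMatrix",
                                                           "matrix", "array"))
}

#' Write module activity scores as TSV (modules x cells)
#'
#' @param scores a `ModuleScoreMatrix`.
#' @param file_path output path.
#' @export
write_scores_tsv <- function(scores, file_path) {
  df <- data.frame(module_id = rownames(scores),
                   apply(scores, 2L, function(x) sprintf("%.17g", x)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("module_id", colnames(scores))
  utils::write.table(df, file_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file_path)
}
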