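#' Area under the ROC curve for a gene ranking
#'
#' Mann-Whitney form: the fraction of (positive, negative) gene pairs where
#' the positive gene scores higher, ties counting one half. When ranking by
#' DKNN, pass the negated DKNN so that informative (low-DKNN) genes score
#' high.
#'
#' @param scores numeric score per gene (higher = more informative).
#' @param truth logical per gene (`TRUE` = truly informative).
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, truth) {
  if (length(scores) != length(truth)) {
    stop("scores and truth must have equal length")
  }
  truth <- as.logical(truth)
  n_pos <- sum(truth)
  n_neg <- sum(!truth)
  if (n_pos == 0L || n_neg == 0L) {
    stop("need at least one positive and one negative gene")
  }
  r <- rank(scores)  # midranks handle ties with half credit
  (sum(r[truth]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' F1 score of a predicted gene set
#'
#' @param predicted character vector of predicted informative genes.
#' @param truth character vector of truly informative genes.
#' @param universe all genes under consideration (must contain both sets).
#' @return list with `f1`, `n_true_positive`, `n_false_positive`,
#'   `n_false_negative`. `f1 = 2TP / (2TP + FP + FN)`, 0 when the
#'   denominator vanishes.
#' @export
f1_score <- function(predicted, truth, universe) {
  predicted <- unique(as.character(predicted))
  truth <- unique(as.character(truth))
  bad <- setdiff(c(predicted, truth), universe)
  if (length(bad)) {
    stop("genes outside the universe: ", paste(bad, collapse = ", "))
  }
  tp <- length(intersect(predicted, truth))
  fp <- length(setdiff(predicted, truth))
  fn <- length(setdiff(truth, predicted))
  denom <- 2 * tp + fp + fn
  list(f1 = if (denom == 0) 0 else 2 * tp / denom,
       n_true_positive = tp, n_false_positive = fp, n_false_negative = fn)
}

#' Jaccard recovery of planted modules
#'
#' Computes the pairwise Jaccard index `|A ∩ B| / |A ∪ B|` between every
#' true module and every predicted module, takes for each true module the
#' best (top) Jaccard over the predicted modules (0 when there are none),
#' and summarizes recovery as the median of those maxima (midpoint for even
#' counts).
#'
#' @param true_modules non-empty list of non-empty character vectors.
#' @param predicted a `ModuleSet` (or plain list of character vectors).
#' @return list with `jaccard_matrix` (true x predicted), `top_jaccard`
#'   (per true module) and `median_top_jaccard`.
#' @export
jaccard_module_recovery <- function(true_modules, predicted) {
  if (!length(true_modules)) stop("true_modules must be non-empty")
  if (any(vapply(true_modules, length, 0L) == 0L)) {
    stop("true modules must be non-empty")
  }
  pred <- if (inherits(predicted, "ModuleSet")) predicted$modules
          else predicted
  jm <- matrix(0, nrow = length(true_modules), ncol = length(pred))
  for (i in seq_along(true_modules)) {
    a <- unique(true_modules[[i]])
    for (j in seq_along(pred)) {
      b <- unique(pred[[j]])
      jm[i, j] <- length(intersect(a, b)) / length(union(a, b))
    }
  }
  top <- if (length(pred)) apply(jm, 1L, max) else rep(0, length(true_modules))
  list(jaccard_matrix = jm, top_jaccard = top,
       median_top_jaccard = stats::median(top))
}

#' Run the full pipeline over a simulation grid and score it
#'
#' For every grid descriptor: simulate, log-normalize, select genes by
#' DKNN, build the neighborhood graph, cluster with MCL, apply the size and
#' supporting-cells filters, then score the result against the planted
#' truth — AUROC of the negated-DKNN ranking, F1 of the selected set, and
#' median top Jaccard of the final modules.
#'
#' @param grid output of [simulate_grid()] (possibly subset).
#' @param sel_params a `SelectionParams` (its seed is overridden per
#'   dataset by the grid seed).
#' @param graph_par a `GraphParams`.
#' @param mcl_par an `MclParams`.
#' @param min_size,min_cells,min_frac module filter settings.
#' @return a long-format `data.frame`, one row per dataset: `fc_max`,
#'   `replicate`, `seed`, `n_selected`, `n_modules`, `auroc`, `f1`,
#'   `median_top_jaccard`.
#' @export
run_benchmark <- function(grid,
                          sel_params = selection_params(),
                          graph_par = graph_params(),
                          mcl_par = mcl_params(),
                          min_size = 10L, min_cells = 5L, min_frac = 0.2) {
  if (!length(grid)) stop("grid must be non-empty")
  rows <- lapply(grid, function(cell) {
    sim <- simulate_dataset(cell$design)
    ln <- lognormalize(sim$matrix)
    sp <- sel_params
    sp$seed <- cell$seed
    sel <- select_genes(ln, sp)
    truth_genes <- names(sim$truth$de_gene_module)
    is_pos <- sel$gene_ids %in% truth_genes
    au <- auroc(-sel$observed_dknn, is_pos)
    f1 <- f1_score(sel$selected_genes,
                   intersect(truth_genes, sel$gene_ids),
                   sel$gene_ids)$f1
    ms <- partition_genes(ln, sel, graph_par, mcl_par)
    ms <- filter_cluster_size(ms, min_size)
    ms <- filter_nb_supporting_cells(ms, sim$matrix, min_cells, min_frac)
    jac <- jaccard_module_recovery(truth_modules(sim$truth), ms)
    data.frame(fc_max = cell$fc_max, replicate = cell$replicate,
               seed = cell$seed, n_selected = length(sel$selected_genes),
               n_modules = length(ms$modules), auroc = au, f1 = f1,
               median_top_jaccard = jac$median_top_jaccard)
  })
  do.call(rbind, rows)
}
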