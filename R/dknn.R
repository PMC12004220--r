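#' Parameters for DKNN gene selection
#'
#' Bundles the tunables of the density-based gene filtering step. Defaults
#' follow the settings used throughout the benchmark analyses: 50
#' neighbors, FDR target 1e-4, noise level 0.05, Pearson distance, and
#' genes kept only when expressed in at least four cells.
#'
#' @param k_neighbors K, the neighbor rank whose distance scores each gene
#'   (integer >= 1). Use 50 with the closest-neighborhood graph and 100 with
#'   the reciprocal graph.
#' @param fdr_target target false discovery rate in (0, 1).
#' @param noise_level fraction in `[0, 1)` describing which genes feed the
#'   null: the sampling pool is restricted to genes whose observed DKNN is
#'   at or above the `noise_level` empirical quantile of observed DKNNs
#'   (0 = all genes; values near 1 = only the highest-DKNN, i.e. noisiest,
#'   genes).
#' @param n_simulations number of simulated null DKNN values (>= 100);
#'   `NULL` (default) means one per gene.
#' @param seed integer seed making selection fully deterministic.
#' @param row_sum minimum number of cells in which a gene must be expressed
#'   (value > 0) to enter the analysis.
#' @param metric distance metric, see [gene_distance_matrix()].
#' @param null_method how the null DKNN sample is simulated:
#'   `"permute_expression"` (default; permute a noise gene's expression
#'   vector across cells and recompute its distances, preserving per-gene
#'   sparsity and marginals, see [simulate_null_dknn_perm()]) or
#'   `"pool_distances"` (resample pooled off-diagonal distances, see
#'   [simulate_null_dknn()]).
#' @return an object of class `SelectionParams`.
#' @export
selection_params <- function(k_neighbors = 50L, fdr_target = 1e-4,
                             noise_level = 0.05, n_simulations = NULL,
                             seed = 123L, row_sum = 4L,
                             metric = c("pearson", "spearman", "euclidean",
                                        "cosine"),
                             null_method = c("permute_expression",
                                             "pool_distances")) {
  metric <- match.arg(metric)
  null_method <- match.arg(null_method)
  k_neighbors <- as.integer(k_neighbors)
  if (k_neighbors < 1L) stop("k_neighbors must be >= 1")
  if (!is.numeric(fdr_target) || fdr_target <= 0 || fdr_target >= 1) {
    stop("fdr_target must lie in (0, 1)")
  }
  if (!is.numeric(noise_level) || noise_level < 0 || noise_level >= 1) {
    stop("noise_level must lie in [0, 1)")
  }
  if (!is.null(n_simulations)) {
    n_simulations <- as.integer(n_simulations)
    if (n_simulations < 100L) stop("n_simulations must be >= 100")
  }
  row_sum <- as.integer(row_sum)
  if (row_sum < 0L) stop("row_sum must be >= 0")
  structure(list(k_neighbors = k_neighbors, fdr_target = fdr_target,
                 noise_level = noise_level, n_simulations = n_simulations,
                 seed = as.integer(seed), row_sum = row_sum, metric = metric,
                 null_method = null_method),
            class = "SelectionParams")
}

#' Distance to the Kth nearest neighbor, per gene
#'
#' For each gene, the Kth smallest off-diagonal entry of its row of the
#' distance matrix. A low DKNN means the gene sits in a dense co-expression
#' neighborhood.
#'
#' @param d a `DistanceMatrix`.
#' @param K integer, `1 <= K <= n_genes - 1`.
#' @return named numeric vector of DKNN values, one per gene.
#' @export
compute_dknn <- function(d, K) {
  stopifnot(inherits(d, "DistanceMatrix"))
  n <- length(d$gene_ids)
  K <- as.integer(K)
  if (K < 1L || K > n - 1L) {
    stop("K must satisfy 1 <= K <= n_genes - 1 (n_genes = ", n, ")")
  }
  vals <- d$values
  out <- vapply(seq_len(n), function(i) {
    row <- vals[i, -i]
    sort.int(row, partial = K)[K]
  }, 0)
  names(out) <- d$gene_ids
  out
}

#' Simulate the null DKNN distribution by permuting expression vectors
#'
#' The default null of [select_genes()]. Each simulated value takes a probe
#' gene (sampled with replacement from all scored genes), permutes its
#' expression vector across cells — a without-replacement rearrangement
#' that destroys any co-expression while preserving the gene's marginal
#' distribution and sparsity — recomputes the probe's distance to every
#' other gene, and records the Kth smallest. Because each probe keeps its
#' own zero pattern and value distribution, the null reproduces the
#' row-level heterogeneity of the observed DKNNs (sparse genes have
#' heavier-tailed distance distributions), which a pooled-distance null
#' cannot.
#'
#' Probes deliberately span *all* genes rather than the high-DKNN noise
#' pool: permutation itself removes any co-expression signal a probe may
#' carry, so no guard against signal leakage is needed, and restricting
#' probes by observed DKNN would under-represent exactly the sparse,
#' heavy-tailed marginals whose null behavior the threshold must account
#' for (making the FDR anti-conservative). The `noise_level` parameter
#' therefore applies only to the pooled-distance null
#' ([simulate_null_dknn()]).
#'
#' @param m an `ExpressionMatrix` over the genes being scored (the working
#'   layer used for the distance matrix).
#' @param observed observed DKNN values aligned with `m$gene_ids` (used
#'   for validation only).
#' @param params a `SelectionParams` (uses `k_neighbors`, `n_simulations`,
#'   `metric`, `seed`).
#' @return numeric vector of `n_simulations` simulated DKNN values.
#' @export
simulate_null_dknn_perm <- function(m, observed, params) {
  stopifnot(inherits(m, "ExpressionMatrix"),
            inherits(params, "SelectionParams"))
  x <- em_values(m)
  n <- nrow(x)
  n_cells <- ncol(x)
  if (length(observed) != n) stop("observed must align with m$gene_ids")
  K <- params$k_neighbors
  n_sim <- if (is.null(params$n_simulations)) n else params$n_simulations

  # metric-specific row representation such that distance is recoverable
  # from cross-products; permutation commutes with the row-wise transforms
  if (params$metric == "spearman") x <- t(apply(x, 1L, rank))
  if (params$metric %in% c("pearson", "spearman")) {
    xc <- x - rowMeans(x)
    ss <- sqrt(rowSums(xc^2))
    if (any(ss == 0)) {
      stop("zero-variance gene(s) under a correlation metric: ",
           paste(m$gene_ids[ss == 0], collapse = ", "))
    }
    rep_rows <- xc / ss
    cross <- function(p) 1 - tcrossprod(p, rep_rows)
  } else if (params$metric == "cosine") {
    nrm <- sqrt(rowSums(x^2))
    if (any(nrm == 0)) {
      stop("zero-vector gene(s) under cosine metric: ",
           paste(m$gene_ids[nrm == 0], collapse = ", "))
    }
    rep_rows <- x / nrm
    cross <- function(p) 1 - tcrossprod(p, rep_rows)
  } else {
    rep_rows <- x
    sq <- rowSums(x^2)
    cross <- function(p) {
      d2 <- outer(rowSums(p^2), sq, "+") - 2 * tcrossprod(p, rep_rows)
      d2[d2 < 0] <- 0
      sqrt(d2)
    }
  }

  withr::with_seed(params$seed, {
    probes <- sample.int(n, n_sim, replace = TRUE)
    perm_rows <- t(vapply(seq_len(n_sim), function(i) {
      rep_rows[probes[i], sample.int(n_cells)]
    }, numeric(n_cells)))
    d_cross <- cross(perm_rows)
    vapply(seq_len(n_sim), function(i) {
      row <- d_cross[i, -probes[i]]
      sort.int(row, partial = K)[K]
    }, 0)
  })
}

#' Simulate the null DKNN distribution by resampling pooled distances
#'
#' An alternative null that resamples the observed
#' distances: the pool is every off-diagonal distance in the rows of the
#' noise genes (genes whose observed DKNN is at or above the `noise_level`
#' quantile; all genes when `noise_level = 0`). Each simulated value draws
#' `n_genes - 1` distances from that pool without replacement — a synthetic
#' gene row under random gene placement — and records its Kth smallest.
#' Being blind to row-level heterogeneity, this null is anti-conservative
#' on sparse droplet-like data; [simulate_null_dknn_perm()] is the default.
#'
#' @param d a `DistanceMatrix`.
#' @param observed observed DKNN values aligned with `d$gene_ids`.
#' @param params a `SelectionParams` (uses `k_neighbors`, `noise_level`,
#'   `n_simulations`, `seed`).
#' @return numeric vector of `n_simulations` simulated DKNN values.
#' @export
simulate_null_dknn <- function(d, observed, params) {
  stopifnot(inherits(d, "DistanceMatrix"), inherits(params, "SelectionParams"))
  n <- length(d$gene_ids)
  if (length(observed) != n) stop("observed must align with d$gene_ids")
  K <- params$k_neighbors
  n_sim <- if (is.null(params$n_simulations)) n else params$n_simulations
  cutoff <- stats::quantile(observed, probs = params$noise_level,
                            names = FALSE)
  pool_genes <- which(observed >= cutoff)
  # off-diagonal entries of the pool rows, column-major over the submatrix
  pool_vals <- d$values[pool_genes, , drop = FALSE]
  keep <- rep(TRUE, length(pool_vals))
  # column-major positions of the diagonal entries within the pool submatrix
  diag_pos <- seq_along(pool_genes) + (pool_genes - 1L) * length(pool_genes)
  keep[diag_pos] <- FALSE
  pool_vals <- pool_vals[keep]
  n_draw <- n - 1L
  if (length(pool_vals) < n_draw) {
    stop("noise pool holds only ", length(pool_vals), " distances but ",
         n_draw, " are drawn per simulation; lower noise_level")
  }
  withr::with_seed(params$seed, {
    vapply(seq_len(n_sim), function(s) {
      draw <- pool_vals[sample.int(length(pool_vals), n_draw)]
      sort.int(draw, partial = K)[K]
    }, 0)
  })
}

#' FDR-controlled DKNN threshold
#'
#' Scans every observed DKNN value as a candidate threshold `t` and
#' estimates `FDR(t)` as the expected number of null genes at or below `t`
#' (simulated fraction times the number of genes) over the observed count at
#' or below `t`, capped at 1. The threshold is the largest candidate whose
#' FDR does not exceed `alpha`; `NA` when no candidate qualifies.
#'
#' @param observed observed DKNN values.
#' @param simulated simulated null DKNN sample.
#' @param alpha FDR target in (0, 1).
#' @return list with `threshold` (number or `NA`) and `fdr_at_threshold`
#'   (1.0 when no threshold qualifies).
#' @export
estimate_fdr_threshold <- function(observed, simulated, alpha) {
  if (!length(observed) || !length(simulated)) {
    stop("observed and simulated must be non-empty")
  }
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop("alpha must lie in (0, 1)")
  }
  n_genes <- length(observed)
  n_sim <- length(simulated)
  cand <- sort(unique(observed))
  obs_sorted <- sort(observed)
  sim_sorted <- sort(simulated)
  n_obs_le <- findInterval(cand, obs_sorted)
  n_sim_le <- findInterval(cand, sim_sorted)
  fdr <- pmin(1, (n_sim_le / n_sim * n_genes) / pmax(1, n_obs_le))
  ok <- which(fdr <= alpha)
  if (!length(ok)) {
    list(threshold = NA_real_, fdr_at_threshold = 1.0)
  } else {
    i <- max(ok)
    list(threshold = cand[i], fdr_at_threshold = fdr[i])
  }
}

#' Select co-expressed genes by density-based filtering
#'
#' The first step of the module-detection algorithm: genes expressed in too
#' few cells are dropped, a gene-gene distance matrix is computed, every
#' gene is scored by its DKNN, a resampling null gives the DKNN distribution
#' expected in the absence of co-regulation, and an FDR-controlled threshold
#' separates co-expressed genes (low DKNN) from noise. Fully deterministic
#' given `params$seed`.
#'
#' @param m an `ExpressionMatrix` (normalized values recommended; pass the
#'   output of [lognormalize()]).
#' @param params a `SelectionParams`.
#' @return an object of class `DknnResult`: `gene_ids` (genes surviving the
#'   `row_sum` pre-filter), `observed_dknn`, `simulated_dknn`, `threshold`,
#'   `selected_genes` (`observed < threshold`), `fdr_at_threshold`, `params`.
#' @export
select_genes <- function(m, params = selection_params()) {
  stopifnot(inherits(m, "ExpressionMatrix"),
            inherits(params, "SelectionParams"))
  n_expressing <- Matrix::rowSums(m$values > 0)
  keep <- which(n_expressing >= params$row_sum)
  if (length(keep) < params$k_neighbors + 1L) {
    stop("only ", length(keep), " genes survive the row_sum filter; ",
         "need more than K = ", params$k_neighbors)
  }
  mk <- expression_matrix(m$values[keep, , drop = FALSE],
                          gene_ids = m$gene_ids[keep],
                          cell_ids = m$cell_ids, layer = m$layer)
  d <- gene_distance_matrix(mk, metric = params$metric)
  observed <- compute_dknn(d, params$k_neighbors)
  simulated <- if (params$null_method == "permute_expression") {
    simulate_null_dknn_perm(mk, observed, params)
  } else {
    simulate_null_dknn(d, observed, params)
  }
  thr <- estimate_fdr_threshold(observed, simulated, params$fdr_target)
  selected <- if (is.na(thr$threshold)) {
    character(0)
  } else {
    names(observed)[observed < thr$threshold]
  }
  structure(list(gene_ids = mk$gene_ids,
                 observed_dknn = observed,
                 simulated_dknn = simulated,
                 threshold = thr$threshold,
                 selected_genes = selected,
                 fdr_at_threshold = thr$fdr_at_threshold,
                 params = params),
            class = "DknnResult")
}

#' @export
print.DknnResult <- function(x, ...) {
  cat(sprintf(
    "DknnResult: %d genes scored, %d selected (threshold %s, FDR %.3g)\n",
    length(x$gene_ids), length(x$selected_genes),
    if (is.na(x$threshold)) "none" else sprintf("%.4f", x$threshold),
    x$fdr_at_threshold))
  invisible(x)
}

#' Export per-gene DKNN scores as TSV
#'
#' Columns: gene, dknn, selected (TRUE/FALSE).
#'
#' @param res a `DknnResult`.
#' @param file_path output path.
#' @export
write_dknn_tsv <- function(res, file_path) {
  stopifnot(inherits(res, "DknnResult"))
  df <- data.frame(gene = res$gene_ids,
                   dknn = sprintf("%.17g", res$observed_dknn),
                   selected = res$gene_ids %in% res$selected_genes,
                   stringsAsFactors = FALSE)
  utils::write.table(df, file_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file_path)
}
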