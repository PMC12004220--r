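#' Parameters for Markov clustering
#'
#' @param inflation r > 1, the entrywise sharpening exponent; larger values
#'   yield more, smaller clusters. The benchmark analyses use 1.2; sparse
#'   real datasets typically take 1.8-2.2.
#' @param expansion integer >= 2, the matrix power simulating flow (2 is
#'   the classical choice).
#' @param pruning_threshold entries below this value are zeroed after each
#'   inflation to keep the flow matrix sparse in effect.
#' @param max_iterations iteration cap.
#' @param convergence_tol stop when the largest entrywise change between
#'   successive flow matrices falls below this.
#' @return an object of class `MclParams`.
#' @export
mcl_params <- function(inflation = 1.2, expansion = 2L,
                       pruning_threshold = 1e-5, max_iterations = 100L,
                       convergence_tol = 1e-6) {
  if (!is.numeric(inflation) || inflation <= 1) {
    stop("inflation must be > 1")
  }
  expansion <- as.integer(expansion)
  if (expansion < 2L) stop("expansion must be >= 2")
  structure(list(inflation = inflation, expansion = expansion,
                 pruning_threshold = pruning_threshold,
                 max_iterations = as.integer(max_iterations),
                 convergence_tol = convergence_tol),
            class = "MclParams")
}

#' Markov clustering of a gene graph
#'
#' A from-scratch Markov Cluster (MCL) implementation. The adjacency matrix
#' (unweighted, with unit self-loops) is column-normalized into a stochastic
#' flow matrix, then alternately expanded (matrix power, extending random
#' walks) and inflated (entrywise power followed by column renormalization,
#' sharpening the walk) until the flow matrix stabilizes. Clusters are read
#' off the attractors: nodes with positive diagonal mass; each attractor's
#' row support forms a cluster, overlapping attractor systems are merged,
#' and nodes left unassigned become singletons.
#'
#' @param g a `GeneGraph`.
#' @param params an `MclParams`.
#' @return a `ModuleSet`. Its provenance records the MCL parameters plus
#'   diagnostics: iteration count, convergence flag and the maximum
#'   deviation of any column sum from 1 observed after normalization steps.
#' @export
mcl_cluster <- function(g, params = mcl_params()) {
  stopifnot(inherits(g, "GeneGraph"), inherits(params, "MclParams"))
  nodes <- sort(g$nodes)
  n <- length(nodes)
  if (n == 0L) stop("graph has no nodes")
  if (nrow(g$edges)) {
    i <- match(g$edges[, 1L], nodes)
    j <- match(g$edges[, 2L], nodes)
    adj <- Matrix::sparseMatrix(i = c(i, j, seq_len(n)),
                                j = c(j, i, seq_len(n)),
                                x = 1, dims = c(n, n),
                                dimnames = list(nodes, nodes))
  } else {
    adj <- Matrix::Diagonal(n)
    dimnames(adj) <- list(nodes, nodes)
  }
  adj <- methods::as(adj, "CsparseMatrix")

  # flow matrices stay sparse throughout thanks to pruning; all products
  # and entrywise operations run on dgCMatrix
  normalize_cols <- function(m) {
    cs <- Matrix::colSums(m)
    cs[cs == 0] <- 1
    m %*% Matrix::Diagonal(x = 1 / cs)
  }
  entry_power <- function(m, r) {
    m <- methods::as(m, "CsparseMatrix")
    m@x <- m@x^r
    m
  }
  prune_small <- function(m, thr) {
    m <- methods::as(m, "CsparseMatrix")
    m@x[m@x < thr] <- 0
    Matrix::drop0(m)
  }
  flow <- normalize_cols(adj)
  col_dev <- max(abs(Matrix::colSums(flow) - 1))
  converged <- FALSE
  iter <- 0L
  while (iter < params$max_iterations) {
    iter <- iter + 1L
    prev <- flow
    # expansion: random-walk extension
    expanded <- flow
    for (e in seq_len(params$expansion - 1L)) expanded <- expanded %*% flow
    # inflation: entrywise power + renormalization
    flow <- normalize_cols(entry_power(expanded, params$inflation))
    col_dev <- max(col_dev, abs(Matrix::colSums(flow) - 1))
    # pruning of negligible flow
    flow <- normalize_cols(prune_small(flow, params$pruning_threshold))
    col_dev <- max(col_dev, abs(Matrix::colSums(flow) - 1))
    if (max(abs(flow - prev)) < params$convergence_tol) {
      converged <- TRUE
      break
    }
  }
  flow <- methods::as(flow, "CsparseMatrix")

  attractors <- which(Matrix::diag(flow) > 0)
  assigned <- rep(NA_integer_, n)
  cluster_of_attr <- rep(NA_integer_, length(attractors))
  next_id <- 0L
  for (ai in seq_along(attractors)) {
    a <- attractors[ai]
    members <- which(flow[a, ] > 0)
    hit <- unique(stats::na.omit(assigned[members]))
    if (!length(hit)) {
      next_id <- next_id + 1L
      assigned[members] <- next_id
    } else {
      # overlapping attractor systems merge into the first cluster hit
      tgt <- min(hit)
      assigned[members] <- tgt
      assigned[assigned %in% hit] <- tgt
    }
  }
  clusters <- split(nodes[!is.na(assigned)], assigned[!is.na(assigned)])
  singletons <- as.list(nodes[is.na(assigned)])
  module_set(c(clusters, singletons),
             provenance = list(mcl = unclass(params),
                               mcl_diagnostics = list(
                                 iterations = iter,
                                 converged = converged,
                                 column_sum_max_dev = col_dev)))
}

#' Cluster selected genes into co-expression modules
#'
#' Steps two and three of the pipeline: rebuilds gene-gene distances over
#' the selected genes, constructs the chosen neighborhood graph, and
#' partitions it with [mcl_cluster()]. Provenance captures the selection,
#' graph and MCL parameters.
#'
#' @param m the `ExpressionMatrix` used for selection.
#' @param sel a `DknnResult` from [select_genes()].
#' @param gp a `GraphParams`.
#' @param mp an `MclParams`.
#' @return a `ModuleSet`.
#' @export
partition_genes <- function(m, sel, gp = graph_params(), mp = mcl_params()) {
  stopifnot(inherits(m, "ExpressionMatrix"), inherits(sel, "DknnResult"),
            inherits(gp, "GraphParams"), inherits(mp, "MclParams"))
  genes <- sel$selected_genes
  if (!length(genes)) stop("no genes selected")
  msub <- expression_matrix(m$values[genes, , drop = FALSE],
                            gene_ids = genes, cell_ids = m$cell_ids,
                            layer = m$layer)
  d <- gene_distance_matrix(msub, metric = sel$params$metric)
  g <- if (gp$method == "closest_neighborhood") {
    build_closest_neighborhood_graph(d, genes, S = gp$s_closest,
                                     K = gp$k_neighbors)
  } else {
    build_reciprocal_graph(d, genes, K = gp$k_neighbors)
  }
  ms <- mcl_cluster(g, mp)
  ms$provenance <- c(list(selection = unclass(sel$params),
                          graph = unclass(gp)),
                     ms$provenance)
  ms
}
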