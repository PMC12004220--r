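#' Parameters for gene neighborhood graph construction
#'
#' @param method `"closest_neighborhood"` (edges from each gene's S nearest
#'   neighbors, symmetrized by union) or `"reciprocal_neighborhood"` (edges
#'   only between mutually K-nearest genes).
#' @param s_closest S, the neighborhood size for the closest method; must be
#'   smaller than `k_neighbors`.
#' @param k_neighbors K, the neighborhood size for the reciprocal method
#'   (and the upper bound on S).
#' @return an object of class `GraphParams`.
#' @export
graph_params <- function(method = c("closest_neighborhood",
                                    "reciprocal_neighborhood"),
                         s_closest = 5L, k_neighbors = 50L) {
  method <- match.arg(method)
  s_closest <- as.integer(s_closest)
  k_neighbors <- as.integer(k_neighbors)
  if (s_closest < 1L || k_neighbors < 1L) stop("S and K must be >= 1")
  if (method == "closest_neighborhood" && s_closest >= k_neighbors) {
    stop("closest_neighborhood requires S < K (got S = ", s_closest,
         ", K = ", k_neighbors, ")")
  }
  structure(list(method = method, s_closest = s_closest,
                 k_neighbors = k_neighbors),
            class = "GraphParams")
}

# top-`k` neighbor indices per row of a distance matrix, excluding self;
# ties broken by distance then gene index so results are deterministic
knn_index_matrix <- function(vals, k) {
  n <- nrow(vals)
  res <- vapply(seq_len(n), function(i) {
    ord <- order(vals[i, ], seq_len(n))
    ord <- ord[ord != i]
    ord[seq_len(k)]
  }, integer(k))
  if (k == 1L) matrix(res, ncol = 1L) else t(res)
}

new_gene_graph <- function(nodes, edge_mat) {
  if (nrow(edge_mat)) {
    a <- pmin(edge_mat[, 1L], edge_mat[, 2L])
    b <- pmax(edge_mat[, 1L], edge_mat[, 2L])
    keep <- a != b
    key <- paste(a[keep], b[keep], sep = "\r")
    dedup <- !duplicated(key)
    edges <- cbind(a[keep][dedup], b[keep][dedup])
    edges <- edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]
  } else {
    edges <- matrix(character(0), ncol = 2L)
  }
  colnames(edges) <- c("from", "to")
  structure(list(nodes = nodes, edges = edges), class = "GeneGraph")
}

#' @export
print.GeneGraph <- function(x, ...) {
  cat(sprintf("GeneGraph: %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Closest-neighborhood gene graph
#'
#' Draws an edge between genes A and B whenever B lies in A's S-nearest
#' neighborhood (computed among the selected genes only); the directed
#' relation is symmetrized by union, so one direction suffices.
#'
#' @param d a `DistanceMatrix`.
#' @param selected character vector of gene ids (subset of `d$gene_ids`).
#' @param S neighborhood size, `1 <= S < K`.
#' @param K the selection neighborhood size bounding S.
#' @return a `GeneGraph` on `selected`.
#' @export
build_closest_neighborhood_graph <- function(d, selected, S, K) {
  stopifnot(inherits(d, "DistanceMatrix"))
  S <- as.integer(S); K <- as.integer(K)
  if (S >= K) stop("closest_neighborhood requires S < K")
  ds <- subset_distance(d, sort(selected))
  n <- length(ds$gene_ids)
  if (n <= S) stop("need more than S = ", S, " selected genes (got ", n, ")")
  nn <- knn_index_matrix(ds$values, S)
  from <- rep(ds$gene_ids, each = S)
  to <- ds$gene_ids[t(nn)]
  new_gene_graph(ds$gene_ids, cbind(from, to))
}

#' Reciprocal-neighborhood gene graph
#'
#' Draws an edge between genes A and B only when each lies in the other's
#' K-nearest neighborhood (mutual nearest neighbors among the selected
#' genes).
#'
#' @param d a `DistanceMatrix`.
#' @param selected character vector of gene ids (subset of `d$gene_ids`).
#' @param K neighborhood size, `1 <= K <= |selected| - 1`.
#' @return a `GeneGraph` on `selected`.
#' @export
build_reciprocal_graph <- function(d, selected, K) {
  stopifnot(inherits(d, "DistanceMatrix"))
  K <- as.integer(K)
  ds <- subset_distance(d, sort(selected))
  n <- length(ds$gene_ids)
  if (K < 1L || K > n - 1L) {
    stop("K must satisfy 1 <= K <= |selected| - 1 (|selected| = ", n, ")")
  }
  nn <- knn_index_matrix(ds$values, K)
  inb <- matrix(FALSE, n, n)
  inb[cbind(rep(seq_len(n), each = K), as.integer(t(nn)))] <- TRUE
  mutual <- inb & t(inb)
  idx <- which(mutual & upper.tri(mutual), arr.ind = TRUE)
  new_gene_graph(ds$gene_ids,
                 cbind(ds$gene_ids[idx[, 1L]], ds$gene_ids[idx[, 2L]]))
}

#' Export a gene graph as an edge-list TSV
#'
#' @param g a `GeneGraph`.
#' @param file_path output path.
#' @export
write_graph_tsv <- function(g, file_path) {
  stopifnot(inherits(g, "GeneGraph"))
  utils::write.table(as.data.frame(g$edges), file_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(file_path)
}
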