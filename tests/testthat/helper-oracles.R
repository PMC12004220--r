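# Independent brute-force oracles and fixture builders used across the
# suite. Oracles are deliberately naive (full sorts, double loops) and
# share no code with the package internals they check.

# random symmetric distance matrix with zero diagonal
random_distance_matrix <- function(n, max_d = 1) {
  m <- matrix(stats::runif(n * n, 0, max_d), n, n)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  dimnames(m) <- list(sprintf("g%03d", seq_len(n)), sprintf("g%03d", seq_len(n)))
  m
}

as_distance <- function(vals, metric = "euclidean") {
  structure(list(gene_ids = rownames(vals), values = vals, metric = metric),
            class = "DistanceMatrix")
}

# Kth nearest distance via full sort of each row without the diagonal
oracle_dknn <- function(vals, K) {
  vapply(seq_len(nrow(vals)), function(i) sort(vals[i, -i])[K], 0)
}

# union of top-S nearest relations (ties by distance then index)
oracle_closest_edges <- function(vals, S) {
  n <- nrow(vals)
  ids <- rownames(vals)
  pairs <- character(0)
  for (i in seq_len(n)) {
    nb <- setdiff(order(vals[i, ], seq_len(n)), i)[seq_len(S)]
    for (j in nb) {
      pairs <- c(pairs, paste(sort(c(ids[i], ids[j])), collapse = "|"))
    }
  }
  sort(unique(pairs))
}

# mutual K-nearest-neighbor relations
oracle_reciprocal_edges <- function(vals, K) {
  n <- nrow(vals)
  ids <- rownames(vals)
  nb <- lapply(seq_len(n), function(i) {
    setdiff(order(vals[i, ], seq_len(n)), i)[seq_len(K)]
  })
  pairs <- character(0)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      if (j %in% nb[[i]] && i %in% nb[[j]]) {
        pairs <- c(pairs, paste(ids[i], ids[j], sep = "|"))
      }
    }
  }
  sort(pairs)
}

graph_edge_keys <- function(g) {
  if (!nrow(g$edges)) return(character(0))
  sort(paste(g$edges[, 1], g$edges[, 2], sep = "|"))
}

# pairwise-count AUROC with half credit for ties
oracle_auroc <- function(scores, truth) {
  pos <- scores[truth]
  neg <- scores[!truth]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + (p > q) + 0.5 * (p == q)
  }
  tot / (length(pos) * length(neg))
}

oracle_f1 <- function(predicted, truth) {
  tp <- length(intersect(predicted, truth))
  fp <- length(setdiff(predicted, truth))
  fn <- length(setdiff(truth, predicted))
  if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
}

oracle_jaccard_matrix <- function(true_mods, pred_mods) {
  jm <- matrix(0, length(true_mods), length(pred_mods))
  for (i in seq_along(true_mods)) {
    for (j in seq_along(pred_mods)) {
      a <- true_mods[[i]]; b <- pred_mods[[j]]
      jm[i, j] <- length(intersect(a, b)) / length(union(a, b))
    }
  }
  jm
}

# textbook dense MCL, coded independently of the package's sparse version
oracle_mcl_partition <- function(adj, inflation, expansion = 2,
                                 max_iter = 100, tol = 1e-6, prune = 1e-5) {
  n <- nrow(adj)
  diag(adj) <- 1
  m <- sweep(adj, 2, colSums(adj), "/")
  for (it in seq_len(max_iter)) {
    prev <- m
    ex <- m
    for (e in seq_len(expansion - 1)) ex <- ex %*% m
    m <- ex^inflation
    m <- sweep(m, 2, colSums(m), "/")
    m[m < prune] <- 0
    m <- sweep(m, 2, colSums(m), "/")
    if (max(abs(m - prev)) < tol) break
  }
  assigned <- rep(NA_integer_, n)
  nid <- 0
  for (a in which(diag(m) > 0)) {
    mem <- which(m[a, ] > 0)
    hit <- unique(stats::na.omit(assigned[mem]))
    if (!length(hit)) {
      nid <- nid + 1
      assigned[mem] <- nid
    } else {
      tgt <- min(hit)
      assigned[mem] <- tgt
      assigned[assigned %in% hit] <- tgt
    }
  }
  assigned[is.na(assigned)] <- nid + seq_len(sum(is.na(assigned)))
  assigned
}

# canonical representation of a partition for set-wise comparison
partition_sets <- function(labels, ids) {
  unname(lapply(split(ids, labels), sort))
}

moduleset_sets <- function(ms) {
  unname(lapply(ms$modules, sort))
}

same_partition <- function(a, b) {
  key <- function(sets) sort(vapply(sets, paste, "", collapse = ","))
  identical(key(a), key(b))
}

# latent-factor expression fixture: `module_sizes` blocks of strongly
# correlated genes plus independent noise genes, shifted non-negative
planted_expression <- function(module_sizes, n_noise, n_cells,
                               loading = 0.9) {
  n_mod_genes <- sum(module_sizes)
  n <- n_mod_genes + n_noise
  vals <- matrix(stats::rnorm(n * n_cells), n, n_cells)
  row0 <- 0
  for (sz in module_sizes) {
    f <- stats::rnorm(n_cells)
    idx <- row0 + seq_len(sz)
    vals[idx, ] <- loading * matrix(f, sz, n_cells, byrow = TRUE) +
      sqrt(1 - loading^2) * vals[idx, ]
    row0 <- row0 + sz
  }
  vals <- vals - min(vals)  # global shift keeps correlations intact
  ids <- c(sprintf("mod%d_g%03d", rep(seq_along(module_sizes), module_sizes),
                   unlist(lapply(module_sizes, seq_len))),
           sprintf("noise_g%03d", seq_len(n_noise)))
  expression_matrix(vals, gene_ids = ids,
                    cell_ids = sprintf("c%03d", seq_len(n_cells)),
                    layer = "lognorm")
}

# tiny 10x triplet directory written by hand
write_toy_10x <- function(dir, entries, n_genes, n_cells, genes, barcodes) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  hdr <- c("%%MatrixMarket matrix coordinate integer general",
           sprintf("%d %d %d", n_genes, n_cells, nrow(entries)))
  body <- if (nrow(entries)) {
    sprintf("%d %d %d", entries[, 1], entries[, 2], entries[, 3])
  } else {
    character(0)
  }
  writeLines(c(hdr, body), file.path(dir, "matrix.mtx"))
  writeLines(genes, file.path(dir, "genes.tsv"))
  writeLines(barcodes, file.path(dir, "barcodes.tsv"))
  dir
}
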