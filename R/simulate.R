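#' Design of a synthetic single-cell benchmark dataset
#'
#' Describes a clustered scRNA-seq count matrix with planted differentially
#' expressed (DE) gene modules. The defaults reproduce the benchmark
#' configuration: 7204 genes by 1755 cells in five equally sized clusters,
#' four DE modules of 500, 300, 200 and 50 genes, each up-regulated in one
#' cluster with fold changes drawn uniformly between 4 and `fc_max`
#' (benchmarks sweep `fc_max` from 10 to 100).
#'
#' Counts come from a Gamma-Poisson (negative binomial) generator: per-gene
#' baseline means follow a log-normal law, per-cell library sizes follow a
#' log-normal law, and per-gene-per-cell Gamma noise (mean 1, shape
#' `dispersion`) supplies biological overdispersion. The log-normal and
#' Gamma defaults are chosen to give droplet-like sparsity (roughly 90%
#' zeros at a ~3000-UMI median library).
#'
#' @param n_genes,n_cells,n_clusters dataset dimensions.
#' @param cluster_proportions fractions summing to 1 (default uniform).
#' @param de_module_sizes integer vector of planted module sizes (may be
#'   empty for a null dataset).
#' @param fc_low,fc_max bounds of the uniform fold-change law,
#'   `fc_max >= fc_low >= 1`.
#' @param baseline_mean_log_params `(meanlog, sdlog)` of the gene baseline
#'   mean law.
#' @param dispersion Gamma shape of the per-entry noise (smaller = noisier).
#' @param libsize_log_params `(meanlog, sdlog)` of the library-size law.
#' @param seed integer seed.
#' @return an object of class `SimulationDesign`.
#' @export
simulation_design <- function(n_genes = 7204L, n_cells = 1755L,
                              n_clusters = 5L,
                              cluster_proportions = NULL,
                              de_module_sizes = c(500L, 300L, 200L, 50L),
                              fc_low = 4, fc_max = 100,
                              baseline_mean_log_params = c(0, 1.5),
                              dispersion = 2,
                              libsize_log_params = c(log(3000), 0.35),
                              seed = 123L) {
  n_genes <- as.integer(n_genes); n_cells <- as.integer(n_cells)
  n_clusters <- as.integer(n_clusters)
  de_module_sizes <- as.integer(de_module_sizes)
  if (is.null(cluster_proportions)) {
    cluster_proportions <- rep(1 / n_clusters, n_clusters)
  }
  if (length(cluster_proportions) != n_clusters ||
      abs(sum(cluster_proportions) - 1) > 1e-8) {
    stop("cluster_proportions must have length n_clusters and sum to 1")
  }
  if (sum(de_module_sizes) > n_genes) {
    stop("sum of de_module_sizes exceeds n_genes")
  }
  if (length(de_module_sizes) && any(de_module_sizes < 1L)) {
    stop("de_module_sizes must be positive")
  }
  if (fc_low < 1 || fc_max < fc_low) {
    stop("need fc_max >= fc_low >= 1")
  }
  if (dispersion <= 0) stop("dispersion must be positive")
  structure(list(n_genes = n_genes, n_cells = n_cells,
                 n_clusters = n_clusters,
                 cluster_proportions = cluster_proportions,
                 de_module_sizes = de_module_sizes,
                 fc_low = fc_low, fc_max = fc_max,
                 baseline_mean_log_params = baseline_mean_log_params,
                 dispersion = dispersion,
                 libsize_log_params = libsize_log_params,
                 seed = as.integer(seed)),
            class = "SimulationDesign")
}

#' Simulate a clustered count dataset with planted DE modules
#'
#' Draws gene baseline means and cell library sizes from log-normal laws,
#' assigns cells to clusters by the design proportions, assigns each DE
#' module to a distinct target cluster (round-robin), draws each DE gene's
#' fold change uniformly from `[fc_low, fc_max]` and applies it in the
#' target cluster only, then samples counts from a Gamma-Poisson law whose
#' expected column sum equals the cell's library size. Deterministic given
#' the design seed.
#'
#' @param design a `SimulationDesign`.
#' @return list with `matrix` (an `ExpressionMatrix`, raw counts) and
#'   `truth` (a `SyntheticTruth`: `cell_cluster` named integer vector,
#'   `de_gene_module` named integer vector, `de_fold_change` named numeric
#'   vector, `de_target_cluster` integer vector per module).
#' @export
simulate_dataset <- function(design = simulation_design()) {
  stopifnot(inherits(design, "SimulationDesign"))
  withr::with_seed(design$seed, {
    n_g <- design$n_genes
    n_c <- design$n_cells
    n_k <- design$n_clusters
    gene_ids <- sprintf("gene_%05d", seq_len(n_g))
    cell_ids <- sprintf("cell_%05d", seq_len(n_c))

    # cluster sizes by largest remainder, cells assigned in blocks
    raw_sizes <- design$cluster_proportions * n_c
    sizes <- floor(raw_sizes)
    rem <- n_c - sum(sizes)
    if (rem > 0) {
      top_up <- order(raw_sizes - sizes, decreasing = TRUE)[seq_len(rem)]
      sizes[top_up] <- sizes[top_up] + 1L
    }
    cell_cluster <- rep(seq_len(n_k), times = sizes)
    names(cell_cluster) <- cell_ids

    # planted DE structure
    n_de <- sum(design$de_module_sizes)
    de_idx <- if (n_de) sort(sample.int(n_g, n_de)) else integer(0)
    de_gene_module <- rep(seq_along(design$de_module_sizes),
                          times = design$de_module_sizes)
    names(de_gene_module) <- gene_ids[de_idx]
    de_target_cluster <- if (length(design$de_module_sizes)) {
      ((seq_along(design$de_module_sizes) - 1L) %% n_k) + 1L
    } else {
      integer(0)
    }
    de_fold_change <- stats::runif(n_de, design$fc_low, design$fc_max)
    names(de_fold_change) <- gene_ids[de_idx]

    # per-cluster relative expression profiles
    mu <- stats::rlnorm(n_g, design$baseline_mean_log_params[1],
                        design$baseline_mean_log_params[2])
    prof <- matrix(mu, nrow = n_g, ncol = n_k)
    if (n_de) {
      prof[cbind(rep(de_idx, 1L), de_target_cluster[de_gene_module])] <-
        mu[de_idx] * de_fold_change
    }
    prof <- sweep(prof, 2L, colSums(prof), "/")

    libsize <- stats::rlnorm(n_c, design$libsize_log_params[1],
                             design$libsize_log_params[2])

    # Gamma-Poisson counts with expected column sums equal to library size
    lambda <- prof[, cell_cluster, drop = FALSE] *
      rep(libsize, each = n_g) *
      matrix(stats::rgamma(n_g * n_c, shape = design$dispersion,
                           rate = design$dispersion), nrow = n_g)
    counts <- matrix(as.double(stats::rpois(n_g * n_c, lambda)), nrow = n_g)

    m <- expression_matrix(counts, gene_ids = gene_ids, cell_ids = cell_ids,
                           layer = "raw_counts")
    truth <- structure(list(cell_cluster = cell_cluster,
                            de_gene_module = de_gene_module,
                            de_fold_change = de_fold_change,
                            de_target_cluster = de_target_cluster),
                       class = "SyntheticTruth")
    list(matrix = m, truth = truth)
  })
}

#' @export
print.SyntheticTruth <- function(x, ...) {
  cat(sprintf(
    "SyntheticTruth: %d cells in %d clusters; %d DE genes in %d modules\n",
    length(x$cell_cluster), length(unique(x$cell_cluster)),
    length(x$de_gene_module),
    length(unique(x$de_gene_module))))
  invisible(x)
}

#' True DE modules as gene-set list
#'
#' @param truth a `SyntheticTruth`.
#' @return list of character vectors, one per planted module.
#' @export
truth_modules <- function(truth) {
  stopifnot(inherits(truth, "SyntheticTruth"))
  if (!length(truth$de_gene_module)) return(list())
  unname(split(names(truth$de_gene_module), truth$de_gene_module))
}

#' Simulate a grid of benchmark datasets
#'
#' One dataset per `(fc_max, replicate)` pair, with seeds derived
#' deterministically from the base design seed so no two grid cells share a
#' seed. The benchmark sweep uses `fc_max` from 10 to 100 in steps of 10
#' with 10 replicates each (100 datasets).
#'
#' @param base a `SimulationDesign` providing all non-`fc_max` settings.
#' @param fc_max_values numeric vector of maximal fold changes.
#' @param replicates replicates per `fc_max` (>= 1).
#' @return list of descriptors, each with `fc_max`, `replicate`, `seed` and
#'   `design` (call [simulate_dataset()] on the design to materialize).
#' @export
simulate_grid <- function(base = simulation_design(),
                          fc_max_values = seq(10, 100, by = 10),
                          replicates = 10L) {
  stopifnot(inherits(base, "SimulationDesign"))
  replicates <- as.integer(replicates)
  if (replicates < 1L) stop("replicates must be >= 1")
  out <- list()
  idx <- 0L
  for (fi in seq_along(fc_max_values)) {
    for (r in seq_len(replicates)) {
      idx <- idx + 1L
      seed <- (base$seed + 104729L * idx) %% 2147483647L
      design <- base
      design$fc_max <- fc_max_values[fi]
      design$seed <- as.integer(seed)
      out[[idx]] <- list(fc_max = fc_max_values[fi], replicate = r,
                         seed = design$seed, design = design)
    }
  }
  out
}

#' Write a simulated dataset as a 10x-style MTX directory plus truth tables
#'
#' Writes `matrix.mtx`, `features.tsv`, `barcodes.tsv`, a `truth_genes.tsv`
#' (gene, module_index, fold_change, target_cluster) and a
#' `truth_cells.tsv` (cell, cluster).
#'
#' @param sim output of [simulate_dataset()].
#' @param directory_path output directory (created if needed).
#' @export
write_simulation <- function(sim, directory_path) {
  dir.create(directory_path, recursive = TRUE, showWarnings = FALSE)
  m <- sim$matrix
  Matrix::writeMM(methods::as(m$values, "CsparseMatrix"),
                  file.path(directory_path, "matrix.mtx"))
  writeLines(m$gene_ids, file.path(directory_path, "features.tsv"))
  writeLines(m$cell_ids, file.path(directory_path, "barcodes.tsv"))
  tr <- sim$truth
  gene_df <- data.frame(
    gene = names(tr$de_gene_module),
    module_index = unname(tr$de_gene_module),
    fold_change = unname(tr$de_fold_change[names(tr$de_gene_module)]),
    target_cluster = tr$de_target_cluster[tr$de_gene_module],
    stringsAsFactors = FALSE)
  utils::write.table(gene_df, file.path(directory_path, "truth_genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cell_df <- data.frame(cell = names(tr$cell_cluster),
                        cluster = unname(tr$cell_cluster),
                        stringsAsFactors = FALSE)
  utils::write.table(cell_df, file.path(directory_path, "truth_cells.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(directory_path)
}
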