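toy_distance <- function() {
  vals <- matrix(0, 3, 3, dimnames = list(c("g1", "g2", "g3"),
                                          c("g1", "g2", "g3")))
  vals["g1", "g2"] <- vals["g2", "g1"] <- 0.1
  vals["g1", "g3"] <- vals["g3", "g1"] <- 0.5
  vals["g2", "g3"] <- vals["g3", "g2"] <- 0.9
  as_distance(vals)
}

test_that("compute_dknn reads off the Kth nearest distance", {
  d <- toy_distance()
  expect_equal(unname(compute_dknn(d, 1)), c(0.1, 0.1, 0.5))
  expect_equal(unname(compute_dknn(d, 2)), c(0.5, 0.9, 0.9))
  expect_error(compute_dknn(d, 3), "K must satisfy")
  expect_error(compute_dknn(d, 0), "K must satisfy")
})

test_that("compute_dknn matches a full-sort oracle on random matrices", {
  set.seed(31)
  for (rep in 1:20) {
    n <- sample(10:50, 1)
    K <- sample.int(n - 1, 1)
    vals <- random_distance_matrix(n)
    expect_equal(unname(compute_dknn(as_distance(vals), K)),
                 oracle_dknn(vals, K))
  }
})

test_that("pooled-distance null sampling follows its declared scheme", {
  # constant distances: every simulated DKNN equals the constant
  vals <- matrix(0.42, 5, 5)
  diag(vals) <- 0
  dimnames(vals) <- list(paste0("g", 1:5), paste0("g", 1:5))
  d <- as_distance(vals)
  obs <- compute_dknn(d, 2)
  p <- selection_params(k_neighbors = 2, n_simulations = 100, seed = 1,
                        null_method = "pool_distances")
  expect_identical(unique(simulate_null_dknn(d, obs, p)), 0.42)

  # duplicate-implementation oracle with the identical seeded scheme
  set.seed(32)
  vals <- random_distance_matrix(30)
  d <- as_distance(vals)
  obs <- compute_dknn(d, 4)
  p <- selection_params(k_neighbors = 4, noise_level = 0.1,
                        n_simulations = 250, seed = 77,
                        null_method = "pool_distances")
  got <- simulate_null_dknn(d, obs, p)
  cutoff <- stats::quantile(obs, 0.1, names = FALSE)
  pool_rows <- which(obs >= cutoff)
  # pool in column-major order over the pool rows, diagonals excluded
  pool_vals <- numeric(0)
  for (j in seq_len(30)) {
    for (i in pool_rows) {
      if (i != j) pool_vals <- c(pool_vals, vals[i, j])
    }
  }
  exp_vals <- withr::with_seed(77, {
    vapply(1:250, function(s) {
      sort(sample(pool_vals, 29))[4]
    }, 0)
  })
  expect_equal(mean(got), mean(exp_vals), tolerance = 1e-12)
  expect_equal(got, unname(exp_vals), tolerance = 1e-12)
})

test_that("noise_level 0 pools every off-diagonal distance", {
  set.seed(33)
  vals <- random_distance_matrix(12)
  d <- as_distance(vals)
  obs <- compute_dknn(d, 2)
  p <- selection_params(k_neighbors = 2, noise_level = 0,
                        n_simulations = 400, seed = 5,
                        null_method = "pool_distances")
  got <- sort(unique(simulate_null_dknn(d, obs, p)))
  all_offdiag <- sort(unique(vals[row(vals) != col(vals)]))
  expect_true(all(got %in% all_offdiag))
  # a high noise_level restricts the pool to the highest-DKNN rows
  p_hi <- selection_params(k_neighbors = 2, noise_level = 0.9,
                           n_simulations = 100, seed = 5,
                           null_method = "pool_distances")
  top_row <- which(obs >= stats::quantile(obs, 0.9, names = FALSE))
  allowed <- unique(unlist(lapply(top_row, function(i) vals[i, -i])))
  expect_true(all(simulate_null_dknn(d, obs, p_hi) %in% allowed))
})

test_that("permutation null matches a duplicate implementation", {
  set.seed(34)
  m <- planted_expression(integer(0), n_noise = 25, n_cells = 15)
  d <- gene_distance_matrix(m, "pearson")
  obs <- compute_dknn(d, 3)
  p <- selection_params(k_neighbors = 3, n_simulations = 200, seed = 9)
  got <- simulate_null_dknn_perm(m, obs, p)

  x <- em_values(m)
  expected <- withr::with_seed(9, {
    probes <- sample.int(25, 200, replace = TRUE)
    perms <- lapply(1:200, function(i) sample.int(15))
    vapply(1:200, function(i) {
      pv <- x[probes[i], perms[[i]]]
      dd <- vapply(seq_len(25), function(j) {
        1 - stats::cor(pv, x[j, ])
      }, 0)
      sort(dd[-probes[i]])[3]
    }, 0)
  })
  expect_equal(got, expected, tolerance = 1e-10)
})

test_that("FDR threshold scan matches hand-checked candidates", {
  # null mass entirely above observations: threshold at max(observed)
  r1 <- estimate_fdr_threshold(c(0.1, 0.2, 0.3), c(0.5, 0.6, 0.7, 0.8), 0.05)
  expect_equal(r1$threshold, 0.3)
  expect_equal(r1$fdr_at_threshold, 0)

  # identical samples: FDR is 1 everywhere, no threshold
  x <- c(0.1, 0.4, 0.5, 0.9)
  r2 <- estimate_fdr_threshold(x, x, 0.05)
  expect_true(is.na(r2$threshold))
  expect_equal(r2$fdr_at_threshold, 1.0)

  # exhaustive scan over four candidates
  r3 <- estimate_fdr_threshold(c(0.1, 0.2, 0.9, 0.95),
                               c(0.9, 0.92, 0.94, 0.96), 0.25)
  expect_equal(r3$threshold, 0.2)
  expect_equal(r3$fdr_at_threshold, 0)

  expect_error(estimate_fdr_threshold(1:3, 1:3, 0), "alpha")
  expect_error(estimate_fdr_threshold(1:3, 1:3, 1), "alpha")
})

test_that("select_genes recovers a planted module and rejects noise", {
  withr::with_seed(41, {
    m <- planted_expression(40, n_noise = 400, n_cells = 120)
  })
  p <- selection_params(k_neighbors = 10, fdr_target = 1e-3,
                        row_sum = 0, seed = 41)
  res <- select_genes(m, p)
  mod_genes <- grep("^mod", m$gene_ids, value = TRUE)
  expect_setequal(intersect(res$selected_genes, mod_genes), mod_genes)
  noise_selected <- setdiff(res$selected_genes, mod_genes)
  expect_lte(length(noise_selected), 0.05 * 400)
})

test_that("selection is monotone in the FDR target", {
  withr::with_seed(42, {
    m <- planted_expression(20, n_noise = 100, n_cells = 60)
  })
  sels <- lapply(c(1e-4, 1e-2, 0.2), function(a) {
    select_genes(m, selection_params(k_neighbors = 5, fdr_target = a,
                                     row_sum = 0, seed = 7))$selected_genes
  })
  expect_true(all(sels[[1]] %in% sels[[2]]))
  expect_true(all(sels[[2]] %in% sels[[3]]))
})

test_that("a duplicated gene row gets DKNN zero and is selected", {
  withr::with_seed(43, {
    m <- planted_expression(15, n_noise = 60, n_cells = 50)
  })
  v <- em_values(m)
  v <- rbind(v, v["mod1_g001", ] )
  m2 <- expression_matrix(v, c(m$gene_ids, "dup_gene"), m$cell_ids,
                          layer = "lognorm")
  res <- select_genes(m2, selection_params(k_neighbors = 1, fdr_target = 0.05,
                                           row_sum = 0, seed = 3))
  expect_equal(unname(res$observed_dknn[c("mod1_g001", "dup_gene")]),
               c(0, 0), tolerance = 1e-10)
  if (!is.na(res$threshold) && res$threshold > 0) {
    expect_true(all(c("mod1_g001", "dup_gene") %in% res$selected_genes))
  }
})

test_that("row_sum removes exactly the weakly expressed genes", {
  set.seed(44)
  counts <- matrix(stats::rpois(40 * 30, 3), 40, 30)
  counts[1:5, ] <- 0
  counts[1:5, 1:4] <- 1  # exactly 4 expressing cells
  counts[6:10, ] <- 0
  counts[6:10, 1:6] <- 1  # exactly 6 expressing cells
  m <- expression_matrix(counts, sprintf("g%02d", 1:40),
                         sprintf("c%02d", 1:30))
  res <- select_genes(lognormalize(m),
                      selection_params(k_neighbors = 5, row_sum = 5,
                                       n_simulations = 100, seed = 2))
  expect_false(any(sprintf("g%02d", 1:5) %in% res$gene_ids))
  expect_true(all(sprintf("g%02d", 6:10) %in% res$gene_ids))
})

test_that("selection is byte-identical under one seed", {
  withr::with_seed(45, {
    m <- planted_expression(10, n_noise = 80, n_cells = 40)
  })
  p <- selection_params(k_neighbors = 4, seed = 19)
  r1 <- select_genes(m, p)
  r2 <- select_genes(m, p)
  expect_identical(r1, r2)
})

test_that("selected genes are exactly those with DKNN below threshold", {
  withr::with_seed(46, {
    m <- planted_expression(25, n_noise = 90, n_cells = 60)
  })
  res <- select_genes(m, selection_params(k_neighbors = 8, fdr_target = 0.01,
                                          row_sum = 0, seed = 8))
  if (!is.na(res$threshold)) {
    expect_identical(res$selected_genes,
                     res$gene_ids[res$observed_dknn < res$threshold])
  }
  expect_length(res$simulated_dknn, length(res$gene_ids))
})
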