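random_modules_and_matrix <- function(n_genes = 120, n_cells = 25,
                                      sizes = c(12, 10, 9, 5)) {
  ids <- sprintf("g%03d", seq_len(n_genes))
  counts <- matrix(stats::rpois(n_genes * n_cells, 1.2), n_genes, n_cells)
  m <- expression_matrix(counts, ids, sprintf("c%02d", seq_len(n_cells)))
  picked <- split(sample(ids, sum(sizes)), rep(seq_along(sizes), sizes))
  list(ms = module_set(unname(picked)), m = m)
}

test_that("size filter keeps modules at or above the threshold", {
  ms <- module_set(list(sprintf("a%02d", 1:12), sprintf("b%02d", 1:10),
                        sprintf("c%02d", 1:9)))
  kept <- filter_cluster_size(ms, 10)
  expect_identical(unname(vapply(kept$modules, length, 0L)), c(12L, 10L))
  # min_size 1 is the identity on contents
  expect_identical(filter_cluster_size(ms, 1)$modules, ms$modules)
  # random module sets match a plain size scan
  set.seed(61)
  for (rep in 1:10) {
    fx <- random_modules_and_matrix(sizes = sample(3:15, 5))
    thr <- sample(3:12, 1)
    kept <- filter_cluster_size(fx$ms, thr)
    manual <- fx$ms$modules[vapply(fx$ms$modules, length, 0L) >= thr]
    expect_true(same_partition(moduleset_sets(kept),
                               unname(lapply(manual, sort))))
  }
})

test_that("supporting-cells filter counts expressing cells per module", {
  # 10-gene module; 5 cells express exactly 2 of its genes (fraction 0.2)
  genes <- sprintf("g%02d", 1:10)
  counts <- matrix(0L, 10, 6)
  counts[1:2, 1:5] <- 1L
  m <- expression_matrix(counts, genes, sprintf("c%d", 1:6))
  ms <- module_set(list(genes))
  expect_length(filter_nb_supporting_cells(ms, m, 5, 0.2)$modules, 1L)
  expect_length(filter_nb_supporting_cells(ms, m, 5, 0.35)$modules, 0L)
  # strict comparison drops cells sitting exactly at the fraction
  expect_length(filter_nb_supporting_cells(ms, m, 5, 0.2,
                                           strict = TRUE)$modules, 0L)
  # trivial thresholds keep everything
  expect_length(filter_nb_supporting_cells(ms, m, 0, 0)$modules, 1L)
  expect_error(filter_nb_supporting_cells(module_set(list("absent")), m),
               "absent")
})

test_that("supporting-cells filter matches a brute-force double loop", {
  set.seed(62)
  for (rep in 1:10) {
    fx <- random_modules_and_matrix()
    v <- em_values(fx$m)
    min_cells <- sample(0:6, 1)
    min_frac <- stats::runif(1, 0, 0.6)
    keep <- vapply(fx$ms$modules, function(genes) {
      supp <- 0
      for (cell in seq_len(ncol(v))) {
        frac <- sum(v[genes, cell] > 0) / length(genes)
        if (frac >= min_frac) supp <- supp + 1
      }
      supp >= min_cells
    }, NA)
    got <- filter_nb_supporting_cells(fx$ms, fx$m, min_cells, min_frac)
    expect_true(same_partition(moduleset_sets(got),
                               unname(lapply(fx$ms$modules[keep], sort))))
  }
})

test_that("sd filter uses the mean per-gene standard deviation", {
  counts <- rbind(matrix(2L, 3, 8),                       # flat genes
                  matrix(stats::rpois(24, 5), 3, 8))
  m <- expression_matrix(counts, sprintf("g%d", 1:6), sprintf("c%d", 1:8),
                         layer = "lognorm")
  flat <- module_set(list(sprintf("g%d", 1:3)))
  expect_length(filter_module_sd(flat, m, 0.1)$modules, 0L)
  expect_identical(filter_module_sd(flat, m, 0)$modules, flat$modules)
  # statistic equals mean of per-gene sds
  varying <- module_set(list(sprintf("g%d", 4:6)))
  stat <- mean(apply(em_values(m)[4:6, ], 1, stats::sd))
  expect_length(filter_module_sd(varying, m, stat + 1e-9)$modules, 0L)
  expect_length(filter_module_sd(varying, m, stat - 1e-9)$modules, 1L)
})

test_that("filters are idempotent and commute on survival", {
  set.seed(63)
  fx <- random_modules_and_matrix()
  f1 <- function(x) filter_cluster_size(x, 8)
  f2 <- function(x) filter_nb_supporting_cells(x, fx$m, 3, 0.3)
  a <- f2(f1(fx$ms))
  b <- f1(f2(fx$ms))
  expect_true(same_partition(moduleset_sets(a), moduleset_sets(b)))
  expect_true(same_partition(moduleset_sets(f1(f1(fx$ms))),
                             moduleset_sets(f1(fx$ms))))
  expect_true(same_partition(moduleset_sets(f2(f2(fx$ms))),
                             moduleset_sets(f2(fx$ms))))
})

test_that("top_genes ranks by mean intra-module correlation", {
  set.seed(64)
  f <- stats::rnorm(30)
  vals <- rbind(f + 0.1 * stats::rnorm(30),
                f + 0.1 * stats::rnorm(30),
                f + 0.1 * stats::rnorm(30),
                -f + 0.1 * stats::rnorm(30))   # anti-correlated straggler
  vals <- vals - min(vals)
  m <- expression_matrix(vals, c("g1", "g2", "g3", "g4"),
                         sprintf("c%02d", 1:30), layer = "lognorm")
  ms <- module_set(list(c("g1", "g2", "g3", "g4")))
  ranked <- top_genes(ms, m, n = 4)$M01
  expect_identical(ranked[4], "g4")
  # asking for more genes than the module holds returns them all
  expect_length(top_genes(ms, m, n = 10)$M01, 4L)

  # brute-force mean-of-row-correlations oracle
  cc <- stats::cor(t(vals))
  score <- vapply(1:4, function(i) mean(cc[i, -i]), 0)
  expect_identical(ranked, c("g1", "g2", "g3", "g4")[order(-score)])
})

test_that("activity scores hit the closed endpoints", {
  # cell 1 expresses exactly the module genes highest; cell 2 none of them
  vals <- cbind(c(9, 8, 7, rep(1, 9)), c(0, 0, 0, rep(5, 9)))
  ids <- sprintf("g%02d", 1:12)
  m <- expression_matrix(vals, ids, c("hit", "miss"), layer = "lognorm")
  ms <- module_set(list(ids[1:3]))
  sc <- module_activity_scores(ms, m, top_fraction = 0.5)
  expect_equal(sc["M01", "hit"], 1.0)
  expect_equal(sc["M01", "miss"], 0.0)
})

test_that("activity scores equal a step-curve enumeration oracle", {
  set.seed(65)
  vals <- matrix(stats::rexp(12 * 7), 12, 7)
  ids <- sprintf("g%02d", 1:12)
  m <- expression_matrix(vals, ids, sprintf("c%d", 1:7), layer = "lognorm")
  first <- sample(ids, 4)
  ms <- module_set(list(first, sample(setdiff(ids, first), 3)))
  top_fraction <- 0.4
  sc <- module_activity_scores(ms, m, top_fraction)
  n_top <- ceiling(top_fraction * 12)
  for (cell in 1:7) {
    ord <- ids[order(-vals[, cell], ids)]
    for (mod in names(ms$modules)) {
      genes <- ms$modules[[mod]]
      hits <- cumsum(ord %in% genes)[seq_len(n_top)]
      best <- cumsum(rep(1, 12))[seq_len(n_top)]
      best <- pmin(best, length(genes))
      expect_equal(sc[mod, cell], sum(hits) / sum(best), tolerance = 1e-12)
    }
  }
})

test_that("duplicating a cell duplicates its score column", {
  set.seed(66)
  vals <- matrix(stats::rexp(60), 12, 5)
  ids <- sprintf("g%02d", 1:12)
  m <- expression_matrix(cbind(vals, vals[, 2]), ids,
                         c(sprintf("c%d", 1:5), "c2_copy"),
                         layer = "lognorm")
  ms <- module_set(list(ids[1:4], ids[5:7]))
  sc <- module_activity_scores(ms, m, 0.3)
  expect_identical(sc[, "c2"], sc[, "c2_copy"])
  expect_true(all(sc >= 0 & sc <= 1))
})
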