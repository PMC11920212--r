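test_that("wilcoxon p-values match exact enumeration for small groups", {
  set.seed(3)
  for (i in 1:15) {
    n1 <- sample(3:8, 1); n2 <- sample(3:8, 1)
    x <- sample(0:5, n1, replace = TRUE)   # ties on purpose
    y <- sample(0:5, n2, replace = TRUE)
    expect_equal(wilcox_rank_sum(x, y)$p_value, oracle_wilcox_p(x, y),
                 tolerance = 1e-12)
  }
  # large-sample route against the reference implementation
  set.seed(4)
  x <- rnorm(40); y <- rnorm(35, 0.5)
  expect_equal(wilcox_rank_sum(x, y)$p_value,
               stats::wilcox.test(x, y, exact = FALSE)$p.value,
               tolerance = 1e-10)
})

test_that("qc keeps cells inside the detected-genes band and mito limit", {
  counts <- Matrix::Matrix(matrix(rpois(50 * 20, 3), 50, 20), sparse = TRUE)
  rownames(counts) <- c(paste0("mt-", 1:5), paste0("g", 1:45))
  colnames(counts) <- paste0("c", 1:20)
  # cell 1: 15% mito reads
  counts[1:5, 1] <- 30
  kept <- qc_filter(counts, mito_genes = paste0("mt-", 1:5))
  expect_false(1 %in% kept)
  # identical cells: degenerate SD keeps everyone under the mito rule
  same <- Matrix::Matrix(matrix(rep(c(1, 2, 0), 20), 3, 20), sparse = TRUE)
  rownames(same) <- paste0("g", 1:3)
  expect_equal(qc_filter(same), 1:20)
})

test_that("log-normalization is depth-invariant and matches the formula", {
  m <- Matrix::Matrix(matrix(c(5, 0, 3, 2, 8, 1, 0, 4, 2, 7, 1, 3,
                               2, 2, 0, 6, 1, 0, 9, 2), 5, 4), sparse = TRUE)
  dimnames(m) <- list(paste0("g", 1:5), paste0("c", 1:4))
  norm <- normalize_log1p(m, scale = 1e4)
  direct <- log1p(t(t(as.matrix(m)) / colSums(as.matrix(m))) * 1e4)
  expect_equal(as.matrix(norm), direct, tolerance = 1e-12)
  # doubling a cell's counts changes nothing
  m2 <- m; m2[, 2] <- m[, 2] * 2
  expect_equal(as.matrix(normalize_log1p(m2, 1e4))[, 2],
               as.matrix(norm)[, 2], tolerance = 1e-12)
  # single-gene cell
  solo <- m; solo[, 3] <- 0; solo[2, 3] <- 7
  ns <- normalize_log1p(solo, 1e4)
  expect_equal(as.matrix(ns)[2, 3], log1p(1e4))
  expect_equal(sum(as.matrix(ns)[-2, 3]), 0)
  # zero-total cell errors with the barcode
  z <- m; z[, 4] <- 0
  expect_error(normalize_log1p(z), "c4")
})

test_that("module scores respond to planted elevation and reject bad sets", {
  set.seed(8)
  m <- matrix(rpois(100 * 30, 4), 100, 30)
  rownames(m) <- paste0("g", 1:100)
  colnames(m) <- paste0("c", 1:30)
  norm <- normalize_log1p(Matrix::Matrix(m, sparse = TRUE))
  # constant matrix gives score 0
  const <- Matrix::Matrix(matrix(2, 40, 10,
                                 dimnames = list(paste0("g", 1:40), NULL)),
                          sparse = TRUE)
  expect_equal(score_module(const, paste0("g", 1:5), seed = 1),
               rep(0, 10), tolerance = 1e-12)
  # doubling the set genes in one cell raises only that cell's score
  set_genes <- paste0("g", 1:10)
  m2 <- norm
  m2[set_genes, 7] <- m2[set_genes, 7] * 2
  sc <- score_module(m2, set_genes, seed = 1)
  expect_gt(sc[7], max(sc[-7]))
  expect_error(score_module(norm, character(0)), "empty")
  expect_error(score_module(norm, c("nope1", "nope2")), "present")
})

test_that("phase assignment follows the score argmax with G1 fallback", {
  expect_equal(assign_phase(0.5, 0.1), "S")
  expect_equal(assign_phase(-0.2, -0.1), "G1")
  expect_equal(assign_phase(0.1, 0.4), "G2M")
  expect_equal(assign_phase(c(0.5, -1), c(0.1, -2)), c("S", "G1"))
})

test_that("regression residuals are orthogonal to covariates", {
  set.seed(9)
  n <- 50
  cov <- data.frame(s = rnorm(n), g2m = rnorm(n))
  m <- matrix(rnorm(20 * n), 20, n)
  m[1, ] <- 3 * cov$s - 2 * cov$g2m + 5      # exactly linear
  res <- regress_out(m, cov)
  expect_equal(max(abs(res[1, ])), 0, tolerance = 1e-10)
  for (j in 1:2)
    expect_true(all(abs(apply(res, 1, function(r)
      sum(r * (cov[[j]] - mean(cov[[j]]))))) < 1e-8))
  # closed-form normal equations oracle on a small case
  X <- cbind(1, as.matrix(cov))
  beta <- solve(t(X) %*% X, t(X) %*% t(m))
  expect_equal(res, m - t(X %*% beta), tolerance = 1e-10)
  expect_error(regress_out(m, data.frame(a = cov$s, b = cov$s)), "collinear")
})

test_that("hvg selection ranks a planted high-dispersion gene first", {
  set.seed(10)
  n <- 200
  lam <- runif(100, 1, 10)
  m <- matrix(rpois(100 * n, lam), 100, n)
  m[7, ] <- rnbinom(n, mu = 5, size = 0.1)   # mid-range mean, huge dispersion
  m[8, ] <- 4                                 # constant
  rownames(m) <- paste0("g", 1:100)
  hv <- select_hvg(Matrix::Matrix(m, sparse = TRUE), n = 10)
  expect_equal(hv[1], "g7")
  expect_false("g8" %in% select_hvg(m, n = 99))
  expect_equal(sort(select_hvg(m, n = 1000)),
               sort(rownames(m)[apply(m, 1, var) > 0]))
})

test_that("clustering recovers planted states and is seed-stable", {
  fx <- fixture_sim(n_genotypes = 4, n_cells = 60, n_states = 3,
                    marker_effect = 8, markers_per_state = 15)
  norm <- normalize_log1p(fx$sim$counts)
  hv <- select_hvg(norm, 120)
  lab1 <- cluster_states(norm, hv, dims = 10, seed = 1)
  expect_equal(length(unique(lab1)), 3L)
  expect_gte(oracle_ari(lab1, fx$sim$cell_meta$state), 0.95)
  lab2 <- cluster_states(norm, hv, dims = 10, seed = 99)
  expect_equal(oracle_ari(lab1, lab2), 1)
  # all-identical cells collapse to one cluster
  flat <- Matrix::Matrix(matrix(1, 30, 25,
                                dimnames = list(paste0("g", 1:30), NULL)),
                         sparse = TRUE)
  expect_equal(unique(cluster_states(flat, dims = 5)), 1L)
  expect_error(cluster_states(norm[1:8, 1:6], dims = 10), "dims")
})

test_that("marker discovery finds planted markers and controls the null", {
  fx <- fixture_sim(n_genotypes = 4, n_cells = 50, n_states = 3,
                    marker_effect = 6)
  sim <- fx$sim
  norm <- normalize_log1p(sim$counts)
  mk <- find_markers(norm, sim$cell_meta$state)
  planted <- sim$gene_meta$gene[!is.na(sim$gene_meta$marker_state) &
                                  sim$gene_meta$marker_state == 1]
  top <- mk[mk$state == 1 & mk$significant, ]
  expect_gte(mean(planted %in% top$gene), 0.8)
  # permuted labels: few significant calls
  set.seed(12)
  perm <- find_markers(norm, sample(sim$cell_meta$state))
  expect_lte(mean(perm$p < 0.05), 0.07)
  # constant gene has p = 1
  cst <- rbind(norm[1:20, ], constant = 1)
  mk2 <- find_markers(cst, sim$cell_meta$state)
  expect_true(all(mk2$p[mk2$gene == "constant"] == 1))
})

test_that("independent filtering chooses the recount-verified argmax", {
  set.seed(13)
  n_a <- 30; n_b <- 30
  high_de <- matrix(rpois(50 * (n_a + n_b), 20), 50)
  high_de[, seq_len(n_a)] <- matrix(rpois(50 * n_a, 45), 50)
  null_low <- matrix(rpois(500 * (n_a + n_b), 0.3), 500)
  m <- rbind(high_de, null_low)
  rownames(m) <- paste0("g", seq_len(nrow(m)))
  res <- de_independent_filtering(m[, seq_len(n_a)],
                                  m[, n_a + seq_len(n_b)])
  expect_gt(res$chosen_filter_threshold, 0)
  n_sig_at_zero <- res$scan$n_significant[1]
  expect_gte(res$n_significant, n_sig_at_zero)
  # exhaustive recount over the grid
  recount <- vapply(res$scan$threshold, function(t) {
    keep <- res$table$mean_count >= t
    sum(stats::p.adjust(res$table$p[keep], "BH") < 0.05)
  }, integer(1))
  expect_equal(res$scan$n_significant, recount)
  expect_equal(res$chosen_filter_threshold,
               res$scan$threshold[which.max(recount)])
  expect_equal(res$n_significant, max(recount))
  # identical groups: nothing significant
  set.seed(14)
  same <- matrix(rpois(100 * 40, 5), 100)
  r0 <- de_independent_filtering(same[, 1:20], same[, 21:40])
  expect_equal(r0$n_significant, 0L)
  # a one-point grid is chosen trivially
  r1 <- de_independent_filtering(m[, 1:n_a], m[, n_a + 1:n_b], grid = 2)
  expect_equal(r1$chosen_filter_threshold, 2)
})

test_that("DE counting applies the fold-change and p thresholds", {
  tab <- data.frame(log2fc = c(1.2, -0.9, -1.5), p = c(0.01, 0.001, 0.2))
  expect_equal(count_de(tab), c(n_up = 1L, n_down = 0L))
  expect_equal(count_de(tab[2, ]), c(n_up = 0L, n_down = 0L))
  expect_equal(count_de(tab[0, ]), c(n_up = 0L, n_down = 0L))
})

test_that("clone-level DE respects size filters, nulls and planted effects", {
  set.seed(15)
  n <- 230
  m <- matrix(rpois(60 * n, 5), 60, n)
  rownames(m) <- paste0("g", 1:60)
  genotypes <- rep("gA", n)
  clones <- rep(c("c1", "c2", "c3"), length.out = n)
  norm <- normalize_log1p(Matrix::Matrix(m, sparse = TRUE))
  # small genotype excluded entirely
  small <- clone_de(norm[, 1:150], genotypes[1:150], clones[1:150])
  expect_equal(nrow(small), 0L)
  res <- clone_de(norm, genotypes, clones)
  expect_gt(nrow(res), 0)
  expect_true(all(res$n_deg / 60 <= 0.05 + 2 * sqrt(0.05 * 0.95 / 60)))
  # planted clone effect: one gene x4 in clone c1
  m2 <- m
  m2[5, clones == "c1"] <- m2[5, clones == "c1"] * 4
  res2 <- clone_de(normalize_log1p(Matrix::Matrix(m2, sparse = TRUE)),
                   genotypes, clones)
  expect_gte(res2$n_deg[res2$clone == "c1"], 1)
})

test_that("rank signature scores follow the U-statistic formula", {
  set.seed(16)
  m <- matrix(rexp(30 * 8), 30, 8)
  rownames(m) <- paste0("g", 1:30)
  sset <- paste0("g", c(2, 9, 17, 21, 28))
  sc <- score_signature_rank(m, sset, r_max = 20)
  direct <- apply(m, 2, function(v) {
    r <- rank(-v); r[r > 20] <- 21
    u <- sum(r[match(sset, rownames(m))]) - 5 * 6 / 2
    max(0, 1 - u / (5 * 20))
  })
  expect_equal(unname(sc), unname(direct), tolerance = 1e-12)
  # set genes occupying the top ranks score 1
  top <- matrix(0, 30, 2, dimnames = list(paste0("g", 1:30), NULL))
  top[match(sset, rownames(top)), ] <- 5:1
  expect_equal(unname(score_signature_rank(top, sset, r_max = 20)), c(1, 1))
  # set genes beyond r_max score ~0 (the clipped-rank formula floor)
  low <- matrix(10, 30, 1, dimnames = list(paste0("g", 1:30), NULL))
  low[match(sset, rownames(low)), ] <- 0
  expect_lt(score_signature_rank(low, sset, r_max = 10)[1], 5 / (2 * 10) + 1e-9)
  expect_error(score_signature_rank(m, "absent"), "no genes")
})
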