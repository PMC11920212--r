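test_that("generated libraries satisfy their invariants and are deterministic", {
  lib <- gen_library(2, clones_per_genotype = 2, min_hamming = 5, seed = 1)
  expect_equal(nrow(lib), 2L)
  expect_true(all(nchar(lib$genotype_barcode) == 20L))
  expect_true(all(vapply(lib$clone_barcodes, function(x)
    all(nchar(x) == 5L) && length(x) == 2L, logical(1))))
  d <- sum(strsplit(lib$genotype_barcode[1], "")[[1]] !=
           strsplit(lib$genotype_barcode[2], "")[[1]])
  expect_gte(d, 5L)
  expect_false(anyDuplicated(lib$genotype_id) > 0)
  expect_true(all(nchar(lib$contig_seq) == 85L))
  expect_identical(lib, gen_library(2, clones_per_genotype = 2,
                                    min_hamming = 5, seed = 1))
  lib2 <- gen_library(2, seed = 2)
  expect_false(identical(lib$genotype_barcode, lib2$genotype_barcode))
})

test_that("unattainable barcode distances raise an explicit error", {
  expect_error(gen_library(3, min_hamming = 21), "unattainable")
})

test_that("knockout silencing is recoverable from simulated counts", {
  fx <- fixture_sim(n_genotypes = 6, n_cells = 60)
  sim <- fx$sim
  wt <- sim$cell_meta$genotype == "WT"
  checked <- 0L
  for (g in paste0("g00", 1:6)) {
    target <- fx$lib$target_gene[fx$lib$genotype_id == g]
    m_wt <- mean(sim$counts[target, wt])
    if (m_wt < 0.5) next   # too lowly expressed to resolve a 2% residual
    m_in <- mean(sim$counts[target, sim$cell_meta$genotype == g])
    expect_lt(m_in, 0.05 * m_wt)
    checked <- checked + 1L
  }
  expect_gte(checked, 2L)
})

test_that("attractor genotypes reach their target state share", {
  lib <- gen_library(3, seed = 4, include_wt = TRUE)
  cfg <- sim_config(n_genotypes = 3, n_cells_per_genotype = 1000,
                    attractors = "g001", pi_target = 0.6, seed = 5)
  sim <- gen_counts(lib, cfg)
  share <- mean(sim$cell_meta$state[sim$cell_meta$genotype == "g001"] ==
                  cfg$attractor_state)
  expect_gt(share, 0.55)
  expect_lt(share, 0.65)
})

test_that("counts follow the gamma-Poisson law when all effects are off", {
  lib <- gen_library(2, seed = 1, include_wt = TRUE)
  cfg <- sim_config(n_genotypes = 2, n_cells_per_genotype = 500,
                    n_states = 1, marker_effect = 1, size_factor_sd = 0,
                    expr_noise_sd = 0, program_sd = 0, dispersion = 2,
                    knockout_residual = 1, n_genes = 300, seed = 6)
  sim <- gen_counts(lib, cfg)
  m <- as.matrix(sim$counts)
  mu <- rowMeans(m)
  v <- apply(m, 1, var)
  keep <- mu > 0.5
  # method of moments: (var - mu) / mu^2 estimates 1/theta = 0.5
  est <- median((v[keep] - mu[keep]) / mu[keep]^2)
  expect_gt(est, 0.3)
  expect_lt(est, 0.7)
})

test_that("per-genotype cell counts are conserved and WT sits on every plate", {
  fx <- fixture_sim(n_genotypes = 5, n_cells = 30)
  meta <- fx$sim$cell_meta
  tab <- table(meta$genotype)
  expect_equal(sum(tab), nrow(meta))
  expect_equal(as.vector(tab[paste0("g00", 1:5)]), rep(30L, 5))
  wt_by_plate <- table(meta$plate[meta$genotype == "WT"])
  expect_equal(length(wt_by_plate), fx$cfg$n_plates)
  expect_true(all(wt_by_plate >= 2))
})

test_that("a fixed seed reproduces counts and FASTQ byte-identically", {
  lib <- gen_library(3, seed = 9, include_wt = TRUE)
  cfg <- sim_config(n_genotypes = 3, n_cells_per_genotype = 10,
                    n_genes = 300, reads_per_cell = 3, seed = 99)
  s1 <- gen_counts(lib, cfg)
  s2 <- gen_counts(lib, cfg)
  expect_identical(as.matrix(s1$counts), as.matrix(s2$counts))
  expect_identical(s1$cell_meta, s2$cell_meta)
  d <- withr::local_tempdir()
  gen_amplicon_fastq(lib, s1$cell_meta, cfg, file.path(d, "a1.fq"),
                     file.path(d, "a2.fq"))
  gen_amplicon_fastq(lib, s1$cell_meta, cfg, file.path(d, "b1.fq"),
                     file.path(d, "b2.fq"))
  expect_identical(readLines(file.path(d, "a2.fq")),
                   readLines(file.path(d, "b2.fq")))
})

test_that("clean amplicon reads carry the truth at the printed positions", {
  lib <- gen_library(4, seed = 3, include_wt = TRUE)
  cfg <- sim_config(n_genotypes = 4, n_cells_per_genotype = 5,
                    n_genes = 300, reads_per_cell = 2,
                    error_rate = 0, ambient_rate = 0, seed = 8)
  sim <- gen_counts(lib, cfg)
  d <- withr::local_tempdir()
  fq <- gen_amplicon_fastq(lib, sim$cell_meta, cfg, file.path(d, "r1.fq"),
                           file.path(d, "r2.fq"))
  r2 <- read_fastq(fq$r2)
  parsed <- lapply(r2$seq, parse_read)
  expect_true(all(vapply(parsed, `[[`, logical(1), "valid")))
  d2 <- vapply(parsed, `[[`, integer(1), "d2_start")
  d1 <- vapply(parsed, `[[`, integer(1), "d1_start")
  expect_true(all(d2 >= 48 & d2 <= 51))
  expect_true(all(d1 >= 85 & d1 <= 90))
  # per-read genotype call equals simulated truth
  r1 <- read_fastq(fq$r1)
  cells <- substr(r1$seq, 1, 16)
  truth_g <- sim$cell_meta$genotype[match(cells, sim$cell_meta$cell_barcode)]
  called <- vapply(parsed, function(p)
    as.character(call_genotype(p$genotype_region, lib)), character(1))
  expect_equal(called, truth_g)
  # clone matches truth too
  truth_c <- sim$cell_meta$clone[match(cells, sim$cell_meta$cell_barcode)]
  expect_equal(vapply(parsed, `[[`, character(1), "clone_seq"), truth_c)
})

test_that("zero wild-type cells and invalid configs are rejected", {
  lib <- gen_library(2, seed = 1, include_wt = TRUE)
  cfg <- sim_config(n_genotypes = 2, n_genes = 300)
  cfg$wt_fraction <- 0
  expect_error(gen_counts(lib, cfg), "WT")
  expect_error(sim_config(error_rate = 1.5), "\\[0, 1\\]")
  expect_error(sim_config(dispersion = 0), "dispersion")
  expect_error(sim_config(state_probs = c(0.5, 0.2), n_states = 2), "sum to 1")
})
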