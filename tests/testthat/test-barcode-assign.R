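test_that("find_pattern matches the all-window Hamming oracle", {
  expect_error(find_pattern("ACGT", "", 0), "non-empty")
  expect_equal(find_pattern("AACGTT", "CGT", 0), 3L)
  expect_equal(find_pattern("ACGACG", "ACG", 0), c(1L, 4L))
  expect_equal(find_pattern("AAACGA", "ACGT", 1), oracle_find_pattern("AAACGA", "ACGT", 1))
  expect_equal(find_pattern("AAACGA", "ACGT", 1), 3L)
  set.seed(42)
  for (i in 1:40) {
    seq <- paste(sample(c("A", "C", "G", "T"), sample(20:200, 1),
                        replace = TRUE), collapse = "")
    pat <- paste(sample(c("A", "C", "G", "T"), sample(3:12, 1),
                        replace = TRUE), collapse = "")
    mm <- sample(0:3, 1)
    expect_identical(find_pattern(seq, pat, mm),
                     oracle_find_pattern(seq, pat, mm))
  }
})

test_that("anchor selection takes the maximum start position", {
  expect_equal(select_anchor(c(1, 4)), 4)
  expect_equal(select_anchor(7), 7)
  expect_true(is.na(select_anchor(integer(0))))
})

test_that("read parsing applies positional filters and reason codes", {
  contig <- build_contig(strrep("ACGT", 5), "CCCCC")
  clean <- paste0(AMPLICON_PRIMER20, contig)
  p <- parse_read(clean)
  expect_true(p$valid)
  expect_equal(p$d2_start, 51L)
  expect_equal(p$d1_start, 89L)
  expect_equal(p$clone_seq, "CCCCC")
  expect_equal(p$genotype_region, strrep("ACGT", 5))

  short <- substr(clean, 1, 60)
  expect_equal(parse_read(short)$reason, "too_short")

  # destroy D1: no anchor within 3 mismatches
  no_d1 <- paste0(substr(clean, 1, 88), strrep("A", 17))
  p2 <- parse_read(no_d1)
  expect_false(p2$valid)
  expect_equal(p2$reason, "missing_anchor")

  # shift the whole cassette so D2 starts at 47: position filter
  shifted <- paste0(substr(AMPLICON_PRIMER20, 1, 16), contig,
                    strrep("A", 4))
  p3 <- parse_read(shifted)
  expect_false(p3$valid)
  expect_equal(p3$reason, "position_filter")
  expect_equal(p3$d2_start, 47L)
})

test_that("vectorized and scalar read parsing agree", {
  lib <- fixture_library(4)
  set.seed(5)
  contigs <- vapply(1:30, function(i) {
    e <- lib[sample(nrow(lib), 1), ]
    paste0(AMPLICON_PRIMER20,
           build_contig(e$genotype_barcode, e$clone_barcodes[[1]][1]))
  }, character(1))
  # sprinkle substitutions and some broken reads
  contigs[1:5] <- vapply(contigs[1:5], function(s) {
    substr(s, 55, 55) <- "N"; s
  }, character(1))
  contigs[6] <- strrep("A", 105)
  vec <- perturbatlas:::parse_reads(contigs)
  for (i in seq_along(contigs)) {
    sc <- parse_read(contigs[i])
    expect_equal(vec$valid[i], sc$valid)
    expect_equal(vec$reason[i], sc$reason)
    expect_equal(vec$genotype_region[i], sc$genotype_region)
  }
})

test_that("genotype calling is mismatch-tolerant, conservative on ambiguity", {
  lib <- fixture_library(5)
  bc <- lib$genotype_barcode[2]
  expect_equal(call_genotype(bc, lib), lib$genotype_id[2])
  mutate_at <- function(s, pos) {
    old <- substr(s, pos, pos)
    sub <- setdiff(c("A", "C", "G", "T"), old)[1]
    substr(s, pos, pos) <- sub
    s
  }
  two_mm <- mutate_at(mutate_at(bc, 1), 10)
  expect_equal(call_genotype(two_mm, lib), lib$genotype_id[2])
  three_mm <- mutate_at(two_mm, 15)
  r3 <- call_genotype(three_mm, lib)
  expect_true(is.na(r3))
  expect_equal(attr(r3, "reason"), "no_hit")
  # a library violating the minimum distance yields an ambiguous call
  bad <- lib
  bad$genotype_barcode[3] <- mutate_at(bc, 5)
  # exhaustive Hamming scan confirms two barcodes within 2 mm of the query
  dists <- vapply(bad$genotype_barcode, function(b)
    sum(strsplit(b, "")[[1]] != strsplit(bc, "")[[1]]), integer(1))
  expect_equal(sum(dists <= 2), 2L)
  ra <- call_genotype(bc, bad)
  expect_true(is.na(ra))
  expect_equal(attr(ra, "reason"), "ambiguous")
})

test_that("the strict 70% majority rule governs cell aggregation", {
  a <- aggregate_cell(c(rep("A", 8), rep("B", 2)))
  expect_equal(a$status, "assigned")
  expect_equal(a$genotype, "A")
  b <- aggregate_cell(c(rep("A", 7), rep("B", 3)))
  expect_equal(b$status, "discarded_multi")
  expect_equal(aggregate_cell(rep("A", 5))$genotype, "A")
  expect_equal(aggregate_cell(NA_character_)$status, "unassigned")
  # clone majority with deterministic tie-break
  cl <- aggregate_cell(rep("A", 4), c("cc", "aa", "aa", "cc"))
  expect_equal(cl$clone, "aa")
  expect_true(cl$clone_tie)
})

test_that("matrix-route calls follow the same rule", {
  expect_equal(matrix_call(c("bc-geneX" = 10))$genotype, "geneX")
  expect_equal(matrix_call(c("bc-geneX" = 5, "bc-geneY" = 5))$status,
               "discarded_multi")
  expect_equal(matrix_call(setNames(numeric(0), character(0)))$status,
               "unassigned")
})

test_that("merging amplicon and matrix calls handles agreement and conflict", {
  call_a <- aggregate_cell(rep("A", 5))
  call_a2 <- aggregate_cell(rep("A", 3))
  call_b <- aggregate_cell(rep("B", 5))
  none <- aggregate_cell(NA_character_)
  m1 <- merge_sources(call_a, call_a2)
  expect_equal(m1$genotype, "A")
  expect_equal(m1$source, "both")
  expect_equal(merge_sources(call_a, call_b)$status, "conflicted")
  expect_equal(merge_sources(call_a, none)$genotype, "A")
  expect_equal(merge_sources(none, call_b)$genotype, "B")
  expect_equal(merge_sources(none, none)$status, "unassigned")
})

test_that("error-free simulations assign every cell correctly end to end", {
  fx <- fixture_sim(n_genotypes = 5, n_cells = 15)
  d <- withr::local_tempdir()
  fq <- gen_amplicon_fastq(fx$lib, fx$sim$cell_meta, fx$cfg,
                           file.path(d, "r1.fq"), file.path(d, "r2.fq"))
  calls <- assign_from_fastq(fq$r1, fq$r2, fx$lib)
  ev <- evaluate_assignment(calls, fx$sim$cell_meta)
  expect_equal(ev$assigned_fraction, 1)
  expect_equal(ev$precision, 1)
  # clones recovered too
  m <- match(calls$cell_barcode, fx$sim$cell_meta$cell_barcode)
  expect_equal(calls$clone, fx$sim$cell_meta$clone[m])
})

test_that("precision never increases along a noise grid", {
  lib <- gen_library(8, seed = 21, include_wt = TRUE)
  prec <- vapply(c(0, 0.02, 0.08), function(e) {
    cfg <- sim_config(n_genotypes = 8, n_cells_per_genotype = 12,
                      n_genes = 300, error_rate = e, ambient_rate = 2 * e,
                      reads_per_cell = 6, seed = 31)
    sim <- gen_counts(lib, cfg)
    d <- withr::local_tempdir()
    fq <- gen_amplicon_fastq(lib, sim$cell_meta, cfg,
                             file.path(d, "r1.fq"), file.path(d, "r2.fq"))
    ev <- evaluate_assignment(assign_from_fastq(fq$r1, fq$r2, lib),
                              sim$cell_meta)
    ev$precision
  }, numeric(1))
  expect_true(all(diff(prec) <= 1e-9))
})

test_that("evaluation demands a complete truth table", {
  calls <- data.frame(cell_barcode = c("AAAA", "CCCC"),
                      genotype = c("g1", NA), status = c("assigned", "unassigned"))
  truth <- data.frame(cell_barcode = "AAAA", genotype = "g1")
  expect_error(evaluate_assignment(calls, truth), "missing")
  none <- data.frame(cell_barcode = "AAAA", genotype = NA,
                     status = "unassigned")
  ev <- evaluate_assignment(none, truth)
  expect_equal(ev$assigned_fraction, 0)
  expect_true(is.na(ev$precision))
})
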