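#' Read a 4-line FASTQ file
#'
#' Gz-transparent reader returning id, sequence and quality per record.
#' Malformed records (truncated files, headers not starting with `@`, or
#' sequence/quality length mismatches) raise an error naming the offending
#' line.
#'
#' @param path FASTQ file (plain or gzip).
#' @return Data.frame with columns `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  if (length(lines) %% 4L != 0L)
    stop("truncated FASTQ: ", length(lines),
         " lines is not a multiple of 4 in ", path, call. = FALSE)
  n <- length(lines) %/% 4L
  id <- lines[seq(1L, by = 4L, length.out = n)]
  seqs <- lines[seq(2L, by = 4L, length.out = n)]
  plus <- lines[seq(3L, by = 4L, length.out = n)]
  qual <- lines[seq(4L, by = 4L, length.out = n)]
  bad <- which(!startsWith(id, "@") | !startsWith(plus, "+"))
  if (length(bad))
    stop("malformed FASTQ record at line ", (bad[1L] - 1L) * 4L + 1L,
         " of ", path, call. = FALSE)
  mism <- which(nchar(seqs) != nchar(qual))
  if (length(mism))
    stop("sequence/quality length mismatch at line ",
         (mism[1L] - 1L) * 4L + 2L, " of ", path, call. = FALSE)
  data.frame(id = id, seq = seqs, qual = qual, stringsAsFactors = FALSE)
}

#' Write a 4-line FASTQ file
#'
#' @param records Data.frame with columns `id` (with or without leading
#'   `@`), `seq`, `qual`.
#' @param path Output path; a `.gz` suffix gzips.
#' @return The path, invisibly.
#' @export
write_fastq <- function(records, path) {
  if (any(nchar(records$seq) != nchar(records$qual)))
    stop("sequence/quality length mismatch in records", call. = FALSE)
  id <- ifelse(startsWith(records$id, "@"), records$id,
               paste0("@", records$id))
  lines <- as.vector(rbind(id, records$seq, "+", records$qual))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Read a MatrixMarket count matrix with sidecars
#'
#' Reads `matrix.mtx`, `genes.tsv`, `barcodes.tsv` and, when present,
#' `cell_metadata.tsv` from a directory. Sidecar lengths must match the
#' matrix dimensions.
#'
#' @param dir Directory containing the triplet.
#' @return A list with `counts` (sparse genes x cells, dimnames set) and
#'   `cell_meta` (or `NULL`).
#' @export
read_mtx <- function(dir) {
  m <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  # normalize to a general double CsparseMatrix whatever readMM returned
  m <- methods::as(methods::as(m * 1, "generalMatrix"), "CsparseMatrix")
  genes <- readLines(file.path(dir, "genes.tsv"))
  cells <- readLines(file.path(dir, "barcodes.tsv"))
  if (length(genes) != nrow(m))
    stop("genes.tsv has ", length(genes), " entries for ", nrow(m),
         " matrix rows", call. = FALSE)
  if (length(cells) != ncol(m))
    stop("barcodes.tsv has ", length(cells), " entries for ", ncol(m),
         " matrix columns", call. = FALSE)
  if (Matrix::nnzero(m) == 0L)
    warning("empty count matrix in ", dir, call. = FALSE)
  dimnames(m) <- list(genes, cells)
  meta_path <- file.path(dir, "cell_metadata.tsv")
  meta <- if (file.exists(meta_path))
    utils::read.delim(meta_path, stringsAsFactors = FALSE) else NULL
  list(counts = m, cell_meta = meta)
}

#' Write a MatrixMarket count matrix with sidecars
#'
#' @param counts Sparse genes x cells matrix with dimnames.
#' @param dir Output directory (created if missing).
#' @param cell_meta Optional per-cell metadata data.frame, written as
#'   `cell_metadata.tsv`.
#' @return The directory, invisibly.
#' @export
write_mtx <- function(counts, dir, cell_meta = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(methods::as(counts, "CsparseMatrix"),
                  file.path(dir, "matrix.mtx"))
  writeLines(rownames(counts), file.path(dir, "genes.tsv"))
  writeLines(colnames(counts), file.path(dir, "barcodes.tsv"))
  if (!is.null(cell_meta))
    utils::write.table(cell_meta, file.path(dir, "cell_metadata.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Pipeline configuration with the screen's standard thresholds
#'
#' Collects every tunable of the analysis pipeline with its standard value:
#' anchor matching at up to 3 mismatches, barcode calling at up to 2, the
#' strict 70% majority rule, the positional windows (clone 21-25, D2 48-51,
#' D1 85-90), the 300-bp locus threshold, QC at +/-2 SD of detected genes
#' and 10% mitochondrial reads, marker log2FC 0.25, DE log2FC 1, alpha 0.05,
#' the 6-cell genotype minimum, 20 singular vectors at gene mean > 0.25,
#' regulator thresholds 1.3 / 0.7, the 40% core-state share, 1000
#' permutations, 14 PCA dimensions and Louvain resolution 1.
#'
#' @param ... Overrides of any default.
#' @param sim A [sim_config()] describing the synthetic cohort (optional).
#' @param seed Master seed; per-stage seeds are derived from it.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(..., sim = NULL, seed = 1L) {
  cfg <- list(
    max_mm_anchor = 3L, max_mm_bc = 2L, majority = 0.70,
    clone_window = c(21L, 25L), d2_window = c(48L, 51L),
    d1_window = c(85L, 90L), locus_threshold = 300,
    qc_sd = 2, qc_mito = 0.10, norm_scale = 1e4,
    marker_lfc = 0.25, de_lfc = 1, alpha = 0.05, min_cells = 6L,
    k_svd = 20L, min_mean = 0.25, reg_up = 1.3, reg_down = 0.7,
    core_share = 0.4, n_perm = 1000L, dims = 14L, resolution = 1.0,
    k_neighbors = 20L, n_hvg = 2000L,
    sim = sim, seed = as.integer(seed)
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("unknown config fields: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg[names(dots)] <- dots
  structure(cfg, class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' Configurations round-trip through serialization unchanged.
#'
#' @param config A `pipeline_config`.
#' @param path YAML file path.
#' @return `write_config` returns the path invisibly; `read_config` a
#'   `pipeline_config`.
#' @export
write_config <- function(config, path) {
  x <- unclass(config)
  if (!is.null(x$sim)) x$sim <- unclass(x$sim)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  sim <- x$sim
  x$sim <- NULL
  for (f in c("clone_window", "d2_window", "d1_window"))
    x[[f]] <- as.integer(x[[f]])
  cfg <- do.call(pipeline_config, x)
  if (!is.null(sim)) {
    sim$attractors <- as.character(sim$attractors %||% character(0))
    sim$het_genotypes <- as.character(sim$het_genotypes %||% character(0))
    cfg$sim <- do.call(sim_config, sim)
  }
  cfg
}

#' Run the simulate-to-report pipeline
#'
#' Drives the full analysis on a synthetic cohort: simulate the library,
#' counts and amplicon FASTQ; assign genotypes from the amplicon reads; QC
#' and normalize; cluster cell states and extract markers; test genotype by
#' state enrichment; compute leverage-score heterogeneity; and run the
#' permutation fitness test on the enriched genotype set against a synthetic
#' fitness table. All stage seeds derive from the master seed, so the same
#' configuration reproduces the same report.
#'
#' @param config A [pipeline_config()] whose `sim` field is set.
#' @param outdir Optional directory for TSV outputs and the report.
#' @return A list of class `pipeline_report` with per-stage summary
#'   statistics and result tables.
#' @export
run_pipeline <- function(config, outdir = NULL) {
  if (is.null(config$sim))
    stop("config$sim must hold a sim_config", call. = FALSE)
  simc <- config$sim
  lib <- gen_library(simc$n_genotypes, simc$clones_per_genotype,
                     seed = derive_seed(config$seed, "library"),
                     include_wt = TRUE)
  sim <- gen_counts(lib, simc)
  tmp <- outdir %||% tempdir()
  dir.create(tmp, showWarnings = FALSE, recursive = TRUE)
  fq <- gen_amplicon_fastq(lib, sim$cell_meta, simc,
                           file.path(tmp, "amplicon_R1.fastq"),
                           file.path(tmp, "amplicon_R2.fastq"))
  calls <- assign_from_fastq(fq$r1, fq$r2, lib,
                             max_mm_anchor = config$max_mm_anchor,
                             max_mm_bc = config$max_mm_bc,
                             majority = config$majority,
                             d2_window = config$d2_window,
                             d1_window = config$d1_window,
                             clone_window = config$clone_window)
  ev <- evaluate_assignment(calls, sim$cell_meta)

  assigned <- calls[calls$status == "assigned", ]
  counts <- sim$counts[, assigned$cell_barcode, drop = FALSE]
  mito <- sim$gene_meta$gene[sim$gene_meta$is_mito]
  ribo <- sim$gene_meta$gene[sim$gene_meta$is_ribosomal]
  kept <- qc_filter(counts, mito, n_sd = config$qc_sd,
                    max_mito = config$qc_mito)
  counts <- counts[, kept, drop = FALSE]
  meta <- assigned[kept, ]
  norm <- normalize_log1p(counts, scale = config$norm_scale,
                          drop_genes = ribo)
  hvgs <- select_hvg(norm, n = config$n_hvg)
  states <- cluster_states(norm, hvgs, dims = min(config$dims,
                                                  ncol(norm) - 1L),
                           resolution = config$resolution,
                           k_neighbors = config$k_neighbors,
                           seed = derive_seed(config$seed, "cluster"))
  markers <- find_markers(norm, states, lfc_cut = config$marker_lfc,
                          p_cut = config$alpha)
  enr <- state_enrichment(states, meta$genotype,
                          min_cells = config$min_cells,
                          alpha = config$alpha)
  plates <- sim$cell_meta$plate[match(meta$cell_barcode,
                                      sim$cell_meta$cell_barcode)]
  lev <- leverage_analysis(counts, norm, plates, meta$genotype,
                           k = config$k_svd, min_mean = config$min_mean,
                           min_cells = config$min_cells,
                           up = config$reg_up, down = config$reg_down)
  fit_tab <- gen_fitness_table(lib$genotype_id,
                               seed = derive_seed(config$seed, "fitness"))
  biased <- unique(enr$genotype[enr$class == "enriched"])
  fit_p <- if (length(biased) &&
               length(biased) <= sum(!fit_tab$genotype %in% biased))
    fitness_permutation(biased, fit_tab, n_perm = config$n_perm,
                        side = "less",
                        seed = derive_seed(config$seed, "perm"))
  else NULL

  report <- structure(list(
    n_cells_simulated = nrow(sim$cell_meta),
    n_reads = fq$n_reads,
    assigned_fraction = ev$assigned_fraction,
    assignment_precision = ev$precision,
    conflict_rate = ev$conflict_rate,
    n_cells_qc = ncol(counts),
    n_states = length(unique(states)),
    n_markers_significant = sum(markers$significant),
    n_enriched = sum(enr$class == "enriched"),
    n_depleted = sum(enr$class == "depleted"),
    n_negative_regulators = sum(lev$genotypes$class == "negative_regulator"),
    n_positive_regulators = sum(lev$genotypes$class == "positive_regulator"),
    fitness_p = fit_p,
    calls = calls, markers = markers, enrichment = enr,
    leverage = lev$genotypes, states = states
  ), class = "pipeline_report")

  if (!is.null(outdir)) {
    utils::write.table(calls, file.path(outdir, "calls.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(markers, file.path(outdir, "markers.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(enr, file.path(outdir, "enrichment.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(lev$genotypes, file.path(outdir, "leverage_genotypes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    scal <- vapply(report[1:12], as.numeric, numeric(1))
    utils::write.table(data.frame(metric = names(scal), value = scal),
                       file.path(outdir, "report.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  report
}
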