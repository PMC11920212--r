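#' Default 20-nt primer prefix of simulated amplicon reads
#'
#' The constant region carried at the 5' end of the genotype-bearing amplicon
#' read before the clone barcode, so that the clone barcode occupies read
#' positions 21-25. The default is the 20 nt immediately upstream of the
#' clone-barcode slot in the cassette template.
#' @export
AMPLICON_PRIMER20 <- "GATGCGGCCAGCAAAACTAA"

#' Generate a barcode library with guaranteed mutual distance
#'
#' Draws one 20-nt genotype barcode per genotype by rejection sampling so
#' that every pair of barcodes differs at `min_hamming` or more positions
#' (the default 5 guarantees unambiguous calling at up to 2 mismatches),
#' plus `clones_per_genotype` random 5-nt clone barcodes per genotype.
#'
#' @param n_genotypes Number of knockout genotypes.
#' @param clones_per_genotype Clone barcodes per genotype.
#' @param min_hamming Minimum pairwise Hamming distance between genotype
#'   barcodes.
#' @param seed Integer seed; fixed seed gives an identical library.
#' @param include_wt Append one wild-type entry (`genotype_id` "WT",
#'   no target gene) carrying its own barcodes, as the barcoded wild-type
#'   strains of the collection do.
#' @return A `barcode_library`: data.frame with columns `genotype_id`,
#'   `genotype_barcode`, `target_gene`, `target_stop_pos`, `contig_seq` and
#'   a list-column `clone_barcodes`.
#' @export
gen_library <- function(n_genotypes, clones_per_genotype = 2L,
                        min_hamming = 5L, seed = 1L, include_wt = FALSE) {
  if (n_genotypes < 1L) stop("n_genotypes must be >= 1", call. = FALSE)
  if (min_hamming < 1L) stop("min_hamming must be >= 1", call. = FALSE)
  if (min_hamming > 20L)
    stop("min_hamming = ", min_hamming,
         " is unattainable for 20-nt barcodes (maximum distance 20)",
         call. = FALSE)
  set.seed(as.integer(seed))
  n_total <- n_genotypes + as.integer(include_wt)
  barcodes <- character(0)
  attempts <- 0L
  max_attempts <- 500L * n_total + 1000L
  while (length(barcodes) < n_total) {
    attempts <- attempts + 1L
    if (attempts > max_attempts)
      stop("rejection sampling failed after ", max_attempts,
           " attempts: cannot place ", n_total,
           " barcodes at pairwise Hamming >= ", min_hamming, call. = FALSE)
    cand <- random_dna(1L, 20L)
    ok <- all(vapply(barcodes, function(b) hamming(b, cand) >= min_hamming,
                     logical(1)))
    if (ok) barcodes <- c(barcodes, cand)
  }
  ids <- sprintf("g%03d", seq_len(n_genotypes))
  genes <- sprintf("gene%03d", seq_len(n_genotypes))
  stops <- sample.int(900000L, n_genotypes) + 100000L
  if (include_wt) {
    ids <- c(ids, "WT")
    genes <- c(genes, NA_character_)
    stops <- c(stops, NA_integer_)
  }
  clones <- lapply(seq_len(n_total), function(i) {
    cl <- unique(random_dna(clones_per_genotype * 4L, 5L))
    while (length(cl) < clones_per_genotype)
      cl <- unique(c(cl, random_dna(clones_per_genotype, 5L)))
    cl[seq_len(clones_per_genotype)]
  })
  lib <- data.frame(
    genotype_id = ids,
    genotype_barcode = barcodes,
    target_gene = genes,
    target_stop_pos = stops,
    stringsAsFactors = FALSE
  )
  lib$contig_seq <- vapply(seq_len(n_total), function(i)
    build_contig(barcodes[i], clones[[i]][1L]), character(1))
  lib$clone_barcodes <- clones
  class(lib) <- c("barcode_library", "data.frame")
  lib
}

#' Simulation configuration
#'
#' Collects every knob of the synthetic Perturb-seq generator: library and
#' cohort sizes, the latent cell-state mixture, perturbation effects
#' (knockout silencing, state attraction, expression-scale variance
#' inflation, a stress program), the gamma-Poisson noise model and the
#' amplicon read model. Defaults describe a desk-scale screen with the
#' structural features of a genome-scale experiment.
#'
#' @param n_genotypes Knockout genotypes simulated.
#' @param clones_per_genotype Clones per genotype.
#' @param n_cells_per_genotype Cells per knockout genotype.
#' @param wt_fraction Fraction of each plate's cells that are wild type.
#' @param n_plates Number of plates (batches); every plate contains WT cells.
#' @param n_genes Genes in the count matrix.
#' @param n_states Latent cell states K.
#' @param state_probs Optional K-vector or genotype-by-K matrix of state
#'   probabilities (rows sum to 1); default uniform.
#' @param attractors Character vector of genotype ids biased toward
#'   `attractor_state` with probability `pi_target`.
#' @param attractor_state State index the attractor genotypes favor.
#' @param pi_target Probability mass an attractor genotype places on its
#'   target state.
#' @param markers_per_state Marker genes per state.
#' @param marker_effect Fold-change of state markers in their state.
#' @param knockout_residual Fraction of wild-type expression retained by the
#'   deleted gene in its own genotype.
#' @param dispersion Gamma-Poisson (negative binomial) size parameter theta.
#' @param het_genotypes Genotypes with inflated expression-scale variance.
#' @param het_inflation Deviation-scale multiplier for the deviant cells of
#'   `het_genotypes` (see `het_penetrance`).
#' @param het_penetrance Fraction of a variance-inflated genotype's cells
#'   that are deviant. Heterogeneity inflation is partially penetrant: a
#'   deviant cell's program-activation SD is `program_sd * het_inflation`
#'   while its siblings stay at baseline, so the genotype's cells spread out
#'   in transcriptional space instead of shifting together.
#' @param n_programs,program_genes_each Number and size of latent
#'   co-expression programs whose activation varies continuously from cell
#'   to cell (the structured cell-to-cell variability that the leverage
#'   score reads out).
#' @param program_sd Baseline SD of per-cell log program activation.
#' @param size_factor_sd Baseline SD of per-cell log size factors (sequencing
#'   depth; removed again by depth normalization).
#' @param expr_noise_sd SD of unstructured per-cell, per-gene log-normal
#'   noise on the mean vector.
#' @param condition "control" or "stress"; stress cells elevate the stress
#'   program.
#' @param stress_genes Number of genes in the stress program.
#' @param stress_effect Fold-change of stress-program genes under stress.
#' @param n_mito,n_ribo Genes flagged mitochondrial / ribosomal.
#' @param reads_per_cell Amplicon reads generated per cell.
#' @param error_rate Per-base substitution rate on the amplicon read.
#' @param ambient_rate Fraction of reads carrying a random other genotype.
#' @param seed Master seed; fixed seed gives byte-identical outputs.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_genotypes = 20L, clones_per_genotype = 2L,
                       n_cells_per_genotype = 100L, wt_fraction = 0.1,
                       n_plates = 2L, n_genes = 500L, n_states = 5L,
                       state_probs = NULL, attractors = character(0),
                       attractor_state = 1L, pi_target = 0.6,
                       markers_per_state = 10L, marker_effect = 4,
                       knockout_residual = 0.02, dispersion = 2,
                       het_genotypes = character(0), het_inflation = 3,
                       het_penetrance = 0.5, n_programs = 20L,
                       program_genes_each = 8L, program_sd = 0.6,
                       size_factor_sd = 0.3, expr_noise_sd = 0.2,
                       condition = "control",
                       stress_genes = 20L, stress_effect = 4,
                       n_mito = 10L, n_ribo = 10L,
                       reads_per_cell = 10L, error_rate = 0,
                       ambient_rate = 0, seed = 1L) {
  cfg <- list(
    n_genotypes = as.integer(n_genotypes),
    clones_per_genotype = as.integer(clones_per_genotype),
    n_cells_per_genotype = as.integer(n_cells_per_genotype),
    wt_fraction = wt_fraction, n_plates = as.integer(n_plates),
    n_genes = as.integer(n_genes), n_states = as.integer(n_states),
    state_probs = state_probs, attractors = attractors,
    attractor_state = as.integer(attractor_state), pi_target = pi_target,
    markers_per_state = as.integer(markers_per_state),
    marker_effect = marker_effect, knockout_residual = knockout_residual,
    dispersion = dispersion, het_genotypes = het_genotypes,
    het_inflation = het_inflation, het_penetrance = het_penetrance,
    n_programs = as.integer(n_programs),
    program_genes_each = as.integer(program_genes_each),
    program_sd = program_sd, size_factor_sd = size_factor_sd,
    expr_noise_sd = expr_noise_sd,
    condition = match.arg(condition, c("control", "stress")),
    stress_genes = as.integer(stress_genes), stress_effect = stress_effect,
    n_mito = as.integer(n_mito), n_ribo = as.integer(n_ribo),
    reads_per_cell = as.integer(reads_per_cell),
    error_rate = error_rate, ambient_rate = ambient_rate,
    seed = as.integer(seed)
  )
  for (r in c("wt_fraction", "pi_target", "error_rate", "ambient_rate",
              "knockout_residual", "het_penetrance"))
    if (cfg[[r]] < 0 || cfg[[r]] > 1)
      stop(r, " must lie in [0, 1]", call. = FALSE)
  if (cfg$dispersion <= 0) stop("dispersion must be > 0", call. = FALSE)
  if (cfg$n_states < 1L) stop("n_states must be >= 1", call. = FALSE)
  if (cfg$attractor_state > cfg$n_states)
    stop("attractor_state exceeds n_states", call. = FALSE)
  if (!is.null(state_probs)) {
    pm <- if (is.matrix(state_probs)) state_probs
          else matrix(state_probs, nrow = 1L)
    if (ncol(pm) != cfg$n_states)
      stop("state_probs must have n_states columns", call. = FALSE)
    if (any(abs(rowSums(pm) - 1) > 1e-8))
      stop("state_probs rows must sum to 1", call. = FALSE)
  }
  if (cfg$n_genes < cfg$n_genotypes + cfg$n_states * cfg$markers_per_state +
        cfg$stress_genes + cfg$n_mito + cfg$n_ribo +
        cfg$n_programs * cfg$program_genes_each)
    stop("n_genes too small for the requested gene programs", call. = FALSE)
  structure(cfg, class = "sim_config")
}

# Per-genotype state probability matrix implied by a config.
.state_prob_matrix <- function(config, genotype_ids) {
  K <- config$n_states
  base <- if (is.null(config$state_probs)) rep(1 / K, K)
          else if (is.matrix(config$state_probs)) NULL
          else config$state_probs
  if (is.matrix(config$state_probs)) {
    pm <- config$state_probs
    if (nrow(pm) != length(genotype_ids))
      stop("state_probs matrix must have one row per genotype (incl. WT)",
           call. = FALSE)
    rownames(pm) <- genotype_ids
    return(pm)
  }
  pm <- matrix(base, nrow = length(genotype_ids), ncol = K, byrow = TRUE,
               dimnames = list(genotype_ids, NULL))
  for (g in intersect(config$attractors, genotype_ids)) {
    rest <- (1 - config$pi_target) / (K - 1)
    pm[g, ] <- rest
    pm[g, config$attractor_state] <- config$pi_target
  }
  pm
}

#' Simulate a structured Perturb-seq count matrix with ground truth
#'
#' Draws gamma-Poisson counts organized into latent cell states with marker
#' programs, knockout-gene silencing, state-attractor genotypes,
#' variance-inflated genotypes, a stress program under the stress condition,
#' per-cell log-normal size factors, clone structure, and wild-type cells on
#' every plate.
#'
#' @param library A `barcode_library` from [gen_library()] covering the
#'   configured genotypes (including a "WT" entry when `wt_fraction > 0`).
#' @param config A [sim_config()].
#' @return A list of class `perturb_sim` with `counts` (sparse genes x
#'   cells), `cell_meta`, `gene_meta`, and `truth` (per-cell truth plus
#'   per-genotype flags).
#' @export
gen_counts <- function(library, config) {
  stopifnot(inherits(library, "barcode_library"), inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, "counts"))
  ko_ids <- setdiff(library$genotype_id, "WT")[seq_len(config$n_genotypes)]
  if (anyNA(ko_ids))
    stop("library does not cover the configured number of genotypes",
         call. = FALSE)
  if (config$wt_fraction <= 0)
    stop("zero WT cells requested: wt_fraction must be > 0 because ",
         "downstream leverage scaling requires wild-type cells",
         call. = FALSE)
  if (!"WT" %in% library$genotype_id)
    stop("library lacks a WT entry; call gen_library(include_wt = TRUE)",
         call. = FALSE)

  # cohort layout: KO cells spread over plates, WT topped up per plate
  geno <- rep(ko_ids, each = config$n_cells_per_genotype)
  plate <- sample(rep_len(seq_len(config$n_plates), length(geno)))
  n_wt_plate <- pmax(2L, round(tabulate(plate, config$n_plates) *
                                 config$wt_fraction / (1 - config$wt_fraction)))
  geno <- c(geno, rep("WT", sum(n_wt_plate)))
  plate <- c(plate, rep(seq_len(config$n_plates), n_wt_plate))
  n_cells <- length(geno)
  ord <- sample.int(n_cells)
  geno <- geno[ord]; plate <- plate[ord]

  all_ids <- c(ko_ids, "WT")
  pm <- .state_prob_matrix(config, all_ids)
  state <- vapply(geno, function(g)
    sample.int(config$n_states, 1L, prob = pm[g, ]), integer(1))
  names(state) <- NULL
  clone_map <- stats::setNames(library$clone_barcodes, library$genotype_id)
  clone <- vapply(geno, function(g)
    sample(clone_map[[g]], 1L), character(1))
  names(clone) <- NULL

  # gene layout: targets, then mito / ribo, marker blocks, stress program
  genes <- sprintf("gene%03d", seq_len(config$n_genes))
  nt <- config$n_genotypes
  mito_idx <- nt + seq_len(config$n_mito)
  ribo_idx <- nt + config$n_mito + seq_len(config$n_ribo)
  mk_start <- nt + config$n_mito + config$n_ribo
  marker_state <- rep(NA_integer_, config$n_genes)
  for (k in seq_len(config$n_states))
    marker_state[mk_start + (k - 1L) * config$markers_per_state +
                   seq_len(config$markers_per_state)] <- k
  stress_idx <- mk_start + config$n_states * config$markers_per_state +
    seq_len(config$stress_genes)
  prog_start <- mk_start + config$n_states * config$markers_per_state +
    config$stress_genes
  program_id <- rep(NA_integer_, config$n_genes)
  for (p in seq_len(config$n_programs))
    program_id[prog_start + (p - 1L) * config$program_genes_each +
                 seq_len(config$program_genes_each)] <- p
  genes[mito_idx] <- sprintf("mt-gene%03d", seq_along(mito_idx))
  genes[ribo_idx] <- sprintf("RPL%03d", seq_along(ribo_idx))
  gene_meta <- data.frame(
    gene = genes,
    is_mito = seq_len(config$n_genes) %in% mito_idx,
    is_ribosomal = seq_len(config$n_genes) %in% ribo_idx,
    marker_state = marker_state,
    is_stress = seq_len(config$n_genes) %in% stress_idx,
    program = program_id,
    target_of = c(ko_ids, rep(NA_character_, config$n_genes - nt)),
    stringsAsFactors = FALSE
  )

  base_mean <- exp(stats::rnorm(config$n_genes, log(0.5), 1))
  base_mean[mito_idx] <- 0.25   # modest mito load so QC keeps typical cells
  sf <- exp(stats::rnorm(n_cells, -config$size_factor_sd^2 / 2,
                         config$size_factor_sd))
  # heterogeneity inflation is partially penetrant: only the deviant cells
  # of an inflated genotype get the widened program-activation scale
  deviant <- geno %in% config$het_genotypes &
    stats::runif(n_cells) < config$het_penetrance
  act_sd <- ifelse(deviant, config$program_sd * config$het_inflation,
                   config$program_sd)

  mu <- matrix(base_mean, config$n_genes, n_cells) *
    matrix(sf, config$n_genes, n_cells, byrow = TRUE)
  for (p in seq_len(config$n_programs)) {
    rows <- which(program_id == p)
    act <- exp(stats::rnorm(n_cells, 0, act_sd))
    mu[rows, ] <- mu[rows, ] * matrix(act, length(rows), n_cells,
                                      byrow = TRUE)
  }
  if (config$expr_noise_sd > 0) {
    s <- config$expr_noise_sd
    mu <- mu * exp(stats::rnorm(length(mu), -s^2 / 2, s))
  }
  for (k in seq_len(config$n_states)) {
    cells_k <- which(state == k)
    gk <- which(marker_state == k)
    if (length(cells_k) && length(gk))
      mu[gk, cells_k] <- mu[gk, cells_k] * config$marker_effect
  }
  target_row <- match(library$target_gene[match(geno, library$genotype_id)],
                      genes)
  has_t <- which(!is.na(target_row))
  mu[cbind(target_row[has_t], has_t)] <-
    mu[cbind(target_row[has_t], has_t)] * config$knockout_residual
  if (config$condition == "stress")
    mu[stress_idx, ] <- mu[stress_idx, ] * config$stress_effect

  counts <- matrix(stats::rnbinom(length(mu), mu = as.vector(mu),
                                  size = config$dispersion),
                   config$n_genes, n_cells)
  cell_bc <- unique(random_dna(n_cells * 2L, 16L))
  while (length(cell_bc) < n_cells)
    cell_bc <- unique(c(cell_bc, random_dna(n_cells, 16L)))
  cell_bc <- cell_bc[seq_len(n_cells)]
  dimnames(counts) <- list(genes, cell_bc)

  cell_meta <- data.frame(
    cell_barcode = cell_bc, plate = paste0("plate", plate),
    condition = config$condition, genotype = geno, clone = clone,
    state = state, stringsAsFactors = FALSE
  )
  truth_cells <- cell_meta
  truth_cells$deviant <- deviant
  truth_genotypes <- data.frame(
    genotype = all_ids,
    attractor_state = ifelse(all_ids %in% config$attractors,
                             config$attractor_state, NA_integer_),
    het_inflated = all_ids %in% config$het_genotypes,
    stringsAsFactors = FALSE
  )
  structure(list(
    counts = methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix"),
    cell_meta = cell_meta, gene_meta = gene_meta,
    truth = list(cells = truth_cells, genotypes = truth_genotypes)
  ), class = "perturb_sim")
}

#' Write paired targeted-amplicon FASTQ for a simulated cohort
#'
#' Read 1 carries the 16-nt cell barcode plus a 12-nt UMI; read 2 carries a
#' 20-nt constant primer prefix followed by the cell's 85-nt barcode contig,
#' so the clone barcode sits at read positions 21-25, the D2 anchor starts
#' at position 51 and the D1 anchor at position 89. Substitution errors are
#' applied to read 2 at `error_rate` per base and a fraction `ambient_rate`
#' of reads carries a random other genotype's contig.
#'
#' @param library A `barcode_library`.
#' @param truth Per-cell truth data.frame (the `cell_meta` of
#'   [gen_counts()]), needing columns `cell_barcode`, `genotype`, `clone`.
#' @param config A [sim_config()].
#' @param r1_path,r2_path Output FASTQ paths (".gz" suffix gzips).
#' @param primer Primer prefix sequence on read 2.
#' @return Invisibly, a list with the paths and the number of read pairs.
#' @export
gen_amplicon_fastq <- function(library, truth, config, r1_path, r2_path,
                               primer = AMPLICON_PRIMER20) {
  stopifnot(inherits(library, "barcode_library"))
  if (config$reads_per_cell < 1L)
    stop("reads_per_cell must be >= 1", call. = FALSE)
  set.seed(derive_seed(config$seed, "fastq"))
  n_cells <- nrow(truth)
  rpc <- config$reads_per_cell
  cell_idx <- rep(seq_len(n_cells), each = rpc)
  geno <- truth$genotype[cell_idx]
  clone <- truth$clone[cell_idx]

  # ambient contamination: the read reports another genotype entirely
  amb <- stats::runif(length(cell_idx)) < config$ambient_rate
  if (any(amb)) {
    others <- vapply(which(amb), function(i) {
      pool <- setdiff(library$genotype_id, geno[i])
      sample(pool, 1L)
    }, character(1))
    geno[amb] <- others
    clone[amb] <- vapply(others, function(g)
      sample(library$clone_barcodes[[match(g, library$genotype_id)]], 1L),
      character(1))
  }
  bc_of <- stats::setNames(library$genotype_barcode, library$genotype_id)
  r2 <- paste0(primer, clone, YKO_LINKER43, bc_of[geno], YKO_FLANK17)
  r2 <- mutate_seqs(r2, config$error_rate)
  umi <- random_dna(length(cell_idx), 12L)
  r1 <- paste0(truth$cell_barcode[cell_idx], umi)
  ids <- sprintf("@read%06d", seq_along(r1))
  write_fastq(data.frame(id = ids, seq = r1, qual = strrep("I", nchar(r1)),
                         stringsAsFactors = FALSE), r1_path)
  write_fastq(data.frame(id = ids, seq = r2, qual = strrep("I", nchar(r2)),
                         stringsAsFactors = FALSE), r2_path)
  invisible(list(r1 = r1_path, r2 = r2_path, n_reads = length(r1)))
}
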