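#' Two-sample Wilcoxon rank-sum test
#'
#' Rank-sum test used throughout marker discovery and differential
#' expression. For small samples (`n1 + n2 <= exact_max`) the two-sided
#' p-value is computed by exact enumeration of all group assignments of the
#' observed (possibly tied) ranks; otherwise a tie-corrected normal
#' approximation with continuity correction is used.
#'
#' @param x,y Numeric samples.
#' @param exact_max Largest combined sample size for which the exact
#'   enumeration is used.
#' @return A list with `statistic` (rank sum of `x`) and `p_value`.
#' @export
wilcox_rank_sum <- function(x, y, exact_max = 16L) {
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  if (n1 == 0L || n2 == 0L) stop("both groups must be non-empty", call. = FALSE)
  r <- rank(c(x, y))
  w <- sum(r[seq_len(n1)])
  if (n <= exact_max) {
    sets <- utils::combn(n, n1)
    ws <- colSums(matrix(r[sets], nrow = n1))
    eps <- 1e-9
    p_lo <- mean(ws <= w + eps)
    p_hi <- mean(ws >= w - eps)
    p <- min(1, 2 * min(p_lo, p_hi))
  } else {
    p <- .wilcox_normal_p(w, r, n1, n2)
  }
  list(statistic = w, p_value = p)
}

.wilcox_normal_p <- function(w, r, n1, n2) {
  n <- n1 + n2
  mu <- n1 * (n + 1) / 2
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / ((n) * (n - 1))
  sig2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
  if (sig2 <= 0) return(1)
  z <- w - mu
  z <- (z - sign(z) * 0.5) / sqrt(sig2)
  2 * stats::pnorm(-abs(z))
}

# Vectorized rank-sum p-values over matrix rows for a two-group comparison.
# mat: genes x cells (dense or sparse); returns p per row.
.wilcox_rows <- function(mat, idx1, idx2, exact_max = 16L) {
  mat <- as.matrix(mat)
  n1 <- length(idx1); n2 <- length(idx2)
  apply(mat[, c(idx1, idx2), drop = FALSE], 1L, function(v) {
    if (n1 + n2 <= exact_max)
      wilcox_rank_sum(v[seq_len(n1)], v[n1 + seq_len(n2)], exact_max)$p_value
    else {
      r <- rank(v)
      .wilcox_normal_p(sum(r[seq_len(n1)]), r, n1, n2)
    }
  })
}

#' Quality-control cell filter
#'
#' Keeps cells whose number of detected genes lies within `n_sd` standard
#' deviations of the population mean and whose mitochondrial read fraction
#' is at most `max_mito`. A degenerate population (SD of detected genes 0)
#' keeps every cell passing the mitochondrial rule.
#'
#' @param counts Sparse genes x cells count matrix.
#' @param mito_genes Character vector of mitochondrial gene names (rows).
#' @param n_sd Width of the detected-genes band in SDs.
#' @param max_mito Maximum mitochondrial fraction.
#' @return Integer indices of kept cells.
#' @export
qc_filter <- function(counts, mito_genes = character(0), n_sd = 2,
                      max_mito = 0.10) {
  det <- Matrix::colSums(counts > 0)
  tot <- Matrix::colSums(counts)
  mito <- if (length(mito_genes)) {
    rows <- intersect(mito_genes, rownames(counts))
    if (length(rows)) Matrix::colSums(counts[rows, , drop = FALSE]) /
      pmax(tot, 1) else rep(0, ncol(counts))
  } else rep(0, ncol(counts))
  s <- stats::sd(det)
  genes_ok <- if (is.na(s) || s == 0) rep(TRUE, ncol(counts))
              else abs(det - mean(det)) <= n_sd * s
  which(genes_ok & mito <= max_mito)
}

#' Depth-normalize and log-transform counts
#'
#' Scales each cell to `scale` total counts and applies `log1p`. Genes in
#' `drop_genes` (e.g. ribosomal genes) are removed before normalization.
#'
#' @param counts Sparse genes x cells count matrix.
#' @param scale Target total counts per cell.
#' @param drop_genes Gene names to exclude.
#' @return A sparse genes x cells matrix of log-normalized expression.
#' @export
normalize_log1p <- function(counts, scale = 1e4, drop_genes = character(0)) {
  if (length(drop_genes))
    counts <- counts[setdiff(rownames(counts), drop_genes), , drop = FALSE]
  tot <- Matrix::colSums(counts)
  if (any(tot == 0)) {
    bad <- colnames(counts)[tot == 0] %||% which(tot == 0)
    stop("cells with zero total counts: ",
         paste(utils::head(bad, 5L), collapse = ", "),
         if (sum(tot == 0) > 5L) " ..." else "", call. = FALSE)
  }
  norm <- counts %*% Matrix::Diagonal(x = scale / tot)
  dimnames(norm) <- dimnames(counts)
  methods::as(log1p(norm), "CsparseMatrix")
}

#' Expression-bin-matched module score
#'
#' Scores a gene program per cell as the mean expression of the program
#' genes minus the mean of control genes drawn from expression-matched bins,
#' the scheme used for cell-cycle scoring.
#'
#' @param normalized Log-normalized genes x cells matrix.
#' @param gene_set Program gene names.
#' @param n_bins Number of average-expression bins.
#' @param n_ctrl Control genes sampled per program gene.
#' @param seed Seed for control sampling.
#' @return Numeric per-cell score.
#' @export
score_module <- function(normalized, gene_set, n_bins = 24L, n_ctrl = 100L,
                         seed = 1L) {
  if (length(gene_set) == 0L) stop("gene_set is empty", call. = FALSE)
  genes <- intersect(gene_set, rownames(normalized))
  if (length(genes) == 0L)
    stop("none of the gene_set genes are present in the matrix",
         call. = FALSE)
  set.seed(as.integer(seed))
  avg <- Matrix::rowMeans(normalized)
  bin <- ceiling(rank(avg, ties.method = "first") /
                   (length(avg) / min(n_bins, length(avg))))
  ctrl <- unlist(lapply(genes, function(g) {
    pool <- names(avg)[bin == bin[g]]
    sample(pool, min(n_ctrl, length(pool)), replace = length(pool) < n_ctrl)
  }))
  set_mean <- Matrix::colMeans(normalized[genes, , drop = FALSE])
  ctrl_mean <- Matrix::colMeans(normalized[unique(ctrl), , drop = FALSE])
  as.numeric(set_mean - ctrl_mean)
}

#' Assign cell-cycle phase from S and G2M scores
#'
#' @param s_score,g2m_score Per-cell module scores for the S and G2M
#'   programs.
#' @return Character vector in `{"G1","S","G2M"}`: G1 when both scores are
#'   non-positive, otherwise the phase with the larger score.
#' @export
assign_phase <- function(s_score, g2m_score) {
  out <- ifelse(s_score <= 0 & g2m_score <= 0, "G1",
                ifelse(s_score >= g2m_score, "S", "G2M"))
  as.character(out)
}

#' Regress covariates out of an expression matrix
#'
#' Per-gene ordinary least squares on the supplied covariates (with
#' intercept); returns the residual matrix. Residuals are orthogonal to
#' every covariate.
#'
#' @param normalized Genes x cells matrix.
#' @param covariates Data.frame or matrix of per-cell covariates.
#' @return Dense genes x cells residual matrix.
#' @export
regress_out <- function(normalized, covariates) {
  X <- cbind(`(Intercept)` = 1, as.matrix(covariates))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("collinear covariates: ", paste(drop, collapse = ", "),
         call. = FALSE)
  }
  res <- t(qr.resid(qrX, t(as.matrix(normalized))))
  dimnames(res) <- dimnames(normalized)
  res
}

#' Select highly variable genes
#'
#' Ranks genes by standardized variance: a loess trend of log variance on
#' log mean predicts each gene's expected SD, observed values are scaled by
#' it (clipped at sqrt(n_cells)), and the variance of the scaled values is
#' the ranking statistic. Constant genes are never selected.
#'
#' @param normalized Genes x cells matrix (any monotone normalization).
#' @param n Number of genes to return.
#' @param loess_span Span of the mean-variance trend fit.
#' @return Character vector of gene names, ordered by decreasing
#'   standardized variance.
#' @export
select_hvg <- function(normalized, n = 2000L, loess_span = 0.3) {
  mat <- as.matrix(normalized)
  mu <- rowMeans(mat)
  v <- apply(mat, 1L, stats::var)
  ok <- v > 0 & mu > 0
  if (!any(ok)) return(character(0))
  fit <- stats::loess(log10(v[ok]) ~ log10(mu[ok]), span = loess_span,
                      degree = 2)
  exp_sd <- sqrt(10^stats::fitted(fit))
  clip <- sqrt(ncol(mat))
  std_var <- vapply(seq_along(which(ok)), function(j) {
    i <- which(ok)[j]
    z <- (mat[i, ] - mu[i]) / exp_sd[j]
    z <- pmin(z, clip)
    sum(z^2) / (ncol(mat) - 1L)
  }, numeric(1))
  names(std_var) <- rownames(mat)[ok]
  names(sort(std_var, decreasing = TRUE))[seq_len(min(n, sum(ok)))]
}

# Shared-nearest-neighbor graph from a cell embedding.
.snn_graph <- function(emb, k_neighbors, prune = 1 / 15) {
  n <- nrow(emb)
  k <- min(k_neighbors + 1L, n)
  nn <- RANN::nn2(emb, k = k)$nn.idx
  adj <- Matrix::sparseMatrix(i = rep(seq_len(n), ncol(nn)),
                              j = as.vector(nn), x = 1, dims = c(n, n))
  shared <- Matrix::tcrossprod(adj)
  jac <- shared / (2 * k - shared)
  jac@x[jac@x < prune] <- 0
  jac <- Matrix::drop0(jac)
  Matrix::diag(jac) <- 0
  igraph::graph_from_adjacency_matrix(jac, mode = "undirected",
                                      weighted = TRUE, diag = FALSE)
}

#' Cluster cells into transcriptional states
#'
#' PCA on the highly variable genes (gene-standardized, clipped), a shared
#' nearest-neighbor graph on the top `dims` components, and Louvain
#' modularity optimization at the given `resolution`. Labels are renumbered
#' by decreasing cluster size.
#'
#' @param normalized Log-normalized genes x cells matrix.
#' @param hvgs Gene names to use (default: all non-constant genes).
#' @param dims Number of principal components.
#' @param resolution Louvain resolution.
#' @param k_neighbors Neighbors for the SNN graph.
#' @param seed Seed controlling PCA initialization and Louvain.
#' @return Integer state labels, one per cell.
#' @export
cluster_states <- function(normalized, hvgs = NULL, dims = 14L,
                           resolution = 1.0, k_neighbors = 20L, seed = 1L) {
  mat <- as.matrix(normalized)
  if (is.null(hvgs)) hvgs <- rownames(mat)
  mat <- mat[intersect(hvgs, rownames(mat)), , drop = FALSE]
  sds <- apply(mat, 1L, stats::sd)
  mat <- mat[sds > 0, , drop = FALSE]
  n_cells <- ncol(mat)
  if (nrow(mat) == 0L) return(rep(1L, n_cells))   # all cells identical
  if (dims >= min(n_cells, nrow(mat)))
    stop("dims must be smaller than min(n_cells, n_genes)", call. = FALSE)
  z <- t(scale(t(mat)))
  z[z > 10] <- 10
  set.seed(as.integer(seed))
  emb <- if (min(dim(z)) > 3L * dims && min(dim(z)) > 50L) {
    pc <- irlba::prcomp_irlba(t(z), n = dims, center = FALSE, scale. = FALSE)
    pc$x
  } else {
    stats::prcomp(t(z), center = FALSE)$x[, seq_len(dims), drop = FALSE]
  }
  g <- .snn_graph(emb, k_neighbors)
  set.seed(as.integer(seed))
  cl <- igraph::cluster_louvain(g, resolution = resolution)
  lab <- as.integer(igraph::membership(cl))
  # renumber by decreasing size for stable, readable labels
  sizes <- sort(table(lab), decreasing = TRUE)
  as.integer(match(lab, as.integer(names(sizes))))
}

#' One-vs-rest cell-state markers
#'
#' For each state, tests every gene against all remaining cells with the
#' two-sided Wilcoxon rank-sum test, adjusts p-values by Benjamini-Hochberg
#' within the state, and reports log2 fold changes on de-logged means with a
#' small pseudocount. States with fewer than `min_cells` cells are skipped
#' with a warning.
#'
#' @param normalized Log-normalized genes x cells matrix.
#' @param labels Per-cell state labels.
#' @param lfc_cut,p_cut Significance rule for the `significant` flag
#'   (upregulated markers: `log2fc > lfc_cut` and `p_adj < p_cut`).
#' @param pseudo Pseudocount on de-logged means.
#' @param min_cells Minimum state size.
#' @return A `marker_table` data.frame: state, gene, log2fc, p, p_adj,
#'   pct_in, pct_out, direction, significant.
#' @export
find_markers <- function(normalized, labels, lfc_cut = 0.25, p_cut = 0.05,
                         pseudo = 1e-9, min_cells = 3L) {
  mat <- as.matrix(normalized)
  states <- sort(unique(labels))
  out <- list()
  for (s in states) {
    idx_in <- which(labels == s)
    idx_out <- which(labels != s)
    if (length(idx_in) < min_cells) {
      warning("state ", s, " has fewer than ", min_cells,
              " cells; skipped", call. = FALSE)
      next
    }
    p <- .wilcox_rows(mat, idx_in, idx_out)
    m_in <- rowMeans(expm1(mat[, idx_in, drop = FALSE]))
    m_out <- rowMeans(expm1(mat[, idx_out, drop = FALSE]))
    lfc <- log2((m_in + pseudo) / (m_out + pseudo))
    p_adj <- stats::p.adjust(p, "BH")
    out[[as.character(s)]] <- data.frame(
      state = s, gene = rownames(mat), log2fc = lfc, p = p, p_adj = p_adj,
      pct_in = rowMeans(mat[, idx_in, drop = FALSE] > 0),
      pct_out = rowMeans(mat[, idx_out, drop = FALSE] > 0),
      direction = ifelse(lfc >= 0, "up", "down"),
      significant = p_adj < p_cut & lfc > lfc_cut,
      stringsAsFactors = FALSE, row.names = NULL
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("marker_table", "data.frame")
  res
}

#' Differential expression with independent filtering
#'
#' Compares two cell groups gene-by-gene with the Wilcoxon rank-sum test
#' after removing genes with zero counts in both groups, then scans a grid
#' of mean-expression thresholds: for each threshold, genes below it are
#' filtered out before Benjamini-Hochberg adjustment and significant genes
#' (adjusted p < `alpha`) are counted. The threshold maximizing that count
#' (smallest on ties) is chosen and defines the reported adjusted p-values.
#'
#' @param group_a,group_b Genes x cells matrices for the two groups (same
#'   genes).
#' @param alpha Significance level on adjusted p-values.
#' @param n_grid Number of thresholds scanned (quantiles of per-gene means).
#' @param grid Optional explicit threshold grid overriding `n_grid`.
#' @param pseudo Pseudocount for fold changes.
#' @return A `de_result` list: `table` (gene, mean_count, log2fc, p, p_adj),
#'   `chosen_filter_threshold`, `n_significant`, and `scan` (threshold,
#'   n_significant over the grid).
#' @export
de_independent_filtering <- function(group_a, group_b, alpha = 0.05,
                                     n_grid = 100L, grid = NULL,
                                     pseudo = 1e-9) {
  a <- as.matrix(group_a); b <- as.matrix(group_b)
  if (ncol(a) < 3L || ncol(b) < 3L)
    stop("both groups need at least 3 cells", call. = FALSE)
  if (is.null(rownames(a))) {
    rn <- paste0("gene", seq_len(nrow(a)))
    rownames(a) <- rn
    rownames(b) <- rn
  }
  keep <- rowSums(a) + rowSums(b) > 0
  a <- a[keep, , drop = FALSE]; b <- b[keep, , drop = FALSE]
  both <- cbind(a, b)
  p <- .wilcox_rows(both, seq_len(ncol(a)), ncol(a) + seq_len(ncol(b)))
  m_a <- rowMeans(a); m_b <- rowMeans(b)
  lfc <- log2((m_a + pseudo) / (m_b + pseudo))
  mean_count <- rowMeans(both)
  if (is.null(grid))
    grid <- sort(unique(stats::quantile(mean_count,
                                        probs = seq(0, 1 - 1 / n_grid,
                                                    length.out = n_grid),
                                        names = FALSE)))
  n_sig <- vapply(grid, function(t) {
    pass <- mean_count >= t
    if (!any(pass)) return(0L)
    sum(stats::p.adjust(p[pass], "BH") < alpha)
  }, integer(1))
  chosen <- grid[which.max(n_sig)]   # which.max takes the first = smallest
  pass <- mean_count >= chosen
  p_adj <- rep(NA_real_, length(p))
  p_adj[pass] <- stats::p.adjust(p[pass], "BH")
  structure(list(
    table = data.frame(gene = rownames(both), mean_count = mean_count,
                       log2fc = lfc, p = p, p_adj = p_adj,
                       stringsAsFactors = FALSE, row.names = NULL),
    chosen_filter_threshold = chosen,
    n_significant = sum(p_adj < alpha, na.rm = TRUE),
    scan = data.frame(threshold = grid, n_significant = n_sig)
  ), class = "de_result")
}

#' Count differentially expressed genes
#'
#' @param table Data.frame with columns `log2fc` and `p`.
#' @param lfc_cut Absolute log2 fold-change threshold.
#' @param p_cut P-value threshold.
#' @return Named integer vector `c(n_up, n_down)`.
#' @export
count_de <- function(table, lfc_cut = 1, p_cut = 0.05) {
  if (is.null(table) || nrow(table) == 0L)
    return(c(n_up = 0L, n_down = 0L))
  c(n_up = sum(table$log2fc >= lfc_cut & table$p < p_cut, na.rm = TRUE),
    n_down = sum(table$log2fc <= -lfc_cut & table$p < p_cut, na.rm = TRUE))
}

#' Clone-level differential expression
#'
#' Within each genotype deep enough to support it (more than
#' `min_genotype_cells` cells), compares every clone with more than
#' `min_clone_cells` cells against the same genotype's remaining clones that
#' have at least `min_other_cells` cells (Wilcoxon + Benjamini-Hochberg per
#' comparison), reporting the number of differentially expressed genes per
#' clone.
#'
#' @param normalized Log-normalized genes x cells matrix.
#' @param genotypes,clones Per-cell genotype and clone labels.
#' @param min_genotype_cells,min_clone_cells,min_other_cells Size filters
#'   (strict for genotype and clone, at-least for comparison clones).
#' @param alpha Adjusted p-value threshold for counting DEGs.
#' @return Data.frame: genotype, clone, n_cells, n_deg.
#' @export
clone_de <- function(normalized, genotypes, clones,
                     min_genotype_cells = 200L, min_clone_cells = 9L,
                     min_other_cells = 3L, alpha = 0.05) {
  mat <- as.matrix(normalized)
  out <- list()
  for (g in names(which(table(genotypes) > min_genotype_cells))) {
    gi <- which(genotypes == g)
    ctab <- table(clones[gi])
    for (cl in names(which(ctab > min_clone_cells))) {
      others <- names(which(ctab >= min_other_cells))
      others <- setdiff(others, cl)
      if (!length(others)) next
      i1 <- gi[clones[gi] == cl]
      i2 <- gi[clones[gi] %in% others]
      keep <- rowSums(mat[, c(i1, i2), drop = FALSE]) > 0
      p <- .wilcox_rows(mat[keep, , drop = FALSE], i1, i2)
      out[[paste(g, cl)]] <- data.frame(
        genotype = g, clone = cl, n_cells = length(i1),
        n_deg = sum(stats::p.adjust(p, "BH") < alpha),
        stringsAsFactors = FALSE
      )
    }
  }
  res <- if (length(out)) do.call(rbind, out)
         else data.frame(genotype = character(0), clone = character(0),
                         n_cells = integer(0), n_deg = integer(0))
  rownames(res) <- NULL
  res
}

#' Rank-based signature score
#'
#' Scores a gene signature per cell from expression ranks alone: genes are
#' ranked by decreasing expression (average ranks on ties), ranks beyond
#' `r_max` are clipped to `r_max + 1`, and the score is
#' `1 - U / (n * r_max)` floored at 0, where `U` is the Mann-Whitney U of
#' the signature ranks. Scores lie in `[0, 1]`; 1 means the signature genes
#' occupy the top ranks.
#'
#' @param normalized Genes x cells matrix.
#' @param gene_set Signature gene names.
#' @param r_max Rank ceiling.
#' @return Numeric per-cell score in `[0, 1]`.
#' @export
score_signature_rank <- function(normalized, gene_set, r_max = 1500L) {
  genes <- intersect(gene_set, rownames(normalized))
  if (length(genes) == 0L)
    stop("gene_set has no genes in the matrix", call. = FALSE)
  mat <- as.matrix(normalized)
  n <- length(genes)
  apply(mat, 2L, function(v) {
    r <- rank(-v, ties.method = "average")
    r[r > r_max] <- r_max + 1
    U <- sum(r[match(genes, rownames(mat))]) - n * (n + 1) / 2
    max(0, 1 - U / (n * r_max))
  })
}
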