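#' Filter genes on raw mean expression
#'
#' Keeps genes whose mean raw count per cell is strictly greater than
#' `min_mean` (default 0.25 UMI counts per cell), the gene universe used for
#' leverage scoring.
#'
#' @param counts Genes x cells count matrix.
#' @param min_mean Strict lower bound on the per-gene mean count.
#' @return Character vector of passing gene names (or indices when the
#'   matrix is unnamed).
#' @export
filter_genes_mean <- function(counts, min_mean = 0.25) {
  mu <- Matrix::rowMeans(counts)
  pass <- which(mu > min_mean)
  if (length(pass) == 0L)
    stop("no genes pass the mean-expression filter (> ", min_mean, ")",
         call. = FALSE)
  if (!is.null(rownames(counts))) rownames(counts)[pass] else pass
}

#' Per-cell SVD leverage scores for one plate
#'
#' Computes the top `k` left singular vectors of the cells x genes
#' expression submatrix of a plate (partial SVD) and returns each cell's raw
#' leverage (row-wise squared norm of the singular-vector matrix) and its
#' normalized leverage (raw divided by the plate total, so normalized
#' leverages sum to 1 per plate). When the matrix supports fewer than `k`
#' components, `k' = min(k, n_cells - 1, n_genes - 1)` is used and recorded.
#'
#' @param mat Cells x genes matrix (one plate), typically log-normalized
#'   expression.
#' @param k Number of singular vectors.
#' @return A list with `raw`, `normalized`, `k_used`.
#' @export
plate_leverage <- function(mat, k = 20L) {
  mat <- as.matrix(mat)
  n <- nrow(mat); g <- ncol(mat)
  if (n < 2L) stop("a plate needs at least 2 cells", call. = FALSE)
  if (sum(mat^2) == 0) stop("rank-0 matrix: no expression", call. = FALSE)
  k_used <- min(k, n - 1L, g - 1L)
  if (k_used < 1L) stop("matrix too small for any singular vector",
                        call. = FALSE)
  if (k_used < 0.5 * min(n, g) && min(n, g) > 50L) {
    sv <- irlba::irlba(mat, nv = k_used, nu = k_used, tol = 1e-10,
                       maxit = 2000L)
    U <- sv$u
  } else {
    U <- svd(mat, nu = k_used, nv = 0L)$u
  }
  raw <- rowSums(U^2)
  list(raw = raw, normalized = raw / sum(raw), k_used = k_used)
}

#' Leverage scores across plates
#'
#' Applies [plate_leverage()] plate by plate on the gene-filtered expression
#' matrix and collects per-cell raw and normalized leverage.
#'
#' @param normalized Genes x cells log-normalized matrix.
#' @param plates Per-cell plate labels.
#' @param genes Optional gene subset (e.g. from [filter_genes_mean()]).
#' @param k Singular vectors per plate.
#' @return Data.frame: cell (column name or index), plate, raw_leverage,
#'   normalized_leverage, k_used.
#' @export
compute_leverage <- function(normalized, plates, genes = NULL, k = 20L) {
  if (!is.null(genes))
    normalized <- normalized[intersect(genes, rownames(normalized)), ,
                             drop = FALSE]
  cells <- colnames(normalized) %||% as.character(seq_len(ncol(normalized)))
  out <- lapply(unique(plates), function(p) {
    idx <- which(plates == p)
    lv <- plate_leverage(t(as.matrix(normalized[, idx, drop = FALSE])), k = k)
    data.frame(cell = cells[idx], plate = p, raw_leverage = lv$raw,
               normalized_leverage = lv$normalized, k_used = lv$k_used,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res[match(cells, res$cell), , drop = FALSE]
}

#' Scale leverage scores to wild type within each plate
#'
#' Log-transforms the normalized leverage scores and z-scores them per plate
#' against the plate's wild-type cells (subtracting the WT mean and dividing
#' by the WT standard deviation of the log scores), so WT cells have mean 0
#' and SD 1 on every plate.
#'
#' @param normalized_leverage Per-cell normalized leverage.
#' @param plates Per-cell plate labels.
#' @param wt_mask Logical per-cell wild-type indicator.
#' @return Numeric per-cell scaled leverage (z).
#' @export
scale_leverage <- function(normalized_leverage, plates, wt_mask) {
  z <- rep(NA_real_, length(normalized_leverage))
  lg <- log(normalized_leverage)
  for (p in unique(plates)) {
    idx <- which(plates == p)
    wt <- idx[wt_mask[idx]]
    if (length(wt) < 2L)
      stop("plate ", p, " has fewer than 2 wild-type cells", call. = FALSE)
    s <- stats::sd(lg[wt])
    if (!is.finite(s) || s == 0)
      stop("plate ", p, ": wild-type leverage has zero variance",
           call. = FALSE)
    z[idx] <- (lg[idx] - mean(lg[wt])) / s
  }
  z
}

#' Per-genotype heterogeneity from scaled leverage
#'
#' Summarizes each genotype with at least `min_cells` cells by the sample
#' standard deviation of its cells' scaled leverage, divided by the pooled
#' wild-type SD so that wild type equals 1 exactly, and classifies
#' heterogeneity regulators with [classify_regulators()].
#'
#' @param z Per-cell scaled leverage (from [scale_leverage()]).
#' @param genotypes Per-cell genotype labels.
#' @param wt_label Wild-type genotype label.
#' @param min_cells Minimum genotype size.
#' @param up,down Regulator thresholds passed to [classify_regulators()].
#' @return Data.frame: genotype, n_cells, sd_scaled, class.
#' @export
genotype_heterogeneity <- function(z, genotypes, wt_label = "WT",
                                   min_cells = 6L, up = 1.3, down = 0.7) {
  if (!wt_label %in% genotypes)
    stop("no cells labeled ", wt_label, call. = FALSE)
  sd_wt <- stats::sd(z[genotypes == wt_label])
  sizes <- table(genotypes)
  keep <- names(sizes)[sizes >= min_cells]
  sd_g <- vapply(keep, function(g) stats::sd(z[genotypes == g]), numeric(1))
  res <- data.frame(
    genotype = keep, n_cells = as.integer(sizes[keep]),
    sd_scaled = sd_g / sd_wt, stringsAsFactors = FALSE, row.names = NULL
  )
  res$sd_scaled[res$genotype == wt_label] <- 1   # exact by definition
  res$class <- classify_regulators(res$sd_scaled, up = up, down = down)
  res
}

#' Classify heterogeneity regulators
#'
#' Genotypes whose scaled-leverage SD is at least `up` times the wild type
#' are negative regulators (their loss increases heterogeneity); those at or
#' below `down` are positive regulators; the rest are `ns`.
#'
#' @param sd_scaled Per-genotype WT-scaled leverage SD.
#' @param up,down Classification thresholds.
#' @return Character vector in
#'   `{"negative_regulator","positive_regulator","ns"}`.
#' @export
classify_regulators <- function(sd_scaled, up = 1.3, down = 0.7) {
  ifelse(sd_scaled >= up, "negative_regulator",
         ifelse(sd_scaled <= down, "positive_regulator", "ns"))
}

#' Full leverage-score heterogeneity analysis
#'
#' Convenience wrapper: gene filter on raw means, per-plate partial-SVD
#' leverage on the log-normalized matrix, WT z-scaling per plate, and
#' per-genotype summary with regulator classes.
#'
#' @param counts Genes x cells raw counts (for the mean filter).
#' @param normalized Genes x cells log-normalized expression.
#' @param plates,genotypes Per-cell labels.
#' @param wt_label Wild-type genotype label.
#' @param k Singular vectors per plate.
#' @param min_mean Gene filter on raw mean counts.
#' @param min_cells Minimum genotype size for the summary.
#' @param up,down Regulator thresholds.
#' @return A list with `cells` (per-cell leverage table incl. `scaled_leverage`)
#'   and `genotypes` (per-genotype summary).
#' @export
leverage_analysis <- function(counts, normalized, plates, genotypes,
                              wt_label = "WT", k = 20L, min_mean = 0.25,
                              min_cells = 6L, up = 1.3, down = 0.7) {
  genes <- filter_genes_mean(counts, min_mean)
  cells <- compute_leverage(normalized, plates, genes = genes, k = k)
  cells$scaled_leverage <- scale_leverage(cells$normalized_leverage, plates,
                                          genotypes == wt_label)
  cells$genotype <- genotypes
  geno <- genotype_heterogeneity(cells$scaled_leverage, genotypes,
                                 wt_label = wt_label, min_cells = min_cells,
                                 up = up, down = down)
  list(cells = cells, genotypes = geno)
}
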