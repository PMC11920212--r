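#' Marker-set overlap between conditions
#'
#' For each pair of states across two conditions, tests whether their
#' upregulated marker sets overlap more than expected from a common gene
#' universe, with the two-sided Fisher exact test on the 2x2 overlap table;
#' p-values are Benjamini-Hochberg adjusted across all pairs. Pairs
#' involving an empty marker set get p = 1 and are flagged.
#'
#' @param markers_a,markers_b Named lists of marker gene sets (one per
#'   state) for the two conditions.
#' @param universe_size Size of the gene universe both sets are drawn from.
#' @return Data.frame: state_a, state_b, overlap, size_a, size_b,
#'   odds_ratio, p, p_adj, empty_set.
#' @export
marker_overlap <- function(markers_a, markers_b, universe_size) {
  union_max <- max(0L, vapply(seq_along(markers_a), function(i)
    max(vapply(seq_along(markers_b), function(j)
      length(union(markers_a[[i]], markers_b[[j]])), integer(1))),
    integer(1)))
  if (universe_size < union_max)
    stop("universe_size smaller than the union of marker sets",
         call. = FALSE)
  rows <- list()
  for (i in seq_along(markers_a)) {
    for (j in seq_along(markers_b)) {
      A <- unique(markers_a[[i]]); B <- unique(markers_b[[j]])
      ov <- length(intersect(A, B))
      empty <- length(A) == 0L || length(B) == 0L
      if (empty) {
        ft <- list(p_value = 1, odds_ratio = NA_real_)
      } else {
        ft <- fisher_2x2(ov, length(A) - ov, length(B) - ov,
                         universe_size - length(A) - length(B) + ov)
      }
      rows[[paste(i, j)]] <- data.frame(
        state_a = names(markers_a)[i] %||% as.character(i),
        state_b = names(markers_b)[j] %||% as.character(j),
        overlap = ov, size_a = length(A), size_b = length(B),
        odds_ratio = ft$odds_ratio, p = ft$p_value, empty_set = empty,
        stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res$p_adj <- bh_adjust(res$p)
  res
}

#' Transfer reference state labels onto a query dataset
#'
#' Re-implements label transfer as PCA projection plus k-nearest-neighbor
#' majority vote: the excluded genes (e.g. stress-program markers) are
#' removed from both datasets, both are depth-normalized and
#' log-transformed, principal components are fit on the reference and the
#' query is projected into them, and each query cell takes the majority
#' state among its `k_neighbors` nearest reference cells (ties resolve to
#' the single nearest neighbor's label).
#'
#' @param ref_counts,query_counts Genes x cells count matrices sharing a
#'   gene space.
#' @param ref_labels Per-reference-cell state labels.
#' @param query_labels Optional query-side cluster labels; when given, the
#'   cross-tabulation of transferred vs. query labels is returned as a
#'   transfer map for [core_states()].
#' @param excluded_genes Genes removed from both datasets before transfer.
#' @param dims Principal components used.
#' @param k_neighbors Reference neighbors voting per query cell.
#' @param seed Seed for the PCA initialization.
#' @return A list with `labels` (per query cell), and when `query_labels`
#'   is supplied, `map`: a `transfer_map` with row-stochastic proportion
#'   matrices `ref_to_query` and `query_to_ref`.
#' @export
transfer_labels <- function(ref_counts, ref_labels, query_counts,
                            query_labels = NULL,
                            excluded_genes = character(0), dims = 14L,
                            k_neighbors = 30L, seed = 1L) {
  shared <- intersect(rownames(ref_counts), rownames(query_counts))
  shared <- setdiff(shared, excluded_genes)
  if (length(shared) == 0L)
    stop("no genes remain after exclusion", call. = FALSE)
  if (k_neighbors > ncol(ref_counts))
    stop("k_neighbors exceeds the number of reference cells", call. = FALSE)
  ref <- as.matrix(normalize_log1p(ref_counts[shared, , drop = FALSE]))
  qry <- as.matrix(normalize_log1p(query_counts[shared, , drop = FALSE]))
  mu <- rowMeans(ref)
  sds <- apply(ref, 1L, stats::sd)
  keep <- sds > 0
  ref <- (ref[keep, ] - mu[keep]) / sds[keep]
  qry <- (qry[keep, ] - mu[keep]) / sds[keep]
  dims <- min(dims, ncol(ref) - 1L, sum(keep) - 1L)
  set.seed(as.integer(seed))
  pc <- if (min(dim(ref)) > 3L * dims && min(dim(ref)) > 50L)
    irlba::prcomp_irlba(t(ref), n = dims, center = FALSE, scale. = FALSE)
  else {
    p <- stats::prcomp(t(ref), center = FALSE)
    p$rotation <- p$rotation[, seq_len(dims), drop = FALSE]
    p$x <- p$x[, seq_len(dims), drop = FALSE]
    p
  }
  ref_emb <- pc$x
  qry_emb <- t(qry) %*% pc$rotation
  nn <- RANN::nn2(ref_emb, qry_emb, k = min(k_neighbors, nrow(ref_emb)))
  lab_mat <- matrix(as.character(ref_labels)[nn$nn.idx], nrow = nrow(nn$nn.idx))
  labels <- vapply(seq_len(nrow(lab_mat)), function(i) {
    tab <- table(lab_mat[i, ])
    best <- names(tab)[tab == max(tab)]
    if (length(best) > 1L) lab_mat[i, 1L] else best
  }, character(1))
  out <- list(labels = labels)
  if (!is.null(query_labels)) {
    tab <- table(transferred = labels, query = as.character(query_labels))
    out$map <- structure(list(
      ref_to_query = prop.table(tab, 1L),
      query_to_ref = t(prop.table(tab, 2L))
    ), class = "transfer_map")
  }
  out
}

#' Classify core versus responsive states
#'
#' A reference state is a core state when at least `min_share` (40%) of its
#' transferred cells concentrate in a single query-side state (its modal
#' counterpart), or when it is manually listed in `overrides`.
#'
#' @param map A `transfer_map` from [transfer_labels()] (or any list with a
#'   row-stochastic `ref_to_query` matrix).
#' @param min_share Minimum modal share for core classification.
#' @param overrides States forced to core regardless of share.
#' @return Data.frame: state, max_share, matched_state, core.
#' @export
core_states <- function(map, min_share = 0.4, overrides = character(0)) {
  pm <- map$ref_to_query
  max_share <- apply(pm, 1L, max)
  matched <- colnames(pm)[apply(pm, 1L, which.max)]
  data.frame(
    state = rownames(pm), max_share = as.numeric(max_share),
    matched_state = matched,
    core = max_share >= min_share | rownames(pm) %in% overrides,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Permutation test of fitness for a genotype set
#'
#' Compares the mean fitness of a genotype set against `n_perm` random
#' equal-size sets drawn from the remaining (unclassified) genotypes, one
#' stressor at a time. The p-value uses the add-one convention,
#' `p = (1 + extreme) / (n_perm + 1)`, so it is never 0.
#'
#' @param genotype_set Genotype ids to test.
#' @param fitness_table Data.frame with a `genotype` column and one numeric
#'   column per stressor.
#' @param n_perm Number of permutations.
#' @param side `"less"` (is the set mean lower than random sets?) or
#'   `"greater"`.
#' @param seed Seed for the permutation draws.
#' @return Named numeric p-values, one per stressor.
#' @export
fitness_permutation <- function(genotype_set, fitness_table, n_perm = 1000L,
                                side = c("less", "greater"), seed = 1L) {
  side <- match.arg(side)
  if (n_perm < 1L) stop("n_perm must be >= 1", call. = FALSE)
  if (anyDuplicated(fitness_table$genotype))
    stop("fitness_table has duplicated genotype rows", call. = FALSE)
  if (!all(genotype_set %in% fitness_table$genotype))
    stop("genotype_set contains genotypes absent from the table",
         call. = FALSE)
  in_set <- fitness_table$genotype %in% genotype_set
  bg <- which(!in_set)
  k <- sum(in_set)
  if (k > length(bg))
    stop("genotype_set larger than the background of unclassified genotypes",
         call. = FALSE)
  stressors <- names(fitness_table)[vapply(fitness_table, is.numeric,
                                           logical(1))]
  set.seed(as.integer(seed))
  draws <- replicate(n_perm, sample(bg, k))
  vapply(stressors, function(sc) {
    v <- fitness_table[[sc]]
    obs <- mean(v[in_set])
    perm <- colMeans(matrix(v[draws], nrow = k))
    extreme <- if (side == "less") sum(perm <= obs) else sum(perm >= obs)
    (1 + extreme) / (n_perm + 1)
  }, numeric(1))
}

#' Synthetic genotype-by-stressor fitness table
#'
#' Stand-in for an external fitness screen: iid standard-normal fitness
#' scores per genotype and stressor (exchangeable across genotypes).
#'
#' @param genotype_ids Genotype identifiers (unique).
#' @param stressors Stressor names.
#' @param seed Seed.
#' @return Data.frame with `genotype` plus one numeric column per stressor.
#' @export
gen_fitness_table <- function(genotype_ids,
                              stressors = paste0("stressor", 1:14),
                              seed = 1L) {
  stopifnot(!anyDuplicated(genotype_ids))
  set.seed(as.integer(seed))
  out <- data.frame(genotype = genotype_ids, stringsAsFactors = FALSE)
  for (s in stressors) out[[s]] <- stats::rnorm(length(genotype_ids))
  out
}
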