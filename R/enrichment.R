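#' Fisher exact test for a 2x2 table
#'
#' Two-sided exact test with fixed margins: the p-value is the sum of
#' hypergeometric probabilities of all tables at least as improbable as the
#' observed one. The odds ratio is the sample cross-product ratio
#' `(a*d)/(b*c)`; when any cell is zero the Haldane-Anscombe correction
#' (+0.5 to every cell) is applied to the odds ratio only and flagged.
#'
#' @param a,b,c,d Non-negative integer cell counts; rows = group in/out,
#'   columns = condition in/out.
#' @return A list with `p_value`, `odds_ratio`, `haldane` (logical flag).
#' @examples
#' fisher_2x2(1, 1, 1, 1)   # p = 1, OR = 1
#' @export
fisher_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells)))
    stop("cell counts must be non-negative integers", call. = FALSE)
  n <- sum(cells)
  if (n < 1) stop("table total must be >= 1", call. = FALSE)
  m1 <- a + b   # row 1 margin
  c1 <- a + c   # column 1 margin
  lo <- max(0L, c1 - (n - m1))
  hi <- min(m1, c1)
  support <- lo:hi
  probs <- stats::dhyper(support, m1, n - m1, c1)
  p_obs <- stats::dhyper(a, m1, n - m1, c1)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  hal <- b * c == 0 || a * d == 0
  or <- if (hal) ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c + 0.5))
        else (a * d) / (b * c)
  list(p_value = min(1, p), odds_ratio = or, haldane = hal)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment (`p * m / i` with monotone
#' enforcement, capped at 1).
#'
#' @param p_values Numeric p-values.
#' @return Adjusted p-values in the input order.
#' @export
bh_adjust <- function(p_values) {
  stats::p.adjust(p_values, method = "BH")
}

#' Genotype-by-state enrichment
#'
#' Tests every genotype with at least `min_cells` cells for enrichment or
#' depletion in every cell state with a two-sided Fisher exact test on the
#' 2x2 table (in state & genotype, out of state & genotype; in state &
#' other, out of state & other). P-values are Benjamini-Hochberg adjusted,
#' by default across all genotype x state tests. A genotype is `enriched` in
#' a state when the odds ratio exceeds 1 at adjusted p < `alpha`, `depleted`
#' when the odds ratio is below 1 at adjusted p < `alpha`, otherwise `ns`.
#'
#' @param states Per-cell state labels.
#' @param genotypes Per-cell genotype labels.
#' @param min_cells Minimum genotype size; smaller genotypes are excluded
#'   and listed in the `excluded` attribute.
#' @param alpha Significance level on adjusted p-values.
#' @param bh_scope `"global"` (all tests; default) or `"per_state"`.
#' @return An `enrichment_table` data.frame: genotype, state, a, b, c, d,
#'   odds_ratio, p, p_adj, class.
#' @export
state_enrichment <- function(states, genotypes, min_cells = 6L,
                             alpha = 0.05, bh_scope = c("global", "per_state")) {
  bh_scope <- match.arg(bh_scope)
  if (length(states) != length(genotypes))
    stop("states and genotypes must be aligned per cell", call. = FALSE)
  st_levels <- sort(unique(states))
  if (length(st_levels) < 2L)
    stop("at least two states are required", call. = FALSE)
  sizes <- table(genotypes)
  keep <- names(sizes)[sizes >= min_cells]
  excluded <- setdiff(names(sizes), keep)
  tab <- table(factor(genotypes, levels = keep),
               factor(states, levels = st_levels))
  state_tot <- colSums(tab)
  n <- sum(tab)
  rows <- list()
  for (g in keep) {
    g_tot <- sum(tab[g, ])
    for (s in seq_along(st_levels)) {
      a <- tab[g, s]
      b <- g_tot - a
      cc <- state_tot[s] - a
      d <- n - g_tot - cc
      ft <- fisher_2x2(a, b, cc, d)
      rows[[paste(g, s)]] <- data.frame(
        genotype = g, state = st_levels[s],
        a = as.integer(a), b = as.integer(b), c = as.integer(cc),
        d = as.integer(d), odds_ratio = ft$odds_ratio, p = ft$p_value,
        stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res$p_adj <- if (bh_scope == "global") bh_adjust(res$p)
               else stats::ave(res$p, res$state, FUN = bh_adjust)
  res$class <- ifelse(res$p_adj < alpha & res$odds_ratio > 1, "enriched",
                      ifelse(res$p_adj < alpha & res$odds_ratio < 1,
                             "depleted", "ns"))
  attr(res, "excluded") <- excluded
  class(res) <- c("enrichment_table", "data.frame")
  res
}
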