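#' Find all mismatch-tolerant matches of a pattern
#'
#' Returns the 1-based start positions of every window of `seq` whose
#' Hamming distance to `pattern` is at most `max_mm` (substitutions only),
#' in ascending order.
#'
#' @param seq Subject DNA string.
#' @param pattern Query string; must be non-empty.
#' @param max_mm Maximum mismatches allowed.
#' @return Integer vector of start positions (possibly empty).
#' @examples
#' find_pattern("ACGACG", "ACG", 0)  # 1, 4
#' @export
find_pattern <- function(seq, pattern, max_mm = 0L) {
  if (!nzchar(pattern)) stop("pattern must be non-empty", call. = FALSE)
  if (max_mm < 0L) stop("max_mm must be >= 0", call. = FALSE)
  np <- nchar(pattern); ns <- nchar(seq)
  if (np > ns) return(integer(0))
  sr <- charToRaw(seq); pr <- charToRaw(pattern)
  starts <- seq_len(ns - np + 1L)
  mm <- vapply(starts, function(i) sum(sr[i:(i + np - 1L)] != pr), integer(1))
  starts[mm <= max_mm]
}

# Vectorized variant over many equal-length reads: returns an integer matrix
# n_reads x n_windows of mismatch counts for `pattern` at each window start.
.window_mismatches <- function(seq_mat, pattern) {
  pr <- charToRaw(pattern); np <- length(pr)
  L <- ncol(seq_mat)
  n_win <- L - np + 1L
  mm <- matrix(0L, nrow(seq_mat), n_win)
  for (j in seq_len(np)) {
    block <- seq_mat[, j:(j + n_win - 1L), drop = FALSE] != pr[j]
    mm <- mm + block
  }
  mm
}

# Reads as a raw-byte matrix (all reads must share one length).
.seq_matrix <- function(seqs) {
  L <- nchar(seqs)
  stopifnot(length(unique(L)) == 1L)
  matrix(unlist(lapply(seqs, charToRaw), use.names = FALSE),
         nrow = length(seqs), ncol = L[1L], byrow = TRUE)
}

#' Select one anchor position among multiple matches
#'
#' When an anchor sequence matches a read more than once, the match with the
#' maximum start position is used.
#'
#' @param starts Integer vector of candidate start positions.
#' @return The maximum position, or `NA_integer_` when empty.
#' @export
select_anchor <- function(starts) {
  if (length(starts) == 0L) return(NA_integer_)
  max(starts)
}

#' Parse a targeted-amplicon read
#'
#' Locates the D2 (upstream) and D1 (downstream) anchors allowing up to
#' `max_mm` mismatches, keeps the rightmost match of each, and applies the
#' positional filters: the clone barcode is read at `clone_window`
#' (positions 21-25), the D2 start must fall in `d2_window` (48-51) and the
#' D1 start in `d1_window` (85-90). The genotype region is the substring
#' strictly between the D2 anchor end and the D1 anchor start. Reads failing
#' any step are flagged invalid with a reason code (`too_short`,
#' `missing_anchor`, `position_filter`).
#'
#' @param read2_seq Amplicon read sequence (single string).
#' @param d2_anchor,d1_anchor Anchor sequences; defaults are the terminal
#'   18 nt of the cassette linker and the 17-nt downstream flank.
#' @param max_mm Maximum anchor mismatches.
#' @param d2_window,d1_window Inclusive 1-based windows for anchor starts.
#' @param clone_window Inclusive window of the clone barcode.
#' @return A list with `clone_seq`, `genotype_region`, `d1_start`,
#'   `d2_start`, `valid`, `reason`.
#' @export
parse_read <- function(read2_seq, d2_anchor = YKO_D2_ANCHOR,
                       d1_anchor = YKO_D1_ANCHOR, max_mm = 3L,
                       d2_window = c(48L, 51L), d1_window = c(85L, 90L),
                       clone_window = c(21L, 25L)) {
  out <- list(clone_seq = NA_character_, genotype_region = NA_character_,
              d1_start = NA_integer_, d2_start = NA_integer_,
              valid = FALSE, reason = NA_character_)
  min_len <- d1_window[1L] + nchar(d1_anchor) - 1L
  if (nchar(read2_seq) < min_len) {
    out$reason <- "too_short"
    return(out)
  }
  d2 <- select_anchor(find_pattern(read2_seq, d2_anchor, max_mm))
  d1 <- select_anchor(find_pattern(read2_seq, d1_anchor, max_mm))
  out$d2_start <- d2; out$d1_start <- d1
  if (is.na(d2) || is.na(d1)) {
    out$reason <- "missing_anchor"
    return(out)
  }
  if (d2 < d2_window[1L] || d2 > d2_window[2L] ||
      d1 < d1_window[1L] || d1 > d1_window[2L]) {
    out$reason <- "position_filter"
    return(out)
  }
  geno_start <- d2 + nchar(d2_anchor)
  if (geno_start > d1 - 1L) {
    out$reason <- "position_filter"
    return(out)
  }
  out$clone_seq <- substr(read2_seq, clone_window[1L], clone_window[2L])
  out$genotype_region <- substr(read2_seq, geno_start, d1 - 1L)
  out$valid <- TRUE
  out
}

# Vectorized read parsing over equal-length reads; returns a data.frame.
parse_reads <- function(read2_seqs, d2_anchor = YKO_D2_ANCHOR,
                        d1_anchor = YKO_D1_ANCHOR, max_mm = 3L,
                        d2_window = c(48L, 51L), d1_window = c(85L, 90L),
                        clone_window = c(21L, 25L)) {
  n <- length(read2_seqs)
  res <- data.frame(clone_seq = rep(NA_character_, n),
                    genotype_region = NA_character_,
                    d1_start = NA_integer_, d2_start = NA_integer_,
                    valid = FALSE, reason = NA_character_,
                    stringsAsFactors = FALSE)
  if (n == 0L) return(res)
  min_len <- d1_window[1L] + nchar(d1_anchor) - 1L
  lens <- nchar(read2_seqs)
  short <- lens < min_len
  res$reason[short] <- "too_short"
  keep <- which(!short)
  if (!length(keep)) return(res)
  if (length(unique(lens[keep])) != 1L) {
    # fall back to the scalar parser on ragged input
    for (i in keep) res[i, ] <- parse_read(read2_seqs[i], d2_anchor, d1_anchor,
                                           max_mm, d2_window, d1_window,
                                           clone_window)
    return(res)
  }
  sm <- .seq_matrix(read2_seqs[keep])
  d2mm <- .window_mismatches(sm, d2_anchor)
  d1mm <- .window_mismatches(sm, d1_anchor)
  last_hit <- function(mm) {
    hit <- mm <= max_mm
    pos <- max.col(hit, ties.method = "last")
    pos[!hit[cbind(seq_len(nrow(hit)), pos)]] <- NA_integer_
    pos
  }
  d2 <- last_hit(d2mm); d1 <- last_hit(d1mm)
  res$d2_start[keep] <- d2; res$d1_start[keep] <- d1
  miss <- is.na(d2) | is.na(d1)
  res$reason[keep][miss] <- "missing_anchor"
  badpos <- !miss & (d2 < d2_window[1L] | d2 > d2_window[2L] |
                     d1 < d1_window[1L] | d1 > d1_window[2L] |
                     d2 + nchar(d2_anchor) > d1 - 1L)
  res$reason[keep][badpos] <- "position_filter"
  ok <- !miss & !badpos
  oki <- keep[ok]
  res$valid[oki] <- TRUE
  res$clone_seq[oki] <- substr(read2_seqs[oki], clone_window[1L],
                               clone_window[2L])
  res$genotype_region[oki] <- substr(read2_seqs[oki],
                                     d2[ok] + nchar(d2_anchor), d1[ok] - 1L)
  res
}

#' Call a genotype from an extracted barcode region
#'
#' Compares the genotype region against every library barcode allowing up to
#' `max_mm` mismatches (whole-region Hamming when lengths match, windowed
#' search otherwise). A unique hit returns that genotype; zero hits or two
#' or more hits return `NA` (ambiguity is recorded in the `reason`
#' attribute).
#'
#' @param genotype_region Extracted DNA region.
#' @param library A `barcode_library`.
#' @param max_mm Maximum mismatches to a library barcode.
#' @return Genotype id, or `NA_character_` with attribute `reason` in
#'   `no_hit` / `ambiguous`.
#' @export
call_genotype <- function(genotype_region, library, max_mm = 2L) {
  if (is.na(genotype_region) || !nzchar(genotype_region))
    stop("genotype_region must be non-empty", call. = FALSE)
  bcs <- library$genotype_barcode
  if (nchar(genotype_region) == nchar(bcs[1L])) {
    rr <- charToRaw(genotype_region)
    d <- vapply(bcs, function(b) sum(charToRaw(b) != rr), integer(1))
    hits <- which(d <= max_mm)
  } else {
    hits <- which(vapply(bcs, function(b) {
      if (nchar(b) <= nchar(genotype_region))
        length(find_pattern(genotype_region, b, max_mm)) > 0L
      else length(find_pattern(b, genotype_region, max_mm)) > 0L
    }, logical(1)))
  }
  if (length(hits) == 1L) return(library$genotype_id[hits])
  structure(NA_character_,
            reason = if (length(hits) == 0L) "no_hit" else "ambiguous")
}

#' Aggregate per-read genotype calls into one cell-level call
#'
#' A cell observing a single genotype is assigned to it. A cell observing
#' several genotypes is assigned to one only if it is supported by strictly
#' more than `majority` (70%) of the genotype-informative reads; otherwise
#' the cell is discarded (`discarded_multi`). Zero informative reads give
#' `unassigned`. The clone is the majority clone among reads supporting the
#' assigned genotype; ties break to the lexicographically smallest clone and
#' are flagged.
#'
#' @param genotype_calls Character vector of per-read genotype calls
#'   (`NA` = uninformative read).
#' @param clone_calls Optional per-read clone barcodes, aligned with
#'   `genotype_calls`.
#' @param majority Majority fraction; assignment requires support
#'   strictly above it.
#' @param source Label for the calling route.
#' @return A list of class `cell_call`: `genotype`, `status`
#'   (`assigned` / `unassigned` / `discarded_multi`), `clone`, `clone_tie`,
#'   `read_support` (named counts), `source`.
#' @export
aggregate_cell <- function(genotype_calls, clone_calls = NULL,
                           majority = 0.70, source = "amplicon") {
  inf <- !is.na(genotype_calls)
  support <- table(genotype_calls[inf])
  out <- list(genotype = NA_character_, status = "unassigned",
              clone = NA_character_, clone_tie = FALSE,
              read_support = support, source = source)
  class(out) <- "cell_call"
  if (length(support) == 0L) return(out)
  if (length(support) == 1L) {
    out$genotype <- names(support)
    out$status <- "assigned"
  } else {
    top <- which.max(support)
    if (support[top] > majority * sum(support)) {
      out$genotype <- names(support)[top]
      out$status <- "assigned"
    } else {
      out$status <- "discarded_multi"
      return(out)
    }
  }
  if (!is.null(clone_calls)) {
    cl <- clone_calls[inf & genotype_calls == out$genotype]
    cl <- cl[!is.na(cl)]
    if (length(cl)) {
      tab <- table(cl)
      best <- names(tab)[tab == max(tab)]
      out$clone <- sort(best)[1L]
      out$clone_tie <- length(best) > 1L
    }
  }
  out
}

#' Call a genotype from expression-matrix contig counts
#'
#' Applies the same strict-majority rule as the amplicon route to per-cell
#' UMI counts over the `bc-` genotype contigs.
#'
#' @param umi_counts Named numeric vector of contig UMI counts for one cell;
#'   names are genotype ids (a leading `"bc-"` prefix is stripped).
#' @param majority Majority fraction.
#' @return A `cell_call` (see [aggregate_cell()]).
#' @export
matrix_call <- function(umi_counts, majority = 0.70) {
  umi_counts <- umi_counts[umi_counts > 0]
  ids <- sub("^bc-", "", names(umi_counts))
  calls <- rep(ids, times = umi_counts)
  aggregate_cell(if (length(calls)) calls else NA_character_,
                 majority = majority, source = "matrix")
}

#' Merge amplicon and expression-matrix genotype calls
#'
#' Cells assigned the same genotype by both routes keep it (source "both");
#' cells assigned different genotypes are marked `conflicted` and must be
#' omitted downstream; cells assigned by exactly one route take that call.
#'
#' @param amplicon_call,matrix_call `cell_call` objects (or `NULL`).
#' @return A merged `cell_call` with `status` possibly `conflicted`.
#' @export
merge_sources <- function(amplicon_call, matrix_call = NULL) {
  a <- amplicon_call; m <- matrix_call
  a_ok <- !is.null(a) && identical(a$status, "assigned")
  m_ok <- !is.null(m) && identical(m$status, "assigned")
  if (a_ok && m_ok) {
    if (identical(a$genotype, m$genotype)) {
      out <- a; out$source <- "both"
      return(out)
    }
    out <- list(genotype = NA_character_, status = "conflicted",
                clone = NA_character_, clone_tie = FALSE,
                read_support = a$read_support, source = "both")
    class(out) <- "cell_call"
    return(out)
  }
  if (a_ok) return(a)
  if (m_ok) return(m)
  # neither assigned: keep the more informative status
  st <- c(if (!is.null(a)) a$status, if (!is.null(m)) m$status)
  out <- list(genotype = NA_character_,
              status = if ("discarded_multi" %in% st) "discarded_multi"
                       else "unassigned",
              clone = NA_character_, clone_tie = FALSE,
              read_support = table(character(0)),
              source = if (is.null(m)) "amplicon" else "both")
  class(out) <- "cell_call"
  out
}

#' Assign genotypes to cells from paired amplicon FASTQ
#'
#' End-to-end amplicon route: reads the paired FASTQ, extracts the cell
#' barcode (read-1 positions 1-16) and UMI (17-28), parses every read 2,
#' calls genotypes from the extracted regions, optionally collapses reads to
#' one vote per (cell, UMI, genotype), and aggregates per cell with the
#' strict 70% majority rule.
#'
#' @param r1_path,r2_path Paired FASTQ files.
#' @param library A `barcode_library`.
#' @param max_mm_anchor,max_mm_bc Mismatch allowances for anchors and
#'   barcode calling.
#' @param majority Majority fraction for [aggregate_cell()].
#' @param dedup_umi Vote over UMI-deduplicated reads (default) or raw reads.
#' @param ... Further arguments passed to [parse_reads()].
#' @return A data.frame of class `cell_calls` with one row per cell:
#'   `cell_barcode`, `genotype`, `clone`, `status`, `source`, `n_reads`,
#'   `n_informative`.
#' @export
assign_from_fastq <- function(r1_path, r2_path, library,
                              max_mm_anchor = 3L, max_mm_bc = 2L,
                              majority = 0.70, dedup_umi = TRUE, ...) {
  r1 <- read_fastq(r1_path)
  r2 <- read_fastq(r2_path)
  if (nrow(r1) != nrow(r2))
    stop("read 1 and read 2 files differ in record count", call. = FALSE)
  cell <- substr(r1$seq, 1L, 16L)
  umi <- substr(r1$seq, 17L, 28L)
  parsed <- parse_reads(r2$seq, max_mm = max_mm_anchor, ...)
  geno <- rep(NA_character_, nrow(parsed))
  ok <- which(parsed$valid)
  if (length(ok)) {
    regions <- parsed$genotype_region[ok]
    uniq <- unique(regions)
    ucall <- vapply(uniq, function(r)
      as.character(call_genotype(r, library, max_mm = max_mm_bc)),
      character(1))
    geno[ok] <- ucall[match(regions, uniq)]
  }
  df <- data.frame(cell = cell, umi = umi, genotype = geno,
                   clone = parsed$clone_seq, stringsAsFactors = FALSE)
  if (dedup_umi) {
    inf <- !is.na(df$genotype)
    df <- rbind(df[!inf, ],
                df[inf, ][!duplicated(df[inf, c("cell", "umi", "genotype")]), ])
  }
  cells <- split(df, df$cell)
  calls <- lapply(cells, function(d)
    aggregate_cell(d$genotype, d$clone, majority = majority))
  out <- data.frame(
    cell_barcode = names(cells),
    genotype = vapply(calls, function(x) x$genotype, character(1)),
    clone = vapply(calls, function(x) x$clone, character(1)),
    status = vapply(calls, function(x) x$status, character(1)),
    source = "amplicon",
    n_reads = as.integer(table(cell)[names(cells)]),
    n_informative = vapply(calls, function(x) sum(x$read_support),
                           integer(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  class(out) <- c("cell_calls", "data.frame")
  out
}

#' Evaluate genotype assignment against simulation truth
#'
#' @param calls A `cell_calls` data.frame (or any data.frame with
#'   `cell_barcode`, `genotype`, `status`).
#' @param truth Truth data.frame with `cell_barcode` and `genotype`.
#' @return A list with `assigned_fraction`, `precision` (over assigned
#'   cells; `NA` when none assigned), and `conflict_rate`.
#' @export
evaluate_assignment <- function(calls, truth) {
  m <- match(calls$cell_barcode, truth$cell_barcode)
  if (anyNA(m))
    stop("truth table is missing ", sum(is.na(m)), " called cell(s)",
         call. = FALSE)
  assigned <- calls$status == "assigned"
  prec <- if (any(assigned))
    mean(calls$genotype[assigned] == truth$genotype[m][assigned])
  else NA_real_
  list(assigned_fraction = mean(assigned),
       precision = prec,
       conflict_rate = mean(calls$status == "conflicted"))
}
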