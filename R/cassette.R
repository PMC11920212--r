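#' Constant segments of the RNA-barcoded deletion cassette
#'
#' The expressed barcode cassette places a 5-nt clone barcode immediately
#' after the selection-marker stop codon, followed by a 43-nt constant
#' terminator linker, the 20-nt genotype (Downtag) barcode and a 17-nt
#' constant downstream flank. `YKO_LINKER43` and `YKO_FLANK17` are those
#' constant segments; `YKO_D2_ANCHOR` is the terminal 18 nt of the linker
#' (the upstream anchor used to locate the genotype barcode in amplicon
#' reads) and `YKO_D1_ANCHOR` is the downstream flank itself.
#' `YKO_CONTIG_TEMPLATE` is the 85-nt artificial barcode contig in template
#' form, with the clone and genotype barcode slots as N-runs.
#'
#' @format Character scalars (DNA, uppercase).
#' @name cassette-constants
NULL

#' @rdname cassette-constants
#' @export
YKO_LINKER43 <- "AACGCCGCCATCCAGTGTCGAAAACGAGCTCGAATTCATCGAT"

#' @rdname cassette-constants
#' @export
YKO_FLANK17 <- "CTACGAGACCGACACCG"

#' @rdname cassette-constants
#' @export
YKO_D2_ANCHOR <- substr(YKO_LINKER43, 26L, 43L)

#' @rdname cassette-constants
#' @export
YKO_D1_ANCHOR <- YKO_FLANK17

#' @rdname cassette-constants
#' @export
YKO_CONTIG_TEMPLATE <- paste0(strrep("N", 5L), YKO_LINKER43,
                              strrep("N", 20L), YKO_FLANK17)

.check_dna <- function(x, len, what) {
  if (length(x) != 1L || is.na(x))
    stop(what, " must be a single DNA string", call. = FALSE)
  if (nchar(x) != len)
    stop(what, " must be ", len, " nt, got ", nchar(x), call. = FALSE)
  if (grepl("[^ACGT]", x))
    stop(what, " contains characters outside {A,C,G,T}", call. = FALSE)
  invisible(x)
}

#' Build an artificial barcode contig
#'
#' Assembles the 85-nt artificial chromosome used to identify a genotype and
#' clone from expression data: clone barcode (5 nt), constant 43-nt
#' terminator linker, genotype barcode (20 nt), constant 17-nt downstream
#' flank.
#'
#' @param genotype_barcode 20-nt DNA string (A/C/G/T).
#' @param clone_barcode 5-nt DNA string.
#' @return An 85-nt DNA string.
#' @examples
#' build_contig(strrep("ACGT", 5), "TTTTT")
#' @export
build_contig <- function(genotype_barcode, clone_barcode) {
  .check_dna(genotype_barcode, 20L, "genotype_barcode")
  .check_dna(clone_barcode, 5L, "clone_barcode")
  paste0(clone_barcode, YKO_LINKER43, genotype_barcode, YKO_FLANK17)
}

#' Parse a cassette template into its structural segments
#'
#' Locates the N-runs marking the clone and genotype barcode slots in a
#' cassette or contig template. When the template carries more than two
#' N-runs (the full printed cassette also contains an upstream Uptag slot),
#' the last two runs are taken as the clone and genotype slots; any upstream
#' runs are reported verbatim in `extra_run_lens` without interpretation.
#'
#' @param template_seq DNA template string containing N-runs.
#' @return A list of class `cassette_structure` with elements `clone_len`,
#'   `linker_seq`, `linker_len`, `genotype_len`, `suffix_seq`, `suffix_len`
#'   and `extra_run_lens`.
#' @examples
#' parse_contig_template(YKO_CONTIG_TEMPLATE)
#' @export
parse_contig_template <- function(template_seq) {
  if (length(template_seq) != 1L || is.na(template_seq) || !nzchar(template_seq))
    stop("template_seq must be a single non-empty string", call. = FALSE)
  m <- gregexpr("N+", template_seq)[[1L]]
  if (m[1L] == -1L || length(m) < 2L)
    stop("template must contain at least two N-runs (clone and genotype slots)",
         call. = FALSE)
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  k <- length(starts)
  clone_i <- k - 1L
  geno_i <- k
  linker_start <- starts[clone_i] + lens[clone_i]
  linker_seq <- substr(template_seq, linker_start, starts[geno_i] - 1L)
  suffix_start <- starts[geno_i] + lens[geno_i]
  suffix_seq <- if (suffix_start > nchar(template_seq)) ""
                else substr(template_seq, suffix_start, nchar(template_seq))
  structure(list(
    clone_len = lens[clone_i],
    linker_seq = linker_seq,
    linker_len = nchar(linker_seq),
    genotype_len = lens[geno_i],
    suffix_seq = suffix_seq,
    suffix_len = nchar(suffix_seq),
    extra_run_lens = if (k > 2L) lens[seq_len(k - 2L)] else integer(0)
  ), class = "cassette_structure")
}

#' Validate the genomic position of a genotype barcode
#'
#' Deletion cassettes should land at the targeted locus, so 3'UTR reads map
#' close to the annotated stop codon of the deleted gene. A genotype passes
#' when the median read-to-stop distance is at most the threshold (default
#' 300 bp); larger medians flag an incorrect genomic position.
#'
#' @param genotype_id Genotype identifier.
#' @param distances Non-negative nucleotide distances between mapped reads
#'   and the annotated stop codon.
#' @param threshold Maximum passing median distance in bp.
#' @return A list of class `locus_validation` with `genotype_id`,
#'   `distances`, `median_distance` and `passed`.
#' @export
validate_locus <- function(genotype_id, distances, threshold = 300) {
  if (length(distances) == 0L)
    stop("unvalidatable: no distances supplied for genotype ", genotype_id,
         call. = FALSE)
  if (any(!is.finite(distances)) || any(distances < 0))
    stop("distances must be finite and non-negative", call. = FALSE)
  med <- stats::median(distances)
  structure(list(
    genotype_id = genotype_id,
    distances = distances,
    median_distance = med,
    passed = med <= threshold
  ), class = "locus_validation")
}
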