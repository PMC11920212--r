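DNA_BASES <- c("A", "C", "G", "T")

# Hamming distance between two equal-length strings.
hamming <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("hamming: unequal lengths", call. = FALSE)
  sum(charToRaw(a) != charToRaw(b))
}

random_dna <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(DNA_BASES, len, replace = TRUE), collapse = ""),
    character(1))
}

# Derive a stage-specific seed from a master seed; keeps results < 2^31.
derive_seed <- function(master, stage) {
  offset <- sum(utf8ToInt(stage)) * 1009L
  (as.integer(master) + offset) %% 2147483647L
}

# Mutate DNA strings with iid substitutions at rate `rate` per base.
mutate_seqs <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  len <- nchar(seqs)
  stopifnot(length(unique(len)) <= 1L)
  if (length(seqs) == 0L) return(seqs)
  L <- len[1L]
  mat <- matrix(unlist(strsplit(seqs, "", fixed = TRUE)),
                nrow = length(seqs), ncol = L, byrow = TRUE)
  hit <- matrix(stats::runif(length(mat)) < rate, nrow = nrow(mat))
  idx <- which(hit)
  if (length(idx)) {
    # substitute with one of the three other bases
    old <- mat[idx]
    shift <- sample.int(3L, length(idx), replace = TRUE)
    pos <- (match(old, DNA_BASES) - 1L + shift) %% 4L + 1L
    mat[idx] <- DNA_BASES[pos]
  }
  apply(mat, 1L, paste, collapse = "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
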