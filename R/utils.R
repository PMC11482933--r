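`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a local RNG seed
#'
#' Sets the RNG seed for the duration of `expr` and restores the previous
#' global RNG state afterwards, so seeded package functions do not perturb
#' the caller's random stream.
#'
#' @param seed integer seed (must be < 2^31).
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic per-stage seed derived from a master seed; keeps values
# well inside 32-bit integer range.
stage_seed <- function(seed, stage) {
  (as.integer(seed) * 131L + as.integer(stage) * 7919L) %% 2147483629L
}

# Random DNA string(s) with slight AT bias (mammalian-ish composition).
random_dna <- function(n_bases, prob = c(A = 0.3, C = 0.2, G = 0.2, T = 0.3)) {
  paste(sample(names(prob), n_bases, replace = TRUE, prob = prob),
        collapse = "")
}

# Reverse complement of plain character vectors.
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Hamming distance between two equal-length strings.
hamming <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# Convert 0-based half-open intervals to an IRanges (1-based closed).
iranges0 <- function(start, end) {
  IRanges::IRanges(start = as.integer(start) + 1L, end = as.integer(end))
}

# GRanges from 0-based half-open coordinates.
granges0 <- function(chrom, start, end, strand = "*") {
  GenomicRanges::GRanges(chrom, iranges0(start, end), strand = strand)
}

stop_config <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

# Substitute random erroneous bases into a character vector of sequences at
# a uniform per-base rate; errors never reproduce the original base.
apply_substitution_errors <- function(seqs, rate) {
  if (rate <= 0 || length(seqs) == 0) return(seqs)
  lens <- nchar(seqs)
  total <- sum(lens)
  n_err <- rbinom(1L, total, rate)
  if (n_err == 0) return(seqs)
  pos_flat <- sample.int(total, n_err)
  ends <- cumsum(lens)
  idx <- findInterval(pos_flat - 1L, ends) + 1L
  offset <- pos_flat - c(0L, ends)[idx]
  bases <- c("A", "C", "G", "T")
  for (j in seq_len(n_err)) {
    i <- idx[j]; p <- offset[j]
    orig <- substr(seqs[i], p, p)
    alt <- sample(setdiff(bases, orig), 1L)
    substr(seqs[i], p, p) <- alt
  }
  seqs
}
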