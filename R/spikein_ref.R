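#' Construct a spike-in (LMS-style) reference
#'
#' A single lambda-model-system-like control sequence with disjoint segments:
#' one densely modified segment per modification (every fragment overlapping
#' it is capturable by the corresponding bead) and one internal-standard
#' segment carrying a single site per modification, used as the denominator
#' of the enrichment factor.
#'
#' @param config a \code{\link{sim_config}} (supplies the seed).
#' @param length total reference length (nt).
#' @param fasta,segments_bed optional output paths (FASTA and a BED segment
#'   map with a modification column).
#' @return object of class \code{spikein_reference}: \code{$sequences}
#'   (DNAStringSet), \code{$segments} (name, start, end, mod, role),
#'   \code{$std_sites} (mod, pos), \code{$std_stoichiometry} (named, the
#'   known input stoichiometries of the internal standard).
#' @export
spikein_reference <- function(config, length = 3000L, fasta = NULL,
                              segments_bed = NULL) {
  mods <- names(config$mbc_whitelist)
  seq <- with_seed(stage_seed(config$seed, 3L), random_dna(length))
  n_mod <- length(mods)
  # lay out n_mod mod-specific segments plus the internal standard
  seg_w <- as.integer(floor(length / (n_mod + 1.5)))
  starts <- as.integer(round(seq(0.03 * length, length - seg_w - 1,
                                 length.out = n_mod + 1L)))
  segments <- data.frame(
    name = c(paste0(mods, "_segment"), "internal_standard"),
    start = starts, end = starts + as.integer(0.8 * seg_w),
    mod = c(mods, "all"),
    role = c(rep("mod_specific", n_mod), "internal_standard"),
    stringsAsFactors = FALSE)
  std <- segments[segments$role == "internal_standard", ]
  std_pos <- as.integer(round(seq(std$start + 0.25 * (std$end - std$start),
                                  std$start + 0.75 * (std$end - std$start),
                                  length.out = n_mod)))
  std_sites <- data.frame(mod = mods, pos = std_pos, stringsAsFactors = FALSE)
  ref <- structure(list(
    sequences = Biostrings::DNAStringSet(setNames(seq, "LMS")),
    segments = segments, std_sites = std_sites,
    std_stoichiometry = setNames(rep(1, n_mod), mods)),
    class = "spikein_reference")
  if (!is.null(fasta)) Biostrings::writeXStringSet(ref$sequences, fasta)
  if (!is.null(segments_bed)) {
    write.table(data.frame(chrom = "LMS", start = segments$start,
                           end = segments$end, name = segments$name,
                           score = 0L, strand = "+", mod = segments$mod,
                           role = segments$role),
                segments_bed, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  }
  ref
}

#' Read a spike-in segment map from BED
#'
#' @param path BED6+2 path as written by \code{\link{spikein_reference}}.
#' @param fasta optional FASTA of the spike-in sequences.
#' @return a \code{spikein_reference} (without standard sites when only the
#'   map is available).
#' @export
read_spikein_segments <- function(path, fasta = NULL) {
  d <- read.table(path, sep = "\t", stringsAsFactors = FALSE)
  names(d) <- c("chrom", "start", "end", "name", "score", "strand", "mod",
                "role")[seq_len(ncol(d))]
  seqs <- if (!is.null(fasta)) Biostrings::readDNAStringSet(fasta) else NULL
  structure(list(sequences = seqs,
                 segments = d[, c("name", "start", "end", "mod", "role")],
                 std_sites = NULL, std_stoichiometry = NULL),
            class = "spikein_reference")
}
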