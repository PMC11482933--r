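#' Write / read peaks as BED6+
#'
#' BED with 0-based half-open coordinates: chrom, start, end, name, score
#' (10 x fold_enrichment, capped at 1000), strand, then the extra columns
#' summit, modification, raw_enrichment, fold_enrichment, enrich_depth,
#' control_depth, high_confidence. The round trip is lossless for these
#' columns.
#'
#' @param peaks peak data.frame.
#' @param path output path.
#' @export
write_peaks <- function(peaks, path) {
  strand <- peaks$strand %||% rep(".", nrow(peaks))
  name <- peaks$peak_id %||% sprintf("peak%05d", seq_len(nrow(peaks)))
  d <- data.frame(chrom = peaks$ref, start = peaks$start, end = peaks$end,
                  name = name,
                  score = pmin(round(10 * peaks$fold_enrichment), 1000),
                  strand = strand, summit = peaks$summit,
                  modification = peaks$modification,
                  raw_enrichment = peaks$raw_enrichment,
                  fold_enrichment = peaks$fold_enrichment,
                  enrich_depth = peaks$enrich_depth,
                  control_depth = peaks$control_depth,
                  high_confidence = peaks$high_confidence)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @rdname write_peaks
#' @export
read_peaks <- function(path) {
  if (file.size(path) == 0) return(empty_peaks())
  d <- read.table(path, sep = "\t", stringsAsFactors = FALSE,
                  na.strings = c("NA"))
  names(d) <- c("chrom", "start", "end", "name", "score", "strand",
                "summit", "modification", "raw_enrichment",
                "fold_enrichment", "enrich_depth", "control_depth",
                "high_confidence")[seq_len(ncol(d))]
  data.frame(ref = d$chrom, start = d$start, end = d$end,
             summit = d$summit, modification = d$modification,
             raw_enrichment = d$raw_enrichment,
             fold_enrichment = d$fold_enrichment,
             enrich_depth = d$enrich_depth, control_depth = d$control_depth,
             high_confidence = as.logical(d$high_confidence),
             strand = d$strand, peak_id = d$name, stringsAsFactors = FALSE)
}

#' Export a coverage track as bedGraph
#'
#' Adjacent equal-valued bases are collapsed into intervals (0-based
#' half-open); zero-valued intervals are omitted.
#'
#' @param track a \code{coverage_track}.
#' @param path output path.
#' @param name optional track name line.
#' @export
write_bedgraph <- function(track, path, name = NULL) {
  v <- track$values
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values != 0
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(name)) {
    writeLines(sprintf("track type=bedGraph name=\"%s\"", name), con)
  }
  if (any(keep)) {
    writeLines(sprintf("%s\t%d\t%d\t%.6g", track$ref, starts[keep],
                       ends[keep], r$values[keep]), con)
  }
  invisible(path)
}

#' Read fragments (truth alignments) from TSV
#'
#' @param path TSV with a header as written by
#'   \code{\link{write_sim_library}}.
#' @return data.frame of fragments.
#' @export
read_fragments_tsv <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
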