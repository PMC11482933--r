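#' Native pileup over regions
#'
#' Walks aligned fragments (genome-forward observed sequence plus an
#' optional CIGAR; absent CIGAR means a full-length match) and produces
#' per-base counts restricted to the requested regions. Reads are processed
#' in input order with a per-position depth cap; bases below the quality
#' floor are ignored when per-base qualities are available. Fragments with a
#' malformed CIGAR are skipped and counted.
#'
#' @param fragments data.frame with \code{ref, start, end, strand, seq} and
#'   optionally \code{qual} (Phred+33) and \code{cigar}.
#' @param reference \code{DNAStringSet} (or named character) of reference
#'   sequences.
#' @param regions data.frame of 0-based half-open intervals (\code{chrom,
#'   start, end}), e.g. inosine peak intervals; an optional \code{peak_id}
#'   column is carried through.
#' @param max_depth per-position depth cap (default 20000).
#' @param min_base_qual base-quality floor (default 13).
#' @return data.frame of pileup columns: \code{chrom, pos} (0-based),
#'   \code{ref_base, A, C, G, T, N, del, depth, depth_rev} (reverse-strand
#'   read depth) and \code{region_id}; attribute \code{"skipped"} counts
#'   records dropped for malformed CIGARs.
#' @export
pileup_fragments <- function(fragments, reference, regions,
                             max_depth = 20000L, min_base_qual = 13L) {
  if (!is.null(reference) && !inherits(reference, "DNAStringSet")) {
    reference <- Biostrings::DNAStringSet(reference)
  }
  out <- list()
  skipped <- 0L
  bases <- c("A", "C", "G", "T", "N")
  for (ri in seq_len(nrow(regions))) {
    chrom <- regions$chrom[ri]
    r_lo <- regions$start[ri]; r_hi <- regions$end[ri]
    width <- r_hi - r_lo
    if (width <= 0) next
    counts <- matrix(0L, nrow = width, ncol = 6L,
                     dimnames = list(NULL, c(bases, "del")))
    depth <- integer(width)
    depth_rev <- integer(width)
    fr <- fragments[fragments$ref == chrom &
                      fragments$start < r_hi & fragments$end > r_lo, ,
                    drop = FALSE]
    for (i in seq_len(nrow(fr))) {
      walked <- walk_cigar(fr$start[i], fr$seq[i],
                           if (!is.null(fr$cigar)) fr$cigar[i] else NA,
                           if (!is.null(fr$qual)) fr$qual[i] else NA)
      if (is.null(walked)) { skipped <- skipped + 1L; next }
      inwin <- walked$pos >= r_lo & walked$pos < r_hi
      if (!any(inwin)) next
      pos <- walked$pos[inwin]; base <- walked$base[inwin]
      q <- walked$qual[inwin]
      pass_q <- is.na(q) | q >= min_base_qual | base == "del"
      idx <- pos - r_lo + 1L
      room <- depth[idx] < max_depth
      use <- pass_q & room
      if (!any(use)) next
      idx <- idx[use]; base <- base[use]
      for (j in seq_along(idx)) {
        counts[idx[j], base[j]] <- counts[idx[j], base[j]] + 1L
      }
      depth[idx] <- depth[idx] + 1L
      if (fr$strand[i] == "-") depth_rev[idx] <- depth_rev[idx] + 1L
    }
    refseq <- if (!is.null(reference) && chrom %in% names(reference)) {
      strsplit(substr(as.character(reference[[chrom]]), r_lo + 1L, r_hi),
               "")[[1]]
    } else rep(NA_character_, width)
    out[[length(out) + 1L]] <- data.frame(
      chrom = chrom, pos = seq(r_lo, r_hi - 1L), ref_base = refseq,
      A = counts[, "A"], C = counts[, "C"], G = counts[, "G"],
      T = counts[, "T"], N = counts[, "N"], del = counts[, "del"],
      depth = depth, depth_rev = depth_rev,
      region_id = regions$peak_id[ri] %||% as.character(ri),
      stringsAsFactors = FALSE)
  }
  res <- if (length(out) > 0) do.call(rbind, out) else
    data.frame(chrom = character(0), pos = integer(0),
               ref_base = character(0), A = integer(0), C = integer(0),
               G = integer(0), T = integer(0), N = integer(0),
               del = integer(0), depth = integer(0), depth_rev = integer(0),
               region_id = character(0))
  rownames(res) <- NULL
  attr(res, "skipped") <- skipped
  res
}

# Expand one aligned record into (ref position, base, qual) triples.
# Supported CIGAR ops: M/=/X (consume both), I/S (query only), D/N
# (reference only; D emits "del"). Returns NULL on malformed CIGAR.
walk_cigar <- function(start, seq, cigar, qual) {
  qv <- if (is.na(qual)) NULL else utf8ToInt(qual) - 33L
  sv <- strsplit(seq, "")[[1]]
  if (is.na(cigar) || cigar == "") {
    return(list(pos = seq(start, start + length(sv) - 1L), base = sv,
                qual = if (is.null(qv)) rep(NA_integer_, length(sv)) else qv))
  }
  ops <- regmatches(cigar, gregexpr("[0-9]+[A-Z=]", cigar))[[1]]
  if (length(ops) == 0 ||
      nchar(paste(ops, collapse = "")) != nchar(cigar)) {
    return(NULL)
  }
  lens <- as.integer(sub("[A-Z=]$", "", ops))
  types <- sub("^[0-9]+", "", ops)
  if (!all(types %in% c("M", "=", "X", "I", "S", "D", "N"))) return(NULL)
  pos <- integer(0); base <- character(0); qout <- integer(0)
  rp <- start; qp <- 1L
  for (k in seq_along(ops)) {
    L <- lens[k]
    if (types[k] %in% c("M", "=", "X")) {
      if (qp + L - 1L > length(sv)) return(NULL)
      pos <- c(pos, seq(rp, rp + L - 1L))
      base <- c(base, sv[qp:(qp + L - 1L)])
      qout <- c(qout, if (is.null(qv)) rep(NA_integer_, L) else qv[qp:(qp + L - 1L)])
      rp <- rp + L; qp <- qp + L
    } else if (types[k] %in% c("I", "S")) {
      qp <- qp + L
    } else if (types[k] == "D") {
      pos <- c(pos, seq(rp, rp + L - 1L))
      base <- c(base, rep("del", L))
      qout <- c(qout, rep(NA_integer_, L))
      rp <- rp + L
    } else if (types[k] == "N") {
      rp <- rp + L
    }
  }
  list(pos = pos, base = base, qual = qout)
}

#' Call A-to-G variant sites under inosine peaks
#'
#' Inosine base-pairs like guanosine and is read as G, so edited adenosines
#' appear as A>G mismatches on the transcript strand (T>C on the genomic
#' minus strand). A site is reported when the reference base is A on the
#' transcript strand, the variant rate (alt/depth, computed after depth
#' capping) is at least \code{min_rate}, and the depth strictly exceeds
#' \code{min_depth_exclusive}.
#'
#' @param columns pileup columns from \code{\link{pileup_fragments}}.
#' @param peaks inosine peak data.frame with \code{ref, start, end} and a
#'   \code{strand} column giving the transcript strand (plus \code{peak_id}
#'   if available).
#' @param min_rate minimum variant rate (default 0.10, non-strict).
#' @param min_depth_exclusive depth must be strictly greater than this
#'   (default 5, i.e. >= 6 reads).
#' @return data.frame of variant sites: \code{chrom, pos} (0-based),
#'   \code{pos1} (1-based, VCF-style), genomic \code{ref}/\code{alt},
#'   \code{depth, alt_count, rate, strand, peak_id}.
#' @export
call_ag_sites <- function(columns, peaks, min_rate = 0.10,
                          min_depth_exclusive = 5L) {
  empty <- data.frame(chrom = character(0), pos = integer(0),
                      pos1 = integer(0), ref = character(0),
                      alt = character(0), depth = integer(0),
                      alt_count = integer(0), rate = numeric(0),
                      strand = character(0), peak_id = character(0),
                      stringsAsFactors = FALSE)
  if (nrow(columns) == 0 || nrow(peaks) == 0) return(empty)
  if (is.null(peaks$peak_id)) {
    peaks$peak_id <- sprintf("peak%05d", seq_len(nrow(peaks)))
  }
  ov <- IRanges::findOverlaps(
    granges0(columns$chrom, columns$pos, columns$pos + 1L),
    granges0(peaks$ref, peaks$start, peaks$end))
  if (length(ov) == 0) return(empty)
  ci <- S4Vectors::queryHits(ov); pi <- S4Vectors::subjectHits(ov)
  strand <- peaks$strand[pi]
  ref_need <- ifelse(strand == "-", "T", "A")
  alt_base <- ifelse(strand == "-", "C", "G")
  alt_count <- ifelse(strand == "-", columns$C[ci], columns$G[ci])
  depth <- columns$depth[ci]
  rate <- ifelse(depth > 0, alt_count / depth, 0)
  keep <- !is.na(columns$ref_base[ci]) & columns$ref_base[ci] == ref_need &
    rate >= min_rate & depth > min_depth_exclusive
  out <- data.frame(chrom = columns$chrom[ci], pos = columns$pos[ci],
                    pos1 = columns$pos[ci] + 1L,
                    ref = columns$ref_base[ci], alt = alt_base,
                    depth = depth, alt_count = alt_count, rate = rate,
                    strand = strand, peak_id = peaks$peak_id[pi],
                    stringsAsFactors = FALSE)[keep, , drop = FALSE]
  # a site may be hit by overlapping peaks; keep one row per site/peak pair
  rownames(out) <- NULL
  out
}

#' Per-peak A-to-G support
#'
#' Annotates each inosine peak with its best supporting variant site and
#' reports the global fraction of inosine peaks containing at least one
#' reported A-to-G site.
#'
#' @param peaks inosine peak data.frame (with \code{peak_id} or row order
#'   matching the ids generated by \code{\link{call_ag_sites}}).
#' @param sites variant sites from \code{\link{call_ag_sites}}.
#' @return list: \code{$peaks} (peaks plus \code{n_sites, best_pos,
#'   best_rate}) and \code{$support_fraction}.
#' @export
peak_variant_support <- function(peaks, sites) {
  if (is.null(peaks$peak_id)) {
    peaks$peak_id <- sprintf("peak%05d", seq_len(nrow(peaks)))
  }
  peaks$n_sites <- rep(0L, nrow(peaks))
  peaks$best_pos <- rep(NA_integer_, nrow(peaks))
  peaks$best_rate <- rep(NA_real_, nrow(peaks))
  if (nrow(sites) > 0) {
    for (i in seq_len(nrow(peaks))) {
      s <- sites[sites$peak_id == peaks$peak_id[i], , drop = FALSE]
      peaks$n_sites[i] <- nrow(s)
      if (nrow(s) > 0) {
        j <- which.max(s$rate)
        peaks$best_pos[i] <- s$pos[j]
        peaks$best_rate[i] <- s$rate[j]
      }
    }
  }
  frac <- if (nrow(peaks) == 0) NA_real_ else mean(peaks$n_sites > 0)
  list(peaks = peaks, support_fraction = frac)
}

#' Write variant sites as VCF 4.2
#'
#' Minimal single-sample-free VCF with INFO fields for depth, alt count,
#' variant rate and owning peak id. Positions are 1-based.
#'
#' @param sites variant sites from \code{\link{call_ag_sites}}.
#' @param path output path.
#' @param reference_name optional reference tag for the header.
#' @export
write_vcf_sites <- function(sites, path, reference_name = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=epimodkit",
               if (!is.null(reference_name))
                 sprintf("##reference=%s", reference_name),
               "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
               "##INFO=<ID=AC,Number=1,Type=Integer,Description=\"Alt count\">",
               "##INFO=<ID=VR,Number=1,Type=Float,Description=\"Variant rate\">",
               "##INFO=<ID=PEAK,Number=1,Type=String,Description=\"Inosine peak id\">",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  if (nrow(sites) > 0) {
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tDP=%d;AC=%d;VR=%.4f;PEAK=%s",
                       sites$chrom, sites$pos1, sites$ref, sites$alt,
                       sites$depth, sites$alt_count, sites$rate,
                       sites$peak_id), con)
  }
  invisible(path)
}
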