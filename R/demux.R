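#' Read layout for barcode extraction
#'
#' Describes where the modification barcode (MBC) and UMI sit on read 2 and
#' the trimming/filtering parameters applied during extraction.
#'
#' @param mbc_whitelist named character vector (modification label ->
#'   barcode sequence); all barcodes must share one length.
#' @param umi_length UMI length (nt), immediately after the MBC on read 2.
#' @param max_mbc_dist maximum Hamming distance for barcode error
#'   correction; observed MBCs farther than this from every whitelist entry
#'   (or equally close to several) are routed to \code{"undetermined"}.
#' @param trim_window,trim_minq 3' sliding-window quality trimming: bases
#'   are removed from the 3' end while the trailing window of
#'   \code{trim_window} bases has mean quality below \code{trim_minq}.
#' @param min_insert minimum trimmed insert length; shorter reads are
#'   rejected (reason \code{"short_insert"}).
#' @return list of class \code{barcode_layout}.
#' @export
barcode_layout <- function(mbc_whitelist = c(m6A = "AAGGCCTT",
                                             inosine = "CCTTAAGG"),
                           umi_length = 10L,
                           max_mbc_dist = 1L,
                           trim_window = 4L,
                           trim_minq = 20,
                           min_insert = 30L) {
  stopifnot(length(unique(nchar(mbc_whitelist))) == 1,
            !is.null(names(mbc_whitelist)))
  structure(list(mbc_whitelist = mbc_whitelist,
                 mbc_length = nchar(mbc_whitelist[[1]]),
                 umi_length = as.integer(umi_length),
                 max_mbc_dist = as.integer(max_mbc_dist),
                 trim_window = as.integer(trim_window),
                 trim_minq = trim_minq,
                 min_insert = as.integer(min_insert)),
            class = "barcode_layout")
}

#' Extract MBC/UMI tags and quality-trim read pairs
#'
#' Read 2 carries the MBC then the UMI at its 5' end; both are removed from
#' the sequence and stored as tags. The insert (read 1) is 3'
#' quality-trimmed with a sliding window and pairs whose trimmed insert is
#' shorter than \code{layout$min_insert} are rejected and counted. Observed
#' MBCs are error-corrected to the whitelist within
#' \code{layout$max_mbc_dist}; unresolvable barcodes go to
#' \code{"undetermined"}.
#'
#' @param read1,read2 character vectors of read sequences.
#' @param qual1,qual2 Phred+33 quality strings (same lengths).
#' @param layout a \code{\link{barcode_layout}}.
#' @param read_id optional read names.
#' @return list with \code{$tagged} (read_id, mbc label, mbc_observed, umi,
#'   insert, insert_qual, insert2, mean_qual), \code{$rejected} (read_id,
#'   reason) and \code{$counts} (named totals: input, tagged, per reason).
#' @export
extract_and_trim <- function(read1, read2, qual1 = NULL, qual2 = NULL,
                             layout = barcode_layout(), read_id = NULL) {
  n <- length(read1)
  stopifnot(length(read2) == n)
  if (is.null(read_id)) read_id <- sprintf("read%06d", seq_len(n))
  if (is.null(qual1)) qual1 <- strrep("I", nchar(read1))
  if (is.null(qual2)) qual2 <- strrep("I", nchar(read2))
  tag_len <- layout$mbc_length + layout$umi_length

  underflow <- nchar(read2) < tag_len
  reasons <- rep(NA_character_, n)
  reasons[underflow] <- "layout_underflow"

  mbc_obs <- substr(read2, 1L, layout$mbc_length)
  umi <- substr(read2, layout$mbc_length + 1L, tag_len)
  insert2 <- substr(read2, tag_len + 1L, nchar(read2))

  trimmed_len <- trim_sliding_window(qual1, layout$trim_window,
                                     layout$trim_minq)
  insert <- substr(read1, 1L, trimmed_len)
  insert_qual <- substr(qual1, 1L, trimmed_len)
  short <- !underflow & trimmed_len < layout$min_insert
  reasons[short] <- "short_insert"

  keep <- is.na(reasons)
  mbc <- correct_mbc(mbc_obs, layout$mbc_whitelist, layout$max_mbc_dist)
  mean_qual <- vapply(insert_qual, function(q) {
    if (nchar(q) == 0) return(0)
    mean(utf8ToInt(q) - 33L)
  }, numeric(1), USE.NAMES = FALSE)

  tagged <- data.frame(read_id = read_id[keep], mbc = mbc[keep],
                       mbc_observed = mbc_obs[keep], umi = umi[keep],
                       insert = insert[keep], insert_qual = insert_qual[keep],
                       insert2 = insert2[keep], mean_qual = mean_qual[keep],
                       stringsAsFactors = FALSE)
  rejected <- data.frame(read_id = read_id[!keep], reason = reasons[!keep],
                         stringsAsFactors = FALSE)
  counts <- c(input = n, tagged = nrow(tagged),
              table(factor(reasons[!keep],
                           levels = c("layout_underflow", "short_insert"))))
  list(tagged = tagged, rejected = rejected, counts = counts)
}

#' Demultiplex a FASTQ pair
#'
#' Convenience wrapper around \code{\link{extract_and_trim}} reading gzipped
#' or plain 4-line FASTQ (Phred+33).
#'
#' @param fq1,fq2 FASTQ paths for read 1 / read 2.
#' @inheritParams extract_and_trim
#' @return see \code{\link{extract_and_trim}}.
#' @export
demux_fastq <- function(fq1, fq2, layout = barcode_layout()) {
  r1 <- Biostrings::readDNAStringSet(fq1, format = "fastq",
                                     with.qualities = TRUE)
  r2 <- Biostrings::readDNAStringSet(fq2, format = "fastq",
                                     with.qualities = TRUE)
  stopifnot(length(r1) == length(r2))
  extract_and_trim(
    read1 = as.character(r1), read2 = as.character(r2),
    qual1 = as.character(S4Vectors::mcols(r1)$qualities),
    qual2 = as.character(S4Vectors::mcols(r2)$qualities),
    layout = layout,
    read_id = sub("\\s.*$", "", names(r1)))
}

# 3' sliding-window trim: returns retained length per read. Bases are
# dropped from the 3' end while the trailing window mean quality < minq.
trim_sliding_window <- function(quals, window, minq) {
  vapply(quals, function(q) {
    v <- utf8ToInt(q) - 33L
    L <- length(v)
    while (L > 0) {
      w <- v[max(1L, L - window + 1L):L]
      if (mean(w) >= minq) break
      L <- L - 1L
    }
    L
  }, integer(1), USE.NAMES = FALSE)
}

# Error-correct observed barcodes against a whitelist: exact match, else a
# unique whitelist entry within max_dist, else "undetermined".
correct_mbc <- function(observed, whitelist, max_dist = 1L) {
  labels <- names(whitelist)
  uo <- unique(observed)
  wl_mat <- do.call(rbind, strsplit(unname(whitelist), ""))
  resolve <- vapply(uo, function(o) {
    if (nchar(o) != ncol(wl_mat)) return("undetermined")
    oc <- strsplit(o, "")[[1]]
    d <- rowSums(sweep(wl_mat, 2, oc, "!="))
    hit <- which(d <= max_dist)
    if (length(hit) == 1) labels[hit] else "undetermined"
  }, character(1))
  unname(resolve[match(observed, uo)])
}
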