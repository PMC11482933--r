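#' Deduplicate aligned fragments by MBC and UMI
#'
#' Collapses PCR duplicates. The default key is (reference, start, strand,
#' MBC, UMI): position-aware UMI collapse, a deliberate strengthening over
#' pure barcode collapse, since identical UMIs on distinct loci are distinct
#' molecules. Set \code{position_aware = FALSE} for pure (reference, MBC,
#' UMI) collapse. The retained representative is the fragment with the
#' highest mean base quality, ties broken by read id (lexicographic).
#'
#' @param fragments data.frame of aligned fragments with columns
#'   \code{ref, start, end, strand, mbc, umi} and optionally
#'   \code{mean_qual} and \code{read_id}.
#' @param position_aware include (start, strand) in the duplicate key.
#' @return list with \code{$fragments} (unique fragments, original column
#'   set, sorted by reference then start) and \code{$report} (per-MBC input
#'   and retained counts).
#' @export
deduplicate_fragments <- function(fragments, position_aware = TRUE) {
  if (nrow(fragments) == 0) {
    return(list(fragments = fragments,
                report = data.frame(mbc = character(0), n_input = integer(0),
                                    n_unique = integer(0))))
  }
  dt <- data.table::as.data.table(fragments)
  if (is.null(dt$mean_qual)) dt$mean_qual <- 0
  if (is.null(dt$read_id)) dt$read_id <- sprintf("frag%08d", seq_len(nrow(dt)))
  key <- if (position_aware) c("ref", "start", "strand", "mbc", "umi")
         else c("ref", "mbc", "umi")
  ord <- order(-dt$mean_qual, dt$read_id)
  dt <- dt[ord, ]
  uniq <- dt[!duplicated(dt, by = key), ]
  data.table::setorder(uniq, ref, start)
  report <- merge(
    as.data.frame(table(mbc = fragments$mbc), responseName = "n_input"),
    as.data.frame(table(mbc = uniq$mbc), responseName = "n_unique"),
    by = "mbc", all = TRUE)
  report$n_input[is.na(report$n_input)] <- 0L
  report$n_unique[is.na(report$n_unique)] <- 0L
  report$mbc <- as.character(report$mbc)
  out <- as.data.frame(uniq)[, names(fragments), drop = FALSE]
  rownames(out) <- NULL
  list(fragments = out, report = report)
}

#' Partition fragments by modification barcode
#'
#' @param fragments fragment data.frame with an \code{mbc} column.
#' @param labels MBC labels defining the output streams; defaults to the
#'   sorted labels present. Labels without fragments yield empty streams.
#' @return named list of data.frames (a partition: counts are conserved).
#' @export
split_by_mbc <- function(fragments, labels = NULL) {
  if (is.null(labels)) labels <- sort(unique(fragments$mbc))
  out <- lapply(labels, function(l) {
    d <- fragments[fragments$mbc == l, , drop = FALSE]
    rownames(d) <- NULL
    d
  })
  names(out) <- labels
  out
}

#' Downsample samples to equal per-MBC coverage
#'
#' For every MBC, each sample is randomly subsampled without replacement to
#' the minimum per-MBC fragment count across samples, so that all samples
#' carry equal read coverage at the MBC level before peak calling.
#'
#' @param fragment_sets named list (>= 2) of fragment data.frames, each with
#'   an \code{mbc} column.
#' @param seed integer seed; selections are reproducible.
#' @return named list of downsampled data.frames, same shape as the input.
#' @export
downsample_equal_mbc <- function(fragment_sets, seed = 1L) {
  stopifnot(length(fragment_sets) >= 2, !is.null(names(fragment_sets)))
  mbcs <- sort(unique(unlist(lapply(fragment_sets, function(d) d$mbc))))
  with_seed(seed, {
    out <- lapply(fragment_sets, function(d) d[0, , drop = FALSE])
    for (m in mbcs) {
      counts <- vapply(fragment_sets, function(d) sum(d$mbc == m), integer(1))
      target <- min(counts)
      if (target == 0 && any(counts > 0)) {
        warning(sprintf(
          "MBC %s has zero fragments in sample(s) %s; downsampled to zero everywhere",
          m, paste(names(counts)[counts == 0], collapse = ", ")))
      }
      for (s in names(fragment_sets)) {
        idx <- which(fragment_sets[[s]]$mbc == m)
        if (length(idx) > target) idx <- sort(sample(idx, target))
        out[[s]] <- rbind(out[[s]], fragment_sets[[s]][idx, , drop = FALSE])
      }
    }
    lapply(out, function(d) { rownames(d) <- NULL; d })
  })
}
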