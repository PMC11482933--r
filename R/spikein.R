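#' Count spike-in fragments per segment
#'
#' Assigns each fragment aligned to the spike-in reference to the segment
#' containing its midpoint (for even-length fragments the left of the two
#' central bases, so a midpoint falling on a segment boundary goes to the
#' left segment) and tabulates counts per (segment, MBC, sample role).
#'
#' @param fragments fragment data.frame with columns \code{ref, start, end,
#'   mbc} and optionally \code{role} (defaults to "enrichment").
#' @param spikein a \code{\link{spikein_reference}} (or anything with a
#'   \code{$segments} data.frame and \code{$sequences} names).
#' @param library_sizes optional data.frame (\code{role, mbc, total}) of
#'   total deduplicated mapped fragments per sample per MBC, used for
#'   per-million normalization; defaults to the fragment counts given.
#' @param genome_refs reference names that are allowed to appear alongside
#'   the spike-in reference (genome fragments, ignored here); any fragment
#'   on a reference in neither set is an error naming the record.
#' @return object of class \code{spikein_report}: \code{$counts} (segment,
#'   mod, role, mbc, count, cpm), \code{$library_sizes}.
#' @export
count_spikein <- function(fragments, spikein, library_sizes = NULL,
                          genome_refs = NULL) {
  segs <- spikein$segments
  refs <- names(spikein$sequences) %||% "LMS"
  if (is.null(fragments$role)) fragments$role <- "enrichment"
  bad <- which(!(fragments$ref %in% c(refs, genome_refs)))
  if (length(bad) > 0) {
    stop_config("unknown reference name '%s' (record %s)",
                fragments$ref[bad[1]],
                fragments$read_id[bad[1]] %||% as.character(bad[1]))
  }
  sp <- fragments[fragments$ref %in% refs, , drop = FALSE]
  mid <- floor((sp$start + sp$end - 1) / 2)
  seg_of <- rep(NA_character_, nrow(sp))
  for (k in seq_len(nrow(segs))) {
    seg_of[mid >= segs$start[k] & mid < segs$end[k]] <- segs$name[k]
  }
  dt <- data.table::data.table(segment = seg_of, role = sp$role, mbc = sp$mbc)
  dt <- dt[!is.na(dt$segment), ]
  grid <- expand.grid(segment = segs$name,
                      role = unique(fragments$role),
                      mbc = sort(unique(fragments$mbc)),
                      stringsAsFactors = FALSE)
  counts <- merge(grid,
                  as.data.frame(dt[, list(count = .N),
                                   by = c("segment", "role", "mbc")]),
                  by = c("segment", "role", "mbc"), all.x = TRUE)
  counts$count[is.na(counts$count)] <- 0L
  counts <- merge(counts, segs[, c("name", "mod", "role")],
                  by.x = "segment", by.y = "name",
                  suffixes = c("", "_segment"))
  names(counts)[names(counts) == "role_segment"] <- "segment_role"
  if (is.null(library_sizes)) {
    lt <- data.table::as.data.table(fragments)[, list(total = .N),
                                               by = c("role", "mbc")]
    library_sizes <- as.data.frame(lt)
  }
  counts <- merge(counts, library_sizes, by = c("role", "mbc"), all.x = TRUE)
  counts$cpm <- ifelse(is.na(counts$total) | counts$total == 0, NA_real_,
                       1e6 * counts$count / counts$total)
  structure(list(counts = counts, library_sizes = library_sizes,
                 segments = segs),
            class = "spikein_report")
}

#' Standard curves for spike-in scaling
#'
#' The enrichment factor is a 1-D monotone transform of the ratio of
#' normalized mod-segment counts to normalized internal-standard counts.
#' Available curves: \code{"identity"}, \code{"linear"} (y = a x), or a
#' piecewise-linear interpolation of a 2-column calibration table
#' (ratio, factor).
#'
#' @param type curve type.
#' @param a slope for the linear curve.
#' @param table data.frame/matrix with columns (x, y) for the
#'   piecewise-linear curve, or a path to a 2-column TSV.
#' @return a function of one numeric argument.
#' @export
standard_curve <- function(type = c("identity", "linear", "piecewise"),
                           a = 1, table = NULL) {
  type <- match.arg(type)
  switch(type,
         identity = function(x) x,
         linear = function(x) a * x,
         piecewise = {
           if (is.character(table)) {
             table <- read.table(table, sep = "\t", header = FALSE)
           }
           stopifnot(ncol(table) >= 2)
           approxfun(table[[1]], table[[2]], rule = 2)
         })
}

#' Spike-in enrichment factor for one modification
#'
#' factor = curve( cpm on the modification-specific segment(s) /
#' cpm on the internal standard ), computed on the enrichment sample using
#' the modification's own MBC channel. Normalization to counts per million
#' mapped fragments makes the factor invariant to total library depth.
#'
#' @param report a \code{\link{count_spikein}} report.
#' @param modification modification label (must match a mod-specific
#'   segment and an MBC label).
#' @param curve a standard-curve function (see \code{\link{standard_curve}});
#'   default identity.
#' @param role sample role to evaluate (default "enrichment").
#' @return positive numeric factor.
#' @export
enrichment_factor <- function(report, modification,
                              curve = standard_curve("identity"),
                              role = "enrichment") {
  ct <- report$counts
  num <- ct[ct$segment_role == "mod_specific" & ct$mod == modification &
              ct$mbc == modification & ct$role == role, ]
  den <- ct[ct$segment_role == "internal_standard" &
              ct$mbc == modification & ct$role == role, ]
  num_cpm <- sum(num$cpm)
  den_cpm <- sum(den$cpm)
  if (!is.finite(den_cpm) || den_cpm <= 0) {
    cond <- structure(class = c("spikein_failed", "error", "condition"),
                      list(message = sprintf(
                        "spikein_failed: zero internal-standard coverage for %s",
                        modification), call = sys.call()))
    stop(cond)
  }
  factor <- curve(num_cpm / den_cpm)
  stopifnot(is.finite(factor), factor > 0)
  factor
}
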