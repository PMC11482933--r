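#' Peak-calling parameters
#'
#' Defaults for the signal-processing peak caller: the per-million
#' normalized enrichment and solution-control tracks are combined into a
#' pseudocounted log2 ratio, smoothed, and searched for local maxima with a
#' minimum prominence. All values are echoed into the peak metadata.
#'
#' @param window smoothing window (nt, odd).
#' @param pseudocount ratio pseudocount (per-million units).
#' @param r_min minimum (smoothed) enrichment ratio at a summit.
#' @param prominence minimum summit prominence, in log2-ratio units.
#' @param boundary_fraction peak boundaries extend from the summit until the
#'   ratio falls below \code{boundary_fraction * r(summit)} or below
#'   \code{r_min}, whichever happens first.
#' @return list of class \code{peak_params}.
#' @export
peak_params <- function(window = 51L, pseudocount = 0.5, r_min = 2,
                        prominence = 0.5, boundary_fraction = 0.5) {
  stopifnot(window >= 1, window %% 2 == 1, pseudocount > 0, r_min > 0,
            prominence >= 0, boundary_fraction > 0, boundary_fraction <= 1)
  structure(list(window = as.integer(window), pseudocount = pseudocount,
                 r_min = r_min, prominence = prominence,
                 boundary_fraction = boundary_fraction),
            class = "peak_params")
}

#' Call peaks from enrichment versus solution-control coverage
#'
#' Both tracks are normalized to coverage per million library fragments; the
#' ratio r(x) = (signal + a) / (background + a) is smoothed in log2 space
#' and candidate summits are local maxima with prominence >=
#' \code{params$prominence} and r(summit) >= \code{params$r_min}. Peak
#' boundaries extend from the summit until the smoothed ratio drops below
#' \code{boundary_fraction * r(summit)} or below \code{r_min}; overlapping
#' candidates are merged keeping the higher summit. The raw enrichment of a
#' peak is the smoothed ratio at its summit; spike-in scaling is applied
#' separately by \code{\link{scale_peaks}}.
#'
#' @param signal,background \code{coverage_track}s on the same reference
#'   (enrichment sample and solution control), or named lists thereof.
#' @param params a \code{\link{peak_params}}.
#' @param modification modification label stored on the peaks.
#' @return data.frame of peaks: \code{ref, start, end} (0-based half-open),
#'   \code{summit, modification, raw_enrichment, fold_enrichment} (NA until
#'   scaled), \code{enrich_depth, control_depth} (raw deduplicated coverage
#'   at the summit) and \code{high_confidence} (NA until filtered), with the
#'   parameters attached as attribute \code{"params"}.
#' @export
call_peaks <- function(signal, background, params = peak_params(),
                       modification = NA_character_) {
  if (inherits(signal, "coverage_track")) signal <- list(signal)
  if (inherits(background, "coverage_track")) background <- list(background)
  out <- list()
  for (i in seq_along(signal)) {
    sig <- signal[[i]]
    ref <- sig$ref
    bg <- if (!is.null(names(background))) background[[ref]] else background[[i]]
    stopifnot(inherits(sig, "coverage_track"), inherits(bg, "coverage_track"),
              identical(sig$ref, bg$ref))
    out[[length(out) + 1L]] <- call_peaks_one(sig, bg, params, modification)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "params") <- unclass(params)
  res
}

empty_peaks <- function() {
  data.frame(ref = character(0), start = integer(0), end = integer(0),
             summit = integer(0), modification = character(0),
             raw_enrichment = numeric(0), fold_enrichment = numeric(0),
             enrich_depth = numeric(0), control_depth = numeric(0),
             high_confidence = logical(0), stringsAsFactors = FALSE)
}

#' Smoothed enrichment-ratio track
#'
#' The smoothed log2 pseudocounted ratio of per-million-normalized signal to
#' background that the peak caller operates on; exposed for reproducibility
#' checks and track export.
#'
#' @param signal,background \code{coverage_track}s on the same reference.
#' @param params a \code{\link{peak_params}}.
#' @return numeric vector of smoothed log2 ratios, one per base.
#' @export
smoothed_ratio <- function(signal, background, params = peak_params()) {
  stopifnot(identical(signal$ref, background$ref))
  sl <- if (signal$library_size > 0) signal$library_size else 1
  bl <- if (background$library_size > 0) background$library_size else 1
  ns <- signal$values / sl * 1e6
  nb <- background$values / bl * 1e6
  moving_average(log2((ns + params$pseudocount) / (nb + params$pseudocount)),
                 params$window)
}

call_peaks_one <- function(sig, bg, params, modification) {
  n <- length(sig$values)
  if (n == 0) stop_config("zero-length reference %s", sig$ref)
  if (length(bg$values) != n) stop_config("track lengths differ on %s", sig$ref)
  sl <- if (sig$library_size > 0) sig$library_size else 1
  bl <- if (bg$library_size > 0) bg$library_size else 1
  ns <- sig$values / sl * 1e6
  nb <- bg$values / bl * 1e6
  lr <- log2((ns + params$pseudocount) / (nb + params$pseudocount))
  sm <- moving_average(lr, params$window)
  sm_sig <- moving_average(ns, params$window)

  cand <- local_maxima(sm)
  if (length(cand) == 0) return(empty_peaks())
  prom <- peak_prominence(sm, cand)
  keep <- prom >= params$prominence & sm[cand] >= log2(params$r_min)
  cand <- cand[keep]
  if (length(cand) == 0) return(empty_peaks())

  lo <- integer(length(cand)); hi <- integer(length(cand))
  for (j in seq_along(cand)) {
    s <- cand[j]
    thr <- max(sm[s] + log2(params$boundary_fraction), log2(params$r_min))
    l <- s; while (l > 1L && sm[l - 1L] >= thr) l <- l - 1L
    r <- s; while (r < n && sm[r + 1L] >= thr) r <- r + 1L
    lo[j] <- l; hi[j] <- r
  }
  # merge overlapping candidates, keeping the higher summit
  ord <- order(lo)
  lo <- lo[ord]; hi <- hi[ord]; cand <- cand[ord]
  m_lo <- lo[1]; m_hi <- hi[1]; m_summit <- cand[1]
  rows <- list()
  flush <- function(a, b, s) {
    # the ratio is flat wherever fragment placement is constrained (e.g.
    # near transcript ends), so the summit is refined to the maximum of the
    # smoothed signal coverage inside the peak, which peaks at the site
    s <- a - 1L + which.max(sm_sig[a:b])
    data.frame(ref = sig$ref, start = a - 1L, end = b,
               summit = s - 1L, modification = modification,
               raw_enrichment = 2^sm[s], fold_enrichment = NA_real_,
               enrich_depth = sig$values[s], control_depth = bg$values[s],
               high_confidence = NA, stringsAsFactors = FALSE)
  }
  for (j in seq_along(cand)[-1]) {
    if (lo[j] <= m_hi) {
      m_hi <- max(m_hi, hi[j])
      if (sm[cand[j]] > sm[m_summit]) m_summit <- cand[j]
    } else {
      rows[[length(rows) + 1L]] <- flush(m_lo, m_hi, m_summit)
      m_lo <- lo[j]; m_hi <- hi[j]; m_summit <- cand[j]
    }
  }
  rows[[length(rows) + 1L]] <- flush(m_lo, m_hi, m_summit)
  do.call(rbind, rows)
}

# indices of strict local maxima; plateaus contribute their first index
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  k <- length(r$values)
  out <- integer(0)
  for (i in seq_len(k)) {
    left_ok <- i > 1 && r$values[i - 1] < r$values[i]
    right_ok <- i < k && r$values[i + 1] < r$values[i]
    if (left_ok && right_ok) out <- c(out, starts[i])
  }
  out
}

# topographic prominence of each candidate summit: height above the highest
# of the two key saddles towards the nearest higher ground (or track edge)
peak_prominence <- function(x, summits) {
  vapply(summits, function(s) {
    h <- x[s]
    left <- x[seq_len(s - 1L)]
    right <- if (s < length(x)) x[(s + 1L):length(x)] else numeric(0)
    lh <- which(left >= h)
    key_l <- if (length(lh) == 0) min(c(left, h)) else min(left[max(lh):length(left)])
    rh <- which(right >= h)
    key_r <- if (length(rh) == 0) min(c(right, h)) else min(right[seq_len(min(rh))])
    h - max(key_l, key_r)
  }, numeric(1))
}

#' Scale raw peak enrichment by spike-in factors
#'
#' fold_enrichment = raw enrichment x the modification's spike-in enrichment
#' factor; positive factors preserve the within-modification peak ranking.
#'
#' @param peaks peak data.frame from \code{\link{call_peaks}}.
#' @param factors named numeric vector (modification -> factor, all > 0), or
#'   a single factor applied to all peaks.
#' @return the peaks with \code{fold_enrichment} filled in.
#' @export
scale_peaks <- function(peaks, factors) {
  stopifnot(all(factors > 0))
  if (nrow(peaks) == 0) {
    peaks$fold_enrichment <- numeric(0)
    return(peaks)
  }
  f <- if (length(factors) == 1 && is.null(names(factors))) {
    rep(factors, nrow(peaks))
  } else {
    unname(factors[peaks$modification])
  }
  stopifnot(!anyNA(f))
  peaks$fold_enrichment <- peaks$raw_enrichment * f
  peaks
}
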