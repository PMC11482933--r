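#' Per-base fragment coverage tracks
#'
#' Counts, for every base of each reference, the number of deduplicated
#' fragments overlapping it (0-based half-open fragment intervals).
#'
#' @param fragments fragment data.frame (\code{ref, start, end}).
#' @param reference_lengths named integer vector of reference lengths.
#' @param library_size library size recorded on the tracks for later
#'   normalization; defaults to \code{nrow(fragments)}.
#' @return named list of \code{coverage_track} objects (one per reference in
#'   \code{reference_lengths}).
#' @export
build_coverage <- function(fragments, reference_lengths,
                           library_size = nrow(fragments)) {
  stopifnot(!is.null(names(reference_lengths)))
  out <- list()
  for (ref in names(reference_lengths)) {
    len <- reference_lengths[[ref]]
    fr <- fragments[fragments$ref == ref, , drop = FALSE]
    if (nrow(fr) > 0 && any(fr$end > len | fr$start < 0)) {
      stop_config("fragment beyond reference end on %s", ref)
    }
    vals <- if (nrow(fr) == 0) integer(len) else {
      as.integer(IRanges::coverage(iranges0(fr$start, fr$end), width = len))
    }
    out[[ref]] <- coverage_track(vals, ref, library_size)
  }
  out
}

coverage_track <- function(values, ref, library_size, smoothing = "none") {
  stopifnot(all(values >= 0))
  structure(list(values = as.numeric(values), ref = ref,
                 library_size = library_size, smoothing = smoothing),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("coverage_track %s: %d bases, library %s, smoothing %s\n",
              x$ref, length(x$values), format(x$library_size), x$smoothing))
  invisible(x)
}

#' Centered moving-average smoothing
#'
#' Smooths a coverage track (or plain numeric vector) with a centered moving
#' average; at the edges the window shrinks to the available bases, so the
#' track sum is preserved up to edge effects.
#'
#' @param track a \code{coverage_track} or numeric vector.
#' @param window_nt odd window width >= 1 (1 = identity).
#' @return same type as the input.
#' @export
smooth_track <- function(track, window_nt) {
  stopifnot(window_nt >= 1, window_nt %% 2 == 1)
  if (inherits(track, "coverage_track")) {
    out <- track
    out$values <- moving_average(track$values, window_nt)
    out$smoothing <- sprintf("ma%d", window_nt)
    return(out)
  }
  moving_average(track, window_nt)
}

moving_average <- function(x, w) {
  if (w == 1 || length(x) == 0) return(as.numeric(x))
  n <- length(x)
  h <- (w - 1) %/% 2
  cs <- c(0, cumsum(x))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}
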