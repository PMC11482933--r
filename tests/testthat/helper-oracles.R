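# Independent brute-force oracles used to cross-check the implementation.

# O(n^2) duplicate scan: keep, per (ref, start, strand, mbc, umi) key, the
# fragment with the highest mean_qual, ties broken by read_id.
bf_dedup <- function(frags) {
  keep <- rep(TRUE, nrow(frags))
  key <- function(i) paste(frags$ref[i], frags$start[i], frags$strand[i],
                           frags$mbc[i], frags$umi[i])
  for (i in seq_len(nrow(frags))) {
    for (j in seq_len(nrow(frags))) {
      if (i == j || key(i) != key(j)) next
      better_j <- frags$mean_qual[j] > frags$mean_qual[i] ||
        (frags$mean_qual[j] == frags$mean_qual[i] &&
           frags$read_id[j] < frags$read_id[i])
      if (better_j) keep[i] <- FALSE
    }
  }
  out <- frags[keep, , drop = FALSE]
  out[order(out$ref, out$start, out$read_id), , drop = FALSE]
}

# per-base overlap count by looping positions
bf_coverage <- function(frags, len) {
  v <- integer(len)
  for (i in seq_len(nrow(frags))) {
    for (p in seq(frags$start[i], frags$end[i] - 1L)) v[p + 1L] <- v[p + 1L] + 1L
  }
  v
}

# per-read per-base pileup walk (full-match alignments, no cap)
bf_pileup_counts <- function(frags, r_lo, r_hi) {
  width <- r_hi - r_lo
  counts <- matrix(0L, nrow = width, ncol = 4L,
                   dimnames = list(NULL, c("A", "C", "G", "T")))
  for (i in seq_len(nrow(frags))) {
    bases <- strsplit(frags$seq[i], "")[[1]]
    for (k in seq_along(bases)) {
      pos <- frags$start[i] + k - 1L
      if (pos >= r_lo && pos < r_hi && bases[k] %in% colnames(counts)) {
        counts[pos - r_lo + 1L, bases[k]] <- counts[pos - r_lo + 1L, bases[k]] + 1L
      }
    }
  }
  counts
}

# direct one-direction FPR: fraction of a-peaks with fe >= cc lacking any
# >=1 nt overlap in b
bf_fpr <- function(a, b, cc) {
  d <- a$fold_enrichment >= cc
  if (!any(d)) return(NA_real_)
  miss <- vapply(which(d), function(i) {
    !any(b$ref == a$ref[i] & b$start < a$end[i] & b$end > a$start[i])
  }, logical(1))
  mean(miss)
}

# Lance-Williams Ward agglomeration on squared Euclidean distances;
# returns the merge sequence (sorted member sets) and heights
bf_ward <- function(X) {
  n <- nrow(X)
  d2 <- as.matrix(dist(X))^2
  active <- as.list(seq_len(n))
  sizes <- rep(1L, n)
  merges <- list(); heights <- numeric(0)
  repeat {
    k <- length(active)
    if (k == 1) break
    best <- c(NA, NA); bestd <- Inf
    for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
      if (d2[i, j] < bestd) { bestd <- d2[i, j]; best <- c(i, j) }
    }
    i <- best[1]; j <- best[2]
    merges[[length(merges) + 1L]] <- sort(unlist(active[c(i, j)]))
    heights <- c(heights, bestd)
    ni <- sizes[i]; nj <- sizes[j]
    newrow <- vapply(seq_len(k), function(h) {
      if (h %in% c(i, j)) return(NA_real_)
      nh <- sizes[h]
      ((ni + nh) * d2[i, h] + (nj + nh) * d2[j, h] - nh * d2[i, j]) /
        (ni + nj + nh)
    }, numeric(1))
    keep <- setdiff(seq_len(k), c(i, j))
    d2 <- rbind(cbind(d2[keep, keep, drop = FALSE], newrow[keep]),
                c(newrow[keep], 0))
    active <- c(active[keep], list(sort(unlist(active[c(i, j)]))))
    sizes <- c(sizes[keep], ni + nj)
  }
  list(merges = merges, heights = heights)
}

# member sets of each hclust merge step
hclust_merge_sets <- function(hc) {
  sets <- list()
  for (s in seq_len(nrow(hc$merge))) {
    members <- function(x) {
      if (x < 0) return(-x)
      unlist(lapply(hc$merge[x, ], members))
    }
    sets[[s]] <- sort(unlist(lapply(hc$merge[s, ], members)))
  }
  sets
}

# combinatorial expansion of the DRACH consensus (T stands for U)
drach_expand <- function() {
  out <- character(0)
  for (d in c("A", "G", "T")) for (r in c("A", "G")) for (h in c("A", "C", "T")) {
    out <- c(out, paste0(d, r, "A", "C", h))
  }
  sort(out)
}

# random peak set on one reference
random_peaks <- function(n, ref = "chrT", len = 10000L, mod = "m6A") {
  start <- sort(sample.int(len - 200L, n))
  width <- sample(30:150, n, replace = TRUE)
  data.frame(ref = ref, start = start, end = pmin(start + width, len),
             summit = pmin(start + width %/% 2, len - 1L),
             modification = mod,
             raw_enrichment = runif(n, 1, 10),
             fold_enrichment = runif(n, 1, 40),
             enrich_depth = sample(1:60, n, replace = TRUE),
             control_depth = sample(1:30, n, replace = TRUE),
             high_confidence = NA, stringsAsFactors = FALSE)
}
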