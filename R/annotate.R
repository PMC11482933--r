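#' Assign peaks to gene features
#'
#' Annotation is by summit position (interval mode available via
#' \code{by = "interval"}, which uses any overlap). When a summit hits
#' features of multiple transcripts the precedence is
#' 3'UTR > 5'UTR > CDS-exon > ncRNA-exon > intron; summits outside all genes
#' are \code{"intergenic"}. Assignment is strand-agnostic in position but
#' the reported gene carries its own strand, so mirroring the annotation to
#' the opposite strand yields identical labels.
#'
#' @param peaks peak data.frame (\code{ref, summit} or \code{ref, start,
#'   end}).
#' @param model a \code{transcript_model}.
#' @param by "summit" (default) or "interval".
#' @return the peaks with \code{feature}, \code{gene_id} and \code{strand}
#'   (transcript strand of the assigned gene, "." for intergenic) columns.
#' @export
assign_feature <- function(peaks, model, by = c("summit", "interval")) {
  by <- match.arg(by)
  feature_order <- c(utr3 = 1L, utr5 = 2L, cds_exon = 3L, ncrna_exon = 4L,
                     intron = 5L)
  labels <- c(utr3 = "3'UTR", utr5 = "5'UTR", cds_exon = "CDS-exon",
              ncrna_exon = "ncRNA-exon", intron = "intron")
  peaks$feature <- rep("intergenic", nrow(peaks))
  peaks$gene_id <- rep(NA_character_, nrow(peaks))
  if (is.null(peaks$strand)) peaks$strand <- rep(".", nrow(peaks))
  if (nrow(peaks) == 0) return(peaks)
  f <- model$features
  q <- if (by == "summit") {
    granges0(peaks$ref, peaks$summit, peaks$summit + 1L)
  } else {
    granges0(peaks$ref, peaks$start, peaks$end)
  }
  s <- granges0(f$chrom, f$start, f$end)
  ov <- IRanges::findOverlaps(q, s, ignore.strand = TRUE)
  if (length(ov) == 0) return(peaks)
  d <- data.frame(pi = S4Vectors::queryHits(ov),
                  type = f$type[S4Vectors::subjectHits(ov)],
                  gene = f$gene_id[S4Vectors::subjectHits(ov)],
                  strand = f$strand[S4Vectors::subjectHits(ov)])
  d$prec <- feature_order[d$type]
  d <- d[order(d$pi, d$prec, d$gene), ]
  d <- d[!duplicated(d$pi), ]
  peaks$feature[d$pi] <- unname(labels[d$type])
  peaks$gene_id[d$pi] <- d$gene
  peaks$strand[d$pi] <- d$strand
  peaks
}

# distance from the TSS along the unspliced transcript (0-based)
tx_offset <- function(model, gene_id, pos) {
  g <- model$genes[model$genes$gene_id == gene_id, ]
  if (g$strand == "+") pos - g$start else g$end - 1L - pos
}

# per-gene segment lengths in transcript order: utr5, cds-with-introns, utr3
gene_segments <- function(model, gene_id) {
  f <- model$features[model$features$gene_id == gene_id, ]
  f <- f[order(f$tx_rank), ]
  w <- f$end - f$start
  utr5 <- sum(w[f$type == "utr5"])
  utr3 <- sum(w[f$type == "utr3"])
  body <- sum(w) - utr5 - utr3
  c(utr5 = utr5, cds = body, utr3 = utr3)
}

#' Metagene profile over 5'UTR | CDS | 3'UTR
#'
#' Maps every annotated peak summit to a fractional position within its
#' transcript segment and histograms the result over concatenated
#' 5'UTR/CDS/3'UTR bins. Intronic summits count within the CDS segment
#' (positions along the unspliced transcript body), matching peak calling in
#' genome space.
#'
#' @param peaks peaks annotated by \code{\link{assign_feature}} (need
#'   \code{gene_id}, \code{summit}).
#' @param model a \code{transcript_model}.
#' @param bins named integer vector of bin counts per segment.
#' @return data.frame of class \code{metagene_profile}: \code{bin} (1-based,
#'   over all segments), \code{segment}, \code{density} (sums to 1).
#' @export
metagene_profile <- function(peaks, model,
                             bins = c(utr5 = 30L, cds = 60L, utr3 = 30L)) {
  stopifnot(all(c("utr5", "cds", "utr3") %in% names(bins)))
  total_bins <- sum(bins)
  counts <- numeric(total_bins)
  seg_names <- rep(c("utr5", "cds", "utr3"),
                   times = bins[c("utr5", "cds", "utr3")])
  offsets <- c(utr5 = 0L, cds = bins[["utr5"]],
               utr3 = bins[["utr5"]] + bins[["cds"]])
  use <- !is.na(peaks$gene_id)
  for (i in which(use)) {
    segs <- gene_segments(model, peaks$gene_id[i])
    off <- tx_offset(model, peaks$gene_id[i], peaks$summit[i])
    if (is.na(off) || off < 0 || off >= sum(segs)) next
    if (off < segs[["utr5"]]) {
      seg <- "utr5"; frac <- off / max(segs[["utr5"]], 1)
    } else if (off < segs[["utr5"]] + segs[["cds"]]) {
      seg <- "cds"; frac <- (off - segs[["utr5"]]) / max(segs[["cds"]], 1)
    } else {
      seg <- "utr3"
      frac <- (off - segs[["utr5"]] - segs[["cds"]]) / max(segs[["utr3"]], 1)
    }
    b <- offsets[[seg]] + pmin(floor(frac * bins[[seg]]) + 1L, bins[[seg]])
    counts[b] <- counts[b] + 1
  }
  dens <- if (sum(counts) > 0) counts / sum(counts) else counts
  out <- data.frame(bin = seq_len(total_bins), segment = seg_names,
                    density = dens, stringsAsFactors = FALSE)
  class(out) <- c("metagene_profile", "data.frame")
  out
}

#' Scan a sequence for DRACH motifs
#'
#' Returns the 0-based start positions of every 5-mer matching DRACH
#' (D = A/G/T, R = A/G, H = A/C/T; the methylated A sits at motif position
#' 3) on the sense strand. U and T are equivalent.
#'
#' @param sequence a single character string or \code{DNAString} over
#'   ACGT(N) (U accepted).
#' @return integer vector of 0-based match positions.
#' @export
drach_scan <- function(sequence) {
  if (is.character(sequence)) {
    sequence <- chartr("Uu", "Tt", sequence)
    sequence <- Biostrings::DNAString(toupper(sequence))
  }
  m <- Biostrings::matchPattern("DRACH", sequence, fixed = FALSE)
  BiocGenerics::start(m) - 1L
}

#' DRACH motif-shift profile around peak summits
#'
#' For every annotated m6A peak summit, the signed transcript-strand
#' distance to the nearest DRACH adenosine is collected; the null is the
#' same statistic for positions drawn uniformly from the gene bodies
#' (weighted by length). Densities are binned over a +/- \code{window} nt
#' range.
#'
#' @param peaks peaks annotated with \code{gene_id} and \code{summit}.
#' @param genome \code{DNAStringSet} of chromosome sequences.
#' @param model a \code{transcript_model}.
#' @param window half-width (nt) of the profile.
#' @param binwidth histogram bin width (nt).
#' @param n_null number of null positions (default 20x the observed count).
#' @param seed seed for the null draw.
#' @return list of class \code{motif_shift_profile}: \code{$distances},
#'   \code{$null_distances}, \code{$density} (data.frame bin_mid /
#'   observed / null, each normalized within the window), \code{$window}.
#' @export
motif_shift <- function(peaks, genome, model, window = 500L, binwidth = 10L,
                        n_null = NULL, seed = 1L) {
  use <- which(!is.na(peaks$gene_id))
  drach_by_gene <- list()
  gene_a_pos <- function(gid) {
    if (is.null(drach_by_gene[[gid]])) {
      drach_by_gene[[gid]] <<- drach_scan(gene_sense_seq(model, genome, gid)) + 2L
    }
    drach_by_gene[[gid]]
  }
  dist_one <- function(gid, pos) {
    a <- gene_a_pos(gid)
    if (length(a) == 0) return(NA_real_)
    off <- tx_offset(model, gid, pos)
    d <- a - off
    as.numeric(d[which.min(abs(d))])
  }
  obs <- vapply(use, function(i) {
    dist_one(peaks$gene_id[i], peaks$summit[i])
  }, numeric(1))
  obs <- obs[!is.na(obs)]

  if (is.null(n_null)) n_null <- max(20L * length(obs), 1000L)
  null <- with_seed(seed, {
    glens <- model$genes$end - model$genes$start
    gi <- sample.int(nrow(model$genes), n_null, replace = TRUE, prob = glens)
    pos <- model$genes$start[gi] +
      floor(runif(n_null) * (model$genes$end[gi] - model$genes$start[gi]))
    vapply(seq_len(n_null), function(k) {
      dist_one(model$genes$gene_id[gi[k]], pos[k])
    }, numeric(1))
  })
  null <- null[!is.na(null)]
  if (length(obs) == 0 && length(null) == 0) {
    warning("no DRACH motif available; empty motif-shift profile")
  }
  breaks <- seq(-window, window, by = binwidth)
  bin_density <- function(d) {
    d <- d[d >= -window & d <= window]
    if (length(d) == 0) return(rep(0, length(breaks) - 1L))
    h <- graphics::hist(d, breaks = breaks, plot = FALSE)
    h$counts / sum(h$counts)
  }
  dens <- data.frame(bin_mid = (head(breaks, -1) + tail(breaks, -1)) / 2,
                     observed = bin_density(obs), null = bin_density(null))
  structure(list(distances = obs, null_distances = null, density = dens,
                 window = window),
            class = "motif_shift_profile")
}

#' Central motif enrichment of a motif-shift profile
#'
#' Ratio of observed to null probability mass within \code{half_width} nt of
#' the summit.
#'
#' @param profile a \code{motif_shift_profile}.
#' @param half_width central window half-width (nt).
#' @return numeric ratio (Inf when the null mass is zero).
#' @export
central_enrichment <- function(profile, half_width = 50) {
  inside <- abs(profile$density$bin_mid) <= half_width
  obs <- sum(profile$density$observed[inside])
  nul <- sum(profile$density$null[inside])
  if (nul == 0) return(Inf)
  obs / nul
}
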