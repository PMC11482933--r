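#' Plant ground-truth modification sites
#'
#' Places m6A sites exclusively on DRACH-matching adenosines (the modified A
#' at position 3 of the 5-mer, transcript-strand orientation) with a
#' configurable 3'UTR bias, and inosine sites on transcript-strand adenosines
#' biased towards introns and UTRs. Sites of the same modification are kept
#' at least \code{min_site_distance} apart so that each corresponds to a
#' resolvable peak. Sites that cannot be placed (no legal position left) are
#' skipped with a warning carrying the skipped count.
#'
#' @param model a \code{transcript_model}.
#' @param genome \code{DNAStringSet} with the chromosome sequences.
#' @param config a \code{\link{sim_config}}.
#' @param bed optional path; when given the truth is written as BED6+
#'   (0-based half-open, stoichiometry column).
#' @return data.frame of sites: \code{site_id, chrom, pos} (0-based position
#'   of the modified A), \code{strand, gene_id, mod, stoichiometry, context}
#'   (5-mer, m6A only), \code{region}.
#' @export
plant_modifications <- function(model, genome, config, bed = NULL) {
  span_kb <- sum(model$genes$end - model$genes$start) / 1000
  counts <- planned_site_counts(config, span_kb)
  sites <- with_seed(stage_seed(config$seed, 2L), {
    m6a <- plant_m6a(model, genome, config, counts[["m6A"]] %||% 0L)
    ino <- plant_inosine(model, genome, config, counts[["inosine"]] %||% 0L,
                         avoid = m6a)
    rbind(m6a, ino)
  })
  if (nrow(sites) > 0) {
    sites$site_id <- sprintf("%s_site%03d", sites$mod,
                             stats::ave(seq_len(nrow(sites)), sites$mod,
                                        FUN = seq_along))
    sites <- sites[, c("site_id", "chrom", "pos", "strand", "gene_id", "mod",
                       "stoichiometry", "context", "region")]
  }
  if (!is.null(bed)) write_truth_bed(sites, bed)
  sites
}

empty_sites <- function() {
  data.frame(chrom = character(0), pos = integer(0), strand = character(0),
             gene_id = character(0), mod = character(0),
             stoichiometry = numeric(0), context = character(0),
             region = character(0), stringsAsFactors = FALSE)
}

# DRACH candidates over all genes: genomic A position, containing exonic
# region, and the 5-mer context.
drach_candidates <- function(model, genome) {
  rows <- list()
  for (i in seq_len(nrow(model$genes))) {
    g <- model$genes[i, ]
    sense <- gene_sense_seq(model, genome, g$gene_id)
    hits <- drach_scan(sense)
    if (length(hits) == 0) next
    a_off <- hits + 2L                      # modified A, sense coords
    pos <- if (g$strand == "+") g$start + a_off else g$end - 1L - a_off
    m_lo <- if (g$strand == "+") g$start + hits else g$end - hits - 5L
    m_hi <- m_lo + 5L
    ctx <- substring(sense, hits + 1L, hits + 5L)
    feats <- model$features[model$features$gene_id == g$gene_id, ]
    region <- feature_at(feats, pos)
    ok <- region %in% c("utr5", "cds_exon", "utr3") &
      contained_in_feature(feats, region, m_lo, m_hi)
    if (!any(ok)) next
    rows[[g$gene_id]] <- data.frame(
      chrom = g$chrom, pos = pos[ok], strand = g$strand, gene_id = g$gene_id,
      context = ctx[ok], region = region[ok], stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) return(NULL)
  do.call(rbind, rows)
}

# region type of each position within one gene's features ("" if none)
feature_at <- function(feats, pos) {
  out <- rep("", length(pos))
  for (j in seq_len(nrow(feats))) {
    in_j <- pos >= feats$start[j] & pos < feats$end[j]
    out[in_j] <- feats$type[j]
  }
  out
}

contained_in_feature <- function(feats, region, lo, hi) {
  out <- rep(FALSE, length(lo))
  for (j in seq_len(nrow(feats))) {
    out <- out | (lo >= feats$start[j] & hi <= feats$end[j])
  }
  out
}

plant_m6a <- function(model, genome, cfg, n) {
  if (n == 0) return(empty_sites())
  cand <- drach_candidates(model, genome)
  if (is.null(cand) || nrow(cand) == 0) {
    warning(sprintf("m6A: 0 of %d sites planted (no DRACH position available)", n))
    return(empty_sites())
  }
  chosen <- integer(0)
  skipped <- 0L
  for (s in seq_len(n)) {
    avail <- setdiff(seq_len(nrow(cand)), chosen)
    if (length(chosen) > 0) {
      faroff <- abs(outer(cand$pos[avail], cand$pos[chosen], "-")) >=
        cfg$min_site_distance
      avail <- avail[rowSums(!faroff) == 0]
    }
    if (length(avail) == 0) { skipped <- skipped + 1L; next }
    use_utr3 <- runif(1) < cfg$utr3_bias
    pool <- if (use_utr3) avail[cand$region[avail] == "utr3"] else avail
    if (length(pool) == 0) {
      if (use_utr3 && cfg$utr3_bias >= 1) { skipped <- skipped + 1L; next }
      pool <- avail
    }
    chosen <- c(chosen, pool[sample.int(length(pool), 1L)])
  }
  if (skipped > 0) {
    warning(sprintf("m6A: %d of %d sites skipped (no legal position)", skipped, n))
  }
  out <- cand[chosen, , drop = FALSE]
  out$mod <- "m6A"
  out$stoichiometry <- runif(nrow(out), cfg$stoichiometry_range[1],
                             cfg$stoichiometry_range[2])
  rownames(out) <- NULL
  out[, names(empty_sites())]
}

plant_inosine <- function(model, genome, cfg, n, avoid = NULL) {
  if (n == 0) return(empty_sites())
  feats <- model$features
  chosen <- empty_sites()
  skipped <- 0L
  w <- cfg$inosine_region_weights
  for (s in seq_len(n)) {
    placed <- FALSE
    for (try in seq_len(200L)) {
      region <- sample(names(w), 1L, prob = w)
      fpool <- feats[feats$type == region, , drop = FALSE]
      if (nrow(fpool) == 0) next
      f <- fpool[sample.int(nrow(fpool), 1L, prob = fpool$end - fpool$start), ]
      seq <- substr(as.character(genome[[f$chrom]]), f$start + 1L, f$end)
      if (f$strand == "-") seq <- revcomp(seq)
      a_off <- gregexpr("A", seq, fixed = TRUE)[[1]]
      if (a_off[1] == -1) next
      off <- a_off[sample.int(length(a_off), 1L)] - 1L
      pos <- if (f$strand == "+") f$start + off else f$end - 1L - off
      if (nrow(chosen) > 0 &&
          any(abs(chosen$pos - pos) < cfg$min_site_distance)) next
      chosen <- rbind(chosen, data.frame(
        chrom = f$chrom, pos = pos, strand = f$strand, gene_id = f$gene_id,
        mod = "inosine", stoichiometry = runif(1, cfg$stoichiometry_range[1],
                                               cfg$stoichiometry_range[2]),
        context = NA_character_, region = region, stringsAsFactors = FALSE))
      placed <- TRUE
      break
    }
    if (!placed) skipped <- skipped + 1L
  }
  if (skipped > 0) {
    warning(sprintf("inosine: %d of %d sites skipped (no legal position)",
                    skipped, n))
  }
  chosen
}

#' Write / read a ground-truth site BED
#'
#' BED6+2 (0-based half-open): name = site id, score = round(1000 x
#' stoichiometry), extra columns modification and stoichiometry.
#'
#' @param sites site data.frame from \code{\link{plant_modifications}}.
#' @param path output path.
#' @export
write_truth_bed <- function(sites, path) {
  d <- data.frame(chrom = sites$chrom, start = sites$pos,
                  end = sites$pos + 1L, name = sites$site_id,
                  score = round(1000 * sites$stoichiometry),
                  strand = sites$strand, mod = sites$mod,
                  stoichiometry = sites$stoichiometry)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @rdname write_truth_bed
#' @export
read_truth_bed <- function(path) {
  d <- read.table(path, sep = "\t", stringsAsFactors = FALSE)
  names(d) <- c("chrom", "start", "end", "name", "score", "strand", "mod",
                "stoichiometry")[seq_len(ncol(d))]
  d
}
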