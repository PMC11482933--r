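#' Match peaks across conditions into loci
#'
#' Overlapping peak intervals (>= 1 nt, same modification) across all
#' conditions are merged by single linkage into loci; per locus and
#' condition the fold-enrichment is the maximum over contributing peaks and
#' absence is recorded as 0 with a presence flag. Every input peak
#' contributes to exactly one locus.
#'
#' @param peak_sets named list of peak data.frames (one per condition),
#'   each with \code{ref, start, end, fold_enrichment, modification} and
#'   optionally \code{gene_id}.
#' @return data.frame of class \code{peak_match_table}: \code{locus_id,
#'   ref, start, end, modification, gene_id} plus \code{fe_<condition>} and
#'   \code{present_<condition>} columns.
#' @export
match_peaks <- function(peak_sets) {
  stopifnot(length(peak_sets) >= 2, !is.null(names(peak_sets)))
  mods <- unique(unlist(lapply(peak_sets, function(p) p$modification)))
  mods <- mods[!is.na(mods)]
  if (length(mods) > 1) {
    stop_config("match_peaks received mixed modifications: %s",
                paste(mods, collapse = ", "))
  }
  all_pk <- do.call(rbind, lapply(names(peak_sets), function(cn) {
    p <- peak_sets[[cn]]
    data.frame(cond = cn, ref = p$ref, start = p$start, end = p$end,
               fe = p$fold_enrichment,
               gene_id = p$gene_id %||% rep(NA_character_, nrow(p)),
               stringsAsFactors = FALSE)
  }))
  if (nrow(all_pk) == 0) {
    stop_config("match_peaks: no peaks in any condition")
  }
  gr <- granges0(all_pk$ref, all_pk$start, all_pk$end)
  # >= 1 nt overlap only: abutting peaks stay distinct loci
  loci <- GenomicRanges::reduce(gr, ignore.strand = TRUE, min.gapwidth = 0L)
  hit <- IRanges::findOverlaps(gr, loci)
  all_pk$locus <- NA_integer_
  all_pk$locus[S4Vectors::queryHits(hit)] <- S4Vectors::subjectHits(hit)

  n_loci <- length(loci)
  out <- data.frame(
    locus_id = sprintf("locus%05d", seq_len(n_loci)),
    ref = as.character(GenomicRanges::seqnames(loci)),
    start = BiocGenerics::start(loci) - 1L,
    end = BiocGenerics::end(loci),
    modification = if (length(mods) == 1) mods else NA_character_,
    gene_id = NA_character_, stringsAsFactors = FALSE)
  for (cn in names(peak_sets)) {
    fe <- rep(0, n_loci); pres <- rep(FALSE, n_loci)
    sub <- all_pk[all_pk$cond == cn, ]
    if (nrow(sub) > 0) {
      agg <- tapply(sub$fe, sub$locus, max)
      fe[as.integer(names(agg))] <- agg
      pres[as.integer(names(agg))] <- TRUE
    }
    out[[paste0("fe_", cn)]] <- fe
    out[[paste0("present_", cn)]] <- pres
  }
  gid <- tapply(all_pk$gene_id, all_pk$locus,
                function(g) { g <- g[!is.na(g)]; if (length(g)) g[1] else NA })
  out$gene_id[as.integer(names(gid))] <- unlist(gid)
  class(out) <- c("peak_match_table", "data.frame")
  out
}

#' Fold-enrichment correlation between two conditions
#'
#' Pearson correlation of the fold-enrichment values over loci present in
#' both conditions (condition-unique loci are excluded, and reported
#' separately in the table's presence flags).
#'
#' @param table a \code{\link{match_peaks}} table.
#' @param cond_a,cond_b condition names.
#' @return list: \code{r}, \code{r_squared}, \code{n} (shared loci).
#' @export
peak_correlation <- function(table, cond_a, cond_b) {
  shared <- table[[paste0("present_", cond_a)]] &
    table[[paste0("present_", cond_b)]]
  if (sum(shared) < 3) stop_config("fewer than 3 shared loci")
  x <- table[[paste0("fe_", cond_a)]][shared]
  y <- table[[paste0("fe_", cond_b)]][shared]
  r <- cor(x, y)
  list(r = r, r_squared = r^2, n = sum(shared))
}

#' Wilcoxon rank-sum test
#'
#' Two-sided Wilcoxon rank-sum: exact when both samples have n <= 8 and no
#' ties are present, otherwise the normal approximation with tie correction
#' and continuity correction. The statistic is rank-based, hence invariant
#' under any common strictly monotone transform of both samples.
#'
#' @param values_a,values_b numeric samples (n >= 1 each).
#' @return list: \code{statistic} (Mann-Whitney W for sample a),
#'   \code{p_value}, \code{method}.
#' @export
rank_test <- function(values_a, values_b) {
  stopifnot(length(values_a) >= 1, length(values_b) >= 1)
  ties <- anyDuplicated(c(values_a, values_b)) > 0
  exact <- !ties && length(values_a) <= 8 && length(values_b) <= 8
  ht <- suppressWarnings(
    wilcox.test(values_a, values_b, alternative = "two.sided",
                exact = exact, correct = TRUE))
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       method = if (exact) "exact" else "normal approximation")
}

#' Cluster gene-level modification scores
#'
#' Aggregates each gene's loci to a mean fold-enrichment per condition,
#' z-scores the profile across conditions within each gene, and clusters
#' genes by agglomerative (Ward) linkage on Euclidean distances. Rows are
#' ordered by gene id, so the result is deterministic for a given table.
#'
#' @param table a \code{\link{match_peaks}} table with gene ids.
#' @param k number of clusters to cut the tree into (default 2).
#' @param zscore_axis "conditions" (default: z-score each gene's profile
#'   across conditions) or "genes" (z-score each condition across genes).
#' @return list: \code{assignments} (named integer vector),
#'   \code{hclust}, \code{scores} (gene x condition z-score matrix).
#' @export
cluster_gene_scores <- function(table, k = 2L,
                                zscore_axis = c("conditions", "genes")) {
  zscore_axis <- match.arg(zscore_axis)
  conds <- sub("^fe_", "", grep("^fe_", names(table), value = TRUE))
  stopifnot(length(conds) >= 2)
  tb <- table[!is.na(table$gene_id), , drop = FALSE]
  genes <- sort(unique(tb$gene_id))
  stopifnot(length(genes) >= 2)
  m <- matrix(0, nrow = length(genes), ncol = length(conds),
              dimnames = list(genes, conds))
  for (cn in conds) {
    agg <- tapply(tb[[paste0("fe_", cn)]], tb$gene_id, mean)
    m[names(agg), cn] <- agg
  }
  z <- if (zscore_axis == "conditions") {
    t(apply(m, 1, function(v) {
      s <- sd(v)
      if (!is.finite(s) || s == 0) rep(0, length(v)) else (v - mean(v)) / s
    }))
  } else {
    apply(m, 2, function(v) {
      s <- sd(v)
      if (!is.finite(s) || s == 0) rep(0, length(v)) else (v - mean(v)) / s
    })
  }
  dimnames(z) <- dimnames(m)
  hc <- hclust(dist(z, method = "euclidean"), method = "ward.D2")
  list(assignments = cutree(hc, k = min(k, length(genes))), hclust = hc,
       scores = z)
}
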