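#' Simulation configuration
#'
#' Builds the fully-seeded configuration that drives the synthetic library
#' generator. The defaults describe the desk-scale study condition used
#' throughout the test-suite: a ~50 kb toy transcriptome of 8 intron-bearing
#' genes carrying 20 m6A sites (3'UTR-biased, DRACH-constrained) and 10
#' inosine sites (intron/UTR-biased), fragmented to ~140 bp, captured on
#' modification-specific beads with an 8-fold capture boost over unmodified
#' fragments, alongside an unenriched solution control.
#'
#' @param seed integer; fully determines every simulator output.
#' @param n_genes number of genes to simulate.
#' @param gene_length_range integer range (nt) of the exonic (mature) length
#'   of each gene; introns add to the genomic span.
#' @param utr_fractions named proportions of the mature transcript assigned
#'   to \code{utr5}, \code{cds} and \code{utr3}; must sum to 1.
#' @param n_introns_range integer range of introns per gene (inserted into
#'   the CDS; UTRs stay intron-free).
#' @param intron_length_range,intergenic_gap_range integer ranges (nt).
#' @param frag_len_mean,frag_len_sd fragment length distribution (nt);
#'   lengths are drawn Normal and truncated at >= 1.
#' @param mbc_length,umi_length barcode lengths (nt) on read 2.
#' @param read1_length,read2_length sequencing read lengths (nt); read 2
#'   carries MBC then UMI at its 5' end, then insert.
#' @param n_reads_enrich,n_reads_control number of fragments offered to the
#'   capture reaction / sampled into the solution control. The realized
#'   enrichment library is the captured subset, so it is smaller than
#'   \code{n_reads_enrich} whenever \code{capture_enrichment > 1}.
#' @param capture_enrichment fold-boost of the capture probability of a
#'   modified fragment relative to an unmodified one (1 = no enrichment).
#' @param inosine_editing_rate fraction of reads over an edited adenosine
#'   that report G, multiplied by the site stoichiometry.
#' @param spikein_fraction proportion of fragments drawn from the spike-in
#'   reference.
#' @param n_sites named integer vector: number of m6A and inosine sites to
#'   plant (overridden by \code{mod_site_density} when that is non-NULL).
#' @param mod_site_density optional named density (sites per kb of gene
#'   span) per modification.
#' @param utr3_bias probability that a planted m6A site is drawn from the
#'   3'UTR DRACH pool rather than from all exonic DRACH positions.
#' @param inosine_region_weights named sampling weights over gene regions
#'   (\code{intron}, \code{utr5}, \code{utr3}, \code{cds_exon}) for inosine
#'   placement.
#' @param min_site_distance minimum genomic distance (nt) between planted
#'   sites of the same modification, so that ground-truth peaks are
#'   resolvable at fragment/smoothing scale.
#' @param stoichiometry_range uniform range for per-site stoichiometry.
#' @param seq_error_rate uniform per-base substitution error rate.
#' @param pcr_duplicate_rate expected fraction of additional PCR duplicate
#'   reads appended to each library.
#' @param mbc_whitelist named character vector of modification barcodes;
#'   names are modification labels.
#' @param expression_sdlog lognormal sdlog of per-gene expression weights.
#' @return A validated list of class \code{sim_config}.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 8L,
                       gene_length_range = c(2500L, 3500L),
                       utr_fractions = c(utr5 = 0.15, cds = 0.55, utr3 = 0.30),
                       n_introns_range = c(1L, 3L),
                       intron_length_range = c(200L, 600L),
                       intergenic_gap_range = c(500L, 1500L),
                       frag_len_mean = 140,
                       frag_len_sd = 20,
                       mbc_length = 8L,
                       umi_length = 10L,
                       read1_length = 100L,
                       read2_length = 60L,
                       n_reads_enrich = 40000L,
                       n_reads_control = 40000L,
                       capture_enrichment = 8,
                       inosine_editing_rate = 1,
                       spikein_fraction = 0.05,
                       n_sites = c(m6A = 20L, inosine = 10L),
                       mod_site_density = NULL,
                       utr3_bias = 0.8,
                       inosine_region_weights = c(intron = 0.5, utr5 = 0.25,
                                                  utr3 = 0.15, cds_exon = 0.10),
                       min_site_distance = 300L,
                       stoichiometry_range = c(0.5, 1),
                       seq_error_rate = 0.001,
                       pcr_duplicate_rate = 0.1,
                       mbc_whitelist = c(m6A = "AAGGCCTT",
                                         inosine = "CCTTAAGG"),
                       expression_sdlog = 0.5) {
  cfg <- as.list(environment())
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$n_genes < 1) stop_config("n_genes must be >= 1")
  props <- c(cfg$utr_fractions, cfg$spikein_fraction, cfg$utr3_bias,
             cfg$seq_error_rate, cfg$pcr_duplicate_rate,
             cfg$inosine_editing_rate)
  if (any(props < 0 | props > 1)) {
    stop_config("all proportions must lie in [0, 1]")
  }
  if (abs(sum(cfg$utr_fractions) - 1) > 1e-8) {
    stop_config("utr_fractions must sum to 1 (got %.4f)",
                sum(cfg$utr_fractions))
  }
  if (!all(c("utr5", "cds", "utr3") %in% names(cfg$utr_fractions))) {
    stop_config("utr_fractions must be named utr5/cds/utr3")
  }
  if (cfg$capture_enrichment <= 0) stop_config("capture_enrichment must be > 0")
  if (cfg$frag_len_mean <= 0) stop_config("frag_len_mean must be > 0")
  if (is.null(names(cfg$mbc_whitelist)) || anyDuplicated(cfg$mbc_whitelist)) {
    stop_config("mbc_whitelist must be a named vector of distinct barcodes")
  }
  if (any(nchar(cfg$mbc_whitelist) != cfg$mbc_length)) {
    stop_config("every whitelist barcode must have length mbc_length")
  }
  if (cfg$read2_length < cfg$mbc_length + cfg$umi_length) {
    stop_config("read2_length must cover MBC + UMI")
  }
  invisible(cfg)
}

# Number of sites to plant per modification under a config, given the total
# genomic gene span in kb.
planned_site_counts <- function(cfg, span_kb) {
  if (!is.null(cfg$mod_site_density)) {
    counts <- round(cfg$mod_site_density * span_kb)
    storage.mode(counts) <- "integer"
    return(counts)
  }
  cfg$n_sites
}
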