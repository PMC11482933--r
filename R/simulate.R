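#' Simulate paired enrichment / solution-control libraries
#'
#' Emulates the proximity-barcoding library architecture: RNA (plus spike-in)
#' is fragmented to ~\code{frag_len_mean} bp; in the enrichment reaction
#' modified fragments are captured by the bead carrying their modification's
#' MBC with a \code{capture_enrichment}-fold probability advantage over
#' unmodified fragments (which are barcoded non-specifically at random),
#' while the solution control barcodes every fragment with a random MBC.
#' Reads over an edited adenosine report G with probability
#' stoichiometry x \code{inosine_editing_rate}; uniform substitution
#' sequencing errors and PCR duplicates are layered on top. Read 1 is the
#' insert in cDNA sense orientation; read 2 starts with the MBC, then the
#' UMI, then insert sequence from the opposite end.
#'
#' \code{n_reads_enrich} counts fragments offered to the beads; the realized
#' enrichment library is the captured subset. Randomness is consumed in a
#' fixed per-candidate layout, so altering the planted sites (e.g. removing
#' one modification entirely) leaves all other channels of the simulation
#' unchanged.
#'
#' @param model,genome transcriptome from \code{\link{build_transcriptome}}.
#' @param sites truth sites from \code{\link{plant_modifications}}.
#' @param spikein a \code{\link{spikein_reference}}.
#' @param config a \code{\link{sim_config}}.
#' @param outdir optional directory; when given, gzipped FASTQ pairs per
#'   role, the truth table and truth alignments are written there.
#' @return object of class \code{sim_library} with \code{$reads} (read
#'   sequences/qualities per role), \code{$fragments} (truth alignments with
#'   observed genome-forward sequence, MBC label, UMI, duplicate flag),
#'   \code{$truth} (the truth table), \code{$expression} and \code{$config}.
#' @export
simulate_library <- function(model, genome, sites, spikein, config,
                             outdir = NULL) {
  validate_sim_config(config)
  mods <- names(config$mbc_whitelist)
  expr_w <- with_seed(stage_seed(config$seed, 10L), {
    w <- stats::rlnorm(nrow(model$genes), 0, config$expression_sdlog)
    setNames(w / sum(w), model$genes$gene_id)
  })

  frag <- list()
  for (role in c("enrichment", "control")) {
    n <- if (role == "enrichment") config$n_reads_enrich else config$n_reads_control
    frag[[role]] <- with_seed(
      stage_seed(config$seed, if (role == "enrichment") 11L else 12L),
      draw_fragments(model, sites, spikein, config, expr_w, n, role))
  }
  frag <- data.table::rbindlist(frag)

  # sense-orientation fragment sequences
  frag$seq_sense <- fragment_sense_seq(frag, genome, spikein)

  # molecule-level inosine read-out (G at edited A, sense strand)
  frag$seq_sense <- with_seed(stage_seed(config$seed, 13L), {
    apply_inosine_edits(frag, sites, config)
  })

  # PCR duplicates: copies of the same molecule (same UMI, same edits)
  frag <- with_seed(stage_seed(config$seed, 14L), {
    n_dup <- rbinom(1L, nrow(frag), config$pcr_duplicate_rate)
    if (n_dup > 0) {
      dup <- frag[sample.int(nrow(frag), n_dup, replace = TRUE), ]
      dup$is_duplicate <- TRUE
      rbind(frag, dup)
    } else frag
  })
  data.table::setorder(frag, role, ref, start)
  frag$read_id <- sprintf("%s_%07d", substr(frag$role, 1, 3),
                          seq_len(nrow(frag)))

  # per-read-copy sequencing errors (insert and barcode prefix separately)
  frag$mbc_seq <- unname(config$mbc_whitelist[frag$mbc])
  with_seed(stage_seed(config$seed, 15L), {
    frag$seq_sense <- apply_substitution_errors(frag$seq_sense,
                                                config$seq_error_rate)
    frag$prefix <- apply_substitution_errors(
      paste0(frag$mbc_seq, frag$umi), config$seq_error_rate)
  })

  insert2_len <- config$read2_length - config$mbc_length - config$umi_length
  rc <- revcomp(frag$seq_sense)
  reads <- data.frame(
    role = frag$role, read_id = frag$read_id,
    read1 = substr(frag$seq_sense, 1L, config$read1_length),
    read2 = paste0(frag$prefix, substr(rc, 1L, insert2_len)),
    stringsAsFactors = FALSE)
  reads$qual1 <- strrep("I", nchar(reads$read1))
  reads$qual2 <- strrep("I", nchar(reads$read2))

  fragments <- data.frame(
    role = frag$role, read_id = frag$read_id, ref = frag$ref,
    start = frag$start, end = frag$end, strand = frag$strand,
    mbc = frag$mbc, umi = frag$umi, mean_qual = rep(40, nrow(frag)),
    modified = frag$modified, mods = frag$mods, gene_id = frag$gene_id,
    is_duplicate = frag$is_duplicate,
    seq = ifelse(frag$strand == "-", rc, frag$seq_sense),
    stringsAsFactors = FALSE)

  sim <- structure(list(reads = reads,
                        fragments = fragments,
                        truth = fragments[, setdiff(names(fragments), "seq")],
                        expression = expr_w, config = config),
                   class = "sim_library")
  if (!is.null(outdir)) write_sim_library(sim, outdir)
  sim
}

# Draw candidate fragments and run the capture reaction for one role.
# RNG layout per candidate is fixed (source, gene, length, placement, two
# fire uniforms, acceptance uniform, MBC uniform, UMI) regardless of the
# planted sites.
draw_fragments <- function(model, sites, spikein, cfg, expr_w, n, role) {
  mods <- names(cfg$mbc_whitelist)
  if (n == 0) {
    return(data.table::data.table(role = character(0), ref = character(0),
      start = integer(0), end = integer(0), strand = character(0),
      mbc = character(0), umi = character(0), modified = logical(0),
      mods = character(0), gene_id = character(0), is_duplicate = logical(0)))
  }
  is_spike <- runif(n) < cfg$spikein_fraction
  gene_idx <- sample.int(nrow(model$genes), n, replace = TRUE, prob = expr_w)
  len <- pmax(1L, as.integer(round(rnorm(n, cfg$frag_len_mean,
                                         cfg$frag_len_sd))))
  u_pos <- runif(n)
  u_fire <- matrix(runif(n * length(mods)), nrow = n)
  u_accept <- runif(n)
  u_mbc <- runif(n)
  umi <- random_kmers(n, cfg$umi_length)

  g <- model$genes[gene_idx, ]
  spike_len <- Biostrings::width(spikein$sequences)[1]
  span <- ifelse(is_spike, spike_len, g$end - g$start)
  len <- pmin(len, span)
  start <- ifelse(is_spike, 0L, g$start) + as.integer(floor(u_pos * (span - len + 1)))
  end <- start + len
  ref <- ifelse(is_spike, names(spikein$sequences)[1], g$chrom)
  strand <- ifelse(is_spike, "+", g$strand)
  gene_id <- ifelse(is_spike, NA_character_, g$gene_id)

  # per-fragment, per-mod firing probability
  p <- matrix(0, nrow = n, ncol = length(mods),
              dimnames = list(NULL, mods))
  if (!is.null(sites) && nrow(sites) > 0) {
    gi <- which(!is_spike)
    if (length(gi) > 0) {
      ov <- IRanges::findOverlaps(
        iranges0(start[gi], end[gi]),
        IRanges::IRanges(sites$pos + 1L, sites$pos + 1L))
      if (length(ov) > 0) {
        dt <- data.table::data.table(
          fi = gi[S4Vectors::queryHits(ov)],
          mod = sites$mod[S4Vectors::subjectHits(ov)],
          stoich = sites$stoichiometry[S4Vectors::subjectHits(ov)])
        agg <- dt[, list(p = 1 - prod(1 - stoich)), by = c("fi", "mod")]
        p[cbind(agg$fi, match(agg$mod, mods))] <- agg$p
      }
    }
  }
  si <- which(is_spike)
  if (length(si) > 0) {
    segs <- spikein$segments[spikein$segments$role == "mod_specific", ]
    for (k in seq_len(nrow(segs))) {
      hit <- si[start[si] < segs$end[k] & end[si] > segs$start[k]]
      p[hit, segs$mod[k]] <- 1
    }
    if (!is.null(spikein$std_sites)) {
      for (k in seq_len(nrow(spikein$std_sites))) {
        m <- spikein$std_sites$mod[k]; pos <- spikein$std_sites$pos[k]
        hit <- si[start[si] <= pos & end[si] > pos]
        p[hit, m] <- pmax(p[hit, m], spikein$std_stoichiometry[[m]])
      }
    }
  }
  fired <- u_fire < p
  fired_any <- rowSums(fired) > 0

  if (role == "enrichment") {
    # bead-capture model: each bead type captures a fragment with affinity
    # proportional to capture_enrichment when the fragment carries that
    # bead's modification, 1 otherwise; the fragment is captured (and gets
    # the capturing bead's MBC) with probability sum(affinity)/(n_beads * k).
    # At capture_enrichment = 1 every fragment is captured and barcoded at
    # random, making the enrichment reaction exchangeable with the control.
    k <- cfg$capture_enrichment
    aff <- matrix(1, nrow = n, ncol = length(mods))
    aff[fired] <- k
    W <- rowSums(aff)
    accept <- u_accept < pmin(W / (length(mods) * k), 1)
    pickv <- u_mbc * W
    cum <- t(apply(aff, 1L, cumsum))
    idx <- rowSums(pickv >= cum) + 1L
    mbc <- mods[pmin(idx, length(mods))]
  } else {
    accept <- rep(TRUE, n)
    mbc <- mods[pmin(floor(u_mbc * length(mods)) + 1L, length(mods))]
  }

  out <- data.table::data.table(
    role = role, ref = ref, start = start, end = end, strand = strand,
    mbc = mbc, umi = umi, modified = fired_any,
    mods = apply(fired, 1L, function(z) paste(mods[z], collapse = ",")),
    gene_id = gene_id, is_duplicate = FALSE)
  out[accept, ]
}

random_kmers <- function(n, k) {
  m <- matrix(sample(c("A", "C", "G", "T"), n * k, replace = TRUE), nrow = n)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

fragment_sense_seq <- function(frag, genome, spikein) {
  refs <- c(as.list(as.character(genome)),
            as.list(as.character(spikein$sequences)))
  out <- character(nrow(frag))
  for (r in unique(frag$ref)) {
    i <- which(frag$ref == r)
    out[i] <- substring(refs[[r]], frag$start[i] + 1L, frag$end[i])
  }
  neg <- which(frag$strand == "-")
  if (length(neg) > 0) out[neg] <- revcomp(out[neg])
  out
}

apply_inosine_edits <- function(frag, sites, cfg) {
  seqs <- frag$seq_sense
  if (is.null(sites) || !any(sites$mod == "inosine") ||
      cfg$inosine_editing_rate <= 0) {
    return(seqs)
  }
  ino <- sites[sites$mod == "inosine", ]
  gi <- which(!is.na(frag$gene_id))
  if (length(gi) == 0) return(seqs)
  ov <- IRanges::findOverlaps(
    iranges0(frag$start[gi], frag$end[gi]),
    IRanges::IRanges(ino$pos + 1L, ino$pos + 1L))
  if (length(ov) == 0) return(seqs)
  fi <- gi[S4Vectors::queryHits(ov)]
  sj <- S4Vectors::subjectHits(ov)
  u <- runif(length(fi))
  edit <- u < ino$stoichiometry[sj] * cfg$inosine_editing_rate
  off <- ifelse(frag$strand[fi] == "+",
                ino$pos[sj] - frag$start[fi],
                frag$end[fi] - 1L - ino$pos[sj])
  for (k in which(edit)) {
    substr(seqs[fi[k]], off[k] + 1L, off[k] + 1L) <- "G"
  }
  seqs
}

#' Write a simulated library to disk
#'
#' Writes gzipped 4-line FASTQ pairs (Phred+33) per sample role plus the
#' truth table and truth alignments as TSV.
#'
#' @param sim a \code{sim_library}.
#' @param outdir output directory (created if missing).
#' @return invisibly, a named vector of written paths.
#' @export
write_sim_library <- function(sim, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- c()
  for (role in unique(c("enrichment", "control", sim$reads$role))) {
    rr <- sim$reads[sim$reads$role == role, ]
    for (mate in 1:2) {
      p <- file.path(outdir, sprintf("%s_R%d.fastq.gz", role, mate))
      sq <- Biostrings::DNAStringSet(rr[[paste0("read", mate)]])
      names(sq) <- rr$read_id
      Biostrings::writeXStringSet(
        sq, p, format = "fastq", compress = TRUE,
        qualities = Biostrings::BStringSet(rr[[paste0("qual", mate)]]))
      paths[sprintf("%s_R%d", role, mate)] <- p
    }
  }
  tt <- file.path(outdir, "truth.tsv")
  write.table(sim$truth, tt, sep = "\t", quote = FALSE, row.names = FALSE)
  paths["truth"] <- tt
  al <- file.path(outdir, "truth_alignments.tsv")
  write.table(sim$fragments, al, sep = "\t", quote = FALSE, row.names = FALSE)
  paths["alignments"] <- al
  invisible(paths)
}
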