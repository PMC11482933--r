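#' Build a synthetic transcriptome
#'
#' Generates a random genome with \code{n_genes} genes laid out on a single
#' chromosome, each with a 5'UTR, one or more CDS exons separated by introns,
#' and a 3'UTR. The mature (exonic) length is drawn from
#' \code{gene_length_range} and split between the regions according to
#' \code{utr_fractions}; introns extend the genomic span beyond the mature
#' length. Coordinates are 0-based half-open throughout the returned model.
#'
#' @param config a \code{\link{sim_config}}.
#' @param fasta,gtf optional output paths; when given, the genome FASTA and
#'   an Ensembl-dialect GTF are written.
#' @return list with \code{model} (a \code{transcript_model}: \code{$genes},
#'   \code{$features}, \code{$chrom_lengths}) and \code{genome}
#'   (a \code{DNAStringSet}).
#' @export
build_transcriptome <- function(config, fasta = NULL, gtf = NULL) {
  validate_sim_config(config)
  res <- with_seed(stage_seed(config$seed, 1L), {
    build_transcriptome_impl(config)
  })
  if (!is.null(fasta) || !is.null(gtf)) {
    write_transcriptome(res$model, res$genome, fasta = fasta, gtf = gtf)
  }
  res
}

build_transcriptome_impl <- function(cfg) {
  chrom <- "chrT"
  cursor <- 0L
  gene_rows <- list()
  feat_rows <- list()
  min_exon <- 50L

  for (g in seq_len(cfg$n_genes)) {
    gap <- as.integer(round(runif(1, cfg$intergenic_gap_range[1],
                                  cfg$intergenic_gap_range[2])))
    gene_start <- cursor + gap
    L <- as.integer(round(runif(1, cfg$gene_length_range[1],
                                cfg$gene_length_range[2])))
    utr5_len <- as.integer(round(cfg$utr_fractions[["utr5"]] * L))
    utr3_len <- as.integer(round(cfg$utr_fractions[["utr3"]] * L))
    cds_len <- L - utr5_len - utr3_len
    n_intr <- if (cfg$n_introns_range[2] < 1) 0L else
      sample(seq(cfg$n_introns_range[1], cfg$n_introns_range[2]), 1L)
    # CDS breakpoints with a minimum exon chunk size
    if (n_intr > 0 && cds_len > (n_intr + 1L) * min_exon) {
      repeat {
        bp <- sort(sample(seq(min_exon, cds_len - min_exon), n_intr))
        if (all(diff(c(0L, bp, cds_len)) >= min_exon)) break
      }
    } else {
      n_intr <- 0L
      bp <- integer(0)
    }
    cds_chunks <- diff(c(0L, bp, cds_len))
    intron_lens <- if (n_intr > 0) {
      as.integer(round(runif(n_intr, cfg$intron_length_range[1],
                             cfg$intron_length_range[2])))
    } else integer(0)

    # segments in transcript 5'->3' order
    seg_type <- c("utr5",
                  as.vector(rbind(rep("cds_exon", n_intr), rep("intron", n_intr))),
                  "cds_exon", "utr3")
    seg_len <- c(utr5_len,
                 as.vector(rbind(cds_chunks[seq_len(n_intr)], intron_lens)),
                 cds_chunks[n_intr + 1L], utr3_len)
    keep <- seg_len > 0L
    seg_type <- seg_type[keep]; seg_len <- seg_len[keep]

    strand <- sample(c("+", "-"), 1L)
    # genomic order: for "-" the transcript runs right-to-left
    geno_len <- if (strand == "+") seg_len else rev(seg_len)
    geno_type <- if (strand == "+") seg_type else rev(seg_type)
    ends <- gene_start + cumsum(geno_len)
    starts <- c(gene_start, head(ends, -1L))
    tx_rank <- if (strand == "+") seq_along(seg_type) else rev(seq_along(seg_type))

    gid <- sprintf("gene%03d", g)
    feat_rows[[g]] <- data.frame(
      gene_id = gid, transcript_id = paste0(gid, ".t1"),
      type = geno_type, chrom = chrom,
      start = starts, end = ends, strand = strand,
      tx_rank = tx_rank, stringsAsFactors = FALSE)
    gene_rows[[g]] <- data.frame(
      gene_id = gid, transcript_id = paste0(gid, ".t1"), chrom = chrom,
      start = gene_start, end = gene_start + sum(seg_len),
      strand = strand, exonic_len = L, stringsAsFactors = FALSE)
    cursor <- gene_start + sum(seg_len)
  }

  genes <- do.call(rbind, gene_rows)
  features <- do.call(rbind, feat_rows)
  tail_gap <- as.integer(round(runif(1, cfg$intergenic_gap_range[1],
                                     cfg$intergenic_gap_range[2])))
  chrom_len <- cursor + tail_gap
  # guarantee a non-empty record even with zero gaps
  chrom_len <- max(chrom_len, cursor)
  seq <- random_dna(chrom_len)
  genome <- Biostrings::DNAStringSet(setNames(seq, chrom))

  model <- structure(list(genes = genes, features = features,
                          chrom_lengths = setNames(chrom_len, chrom)),
                     class = "transcript_model")
  list(model = model, genome = genome)
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("transcript_model: %d gene(s) on %d sequence(s), %d features\n",
              nrow(x$genes), length(x$chrom_lengths), nrow(x$features)))
  invisible(x)
}

#' Write a transcriptome to FASTA/GTF
#'
#' @param model a \code{transcript_model}.
#' @param genome \code{DNAStringSet} of the chromosome sequences.
#' @param fasta,gtf output paths (either may be NULL).
#' @return invisibly, the paths written.
#' @export
write_transcriptome <- function(model, genome, fasta = NULL, gtf = NULL) {
  if (!is.null(fasta)) Biostrings::writeXStringSet(genome, fasta)
  if (!is.null(gtf)) {
    gr <- model_to_gtf_granges(model)
    rtracklayer::export(gr, gtf, format = "gtf")
  }
  invisible(c(fasta = fasta, gtf = gtf))
}

gtf_type_map <- c(utr5 = "five_prime_utr", cds_exon = "CDS",
                  utr3 = "three_prime_utr")

model_to_gtf_granges <- function(model) {
  f <- model$features
  rows <- list()
  for (tid in unique(f$transcript_id)) {
    ft <- f[f$transcript_id == tid, ]
    gid <- ft$gene_id[1]
    # exons: maximal exonic blocks (UTRs fused with adjacent CDS chunks)
    ex <- ft[ft$type != "intron", ]
    exr <- IRanges::reduce(iranges0(ex$start, ex$end))
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = ft$chrom[1],
      start = c(min(ft$start), min(ft$start),
                IRanges::start(exr) - 1L, ft$start[ft$type != "intron"]),
      end = c(max(ft$end), max(ft$end), IRanges::end(exr),
              ft$end[ft$type != "intron"]),
      type = c("gene", "transcript", rep("exon", length(exr)),
               gtf_type_map[ft$type[ft$type != "intron"]]),
      strand = ft$strand[1], gene_id = gid, transcript_id = tid,
      stringsAsFactors = FALSE)
  }
  d <- do.call(rbind, rows)
  gr <- granges0(d$chrom, d$start, d$end, d$strand)
  S4Vectors::mcols(gr)$type <- d$type
  S4Vectors::mcols(gr)$gene_id <- d$gene_id
  S4Vectors::mcols(gr)$transcript_id <- d$transcript_id
  S4Vectors::mcols(gr)$source <- "epimodkit"
  S4Vectors::mcols(gr)$phase <- cds_phases(d)
  gr
}

# reading frame of each CDS chunk in transcript order; NA for other rows
cds_phases <- function(d) {
  phase <- rep(NA_integer_, nrow(d))
  for (tid in unique(d$transcript_id)) {
    i <- which(d$transcript_id == tid & d$type == "CDS")
    if (length(i) == 0) next
    minus <- d$strand[i[1]] == "-"
    ord <- i[order(d$start[i], decreasing = minus)]
    cum <- 0L
    for (j in ord) {
      phase[j] <- (3L - cum %% 3L) %% 3L
      cum <- cum + (d$end[j] - d$start[j])
    }
  }
  phase
}

#' Load a transcript model from a GTF file
#'
#' Reads an Ensembl-dialect GTF (attributes \code{gene_id} /
#' \code{transcript_id}) and reconstructs the region structure used by
#' annotation and metagene profiling: 5'UTR, CDS exons, introns and 3'UTR per
#' transcript. UTRs are inferred as the exonic sequence outside the CDS span
#' when not given explicitly; introns are the gaps between exons.
#'
#' @param path GTF file path.
#' @param chrom_lengths optional named integer vector; when NULL, the
#'   per-chromosome maximum feature end is used.
#' @return a \code{transcript_model}.
#' @export
model_from_gtf <- function(path, chrom_lengths = NULL) {
  gr <- rtracklayer::import(path, format = "gtf")
  md <- as.data.frame(gr)
  md$chrom <- as.character(md$seqnames)
  md$start0 <- md$start - 1L
  md$strand <- as.character(md$strand)
  feat_rows <- list(); gene_rows <- list()
  for (tid in unique(md$transcript_id[md$type == "exon"])) {
    mt <- md[!is.na(md$transcript_id) & md$transcript_id == tid, ]
    ex <- mt[mt$type == "exon", ]
    cds <- mt[mt$type == "CDS", ]
    strand <- ex$strand[1]; chrom <- ex$chrom[1]; gid <- ex$gene_id[1]
    exr <- IRanges::reduce(IRanges::IRanges(ex$start, ex$end))
    segs <- data.frame(start = IRanges::start(exr) - 1L,
                       end = IRanges::end(exr), type = "exon")
    if (nrow(cds) > 0) {
      cds_lo <- min(cds$start) - 1L; cds_hi <- max(cds$end)
      pieces <- list()
      for (i in seq_len(nrow(segs))) {
        s <- segs$start[i]; e <- segs$end[i]
        cuts <- sort(unique(pmax(pmin(c(cds_lo, cds_hi), e), s)))
        bounds <- unique(c(s, cuts, e))
        for (j in seq_len(length(bounds) - 1L)) {
          a <- bounds[j]; b <- bounds[j + 1L]
          if (b <= a) next
          lab <- if (b <= cds_lo) "left" else if (a >= cds_hi) "right" else "cds_exon"
          pieces[[length(pieces) + 1L]] <- data.frame(start = a, end = b, type = lab)
        }
      }
      segs <- do.call(rbind, pieces)
      up <- if (strand == "+") "utr5" else "utr3"
      dn <- if (strand == "+") "utr3" else "utr5"
      segs$type[segs$type == "left"] <- up
      segs$type[segs$type == "right"] <- dn
    } else {
      segs$type <- "ncrna_exon"  # no CDS: non-coding transcript
    }
    # introns = gaps between reduced exons
    if (length(exr) > 1) {
      gaps <- IRanges::gaps(exr)
      segs <- rbind(segs, data.frame(start = IRanges::start(gaps) - 1L,
                                     end = IRanges::end(gaps),
                                     type = "intron"))
    }
    segs <- segs[order(segs$start), ]
    segs$tx_rank <- if (strand == "+") seq_len(nrow(segs)) else rev(seq_len(nrow(segs)))
    feat_rows[[tid]] <- data.frame(gene_id = gid, transcript_id = tid,
                                   type = segs$type, chrom = chrom,
                                   start = segs$start, end = segs$end,
                                   strand = strand, tx_rank = segs$tx_rank,
                                   stringsAsFactors = FALSE)
    gene_rows[[tid]] <- data.frame(gene_id = gid, transcript_id = tid,
                                   chrom = chrom, start = min(segs$start),
                                   end = max(segs$end), strand = strand,
                                   exonic_len = sum(segs$end - segs$start) -
                                     sum(segs$end[segs$type == "intron"] -
                                           segs$start[segs$type == "intron"]),
                                   stringsAsFactors = FALSE)
  }
  genes <- do.call(rbind, gene_rows)
  features <- do.call(rbind, feat_rows)
  rownames(genes) <- rownames(features) <- NULL
  if (is.null(chrom_lengths)) {
    chrom_lengths <- tapply(features$end, features$chrom, max)
    chrom_lengths <- setNames(as.integer(chrom_lengths), names(chrom_lengths))
  }
  structure(list(genes = genes, features = features,
                 chrom_lengths = chrom_lengths),
            class = "transcript_model")
}

# Sense-strand (transcript orientation) sequence of a gene.
gene_sense_seq <- function(model, genome, gene_id) {
  g <- model$genes[model$genes$gene_id == gene_id, ]
  s <- substr(as.character(genome[[g$chrom]]), g$start + 1L, g$end)
  if (g$strand == "-") revcomp(s) else s
}
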