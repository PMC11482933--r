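test_that("pileup counts bases, caps depth and applies the quality floor", {
  ref <- Biostrings::DNAStringSet(c(chr1 = strrep("A", 50)))
  reads <- data.frame(ref = "chr1", start = 10L, end = 20L, strand = "+",
                      seq = strrep("G", 10), stringsAsFactors = FALSE)
  reads <- reads[rep(1, 10), ]
  regions <- data.frame(chrom = "chr1", start = 10L, end = 20L)
  cols <- pileup_fragments(reads, ref, regions)
  expect_equal(cols$G, rep(10L, 10))
  expect_equal(cols$A, rep(0L, 10))
  expect_equal(cols$depth, rep(10L, 10))
  expect_equal(cols$ref_base, rep("A", 10))
  # depth cap
  capped <- pileup_fragments(reads, ref, regions, max_depth = 5L)
  expect_true(all(capped$depth <= 5L))
  expect_equal(capped$G, rep(5L, 10))
  # quality floor: bases below Q13 are ignored
  reads$qual <- strrep("+", 10)  # Q10
  lowq <- pileup_fragments(reads, ref, regions, min_base_qual = 13L)
  expect_equal(lowq$depth, rep(0L, 10))
})

test_that("pileup equals a brute-force per-read walk on random fragments", {
  set.seed(19)
  refseq <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE),
                  collapse = "")
  ref <- Biostrings::DNAStringSet(setNames(refseq, "chr1"))
  n <- 100L
  start <- sample.int(300L, n, replace = TRUE) - 1L
  len <- sample(20:80, n, replace = TRUE)
  seqs <- substring(refseq, start + 1L, start + len)
  # sprinkle mismatches
  for (i in sample.int(n, 40)) {
    p <- sample.int(nchar(seqs[i]), 1)
    substr(seqs[i], p, p) <- sample(c("A", "C", "G", "T"), 1)
  }
  frags <- data.frame(ref = "chr1", start = start, end = start + len,
                      strand = "+", seq = seqs, stringsAsFactors = FALSE)
  regions <- data.frame(chrom = "chr1", start = 50L, end = 250L)
  cols <- pileup_fragments(frags, ref, regions)
  oracle <- bf_pileup_counts(frags, 50L, 250L)
  for (b in c("A", "C", "G", "T")) {
    expect_equal(cols[[b]], unname(oracle[, b]), info = b)
  }
  expect_equal(cols$depth, unname(rowSums(oracle)))
})

test_that("CIGAR walking handles indels, clips and malformed strings", {
  ref <- Biostrings::DNAStringSet(c(chr1 = strrep("A", 40)))
  regions <- data.frame(chrom = "chr1", start = 0L, end = 40L)
  # 5M2D5M: a deletion consumes reference without bases
  fr <- data.frame(ref = "chr1", start = 0L, end = 12L, strand = "+",
                   seq = strrep("G", 10), cigar = "5M2D5M",
                   stringsAsFactors = FALSE)
  cols <- pileup_fragments(fr, ref, regions)
  expect_equal(cols$G[1:12], c(rep(1L, 5), 0L, 0L, rep(1L, 5)))
  expect_equal(cols$del[6:7], c(1L, 1L))
  expect_equal(cols$depth[6:7], c(1L, 1L))
  # soft clip consumes query only
  fr2 <- data.frame(ref = "chr1", start = 0L, end = 5L, strand = "+",
                    seq = paste0("TTT", strrep("G", 5)), cigar = "3S5M",
                    stringsAsFactors = FALSE)
  cols2 <- pileup_fragments(fr2, ref, regions)
  expect_equal(cols2$G[1:5], rep(1L, 5))
  expect_equal(sum(cols2$T), 0L)
  # malformed CIGAR: skipped and counted
  bad <- data.frame(ref = "chr1", start = 0L, end = 5L, strand = "+",
                    seq = "GGGGG", cigar = "5Q", stringsAsFactors = FALSE)
  cols3 <- pileup_fragments(bad, ref, regions)
  expect_equal(attr(cols3, "skipped"), 1L)
  expect_equal(sum(cols3$depth), 0L)
})

test_that("A-to-G calling applies the printed rate and depth thresholds", {
  mk_cols <- function(depth, alt, ref_base = "A", pos = 100L) {
    data.frame(chrom = "chr1", pos = pos, ref_base = ref_base,
               A = ifelse(ref_base == "A", depth - alt, 0L),
               C = ifelse(ref_base == "T", alt, 0L),
               G = ifelse(ref_base == "A", alt, 0L),
               T = ifelse(ref_base == "T", depth - alt, 0L),
               N = 0L, del = 0L, depth = depth, depth_rev = 0L,
               region_id = "p1", stringsAsFactors = FALSE)
  }
  peaks <- data.frame(ref = "chr1", start = 50L, end = 150L, strand = "+",
                      peak_id = "p1", stringsAsFactors = FALSE)
  # rate 0.09 at depth 100: silent; rate 0.10: reported
  expect_equal(nrow(call_ag_sites(mk_cols(100L, 9L), peaks)), 0L)
  r10 <- call_ag_sites(mk_cols(100L, 10L), peaks)
  expect_equal(nrow(r10), 1L)
  expect_equal(r10$rate, 0.10)
  expect_equal(r10$pos1, 101L)
  # depth must strictly exceed 5: rate 0.5 at depth 5 silent, depth 6 reported
  expect_equal(nrow(call_ag_sites(mk_cols(5L, 3L), peaks)), 0L)
  expect_equal(nrow(call_ag_sites(mk_cols(6L, 3L), peaks)), 1L)
  # minus-strand transcripts: genomic T>C read as A-to-G
  peaks_m <- peaks; peaks_m$strand <- "-"
  rm_ <- call_ag_sites(mk_cols(100L, 30L, ref_base = "T"), peaks_m)
  expect_equal(nrow(rm_), 1L)
  expect_equal(rm_$ref, "T"); expect_equal(rm_$alt, "C")
  # sites outside every peak are never reported
  far <- mk_cols(100L, 50L, pos = 500L)
  expect_equal(nrow(call_ag_sites(far, peaks)), 0L)
})

test_that("per-peak support summarises best sites and the global fraction", {
  peaks <- data.frame(ref = "chr1", start = c(0L, 100L), end = c(50L, 150L),
                      strand = "+", peak_id = c("p1", "p2"),
                      stringsAsFactors = FALSE)
  sites <- data.frame(chrom = "chr1", pos = c(10L, 20L), pos1 = c(11L, 21L),
                      ref = "A", alt = "G", depth = c(50L, 40L),
                      alt_count = c(10L, 20L), rate = c(0.2, 0.5),
                      strand = "+", peak_id = "p1", stringsAsFactors = FALSE)
  sup <- peak_variant_support(peaks, sites)
  expect_equal(sup$support_fraction, 0.5)
  expect_equal(sup$peaks$n_sites, c(2L, 0L))
  expect_equal(sup$peaks$best_rate[1], 0.5)
  # every peak supported / none supported
  sup1 <- peak_variant_support(peaks[1, ], sites)
  expect_equal(sup1$support_fraction, 1)
  sup0 <- peak_variant_support(peaks, sites[0, ])
  expect_equal(sup0$support_fraction, 0)
})

test_that("reported sites are strand-stable in genomic coordinates", {
  # same molecules read from a + gene and from its - mirror must yield the
  # same genomic site. Build reads over an edited A (pos 25, + sense).
  refseq <- paste0(strrep("C", 25), "A", strrep("C", 24))
  ref_p <- Biostrings::DNAStringSet(setNames(refseq, "chr1"))
  reads_p <- data.frame(ref = "chr1", start = 5L, end = 45L, strand = "+",
                        seq = paste0(strrep("C", 20), "G", strrep("C", 19)),
                        stringsAsFactors = FALSE)[rep(1, 20), ]
  # mirrored: the genome carries T at the site; edited reads carry C there
  refseq_m <- chartr("ACGT", "TGCA", refseq)
  ref_m <- Biostrings::DNAStringSet(setNames(refseq_m, "chr1"))
  reads_m <- data.frame(ref = "chr1", start = 5L, end = 45L, strand = "-",
                        seq = chartr("ACGT", "TGCA",
                                     paste0(strrep("C", 20), "G", strrep("C", 19))),
                        stringsAsFactors = FALSE)[rep(1, 20), ]
  regions <- data.frame(chrom = "chr1", start = 0L, end = 50L,
                        peak_id = "p1")
  pk_p <- data.frame(ref = "chr1", start = 0L, end = 50L, strand = "+",
                     peak_id = "p1", stringsAsFactors = FALSE)
  pk_m <- pk_p; pk_m$strand <- "-"
  s_p <- call_ag_sites(pileup_fragments(reads_p, ref_p, regions), pk_p)
  s_m <- call_ag_sites(pileup_fragments(reads_m, ref_m, regions), pk_m)
  expect_equal(s_p$pos, 25L)
  expect_equal(s_m$pos, 25L)
  expect_equal(s_p$rate, s_m$rate)
})

test_that("sequencing error alone produces no A-to-G sites at the 10% threshold", {
  # planted inosine sites removed; only the 0.1% substitution error remains
  cfg <- sim_config(seed = 4, n_sites = c(m6A = 10L, inosine = 0L),
                    n_reads_enrich = 15000L, n_reads_control = 0L)
  tr <- build_transcriptome(cfg)
  st <- suppressWarnings(plant_modifications(tr$model, tr$genome, cfg))
  sim <- simulate_library(tr$model, tr$genome, st, spikein_reference(cfg), cfg)
  fr <- sim$fragments[sim$fragments$ref != "LMS", ]
  g <- tr$model$genes[1, ]
  regions <- data.frame(chrom = g$chrom, start = g$start,
                        end = min(g$start + 2000L, g$end), peak_id = "p1")
  pk <- data.frame(ref = g$chrom, start = regions$start, end = regions$end,
                   strand = g$strand, peak_id = "p1",
                   stringsAsFactors = FALSE)
  cols <- pileup_fragments(fr, tr$genome, regions)
  sites <- call_ag_sites(cols, pk)
  expect_equal(nrow(sites), 0L)
})

test_that("VCF output is 1-based and carries rate/depth/peak INFO", {
  sites <- data.frame(chrom = "chr1", pos = 24L, pos1 = 25L, ref = "A",
                      alt = "G", depth = 30L, alt_count = 9L, rate = 0.3,
                      strand = "+", peak_id = "ino1", stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf_sites(sites, path)
  lines <- readLines(path)
  expect_true(any(grepl("^##fileformat=VCFv4.2", lines)))
  rec <- lines[!grepl("^#", lines)]
  expect_length(rec, 1L)
  f <- strsplit(rec, "\t")[[1]]
  expect_equal(f[2], "25")
  expect_match(f[8], "DP=30;AC=9;VR=0.3000;PEAK=ino1")
})
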