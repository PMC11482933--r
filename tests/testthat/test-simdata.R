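test_that("transcriptome builder writes consistent, deterministic FASTA/GTF", {
  cfg <- sim_config(seed = 7, n_genes = 1L,
                    n_introns_range = c(0L, 0L),
                    intergenic_gap_range = c(0L, 0L))
  d1 <- withr::local_tempdir()
  tr1 <- build_transcriptome(cfg, fasta = file.path(d1, "g.fa"),
                             gtf = file.path(d1, "g.gtf"))
  # single gene, no introns, no gaps: the exon spans the whole record
  md <- tr1$model
  expect_equal(nrow(md$genes), 1L)
  expect_equal(md$genes$start, 0L)
  expect_equal(md$genes$end, unname(md$chrom_lengths))
  ex <- md$features[md$features$type != "intron", ]
  expect_equal(sum(ex$end - ex$start), unname(md$chrom_lengths))
  expect_equal(Biostrings::width(tr1$genome)[1], unname(md$chrom_lengths))

  # identical seed: byte-identical outputs
  d2 <- withr::local_tempdir()
  build_transcriptome(cfg, fasta = file.path(d2, "g.fa"),
                      gtf = file.path(d2, "g.gtf"))
  expect_identical(readLines(file.path(d1, "g.fa")),
                   readLines(file.path(d2, "g.fa")))
  expect_identical(readLines(file.path(d1, "g.gtf")),
                   readLines(file.path(d2, "g.gtf")))
})

test_that("UTR/CDS lengths follow the configured fractions", {
  cfg <- sim_config(seed = 3, n_genes = 4L,
                    gene_length_range = c(1000L, 1000L),
                    utr_fractions = c(utr5 = 0.1, cds = 0.6, utr3 = 0.3),
                    n_introns_range = c(0L, 2L))
  md <- build_transcriptome(cfg)$model
  for (g in md$genes$gene_id) {
    f <- md$features[md$features$gene_id == g, ]
    w <- function(tp) sum(f$end[f$type == tp] - f$start[f$type == tp])
    expect_equal(w("utr5"), 100L)
    expect_equal(w("cds_exon"), 600L)
    expect_equal(w("utr3"), 300L)
  }
})

test_that("GTF round-trips into an equivalent transcript model", {
  w <- toy_world()
  path <- withr::local_tempfile(fileext = ".gtf")
  suppressWarnings(write_transcriptome(w$model, w$genome, gtf = path))
  back <- model_from_gtf(path)
  a <- w$model$features[order(w$model$features$gene_id,
                              w$model$features$start), ]
  b <- back$features[order(back$features$gene_id, back$features$start), ]
  expect_equal(a$start, b$start)
  expect_equal(a$end, b$end)
  expect_equal(a$type, b$type)
  expect_equal(a$strand, b$strand)
})

test_that("planted m6A sites all sit on DRACH motifs, biased to the 3'UTR", {
  w <- toy_world()
  m6a <- w$sites[w$sites$mod == "m6A", ]
  expect_equal(nrow(m6a), 20L)
  # independent regex oracle on the stored 5-mer context
  expect_true(all(grepl("^[AGT][AG]AC[ACT]$", m6a$context)))
  # and on the genome itself: the modified A at motif position 3
  chrom <- as.character(w$genome[[1]])
  for (i in seq_len(nrow(m6a))) {
    # 1-based window pos-1..pos+3 covers 0-based pos-2..pos+2, A centered
    win <- substr(chrom, m6a$pos[i] - 1L, m6a$pos[i] + 3L)
    kmer <- if (m6a$strand[i] == "+") win else
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(win)))
    expect_match(kmer, "^[AGT][AG]AC[ACT]$")
  }

  # full 3'UTR bias forces every site into an annotated 3'UTR
  cfg_b <- sim_config(seed = 5, utr3_bias = 1,
                      n_sites = c(m6A = 10L, inosine = 0L))
  wb <- build_transcriptome(cfg_b)
  sb <- suppressWarnings(plant_modifications(wb$model, wb$genome, cfg_b))
  expect_true(all(sb$region == "utr3"))
})

test_that("a transcriptome without DRACH motifs yields zero m6A sites with a warning", {
  model <- tiny_model()
  # all-C chromosome: no DRACH anywhere, and no A for inosine either
  genome <- Biostrings::DNAStringSet(c(chr1 = strrep("C", 3500)))
  cfg <- sim_config(seed = 1, n_sites = c(m6A = 5L, inosine = 0L))
  expect_warning(sites <- plant_modifications(model, genome, cfg),
                 "no legal position|no DRACH")
  expect_equal(nrow(sites), 0L)
})

test_that("fragment lengths follow the configured ~140 bp distribution", {
  s <- toy_sim()
  fr <- s$sim$fragments
  fr <- fr[fr$role == "control" & !fr$is_duplicate, ]
  lens <- (fr$end - fr$start)[seq_len(10000L)]
  sem <- sd(lens) / sqrt(length(lens))
  expect_lt(abs(mean(lens) - s$cfg$frag_len_mean), 2 * sem + 0.5)
})

test_that("simulator output is deterministic and conserves reads in the truth table", {
  w <- toy_world()
  sim1 <- simulate_library(w$model, w$genome, w$sites, w$spikein, w$cfg)
  sim2 <- simulate_library(w$model, w$genome, w$sites, w$spikein, w$cfg)
  expect_identical(sim1$reads, sim2$reads)
  expect_identical(sim1$fragments, sim2$fragments)
  # conservation: every read appears exactly once in the truth table
  expect_setequal(sim1$reads$read_id, sim1$truth$read_id)
  expect_false(anyDuplicated(sim1$truth$read_id) > 0)
})

test_that("spike-in reads make up the configured fraction of the control", {
  s <- toy_sim()
  fr <- s$sim$fragments
  ctl <- fr[fr$role == "control" & !fr$is_duplicate, ]
  n <- nrow(ctl)
  p <- s$cfg$spikein_fraction
  obs <- mean(ctl$ref == "LMS")
  expect_lt(abs(obs - p), 4 * sqrt(p * (1 - p) / n))
})

test_that("zero editing rate leaves no G at inosine sites in read-out fragments", {
  cfg <- sim_config(seed = 2, inosine_editing_rate = 0, seq_error_rate = 0)
  tr <- build_transcriptome(cfg)
  sites <- suppressWarnings(plant_modifications(tr$model, tr$genome, cfg))
  spk <- spikein_reference(cfg)
  sim <- simulate_library(tr$model, tr$genome, sites, spk, cfg)
  ino <- sites[sites$mod == "inosine", ]
  fr <- sim$fragments[!is.na(sim$fragments$gene_id), ]
  n_checked <- 0L
  for (i in seq_len(nrow(ino))) {
    hit <- fr[fr$start <= ino$pos[i] & fr$end > ino$pos[i], ]
    if (nrow(hit) == 0) next
    base <- substr(hit$seq, ino$pos[i] - hit$start + 1L,
                   ino$pos[i] - hit$start + 1L)
    # genome-forward base: A on + genes, T on - genes; never the edited form
    expected <- if (ino$strand[i] == "+") "A" else "T"
    expect_true(all(base == expected))
    n_checked <- n_checked + nrow(hit)
  }
  expect_gt(n_checked, 100L)
})

test_that("unit capture enrichment makes the reaction exchangeable with the control", {
  # with capture_enrichment = 1 every fragment is captured and randomly
  # barcoded, so per-site coverage in enrichment vs control should agree
  pvals <- vapply(1:5, function(seed) {
    cfg <- sim_config(seed = seed, capture_enrichment = 1,
                      n_reads_enrich = 8000L, n_reads_control = 8000L)
    tr <- build_transcriptome(cfg)
    sites <- suppressWarnings(plant_modifications(tr$model, tr$genome, cfg))
    spk <- spikein_reference(cfg)
    sim <- simulate_library(tr$model, tr$genome, sites, spk, cfg)
    fr <- sim$fragments[!sim$fragments$is_duplicate & sim$fragments$ref != "LMS", ]
    cov_at <- function(role) {
      d <- fr[fr$role == role, ]
      vapply(sites$pos, function(p) sum(d$start <= p & d$end > p), integer(1))
    }
    suppressWarnings(stats::ks.test(cov_at("enrichment"), cov_at("control"))$p.value)
  }, numeric(1))
  expect_gte(sum(pvals > 0.01), 4L)
})

test_that("zero requested reads produce empty but valid FASTQ files", {
  cfg <- sim_config(seed = 1, n_reads_enrich = 0L, n_reads_control = 0L)
  tr <- build_transcriptome(cfg)
  sites <- suppressWarnings(plant_modifications(tr$model, tr$genome, cfg))
  spk <- spikein_reference(cfg)
  out <- withr::local_tempdir()
  sim <- simulate_library(tr$model, tr$genome, sites, spk, cfg, outdir = out)
  expect_equal(nrow(sim$reads), 0L)
  r1 <- file.path(out, "enrichment_R1.fastq.gz")
  expect_true(file.exists(r1))
  expect_equal(length(Biostrings::readDNAStringSet(r1, format = "fastq")), 0L)
})
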