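layout <- barcode_layout()

test_that("read 2 tags are extracted by layout and MBCs error-corrected", {
  wl <- layout$mbc_whitelist
  umi <- "ACGTACGTAC"
  insert2 <- strrep("ACGT", 10)
  r2 <- paste0(wl[["m6A"]], umi, insert2)
  r1 <- strrep("TGCA", 20)
  res <- extract_and_trim(r1, r2, layout = layout)
  expect_equal(res$tagged$mbc, "m6A")
  expect_equal(res$tagged$umi, umi)
  expect_equal(res$tagged$insert, r1)
  expect_equal(res$tagged$insert2, insert2)

  # exhaustive single-base substitutions of each whitelist barcode: all
  # corrected back; every distance-2 corruption is undetermined
  for (lab in names(wl)) {
    bc <- wl[[lab]]
    for (p in seq_len(nchar(bc))) {
      for (alt in setdiff(c("A", "C", "G", "T"), substr(bc, p, p))) {
        mut <- bc
        substr(mut, p, p) <- alt
        res1 <- extract_and_trim(r1, paste0(mut, umi, insert2), layout = layout)
        expect_equal(res1$tagged$mbc, lab)
        # add a second error at a different position
        p2 <- if (p == 1L) 2L else 1L
        mut2 <- mut
        substr(mut2, p2, p2) <- setdiff(c("A", "C", "G", "T"),
                                        substr(mut, p2, p2))[1]
        res2 <- extract_and_trim(r1, paste0(mut2, umi, insert2), layout = layout)
        expect_equal(res2$tagged$mbc, "undetermined")
      }
    }
  }
})

test_that("quality trimming enforces the 30 nt minimum insert", {
  wl <- layout$mbc_whitelist
  r2 <- paste0(wl[["m6A"]], "ACGTACGTAC", strrep("A", 40))
  # a 29 nt insert is removed; 30 nt is retained
  res29 <- extract_and_trim(strrep("A", 29), r2, layout = layout)
  expect_equal(nrow(res29$tagged), 0L)
  expect_equal(res29$rejected$reason, "short_insert")
  res30 <- extract_and_trim(strrep("A", 30), r2, layout = layout)
  expect_equal(nrow(res30$tagged), 1L)
  expect_equal(nchar(res30$tagged$insert), 30L)
  # the sliding window removes a low-quality 3' tail (window mean < Q20);
  # at most trim_window - 1 trailing low-quality bases can survive
  r1 <- strrep("A", 60)
  qual <- paste0(strrep("I", 29), strrep("#", 31))
  res <- extract_and_trim(r1, r2, qual1 = qual, layout = layout)
  expect_equal(nrow(res$tagged), 1L)
  expect_lte(nchar(res$tagged$insert), 29L + layout$trim_window - 1L)
  expect_gte(nchar(res$tagged$insert), 29L)
})

test_that("read 2 shorter than MBC+UMI is rejected as layout_underflow", {
  res <- extract_and_trim("ACGTACGTACGTACGTACGTACGTACGTACGT", "ACGTACG",
                          layout = layout)
  expect_equal(res$rejected$reason, "layout_underflow")
  expect_equal(unname(res$counts[["layout_underflow"]]), 1L)
})

test_that("deduplication matches a brute-force duplicate scan", {
  set.seed(42)
  n <- 500L
  frags <- data.frame(
    ref = sample(c("chr1", "chr2"), n, replace = TRUE),
    start = sample(1:40, n, replace = TRUE),
    end = 0L, strand = sample(c("+", "-"), n, replace = TRUE),
    mbc = sample(c("m6A", "inosine"), n, replace = TRUE),
    umi = sample(c("AAAA", "CCCC", "GGGG"), n, replace = TRUE),
    mean_qual = sample(30:40, n, replace = TRUE),
    read_id = sprintf("r%04d", sample.int(n)),
    stringsAsFactors = FALSE)
  frags$end <- frags$start + 100L
  res <- deduplicate_fragments(frags)
  oracle <- bf_dedup(frags)
  got <- res$fragments[order(res$fragments$ref, res$fragments$start,
                             res$fragments$read_id), ]
  rownames(got) <- rownames(oracle) <- NULL
  expect_equal(got, oracle)
  # report reconciles totals
  expect_equal(sum(res$report$n_input), n)
  expect_equal(sum(res$report$n_unique), nrow(res$fragments))
  # idempotence
  again <- deduplicate_fragments(res$fragments)
  expect_equal(nrow(again$fragments), nrow(res$fragments))
})

test_that("duplicate keys respect MBC and position", {
  base <- data.frame(ref = "chr1", start = 10L, end = 110L, strand = "+",
                     mbc = "m6A", umi = "AAAA", mean_qual = 35,
                     read_id = c("a", "b"), stringsAsFactors = FALSE)
  expect_equal(nrow(deduplicate_fragments(base)$fragments), 1L)
  diff_mbc <- base
  diff_mbc$mbc <- c("m6A", "inosine")
  expect_equal(nrow(deduplicate_fragments(diff_mbc)$fragments), 2L)
  # positionless collapse merges across positions
  diff_pos <- base
  diff_pos$start <- c(10L, 500L)
  expect_equal(nrow(deduplicate_fragments(diff_pos)$fragments), 2L)
  expect_equal(nrow(deduplicate_fragments(diff_pos,
                                          position_aware = FALSE)$fragments), 1L)
})

test_that("split_by_mbc is an order-independent partition", {
  set.seed(11)
  frags <- data.frame(mbc = c(rep("m6A", 10), rep("inosine", 5)),
                      read_id = sprintf("r%02d", 1:15),
                      stringsAsFactors = FALSE)
  sp <- split_by_mbc(frags)
  expect_equal(vapply(sp, nrow, integer(1)), c(inosine = 5L, m6A = 10L))
  expect_equal(sum(vapply(sp, nrow, integer(1))), nrow(frags))
  shuffled <- frags[sample.int(nrow(frags)), ]
  sp2 <- split_by_mbc(shuffled)
  for (m in names(sp)) {
    expect_setequal(sp[[m]]$read_id, sp2[[m]]$read_id)
  }
  empty <- split_by_mbc(frags[0, , drop = FALSE],
                        labels = c("m6A", "inosine"))
  expect_equal(names(empty), c("m6A", "inosine"))
  expect_true(all(vapply(empty, nrow, integer(1)) == 0L))
})

test_that("downsampling equalizes per-MBC counts across samples", {
  mk <- function(n_m6a, n_ino) data.frame(
    mbc = c(rep("m6A", n_m6a), rep("inosine", n_ino)),
    read_id = sprintf("r%03d", seq_len(n_m6a + n_ino)),
    stringsAsFactors = FALSE)
  sets <- list(A = mk(100, 30), B = mk(80, 50))
  ds <- downsample_equal_mbc(sets, seed = 4)
  for (s in names(ds)) {
    expect_equal(sum(ds[[s]]$mbc == "m6A"), 80L)
    expect_equal(sum(ds[[s]]$mbc == "inosine"), 30L)
  }
  # deterministic given the seed
  ds2 <- downsample_equal_mbc(sets, seed = 4)
  expect_identical(ds, ds2)
  # equal counts: identical multisets
  eq <- list(A = mk(50, 20), B = mk(50, 20))
  dse <- downsample_equal_mbc(eq, seed = 9)
  expect_setequal(dse$A$read_id, eq$A$read_id)
  # an MBC absent from one sample drops to zero everywhere, with warning
  zero <- list(A = mk(10, 0), B = mk(10, 5))
  expect_warning(dz <- downsample_equal_mbc(zero, seed = 2), "zero")
  expect_equal(sum(dz$B$mbc == "inosine"), 0L)
})

test_that("demultiplexing recovers true MBCs at >= 99% with error correction", {
  s <- toy_sim()
  lay <- barcode_layout(mbc_whitelist = s$cfg$mbc_whitelist,
                        umi_length = s$cfg$umi_length)
  rr <- s$sim$reads[s$sim$reads$role == "control", ][1:4000, ]
  res <- extract_and_trim(rr$read1, rr$read2, qual1 = rr$qual1,
                          qual2 = rr$qual2, layout = lay,
                          read_id = rr$read_id)
  truth <- s$sim$truth
  i <- match(res$tagged$read_id, truth$read_id)
  acc <- mean(res$tagged$mbc == truth$mbc[i])
  expect_gte(acc, 0.99)

  # with no sequencing error, demultiplexing is perfect
  cfg0 <- sim_config(seed = 6, seq_error_rate = 0, n_reads_enrich = 2000L,
                     n_reads_control = 2000L)
  tr0 <- build_transcriptome(cfg0)
  st0 <- suppressWarnings(plant_modifications(tr0$model, tr0$genome, cfg0))
  sim0 <- simulate_library(tr0$model, tr0$genome, st0,
                           spikein_reference(cfg0), cfg0)
  res0 <- extract_and_trim(sim0$reads$read1, sim0$reads$read2,
                           layout = barcode_layout(
                             mbc_whitelist = cfg0$mbc_whitelist,
                             umi_length = cfg0$umi_length),
                           read_id = sim0$reads$read_id)
  j <- match(res0$tagged$read_id, sim0$truth$read_id)
  expect_equal(mean(res0$tagged$mbc == sim0$truth$mbc[j]), 1)
})
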