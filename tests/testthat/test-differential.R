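test_that("peak matching merges overlapping loci across conditions", {
  set.seed(33)
  a <- random_peaks(30)
  # identical sets: every locus present in both with equal values
  tb <- match_peaks(list(ctrl = a, trt = a))
  expect_true(all(tb$present_ctrl & tb$present_trt))
  expect_equal(tb$fe_ctrl, tb$fe_trt)
  # conservation: all input peaks fall in some locus
  expect_equal(sum(vapply(seq_len(nrow(a)), function(i)
    any(tb$ref == a$ref[i] & tb$start <= a$start[i] & tb$end >= a$end[i]),
    logical(1))), nrow(a))

  # disjoint sets: every locus condition-unique
  b <- a
  b$start <- a$start + 20000L
  b$end <- a$end + 20000L
  td <- match_peaks(list(ctrl = a, trt = b))
  expect_true(all(xor(td$present_ctrl, td$present_trt)))
  expect_equal(sum(td$present_ctrl) + sum(td$present_trt), nrow(td))

  # random sets against a brute-force single-linkage merge
  for (rep in 1:5) {
    x <- random_peaks(40); y <- random_peaks(40)
    tr <- match_peaks(list(x = x, y = y))
    iv <- rbind(x[, c("start", "end")], y[, c("start", "end")])
    iv <- iv[order(iv$start), ]
    merged <- list(); cur <- c(iv$start[1], iv$end[1])
    for (i in 2:nrow(iv)) {
      if (iv$start[i] < cur[2]) cur[2] <- max(cur[2], iv$end[i])
      else { merged[[length(merged) + 1]] <- cur; cur <- c(iv$start[i], iv$end[i]) }
    }
    merged[[length(merged) + 1]] <- cur
    om <- do.call(rbind, merged)
    expect_equal(tr$start, om[, 1])
    expect_equal(tr$end, om[, 2])
  }
  # mixed modifications are refused
  z <- random_peaks(10); z$modification <- "inosine"
  expect_error(match_peaks(list(a = random_peaks(10), b = z)), "mixed")
})

test_that("fold-enrichment correlation is Pearson over co-present loci", {
  set.seed(41)
  # spaced, non-overlapping peaks so loci correspond 1:1 to peaks
  a <- random_peaks(50)
  a$start <- seq(0L, by = 300L, length.out = 50L)
  a$end <- a$start + 100L
  a$summit <- a$start + 50L
  b <- a
  b$fold_enrichment <- 2 * a$fold_enrichment + rnorm(50, 0, 0.5)
  tb <- match_peaks(list(A = a, B = b))
  res <- peak_correlation(tb, "A", "B")
  # from-scratch covariance oracle
  x <- tb$fe_A; y <- tb$fe_B
  r_manual <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(res$r, r_manual, tolerance = 1e-12)
  expect_equal(res$r_squared, r_manual^2, tolerance = 1e-12)
  # identical vectors: perfect correlation
  ti <- match_peaks(list(A = a, B = a))
  expect_equal(peak_correlation(ti, "A", "B")$r_squared, 1)
  # y = -x: r = -1 but R^2 = 1
  neg <- a
  neg$fold_enrichment <- -a$fold_enrichment
  tn <- match_peaks(list(A = a, B = neg))
  rn <- peak_correlation(tn, "A", "B")
  expect_equal(rn$r, -1)
  expect_equal(rn$r_squared, 1)
})

test_that("the rank-sum test matches exact enumeration and rank properties", {
  # identical samples: p = 1 under tie handling
  expect_equal(rank_test(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  # the most extreme arrangement of 3 vs 3: exact two-sided p = 2/20
  res <- rank_test(c(1, 2, 3), c(10, 20, 30))
  expect_equal(res$p_value, 0.1)
  expect_equal(res$method, "exact")
  # independent oracle: full enumeration of C(6,3) rank splits
  pooled <- c(1, 2, 3, 10, 20, 30)
  combs <- utils::combn(6, 3)
  w_obs <- sum(rank(pooled)[1:3]) - 3 * 4 / 2
  ws <- apply(combs, 2, function(ix) sum(rank(pooled)[ix]) - 3 * 4 / 2)
  p_exact <- mean(abs(ws - 4.5) >= abs(w_obs - 4.5))
  expect_equal(res$p_value, p_exact)
  # invariance under common monotone transforms
  set.seed(15)
  x <- rnorm(12); y <- rnorm(10, 1)
  base <- rank_test(x, y)
  for (f in list(function(v) exp(v), function(v) v^3, function(v) 5 * v + 2)) {
    tr <- rank_test(f(x), f(y))
    expect_equal(tr$statistic, base$statistic)
    expect_equal(tr$p_value, base$p_value)
  }
})

test_that("gene-score clustering reproduces Ward agglomeration", {
  set.seed(55)
  # toy table: 10 genes x 3 conditions
  genes <- sprintf("g%02d", 1:10)
  tb <- data.frame(locus_id = sprintf("l%02d", 1:10), ref = "chr1",
                   start = 1:10 * 100L, end = 1:10 * 100L + 50L,
                   modification = "m6A", gene_id = genes)
  for (cn in c("c1", "c2", "c3")) {
    tb[[paste0("fe_", cn)]] <- runif(10, 1, 20)
    tb[[paste0("present_", cn)]] <- TRUE
  }
  res <- cluster_gene_scores(tb, k = 3)
  expect_length(res$assignments, 10L)
  expect_equal(length(unique(res$assignments)), 3L)
  # merge order equals an independent Lance-Williams Ward implementation
  oracle <- bf_ward(res$scores)
  got_sets <- hclust_merge_sets(res$hclust)
  for (s in seq_along(oracle$merges)) {
    expect_equal(got_sets[[s]], oracle$merges[[s]], info = paste("step", s))
  }
  # ward.D2 heights are the square roots of the Lance-Williams d^2 heights
  expect_equal(res$hclust$height, sqrt(oracle$heights), tolerance = 1e-8)

  # identical profiles merge first at distance zero
  tb2 <- tb
  tb2$fe_c1[2] <- tb2$fe_c1[1]
  tb2$fe_c2[2] <- tb2$fe_c2[1]
  tb2$fe_c3[2] <- tb2$fe_c3[1]
  res2 <- cluster_gene_scores(tb2, k = 2)
  expect_equal(res2$hclust$height[1], 0)
  expect_setequal(hclust_merge_sets(res2$hclust)[[1]], c(1L, 2L))
  # k = n gives singletons
  resn <- cluster_gene_scores(tb, k = 10)
  expect_equal(length(unique(resn$assignments)), 10L)
})

test_that("halving m6A stoichiometry shows in the differential scatter", {
  w <- toy_world()
  sites_b <- w$sites
  halve <- sites_b$mod == "m6A"
  sites_b$stoichiometry[halve] <- sites_b$stoichiometry[halve] / 2
  call_all <- function(sites) {
    sim <- simulate_library(w$model, w$genome, sites, w$spikein, w$cfg)
    dd <- lapply(split(sim$fragments, sim$fragments$role),
                 function(d) deduplicate_fragments(d)$fragments)
    lens <- w$model$chrom_lengths
    out <- list()
    for (m in c("m6A", "inosine")) {
      sig_fr <- dd$enrichment
      sig_fr <- sig_fr[sig_fr$mbc == m & sig_fr$ref != "LMS", ]
      bg_fr <- dd$control
      bg_fr <- bg_fr[bg_fr$mbc == m & bg_fr$ref != "LMS", ]
      p <- call_peaks(build_coverage(sig_fr, lens, sum(dd$enrichment$mbc == m)),
                      build_coverage(bg_fr, lens, sum(dd$control$mbc == m)),
                      modification = m)
      out[[m]] <- scale_peaks(p, setNames(1, m))
    }
    out
  }
  pa <- call_all(w$sites)
  pb <- call_all(sites_b)
  slope_of <- function(m) {
    tb <- match_peaks(list(A = pa[[m]], B = pb[[m]]))
    shared <- tb$present_A & tb$present_B
    sum(tb$fe_A[shared] * tb$fe_B[shared]) / sum(tb$fe_A[shared]^2)
  }
  expect_lt(slope_of("m6A"), 0.85)
  expect_gt(slope_of("inosine"), 0.8)
  expect_lt(slope_of("inosine"), 1.25)
})
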