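# Shared simulated fixtures, built once per test session and cached.

.sim_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .sim_cache)) {
    assign(key, builder(), envir = .sim_cache)
  }
  get(key, envir = .sim_cache)
}

# the default study-condition toy: 50 kb, 8 genes, 20 m6A + 10 inosine
toy_world <- function(seed = 1, ...) {
  key <- paste0("world_", seed, "_", paste(c(...), collapse = "_"))
  cached(key, function() {
    cfg <- sim_config(seed = seed, ...)
    tr <- build_transcriptome(cfg)
    sites <- suppressWarnings(plant_modifications(tr$model, tr$genome, cfg))
    spk <- spikein_reference(cfg)
    list(cfg = cfg, model = tr$model, genome = tr$genome,
         sites = sites, spikein = spk)
  })
}

toy_sim <- function(seed = 1, ...) {
  key <- paste0("sim_", seed, "_", paste(c(...), collapse = "_"))
  cached(key, function() {
    w <- toy_world(seed, ...)
    sim <- simulate_library(w$model, w$genome, w$sites, w$spikein, w$cfg)
    c(w, list(sim = sim))
  })
}

# a full pipeline run (markers, outputs) cached per variant tag
toy_pipeline <- function(tag = "full", seed = 1, ...) {
  key <- paste0("pipe_", tag)
  cached(key, function() {
    outdir <- file.path(tempdir(), paste0("epimodkit_", tag))
    rc <- run_config(outdir = outdir, sim = sim_config(seed = seed, ...))
    res <- suppressWarnings(run_pipeline(rc))
    list(config = rc, res = res, outdir = outdir)
  })
}

# deduplicated fragments split by role, derived from the cached toy sim
toy_dedup <- function(seed = 1, ...) {
  key <- paste0("dedup_", seed, "_", paste(c(...), collapse = "_"))
  cached(key, function() {
    s <- toy_sim(seed, ...)
    lapply(split(s$sim$fragments, s$sim$fragments$role),
           function(d) deduplicate_fragments(d)$fragments)
  })
}

# hand-built tiny transcript model: one + strand gene, one - strand gene
tiny_model <- function() {
  features <- rbind(
    data.frame(gene_id = "gA", transcript_id = "gA.t1",
               type = c("utr5", "cds_exon", "intron", "cds_exon", "utr3"),
               chrom = "chr1",
               start = c(100L, 200L, 500L, 700L, 900L),
               end = c(200L, 500L, 700L, 900L, 1100L),
               strand = "+", tx_rank = 1:5),
    data.frame(gene_id = "gB", transcript_id = "gB.t1",
               type = c("utr3", "cds_exon", "utr5"),
               chrom = "chr1",
               start = c(2000L, 2300L, 2800L),
               end = c(2300L, 2800L, 3000L),
               strand = "-", tx_rank = c(3L, 2L, 1L)))
  genes <- data.frame(
    gene_id = c("gA", "gB"), transcript_id = c("gA.t1", "gB.t1"),
    chrom = "chr1", start = c(100L, 2000L), end = c(1100L, 3000L),
    strand = c("+", "-"), exonic_len = c(800L, 1000L),
    stringsAsFactors = FALSE)
  structure(list(genes = genes, features = features,
                 chrom_lengths = c(chr1 = 3500L)),
            class = "transcript_model")
}

# constant-quality FASTQ-style reads for barcode tests
q40 <- function(s) strrep("I", nchar(s))
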