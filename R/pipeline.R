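#' Pipeline run configuration
#'
#' Bundles every stage parameter of an end-to-end run (simulate -> demux ->
#' truth-alignment -> dedup -> spike-in -> peaks -> confidence filter ->
#' variants -> annotation) into one validated object that is echoed into the
#' run manifest.
#'
#' @param outdir run directory (created if needed).
#' @param sim a \code{\link{sim_config}} describing the synthetic input
#'   (simulation test mode; alignment is pluggable, see Details).
#' @param params a \code{\link{peak_params}} object.
#' @param max_fpr maximum modeled false-positive rate for cutoff selection.
#' @param min_depth high-confidence minimum summit depth (>=).
#' @param min_rate minimum A-to-G variant rate.
#' @param min_depth_exclusive variant depth threshold (strict >).
#' @param fragments_tsv optional path to externally aligned fragments (TSV
#'   with the \code{\link{write_sim_library}} alignment columns); when
#'   given, the simulate/demux/align stages are replaced by loading it.
#' @param force rerun all stages even when completion markers exist.
#' @return list of class \code{run_config}.
#' @details Read alignment itself is out of scope: the pipeline either
#'   consumes externally aligned fragments or, in simulation mode, joins the
#'   demultiplexed reads to the simulator's truth alignments by read id.
#' @export
run_config <- function(outdir, sim = sim_config(), params = peak_params(),
                       max_fpr = 0.05, min_depth = 5, min_rate = 0.10,
                       min_depth_exclusive = 5L, fragments_tsv = NULL,
                       force = FALSE) {
  structure(list(outdir = outdir, sim = sim, peak_params = params,
                 max_fpr = max_fpr, min_depth = min_depth,
                 min_rate = min_rate,
                 min_depth_exclusive = min_depth_exclusive,
                 fragments_tsv = fragments_tsv, force = force),
            class = "run_config")
}

pipeline_stages <- c("simulate", "demux", "align", "dedup", "spikein",
                     "callpeaks", "filter", "variants", "annotate")

#' Run the full pipeline
#'
#' Executes the stages in dependency order. Every completed stage writes its
#' state under \code{outdir/state/} and a completion marker under
#' \code{outdir/markers/}; on re-run, completed stages are skipped (their
#' state reloaded) until the first missing marker, after which that stage
#' and everything downstream is regenerated. \code{force = TRUE} reruns
#' everything. A manifest with all parameters and a per-stage read
#' accounting log are written alongside the outputs.
#'
#' @param config a \code{\link{run_config}}.
#' @return invisibly, a list with the main results: \code{peaks} (per
#'   modification, flagged), \code{cutoffs}, \code{spikein_factors},
#'   \code{variant_sites}, \code{support_fraction}, \code{metagene},
#'   \code{motif}, \code{log}.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$outdir
  for (d in c("", "markers", "state", "sim", "peaks", "noise", "variants",
              "annotation")) {
    dir.create(file.path(out, d), recursive = TRUE, showWarnings = FALSE)
  }
  if (!is.null(config$fragments_tsv) && !file.exists(config$fragments_tsv)) {
    stop_config("missing input: %s", config$fragments_tsv)
  }
  manifest <- list(package = "epimodkit",
                   version = as.character(utils::packageVersion("epimodkit")),
                   seed = config$sim$seed,
                   sim = unclass(config$sim),
                   peak_params = unclass(config$peak_params),
                   max_fpr = config$max_fpr, min_depth = config$min_depth,
                   min_rate = config$min_rate,
                   min_depth_exclusive = config$min_depth_exclusive,
                   stages = pipeline_stages)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE,
                       digits = NA)

  env <- new.env(parent = emptyenv())
  env$log <- list()
  ran_any <- isTRUE(config$force)
  for (stage in pipeline_stages) {
    marker <- file.path(out, "markers", paste0(stage, ".done"))
    state <- file.path(out, "state", paste0(stage, ".rds"))
    if (!ran_any && file.exists(marker) && file.exists(state)) {
      restore_stage(env, state)
      next
    }
    ran_any <- TRUE
    run_stage(stage, env, config)
    save_stage(env, stage, state)
    writeLines(format(Sys.time()), marker)
  }
  log_df <- do.call(rbind, env$log)
  if (!is.null(log_df)) {
    write.table(log_df, file.path(out, "log.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  invisible(list(peaks = env$peaks_flagged, cutoffs = env$cutoffs,
                 spikein_factors = env$factors,
                 variant_sites = env$variant_sites,
                 support_fraction = env$support_fraction,
                 metagene = env$metagene, motif = env$motif, log = log_df))
}

stage_vars <- list(
  simulate = c("model", "genome", "sites", "spikein_ref", "sim_paths"),
  demux = c("tagged"),
  align = c("fragments"),
  dedup = c("dedup", "library_sizes"),
  spikein = c("spike_report", "factors"),
  callpeaks = c("peaks_scaled"),
  filter = c("peaks_flagged", "cutoffs", "noise_models"),
  variants = c("variant_sites", "support_fraction"),
  annotate = c("annotated", "metagene", "motif"))

save_stage <- function(env, stage, path) {
  keep <- c(stage_vars[[stage]], "log")
  obj <- mget(keep, envir = env, ifnotfound = list(NULL))
  saveRDS(obj, path)
}

restore_stage <- function(env, path) {
  obj <- readRDS(path)
  for (nm in names(obj)) assign(nm, obj[[nm]], envir = env)
}

log_count <- function(env, stage, metric, value) {
  env$log[[length(env$log) + 1L]] <-
    data.frame(stage = stage, metric = metric, value = value,
               stringsAsFactors = FALSE)
}

run_stage <- function(stage, env, config) {
  out <- config$outdir
  cfg <- config$sim
  switch(stage,
    simulate = {
      if (!is.null(config$fragments_tsv)) {
        env$model <- NULL; env$genome <- NULL; env$sites <- NULL
        env$spikein_ref <- NULL; env$sim_paths <- NULL
        return(invisible())
      }
      tr <- build_transcriptome(cfg,
                                fasta = file.path(out, "sim", "genome.fa"),
                                gtf = file.path(out, "sim", "genes.gtf"))
      env$model <- tr$model; env$genome <- tr$genome
      env$sites <- plant_modifications(tr$model, tr$genome, cfg,
                                       bed = file.path(out, "sim", "truth_sites.bed"))
      env$spikein_ref <- spikein_reference(
        cfg, fasta = file.path(out, "sim", "spikein.fa"),
        segments_bed = file.path(out, "sim", "spikein_segments.bed"))
      sim <- simulate_library(tr$model, tr$genome, env$sites,
                              env$spikein_ref, cfg,
                              outdir = file.path(out, "sim"))
      env$sim_paths <- file.path(out, "sim")
      log_count(env, stage, "reads_enrichment",
                sum(sim$reads$role == "enrichment"))
      log_count(env, stage, "reads_control", sum(sim$reads$role == "control"))
      log_count(env, stage, "sites_planted", nrow(env$sites))
    },
    demux = {
      if (!is.null(config$fragments_tsv)) { env$tagged <- NULL; return(invisible()) }
      layout <- barcode_layout(mbc_whitelist = cfg$mbc_whitelist,
                               umi_length = cfg$umi_length)
      tg <- list()
      for (role in c("enrichment", "control")) {
        dm <- demux_fastq(file.path(out, "sim", sprintf("%s_R1.fastq.gz", role)),
                          file.path(out, "sim", sprintf("%s_R2.fastq.gz", role)),
                          layout)
        dm$tagged$role <- if (nrow(dm$tagged)) role else character(0)
        tg[[role]] <- dm$tagged
        log_count(env, stage, paste0(role, "_input"), dm$counts[["input"]])
        log_count(env, stage, paste0(role, "_tagged"), dm$counts[["tagged"]])
        log_count(env, stage, paste0(role, "_rejected"), nrow(dm$rejected))
      }
      env$tagged <- do.call(rbind, tg)
    },
    align = {
      if (!is.null(config$fragments_tsv)) {
        env$fragments <- read_fragments_tsv(config$fragments_tsv)
      } else {
        truth <- read_fragments_tsv(file.path(out, "sim",
                                              "truth_alignments.tsv"))
        keep <- truth$read_id %in% env$tagged$read_id
        fr <- truth[keep, , drop = FALSE]
        # demultiplexed (error-corrected) MBC/UMI replace the truth tags
        i <- match(fr$read_id, env$tagged$read_id)
        fr$mbc <- env$tagged$mbc[i]
        fr$umi <- env$tagged$umi[i]
        fr$mean_qual <- env$tagged$mean_qual[i]
        env$fragments <- fr[fr$mbc != "undetermined", , drop = FALSE]
      }
      log_count(env, stage, "aligned_fragments", nrow(env$fragments))
    },
    dedup = {
      dd <- list()
      for (role in unique(env$fragments$role)) {
        res <- deduplicate_fragments(
          env$fragments[env$fragments$role == role, , drop = FALSE])
        dd[[role]] <- res$fragments
        for (j in seq_len(nrow(res$report))) {
          log_count(env, stage, sprintf("%s_%s_unique", role,
                                        res$report$mbc[j]),
                    res$report$n_unique[j])
        }
      }
      env$dedup <- dd
      ls <- do.call(rbind, lapply(names(dd), function(role) {
        t <- table(dd[[role]]$mbc)
        data.frame(role = role, mbc = names(t), total = as.integer(t),
                   stringsAsFactors = FALSE)
      }))
      env$library_sizes <- ls
    },
    spikein = {
      allfr <- do.call(rbind, env$dedup)
      genome_refs <- if (!is.null(env$model)) names(env$model$chrom_lengths)
                     else setdiff(unique(allfr$ref), "LMS")
      spk <- env$spikein_ref %||% spikein_reference(cfg)
      env$spike_report <- count_spikein(allfr, spk,
                                        library_sizes = env$library_sizes,
                                        genome_refs = genome_refs)
      mods <- names(cfg$mbc_whitelist)
      env$factors <- setNames(vapply(mods, function(m) {
        tryCatch(enrichment_factor(env$spike_report, m),
                 spikein_failed = function(e) {
                   warning(conditionMessage(e), "; continuing unscaled")
                   1
                 })
      }, numeric(1)), mods)
      for (m in mods) log_count(env, stage, paste0("factor_", m),
                                env$factors[[m]])
    },
    callpeaks = {
      lens <- genome_lengths(env, config)
      mods <- names(cfg$mbc_whitelist)
      pk <- list()
      for (m in mods) {
        sig_fr <- env$dedup$enrichment
        sig_fr <- sig_fr[sig_fr$mbc == m & sig_fr$ref %in% names(lens), ]
        bg_fr <- env$dedup$control
        bg_fr <- bg_fr[bg_fr$mbc == m & bg_fr$ref %in% names(lens), ]
        sig <- build_coverage(sig_fr, lens,
                              library_size = lib_size(env, "enrichment", m))
        bg <- build_coverage(bg_fr, lens,
                             library_size = lib_size(env, "control", m))
        p <- call_peaks(sig, bg, config$peak_params, modification = m)
        p <- scale_peaks(p, env$factors[m])
        pk[[m]] <- p
        log_count(env, stage, paste0("peaks_", m), nrow(p))
        if (length(sig) > 0) {
          write_bedgraph(sig[[1]], file.path(out, "peaks",
                                             sprintf("%s_signal.bedgraph", m)))
        }
      }
      env$peaks_scaled <- pk
    },
    filter = {
      lens <- genome_lengths(env, config)
      env$cutoffs <- list(); env$noise_models <- list()
      flagged <- list()
      for (m in names(env$peaks_scaled)) {
        res <- replicate_cutoff(env, config, m, lens)
        env$cutoffs[[m]] <- res$selection
        env$noise_models[[m]] <- res$model
        fl <- filter_high_confidence(env$peaks_scaled[[m]],
                                     res$selection$cutoff, config$min_depth)
        flagged[[m]] <- fl
        write_peaks(fl, file.path(out, "peaks", sprintf("%s_peaks.bed", m)))
        nm_json <- list(modification = m,
                        cutoff = res$selection$cutoff,
                        method = res$selection$method,
                        fpr_at_cutoff = res$selection$fpr_at_cutoff)
        if (!is.null(res$model)) {
          nm_json <- c(nm_json, res$model[c("A", "k", "m", "b", "rmse",
                                            "linear_ok", "converged")])
        }
        jsonlite::write_json(nm_json,
                             file.path(out, "noise", sprintf("%s_noise.json", m)),
                             auto_unbox = TRUE, pretty = TRUE, digits = NA)
        log_count(env, stage, paste0("hc_peaks_", m),
                  sum(fl$high_confidence, na.rm = TRUE))
      }
      env$peaks_flagged <- flagged
    },
    variants = {
      ip <- env$peaks_flagged$inosine
      ip <- ip[ip$high_confidence %in% TRUE, , drop = FALSE]
      ip <- assign_feature(ip, env$model)
      ip$peak_id <- sprintf("ino%05d", seq_len(nrow(ip)))
      frags <- env$dedup$enrichment
      frags <- frags[frags$mbc == "inosine" & frags$ref != "LMS", ]
      cols <- pileup_fragments(frags, env$genome,
                               data.frame(chrom = ip$ref, start = ip$start,
                                          end = ip$end, peak_id = ip$peak_id))
      env$variant_sites <- call_ag_sites(cols, ip,
                                         min_rate = config$min_rate,
                                         min_depth_exclusive =
                                           config$min_depth_exclusive)
      sup <- peak_variant_support(ip, env$variant_sites)
      env$support_fraction <- sup$support_fraction
      write_vcf_sites(env$variant_sites,
                      file.path(out, "variants", "inosine_AG.vcf"))
      log_count(env, stage, "variant_sites", nrow(env$variant_sites))
      log_count(env, stage, "peak_support_fraction",
                sup$support_fraction %||% NA_real_)
    },
    annotate = {
      ann <- list(); mg <- list()
      for (m in names(env$peaks_flagged)) {
        p <- env$peaks_flagged[[m]]
        p <- p[p$high_confidence %in% TRUE, , drop = FALSE]
        p <- assign_feature(p, env$model)
        ann[[m]] <- p
        mg[[m]] <- metagene_profile(p, env$model)
        write.table(mg[[m]],
                    file.path(out, "annotation",
                              sprintf("metagene_%s.tsv", m)),
                    sep = "\t", quote = FALSE, row.names = FALSE)
      }
      env$annotated <- ann
      all_ann <- do.call(rbind, ann)
      write.table(all_ann, file.path(out, "annotation", "annotated_peaks.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      env$metagene <- mg
      env$motif <- if (!is.null(ann$m6A) && nrow(ann$m6A) > 0) {
        motif_shift(ann$m6A, env$genome, env$model, seed = cfg$seed)
      } else NULL
      if (!is.null(env$motif)) {
        write.table(env$motif$density,
                    file.path(out, "annotation", "motif_shift_m6A.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
      }
      log_count(env, stage, "annotated_peaks",
                if (is.null(all_ann)) 0L else nrow(all_ann))
    })
  invisible()
}

genome_lengths <- function(env, config) {
  if (!is.null(env$model)) return(env$model$chrom_lengths)
  fr <- do.call(rbind, env$dedup)
  fr <- fr[fr$ref != "LMS", ]
  tapply(fr$end, fr$ref, max)
}

lib_size <- function(env, role, mbc) {
  ls <- env$library_sizes
  v <- ls$total[ls$role == role & ls$mbc == mbc]
  if (length(v) == 0) 0L else v
}

# Confidence filtering needs replicates; a single run supplies them as
# seeded pseudo-replicates (random halves of the deduplicated enrichment
# fragments), each called against the full solution control.
replicate_cutoff <- function(env, config, m, lens) {
  cfg <- config$sim
  sig_fr <- env$dedup$enrichment
  sig_fr <- sig_fr[sig_fr$mbc == m & sig_fr$ref %in% names(lens), ]
  bg_fr <- env$dedup$control
  bg_fr <- bg_fr[bg_fr$mbc == m & bg_fr$ref %in% names(lens), ]
  bg <- build_coverage(bg_fr, lens, library_size = lib_size(env, "control", m))
  # content-stable split: each fragment hashes to a half from its own UMI
  # and position (UMIs are random, so the halves are an unbiased random
  # split), independent of what other fragments are present
  hash <- vapply(seq_len(nrow(sig_fr)), function(i) {
    (sum(utf8ToInt(sig_fr$umi[i])) + sig_fr$start[i]) %% 2L
  }, numeric(1))
  pp <- config$peak_params
  # a full-depth peak is reproduced in a pseudo-replicate half when the
  # half's smoothed enrichment ratio at the peak summit reaches a relaxed
  # threshold (half the log-fold of r_min). Requiring a relaxed re-call
  # would penalize shape noise at half depth; requiring the summit-level
  # ratio keeps weak true peaks while false-positive fluctuations split
  # across the halves and fail in at least one of them.
  full <- env$peaks_scaled[[m]]
  if (nrow(full) < 10) {
    fe_max <- max(c(full$fold_enrichment, 0), na.rm = TRUE)
    return(list(selection = list(cutoff = fe_max + 1,
                                 method = "insufficient_peaks",
                                 fpr_at_cutoff = NA_real_),
                model = NULL))
  }
  thr <- log2(1 + (pp$r_min - 1) / 2)
  repro <- vapply(0:1, function(h) {
    fr <- sig_fr[hash == h, , drop = FALSE]
    cov <- build_coverage(fr, lens, library_size = nrow(fr))
    ok <- rep(FALSE, nrow(full))
    for (ref in unique(full$ref)) {
      sm <- smoothed_ratio(cov[[ref]], bg[[ref]], pp)
      i <- which(full$ref == ref)
      ok[i] <- sm[full$summit[i] + 1L] >= thr
    }
    ok
  }, logical(nrow(full)))
  points <- tryCatch({
    fe <- full$fold_enrichment
    top <- max(quantile(fe, 0.995, names = FALSE), 1 + 1e-6)
    grid <- exp(seq(log(1), log(top), length.out = 40L))
    fpr <- vapply(grid, function(cc) {
      d <- fe >= cc
      if (!any(d)) return(NA_real_)
      mean(c(mean(!repro[d, 1]), mean(!repro[d, 2])))
    }, numeric(1))
    n_above <- vapply(grid, function(cc) sum(fe >= cc), integer(1))
    out <- data.frame(cutoff = grid, fpr = fpr, n1 = n_above, n2 = n_above)
    out <- out[!is.na(out$fpr), ]
    class(out) <- c("fpr_points", "data.frame")
    out
  }, error = function(e) NULL)
  if (is.null(points) || nrow(points) < 5) {
    # too few peaks to estimate reproducibility: conservative cutoff above
    # every observed fold-enrichment, so nothing is called high-confidence
    fe_max <- max(c(env$peaks_scaled[[m]]$fold_enrichment, 0), na.rm = TRUE)
    return(list(selection = list(cutoff = fe_max + 1,
                                 method = "insufficient_peaks",
                                 fpr_at_cutoff = NA_real_),
                model = NULL))
  }
  model <- fit_noise_model(points)
  list(selection = select_cutoff(model, config$max_fpr), model = model)
}
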