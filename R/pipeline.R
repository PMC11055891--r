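#' End-to-end pipeline configuration and driver
#'
#' \code{pipeline_config} collects every tunable threshold with its standard
#' default; \code{run_pipeline} chains the stages on a synthetic dataset
#' (junctions -> pileup -> RDC calls; Repli-seq -> corrected fractions ->
#' features -> termination anchors -> forks; merge -> classification -> TRC
#' statistics) and returns a consolidated report. Stage outputs can be
#' cached on disk keyed by an input checksum; cached and recomputed results
#' are identical.
#'
#' @name orchestration
NULL

#' Pipeline thresholds with standard defaults
#'
#' @param p_seed,p_extend RDC seed/extension p-value thresholds.
#' @param seed_gap,island_gap,min_sig,min_len RDC joining/filter rules (bp).
#' @param rpkm_min Active-transcription RPKM cutoff.
#' @param bin_size Repli-seq bin (bp).
#' @param pileup_bin RDC pileup grid (bp).
#' @param half_width Junction extension half-width (bp).
#' @param n_clusters Corrected-fraction cluster count.
#' @param cnn Named list of network hyperparameters.
#' @param seed Master seed.
#' @return A \code{pipeline_config} list (YAML-serializable via
#'   \code{\link{write_pipeline_config}}).
#' @export
pipeline_config <- function(p_seed = 0.01, p_extend = 0.1, seed_gap = 10000,
                            island_gap = 100000, min_sig = 100000,
                            min_len = 300000, rpkm_min = 0.05,
                            bin_size = 50000, pileup_bin = 1000,
                            half_width = 50000, n_clusters = 80,
                            cnn = list(epochs = 60, lr = 0.001,
                                       batch_size = 32, dropout = 0.9,
                                       threshold = 0.5),
                            seed = 1) {
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read/write a pipeline configuration as YAML
#'
#' @param cfg A \code{pipeline_config}.
#' @param path YAML path.
#' @export
write_pipeline_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(pipeline_config, cfg)
}

# checksum-keyed stage cache over plain-data inputs
.cache_key <- function(obj) {
  tf <- tempfile(fileext = ".rds")
  on.exit(unlink(tf))
  saveRDS(obj, tf, compress = FALSE, version = 2)
  unname(tools::md5sum(tf))
}

.cached <- function(cache_dir, name, key_obj, fun) {
  if (is.null(cache_dir)) return(fun())
  dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
  f <- file.path(cache_dir, paste0(name, "-", .cache_key(key_obj), ".rds"))
  if (file.exists(f)) return(readRDS(f))
  v <- fun()
  saveRDS(v, f)
  v
}

#' Run the full pipeline on a synthetic dataset
#'
#' @param simcfg A \code{\link{sim_config}} describing the dataset.
#' @param pcfg A \code{\link{pipeline_config}}.
#' @param train_cnn Train the termination network and use its anchors
#'   (default FALSE: RFD-derived anchors are used directly).
#' @param out_dir Optional directory for BED/bedGraph/TSV outputs.
#' @param cache_dir Optional stage cache directory.
#' @return Report list: RDC calls, features, forks, classifications, TRC
#'   statistics, off-target weights, genome feature fractions and the
#'   stage log.
#' @export
run_pipeline <- function(simcfg, pcfg = pipeline_config(),
                         train_cnn = FALSE, out_dir = NULL,
                         cache_dir = NULL) {
  log <- character(0)
  say <- function(...) {
    msg <- sprintf(...)
    log <<- c(log, msg)
    message(msg)
  }
  say("simulating dataset (seed %d)", simcfg$seed)
  ds <- .cached(cache_dir, "simulate", unclass(simcfg),
                function() simulate_dataset(simcfg))
  chrom_len <- simcfg$chrom_sizes[[simcfg$chrom]]

  say("filtering viewpoints and computing off-target weights")
  libs <- lapply(ds$libraries, filter_viewpoint)
  w <- offtarget_weights(ds$libraries, attr(ds$libraries, "offtargets"))

  say("calling RDCs on pooled interchromosomal junctions")
  pooled <- do.call(c, unname(lapply(libs, function(l) l$junctions)))
  pooled <- pooled[as.character(seqnames(pooled)) == simcfg$chrom]
  rdcs <- .cached(cache_dir, "rdc",
                  list(unclass(simcfg), pcfg$p_seed, pcfg$p_extend,
                       pcfg$seed_gap, pcfg$island_gap, pcfg$min_sig,
                       pcfg$min_len, pcfg$pileup_bin, pcfg$half_width),
                  function() scan_rdc(pooled, chrom_len,
                                      half_width = pcfg$half_width,
                                      bin_size = pcfg$pileup_bin,
                                      p_seed = pcfg$p_seed,
                                      p_extend = pcfg$p_extend,
                                      seed_gap = pcfg$seed_gap,
                                      island_gap = pcfg$island_gap,
                                      min_sig = pcfg$min_sig,
                                      min_len = pcfg$min_len))
  say("%d RDC call(s)", length(rdcs))

  say("normalizing Repli-seq and assigning corrected fractions")
  norm <- lapply(ds$repliseq, normalize_and_smooth)
  fracs <- lapply(norm, birch_fractions, n_clusters = pcfg$n_clusters)
  feats <- lapply(fracs, call_features)
  covered <- sum(!is.na(fracs[[1]]$fraction)) * simcfg$bin_size
  gff <- genome_feature_fractions(feats[[1]], covered)

  say("deriving termination anchors")
  rfd <- compute_rfd(ds$okseq$F, ds$okseq$R)
  labels <- reference_iz_tz(rfd)
  tz_pos <- (labels$tz_bins - 0.5) * simcfg$bin_size
  if (train_cnn) {
    say("training termination network")
    windows <- make_training_windows(norm[[1]], labels)
    model <- train_tz_model(windows, seed = pcfg$seed,
                            epochs = pcfg$cnn$epochs, lr = pcfg$cnn$lr,
                            batch_size = pcfg$cnn$batch_size,
                            dropout = pcfg$cnn$dropout)
    pred <- predict_tz(model, norm[[1]], threshold = pcfg$cnn$threshold)
    tz_pos <- (pred$anchors - 0.5) * simcfg$bin_size
  }

  say("assembling consensus forks")
  forks <- lapply(seq_along(feats), function(i) {
    fi <- feats[[i]]
    assemble_forks(fi[mcols(fi)$kind == "IZ"], tz_pos, ttr = fi,
                   replicate = names(ds$repliseq)[i])
  })
  cons <- if (length(forks) >= 2) {
    consensus_forks(forks[[1]], forks[[2]])
  } else forks[[1]]

  say("classifying RDCs and computing TRC statistics")
  genes <- ds$annotation$genes
  cls <- lapply(seq_along(rdcs), function(i)
    classify_rdc(rdcs[i], cons, feats[[1]]))
  trc <- lapply(seq_along(rdcs), function(i) {
    comp <- assign_compartments(rdcs[i], cons, genes, min_rpkm = pcfg$rpkm_min)
    per_cond <- lapply(names(libs), function(cn) {
      jx <- libs[[cn]]$junctions
      jx <- jx[as.character(seqnames(jx)) == simcfg$chrom]
      pr <- trc_proportions(jx, comp,
                            weights = rep(w[[cn]], length(jx)))
      pr$condition <- cn
      pr
    })
    counts <- vapply(names(libs), function(cn) {
      jx <- libs[[cn]]$junctions
      sum(IRanges::overlapsAny(jx, rdcs[i], ignore.strand = TRUE)) * w[[cn]]
    }, numeric(1))
    rel <- if (sum(counts) > 0) relative_dsb_count(counts) else NULL
    list(compartments = comp, proportions = per_cond, relative_dsb = rel)
  })
  hyb <- if (length(rdcs) > 0 && length(ds$annotation$dripc_plus) > 0) {
    hybrid_stratify(rdcs, ds$annotation$dripc_plus, ds$annotation$dripc_minus)
  } else NULL

  report <- list(rdcs = rdcs,
                 classifications = cls,
                 features = feats[[1]],
                 feature_fractions = gff,
                 forks = cons,
                 trc = trc,
                 hybrid = hyb,
                 offtarget_weights = w,
                 log = log)
  if (!is.null(out_dir)) write_report(report, out_dir, simcfg)
  report
}

#' Write pipeline outputs as BED/bedGraph/TSV
#'
#' @param report Output of \code{\link{run_pipeline}}.
#' @param out_dir Output directory (created if needed).
#' @param simcfg The simulation config (for chromosome sizes).
#' @export
write_report <- function(report, out_dir, simcfg = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (length(report$rdcs) > 0) {
    df <- data.frame(chrom = as.character(seqnames(report$rdcs)),
                     start = GenomicRanges::start(report$rdcs) - 1L,
                     end = GenomicRanges::end(report$rdcs),
                     name = paste0("RDC_", seq_along(report$rdcs)),
                     sig_bp = mcols(report$rdcs)$sig_bp,
                     klass = vapply(report$classifications, `[[`,
                                    character(1), "klass"))
    write.table(df, file.path(out_dir, "rdc_calls.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  if (length(report$forks) > 0) {
    rtracklayer::export(report$forks, file.path(out_dir, "forks.bed"))
  }
  if (length(report$features) > 0) {
    f <- report$features
    mcols(f)$name <- mcols(f)$kind
    mcols(f)$score <- 0L
    rtracklayer::export(f, file.path(out_dir, "features.bed"))
  }
  props <- do.call(rbind, lapply(seq_along(report$trc), function(i) {
    do.call(rbind, lapply(report$trc[[i]]$proportions, function(p)
      data.frame(rdc = i, condition = p$condition,
                 P_HO = p$P_HO, P_CD = p$P_CD,
                 N_HO = p$N_HO, N_CD = p$N_CD)))
  }))
  if (!is.null(props)) {
    write.table(props, file.path(out_dir, "trc_proportions.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  invisible(out_dir)
}
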