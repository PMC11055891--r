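#' Synthetic replication-stress genomes with planted ground truth
#'
#' The generator emulates the full input surface of the pipeline on a
#' deterministic seeded genome: a replication program (origins with firing
#' fractions and a constant fork speed) implies per-bin true replication
#' timing, fork directions, initiation zones and termination meeting points;
#' 16-fraction Repli-seq matrices are Poisson-sampled around the true timing;
#' OK-seq strand counts follow the true fork directionality; translocation
#' junction libraries mix negative binomial background with planted RDCs
#' whose orientation composition follows the local fork direction and a
#' head-on bias; genes, expression and strand-specific DRIPc peaks complete
#' the annotation. Every planted truth object is returned in a machine
#' readable bundle.
#'
#' @name synthetic_data
NULL

#' Simulation configuration
#'
#' Defaults describe the study conditions: 16 S-phase fractions over 50-kb
#' bins, a 100-Mb chromosome, fork speed of 100 kb per S-phase fraction
#' (about 1.8 kb/min over a ~55-min fraction), negative binomial junction
#' background, five aphidicolin dose conditions with 3x RDC enrichment at
#' the highest dose, and a head-on bias of 0.6.
#'
#' @param seed Master RNG seed (all stage seeds derive from it).
#' @param chrom_sizes Named chromosome lengths in bp (a bait chromosome
#'   named in \code{bait_chrom} should be included for viewpoint filtering).
#' @param bait_chrom Bait chromosome name.
#' @param origins data.frame(pos, fraction): origin position (bp) and firing
#'   fraction (1..16) on the junction chromosome.
#' @param fork_speed_bp_per_fraction Fork speed (bp per S fraction).
#' @param bin_size Repli-seq bin (bp).
#' @param background_nb c(mean, dispersion): NB junction background per bin.
#' @param conditions Condition labels (aphidicolin doses).
#' @param dose_enrichment Per-condition RDC fold enrichment.
#' @param depth_factors Per-condition library depth multipliers.
#' @param planted_rdcs data.frame(start, end, theta): planted RDC intervals
#'   and their head-on bias.
#' @param genes data.frame(start, end, strand, rpkm).
#' @param dripc_pairs Dual-strand DRIPc peak pairs planted per gene.
#' @param repliseq_depth Mean Repli-seq reads per bin column.
#' @param okseq_depth Mean OK-seq reads per bin.
#' @param fraction_sigma Gaussian width of the Repli-seq band (fractions).
#' @param offtarget_rate Expected off-target junction count per library
#'   (dose-invariant).
#' @return A \code{sim_config} list.
#' @export
sim_config <- function(seed = 1,
                       chrom_sizes = c(chrSim = 100e6, chrBait = 10e6),
                       bait_chrom = "chrBait",
                       origins = NULL,
                       fork_speed_bp_per_fraction = 100000,
                       bin_size = 50000,
                       background_nb = c(mean = 2, dispersion = 5),
                       conditions = c("untreated", "0.2uM", "0.3uM",
                                      "0.4uM", "0.6uM"),
                       dose_enrichment = c(1, 1.5, 2, 2.5, 3),
                       depth_factors = c(1, 0.9, 1.1, 0.8, 1.2),
                       planted_rdcs = NULL,
                       genes = NULL,
                       dripc_pairs = 3,
                       repliseq_depth = 200,
                       okseq_depth = 100,
                       fraction_sigma = 1.5,
                       offtarget_rate = 500) {
  chrom <- setdiff(names(chrom_sizes), bait_chrom)[1]
  if (is.null(origins)) {
    # origins every ~2 Mb with varied firing fractions
    pos <- seq(1e6, chrom_sizes[[chrom]] - 1e6, by = 2e6)
    set.seed(derive_seed(seed, 7))
    origins <- data.frame(pos = pos,
                          fraction = sample(1:8, length(pos), replace = TRUE))
  }
  if (is.null(planted_rdcs)) planted_rdcs <- data.frame(
    start = numeric(0), end = numeric(0), theta = numeric(0))
  if (is.null(genes)) genes <- data.frame(
    start = numeric(0), end = numeric(0), strand = character(0),
    rpkm = numeric(0))
  cfg <- list(seed = seed, chrom_sizes = chrom_sizes, chrom = chrom,
              bait_chrom = bait_chrom, origins = origins,
              fork_speed_bp_per_fraction = fork_speed_bp_per_fraction,
              bin_size = bin_size, background_nb = background_nb,
              conditions = conditions, dose_enrichment = dose_enrichment,
              depth_factors = depth_factors, planted_rdcs = planted_rdcs,
              genes = genes, dripc_pairs = dripc_pairs,
              repliseq_depth = repliseq_depth, okseq_depth = okseq_depth,
              fraction_sigma = fraction_sigma,
              offtarget_rate = offtarget_rate)
  class(cfg) <- "sim_config"
  cfg
}

# continuous true timing and fork direction per bin from the origin program
.true_program <- function(cfg) {
  nb <- n_bins(cfg$chrom_sizes[[cfg$chrom]], cfg$bin_size)
  centers <- (seq_len(nb) - 0.5) * cfg$bin_size
  o <- cfg$origins
  if (nrow(o) < 1) stop("at least one origin required")
  o <- o[order(o$pos), , drop = FALSE]
  ob <- pos_to_bin(o$pos, cfg$bin_size)
  if (any(diff(ob) < 2)) stop("origins denser than one per two bins are unresolvable")
  timing <- matrix(NA_real_, nb, nrow(o))
  for (i in seq_len(nrow(o))) {
    timing[, i] <- o$fraction[i] +
      abs(centers - o$pos[i]) / cfg$fork_speed_bp_per_fraction
  }
  src <- max.col(-timing, ties.method = "first")
  tcont <- timing[cbind(seq_len(nb), src)]
  tcont <- pmin(tcont, 16)
  direction <- ifelse(centers > o$pos[src], "rightward",
                      ifelse(centers < o$pos[src], "leftward", "origin"))
  # origin bins: the bin containing each origin
  direction[ob] <- "origin"
  # termination meeting points: boundaries where the dominant origin switches
  tz_bins <- which(diff(src) != 0)
  # meeting point position in bp (closed form: where arrival times are equal)
  tz_pos <- vapply(tz_bins, function(b) {
    i <- src[b]; j <- src[b + 1]
    v <- cfg$fork_speed_bp_per_fraction
    (v * (o$fraction[j] - o$fraction[i]) + o$pos[i] + o$pos[j]) / 2
  }, numeric(1))
  list(n_bins = nb, timing = tcont, fraction = pmax(1L, pmin(16L, round(tcont))),
       direction = direction, origin_bins = ob, tz_bins = tz_bins,
       tz_pos = tz_pos, dominant_origin = src)
}

#' Simulate a 16-fraction Repli-seq matrix and the true replication program
#'
#' Per-bin true timing = earliest origin arrival (firing fraction +
#' distance / fork speed), capped at S16; the matrix is a Gaussian band
#' around the true timing on the fraction axis, scaled to depth and
#' Poisson-sampled.
#'
#' @param cfg A \code{sim_config}.
#' @param replicate_id Replicate label (also offsets the noise seed).
#' @return List: \code{matrix} (raw-count \code{repliseq_matrix}),
#'   \code{truth} (timing, fork directions, origin/termination bins,
#'   termination positions in bp).
#' @export
simulate_replication <- function(cfg, replicate_id = "rep1") {
  if (cfg$repliseq_depth <= 0) stop("repliseq depth must be positive")
  tp <- .true_program(cfg)
  set.seed(derive_seed(cfg$seed, 11 + sum(utf8ToInt(replicate_id))))
  expected <- vapply(seq_len(tp$n_bins), function(b) {
    w <- dnorm(1:16, mean = tp$timing[b], sd = cfg$fraction_sigma)
    w / sum(w) * cfg$repliseq_depth
  }, numeric(16))
  counts <- matrix(rpois(length(expected), lambda = expected), nrow = 16)
  list(matrix = repliseq_matrix(counts, cfg$chrom, cfg$bin_size,
                                replicate_id = replicate_id),
       truth = tp)
}

#' Simulate OK-seq strand-specific counts from the true fork program
#'
#' Expected RFD is +0.9 in rightward-replicated bins, -0.9 in leftward bins
#' and 0 at origin bins; forward/reverse counts are Poisson around the
#' implied strand split, so the smoothed RFD ascends through zero at planted
#' origins and descends at termination zones.
#'
#' @param cfg A \code{sim_config}.
#' @param truth Truth list from \code{\link{simulate_replication}}.
#' @param amplitude Expected |RFD| away from transitions (default 0.9).
#' @return List with \code{F}, \code{R} count vectors.
#' @export
simulate_okseq <- function(cfg, truth, amplitude = 0.9) {
  set.seed(derive_seed(cfg$seed, 23))
  e <- ifelse(truth$direction == "rightward", amplitude,
              ifelse(truth$direction == "leftward", -amplitude, 0))
  d <- cfg$okseq_depth
  R <- rpois(length(e), d * (1 + e) / 2)
  F_ <- rpois(length(e), d * (1 - e) / 2)
  list(F = F_, R = R)
}

#' Simulate LAM-HTGTS junction libraries per condition
#'
#' Background junctions per bin are negative binomial with random
#' orientation; inside planted RDCs the rate is multiplied by the
#' condition's fold enrichment, orientations match the local fork direction
#' (Dcen under rightward, Dtel under leftward forks) and head-on
#' compartments (fork direction opposing the local gene) receive
#' theta/(1-theta) times the co-directional rate. Off-target intervals (on
#' the bait chromosome) receive dose-invariant counts scaled only by the
#' library depth factor; a uniform scatter on the bait chromosome provides
#' viewpoint junctions.
#'
#' @param cfg A \code{sim_config}.
#' @param truth Truth list from \code{\link{simulate_replication}}.
#' @return List of \code{htgts_library}, one per condition, plus the
#'   off-target \code{GRanges} as attribute \code{offtargets}.
#' @export
simulate_junctions <- function(cfg, truth) {
  set.seed(derive_seed(cfg$seed, 37))
  nb <- truth$n_bins
  bs <- cfg$bin_size
  mu0 <- cfg$background_nb[["mean"]]
  size0 <- cfg$background_nb[["dispersion"]]
  # per-bin enrichment and orientation policy
  centers <- (seq_len(nb) - 0.5) * bs
  genes <- cfg$genes
  gene_dir <- rep(NA_character_, nb)
  if (nrow(genes) > 0) {
    for (i in seq_len(nrow(genes))) {
      sel <- centers >= genes$start[i] & centers <= genes$end[i]
      gene_dir[sel] <- if (genes$strand[i] == "+") "rightward" else "leftward"
    }
  }
  rdc_idx <- rep(0L, nb)
  theta <- rep(NA_real_, nb)
  if (nrow(cfg$planted_rdcs) > 0) {
    for (i in seq_len(nrow(cfg$planted_rdcs))) {
      sel <- centers >= cfg$planted_rdcs$start[i] &
        centers <= cfg$planted_rdcs$end[i]
      rdc_idx[sel] <- i
      theta[sel] <- cfg$planted_rdcs$theta[i]
    }
  }
  offt <- GenomicRanges::GRanges(
    cfg$bait_chrom,
    IRanges::IRanges(start = c(1e6, 3e6), width = 5000))
  libs <- vector("list", length(cfg$conditions))
  names(libs) <- cfg$conditions
  for (ci in seq_along(cfg$conditions)) {
    fold <- cfg$dose_enrichment[ci]
    depth <- cfg$depth_factors[ci]
    rate <- rep(mu0, nb)
    in_rdc <- rdc_idx > 0
    rate[in_rdc] <- rate[in_rdc] * fold
    # head-on compartments: fork opposes transcription
    ho <- in_rdc & !is.na(gene_dir) &
      truth$direction %in% c("rightward", "leftward") &
      truth$direction != gene_dir
    th <- ifelse(is.na(theta), 0.5, theta)
    rate[ho] <- rate[ho] * th[ho] / (1 - th[ho])
    counts <- rnbinom(nb, size = size0, mu = rate * depth)
    pos <- unlist(lapply(which(counts > 0), function(b) {
      floor(runif(counts[b], (b - 1) * bs, min(b * bs, cfg$chrom_sizes[[cfg$chrom]]) - 1)) + 1
    }))
    if (is.null(pos)) pos <- numeric(0)
    binof <- pos_to_bin(pos, bs)
    ori <- ifelse(rdc_idx[binof] > 0 & truth$direction[binof] == "rightward", "Dcen",
           ifelse(rdc_idx[binof] > 0 & truth$direction[binof] == "leftward", "Dtel",
                  ifelse(runif(length(pos)) < 0.5, "Dcen", "Dtel")))
    chroms <- rep(cfg$chrom, length(pos))
    # off-target junctions (dose-invariant rate, depth-scaled) + bait scatter
    not_count <- rpois(length(offt), cfg$offtarget_rate * depth)
    opos <- unlist(lapply(seq_along(offt), function(i) {
      floor(runif(not_count[i], GenomicRanges::start(offt)[i],
                  GenomicRanges::end(offt)[i]))
    }))
    if (is.null(opos)) opos <- numeric(0)
    bait_n <- rpois(1, 200 * depth)
    bpos <- floor(runif(bait_n, 1, cfg$chrom_sizes[[cfg$bait_chrom]] - 1)) + 1
    all_pos <- c(pos, opos, bpos)
    all_chrom <- c(chroms, rep(cfg$bait_chrom, length(opos) + length(bpos)))
    all_ori <- c(ori, ifelse(runif(length(opos) + length(bpos)) < 0.5,
                             "Dcen", "Dtel"))
    jx <- new_junctions(all_chrom, all_pos, all_ori,
                        bait_chrom = cfg$bait_chrom,
                        library_id = paste0("lib_", cfg$conditions[ci]),
                        condition = cfg$conditions[ci],
                        seqlengths = cfg$chrom_sizes)
    libs[[ci]] <- htgts_library(jx)
  }
  attr(libs, "offtargets") <- offt
  libs
}

#' Simulate gene annotation, expression and DRIPc peaks
#'
#' Genes come from the configuration; each gene receives
#' \code{cfg$dripc_pairs} dual-strand DRIPc peak pairs (an identical
#' plus/minus interval pair) plus one coding-strand-only peak, evenly placed
#' in the gene body.
#'
#' @param cfg A \code{sim_config}.
#' @return List with \code{genes} (\code{GRanges} with \code{rpkm}),
#'   \code{dripc_plus}, \code{dripc_minus}.
#' @export
simulate_annotation <- function(cfg) {
  g <- cfg$genes
  if (nrow(g) == 0) {
    empty <- GenomicRanges::GRanges()
    return(list(genes = empty, dripc_plus = empty, dripc_minus = empty))
  }
  genes <- GenomicRanges::GRanges(cfg$chrom,
                                  IRanges::IRanges(g$start, g$end),
                                  strand = g$strand)
  mcols(genes)$rpkm <- g$rpkm
  plus <- GenomicRanges::GRanges(); minus <- GenomicRanges::GRanges()
  npairs <- rep_len(cfg$dripc_pairs, nrow(g))
  for (i in seq_len(nrow(g))) {
    k <- npairs[i]
    if (k > 0) {
      at <- seq(g$start[i], g$end[i], length.out = k + 2)[2:(k + 1)]
      pk <- GenomicRanges::GRanges(cfg$chrom,
                                   IRanges::IRanges(floor(at), width = 2000))
      GenomicRanges::strand(pk) <- "+"
      plus <- c(plus, pk)
      pk2 <- pk; GenomicRanges::strand(pk2) <- "-"
      minus <- c(minus, pk2)
    }
    # one coding-strand-only peak near the gene start
    solo <- GenomicRanges::GRanges(cfg$chrom,
                                   IRanges::IRanges(g$start[i] + 1000, width = 2000),
                                   strand = g$strand[i])
    if (g$strand[i] == "+") plus <- c(plus, solo) else minus <- c(minus, solo)
  }
  list(genes = genes, dripc_plus = plus, dripc_minus = minus)
}

#' Simulate a complete synthetic dataset
#'
#' @param cfg A \code{sim_config}.
#' @param replicates Repli-seq replicate labels (default two technical
#'   repeats).
#' @return List with \code{repliseq} (list per replicate), \code{okseq},
#'   \code{libraries}, \code{annotation}, \code{truth}.
#' @export
simulate_dataset <- function(cfg, replicates = c("rep1", "rep2")) {
  reps <- lapply(replicates, function(r) simulate_replication(cfg, r))
  names(reps) <- replicates
  truth <- reps[[1]]$truth
  ok <- simulate_okseq(cfg, truth)
  libs <- simulate_junctions(cfg, truth)
  ann <- simulate_annotation(cfg)
  list(repliseq = lapply(reps, `[[`, "matrix"),
       okseq = ok, libraries = libs, annotation = ann, truth = truth,
       config = cfg)
}

#' Write the planted truth bundle as JSON
#'
#' @param dataset Output of \code{\link{simulate_dataset}}.
#' @param path Output JSON path.
#' @export
write_truth_bundle <- function(dataset, path) {
  t <- dataset$truth
  cfg <- dataset$config
  bundle <- list(
    chrom = cfg$chrom,
    bin_size = cfg$bin_size,
    origins = cfg$origins,
    tz_pos = t$tz_pos,
    origin_bins = t$origin_bins,
    tz_bins = t$tz_bins,
    fraction = t$fraction,
    direction = t$direction,
    planted_rdcs = cfg$planted_rdcs,
    genes = cfg$genes
  )
  jsonlite::write_json(bundle, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
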