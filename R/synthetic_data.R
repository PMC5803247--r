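## Kinematic two-population simulator.
##
## After instantaneous kinase inhibition, polymerases upstream of a
## promoter-proximal checkpoint elongate at a severely reduced rate v_slow,
## while polymerases already past the checkpoint keep a fast rate v_fast.
## With constant initiation and conveyor-belt kinematics the steady-state
## density is rho = r / v, so the slow 5' population piles up to
## initiation_density * (v_ref / v_slow) while the fast population clears a
## growing zone behind it. At time t (minutes) the expected density along a
## gene, measured from the TSS, is piecewise:
##
##   [0, v_slow t)                          init * v_ref / v_slow   (advancing wave)
##   [v_slow t, ckpt + v_slow t)            init                    (pre-checkpoint residue)
##   [ckpt + v_slow t, ckpt + v_fast t)     0 over background       (cleared zone)
##   [ckpt + v_fast t, L)                   init                    (undisturbed)
##
## plus an additive promoter-proximal pause peak, an exponential
## termination decay past the CPS, and a uniform intergenic background.
## Per-base counts are Poisson (optionally negative-binomial) draws.

#' Simulation configuration
#'
#' Defaults describe a small fission-yeast-like genome under rapid kinase
#' inhibition: slow advancing population at 400 bp/min, fast clearing
#' population at 1200 bp/min split at a 500 bp checkpoint, intergenic
#' background on the scale of a typical combined untreated library
#' (0.04 reads/bp), and Poisson count noise.
#'
#' @param n_chromosomes number of chromosomes.
#' @param chrom_length chromosome length (bp).
#' @param n_genes number of genes.
#' @param gene_length_range admissible gene length range (bp); lengths are
#'   drawn from a log-normal (median ~1.8 kb, the fission-yeast scale)
#'   truncated to this range.
#' @param v_slow,v_fast slow/fast elongation rates (bp/min), `v_fast > v_slow`.
#' @param checkpoint_distance checkpoint position downstream of the TSS (bp).
#' @param initiation_density expected gene-body reads/bp at steady state.
#' @param pause_peak_height pause peak height as a multiplier over body
#'   density (additive peak of `pause_peak_height * initiation_density`).
#' @param pause_peak_width pause peak width (bp) from the TSS.
#' @param background_density expected intergenic reads/bp.
#' @param termination_decay_bp e-folding length of the post-CPS decay (bp).
#' @param timepoints inhibition durations in minutes (must include 0; the
#'   0-min sample is the untreated reference).
#' @param n_replicates biological replicates per timepoint.
#' @param spike_reads_per_library spike-in mapped reads per library (scalar
#'   or vector recycled across samples).
#' @param v_ref pre-inhibition effective elongation rate (bp/min) used in
#'   the density-rate relation; an assumption, set to the ~2 kb/min scale
#'   reported for budding yeast.
#' @param front_offset advancing-wave position at t = 0 (bp; default 0, the
#'   wave starts at the TSS).
#' @param procap_peak_height expected PRO-cap reads at the true TSS base.
#' @param noise_model `"poisson"` or `"nb"` (negative binomial).
#' @param nb_dispersion NB dispersion alpha (var = mu + alpha mu^2) when
#'   `noise_model = "nb"`.
#' @param min_gene_gap minimum intergenic gap between placed genes (bp).
#' @param seed master seed; all per-sample streams derive from it.
#' @return a validated `SimulationConfig` list.
#' @export
simulation_config <- function(n_chromosomes = 2L, chrom_length = 300000L,
                              n_genes = 50L, gene_length_range = c(1000, 8000),
                              v_slow = 400, v_fast = 1200,
                              checkpoint_distance = 500,
                              initiation_density = 0.5,
                              pause_peak_height = 4, pause_peak_width = 50,
                              background_density = 0.04,
                              termination_decay_bp = 300,
                              timepoints = c(0, 0.5, 1, 2.5, 5),
                              n_replicates = 2L,
                              spike_reads_per_library = 1e5,
                              v_ref = 2000, front_offset = 0,
                              procap_peak_height = 100,
                              noise_model = c("poisson", "nb"),
                              nb_dispersion = 0.05,
                              min_gene_gap = 3500, seed = 1L) {
  cfg <- list(n_chromosomes = as.integer(n_chromosomes),
              chrom_length = as.numeric(chrom_length),
              n_genes = as.integer(n_genes),
              gene_length_range = as.numeric(gene_length_range),
              v_slow = v_slow, v_fast = v_fast,
              checkpoint_distance = checkpoint_distance,
              initiation_density = initiation_density,
              pause_peak_height = pause_peak_height,
              pause_peak_width = pause_peak_width,
              background_density = background_density,
              termination_decay_bp = termination_decay_bp,
              timepoints = sort(unique(as.numeric(timepoints))),
              n_replicates = as.integer(n_replicates),
              spike_reads_per_library = spike_reads_per_library,
              v_ref = v_ref, front_offset = front_offset,
              procap_peak_height = procap_peak_height,
              noise_model = match.arg(noise_model),
              nb_dispersion = nb_dispersion,
              min_gene_gap = min_gene_gap, seed = as.integer(seed))
  validate_config(cfg)
  structure(cfg, class = "SimulationConfig")
}

validate_config <- function(cfg) {
  if (!(cfg$v_fast > cfg$v_slow && cfg$v_slow > 0))
    stop("config invalid: require v_fast > v_slow > 0")
  if (cfg$checkpoint_distance < 0)
    stop("config invalid: checkpoint_distance must be >= 0")
  if (cfg$background_density >= cfg$initiation_density)
    stop("config invalid: background_density must be < initiation_density")
  if (any(cfg$gene_length_range <= 0) || cfg$chrom_length <= 0 ||
      cfg$pause_peak_width <= 0 || cfg$termination_decay_bp <= 0)
    stop("config invalid: all lengths must be positive")
  if (cfg$gene_length_range[2] < cfg$gene_length_range[1])
    stop("config invalid: gene_length_range must be increasing")
  if (cfg$n_genes < 1L || cfg$n_chromosomes < 1L || cfg$n_replicates < 1L)
    stop("config invalid: counts must be positive")
  invisible(cfg)
}

decay_extent <- function(cfg) round(5 * cfg$termination_decay_bp)

#' Generate a toy genome and gene set
#'
#' Genes are placed without overlap, separated by at least `min_gene_gap`
#' (leaving room for upstream windows and post-CPS termination zones), with
#' random strands. If the configured length range allows, at least 10% of
#' genes are at least 6 kb so long-gene analyses are exercisable.
#'
#' @param config a [simulation_config()].
#' @return list with `genes` (see [read_genes()] for columns) and
#'   `chrom_sizes` (named vector).
#' @export
make_toy_genome <- function(config) {
  validate_config(config)
  with_seed(derive_seed(config$seed, 1L), {
    lo <- config$gene_length_range[1]; hi <- config$gene_length_range[2]
    ## log-normal length body (median ~1.8 kb, matching the scale of
    ## fission-yeast transcription units), truncated to the configured
    ## range by inverse-CDF sampling
    meanlog <- log(1800); sdlog <- 0.6
    plo <- stats::plnorm(lo, meanlog, sdlog)
    phi <- stats::plnorm(hi, meanlog, sdlog)
    u <- stats::runif(config$n_genes, plo, phi)
    lens <- round(stats::qlnorm(u, meanlog, sdlog))
    if (hi >= 6000 && mean(lens >= 6000) < 0.10) {
      k <- ceiling(0.10 * config$n_genes)
      idx <- sample.int(config$n_genes, k)
      lens[idx] <- round(stats::runif(k, max(lo, 6000), hi))
    }
    strands <- sample(c("+", "-"), config$n_genes, replace = TRUE)
    chrom_names <- paste0("chrS", seq_len(config$n_chromosomes))
    chrom_sizes <- stats::setNames(rep(config$chrom_length, config$n_chromosomes),
                                   chrom_names)
    chrom_of <- rep_len(chrom_names, config$n_genes)
    cursor <- stats::setNames(rep(1000, config$n_chromosomes), chrom_names)
    start <- end <- numeric(config$n_genes)
    for (i in seq_len(config$n_genes)) {
      ch <- chrom_of[i]
      gap <- config$min_gene_gap + floor(stats::rexp(1, 1 / 250))
      s <- cursor[[ch]]
      e <- s + lens[i]
      if (e + config$min_gene_gap > config$chrom_length)
        stop("gene placement failure: gene ", i, " (", lens[i],
             " bp) does not fit on ", ch, "; config: n_genes=", config$n_genes,
             ", chrom_length=", config$chrom_length, ", n_chromosomes=",
             config$n_chromosomes, ", min_gene_gap=", config$min_gene_gap)
      start[i] <- s; end[i] <- e
      cursor[[ch]] <- e + gap
    }
    genes <- make_gene_table(sprintf("g%03d", seq_len(config$n_genes)),
                             chrom_of, start, end, strands)
    list(genes = genes, chrom_sizes = chrom_sizes)
  })
}

## Expected gene-attributable density (excluding global background) at
## gene-relative positions 0 .. L + decay_extent - 1. t = NULL means
## untreated; t = 0 gives an identical profile.
expected_gene_profile <- function(config, L, t = NULL) {
  init <- config$initiation_density
  x <- seq.int(0, L - 1)
  if (is.null(t) || t == 0) {
    dens <- rep(init, L)
  } else {
    b1 <- min(config$v_slow * t + config$front_offset, L)
    b2 <- min(config$checkpoint_distance + config$v_slow * t, L)
    b3 <- min(config$checkpoint_distance + config$v_fast * t, L)
    dens <- numeric(L)
    dens[x < b1] <- init * config$v_ref / config$v_slow
    dens[x >= b1 & x < b2] <- init
    dens[x >= b2 & x < b3] <- 0            # cleared zone: background only
    dens[x >= b3] <- init
  }
  amp <- dens[L]                            # body density at the CPS
  w <- min(config$pause_peak_width, L)
  dens[seq_len(w)] <- dens[seq_len(w)] + config$pause_peak_height * init
  ext <- decay_extent(config)
  c(dens, amp * exp(-seq_len(ext) / config$termination_decay_bp))
}

## Build per-chromosome, per-strand expected-count (lambda) fields for one
## sample, then draw counts.
simulate_track <- function(config, genome, t, sample_id, treatment,
                           spike_reads, stream) {
  genes <- genome$genes
  lam <- list(`+` = lapply(genome$chrom_sizes, function(n) rep(config$background_density, n)),
              `-` = lapply(genome$chrom_sizes, function(n) rep(config$background_density, n)))
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    prof <- expected_gene_profile(config, g$length, t)
    dir <- if (g$strand == "+") 1L else -1L
    pos <- g$tss + dir * seq.int(0L, length(prof) - 1L)
    ok <- pos >= 0 & pos < genome$chrom_sizes[[g$chrom]]
    idx <- pos[ok] + 1L
    lam[[g$strand]][[g$chrom]][idx] <- lam[[g$strand]][[g$chrom]][idx] + prof[ok]
  }
  with_seed(derive_seed(config$seed, stream), {
    for (s in c("+", "-")) for (ch in names(lam[[s]])) {
      mu <- lam[[s]][[ch]]
      lam[[s]][[ch]] <- if (config$noise_model == "poisson")
        stats::rpois(length(mu), mu)
      else
        stats::rnbinom(length(mu), mu = mu, size = 1 / config$nb_dispersion)
    }
    signal_track(lam$`+`, lam$`-`, genome$chrom_sizes, sample_id = sample_id,
                 timepoint = t, treatment = treatment, spike_reads = spike_reads)
  })
}

#' Simulate an untreated PRO-seq library
#'
#' Expected per-base counts are `background_density` everywhere, plus, on
#' each gene's strand: a gene-body plateau at `initiation_density`, an
#' additive pause peak at the TSS, and an exponential termination decay
#' past the CPS.
#'
#' @param config a [simulation_config()].
#' @param genome output of [make_toy_genome()].
#' @param replicate replicate index (selects the random stream).
#' @return a [signal_track()].
#' @export
simulate_untreated <- function(config, genome, replicate = 1L) {
  spike <- rep_len(config$spike_reads_per_library, replicate)[replicate]
  simulate_track(config, genome, t = NULL,
                 sample_id = paste0("untreated_rep", replicate),
                 treatment = "untreated", spike_reads = spike,
                 stream = 100L + replicate)
}

#' Simulate an inhibition time course
#'
#' Generates `n_replicates` libraries per timepoint. The 0-min sample is
#' the untreated reference and matches [simulate_untreated()] in
#' expectation; later timepoints follow the two-population piecewise
#' density (see the package vignette).
#'
#' @param config a [simulation_config()]; `timepoints` must include 0.
#' @param genome output of [make_toy_genome()].
#' @return list with `tracks` (list keyed by timepoint as character, each a
#'   list of replicate [signal_track()]s) and `ground_truth` (see
#'   [ground_truth_table()]).
#' @export
simulate_inhibition_timecourse <- function(config, genome) {
  if (!0 %in% config$timepoints)
    stop("timepoints must include 0 (the untreated reference)")
  spikes <- rep_len(config$spike_reads_per_library,
                    length(config$timepoints) * config$n_replicates)
  tracks <- list()
  k <- 0L
  for (ti in seq_along(config$timepoints)) {
    tp <- config$timepoints[ti]
    reps <- vector("list", config$n_replicates)
    for (r in seq_len(config$n_replicates)) {
      k <- k + 1L
      reps[[r]] <- simulate_track(
        config, genome, t = tp,
        sample_id = sprintf("t%g_rep%d", tp, r),
        treatment = if (tp == 0) "untreated" else "treated",
        spike_reads = spikes[k], stream = 1000L + 20L * ti + r)
    }
    tracks[[as.character(tp)]] <- reps
  }
  list(tracks = tracks, ground_truth = ground_truth_table(config, genome$genes))
}

#' Ground-truth wave positions for a simulated cohort
#'
#' The advancing-wave front is `min(v_slow t + front_offset, L)` and the
#' clearing-wave start `min(checkpoint + v_fast t, L)`; both are
#' non-decreasing in t.
#'
#' @param config a [simulation_config()].
#' @param genes gene table.
#' @return data.frame with gene_id, timepoint, true TSS, front_bp,
#'   clearing_start_bp.
#' @export
ground_truth_table <- function(config, genes) {
  tp <- config$timepoints
  df <- expand.grid(gene_id = genes$gene_id, timepoint = tp,
                    stringsAsFactors = FALSE)
  df <- merge(df, genes[, c("gene_id", "tss", "length")], by = "gene_id")
  df$front_bp <- pmin(config$v_slow * df$timepoint + config$front_offset,
                      df$length)
  df$clearing_start_bp <- pmin(config$checkpoint_distance +
                                 config$v_fast * df$timepoint, df$length)
  df <- df[order(df$gene_id, df$timepoint), ]
  rownames(df) <- NULL
  attr(df, "v_slow") <- config$v_slow
  attr(df, "v_fast") <- config$v_fast
  df
}

#' Simulate a PRO-cap library (nascent 5' ends)
#'
#' A sharp peak of expected height `procap_peak_height` at each gene's true
#' TSS base on the gene strand, over a uniform `background_density`.
#'
#' @inheritParams simulate_untreated
#' @return a [signal_track()].
#' @export
simulate_procap <- function(config, genome, replicate = 1L) {
  genes <- genome$genes
  lam <- list(`+` = lapply(genome$chrom_sizes, function(n) rep(config$background_density, n)),
              `-` = lapply(genome$chrom_sizes, function(n) rep(config$background_density, n)))
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    lam[[g$strand]][[g$chrom]][g$tss + 1L] <-
      lam[[g$strand]][[g$chrom]][g$tss + 1L] + config$procap_peak_height
  }
  with_seed(derive_seed(config$seed, 5000L + replicate), {
    for (s in c("+", "-")) for (ch in names(lam[[s]]))
      lam[[s]][[ch]] <- stats::rpois(length(lam[[s]][[ch]]), lam[[s]][[ch]])
    signal_track(lam$`+`, lam$`-`, genome$chrom_sizes,
                 sample_id = paste0("procap_rep", replicate),
                 treatment = "procap",
                 spike_reads = rep_len(config$spike_reads_per_library, 1L)[1L])
  })
}

#' Jitter annotated TSSs to exercise PRO-cap re-annotation
#'
#' Shifts each gene's annotated 5' end by a uniform offset in
#' `[-max_shift, max_shift]` along the strand (truth retained in column
#' `true_tss`), emulating imperfect existing annotations.
#'
#' @param genes gene table.
#' @param max_shift maximum shift (bp).
#' @param seed RNG seed.
#' @return gene table with perturbed `tss` and added `true_tss`.
#' @export
jitter_tss <- function(genes, max_shift = 30, seed = 1L) {
  with_seed(seed, {
    shift <- sample.int(2L * max_shift + 1L, nrow(genes), replace = TRUE) -
      max_shift - 1L
    out <- genes
    out$true_tss <- out$tss
    out$tss <- ifelse(out$strand == "+", out$tss + shift, out$tss - shift)
    out
  })
}

#' Write a complete simulated fixture set to disk
#'
#' Emits per-sample plus/minus bedGraph files, genes as BED6, a sample
#' sheet (sample id, timepoint, treatment, replicate, spike-in reads, file
#' paths), the ground-truth table, chromosome sizes, and the configuration
#' as YAML. Tracks round-trip losslessly through [read_bedgraph_pair()].
#'
#' @param config a [simulation_config()].
#' @param outdir writable output directory (created if missing).
#' @return list with `genome`, `sim`, `procap`, and the file `paths`.
#' @export
write_fixture_set <- function(config, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  genome <- make_toy_genome(config)
  sim <- simulate_inhibition_timecourse(config, genome)
  procap <- simulate_procap(config, genome)

  paths <- list(genes = file.path(outdir, "genes.bed"),
                sample_sheet = file.path(outdir, "sample_sheet.tsv"),
                ground_truth = file.path(outdir, "ground_truth.tsv"),
                chrom_sizes = file.path(outdir, "chrom_sizes.tsv"),
                config = file.path(outdir, "config.yaml"))
  write_genes_bed(genome$genes, paths$genes)
  write_tsv_file(data.frame(chrom = names(genome$chrom_sizes),
                            size = as.integer(genome$chrom_sizes)),
                 paths$chrom_sizes)
  write_tsv_file(sim$ground_truth, paths$ground_truth)
  yaml::write_yaml(unclass(config), paths$config)

  rows <- list()
  for (tp in names(sim$tracks)) for (r in seq_along(sim$tracks[[tp]])) {
    tr <- sim$tracks[[tp]][[r]]
    pf <- file.path(outdir, paste0(tr$sample_id, "_plus.bedgraph"))
    mf <- file.path(outdir, paste0(tr$sample_id, "_minus.bedgraph"))
    write_bedgraph(tr, pf, mf)
    rows[[length(rows) + 1L]] <- data.frame(
      sample_id = tr$sample_id, timepoint = tr$timepoint,
      treatment = tr$treatment, replicate = r,
      spike_reads = tr$spike_reads,
      plus_file = basename(pf), minus_file = basename(mf))
  }
  pf <- file.path(outdir, "procap_plus.bedgraph")
  mf <- file.path(outdir, "procap_minus.bedgraph")
  write_bedgraph(procap, pf, mf)
  rows[[length(rows) + 1L]] <- data.frame(
    sample_id = procap$sample_id, timepoint = NA_real_, treatment = "procap",
    replicate = 1L, spike_reads = procap$spike_reads,
    plus_file = basename(pf), minus_file = basename(mf))
  write_tsv_file(do.call(rbind, rows), paths$sample_sheet)
  list(genome = genome, sim = sim, procap = procap, paths = paths)
}
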