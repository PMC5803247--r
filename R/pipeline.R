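## Stage orchestration: simulate | filter | metrics | diff | waves |
## rates | all. Each stage reads its inputs from the output directory,
## writes TSV artifacts plus a JSON manifest (parameters, seed, package
## version, input/output checksums), and re-runs byte-identically on
## identical inputs. The function surface is the entry point; a thin
## Rscript wrapper ships in inst/scripts/polwaves.R.

#' Default pipeline configuration
#'
#' All stage parameters with their defaults: 50-bp wave windows with a
#' -500 bp upstream extension, promoter/early/late regions TSS..+100,
#' +150..+450 and CPS-300..CPS, p thresholds 0.01, 10-bp fold-change bins
#' over -250..+4000, per-timepoint wave initialization distances,
#' TSmooth 5, and a 10% x 1000-replicate bootstrap.
#'
#' @param seed master seed for the simulation stage and bootstrap.
#' @return nested configuration list.
#' @export
default_run_config <- function(seed = 1L) {
  list(seed = as.integer(seed),
       simulation = list(),             # overrides for simulation_config()
       filter = list(p_threshold = 0.01, search = 250, min_excess = 4),
       metrics = list(bin = 10, span = c(-250, 4000), eps = 0.5,
                      composite_window = c(-250, 1000),
                      termination_window = 1000, termination_f = 0.25),
       diff = list(threshold = 0.01, min_length = 800),
       waves = list(window = 50, upstream = 500, tsmooth = 5,
                    advancing_min_length = 4000, clearing_min_length = 6000,
                    clearing_max_timepoint = 2.5),
       rates = list(bootstrap_fraction = 0.10, bootstrap_reps = 1000L))
}

merge_config <- function(defaults, user) {
  if (is.null(user)) return(defaults)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  for (k in names(user)) {
    defaults[[k]] <- if (is.list(defaults[[k]]) && is.list(user[[k]]) &&
                         k != "simulation")
      merge_config(defaults[[k]], user[[k]]) else user[[k]]
  }
  defaults
}

write_manifest <- function(outdir, stage, params, inputs, outputs) {
  manifest <- list(stage = stage,
                   package_version = as.character(utils::packageVersion("polwaves")),
                   parameters = params,
                   inputs = as.list(tools::md5sum(inputs[file.exists(inputs)])),
                   outputs = as.list(tools::md5sum(outputs[file.exists(outputs)])))
  jsonlite::write_json(manifest, file.path(outdir, paste0("manifest_", stage, ".json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

require_artifact <- function(path, producing_stage) {
  if (!file.exists(path))
    stop("missing artifact '", basename(path), "'; run stage '",
         producing_stage, "' first")
  path
}

load_fixture <- function(outdir) {
  fx <- file.path(outdir, "fixtures")
  sheet <- read_tsv_file(require_artifact(file.path(fx, "sample_sheet.tsv"),
                                          "simulate"))
  cs_df <- read_tsv_file(file.path(fx, "chrom_sizes.tsv"))
  chrom_sizes <- stats::setNames(cs_df$size, cs_df$chrom)
  genes <- read_genes(file.path(fx, "genes.bed"))
  tracks <- list()
  for (i in seq_len(nrow(sheet))) {
    s <- sheet[i, ]
    tracks[[s$sample_id]] <- read_bedgraph_pair(
      file.path(fx, s$plus_file), file.path(fx, s$minus_file), chrom_sizes,
      sample_id = s$sample_id, timepoint = s$timepoint,
      treatment = s$treatment, spike_reads = s$spike_reads)
  }
  proseq <- tracks[sheet$treatment != "procap"]
  sheet_ps <- sheet[sheet$treatment != "procap", , drop = FALSE]
  combined <- lapply(split(sheet_ps$sample_id, sheet_ps$timepoint),
                     function(ids) combine_tracks(tracks[ids]))
  list(sheet = sheet, chrom_sizes = chrom_sizes, genes = genes,
       tracks = tracks, procap = tracks[[which(sheet$treatment == "procap")[1L]]],
       combined = combined,
       untreated = combined[["0"]],
       timepoints = sort(unique(sheet_ps$timepoint)))
}

load_filtered_genes <- function(outdir) {
  read_genes(require_artifact(file.path(outdir, "genes_filtered.bed"), "filter"))
}

stage_simulate <- function(config, outdir) {
  sim_cfg <- do.call(simulation_config,
                     c(config$simulation, list(seed = config$seed)))
  fx <- write_fixture_set(sim_cfg, file.path(outdir, "fixtures"))
  outs <- list.files(file.path(outdir, "fixtures"), full.names = TRUE)
  write_manifest(outdir, "simulate", unclass(sim_cfg), character(), outs)
  invisible(fx)
}

stage_filter <- function(config, outdir) {
  fx <- load_fixture(outdir)
  res <- filter_genes(fx$genes, fx$procap, fx$untreated, fx$chrom_sizes,
                      p_threshold = config$filter$p_threshold,
                      search = config$filter$search,
                      min_excess = config$filter$min_excess)
  report_path <- file.path(outdir, "filter_report.tsv")
  genes_path <- file.path(outdir, "genes_filtered.bed")
  write_tsv_file(res$report, report_path)
  write_genes_bed(res$genes, genes_path)
  write_manifest(outdir, "filter",
                 c(config$filter, lambda = res$lambda,
                   as.list(res$counts)),
                 file.path(outdir, "fixtures", "sample_sheet.tsv"),
                 c(report_path, genes_path))
  invisible(res)
}

stage_metrics <- function(config, outdir) {
  fx <- load_fixture(outdir)
  genes <- load_filtered_genes(outdir)
  tmax <- max(fx$timepoints)
  treated <- fx$combined[[as.character(tmax)]]
  untreated <- fx$untreated
  mc <- config$metrics
  pi_u <- pausing_index(untreated, genes)
  pi_t <- pausing_index(treated, genes)
  qu <- pi_quartiles(pi_u)
  cdf <- pi_cdf_compare(pi_t, pi_u)
  comp <- composite_profile(untreated, genes, "tss", mc$composite_window, mc$bin)
  fc <- foldchange_matrix(treated, untreated, genes, mc$span, mc$bin, mc$eps)
  fc_df <- data.frame(gene_id = rownames(fc), length = attr(fc, "gene_length"))
  fc_df <- cbind(fc_df, as.data.frame(fc, optional = TRUE))
  names(fc_df)[-(1:2)] <- paste0("bin_", attr(fc, "bin_start"))
  outs <- c(pi = file.path(outdir, "pi_table.tsv"),
            quart = file.path(outdir, "pi_quartiles.tsv"),
            comp = file.path(outdir, "composite_tss.tsv"),
            fc = file.path(outdir, "foldchange_matrix.tsv"))
  write_tsv_file(rbind(cbind(pi_u, condition = "untreated"),
                       cbind(pi_t, condition = "treated")), outs[["pi"]])
  write_tsv_file(qu, outs[["quart"]])
  write_tsv_file(comp, outs[["comp"]])
  write_tsv_file(fc_df, outs[["fc"]])
  write_manifest(outdir, "metrics",
                 c(mc, ks_stat = cdf$ks_stat, ks_p = cdf$ks_p,
                   pi_shift_log10 = cdf$shift),
                 file.path(outdir, "genes_filtered.bed"), unname(outs))
  invisible(list(cdf = cdf, quartiles = qu))
}

stage_diff <- function(config, outdir) {
  fx <- load_fixture(outdir)
  genes <- load_filtered_genes(outdir)
  tmax <- max(fx$timepoints)
  samples <- fx$sheet[fx$sheet$treatment != "procap" &
                        fx$sheet$timepoint %in% c(0, tmax), , drop = FALSE]
  rc <- count_regions(fx$tracks[samples$sample_id], genes)
  res <- differential_regions(rc, threshold = config$diff$threshold)
  calls <- classify_changes(res, genes, threshold = config$diff$threshold)
  outs <- c(counts = file.path(outdir, "region_counts.tsv"),
            results = file.path(outdir, "diff_results.tsv"),
            calls = file.path(outdir, "change_calls.tsv"))
  write_tsv_file(rc$counts, outs[["counts"]])
  write_tsv_file(res, outs[["results"]])
  write_tsv_file(calls, outs[["calls"]])
  write_manifest(outdir, "diff", config$diff,
                 file.path(outdir, "genes_filtered.bed"), unname(outs))
  invisible(list(results = res, calls = calls))
}

stage_waves <- function(config, outdir) {
  fx <- load_fixture(outdir)
  genes <- load_filtered_genes(outdir)
  wc <- config$waves
  treated <- fx$combined[setdiff(names(fx$combined), "0")]
  adv <- call_waves(treated, fx$untreated, genes, "advancing",
                    window = wc$window, upstream = wc$upstream,
                    min_length = wc$advancing_min_length)
  clr <- call_waves(treated, fx$untreated, genes, "clearing",
                    window = wc$window, tsmooth = wc$tsmooth,
                    min_length = wc$clearing_min_length,
                    max_timepoint = wc$clearing_max_timepoint)
  outs <- c(adv = file.path(outdir, "wave_calls_advancing.tsv"),
            clr = file.path(outdir, "wave_calls_clearing.tsv"))
  write_tsv_file(adv, outs[["adv"]])
  write_tsv_file(clr, outs[["clr"]])
  write_manifest(outdir, "waves", wc,
                 file.path(outdir, "genes_filtered.bed"), unname(outs))
  invisible(list(advancing = adv, clearing = clr))
}

stage_rates <- function(config, outdir) {
  adv <- read_tsv_file(require_artifact(
    file.path(outdir, "wave_calls_advancing.tsv"), "waves"))
  clr <- read_tsv_file(require_artifact(
    file.path(outdir, "wave_calls_clearing.tsv"), "waves"))
  rc <- config$rates
  summarize <- function(calls, tag, seed) {
    fs <- filter_wave_series(calls)
    if (length(fs$retained) < 2L)
      return(list(tag = tag, n_retained = length(fs$retained)))
    est <- fit_rate(fs$calls)
    boot <- if (length(fs$retained) >= 10L)
      bootstrap_rate(fs$calls, rc$bootstrap_fraction, rc$bootstrap_reps, seed)
    else NULL
    list(tag = tag, slope_bp_per_min = est$slope, intercept = est$intercept,
         r_squared = est$r_squared, n_genes = est$n_genes,
         per_gene_mean = est$per_gene_mean, per_gene_sd = est$per_gene_sd,
         bootstrap_ci = if (!is.null(boot)) unname(boot$ci) else NULL,
         est = est, boot = boot)
  }
  a <- summarize(adv, "advancing", derive_seed(config$seed, 71L))
  b <- summarize(clr, "clearing", derive_seed(config$seed, 72L))
  cmp <- if (!is.null(a$est) && !is.null(b$est))
    compare_rates(a$est, b$est, a$boot, b$boot) else NULL
  out <- file.path(outdir, "rates.json")
  strip <- function(x) x[setdiff(names(x), c("est", "boot"))]
  jsonlite::write_json(list(advancing = strip(a), clearing = strip(b),
                            comparison = cmp, settings = rc,
                            seed = config$seed),
                       out, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  write_manifest(outdir, "rates", rc,
                 c(file.path(outdir, "wave_calls_advancing.tsv"),
                   file.path(outdir, "wave_calls_clearing.tsv")), out)
  invisible(list(advancing = a, clearing = b, comparison = cmp))
}

#' Run pipeline stages
#'
#' Executes one stage (or `"all"`) against an output directory. Stages:
#' `simulate` (write a simulated fixture set), `filter` (TSS
#' re-annotation + activity + read-through filters), `metrics` (pausing
#' indices, composites, fold-change matrix), `diff` (region counts +
#' NB Wald tests), `waves` (advancing/clearing HMM calls), `rates`
#' (regression, bootstrap, comparison). Each stage writes a manifest with
#' its parameters and artifact checksums; reruns on identical inputs are
#' byte-identical.
#'
#' @param stage stage name or `"all"`.
#' @param config configuration list (see [default_run_config()]); partial
#'   lists are merged over the defaults, unknown keys rejected. May also
#'   be a path to a YAML file.
#' @param outdir output directory.
#' @return the last stage's (invisible) result.
#' @export
run_pipeline <- function(stage = "all", config = default_run_config(),
                         outdir = "polwaves_run") {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  config <- merge_config(default_run_config(), config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  stages <- c("simulate", "filter", "metrics", "diff", "waves", "rates")
  stage <- match.arg(stage, c("all", stages))
  todo <- if (stage == "all") stages else stage
  res <- NULL
  for (st in todo) {
    message("[polwaves] stage: ", st)
    res <- switch(st,
                  simulate = stage_simulate(config, outdir),
                  filter = stage_filter(config, outdir),
                  metrics = stage_metrics(config, outdir),
                  diff = stage_diff(config, outdir),
                  waves = stage_waves(config, outdir),
                  rates = stage_rates(config, outdir))
  }
  invisible(res)
}
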