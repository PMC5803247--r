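## Shared simulated fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

## mixed-length cohort exercising filters, metrics and differential tests
fx_mixed <- function() cached("mixed", function() {
  cfg <- simulation_config(n_genes = 24, gene_length_range = c(1000, 8000),
                           n_chromosomes = 2, chrom_length = 120000,
                           timepoints = c(0, 5), seed = 42)
  genome <- make_toy_genome(cfg)
  sim <- simulate_inhibition_timecourse(cfg, genome)
  combined <- lapply(sim$tracks, combine_tracks)
  list(cfg = cfg, genome = genome, sim = sim, combined = combined,
       untreated = combined[["0"]], treated = combined[["5"]],
       procap = simulate_procap(cfg, genome))
})

## long-gene cohort for wave calling
fx_long <- function() cached("long", function() {
  cfg <- simulation_config(n_genes = 10, gene_length_range = c(6000, 8000),
                           n_chromosomes = 1, chrom_length = 120000,
                           seed = 7)
  genome <- make_toy_genome(cfg)
  sim <- simulate_inhibition_timecourse(cfg, genome)
  combined <- lapply(sim$tracks, combine_tracks)
  list(cfg = cfg, genome = genome, sim = sim, combined = combined,
       untreated = combined[["0"]],
       treated = combined[setdiff(names(combined), "0")])
})

## a deterministic flat track: value `fill` everywhere on both strands
flat_track <- function(chrom_sizes, fill = 1, spike_reads = 1e5, ...) {
  mk <- function() lapply(chrom_sizes, function(n) rep(fill, n))
  signal_track(mk(), mk(), chrom_sizes, spike_reads = spike_reads, ...)
}

## a track with explicit per-base values on one chromosome/strand
sparse_track <- function(chrom_sizes, strand, chrom, pos, values,
                         spike_reads = 1e5, ...) {
  mk <- function() lapply(chrom_sizes, function(n) numeric(n))
  plus <- mk(); minus <- mk()
  tgt <- if (strand == "+") plus else minus
  tgt[[chrom]][pos + 1L] <- values
  if (strand == "+") plus <- tgt else minus <- tgt
  signal_track(plus, minus, chrom_sizes, spike_reads = spike_reads, ...)
}

## single-row gene record
one_gene <- function(chrom = "chr1", start = 1000, end = 3000, strand = "+",
                     gene_id = "gX") {
  polwaves:::make_gene_table(gene_id, chrom, start, end, strand)
}

## random emission parameters for decoder tests
random_emissions <- function(variant = c("advancing", "clearing")) {
  variant <- match.arg(variant)
  gam <- function() list(family = "gamma", shape = runif(1, 0.5, 8),
                         rate = runif(1, 0.1, 2))
  nor <- function() list(family = "normal", mean = runif(1, -2, 2),
                         sd = runif(1, 0.3, 3))
  if (variant == "advancing") list(nor(), gam(), gam())
  else list(gam(), gam(), gam())
}

random_hmm <- function(variant) {
  a11 <- runif(1, 0.5, 0.95); a22 <- runif(1, 0.5, 0.95)
  A <- matrix(c(a11, 1 - a11, 0,
                0, a22, 1 - a22,
                0, 0, 1), 3, 3, byrow = TRUE)
  list(emissions = random_emissions(variant), A = A)
}

## acceptance-scale cohort: 40 long genes under the full time course
fx_accept <- function() cached("accept", function() {
  cfg <- simulation_config(n_genes = 40, gene_length_range = c(6000, 8000),
                           n_chromosomes = 2, chrom_length = 250000,
                           seed = 101)
  genome <- make_toy_genome(cfg)
  sim <- simulate_inhibition_timecourse(cfg, genome)
  combined <- lapply(sim$tracks, combine_tracks)
  treated <- combined[setdiff(names(combined), "0")]
  adv <- call_waves(treated, combined[["0"]], genome$genes, "advancing")
  clr <- call_waves(treated, combined[["0"]], genome$genes, "clearing")
  list(cfg = cfg, genome = genome, sim = sim, combined = combined,
       untreated = combined[["0"]], treated = treated,
       adv = adv, clr = clr)
})
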