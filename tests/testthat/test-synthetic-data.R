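test_that("toy genome construction is deterministic, non-overlapping, and length-aware", {
  cfg <- simulation_config(n_genes = 50, seed = 1)
  g1 <- make_toy_genome(cfg)
  g2 <- make_toy_genome(cfg)
  expect_identical(g1, g2)
  expect_equal(nrow(g1$genes), 50)
  ## no overlap within a chromosome (any strand)
  for (ch in names(g1$chrom_sizes)) {
    g <- g1$genes[g1$genes$chrom == ch, ]
    g <- g[order(g$start), ]
    if (nrow(g) > 1) expect_true(all(g$start[-1] >= g$end[-nrow(g)]))
  }
  expect_gte(mean(g1$genes$length >= 6000), 0.10)

  cfg6 <- simulation_config(n_genes = 10, gene_length_range = c(6000, 8000),
                            chrom_length = 120000, seed = 2)
  expect_true(all(make_toy_genome(cfg6)$genes$length >= 6000))

  ## impossible placement is reported with config context
  bad <- simulation_config(n_genes = 100, chrom_length = 20000,
                           n_chromosomes = 1, seed = 1)
  expect_error(make_toy_genome(bad), "placement failure")
})

test_that("config invariants are enforced", {
  expect_error(simulation_config(v_slow = 1500, v_fast = 1200), "v_fast > v_slow")
  expect_error(simulation_config(checkpoint_distance = -5), "checkpoint")
  expect_error(simulation_config(background_density = 0.9,
                                 initiation_density = 0.5), "background")
  expect_error(simulation_config(gene_length_range = c(2000, 1000)),
               "increasing")
})

test_that("untreated simulation matches its stated expectation model", {
  ## total gene-body reads ~ initiation_density * length (Poisson)
  cfg <- simulation_config(n_genes = 4, gene_length_range = c(2000, 2000),
                           n_chromosomes = 1, chrom_length = 40000,
                           initiation_density = 0.5, pause_peak_height = 0,
                           background_density = 0.01, seed = 5)
  genome <- make_toy_genome(cfg)
  tr <- simulate_untreated(cfg, genome)
  for (i in seq_len(4)) {
    g <- genome$genes[i, ]
    tot <- region_signal(tr, g, 0, g$length, "tss", normalized = FALSE)$sum
    expect_lt(abs(tot - 1000), 4 * sqrt(1000))
  }
  ## pause_peak_height = 0: promoter density ~ body density, PI ~ 1
  pis <- pausing_index(tr, genome$genes)
  expect_true(all(abs(pis$pi - 1) < 0.5))

  ## background_density = 0 gives zero far-intergenic reads
  cfg0 <- simulation_config(n_genes = 2, gene_length_range = c(1500, 1500),
                            n_chromosomes = 1, chrom_length = 30000,
                            background_density = 0, seed = 5)
  gn0 <- make_toy_genome(cfg0)
  tr0 <- simulate_untreated(cfg0, gn0)
  far <- 25000:29999  # beyond all genes and decay zones
  expect_equal(sum(tr0$counts$`+`$chrS1[far + 1]) +
                 sum(tr0$counts$`-`$chrS1[far + 1]), 0)
})

test_that("pause peak raises promoter density by its stated multiple", {
  base <- list(n_genes = 4, gene_length_range = c(3000, 3000),
               n_chromosomes = 1, chrom_length = 40000, seed = 9)
  med_pi <- vapply(c(0, 2, 6), function(h) {
    cfg <- do.call(simulation_config, c(base, pause_peak_height = h))
    gn <- make_toy_genome(cfg)
    tr <- simulate_untreated(cfg, gn)
    stats::median(pausing_index(tr, gn$genes)$pi, na.rm = TRUE)
  }, 0)
  expect_true(all(diff(med_pi) > 0))
})

test_that("time-course expectation follows the two-population piecewise density", {
  cfg <- simulation_config(seed = 3)
  ## t = 0 equals the untreated profile exactly (in expectation)
  expect_equal(polwaves:::expected_gene_profile(cfg, 4000, 0),
               polwaves:::expected_gene_profile(cfg, 4000, NULL))
  ## closed-form segment boundaries at t = 2.5 (v_slow = 400)
  prof <- polwaves:::expected_gene_profile(cfg, 6000, 2.5)
  elev <- cfg$initiation_density * cfg$v_ref / cfg$v_slow
  expect_equal(prof[cfg$pause_peak_width + 1], elev)     # within wave, past pause
  expect_equal(prof[1000], elev)                          # end of elevated segment
  expect_equal(prof[1001], cfg$initiation_density)        # residue segment
  expect_equal(prof[1501], 0)                             # cleared zone
  expect_equal(prof[3500], 0)
  expect_equal(prof[3501], cfg$initiation_density)        # undisturbed 3'
  ## run-off limit: no cleared zone remains
  prof_late <- polwaves:::expected_gene_profile(cfg, 2000, 10)
  expect_true(all(prof_late[1:2000] >= cfg$initiation_density))

  ## Monte-Carlo mass conservation: simulated gene totals match the
  ## analytic integral of the piecewise density within 3 SE
  cfgS <- simulation_config(n_genes = 6, gene_length_range = c(6000, 6000),
                            n_chromosomes = 1, chrom_length = 80000,
                            timepoints = c(0, 1), n_replicates = 1, seed = 13)
  gnS <- make_toy_genome(cfgS)
  simS <- simulate_inhibition_timecourse(cfgS, gnS)
  tr1 <- simS$tracks[["1"]][[1]]
  ## analytic expectation at t = 1 for L = 6000 (computed segment-wise)
  exp_total <- 400 * cfgS$initiation_density * cfgS$v_ref / cfgS$v_slow +
    500 * cfgS$initiation_density +                    # residue [400, 900)
    0 +                                                # cleared [900, 1700)
    (6000 - 1700) * cfgS$initiation_density +          # undisturbed
    cfgS$pause_peak_width * cfgS$pause_peak_height * cfgS$initiation_density +
    6000 * cfgS$background_density
  for (i in seq_len(3)) {
    g <- gnS$genes[i, ]
    tot <- region_signal(tr1, g, 0, g$length, "tss", normalized = FALSE)$sum
    expect_lt(abs(tot - exp_total), 3 * sqrt(exp_total))
  }
})

test_that("ground truth distances follow the kinematics and are monotone in time", {
  fx <- fx_long()
  gt <- fx$sim$ground_truth
  cfg <- fx$cfg
  expect_equal(gt$front_bp,
               pmin(cfg$v_slow * gt$timepoint + cfg$front_offset, gt$length))
  expect_equal(gt$clearing_start_bp,
               pmin(cfg$checkpoint_distance + cfg$v_fast * gt$timepoint, gt$length))
  for (df in split(gt, gt$gene_id)) {
    df <- df[order(df$timepoint), ]
    expect_true(all(diff(df$front_bp) >= 0))
    expect_true(all(diff(df$clearing_start_bp) >= 0))
  }
})

test_that("PRO-cap peaks sit on the true TSS and are deterministic", {
  fx <- fx_mixed()
  pc <- fx$procap
  pc2 <- simulate_procap(fx$cfg, fx$genome)
  expect_identical(pc$counts, pc2$counts)
  hits <- vapply(seq_len(nrow(fx$genome$genes)), function(i) {
    g <- fx$genome$genes[i, ]
    v <- polwaves:::gene_signal_vector(pc, g, -250, 251, "tss", FALSE)
    which.max(v) == 251  # offset 0 = annotated (true) TSS
  }, TRUE)
  expect_true(all(hits))
})

test_that("fixture sets round-trip through the track readers", {
  cfg <- simulation_config(n_genes = 6, gene_length_range = c(1000, 4000),
                           n_chromosomes = 1, chrom_length = 40000,
                           timepoints = c(0, 1), n_replicates = 1, seed = 21)
  outdir <- withr::local_tempdir()
  fx <- write_fixture_set(cfg, outdir)
  sheet <- read.table(fx$paths$sample_sheet, header = TRUE, sep = "\t")
  expect_true(all(c("sample_id", "timepoint", "treatment", "spike_reads")
                  %in% names(sheet)))
  s <- sheet[sheet$sample_id == "t1_rep1", ]
  tr <- read_bedgraph_pair(file.path(outdir, s$plus_file),
                           file.path(outdir, s$minus_file),
                           fx$genome$chrom_sizes, spike_reads = s$spike_reads)
  expect_equal(tr$counts, fx$sim$tracks[["1"]][[1]]$counts)
  ## genes round-trip through BED6
  genes2 <- read_genes(fx$paths$genes)
  expect_equal(genes2[, c("gene_id", "chrom", "start", "end", "strand")],
               fx$genome$genes[, c("gene_id", "chrom", "start", "end", "strand")])
  ## spike reads of 1e5 give downstream normalization factor 1
  expect_equal(normalization_factor(s$spike_reads), 1)
})
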