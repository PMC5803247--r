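test_that("windowed differences are exact window sums of normalized signal", {
  cs <- c(chr1 = 20000L)
  g <- one_gene("chr1", 5000, 11000, "+")     # 6 kb
  u <- flat_track(cs, fill = 1, treatment = "untreated")
  t_same <- flat_track(cs, fill = 1, treatment = "treated")
  wd0 <- windowed_difference(t_same, u, g[1, ], window = 50, upstream = 500)
  expect_equal(length(wd0$values), 130)        # 10 upstream + 120 gene windows
  expect_true(all(wd0$values == 0))

  ## treated adds +1/bp over the first 500 gene bases: 10 windows of +50
  plus <- list(chr1 = rep(1, 20000)); plus$chr1[5001:5500] <- 2
  t_step <- signal_track(plus, list(chr1 = rep(1, 20000)), cs,
                         spike_reads = 1e5, treatment = "treated")
  wd <- windowed_difference(t_step, u, g[1, ], 50, 500)
  expect_equal(wd$values[11:20], rep(50, 10))
  expect_equal(wd$values[-(11:20)], rep(0, 120))

  expect_error(windowed_difference(t_step, u, one_gene("chr1", 5000, 5100)[1, ],
                                   50, 0), "too short")
  expect_error(windowed_difference(t_step, u, g[1, ], 50, 30), "multiple")
})

test_that("Viterbi decoding equals the exhaustive path-enumeration oracle", {
  set.seed(404)
  for (variant in c("advancing", "clearing")) {
    for (i in 1:100) {
      hmm <- random_hmm(variant)
      Tn <- sample(2:12, 1)
      x <- abs(rnorm(Tn, mean = 2, sd = 1.5)) + 0.05
      expect_identical(viterbi_decode(x, hmm), viterbi_bruteforce(x, hmm))
    }
  }
  ## single window decodes to the initial state
  hmm <- random_hmm("clearing")
  expect_identical(viterbi_decode(0.7, hmm), 1L)
  expect_identical(viterbi_bruteforce(0.7, hmm), 1L)
  expect_error(viterbi_bruteforce(rep(1, 15), hmm), "refusing")
})

test_that("tied paths resolve to the earliest-transition path in both decoders", {
  ## identical emissions for all states with a symmetric transition
  ## structure create exact ties; earliest transitions must win
  em <- list(family = "gamma", shape = 2, rate = 1)
  A <- matrix(c(0.5, 0.5, 0, 0, 0.5, 0.5, 0, 0, 1), 3, 3, byrow = TRUE)
  hmm <- list(emissions = list(em, em, em), A = A)
  x <- rep(1.7, 6)
  expect_identical(viterbi_decode(x, hmm), c(1L, 2L, 3L, 3L, 3L, 3L))
  expect_identical(viterbi_bruteforce(x, hmm), c(1L, 2L, 3L, 3L, 3L, 3L))
})

test_that("KL divergence matches closed forms and quadrature", {
  n1 <- list(family = "normal", mean = 0, sd = 1)
  n2 <- list(family = "normal", mean = 1, sd = 1)
  expect_equal(kl_divergence(n1, n1), 0)
  expect_equal(kl_divergence(n1, n2), 0.5)
  g1 <- list(family = "gamma", shape = 2, rate = 1)
  g2 <- list(family = "gamma", shape = 2, rate = 2)
  expect_equal(kl_divergence(g1, g1), 0)
  expect_equal(kl_divergence(g1, g2), kl_divergence(g1, g2, "quadrature"),
               tolerance = 1e-6)
  expect_equal(kl_divergence(n1, n2), kl_divergence(n1, n2, "quadrature"),
               tolerance = 1e-6)
  ## mixed families fall back to quadrature
  expect_gt(kl_divergence(g1, n2), 0)
})

test_that("EM increases the likelihood and flags degenerate inputs", {
  fx <- fx_long()
  g <- fx$genome$genes[1, ]
  for (tp in c("0.5", "2.5")) {
    wd <- windowed_difference(fx$combined[[tp]], fx$untreated, g, 50, 500)
    res <- fit_advancing_hmm(wd, default_init_distances("advancing")[[tp]])
    expect_true(res$fit$monotone)
    expect_true(res$fit$converged)
    wdc <- windowed_difference(fx$combined[[tp]], fx$untreated, g, 50, 0)
    resc <- fit_clearing_hmm(wdc, default_init_distances("clearing")[["1"]])
    expect_true(resc$fit$monotone)
  }
  ## all-zero difference: no credible wave, KL ~ 0, quality fail
  cs <- c(chr1 = 20000L)
  u <- flat_track(cs, fill = 1, treatment = "untreated")
  g0 <- one_gene("chr1", 5000, 11000, "+")[1, ]
  wd0 <- windowed_difference(u, u, g0, 50, 500)
  res0 <- fit_advancing_hmm(wd0, 1000)
  expect_false(res0$call$pass)
})

test_that("a clean step signal yields a front at the step boundary", {
  ## windows 1..10 upstream ~0; gene windows 1..20 high, 21..60 ~0
  cs <- c(chr1 = 20000L)
  u <- flat_track(cs, fill = 1, treatment = "untreated")
  g <- one_gene("chr1", 5000, 8000, "+")[1, ]   # 60 windows
  mk_step <- function(k) {
    plus <- list(chr1 = rep(1, 20000))
    plus$chr1[5001:(5000 + k * 50)] <- 3
    signal_track(plus, list(chr1 = rep(1, 20000)), cs, spike_reads = 1e5,
                 treatment = "treated")
  }
  wd <- windowed_difference(mk_step(20), u, g, 50, 500)
  res <- fit_advancing_hmm(wd, 1000)
  expect_equal(res$call$distance_bp, 1000)
  expect_true(res$call$pass)

  ## shift-equivariance: moving the step by k windows moves the call by k
  for (k in c(12, 28)) {
    wdk <- windowed_difference(mk_step(k), u, g, 50, 500)
    resk <- fit_advancing_hmm(wdk, 1000)
    expect_equal(resk$call$distance_bp, k * 50)
  }
})

test_that("a three-level profile yields a clearing boundary at the trough end", {
  cs <- c(chr1 = 20000L)
  u <- flat_track(cs, fill = 2, treatment = "untreated")
  ## treated: high over [0,1 kb), trough (cleared) over [1,3 kb),
  ## recovered moderate beyond
  plus <- list(chr1 = rep(2, 20000))
  plus$chr1[5001:6000] <- 6
  plus$chr1[6001:8000] <- 0.2
  tr <- signal_track(plus, list(chr1 = rep(2, 20000)), cs, spike_reads = 1e5,
                     treatment = "treated")
  g <- one_gene("chr1", 5000, 11500, "+")[1, ]   # 6.5 kb
  wd <- windowed_difference(tr, u, g, 50, 0)
  res <- fit_clearing_hmm(wd, 4000)
  expect_equal(res$call$distance_bp, 3000)
  expect_true(res$call$kl > 1)
  expect_true(res$call$pass)

  ## trough absent (two-level signal): states 2 and 3 collapse, KL <= 1
  plus2 <- list(chr1 = rep(2, 20000))
  plus2$chr1[5001:6000] <- 6
  tr2 <- signal_track(plus2, list(chr1 = rep(2, 20000)), cs,
                      spike_reads = 1e5, treatment = "treated")
  wd2 <- windowed_difference(tr2, u, g, 50, 0)
  res2 <- fit_clearing_hmm(wd2, 4000)
  expect_false(res2$call$pass)
})

test_that("TSmooth clamps outlying windows before clearing fits", {
  set.seed(12)
  x <- rnorm(100)
  x[40] <- 60  # a wild outlier
  wd <- structure(list(gene_id = "g", window = 50, upstream = 0,
                       n_upstream = 0L, values = x, timepoint = 1),
                  class = "WindowedDiff")
  res <- fit_clearing_hmm(wd, 2500, tsmooth = 5)
  ## with the clamp the fit runs and the outlier cannot dominate state 2
  expect_true(is.finite(res$call$kl))
  m <- mean(x); s <- sd(x)
  clamped <- m + pmin(pmax((x - m) / s, -5), 5) * s
  expect_lt(max(clamped), 60)
})

test_that("wave series filtering enforces quality at all timepoints and no recession", {
  mk <- function(id, d, pass = TRUE) data.frame(
    gene_id = id, timepoint = c(0.5, 1, 2.5, 5), type = "advancing",
    distance_bp = d, kl = 5, converged = TRUE, monotone_ll = TRUE,
    pass = pass)
  calls <- rbind(
    mk("ok", c(500, 800, 1500, 2600)),
    mk("recedes", c(500, 400, 900, 1800)),
    mk("flaky", c(500, 800, 1500, 2600), pass = c(TRUE, TRUE, FALSE, TRUE)))
  fs <- filter_wave_series(calls)
  expect_identical(fs$retained, "ok")
  expect_equal(nrow(fs$calls), 4)
  ## a gene missing one timepoint entirely is also dropped
  partial <- mk("partial", c(500, 800, 1500, 2600))[-2, ]
  fs2 <- filter_wave_series(rbind(mk("ok", c(0, 100, 200, 300)), partial))
  expect_identical(fs2$retained, "ok")
})

test_that("the simulated cohort is recovered near-perfectly by the full wave stage", {
  fx <- fx_long()
  adv <- call_waves(fx$treated, fx$untreated, fx$genome$genes, "advancing")
  fs <- filter_wave_series(adv)
  ## retention of at least 90% of simulated genes at default noise
  expect_gte(length(fs$retained), 0.9 * nrow(fx$genome$genes))
  ## mean absolute front error within one window of the kinematic truth
  gt <- fx$sim$ground_truth
  m <- merge(fs$calls, gt, by = c("gene_id", "timepoint"))
  expect_lte(mean(abs(m$distance_bp - m$front_bp)), 50)

  clr <- call_waves(fx$treated, fx$untreated, fx$genome$genes, "clearing")
  expect_true(all(clr$timepoint <= 2.5))
  fsc <- filter_wave_series(clr)
  mc <- merge(fsc$calls, gt, by = c("gene_id", "timepoint"))
  expect_lte(mean(abs(mc$distance_bp - mc$clearing_start_bp)), 100)
})
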