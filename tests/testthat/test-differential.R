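test_that("region counts have the stated widths, strandedness and length gate", {
  cs <- c(chr1 = 10000L)
  g <- one_gene("chr1", 2000, 4000, "+")        # 2 kb gene
  tracks <- list(u = flat_track(cs, fill = 1, treatment = "untreated"),
                 t = flat_track(cs, fill = 1, treatment = "treated"))
  rc <- count_regions(tracks, g)
  cnt <- rc$counts
  ## uniform 1 read/bp: promoter 100, early 300, late 300
  expect_equal(cnt$count[cnt$region == "promoter"], c(100L, 100L))
  expect_equal(cnt$count[cnt$region == "early"], c(300L, 300L))
  expect_equal(cnt$count[cnt$region == "late"], c(300L, 300L))
  ## genes under 800 nt are excluded with a reason
  g799 <- one_gene("chr1", 2000, 2799, "+", "tiny")
  rc2 <- count_regions(tracks, rbind(g, g799))
  expect_equal(rc2$excluded, "tiny")
  expect_false("tiny" %in% rc2$counts$gene_id)
  ## region off the chromosome end is a loud error naming the gene
  gend <- one_gene("chr1", 9500, 11000, "+", "edge")
  gend$end <- 10500; gend$cps <- 10499; gend$length <- 1000
  expect_error(suppressWarnings(count_regions(tracks, gend)), "edge")

  ## fixture counts match the generator means within 3 SE
  fx <- fx_mixed()
  genes <- fx$genome$genes
  long <- genes[genes$length >= 800, ][1:3, ]
  rcf <- count_regions(list(u = fx$untreated), long)
  d <- fx$cfg$initiation_density * fx$cfg$n_replicates +
    fx$cfg$background_density * fx$cfg$n_replicates
  for (i in 1:3) {
    early <- rcf$counts$count[rcf$counts$region == "early" &
                                rcf$counts$gene_id == long$gene_id[i]]
    expect_lt(abs(early - 300 * d), 3 * sqrt(300 * d))
  }
})

test_that("BH adjustment matches a hand step-up reference exactly", {
  ## independent step-up implementation
  bh_ref <- function(p) {
    n <- length(p); o <- order(p, decreasing = TRUE)
    ro <- order(o)
    pmin(1, cummin(n / (n:1) * p[o]))[ro]
  }
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  set.seed(8)
  for (i in 1:20) {
    p <- runif(sample(1:400, 1))
    expect_identical(bh_adjust(p), bh_ref(p))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(0.5, -0.1)), "\\[0, 1\\]")
})

test_that("NB Wald test behaves on degenerate and consistency-limit inputs", {
  sf <- rep(1, 6)
  cond <- rep(c("untreated", "treated"), each = 3)
  ## identical counts: log2FC 0, p near 1
  y <- matrix(rep(c(50L, 55L, 45L), 2), nrow = 1)
  r <- nb_wald_test(rbind(y, y + 10L, y * 2L), sf, cond)
  expect_equal(r$log2fc, rep(0, 3), tolerance = 1e-6)
  expect_true(all(r$p > 0.9))
  ## all-zero unit: ns with p = 1
  r0 <- nb_wald_test(matrix(0L, 1, 6), sf, cond)
  expect_equal(r0$p, 1); expect_equal(r0$log2fc, 0)
  ## exact doubling with many replicates converges to log2FC = 1
  set.seed(3)
  n <- 40
  base <- rpois(n, 200)
  y2 <- matrix(c(base, 2L * base), nrow = 1)
  r2 <- nb_wald_test(rbind(y2, y2), rep(1, 2 * n),
                     rep(c("untreated", "treated"), each = n))
  expect_equal(r2$log2fc, c(1, 1), tolerance = 0.02)
  expect_lt(r2$p[1], 1e-6)
})

test_that("test results are invariant to joint count/spike rescaling of one sample", {
  set.seed(5)
  G <- 50
  sf <- c(1, 1.2, 0.9, 1.1, 1.3, 0.8)
  cond <- rep(c("untreated", "treated"), each = 3)
  y <- matrix(rnbinom(G * 6, mu = 100, size = 20), G, 6)
  r1 <- nb_wald_test(y, sf, cond)
  y2 <- y; y2[, 3] <- y2[, 3] * 3L
  sf2 <- sf; sf2[3] <- sf2[3] * 3
  r2 <- nb_wald_test(y2, sf2, cond)
  ## invariance is exact in the normalized group means and near-exact in
  ## the likelihood-based quantities (the NB likelihood itself is not
  ## scale-free in the counts)
  expect_lt(max(abs(r1$log2fc - r2$log2fc)), 0.05)
  expect_lt(max(abs(r1$p - r2$p)), 0.03)
  expect_identical(ifelse(r1$p < 0.01, sign(r1$log2fc), 0),
                   ifelse(r2$p < 0.01, sign(r2$log2fc), 0))
})

test_that("null NB simulation is calibrated at the call threshold", {
  set.seed(17)
  G <- 5000
  sf <- c(1.0, 1.3, 0.8, 1.1, 0.9, 1.2)
  cond <- rep(c("untreated", "treated"), each = 3)
  q <- exp(runif(G, log(20), log(500)))
  y <- matrix(rnbinom(G * 6, mu = outer(q, sf), size = 1 / 0.05), G, 6)
  res <- nb_wald_test(y, sf, cond)
  ## raw type-I error ~ nominal at the 0.01 threshold
  expect_lt(abs(mean(res$p < 0.01) - 0.01), 3 * sqrt(0.01 * 0.99 / G))
  ## after BH, essentially nothing is called on a global null
  expect_lte(mean(bh_adjust(res$p) < 0.01), 0.011)
})

test_that("calls agree directionally with DESeq2 on a strong-effect simulation", {
  skip_if_not_installed("DESeq2")
  set.seed(31)
  G <- 300
  sf <- c(1, 1.1, 0.9, 1.2, 0.8, 1.05)
  cond <- rep(c("untreated", "treated"), each = 3)
  q <- exp(runif(G, log(30), log(300)))
  lfc <- sample(c(-2, 0, 2), G, replace = TRUE, prob = c(0.2, 0.6, 0.2))
  mu <- outer(q, sf) * 2^(lfc %o% c(0, 0, 0, 1, 1, 1))
  y <- matrix(rnbinom(G * 6, mu = mu, size = 1 / 0.05), G, 6)
  mine <- nb_wald_test(y, sf, cond)
  mine$padj <- bh_adjust(mine$p)
  dds <- DESeq2::DESeqDataSetFromMatrix(
    y, S4Vectors::DataFrame(condition = factor(cond, c("untreated", "treated"))),
    ~condition)
  DESeq2::sizeFactors(dds) <- sf
  dds <- DESeq2::DESeq(dds, quiet = TRUE)
  ref <- as.data.frame(DESeq2::results(dds))
  call_mine <- ifelse(mine$padj < 0.01, sign(mine$log2fc), 0)
  call_ref <- ifelse(!is.na(ref$padj) & ref$padj < 0.01, sign(ref$log2FoldChange), 0)
  ## directional agreement on the vast majority of units
  expect_gt(mean(call_mine == call_ref), 0.9)
  ## and near-perfect recovery of the planted signs among confident calls
  expect_gt(mean(call_mine[lfc != 0] == sign(lfc[lfc != 0])), 0.9)
})

test_that("change classification is length-ordered, quartiled and order-stable", {
  fx <- fx_mixed()
  genes <- fx$genome$genes
  tracks <- c(stats::setNames(fx$sim$tracks[["0"]],
                              sapply(fx$sim$tracks[["0"]], `[[`, "sample_id")),
              stats::setNames(fx$sim$tracks[["5"]],
                              sapply(fx$sim$tracks[["5"]], `[[`, "sample_id")))
  rc <- count_regions(tracks, genes)
  res <- differential_regions(rc)
  calls <- classify_changes(res, genes)
  expect_true(!is.unsorted(calls$length))
  expect_true(all(calls$length_quartile %in% 1:4))
  ## shuffled gene order gives the identical matrix
  rc2 <- count_regions(tracks, genes[sample.int(nrow(genes)), ])
  calls2 <- classify_changes(differential_regions(rc2), genes)
  expect_identical(calls, calls2)
  ## 5-min inhibition signatures: early region goes up almost everywhere,
  ## late-region decreases concentrate in the longest quartile
  expect_gt(mean(calls$early == "up"), 0.6)
  late_down_long <- mean(calls$late[calls$length_quartile == 4] == "down")
  late_down_short <- mean(calls$late[calls$length_quartile == 1] == "down")
  expect_gt(late_down_long, late_down_short)
})
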