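## Elongation-rate estimation from wave-call series: pooled ordinary
## least squares of distance on time (the headline rate), a bootstrap
## over genes, and a conservative gene-by-gene slope distribution.

#' Pooled elongation-rate estimate
#'
#' Ordinary least squares of wave distance (bp) on time (min), pooled
#' over all gene x timepoint calls, intercept included. The slope is the
#' elongation rate in bp/min. Per-gene slopes (genes with >= 2
#' timepoints) are attached for variance reporting.
#'
#' @param calls wave-call data.frame (typically the `calls` element of
#'   [filter_wave_series()]).
#' @return list of class `RateEstimate`: `slope` (bp/min), `intercept`,
#'   `r_squared`, `n_points`, `n_genes`, `per_gene` (data.frame gene_id,
#'   slope), `per_gene_mean`, `per_gene_sd`.
#' @export
fit_rate <- function(calls) {
  calls <- calls[!is.na(calls$distance_bp), , drop = FALSE]
  if (length(unique(calls$timepoint)) < 2L)
    stop("need calls at >= 2 distinct timepoints to fit a rate")
  fit <- stats::lm(distance_bp ~ timepoint, data = calls)
  pg <- per_gene_rates(calls)
  ## noise-free cohorts fit exactly; the perfect-fit warning is expected
  r2 <- suppressWarnings(summary(fit)$r.squared)
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 r_squared = r2,
                 n_points = nrow(calls),
                 n_genes = length(unique(calls$gene_id)),
                 per_gene = pg$per_gene,
                 per_gene_mean = pg$mean, per_gene_sd = pg$sd),
            class = "RateEstimate")
}

#' @export
print.RateEstimate <- function(x, ...) {
  cat(sprintf("RateEstimate: %.1f bp/min (intercept %.0f bp, r2 %.3f, %d genes, %d points)\n",
              x$slope, x$intercept, x$r_squared, x$n_genes, x$n_points))
  invisible(x)
}

#' Bootstrap distribution of the mean rate
#'
#' Each replicate samples `ceiling(fraction * n)` genes with replacement
#' (default 10% of called genes), refits the pooled regression on their
#' calls, and records the slope; repeated `reps` times (default 1000).
#'
#' @param calls wave-call data.frame.
#' @param fraction fraction of genes per replicate (default 0.10).
#' @param reps bootstrap replicates (default 1000).
#' @param seed RNG seed.
#' @return list with `slopes` (length `reps`), `ci` (2.5/50/97.5
#'   percentiles), `fraction`, `reps`, `seed`.
#' @export
bootstrap_rate <- function(calls, fraction = 0.10, reps = 1000L, seed = 1L) {
  genes <- unique(calls$gene_id)
  if (length(genes) < 10L) stop("need >= 10 genes to bootstrap, got ",
                                length(genes))
  m <- ceiling(fraction * length(genes))
  if (m < 2L) stop("fraction yields fewer than 2 genes per replicate")
  by_gene <- split(calls, calls$gene_id)
  slopes <- with_seed(seed, vapply(seq_len(reps), function(r) {
    pick <- sample(genes, m, replace = TRUE)
    df <- do.call(rbind, by_gene[pick])   # duplicates contribute repeatedly
    stats::coef(stats::lm(distance_bp ~ timepoint, data = df))[2L]
  }, 0))
  list(slopes = unname(slopes),
       ci = stats::quantile(slopes, c(0.025, 0.5, 0.975), names = TRUE),
       fraction = fraction, reps = reps, seed = seed)
}

#' Per-gene rate distribution
#'
#' OLS slope per gene over its own timepoints (genes with fewer than two
#' calls are skipped with a count), summarizing the gene-by-gene spread
#' of rates.
#'
#' @param calls wave-call data.frame.
#' @return list with `per_gene` (gene_id, slope, n), `mean`, `sd`,
#'   `n_skipped`.
#' @export
per_gene_rates <- function(calls) {
  by_gene <- split(calls[!is.na(calls$distance_bp), , drop = FALSE],
                   calls$gene_id[!is.na(calls$distance_bp)])
  rows <- lapply(names(by_gene), function(g) {
    df <- by_gene[[g]]
    if (length(unique(df$timepoint)) < 2L) return(NULL)
    data.frame(gene_id = g,
               slope = unname(stats::coef(
                 stats::lm(distance_bp ~ timepoint, data = df))[2L]),
               n = nrow(df))
  })
  skipped <- sum(vapply(rows, is.null, TRUE))
  per_gene <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(per_gene))
    per_gene <- data.frame(gene_id = character(), slope = numeric(),
                           n = integer())
  list(per_gene = per_gene,
       mean = if (nrow(per_gene)) mean(per_gene$slope) else NA_real_,
       sd = if (nrow(per_gene) > 1) stats::sd(per_gene$slope) else NA_real_,
       n_skipped = skipped)
}

#' Compare two rate estimates
#'
#' Difference is reported as second minus first. Two procedures: a Welch
#' t test on the per-gene slope distributions, and (when bootstrap
#' distributions are supplied) the overlap of bootstrap slope
#' distributions as the two-sided percentile of zero in the difference
#' distribution.
#'
#' @param a,b `RateEstimate` objects (e.g. advancing and clearing).
#' @param boot_a,boot_b optional [bootstrap_rate()] outputs.
#' @return list with `difference` (b - a pooled slopes), `welch_p`,
#'   `welch_t`, and, if bootstraps given, `bootstrap_p`.
#' @export
compare_rates <- function(a, b, boot_a = NULL, boot_b = NULL) {
  if (is.null(a$per_gene) || is.null(b$per_gene) ||
      nrow(a$per_gene) == 0L || nrow(b$per_gene) == 0L)
    stop("both estimates need per-gene slopes")
  tt <- stats::t.test(b$per_gene$slope, a$per_gene$slope)
  out <- list(difference = b$slope - a$slope,
              welch_t = unname(tt$statistic), welch_p = tt$p.value)
  if (!is.null(boot_a) && !is.null(boot_b)) {
    nd <- min(length(boot_a$slopes), length(boot_b$slopes))
    d <- boot_b$slopes[seq_len(nd)] - boot_a$slopes[seq_len(nd)]
    frac <- mean(d < 0)
    out$bootstrap_p <- 2 * min(frac, 1 - frac)
    out$bootstrap_diff_ci <- stats::quantile(d, c(0.025, 0.975))
  }
  out
}
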