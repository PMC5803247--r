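## Pausing indices, quartiles and CDFs, composite anchored profiles,
## fold-change matrices, and post-CPS termination metrics.

#' Pausing index per gene
#'
#' PI = promoter-proximal density (TSS to +100) over gene-body density
#' (+100 to CPS), both spike-in normalized. Genes shorter than 200 bp, or
#' with zero body density, are excluded with a reason.
#'
#' @param track a [signal_track()].
#' @param genes gene table (filtered genes).
#' @return data.frame with gene_id, promoter_density, body_density, pi,
#'   excluded, reason.
#' @export
pausing_index <- function(track, genes) {
  res <- lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    if (g$length < 200)
      return(data.frame(gene_id = g$gene_id, promoter_density = NA_real_,
                        body_density = NA_real_, pi = NA_real_,
                        excluded = TRUE, reason = "shorter than 200 bp"))
    prom <- region_signal(track, g, 0, 100, "tss")$density
    body <- region_signal(track, g, 100, g$length, "tss")$density
    if (body <= 0)
      return(data.frame(gene_id = g$gene_id, promoter_density = prom,
                        body_density = body, pi = NA_real_,
                        excluded = TRUE, reason = "zero body density"))
    data.frame(gene_id = g$gene_id, promoter_density = prom,
               body_density = body, pi = prom / body,
               excluded = FALSE, reason = "")
  })
  do.call(rbind, res)
}

#' Quartile labels by increasing pausing index
#'
#' Rank-based quartiles (1 = lowest PI); ties broken by gene id for
#' determinism; group sizes differ by at most one.
#'
#' @param records output of [pausing_index()] (excluded genes dropped).
#' @return the records with an added integer `quartile` column.
#' @export
pi_quartiles <- function(records) {
  records <- records[!records$excluded, , drop = FALSE]
  n <- nrow(records)
  if (n < 4L) stop("need at least 4 genes to form quartiles, got ", n)
  rank <- order(order(records$pi, records$gene_id))
  records$quartile <- floor((rank - 1) * 4 / n) + 1L
  records
}

#' Compare pausing-index CDFs between conditions
#'
#' Empirical CDFs of log10 PI on a shared grid, with a two-sample
#' Kolmogorov-Smirnov comparison. Non-positive PIs are excluded (count
#' reported).
#'
#' @param records_treated,records_untreated outputs of [pausing_index()].
#' @return list with `grid`, `cdf_treated`, `cdf_untreated`, `ks_stat`,
#'   `ks_p`, `n_excluded`, and `shift` (median log10 PI difference,
#'   treated minus untreated).
#' @export
pi_cdf_compare <- function(records_treated, records_untreated) {
  xt <- records_treated$pi[!records_treated$excluded]
  xu <- records_untreated$pi[!records_untreated$excluded]
  n_excl <- sum(xt <= 0, na.rm = TRUE) + sum(xu <= 0, na.rm = TRUE)
  lt <- log10(xt[xt > 0]); lu <- log10(xu[xu > 0])
  if (!length(lt) || !length(lu)) stop("no positive pausing indices to compare")
  grid <- sort(unique(c(lt, lu)))
  ks <- suppressWarnings(stats::ks.test(lt, lu))
  list(grid = grid,
       cdf_treated = stats::ecdf(lt)(grid),
       cdf_untreated = stats::ecdf(lu)(grid),
       ks_stat = unname(ks$statistic), ks_p = ks$p.value,
       n_excluded = n_excl,
       shift = stats::median(lt) - stats::median(lu))
}

bin_means <- function(v, bin) {
  nb <- length(v) %/% bin
  m <- matrix(v[seq_len(nb * bin)], nrow = bin)
  colMeans(m, na.rm = TRUE)
}

#' Composite (metagene) profile anchored at the TSS or CPS
#'
#' Normalized per-base signal is averaged within bins, then unweighted
#' across genes (each gene contributes equally). Multiple tracks are
#' averaged after normalization (replicate averaging).
#'
#' @param tracks a [signal_track()] or list of them.
#' @param genes gene table (non-empty).
#' @param anchor `"tss"` or `"cps"`.
#' @param window c(upstream, downstream) bounds in bp relative to the
#'   anchor (half-open at the downstream edge).
#' @param bin bin width in bp.
#' @return data.frame with bin_start (relative bp), bin_mid, mean_signal;
#'   attribute `n_genes`.
#' @export
composite_profile <- function(tracks, genes, anchor = c("tss", "cps"),
                              window = c(-250, 1000), bin = 10) {
  anchor <- match.arg(anchor)
  if (nrow(genes) == 0L) stop("empty gene set")
  if (inherits(tracks, "SignalTrack")) tracks <- list(tracks)
  width <- window[2] - window[1]
  nb <- width %/% bin
  acc <- matrix(0, nrow = length(tracks), ncol = nb)
  per_gene <- matrix(NA_real_, nrow = nrow(genes), ncol = nb)
  for (ti in seq_along(tracks)) {
    for (i in seq_len(nrow(genes))) {
      v <- gene_signal_vector(tracks[[ti]], genes[i, ], window[1], window[2],
                              anchor = anchor, normalized = TRUE)
      per_gene[i, ] <- bin_means(v, bin)
    }
    acc[ti, ] <- colMeans(per_gene, na.rm = TRUE)
  }
  starts <- window[1] + bin * (seq_len(nb) - 1)
  out <- data.frame(bin_start = starts, bin_mid = starts + bin / 2,
                    mean_signal = colMeans(acc))
  attr(out, "n_genes") <- nrow(genes)
  attr(out, "anchor") <- anchor
  out
}

#' Log2 fold-change matrix of treated over untreated signal
#'
#' Normalized signal is summed within fixed bins spanning a TSS-relative
#' window; values are epsilon-stabilized log2 ratios. Rows are genes
#' sorted by increasing length; bins past a gene's CPS are NA.
#'
#' @param treated,untreated [signal_track()]s.
#' @param genes filtered gene table.
#' @param window TSS-relative span (default -250..+4000 bp).
#' @param bin bin width (default 10 bp).
#' @param eps pseudo-signal per bin avoiding infinite ratios (default 0.5
#'   normalized reads).
#' @return numeric matrix (genes x bins) with rownames = gene ids,
#'   attributes `bin_start` and `gene_length`.
#' @export
foldchange_matrix <- function(treated, untreated, genes,
                              window = c(-250, 4000), bin = 10, eps = 0.5) {
  genes <- genes[order(genes$length, genes$gene_id), , drop = FALSE]
  nb <- (window[2] - window[1]) %/% bin
  starts <- window[1] + bin * (seq_len(nb) - 1)
  m <- matrix(NA_real_, nrow = nrow(genes), ncol = nb,
              dimnames = list(genes$gene_id, NULL))
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    vt <- gene_signal_vector(treated, g, window[1], window[2], "tss", TRUE)
    vu <- gene_signal_vector(untreated, g, window[1], window[2], "tss", TRUE)
    st <- bin_means(vt, bin) * bin       # per-bin sums
    su <- bin_means(vu, bin) * bin
    lfc <- log2((st + eps) / (su + eps))
    lfc[starts >= g$length] <- NA_real_  # past the CPS
    m[i, ] <- lfc
  }
  attr(m, "bin_start") <- starts
  attr(m, "gene_length") <- genes$length
  m
}

#' Post-CPS termination-zone metrics
#'
#' Builds a CPS-anchored composite of the region downstream of the CPS for
#' genes with sufficient clearance to the next gene, and measures the
#' termination-zone width: the distance from the CPS at which the
#' composite first falls below fraction `f` of its CPS-proximal level
#' (the first bin). Also reports the total post-CPS normalized signal.
#'
#' @param track a [signal_track()].
#' @param genes gene table (used both for profiles and clearance checks).
#' @param post_cps_window window downstream of the CPS (bp, default 1000).
#' @param f threshold fraction of the CPS-proximal level (default 0.25).
#' @param bin bin width (default 10 bp).
#' @param all_genes optional full gene table for clearance computation
#'   (defaults to `genes`).
#' @return list with `profile` (data.frame), `zone_width` (bp; the window
#'   width if the profile never crosses), `total_signal`, `n_genes`.
#' @export
termination_zone_metrics <- function(track, genes, post_cps_window = 1000,
                                     f = 0.25, bin = 10, all_genes = genes) {
  eligible <- vapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    others <- all_genes[all_genes$chrom == g$chrom &
                          all_genes$gene_id != g$gene_id, , drop = FALSE]
    if (g$strand == "+") {
      lim <- g$end + post_cps_window
      lim <= track$chrom_sizes[[g$chrom]] && !any(others$start < lim & others$end > g$end)
    } else {
      lim <- g$start - post_cps_window
      lim >= 0 && !any(others$end > lim & others$start < g$start)
    }
  }, TRUE)
  if (!any(eligible)) stop("no genes with ", post_cps_window,
                           " bp post-CPS clearance")
  gsub <- genes[eligible, , drop = FALSE]
  prof <- composite_profile(track, gsub, anchor = "cps",
                            window = c(1, post_cps_window + 1), bin = bin)
  base <- prof$mean_signal[1L]
  below <- which(prof$mean_signal < f * base)
  zone_width <- if (base <= 0) 0 else if (length(below))
    prof$bin_start[below[1L]] else post_cps_window
  total <- sum(vapply(seq_len(nrow(gsub)), function(i)
    region_signal(track, gsub[i, ], 1, post_cps_window + 1, "cps")$sum, 0))
  list(profile = prof, zone_width = zone_width, total_signal = total,
       n_genes = nrow(gsub))
}
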