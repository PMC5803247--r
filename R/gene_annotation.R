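## Gene set construction: TSS re-annotation from PRO-cap 5' end signal,
## a Poisson activity filter against intergenic background density, and an
## upstream read-through filter.

#' Derive intergenic background regions
#'
#' The complement of all gene bodies, excluding a buffer on each side of
#' every gene, per chromosome. The buffer on the CPS side is larger so
#' that post-CPS termination zones (which carry gene-derived signal well
#' past the annotated 3' end) do not contaminate the background. Used
#' both for the Poisson activity filter and, scaled to the PRO-cap
#' library, as the PRO-cap background.
#'
#' @param genes gene table.
#' @param chrom_sizes named vector of chromosome lengths.
#' @param buffer bp excluded upstream of the TSS (default 500).
#' @param downstream_buffer bp excluded past the CPS (default 2000,
#'   covering typical termination-zone extents).
#' @return data.frame with chrom, start, end (0-based half-open).
#' @export
auto_background_regions <- function(genes, chrom_sizes, buffer = 500,
                                    downstream_buffer = 2000) {
  out <- list()
  for (ch in names(chrom_sizes)) {
    g <- genes[genes$chrom == ch, , drop = FALSE]
    if (nrow(g) == 0L) {
      out[[ch]] <- data.frame(chrom = ch, start = 0, end = chrom_sizes[[ch]])
      next
    }
    up <- ifelse(g$strand == "+", buffer, downstream_buffer)
    dn <- ifelse(g$strand == "+", downstream_buffer, buffer)
    ir <- IRanges::reduce(IRanges::IRanges(
      start = pmax(g$start - up, 0) + 1, end = pmin(g$end + dn, chrom_sizes[[ch]])))
    gaps <- IRanges::gaps(ir, start = 1, end = chrom_sizes[[ch]])
    if (length(gaps))
      out[[ch]] <- data.frame(chrom = ch, start = IRanges::start(gaps) - 1,
                              end = IRanges::end(gaps))
  }
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}

region_raw_total <- function(track, regions) {
  tot <- 0
  for (i in seq_len(nrow(regions))) {
    ch <- regions$chrom[i]
    idx <- seq.int(regions$start[i] + 1L, regions$end[i])
    tot <- tot + sum(track$counts$`+`[[ch]][idx]) + sum(track$counts$`-`[[ch]][idx])
  }
  tot
}

#' Estimate intergenic background density
#'
#' lambda = total raw reads (both strands) within the background regions
#' divided by total region width in bp, per library.
#'
#' @param track a [signal_track()].
#' @param regions background regions (chrom/start/end data.frame).
#' @return lambda in reads/bp (raw, unnormalized).
#' @export
estimate_background <- function(track, regions) {
  width <- sum(regions$end - regions$start)
  if (width <= 0) stop("background region set has zero width")
  if (width < 10000)
    stop("background regions total ", width, " bp; at least 10 kb required")
  region_raw_total(track, regions) / width
}

#' Poisson activity test for one or more genes
#'
#' A gene is active if its gene-body read count is significantly higher
#' than expected from the intergenic background: the p-value is the upper
#' tail P(X >= k) of a Poisson with mean lambda * L for observed body
#' count k over body length L (observed TSS through CPS, promoter
#' included). Active iff p < p_threshold.
#'
#' @param track untreated [signal_track()] (raw counts are used, matching
#'   the raw-scale lambda).
#' @param genes gene table (one or more rows).
#' @param lambda background density in reads/bp (> 0).
#' @param p_threshold significance threshold (default 0.01).
#' @return data.frame with gene_id, body_count, p_value, active.
#' @export
activity_test <- function(track, genes, lambda, p_threshold = 0.01) {
  if (!is.numeric(lambda) || lambda <= 0)
    stop("lambda must be > 0 (zero background density cannot be tested)")
  k <- vapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    region_signal(track, g, 0, g$length, anchor = "tss", normalized = FALSE)$sum
  }, 0)
  p <- stats::ppois(k - 1, lambda * genes$length, lower.tail = FALSE)
  data.frame(gene_id = genes$gene_id, body_count = k, p_value = p,
             active = p < p_threshold)
}

#' Re-annotate TSSs from PRO-cap signal
#'
#' For each gene, the observed TSS is the position with the maximum
#' background-subtracted PRO-cap signal within +/- `search` bp of the
#' annotated TSS (strand-relative window). The selected base must carry
#' more than `min_excess` reads over background after accounting for
#' library size (raw excess divided by the PRO-cap normalization factor);
#' otherwise the gene has no observed TSS. Argmax ties are broken toward
#' the position nearest the existing annotation, then upstream.
#'
#' @param procap_track PRO-cap 5' end [signal_track()].
#' @param genes gene table (annotated TSSs in column `tss`).
#' @param background PRO-cap background density in raw reads/bp (e.g. from
#'   [estimate_background()] on the PRO-cap track).
#' @param search half-width of the search window (bp, default 250).
#' @param min_excess minimum library-size-scaled excess (strict >,
#'   default 4).
#' @return gene table with `tss`/`cps`/`length` updated to the observed
#'   TSS where found, plus columns `has_observed_tss` and `tss_shift`;
#'   genes without an observed TSS keep their annotation and are flagged.
#' @export
reannotate_tss <- function(procap_track, genes, background, search = 250,
                           min_excess = 4) {
  nf <- procap_track$normalization_factor
  if (is.na(nf)) stop("PRO-cap track has no spike-in reads; cannot scale excess")
  out <- genes
  out$has_observed_tss <- FALSE
  out$tss_shift <- NA_real_
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    v <- suppressWarnings(
      gene_signal_vector(procap_track, g, -search, search + 1L,
                         anchor = "tss", normalized = FALSE))
    if (anyNA(v))
      warning("TSS search window clipped at chromosome end for ", g$gene_id)
    excess <- v - background
    best <- max(excess, na.rm = TRUE)
    if (!is.finite(best) || best / nf <= min_excess) next
    cand <- which(excess == best)            # offsets (index) into -search..+search
    rel <- cand - (search + 1L)              # strand-relative shift from annotation
    ## nearest the original annotation, then upstream (more negative rel)
    cand_rel <- rel[order(abs(rel), rel)][1L]
    new_tss <- if (g$strand == "+") g$tss + cand_rel else g$tss - cand_rel
    out$tss[i] <- new_tss
    out$has_observed_tss[i] <- TRUE
    out$tss_shift[i] <- cand_rel
  }
  ## re-derive gene extent from the observed TSS
  out$start <- ifelse(out$strand == "+", out$tss, out$start)
  out$end <- ifelse(out$strand == "+", out$end, out$tss + 1)
  out$length <- out$end - out$start
  out
}

#' Upstream read-through filter
#'
#' Compares normalized PRO-seq signal immediately upstream of the observed
#' TSS (-300 to TSS) with signal in the early gene body (+250 to +550). A
#' gene passes only if the downstream sum strictly exceeds the upstream
#' sum ("more downstream" is strict; ties fail).
#'
#' @param track untreated [signal_track()].
#' @param genes gene table.
#' @return data.frame with gene_id, upstream_sum, downstream_sum,
#'   readthrough_pass.
#' @export
readthrough_filter <- function(track, genes) {
  res <- lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    up <- suppressWarnings(region_signal(track, g, -300, 0, "tss"))
    dn <- suppressWarnings(region_signal(track, g, 250, 550, "tss"))
    data.frame(gene_id = g$gene_id, upstream_sum = up$sum,
               downstream_sum = dn$sum,
               readthrough_pass = dn$sum > up$sum)
  })
  do.call(rbind, res)
}

#' Full gene-set filter pipeline
#'
#' Applies, in order: PRO-cap TSS re-annotation (genes must have an
#' observed TSS), the Poisson activity filter on the untreated track, and
#' the upstream read-through filter. The result is independent of the
#' gene input order.
#'
#' @param genes annotated gene table.
#' @param procap_track PRO-cap [signal_track()].
#' @param untreated_track untreated PRO-seq [signal_track()].
#' @param chrom_sizes named chromosome sizes (for auto background regions).
#' @param background_regions optional background regions; derived as the
#'   buffered intergenic complement when `NULL`.
#' @param p_threshold activity threshold (default 0.01).
#' @param search,min_excess see [reannotate_tss()].
#' @return list with `report` (per-gene FilterReport data.frame: flags,
#'   p-values, sums, `final_keep`), `genes` (re-annotated genes passing all
#'   filters), `lambda` (background density), and per-stage `counts`.
#' @export
filter_genes <- function(genes, procap_track, untreated_track, chrom_sizes,
                         background_regions = NULL, p_threshold = 0.01,
                         search = 250, min_excess = 4) {
  genes <- genes[order(genes$chrom, genes$start, genes$gene_id), , drop = FALSE]
  if (is.null(background_regions))
    background_regions <- auto_background_regions(genes, chrom_sizes)
  lam_procap <- estimate_background(procap_track, background_regions)
  lam <- estimate_background(untreated_track, background_regions)
  rea <- reannotate_tss(procap_track, genes, lam_procap,
                        search = search, min_excess = min_excess)
  act <- activity_test(untreated_track, rea, lam, p_threshold)
  rt <- readthrough_filter(untreated_track, rea)
  report <- data.frame(gene_id = rea$gene_id,
                       has_observed_tss = rea$has_observed_tss,
                       tss_shift = rea$tss_shift,
                       body_count = act$body_count,
                       activity_p = act$p_value,
                       active = act$active,
                       upstream_sum = rt$upstream_sum,
                       downstream_sum = rt$downstream_sum,
                       readthrough_pass = rt$readthrough_pass)
  report$final_keep <- report$has_observed_tss & report$active &
    report$readthrough_pass
  kept <- rea[report$final_keep, , drop = FALSE]
  rownames(kept) <- NULL
  list(report = report, genes = kept, lambda = lam,
       counts = c(input = nrow(genes),
                  observed_tss = sum(report$has_observed_tss),
                  active = sum(report$has_observed_tss & report$active),
                  readthrough = sum(report$final_keep)))
}
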