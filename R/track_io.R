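## Strand-specific single-base 3' end signal tracks.
##
## A SignalTrack stores, per chromosome and strand, the number of read 3'
## ends (the last incorporated base) at every position, together with the
## library metadata needed for spike-in normalization. Coordinates are
## 0-based half-open throughout (the bedGraph convention); R vector index
## i holds position i-1.

#' Construct a SignalTrack
#'
#' @param plus,minus named lists (one numeric vector per chromosome) of
#'   non-negative per-base counts for the plus and minus strand. Vector
#'   lengths must equal the chromosome sizes.
#' @param chrom_sizes named integer vector of chromosome lengths (bp).
#' @param sample_id sample identifier.
#' @param timepoint treatment duration in minutes (`NA` if not applicable).
#' @param treatment treatment label, e.g. `"treated"` / `"untreated"`.
#' @param spike_reads total spike-in mapped reads for the library; used to
#'   compute the normalization factor (spike reads / 1e5).
#' @return an object of class `SignalTrack`.
#' @export
signal_track <- function(plus, minus, chrom_sizes, sample_id = "sample",
                         timepoint = NA_real_, treatment = NA_character_,
                         spike_reads = NA_real_) {
  chrom_sizes <- stats::setNames(as.numeric(chrom_sizes), names(chrom_sizes))
  if (is.null(names(chrom_sizes)) || any(!nzchar(names(chrom_sizes))))
    stop("chrom_sizes must be a named vector")
  for (strand in list(plus = plus, minus = minus)) {
    if (!setequal(names(strand), names(chrom_sizes)))
      stop("strand chromosome set inconsistent with chrom_sizes")
  }
  for (ch in names(chrom_sizes)) {
    if (length(plus[[ch]]) != chrom_sizes[[ch]] ||
        length(minus[[ch]]) != chrom_sizes[[ch]])
      stop("counts vector length does not match chrom_sizes for ", ch)
    if (any(plus[[ch]] < 0) || any(minus[[ch]] < 0))
      stop("negative counts in track on ", ch,
           " (minus-strand values are stored as magnitudes)")
  }
  nf <- if (is.na(spike_reads)) NA_real_ else normalization_factor(spike_reads)
  structure(list(counts = list(`+` = plus[names(chrom_sizes)],
                               `-` = minus[names(chrom_sizes)]),
                 chrom_sizes = chrom_sizes,
                 sample_id = sample_id,
                 timepoint = timepoint,
                 treatment = treatment,
                 spike_reads = spike_reads,
                 normalization_factor = nf),
            class = "SignalTrack")
}

#' @export
print.SignalTrack <- function(x, ...) {
  tot <- sum(vapply(x$counts$`+`, sum, 0)) + sum(vapply(x$counts$`-`, sum, 0))
  cat(sprintf("SignalTrack '%s' (%s, t = %s min): %d chromosome(s), %.0f reads, spike = %s, nf = %s\n",
              x$sample_id, x$treatment, format(x$timepoint), length(x$chrom_sizes),
              tot, format(x$spike_reads), format(x$normalization_factor)))
  invisible(x)
}

#' Spike-in normalization factor
#'
#' Each library is scaled by the number of reads mapping to the exogenous
#' spike-in genome: factor = total spike-in mapped reads / 1e5. Normalized
#' signal is raw signal divided by this factor.
#'
#' @param spike_mapped_reads total spike-in mapped reads (> 0).
#' @return the normalization factor (numeric scalar).
#' @export
normalization_factor <- function(spike_mapped_reads) {
  if (!is.numeric(spike_mapped_reads) || length(spike_mapped_reads) != 1L ||
      is.na(spike_mapped_reads) || spike_mapped_reads <= 0)
    stop("spike_mapped_reads must be a positive count; cannot normalize")
  spike_mapped_reads / 1e5
}

## ---- bedGraph reading/writing -------------------------------------------

## pre-scan for structurally malformed lines so errors carry line numbers;
## content parsing is delegated to rtracklayer.
check_bedgraph_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (!nzchar(ln) || grepl("^(track|browser|#)", ln)) next
    nf <- length(strsplit(ln, "[ \t]+")[[1]])
    if (nf != 4L)
      stop("malformed bedGraph line ", i, " in '", path, "': expected 4 fields, got ", nf)
  }
  invisible(TRUE)
}

read_bedgraph_one <- function(path, chrom_sizes) {
  check_bedgraph_lines(path)
  gr <- tryCatch(rtracklayer::import(path, format = "bedGraph"),
                 error = function(e) stop("failed to parse bedGraph '", path,
                                          "': ", conditionMessage(e), call. = FALSE))
  out <- lapply(chrom_sizes, function(n) numeric(n))
  if (length(gr) == 0L) return(out)
  chroms <- as.character(GenomicRanges::seqnames(gr))
  unknown <- setdiff(unique(chroms), names(chrom_sizes))
  if (length(unknown))
    stop("bedGraph '", path, "' refers to unknown chromosome(s): ",
         paste(unknown, collapse = ", "))
  if (any(GenomicRanges::end(gr) > chrom_sizes[chroms]))
    stop("bedGraph '", path, "' has intervals beyond chromosome bounds")
  if (!GenomicRanges::isDisjoint(gr))
    stop("bedGraph '", path, "' contains overlapping intervals")
  ## minus-strand files may carry either positive or negative magnitudes
  val <- abs(gr$score)
  for (ch in unique(chroms)) {
    sel <- chroms == ch
    cov <- IRanges::coverage(GenomicRanges::ranges(gr)[sel],
                             weight = val[sel], width = chrom_sizes[[ch]])
    out[[ch]] <- as.numeric(cov)
  }
  out
}

#' Read a strand pair of bedGraph files into a SignalTrack
#'
#' bedGraph intervals (4 columns, 0-based half-open) are expanded to
#' per-base values. Minus-strand values may be encoded as positive or
#' negative magnitudes; they are stored as magnitudes. Overlapping
#' intervals within one file are an error.
#'
#' @param plus_path,minus_path bedGraph file paths for the two strands.
#' @param chrom_sizes named vector of chromosome lengths.
#' @inheritParams signal_track
#' @return a [signal_track()] object.
#' @export
read_bedgraph_pair <- function(plus_path, minus_path, chrom_sizes,
                               sample_id = "sample", timepoint = NA_real_,
                               treatment = NA_character_, spike_reads = NA_real_) {
  signal_track(plus  = read_bedgraph_one(plus_path, chrom_sizes),
               minus = read_bedgraph_one(minus_path, chrom_sizes),
               chrom_sizes = chrom_sizes, sample_id = sample_id,
               timepoint = timepoint, treatment = treatment,
               spike_reads = spike_reads)
}

write_bedgraph_one <- function(per_chrom, path) {
  rows <- list()
  for (ch in names(per_chrom)) {
    v <- per_chrom[[ch]]
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths   # 0-based starts
    keep <- r$values != 0
    if (any(keep))
      rows[[ch]] <- data.frame(chrom = ch, start = starts[keep], end = ends[keep],
                               value = r$values[keep])
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(), start = numeric(), end = numeric(),
               value = numeric())
  lines <- sprintf("%s\t%d\t%d\t%.15g", df$chrom, as.integer(df$start),
                   as.integer(df$end), df$value)
  ok <- tryCatch(writeLines(lines, path), error = function(e)
    stop("cannot write bedGraph '", path, "': ", conditionMessage(e), call. = FALSE))
  invisible(path)
}

#' Write a SignalTrack to a strand pair of bedGraph files
#'
#' Runs of equal value are collapsed to intervals; zero runs are omitted;
#' intervals are sorted and non-overlapping by construction.
#'
#' @param track a [signal_track()] object.
#' @param plus_path,minus_path output paths.
#' @return the two paths, invisibly.
#' @export
write_bedgraph <- function(track, plus_path, minus_path) {
  stopifnot(inherits(track, "SignalTrack"))
  write_bedgraph_one(track$counts$`+`, plus_path)
  write_bedgraph_one(track$counts$`-`, minus_path)
  invisible(c(plus_path, minus_path))
}

## ---- gene-relative coordinate access ------------------------------------

## Per-base signal along a gene-relative half-open interval [rel_start,
## rel_end) measured downstream (+) from the anchor along the gene strand.
## Returns a vector oriented 5'->3'; positions off the chromosome are NA.
gene_signal_vector <- function(track, gene, rel_start, rel_end,
                               anchor = c("tss", "cps"), normalized = TRUE) {
  anchor <- match.arg(anchor)
  a <- if (anchor == "tss") gene$tss else gene$cps
  offs <- seq.int(rel_start, rel_end - 1L)
  pos <- if (gene$strand == "+") a + offs else a - offs
  v <- track$counts[[gene$strand]][[gene$chrom]]
  n <- track$chrom_sizes[[gene$chrom]]
  out <- rep(NA_real_, length(pos))
  ok <- pos >= 0 & pos < n
  out[ok] <- v[pos[ok] + 1L]
  if (normalized) {
    if (is.na(track$normalization_factor))
      stop("track '", track$sample_id, "' has no spike-in reads; cannot normalize")
    out <- out / track$normalization_factor
  }
  out
}

#' Sum and density of signal over a gene-relative region
#'
#' Offsets are measured along the gene's strand: `+n` means n bases
#' downstream of the anchor (TSS or CPS), negative offsets upstream.
#' Intervals are half-open at the downstream edge.
#'
#' @param track a [signal_track()].
#' @param gene a single-row gene record (see [read_genes()]).
#' @param rel_start,rel_end strand-relative offsets from the anchor.
#' @param anchor `"tss"` or `"cps"`.
#' @param normalized divide by the spike-in normalization factor?
#' @return list with `sum`, `density` (sum / width), `width`, and
#'   `clipped` (bases falling off the chromosome).
#' @export
region_signal <- function(track, gene, rel_start, rel_end,
                          anchor = c("tss", "cps"), normalized = TRUE) {
  if (rel_end < rel_start) stop("inverted interval: rel_end < rel_start")
  if (rel_end == rel_start) stop("zero-width region")
  v <- gene_signal_vector(track, gene, rel_start, rel_end, anchor, normalized)
  clipped <- sum(is.na(v))
  if (clipped > 0)
    warning("region for gene ", gene$gene_id, " truncated at chromosome end (",
            clipped, " bp clipped)")
  s <- sum(v, na.rm = TRUE)
  w <- length(v) - clipped
  list(sum = s, density = if (w > 0) s / w else NA_real_,
       width = w, clipped = clipped)
}

#' Combine replicate tracks by summing raw counts
#'
#' Mirrors pooling of biological replicates for added depth: raw counts and
#' spike-in reads are summed, so the combined normalization factor is the
#' sum of the replicate factors.
#'
#' @param tracks list of [signal_track()] objects on the same genome.
#' @param sample_id identifier for the combined track.
#' @return a [signal_track()].
#' @export
combine_tracks <- function(tracks, sample_id = NULL) {
  stopifnot(length(tracks) >= 1L)
  t0 <- tracks[[1L]]
  plus <- t0$counts$`+`; minus <- t0$counts$`-`
  spike <- t0$spike_reads
  for (tr in tracks[-1L]) {
    if (!identical(tr$chrom_sizes, t0$chrom_sizes))
      stop("tracks to combine are on different genomes")
    for (ch in names(plus)) {
      plus[[ch]] <- plus[[ch]] + tr$counts$`+`[[ch]]
      minus[[ch]] <- minus[[ch]] + tr$counts$`-`[[ch]]
    }
    spike <- spike + tr$spike_reads
  }
  signal_track(plus, minus, t0$chrom_sizes,
               sample_id = sample_id %||%
                 paste(vapply(tracks, `[[`, "", "sample_id"), collapse = "+"),
               timepoint = t0$timepoint, treatment = t0$treatment,
               spike_reads = spike)
}
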