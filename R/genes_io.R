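## Gene annotations: stranded transcription units anchored by an observed
## TSS (5') and a CPS (3'). Stored as a plain data.frame with 0-based
## half-open [start, end) genomic coordinates; tss/cps are 0-based single
## base positions derived from the strand.

make_gene_table <- function(gene_id, chrom, start, end, strand) {
  if (any(end - start <= 0)) stop("zero- or negative-length gene feature")
  if (any(!strand %in% c("+", "-"))) stop("gene without strand (+/- required)")
  df <- data.frame(gene_id = as.character(gene_id), chrom = as.character(chrom),
                   start = as.numeric(start), end = as.numeric(end),
                   strand = as.character(strand), stringsAsFactors = FALSE)
  df$tss <- ifelse(df$strand == "+", df$start, df$end - 1)
  df$cps <- ifelse(df$strand == "+", df$end - 1, df$start)
  df$length <- df$end - df$start
  df <- df[order(df$chrom, df$start, df$gene_id), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Read gene annotations from BED6 or GFF3
#'
#' BED is interpreted as 0-based half-open; GFF3 as 1-based closed and
#' converted on read. TSS and CPS are derived strand-aware: for a plus
#' strand gene over `[start, end)` TSS = start and CPS = end - 1; for a
#' minus strand gene TSS = end - 1 and CPS = start. Output is ordered by
#' (chrom, start).
#'
#' @param path annotation file path.
#' @param format `"auto"` (by extension), `"bed"`, or `"gff3"`.
#' @return a data.frame with columns gene_id, chrom, start, end, strand,
#'   tss, cps, length.
#' @export
read_genes <- function(path, format = c("auto", "bed", "gff3")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(gff3?|gff)$", path, ignore.case = TRUE)) "gff3" else "bed"
  }
  gr <- tryCatch(
    rtracklayer::import(path, format = if (format == "bed") "BED" else "GFF3"),
    error = function(e) stop("failed to parse ", format, " '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  if (format == "gff3" && "type" %in% names(S4Vectors::mcols(gr)) &&
      any(gr$type == "gene"))
    gr <- gr[gr$type == "gene"]
  if (length(gr) == 0L) {
    warning("no gene features in '", path, "'")
    return(make_gene_table(character(), character(), numeric(), numeric(),
                           character())[0, ])
  }
  strand <- as.character(GenomicRanges::strand(gr))
  if (any(strand == "*")) stop("gene(s) missing strand in '", path, "'")
  ids <- if (format == "bed") gr$name else {
    mc <- S4Vectors::mcols(gr)
    id <- if ("ID" %in% names(mc)) mc$ID else NULL
    id <- id %||% (if ("Name" %in% names(mc)) mc$Name else NULL)
    id %||% paste0("gene", seq_along(gr))
  }
  ## GRanges are 1-based closed: 0-based half-open is [start-1, end)
  make_gene_table(ids, as.character(GenomicRanges::seqnames(gr)),
                  GenomicRanges::start(gr) - 1, GenomicRanges::end(gr), strand)
}

#' Write genes as BED6
#'
#' @param genes gene table (see [read_genes()]).
#' @param path output path.
#' @param score score column value (default 0).
#' @return the path, invisibly.
#' @export
write_genes_bed <- function(genes, path, score = 0) {
  if (nrow(genes) == 0L) warning("writing empty gene set to '", path, "'")
  lines <- sprintf("%s\t%d\t%d\t%s\t%s\t%s", genes$chrom,
                   as.integer(genes$start), as.integer(genes$end),
                   genes$gene_id, format(score), genes$strand)
  writeLines(lines, path)
  invisible(path)
}
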