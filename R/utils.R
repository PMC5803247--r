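`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible child seed from a master seed
#'
#' Every stochastic routine in the package draws its randomness from a seed
#' derived deterministically from one master seed plus an integer stream tag,
#' so that per-sample simulation streams are independent but reproducible.
#'
#' @param master master seed (integer).
#' @param stream non-negative integer stream index.
#' @return an integer seed in `[0, 2^31)`.
#' @export
derive_seed <- function(master, stream) {
  stopifnot(is.numeric(master), length(master) == 1L,
            is.numeric(stream), length(stream) == 1L, stream >= 0)
  as.integer((abs(as.numeric(master)) * 48271 + as.numeric(stream) * 7919 + 1) %%
               2147483629)
}

## evaluate expr under a temporary RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

## consistent TSV writers so pipeline reruns are byte-identical
write_tsv_file <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_tsv_file <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE)
}
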