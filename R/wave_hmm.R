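## Advancing- and clearing-wave calling from treated-minus-untreated
## windowed signal, per gene and timepoint.
##
## Advancing variant: state 1 (upstream background, normal emission),
## state 2 (advancing wave of elevated slow polymerase density, gamma),
## state 3 (downstream of the front, gamma). The wave front is the
## downstream edge of the last state-2 window.
##
## Clearing variant: all three states gamma. State 1 covers the advancing
## wave at the 5' end, state 2 the depleted region between the advancing
## and clearing waves, state 3 the undisturbed 3' region; the clearing
## wave start is the state-2/state-3 boundary. Because gamma emissions
## need positive support, windowed differences are affinely shifted by
## the per-gene minimum minus a small margin before fitting (the shift is
## recorded and invertible).

#' Per-timepoint wave initialization distances (bp from the TSS)
#'
#' Approximate wave positions used to initialize the HMM state split,
#' derived from inspection of fold-change heat maps.
#'
#' @param type `"advancing"` or `"clearing"`.
#' @return named numeric vector keyed by timepoint in minutes.
#' @export
default_init_distances <- function(type = c("advancing", "clearing")) {
  type <- match.arg(type)
  if (type == "advancing")
    c(`0.5` = 1000, `1` = 1500, `2.5` = 2500, `5` = 3500)
  else
    c(`0.5` = 3000, `1` = 4000, `2.5` = 5500)
}

#' Treated-minus-untreated windowed signal along a gene
#'
#' Sums spike-in normalized signal in fixed windows along the gene strand
#' (optionally extended upstream of the TSS) and differences treated
#' minus untreated.
#'
#' @param treated,untreated [signal_track()]s (normalization metadata
#'   required).
#' @param gene single-row gene record.
#' @param window window width in bp (default 50).
#' @param upstream upstream extension before the TSS in bp (default 500
#'   for the advancing variant; use 0 for the clearing variant). Must be
#'   a multiple of `window`.
#' @return list of class `WindowedDiff`: gene_id, window, upstream,
#'   n_upstream, values (one per window, 5' to 3'), timepoint.
#' @export
windowed_difference <- function(treated, untreated, gene, window = 50,
                                upstream = 500) {
  if (upstream %% window != 0) stop("upstream must be a multiple of window")
  n_up <- upstream %/% window
  n_gene <- gene$length %/% window
  if (n_gene + n_up < 3L)
    stop("gene ", gene$gene_id, " too short for windowed analysis: need >= 3 windows of ",
         window, " bp")
  span <- (n_up + n_gene) * window
  vt <- gene_signal_vector(treated, gene, -upstream, -upstream + span, "tss", TRUE)
  vu <- gene_signal_vector(untreated, gene, -upstream, -upstream + span, "tss", TRUE)
  d <- vt - vu
  vals <- colSums(matrix(d, nrow = window), na.rm = TRUE)
  structure(list(gene_id = gene$gene_id, window = window, upstream = upstream,
                 n_upstream = n_up, values = vals,
                 timepoint = treated$timepoint),
            class = "WindowedDiff")
}

## Scale-aware emission variance floor: a state is never allowed to
## collapse onto a (near-)constant run of windows, which would otherwise
## dominate the likelihood with a delta-like emission.
emission_var_floor <- function(x) {
  max(1e-8, (0.02 * diff(range(x)))^2)
}

shift_positive <- function(x) {
  margin <- 0.05 * stats::sd(x) + 1e-3
  if (!is.finite(margin)) margin <- 1e-3
  shift <- min(x) - margin
  list(values = x - shift, shift = shift)
}

segment_or_widen <- function(idx, Tn) {
  ## guarantee >= 2 windows for moment initialization
  idx <- idx[idx >= 1 & idx <= Tn]
  if (length(idx) >= 2L) return(idx)
  max(1L, Tn - 1L):Tn
}

make_wave_call <- function(wdiff, fit, path, type) {
  n_up <- if (type == "advancing") wdiff$n_upstream else 0L
  last2 <- if (any(path == 2L)) max(which(path == 2L)) else NA_integer_
  dist <- if (is.na(last2)) NA_real_ else (last2 - n_up) * wdiff$window
  kl <- kl_divergence(fit$emissions[[2L]], fit$emissions[[3L]])
  pass <- isTRUE(fit$converged) && !is.na(dist) && dist > 0 && kl > 1
  data.frame(gene_id = wdiff$gene_id, timepoint = wdiff$timepoint,
             type = type, distance_bp = dist,
             kl = kl, converged = fit$converged, monotone_ll = fit$monotone,
             pass = pass)
}

#' Call an advancing wave on one gene
#'
#' Fits the advancing-variant HMM to a [windowed_difference()] built with
#' an upstream extension: the state-1 normal emission is initialized from
#' the upstream windows, and states 2/3 (gamma) from the windows on
#' either side of `init_distance`. After Baum-Welch and Viterbi decoding,
#' the wave front is the genomic distance from the TSS to the downstream
#' edge of the last state-2 window. Call quality requires EM convergence
#' and Kullback-Leibler divergence > 1 between the state-2 and state-3
#' emissions.
#'
#' @param wdiff a [windowed_difference()] with `upstream` > 0.
#' @param init_distance approximate wave distance (bp from TSS) used to
#'   initialize the state split (see [default_init_distances()]).
#' @param rectify floor the windowed differences at zero before fitting
#'   (default TRUE). The advancing wave is a signal-gain feature; windows
#'   where treated signal drops below untreated carry the clearing
#'   population's signature, and rectification keeps the state-2/3
#'   boundary on the front of the slow population rather than the rear of
#'   the fast one.
#' @param max_iter,tol EM controls (see [baum_welch()]).
#' @param init_factors multipliers of `init_distance` used as EM restart
#'   points; the restart with the highest final log-likelihood wins
#'   (Baum-Welch is a local optimizer).
#' @return list with `fit` (Baum-Welch output plus `shift`), `path`, and
#'   `call` (one-row data.frame: distance_bp, kl, converged, pass).
#' @export
fit_advancing_hmm <- function(wdiff, init_distance, rectify = TRUE,
                              max_iter = 200L, tol = 1e-6,
                              init_factors = c(1, 0.5, 0.75, 1.25)) {
  stopifnot(inherits(wdiff, "WindowedDiff"))
  if (wdiff$n_upstream < 1L)
    stop("advancing variant needs an upstream extension (upstream > 0)")
  v <- if (rectify) pmax(wdiff$values, 0) else wdiff$values
  sp <- shift_positive(v)
  x <- sp$values
  vf <- emission_var_floor(x)
  Tn <- length(x)
  n_up <- wdiff$n_upstream
  best <- NULL
  for (f in init_factors) {
    init_w <- n_up + min(max(round(f * init_distance / wdiff$window), 1L),
                         Tn - n_up - 1L)
    seg1 <- segment_or_widen(seq_len(n_up), Tn)
    seg2 <- segment_or_widen((n_up + 1L):init_w, Tn)
    seg3 <- segment_or_widen((init_w + 1L):Tn, Tn)
    emissions <- list(moment_emission(x[seg1], "normal", vf),
                      moment_emission(x[seg2], "gamma", vf),
                      moment_emission(x[seg3], "gamma", vf))
    fit <- baum_welch(x, emissions, max_iter = max_iter, tol = tol,
                      var_floor = vf)
    if (is.null(best) ||
        utils::tail(fit$loglik_trace, 1) > utils::tail(best$loglik_trace, 1))
      best <- fit
  }
  best$shift <- sp$shift
  path <- viterbi_decode(x, best)
  list(fit = best, path = path,
       call = make_wave_call(wdiff, best, path, "advancing"))
}

#' Call a clearing wave on one gene
#'
#' Fits the clearing-variant HMM (all-gamma emissions) to a
#' [windowed_difference()] built without upstream extension. State 1 is
#' initialized from the first 1000 nt downstream of the TSS (within the
#' advancing wave), state 3 from beyond `init_distance`. Standardized
#' window values are clamped to |z| <= `tsmooth` before fitting to limit
#' the influence of outlying windows. The clearing-wave start is the
#' state-2/state-3 boundary; quality requires KL(2||3) > 1.
#'
#' @param wdiff a [windowed_difference()] with `upstream = 0`.
#' @param init_distance approximate clearing-wave start (bp from TSS).
#' @param tsmooth smoothing clamp on standardized windows (default 5).
#' @param init_state1_bp extent used to initialize state 1 (default
#'   1000 bp).
#' @inheritParams fit_advancing_hmm
#' @return as [fit_advancing_hmm()].
#' @export
fit_clearing_hmm <- function(wdiff, init_distance, tsmooth = 5,
                             init_state1_bp = 1000, max_iter = 200L,
                             tol = 1e-6, init_factors = c(1, 0.5, 0.75, 1.25)) {
  stopifnot(inherits(wdiff, "WindowedDiff"))
  v <- wdiff$values
  if (!is.null(tsmooth) && is.finite(tsmooth)) {
    m <- mean(v); s <- stats::sd(v)
    if (is.finite(s) && s > 0) {
      z <- pmin(pmax((v - m) / s, -tsmooth), tsmooth)
      v <- m + z * s
    }
  }
  sp <- shift_positive(v)
  x <- sp$values
  if (any(x <= 0)) stop("positive-support transform failed for ", wdiff$gene_id)
  vf <- emission_var_floor(x)
  Tn <- length(x)
  n1 <- min(max(round(init_state1_bp / wdiff$window), 1L), Tn - 2L)
  best <- NULL
  for (f in init_factors) {
    init_w <- min(max(round(f * init_distance / wdiff$window), n1 + 1L),
                  Tn - 1L)
    seg1 <- segment_or_widen(seq_len(n1), Tn)
    seg2 <- segment_or_widen((n1 + 1L):init_w, Tn)
    seg3 <- segment_or_widen((init_w + 1L):Tn, Tn)
    emissions <- list(moment_emission(x[seg1], "gamma", vf),
                      moment_emission(x[seg2], "gamma", vf),
                      moment_emission(x[seg3], "gamma", vf))
    fit <- baum_welch(x, emissions, max_iter = max_iter, tol = tol,
                      var_floor = vf)
    if (is.null(best) ||
        utils::tail(fit$loglik_trace, 1) > utils::tail(best$loglik_trace, 1))
      best <- fit
  }
  best$shift <- sp$shift
  path <- viterbi_decode(x, best)
  list(fit = best, path = path,
       call = make_wave_call(wdiff, best, path, "clearing"))
}

#' Call waves across a gene cohort and time course
#'
#' Convenience driver: for every eligible gene and treated timepoint,
#' builds the windowed difference against the untreated reference and
#' fits the requested HMM variant.
#'
#' @param treated_by_timepoint named list (names = timepoints in minutes)
#'   of treated [signal_track()]s (combined replicates).
#' @param untreated untreated reference [signal_track()].
#' @param genes filtered gene table.
#' @param type `"advancing"` (genes > `min_length`, default 4 kb, all
#'   timepoints) or `"clearing"` (genes > 6 kb, timepoints <= 2.5 min).
#' @param init_distances named vector of initialization distances (bp)
#'   keyed by timepoint; defaults from [default_init_distances()].
#' @param window window width (bp).
#' @param upstream upstream extension for the advancing variant (bp).
#' @param min_length minimum gene length (bp); default 4000 for
#'   advancing, 6000 for clearing.
#' @param max_timepoint maximum timepoint used (default Inf for
#'   advancing, 2.5 for clearing).
#' @param tsmooth clearing-variant smoothing clamp.
#' @return data.frame of wave calls (gene_id, timepoint, type,
#'   distance_bp, kl, converged, pass).
#' @export
call_waves <- function(treated_by_timepoint, untreated, genes,
                       type = c("advancing", "clearing"),
                       init_distances = NULL, window = 50, upstream = 500,
                       min_length = NULL, max_timepoint = NULL, tsmooth = 5) {
  type <- match.arg(type)
  min_length <- min_length %||% if (type == "advancing") 4000 else 6000
  max_timepoint <- max_timepoint %||% if (type == "advancing") Inf else 2.5
  init_distances <- init_distances %||% default_init_distances(type)
  genes <- genes[genes$length > min_length, , drop = FALSE]
  tps <- as.numeric(names(treated_by_timepoint))
  keep <- !is.na(tps) & tps > 0 & tps <= max_timepoint
  out <- list()
  for (ti in which(keep)) {
    tp <- tps[ti]
    init <- if (as.character(tp) %in% names(init_distances))
      init_distances[[as.character(tp)]]
    else stats::approx(as.numeric(names(init_distances)), init_distances,
                       xout = tp, rule = 2)$y
    for (i in seq_len(nrow(genes))) {
      g <- genes[i, ]
      res <- if (type == "advancing") {
        wd <- windowed_difference(treated_by_timepoint[[ti]], untreated, g,
                                  window = window, upstream = upstream)
        fit_advancing_hmm(wd, init)
      } else {
        wd <- windowed_difference(treated_by_timepoint[[ti]], untreated, g,
                                  window = window, upstream = 0)
        fit_clearing_hmm(wd, init, tsmooth = tsmooth)
      }
      out[[length(out) + 1L]] <- res$call
    }
  }
  calls <- do.call(rbind, out)
  rownames(calls) <- NULL
  calls
}

#' Filter wave-call series per gene
#'
#' Keeps genes with a quality-passing call at every timepoint of the
#' common grid whose call distances do not recede toward the TSS over
#' time (non-decreasing).
#'
#' @param calls wave-call data.frame from [call_waves()].
#' @param timepoints the required timepoint grid (default: all timepoints
#'   present in `calls`).
#' @return list with `retained` (gene ids), `calls` (their calls), and
#'   `n` per filtering reason.
#' @export
filter_wave_series <- function(calls, timepoints = NULL) {
  timepoints <- sort(timepoints %||% unique(calls$timepoint))
  by_gene <- split(calls, calls$gene_id)
  keep <- vapply(by_gene, function(df) {
    df <- df[match(timepoints, df$timepoint), , drop = FALSE]
    if (anyNA(df$pass) || !all(df$pass)) return(FALSE)
    all(diff(df$distance_bp) >= 0)
  }, TRUE)
  retained <- names(by_gene)[keep]
  list(retained = retained,
       calls = calls[calls$gene_id %in% retained &
                       calls$timepoint %in% timepoints, , drop = FALSE],
       n = c(candidates = length(by_gene), retained = length(retained)))
}
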