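## Three-state left-to-right hidden Markov machinery used for wave
## calling. Topology: states 1 -> 2 -> 3, no backward transitions and no
## state skipping; the chain starts in state 1. Emissions are normal or
## gamma per state. Because legal state paths are exactly the monotone
## ones, a decoded path is fully described by its two transition times.

new_hmm <- function(emissions, A = NULL) {
  stopifnot(length(emissions) == 3L)
  if (is.null(A)) {
    A <- matrix(0, 3, 3)
    A[1, 1] <- A[2, 2] <- 0.9; A[1, 2] <- A[2, 3] <- 0.1; A[3, 3] <- 1
  }
  stopifnot(all(abs(rowSums(A) - 1) < 1e-8), A[2, 1] == 0, A[3, 1] == 0,
            A[3, 2] == 0, A[1, 3] == 0)
  list(emissions = emissions, A = A)
}

emission_logdens <- function(x, em) {
  switch(em$family,
         normal = stats::dnorm(x, em$mean, em$sd, log = TRUE),
         gamma = stats::dgamma(x, shape = em$shape, rate = em$rate, log = TRUE),
         stop("unknown emission family: ", em$family))
}

log_emission_matrix <- function(x, emissions) {
  matrix(vapply(emissions, function(em) emission_logdens(x, em),
                numeric(length(x))),
         nrow = length(x), ncol = length(emissions))
}

fit_normal_weighted <- function(x, w, var_floor = 1e-8) {
  sw <- sum(w)
  m <- sum(w * x) / sw
  v <- max(sum(w * (x - m)^2) / sw, var_floor)
  list(family = "normal", mean = m, sd = sqrt(v))
}

## Weighted maximum-likelihood gamma fit (Newton iteration on the shape;
## this is the exact M-step, so EM ascent is preserved). The variance
## floor acts as a cap on the shape (var = m^2 / shape >= floor), keeping
## emissions from collapsing onto near-constant runs.
fit_gamma_weighted <- function(x, w, var_floor = 1e-8) {
  sw <- sum(w)
  m <- max(sum(w * x) / sw, 1e-8)
  s <- log(m) - sum(w * log(pmax(x, 1e-300))) / sw
  lbar <- sum(w * log(pmax(x, 1e-300))) / sw
  if (!is.finite(s) || s <= 0) {
    shape <- 1e8
  } else {
    shape <- (3 - s + sqrt((s - 3)^2 + 24 * s)) / (12 * s)
    for (i in 1:50) {
      step <- (log(shape) - digamma(shape) - s) / (1 / shape - trigamma(shape))
      newk <- shape - step
      if (!is.finite(newk) || newk <= 0) break
      shape <- newk
      if (abs(step) < 1e-12 * shape) break
    }
  }
  shape <- min(max(shape, 1e-3), 1e8)
  rate <- shape / m
  if (shape / rate^2 < var_floor) {
    ## profile optimum violates the variance floor: maximize on the
    ## boundary var = floor, i.e. rate = sqrt(shape / floor). The
    ## boundary objective can be multimodal, so bracket on a log grid
    ## before local refinement.
    h <- function(lk) {
      k <- exp(lk); r <- sqrt(k / var_floor)
      k * log(r) - lgamma(k) + (k - 1) * lbar - r * m
    }
    grid <- seq(log(1e-3), log(1e8), length.out = 61L)
    hv <- vapply(grid, h, 0)
    i <- which.max(hv)
    lo <- grid[max(i - 1L, 1L)]; hi <- grid[min(i + 1L, length(grid))]
    opt <- stats::optimize(h, c(lo, hi), maximum = TRUE, tol = 1e-10)
    shape <- exp(opt$maximum)
    rate <- sqrt(shape / var_floor)
  }
  list(family = "gamma", shape = shape, rate = rate)
}

fit_emission_weighted <- function(x, w, family, var_floor = 1e-8) {
  if (family == "normal") fit_normal_weighted(x, w, var_floor)
  else fit_gamma_weighted(x, w, var_floor)
}

moment_emission <- function(x, family, var_floor = 1e-8) {
  fit_emission_weighted(x, rep(1, length(x)), family, var_floor)
}

## scaled forward-backward; returns state posteriors, expected transition
## counts and the log-likelihood.
forward_backward <- function(logB, A) {
  Tn <- nrow(logB)
  off <- apply(logB, 1, max)
  B <- exp(logB - off)
  alpha <- matrix(0, Tn, 3); beta <- matrix(0, Tn, 3)
  cs <- numeric(Tn)
  alpha[1, ] <- c(B[1, 1], 0, 0)
  cs[1] <- sum(alpha[1, ]); alpha[1, ] <- alpha[1, ] / cs[1]
  if (Tn == 1L)
    return(list(gamma = alpha, xi = matrix(0, 3, 3),
                loglik = log(cs[1]) + off[1]))
  for (t in 2:Tn) {
    a <- (alpha[t - 1, ] %*% A) * B[t, ]
    cs[t] <- sum(a)
    if (cs[t] <= 0) { cs[t] <- .Machine$double.xmin; a[] <- 1 / 3 }
    alpha[t, ] <- a / cs[t]
  }
  ## beta is rescaled per step (posteriors are renormalized, so only the
  ## direction matters); this stays finite even with near-delta emissions
  beta[Tn, ] <- 1
  for (t in (Tn - 1):1) {
    b <- as.numeric(A %*% (B[t + 1, ] * beta[t + 1, ]))
    mx <- max(b)
    beta[t, ] <- if (mx > 0) b / mx else rep(1, 3)
  }
  gamma <- alpha * beta
  rs <- rowSums(gamma)
  rs[rs <= 0] <- 1
  gamma <- gamma / rs
  xi <- matrix(0, 3, 3)
  for (t in 1:(Tn - 1)) {
    m <- (alpha[t, ] %o% (B[t + 1, ] * beta[t + 1, ])) * A
    tot <- sum(m)
    if (tot > 0) xi <- xi + m / tot
  }
  list(gamma = gamma, xi = xi, loglik = sum(log(cs)) + sum(off))
}

#' Fit a constrained three-state HMM by expectation-maximization
#'
#' Baum-Welch on a single observation sequence with the left-to-right
#' transition structure held fixed (zero mass stays zero) and emission
#' families per state as given. The log-likelihood is non-decreasing
#' across iterations (tracked and asserted downstream).
#'
#' @param x observation vector (already shifted to positive support where
#'   gamma emissions are used).
#' @param emissions list of 3 initial emission parameter lists (`family`
#'   plus `mean`/`sd` or `shape`/`rate`).
#' @param A optional initial transition matrix.
#' @param max_iter,tol EM iteration cap and absolute log-likelihood
#'   convergence tolerance.
#' @param var_floor emission variance floor (degenerate fits are floored
#'   and flagged).
#' @return list with `emissions`, `A`, `loglik_trace`, `converged`,
#'   `monotone`, `floored`.
#' @export
baum_welch <- function(x, emissions, A = NULL, max_iter = 200L, tol = 1e-6,
                       var_floor = 1e-8) {
  hmm <- new_hmm(emissions, A)
  trace <- numeric(0)
  floored <- FALSE
  for (it in seq_len(max_iter)) {
    logB <- log_emission_matrix(x, hmm$emissions)
    fb <- forward_backward(logB, hmm$A)
    trace <- c(trace, fb$loglik)
    ## M-step: transitions (structure preserved)
    A2 <- hmm$A
    for (s in 1:2) {
      tot <- fb$xi[s, s] + fb$xi[s, s + 1]
      if (tot > 0) {
        stay <- min(max(fb$xi[s, s] / tot, 1e-6), 1 - 1e-6)
        A2[s, s] <- stay; A2[s, s + 1] <- 1 - stay
      }
    }
    ## M-step: emissions. Generalized-EM safeguard: an update is only
    ## accepted if it does not lower the expected complete-data
    ## log-likelihood for its state (keeps the ascent property even at
    ## constraint boundaries).
    em2 <- hmm$emissions
    for (s in 1:3) {
      w <- fb$gamma[, s]
      if (sum(w) > 1e-8) {
        fit <- fit_emission_weighted(x, w, hmm$emissions[[s]]$family, var_floor)
        if (!is.null(fit$sd) && fit$sd^2 <= var_floor * 1.001) floored <- TRUE
        q_old <- sum(w * emission_logdens(x, hmm$emissions[[s]]))
        q_new <- sum(w * emission_logdens(x, fit))
        if (is.finite(q_new) && q_new >= q_old - 1e-10) em2[[s]] <- fit
      }
    }
    hmm$A <- A2; hmm$emissions <- em2
    if (it > 1 && abs(trace[it] - trace[it - 1]) < tol) break
  }
  logB <- log_emission_matrix(x, hmm$emissions)
  final <- forward_backward(logB, hmm$A)$loglik
  diffs <- diff(trace)
  list(emissions = hmm$emissions, A = hmm$A,
       loglik_trace = c(trace, final),
       converged = length(trace) > 1 &&
         abs(trace[length(trace)] - trace[length(trace) - 1]) < tol,
       monotone = all(diffs > -1e-6 * (1 + abs(trace[-length(trace)]))),
       floored = floored)
}

compare_keys <- function(k1, k2) {
  ## -1 if k1 earlier-transition (lexicographically smaller), 1 if later
  if (k1[1] != k2[1]) return(sign(k1[1] - k2[1]))
  sign(k1[2] - k2[2])
}

#' Viterbi decoding of the constrained three-state HMM
#'
#' Dynamic-programming maximum a posteriori path. Ties are broken toward
#' the earliest state transitions (conservative, shorter wave distances).
#'
#' @param x observation vector.
#' @param hmm list with `emissions` and `A` (e.g. a [baum_welch()] fit).
#' @return integer state path (values 1..3).
#' @export
viterbi_decode <- function(x, hmm) {
  logB <- log_emission_matrix(x, hmm$emissions)
  la <- log(hmm$A)
  Tn <- nrow(logB)
  delta <- matrix(-Inf, Tn, 3)
  keys <- array(Inf, c(Tn, 3, 2))   # entry times into state 2 / state 3
  delta[1, 1] <- logB[1, 1]
  for (t in 2:max(Tn, 2)) {
    if (t > Tn) break
    delta[t, 1] <- delta[t - 1, 1] + la[1, 1] + logB[t, 1]
    keys[t, 1, ] <- keys[t - 1, 1, ]
    ## state 2: stay beats enter at ties (it transitioned earlier)
    stay <- delta[t - 1, 2] + la[2, 2]
    enter <- delta[t - 1, 1] + la[1, 2]
    if (stay >= enter) {
      delta[t, 2] <- stay + logB[t, 2]; keys[t, 2, ] <- keys[t - 1, 2, ]
    } else {
      delta[t, 2] <- enter + logB[t, 2]; keys[t, 2, ] <- c(t, Inf)
    }
    stay <- delta[t - 1, 3] + la[3, 3]
    enter <- delta[t - 1, 2] + la[2, 3]
    if (stay >= enter) {
      delta[t, 3] <- stay + logB[t, 3]; keys[t, 3, ] <- keys[t - 1, 3, ]
    } else {
      delta[t, 3] <- enter + logB[t, 3]
      keys[t, 3, ] <- c(keys[t - 1, 2, 1], t)
    }
  }
  best <- 1
  for (s in 2:3) {
    if (delta[Tn, s] > delta[Tn, best] ||
        (delta[Tn, s] == delta[Tn, best] &&
         compare_keys(keys[Tn, s, ], keys[Tn, best, ]) < 0))
      best <- s
  }
  k <- keys[Tn, best, ]
  tgrid <- seq_len(Tn)
  path <- rep(1L, Tn)
  path[tgrid >= k[1]] <- 2L
  path[tgrid >= k[2]] <- 3L
  path
}

#' Exhaustive-enumeration Viterbi oracle
#'
#' Enumerates every legal left-to-right path (at most `max_windows`
#' observations) and returns the maximum-probability one, with the same
#' earliest-transition tie rule as [viterbi_decode()]. Test oracle only.
#'
#' @param x observation vector (length <= `max_windows`).
#' @param hmm list with `emissions` and `A`.
#' @param max_windows refusal threshold (default 14).
#' @return integer state path.
#' @export
viterbi_bruteforce <- function(x, hmm, max_windows = 14L) {
  Tn <- length(x)
  if (Tn > max_windows)
    stop("refusing exhaustive enumeration beyond ", max_windows, " windows")
  logB <- log_emission_matrix(x, hmm$emissions)
  la <- log(hmm$A)
  best_lp <- -Inf; best_key <- c(Inf, Inf); best_path <- rep(1L, Tn)
  for (n1 in seq_len(Tn)) {
    for (j in n1:Tn) {        # j = last window of state 2 (j == n1: no state 2)
      n2 <- j - n1; n3 <- Tn - j
      if (n2 == 0L && n3 > 0L) next     # state skipping forbidden
      lp <- (n1 - 1) * la[1, 1] + sum(logB[seq_len(n1), 1])
      if (n2 > 0) lp <- lp + la[1, 2] + (n2 - 1) * la[2, 2] +
          sum(logB[(n1 + 1):j, 2])
      if (n3 > 0) lp <- lp + la[2, 3] + (n3 - 1) * la[3, 3] +
          sum(logB[(j + 1):Tn, 3])
      key <- c(if (n2 > 0) n1 + 1 else Inf, if (n3 > 0) j + 1 else Inf)
      if (lp > best_lp || (lp == best_lp && compare_keys(key, best_key) < 0)) {
        best_lp <- lp; best_key <- key
        best_path <- c(rep(1L, n1), rep(2L, n2), rep(3L, n3))
      }
    }
  }
  best_path
}

#' Kullback-Leibler divergence between two emission distributions
#'
#' Closed forms for normal/normal and gamma/gamma; numeric quadrature on a
#' grid otherwise (and available for cross-checking the closed forms).
#'
#' @param em_a,em_b emission parameter lists (`family` + parameters).
#' @param method `"closed"` (default, falls back to quadrature for mixed
#'   families) or `"quadrature"`.
#' @return KL(a || b), a non-negative scalar.
#' @export
kl_divergence <- function(em_a, em_b, method = c("closed", "quadrature")) {
  method <- match.arg(method)
  if (method == "closed" && em_a$family == em_b$family) {
    if (em_a$family == "normal") {
      return(log(em_b$sd / em_a$sd) +
               (em_a$sd^2 + (em_a$mean - em_b$mean)^2) / (2 * em_b$sd^2) - 0.5)
    }
    if (em_a$family == "gamma") {
      a1 <- em_a$shape; b1 <- em_a$rate; a2 <- em_b$shape; b2 <- em_b$rate
      return((a1 - a2) * digamma(a1) - lgamma(a1) + lgamma(a2) +
               a2 * (log(b1) - log(b2)) + a1 * (b2 - b1) / b1)
    }
  }
  ## quadrature over the support of a
  q <- function(em, p) switch(em$family,
    normal = stats::qnorm(p, em$mean, em$sd),
    gamma = stats::qgamma(p, shape = em$shape, rate = em$rate))
  lo <- q(em_a, 1e-9); hi <- q(em_a, 1 - 1e-9)
  if (em_a$family == "gamma" || em_b$family == "gamma") lo <- max(lo, 1e-12)
  grid <- seq(lo, hi, length.out = 20001L)
  la <- emission_logdens(grid, em_a); lb <- emission_logdens(grid, em_b)
  fa <- exp(la)
  ok <- is.finite(la) & is.finite(lb)
  if (!all(is.finite(lb[fa > 1e-300]))) stop("support mismatch: KL undefined")
  sum((fa * (la - lb))[ok]) * (grid[2] - grid[1])
}
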