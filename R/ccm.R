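# Cross-map prediction skill of a single library/test split.
# The effect's shadow manifold predicts contemporaneous values of the cause;
# the first floor(split * n_states) states form the library pool, the rest
# are prediction targets. lib_size limits how many pool states are used
# (first lib_size, deterministically, unless sample_idx supplies a draw).
.cross_map_skill <- function(cause, effect, E, l, split = 0.75,
                             lib_size = NULL, sample_idx = NULL) {
  X <- delay_embed(effect, E, l)
  t_idx <- as.integer(rownames(X))
  y <- cause[t_idx]
  n <- nrow(X)
  n_lib <- floor(split * n)
  if (n_lib < E + 2 || n - n_lib < 3) return(NA_real_)
  lib_rows <- seq_len(n_lib)
  if (!is.null(sample_idx)) {
    lib_rows <- sort(sample_idx)
  } else if (!is.null(lib_size) && lib_size < n_lib) {
    lib_rows <- seq_len(lib_size)
  }
  tgt_rows <- (n_lib + 1L):n
  pred <- .simplex_predict(X[lib_rows, , drop = FALSE], y[lib_rows],
                           X[tgt_rows, , drop = FALSE], k = E + 1L)
  obs <- y[tgt_rows]
  ok <- !is.na(pred)
  if (sum(ok) < 3 || stats::sd(pred[ok]) == 0 || stats::sd(obs[ok]) == 0) {
    return(NA_real_)
  }
  stats::cor(pred[ok], obs[ok])
}

# skill at every library size, computing embeddings, distances and per-row
# neighbour orderings once (the L-size library is the first L pool states,
# so the k nearest within 1..L fall out of the full ordering by filtering)
.cross_map_curve <- function(cause, effect, E, l, split, library_sizes) {
  X <- delay_embed(effect, E, l)
  t_idx <- as.integer(rownames(X))
  y <- cause[t_idx]
  n <- nrow(X)
  n_lib <- floor(split * n)
  if (n_lib < E + 2 || n - n_lib < 3) {
    return(rep(NA_real_, length(library_sizes)))
  }
  libX <- X[seq_len(n_lib), , drop = FALSE]
  tgtX <- X[(n_lib + 1L):n, , drop = FALSE]
  liby <- y[seq_len(n_lib)]
  obs <- y[(n_lib + 1L):n]
  d2 <- outer(rowSums(tgtX^2), rowSums(libX^2), "+") -
    2 * tcrossprod(tgtX, libX)
  d2[d2 < 0] <- 0
  d <- sqrt(d2)
  nt <- nrow(tgtX)
  ord <- t(apply(d, 1, order))
  k <- E + 1L
  vapply(library_sizes, function(L) {
    pred <- vapply(seq_len(nt), function(i) {
      oi <- ord[i, ]
      nb <- oi[oi <= L][seq_len(min(k, L))]
      dnb <- d[i, nb]
      if (dnb[1] == 0) {
        mean(liby[nb[dnb == 0]])
      } else {
        w <- exp(-dnb / dnb[1])
        sum(w * liby[nb]) / sum(w)
      }
    }, numeric(1))
    if (stats::sd(pred) == 0 || stats::sd(obs) == 0) return(NA_real_)
    stats::cor(pred, obs)
  }, numeric(1))
}

#' Convergent cross mapping over increasing library sizes
#'
#' Tests whether `cause` drives `effect` by reconstructing the effect's
#' shadow manifold and cross-mapping the cause's values: if the cause leaves
#' a signature in the effect's dynamics, prediction skill rises
#' ("converges") as more states enter the library.
#'
#' The first `split` fraction of states is the chronological library pool;
#' skill is measured on the held-out remainder. At each library size the
#' first `L` pool states are used, which keeps the curve deterministic.
#'
#' @param cause,effect Numeric series of equal length (already conditioned:
#'   uniform grid, normalized).
#' @param E,l Embedding parameters (defaults 5 and 2).
#' @param library_sizes Ascending library sizes; default 15 log-spaced sizes
#'   from `E + 2` to the pool maximum.
#' @param split Fraction of states forming the library pool (default 0.75).
#' @return A `ccm_curve`: tibble with columns `library_size` and `skill`,
#'   attributes `converged` (see [convergence_test()]) and `final_skill`.
#' @export
cross_map <- function(cause, effect, E = 5, l = 2, library_sizes = NULL,
                      split = 0.75) {
  stopifnot(length(cause) == length(effect))
  n_states <- length(effect) - (E - 1) * l
  n_pool <- floor(split * n_states)
  if (n_pool < E + 2) stop("library pool smaller than E + 2 states",
                           call. = FALSE)
  if (is.null(library_sizes)) {
    library_sizes <- unique(round(exp(seq(log(E + 2), log(n_pool),
                                          length.out = 15))))
  }
  library_sizes <- sort(unique(pmin(library_sizes, n_pool)))
  if (max(library_sizes) > n_pool) {
    warning("library sizes truncated to pool size ", n_pool, call. = FALSE)
  }
  skill <- .cross_map_curve(cause, effect, E, l, split, library_sizes)
  out <- tibble::tibble(library_size = as.integer(library_sizes),
                        skill = skill)
  ok <- !is.na(skill)
  attr(out, "final_skill") <- if (any(ok)) skill[max(which(ok))] else NA_real_
  attr(out, "converged") <- convergence_test(out)
  class(out) <- c("ccm_curve", class(out))
  out
}

#' Test a cross-map curve for convergence
#'
#' A curve converges when skill at the largest library exceeds skill at the
#' smallest by at least `min_gain` *and* a one-sided Kendall trend test over
#' (library size, skill) finds a positive trend at level `alpha`.
#'
#' @param curve A `ccm_curve`, or a data frame with columns `library_size`
#'   and `skill`.
#' @param min_gain Minimum skill gain (default 0.05).
#' @param alpha Trend-test level (default 0.05).
#' @return Logical.
#' @export
convergence_test <- function(curve, min_gain = 0.05, alpha = 0.05) {
  sk <- curve$skill
  L <- curve$library_size
  ok <- !is.na(sk)
  if (sum(ok) < 3) return(FALSE)
  sk <- sk[ok]; L <- L[ok]
  gain <- sk[length(sk)] - sk[1]
  if (is.na(gain) || gain < min_gain) return(FALSE)
  # one-sided Kendall trend test, normal approximation (L is strictly
  # increasing so only skill ties could occur, and exact skill ties are
  # measure-zero here)
  tau <- stats::cor(L, sk, method = "kendall")
  if (is.na(tau) || tau <= 0) return(FALSE)
  n <- length(sk)
  z <- 3 * tau * sqrt(n * (n - 1)) / sqrt(2 * (2 * n + 5))
  p <- stats::pnorm(z, lower.tail = FALSE)
  isTRUE(p < alpha)
}

#' Sliding-window convergent cross mapping
#'
#' Splits the pair into overlapping windows (length `window`, start step
#' `gap`), makes each window segment stationary (differencing on a failed
#' Dickey-Fuller test, see [ensure_stationary()]), runs [cross_map()] per
#' window, and aggregates: the pair's skill is the mean final skill over the
#' *converged* windows only. Windowing localizes the test so that periods of
#' weak or absent coupling do not dilute periods of strong coupling.
#'
#' @inheritParams cross_map
#' @param window Window length in samples (default 100).
#' @param gap Step between window starts in samples (default 10).
#' @return A `ccm_windows`: tibble with one row per window (`window_start`,
#'   `skill`, `converged`, `differenced`), attributes `mean_skill` (NA when
#'   no window converged) and `n_converged`.
#' @export
sliding_window_ccm <- function(cause, effect, window = 100, gap = 10,
                               E = 5, l = 2, split = 0.75,
                               library_sizes = NULL) {
  n <- length(cause)
  stopifnot(length(effect) == n, n >= window)
  starts <- seq(1L, n - window + 1L, by = gap)
  skill <- rep(NA_real_, length(starts))
  converged <- logical(length(starts))
  differenced <- logical(length(starts))
  for (i in seq_along(starts)) {
    s <- starts[i]
    ca2 <- ensure_stationary(cause[s:(s + window - 1L)])
    ef2 <- ensure_stationary(effect[s:(s + window - 1L)])
    differenced[i] <- attr(ca2, "differenced") || attr(ef2, "differenced")
    # differencing shortens by one; trim the other series to match
    m <- min(length(ca2), length(ef2))
    ca2 <- ca2[(length(ca2) - m + 1L):length(ca2)]
    ef2 <- ef2[(length(ef2) - m + 1L):length(ef2)]
    n_states <- m - (E - 1) * l
    n_pool <- floor(split * n_states)
    if (n_pool < E + 2) next
    sizes <- if (is.null(library_sizes)) {
      unique(round(exp(seq(log(E + 2), log(n_pool), length.out = 15))))
    } else sort(unique(pmin(library_sizes, n_pool)))
    sk <- .cross_map_curve(ca2, ef2, E, l, split, sizes)
    ok <- !is.na(sk)
    if (!any(ok)) next
    skill[i] <- sk[max(which(ok))]
    converged[i] <- convergence_test(
      data.frame(library_size = sizes, skill = sk))
  }
  rows <- tibble::tibble(window_start = starts, skill = skill,
                         converged = converged, differenced = differenced)
  conv <- rows$converged & !is.na(rows$skill)
  attr(rows, "n_converged") <- sum(conv)
  attr(rows, "mean_skill") <- if (any(conv)) mean(rows$skill[conv]) else NA_real_
  class(rows) <- c("ccm_windows", class(rows))
  rows
}

#' Phase-randomized (Ebisuzaki) surrogate series
#'
#' Randomizes the Fourier phases of `x` while preserving the amplitude
#' spectrum exactly (DC untouched; the Nyquist component keeps its amplitude
#' and gets a random sign), so the surrogate shares the original's mean,
#' variance and autocorrelation but destroys any nonlinear dependence on
#' other series.
#'
#' @param x Numeric series.
#' @param seed Optional integer seed.
#' @return Numeric surrogate series of the same length.
#' @export
ebisuzaki_surrogate <- function(x, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(x)
  f <- stats::fft(x)
  half <- if (n %% 2 == 0) n / 2 else (n - 1) / 2
  idx <- 2:half  # skip DC; Nyquist handled separately for even n
  ph <- stats::runif(length(idx), 0, 2 * pi)
  f[idx] <- Mod(f[idx]) * exp(1i * ph)
  f[n + 2 - idx] <- Conj(f[idx])
  if (n %% 2 == 0) {
    f[half + 1] <- Mod(f[half + 1]) * sample(c(-1, 1), 1)
  }
  Re(stats::fft(f, inverse = TRUE)) / n
}

#' Surrogate significance test for a cross-map skill
#'
#' Recomputes the cross-map skill with the putative cause replaced by
#' phase-randomized surrogates on a fixed frame (the most recent `frame`
#' samples), and compares the observed skill with the empirical
#' `quantile` of the surrogate skills. Significance requires the observed
#' skill to be *strictly* greater; the observed value is not pooled with the
#' surrogates.
#'
#' @inheritParams cross_map
#' @param n_surrogates Number of surrogates (default 1000; smaller values are
#'   allowed with a warning).
#' @param quantile Null quantile the observed skill must exceed (default 0.9).
#' @param frame Frame length in samples (default 400, shrunk to the series).
#' @param seed Integer seed for the surrogate draws.
#' @return A list: `observed`, `surrogate_q` (the null quantile value),
#'   `significant`, `surrogate_skills`.
#' @export
surrogate_significance <- function(cause, effect, E = 5, l = 2,
                                   n_surrogates = 1000, quantile = 0.9,
                                   frame = 400, split = 0.75, seed = NULL) {
  stopifnot(length(cause) == length(effect), quantile >= 0, quantile <= 1)
  if (n_surrogates < 100) {
    warning("n_surrogates < 100: null quantile will be coarse", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  n <- length(cause)
  use <- max(1L, n - min(frame, n) + 1L):n
  ca <- cause[use]
  ef <- effect[use]
  observed <- .cross_map_skill(ca, ef, E, l, split)
  sur <- vapply(seq_len(n_surrogates), function(i) {
    s <- ebisuzaki_surrogate(ca)
    sk <- .cross_map_skill(s, ef, E, l, split)
    if (is.na(sk)) -Inf else sk
  }, numeric(1))
  qv <- stats::quantile(sur, quantile, names = FALSE, type = 7)
  list(observed = observed,
       surrogate_q = qv,
       significant = isTRUE(observed > qv),
       surrogate_skills = sur)
}
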