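#' Time-delay embedding of a scalar series
#'
#' Builds the lagged coordinate vectors of state-space reconstruction: the
#' vector at time `t` is `(x_t, x_{t-l}, ..., x_{t-(E-1)l})`.
#'
#' @param x Numeric series.
#' @param E Embedding dimension (>= 1).
#' @param l Lag step in samples (>= 1).
#' @return A matrix with `length(x) - (E-1)*l` rows and `E` columns; row
#'   names give the original time index of each vector.
#' @export
delay_embed <- function(x, E, l = 1) {
  x <- as.numeric(x)
  n <- length(x)
  stopifnot(E >= 1, l >= 1)
  span <- (E - 1) * l
  if (n <= span) {
    stop("series too short for E = ", E, ", l = ", l, call. = FALSE)
  }
  times <- (span + 1L):n
  m <- vapply(0:(E - 1L), function(j) x[times - j * l], numeric(length(times)))
  m <- matrix(m, nrow = length(times), ncol = E)
  rownames(m) <- times
  m
}

# Simplex-weight nearest-neighbour prediction.
# libX: library embedding (rows = states); liby: value predicted from each
# library state; tgtX: query states; k: neighbours (E+1 for simplex);
# excl: optional integer vector, per target row, of a library row to exclude
# (leave-one-out). Weights w_i = exp(-d_i/d_1); if d_1 = 0 only
# zero-distance neighbours are used, equally weighted; if all library states
# coincide, weights are uniform.
.simplex_predict <- function(libX, liby, tgtX, k, excl = NULL) {
  nl <- nrow(libX)
  nt <- nrow(tgtX)
  k <- min(k, nl)
  # squared distances via |a|^2 + |b|^2 - 2 a.b
  d2 <- outer(rowSums(tgtX^2), rowSums(libX^2), "+") -
    2 * tcrossprod(tgtX, libX)
  d2[d2 < 0] <- 0
  if (!is.null(excl)) {
    ok <- !is.na(excl)
    d2[cbind(which(ok), excl[ok])] <- Inf
  }
  pred <- numeric(nt)
  for (i in seq_len(nt)) {
    di <- sqrt(d2[i, ])
    nb <- order(di)[seq_len(k)]
    dnb <- di[nb]
    if (!is.finite(dnb[1])) { pred[i] <- NA_real_; next }
    if (dnb[1] == 0) {
      zero <- nb[dnb == 0]
      pred[i] <- mean(liby[zero])
    } else {
      w <- exp(-dnb / dnb[1])
      pred[i] <- sum(w * liby[nb]) / sum(w)
    }
  }
  pred
}

#' Simplex projection forecast
#'
#' Predicts each target state's future as the weighted mean of the futures of
#' its `E + 1` nearest library neighbours in embedding space, with weights
#' `exp(-d_i / d_1)`. Skill is the Pearson correlation between predictions and
#' observations.
#'
#' @param lib Numeric series providing the library (training) states.
#' @param target Numeric series providing the query states and the observed
#'   futures; defaults to `lib`, in which case prediction is leave-one-out.
#' @param E,l Embedding parameters.
#' @param horizon Forecast horizon in samples (default 1).
#' @return A list with `predictions`, `observed`, `time` (target indices of
#'   the predicted values) and `skill`.
#' @export
simplex_forecast <- function(lib, target = NULL, E, l = 1, horizon = 1) {
  loo <- is.null(target)
  if (loo) target <- lib
  libX <- delay_embed(lib, E, l)
  tgtX <- delay_embed(target, E, l)
  lib_t <- as.integer(rownames(libX))
  tgt_t <- as.integer(rownames(tgtX))
  # library states must have an observed future
  keep_lib <- lib_t + horizon <= length(lib)
  libX <- libX[keep_lib, , drop = FALSE]
  liby <- lib[lib_t[keep_lib] + horizon]
  lib_t <- lib_t[keep_lib]
  keep_tgt <- tgt_t + horizon <= length(target)
  tgtX <- tgtX[keep_tgt, , drop = FALSE]
  tgt_t <- tgt_t[keep_tgt]
  obs <- target[tgt_t + horizon]
  if (nrow(libX) < E + 1) stop("library too small (need >= E+1 states)",
                               call. = FALSE)
  excl <- if (loo) match(tgt_t, lib_t) else NULL
  pred <- .simplex_predict(libX, liby, tgtX, k = E + 1L, excl = excl)
  ok <- !is.na(pred)
  skill <- if (sum(ok) > 2 && stats::sd(pred[ok]) > 0 && stats::sd(obs[ok]) > 0) {
    stats::cor(pred[ok], obs[ok])
  } else NA_real_
  list(predictions = pred, observed = obs, time = tgt_t + horizon,
       skill = skill)
}

#' Select the embedding dimension by leave-one-out simplex skill
#'
#' Sweeps `E` over `E_range`, scoring each by leave-one-out simplex
#' projection skill on `x`; ties go to the smaller `E`. The range is silently
#' truncated when the series is too short for its upper end. A selected value
#' above `cap` falls back to the default of 5, keeping the reconstruction in
#' the scope of short- to mid-term dynamics.
#'
#' @param x Numeric series.
#' @param E_range Candidate dimensions (default 1:20).
#' @param l Embedding lag.
#' @param cap Upper bound above which the default is used (default 20).
#' @return Selected `E` (integer).
#' @export
select_embedding_dimension <- function(x, E_range = 1:20, l = 1, cap = 20) {
  n <- length(x)
  feasible <- E_range[(E_range - 1) * l + E_range + 2 < n]
  if (length(feasible) == 0) stop("series too short for any candidate E",
                                  call. = FALSE)
  skills <- vapply(feasible, function(E) {
    s <- simplex_forecast(x, E = E, l = l)$skill
    if (is.na(s)) -Inf else s
  }, numeric(1))
  best <- feasible[which.max(skills)]  # which.max takes the first (smallest E) on ties
  if (best > cap) best <- 5L
  as.integer(best)
}

# Histogram mutual information between x and y, ceiling(sqrt(n/5)) bins/axis.
.mutual_information <- function(x, y) {
  n <- length(x)
  nb <- max(2L, ceiling(sqrt(n / 5)))
  bx <- cut(x, breaks = nb, labels = FALSE, include.lowest = TRUE)
  by <- cut(y, breaks = nb, labels = FALSE, include.lowest = TRUE)
  joint <- table(bx, by) / n
  px <- rowSums(joint)
  py <- colSums(joint)
  nz <- joint > 0
  sum(joint[nz] * log(joint[nz] / outer(px, py)[nz]))
}

#' Select the embedding lag from the first minimum of mutual information
#'
#' Computes the histogram mutual information between `x` and its lagged copy
#' for lags 1..`max_lag + 1` and returns the first interior minimum (MI below
#' both neighbours; lag 0 counts as the self-information, which always
#' exceeds lag 1). If no interior minimum occurs within `max_lag`, the
#' default of 2 is returned.
#'
#' @param x Numeric series.
#' @param max_lag Largest lag considered (default 20).
#' @param default Fallback lag (default 2).
#' @return Selected lag (integer).
#' @export
select_lag <- function(x, max_lag = 20, default = 2) {
  n <- length(x)
  max_lag <- min(max_lag, n %/% 4)
  if (max_lag < 1) return(as.integer(default))
  mi <- vapply(0:(max_lag + 1L), function(k) {
    if (k == 0) return(.mutual_information(x, x))
    if (n - k < 10) return(NA_real_)
    .mutual_information(x[1:(n - k)], x[(k + 1):n])
  }, numeric(1))
  # centered 3-point moving average damps histogram jitter before the
  # first-minimum search (lag 0, the self-information, is left untouched)
  if (length(mi) >= 4) {
    sm <- stats::filter(mi[-1], rep(1 / 3, 3), sides = 2)
    sm[is.na(sm)] <- mi[-1][is.na(sm)]
    mi <- c(mi[1], as.numeric(sm))
  }
  # first interior minimum; additionally, a lag whose MI has already come
  # within 10% of the curve's range above its global minimum counts as the
  # first minimum (a chaotic or white series whose MI collapses to the noise
  # floor at once then selects a small lag rather than a jitter artifact).
  lag_mi <- mi[-1]
  ok <- which(!is.na(lag_mi))
  if (length(ok) == 0) return(as.integer(default))
  # the floor shortcut only applies when the global minimum is interior to
  # the scanned range; a monotone-decreasing curve (minimum at the boundary)
  # has no first minimum and falls through to the default
  interior_min <- which.min(lag_mi[ok]) < length(ok)
  floor_lev <- min(lag_mi[ok]) + 0.1 * diff(range(lag_mi[ok]))
  for (k in seq_len(max_lag)) {
    if (is.na(mi[k + 1]) || is.na(mi[k + 2])) break
    if (interior_min && mi[k + 1] <= floor_lev) return(as.integer(k))
    if (mi[k + 1] < mi[k] && mi[k + 1] < mi[k + 2]) return(as.integer(k))
  }
  as.integer(default)
}

#' S-map test of state-dependent (nonlinear) dynamics
#'
#' Sequential locally weighted global linear maps: for each query state the
#' regression of futures on states is weighted by `exp(-theta * d / dbar)`
#' where `dbar` is the mean distance to the query. At `theta = 0` the method
#' reduces to a single global linear forecast; improving skill at
#' `theta > 0` indicates state dependence, the empirical-dynamic-modeling
#' signature of nonlinearity.
#'
#' @param x Numeric series.
#' @param theta_grid Nonlinearity parameter grid (default the conventional
#'   0..8 grid).
#' @param E,l Embedding parameters.
#' @param horizon Forecast horizon (default 1).
#' @param tol Skill improvement over `theta = 0` required to flag
#'   nonlinearity (default 0.01).
#' @return A tibble with columns `theta` and `skill`, with attribute
#'   `nonlinear` (logical).
#' @export
smap_nonlinearity <- function(x, theta_grid = c(0, 0.1, 0.25, 0.5, 0.75, 1,
                                                1.5, 2, 3, 4, 6, 8),
                              E, l = 1, horizon = 1, tol = 0.01) {
  X <- delay_embed(x, E, l)
  t_idx <- as.integer(rownames(X))
  keep <- t_idx + horizon <= length(x)
  X <- X[keep, , drop = FALSE]
  y <- x[t_idx[keep] + horizon]
  n <- nrow(X)
  d2 <- outer(rowSums(X^2), rowSums(X^2), "+") - 2 * tcrossprod(X)
  d2[d2 < 0] <- 0
  d <- sqrt(d2)
  Xd <- cbind(1, X)
  p <- ncol(Xd)
  ridge <- diag(1e-8, p)
  skills <- vapply(theta_grid, function(theta) {
    pred <- vapply(seq_len(n), function(i) {
      di <- d[i, ]
      di[i] <- NA  # leave-one-out
      dbar <- mean(di, na.rm = TRUE)
      w <- if (theta == 0 || dbar == 0) rep(1, n) else exp(-theta * di / dbar)
      w[i] <- 0
      w[is.na(w)] <- 0
      sw <- sqrt(w)
      A <- Xd * sw
      b <- y * sw
      coef <- solve(crossprod(A) + ridge, crossprod(A, b))
      sum(Xd[i, ] * coef)
    }, numeric(1))
    if (stats::sd(pred) == 0 || stats::sd(y) == 0) return(NA_real_)
    stats::cor(pred, y)
  }, numeric(1))
  out <- tibble::tibble(theta = theta_grid, skill = skills)
  s0 <- skills[theta_grid == 0][1]
  pos <- skills[theta_grid > 0]
  attr(out, "nonlinear") <- length(pos) > 0 && !all(is.na(pos)) &&
    isTRUE(max(pos, na.rm = TRUE) > s0 + tol)
  class(out) <- c("smap_result", class(out))
  out
}
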