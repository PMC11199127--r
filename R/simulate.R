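#' Simulate the four-species coupled logistic validation system
#'
#' Iterates a discrete-time four-species system with chained direct
#' couplings (Y1 drives Y2, Y2 drives Y3, Y3 drives Y4) plus logistic
#' self-dynamics:
#'
#' \deqn{Y1_{t+1} = Y1_t (3.9 - 3.9 Y1_t)}
#' \deqn{Y2_{t+1} = Y2_t (3.6 - 0.4 Y1_t - 3.6 Y2_t)}
#' \deqn{Y3_{t+1} = Y3_t (3.6 - 0.4 Y2_t - 3.6 Y3_t)}
#' \deqn{Y4_{t+1} = Y4_t (3.8 - 0.35 Y3_t - 3.8 Y4_t)}
#'
#' The chain induces indirect dependencies (Y1 on Y3 and Y4, Y2 on Y4) that a
#' causal-inference method should *not* confuse with direct ones, which is what
#' makes the system a useful validation harness for cross mapping.
#'
#' In the `"heterogeneous"` regime the couplings into and out of Y2 and Y3 are
#' weakened over the final `weaken_fraction` of the series by multiplying Y2
#' and Y3 by i.i.d. uniform noise inside the iteration (see
#' [heterogenize()]), emulating an ecosystem whose interaction strengths
#' drift over time.
#'
#' @param n_steps Number of time steps returned (after burn-in). Must be
#'   at least 50.
#' @param init Numeric vector of 4 initial values, each in (0, 1).
#' @param regime `"homogeneous"` (deterministic) or `"heterogeneous"`
#'   (coupling weakened over the tail of the run).
#' @param weaken_fraction Fraction of the returned series (from the end) over
#'   which couplings are weakened in the heterogeneous regime. Default 2/3.
#' @param noise_low,noise_high Bounds of the uniform multiplicative noise
#'   applied to Y2 and Y3 in the heterogeneous regime. Defaults 0.5 and 1.5.
#' @param seed Integer seed controlling the heterogeneous noise draws.
#' @param burn_in Steps discarded from the start so analyses see
#'   post-transient dynamics. Default 100. Set 0 to inspect the raw orbit.
#' @return A tibble with columns `time` (1..n_steps) and `Y1`..`Y4`, carrying
#'   attribute `ground_truth` (see [four_species_ground_truth()]).
#' @examples
#' sim <- simulate_four_species(500, seed = 1)
#' head(sim)
#' @export
simulate_four_species <- function(n_steps,
                                  init = c(0.4, 0.4, 0.4, 0.4),
                                  regime = c("homogeneous", "heterogeneous"),
                                  weaken_fraction = 2 / 3,
                                  noise_low = 0.5,
                                  noise_high = 1.5,
                                  seed = NULL,
                                  burn_in = 100) {
  regime <- match.arg(regime)
  stopifnot(n_steps >= 50, length(init) == 4,
            weaken_fraction >= 0, weaken_fraction <= 1,
            noise_low <= noise_high, burn_in >= 0)
  if (any(init < 0) || any(init > 1)) {
    stop("initial values must lie in (0, 1)", call. = FALSE)
  }
  total <- n_steps + burn_in
  # noise multipliers hit Y2/Y3 only over the weakened tail of the run
  noisy_from <- total - floor(weaken_fraction * n_steps) + 1L
  mult <- matrix(1, nrow = total, ncol = 2)
  if (regime == "heterogeneous") {
    if (!is.null(seed)) set.seed(seed)
    n_noisy <- total - noisy_from + 1L
    if (n_noisy > 0) {
      mult[noisy_from:total, ] <- stats::runif(2L * n_noisy, noise_low, noise_high)
    }
  }
  y <- matrix(NA_real_, nrow = total, ncol = 4,
              dimnames = list(NULL, c("Y1", "Y2", "Y3", "Y4")))
  y[1, ] <- init
  for (t in seq_len(total - 1L)) {
    s <- y[t, ]
    if (regime == "heterogeneous" && t >= noisy_from) {
      s[2] <- min(max(s[2] * mult[t, 1], 0), 1)
      s[3] <- min(max(s[3] * mult[t, 2], 0), 1)
    }
    nxt <- c(
      s[1] * (3.9 - 3.9 * s[1]),
      s[2] * (3.6 - 0.4 * s[1] - 3.6 * s[2]),
      s[3] * (3.6 - 0.4 * s[2] - 3.6 * s[3]),
      s[4] * (3.8 - 0.35 * s[3] - 3.8 * s[4])
    )
    if (any(abs(nxt) > 10)) {
      stop("trajectory diverged (|Y| > 10): invalid initial condition",
           call. = FALSE)
    }
    # a noise excursion can push the update negative; zero is absorbing for
    # every rule, so a clip to exactly 0 would extinguish the species for the
    # rest of the run. Floor negative updates at a tiny biomass instead: the
    # logistic term regrows it within a few steps. Exact zeros stay zero.
    nxt[nxt < 0] <- 1e-4
    y[t + 1L, ] <- pmin(nxt, 1)
  }
  out <- tibble::as_tibble(y[(burn_in + 1L):total, , drop = FALSE])
  out <- dplyr::mutate(out, time = dplyr::row_number(), .before = 1)
  attr(out, "ground_truth") <- four_species_ground_truth()
  out
}

#' Ground-truth causal structure of the four-species system
#'
#' @return A tibble of edges with columns `source`, `target`, `type`
#'   (`"direct"` or `"indirect"`) and `lag_steps` (1 for every direct edge:
#'   each update reads the driver at the previous step).
#' @export
four_species_ground_truth <- function() {
  tibble::tibble(
    source = c("Y1", "Y2", "Y3", "Y1", "Y1", "Y2"),
    target = c("Y2", "Y3", "Y4", "Y3", "Y4", "Y4"),
    type = c(rep("direct", 3), rep("indirect", 3)),
    lag_steps = c(1L, 1L, 1L, NA_integer_, NA_integer_, NA_integer_)
  )
}

#' Weaken the couplings of an existing homogeneous run
#'
#' Re-runs the four-species iteration from the first row of `series`,
#' multiplying Y2 and Y3 by i.i.d. Uniform(noise_low, noise_high) draws inside
#' the loop over the final `weaken_fraction` of the rows (then clipping to
#' [0, 1]), so the weakening propagates dynamically through the couplings.
#' With `noise_low = noise_high = 1` or `weaken_fraction = 0` the input is
#' returned unchanged.
#'
#' @param series A tibble from [simulate_four_species()] (homogeneous).
#' @inheritParams simulate_four_species
#' @return A tibble of the same shape as `series`.
#' @export
heterogenize <- function(series, weaken_fraction = 2 / 3,
                         noise_low = 0.5, noise_high = 1.5, seed = NULL) {
  stopifnot(all(c("Y1", "Y2", "Y3", "Y4") %in% names(series)),
            weaken_fraction >= 0, weaken_fraction <= 1,
            noise_low <= noise_high)
  if (weaken_fraction == 0 || (noise_low == 1 && noise_high == 1)) {
    return(series)
  }
  n <- nrow(series)
  init <- as.numeric(series[1, c("Y1", "Y2", "Y3", "Y4")])
  out <- simulate_four_species(
    n_steps = n, init = init, regime = "heterogeneous",
    weaken_fraction = weaken_fraction, noise_low = noise_low,
    noise_high = noise_high, seed = seed, burn_in = 0
  )
  out$time <- series$time
  attr(out, "ground_truth") <- attr(series, "ground_truth")
  out
}

#' Simulate a lake-like seasonal multivariate series with known lagged edges
#'
#' A synthetic fixture for end-to-end pipeline and Bayesian-network tests:
#' each variable follows a seasonal sinusoid (phase-shifted per variable) plus
#' Gaussian noise, and each declared edge adds a lagged linear dependence of
#' the child on the parent. The declared edges must form a DAG.
#'
#' This fixture emulates the gross statistical shape of lake monitoring data
#' (seasonality, lagged drivers, noise); it is not a mechanistic lake model.
#'
#' @param n_steps Series length.
#' @param edges A data frame with columns `source`, `target`, `lag_steps`
#'   (positive integer: child at `t` depends on parent at `t - lag_steps`)
#'   and optionally `strength` (default 0.8). `NULL` for independent
#'   sinusoids.
#' @param variables Character vector of variable names; defaults to the nodes
#'   of `edges`, or `c("A","B","C")` when `edges` is `NULL`.
#' @param seasonal_period Period of the seasonal component in samples
#'   (default 73, i.e. one year at a 5-day step).
#' @param seasonal_amp Amplitude of the seasonal component (default 1).
#' @param noise_sd Standard deviation of the additive Gaussian noise.
#' @param step_days Spacing of the emitted time axis in days (default 5),
#'   so the fixture is already on the standard resampling grid.
#' @param seed Integer seed.
#' @return A tibble with `time` plus one column per variable; attribute
#'   `ground_truth` holds the declared edge table.
#' @examples
#' edges <- tibble::tibble(source = "A", target = "B", lag_steps = 3)
#' sim <- simulate_lake_like(200, edges, noise_sd = 0, seed = 1)
#' @export
simulate_lake_like <- function(n_steps, edges = NULL, variables = NULL,
                               seasonal_period = 73, seasonal_amp = 1,
                               noise_sd = 0.1, step_days = 5, seed = NULL) {
  stopifnot(n_steps >= 10)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(edges)) {
    edges <- tibble::tibble(source = character(), target = character(),
                            lag_steps = integer())
  }
  edges <- tibble::as_tibble(edges)
  if (nrow(edges) > 0 && !"strength" %in% names(edges)) edges$strength <- 0.8
  if (is.null(variables)) {
    variables <- unique(c(edges$source, edges$target))
    if (length(variables) == 0) variables <- c("A", "B", "C")
  }
  if (nrow(edges) > 0) {
    g <- igraph::graph_from_data_frame(edges[, c("source", "target")],
                                       vertices = variables)
    if (!igraph::is_dag(g)) {
      stop("declared edges contain a cycle; the ground truth must be a DAG",
           call. = FALSE)
    }
    order_names <- names(igraph::topo_sort(g))
  } else {
    order_names <- variables
  }
  k <- length(variables)
  phases <- stats::runif(k, 0, 2 * pi)
  names(phases) <- variables
  t_idx <- seq_len(n_steps)
  vals <- matrix(0, nrow = n_steps, ncol = k,
                 dimnames = list(NULL, variables))
  for (v in order_names) {
    x <- seasonal_amp * sin(2 * pi * t_idx / seasonal_period + phases[[v]])
    if (noise_sd > 0) x <- x + stats::rnorm(n_steps, 0, noise_sd)
    par_edges <- edges[edges$target == v, , drop = FALSE]
    if (nrow(par_edges) > 0) {
      for (i in seq_len(nrow(par_edges))) {
        p <- par_edges$source[i]
        lag <- par_edges$lag_steps[i]
        shifted <- c(rep(vals[1, p], lag), vals[seq_len(n_steps - lag), p])
        x <- x + par_edges$strength[i] * shifted
      }
    }
    vals[, v] <- x
  }
  out <- tibble::as_tibble(vals)
  out <- dplyr::mutate(out, time = t_idx * step_days, .before = 1)
  attr(out, "ground_truth") <- edges
  attr(out, "step_days") <- step_days
  out
}
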