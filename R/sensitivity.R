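#' Random environmental scenarios and their inferred bloom probabilities
#'
#' Draws up to `n` distinct category assignments over all non-target nodes
#' (uniformly; when the full category space holds at most `n` assignments it
#' is enumerated exhaustively) and infers P(target = high) for each.
#'
#' @param bn A `bayes_net`.
#' @param n Maximum number of scenarios (default 20000).
#' @param seed Integer seed.
#' @return A `scenario_set`: tibble with one column per non-target node plus
#'   `prob`; attributes `target` and `seed`.
#' @export
random_scenarios <- function(bn, n = 20000, seed = NULL) {
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  inputs <- setdiff(bn$nodes, bn$target)
  cards <- bn$cardinalities[inputs]
  space <- prod(cards)
  if (space <= n) {
    grid <- do.call(expand.grid, lapply(cards, function(k) 0:(k - 1)))
  } else {
    draws <- vapply(cards, function(k) sample.int(k, n, replace = TRUE) - 1L,
                    integer(n))
    grid <- unique(as.data.frame(draws))
  }
  names(grid) <- inputs
  probs <- vapply(seq_len(nrow(grid)), function(r) {
    infer(bn, as.list(grid[r, , drop = FALSE]))[["1"]]
  }, numeric(1))
  out <- tibble::as_tibble(grid)
  out$prob <- probs
  attr(out, "target") <- bn$target
  attr(out, "seed") <- seed
  class(out) <- c("scenario_set", class(out))
  out
}

#' Per-variable contribution to the model output
#'
#' Residuals are scenario probabilities centred on their mean. For each
#' variable the bloom-maximizing term identifies the variable's most
#' frequent category among the scenarios with P > 0.5 and takes the mean
#' residual over *all* scenarios in that category; the minimizing term
#' mirrors this for P < 0.5. The contribution is the sum of the two absolute
#' values. A variable whose state does not move the output has residuals
#' that cancel within any of its categories, so its contribution is near 0;
#' a strong driver's bloom-favouring state collects the positive residuals
#' and scores high.
#'
#' @param scenarios A `scenario_set`.
#' @return Tibble with columns `variable`, `m_max`, `m_min`, `contribution`,
#'   sorted by decreasing contribution.
#' @export
variable_contributions <- function(scenarios) {
  vars <- setdiff(names(scenarios), "prob")
  res <- scenarios$prob - mean(scenarios$prob)
  hi <- scenarios$prob > 0.5
  lo <- scenarios$prob < 0.5
  side_mean <- function(v, side) {
    if (!any(side)) return(0)
    modal <- as.integer(names(which.max(table(scenarios[[v]][side]))))
    mean(res[scenarios[[v]] == modal])
  }
  out <- purrr::map_dfr(vars, function(v) {
    m_max <- side_mean(v, hi)
    m_min <- side_mean(v, lo)
    tibble::tibble(variable = v, m_max = m_max, m_min = m_min,
                   contribution = abs(m_max) + abs(m_min))
  })
  dplyr::arrange(out, dplyr::desc(.data$contribution))
}

#' Mean blooming and non-blooming scenario profiles
#'
#' The mean category of every input variable over the scenarios whose
#' inferred probability exceeds `cutoff` (the blooming profile) and over
#' those below it (the non-blooming profile). Ties at exactly `cutoff`
#' belong to neither side.
#'
#' @param scenarios A `scenario_set`.
#' @param cutoff Probability cutoff (default 0.5).
#' @return Tibble with columns `variable`, `maximizing`, `minimizing`;
#'   attributes `n_max` and `n_min` give the side counts.
#' @export
mean_scenarios <- function(scenarios, cutoff = 0.5) {
  vars <- setdiff(names(scenarios), "prob")
  hi <- scenarios$prob > cutoff
  lo <- scenarios$prob < cutoff
  out <- purrr::map_dfr(vars, function(v) {
    tibble::tibble(
      variable = v,
      maximizing = if (any(hi)) mean(scenarios[[v]][hi]) else NA_real_,
      minimizing = if (any(lo)) mean(scenarios[[v]][lo]) else NA_real_
    )
  })
  attr(out, "n_max") <- sum(hi)
  attr(out, "n_min") <- sum(lo)
  out
}
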