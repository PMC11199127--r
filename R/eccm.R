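#' Extended CCM: cross-map skill as a function of time shift
#'
#' For each shift `s` in `-shifts..shifts`, the effect's manifold is asked to
#' predict the cause displaced by `s` samples, in both directions of the pair.
#' A genuine cause can only influence the present or future of its effect, so
#' the effect's manifold best recovers *past* values of the cause: the
#' optimal shift of a true interaction is non-positive, and its position
#' estimates the cause-to-effect delay. The pattern of optimal shifts in the
#' two directions separates unidirectional and bidirectional coupling from
#' synchrony (see [classify_interaction()]).
#'
#' `skill_xy(s)` is the skill of Y's manifold predicting `x(t + s)` (the
#' "X causes Y" direction); `skill_yx(s)` is the mirror.
#'
#' @param x,y Aligned numeric series.
#' @param E,l Embedding parameters (defaults 5 and 2).
#' @param frame Number of most recent samples analysed (default 400; shrunk
#'   with a warning, never below 100, when the pair is shorter).
#' @param max_library Library-size cap for the cross map (default 200).
#' @param shifts Half-width of the shift grid in samples (default 20).
#' @param split Library fraction (default 0.75).
#' @param sync_tol Skill-difference tolerance declaring two instantaneous
#'   optima "of similar magnitude" (default 0.05).
#' @param tie_tol Skills within this distance of the maximum count as tied
#'   when locating the optimal shift; ties resolve toward shift 0
#'   (default 0.05, the same similar-skill scale as `sync_tol`).
#' @return An `eccm_profile`: tibble with columns `shift`, `skill_xy`,
#'   `skill_yx`; attributes `opt_lag_xy`, `opt_lag_yx` (argmax shifts, ties
#'   toward 0), `peak_xy`, `peak_yx`, and `classification`.
#' @export
eccm_scan <- function(x, y, E = 5, l = 2, frame = 400, max_library = 200,
                      shifts = 20, split = 0.75, sync_tol = 0.05,
                      tie_tol = 0.05) {
  n <- length(x)
  stopifnot(length(y) == n, shifts >= 1)
  need <- frame + shifts
  if (n < need) {
    frame <- max(100L, n - shifts)
    if (n < frame + shifts) stop("series too short for the shift grid",
                                 call. = FALSE)
    warning("frame shrunk to ", frame, " samples", call. = FALSE)
  }
  grid <- (-shifts):shifts
  one_dir <- function(cause, effect) {
    vapply(grid, function(s) {
      # effect at t predicts cause at t + s
      if (s >= 0) {
        ca <- cause[(1 + s):n]
        ef <- effect[1:(n - s)]
      } else {
        ca <- cause[1:(n + s)]
        ef <- effect[(1 - s):n]
      }
      m <- length(ca)
      use <- (m - min(frame, m) + 1L):m
      ca <- ca[use]; ef <- ef[use]
      sk <- .cross_map_skill(ca, ef, E, l, split,
                             lib_size = max_library)
      if (is.na(sk)) 0 else sk
    }, numeric(1))
  }
  skill_xy <- one_dir(x, y)
  skill_yx <- one_dir(y, x)
  pick <- function(sk) {
    # shifts within tie_tol of the best skill count as tied; the tie goes to
    # the shift closest to 0. Without a tolerance, a lagged-copy pair ties
    # across every shift at which the copy appears as an embedding
    # coordinate and sampling jitter would decide the optimum.
    best <- max(sk)
    cand <- grid[sk >= best - tie_tol]
    cand[which.min(abs(cand))]
  }
  out <- tibble::tibble(shift = grid, skill_xy = skill_xy,
                        skill_yx = skill_yx)
  attr(out, "opt_lag_xy") <- pick(skill_xy)
  attr(out, "opt_lag_yx") <- pick(skill_yx)
  attr(out, "peak_xy") <- max(skill_xy)
  attr(out, "peak_yx") <- max(skill_yx)
  attr(out, "classification") <- classify_interaction(out, sync_tol = sync_tol)
  class(out) <- c("eccm_profile", class(out))
  out
}

#' Classify an interaction from its extended-CCM profile
#'
#' Rule table over the optimal shifts (`oxy`, `oyx`) and peak skills of the
#' two directions:
#' \itemize{
#'   \item both optima at 0 with peak skills within `sync_tol`: both
#'     variables respond instantaneously to a strong common force
#'     (`synchrony_common_force`);
#'   \item `oxy < 0` and `oyx > 0`: X enslaves Y through synchrony
#'     (`synchrony_enslaved_xy`); mirrored for `synchrony_enslaved_yx`;
#'   \item both optima negative (or one negative, one 0, both peaks at least
#'     `min_skill`): `bidirectional`;
#'   \item exactly one direction with a non-positive optimum and peak at
#'     least `min_skill`: `unidirectional_xy` / `unidirectional_yx`;
#'   \item otherwise (best lag strictly positive in the claimed direction, or
#'     no peak reaching `min_skill`): `false_interaction`.
#' }
#'
#' @param profile An `eccm_profile` (or a list with `opt_lag_xy`,
#'   `opt_lag_yx`, `peak_xy`, `peak_yx` entries).
#' @param sync_tol Similar-magnitude tolerance (default 0.05).
#' @param min_skill Minimal peak skill for a real interaction (default 0.01).
#' @return A single classification string.
#' @export
classify_interaction <- function(profile, sync_tol = 0.05, min_skill = 0.01) {
  g <- function(nm) {
    v <- attr(profile, nm)
    if (is.null(v)) v <- profile[[nm]]
    v
  }
  oxy <- g("opt_lag_xy"); oyx <- g("opt_lag_yx")
  pxy <- g("peak_xy"); pyx <- g("peak_yx")
  # below the skill floor no lag pattern is interpretable
  if (max(pxy, pyx) < min_skill) return("false_interaction")
  if (oxy == 0 && oyx == 0 && abs(pxy - pyx) < sync_tol) {
    return("synchrony_common_force")
  }
  if (oxy < 0 && oyx > 0) return("synchrony_enslaved_xy")
  if (oyx < 0 && oxy > 0) return("synchrony_enslaved_yx")
  q_xy <- oxy <= 0 && pxy >= min_skill
  q_yx <- oyx <= 0 && pyx >= min_skill
  if (oxy < 0 && oyx < 0) return("bidirectional")
  if (q_xy && q_yx && (oxy < 0 || oyx < 0)) return("bidirectional")
  if (q_xy && !q_yx) return("unidirectional_xy")
  if (q_yx && !q_xy) return("unidirectional_yx")
  "false_interaction"
}

#' Convert a shift-grid lag to a delay in days
#'
#' @param opt_lag Optimal lag in grid samples (usually non-positive).
#' @param step_days Grid step in days (default 5).
#' @return Delay in days (non-negative).
#' @export
lag_to_days <- function(opt_lag, step_days = 5) {
  abs(opt_lag) * step_days
}
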