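#' @keywords internal
#' Split a series tibble into its time column and value columns.
split_series <- function(data, time_col = NULL) {
  data <- tibble::as_tibble(data)
  if (is.null(time_col)) {
    nm <- names(data)
    time_col <- if ("time" %in% nm) "time" else if ("date" %in% nm) "date" else nm[1]
  }
  vars <- setdiff(names(data), time_col)
  list(time = data[[time_col]], time_col = time_col, vars = vars,
       values = data[vars])
}

#' Replace extreme values by interpolation
#'
#' Cells whose absolute z-score (population standard deviation) meets or
#' exceeds `z_threshold` are treated as recording artifacts: they are dropped
#' and refilled by linear interpolation between the nearest retained
#' neighbours (nearest retained value at the boundaries). Flagging is a
#' single pass; constant columns are passed through untouched.
#'
#' @param data A tibble with a time column plus numeric variable columns.
#' @param z_threshold Z-score at or above which a cell is an outlier
#'   (default 3). `Inf` disables flagging.
#' @param time_col Name of the time column; auto-detected by default.
#' @return A tibble of the same shape.
#' @export
remove_outliers <- function(data, z_threshold = 3, time_col = NULL) {
  s <- split_series(data, time_col)
  out <- s$values
  for (v in s$vars) {
    x <- out[[v]]
    ok <- !is.na(x)
    sdev <- sqrt(mean((x[ok] - mean(x[ok]))^2))  # population sd
    if (!is.finite(sdev) || sdev == 0) next
    z <- abs(x - mean(x[ok])) / sdev
    bad <- !is.na(z) & z >= z_threshold
    if (all(bad[ok])) {
      stop("column '", v, "': every value flagged as an outlier", call. = FALSE)
    }
    if (any(bad)) {
      keep <- which(!bad & ok)
      x[bad] <- stats::approx(keep, x[keep], xout = which(bad),
                              rule = 2)$y
      out[[v]] <- x
    }
  }
  res <- dplyr::bind_cols(tibble::tibble(!!s$time_col := s$time), out)
  tibble::as_tibble(res)
}

#' Resample a series onto a uniform grid
#'
#' Observations are averaged over duplicated timestamps, then each variable is
#' linearly interpolated onto a uniform grid of spacing `step_days` spanning
#' the observed range (no extrapolation).
#'
#' @inheritParams remove_outliers
#' @param step_days Grid spacing in the units of the time column (default 5).
#' @return A tibble on the uniform grid, time column named as in the input.
#' @export
resample_series <- function(data, step_days = 5, time_col = NULL) {
  s <- split_series(data, time_col)
  t_num <- as.numeric(s$time)
  ord <- order(t_num)
  t_num <- t_num[ord]
  vals <- s$values[ord, , drop = FALSE]
  # average duplicates
  if (anyDuplicated(t_num)) {
    grp <- match(t_num, unique(t_num))
    vals <- dplyr::summarise(
      dplyr::group_by(dplyr::mutate(vals, .grp = grp), .data$.grp),
      dplyr::across(dplyr::everything(), ~ mean(.x, na.rm = TRUE))
    )[, -1]
    t_num <- unique(t_num)
  }
  grid <- seq(t_num[1], t_num[length(t_num)], by = step_days)
  out <- purrr::map_dfc(vals, function(x) {
    ok <- !is.na(x)
    if (sum(ok) < 2) stop("fewer than 2 observations in a column", call. = FALSE)
    stats::approx(t_num[ok], x[ok], xout = grid, rule = 2)$y
  })
  res <- dplyr::bind_cols(tibble::tibble(!!s$time_col := grid), out)
  attr(res, "step_days") <- step_days
  res
}

#' Min-max normalize each variable to [0, 1]
#'
#' Each column is mapped by (x - min) / (max - min); a constant column maps
#' to 0. Cross-map skill is scale-invariant but a common [0, 1] range keeps
#' embedding-space distances comparable across variables.
#'
#' @inheritParams remove_outliers
#' @return A tibble of the same shape with all variables in [0, 1].
#' @export
normalize_minmax <- function(data, time_col = NULL) {
  s <- split_series(data, time_col)
  out <- purrr::map_dfc(s$values, function(x) {
    rng <- range(x, na.rm = TRUE)
    if (diff(rng) == 0) return(rep(0, length(x)))
    (x - rng[1]) / diff(rng)
  })
  dplyr::bind_cols(tibble::tibble(!!s$time_col := s$time), out)
}

# ---- Augmented Dickey-Fuller test ------------------------------------------

# MacKinnon (2010) response-surface coefficients, constant-only case.
# cv(level, T) = b0 + b1/T + b2/T^2 + b3/T^3
.adf_cv_tab <- rbind(
  `0.01` = c(-3.43035, -6.5393, -16.786, -79.433),
  `0.05` = c(-2.86154, -2.8903, -4.234, -40.040),
  `0.10` = c(-2.56677, -1.5384, -2.809, 0)
)

#' Augmented Dickey-Fuller unit-root test (constant term)
#'
#' Fits the regression \eqn{\Delta y_t = a + \gamma y_{t-1} + \sum_i \phi_i
#' \Delta y_{t-i} + e_t} with the augmentation order chosen by AIC over
#' 0..`max_lag`, and compares the t-statistic of \eqn{\gamma} with MacKinnon
#' (2010) finite-sample critical values. The null hypothesis is a unit root;
#' rejection means the series looks stationary.
#'
#' @param x Numeric series, length at least 25.
#' @param max_lag Maximum augmentation order; default
#'   `trunc(4 * (n/100)^0.25)` (Schwert's short rule).
#' @return A list with `statistic`, `lag`, `reject_unit_root` (at the 0.05
#'   level), and approximate `p_value` interpolated between tabulated levels.
#' @export
adf_test <- function(x, max_lag = NULL) {
  x <- as.numeric(x)
  n <- length(x)
  stopifnot(n >= 25)
  if (stats::sd(x) == 0) {
    return(list(statistic = -Inf, lag = 0L, reject_unit_root = TRUE,
                p_value = 0))
  }
  if (is.null(max_lag)) max_lag <- min(trunc(4 * (n / 100)^0.25), n %/% 3)
  dx <- diff(x)
  best <- NULL
  for (p in 0:max_lag) {
    nn <- length(dx) - p
    yy <- dx[(p + 1):length(dx)]
    X <- cbind(1, x[(p + 1):(n - 1)])
    if (p > 0) {
      for (i in seq_len(p)) X <- cbind(X, dx[(p + 1 - i):(length(dx) - i)])
    }
    fit <- stats::lm.fit(X, yy)
    rss <- sum(fit$residuals^2)
    k <- ncol(X)
    aic <- nn * log(rss / nn) + 2 * k
    if (is.null(best) || aic < best$aic) best <- list(aic = aic, fit = fit,
                                                     X = X, rss = rss, p = p,
                                                     nn = nn)
  }
  fit <- best$fit
  sigma2 <- best$rss / (best$nn - ncol(best$X))
  XtXinv <- chol2inv(chol(crossprod(best$X)))
  se <- sqrt(sigma2 * XtXinv[2, 2])
  stat <- fit$coefficients[2] / se
  cv <- .adf_cv_tab %*% c(1, 1 / n, 1 / n^2, 1 / n^3)
  levels <- as.numeric(rownames(.adf_cv_tab))
  p_value <- stats::approx(c(min(cv) - 10, cv, 1), c(1e-4, levels, 0.9),
                           xout = stat, rule = 2, ties = "ordered")$y
  list(statistic = unname(stat), lag = best$p,
       reject_unit_root = unname(stat < cv["0.05", ]),
       p_value = unname(p_value))
}

#' Difference a segment when it fails a stationarity check
#'
#' Applies [adf_test()]; if the unit-root null is not rejected at the 0.05
#' level the first difference is returned (one sample shorter), otherwise the
#' segment is returned unchanged. Constant segments are treated as stationary.
#'
#' @param x Numeric segment, length at least 25.
#' @return Numeric vector with attribute `differenced` (logical).
#' @export
ensure_stationary <- function(x) {
  x <- as.numeric(x)
  stopifnot(length(x) >= 25)
  if (stats::sd(x) == 0) {
    attr(x, "differenced") <- FALSE
    return(x)
  }
  res <- adf_test(x)
  if (!res$reject_unit_root) {
    out <- diff(x)
    attr(out, "differenced") <- TRUE
    out
  } else {
    attr(x, "differenced") <- FALSE
    x
  }
}

#' Categorize a series table for discrete Bayesian-network fitting
#'
#' Predictors are coded 0/1/2 at their tertiles by default (or at
#' user-supplied cutoffs); the target is coded 0/1 at its 0.75 quantile (the
#' "bloom" threshold). Intervals are left-closed, right-open except the last,
#' so a target exactly at its threshold codes as 1 ("high"). Cutoffs are
#' stored so test data can be recoded consistently.
#'
#' Categorization operates on the resampled raw values, not min-max-normalized
#' ones: quantile codes are scale-invariant and stored cutoffs stay in
#' measurement units.
#'
#' @inheritParams remove_outliers
#' @param target Name of the target variable (coded 0/1).
#' @param cutoffs Optional named list of numeric cutoff vectors per variable;
#'   variables absent from the list fall back to the quantile rule.
#' @param target_quantile Quantile defining the target's "high" state
#'   (default 0.75).
#' @return An object of class `discrete_table`: a tibble of integer codes
#'   (plus the time column), with attributes `cutoffs` (named list) and
#'   `target`.
#' @export
categorize <- function(data, target, cutoffs = NULL,
                       target_quantile = 0.75, time_col = NULL) {
  s <- split_series(data, time_col)
  stopifnot(target %in% s$vars)
  used <- list()
  out <- s$values
  for (v in s$vars) {
    x <- out[[v]]
    if (!is.null(cutoffs) && v %in% names(cutoffs)) {
      cuts <- sort(as.numeric(cutoffs[[v]]))
    } else if (v == target) {
      cuts <- stats::quantile(x, target_quantile, na.rm = TRUE, names = FALSE)
    } else {
      cuts <- stats::quantile(x, c(1 / 3, 2 / 3), na.rm = TRUE, names = FALSE)
    }
    codes <- findInterval(x, cuts)  # left-closed at each cutoff: x >= cut -> next code
    counts <- tabulate(codes + 1L, nbins = length(cuts) + 1L)
    if (any(counts == 0)) {
      warning("variable '", v, "': category with zero support under cutoffs",
              call. = FALSE)
    }
    out[[v]] <- as.integer(codes)
    used[[v]] <- cuts
  }
  res <- dplyr::bind_cols(tibble::tibble(!!s$time_col := s$time), out)
  attr(res, "cutoffs") <- used
  attr(res, "target") <- target
  class(res) <- c("discrete_table", class(res))
  res
}

#' Standard conditioning pipeline for a raw series table
#'
#' Outlier removal, resampling to a uniform grid, then min-max normalization,
#' in that fixed order. Categorization (for the Bayesian network) reads the
#' resampled but un-normalized values and is exposed separately via
#' [categorize()].
#'
#' @inheritParams remove_outliers
#' @inheritParams resample_series
#' @return A list with `normalized` (tibble for cross mapping) and
#'   `resampled` (tibble for categorization).
#' @export
preprocess_series <- function(data, step_days = 5, z_threshold = 3,
                              time_col = NULL) {
  cleaned <- remove_outliers(data, z_threshold = z_threshold, time_col = time_col)
  resampled <- resample_series(cleaned, step_days = step_days, time_col = time_col)
  list(normalized = normalize_minmax(resampled, time_col = time_col),
       resampled = resampled)
}
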