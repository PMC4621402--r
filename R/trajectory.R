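#' Shape labels for SCC trajectories
#'
#' The five mutually exclusive trajectory classes, in their canonical order.
#'
#' @return Character vector of the five shape labels.
#' @export
shape_levels <- function() {
  c("monotonic_increase", "v_shape", "discontinuous_other",
    "plateau", "monotonic_decrease")
}

check_series <- function(scores, occasions) {
  if (!is.numeric(scores) || length(scores) < 2L)
    stop("insufficient-data: a series needs at least 2 measurements")
  if (anyNA(scores)) stop("invalid-argument: scores contain NA")
  if (length(occasions) != length(scores))
    stop("invalid-argument: occasions and scores differ in length")
  if (any(diff(occasions) <= 0))
    stop("invalid-argument: occasions must be strictly increasing")
  k <- length(scores)
  if (k < 4L || k > 9L)
    warning(sprintf("series has %d occasions; study-like data has 4-9", k))
  invisible(k)
}

#' Fit a per-subject logarithmic trend
#'
#' Ordinary least squares of the SCC scores on the natural log of the
#' (1-based) occasion index: \eqn{Y_i = a + b \ln(t_i) + e_i}. The residual
#' summary is the root mean square error with denominator \eqn{k} (the number
#' of occasions), i.e. the population SD of the residuals, not the usual
#' regression sigma with \eqn{k - 2}.
#'
#' @param scores Numeric vector of SCC scores, one per occasion.
#' @param occasions Occasion time points used as the trend regressor after
#'   log transform; defaults to the 1-based occasion index. Must be strictly
#'   increasing and positive.
#' @return An object of class `"log_trend_fit"`: list with `intercept`,
#'   `slope`, `fitted`, `residuals`, `rmse`, `k`.
#' @examples
#' f <- fit_log_trajectory(30 + 5 * log(1:5))
#' f$slope   # 5
#' f$rmse    # 0
#' @export
fit_log_trajectory <- function(scores, occasions = seq_along(scores)) {
  k <- check_series(scores, occasions)
  if (any(occasions <= 0))
    stop("invalid-argument: occasions must be positive so log() is defined")
  x <- log(occasions)
  if (max(x) - min(x) < .Machine$double.eps^0.5)
    stop("degenerate-design: all occasion times are equal")
  fit <- stats::lm.fit(cbind(`(Intercept)` = 1, logt = x), scores)
  fitted <- as.numeric(fit$fitted.values)
  resid <- scores - fitted
  structure(
    list(intercept = unname(fit$coefficients[1L]),
         slope = unname(fit$coefficients[2L]),
         fitted = fitted, residuals = resid,
         rmse = sqrt(mean(resid^2)), k = k),
    class = "log_trend_fit"
  )
}

#' @export
print.log_trend_fit <- function(x, ...) {
  cat(sprintf("Log-trend fit (k = %d): intercept %.3f, slope %.3f, RMSE %.3f\n",
              x$k, x$intercept, x$slope, x$rmse))
  invisible(x)
}

#' SCC fluctuation: RMSE around the logarithmic trend
#'
#' The per-subject fluctuation statistic: root mean square of the residuals
#' around the individually fitted log trend, with denominator \eqn{k}.
#' Larger values mean a more turbulent SCC trajectory.
#'
#' @inheritParams fit_log_trajectory
#' @return Non-negative scalar; 0 iff the series lies exactly on its fitted
#'   log curve.
#' @export
fluctuation_rmse <- function(scores, occasions = seq_along(scores)) {
  fit_log_trajectory(scores, occasions)$rmse
}

#' Classify an SCC trajectory into one of five reliable-change shapes
#'
#' Consecutive-occasion differences \eqn{d_i = Y_{i+1} - Y_i} are compared
#' against the reliable-change threshold `rci` (strict inequality: a change
#' of exactly `rci` is not reliable). The five labels are total and mutually
#' exclusive:
#'
#' * `plateau` — no reliable increase and no reliable decrease;
#' * `monotonic_increase` — at least one reliable increase, no reliable
#'   decrease;
#' * `monotonic_decrease` — at least one reliable decrease, no reliable
#'   increase;
#' * `v_shape` — exactly one reliable decrease, immediately followed by a
#'   reliable increase (extra reliable increases elsewhere are allowed);
#' * `discontinuous_other` — both a reliable increase and a reliable
#'   decrease occur, and the v-shape rule does not hold.
#'
#' @param scores Numeric vector of SCC scores over occasions (length >= 2).
#' @param rci Reliable-change threshold in raw points (default 3.48, the
#'   SCCS value at 95% confidence).
#' @return One of [shape_levels()], as a length-1 character vector.
#' @examples
#' classify_shape(c(40, 45, 46))       # monotonic_increase
#' classify_shape(c(38, 33, 39))       # v_shape
#' classify_shape(c(35, 36, 34, 37))   # plateau
#' @export
classify_shape <- function(scores, rci = 3.48) {
  if (!is.numeric(scores) || length(scores) < 2L)
    stop("insufficient-data: a series needs at least 2 measurements")
  if (anyNA(scores)) stop("invalid-argument: scores contain NA")
  if (!is.finite(rci) || rci <= 0)
    stop("invalid-argument: rci must be positive")
  d <- diff(scores)
  inc <- d > rci
  dec <- d < -rci
  n_inc <- sum(inc)
  n_dec <- sum(dec)
  if (n_inc == 0L && n_dec == 0L) return("plateau")
  if (n_dec == 0L) return("monotonic_increase")
  if (n_inc == 0L) return("monotonic_decrease")
  if (n_dec == 1L) {
    i <- which(dec)
    if (i < length(d) && inc[i + 1L]) return("v_shape")
  }
  "discontinuous_other"
}
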