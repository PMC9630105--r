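#' Select terminal dates for boundary estimation
#'
#' Picks the m most extreme calibrated medians of a culture's dated record:
#' the youngest dates anchor an end (disappearance) boundary, the oldest a
#' start (appearance) boundary. Each sighting carries a normal-equivalent
#' sigma derived from its 95.4% calibrated range, sigma = (upper - lower)/4.
#'
#' @param cal_table Data frame with columns `median`, `lower`, `upper`
#'   (cal BP), e.g. one row per calibrated assemblage.
#' @param which `"youngest"` (for an end boundary) or `"oldest"` (start).
#' @param m Number of terminal dates to use, capped at 10 and at the rows
#'   available; at least 3 eligible dates are required.
#' @return A `sighting_set`: data frame with `median` and `sigma_equiv`
#'   columns, sorted outward from the record interior, with attributes
#'   `direction` (`end_boundary`/`start_boundary`) and `k`.
#' @export
select_terminal_dates <- function(cal_table, which = c("youngest", "oldest"), m = 10) {
  which <- match.arg(which)
  stopifnot(is.data.frame(cal_table),
            all(c("median", "lower", "upper") %in% names(cal_table)))
  n <- nrow(cal_table)
  if (n < 3)
    stop("at least 3 eligible dates are required for boundary estimation; got ", n)
  m <- min(m, 10, n)
  o <- order(cal_table$median, decreasing = (which == "oldest"))
  sel <- cal_table[o[seq_len(m)], , drop = FALSE]
  s <- data.frame(median = sel$median,
                  sigma_equiv = (sel$upper - sel$lower) / 4)
  structure(s, class = c("sighting_set", "data.frame"),
            direction = if (which == "youngest") "end_boundary" else "start_boundary",
            k = m)
}

# Core optimal linear estimator on a working axis where the boundary lies
# beyond the maximum sighting. Returns the point estimate and the one-sided
# (1 - alpha) upper bound on that axis.
ole_core <- function(t, alpha = 0.05) {
  if (diff(range(t)) == 0)
    stop("degenerate sighting record: all sightings coincide")
  # tied sightings (e.g. medians snapped to one calendar-grid cell) carry no
  # spacing information; collapse them before estimating the joint shape
  t <- sort(unique(t), decreasing = TRUE)
  k <- length(t)
  if (k < 3)
    stop("degenerate sighting record: fewer than 3 distinct sightings")
  gaps <- t[1] - t[2:(k - 1)]
  # Weibull joint-shape estimate from log-spacings of the k extremes
  v <- sum(log((t[1] - t[k]) / gaps)) / (k - 1)
  # covariance of the extremes under the joint Weibull model (log-gamma form
  # avoids overflow); symmetric, defined by the j <= i triangle
  lam <- function(i, j) exp(lgamma(2 * v + i) + lgamma(v + j) -
                            lgamma(v + i) - lgamma(j))
  L <- outer(seq_len(k), seq_len(k), function(i, j) lam(pmax(i, j), pmin(i, j)))
  Li <- solve(L, rep(1, k))
  a <- Li / sum(Li)                  # optimal weights, sum to 1
  point <- sum(a * t)
  su <- (-log(alpha) / k)^(-v)
  upper <- t[1] + (t[1] - t[k]) / (su - 1)
  list(point = point, upper = upper, shape = v, weights = a)
}

#' Optimal linear estimation of a chronological boundary
#'
#' Estimates when a dated record truly ended (or began) beyond its most
#' extreme observed occurrence, from the joint extreme-value distribution of
#' its k terminal sightings: the Weibull shape is estimated from log-spacings,
#' the optimal weight vector from the modelled covariance of the k extremes,
#' and the point estimate is the weighted sum of sighting times. The one-sided
#' (1 - alpha) bound is returned as the far end of `ci95`. End boundaries are
#' computed on negated cal BP so "beyond the most recent occurrence" is always
#' "beyond the maximum" on the working axis.
#'
#' @param s A `sighting_set` from [select_terminal_dates()], or a data frame
#'   with `median` and `sigma_equiv` plus a `direction` argument.
#' @param alpha One-sided tail probability (default 0.05).
#' @param direction Overrides the sighting set's direction attribute.
#' @return A `boundary_estimate`: list with `point` (cal BP), `ci95`
#'   (younger, older cal BP; brackets the point), `n_iter = 1`, `direction`.
#' @export
ole_point <- function(s, alpha = 0.05, direction = NULL) {
  direction <- direction %||% attr(s, "direction")
  stopifnot(direction %in% c("end_boundary", "start_boundary"))
  sgn <- if (direction == "end_boundary") -1 else 1  # work beyond the maximum
  fit <- ole_core(sgn * s$median, alpha = alpha)
  point <- sgn * fit$point
  extreme <- if (direction == "end_boundary") min(s$median) else max(s$median)
  bound <- sgn * fit$upper
  ci <- sort(c(extreme, bound))
  structure(list(point = point, ci95 = c(lower = ci[1], upper = ci[2]),
                 n_iter = 1L, direction = direction, shape = fit$shape,
                 per_iteration = NULL),
            class = "boundary_estimate")
}

#' Boundary estimation with Monte-Carlo resampling of dating uncertainty
#'
#' Propagates calibration uncertainty through the optimal linear estimator:
#' in each iteration every sighting is redrawn as
#' Normal(median, sigma_equiv), the redrawn set is re-sorted, and the point
#' estimator applied. The reported boundary is the median of the per-iteration
#' estimates and `ci95` their 2.5/97.5 percentiles. Iterations with a
#' degenerate redrawn record are dropped; more than 50% degenerate aborts.
#'
#' @inheritParams ole_point
#' @param n_iter Number of resampling iterations (default 10000).
#' @param seed Integer seed; required for reproducibility.
#' @param keep_iterations Keep the per-iteration estimates in the result.
#' @return A `boundary_estimate` with `n_iter` set and, optionally,
#'   `per_iteration`.
#' @export
ole_resample <- function(s, n_iter = 10000, seed = NULL, alpha = 0.05,
                         direction = NULL, keep_iterations = FALSE) {
  direction <- direction %||% attr(s, "direction")
  stopifnot(direction %in% c("end_boundary", "start_boundary"))
  if (!is.null(seed)) set.seed(seed)
  sgn <- if (direction == "end_boundary") -1 else 1
  k <- nrow(s)
  est <- rep(NA_real_, n_iter)
  for (i in seq_len(n_iter)) {
    draw <- stats::rnorm(k, s$median, s$sigma_equiv)
    fit <- try(ole_core(sgn * draw, alpha = alpha), silent = TRUE)
    if (!inherits(fit, "try-error")) est[i] <- sgn * fit$point
  }
  est <- est[!is.na(est)]
  if (length(est) < n_iter / 2)
    stop("more than half of the resampling iterations were degenerate")
  q <- stats::quantile(est, c(0.025, 0.5, 0.975), names = FALSE)
  structure(list(point = q[2], ci95 = c(lower = q[1], upper = q[3]),
                 n_iter = length(est), direction = direction,
                 per_iteration = if (keep_iterations) est else NULL),
            class = "boundary_estimate")
}

#' @export
print.boundary_estimate <- function(x, ...) {
  lab <- if (x$direction == "end_boundary") "End" else "Start"
  cat(sprintf("%s boundary: %.0f cal BP (95%% interval %.0f-%.0f), %d iteration%s\n",
              lab, x$point, x$ci95[["lower"]], x$ci95[["upper"]], x$n_iter,
              if (x$n_iter > 1) "s" else ""))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
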