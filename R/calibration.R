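#' Calibration curves
#'
#' A calibration curve maps calendar age (cal BP) to conventional radiocarbon
#' age with a curve uncertainty. `read_calcurve()` parses the standard `.14c`
#' text dialect: comment/header lines prefixed with `#`, then three columns
#' (cal BP, 14C age BP, 1-sigma error), comma- or whitespace-separated.
#' `calcurve()` builds a curve from vectors.
#'
#' @param path Path to a `.14c` file.
#' @param name Curve label.
#' @return An object of class `calcurve`: a list with `grid` (cal BP,
#'   ascending), `mu14c`, `sigma_curve` and `name`.
#' @export
read_calcurve <- function(path, name = basename(path)) {
  lines <- readLines(path)
  lines <- lines[!startsWith(trimws(lines), "#")]
  lines <- lines[nzchar(trimws(lines))]
  # accept both comma- and whitespace-separated columns
  fields <- strsplit(trimws(lines), "[,[:space:]]+")
  mat <- do.call(rbind, lapply(fields, function(f) as.numeric(f[1:3])))
  if (anyNA(mat)) stop("malformed calibration curve: non-numeric fields")
  calcurve(mat[, 1], mat[, 2], mat[, 3], name = name)
}

#' @param grid Calendar ages (cal BP), strictly monotone.
#' @param mu14c Radiocarbon age at each grid point.
#' @param sigma_curve Curve 1-sigma at each grid point, all > 0 allowed 0 for
#'   synthetic test curves.
#' @rdname read_calcurve
#' @export
calcurve <- function(grid, mu14c, sigma_curve, name = "curve") {
  stopifnot(length(grid) == length(mu14c), length(grid) == length(sigma_curve))
  o <- order(grid)
  grid <- grid[o]; mu14c <- mu14c[o]; sigma_curve <- sigma_curve[o]
  if (any(diff(grid) <= 0)) stop("calibration-curve grid must be strictly monotone")
  if (any(sigma_curve < 0)) stop("calibration-curve sigma must be >= 0")
  structure(list(grid = grid, mu14c = mu14c, sigma_curve = sigma_curve,
                 name = name), class = "calcurve")
}

#' @export
print.calcurve <- function(x, ...) {
  cat("Calibration curve '", x$name, "': ", length(x$grid), " knots, ",
      min(x$grid), "-", max(x$grid), " cal BP\n", sep = "")
  invisible(x)
}

# linear interpolation of the curve at calendar ages theta
curve_at <- function(curve, theta) {
  list(mu = stats::approx(curve$grid, curve$mu14c, theta, rule = 1)$y,
       sigma = stats::approx(curve$grid, curve$sigma_curve, theta, rule = 1)$y)
}

#' Calibrate a chronometric date
#'
#' Converts a radiocarbon determination into a probability mass function over
#' a calendar-age grid. The likelihood at calendar age theta is a normal
#' density of (age - mu14c(theta)) with variance error^2 + sigma_curve(theta)^2,
#' normalised over the grid. Dates obtained by methods that already live on
#' the calendar axis (TL, OSL, U-series) bypass the curve and return a normal
#' density centred on the reported age.
#'
#' @param age Reported age (radiocarbon years BP for `method = "14C"`,
#'   calendar years BP otherwise).
#' @param error One-sigma lab error, years.
#' @param curve A [calcurve] (required for 14C dates).
#' @param step Grid step in calendar years (default 20).
#' @param method One of `"14C"`, `"TL"`, `"OSL"`, `"U-series"`.
#' @param lab_code Optional identifier used in error messages.
#' @return A `cal_density`: list with `grid` (cal BP, ascending), `p`
#'   (probability mass per cell, summing to 1), `median` and `range95`
#'   (younger, older bounds of the central 95.4% interval).
#' @export
calibrate <- function(age, error, curve = NULL, step = 20, method = "14C",
                      lab_code = NULL) {
  if (step <= 0) stop("grid step must be positive")
  if (age <= 0 || error <= 0) stop("age and error must be positive")
  id <- if (is.null(lab_code)) sprintf("%s %.0f+/-%.0f", method, age, error) else lab_code
  if (method != "14C") {
    theta <- seq_grid(age - 5 * error, age + 5 * error, step)
    p <- stats::dnorm(theta, age, error)
  } else {
    if (is.null(curve)) stop("a calibration curve is required for 14C dates")
    lo <- min(curve$mu14c) - 3 * error
    hi <- max(curve$mu14c) + 3 * error
    if (age < lo || age > hi)
      stop(sprintf("date %s lies beyond the calibration curve range", id))
    if (age > max(curve$mu14c) - 2 * error)
      warning(sprintf("date %s is within 2 sigma of the old limit of curve '%s'; calibration is unstable there",
                      id, curve$name))
    theta <- seq_grid(min(curve$grid), max(curve$grid), step)
    cv <- curve_at(curve, theta)
    p <- stats::dnorm(age, cv$mu, sqrt(error^2 + cv$sigma^2))
  }
  if (!any(p > 0)) stop(sprintf("date %s has zero likelihood everywhere on the grid", id))
  # trim negligible tails to keep densities compact
  keep <- which(p > max(p) * 1e-9)
  idx <- min(keep):max(keep)
  theta <- theta[idx]; p <- p[idx]
  p <- p / sum(p)
  cal_density(theta, p)
}

# a grid of multiples of `step` covering [lo, hi]
seq_grid <- function(lo, hi, step) {
  seq(floor(lo / step) * step, ceiling(hi / step) * step, by = step)
}

cal_density <- function(grid, p) {
  cum <- cumsum(p)
  med <- grid[which(cum >= 0.5)[1]]
  lower <- grid[which(cum >= (1 - 0.954) / 2)[1]]
  upper <- grid[which(cum >= 1 - (1 - 0.954) / 2)[1]]
  structure(list(grid = grid, p = p, median = med,
                 range95 = c(lower = lower, upper = upper)),
            class = "cal_density")
}

#' @export
print.cal_density <- function(x, ...) {
  cat("Calibrated density: median", x$median, "cal BP; 95.4% range [",
      x$range95[["lower"]], ",", x$range95[["upper"]], "] cal BP;",
      length(x$grid), "grid cells\n")
  invisible(x)
}

#' @export
plot.cal_density <- function(x, ...) {
  plot(x$grid, x$p, type = "h", xlab = "cal BP", ylab = "probability mass",
       xlim = rev(range(x$grid)), ...)
  invisible(x)
}

#' Combine same-level radiocarbon determinations
#'
#' Pools repeat 14C measurements of one event before calibration using the
#' inverse-variance weighted mean, with a chi-square consistency statistic
#' T = sum w_i (age_i - mean)^2 on k - 1 degrees of freedom. A failure of the
#' consistency test at alpha = 0.05 is reported but does not abort: the
#' combined date is still returned.
#'
#' @param age,error Vectors of 14C ages and 1-sigma errors (same method only).
#' @return List with `age`, `error`, `T`, `df`, `p_value`, `consistent`, `n`.
#' @export
r_combine <- function(age, error) {
  stopifnot(length(age) == length(error), all(error > 0))
  n <- length(age)
  if (n == 1)
    return(list(age = age, error = error, T = 0, df = 0, p_value = NA_real_,
                consistent = TRUE, n = 1L))
  w <- 1 / error^2
  m <- sum(w * age) / sum(w)
  se <- 1 / sqrt(sum(w))
  T <- sum(w * (age - m)^2)
  p <- stats::pchisq(T, df = n - 1, lower.tail = FALSE)
  ok <- p >= 0.05
  if (!ok)
    warning(sprintf("combined dates fail the chi-square consistency test (T = %.2f, df = %d, p = %.3g)",
                    T, n - 1L, p))
  list(age = m, error = se, T = T, df = n - 1L, p_value = p, consistent = ok, n = n)
}

#' Filter a chronometric dataset for SPD analysis
#'
#' Applies the three exclusion rules used before summing probability
#' distributions: determinations with coefficient of variation
#' error/age >= 0.05 (inclusive), determinations on shell (marine reservoir
#' uncertainty), and determinations from levels carrying a stratigraphic or
#' cultural-attribution flag. Idempotent and order-independent.
#'
#' @param dates A data frame with at least `age`, `error_1sigma`, `material`
#'   and `flags` columns (`flags` a string, empty or semicolon-separated).
#' @param cv_max Inclusive coefficient-of-variation threshold (default 0.05).
#' @return List with `kept` (data frame) and `removed` (data frame with an
#'   extra `reason` column; codes `cv_threshold`, `shell_material`,
#'   `level_flagged`).
#' @export
filter_for_spd <- function(dates, cv_max = 0.05) {
  stopifnot(is.data.frame(dates))
  if (nrow(dates) == 0)
    return(list(kept = dates, removed = cbind(dates, reason = character(0))))
  flags <- if ("flags" %in% names(dates)) as.character(dates$flags) else rep("", nrow(dates))
  flags[is.na(flags)] <- ""
  material <- if ("material" %in% names(dates)) as.character(dates$material) else rep("", nrow(dates))
  cv <- dates$error_1sigma / dates$age
  reason <- rep(NA_character_, nrow(dates))
  reason[nzchar(flags)] <- "level_flagged"
  reason[material == "shell"] <- "shell_material"
  reason[cv >= cv_max] <- "cv_threshold"
  drop <- !is.na(reason)
  removed <- dates[drop, , drop = FALSE]
  if (nrow(removed)) removed$reason <- reason[drop]
  else removed$reason <- character(0)
  list(kept = dates[!drop, , drop = FALSE], removed = removed)
}

#' Merge and calibrate a dates table into per-level assemblages
#'
#' Groups a chronometric dataset by site and level, pools same-method 14C
#' repeats with [r_combine()] (mixed-method groups are kept separate, per
#' method), and calibrates each pooled determination.
#'
#' @param dates Data frame of determinations (columns `site_id`, `level_id`,
#'   `method`, `age`, `error_1sigma`, optionally `culture`, `region`).
#' @param curve A [calcurve].
#' @param step Calendar grid step, years.
#' @return A list of assemblages; each has `site_id`, `level_id`, `culture`,
#'   `region`, `n_dates` and `density` (a `cal_density`).
#' @export
assemble_levels <- function(dates, curve, step = 20) {
  stopifnot(is.data.frame(dates), nrow(dates) > 0)
  key <- interaction(dates$site_id, dates$level_id, drop = TRUE)
  out <- list()
  for (lev in levels(key)) {
    d <- dates[key == lev, , drop = FALSE]
    for (meth in unique(d$method)) {
      dm <- d[d$method == meth, , drop = FALSE]
      cmb <- if (meth == "14C") r_combine(dm$age, dm$error_1sigma)
             else list(age = mean(dm$age), error = sqrt(mean(dm$error_1sigma^2) / nrow(dm)),
                       n = nrow(dm))
      dens <- calibrate(cmb$age, cmb$error, curve = curve, step = step,
                        method = meth,
                        lab_code = paste(dm$site_id[1], dm$level_id[1]))
      out[[length(out) + 1]] <- list(
        site_id = dm$site_id[1], level_id = dm$level_id[1],
        culture = if ("culture" %in% names(dm)) dm$culture[1] else NA_character_,
        region = if ("region" %in% names(dm)) dm$region[1] else NA_character_,
        method = meth, n_dates = nrow(dm), density = dens)
    }
  }
  out
}

#' Summed probability distribution of calibrated assemblages
#'
#' Sums the per-assemblage calibrated densities (each normalised to unit
#' mass) on a common calendar grid restricted to an analysis window. Density
#' mass falling outside the window is truncated, not renormalised, so the
#' total SPD mass equals the number of assemblages wholly inside the window
#' plus the within-window fraction of any assemblage straddling an edge.
#'
#' @param assemblages List of assemblages from [assemble_levels()], or a bare
#'   list of `cal_density` objects.
#' @param step Grid step (must match the calibration step).
#' @param window `c(old, young)` window bounds in cal BP, or NULL for the
#'   union of supports.
#' @return Data frame with `cal_bp` (descending, old to young) and `prob`.
#' @export
spd <- function(assemblages, step = 20, window = NULL) {
  dens <- lapply(assemblages, function(a) if (inherits(a, "cal_density")) a else a$density)
  if (length(dens) == 0)
    return(data.frame(cal_bp = numeric(0), prob = numeric(0)))
  lo <- min(vapply(dens, function(d) min(d$grid), 0))
  hi <- max(vapply(dens, function(d) max(d$grid), 0))
  if (!is.null(window)) { lo <- max(lo, min(window)); hi <- min(hi, max(window)) }
  grid <- seq_grid(lo, hi, step)
  total <- numeric(length(grid))
  for (d in dens) {
    i <- match(d$grid, grid)
    ok <- !is.na(i)
    total[i[ok]] <- total[i[ok]] + d$p[ok]
  }
  data.frame(cal_bp = rev(grid), prob = rev(total))
}
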