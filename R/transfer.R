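#' Pollen assemblages
#'
#' A pollen assemblage holds taxon percentages (or counts converted to
#' percentages), the total grain count behind them, and a per-taxon
#' terrestrial flag. Aquatic taxa, ferns and other non-pollen palynomorphs
#' respond to local hydrology rather than regional climate, so they are
#' excluded before climate reconstruction.
#'
#' @param sample_id Sample identifier.
#' @param taxa Named numeric vector of percentages (or counts if
#'   `counts = TRUE`).
#' @param total_count Total pollen grains counted.
#' @param terrestrial Named logical vector (defaults to all TRUE).
#' @param counts If TRUE, `taxa` are raw counts and `total_count` defaults to
#'   their sum.
#' @return A `pollen_assemblage` object.
#' @export
pollen_assemblage <- function(sample_id, taxa, total_count = NULL,
                              terrestrial = NULL, counts = FALSE) {
  stopifnot(!is.null(names(taxa)), all(taxa >= 0))
  if (counts) {
    total_count <- total_count %||% sum(taxa)
    taxa <- if (sum(taxa) > 0) 100 * taxa / sum(taxa) else taxa
  }
  if (is.null(total_count)) stop("total_count is required for percentage data")
  terrestrial <- terrestrial %||% stats::setNames(rep(TRUE, length(taxa)), names(taxa))
  structure(list(sample_id = sample_id, taxa = taxa,
                 total_count = total_count,
                 terrestrial = terrestrial[names(taxa)]),
            class = "pollen_assemblage")
}

#' Filter a pollen assemblage for climate reconstruction
#'
#' Rejects assemblages with fewer than 100 counted grains, drops taxa below
#' the 5% representation threshold and all non-terrestrial taxa, then
#' renormalises the surviving percentages to 100.
#'
#' @param a A [pollen_assemblage].
#' @param min_count Minimum grain count (default 100; assemblages strictly
#'   below are rejected).
#' @param min_pct Minimum taxon percentage (default 5; strictly below dropped).
#' @return The filtered `pollen_assemblage`, or a `pollen_rejection` object
#'   (with a `reason` field) if the assemblage cannot be used.
#' @export
filter_pollen <- function(a, min_count = 100, min_pct = 5) {
  stopifnot(inherits(a, "pollen_assemblage"))
  if (a$total_count < min_count)
    return(structure(list(sample_id = a$sample_id,
                          reason = sprintf("low_count (%d < %d grains)",
                                           a$total_count, min_count)),
                     class = "pollen_rejection"))
  keep <- a$taxa >= min_pct & a$terrestrial
  taxa <- a$taxa[keep]
  if (length(taxa) == 0 || sum(taxa) == 0)
    return(structure(list(sample_id = a$sample_id, reason = "all_taxa_removed"),
                     class = "pollen_rejection"))
  taxa <- 100 * taxa / sum(taxa)
  pollen_assemblage(a$sample_id, taxa, total_count = a$total_count,
                    terrestrial = a$terrestrial[names(taxa)])
}

#' @export
print.pollen_rejection <- function(x, ...) {
  cat("Rejected pollen sample", x$sample_id, "-", x$reason, "\n")
  invisible(x)
}

#' Weighted-averaging transfer function
#'
#' Fits a weighted-averaging (WA) regression of a climate variable on a
#' modern pollen training set. The method assumes each taxon is most abundant
#' near its climatic optimum: the optimum is the abundance-weighted mean of
#' the climate variable over the training samples, an initial sample estimate
#' is the abundance-weighted mean of the optima of its taxa, and the
#' compression inherent in averaging twice is undone by inverse deshrinking
#' (linear regression of observed climate on the initial estimates).
#'
#' @param Y Samples x taxa matrix (or data frame) of pollen percentages.
#' @param x Climate value per training sample (MAT in deg C or MAP in mm).
#' @param variable Label, `"MAT"` or `"MAP"`.
#' @param deshrink `"inverse"` (default) or `"none"`.
#' @return A `wa_tf` object: `optima` (named), `deshrink` coefficients
#'   `(intercept, slope)`, `variable`, apparent `r2` and `rmse`.
#' @export
wa_fit <- function(Y, x, variable = c("MAT", "MAP"), deshrink = c("inverse", "none")) {
  variable <- match.arg(variable)
  deshrink <- match.arg(deshrink)
  Y <- as.matrix(Y)
  stopifnot(nrow(Y) == length(x), nrow(Y) >= 2, ncol(Y) >= 1,
            all(is.finite(x)), all(Y >= 0))
  if (any(rowSums(Y) == 0)) stop("training set contains all-zero sample rows")
  tot <- colSums(Y)
  if (any(tot == 0)) {
    warning("excluding taxa with zero total abundance: ",
            paste(colnames(Y)[tot == 0], collapse = ", "))
    Y <- Y[, tot > 0, drop = FALSE]
    tot <- tot[tot > 0]
  }
  optima <- colSums(Y * x) / tot
  init <- as.vector(Y %*% optima) / rowSums(Y)
  if (deshrink == "inverse" && stats::sd(init) > 0) {
    co <- stats::coef(stats::lm(x ~ init))
    ds <- c(intercept = unname(co[1]), slope = unname(co[2]))
  } else {
    ds <- c(intercept = 0, slope = 1)
  }
  pred <- ds[["intercept"]] + ds[["slope"]] * init
  ss <- sum((x - mean(x))^2)
  r2 <- if (ss > 0) 1 - sum((x - pred)^2) / ss else NA_real_
  structure(list(optima = optima, deshrink = ds, variable = variable,
                 deshrink_method = deshrink, n_samples = nrow(Y),
                 r2 = r2, rmse = sqrt(mean((x - pred)^2))),
            class = "wa_tf")
}

#' @export
print.wa_tf <- function(x, ...) {
  cat(sprintf("Weighted-averaging transfer function for %s\n", x$variable))
  cat(sprintf("  %d taxa, %d training samples; apparent r2 = %.3f, RMSE = %.3f\n",
              length(x$optima), x$n_samples, x$r2, x$rmse))
  cat(sprintf("  deshrinking: %s (intercept %.4g, slope %.4g)\n",
              x$deshrink_method, x$deshrink[["intercept"]], x$deshrink[["slope"]]))
  invisible(x)
}

#' @export
coef.wa_tf <- function(object, ...) object$optima

#' Predict climate from a fossil pollen spectrum
#'
#' Applies a fitted transfer function: abundance-weighted mean of taxon
#' optima over the taxa shared with the training set, then deshrinking.
#'
#' @param object A [wa_fit()] transfer function.
#' @param newdata A [pollen_assemblage], a named percentage vector, or a
#'   samples x taxa matrix.
#' @param ... Unused.
#' @return Numeric climate estimate(s).
#' @export
predict.wa_tf <- function(object, newdata, ...) {
  if (inherits(newdata, "pollen_assemblage")) newdata <- newdata$taxa
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1,
                                               dimnames = list(NULL, names(newdata)))
  newdata <- as.matrix(newdata)
  shared <- intersect(colnames(newdata), names(object$optima))
  if (length(shared) == 0)
    stop("no-analogue situation: no fossil taxon occurs in the training set")
  Y <- newdata[, shared, drop = FALSE]
  w <- rowSums(Y)
  if (any(w == 0)) stop("a fossil sample has zero abundance over shared taxa")
  init <- as.vector(Y %*% object$optima[shared]) / w
  object$deshrink[["intercept"]] + object$deshrink[["slope"]] * init
}

#' Bootstrap cross-validation of a transfer function
#'
#' Estimates out-of-sample prediction skill: in each cycle the training
#' samples are resampled with replacement, a transfer function is fitted to
#' the bootstrap sample, and the out-of-bag samples are predicted. r2 and
#' RMSE are computed on the pooled out-of-bag predictions across all cycles.
#'
#' @inheritParams wa_fit
#' @param n_boot Number of bootstrap cycles (default 500).
#' @param seed Integer seed.
#' @return A `cv_report`: list with `r2`, `rmse`, `n_boot`, `n_skipped`,
#'   `variable` and a `degenerate` flag (TRUE when the climate variable is
#'   constant, in which case r2 is reported as 0).
#' @export
bootstrap_cv <- function(Y, x, variable = c("MAT", "MAP"), n_boot = 500,
                         seed = NULL, deshrink = c("inverse", "none")) {
  variable <- match.arg(variable)
  deshrink <- match.arg(deshrink)
  Y <- as.matrix(Y)
  n <- nrow(Y)
  stopifnot(n >= 10, length(x) == n)
  if (!is.null(seed)) set.seed(seed)
  obs <- pred <- list()
  skipped <- 0L
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    oob <- setdiff(seq_len(n), idx)
    if (length(oob) == 0) { skipped <- skipped + 1L; next }
    tf <- suppressWarnings(wa_fit(Y[idx, , drop = FALSE], x[idx],
                                  variable = variable, deshrink = deshrink))
    p <- try(suppressWarnings(predict(tf, Y[oob, , drop = FALSE])), silent = TRUE)
    if (inherits(p, "try-error")) { skipped <- skipped + 1L; next }
    obs[[length(obs) + 1]] <- x[oob]
    pred[[length(pred) + 1]] <- p
  }
  obs <- unlist(obs); pred <- unlist(pred)
  degen <- stats::sd(obs) == 0
  r2 <- if (degen) 0 else stats::cor(obs, pred)^2
  structure(list(r2 = r2, rmse = sqrt(mean((obs - pred)^2)),
                 n_boot = n_boot, n_skipped = skipped, n_oob = length(obs),
                 variable = variable, degenerate = degen),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("Bootstrap cross-validation (%s, %d cycles, %d OOB predictions)\n",
              x$variable, x$n_boot, x$n_oob))
  cat(sprintf("  r2 = %.3f, RMSE = %.3f%s\n", x$r2, x$rmse,
              if (x$degenerate) " [degenerate: constant climate]" else ""))
  invisible(x)
}

#' Delta-method bias correction of simulated climate
#'
#' Corrects systematic bias in palaeoclimate simulations using the
#' present-day discrepancy between observations and the simulation at the
#' same location: temperature is corrected additively,
#' T(x,t) = T_sim_raw(x,t) + (T_obs(x,0) - T_sim_raw(x,0)); precipitation
#' multiplicatively, P(x,t) = P_sim_raw(x,t) * P_obs(x,0) / P_sim_raw(x,0).
#' The additive form removes any constant simulation bias exactly; the
#' multiplicative form removes any constant relative bias exactly and
#' preserves non-negativity.
#'
#' @param t_sim_t Simulated temperature at past time t (deg C).
#' @param t_obs0,t_sim0 Observed and simulated present-day temperature.
#' @return Corrected values, same shape as the inputs.
#' @export
delta_correct_temperature <- function(t_sim_t, t_obs0, t_sim0) {
  if (anyNA(t_sim_t) || anyNA(t_obs0) || anyNA(t_sim0))
    stop("missing baseline: all three temperature fields are required")
  t_sim_t + (t_obs0 - t_sim0)
}

#' @param p_sim_t Simulated precipitation at past time t (mm per month).
#' @param p_obs0,p_sim0 Observed and simulated present-day precipitation.
#' @param floor Cells with `p_sim0 <= floor` are masked (NA) with a warning
#'   rather than divided.
#' @rdname delta_correct_temperature
#' @export
delta_correct_precipitation <- function(p_sim_t, p_obs0, p_sim0, floor = 1e-8) {
  if (anyNA(p_sim_t) || anyNA(p_obs0) || anyNA(p_sim0))
    stop("missing baseline: all three precipitation fields are required")
  if (any(p_sim_t < 0) || any(p_obs0 < 0) || any(p_sim0 < 0))
    stop("precipitation values must be non-negative")
  bad <- p_sim0 <= floor
  out <- p_sim_t * p_obs0 / ifelse(bad, NA_real_, p_sim0)
  if (any(bad))
    warning(sum(bad), " cell(s) masked: present-day simulated precipitation at or below the floor")
  out
}

#' Assess simulation bias before and after correction
#'
#' Compares proxy-based reconstructions against raw and bias-corrected
#' simulated values: mean absolute difference and Pearson correlation (with
#' two-sided p) for both series.
#'
#' @param reconstructed Proxy-based climate estimates.
#' @param simulated_raw Uncorrected simulated values at the same points.
#' @param simulated_corrected Bias-corrected simulated values.
#' @return List with `mean_abs_diff_before`, `mean_abs_diff_after`, `r`, `p`
#'   (correlation of reconstructed with corrected values), `r_before`,
#'   `p_before`, and a `degenerate` flag when a correlation is undefined.
#' @export
bias_assessment <- function(reconstructed, simulated_raw, simulated_corrected) {
  n <- length(reconstructed)
  if (n < 3) stop("at least 3 reconstruction/simulation pairs are required")
  stopifnot(length(simulated_raw) == n, length(simulated_corrected) == n)
  mad_before <- mean(abs(reconstructed - simulated_raw))
  mad_after <- mean(abs(reconstructed - simulated_corrected))
  degen <- stats::sd(reconstructed) == 0 || stats::sd(simulated_corrected) == 0 ||
    stats::sd(simulated_raw) == 0
  if (degen) {
    r <- p <- rb <- pb <- NA_real_
  } else {
    ct <- stats::cor.test(reconstructed, simulated_corrected)
    cb <- stats::cor.test(reconstructed, simulated_raw)
    r <- unname(ct$estimate); p <- ct$p.value
    rb <- unname(cb$estimate); pb <- cb$p.value
  }
  list(mean_abs_diff_before = mad_before, mean_abs_diff_after = mad_after,
       r = r, p = p, r_before = rb, p_before = pb, n = n, degenerate = degen)
}
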