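#' Fit the herbivore-biomass allometry on modern data
#'
#' Fits the log-log macroecological law linking total herbivore biomass (THB)
#' to net primary productivity, log10(THB) = slope * log10(NPP) + intercept,
#' by a robust MM-type linear estimator (ordinary least squares as fallback
#' for tiny or degenerate inputs). Robustness matters because modern density
#' compilations contain gross outliers (fenced reserves, provisioned parks).
#'
#' @param npp,thb Positive vectors, one value per modern site, in the
#'   declared units.
#' @param method `"MM"` (default) or `"ls"`.
#' @param units Named character vector declaring the units of `npp` and `thb`
#'   (stored, never converted silently).
#' @return A `thb_model`: coefficients, standard errors, 95% CI, residual
#'   scale, n, the declared units, and the underlying fit (for prediction
#'   bands).
#' @export
fit_thb_model <- function(npp, thb, method = c("MM", "ls"),
                          units = c(npp = "g m-2 yr-1", thb = "g m-2 yr-1")) {
  method <- match.arg(method)
  stopifnot(length(npp) == length(thb))
  if (length(npp) < 2) stop("at least 2 sites are required")
  bad <- which(npp <= 0 | thb <= 0)
  if (length(bad))
    stop("non-positive NPP or THB at record(s) ", paste(bad, collapse = ", "),
         "; the law is fitted on log10 scales")
  x <- log10(npp); y <- log10(thb)
  df <- data.frame(x = x, y = y)
  fit <- NULL
  if (method == "MM" && length(x) >= 4 && stats::sd(x) > 0) {
    fit <- try(MASS::rlm(y ~ x, data = df, method = "MM", maxit = 100),
               silent = TRUE)
    if (inherits(fit, "try-error")) fit <- NULL
  }
  if (is.null(fit)) fit <- stats::lm(y ~ x, data = df)
  co <- stats::coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit))), error = function(e) c(NA, NA))
  dfree <- length(x) - 2
  tq <- if (dfree > 0) stats::qt(0.975, dfree) else NA_real_
  ci <- cbind(lower = co - tq * se, upper = co + tq * se)
  structure(list(slope = unname(co[2]), intercept = unname(co[1]),
                 se = stats::setNames(unname(se), c("intercept", "slope")),
                 ci = ci, scale = summary_scale(fit), n = length(x),
                 method = if (inherits(fit, "rlm")) "MM" else "ls",
                 units = units, fit = fit),
            class = "thb_model")
}

summary_scale <- function(fit) {
  if (inherits(fit, "rlm")) fit$s else summary(fit)$sigma
}

#' @export
print.thb_model <- function(x, ...) {
  cat(sprintf("Herbivore biomass allometry (%s fit, n = %d sites)\n",
              x$method, x$n))
  cat(sprintf("  log10(THB) = %.3f * log10(NPP) %+.3f\n", x$slope, x$intercept))
  if (all(is.finite(x$ci)))
    cat(sprintf("  95%% CI slope [%.3f, %.3f], intercept [%.3f, %.3f]\n",
                x$ci[2, 1], x$ci[2, 2], x$ci[1, 1], x$ci[1, 2]))
  cat(sprintf("  units: NPP %s, THB %s\n", x$units[["npp"]], x$units[["thb"]]))
  invisible(x)
}

#' @export
coef.thb_model <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' Predict total herbivore biomass from productivity
#'
#' THB = 10^(slope * log10(NPP) + intercept), in the model's declared units.
#' With `interval = TRUE` a 95% prediction band (on the log10 scale, mapped
#' back) is attached.
#'
#' @param object A [fit_thb_model()] model, or use [thb_model()] to build one
#'   from published coefficients.
#' @param npp Positive productivity value(s).
#' @param interval Attach a 95% prediction interval (requires a fitted model
#'   with stored covariance).
#' @param ... Unused.
#' @return Numeric THB, or a data frame `fit`, `lower`, `upper` when
#'   `interval = TRUE`.
#' @export
predict.thb_model <- function(object, npp, interval = FALSE, ...) {
  if (any(npp <= 0)) stop("NPP must be positive")
  lx <- log10(npp)
  fit <- 10^(object$intercept + object$slope * lx)
  if (!interval) return(fit)
  if (is.null(object$fit)) stop("model carries no covariance; cannot form an interval")
  pr <- stats::predict(object$fit, newdata = data.frame(x = lx), se.fit = TRUE)
  s <- object$scale
  se_pred <- sqrt(pr$se.fit^2 + s^2)
  dfree <- max(object$n - 2, 1)
  tq <- stats::qt(0.975, dfree)
  data.frame(fit = fit,
             lower = 10^(pr$fit - tq * se_pred),
             upper = 10^(pr$fit + tq * se_pred))
}

#' Build an allometry model from published coefficients
#'
#' @param slope,intercept Coefficients of the log10-log10 law (defaults
#'   1.401 and -0.642).
#' @param scaling_exponent Density-mass scaling exponent (default -0.75).
#' @inheritParams fit_thb_model
#' @export
thb_model <- function(slope = 1.401, intercept = -0.642,
                      scaling_exponent = -0.75,
                      units = c(npp = "g m-2 yr-1", thb = "g m-2 yr-1")) {
  if (scaling_exponent >= 0) stop("the density-mass scaling exponent must be negative")
  structure(list(slope = slope, intercept = intercept,
                 scaling_exponent = scaling_exponent,
                 se = NULL, ci = NULL, scale = NULL, n = 0L,
                 method = "fixed", units = units, fit = NULL),
            class = "thb_model")
}

#' Herbivore size classes
#'
#' Four weight categories: small (< 10 kg), medium (\[10, 100) kg),
#' medium-large (\[100, 500) kg) and large (>= 500 kg); half-open on the
#' right, so a 100 kg species is medium-large.
#'
#' @param w Body mass (kg).
#' @return Factor with levels small, medium, medium_large, large.
#' @export
size_class <- function(w) {
  stopifnot(all(w > 0))
  cut(w, breaks = c(0, 10, 100, 500, Inf), right = FALSE,
      labels = c("small", "medium", "medium_large", "large"))
}

#' Damuth proportionality constant of a community
#'
#' Under the density-mass allometry D_i = c W_i^(-3/4), the total biomass
#' THB = sum c W_i^(1/4) fixes c = THB / sum W_i^(1/4).
#'
#' @param thb Total herbivore biomass (>= 0), in kg km-2 when densities are
#'   wanted in ind km-2 and masses are in kg.
#' @param masses Body masses (kg), one per species, all > 0.
#' @export
damuth_constant <- function(thb, masses) {
  if (length(masses) == 0) stop("the community must contain at least one species")
  stopifnot(thb >= 0, all(masses > 0))
  thb / sum(masses^0.25)
}

#' Partition total biomass among species by Damuth's rule
#'
#' Distributes a community's total herbivore biomass across its species under
#' the allometric density law: D_i = c W_i^(-3/4) individuals per km2 and
#' B_i = D_i W_i = c W_i^(1/4), with c from [damuth_constant()]. The
#' partition is exactly closed: sum(B_i) = THB.
#'
#' @param thb Total herbivore biomass.
#' @param masses Named vector of body masses (kg); names are taxa and must be
#'   unique (duplicates would double-count).
#' @return A `biomass_result`: data frame with `taxon`, `mass_kg`,
#'   `size_class`, `density` and `biomass`, with attributes `THB` and `c`.
#' @export
partition_biomass <- function(thb, masses) {
  taxa <- names(masses) %||% paste0("sp", seq_along(masses))
  if (anyDuplicated(taxa)) stop("duplicate taxa would double-count biomass")
  cc <- damuth_constant(thb, masses)
  D <- cc * masses^(-0.75)
  B <- D * masses
  out <- data.frame(taxon = taxa, mass_kg = unname(masses),
                    size_class = size_class(masses),
                    density = unname(D), biomass = unname(B))
  structure(out, class = c("biomass_result", "data.frame"), THB = thb, c = cc)
}

#' @export
print.biomass_result <- function(x, ...) {
  cat(sprintf("Biomass partition: THB = %.4g, c = %.4g, %d species\n",
              attr(x, "THB"), attr(x, "c"), nrow(x)))
  print.data.frame(x, ...)
  invisible(x)
}

#' Size-class biomass totals
#'
#' @param result A [partition_biomass()] result.
#' @return Named numeric vector of biomass per size class (all four classes,
#'   zeros included); sums to THB.
#' @export
size_class_totals <- function(result) {
  lv <- levels(result$size_class)
  out <- vapply(lv, function(l) sum(result$biomass[result$size_class == l]), 0)
  stats::setNames(out, lv)
}

#' Validate the allometric model against modern census data
#'
#' For each modern site, predicts THB from its productivity, partitions it
#' over the species observed there, and correlates predicted against
#' observed per-species densities (pairing strictly by taxon), by default on
#' log10 scales since the density-mass law is log-linear. Reports per-site
#' Pearson r and p, the pooled correlation, and the fraction of sites
#' significant at p < 0.05.
#'
#' @param sites List of modern site records: each a list with `site`, `npp`,
#'   and `species` (data frame with `taxon`, `mass_kg`, `density_obs`).
#' @param model A `thb_model`.
#' @param log Correlate log10 densities (default TRUE).
#' @return List with `per_site` (data frame), `pooled` (list `r`, `p`, `n`),
#'   `fraction_significant`, `n_sites_used`, `skipped` (site names with < 3
#'   species).
#' @export
validate_model <- function(sites, model, log = TRUE) {
  per <- list(); obs_all <- pred_all <- numeric(0); skipped <- character(0)
  for (s in sites) {
    sp <- s$species
    if (nrow(sp) < 3) { skipped <- c(skipped, s$site); next }
    if (anyDuplicated(sp$taxon)) stop("duplicate taxa at site ", s$site)
    thb <- predict(model, s$npp)
    part <- partition_biomass(thb, stats::setNames(sp$mass_kg, sp$taxon))
    pred <- part$density[match(sp$taxon, part$taxon)]  # pair by taxon
    o <- sp$density_obs; p <- pred
    if (log) {
      ok <- o > 0 & p > 0
      o <- log10(o[ok]); p <- log10(p[ok])
    }
    if (length(o) < 3 || stats::sd(o) == 0 || stats::sd(p) == 0) {
      skipped <- c(skipped, s$site); next
    }
    ct <- stats::cor.test(o, p)
    per[[length(per) + 1]] <- data.frame(site = s$site, n_species = length(o),
                                         r = unname(ct$estimate), p = ct$p.value)
    obs_all <- c(obs_all, o); pred_all <- c(pred_all, p)
  }
  if (length(per) == 0) stop("no site had enough species to validate against")
  per <- do.call(rbind, per)
  pooled_ct <- stats::cor.test(obs_all, pred_all)
  list(per_site = per,
       pooled = list(r = unname(pooled_ct$estimate), p = pooled_ct$p.value,
                     n = length(obs_all)),
       fraction_significant = mean(per$p < 0.05),
       n_sites_used = nrow(per), skipped = skipped)
}

#' Minimum-census palaeocommunity assembly
#'
#' Builds region-by-phase species lists from dated local faunal assemblages
#' (LFAs). Rather than requiring a species to be directly dated within each
#' phase, its regional chronological range is taken as the union envelope of
#' its LFA 95.4% calendar intervals (oldest upper bound to youngest lower
#' bound), and the species is a member of every phase that range overlaps.
#' A species known from a single LFA gets that LFA's interval as its range.
#'
#' @param lfas Data frame with columns `species`, `region`, `lower`, `upper`
#'   (95.4% calendar interval bounds in cal BP, lower < upper).
#' @param phases A [phase_table()] (kyr BP; converted internally to years).
#' @return List with `membership` (data frame `region`, `phase`, `kind`,
#'   `species`) and `ranges` (data frame `region`, `species`, `oldest`,
#'   `youngest` in cal BP).
#' @export
minimum_census <- function(lfas, phases) {
  stopifnot(all(c("species", "region", "lower", "upper") %in% names(lfas)),
            all(lfas$lower < lfas$upper))
  key <- interaction(lfas$region, lfas$species, drop = TRUE)
  ranges <- do.call(rbind, lapply(levels(key), function(kk) {
    d <- lfas[key == kk, , drop = FALSE]
    data.frame(region = d$region[1], species = d$species[1],
               oldest = max(d$upper), youngest = min(d$lower))
  }))
  rows <- list()
  for (i in seq_len(nrow(phases))) {
    p_old <- phases$start_kyr_bp[i] * 1000
    p_young <- phases$end_kyr_bp[i] * 1000
    hit <- ranges$oldest > p_young & ranges$youngest < p_old  # interval overlap
    if (any(hit))
      rows[[length(rows) + 1]] <- data.frame(
        region = ranges$region[hit], phase = phases$name[i],
        kind = phases$kind[i], species = ranges$species[hit])
  }
  membership <- if (length(rows)) do.call(rbind, rows)
    else data.frame(region = character(0), phase = character(0),
                    kind = character(0), species = character(0))
  list(membership = membership, ranges = ranges)
}

#' Rarefaction and extrapolation of species richness
#'
#' Sample-based (incidence) rarefaction: the expected number of species in h
#' of the H observed LFAs follows the hypergeometric formula
#' E\[S(h)\] = sum_j (1 - C(H - H_j, h) / C(H, h)), where H_j is the number of
#' LFAs containing species j. Extrapolation beyond H uses the standard
#' incidence-based asymptotic (Chao-type) estimator of undetected richness.
#' A bootstrap over LFAs (resampled with replacement) yields the 95% CI of
#' the estimate at the target effort.
#'
#' @param incidence LFAs x species matrix (logical or 0/1).
#' @param target Target number of LFAs (default 100); may exceed the
#'   observed count.
#' @param n_boot Bootstrap replicates for the CI (default 500).
#' @param seed Integer seed.
#' @return List with `observed_S`, `expected_S` (at `target`), `ci95`,
#'   `n_lfas`, `target`.
#' @export
rarefy_richness <- function(incidence, target = 100, n_boot = 500, seed = NULL) {
  if (target < 1) stop("target sample size must be >= 1")
  incidence <- as.matrix(incidence) > 0
  H <- nrow(incidence)
  stopifnot(H >= 2, ncol(incidence) >= 1)
  if (!is.null(seed)) set.seed(seed)
  est <- richness_at(incidence, target)
  boot <- replicate(n_boot, {
    idx <- sample.int(H, H, replace = TRUE)
    richness_at(incidence[idx, , drop = FALSE], target)
  })
  list(observed_S = sum(colSums(incidence) > 0),
       expected_S = est,
       ci95 = stats::quantile(boot, c(0.025, 0.975), names = FALSE),
       n_lfas = H, target = target)
}

# expected richness at h sampling units (interpolation for h <= H,
# asymptotic extrapolation beyond)
richness_at <- function(incidence, h) {
  Hj <- colSums(incidence)
  Hj <- Hj[Hj > 0]
  H <- nrow(incidence)
  S_obs <- length(Hj)
  if (h <= H) {
    # hypergeometric expectation; lchoose is stable for large H
    miss <- exp(lchoose(H - Hj, h) - lchoose(H, h))
    miss[H - Hj < h] <- 0
    return(sum(1 - miss))
  }
  q1 <- sum(Hj == 1); q2 <- sum(Hj == 2)
  q0 <- if (q2 > 0) (H - 1) / H * q1^2 / (2 * q2)
        else (H - 1) / H * q1 * (q1 - 1) / 2
  if (q0 == 0 || q1 == 0) return(S_obs)
  m <- h - H
  S_obs + q0 * (1 - (1 - q1 / (q1 + H * q0))^m)
}

#' Propagate regression uncertainty into the biomass partition
#'
#' Maps the 95% prediction band of the THB regression at a given
#' productivity through the Damuth partition. Because the partition is
#' linear in THB, applying it to the band endpoints bounds every per-species
#' and per-class quantity.
#'
#' @param model A fitted `thb_model` (with stored covariance).
#' @param npp Productivity value.
#' @param masses Named vector of species body masses (kg).
#' @return List with `point` (a `biomass_result`), `lower`, `upper` (the
#'   partitions at the band endpoints), and `thb` (fit, lower, upper).
#' @export
propagate_ci <- function(model, npp, masses) {
  if (is.null(model$fit))
    stop("model carries no uncertainty information; fit it to data first")
  band <- predict(model, npp, interval = TRUE)
  list(point = partition_biomass(band$fit, masses),
       lower = partition_biomass(band$lower, masses),
       upper = partition_biomass(band$upper, masses),
       thb = band)
}
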