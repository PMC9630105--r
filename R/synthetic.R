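#' Synthetic-study scenarios
#'
#' A scenario bundles every ground-truth parameter the generators need, so a
#' whole synthetic study can be regenerated bit-identically from the scenario
#' plus its seed. Defaults emulate the structure of the real study inputs:
#' occupation phases spanning several millennia dated with percent-level lab
#' errors, four biogeographical regions whose productivity shifts between
#' stadial and interstadial levels, pollen taxa with unimodal (Gaussian)
#' climate responses, and modern herbivore communities scattered around a
#' log-log biomass-productivity law partitioned by Damuth's rule.
#'
#' @param seed Integer master seed.
#' @param chronology,npp,pollen,allometry Named lists overriding individual
#'   defaults (partial overrides are merged).
#' @return A `scenario` object (a named list).
#' @export
scenario <- function(seed = 1L, chronology = list(), npp = list(),
                     pollen = list(), allometry = list()) {
  defaults <- list(
    seed = as.integer(seed),
    chronology = list(
      true_start = 47000, true_end = 41000,  # cal BP occupation bounds
      n_levels = 30, dates_per_level = 2,
      error_cv = c(0.015, 0.03),             # lab error as fraction of age
      shell_frac = 0.1, flagged_frac = 0.05, highcv_frac = 0.05),
    npp = list(
      # per-region phase-kind means in the unit declared below
      profiles = list(
        Eurosiberian       = c(interstadial = 0.33, stadial = 0.27),
        Supramediterranean = c(interstadial = 0.26, stadial = 0.20),
        Mesomediterranean  = c(interstadial = 0.31, stadial = 0.30),
        Thermomediterranean = c(interstadial = 0.25, stadial = 0.25)),
      unit = "kg km-2 yr-1",
      noise_sd = 0.01, sites_per_region = 5,
      t_from = 54, t_to = 28, t_step = 0.2),  # kyr BP grid
    pollen = list(
      n_taxa = 12, n_train = 80, n_fossil = 10,
      mat_range = c(-2, 16),                  # deg C climate gradient
      tolerance = 3, count_depth = 400),
    allometry = list(
      slope = 1.401, intercept = -0.642,
      scatter_sd = 0.15,                      # lognormal scatter, log10 units
      n_sites = 516, richness = c(3, 12),
      mass_range = c(1, 1000),                # kg, log-uniform
      npp_range = c(50, 2000),                # g m-2 yr-1, log-uniform
      density_noise_sd = 0))
  merge_into <- function(base, upd) { base[names(upd)] <- upd; base }
  defaults$chronology <- merge_into(defaults$chronology, chronology)
  defaults$npp <- merge_into(defaults$npp, npp)
  defaults$pollen <- merge_into(defaults$pollen, pollen)
  defaults$allometry <- merge_into(defaults$allometry, allometry)
  structure(defaults, class = "scenario")
}

#' @param x A `scenario` object.
#' @param path YAML file path.
#' @rdname scenario
#' @export
write_scenario <- function(x, path) {
  out <- unclass(x)
  # named numeric vectors serialize as YAML maps only as lists
  out$npp$profiles <- lapply(out$npp$profiles, as.list)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname scenario
#' @export
read_scenario <- function(path) {
  raw <- yaml::read_yaml(path)
  sc <- scenario(seed = raw$seed, chronology = raw$chronology, npp = raw$npp,
                 pollen = raw$pollen, allometry = raw$allometry)
  # yaml flattens named numeric vectors to lists; restore
  sc$npp$profiles <- lapply(raw$npp$profiles, function(p) unlist(p))
  sc
}

#' Synthetic calibration curves
#'
#' `syn_calcurve()` builds a smooth, strictly invertible synthetic
#' calibration curve with gentle wiggles (derivative bounded away from zero)
#' and an age-growing curve uncertainty; `identity_calcurve()` maps calendar
#' age to itself with negligible curve error, so calibrated medians equal
#' true ages - useful as a round-trip oracle.
#'
#' @param from,to,by Calendar grid (cal BP).
#' @return A [calcurve].
#' @export
syn_calcurve <- function(from = 0, to = 60000, by = 20) {
  grid <- seq(from, to, by = by)
  mu <- 0.95 * grid + 150 * sin(2 * pi * grid / 5000)
  sigma <- 15 + 0.004 * grid
  calcurve(grid, mu, sigma, name = "synthetic-wiggle")
}

#' @rdname syn_calcurve
#' @export
identity_calcurve <- function(from = 0, to = 60000, by = 20) {
  grid <- seq(from, to, by = by)
  calcurve(grid, grid, rep(1e-6, length(grid)), name = "identity")
}

#' Generate a chronometric dataset with known boundaries
#'
#' Draws true calendar ages uniformly over the scenario's occupation
#' interval (the simplest process consistent with the extreme-value
#' assumptions of boundary estimation), maps them through the calibration
#' curve to radiocarbon ages, adds normal lab noise, and injects a known
#' fraction of shell-material, flagged, and high-CV determinations so that
#' the filtering rules have work to do.
#'
#' @param scn A [scenario()].
#' @param curve A [calcurve] covering the occupation interval.
#' @param seed Overrides the scenario seed.
#' @return List with `dates` (a data frame in the standard dates-table
#'   schema) and `truth` (true boundaries and per-date true calendar ages).
#' @export
gen_radiocarbon_dataset <- function(scn, curve, seed = NULL) {
  ch <- scn$chronology
  set.seed(seed %||% scn$seed)
  if (ch$true_start <= ch$true_end) stop("true_start must be older than true_end")
  if (ch$true_start > max(curve$grid) || ch$true_end < min(curve$grid))
    stop("occupation interval lies outside the calibration curve support")
  n <- ch$n_levels * ch$dates_per_level
  level <- rep(seq_len(ch$n_levels), each = ch$dates_per_level)
  true_age <- rep(stats::runif(ch$n_levels, ch$true_end, ch$true_start),
                  each = ch$dates_per_level)
  mu <- curve_at(curve, true_age)$mu
  cv <- stats::runif(n, ch$error_cv[1], ch$error_cv[2])
  err <- pmax(cv * mu, 30)
  age14c <- stats::rnorm(n, mu, err)
  material <- rep("bone", n)
  flags <- rep("", n)
  material[seq_len(floor(ch$shell_frac * n))] <- "shell"
  fl <- floor(ch$flagged_frac * n)
  if (fl > 0) flags[floor(ch$shell_frac * n) + seq_len(fl)] <- "stratigraphic_issue"
  hc <- floor(ch$highcv_frac * n)
  if (hc > 0) {
    idx <- n - seq_len(hc) + 1
    err[idx] <- age14c[idx] * 0.06  # push CV over the 0.05 threshold
  }
  dates <- data.frame(
    lab_code = sprintf("SYN-%04d", seq_len(n)),
    site_id = sprintf("site%02d", (level - 1) %/% 3 + 1),
    level_id = sprintf("L%02d", level),
    region = "Eurosiberian", culture = "Mousterian", method = "14C",
    age = round(age14c), error_1sigma = round(err),
    material = material, flags = flags, stringsAsFactors = FALSE)
  list(dates = dates,
       truth = list(true_start = ch$true_start, true_end = ch$true_end,
                    true_age = true_age,
                    injected = list(shell = which(material == "shell"),
                                    flagged = which(nzchar(flags)),
                                    high_cv = which(err / age14c >= 0.05))))
}

#' Generate productivity series with planted cluster structure
#'
#' Builds per-site series on a shared time grid: each region follows its
#' scenario profile (one mean per phase kind) plus Gaussian noise, so sites
#' sharing a profile form a recoverable cluster and stadial/interstadial
#' contrasts are planted by construction.
#'
#' @param scn A [scenario()].
#' @param phases A [phase_table()].
#' @param seed Overrides the scenario seed.
#' @return List with `series` (list of [npp_series]), `truth` (integer
#'   cluster label per site, profile means) and `regions` (per site).
#' @export
gen_npp_series <- function(scn, phases, seed = NULL) {
  np <- scn$npp
  set.seed(seed %||% scn$seed)
  times <- seq(np$t_from, np$t_to, by = -abs(np$t_step))
  kind <- classify_phase(times, phases)$kind
  if (anyNA(kind)) stop("phase table does not cover the scenario time grid")
  series <- list(); labels <- integer(0); regions <- character(0)
  prof_id <- 0L
  for (region in names(np$profiles)) {
    prof_id <- prof_id + 1L
    prof <- np$profiles[[region]]
    base <- unname(prof[kind])
    for (s in seq_len(np$sites_per_region)) {
      vals <- pmax(base + stats::rnorm(length(times), 0, np$noise_sd), 0)
      id <- sprintf("%s_%02d", region, s)
      series[[id]] <- npp_series(id, region, times, vals, unit = np$unit)
      labels <- c(labels, prof_id); regions <- c(regions, region)
    }
  }
  names(labels) <- names(series)
  list(series = series, truth = list(labels = labels, profiles = np$profiles),
       regions = stats::setNames(regions, names(series)))
}

#' Generate pollen training and fossil data with known climates
#'
#' Taxon abundances follow unimodal Gaussian response curves centred on
#' known optima spread along a climate gradient; counts are multinomial at
#' the scenario's count depth. Fossil samples are drawn at held-out
#' climates, giving a ground truth for transfer-function recovery tests.
#'
#' @param scn A [scenario()].
#' @param seed Overrides the scenario seed.
#' @param noise_free If TRUE, percentages are the exact response-curve
#'   proportions (infinite count depth).
#' @return List with `train` (`Y` matrix, `climate` vector), `fossils`
#'   (list of [pollen_assemblage]), `truth` (taxon optima, fossil climates).
#' @export
gen_pollen <- function(scn, seed = NULL, noise_free = FALSE) {
  po <- scn$pollen
  set.seed(seed %||% scn$seed)
  optima <- seq(po$mat_range[1], po$mat_range[2], length.out = po$n_taxa)
  taxa <- sprintf("taxon%02d", seq_len(po$n_taxa))
  names(optima) <- taxa
  response <- function(x) {
    w <- exp(-(x - optima)^2 / (2 * po$tolerance^2))
    w / sum(w)
  }
  draw <- function(x) {
    pr <- response(x)
    if (noise_free) 100 * pr
    else {
      counts <- stats::rmultinom(1, po$count_depth, pr)[, 1]
      100 * counts / sum(counts)
    }
  }
  x_train <- stats::runif(po$n_train, po$mat_range[1], po$mat_range[2])
  Y <- t(vapply(x_train, draw, numeric(po$n_taxa)))
  colnames(Y) <- taxa
  x_fossil <- stats::runif(po$n_fossil, po$mat_range[1] + 2, po$mat_range[2] - 2)
  fossils <- lapply(seq_along(x_fossil), function(i)
    pollen_assemblage(sprintf("fossil%02d", i), draw(x_fossil[i]),
                      total_count = po$count_depth))
  list(train = list(Y = Y, climate = x_train), fossils = fossils,
       truth = list(optima = optima, fossil_climate = x_fossil))
}

#' Generate a modern herbivore density compilation
#'
#' Emulates a protected-area census compilation: per site, productivity is
#' drawn log-uniform, total herbivore biomass follows the scenario's
#' log-log law with lognormal scatter, species masses are log-uniform, and
#' observed densities are the exact Damuth partition perturbed by optional
#' per-species lognormal noise.
#'
#' @param scn A [scenario()].
#' @param seed Overrides the scenario seed.
#' @return List with `sites` (list of records usable by [validate_model()]:
#'   `site`, `npp`, `thb_obs`, `species` data frame) and `truth`
#'   (slope, intercept, scatter).
#' @export
gen_modern_density_dataset <- function(scn, seed = NULL) {
  al <- scn$allometry
  set.seed(seed %||% scn$seed)
  sites <- vector("list", al$n_sites)
  for (i in seq_len(al$n_sites)) {
    npp <- 10^stats::runif(1, log10(al$npp_range[1]), log10(al$npp_range[2]))
    thb <- 10^(al$intercept + al$slope * log10(npp) +
               stats::rnorm(1, 0, al$scatter_sd))
    S <- sample(al$richness[1]:al$richness[2], 1)
    w <- 10^stats::runif(S, log10(al$mass_range[1]), log10(al$mass_range[2]))
    names(w) <- sprintf("sp%02d", seq_len(S))
    part <- partition_biomass(thb, w)
    dens <- part$density * 10^stats::rnorm(S, 0, al$density_noise_sd)
    sites[[i]] <- list(site = sprintf("pa%03d", i), npp = npp, thb_obs = thb,
                       species = data.frame(taxon = part$taxon,
                                            mass_kg = part$mass_kg,
                                            density_obs = dens))
  }
  list(sites = sites,
       truth = list(slope = al$slope, intercept = al$intercept,
                    scatter_sd = al$scatter_sd))
}
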