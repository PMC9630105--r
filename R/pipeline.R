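#' Pipeline run configuration
#'
#' Validates a run configuration before anything executes, so a broken
#' configuration fails fast rather than mid-run. A configuration is a named
#' list (or YAML file) with a `paths` block (dates, curve, phases required;
#' npp, pollen_train, pollen_fossil, densities, lfas optional), a
#' `parameters` block (step, k, n_clusters, m, iters, boot, seed; defaults
#' mirror the study-level choices: 20 yr grid, k = 2, 3 clusters, m = 10,
#' 10000 iterations, 500 boot cycles), a `units` block declaring NPP units,
#' and an `out_dir`.
#'
#' @param config Named list or path to a YAML file.
#' @return The validated configuration (with defaults filled in).
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config), !is.null(config$paths), !is.null(config$out_dir))
  req <- c("dates", "curve", "phases")
  missing_req <- setdiff(req, names(config$paths))
  if (length(missing_req))
    stop("configuration is missing required path(s): ",
         paste(missing_req, collapse = ", "))
  for (nm in names(config$paths)) {
    p <- config$paths[[nm]]
    if (!is.null(p) && !file.exists(p))
      stop("configured path does not exist: ", nm, " = ", p)
  }
  defaults <- list(step = 20, k = 2, n_clusters = 3, m = 10, iters = 10000,
                   boot = 500, seed = 1L)
  pars <- config$parameters %||% list()
  for (nm in names(defaults)) pars[[nm]] <- pars[[nm]] %||% defaults[[nm]]
  config$parameters <- pars
  config$units <- config$units %||% list(npp_series = "kg km-2 yr-1",
                                         allometry_npp = "g m-2 yr-1")
  config
}

#' Run the full analysis pipeline
#'
#' Orchestrates every stage on the configured inputs: date filtering,
#' same-level combination, calibration, summed probability distributions and
#' boundary estimation per culture and region; productivity phase statistics,
#' dCORT clustering and regional cluster composition; optional pollen
#' transfer functions with bootstrap cross-validation; optional allometry
#' refit and validation on a modern density compilation; optional
#' minimum-census carrying-capacity estimates per region and phase. Writes
#' CSV/JSON artifacts plus a manifest (seeds, parameters, row counts, file
#' hashes) into `out_dir`. Any stage failure aborts with the stage name.
#'
#' @param config See [validate_config()].
#' @return Invisibly, the artifact bundle (a named list of results).
#' @export
run_pipeline <- function(config) {
  config <- validate_config(config)
  pars <- config$parameters
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  bundle <- list(config = config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  curve <- stage("curve", read_calcurve(config$paths$curve))
  phases <- stage("phases", read_phase_table(config$paths$phases))
  dates <- stage("dates", utils::read.csv(config$paths$dates,
                                          stringsAsFactors = FALSE))

  # chronology: filter, merge, calibrate, SPD + boundary estimates
  bundle$filter <- stage("filter", filter_for_spd(dates))
  kept <- bundle$filter$kept
  bundle$assemblages <- stage("calibrate",
    suppressWarnings(assemble_levels(kept, curve, step = pars$step)))
  groups <- split(seq_along(bundle$assemblages),
                  paste(vapply(bundle$assemblages, `[[`, "", "region"),
                        vapply(bundle$assemblages, `[[`, "", "culture"),
                        sep = "|"))
  bundle$spd <- lapply(groups, function(ix)
    spd(bundle$assemblages[ix], step = pars$step))
  boundaries <- list()
  for (g in names(groups)) {
    ax <- bundle$assemblages[groups[[g]]]
    cal_tab <- data.frame(
      median = vapply(ax, function(a) a$density$median, 0),
      lower = vapply(ax, function(a) a$density$range95[["lower"]], 0),
      upper = vapply(ax, function(a) a$density$range95[["upper"]], 0))
    if (nrow(cal_tab) < 3) next
    parts <- strsplit(g, "|", fixed = TRUE)[[1]]
    for (w in c("oldest", "youngest")) {
      ss <- select_terminal_dates(cal_tab, which = w, m = pars$m)
      est <- stage(paste("ole", g, w),
                   ole_resample(ss, n_iter = pars$iters, seed = pars$seed))
      boundaries[[length(boundaries) + 1]] <- data.frame(
        region = parts[1], culture = parts[2],
        boundary = if (w == "youngest") "end" else "start",
        median = est$point, lower = est$ci95[["lower"]],
        upper = est$ci95[["upper"]], n_iter = est$n_iter)
    }
  }
  bundle$boundaries <- if (length(boundaries)) do.call(rbind, boundaries)
    else data.frame()

  # productivity dynamics
  if (!is.null(config$paths$npp)) {
    npp_long <- stage("npp", utils::read.csv(config$paths$npp,
                                             stringsAsFactors = FALSE))
    series <- lapply(split(npp_long, npp_long$site_id), function(d) {
      d <- d[order(-d$time_kyr_bp), ]
      npp_series(d$site_id[1], d$region[1], d$time_kyr_bp, d$npp,
                 unit = config$units$npp_series)
    })
    D <- stage("dcort", dissimilarity_matrix(series, k = pars$k))
    cl <- stage("cluster", cluster_series(D, n_clusters = pars$n_clusters))
    regions <- vapply(series, `[[`, "", "region")
    bundle$clusters <- list(labels = cl$labels, tree = cl$tree,
                            composition = cluster_region_composition(
                              cl$labels, regions))
    bundle$phase_stats <- stage("phase_stats", {
      out <- list()
      for (r in unique(regions)) {
        sr <- series[regions == r]
        times <- rep(sr[[1]]$times, length(sr))
        vals <- unlist(lapply(sr, `[[`, "values"))
        st <- suppressWarnings(phase_stats(times, vals, phases))
        st$summary$region <- r
        st$summary$W <- st$test$W
        st$summary$p <- st$test$p
        out[[r]] <- st$summary
      }
      do.call(rbind, out)
    })
  }

  # pollen transfer functions
  if (!is.null(config$paths$pollen_train)) {
    tr <- stage("pollen_train", utils::read.csv(config$paths$pollen_train,
                                                stringsAsFactors = FALSE))
    clim_cols <- intersect(c("MAT", "MAP"), names(tr))
    taxa_cols <- setdiff(names(tr), c("sample_id", clim_cols))
    Y <- as.matrix(tr[, taxa_cols, drop = FALSE])
    bundle$transfer <- list()
    for (v in clim_cols) {
      tf <- stage(paste("wa_fit", v), wa_fit(Y, tr[[v]], variable = v))
      cvr <- stage(paste("wa_cv", v),
                   bootstrap_cv(Y, tr[[v]], variable = v,
                                n_boot = pars$boot, seed = pars$seed))
      bundle$transfer[[v]] <- list(tf = tf, cv = cvr)
    }
    if (!is.null(config$paths$pollen_fossil)) {
      fo <- utils::read.csv(config$paths$pollen_fossil, stringsAsFactors = FALSE)
      fx <- lapply(seq_len(nrow(fo)), function(i) {
        taxa <- unlist(fo[i, setdiff(names(fo), c("sample_id", "total_count"))])
        filter_pollen(pollen_assemblage(fo$sample_id[i], taxa,
                                        total_count = fo$total_count[i]))
      })
      keep_f <- vapply(fx, inherits, TRUE, "pollen_assemblage")
      bundle$pollen_rejected <- fx[!keep_f]
      bundle$reconstructions <- do.call(rbind, lapply(fx[keep_f], function(a) {
        row <- data.frame(sample_id = a$sample_id)
        for (v in names(bundle$transfer))
          row[[v]] <- predict(bundle$transfer[[v]]$tf, a)
        row
      }))
    }
  }

  # allometry: refit on modern data and validate
  if (!is.null(config$paths$densities)) {
    dd <- stage("densities", utils::read.csv(config$paths$densities,
                                             stringsAsFactors = FALSE))
    per_site <- split(dd, dd$site)
    thb_obs <- vapply(per_site, function(d) sum(d$density * d$mass_kg), 0)
    npp_site <- vapply(per_site, function(d) d$npp[1], 0)
    model <- stage("fit_thb", fit_thb_model(npp_site, thb_obs,
      units = c(npp = config$units$allometry_npp,
                thb = config$units$allometry_npp)))
    records <- lapply(per_site, function(d)
      list(site = d$site[1], npp = d$npp[1],
           species = data.frame(taxon = d$taxon, mass_kg = d$mass_kg,
                                density_obs = d$density)))
    bundle$allometry <- list(model = model,
                             validation = stage("validate",
                               validate_model(records, model)))
  }

  # carrying capacity per region x phase (needs model, NPP stats and LFAs)
  if (!is.null(config$paths$lfas) && !is.null(bundle$allometry) &&
      !is.null(bundle$phase_stats)) {
    lfas <- stage("lfas", utils::read.csv(config$paths$lfas,
                                          stringsAsFactors = FALSE))
    census <- stage("minimum_census", minimum_census(lfas, phases))
    masses <- stats::setNames(lfas$mass_kg, lfas$species)
    masses <- masses[!duplicated(names(masses))]
    cc_rows <- list()
    for (i in seq_len(nrow(bundle$phase_stats))) {
      r <- bundle$phase_stats$region[i]; kind <- bundle$phase_stats$kind[i]
      mem <- census$membership
      sp <- unique(mem$species[mem$region == r & mem$kind == kind])
      if (length(sp) == 0) next
      npp_gm2 <- npp_convert(bundle$phase_stats$mean[i],
                             from = config$units$npp_series,
                             to = bundle$allometry$model$units[["npp"]])
      thb <- predict(bundle$allometry$model, npp_gm2)
      part <- partition_biomass(thb, masses[sp])
      cc_rows[[length(cc_rows) + 1]] <- data.frame(
        region = r, kind = kind, THB = thb, n_species = length(sp),
        t(size_class_totals(part)))
    }
    bundle$carrying_capacity <- if (length(cc_rows)) do.call(rbind, cc_rows)
      else data.frame()
  }

  emit_tables(bundle, config$out_dir)
  invisible(bundle)
}

#' Write pipeline artifacts and the run manifest
#'
#' Emits the phase-statistics table (one row per region and phase kind:
#' mean, sd, CV%, rank-sum W and p), the boundary table (one row per region,
#' culture and boundary: resampled median and 95% bounds), SPD series,
#' cluster assignments, carrying-capacity and reconstruction tables, a JSON
#' mirror of the two headline tables, and `manifest.json` with parameters,
#' seeds, row counts and md5 hashes of every artifact.
#'
#' @param bundle Result of [run_pipeline()] (called internally).
#' @param out_dir Output directory.
#' @return Invisibly, the manifest list.
#' @export
emit_tables <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  wcsv <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    files <<- c(files, p)
  }
  if (!is.null(bundle$boundaries) && nrow(bundle$boundaries))
    wcsv(bundle$boundaries, "boundaries.csv")
  if (!is.null(bundle$phase_stats))
    wcsv(bundle$phase_stats, "phase_stats.csv")
  if (!is.null(bundle$spd))
    for (g in names(bundle$spd))
      wcsv(bundle$spd[[g]], paste0("spd_", gsub("[^A-Za-z0-9]+", "_", g), ".csv"))
  if (!is.null(bundle$clusters)) {
    wcsv(data.frame(site_id = names(bundle$clusters$labels),
                    cluster = unname(bundle$clusters$labels)),
         "cluster_assignments.csv")
    if (requireNamespace("ape", quietly = TRUE)) {
      nwk <- file.path(out_dir, "dendrogram.nwk")
      ape::write.tree(ape::as.phylo(bundle$clusters$tree), nwk)
      files <- c(files, nwk)
    }
  }
  if (!is.null(bundle$reconstructions))
    wcsv(bundle$reconstructions, "climate_reconstructions.csv")
  if (!is.null(bundle$carrying_capacity) && nrow(bundle$carrying_capacity))
    wcsv(bundle$carrying_capacity, "carrying_capacity.csv")
  tables_json <- file.path(out_dir, "tables.json")
  jsonlite::write_json(list(phase_stats = bundle$phase_stats,
                            boundaries = bundle$boundaries),
                       tables_json, auto_unbox = TRUE, digits = NA, na = "null")
  files <- c(files, tables_json)
  manifest <- list(
    parameters = bundle$config$parameters,
    units = bundle$config$units,
    counts = list(
      assemblages = length(bundle$assemblages),
      dates_kept = nrow(bundle$filter$kept),
      dates_removed = nrow(bundle$filter$removed),
      boundaries = if (is.null(bundle$boundaries)) 0 else nrow(bundle$boundaries)),
    files = as.list(stats::setNames(unname(tools::md5sum(files)),
                                    basename(files))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Write a complete synthetic study to disk
#'
#' Materialises a scenario as the CSV/curve inputs the pipeline reads, plus
#' a ready-to-run YAML configuration, so an end-to-end run needs no external
#' data.
#'
#' @param scn A [scenario()].
#' @param dir Output directory.
#' @param curve A [calcurve] (default [syn_calcurve()]).
#' @return The path of the written `run.yaml`.
#' @export
simulate_to_dir <- function(scn, dir, curve = syn_calcurve()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  # calibration curve
  curve_path <- file.path(dir, "curve.14c")
  writeLines(c("# synthetic calibration curve",
               sprintf("%g,%g,%g", curve$grid, curve$mu14c, curve$sigma_curve)),
             curve_path)
  # phase table
  phases_path <- file.path(dir, "phases.csv")
  file.copy(system.file("extdata", "phases_gs_gi.csv", package = "paleotrophic"),
            phases_path, overwrite = TRUE)
  phases <- read_phase_table(phases_path)
  # chronometric dates
  chron <- gen_radiocarbon_dataset(scn, curve)
  dates_path <- file.path(dir, "dates.csv")
  utils::write.csv(chron$dates, dates_path, row.names = FALSE)
  # NPP series
  npp <- gen_npp_series(scn, phases)
  npp_long <- do.call(rbind, lapply(npp$series, function(s)
    data.frame(site_id = s$site_id, region = s$region,
               time_kyr_bp = s$times, npp = s$values)))
  npp_path <- file.path(dir, "npp_long.csv")
  utils::write.csv(npp_long, npp_path, row.names = FALSE)
  # pollen
  pol <- gen_pollen(scn)
  train <- data.frame(sample_id = sprintf("mod%03d", seq_len(nrow(pol$train$Y))),
                      MAT = pol$train$climate, pol$train$Y)
  train_path <- file.path(dir, "pollen_train.csv")
  utils::write.csv(train, train_path, row.names = FALSE)
  fossil <- do.call(rbind, lapply(pol$fossils, function(a)
    data.frame(sample_id = a$sample_id, total_count = a$total_count,
               as.list(a$taxa))))
  fossil_path <- file.path(dir, "pollen_fossil.csv")
  utils::write.csv(fossil, fossil_path, row.names = FALSE)
  # modern densities
  dens <- gen_modern_density_dataset(scn)
  dens_long <- do.call(rbind, lapply(dens$sites, function(s)
    data.frame(site = s$site, npp = s$npp, taxon = s$species$taxon,
               mass_kg = s$species$mass_kg, density = s$species$density_obs)))
  dens_path <- file.path(dir, "modern_densities.csv")
  utils::write.csv(dens_long, dens_path, row.names = FALSE)
  # LFAs: one herbivore list per region with ranges inside the study window
  set.seed(scn$seed + 7)
  taxa <- c("Equus ferus" = 400, "Cervus elaphus" = 180, "Capra pyrenaica" = 60,
            "Rupicapra rupicapra" = 30, "Bos primigenius" = 700,
            "Capreolus capreolus" = 25, "Sus scrofa" = 90,
            "Oryctolagus cuniculus" = 1.5)
  lfa_rows <- list()
  for (r in names(scn$npp$profiles)) {
    for (sp in sample(names(taxa), 6)) {
      centre <- stats::runif(2, 31000, 53000)
      lfa_rows[[length(lfa_rows) + 1]] <- data.frame(
        species = sp, region = r, mass_kg = taxa[[sp]],
        lower = min(centre) - 500, upper = max(centre) + 500)
    }
  }
  lfas_path <- file.path(dir, "lfas.csv")
  utils::write.csv(do.call(rbind, lfa_rows), lfas_path, row.names = FALSE)
  # scenario + config
  write_scenario(scn, file.path(dir, "scenario.yaml"))
  config <- list(
    paths = list(dates = dates_path, curve = curve_path, phases = phases_path,
                 npp = npp_path, pollen_train = train_path,
                 pollen_fossil = fossil_path, densities = dens_path,
                 lfas = lfas_path),
    parameters = list(step = 20, k = 2, n_clusters = 3, m = 10,
                      iters = 500, boot = 100, seed = scn$seed),
    units = list(npp_series = scn$npp$unit, allometry_npp = "g m-2 yr-1"),
    out_dir = file.path(dir, "out"))
  cfg_path <- file.path(dir, "run.yaml")
  yaml::write_yaml(config, cfg_path)
  cfg_path
}
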