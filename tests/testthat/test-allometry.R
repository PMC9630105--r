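test_that("THB prediction follows the log-log law", {
  m <- thb_model()  # published coefficients
  expect_equal(predict(m, 1), 10^(-0.642), tolerance = 1e-12)
  expect_equal(predict(m, 10) / predict(m, 1), 10^1.401, tolerance = 1e-9)
  ident <- thb_model(slope = 1, intercept = 0)
  expect_equal(predict(ident, c(0.5, 3, 42)), c(0.5, 3, 42))
  expect_error(predict(m, -1), "positive")
})

test_that("an exact two-point fit reproduces the line", {
  # two points on log10(THB) = 1.2 log10(NPP) + 0.3 (least-squares path)
  npp <- c(10, 1000)
  thb <- 10^(0.3 + 1.2 * log10(npp))
  fit <- fit_thb_model(npp, thb)
  expect_equal(fit$slope, 1.2, tolerance = 1e-9)
  expect_equal(fit$intercept, 0.3, tolerance = 1e-9)
  expect_error(fit_thb_model(c(1, -2, 3), c(1, 2, 3)), "non-positive")
})

test_that("the robust fit recovers planted coefficients and resists outliers", {
  g <- gen_modern_density_dataset(scenario(seed = 14,
                                           allometry = list(n_sites = 500)))
  npp <- vapply(g$sites, `[[`, 0, "npp")
  thb <- vapply(g$sites, `[[`, 0, "thb_obs")
  fit <- fit_thb_model(npp, thb)
  expect_equal(fit$method, "MM")
  expect_true(fit$ci["x", "lower"] <= 1.401 && 1.401 <= fit$ci["x", "upper"])
  expect_lt(abs(fit$intercept - (-0.642)), 0.05)

  # inject 10% gross outliers: the robust slope moves less than least squares
  set.seed(99)
  out <- sample(length(thb), 50)
  thb_bad <- thb
  thb_bad[out] <- thb_bad[out] * 10^3
  rob <- fit_thb_model(npp, thb_bad, method = "MM")
  ols <- fit_thb_model(npp, thb_bad, method = "ls")
  expect_lt(abs(rob$slope - 1.401), abs(ols$slope - 1.401))
})

test_that("coefficient recovery lands inside the 95% CI at the expected rate", {
  hits <- 0L
  n_rep <- 40
  for (i in seq_len(n_rep)) {
    g <- gen_modern_density_dataset(scenario(seed = 3000 + i,
                                             allometry = list(n_sites = 200)))
    fit <- fit_thb_model(vapply(g$sites, `[[`, 0, "npp"),
                         vapply(g$sites, `[[`, 0, "thb_obs"))
    if (fit$ci["x", "lower"] <= 1.401 && 1.401 <= fit$ci["x", "upper"])
      hits <- hits + 1L
  }
  expect_gte(hits / n_rep, 0.9)
})

test_that("the Damuth constant follows quarter-power arithmetic", {
  expect_equal(damuth_constant(100, c(16, 81)), 20)  # sum W^(1/4) = 2 + 3
  expect_equal(damuth_constant(55, 1), 55)
  expect_equal(damuth_constant(0, c(10, 20)), 0)
  expect_error(damuth_constant(10, numeric(0)), "at least one species")
})

test_that("biomass partitioning matches hand evaluation and closes exactly", {
  part <- partition_biomass(100, c(small = 16, big = 81))
  expect_equal(part$biomass, c(40, 60), tolerance = 1e-12)
  expect_equal(part$density, c(20 * 16^-0.75, 20 * 81^-0.75), tolerance = 1e-9)
  expect_equal(part$density[2], 0.7407, tolerance = 1e-4)
  expect_equal(sum(part$biomass), 100, tolerance = 1e-12)

  one <- partition_biomass(37, c(x = 250))
  expect_equal(one$biomass, 37)
  expect_equal(one$density, 37 / 250)

  equal_masses <- partition_biomass(90, setNames(rep(50, 3), letters[1:3]))
  expect_equal(equal_masses$biomass, rep(30, 3))

  expect_error(partition_biomass(10, c(a = 5, a = 7)), "duplicate")
})

test_that("partitioning conserves biomass and scales allometrically on random communities", {
  set.seed(123)
  for (i in 1:200) {
    S <- sample(2:15, 1)
    w <- 10^runif(S, 0, 3)
    names(w) <- paste0("s", seq_len(S))
    thb <- 10^runif(1, 1, 4)
    part <- partition_biomass(thb, w)
    expect_equal(sum(part$biomass), thb, tolerance = 1e-9 * thb)
    # log-log slopes are exactly 1/4 and -3/4
    expect_equal(unname(coef(lm(log10(part$biomass) ~ log10(part$mass_kg)))[2]),
                 0.25, tolerance = 1e-9)
    expect_equal(unname(coef(lm(log10(part$density) ~ log10(part$mass_kg)))[2]),
                 -0.75, tolerance = 1e-9)
  }
})

test_that("size classes partition species on the documented half-open bounds", {
  expect_equal(as.character(size_class(c(5, 50, 200, 800))),
               c("small", "medium", "medium_large", "large"))
  expect_equal(as.character(size_class(c(10, 100, 500))),
               c("medium", "medium_large", "large"))
  part <- partition_biomass(100, c(a = 50, b = 50))
  totals <- size_class_totals(part)
  expect_equal(unname(totals["medium"]), 100)
  expect_equal(sum(totals), 100)
  mixed <- partition_biomass(120, c(a = 5, b = 50, c = 200, d = 800))
  expect_equal(sum(size_class_totals(mixed)), 120, tolerance = 1e-9)
  expect_true(all(size_class_totals(mixed) > 0))
})

test_that("model validation is a noise-free round trip and degrades with noise", {
  g0 <- gen_modern_density_dataset(scenario(seed = 6,
    allometry = list(n_sites = 40, scatter_sd = 0, density_noise_sd = 0)))
  truth_model <- thb_model()
  v0 <- validate_model(g0$sites, truth_model)
  expect_true(all(abs(v0$per_site$r - 1) < 1e-9))
  expect_equal(v0$fraction_significant, 1)

  pooled_r <- vapply(c(0, 0.2, 0.6), function(sd) {
    g <- gen_modern_density_dataset(scenario(seed = 61,
      allometry = list(n_sites = 40, scatter_sd = 0, density_noise_sd = sd)))
    validate_model(g$sites, truth_model)$pooled$r
  }, 0)
  expect_true(all(diff(pooled_r) < 0))

  # pairing is by taxon, so permuting species rows changes nothing
  g1 <- g0
  g1$sites[[1]]$species <- g1$sites[[1]]$species[rev(seq_len(
    nrow(g1$sites[[1]]$species))), ]
  v1 <- validate_model(g1$sites, truth_model)
  expect_equal(v1$per_site$r, v0$per_site$r, tolerance = 1e-9)
})

test_that("minimum census extends species membership over chronological ranges", {
  ph <- fixture_phases()
  lfas <- data.frame(
    species = c("Cervus", "Cervus", "Equus"),
    region = "Mesomediterranean",
    lower = c(42000, 43500, 36000),
    upper = c(43200, 44100, 37000))
  mc <- minimum_census(lfas, ph)
  # Cervus is directly dated only around GI-11/GS-12 but its chronological
  # envelope 42000-44100 also reaches into GS-11
  cervus <- mc$membership[mc$membership$species == "Cervus", "phase"]
  expect_setequal(cervus, c("GS-12", "GI-11", "GS-11"))
  # Equus and Cervus never share a phase: ranges are disjoint
  eq <- mc$membership[mc$membership$species == "Equus", "phase"]
  expect_length(intersect(eq, cervus), 0)
  expect_equal(mc$ranges$oldest[mc$ranges$species == "Cervus"], 44100)
  # a single-LFA species takes its own interval as range
  expect_equal(mc$ranges$youngest[mc$ranges$species == "Equus"], 36000)
})

test_that("minimum census recovers planted species spans", {
  ph <- fixture_phases()
  set.seed(52)
  spans <- data.frame(species = paste0("sp", 1:6),
                      from = runif(6, 45000, 52000))
  spans$to <- spans$from - runif(6, 3000, 9000)
  lfa_rows <- do.call(rbind, lapply(seq_len(nrow(spans)), function(i) {
    centres <- runif(4, spans$to[i] + 400, spans$from[i] - 400)
    data.frame(species = spans$species[i], region = "R",
               lower = centres - 400, upper = centres + 400)
  }))
  mc <- minimum_census(lfa_rows, ph)
  for (i in seq_len(nrow(spans))) {
    got <- mc$ranges[mc$ranges$species == spans$species[i], ]
    expect_lte(got$oldest, spans$from[i])
    expect_gte(got$youngest, spans$to[i])
    # membership covers every phase the envelope overlaps
    phases_hit <- ph$name[ph$start_kyr_bp * 1000 > got$youngest &
                          ph$end_kyr_bp * 1000 < got$oldest]
    member <- mc$membership$phase[mc$membership$species == spans$species[i]]
    expect_setequal(member, phases_hit)
  }
})

test_that("rarefaction interpolation equals the exhaustive-subset oracle", {
  set.seed(77)
  for (rep in 1:6) {
    H <- sample(2:8, 1); S <- sample(1:6, 1)
    M <- matrix(runif(H * S) < 0.6, H, S)
    if (all(colSums(M) == 0)) M[1, ] <- TRUE
    for (h in 1:H) {
      expect_equal(paleotrophic:::richness_at(M, h),
                   exhaustive_richness(M, h), tolerance = 1e-9,
                   label = sprintf("H=%d S=%d h=%d", H, S, h))
    }
    # endpoint identity: at full effort the expectation is observed richness
    expect_equal(paleotrophic:::richness_at(M, H), sum(colSums(M) > 0))
  }
})

test_that("rarefaction agrees with vegan's exact accumulation curve", {
  skip_if_not_installed("vegan")
  set.seed(15)
  M <- matrix(runif(60) < 0.4, 10, 6)
  M[1, ] <- TRUE
  acc <- vegan::specaccum(as.data.frame(M * 1), method = "exact")
  for (h in 1:10)
    expect_equal(paleotrophic:::richness_at(M, h), acc$richness[h],
                 tolerance = 1e-8)
})

test_that("rarefaction extrapolates saturated and undersampled communities sensibly", {
  sat <- matrix(TRUE, 5, 4)
  r <- rarefy_richness(sat, target = 100, n_boot = 50, seed = 1)
  expect_equal(r$expected_S, 4)
  expect_equal(r$ci95, c(4, 4))

  set.seed(19)
  M <- matrix(runif(80) < 0.25, 10, 8)
  M[2, ] <- TRUE
  r2 <- rarefy_richness(M, target = 100, n_boot = 100, seed = 2)
  expect_gte(r2$expected_S, r2$observed_S)
  expect_true(r2$ci95[1] <= r2$expected_S)
  expect_error(rarefy_richness(M, target = 0), "target")
  same <- rarefy_richness(M, target = 100, n_boot = 100, seed = 2)
  expect_equal(same$ci95, r2$ci95)
})

test_that("regression uncertainty maps linearly through the partition", {
  g <- gen_modern_density_dataset(scenario(seed = 9,
                                           allometry = list(n_sites = 120)))
  fit <- fit_thb_model(vapply(g$sites, `[[`, 0, "npp"),
                       vapply(g$sites, `[[`, 0, "thb_obs"))
  masses <- c(horse = 400, deer = 180, ibex = 60)
  pc <- propagate_ci(fit, 300, masses)
  expect_true(pc$thb$lower < pc$thb$fit && pc$thb$fit < pc$thb$upper)
  # endpoints map monotonically for every species
  expect_true(all(pc$lower$biomass < pc$point$biomass))
  expect_true(all(pc$point$biomass < pc$upper$biomass))
  # the class interval is the hand-mapped band: linear in THB
  ratio <- pc$upper$biomass / pc$lower$biomass
  expect_equal(ratio, rep(pc$thb$upper / pc$thb$lower, 3), tolerance = 1e-9)
  expect_error(propagate_ci(thb_model(), 300, masses), "uncertainty")
})
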