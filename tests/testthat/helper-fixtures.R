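# Shared fixtures built in code.

# a toy dates table exercising all three SPD filtering rules
toy_dates <- function() {
  data.frame(
    lab_code = sprintf("D%02d", 1:10),
    site_id = "siteA", level_id = sprintf("L%02d", 1:10),
    region = "Eurosiberian", culture = "Mousterian", method = "14C",
    age = rep(40000, 10),
    error_1sigma = c(400, 400, 400, 400, 400, 400, 2000, 400, 400, 400),
    material = c("shell", "shell", rep("bone", 8)),
    flags = c("", "", "stratigraphic_issue", rep("", 7)),
    stringsAsFactors = FALSE)
}

# identity calibration: calendar age maps to itself, negligible curve error
id_curve <- function() identity_calcurve(30000, 50000, 20)

fixture_phases <- function() {
  read_phase_table(system.file("extdata", "phases_gs_gi.csv",
                               package = "paleotrophic"))
}

# three well-separated productivity profiles: a stadial drop, an anti-phase
# rise, and a flat trajectory
three_profile_scenario <- function(seed, noise_sd = 0.01) {
  scenario(seed = seed, npp = list(profiles = list(
    drop = c(interstadial = 0.40, stadial = 0.20),
    rise = c(interstadial = 0.20, stadial = 0.40),
    flat = c(interstadial = 0.30, stadial = 0.30)),
    sites_per_region = 5, noise_sd = noise_sd))
}

# exhaustive-subset oracle for incidence rarefaction: average richness over
# every subset of h sampling units
exhaustive_richness <- function(incidence, h) {
  H <- nrow(incidence)
  subsets <- utils::combn(H, h)
  mean(apply(subsets, 2, function(ix)
    sum(colSums(incidence[ix, , drop = FALSE] > 0) > 0)))
}
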