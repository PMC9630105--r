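test_that("temporal correlation of first differences behaves like a correlation", {
  s1 <- c(0, 1, 0.5, 2, 1.5)
  expect_equal(cort(s1, s1), 1)
  expect_equal(cort(s1, cumsum(c(0, -diff(s1)))), -1)
  # hand evaluation: numerator 1*2 + (-1)(-2) = 4, denominator sqrt(2)*sqrt(8)
  expect_equal(cort(c(0, 1, 0), c(0, 2, 0)), 1)
  expect_equal(cort(c(0, 1, 0), c(0, -2, 0)), -1)
  expect_warning(z <- cort(c(1, 1, 1), s1[1:3]), "degenerate")
  expect_equal(z, 0)
  # bounded on random pairs
  set.seed(7)
  for (i in 1:25) {
    a <- rnorm(12); b <- rnorm(12)
    expect_true(abs(cort(a, b)) <= 1 + 1e-12)
  }
})

test_that("the tuning function has the documented shape and constant", {
  expect_equal(tuning(0, 0), 1)
  expect_equal(tuning(0, 5), 1)
  expect_equal(tuning(1, 2), 2 / (1 + exp(2)), tolerance = 1e-12)
  # at full positive correlation with k = 2 the raw distance is cut by 76%
  expect_equal(round((1 - tuning(1, 2)) * 100), 76)
  expect_equal(tuning(0.3, 0), 1)  # k = 0 disables the weighting
  x <- seq(-1, 1, 0.1)
  expect_true(all(diff(tuning(x, 2)) < 0))
  expect_true(all(tuning(x, 2) > 0 & tuning(x, 2) < 2))
  expect_error(tuning(0.5, -1), "k")
})

test_that("dCORT combines correlation weighting with Euclidean distance", {
  expect_equal(dcort(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(dcort(c(0, 1, 0), c(0, 2, 0), k = 2),
               2 / (1 + exp(2)) * 1, tolerance = 1e-12)
  set.seed(11)
  for (i in 1:20) {
    a <- rnorm(10); b <- rnorm(10)
    expect_equal(dcort(a, b), dcort(b, a), tolerance = 1e-12)
    expect_gte(dcort(a, b), 0)
  }
  expect_error(
    cort(npp_series("a", "r", c(50, 49, 48), c(1, 2, 3)),
         npp_series("b", "r", c(50, 49.5, 49), c(1, 2, 3))),
    "aligned")
})

test_that("the dissimilarity matrix matches pairwise calls and permutes consistently", {
  set.seed(3)
  m <- matrix(rnorm(4 * 8), 4, 8, dimnames = list(paste0("x", 1:4), NULL))
  D <- dissimilarity_matrix(m, k = 2)
  expect_equal(diag(D), setNames(rep(0, 4), rownames(m)))
  expect_equal(D, t(D))
  for (i in 1:4) for (j in 1:4)
    expect_equal(D[i, j], dcort(m[i, ], m[j, ], k = 2), tolerance = 1e-12)
  # duplicates have zero off-diagonal dissimilarity
  Dd <- dissimilarity_matrix(m[c(1, 1, 2), ], k = 2)
  expect_equal(Dd[1, 2], 0)
  # permutation of input order permutes rows/columns
  perm <- c(3, 1, 4, 2)
  Dp <- dissimilarity_matrix(m[perm, ], k = 2)
  expect_equal(Dp, D[perm, perm])
  # k = 0 reduces to the plain Euclidean distance matrix
  D0 <- dissimilarity_matrix(m, k = 0)
  expect_equal(D0, as.matrix(dist(m)), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("hierarchical clustering is deterministic and respects cluster counts", {
  set.seed(5)
  m <- rbind(matrix(rnorm(10, 0, 0.1), 2), matrix(rnorm(10, 5, 0.1), 2))
  D <- dissimilarity_matrix(m, k = 2)
  cl <- cluster_series(D, 2)
  expect_equal(length(unique(cl$labels)), 2)
  expect_equal(cl$labels, cluster_series(D, 2)$labels)
  singletons <- cluster_series(D, 4)
  expect_equal(length(unique(singletons$labels)), 4)
  expect_error(cluster_series(D, 5), "exceeds")
})

test_that("planted productivity profiles are recovered from the dendrogram cut", {
  skip_if_not_installed("mclust")
  g <- gen_npp_series(three_profile_scenario(seed = 42), fixture_phases())
  D <- dissimilarity_matrix(g$series, k = 2)
  cl <- cluster_series(D, 3)
  expect_equal(mclust::adjustedRandIndex(cl$labels, g$truth$labels), 1)
})

test_that("regional cluster composition is a row-normalised contingency table", {
  comp <- cluster_region_composition(c(1, 1, 1, 2, 2, 2, 2, 2),
                                     c(rep("N", 4), rep("S", 4)))
  expect_equal(unname(comp["N", ]), c(75, 25))
  expect_equal(unname(comp["S", ]), c(0, 100))
  expect_equal(unname(rowSums(comp)), c(100, 100))
  # permuting site order changes nothing
  ix <- sample(8)
  expect_equal(cluster_region_composition(c(1, 1, 1, 2, 2, 2, 2, 2)[ix],
                                          c(rep("N", 4), rep("S", 4))[ix]),
               comp)
  one <- cluster_region_composition(rep(1, 3), rep("N", 3))
  expect_equal(unname(one[1, 1]), 100)
})

test_that("Jaccard similarity counts shared over total species", {
  expect_equal(jsi(c("a", "b"), c("a", "b")), 1)
  expect_equal(jsi(c("a", "b"), c("c", "d")), 0)
  expect_equal(jsi(c("x", "s1", "s2"), c("y", "s1", "s2")), 0.5)
  expect_equal(jsi(c("a", "b"), c("b", "c")), jsi(c("b", "c"), c("a", "b")))
  # invariant to relabeling
  expect_equal(jsi(c("a", "b", "c"), c("b", "c")),
               jsi(c("A", "B", "C"), c("B", "C")))
  expect_error(jsi(character(0), character(0)), "empty")
})

test_that("phase tables validate alternation, ordering and overlap", {
  ph <- fixture_phases()
  expect_s3_class(ph, "phase_table")
  expect_true(all(ph$start_kyr_bp > ph$end_kyr_bp))
  bad_kind <- data.frame(name = c("A", "B"), kind = c("stadial", "stadial"),
                         start_kyr_bp = c(50, 45), end_kyr_bp = c(45, 40))
  expect_error(phase_table(bad_kind), "alternate")
  overlap <- data.frame(name = c("A", "B"),
                        kind = c("stadial", "interstadial"),
                        start_kyr_bp = c(50, 47), end_kyr_bp = c(45, 40))
  expect_error(phase_table(overlap), "overlap")
  expect_equal(b2k_to_bp(44.28), 44.23)
})

test_that("phase statistics stratify by kind and detect planted contrasts", {
  ph <- fixture_phases()
  times <- seq(54, 28.2, by = -0.1)
  kinds <- classify_phase(times, ph)$kind

  const <- suppressWarnings(phase_stats(times, rep(0.3, length(times)), ph))
  expect_equal(const$summary$cv_pct, c(0, 0))
  expect_equal(const$test$p, 1)

  set.seed(17)
  vals <- ifelse(kinds == "stadial", 0.27, 0.34) + rnorm(length(times), 0, 0.01)
  st <- phase_stats(times, vals, ph)
  expect_lt(st$test$p, 0.05)
  expect_equal(st$summary$mean[st$summary$kind == "stadial"], 0.27,
               tolerance = 0.01)
  expect_equal(st$summary$mean[st$summary$kind == "interstadial"], 0.34,
               tolerance = 0.01)

  # swapping the phase kinds swaps the summary rows and complements W
  ph_sw <- ph
  ph_sw$kind <- ifelse(ph$kind == "stadial", "interstadial", "stadial")
  ph_sw <- phase_table(as.data.frame(ph_sw))
  sw <- phase_stats(times, vals, ph_sw)
  expect_equal(sw$summary$mean[sw$summary$kind == "interstadial"],
               st$summary$mean[st$summary$kind == "stadial"])
  n1 <- sum(kinds == "stadial"); n2 <- sum(kinds == "interstadial")
  expect_equal(sw$test$W, n1 * n2 - st$test$W)

  # unclassifiable points are excluded with a warning
  expect_warning(phase_stats(c(60, times), c(9, vals), ph), "outside")
})

test_that("percent change between phases is signed mean change", {
  ph <- phase_table(data.frame(name = c("P1", "P0"),
                               kind = c("interstadial", "stadial"),
                               start_kyr_bp = c(50, 45), end_kyr_bp = c(45, 40)))
  times <- c(49, 48, 44, 43)
  expect_equal(percent_change(times, c(0.30, 0.30, 0.20, 0.20), ph, "P1", "P0"),
               -100 / 3, tolerance = 1e-9)
  expect_equal(percent_change(times, c(0.20, 0.20, 0.30, 0.30), ph, "P1", "P0"),
               50, tolerance = 1e-9)
  expect_equal(percent_change(times, rep(0.25, 4), ph, "P1", "P0"), 0)
  expect_error(percent_change(times, c(0, 0, 1, 1), ph, "P1", "P0"), "zero")
})

test_that("unit conversion between NPP conventions is explicit and exact", {
  expect_equal(npp_convert(0.3, "g m-2 yr-1", "kg km-2 yr-1"), 300)
  expect_equal(npp_convert(300, "kg km-2 yr-1", "g m-2 yr-1"), 0.3)
  s <- npp_series("a", "r", c(50, 49), c(0.2, 0.4), unit = "g m-2 yr-1")
  s2 <- npp_convert(s, to = "kg km-2 yr-1")
  expect_equal(s2$values, c(200, 400))
  expect_error(npp_convert(1, "furlongs", "g m-2 yr-1"), "unknown")
})
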