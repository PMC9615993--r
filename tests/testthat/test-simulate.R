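test_that("generators are bit-identical under a fixed seed", {
  s1 <- simulate_two_species(50, 8, 0.5, 0.3, 0.6, 0.4, 0.4,
                             missing_fraction = 0.1, seed = 42)
  s2 <- simulate_two_species(50, 8, 0.5, 0.3, 0.6, 0.4, 0.4,
                             missing_fraction = 0.1, seed = 42)
  expect_identical(s1, s2)
  expect_identical(simulate_activity(100, pi, 2, seed = 5),
                   simulate_activity(100, pi, 2, seed = 5))
  expect_identical(simulate_scats(c(a = 0.6, b = 0.4), 0.2, 25, seed = 5),
                   simulate_scats(c(a = 0.6, b = 0.4), 0.2, 25, seed = 5))
})

test_that("occupancy generator hits its occupancy and conditioning rates", {
  sim <- simulate_two_species(10000, 5, psiA = 0.5, psiBA = 0.3, psiBa = 0.6,
                              pA = 0.4, pB = 0.4, seed = 1)
  expect_lt(abs(mean(sim$zA) - 0.5), 0.015)
  expect_lt(abs(mean(sim$zB[sim$zA == 1]) - 0.3), 0.02)
  expect_lt(abs(mean(sim$zB[sim$zA == 0]) - 0.6), 0.02)
  # a detection implies occupancy, never the reverse
  expect_true(all(sim$zA[rowSums(sim$pair$A, na.rm = TRUE) > 0] == 1))
  expect_true(all(rowSums(sim$pair$B[sim$zB == 0, ], na.rm = TRUE) == 0))
})

test_that("identically-conditioned species have empirical SIF near 1", {
  sim <- simulate_two_species(10000, 3, psiA = 0.5, psiBA = 0.4, psiBa = 0.4,
                              pA = 0.4, pB = 0.4, seed = 2)
  emp_sif <- mean(sim$zA & sim$zB) / (mean(sim$zA) * mean(sim$zB))
  expect_lt(abs(emp_sif - 1), 0.05)
})

test_that("missingness is joint across species and bounded", {
  sim <- simulate_two_species(400, 8, 0.5, 0.3, 0.6, 0.4, 0.4,
                              missing_fraction = 0.3, seed = 3)
  expect_identical(is.na(sim$pair$A), is.na(sim$pair$B))
  expect_lt(abs(mean(is.na(sim$pair$A)) - 0.3), 0.05)
  expect_true(all(rowSums(!is.na(sim$pair$A)) >= 1))  # every site surveyable
  expect_error(simulate_two_species(10, 5, 0.5, 0.3, 0.6, 0.4, 0.4,
                                    missing_fraction = 1), "missing_fraction")
})

test_that("activity generator matches its mixture", {
  x <- simulate_activity(2000, means = pi, kappas = 4, seed = 4)
  expect_true(all(x >= 0 & x < 2 * pi))
  d <- abs(circular_mean(x) - pi)
  expect_lt(min(d, 2 * pi - d), 0.1)
  # near-zero concentration is uniform on 12 bins
  u <- simulate_activity(2400, means = 0, kappas = 1e-10, seed = 5)
  counts <- table(cut(u, breaks = seq(0, 2 * pi, length.out = 13)))
  expect_gt(stats::chisq.test(as.vector(counts))$p.value, 0.01)
  expect_error(simulate_activity(0, pi, 1), "n must be")
  expect_error(simulate_activity(10, c(0, pi), c(1, 1), weights = c(0.7, 0.7)),
               "sum to 1")
})

test_that("rvonmises matches the closed-form density", {
  set.seed(6)
  x <- rvonmises(20000, 2, 3)
  grid <- seq(0, 2 * pi, length.out = 25)
  emp <- as.vector(table(cut(x, grid))) / 20000
  theo <- diff(grid)[1] * dvonmises((grid[-1] + grid[-25]) / 2, 2, 3)
  expect_lt(max(abs(emp - theo)), 0.01)
})

test_that("two species with the same mixture overlap almost completely", {
  a <- simulate_activity(1500, c(pi / 2, 3 * pi / 2), c(3, 3), seed = 7)
  b <- simulate_activity(1500, c(pi / 2, 3 * pi / 2), c(3, 3), seed = 8)
  ka <- estimate_kappa(a); kb <- estimate_kappa(b)
  expect_gte(delta1(vonmises_kde(a, ka), vonmises_kde(b, kb)), 0.9)
})

test_that("scat generator reproduces its prey-use profile", {
  s <- simulate_scats(c(bharal = 0.6, livestock = 0.4), multi_prob = 0,
                      N = 10000, predator = "p", seed = 9)
  fo <- frequency_of_occurrence(s, "p")
  expect_lt(abs(fo[["bharal"]] - 60), 1.5)
  expect_lt(abs(fo[["livestock"]] - 40), 1.5)
  expect_equal(max(table(s$scat_id)), 1L)  # no multi-prey scats
  s2 <- simulate_scats(c(a = 0.5, b = 0.5), multi_prob = 0.3, N = 2000,
                       predator = "p", seed = 10)
  expect_lt(abs(mean(table(s2$scat_id) == 2) - 0.3), 0.05)
  expect_error(simulate_scats(c(a = 1), multi_prob = 0.2, N = 10),
               "at least 2 prey")
})

test_that("matched prey profiles give Pianka overlap near 1", {
  probs <- c(bharal = 0.5, livestock = 0.3, marmot = 0.2)
  s <- rbind(simulate_scats(probs, 0.05, 4000, predator = "p1", seed = 11),
             simulate_scats(probs, 0.05, 4000, predator = "p2", seed = 12))
  expect_gt(diet_overlap(s)$overlap, 0.99)
})

test_that("dataset blocks run on independent substreams", {
  spec <- default_simulation_spec()
  d1 <- simulate_dataset(spec, seed = 20)
  d2 <- simulate_dataset(spec, seed = 20)
  expect_identical(d1, d2)
  # dropping one block leaves the others' draws untouched
  spec_noact <- spec[c("occupancy", "diet")]
  d3 <- simulate_dataset(spec_noact, seed = 20)
  expect_identical(d3$occupancy, d1$occupancy)
  expect_identical(d3$scats, d1$scats)
})
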