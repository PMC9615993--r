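test_that("site likelihood matches exact latent-state enumeration", {
  p <- two_species_params(0.5, 0.5, 0.5, 0.5, 0.5)
  expect_equal(site_likelihood(p, c(0, 0), c(0, 0)), 0.390625)
  expect_equal(site_likelihood(p, 1, 0), 0.1875)
  expect_equal(site_likelihood(list(psiA = 1, psiBA = 0.5, psiBa = 0.5,
                                    pA = 1, pB = 0.5), 0, 0), 0)

  set.seed(42)
  for (K in 1:3) {
    hists <- all_paired_histories(K)
    for (rep in 1:5) {
      pr <- as.list(stats::setNames(runif(5), c("psiA", "psiBA", "psiBa",
                                                "pA", "pB")))
      lik <- vapply(hists, function(h) site_likelihood(pr, h$a, h$b),
                    numeric(1))
      orc <- vapply(hists, function(h) enum_site_lik(pr, h$a, h$b),
                    numeric(1))
      expect_equal(lik, orc, tolerance = 1e-13)
      expect_equal(sum(lik), 1, tolerance = 1e-12)  # total probability mass
    }
  }
})

test_that("missing occasions enter the likelihood as no information", {
  p <- two_species_params(0.4, 0.3, 0.6, 0.5, 0.5)
  expect_equal(site_likelihood(p, c(1, NA), c(0, NA)),
               site_likelihood(p, 1, 0))
  expect_error(site_likelihood(p, c(1, NA), c(0, 0)), "missing pattern")
  expect_error(site_likelihood(p, c(1, 2), c(0, 0)), "1, 0 or NA")
})

test_that("SIF is the ratio of conditional to marginal subordinate occupancy", {
  expect_equal(compute_sif(0.5, 0.3, 0.6), 0.3 / 0.45)
  expect_equal(compute_sif(0.7, 0.4, 0.4), 1)   # independence
  expect_equal(compute_sif(0.5, 0.4, 0), 2)     # 1/psiA when psiBa = 0
  expect_error(compute_sif(0.5, 0, 0), "undefined")
})

test_that("hdi finds the shortest mass-covering interval", {
  expect_equal(hdi(rep(0.2, 10)), c(lower = 0.2, upper = 0.2))
  x <- (1:1000) / 1000
  h <- hdi(x, 0.95)
  expect_equal(unname(h[2] - h[1]), 0.949)  # 950 consecutive order stats
  expect_equal(hdi(x, 1), c(lower = 0.001, upper = 1))
  # oracle: brute-force minimization over all windows of a skewed sample
  set.seed(7)
  y <- sort(rexp(200))
  m <- ceiling(0.9 * 200)
  widths <- y[m:200] - y[1:(200 - m + 1)]
  i <- which.min(widths)
  expect_equal(hdi(y, 0.9), c(lower = y[i], upper = y[i + m - 1]))
  expect_error(hdi(numeric(0)), "empty")
})

test_that("split-Rhat separates mixed from unmixed chains", {
  set.seed(11)
  same <- matrix(rnorm(4000), ncol = 4)
  expect_lt(abs(rhat(same) - 1), 0.05)
  apart <- cbind(rnorm(500, 0), rnorm(500, 10))
  expect_gt(rhat(apart), 1.5)
  expect_error(rhat(matrix(1:10, ncol = 1)), "2 chains")
  expect_error(rhat(matrix(1:4, ncol = 2)), "short")
})

test_that("the Gibbs sampler recovers generating parameters", {
  sim <- simulate_two_species(200, 10, psiA = 0.5, psiBA = 0.3, psiBa = 0.6,
                              pA = 0.4, pB = 0.4, seed = 101)
  fit <- fit_cooccupancy(sim$pair, chains = 3, burn_in = 500,
                         iterations = 1000, seed = 101)
  means <- stats::setNames(fit$summary$mean, fit$summary$parameter)
  truth <- c(psiA = 0.5, psiBA = 0.3, psiBa = 0.6, pA = 0.4, pB = 0.4)
  expect_true(all(abs(means[names(truth)] - truth) < 0.1))
  expect_true(all(fit$summary$rhat < 1.1))
  expect_equal(fit$draws$sif,
               compute_sif(fit$draws$psiA, fit$draws$psiBA, fit$draws$psiBa))
})

test_that("independent species yield SIF centred at 1", {
  sim <- simulate_two_species(250, 10, psiA = 0.5, psiBA = 0.45, psiBa = 0.45,
                              pA = 0.4, pB = 0.4, seed = 5)
  fit <- fit_cooccupancy(sim$pair, chains = 3, burn_in = 500,
                         iterations = 1000, seed = 5)
  expect_lt(abs(fit$summary$mean[fit$summary$parameter == "sif"] - 1), 0.1)
  expect_false(fit$sif_hdi_excludes_one)
})

test_that("degenerate detection pairs are rejected or flagged", {
  empty <- structure(list(A = matrix(NA_integer_, 2, 3),
                          B = matrix(NA_integer_, 2, 3), occasion_days = 6),
                     class = "detection_pair")
  expect_error(fit_cooccupancy(empty), "no surveyed")
  sim <- simulate_two_species(30, 5, 0.5, 0.3, 0.6, 0.4, 0.4, seed = 2)
  sim$pair$B[] <- ifelse(is.na(sim$pair$B), NA_integer_, 0L)
  expect_warning(fit_cooccupancy(sim$pair, chains = 2, burn_in = 50,
                                 iterations = 50, seed = 2),
                 "never detected")
})

test_that("chains are reproducible from the master seed", {
  sim <- simulate_two_species(40, 6, 0.5, 0.3, 0.6, 0.4, 0.4, seed = 3)
  f1 <- fit_cooccupancy(sim$pair, chains = 2, burn_in = 100,
                        iterations = 100, seed = 9)
  f2 <- fit_cooccupancy(sim$pair, chains = 2, burn_in = 100,
                        iterations = 100, seed = 9)
  expect_identical(f1$draws, f2$draws)
})

test_that("ML and Bayesian fits agree on large data", {
  sim <- simulate_two_species(1000, 10, psiA = 0.5, psiBA = 0.3, psiBa = 0.6,
                              pA = 0.4, pB = 0.4, seed = 21)
  ml <- ml_fit(sim$pair)
  expect_true(ml$converged)
  expect_false(ml$boundary)
  truth <- c(psiA = 0.5, psiBA = 0.3, psiBa = 0.6, pA = 0.4, pB = 0.4)
  expect_true(all(abs(ml$params - truth) < 0.05))
  fit <- fit_cooccupancy(sim$pair, chains = 2, burn_in = 300,
                         iterations = 500, seed = 21)
  means <- stats::setNames(fit$summary$mean, fit$summary$parameter)
  expect_true(all(abs(means[names(truth)] - ml$params) < 0.05))
})

test_that("a never-present subordinate drives ML to the boundary", {
  sim <- simulate_two_species(100, 8, 0.5, 0.3, 0.6, 0.4, 0.4, seed = 4)
  sim$pair$B[] <- ifelse(is.na(sim$pair$B), NA_integer_, 0L)
  ml <- ml_fit(sim$pair)
  expect_true(ml$boundary)
})
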