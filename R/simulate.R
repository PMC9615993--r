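#' Draw from a von Mises distribution
#'
#' Rejection sampler with a wrapped-Cauchy envelope (Best & Fisher 1979).
#' For `kappa` below 1e-8 the distribution is indistinguishable from
#' circular uniform and is sampled as such.
#'
#' @param n Number of draws.
#' @param mu Mean direction in radians.
#' @param kappa Concentration (>= 0).
#' @return Angles in `[0, 2*pi)`.
#' @export
rvonmises <- function(n, mu, kappa) {
  if (n == 0L) return(numeric(0))
  if (kappa < 1e-8) return(stats::runif(n, 0, 2 * pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(0)
  while (length(out) < n) {
    todo <- n - length(out)
    u1 <- stats::runif(todo)
    u2 <- stats::runif(todo)
    u3 <- stats::runif(todo)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    accept <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    th <- sign(u3 - 0.5) * acos(f)
    out <- c(out, (mu + th[accept]) %% (2 * pi))
  }
  out[seq_len(n)]
}

#' Simulate paired detection histories under the two-species model
#'
#' Generative twin of the likelihood fitted by [fit_cooccupancy()]:
#' `zA ~ Bernoulli(psiA)`; `zB ~ Bernoulli(psiBA)` where A is present and
#' `Bernoulli(psiBa)` where absent; detections are per-occasion Bernoulli
#' draws at occupied sites. Missing site-occasions are placed jointly in
#' both matrices at rate `missing_fraction`, mirroring occasions when a
#' camera was not operating.
#'
#' @param n_sites,K Number of sites and pooled occasions.
#' @param psiA,psiBA,psiBa,pA,pB Model parameters; see
#'   [two_species_params()].
#' @param missing_fraction Fraction of site-occasions coded missing
#'   (default 0; must leave at least one surveyed occasion).
#' @param seed Seed.
#' @return List with `pair` (a `detection_pair`), `zA`, `zB` (true latent
#'   states), and `params`.
#' @export
simulate_two_species <- function(n_sites, K, psiA, psiBA, psiBa, pA, pB,
                                 missing_fraction = 0, seed = 1) {
  if (n_sites < 1L || K < 1L) stop("n_sites and K must be >= 1")
  if (missing_fraction < 0 || missing_fraction >= 1) {
    stop("missing_fraction must be in [0, 1)")
  }
  params <- two_species_params(psiA, psiBA, psiBa, pA, pB)
  set.seed(seed)
  zA <- stats::rbinom(n_sites, 1, psiA)
  zB <- stats::rbinom(n_sites, 1, ifelse(zA == 1, psiBA, psiBa))
  yA <- matrix(stats::rbinom(n_sites * K, 1, rep(zA * pA, K)), n_sites, K)
  yB <- matrix(stats::rbinom(n_sites * K, 1, rep(zB * pB, K)), n_sites, K)
  if (missing_fraction > 0) {
    miss <- matrix(stats::runif(n_sites * K) < missing_fraction, n_sites, K)
    # keep every site surveyable: re-open one occasion at fully-missing sites
    all_missing <- rowSums(!miss) == 0
    miss[cbind(which(all_missing),
               sample.int(K, sum(all_missing), replace = TRUE))] <- FALSE
    yA[miss] <- NA_integer_
    yB[miss] <- NA_integer_
  }
  rownames(yA) <- rownames(yB) <- sprintf("site_%03d", seq_len(n_sites))
  list(pair = align_pair(yA, yB), zA = zA, zB = zB, params = params)
}

#' Simulate diel activity times from a von Mises mixture
#'
#' @param n Number of capture times.
#' @param means Component mean directions (radians).
#' @param kappas Component concentrations.
#' @param weights Mixture weights (default equal), summing to 1.
#' @param seed Seed.
#' @return Angles in `[0, 2*pi)`.
#' @export
simulate_activity <- function(n, means, kappas,
                              weights = rep(1 / length(means), length(means)),
                              seed = 1) {
  if (n < 1L) stop("n must be >= 1")
  if (length(means) != length(kappas) || length(means) != length(weights)) {
    stop("means, kappas and weights must have equal length")
  }
  if (abs(sum(weights) - 1) > 1e-8) stop("mixture weights must sum to 1")
  set.seed(seed)
  comp <- sample.int(length(means), n, replace = TRUE, prob = weights)
  out <- numeric(n)
  for (j in seq_along(means)) {
    sel <- comp == j
    if (any(sel)) out[sel] <- rvonmises(sum(sel), means[j], kappas[j])
  }
  out
}

#' Simulate a scat table from prey-use probabilities
#'
#' Each scat receives one primary prey drawn from `prey_probs`; with
#' probability `multi_prob` a second, distinct prey is added (uniformly over
#' the remaining categories, weighted by `prey_probs`), emulating the
#' occasional multi-prey scat.
#'
#' @param prey_probs Named probability vector over prey categories
#'   (positive, summing to 1).
#' @param multi_prob Probability a scat contains a second prey, in `[0, 1)`.
#' @param N Number of scats.
#' @param predator Predator code written into the table.
#' @param region Region code written into the table.
#' @param seed Seed.
#' @return Scat table data frame (`scat_id`, `predator`, `region`, `prey`).
#' @export
simulate_scats <- function(prey_probs, multi_prob, N, predator = "predator_A",
                           region = "synthetic", seed = 1) {
  if (N < 1L) stop("N must be >= 1")
  if (is.null(names(prey_probs))) stop("prey_probs must be named")
  if (any(prey_probs <= 0) || abs(sum(prey_probs) - 1) > 1e-8) {
    stop("prey_probs must be positive and sum to 1")
  }
  if (multi_prob < 0 || multi_prob >= 1) stop("multi_prob must be in [0, 1)")
  if (length(prey_probs) < 2L && multi_prob > 0) {
    stop("multi-prey scats need at least 2 prey categories")
  }
  set.seed(seed)
  prey <- names(prey_probs)
  primary <- sample(prey, N, replace = TRUE, prob = prey_probs)
  extra <- stats::runif(N) < multi_prob
  rows <- data.frame(scat_id = sprintf("%s_scat_%04d", predator, seq_len(N)),
                     predator = predator, region = region, prey = primary)
  if (any(extra)) {
    second <- vapply(which(extra), function(i) {
      others <- setdiff(prey, primary[i])
      sample(others, 1, prob = prey_probs[others])
    }, character(1))
    rows <- rbind(rows, data.frame(scat_id = rows$scat_id[extra],
                                   predator = predator, region = region,
                                   prey = second))
  }
  rows[order(rows$scat_id), , drop = FALSE]
}

#' Simulate a full three-axis dataset
#'
#' Drives the three generators from one specification list and a master
#' seed; each block runs on its own deterministic substream so any block
#' can be regenerated independently.
#'
#' @param spec List with blocks `occupancy` (arguments of
#'   [simulate_two_species()]), `activity` (named list of per-species
#'   mixtures: `means`, `kappas`, `weights`, `n`), and `diet` (named list of
#'   per-predator `prey_probs`, `multi_prob`, `N`). Any block may be
#'   omitted. See [default_simulation_spec()].
#' @param seed Master seed; blocks use `seed + 1000`, `seed + 2000`,
#'   `seed + 3000`.
#' @return List with the present blocks: `occupancy`, `activity` (named list
#'   of radian vectors), `scats` (one combined table).
#' @export
simulate_dataset <- function(spec, seed = 1) {
  out <- list()
  if (!is.null(spec$occupancy)) {
    out$occupancy <- do.call(simulate_two_species,
                             c(spec$occupancy, list(seed = seed + 1000)))
  }
  if (!is.null(spec$activity)) {
    out$activity <- lapply(seq_along(spec$activity), function(j) {
      m <- spec$activity[[j]]
      simulate_activity(m$n, m$means, m$kappas,
                        m$weights %||% rep(1 / length(m$means), length(m$means)),
                        seed = seed + 2000 + j)
    })
    names(out$activity) <- names(spec$activity)
  }
  if (!is.null(spec$diet)) {
    tabs <- lapply(seq_along(spec$diet), function(j) {
      d <- spec$diet[[j]]
      simulate_scats(unlist(d$prey_probs), d$multi_prob, d$N,
                     predator = names(spec$diet)[j], seed = seed + 3000 + j)
    })
    out$scats <- do.call(rbind, tabs)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Default simulation specification
#'
#' Study-scale defaults for [simulate_dataset()]: a two-predator survey of
#' 60 stations over 10 pooled occasions with moderate occupancy avoidance
#' and 10% missing effort; crepuscular (dawn/dusk bimodal) activity for both
#' species; and two scat sets of 40 with largely shared prey use.
#'
#' @return Specification list.
#' @export
default_simulation_spec <- function() {
  crepuscular <- list(means = c(pi / 2, 3 * pi / 2), kappas = c(3, 3),
                      weights = c(0.5, 0.5), n = 150)
  list(
    occupancy = list(n_sites = 60, K = 10, psiA = 0.5, psiBA = 0.3,
                     psiBa = 0.6, pA = 0.4, pB = 0.4, missing_fraction = 0.1),
    activity = list(species_a = crepuscular,
                    species_b = list(means = c(pi / 2, 3 * pi / 2),
                                     kappas = c(2, 2), weights = c(0.4, 0.6),
                                     n = 150)),
    diet = list(predator_a = list(prey_probs = c(bharal = 0.5, livestock = 0.3,
                                                 marmot = 0.1, small_prey = 0.1),
                                  multi_prob = 0.1, N = 40),
                predator_b = list(prey_probs = c(bharal = 0.45, livestock = 0.25,
                                                 marmot = 0.2, small_prey = 0.1),
                                  multi_prob = 0.1, N = 40))
  )
}
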