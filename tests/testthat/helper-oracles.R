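# Independent oracles used to validate the package's own implementations.
# These are deliberately coded by a different route than the package code.

# brute-force marginal likelihood of a paired site history: enumerate the
# four latent states and use dbinom for every surveyed occasion
enum_site_lik <- function(params, hist_a, hist_b) {
  total <- 0
  for (zA in 0:1) {
    for (zB in 0:1) {
      pz <- (if (zA == 1) params$psiA else 1 - params$psiA) *
        (if (zA == 1) {
          if (zB == 1) params$psiBA else 1 - params$psiBA
        } else {
          if (zB == 1) params$psiBa else 1 - params$psiBa
        })
      oa <- hist_a[!is.na(hist_a)]
      ob <- hist_b[!is.na(hist_b)]
      da <- prod(stats::dbinom(oa, 1, zA * params$pA))
      db <- prod(stats::dbinom(ob, 1, zB * params$pB))
      total <- total + pz * da * db
    }
  }
  total
}

# all paired detection histories of length K as a list of (hist_a, hist_b)
all_paired_histories <- function(K) {
  g <- expand.grid(rep(list(0:1), 2 * K))
  lapply(seq_len(nrow(g)), function(i) {
    row <- as.integer(g[i, ])
    list(a = row[seq_len(K)], b = row[K + seq_len(K)])
  })
}

# exact posterior means of the occupancy parameters on tiny data, by
# enumerating all latent-state configurations and integrating each
# parameter's polynomial factor on a fine grid (Uniform(0,1) priors make
# the posterior a mixture whose factors separate given z)
grid_posterior_means <- function(yA, yB, ngrid = 4001) {
  th <- seq(0, 1, length.out = ngrid)
  w <- rep(1, ngrid); w[c(1, ngrid)] <- 0.5
  integ <- function(f) sum(w * f) / (ngrid - 1)       # trapezoid on [0,1]
  poly_int <- function(a, b) integ(th^a * (1 - th)^b)
  poly_int_x <- function(a, b) integ(th^(a + 1) * (1 - th)^b)

  n <- nrow(yA)
  Ki <- rowSums(!is.na(yA))
  detA <- rowSums(yA == 1, na.rm = TRUE)
  detB <- rowSums(yB == 1, na.rm = TRUE)
  conf <- expand.grid(rep(list(0:1), 2 * n))
  den <- 0
  num <- c(psiA = 0, psiBA = 0, psiBa = 0, pA = 0, pB = 0)
  for (i in seq_len(nrow(conf))) {
    zA <- as.integer(conf[i, seq_len(n)])
    zB <- as.integer(conf[i, n + seq_len(n)])
    if (any(detA[zA == 0] > 0) || any(detB[zB == 0] > 0)) next  # infeasible
    aA <- sum(zA)
    c1 <- sum(zB[zA == 1]); d1 <- aA - c1
    c0 <- sum(zB[zA == 0]); d0 <- (n - aA) - c0
    sA <- sum(detA[zA == 1]); fA <- sum(Ki[zA == 1]) - sA
    sB <- sum(detB[zB == 1]); fB <- sum(Ki[zB == 1]) - sB
    I <- c(psiA = poly_int(aA, n - aA), psiBA = poly_int(c1, d1),
           psiBa = poly_int(c0, d0), pA = poly_int(sA, fA),
           pB = poly_int(sB, fB))
    Ix <- c(psiA = poly_int_x(aA, n - aA), psiBA = poly_int_x(c1, d1),
            psiBa = poly_int_x(c0, d0), pA = poly_int_x(sA, fA),
            pB = poly_int_x(sB, fB))
    den <- den + prod(I)
    for (pn in names(num)) {
      num[pn] <- num[pn] + prod(I[setdiff(names(I), pn)]) * Ix[pn]
    }
  }
  num / den
}

# closed-form von Mises density
dvonmises <- function(x, mu, kappa) {
  exp(kappa * cos(x - mu)) / (2 * pi * besselI(kappa, 0))
}

circular_mean <- function(x) atan2(mean(sin(x)), mean(cos(x))) %% (2 * pi)

# minimal well-formed capture-record / deployment fixtures
toy_deployments <- function() {
  data.frame(station_id = c("s1", "s2"),
             start_date = c("2018-01-01", "2018-01-01"),
             end_date = c("2018-01-12", "2018-01-06"))
}
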