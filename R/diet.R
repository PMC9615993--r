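.check_scats <- function(scats) {
  need <- c("scat_id", "predator", "prey")
  if (!all(need %in% names(scats))) {
    stop("scat table must have columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(scats[c("scat_id", "prey")])) {
    stop("duplicated (scat_id, prey) rows in scat table")
  }
  invisible(scats)
}

# scat x prey incidence matrix for one predator
.incidence <- function(scats, predator, prey_levels = NULL) {
  .check_scats(scats)
  s <- scats[scats$predator == predator, , drop = FALSE]
  if (nrow(s) == 0L) stop("no scats for predator: ", predator)
  ids <- unique(as.character(s$scat_id))
  if (is.null(prey_levels)) prey_levels <- sort(unique(as.character(s$prey)))
  m <- matrix(0L, length(ids), length(prey_levels),
              dimnames = list(ids, prey_levels))
  m[cbind(match(as.character(s$scat_id), ids),
          match(as.character(s$prey), prey_levels))] <- 1L
  m
}

#' Frequency of occurrence of prey in scats
#'
#' `F_i = 100 * n_i / N`: the percentage of a predator's scats containing
#' prey category i, where `N` is the number of scats analysed. A scat with
#' several prey counts once towards each prey it contains, so the column can
#' sum past 100%.
#'
#' @param scats Scat table: data frame with one row per (scat, prey) pair and
#'   columns `scat_id`, `predator`, `prey` (a `region` column is allowed and
#'   ignored).
#' @param predator Predator code to summarise.
#' @param prey_levels Optional prey vocabulary fixing the output order (and
#'   reporting 0% for absent categories).
#' @return Named numeric vector of FO percentages.
#' @export
frequency_of_occurrence <- function(scats, predator, prey_levels = NULL) {
  m <- .incidence(scats, predator, prey_levels)
  100 * colMeans(m)
}

#' Bootstrap mean and bias-corrected CI for frequency of occurrence
#'
#' Resamples `N` scats with replacement `n_iter` times and reports, per prey,
#' the bootstrap mean FO and a bias-corrected (BC) percentile interval: the
#' bias correction `z0` is the normal quantile of the fraction of bootstrap
#' values below the point estimate, and the interval endpoints are the
#' bootstrap quantiles at `pnorm(2*z0 + qnorm(c(alpha/2, 1-alpha/2)))`.
#' Prey found in every scat or in none get a zero-width interval at the
#' estimate.
#'
#' @inheritParams frequency_of_occurrence
#' @param n_iter Bootstrap iterations (default 10000; fewer than 100 warns).
#' @param seed Seed for the resampling stream.
#' @param conf Confidence level (default 0.95).
#' @return Data frame with columns `prey`, `fo`, `boot_mean`, `ci_low`,
#'   `ci_high`.
#' @export
bootstrap_fo <- function(scats, predator, n_iter = 10000, seed = 1,
                         conf = 0.95, prey_levels = NULL) {
  if (n_iter < 100) warning("n_iter < 100 gives unstable intervals")
  m <- .incidence(scats, predator, prey_levels)
  N <- nrow(m)
  if (N < 2L) stop("need at least 2 scats to bootstrap")
  fo <- 100 * colMeans(m)
  set.seed(seed)
  idx <- matrix(sample.int(N, N * n_iter, replace = TRUE), n_iter, N)
  alpha <- (1 - conf) / 2
  zq <- stats::qnorm(c(alpha, 1 - alpha))
  out <- lapply(colnames(m), function(prey) {
    boot <- 100 * rowMeans(matrix(m[, prey][idx], n_iter, N))
    if (fo[prey] %in% c(0, 100)) {
      ci <- c(fo[prey], fo[prey])
    } else {
      p0 <- sum(boot < fo[prey]) / n_iter
      p0 <- min(max(p0, 1 / n_iter), 1 - 1 / n_iter)
      z0 <- stats::qnorm(p0)
      ci <- unname(stats::quantile(boot, stats::pnorm(2 * z0 + zq)))
    }
    data.frame(prey = prey, fo = unname(fo[prey]), boot_mean = mean(boot),
               ci_low = ci[1], ci_high = ci[2])
  })
  do.call(rbind, out)
}

#' Biomass of prey consumed per collectable scat
#'
#' Predator-specific regressions of `Y`, the kg of prey consumed to produce
#' one scat, on `X`, the mean body mass (kg) of the prey:
#' snow leopard `Y = 1.980 + 0.035 X`; woolly wolf `Y = 0.439 + 0.008 X`;
#' common leopard `Y = 2.171 - 1.671 exp(-0.056 X)`.
#'
#' @param predator One of `"snow_leopard"`, `"woolly_wolf"`,
#'   `"common_leopard"`.
#' @param X Mean prey body mass in kg (vectorised).
#' @return `Y` in kg per scat.
#' @examples
#' biomass_factor("woolly_wolf", 50)  # 0.839
#' @export
biomass_factor <- function(predator, X) {
  if (any(X < 0)) stop("prey mass must be non-negative")
  switch(predator,
         snow_leopard = 1.980 + 0.035 * X,
         woolly_wolf = 0.439 + 0.008 * X,
         common_leopard = 2.171 - 1.671 * exp(-0.056 * X),
         stop("unknown predator: ", predator))
}

#' Relative biomass contribution of each prey
#'
#' Converts frequencies of occurrence to percentage biomass shares:
#' `B_i = 100 * F_i * Y_i / sum_j F_j * Y_j`, weighting each prey's FO by the
#' predator-specific biomass-per-scat factor [biomass_factor()].
#'
#' @param fo Named FO vector (percent).
#' @param y Biomass-per-scat factors aligned with `fo`.
#' @return Percentages summing to 100.
#' @export
relative_biomass <- function(fo, y) {
  if (length(fo) != length(y)) stop("fo and y must align on prey categories")
  tot <- sum(fo * y)
  if (tot == 0) stop("all frequencies are zero: relative biomass undefined")
  100 * fo * y / tot
}

#' Pianka's niche overlap index
#'
#' `O_jk = sum_i p_ij p_ik / sqrt(sum_i p_ij^2 * sum_i p_ik^2)` for two
#' species' resource-use proportion vectors over a shared prey vocabulary
#' (absent categories as 0). This is the cosine similarity of the vectors:
#' 0 = complete separation, 1 = complete overlap, and scale-invariant per
#' species, so raw FO columns work as well as normalised proportions.
#'
#' @param p_j,p_k Non-negative use vectors over aligned categories, each with
#'   a positive sum.
#' @return Overlap in `[0, 1]`.
#' @export
pianka <- function(p_j, p_k) {
  if (length(p_j) != length(p_k)) stop("vectors must align on categories")
  if (any(p_j < 0) || any(p_k < 0)) stop("use vectors must be non-negative")
  if (sum(p_j) == 0 || sum(p_k) == 0) stop("zero use vector")
  sum(p_j * p_k) / sqrt(sum(p_j^2) * sum(p_k^2))
}

#' Full diet summary for one predator
#'
#' Frequency of occurrence with bootstrap mean and bias-corrected 95% CI,
#' plus biomass-per-scat factors and percentage relative biomass when prey
#' masses are supplied.
#'
#' @inheritParams bootstrap_fo
#' @param prey_masses Optional named vector (or single-column data frame)
#'   of mean prey body masses in kg.
#' @return Data frame with one row per prey category.
#' @export
diet_summary <- function(scats, predator, prey_masses = NULL, n_iter = 10000,
                         seed = 1, prey_levels = NULL) {
  out <- bootstrap_fo(scats, predator, n_iter = n_iter, seed = seed,
                      prey_levels = prey_levels)
  if (!is.null(prey_masses)) {
    if (is.data.frame(prey_masses)) {
      prey_masses <- stats::setNames(prey_masses$mass_kg, prey_masses$prey)
    }
    missing_mass <- setdiff(out$prey, names(prey_masses))
    if (length(missing_mass)) {
      stop("no body mass configured for prey: ",
           paste(missing_mass, collapse = ", "))
    }
    out$y <- biomass_factor(predator, unname(prey_masses[out$prey]))
    out$relative_biomass <- relative_biomass(out$fo, out$y)
  }
  out
}

#' Pairwise dietary overlap between predators
#'
#' Pianka overlap for every predator pair in a scat table, computed from FO
#' proportions by default, or from relative-biomass shares when
#' `basis = "biomass"` (requires `prey_masses`).
#'
#' @inheritParams diet_summary
#' @param basis `"fo"` (default) or `"biomass"`.
#' @return Data frame `predator_j`, `predator_k`, `overlap`.
#' @export
diet_overlap <- function(scats, prey_masses = NULL, basis = c("fo", "biomass")) {
  basis <- match.arg(basis)
  .check_scats(scats)
  preds <- sort(unique(as.character(scats$predator)))
  if (length(preds) < 2L) stop("need at least two predators")
  prey_levels <- sort(unique(as.character(scats$prey)))
  use <- lapply(preds, function(pd) {
    fo <- frequency_of_occurrence(scats, pd, prey_levels)
    if (basis == "fo") return(fo)
    if (is.null(prey_masses)) stop("biomass basis requires prey_masses")
    if (is.data.frame(prey_masses)) {
      prey_masses <- stats::setNames(prey_masses$mass_kg, prey_masses$prey)
    }
    y <- biomass_factor(pd, unname(prey_masses[prey_levels]))
    b <- fo * y
    100 * b / sum(b)
  })
  names(use) <- preds
  pairs <- utils::combn(preds, 2)
  data.frame(predator_j = pairs[1, ], predator_k = pairs[2, ],
             overlap = apply(pairs, 2, function(pr) {
               pianka(use[[pr[1]]], use[[pr[2]]])
             }))
}
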