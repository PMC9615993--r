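# configuration plumbing shared by the run_* front-ends

.load_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or a YAML path")
  config
}

.require_fields <- function(config, fields) {
  missing <- setdiff(fields, names(config))
  if (length(missing)) {
    stop("missing config field(s): ", paste(missing, collapse = ", "))
  }
  invisible(config)
}

.log_config <- function(what, config) {
  flat <- vapply(config, function(v) paste(format(v), collapse = ","),
                 character(1))
  message(sprintf("[%s] %s", what,
                  paste(names(flat), flat, sep = "=", collapse = " ")))
}

#' Run the spatial-interaction (two-species occupancy) analysis
#'
#' Reads two detection-matrix CSVs (dominant species first), fits the
#' conditional occupancy model with [fit_cooccupancy()], and writes
#' `occupancy_summary.csv` and `occupancy_draws.csv` to `out_dir`. The SIF
#' verdict ("HDI excludes 1: yes/no") and all split-Rhat values are logged;
#' any `rhat >= 1.1` is an error so non-converged runs cannot pass silently.
#'
#' @param config List or YAML path with fields `matrix_a`, `matrix_b`
#'   (paths), `seed`, and optionally `chains`, `burn_in`, `iterations`.
#' @param out_dir Output directory (created if absent).
#' @return The `cooccu_fit`, invisibly.
#' @export
run_occupancy <- function(config, out_dir = ".") {
  config <- .load_config(config)
  .require_fields(config, c("matrix_a", "matrix_b", "seed"))
  .log_config("occupancy", config)
  mA <- read_detection_matrix(config$matrix_a)
  mB <- read_detection_matrix(config$matrix_b)
  pair <- align_pair(mA, mB)
  fit <- fit_cooccupancy(pair,
                         chains = config$chains %||% 3,
                         burn_in = config$burn_in %||% 10000,
                         iterations = config$iterations %||% 1000,
                         seed = config$seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(fit$summary, file.path(out_dir, "occupancy_summary.csv"),
                   row.names = FALSE)
  utils::write.csv(fit$draws, file.path(out_dir, "occupancy_draws.csv"),
                   row.names = FALSE)
  s <- fit$summary
  message(sprintf("SIF = %.3f (HDI %.3f-%.3f); HDI excludes 1: %s",
                  s$mean[s$parameter == "sif"],
                  s$hdi_low[s$parameter == "sif"],
                  s$hdi_high[s$parameter == "sif"],
                  if (fit$sif_hdi_excludes_one) "yes" else "no"))
  bad <- s$parameter[s$rhat >= 1.1]
  if (length(bad)) {
    stop("chains did not converge (rhat >= 1.1) for: ",
         paste(bad, collapse = ", "))
  }
  invisible(fit)
}

#' Run the temporal-interaction (activity overlap) analysis
#'
#' Reads a capture-record CSV, computes the Delta-1 activity overlap between
#' two species with [activity_overlap()], and writes
#' `activity_densities.csv` (grid and per-species densities) plus a one-line
#' `activity_report.csv` to `out_dir`.
#'
#' @param config List or YAML path with fields `records` (path), `species_a`,
#'   `species_b`, and optionally `season`, `adjust`, `grid_n`.
#' @param out_dir Output directory.
#' @return The `activity_overlap` object, invisibly.
#' @export
run_activity <- function(config, out_dir = ".") {
  config <- .load_config(config)
  .require_fields(config, c("records", "species_a", "species_b"))
  .log_config("activity", config)
  records <- utils::read.csv(config$records)
  ov <- activity_overlap(records, config$species_a, config$species_b,
                         season = config$season,
                         adjust = config$adjust %||% 0.8,
                         grid_n = config$grid_n %||% 128)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(data.frame(grid_rad = ov$dens_a$grid,
                              density_a = ov$dens_a$y,
                              density_b = ov$dens_b$y),
                   file.path(out_dir, "activity_densities.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(species_a = ov$species[1],
                              species_b = ov$species[2],
                              season = ov$season %||% "all",
                              n_a = ov$n_a, n_b = ov$n_b, delta1 = ov$delta1),
                   file.path(out_dir, "activity_report.csv"),
                   row.names = FALSE)
  message(sprintf("Delta1(%s, %s%s) = %.3f",
                  ov$species[1], ov$species[2],
                  if (is.null(ov$season)) "" else paste0(", ", ov$season),
                  ov$delta1))
  invisible(ov)
}

#' Run the dietary analysis
#'
#' Reads a scat CSV and (optionally) a prey body-mass YAML/CSV, writes a
#' per-predator `diet_<predator>.csv` (FO, bootstrap CI, relative biomass)
#' and a `diet_overlap.csv` of pairwise Pianka indices to `out_dir`.
#'
#' @param config List or YAML path with fields `scats` (path), `seed`, and
#'   optionally `masses` (YAML with a `prey:` mass mapping, or CSV with
#'   columns `prey`, `mass_kg`), `predators`, `n_iter`.
#' @param out_dir Output directory.
#' @return List of per-predator summaries plus `overlap`, invisibly.
#' @export
run_diet <- function(config, out_dir = ".") {
  config <- .load_config(config)
  .require_fields(config, c("scats", "seed"))
  .log_config("diet", config)
  scats <- utils::read.csv(config$scats)
  .check_scats(scats)
  masses <- NULL
  if (!is.null(config$masses)) {
    masses <- if (grepl("\\.ya?ml$", config$masses)) {
      unlist(yaml::read_yaml(config$masses))
    } else {
      m <- utils::read.csv(config$masses)
      stats::setNames(m$mass_kg, m$prey)
    }
  }
  predators <- config$predators %||% sort(unique(as.character(scats$predator)))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- lapply(predators, function(pd) {
    s <- diet_summary(scats, pd, prey_masses = masses,
                      n_iter = config$n_iter %||% 10000, seed = config$seed)
    utils::write.csv(s, file.path(out_dir, paste0("diet_", pd, ".csv")),
                     row.names = FALSE)
    s
  })
  names(res) <- predators
  if (length(predators) >= 2L) {
    res$overlap <- diet_overlap(scats[scats$predator %in% predators, ],
                                prey_masses = masses)
    utils::write.csv(res$overlap, file.path(out_dir, "diet_overlap.csv"),
                     row.names = FALSE)
    message(paste(sprintf("Pianka(%s, %s) = %.3f", res$overlap$predator_j,
                          res$overlap$predator_k, res$overlap$overlap),
                  collapse = "; "))
  }
  invisible(res)
}

#' Generate a synthetic three-axis dataset on disk
#'
#' Runs [simulate_dataset()] and writes the CSVs the other front-ends
#' consume: `matrix_a.csv` / `matrix_b.csv` (detection matrices),
#' `records.csv` (capture records with synthetic times), `scats.csv`.
#'
#' @param config List or YAML path with optional `spec` (a simulation
#'   specification as in [default_simulation_spec()], which is the default)
#'   and `seed`.
#' @param out_dir Output directory.
#' @return The simulated dataset, invisibly.
#' @export
run_simulate <- function(config = list(), out_dir = ".") {
  config <- .load_config(config)
  .log_config("simulate", config)
  spec <- config$spec %||% default_simulation_spec()
  seed <- config$seed %||% 1
  sim <- simulate_dataset(spec, seed = seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(sim$occupancy)) {
    write_detection_matrix(sim$occupancy$pair$A, file.path(out_dir, "matrix_a.csv"))
    write_detection_matrix(sim$occupancy$pair$B, file.path(out_dir, "matrix_b.csv"))
  }
  if (!is.null(sim$activity)) {
    recs <- do.call(rbind, lapply(names(sim$activity), function(sp) {
      hrs <- sim$activity[[sp]] * 24 / (2 * pi)
      data.frame(station_id = NA, species = sp,
                 datetime = sprintf("%02d:%02d:%02d", floor(hrs),
                                    floor((hrs * 60) %% 60),
                                    floor((hrs * 3600) %% 60)),
                 season = "all")
    }))
    utils::write.csv(recs, file.path(out_dir, "records.csv"), row.names = FALSE)
  }
  if (!is.null(sim$scats)) {
    utils::write.csv(sim$scats, file.path(out_dir, "scats.csv"),
                     row.names = FALSE)
  }
  invisible(sim)
}
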