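#' Simulation configuration
#'
#' Bundle and validate every parameter of the synthetic-data generator. The
#' generator emulates the output of manual tracking of 1-min-resolution
#' time-lapse microscopy of single stem cells interacting with a ligand-coated
#' microbead: per-minute 2D coordinates of the cell centre, the bead, and a
#' membrane reference point, plus first-contact/first-cytoneme waiting times,
#' anaphase geometry, and two-daughter-cell intensity partitions.
#'
#' Radial bead dynamics follow a clamped discrete mean-reverting
#' (Ornstein-Uhlenbeck-type) process on the radius fraction
#' \eqn{r_{t+1} = r_t + k_{reloc} (r_{eq} - r_t) + \sigma_r \epsilon_t},
#' clamped to (0, 1]. Waiting times (first cytoneme, first bead contact,
#' contact loss after uptake, division) are geometric with the stated
#' per-minute hazards, supported on minutes 1, 2, .... Spindle angles are
#' drawn from a two-component mixture: with probability `angle_mix_p` a
#' bead-oriented component (normal centred at 90 degrees with SD
#' \eqn{(180/\pi)/\sqrt{\kappa}}, truncated to \[0, 90\]), otherwise uniform
#' on \[0, 90\]. Daughter-cell proximal intensity fractions are
#' Beta(`partition_alpha`, `partition_beta`).
#'
#' @param n_cells number of cells to simulate.
#' @param duration_min observation length in minutes (default 180; sampling
#'   interval is fixed at 1 min, so tracks have `duration_min + 1` rows,
#'   minutes 0..`duration_min`).
#' @param r0 initial bead radius fraction in (0, 1].
#' @param r_eq equilibrium radius fraction in (0, 1].
#' @param k_reloc per-minute relocation (mean-reversion) rate in \[0, 1\].
#' @param sigma_r per-step radial noise SD, radius-fraction units.
#' @param sigma_theta per-step angular noise SD of the bead's wrapped random
#'   walk around the cell, radians.
#' @param cell_step_sigma per-axis per-step SD of the cell-centre Gaussian
#'   random walk, micrometres.
#' @param cell_radius_um cell radius in micrometres (> 0).
#' @param contact_hazard per-minute probability of first bead contact.
#' @param cytoneme_hazard per-minute probability of first cytoneme appearance.
#' @param drop_hazard per-minute probability of contact loss after uptake.
#' @param division_hazard per-minute probability of division.
#' @param angle_mix_p mixture weight of the bead-oriented angle component.
#' @param angle_kappa concentration of the oriented angle component.
#' @param partition_alpha,partition_beta Beta shape parameters of the
#'   proximal-fraction distribution.
#' @param background_mean background fluorescence intensity (arbitrary units).
#' @param total_intensity total signal partitioned between the two daughters.
#' @param noise_sd intensity measurement noise SD.
#' @param seed integer seed; identical config (including seed) produces
#'   byte-identical output from every generator.
#'
#' @return An object of class `sim_config` (a validated named list).
#' @examples
#' cfg <- sim_config(n_cells = 5, seed = 1)
#' cfg$r_eq
#' @export
sim_config <- function(n_cells = 50,
                       duration_min = 180,
                       r0 = 0.95,
                       r_eq = 0.5,
                       k_reloc = 0.1,
                       sigma_r = 0.02,
                       sigma_theta = 0.15,
                       cell_step_sigma = 0.7,
                       cell_radius_um = 10,
                       contact_hazard = 0.02,
                       cytoneme_hazard = 0.01,
                       drop_hazard = 0.0005,
                       division_hazard = 0.001,
                       angle_mix_p = 0.8,
                       angle_kappa = 30,
                       partition_alpha = 3,
                       partition_beta = 2,
                       background_mean = 10,
                       total_intensity = 100,
                       noise_sd = 2,
                       seed = 1L) {
  cfg <- list(
    n_cells = n_cells, duration_min = duration_min, dt_min = 1L,
    r0 = r0, r_eq = r_eq, k_reloc = k_reloc, sigma_r = sigma_r,
    sigma_theta = sigma_theta, cell_step_sigma = cell_step_sigma,
    cell_radius_um = cell_radius_um,
    contact_hazard = contact_hazard, cytoneme_hazard = cytoneme_hazard,
    drop_hazard = drop_hazard, division_hazard = division_hazard,
    angle_mix_p = angle_mix_p, angle_kappa = angle_kappa,
    partition_alpha = partition_alpha, partition_beta = partition_beta,
    background_mean = background_mean, total_intensity = total_intensity,
    noise_sd = noise_sd, seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  num <- setdiff(names(cfg), "seed")
  for (nm in num) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("sim_config: parameter '", nm, "' must be a finite scalar", call. = FALSE)
    }
  }
  rates <- c("k_reloc", "contact_hazard", "cytoneme_hazard", "drop_hazard",
             "division_hazard", "angle_mix_p")
  for (nm in rates) {
    if (cfg[[nm]] < 0 || cfg[[nm]] > 1) {
      stop("sim_config: rate '", nm, "' must lie in [0, 1]", call. = FALSE)
    }
  }
  for (nm in c("r0", "r_eq")) {
    if (cfg[[nm]] <= 0 || cfg[[nm]] > 1) {
      stop("sim_config: '", nm, "' must lie in (0, 1]", call. = FALSE)
    }
  }
  if (cfg$cell_radius_um <= 0) stop("sim_config: cell_radius_um must be > 0", call. = FALSE)
  if (cfg$duration_min < 1) stop("sim_config: duration_min must be >= 1", call. = FALSE)
  if (cfg$n_cells < 1) stop("sim_config: n_cells must be >= 1", call. = FALSE)
  if (cfg$sigma_r < 0 || cfg$sigma_theta < 0 || cfg$cell_step_sigma < 0 ||
      cfg$noise_sd < 0) {
    stop("sim_config: noise SDs must be >= 0", call. = FALSE)
  }
  if (cfg$partition_alpha <= 0 || cfg$partition_beta <= 0) {
    stop("sim_config: Beta shape parameters must be > 0", call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic tracking configuration\n")
  cat(sprintf("  %d cells x %d min (dt = 1 min), seed %d\n",
              x$n_cells, x$duration_min, x$seed))
  cat(sprintf("  bead radial OU: r0 = %.2f, r_eq = %.2f, k_reloc = %.3f, sigma_r = %.3f\n",
              x$r0, x$r_eq, x$k_reloc, x$sigma_r))
  cat(sprintf("  hazards/min: contact %.3g, cytoneme %.3g, drop %.3g, division %.3g\n",
              x$contact_hazard, x$cytoneme_hazard, x$drop_hazard, x$division_hazard))
  cat(sprintf("  angles: P(oriented) = %.2f, kappa = %.1f; partition Beta(%.1f, %.1f)\n",
              x$angle_mix_p, x$angle_kappa, x$partition_alpha, x$partition_beta))
  invisible(x)
}

#' Read or write a simulation configuration as YAML
#'
#' @param path file path.
#' @return `read_sim_config()` returns a `sim_config`; `write_sim_config()`
#'   returns `path` invisibly.
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  vals <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  extra <- setdiff(names(vals), c(known, "dt_min"))
  if (length(extra)) {
    stop("unknown config keys: ", paste(extra, collapse = ", "), call. = FALSE)
  }
  vals$dt_min <- NULL
  do.call(sim_config, vals)
}

#' @rdname read_sim_config
#' @param config a `sim_config` object.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# Evaluate `expr` under a deterministic RNG stream derived from `seed`,
# restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Stable derived seed for sub-stream i, kept within 32-bit integer range.
derive_seed <- function(seed, i) {
  as.integer((as.double(seed) * 48271 + i * 16807) %% 2147483647)
}

# Geometric first-event minute with per-minute hazard h, supported on 1,2,...;
# Inf when h == 0.
rgeom_minute <- function(n, h) {
  if (h <= 0) return(rep(Inf, n))
  if (h >= 1) return(rep(1, n))
  stats::rgeom(n, h) + 1
}
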