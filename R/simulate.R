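#' Simulate a single tracked cell-bead interaction
#'
#' Generates the per-minute track of one cell interacting with a ligand bead,
#' in the same coordinate system a manual-tracking export would use: cell
#' centre, bead, and a membrane reference point, all in micrometres, at 1-min
#' resolution over minutes `0..duration_min`.
#'
#' The cell centre performs an isotropic Gaussian random walk (per-axis,
#' per-step SD `cell_step_sigma`). Bead uptake occurs at a geometric waiting
#' time driven by `contact_hazard` (minute 0 when the hazard is 1). While in
#' contact, the bead's radius fraction follows the clamped mean-reverting
#' process of [sim_config()] starting at `r0`, and its angular position
#' performs a wrapped Gaussian walk with SD `sigma_theta`. The membrane
#' reference point lies on the ray from the cell centre through the bead at
#' distance `cell_radius_um`; before uptake the ray direction still evolves so
#' the membrane point is always defined and never coincides with the centre.
#' Contact may end at a geometric drop time (`drop_hazard`) and the cell may
#' divide (`division_hazard`); both are recorded.
#'
#' @param config a [sim_config()].
#' @param cell_id identifier for the simulated cell.
#' @param condition condition label stored in the track.
#' @param experiment_id experiment identifier stored in the track.
#' @param .seed optional integer overriding the config seed (used by
#'   [simulate_tracks()] to give each cell its own derived stream).
#' @return A `data.frame` in the track-table schema (see [read_tracks()]):
#'   one row per minute, bead coordinates `NA` outside contact.
#' @examples
#' cfg <- sim_config(n_cells = 1, duration_min = 20, contact_hazard = 1, seed = 7)
#' tr <- simulate_bead_track(cfg, "cell1")
#' head(tr)
#' @export
simulate_bead_track <- function(config, cell_id, condition = "WT",
                                experiment_id = "exp1", .seed = NULL) {
  validate_sim_config(config)
  seed <- if (is.null(.seed)) config$seed else .seed
  with_seed(seed, {
    n_t <- config$duration_min + 1L
    t_min <- 0:config$duration_min

    # cell-centre random walk, started at the origin of the field of view
    steps_x <- stats::rnorm(n_t - 1L, 0, config$cell_step_sigma)
    steps_y <- stats::rnorm(n_t - 1L, 0, config$cell_step_sigma)
    x_cell <- cumsum(c(0, steps_x))
    y_cell <- cumsum(c(0, steps_y))

    # bead direction (shared by the membrane reference): wrapped Gaussian walk
    theta <- cumsum(c(stats::runif(1, 0, 2 * pi),
                      stats::rnorm(n_t - 1L, 0, config$sigma_theta))) %% (2 * pi)

    # event times: uptake at minute 0 when contact_hazard = 1
    t_uptake <- rgeom_minute(1, config$contact_hazard) - 1
    t_loss <- t_uptake + rgeom_minute(1, config$drop_hazard)
    t_div <- rgeom_minute(1, config$division_hazard)

    in_contact <- t_min >= t_uptake & t_min < t_loss

    # radius fraction: r0 at uptake, then clamped mean reversion
    r <- rep(NA_real_, n_t)
    if (any(in_contact)) {
      idx <- which(in_contact)
      r[idx[1]] <- config$r0
      if (length(idx) > 1) {
        eps <- stats::rnorm(length(idx) - 1L, 0, 1)
        for (j in seq_along(eps)) {
          rv <- r[idx[j]] +
            config$k_reloc * (config$r_eq - r[idx[j]]) +
            config$sigma_r * eps[j]
          r[idx[j + 1]] <- min(max(rv, .Machine$double.eps), 1)
        }
      }
    }

    x_membrane <- x_cell + config$cell_radius_um * cos(theta)
    y_membrane <- y_cell + config$cell_radius_um * sin(theta)
    x_bead <- ifelse(in_contact, x_cell + r * config$cell_radius_um * cos(theta), NA_real_)
    y_bead <- ifelse(in_contact, y_cell + r * config$cell_radius_um * sin(theta), NA_real_)

    data.frame(
      experiment_id = experiment_id,
      position_id = "pos1",
      cell_id = as.character(cell_id),
      condition = condition,
      t_min = t_min,
      x_cell = x_cell, y_cell = y_cell,
      x_bead = x_bead, y_bead = y_bead,
      x_membrane = x_membrane, y_membrane = y_membrane,
      in_contact = in_contact,
      divided_at = if (t_div <= config$duration_min) t_div else NA_real_,
      stringsAsFactors = FALSE
    )
  })
}

#' Simulate a cohort of tracked cells
#'
#' Runs [simulate_bead_track()] for `config$n_cells` cells, each on its own
#' RNG stream derived deterministically from the config seed.
#'
#' @inheritParams simulate_bead_track
#' @return A track table (`data.frame`) with one block of rows per cell.
#' @export
simulate_tracks <- function(config, condition = "WT", experiment_id = "exp1") {
  validate_sim_config(config)
  out <- vector("list", config$n_cells)
  for (i in seq_len(config$n_cells)) {
    out[[i]] <- simulate_bead_track(
      config, cell_id = sprintf("cell%03d", i),
      condition = condition, experiment_id = experiment_id,
      .seed = derive_seed(config$seed, i)
    )
  }
  do.call(rbind, out)
}

#' Simulate population-level cytoneme and bead-contact kinetics
#'
#' Emulates low-density population videos scored per minute: each cell gets a
#' first-cytoneme time (geometric, `cytoneme_hazard`) and a first-contact time
#' (geometric, `contact_hazard`), both supported on minutes 1, 2, ...; events
#' are irreversible. Cells are split as evenly as possible across imaging
#' positions.
#'
#' @param config a [sim_config()]; `n_cells` is the total across positions and
#'   `duration_min` the video length.
#' @param n_positions number of imaging positions (>= 1).
#' @param experiment_id experiment identifier.
#' @return A population-count `data.frame` with columns `experiment_id`,
#'   `position_id`, `t_min`, `n_total`, `n_with_cytonemes`, `n_with_beads`.
#' @examples
#' cfg <- sim_config(n_cells = 40, duration_min = 120, seed = 2)
#' pop <- simulate_population(cfg, n_positions = 4)
#' @export
simulate_population <- function(config, n_positions = 1L, experiment_id = "exp1") {
  validate_sim_config(config)
  if (n_positions < 1) stop("n_positions must be >= 1", call. = FALSE)
  if (config$n_cells < 1) stop("at least one cell is required", call. = FALSE)
  with_seed(config$seed, {
    pos_of <- rep(seq_len(n_positions), length.out = config$n_cells)
    t_cyt <- rgeom_minute(config$n_cells, config$cytoneme_hazard)
    t_con <- rgeom_minute(config$n_cells, config$contact_hazard)
    t_min <- 0:config$duration_min
    out <- vector("list", n_positions)
    for (p in seq_len(n_positions)) {
      cells <- which(pos_of == p)
      out[[p]] <- data.frame(
        experiment_id = experiment_id,
        position_id = sprintf("pos%02d", p),
        t_min = t_min,
        n_total = length(cells),
        n_with_cytonemes = vapply(t_min, function(tt) sum(t_cyt[cells] <= tt), 0L),
        n_with_beads = vapply(t_min, function(tt) sum(t_con[cells] <= tt), 0L),
        stringsAsFactors = FALSE
      )
    }
    do.call(rbind, out)
  })
}

#' Simulate anaphase division events with a known spindle-to-bead angle
#'
#' Draws each division's spindle-to-bead angle from the mixture described in
#' [sim_config()] (bead-oriented truncated normal at 90 degrees with weight
#' `angle_mix_p`, otherwise uniform on \[0, 90\]) and constructs pole and bead
#' coordinates that realise the drawn angle exactly, at a random location,
#' global orientation, spindle length and bead distance. The drawn angle is
#' stored in `true_angle_deg` so geometry round-trips can be checked.
#'
#' @param config a [sim_config()].
#' @param n_events number of division events.
#' @param condition condition label.
#' @return A `data.frame` with columns `event_id`, `condition`,
#'   `experiment_id`, `x_pole_a`, `y_pole_a`, `x_pole_b`, `y_pole_b`,
#'   `x_bead`, `y_bead`, `true_angle_deg`.
#' @export
simulate_divisions <- function(config, n_events, condition = "WT",
                               experiment_id = "exp1") {
  validate_sim_config(config)
  if (n_events < 1) stop("n_events must be >= 1", call. = FALSE)
  with_seed(derive_seed(config$seed, 104729L), {
    oriented <- stats::runif(n_events) < config$angle_mix_p
    sd_deg <- (180 / pi) / sqrt(config$angle_kappa)
    ang <- numeric(n_events)
    # truncated normal at 90 by rejection; falls through fast for sane kappa
    for (i in seq_len(n_events)) {
      if (oriented[i]) {
        repeat {
          a <- stats::rnorm(1, 90, sd_deg)
          if (a >= 0 && a <= 90) break
          a <- 180 - a                      # reflect overshoot beyond 90
          if (a >= 0 && a <= 90) break
        }
        ang[i] <- a
      } else {
        ang[i] <- stats::runif(1, 0, 90)
      }
    }

    centre_x <- stats::runif(n_events, -50, 50)
    centre_y <- stats::runif(n_events, -50, 50)
    phi <- stats::runif(n_events, 0, 2 * pi)      # spindle (major axis) direction
    half_len <- stats::runif(n_events, 4, 8)      # pole-to-midpoint distance, um
    bead_dist <- stats::runif(n_events, 5, 12)    # midpoint-to-bead distance, um
    side <- sample(c(-1, 1), n_events, replace = TRUE)

    ux <- cos(phi); uy <- sin(phi)                # major axis unit
    mx <- -uy;     my <- ux                       # minor axis unit
    a_rad <- ang * pi / 180
    # bead direction: angle `ang` away from the (undirected) minor axis
    bx <- cos(a_rad) * mx * side + sin(a_rad) * ux
    by <- cos(a_rad) * my * side + sin(a_rad) * uy

    data.frame(
      event_id = sprintf("div%04d", seq_len(n_events)),
      condition = condition,
      experiment_id = experiment_id,
      x_pole_a = centre_x - half_len * ux, y_pole_a = centre_y - half_len * uy,
      x_pole_b = centre_x + half_len * ux, y_pole_b = centre_y + half_len * uy,
      x_bead = centre_x + bead_dist * bx, y_bead = centre_y + bead_dist * by,
      true_angle_deg = ang,
      stringsAsFactors = FALSE
    )
  })
}

#' Simulate two-daughter-cell intensity partitions
#'
#' For each doublet and channel, draws the proximal intensity fraction `p`
#' and synthesises mean fluorescence intensities
#' `I_proximal = B + p * T + noise`, `I_distal = B + (1 - p) * T + noise`,
#' with background `B = background_mean` and total partitioned signal
#' `T = total_intensity`. By default `p ~ Beta(partition_alpha,
#' partition_beta)`; when `true_category_rates` is supplied, each doublet is
#' first assigned a category at those rates and `p` is drawn uniformly within
#' the category's partition band (>55%, 45-55%, <45%).
#'
#' @param config a [sim_config()].
#' @param n_doublets number of doublets.
#' @param true_category_rates optional numeric vector
#'   `c(proximal, distributed, distal)` summing to 1.
#' @param channels channel labels; one record per doublet x channel.
#' @param condition condition label.
#' @return A doublet `data.frame` with columns `doublet_id`, `condition`,
#'   `experiment_id`, `channel`, `I_proximal`, `I_distal`, `I_background`.
#' @export
simulate_doublets <- function(config, n_doublets, true_category_rates = NULL,
                              channels = "Nanog", condition = "WT",
                              experiment_id = "exp1") {
  validate_sim_config(config)
  if (n_doublets < 1) stop("n_doublets must be >= 1", call. = FALSE)
  if (!is.null(true_category_rates)) {
    if (length(true_category_rates) != 3 ||
        abs(sum(true_category_rates) - 1) > 1e-8 || any(true_category_rates < 0)) {
      stop("true_category_rates must be 3 non-negative rates summing to 1",
           call. = FALSE)
    }
  }
  with_seed(derive_seed(config$seed, 224737L), {
    n <- n_doublets * length(channels)
    if (is.null(true_category_rates)) {
      p <- stats::rbeta(n, config$partition_alpha, config$partition_beta)
    } else {
      cat_idx <- sample.int(3, n, replace = TRUE, prob = true_category_rates)
      p <- numeric(n)
      p[cat_idx == 1] <- stats::runif(sum(cat_idx == 1), 0.5501, 0.999)
      p[cat_idx == 2] <- stats::runif(sum(cat_idx == 2), 0.4501, 0.5499)
      p[cat_idx == 3] <- stats::runif(sum(cat_idx == 3), 0.001, 0.4499)
    }
    B <- config$background_mean
    Tt <- config$total_intensity
    noise <- function() stats::rnorm(n, 0, config$noise_sd)
    data.frame(
      doublet_id = rep(sprintf("dbl%04d", seq_len(n_doublets)),
                       times = length(channels)),
      condition = condition,
      experiment_id = experiment_id,
      channel = rep(channels, each = n_doublets),
      I_proximal = pmax(B + p * Tt + noise(), 0),
      I_distal = pmax(B + (1 - p) * Tt + noise(), 0),
      I_background = pmax(B + noise(), 0),
      stringsAsFactors = FALSE
    )
  })
}
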