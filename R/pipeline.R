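#' Run one analysis stage
#'
#' Dispatcher behind the command-line interface. Each stage reads validated
#' CSV inputs (or, for `"simulate"`, a [sim_config()]), runs the
#' corresponding module, and writes its summary tables plus a YAML run
#' manifest to `out_dir` via [build_report()]. Analysis defaults are the
#' protocol constants: post-uptake windows 0-30/31-120/121-180 min, retention
#' window 180 min, zone edges 0.7/0.3, partition bands 45/55%, 5-degree rose
#' bins.
#'
#' @param stage one of `"simulate"`, `"tracks"`, `"population"`,
#'   `"spindle"`, `"acd"`.
#' @param out_dir output directory.
#' @param config a [sim_config()] (required for `"simulate"`; optional
#'   elsewhere, recorded in the manifest).
#' @param input input CSV path (ignored by `"simulate"`).
#' @param windows post-uptake windows for the `"tracks"` stage.
#' @param retention_window retention observation window, minutes.
#' @param bin_width rose-plot bin width, degrees.
#' @param n_events,n_doublets,n_positions simulated set sizes for the
#'   `"simulate"` stage.
#' @return Invisibly, a named list of the tables written.
#' @examples
#' \donttest{
#' cfg <- sim_config(n_cells = 4, duration_min = 30, contact_hazard = 1, seed = 5)
#' out <- file.path(tempdir(), "run1")
#' run_stage("simulate", out, config = cfg)
#' run_stage("tracks", file.path(out, "tracks_out"),
#'           input = file.path(out, "tracks.csv"))
#' }
#' @export
run_stage <- function(stage, out_dir, config = NULL, input = NULL,
                      windows = list(c(0, 30), c(31, 120), c(121, 180)),
                      retention_window = 180L, bin_width = 5,
                      n_events = 100L, n_doublets = 100L, n_positions = 4L) {
  stages <- c("simulate", "tracks", "population", "spindle", "acd")
  if (!stage %in% stages) {
    stop("unknown stage '", stage, "'; expected one of: ",
         paste(stages, collapse = ", "), call. = FALSE)
  }
  if (stage == "simulate") {
    if (!inherits(config, "sim_config")) {
      stop("the simulate stage requires a sim_config", call. = FALSE)
    }
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    tracks <- simulate_tracks(config)
    pop <- simulate_population(config, n_positions = n_positions)
    div <- simulate_divisions(config, n_events = n_events)
    dbl <- simulate_doublets(config, n_doublets = n_doublets)
    write_tracks(tracks, file.path(out_dir, "tracks.csv"))
    write_population_counts(pop, file.path(out_dir, "population.csv"))
    write_divisions(div, file.path(out_dir, "divisions.csv"))
    write_doublets(dbl, file.path(out_dir, "doublets.csv"))
    build_report(list(sim_summary = data.frame(
      table = c("tracks", "population", "divisions", "doublets"),
      rows = c(nrow(tracks), nrow(pop), nrow(div), nrow(dbl)))),
      out_dir, config = config, seed = config$seed)
    return(invisible(list(tracks = tracks, population = pop,
                          divisions = div, doublets = dbl)))
  }

  if (is.null(input)) stop("stage '", stage, "' requires an input file",
                           call. = FALSE)
  tables <- switch(stage,
    tracks = analyse_tracks(read_tracks(input), windows = windows,
                            retention_window = retention_window),
    population = {
      pop <- read_population_counts(input)
      list(percent_cytonemes = population_percent(pop, "cytonemes"),
           percent_beads = population_percent(pop, "beads"))
    },
    spindle = analyse_divisions(read_divisions(input), bin_width = bin_width),
    acd = {
      calls <- doublet_calls(read_doublets(input))
      rates <- category_rates(calls)
      list(doublet_calls = calls, category_rates = rates,
           category_summary = attr(rates, "summary"))
    })
  build_report(tables, out_dir, config = config,
               seed = if (!is.null(config)) config$seed else NULL)
  invisible(tables)
}

#' Per-cell and per-condition track summaries
#'
#' For every cell with an uptake event: window means of the bead radius
#' ratio, cell and bead MSD at 1-min lag, and the retention record. Also
#' returns the per-minute mean +/- SEM radius-ratio profile per condition
#' and per-condition retention counts.
#'
#' @param tracks a track table.
#' @param windows inclusive post-uptake windows, minutes.
#' @param retention_window retention observation window, minutes.
#' @return A named list of `data.frame`s: `per_cell`, `window_means`,
#'   `position_profile`, `retention_records`, `retention_counts`.
#' @export
analyse_tracks <- function(tracks,
                           windows = list(c(0, 30), c(31, 120), c(121, 180)),
                           retention_window = 180L) {
  cells <- unique(tracks$cell_id)
  per_cell <- list(); wm_all <- list(); prof <- list()
  for (cid in cells) {
    tr <- tracks[tracks$cell_id == cid, , drop = FALSE]
    msd_c <- if (nrow(tr) >= 2) msd_cell(tr) else NA_real_
    if (!any(tr$in_contact)) {
      per_cell[[cid]] <- data.frame(cell_id = cid, condition = tr$condition[1],
                                    msd_cell = msd_c, msd_bead = NA_real_,
                                    t_uptake = NA_real_,
                                    stringsAsFactors = FALSE)
      next
    }
    ser <- position_series(tr)
    wm <- window_means(ser, windows = windows)
    wm$cell_id <- cid
    wm$condition <- tr$condition[1]
    wm_all[[cid]] <- wm
    prof[[cid]] <- data.frame(condition = tr$condition[1], t_rel = ser$t_rel,
                              ratio = ser$ratio, stringsAsFactors = FALSE)
    msd_b <- if (nrow(ser) >= 2) msd_bead(tr) else NA_real_
    per_cell[[cid]] <- data.frame(cell_id = cid, condition = tr$condition[1],
                                  msd_cell = msd_c, msd_bead = msd_b,
                                  t_uptake = ser$t_abs[1],
                                  stringsAsFactors = FALSE)
  }
  prof_df <- do.call(rbind, prof)
  profile <- NULL
  if (!is.null(prof_df)) {
    agg_m <- stats::aggregate(ratio ~ condition + t_rel, prof_df, mean)
    agg_s <- stats::aggregate(ratio ~ condition + t_rel, prof_df,
                              function(v) if (length(v) > 1)
                                stats::sd(v) / sqrt(length(v)) else NA_real_)
    agg_n <- stats::aggregate(ratio ~ condition + t_rel, prof_df, length)
    profile <- data.frame(condition = agg_m$condition, t_rel = agg_m$t_rel,
                          mean_ratio = agg_m$ratio, sem_ratio = agg_s$ratio,
                          n_cells = agg_n$ratio, stringsAsFactors = FALSE)
    profile <- profile[order(profile$condition, profile$t_rel), ]
    rownames(profile) <- NULL
  }
  records <- retention_table(tracks, window = retention_window)
  list(per_cell = do.call(rbind, per_cell),
       window_means = do.call(rbind, wm_all),
       position_profile = profile,
       retention_records = records,
       retention_counts = retention_counts(records))
}

#' Spindle-angle summaries for a division-event table
#'
#' Measures every event's angle, bins a rose histogram and runs the
#' randomised-null chi-squared test per condition, and, when several
#' conditions are present, pairwise two-sample K-S tests between them.
#'
#' @param events a division-event table.
#' @param bin_width rose-plot bin width, degrees.
#' @return A named list of `data.frame`s: `angles`, `rose_counts`,
#'   `null_tests`, `ks_tests` (omitted for a single condition).
#' @export
analyse_divisions <- function(events, bin_width = 5) {
  ev <- spindle_angles(events)
  conds <- unique(ev$condition)
  rose <- list(); nulls <- list()
  for (cc in conds) {
    a <- ev$angle_deg[ev$condition == cc]
    h <- rose_histogram(a, bin_width = bin_width)
    rose[[cc]] <- data.frame(condition = cc,
                             bin_lo = h$breaks[-length(h$breaks)],
                             bin_hi = h$breaks[-1], count = h$counts,
                             stringsAsFactors = FALSE)
    ch <- randomized_null_chisq(a)
    nulls[[cc]] <- data.frame(condition = cc, n = length(a),
                              chi2 = ch$chi2, df = ch$df, p = ch$p,
                              stringsAsFactors = FALSE)
  }
  out <- list(angles = ev[c("event_id", "condition", "angle_deg")],
              rose_counts = do.call(rbind, rose),
              null_tests = do.call(rbind, nulls))
  if (length(conds) > 1) {
    pairs <- utils::combn(conds, 2)
    out$ks_tests <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(i) {
      ks <- ks_two_sample(ev$angle_deg[ev$condition == pairs[1, i]],
                          ev$angle_deg[ev$condition == pairs[2, i]])
      data.frame(condition_a = pairs[1, i], condition_b = pairs[2, i],
                 D = ks$D, p = ks$p, stringsAsFactors = FALSE)
    }))
  }
  out
}

#' Run the full simulate-and-analyse pipeline
#'
#' Simulates all four table types from `config`, writes them, re-reads them
#' through the validating readers, and runs the track, population, spindle
#' and doublet analyses, each stage under `out_dir/<stage>/` with its own
#' manifest.
#'
#' @inheritParams run_stage
#' @return Invisibly, a named list of every stage's tables.
#' @export
run_pipeline <- function(config, out_dir,
                         n_events = 100L, n_doublets = 100L,
                         n_positions = 4L) {
  sim_dir <- file.path(out_dir, "simulate")
  run_stage("simulate", sim_dir, config = config, n_events = n_events,
            n_doublets = n_doublets, n_positions = n_positions)
  res <- list(
    tracks = run_stage("tracks", file.path(out_dir, "tracks"),
                       config = config,
                       input = file.path(sim_dir, "tracks.csv")),
    population = run_stage("population", file.path(out_dir, "population"),
                           config = config,
                           input = file.path(sim_dir, "population.csv")),
    spindle = run_stage("spindle", file.path(out_dir, "spindle"),
                        config = config,
                        input = file.path(sim_dir, "divisions.csv")),
    acd = run_stage("acd", file.path(out_dir, "acd"), config = config,
                    input = file.path(sim_dir, "doublets.csv"))
  )
  invisible(res)
}
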