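#' Euclidean distance between two points
#'
#' @param p,q numeric length-2 vectors (x, y), micrometres.
#' @return The Euclidean norm of `p - q`.
#' @examples
#' distance(c(0, 0), c(3, 4))  # 5
#' @export
distance <- function(p, q) {
  if (length(p) != 2L || length(q) != 2L || !all(is.finite(c(p, q)))) {
    stop("distance() expects two finite (x, y) points", call. = FALSE)
  }
  sqrt(sum((p - q)^2))
}

single_cell <- function(track) {
  if (length(unique(track$cell_id)) != 1L) {
    stop("expected a track for a single cell", call. = FALSE)
  }
  track[order(track$t_min), , drop = FALSE]
}

#' Bead position as a fraction of the cell radius
#'
#' The centre-to-bead distance divided by the centre-to-membrane distance
#' (the cell radius) at minute `t`. Because the membrane reference point is
#' tracked independently and need not be collinear with the bead, the ratio
#' can exceed 1; such values are legal and are flagged, not clamped, by
#' [assign_zone()].
#'
#' @param track a single-cell track table.
#' @param t minute at which to evaluate; the cell must be in contact.
#' @return The dimensionless radius ratio.
#' @examples
#' tr <- data.frame(cell_id = "c", t_min = 0, x_cell = 0, y_cell = 0,
#'                  x_bead = 3, y_bead = 4, x_membrane = 6, y_membrane = 8,
#'                  in_contact = TRUE)
#' radius_ratio(tr, 0)  # 0.5
#' @export
radius_ratio <- function(track, t) {
  tr <- single_cell(track)
  row <- tr[tr$t_min == t, , drop = FALSE]
  if (nrow(row) != 1L) stop("no timepoint t = ", t, " in track", call. = FALSE)
  if (!isTRUE(row$in_contact)) {
    stop("cell is not in contact with the bead at t = ", t, call. = FALSE)
  }
  d_mem <- distance(c(row$x_cell, row$y_cell), c(row$x_membrane, row$y_membrane))
  if (d_mem == 0) {
    stop("degenerate geometry: membrane reference coincides with cell centre",
         call. = FALSE)
  }
  distance(c(row$x_cell, row$y_cell), c(row$x_bead, row$y_bead)) / d_mem
}

#' Per-minute bead position series for one cell
#'
#' Computes, for every in-contact minute, the radius ratio and the
#' cell-normalised bead position `NP_bead(t) = P_bead(t) - P_cell(t)`,
#' re-indexed so that the uptake minute (first in-contact minute) is minute 0.
#'
#' @param track a single-cell track table.
#' @return A `data.frame` of class `bead_series` with columns `cell_id`,
#'   `t_abs` (original minute), `t_rel` (minutes since uptake), `ratio`,
#'   `np_x`, `np_y`.
#' @export
position_series <- function(track) {
  tr <- single_cell(track)
  tr <- tr[tr$in_contact, , drop = FALSE]
  if (nrow(tr) == 0L) {
    stop("empty series: cell '", track$cell_id[1],
         "' has no in-contact timepoints", call. = FALSE)
  }
  d_mem <- sqrt((tr$x_membrane - tr$x_cell)^2 + (tr$y_membrane - tr$y_cell)^2)
  if (any(d_mem == 0)) {
    stop("degenerate geometry: membrane reference coincides with cell centre",
         call. = FALSE)
  }
  d_bead <- sqrt((tr$x_bead - tr$x_cell)^2 + (tr$y_bead - tr$y_cell)^2)
  out <- data.frame(
    cell_id = tr$cell_id,
    t_abs = tr$t_min,
    t_rel = tr$t_min - tr$t_min[1],
    ratio = d_bead / d_mem,
    np_x = tr$x_bead - tr$x_cell,
    np_y = tr$y_bead - tr$y_cell,
    stringsAsFactors = FALSE
  )
  class(out) <- c("bead_series", "data.frame")
  out
}

#' Mean bead position in representative time windows
#'
#' Averages the radius ratio within inclusive post-uptake windows, by default
#' 0-30, 31-120 and 121-180 min. A window only partially covered by the
#' series is averaged over the minutes available and flagged `partial`; a
#' window with no covered minutes yields `NA` and is flagged.
#'
#' @param series a [position_series()] result.
#' @param windows list of `c(lo, hi)` minute pairs (inclusive, relative to
#'   uptake).
#' @return A `data.frame` with one row per window: `window_lo`, `window_hi`,
#'   `mean_ratio`, `n_minutes`, `partial`.
#' @export
window_means <- function(series,
                         windows = list(c(0, 30), c(31, 120), c(121, 180))) {
  stopifnot(inherits(series, "bead_series") || is.data.frame(series))
  out <- do.call(rbind, lapply(windows, function(w) {
    stopifnot(length(w) == 2L, w[1] <= w[2])
    inside <- series$t_rel >= w[1] & series$t_rel <= w[2]
    n <- sum(inside)
    data.frame(
      window_lo = w[1], window_hi = w[2],
      mean_ratio = if (n > 0) mean(series$ratio[inside]) else NA_real_,
      n_minutes = n,
      partial = n < (w[2] - w[1] + 1)
    )
  }))
  rownames(out) <- NULL
  out
}

#' Mean squared displacement of the cell centre
#'
#' `MSD_cell(tau)` is the average over `t` of
#' `|P_cell(t + tau) - P_cell(t)|^2`, using every overlapping interval of lag
#' `tau` (default 1 min), in square micrometres per interval.
#'
#' @param track a single-cell track table.
#' @param tau lag in minutes.
#' @return The MSD (um^2 per tau minutes).
#' @export
msd_cell <- function(track, tau = 1L) {
  tr <- single_cell(track)
  if (nrow(tr) < tau + 1L) {
    stop("insufficient data: need at least tau + 1 timepoints", call. = FALSE)
  }
  n <- nrow(tr)
  idx <- seq_len(n - tau)
  dx <- tr$x_cell[idx + tau] - tr$x_cell[idx]
  dy <- tr$y_cell[idx + tau] - tr$y_cell[idx]
  mean(dx^2 + dy^2)
}

#' Mean squared displacement of the bead, normalised to the cell
#'
#' The bead position is first expressed relative to the cell centre
#' (`NP_bead(t) = P_bead(t) - P_cell(t)`), removing cell locomotion, and the
#' MSD of that normalised position is averaged over every pair of in-contact
#' minutes `t`, `t + tau`.
#'
#' @param track a single-cell track table.
#' @param tau lag in minutes.
#' @return The bead MSD (um^2 per tau minutes).
#' @export
msd_bead <- function(track, tau = 1L) {
  tr <- single_cell(track)
  tr <- tr[tr$in_contact, , drop = FALSE]
  if (nrow(tr) < tau + 1L) {
    stop("insufficient data: need at least tau + 1 in-contact timepoints",
         call. = FALSE)
  }
  np_x <- tr$x_bead - tr$x_cell
  np_y <- tr$y_bead - tr$y_cell
  # pair minutes t, t + tau only where both are in contact
  keep <- match(tr$t_min + tau, tr$t_min)
  idx <- which(!is.na(keep))
  if (length(idx) == 0L) {
    stop("insufficient data: no in-contact pairs at lag tau", call. = FALSE)
  }
  dx <- np_x[keep[idx]] - np_x[idx]
  dy <- np_y[keep[idx]] - np_y[idx]
  mean(dx^2 + dy^2)
}

#' Assign a bead radius ratio to a membrane zone
#'
#' Periphery for ratios above 0.7, intermediate for (0.3, 0.7\], centre for
#' \[0, 0.3\]. Ratios above 1 (bead beyond the membrane reference point,
#' possible because the two are tracked independently) are labelled periphery
#' and flagged out-of-cell.
#'
#' @param ratio numeric vector of non-negative radius ratios.
#' @return A character vector in `{"periphery", "intermediate", "centre"}`
#'   with a logical attribute `out_of_cell` marking ratios > 1.
#' @examples
#' assign_zone(c(0.2, 0.5, 0.85))
#' @export
assign_zone <- function(ratio) {
  if (any(!is.finite(ratio)) || any(ratio < 0)) {
    stop("radius ratios must be finite and >= 0", call. = FALSE)
  }
  zone <- ifelse(ratio > 0.7, "periphery",
                 ifelse(ratio > 0.3, "intermediate", "centre"))
  attr(zone, "out_of_cell") <- ratio > 1
  zone
}

#' Classify a cell as dropping or retaining the bead
#'
#' After uptake (the first in-contact minute), the cell is observed for a
#' fixed window (default 180 min). Loss of contact at or before
#' `t_uptake + window` classifies the cell as `drops`; contact maintained
#' beyond the window classifies it as `retains`; a cell that divides within
#' the window is `excluded`. A track that ends, still in contact, before the
#' window closes cannot be classified and returns outcome `NA` with
#' `censored = TRUE`.
#'
#' @param track a single-cell track table containing an uptake event.
#' @param window observation window after uptake, minutes.
#' @return A one-row `data.frame`: `cell_id`, `t_uptake`, `t_loss`,
#'   `divided_at`, `outcome` in `{"drops", "retains", "excluded"}` (or `NA`),
#'   `censored`.
#' @export
classify_retention <- function(track, window = 180L) {
  tr <- single_cell(track)
  if (!any(tr$in_contact)) {
    stop("cell '", tr$cell_id[1], "' has no bead uptake event", call. = FALSE)
  }
  t_uptake <- tr$t_min[which(tr$in_contact)[1]]
  after <- tr[tr$t_min > t_uptake, , drop = FALSE]
  lost <- which(!after$in_contact)
  t_loss <- if (length(lost)) after$t_min[lost[1]] else NA_real_
  divided_at <- tr$divided_at[1]
  deadline <- t_uptake + window

  censored <- FALSE
  if (!is.na(divided_at) && divided_at <= deadline) {
    outcome <- "excluded"
  } else if (!is.na(t_loss) && t_loss <= deadline) {
    outcome <- "drops"
  } else if (!is.na(t_loss) || max(tr$t_min) >= deadline) {
    # either loss observed after the window, or contact held through it
    outcome <- "retains"
  } else {
    outcome <- NA_character_
    censored <- TRUE
  }
  data.frame(cell_id = tr$cell_id[1], t_uptake = t_uptake, t_loss = t_loss,
             divided_at = divided_at, outcome = outcome, censored = censored,
             stringsAsFactors = FALSE)
}

#' Retention records for every cell in a track table
#'
#' Applies [classify_retention()] per cell, skipping cells that never take up
#' a bead.
#'
#' @param tracks a track table (possibly many cells).
#' @param window observation window after uptake, minutes.
#' @return A `data.frame` with one row per cell with an uptake event.
#' @export
retention_table <- function(tracks, window = 180L) {
  cells <- unique(tracks$cell_id)
  recs <- lapply(cells, function(cid) {
    tr <- tracks[tracks$cell_id == cid, , drop = FALSE]
    if (!any(tr$in_contact)) return(NULL)
    rec <- classify_retention(tr, window = window)
    rec$condition <- tr$condition[1]
    rec
  })
  out <- do.call(rbind, recs)
  if (is.null(out)) {
    out <- data.frame(cell_id = character(), t_uptake = numeric(),
                      t_loss = numeric(), divided_at = numeric(),
                      outcome = character(), censored = logical(),
                      condition = character(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Per-condition drop/retain counts
#'
#' Tabulates non-excluded, non-censored retention records into the 2x2-ready
#' counts used for exact testing.
#'
#' @param records a [retention_table()] result.
#' @return A `data.frame` with columns `condition`, `drops`, `retains`,
#'   `excluded`, `percent_drops`.
#' @export
retention_counts <- function(records) {
  conds <- unique(records$condition)
  if (length(conds) == 0L) {
    return(data.frame(condition = character(), drops = integer(),
                      retains = integer(), excluded = integer(),
                      percent_drops = numeric(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, lapply(conds, function(cc) {
    r <- records[records$condition == cc, ]
    drops <- sum(r$outcome == "drops", na.rm = TRUE)
    retains <- sum(r$outcome == "retains", na.rm = TRUE)
    data.frame(condition = cc, drops = drops, retains = retains,
               excluded = sum(r$outcome == "excluded", na.rm = TRUE),
               percent_drops = if (drops + retains > 0)
                 100 * drops / (drops + retains) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
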