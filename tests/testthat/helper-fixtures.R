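# Hand-built tracks with fully controlled geometry. The cell sits at
# `centre`, the membrane reference at distance `radius` along angle 0, and
# the bead at `ratio * radius` along the same ray, so the radius ratio at
# minute i is exactly ratio[i].
make_track <- function(ratio, centre = c(0, 0), radius = 10,
                       t_start = 0, in_contact = rep(TRUE, length(ratio)),
                       divided_at = NA_real_, cell_id = "cellA",
                       condition = "WT") {
  n <- length(ratio)
  data.frame(
    experiment_id = "exp1", position_id = "pos1",
    cell_id = cell_id, condition = condition,
    t_min = seq(t_start, length.out = n),
    x_cell = rep(centre[1], n), y_cell = rep(centre[2], n),
    x_bead = ifelse(in_contact, centre[1] + ratio * radius, NA_real_),
    y_bead = ifelse(in_contact, centre[2], NA_real_),
    x_membrane = rep(centre[1] + radius, n), y_membrane = rep(centre[2], n),
    in_contact = in_contact, divided_at = divided_at,
    stringsAsFactors = FALSE
  )
}

# Track whose cell centre follows the supplied coordinates while the bead
# keeps a fixed offset `np` from the centre (rigid co-movement by default).
make_moving_track <- function(xy_cell, np = c(3, 0), radius = 10,
                              cell_id = "cellM", in_contact = TRUE) {
  n <- nrow(xy_cell)
  data.frame(
    experiment_id = "exp1", position_id = "pos1",
    cell_id = cell_id, condition = "WT",
    t_min = seq_len(n) - 1L,
    x_cell = xy_cell[, 1], y_cell = xy_cell[, 2],
    x_bead = xy_cell[, 1] + np[1], y_bead = xy_cell[, 2] + np[2],
    x_membrane = xy_cell[, 1] + radius, y_membrane = xy_cell[, 2],
    in_contact = rep(in_contact, n), divided_at = NA_real_,
    stringsAsFactors = FALSE
  )
}

# Independent brute-force oracle for the two-sided Fisher exact p: enumerate
# every table with the observed margins and sum the hypergeometric
# probabilities of those no more probable than the observed table.
fisher_bruteforce <- function(a, b, c, d) {
  m <- a + c; n_ <- b + d; k <- a + b
  lo <- max(0L, k - n_); hi <- min(k, m)
  support <- lo:hi
  probs <- stats::dhyper(support, m, n_, k)
  p_obs <- stats::dhyper(a, m, n_, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
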