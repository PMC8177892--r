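test_that("distance is the Euclidean norm", {
  expect_equal(distance(c(0, 0), c(3, 4)), 5)
  expect_equal(distance(c(2, -1), c(2, -1)), 0)
  expect_equal(distance(c(1, 1), c(4, 5)), 5)  # sqrt(9 + 16) by hand
  expect_error(distance(c(Inf, 0), c(0, 0)), "finite")
})

test_that("radius_ratio follows the distance-quotient definition", {
  tr <- data.frame(experiment_id = "e", position_id = "p", cell_id = "c",
                   condition = "WT", t_min = 0, x_cell = 0, y_cell = 0,
                   x_bead = 3, y_bead = 4, x_membrane = 6, y_membrane = 8,
                   in_contact = TRUE, divided_at = NA_real_)
  expect_equal(radius_ratio(tr, 0), 0.5)

  tr$x_bead <- 6; tr$y_bead <- 8           # bead at the membrane point
  expect_equal(radius_ratio(tr, 0), 1)

  # membrane need not be collinear with the bead
  tr$x_bead <- 1; tr$y_bead <- 0; tr$x_membrane <- 0; tr$y_membrane <- 2
  expect_equal(radius_ratio(tr, 0), 0.5)

  tr$x_membrane <- 0; tr$y_membrane <- 0   # degenerate geometry
  expect_error(radius_ratio(tr, 0), "degenerate")
  expect_error(radius_ratio(tr, 5), "no timepoint")
})

test_that("radius_ratio is invariant under translation, rotation, scaling", {
  set.seed(101)
  base <- list(cell = c(1, 2), bead = c(4, 3), mem = c(7, -2))
  as_track <- function(pts) {
    data.frame(experiment_id = "e", position_id = "p", cell_id = "c",
               condition = "WT", t_min = 0,
               x_cell = pts$cell[1], y_cell = pts$cell[2],
               x_bead = pts$bead[1], y_bead = pts$bead[2],
               x_membrane = pts$mem[1], y_membrane = pts$mem[2],
               in_contact = TRUE, divided_at = NA_real_)
  }
  r0 <- radius_ratio(as_track(base), 0)
  for (i in 1:20) {
    th <- runif(1, 0, 2 * pi); s <- runif(1, 0.1, 5); shift <- rnorm(2, 0, 50)
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    tf <- lapply(base, function(p) as.vector(s * R %*% p + shift))
    expect_equal(radius_ratio(as_track(tf), 0), r0, tolerance = 1e-10)
  }
})

test_that("position_series re-indexes uptake to minute zero", {
  tr <- make_track(rep(0.6, 10), t_start = 30,
                   in_contact = c(rep(FALSE, 7), rep(TRUE, 3)))
  ser <- position_series(tr)
  expect_equal(ser$t_abs[1], 37)
  expect_equal(ser$t_rel, 0:2)
  expect_equal(ser$ratio, rep(0.6, 3))
  expect_error(position_series(make_track(0.5, in_contact = FALSE)),
               "empty series")
})

test_that("window means match hand-computed values and flag gaps", {
  # constant series: every window mean equals the constant
  ser <- position_series(make_track(rep(0.5, 181)))
  wm <- window_means(ser)
  expect_equal(wm$mean_ratio, rep(0.5, 3))
  expect_false(any(wm$partial))

  # linear ramp ratio = t/180: window mean is the arithmetic-series mean
  ser2 <- position_series(make_track((0:180) / 180))
  wm2 <- window_means(ser2)
  expect_equal(wm2$mean_ratio,
               c(mean(0:30), mean(31:120), mean(121:180)) / 180)
  expect_equal(wm2$mean_ratio[1], 15 / 180)

  # series covering only 0-100 min: third window absent and flagged
  ser3 <- position_series(make_track(rep(0.4, 101)))
  wm3 <- window_means(ser3)
  expect_true(is.na(wm3$mean_ratio[3]))
  expect_true(wm3$partial[3])
  expect_equal(wm3$n_minutes[3], 0)
})

test_that("msd_cell matches closed forms", {
  still <- make_moving_track(cbind(rep(1, 10), rep(2, 10)))
  expect_equal(msd_cell(still), 0)

  straight <- make_moving_track(cbind(2 * (0:9), rep(0, 10)))  # 2 um/min
  expect_equal(msd_cell(straight), 4)

  expect_error(msd_cell(still[1, ]), "insufficient")
})

test_that("msd_cell recovers 2 sigma^2 for a Gaussian walk", {
  sigma <- 1
  set.seed(202)
  msds <- replicate(100, {
    xy <- cbind(cumsum(rnorm(181, 0, sigma)), cumsum(rnorm(181, 0, sigma)))
    msd_cell(make_moving_track(xy))
  })
  se <- sd(msds) / sqrt(length(msds))
  expect_lt(abs(mean(msds) - 2 * sigma^2), 3 * se)
})

test_that("msd_bead removes rigid cell motion and equals the by-hand mean", {
  set.seed(303)
  walk <- cbind(cumsum(rnorm(30)), cumsum(rnorm(30)))
  rigid <- make_moving_track(walk, np = c(3, 1))
  expect_equal(msd_bead(rigid), 0)

  # static cell, bead moving 1 um/min in a straight line
  tr <- make_moving_track(cbind(rep(0, 10), rep(0, 10)))
  tr$x_bead <- 0:9; tr$y_bead <- 0
  expect_equal(msd_bead(tr), 1)

  # 5-point toy track: estimator equals the hand mean of squared NP diffs
  tr5 <- make_moving_track(cbind(c(0, 1, 1, 2, 3), c(0, 0, 1, 1, 2)))
  tr5$x_bead <- c(2, 4, 3, 6, 5); tr5$y_bead <- c(0, 1, 2, 2, 4)
  np <- cbind(tr5$x_bead - tr5$x_cell, tr5$y_bead - tr5$y_cell)
  hand <- mean(rowSums((np[-1, ] - np[-5, ])^2))
  expect_equal(msd_bead(tr5), hand)
})

test_that("msd_bead is invariant under rigid translation of the whole scene", {
  set.seed(404)
  xy <- cbind(cumsum(rnorm(40)), cumsum(rnorm(40)))
  tr <- make_moving_track(xy)
  tr$x_bead <- tr$x_bead + rnorm(40, 0, 0.5)
  tr$y_bead <- tr$y_bead + rnorm(40, 0, 0.5)
  ref <- msd_bead(tr)
  shifted <- tr
  for (col in c("x_cell", "x_bead", "x_membrane")) shifted[[col]] <- shifted[[col]] + 123.4
  for (col in c("y_cell", "y_bead", "y_membrane")) shifted[[col]] <- shifted[[col]] - 56.7
  expect_equal(msd_bead(shifted), ref, tolerance = 1e-9)
})

test_that("zone assignment uses the 0.7 / 0.3 edges with flags above 1", {
  expect_identical(as.vector(assign_zone(0.85)), "periphery")
  expect_identical(as.vector(assign_zone(0.5)), "intermediate")
  expect_identical(as.vector(assign_zone(0.2)), "centre")
  # boundary convention: upper-inclusive
  expect_identical(as.vector(assign_zone(c(0.3, 0.7))),
                   c("centre", "intermediate"))
  z <- assign_zone(1.2)
  expect_identical(as.vector(z), "periphery")
  expect_true(attr(z, "out_of_cell"))
  expect_error(assign_zone(-0.1), ">= 0")
})

test_that("retention classification matches the 180-min window contract", {
  # contact lost at t_uptake + 100 -> drops
  tr <- make_track(rep(0.5, 301),
                   in_contact = c(rep(TRUE, 100), rep(FALSE, 201)))
  expect_identical(classify_retention(tr)$outcome, "drops")

  # contact continuous through t_uptake + 200 -> retains
  tr2 <- make_track(rep(0.5, 201))
  expect_identical(classify_retention(tr2)$outcome, "retains")

  # division inside the window -> excluded
  tr3 <- make_track(rep(0.5, 301), divided_at = 90)
  expect_identical(classify_retention(tr3)$outcome, "excluded")

  expect_error(classify_retention(make_track(0.5, in_contact = FALSE)),
               "no bead uptake")
})

test_that("drops/retains switch exactly between contact durations 180 and 181", {
  outcomes <- vapply(1:300, function(d) {
    tr <- make_track(rep(0.5, 302),
                     in_contact = c(rep(TRUE, d), rep(FALSE, 302 - d)))
    classify_retention(tr)$outcome
  }, "")
  expect_true(all(outcomes[1:180] == "drops"))
  expect_true(all(outcomes[181:300] == "retains"))
})

test_that("a censored track (ends in contact before the window) is flagged", {
  tr <- make_track(rep(0.5, 100))
  rec <- classify_retention(tr)
  expect_true(is.na(rec$outcome))
  expect_true(rec$censored)
})

test_that("retention_counts tabulates per condition", {
  mk <- function(id, cond, d, div = NA_real_) {
    make_track(rep(0.5, 302), cell_id = id, condition = cond,
               in_contact = c(rep(TRUE, d), rep(FALSE, 302 - d)),
               divided_at = div)
  }
  tracks <- rbind(mk("a", "WT", 50), mk("b", "WT", 300), mk("c", "WT", 300),
                  mk("d", "KO", 300), mk("e", "KO", 120, div = 60))
  counts <- retention_counts(retention_table(tracks))
  wt <- counts[counts$condition == "WT", ]
  expect_equal(c(wt$drops, wt$retains), c(1, 2))
  expect_equal(wt$percent_drops, 100 / 3)
  ko <- counts[counts$condition == "KO", ]
  expect_equal(c(ko$drops, ko$retains, ko$excluded), c(0, 1, 1))
})
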