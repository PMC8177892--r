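cfg_contact <- function(...) {
  sim_config(n_cells = 1, duration_min = 60, contact_hazard = 1,
             drop_hazard = 0, division_hazard = 0, sigma_theta = 0, ...)
}

test_that("frozen radial dynamics hold the initial radius fraction", {
  cfg <- cfg_contact(k_reloc = 0, sigma_r = 0, r0 = 0.9, seed = 4)
  tr <- simulate_bead_track(cfg, "c1")
  ser <- position_series(tr)
  expect_equal(ser$ratio, rep(0.9, nrow(ser)), tolerance = 1e-12)
})

test_that("full relocation converges to r_eq in one step", {
  cfg <- cfg_contact(k_reloc = 1, sigma_r = 0, r0 = 0.9, r_eq = 0.5, seed = 4)
  ser <- position_series(simulate_bead_track(cfg, "c1"))
  expect_equal(ser$ratio[1], 0.9)
  expect_equal(ser$ratio[-1], rep(0.5, nrow(ser) - 1), tolerance = 1e-12)
})

test_that("identical config and seed give byte-identical output", {
  cfg <- sim_config(n_cells = 3, duration_min = 40, seed = 99)
  expect_identical(simulate_tracks(cfg), simulate_tracks(cfg))
  expect_identical(simulate_population(cfg, 2), simulate_population(cfg, 2))
  expect_identical(simulate_divisions(cfg, 20), simulate_divisions(cfg, 20))
  expect_identical(simulate_doublets(cfg, 20), simulate_doublets(cfg, 20))
})

test_that("radius fraction stays in (0, 1] under heavy noise", {
  cfg <- cfg_contact(sigma_r = 0.5, r0 = 0.9, seed = 21)
  for (s in 1:10) {
    ser <- position_series(simulate_bead_track(cfg, "c", .seed = s))
    expect_true(all(ser$ratio > 0 & ser$ratio <= 1))
  }
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(contact_hazard = 1.2), "rate")
  expect_error(sim_config(r_eq = 0), "\\(0, 1\\]")
  expect_error(sim_config(cell_step_sigma = NaN), "finite")
  expect_error(sim_config(cell_radius_um = -1))
})

test_that("deterministic hazards pin population event times", {
  cfg <- sim_config(n_cells = 30, duration_min = 20, cytoneme_hazard = 1,
                    contact_hazard = 0, seed = 5)
  pop <- simulate_population(cfg, n_positions = 3)
  at0 <- pop[pop$t_min == 0, ]
  expect_true(all(at0$n_with_cytonemes == 0))
  later <- pop[pop$t_min >= 1, ]
  expect_true(all(later$n_with_cytonemes == later$n_total))
  expect_true(all(pop$n_with_beads == 0))
})

test_that("first-contact times follow the geometric closed form", {
  h <- 0.05
  cfg <- sim_config(n_cells = 2000, duration_min = 120, contact_hazard = h,
                    seed = 31)
  pop <- simulate_population(cfg, n_positions = 1)
  for (tt in c(10, 30, 60)) {
    frac <- pop$n_with_beads[pop$t_min == tt] / pop$n_total[pop$t_min == tt]
    expected <- 1 - (1 - h)^tt
    se <- sqrt(expected * (1 - expected) / 2000)
    expect_lt(abs(frac - expected), 3 * se)
  }
})

test_that("population events are irreversible (counts non-decreasing)", {
  cfg <- sim_config(n_cells = 100, duration_min = 100, seed = 8)
  pop <- simulate_population(cfg, n_positions = 4)
  for (p in unique(pop$position_id)) {
    sub <- pop[pop$position_id == p, ]
    expect_true(all(diff(sub$n_with_cytonemes) >= 0))
    expect_true(all(diff(sub$n_with_beads) >= 0))
  }
})

test_that("angle mixture degenerates as specified at its extremes", {
  cfg0 <- sim_config(angle_mix_p = 0, seed = 13)
  ang <- simulate_divisions(cfg0, 2000)$true_angle_deg
  expect_gt(stats::ks.test(ang, "punif", 0, 90)$p.value, 0.01)

  cfg1 <- sim_config(angle_mix_p = 1, angle_kappa = 5000, seed = 13)
  ang1 <- simulate_divisions(cfg1, 500)$true_angle_deg
  expect_true(all(ang1 >= 85))
})

test_that("noiseless doublets reproduce the intensity arithmetic", {
  cfg <- sim_config(noise_sd = 0, total_intensity = 100, background_mean = 10,
                    partition_alpha = 3, partition_beta = 2, seed = 17)
  db <- simulate_doublets(cfg, 200)
  p_true <- (db$I_proximal - 10) / 100
  calls <- doublet_calls(db)
  expect_equal(calls$percent_proximal, 100 * p_true, tolerance = 1e-9)
  expect_true(all(abs((db$I_proximal + db$I_distal - 20) - 100) < 1e-9))
})

test_that("symmetric partition shapes give a mean partition near 50%", {
  cfg <- sim_config(noise_sd = 0, partition_alpha = 4, partition_beta = 4,
                    seed = 19)
  calls <- doublet_calls(simulate_doublets(cfg, 5000))
  expect_lt(abs(mean(calls$percent_proximal) - 50), 1)
})

test_that("late-window mean radius ratio recovers r_eq across cohorts", {
  for (req in c(0.5, 0.7)) {
    cfg <- sim_config(n_cells = 50, duration_min = 180, contact_hazard = 1,
                      drop_hazard = 0, division_hazard = 0, k_reloc = 0.1,
                      sigma_r = 0.02, r0 = 0.95, r_eq = req, seed = 42)
    tracks <- simulate_tracks(cfg)
    late <- vapply(unique(tracks$cell_id), function(cid) {
      ser <- position_series(tracks[tracks$cell_id == cid, ])
      window_means(ser)$mean_ratio[3]
    }, 0)
    expect_lt(abs(mean(late) - req), 0.05)
  }
})

test_that("recovered late-window mean is monotone in r_eq", {
  means <- vapply(c(0.3, 0.5, 0.7, 0.9), function(req) {
    cfg <- sim_config(n_cells = 25, duration_min = 180, contact_hazard = 1,
                      drop_hazard = 0, division_hazard = 0, k_reloc = 0.1,
                      sigma_r = 0.02, r0 = 0.95, r_eq = req, seed = 7)
    tracks <- simulate_tracks(cfg)
    mean(vapply(unique(tracks$cell_id), function(cid) {
      window_means(position_series(tracks[tracks$cell_id == cid, ]))$mean_ratio[3]
    }, 0))
  }, 0)
  expect_true(all(diff(means) > 0))
})
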