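test_that("spindle_angle reproduces the reference geometries", {
  expect_equal(spindle_angle(c(-1, 0), c(1, 0), c(2, 0)), 90)
  expect_equal(spindle_angle(c(-1, 0), c(1, 0), c(0, 2)), 0)
  expect_equal(spindle_angle(c(-1, 0), c(1, 0), c(3, 3)), 45)
  expect_error(spindle_angle(c(1, 1), c(1, 1), c(0, 0)), "poles coincide")
  expect_error(spindle_angle(c(-1, 0), c(1, 0), c(0, 0)), "midpoint")
})

test_that("spindle_angle is invariant under pole swap, rigid motion, reflection", {
  set.seed(77)
  for (i in 1:25) {
    pa <- rnorm(2, 0, 5); pb <- rnorm(2, 0, 5); bd <- rnorm(2, 0, 5)
    if (all(pa == pb) || all(bd == (pa + pb) / 2)) next
    a0 <- spindle_angle(pa, pb, bd)
    expect_equal(spindle_angle(pb, pa, bd), a0, tolerance = 1e-10)
    th <- runif(1, 0, 2 * pi); shift <- rnorm(2, 0, 20)
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    tf <- function(p) as.vector(R %*% p + shift)
    expect_equal(spindle_angle(tf(pa), tf(pb), tf(bd)), a0, tolerance = 1e-9)
    refl <- function(p) c(-p[1], p[2])
    expect_equal(spindle_angle(refl(pa), refl(pb), refl(bd)), a0,
                 tolerance = 1e-9)
    expect_gte(a0, 0); expect_lte(a0, 90)
  }
})

test_that("simulated division geometry round-trips through spindle_angle", {
  cfg <- sim_config(seed = 60)
  ev <- spindle_angles(simulate_divisions(cfg, 1000))
  expect_lt(max(abs(ev$angle_deg - ev$true_angle_deg)), 1e-6)
})

test_that("rose histogram bins right-open with 90 in the last bin", {
  h <- rose_histogram(c(87, 89, 90))
  expect_equal(h$counts[18], 3)
  expect_equal(sum(h$counts), 3)

  h0 <- rose_histogram(numeric())
  expect_equal(h0$counts, rep(0L, 18))

  hu <- rose_histogram(0:89)
  expect_equal(hu$counts, rep(5L, 18))

  expect_equal(sum(rose_histogram(runif(37, 0, 90))$counts), 37)
  expect_error(rose_histogram(c(10, 95)), "\\[0, 90\\]")
  expect_error(rose_histogram(10, bin_width = 7), "divisor")
})

test_that("randomised-null chi-squared matches hand arithmetic", {
  r1 <- randomized_null_chisq(c(rep(10, 10), rep(40, 10), rep(80, 10)))
  expect_equal(r1$counts, c(10L, 10L, 10L))
  expect_equal(r1$chi2, 0)
  expect_equal(r1$p, 1)

  r2 <- randomized_null_chisq(rep(15, 30))  # all in the first bin
  expect_equal(r2$counts, c(30L, 0L, 0L))
  expect_equal(r2$chi2, 60)                 # (400 + 100 + 100) / 10
  expect_equal(r2$df, 2L)

  # chi2 = 0 iff the three counts are exactly equal
  r3 <- randomized_null_chisq(c(rep(10, 10), rep(40, 10), rep(80, 11)))
  expect_gt(r3$chi2, 0)
})

test_that("exact multinomial option agrees with chi-squared in direction", {
  ang <- c(rep(10, 10), 40, 70)
  asym <- randomized_null_chisq(ang, exact = TRUE)
  expect_identical(asym$method, "exact multinomial")
  expect_lt(asym$p, 0.05)
  even <- randomized_null_chisq(c(10, 40, 80), exact = TRUE)
  expect_equal(even$p, 1)
})

test_that("two-sample K-S matches ECDF enumeration", {
  expect_equal(ks_two_sample(c(1, 2, 3), c(1, 2, 3))$D, 0)
  expect_equal(ks_two_sample(10, 80)$D, 1)
  expect_equal(ks_two_sample(c(1, 2, 3), c(2, 3, 4))$D, 1 / 3)
  expect_error(ks_two_sample(numeric(), 1), "non-empty")
})

test_that("permutation K-S p is seeded and agrees broadly with asymptotic", {
  set.seed(91)
  a <- runif(40, 0, 90); b <- runif(40, 20, 90)
  p1 <- ks_two_sample(a, b, permutation = TRUE, n_perm = 500, seed = 3)
  p2 <- ks_two_sample(a, b, permutation = TRUE, n_perm = 500, seed = 3)
  expect_identical(p1$p, p2$p)
  pa <- ks_two_sample(a, b)
  expect_lt(abs(p1$p - pa$p), 0.1)
})

test_that("analyse_divisions summarises per condition and across conditions", {
  cfg <- sim_config(seed = 62)
  wt <- simulate_divisions(cfg, 60, condition = "WT")
  cfg0 <- sim_config(angle_mix_p = 0, seed = 63)
  ko <- simulate_divisions(cfg0, 60, condition = "KO")
  res <- analyse_divisions(rbind(wt, ko))
  expect_setequal(unique(res$rose_counts$condition), c("WT", "KO"))
  expect_equal(sum(res$rose_counts$count), 120)
  expect_equal(nrow(res$null_tests), 2)
  # the oriented condition rejects the randomised null; both appear in K-S
  expect_lt(res$null_tests$p[res$null_tests$condition == "WT"], 0.001)
  expect_equal(nrow(res$ks_tests), 1)
})
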