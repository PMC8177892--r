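#' Spindle-to-bead angle at anaphase
#'
#' The spindle (major) axis runs pole to pole; the minor axis is its
#' perpendicular through the division midpoint. The angle `alpha` is the
#' acute angle between the minor axis — taken as an undirected line — and the
#' vector from the midpoint to the bead, folded into \[0, 90\] degrees.
#' 90 degrees is a fully bead-oriented division (bead on the spindle axis),
#' 0 degrees a division whose plane faces the bead.
#'
#' @param pole_a,pole_b numeric (x, y) coordinates of the two spindle poles,
#'   micrometres; must be distinct.
#' @param bead numeric (x, y) coordinate of the bead; must not coincide with
#'   the division midpoint.
#' @return The angle in degrees in \[0, 90\].
#' @examples
#' spindle_angle(c(-1, 0), c(1, 0), c(2, 0))  # 90: bead on the spindle axis
#' spindle_angle(c(-1, 0), c(1, 0), c(0, 2))  # 0: bead on the minor axis
#' @export
spindle_angle <- function(pole_a, pole_b, bead) {
  if (length(pole_a) != 2L || length(pole_b) != 2L || length(bead) != 2L ||
      !all(is.finite(c(pole_a, pole_b, bead)))) {
    stop("spindle_angle() expects three finite (x, y) points", call. = FALSE)
  }
  major <- pole_b - pole_a
  if (all(major == 0)) {
    stop("degenerate geometry: spindle poles coincide", call. = FALSE)
  }
  mid <- (pole_a + pole_b) / 2
  v <- bead - mid
  if (all(v == 0)) {
    stop("degenerate geometry: bead at the division midpoint", call. = FALSE)
  }
  minor <- c(-major[2], major[1])
  cosang <- abs(sum(minor * v)) / (sqrt(sum(minor^2)) * sqrt(sum(v^2)))
  acos(min(max(cosang, 0), 1)) * 180 / pi
}

#' Spindle angles for a division-event table
#'
#' @param events a division-event `data.frame` (see [read_divisions()]).
#' @return `events` with an `angle_deg` column appended.
#' @export
spindle_angles <- function(events) {
  events$angle_deg <- vapply(seq_len(nrow(events)), function(i) {
    spindle_angle(c(events$x_pole_a[i], events$y_pole_a[i]),
                  c(events$x_pole_b[i], events$y_pole_b[i]),
                  c(events$x_bead[i], events$y_bead[i]))
  }, 0)
  events
}

#' Rose-plot histogram of spindle angles
#'
#' Bins angles over \[0, 90\] degrees into right-open bins of `bin_width`
#' degrees; the terminal value 90 is assigned to the last bin.
#'
#' @param angles numeric vector of angles in \[0, 90\] degrees.
#' @param bin_width bin width in degrees; must divide 90.
#' @return An object of class `angle_distribution`: a list with `angles`,
#'   `bin_width`, `breaks`, and integer `counts` per bin.
#' @examples
#' rose_histogram(c(87, 89, 90))$counts
#' @export
rose_histogram <- function(angles, bin_width = 5) {
  if (length(angles) && (any(!is.finite(angles)) ||
                         any(angles < 0) || any(angles > 90))) {
    stop("angles must lie in [0, 90] degrees", call. = FALSE)
  }
  if (bin_width <= 0 || abs(90 / bin_width - round(90 / bin_width)) > 1e-9) {
    stop("bin_width must be a positive divisor of 90", call. = FALSE)
  }
  breaks <- seq(0, 90, by = bin_width)
  idx <- pmin(floor(angles / bin_width) + 1L, length(breaks) - 1L)
  counts <- tabulate(idx, nbins = length(breaks) - 1L)
  structure(list(angles = angles, bin_width = bin_width,
                 breaks = breaks, counts = counts),
            class = "angle_distribution")
}

#' @export
print.angle_distribution <- function(x, ...) {
  cat(sprintf("Spindle angle distribution: n = %d, %g-degree bins\n",
              length(x$angles), x$bin_width))
  lab <- sprintf("[%g,%g%s", x$breaks[-length(x$breaks)], x$breaks[-1],
                 c(rep(")", length(x$counts) - 1L), "]"))
  print(stats::setNames(x$counts, lab))
  invisible(x)
}

#' Polar rose plot of an angle distribution
#'
#' Draws the binned angle counts as wedges on the \[0, 90\]-degree quadrant
#' using base graphics.
#'
#' @param x an `angle_distribution` from [rose_histogram()].
#' @param col wedge fill colour.
#' @param ... ignored.
#' @return `x`, invisibly.
#' @export
plot.angle_distribution <- function(x, col = "steelblue3", ...) {
  r_max <- max(x$counts, 1)
  op <- graphics::par(mar = c(1, 1, 2, 1), pty = "s")
  on.exit(graphics::par(op))
  plot(NA, xlim = c(0, r_max * 1.05), ylim = c(0, r_max * 1.05),
       axes = FALSE, xlab = "", ylab = "", asp = 1,
       main = sprintf("Spindle angles (n = %d)", length(x$angles)))
  for (i in seq_along(x$counts)) {
    if (x$counts[i] == 0) next
    th <- seq(x$breaks[i], x$breaks[i + 1], length.out = 20) * pi / 180
    graphics::polygon(c(0, x$counts[i] * cos(th), 0),
                      c(0, x$counts[i] * sin(th), 0),
                      col = col, border = "grey25")
  }
  for (ang in seq(0, 90, 30)) {
    graphics::lines(c(0, r_max * 1.02 * cos(ang * pi / 180)),
                    c(0, r_max * 1.02 * sin(ang * pi / 180)),
                    col = "grey70", lty = 3)
    graphics::text(r_max * 1.05 * cos(ang * pi / 180),
                   r_max * 1.05 * sin(ang * pi / 180),
                   sprintf("%d°", ang), cex = 0.8)
  }
  invisible(x)
}

#' Chi-squared test against a randomised (bead-independent) null
#'
#' Under the null of bead-independent division, spindle angles are taken as
#' equally likely to fall in the three 30-degree bins 0-30, 30-60 and 60-90.
#' The observed counts (right-open bins, 90 in the last) are tested against
#' equal expected counts `n/3` with a Pearson chi-squared test on 2 degrees
#' of freedom. For small samples (`n < 15`) an exact multinomial p-value is
#' available.
#'
#' @param angles numeric vector of angles in \[0, 90\] degrees.
#' @param exact logical; compute the exact multinomial p instead of the
#'   chi-squared approximation.
#' @return A list: `counts` (length 3), `chi2`, `df`, `p`, `method`.
#' @export
randomized_null_chisq <- function(angles, exact = FALSE) {
  if (length(angles) < 1) stop("at least one angle is required", call. = FALSE)
  if (any(!is.finite(angles)) || any(angles < 0) || any(angles > 90)) {
    stop("angles must lie in [0, 90] degrees", call. = FALSE)
  }
  idx <- pmin(floor(angles / 30) + 1L, 3L)
  counts <- tabulate(idx, nbins = 3L)
  chi <- suppressWarnings(stats::chisq.test(counts, p = rep(1 / 3, 3)))
  p <- unname(chi$p.value)
  method <- "Pearson chi-squared"
  if (exact) {
    p <- exact_multinomial_p(counts, rep(1 / 3, 3))
    method <- "exact multinomial"
  }
  list(counts = counts, chi2 = unname(chi$statistic), df = 2L, p = p,
       method = method)
}

# Exact multinomial goodness-of-fit p: total probability of outcomes no more
# probable than the observed one, by enumeration over all compositions.
exact_multinomial_p <- function(counts, prob) {
  n <- sum(counts)
  p_obs <- stats::dmultinom(counts, prob = prob)
  tot <- 0
  for (a in 0:n) for (b in 0:(n - a)) {
    pr <- stats::dmultinom(c(a, b, n - a - b), prob = prob)
    if (pr <= p_obs * (1 + 1e-7)) tot <- tot + pr
  }
  min(tot, 1)
}

#' Two-sample Kolmogorov-Smirnov test on angle distributions
#'
#' `D` is the supremum distance between the two empirical CDFs; the p-value
#' uses the asymptotic two-sample formula. Because measured angle samples are
#' small and discrete, a seeded permutation p-value is available as an
#' option.
#'
#' @param angles_a,angles_b non-empty numeric angle samples.
#' @param permutation logical; compute a permutation p instead of the
#'   asymptotic one.
#' @param n_perm number of label shuffles for the permutation p.
#' @param seed RNG seed for the permutation p.
#' @return A list: `D`, `p`, `method`.
#' @export
ks_two_sample <- function(angles_a, angles_b, permutation = FALSE,
                          n_perm = 10000L, seed = 1L) {
  if (length(angles_a) == 0L || length(angles_b) == 0L) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  kt <- suppressWarnings(stats::ks.test(angles_a, angles_b, exact = FALSE))
  D <- unname(kt$statistic)
  if (!permutation) {
    return(list(D = D, p = unname(kt$p.value), method = "asymptotic"))
  }
  pooled <- c(angles_a, angles_b)
  na <- length(angles_a)
  hits <- with_seed(seed, {
    sum(vapply(seq_len(n_perm), function(i) {
      idx <- sample.int(length(pooled), na)
      d <- suppressWarnings(
        stats::ks.test(pooled[idx], pooled[-idx], exact = FALSE)$statistic)
      d >= D - 1e-12
    }, TRUE))
  })
  list(D = D, p = (hits + 1) / (n_perm + 1),
       method = sprintf("permutation (%d shuffles)", n_perm))
}
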