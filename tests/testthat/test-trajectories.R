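# builds a raw trajectory from vectors, with optional click times
traj <- function(t, x, y, ...) raw_trajectory(t, x, y, ...)

test_that("time normalization is the identity on already-uniform input", {
  t <- seq(0, 1000, length.out = 101)
  x <- seq(0, -0.5, length.out = 101) + sin(seq(0, pi, length.out = 101))
  y <- seq(-0.35, 0.25, length.out = 101)
  n <- time_normalize(traj(t, x, y), 101)
  expect_equal(n$x, x, tolerance = 1e-12)
  expect_equal(n$y, y, tolerance = 1e-12)
  expect_equal(n$step_times, t, tolerance = 1e-12)
})

test_that("two samples normalize to equally spaced collinear points", {
  n <- time_normalize(traj(c(0, 500), c(0, -0.5), c(-0.35, 0.25)), 101)
  expect_equal(diff(n$x), rep(-0.5 / 100, 100), tolerance = 1e-12)
  expect_equal(diff(n$y), rep(0.6 / 100, 100), tolerance = 1e-12)
  # collinearity
  expect_equal(stats::cor(n$x, n$y), -1, tolerance = 1e-12)
})

test_that("normalization matches an independent piecewise-linear oracle and preserves endpoints", {
  set.seed(7)
  for (rep in 1:20) {
    k <- sample(5:40, 1)
    t <- cumsum(runif(k, 5, 30)); x <- rnorm(k); y <- rnorm(k)
    n <- time_normalize(traj(t, x, y), 101)
    tt <- seq(t[1], t[k], length.out = 101)
    expect_equal(n$x, manual_interp(t, x, tt), tolerance = 1e-10)
    expect_equal(n$y, manual_interp(t, y, tt), tolerance = 1e-10)
    expect_identical(n$x[c(1, 101)], x[c(1, k)])
    expect_identical(n$y[c(1, 101)], y[c(1, k)])
  }
  expect_error(raw_trajectory(0, 0, 0), "fewer than 2")
})

test_that("symmetric remapping mirrors right-enders, is an involution, and needs the response to break ties", {
  t <- seq(0, 600, length.out = 21)
  left <- time_normalize(traj(t, seq(0, -0.5, length.out = 21),
                              seq(-0.35, 0.25, length.out = 21)))
  expect_equal(remap_symmetric(left)$x, left$x)
  right <- time_normalize(traj(t, seq(0, 0.5, length.out = 21) + 0.01 *
                                 sin(seq(0, pi, length.out = 21)),
                               seq(-0.35, 0.25, length.out = 21)))
  r1 <- remap_symmetric(right)
  expect_equal(r1$x, 2 * right$x[1] - right$x, tolerance = 1e-12)
  expect_equal(r1$chosen_side, "left")
  # mirror of the mirror restores the original coordinates
  r2 <- r1; r2$chosen_side <- "right"
  expect_equal(remap_symmetric(r2)$x, right$x, tolerance = 1e-12)
  # endpoint exactly on the start abscissa
  amb <- time_normalize(traj(c(0, 100, 200), c(0, 0.3, 0), c(0, 0.5, 1)))
  expect_error(remap_symmetric(amb), "ambiguous")
  expect_equal(remap_symmetric(amb, "left")$chosen_side, "left")
})

test_that("a right-ending trajectory and its mirrored twin yield identical measures", {
  set.seed(13)
  t <- c(0, sort(runif(30, 1, 799)), 800)
  x <- c(0, cumsum(rnorm(30, 0.015, 0.01)), 0.5)
  y <- seq(-0.35, 0.25, length.out = 32) + c(0, rnorm(30, 0, 0.01), 0)
  pr <- measure_params()
  m_right <- measure_trial(traj(t, x, y), pr)
  m_left <- measure_trial(traj(t, -x, y), pr)
  for (col in c("initiation_rt", "md", "sample_entropy", "md_time",
                "total_rt"))
    expect_equal(m_right[[col]], m_left[[col]], tolerance = 1e-12,
                 label = col)
})

test_that("maximum deviation matches the analytic point-line distance", {
  # straight path deviates nowhere
  s <- time_normalize(traj(c(0, 500), c(0, -0.5), c(-0.35, 0.25)))
  expect_equal(max_deviation(s)$md, 0, tolerance = 1e-12)
  # start (0,0), end (-1,1), apex (0,1): |md| = sqrt(2)/2, toward the
  # non-chosen (right) side, hence positive
  a <- time_normalize(traj(c(0, 50, 100), c(0, 0, -1), c(0, 1, 1)), 3)
  md <- max_deviation(a)
  expect_equal(md$md, sqrt(2) / 2, tolerance = 1e-12)
  expect_identical(md$md_step, 2L)
  # curvature away from the competitor is negative
  b <- time_normalize(traj(c(0, 50, 100), c(0, -1, -1), c(0, 0, 1)), 3)
  expect_equal(max_deviation(b)$md, -sqrt(2) / 2, tolerance = 1e-12)
  expect_error(max_deviation(time_normalize(
    traj(c(0, 10, 20), c(0, 1, 0), c(0, 0.5, 1)), 3)), "side")
})

test_that("maximum deviation is invariant under rotation and covariant under scaling", {
  set.seed(17)
  base <- time_normalize(traj(cumsum(runif(15, 5, 20)),
                              c(0, rnorm(13, 0, 0.3), -1),
                              seq(0, 1, length.out = 15)))
  m0 <- max_deviation(base)
  for (theta in runif(5, 0, 2 * pi)) {
    rot <- base
    rot$x <- cos(theta) * base$x - sin(theta) * base$y
    rot$y <- sin(theta) * base$x + cos(theta) * base$y
    rot$chosen_side <- base$chosen_side  # side is a recorded fact
    m1 <- max_deviation(rot)
    expect_equal(m1$md, m0$md, tolerance = 1e-10)
    expect_identical(m1$md_step, m0$md_step)
  }
  for (lambda in c(0.5, 3, 10)) {
    sc <- base; sc$x <- lambda * base$x; sc$y <- lambda * base$y
    m2 <- max_deviation(sc)
    expect_equal(m2$md, lambda * m0$md, tolerance = 1e-10)
    expect_identical(m2$md_step, m0$md_step)
  }
})

test_that("sample entropy agrees with the naive double loop and handles edge cases", {
  expect_equal(sample_entropy(rep(5, 30), m = 3, r = 0.1), 0)
  set.seed(23)
  z <- rnorm(40)
  expect_equal(sample_entropy(z, m = 2, r = 1e9), 0)
  for (rep in 1:25) {
    x <- if (rep %% 2) cumsum(rnorm(30)) else rnorm(30)
    r <- 0.2 * stats::sd(x)
    ref <- naive_sampen(x, 3, r)
    if (is.finite(ref)) {
      expect_equal(sample_entropy(x, m = 3, r = r), ref,
                   tolerance = 1e-12)
    } else {
      expect_error(sample_entropy(x, m = 3, r = r),
                   class = "drmtrack_entropy_undefined")
    }
  }
  expect_error(sample_entropy(rnorm(4), m = 3), "too short")
  # far-apart templates: no matches at m+1 -> undefined, classed error
  expect_error(sample_entropy(c(0, 1e3, -1e3, 2e3, -2e3, 3e3, -3e3, 4e3,
                                -4e3, 5e3), m = 3, r = 1e-6),
               class = "drmtrack_entropy_undefined")
})

test_that("md_time reports the step clock, with the earliest-step tie rule", {
  t <- seq(0, 1000, length.out = 5)
  # apex at the final step
  tr <- time_normalize(traj(t, c(0, 0.05, 0.1, 0.2, 1e-6 - 0),
                            c(0, 0.25, 0.5, 0.75, 1)), 5)
  tr$chosen_side <- "left"
  expect_equal(md_time(tr, 5L), 1000)
  # straight line: all deviations tie at zero -> earliest step
  st <- time_normalize(traj(c(0, 400), c(0, -0.5), c(-0.35, 0.25)), 101)
  expect_identical(max_deviation(st)$md_step, 1L)
  # symmetric triangle: apex at the midpoint of the movement interval
  tri <- time_normalize(traj(c(0, 500, 1000), c(0, 0.5, -1), c(0, 0.5, 1)),
                        101)
  mdv <- max_deviation(tri)
  expect_equal(md_time(tri, mdv$md_step), 500, tolerance = 10)
  expect_error(md_time(tri, 200L), "range")
})

test_that("initiation RT is the first threshold crossing", {
  t <- seq(100, 400, by = 50)
  # first sample already beyond threshold relative to the button origin
  r1 <- traj(t, c(0.3, 0.3, 0.3, 0.4, 0.5, 0.6, 0.7) - 0.28,
             rep(0, 7), start_click_t = 80)
  expect_equal(initiation_rt(r1, origin = c(0, 0)), 100 - 80)
  # monotone outward drift: equals a direct scan
  x <- c(0, 0.002, 0.004, 0.009, 0.02, 0.05, 0.1)
  r2 <- traj(t, x, rep(0, 7), start_click_t = 100)
  scan <- t[which(sqrt((x - x[1])^2) > 0.01)[1]] - 100
  expect_equal(initiation_rt(r2, 0.01), scan)
  # no movement at all
  r3 <- traj(t, rep(0, 7), rep(0, 7))
  expect_error(initiation_rt(r3), "no movement")
})

test_that("measure_trial composes the chain and downgrades failures to aberrant flags", {
  # a well-behaved curved leftward trial
  set.seed(31)
  t <- c(0, 40, seq(80, 880, by = 16))
  k <- length(t)
  x <- c(0, 0, seq(0, -0.5, length.out = k - 2) +
           0.08 * sin(seq(0, pi, length.out = k - 2)) +
           cumsum(rnorm(k - 2, 0, 5e-4)))
  y <- c(-0.35, -0.35, seq(-0.35, 0.25, length.out = k - 2))
  m <- measure_trial(traj(t, x, y, start_click_t = 0))
  expect_false(m$aberrant)
  expect_gt(m$initiation_rt, 0)
  expect_true(m$md_time >= 0 && m$md_time <= m$total_rt)
  expect_gte(m$sample_entropy, 0)

  # stationary trial -> aberrant, not an error
  m2 <- measure_trial(traj(c(0, 100, 200), rep(0, 3), rep(0, 3)))
  expect_true(m2$aberrant)
  expect_match(m2$aberrant_reason, "no movement")
})

test_that("measure_trials batches, flags degenerate trials, and keeps row order", {
  t <- seq(0, 800, by = 20); k <- length(t)
  good <- data.frame(trial_id = "a", t = t,
                     x = seq(0, -0.5, length.out = k) +
                       0.05 * sin(seq(0, pi, length.out = k)),
                     y = seq(-0.35, 0.25, length.out = k))
  lone <- data.frame(trial_id = "b", t = 0, x = 0, y = 0)
  trials <- data.frame(trial_id = c("a", "b"), participant = "p1",
                       start_click_t = 0, end_click_t = 800)
  out <- measure_trials(trials, rbind(good, lone))
  expect_identical(out$trial_id, c("a", "b"))
  expect_false(out$aberrant[1])
  expect_true(out$aberrant[2])
  expect_match(out$aberrant_reason[2], "degenerate")
})
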