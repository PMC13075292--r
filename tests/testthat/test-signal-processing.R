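make_trace <- function(signal, dt = 0.1, speed = 1, clock = 7, x_start = 0)
  scan_trace(seq(0, by = dt, length.out = length(signal)), signal,
             scan_speed = speed, scan_start_clock = clock, x_start = x_start)

test_that("baseline subtraction: self, zero, and shifted-grid resampling oracle", {
  set.seed(21)
  s <- rnorm(50)
  tr <- make_trace(s)
  expect_equal(subtract_baseline(tr, tr)$signal, rep(0, 50))

  zero <- make_trace(rep(0, 50))
  expect_equal(subtract_baseline(tr, zero)$signal, s)

  # baseline sampled on a shifted position grid: oracle interpolates by hand
  bsig <- sin(seq(0, 2 * pi, length.out = 60))
  base <- scan_trace(seq(0, by = 0.1, length.out = 60), bsig,
                     scan_speed = 1, scan_start_clock = 0, x_start = 0.03)
  out <- subtract_baseline(tr, base)
  xb <- base$x_start + base$scan_speed * base$t
  xs <- tr$x_start + tr$scan_speed * tr$t
  oracle <- s - approx(xb, bsig, xout = xs, rule = 2)$y
  expect_equal(out$signal, oracle)

  fast <- make_trace(s, speed = 2)
  expect_error(subtract_baseline(tr, fast), class = "mrbscan_config_error")
})

test_that("moving average: identity cases, brute-force oracle, bounds, errors", {
  expect_equal(moving_average(rep(3.5, 10)), rep(3.5, 10))
  set.seed(22)
  s <- rnorm(20)
  expect_equal(moving_average(s, 1), s)

  # double-loop windowed-mean oracle with symmetric edge shrinkage
  oracle <- vapply(seq_along(s), function(i) {
    h <- min(2, i - 1, length(s) - i)
    mean(s[(i - h):(i + h)])
  }, 0)
  expect_equal(moving_average(s, 5), oracle)

  sm <- moving_average(s, 7)
  expect_true(all(sm >= min(s) - 1e-12 & sm <= max(s) + 1e-12))

  expect_error(moving_average(s, 4), class = "mrbscan_domain_error")
  expect_error(moving_average(s, -3), class = "mrbscan_domain_error")
  expect_error(moving_average(s, 21), class = "mrbscan_domain_error")
})

test_that("gradient localization follows the non-negative-run rule", {
  # strictly increasing ramp: one non-negative run from the first sample
  ramp <- make_trace(seq(0, 1, length.out = 20))
  fix <- locate_boundary_gradient(ramp)
  expect_equal(fix$t_boundary, 0)
  expect_equal(fix$x_boundary, ramp$x_start)

  # canonical trough: derivative 0,0,-2,0,2,0 -> rising-edge run starts at
  # the sample where the derivative first turns non-negative after the fall
  s <- c(0, 0, 0, -2, -2, 0, 0)
  tr <- make_trace(s, dt = 1)
  fix <- locate_boundary_trough(tr)  # trough itself: earliest minimum
  expect_equal(fix$t_boundary, 3)
  gfix <- locate_boundary_gradient(tr)
  d <- diff(s) / 1
  expect_equal(gfix$t_boundary, tr$t[oracle_run_start(d)])
  expect_equal(gfix$t_boundary, 3)   # first sample of the run containing max d
  expect_equal(gfix$quality, 2)

  # ties in the maximum derivative resolve to the earliest index
  s2 <- c(0, -1, 0, 5, 4, -1, 0, 5)
  g2 <- locate_boundary_gradient(make_trace(s2, dt = 1))
  expect_equal(g2$t_boundary, make_trace(s2, dt = 1)$t[oracle_run_start(diff(s2))])

  expect_error(locate_boundary_gradient(make_trace(rep(1, 10))),
               class = "mrbscan_no_boundary")
})

test_that("trough localization takes the earliest global minimum", {
  s <- c(0, -1, -3, -1, 0, -1, -3, -1, 0)
  fix <- locate_boundary_trough(make_trace(s, dt = 1))
  expect_equal(fix$t_boundary, 2)  # earliest of the two equal troughs
  expect_equal(fix$quality, 3)
  expect_error(locate_boundary_trough(make_trace(rep(0, 5))),
               class = "mrbscan_no_boundary")
})

test_that("localization is shift-equivariant away from edges", {
  base <- c(rep(0, 30), -1, -2.5, -2, -0.5, rep(0, 30))
  for (k in c(3, 11)) {
    shifted <- c(rep(0, k), base[seq_len(length(base) - k)])
    f0 <- locate_boundary_gradient(make_trace(base, dt = 0.5))
    fk <- locate_boundary_gradient(make_trace(shifted, dt = 0.5))
    expect_equal(fk$t_boundary - f0$t_boundary, k * 0.5)
    t0 <- locate_boundary_trough(make_trace(base, dt = 0.5))
    tk <- locate_boundary_trough(make_trace(shifted, dt = 0.5))
    expect_equal(tk$t_boundary - t0$t_boundary, k * 0.5)
  }
})

test_that("gradient and trough fixes agree within the trough width on clean signals", {
  x <- seq(0, 24, by = 0.025)
  s <- -exp(-0.5 * ((x - 10) / 0.4)^2)       # symmetric noiseless trough
  tr <- make_trace(s, dt = 0.025)
  g <- locate_boundary_gradient(tr)
  t <- locate_boundary_trough(tr)
  expect_lt(abs(g$x_boundary - t$x_boundary), 0.4)
})

test_that("simulated boundaries are recovered across the velocity range", {
  # noiseless generator round trip, U in 0.1..1.0 mm/min; tolerance is half
  # the window support plus one sample step (delta window: one sample)
  for (U in c(0.1, 0.4, 0.7, 1.0)) {
    cfg <- const_u_config(U)
    exp <- generate_experiment(cfg)
    e <- exp$experiments[[1]]
    tol <- cfg$window$support / 2 + cfg$scan_speed / cfg$sample_rate + 1e-6
    for (k in seq_along(e$traces)) {
      tr <- subtract_baseline(e$traces[[k]], exp$baseline)
      tr$signal <- moving_average(tr$signal, 5)
      g <- locate_boundary_gradient(tr)
      t <- locate_boundary_trough(tr)
      expect_lt(abs(g$x_boundary - e$truth$true_x_mm[k]), tol)
      expect_lt(abs(t$x_boundary - e$truth$true_x_mm[k]), tol)
    }
  }
})

test_that("scan-series pipeline applies the first-four-valid rule", {
  cfg <- quick_config(concentrations = 10, n_scans = 6)
  exp <- generate_experiment(cfg)
  e <- exp$experiments[[1]]

  fixes <- fixes_from_scan_series(e$traces, exp$baseline)
  expect_s3_class(fixes, "boundary_fixes")
  expect_equal(nrow(fixes), 4)                       # 6 valid -> first 4 kept
  expect_equal(fixes$clock_min, sort(fixes$clock_min))
  expect_true(all(diff(fixes$x_boundary_mm) > 0))    # boundary advances
  expect_equal(nrow(attr(fixes, "all_fixes")), 6)

  # positions track the ground truth
  expect_equal(fixes$x_boundary_mm, e$truth$true_x_mm[1:4], tolerance = 0.05)

  expect_error(fixes_from_scan_series(e$traces[1:2], exp$baseline),
               class = "mrbscan_insufficient_data")
})

test_that("t2 convention shifts the trough position by the geometric offset", {
  cfg <- quick_config()
  exp <- generate_experiment(cfg)
  e <- exp$experiments[[1]]
  f_tr <- fixes_from_scan_series(e$traces, exp$baseline, method = "trough")
  f_t2 <- fixes_from_scan_series(e$traces, exp$baseline, method = "t2",
                                 t2_offset = 1.25)
  expect_equal(f_t2$x_boundary_mm, f_tr$x_boundary_mm - 1.25)
})
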