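test_that("conductivity law: zero input, linearity, hand-summed KCl value", {
  sp <- kcl_species()
  expect_equal(conductivity_from_species(c(0, 0), sp), 0)

  set.seed(11)
  c1 <- runif(2, 0, 5)
  expect_equal(conductivity_from_species(2 * c1, sp),
               2 * conductivity_from_species(c1, sp))

  # independent scalar arithmetic for 1 mol/m^3 KCl
  F_const <- 96485.33212
  by_hand <- F_const * (7.62e-8 * 1 + 7.91e-8 * 1)
  expect_equal(conductivity_from_species(c(1, 1), sp), by_hand)

  # named concentrations are matched by species name
  expect_equal(conductivity_from_species(c("Cl-" = 1, "K+" = 0), sp),
               F_const * 7.91e-8)

  expect_error(conductivity_from_species(c(-1, 1), sp),
               class = "mrbscan_domain_error")
  expect_error(conductivity_from_species(numeric(0), list()),
               class = "mrbscan_config_error")
})

test_that("linear boundary profile matches pointwise two-point interpolation", {
  st <- boundary_state(sigma1 = 0.4, sigma2 = 1.1)
  grid <- seq(0, 24, by = 0.25)
  p <- linear_boundary_profile(st, x1 = 8, x2 = 12, grid = grid)

  expect_equal(p$sigma[grid == 10], (0.4 + 1.1) / 2)  # midpoint
  expect_true(all(p$sigma[grid <= 8] == 0.4))
  expect_true(all(p$sigma[grid >= 12] == 1.1))

  # brute-force pointwise oracle
  oracle <- vapply(grid, function(x) {
    if (x <= 8) 0.4 else if (x >= 12) 1.1 else 0.4 + (1.1 - 0.4) * (x - 8) / 4
  }, 0)
  expect_equal(p$sigma, oracle)

  # sigma1 == sigma2 is constant
  stc <- boundary_state(sigma1 = 0.7, sigma2 = 0.7)
  expect_equal(unique(linear_boundary_profile(stc, 5, 6, grid)$sigma), 0.7)

  expect_error(linear_boundary_profile(st, 12, 8, grid),
               class = "mrbscan_domain_error")
})

test_that("erf concentration front has the right midpoint, tails and erf(1) value", {
  st <- boundary_state(U = 0.3, D = 5e-10, c0 = 0.25)
  t <- 7
  xb <- st$U * t
  expect_equal(erf_front_concentration(xb, t, st), st$c0)
  expect_equal(erf_front_concentration(xb + 100, t, st), 0, tolerance = 1e-12)
  expect_equal(erf_front_concentration(xb - 100, t, st), 2 * st$c0,
               tolerance = 1e-12)

  # quadrature oracle for erf(1): 2/sqrt(pi) * int_0^1 exp(-u^2) du
  erf1 <- 2 / sqrt(pi) * integrate(function(u) exp(-u^2), 0, 1,
                                   rel.tol = 1e-12)$value
  ell <- 2 * sqrt(st$D * t * 60) * 1000   # diffusion length, mm
  expect_equal(erf_front_concentration(xb + ell, t, st), st$c0 * (1 - erf1),
               tolerance = 1e-10)

  # monotone non-increasing in x
  x <- seq(-5, 15, by = 0.05)
  expect_true(all(diff(erf_front_concentration(x, t, st)) <= 0))

  expect_error(erf_front_concentration(1, 0, st), class = "mrbscan_domain_error")
})

test_that("erf conductivity profile: midpoint, asymptotes, pointwise oracle, positivity", {
  st <- boundary_state(sigma1 = 0.5, sigma2 = 1.0, U = 0.4, D = 5e-10)
  t <- 9
  grid <- seq(0, 24, by = 0.02)
  p <- erf_conductivity_profile(grid, t, st)
  xb <- st$U * t

  i_mid <- which.min(abs(grid - xb))
  expect_equal(p$sigma[i_mid], (st$sigma1 + st$sigma2) / 2, tolerance = 1e-3)

  # asymptote invariant at 6 diffusion lengths
  ell <- 2 * sqrt(st$D * t * 60) * 1000
  behind <- grid <= xb - 6 * ell
  ahead <- grid >= xb + 6 * ell
  expect_true(all(abs(p$sigma[behind] - st$sigma1) <=
                    1e-9 * abs(st$sigma2 - st$sigma1)))
  expect_true(all(abs(p$sigma[ahead] - st$sigma2) <=
                    1e-9 * abs(st$sigma2 - st$sigma1)))

  # brute-force pointwise scalar oracle (erf via quadrature-backed pnorm is
  # the implementation's primitive; the oracle recomputes the full formula)
  oracle <- vapply(grid, function(x) {
    xi <- (x - xb) / ell
    st$sigma1 + (st$sigma2 - st$sigma1) / 2 * (1 + (2 * pnorm(xi * sqrt(2)) - 1))
  }, 0)
  expect_equal(p$sigma, oracle, tolerance = 1e-12)

  # constant profile when sigma1 == sigma2
  stc <- boundary_state(sigma1 = 0.8, sigma2 = 0.8, U = 0.4)
  expect_equal(unique(erf_conductivity_profile(grid, t, stc)$sigma), 0.8)

  # a depletion trough deeper than the profile floor is rejected
  stbad <- boundary_state(sigma1 = 0.5, sigma2 = 1.0, U = 0.4,
                          depletion_amp = 0.9)
  expect_error(erf_conductivity_profile(grid, t, stbad),
               class = "mrbscan_domain_error")
})

test_that("delta-window scan response resamples the profile along the scan path", {
  st <- boundary_state(sigma1 = 0.5, sigma2 = 1.0, U = 0.3,
                       depletion_amp = 0.4, depletion_width = 0.3)
  grid <- seq(0, 24, by = 0.01)
  prof <- erf_conductivity_profile(grid, 8, st)
  tr <- scan_response(prof, electrode_window("delta"), scan_speed = 1,
                      sample_rate = 40)
  centers <- tr$x_start + tr$scan_speed * tr$t
  # independent evaluation of the closed-form profile at the scan path
  ell <- 2 * sqrt(st$D * 8 * 60) * 1000
  direct <- st$sigma1 + (st$sigma2 - st$sigma1) / 2 *
    (1 + (2 * pnorm((centers - st$U * 8) / ell * sqrt(2)) - 1)) -
    st$depletion_amp * exp(-0.5 * ((centers - st$U * 8) / st$depletion_width)^2)
  # dominated by linear interpolation of the curved trough on the 10 um grid
  expect_equal(tr$signal, direct, tolerance = 1e-3)
})

test_that("unipolar windows preserve constants and match the convolution oracle", {
  win <- electrode_window("unipolar_trapezoid", dx = 0.05)
  expect_equal(sum(win$weights), 1)

  grid <- seq(0, 24, by = 0.05)
  const <- spatial_profile(grid, rep(0.9, length(grid)), 5)
  trc <- scan_response(const, win, sample_rate = 10)
  expect_equal(trc$signal, rep(0.9, length(trc$signal)))

  # step profile: brute-force double-loop convolution oracle
  st <- boundary_state(sigma1 = 0.5, sigma2 = 1.0)
  step <- linear_boundary_profile(st, 11.9, 12.1, grid, time = 5)
  tr <- scan_response(step, win, sample_rate = 10)
  centers <- tr$x_start + tr$scan_speed * tr$t
  expect_equal(tr$signal,
               oracle_window_transform(grid, step$sigma, win, centers),
               tolerance = 1e-10)
  # response to an upward step through a non-negative window is monotone
  expect_true(all(diff(tr$signal) >= -1e-12))
})

test_that("unipolar window output is bounded by the profile range", {
  win <- electrode_window("unipolar_trapezoid", dx = 0.05)
  grid <- seq(0, 24, by = 0.05)
  for (seed in 1:5) {
    set.seed(seed)
    # smooth random positive profile
    sig <- 1 + 0.5 * sin(seq(0, 6 * pi, length.out = length(grid)) + runif(1, 0, 2 * pi)) +
      0.2 * runif(1)
    prof <- spatial_profile(grid, sig, 1)
    tr <- scan_response(prof, win, sample_rate = 5)
    expect_true(all(tr$signal >= min(sig) - 1e-12))
    expect_true(all(tr$signal <= max(sig) + 1e-12))
  }
})

test_that("bipolar window has zero net weight and rejects oversized windows", {
  win <- electrode_window("bipolar_differential", dx = 0.05)
  expect_equal(sum(win$weights), 0, tolerance = 1e-12)
  # zero response to a constant profile
  grid <- seq(0, 24, by = 0.05)
  const <- spatial_profile(grid, rep(1.3, length(grid)), 2)
  expect_equal(max(abs(scan_response(const, win, sample_rate = 5)$signal)), 0,
               tolerance = 1e-12)

  big <- electrode_window("unipolar_trapezoid", actuator_width = 12,
                          pickup_width = 12, gap = 4, dx = 0.1)
  expect_error(scan_response(const, big, sample_rate = 5),
               class = "mrbscan_config_error")
})
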