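test_that("sigmoid rate is bounded, monotone and centred at sigma0", {
  spec <- sigmoid_spec()
  expect_equal(sigmoid_rate(0, spec), spec$sigma0)
  expect_equal(spec$sigma0, 0.5)
  expect_equal(sigmoid_rate(1e4, spec), 1)
  expect_equal(sigmoid_rate(-1e4, spec), 0)
  v <- seq(-20, 20, by = 0.5)
  r <- sigmoid_rate(v, spec)
  expect_true(all(diff(r) > 0))
  expect_true(all(r >= 0 & r <= 1))
  expect_error(sigmoid_rate(NaN, spec), "non-finite")
})

test_that("precision is the exponential of negative self-inhibition", {
  expect_equal(precision_of(0), 1)
  expect_equal(precision_of(-log(2)), 2)
  pis <- c(0.1, 1, 2, 7.39)
  expect_equal(precision_of(precision_inverse(pis)), pis)
  g <- seq(-3, 3, by = 0.5)
  expect_true(all(diff(precision_of(g)) < 0))   # more inhibition, less precision
  expect_true(all(exp(g) > 0))
  expect_error(precision_inverse(-1), "positive")
})

test_that("effective gamma reduces to the condition baseline at baseline rates", {
  spec <- sigmoid_spec()
  mod <- c(2, 1)
  expect_equal(effective_gamma(0.3, 0.5, "valid", numeric(0), numeric(0)), 0.3)
  expect_equal(effective_gamma(0.3, 0.5, "invalid", numeric(0), numeric(0)), 0.8)
  base_rates <- rep(spec$sigma0, 2)
  expect_equal(effective_gamma(0.3, 0.5, "valid", mod, base_rates, spec), 0.3)
  expect_equal(effective_gamma(0.3, 0.5, "invalid", mod, base_rates, spec), 0.8)
  # active afferents with positive modulation suppress self-inhibition
  expect_lt(effective_gamma(0.3, 0, "valid", mod, c(0.9, 0.8), spec), 0.3)
  expect_error(effective_gamma(0, 0, "valid", mod, 0.5), "same length")
})

test_that("effective gamma is linear in each afferent rate", {
  spec <- sigmoid_spec()
  mod <- c(1.5, 0.7, 0.2)
  base <- rep(spec$sigma0, 3)
  for (k in 1:3) {
    rs <- seq(0, 1, length.out = 5)
    vals <- vapply(rs, function(r) {
      rates <- base
      rates[k] <- r
      effective_gamma(0.1, 0, "valid", mod, rates, spec)
    }, numeric(1))
    slopes <- diff(vals) / diff(rs)
    expect_equal(max(slopes) - min(slopes), 0, tolerance = 1e-12)
    expect_equal(slopes[1], -1.5 * mod[k], tolerance = 1e-12)
  }
})

test_that("population kinetics match the analytic alpha-kernel response", {
  kappa <- 0.25
  expect_equal(population_derivative(c(0, 0), 0, kappa), c(dv = 0, di = 0))
  expect_error(population_derivative(c(0, 0), 0, -1), "kappa")

  # steady state under constant input: v -> u / kappa
  integrate_pop <- function(u_of_t, t_end, dt) {
    st <- c(0, 0)
    steps <- ceiling(t_end / dt)
    out <- numeric(steps)
    for (k in seq_len(steps)) {
      t <- (k - 1) * dt
      f <- function(s, tt) population_derivative(s, u_of_t(tt), kappa)
      k1 <- f(st, t); k2 <- f(st + dt / 2 * k1, t + dt / 2)
      k3 <- f(st + dt / 2 * k2, t + dt / 2); k4 <- f(st + dt * k3, t + dt)
      st <- st + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      out[k] <- st[1]
    }
    out
  }
  v <- integrate_pop(function(t) 2, 200, 0.5)
  expect_equal(v[length(v)], 2 / kappa, tolerance = 1e-6)

  # impulse response kappa * t * exp(-kappa t), peak at t = 1/kappa;
  # integration error at least halves under step halving
  tt_end <- 60
  analytic <- function(t) kappa * t * exp(-kappa * t)
  err_at <- function(dt) {
    st <- c(0, 1 * kappa)  # impulse: i jumps to kappa * area
    steps <- ceiling(tt_end / dt)
    errs <- numeric(steps)
    for (k in seq_len(steps)) {
      t <- (k - 1) * dt
      f <- function(s) population_derivative(s, 0, kappa)
      k1 <- f(st); k2 <- f(st + dt / 2 * k1)
      k3 <- f(st + dt / 2 * k2); k4 <- f(st + dt * k3)
      st <- st + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      errs[k] <- abs(st[1] - analytic(k * dt))
    }
    max(errs)
  }
  e1 <- err_at(0.5); e2 <- err_at(0.25)
  expect_lt(e2, e1 / 2)
  peak_t <- 1 / kappa
  expect_equal(analytic(peak_t), max(analytic(seq(0.1, 40, by = 0.01))),
               tolerance = 1e-6)
})

test_that("error units converge to precision-weighted prediction error", {
  tr <- error_unit_trajectory(error_unit(mu = 1, prediction = 1, gamma = 0))
  expect_equal(tr$xi[length(tr$xi)], 0, tolerance = 1e-9)

  tr <- error_unit_trajectory(error_unit(mu = 1, prediction = 0, gamma = 0))
  expect_equal(tr$xi[length(tr$xi)], 1, tolerance = 1e-8)

  # gamma = -ln 2 doubles the precision: xi -> 2 * 0.5 = 1
  tr <- error_unit_trajectory(error_unit(mu = 0.5, prediction = 0,
                                         gamma = -log(2)))
  expect_equal(tr$xi[length(tr$xi)], 1, tolerance = 1e-8)
  expect_equal(tr$steady_state, 1)

  expect_error(
    error_unit_trajectory(error_unit(1, 0, gamma = 1), dt = 2),
    "unstable")
})

test_that("steady-state precision identity holds over a parameter grid", {
  for (gamma in seq(-2, 2, by = 1)) {
    for (drive in seq(-1, 1, by = 0.5)) {
      tr <- error_unit_trajectory(error_unit(mu = drive, prediction = 0,
                                             gamma = gamma))
      expect_lt(abs(tr$xi[length(tr$xi)] - precision_of(gamma) * drive), 1e-6)
    }
  }
})

test_that("source intrinsics validate sign structure and the gamma contract", {
  si <- source_intrinsics()
  expect_equal(si$intrinsic_coupling["sp", "sp"], 0)
  expect_true(all(si$kappa > 0))
  bad <- default_intrinsic_coupling()
  bad["sp", "sp"] <- 1
  expect_error(source_intrinsics(intrinsic_coupling = bad), "gamma")
  bad2 <- default_intrinsic_coupling()
  bad2["sp", "ii"] <- 2   # interneuron afferents must inhibit
  expect_error(source_intrinsics(intrinsic_coupling = bad2), "inhibitory")
})
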