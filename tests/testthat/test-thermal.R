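test_that("closed-form solution honours its limits", {
  p <- thermal_params(Pin = 30, Rcond = 0.5, Tenv = 22, T0 = 22)
  expect_equal(solve_temperature(p, 0), 22)
  # asymptote A/B = (Pin + Rcond Tenv)/Rcond = 82 degC
  expect_equal(solve_temperature(p, 1e7), (30 + 0.5 * 22) / 0.5,
               tolerance = 1e-9)
  # loss-free limit: linear heating, dT = Pin t/(m0 cs)
  p0 <- thermal_params(Pin = 10, Rcond = 0, T0 = 22, m0 = 0.02, cs = 4186)
  expect_equal(solve_temperature(p0, 60) - 22, 600 / 83.72, tolerance = 1e-9)
  # heating from T0 = Tenv is strictly increasing
  tt <- seq(0, 600, 5)
  expect_true(all(diff(solve_temperature(p, tt)) > 0))
})

test_that("ODE integration agrees with the closed form at zero mass loss", {
  # parameter grid: 100 combinations
  grid <- expand.grid(Pin = c(1, 5, 30, 100, 900),
                      Rcond = c(0.05, 0.2, 0.5, 1),
                      m0 = c(0.02, 0.05),
                      T0 = c(15, 25))
  tt <- seq(0, 600, 20)
  worst <- 0
  for (i in seq_len(nrow(grid))) {
    p <- thermal_params(Pin = grid$Pin[i], Rcond = grid$Rcond[i],
                        Tenv = 22, T0 = grid$T0[i], m0 = grid$m0[i])
    closed <- solve_temperature(p, tt)
    ode <- simulate_thermal_ode(p, tt)
    worst <- max(worst, max(abs(ode - closed) / pmax(abs(closed), 1)))
  }
  expect_lt(worst, 1e-6)
})

test_that("equilibrium and cooling behave physically", {
  p <- thermal_params(Pin = 0, Rcond = 0.5, Tenv = 22, T0 = 22)
  tt <- seq(0, 600, 5)
  expect_equal(simulate_thermal_ode(p, tt), rep(22, length(tt)),
               tolerance = 1e-9)
  # decay relaxes monotonically toward Tenv
  hot <- thermal_params(Pin = 0, Rcond = 0.5, Tenv = 22, T0 = 60)
  temps <- solve_temperature(hot, tt)
  expect_true(all(diff(temps) < 0))
  expect_true(all(temps >= 22))
})

test_that("mass loss raises the final temperature and is bounded", {
  base <- thermal_params(Pin = 100, Rcond = 0.5, Tenv = 22, T0 = 22,
                         m0 = 0.05)
  loss <- thermal_params(Pin = 100, Rcond = 0.5, Tenv = 22, T0 = 22,
                         m0 = 0.05, mass_loss_rate = 2e-5)
  tt <- seq(0, 600, 10)
  expect_gt(simulate_thermal_ode(loss, tt)[length(tt)],
            simulate_thermal_ode(base, tt)[length(tt)])
  # closed form refuses mass loss; ODE refuses vanishing mass
  expect_error(solve_temperature(loss, tt), "constant mass")
  gone <- thermal_params(Pin = 100, m0 = 0.01, mass_loss_rate = 1e-4)
  expect_error(simulate_thermal_ode(gone, seq(0, 600, 10)), "mass")
})

test_that("temperature series generator covers both phases and is seeded", {
  truth <- thermal_params(Pin = 30, Rcond = 0.5, Tenv = 22, T0 = 22)
  tt <- seq(0, 480, 5)
  s1 <- make_temperature_series(truth, tt, noise_sd = 0.1, seed = 3,
                                activation_time = 180)
  s2 <- make_temperature_series(truth, tt, noise_sd = 0.1, seed = 3,
                                activation_time = 180)
  expect_identical(s1$temp_C, s2$temp_C)
  expect_setequal(unique(s1$phase), c("heating", "decay"))
  expect_error(make_temperature_series(truth, tt, noise_sd = -1), "noise_sd")
  # noiseless series matches the closed form segment-wise
  s0 <- make_temperature_series(truth, tt, noise_sd = 0, seed = 1,
                                activation_time = 180)
  heat <- s0$time_s <= 180
  expect_equal(s0$temp_C[heat], solve_temperature(truth, s0$time_s[heat]))
})

test_that("noiseless two-phase data recover the parameters exactly", {
  truth <- thermal_params(Pin = 30, Rcond = 0.5, Tenv = 22, T0 = 22)
  tt <- seq(0, 480, 5)
  s <- make_temperature_series(truth, tt, noise_sd = 0, seed = 1,
                               activation_time = 180)
  fit <- fit_thermal(s, m0 = 0.02, cs = 4186, Tenv = 22)
  expect_equal(fit$Pin_hat, 30, tolerance = 1e-6)
  expect_equal(fit$Rcond_hat, 0.5, tolerance = 1e-6)
  expect_lt(fit$residual_rms[["heating"]], 1e-8)
})

test_that("parameters are recovered within 10% under measurement noise", {
  # heating 180 s + decay 300 s, 5 s sampling, 0.1 K noise, 200 replicates
  truth <- thermal_params(Pin = 30, Rcond = 0.5, Tenv = 22, T0 = 22)
  tt <- seq(0, 480, 5)
  ok <- logical(200)
  for (r in seq_len(200)) {
    s <- make_temperature_series(truth, tt, noise_sd = 0.1, seed = 5000 + r,
                                 activation_time = 180)
    fit <- fit_thermal(s, m0 = 0.02, cs = 4186, Tenv = 22)
    ok[r] <- abs(fit$Pin_hat - 30) / 30 < 0.1 &&
      abs(fit$Rcond_hat - 0.5) / 0.5 < 0.1
  }
  expect_gte(mean(ok), 0.95)
})

test_that("loss-free data trigger the linear heating fallback", {
  truth <- thermal_params(Pin = 10, Rcond = 0, Tenv = 22, T0 = 22)
  tt <- seq(0, 480, 5)
  s <- make_temperature_series(truth, tt, noise_sd = 0, seed = 1,
                               activation_time = 180)
  fit <- fit_thermal(s, m0 = 0.02, cs = 4186, Tenv = 22)
  expect_true("linear_fallback" %in% fit$flags)
  expect_equal(fit$Rcond_hat, 0)
  expect_equal(fit$Pin_hat, 10, tolerance = 1e-6)
})

test_that("transferred energy is power times activation time per mass", {
  fit <- structure(list(Pin_hat = 10), class = "thermal_fit")
  expect_equal(transferred_energy(fit, 180, 0.02)$energy_per_mass, 9e4)
  expect_equal(transferred_energy(fit, 0, 0.02)$energy_per_mass, 0)
  e1 <- transferred_energy(fit, 300, 0.02)$energy_per_mass
  e2 <- transferred_energy(fit, 600, 0.02)$energy_per_mass
  expect_equal(e2, 2 * e1)
})

test_that("fits refuse series with too few samples per phase", {
  truth <- thermal_params()
  s <- make_temperature_series(truth, seq(0, 195, 5), noise_sd = 0,
                               seed = 1, activation_time = 180)
  expect_error(fit_thermal(s), "4 samples")
})
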