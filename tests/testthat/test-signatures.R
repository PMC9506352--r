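# helper: ca_trace from explicit values (bypasses the generator on purpose)
ca_from_values <- function(times, ca, well = "w1") {
  tr <- new_ca_trace_for_test(times, 1e-7)
  tr$ca <- ca
  tr$well_id <- well
  tr
}

test_that("baseline is the mean over the 60 s before the epoch", {
  tt <- seq(0, 600, 5)
  ep <- epoch(100, 600)
  flat <- ca_from_values(tt, rep(1e-7, length(tt)))
  expect_equal(trace_baseline(flat, ep), 1e-7)
  # linear ramp 1e-7 -> 2e-7 across the 60 s window [40, 100)
  ca <- rep(1e-7, length(tt))
  ramp <- tt >= 40 & tt < 100
  ca[ramp] <- 1e-7 + (2e-7 - 1e-7) * (tt[ramp] - 40) / 60
  tr <- ca_from_values(tt, ca)
  expect_equal(trace_baseline(tr, ep), 1.5e-7, tolerance = 0.05)
  # only pre-stimulus samples enter
  ca2 <- ca
  ca2[tt >= 100] <- 1e-3
  expect_equal(trace_baseline(ca_from_values(tt, ca2), ep),
               trace_baseline(tr, ep))
})

test_that("peak returns the maximum with earliest-time tie-break", {
  tt <- seq(0, 600, 5)
  ep <- epoch(100, 600)
  flat <- ca_from_values(tt, rep(1e-7, length(tt)))
  pk <- trace_peak(flat, ep)
  expect_equal(pk$peak_ca, 1e-7)
  expect_equal(pk$peak_time, 100)  # tie -> epoch start
  ca <- rep(1e-7, length(tt))
  ca[tt == 200] <- 5e-7
  ca[tt == 400] <- 5e-7
  expect_equal(trace_peak(ca_from_values(tt, ca), ep)$peak_time, 200)
})

test_that("peak time of a transient matches the closed-form argmax", {
  k <- ca_kinetics(baseline = 1e-7, transient_amplitude = 5e-7,
                   rise_tau = 10, decay_tau = 120, stimulus_time = 100)
  tr <- make_ca_trajectory(k, seq(0, 1800, 5))
  pk <- trace_peak(tr, epoch(100, 1800))
  t_star <- 100 + log(12) * 10 * 120 / 110
  expect_lte(abs(pk$peak_time - t_star), 5)  # within one sampling interval
})

test_that("onset delay detects a step one sample after the injection", {
  tt <- seq(0, 600, 5)
  set.seed(2)
  ca <- 1e-7 + rnorm(length(tt), 0, 1e-9)
  ca[tt >= 100] <- 5e-7
  od <- onset_delay(ca_from_values(tt, ca), epoch(100, 600))
  expect_equal(od$onset_delay, 5)
  expect_false(od$censored)
})

test_that("non-responding traces are censored at the window length", {
  tt <- seq(0, 600, 5)
  set.seed(3)
  ca <- 1e-7 + rnorm(length(tt), 0, 1e-9)
  od <- onset_delay(ca_from_values(tt, ca), epoch(100, 600))
  expect_true(od$censored)
  expect_equal(od$onset_delay, 500)
})

test_that("zero pre-stimulus variance falls back to a relative threshold", {
  tt <- seq(0, 600, 5)
  ca <- rep(1e-7, length(tt))
  ca[tt >= 300] <- 2e-7
  od <- onset_delay(ca_from_values(tt, ca), epoch(100, 600))
  expect_true(od$relative_threshold)
  expect_equal(od$onset_delay, 200)
})

test_that("slow-onset crossing time matches the analytic solution", {
  # sustained rise: crossing of baseline + 3 sd at
  # dt = -tau * log(1 - thr/S)
  tt <- seq(0, 1800, 5)
  base <- 1e-7
  S <- 3e-7
  tau <- 300
  set.seed(9)
  noise <- rnorm(length(tt), 0, 5e-10)
  ca <- base + noise
  post <- tt >= 100
  ca[post] <- base + S * (1 - exp(-(tt[post] - 100) / tau)) + noise[post]
  tr <- ca_from_values(tt, ca)
  od <- onset_delay(tr, epoch(100, 1800))
  sd_pre <- sd(ca[tt >= 40 & tt < 100])
  base_est <- mean(ca[tt >= 40 & tt < 100])
  dt_analytic <- -tau * log(1 - (base_est + 3 * sd_pre - base) / S)
  expect_lte(abs(od$onset_delay - dt_analytic), 5)
})

test_that("rise slope is exact on a linear ramp and zero on flat traces", {
  tt <- seq(0, 600, 5)
  b <- 2e-9
  ca <- rep(1e-7, length(tt))
  ca[tt >= 100] <- 1e-7 + b * (tt[tt >= 100] - 100)
  tr <- ca_from_values(tt, ca)
  expect_equal(rise_slope(tr, epoch(100, 600)), b, tolerance = 1e-9)
  flat <- ca_from_values(tt, rep(1e-7, length(tt)))
  expect_equal(rise_slope(flat, epoch(100, 600)), 0)
})

test_that("noisy linear rise gives an unbiased slope with OLS sampling variance", {
  # n = 20 samples on the rise, known sigma: check against OLS theory
  tt <- seq(0, 300, 5)
  b <- 5e-9
  sigma <- 2e-9
  n_rep <- 300
  slopes <- numeric(n_rep)
  rise_t <- tt[tt >= 100 & tt <= 195]   # 20 samples
  for (r in seq_len(n_rep)) {
    set.seed(1000 + r)
    ca <- rep(1e-7, length(tt))
    ca[tt >= 100] <- 1e-7 + b * (tt[tt >= 100] - 100)
    ca <- ca + c(rep(0, sum(tt < 100)), rnorm(sum(tt >= 100), 0, sigma))
    # fix epoch end at the last rise sample so the OLS window is n = 20
    i <- tt >= 100 & tt <= 195
    slopes[r] <- unname(coef(lm(ca[i] ~ tt[i]))[2])
  }
  var_theory <- sigma^2 / sum((rise_t - mean(rise_t))^2)
  expect_equal(mean(slopes), b, tolerance = 3 * sqrt(var_theory / n_rep) / b)
  expect_equal(var(slopes), var_theory, tolerance = 0.2)
})

test_that("trapezoid integral matches simple closed forms", {
  tt <- seq(0, 1900, 5)
  const <- ca_from_values(tt, rep(1e-7, length(tt)))
  expect_equal(integrate_ca(const, epoch(100, 1900), window = 1800), 1.8e-4)
  # triangular bump height h width w on zero baseline -> h w / 2
  ca <- rep(0, length(tt))
  up <- tt >= 100 & tt <= 200
  down <- tt > 200 & tt <= 300
  ca[up] <- 4e-7 * (tt[up] - 100) / 100
  ca[down] <- 4e-7 * (300 - tt[down]) / 100
  tri <- ca_from_values(tt, ca)
  expect_equal(integrate_ca(tri, epoch(100, 1900), window = 1800),
               4e-7 * 200 / 2, tolerance = 1e-12)
})

test_that("double-exponential AUC matches the closed form within 0.1%", {
  k <- ca_kinetics(baseline = 1e-7, transient_amplitude = 5e-7,
                   rise_tau = 10, decay_tau = 120, stimulus_time = 100)
  tr <- make_ca_trajectory(k, seq(0, 2000, 5))
  got <- integrate_ca(tr, epoch(100, 2000), window = 1800)
  expect_equal(got, kinetics_auc(k, 1800), tolerance = 1e-3)
})

test_that("AUC is additive over adjacent windows on a shared grid", {
  k <- ca_kinetics(baseline = 1e-7, transient_amplitude = 3e-7,
                   sustained_amplitude = 1e-7)
  tr <- make_ca_trajectory(k, seq(0, 2000, 5))
  whole <- integrate_ca(tr, epoch(100, 1900), window = 1800)
  first <- integrate_ca(tr, epoch(100, 1000), window = 900)
  second <- integrate_ca(tr, epoch(1000, 1900), window = 900)
  expect_equal(first + second, whole, tolerance = 1e-12)
})

test_that("metrics scale equivariantly under trace rescaling", {
  k <- ca_kinetics(baseline = 1e-7, transient_amplitude = 4e-7)
  tr <- make_ca_trajectory(k, seq(0, 2000, 5))
  # add small noise so the onset threshold is well defined
  set.seed(5)
  tr$ca <- tr$ca + rnorm(length(tr$ca), 0, 5e-10)
  scaled <- tr
  scaled$ca <- tr$ca * 3
  ep <- epoch(100, 1900)
  m1 <- signature_metrics(tr, ep, window = 1800)
  m3 <- signature_metrics(scaled, ep, window = 1800)
  expect_equal(m3$peak_ca, 3 * m1$peak_ca)
  expect_equal(m3$rise_slope, 3 * m1$rise_slope, tolerance = 1e-9)
  expect_equal(m3$auc, 3 * m1$auc)
  expect_equal(m3$peak_time_s, m1$peak_time_s)
  expect_equal(m3$onset_delay_s, m1$onset_delay_s)
})

test_that("two-dose analysis builds per-dose epochs with local baselines", {
  # identical responses to both doses -> equal metrics
  tt <- seq(0, 4000, 5)
  base <- 1e-7
  set.seed(6)
  noise <- rnorm(length(tt), 0, 5e-10)
  bump <- function(t0) {
    d <- tt - t0
    out <- rep(0, length(tt))
    p <- d >= 0
    out[p] <- 4e-7 * (exp(-d[p] / 120) - exp(-d[p] / 10)) /
      ((120 / 10)^(-10 / 110) - (120 / 10)^(-120 / 110))
    out
  }
  ca <- base + bump(100) + bump(2100) + noise
  tr <- ca_from_values(tt, ca)
  m <- two_dose_analysis(tr, c(100, 2100), window = 1800)
  expect_equal(nrow(m), 2)
  expect_equal(m$peak_ca[2], m$peak_ca[1], tolerance = 0.02)
  expect_equal(m$auc[2], m$auc[1], tolerance = 0.02)
  # doubled second response -> peak ratio ~ 2 (above local baseline)
  ca2 <- base + bump(100) + 2 * bump(2100) + noise
  m2 <- two_dose_analysis(ca_from_values(tt, ca2), c(100, 2100),
                          window = 1800)
  expect_equal((m2$peak_ca[2] - m2$baseline_ca[2]) /
                 (m2$peak_ca[1] - m2$baseline_ca[1]), 2, tolerance = 0.05)
  # epochs truncate at the next dose: no overlap even if window is longer
  m3 <- two_dose_analysis(tr, c(100, 700), window = 1800)
  expect_equal(nrow(m3), 2)
})
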