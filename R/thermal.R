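#' Parameters of the zero-dimensional water heating model
#'
#' During plasma activation the water obeys
#' \deqn{\frac{d}{dt}\big(m(t) c_s T(t)\big) = P_{in} - R_{cond}\,(T - T_{env})}
#' where `Pin` is the effective power delivered by the source, `Rcond` the
#' thermal conductance towards the environment and `Tenv` the environmental
#' temperature. For constant mass the solution is
#' \deqn{T(t) = T_0 e^{-Bt} + \frac{A}{B}(1 - e^{-Bt}),\quad
#'   A = \frac{P_{in} + R_{cond} T_{env}}{m_0 c_s},\quad
#'   B = \frac{R_{cond}}{m_0 c_s}.}
#' Temperatures are handled in deg C throughout: only differences enter the
#' model, so the unit offset cancels.
#'
#' @param Pin Effective power into the water (W).
#' @param Rcond Thermal conductance to the environment (W/K).
#' @param Tenv Environmental temperature (deg C).
#' @param T0 Initial water temperature (deg C).
#' @param m0 Initial water mass (kg). 0.020 kg for 20 mL DBD aliquots,
#'   0.050 kg for the 50 mL torch beaker.
#' @param cs Specific heat of water (J/(kg K)).
#' @param mass_loss_rate Linear mass-loss rate (kg/s), torch ejection; the
#'   closed form requires 0.
#' @return An object of class `thermal_params`.
#' @export
thermal_params <- function(Pin = 30, Rcond = 0.5, Tenv = 22, T0 = 22,
                           m0 = 0.02, cs = 4186, mass_loss_rate = 0) {
  stopifnot(Pin >= 0, Rcond >= 0, m0 > 0, cs > 0, mass_loss_rate >= 0)
  structure(
    list(Pin = Pin, Rcond = Rcond, Tenv = Tenv, T0 = T0, m0 = m0, cs = cs,
         mass_loss_rate = mass_loss_rate),
    class = "thermal_params"
  )
}

#' Closed-form temperature during plasma activation
#'
#' Evaluates the constant-mass solution of the heat-transport equation (see
#' [thermal_params()]); the loss-free limit B = 0 reduces analytically to the
#' linear heating T0 + Pin t / (m0 cs).
#'
#' @param params [thermal_params()] with `mass_loss_rate = 0`.
#' @param times Times (s).
#' @return Temperatures (deg C) at `times`.
#' @export
solve_temperature <- function(params, times) {
  stopifnot(inherits(params, "thermal_params"))
  if (params$mass_loss_rate != 0) {
    stop("closed form requires constant mass; use simulate_thermal_ode()",
         call. = FALSE)
  }
  A <- (params$Pin + params$Rcond * params$Tenv) / (params$m0 * params$cs)
  B <- params$Rcond / (params$m0 * params$cs)
  if (B == 0) {
    params$T0 + A * times
  } else {
    params$T0 * exp(-B * times) + (A / B) * (1 - exp(-B * times))
  }
}

#' Numerical integration of the heat-transport ODE
#'
#' Independent numerical solution of
#' d(m(t) cs T)/dt = Pin - Rcond (T - Tenv) with m(t) = m0 - mass_loss_rate t,
#' via `deSolve::ode` (lsoda). For zero mass loss it agrees with the closed
#' form to relative tolerance 1e-6 and serves as its oracle; with mass loss
#' it is the only valid path.
#'
#' @param params [thermal_params()].
#' @param times Times (s), starting at 0.
#' @return Temperatures (deg C) at `times`.
#' @export
simulate_thermal_ode <- function(params, times) {
  stopifnot(inherits(params, "thermal_params"))
  if (times[1L] != 0) stop("times must start at 0", call. = FALSE)
  m_end <- params$m0 - params$mass_loss_rate * max(times)
  if (m_end <= 0) {
    stop("water mass reaches zero within the requested interval",
         call. = FALSE)
  }
  deriv <- function(t, state, p) {
    m <- p$m0 - p$mass_loss_rate * t
    # d(m cs T)/dt = Pin - Rcond (T - Tenv)  =>
    # T' = (Pin - Rcond (T - Tenv) + cs * mass_loss_rate * T) / (m cs)
    dT <- (p$Pin - p$Rcond * (state[1L] - p$Tenv) +
             p$cs * p$mass_loss_rate * state[1L]) / (m * p$cs)
    list(dT)
  }
  sol <- deSolve::ode(y = c(T = params$T0), times = times, func = deriv,
                      parms = params, rtol = 1e-9, atol = 1e-9)
  unname(sol[, "T"])
}

#' Simulate a noisy water-temperature measurement series
#'
#' Heating follows the closed-form solution with the true parameters up to
#' `activation_time`; after source switch-off the decay follows the same
#' form with Pin = 0 started from the switch-off temperature. i.i.d. Gaussian
#' measurement noise is added.
#'
#' @param truth [thermal_params()] (constant mass).
#' @param times Time grid (s) spanning both phases.
#' @param noise_sd Measurement noise sd (K), >= 0.
#' @param seed Integer seed.
#' @param activation_time Source-on duration (s).
#' @return A `temperature_series`: data.frame with `time_s`, `temp_C`,
#'   `phase` ("heating"/"decay") and attribute `activation_time`.
#' @export
make_temperature_series <- function(truth, times, noise_sd = 0.1, seed = 1L,
                                    activation_time = 180) {
  stopifnot(inherits(truth, "thermal_params"))
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  heating <- times <= activation_time
  temp <- numeric(length(times))
  temp[heating] <- solve_temperature(truth, times[heating])
  if (any(!heating)) {
    T_off <- solve_temperature(truth, activation_time)
    cool <- thermal_params(Pin = 0, Rcond = truth$Rcond, Tenv = truth$Tenv,
                           T0 = T_off, m0 = truth$m0, cs = truth$cs)
    temp[!heating] <- solve_temperature(cool, times[!heating] - activation_time)
  }
  if (noise_sd > 0) {
    old_seed <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                           envir = globalenv()))
    set.seed(seed)
    temp <- temp + stats::rnorm(length(temp), 0, noise_sd)
  }
  out <- data.frame(
    time_s = times, temp_C = temp,
    phase = ifelse(heating, "heating", "decay")
  )
  attr(out, "activation_time") <- activation_time
  class(out) <- c("temperature_series", "data.frame")
  out
}

#' Fit the heat-transport model to a two-phase temperature series
#'
#' Two-stage least squares, decoupling the loss parameter from the power:
#' \enumerate{
#'   \item Decay phase (Pin = 0): `T = Tenv + D exp(-B (t - t_off))` fitted by
#'     nonlinear least squares (Levenberg-Marquardt, log-linear start) giving
#'     B, hence Rcond = B m0 cs.
#'   \item Heating phase: with B fixed, `T = T0 exp(-B t) + C (1 - exp(-B t))`
#'     is linear in (T0, C); ordinary least squares gives C = A/B, hence
#'     Pin = A m0 cs - Rcond Tenv.
#' }
#' A non-positive or non-identifiable B falls back to a linear heating fit
#' (Rcond = 0, Pin from the slope) flagged `"linear_fallback"`.
#'
#' @param series A `temperature_series` (needs both phases, >= 4 samples
#'   each).
#' @param m0 Water mass (kg).
#' @param cs Specific heat (J/(kg K)).
#' @param Tenv Environmental temperature (deg C), treated as measured input.
#' @return An object of class `thermal_fit` with `Pin_hat`, `Rcond_hat`,
#'   `A_hat`, `B_hat`, per-phase residual RMS, and `flags`.
#' @export
fit_thermal <- function(series, m0 = 0.02, cs = 4186, Tenv = 22) {
  stopifnot(inherits(series, "data.frame"),
            all(c("time_s", "temp_C", "phase") %in% names(series)))
  heat <- series[series$phase == "heating", ]
  decay <- series[series$phase == "decay", ]
  if (nrow(heat) < 4L || nrow(decay) < 4L) {
    stop("need at least 4 samples in each phase", call. = FALSE)
  }
  t_off <- max(heat$time_s)
  flags <- character()

  # stage 1: decay -> B
  td <- decay$time_s - t_off
  dT <- decay$temp_C - Tenv
  B_hat <- NA_real_
  D_hat <- NA_real_
  if (all(dT > 0)) {
    lin <- stats::lm(log(dT) ~ td)
    B0 <- max(-unname(stats::coef(lin)[2L]), 1e-6)
    fit1 <- tryCatch(
      minpack.lm::nlsLM(
        temp_C ~ Tenv + D * exp(-B * td),
        data = data.frame(temp_C = decay$temp_C, td = td),
        start = list(D = max(dT[1L], 1e-3), B = B0),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
    if (!is.null(fit1)) {
      B_hat <- unname(stats::coef(fit1)["B"])
      D_hat <- unname(stats::coef(fit1)["D"])
    }
  }

  if (!is.finite(B_hat) || B_hat <= 0) {
    # degenerate loss-free data: linear heating fit
    flags <- c(flags, "linear_fallback")
    lf <- stats::lm(temp_C ~ time_s, data = heat)
    slope <- unname(stats::coef(lf)[2L])
    Pin_hat <- slope * m0 * cs
    A_hat <- slope
    fit <- list(
      Pin_hat = Pin_hat, Rcond_hat = 0, A_hat = A_hat, B_hat = 0,
      residual_rms = c(
        heating = sqrt(mean(stats::resid(lf)^2)),
        decay = NA_real_
      ),
      Tenv = Tenv, m0 = m0, cs = cs, t_off = t_off, flags = flags
    )
    class(fit) <- "thermal_fit"
    return(fit)
  }

  Rcond_hat <- B_hat * m0 * cs
  rms_decay <- sqrt(mean((decay$temp_C - (Tenv + D_hat * exp(-B_hat * td)))^2))

  # stage 2: heating, B fixed -> (T0, C) by OLS
  eb <- exp(-B_hat * heat$time_s)
  X <- cbind(eb = eb, gb = 1 - eb)
  fit2 <- stats::lm.fit(X, heat$temp_C)
  T0_hat <- unname(fit2$coefficients["eb"])
  C_hat <- unname(fit2$coefficients["gb"])  # = A/B
  A_hat <- C_hat * B_hat
  Pin_hat <- A_hat * m0 * cs - Rcond_hat * Tenv
  rms_heat <- sqrt(mean(fit2$residuals^2))

  fit <- list(
    Pin_hat = Pin_hat, Rcond_hat = Rcond_hat,
    A_hat = A_hat, B_hat = B_hat, T0_hat = T0_hat,
    residual_rms = c(heating = rms_heat, decay = rms_decay),
    Tenv = Tenv, m0 = m0, cs = cs, t_off = t_off, flags = flags
  )
  class(fit) <- "thermal_fit"
  fit
}

#' @export
print.thermal_fit <- function(x, ...) {
  cat(sprintf(
    "<thermal_fit> Pin %.3g W, Rcond %.3g W/K (rms heat %.3g K, decay %.3g K)%s\n",
    x$Pin_hat, x$Rcond_hat, x$residual_rms[["heating"]],
    x$residual_rms[["decay"]],
    if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]")
    else ""
  ))
  invisible(x)
}

#' Transferred energy per unit mass (the PAW dose)
#'
#' The effective power from the thermal fit multiplied by the activation time
#' gives the energy transferred to the water; dividing by the water mass
#' yields the dose axis used for the plasma-source comparison.
#'
#' @param fit A `thermal_fit` (or a bare effective power in W).
#' @param activation_time Source-on duration (s).
#' @param m0 Water mass (kg).
#' @return An `energy_dose` list: `energy_per_mass` (J/kg),
#'   `effective_power` (W), `activation_time` (s).
#' @export
transferred_energy <- function(fit, activation_time, m0 = 0.02) {
  Pin <- if (inherits(fit, "thermal_fit")) fit$Pin_hat else fit
  stopifnot(is.numeric(Pin), activation_time >= 0, m0 > 0)
  structure(
    list(energy_per_mass = Pin * activation_time / m0,
         effective_power = Pin,
         activation_time = activation_time,
         m0 = m0),
    class = "energy_dose"
  )
}
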