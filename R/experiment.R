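#' Experiment design mirroring the PAW treatment panel
#'
#' One row per treatment: plasma source, discharge frequency, activation
#' time, effective power into the water and water mass. The default panel
#' follows the DBD protocol (20 mL aliquots activated for 3 to 30 min at one
#' discharge frequency), with an effective power of 5 W — the fraction of
#' the source's nominal power actually transferred to the water.
#'
#' @param source Source label(s), e.g. "DBD" or "PT".
#' @param frequency_khz Discharge frequency (kHz).
#' @param activation_time_s Activation times (s); one treatment per value.
#' @param power_W True effective power into the water (W).
#' @param m0_kg Water mass (kg).
#' @param replicates Seedlings per treatment (default 6).
#' @return data.frame with one row per treatment, including the true
#'   transferred energy per unit mass `energy_per_mass` (J/kg).
#' @export
experiment_design <- function(source = "DBD",
                              frequency_khz = 20,
                              activation_time_s = c(180, 300, 600, 900, 1800),
                              power_W = 5,
                              m0_kg = 0.02,
                              replicates = 6L) {
  stopifnot(all(activation_time_s > 0), all(power_W > 0), all(m0_kg > 0),
            replicates >= 1L)
  d <- data.frame(
    source = source,
    frequency_khz = frequency_khz,
    activation_time_s = activation_time_s,
    power_W = power_W,
    m0_kg = m0_kg,
    replicates = as.integer(replicates),
    stringsAsFactors = FALSE
  )
  d$treatment <- sprintf("%s_%gkHz_%gmin", d$source, d$frequency_khz,
                         d$activation_time_s / 60)
  d$energy_per_mass <- d$power_W * d$activation_time_s / d$m0_kg
  d
}

#' Generate a full synthetic plate experiment with ground truth
#'
#' For each treatment, the transferred energy per unit mass E sets the true
#' response size through the saturating dose rule
#' \deqn{AUC_{true}(E) \propto \frac{E}{E + E_{half}}}
#' (applied to the above-baseline integral; strictly increasing and concave
#' in E). Both the transient and the sustained amplitude scale with the same
#' factor, multiplied by a per-well lognormal biological variability, and
#' each well is forward-simulated into Poisson photon counts.
#'
#' @param design An [experiment_design()] data.frame.
#' @param seed Master integer seed; the same seed reproduces the experiment
#'   byte-identically.
#' @param E_half Half-saturation energy (J/kg).
#' @param transient_max Transient amplitude at saturation (M).
#' @param sustained_max Sustained amplitude at saturation (M).
#' @param baseline Resting Ca2+ (M).
#' @param rise_tau,decay_tau,sustained_tau Shape time constants (s).
#' @param bio_cv Lognormal coefficient of variation of the per-well
#'   amplitude factor (biological replicate variability).
#' @param pool_counts Aequorin pool per well (recordable counts).
#' @param config A [plate_run_config()]; its `seed` is ignored in favour of
#'   per-well seeds derived from `seed`.
#' @param window Integration window used for the ledger's true AUC (s).
#' @return List with `traces` (list of `lum_trace`), `ledger` (data.frame:
#'   well, treatment, design columns, kinetics parameters, true response AUC
#'   `auc_true` in M*s and total AUC `auc_true_total`), and `design`.
#' @export
make_experiment <- function(design = experiment_design(),
                            seed = 1L,
                            E_half = 1e5,
                            transient_max = 6e-7,
                            sustained_max = 2e-7,
                            baseline = 1e-7,
                            rise_tau = 10, decay_tau = 120,
                            sustained_tau = 300,
                            bio_cv = 0.10,
                            pool_counts = 1e7,
                            config = plate_run_config(run_duration = 2000,
                                                      discharge_time = 1950),
                            window = 1800) {
  stopifnot(is.data.frame(design), nrow(design) >= 1L, E_half > 0)
  n_wells <- sum(design$replicates)

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  well_seeds <- sample.int(.Machine$integer.max - 1L, n_wells)
  sdlog <- sqrt(log(1 + bio_cv^2))
  bio <- stats::rlnorm(n_wells, meanlog = -sdlog^2 / 2, sdlog = sdlog)

  times <- seq(0, config$run_duration, by = 1)
  traces <- vector("list", n_wells)
  rows <- vector("list", n_wells)
  w <- 0L
  for (i in seq_len(nrow(design))) {
    E <- design$energy_per_mass[i]
    f <- E / (E + E_half)
    for (r in seq_len(design$replicates[i])) {
      w <- w + 1L
      well_id <- sprintf("%s_w%02d", design$treatment[i], r)
      kin <- ca_kinetics(
        baseline = baseline,
        transient_amplitude = transient_max * f * bio[w],
        rise_tau = rise_tau, decay_tau = decay_tau,
        sustained_amplitude = sustained_max * f * bio[w],
        sustained_tau = sustained_tau,
        stimulus_time = config$stimulus_time
      )
      ca <- make_ca_trajectory(kin, times, well_id = well_id)
      traces[[w]] <- make_luminescence(ca, pool_counts = pool_counts,
                                       config = config,
                                       seed = well_seeds[w])
      auc_total <- kinetics_auc(kin, window)
      rows[[w]] <- data.frame(
        well_id = well_id,
        treatment = design$treatment[i],
        source = design$source[i],
        frequency_khz = design$frequency_khz[i],
        activation_time_s = design$activation_time_s[i],
        energy_per_mass = E,
        baseline = baseline,
        transient_amplitude = kin$transient_amplitude,
        sustained_amplitude = kin$sustained_amplitude,
        rise_tau = rise_tau, decay_tau = decay_tau,
        sustained_tau = sustained_tau,
        auc_true = auc_total - baseline * window,
        auc_true_total = auc_total,
        seed = well_seeds[w],
        stringsAsFactors = FALSE
      )
    }
  }
  list(traces = traces, ledger = do.call(rbind, rows), design = design)
}
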