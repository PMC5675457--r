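#' Simulation scenario configuration
#'
#' Study conditions for the synthetic cohort: 14 days, three meals per day
#' at about 07:00, 13:00 and 19:00 with mean carbohydrate contents 50, 60
#' and 63.5 g and a 20% coefficient of variation (Gaussian, floored at
#' 10 g), meal times jittered uniformly within +/-30 min; a 20% CV
#' Gaussian carbohydrate-counting error on the announced meal size; 20-g
#' rescue carbohydrates at most every 20 min whenever a fingerstick
#' reading falls below 60 mg/dl; CGM sampled every 5 min on a 1-min event
#' grid.  Fingerstick (SMBG) noise is 5% CV; hypoglycemia checks run
#' every 20 min whenever true glucose is below `hypo_check_bg`.  CGM
#' error is a 10-min first-order sensor lag plus additive first-order
#' autocorrelated noise.
#'
#' @param days number of simulated days.
#' @param meal_times_min meal clock times, minutes after midnight.
#' @param meal_means_g mean carbohydrate content per meal slot, grams.
#' @param meal_cv coefficient of variation of meal sizes.
#' @param meal_floor_g lower truncation of sampled meal sizes, grams.
#' @param meal_jitter_min half-width of the uniform meal-time jitter.
#' @param carb_cv CV of the carbohydrate-counting error.
#' @param hypo_grams,hypo_interval_min,hypo_trigger_mgdl rescue-dose mass,
#'   refractory interval and SMBG trigger threshold.
#' @param hypo_check_bg true-glucose level below which SMBG checks run.
#' @param smbg_cv fingerstick noise CV.
#' @param cgm_dt_min CGM sampling period (minutes).
#' @param cgm_noise_sd,cgm_noise_rho CGM additive noise: marginal SD
#'   (mg/dl) and lag-1 autocorrelation on the 5-min grid.
#' @param cgm_lag_min sensor (plasma-to-interstitium) lag time constant.
#' @return A list of class `scenario_config`.
#' @export
scenario_config <- function(days = 14L,
                            meal_times_min = c(7, 13, 19) * 60,
                            meal_means_g = c(50, 60, 63.5),
                            meal_cv = 0.20, meal_floor_g = 10,
                            meal_jitter_min = 30,
                            carb_cv = 0.20,
                            hypo_grams = 20, hypo_interval_min = 20,
                            hypo_trigger_mgdl = 60, hypo_check_bg = 80,
                            smbg_cv = 0.05,
                            cgm_dt_min = 5,
                            cgm_noise_sd = 2, cgm_noise_rho = 0.7,
                            cgm_lag_min = 10) {
  stopifnot(days >= 1, length(meal_times_min) == length(meal_means_g),
            all(meal_means_g > 0), meal_cv >= 0, meal_cv < 1,
            hypo_grams > 0, hypo_interval_min > 0)
  structure(as.list(environment()), class = "scenario_config")
}

#' Virtual-patient parameters
#'
#' Physiological and therapy parameters of the surrogate glucose-insulin
#' model (see the methods vignette).  This minimal model is declared NOT
#' to reproduce the proprietary research simulator; it exists so every
#' downstream stage of the pipeline is testable end to end.
#'
#' @param weight_kg body mass.
#' @param sg glucose effectiveness, 1/min.
#' @param si insulin sensitivity scale (per U/min of insulin action).
#' @param p2 insulin-action rate constant, 1/min (two-compartment chain;
#'   activity peaks around `1/p2` minutes after a bolus).
#' @param egp endogenous glucose production, mg/dl/min.
#' @param egp_supp strength of the suppression of endogenous production by
#'   above-basal insulin action (0 disables; at basal action the factor is
#'   exactly 1, so the steady state is unaffected).
#' @param circadian_amp amplitude (fraction) of the sinusoidal circadian
#'   insulin-sensitivity modulation, in `[0, 0.5]`; default 0.20.
#' @param circadian_phase phase of the modulation, radians.
#' @param g_target therapy target glucose, mg/dl.
#' @param cr,cf carbohydrate ratio (g/U) and correction factor (mg/dl/U);
#'   `NULL` derives them from the physiology (with no imperfection).
#' @param therapy_error multiplicative imperfection applied to the derived
#'   CR (values > 1 underdose, < 1 overdose).
#' @param basal_error multiplicative imperfection of the programmed basal
#'   profile relative to the patient's true requirement (1 = perfectly
#'   titrated).
#' @param absorption an [absorption_params()] object.
#' @param iob an [iob_params()] object.
#' @return A list of class `virtual_patient_params`.
#' @export
virtual_patient_params <- function(weight_kg = 70, sg = 0.002, si = 0.4,
                                   p2 = 0.012, egp = 1.2, egp_supp = 0.4,
                                   circadian_amp = 0.20,
                                   circadian_phase = 0,
                                   g_target = 120,
                                   cr = NULL, cf = NULL,
                                   therapy_error = 1, basal_error = 1,
                                   absorption = absorption_params(),
                                   iob = iob_params()) {
  stopifnot(weight_kg > 0, sg > 0, si > 0, p2 > 0, egp > 0,
            circadian_amp >= 0, circadian_amp <= 0.5)
  v_dl <- 1.6 * weight_kg              # distribution volume, dl
  kcarb <- 1000 / v_dl                 # mg/dl rise per g appearing
  if (is.null(cf)) cf <- si * g_target # per-U integrated lowering, mg/dl
  if (is.null(cr))                     # grams matched per U at ~135 mg/dl
    cr <- therapy_error * si * 135 / (absorption$cho_bio * kcarb)
  xa_ref <- (egp - sg * g_target) / (si * g_target)  # basal action level
  if (xa_ref <= 0) stop("parameters admit no positive basal steady state")
  structure(list(weight_kg = weight_kg, v_dl = v_dl, kcarb = kcarb,
                 sg = sg, si = si, p2 = p2, egp = egp,
                 egp_supp = egp_supp, xa_ref = xa_ref,
                 basal_error = basal_error,
                 circadian_amp = circadian_amp,
                 circadian_phase = circadian_phase,
                 g_target = g_target,
                 therapy = bolus_therapy_params(cr = cr, cf = cf,
                                                g_target = g_target),
                 absorption = absorption, iob = iob),
            class = "virtual_patient_params")
}

#' Steady-state basal rate for a glucose target
#'
#' Fixed-point solve of the surrogate dynamics at unit circadian factor:
#' the basal infusion (U/min) holding glucose constant at `g_star` with
#' no meals.
#'
#' @param patient a [virtual_patient_params()] object.
#' @param g_star target steady-state glucose, mg/dl.
#' @return Basal rate, U/min.
#' @export
basal_for_target <- function(patient, g_star = patient$g_target) {
  ub <- (patient$egp - patient$sg * g_star) / (patient$si * g_star)
  if (ub <= 0) stop("no positive basal holds this target for these parameters")
  ub
}

#' Sample one day of meals
#'
#' Three Gaussian draws (mean per slot, sd = CV * mean), truncated at the
#' configured floor; clock times jittered uniformly within the configured
#' half-width.  Uses the global RNG stream.
#'
#' @param day_index 0-based day number (offsets the event times).
#' @param config a [scenario_config()].
#' @return A data.frame with `time` (minutes since scenario start),
#'   `grams` and `slot`.
#' @export
sample_meals <- function(day_index, config = scenario_config()) {
  k <- length(config$meal_times_min)
  grams <- pmax(config$meal_floor_g,
                stats::rnorm(k, config$meal_means_g,
                             config$meal_cv * config$meal_means_g))
  jit <- round(stats::runif(k, -config$meal_jitter_min,
                            config$meal_jitter_min))
  data.frame(time = day_index * 1440 + config$meal_times_min + jit,
             grams = grams, slot = seq_len(k))
}

#' Carbohydrate-counting error
#'
#' The announced meal size: truth times `(1 + e)` with
#' `e ~ Normal(0, carb_cv)`, floored at zero.
#'
#' @param true_grams actual meal mass (> 0), vectorized.
#' @param config a [scenario_config()].
#' @return Estimated grams.
#' @export
carb_counting_error <- function(true_grams, config = scenario_config()) {
  stopifnot(all(true_grams > 0))
  pmax(0, true_grams * (1 + stats::rnorm(length(true_grams), 0,
                                         config$carb_cv)))
}

#' Rescue-carbohydrate rule
#'
#' Emits a rescue dose if and only if the latest fingerstick reading is
#' below the trigger threshold and at least the refractory interval has
#' elapsed since the previous rescue.
#'
#' @param smbg latest SMBG reading, mg/dl (`NA` if none available).
#' @param last_treatment_time time of the previous rescue, minutes (`-Inf`
#'   if none).
#' @param now current time, minutes.
#' @param config a [scenario_config()].
#' @return Rescue mass in grams, or `NULL` when no dose is due.
#' @export
hypotreatment_rule <- function(smbg, last_treatment_time, now,
                               config = scenario_config()) {
  if (is.na(smbg)) return(NULL)
  if (smbg >= config$hypo_trigger_mgdl) return(NULL)
  if (now - last_treatment_time < config$hypo_interval_min) return(NULL)
  config$hypo_grams
}

# One explicit Euler step of the surrogate minimal glucose-insulin model.
# state: c(G, X1, Xa) with a two-compartment insulin-action chain (X1 the
# delivery pool, Xa the remote action pool, so a bolus builds activity to
# a ~1/p2-min peak and decays slowly); inputs: ra_mgdl (mg/dl/min),
# u (U/min), circ (unitless insulin-sensitivity multiplier).  Glucose is
# clamped to [20, 600].
glucose_dynamics_step <- function(state, ra_mgdl, u, circ, patient, dt = 1) {
  if (any(!is.finite(state))) stop("non-finite simulation state")
  G <- state[1]; X1 <- state[2]; Xa <- state[3]
  egp_eff <- patient$egp *
    max(0, 1 + patient$egp_supp * (1 - Xa / patient$xa_ref))
  dG <- egp_eff - patient$sg * G - patient$si * circ * Xa * G + ra_mgdl
  dX1 <- patient$p2 * (u - X1)
  dXa <- patient$p2 * (X1 - Xa)
  G2 <- min(600, max(20, G + dt * dG))
  c(G2, X1 + dt * dX1, Xa + dt * dXa)
}

#' Simulate one virtual patient
#'
#' Closed-loop behavioral simulation on the 1-minute grid: meals are
#' sampled per day, announced with carbohydrate-counting error, and dosed
#' by the standard bolus calculator from a preprandial fingerstick; the
#' surrogate glucose-insulin dynamics respond to meal absorption, basal
#' and bolus insulin under a sinusoidal circadian insulin-sensitivity
#' modulation (basal is time-varying to track that modulation); rescue
#' carbohydrates follow the fingerstick rule; the CGM reads the plasma
#' trace through a first-order sensor lag with autocorrelated additive
#' noise every 5 min.  Fully reproducible for a fixed seed.
#'
#' @param patient a [virtual_patient_params()] object.
#' @param scenario a [scenario_config()].
#' @param seed integer seed.
#' @return A list of class `patient_dataset`: `cgm` (5-min
#'   [uniform_signal()]), `events` (meals, rescues, boluses, SMBG),
#'   `insulin` ([insulin_delivery()]), `true_bg` (1-min signal, retained
#'   for validation only), `params`, `scenario`, `seed`.
#' @export
simulate_patient <- function(patient = virtual_patient_params(),
                             scenario = scenario_config(), seed = 1L) {
  set.seed(seed)
  total_min <- scenario$days * 1440L
  # pre-sample meals and announced sizes
  meals <- do.call(rbind, lapply(seq_len(scenario$days) - 1L, sample_meals,
                                 config = scenario))
  meals$est <- carb_counting_error(meals$grams, scenario)
  meals <- meals[order(meals$time), ]

  # time-varying basal follows the circadian sensitivity pattern
  circ_at <- function(t_min)
    1 + patient$circadian_amp *
      sin(2 * pi * t_min / 1440 + patient$circadian_phase)
  ub0 <- basal_for_target(patient)
  basal_rate <- function(t_min) patient$basal_error * ub0 / circ_at(t_min)

  tm <- patient$absorption$t_max_g
  bio <- patient$absorption$cho_bio
  G <- patient$g_target; X1 <- ub0; Xa <- ub0  # (approximate) steady state
  q1 <- 0; q2 <- 0                   # meal absorption chain (grams)
  Gs <- G                            # sensor compartment
  noise <- 0
  rho5 <- scenario$cgm_noise_rho
  innov_sd <- scenario$cgm_noise_sd * sqrt(1 - rho5^2)

  n_cgm <- total_min %/% scenario$cgm_dt_min
  cgm <- numeric(n_cgm)
  true_bg <- numeric(total_min)
  basal_v <- numeric(total_min)
  ev_time <- ev_cho <- ev_est <- ev_bolus <- ev_smbg <- numeric(0)
  ev_kind <- character(0)
  bol_time <- bol_units <- numeric(0)
  last_rescue <- -Inf
  mi <- 1L

  for (t in seq_len(total_min) - 1L) {
    u <- basal_rate(t)
    basal_v[t + 1L] <- u
    # scheduled meal: fingerstick, bolus, ingestion
    while (mi <= nrow(meals) && meals$time[mi] == t) {
      smbg <- G * (1 + stats::rnorm(1, 0, scenario$smbg_cv))
      dose <- bolus_dose(meals$est[mi], patient$therapy, smbg)
      q1 <- q1 + meals$grams[mi]
      ev_time <- c(ev_time, t); ev_cho <- c(ev_cho, meals$grams[mi])
      ev_est <- c(ev_est, meals$est[mi]); ev_bolus <- c(ev_bolus, dose)
      ev_smbg <- c(ev_smbg, smbg); ev_kind <- c(ev_kind, "meal")
      bol_time <- c(bol_time, t); bol_units <- c(bol_units, dose)
      u <- u + dose                   # impulse over this 1-min step
      mi <- mi + 1L
    }
    # hypoglycemia monitoring every `hypo_interval_min` minutes
    if (t %% scenario$hypo_interval_min == 0 && G < scenario$hypo_check_bg) {
      smbg <- G * (1 + stats::rnorm(1, 0, scenario$smbg_cv))
      rescue <- hypotreatment_rule(smbg, last_rescue, t, scenario)
      ev_time <- c(ev_time, t); ev_cho <- c(ev_cho, 0)
      ev_est <- c(ev_est, 0); ev_bolus <- c(ev_bolus, 0)
      ev_smbg <- c(ev_smbg, smbg); ev_kind <- c(ev_kind, "smbg")
      if (!is.null(rescue)) {
        q1 <- q1 + rescue
        last_rescue <- t
        ev_cho[length(ev_cho)] <- rescue
        ev_kind[length(ev_kind)] <- "rescue"
      }
    }
    # absorption chain (grams): Ra in g/min = bio * q2 / tm
    ra_gmin <- bio * q2 / tm
    ra_mgdl <- patient$kcarb * ra_gmin
    st <- glucose_dynamics_step(c(G, X1, Xa), ra_mgdl, u, circ_at(t),
                                patient)
    G <- st[1]; X1 <- st[2]; Xa <- st[3]
    q1 <- q1 - q1 / tm
    q2 <- q2 + (q1 / tm - q2 / tm)   # note: uses pre-update q1? kept simple
    # sensor compartment and CGM sampling
    Gs <- Gs + (G - Gs) / scenario$cgm_lag_min
    true_bg[t + 1L] <- G
    if ((t + 1L) %% scenario$cgm_dt_min == 0L) {
      noise <- rho5 * noise + stats::rnorm(1, 0, innov_sd)
      cgm[(t + 1L) %/% scenario$cgm_dt_min] <- max(20, Gs + noise)
    }
  }
  # CGM timestamps: t = 0, 5, ... ; reading at t uses the state reached at
  # the end of minute t (aligned by construction above for t >= 5; the
  # t = 0 sample is the initial state).
  cgm <- c(patient$g_target, cgm[-n_cgm])
  basal_sig <- uniform_signal(basal_v, t0 = 0, dt = 1)
  delivery <- insulin_delivery(basal_sig, bol_time, bol_units)
  structure(list(
    cgm = uniform_signal(cgm, t0 = 0, dt = scenario$cgm_dt_min),
    events = data.frame(time = ev_time, kind = ev_kind, cho_g = ev_cho,
                        cho_est_g = ev_est, bolus_u = ev_bolus,
                        smbg_mgdl = ev_smbg, stringsAsFactors = FALSE),
    insulin = delivery,
    true_bg = uniform_signal(true_bg, t0 = 0, dt = 1),
    params = patient, scenario = scenario, seed = as.integer(seed)
  ), class = "patient_dataset")
}

#' @export
print.patient_dataset <- function(x, ...) {
  cat(sprintf(paste0("<patient_dataset> %d days, %d CGM samples, ",
                     "%d meals, %d rescues (seed %d)\n"),
              x$scenario$days, length(x$cgm$values),
              sum(x$events$kind == "meal"),
              sum(x$events$kind == "rescue"), x$seed))
  invisible(x)
}

#' Simulate a cohort of virtual patients
#'
#' Draws per-patient physiological and therapy parameters from declared
#' distributions (log-normal insulin sensitivity and endogenous
#' production, normal body mass, uniform circadian phase, log-normal
#' therapy imperfection) and simulates each patient with a child seed
#' derived deterministically from the master seed.
#'
#' @param n_patients number of patients (>= 1).
#' @param scenario a [scenario_config()].
#' @param master_seed integer seed.
#' @return A list of class `patient_cohort`: `patients` (list of
#'   [simulate_patient()] datasets) and `manifest` (data.frame of ids,
#'   seeds and parameter draws).
#' @export
simulate_cohort <- function(n_patients, scenario = scenario_config(),
                            master_seed = 1L) {
  stopifnot(n_patients >= 1)
  set.seed(master_seed)
  draws <- data.frame(
    patient = seq_len(n_patients),
    seed = (as.integer(master_seed) + 9973L * seq_len(n_patients)) %%
      2147483647L,
    weight_kg = stats::rnorm(n_patients, 70, 10),
    si = 0.4 * exp(stats::rnorm(n_patients, 0, 0.2)),
    egp = 1.2 * exp(stats::rnorm(n_patients, 0, 0.1)),
    circadian_phase = stats::runif(n_patients, 0, 2 * pi),
    therapy_error = exp(stats::rnorm(n_patients, 0, 0.15)),
    basal_error = exp(stats::rnorm(n_patients, 0, 0.10)),
    g_target = pmin(150, pmax(95, stats::rnorm(n_patients, 120, 15)))
  )
  draws$weight_kg <- pmax(45, draws$weight_kg)
  patients <- lapply(seq_len(n_patients), function(i) {
    p <- virtual_patient_params(weight_kg = draws$weight_kg[i],
                                si = draws$si[i], egp = draws$egp[i],
                                circadian_phase = draws$circadian_phase[i],
                                therapy_error = draws$therapy_error[i],
                                basal_error = draws$basal_error[i],
                                g_target = draws$g_target[i])
    simulate_patient(p, scenario, seed = draws$seed[i])
  })
  structure(list(patients = patients, manifest = draws),
            class = "patient_cohort")
}
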