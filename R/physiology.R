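#' Carbohydrate absorption parameters
#'
#' Parameters of the two-compartment meal-absorption kernel used to turn a
#' discrete carbohydrate intake into a continuous glucose rate-of-appearance
#' (Ra) signal.  `t_max_g` is the time (minutes) at which a meal's
#' appearance rate peaks; `cho_bio` is the fraction of the ingested mass
#' that eventually appears in circulation.  Defaults are the adult
#' population values commonly used with this kernel (50 min, 0.8).
#'
#' @param t_max_g time of peak appearance, minutes (> 0).
#' @param cho_bio carbohydrate bioavailability, in (0, 1].
#' @return A list of class `absorption_params`.
#' @export
absorption_params <- function(t_max_g = 50, cho_bio = 0.8) {
  if (!is.numeric(t_max_g) || length(t_max_g) != 1L || t_max_g <= 0)
    stop("'t_max_g' must be a single positive number of minutes")
  if (!is.numeric(cho_bio) || length(cho_bio) != 1L ||
      cho_bio <= 0 || cho_bio > 1)
    stop("'cho_bio' must lie in (0, 1]")
  structure(list(t_max_g = t_max_g, cho_bio = cho_bio),
            class = "absorption_params")
}

#' Meal events
#'
#' @param time minutes since scenario start (>= 0).
#' @param grams carbohydrate mass in grams (> 0).
#' @return A data.frame with columns `time` and `grams`, one row per meal.
#' @export
meal_events <- function(time = numeric(), grams = numeric()) {
  time <- as.numeric(time); grams <- as.numeric(grams)
  if (length(time) != length(grams))
    stop("'time' and 'grams' must have equal length")
  if (length(grams) && (any(grams <= 0) || any(time < 0)))
    stop("meal events require grams > 0 and time >= 0")
  data.frame(time = time, grams = grams)
}

#' Glucose rate-of-appearance signal from meal events
#'
#' Superposes, over all meals, the two-compartment absorption kernel
#' \deqn{Ra(t) = CHO \cdot bio \cdot \tau e^{-\tau/t_{max}} / t_{max}^2,
#'       \quad \tau = t - t_{meal},}
#' zero before each meal.  Carbohydrate mass is kept in grams, so the
#' returned signal is in g/min; multiply by `mg_per_g` (config-level
#' constant, 1000) where mg/min is required.  The kernel is truncated at
#' `tau > 12 * t_max_g`, where it is numerically negligible (the neglected
#' tail carries < 1e-4 of the mass).
#'
#' @param meals a data.frame from [meal_events()].
#' @param params an [absorption_params()] object.
#' @param dt output sampling period, minutes.
#' @param duration scenario duration, minutes; the signal covers
#'   `t = 0, dt, ..., duration`.
#' @return A [uniform_signal()] in g/min on the `dt` grid.
#' @examples
#' ra <- ra_signal(meal_events(0, 50), absorption_params(), dt = 1,
#'                 duration = 300)
#' signal_time(ra)[which.max(ra$values)]  # peaks at t_max_g
#' @export
ra_signal <- function(meals, params = absorption_params(), dt = 1,
                      duration) {
  if (!inherits(params, "absorption_params"))
    stop("'params' must be an absorption_params object")
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0)
    stop("'dt' must be a single positive number of minutes")
  if (missing(duration) || !is.numeric(duration) || duration <= 0)
    stop("'duration' must be a positive number of minutes")
  if (nrow(meals) && any(meals$time > duration))
    stop("'duration' must cover all meal times")
  tt <- seq(0, duration, by = dt)
  out <- numeric(length(tt))
  tmax <- params$t_max_g
  cutoff <- 12 * tmax
  for (j in seq_len(NROW(meals))) {
    tau <- tt - meals$time[j]
    live <- tau >= 0 & tau <= cutoff
    out[live] <- out[live] +
      meals$grams[j] * params$cho_bio *
      tau[live] * exp(-tau[live] / tmax) / tmax^2
  }
  uniform_signal(out, t0 = 0, dt = dt)
}

#' Insulin-on-board model parameters
#'
#' Rate constant of the two-compartment insulin-on-board (IOB) estimator.
#' The mapping between the nominal duration of insulin action (DIA, hours)
#' and the per-minute rate constant is kept as a lookup with the single
#' published pair: DIA 2 h corresponds to `k_dia = 0.039` per minute.
#'
#' @param k_dia per-minute rate constant (> 0).
#' @param dia_hours nominal duration of insulin action, hours (metadata).
#' @return A list of class `iob_params`.
#' @export
iob_params <- function(k_dia = 0.039, dia_hours = 2) {
  if (!is.numeric(k_dia) || length(k_dia) != 1L || k_dia <= 0)
    stop("'k_dia' must be a single positive rate (1/min)")
  structure(list(k_dia = k_dia, dia_hours = dia_hours), class = "iob_params")
}

#' Insulin delivery record
#'
#' Combines a basal infusion signal on the 1-minute grid with discrete
#' boluses, each modelled as an impulse (the full dose delivered within one
#' 1-minute sample, consistent with pump bolus records).
#'
#' @param basal a [uniform_signal()] of U/min with `dt = 1`, or a single
#'   constant rate (U/min) to be held over `duration`.
#' @param bolus_time,bolus_units bolus times (min) and doses (U).
#' @param duration scenario duration in minutes (required when `basal` is a
#'   constant).
#' @return A list of class `insulin_delivery` with the dose-rate signal
#'   `u` (U/min, 1-min grid) combining basal and impulse boluses.
#' @export
insulin_delivery <- function(basal, bolus_time = numeric(),
                             bolus_units = numeric(), duration = NULL) {
  if (is.numeric(basal) && length(basal) == 1L) {
    if (is.null(duration)) stop("'duration' required with a constant basal")
    basal <- uniform_signal(rep(basal, duration + 1), t0 = 0, dt = 1)
  }
  stopifnot(inherits(basal, "uniform_signal"))
  if (basal$dt != 1) stop("basal must be sampled on the 1-min grid")
  if (any(basal$values < 0) || any(bolus_units < 0))
    stop("insulin doses must be nonnegative")
  if (length(bolus_time) != length(bolus_units))
    stop("'bolus_time' and 'bolus_units' must have equal length")
  u <- basal$values
  for (j in seq_along(bolus_time)) {
    i <- round((bolus_time[j] - basal$t0) / basal$dt) + 1L
    if (i < 1L || i > length(u)) stop("bolus time outside the basal signal")
    u[i] <- u[i] + bolus_units[j]   # impulse: full dose in one 1-min sample
  }
  structure(list(u = uniform_signal(u, t0 = basal$t0, dt = 1),
                 basal = basal,
                 boluses = data.frame(time = as.numeric(bolus_time),
                                      units = as.numeric(bolus_units))),
            class = "insulin_delivery")
}

#' Insulin-on-board signal
#'
#' Discrete-time integration of the two-compartment IOB model
#' \deqn{dC_1/dt = u(t) - K C_1,\qquad dC_2/dt = K(C_1 - C_2),\qquad
#'       IOB = C_1 + C_2,}
#' by explicit forward Euler on the 1-minute delivery grid (stable since
#' `K * dt = 0.039 < 1`), starting from an empty state.  The impulse
#' response of the continuous model is `e^{-Kt}(1 + Kt)`, which the scheme
#' approaches with O(dt) error.
#'
#' @param insulin an [insulin_delivery()] record (or a raw
#'   [uniform_signal()] of U/min).
#' @param params an [iob_params()] object.
#' @param dt integration/output period, minutes (default 1, the native
#'   grid).
#' @param duration optional duration; defaults to the delivery signal span.
#' @return A [uniform_signal()] of units of insulin on board.
#' @export
iob_signal <- function(insulin, params = iob_params(), dt = 1,
                       duration = NULL) {
  if (!inherits(params, "iob_params"))
    stop("'params' must be an iob_params object")
  if (inherits(insulin, "insulin_delivery")) {
    base_sig <- insulin$basal
    boluses <- insulin$boluses
  } else {
    stopifnot(inherits(insulin, "uniform_signal"))
    base_sig <- insulin
    boluses <- data.frame(time = numeric(), units = numeric())
  }
  if (dt <= 0) stop("'dt' must be positive")
  if (is.null(duration))
    duration <- (length(base_sig$values) - 1L) * base_sig$dt
  n_out <- floor(duration / dt) + 1L
  K <- params$k_dia
  # forward Euler at step dt; basal enters as a rate, boluses as
  # instantaneous increments to C1 (impulse doses)
  c1 <- 0; c2 <- 0
  iob <- numeric(n_out)
  bv <- base_sig$values
  bt <- boluses$time[order(boluses$time)]
  bu <- boluses$units[order(boluses$time)]
  bi <- 1L
  for (s in seq_len(n_out)) {
    t_now <- (s - 1) * dt
    while (bi <= length(bt) && bt[bi] <= t_now + 1e-9) {
      c1 <- c1 + bu[bi]; bi <- bi + 1L
    }
    iob[s] <- c1 + c2
    ui <- floor(t_now / base_sig$dt + 1e-9) + 1L
    u_now <- if (ui <= length(bv)) bv[ui] else 0
    c1_new <- c1 + dt * (u_now - K * c1)
    c2_new <- c2 + dt * K * (c1 - c2)
    c1 <- c1_new; c2 <- c2_new
  }
  uniform_signal(iob, t0 = base_sig$t0, dt = dt)
}

#' Bolus-therapy parameters and the standard bolus calculator
#'
#' The mealtime bolus is the carbohydrate dose plus a correction toward the
#' glucose target:
#' \deqn{I_{bolus} = CHO_{IN}/CR + (G_B - G_T)/CF}
#' where `CR` is the carbohydrate-to-insulin ratio (g/U), `CF` the
#' correction factor (mg/dl per U), `G_T` the target glucose and `G_B` the
#' preprandial fingerstick reading.  The correction sign follows clinical
#' convention (glucose above target adds insulin).  Setting
#' `correction_sign = "target-minus-reading"` selects the opposite
#' convention instead.  Negative computed doses are clamped to zero: a pump
#' cannot deliver negative insulin.
#'
#' @param cr carbohydrate-to-insulin ratio, g/U (> 0).
#' @param cf correction factor, mg/dl per U (> 0).
#' @param g_target target glucose, mg/dl.
#' @param correction_sign `"reading-minus-target"` (clinical, default) or
#'   `"target-minus-reading"`.
#' @return `bolus_therapy_params`: a parameter list.  `bolus_dose`: the
#'   dose in U (>= 0).
#' @export
bolus_therapy_params <- function(cr = 10, cf = 40, g_target = 120,
                                 correction_sign = c("reading-minus-target",
                                                     "target-minus-reading")) {
  correction_sign <- match.arg(correction_sign)
  if (!is.numeric(cr) || cr <= 0) stop("'cr' must be positive")
  if (!is.numeric(cf) || cf <= 0) stop("'cf' must be positive")
  structure(list(cr = cr, cf = cf, g_target = g_target,
                 correction_sign = correction_sign),
            class = "bolus_therapy_params")
}

#' @rdname bolus_therapy_params
#' @param cho_est estimated meal carbohydrate, grams (>= 0; carb-counting
#'   error included upstream).
#' @param params a [bolus_therapy_params()] object.
#' @param g_b preprandial SMBG reading, mg/dl.
#' @export
bolus_dose <- function(cho_est, params = bolus_therapy_params(), g_b) {
  if (!inherits(params, "bolus_therapy_params"))
    stop("'params' must be a bolus_therapy_params object")
  if (any(cho_est < 0)) stop("'cho_est' must be >= 0")
  corr <- if (params$correction_sign == "reading-minus-target")
    (g_b - params$g_target) / params$cf
  else
    (params$g_target - g_b) / params$cf
  pmax(0, cho_est / params$cr + corr)
}
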