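# Day segmentation for piecewise modeling, and construction of the
# (history, target) training pairs on the 5-min CGM grid.

#' Day-segment specifications
#'
#' `segment_specs_6h()` returns the default four 6-hour segments tiling
#' the day: Nocturnal 01:00-06:59, Breakfast 07:00-12:59, Lunch
#' 13:00-18:59 and Dinner 19:00-00:59 (wrapping midnight).  Segments are
#' half-open `[start, end + 1 min)` on the clock; a timestamp at exactly
#' 07:00 belongs to Breakfast.  `postprandial_windows()` returns the
#' alternative late-postprandial windows 09:00-13:00, 15:00-19:00 and
#' 19:00-01:00 used to fit models that skip the first two unpredictable
#' hours after each meal (the third window is kept at its conventional
#' six-hour printed extent).
#'
#' @return A data.frame with columns `label`, `start_min`, `end_min`
#'   (clock minutes; `end_min` exclusive; `end_min < start_min` indicates
#'   a segment wrapping midnight).
#' @export
segment_specs_6h <- function() {
  data.frame(label = c("Nocturnal", "Breakfast", "Lunch", "Dinner"),
             start_min = c(60, 420, 780, 1140),
             end_min = c(420, 780, 1140, 60),
             stringsAsFactors = FALSE)
}

#' @rdname segment_specs_6h
#' @export
postprandial_windows <- function() {
  data.frame(label = c("09:00-13:00", "15:00-19:00", "19:00-01:00"),
             start_min = c(540, 900, 1140),
             end_min = c(780, 1140, 60),
             stringsAsFactors = FALSE)
}

# is clock time (minutes after midnight) inside the half-open segment?
in_segment <- function(clock_min, start_min, end_min) {
  if (end_min > start_min) clock_min >= start_min & clock_min < end_min
  else clock_min >= start_min | clock_min < end_min
}

#' Aligned model inputs for a patient dataset
#'
#' Computes the Ra and IOB signals on the 1-min event grid from the
#' dataset's carbohydrate events (meals and rescues alike) and insulin
#' record, then subsamples both at the CGM timestamps so that all three
#' signals share the 5-min grid.
#'
#' @param dataset a `patient_dataset`.
#' @return A list with `g`, `ra`, `iob` (aligned [uniform_signal()]s) and
#'   `time_min`.
#' @export
model_inputs <- function(dataset) {
  cho <- dataset$events[dataset$events$cho_g > 0, ]
  duration <- (length(dataset$cgm$values) - 1L) * dataset$cgm$dt
  absorption <- if (!is.null(dataset$params)) dataset$params$absorption
                else absorption_params()
  iobp <- if (!is.null(dataset$params)) dataset$params$iob else iob_params()
  ra1 <- ra_signal(meal_events(cho$time, cho$cho_g), absorption,
                   dt = 1, duration = duration)
  iob1 <- iob_signal(dataset$insulin, iobp, dt = 1, duration = duration)
  list(g = dataset$cgm,
       ra = subsample_signal(ra1, dataset$cgm$dt),
       iob = subsample_signal(iob1, dataset$cgm$dt),
       time_min = signal_time(dataset$cgm))
}

#' Prediction pairs for a segment
#'
#' Enumerates the (history index, target) pairs available on the 5-min
#' grid: `n` must leave `lag_max` samples of history (the first 120 min
#' of a record yield no pairs) and the target `n + horizon` must lie
#' inside the record.  A pair belongs to a segment when the *target*
#' clock time falls in the segment window, regardless of where the
#' history lies.
#'
#' @param inputs a [model_inputs()] list.
#' @param segment one row of a segment-spec data.frame, or `NULL` for all
#'   predictable timestamps.
#' @param horizon prediction horizon in samples (24 = 120 min).
#' @param lag_max history depth in samples required by the grammar.
#' @param days optional 1-based day numbers to which *target* timestamps
#'   are restricted (train/test split).
#' @return A data.frame with `n` (history index), `m` (target index),
#'   `target` (CGM at `m`), `clock_min` and `day`.
#' @export
segment_pairs <- function(inputs, segment = NULL, horizon = 24L,
                          lag_max = 24L, days = NULL) {
  nsig <- length(inputs$g$values)
  n <- seq_len(nsig)
  n <- n[n > lag_max & n + horizon <= nsig]
  if (!length(n)) stop("record too short for any (history, target) pair")
  m <- n + horizon
  t_target <- inputs$time_min[m]
  clock <- t_target %% 1440
  day <- t_target %/% 1440 + 1L
  keep <- rep(TRUE, length(n))
  if (!is.null(segment))
    keep <- keep & in_segment(clock, segment$start_min, segment$end_min)
  if (!is.null(days)) keep <- keep & day %in% days
  if (!any(keep)) stop("segment contains no (history, target) pairs")
  data.frame(n = n[keep], m = m[keep],
             target = inputs$g$values[m[keep]],
             clock_min = clock[keep], day = day[keep])
}

#' Restrict a patient dataset to whole days
#'
#' Returns the dataset slice covering the given 1-based day numbers
#' (which must be consecutive), re-timed to start at 00:00 of the first
#' kept day.  Used to evaluate test days as a standalone record.
#'
#' @param dataset a `patient_dataset`.
#' @param days consecutive 1-based day numbers.
#' @return A `patient_dataset`.
#' @export
slice_days <- function(dataset, days) {
  days <- sort(unique(as.integer(days)))
  if (length(days) > 1L && any(diff(days) != 1L))
    stop("'days' must be consecutive")
  t0 <- (days[1] - 1L) * 1440
  t1 <- days[length(days)] * 1440    # exclusive
  keep_cgm <- signal_time(dataset$cgm) >= t0 & signal_time(dataset$cgm) < t1
  ev <- dataset$events[dataset$events$time >= t0 & dataset$events$time < t1, ]
  ev$time <- ev$time - t0
  bt <- signal_time(dataset$insulin$basal)
  kb <- bt >= t0 & bt < t1
  basal <- uniform_signal(dataset$insulin$basal$values[kb], t0 = 0, dt = 1)
  bol <- dataset$insulin$boluses
  bol <- bol[bol$time >= t0 & bol$time < t1, ]
  out <- dataset
  out$cgm <- uniform_signal(dataset$cgm$values[keep_cgm], t0 = 0,
                            dt = dataset$cgm$dt)
  out$events <- ev
  out$insulin <- insulin_delivery(basal, bol$time - t0, bol$units)
  if (!is.null(dataset$true_bg)) {
    tb <- signal_time(dataset$true_bg)
    out$true_bg <- uniform_signal(
      dataset$true_bg$values[tb >= t0 & tb < t1], t0 = 0, dt = 1)
  }
  out
}
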