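#' Fit a personalized piecewise glucose forecaster
#'
#' The package's main fitting function.  For one patient record it
#' computes the physiological input signals (meal rate of appearance and
#' insulin on board), splits the day into segments, and evolves one
#' predictor expression per segment by grammatical evolution, minimizing
#' the glucose-specific penalized fitness over the training days only.
#' The prediction horizon is 24 samples (120 min) by default.
#'
#' @param dataset a `patient_dataset` (from [simulate_patient()] or
#'   [read_patient_csv()]).
#' @param segments segment specification data.frame
#'   ([segment_specs_6h()], the default, or [postprandial_windows()]).
#' @param grammar a `ge_grammar`; defaults to the shipped
#'   [glucose_grammar()].
#' @param control a [ge_control()]; the per-segment run seed is
#'   `control$rng_seed + segment index - 1`.
#' @param pen_par a [pen_params()] object.
#' @param horizon prediction horizon in 5-min samples.
#' @param train_days 1-based day numbers used for fitting (default the
#'   first 10 of a 14-day record).
#' @param lag_max history depth required by the grammar (samples).
#' @return An object of class `ge_fit` with one evolved model per
#'   segment; see [predict.ge_fit()], [summary.ge_fit()],
#'   [coef.ge_fit()], [residuals.ge_fit()] and [plot.ge_fit()].
#' @examples
#' \donttest{
#' ds <- simulate_patient(seed = 7)
#' fit <- ge_fit(ds, control = ge_control(population_size = 20,
#'                                        generations = 20))
#' summary(fit)
#' }
#' @export
ge_fit <- function(dataset, segments = segment_specs_6h(),
                   grammar = glucose_grammar(), control = ge_control(),
                   pen_par = pen_params(), horizon = 24L,
                   train_days = 1:10, lag_max = 24L) {
  inputs <- model_inputs(dataset)
  models <- vector("list", nrow(segments))
  names(models) <- segments$label
  for (s in seq_len(nrow(segments))) {
    pairs <- segment_pairs(inputs, segments[s, ], horizon = horizon,
                           lag_max = lag_max, days = train_days)
    train <- ge_training_set(inputs$g, inputs$ra, inputs$iob,
                             pairs$n, pairs$target)
    ctl <- control
    ctl$rng_seed <- control$rng_seed + s - 1L
    run <- tryCatch(evolve(train, grammar, ctl, pen_par),
                    error = function(e)
                      stop("evolution failed for segment '",
                           segments$label[s], "': ", conditionMessage(e)))
    models[[s]] <- list(label = segments$label[s],
                        phenotype = run$best$phenotype,
                        fitness = run$best$fitness,
                        expression = run$best$expression,
                        seed = ctl$rng_seed,
                        n_train_pairs = nrow(pairs),
                        log = run$log)
  }
  structure(list(models = models, segments = segments,
                 control = control, pen_par = pen_par,
                 horizon = as.integer(horizon), lag_max = as.integer(lag_max),
                 train_days = as.integer(train_days),
                 patient_seed = dataset$seed),
            class = "ge_fit")
}

#' @export
print.ge_fit <- function(x, ...) {
  cat(sprintf("Piecewise GE glucose forecaster (%d segments, horizon %d min)\n",
              length(x$models), x$horizon * 5))
  for (m in x$models)
    cat(sprintf("  %-12s train gMSE %8.2f  %s\n", m$label, m$fitness,
                m$phenotype))
  invisible(x)
}

#' @export
summary.ge_fit <- function(object, ...) {
  df <- data.frame(
    segment = vapply(object$models, `[[`, character(1), "label"),
    train_gmse = vapply(object$models, `[[`, numeric(1), "fitness"),
    n_train_pairs = vapply(object$models, `[[`, numeric(1), "n_train_pairs"),
    expression = vapply(object$models, `[[`, character(1), "phenotype"),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(table = df, horizon_min = object$horizon * 5,
                 train_days = object$train_days),
            class = "summary.ge_fit")
}

#' @export
print.summary.ge_fit <- function(x, ...) {
  cat(sprintf("Horizon %d min; trained on days %s\n", x$horizon_min,
              paste(range(x$train_days), collapse = "-")))
  print(x$table, right = FALSE)
  invisible(x)
}

#' @export
coef.ge_fit <- function(object, ...) {
  vapply(object$models, `[[`, character(1), "phenotype")
}

#' Predict with a fitted piecewise forecaster
#'
#' Routes every predictable timestamp of `newdata` to the segment model
#' owning the *target* time (not the history time) and evaluates the
#' evolved expressions.  Timestamps whose target falls outside every
#' segment are dropped (with the default 6-h segments none are).
#'
#' @param object a [ge_fit()] model set.
#' @param newdata a `patient_dataset`; typically [slice_days()] of the
#'   held-out test days.
#' @param days optional day filter applied to target timestamps.
#' @param ... unused.
#' @return A data.frame with columns `n`, `m`, `time_min` (target time),
#'   `segment`, `reference` and `predicted`.
#' @export
predict.ge_fit <- function(object, newdata, days = NULL, ...) {
  inputs <- model_inputs(newdata)
  out <- NULL
  for (s in seq_len(nrow(object$segments))) {
    pairs <- tryCatch(
      segment_pairs(inputs, object$segments[s, ], horizon = object$horizon,
                    lag_max = object$lag_max, days = days),
      error = function(e) NULL)
    if (is.null(pairs)) next
    expr <- object$models[[s]]$expression
    if (is.null(expr)) stop("segment '", object$segments$label[s],
                            "' has no valid expression")
    pred <- evaluate_predictor(expr, inputs$g, inputs$ra, inputs$iob,
                               pairs$n)
    out <- rbind(out, data.frame(
      n = pairs$n, m = pairs$m,
      time_min = inputs$time_min[pairs$m],
      segment = object$segments$label[s],
      reference = pairs$target, predicted = pred,
      stringsAsFactors = FALSE))
  }
  if (is.null(out)) stop("no timestamp of 'newdata' falls in any segment")
  out[order(out$m), ]
}

#' @export
residuals.ge_fit <- function(object, newdata, ...) {
  pr <- predict(object, newdata, ...)
  stats::setNames(pr$reference - pr$predicted, pr$m)
}

#' Clarke error-grid plot of a fitted forecaster
#'
#' Scatters (reference, predicted) pairs over the error-grid zone
#' boundaries.
#'
#' @param x a [ge_fit()] object.
#' @param newdata a `patient_dataset` to predict on.
#' @param ... passed to [graphics::plot()].
#' @export
plot.ge_fit <- function(x, newdata, ...) {
  pr <- predict(x, newdata)
  zones <- ceg_classify(pr$reference, pmax(pr$predicted, 1))
  cols <- c(A = "forestgreen", B = "olivedrab3", C = "orange",
            D = "red", E = "darkred")
  graphics::plot(pr$reference, pr$predicted, col = cols[zones], pch = 16,
                 cex = 0.5, xlim = c(0, 400), ylim = c(0, 400),
                 xlab = "reference glucose (mg/dl)",
                 ylab = "predicted glucose (mg/dl)", ...)
  graphics::abline(0, 1, col = "grey40")
  graphics::abline(0, 1.2, lty = 2, col = "grey60")
  graphics::abline(0, 0.8, lty = 2, col = "grey60")
  graphics::abline(h = 70, v = 70, lty = 3, col = "grey70")
  graphics::legend("topleft", legend = names(cols), col = cols, pch = 16,
                   bty = "n", title = "CEG zone")
  invisible(pr)
}

#' Serialize / restore a fitted model set
#'
#' Models are stored as plain JSON holding the segment table, the
#' phenotype strings (the canonical text form of the evolved
#' expressions), the run configuration and penalty constants.  Reloading
#' re-parses the phenotypes, so predictions reproduce bit-exactly.
#'
#' @param object a [ge_fit()] object.
#' @param path file path.
#' @return `read_ge_fit` returns the restored `ge_fit`.
#' @export
write_ge_fit <- function(object, path) {
  payload <- list(
    segments = object$segments,
    models = lapply(object$models, function(m)
      m[c("label", "phenotype", "fitness", "seed", "n_train_pairs")]),
    control = unclass(object$control),
    pen_par = unclass(object$pen_par),
    horizon = object$horizon, lag_max = object$lag_max,
    train_days = object$train_days,
    patient_seed = object$patient_seed)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_ge_fit
#' @export
read_ge_fit <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  control <- do.call(ge_control, p$control[setdiff(names(p$control), NULL)])
  pen_par <- do.call(pen_params, p$pen_par)
  models <- lapply(p$models, function(m) {
    m <- as.list(m)
    m$expression <- parse_predictor(m$phenotype)
    m$log <- NULL
    m
  })
  structure(list(models = models,
                 segments = as.data.frame(p$segments),
                 control = control, pen_par = pen_par,
                 horizon = as.integer(p$horizon),
                 lag_max = as.integer(p$lag_max),
                 train_days = as.integer(p$train_days),
                 patient_seed = p$patient_seed),
            class = "ge_fit")
}
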