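#' Parameters of the clinical penalty function
#'
#' Constants of the glucose-specific penalty `Pen(g, ghat)` that inflates
#' prediction errors according to their clinical harmfulness:
#' overestimation in hypoglycemia (reference below `t_l`) and
#' underestimation in hyperglycemia (reference above `t_h`).
#' `alpha_l`/`alpha_h` are the weights of the two penalty terms,
#' `beta_l`/`beta_h` the widths of the glucose-axis transitions at
#' `t_l`/`t_h`, and `gamma_l`/`gamma_h` the widths (and onsets) of the
#' error-axis transitions.
#'
#' @param alpha_l,alpha_h penalty weights (>= 0).
#' @param beta_l,beta_h glucose-axis transition widths, mg/dl (> 0).
#' @param gamma_l,gamma_h error-axis transition scales, mg/dl (> 0).
#' @param t_l,t_h hypo-/hyperglycemia thresholds, mg/dl (`t_l < t_h`).
#' @return A list of class `pen_params`.
#' @export
pen_params <- function(alpha_l = 1.5, alpha_h = 1, beta_l = 30,
                       beta_h = 100, gamma_l = 10, gamma_h = 20,
                       t_l = 85, t_h = 155) {
  if (alpha_l < 0 || alpha_h < 0) stop("penalty weights must be >= 0")
  if (!(t_l < t_h)) stop("'t_l' must be below 't_h'")
  if (any(c(beta_l, beta_h, gamma_l, gamma_h) <= 0))
    stop("transition widths must be positive")
  structure(list(alpha_l = alpha_l, alpha_h = alpha_h, beta_l = beta_l,
                 beta_h = beta_h, gamma_l = gamma_l, gamma_h = gamma_h,
                 t_l = t_l, t_h = t_h),
            class = "pen_params")
}

# smooth rising transition: ~0 well below `center`, ~1 well above, with
# most of the rise inside a band of width `width`.
sigmoid_rise <- function(x, center, width) {
  stats::plogis(4 * (x - center) / width)
}

#' Clinical penalty factor
#'
#' \deqn{Pen = 1
#'   + \alpha_L\,\bar S(g; T_L, \beta_L)\, S(\hat g - g; \gamma_L)
#'   + \alpha_H\, S(g; T_H, \beta_H)\,\bar S(\hat g - g; \gamma_H)}
#' where `S`/`S-bar` are smooth rising/falling logistic transitions.  The
#' first term activates when the reference is hypoglycemic and the
#' prediction overestimates it; the second when the reference is
#' hyperglycemic and the prediction underestimates it.  `Pen` is bounded
#' in `(1, 1 + alpha_l + alpha_h)` and is approximately 1 wherever neither
#' dangerous regime applies.  The error-axis transitions are centered at
#' `+gamma_l` (overestimation) and `-gamma_h` (underestimation), so a
#' perfect prediction carries essentially no penalty.
#'
#' @param g reference glucose, mg/dl (> 0); vectorized.
#' @param g_hat predicted glucose, mg/dl; vectorized.
#' @param params a [pen_params()] object.
#' @return Penalty factors, same length as the inputs.
#' @examples
#' pen(50, 75)   # missed hypoglycemia: strongly penalized
#' pen(175, 150) # conservative in hyperglycemia: mildly penalized
#' @export
pen <- function(g, g_hat, params = pen_params()) {
  if (!inherits(params, "pen_params")) stop("'params' must be pen_params")
  if (any(!is.finite(g)) || any(g <= 0))
    stop("reference glucose must be positive and finite")
  e <- g_hat - g
  low  <- 1 - sigmoid_rise(g, params$t_l, params$beta_l)
  over <- sigmoid_rise(e, params$gamma_l, params$gamma_l)
  high <- sigmoid_rise(g, params$t_h, params$beta_h)
  under <- 1 - sigmoid_rise(e, -params$gamma_h, params$gamma_h)
  1 + params$alpha_l * low * over + params$alpha_h * high * under
}

check_paired <- function(g, g_hat) {
  if (length(g) != length(g_hat))
    stop("reference and prediction series must have equal length")
  if (!length(g)) stop("empty series")
  if (any(!is.finite(g)) || any(g <= 0))
    stop("reference glucose must be positive and finite")
}

#' Glucose-specific mean squared error
#'
#' Mean of the pointwise penalized squared errors,
#' `mean(Pen(g, ghat) * (g - ghat)^2)`: the fitness minimized by the
#' evolutionary engine.  Reduces to the plain MSE wherever the penalty is
#' inactive, and never falls below it.
#'
#' @inheritParams pen
#' @return A single nonnegative number (mg^2/dl^2).
#' @export
gmse <- function(g, g_hat, params = pen_params()) {
  check_paired(g, g_hat)
  mean(pen(g, g_hat, params) * (g - g_hat)^2)
}

#' Standard and glucose-weighted accuracy metrics
#'
#' The six-metric suite used to report forecast accuracy: RMSE, MAD
#' (mg/dl) and MARD (%), each alongside its glucose-weighted counterpart
#' in which the squared/absolute/relative error is multiplied pointwise by
#' the clinical penalty:
#' `gRMSE = sqrt(mean(Pen e^2))`, `gMAD = mean(Pen |e|)`,
#' `gMARD = 100 mean(Pen |e| / g)`.
#'
#' @inheritParams pen
#' @return A list of class `metrics_report` with elements `rmse`,
#'   `g_rmse`, `mad`, `g_mad` (mg/dl), `mard`, `g_mard` (%), and `n`.
#' @export
glucose_metrics <- function(g, g_hat, params = pen_params()) {
  check_paired(g, g_hat)
  e <- g - g_hat
  p <- pen(g, g_hat, params)
  structure(list(
    rmse   = sqrt(mean(e^2)),
    g_rmse = sqrt(mean(p * e^2)),
    mad    = mean(abs(e)),
    g_mad  = mean(p * abs(e)),
    mard   = 100 * mean(abs(e) / g),
    g_mard = 100 * mean(p * abs(e) / g),
    n = length(g)
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(paste0("RMSE %.2f  gRMSE %.2f  MAD %.2f  gMAD %.2f (mg/dl)",
                     "  MARD %.2f  gMARD %.2f (%%)  [n = %d]\n"),
              x$rmse, x$g_rmse, x$mad, x$g_mad, x$mard, x$g_mard, x$n))
  invisible(x)
}

#' Clarke error-grid classification
#'
#' Assigns each (reference, predicted) glucose pair to one of the five
#' zones of the Clarke error grid using the canonical published boundary
#' inequalities.  Zone A (clinically accurate) contains pairs within 20%
#' of the reference or with both values below 70 mg/dl; B is benign
#' error; C leads to overtreatment; D misses hypo-/hyperglycemia; E
#' confuses the two.  Boundary ties resolve toward the more benign zone
#' (the A test is applied first, inclusively).  Values above 400 mg/dl
#' are clamped to 400 (the grid's domain); non-positive values are a
#' domain error.
#'
#' @param g_ref,g_pred reference and predicted glucose, mg/dl; vectorized.
#' @return Character vector of zones `"A"`..`"E"`.
#' @export
ceg_classify <- function(g_ref, g_pred) {
  if (length(g_ref) != length(g_pred)) stop("lengths differ")
  if (any(!is.finite(g_ref)) || any(!is.finite(g_pred)) ||
      any(g_ref <= 0) || any(g_pred <= 0))
    stop("glucose values must be positive and finite")
  y <- pmin(g_ref, 400); yp <- pmin(g_pred, 400)
  zone <- rep("B", length(y))
  a <- (y <= 70 & yp <= 70) | (yp >= 0.8 * y & yp <= 1.2 * y)
  e <- !a & ((y >= 180 & yp <= 70) | (y <= 70 & yp >= 180))
  cc <- !a & !e &
    ((y >= 70 & y <= 290 & yp >= y + 110) |
     (y >= 130 & y <= 180 & yp <= (7 / 5) * y - 182))
  d <- !a & !e & !cc &
    ((y >= 240 & yp >= 70 & yp <= 180) |
     (y <= 175 / 3 & yp <= 180 & yp >= 70) |
     (y >= 175 / 3 & y <= 70 & yp >= (6 / 5) * y))
  zone[a] <- "A"; zone[e] <- "E"; zone[cc] <- "C"; zone[d] <- "D"
  zone
}

#' Clarke error-grid summary
#'
#' Per-zone counts and percentages for a paired series, with the A+B
#' percentage (clinically acceptable predictions) as the headline figure.
#'
#' @inheritParams ceg_classify
#' @return A list of class `ceg_counts` with `counts`, `percent` (named
#'   A-E), `ab_percent` and `n`.
#' @export
ceg_summary <- function(g_ref, g_pred) {
  zones <- ceg_classify(g_ref, g_pred)
  counts <- vapply(c("A", "B", "C", "D", "E"),
                   function(z) sum(zones == z), integer(1))
  percent <- 100 * counts / length(zones)
  structure(list(counts = counts, percent = percent,
                 ab_percent = unname(percent["A"] + percent["B"]),
                 n = length(zones)),
            class = "ceg_counts")
}

#' @export
print.ceg_counts <- function(x, ...) {
  cat(sprintf("Clarke error grid (n = %d): A+B = %.2f%%\n", x$n,
              x$ab_percent))
  print(round(x$percent, 2))
  invisible(x)
}
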