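# Tabular reporting: per-segment train/test metric rows in the standard
# 12-column layout (six accuracy metrics + five error-grid zones + A+B),
# with a "24 hour" summary row equal to the mean of the equal-volume
# segment rows.

metric_row <- function(reference, predicted, pen_par) {
  mr <- glucose_metrics(reference, predicted, pen_par)
  cg <- ceg_summary(reference, pmax(predicted, 1))
  data.frame(rmse = mr$rmse, g_rmse = mr$g_rmse, mad = mr$mad,
             g_mad = mr$g_mad, mard = mr$mard, g_mard = mr$g_mard,
             zone_ab = cg$ab_percent,
             zone_a = unname(cg$percent["A"]),
             zone_b = unname(cg$percent["B"]),
             zone_c = unname(cg$percent["C"]),
             zone_d = unname(cg$percent["D"]),
             zone_e = unname(cg$percent["E"]),
             n = length(reference))
}

#' Per-segment accuracy report for one patient
#'
#' Computes, for each segment of a prediction frame (from
#' [predict.ge_fit()]), the six accuracy metrics and the Clarke
#' error-grid zone percentages, and appends a `24 hour` row holding the
#' arithmetic mean of the segment rows (the segments carry equal data
#' volumes under the default 6-h tiling).
#'
#' @param predictions a data.frame with `segment`, `reference`,
#'   `predicted` columns.
#' @param pen_par a [pen_params()] object.
#' @return A data.frame, one row per segment plus the summary row.
#' @export
segment_report <- function(predictions, pen_par = pen_params()) {
  segs <- unique(predictions$segment)
  rows <- lapply(segs, function(sg) {
    d <- predictions[predictions$segment == sg, ]
    cbind(segment = sg, metric_row(d$reference, d$predicted, pen_par))
  })
  tab <- do.call(rbind, rows)
  summary_row <- cbind(segment = "24 hour",
                       as.data.frame(lapply(tab[-1], mean)))
  summary_row$n <- sum(tab$n)
  rbind(tab, summary_row)
}

#' Cohort-mean report
#'
#' Averages per-patient [segment_report()] tables row-wise (the cohort
#' mean of each metric for each segment).
#'
#' @param reports list of per-patient report data.frames with identical
#'   row layout.
#' @return A data.frame of the same shape holding cohort means (`n` is
#'   summed).
#' @export
cohort_report <- function(reports) {
  stopifnot(length(reports) >= 1)
  base <- reports[[1]]
  for (r in reports[-1])
    if (!identical(r$segment, base$segment))
      stop("reports must share the segment layout")
  out <- base
  num <- setdiff(names(base), c("segment", "n"))
  for (cn in num)
    out[[cn]] <- rowMeans(vapply(reports, `[[`, numeric(nrow(base)), cn))
  out$n <- rowSums(vapply(reports, `[[`, numeric(nrow(base)), "n"))
  out
}

#' Write a report table as CSV
#'
#' @param report a [segment_report()] or [cohort_report()] data.frame.
#' @param path file path.
#' @export
write_report_csv <- function(report, path) {
  utils::write.csv(report, path, row.names = FALSE)
  invisible(path)
}
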