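# Plain-text interchange format for patient records: one CSV row per
# 1-min grid point, columns time_min, cho_g, basal_u_per_min, bolus_u,
# smbg_mgdl, cgm_mgdl; empty cells mean "no event / no reading".

#' Write / read a patient dataset as CSV
#'
#' The on-disk format is a 1-minute-grid CSV with columns `time_min`,
#' `cho_g`, `basal_u_per_min`, `bolus_u`, `smbg_mgdl`, `cgm_mgdl`; empty
#' cells denote the absence of an event or reading.  Values are printed
#' with 17 significant digits, so a write/read cycle reproduces the
#' numbers exactly.
#'
#' @param dataset a [simulate_patient()] dataset (any object with `cgm`,
#'   `events` and `insulin` components on the standard grids).
#' @param path file path.
#' @return `read_patient_csv` returns a list of class `patient_dataset`
#'   (without the surrogate-internal true trace).
#' @export
write_patient_csv <- function(dataset, path) {
  total_min <- length(dataset$insulin$basal$values)
  tm <- seq_len(total_min) - 1L
  cho <- bol <- smbg <- cgm <- rep(NA_real_, total_min)
  ev <- dataset$events
  for (i in seq_len(nrow(ev))) {
    r <- ev$time[i] + 1L
    if (!is.na(ev$cho_g[i]) && ev$cho_g[i] > 0)
      cho[r] <- ifelse(is.na(cho[r]), 0, cho[r]) + ev$cho_g[i]
    if (!is.na(ev$bolus_u[i]) && ev$bolus_u[i] > 0)
      bol[r] <- ifelse(is.na(bol[r]), 0, bol[r]) + ev$bolus_u[i]
    if (!is.na(ev$smbg_mgdl[i]))
      smbg[r] <- ev$smbg_mgdl[i]
  }
  ct <- signal_time(dataset$cgm)
  cgm[ct + 1L] <- dataset$cgm$values
  df <- data.frame(time_min = tm, cho_g = cho,
                   basal_u_per_min = dataset$insulin$basal$values,
                   bolus_u = bol, smbg_mgdl = smbg, cgm_mgdl = cgm)
  num <- vapply(df, is.numeric, logical(1))
  out <- df
  for (j in which(num))
    out[[j]] <- ifelse(is.na(df[[j]]), "",
                       formatC(df[[j]], digits = 17, format = "g"))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_patient_csv
#' @export
read_patient_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_min", "cho_g", "basal_u_per_min", "bolus_u",
            "smbg_mgdl", "cgm_mgdl")
  if (!all(need %in% names(df)))
    stop("patient CSV must have columns: ", paste(need, collapse = ", "))
  for (nm in need) df[[nm]] <- as.numeric(df[[nm]])
  basal <- uniform_signal(df$basal_u_per_min, t0 = 0, dt = 1)
  has_b <- which(!is.na(df$bolus_u) & df$bolus_u > 0)
  delivery <- insulin_delivery(basal, df$time_min[has_b], df$bolus_u[has_b])
  cgm_rows <- which(!is.na(df$cgm_mgdl))
  dts <- unique(diff(df$time_min[cgm_rows]))
  if (length(dts) != 1L)
    stop("CGM readings must lie on a uniform grid")
  cgm <- uniform_signal(df$cgm_mgdl[cgm_rows],
                        t0 = df$time_min[cgm_rows[1]], dt = dts)
  has_e <- which((!is.na(df$cho_g) & df$cho_g > 0) |
                 (!is.na(df$bolus_u) & df$bolus_u > 0) |
                 !is.na(df$smbg_mgdl))
  ev <- data.frame(
    time = df$time_min[has_e],
    kind = ifelse(!is.na(df$cho_g[has_e]) & df$cho_g[has_e] > 0,
                  ifelse(!is.na(df$bolus_u[has_e]) & df$bolus_u[has_e] > 0,
                         "meal", "rescue"),
                  "smbg"),
    cho_g = ifelse(is.na(df$cho_g[has_e]), 0, df$cho_g[has_e]),
    cho_est_g = NA_real_,
    bolus_u = ifelse(is.na(df$bolus_u[has_e]), 0, df$bolus_u[has_e]),
    smbg_mgdl = df$smbg_mgdl[has_e],
    stringsAsFactors = FALSE)
  structure(list(cgm = cgm, events = ev, insulin = delivery,
                 true_bg = NULL, params = NULL,
                 scenario = NULL, seed = NA_integer_),
            class = "patient_dataset")
}

#' Write a cohort manifest
#'
#' @param cohort a [simulate_cohort()] result.
#' @param path file path.
#' @export
write_cohort_manifest <- function(cohort, path) {
  utils::write.csv(cohort$manifest, path, row.names = FALSE)
  invisible(path)
}
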