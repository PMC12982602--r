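# Validation surfaces: estimated-vs-historical consistency tables and
# parameter-recovery summaries for synthetic experiments.

#' Consistency table of estimated vs historical series
#'
#' Pearson R and RMSE per (region, degree), computed with the same
#' [pearson_r()] / [rmse()] operations used during calibration, plus pooled
#' rows per degree that concatenate all (region, year) pairs (scatter-plot
#' style pooling). R is reported only for groups with at least 3 years.
#'
#' @param ea_series Data frame with `region_id`, `degree`, `year`, `EA` (e.g.
#'   the `ea_series` attribute of [calibrate_all()]), or a
#'   `calibration_result`.
#' @param stats `historical_stats` with the matching HA values.
#' @return Data frame with `region_id`, `degree`, `n_years`, `R`,
#'   `RMSE_thousand_ha`; pooled rows carry region_id `"(pooled)"`.
#' @export
validate_series <- function(ea_series, stats) {
  if (inherits(ea_series, "calibration_result"))
    ea_series <- attr(ea_series, "ea_series")
  stopifnot(all(c("region_id", "degree", "year", "EA") %in% names(ea_series)))
  m <- merge(ea_series[c("region_id", "degree", "year", "EA")],
             stats[c("region_id", "degree", "year", "area_thousand_ha")],
             by = c("region_id", "degree", "year"))
  if (!nrow(m)) stop("validate_series: no overlapping (region, degree, year) keys")
  names(m)[names(m) == "area_thousand_ha"] <- "HA"
  m <- m[order(m$region_id, m$degree, m$year), ]
  one <- function(d, label) {
    data.frame(region_id = label, degree = d$degree[1], n_years = nrow(d),
               R = if (nrow(d) >= 3L) pearson_r(d$EA, d$HA) else NA_real_,
               RMSE_thousand_ha = rmse(d$EA, d$HA))
  }
  per <- do.call(rbind, lapply(
    split(m, list(m$region_id, m$degree), drop = TRUE),
    function(d) one(d, d$region_id[1])))
  pooled <- do.call(rbind, lapply(split(m, m$degree),
                                  function(d) one(d, "(pooled)")))
  out <- rbind(per, pooled)
  rownames(out) <- NULL
  out[order(out$region_id != "(pooled)", out$region_id,
            match(out$degree, DEGREES)), , drop = FALSE]
}

#' Parameter-recovery summary against synthetic ground truth
#'
#' Per (region, crop, degree): the threshold error `T_hat - T_true`, whether
#' the recovered window equals the truth window, and the achieved R / RMSE.
#'
#' @param truth A `synthetic_truth`.
#' @param calib A `calibration_result`.
#' @return Data frame with one row per (region, crop, degree).
#' @export
recovery_summary <- function(truth, calib) {
  m <- merge(as.data.frame(calib),
             truth$thresholds, by = c("region_id", "crop", "degree"),
             suffixes = c("_hat", "_true"))
  m <- merge(m, truth$windows, by = c("region_id", "crop"),
             suffixes = c("", "_true"))
  data.frame(
    region_id = m$region_id, crop = m$crop, degree = m$degree,
    T_hat = m$T_percent_hat, T_true = m$T_percent_true,
    delta_T = m$T_percent_hat - m$T_percent_true,
    window_match = m$window_start_doy == m$start_doy &
      m$window_end_doy == m$end_doy,
    R = m$R, RMSE = m$RMSE
  )[order(m$region_id, m$crop, match(m$degree, DEGREES)), ]
}
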