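#' @keywords internal
"_PACKAGE"

.support_modes <- c("NONE", "NASAL_CANNULA", "HFNC", "CPAP", "NIPPV",
                    "IMV", "HFOV")
.low_support_modes <- c("NONE", "NASAL_CANNULA", "HFNC")
.spo2_sites <- c("RIGHT_UPPER_LIMB", "LEFT_UPPER_LIMB", "LOWER_LIMB")

#' A pulse-oximetry reading
#'
#' @param value oxygen saturation in percent, in (0, 100].
#' @param site measurement site, one of \code{"RIGHT_UPPER_LIMB"},
#'   \code{"LEFT_UPPER_LIMB"}, \code{"LOWER_LIMB"} (preference is in that
#'   order: right upper limb is the preductal reference).
#' @param offset_hours signed time of the reading relative to the
#'   echocardiogram, in hours (negative = before the echo).
#' @return a one-row data frame with columns value, site, offset_hours.
#' @export
spo2_reading <- function(value, site, offset_hours = 0) {
  if (is.na(value) || value <= 0 || value > 100)
    abort_validation("SpO2 must be in (0, 100] percent")
  site <- match.arg(site, .spo2_sites)
  data.frame(value = as.numeric(value), site = site,
             offset_hours = as.numeric(offset_hours),
             stringsAsFactors = FALSE)
}

#' Respiratory support and oxygenation at the time of the echocardiogram
#'
#' Bundles the inputs of the oxygenation (HRF) sub-score: support mode, flow,
#' FiO2, mean airway pressure, the arterial gas (if any) with its time offset
#' from the echo, and any pulse-oximetry readings.
#'
#' @param mode support mode, one of \code{"NONE"}, \code{"NASAL_CANNULA"},
#'   \code{"HFNC"}, \code{"CPAP"}, \code{"NIPPV"}, \code{"IMV"},
#'   \code{"HFOV"}.
#' @param fio2 fraction of inspired oxygen in [0.21, 1.0]. Percent-scale
#'   values (> 1) are rejected with a unit error.
#' @param flow_lpm gas flow in L/min (nasal cannula / HFNC branch).
#' @param map_cmh2o mean airway pressure in cmH2O; required (> 0) for CPAP,
#'   NIPPV, IMV and HFOV.
#' @param pao2_mmhg arterial partial pressure of oxygen in mmHg, optional.
#' @param gas_offset_hours absolute time between the arterial gas and the
#'   echocardiogram in hours; required whenever \code{pao2_mmhg} is given.
#' @param spo2 data frame of pulse-oximetry readings as built by
#'   \code{\link{spo2_reading}} (rbind several for multiple readings).
#' @return an object of class \code{hrfph_ox_obs}.
#' @export
oxygenation_observation <- function(mode, fio2, flow_lpm = NA_real_,
                                    map_cmh2o = NA_real_,
                                    pao2_mmhg = NA_real_,
                                    gas_offset_hours = NA_real_,
                                    spo2 = NULL) {
  mode <- match.arg(mode, .support_modes)
  if (is.na(fio2)) abort_missing("FiO2 is required")
  if (fio2 > 1.0)
    abort_unit(sprintf(
      "FiO2 = %g looks percent-scaled; supply a fraction in [0.21, 1.0]", fio2))
  if (fio2 < 0.21) abort_validation("FiO2 below 0.21 is not physical")
  if (!is.na(flow_lpm) && flow_lpm < 0)
    abort_validation("flow_lpm must be non-negative")
  if (!(mode %in% .low_support_modes)) {
    if (is.na(map_cmh2o) || map_cmh2o <= 0)
      abort_validation(sprintf(
        "mode %s requires a positive mean airway pressure", mode))
  } else if (!is.na(map_cmh2o) && map_cmh2o < 0) {
    abort_validation("map_cmh2o must be non-negative")
  }
  if (!is.na(pao2_mmhg)) {
    if (pao2_mmhg <= 0) abort_domain("PaO2 must be positive")
    if (is.na(gas_offset_hours) || gas_offset_hours < 0)
      abort_validation("a PaO2 needs a non-negative gas_offset_hours")
  }
  if (!is.null(spo2)) {
    if (!is.data.frame(spo2) || nrow(spo2) == 0) {
      spo2 <- NULL
    } else {
      stopifnot(all(c("value", "site", "offset_hours") %in% names(spo2)))
      if (any(is.na(spo2$value)) || any(spo2$value <= 0) ||
          any(spo2$value > 100))
        abort_validation("every SpO2 value must be in (0, 100]")
      if (!all(spo2$site %in% .spo2_sites))
        abort_validation("unknown SpO2 site")
    }
  }
  structure(list(mode = mode, fio2 = as.numeric(fio2),
                 flow_lpm = as.numeric(flow_lpm),
                 map_cmh2o = as.numeric(map_cmh2o),
                 pao2_mmhg = as.numeric(pao2_mmhg),
                 gas_offset_hours = as.numeric(gas_offset_hours),
                 spo2 = spo2),
            class = "hrfph_ox_obs")
}

#' Oxygenation index
#'
#' OI = FiO2 x 100 x mean airway pressure / PaO2 (dimensionless).
#'
#' @param fio2 fraction of inspired oxygen in [0.21, 1.0].
#' @param map_cmh2o mean airway pressure in cmH2O (>= 0).
#' @param pao2_mmhg arterial partial pressure of oxygen in mmHg (> 0).
#' @return the OI; vectorized over its arguments.
#' @export
compute_oi <- function(fio2, map_cmh2o, pao2_mmhg) {
  if (any(is.na(fio2)) || any(fio2 < 0.21) || any(fio2 > 1.0))
    abort_validation("FiO2 must be a fraction in [0.21, 1.0]")
  if (any(is.na(map_cmh2o)) || any(map_cmh2o < 0))
    abort_validation("mean airway pressure must be non-negative")
  if (any(is.na(pao2_mmhg)) || any(pao2_mmhg <= 0))
    abort_domain("PaO2 must be positive")
  fio2 * 100 * map_cmh2o / pao2_mmhg
}

#' Oxygen saturation index
#'
#' OSI = FiO2 x 100 x mean airway pressure / SpO2, the non-invasive surrogate
#' of the OI (typically about OI/2).
#'
#' @param fio2 fraction of inspired oxygen in [0.21, 1.0].
#' @param map_cmh2o mean airway pressure in cmH2O (>= 0).
#' @param spo2_pct oxygen saturation in percent, in (0, 100].
#' @return the OSI; vectorized over its arguments.
#' @export
compute_osi <- function(fio2, map_cmh2o, spo2_pct) {
  if (any(is.na(fio2)) || any(fio2 < 0.21) || any(fio2 > 1.0))
    abort_validation("FiO2 must be a fraction in [0.21, 1.0]")
  if (any(is.na(map_cmh2o)) || any(map_cmh2o < 0))
    abort_validation("mean airway pressure must be non-negative")
  if (any(is.na(spo2_pct)) || any(spo2_pct <= 0))
    abort_domain("SpO2 must be positive")
  if (any(spo2_pct > 100)) abort_validation("SpO2 cannot exceed 100 percent")
  fio2 * 100 * map_cmh2o / spo2_pct
}

#' Select the preductal SpO2 reading
#'
#' Site preference is right upper limb > left upper limb > lower limb. Among
#' readings from the same (best available) site, the one nearest the
#' echocardiogram is chosen; when two are equidistant, the later one.
#'
#' @param readings data frame of readings (columns value, site,
#'   offset_hours), e.g. several \code{\link{spo2_reading}}s rbind-ed.
#' @return the selected one-row reading.
#' @export
select_spo2 <- function(readings) {
  if (is.null(readings) || !is.data.frame(readings) || nrow(readings) == 0)
    abort_missing("no SpO2 readings available")
  rank <- match(readings$site, .spo2_sites)
  if (anyNA(rank)) abort_validation("unknown SpO2 site")
  off <- readings$offset_hours
  off[is.na(off)] <- 0
  ord <- order(rank, abs(off), -off)
  readings[ord[1L], , drop = FALSE]
}

#' Choose OI or OSI for an observation
#'
#' The OI is used when an arterial gas is available within the configured
#' window of the echocardiogram (default 4 hours); otherwise the OSI is
#' computed from the preferred preductal SpO2 reading.
#'
#' @param obs an \code{\link{oxygenation_observation}}.
#' @param config an \code{\link{score_config}}.
#' @param window_hours optional override of the gas window.
#' @return a list with \code{kind} ("OI" or "OSI"), \code{value}, and for the
#'   OSI the selected \code{spo2} reading.
#' @export
select_severity_index <- function(obs, config = score_config(),
                                  window_hours = NULL) {
  stopifnot(inherits(obs, "hrfph_ox_obs"))
  if (is.null(window_hours)) window_hours <- config$gas_window_hours
  map <- if (is.na(obs$map_cmh2o)) 0 else obs$map_cmh2o
  if (!is.na(obs$pao2_mmhg) && !is.na(obs$gas_offset_hours) &&
      obs$gas_offset_hours <= window_hours) {
    return(list(kind = "OI",
                value = compute_oi(obs$fio2, map, obs$pao2_mmhg)))
  }
  if (is.null(obs$spo2))
    abort_missing(
      "no arterial gas within the window and no SpO2 reading available")
  r <- select_spo2(obs$spo2)
  list(kind = "OSI", value = compute_osi(obs$fio2, map, r$value), spo2 = r)
}

#' Oxygenation (HRF) sub-score, 0-5
#'
#' Neonates on no support, nasal cannula or HFNC score 0 or 1 (1 when flow is
#' at least 2 L/min or FiO2 at least 0.30). Neonates on CPAP, NIPPV, IMV or
#' HFOV score 2-5 by band lookup of the OI (arterial gas within the window)
#' or otherwise the OSI from the preferred preductal SpO2.
#'
#' @param obs an \code{\link{oxygenation_observation}}.
#' @param config an \code{\link{score_config}}.
#' @return a list of class \code{hrfph_hrf} with \code{score} (integer 0-5),
#'   \code{branch}, the severity \code{index} used (invasive branch) and the
#'   \code{band} chosen.
#' @export
oxygenation_score <- function(obs, config = score_config()) {
  stopifnot(inherits(obs, "hrfph_ox_obs"))
  validate_config(config)
  if (obs$mode %in% .low_support_modes) {
    flow <- if (is.na(obs$flow_lpm)) 0 else obs$flow_lpm
    hit_flow <- flow >= config$nc_flow_lpm
    hit_fio2 <- obs$fio2 >= config$nc_fio2
    score <- as.integer(hit_flow || hit_fio2)
    band <- if (score == 1L)
      sprintf("flow >= %g L/min or FiO2 >= %g -> 1",
              config$nc_flow_lpm, config$nc_fio2)
    else "below flow and FiO2 thresholds -> 0"
    return(structure(list(score = score, branch = "low_support",
                          index = NULL, band = band), class = "hrfph_hrf"))
  }
  idx <- select_severity_index(obs, config)
  breaks <- if (idx$kind == "OI") config$oi_breaks else config$osi_breaks
  score <- band_lookup(idx$value, breaks, base = 2L)
  band <- paste(idx$kind, band_label(idx$value, breaks, base = 2L))
  structure(list(score = as.integer(score), branch = "positive_pressure",
                 index = idx, band = band), class = "hrfph_hrf")
}
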