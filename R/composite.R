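.categories <- c("MILD", "MODERATE", "SEVERE")

#' Severity category of a total HRF/PH score
#'
#' Totals 0-5 are mild, 6-10 moderate, 11-15 severe (bounds inclusive as
#' printed; totals are integers so no rounding arises).
#'
#' @param total integer total score in [0, 15]; vectorized.
#' @param config an \code{\link{score_config}} (category breaks).
#' @return ordered factor with levels MILD < MODERATE < SEVERE.
#' @export
categorize <- function(total, config = score_config()) {
  if (any(is.na(total)) || any(total < 0) || any(total > 15) ||
      any(total != round(total)))
    abort_validation("total must be an integer in [0, 15]")
  factor(.categories[findInterval(total, config$category_breaks) + 1L],
         levels = .categories, ordered = TRUE)
}

#' Combine the sub-scores into the total HRF/PH score
#'
#' @param hrf oxygenation sub-score, integer 0-5 or an \code{hrfph_hrf}
#'   object.
#' @param ph echocardiographic sub-score, integer 0-10 or an \code{hrfph_ph}
#'   object.
#' @param config an \code{\link{score_config}}.
#' @return an object of class \code{hrfph_score} with fields \code{hrf},
#'   \code{ph}, \code{total} (0-15), \code{category} and an \code{audit}
#'   data frame of band lookups when built from component objects.
#' @export
total_score <- function(hrf, ph, config = score_config()) {
  audit <- NULL
  if (inherits(hrf, "hrfph_hrf")) {
    audit <- rbind(audit, data.frame(
      component = "oxygenation",
      input = if (is.null(hrf$index)) NA_real_ else hrf$index$value,
      band = hrf$band, stringsAsFactors = FALSE))
    hrf <- hrf$score
  }
  if (inherits(ph, "hrfph_ph")) {
    cm <- ph$components
    for (nm in setdiff(names(cm), "rvsp_mmhg"))
      audit <- rbind(audit, data.frame(
        component = nm, input = as.numeric(cm[[nm]]),
        band = sprintf("grade %d", as.integer(cm[[nm]])),
        stringsAsFactors = FALSE))
    if (ph$fallback_used)
      audit <- rbind(audit, data.frame(
        component = "tr_jet", input = NA_real_,
        band = "absent: 2 x IVS substitution", stringsAsFactors = FALSE))
    ph <- ph$score
  }
  if (is.na(hrf) || !(hrf %in% 0:5))
    abort_validation("hrf sub-score must be an integer in 0..5")
  if (is.na(ph) || !(ph %in% 0:10))
    abort_validation("ph sub-score must be an integer in 0..10")
  total <- as.integer(hrf + ph)
  structure(list(hrf = as.integer(hrf), ph = as.integer(ph), total = total,
                 category = categorize(total, config), audit = audit),
            class = "hrfph_score")
}

#' Score a single patient
#'
#' Runs the full pipeline: oxygenation sub-score from the respiratory-support
#' observation, PH sub-score from the echocardiogram, composite total and
#' severity category, with an audit trail of every band lookup.
#'
#' @param ox an \code{\link{oxygenation_observation}}.
#' @param echo an \code{\link{echo_observation}}.
#' @param config an \code{\link{score_config}}.
#' @return an \code{hrfph_score} object.
#' @export
score_patient <- function(ox, echo, config = score_config()) {
  total_score(oxygenation_score(ox, config), ph_score(echo, config), config)
}

#' @export
print.hrfph_score <- function(x, ...) {
  cat(sprintf("HRF/PH score: %d (HRF %d + PH %d) - %s\n",
              x$total, x$hrf, x$ph, as.character(x$category)))
  if (!is.null(x$audit)) {
    cat("components:\n")
    for (i in seq_len(nrow(x$audit)))
      cat(sprintf("  %-14s %-8s %s\n", x$audit$component[i],
                  ifelse(is.na(x$audit$input[i]), "",
                         format(signif(x$audit$input[i], 4))),
                  x$audit$band[i]))
  }
  invisible(x)
}

#' Vasoactive-inotropic score (VIS)
#'
#' Weighted sum of vasoactive infusion doses; under the default coefficients
#' VIS = dopamine + dobutamine + 10 x milrinone + 100 x epinephrine +
#' 100 x norepinephrine + 10000 x vasopressin, with catecholamines and
#' milrinone in micrograms/kg/min and vasopressin in U/kg/min.
#'
#' @param doses named numeric vector or list of doses; drugs not named are
#'   taken as zero. Names must be a subset of the configured coefficients.
#' @param config an \code{\link{score_config}}.
#' @return the VIS (dimensionless).
#' @export
vis <- function(doses, config = score_config()) {
  doses <- unlist(doses)
  if (length(doses) == 0) return(0)
  coefs <- config$vis_coefficients
  unknown <- setdiff(names(doses), names(coefs))
  if (is.null(names(doses)) || length(unknown))
    abort_validation(sprintf("unknown vasoactive drug(s): %s",
                             paste(unknown, collapse = ", ")))
  if (anyNA(doses) || any(doses < 0))
    abort_validation("doses must be non-negative")
  sum(coefs[names(doses)] * doses)
}

#' Enumerate attainable sub-scores and totals under a configuration
#'
#' Constructs representative observations in every band of every component
#' and runs them through the actual scoring pipeline, returning the sets of
#' attainable oxygenation sub-scores, PH sub-scores and totals. Under the
#' default configuration the totals cover exactly 0..15.
#'
#' @param config an \code{\link{score_config}}.
#' @return list with sorted unique \code{hrf}, \code{ph} and \code{total}
#'   integer vectors.
#' @export
attainable_scores <- function(config = score_config()) {
  # low-support branch: 0 and 1
  hrf <- c(
    oxygenation_score(oxygenation_observation("NASAL_CANNULA", fio2 = 0.21,
                                              flow_lpm = 0.5), config)$score,
    oxygenation_score(oxygenation_observation("HFNC", fio2 = 0.21,
                                              flow_lpm = config$nc_flow_lpm),
                      config)$score)
  # positive-pressure branch: one representative OI per band, realised with
  # PaO2 fixed at 50 mmHg and MAP solving OI = target
  edges <- c(0, config$oi_breaks)
  targets <- edges + c(diff(edges) / 2, 5)
  for (tg in targets) {
    map <- max(tg * 50 / 100, 1e-6)
    obs <- oxygenation_observation("IMV", fio2 = 1.0, map_cmh2o = map,
                                   pao2_mmhg = 50, gas_offset_hours = 0)
    hrf <- c(hrf, oxygenation_score(obs, config)$score)
  }
  # echo: one representative raw value per grade of each component
  tap_edges <- c(0, config$tapse_breaks_mm)
  tap_vals <- rev(tap_edges + c(diff(tap_edges) / 2, 2))  # grade 0 first
  sbp <- 60
  ratio_edges <- c(0, config$rvsp_ratio_breaks)
  ratio_vals <- ratio_edges + c(diff(ratio_edges) / 2, 0.2)
  tr_vals <- sqrt(ratio_vals * sbp / 4)
  ph <- integer(0)
  for (ivs in 0:3) for (tp in tap_vals) for (v in tr_vals) for (rvd in c(FALSE, TRUE)) {
    e <- echo_observation(ivs, tapse_mm = tp, tr_velocity_ms = v,
                          rv_dysfunction = rvd, systolic_bp_mmhg = sbp)
    ph <- c(ph, ph_score(e, config)$score)
  }
  # TR-absent fallback path contributes as well
  for (ivs in 0:3) for (tp in tap_vals) for (rvd in c(FALSE, TRUE)) {
    e <- echo_observation(ivs, tapse_mm = tp, rv_dysfunction = rvd,
                          systolic_bp_mmhg = sbp)
    ph <- c(ph, ph_score(e, config)$score)
  }
  hrf <- sort(unique(hrf))
  ph <- sort(unique(ph))
  list(hrf = hrf, ph = ph,
       total = sort(unique(as.integer(outer(hrf, ph, `+`)))))
}
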