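#' First-echocardiogram measurements entering the PH sub-score
#'
#' @param ivs_grade interventricular septal position grade 0-3 from the
#'   parasternal short axis (0 = normal bow into the right ventricle, 3 =
#'   bowing into the left ventricle), as read by the cardiologist.
#' @param tapse_mm tricuspid annular plane systolic excursion in mm
#'   (apical four-chamber window); may be \code{NA}.
#' @param tr_velocity_ms peak tricuspid regurgitant jet velocity in m/s;
#'   \code{NA} means no measurable jet (a legal state, handled by the septal
#'   fallback), not an error.
#' @param rv_dysfunction logical (or 0/1): right ventricular dysfunction
#'   present, per the cardiologist.
#' @param systolic_bp_mmhg systemic systolic blood pressure in mmHg (> 0).
#' @param age_at_echo_days postnatal age at the echocardiogram, days.
#' @return an object of class \code{hrfph_echo_obs}.
#' @export
echo_observation <- function(ivs_grade, tapse_mm = NA_real_,
                             tr_velocity_ms = NA_real_,
                             rv_dysfunction = FALSE,
                             systolic_bp_mmhg,
                             age_at_echo_days = NA_integer_) {
  if (is.na(ivs_grade) || !(ivs_grade %in% 0:3))
    abort_validation("ivs_grade must be an integer in 0..3")
  if (!is.na(tapse_mm) && tapse_mm < 0)
    abort_validation("tapse_mm must be non-negative")
  if (!is.na(tr_velocity_ms) && tr_velocity_ms <= 0)
    abort_domain("tr_velocity_ms must be positive when present")
  if (is.na(systolic_bp_mmhg) || systolic_bp_mmhg <= 0)
    abort_domain("systolic_bp_mmhg must be positive")
  rvd <- as.logical(rv_dysfunction)
  if (is.na(rvd)) abort_validation("rv_dysfunction must be TRUE/FALSE or 0/1")
  structure(list(ivs_grade = as.integer(ivs_grade),
                 tapse_mm = as.numeric(tapse_mm),
                 tr_velocity_ms = as.numeric(tr_velocity_ms),
                 rv_dysfunction = rvd,
                 systolic_bp_mmhg = as.numeric(systolic_bp_mmhg),
                 age_at_echo_days = as.integer(age_at_echo_days)),
            class = "hrfph_echo_obs")
}

#' Estimated right ventricular systolic pressure from the TR jet
#'
#' Simplified Bernoulli equation: RVsP = 4 v^2, with v the peak tricuspid
#' regurgitant jet velocity in m/s and RVsP in mmHg.
#'
#' @param tr_velocity_ms peak TR jet velocity in m/s (> 0).
#' @return RVsP in mmHg; vectorized.
#' @export
rvsp_from_tr <- function(tr_velocity_ms) {
  if (any(is.na(tr_velocity_ms)) || any(tr_velocity_ms <= 0))
    abort_domain("TR jet velocity must be positive")
  4 * tr_velocity_ms^2
}

#' Grade estimated RVsP against systemic pressure, 0-3
#'
#' The ratio RVsP / systolic BP is band-looked-up: under the defaults,
#' below half-systemic is 0, half- to two-thirds-systemic 1, up to systemic
#' 2, and systemic or suprasystemic 3.
#'
#' @param rvsp_mmhg estimated RVsP in mmHg (> 0).
#' @param systolic_bp_mmhg systemic systolic blood pressure in mmHg (> 0).
#' @param config an \code{\link{score_config}}.
#' @return integer grade 0-3; vectorized.
#' @export
grade_rvsp <- function(rvsp_mmhg, systolic_bp_mmhg, config = score_config()) {
  if (any(is.na(systolic_bp_mmhg)) || any(systolic_bp_mmhg <= 0))
    abort_domain("systolic blood pressure must be positive")
  if (any(is.na(rvsp_mmhg)) || any(rvsp_mmhg <= 0))
    abort_domain("RVsP must be positive")
  band_lookup(rvsp_mmhg / systolic_bp_mmhg, config$rvsp_ratio_breaks)
}

#' Grade TAPSE, 0-3
#'
#' Lower excursion means worse right ventricular longitudinal function and a
#' higher grade: under the defaults TAPSE >= 10 mm grades 0, [8, 10) 1,
#' [6, 8) 2, and below 6 mm 3.
#'
#' @param tapse_mm TAPSE in mm (>= 0).
#' @param config an \code{\link{score_config}}.
#' @return integer grade 0-3; vectorized.
#' @export
grade_tapse <- function(tapse_mm, config = score_config()) {
  if (any(is.na(tapse_mm)) || any(tapse_mm < 0))
    abort_validation("TAPSE must be non-negative")
  length(config$tapse_breaks_mm) - findInterval(tapse_mm, config$tapse_breaks_mm)
}

#' Echocardiographic (PH) sub-score, 0-10
#'
#' With a measurable TR jet the sub-score is the sum of the septal position
#' grade (0-3), the TAPSE grade (0-3), the RVsP grade (0-3) and one point for
#' right ventricular dysfunction. Without a measurable jet the RVsP cannot be
#' estimated, and the septal position score doubled stands in for the
#' combined septum + RVsP contribution (keeping the sub-score within 0-10):
#' 2 x IVS + TAPSE grade + dysfunction point.
#'
#' @param echo an \code{\link{echo_observation}}.
#' @param config an \code{\link{score_config}}; \code{tapse_default_mm}, if
#'   set, fills a missing TAPSE.
#' @return a list of class \code{hrfph_ph} with \code{score} (integer 0-10),
#'   itemized \code{components} and \code{fallback_used}.
#' @export
ph_score <- function(echo, config = score_config()) {
  stopifnot(inherits(echo, "hrfph_echo_obs"))
  validate_config(config)
  tapse <- echo$tapse_mm
  if (is.na(tapse)) {
    if (is.null(config$tapse_default_mm))
      abort_missing("TAPSE is missing and the config supplies no default")
    tapse <- config$tapse_default_mm
  }
  tg <- grade_tapse(tapse, config)
  rvd <- as.integer(echo$rv_dysfunction)
  if (!is.na(echo$tr_velocity_ms)) {
    rvsp <- rvsp_from_tr(echo$tr_velocity_ms)
    rg <- grade_rvsp(rvsp, echo$systolic_bp_mmhg, config)
    comps <- list(ivs = echo$ivs_grade, tapse = tg, rvsp = rg,
                  rv_dysfunction = rvd, rvsp_mmhg = rvsp)
    score <- echo$ivs_grade + tg + rg + rvd
    fb <- FALSE
  } else {
    comps <- list(ivs_doubled = 2L * echo$ivs_grade, tapse = tg,
                  rv_dysfunction = rvd)
    score <- 2L * echo$ivs_grade + tg + rvd
    fb <- TRUE
  }
  structure(list(score = as.integer(score), components = comps,
                 fallback_used = fb), class = "hrfph_ph")
}
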