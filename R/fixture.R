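#' Specification of the reconstructed 83-patient cohort
#'
#' Category-level constraints of the published cohort: category sizes
#' (5 mild, 65 moderate, 13 severe), per-category event counts for each
#' dichotomous outcome, the death/ECLS composite, selected demographics, and
#' per-category median/IQR anchors for the continuous durations. Continuous
#' anchors are reconstructions (patient-level data are unpublished) and are
#' flagged as such; only category-level counts are reproduction targets.
#'
#' @param category_n integer vector (mild, moderate, severe) summing to 83.
#' @param outcomes named list of per-category event-count vectors.
#' @param continuous named list of per-category \code{c(median, q1, q3)}
#'   anchors (NA where the category has no observations).
#' @param scores named list of per-category total-score multisets covering
#'   the observed range 2-12.
#' @return object of class \code{hrfph_fixture_spec}.
#' @export
fixture_spec <- function(
    category_n = c(mild = 5L, moderate = 65L, severe = 13L),
    outcomes = list(
      death_ecls        = c(0L, 12L, 10L),
      ecls              = c(0L, 8L, 8L),
      died              = c(0L, 7L, 7L),
      ino               = c(1L, 50L, 13L),
      vasoactive        = c(0L, 42L, 13L),
      imv               = c(1L, 49L, 13L),
      hfov              = c(0L, 41L, 13L),
      ventilated_week   = c(0L, 21L, 3L),
      ventilated_2week  = c(0L, 7L, 3L),
      los_over_week     = c(4L, 53L, 6L),
      male              = c(1L, 43L, 9L),
      meconium          = c(1L, 25L, 4L),
      lung_malformation = c(0L, 2L, 3L)),
    continuous = list(
      # reconstructed, not target: median, q1, q3 per category
      ino_hours  = list(mild = c(8, 8, 8), moderate = c(86, 57, 158),
                        severe = c(120, 58, 242)),
      imv_days   = list(mild = c(1, 1, 1), moderate = c(6.5, 4, 11),
                        severe = c(9, 4, 16)),
      los_days   = list(mild = c(16, 13, 23), moderate = c(19, 11, 33),
                        severe = c(32.5, 16, 76)),
      vis_max    = list(mild = NULL, moderate = c(14.5, 9, 27.5),
                        severe = c(25, 15, 45)),
      ecls_hours = list(mild = NULL, moderate = c(106, 96, 162),
                        severe = c(152, 86, 278))),
    scores = list(
      mild = c(2L, 3L, 4L, 5L, 5L),
      moderate = rep(6:10, times = c(8L, 12L, 15L, 15L, 15L)),
      severe = rep(11:12, times = c(7L, 6L)))) {
  spec <- structure(list(category_n = category_n, outcomes = outcomes,
                         continuous = continuous, scores = scores),
                    class = "hrfph_fixture_spec")
  validate_fixture_spec(spec)
  spec
}

validate_fixture_spec <- function(spec) {
  n <- spec$category_n
  if (length(n) != 3 || any(n < 0)) abort_consistency("need 3 category sizes")
  for (nm in names(spec$outcomes)) {
    k <- spec$outcomes[[nm]]
    if (length(k) != 3 || any(k < 0))
      abort_consistency(sprintf("outcome %s needs 3 non-negative counts", nm))
  }
  # survivor-denominator outcomes cannot exceed their denominators
  died <- spec$outcomes$died
  if (any(spec$outcomes$los_over_week > n - died))
    abort_consistency("los_over_week exceeds the survivor denominator")
  surv_vent <- spec$outcomes$imv - died  # every death occurred on support
  if (any(spec$outcomes$ventilated_week > surv_vent))
    abort_consistency("ventilated_week exceeds the ventilated-survivor denominator")
  for (i in 1:3) {
    de <- spec$outcomes$death_ecls[i]
    d <- died[i]; e <- spec$outcomes$ecls[i]
    overlap <- d + e - de
    if (de > n[i] || d > n[i] || e > n[i])
      abort_consistency("an event count exceeds its category size")
    if (overlap < 0)
      abort_consistency(sprintf(
        "category %d: died + ECLS - death/ECLS = %d + %d - %d < 0 violates inclusion-exclusion",
        i, d, e, de))
    if (de < max(d, e))
      abort_consistency(sprintf(
        "category %d: composite death/ECLS (%d) below max(died, ECLS) is impossible",
        i, de))
  }
  for (i in 1:3)
    if (length(spec$scores[[i]]) != n[i])
      abort_consistency("score multiset length must equal category size")
  invisible(spec)
}

# deterministic values matching a median/IQR anchor: evaluate the piecewise
# linear quantile function through (0,lo) (.25,q1) (.5,med) (.75,q3) (1,hi)
# at the mid-rank grid (reconstructed, not a reproduction target)
quantile_matched <- function(n, anchor) {
  if (n == 0 || is.null(anchor)) return(numeric(0))
  med <- anchor[1]; q1 <- anchor[2]; q3 <- anchor[3]
  if (n == 1) return(med)
  spread <- max(q3 - q1, 1e-6)
  lo <- max(q1 - 0.5 * spread, min(q1, med) * 0.5, 0.1)
  hi <- q3 + 1.5 * spread
  p <- (seq_len(n) - 0.5) / n
  stats::approx(c(0, 0.25, 0.5, 0.75, 1), c(lo, q1, med, q3, hi), xout = p)$y
}

# invert a target total score into raw measurements that score back to it
decompose_total <- function(total) {
  if (total <= 1) {
    hrf <- total; ph <- 0L
  } else {
    hrf <- max(2L, min(5L, total - 5L))
    ph <- total - hrf
  }
  # oxygenation raw inputs per sub-score
  ox <- switch(as.character(hrf),
    "0" = list(mode = "NASAL_CANNULA", flow_lpm = 1, fio2 = 0.21,
               map_cmh2o = NA, pao2_mmhg = NA, gas_offset_hours = NA,
               spo2_value_1 = 98),
    "1" = list(mode = "HFNC", flow_lpm = 2, fio2 = 0.25, map_cmh2o = NA,
               pao2_mmhg = NA, gas_offset_hours = NA, spo2_value_1 = 97),
    "2" = list(mode = "CPAP", flow_lpm = NA, fio2 = 0.30, map_cmh2o = 6,
               pao2_mmhg = NA, gas_offset_hours = NA, spo2_value_1 = 95),
    "3" = list(mode = "IMV", flow_lpm = NA, fio2 = 0.50, map_cmh2o = 10,
               pao2_mmhg = 42, gas_offset_hours = 1, spo2_value_1 = 93),
    "4" = list(mode = "IMV", flow_lpm = NA, fio2 = 0.80, map_cmh2o = 12,
               pao2_mmhg = 48, gas_offset_hours = 1, spo2_value_1 = 90),
    "5" = list(mode = "IMV", flow_lpm = NA, fio2 = 1.00, map_cmh2o = 16,
               pao2_mmhg = 40, gas_offset_hours = 1, spo2_value_1 = 85))
  # echo components, greedy decomposition: ivs then TAPSE then RVsP then RVD
  ivs <- min(3L, ph); r <- ph - ivs
  tg <- min(3L, r); r <- r - tg
  rg <- min(3L, r); r <- r - rg
  rvd <- r
  tapse_by_grade <- c(12, 9, 7, 5)
  rvsp_target <- c(18, 33.6, 45.6, 66)  # SBP 60: ratios .30 .56 .76 1.10
  c(ox,
    list(hrf = hrf, ph = ph,
         ivs_grade = ivs, tapse_mm = tapse_by_grade[tg + 1L],
         tr_velocity_ms = sqrt(rvsp_target[rg + 1L] / 4),
         rv_dysfunction = rvd, systolic_bp_mmhg = 60))
}

#' Reconstruct the deterministic fixture cohort
#'
#' Builds exactly 83 patient records satisfying every category-level count of
#' the specification: category sizes, each dichotomous outcome, and the
#' died/ECLS overlap implied by inclusion-exclusion (3 in the moderate
#' category, 5 in the severe; 8 overall). Each record carries a total score
#' consistent with its category (covering the observed range 2-12) together
#' with raw respiratory-support and echo measurements that reproduce that
#' score when run through the scoring pipeline. Survivor-only outcomes
#' (ventilation duration flags, durations, length of stay) are \code{NA} for
#' patients who died. Continuous durations are deterministic
#' quantile-matched reconstructions, not reproduction targets.
#'
#' @param spec a \code{\link{fixture_spec}}.
#' @param config an \code{\link{score_config}} (used only for category
#'   consistency of the assigned scores).
#' @return data frame of 83 patient records; the ventilated-denominator
#'   reading of the HFOV row is attached as attribute \code{"hfov_ventilated"}.
#' @export
reconstruct_fixture <- function(spec = fixture_spec(),
                                config = score_config()) {
  validate_fixture_spec(spec)
  n <- spec$category_n
  cats <- rep(.categories, times = n)
  recs <- vector("list", sum(n))
  idx <- 0L
  for (ci in 1:3) {
    scores <- spec$scores[[ci]]
    d <- spec$outcomes$died[ci]; e <- spec$outcomes$ecls[ci]
    overlap <- d + e - spec$outcomes$death_ecls[ci]
    ecls_idx <- seq_len(e)
    died_idx <- c(seq_len(overlap),
                  if (d > overlap) e + seq_len(d - overlap))
    first_k <- function(k) seq_len(k)
    ino_idx <- first_k(spec$outcomes$ino[ci])
    vaso_idx <- first_k(spec$outcomes$vasoactive[ci])
    imv_idx <- first_k(spec$outcomes$imv[ci])
    hfov_idx <- first_k(spec$outcomes$hfov[ci])
    male_idx <- first_k(spec$outcomes$male[ci])
    mec_idx <- first_k(spec$outcomes$meconium[ci])
    lung_idx <- first_k(spec$outcomes$lung_malformation[ci])
    surv <- setdiff(seq_len(n[ci]), died_idx)
    vent_surv <- intersect(imv_idx, surv)
    vw_idx <- vent_surv[seq_len(spec$outcomes$ventilated_week[ci])]
    v2_idx <- vw_idx[seq_len(spec$outcomes$ventilated_2week[ci])]
    losw_idx <- surv[seq_len(spec$outcomes$los_over_week[ci])]
    # continuous anchors, assigned over the relevant surviving subsets
    cat_name <- c("mild", "moderate", "severe")[ci]
    ino_surv <- intersect(ino_idx, surv)
    ecls_surv <- intersect(ecls_idx, surv)
    vals <- list(
      ino_hours = stats::setNames(
        quantile_matched(length(ino_surv), spec$continuous$ino_hours[[cat_name]]),
        ino_surv),
      imv_days = stats::setNames(
        quantile_matched(length(vent_surv), spec$continuous$imv_days[[cat_name]]),
        vent_surv),
      los_days = stats::setNames(
        quantile_matched(length(surv), spec$continuous$los_days[[cat_name]]),
        surv),
      vis_max = stats::setNames(
        quantile_matched(length(intersect(vaso_idx, surv)),
                         spec$continuous$vis_max[[cat_name]]),
        intersect(vaso_idx, surv)),
      ecls_hours = stats::setNames(
        quantile_matched(length(ecls_surv), spec$continuous$ecls_hours[[cat_name]]),
        ecls_surv))
    for (j in seq_len(n[ci])) {
      idx <- idx + 1L
      raw <- decompose_total(scores[j])
      getval <- function(field) {
        v <- vals[[field]][as.character(j)]
        if (length(v) == 0 || is.na(names(v))) NA_real_ else unname(v)
      }
      recs[[idx]] <- data.frame(
        id = sprintf("P%03d", idx),
        mode = raw$mode, flow_lpm = raw$flow_lpm, fio2 = raw$fio2,
        map_cmh2o = raw$map_cmh2o, pao2_mmhg = raw$pao2_mmhg,
        gas_offset_hours = raw$gas_offset_hours,
        spo2_value_1 = raw$spo2_value_1, spo2_site_1 = "RIGHT_UPPER_LIMB",
        spo2_offset_1 = 0,
        ivs_grade = raw$ivs_grade, tapse_mm = raw$tapse_mm,
        tr_velocity_ms = raw$tr_velocity_ms,
        rv_dysfunction = as.integer(raw$rv_dysfunction),
        systolic_bp_mmhg = raw$systolic_bp_mmhg, age_at_echo_days = 1L,
        assigned_total = scores[j],
        died = as.integer(j %in% died_idx),
        ecls = as.integer(j %in% ecls_idx),
        death_ecls = as.integer(j %in% died_idx || j %in% ecls_idx),
        ino = as.integer(j %in% ino_idx),
        vasoactive = as.integer(j %in% vaso_idx),
        imv = as.integer(j %in% imv_idx),
        hfov = as.integer(j %in% hfov_idx),
        male = as.integer(j %in% male_idx),
        meconium = as.integer(j %in% mec_idx),
        lung_malformation = as.integer(j %in% lung_idx),
        ventilated_week = if (j %in% vent_surv)
          as.integer(j %in% vw_idx) else NA_integer_,
        ventilated_2week = if (j %in% vent_surv)
          as.integer(j %in% v2_idx) else NA_integer_,
        los_over_week = if (j %in% surv)
          as.integer(j %in% losw_idx) else NA_integer_,
        ino_hours = getval("ino_hours"),
        imv_days = getval("imv_days"),
        los_days = getval("los_days"),
        vis_max = getval("vis_max"),
        ecls_hours = getval("ecls_hours"),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, recs)
  # records with hrf 0/1 have no measurable TR jet pathway issue: keep jet
  attr(out, "hfov_ventilated") <- list(numerator = spec$outcomes$hfov,
                                       denominator = spec$outcomes$imv)
  out
}
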