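#' Scoring configuration
#'
#' All thresholds of the HRF/PH score live in a single versioned configuration
#' object so that every cut point the bedside figure does not pin down exactly
#' remains overridable. Band tables are represented by their interior break
#' points: a breaks vector \code{c(b1, b2, b3)} defines the bands
#' \code{[0, b1), [b1, b2), [b2, b3), [b3, Inf)}, lower-inclusive and
#' upper-exclusive, so the table covers \code{[0, Inf)} with no gaps or
#' overlaps by construction.
#'
#' Defaults:
#' \itemize{
#'   \item nasal cannula / HFNC branch: score 1 when flow >= 2 L/min or
#'     FiO2 >= 0.30, else 0;
#'   \item OI bands (invasive/positive-pressure branch, scores 2..5):
#'     breaks at 10, 15, 25;
#'   \item OSI bands at half the OI cut points (OSI is conventionally about
#'     OI/2): breaks at 5, 7.5, 12.5;
#'   \item arterial gas usable within 4 hours of the echocardiogram;
#'   \item TAPSE grades 0..3 (lower excursion = higher grade) with breaks at
#'     6, 8, 10 mm, anchored to published term-neonate reference values;
#'   \item RVsP graded against systemic systolic pressure: ratio breaks at
#'     0.5, 2/3 and 1.0 (sub-half-systemic, mild, near-systemic,
#'     systemic/suprasystemic);
#'   \item vasoactive-inotropic score coefficients: dopamine 1, dobutamine 1,
#'     milrinone 10, epinephrine 100, norepinephrine 100, vasopressin 10000;
#'   \item severity categories: mild 0-5, moderate 6-10, severe 11-15
#'     (category breaks 6 and 11 on the total).
#' }
#'
#' @param gas_window_hours maximum age, in hours, of an arterial gas for the
#'   OI to be used instead of the OSI.
#' @param nc_flow_lpm flow threshold (L/min) scoring 1 on nasal cannula/HFNC.
#' @param nc_fio2 FiO2 threshold (fraction) scoring 1 on nasal cannula/HFNC.
#' @param oi_breaks,osi_breaks strictly increasing positive break points for
#'   the OI/OSI band tables mapping to scores 2..5.
#' @param tapse_breaks_mm strictly increasing TAPSE break points (mm); grades
#'   run 3 down to 0 as TAPSE increases.
#' @param rvsp_ratio_breaks strictly increasing break points on the
#'   RVsP / systolic BP ratio mapping to grades 0..3.
#' @param vis_coefficients named numeric vector of VIS dose weights
#'   (micrograms/kg/min except vasopressin, U/kg/min).
#' @param category_breaks two increasing integers on the 0-15 total: totals
#'   below the first are mild, below the second moderate, else severe.
#' @param tapse_default_mm optional TAPSE (mm) to substitute when a record is
#'   missing the measurement; \code{NULL} (default) makes missing TAPSE an
#'   error.
#' @param schema_version configuration schema version string.
#' @return an object of class \code{hrfph_config}.
#' @export
score_config <- function(gas_window_hours = 4,
                         nc_flow_lpm = 2,
                         nc_fio2 = 0.3,
                         oi_breaks = c(10, 15, 25),
                         osi_breaks = c(5, 7.5, 12.5),
                         tapse_breaks_mm = c(6, 8, 10),
                         rvsp_ratio_breaks = c(0.5, 2 / 3, 1),
                         vis_coefficients = c(dopamine = 1, dobutamine = 1,
                                              milrinone = 10, epinephrine = 100,
                                              norepinephrine = 100,
                                              vasopressin = 10000),
                         category_breaks = c(6, 11),
                         tapse_default_mm = NULL,
                         schema_version = "1.0") {
  cfg <- structure(list(
    schema_version = as.character(schema_version),
    gas_window_hours = as.numeric(gas_window_hours),
    nc_flow_lpm = as.numeric(nc_flow_lpm),
    nc_fio2 = as.numeric(nc_fio2),
    oi_breaks = as.numeric(oi_breaks),
    osi_breaks = as.numeric(osi_breaks),
    tapse_breaks_mm = as.numeric(tapse_breaks_mm),
    rvsp_ratio_breaks = as.numeric(rvsp_ratio_breaks),
    vis_coefficients = unlist(vis_coefficients),
    category_breaks = as.numeric(category_breaks),
    tapse_default_mm = if (is.null(tapse_default_mm)) NULL else
      as.numeric(tapse_default_mm)
  ), class = "hrfph_config")
  validate_config(cfg)
  cfg
}

#' Validate a scoring configuration
#'
#' Checks that every band table covers \code{[0, Inf)} without gaps or
#' overlaps (strictly increasing positive breaks), that thresholds and VIS
#' coefficients are non-negative, and that the category bounds are increasing
#' integers within 0-15.
#'
#' @param config an \code{hrfph_config} object.
#' @return \code{config}, invisibly; errors (class
#'   \code{hrfph_config_error}) otherwise.
#' @export
validate_config <- function(config) {
  if (!inherits(config, "hrfph_config"))
    abort_config("not an hrfph_config object")
  chk_breaks <- function(b, what, k = 3L) {
    if (length(b) != k || anyNA(b) || any(b <= 0) || any(diff(b) <= 0))
      abort_config(sprintf(
        "%s must be %d strictly increasing positive break points", what, k))
  }
  chk_breaks(config$oi_breaks, "oi_breaks")
  chk_breaks(config$osi_breaks, "osi_breaks")
  chk_breaks(config$tapse_breaks_mm, "tapse_breaks_mm")
  chk_breaks(config$rvsp_ratio_breaks, "rvsp_ratio_breaks")
  chk_breaks(config$category_breaks, "category_breaks", 2L)
  if (any(config$category_breaks > 15) ||
      any(config$category_breaks != round(config$category_breaks)))
    abort_config("category_breaks must be integers within the 0-15 total range")
  if (is.na(config$gas_window_hours) || config$gas_window_hours < 0)
    abort_config("gas_window_hours must be non-negative")
  if (config$nc_flow_lpm < 0) abort_config("nc_flow_lpm must be non-negative")
  if (is.na(config$nc_fio2) || config$nc_fio2 < 0.21 || config$nc_fio2 > 1)
    abort_config("nc_fio2 must be a fraction in [0.21, 1]")
  vc <- config$vis_coefficients
  if (is.null(names(vc)) || any(!nzchar(names(vc))) || anyNA(vc) || any(vc < 0))
    abort_config("vis_coefficients must be a named non-negative vector")
  if (!is.null(config$tapse_default_mm) && config$tapse_default_mm < 0)
    abort_config("tapse_default_mm must be non-negative")
  invisible(config)
}

# Lower-inclusive band lookup: value in [0, b1) -> base, [b1, b2) -> base+1, ...
band_lookup <- function(x, breaks, base = 0L) {
  base + findInterval(x, breaks)
}

# Human-readable label of the band containing x, for audit trails.
band_label <- function(x, breaks, base = 0L) {
  edges <- c(0, breaks, Inf)
  i <- findInterval(x, breaks) + 1L
  sprintf("[%g, %g) -> %d", edges[i], edges[i + 1L], base + i - 1L)
}

.config_keys <- c("schema_version", "gas_window_hours", "nc_flow_lpm",
                  "nc_fio2", "oi_breaks", "osi_breaks", "tapse_breaks_mm",
                  "rvsp_ratio_breaks", "vis_coefficients", "category_breaks",
                  "tapse_default_mm")

#' Read a scoring configuration from a YAML file
#'
#' Unrecognized keys are an error, not a warning; omitted keys take their
#' defaults. A missing \code{schema_version} is an error.
#'
#' @param path path to a YAML configuration file.
#' @return an \code{hrfph_config} object.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) abort_usage(sprintf("config file not found: %s", path))
  y <- tryCatch(yaml::read_yaml(path),
                error = function(e) abort_parse(sprintf(
                  "cannot parse config %s: %s", path, conditionMessage(e))))
  unknown <- setdiff(names(y), .config_keys)
  if (length(unknown))
    abort_config(sprintf("unrecognized config keys: %s",
                         paste(unknown, collapse = ", ")))
  if (is.null(y$schema_version))
    abort_config("config is missing schema_version")
  if (!is.null(y$vis_coefficients)) y$vis_coefficients <- unlist(y$vis_coefficients)
  do.call(score_config, y)
}

#' Write a scoring configuration to a YAML file
#'
#' @param config an \code{hrfph_config} object.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_config <- function(config, path) {
  validate_config(config)
  x <- unclass(config)
  x$vis_coefficients <- as.list(x$vis_coefficients)
  writeLines(yaml::as.yaml(x, precision = 15L), path)
  invisible(path)
}

#' @export
print.hrfph_config <- function(x, ...) {
  cat("HRF/PH scoring configuration (schema", x$schema_version, ")\n")
  cat("  gas window (h):     ", x$gas_window_hours, "\n")
  cat("  NC/HFNC thresholds: flow >=", x$nc_flow_lpm, "L/min or FiO2 >=",
      x$nc_fio2, "\n")
  cat("  OI breaks:          ", paste(x$oi_breaks, collapse = ", "), "\n")
  cat("  OSI breaks:         ", paste(x$osi_breaks, collapse = ", "), "\n")
  cat("  TAPSE breaks (mm):  ", paste(x$tapse_breaks_mm, collapse = ", "), "\n")
  cat("  RVsP/SBP breaks:    ", paste(signif(x$rvsp_ratio_breaks, 4),
                                      collapse = ", "), "\n")
  cat("  category breaks:    ", paste(x$category_breaks, collapse = ", "), "\n")
  invisible(x)
}
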