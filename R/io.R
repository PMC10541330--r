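# Patient-record CSV schema. Comma-separated, UTF-8, "." decimal point;
# hours/days are plain numbers. Empty cell = missing ("NA" accepted on read,
# never written). Unknown columns are preserved and passed through.

.numeric_cols <- c("flow_lpm", "fio2", "map_cmh2o", "pao2_mmhg",
                   "gas_offset_hours",
                   "spo2_value_1", "spo2_offset_1", "spo2_value_2",
                   "spo2_offset_2", "spo2_value_3", "spo2_offset_3",
                   "tapse_mm", "tr_velocity_ms", "systolic_bp_mmhg",
                   "ino_hours", "imv_days", "los_days", "vis_max",
                   "ecls_hours",
                   "dose_dopamine", "dose_dobutamine", "dose_milrinone",
                   "dose_epinephrine", "dose_norepinephrine",
                   "dose_vasopressin")
.integer_cols <- c("ivs_grade", "age_at_echo_days", "assigned_total")
.flag_cols <- c("rv_dysfunction", "died", "ecls", "death_ecls", "ino",
                "vasoactive", "imv", "hfov", "male", "meconium",
                "lung_malformation", "ventilated_week", "ventilated_2week",
                "los_over_week")
.character_cols <- c("id", "mode", "spo2_site_1", "spo2_site_2",
                     "spo2_site_3")

#' Read patient records from CSV
#'
#' Types and unit-checks every recognized column; per-row problems are
#' collected with their row numbers and raised together rather than silently
#' dropped. Percent-scale FiO2 (> 1) is a unit error; an empty
#' \code{tr_velocity_ms} cell is the legal no-measurable-jet state, not an
#' error. Unknown columns are preserved.
#'
#' @param path path to a CSV file with a header row.
#' @param config an \code{\link{score_config}} (reserved for schema options).
#' @return data frame of typed patient records.
#' @export
read_records <- function(path, config = score_config()) {
  if (!file.exists(path)) abort_usage(sprintf("file not found: %s", path))
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                    na.strings = c("", "NA"), check.names = FALSE),
    error = function(e) abort_parse(sprintf("cannot parse %s: %s", path,
                                            conditionMessage(e))))
  if (nrow(df) == 0) abort_parse("no records in file")
  problems <- character(0)
  note <- function(row, msg)
    problems <<- c(problems, sprintf("row %d: %s", row, msg))
  to_num <- function(col) {
    raw <- df[[col]]
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & is.na(val))
    for (r in bad) note(r, sprintf("unparseable %s: '%s'", col, raw[r]))
    val
  }
  for (col in intersect(.numeric_cols, names(df))) df[[col]] <- to_num(col)
  for (col in intersect(.integer_cols, names(df))) {
    v <- to_num(col)
    bad <- which(!is.na(v) & v != round(v))
    for (r in bad) note(r, sprintf("%s must be an integer", col))
    df[[col]] <- as.integer(round(v))
  }
  for (col in intersect(.flag_cols, names(df))) {
    raw <- toupper(trimws(ifelse(is.na(df[[col]]), "", df[[col]])))
    v <- ifelse(raw %in% c("1", "TRUE"), 1L,
                ifelse(raw %in% c("0", "FALSE"), 0L, NA_integer_))
    bad <- which(nzchar(raw) & is.na(v))
    for (r in bad) note(r, sprintf("%s must be 0/1: '%s'", col, df[[col]][r]))
    df[[col]] <- v
  }
  if ("fio2" %in% names(df)) {
    bad <- which(!is.na(df$fio2) & df$fio2 > 1)
    if (length(bad))
      abort_unit(sprintf(
        "percent-scale FiO2 (> 1.0) in row(s) %s; supply a fraction",
        paste(bad, collapse = ", ")))
  }
  if ("mode" %in% names(df)) {
    bad <- which(!is.na(df$mode) & !(df$mode %in% .support_modes))
    for (r in bad) note(r, sprintf("unknown support mode '%s'", df$mode[r]))
  }
  for (col in intersect(c("spo2_site_1", "spo2_site_2", "spo2_site_3"),
                        names(df))) {
    bad <- which(!is.na(df[[col]]) & !(df[[col]] %in% .spo2_sites))
    for (r in bad) note(r, sprintf("unknown SpO2 site '%s'", df[[col]][r]))
  }
  if (length(problems))
    abort_parse(paste(c("invalid records:", problems), collapse = "\n  "))
  df
}

#' Write patient records to CSV
#'
#' Missing values are written as empty cells; the write/read cycle is the
#' identity for valid files.
#'
#' @param records data frame of patient records.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_records <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

spo2_frame_from_row <- function(row) {
  out <- NULL
  for (k in 1:3) {
    v <- row[[paste0("spo2_value_", k)]]
    if (is.null(v) || is.na(v)) next
    s <- row[[paste0("spo2_site_", k)]]
    o <- row[[paste0("spo2_offset_", k)]]
    out <- rbind(out, data.frame(
      value = v, site = if (is.null(s) || is.na(s)) "RIGHT_UPPER_LIMB" else s,
      offset_hours = if (is.null(o) || is.na(o)) 0 else o,
      stringsAsFactors = FALSE))
  }
  out
}

get_or_na <- function(row, col) if (col %in% names(row)) row[[col]] else NA

#' Score a data frame of patient records
#'
#' Runs the full HRF/PH pipeline on every row and appends the columns
#' \code{hrf}, \code{ph}, \code{total}, \code{category}, \code{index_kind}
#' and \code{index_value}. Pure: the same records and configuration always
#' produce identical output.
#'
#' @param records data frame as returned by \code{\link{read_records}} (or
#'   built in code with the same column names).
#' @param config an \code{\link{score_config}}.
#' @return the input data frame with scoring columns appended.
#' @export
score_records <- function(records, config = score_config()) {
  n <- nrow(records)
  hrf <- ph <- total <- integer(n)
  cat_chr <- kind <- character(n)
  idxv <- numeric(n)
  for (i in seq_len(n)) {
    row <- records[i, , drop = FALSE]
    ox <- oxygenation_observation(
      mode = row$mode, fio2 = row$fio2,
      flow_lpm = as.numeric(get_or_na(row, "flow_lpm")),
      map_cmh2o = as.numeric(get_or_na(row, "map_cmh2o")),
      pao2_mmhg = as.numeric(get_or_na(row, "pao2_mmhg")),
      gas_offset_hours = as.numeric(get_or_na(row, "gas_offset_hours")),
      spo2 = spo2_frame_from_row(row))
    echo <- echo_observation(
      ivs_grade = row$ivs_grade,
      tapse_mm = as.numeric(get_or_na(row, "tapse_mm")),
      tr_velocity_ms = as.numeric(get_or_na(row, "tr_velocity_ms")),
      rv_dysfunction = get_or_na(row, "rv_dysfunction") %in% c(1, TRUE),
      systolic_bp_mmhg = row$systolic_bp_mmhg,
      age_at_echo_days = as.numeric(get_or_na(row, "age_at_echo_days")))
    res <- score_patient(ox, echo, config)
    hrf[i] <- res$hrf; ph[i] <- res$ph; total[i] <- res$total
    cat_chr[i] <- as.character(res$category)
    ox_row <- res$audit[res$audit$component == "oxygenation", , drop = FALSE]
    kind[i] <- if (nrow(ox_row) && !is.na(ox_row$input[1]))
      sub(" .*", "", ox_row$band[1]) else "NONE"
    idxv[i] <- if (nrow(ox_row)) ox_row$input[1] else NA_real_
  }
  records$hrf <- hrf
  records$ph <- ph
  records$total <- total
  records$category <- cat_chr
  records$index_kind <- kind
  records$index_value <- idxv
  records
}
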