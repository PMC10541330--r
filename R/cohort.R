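#' Severity-category by outcome contingency table
#'
#' Tabulates an outcome over the three severity categories. Records missing
#' the outcome are excluded and the exclusion count reported (some outcomes
#' are only defined among survivors, so their denominators shrink).
#'
#' @param records data frame of scored patients; must carry
#'   \code{category_col} and the named outcome column.
#' @param outcome name of the outcome column (0/1, logical or factor).
#' @param category_col name of the category column.
#' @return object of class \code{hrfph_cohort_table}: counts matrix with
#'   category rows in MILD < MODERATE < SEVERE order, row/column margins and
#'   \code{n_excluded}.
#' @export
build_table <- function(records, outcome, category_col = "category") {
  if (!is.data.frame(records) || nrow(records) == 0)
    abort_validation("records must be a non-empty data frame")
  for (col in c(category_col, outcome))
    if (!col %in% names(records))
      abort_validation(sprintf("unknown field: %s", col))
  cat_f <- factor(as.character(records[[category_col]]), levels = .categories)
  if (anyNA(cat_f)) abort_validation("records carry an unknown category")
  y <- records[[outcome]]
  keep <- !is.na(y)
  counts <- as.matrix(table(category = cat_f[keep], outcome = y[keep]))
  structure(list(outcome = outcome, counts = counts,
                 row_margins = rowSums(counts),
                 col_margins = colSums(counts),
                 n_excluded = sum(!keep)),
            class = "hrfph_cohort_table")
}

#' @export
print.hrfph_cohort_table <- function(x, ...) {
  cat(sprintf("Contingency table for '%s' (%d excluded)\n",
              x$outcome, x$n_excluded))
  print(x$counts)
  invisible(x)
}

as_count_matrix <- function(x) {
  if (inherits(x, "hrfph_cohort_table")) x <- x$counts
  m <- as.matrix(x)
  if (anyNA(m) || any(m < 0) || any(m != round(m)))
    abort_validation("table must contain non-negative integer counts")
  storage.mode(m) <- "double"
  m
}

# relative slack when comparing point probabilities (ties in the
# no-more-probable rule must not be lost to floating-point noise)
.fisher_releps <- 1e-7

fisher_2x2 <- function(m) {
  r1 <- sum(m[1, ]); n <- sum(m); c1 <- sum(m[, 1]); r2 <- n - r1
  a <- max(0, c1 - r2):min(r1, c1)
  lp <- lchoose(r1, a) + lchoose(r2, c1 - a) - lchoose(n, c1)
  lp_obs <- lp[a == m[1, 1]]
  min(1, sum(exp(lp[lp <= lp_obs + .fisher_releps])))
}

# Freeman-Halton: full enumeration of r x c tables with the observed margins;
# p = total probability of tables no more probable than the observed one.
fisher_rxc <- function(m) {
  rs <- rowSums(m); cs <- colSums(m); n <- sum(m)
  const <- sum(lgamma(rs + 1)) + sum(lgamma(cs + 1)) - lgamma(n + 1)
  lp_obs <- const - sum(lgamma(m + 1))
  nr <- nrow(m); nc <- ncol(m)
  total <- 0
  fill_row <- function(row, colrem, acc) {
    if (row == nr) {
      lp <- const - (acc + sum(lgamma(colrem + 1)))
      if (lp <= lp_obs + .fisher_releps) total <<- total + exp(lp)
      return(invisible())
    }
    fill_cell <- function(col, left, colrem, acc) {
      if (col == nc) {
        if (left <= colrem[nc]) {
          cr <- colrem; cr[nc] <- cr[nc] - left
          fill_row(row + 1L, cr, acc + lgamma(left + 1))
        }
        return(invisible())
      }
      for (v in 0:min(left, colrem[col])) {
        cr <- colrem; cr[col] <- cr[col] - v
        fill_cell(col + 1L, left - v, cr, acc + lgamma(v + 1))
      }
    }
    fill_cell(1L, rs[row], colrem, acc)
  }
  fill_row(1L, cs, 0)
  min(1, total)
}

#' Fisher's exact test
#'
#' Two-sided exact test of independence on a contingency table. 2x2 tables
#' use hypergeometric tail summation with the point-probability rule (the
#' two-sided p is the total probability of tables whose probability does not
#' exceed the observed one); r x c tables use the Freeman-Halton extension by
#' full enumeration over tables with the observed margins. Guarded to tables
#' with total n <= 500.
#'
#' @param table a count matrix or \code{\link{build_table}} result.
#' @return the two-sided p-value, in (0, 1].
#' @export
fisher_exact <- function(table) {
  m <- as_count_matrix(table)
  n <- sum(m)
  if (n == 0) abort_degenerate("table has no observations")
  if (n > 500) abort_validation("exact enumeration guarded to n <= 500")
  # zero margins carry no information; drop them (a table left with a single
  # row or column has exactly one attainable configuration: p = 1)
  m <- m[rowSums(m) > 0, colSums(m) > 0, drop = FALSE]
  if (nrow(m) < 2 || ncol(m) < 2) return(1.0)
  if (nrow(m) == 2 && ncol(m) == 2) fisher_2x2(m) else fisher_rxc(m)
}

#' Linear regression with heteroskedasticity-consistent standard errors
#'
#' Ordinary least squares point estimates with HC1 sandwich standard errors
#' and t-based Wald p-values (the convention of Stata's \code{robust}
#' option).
#'
#' @param y outcome vector, or a formula.
#' @param x predictor vector/matrix (when \code{y} is a vector), or a data
#'   frame (when \code{y} is a formula).
#' @return object of class \code{hrfph_robust_fit} with \code{coefficients},
#'   \code{robust_se}, \code{p_value}, \code{n} and the underlying
#'   \code{lm} fit.
#' @export
robust_ols <- function(y, x) {
  if (inherits(y, "formula")) {
    fit <- stats::lm(y, data = x)
  } else {
    y <- as.numeric(y)
    if (anyNA(y) || anyNA(x)) abort_validation("missing values in y or x")
    dat <- data.frame(y = y, x = x)
    fit <- stats::lm(y ~ ., data = dat)
  }
  X <- stats::model.matrix(fit)
  if (fit$rank < ncol(X))
    abort_singular("design matrix is rank deficient")
  if (nrow(X) <= ncol(X))
    abort_validation("need more observations than predictors")
  V <- sandwich::vcovHC(fit, type = "HC1")
  se <- sqrt(diag(V))
  b <- stats::coef(fit)
  tval <- b / se
  p <- 2 * stats::pt(-abs(tval), df = fit$df.residual)
  structure(list(coefficients = b, robust_se = se, t_value = tval,
                 p_value = p, n = nrow(X), fit = fit),
            class = "hrfph_robust_fit")
}

#' @export
print.hrfph_robust_fit <- function(x, ...) {
  cat(sprintf("OLS with HC1 robust standard errors (n = %d)\n", x$n))
  print(data.frame(estimate = x$coefficients, robust_se = x$robust_se,
                   t = x$t_value, p = x$p_value))
  invisible(x)
}

# round half away from zero, for percent display
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Summarize an outcome column
#'
#' Dichotomous (0/1 or logical) outcomes are summarized as count,
#' denominator and percent; continuous ones as median and interquartile
#' range (linear interpolation between order statistics). Missing values
#' shrink the denominator.
#'
#' @param x outcome vector.
#' @param type \code{"auto"} (default: dichotomous iff all non-missing
#'   values are in {0, 1}), \code{"dichotomous"} or \code{"continuous"}.
#' @return for dichotomous: list(count, denominator, percent,
#'   percent_display); for continuous: list(median, q1, q3, n).
#' @export
summarize_outcome <- function(x, type = c("auto", "dichotomous",
                                          "continuous")) {
  type <- match.arg(type)
  x <- x[!is.na(x)]
  if (length(x) == 0) abort_missing("all values of the field are missing")
  if (type == "auto")
    type <- if (all(x %in% c(0, 1))) "dichotomous" else "continuous"
  if (type == "dichotomous") {
    x <- as.numeric(as.logical(x))
    pct <- 100 * sum(x) / length(x)
    list(count = sum(x), denominator = length(x), percent = pct,
         percent_display = round_half_away(pct))
  } else {
    q <- unname(stats::quantile(as.numeric(x), c(0.25, 0.5, 0.75), type = 7))
    list(median = q[2], q1 = q[1], q3 = q[3], n = length(x))
  }
}

.default_dichotomous <- c("death_ecls", "ecls", "died", "ino", "vasoactive",
                          "imv", "hfov", "ventilated_week",
                          "ventilated_2week", "los_over_week")
.default_continuous <- c("ino_hours", "imv_days", "los_days", "vis_max",
                         "ecls_hours")

#' Cohort-level association analysis
#'
#' Reproduces the outcome-by-severity-category analysis: for each
#' dichotomous outcome a 3 x 2 contingency table, Fisher's exact p, and an
#' ordinary maximum-likelihood logistic fit on the category index (flagged
#' non-exact: the conditional-exact logistic procedure is out of scope); for
#' each continuous outcome, per-category median/IQR and a linear regression
#' of the outcome on the category index with HC1 robust standard errors,
#' restricted to records with the outcome observed (several durations are
#' defined only among survivors).
#'
#' @param scored data frame of scored patient records (needs a
#'   \code{category} column, e.g. from \code{\link{score_records}}).
#' @param dichotomous,continuous outcome column names to analyze; columns
#'   absent from \code{scored} are skipped.
#' @param config an \code{\link{score_config}}.
#' @return object of class \code{hrfph_analysis}.
#' @export
cohort_analysis <- function(scored,
                            dichotomous = .default_dichotomous,
                            continuous = .default_continuous,
                            config = score_config()) {
  if (!"category" %in% names(scored))
    abort_validation("records are not scored: no category column")
  cat_f <- factor(as.character(scored$category), levels = .categories)
  cat_idx <- as.integer(cat_f)
  n_cat <- table(cat_f)

  dich <- list()
  for (oc in intersect(dichotomous, names(scored))) {
    tab <- build_table(scored, oc)
    keep <- !is.na(scored[[oc]])
    y <- as.numeric(scored[[oc]][keep])
    p_fisher <- fisher_exact(tab)
    logit <- tryCatch(
      suppressWarnings(stats::glm(y ~ cat_idx[keep], family = stats::binomial())),
      error = function(e) NULL)
    per_cat <- lapply(.categories, function(cc) {
      v <- scored[[oc]][keep][cat_f[keep] == cc]
      if (length(v) == 0) list(count = 0, denominator = 0, percent = NA_real_,
                               percent_display = NA_real_)
      else summarize_outcome(v, "dichotomous")
    })
    names(per_cat) <- .categories
    dich[[oc]] <- list(table = tab, per_category = per_cat,
                       p_fisher = p_fisher,
                       p_logistic = if (is.null(logit)) NA_real_ else
                         summary(logit)$coefficients[2, 4],
                       logistic_method = "ml_logistic_non_exact")
  }

  cont <- list()
  for (oc in intersect(continuous, names(scored))) {
    keep <- !is.na(scored[[oc]])
    if (!any(keep)) next
    per_cat <- lapply(.categories, function(cc) {
      v <- scored[[oc]][keep][cat_f[keep] == cc]
      if (length(v) == 0) NULL else summarize_outcome(v, "continuous")
    })
    names(per_cat) <- .categories
    fit <- if (length(unique(cat_idx[keep])) > 1 && sum(keep) > 2)
      robust_ols(as.numeric(scored[[oc]][keep]), cat_idx[keep]) else NULL
    cont[[oc]] <- list(per_category = per_cat,
                       p_robust = if (is.null(fit)) NA_real_ else
                         fit$p_value[2],
                       fit = fit, n = sum(keep))
  }

  structure(list(n_per_category = as.integer(n_cat),
                 n_total = length(cat_idx),
                 dichotomous = dich, continuous = cont),
            class = "hrfph_analysis")
}

fmt_p <- function(p) {
  if (is.na(p)) return("")
  if (p < 0.0001) "<0.0001" else sprintf("%.2g", p)
}

#' Render an analysis as a report table
#'
#' One row per outcome, columns per severity category ("n (pct)" for
#' dichotomous outcomes, "median (q1-q3)" for continuous ones) plus the
#' p-value, mirroring the shape of a published outcome table.
#'
#' @param x an \code{hrfph_analysis}.
#' @return a data frame.
#' @export
analysis_report <- function(x) {
  stopifnot(inherits(x, "hrfph_analysis"))
  rows <- list()
  for (oc in names(x$dichotomous)) {
    d <- x$dichotomous[[oc]]
    cells <- vapply(.categories, function(cc) {
      s <- d$per_category[[cc]]
      if (s$denominator == 0) return("-")
      sprintf("%d/%d (%d)", s$count, s$denominator, s$percent_display)
    }, character(1))
    rows[[length(rows) + 1L]] <- data.frame(
      outcome = oc, type = "dichotomous", mild = cells[1], moderate = cells[2],
      severe = cells[3], p = fmt_p(d$p_fisher), test = "fisher_exact",
      stringsAsFactors = FALSE)
  }
  for (oc in names(x$continuous)) {
    d <- x$continuous[[oc]]
    cells <- vapply(.categories, function(cc) {
      s <- d$per_category[[cc]]
      if (is.null(s)) return("-")
      sprintf("%g (%g-%g)", s$median, s$q1, s$q3)
    }, character(1))
    rows[[length(rows) + 1L]] <- data.frame(
      outcome = oc, type = "continuous", mild = cells[1], moderate = cells[2],
      severe = cells[3], p = fmt_p(d$p_robust), test = "robust_ols",
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' @export
print.hrfph_analysis <- function(x, ...) {
  cat(sprintf("HRF/PH cohort analysis: n = %d (mild %d, moderate %d, severe %d)\n",
              x$n_total, x$n_per_category[1], x$n_per_category[2],
              x$n_per_category[3]))
  rep <- analysis_report(x)
  if (!is.null(rep)) print(rep, row.names = FALSE)
  invisible(x)
}

#' @export
summary.hrfph_analysis <- function(object, ...) {
  print(object)
  invisible(object)
}

#' Write an analysis report to CSV
#'
#' @param x an \code{hrfph_analysis}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_report <- function(x, path) {
  utils::write.csv(analysis_report(x), path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
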