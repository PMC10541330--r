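# Shorthand constructors used across test files.

ox_nc <- function(flow = 1, fio2 = 0.21, mode = "NASAL_CANNULA")
  oxygenation_observation(mode, fio2 = fio2, flow_lpm = flow)

ox_imv <- function(fio2, map, pao2 = NA, gas = NA, spo2 = NULL,
                   mode = "IMV")
  oxygenation_observation(mode, fio2 = fio2, map_cmh2o = map,
                          pao2_mmhg = pao2, gas_offset_hours = gas,
                          spo2 = spo2)

echo_simple <- function(ivs = 0, tapse = 12, v = NA, rvd = FALSE, sbp = 60)
  echo_observation(ivs, tapse_mm = tapse, tr_velocity_ms = v,
                   rv_dysfunction = rvd, systolic_bp_mmhg = sbp)

# independent oracle for band tables: explicit interval walk, no findInterval
interval_oracle <- function(x, breaks, base = 0L) {
  edges <- c(0, breaks, Inf)
  for (i in seq_len(length(edges) - 1L))
    if (x >= edges[i] && x < edges[i + 1L]) return(base + i - 1L)
  stop("uncovered value")
}

# brute-force two-sided Fisher oracle: generate every table with the observed
# margins row by row from an expand.grid of row compositions, probability by
# exact log-factorials, point-probability two-sided rule
fisher_oracle <- function(m) {
  rs <- rowSums(m); cs <- colSums(m); n <- sum(m)
  logp <- function(tab)
    sum(lfactorial(rs)) + sum(lfactorial(cs)) - lfactorial(n) -
      sum(lfactorial(tab))
  lp_obs <- logp(m)
  tabs <- list()
  gen <- function(row, acc) {
    placed <- if (nrow(acc)) colSums(acc) else numeric(ncol(m))
    if (row == nrow(m)) {
      last <- cs - placed
      if (all(last >= 0) && sum(last) == rs[row])
        tabs[[length(tabs) + 1L]] <<- rbind(acc, last)
      return(invisible())
    }
    rem <- cs - placed
    cells <- expand.grid(lapply(rem, function(cj) 0:max(cj, 0)))
    cells <- cells[rowSums(cells) == rs[row], , drop = FALSE]
    for (k in seq_len(nrow(cells))) gen(row + 1L,
                                        rbind(acc, as.numeric(cells[k, ])))
  }
  gen(1L, matrix(numeric(0), nrow = 0, ncol = ncol(m)))
  p <- 0
  for (tb in tabs) {
    lp <- logp(tb)
    if (lp <= lp_obs + 1e-7) p <- p + exp(lp)
  }
  min(1, p)
}

# hand-coded HC1 sandwich standard errors
hc1_oracle <- function(y, X) {
  XtXi <- solve(t(X) %*% X)
  b <- XtXi %*% t(X) %*% y
  e <- as.numeric(y - X %*% b)
  n <- nrow(X); k <- ncol(X)
  meat <- t(X) %*% diag(e^2) %*% X
  V <- (n / (n - k)) * XtXi %*% meat %*% XtXi
  list(coef = as.numeric(b), se = unname(sqrt(diag(V))))
}

# random valid r x c count table with total n
random_table <- function(nr, nc, n)
  matrix(as.numeric(stats::rmultinom(1, n, rep(1, nr * nc))), nrow = nr)
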