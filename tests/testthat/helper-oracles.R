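# Independent brute-force oracles for the agreement metrics, coded from the
# bare formulas with explicit loops, deliberately separate from the package
# implementations.

oracle_nrmse <- function(test, ref) {
  se <- 0
  for (i in seq_along(test)) se <- se + (test[i] - ref[i])^2
  sqrt(se / length(test)) / (max(ref) - min(ref))
}

oracle_rho <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  num <- 0; dx <- 0; dy <- 0
  for (i in seq_len(n)) {
    num <- num + (x[i] - mx) * (y[i] - my)
    dx <- dx + (x[i] - mx)^2
    dy <- dy + (y[i] - my)^2
  }
  num / sqrt(dx * dy)
}

oracle_slope <- function(y, t) {
  n <- length(y)
  mt <- sum(t) / n; my <- sum(y) / n
  num <- 0; den <- 0
  for (i in seq_len(n)) {
    num <- num + (t[i] - mt) * (y[i] - my)
    den <- den + (t[i] - mt)^2
  }
  num / den
}

oracle_ba <- function(test, ref) {
  d <- numeric(length(test))
  for (i in seq_along(test)) d[i] <- test[i] - ref[i]
  m <- mean(d); s <- sd(d)
  c(m, m - 1.96 * s, m + 1.96 * s)
}

oracle_ttest <- function(values, mu0 = 0) {
  n <- length(values)
  tstat <- (mean(values) - mu0) / (sd(values) / sqrt(n))
  p <- 2 * pt(-abs(tstat), df = n - 1)
  c(tstat, p)
}

# O(n^2) double-loop cross-approximate entropy with the same standardization
# and unmatched-template exclusion convention as the package definition
oracle_xapen <- function(x, y, m = 2L, r = 0.2) {
  std <- function(v) if (sd(v) > 0) (v - mean(v)) / sd(v) else v - mean(v)
  x <- std(x); y <- std(y)
  phi <- function(mm) {
    nt <- length(x) - mm + 1L
    logs <- c()
    for (i in seq_len(nt)) {
      cnt <- 0L
      for (j in seq_len(nt)) {
        d <- 0
        for (k in 0:(mm - 1L)) d <- max(d, abs(x[i + k] - y[j + k]))
        if (d <= r) cnt <- cnt + 1L
      }
      if (cnt > 0L) logs <- c(logs, log(cnt / nt))
    }
    mean(logs)
  }
  phi(m) - phi(m + 1L)
}
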