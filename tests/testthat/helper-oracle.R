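# Independent brute-force oracles for the 2x2 statistics. These deliberately
# follow a different computational route from the package (cell-wise
# observed/expected sums, literal moment formulas) so that agreement is a
# genuine cross-check.

oracle_ror <- function(a, b, c, d, conf = 0.95) {
  z <- qnorm((1 + conf) / 2)
  est <- (a / b) / (c / d)               # odds ratio via row odds
  se <- sqrt(sum(1 / c(a, b, c, d)))
  list(est = est, lo = exp(log(est) - z * se), hi = exp(log(est) + z * se))
}

oracle_prr <- function(a, b, c, d, conf = 0.95) {
  z <- qnorm((1 + conf) / 2)
  est <- (a / (a + b)) / (c / (c + d))
  se <- sqrt(1 / a - 1 / (a + b) + 1 / c - 1 / (c + d))
  list(est = est, lo = exp(log(est) - z * se), hi = exp(log(est) + z * se))
}

# Pearson / Yates via the textbook observed-expected cell sum
oracle_chisq <- function(a, b, c, d, yates = FALSE) {
  o <- c(a, b, c, d)
  n <- sum(o)
  e <- c((a + b) * (a + c), (a + b) * (b + d),
         (c + d) * (a + c), (c + d) * (b + d)) / n
  dev <- abs(o - e)
  if (yates) dev <- pmax(dev - 0.5, 0)
  sum(dev^2 / e)
}

# literal closed-form BCPNN posterior moments (priors alpha1=beta1=1,
# alpha=beta=2, gamma11=1)
oracle_bate <- function(a, b, c, d) {
  n <- a + b + c + d
  a1 <- 1; b1 <- 1; al <- 2; be <- 2; g11 <- 1
  gam <- g11 * (n + al) * (n + be) / ((a + b + a1) * (a + c + b1))
  e_ic <- (log((a + g11)) + log(n + al) + log(n + be) -
             log(n + gam) - log(a + b + a1) - log(a + c + b1)) / log(2)
  v_ic <- ((n - a + gam - g11) / ((a + g11) * (1 + n + gam)) +
             (n - a - b + al - a1) / ((a + b + a1) * (1 + n + al)) +
             (n - a - c + be - b1) / ((a + c + b1) * (1 + n + be))) / log(2)^2
  list(ic = e_ic, ic025 = e_ic - 2 * sqrt(v_ic), var = v_ic)
}

oracle_oe_ic <- function(a, b, c, d, continuity = TRUE) {
  n <- a + b + c + d
  e <- (a + b) * (a + c) / n
  ic <- if (continuity) log2((a + 0.5) / (e + 0.5)) else log2(a / e)
  list(ic = ic,
       ic025 = ic - 3.3 * (a + 0.5)^(-0.5) - 2 * (a + 0.5)^(-1.5))
}

# brute-force 2x2 from a report list: filter then count set membership
oracle_contingency <- function(reports, exposed, event) {
  has_event <- vapply(reports$pts, function(p) event %in% p, TRUE)
  list(a = sum(exposed & has_event), b = sum(exposed & !has_event),
       c = sum(!exposed & has_event), d = sum(!exposed & !has_event))
}
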