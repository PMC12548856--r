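#' Construct a 2x2 drug-event contingency table
#'
#' Cells are counts of deduplicated reports: `a` with target drug and target
#' event, `b` drug without event, `c` event without drug, `d` neither.
#'
#' @param a,b,c,d non-negative counts.
#' @return object of class `contingency` (list `a`, `b`, `c`, `d`, `n`).
#' @export
contingency_table <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(is.na(cells)) || any(cells < 0))
    stop("contingency cells must be non-negative counts")
  structure(list(a = a, b = b, c = c, d = d, n = a + b + c + d),
            class = "contingency")
}

#' @export
print.contingency <- function(x, ...) {
  m <- matrix(c(x$a, x$c, x$b, x$d), 2, 2,
              dimnames = list(c("drug", "no drug"),
                              c("event", "no event")))
  print(m)
  cat("N =", x$n, "\n")
  invisible(x)
}

# unpack either a contingency object or four parallel vectors;
# cells become double so products of large counts cannot overflow
unpack_cells <- function(a, b, c, d) {
  k <- if (inherits(a, "contingency")) list(a = a$a, b = a$b, c = a$c, d = a$d)
       else list(a = a, b = b, c = c, d = d)
  lapply(k, as.numeric)
}

# Haldane-Anscombe: +0.5 to all four cells when any cell is zero (per table)
apply_zero_correction <- function(k) {
  zero <- k$a == 0 | k$b == 0 | k$c == 0 | k$d == 0
  add <- fifelse(zero, 0.5, 0)
  list(a = k$a + add, b = k$b + add, c = k$c + add, d = k$d + add,
       corrected = zero)
}

#' Reporting odds ratio with Woolf confidence interval
#'
#' ROR = ad/(bc); the log-scale interval uses
#' se = sqrt(1/a + 1/b + 1/c + 1/d). With `zero_correction = TRUE`
#' (default), tables containing a zero cell get the Haldane-Anscombe +0.5
#' added to all four cells and are flagged `corrected`; with correction off,
#' a zero cell yields `NA` (undefined-result marker), never an error.
#'
#' @param a a `contingency` object, or the `a` cell as a numeric vector.
#' @param b,c,d remaining cells when `a` is numeric (vectorized).
#' @param conf_level confidence level (default 0.95).
#' @param zero_correction logical.
#' @return data.table (`ror`, `ror_lo`, `ror_hi`, `corrected`).
#' @export
ror_stats <- function(a, b = NULL, c = NULL, d = NULL, conf_level = 0.95,
                      zero_correction = TRUE) {
  k <- unpack_cells(a, b, c, d)
  z <- qnorm((1 + conf_level) / 2)
  if (zero_correction) k <- apply_zero_correction(k)
  corrected <- k$corrected %||% rep(FALSE, length(k$a))
  bad <- k$a == 0 | k$b == 0 | k$c == 0 | k$d == 0
  est <- (k$a * k$d) / (k$b * k$c)
  se <- sqrt(1 / k$a + 1 / k$b + 1 / k$c + 1 / k$d)
  out <- data.table(ror = est,
                    ror_lo = exp(log(est) - z * se),
                    ror_hi = exp(log(est) + z * se),
                    corrected = corrected)
  out[bad, c("ror", "ror_lo", "ror_hi") := NA_real_]
  out[]
}

#' Proportional reporting ratio with confidence interval
#'
#' PRR = (a/(a+b)) / (c/(c+d)); log-scale interval with
#' se = sqrt(1/a - 1/(a+b) + 1/c - 1/(c+d)). Zero-cell handling mirrors
#' [ror_stats()].
#'
#' @inheritParams ror_stats
#' @return data.table (`prr`, `prr_lo`, `prr_hi`, `corrected`).
#' @export
prr_stats <- function(a, b = NULL, c = NULL, d = NULL, conf_level = 0.95,
                      zero_correction = TRUE) {
  k <- unpack_cells(a, b, c, d)
  z <- qnorm((1 + conf_level) / 2)
  if (zero_correction) k <- apply_zero_correction(k)
  corrected <- k$corrected %||% rep(FALSE, length(k$a))
  bad <- k$a == 0 | (k$a + k$b) == 0 | k$c == 0
  est <- (k$a / (k$a + k$b)) / (k$c / (k$c + k$d))
  se <- sqrt(1 / k$a - 1 / (k$a + k$b) + 1 / k$c - 1 / (k$c + k$d))
  out <- data.table(prr = est,
                    prr_lo = exp(log(est) - z * se),
                    prr_hi = exp(log(est) + z * se),
                    corrected = corrected)
  out[bad, c("prr", "prr_lo", "prr_hi") := NA_real_]
  out[]
}

#' Pearson chi-square statistic for a 2x2 table
#'
#' `N(ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))`; with `yates = TRUE` the
#' numerator uses `(|ad - bc| - N/2)^2` (floored at zero). A zero margin
#' yields `NA`.
#'
#' @inheritParams ror_stats
#' @param yates apply Yates continuity correction.
#' @return numeric vector.
#' @export
chisq_stat <- function(a, b = NULL, c = NULL, d = NULL, yates = FALSE) {
  k <- unpack_cells(a, b, c, d)
  n <- k$a + k$b + k$c + k$d
  denom <- (k$a + k$b) * (k$c + k$d) * (k$a + k$c) * (k$b + k$d)
  num <- if (yates) pmax(abs(k$a * k$d - k$b * k$c) - n / 2, 0)^2
         else (k$a * k$d - k$b * k$c)^2
  out <- n * num / denom
  out[denom == 0] <- NA_real_
  out
}

#' BCPNN information component
#'
#' Two variants of the Bayesian confidence propagation neural network
#' information component for a 2x2 report table.
#'
#' `variant = "bate"` (default) uses the closed-form posterior moments of
#' the original BCPNN with priors `alpha1 = beta1 = 1`, `alpha = beta = 2`,
#' `gamma11 = 1` and
#' `gamma = gamma11 (N+alpha)(N+beta) / ((a+b+alpha1)(a+c+beta1))`:
#' \deqn{E(IC) = \log_2 \frac{(a+1)(N+2)^2}{(N+\gamma)(a+b+1)(a+c+1)}}
#' with the matching closed-form variance, and `ic025 = E(IC) - 2 sd(IC)`.
#'
#' `variant = "oe_simple"` is the observed/expected form
#' `IC = log2((a + 0.5) / (E + 0.5))` with `E = (a+b)(a+c)/N` (set
#' `continuity = FALSE` for `log2(a/E)`), with the credibility bound
#' `ic025 = IC - 3.3 (a+0.5)^{-1/2} - 2 (a+0.5)^{-3/2}`.
#'
#' @inheritParams ror_stats
#' @param variant `"bate"` or `"oe_simple"`.
#' @param continuity apply the +0.5 continuity term (oe_simple only).
#' @return data.table (`ic`, `ic025`, and `ic_var` for the bate variant).
#' @export
bcpnn_stats <- function(a, b = NULL, c = NULL, d = NULL,
                        variant = c("bate", "oe_simple"),
                        continuity = TRUE) {
  variant <- match.arg(variant)
  k <- unpack_cells(a, b, c, d)
  n <- k$a + k$b + k$c + k$d
  bad <- (k$a + k$b) == 0 | (k$a + k$c) == 0 | n == 0
  if (variant == "bate") {
    a1 <- 1; b1 <- 1; al <- 2; be <- 2; g11 <- 1
    gamma <- g11 * (n + al) * (n + be) / ((k$a + k$b + a1) * (k$a + k$c + b1))
    eic <- log2((k$a + g11) * (n + al) * (n + be) /
                  ((n + gamma) * (k$a + k$b + a1) * (k$a + k$c + b1)))
    vic <- (1 / log(2)^2) * (
      (n - k$a + gamma - g11) / ((k$a + g11) * (1 + n + gamma)) +
      (n - k$a - k$b + al - a1) / ((k$a + k$b + a1) * (1 + n + al)) +
      (n - k$a - k$c + be - b1) / ((k$a + k$c + b1) * (1 + n + be)))
    out <- data.table(ic = eic, ic025 = eic - 2 * sqrt(vic), ic_var = vic)
  } else {
    expct <- (k$a + k$b) * (k$a + k$c) / n
    obs <- if (continuity) k$a + 0.5 else k$a
    expd <- if (continuity) expct + 0.5 else expct
    ic <- log2(obs / expd)
    ic[!continuity & k$a == 0] <- NA_real_
    out <- data.table(
      ic = ic,
      ic025 = ic - 3.3 * (k$a + 0.5)^(-0.5) - 2 * (k$a + 0.5)^(-1.5))
  }
  if (any(bad)) out[bad, (names(out)) := NA_real_]
  out[]
}

#' All disproportionality statistics for one or more 2x2 tables
#'
#' @inheritParams ror_stats
#' @param yates Yates correction for the chi-square.
#' @param bcpnn_variant passed to [bcpnn_stats()].
#' @return data.table with `a`, `b`, `c`, `d`, ROR/PRR and intervals,
#'   `chisq`, `ic`, `ic025`.
#' @export
signal_stats <- function(a, b = NULL, c = NULL, d = NULL, yates = FALSE,
                         bcpnn_variant = "bate", conf_level = 0.95,
                         zero_correction = TRUE) {
  k <- unpack_cells(a, b, c, d)
  cbind(data.table(a = k$a, b = k$b, c = k$c, d = k$d),
        ror_stats(k$a, k$b, k$c, k$d, conf_level, zero_correction)[
          , c("ror", "ror_lo", "ror_hi")],
        prr_stats(k$a, k$b, k$c, k$d, conf_level, zero_correction)[
          , c("prr", "prr_lo", "prr_hi")],
        data.table(chisq = chisq_stat(k$a, k$b, k$c, k$d, yates)),
        bcpnn_stats(k$a, k$b, k$c, k$d, variant = bcpnn_variant)[
          , c("ic", "ic025")])
}
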