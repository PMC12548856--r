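#' Bundled reference tables from the edaravone FAERS analysis
#'
#' The package ships the printed summary tables of a published
#' pharmacovigilance disproportionality analysis of edaravone (FAERS pool,
#' 2017Q2-2024Q2; 2,931 primary-suspect reports) as plain-text fixtures:
#' the descriptive category counts, the indication counts, the SOC-level
#' information-component table, and the top-30 PT signal table with ROR,
#' PRR, chi-square and IC columns. They serve as inputs for the percentage
#' checks and the formula-consistency audit; the underlying full FAERS
#' extract is not redistributable at desk scale.
#'
#' @param which one of `"table1_counts"`, `"indications"`, `"soc_ic"`,
#'   `"pt_signals"`.
#' @return data.table.
#' @export
reference_table <- function(which = c("table1_counts", "indications",
                                      "soc_ic", "pt_signals")) {
  which <- match.arg(which)
  f <- c(table1_counts = "edaravone_table1_counts.csv",
         indications = "edaravone_indications.csv",
         soc_ic = "edaravone_soc_ic.csv",
         pt_signals = "edaravone_pt_signals.csv")[[which]]
  fread(system.file("extdata", f, package = "faersignal", mustWork = TRUE))
}

#' Invert printed signal rows and audit the IC formula
#'
#' The headline PT signal table of the reference analysis prints, per
#' preferred term, the exposed case count `a`, ROR, PRR, chi-square and
#' IC(IC025), but not the full 2x2. Given the known exposure margin
#' (`a + b = n_exposed` reports), PRR fixes the background odds `d/c` and
#' the chi-square then pins the scale: `c` is solved numerically
#' (ROR would fix `d/c` too, but the two printed ratios are slightly
#' inconsistent after rounding and the PRR route is the numerically stable
#' one; the implied-ROR residual is reported as its own diagnostic).
#' With the implied table in hand the information component is recomputed
#' under both BCPNN variants and the gap to the printed IC reported — a
#' diagnostic of which formula the reference analysis used, not an
#' equality assertion.
#'
#' @param rows data.table with columns `pt`, `a`, `ror`, `prr`, `chisq`,
#'   `ic`, `ic025` (default: the bundled reference signal table).
#' @param n_exposed total exposed reports (margin `a + b`).
#' @return data.table per row: implied `b`, `c`, `d`, `n`, recomputed
#'   `ic_bate`, `ic_oe`, gaps to the printed IC, and `ror_implied`.
#' @export
audit_signal_table <- function(rows = reference_table("pt_signals"),
                               n_exposed = 2931L) {
  rows <- as.data.table(rows)
  out <- rows[, {
    b <- n_exposed - a
    k <- (a / n_exposed) / prr          # implied c / (c + d)
    r <- (1 - k) / k                    # implied d / c
    chi_of_c <- function(cc) chisq_stat(a, b, cc, r * cc) - chisq
    # chi-square is increasing in c toward a finite asymptote; a printed
    # value above it means the rounded inputs admit no exact table
    sol <- tryCatch({
      lo <- 1e-3
      hi <- 1e9
      if (chi_of_c(lo) * chi_of_c(hi) > 0) NA_real_
      else uniroot(chi_of_c, c(lo, hi), tol = 1e-8)$root
    }, error = function(e) NA_real_)
    if (is.na(sol)) {
      .(b = b, c = NA_real_, d = NA_real_, n = NA_real_,
        ic_bate = NA_real_, ic_oe = NA_real_,
        gap_bate = NA_real_, gap_oe = NA_real_, ror_implied = NA_real_,
        solved = FALSE)
    } else {
      cc <- sol; dd <- r * cc; nn <- a + b + cc + dd
      icb <- bcpnn_stats(a, b, cc, dd, variant = "bate")$ic
      ico <- bcpnn_stats(a, b, cc, dd, variant = "oe_simple",
                         continuity = TRUE)$ic
      .(b = b, c = cc, d = dd, n = nn,
        ic_bate = icb, ic_oe = ico,
        gap_bate = abs(icb - ic), gap_oe = abs(ico - ic),
        ror_implied = a * dd / (b * cc), solved = TRUE)
    }
  }, by = pt]
  out
}
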