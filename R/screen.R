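#' Signal screening thresholds
#'
#' The conventional three-algorithm screen: a preferred term enters the
#' candidate set when its exposed report count `a` is at least `min_count`
#' (default 3); it is flagged per method by `ror_lo > 1` (ROR), `prr >= 2`
#' together with `chisq >= 4` (PRR), and `ic025 > 0` (BCPNN). The
#' `combine` mode says whether a signal needs all three rules (`"all"`,
#' default — cross-validation across methods) or any one (`"any"`).
#'
#' @param min_count minimum exposed report count per PT.
#' @param ror_lo_gt ROR rule threshold on the CI lower bound.
#' @param prr_ge,chisq_ge PRR rule thresholds.
#' @param ic025_gt BCPNN rule threshold.
#' @param combine `"all"` or `"any"`.
#' @return a `signal_criteria` list.
#' @export
signal_criteria <- function(min_count = 3L, ror_lo_gt = 1, prr_ge = 2,
                            chisq_ge = 4, ic025_gt = 0,
                            combine = c("all", "any")) {
  combine <- match.arg(combine)
  stopifnot(min_count > 0, ror_lo_gt > 0, prr_ge > 0, chisq_ge > 0)
  structure(list(min_count = as.integer(min_count), ror_lo_gt = ror_lo_gt,
                 prr_ge = prr_ge, chisq_ge = chisq_ge, ic025_gt = ic025_gt,
                 combine = combine),
            class = "signal_criteria")
}

# per-PT (or per-SOC) cell counts for an exposure split of a report table
event_cells <- function(event_long, exposed) {
  n <- length(exposed)
  n_exp <- sum(exposed)
  tab <- event_long[, .(n_event = .N, a = sum(exposed[row_id])), by = event]
  tab[, `:=`(b = n_exp - a, c = n_event - a)]
  tab[, d := n - n_exp - c]
  tab[]
}

#' Build one drug-event 2x2 table
#'
#' Cells are computed at report level within the stratum: a report
#' contributes at most once to each margin for a given event, no matter how
#' many matching reaction rows it has.
#'
#' @param reports deduplicated `faers_reports` table.
#' @param drug canonical target drug name.
#' @param event event term (normalized match).
#' @param event_level `"pt"` or `"soc"`.
#' @param stratum optional logical vector selecting reports.
#' @param synonyms,soc_map,roles mapping inputs (see [is_exposed()],
#'   [map_pt_to_soc()]).
#' @return a `contingency` object (all-zero when the stratum is empty).
#' @export
build_contingency <- function(reports, drug, event,
                              event_level = c("pt", "soc"),
                              stratum = NULL,
                              synonyms = default_synonym_table(),
                              soc_map = default_pt_soc_map(),
                              roles = "PS") {
  event_level <- match.arg(event_level)
  exposed <- is_exposed(reports, drug, synonyms, roles)
  if (!is.null(stratum)) {
    reports <- reports[stratum]
    exposed <- exposed[stratum]
  }
  if (!nrow(reports)) return(contingency_table(0, 0, 0, 0))
  pl <- pt_long(reports)
  if (event_level == "soc") pl[, pt := map_pt_to_soc(pt, soc_map)]
  pl <- unique(pl)
  ev <- normalize_term(event)
  has_event <- seq_len(nrow(reports)) %in% pl[normalize_term(pt) == ev |
                                                pt == event, row_id]
  contingency_table(sum(exposed & has_event), sum(exposed & !has_event),
                    sum(!exposed & has_event), sum(!exposed & !has_event))
}

#' Screen preferred terms for disproportionality signals
#'
#' Builds the per-PT 2x2 tables for the target drug against the full
#' background (all other deduplicated reports in the pool), computes ROR,
#' PRR, chi-square and the information component, applies the screening
#' thresholds and returns ranked signal candidates.
#'
#' Counting is per report: a report with several identical PTs counts once
#' for that PT, and since a report may carry several distinct PTs the column
#' sum of `a` can exceed the number of exposed reports.
#'
#' @param reports deduplicated `faers_reports` table.
#' @param drug canonical target drug name.
#' @param criteria a [signal_criteria()] object.
#' @param stratum optional logical vector selecting reports (all four cells
#'   are computed within the stratum).
#' @param synonyms,soc_map mapping tables.
#' @param roles exposure role codes (default primary suspect only).
#' @param yates,bcpnn_variant,zero_correction statistic options.
#' @return data.table of class `pt_signals`: `pt`, `soc`, `a`, statistics,
#'   per-criterion flags (`flag_ror`, `flag_prr`, `flag_bcpnn`), `signal`,
#'   ranked by descending `ror_lo`.
#' @export
screen_signals <- function(reports, drug, criteria = signal_criteria(),
                           stratum = NULL,
                           synonyms = default_synonym_table(),
                           soc_map = default_pt_soc_map(),
                           roles = "PS", yates = FALSE,
                           bcpnn_variant = "bate", zero_correction = TRUE) {
  exposed <- is_exposed(reports, drug, synonyms, roles)
  if (!is.null(stratum)) {
    reports <- reports[stratum]
    exposed <- exposed[stratum]
  }
  empty <- data.table(pt = character(), soc = character(), a = numeric(),
                      b = numeric(), c = numeric(), d = numeric(),
                      ror = numeric(), ror_lo = numeric(), ror_hi = numeric(),
                      prr = numeric(), prr_lo = numeric(), prr_hi = numeric(),
                      chisq = numeric(), ic = numeric(), ic025 = numeric(),
                      flag_ror = logical(), flag_prr = logical(),
                      flag_bcpnn = logical(), signal = logical())
  if (!nrow(reports) || !any(exposed)) {
    warning("stratum contains no exposed reports; returning empty signal list",
            call. = FALSE)
    return(empty)
  }
  pl <- unique(pt_long(reports))
  setnames(pl, "pt", "event")
  cells <- event_cells(pl, exposed)
  cells <- cells[a >= criteria$min_count]
  if (!nrow(cells)) return(empty)
  st <- signal_stats(cells$a, cells$b, cells$c, cells$d, yates = yates,
                     bcpnn_variant = bcpnn_variant,
                     zero_correction = zero_correction)
  out <- cbind(data.table(pt = cells$event,
                          soc = map_pt_to_soc(cells$event, soc_map)), st)
  out[, flag_ror := !is.na(ror_lo) & ror_lo > criteria$ror_lo_gt]
  out[, flag_prr := !is.na(prr) & !is.na(chisq) &
        prr >= criteria$prr_ge & chisq >= criteria$chisq_ge]
  out[, flag_bcpnn := !is.na(ic025) & ic025 > criteria$ic025_gt]
  out[, signal := if (criteria$combine == "all")
    flag_ror & flag_prr & flag_bcpnn else flag_ror | flag_prr | flag_bcpnn]
  rank_signals(out, key = "ror_lo")
}

#' Rank a signal table
#'
#' Stable descending sort by the chosen key; ties broken by descending
#' exposed count `a`, then PT alphabetical.
#'
#' @param signals a signal table from [screen_signals()].
#' @param key `"ror_lo"` (signal strength by CI lower bound) or `"a"`
#'   (report number).
#' @return the reordered table.
#' @export
rank_signals <- function(signals, key = c("ror_lo", "a")) {
  key <- match.arg(key)
  setorderv(signals, c(key, "a", "pt"), order = c(-1L, -1L, 1L),
            na.last = TRUE)
  signals[]
}

#' SOC-level report counts and information component
#'
#' A report contributes once to a system organ class even when several of
#' its PTs map into that SOC; the BCPNN is computed on the SOC-level 2x2.
#'
#' @inheritParams screen_signals
#' @return data.table (`soc`, `a` case reports, `ic`, `ic025`), ordered by
#'   descending `ic`.
#' @export
soc_level_stats <- function(reports, drug,
                            synonyms = default_synonym_table(),
                            soc_map = default_pt_soc_map(), roles = "PS",
                            bcpnn_variant = "bate") {
  exposed <- is_exposed(reports, drug, synonyms, roles)
  pl <- pt_long(reports)
  pl[, soc := map_pt_to_soc(pt, soc_map)]
  sl <- unique(pl[, .(row_id, event = soc)])
  cells <- event_cells(sl, exposed)
  ic <- bcpnn_stats(cells$a, cells$b, cells$c, cells$d,
                    variant = bcpnn_variant)
  out <- data.table(soc = cells$event, a = cells$a, ic = ic$ic,
                    ic025 = ic$ic025)
  setorderv(out, "ic", -1L, na.last = TRUE)
  out[]
}

#' Sex-stratified signal screening
#'
#' Screens females and males separately; each stratum's 2x2 tables use only
#' that stratum's reports for all four cells. Reports with unknown sex are
#' excluded from both strata.
#'
#' @inheritParams screen_signals
#' @return named list of signal tables, elements `F` and `M`.
#' @export
stratified_signals <- function(reports, drug, criteria = signal_criteria(),
                               synonyms = default_synonym_table(),
                               soc_map = default_pt_soc_map(), roles = "PS",
                               yates = FALSE, bcpnn_variant = "bate") {
  lapply(stats::setNames(c("F", "M"), c("F", "M")), function(s)
    screen_signals(reports, drug, criteria, stratum = reports$sex == s,
                   synonyms = synonyms, soc_map = soc_map, roles = roles,
                   yates = yates, bcpnn_variant = bcpnn_variant))
}
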