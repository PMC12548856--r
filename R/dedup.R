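#' Deduplicate report versions
#'
#' FAERS contains several versions of the same safety report (same CASEID,
#' different PRIMARYID/FDA_DT). For each CASEID the version with the most
#' recent FDA_DT is retained; when FDA_DT ties, the higher PRIMARYID wins.
#' Applied across the whole pooled extract, so a case revised in a later
#' quarter supersedes its earlier versions.
#'
#' PRIMARYIDs are compared numerically when fully numeric (the FAERS case),
#' otherwise lexicographically after zero-padding to a common width.
#'
#' @param reports a `faers_reports` table (one row per report version).
#' @return list with `kept` (one row per caseid, in first-appearance order of
#'   caseid), `dropped` (data.table `caseid`, `fda_dt`, `primaryid` of the
#'   superseded versions) and `report` (data.table `caseid`,
#'   `kept_primaryid`, `n_versions`).
#' @export
deduplicate_reports <- function(reports) {
  dt <- as.data.table(reports)
  if (!nrow(dt)) {
    return(list(kept = reports,
                dropped = data.table(caseid = character(), fda_dt = integer(),
                                     primaryid = character()),
                report = data.table(caseid = character(),
                                    kept_primaryid = character(),
                                    n_versions = integer())))
  }
  dt[, `:=`(.first = .I, .pid_ord = primaryid_order(primaryid))]

  dup_key <- duplicated(dt, by = c("caseid", "fda_dt", "primaryid"))
  if (any(dup_key)) {
    warning(sprintf(
      "identical (caseid, fda_dt, primaryid) rows for caseid(s) %s; keeping the first occurrence",
      paste(unique(dt$caseid[dup_key]), collapse = ", ")), call. = FALSE)
    dt <- dt[!dup_key]
  }

  # rank versions within case under the lexicographic (fda_dt, primaryid)
  # total order; the maximum is kept
  dt[, .rank := frank(list(fda_dt, .pid_ord), ties.method = "first"),
     by = caseid]
  dt[, .keep := .rank == max(.rank), by = caseid]

  kept <- dt[.keep == TRUE]
  first_seen <- dt[, .(.case_first = min(.first)), by = caseid]
  kept <- kept[first_seen, on = "caseid", nomatch = 0L][order(.case_first)]
  dropped <- dt[.keep == FALSE, .(caseid, fda_dt, primaryid)]
  rep_tab <- dt[, .(n_versions = .N), by = caseid][
    kept[, .(caseid, kept_primaryid = primaryid)], on = "caseid"]
  setcolorder(rep_tab, c("caseid", "kept_primaryid", "n_versions"))

  kept[, c(".first", ".pid_ord", ".rank", ".keep", ".case_first") := NULL]
  setattr(kept, "class", c("faers_reports", class(data.table())))
  list(kept = kept[], dropped = dropped[], report = rep_tab[])
}

# numeric order when all ids are numeric, else zero-padded lexicographic
primaryid_order <- function(ids) {
  num <- suppressWarnings(as.numeric(ids))
  if (!anyNA(num)) return(num)
  w <- max(nchar(ids))
  padded <- formatC(ids, width = w, flag = "0")
  as.numeric(factor(padded, levels = sort(unique(padded))))
}
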