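#' Build a frequency table with a stated denominator
#'
#' Percentages are `round(100 * count / denominator, 2)`. The denominator
#' need not be the sum of counts (e.g. outcome percentages run over reports
#' that specified an outcome).
#'
#' @param variable variable name.
#' @param levels character vector of level labels.
#' @param counts integer vector, parallel to `levels`.
#' @param denominator denominator for percentages.
#' @return data.table (`variable`, `level`, `count`, `percent`,
#'   `denominator`).
#' @export
frequency_table <- function(variable, levels, counts, denominator) {
  data.table(variable = variable, level = levels, count = as.integer(counts),
             percent = round(100 * counts / denominator, 2),
             denominator = as.integer(denominator))
}

.age_bands <- function(age) {
  cut_lab <- rep("Unknown", length(age))
  cut_lab[!is.na(age) & age < 18] <- "<18"
  cut_lab[!is.na(age) & age >= 18 & age < 45] <- "18-45"
  cut_lab[!is.na(age) & age >= 45 & age < 60] <- "45-60"
  cut_lab[!is.na(age) & age >= 60] <- ">=60"
  factor(cut_lab, levels = c("<18", "18-45", "45-60", ">=60", "Unknown"))
}

.tto_bands <- function(tto) {
  lab <- rep("Unknown", length(tto))
  lab[!is.na(tto) & tto < 7] <- "<7"
  lab[!is.na(tto) & tto >= 7 & tto < 28] <- "7-28"
  lab[!is.na(tto) & tto >= 28 & tto < 60] <- "28-60"
  lab[!is.na(tto) & tto >= 60] <- ">=60"
  factor(lab, levels = c("<7", "7-28", "28-60", ">=60", "Unknown"))
}

.outcome_labels <- c(DE = "Death", LT = "Life threatening",
                     HO = "Hospitalization", DS = "Disability",
                     CA = "Congenital anomaly",
                     RI = "Required intervention", OT = "Other serious")

#' Demographic and outcome summary of a report set
#'
#' The descriptive layer for a drug-filtered, deduplicated report pool:
#' sex, age band, reporter occupation, reporter country (top two plus
#' Other), administration route, outcomes, and time-to-onset band, plus a
#' weight summary (median and interquartile range).
#'
#' Denominators differ by variable: sex, age, reporter, country and route
#' percentages run over all reports; outcome percentages over reports with
#' at least one outcome record; onset percentages over reports with any
#' therapy record (within which onset may still be unknown).
#'
#' @param reports `faers_reports` table.
#' @return list of frequency tables (`sex`, `age`, `reporter`, `country`,
#'   `route`, `outcome`, `onset`), a `weight` summary (median, q1, q3, n),
#'   and `combined` (all frequency tables stacked).
#' @export
demographic_table <- function(reports) {
  n_all <- nrow(reports)
  tabs <- list()

  cnt <- function(x) {
    t <- table(x)
    list(levels = names(t), counts = as.integer(t))
  }

  s <- cnt(factor(fifelse(reports$sex %in% c("F", "M"), reports$sex, "UNK"),
                  levels = c("F", "M", "UNK"),
                  labels = c("Female", "Male", "Unknown")))
  tabs$sex <- frequency_table("sex", s$levels, s$counts, n_all)

  ab <- cnt(.age_bands(reports$age_years))
  tabs$age <- frequency_table("age", ab$levels, ab$counts, n_all)

  rp <- cnt(factor(reports$reporter,
                   levels = c("Consumer", "Physician", "Pharmacist",
                              "OtherHealthProfessional", "Lawyer", "UNK")))
  tabs$reporter <- frequency_table("reporter", rp$levels, rp$counts, n_all)

  cc <- table(reports$country)
  cc <- sort(cc, decreasing = TRUE)
  top <- head(names(cc), 2L)
  lev <- c(top, "Other")
  counts <- c(as.integer(cc[top]), sum(cc) - sum(cc[top]))
  tabs$country <- frequency_table("country", lev, counts, n_all)

  rl <- data.table(row_id = rep(seq_len(n_all),
                                vapply(reports$routes, length, 0L)),
                   route = unlist(reports$routes, use.names = FALSE))
  if (nrow(rl)) {
    rt <- unique(rl)[, .(count = .N), by = route][order(-count)]
    tabs$route <- frequency_table("route", rt$route, rt$count, n_all)
  } else {
    tabs$route <- frequency_table("route", character(), integer(), n_all)
  }

  ol <- data.table(row_id = rep(seq_len(n_all),
                                vapply(reports$outcomes, length, 0L)),
                   code = unlist(reports$outcomes, use.names = FALSE))
  n_outcome <- length(unique(ol$row_id))
  if (nrow(ol)) {
    ot <- unique(ol)[, .(count = .N), by = code][order(-count)]
    tabs$outcome <- frequency_table("outcome",
                                    unname(.outcome_labels[ot$code]),
                                    ot$count, n_outcome)
  } else {
    tabs$outcome <- frequency_table("outcome", character(), integer(), 0L)
  }

  has_onset_info <- reports$has_ther
  n_onset <- sum(has_onset_info)
  tb <- cnt(.tto_bands(reports$tto_days[has_onset_info]))
  tabs$onset <- frequency_table("onset", tb$levels, tb$counts,
                                if (n_onset > 0) n_onset else 1L)

  w <- reports$weight_kg
  weight <- list(median = median(w, na.rm = TRUE),
                 q1 = unname(quantile(w, 0.25, na.rm = TRUE, names = FALSE)),
                 q3 = unname(quantile(w, 0.75, na.rm = TRUE, names = FALSE)),
                 n = sum(!is.na(w)))

  c(tabs, list(weight = weight, combined = rbindlist(tabs)))
}

#' Indication frequency table for a target drug
#'
#' Counts the standardized indication terms attached to the target drug's
#' rows in each report, in descending order. A report listing two
#' indications for the drug contributes to both levels, so percentages run
#' over indication records, not reports. Reports whose target-drug rows
#' carry no indication fall into the
#' "product used for unknown indication" bucket.
#'
#' @param reports `faers_reports` table.
#' @param drug canonical target drug name.
#' @param synonyms synonym dictionary.
#' @param roles exposure role codes.
#' @return a frequency table over indication records.
#' @export
indication_table <- function(reports, drug,
                             synonyms = default_synonym_table(),
                             roles = "PS") {
  dl <- drug_long(reports)
  dl[, name_std := standardize_drug(name_raw, synonyms)]
  target <- dl[role %in% roles & name_std == normalize_term(drug),
               .(row_id, seq)]
  il <- rbindlist(reports$indications, idcol = "row_id")
  hit <- il[target, on = c("row_id", "seq"), nomatch = 0L]
  hit <- unique(hit[, .(row_id, term)])
  unk <- setdiff(unique(target$row_id), unique(hit$row_id))
  terms <- c(hit$term,
             rep("product used for unknown indication", length(unk)))
  t <- sort(table(terms), decreasing = TRUE)
  frequency_table("indication", names(t), as.integer(t), sum(t))
}

#' Quarterly distribution of reports
#'
#' @param reports `faers_reports` table.
#' @param from,to optional quarter labels bounding the range; defaults to
#'   the observed range. Zero-count quarters inside the range are included.
#' @return data.table (`quarter`, `count`) in calendar order.
#' @export
quarterly_distribution <- function(reports, from = NULL, to = NULL) {
  q <- reports$quarter
  q <- q[!is.na(q)]
  if (is.null(from)) from <- if (length(q)) min(q) else "2017Q2"
  if (is.null(to)) to <- if (length(q)) max(q) else from
  all_q <- quarter_seq(from, to)
  counts <- table(factor(q, levels = all_q))
  data.table(quarter = all_q, count = as.integer(counts))
}

#' Top-k quarters by report count
#'
#' @param qd output of [quarterly_distribution()].
#' @param k number of quarters.
#' @return the `k` rows with the highest counts, descending (ties by
#'   calendar order).
#' @export
top_quarters <- function(qd, k = 3L) {
  head(qd[order(-count)], k)
}
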