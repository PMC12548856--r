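#' Run the full signal-detection pipeline
#'
#' Ingest -> dedup -> standardize -> screen -> stratify -> summarize, with
#' every tabular result written to `out_dir` and a stage-count log that is
#' conserved at every boundary (`reports in = kept + dropped`, etc.).
#'
#' @param input_dir directory of FAERS-style quarterly files.
#' @param quarters character vector of quarter labels to ingest.
#' @param drug canonical target drug name.
#' @param out_dir output directory (created if needed).
#' @param synonyms synonym dictionary (a `SynonymTable` or a TSV path).
#' @param soc_map PT-SOC map (a `PtSocMap` or a TSV path).
#' @param criteria a [signal_criteria()] object.
#' @param stratify_sex also produce per-sex signal tables.
#' @param roles exposure role codes.
#' @param yates,bcpnn_variant statistic options.
#' @return invisibly, a list with `reports` (deduplicated pool), `signals`,
#'   `soc`, `strata`, `demographics`, `indications`, `quarterly` and
#'   `log` (stage-count data.table).
#' @export
run_pipeline <- function(input_dir, quarters, drug, out_dir,
                         synonyms = default_synonym_table(),
                         soc_map = default_pt_soc_map(),
                         criteria = signal_criteria(),
                         stratify_sex = TRUE, roles = "PS",
                         yates = FALSE, bcpnn_variant = "bate") {
  if (is.character(synonyms) && length(synonyms) == 1L) {
    if (!file.exists(synonyms)) stop("synonym table not found: ", synonyms)
    synonyms <- read_synonym_table(synonyms)
  }
  if (is.character(soc_map) && length(soc_map) == 1L) {
    if (!file.exists(soc_map)) stop("PT-SOC map not found: ", soc_map)
    soc_map <- read_pt_soc_map(soc_map)
  }
  if (!dir.exists(input_dir)) stop("input directory not found: ", input_dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  pooled <- ingest_quarters(input_dir, quarters)
  n_in <- nrow(pooled) + attr(pooled, "n_quarantined")
  dd <- deduplicate_reports(pooled)
  reports <- dd$kept

  exposed <- is_exposed(reports, drug, synonyms, roles)
  n_exposed <- sum(exposed)

  signals <- screen_signals(reports, drug, criteria, synonyms = synonyms,
                            soc_map = soc_map, roles = roles, yates = yates,
                            bcpnn_variant = bcpnn_variant)
  soc <- soc_level_stats(reports, drug, synonyms, soc_map, roles,
                         bcpnn_variant)
  strata <- if (stratify_sex)
    stratified_signals(reports, drug, criteria, synonyms, soc_map, roles,
                       yates, bcpnn_variant) else NULL

  drug_reports <- reports[exposed]
  demo <- demographic_table(drug_reports)
  indi <- indication_table(reports, drug, synonyms, roles)
  qd <- quarterly_distribution(drug_reports)

  log <- data.table(
    stage = c("report_versions_in", "assembled", "quarantined_no_reaction",
              "duplicates_removed", "cases_kept", "exposed_reports",
              "pts_screened", "signals_flagged"),
    count = c(n_in, nrow(pooled), attr(pooled, "n_quarantined"),
              nrow(dd$dropped), nrow(reports), n_exposed,
              nrow(signals), sum(signals$signal)))

  write_table_file(signals, file.path(out_dir, "pt_signals.csv"))
  write_table_file(soc, file.path(out_dir, "soc_stats.csv"))
  write_table_file(demo$combined, file.path(out_dir, "demographics.csv"))
  write_table_file(indi, file.path(out_dir, "indications.csv"))
  write_table_file(qd, file.path(out_dir, "quarterly_counts.csv"))
  write_table_file(dd$report, file.path(out_dir, "dedup_report.csv"))
  write_table_file(log, file.path(out_dir, "run_log.csv"))
  if (stratify_sex) {
    write_table_file(strata$F, file.path(out_dir, "pt_signals_female.csv"))
    write_table_file(strata$M, file.path(out_dir, "pt_signals_male.csv"))
  }

  invisible(list(reports = reports, signals = signals, soc = soc,
                 strata = strata, demographics = demo, indications = indi,
                 quarterly = qd, log = log))
}
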