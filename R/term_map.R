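#' Default dosage/form stop-list
#'
#' Regular expressions for trailing tokens stripped from raw drug names
#' before dictionary lookup (dosage amounts, formulation words, routes).
#'
#' @return character vector of regexes, each matched against a whole
#'   trailing token.
#' @export
default_dose_stoplist <- function() {
  c("\\d+(\\.\\d+)?\\s*(mg|g|mcg|ug|ml|iu)(/(ml|kg|day|d))?",
    "mg", "tablet[s]?", "tab[s]?", "capsule[s]?", "cap[s]?",
    "injection", "injectable", "infusion", "solution", "suspension",
    "oral", "iv", "intravenous", "hcl", "sodium")
}

#' Read a two-column synonym table
#'
#' @param path TSV with columns `raw` and `canonical` (header required).
#' @return a `SynonymTable`: named character vector mapping normalized raw
#'   name to canonical name.
#' @export
read_synonym_table <- function(path) {
  dt <- fread(path, sep = "\t", header = TRUE, colClasses = "character")
  if (!all(c("raw", "canonical") %in% names(dt)))
    stop("synonym table must have columns 'raw' and 'canonical': ", path)
  key <- normalize_term(dt$raw)
  canon <- normalize_term(dt$canonical)
  if (any(tapply(canon, key, function(v) length(unique(v))) > 1L))
    stop("synonym table maps a raw name to two canonicals: ", path)
  keep <- !duplicated(key)
  setNames(canon[keep], key[keep])
}

#' Bundled synonym dictionary for the edaravone analysis
#'
#' Maps trade and code names (Radicava, Radicut, MCI-186, ...) onto the
#' ingredient name, plus entries for common background drugs used by the
#' synthetic generator. A deterministic dictionary stands in for NLP-based
#' drug-name normalization.
#'
#' @return a `SynonymTable` (see [read_synonym_table()]).
#' @export
default_synonym_table <- function() {
  read_synonym_table(system.file("extdata", "edaravone_synonyms.tsv",
                                 package = "faersignal", mustWork = TRUE))
}

#' Standardize raw drug names against a synonym dictionary
#'
#' Names are normalized (trim, case-fold, collapse whitespace), looked up,
#' and on a miss retried after iteratively stripping trailing dosage/form
#' tokens from the stop-list. Deterministic; unmatched names return
#' `"UNMAPPED"`.
#'
#' @param raw_name character vector of raw drug name strings.
#' @param table a `SynonymTable`.
#' @param stoplist character vector of token regexes
#'   (default [default_dose_stoplist()]).
#' @return character vector of canonical names or `"UNMAPPED"`.
#' @export
standardize_drug <- function(raw_name, table = default_synonym_table(),
                             stoplist = default_dose_stoplist()) {
  x <- normalize_term(raw_name)
  out <- unname(table[x])
  miss <- is.na(out) & !is.na(x) & x != ""
  if (any(miss)) {
    pat <- sprintf("\\s+(%s)$", paste(stoplist, collapse = "|"))
    y <- x[miss]
    repeat {
      y2 <- sub(pat, "", y)
      if (all(y2 == y)) break
      y <- y2
    }
    out[miss] <- unname(table[y])
  }
  out[is.na(out)] <- "UNMAPPED"
  out
}

#' Drug-name coverage report
#'
#' @param raw_names character vector (may repeat).
#' @param table a `SynonymTable`.
#' @param stoplist see [standardize_drug()].
#' @return data.table with one row per distinct raw name (`raw`, `canonical`,
#'   `n`) plus attribute `summary` (`mapped`, `unmapped`, `total`).
#' @export
drug_coverage <- function(raw_names, table = default_synonym_table(),
                          stoplist = default_dose_stoplist()) {
  dt <- data.table(raw = normalize_term(raw_names))[, .(n = .N), by = raw]
  dt[, canonical := standardize_drug(raw, table, stoplist)]
  s <- c(mapped = sum(dt$canonical != "UNMAPPED"),
         unmapped = sum(dt$canonical == "UNMAPPED"),
         total = nrow(dt))
  setattr(dt, "summary", s)
  dt[]
}

#' Read a PT to SOC mapping table
#'
#' @param path TSV with columns `pt` and `soc`.
#' @return a `PtSocMap`: named character vector keyed by normalized PT.
#' @export
read_pt_soc_map <- function(path) {
  dt <- fread(path, sep = "\t", header = TRUE, colClasses = "character")
  if (!all(c("pt", "soc") %in% names(dt)))
    stop("PT-SOC map must have columns 'pt' and 'soc': ", path)
  key <- normalize_term(dt$pt)
  if (any(tapply(trimws(dt$soc), key, function(v) length(unique(v))) > 1L))
    stop("PT maps to more than one SOC (primary-SOC convention violated): ",
         path)
  dt <- dt[!duplicated(key)]
  setNames(trimws(dt$soc), normalize_term(dt$pt))
}

#' Bundled PT to SOC map
#'
#' Covers the preferred terms appearing in the edaravone reference signal
#' tables and the synthetic generator's catalog, each with its primary
#' system organ class. MedDRA itself is licensed; the analysis only needs a
#' PT -> SOC function, supplied as a plain table.
#'
#' @return a `PtSocMap` (see [read_pt_soc_map()]).
#' @export
default_pt_soc_map <- function() {
  read_pt_soc_map(system.file("extdata", "pt_soc_map.tsv",
                              package = "faersignal", mustWork = TRUE))
}

#' Map preferred terms to system organ classes
#'
#' Case-insensitive match on the normalized PT; unknown PTs return
#' `"UNMAPPED_SOC"`.
#'
#' @param pt character vector of PT strings.
#' @param map a `PtSocMap`.
#' @return character vector of SOC names or `"UNMAPPED_SOC"`.
#' @export
map_pt_to_soc <- function(pt, map = default_pt_soc_map()) {
  out <- unname(map[normalize_term(pt)])
  out[is.na(out)] <- "UNMAPPED_SOC"
  out
}

#' Flag reports exposed to a target drug
#'
#' A report counts as exposed when at least one of its drug rows has a role
#' code in `roles` (default primary suspect only) and standardizes to the
#' target name.
#'
#' @param reports `faers_reports` table.
#' @param drug canonical drug name.
#' @param table synonym dictionary.
#' @param roles role codes that define exposure; default `"PS"`, add `"SS"`
#'   to include secondary suspects.
#' @param stoplist see [standardize_drug()].
#' @return logical vector, one element per report.
#' @export
is_exposed <- function(reports, drug, table = default_synonym_table(),
                       roles = "PS", stoplist = default_dose_stoplist()) {
  dl <- drug_long(reports)
  if (!nrow(dl)) return(rep(FALSE, nrow(reports)))
  dl <- dl[role %in% roles]
  dl[, name_std := standardize_drug(name_raw, table, stoplist)]
  hit <- unique(dl[name_std == normalize_term(drug), row_id])
  seq_len(nrow(reports)) %in% hit
}
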