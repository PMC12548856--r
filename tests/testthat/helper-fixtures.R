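# In-code fixture builders shared across test files.

# Minimal report table in the internal shape, built directly (bypassing the
# file layer) for signal-engine and summary tests.
mk_reports <- function(pts_list, exposed, sex = NULL, caseid = NULL,
                       fda_dt = NULL, primaryid = NULL, outcomes = NULL,
                       tto = NULL, has_ther = NULL) {
  n <- length(pts_list)
  sex <- sex %||% rep("UNK", n)
  caseid <- caseid %||% sprintf("C%03d", seq_len(n))
  primaryid <- primaryid %||% as.character(seq_len(n) + 1000L)
  fda_dt <- fda_dt %||% rep(20200115L, n)
  drugs <- lapply(exposed, function(e)
    if (e) data.table::data.table(seq = 1L, role = "PS",
                                  name_raw = "EDARAVONE",
                                  route = "intravenous")
    else data.table::data.table(seq = 1L, role = "PS",
                                name_raw = "UNRELATED DRUG",
                                route = "oral"))
  out <- data.table::data.table(
    caseid = caseid, primaryid = primaryid,
    primaryid_num = suppressWarnings(as.numeric(primaryid)),
    fda_dt = fda_dt, fda_dt_imprecise = FALSE,
    quarter = faersignal:::quarter_label(fda_dt),
    sex = sex, age_years = NA_real_, weight_kg = NA_real_,
    reporter = "UNK", country = "US",
    routes = lapply(exposed, function(e) if (e) "intravenous" else "oral"),
    outcomes = outcomes %||% replicate(n, character(), simplify = FALSE),
    drugs = drugs,
    indications = replicate(n, data.table::data.table(seq = integer(),
                                                      term = character()),
                            simplify = FALSE),
    pts = pts_list,
    has_ther = has_ther %||% rep(FALSE, n),
    tto_days = tto %||% rep(NA_real_, n))
  data.table::setattr(out, "class",
                      c("faers_reports", class(data.table::data.table())))
  out
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# the 10-report toy set: 4 exposed, 3 with the event, 2 of them exposed
toy_reports <- function() {
  pts <- list(c("nausea", "death"), "nausea", "fatigue", "death",
              "fatigue", "nausea", "death", "fatigue", "death", "fatigue")
  exposed <- c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE,
               FALSE)
  mk_reports(pts, exposed)
}

# Hand-written quarterly FAERS files exercising parser edge cases:
# an invalid date row, a blank-sex row, MON/DEC age units, an unknown
# column, an orphan reaction row, and a report with no reactions.
write_faers_fixture <- function(dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(name, lines) writeLines(lines, file.path(dir, name))
  w("demo18q4.txt", c(
    "primaryid$caseid$fda_dt$sex$age$age_cod$wt$occp_cod$reporter_country$junkcol",
    "1001$111$20181001$F$780$MON$62$CN$US$x",
    "1002$112$20181115$$6.5$DEC$$MD$JP$x",
    "1003$113$20189999$M$70$YR$80$PH$US$x",
    "1004$114$20181201$M$70$YR$81$OT$FR$x"))
  w("drug18q4.txt", c(
    "primaryid$drug_seq$role_cod$drugname$route",
    "1001$1$PS$RADICAVA$Intravenous",
    "1001$2$C$TYLENOL$",
    "1002$1$PS$Edaravone 30mg$Intravenous drip",
    "1003$1$PS$EDARAVONE$Oral",
    "1004$1$PS$ASPIRIN$Oral"))
  w("reac18q4.txt", c(
    "primaryid$pt",
    "1001$Death",
    "1001$Fatigue",
    "1002$Nausea",
    "9999$Headache"))
  w("outc18q4.txt", c(
    "primaryid$outc_cod",
    "1001$DE",
    "1002$HO"))
  w("indi18q4.txt", c(
    "primaryid$indi_drug_seq$indi_pt",
    "1001$1$Amyotrophic lateral sclerosis"))
  w("ther18q4.txt", c(
    "primaryid$dsg_drug_seq$start_dt$end_dt",
    "1001$1$20180901$",
    "1002$1$2018$"))
  invisible(dir)
}
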