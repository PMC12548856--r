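#' Parse FAERS-style dates
#'
#' FAERS dates are YYYYMMDD integers; partial dates (YYYYMM, YYYY) occur and
#' are padded to the first day/month so that report versions remain totally
#' ordered, but are flagged as imprecise. Anything else is invalid.
#'
#' @param x character or integer vector of raw date fields.
#' @return a `data.table` with columns `date` (YYYYMMDD integer, NA when
#'   invalid), `imprecise` (logical) and `valid` (logical).
#' @export
parse_fda_dt <- function(x) {
  x <- trimws(as.character(x))
  n <- nchar(x)
  padded <- rep(NA_character_, length(x))
  imprecise <- rep(FALSE, length(x))
  ok8 <- !is.na(x) & n == 8L & grepl("^\\d{8}$", x)
  ok6 <- !is.na(x) & n == 6L & grepl("^\\d{6}$", x)
  ok4 <- !is.na(x) & n == 4L & grepl("^\\d{4}$", x)
  padded[ok8] <- x[ok8]
  padded[ok6] <- paste0(x[ok6], "01")
  padded[ok4] <- paste0(x[ok4], "0101")
  imprecise[ok6 | ok4] <- TRUE
  cal <- as.Date(padded, format = "%Y%m%d")
  valid <- !is.na(cal)
  data.table(
    date = ifelse(valid, suppressWarnings(as.integer(padded)), NA_integer_),
    imprecise = imprecise & valid,
    valid = valid
  )
}

# canonical column sets per table; first block is required
.faers_columns <- list(
  demo = list(required = c("primaryid", "caseid", "fda_dt"),
              optional = c("sex", "gndr_cod", "age", "age_cod", "wt",
                           "occp_cod", "reporter_country")),
  drug = list(required = c("primaryid", "drug_seq", "role_cod", "drugname"),
              optional = "route"),
  reac = list(required = c("primaryid", "pt"), optional = character()),
  outc = list(required = c("primaryid", "outc_cod"), optional = character()),
  indi = list(required = c("primaryid", "indi_drug_seq", "indi_pt"),
              optional = character()),
  ther = list(required = c("primaryid", "dsg_drug_seq", "start_dt"),
              optional = "end_dt")
)

.outcome_codes <- c("DE", "LT", "HO", "DS", "CA", "RI", "OT")

find_faers_file <- function(dir_path, table, quarter = NULL) {
  tag <- if (is.null(quarter)) "" else {
    pq <- parse_quarter(quarter)
    sprintf("%02dq%d", pq[1] %% 100L, pq[2])
  }
  pat <- sprintf("^%s.*%s.*\\.txt$", table, tag)
  hits <- list.files(dir_path, pattern = pat, ignore.case = TRUE)
  if (length(hits) == 0L) return(NA_character_)
  file.path(dir_path, sort(hits)[1])
}

read_faers_table <- function(path, table) {
  spec <- .faers_columns[[table]]
  dt <- fread(path, sep = "$", quote = "", header = TRUE,
              colClasses = "character", fill = TRUE, na.strings = NULL)
  setnames(dt, tolower(names(dt)))
  if (table == "demo" && "gndr_cod" %in% names(dt) && !"sex" %in% names(dt))
    setnames(dt, "gndr_cod", "sex")
  known <- setdiff(c(spec$required, spec$optional), "gndr_cod")
  unknown <- setdiff(names(dt), known)
  if (length(unknown)) {
    warning(sprintf("%s: ignoring unknown column(s): %s",
                    basename(path), paste(unknown, collapse = ", ")),
            call. = FALSE)
    dt[, (unknown) := NULL]
  }
  missing_req <- setdiff(spec$required, names(dt))
  if (length(missing_req))
    stop(sprintf("%s: missing required column(s): %s",
                 basename(path), paste(missing_req, collapse = ", ")))
  for (col in setdiff(known, names(dt))) dt[, (col) := NA_character_]
  dt
}

#' Read one quarter of FAERS-style ASCII tables
#'
#' Reads the six '$'-delimited tables (DEMO, DRUG, REAC, OUTC, INDI, THER)
#' from `dir_path`. Rows that cannot be interpreted — blank primaryid,
#' unparseable FDA_DT in DEMO, or a primaryid in a satellite table that has
#' no DEMO row — are quarantined with file and line diagnostics, never
#' silently dropped.
#'
#' @param dir_path directory containing the table files.
#' @param quarter optional quarter label (e.g. `"2018Q4"`) used to select
#'   files named in FAERS style (`DEMO18Q4.txt`); when `NULL` the first file
#'   matching each table prefix is used.
#' @return an object of class `faers_raw`: a list with the six parsed tables,
#'   a `load_report` data.table (`table`, `rows_in`, `rows_parsed`,
#'   `rows_quarantined`) and a `quarantine` data.table (`table`, `file`,
#'   `line`, `reason`).
#' @export
read_faers_quarter <- function(dir_path, quarter = NULL) {
  if (!dir.exists(dir_path)) stop("input directory does not exist: ", dir_path)
  tables <- names(.faers_columns)
  raw <- list(); quar <- list(); rep_rows <- list()
  paths <- vapply(tables, find_faers_file, "", dir_path = dir_path,
                  quarter = quarter)
  for (tb in c("demo", "drug", "reac")) {
    if (is.na(paths[[tb]]))
      stop(sprintf("mandatory %s table not found in %s", toupper(tb), dir_path))
  }
  for (tb in tables) {
    if (is.na(paths[[tb]])) {   # optional table absent: empty
      cols <- c(.faers_columns[[tb]]$required, .faers_columns[[tb]]$optional)
      cols <- setdiff(cols, "gndr_cod")
      dt <- setnames(data.table(matrix(character(), 0, length(cols))), cols)
      raw[[tb]] <- dt
      rep_rows[[tb]] <- data.table(table = tb, rows_in = 0L, rows_parsed = 0L,
                                   rows_quarantined = 0L)
      next
    }
    dt <- read_faers_table(paths[[tb]], tb)
    dt[, line := .I + 1L]   # header is line 1
    bad <- trimws(dt$primaryid) == "" | is.na(dt$primaryid)
    reason <- ifelse(bad, "blank primaryid", NA_character_)
    if (tb == "demo") {
      pd <- parse_fda_dt(dt$fda_dt)
      reason[!bad & !pd$valid] <- "unparseable fda_dt"
      bad <- bad | !pd$valid
      dt[, fda_dt_int := pd$date]
      dt[, fda_dt_imprecise := pd$imprecise]
    }
    rows_in <- nrow(dt)
    q <- dt[bad][, .(table = tb, file = basename(paths[[tb]]), line,
                     reason = reason[bad])]
    raw[[tb]] <- dt[!bad]
    quar[[tb]] <- q
    rep_rows[[tb]] <- data.table(table = tb, rows_in = rows_in,
                                 rows_parsed = rows_in - nrow(q),
                                 rows_quarantined = nrow(q))
  }
  # satellite rows must refer to a DEMO primaryid
  demo_ids <- unique(raw$demo$primaryid)
  for (tb in setdiff(tables, "demo")) {
    dt <- raw[[tb]]
    if (!nrow(dt)) next
    orphan <- !dt$primaryid %in% demo_ids
    if (any(orphan)) {
      quar[[paste0(tb, "_orphan")]] <-
        dt[orphan, .(table = tb, file = basename(paths[[tb]]), line,
                     reason = "primaryid absent from DEMO")]
      raw[[tb]] <- dt[!orphan]
      rep_rows[[tb]][, `:=`(rows_parsed = rows_parsed - sum(orphan),
                            rows_quarantined = rows_quarantined + sum(orphan))]
    }
  }
  for (tb in tables) if ("line" %in% names(raw[[tb]])) raw[[tb]][, line := NULL]
  structure(
    list(demo = raw$demo, drug = raw$drug, reac = raw$reac, outc = raw$outc,
         indi = raw$indi, ther = raw$ther,
         load_report = rbindlist(rep_rows),
         quarantine = if (length(quar)) rbindlist(quar) else
           data.table(table = character(), file = character(),
                      line = integer(), reason = character())),
    class = "faers_raw")
}

#' @export
print.faers_raw <- function(x, ...) {
  cat("FAERS raw tables\n")
  print(x$load_report)
  invisible(x)
}

# age unit conversion to years; unknown unit -> NA
.age_factor <- c(DEC = 10, YR = 1, MON = 1 / 12, WK = 1 / 52.14,
                 DY = 1 / 365.25, HR = 1 / 8766)

convert_age_years <- function(age, age_cod) {
  v <- suppressWarnings(as.numeric(age))
  f <- .age_factor[toupper(trimws(age_cod))]
  unname(v * f)
}

.reporter_map <- c(CN = "Consumer", MD = "Physician", PH = "Pharmacist",
                   OT = "OtherHealthProfessional",
                   HP = "OtherHealthProfessional", LW = "Lawyer")

#' Assemble case reports from raw FAERS tables
#'
#' Joins the six tables on `primaryid` (and drug sequence number where
#' relevant) into one row per report version. Ages are converted to years
#' from the FAERS unit code (DEC, YR, MON, WK, DY, HR); blank or unknown sex
#' becomes `"UNK"`; reaction terms are case-normalized. Reports with no
#' reaction rows are quarantined (a safety report without an adverse event
#' carries no signal information).
#'
#' Time to onset is a proxy: the difference in days between FDA_DT and the
#' earliest therapy start date, computed only when both are full calendar
#' dates and the start does not postdate the report; otherwise missing.
#' `has_ther` records whether any therapy row exists, which defines the
#' denominator for onset summaries.
#'
#' @param raw a `faers_raw` object from [read_faers_quarter()].
#' @return a `data.table` of class `faers_reports`, one row per report
#'   version, with list-columns `pts`, `outcomes`, `routes`, `drugs`
#'   (per-report data.table of `seq`, `role`, `name_raw`, `route`) and
#'   `indications` (`seq`, `term`). The number of reaction-less quarantined
#'   reports is in `attr(x, "n_quarantined")`.
#' @export
assemble_reports <- function(raw) {
  stopifnot(inherits(raw, "faers_raw"))
  demo <- copy(raw$demo)
  rep <- demo[, .(
    primaryid = trimws(primaryid),
    caseid = trimws(caseid),
    fda_dt = fda_dt_int,
    fda_dt_imprecise = fda_dt_imprecise,
    quarter = quarter_label(fda_dt_int),
    sex = fifelse(toupper(trimws(sex)) %in% c("F", "M"),
                  toupper(trimws(sex)), "UNK"),
    age_years = convert_age_years(age, age_cod),
    weight_kg = suppressWarnings(as.numeric(wt)),
    reporter = {
      r <- .reporter_map[toupper(trimws(occp_cod))]
      fifelse(is.na(r), "UNK", r)
    },
    country = {
      cc <- toupper(trimws(reporter_country))
      fifelse(is.na(cc) | cc == "", "UNK", cc)
    }
  )]
  rep[, primaryid_num := suppressWarnings(as.numeric(primaryid))]

  reac <- raw$reac[, .(primaryid = trimws(primaryid), pt = normalize_term(pt))]
  reac <- unique(reac[pt != ""])
  pts <- reac[, .(pts = list(pt)), by = primaryid]

  outc <- raw$outc[, .(primaryid = trimws(primaryid),
                       code = toupper(trimws(outc_cod)))]
  outc <- unique(outc[code %in% .outcome_codes])
  outs <- outc[, .(outcomes = list(code)), by = primaryid]

  drug <- raw$drug[, .(primaryid = trimws(primaryid),
                       seq = suppressWarnings(as.integer(drug_seq)),
                       role = toupper(trimws(role_cod)),
                       name_raw = trimws(drugname),
                       route = normalize_term(route))]
  drugs <- drug[, .(drugs = list(data.table(seq, role, name_raw, route))),
                by = primaryid]
  routes <- drug[role == "PS" & !is.na(route) & route != "",
                 .(routes = list(unique(route))), by = primaryid]

  indi <- raw$indi[, .(primaryid = trimws(primaryid),
                       seq = suppressWarnings(as.integer(indi_drug_seq)),
                       term = normalize_term(indi_pt))]
  inds <- indi[term != "", .(indications = list(data.table(seq, term))),
               by = primaryid]

  ther <- raw$ther[, .(primaryid = trimws(primaryid), start_dt)]
  if (nrow(ther)) {
    ps <- parse_fda_dt(ther$start_dt)
    ther[, `:=`(start_int = ps$date, start_full = ps$valid & !ps$imprecise)]
    ths <- ther[, .(has_ther = TRUE,
                    ther_start = if (any(start_full))
                      min(start_int[start_full]) else NA_integer_),
                by = primaryid]
  } else {
    ths <- data.table(primaryid = character(), has_ther = logical(),
                      ther_start = integer())
  }

  for (x in list(pts, outs, drugs, routes, inds, ths)) setkey(x, primaryid)
  setkey(rep, primaryid)
  rep <- ths[inds[routes[drugs[outs[pts[rep]]]]]]
  setnames(rep, "pts", "pts")
  rep[, has_ther := fifelse(is.na(has_ther), FALSE, has_ther)]
  # onset proxy: report date minus earliest full therapy start date
  rep[, tto_days := {
    ok <- !is.na(ther_start) & !is.na(fda_dt) & !fda_dt_imprecise
    tt <- as.numeric(ymd_int_to_date(fda_dt) - ymd_int_to_date(ther_start))
    fifelse(ok & tt >= 0, tt, NA_real_)
  }]
  rep[, ther_start := NULL]

  empty_dt <- function(col, proto) {
    idx <- vapply(rep[[col]], is.null, TRUE)
    if (any(idx)) rep[idx, (col) := list(list(proto))]
  }
  empty_dt("drugs", data.table(seq = integer(), role = character(),
                               name_raw = character(), route = character()))
  empty_dt("indications", data.table(seq = integer(), term = character()))
  for (col in c("outcomes", "routes")) {
    idx <- vapply(rep[[col]], is.null, TRUE)
    if (any(idx)) rep[idx, (col) := list(list(character()))]
  }

  no_pt <- vapply(rep$pts, function(p) is.null(p) || length(p) == 0L, TRUE)
  out <- rep[!no_pt]
  setcolorder(out, c("caseid", "primaryid", "primaryid_num", "fda_dt",
                     "fda_dt_imprecise", "quarter", "sex", "age_years",
                     "weight_kg", "reporter", "country"))
  setattr(out, "class", c("faers_reports", class(data.table())))
  setattr(out, "n_quarantined", sum(no_pt))
  out[]
}

#' Read and pool several quarters
#'
#' @param dir_path directory holding quarterly FAERS-style files.
#' @param quarters character vector of quarter labels.
#' @return pooled `faers_reports` table (not yet deduplicated).
#' @export
ingest_quarters <- function(dir_path, quarters) {
  parts <- lapply(quarters, function(q) {
    raw <- read_faers_quarter(dir_path, quarter = q)
    assemble_reports(raw)
  })
  out <- rbindlist(parts, use.names = TRUE)
  setattr(out, "class", c("faers_reports", class(data.table())))
  setattr(out, "n_quarantined",
          sum(vapply(parts, attr, 0L, "n_quarantined")))
  out[]
}

#' Write a tabular result to CSV or TSV
#'
#' UTF-8, header always written, round-trips through [read_table_file()]
#' without loss.
#'
#' @param rows data.frame of results (no list columns).
#' @param path output file path.
#' @param format `"csv"` or `"tsv"`.
#' @export
write_table_file <- function(rows, path, format = c("csv", "tsv")) {
  format <- match.arg(format)
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("unwritable path (no such directory): ", dir)
  fwrite(as.data.table(rows), path, sep = if (format == "csv") "," else "\t",
         quote = "auto", na = "NA")
}

#' @rdname write_table_file
#' @export
read_table_file <- function(path, format = c("csv", "tsv")) {
  format <- match.arg(format)
  fread(path, sep = if (format == "csv") "," else "\t", na.strings = "NA")
}

# long views used by the signal engine ---------------------------------------

#' Long preferred-term view of a report table
#'
#' @param reports a `faers_reports` table.
#' @return data.table (`row_id`, `pt`), unique per report and PT.
#' @export
pt_long <- function(reports) {
  n <- vapply(reports$pts, length, 0L)
  data.table(row_id = rep(seq_len(nrow(reports)), n),
             pt = unlist(reports$pts, use.names = FALSE))
}

#' Long drug view of a report table
#'
#' @param reports a `faers_reports` table.
#' @return data.table (`row_id`, `seq`, `role`, `name_raw`, `route`, and
#'   `name_std` when standardization has been applied).
#' @export
drug_long <- function(reports) {
  dl <- rbindlist(reports$drugs, idcol = "row_id", use.names = TRUE,
                  fill = TRUE)
  dl
}
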