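`%||%` <- function(x, y) if (is.null(x)) y else x

#' Normalize a free-text term
#'
#' Trims, case-folds and collapses internal whitespace. Used for drug names,
#' MedDRA-style preferred terms and indication terms so that matching is
#' insensitive to case and spacing.
#'
#' @param x character vector.
#' @return normalized character vector.
#' @export
normalize_term <- function(x) {
  x <- tolower(trimws(as.character(x)))
  gsub("[[:space:]]+", " ", x)
}

# quarter label ("2018Q4") from a YYYYMMDD integer date
quarter_label <- function(fda_dt) {
  yr <- fda_dt %/% 10000L
  mo <- (fda_dt %/% 100L) %% 100L
  ifelse(is.na(fda_dt), NA_character_, sprintf("%dQ%d", yr, (mo - 1L) %/% 3L + 1L))
}

# sequence of quarter labels spanning two labels inclusive
quarter_seq <- function(from, to) {
  pf <- parse_quarter(from); pt_ <- parse_quarter(to)
  idx <- seq(pf[1] * 4L + pf[2] - 1L, pt_[1] * 4L + pt_[2] - 1L)
  sprintf("%dQ%d", idx %/% 4L, idx %% 4L + 1L)
}

parse_quarter <- function(q) {
  m <- regmatches(q, regexec("^(\\d{4})Q([1-4])$", q))[[1]]
  if (length(m) != 3L) stop("invalid quarter label: ", q)
  c(as.integer(m[2]), as.integer(m[3]))
}

# YYYYMMDD integer -> Date
ymd_int_to_date <- function(x) {
  as.Date(sprintf("%08d", x), format = "%Y%m%d")
}

date_to_ymd_int <- function(d) {
  as.integer(format(d, "%Y%m%d"))
}
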