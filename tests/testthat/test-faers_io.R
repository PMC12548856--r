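test_that("quarter reading parses, quarantines and conserves row counts", {
  d <- write_faers_fixture(withr::local_tempdir())
  raw <- suppressWarnings(read_faers_quarter(d, "2018Q4"))

  lr <- raw$load_report
  expect_equal(lr[table == "demo", rows_in], 4L)
  expect_equal(lr[table == "drug", rows_in], 5L)
  # invalid calendar date 20189999 quarantined, not dropped
  expect_equal(lr[table == "demo", rows_quarantined], 1L)
  expect_true(any(raw$quarantine$reason == "unparseable fda_dt"))
  # orphan reaction (primaryid absent from DEMO) quarantined with line info
  expect_true(any(raw$quarantine$table == "reac" & raw$quarantine$line == 5L))
  # conservation: rows_in == rows_parsed + rows_quarantined everywhere
  expect_equal(lr$rows_in, lr$rows_parsed + lr$rows_quarantined)
})

test_that("unknown columns warn and mandatory files are required", {
  d <- write_faers_fixture(withr::local_tempdir())
  expect_warning(read_faers_quarter(d, "2018Q4"), "junkcol")
  file.remove(file.path(d, "reac18q4.txt"))
  expect_error(read_faers_quarter(d, "2018Q4"), "REAC")
})

test_that("header-only reaction file yields zero rows without error", {
  d <- write_faers_fixture(withr::local_tempdir())
  writeLines("primaryid$pt", file.path(d, "reac18q4.txt"))
  raw <- suppressWarnings(read_faers_quarter(d, "2018Q4"))
  expect_equal(nrow(raw$reac), 0L)
  expect_equal(raw$load_report[table == "reac", rows_in], 0L)
})

test_that("assembly converts units, normalizes terms and quarantines empty reports", {
  d <- write_faers_fixture(withr::local_tempdir())
  rep <- assemble_reports(suppressWarnings(read_faers_quarter(d, "2018Q4")))

  r1 <- rep[caseid == "111"]
  expect_equal(r1$age_years, 65)                       # 780 months
  expect_setequal(r1$pts[[1]], c("death", "fatigue"))  # case-normalized
  expect_equal(r1$quarter, "2018Q4")
  expect_equal(r1$tto_days, 30)                        # 20180901 -> 20181001

  r2 <- rep[caseid == "112"]
  expect_equal(r2$sex, "UNK")                          # blank sex
  expect_equal(r2$age_years, 65)                       # 6.5 decades
  expect_true(r2$has_ther)
  expect_true(is.na(r2$tto_days))                      # partial start date

  # report 114 has no reaction rows: quarantined
  expect_false("114" %in% rep$caseid)
  expect_equal(attr(rep, "n_quarantined"), 1L)
})

test_that("age unit conversion follows the FAERS unit codes", {
  expect_equal(convert_age_years(780, "MON"), 65)
  expect_equal(convert_age_years(6.5, "DEC"), 65)
  expect_equal(convert_age_years(70, "YR"), 70)
  expect_equal(convert_age_years(52.14, "WK"), 1)
  expect_equal(convert_age_years(365.25, "DY"), 1)
  expect_equal(convert_age_years(8766, "HR"), 1)
  expect_true(is.na(convert_age_years(70, "XX")))      # unknown unit
})

test_that("partial dates pad for ordering and are flagged imprecise", {
  p <- parse_fda_dt(c("20181001", "201810", "2018", "20189999", "garbage"))
  expect_equal(p$date, c(20181001L, 20181001L, 20180101L, NA, NA))
  expect_equal(p$imprecise, c(FALSE, TRUE, TRUE, FALSE, FALSE))
  expect_equal(p$valid, c(TRUE, TRUE, TRUE, FALSE, FALSE))
})

test_that("tabular output round-trips through write and read", {
  sig <- data.table::data.table(
    pt = c("death", "nausea", "fatigue", "fall", "rash"),
    a = 1:5, ror = c(1.5, 2.25, 0.5, 10, 1),
    signal = c(TRUE, FALSE, TRUE, TRUE, FALSE))
  f <- withr::local_tempfile(fileext = ".csv")
  write_table_file(sig, f)
  back <- read_table_file(f)
  expect_equal(as.data.frame(back), as.data.frame(sig))

  # empty table -> header-only file
  write_table_file(sig[0], f)
  expect_equal(readLines(f), "pt,a,ror,signal")
  expect_equal(nrow(read_table_file(f)), 0L)
})
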