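test_that("frequency tables conserve counts and percentages", {
  ft <- frequency_table("sex", c("Female", "Male", "Unknown"),
                        c(796, 1193, 942), 2931)
  expect_equal(sum(ft$count), 2931)
  expect_equal(sum(ft$percent), 100, tolerance = 0.05)
  expect_equal(ft$percent, c(27.16, 40.70, 32.14))
})

test_that("outcome and onset percentages use their specified denominators", {
  n <- 20
  outcomes <- c(rep(list("DE"), 8), rep(list("HO"), 4),
                replicate(8, character(), simplify = FALSE))
  has_ther <- c(rep(TRUE, 10), rep(FALSE, 10))
  tto <- c(3, 10, 40, 70, 100, rep(NA_real_, 15))
  rep <- mk_reports(rep(list("death"), n), exposed = rep(TRUE, n),
                    outcomes = outcomes, has_ther = has_ther, tto = tto)
  dt <- demographic_table(rep)
  # outcomes: 12 reports specified one; Death 8/12
  expect_equal(dt$outcome[level == "Death", percent], round(800 / 12, 2))
  expect_equal(dt$outcome$denominator[1], 12L)
  # onset: 10 reports carry a therapy record; 5 have computable onset
  expect_equal(dt$onset$denominator[1], 10L)
  expect_equal(dt$onset[level == "Unknown", count], 5L)
  expect_equal(dt$onset[level == "<7", percent], 10)
  expect_equal(dt$onset[level == ">=60", count], 2L)
})

test_that("a single report yields 100 percent everywhere it is counted", {
  rep <- mk_reports(list("death"), exposed = TRUE, sex = "F",
                    outcomes = list("DE"))
  dt <- demographic_table(rep)
  expect_equal(dt$sex[level == "Female", percent], 100)
  expect_equal(dt$outcome[level == "Death", percent], 100)
  expect_equal(dt$country[level == "US", percent], 100)
})

test_that("indication counting follows the drug rows", {
  rep <- mk_reports(rep(list("death"), 5), exposed = rep(TRUE, 5))
  rep$indications[[1]] <- data.table::data.table(
    seq = 1L, term = "amyotrophic lateral sclerosis")
  rep$indications[[2]] <- data.table::data.table(
    seq = 1L, term = "amyotrophic lateral sclerosis")
  rep$indications[[3]] <- data.table::data.table(
    seq = c(1L, 1L), term = c("amyotrophic lateral sclerosis",
                              "cerebral infarction"))
  # reports 4 and 5 carry no indication for the drug
  it <- indication_table(rep, "edaravone")
  expect_equal(it$level[1], "amyotrophic lateral sclerosis")
  expect_equal(it[level == "amyotrophic lateral sclerosis", count], 3L)
  # report 3 contributes to both of its indication levels
  expect_equal(it[level == "cerebral infarction", count], 1L)
  expect_equal(it[level == "product used for unknown indication", count], 2L)
  expect_equal(sum(it$count), it$denominator[1])
})

test_that("quarter bucketing and the top-k helper follow the calendar", {
  rep <- mk_reports(rep(list("death"), 4), exposed = rep(TRUE, 4),
                    fda_dt = c(20181001L, 20181231L, 20190215L, 20181115L))
  qd <- quarterly_distribution(rep)
  expect_equal(qd[quarter == "2018Q4", count], 3L)
  expect_equal(qd[quarter == "2019Q1", count], 1L)

  # zero-count quarters inside the range are present
  qd2 <- quarterly_distribution(rep, from = "2018Q1", to = "2019Q2")
  expect_equal(nrow(qd2), 6L)
  expect_equal(qd2[quarter == "2018Q2", count], 0L)

  toy <- data.table::data.table(
    quarter = c("2018Q4", "2020Q4", "2018Q1", "2019Q2"),
    count = c(196L, 176L, 164L, 10L))
  expect_equal(top_quarters(toy, 3)$count, c(196L, 176L, 164L))

  # empty input: all quarters zero
  qe <- quarterly_distribution(rep[0], from = "2018Q1", to = "2018Q4")
  expect_equal(qe$count, rep(0L, 4))
})
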