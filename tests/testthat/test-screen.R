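test_that("the toy 2x2 matches direct enumeration", {
  rep <- toy_reports()
  tab <- build_contingency(rep, "edaravone", "nausea")
  expect_equal(tab$a, 2); expect_equal(tab$b, 2)
  expect_equal(tab$c, 1); expect_equal(tab$d, 5)
  expect_equal(tab$n, nrow(rep))

  # event nobody reports: a = c = 0, margins preserved
  t0 <- build_contingency(rep, "edaravone", "vertigo")
  expect_equal(t0$a, 0); expect_equal(t0$c, 0)
  expect_equal(t0$a + t0$b, 4)
  expect_equal(t0$n, 10)
})

test_that("stratified cells equal a brute-force filter-then-count", {
  rep <- toy_reports()
  rep$sex <- c("F", "M", "F", "F", "M", "F", "F", "M", "F", "M")
  stratum <- rep$sex == "F"
  tab <- build_contingency(rep, "edaravone", "nausea", stratum = stratum)
  exp_flag <- is_exposed(rep, "edaravone")
  oracle <- oracle_contingency(rep[stratum], exp_flag[stratum], "nausea")
  expect_equal(tab$a, oracle$a); expect_equal(tab$b, oracle$b)
  expect_equal(tab$c, oracle$c); expect_equal(tab$d, oracle$d)
})

test_that("screening enforces the minimum report count", {
  # one PT passes on disproportionality but has only a = 2
  pts <- c(rep(list(c("nausea")), 2), rep(list("fatigue"), 6),
           rep(list("headache"), 22))
  exposed <- c(TRUE, TRUE, rep(TRUE, 6), rep(FALSE, 22))
  rep <- mk_reports(pts, exposed)
  sig <- screen_signals(rep, "edaravone")
  expect_false("nausea" %in% sig$pt)
  expect_true(all(sig$a >= 3))
})

test_that("a strongly injected association passes all three rules", {
  set.seed(41)
  n <- 8000; p_exp <- 0.1; p_ev <- 0.02; rho <- 10
  exposed <- runif(n) < p_exp
  p <- ifelse(exposed, min(1, rho * p_ev), p_ev)
  has_ev <- runif(n) < p
  pts <- lapply(seq_len(n), function(i)
    if (has_ev[i]) c("nausea", "fatigue") else "fatigue")
  rep <- mk_reports(pts, exposed)
  sig <- screen_signals(rep, "edaravone")
  row <- sig[pt == "nausea"]
  expect_true(row$flag_ror && row$flag_prr && row$flag_bcpnn)
  expect_true(row$signal)
})

test_that("combination mode 'all' flags a subset of 'any'", {
  set.seed(42)
  n <- 4000
  exposed <- runif(n) < 0.1
  pts <- lapply(seq_len(n), function(i)
    sample(c("nausea", "fatigue", "headache", "death"),
           sample(1:2, 1)))
  rep <- mk_reports(pts, exposed)
  all_m <- screen_signals(rep, "edaravone",
                          signal_criteria(combine = "all"))
  any_m <- screen_signals(rep, "edaravone",
                          signal_criteria(combine = "any"))
  expect_true(all(all_m[signal == TRUE, pt] %in% any_m[signal == TRUE, pt]))
})

test_that("ranking is descending with count then alphabetical tie-breaks", {
  sig <- data.table::data.table(
    pt = c("b term", "a term", "c term", "d term"),
    soc = "x", a = c(5, 7, 7, 9),
    ror_lo = c(6.16, 4.93, 4.93, 4.93))
  r <- rank_signals(data.table::copy(sig), key = "ror_lo")
  expect_equal(r$pt, c("b term", "d term", "a term", "c term"))
  r2 <- rank_signals(data.table::copy(sig), key = "a")
  expect_equal(r2$pt[1], "d term")
})

test_that("SOC counting is per report and intervals are ordered", {
  # one report with three PTs in the same SOC counts once at SOC level
  rep <- mk_reports(list(c("nausea", "vomiting", "dysphagia"), "fatigue",
                         "death", "rash"),
                    exposed = c(TRUE, TRUE, FALSE, FALSE))
  soc <- soc_level_stats(rep, "edaravone")
  expect_equal(soc[soc == "Gastrointestinal disorders", a], 1L)
  expect_true(all(soc$ic025 < soc$ic, na.rm = TRUE))

  # brute-force per-report SOC membership count among exposed reports
  m <- default_pt_soc_map()
  exp_flag <- is_exposed(rep, "edaravone")
  socs_per_report <- lapply(rep$pts[exp_flag],
                            function(p) unique(map_pt_to_soc(p, m)))
  brute <- table(unlist(socs_per_report))
  for (s in names(brute))
    expect_equal(soc[soc == s, a], as.integer(brute[[s]]))
})

test_that("sex strata are isolated and an association shows only where injected", {
  set.seed(43)
  n <- 6000
  sex <- sample(c("F", "M", "UNK"), n, replace = TRUE,
                prob = c(0.35, 0.45, 0.2))
  exposed <- runif(n) < 0.1
  p_ev <- ifelse(exposed & sex == "M", 0.25, 0.02)   # male-only association
  has_ev <- runif(n) < p_ev
  pts <- lapply(seq_len(n), function(i)
    if (has_ev[i]) c("nausea", "fatigue") else "fatigue")
  rep <- mk_reports(pts, exposed, sex = sex)
  strata <- stratified_signals(rep, "edaravone")
  expect_true(strata$M[pt == "nausea", signal])
  expect_true(nrow(strata$F[pt == "nausea"]) == 0 ||
                !strata$F[pt == "nausea", signal])
  # strata are computed on disjoint report sets
  expect_equal(strata$M[pt == "fatigue", a + b],
               sum(exposed & sex == "M"))
  expect_equal(strata$F[pt == "fatigue", a + b],
               sum(exposed & sex == "F"))
})

test_that("a stratum without exposed reports returns empty with a warning", {
  rep <- mk_reports(list("death", "nausea"), exposed = c(TRUE, FALSE),
                    sex = c("M", "F"))
  expect_warning(out <- screen_signals(rep, "edaravone",
                                       stratum = rep$sex == "F"),
                 "no exposed")
  expect_equal(nrow(out), 0L)
})
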