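#' Default drug catalog for the synthetic generator
#'
#' One target drug (edaravone) plus background drugs. `prevalence` is the
#' probability that a report's primary-suspect drug is this one
#' (probabilities sum to 1). Raw-name variants exercise the synonym
#' dictionary.
#'
#' @return data.table (`name`, `prevalence`, `variants` list-column).
#' @export
default_drug_catalog <- function() {
  data.table(
    name = c("edaravone", "riluzole", "baclofen", "omeprazole",
             "acetaminophen", "gabapentin"),
    prevalence = c(0.05, 0.10, 0.10, 0.20, 0.30, 0.25),
    variants = list(
      c("EDARAVONE", "Radicava", "RADICUT", "MCI-186", "Edaravone 30mg"),
      c("RILUZOLE", "Rilutek"),
      c("BACLOFEN", "Baclofen 10mg"),
      c("OMEPRAZOLE", "Prilosec"),
      c("ACETAMINOPHEN", "Tylenol", "Paracetamol"),
      c("GABAPENTIN", "Neurontin")))
}

#' Default preferred-term catalog
#'
#' Baseline per-report probabilities of each PT among unexposed reports.
#' "drug ineffective" doubles as the fallback term assigned to a report
#' whose independent draws produce no reaction, so that every generated
#' report carries at least one PT; its realized frequency therefore exceeds
#' its baseline.
#'
#' @return data.table (`pt`, `baseline`).
#' @export
default_pt_catalog <- function() {
  data.table(
    pt = c("drug ineffective", "death", "fatigue", "headache", "dizziness",
           "asthenia", "fall", "vomiting", "insomnia", "rash", "pneumonia",
           "nausea", "gait disturbance", "dysphagia",
           "catheter site thrombosis"),
    baseline = c(0.30, 0.18, 0.15, 0.12, 0.10, 0.08, 0.05, 0.05, 0.04,
                 0.04, 0.03, 0.02, 0.015, 0.008, 0.002))
}

#' Synthetic FAERS generator configuration
#'
#' Defaults emulate the composition of the edaravone report pool: sex split
#' 40.7% male / 27.2% female / rest unknown, 68.8% age missingness,
#' reporter, country, route and outcome distributions matching the
#' descriptive table of that pool, ~59% of reports carrying an outcome
#' record and ~42% a therapy record (of which about a third have a full
#' start date). Quarters span 2017Q2-2024Q2.
#'
#' @param n_cases number of distinct cases.
#' @param duplicate_rate probability parameter of the geometric number of
#'   extra report versions per case (0 = no duplicates).
#' @param quarters character vector `c(from, to)` of quarter labels.
#' @param drug_catalog see [default_drug_catalog()].
#' @param pt_catalog see [default_pt_catalog()].
#' @param associations data.frame (`drug`, `pt`, `rho`): for reports whose
#'   primary suspect is `drug`, the probability of `pt` becomes
#'   `min(1, rho * baseline)`.
#' @param p_male,p_female sex probabilities (remainder unknown).
#' @param missing_age,missing_weight missingness rates.
#' @param p_outcome probability a report carries an outcome record.
#' @param outcome_probs named outcome-code distribution.
#' @param country_probs,reporter_probs,route_probs categorical
#'   distributions.
#' @param p_ther probability of a therapy record; `p_ther_dated` the
#'   conditional probability its start date is a full date.
#' @param tto_band_probs distribution over onset bands (days <7, 7-28,
#'   28-60, >=60) for dated therapy records.
#' @param indication_probs indication distribution for the target drug.
#' @param fallback_pt the guaranteed-reaction fallback term.
#' @param seed integer seed; all generator randomness flows from it.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(n_cases = 20000L,
                             duplicate_rate = 0.1,
                             quarters = c("2017Q2", "2024Q2"),
                             drug_catalog = default_drug_catalog(),
                             pt_catalog = default_pt_catalog(),
                             associations = data.table(drug = character(),
                                                       pt = character(),
                                                       rho = numeric()),
                             p_male = 0.407, p_female = 0.272,
                             missing_age = 0.688, missing_weight = 0.65,
                             p_outcome = 0.592,
                             outcome_probs = c(DE = 0.555, OT = 0.216,
                                               HO = 0.209, LT = 0.011,
                                               DS = 0.006, RI = 0.003),
                             country_probs = c(US = 0.780, JP = 0.157,
                                               OTHER = 0.063),
                             reporter_probs = c(CN = 0.588, MD = 0.221,
                                                PH = 0.097, OT = 0.093,
                                                UNK = 0.0007, LW = 0.0003),
                             route_probs = c("unknown" = 0.435,
                                             "intravenous" = 0.346,
                                             "intravenous drip" = 0.145,
                                             "oral" = 0.065,
                                             "parenteral" = 0.009),
                             p_ther = 0.424, p_ther_dated = 0.325,
                             tto_band_probs = c(0.33, 0.19, 0.08, 0.40),
                             indication_probs = c(
                               "amyotrophic lateral sclerosis" = 0.72,
                               "product used for unknown indication" = 0.24,
                               "cerebral infarction" = 0.03,
                               "thrombotic cerebral infarction" = 0.01),
                             fallback_pt = "drug ineffective",
                             seed = 1L) {
  stopifnot(n_cases > 0, duplicate_rate >= 0, duplicate_rate < 1,
            all(pt_catalog$baseline >= 0 & pt_catalog$baseline <= 1),
            nrow(associations) == 0 || all(associations$rho > 0),
            abs(sum(drug_catalog$prevalence) - 1) < 1e-8)
  structure(as.list(environment()), class = "synthetic_config")
}

#' Drop injected associations from a configuration
#'
#' The null scenario: drug exposure and events are independent; used for
#' type-I error calibration.
#'
#' @param config a `synthetic_config`.
#' @return the configuration with an empty association list.
#' @export
null_config <- function(config) {
  config$associations <- data.table(drug = character(), pt = character(),
                                    rho = numeric())
  config
}

#' Generate ground-truth case reports in memory
#'
#' Draws the final (true) version of every case from the configuration's
#' probability model: exposure, demographics, reactions (independent
#' Bernoulli per catalog PT, with association multipliers on the exposed
#' arm and the fallback PT guaranteeing at least one reaction), outcome,
#' indication and therapy dates.
#'
#' @param config a `synthetic_config`.
#' @return data.table, one row per case, with generator-level fields.
#' @export
generate_truth <- function(config) {
  set.seed(config$seed)
  n <- config$n_cases
  dc <- config$drug_catalog
  pc <- config$pt_catalog

  qfrom <- parse_quarter(config$quarters[1])
  qto <- parse_quarter(config$quarters[2])
  d0 <- as.Date(sprintf("%d-%02d-01", qfrom[1], (qfrom[2] - 1) * 3 + 1))
  d1 <- as.Date(sprintf("%d-%02d-01", qto[1], qto[2] * 3)) + 27
  fda <- d0 + sample.int(as.integer(d1 - d0) + 1L, n, replace = TRUE) - 1L

  sex <- sample(c("M", "F", ""), n, replace = TRUE,
                prob = c(config$p_male, config$p_female,
                         1 - config$p_male - config$p_female))
  age <- ifelse(runif(n) < config$missing_age, NA_real_, {
    band <- sample.int(4L, n, replace = TRUE,
                       prob = c(0.01, 0.04, 0.23, 0.72))
    lo <- c(2, 18, 45, 60)[band]; hi <- c(17, 44, 59, 90)[band]
    round(runif(n, lo, hi), 1)
  })
  wt <- ifelse(runif(n) < config$missing_weight, NA_real_,
               round(rnorm(n, 70, 12), 1))
  occp <- sample(c("CN", "MD", "PH", "OT", "", "LW"), n, replace = TRUE,
                 prob = config$reporter_probs)
  country <- sample(names(config$country_probs), n, replace = TRUE,
                    prob = config$country_probs)
  country[country == "OTHER"] <- sample(c("FR", "DE", "CN", "GB", "CA"),
                                        sum(country == "OTHER"),
                                        replace = TRUE)
  ps_idx <- sample.int(nrow(dc), n, replace = TRUE, prob = dc$prevalence)
  ps_drug <- dc$name[ps_idx]
  ps_raw <- vapply(ps_idx, function(i) {
    v <- dc$variants[[i]]; v[sample.int(length(v), 1L)]
  }, "")
  route <- sample(names(config$route_probs), n, replace = TRUE,
                  prob = config$route_probs)
  n_con <- sample(0:2, n, replace = TRUE, prob = c(0.5, 0.35, 0.15))
  bg <- dc[name != "edaravone"]
  concomitants <- lapply(n_con, function(k)
    if (k == 0) character() else sample(toupper(bg$name), k))

  # reaction draws: n x K Bernoulli with association-adjusted probabilities
  K <- nrow(pc)
  pm <- matrix(pc$baseline, n, K, byrow = TRUE)
  assoc <- as.data.table(config$associations)
  if (nrow(assoc)) {
    for (i in seq_len(nrow(assoc))) {
      j <- match(normalize_term(assoc$pt[i]), pc$pt)
      if (is.na(j)) stop("association PT not in catalog: ", assoc$pt[i])
      rows <- ps_drug == normalize_term(assoc$drug[i])
      pm[rows, j] <- pmin(1, assoc$rho[i] * pc$baseline[j])
    }
  }
  draws <- matrix(runif(n * K), n, K) < pm
  fb <- match(config$fallback_pt, pc$pt)
  empty <- rowSums(draws) == 0L
  draws[empty, fb] <- TRUE
  pts <- apply(draws, 1L, function(r) pc$pt[r], simplify = FALSE)

  outcome <- ifelse(runif(n) < config$p_outcome,
                    sample(names(config$outcome_probs), n, replace = TRUE,
                           prob = config$outcome_probs), NA_character_)
  indication <- ifelse(ps_drug == "edaravone",
                       sample(names(config$indication_probs), n,
                              replace = TRUE,
                              prob = config$indication_probs),
                       ifelse(runif(n) < 0.5,
                              "product used for unknown indication",
                              NA_character_))
  has_ther <- runif(n) < config$p_ther
  ther_dated <- has_ther & runif(n) < config$p_ther_dated
  band <- sample.int(4L, n, replace = TRUE, prob = config$tto_band_probs)
  tto <- floor(runif(n, c(0, 7, 28, 60)[band], c(7, 28, 60, 366)[band]))

  data.table(
    case_num = seq_len(n),
    caseid = as.character(10000000L + seq_len(n)),
    fda_dt = date_to_ymd_int(fda),
    sex = sex, age = age, wt = wt, occp = occp, country = country,
    ps_drug = ps_drug, ps_raw = ps_raw, route = route,
    concomitants = concomitants, pts = pts,
    outcome = outcome, indication = indication,
    has_ther = has_ther, ther_dated = ther_dated, tto = tto)
}

#' Write synthetic FAERS-style quarterly files
#'
#' Expands each case into one or more report versions (geometric number of
#' extras at `duplicate_rate`), with strictly increasing (FDA_DT,
#' PRIMARYID) within a case and the last version equal to the ground truth.
#' Earlier versions differ only in mutable fields: report date, primaryid,
#' and possibly one fewer reaction. Writes the six '$'-delimited tables per
#' quarter into `out_dir` and a `manifest.csv` naming every case's true
#' final version.
#'
#' @param config a `synthetic_config`.
#' @param out_dir output directory (created if needed; must be creatable).
#' @return invisibly, a list with `truth` (from [generate_truth()]),
#'   `manifest` (data.table `caseid`, `true_primaryid`, `n_versions`) and
#'   `associations`.
#' @export
generate_faers <- function(config, out_dir) {
  truth <- generate_truth(config)
  n <- nrow(truth)
  ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)

  extra <- if (config$duplicate_rate > 0)
    rgeom(n, 1 - config$duplicate_rate) else integer(n)
  n_ver <- 1L + extra

  ver <- truth[rep(seq_len(n), n_ver)]
  ver[, version := seq_len(.N), by = case_num]
  ver[, n_versions := .N, by = case_num]
  ver[, primaryid := as.character(case_num * 100L + version)]
  # earlier versions predate the truth by a random non-negative offset,
  # sorted so (fda_dt, primaryid) increases with version; offset 0 creates
  # the FDA_DT tie resolved by the higher primaryid
  off <- integer(nrow(ver))
  extra_rows <- ver$version < ver$n_versions
  off[extra_rows] <- sample(0:120, sum(extra_rows), replace = TRUE)
  ver[, off := off]
  ver[, off := sort(off, decreasing = TRUE), by = case_num]
  ver[version == n_versions, off := 0L]
  ver[, fda_dt := date_to_ymd_int(ymd_int_to_date(fda_dt) - off)]
  # non-final versions may lack the most recently added reaction
  trim <- extra_rows & vapply(ver$pts, length, 0L) > 1L
  ver[trim, pts := lapply(pts, function(p) p[-length(p)])]

  emit_pt <- function(p) paste0(toupper(substring(p, 1, 1)), substring(p, 2))
  ver[, quarter := quarter_label(fda_dt)]

  for (q in unique(ver$quarter)) {
    vq <- ver[quarter == q]
    pq <- parse_quarter(q)
    tag <- sprintf("%02dq%d", pq[1] %% 100L, pq[2])
    wf <- function(dt, name) {
      fwrite(dt, file.path(out_dir, sprintf("%s%s.txt", name, tag)),
             sep = "$", quote = FALSE, na = "")
    }
    wf(vq[, .(primaryid, caseid, fda_dt,
              sex = sex, age = fifelse(is.na(age), "", as.character(age)),
              age_cod = fifelse(is.na(age), "", "YR"),
              wt = fifelse(is.na(wt), "", as.character(wt)),
              occp_cod = occp, reporter_country = country)], "demo")
    drg <- vq[, {
      nms <- c(ps_raw[[1]], concomitants[[1]])
      .(drug_seq = seq_along(nms),
        role_cod = c("PS", rep("C", length(nms) - 1L)),
        drugname = nms,
        route = c(route[[1]], rep("", length(nms) - 1L)))
    }, by = primaryid]
    wf(drg, "drug")
    rc <- vq[, .(pt = emit_pt(pts[[1]])), by = primaryid]
    wf(rc, "reac")
    oc <- vq[!is.na(outcome), .(primaryid, outc_cod = outcome)]
    wf(oc, "outc")
    ind <- vq[!is.na(indication),
              .(primaryid, indi_drug_seq = 1L, indi_pt = indication)]
    wf(ind, "indi")
    th <- vq[has_ther == TRUE,
             .(primaryid, dsg_drug_seq = 1L,
               start_dt = fifelse(
                 ther_dated,
                 as.character(date_to_ymd_int(ymd_int_to_date(fda_dt) - tto)),
                 substr(as.character(fda_dt), 1, 4)),
               end_dt = "")]
    wf(th, "ther")
  }

  manifest <- ver[version == n_versions,
                  .(caseid, true_primaryid = primaryid, n_versions)]
  write_table_file(manifest, file.path(out_dir, "manifest.csv"))
  invisible(list(truth = truth, manifest = manifest,
                 associations = as.data.table(config$associations),
                 quarters = sort(unique(ver$quarter))))
}

#' Simulate drug-event 2x2 cell counts from the generator's model
#'
#' Exposure and events are independent Bernoulli draws per report in the
#' generator, so the 2x2 cells are binomial: `a ~ Bin(nE, min(1, rho p))`,
#' `c ~ Bin(n - nE, p)` with `nE ~ Bin(n, p_exposed)`. This marginalizes
#' the file-level generator and is used for replicated calibration and
#' recovery experiments.
#'
#' @param n reports per replicate.
#' @param p_exposed probability a report is exposed (primary suspect).
#' @param p_event baseline event probability.
#' @param rho injected relative reporting rate (1 = null).
#' @param nrep number of replicates.
#' @return data.table (`a`, `b`, `c`, `d`), one row per replicate.
#' @export
simulate_contingency <- function(n, p_exposed, p_event, rho = 1,
                                 nrep = 1L) {
  ne <- rbinom(nrep, n, p_exposed)
  a <- rbinom(nrep, ne, min(1, rho * p_event))
  cc <- rbinom(nrep, n - ne, p_event)
  data.table(a = a, b = ne - a, c = cc, d = n - ne - cc)
}

#' Type-I error calibration under the null
#'
#' Replicates the null scenario (no injected association) and records how
#' often each screening rule fires. The ROR rule (`ror_lo > 1`) is a
#' one-sided 95% bound, so its null flag rate should sit near 2.5%.
#'
#' @param n_rep replicates.
#' @param n,p_exposed,p_event scenario size (defaults: 20,000 reports, 5%
#'   exposure, 2% event rate — moderate cell counts where the Woolf
#'   interval is well calibrated).
#' @param criteria a [signal_criteria()] object.
#' @param bcpnn_variant passed to [bcpnn_stats()].
#' @return list with `rates` (named: `ror`, `prr`, `bcpnn`, `all`) and the
#'   per-replicate flag table.
#' @export
null_calibration <- function(n_rep = 2000L, n = 20000L, p_exposed = 0.05,
                             p_event = 0.02, criteria = signal_criteria(),
                             bcpnn_variant = "bate") {
  tabs <- simulate_contingency(n, p_exposed, p_event, rho = 1, nrep = n_rep)
  st <- signal_stats(tabs$a, tabs$b, tabs$c, tabs$d,
                     bcpnn_variant = bcpnn_variant)
  flags <- data.table(
    ror = !is.na(st$ror_lo) & st$ror_lo > criteria$ror_lo_gt,
    prr = !is.na(st$prr) & st$prr >= criteria$prr_ge &
      st$chisq >= criteria$chisq_ge,
    bcpnn = !is.na(st$ic025) & st$ic025 > criteria$ic025_gt)
  flags[, all := ror & prr & bcpnn]
  list(rates = vapply(flags, mean, 0), flags = flags)
}

#' Parameter recovery for injected associations
#'
#' For each injected relative reporting rate, replicates the generator
#' model and measures the median estimated ROR and the fraction of Woolf
#' intervals covering the injected value.
#'
#' @param rho injected relative rates.
#' @param n_rep replicates per rate.
#' @param n,p_exposed,p_event scenario (defaults: 50,000 reports, 5%
#'   exposure, a rare event at 0.2% where the odds ratio approximates the
#'   rate ratio).
#' @return data.table (`rho`, `median_ror`, `coverage`, `n_rep`).
#' @export
recovery_experiment <- function(rho = c(2, 5, 10), n_rep = 500L,
                                n = 50000L, p_exposed = 0.05,
                                p_event = 0.002) {
  rbindlist(lapply(rho, function(r) {
    tabs <- simulate_contingency(n, p_exposed, p_event, rho = r,
                                 nrep = n_rep)
    rr <- ror_stats(tabs$a, tabs$b, tabs$c, tabs$d)
    data.table(rho = r,
               median_ror = median(rr$ror, na.rm = TRUE),
               coverage = mean(rr$ror_lo <= r & rr$ror_hi >= r,
                               na.rm = TRUE),
               n_rep = n_rep)
  }))
}
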