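params <- suppressWarnings(econ_parameters())

test_that("Mosteller BSA uses the square-root form and is monotone", {
  expect_equal(mosteller_bsa(60, 60), 1.0)
  expect_equal(mosteller_bsa(168.3, 84.7), 1.99, tolerance = 0.005)
  expect_gt(mosteller_bsa(170, 85), mosteller_bsa(160, 85))
  expect_gt(mosteller_bsa(170, 85), mosteller_bsa(170, 75))
  expect_error(mosteller_bsa(0, 70), "positive")
})

test_that("the parameter table carries the published values and repairs the BSC range", {
  expect_warning(econ_parameters(), "supportive")
  expect_equal(param_value(params, "cost_durvalumab"), 12787.50)
  expect_equal(param_value(params, "util_efs"), 0.797)
  expect_equal(param_value(params, "cost_hospice"), 4563.28)
  bsc <- params[params$name == "cost_bsc", ]
  expect_lt(bsc$min, bsc$value)
  expect_gt(bsc$max, bsc$value)
  expect_error(param_value(params, "no_such_row"), "Unknown parameter")
})

test_that("the parameter file round-trips and rejects unknown rows", {
  p <- file.path(withr::local_tempdir(), "params.tsv")
  write_econ_parameters(params, p)
  back <- read_econ_parameters(p)
  expect_equal(back$value, params$value)
  expect_equal(back$name, params$name)
  tab <- readr::read_tsv(p, show_col_types = FALSE)
  tab$label[1] <- "Diarrhoea (typo)"
  readr::write_tsv(tab, p)
  expect_error(read_econ_parameters(p), "Unknown parameter rows")
})

test_that("per-cycle drug costs decompose as acquisition plus administration", {
  v <- function(nm) param_value(params, nm)
  flot_drugs <- 35.40 + 62.68 + 61.42 + 75.23
  expect_equal(flot_drugs, 234.73)
  flot_admin <- 2 * (2 * v("cost_iv_short") + 2 * v("cost_iv_long"))
  expect_equal(drug_cost_per_cycle("FLOT", "neoadjuvant", params),
               flot_drugs + flot_admin)
  expect_equal(drug_cost_per_cycle("DFLOT", "adjuvant", params),
               flot_drugs + flot_admin + 12787.50 + v("cost_iv_short"))
  expect_equal(drug_cost_per_cycle("DFLOT", "monotherapy", params),
               12787.50 + v("cost_iv_short"))
  expect_equal(drug_cost_per_cycle("FLOT", "monotherapy", params), 0)
  expect_equal(drug_cost_per_cycle("DFLOT", "second_line", params),
               20179.74 + 50.50 + 5 * v("cost_iv_short"))
  expect_equal(20179.74 + 50.50, 20230.24)
  cfg2 <- default_config(flot_reading = "chemo_cycle")
  expect_equal(drug_cost_per_cycle("FLOT", "neoadjuvant", params, cfg2),
               2 * flot_drugs + flot_admin)
  expect_error(drug_cost_per_cycle("FLOT", "maintenance", params), "Unknown phase")
})

test_that("the treatment calendar schedules 14 durvalumab-bearing cycles", {
  cal <- treatment_calendar("DFLOT", 130)
  durva_phases <- c("neoadjuvant", "adjuvant", "monotherapy")
  expect_equal(sum(cal$phase %in% durva_phases), 14)
  expect_equal(cal$phase[cal$cycle == 2], "surgery")
  expect_equal(sum(cal$phase == "monotherapy"), 10)
  cal_f <- treatment_calendar("FLOT", 130)
  expect_equal(sum(cal_f$phase == "monotherapy"), 0)
  # no drug cost after the adjuvant phase in the chemotherapy-only arm
  expect_true(all(cal_f$phase[cal_f$cycle > 4] == "off"))
})

test_that("adverse-event burden is the incidence-weighted sum of costs and disutilities", {
  expect_equal(ae_burden(c(0, 0), c(10, 20), c(0.1, 0.2)),
               list(cost = 0, disutility = 0))
  b <- flotcea:::ae_burden_for_arm("DFLOT", params)
  expect_equal(b$cost,
               0.063 * 3928 + 0.051 * 528 + 0.409 * 18987 + 0.053 * 96238)
  expect_equal(ae_burden(0.409, 0, 0.159)$disutility, 0.409 * 0.159)
  expect_error(ae_burden(c(0.1, 0.2), c(1, 2, 3), c(0, 0)), "align")
})

test_that("the surveillance calendar prices visits and scans as scheduled", {
  fu <- followup_cost(params, 130)
  d <- CYCLE_LENGTH_MONTHS
  # first encounter (month 3): initial visit + CBC
  c3 <- floor(3 / d) + 1
  expect_equal(fu[c3], 165.44 + 19.00)
  # two CTs within the first year (months 6 and 12)
  year1 <- which((seq_len(130) - 1) * d < 12)
  ct_year1 <- sum(fu[year1]) -
    (165.44 + 19.00) - 3 * (130.15 + 19.00)  # 4 quarterly visits, 1 initial
  expect_equal(ct_year1, 2 * 171.10)
  # a cycle with no scheduled encounter costs nothing
  expect_equal(fu[2], 0)
})

test_that("accumulation satisfies additivity, separation and monotonicity", {
  m <- small_model()
  res <- accumulate(m$traces$DFLOT, params, "DFLOT")
  expect_s3_class(res, "econ_result")
  expect_equal(res$cost_total,
               res$cost_drug + res$cost_ae + res$cost_followup + res$cost_eol)
  expect_lte(res$qaly, res$life_years)
  # zero prices: no cost, unchanged QALYs
  p0 <- params
  p0$value[grepl("^(cost_|ae_cost_)", p0$name)] <- 0
  res0 <- accumulate(m$traces$DFLOT, p0, "DFLOT")
  expect_equal(res0$cost_total, 0)
  expect_equal(res0$qaly, res$qaly)
  # raising a price raises cost; raising a utility raises QALYs
  res_hi <- accumulate(m$traces$DFLOT, set_param(params, "cost_durvalumab", 15000),
                       "DFLOT")
  expect_gt(res_hi$cost_total, res$cost_total)
  res_u <- accumulate(m$traces$DFLOT, set_param(params, "util_efs", 0.9), "DFLOT")
  expect_gt(res_u$qaly, res$qaly)
  # zero utilities (and no AE decrement) zero the QALYs but not life-years
  pz <- params
  pz$value[grepl("^util_", pz$name)] <- 0
  pz$value[grepl("^disutil_", pz$name)] <- 0
  resz <- accumulate(m$traces$DFLOT, pz, "DFLOT")
  expect_equal(resz$qaly, 0)
  expect_gt(resz$life_years, 0)
})

test_that("a toy trace accrues closed-form QALYs", {
  n <- 20
  sch <- transition_schedule(rep(0, n), rep(0, n), rep(0, n), rep(0, n), rep(0, n))
  tr <- run_cohort(sch, n)
  cfg <- default_config(n_cycles = n)
  p <- params
  p$value[grepl("^(cost_|ae_cost_)", p$name)] <- 0
  p$value[p$name %in% c("util_gastrectomy")] <- 0.797
  p$value[grepl("^(disutil_|ae_inc_)", p$name)] <- 0
  p <- set_param(p, "discount_rate", 0)
  res <- accumulate(tr, p, "FLOT", cfg)
  expect_equal(res$qaly, n * 0.797 * (28 / 365.25), tolerance = 1e-10)
  expect_equal(res$life_years, n * 28 / 365.25, tolerance = 1e-10)
})

test_that("the gastrectomy utility applies for the configured post-surgery window", {
  n <- 30
  sch <- transition_schedule(rep(0, n), rep(0, n), rep(0, n), rep(0, n), rep(0, n))
  tr <- run_cohort(sch, n)
  cfg <- default_config(n_cycles = n)
  p <- params
  p$value[grepl("^(cost_|ae_cost_)", p$name)] <- 0
  p$value[grepl("^(disutil_|ae_inc_)", p$name)] <- 0
  p <- set_param(p, "discount_rate", 0)
  base <- accumulate(tr, p, "FLOT", cfg)
  # 13 cycles at the gastrectomy utility instead of the EFS utility
  expected <- (30 * 0.797 + 13 * (0.773 - 0.797)) * 28 / 365.25
  expect_equal(base$qaly, expected, tolerance = 1e-10)
})

test_that("ICER arithmetic, dominance and degenerate labels are correct", {
  a <- econ_result("A", 100, 0, 0, 0, life_years = 3, qaly = 2)
  b <- econ_result("B", 50, 0, 0, 0, life_years = 2.5, qaly = 1.5)
  ic <- icer(a, b)
  expect_equal(ic$icer, (100 - 50) / (2 - 1.5))
  expect_equal(ic$label, "ICER")
  same <- icer(a, a)
  expect_match(same$label, "undefined")
  expect_true(is.na(same$icer))
  cheap_better <- econ_result("A", 40, 0, 0, 0, life_years = 3, qaly = 2)
  expect_match(icer(cheap_better, b)$label, "dominant")
  worse <- econ_result("A", 100, 0, 0, 0, life_years = 2, qaly = 1)
  expect_match(icer(worse, b)$label, "dominated")
})

test_that("econ_result enforces additivity and QALY <= LY", {
  expect_error(econ_result("X", 10, 10, 10, 10, cost_total = 50,
                           life_years = 1, qaly = 0.5), "sum")
  expect_error(econ_result("X", 10, 0, 0, 0, life_years = 1, qaly = 1.5),
               "exceed")
})
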