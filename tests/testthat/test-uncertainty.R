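params <- suppressWarnings(econ_parameters())

test_that("one-way bounds are plus/minus 25% where no published sd exists", {
  durva <- params[params$name == "cost_durvalumab", ]
  expect_equal(durva$min, 12787.50 * 0.75, tolerance = 1e-5)
  expect_equal(durva$max, 12787.50 * 1.25, tolerance = 1e-5)
  hospice <- params[params$name == "cost_hospice", ]
  expect_equal(hospice$max, 4563.28 * 1.25, tolerance = 1e-5)
})

test_that("the tornado responds monotonically and ignores unread parameters", {
  m <- small_model()
  tor <- owsa(m)
  dr <- tor[tor$name == "cost_durvalumab", ]
  expect_gt(dr$icer_high, dr$icer_low)  # ICER nondecreasing in the drug price
  bw <- tor[tor$name == "body_weight", ]  # dosing is priced per cycle, not per kg
  expect_equal(bw$swing_inmb, 0)
  expect_equal(bw$icer_low, bw$icer_high)
  # entries are sorted by NMB swing
  expect_true(all(diff(tor$swing_inmb) <= 1e-9))
})

test_that("parameter draws honour their moment construction", {
  degenerate <- params
  degenerate$min <- degenerate$value
  degenerate$max <- degenerate$value
  set.seed(61)
  d0 <- sample_params(degenerate, 5)
  expect_true(all(vapply(seq_len(ncol(d0)), function(j) stats::sd(d0[[j]]) == 0,
                         logical(1))))
  set.seed(62)
  dr <- sample_params(params, 50000)
  expect_equal(mean(dr$util_efs), 0.797, tolerance = 0.005)
  expect_lt(abs(mean(dr$cost_durvalumab) - 12787.50) / 12787.50, 0.01)
  expect_true(all(dr$util_efs >= 0 & dr$util_efs <= 1))
  expect_true(all(dr$cost_durvalumab >= 0))
  bad <- params
  bad$max[bad$name == "util_efs"] <- 3  # sd too large for a beta mean
  expect_error(sample_params(bad, 2), "util_efs")
})

test_that("the PSA is reproducible, sized correctly and degenerates to base case", {
  m <- small_model()
  c1 <- suppressWarnings(run_psa(m, n = 8, seed = 63))
  c2 <- suppressWarnings(run_psa(m, n = 8, seed = 63))
  expect_equal(tibble::as_tibble(c1), tibble::as_tibble(c2))
  expect_equal(nrow(c1), 16)  # 8 draws x 2 strategies
  expect_equal(dplyr::n_distinct(c1$draw), 8)
  one <- suppressWarnings(run_psa(m, n = 1, seed = 64))
  expect_equal(nrow(one), 2)
  # frozen curves + degenerate distributions reproduce the base case
  degenerate <- m$params
  degenerate$min <- degenerate$value
  degenerate$max <- degenerate$value
  m2 <- m
  m2$params <- degenerate
  cd <- run_psa(m2, n = 3, seed = 65, resample_survival = FALSE)
  base <- evaluate_cea(m)
  for (s in c("DFLOT", "FLOT")) {
    expect_equal(unique(cd$cost[cd$strategy == s]),
                 base$results$cost_total[base$results$strategy == s],
                 tolerance = 1e-9)
  }
})

test_that("CEAC probabilities are limits of the NMB ordering and sum to one", {
  m <- small_model()
  cloud <- suppressWarnings(run_psa(m, n = 40, seed = 66))
  grid <- c(0, 5e4, 1.5e5, 1e7)
  acc <- ceac(cloud, grid)
  sums <- acc |>
    dplyr::group_by(wtp) |>
    dplyr::summarise(p = sum(probability))
  expect_equal(sums$p, rep(1, length(grid)))
  wide_c <- tidyr::pivot_wider(cloud, id_cols = "draw", names_from = "strategy",
                               values_from = "cost")
  cheaper_frac <- mean(wide_c$DFLOT < wide_c$FLOT)
  expect_equal(acc$probability[acc$wtp == 0 & acc$strategy == "DFLOT"],
               cheaper_frac)
  wide_q <- tidyr::pivot_wider(cloud, id_cols = "draw", names_from = "strategy",
                               values_from = "qaly")
  better_frac <- mean(wide_q$DFLOT > wide_q$FLOT)
  expect_equal(acc$probability[acc$wtp == 1e7 & acc$strategy == "DFLOT"],
               better_frac)
  expect_error(ceac(cloud, numeric(0)), "non-empty")
})

test_that("EVPI matches the two-draw hand oracle and is non-negative", {
  hand <- tibble::tibble(
    draw = c(1L, 1L, 2L, 2L),
    strategy = rep(c("A", "B"), 2),
    cost = c(-10, 0, 0, -10),  # at wtp 0: NMB pairs (10, 0) and (0, 10)
    qaly = 0
  )
  class(hand) <- c("psa_cloud", class(hand))
  ev <- evpi(hand, 0)
  expect_equal(ev$evpi, 5)  # E[max] = 10, max of means = 5
  m <- small_model()
  cloud <- suppressWarnings(run_psa(m, n = 30, seed = 67))
  grid <- seq(0, 4e5, by = 5e4)
  ev2 <- evpi(cloud, grid)
  expect_true(all(ev2$evpi >= -1e-9))
  # one strategy optimal in every draw -> zero EVPI
  sure <- tibble::tibble(
    draw = rep(1:3, each = 2), strategy = rep(c("A", "B"), 3),
    cost = rep(c(0, 100), 3), qaly = rep(c(2, 1), 3)
  )
  class(sure) <- c("psa_cloud", class(sure))
  expect_equal(evpi(sure, c(0, 1e5))$evpi, c(0, 0))
})

test_that("EVPI vanishes at extreme thresholds when the decision is clear", {
  m <- small_model()
  cloud <- suppressWarnings(run_psa(m, n = 60, seed = 68))
  ev <- evpi(cloud, c(1e3, 1e7))
  expect_lt(ev$evpi[1] / max(evpi(cloud, 1.5e5)$evpi, 1), 0.05)
})

test_that("the adjuvant-completion scenario scales exposure, not efficacy", {
  m <- small_model()
  base <- evaluate_cea(m)
  scen <- scenario_adjuvant_completion(m, m = c(2, 6, 10))
  expect_equal(scen$expected_cycles[scen$m == 2], 0.523 * 10 + 0.477 * 2)
  expect_equal(scen$cost_dflot[scen$m == 10],
               base$results$cost_total[base$results$strategy == "DFLOT"])
  expect_equal(scen$delta_qaly, rep(base$icer$delta_qaly, 3))
  expect_true(all(diff(scen$icer) > 0))  # ICER declines as exposure shrinks
  expect_error(scenario_adjuvant_completion(m, m = 12), "cannot exceed")
  expect_warning(
    scenario_adjuvant_completion(m, m = 10, completer_fraction = 0.523,
                                 noncompleter_fraction = 0.483),
    "sum to 1"
  )
})
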