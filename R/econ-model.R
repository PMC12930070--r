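# Mapping the cohort trace to discounted costs by category and QALYs:
# dosing calendars, infusion administration, surveillance schedule,
# adverse-event burden, terminal-care costs and the ICER.

#' Default run configuration
#'
#' @param n_cycles Model cycles (130 covers the 10-year horizon at 4-week
#'   cycles).
#' @param cycle_len Cycle length, months.
#' @param wtp Willingness-to-pay threshold, USD/QALY.
#' @param flot_reading Reading of the published per-cycle FLOT component
#'   prices: `"model_cycle"` (price covers one 4-week model cycle, the
#'   default) or `"chemo_cycle"` (price is per 2-week chemotherapy cycle,
#'   doubled per model cycle).
#' @param bsc_mode Best supportive care charged `"per_cycle"` of PD2
#'   occupancy (default) or `"per_episode"` on PD2 entry.
#' @param efs_split EFS exit split mode, see [build_transition_schedule()].
#' @param efs_death_share Fixed split share when `efs_split = "constant"`.
#' @param surgery_cycle Model cycle of curative resection (0-based).
#' @param mono_cycles Planned durvalumab monotherapy cycles.
#' @param mono_scale Scaling of monotherapy drug exposure (used by the
#'   adjuvant-completion scenario; 1 = full 10 cycles).
#' @return A list of class `run_config`.
#' @export
default_config <- function(n_cycles = 130, cycle_len = CYCLE_LENGTH_MONTHS,
                           wtp = 150000,
                           flot_reading = c("model_cycle", "chemo_cycle"),
                           bsc_mode = c("per_cycle", "per_episode"),
                           efs_split = c("hazard_ratio", "constant"),
                           efs_death_share = 0, surgery_cycle = 2,
                           mono_cycles = 10, mono_scale = 1) {
  structure(list(
    n_cycles = n_cycles, cycle_len = cycle_len, wtp = wtp,
    flot_reading = match.arg(flot_reading), bsc_mode = match.arg(bsc_mode),
    efs_split = match.arg(efs_split), efs_death_share = efs_death_share,
    surgery_cycle = surgery_cycle, mono_cycles = mono_cycles,
    mono_scale = mono_scale
  ), class = "run_config")
}

#' Treatment calendar for one strategy
#'
#' Phase per model cycle: 2 neoadjuvant chemotherapy cycles, resection at
#' the surgery cycle, 2 adjuvant chemotherapy cycles, then (combination arm
#' only) 10 durvalumab monotherapy cycles. Receipt of scheduled treatment
#' is gated downstream by event-free occupancy.
#'
#' @param arm `"DFLOT"` or `"FLOT"`.
#' @param n_cycles Number of cycles.
#' @param config A `run_config`.
#' @return A tibble `cycle`, `phase` with phase in
#'   neoadjuvant/surgery/adjuvant/monotherapy/off.
#' @export
treatment_calendar <- function(arm = c("DFLOT", "FLOT"), n_cycles = 130,
                               config = default_config()) {
  arm <- match.arg(arm)
  sc <- config$surgery_cycle
  phase <- rep("off", n_cycles)
  phase[1:2] <- "neoadjuvant"
  phase[sc + 1] <- "surgery"
  phase[sc + 2:3] <- "adjuvant"
  if (arm == "DFLOT") phase[sc + 4:(3 + config$mono_cycles)] <- "monotherapy"
  tibble::tibble(cycle = 0:(n_cycles - 1), phase = phase)
}

#' Drug-acquisition plus administration cost for one model cycle of a phase
#'
#' FLOT phases bundle two 2-week chemotherapy cycles per 4-week model
#' cycle; under the default `"model_cycle"` reading the published per-cycle
#' component prices already cover the model cycle. Each chemotherapy
#' administration is charged two short and two long infusion fees (the
#' 24-hour fluorouracil and oxaliplatin infusions run over an hour;
#' docetaxel and leucovorin do not). Durvalumab adds its per-cycle price
#' plus one short infusion; second-line ramucirumab/paclitaxel adds the two
#' published per-cycle prices plus five short infusion fees (two
#' ramucirumab and three weekly paclitaxel administrations).
#'
#' @param arm `"DFLOT"` or `"FLOT"`.
#' @param phase One of neoadjuvant/surgery/adjuvant/monotherapy/second_line/off.
#' @param params An `econ_params` tibble.
#' @param config A `run_config` (controls the FLOT price reading).
#' @return Cost in USD for one model cycle.
#' @export
drug_cost_per_cycle <- function(arm = c("DFLOT", "FLOT"), phase, params,
                                config = default_config()) {
  arm <- match.arg(arm)
  v <- function(nm) param_value(params, nm)
  flot_drug <- v("cost_fluorouracil") + v("cost_leucovorin") +
    v("cost_oxaliplatin") + v("cost_docetaxel")
  if (config$flot_reading == "chemo_cycle") flot_drug <- 2 * flot_drug
  flot_admin <- 2 * (2 * v("cost_iv_short") + 2 * v("cost_iv_long"))
  durva <- v("cost_durvalumab") + v("cost_iv_short")
  switch(
    phase,
    neoadjuvant = ,
    adjuvant = flot_drug + flot_admin + if (arm == "DFLOT") durva else 0,
    monotherapy = if (arm == "DFLOT") durva else 0,
    second_line = v("cost_ramucirumab") + v("cost_paclitaxel") + 5 * v("cost_iv_short"),
    surgery = 0,
    off = 0,
    stop("Unknown phase: ", phase, call. = FALSE)
  )
}

#' Expected adverse-event burden at treatment start
#'
#' One-off expected management cost `sum(p_i * c_i)` and utility decrement
#' `sum(p_i * d_i)` over the grade >= 3 events with incidence >= 5%
#' (diarrhea, anemia, neutropenia, thrombocytopenia), applied once at the
#' start of first-line treatment; the decrement lasts one model cycle.
#'
#' @param incidences,unit_costs,disutilities Aligned numeric vectors over
#'   the four events.
#' @return A list with `cost` (USD) and `disutility`.
#' @export
ae_burden <- function(incidences, unit_costs, disutilities) {
  if (length(incidences) != length(unit_costs) ||
      length(incidences) != length(disutilities)) {
    stop("Incidence, cost and disutility vectors must align.", call. = FALSE)
  }
  list(cost = sum(incidences * unit_costs),
       disutility = sum(incidences * disutilities))
}

ae_burden_for_arm <- function(arm, params) {
  pre <- if (arm == "DFLOT") "ae_inc_dflot_" else "ae_inc_flot_"
  ev <- c("diarrhea", "anemia", "neutropenia", "thrombocytopenia")
  ae_burden(
    param_value(params, paste0(pre, ev)),
    param_value(params, paste0("ae_cost_", ev)),
    param_value(params, paste0("disutil_", ev))
  )
}

#' Per-cycle surveillance (follow-up) cost schedule
#'
#' Imaging and visit calendar: CT every 6 months for 2 years then annually
#' to 5 years; history & physical with CBC every 3 months for 2 years then
#' every 6 months for the rest of the horizon. The first encounter is
#' priced as an initial visit, later ones as subsequent visits. Costs are
#' assigned to the model cycle containing the scheduled month and applied
#' downstream to alive, non-PD2 occupancy.
#'
#' @param params An `econ_params` tibble.
#' @param n_cycles Number of cycles.
#' @param cycle_len Cycle length, months.
#' @return Numeric vector of per-cycle USD costs (length `n_cycles`).
#' @export
followup_cost <- function(params, n_cycles = 130,
                          cycle_len = CYCLE_LENGTH_MONTHS) {
  v <- function(nm) param_value(params, nm)
  horizon <- n_cycles * cycle_len
  ct_months <- c(seq(6, 24, by = 6), seq(36, 60, by = 12))
  visit_months <- seq(3, 24, by = 3)
  if (horizon >= 30) visit_months <- c(visit_months, seq(30, horizon, by = 6))
  ct_months <- ct_months[ct_months <= horizon]
  visit_months <- visit_months[visit_months <= horizon]
  cost <- numeric(n_cycles)
  cyc_of <- function(m) pmin(floor(m / cycle_len), n_cycles - 1) + 1
  for (m in ct_months) cost[cyc_of(m)] <- cost[cyc_of(m)] + v("cost_ct")
  first <- TRUE
  for (m in sort(visit_months)) {
    fee <- if (first) v("cost_visit_initial") else v("cost_visit_subsequent")
    first <- FALSE
    cost[cyc_of(m)] <- cost[cyc_of(m)] + fee + v("cost_cbc")
  }
  cost
}

#' Construct an economic result row
#'
#' Validates the category-additivity and QALY <= life-years invariants.
#'
#' @param strategy Strategy label.
#' @param cost_drug,cost_ae,cost_followup,cost_eol Category costs, USD.
#' @param cost_total Total cost; defaults to the category sum and must
#'   match it within 0.01 USD.
#' @param life_years,qaly (Discounted) life-years and QALYs.
#' @return A one-row tibble of class `econ_result`.
#' @export
econ_result <- function(strategy, cost_drug, cost_ae, cost_followup,
                        cost_eol, cost_total = NULL, life_years, qaly) {
  cats <- cost_drug + cost_ae + cost_followup + cost_eol
  if (is.null(cost_total)) cost_total <- cats
  if (abs(cost_total - cats) > 0.011) {
    stop("Cost categories (", round(cats, 2), ") do not sum to the total (",
         round(cost_total, 2), ").", call. = FALSE)
  }
  if (any(c(cost_drug, cost_ae, cost_followup, cost_eol, life_years, qaly) < -1e-9)) {
    stop("Economic results must be non-negative.", call. = FALSE)
  }
  if (qaly > life_years + 1e-9) {
    stop("QALYs cannot exceed life-years.", call. = FALSE)
  }
  out <- tibble::tibble(
    strategy = strategy, cost_drug = cost_drug, cost_ae = cost_ae,
    cost_followup = cost_followup, cost_eol = cost_eol,
    cost_total = cost_total, life_years = life_years, qaly = qaly
  )
  class(out) <- c("econ_result", class(out))
  out
}

#' Accumulate discounted costs and QALYs over a cohort trace
#'
#' Each category is the cycle sum of half-cycle-corrected occupancy times
#' the per-cycle value times the discount weight. Drug costs are gated by
#' EFS occupancy for scheduled perioperative treatment (progressing
#' patients stop), with the resection fee charged once at the surgery
#' cycle and second-line drug costs accruing over PD1 occupancy. The
#' adverse-event burden is a one-off at treatment start (undiscounted);
#' best supportive care accrues in PD2 and a single hospice episode per
#' incident death. The gastrectomy utility replaces the EFS utility for
#' the configured number of cycles after surgery.
#'
#' @param trace A `cohort_trace` (with its incident-flow attribute).
#' @param params An `econ_params` tibble.
#' @param arm `"DFLOT"` or `"FLOT"`.
#' @param config A `run_config`.
#' @param discount_rate Annual discount rate; default taken from `params`.
#' @return A one-row `econ_result` tibble.
#' @export
accumulate <- function(trace, params, arm = c("DFLOT", "FLOT"),
                       config = default_config(),
                       discount_rate = param_value(params, "discount_rate")) {
  arm <- match.arg(arm)
  stopifnot(inherits(trace, "cohort_trace"))
  n <- nrow(trace) - 1
  if (n != config$n_cycles) {
    stop("Trace covers ", n, " cycles but the configuration expects ",
         config$n_cycles, ".", call. = FALSE)
  }
  hw <- half_cycle_correct(trace)
  flows <- attr(trace, "flows")
  w <- discount_weights(discount_rate, n, config$cycle_len)
  cycle_years <- config$cycle_len / 12
  v <- function(nm) param_value(params, nm)

  cal <- treatment_calendar(arm, n, config)
  phase_cost <- vapply(unique(cal$phase), function(ph)
    drug_cost_per_cycle(arm, ph, params, config), numeric(1))
  drug_vec <- unname(phase_cost[cal$phase])
  drug_vec[cal$phase == "monotherapy"] <-
    drug_vec[cal$phase == "monotherapy"] * config$mono_scale

  sc <- config$surgery_cycle + 1
  cost_drug <- sum(hw$EFS * drug_vec * w) +
    hw$EFS[sc] * v("cost_gastrectomy") * w[sc] +
    sum(hw$PD1 * drug_cost_per_cycle(arm, "second_line", params, config) * w)

  ae <- ae_burden_for_arm(arm, params)
  cost_ae <- ae$cost

  fu <- followup_cost(params, n, config$cycle_len)
  cost_followup <- sum((hw$EFS + hw$PD1) * fu * w)

  cost_bsc <- if (config$bsc_mode == "per_cycle") {
    sum(hw$PD2 * v("cost_bsc") * w)
  } else {
    sum(flows$pd2_entry * v("cost_bsc") * w)
  }
  cost_eol <- cost_bsc + sum(flows$death_entry * v("cost_hospice") * w)

  g_cycles <- max(0, round(v("gastrectomy_utility_cycles")))
  u_efs <- rep(v("util_efs"), n)
  if (g_cycles > 0) {
    idx <- (config$surgery_cycle + 1):min(config$surgery_cycle + g_cycles, n - 1) + 1
    u_efs[idx] <- v("util_gastrectomy")
  }
  qaly <- sum((hw$EFS * u_efs + (hw$PD1 + hw$PD2) * v("util_pd")) * w) * cycle_years -
    ae$disutility * cycle_years
  life_years <- sum((1 - hw$Death) * w) * cycle_years

  econ_result(arm, cost_drug, cost_ae, cost_followup, cost_eol,
              life_years = life_years, qaly = max(qaly, 0))
}

#' Incremental cost-effectiveness ratio
#'
#' `(cost_a - cost_b) / (qaly_a - qaly_b)` for intervention `a` versus
#' comparator `b`. Dominance (sign disagreement) is labelled instead of
#' reported as a ratio; a zero QALY difference is labelled undefined and
#' only the cost difference is meaningful.
#'
#' @param a,b One-row `econ_result` tibbles on the same horizon.
#' @return A one-row tibble of class `icer_result`: `delta_cost`,
#'   `delta_qaly`, `delta_ly`, `icer`, `label`.
#' @export
icer <- function(a, b) {
  stopifnot(inherits(a, "econ_result"), inherits(b, "econ_result"))
  dc <- a$cost_total - b$cost_total
  dq <- a$qaly - b$qaly
  dly <- a$life_years - b$life_years
  if (abs(dq) < 1e-12) {
    label <- "undefined, report delta cost"
    ratio <- NA_real_
  } else if (dc <= 0 && dq > 0) {
    label <- paste(a$strategy, "dominant")
    ratio <- NA_real_
  } else if (dc >= 0 && dq < 0) {
    label <- paste(a$strategy, "dominated")
    ratio <- NA_real_
  } else {
    label <- "ICER"
    ratio <- dc / dq
  }
  out <- tibble::tibble(
    intervention = a$strategy, comparator = b$strategy,
    delta_cost = dc, delta_qaly = dq, delta_ly = dly,
    icer = ratio, label = label
  )
  class(out) <- c("icer_result", class(out))
  out
}
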