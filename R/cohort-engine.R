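# Four-state semi-Markov cohort engine: EFS -> PD1 -> PD2 -> Death over
# 4-week cycles, with residence-time-dependent exit probabilities for the
# progressed states (entry-cohort "tunnel" bookkeeping), half-cycle
# correction and discounting.

STATE_NAMES <- c("EFS", "PD1", "PD2", "Death")

#' Model cycle length in months (4 weeks)
#'
#' 28 days expressed in average months (30.4375 days/month), the single
#' canonical time unit of the model.
#' @export
CYCLE_LENGTH_MONTHS <- 28 / 30.4375

#' Construct a transition schedule from raw probability vectors
#'
#' Low-level constructor used by [build_transition_schedule()] and by
#' tests. EFS exit probabilities are indexed by model cycle; PD1/PD2 exit
#' probabilities by residence cycle (clock reset on state entry).
#'
#' @param p_efs_exit Per-model-cycle probability of leaving EFS.
#' @param efs_death_share Share of EFS exits going directly to Death
#'   (remainder enters PD1); per model cycle.
#' @param p_pd1_exit Per-residence-cycle probability of leaving PD1.
#' @param pd1_death_share Share of PD1 exits going to Death (remainder to
#'   PD2); per residence cycle.
#' @param p_pd2_death Per-residence-cycle probability of PD2 -> Death.
#' @param cycle_len Cycle length, months.
#' @return A `transition_schedule`.
#' @export
transition_schedule <- function(p_efs_exit, efs_death_share, p_pd1_exit,
                                pd1_death_share, p_pd2_death,
                                cycle_len = CYCLE_LENGTH_MONTHS) {
  n <- length(p_efs_exit)
  stopifnot(length(efs_death_share) == n, length(p_pd1_exit) == n,
            length(pd1_death_share) == n, length(p_pd2_death) == n)
  vecs <- list(p_efs_exit = p_efs_exit, efs_death_share = efs_death_share,
               p_pd1_exit = p_pd1_exit, pd1_death_share = pd1_death_share,
               p_pd2_death = p_pd2_death)
  for (nm in names(vecs)) {
    bad <- which(vecs[[nm]] < -1e-12 | vecs[[nm]] > 1 + 1e-12)
    if (length(bad)) {
      stop("Transition component `", nm, "` outside [0, 1] at cycle index ",
           bad[1] - 1, " (value ", signif(vecs[[nm]][bad[1]], 6), ").",
           call. = FALSE)
    }
    vecs[[nm]] <- pmin(pmax(vecs[[nm]], 0), 1)
  }
  structure(c(vecs, list(n_cycles = n, cycle_len = cycle_len)),
            class = "transition_schedule")
}

#' Build the transition schedule from fitted survival curves
#'
#' EFS exit probabilities come from the first-line EFS fit on the model
#' clock; the exit is split between pre-progression death and PD1 by the
#' ratio of the first-line OS to EFS hazards at the cycle midpoint
#' (`efs_split = "hazard_ratio"`, capped at 1) or by a fixed share
#' (`efs_split = "constant"`). PD1 exits follow the second-line
#' progression-free survival fit on the residence clock, split between PD2
#' and Death by the second-line OS/PFS hazard ratio; PD2 -> Death follows
#' the second-line OS fit on the residence clock.
#'
#' @param efs_fit,os_fit First-line EFS and OS `surv_extrap` fits (per arm).
#' @param pd1_pfs_fit,pd1_os_fit Second-line PFS and OS fits.
#' @param n_cycles Number of model cycles (130 for the 10-year horizon).
#' @param cycle_len Cycle length, months.
#' @param efs_split `"hazard_ratio"` or `"constant"`.
#' @param efs_death_share Fixed share for `efs_split = "constant"`.
#' @return A `transition_schedule`.
#' @export
build_transition_schedule <- function(efs_fit, os_fit, pd1_pfs_fit, pd1_os_fit,
                                      n_cycles = 130,
                                      cycle_len = CYCLE_LENGTH_MONTHS,
                                      efs_split = c("hazard_ratio", "constant"),
                                      efs_death_share = 0) {
  efs_split <- match.arg(efs_split)
  for (f in list(efs_fit, os_fit, pd1_pfs_fit, pd1_os_fit)) {
    stopifnot(inherits(f, "surv_extrap"))
    if (!f$converged) stop("All schedule fits must have converged.", call. = FALSE)
  }
  u <- 0:(n_cycles - 1)
  t_mid <- (u + 0.5) * cycle_len
  p_efs <- transition_probability(efs_fit, u, cycle_len)
  share <- if (efs_split == "constant") {
    rep(efs_death_share, n_cycles)
  } else {
    h_efs <- efs_fit$haz(t_mid)
    h_os <- os_fit$haz(t_mid)
    ifelse(h_efs > 0, pmin(1, pmax(0, h_os / h_efs)), 0)
  }
  p_pd1 <- transition_probability(pd1_pfs_fit, u, cycle_len)
  h_pfs <- pd1_pfs_fit$haz(t_mid)
  h_os2 <- pd1_os_fit$haz(t_mid)
  share_pd1 <- ifelse(h_pfs > 0, pmin(1, pmax(0, h_os2 / h_pfs)), 0)
  p_pd2 <- transition_probability(pd1_os_fit, u, cycle_len)
  transition_schedule(p_efs, share, p_pd1, share_pd1, p_pd2, cycle_len)
}

#' Materialize the 4x4 transition matrix for a (cycle, residence) pair
#'
#' States in order EFS, PD1, PD2, Death; rows sum to 1 by construction and
#' the Death row is absorbing. Used for validation and by the
#' microsimulation cross-checks.
#'
#' @param schedule A `transition_schedule`.
#' @param cycle Model cycle index (0-based).
#' @param residence Residence cycle index for PD1/PD2 rows (0-based).
#' @return A 4x4 row-stochastic matrix.
#' @export
schedule_matrix <- function(schedule, cycle, residence = 0) {
  stopifnot(inherits(schedule, "transition_schedule"))
  i <- cycle + 1
  r <- residence + 1
  pe <- schedule$p_efs_exit[i]
  ds <- schedule$efs_death_share[i]
  p1 <- schedule$p_pd1_exit[r]
  d1 <- schedule$pd1_death_share[r]
  p2 <- schedule$p_pd2_death[r]
  m <- rbind(
    c(1 - pe, pe * (1 - ds), 0, pe * ds),
    c(0, 1 - p1, p1 * (1 - d1), p1 * d1),
    c(0, 0, 1 - p2, p2),
    c(0, 0, 0, 1)
  )
  dimnames(m) <- list(STATE_NAMES, STATE_NAMES)
  m
}

#' Run the semi-Markov cohort trace
#'
#' Propagates the cohort through the schedule with per-entry-cohort
#' bookkeeping for the residence-clocked states. Mass conservation (row
#' sums to 1 within 1e-9) and monotone Death occupancy are asserted every
#' cycle.
#'
#' @param schedule A `transition_schedule`.
#' @param n_cycles Number of cycles to run (must not exceed the schedule).
#' @param init Initial occupancy over (EFS, PD1, PD2, Death); defaults to
#'   the whole cohort event-free.
#' @return A `cohort_trace` tibble with rows for cycles `0..n_cycles`
#'   (columns `cycle`, `time_months`, `EFS`, `PD1`, `PD2`, `Death`) and a
#'   `flows` attribute recording incident PD1/PD2 entries and deaths during
#'   each cycle.
#' @export
run_cohort <- function(schedule, n_cycles = schedule$n_cycles,
                       init = c(1, 0, 0, 0)) {
  stopifnot(inherits(schedule, "transition_schedule"))
  if (n_cycles > schedule$n_cycles) {
    stop("Schedule covers ", schedule$n_cycles, " cycles; ", n_cycles,
         " requested.", call. = FALSE)
  }
  if (abs(sum(init) - 1) > 1e-9) stop("`init` must sum to 1.", call. = FALSE)
  efs <- init[1]
  pd1 <- numeric(n_cycles + 1); pd1[1] <- init[2]  # occupancy by residence cycle
  pd2 <- numeric(n_cycles + 1); pd2[1] <- init[3]
  dead <- init[4]

  occ <- matrix(0, n_cycles + 1, 4, dimnames = list(NULL, STATE_NAMES))
  flow <- matrix(0, n_cycles, 3, dimnames = list(NULL, c("pd1_entry", "pd2_entry", "death_entry")))
  occ[1, ] <- c(efs, sum(pd1), sum(pd2), dead)

  for (u in seq_len(n_cycles)) {
    e_exit <- efs * schedule$p_efs_exit[u]
    e_death <- e_exit * schedule$efs_death_share[u]
    e_pd1 <- e_exit - e_death

    r <- seq_len(u)  # occupied residence bins 0..u-1
    p1 <- schedule$p_pd1_exit[r]
    d1 <- schedule$pd1_death_share[r]
    pd1_exit <- pd1[r] * p1
    pd1_death <- pd1_exit * d1
    pd1_to_pd2 <- pd1_exit - pd1_death

    p2 <- schedule$p_pd2_death[r]
    pd2_death <- pd2[r] * p2

    efs <- efs - e_exit
    new_pd1 <- numeric(n_cycles + 1)
    new_pd1[r + 1] <- pd1[r] - pd1_exit
    new_pd1[1] <- e_pd1
    new_pd2 <- numeric(n_cycles + 1)
    new_pd2[r + 1] <- pd2[r] - pd2_death
    new_pd2[1] <- sum(pd1_to_pd2)
    pd1 <- new_pd1
    pd2 <- new_pd2
    deaths_u <- e_death + sum(pd1_death) + sum(pd2_death)
    dead <- dead + deaths_u

    occ[u + 1, ] <- c(efs, sum(pd1), sum(pd2), dead)
    flow[u, ] <- c(e_pd1, sum(pd1_to_pd2), deaths_u)

    if (abs(sum(occ[u + 1, ]) - 1) > 1e-9) {
      stop("Mass conservation violated at cycle ", u, call. = FALSE)
    }
    if (occ[u + 1, 4] < occ[u, 4] - 1e-12) {
      stop("Death occupancy decreased at cycle ", u, call. = FALSE)
    }
    if (any(occ[u + 1, ] < -1e-12)) {
      stop("Negative occupancy at cycle ", u, call. = FALSE)
    }
  }

  out <- tibble::tibble(
    cycle = 0:n_cycles,
    time_months = (0:n_cycles) * schedule$cycle_len,
    EFS = occ[, 1], PD1 = occ[, 2], PD2 = occ[, 3], Death = occ[, 4]
  )
  attr(out, "flows") <- tibble::tibble(
    cycle = 0:(n_cycles - 1),
    pd1_entry = flow[, 1], pd2_entry = flow[, 2], death_entry = flow[, 3]
  )
  attr(out, "cycle_len") <- schedule$cycle_len
  class(out) <- c("cohort_trace", class(out))
  out
}

#' Half-cycle-corrected occupancy
#'
#' Trapezoid correction: the effective occupancy credited to cycle `u` is
#' the mean of the start-of-cycle `u` and `u + 1` occupancies, so
#' transitions are treated as occurring on average mid-cycle.
#'
#' @param trace A `cohort_trace` with at least 2 cycles.
#' @return A tibble with rows for cycles `0..n-1` and the corrected
#'   occupancy columns.
#' @export
half_cycle_correct <- function(trace) {
  stopifnot(inherits(trace, "cohort_trace"), nrow(trace) >= 2)
  n <- nrow(trace) - 1
  cols <- STATE_NAMES
  eff <- (as.matrix(trace[1:n, cols]) + as.matrix(trace[2:(n + 1), cols])) / 2
  out <- tibble::as_tibble(eff)
  dplyr::bind_cols(tibble::tibble(cycle = trace$cycle[1:n],
                                  time_months = trace$time_months[1:n]), out)
}

#' Per-cycle discount weights
#'
#' `w_u = (1 + annual_rate)^(-t_u / 12)` with `t_u` the cycle midpoint in
#' months, matching the half-cycle-corrected occupancy.
#'
#' @param annual_rate Annual discount rate (base case 0.03; Table-range
#'   0 to 0.05).
#' @param n_cycles Number of cycles.
#' @param cycle_len Cycle length, months.
#' @return Numeric vector of length `n_cycles`, in `(0, 1]`.
#' @export
discount_weights <- function(annual_rate = 0.03, n_cycles = 130,
                             cycle_len = CYCLE_LENGTH_MONTHS) {
  if (annual_rate < 0) stop("Discount rate must be non-negative.", call. = FALSE)
  if (annual_rate > 0.05) {
    warning("Discount rate above the 5% upper range.", call. = FALSE)
  }
  t_mid <- (seq_len(n_cycles) - 0.5) * cycle_len
  (1 + annual_rate)^(-t_mid / 12)
}

#' Plot a cohort trace
#'
#' @param object A `cohort_trace`.
#' @param ... Unused.
#' @return A ggplot of state occupancy over time.
#' @export
autoplot.cohort_trace <- function(object, ...) {
  long <- tidyr::pivot_longer(object, dplyr::all_of(STATE_NAMES),
                              names_to = "state", values_to = "occupancy")
  long$state <- factor(long$state, levels = STATE_NAMES)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_months, y = .data$occupancy,
                                     colour = .data$state)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Months", y = "Occupancy", colour = "State") +
    ggplot2::theme_minimal()
}
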