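# Shared fixtures: small synthetic datasets, cheap fitted models and the
# microsimulation oracle used to cross-check the cohort engine.

make_exp_ipd <- function(n = 200, rate = 0.03, censor = 36, seed = 1) {
  simulate_arm_ipd(
    arm_spec(n, "exponential", list(rate = rate), censor_time = censor),
    seed = seed
  )
}

# Hand example used in several places: events at 2 and 4, censorings at
# 3, 5, 6; S(2) = 4/5, S(4) = 4/5 * 2/3.
hand_ipd <- function() {
  tibble::tibble(
    time = c(2, 3, 4, 5, 6),
    event = c(1L, 0L, 1L, 0L, 0L),
    arm = "hand"
  )
}

# A small but realistic model bundle (fits on modest synthetic samples);
# cached per session since several test files reuse it.
small_model <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      trial <- simulate_trial(n_per_arm = 300, seed = 401)
      second <- simulate_second_line(n = 250, seed = 402)
      pick <- function(a, e) dplyr::filter(trial, arm == a, endpoint == e)
      fits <- list(
        efs = list(DFLOT = fit_parametric(pick("DFLOT", "EFS"), "weibull"),
                   FLOT = fit_parametric(pick("FLOT", "EFS"), "exponential")),
        os = list(DFLOT = fit_parametric(pick("DFLOT", "OS"), "exponential"),
                  FLOT = fit_parametric(pick("FLOT", "OS"), "exponential")),
        pd1_pfs = fit_flexible(dplyr::filter(second, endpoint == "PFS2"),
                               "rp", scale = "hazard", k = 1),
        pd1_os = fit_parametric(dplyr::filter(second, endpoint == "OS2"), "gamma")
      )
      # long-residence second-line curves can reach S = 0 inside the horizon;
      # the engine warns and sets the transition to 1, which is intended here
      cache <<- suppressWarnings(cea_model(fits, suppressWarnings(econ_parameters())))
    }
    cache
  }
})

# Individual-level Monte Carlo oracle for the semi-Markov cohort engine:
# walkers carry a residence clock that resets on entering PD1/PD2.
microsim_trace <- function(schedule, n_walkers = 2e5, n_cycles = 40, seed = 1) {
  set.seed(seed)
  state <- rep(1L, n_walkers)  # 1 EFS, 2 PD1, 3 PD2, 4 Death
  res <- rep(0L, n_walkers)
  occ <- matrix(0, n_cycles + 1, 4)
  occ[1, ] <- tabulate(state, 4) / n_walkers
  for (u in seq_len(n_cycles)) {
    r1 <- stats::runif(n_walkers)
    r2 <- stats::runif(n_walkers)
    new_state <- state
    new_res <- res + 1L
    in_efs <- state == 1L
    exit <- in_efs & r1 < schedule$p_efs_exit[u]
    to_death <- exit & r2 < schedule$efs_death_share[u]
    new_state[exit] <- 2L
    new_state[to_death] <- 4L
    new_res[exit] <- 0L
    in_pd1 <- state == 2L
    p1 <- schedule$p_pd1_exit[res + 1L]
    d1 <- schedule$pd1_death_share[res + 1L]
    exit1 <- in_pd1 & r1 < p1
    new_state[exit1] <- ifelse(r2[exit1] < d1[exit1], 4L, 3L)
    new_res[exit1] <- 0L
    in_pd2 <- state == 3L
    p2 <- schedule$p_pd2_death[res + 1L]
    exit2 <- in_pd2 & r1 < p2
    new_state[exit2] <- 4L
    state <- new_state
    res <- new_res
    occ[u + 1, ] <- tabulate(state, 4) / n_walkers
  }
  colnames(occ) <- c("EFS", "PD1", "PD2", "Death")
  occ
}
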