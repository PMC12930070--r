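# Sensitivity and decision-uncertainty analyses: one-way (tornado),
# probabilistic (Monte Carlo), acceptability curves, expected value of
# perfect information and the adjuvant-completion scenario.

#' One-way sensitivity analysis
#'
#' Re-evaluates the model at each parameter's lower and upper bound with
#' everything else held at base, reporting the ICER and incremental net
#' monetary benefit at both bounds (the ICER is unstable near a zero QALY
#' difference, so both swings are reported; entries are sorted by the NMB
#' swing). Utility bounds above 1 are clipped with a warning. Fitted
#' survival curves are held at their base estimates: varied parameters
#' only enter the economic layer, so a parameter the model never reads has
#' zero swing.
#'
#' @param model A `cea_model` (see [cea_model()]).
#' @param wtp Willingness-to-pay threshold for the NMB swing.
#' @return A tibble with one row per varied parameter: bounds, ICERs,
#'   incremental NMBs and swings, sorted by decreasing NMB swing.
#' @export
owsa <- function(model, wtp = model$config$wtp) {
  stopifnot(inherits(model, "cea_model"))
  base_params <- model$params
  vary <- base_params[base_params$max > base_params$min, ]
  eval_at <- function(params) {
    ev <- evaluate_cea(model, params = params)
    list(ic = ev$icer, inmb = wtp * ev$icer$delta_qaly - ev$icer$delta_cost)
  }
  rows <- purrr::pmap_dfr(
    vary[, c("name", "label", "min", "max")],
    function(name, label, min, max) {
      is_util <- grepl("^(util_|disutil_|ae_inc_)", name)
      bounds <- c(min, max)
      if (is_util && any(bounds > 1)) {
        warning("Bound above 1 clipped to 1 for ", name, call. = FALSE)
        bounds <- pmin(bounds, 1)
      }
      lo <- eval_at(set_param(base_params, name, bounds[1]))
      hi <- eval_at(set_param(base_params, name, bounds[2]))
      tibble::tibble(
        name = name, label = label, low = bounds[1], high = bounds[2],
        icer_low = lo$ic$icer, icer_high = hi$ic$icer,
        inmb_low = lo$inmb, inmb_high = hi$inmb
      )
    }
  )
  rows$swing_icer <- abs(rows$icer_high - rows$icer_low)
  rows$swing_inmb <- abs(rows$inmb_high - rows$inmb_low)
  dplyr::arrange(rows, dplyr::desc(.data$swing_inmb))
}

#' Sample parameter draws for probabilistic analysis
#'
#' Costs draw from gamma distributions, utilities/probabilities from beta,
#' anthropometrics from normal; `fixed` rows stay at base. Distribution
#' parameters come from the mean and a standard deviation derived from the
#' range, `sd = (max - min) / (2 * 1.96)` (a 95% interval read of the
#' published range), by the method of moments. A zero sd degenerates to
#' the mean; moments infeasible for a beta (variance >= m(1-m)) raise an
#' error naming the parameter.
#'
#' @param params An `econ_params` tibble.
#' @param n Number of draws.
#' @return An `n` x parameters tibble of draws (columns named by internal
#'   parameter name).
#' @export
sample_params <- function(params, n = 1) {
  draws <- purrr::pmap(
    params[, c("name", "value", "min", "max", "dist")],
    function(name, value, min, max, dist) {
      s <- (max - min) / (2 * 1.96)
      if (dist == "fixed" || s == 0) return(rep(value, n))
      m <- value
      switch(
        dist,
        beta = {
          if (s^2 >= m * (1 - m)) {
            stop("Beta moments infeasible (sd too large) for parameter `",
                 name, "`.", call. = FALSE)
          }
          nu <- m * (1 - m) / s^2 - 1
          stats::rbeta(n, m * nu, (1 - m) * nu)
        },
        gamma = {
          if (m <= 0) stop("Gamma mean must be positive for `", name, "`.", call. = FALSE)
          stats::rgamma(n, shape = m^2 / s^2, rate = m / s^2)
        },
        normal = stats::rnorm(n, m, s),
        stop("Unknown distribution `", dist, "` for parameter `", name, "`.",
             call. = FALSE)
      )
    }
  )
  names(draws) <- params$name
  tibble::as_tibble(draws)
}

inject_draw <- function(params, draw_row) {
  params$value <- as.numeric(draw_row[params$name])
  params
}

#' Run the probabilistic sensitivity analysis
#'
#' Monte Carlo over parameter uncertainty: each iteration draws one common
#' economic parameter set (and, by default, one draw of each fitted
#' survival model's parameters from its asymptotic multivariate normal),
#' runs the full model for both strategies and records the discounted
#' (cost, QALY) pair. A draw violating model invariants is rejected,
#' logged and resampled.
#'
#' @param model A `cea_model`.
#' @param n Number of iterations (5000 in the reference analysis).
#' @param seed Integer seed for reproducibility.
#' @param resample_survival Also draw survival-model parameters (default
#'   TRUE); set FALSE to freeze the fitted curves.
#' @return A `psa_cloud` tibble (`draw`, `strategy`, `cost`, `qaly`) with
#'   the parameter draws, seed and rejection count as attributes.
#' @export
run_psa <- function(model, n = 5000, seed = NULL, resample_survival = TRUE) {
  stopifnot(inherits(model, "cea_model"))
  if (!is.null(seed)) set.seed(seed)
  draws <- sample_params(model$params, n)
  out <- vector("list", n)
  kept_draws <- draws
  n_rejected <- 0L
  for (i in seq_len(n)) {
    repeat {
      res <- tryCatch({
        params_i <- inject_draw(model$params, kept_draws[i, ])
        mod_i <- if (resample_survival) {
          refresh_traces(model, purrr::map(model$fits_flat, resample_extrap))
        } else {
          model
        }
        ev <- evaluate_cea(mod_i, params = params_i)
        dplyr::mutate(ev$results[, c("strategy", "cost_total", "qaly")], draw = i)
      }, error = function(e) e)
      if (!inherits(res, "error")) break
      n_rejected <- n_rejected + 1L
      kept_draws[i, ] <- sample_params(model$params, 1)
    }
    out[[i]] <- res
  }
  cloud <- dplyr::bind_rows(out)
  cloud <- tibble::tibble(draw = cloud$draw, strategy = cloud$strategy,
                          cost = cloud$cost_total, qaly = cloud$qaly)
  attr(cloud, "param_draws") <- kept_draws
  attr(cloud, "seed") <- seed
  attr(cloud, "n_rejected") <- n_rejected
  class(cloud) <- c("psa_cloud", class(cloud))
  cloud
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value, the probability that each strategy
#' maximizes net monetary benefit `wtp * QALY - cost` across the PSA
#' draws. Probabilities sum to 1 at every threshold (ties, measure-zero
#' events, break toward the cheaper strategy).
#'
#' @param cloud A `psa_cloud`.
#' @param wtp_grid Vector of thresholds, USD/QALY.
#' @return A tibble `wtp`, `strategy`, `probability`.
#' @export
ceac <- function(cloud, wtp_grid) {
  stopifnot(inherits(cloud, "psa_cloud"))
  if (!length(wtp_grid)) stop("`wtp_grid` must be non-empty.", call. = FALSE)
  purrr::map_dfr(wtp_grid, function(l) {
    nmb <- dplyr::mutate(cloud, nmb = l * .data$qaly - .data$cost)
    win <- nmb |>
      dplyr::group_by(.data$draw) |>
      dplyr::arrange(dplyr::desc(.data$nmb), .data$cost, .by_group = TRUE) |>
      dplyr::slice(1) |>
      dplyr::ungroup()
    counts <- table(factor(win$strategy, levels = unique(cloud$strategy)))
    tibble::tibble(wtp = l, strategy = names(counts),
                   probability = as.numeric(counts) / dplyr::n_distinct(cloud$draw))
  })
}

#' Expected value of perfect information
#'
#' `EVPI(wtp) = E[max_s NMB_s] - max_s E[NMB_s]` over the PSA draws; the
#' per-patient value of resolving all parameter uncertainty before
#' deciding. Non-negative by Jensen's inequality, and it approaches zero
#' wherever one strategy wins in (almost) every draw.
#'
#' @param cloud A `psa_cloud`.
#' @param wtp_grid Vector of thresholds, USD/QALY.
#' @return A tibble `wtp`, `evpi` (USD per patient).
#' @export
evpi <- function(cloud, wtp_grid) {
  stopifnot(inherits(cloud, "psa_cloud"))
  wide_c <- tidyr::pivot_wider(cloud, id_cols = "draw", names_from = "strategy",
                               values_from = "cost")
  wide_q <- tidyr::pivot_wider(cloud, id_cols = "draw", names_from = "strategy",
                               values_from = "qaly")
  cmat <- as.matrix(wide_c[, -1])
  qmat <- as.matrix(wide_q[, -1])
  purrr::map_dfr(wtp_grid, function(l) {
    nmb <- l * qmat - cmat
    tibble::tibble(wtp = l,
                   evpi = mean(apply(nmb, 1, max)) - max(colMeans(nmb)))
  })
}

#' Adjuvant durvalumab completion scenario
#'
#' Holds the four perioperative durvalumab cycles fixed and assumes a
#' `completer_fraction` of the cohort completes all 10 planned
#' postoperative monotherapy cycles while the remainder averages `m`
#' cycles: expected monotherapy exposure
#' `completer_fraction * 10 + noncompleter_fraction * m` scales the
#' monotherapy drug cost; efficacy is unchanged.
#'
#' @param model A `cea_model`.
#' @param m Average postoperative cycles among non-completers; values in
#'   `{2, 4, 6, 8, 10}` (must not exceed the planned 10).
#' @param completer_fraction Fraction completing all 10 cycles (0.523 in
#'   the reference trial report).
#' @param noncompleter_fraction Defaults to `1 - completer_fraction`; a
#'   different published value (e.g. 0.483) is accepted with a warning
#'   that the fractions do not sum to 1.
#' @return A tibble with one row per `m`: expected cycles, per-strategy
#'   totals and the ICER.
#' @export
scenario_adjuvant_completion <- function(model, m = c(2, 4, 6, 8, 10),
                                         completer_fraction = 0.523,
                                         noncompleter_fraction = NULL) {
  stopifnot(inherits(model, "cea_model"))
  if (any(m > model$config$mono_cycles)) {
    stop("Scenario cycles cannot exceed the planned ",
         model$config$mono_cycles, " monotherapy cycles.", call. = FALSE)
  }
  if (is.null(noncompleter_fraction)) {
    noncompleter_fraction <- 1 - completer_fraction
  } else if (abs(completer_fraction + noncompleter_fraction - 1) > 1e-9) {
    warning("Completer and non-completer fractions do not sum to 1 (",
            completer_fraction, " + ", noncompleter_fraction,
            "); using both as given.", call. = FALSE)
  }
  purrr::map_dfr(m, function(mi) {
    expected <- completer_fraction * model$config$mono_cycles +
      noncompleter_fraction * mi
    cfg <- model$config
    cfg$mono_scale <- expected / cfg$mono_cycles
    ev <- evaluate_cea(model, config = cfg)
    tibble::tibble(
      m = mi, expected_cycles = expected,
      cost_dflot = ev$results$cost_total[ev$results$strategy == "DFLOT"],
      cost_flot = ev$results$cost_total[ev$results$strategy == "FLOT"],
      delta_cost = ev$icer$delta_cost, delta_qaly = ev$icer$delta_qaly,
      icer = ev$icer$icer, label = ev$icer$label
    )
  })
}
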