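# Synthetic two-arm trial evidence: pseudo-IPD, Kaplan-Meier coordinates and
# number-at-risk tables with the statistical structure the downstream
# cost-effectiveness analysis assumes.

#' Calibrate an exponential event rate to a landmark survival probability
#'
#' Solves `exp(-lambda * landmark) = surv_prob` for the monthly rate
#' `lambda`. Used to anchor the synthetic control arm to a published
#' landmark, e.g. 2-year event-free survival of 58.5% gives
#' `-log(0.585) / 24` events per month.
#'
#' @param surv_prob Survival probability at the landmark, in `(0, 1]`.
#' @param landmark Landmark time in months, `> 0`.
#' @return Event rate per month (0 when `surv_prob = 1`).
#' @examples
#' calibrate_exponential_rate(0.585, 24)
#' @export
calibrate_exponential_rate <- function(surv_prob, landmark) {
  if (!is.numeric(surv_prob) || any(surv_prob <= 0) || any(surv_prob > 1)) {
    stop("`surv_prob` must lie in (0, 1].", call. = FALSE)
  }
  if (!is.numeric(landmark) || any(landmark <= 0)) {
    stop("`landmark` must be positive (months).", call. = FALSE)
  }
  -log(surv_prob) / landmark
}

#' Specify one synthetic trial arm
#'
#' @param n Number of subjects (>= 2).
#' @param family Event-time family: `"exponential"` (rate per month) or
#'   `"weibull"` (shape, scale in months).
#' @param params Named list of family parameters, e.g. `list(rate = 0.02)`
#'   or `list(shape = 1.2, scale = 14)`.
#' @param hazard_ratio Proportional-hazards multiplier applied to the
#'   family's baseline hazard (1 = reference arm).
#' @param censor_time Administrative censoring time in months.
#' @param arm Arm label carried into the IPD records.
#' @return A list of class `arm_spec`.
#' @export
arm_spec <- function(n, family = c("exponential", "weibull"), params,
                     hazard_ratio = 1, censor_time = 36, arm = "arm") {
  family <- match.arg(family)
  stopifnot(n >= 2, censor_time > 0, hazard_ratio > 0)
  structure(
    list(n = as.integer(n), family = family, params = params,
         hazard_ratio = hazard_ratio, censor_time = censor_time, arm = arm),
    class = "arm_spec"
  )
}

#' Simulate pseudo-IPD for one arm
#'
#' Event times are drawn from the arm's family with the hazard scaled by
#' `hazard_ratio` (proportional hazards), then administratively censored at
#' `censor_time`. Under proportional hazards `S(t)^h` is the treated
#' survival, so times are generated by inverse transform on `U^(1/h)`.
#'
#' @param spec An [arm_spec()].
#' @param seed Optional integer seed for reproducibility.
#' @return A tibble with columns `time` (months), `event` (0/1), `arm`.
#' @export
simulate_arm_ipd <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "arm_spec"))
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  u <- stats::runif(spec$n)
  # PH scaling: S_arm(t) = S_0(t)^h  =>  t = S_0^{-1}(u^{1/h})
  u0 <- u^(1 / spec$hazard_ratio)
  t_event <- switch(
    spec$family,
    exponential = {
      rate <- spec$params$rate
      if (is.null(rate) || rate < 0) stop("exponential family needs `rate` >= 0.", call. = FALSE)
      if (rate == 0) rep(Inf, spec$n) else -log(u0) / rate
    },
    weibull = {
      shape <- spec$params$shape; scale <- spec$params$scale
      if (is.null(shape) || is.null(scale)) stop("weibull family needs `shape` and `scale`.", call. = FALSE)
      scale * (-log(u0))^(1 / shape)
    },
    stop("Unknown event-time family: ", spec$family, call. = FALSE)
  )
  tibble::tibble(
    time = pmin(t_event, spec$censor_time),
    event = as.integer(t_event <= spec$censor_time),
    arm = spec$arm
  )
}

#' Simulate a two-arm synthetic trial
#'
#' Defaults emulate a MATTERHORN-like perioperative trial: the control-arm
#' event-free survival is exponential calibrated to a 2-year landmark of
#' 58.5%, the treatment arm applies a hazard ratio of 0.71 to the control
#' hazard, overall survival per arm is calibrated marginally to its own
#' 2-year landmark (75.7% vs 70.4%), 474 subjects per arm, administrative
#' censoring at 36 months.
#'
#' @param n_per_arm Subjects per arm.
#' @param efs_landmark_ctrl Control-arm EFS at `landmark_months`.
#' @param efs_hr Treatment-vs-control EFS hazard ratio.
#' @param os_landmark_trt,os_landmark_ctrl 2-year OS landmarks per arm.
#' @param landmark_months Landmark time, months.
#' @param censor_time Administrative censoring, months.
#' @param arms Length-2 character vector: treatment, control labels.
#' @param seed Integer seed.
#' @return A tibble of IPD with columns `time`, `event`, `arm`, `endpoint`
#'   (EFS or OS).
#' @export
simulate_trial <- function(n_per_arm = 474,
                           efs_landmark_ctrl = 0.585,
                           efs_hr = 0.71,
                           os_landmark_trt = 0.757,
                           os_landmark_ctrl = 0.704,
                           landmark_months = 24,
                           censor_time = 36,
                           arms = c("DFLOT", "FLOT"),
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rate_efs <- calibrate_exponential_rate(efs_landmark_ctrl, landmark_months)
  rate_os_t <- calibrate_exponential_rate(os_landmark_trt, landmark_months)
  rate_os_c <- calibrate_exponential_rate(os_landmark_ctrl, landmark_months)
  specs <- list(
    list(arm_spec(n_per_arm, "exponential", list(rate = rate_efs),
                  hazard_ratio = efs_hr, censor_time = censor_time, arm = arms[1]), "EFS"),
    list(arm_spec(n_per_arm, "exponential", list(rate = rate_efs),
                  hazard_ratio = 1, censor_time = censor_time, arm = arms[2]), "EFS"),
    list(arm_spec(n_per_arm, "exponential", list(rate = rate_os_t),
                  hazard_ratio = 1, censor_time = censor_time, arm = arms[1]), "OS"),
    list(arm_spec(n_per_arm, "exponential", list(rate = rate_os_c),
                  hazard_ratio = 1, censor_time = censor_time, arm = arms[2]), "OS")
  )
  purrr::map_dfr(specs, function(s) {
    dplyr::mutate(simulate_arm_ipd(s[[1]]), endpoint = s[[2]])
  })
}

#' Second-line (post-progression) synthetic evidence
#'
#' Weibull progression-free and overall survival standing in for a
#' second-line trial. The default medians are explicitly synthetic
#' placeholders, not trial estimates; configure them to match whichever
#' evidence base is at hand.
#'
#' @param n Number of subjects.
#' @param median_os,median_pfs Median OS and PFS in months.
#' @param shape Weibull shape shared by both endpoints.
#' @param censor_time Administrative censoring, months.
#' @param seed Integer seed.
#' @return A tibble of IPD with columns `time`, `event`, `arm`, `endpoint`
#'   (`PFS2`/`OS2`).
#' @export
simulate_second_line <- function(n = 300, median_os = 10, median_pfs = 4.5,
                                 shape = 1.2, censor_time = 30, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  scale_for_median <- function(m) m / log(2)^(1 / shape)
  mk <- function(median, label) {
    s <- arm_spec(n, "weibull", list(shape = shape, scale = scale_for_median(median)),
                  censor_time = censor_time, arm = "second_line")
    dplyr::mutate(simulate_arm_ipd(s), endpoint = label)
  }
  dplyr::bind_rows(mk(median_pfs, "PFS2"), mk(median_os, "OS2"))
}

#' Kaplan-Meier coordinates and risk table from pseudo-IPD
#'
#' Evaluates the product-limit estimator on a time grid and reports the
#' number at risk on a regular interval, producing the digitized-curve
#' interchange format the reconstruction step consumes.
#'
#' @param ipd Tibble with columns `time`, `event` (single arm/endpoint).
#' @param grid Increasing time grid starting at 0 (months). Default: event
#'   and censoring times plus 0.
#' @param risk_interval Spacing of risk-table rows, months.
#' @return A `digitized_curve`: list with tibbles `points` (time, survival)
#'   and `risk_table` (time, n_at_risk).
#' @export
km_coordinates_from_ipd <- function(ipd, grid = NULL, risk_interval = 6) {
  check_ipd(ipd)
  sf <- survival::survfit(survival::Surv(time, event) ~ 1, data = ipd)
  if (is.null(grid)) grid <- sort(unique(c(0, ipd$time)))
  if (is.unsorted(grid, strictly = TRUE) || grid[1] != 0) {
    stop("`grid` must be strictly increasing and start at 0.", call. = FALSE)
  }
  s <- summary(sf, times = grid, extend = TRUE)
  risk_times <- seq(0, max(ipd$time), by = risk_interval)
  n_at_risk <- vapply(risk_times, function(tt) sum(ipd$time >= tt), integer(1))
  new_digitized_curve(
    points = tibble::tibble(time = grid, survival = s$surv),
    risk_table = tibble::tibble(time = risk_times, n_at_risk = n_at_risk)
  )
}

new_digitized_curve <- function(points, risk_table) {
  structure(list(points = points, risk_table = risk_table),
            class = "digitized_curve")
}

#' Validate a digitized curve
#'
#' Checks the interchange invariants: survival starts at 1 at time 0, is
#' non-increasing and within `[0, 1]`; the number at risk is non-increasing.
#' With `repair = TRUE` (the default for downstream consumers) noisy
#' digitizer output is monotonized by a running minimum and clipped to
#' `[0, 1]` with a warning instead of failing.
#'
#' @param curve A `digitized_curve`.
#' @param repair Monotonize/clip noisy survival coordinates with a warning.
#' @return The (possibly repaired) curve, invisibly usable in pipes.
#' @export
validate_digitized_curve <- function(curve, repair = FALSE) {
  stopifnot(inherits(curve, "digitized_curve"))
  pts <- curve$points
  rt <- curve$risk_table
  if (nrow(pts) < 2) stop("Digitized curve needs at least 2 points.", call. = FALSE)
  if (is.unsorted(pts$time)) stop("Digitized times must be non-decreasing.", call. = FALSE)
  if (any(diff(rt$n_at_risk) > 0)) {
    stop("Number at risk must be non-increasing.", call. = FALSE)
  }
  s <- pts$survival
  bad <- any(s > 1) || any(s < 0) || any(diff(s) > 0) ||
    abs(s[1] - 1) > 1e-9 || pts$time[1] != 0
  if (bad) {
    if (!repair) {
      stop("Survival coordinates violate curve invariants (start at 1, non-increasing, in [0,1]); use repair = TRUE for digitizer noise.",
           call. = FALSE)
    }
    warning("Repairing digitized survival: clipping to [0,1] and monotonizing by running minimum.",
            call. = FALSE)
    s <- pmin(pmax(s, 0), 1)
    s[1] <- 1
    s <- cummin(s)
    curve$points$survival <- s
    if (curve$points$time[1] != 0) {
      curve$points <- dplyr::bind_rows(
        tibble::tibble(time = 0, survival = 1), curve$points
      )
    }
  }
  curve
}

#' @export
print.digitized_curve <- function(x, ...) {
  cat("<digitized_curve> ", nrow(x$points), " coordinates, ",
      nrow(x$risk_table), " risk-table rows, follow-up ",
      round(max(x$points$time), 2), " months\n", sep = "")
  invisible(x)
}

#' Write / read a digitized curve as a delimited file pair
#'
#' The curve is stored as two tab-separated files: `<stem>_curve.tsv` with
#' columns `time`, `survival` and `<stem>_risk.tsv` with columns `time`,
#' `n_at_risk`.
#'
#' @param curve A `digitized_curve`.
#' @param stem Path stem (directory + basename without suffix).
#' @return `write_digitized_curve` returns the two paths invisibly;
#'   `read_digitized_curve` returns a `digitized_curve`.
#' @export
write_digitized_curve <- function(curve, stem) {
  stopifnot(inherits(curve, "digitized_curve"))
  paths <- paste0(stem, c("_curve.tsv", "_risk.tsv"))
  readr::write_tsv(curve$points, paths[1])
  readr::write_tsv(curve$risk_table, paths[2])
  invisible(paths)
}

#' @rdname write_digitized_curve
#' @export
read_digitized_curve <- function(stem) {
  paths <- paste0(stem, c("_curve.tsv", "_risk.tsv"))
  pts <- readr::read_tsv(paths[1], col_types = readr::cols(
    time = readr::col_double(), survival = readr::col_double()
  ))
  rt <- readr::read_tsv(paths[2], col_types = readr::cols(
    time = readr::col_double(), n_at_risk = readr::col_double()
  ))
  new_digitized_curve(points = pts, risk_table = rt)
}

#' Write pseudo-IPD as delimited text
#'
#' @param ipd IPD tibble (`time`, `event`, `arm`, optionally `endpoint`).
#' @param path Output path (TSV).
#' @export
write_ipd <- function(ipd, path) {
  check_ipd(ipd)
  readr::write_tsv(ipd, path)
  invisible(path)
}

#' @rdname write_ipd
#' @export
read_ipd <- function(path) {
  readr::read_tsv(path, col_types = readr::cols())
}

check_ipd <- function(ipd) {
  if (!is.data.frame(ipd) || nrow(ipd) == 0) {
    stop("IPD must be a non-empty data frame.", call. = FALSE)
  }
  if (!all(c("time", "event") %in% names(ipd))) {
    stop("IPD needs `time` and `event` columns.", call. = FALSE)
  }
  if (any(ipd$time < 0)) stop("IPD times must be >= 0.", call. = FALSE)
  if (!all(ipd$event %in% c(0, 1))) stop("IPD `event` must be 0/1.", call. = FALSE)
  invisible(ipd)
}
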