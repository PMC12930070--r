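# Rebuild pseudo individual patient data from digitized Kaplan-Meier
# coordinates and number-at-risk tables (the Guyot-style reconstruction that
# turns published survival figures into analyzable records).

#' Product-limit (Kaplan-Meier) step curve from pseudo-IPD
#'
#' Ties are handled in the conventional order: events before censorings at
#' equal times (the product-limit convention).
#'
#' @param ipd Tibble with `time`, `event` for a single arm/endpoint.
#' @return A tibble of class `step_curve` with columns `time`, `survival`,
#'   `n_risk`, `n_event`, `n_censor`; right-continuous, starting at
#'   `survival = 1` at time 0.
#' @export
km_estimator <- function(ipd) {
  check_ipd(ipd)
  sf <- survival::survfit(survival::Surv(time, event) ~ 1, data = ipd)
  out <- tibble::tibble(
    time = c(0, sf$time),
    survival = c(1, sf$surv),
    n_risk = c(sf$n, sf$n.risk),
    n_event = c(0, sf$n.event),
    n_censor = c(0, sf$n.censor)
  )
  class(out) <- c("step_curve", class(out))
  out
}

#' Evaluate a step curve at arbitrary times
#'
#' @param curve A `step_curve` (from [km_estimator()]).
#' @param times Times at which to evaluate (right-continuous lookup).
#' @return Numeric vector of survival probabilities.
#' @export
step_curve_at <- function(curve, times) {
  idx <- findInterval(times, curve$time)
  ifelse(idx == 0, 1, curve$survival[pmax(idx, 1)])
}

#' Reconstruct pseudo-IPD from a digitized Kaplan-Meier curve
#'
#' Iterative interval-solving in the style of Guyot et al.: within each
#' interval between consecutive number-at-risk times, censorings are assumed
#' uniformly spread, and the number censored is adjusted until the implied
#' number at risk at the next risk time matches the published table; event
#' counts at each digitized drop follow from the product-limit relation.
#' If `total_events` is supplied, censoring in the final interval is tuned
#' so the total event count matches the reported figure as closely as the
#' integer system allows.
#'
#' @param curve A `digitized_curve` (coordinates + risk table). Noisy
#'   digitizer output is repaired (monotonized/clipped) with a warning.
#' @param total_events Optional reported total number of events.
#' @param arm Arm label for the output records.
#' @return A tibble of pseudo-IPD (`time`, `event`, `arm`) whose
#'   Kaplan-Meier estimate reproduces the digitized coordinates.
#' @export
reconstruct_ipd <- function(curve, total_events = NULL, arm = "arm") {
  stopifnot(inherits(curve, "digitized_curve"))
  curve <- validate_digitized_curve(curve, repair = TRUE)
  rt <- curve$risk_table
  if (nrow(rt) < 2) stop("Risk table needs at least 2 entries.", call. = FALSE)
  if (any(diff(rt$n_at_risk) > 0)) stop("Risk table n_at_risk increases.", call. = FALSE)

  pts <- interpolate_boundaries(curve$points, rt$time)
  t_s <- pts$time
  s <- pts$survival
  if (any(diff(s) > 1e-12)) stop("Survival increases within an interval.", call. = FALSE)

  n_int <- nrow(rt)
  n_risk <- as.numeric(rt$n_at_risk)
  # index of first digitized point at each risk time (exists by construction)
  lower <- vapply(rt$time, function(tt) which(abs(t_s - tt) < 1e-9)[1], integer(1))
  upper <- c(lower[-1] - 1L, length(t_s))
  n_t <- upper[n_int]

  n_censor <- numeric(n_int)
  n_hat <- rep(n_risk[1] + 1, n_t + 1)
  cen <- numeric(n_t)
  d <- numeric(n_t)
  km_hat <- rep(1, n_t)
  last_i <- rep(1L, n_int + 1)

  solve_interval <- function(i, n_target) {
    # distribute n_censor[i] censorings uniformly, then walk the clicks
    if (n_censor[i] > 0) {
      cen_t <- t_s[lower[i]] + seq_len(n_censor[i]) *
        (t_s[min(upper[i] + 1, n_t)] - t_s[lower[i]]) / (n_censor[i] + 1)
      brks <- t_s[lower[i]:min(upper[i] + 1, n_t)]
      if (length(brks) >= 2) {
        cen[lower[i]:(min(upper[i] + 1, n_t) - 1)] <<-
          graphics::hist(cen_t, breaks = brks, plot = FALSE)$counts
      } else {
        cen[lower[i]] <<- n_censor[i]
      }
    } else {
      cen[lower[i]:upper[i]] <<- 0
    }
    n_hat[lower[i]] <<- n_risk[i]
    last <- last_i[i]
    for (k in lower[i]:upper[i]) {
      if (i == 1 && k == lower[i]) {
        d[k] <<- 0
        km_hat[k] <<- 1
      } else {
        d[k] <<- round(n_hat[k] * (1 - s[k] / km_hat[last]))
        d[k] <<- max(0, min(d[k], n_hat[k]))
        km_hat[k] <<- km_hat[last] * (1 - d[k] / max(n_hat[k], 1))
      }
      n_hat[k + 1] <<- n_hat[k] - d[k] - cen[k]
      if (d[k] != 0) last <- k
    }
    last_i[i + 1] <<- last
    invisible(NULL)
  }

  if (n_int > 1) {
    for (i in 1:(n_int - 1)) {
      s_lo <- s[lower[i]]
      n_censor[i] <- if (s_lo > 0) round(n_risk[i] * s[lower[i + 1]] / s_lo - n_risk[i + 1]) else 0
      repeat {
        if (n_censor[i] < 0) n_censor[i] <- 0
        solve_interval(i, n_risk[i + 1])
        gap <- n_hat[lower[i + 1]] - n_risk[i + 1]
        if (gap == 0 || (gap < 0 && n_censor[i] <= 0)) break
        n_censor[i] <- n_censor[i] + gap
        if (n_censor[i] < 0) {
          n_censor[i] <- 0
          solve_interval(i, n_risk[i + 1])
          break
        }
      }
      if (n_hat[lower[i + 1]] < n_risk[i + 1]) n_risk[i + 1] <- n_hat[lower[i + 1]]
    }
  }
  # final interval: carry the average censoring rate forward unless anchored
  # by a reported event total
  i <- n_int
  if (n_int > 1) {
    span_prev <- t_s[upper[n_int - 1]] - t_s[lower[1]]
    rate <- if (span_prev > 0) sum(n_censor[1:(n_int - 1)]) / span_prev else 0
    n_censor[i] <- min(round(rate * (t_s[upper[i]] - t_s[lower[i]])), n_risk[i])
  }
  solve_interval(i, 0)

  if (!is.null(total_events)) {
    best <- NULL
    for (cand in 0:n_risk[i]) {
      n_censor[i] <- cand
      solve_interval(i, 0)
      diff_ev <- abs(sum(d) - total_events)
      if (is.null(best) || diff_ev < best$diff) best <- list(cand = cand, diff = diff_ev)
      if (diff_ev == 0) break
    }
    n_censor[i] <- best$cand
    solve_interval(i, 0)
  }

  # emit records: events at click times, censorings at interval midpoints,
  # survivors censored at end of follow-up
  ev_times <- rep(t_s[seq_len(n_t)], times = d[seq_len(n_t)])
  cen_mid <- (t_s[seq_len(n_t)] + c(t_s[2:n_t], t_s[n_t])) / 2
  cen_times <- rep(cen_mid, times = cen[seq_len(n_t)])
  n_left <- n_risk[1] - length(ev_times) - length(cen_times)
  tail_times <- rep(t_s[n_t], times = max(n_left, 0))
  out <- tibble::tibble(
    time = c(ev_times, cen_times, tail_times),
    event = c(rep(1L, length(ev_times)), rep(0L, length(cen_times) + length(tail_times))),
    arm = arm
  )
  dplyr::arrange(out, .data$time, dplyr::desc(.data$event))
}

# Ensure a digitized point exists at every risk-table time, interpolating
# survival linearly between neighbouring coordinates when a boundary was not
# digitized; coordinates at boundaries are treated as exact.
interpolate_boundaries <- function(points, risk_times) {
  pts <- dplyr::distinct(points, .data$time, .keep_all = TRUE)
  missing <- risk_times[!vapply(risk_times, function(tt) any(abs(pts$time - tt) < 1e-9), logical(1))]
  missing <- missing[missing <= max(pts$time)]
  if (length(missing)) {
    sv <- stats::approx(pts$time, pts$survival, xout = missing, rule = 2)$y
    pts <- dplyr::bind_rows(pts, tibble::tibble(time = missing, survival = sv))
  }
  dplyr::arrange(pts, .data$time)
}
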