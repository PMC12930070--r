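# Survival extrapolation: the standard parametric zoo, Royston-Parmar
# splines, fractional-polynomial hazard models and mixture-cure models, all
# wrapped in a common `surv_extrap` object exposing S(t), h(t) and H(t)
# evaluators for the cohort engine.

STANDARD_FAMILIES <- c("exponential", "weibull", "gompertz", "lognormal",
                       "loglogistic", "gamma", "gengamma")

.flexsurv_dist <- c(
  exponential = "exp", weibull = "weibull", gompertz = "gompertz",
  lognormal = "lnorm", loglogistic = "llogis", gamma = "gamma",
  gengamma = "gengamma"
)

new_surv_extrap <- function(family, params, params_t, vcov, loglik, k, n,
                            nevent, evaluators, converged = TRUE,
                            diagnostics = character(), aux = list(),
                            data = NULL) {
  structure(
    list(
      family = family, params = params, params_t = params_t, vcov = vcov,
      loglik = loglik, k = k, n = n, nevent = nevent,
      aic = 2 * k - 2 * loglik, bic = log(n) * k - 2 * loglik,
      surv = evaluators$surv, haz = evaluators$haz, cumhaz = evaluators$cumhaz,
      converged = converged, diagnostics = diagnostics, aux = aux, data = data
    ),
    class = "surv_extrap"
  )
}

# Survival / hazard / cumulative-hazard closures for a parameter vector of
# one of the standard families.
parametric_evaluators <- function(family, params) {
  p <- as.list(params)
  fns <- switch(
    family,
    exponential = list(p = stats::pexp, h = flexsurv::hexp, H = flexsurv::Hexp),
    weibull = list(p = stats::pweibull, h = flexsurv::hweibull, H = flexsurv::Hweibull),
    gompertz = list(p = flexsurv::pgompertz, h = flexsurv::hgompertz, H = flexsurv::Hgompertz),
    lognormal = list(p = stats::plnorm, h = flexsurv::hlnorm, H = flexsurv::Hlnorm),
    loglogistic = list(p = flexsurv::pllogis, h = flexsurv::hllogis, H = flexsurv::Hllogis),
    gamma = list(p = stats::pgamma, h = flexsurv::hgamma, H = flexsurv::Hgamma),
    gengamma = list(p = flexsurv::pgengamma, h = flexsurv::hgengamma, H = flexsurv::Hgengamma),
    stop("Unknown standard family: ", family, call. = FALSE)
  )
  list(
    surv = function(t) do.call(fns$p, c(list(q = t), p, list(lower.tail = FALSE))),
    haz = function(t) do.call(fns$h, c(list(x = t), p)),
    cumhaz = function(t) do.call(fns$H, c(list(x = t), p))
  )
}

spline_evaluators <- function(gamma, knots, scale) {
  list(
    surv = function(t) flexsurv::psurvspline(t, gamma = gamma, knots = knots,
                                             scale = scale, lower.tail = FALSE),
    haz = function(t) flexsurv::hsurvspline(t, gamma = gamma, knots = knots, scale = scale),
    cumhaz = function(t) flexsurv::Hsurvspline(t, gamma = gamma, knots = knots, scale = scale)
  )
}

wrap_flexsurv <- function(f, family, ipd, aux = list()) {
  est_t <- f$res.t[, "est"]
  est <- f$res[, "est"]
  names(est_t) <- names(est) <- rownames(f$res)
  if (family %in% STANDARD_FAMILIES) {
    ev <- parametric_evaluators(family, est)
  } else {
    ev <- spline_evaluators(est_t, aux$knots, aux$scale)
  }
  conv <- is.null(f$opt$convergence) || f$opt$convergence == 0
  new_surv_extrap(
    family = family, params = est, params_t = est_t, vcov = f$cov,
    loglik = f$loglik, k = f$npars, n = f$N, nevent = f$events,
    evaluators = ev, converged = conv,
    diagnostics = if (conv) character() else "optimizer did not report convergence",
    aux = c(aux, list(inv_transforms = f$dlist$inv.transforms,
                      backend = "flexsurv")),
    data = ipd[, c("time", "event")]
  )
}

#' Fit a standard parametric survival model to pseudo-IPD
#'
#' Maximum likelihood with right censoring, for the seven standard
#' extrapolation families: exponential, Weibull, Gompertz, log-normal,
#' log-logistic, gamma and generalized gamma. Fitting is delegated to
#' [flexsurv::flexsurvreg()]; a non-converged optimizer is retried from
#' perturbed initial values and, failing that, returned flagged rather than
#' silently dropped.
#'
#' @param ipd Tibble with `time` (months) and `event` (0/1); at least one
#'   event is required.
#' @param family One of `"exponential"`, `"weibull"`, `"gompertz"`,
#'   `"lognormal"`, `"loglogistic"`, `"gamma"`, `"gengamma"`.
#' @return A `surv_extrap` object: parameter estimates (natural and
#'   estimation scale), covariance, log-likelihood, AIC/BIC and `S(t)`,
#'   `h(t)`, `H(t)` evaluator closures.
#' @export
fit_parametric <- function(ipd, family) {
  family <- match.arg(family, STANDARD_FAMILIES)
  check_ipd(ipd)
  if (sum(ipd$event) < 1) stop("At least one event is required to fit.", call. = FALSE)
  dist <- .flexsurv_dist[[family]]
  fit1 <- try(flexsurv::flexsurvreg(survival::Surv(time, event) ~ 1,
                                    data = ipd, dist = dist), silent = TRUE)
  if (inherits(fit1, "try-error") || fit1$opt$convergence != 0) {
    # one restart from jittered initials before flagging failure
    init <- if (!inherits(fit1, "try-error")) fit1$res.t[, "est"] * 1.05 + 0.01 else NULL
    fit2 <- try(flexsurv::flexsurvreg(survival::Surv(time, event) ~ 1,
                                      data = ipd, dist = dist, inits = init),
                silent = TRUE)
    if (!inherits(fit2, "try-error") && fit2$opt$convergence == 0) {
      fit1 <- fit2
    } else if (inherits(fit1, "try-error")) {
      return(failed_fit(family, ipd, as.character(fit1)))
    }
  }
  wrap_flexsurv(fit1, family, ipd)
}

failed_fit <- function(family, ipd, msg) {
  new_surv_extrap(
    family = family, params = numeric(), params_t = numeric(), vcov = NULL,
    loglik = NA_real_, k = NA_integer_, n = nrow(ipd), nevent = sum(ipd$event),
    evaluators = list(surv = function(t) rep(NA_real_, length(t)),
                      haz = function(t) rep(NA_real_, length(t)),
                      cumhaz = function(t) rep(NA_real_, length(t))),
    converged = FALSE, diagnostics = msg, data = ipd[, c("time", "event")]
  )
}

#' Fit a flexible survival model (Royston-Parmar, fractional polynomial or
#' mixture cure)
#'
#' * `kind = "rp"`: restricted cubic spline in log time on a transformed
#'   survival scale (`"hazard"` = log cumulative hazard, `"odds"` = log
#'   cumulative odds, `"normal"` = probit), via [flexsurv::flexsurvspline()].
#'   With 0 interior knots the hazard scale reduces exactly to Weibull.
#'   Interior knots default to 1, placed at quantiles of the log event
#'   times (the median for 1 knot) with boundary knots at the extremes.
#' * `kind = "fp"`: log-hazard fractional polynomial of order 1 or 2 with
#'   powers from \{-2, -1, -0.5, 0, 0.5, 1, 2, 3\} (0 meaning `log t`;
#'   repeated FP2 powers use `t^p` and `t^p log t`), selected by deviance
#'   when `powers` is `NULL`; the cumulative hazard is integrated by
#'   Gauss-Legendre quadrature.
#' * `kind = "mixture_cure"`: `S(t) = pi + (1 - pi) * S_u(t)` with cure
#'   fraction `pi` estimated on the logit scale and an uncured latency from
#'   the standard registry. A fit driven to the `pi -> 0` boundary is
#'   reported in the diagnostics, not hidden.
#' * `kind = "gam"`: registered for completeness but not available.
#'
#' @param ipd Tibble with `time`, `event`.
#' @param kind `"rp"`, `"fp"`, `"mixture_cure"` or `"gam"`.
#' @param scale RP scale: `"hazard"`, `"odds"` or `"normal"`.
#' @param k Number of interior knots for RP.
#' @param order FP order, 1 or 2.
#' @param powers Optional fixed FP power(s); otherwise selected by deviance.
#' @param latency Mixture-cure latency family (standard registry).
#' @return A `surv_extrap` object.
#' @export
fit_flexible <- function(ipd, kind = c("rp", "fp", "mixture_cure", "gam"),
                         scale = c("hazard", "odds", "normal"), k = 1,
                         order = 1, powers = NULL, latency = "weibull") {
  kind <- match.arg(kind)
  check_ipd(ipd)
  if (kind == "gam") {
    stop("GAM extrapolation is registered but not available in this registry.",
         call. = FALSE)
  }
  if (sum(ipd$event) < 1) stop("At least one event is required to fit.", call. = FALSE)
  switch(kind,
         rp = fit_rp(ipd, match.arg(scale), k),
         fp = fit_fp(ipd, order, powers),
         mixture_cure = fit_mcm(ipd, latency))
}

fit_rp <- function(ipd, scale, k) {
  f <- try(flexsurv::flexsurvspline(survival::Surv(time, event) ~ 1,
                                    data = ipd, k = k, scale = scale),
           silent = TRUE)
  fam <- paste0("rp_", scale)
  if (inherits(f, "try-error") || f$opt$convergence != 0) {
    # gradient-based fit can fail on the probit/odds scales; retry derivative-free
    f2 <- try(flexsurv::flexsurvspline(survival::Surv(time, event) ~ 1,
                                       data = ipd, k = k, scale = scale,
                                       method = "Nelder-Mead",
                                       control = list(maxit = 2000)),
              silent = TRUE)
    if (!inherits(f2, "try-error") && f2$opt$convergence == 0) f <- f2
  }
  if (inherits(f, "try-error")) return(failed_fit(fam, ipd, as.character(f)))
  wrap_flexsurv(f, fam, ipd, aux = list(knots = f$knots, scale = scale))
}

# ---- fractional polynomial log-hazard models --------------------------------

FP_POWERS <- c(-2, -1, -0.5, 0, 0.5, 1, 2, 3)

fp_basis <- function(t, powers) {
  t <- pmax(t, 1e-8)
  if (length(powers) == 2 && powers[1] == powers[2]) {
    p <- powers[1]
    b1 <- if (p == 0) log(t) else t^p
    cbind(b1, b1 * log(t))
  } else {
    vapply(powers, function(p) if (p == 0) log(t) else t^p, numeric(length(t)))
  }
}

# H(t) by fixed-node Gauss-Legendre on [0, t] for each t
fp_cumhaz <- function(t, beta, powers, nodes) {
  vapply(t, function(tt) {
    if (tt <= 0) return(0)
    u <- tt / 2 * (nodes$x + 1)
    hz <- exp(drop(cbind(1, fp_basis(u, powers)) %*% beta))
    tt / 2 * sum(nodes$w * hz)
  }, numeric(1))
}

fp_loglik <- function(beta, time, event, powers, nodes) {
  X <- cbind(1, fp_basis(time, powers))
  lh <- drop(X %*% beta)
  sum(event * lh) - sum(fp_cumhaz(time, beta, powers, nodes))
}

fit_fp_fixed <- function(ipd, powers, nodes) {
  npar <- length(powers) + 1
  init <- c(log(sum(ipd$event) / sum(ipd$time)), rep(0, npar - 1))
  opt <- try(stats::optim(init, fp_loglik, time = ipd$time, event = ipd$event,
                          powers = powers, nodes = nodes, method = "BFGS",
                          control = list(fnscale = -1, maxit = 500, reltol = 1e-10),
                          hessian = TRUE), silent = TRUE)
  if (inherits(opt, "try-error")) return(NULL)
  list(opt = opt, powers = powers)
}

fit_fp <- function(ipd, order, powers) {
  stopifnot(order %in% c(1, 2))
  nodes <- pracma::gaussLegendre(30, -1, 1)
  nodes <- list(x = nodes$x, w = nodes$w)
  cand <- if (!is.null(powers)) {
    list(powers)
  } else if (order == 1) {
    as.list(FP_POWERS)
  } else {
    pairs <- expand.grid(p1 = FP_POWERS, p2 = FP_POWERS)
    pairs <- pairs[pairs$p1 <= pairs$p2, ]
    purrr::map2(pairs$p1, pairs$p2, c)
  }
  fits <- purrr::compact(purrr::map(cand, ~ fit_fp_fixed(ipd, .x, nodes)))
  if (!length(fits)) return(failed_fit(paste0("fp", order), ipd, "no FP fit converged"))
  best <- fits[[which.max(purrr::map_dbl(fits, ~ .x$opt$value))]]
  beta <- best$opt$par
  pw <- best$powers
  names(beta) <- c("beta0", paste0("beta", seq_along(pw)))
  vc <- try(solve(-best$opt$hessian), silent = TRUE)
  if (inherits(vc, "try-error")) vc <- NULL
  ev <- list(
    surv = function(t) exp(-fp_cumhaz(t, beta, pw, nodes)),
    haz = function(t) exp(drop(cbind(1, fp_basis(t, pw)) %*% beta)),
    cumhaz = function(t) fp_cumhaz(t, beta, pw, nodes)
  )
  new_surv_extrap(
    family = paste0("fp", order), params = beta, params_t = beta, vcov = vc,
    loglik = best$opt$value, k = length(beta), n = nrow(ipd),
    nevent = sum(ipd$event), evaluators = ev,
    converged = best$opt$convergence == 0,
    diagnostics = if (best$opt$convergence == 0) character() else "optim non-convergence",
    aux = list(powers = pw, inv_transforms = rep(list(identity), length(beta)),
               backend = "fp"),
    data = ipd[, c("time", "event")]
  )
}

# ---- mixture-cure models ----------------------------------------------------

fit_mcm <- function(ipd, latency) {
  latency <- match.arg(latency, STANDARD_FAMILIES)
  base <- fit_parametric(ipd, latency)
  if (!base$converged) return(failed_fit("mixture_cure", ipd, "latency fit failed"))
  dist <- .flexsurv_dist[[latency]]
  dfun <- get(paste0("d", dist), envir = asNamespace(if (dist %in% c("exp", "weibull", "lnorm", "gamma")) "stats" else "flexsurv"))
  pfun <- get(paste0("p", dist), envir = asNamespace(if (dist %in% c("exp", "weibull", "lnorm", "gamma")) "stats" else "flexsurv"))
  inv_tr <- base$aux$inv_transforms

  natural <- function(theta_lat) {
    stats::setNames(
      purrr::map2_dbl(as.list(theta_lat), inv_tr, function(v, f) f(v)),
      names(base$params)
    )
  }
  nll <- function(theta) {
    pi_c <- stats::plogis(theta[1])
    pars <- as.list(natural(theta[-1]))
    # extreme optimizer excursions can NaN the density; treat as -Inf loglik
    f_u <- suppressWarnings(do.call(dfun, c(list(x = ipd$time), pars)))
    s_u <- suppressWarnings(do.call(pfun, c(list(q = ipd$time), pars, list(lower.tail = FALSE))))
    if (anyNA(f_u) || anyNA(s_u)) return(1e10)
    ll <- ipd$event * log(pmax((1 - pi_c) * f_u, 1e-300)) +
      (1 - ipd$event) * log(pmax(pi_c + (1 - pi_c) * s_u, 1e-300))
    -sum(ll)
  }
  km_tail <- min(km_estimator(ipd)$survival)
  starts <- unique(pmin(pmax(c(km_tail, 0.1, 0.3), 0.01), 0.9))
  best <- NULL
  for (p0 in starts) {
    o <- try(stats::optim(c(stats::qlogis(p0), base$params_t), nll,
                          method = "BFGS",
                          control = list(maxit = 1000, reltol = 1e-10),
                          hessian = TRUE), silent = TRUE)
    if (!inherits(o, "try-error") && (is.null(best) || o$value < best$value)) best <- o
  }
  if (is.null(best)) return(failed_fit("mixture_cure", ipd, "optim failed from all starts"))
  theta <- best$par
  pi_hat <- stats::plogis(theta[1])
  lat_nat <- natural(theta[-1])
  params <- c(cure_fraction = pi_hat, lat_nat)
  params_t <- stats::setNames(theta, c("logit_cure", names(lat_nat)))
  diag_msgs <- character()
  if (theta[1] < stats::qlogis(1e-3)) {
    diag_msgs <- "cure fraction at the pi -> 0 boundary; data show no late plateau"
  }
  pars_l <- as.list(lat_nat)
  ev <- list(
    surv = function(t) pi_hat + (1 - pi_hat) *
      do.call(pfun, c(list(q = t), pars_l, list(lower.tail = FALSE))),
    haz = function(t) {
      s <- pi_hat + (1 - pi_hat) * do.call(pfun, c(list(q = t), pars_l, list(lower.tail = FALSE)))
      (1 - pi_hat) * do.call(dfun, c(list(x = t), pars_l)) / pmax(s, 1e-300)
    },
    cumhaz = function(t) -log(pmax(pi_hat + (1 - pi_hat) *
      do.call(pfun, c(list(q = t), pars_l, list(lower.tail = FALSE))), 1e-300))
  )
  vc <- try(solve(best$hessian), silent = TRUE)
  if (inherits(vc, "try-error")) vc <- NULL
  new_surv_extrap(
    family = "mixture_cure", params = params, params_t = params_t, vcov = vc,
    loglik = -best$value, k = length(theta), n = nrow(ipd),
    nevent = sum(ipd$event), evaluators = ev,
    converged = best$convergence == 0, diagnostics = diag_msgs,
    aux = list(latency = latency,
               inv_transforms = c(list(stats::plogis), inv_tr),
               backend = "mcm"),
    data = ipd[, c("time", "event")]
  )
}

# ---- comparison, transitions, methods ---------------------------------------

#' Compare fitted extrapolation models and select one
#'
#' Builds the comparison table (log-likelihood, AIC, BIC, landmark
#' survival at 2/5/10 years) and applies a selection policy:
#' `"aic"` picks the AIC-best converged fit; `"conservative"` picks, among
#' converged fits within `delta_aic` of the best AIC, the one with the
#' lowest extrapolated 10-year survival (a guard against over-optimistic
#' long-term extrapolation when trial data are immature). AIC ties are
#' broken by BIC, then by input order.
#'
#' @param fits A (possibly named) list of `surv_extrap` objects.
#' @param policy `"conservative"` or `"aic"`.
#' @param delta_aic Acceptability window around the best AIC.
#' @return A list of class `model_comparison`: `$table` (tibble, sorted by
#'   AIC, convergence failures flagged) and `$selected` (family id).
#' @export
compare_models <- function(fits, policy = c("conservative", "aic"), delta_aic = 3) {
  policy <- match.arg(policy)
  if (!length(fits)) stop("`fits` must contain at least one model.", call. = FALSE)
  if (inherits(fits, "surv_extrap")) fits <- list(fits)
  tab <- purrr::imap_dfr(fits, function(f, i) {
    tibble::tibble(
      family = f$family, converged = f$converged, loglik = f$loglik,
      k = f$k, aic = f$aic, bic = f$bic,
      s_2y = if (f$converged) f$surv(24) else NA_real_,
      s_5y = if (f$converged) f$surv(60) else NA_real_,
      s_10y = if (f$converged) f$surv(120) else NA_real_,
      order = if (is.character(i)) match(i, names(fits)) else as.integer(i)
    )
  })
  ok <- tab[tab$converged, , drop = FALSE]
  if (!nrow(ok)) stop("No fit converged; nothing to select.", call. = FALSE)
  ok <- dplyr::arrange(ok, .data$aic, .data$bic, .data$order)
  selected <- if (policy == "aic") {
    ok$family[1]
  } else {
    window <- ok[ok$aic <= ok$aic[1] + delta_aic, , drop = FALSE]
    window <- dplyr::arrange(window, .data$s_10y, .data$bic, .data$order)
    window$family[1]
  }
  tab <- dplyr::select(dplyr::arrange(tab, .data$aic), -"order")
  structure(list(table = tab, selected = selected, policy = policy),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("<model_comparison> policy =", x$policy, "-> selected:", x$selected, "\n")
  print(x$table, ...)
  invisible(x)
}

#' Per-cycle transition probability from a fitted survival curve
#'
#' `p_u = 1 - S(t_{u+1}) / S(t_u)` with `t_u = cycle_index * cycle_len`;
#' the clock may be model time or residence time depending on the caller.
#' If the curve has already reached 0 at the cycle start the probability is
#' 1 (with a warning). Vectorized over `cycle_index`.
#'
#' @param model A `surv_extrap`.
#' @param cycle_index Zero-based cycle index (integer vector).
#' @param cycle_len Cycle length in months.
#' @return Probabilities in `[0, 1]`.
#' @export
transition_probability <- function(model, cycle_index, cycle_len) {
  stopifnot(inherits(model, "surv_extrap"), cycle_len > 0)
  t0 <- cycle_index * cycle_len
  s0 <- model$surv(t0)
  s1 <- model$surv(t0 + cycle_len)
  p <- ifelse(s0 <= 0, 1, 1 - s1 / s0)
  if (any(s0 <= 0)) {
    warning("S(t) = 0 at a cycle start; transition probability set to 1.", call. = FALSE)
  }
  pmin(pmax(p, 0), 1)
}

#' Draw survival-model parameters from their asymptotic distribution
#'
#' Samples the estimation-scale parameter vector from a multivariate normal
#' with the fit's covariance matrix and rebuilds the evaluators at the
#' drawn values (used by the probabilistic sensitivity analysis).
#'
#' @param model A converged `surv_extrap` with a covariance matrix.
#' @return A `surv_extrap` at the drawn parameter values (loglik and
#'   information criteria carried over unchanged, flagged in `aux$resampled`).
#' @export
resample_extrap <- function(model) {
  stopifnot(inherits(model, "surv_extrap"))
  if (!model$converged || is.null(model$vcov)) return(model)
  vc <- (model$vcov + t(model$vcov)) / 2
  ev <- eigen(vc, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 0) vc <- vc + diag(abs(min(ev)) + 1e-10, nrow(vc))
  draw_t <- drop(MASS::mvrnorm(1, mu = model$params_t, Sigma = vc))
  inv_tr <- model$aux$inv_transforms
  fam <- model$family
  out <- model
  out$params_t <- stats::setNames(draw_t, names(model$params_t))
  if (identical(model$aux$backend, "fp")) {
    pw <- model$aux$powers
    nodes <- pracma::gaussLegendre(30, -1, 1)
    beta <- out$params_t
    out$params <- beta
    out$surv <- function(t) exp(-fp_cumhaz(t, beta, pw, nodes))
    out$haz <- function(t) exp(drop(cbind(1, fp_basis(t, pw)) %*% beta))
    out$cumhaz <- function(t) fp_cumhaz(t, beta, pw, nodes)
  } else if (identical(model$aux$backend, "mcm")) {
    pi_hat <- stats::plogis(draw_t[1])
    lat_t <- draw_t[-1]
    lat_nat <- purrr::map2_dbl(as.list(lat_t), inv_tr[-1], function(v, f) f(v))
    names(lat_nat) <- names(model$params)[-1]
    out$params <- c(cure_fraction = pi_hat, lat_nat)
    latency <- model$aux$latency
    dist <- .flexsurv_dist[[latency]]
    ns <- if (dist %in% c("exp", "weibull", "lnorm", "gamma")) "stats" else "flexsurv"
    dfun <- get(paste0("d", dist), envir = asNamespace(ns))
    pfun <- get(paste0("p", dist), envir = asNamespace(ns))
    pars_l <- as.list(lat_nat)
    out$surv <- function(t) pi_hat + (1 - pi_hat) *
      do.call(pfun, c(list(q = t), pars_l, list(lower.tail = FALSE)))
    out$haz <- function(t) {
      s <- out$surv(t)
      (1 - pi_hat) * do.call(dfun, c(list(x = t), pars_l)) / pmax(s, 1e-300)
    }
    out$cumhaz <- function(t) -log(pmax(out$surv(t), 1e-300))
  } else if (fam %in% STANDARD_FAMILIES) {
    nat <- purrr::map2_dbl(as.list(draw_t), inv_tr, function(v, f) f(v))
    names(nat) <- names(model$params)
    out$params <- nat
    evs <- parametric_evaluators(fam, nat)
    out$surv <- evs$surv; out$haz <- evs$haz; out$cumhaz <- evs$cumhaz
  } else {
    # Royston-Parmar spline: gamma coefficients are on the identity scale
    out$params <- out$params_t
    evs <- spline_evaluators(draw_t, model$aux$knots, model$aux$scale)
    out$surv <- evs$surv; out$haz <- evs$haz; out$cumhaz <- evs$cumhaz
  }
  out$aux$resampled <- TRUE
  out
}

#' @export
print.surv_extrap <- function(x, ...) {
  cat("<surv_extrap> family:", x$family,
      if (!x$converged) "[NOT CONVERGED]" else "", "\n")
  if (x$converged) {
    cat("  loglik:", round(x$loglik, 3), " AIC:", round(x$aic, 3),
        " BIC:", round(x$bic, 3), "\n")
    cat("  params:", paste(names(x$params), signif(x$params, 5),
                           sep = "=", collapse = ", "), "\n")
  } else {
    cat("  diagnostics:", x$diagnostics, "\n")
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted extrapolation model
#'
#' @param x A `surv_extrap`.
#' @param ... Unused.
#' @return A tibble with one row per parameter: `term`, `estimate` (natural
#'   scale), `transformed` (estimation scale) and `std.error` (estimation
#'   scale, when a covariance is available).
#' @export
tidy.surv_extrap <- function(x, ...) {
  if (!x$converged) return(tibble::tibble(term = character(), estimate = double(),
                                          transformed = double(), std.error = double()))
  se <- if (!is.null(x$vcov)) sqrt(pmax(diag(as.matrix(x$vcov)), 0)) else rep(NA_real_, x$k)
  tibble::tibble(
    term = names(x$params), estimate = unname(x$params),
    transformed = unname(x$params_t), std.error = unname(se)
  )
}

#' One-row model summary
#'
#' @param x A `surv_extrap`.
#' @param ... Unused.
#' @return A tibble: family, logLik, AIC, BIC, df, nobs, nevent, converged.
#' @export
glance.surv_extrap <- function(x, ...) {
  tibble::tibble(
    family = x$family, logLik = x$loglik, AIC = x$aic, BIC = x$bic,
    df = x$k, nobs = x$n, nevent = x$nevent, converged = x$converged
  )
}

#' Plot a fitted curve against its Kaplan-Meier estimate
#'
#' @param object A `surv_extrap` carrying its fitting data.
#' @param horizon Extrapolation horizon in months.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.surv_extrap <- function(object, horizon = 120, ...) {
  stopifnot(inherits(object, "surv_extrap"))
  grid <- seq(0, horizon, length.out = 400)
  fitted <- tibble::tibble(time = grid, survival = object$surv(grid))
  p <- ggplot2::ggplot(fitted, ggplot2::aes(x = .data$time, y = .data$survival)) +
    ggplot2::geom_line(colour = "#2c7fb8") +
    ggplot2::labs(x = "Months", y = "Survival",
                  title = paste("Extrapolation:", object$family)) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
  if (!is.null(object$data)) {
    km <- km_estimator(object$data)
    p <- p + ggplot2::geom_step(data = km, colour = "grey30",
                                ggplot2::aes(x = .data$time, y = .data$survival))
  }
  p
}
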