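test_that("the exponential MLE matches its closed form and the Weibull nests it", {
  ipd <- make_exp_ipd(n = 300, rate = 0.04, censor = 30, seed = 31)
  f <- fit_parametric(ipd, "exponential")
  expect_equal(unname(f$params["rate"]), sum(ipd$event) / sum(ipd$time),
               tolerance = 1e-6)
  w <- fit_parametric(ipd, "weibull")
  expect_gte(w$loglik, f$loglik - 1e-6)
  expect_error(fit_parametric(dplyr::mutate(ipd, event = 0L), "weibull"),
               "event")
})

test_that("log-likelihood is maximal at the MLE (perturbation property)", {
  ipd <- make_exp_ipd(n = 250, rate = 0.05, censor = 24, seed = 32)
  loglik_at <- function(rate) {
    sum(ipd$event * log(rate)) - rate * sum(ipd$time)
  }
  f <- fit_parametric(ipd, "exponential")
  for (eps in c(-0.1, -0.02, 0.02, 0.1)) {
    expect_gte(f$loglik, loglik_at(unname(f$params["rate"]) * (1 + eps)))
  }
})

test_that("evaluators are internally consistent: S(0)=1, S=exp(-H), AIC/BIC identities", {
  ipd <- make_exp_ipd(n = 200, rate = 0.03, censor = 36, seed = 33)
  tgrid <- c(0.5, 3, 12, 40, 90)
  for (fam in c("exponential", "weibull", "loglogistic", "gompertz",
                "lognormal", "gamma", "gengamma")) {
    f <- fit_parametric(ipd, fam)
    expect_true(f$converged, info = fam)
    expect_equal(f$surv(0), 1, tolerance = 1e-12, info = fam)
    expect_equal(f$surv(tgrid), exp(-f$cumhaz(tgrid)), tolerance = 1e-8, info = fam)
    expect_true(all(diff(f$surv(c(0, tgrid))) <= 0), info = fam)
    expect_equal(f$aic, 2 * f$k - 2 * f$loglik, info = fam)
    expect_equal(f$bic, log(f$n) * f$k - 2 * f$loglik, info = fam)
  }
})

test_that("every standard family recovers its own parameters at n = 2000", {
  set.seed(7)
  n <- 2000
  ev <- rep(1L, n)
  cases <- list(
    exponential = list(r = function() stats::rexp(n, rate = 0.05)),
    weibull = list(r = function() stats::rweibull(n, shape = 1.3, scale = 20)),
    gompertz = list(r = function() flexsurv::rgompertz(n, shape = 0.1, rate = 0.05)),
    lognormal = list(r = function() stats::rlnorm(n, 2.5, 0.8)),
    loglogistic = list(r = function() flexsurv::rllogis(n, shape = 1.5, scale = 15)),
    gamma = list(r = function() stats::rgamma(n, shape = 1.5, rate = 0.08)),
    gengamma = list(r = function() flexsurv::rgengamma(n, mu = 2.5, sigma = 0.8, Q = 1.5))
  )
  truths <- list(
    exponential = c(rate = 0.05), weibull = c(shape = 1.3, scale = 20),
    gompertz = c(shape = 0.1, rate = 0.05), lognormal = c(meanlog = 2.5, sdlog = 0.8),
    loglogistic = c(shape = 1.5, scale = 15), gamma = c(shape = 1.5, rate = 0.08),
    gengamma = c(mu = 2.5, sigma = 0.8, Q = 1.5)
  )
  for (fam in names(cases)) {
    ipd <- tibble::tibble(time = cases[[fam]]$r(), event = ev, arm = "sim")
    f <- fit_parametric(ipd, fam)
    rel <- abs(f$params - truths[[fam]]) / abs(truths[[fam]])
    expect_true(all(rel < 0.10),
                info = paste(fam, paste(signif(rel, 2), collapse = ", ")))
  }
})

test_that("the hazard-scale spline with no interior knots reduces to Weibull", {
  ipd <- make_exp_ipd(n = 300, rate = 0.03, censor = 36, seed = 34)
  w <- fit_parametric(ipd, "weibull")
  rp <- fit_flexible(ipd, "rp", scale = "hazard", k = 0)
  expect_lt(abs(rp$loglik - w$loglik), 1e-3)
  expect_equal(rp$surv(c(6, 18, 30)), w$surv(c(6, 18, 30)), tolerance = 1e-4)
})

test_that("spline fits work on the odds and probit scales with interior knots", {
  ipd <- make_exp_ipd(n = 300, rate = 0.03, censor = 36, seed = 35)
  for (sc in c("odds", "normal")) {
    f <- fit_flexible(ipd, "rp", scale = sc, k = 1)
    expect_true(f$converged, info = sc)
    expect_equal(f$surv(0), 1, tolerance = 1e-9)
    expect_true(all(diff(f$cumhaz(seq(0.5, 100, by = 0.5))) > -1e-9), info = sc)
  }
})

test_that("a first-order fractional polynomial with log-time power matches Weibull", {
  ipd <- make_exp_ipd(n = 200, rate = 0.04, censor = 30, seed = 36)
  w <- fit_parametric(ipd, "weibull")
  # log h(t) = b0 + b1 log t is exactly the Weibull hazard family
  fp <- fit_flexible(ipd, "fp", order = 1, powers = 0)
  expect_true(fp$converged)
  expect_lt(abs(fp$loglik - w$loglik), 0.01)
})

test_that("fractional-polynomial power selection picks the best deviance", {
  ipd <- make_exp_ipd(n = 150, rate = 0.04, censor = 30, seed = 37)
  fp <- fit_flexible(ipd, "fp", order = 1)
  for (p in c(-1, 0, 1)) {
    fixed <- fit_flexible(ipd, "fp", order = 1, powers = p)
    expect_gte(fp$loglik, fixed$loglik - 1e-6)
  }
  expect_equal(fp$family, "fp1")
  expect_length(fp$aux$powers, 1)
})

test_that("the mixture-cure model recovers a true cure fraction of 0.3", {
  set.seed(41)
  n <- 2000
  cured <- stats::runif(n) < 0.3
  t_lat <- stats::rweibull(n, shape = 1.4, scale = 12)
  time <- ifelse(cured, 120, pmin(t_lat, 120))
  event <- as.integer(!cured & t_lat <= 120)
  ipd <- tibble::tibble(time = time, event = event, arm = "sim")
  mcm <- fit_flexible(ipd, "mixture_cure", latency = "weibull")
  expect_true(mcm$converged)
  expect_lt(abs(unname(mcm$params["cure_fraction"]) - 0.3), 0.05)
  # nesting: the mixture never fits worse than its latency alone
  lat <- fit_parametric(ipd, "weibull")
  expect_gte(mcm$loglik, lat$loglik - 1e-6)
})

test_that("a cure fraction collapsing to zero is reported, not hidden", {
  ipd <- tibble::tibble(time = stats::rweibull(800, 1.2, 10), event = 1L, arm = "x")
  mcm <- fit_flexible(ipd, "mixture_cure", latency = "weibull")
  expect_lt(unname(mcm$params["cure_fraction"]), 0.05)
})

test_that("the GAM registry slot raises a clear not-available error", {
  expect_error(fit_flexible(hand_ipd(), "gam"), "not available")
})

test_that("model comparison sorts by AIC and the conservative policy prefers low tails", {
  mk <- function(family, loglik, k, s10) {
    flotcea:::new_surv_extrap(
      family = family, params = c(a = 1), params_t = c(a = 1), vcov = NULL,
      loglik = loglik, k = k, n = 100, nevent = 60,
      evaluators = list(
        surv = function(t) ifelse(t >= 120, s10, exp(-0.01 * t)),
        haz = function(t) rep(0.01, length(t)),
        cumhaz = function(t) 0.01 * t
      )
    )
  }
  a <- mk("optimist", -100, 2, 0.30)
  b <- mk("pessimist", -100, 2, 0.05)
  c <- mk("poor", -150, 2, 0.01)
  cmp <- compare_models(list(a, b, c), policy = "conservative")
  expect_equal(cmp$selected, "pessimist")
  expect_equal(cmp$table$family[1:2], c("optimist", "pessimist"))
  expect_equal(compare_models(list(a, b, c), policy = "aic")$selected, "optimist")
  expect_equal(compare_models(list(a))$selected, "optimist")
  expect_error(compare_models(list()), "at least one")
})

test_that("transition probabilities follow 1 - S(t+d)/S(t)", {
  ipd <- make_exp_ipd(n = 400, rate = 0.05, censor = 30, seed = 38)
  f <- fit_parametric(ipd, "exponential")
  lam <- unname(f$params["rate"])
  d <- CYCLE_LENGTH_MONTHS
  p <- transition_probability(f, 0:49, d)
  expect_equal(p, rep(1 - exp(-lam * d), 50), tolerance = 1e-10)
  w <- fit_parametric(ipd, "weibull")
  expect_equal(transition_probability(w, 0, d), 1 - w$surv(d), tolerance = 1e-12)
  pw <- transition_probability(w, 0:129, d)
  expect_true(all(pw >= 0 & pw <= 1))
})

test_that("tidy and glance expose broom-shaped summaries", {
  f <- fit_parametric(make_exp_ipd(seed = 39), "weibull")
  td <- generics::tidy(f)
  expect_named(td, c("term", "estimate", "transformed", "std.error"))
  expect_equal(td$term, c("shape", "scale"))
  gl <- generics::glance(f)
  expect_equal(gl$df, 2)
  expect_true(gl$converged)
})

test_that("parameter resampling perturbs curves but preserves structure", {
  f <- fit_parametric(make_exp_ipd(n = 400, seed = 40), "weibull")
  set.seed(1)
  draws <- replicate(30, unname(resample_extrap(f)$params["shape"]))
  expect_gt(stats::sd(draws), 0)
  expect_lt(abs(mean(draws) - unname(f$params["shape"])), 0.2)
  r <- resample_extrap(f)
  expect_equal(r$surv(0), 1)
  expect_true(all(diff(r$surv(seq(0, 100, 2))) <= 0))
})
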