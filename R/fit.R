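#' @section Model: fitted time-to-revision objects
#'
#' All fitters return an object of class `hip_survfit` holding the family,
#' natural-scale baseline parameters (or spline coefficients and knots),
#' proportional-hazards covariate coefficients, the maximised log-likelihood
#' and a variance-covariance matrix on the working (unconstrained) scale.
#' Covariates act multiplicatively on the cumulative hazard:
#' H(t | x) = H0(t) exp(x'beta) (for the spline model, additively on the log
#' cumulative hazard). Covariates are centred at their sample means
#' internally; predictions take natural-scale covariate values.
#' @name hip_survfit
#' @keywords internal
NULL

## ---- working-scale transforms -------------------------------------------

theta_to_params <- function(family, theta) {
  switch(family,
    weibull = c(shape = exp(theta[1]), scale = exp(theta[2])),
    exponential = c(rate = exp(theta[1])),
    gompertz = c(shape = theta[1], rate = exp(theta[2])),
    loglogistic = c(shape = exp(theta[1]), scale = exp(theta[2])),
    gengamma = c(mu = theta[1], sigma = exp(theta[2]), Q = theta[3]),
    bathtub = c(shape1 = stats::plogis(theta[1]), scale1 = exp(theta[2]),
                shape2 = 1 + exp(theta[3]), scale2 = exp(theta[4])),
    stop("unknown family: ", family)
  )
}

params_to_theta <- function(family, params) {
  p <- as.list(params)
  switch(family,
    weibull = c(log(p$shape), log(p$scale)),
    exponential = log(p$rate),
    gompertz = c(p$shape, log(p$rate)),
    loglogistic = c(log(p$shape), log(p$scale)),
    gengamma = c(p$mu, log(p$sigma), p$Q),
    bathtub = c(stats::qlogis(p$shape1), log(p$scale1),
                log(p$shape2 - 1), log(p$scale2)),
    stop("unknown family: ", family)
  )
}

n_baseline_params <- function(family) {
  switch(family, weibull = 2L, exponential = 1L, gompertz = 2L,
         loglogistic = 2L, gengamma = 3L, bathtub = 4L)
}

## ---- restricted cubic spline basis (log-time scale) ---------------------

# Basis columns: 1, x, and one restricted cubic term per internal knot.
# Restricted so the spline is linear beyond the boundary knots, which
# gives Weibull-like (log-linear cumulative hazard) extrapolation.
rp_basis <- function(x, knots) {
  kmin <- knots[1]; kmax <- knots[length(knots)]
  internal <- knots[-c(1, length(knots))]
  cols <- list(rep(1, length(x)), x)
  for (kj in internal) {
    lam <- (kmax - kj) / (kmax - kmin)
    cols[[length(cols) + 1L]] <-
      pmax(x - kj, 0)^3 - lam * pmax(x - kmin, 0)^3 -
      (1 - lam) * pmax(x - kmax, 0)^3
  }
  do.call(cbind, cols)
}

rp_basis_deriv <- function(x, knots) {
  kmin <- knots[1]; kmax <- knots[length(knots)]
  internal <- knots[-c(1, length(knots))]
  cols <- list(rep(0, length(x)), rep(1, length(x)))
  for (kj in internal) {
    lam <- (kmax - kj) / (kmax - kmin)
    cols[[length(cols) + 1L]] <-
      3 * pmax(x - kj, 0)^2 - 3 * lam * pmax(x - kmin, 0)^2 -
      3 * (1 - lam) * pmax(x - kmax, 0)^2
  }
  do.call(cbind, cols)
}

## ---- shared fitting helpers ---------------------------------------------

extract_surv_data <- function(records, covariates,
                              time_col = "followup_time",
                              event_col = "revised") {
  if (is.data.frame(records)) {
    t <- records[[time_col]]
    d <- records[[event_col]]
    Z <- if (length(covariates)) {
      as.matrix(records[, covariates, drop = FALSE])
    } else matrix(0, nrow(records), 0)
  } else {
    stop("records must be a data frame with follow-up time and event columns",
         call. = FALSE)
  }
  if (is.null(t) || is.null(d))
    stop(sprintf("records must contain '%s' and '%s' columns",
                 time_col, event_col), call. = FALSE)
  stopifnot(all(t > 0), all(d %in% c(0, 1)))
  if (ncol(Z) && !all(is.finite(Z))) stop("covariate values must be finite",
                                          call. = FALSE)
  list(t = t, d = d, Z = Z)
}

# maximise with up to `restarts` jittered re-initialisations
maximise_loglik <- function(negll, init, restarts = 5) {
  best <- NULL
  cur_init <- init
  for (r in seq_len(restarts + 1)) {
    fit <- tryCatch(
      stats::optim(cur_init, negll, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-12),
                   hessian = FALSE),
      error = function(e) NULL)
    if (is.null(fit))
      fit <- tryCatch(
        stats::optim(cur_init, negll, method = "Nelder-Mead",
                     control = list(maxit = 2000)),
        error = function(e) NULL)
    if (!is.null(fit) && is.finite(fit$value) &&
        (is.null(best) || fit$value < best$value - 1e-9)) {
      best <- fit
    }
    if (!is.null(best) && best$convergence == 0 && r > 1) break
    if (!is.null(best) && best$convergence == 0 && r == 1) break
    cur_init <- init + stats::rnorm(length(init), 0, 0.3)
  }
  if (is.null(best)) return(list(converged = FALSE))
  # polish + hessian at the optimum
  pol <- tryCatch(
    stats::optim(best$par, negll, method = "BFGS",
                 control = list(maxit = 200, reltol = 1e-12), hessian = TRUE),
    error = function(e) NULL)
  if (!is.null(pol) && is.finite(pol$value) && pol$value <= best$value + 1e-9)
    best <- pol
  vcov <- NULL
  if (!is.null(best$hessian)) {
    vcov <- tryCatch(solve(best$hessian), error = function(e) NULL)
    if (!is.null(vcov) && any(!is.finite(vcov))) vcov <- NULL
  }
  list(par = best$par, value = best$value,
       converged = best$convergence == 0 && is.finite(best$value),
       vcov = vcov)
}

new_hip_survfit <- function(family, dat, covariates, opt, extra = list()) {
  centers <- if (ncol(dat$Z)) colMeans(dat$Z) else numeric(0)
  out <- c(list(family = family,
                covariates = covariates,
                centers = centers,
                n = length(dat$t),
                n_events = sum(dat$d),
                log_likelihood = if (opt$converged) -opt$value else NA_real_,
                converged = opt$converged,
                vcov = opt$vcov),
           extra)
  class(out) <- "hip_survfit"
  out
}

## ---- parametric families -------------------------------------------------

#' Fit a parametric time-to-revision model
#'
#' Right-censored maximum likelihood for the supported families, with
#' optional proportional-hazards covariates: H(t | x) = H0(t) exp(x'beta).
#' The `bathtub` family is an additive two-Weibull hazard, one decreasing
#' (shape < 1) and one increasing (shape > 1) component, so early
#' (surgery-related) and late (wear-related) revision risks are modelled
#' jointly. Optimisation restarts from jittered initial values (Weibull-based)
#' up to `restarts` times before flagging non-convergence.
#'
#' @param records data frame with `followup_time` (> 0 years) and `revised`
#'   (0/1) columns plus any covariate columns
#' @param family one of `"weibull"`, `"gompertz"`, `"loglogistic"`,
#'   `"gengamma"`, `"bathtub"`, `"exponential"`
#' @param covariates character vector of covariate column names (centred
#'   internally; proportional effect on the cumulative hazard)
#' @param restarts jittered re-initialisations before giving up (default 5)
#' @param min_events minimum number of events required (default 10)
#' @return a `hip_survfit` (see [predict_cumulative_revision()])
#' @examples
#' reg <- generate_registry(cohort_spec(n_patients = 2000, seed = 7))
#' fit <- fit_parametric(reg[reg$device_class == "RS", ], "weibull")
#' fit$params
#' @export
fit_parametric <- function(records, family, covariates = character(),
                           restarts = 5, min_events = 10) {
  family <- match.arg(family, c("weibull", "gompertz", "loglogistic",
                                "gengamma", "bathtub", "exponential"))
  dat <- extract_surv_data(records, covariates)
  if (sum(dat$d) < min_events)
    stop(sprintf("fit refused: %d event(s) observed, need >= %d",
                 sum(dat$d), min_events), call. = FALSE)
  Zc <- if (ncol(dat$Z)) sweep(dat$Z, 2, colMeans(dat$Z)) else dat$Z
  npar <- n_baseline_params(family)
  nbeta <- ncol(Zc)

  negll <- function(par) {
    params <- theta_to_params(family, par[seq_len(npar)])
    if (!isTRUE(family_check_params(family, params))) return(1e10)
    beta <- par[npar + seq_len(nbeta)]
    lin <- if (nbeta) drop(Zc %*% beta) else 0
    h0 <- family_hazard(family, dat$t, params)
    H0 <- family_cumhaz(family, dat$t, params)
    ll <- sum(dat$d * (log(h0) + lin)) - sum(H0 * exp(lin))
    if (!is.finite(ll)) return(1e10)
    -ll
  }

  init <- c(initial_theta(family, dat), rep(0, nbeta))
  opt <- maximise_loglik(negll, init, restarts)
  if (!opt$converged)
    warning(sprintf("fit_parametric(%s): optimiser did not converge", family))
  params <- if (!is.null(opt$par)) {
    theta_to_params(family, opt$par[seq_len(npar)])
  } else NULL
  beta <- if (!is.null(opt$par) && nbeta) {
    stats::setNames(opt$par[npar + seq_len(nbeta)], covariates)
  } else stats::setNames(numeric(0), character(0))
  new_hip_survfit(family, dat, covariates, opt,
                  list(params = params, beta = beta,
                       theta = if (!is.null(opt$par)) opt$par[seq_len(npar)]))
}

# Weibull-flavoured starting values: exponential-rate scale, then per-family
# correspondence (gengamma Q=1 sigma=1/k IS Weibull; others matched loosely).
initial_theta <- function(family, dat) {
  rate <- sum(dat$d) / sum(dat$t)
  scale0 <- 1 / max(rate, 1e-10)
  switch(family,
    exponential = log(rate),
    weibull = c(0, log(scale0)),
    gompertz = c(0.01, log(rate)),
    loglogistic = c(0, log(scale0)),
    gengamma = c(log(scale0), 0, 1),
    bathtub = c(stats::qlogis(0.5), log(scale0 * 8),
                log(2 - 1), log(scale0 * 1.5))
  )
}

## ---- Royston-Parmar -------------------------------------------------------

#' Fit a Royston-Parmar flexible parametric survival model
#'
#' Models the log cumulative revision hazard as a restricted cubic spline in
#' log time plus a linear predictor: log H(t | x) = s(log t; gamma) + x'beta.
#' With `df = 1` the spline is a straight line and the model is exactly a
#' Weibull. Internal knots (`df - 1` of them) sit at equally spaced centiles
#' of the uncensored log event times; boundary knots at their extremes, so
#' extrapolation beyond the data is log-linear.
#'
#' @inheritParams fit_parametric
#' @param df spline degrees of freedom (>= 1); `df - 1` internal knots
#' @return a `hip_survfit` with elements `gamma` (spline coefficients) and
#'   `knots` (log-time scale)
#' @examples
#' reg <- generate_registry(cohort_spec(n_patients = 3000, seed = 11))
#' rs <- reg[reg$device_class == "RS", ]
#' fit <- fit_royston_parmar(rs, df = 2, covariates = "age_at_primary")
#' predict_cumulative_revision(fit, 10,
#'   covariate_values = c(age_at_primary = 55))
#' @export
fit_royston_parmar <- function(records, df = 3, covariates = character(),
                               restarts = 5, min_events = 10) {
  stopifnot(df >= 1)
  dat <- extract_surv_data(records, covariates)
  if (sum(dat$d) < min_events)
    stop(sprintf("fit refused: %d event(s) observed, need >= %d",
                 sum(dat$d), min_events), call. = FALSE)
  logt_events <- log(dat$t[dat$d == 1])
  probs <- seq(0, 1, length.out = df + 1)
  knots <- unname(stats::quantile(logt_events, probs, type = 7))
  if (any(diff(knots) <= 0))
    stop("degenerate knots: too few distinct event times for df = ", df,
         call. = FALSE)
  Zc <- if (ncol(dat$Z)) sweep(dat$Z, 2, colMeans(dat$Z)) else dat$Z
  nbeta <- ncol(Zc)
  x <- log(dat$t)
  B <- rp_basis(x, knots)
  Bd <- rp_basis_deriv(x, knots)
  ngam <- ncol(B)
  ev <- dat$d == 1

  negll <- function(par) {
    gamma <- par[seq_len(ngam)]
    beta <- par[ngam + seq_len(nbeta)]
    s <- drop(B %*% gamma)
    ds <- drop(Bd %*% gamma)
    if (any(ds[ev] <= 0)) return(1e10)
    lin <- if (nbeta) drop(Zc %*% beta) else 0
    eta <- s + lin
    # h(t) = ds/dlogt * H(t) / t;  log h = log ds - log t + eta
    ll <- sum(log(ds[ev]) - x[ev] + eta[ev]) - sum(exp(eta))
    if (!is.finite(ll)) return(1e10)
    -ll
  }

  # init from a Weibull (straight-line spline), interior terms zero
  wb <- initial_theta("weibull", dat)
  k0 <- exp(wb[1]); b0 <- exp(wb[2])
  init <- c(-k0 * log(b0), k0, rep(0, ngam - 2), rep(0, nbeta))
  opt <- maximise_loglik(negll, init, restarts)
  if (!opt$converged)
    warning("fit_royston_parmar: optimiser did not converge")
  gamma <- if (!is.null(opt$par)) opt$par[seq_len(ngam)]
  beta <- if (!is.null(opt$par) && nbeta) {
    stats::setNames(opt$par[ngam + seq_len(nbeta)], covariates)
  } else stats::setNames(numeric(0), character(0))
  new_hip_survfit("royston_parmar", dat, covariates, opt,
                  list(df = df, knots = knots, gamma = gamma, beta = beta))
}

#' Interpret a df = 1 spline fit as a Weibull
#'
#' A straight-line log-cumulative-hazard spline is exactly Weibull with
#' shape = gamma1 and scale = exp(-gamma0 / gamma1). Standard errors follow
#' by the delta method from the fit's variance-covariance matrix.
#'
#' @param fit a converged `hip_survfit` of family `royston_parmar`, `df = 1`
#' @return list with `shape`, `scale`, `se_shape`, `se_scale`
#' @export
rp_as_weibull <- function(fit) {
  stopifnot(inherits(fit, "hip_survfit"), fit$family == "royston_parmar",
            fit$df == 1, isTRUE(fit$converged))
  g0 <- fit$gamma[1]; g1 <- fit$gamma[2]
  shape <- g1
  scale <- exp(-g0 / g1)
  se_shape <- se_scale <- NA_real_
  if (!is.null(fit$vcov)) {
    V <- fit$vcov[1:2, 1:2]
    se_shape <- sqrt(V[2, 2])
    grad <- c(-scale / g1, scale * g0 / g1^2)  # d scale / d (g0, g1)
    se_scale <- sqrt(drop(t(grad) %*% V %*% grad))
  }
  list(shape = shape, scale = scale, se_shape = se_shape, se_scale = se_scale)
}

## ---- prediction -----------------------------------------------------------

# survival S(t | x) for any hip_survfit; t may be a vector, t = 0 allowed
survfit_surv <- function(fit, t, covariate_values = NULL) {
  stopifnot(inherits(fit, "hip_survfit"))
  if (!isTRUE(fit$converged))
    stop("prediction refused: fit did not converge", call. = FALSE)
  if (any(t < 0)) stop("t must be >= 0", call. = FALSE)
  lin <- 0
  if (length(fit$covariates)) {
    if (is.null(covariate_values))
      stop("covariate_values required for a fit with covariates",
           call. = FALSE)
    z <- covariate_values[fit$covariates]
    if (any(is.na(z)))
      stop("covariate_values must name: ",
           paste(fit$covariates, collapse = ", "), call. = FALSE)
    lin <- sum((z - fit$centers) * fit$beta)
  }
  out <- numeric(length(t))
  pos <- t > 0
  if (fit$family == "royston_parmar") {
    x <- log(t[pos])
    s <- drop(rp_basis(x, fit$knots) %*% fit$gamma)
    out[pos] <- exp(-exp(s + lin))
  } else {
    H0 <- family_cumhaz(fit$family, t[pos], fit$params)
    out[pos] <- exp(-H0 * exp(lin))
  }
  out[!pos] <- 1
  out
}

#' Predicted cumulative revision probability
#'
#' Returns 1 - S(t | x) from a converged fit; vectorised over `t`.
#'
#' @param fit a converged `hip_survfit`
#' @param t times since primary surgery (years, >= 0)
#' @param covariate_values named vector of natural-scale covariate values
#'   (required when the fit has covariates)
#' @return numeric vector of probabilities
#' @export
predict_cumulative_revision <- function(fit, t, covariate_values = NULL) {
  1 - survfit_surv(fit, t, covariate_values)
}

#' Annual revision transition probabilities from a fitted model
#'
#' Converts fitted survival into the cohort model's conditional annual
#' revision probabilities p_t = (S(t-1) - S(t)) / S(t-1), t = 1..horizon.
#' The product of (1 - p_t) telescopes back to S(horizon) exactly. If S
#' reaches 0 the schedule is truncated there with a warning.
#'
#' @inheritParams predict_cumulative_revision
#' @param horizon integer number of annual cycles (>= 1)
#' @return a `revision_schedule`: numeric vector p_1..p_horizon with the
#'   survival curve in attribute `"surv"`
#' @export
annual_transition_probs <- function(fit, covariate_values = NULL,
                                    horizon = 10) {
  stopifnot(horizon >= 1, horizon == round(horizon))
  S <- survfit_surv(fit, 0:horizon, covariate_values)
  make_schedule_from_surv(S)
}

make_schedule_from_surv <- function(S) {
  horizon <- length(S) - 1L
  p <- numeric(horizon)
  for (t in seq_len(horizon)) {
    if (S[t] <= 0) {
      warning("revision schedule truncated at cycle ", t - 1,
              ": survival reached 0")
      p <- p[seq_len(t - 1)]
      S <- S[seq_len(t)]
      break
    }
    p[t] <- (S[t] - S[t + 1]) / S[t]
  }
  structure(pmin(pmax(p, 0), 1), surv = S, class = "revision_schedule")
}

#' Build a revision schedule from explicit annual probabilities
#'
#' @param p vector of conditional annual revision probabilities in \[0, 1\]
#' @return a `revision_schedule`
#' @export
revision_schedule <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  structure(as.numeric(p), surv = cumprod(c(1, 1 - p)),
            class = "revision_schedule")
}

## ---- methods & serialisation ---------------------------------------------

#' @export
logLik.hip_survfit <- function(object, ...) {
  structure(object$log_likelihood,
            df = length(object$gamma) + length(object$theta) +
              length(object$beta),
            class = "logLik")
}

#' @export
print.hip_survfit <- function(x, ...) {
  cat("Time-to-revision fit:", x$family,
      if (x$family == "royston_parmar") sprintf("(df = %d)", x$df) else "",
      "\n")
  cat(sprintf("  n = %d, events = %d, logLik = %.4f, converged = %s\n",
              x$n, x$n_events, x$log_likelihood, x$converged))
  if (!is.null(x$params))
    cat("  params:", paste(names(x$params), signif(x$params, 5),
                           sep = " = ", collapse = ", "), "\n")
  if (!is.null(x$gamma))
    cat("  gamma:", paste(signif(x$gamma, 5), collapse = ", "),
        " knots(log t):", paste(signif(x$knots, 4), collapse = ", "), "\n")
  if (length(x$beta))
    cat("  beta:", paste(names(x$beta), signif(x$beta, 5),
                         sep = " = ", collapse = ", "), "\n")
  invisible(x)
}

#' Serialise a fit summary to JSON
#'
#' @param fit a `hip_survfit`
#' @param path optional file path; when `NULL` the JSON string is returned
#' @return the JSON string, invisibly when written to a file
#' @export
fit_to_json <- function(fit, path = NULL) {
  obj <- list(family = fit$family,
              params = as.list(fit$params),
              gamma = fit$gamma, knots = fit$knots, df = fit$df,
              beta = as.list(fit$beta), centers = as.list(fit$centers),
              log_likelihood = fit$log_likelihood,
              n = fit$n, n_events = fit$n_events, converged = fit$converged)
  obj <- obj[!vapply(obj, is.null, logical(1))]
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}

#' Export a fitted survival curve as CSV
#'
#' Columns `t`, `S`; pointwise uncertainty columns are omitted for spline
#' fits without a stored covariance.
#' @param fit a converged `hip_survfit`
#' @param t evaluation times
#' @param path file path
#' @param covariate_values as in [predict_cumulative_revision()]
#' @export
write_survival_curve <- function(fit, t, path, covariate_values = NULL) {
  S <- survfit_surv(fit, t, covariate_values)
  utils::write.csv(data.frame(t = t, S = S), path, row.names = FALSE)
  invisible(path)
}
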