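#' Parametric time-to-event families
#'
#' Internal definitions of the hazard families shared by the synthetic
#' registry generator and the maximum-likelihood fitters, so that simulated
#' "truth" and fitted models use one and the same formula.
#'
#' Parameterisations (all times in years, all parameters on their natural
#' scale):
#' \describe{
#'   \item{weibull}{`shape` k, `scale` b; H(t) = (t/b)^k.}
#'   \item{gompertz}{`shape` a (real), `rate` r > 0; h(t) = r e^{at},
#'     H(t) = r(e^{at}-1)/a (limit r t as a -> 0).}
#'   \item{loglogistic}{`shape` k, `scale` b; S(t) = 1/(1 + (t/b)^k).}
#'   \item{gengamma}{Prentice `mu`, `sigma` > 0, `Q` (real); reduces to
#'     Weibull at Q = 1, lognormal at Q = 0, gamma at Q = sigma.}
#'   \item{bathtub}{additive two-Weibull hazard: a decreasing component
#'     (`shape1` < 1, `scale1`) plus an increasing component (`shape2` > 1,
#'     `scale2`); h = h1 + h2, H = H1 + H2.}
#'   \item{exponential}{`rate`; constant hazard (handy ground truth).}
#'   \item{zero}{no events ever; for degenerate test worlds.}
#' }
#'
#' @name families
#' @keywords internal
NULL

.hip_families <- c("weibull", "gompertz", "loglogistic", "gengamma",
                   "bathtub", "exponential", "zero")

## cumulative hazard H(t) on the baseline (no covariates)
family_cumhaz <- function(family, t, params) {
  p <- as.list(params)
  switch(family,
    weibull = (t / p$scale)^p$shape,
    exponential = p$rate * t,
    gompertz = {
      a <- p$shape
      if (abs(a) < 1e-10) p$rate * t else p$rate * expm1(a * t) / a
    },
    loglogistic = log1p((t / p$scale)^p$shape),
    gengamma = -gengamma_logsurv(t, p$mu, p$sigma, p$Q),
    bathtub = (t / p$scale1)^p$shape1 + (t / p$scale2)^p$shape2,
    zero = rep(0, length(t)),
    stop("unknown family: ", family)
  )
}

## hazard h(t) on the baseline
family_hazard <- function(family, t, params) {
  p <- as.list(params)
  switch(family,
    weibull = (p$shape / p$scale) * (t / p$scale)^(p$shape - 1),
    exponential = rep(p$rate, length(t)),
    gompertz = p$rate * exp(p$shape * t),
    loglogistic = {
      z <- (t / p$scale)^p$shape
      (p$shape / t) * z / (1 + z)
    },
    gengamma = exp(gengamma_logdens(t, p$mu, p$sigma, p$Q) -
                     gengamma_logsurv(t, p$mu, p$sigma, p$Q)),
    bathtub = (p$shape1 / p$scale1) * (t / p$scale1)^(p$shape1 - 1) +
              (p$shape2 / p$scale2) * (t / p$scale2)^(p$shape2 - 1),
    zero = rep(0, length(t)),
    stop("unknown family: ", family)
  )
}

## log survivor function of the generalised gamma (Prentice form)
gengamma_logsurv <- function(t, mu, sigma, Q) {
  w <- (log(t) - mu) / sigma
  if (abs(Q) < 1e-7) return(stats::pnorm(w, lower.tail = FALSE, log.p = TRUE))
  qq <- 1 / (Q * Q)
  u <- qq * exp(Q * w)
  if (Q > 0) {
    stats::pgamma(u, shape = qq, lower.tail = FALSE, log.p = TRUE)
  } else {
    stats::pgamma(u, shape = qq, lower.tail = TRUE, log.p = TRUE)
  }
}

gengamma_logdens <- function(t, mu, sigma, Q) {
  w <- (log(t) - mu) / sigma
  if (abs(Q) < 1e-7) {
    return(stats::dnorm(w, log = TRUE) - log(sigma * t))
  }
  qq <- 1 / (Q * Q)
  log(abs(Q)) - log(sigma * t) + qq * log(qq) + qq * (Q * w - exp(Q * w)) -
    lgamma(qq)
}

## validity check on natural-scale parameters; returns TRUE or a message
family_check_params <- function(family, params) {
  p <- as.list(params)
  pos <- function(x) is.finite(x) && x > 0
  ok <- switch(family,
    weibull = pos(p$shape) && pos(p$scale),
    exponential = is.finite(p$rate) && p$rate >= 0,
    gompertz = is.finite(p$shape) && pos(p$rate),
    loglogistic = pos(p$shape) && pos(p$scale),
    gengamma = is.finite(p$mu) && pos(p$sigma) && is.finite(p$Q),
    bathtub = pos(p$shape1) && p$shape1 < 1 && pos(p$scale1) &&
              is.finite(p$shape2) && p$shape2 > 1 && pos(p$scale2),
    zero = TRUE,
    FALSE
  )
  if (!isTRUE(ok)) {
    return(sprintf("invalid parameters for family '%s': %s", family,
                   paste(names(params), signif(unlist(params), 4),
                         sep = "=", collapse = ", ")))
  }
  TRUE
}

#' Draw event times from a parametric hazard by inversion
#'
#' Solves H(T) = -log(U) for U ~ Uniform(0,1). Closed forms are used where
#' available; otherwise a bracketed root search on the shared cumulative
#' hazard. A `zero` family (or a draw beyond `t_max`) returns `Inf`.
#'
#' @param n number of draws
#' @param family family name (see [families])
#' @param params named numeric vector of natural-scale parameters
#' @param t_max upper bracket for root finding (years)
#' @return numeric vector of event times (possibly `Inf`)
#' @keywords internal
rsurv_family <- function(n, family, params, t_max = 500) {
  msg <- family_check_params(family, params)
  if (!isTRUE(msg)) stop(msg, call. = FALSE)
  if (family == "zero") return(rep(Inf, n))
  u <- stats::runif(n)
  target <- -log(u)
  p <- as.list(params)
  if (family == "weibull") return(p$scale * target^(1 / p$shape))
  if (family == "exponential") {
    if (p$rate == 0) return(rep(Inf, n))
    return(target / p$rate)
  }
  if (family == "gompertz" && p$shape > 0) {
    # H^{-1}(y) = log(1 + a y / r) / a
    return(log1p(p$shape * target / p$rate) / p$shape)
  }
  if (family == "loglogistic") {
    # H = log(1+z) => z = e^y - 1
    return(p$scale * expm1(target)^(1 / p$shape))
  }
  Hmax <- family_cumhaz(family, t_max, params)
  vapply(target, function(y) {
    if (y >= Hmax) return(Inf)
    stats::uniroot(function(t) family_cumhaz(family, t, params) - y,
                   lower = 1e-12, upper = t_max, tol = 1e-10)$root
  }, numeric(1))
}
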