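#' Kaplan-Meier estimate of revision-free survival
#'
#' Product-limit estimator with Greenwood standard errors and log-log 95%
#' confidence intervals, computed via [survival::survfit]. Returned on the
#' package's own contract: one row per distinct event time, ascending.
#'
#' @param times follow-up times (> 0, years)
#' @param events event indicators (1 = revised, 0 = censored)
#' @param conf_level confidence level (default 0.95)
#' @return object of class `km_estimate`: data frame with columns `time`,
#'   `n_risk`, `n_event`, `surv`, `std_err` (Greenwood SE of S), `lower`,
#'   `upper`
#' @examples
#' km <- kaplan_meier(c(1, 2, 3), c(1, 1, 1))
#' km$surv  # 2/3, 1/3, 0
#' @export
kaplan_meier <- function(times, events, conf_level = 0.95) {
  stopifnot(length(times) == length(events))
  if (any(times <= 0)) stop("times must be > 0", call. = FALSE)
  if (!all(events %in% c(0, 1))) stop("events must be 0/1", call. = FALSE)
  if (sum(events) == 0)
    warning("kaplan_meier: no events; survival is identically 1")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1,
                           conf.type = "log-log", conf.int = conf_level)
  keep <- fit$n.event > 0
  out <- data.frame(time = fit$time[keep],
                    n_risk = fit$n.risk[keep],
                    n_event = fit$n.event[keep],
                    surv = fit$surv[keep],
                    std_err = fit$std.err[keep] * fit$surv[keep],
                    lower = ifelse(is.na(fit$lower[keep]), 0, fit$lower[keep]),
                    upper = ifelse(is.na(fit$upper[keep]), 1, fit$upper[keep]))
  rownames(out) <- NULL
  class(out) <- c("km_estimate", "data.frame")
  out
}

#' Evaluate a Kaplan-Meier estimate at given times
#'
#' Step-function evaluation: S(t) is the estimate at the largest event time
#' <= t, and 1 before the first event.
#'
#' @param km a `km_estimate`
#' @param t times at which to evaluate (vectorised)
#' @return numeric vector of survival probabilities
#' @export
km_surv_at <- function(km, t) {
  vapply(t, function(ti) {
    idx <- which(km$time <= ti)
    if (!length(idx)) 1 else km$surv[max(idx)]
  }, numeric(1))
}
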