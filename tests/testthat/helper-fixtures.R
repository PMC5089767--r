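# Shared fixtures: all synthetic, built in code at test time.

# right-censored Weibull sample with administrative censoring U(0, cmax)
sim_weibull_censored <- function(n, shape, scale, cmax, seed) {
  set.seed(seed)
  tt <- scale * (-log(runif(n)))^(1 / shape)
  cc <- runif(n, 0, cmax)
  data.frame(followup_time = pmin(tt, cc),
             revised = as.integer(tt <= cc))
}

# a hand-built converged Weibull fit (for tests that need a fit with an
# exactly known survival curve, without an optimiser in the loop)
fake_weibull_fit <- function(shape, scale) {
  structure(list(family = "weibull", covariates = character(0),
                 centers = numeric(0), n = 1000L, n_events = 100L,
                 log_likelihood = 0, converged = TRUE, vcov = NULL,
                 params = c(shape = shape, scale = scale),
                 beta = stats::setNames(numeric(0), character(0)),
                 theta = c(log(shape), log(scale))),
            class = "hip_survfit")
}

# flat utilities over all ages, one value per state
flat_utilities <- function(sex = "male", u_succ = 0.8, u_rev = 0.5) {
  data.frame(sex = sex, age_lo = 0, age_hi = 200,
             state = c("successful", "revision"),
             utility = c(u_succ, u_rev))
}

base_costs <- c(prosthesis = 2808, surgery = 1738, inpatient = 1628,
                followup_primary = 509, revision_surgery = 16794,
                followup_postrevision = 400)

zero_qx_table <- function(sex = "male") make_life_table(sex, 0, 0, 0)

quick_inputs <- function(p = rep(0, 9), sex = "male", sm = 0, qx_flat = 0,
                         costs = base_costs, u_succ = 0.8, u_rev = 0.5,
                         rr = 0.0518, rate = 0.035, ...) {
  lt <- if (qx_flat == 0) zero_qx_table(sex) else {
    out <- make_life_table(sex, -log(1 - qx_flat), 0, 0)
    out$qx <- qx_flat
    out
  }
  model_inputs("test", revision_schedule(p), lt,
               flat_utilities(sex, u_succ, u_rev), costs,
               surgical_mortality = sm, rerevision_prob = rr,
               discount_rate = rate, ...)
}

# independent brute-force oracle for the cohort model: enumerate every state
# path over n_cycles annual cycles, accruing per the package's stated
# conventions, written without reference to run_cohort's internals
enumerate_cohort <- function(p, qx, sm, rr, costs, u_succ, u_rev, rate,
                             n_cycles) {
  acc <- new.env()
  acc$cost <- 0; acc$qaly <- 0
  acc$occ <- matrix(0, n_cycles, 4,
                    dimnames = list(NULL, c("S", "R", "V", "D")))
  dfac <- function(t) 1 / (1 + rate)^t
  fu_p <- costs[["followup_primary"]]; fu_v <- costs[["followup_postrevision"]]
  c_rev <- costs[["revision_surgery"]]

  recurse <- function(state, t, prob) {
    if (prob == 0) return()
    acc$occ[t + 1, state] <- acc$occ[t + 1, state] + prob
    if (t == n_cycles - 1) return()
    tn <- t + 1
    if (state == "D") {
      recurse("D", tn, prob)
    } else if (state == "S") {
      pt <- p[tn]
      recurse("D", tn, prob * qx)                                  # bg death
      branch_rev <- prob * (1 - qx) * pt
      acc$cost <- acc$cost + branch_rev * c_rev * dfac(tn)         # op cost
      recurse("D", tn, branch_rev * sm)                            # op death
      acc$qaly <- acc$qaly + branch_rev * (1 - sm) * u_rev * dfac(tn)
      recurse("R", tn, branch_rev * (1 - sm))
      stay <- prob * (1 - qx) * (1 - pt)
      acc$cost <- acc$cost + stay * fu_p * dfac(tn)
      acc$qaly <- acc$qaly + stay * u_succ * dfac(tn)
      recurse("S", tn, stay)
    } else {                                  # R graduates to V, V recycles
      recurse("D", tn, prob * qx)
      branch_rev <- prob * (1 - qx) * rr
      acc$cost <- acc$cost + branch_rev * c_rev * dfac(tn)
      recurse("D", tn, branch_rev * sm)
      acc$qaly <- acc$qaly + branch_rev * (1 - sm) * u_rev * dfac(tn)
      recurse("R", tn, branch_rev * (1 - sm))
      stay <- prob * (1 - qx) * (1 - rr)
      acc$cost <- acc$cost + stay * fu_v * dfac(tn)
      acc$qaly <- acc$qaly + stay * u_succ * dfac(tn)
      recurse("V", tn, stay)
    }
  }

  # cycle 0: operation cost for all, utility for survivors, undiscounted
  acc$cost <- costs[["prosthesis"]] + costs[["surgery"]] + costs[["inpatient"]]
  acc$qaly <- (1 - sm) * u_succ
  recurse("D", 0, sm)        # operative deaths at cycle 0 stay dead
  recurse("S", 0, 1 - sm)    # survivors sit in successful-primary
  list(cost = acc$cost, qaly = acc$qaly, occ = acc$occ)
}
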