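#' Assemble cohort-model inputs for one strategy
#'
#' Bundles everything one strategy (e.g. resurfacing with a given device, or
#' a THR bearing category) needs: the annual revision schedule from its
#' fitted survival model, background mortality, state utilities, costs in
#' 2014 GBP, and the economic settings. Utilities are age-banded (40-50,
#' 50-60, 60-70); ages outside that range use the nearest band.
#'
#' @param strategy strategy label
#' @param revision_schedule a `revision_schedule` covering the horizon
#' @param life_table a `life_table` data frame (see [make_life_table()])
#' @param utilities data frame with columns `sex`, `age_lo`, `age_hi`,
#'   `state` (`"successful"` or `"revision"`), `utility`
#' @param costs named list/vector: `prosthesis`, `surgery`, `inpatient`,
#'   `followup_primary`, `revision_surgery`, `followup_postrevision` (GBP)
#' @param surgical_mortality per-operation death probability (default 0.0050)
#' @param rerevision_prob annual re-revision probability (default 0.0518)
#' @param discount_rate annual discount rate for costs and QALYs (default
#'   0.035)
#' @param half_cycle apply a half-cycle correction to accruals (default FALSE)
#' @param utility_bonus optional per-cycle utility increments for alive
#'   states, cycle 0 first (scenario analyses, e.g. a transient
#'   quality-of-life advantage in the first two post-surgery years); cycles
#'   beyond the vector's length get no increment
#' @return a `model_inputs` list
#' @export
model_inputs <- function(strategy, revision_schedule, life_table, utilities,
                         costs, surgical_mortality = 0.0050,
                         rerevision_prob = 0.0518, discount_rate = 0.035,
                         half_cycle = FALSE, utility_bonus = numeric(0)) {
  costs <- as.list(costs)
  need <- c("prosthesis", "surgery", "inpatient", "followup_primary",
            "revision_surgery", "followup_postrevision")
  missing_cost <- setdiff(need, names(costs))
  if (length(missing_cost))
    stop("costs missing: ", paste(missing_cost, collapse = ", "),
         call. = FALSE)
  stopifnot(all(unlist(costs[need]) >= 0),
            surgical_mortality >= 0, surgical_mortality <= 1,
            rerevision_prob >= 0, rerevision_prob <= 1,
            discount_rate >= 0,
            all(utilities$utility >= 0 & utilities$utility <= 1))
  structure(list(strategy = strategy,
                 revision_schedule = revision_schedule,
                 life_table = life_table,
                 utilities = utilities,
                 costs = costs[need],
                 surgical_mortality = surgical_mortality,
                 rerevision_prob = rerevision_prob,
                 discount_rate = discount_rate,
                 half_cycle = half_cycle,
                 utility_bonus = utility_bonus),
            class = "model_inputs")
}

#' Discount factor for an annual cycle
#'
#' @param cycle cycle index (0-based integer, vectorised)
#' @param rate annual discount rate
#' @return 1 / (1 + rate)^cycle
#' @export
discount_factor <- function(cycle, rate) {
  stopifnot(all(cycle >= 0), all(cycle == round(cycle)), rate >= 0)
  1 / (1 + rate)^cycle
}

# vectorised over age; boundary bands carried outward for uncovered ages
utility_by_age <- function(utilities, sex, ages, state) {
  keep <- utilities$sex == sex & utilities$state == state
  if (!any(keep)) stop("no utility rows for sex=", sex, " state=", state,
                       call. = FALSE)
  lo <- utilities$age_lo[keep]; hi <- utilities$age_hi[keep]
  u <- utilities$utility[keep]
  ord <- order(lo); lo <- lo[ord]; hi <- hi[ord]; u <- u[ord]
  idx <- findInterval(ages, lo)        # 0 = below the youngest band
  idx[idx == 0L] <- 1L
  out <- u[idx]
  above <- ages >= hi[length(hi)]      # beyond the oldest band
  out[above] <- u[length(u)]
  out
}

lookup_utility <- function(utilities, sex, age, state) {
  utility_by_age(utilities, sex, age, state)[1]
}

#' Run the four-state semi-Markov cohort model for one strategy
#'
#' States: successful primary, revision surgery (occupied for exactly one
#' annual cycle), successful revision, dead. Cycle 0 is the primary operation:
#' the whole cohort incurs prosthesis + surgery + inpatient costs, operative
#' mortality applies, and survivors spend the year in the successful-primary
#' state. From cycle 1 on, background mortality acts at the current cohort
#' age, the fitted schedule moves patients to revision surgery (operative
#' mortality applies again on entry and at each re-revision), and revised
#' patients face a constant annual re-revision risk thereafter. Operation
#' costs fall on everyone undergoing the operation (including operative
#' deaths); follow-up costs and utilities accrue only to patients alive
#' through the cycle. Accruals at cycle 0 are undiscounted.
#'
#' @param inputs a [model_inputs()]
#' @param start_age cohort age at primary surgery (years)
#' @param sex `"male"` or `"female"`
#' @param horizon `"lifetime"` (cycles to age 100) or an integer number of
#'   years
#' @return a `strategy_result`: list with `strategy`, `horizon`, `cost`
#'   (total mean discounted cost), `qaly`, and `trace` (per-cycle data frame)
#' @examples
#' lt <- make_life_table("male", 0, 0, 0)  # immortal test cohort
#' u <- data.frame(sex = "male", age_lo = 0, age_hi = 200,
#'                 state = c("successful", "revision"), utility = c(0.8, 0.5))
#' inp <- model_inputs("demo", revision_schedule(rep(0, 9)), lt, u,
#'                     c(prosthesis = 2808, surgery = 1738, inpatient = 1628,
#'                       followup_primary = 509, revision_surgery = 16794,
#'                       followup_postrevision = 400),
#'                     surgical_mortality = 0)
#' run_cohort(inp, 50, "male", horizon = 10)$qaly
#' @export
run_cohort <- function(inputs, start_age, sex, horizon = "lifetime") {
  stopifnot(inherits(inputs, "model_inputs"))
  n_cycles <- if (identical(horizon, "lifetime")) {
    101L - as.integer(start_age)   # cycles 0..(100 - start_age)
  } else {
    as.integer(horizon)
  }
  stopifnot(n_cycles >= 1)
  p <- as.numeric(inputs$revision_schedule)
  if (length(p) < n_cycles - 1)
    stop(sprintf("revision schedule covers %d cycles; horizon needs %d",
                 length(p), n_cycles - 1), call. = FALSE)
  sm <- inputs$surgical_mortality
  rr <- inputs$rerevision_prob
  cst <- inputs$costs
  r <- inputs$discount_rate
  hc <- if (isTRUE(inputs$half_cycle)) 0.5 else 1

  tr <- matrix(0, n_cycles, 8,
               dimnames = list(NULL, c("succ_primary", "revision",
                                       "succ_revision", "dead", "cost_inc",
                                       "qaly_inc", "disc_cost_inc",
                                       "disc_qaly_inc")))

  ub <- inputs$utility_bonus
  bonus <- function(t) if (t < length(ub)) ub[t + 1] else 0

  # precompute age-indexed quantities for the whole horizon
  ages <- start_age + 0:(n_cycles - 1)
  qx_vec <- lookup_qx(inputs$life_table, sex, ages)
  u_succ_vec <- utility_by_age(inputs$utilities, sex, ages, "successful")
  u_rev_vec <- utility_by_age(inputs$utilities, sex, ages, "revision")
  df_vec <- discount_factor(0:(n_cycles - 1), r)

  # cycle 0: primary operation
  sp <- 1 - sm; rv <- 0; sr <- 0; dead <- sm
  cost0 <- cst$prosthesis + cst$surgery + cst$inpatient   # paid by all
  qaly0 <- sp * (u_succ_vec[1] + bonus(0)) * hc
  tr[1, ] <- c(sp, rv, sr, dead, cost0, qaly0, cost0, qaly0)

  for (t in seq_len(n_cycles - 1)) {
    qx <- qx_vec[t + 1]
    pt <- p[t]

    # successful primary: background death, then revision among survivors
    sp_die <- sp * qx
    sp_alive <- sp - sp_die
    to_rv1 <- sp_alive * pt
    sp_new <- sp_alive - to_rv1

    # last cycle's revision patients graduate to successful revision,
    # then the pooled successful-revision state transitions
    sr_pool <- sr + rv
    sr_die <- sr_pool * qx
    sr_alive <- sr_pool - sr_die
    to_rv2 <- sr_alive * rr
    sr_new <- sr_alive - to_rv2

    ops <- to_rv1 + to_rv2                  # undergo revision this cycle
    op_die <- ops * sm
    rv_new <- ops - op_die
    dead <- dead + sp_die + sr_die + op_die

    sp <- sp_new; rv <- rv_new; sr <- sr_new

    u_succ <- u_succ_vec[t + 1]
    u_rev <- u_rev_vec[t + 1]
    cost_inc <- ops * cst$revision_surgery +
      (sp * cst$followup_primary + sr * cst$followup_postrevision) * hc
    qaly_inc <- (sp * (u_succ + bonus(t)) + rv * (u_rev + bonus(t)) +
                   sr * (u_succ + bonus(t))) * hc
    df <- df_vec[t + 1]
    tr[t + 1, ] <- c(sp, rv, sr, dead, cost_inc, qaly_inc,
                     cost_inc * df, qaly_inc * df)
  }
  trace <- data.frame(cycle = 0:(n_cycles - 1), age = ages, tr)

  structure(list(strategy = inputs$strategy,
                 horizon = if (identical(horizon, "lifetime")) "lifetime"
                           else n_cycles,
                 start_age = start_age, sex = sex,
                 cost = sum(trace$disc_cost_inc),
                 qaly = sum(trace$disc_qaly_inc),
                 trace = trace),
            class = "strategy_result")
}

#' @export
print.strategy_result <- function(x, ...) {
  cat(sprintf("%s | start age %s (%s), horizon %s: cost £%s, QALYs %.4f\n",
              x$strategy, x$start_age, x$sex, x$horizon,
              format(round(x$cost), big.mark = ","), x$qaly))
  invisible(x)
}

#' Compare two strategy results
#'
#' Incremental cost and QALYs of strategy `a` over `b`, the ICER where it is
#' defined, a dominance classification, and net monetary benefit at the
#' willingness-to-pay threshold.
#'
#' @param a,b `strategy_result` objects with matching horizon, age and sex
#' @param wtp willingness to pay per QALY (default 20000 GBP)
#' @return a `strategy_comparison` list: `delta_cost`, `delta_qaly`, `icer`
#'   (NA when undefined or under dominance), `classification` (one of
#'   `"dominant"`, `"dominated"`, `"icer"`, `"cost_saving"`, `"undefined"`),
#'   `nmb`
#' @export
compare_strategies <- function(a, b, wtp = 20000) {
  stopifnot(inherits(a, "strategy_result"), inherits(b, "strategy_result"))
  if (!identical(a$horizon, b$horizon) || a$start_age != b$start_age ||
      a$sex != b$sex)
    stop("strategies must share horizon, start age and sex", call. = FALSE)
  dc <- a$cost - b$cost
  dq <- a$qaly - b$qaly
  icer <- NA_real_
  classification <- if (dq > 0 && dc < 0) {
    "dominant"
  } else if (dq < 0 && dc > 0) {
    "dominated"
  } else if (dq == 0) {
    "undefined"
  } else if (dq > 0 && dc > 0) {
    icer <- dc / dq
    "icer"
  } else {
    # dq < 0, dc < 0: cost saving per QALY forgone
    icer <- dc / dq
    "cost_saving"
  }
  structure(list(strategy_a = a$strategy, strategy_b = b$strategy,
                 horizon = a$horizon, start_age = a$start_age, sex = a$sex,
                 delta_cost = dc, delta_qaly = dq, icer = icer,
                 classification = classification,
                 wtp = wtp, nmb = wtp * dq - dc),
            class = "strategy_comparison")
}

#' @export
print.strategy_comparison <- function(x, ...) {
  icer_txt <- switch(x$classification,
    dominated = "Dominated",
    dominant = "Dominant",
    undefined = "undefined (ΔQALY = 0)",
    sprintf("£%s/QALY", format(round(x$icer), big.mark = ",")))
  cat(sprintf("%s vs %s (age %s, %s, horizon %s):\n", x$strategy_a,
              x$strategy_b, x$start_age, x$sex, x$horizon))
  cat(sprintf("  Δcost £%s, ΔQALY %.4f, ICER %s, NMB@£%s %.0f\n",
              format(round(x$delta_cost), big.mark = ","), x$delta_qaly,
              icer_txt, format(x$wtp, big.mark = ","), x$nmb))
  invisible(x)
}

#' Export a cohort trace as CSV
#' @param result a `strategy_result`
#' @param path file path
#' @export
write_trace <- function(result, path) {
  utils::write.csv(result$trace, path, row.names = FALSE)
  invisible(path)
}
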