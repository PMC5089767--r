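test_that("discount factors follow 1/(1+r)^t", {
  expect_equal(discount_factor(0, 0.035), 1)
  expect_equal(discount_factor(2, 0.035), 1 / 1.035^2, tolerance = 1e-12)
  expect_equal(discount_factor(0:5, 0), rep(1, 6))
  expect_error(discount_factor(-1, 0.035))
  expect_error(discount_factor(1.5, 0.035))
})

test_that("zero-hazard cohort QALYs equal the discounted annuity", {
  u <- 0.8
  inp <- quick_inputs(p = rep(0, 9), u_succ = u, sm = 0)
  res <- run_cohort(inp, 50, "male", horizon = 10)
  expect_equal(res$qaly, u * sum(1 / 1.035^(0:9)), tolerance = 1e-10)
  # costs: primary procedure at cycle 0 plus discounted follow-up from cycle 1
  expect_equal(res$cost,
               sum(base_costs[c("prosthesis", "surgery", "inpatient")]) +
                 base_costs[["followup_primary"]] * sum(1 / 1.035^(1:9)),
               tolerance = 1e-9)
})

test_that("trace matches exhaustive path enumeration over 3 cycles", {
  p <- c(0.15, 0.25); qx <- 0.07; sm <- 0.04; rr <- 0.30; rate <- 0.035
  inp <- quick_inputs(p = p, sm = sm, qx_flat = qx, rr = rr, rate = rate,
                      u_succ = 0.77, u_rev = 0.51)
  res <- run_cohort(inp, 50, "male", horizon = 3)
  oracle <- enumerate_cohort(p, qx, sm, rr, base_costs, 0.77, 0.51, rate, 3)
  expect_equal(res$cost, oracle$cost, tolerance = 1e-12)
  expect_equal(res$qaly, oracle$qaly, tolerance = 1e-12)
  expect_equal(res$trace$succ_primary, unname(oracle$occ[, "S"]),
               tolerance = 1e-12)
  expect_equal(res$trace$revision, unname(oracle$occ[, "R"]),
               tolerance = 1e-12)
  expect_equal(res$trace$succ_revision, unname(oracle$occ[, "V"]),
               tolerance = 1e-12)
  expect_equal(res$trace$dead, unname(oracle$occ[, "D"]), tolerance = 1e-12)
})

test_that("path enumeration agrees across 4 cycles and parameter corners", {
  grid <- list(
    list(p = c(0, 0.5, 1), qx = 0, sm = 0, rr = 0),
    list(p = c(0.3, 0.3, 0.3), qx = 0.2, sm = 0.1, rr = 0.6),
    list(p = c(1, 0, 0.4), qx = 0.05, sm = 0.5, rr = 1)
  )
  for (g in grid) {
    inp <- quick_inputs(p = g$p, sm = g$sm, qx_flat = g$qx, rr = g$rr,
                        rate = 0.02, u_succ = 0.9, u_rev = 0.4)
    res <- run_cohort(inp, 60, "male", horizon = 4)
    oracle <- enumerate_cohort(g$p, g$qx, g$sm, g$rr, base_costs, 0.9, 0.4,
                               0.02, 4)
    expect_equal(res$cost, oracle$cost, tolerance = 1e-12)
    expect_equal(res$qaly, oracle$qaly, tolerance = 1e-12)
  }
})

test_that("total surgical mortality kills the cohort at cycle 0", {
  inp <- quick_inputs(p = rep(0.1, 9), sm = 1, qx_flat = 0.01)
  res <- run_cohort(inp, 50, "male", horizon = 10)
  expect_equal(res$qaly, 0)
  expect_equal(res$cost,
               sum(base_costs[c("prosthesis", "surgery", "inpatient")]))
  expect_equal(res$trace$dead[1], 1)
})

test_that("occupancies conserve mass and death is absorbing", {
  inp <- quick_inputs(p = rep(0.05, 60), sm = 0.005, qx_flat = 0.02)
  res <- run_cohort(inp, 40, "male", "lifetime")
  occ <- res$trace[, c("succ_primary", "revision", "succ_revision", "dead")]
  expect_true(all(abs(rowSums(occ) - 1) < 1e-10))
  expect_true(all(diff(res$trace$dead) >= -1e-14))
  expect_true(all(res$trace$disc_cost_inc <= res$trace$cost_inc + 1e-12))
  expect_true(all(res$trace$disc_qaly_inc <= res$trace$qaly_inc + 1e-12))
  # lifetime horizon reaches age 100 exactly
  expect_equal(res$trace$age[nrow(res$trace)], 100)
  # totals equal trace sums
  expect_equal(res$cost, sum(res$trace$disc_cost_inc), tolerance = 1e-9)
  expect_equal(res$qaly, sum(res$trace$disc_qaly_inc), tolerance = 1e-9)
})

test_that("discounting lowers totals; higher revision risk worsens both", {
  mk <- function(rate, pmult) {
    inp <- quick_inputs(p = rep(0.03, 60) * pmult, sm = 0.005,
                        qx_flat = 0.015, rate = rate)
    run_cohort(inp, 50, "male", "lifetime")
  }
  r0 <- mk(0, 1); r35 <- mk(0.035, 1)
  expect_gt(r0$cost, r35$cost)
  expect_gt(r0$qaly, r35$qaly)
  lo <- mk(0.035, 1); hi <- mk(0.035, 2)
  expect_gt(hi$cost, lo$cost)
  expect_lt(hi$qaly, lo$qaly)
  # QALYs bounded by horizon length
  expect_lt(r0$qaly, 61)
})

test_that("utility age bands carry outward and switch at band edges", {
  ut <- data.frame(sex = "male",
                   age_lo = c(40, 50, 60, 0),
                   age_hi = c(50, 60, 70, 200),
                   state = c(rep("successful", 3), "revision"),
                   utility = c(0.736, 0.767, 0.762, 0.575))
  inp <- model_inputs("t", revision_schedule(rep(0, 40)), zero_qx_table(),
                      ut, base_costs, surgical_mortality = 0,
                      discount_rate = 0)
  res <- run_cohort(inp, 35, "male", horizon = 40)
  q <- res$trace$qaly_inc
  expect_equal(q[1], 0.736)            # age 35 -> youngest band carried down
  expect_equal(q[res$trace$age == 55], 0.767)
  expect_equal(q[res$trace$age == 60], 0.762)   # band edge: [60, 70)
  expect_equal(q[res$trace$age == 74], 0.762)   # oldest band carried up
})

test_that("the Edlin-style utility bonus applies to the first cycles only", {
  base <- quick_inputs(p = rep(0, 9), sm = 0, rate = 0)
  plus <- quick_inputs(p = rep(0, 9), sm = 0, rate = 0,
                       utility_bonus = c(0.1, 0.1))
  d <- run_cohort(plus, 50, "male", 10)$qaly -
    run_cohort(base, 50, "male", 10)$qaly
  expect_equal(d, 0.2, tolerance = 1e-12)
})

test_that("strategy comparisons classify dominance and ICERs", {
  mk <- function(cost, qaly) {
    structure(list(strategy = "x", horizon = 10, start_age = 40,
                   sex = "male", cost = cost, qaly = qaly),
              class = "strategy_result")
  }
  # printed-table arithmetic: 12,211 vs 10,348 gives 1,863 incremental
  cmp <- compare_strategies(mk(12211, 7.326), mk(10348, 7.321))
  expect_equal(cmp$delta_cost, 1863)
  expect_equal(cmp$classification, "icer")
  # more cost, fewer QALYs: dominated
  cmp2 <- compare_strategies(mk(16421, 12.109), mk(13130, 12.110))
  expect_equal(cmp2$delta_cost, 3291)
  expect_equal(cmp2$classification, "dominated")
  expect_true(is.na(cmp2$icer))
  # identical: undefined, never infinite
  cmp3 <- compare_strategies(mk(100, 1), mk(100, 1))
  expect_equal(cmp3$classification, "undefined")
  expect_true(is.na(cmp3$icer))
  # dominant quadrant and NMB
  cmp4 <- compare_strategies(mk(90, 2), mk(100, 1), wtp = 20000)
  expect_equal(cmp4$classification, "dominant")
  expect_equal(cmp4$nmb, 20000 * 1 + 10)
  expect_error(compare_strategies(mk(1, 1),
                                  structure(list(strategy = "y",
                                                 horizon = 5,
                                                 start_age = 40,
                                                 sex = "male", cost = 1,
                                                 qaly = 1),
                                            class = "strategy_result")),
               "share")
})

test_that("schedule shorter than the horizon is refused", {
  inp <- quick_inputs(p = rep(0.01, 5))
  expect_error(run_cohort(inp, 50, "male", horizon = 10), "schedule")
})
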