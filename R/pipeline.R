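#' End-to-end run configuration
#'
#' Collects everything a full analysis run needs: registry source, inclusion
#' filters, survival model choice, the two strategies to compare, start ages,
#' horizons, and PSA settings. Defaults encode the base case: the
#' within-benchmark resurfacing pool of the most used RS device versus the
#' most used cemented metal-on-polyethylene THR (CeMoP), men, ages 40/50/60,
#' 10-year and lifetime horizons.
#'
#' @param registry either a registry data frame, a CSV path, or a
#'   [cohort_spec()] to simulate from
#' @param model_config a `model_config` (default: packaged base case)
#' @param allowed_asa,excluded_manufacturers inclusion filters
#' @param family survival family for the arm-level fits
#'   (`"royston_parmar"` or a parametric family name)
#' @param df spline degrees of freedom when `family = "royston_parmar"`
#' @param strategy_a RS arm: list with `manufacturer` (RS device pool) and
#'   `cost_set` (default `"RS"`)
#' @param strategy_b THR arm: list with `thr_category` and matching
#'   `cost_set`
#' @param start_ages cohort start ages (default 40, 50, 60)
#' @param sex cohort sex (default `"male"`)
#' @param horizons subset of `c("10y", "lifetime")`
#' @param psa_n,psa_seed PSA iterations and seed (`psa_n = 0` skips PSA)
#' @param benchmark_threshold revision benchmark (default 0.05 at 10 years)
#' @param edlin_qaly_gain optional per-year RS utility advantage applied for
#'   the first two post-surgery years (scenario analysis)
#' @param seed seed for any simulation steps
#' @return a `run_config` list
#' @export
run_config <- function(registry = cohort_spec(n_patients = 20000),
                       model_config = load_model_config(),
                       allowed_asa = c(1, 2),
                       excluded_manufacturers = "DePuy",
                       family = "royston_parmar", df = 3,
                       strategy_a = list(manufacturer = "BirminghamHip",
                                         cost_set = "RS"),
                       strategy_b = list(thr_category = "CeMoP",
                                         cost_set = "CeMoP"),
                       start_ages = c(40, 50, 60),
                       sex = "male",
                       horizons = c("10y", "lifetime"),
                       psa_n = 1000, psa_seed = 1L,
                       benchmark_threshold = 0.05,
                       edlin_qaly_gain = NULL,
                       seed = 1L) {
  structure(as.list(environment()), class = "run_config")
}

resolve_registry <- function(cfg) {
  reg <- cfg$registry
  if (inherits(reg, "cohort_spec")) return(generate_registry(reg))
  if (is.character(reg)) {
    if (!file.exists(reg)) stop("registry file not found: ", reg,
                                call. = FALSE)
    return(read_registry(reg))
  }
  stopifnot(is.data.frame(reg))
  reg
}

fit_arm <- function(records, family, df) {
  if (family == "royston_parmar") {
    fit_royston_parmar(records, df = df)
  } else {
    fit_parametric(records, family)
  }
}

#' Run the full analysis pipeline
#'
#' Stages: load/simulate the registry; apply inclusion filters; classify RS
#' subgroups against the revision benchmark and pool the within-benchmark
#' records of the chosen RS device; fit the survival model per arm; run the
#' cohort model per start age and horizon; compare strategies; run the PSA on
#' the lifetime horizon; optionally write all artifacts (CSV tables, fit
#' JSON, CEAC data, a manifest) to `out_dir`.
#'
#' @param config a [run_config()]
#' @param out_dir optional directory for artifacts
#' @return a `pipeline_result`: list with `results` (one row per age x
#'   horizon: totals, incrementals, ICER/dominance, probability
#'   cost-effective), `decisions`, `fits`, `psa` (per start age), `counts`
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  cfg <- config$model_config
  stage <- "registry"
  res <- tryCatch({
    registry <- resolve_registry(config)
    n0 <- nrow(registry)

    stage <- "filter"
    filtered <- filter_registry(registry,
                                allowed_asa = config$allowed_asa,
                                excluded_manufacturers =
                                  config$excluded_manufacturers)

    stage <- "benchmark"
    rs <- filtered[filtered$device_class == "RS", ]
    decisions <- benchmark_registry(rs,
                                    threshold = config$benchmark_threshold)
    pools <- dichotomize(rs, decisions)
    pool_a <- pools$within[pools$within$manufacturer ==
                             config$strategy_a$manufacturer &
                             pools$within$sex == config$sex, ]
    if (nrow(pool_a) < 50)
      stop("within-benchmark pool for ", config$strategy_a$manufacturer,
           " has only ", nrow(pool_a), " records", call. = FALSE)
    thr <- filtered[filtered$device_class == "THR" &
                      filtered$thr_category == config$strategy_b$thr_category &
                      filtered$sex == config$sex, ]

    stage <- "fit"
    fit_a <- fit_arm(pool_a, config$family, config$df)
    fit_b <- fit_arm(thr, config$family, config$df)

    stage <- "cohort"
    lt <- default_life_tables()
    bonus_a <- if (!is.null(config$edlin_qaly_gain)) {
      rep(config$edlin_qaly_gain, 2)
    } else numeric(0)
    rows <- list(); psa_out <- list()
    for (age in config$start_ages) {
      max_cycles <- 101 - age
      sched_a <- annual_transition_probs(fit_a, horizon = max_cycles)
      sched_b <- annual_transition_probs(fit_b, horizon = max_cycles)
      in_a <- build_strategy_inputs(cfg, config$strategy_a$cost_set, sched_a,
                                    lt, utility_bonus = bonus_a)
      in_a$strategy <- paste0(config$strategy_a$manufacturer, "_within")
      in_b <- build_strategy_inputs(cfg, config$strategy_b$cost_set, sched_b,
                                    lt)
      for (hz in config$horizons) {
        horizon <- if (hz == "lifetime") "lifetime" else 10
        ra <- run_cohort(in_a, age, config$sex, horizon)
        rb <- run_cohort(in_b, age, config$sex, horizon)
        cmp <- compare_strategies(ra, rb, wtp = cfg$wtp)
        rows[[length(rows) + 1L]] <- data.frame(
          age = age, horizon = hz, sex = config$sex,
          strategy_a = ra$strategy, strategy_b = rb$strategy,
          cost_a = ra$cost, cost_b = rb$cost,
          qaly_a = ra$qaly, qaly_b = rb$qaly,
          delta_cost = cmp$delta_cost, delta_qaly = cmp$delta_qaly,
          icer = cmp$icer, classification = cmp$classification,
          prob_ce = NA_real_)
      }
      if (config$psa_n > 0) {
        stage <- "psa"
        psa <- run_psa(in_a, in_b,
                       config_psa_specs(cfg, config$strategy_a$cost_set),
                       config_psa_specs(cfg, config$strategy_b$cost_set),
                       start_age = age, sex = config$sex,
                       horizon = "lifetime", n = config$psa_n,
                       seed = config$psa_seed + age, wtp = cfg$wtp)
        psa_out[[as.character(age)]] <- psa
        for (k in seq_along(rows)) {
          if (rows[[k]]$age == age && rows[[k]]$horizon == "lifetime")
            rows[[k]]$prob_ce <- psa$prob_ce_at_wtp
        }
      }
    }
    results <- do.call(rbind, rows)
    list(results = results, decisions = decisions, pools = pools$summary,
         fits = list(a = fit_a, b = fit_b), psa = psa_out,
         counts = c(total = n0, filtered = nrow(filtered),
                    rs = nrow(rs), pool_a = nrow(pool_a), thr = nrow(thr)))
  }, error = function(e) {
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  class(res) <- "pipeline_result"

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(res$results, file.path(out_dir, "results.csv"),
                     row.names = FALSE)
    write_decisions(res$decisions, file.path(out_dir, "decisions.csv"))
    fit_to_json(res$fits$a, file.path(out_dir, "fit_a.json"))
    fit_to_json(res$fits$b, file.path(out_dir, "fit_b.json"))
    for (age in names(res$psa)) {
      write_ceac(res$psa[[age]],
                 file.path(out_dir, sprintf("ceac_age%s.csv", age)))
      write_psa_scatter(res$psa[[age]],
                        file.path(out_dir, sprintf("psa_age%s.csv", age)))
    }
    manifest <- list(package_version =
                       as.character(utils::packageVersion("hipcea")),
                     seed = config$seed, psa_seed = config$psa_seed,
                     family = config$family, df = config$df,
                     counts = as.list(res$counts),
                     timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  res
}

#' Render results in the two-strategy summary-table layout
#'
#' Costs to whole pounds with thousands separators, QALYs to 3-4 decimal
#' places, ICER to whole pounds or a dominance label. Missing cells render as
#' "-" with a warning.
#'
#' @param results the `results` data frame of a `pipeline_result` (or the
#'   object itself)
#' @return a character data frame, one row per quantity, one column pair per
#'   age
#' @export
render_table2 <- function(results) {
  if (inherits(results, "pipeline_result")) results <- results$results
  if (is.null(results) || !nrow(results)) {
    warning("render_table2: empty results")
    return(data.frame())
  }
  fmt_cost <- function(x) ifelse(is.na(x), "-",
                                 format(round(x), big.mark = ",",
                                        trim = TRUE))
  fmt_q <- function(x) ifelse(is.na(x), "-", sprintf("%.4f", x))
  fmt_icer <- function(icer, cls) {
    ifelse(cls == "dominated", "Dominated",
    ifelse(cls == "dominant", "Dominant",
    ifelse(is.na(icer), "-", fmt_cost(icer))))
  }
  out <- list()
  for (hz in unique(results$horizon)) {
    sub <- results[results$horizon == hz, ]
    sub <- sub[order(sub$age), ]
    lab <- if (hz == "lifetime") "Lifetime horizon" else "10-year horizon"
    block <- data.frame(
      quantity = c(paste0("-- ", lab, " --"),
                   paste("Total mean costs £ (", sub$strategy_a[1], ")"),
                   paste("Total mean costs £ (", sub$strategy_b[1], ")"),
                   paste("Total mean QALYs (", sub$strategy_a[1], ")"),
                   paste("Total mean QALYs (", sub$strategy_b[1], ")"),
                   "Incremental cost £", "Incremental QALYs",
                   "ICER (£/QALY)", "P(cost-effective at WTP)"),
      stringsAsFactors = FALSE)
    for (i in seq_len(nrow(sub))) {
      block[[paste0("age_", sub$age[i])]] <-
        c("", fmt_cost(sub$cost_a[i]), fmt_cost(sub$cost_b[i]),
          fmt_q(sub$qaly_a[i]), fmt_q(sub$qaly_b[i]),
          fmt_cost(sub$delta_cost[i]), fmt_q(sub$delta_qaly[i]),
          fmt_icer(sub$icer[i], sub$classification[i]),
          fmt_q(sub$prob_ce[i]))
    }
    out[[hz]] <- block
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  if (any(res == "-")) warning("render_table2: missing cells rendered as '-'")
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Pipeline run:", paste(names(x$counts), x$counts, sep = "=",
                             collapse = ", "), "\n")
  print(render_table2(x$results), right = FALSE)
  invisible(x)
}
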