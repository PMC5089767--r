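#' Uncertainty distribution specifications
#'
#' A `dist_spec` describes one uncertain model input: `beta(alpha, beta)` for
#' probabilities and utilities, `gamma(shape, scale)` for costs, or
#' `fixed(value)` for inputs sampled degenerately. The printed mean/SE a spec
#' was derived from may be attached for reporting.
#'
#' @param alpha,beta Beta parameters (> 0)
#' @param shape,scale Gamma parameters (> 0)
#' @param value fixed value
#' @param mean,se source moments as printed (optional metadata)
#' @return a `dist_spec`
#' @export
dist_beta <- function(alpha, beta, mean = NULL, se = NULL) {
  if (alpha <= 0 || beta <= 0)
    stop("beta parameters must be positive", call. = FALSE)
  structure(list(kind = "beta", alpha = alpha, beta = beta,
                 mean = mean %||% (alpha / (alpha + beta)), se = se),
            class = "dist_spec")
}

#' @rdname dist_beta
#' @export
dist_gamma <- function(shape, scale, mean = NULL, se = NULL) {
  if (shape <= 0 || scale <= 0)
    stop("gamma parameters must be positive", call. = FALSE)
  structure(list(kind = "gamma", shape = shape, scale = scale,
                 mean = mean %||% (shape * scale), se = se),
            class = "dist_spec")
}

#' @rdname dist_beta
#' @export
dist_fixed <- function(value) {
  structure(list(kind = "fixed", value = value, mean = value, se = 0),
            class = "dist_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Mean of a Beta distribution
#' @param alpha,beta Beta parameters (> 0)
#' @return alpha / (alpha + beta)
#' @export
beta_mean <- function(alpha, beta) {
  if (any(alpha <= 0) || any(beta <= 0))
    stop("beta parameters must be positive", call. = FALSE)
  alpha / (alpha + beta)
}

#' Method-of-moments Beta parameters
#'
#' nu = mean(1 - mean)/se^2 - 1; alpha = mean nu, beta = (1 - mean) nu.
#' Rejected when the SE is too large for a Beta (se^2 >= mean(1-mean)) or so
#' small that nu exceeds `nu_cap` (a near-degenerate distribution; use
#' [dist_fixed()] instead).
#'
#' @param mean mean in (0, 1)
#' @param se standard error (> 0)
#' @param nu_cap upper bound on alpha + beta (default 1e8)
#' @return named vector `c(alpha, beta)`
#' @export
beta_from_moments <- function(mean, se, nu_cap = 1e8) {
  if (mean <= 0 || mean >= 1) stop("mean must lie in (0, 1)", call. = FALSE)
  if (se <= 0) stop("se must be > 0", call. = FALSE)
  if (se^2 >= mean * (1 - mean))
    stop(sprintf("se too large for a Beta: need se^2 < mean(1-mean) = %.4g",
                 mean * (1 - mean)), call. = FALSE)
  nu <- mean * (1 - mean) / se^2 - 1
  if (nu > nu_cap)
    stop("se implies alpha+beta > ", format(nu_cap),
         "; treat the input as fixed instead", call. = FALSE)
  c(alpha = mean * nu, beta = (1 - mean) * nu)
}

#' Method-of-moments Gamma parameters (shape/scale convention)
#'
#' shape = (mean/se)^2, scale = se^2/mean.
#'
#' @param mean mean (> 0)
#' @param se standard error (> 0)
#' @return named vector `c(shape, scale)`
#' @export
gamma_from_moments <- function(mean, se) {
  if (mean <= 0 || se <= 0) stop("mean and se must be > 0", call. = FALSE)
  c(shape = (mean / se)^2, scale = se^2 / mean)
}

draw_dist <- function(spec, n = 1) {
  switch(spec$kind,
    beta = stats::rbeta(n, spec$alpha, spec$beta),
    gamma = stats::rgamma(n, shape = spec$shape, scale = spec$scale),
    fixed = rep(spec$value, n),
    stop("unknown dist kind: ", spec$kind)
  )
}

## ---- PSA over the cohort model -------------------------------------------

# Apply a named list of sampled values to a model_inputs object. Keys:
# "surgical_mortality", "rerevision_prob", "utility:<sex>:<age_lo>:<state>",
# "cost:<name>". Anything not listed stays at its deterministic value.
apply_draws <- function(inputs, draws) {
  for (nm in names(draws)) {
    v <- draws[[nm]]
    if (nm == "surgical_mortality") {
      inputs$surgical_mortality <- v
    } else if (nm == "rerevision_prob") {
      inputs$rerevision_prob <- v
    } else if (startsWith(nm, "cost:")) {
      inputs$costs[[sub("^cost:", "", nm)]] <- v
    } else if (startsWith(nm, "utility:")) {
      parts <- strsplit(nm, ":", fixed = TRUE)[[1]]
      hit <- inputs$utilities$sex == parts[2] &
        inputs$utilities$age_lo == as.numeric(parts[3]) &
        inputs$utilities$state == parts[4]
      inputs$utilities$utility[hit] <- v
    } else {
      stop("unknown PSA parameter key: ", nm, call. = FALSE)
    }
  }
  inputs
}

#' Probabilistic sensitivity analysis comparing two strategies
#'
#' Per iteration, draws every uncertain input from its distribution, applies
#' the draws to both strategies' inputs, runs the cohort model for each, and
#' records incremental cost and QALYs (strategy A minus strategy B).
#' Parameters whose specs are present in both arms under the same key and
#' with identical distributions are drawn once per iteration and shared, so
#' the comparison is not inflated by independent noise on common inputs
#' (revision cost, surgical mortality, utilities).
#'
#' @param inputs_a,inputs_b [model_inputs()] for the two strategies
#' @param specs_a,specs_b named lists of [dist_beta()]/[dist_gamma()]/
#'   [dist_fixed()] keyed as `"surgical_mortality"`, `"rerevision_prob"`,
#'   `"cost:<name>"`, `"utility:<sex>:<age_lo>:<state>"`
#' @param start_age,sex,horizon passed to [run_cohort()]
#' @param n iterations (default 1000)
#' @param seed RNG seed (draws are reproducible)
#' @param wtp_grid willingness-to-pay grid for the CEAC (default 0..50000 by
#'   500; 20000 always included)
#' @return a `psa_result`: data frame `iterations` (`iter`, `delta_cost`,
#'   `delta_qaly`), `ceac` data frame (`wtp`, `prob_ce`), summary fields
#'   `mean_delta_cost`, `mean_delta_qaly`, `icer_of_means`, `prob_ce_at_wtp`,
#'   `n`, `seed`
#' @export
run_psa <- function(inputs_a, inputs_b, specs_a, specs_b,
                    start_age, sex, horizon = "lifetime",
                    n = 1000, seed = 1L,
                    wtp_grid = seq(0, 50000, by = 500), wtp = 20000) {
  stopifnot(n >= 1)
  if (!length(wtp_grid)) stop("wtp_grid must be non-empty", call. = FALSE)
  wtp_grid <- sort(unique(c(wtp_grid, wtp)))
  set.seed(seed)
  shared_keys <- intersect(names(specs_a), names(specs_b))
  shared_keys <- shared_keys[vapply(shared_keys, function(k)
    identical(specs_a[[k]], specs_b[[k]]), logical(1))]

  dc <- dq <- numeric(n)
  aborted <- 0L
  for (i in seq_len(n)) {
    shared <- lapply(specs_a[shared_keys], draw_dist)
    own_a <- lapply(specs_a[setdiff(names(specs_a), shared_keys)], draw_dist)
    own_b <- lapply(specs_b[setdiff(names(specs_b), shared_keys)], draw_dist)
    res <- tryCatch({
      ia <- apply_draws(inputs_a, c(shared, own_a))
      ib <- apply_draws(inputs_b, c(shared, own_b))
      ra <- run_cohort(ia, start_age, sex, horizon)
      rb <- run_cohort(ib, start_age, sex, horizon)
      c(ra$cost - rb$cost, ra$qaly - rb$qaly)
    }, error = function(e) NULL)
    if (is.null(res)) {
      aborted <- aborted + 1L
      dc[i] <- NA_real_; dq[i] <- NA_real_
    } else {
      dc[i] <- res[1]; dq[i] <- res[2]
    }
  }
  iters <- data.frame(iter = seq_len(n), delta_cost = dc, delta_qaly = dq)
  iters <- iters[!is.na(iters$delta_cost), , drop = FALSE]
  out <- structure(list(iterations = iters,
                        n = n, aborted = aborted, seed = seed,
                        strategy_a = inputs_a$strategy,
                        strategy_b = inputs_b$strategy,
                        mean_delta_cost = mean(iters$delta_cost),
                        mean_delta_qaly = mean(iters$delta_qaly)),
                   class = "psa_result")
  out$icer_of_means <- if (out$mean_delta_qaly != 0) {
    out$mean_delta_cost / out$mean_delta_qaly
  } else NA_real_
  out$ceac <- ceac(out, wtp_grid)
  out$prob_ce_at_wtp <- out$ceac$prob_ce[match(wtp, out$ceac$wtp)]
  out$wtp <- wtp
  out
}

#' Cost-effectiveness acceptability curve
#'
#' At each willingness-to-pay value, the fraction of PSA iterations in which
#' strategy A's net monetary benefit exceeds strategy B's (lambda dQ - dC >
#' 0; exact ties count as not cost-effective).
#'
#' @param psa a `psa_result`
#' @param wtp_grid willingness-to-pay values (non-empty)
#' @return data frame with columns `wtp`, `prob_ce`
#' @export
ceac <- function(psa, wtp_grid = seq(0, 50000, by = 500)) {
  stopifnot(inherits(psa, "psa_result"))
  if (!length(wtp_grid)) stop("wtp_grid must be non-empty", call. = FALSE)
  it <- psa$iterations
  if (!nrow(it)) stop("PSA has no successful iterations", call. = FALSE)
  prob <- vapply(wtp_grid, function(l)
    mean(l * it$delta_qaly - it$delta_cost > 0), numeric(1))
  data.frame(wtp = wtp_grid, prob_ce = prob)
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("PSA %s vs %s: %d iterations (seed %d, %d aborted)\n",
              x$strategy_a, x$strategy_b, x$n, x$seed, x$aborted))
  cat(sprintf("  mean Δcost £%s, mean ΔQALY %.4f, P(CE at £%s) = %.3f\n",
              format(round(x$mean_delta_cost), big.mark = ","),
              x$mean_delta_qaly, format(x$wtp, big.mark = ","),
              x$prob_ce_at_wtp))
  invisible(x)
}

#' Export PSA iterations / CEAC as CSV
#' @param psa a `psa_result`
#' @param path file path
#' @export
write_psa_scatter <- function(psa, path) {
  utils::write.csv(psa$iterations, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_psa_scatter
#' @export
write_ceac <- function(psa, path) {
  utils::write.csv(psa$ceac, path, row.names = FALSE)
  invisible(path)
}
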