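#' Load the model-inputs configuration
#'
#' Reads the JSON bundle of transition probabilities, utilities (with Beta
#' parameters) and costs (with Gamma uncertainty) shipped with the package,
#' or a user-supplied file of the same shape.
#'
#' @param path JSON file; default is the packaged base-case configuration
#' @return a named list (`model_config`)
#' @export
load_model_config <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "model_inputs.json", package = "hipcea")
  cfg <- jsonlite::read_json(path, simplifyVector = FALSE)
  stopifnot(!is.null(cfg$discount_rate), !is.null(cfg$utilities),
            !is.null(cfg$costs))
  class(cfg) <- c("model_config", "list")
  cfg
}

#' Utility table from a model configuration
#'
#' Returns the deterministic utility data frame [model_inputs()] expects.
#' Printed Beta pairs are kept when they reproduce the printed mean to 3
#' decimal places; otherwise the mean/SE moments win (the shipped
#' configuration has one such inconsistent row) and the derived pair is used
#' for both the mean and the PSA distribution.
#'
#' @param cfg a `model_config`
#' @return data frame with columns `sex`, `age_lo`, `age_hi`, `state`,
#'   `utility`, `alpha`, `beta`, `rederived`
#' @export
config_utilities <- function(cfg) {
  rows <- lapply(cfg$utilities, function(u) {
    a <- u$alpha; b <- u$beta
    rederived <- FALSE
    if (is.null(a) || is.null(b) ||
        round(beta_mean(a, b), 3) != round(u$mean, 3)) {
      ab <- beta_from_moments(u$mean, u$se)
      a <- ab[["alpha"]]; b <- ab[["beta"]]
      rederived <- TRUE
    }
    data.frame(sex = u$sex, age_lo = u$age_lo, age_hi = u$age_hi,
               state = u$state, utility = u$mean, alpha = a, beta = b,
               rederived = rederived)
  })
  do.call(rbind, rows)
}

#' Cost set for one strategy from a model configuration
#'
#' @param cfg a `model_config`
#' @param strategy a key of `cfg$costs` (`"RS"`, `"CeMoP"`, `"CeCoP"`,
#'   `"CeLCoC"`)
#' @return named numeric vector of mean costs (GBP)
#' @export
config_costs <- function(cfg, strategy) {
  cs <- cfg$costs[[strategy]]
  if (is.null(cs)) stop("no cost set for strategy '", strategy, "'; have: ",
                        paste(names(cfg$costs), collapse = ", "),
                        call. = FALSE)
  vapply(cs, function(x) x$mean, numeric(1))
}

#' PSA distribution specs for one strategy
#'
#' Builds the named `dist_spec` list [run_psa()] consumes: Beta for surgical
#' mortality (method of moments) and every utility row, Gamma
#' (moment-matched shape/scale) for each cost that carries a standard error.
#' Costs without an SE and the re-revision probability stay fixed
#' (deterministic), matching the source table.
#'
#' @param cfg a `model_config`
#' @param strategy a key of `cfg$costs`
#' @return named list of `dist_spec`
#' @export
config_psa_specs <- function(cfg, strategy) {
  specs <- list()
  sm <- cfg$surgical_mortality
  ab <- beta_from_moments(sm$mean, sm$se)
  specs[["surgical_mortality"]] <- dist_beta(ab[["alpha"]], ab[["beta"]],
                                             mean = sm$mean, se = sm$se)
  ut <- config_utilities(cfg)
  for (i in seq_len(nrow(ut))) {
    key <- sprintf("utility:%s:%s:%s", ut$sex[i], ut$age_lo[i], ut$state[i])
    specs[[key]] <- dist_beta(ut$alpha[i], ut$beta[i],
                              mean = ut$utility[i])
  }
  cs <- cfg$costs[[strategy]]
  for (nm in names(cs)) {
    if (!is.null(cs[[nm]]$se)) {
      gp <- gamma_from_moments(cs[[nm]]$mean, cs[[nm]]$se)
      specs[[paste0("cost:", nm)]] <- dist_gamma(gp[["shape"]],
                                                 gp[["scale"]],
                                                 mean = cs[[nm]]$mean,
                                                 se = cs[[nm]]$se)
    }
  }
  specs
}

#' Build strategy model inputs straight from a configuration
#'
#' @param cfg a `model_config`
#' @param strategy cost-set key and strategy label
#' @param revision_schedule a `revision_schedule` for the strategy's device
#' @param life_table a `life_table`; default [default_life_tables()]
#' @param ... passed on to [model_inputs()] (e.g. `utility_bonus`)
#' @return a `model_inputs`
#' @export
build_strategy_inputs <- function(cfg, strategy, revision_schedule,
                                  life_table = default_life_tables(), ...) {
  model_inputs(strategy = strategy,
               revision_schedule = revision_schedule,
               life_table = life_table,
               utilities = config_utilities(cfg),
               costs = config_costs(cfg, strategy),
               surgical_mortality = cfg$surgical_mortality$mean,
               rerevision_prob = cfg$rerevision_prob,
               discount_rate = cfg$discount_rate,
               ...)
}
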