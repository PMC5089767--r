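#' Subgroup key for benchmark classification
#'
#' Identifies a device-patient subgroup: manufacturer x sex x head size x age
#' band. Age bands are half-open `[lo, hi)`.
#'
#' @param manufacturer manufacturer code
#' @param sex `"male"` or `"female"`
#' @param head_size head size in mm
#' @param age_lo,age_hi age band bounds in years (`lo < hi`)
#' @return a `subgroup_key` list
#' @export
subgroup_key <- function(manufacturer, sex, head_size, age_lo = 0,
                         age_hi = Inf) {
  stopifnot(age_lo < age_hi)
  structure(list(manufacturer = manufacturer, sex = sex,
                 head_size = head_size, age_lo = age_lo, age_hi = age_hi),
            class = "subgroup_key")
}

#' Classify a subgroup against the 10-year revision benchmark
#'
#' NICE's benchmark asks for a revision rate below 5% at 10 years. The
#' decision uses the point prediction of cumulative revision at `horizon`
#' years from the supplied fit (evaluated at the subgroup's covariate values
#' if the fit carries covariates, e.g. age at primary at the band midpoint).
#'
#' @param fit a converged `hip_survfit` applicable to the subgroup
#' @param subgroup a [subgroup_key()]
#' @param threshold benchmark revision probability (default 0.05)
#' @param horizon benchmark horizon in years (default 10)
#' @param n_patients number of registry patients in the subgroup (metadata)
#' @param flagged TRUE when the decision was inherited from a parent stratum
#'   or is an extrapolation beyond fitted support
#' @return a `benchmark_decision` list with fields `subgroup`,
#'   `predicted_10y_revision`, `threshold`, `within`, `n_patients`, `flagged`
#' @export
classify_subgroup <- function(fit, subgroup, threshold = 0.05, horizon = 10,
                              n_patients = NA_integer_, flagged = FALSE) {
  stopifnot(inherits(subgroup, "subgroup_key"))
  cov_vals <- NULL
  if (length(fit$covariates)) {
    mid <- band_midpoint(subgroup$age_lo, subgroup$age_hi)
    cov_vals <- vapply(fit$covariates, function(nm) {
      if (nm == "head_size") return(as.numeric(subgroup$head_size))
      if (grepl("age", nm)) return(mid)
      stop("classify_subgroup cannot supply covariate '", nm, "'",
           call. = FALSE)
    }, numeric(1))
  }
  pred <- predict_cumulative_revision(fit, horizon, cov_vals)
  structure(list(subgroup = subgroup,
                 predicted_10y_revision = pred,
                 threshold = threshold,
                 within = pred < threshold,
                 n_patients = n_patients,
                 flagged = flagged),
            class = "benchmark_decision")
}

subgroup_label <- function(manufacturer, sex, head_size, age_lo, age_hi) {
  paste(manufacturer, sex, head_size, age_lo, age_hi, sep = "|")
}

band_midpoint <- function(lo, hi) {
  if (!is.finite(lo)) return(hi - 2.5)
  if (!is.finite(hi)) return(lo + 2.5)
  (lo + hi) / 2
}

# Greedily merge ascending head sizes into groups carrying at least
# `min_events` revisions each, so every categorical effect is estimable.
group_head_sizes <- function(sizes, events_by_size, min_events) {
  sizes <- sort(sizes)
  groups <- integer(length(sizes))
  g <- 1L; acc <- 0
  for (i in seq_along(sizes)) {
    groups[i] <- g
    acc <- acc + events_by_size[as.character(sizes[i])]
    if (acc >= min_events && i < length(sizes)) {
      g <- g + 1L; acc <- 0
    }
  }
  # fold an underpowered trailing group into its predecessor
  if (acc < min_events && g > 1)
    groups[groups == g] <- g - 1L
  stats::setNames(groups, sizes)
}

#' Fit and classify every registry subgroup
#'
#' Driver over a (filtered) registry of RS records, mirroring the workflow
#' of screening head-size/age/manufacturer categories against the benchmark.
#' Per manufacturer x sex, one parametric model is fitted with head size as a
#' categorical effect (a common baseline time-shape with per-size levels -
#' small strata cannot support stable 10-year extrapolation on their own) and
#' age at primary as a linear covariate. Head sizes with fewer than
#' `min_events` revisions are merged into the neighbouring size group and
#' their decisions flagged as borrowed. Every subgroup (size x 5-year age
#' band) is then classified against the benchmark from its model prediction.
#'
#' @param records RS registry records (must carry `manufacturer`, `sex`,
#'   `head_size`, `age_at_primary`, `followup_time`, `revised`)
#' @param threshold,horizon as in [classify_subgroup()]
#' @param age_breaks age band cut points (default 5-year bins 35..75)
#' @param min_events minimum revisions for a size-specific effect (default 5)
#' @param family parametric family for the stratum fits (default weibull)
#' @return data frame of decisions, one row per non-empty subgroup: columns
#'   `manufacturer`, `sex`, `head_size`, `age_lo`, `age_hi`, `predicted`,
#'   `within`, `n`, `flagged`
#' @export
benchmark_registry <- function(records, threshold = 0.05, horizon = 10,
                               age_breaks = seq(35, 75, by = 5),
                               min_events = 5, family = "weibull") {
  stopifnot(nrow(records) > 0)
  lo <- c(-Inf, age_breaks)
  hi <- c(age_breaks, Inf)
  records$.band <- findInterval(records$age_at_primary, age_breaks) + 1L

  rows <- list()
  for (m in unique(records$manufacturer)) {
    for (s in unique(records$sex)) {
      sub <- records[records$manufacturer == m & records$sex == s, ]
      if (!nrow(sub)) next
      sizes <- sort(unique(sub$head_size))
      ev_by_size <- vapply(as.character(sizes), function(h)
        sum(sub$revised[sub$head_size == as.integer(h)]), numeric(1))
      grp <- group_head_sizes(sizes, ev_by_size, min_events)
      sub$.grp <- grp[as.character(sub$head_size)]
      ngrp <- max(grp)
      # dummies for all size groups but the largest (reference)
      ref <- as.integer(names(which.max(table(sub$.grp))))
      covs <- "age_at_primary"
      for (g in setdiff(seq_len(ngrp), ref)) {
        nm <- paste0(".size_grp", g)
        sub[[nm]] <- as.numeric(sub$.grp == g)
        covs <- c(covs, nm)
      }
      fit <- tryCatch(
        suppressWarnings(fit_parametric(sub, family, covariates = covs)),
        error = function(e) NULL)
      if (is.null(fit) || !isTRUE(fit$converged)) {
        fit <- tryCatch(
          suppressWarnings(fit_parametric(sub, family,
                                          covariates = "age_at_primary")),
          error = function(e) NULL)
        covs <- "age_at_primary"
      }
      for (h in sizes) {
        cell <- sub[sub$head_size == h, ]
        borrowed <- ev_by_size[as.character(h)] < min_events ||
          is.null(fit) || length(fit$covariates) < length(covs)
        for (b in sort(unique(cell$.band))) {
          nb <- sum(cell$.band == b)
          if (is.null(fit) || !isTRUE(fit$converged)) {
            # nothing estimable in the parent: conservative "not within"
            rows[[length(rows) + 1L]] <-
              data.frame(manufacturer = m, sex = s, head_size = h,
                         age_lo = lo[b], age_hi = hi[b],
                         predicted = NA_real_, within = FALSE, n = nb,
                         flagged = TRUE)
            next
          }
          cv <- stats::setNames(numeric(length(fit$covariates)),
                                fit$covariates)
          cv["age_at_primary"] <- band_midpoint(lo[b], hi[b])
          gnm <- paste0(".size_grp", grp[as.character(h)])
          if (gnm %in% names(cv)) cv[gnm] <- 1
          pred <- predict_cumulative_revision(fit, horizon, cv)
          rows[[length(rows) + 1L]] <-
            data.frame(manufacturer = m, sex = s, head_size = h,
                       age_lo = lo[b], age_hi = hi[b], predicted = pred,
                       within = pred < threshold, n = nb,
                       flagged = borrowed)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pool registry records by benchmark status
#'
#' Partitions records into those belonging to subgroups predicted within the
#' benchmark and those not, per a decisions table from
#' [benchmark_registry()]. Every record must map to exactly one decision row.
#'
#' @param records RS registry records
#' @param decisions decisions data frame (columns `manufacturer`, `sex`,
#'   `head_size`, `age_lo`, `age_hi`, `within`)
#' @return list with elements `within` and `not_within` (data frames) and
#'   `summary` (per-manufacturer proportion of records within)
#' @export
dichotomize <- function(records, decisions) {
  stopifnot(nrow(records) > 0)
  dec_key <- subgroup_label(decisions$manufacturer, decisions$sex,
                            decisions$head_size, decisions$age_lo,
                            decisions$age_hi)
  if (anyDuplicated(dec_key))
    stop("decisions table has duplicate subgroup keys", call. = FALSE)
  idx <- rep(NA_integer_, nrow(records))
  for (j in seq_len(nrow(decisions))) {
    hit <- records$manufacturer == decisions$manufacturer[j] &
      records$sex == decisions$sex[j] &
      records$head_size %in% decisions$head_size[j] &
      records$age_at_primary >= decisions$age_lo[j] &
      records$age_at_primary < decisions$age_hi[j]
    clash <- hit & !is.na(idx)
    if (any(clash))
      stop("record maps to multiple subgroups: ",
           paste(records$patient_id[clash][1]), call. = FALSE)
    idx[hit] <- j
  }
  if (anyNA(idx)) {
    bad <- records[is.na(idx), c("manufacturer", "sex", "head_size",
                                 "age_at_primary")][1, ]
    stop("record with no matching subgroup decision: ",
         paste(names(bad), unlist(bad), sep = "=", collapse = ", "),
         call. = FALSE)
  }
  within <- decisions$within[idx]
  summ <- stats::aggregate(within, list(manufacturer = records$manufacturer),
                           mean)
  names(summ)[2] <- "prop_within"
  list(within = records[within, , drop = FALSE],
       not_within = records[!within, , drop = FALSE],
       summary = summ)
}

#' Export benchmark decisions as CSV
#' @param decisions decisions data frame from [benchmark_registry()]
#' @param path file path
#' @export
write_decisions <- function(decisions, path) {
  utils::write.csv(decisions, path, row.names = FALSE)
  invisible(path)
}
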