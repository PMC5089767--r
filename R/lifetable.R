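#' Build a synthetic period life table
#'
#' Stand-in for national statistics life tables: annual death probabilities
#' from a Gompertz-Makeham hazard, qx = 1 - exp(-(a + b e^{c age})), clipped
#' to \[0, 1\]. With positive `gompertz_c` the hazard (and hence qx) is
#' non-decreasing in age.
#'
#' @param sex `"male"` or `"female"` (label only; pick parameters per sex)
#' @param makeham_a age-independent hazard component (per year, >= 0)
#' @param gompertz_b baseline senescent hazard (per year, >= 0)
#' @param gompertz_c exponential ageing rate (per year of age, >= 0)
#' @param max_age oldest tabulated age (<= 120)
#' @param min_age youngest tabulated age
#' @return data frame of class `life_table` with columns `sex`, `age`, `qx`
#' @examples
#' lt <- make_life_table("male", 5e-4, 3e-5, 0.09)
#' lt$qx[lt$age == 60]
#' @export
make_life_table <- function(sex, makeham_a, gompertz_b, gompertz_c,
                            max_age = 100, min_age = 0) {
  if (makeham_a < 0 || gompertz_b < 0 || gompertz_c < 0)
    stop("life table parameters must be non-negative (makeham_a, gompertz_b, gompertz_c)",
         call. = FALSE)
  if (max_age > 120) stop("max_age must be <= 120", call. = FALSE)
  age <- min_age:max_age
  qx <- 1 - exp(-(makeham_a + gompertz_b * exp(gompertz_c * age)))
  qx <- pmin(pmax(qx, 0), 1)
  out <- data.frame(sex = sex, age = age, qx = qx, stringsAsFactors = FALSE)
  class(out) <- c("life_table", "data.frame")
  out
}

#' Default synthetic life tables for both sexes
#'
#' Gompertz-Makeham parameters chosen to echo recent UK period tables
#' (male qx ~ 0.005 at 60, ~ 0.05 at 80; female hazards about 40% lower).
#' @return a `life_table` data frame covering both sexes, ages 0-100
#' @export
default_life_tables <- function() {
  rbind(make_life_table("male", 4e-4, 2.8e-5, 0.095),
        make_life_table("female", 3e-4, 1.6e-5, 0.098))
}

#' Look up annual death probability
#'
#' Ages beyond the table's range use the nearest tabulated age.
#'
#' @param life_table a `life_table` data frame (may contain both sexes)
#' @param sex sex to look up
#' @param age integer age (vectorised)
#' @return numeric vector of qx
#' @export
lookup_qx <- function(life_table, sex, age) {
  sub <- life_table[life_table$sex == sex, ]
  if (!nrow(sub)) stop("life table has no rows for sex '", sex, "'",
                       call. = FALSE)
  age <- pmin(pmax(round(age), min(sub$age)), max(sub$age))
  sub$qx[match(age, sub$age)]
}

#' @export
write_life_table <- function(life_table, path) {
  utils::write.csv(life_table, path, row.names = FALSE)
  invisible(path)
}

#' Read a life table from CSV (columns sex, age, qx)
#' @param path file path
#' @return a `life_table` data frame
#' @rdname write_life_table
#' @export
read_life_table <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("sex", "age", "qx") %in% names(out)))
  if (any(out$qx < 0 | out$qx > 1))
    stop("life table qx values must lie in [0, 1]", call. = FALSE)
  class(out) <- c("life_table", "data.frame")
  out
}
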