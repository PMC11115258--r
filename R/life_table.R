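#' Life tables: baseline annual mortality probabilities
#'
#' A life table gives the annual probability of death `q` by birth cohort,
#' sex and attained age.  It is the source of the baseline hazard in the
#' cohort simulator: every simulated individual's death probability in a
#' given year is the life-table `q` for their age, multiplied by the
#' relative risk implied by their city's exposure.
#'
#' Because the simulation measures relative risk, any plausible baseline
#' schedule gives the same shape results; [synthetic_life_table()] provides
#' a Gompertz-Makeham baseline so no external data are needed, and
#' [load_life_table()] reads a user-supplied CSV (columns
#' `birth_year,sex,age,q`) for users who have real cohort tables.
#'
#' @name life_table
NULL

new_life_table <- function(df) {
  df <- df[order(df$sex, df$birth_year, df$age), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("life_table", "data.frame")
  df
}

validate_life_table <- function(df, where = "life table") {
  required <- c("birth_year", "sex", "age", "q")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(sprintf("%s is missing column(s): %s", where,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  bad_q <- which(!is.finite(df$q) | df$q < 0 | df$q > 1)
  if (length(bad_q)) {
    stop(sprintf("%s: q outside [0, 1] at row %d (q = %g)",
                 where, bad_q[1], df$q[bad_q[1]]), call. = FALSE)
  }
  if (!all(df$sex %in% c("male", "female"))) {
    stop(sprintf("%s: sex must be 'male' or 'female'", where), call. = FALSE)
  }
  if (any(df$age != round(df$age))) {
    stop(sprintf("%s: ages must be integers", where), call. = FALSE)
  }
  # ages contiguous within each (birth_year, sex) block
  by_cohort <- split(df$age, interaction(df$birth_year, df$sex, drop = TRUE))
  for (nm in names(by_cohort)) {
    a <- sort(by_cohort[[nm]])
    if (length(a) > 1L && any(diff(a) != 1L)) {
      stop(sprintf("%s: non-contiguous ages for cohort %s", where, nm),
           call. = FALSE)
    }
  }
  invisible(df)
}

#' Load a life table from CSV
#'
#' @param path Path to a CSV file with columns `birth_year,sex,age,q`
#'   (one row per cohort-age; `q` is the annual death probability).
#' @return A `life_table` data frame, validated: all `q` in \[0, 1\],
#'   integer ages contiguous within each (birth_year, sex) cohort.
#' @seealso [synthetic_life_table()], [mortality_schedule()]
#' @export
load_life_table <- function(path) {
  if (!file.exists(path)) stop("life table file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_life_table(df, where = paste0("life table '", basename(path), "'"))
  new_life_table(df)
}

#' Construct a Gompertz-Makeham life table
#'
#' Annual death probability `q(age) = min(1, a + b * exp(c * age))`,
#' identical across birth cohorts unless `drift` is nonzero, in which case
#' the Gompertz level `b` is scaled by `exp(drift * (birth_year - min))`
#' (a simple secular mortality trend).
#'
#' Defaults are anchored so that `q(60) = 0.01` and `q(80) = 0.06`,
#' a realistic all-cause schedule for older US men.
#'
#' @param a Makeham (age-independent) offset, >= 0.
#' @param b Gompertz level, > 0.
#' @param c Gompertz log-slope per year of age, > 0 (0 allowed: constant q).
#' @param ages Integer vector of ages covered (contiguous).
#' @param birth_years Integer vector of tabulated birth cohorts.
#' @param sexes Character vector, subset of `c("male", "female")`.
#' @param drift Log-linear change in `b` per calendar year of birth
#'   (negative = mortality improvement). Default 0.
#' @return A `life_table` data frame.
#' @examples
#' lt <- synthetic_life_table()
#' subset(lt, birth_year == 1940 & age %in% c(60, 80))
#' @export
synthetic_life_table <- function(a = 0,
                                 b = 0.01 * exp(-60 * log(6) / 20),
                                 c = log(6) / 20,
                                 ages = 50:99,
                                 birth_years = seq(1900, 2100, by = 10),
                                 sexes = "male",
                                 drift = 0) {
  stopifnot(a >= 0, b >= 0, c >= 0, length(ages) >= 1)
  ages <- as.integer(ages)
  if (length(ages) > 1L && any(diff(sort(ages)) != 1L)) {
    stop("ages must be a contiguous integer range", call. = FALSE)
  }
  grid <- expand.grid(age = ages, birth_year = as.integer(birth_years),
                      sex = sexes, stringsAsFactors = FALSE)
  bb <- b * exp(drift * (grid$birth_year - min(birth_years)))
  q <- a + bb * exp(c * grid$age)
  if (any(q > 1)) {
    warning(sprintf("%d q values exceeded 1 and were clipped", sum(q > 1)))
    q <- pmin(1, q)
  }
  df <- data.frame(birth_year = grid$birth_year, sex = grid$sex,
                   age = grid$age, q = q, stringsAsFactors = FALSE)
  validate_life_table(df, where = "synthetic life table")
  new_life_table(df)
}

#' Mortality schedule for a birth cohort
#'
#' Returns the age-indexed annual death probabilities for one birth year
#' and sex, linearly interpolating `q` at each age between the two
#' bracketing tabulated cohorts when `birth_year` is not itself tabulated.
#' No extrapolation: `birth_year` must lie inside the tabulated range.
#'
#' @param table A `life_table`.
#' @param birth_year Calendar birth year (may fall between tabulated cohorts).
#' @param sex `"male"` or `"female"`.
#' @return A data frame with columns `age` and `q`, one row per age covered
#'   by both bracketing cohorts.
#' @export
mortality_schedule <- function(table, birth_year, sex = "male") {
  stopifnot(inherits(table, "life_table"))
  sub <- table[table$sex == sex, , drop = FALSE]
  if (!nrow(sub)) stop("no rows for sex '", sex, "' in life table", call. = FALSE)
  ys <- sort(unique(sub$birth_year))
  if (birth_year < min(ys) || birth_year > max(ys)) {
    stop(sprintf("birth_year %s outside tabulated range [%d, %d]",
                 format(birth_year), min(ys), max(ys)), call. = FALSE)
  }
  if (birth_year %in% ys) {
    block <- sub[sub$birth_year == birth_year, c("age", "q")]
    out <- block[order(block$age), ]
    rownames(out) <- NULL
    return(out)
  }
  lo <- max(ys[ys < birth_year])
  hi <- min(ys[ys > birth_year])
  w <- (birth_year - lo) / (hi - lo)
  blo <- sub[sub$birth_year == lo, c("age", "q")]
  bhi <- sub[sub$birth_year == hi, c("age", "q")]
  ages <- intersect(blo$age, bhi$age)
  if (!length(ages)) stop("bracketing cohorts share no ages", call. = FALSE)
  ages <- sort(ages)
  qlo <- blo$q[match(ages, blo$age)]
  qhi <- bhi$q[match(ages, bhi$age)]
  data.frame(age = ages, q = (1 - w) * qlo + w * qhi)
}
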