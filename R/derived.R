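# Derived minimum-data-set features: BMI category and age category.
#
# Both derivations exist in two modes. "faithful" reproduces the deployed
# screening system's coding path literally, including its quirks (an
# undefined BMI falls through every "<" comparison into category 4; age is a
# plain difference of calendar years). "strict" is the corrected behaviour
# (missing stays missing; optional birthday adjustment for age).

#' Body-mass index and its category code
#'
#' BMI is `weight / (height/100)^2` (kg/m^2). The category code follows the
#' strict less-than chain `bmi < 18.5 -> 1`, `bmi < 24.9 -> 2`,
#' `bmi < 29.9 -> 3`, else `4` (so a BMI of exactly 24.9 codes as 3).
#'
#' When weight or height is missing or zero, BMI is undefined. In `"strict"`
#' mode (default) the category is then `NA`. In `"faithful"` mode the
#' undefined BMI fails every comparison in the chain and lands in the final
#' branch, category 4 — the literal behaviour of the original coding script,
#' kept available because registries coded with it exist.
#'
#' @param weight Numeric vector, kilograms. Zero or `NA` means missing.
#' @param height Numeric vector, centimetres. Zero or `NA` means missing.
#' @param mode `"strict"` or `"faithful"` handling of undefined BMI.
#' @return A tibble with columns `bmi` (double, `NA` when undefined) and
#'   `category` (integer 1--4, or `NA` in strict mode).
#' @export
#' @examples
#' compute_bmi(70, 175) # bmi 22.86, category 2
#' compute_bmi(0, 175, mode = "faithful") # category 4
compute_bmi <- function(weight, height, mode = c("strict", "faithful")) {
  mode <- match.arg(mode)
  n <- max(length(weight), length(height))
  weight <- rep_len(as.numeric(weight), n)
  height <- rep_len(as.numeric(height), n)
  if (any(weight < 0, na.rm = TRUE) || any(height < 0, na.rm = TRUE)) {
    stop("weight and height must be nonnegative", call. = FALSE)
  }
  defined <- !is.na(weight) & !is.na(height) & weight != 0 & height != 0
  bmi <- ifelse(defined, weight / (height / 100)^2, NA_real_)
  category <- dplyr::case_when(
    bmi < 18.5 ~ 1L,
    bmi < 24.9 ~ 2L,
    bmi < 29.9 ~ 3L,
    !is.na(bmi) ~ 4L,
    mode == "faithful" ~ 4L,
    .default = NA_integer_
  )
  tibble::tibble(bmi = bmi, category = category)
}

age_to_category <- function(age) {
  dplyr::case_when(
    age < 45 ~ 1L,
    age < 65 ~ 2L,
    !is.na(age) ~ 3L,
    .default = NA_integer_
  )
}

#' Age and age category from a Persian birthdate
#'
#' Converts the `"YYYY-MM-DD"` Persian-calendar birthdate to Gregorian and
#' derives age relative to `reference_year`. The default (`adjust = FALSE`)
#' is faithful to the deployed system: age is simply
#' `reference_year - Gregorian birth year`, with no birthday adjustment.
#' `adjust = TRUE` instead counts completed years at a mid-year census date
#' (July 1 of the reference year), subtracting one year when the birthday
#' falls after it.
#'
#' The category code is `1` for age < 45, `2` for 45--64, `3` for 65 and
#' over.
#'
#' @param birthdate_persian Character vector of `"YYYY-MM-DD"` Persian dates.
#'   `NA` propagates.
#' @param reference_year Gregorian year the age is computed against. An
#'   explicit parameter (never the wall clock) so results are reproducible.
#' @param adjust If `TRUE`, count completed years at July 1 of the reference
#'   year; default `FALSE` reproduces the plain year-difference of the
#'   original system.
#' @return A tibble with columns `gregorian_birthdate` ([Date]), `age`
#'   (integer) and `category` (integer 1--3).
#' @export
#' @examples
#' compute_age("1370-01-01", reference_year = 2017) # age 26, category 1
compute_age <- function(birthdate_persian, reference_year, adjust = FALSE) {
  stopifnot(is.numeric(reference_year), length(reference_year) == 1)
  parts <- parse_persian_date(birthdate_persian)
  ok <- !is.na(parts$year)
  gdate <- rep(as.Date(NA), length(birthdate_persian))
  if (any(ok)) {
    gdate[ok] <- jalali_to_gregorian(parts$year[ok], parts$month[ok],
                                     parts$day[ok])
  }
  gyear <- as.integer(format(gdate, "%Y"))
  age <- as.integer(reference_year) - gyear
  if (adjust) {
    # completed years at the July 1 census date of the reference year
    age <- age - as.integer(format(gdate, "%m-%d") > "07-01")
  }
  if (any(age < 0, na.rm = TRUE)) {
    stop("reference_year precedes a birth year", call. = FALSE)
  }
  tibble::tibble(
    gregorian_birthdate = gdate,
    age = age,
    category = age_to_category(age)
  )
}
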