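# Persian (Jalali) <-> Gregorian conversion via Julian day numbers, using the
# arithmetic 33-year-cycle (jalaali) leap rule. Integer arithmetic throughout
# uses truncated division, which the day-number formulas below assume.

.jal_breaks <- c(-61, 9, 38, 199, 426, 686, 756, 818, 1111, 1181, 1210,
                 1635, 2060, 2097, 2192, 2262, 2324, 2394, 2456, 3178)

.tdiv <- function(a, b) trunc(a / b)
.tmod <- function(a, b) a - trunc(a / b) * b

# Leap status and the Gregorian March day of 1 Farvardin for one Jalali year.
jal_cal <- function(jy) {
  bl <- length(.jal_breaks)
  gy <- jy + 621
  if (jy < .jal_breaks[1] || jy >= .jal_breaks[bl]) {
    stop("Jalali year ", jy, " outside supported range", call. = FALSE)
  }
  leap_j <- -14
  jp <- .jal_breaks[1]
  jump <- 0
  for (i in 2:bl) {
    jm <- .jal_breaks[i]
    jump <- jm - jp
    if (jy < jm) break
    leap_j <- leap_j + .tdiv(jump, 33) * 8 + .tdiv(.tmod(jump, 33), 4)
    jp <- jm
  }
  n <- jy - jp
  leap_j <- leap_j + .tdiv(n, 33) * 8 + .tdiv(.tmod(n, 33) + 3, 4)
  if (.tmod(jump, 33) == 4 && jump - n == 4) leap_j <- leap_j + 1
  leap_g <- .tdiv(gy, 4) - .tdiv((.tdiv(gy, 100) + 1) * 3, 4) - 150
  march <- 20 + leap_j - leap_g
  if (jump - n < 6) n <- n - jump + .tdiv(jump + 4, 33) * 33
  leap <- .tmod(.tmod(n + 1, 33) - 1, 4)
  if (leap == -1) leap <- 4
  list(leap = leap, gy = gy, march = march)
}

g2d <- function(gy, gm, gd) {
  d <- .tdiv((gy + .tdiv(gm - 8, 6) + 100100) * 1461, 4) +
    .tdiv(153 * .tmod(gm + 9, 12) + 2, 5) + gd - 34840408
  d - .tdiv(.tdiv(gy + 100100 + .tdiv(gm - 8, 6), 100) * 3, 4) + 752
}

d2g <- function(jdn) {
  j <- 4 * jdn + 139361631
  j <- j + .tdiv(.tdiv(4 * jdn + 183187720, 146097) * 3, 4) * 4 - 3908
  i <- .tdiv(.tmod(j, 1461), 4) * 5 + 308
  gd <- .tdiv(.tmod(i, 153), 5) + 1
  gm <- .tmod(.tdiv(i, 153), 12) + 1
  gy <- .tdiv(j, 1461) - 100100 + .tdiv(8 - gm, 6)
  c(gy, gm, gd)
}

j2d <- function(jy, jm, jd) {
  r <- jal_cal(jy)
  g2d(r$gy, 3, r$march) + (jm - 1) * 31 - .tdiv(jm, 7) * (jm - 7) + jd - 1
}

d2j <- function(jdn) {
  gy <- d2g(jdn)[1]
  jy <- gy - 621
  r <- jal_cal(jy)
  k <- jdn - g2d(gy, 3, r$march)
  if (k >= 0) {
    if (k <= 185) {
      return(c(jy, 1 + .tdiv(k, 31), .tmod(k, 31) + 1))
    }
    k <- k - 186
  } else {
    jy <- jy - 1
    k <- k + 179
    if (r$leap == 1) k <- k + 1
  }
  c(jy, 7 + .tdiv(k, 30), .tmod(k, 30) + 1)
}

#' Is a Jalali year a leap year?
#'
#' Uses the arithmetic 33-year-cycle rule. A leap year has 30 days in
#' Esfand (month 12) instead of 29.
#'
#' @param year Integer vector of Jalali years.
#' @return Logical vector.
#' @export
#' @examples
#' jalali_leap_year(c(1399, 1400, 1403))
jalali_leap_year <- function(year) {
  vapply(year, function(y) jal_cal(y)$leap == 0, logical(1))
}

#' Number of days in a Jalali month
#'
#' @param year Jalali year (used only for month 12, whose length depends on
#'   the leap rule).
#' @param month Month number, 1--12.
#' @return Integer vector of month lengths.
#' @export
jalali_month_length <- function(year, month) {
  n <- max(length(year), length(month))
  year <- rep_len(year, n)
  month <- rep_len(month, n)
  out <- integer(n)
  for (i in seq_len(n)) {
    m <- month[i]
    if (is.na(m) || m < 1 || m > 12) {
      out[i] <- NA_integer_
    } else if (m <= 6) {
      out[i] <- 31L
    } else if (m <= 11) {
      out[i] <- 30L
    } else {
      out[i] <- if (jalali_leap_year(year[i])) 30L else 29L
    }
  }
  out
}

check_jalali_date <- function(year, month, day) {
  if (any(is.na(year) | is.na(month) | is.na(day))) {
    stop("Jalali date components must not be missing", call. = FALSE)
  }
  bad_month <- month < 1 | month > 12
  if (any(bad_month)) {
    stop("invalid Jalali month: ", paste(month[bad_month], collapse = ", "),
         call. = FALSE)
  }
  ml <- jalali_month_length(year, month)
  bad_day <- day < 1 | day > ml
  if (any(bad_day)) {
    stop("invalid Jalali day of month: ",
         paste(sprintf("%d-%02d-%02d", year[bad_day], month[bad_day],
                       day[bad_day]), collapse = ", "),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Convert Jalali (Persian) dates to Gregorian
#'
#' Converts civil Persian-calendar dates to Gregorian [Date]s through Julian
#' day numbers, using the arithmetic 33-year-cycle leap rule. The conversion
#' is a bijection against [gregorian_to_jalali()] over the supported range
#' (Jalali years -61 to 3177; the package is exercised on 1300--1450 AP).
#'
#' @param year,month,day Integer vectors (recycled to a common length) giving
#'   the Jalali date. Months 1--6 have 31 days, 7--11 have 30, and month 12
#'   has 29 or 30 by the leap rule.
#' @return A [Date] vector.
#' @export
#' @examples
#' jalali_to_gregorian(1370, 1, 1) # "1991-03-21"
jalali_to_gregorian <- function(year, month, day) {
  n <- max(length(year), length(month), length(day))
  year <- rep_len(as.integer(year), n)
  month <- rep_len(as.integer(month), n)
  day <- rep_len(as.integer(day), n)
  check_jalali_date(year, month, day)
  out <- vapply(seq_len(n), function(i) {
    g <- d2g(j2d(year[i], month[i], day[i]))
    sprintf("%04d-%02d-%02d", g[1], g[2], g[3])
  }, character(1))
  as.Date(out)
}

#' Convert Gregorian dates to Jalali (Persian)
#'
#' Inverse of [jalali_to_gregorian()].
#'
#' @param date A [Date] vector (or anything `as.Date()` accepts).
#' @return A tibble with integer columns `year`, `month`, `day`.
#' @export
#' @examples
#' gregorian_to_jalali(as.Date("1991-03-21"))
gregorian_to_jalali <- function(date) {
  date <- as.Date(date)
  parts <- lapply(date, function(d) {
    y <- as.integer(format(d, "%Y"))
    m <- as.integer(format(d, "%m"))
    dd <- as.integer(format(d, "%d"))
    d2j(g2d(y, m, dd))
  })
  tibble::tibble(
    year = vapply(parts, `[`, numeric(1), 1),
    month = vapply(parts, `[`, numeric(1), 2),
    day = vapply(parts, `[`, numeric(1), 3)
  ) |> dplyr::mutate(dplyr::across(dplyr::everything(), as.integer))
}

#' Parse a Persian date string
#'
#' Accepts strictly `"YYYY-MM-DD"` (hyphen-separated); anything else is a
#' format error, matching the registry ingest contract.
#'
#' @param x Character vector of Persian date strings.
#' @return A tibble with integer columns `year`, `month`, `day`.
#' @export
parse_persian_date <- function(x) {
  m <- stringr::str_match(x, "^(\\d{4})-(\\d{1,2})-(\\d{1,2})$")
  bad <- !is.na(x) & is.na(m[, 1])
  if (any(bad)) {
    stop("unparseable Persian date (expected YYYY-MM-DD): ",
         paste(unique(x[bad]), collapse = ", "), call. = FALSE)
  }
  tibble::tibble(
    year = as.integer(m[, 2]),
    month = as.integer(m[, 3]),
    day = as.integer(m[, 4])
  )
}
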