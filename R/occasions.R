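# Occasion grid on the demographic ("lynx") year: 1 May of year Y to
# 30 April of Y+1. Occasions are half-open [start, end) intervals of 1 or 2
# months; within-year indices are 0-based.

#' Capture-occasion grid aligned to lynx years
#'
#' Builds the occasion grid used to discretise detections. A lynx year runs
#' from 1 May of calendar year `start_lynx_year + k` to 30 April of the next
#' calendar year; each lynx year is partitioned into `12 / interval_months`
#' occasions.
#'
#' @param start_lynx_year first lynx year covered (integer; the year whose
#'   1 May opens the study window).
#' @param n_years number of lynx years covered.
#' @param interval_months occasion length in months, 1 or 2.
#' @return an object of class `occasion_grid` with the occasion table
#'   (`occasion` 1-based global index, `lynx_year`, `within` 0-based).
#' @export
occasion_grid <- function(start_lynx_year, n_years, interval_months = 2) {
  stopifnot(interval_months %in% c(1L, 2L), n_years >= 1)
  per_year <- 12L %/% as.integer(interval_months)
  n_occ <- per_year * as.integer(n_years)
  tab <- data.frame(
    occasion = seq_len(n_occ),
    lynx_year = start_lynx_year + rep(seq_len(n_years) - 1L, each = per_year),
    within = rep(seq_len(per_year) - 1L, times = n_years)
  )
  structure(
    list(start_lynx_year = as.integer(start_lynx_year),
         n_years = as.integer(n_years),
         interval_months = as.integer(interval_months),
         per_year = per_year, n_occasions = n_occ, table = tab),
    class = "occasion_grid")
}

#' @export
print.occasion_grid <- function(x, ...) {
  cat(sprintf("occasion grid: lynx years %d-%d, %d-month occasions (%d per year, %d total)\n",
              x$start_lynx_year, x$start_lynx_year + x$n_years - 1L,
              x$interval_months, x$per_year, x$n_occasions))
  invisible(x)
}

#' Lynx year containing a calendar date
#'
#' @param date a `Date` vector.
#' @return integer vector: the lynx year (year of its 1 May start).
#' @export
lynx_year_of <- function(date) {
  date <- as.Date(date)
  y <- as.integer(format(date, "%Y"))
  m <- as.integer(format(date, "%m"))
  y - as.integer(m < 5L)
}

#' Map calendar dates to occasion indices
#'
#' @param grid an [occasion_grid()].
#' @param date a `Date` vector inside the grid window.
#' @return integer vector of 1-based global occasion indices.
#' @export
occasion_of_date <- function(grid, date) {
  date <- as.Date(date)
  ly <- lynx_year_of(date)
  m <- as.integer(format(date, "%m"))
  month_off <- (m - 5L) %% 12L            # months since 1 May
  within <- month_off %/% grid$interval_months
  bad <- ly < grid$start_lynx_year | ly > grid$start_lynx_year + grid$n_years - 1L
  if (any(bad)) {
    stop("date(s) outside occasion grid window: ",
         paste(format(date[bad]), collapse = ", "))
  }
  (ly - grid$start_lynx_year) * grid$per_year + within + 1L
}

#' Lynx year of each occasion (1-based year index within the grid)
#' @param grid an [occasion_grid()].
#' @return integer vector of length `n_occasions`, values in `1..n_years`.
#' @export
occasion_year_index <- function(grid) {
  rep(seq_len(grid$n_years), each = grid$per_year)
}

# first day of occasion t (used by the simulator to stamp dates)
occasion_start_date <- function(grid, t) {
  row <- grid$table[t, ]
  month0 <- 5L + row$within * grid$interval_months
  yr <- row$lynx_year + as.integer(month0 > 12L)
  mo <- ((month0 - 1L) %% 12L) + 1L
  as.Date(sprintf("%04d-%02d-01", yr, mo))
}

#' Age class from birth year
#'
#' Assigns the age class in a given lynx year: juvenile in the first year of
#' life, subadult in the second, adult from the third onwards. Individuals
#' with unknown birth year are treated as adults from their first detection.
#'
#' @param birth_lynx_year integer lynx year of birth, or `NA` if unknown.
#' @param current_lynx_year lynx year for which the class is wanted.
#' @param first_detection_year lynx year of first detection (used when the
#'   birth year is unknown).
#' @return integer age class: 1 juvenile, 2 subadult, 3 adult.
#' @export
assign_age_class <- function(birth_lynx_year, current_lynx_year,
                             first_detection_year) {
  n <- max(length(birth_lynx_year), length(current_lynx_year),
           length(first_detection_year))
  b <- rep_len(birth_lynx_year, n)
  cur <- rep_len(current_lynx_year, n)
  fd <- rep_len(first_detection_year, n)
  known <- !is.na(b)
  if (any(known & cur < b)) stop("current lynx year precedes birth year")
  if (any(!known & cur < fd)) stop("current lynx year precedes first detection")
  out <- integer(n)
  out[known] <- pmin(cur[known] - b[known] + 1L, 3L)
  out[!known] <- 3L   # adults from first detection when birth year unknown
  out
}

AGE_CLASSES <- c("juvenile", "subadult", "adult")
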