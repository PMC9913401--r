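#' Life tables of expected (background) mortality
#'
#' A `life_table` holds gridded all-cause mortality rates of the general
#' population, indexed by sex, single year of age, calendar year, region and
#' optionally a deprivation quintile (1..5).  Rates are hazards per
#' person-year, treated as constant on each unit age x unit calendar-year
#' cell.  The grid must be complete: every combination of the declared sexes,
#' ages, years, regions (and quintiles, when stratified) carries exactly one
#' non-negative rate.
#'
#' @param data data.frame with columns `sex`, `age`, `year`, `region`,
#'   optionally `quintile`, and `rate`.
#' @param prob logical; if `TRUE`, the `rate` column holds annual death
#'   probabilities q and is converted to hazards via `-log(1 - q)`.
#' @return An object of class `life_table`.
#' @export
life_table <- function(data, prob = FALSE) {
  req <- c("sex", "age", "year", "region", "rate")
  miss <- setdiff(req, names(data))
  if (length(miss))
    stop("life table is missing required column(s): ", paste(miss, collapse = ", "))
  stratified <- "quintile" %in% names(data)
  if (stratified && anyNA(data$quintile))
    stop("quintile column present but contains missing values; it must cover all rows")

  sex <- as.character(data$sex)
  bad_sex <- setdiff(unique(sex), c("male", "female"))
  if (length(bad_sex))
    stop("unknown sex label(s): ", paste(bad_sex, collapse = ", "))
  age <- as.integer(data$age)
  year <- as.integer(data$year)
  region <- as.character(data$region)
  rate <- as.numeric(data$rate)
  if (anyNA(rate) || any(!is.finite(rate)))
    stop("life-table rates must be finite")
  if (prob) {
    if (any(rate < 0 | rate >= 1))
      stop("death probabilities must lie in [0, 1) for conversion to hazards")
    rate <- -log1p(-rate)
  }
  if (any(rate < 0))
    stop("negative life-table rate(s) found (min ", format(min(rate)), ")")

  quintile <- if (stratified) as.integer(data$quintile) else rep(1L, length(rate))
  if (stratified && any(!quintile %in% 1:5))
    stop("quintile values must be integers 1..5")

  ages <- sort(unique(age))
  years <- sort(unique(year))
  sexes <- sort(unique(sex))
  regions <- sort(unique(region))
  nq <- if (stratified) 5L else 1L
  if (!identical(ages, seq(min(ages), max(ages))))
    stop("age grid must cover consecutive integer ages ", min(ages), "..", max(ages))
  if (!identical(years, seq(min(years), max(years))))
    stop("year grid must cover consecutive calendar years ", min(years), "..", max(years))

  arr <- array(NA_real_,
               dim = c(length(ages), length(years), length(sexes), length(regions), nq),
               dimnames = list(age = ages, year = years, sex = sexes,
                               region = regions, quintile = seq_len(nq)))
  idx <- cbind(match(age, ages), match(year, years), match(sex, sexes),
               match(region, regions), quintile)
  if (anyDuplicated(idx)) {
    d <- idx[duplicated(idx), , drop = FALSE][1, ]
    stop("duplicate life-table stratum: sex=", sexes[d[3]], " age=", ages[d[1]],
         " year=", years[d[2]], " region=", regions[d[4]],
         if (stratified) paste0(" quintile=", d[5]) else "")
  }
  arr[idx] <- rate
  if (anyNA(arr)) {
    holes <- which(is.na(arr), arr.ind = TRUE)
    k <- min(nrow(holes), 5L)
    desc <- apply(holes[seq_len(k), , drop = FALSE], 1, function(h)
      paste0("(sex=", sexes[h[3]], ", age=", ages[h[1]], ", year=", years[h[2]],
             ", region=", regions[h[4]],
             if (stratified) paste0(", quintile=", h[5]) else "", ")"))
    stop("incomplete life-table grid: ", nrow(holes), " missing stratum/strata, e.g. ",
         paste(desc, collapse = ", "))
  }

  structure(list(rates = arr, ages = ages, years = years, sexes = sexes,
                 regions = regions, stratified = stratified,
                 A_max = max(ages)),
            class = "life_table")
}

#' Read a life table from a delimited file
#'
#' The file must have a header `sex,age,year,region[,quintile],rate`.  With
#' `prob = TRUE` the rate column is interpreted as annual death probabilities
#' and converted to hazards.
#'
#' @param path file path.
#' @param prob see [life_table()].
#' @param sep field separator.
#' @return A `life_table`.
#' @export
read_life_table <- function(path, prob = FALSE, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  life_table(df, prob = prob)
}

#' Write a life table to a delimited file
#'
#' Rows are emitted in the canonical order sex, region, year, age, quintile so
#' that write/read round trips are byte-stable.
#'
#' @param lt a `life_table`.
#' @param path output path.
#' @export
write_life_table <- function(lt, path) {
  df <- as.data.frame(lt)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
as.data.frame.life_table <- function(x, ...) {
  nq <- dim(x$rates)[5]
  g <- expand.grid(age = x$ages, year = x$years, sex = x$sexes,
                   region = x$regions, quintile = seq_len(nq),
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g$rate <- as.vector(x$rates)
  o <- order(g$sex, g$region, g$year, g$age, g$quintile)
  g <- g[o, c("sex", "age", "year", "region", "quintile", "rate")]
  if (!x$stratified) g$quintile <- NULL
  rownames(g) <- NULL
  g
}

#' @export
print.life_table <- function(x, ...) {
  cat("Life table:", if (x$stratified) "deprivation-stratified (quintiles 1..5)"
      else "unstratified", "\n")
  cat("  sexes:  ", paste(x$sexes, collapse = ", "), "\n")
  cat("  ages:   ", min(x$ages), "..", x$A_max, "\n")
  cat("  years:  ", min(x$years), "..", max(x$years), "\n")
  cat("  regions:", length(x$regions), "\n")
  cat("  rates:  [", format(min(x$rates), digits = 4), ",",
      format(max(x$rates), digits = 4), "] per person-year\n")
  invisible(x)
}

## Resolve (and clamp) array indices for a set of demographic coordinates.
## Ages above A_max (or below the youngest tabulated age) and years outside
## the covered range are clamped to the nearest covered value; clamping is
## reported once per call via a message.
lt_index <- function(lt, sex, region, quintile, age, year, warn = TRUE) {
  si <- match(sex, lt$sexes)
  if (anyNA(si))
    stop("unknown sex label(s): ", paste(unique(sex[is.na(si)]), collapse = ", "))
  ri <- match(region, lt$regions)
  if (anyNA(ri))
    stop("unknown region label(s): ", paste(unique(region[is.na(ri)]), collapse = ", "))
  if (lt$stratified) {
    if (is.null(quintile) || anyNA(quintile))
      stop("life table is deprivation-stratified: quintile is required")
    if (any(!quintile %in% 1:5)) stop("quintile must be in 1..5")
    qi <- as.integer(quintile)
  } else {
    qi <- rep(1L, length(si))
  }
  ai_raw <- floor(age) - min(lt$ages) + 1
  yi_raw <- floor(year) - min(lt$years) + 1
  ai <- pmin(pmax(ai_raw, 1L), length(lt$ages))
  yi <- pmin(pmax(yi_raw, 1L), length(lt$years))
  if (warn) {
    ncl <- sum(ai != ai_raw) + sum(yi != yi_raw)
    if (ncl > 0)
      message("life-table lookup clamped ", ncl,
              " age/year coordinate(s) to the covered grid")
  }
  cbind(ai, yi, si, ri, qi, deparse.level = 0)
}

#' Look up an expected mortality rate
#'
#' Returns the hazard of the life-table cell containing `(current_age,
#' current_year)` for the given demographic profile.  Rates are
#' piecewise-constant on unit age x unit year cells (both coordinates are
#' floored).  Ages beyond the oldest tabulated age and years outside the
#' covered range are clamped to the nearest covered cell (reported via a
#' message).
#'
#' @param lt a `life_table`.
#' @param sex,region,quintile demographic profile (vectors are recycled to a
#'   common length); `quintile` is required iff `lt` is
#'   deprivation-stratified.
#' @param current_age,current_year attained age (years, >= 0) and calendar
#'   time at which the rate applies.
#' @return Numeric vector of hazards per person-year.
#' @export
lookup_rate <- function(lt, sex, region, current_age, current_year,
                        quintile = NULL) {
  stopifnot(inherits(lt, "life_table"))
  if (any(current_age < 0)) stop("current_age must be >= 0")
  n <- max(length(sex), length(region), length(current_age),
           length(current_year), length(quintile))
  sex <- rep_len(sex, n); region <- rep_len(region, n)
  current_age <- rep_len(current_age, n); current_year <- rep_len(current_year, n)
  if (!is.null(quintile)) quintile <- rep_len(quintile, n)
  lt$rates[lt_index(lt, sex, region, quintile, current_age, current_year)]
}

## Piecewise-constant hazard experienced by each subject along the diagonal
## (age_dx + u, year_dx + u), u in [0, horizon].  Returns matrices with one
## row per subject: segment end times (`ends`), per-segment hazards (`rate`)
## and the cumulative hazard at segment ends (`cumhaz`).  Segment boundaries
## sit at every integer age and integer calendar-year crossing.
lt_hazard_path <- function(lt, sex, age_dx, year_dx, region, quintile, horizon) {
  n <- length(age_dx)
  stopifnot(length(year_dx) == n, horizon > 0)
  K <- ceiling(horizon)
  off_a <- 1 - (age_dx %% 1)
  off_y <- 1 - (year_dx %% 1)
  steps <- 0:K
  M <- cbind(outer(off_a, steps, `+`), outer(off_y, steps, `+`))
  M[M > horizon] <- horizon
  M <- cbind(M, horizon)
  ends <- t(apply(M, 1, sort))
  starts <- cbind(0, ends[, -ncol(ends), drop = FALSE])
  len <- ends - starts
  mids <- (starts + ends) / 2
  m <- ncol(ends)
  idx <- lt_index(lt,
                  sex = rep(sex, m), region = rep(region, m),
                  quintile = if (is.null(quintile)) NULL else rep(quintile, m),
                  age = rep(age_dx, m) + as.vector(mids),
                  year = rep(year_dx, m) + as.vector(mids),
                  warn = FALSE)
  rate <- matrix(lt$rates[idx], nrow = n)
  inc <- rate * len
  cumhaz <- inc
  for (j in seq_len(m)[-1]) cumhaz[, j] <- cumhaz[, j - 1] + inc[, j]
  list(ends = ends, starts = starts, rate = rate, cumhaz = cumhaz)
}

## Evaluate the path hazard and cumulative hazard at one common time u.
## Returns list(rate, cumhaz) vectors over subjects.  u beyond the horizon is
## an error (paths must be built long enough).
lt_path_eval <- function(path, u) {
  m <- ncol(path$ends)
  if (u > path$ends[1, m] + 1e-9) stop("path evaluated beyond its horizon")
  j <- rowSums(path$ends < u) + 1L
  j[j > m] <- m
  ii <- cbind(seq_len(nrow(path$ends)), j)
  rate <- path$rate[ii]
  base <- ifelse(j > 1, path$cumhaz[cbind(ii[, 1], pmax(j - 1L, 1L))], 0)
  cumhaz <- base + rate * (u - path$starts[ii])
  list(rate = rate, cumhaz = cumhaz)
}

#' Cumulative expected hazard along a patient's follow-up diagonal
#'
#' Integrates the life-table hazard along `(age_dx + u, year_dx + u)` for
#' `u` in `[0, t]`, splitting the integral at every integer age and calendar
#' year crossing (the hazard is constant within each cell).  The expected
#' survival is `exp(-`the returned value`)`.
#'
#' @inheritParams lookup_rate
#' @param age_dx,year_dx continuous age and calendar time at diagnosis.
#' @param t follow-up time(s) in years, `t >= 0`; recycled against the
#'   profile vectors.
#' @return Numeric vector of cumulative hazards.
#' @export
cumulative_expected_hazard <- function(lt, sex, region, age_dx, year_dx, t,
                                       quintile = NULL) {
  stopifnot(inherits(lt, "life_table"))
  if (any(t < 0)) stop("t must be >= 0")
  n <- max(length(sex), length(region), length(age_dx), length(year_dx),
           length(t), length(quintile))
  sex <- rep_len(sex, n); region <- rep_len(region, n)
  age_dx <- rep_len(age_dx, n); year_dx <- rep_len(year_dx, n)
  t <- rep_len(t, n)
  if (!is.null(quintile)) quintile <- rep_len(quintile, n)
  out <- numeric(n)
  pos <- t > 0
  if (any(pos)) {
    path <- lt_hazard_path(lt, sex[pos], age_dx[pos], year_dx[pos],
                           region[pos], if (is.null(quintile)) NULL else quintile[pos],
                           horizon = max(t))
    ## evaluate each subject at its own t: segment index per row
    tp <- t[pos]
    m <- ncol(path$ends)
    j <- rowSums(path$ends < tp) + 1L
    j[j > m] <- m
    ii <- cbind(seq_len(sum(pos)), j)
    base <- ifelse(j > 1, path$cumhaz[cbind(ii[, 1], pmax(j - 1L, 1L))], 0)
    out[pos] <- base + path$rate[ii] * (tp - path$starts[ii])
  }
  out
}
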