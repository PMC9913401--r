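#' External mortality-gradient sources
#'
#' An `external_rate_source` holds smoothed all-cause mortality rates of some
#' reference population by sex, age, optionally calendar year, and an ordered
#' deprivation level 1..L (L = 5 for quintile sources, L = 20 for vingtile
#' sources such as income 20-quantiles).  An overall (all-population) rate
#' per stratum may be supplied directly, or be derivable as the
#' `level_weights`-weighted mean of the level rates.
#'
#' @param data data.frame with columns `sex`, `age`, optionally `year`,
#'   `level`, `rate`, optionally `weight` (population share of the level).
#'   Rows with `level == 0` carry the overall rate for their stratum.
#' @param unit rate unit in the file: `"py"` (per person-year), `"per1000"`
#'   or `"per100000"`; rates are normalized to per person-year on read.
#' @return An object of class `external_rate_source`: a data.frame of level
#'   rates with attributes `overall` (data.frame or NULL), `weights`
#'   (named numeric or NULL), `L`, `has_year`.
#' @export
external_rate_source <- function(data, unit = c("py", "per1000", "per100000")) {
  unit <- match.arg(unit)
  req <- c("sex", "age", "level", "rate")
  miss <- setdiff(req, names(data))
  if (length(miss))
    stop("external source is missing column(s): ", paste(miss, collapse = ", "))
  fac <- switch(unit, py = 1, per1000 = 1e-3, per100000 = 1e-5)
  data$rate <- as.numeric(data$rate) * fac
  if (any(!is.finite(data$rate)) || any(data$rate < 0))
    stop("external-source rates must be finite and >= 0")
  has_year <- "year" %in% names(data)
  overall <- data[data$level == 0, , drop = FALSE]
  lev <- data[data$level != 0, , drop = FALSE]
  L <- max(lev$level)
  if (!setequal(unique(lev$level), seq_len(L)))
    stop("levels must be 1..L (L = ", L, ")")
  key <- function(d) interaction(d$sex, d$age, if (has_year) d$year else 0,
                                 drop = TRUE)
  tab <- table(key(lev))
  if (any(tab != L))
    stop("every (sex, age[, year]) stratum must carry all ", L, " levels")
  weights <- NULL
  if ("weight" %in% names(lev)) {
    w <- tapply(lev$weight, lev$level, function(x) x[1])
    weights <- as.numeric(w) / sum(w)
    names(weights) <- names(w)
  }
  if (nrow(overall) == 0 && is.null(weights))
    stop("overall rates absent: level weights are required to derive them")
  structure(lev[order(key(lev), lev$level),
                c("sex", "age", if (has_year) "year", "level", "rate")],
            overall = if (nrow(overall)) overall[, c("sex", "age", if (has_year) "year", "rate")] else NULL,
            weights = weights, L = L, has_year = has_year,
            class = c("external_rate_source", "data.frame"))
}

#' Read an external mortality-gradient source from a delimited file
#'
#' Header `sex,age[,year],level,rate[,weight]`; rows with `level = 0` carry
#' the overall rate of their stratum.
#'
#' @inheritParams external_rate_source
#' @param path file path.
#' @export
read_rate_source <- function(path, unit = c("py", "per1000", "per100000")) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  external_rate_source(df, unit = match.arg(unit))
}

src_key <- function(d, has_year) {
  paste(d$sex, d$age, if (has_year) d$year else 0, sep = "\r")
}

#' Collapse a 20-level source to deprivation quintile-like fifths
#'
#' Vingtile levels 1-4, 5-8, 9-12, 13-16 and 17-20 are averaged
#' (arithmetic mean of the four rates) to produce levels 1..5.  Overall rates
#' and level weights are carried through (weights summed within fifths).
#'
#' @param src an `external_rate_source` with L = 20.
#' @return An `external_rate_source` with L = 5.
#' @export
aggregate_vingtiles <- function(src) {
  stopifnot(inherits(src, "external_rate_source"))
  if (attr(src, "L") != 20)
    stop("aggregate_vingtiles requires a 20-level source (L = ",
         attr(src, "L"), ")")
  has_year <- attr(src, "has_year")
  grp <- (src$level - 1) %/% 4 + 1
  k <- src_key(src, has_year)
  agg <- stats::aggregate(src$rate, by = list(key = k, level = grp), FUN = mean)
  first <- !duplicated(paste(k, grp))
  meta <- src[first, c("sex", "age", if (has_year) "year"), drop = FALSE]
  meta$level <- grp[first]
  meta$rate <- agg$x[match(paste(k[first], grp[first]),
                           paste(agg$key, agg$level))]
  w <- attr(src, "weights")
  if (!is.null(w)) {
    w5 <- tapply(w, (seq_along(w) - 1) %/% 4 + 1, sum)
    meta$weight <- as.numeric(w5)[meta$level]
  }
  out <- meta
  ov <- attr(src, "overall")
  if (!is.null(ov)) {
    ov$level <- 0
    out <- rbind(out[, c("sex", "age", if (has_year) "year", "level", "rate",
                         if (!is.null(w)) "weight")],
                 cbind(ov[, c("sex", "age", if (has_year) "year")],
                       level = 0, rate = ov$rate,
                       if (!is.null(w)) data.frame(weight = NA)))
  }
  external_rate_source(out)
}

#' Moving-average age smoothing for raw external sources
#'
#' Published gradient sources are usually already smoothed; for raw ones,
#' this applies a centered moving average over age (window shrinking at the
#' edges) within each (sex\[, year\], level) series, including the overall
#' (`level = 0`) series.
#'
#' @param src an `external_rate_source`.
#' @param window odd window width in years of age.
#' @return An `external_rate_source` with smoothed rates.
#' @export
smooth_source_rates <- function(src, window = 5) {
  stopifnot(inherits(src, "external_rate_source"), window %% 2 == 1)
  half <- (window - 1) / 2
  has_year <- attr(src, "has_year")
  smooth_series <- function(d) {
    o <- order(d$age)
    r <- d$rate[o]
    sm <- vapply(seq_along(r), function(i) {
      j <- max(1, i - half):min(length(r), i + half)
      mean(r[j])
    }, numeric(1))
    d$rate[o] <- sm
    d
  }
  grp <- function(d) paste(d$sex, if (has_year) d$year else 0, d$level)
  lev <- do.call(rbind, lapply(split(as.data.frame(src), grp(src)),
                               smooth_series))
  out <- lev
  ov <- attr(src, "overall")
  if (!is.null(ov)) {
    ov$level <- 0
    ov <- do.call(rbind, lapply(split(ov, paste(ov$sex,
                    if (has_year) ov$year else 0)), smooth_series))
    w <- attr(src, "weights")
    if (!is.null(w)) { out$weight <- w[out$level]; ov$weight <- NA }
    out <- rbind(out[, names(ov)[names(ov) %in% names(out)], drop = FALSE][
                   , c("sex", "age", if (has_year) "year", "level", "rate",
                       if (!is.null(w)) "weight")],
                 ov[, c("sex", "age", if (has_year) "year", "level", "rate",
                        if (!is.null(w)) "weight")])
  } else {
    w <- attr(src, "weights")
    if (!is.null(w)) out$weight <- w[out$level]
  }
  external_rate_source(out)
}

#' Deprivation-level to overall mortality rate ratios
#'
#' For each (sex, age[, year]) stratum, divides each of the five level rates
#' by the overall rate of the stratum.  When the source carries no overall
#' rates they are derived as the `level_weights`-weighted mean of the level
#' rates.  Strata where the overall rate and all level rates are zero yield
#' ratios of 1.
#'
#' @param src an `external_rate_source` with L = 5.
#' @return A `rate_ratio_table`: data.frame `sex, age[, year], quintile, rr`
#'   with attribute `has_year`.
#' @export
compute_rate_ratios <- function(src) {
  stopifnot(inherits(src, "external_rate_source"))
  if (attr(src, "L") != 5)
    stop("compute_rate_ratios requires a 5-level source; aggregate first")
  has_year <- attr(src, "has_year")
  k <- src_key(src, has_year)
  ov <- attr(src, "overall")
  if (!is.null(ov)) {
    ov_rate <- ov$rate[match(k, src_key(ov, has_year))]
    if (anyNA(ov_rate))
      stop("overall rate missing for some strata of the source")
  } else {
    w <- attr(src, "weights")
    wl <- w[src$level]
    ov_map <- tapply(src$rate * wl, k, sum) / tapply(wl, k, sum)
    ov_rate <- as.numeric(ov_map[k])
  }
  rr <- src$rate / ov_rate
  zero <- ov_rate == 0
  if (any(zero)) {
    bad <- zero & src$rate > 0
    if (any(bad)) {
      i <- which(bad)[1]
      stop("overall rate is zero but level rate is positive at stratum sex=",
           src$sex[i], " age=", src$age[i],
           if (has_year) paste0(" year=", src$year[i]) else "")
    }
    rr[zero] <- 1
  }
  out <- src[, c("sex", "age", if (has_year) "year"), drop = FALSE]
  out$quintile <- src$level
  out$rr <- rr
  rownames(out) <- NULL
  structure(as.data.frame(out), has_year = has_year,
            class = c("rate_ratio_table", "data.frame"))
}

#' Extend a rate-ratio table over target calendar years
#'
#' Year-indexed ratio tables are completed over `target_years` by carrying
#' the last covered year's ratios forward and the first covered year's
#' backward (the latter reported via a message).  Year-free tables are
#' replicated over all target years.
#'
#' @param rrt a `rate_ratio_table`.
#' @param target_years integer vector of calendar years to cover.
#' @return A year-indexed `rate_ratio_table` covering `target_years`.
#' @export
extend_years <- function(rrt, target_years) {
  stopifnot(inherits(rrt, "rate_ratio_table"))
  if (length(target_years) == 0) stop("target_years must be non-empty")
  target_years <- sort(unique(as.integer(target_years)))
  has_year <- isTRUE(attr(rrt, "has_year"))
  if (!has_year) {
    out <- do.call(rbind, lapply(target_years, function(y) {
      d <- rrt; d$year <- y; d
    }))
  } else {
    cov <- sort(unique(rrt$year))
    pick <- pmin(pmax(target_years, min(cov)), max(cov))
    ## carry to nearest covered year (coverage is assumed contiguous over its
    ## own range; intermediate gaps also map to the nearest covered year)
    pick <- vapply(pick, function(y) cov[which.min(abs(cov - y))], numeric(1))
    if (any(target_years < min(cov)))
      message("rate ratios carried backward to year(s) ",
              paste(target_years[target_years < min(cov)], collapse = ", "))
    out <- do.call(rbind, Map(function(ty, sy) {
      d <- rrt[rrt$year == sy, , drop = FALSE]
      d$year <- ty
      d
    }, target_years, pick))
  }
  out <- out[order(out$sex, out$year, out$age, out$quintile),
             c("sex", "age", "year", "quintile", "rr")]
  rownames(out) <- NULL
  structure(out, has_year = TRUE,
            class = c("rate_ratio_table", "data.frame"))
}

#' Simulate a deprivation-stratified life table by rate-ratio transfer
#'
#' For every stratum (sex, age, year, region) of the unstratified base table
#' and every quintile d, the simulated rate is the base rate multiplied by
#' the external source's rate ratio `rr(sex, age[, year], d)`.  Ratio tables
#' on a coarser age grid than the base table are expanded by nearest-age
#' matching (reported via a message); year-indexed tables must cover (or be
#' extended over, see [extend_years()]) the base table's years.
#'
#' @param base an unstratified `life_table`.
#' @param rrt a `rate_ratio_table`.
#' @return A deprivation-stratified `life_table`.
#' @export
apply_rate_ratios <- function(base, rrt) {
  stopifnot(inherits(base, "life_table"), inherits(rrt, "rate_ratio_table"))
  if (base$stratified)
    stop("base life table must be unstratified")
  has_year <- isTRUE(attr(rrt, "has_year"))
  rr_ages <- sort(unique(rrt$age))
  if (!all(base$ages %in% rr_ages))
    message("rate-ratio age grid coarser than the life table: ",
            "nearest-age matching applied")
  age_map <- vapply(base$ages, function(a) rr_ages[which.min(abs(rr_ages - a))],
                    numeric(1))
  if (has_year) {
    rr_years <- sort(unique(rrt$year))
    if (!all(base$years %in% rr_years))
      stop("rate-ratio years do not cover the base table years; ",
           "use extend_years() first")
  }
  kq <- function(sex, age, year, q)
    paste(sex, age, if (has_year) year else 0, q, sep = "\r")
  rr_lookup <- rrt$rr
  names(rr_lookup) <- kq(rrt$sex, rrt$age, if (has_year) rrt$year else 0,
                         rrt$quintile)
  bdf <- as.data.frame(base)
  out <- do.call(rbind, lapply(1:5, function(d) {
    key <- kq(bdf$sex, age_map[match(bdf$age, base$ages)], bdf$year, d)
    rr <- unname(rr_lookup[key])
    if (anyNA(rr)) {
      i <- which(is.na(rr))[1]
      stop("missing rate ratio for stratum sex=", bdf$sex[i], " age=",
           bdf$age[i], " year=", bdf$year[i], " quintile=", d)
    }
    data.frame(sex = bdf$sex, age = bdf$age, year = bdf$year,
               region = bdf$region, quintile = d, rate = bdf$rate * rr)
  }))
  life_table(out)
}
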