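#' @export
print.excess_fit <- function(x, ...) {
  forms <- c("1 (no EDI effect)", "2 (proportional EDI effect)",
             "3 (time-dependent EDI effect)",
             "4 (time- and/or age-dependent EDI effect)")
  cat("Penalized excess-hazard fit, form", forms[x$form], "\n")
  cat(sprintf("  n = %d, events = %d, coefficients = %d, EDF = %.2f\n",
              x$n, x$n_events, length(x$coefficients), x$edf))
  cat(sprintf("  log-likelihood = %.3f, AICc = %.3f\n", x$loglik, x$aicc))
  cat("  smoothing multipliers:", paste(format(x$lambda, digits = 3),
                                        collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.excess_fit <- function(object, ...) {
  out <- list(fit = object,
              se = sqrt(pmax(diag(object$V), 0)))
  class(out) <- "summary.excess_fit"
  out
}

#' @export
print.summary.excess_fit <- function(x, ...) {
  print(x$fit)
  cat("  coefficient range: [", format(min(x$fit$coefficients), digits = 3),
      ", ", format(max(x$fit$coefficients), digits = 3), "]\n", sep = "")
  invisible(x)
}

#' @export
coef.excess_fit <- function(object, ...) object$coefficients

#' @export
vcov.excess_fit <- function(object, ...) object$V

#' @export
logLik.excess_fit <- function(object, ...) {
  structure(object$loglik, df = object$edf, nobs = object$n,
            class = "logLik")
}

#' Predict the excess hazard at new covariate values
#'
#' @param object an `excess_fit`.
#' @param newdata data.frame with columns `time`, `age` and `edi` (the EDI
#'   column may be omitted for form-1 fits).
#' @param type `"hazard"` for `lambda_E`, `"log_hazard"` for its log.
#' @param se.fit return delta-method standard errors (on the log scale).
#' @param ... unused.
#' @return Numeric vector, or list with `fit` and `se.fit`.
#' @export
predict.excess_fit <- function(object, newdata,
                               type = c("hazard", "log_hazard"),
                               se.fit = FALSE, ...) {
  type <- match.arg(type)
  edi <- if ("edi" %in% names(newdata)) newdata$edi else rep(0, nrow(newdata))
  X <- build_design(object$spec, newdata$time, newdata$age, edi)
  eta <- drop(X %*% object$coefficients)
  fit <- if (type == "hazard") exp(eta) else eta
  if (!se.fit) return(fit)
  se <- sqrt(pmax(rowSums((X %*% object$V) * X), 0))
  list(fit = fit, se.fit = se)
}

## delta-method EHR with CI between two design points
ehr_contrast <- function(fit, X1, X0) {
  D <- X1 - X0
  logehr <- drop(D %*% fit$coefficients)
  se <- sqrt(pmax(rowSums((D %*% fit$V) * D), 0))
  data.frame(ehr = exp(logehr), lo = exp(logehr - 1.96 * se),
             hi = exp(logehr + 1.96 * se))
}

#' Excess-hazard ratio as a function of the EDI score
#'
#' `EHR(e) = lambda_E(t, age, e) / lambda_E(t, age, ref_edi)` at fixed
#' follow-up time and age, with a delta-method 95% CI on the log scale.
#' The conventional reference is the 10th percentile of the national EDI
#' distribution (-3.9).
#'
#' @param fit an `excess_fit`.
#' @param t_fixed,age_fixed follow-up time (years) and age at which the
#'   hazard is evaluated.
#' @param ref_edi reference EDI score (EHR = 1 there).
#' @param edi_grid abscissa; defaults to 50 points over the observed EDI
#'   range.
#' @return data.frame of class `ehr_curve`: `edi`, `ehr`, `lo`, `hi`.
#' @export
ehr_vs_edi <- function(fit, t_fixed = 1, age_fixed = 65, ref_edi = -3.9,
                       edi_grid = NULL) {
  stopifnot(inherits(fit, "excess_fit"))
  if (is.null(edi_grid))
    edi_grid <- seq(fit$edi_range[1], fit$edi_range[2], length.out = 50)
  ng <- length(edi_grid)
  X1 <- build_design(fit$spec, rep(t_fixed, ng), rep(age_fixed, ng), edi_grid)
  X0 <- build_design(fit$spec, rep(t_fixed, ng), rep(age_fixed, ng),
                     rep(ref_edi, ng))
  out <- cbind(data.frame(edi = edi_grid), ehr_contrast(fit, X1, X0))
  structure(out, t_fixed = t_fixed, age_fixed = age_fixed, ref = ref_edi,
            class = c("ehr_curve", "data.frame"))
}

#' Excess-hazard ratio p90 vs p10 of EDI over follow-up time
#'
#' `EHR(t; age) = lambda_E(t, age, p90) / lambda_E(t, age, p10)` with
#' delta-method 95% CI, evaluated at one or more ages (conventionally the
#' cohort age quartiles).  Forms 1-2 give time-constant curves; form 3
#' varies in time; form 4 in time and age.
#'
#' @param fit an `excess_fit`.
#' @param time_grid follow-up times (years).
#' @param ages ages at which to evaluate the curve.
#' @param p90,p10 EDI scores contrasted (defaults: national 90th and 10th
#'   percentiles, 4.4 and -3.9).
#' @return data.frame of class `ehr_curve`: `time`, `age`, `ehr`, `lo`,
#'   `hi`.
#' @export
ehr_p90_p10_over_time <- function(fit, time_grid = seq(0.05, 5, by = 0.05),
                                  ages = 65, p90 = 4.4, p10 = -3.9) {
  stopifnot(inherits(fit, "excess_fit"))
  out <- do.call(rbind, lapply(ages, function(a) {
    ng <- length(time_grid)
    X1 <- build_design(fit$spec, time_grid, rep(a, ng), rep(p90, ng))
    X0 <- build_design(fit$spec, time_grid, rep(a, ng), rep(p10, ng))
    cbind(data.frame(time = time_grid, age = a), ehr_contrast(fit, X1, X0))
  }))
  structure(out, p90 = p90, p10 = p10,
            class = c("ehr_curve", "data.frame"))
}

#' @export
plot.excess_fit <- function(x, t_fixed = 1, age_fixed = 65, ...) {
  if (x$form == 1) {
    tg <- seq(0.02, x$config$t_trunc, length.out = 100)
    h <- predict(x, data.frame(time = tg, age = age_fixed, edi = 0))
    graphics::plot(tg, h, type = "l", xlab = "Years since diagnosis",
                   ylab = "Excess hazard", ...)
  } else {
    cv <- ehr_vs_edi(x, t_fixed = t_fixed, age_fixed = age_fixed)
    graphics::plot(cv$edi, cv$ehr, type = "l", xlab = "EDI score",
                   ylab = "Excess hazard ratio",
                   ylim = range(cv$lo, cv$hi, finite = TRUE), ...)
    graphics::lines(cv$edi, cv$lo, lty = 3)
    graphics::lines(cv$edi, cv$hi, lty = 3)
    graphics::abline(h = 1, col = "grey")
  }
  invisible(x)
}
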