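#' Read / write patient cohorts
#'
#' Delimited files with header
#' `id,sex,age_dx,year_dx,region,edi,quintile,time,status`.
#'
#' @param path file path.
#' @return `read_cohort`: a validated cohort data.frame.
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_cohort(df)
  df
}

#' @rdname read_cohort
#' @param cohort a cohort data.frame.
#' @export
write_cohort <- function(cohort, path) {
  validate_cohort(cohort)
  utils::write.csv(cohort, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Compare net-survival analyses under alternative life tables
#'
#' Runs, on one cohort, the non-parametric arm (age-standardized net
#' survival per deprivation quintile and the Q1-Q5 gap at each horizon) and
#' optionally the flexible arm (corrected-AIC selection among the four
#' deprivation-effect forms, plus EHR curves) once with the main
#' (unstratified) life table and once with each simulated
#' deprivation-stratified table, and classifies the concordance of each
#' sensitivity analysis against the main one.
#'
#' Classification (declared operationalization, in order of precedence):
#' `inversed` - the 5-year gap changes sign with non-overlapping CIs;
#' `inconsistent` - the selected form changes to or from "no effect" (or,
#' with the model arm disabled, the gap CIs are disjoint without a sign
#' flip and the sensitivity gap is not smaller);
#' `consistent` - same selected form and overlapping gap CIs, without a
#' smaller sensitivity gap;
#' `attenuated` - same sign but a smaller absolute sensitivity gap.
#'
#' @param cohort a cohort data.frame (see [read_cohort()]).
#' @param lt_main the original unstratified [life_table()].
#' @param lt_sims named list of deprivation-stratified life tables.
#' @param horizons gap horizons in years (the last one drives the
#'   classification).
#' @param config an [excess_basis_config()] for the flexible arm.
#' @param do_model run the flexible arm (slower).
#' @param ehr_time_ages ages for the EHR-over-time curves (defaults to the
#'   cohort age quartiles).
#' @return Object of class `lt_comparison`.
#' @export
run_comparison <- function(cohort, lt_main, lt_sims, horizons = c(1, 5),
                           config = excess_basis_config(), do_model = TRUE,
                           ehr_time_ages = NULL) {
  validate_cohort(cohort)
  stopifnot(inherits(lt_main, "life_table"))
  if (lt_main$stratified)
    stop("lt_main must be unstratified")
  if (is.null(names(lt_sims)) || any(names(lt_sims) == ""))
    stop("lt_sims must be a named list")
  if (anyDuplicated(names(lt_sims))) stop("duplicate analysis labels")
  for (nm in names(lt_sims)) {
    if (!inherits(lt_sims[[nm]], "life_table") || !lt_sims[[nm]]$stratified)
      stop("sensitivity life table '", nm, "' must be deprivation-stratified")
  }
  if (is.null(ehr_time_ages))
    ehr_time_ages <- unname(stats::quantile(cohort$age_dx, c(0.25, 0.5, 0.75)))

  tables <- c(list(main = lt_main), lt_sims)
  analyses <- lapply(names(tables), function(lab) {
    lt <- tables[[lab]]
    gaps <- lapply(horizons, function(h)
      deprivation_gap(cohort, lt, horizon = h))
    names(gaps) <- paste0("h", horizons)
    asns <- do.call(rbind, lapply(1:5, function(q) {
      sub <- cohort[cohort$quintile == q, , drop = FALSE]
      if (nrow(sub) == 0) return(NULL)
      f <- age_standardized_ns(sub, lt, eval_times = horizons)
      data.frame(quintile = q, time = f$time, ns = f$ns,
                 se = sqrt(f$ns_var))
    }))
    model <- NULL; model_error <- NULL
    if (do_model) {
      model <- tryCatch(select_model(cohort, lt, config = config),
                        error = function(e) e)
      if (inherits(model, "error")) {
        model_error <- conditionMessage(model)
        model <- NULL
      }
    }
    ehr_edi <- ehr_time <- NULL
    if (!is.null(model)) {
      med_age <- stats::median(cohort$age_dx)
      ehr_edi <- tryCatch(ehr_vs_edi(model$best, t_fixed = 1,
                                     age_fixed = med_age),
                          error = function(e) NULL)
      ehr_time <- tryCatch(ehr_p90_p10_over_time(model$best,
                                                 ages = ehr_time_ages),
                           error = function(e) NULL)
    }
    list(label = lab, gaps = gaps, asns = asns, selection = model,
         model_error = model_error, ehr_edi = ehr_edi, ehr_time = ehr_time)
  })
  names(analyses) <- names(tables)

  hkey <- paste0("h", horizons[length(horizons)])
  main <- analyses$main
  classification <- lapply(names(lt_sims), function(lab) {
    classify_concordance(main$gaps[[hkey]], analyses[[lab]]$gaps[[hkey]],
                         form_main = if (!is.null(main$selection))
                           main$selection$form else NA,
                         form_sens = if (!is.null(analyses[[lab]]$selection))
                           analyses[[lab]]$selection$form else NA)
  })
  names(classification) <- names(lt_sims)

  structure(list(analyses = analyses, classification = classification,
                 horizons = horizons),
            class = "lt_comparison")
}

ci_overlap <- function(a, b) a$ci[1] <= b$ci[2] && b$ci[1] <= a$ci[2]

classify_concordance <- function(gap_main, gap_sens, form_main = NA,
                                 form_sens = NA) {
  sign_flip <- sign(gap_main$gap) != sign(gap_sens$gap) &&
    gap_main$gap != 0 && gap_sens$gap != 0
  if (sign_flip && !ci_overlap(gap_main, gap_sens)) return("inversed")
  if (!is.na(form_main) && !is.na(form_sens) &&
      xor(form_main == 1, form_sens == 1)) return("inconsistent")
  smaller <- abs(gap_sens$gap) < abs(gap_main$gap)
  same_form <- !is.na(form_main) && !is.na(form_sens) &&
    form_main == form_sens
  if (ci_overlap(gap_main, gap_sens) && (same_form || is.na(form_main)) &&
      !smaller) return("consistent")
  if (smaller) return("attenuated")
  "inconsistent"
}

#' @export
print.lt_comparison <- function(x, ...) {
  hkey <- paste0("h", x$horizons[length(x$horizons)])
  cat("Life-table sensitivity comparison (",
      x$horizons[length(x$horizons)], "-year gaps)\n", sep = "")
  for (lab in names(x$analyses)) {
    a <- x$analyses[[lab]]
    g <- a$gaps[[hkey]]
    cat(sprintf("  %-10s gap = %6.2f pp (%.2f; %.2f)", lab, g$gap,
                g$ci[1], g$ci[2]))
    if (!is.null(a$selection))
      cat("  selected form:", a$selection$form)
    if (lab != "main" && lab %in% names(x$classification))
      cat("  [", x$classification[[lab]], "]", sep = "")
    cat("\n")
  }
  invisible(x)
}

#' Write / read a comparison report
#'
#' `write_report` writes `report.json` (gaps, ASNS, selected forms, AICc
#' tables, classification) plus one delimited file per EHR curve into
#' `path`; ordering is deterministic.  `read_report` reads the JSON summary
#' back.
#'
#' @param report an `lt_comparison`.
#' @param path output directory (created if absent).
#' @param strict error (after writing) if any model arm failed.
#' @return `write_report`: the directory path, invisibly.
#' @export
write_report <- function(report, path, strict = FALSE) {
  stopifnot(inherits(report, "lt_comparison"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  summ <- list(schema = "depnetsurv-report/1",
               horizons = report$horizons,
               analyses = lapply(report$analyses, function(a) {
                 Filter(Negate(is.null),
                        list(label = a$label,
                             gaps = lapply(a$gaps, function(g)
                               list(gap = g$gap, se = g$se, ci_low = g$ci[1],
                                    ci_high = g$ci[2], horizon = g$horizon,
                                    n_q1 = g$n[1], n_q5 = g$n[2])),
                             asns = a$asns,
                             selected_form = if (!is.null(a$selection))
                               a$selection$form else NULL,
                             aicc = if (!is.null(a$selection))
                               as.list(a$selection$aicc) else NULL,
                             model_error = a$model_error))
               }),
               classification = report$classification)
  jsonlite::write_json(summ, file.path(path, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  for (lab in names(report$analyses)) {
    a <- report$analyses[[lab]]
    if (!is.null(a$ehr_edi))
      utils::write.csv(as.data.frame(a$ehr_edi),
                       file.path(path, paste0("ehr_edi_", lab, ".csv")),
                       row.names = FALSE, quote = FALSE)
    if (!is.null(a$ehr_time))
      utils::write.csv(as.data.frame(a$ehr_time),
                       file.path(path, paste0("ehr_time_", lab, ".csv")),
                       row.names = FALSE, quote = FALSE)
  }
  if (strict) {
    errs <- Filter(Negate(is.null),
                   lapply(report$analyses, `[[`, "model_error"))
    if (length(errs))
      stop("model arm failed in analysis: ",
           paste(names(errs), collapse = ", "))
  }
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  jsonlite::read_json(file.path(path, "report.json"), simplifyVector = TRUE)
}
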