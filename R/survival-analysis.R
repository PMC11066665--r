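# Endpoint-specific time-to-event construction (with prevalent-case
# exclusion) and Cox proportional-hazards fits, including the forward
# stepwise polygenic-score scan within Cox models and the first-year
# adherence analysis among treated cases.

#' Metabolic endpoint definitions
#'
#' ICD-10 code-prefix sets for the six endpoints. `any_metabolic` is the
#' union of the other five. The code maps are configuration, not hard truth:
#' replace the list to use institution-specific sets.
#'
#' @return named list of character prefix vectors.
#' @export
endpoint_specs <- function() {
  specs <- list(
    T2D = "E11",
    hypercholesterolemia = "E78.0",
    essential_hypertension = "I10",
    CHD = paste0("I2", 0:5),
    CVD = c(paste0("I6", 0:9), "I21"))
  specs$any_metabolic <- unique(unlist(specs))
  specs
}

matches_prefix <- function(codes, prefixes) {
  out <- rep(FALSE, length(codes))
  for (p in prefixes) out <- out | startsWith(codes, p)
  out
}

who_bmi_category <- function(bmi) {
  cut(bmi, breaks = c(-Inf, 18.5, 25, 30, Inf),
      labels = c("underweight", "normal", "overweight", "obese"),
      right = FALSE)
}

#' Build endpoint-specific survival records from a matched cohort
#'
#' One row per eligible person: time from the index date (case onset,
#' inherited by matched controls) to the first qualifying diagnosis, death or
#' end of follow-up, whichever comes first. Persons with a qualifying
#' diagnosis on or before the index date are excluded by the prevalence rule;
#' persons with no follow-up after index are excluded too. Bookkeeping is
#' total: eligible + prevalent + no-followup counts sum to the cohort size.
#'
#' @param matched a [match_controls()] result.
#' @param persons,diagnoses validated tables.
#' @param endpoint endpoint name from [endpoint_specs()], or a character
#'   vector of ICD-10 prefixes.
#' @param measurements optional validated measurements (adds `smoking` and
#'   WHO `bmi_cat` covariates).
#' @param prs optional polygenic-score table (joins score columns).
#' @return object of class `survival_records`: data.frame with `person_id`,
#'   `group`, `time` (years), `event`, covariates; attributes `endpoint` and
#'   `counts`.
#' @export
build_survival <- function(matched, persons, diagnoses, endpoint,
                           measurements = NULL, prs = NULL) {
  prefixes <- if (is.character(endpoint) && length(endpoint) == 1L &&
                  endpoint %in% names(endpoint_specs())) {
    endpoint_specs()[[endpoint]]
  } else endpoint
  ep_name <- if (is.character(endpoint) && length(endpoint) == 1L) endpoint else "custom"

  cohort <- rbind(
    data.frame(person_id = unique(matched$case_id), group = "case",
               index_date = matched$index_date[match(unique(matched$case_id),
                                                     matched$case_id)],
               stringsAsFactors = FALSE),
    data.frame(person_id = matched$control_id, group = "control",
               index_date = matched$index_date, stringsAsFactors = FALSE))

  dx <- diagnoses[matches_prefix(diagnoses$icd10, prefixes), , drop = FALSE]
  first_ev <- tapply(as_day(dx$event_date), dx$person_id, min)

  p <- persons[match(cohort$person_id, persons$person_id), ]
  index <- as_day(cohort$index_date)
  end_day <- as_day(p$followup_end)
  dd <- as_day(p$death_date)
  end_day <- ifelse(!is.na(dd), pmin(end_day, dd), end_day)
  ev_day <- unname(first_ev[cohort$person_id])

  prevalent <- !is.na(ev_day) & ev_day <= index
  stop_day <- pmin(ifelse(is.na(ev_day), Inf, ev_day), end_day)
  no_followup <- !prevalent & stop_day <= index
  keep <- !prevalent & !no_followup

  rec <- data.frame(person_id = cohort$person_id[keep],
                    group = cohort$group[keep],
                    time = days_to_years(stop_day[keep] - index[keep]),
                    event = as.integer(!is.na(ev_day[keep]) &
                                         ev_day[keep] <= end_day[keep]),
                    sex = p$sex[keep],
                    birth_year = as.integer(format(p$birth_date[keep], "%Y")),
                    stringsAsFactors = FALSE)
  if (!is.null(measurements)) {
    smk <- reduce_smoking(measurements)
    rec$smoking <- smk$smoking[match(rec$person_id, smk$person_id)]
    bmi <- measurements[measurements$kind == "bmi", ]
    med_bmi <- tapply(as.numeric(bmi$value), bmi$person_id, stats::median)
    rec$bmi_cat <- who_bmi_category(unname(med_bmi[rec$person_id]))
  }
  if (!is.null(prs)) {
    idx <- match(rec$person_id, prs$person_id)
    rec <- cbind(rec, prs[idx, setdiff(names(prs), "person_id"), drop = FALSE])
  }
  rownames(rec) <- NULL
  counts <- c(total = nrow(cohort), eligible = sum(keep),
              prevalent_excluded = sum(prevalent),
              no_followup = sum(no_followup),
              events_case = sum(rec$event[rec$group == "case"]),
              events_control = sum(rec$event[rec$group == "control"]))
  structure(rec, endpoint = ep_name, counts = counts,
            class = c("survival_records", "data.frame"))
}

#' @export
print.survival_records <- function(x, ...) {
  ct <- attr(x, "counts")
  cat("Survival records for endpoint '", attr(x, "endpoint"), "': ",
      ct["eligible"], " eligible (", ct["prevalent_excluded"],
      " prevalent excluded), events ", ct["events_case"], " case / ",
      ct["events_control"], " control\n", sep = "")
  invisible(x)
}

#' Fit a Cox proportional-hazards model to survival records
#'
#' Partial-likelihood fit with Efron tie handling via [survival::coxph()],
#' reporting hazard ratios with 95% confidence intervals, optionally followed
#' by a forward-stepwise scan of polygenic scores added on top of the model
#' terms (entry threshold Bonferroni-corrected for the endpoint family).
#'
#' @param records a [build_survival()] result (or any data.frame with `time`
#'   and `event`).
#' @param terms character vector of model terms (default `group`).
#' @param prs_candidates optional candidate score names for the stepwise scan.
#' @param alpha entry threshold for the stepwise scan; default 0.05/6 for the
#'   six-endpoint family.
#' @return object of class `cox_fit`: list with the `survival::coxph` fit,
#'   a hazard-ratio `table`, and when scanned a `stepwise` element with
#'   marginal scan and inclusion trace.
#' @export
fit_cox <- function(records, terms = "group", prs_candidates = NULL,
                    alpha = 0.05 / 6) {
  if (!any(records$event == 1)) {
    stop("no events in the records; refusing to fit", call. = FALSE)
  }
  for (g in unique(records$group %||% "all")) {
    if (!is.null(records$group) && "group" %in% terms &&
        sum(records$event[records$group == g]) == 0) {
      stop("zero events in group '", g, "'; fit refused", call. = FALSE)
    }
  }
  base_fit <- cox_refit(records, terms)
  out <- list(fit = base_fit, table = cox_table(base_fit), terms = terms)
  if (!is.null(prs_candidates)) {
    marginal <- do.call(rbind, lapply(prs_candidates, function(tr) {
      cox_term_row(records, c(terms, tr), tr)
    }))
    marginal$sig_bonferroni <- !is.na(marginal$p) & marginal$p < alpha
    marginal$sig_nominal <- !is.na(marginal$p) & marginal$p < 0.05
    included <- character(0)
    remaining <- prs_candidates
    trace <- data.frame(step = integer(0), term = character(0), p = numeric(0))
    repeat {
      if (!length(remaining)) break
      scan <- do.call(rbind, lapply(remaining, function(tr) {
        cox_term_row(records, c(terms, included, tr), tr)
      }))
      scan <- scan[order(scan$p, scan$term), ]
      best <- scan[!is.na(scan$p), ][1, ]
      if (!nrow(best) || is.na(best$p) || best$p >= alpha) break
      included <- c(included, best$term)
      remaining <- setdiff(remaining, best$term)
      trace <- rbind(trace, data.frame(step = length(included),
                                       term = best$term, p = best$p))
    }
    final_fit <- cox_refit(records, c(terms, included))
    out$stepwise <- list(marginal = marginal, trace = trace,
                         included = included, alpha = alpha,
                         final = cox_table(final_fit))
  }
  class(out) <- "cox_fit"
  out
}

cox_refit <- function(records, terms) {
  f <- stats::as.formula(paste("survival::Surv(time, event) ~",
                               paste(terms, collapse = " + ")))
  survival::coxph(f, data = records, ties = "efron")
}

cox_table <- function(fit) {
  s <- summary(fit)
  co <- s$coefficients
  data.frame(term = rownames(co), coef = co[, "coef"],
             hr = exp(co[, "coef"]),
             ci_lo = exp(co[, "coef"] - 1.96 * co[, "se(coef)"]),
             ci_hi = exp(co[, "coef"] + 1.96 * co[, "se(coef)"]),
             se = co[, "se(coef)"], p = co[, "Pr(>|z|)"],
             row.names = NULL, stringsAsFactors = FALSE)
}

cox_term_row <- function(records, terms, term) {
  res <- tryCatch({
    tab <- cox_table(cox_refit(records, terms))
    row <- tab[grepl(paste0("^", term), tab$term), , drop = FALSE][1, ]
    data.frame(term = term, estimate = row$coef, se = row$se, p = row$p,
               hr = row$hr, ci_lo = row$ci_lo, ci_hi = row$ci_hi,
               status = "ok", stringsAsFactors = FALSE)
  }, error = function(e) {
    data.frame(term = term, estimate = NA_real_, se = NA_real_, p = NA_real_,
               hr = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
               status = conditionMessage(e), stringsAsFactors = FALSE)
  }, warning = function(w) {
    data.frame(term = term, estimate = NA_real_, se = NA_real_, p = NA_real_,
               hr = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
               status = conditionMessage(w), stringsAsFactors = FALSE)
  })
  res
}

#' @export
print.cox_fit <- function(x, ...) {
  cat("Cox proportional-hazards fit (Efron ties)\n")
  print(x$table, digits = 3)
  if (!is.null(x$stepwise)) {
    cat("Stepwise-included scores:",
        if (length(x$stepwise$included)) paste(x$stepwise$included, collapse = ", ")
        else "(none)", "\n")
  }
  invisible(x)
}

#' First-year adherence and endpoint incidence among treated cases
#'
#' Cox fit restricted to schizophrenia cases with at least one purchase and
#' at least one year of potential follow-up, with first-treatment-year
#' adherence (`pdc_1year`) as the exposure of interest.
#'
#' @param records a [build_survival()] result.
#' @param profiles a [derive_profiles()] result.
#' @param covariates additional model terms present in `records`.
#' @param per_sd standardise the adherence term to unit SD (default TRUE).
#' @return a `cox_fit` object.
#' @export
adherence_survival <- function(records, profiles, covariates = c("sex", "birth_year"),
                               per_sd = TRUE) {
  cases <- records[records$group == "case", , drop = FALSE]
  idx <- match(cases$person_id, profiles$person_id)
  cases$pdc_1year <- profiles$pdc_1year[idx]
  treated <- !is.na(cases$pdc_1year) & profiles$n_purchases[idx] >= 1 &
    cases$time > 0
  cases <- cases[treated, , drop = FALSE]
  if (stats::sd(cases$pdc_1year) == 0) {
    stop("pdc_1year is constant across cases; singular term", call. = FALSE)
  }
  if (per_sd) cases$pdc_1year <- as.numeric(scale(cases$pdc_1year))
  fit_cox(cases, terms = c("pdc_1year", covariates))
}
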