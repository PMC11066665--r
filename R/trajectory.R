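# BMI-trajectory analysis: a nested ladder of linear mixed models (random
# intercept and random age slope per subject, maximum likelihood so that
# fixed-effect structures can be compared by likelihood-ratio tests),
# scenario-based population-level trajectory prediction with 83% confidence
# bands, decade BMI gain, and the treatment-intensity model among cases.

AGE_CENTER <- 27

#' Assemble the BMI modelling frame
#'
#' Joins BMI measurements with person-level covariates, case status, the BMI
#' polygenic score, genotype PCs, reduced smoking status and (optionally)
#' windowed treatment exposure at each measurement. Age is centred at 27
#' years (the typical onset age) for numerical stability of the treatment
#' polynomial.
#'
#' @param measurements validated measurements data.frame.
#' @param persons validated persons data.frame.
#' @param case_ids person ids of schizophrenia cases.
#' @param prs polygenic-score table.
#' @param windowed optional [derive_windowed_exposure()] result; when absent,
#'   treatment years are zero for everyone.
#' @param drop_missing_smoking drop rows with unknown smoking (default TRUE).
#' @return data.frame with numeric modelling columns (`bmi`, `age_c`,
#'   `sex_male`, `smoking_ever`, `bmi_prs`, PCs, `case`, `case_age`, `ty`,
#'   and windowed `pdc_window` / `median_cpz_window_mg` when supplied).
#' @export
build_bmi_frame <- function(measurements, persons, case_ids, prs,
                            windowed = NULL, drop_missing_smoking = TRUE) {
  bmi <- measurements[measurements$kind == "bmi", , drop = FALSE]
  p <- persons[match(bmi$person_id, persons$person_id), ]
  smk <- reduce_smoking(measurements)
  out <- data.frame(
    person_id = bmi$person_id,
    bmi = as.numeric(bmi$value),
    age_c = days_to_years(as_day(bmi$measure_date) - as_day(p$birth_date)) - AGE_CENTER,
    sex_male = as.numeric(p$sex == "male"),
    case = as.numeric(bmi$person_id %in% case_ids),
    stringsAsFactors = FALSE)
  smoking <- smk$smoking[match(bmi$person_id, smk$person_id)]
  out$smoking_ever <- as.numeric(smoking == "ever")
  idx <- match(bmi$person_id, prs$person_id)
  out$bmi_prs <- prs$BMI[idx]
  for (pc in pc_names()) out[[pc]] <- prs[[pc]][idx]
  out$case_age <- out$case * out$age_c
  if (!is.null(windowed)) {
    key <- paste(windowed$person_id, format(windowed$anchor))
    m <- match(paste(bmi$person_id, format(bmi$measure_date)), key)
    out$ty <- ifelse(is.na(m), 0, windowed$ty_supply_to_anchor[m])
    out$pdc_window <- windowed$pdc_window[m]
    out$median_cpz_window_mg <- windowed$median_cpz_window_mg[m]
  } else {
    out$ty <- 0
  }
  if (drop_missing_smoking) out <- out[!is.na(out$smoking_ever), , drop = FALSE]
  out <- out[!is.na(out$bmi_prs), , drop = FALSE]
  rownames(out) <- NULL
  out
}

ty_basis_columns <- function(ty, degree, basis = NULL) {
  if (is.null(basis)) {
    if (stats::var(ty) == 0) return(list(cols = NULL, basis = NULL))
    basis <- stats::poly(ty, degree = degree)
  }
  cols <- stats::predict(basis, ty)
  colnames(cols) <- paste0("TY", seq_len(ncol(cols)))
  list(cols = cols, basis = basis)
}

lmm_formula <- function(model, include_smoking, ty_degree, extra = character(0),
                        diagonal_re = FALSE) {
  fixed <- c("sex_male", if (include_smoking) "smoking_ever", "bmi_prs",
             pc_names(), "age_c", "case")
  if (model %in% c("interaction", "treatment")) fixed <- c(fixed, "case_age")
  if (model == "treatment") fixed <- c(fixed, paste0("TY", seq_len(ty_degree)))
  fixed <- c(fixed, extra)
  re <- if (diagonal_re) "(age_c || person_id)" else "(age_c | person_id)"
  stats::as.formula(paste("bmi ~", paste(c(fixed, re), collapse = " + ")))
}

#' Fit one BMI linear mixed model
#'
#' Random intercept and random age slope per subject; fixed effects per the
#' model rung: `baseline` (sex, smoking, BMI PRS, 10 PCs, age, case status),
#' `interaction` (adds case-by-age), `treatment` (adds an orthogonalised
#' polynomial of accumulated treatment years, default quartic). Fitted by
#' maximum likelihood so rungs are comparable by likelihood-ratio tests. A
#' singular random-effects covariance triggers a diagonal-structure refit
#' with a warning.
#'
#' @param data a [build_bmi_frame()] result.
#' @param model one of "baseline", "interaction", "treatment".
#' @param include_smoking include the smoking fixed effect (default TRUE).
#' @param ty_degree degree of the treatment-years polynomial (default 4).
#' @param extra_terms additional fixed-effect column names (used by the
#'   treatment-intensity analysis).
#' @return object of class `bmi_lmm`: list with the `lmerMod` fit, the model
#'   label, the orthogonal polynomial basis and fit metadata.
#' @export
fit_bmi_lmm <- function(data, model = c("baseline", "interaction", "treatment"),
                        include_smoking = TRUE, ty_degree = 4L,
                        extra_terms = character(0)) {
  model <- match.arg(model)
  basis <- NULL
  if (model == "treatment") {
    tb <- ty_basis_columns(data$ty, ty_degree)
    if (is.null(tb$cols)) {
      stop("treatment years are constant; treatment model unidentifiable",
           call. = FALSE)
    }
    basis <- tb$basis
    data <- cbind(data, tb$cols)
  }
  f <- lmm_formula(model, include_smoking, ty_degree, extra_terms)
  fit <- lme4::lmer(f, data = data, REML = FALSE,
                    control = lme4::lmerControl(calc.derivs = FALSE,
                                                check.conv.singular = "ignore"))
  if (lme4::isSingular(fit, tol = 1e-5)) {
    warning("singular random-effects covariance; refitting with diagonal structure")
    f2 <- lmm_formula(model, include_smoking, ty_degree, extra_terms,
                      diagonal_re = TRUE)
    fit <- lme4::lmer(f2, data = data, REML = FALSE,
                      control = lme4::lmerControl(calc.derivs = FALSE,
                                                  check.conv.singular = "ignore"))
  }
  structure(list(fit = fit, model = model, basis = basis,
                 ty_degree = ty_degree, include_smoking = include_smoking,
                 n_obs = nrow(data),
                 n_subjects = length(unique(data$person_id))),
            class = "bmi_lmm")
}

#' @export
print.bmi_lmm <- function(x, ...) {
  cat("BMI linear mixed model ('", x$model, "'): ", x$n_obs,
      " observations, ", x$n_subjects, " subjects, logLik ",
      round(as.numeric(stats::logLik(x$fit)), 1), "\n", sep = "")
  invisible(x)
}

#' Fit the nested model ladder and compare by likelihood-ratio tests
#'
#' Fits the requested rungs (all by maximum likelihood, identical random
#' structure) and compares successive rungs with likelihood-ratio tests whose
#' degrees of freedom equal the fixed-parameter difference.
#'
#' @inheritParams fit_bmi_lmm
#' @param models ordered character vector of nested rungs.
#' @return list with `fits` (named list of `bmi_lmm`) and `comparison`
#'   (data.frame: model, npar, logLik, chisq, df, p vs the previous rung).
#' @export
fit_ladder <- function(data, models = c("baseline", "interaction", "treatment"),
                       include_smoking = TRUE, ty_degree = 4L) {
  fits <- lapply(models, function(m) {
    fit_bmi_lmm(data, m, include_smoking, ty_degree)
  })
  names(fits) <- models
  ll <- vapply(fits, function(f) as.numeric(stats::logLik(f$fit)), numeric(1))
  np <- vapply(fits, function(f) attr(stats::logLik(f$fit), "df"), numeric(1))
  chisq <- c(NA, pmax(2 * diff(ll), 0))
  dfd <- c(NA, diff(np))
  pval <- ifelse(is.na(chisq), NA,
                 stats::pchisq(chisq, dfd, lower.tail = FALSE))
  list(fits = fits,
       comparison = data.frame(model = models, npar = np, logLik = ll,
                               chisq = chisq, df = dfd, p = pval,
                               row.names = NULL))
}

#' Define a trajectory scenario
#'
#' @param group "control", "untreated_case" or "treated_case".
#' @param sex "male" or "female".
#' @param smoking "ever" or "never".
#' @param bmi_prs_sd BMI polygenic score in SD units (-1, 0, 1 for the
#'   low/average/high panels).
#' @param treatment_days_per_year days of antipsychotic supply per year for
#'   treated scenarios (default 180); must be 0 otherwise.
#' @param start_age age at scenario start (default 27).
#' @param horizon_years prediction horizon (default 10).
#' @param step age-grid step in years (default 0.5).
#' @return list of class `trajectory_scenario`.
#' @export
trajectory_scenario <- function(group = c("control", "untreated_case", "treated_case"),
                                sex = "male", smoking = "ever", bmi_prs_sd = 0,
                                treatment_days_per_year = if (match.arg(group) == "treated_case") 180L else 0L,
                                start_age = 27, horizon_years = 10, step = 0.5) {
  group <- match.arg(group)
  if (group != "treated_case" && treatment_days_per_year != 0) {
    stop("treatment days must be zero for untreated scenarios", call. = FALSE)
  }
  structure(list(group = group, sex = sex, smoking = smoking,
                 bmi_prs_sd = bmi_prs_sd,
                 treatment_days_per_year = treatment_days_per_year,
                 start_age = start_age, horizon_years = horizon_years,
                 step = step),
            class = "trajectory_scenario")
}

#' Predict a population-level BMI trajectory with confidence band
#'
#' Random effects at zero; treatment years accumulate piecewise-linearly at
#' `treatment_days_per_year / 365.25` per year from the start age for treated
#' scenarios. The band comes from the fixed-effect covariance through the
#' linear predictor, at the normal quantile of `(1 + ci_level)/2`; the
#' default 83% level makes non-overlap of two independent bands an
#' approximate alpha = 0.05 test of equal means.
#'
#' @param fit a [fit_bmi_lmm()] result (interaction or treatment model).
#' @param scenario a [trajectory_scenario()].
#' @param ci_level confidence level (default 0.83).
#' @return object of class `trajectory_prediction`: data.frame (age, mean,
#'   lo, hi) with attribute `decade_gain` = prediction at the horizon minus
#'   prediction at the start.
#' @export
predict_trajectory <- function(fit, scenario, ci_level = 0.83) {
  stopifnot(inherits(fit, "bmi_lmm"), inherits(scenario, "trajectory_scenario"))
  ages <- seq(scenario$start_age, scenario$start_age + scenario$horizon_years,
              by = scenario$step)
  is_case <- scenario$group != "control"
  ty <- if (scenario$group == "treated_case") {
    (ages - scenario$start_age) * scenario$treatment_days_per_year / DAYS_PER_YEAR
  } else rep(0, length(ages))

  beta <- lme4::fixef(fit$fit)
  nd <- data.frame(`(Intercept)` = 1,
                   sex_male = as.numeric(scenario$sex == "male"),
                   smoking_ever = as.numeric(scenario$smoking == "ever"),
                   bmi_prs = scenario$bmi_prs_sd,
                   check.names = FALSE)
  nd <- nd[rep(1, length(ages)), , drop = FALSE]
  for (pc in pc_names()) nd[[pc]] <- 0
  nd$age_c <- ages - AGE_CENTER
  nd$case <- as.numeric(is_case)
  nd$case_age <- nd$case * nd$age_c
  if (fit$model == "treatment") {
    tb <- ty_basis_columns(ty, fit$ty_degree, fit$basis)
    nd <- cbind(nd, tb$cols)
  } else if (scenario$group == "treated_case") {
    stop("scenario has treatment but the fitted model has no treatment term",
         call. = FALSE)
  }
  missing_terms <- setdiff(names(beta), names(nd))
  if (length(missing_terms)) {
    stop("model term(s) absent from scenario design: ",
         paste(missing_terms, collapse = ", "), call. = FALSE)
  }
  X <- as.matrix(nd[, names(beta), drop = FALSE])
  mu <- unname(drop(X %*% beta))
  V <- as.matrix(stats::vcov(fit$fit))
  se <- sqrt(rowSums((X %*% V) * X))
  z <- stats::qnorm((1 + ci_level) / 2)
  out <- data.frame(age = ages, mean = mu, lo = mu - z * se, hi = mu + z * se)
  structure(out, decade_gain = mu[length(mu)] - mu[1],
            ci_level = ci_level, scenario = scenario,
            class = c("trajectory_prediction", "data.frame"))
}

#' Decade BMI gain of a predicted trajectory
#'
#' @param pred a [predict_trajectory()] result.
#' @return numeric: predicted BMI at the end of the horizon minus at the
#'   start.
#' @export
decade_gain <- function(pred) attr(pred, "decade_gain")

#' @export
print.trajectory_prediction <- function(x, ...) {
  sc <- attr(x, "scenario")
  cat("Predicted BMI trajectory (", sc$group, ", ", sc$sex, ", smoking ",
      sc$smoking, ", BMI PRS ", sc$bmi_prs_sd, " SD): gain over ",
      sc$horizon_years, " years = ", round(attr(x, "decade_gain"), 2),
      " BMI points\n", sep = "")
  invisible(x)
}

#' Age-wise non-overlap of two confidence bands
#'
#' Two means are declared different (at approximately alpha = 0.05 for 83%
#' bands on independent means) where the bands are disjoint.
#'
#' @param pred_a,pred_b [predict_trajectory()] results on the same age grid.
#' @return logical vector along the age grid.
#' @export
nonoverlap_test <- function(pred_a, pred_b) {
  if (!isTRUE(all.equal(pred_a$age, pred_b$age))) {
    stop("age grids differ", call. = FALSE)
  }
  pred_a$lo > pred_b$hi | pred_b$lo > pred_a$hi
}

#' Treatment-intensity effects on BMI among cases
#'
#' Mixed model restricted to schizophrenia cases with windowed exposure:
#' fixed effects for accumulated treatment years, look-back adherence,
#' standardised look-back median chlorpromazine-equivalent dose and the BMI
#' polygenic score (plus sex, smoking, age, PCs); random intercept and age
#' slope. Constant windowed terms are dropped with a warning.
#'
#' @param data a [build_bmi_frame()] result with windowed exposure columns,
#'   already restricted to cases (rows with `case == 1` are used).
#' @return list with `fit` (a `bmi_lmm`) and `effects` (rows for the four
#'   headline terms: dose, adherence, treatment years, BMI PRS).
#' @export
dose_adherence_effects <- function(data) {
  d <- data[data$case == 1 & !is.na(data$pdc_window) &
              !is.na(data$median_cpz_window_mg), , drop = FALSE]
  d$dose_std <- as.numeric(scale(d$median_cpz_window_mg))
  extra <- c("ty", "pdc_window", "dose_std")
  keep <- vapply(extra, function(v) stats::var(d[[v]]) > 0, logical(1))
  if (!all(keep)) {
    warning("dropping constant term(s): ", paste(extra[!keep], collapse = ", "))
    extra <- extra[keep]
  }
  d$case_age <- 0 # cases only: no case terms
  fit <- fit_bmi_lmm_terms(d, extra)
  co <- summary(fit$fit)$coefficients
  rows <- intersect(c("dose_std", "pdc_window", "ty", "bmi_prs"), rownames(co))
  list(fit = fit,
       effects = data.frame(term = rows, estimate = co[rows, 1],
                            se = co[rows, 2], row.names = NULL))
}

# Case-only intensity model: baseline covariates + explicit extra terms,
# no case/case_age columns (constant within cases).
fit_bmi_lmm_terms <- function(data, extra) {
  fixed <- c("sex_male", "smoking_ever", "bmi_prs", pc_names(), "age_c", extra)
  f <- stats::as.formula(paste("bmi ~", paste(c(fixed, "(age_c | person_id)"),
                                              collapse = " + ")))
  fit <- lme4::lmer(f, data = data, REML = FALSE,
                    control = lme4::lmerControl(calc.derivs = FALSE,
                                                check.conv.singular = "ignore"))
  structure(list(fit = fit, model = "intensity", basis = NULL,
                 ty_degree = NA, include_smoking = TRUE, n_obs = nrow(data),
                 n_subjects = length(unique(data$person_id))),
            class = "bmi_lmm")
}
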