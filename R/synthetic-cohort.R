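# Synthetic biobank-extract generator. Produces persons, dispensing records,
# diagnosis events, BMI/smoking measurements and a polygenic-score table with
# the statistical structure the downstream analyses assume, plus a truth
# record of every latent quantity, so each stage can be exercised and
# parameter-recovery-tested without access to restricted data.

#' Default correlation matrix of the fifteen polygenic scores
#'
#' Block structure mirroring the empirical clustering of polygenic scores:
#' lipids (TC/LDL/nonHDL strongly positive, HDL negative), blood pressure
#' (SBP-DBP), glycaemic traits (HbA1c-random glucose 0.43, HbA1c-fasting
#' glucose 0.05), and the adiposity/inflammation cluster (CRP-BMI 0.40,
#' CRP-T2D 0.32), with schizophrenia essentially uncorrelated but slightly
#' negative against BMI and CRP.
#'
#' @return symmetric positive-definite 15 x 15 matrix with unit diagonal.
#' @export
default_prs_correlation <- function() {
  traits <- prs_traits()
  R <- diag(length(traits))
  dimnames(R) <- list(traits, traits)
  set2 <- function(a, b, v) {
    R[a, b] <<- v
    R[b, a] <<- v
  }
  set2("TC", "LDL", 0.85); set2("TC", "nonHDL", 0.85); set2("LDL", "nonHDL", 0.85)
  set2("TC", "TG", 0.30); set2("LDL", "TG", 0.20); set2("nonHDL", "TG", 0.40)
  set2("HDL", "TG", -0.40); set2("HDL", "TC", -0.10); set2("HDL", "LDL", -0.15)
  set2("HDL", "nonHDL", -0.25)
  set2("SBP", "DBP", 0.70)
  set2("HbA1c", "RG", 0.43); set2("HbA1c", "FG", 0.05); set2("FG", "RG", 0.30)
  set2("T2D", "FG", 0.35); set2("T2D", "HbA1c", 0.30); set2("T2D", "RG", 0.25)
  set2("CRP", "BMI", 0.40); set2("CRP", "T2D", 0.32); set2("BMI", "T2D", 0.35)
  set2("HDL", "BMI", -0.30); set2("HDL", "T2D", -0.30); set2("HDL", "CRP", -0.25)
  set2("TG", "T2D", 0.30); set2("TG", "BMI", 0.25); set2("TG", "CRP", 0.30)
  set2("CHD", "LDL", 0.30); set2("CHD", "nonHDL", 0.30); set2("CHD", "TC", 0.25)
  set2("CHD", "SBP", 0.20); set2("CHD", "DBP", 0.15); set2("CHD", "T2D", 0.20)
  set2("CHD", "BMI", 0.15); set2("CHD", "TG", 0.20); set2("CHD", "HDL", -0.20)
  set2("SCZ", "BMI", -0.08); set2("SCZ", "CRP", -0.05)
  R
}

#' Default metabolic endpoint truth used by the generator
#'
#' Per endpoint: the true log hazard ratio of schizophrenia, the control-group
#' event rate per person-year, the pre-index prevalence probabilities (events
#' generated before the index date, later excluded by the prevalence rule),
#' and a representative ICD-10 code emitted at the event date.
#'
#' @return data.frame with one row per component endpoint.
#' @export
endpoint_truth_defaults <- function() {
  data.frame(
    endpoint = c("T2D", "hypercholesterolemia", "essential_hypertension",
                 "CHD", "CVD"),
    log_hr = log(c(4.19, 1.43, 1.92, 3.35, 3.48)),
    control_rate = c(12 / 2511, 188 / 2479, 151 / 2396, 19 / 2511, 23 / 2510) / 10,
    prev_case = 1 - c(528, 525, 494, 531, 530) / 677,
    prev_control = 1 - c(2511, 2479, 2396, 2511, 2510) / 2708,
    icd10 = c("E11", "E78.0", "I10", "I21", "I63"),
    stringsAsFactors = FALSE)
}

default_drug_weights <- function() {
  w <- c(quetiapine = 0.22, olanzapine = 0.22, clozapine = 0.14,
         risperidone = 0.09, aripiprazole = 0.08, haloperidol = 0.05,
         amisulpride = 0.04, sulpiride = 0.02, ziprasidone = 0.02,
         flupentixol = 0.02, zuclopenthixol = 0.02, perphenazine = 0.015,
         levomepromazine = 0.015, chlorprothixene = 0.01, sertindole = 0.01,
         cariprazine = 0.01, melperone = 0.01, chlorpromazine = 0.01,
         fluphenazine = 0.01, paliperidone = 0.01)
  w / sum(w)
}

drug_atc <- function() {
  c(quetiapine = "N05AH04", olanzapine = "N05AH03", clozapine = "N05AH02",
    aripiprazole = "N05AX12", risperidone = "N05AX08", paliperidone = "N05AX13",
    haloperidol = "N05AD01", amisulpride = "N05AL05", sulpiride = "N05AL01",
    sertindole = "N05AE03", ziprasidone = "N05AE04", flupentixol = "N05AF01",
    zuclopenthixol = "N05AF05", chlorprothixene = "N05AF03",
    perphenazine = "N05AB03", fluphenazine = "N05AB02",
    chlorpromazine = "N05AA01", levomepromazine = "N05AA02",
    melperone = "N05AD03", cariprazine = "N05AX15")
}

#' Generator configuration
#'
#' Bundles every knob of the synthetic cohort: sample sizes, the polygenic
#' correlation structure, the true effect sizes that downstream recovery
#' tests re-estimate, the dispensing purchase process, and the BMI trajectory
#' model coefficients. Defaults encode the emulated study conditions: 677
#' cases with 4 matched controls each, 54% female, a case-control log-odds of
#' log(1.75) on the schizophrenia polygenic score, endpoint hazards of
#' Table-2 magnitude, and trajectory coefficients giving decade BMI gains of
#' 1.5 (control), 1.8 (untreated case) and 4.6 points (case treated 180
#' days/year).
#'
#' @param n_cases number of schizophrenia cases (default 677).
#' @param controls_per_case matched controls per case (default 4).
#' @param pool_multiplier candidate-pool inflation over the needed number of
#'   controls, so nearest-neighbour matching has slack (default 1.3).
#' @param fraction_female fraction of female cases (default 0.54).
#' @param prs_correlation 15 x 15 positive-semidefinite correlation matrix.
#' @param scz_prs_log_or true log odds ratio of case status per SD of the
#'   schizophrenia polygenic score (default log 1.75).
#' @param endpoints endpoint truth table, see [endpoint_truth_defaults()].
#' @param dispensing list of purchase-process parameters (see Details).
#' @param bmi list of trajectory-model coefficients and variance components.
#' @param freeze_date end of follow-up for survivors (default "2023-03-31").
#' @param seed root seed, expanded into named substreams per stage.
#' @details The dispensing process: a case is ever-treated with probability
#'   `treated_fraction` (default 0.88); purchases supply 30/60/90 days, the
#'   next purchase follows after `days_supplied / adherence` (per-person
#'   adherence propensity ~ Beta(4, 2)) with lognormal jitter and occasional
#'   long breaks; a `1 - persistent_prob` fraction stops for good after a
#'   lognormal treatment duration (median about 2.1 years). The BMI model:
#'   population intercept at age 27, fixed effects for sex, smoking, BMI PRS,
#'   age, case status, case-by-age interaction and accumulated treatment
#'   years, plus per-subject random intercept and age slope.
#' @return object of class `generator_config`.
#' @export
generator_config <- function(n_cases = 677L,
                             controls_per_case = 4L,
                             pool_multiplier = 1.3,
                             fraction_female = 0.54,
                             prs_correlation = default_prs_correlation(),
                             scz_prs_log_or = log(1.75),
                             endpoints = endpoint_truth_defaults(),
                             dispensing = list(),
                             bmi = list(),
                             freeze_date = as.Date("2023-03-31"),
                             seed = 1L) {
  ev <- eigen(prs_correlation, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    stop("prs_correlation is not positive semidefinite", call. = FALSE)
  }
  if (!isTRUE(all.equal(unname(diag(prs_correlation)),
                        rep(1, nrow(prs_correlation))))) {
    stop("prs_correlation must have unit diagonal", call. = FALSE)
  }
  disp_defaults <- list(
    treated_fraction = 0.88,
    first_purchase_lag_mean = 20,
    days_supplied = c("30" = 0.6, "60" = 0.3, "90" = 0.1),
    gap_sdlog = 0.25,
    long_gap_prob = 0.05,
    long_gap_range = c(2, 7),
    switch_prob = 0.25,
    persistent_prob = 0.58,
    stop_duration_meanlog = log(2.1 * DAYS_PER_YEAR),
    stop_duration_sdlog = 0.8,
    adherence_shape = c(3.5, 2.2),
    cpz_level_meanlog = log(186),
    cpz_level_sdlog = 0.55,
    dose_jitter_sdlog = 0.15,
    n_drugs_lambda = 2.2,
    drug_weights = default_drug_weights(),
    max_purchases = 400L)
  dispensing <- utils::modifyList(disp_defaults, dispensing)
  # treatment-years slope chosen so a case treated 180 days/year for a decade
  # gains 4.6 BMI points against 1.8 for an untreated case
  bmi_defaults <- list(
    intercept = 24.0, male = 0.5, smoking_ever = 0.5, bmi_prs = 1.56,
    age = 0.15, case = -0.61, case_age = 0.03,
    ty = 2.8 / (10 * 180 / DAYS_PER_YEAR), ty2 = 0, ty3 = 0, ty4 = 0,
    sd_intercept = 3.5, sd_slope = 0.1, cor_re = 0.2, sd_resid = 1.2,
    n_lambda = 2.5, spacing_mean = 330, spacing_shape = 4.8,
    smoking_ever_case = 377 / (377 + 248),
    smoking_ever_control = 1157 / (1157 + 1385),
    smoking_missing = 0.07)
  bmi <- utils::modifyList(bmi_defaults, bmi)
  structure(list(n_cases = as.integer(n_cases),
                 controls_per_case = as.integer(controls_per_case),
                 pool_multiplier = pool_multiplier,
                 fraction_female = fraction_female,
                 prs_correlation = prs_correlation,
                 scz_prs_log_or = scz_prs_log_or,
                 endpoints = endpoints,
                 dispensing = dispensing,
                 bmi = bmi,
                 freeze_date = as.Date(freeze_date),
                 seed = as.integer(seed)),
            class = "generator_config")
}

#' @export
print.generator_config <- function(x, ...) {
  cat("Synthetic cohort config:", x$n_cases, "cases,",
      x$n_cases * x$controls_per_case, "target controls, seed", x$seed, "\n")
  invisible(x)
}

# Truncated-normal onset ages via rejection.
rtnorm <- function(n, mean, sd, lo, hi) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(n, mean, sd)
    out <- c(out, x[x >= lo & x <= hi])
  }
  out[seq_len(n)]
}

#' Simulate a dispensing history for one treated case
#'
#' Purchase process: the first purchase follows the onset date after an
#' exponential lag; each purchase supplies 30/60/90 days of one drug from the
#' person's drug set (switching with configured probability); the gap to the
#' next purchase is the supplied days inflated by the person's adherence
#' propensity with lognormal jitter, occasionally stretched into a long break;
#' non-persistent histories are truncated for good after a lognormal
#' treatment duration.
#'
#' @param person one-row persons data.frame with an `onset_date` column (or
#'   pass `onset_date` explicitly).
#' @param process dispensing-process parameter list (see
#'   [generator_config()]).
#' @param seed integer seed.
#' @param onset_date overrides `person$onset_date`.
#' @return validated-shape dispensing data.frame (possibly zero rows).
#' @export
simulate_dispensing <- function(person, process = generator_config()$dispensing,
                                seed = 1L, onset_date = NULL) {
  onset <- as_day(onset_date %||% person$onset_date)
  end_day <- as_day(person$followup_end)
  with_seed(seed, {
    lat <- draw_dispensing_latents(1, process)
    gen_history(person$person_id, onset, end_day, process, lat, 1L)
  })
}

draw_dispensing_latents <- function(n, process) {
  list(adherence = stats::rbeta(n, process$adherence_shape[1], process$adherence_shape[2]),
       persistent = stats::runif(n) < process$persistent_prob,
       stop_days = stats::rlnorm(n, process$stop_duration_meanlog,
                                 process$stop_duration_sdlog),
       cpz_level = stats::rlnorm(n, process$cpz_level_meanlog,
                                 process$cpz_level_sdlog),
       n_drugs = pmin(1L + stats::rpois(n, process$n_drugs_lambda), 8L))
}

gen_history <- function(person_id, onset, end_day, process, lat, i,
                        cpz = cpz_table()) {
  first <- onset + round(stats::rexp(1, 1 / process$first_purchase_lag_mean))
  if (first >= end_day) return(empty_dispensing())
  drugs <- sample(names(process$drug_weights), lat$n_drugs[i],
                  prob = process$drug_weights,
                  replace = FALSE)
  stop_day <- if (lat$persistent[i]) Inf else first + lat$stop_days[i]
  supplies <- as.integer(names(process$days_supplied))
  t <- first
  cur_drug <- drugs[1]
  day <- integer(0); drug <- character(0); dose <- numeric(0); supp <- integer(0)
  while (t < end_day && t < stop_day && length(day) < process$max_purchases) {
    s <- supplies[sample.int(length(supplies), 1, prob = process$days_supplied)]
    f <- cpz$factor[match(cur_drug, cpz$drug)]
    d <- lat$cpz_level[i] * stats::rlnorm(1, 0, process$dose_jitter_sdlog) / f
    day <- c(day, t); drug <- c(drug, cur_drug)
    dose <- c(dose, round(d, 1)); supp <- c(supp, s)
    gap <- s / lat$adherence[i] * stats::rlnorm(1, 0, process$gap_sdlog)
    if (stats::runif(1) < process$long_gap_prob) {
      gap <- gap * stats::runif(1, process$long_gap_range[1],
                                process$long_gap_range[2])
    }
    t <- t + max(1L, as.integer(round(gap)))
    if (length(drugs) > 1 && stats::runif(1) < process$switch_prob) {
      others <- setdiff(drugs, cur_drug)
      cur_drug <- others[sample.int(length(others), 1)]
    }
  }
  if (!length(day)) return(empty_dispensing())
  data.frame(person_id = person_id,
             purchase_date = day_to_date(day),
             atc_code = unname(drug_atc()[drug]),
             drug_name = drug,
             daily_dose_mg = dose,
             days_supplied = supp,
             stringsAsFactors = FALSE)
}

empty_dispensing <- function() {
  data.frame(person_id = character(0), purchase_date = as.Date(character(0)),
             atc_code = character(0), drug_name = character(0),
             daily_dose_mg = numeric(0), days_supplied = integer(0))
}

#' Simulate a full synthetic biobank extract
#'
#' Generates all five canonical tables plus a truth record. Case status
#' shifts the polygenic-score mean vector along the schizophrenia column of
#' the correlation matrix so that the implied logistic model has exactly the
#' configured log odds ratio on the schizophrenia score; metabolic endpoint
#' onsets follow exponential proportional hazards from the index date; BMI
#' measurements are drawn from the random-intercept/random-slope trajectory
#' model with treatment years accumulated from the generated dispensing
#' history itself.
#'
#' Each stage draws from its own named substream of the root seed, so adding
#' a stage never perturbs earlier draws and identical (config, seed) give
#' identical output.
#'
#' @param config a [generator_config()].
#' @return list with `persons`, `dispensing`, `diagnoses`, `measurements`,
#'   `prs` (validated-shape data.frames) and `truth` (per-person latent
#'   quantities plus the generating config).
#' @export
simulate_cohort <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  n_cases <- config$n_cases
  n_pool <- as.integer(ceiling(n_cases * config$controls_per_case *
                                 config$pool_multiplier))
  freeze <- as_day(config$freeze_date)

  if (n_cases == 0L) {
    return(list(persons = data.frame(person_id = character(0), sex = character(0),
                                     birth_date = as.Date(character(0)),
                                     death_date = as.Date(character(0)),
                                     followup_end = as.Date(character(0))),
                dispensing = empty_dispensing(),
                diagnoses = data.frame(person_id = character(0),
                                       event_date = as.Date(character(0)),
                                       icd10 = character(0)),
                measurements = data.frame(person_id = character(0),
                                          measure_date = as.Date(character(0)),
                                          kind = character(0), value = character(0)),
                prs = data.frame(person_id = character(0)),
                truth = list(persons = data.frame(), config = config)))
  }

  ## -- persons -------------------------------------------------------------
  pers <- with_seed(substream_seed(config$seed, "persons"), {
    sex_case <- ifelse(stats::runif(n_cases) < config$fraction_female,
                       "female", "male")
    onset_age <- rtnorm(n_cases, 27, 6.9, 15.2, 39.8)
    onset_day <- as_day("2007-01-01") +
      floor(stats::runif(n_cases) * (as_day("2019-12-31") - as_day("2007-01-01")))
    birth_day <- onset_day - as.integer(round(onset_age * DAYS_PER_YEAR))
    death_case <- stats::runif(n_cases) < 0.0192
    death_day <- ifelse(death_case,
                        onset_day + 365L +
                          floor(stats::runif(n_cases) *
                                  pmax(1, freeze - onset_day - 365L)),
                        NA_integer_)
    ctrl_of <- sample.int(n_cases, n_pool, replace = TRUE)
    jitter <- sample(-2:2, n_pool, replace = TRUE,
                     prob = c(0.1, 0.2, 0.4, 0.2, 0.1))
    ctrl_birth <- birth_day[ctrl_of] + jitter * 365L +
      sample(-60:60, n_pool, replace = TRUE)
    death_ctrl <- stats::runif(n_pool) < 0.0018
    ctrl_death <- ifelse(death_ctrl,
                         onset_day[ctrl_of] + 365L +
                           floor(stats::runif(n_pool) *
                                   pmax(1, freeze - onset_day[ctrl_of] - 365L)),
                         NA_integer_)
    list(case = data.frame(person_id = sprintf("case_%04d", seq_len(n_cases)),
                           sex = sex_case,
                           birth_day = birth_day, onset_day = onset_day,
                           death_day = death_day, stringsAsFactors = FALSE),
         ctrl = data.frame(person_id = sprintf("ctrl_%05d", seq_len(n_pool)),
                           sex = sex_case[ctrl_of],
                           birth_day = ctrl_birth,
                           pseudo_index = onset_day[ctrl_of],
                           death_day = ctrl_death, stringsAsFactors = FALSE))
  })
  case_df <- pers$case; ctrl_df <- pers$ctrl
  case_df$followup_day <- ifelse(is.na(case_df$death_day), freeze,
                                 pmin(case_df$death_day, freeze))
  ctrl_df$followup_day <- ifelse(is.na(ctrl_df$death_day), freeze,
                                 pmin(ctrl_df$death_day, freeze))

  all_ids <- c(case_df$person_id, ctrl_df$person_id)
  n_all <- length(all_ids)
  is_case <- c(rep(TRUE, n_cases), rep(FALSE, n_pool))
  index_day <- c(case_df$onset_day, ctrl_df$pseudo_index)
  followup_day <- c(case_df$followup_day, ctrl_df$followup_day)
  birth_day_all <- c(case_df$birth_day, ctrl_df$birth_day)
  sex_all <- c(case_df$sex, ctrl_df$sex)
  death_day_all <- c(case_df$death_day, ctrl_df$death_day)

  persons <- data.frame(person_id = all_ids, sex = sex_all,
                        birth_date = day_to_date(birth_day_all),
                        death_date = day_to_date(death_day_all),
                        followup_end = day_to_date(followup_day),
                        stringsAsFactors = FALSE)

  ## -- polygenic scores ----------------------------------------------------
  prs <- with_seed(substream_seed(config$seed, "prs"), {
    Sigma <- config$prs_correlation
    scores <- MASS::mvrnorm(n_all, mu = rep(0, nrow(Sigma)), Sigma = Sigma)
    colnames(scores) <- prs_traits()
    shift <- config$scz_prs_log_or * Sigma[, "SCZ"]
    scores[is_case, ] <- sweep(scores[is_case, , drop = FALSE], 2, shift, "+")
    pcs <- matrix(stats::rnorm(n_all * 10), n_all, 10,
                  dimnames = list(NULL, pc_names()))
    cbind(data.frame(person_id = all_ids, stringsAsFactors = FALSE),
          as.data.frame(scores), as.data.frame(pcs))
  })

  ## -- dispensing ----------------------------------------------------------
  disp_res <- with_seed(substream_seed(config$seed, "dispensing"), {
    proc <- config$dispensing
    treated <- stats::runif(n_cases) < proc$treated_fraction
    lat <- draw_dispensing_latents(n_cases, proc)
    onset_src <- ifelse(stats::runif(n_cases) < 0.5, "diagnosis", "prescription")
    onset_src[!treated] <- "diagnosis"
    dx_lag <- ifelse(onset_src == "diagnosis", 0,
                     round(stats::rexp(n_cases, 1 / 180)))
    rx_lag <- ifelse(onset_src == "prescription", 0,
                     round(stats::rexp(n_cases, 1 / 60)))
    cpz <- cpz_table()
    hist_list <- lapply(seq_len(n_cases), function(i) {
      if (!treated[i]) return(empty_dispensing())
      gen_history(case_df$person_id[i], case_df$onset_day[i] + rx_lag[i],
                  case_df$followup_day[i], proc, lat, i, cpz)
    })
    list(dispensing = do.call(rbind, hist_list), treated = treated,
         lat = lat, dx_lag = dx_lag, onset_src = onset_src)
  })
  dispensing <- disp_res$dispensing
  rownames(dispensing) <- NULL

  ## -- outcomes (endpoint events) -----------------------------------------
  diagnoses <- with_seed(substream_seed(config$seed, "outcomes"), {
    ep <- config$endpoints
    rows <- list()
    # one shared pre-index morbidity uniform per person: endpoint-specific
    # prevalent exclusions overlap heavily (largely the same persons), so the
    # union endpoint excludes barely more than its worst component
    prev_u <- stats::runif(n_all)
    for (j in seq_len(nrow(ep))) {
      rate <- ep$control_rate[j] * exp(ifelse(is_case, ep$log_hr[j], 0))
      prev_p <- ifelse(is_case, ep$prev_case[j], ep$prev_control[j])
      prevalent <- prev_u < prev_p
      t_years <- stats::rexp(n_all, rate)
      ev_day <- ifelse(prevalent,
                       index_day - floor(stats::runif(n_all) * 5 * DAYS_PER_YEAR) - 1,
                       index_day + round(t_years * DAYS_PER_YEAR))
      seen <- ev_day <= followup_day & (prevalent | ev_day > index_day)
      if (any(seen)) {
        rows[[ep$endpoint[j]]] <- data.frame(
          person_id = all_ids[seen],
          event_date = day_to_date(as.integer(ev_day[seen])),
          icd10 = ep$icd10[j], stringsAsFactors = FALSE)
      }
    }
    # SSD diagnoses for cases
    dx_day <- case_df$onset_day + disp_res$dx_lag
    dx_day <- pmin(dx_day, case_df$followup_day - 1L)
    rows$ssd <- data.frame(person_id = case_df$person_id,
                           event_date = day_to_date(dx_day),
                           icd10 = "F20.0", stringsAsFactors = FALSE)
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out[order(out$person_id, out$event_date), ]
  })

  ## -- BMI + smoking measurements -----------------------------------------
  bmi_cfg <- config$bmi
  timelines <- lapply(split(dispensing, dispensing$person_id), function(d) {
    fe <- followup_day[match(d$person_id[1], all_ids)]
    build_timeline(d, fe)
  })
  meas <- with_seed(substream_seed(config$seed, "measurements"), {
    smoking_latent <- stats::runif(n_all) <
      ifelse(is_case, bmi_cfg$smoking_ever_case, bmi_cfg$smoking_ever_control)
    smoking_missing <- stats::runif(n_all) < bmi_cfg$smoking_missing
    re <- MASS::mvrnorm(n_all, mu = c(0, 0),
                        Sigma = matrix(c(bmi_cfg$sd_intercept^2,
                                         rep(bmi_cfg$cor_re * bmi_cfg$sd_intercept * bmi_cfg$sd_slope, 2),
                                         bmi_cfg$sd_slope^2), 2, 2))
    rows <- vector("list", n_all)
    for (i in seq_len(n_all)) {
      n_bmi <- min(1L + stats::rpois(1, bmi_cfg$n_lambda), 12L)
      gaps <- stats::rgamma(n_bmi, shape = bmi_cfg$spacing_shape,
                            scale = bmi_cfg$spacing_mean / bmi_cfg$spacing_shape)
      # measurement windows sit anywhere in follow-up (timing is
      # noninformative: health-care contacts, not disease milestones)
      t0 <- index_day[i] + round(stats::runif(
        1, -DAYS_PER_YEAR,
        max(-DAYS_PER_YEAR, followup_day[i] - index_day[i] - DAYS_PER_YEAR)))
      days <- as.integer(round(t0 + cumsum(c(0, gaps[-1]))))
      days <- days[days < followup_day[i] & days > birth_day_all[i] + 15 * 365]
      if (!length(days)) days <- as.integer(followup_day[i] - 30L)
      age_c <- days_to_years(days - birth_day_all[i]) - 27
      tl <- timelines[[all_ids[i]]]
      ty <- if (is.null(tl)) rep(0, length(days)) else {
        vapply(days, function(d) {
          days_to_years(interval_overlap_days(tl$covered, tl$first_purchase, d))
        }, numeric(1))
      }
      mu <- bmi_cfg$intercept +
        bmi_cfg$male * (sex_all[i] == "male") +
        bmi_cfg$smoking_ever * smoking_latent[i] +
        bmi_cfg$bmi_prs * prs$BMI[i] +
        bmi_cfg$age * age_c +
        bmi_cfg$case * is_case[i] +
        bmi_cfg$case_age * is_case[i] * age_c +
        bmi_cfg$ty * ty + bmi_cfg$ty2 * ty^2 +
        bmi_cfg$ty3 * ty^3 + bmi_cfg$ty4 * ty^4 +
        re[i, 1] + re[i, 2] * age_c
      val <- pmin(pmax(round(mu + stats::rnorm(length(days), 0, bmi_cfg$sd_resid), 1),
                       10.5), 79.5)
      bmi_rows <- data.frame(person_id = all_ids[i],
                             measure_date = day_to_date(days),
                             kind = "bmi", value = format(val),
                             stringsAsFactors = FALSE)
      if (!smoking_missing[i]) {
        smk_day <- min(index_day[i] +
                         as.integer(round(3.7 * DAYS_PER_YEAR * stats::runif(1, 0.3, 1.7))),
                       followup_day[i] - 1L)
        bmi_rows <- rbind(bmi_rows,
                          data.frame(person_id = all_ids[i],
                                     measure_date = day_to_date(smk_day),
                                     kind = "smoking",
                                     value = if (smoking_latent[i]) "ever" else "never",
                                     stringsAsFactors = FALSE))
      }
      rows[[i]] <- bmi_rows
    }
    list(measurements = do.call(rbind, rows), smoking_latent = smoking_latent,
         re = re)
  })
  measurements <- meas$measurements
  rownames(measurements) <- NULL

  truth_persons <- data.frame(
    person_id = all_ids,
    case = is_case,
    index_date = day_to_date(index_day),
    treated = c(disp_res$treated, rep(FALSE, n_pool)),
    adherence = c(disp_res$lat$adherence, rep(NA_real_, n_pool)),
    persistent = c(disp_res$lat$persistent, rep(NA, n_pool)),
    smoking_ever = meas$smoking_latent,
    re_intercept = meas$re[, 1],
    re_slope = meas$re[, 2],
    stringsAsFactors = FALSE)

  list(persons = persons, dispensing = dispensing, diagnoses = diagnoses,
       measurements = measurements, prs = prs,
       truth = list(persons = truth_persons, config = config))
}

#' Simulate proportional-hazards time-to-event records directly
#'
#' Purpose-built exponential proportional-hazards draw used for Cox
#' parameter-recovery experiments: each person gets an administrative
#' follow-up drawn uniformly over a range of years and an exponential event
#' time with rate `control_rate * exp(log_hr * case)`.
#'
#' @param n_cases,n_controls group sizes.
#' @param log_hr true log hazard ratio for cases (default log 1.95).
#' @param control_rate control event rate per person-year (default 0.0127,
#'   about a 12% ten-year risk).
#' @param followup_range administrative censoring range in years.
#' @param seed integer seed.
#' @return data.frame with `group` ("case"/"control"), `time` (years) and
#'   `event` (0/1), suitable for [survival::coxph()].
#' @export
simulate_ph_records <- function(n_cases = 677L, n_controls = 2708L,
                                log_hr = log(1.95), control_rate = 0.0127,
                                followup_range = c(4, 16), seed = 1L) {
  with_seed(seed, {
    n <- n_cases + n_controls
    case <- c(rep(1L, n_cases), rep(0L, n_controls))
    cens <- stats::runif(n, followup_range[1], followup_range[2])
    t_ev <- stats::rexp(n, control_rate * exp(log_hr * case))
    data.frame(group = ifelse(case == 1L, "case", "control"),
               time = pmin(t_ev, cens),
               event = as.integer(t_ev <= cens))
  })
}

#' Simulate a case-control polygenic-score table with a known log odds ratio
#'
#' Controls draw scores from N(0, Sigma); cases from the same distribution
#' with the mean shifted along the schizophrenia column of Sigma, so the
#' implied logistic model has coefficient `log_or` on the schizophrenia score
#' and zero on all others.
#'
#' @param n_cases,n_controls group sizes.
#' @param log_or true log odds ratio per SD of the schizophrenia score.
#' @param Sigma score correlation matrix (default
#'   [default_prs_correlation()]).
#' @param seed integer seed.
#' @return data.frame with `case` (0/1), the 15 score columns and 10 PCs,
#'   plus `sex` and `birth_year` nuisance covariates.
#' @export
simulate_case_control_prs <- function(n_cases = 677L, n_controls = 2708L,
                                      log_or = log(1.75),
                                      Sigma = default_prs_correlation(),
                                      seed = 1L) {
  with_seed(seed, {
    n <- n_cases + n_controls
    case <- c(rep(1L, n_cases), rep(0L, n_controls))
    scores <- MASS::mvrnorm(n, mu = rep(0, nrow(Sigma)), Sigma = Sigma)
    colnames(scores) <- rownames(Sigma) %||% prs_traits()
    shift <- log_or * Sigma[, "SCZ"]
    scores[case == 1L, ] <- sweep(scores[case == 1L, , drop = FALSE], 2, shift, "+")
    pcs <- matrix(stats::rnorm(n * 10), n, 10, dimnames = list(NULL, pc_names()))
    out <- cbind(data.frame(case = case,
                            sex = sample(c("female", "male"), n, TRUE),
                            birth_year = sample(1967:1995, n, TRUE)),
                 as.data.frame(scores), as.data.frame(pcs))
    out
  })
}
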