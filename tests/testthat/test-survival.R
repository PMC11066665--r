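mk_matched <- function(case_ids, control_ids, index = as.Date("2012-01-01")) {
  k <- length(control_ids) / length(case_ids)
  structure(data.frame(case_id = rep(case_ids, each = k),
                       control_id = control_ids,
                       birth_year_distance = 0,
                       index_date = index, stringsAsFactors = FALSE),
            class = c("matched_cohort", "data.frame"))
}

mk_pers <- function(ids, birth = "1985-01-01", fend = "2023-03-31") {
  data.frame(person_id = ids, sex = "female", birth_date = as.Date(birth),
             death_date = as.Date(NA), followup_end = as.Date(fend),
             stringsAsFactors = FALSE)
}

test_that("prevalent cases are excluded and censoring defaults to follow-up end", {
  matched <- mk_matched("c1", c("k1", "k2", "k3", "k4"))
  pers <- mk_pers(c("c1", "k1", "k2", "k3", "k4"))
  dx <- data.frame(person_id = c("k1", "k2"),
                   event_date = as.Date(c("2010-05-01", "2015-05-01")),
                   icd10 = "E11.9", stringsAsFactors = FALSE)
  rec <- build_survival(matched, pers, dx, "T2D")
  ct <- attr(rec, "counts")
  expect_false("k1" %in% rec$person_id) # E11 before index
  expect_equal(unname(ct["prevalent_excluded"]), 1)
  expect_equal(sum(rec$event), 1) # k2 incident
  expect_equal(rec$event[rec$person_id == "k3"], 0)
  # censored at follow-up end
  expect_equal(rec$time[rec$person_id == "k3"],
               as.numeric(as.Date("2023-03-31") - as.Date("2012-01-01")) / 365.25)
  # bookkeeping is total
  expect_equal(unname(ct["eligible"] + ct["prevalent_excluded"] + ct["no_followup"]),
               unname(ct["total"]))
})

test_that("endpoint code maps drive event selection; union covers all five", {
  matched <- mk_matched("c1", c("k1", "k2", "k3", "k4"))
  pers <- mk_pers(c("c1", "k1", "k2", "k3", "k4"))
  dx <- data.frame(person_id = "k1", event_date = as.Date("2015-05-01"),
                   icd10 = "I25.1", stringsAsFactors = FALSE)
  expect_equal(sum(build_survival(matched, pers, dx, "CHD")$event), 1)
  expect_equal(sum(build_survival(matched, pers, dx, "T2D")$event), 0)
  expect_equal(sum(build_survival(matched, pers, dx, "any_metabolic")$event), 1)
  # E78.0 belongs to hypercholesterolemia, E78.5 does not
  dx2 <- data.frame(person_id = "k1", event_date = as.Date("2015-05-01"),
                    icd10 = "E78.5", stringsAsFactors = FALSE)
  expect_equal(sum(build_survival(matched, pers, dx2, "hypercholesterolemia")$event), 0)
})

test_that("the Cox partial-likelihood maximum matches a direct optimisation oracle", {
  # six subjects, distinct times (no ties): every tie convention coincides
  rec <- data.frame(person_id = letters[1:6],
                    group = c("case", "case", "case", "control", "control", "control"),
                    time = c(2.3, 5.1, 8.2, 3.4, 7.7, 11.0),
                    event = c(1L, 1L, 0L, 1L, 1L, 0L))
  fit <- fit_cox(rec, terms = "group")
  x <- as.numeric(rec$group == "control")
  oracle <- stats::optimize(neg_log_partial_lik, c(-5, 5), time = rec$time,
                            event = rec$event, x = x, tol = 1e-10)$minimum
  expect_equal(unname(coef(fit$fit)), oracle, tolerance = 1e-6)
})

test_that("fit_cox refuses event-free data and reports HRs with CIs", {
  rec <- data.frame(group = c("case", "control"), time = c(1, 2), event = c(0L, 0L))
  expect_error(fit_cox(rec), "no events")
  rec <- simulate_ph_records(300, 1200, log_hr = log(2), seed = 1)
  fit <- fit_cox(rec)
  # coefficient is for 'groupcontrol' (case is the reference level)
  expect_equal(fit$table$term, "groupcontrol")
  expect_true(fit$table$ci_lo < fit$table$hr & fit$table$hr < fit$table$ci_hi)
  expect_lt(fit$table$hr, 1) # controls at lower hazard
})

test_that("null simulation: the 95% CI covers HR = 1 at the nominal rate", {
  covered <- 0; n_rep <- 60
  for (i in seq_len(n_rep)) {
    rec <- simulate_ph_records(250, 1000, log_hr = 0, control_rate = 0.02,
                               seed = 2000 + i)
    tab <- fit_cox(rec)$table
    if (tab$ci_lo <= 1 && 1 <= tab$ci_hi) covered <- covered + 1
  }
  expect_gte(covered / n_rep, 0.88)
})

test_that("shortening follow-up can only reduce event counts", {
  rec <- simulate_ph_records(200, 800, seed = 3)
  shorter <- rec
  shorter$event[shorter$time > 5] <- 0L
  shorter$time <- pmin(shorter$time, 5)
  expect_lte(sum(shorter$event), sum(rec$event))
})

test_that("stepwise PRS scan inside Cox finds a planted hazard score", {
  set.seed(4)
  n <- 2500
  prs <- simulate_case_control_prs(0, n, log_or = 0, seed = 5)
  lp <- 0.5 * prs$DBP
  t_ev <- stats::rexp(n, 0.02 * exp(lp))
  cens <- stats::runif(n, 4, 16)
  rec <- cbind(data.frame(group = sample(c("case", "control"), n, TRUE),
                          time = pmin(t_ev, cens),
                          event = as.integer(t_ev <= cens)),
               prs[, c(prs_traits(), paste0("PC", 1:10))])
  fit <- fit_cox(rec, terms = "group", prs_candidates = prs_traits(),
                 alpha = 0.05 / 6)
  expect_true("DBP" %in% fit$stepwise$included)
  expect_equal(fit$stepwise$trace$term[1], "DBP")
  expect_true(all(fit$stepwise$trace$p < 0.05 / 6))
})

test_that("adherence analysis: protective sign recovered, constant term refused", {
  prof_template <- data.frame(person_id = sprintf("c%03d", 1:300),
                              n_purchases = 20L, pdc_1year = runif(300))
  set.seed(6)
  hits <- 0; n_rep <- 20
  for (i in seq_len(n_rep)) {
    prof <- prof_template
    prof$pdc_1year <- runif(300)
    lp <- -0.5 * prof$pdc_1year
    t_ev <- rexp(300, 0.05 * exp(lp))
    cens <- runif(300, 5, 15)
    rec <- data.frame(person_id = prof$person_id, group = "case",
                      time = pmin(t_ev, cens), event = as.integer(t_ev <= cens),
                      sex = "female", birth_year = 1985L)
    fit <- adherence_survival(rec, prof, covariates = character(0))
    if (fit$table$coef[fit$table$term == "pdc_1year"] < 0) hits <- hits + 1
  }
  expect_gte(hits / n_rep, 0.9)

  prof <- prof_template
  prof$pdc_1year <- 0.5
  rec <- data.frame(person_id = prof$person_id, group = "case", time = 5,
                    event = rbinom(300, 1, 0.3), sex = "female",
                    birth_year = 1985L)
  expect_error(adherence_survival(rec, prof), "constant")
})
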