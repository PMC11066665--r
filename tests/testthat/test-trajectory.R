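# helper: full synthetic frame (cases + controls) with windowed exposure
sim_bmi_frame <- function(seed, n_cases = 150, bmi_overrides = list()) {
  cfg <- generator_config(n_cases = n_cases, seed = seed, bmi = bmi_overrides)
  sim <- simulate_cohort(cfg)
  case_ids <- sim$truth$persons$person_id[sim$truth$persons$case]
  win <- derive_windowed_exposure(sim$persons, sim$dispensing, sim$measurements)
  build_bmi_frame(sim$measurements, sim$persons, case_ids, sim$prs, win)
}

test_that("decade gain equals slope times horizon and is origin-invariant", {
  # near-noise-free data so the fitted age effect is essentially exact
  set.seed(1)
  n <- 400
  ids <- sprintf("p%03d", 1:n)
  d <- do.call(rbind, lapply(seq_len(n), function(i) {
    age <- sort(runif(4, 20, 55))
    data.frame(person_id = ids[i], age_c = age - 27,
               sex_male = i %% 2, smoking_ever = (i %/% 2) %% 2,
               bmi_prs = rnorm(1), case = 0, case_age = 0, ty = 0)
  }))
  for (pc in paste0("PC", 1:10)) d[[pc]] <- rnorm(nrow(d))
  d$bmi <- 24 + 0.5 * d$sex_male + 0.15 * d$age_c + 1.2 * d$bmi_prs +
    rep(rnorm(n, 0, 0.02), each = 4)[seq_len(nrow(d))] + rnorm(nrow(d), 0, 0.02)
  fit <- fit_bmi_lmm(d, "interaction")
  sc <- trajectory_scenario("control", sex = "male", smoking = "never")
  pred <- predict_trajectory(fit, sc)
  expect_equal(decade_gain(pred), 1.5, tolerance = 0.01)
  # shifting the start age leaves the decade gain unchanged (linear model)
  sc2 <- trajectory_scenario("control", sex = "male", smoking = "never",
                             start_age = 35)
  expect_equal(decade_gain(predict_trajectory(fit, sc2)), decade_gain(pred),
               tolerance = 0.01)
})

test_that("the 83% band uses the normal quantile of (1+level)/2", {
  z83_oracle <- quantile_by_bisection((1 + 0.83) / 2)
  expect_equal(z83_oracle, 1.3722, tolerance = 1e-4)
  expect_equal(stats::qnorm((1 + 0.83) / 2), z83_oracle, tolerance = 1e-8)
  d <- sim_bmi_frame(2, n_cases = 60)
  fit <- fit_bmi_lmm(d, "interaction")
  sc <- trajectory_scenario("control")
  p83 <- predict_trajectory(fit, sc, ci_level = 0.83)
  p95 <- predict_trajectory(fit, sc, ci_level = 0.95)
  ratio <- (p83$hi - p83$mean) / (p95$hi - p95$mean)
  expect_equal(unique(round(ratio, 6)),
               round(z83_oracle / stats::qnorm(0.975), 6))
})

test_that("non-overlap testing: identical, separated, mismatched grids", {
  d <- sim_bmi_frame(3, n_cases = 60)
  fit <- fit_bmi_lmm(d, "interaction")
  a <- predict_trajectory(fit, trajectory_scenario("control"))
  expect_false(any(nonoverlap_test(a, a)))
  b <- a
  b$lo <- b$lo + 50; b$hi <- b$hi + 50; b$mean <- b$mean + 50
  expect_true(all(nonoverlap_test(a, b)))
  c <- a[-1, ]
  expect_error(nonoverlap_test(a, c), "grids differ")
})

test_that("under the null the 83% rule rejects at about alpha = 0.05", {
  set.seed(7)
  n_draws <- 10000
  z <- stats::qnorm((1 + 0.83) / 2)
  s <- 1.7
  x <- rnorm(n_draws, 0, s); y <- rnorm(n_draws, 0, s)
  hit <- vapply(seq_len(n_draws), function(i) {
    a <- data.frame(age = 1, mean = x[i], lo = x[i] - z * s, hi = x[i] + z * s)
    b <- data.frame(age = 1, mean = y[i], lo = y[i] - z * s, hi = y[i] + z * s)
    any(nonoverlap_test(a, b))
  }, logical(1))
  expect_lt(abs(mean(hit) - 0.05), 0.02)
})

test_that("ML log-likelihood never decreases up the nested ladder", {
  d <- sim_bmi_frame(4, n_cases = 120)
  lad <- fit_ladder(d)
  expect_true(all(diff(lad$comparison$logLik) >= -1e-6))
  expect_true(all(diff(lad$comparison$npar) > 0))
  expect_true(all(lad$comparison$p[-1] >= 0 & lad$comparison$p[-1] <= 1))
})

test_that("a generated disease-by-age interaction and treatment effect are detected", {
  hits_int <- 0; hits_ty <- 0; n_rep <- 5
  for (i in seq_len(n_rep)) {
    d <- sim_bmi_frame(100 + i, n_cases = 250)
    lad <- fit_ladder(d)
    if (lad$comparison$p[2] < 0.05) hits_int <- hits_int + 1
    if (lad$comparison$p[3] < 0.05) hits_ty <- hits_ty + 1
  }
  expect_gte(hits_int, 4)
  expect_equal(hits_ty, n_rep) # the treatment signal is strong
})

test_that("subject-level BLUP predictions interpolate better than population ones", {
  d <- sim_bmi_frame(5, n_cases = 80)
  fit <- suppressWarnings(fit_bmi_lmm(d, "interaction"))
  rss_blup <- sum((d$bmi - predict(fit$fit))^2)
  rss_pop <- sum((d$bmi - predict(fit$fit, re.form = NA))^2)
  expect_lt(rss_blup, rss_pop)
})

test_that("scenario terms absent from the fitted model raise errors", {
  d <- sim_bmi_frame(6, n_cases = 60)
  fit <- fit_bmi_lmm(d, "interaction")
  expect_error(predict_trajectory(fit, trajectory_scenario("treated_case")),
               "no treatment term")
  expect_error(trajectory_scenario("control", treatment_days_per_year = 100),
               "must be zero")
})

test_that("treatment-intensity effects recover their generated signs", {
  d <- sim_bmi_frame(8, n_cases = 250)
  res <- dose_adherence_effects(d)
  eff <- res$effects
  expect_setequal(eff$term, c("dose_std", "pdc_window", "ty", "bmi_prs"))
  # generated truth: positive treatment-years and BMI PRS effects
  expect_gt(eff$estimate[eff$term == "ty"], 0)
  expect_gt(eff$estimate[eff$term == "bmi_prs"], 0)
})

test_that("constant treatment-years columns are dropped with a warning", {
  d <- sim_bmi_frame(9, n_cases = 40)
  d <- d[d$case == 1 & !is.na(d$pdc_window) & !is.na(d$median_cpz_window_mg), ]
  d$ty <- 1.5
  expect_warning(dose_adherence_effects(d), "constant")
  expect_error(fit_bmi_lmm(transform(d, ty = 0), "treatment"), "constant")
})
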