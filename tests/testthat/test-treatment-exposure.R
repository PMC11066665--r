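mk_purchases <- function(days, supplied = 30L, drug = "chlorpromazine",
                         dose = 100, origin = as.Date("2015-01-01")) {
  data.frame(person_id = "p1", purchase_date = origin + days,
             atc_code = "N05AA01", drug_name = drug,
             daily_dose_mg = dose,
             days_supplied = rep_len(supplied, length(days)),
             stringsAsFactors = FALSE)
}
ORIGIN <- as.Date("2015-01-01")
FEND <- ORIGIN + 4000

test_that("stockpiling shifts overlapping supply forward; merging loses it", {
  p <- mk_purchases(c(0, 10))
  tl <- build_timeline(p, FEND, stockpile = TRUE)
  expect_equal(tl$covered, data.frame(start = day0(ORIGIN),
                                      end = day0(ORIGIN) + 60L))
  tl2 <- build_timeline(p, FEND, stockpile = FALSE)
  expect_equal(tl2$covered$end - tl2$covered$start, 40L)
})

test_that("PDC windows follow their definitions", {
  # single 30-day purchase with over a year of follow-up
  tl <- build_timeline(mk_purchases(0), FEND)
  expect_equal(compute_pdc(tl, "first_year"), 30 / 365)
  # mock history {0, 40, 100} x 30 days
  tl <- build_timeline(mk_purchases(c(0, 40, 100)), FEND)
  expect_equal(compute_pdc(tl, "first_year"), 90 / 365)
  # gap-free monthly purchases for three years: all four PDCs = 1
  days <- seq(0, 1050, by = 30) # coverage [0, 1080)
  tl <- build_timeline(mk_purchases(days), FEND)
  for (w in c("first_year", "last_year", "purchase_span", "followup")) {
    # followup window runs to followup_end, so truncate follow-up at supply end
    tlw <- build_timeline(mk_purchases(days), ORIGIN + 1080)
    expect_equal(compute_pdc(if (w == "followup") tlw else tl, w), 1.0)
  }
})

test_that("treatment lengths: supply never exceeds purchase span", {
  tl <- build_timeline(mk_purchases(seq(0, 690, by = 30), supplied = 30L),
                       ORIGIN + 720)
  tls <- treatment_lengths(tl)
  expect_equal(unname(tls["ty_purchase"]), 720 / 365.25)
  expect_equal(unname(tls["ty_supply"]), 720 / 365.25)
  # covered [0,365) and [1095,1460): supply 2y, span ~4y
  p <- mk_purchases(c(0, 1095), supplied = 365L)
  tl <- build_timeline(p, FEND)
  tls <- treatment_lengths(tl)
  expect_equal(unname(tls["ty_supply"]), 730 / 365.25)
  expect_equal(unname(tls["ty_purchase"]), 1460 / 365.25)
  set.seed(7)
  for (i in 1:100) {
    tl <- build_timeline(random_history(), FEND)
    tls <- treatment_lengths(tl)
    expect_lte(tls["ty_supply"], tls["ty_purchase"] + 1e-12)
  }
})

test_that("discontinuation is supply ending >1 year before follow-up end or death", {
  tl <- build_timeline(mk_purchases(0), ORIGIN + 430)
  expect_true(flag_discontinuation(tl, ORIGIN + 430)$discontinued)
  tl <- build_timeline(mk_purchases(0), FEND)
  expect_false(flag_discontinuation(tl, FEND, death_date = ORIGIN + 130)$discontinued)
  expect_true(flag_discontinuation(tl, FEND, death_date = ORIGIN + 400)$discontinued)
})

test_that("median CPZ dose: anchor factor, two-batch enumeration, split invariance", {
  cpz <- cpz_table()
  tl <- build_timeline(mk_purchases(0, dose = 100), FEND)
  expect_equal(as.numeric(median_cpz_dose(tl, cpz)), 100)
  # two batches, 150 and 250 mg/day, equal covered days -> median 200
  p <- rbind(mk_purchases(0, supplied = 30L, dose = 150),
             mk_purchases(200, supplied = 30L, dose = 250))
  med <- median_cpz_dose(tl <- build_timeline(p, FEND), cpz)
  expect_equal(as.numeric(med), 200)
  expect_equal(attr(med, "n_batches"), 2L)
  # splitting one purchase into two consecutive ones changes nothing
  whole <- build_timeline(mk_purchases(0, supplied = 60L, dose = 300,
                                       drug = "olanzapine") , FEND)
  split2 <- build_timeline(mk_purchases(c(0, 30), supplied = 30L, dose = 300,
                                        drug = "olanzapine"), FEND)
  expect_equal(as.numeric(median_cpz_dose(whole, cpz)),
               as.numeric(median_cpz_dose(split2, cpz)))
  # unknown drug errors by name
  bad <- mk_purchases(0, drug = "notadrug")
  expect_error(median_cpz_dose(build_timeline(bad, FEND), cpz), "notadrug")
})

test_that("active-drug share counts covered days on olanzapine/clozapine/quetiapine", {
  expect_equal(active_drug_share(build_timeline(
    mk_purchases(c(0, 30), drug = "olanzapine"), FEND)), 1.0)
  expect_equal(active_drug_share(build_timeline(
    mk_purchases(c(0, 30), drug = "haloperidol"), FEND)), 0.0)
  p <- rbind(mk_purchases(0, supplied = 30L, drug = "quetiapine"),
             mk_purchases(60, supplied = 30L, drug = "haloperidol"))
  expect_equal(active_drug_share(build_timeline(p, FEND)), 0.5)
})

test_that("windowed exposure intersects the look-back with the history", {
  cpz <- cpz_table()
  tl <- build_timeline(mk_purchases(seq(0, 720, by = 30), dose = 100), FEND)
  w <- windowed_exposure(tl, cpz, ORIGIN + 730)
  expect_equal(w$pdc_window, 1.0)
  expect_equal(w$median_cpz_window_mg, 100)
  expect_equal(w$ty_supply_to_anchor, 730 / 365.25)
  # anchor before the first purchase: nothing accumulated
  w0 <- windowed_exposure(tl, cpz, ORIGIN - 10)
  expect_equal(w0$ty_supply_to_anchor, 0)
  expect_true(is.na(w0$pdc_window))
  # anchor shortly after the first purchase: window clipped at first purchase
  w1 <- windowed_exposure(tl, cpz, ORIGIN + 100)
  expect_equal(w1$pdc_window, 1.0)
})

test_that("all coverage metrics match the day-grid FIFO oracle exactly", {
  cpz <- cpz_table()
  set.seed(1234)
  n_checked <- 0
  for (i in 1:250) {
    for (stock in c(TRUE, FALSE)) {
      h <- random_history()
      fend <- max(as.Date(h$purchase_date)) + sample(200:1500, 1)
      tl <- build_timeline(h, fend, stockpile = stock)
      g <- day_grid_profile(h, fend, cpz, stockpile = stock)
      om <- oracle_metrics(g)
      expect_identical(sum(tl$covered$end - tl$covered$start),
                       as.integer(om$covered_days))
      expect_equal(compute_pdc(tl, "first_year"), om$pdc_1year)
      expect_equal(compute_pdc(tl, "last_year"), om$pdc_lastyear)
      expect_equal(compute_pdc(tl, "purchase_span"), om$pdc_purchase)
      expect_equal(compute_pdc(tl, "followup"), om$pdc_followup)
      tls <- treatment_lengths(tl)
      expect_equal(unname(tls["ty_purchase"]), om$ty_purchase)
      expect_equal(unname(tls["ty_supply"]), om$ty_supply)
      expect_equal(as.numeric(median_cpz_dose(tl, cpz)), om$median_cpz)
      expect_equal(active_drug_share(tl), om$active_share)
      expect_identical(tl$supply_end, as.integer(om$supply_end))
      n_checked <- n_checked + 1
    }
  }
  expect_gte(n_checked, 500)
})

test_that("pdc_followup never exceeds pdc_purchase", {
  set.seed(99)
  for (i in 1:200) {
    h <- random_history()
    fend <- max(as.Date(h$purchase_date)) + sample(100:2000, 1)
    tl <- build_timeline(h, fend)
    expect_lte(compute_pdc(tl, "followup"), compute_pdc(tl, "purchase_span") + 1e-12)
  }
})

test_that("look-back metrics track whole-history exposure across a cohort", {
  # two-year look-back anchored at the end of each person's supply (during
  # treatment, a look-back is only meaningful before treatment stops) should
  # correlate strongly with whole-history dose and adherence
  sim <- simulate_cohort(generator_config(n_cases = 150, seed = 314))
  cases <- sim$persons[grepl("^case", sim$persons$person_id), ]
  prof <- derive_profiles(cases, sim$dispensing)
  cpz <- cpz_table()
  sd <- split(sim$dispensing, sim$dispensing$person_id)
  res <- do.call(rbind, lapply(seq_len(nrow(cases)), function(i) {
    p <- cases[i, ]
    tl <- build_timeline(sd[[p$person_id]], p$followup_end)
    if (is.null(tl)) return(NULL)
    w <- windowed_exposure(tl, cpz, as.Date(tl$supply_end, origin = "1970-01-01"))
    cbind(person_id = p$person_id, w)
  }))
  j <- match(res$person_id, prof$person_id)
  ok <- !is.na(res$median_cpz_window_mg) & !is.na(prof$median_cpz_mg[j])
  expect_gt(sum(ok), 100)
  expect_gt(cor(res$median_cpz_window_mg[ok], prof$median_cpz_mg[j][ok]), 0.7)
  expect_gt(cor(res$pdc_window[ok], prof$pdc_purchase[j][ok]), 0.5)
})

test_that("profiles handle never-treated persons and totalize the cohort", {
  pers <- random_persons(20)
  set.seed(5)
  disp <- do.call(rbind, lapply(pers$person_id[1:10], function(id) {
    h <- random_history()
    h$person_id <- id
    h$purchase_date <- pmin(h$purchase_date,
                            pers$followup_end[pers$person_id == id] - 1)
    h
  }))
  prof <- derive_profiles(pers, disp)
  expect_equal(nrow(prof), 20)
  expect_equal(sum(prof$n_purchases == 0), 10)
  expect_true(all(is.na(prof$pdc_purchase[prof$n_purchases == 0])))
  expect_true(all(prof$pdc_purchase[prof$n_purchases > 0] >= 0 &
                    prof$pdc_purchase[prof$n_purchases > 0] <= 1))
})
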