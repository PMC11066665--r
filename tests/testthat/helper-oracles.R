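# Independent brute-force oracles used across the suite. These deliberately
# use different mechanisms than the package implementation (day-by-day
# simulation with a FIFO stock instead of interval arithmetic; exhaustive
# enumeration instead of greedy selection; direct partial-likelihood
# optimisation instead of coxph).

day0 <- function(date) as.integer(as.Date(date))

# Day-grid simulation of medication coverage. Walks the calendar one day at
# a time keeping a FIFO queue of dispensed supplies: with stockpiling, one
# day of supply is consumed per day from the earliest purchase still in
# stock; without, each purchase covers exactly [purchase, purchase+supply).
# Returns per-day covered flags, the consuming drug and its CPZ dose.
day_grid_profile <- function(purchases, followup_end, cpz, stockpile = TRUE) {
  fend <- day0(followup_end)
  pday <- as.integer(as.Date(purchases$purchase_date))
  o <- order(pday)
  purchases <- purchases[o, , drop = FALSE]
  pday <- pday[o]
  start <- min(pday)
  ndays <- fend - start
  covered <- logical(ndays)
  dose <- numeric(ndays)
  active_drug <- character(ndays)
  fac <- cpz$factor[match(tolower(purchases$drug_name), cpz$drug)]
  if (stockpile) {
    # FIFO stock: remaining supply days per purchase
    remaining <- integer(nrow(purchases))
    for (d in seq_len(ndays)) {
      today <- start + d - 1L
      arrived <- which(pday == today)
      remaining[arrived] <- purchases$days_supplied[arrived]
      in_stock <- which(remaining > 0L & pday <= today)
      if (length(in_stock)) {
        k <- in_stock[1] # earliest purchase first
        remaining[k] <- remaining[k] - 1L
        covered[d] <- TRUE
        dose[d] <- purchases$daily_dose_mg[k] * fac[k]
        active_drug[d] <- tolower(purchases$drug_name[k])
      }
    }
  } else {
    for (d in seq_len(ndays)) {
      today <- start + d - 1L
      hits <- which(pday <= today & today < pday + purchases$days_supplied)
      if (length(hits)) {
        covered[d] <- TRUE
        dose[d] <- sum(purchases$daily_dose_mg[hits] * fac[hits])
        active_drug[d] <- paste(tolower(purchases$drug_name[hits]), collapse = "|")
      }
    }
  }
  list(start = start, covered = covered, dose = dose, drug = active_drug,
       first_purchase = start, fend = fend)
}

# All exposure metrics from the day grid.
oracle_metrics <- function(grid, active_set = c("olanzapine", "clozapine", "quetiapine")) {
  cov_days <- which(grid$covered)
  supply_end <- grid$start + max(cov_days)
  fp <- grid$first_purchase
  pdc_win <- function(lo, hi) {
    days <- seq.int(lo, hi - 1L)
    days <- days[days >= grid$start & days < grid$start + length(grid$covered)]
    inwin <- grid$covered[days - grid$start + 1L]
    sum(inwin) / (hi - lo)
  }
  doses <- grid$dose[grid$covered]
  act <- vapply(strsplit(grid$drug[grid$covered], "|", fixed = TRUE),
                function(d) any(d %in% active_set), logical(1))
  list(
    covered_days = length(cov_days),
    pdc_1year = pdc_win(fp, min(fp + 365L, grid$fend)),
    pdc_lastyear = pdc_win(supply_end - 365L, supply_end),
    pdc_purchase = pdc_win(fp, supply_end),
    pdc_followup = pdc_win(fp, grid$fend),
    ty_purchase = (supply_end - fp) / 365.25,
    ty_supply = length(cov_days) / 365.25,
    median_cpz = stats::median(doses),
    active_share = mean(act),
    supply_end = supply_end)
}

# Random dispensing history for property tests.
random_history <- function(n_purchases = NULL, span_days = 3000,
                           drugs = c("olanzapine", "haloperidol", "quetiapine",
                                     "chlorpromazine", "risperidone")) {
  n <- n_purchases %||% sample(1:25, 1)
  data.frame(
    person_id = "p1",
    purchase_date = as.Date(sort(sample.int(span_days, n, replace = TRUE)),
                            origin = "2010-01-01"),
    atc_code = "N05AH03",
    drug_name = sample(drugs, n, replace = TRUE),
    daily_dose_mg = round(stats::runif(n, 25, 600), 1),
    days_supplied = sample(c(7L, 14L, 30L, 60L, 90L), n, replace = TRUE),
    stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Exhaustive minimal-total-distance assignment of one control per case
# (injective), by enumerating all candidate permutations.
brute_force_assignment <- function(case_by, case_sex, cand_by, cand_sex) {
  n <- length(case_by)
  m <- length(cand_by)
  idx <- seq_len(m)
  combos <- utils::combn(m, n, simplify = FALSE)
  best <- Inf
  for (co in combos) {
    for (perm in all_perms(co)) {
      if (any(cand_sex[perm] != case_sex)) next
      d <- sum(abs(cand_by[perm] - case_by))
      if (d < best) best <- d
    }
  }
  best
}

all_perms <- function(x) {
  if (length(x) <= 1) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in all_perms(x[-i])) out[[length(out) + 1]] <- c(x[i], rest)
  }
  out
}

# Negative log partial likelihood for a single-covariate Cox model with
# distinct event times (no ties, so all tie conventions agree).
neg_log_partial_lik <- function(beta, time, event, x) {
  ll <- 0
  for (i in which(event == 1)) {
    risk <- which(time >= time[i])
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  -ll
}

# Standard-normal quantile by bisection on the integrated density —
# an inversion path independent of qnorm().
quantile_by_bisection <- function(p, lo = 0, hi = 10, tol = 1e-10) {
  cdf <- function(z) 0.5 + stats::integrate(stats::dnorm, 0, z,
                                            abs.tol = 1e-12)$value
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (cdf(mid) < p) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Small fully valid synthetic tables for IO round-trips.
random_persons <- function(n) {
  birth <- as.Date("1960-01-01") + sample.int(12000, n, replace = TRUE)
  dead <- stats::runif(n) < 0.1
  death <- as.Date(ifelse(dead, birth + 15000 + sample.int(5000, n, TRUE),
                          NA), origin = "1970-01-01")
  data.frame(person_id = sprintf("p%04d", seq_len(n)),
             sex = sample(c("female", "male"), n, TRUE),
             birth_date = birth,
             death_date = death,
             followup_end = as.Date(ifelse(dead, death,
                                           as.Date("2023-03-31")),
                                    origin = "1970-01-01"),
             stringsAsFactors = FALSE)
}
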