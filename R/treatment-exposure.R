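# Derivation of antipsychotic exposure variables from dispensing records:
# supply timelines, PDC adherence metrics, treatment lengths, discontinuation,
# batched median chlorpromazine-equivalent dose, active-drug share and
# look-back windowed metrics. All coverage arithmetic is exact integer day
# arithmetic on half-open intervals [start, end); no rounding, no RNG.

PDC_WINDOW_DAYS <- 365L

#' Build a per-person medication supply timeline
#'
#' Each purchase contributes `days_supplied` covered days. With stockpiling
#' (the default, standard PDC practice) an early refill is shifted forward to
#' start when the previous supply runs out; without it, supplies start on the
#' purchase date and overlapping days are merged (i.e. lost). All coverage is
#' truncated at `followup_end`.
#'
#' @param purchases data.frame of validated dispensing rows for one person
#'   (columns `purchase_date`, `drug_name`, `daily_dose_mg`, `days_supplied`).
#' @param followup_end Date: end of observation (pass the minimum of the
#'   administrative follow-up end and death for decedents).
#' @param stockpile logical; carry early refills forward (default TRUE).
#' @return object of class `supply_timeline`: covered intervals (integer day
#'   numbers, half-open), per-purchase attributed intervals, first/last
#'   purchase days and the supply end day. `NULL` if there are no purchases
#'   on or before `followup_end` ("never treated").
#' @export
build_timeline <- function(purchases, followup_end, stockpile = TRUE) {
  fend <- as_day(followup_end)
  if (is.null(purchases) || nrow(purchases) == 0L) return(NULL)
  day <- as_day(purchases$purchase_date)
  keep <- day < fend
  if (!any(keep)) return(NULL)
  purchases <- purchases[keep, , drop = FALSE]
  day <- day[keep]
  o <- order(day)
  purchases <- purchases[o, , drop = FALSE]
  day <- day[o]
  supplied <- as.integer(purchases$days_supplied)

  n <- length(day)
  start <- integer(n); end <- integer(n)
  if (stockpile) {
    prev_end <- -.Machine$integer.max
    for (i in seq_len(n)) {
      start[i] <- max(day[i], prev_end)
      end[i] <- start[i] + supplied[i]
      prev_end <- end[i]
    }
  } else {
    start <- day
    end <- day + supplied
  }
  # per-purchase attribution, clipped at end of observation
  pi <- data.frame(start = start, end = pmin(end, fend),
                   drug_name = tolower(purchases$drug_name),
                   daily_dose_mg = as.numeric(purchases$daily_dose_mg))
  pi <- pi[pi$end > pi$start, , drop = FALSE]
  covered <- interval_union(pi$start, pi$end)
  structure(list(
    person_id = if ("person_id" %in% names(purchases)) purchases$person_id[1] else NA_character_,
    covered = covered,
    purchase_intervals = pi,
    first_purchase = min(day),
    last_purchase = max(day),
    supply_end = if (nrow(covered)) max(covered$end) else min(day),
    followup_end = fend,
    stockpile = stockpile,
    n_purchases = n,
    n_distinct_drugs = length(unique(tolower(purchases$drug_name)))
  ), class = "supply_timeline")
}

#' @export
print.supply_timeline <- function(x, ...) {
  cat("Supply timeline:", x$n_purchases, "purchase(s),",
      sum(x$covered$end - x$covered$start), "covered day(s) in",
      nrow(x$covered), "interval(s)\n")
  cat("  first purchase", format(day_to_date(x$first_purchase)),
      "| supply end", format(day_to_date(x$supply_end)), "\n")
  invisible(x)
}

pdc_window_bounds <- function(timeline, window) {
  fp <- timeline$first_purchase
  se <- timeline$supply_end
  fe <- timeline$followup_end
  switch(window,
         first_year = c(fp, min(fp + PDC_WINDOW_DAYS, fe)),
         last_year = c(se - PDC_WINDOW_DAYS, se),
         purchase_span = c(fp, se),
         followup = c(fp, fe),
         stop("unknown PDC window: ", window, call. = FALSE))
}

#' Proportion of days covered in a named window
#'
#' Windows: `first_year` = the 365 days from first purchase (truncated at end
#' of observation), `last_year` = the 365 days ending at the supply end,
#' `purchase_span` = first purchase to supply end, `followup` = first purchase
#' to end of observation.
#'
#' @param timeline a [build_timeline()] result.
#' @param window one of "first_year", "last_year", "purchase_span", "followup".
#' @return proportion in [0, 1], or `NA` for a zero-length window.
#' @export
compute_pdc <- function(timeline, window) {
  if (is.null(timeline)) return(NA_real_)
  b <- pdc_window_bounds(timeline, window)
  len <- b[2] - b[1]
  if (len <= 0L) return(NA_real_)
  cov <- interval_overlap_days(timeline$covered, b[1], b[2])
  min(1, cov / len)
}

#' Treatment length in years, by purchase span and by supplied days
#'
#' @param timeline a [build_timeline()] result.
#' @return named numeric: `ty_purchase` (first purchase to supply end) and
#'   `ty_supply` (total covered days), both in years of 365.25 days.
#' @export
treatment_lengths <- function(timeline) {
  if (is.null(timeline)) return(c(ty_purchase = NA_real_, ty_supply = NA_real_))
  c(ty_purchase = days_to_years(timeline$supply_end - timeline$first_purchase),
    ty_supply = days_to_years(sum(timeline$covered$end - timeline$covered$start)))
}

#' Flag treatment discontinuation
#'
#' Discontinuation means the last medication supply ended more than
#' `threshold_days` (default one year) before the end of follow-up or death.
#'
#' @param timeline a [build_timeline()] result.
#' @param followup_end Date of administrative follow-up end.
#' @param death_date Date of death, or `NA`.
#' @param threshold_days integer threshold, default 365.
#' @return list(discontinued = logical, discontinuation_years = years from
#'   first purchase to supply end).
#' @export
flag_discontinuation <- function(timeline, followup_end, death_date = NA,
                                 threshold_days = 365L) {
  if (is.null(timeline)) {
    return(list(discontinued = NA, discontinuation_years = NA_real_))
  }
  end_day <- as_day(followup_end)
  if (!is.na(death_date)) end_day <- min(end_day, as_day(death_date))
  list(discontinued = (end_day - timeline$supply_end) > threshold_days,
       discontinuation_years = days_to_years(timeline$supply_end - timeline$first_purchase))
}

# Piecewise-constant total CPZ-equivalent dose over covered days.
# Returns data.frame(start, end, dose) with dose > 0 on every segment;
# segments partition the covered set exactly.
dose_segments <- function(timeline, cpz) {
  pi <- timeline$purchase_intervals
  if (nrow(pi) == 0L) return(data.frame(start = integer(0), end = integer(0), dose = numeric(0)))
  dose <- pi$daily_dose_mg * cpz_factor(pi$drug_name, cpz)
  pts <- sort(unique(c(pi$start, pi$end)))
  seg_s <- pts[-length(pts)]
  seg_e <- pts[-1]
  seg_d <- vapply(seq_along(seg_s), function(i) {
    active <- pi$start <= seg_s[i] & pi$end >= seg_e[i]
    sum(dose[active])
  }, numeric(1))
  keep <- seg_d > 0
  data.frame(start = seg_s[keep], end = seg_e[keep], dose = seg_d[keep])
}

# Median of the per-day dose multiset given constant-dose segments; equals
# stats::median applied to the expanded day-by-day vector.
weighted_day_median <- function(dose, ndays) {
  keep <- ndays > 0
  dose <- dose[keep]; ndays <- as.numeric(ndays[keep])
  if (!length(dose)) return(NA_real_)
  o <- order(dose)
  dose <- dose[o]; ndays <- ndays[o]
  n <- sum(ndays)
  cum <- cumsum(ndays)
  if (n %% 2 == 1) {
    k <- (n + 1) / 2
    dose[which(cum >= k)[1]]
  } else {
    lo <- dose[which(cum >= n / 2)[1]]
    hi <- dose[which(cum >= n / 2 + 1)[1]]
    (lo + hi) / 2
  }
}

# Partition covered intervals into batches separated by uncovered gaps longer
# than batch_gap_days; returns an integer batch id per covered interval.
batch_ids <- function(covered, batch_gap_days) {
  if (nrow(covered) == 0L) return(integer(0))
  gaps <- c(0L, covered$start[-1] - covered$end[-nrow(covered)])
  cumsum(gaps > batch_gap_days) + 1L
}

#' Batched median chlorpromazine-equivalent daily dose
#'
#' On every covered day the dose is the sum of daily doses of concurrently
#' active purchases, converted to chlorpromazine milligram equivalents. Days
#' without supply contribute nothing: purchases are considered in batches
#' separated by supply gaps longer than `batch_gap_days`, and the median is
#' taken over covered days across batches (gap days excluded), so long
#' treatment breaks cannot drag the dose summary toward zero.
#'
#' @param timeline a [build_timeline()] result.
#' @param cpz a [cpz_table()] data.frame.
#' @param batch_gap_days gap length (days) separating batches, default 90.
#' @return median dose in chlorpromazine mg/day, with attribute `n_batches`.
#' @export
median_cpz_dose <- function(timeline, cpz, batch_gap_days = 90L) {
  if (is.null(timeline)) return(NA_real_)
  seg <- dose_segments(timeline, cpz)
  med <- weighted_day_median(seg$dose, seg$end - seg$start)
  structure(med, n_batches = length(unique(batch_ids(timeline$covered, batch_gap_days))))
}

#' Share of covered days on metabolically more active antipsychotics
#'
#' A covered day counts as active if any purchase covering it is of an
#' active-set drug (default: olanzapine, clozapine, quetiapine, the agents
#' with the greatest metabolic side-effect burden).
#'
#' @param timeline a [build_timeline()] result.
#' @param active_set character vector of drug names.
#' @return fraction in [0, 1] of covered days on an active-set drug.
#' @export
active_drug_share <- function(timeline,
                              active_set = c("olanzapine", "clozapine", "quetiapine")) {
  if (is.null(timeline)) return(NA_real_)
  total <- sum(timeline$covered$end - timeline$covered$start)
  if (total == 0L) return(NA_real_)
  pi <- timeline$purchase_intervals
  act <- pi[pi$drug_name %in% tolower(active_set), , drop = FALSE]
  if (nrow(act) == 0L) return(0)
  u <- interval_union(act$start, act$end)
  sum(u$end - u$start) / total
}

#' Exposure metrics in a look-back window before an anchor date
#'
#' Computes adherence, median dose and accumulated supply years in the window
#' `[anchor - lookback, anchor)`, intersected with the person's treatment
#' history `[first_purchase, anchor)` — the look-back construction used to
#' attach treatment intensity to each BMI measurement.
#'
#' @param timeline a [build_timeline()] result.
#' @param cpz a [cpz_table()] data.frame.
#' @param anchor Date (typically a BMI measurement date).
#' @param lookback_years look-back length in years (default 2).
#' @param segments optional precomputed dose segments for the timeline
#'   (internal caching across anchors).
#' @return one-row data.frame: `anchor`, `pdc_window`, `median_cpz_window_mg`,
#'   `ty_supply_to_anchor`. Adherence/dose are `NA` when the anchor precedes
#'   the first purchase.
#' @export
windowed_exposure <- function(timeline, cpz, anchor, lookback_years = 2,
                              segments = NULL) {
  a <- as_day(anchor)
  out <- data.frame(anchor = day_to_date(a), pdc_window = NA_real_,
                    median_cpz_window_mg = NA_real_, ty_supply_to_anchor = 0)
  if (is.null(timeline) || a <= timeline$first_purchase) return(out)
  lo <- max(a - as.integer(round(lookback_years * DAYS_PER_YEAR)),
            timeline$first_purchase)
  len <- a - lo
  if (len > 0L) {
    cov <- interval_overlap_days(timeline$covered, lo, a)
    out$pdc_window <- min(1, cov / len)
    if (is.null(segments)) segments <- dose_segments(timeline, cpz)
    seg <- interval_clip_segments(segments, lo, a)
    out$median_cpz_window_mg <- weighted_day_median(seg$dose, seg$end - seg$start)
  }
  out$ty_supply_to_anchor <-
    days_to_years(interval_overlap_days(timeline$covered, timeline$first_purchase, a))
  out
}

interval_clip_segments <- function(seg, lo, hi) {
  s <- pmax(seg$start, lo); e <- pmin(seg$end, hi)
  keep <- e > s
  data.frame(start = s[keep], end = e[keep], dose = seg$dose[keep])
}

#' Derive per-person treatment profiles for a cohort
#'
#' Runs the whole exposure derivation (timeline, four PDCs, treatment lengths,
#' discontinuation, batched median chlorpromazine-equivalent dose, active-drug
#' share) for every person. Persons with no dispensing rows get a profile with
#' `n_purchases = 0` and missing adherence fields — they remain in the cohort
#' as untreated cases.
#'
#' @param persons validated persons data.frame.
#' @param dispensing validated dispensing data.frame.
#' @param cpz a [cpz_table()] data.frame.
#' @param stockpile carry early refills forward (default TRUE).
#' @param batch_gap_days batch separator for the median dose, default 90.
#' @param active_set drugs counted as metabolically more active.
#' @param discontinuation_days discontinuation threshold in days, default 365.
#' @return data.frame, one row per person, with all derived exposure metrics.
#' @export
derive_profiles <- function(persons, dispensing, cpz = cpz_table(),
                            stockpile = TRUE, batch_gap_days = 90L,
                            active_set = c("olanzapine", "clozapine", "quetiapine"),
                            discontinuation_days = 365L) {
  split_disp <- split(dispensing, dispensing$person_id)
  rows <- lapply(seq_len(nrow(persons)), function(i) {
    p <- persons[i, ]
    end_date <- p$followup_end
    if (!is.na(p$death_date)) end_date <- min(end_date, p$death_date)
    disp <- split_disp[[p$person_id]]
    tl <- build_timeline(disp, end_date, stockpile = stockpile)
    if (is.null(tl)) {
      return(data.frame(person_id = p$person_id, n_purchases = 0L,
                        n_distinct_drugs = 0L,
                        pdc_1year = NA_real_, pdc_lastyear = NA_real_,
                        pdc_purchase = NA_real_, pdc_followup = NA_real_,
                        ty_purchase = NA_real_, ty_supply = NA_real_,
                        median_cpz_mg = NA_real_, active_share = NA_real_,
                        discontinued = NA, discontinuation_years = NA_real_))
    }
    tls <- treatment_lengths(tl)
    disc <- flag_discontinuation(tl, p$followup_end, p$death_date,
                                 discontinuation_days)
    data.frame(person_id = p$person_id,
               n_purchases = tl$n_purchases,
               n_distinct_drugs = tl$n_distinct_drugs,
               pdc_1year = compute_pdc(tl, "first_year"),
               pdc_lastyear = compute_pdc(tl, "last_year"),
               pdc_purchase = compute_pdc(tl, "purchase_span"),
               pdc_followup = compute_pdc(tl, "followup"),
               ty_purchase = unname(tls["ty_purchase"]),
               ty_supply = unname(tls["ty_supply"]),
               median_cpz_mg = as.numeric(median_cpz_dose(tl, cpz, batch_gap_days)),
               active_share = active_drug_share(tl, active_set),
               discontinued = disc$discontinued,
               discontinuation_years = disc$discontinuation_years)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Windowed exposure metrics at each BMI measurement
#'
#' @param persons validated persons data.frame.
#' @param dispensing validated dispensing data.frame.
#' @param measurements validated measurements data.frame (BMI rows are used as
#'   anchors).
#' @param cpz a [cpz_table()] data.frame.
#' @param lookback_years look-back length, default 2.
#' @param stockpile carry early refills forward (default TRUE).
#' @return data.frame keyed by (person_id, anchor) with `pdc_window`,
#'   `median_cpz_window_mg`, `ty_supply_to_anchor`.
#' @export
derive_windowed_exposure <- function(persons, dispensing, measurements,
                                     cpz = cpz_table(), lookback_years = 2,
                                     stockpile = TRUE) {
  bmi <- measurements[measurements$kind == "bmi", , drop = FALSE]
  split_disp <- split(dispensing, dispensing$person_id)
  anchors_by_person <- split(as_day(bmi$measure_date), bmi$person_id)
  lb_days <- as.integer(round(lookback_years * DAYS_PER_YEAR))

  n_out <- nrow(bmi)
  out_id <- character(n_out); out_anchor <- integer(n_out)
  out_pdc <- rep(NA_real_, n_out); out_med <- rep(NA_real_, n_out)
  out_ty <- numeric(n_out)
  k <- 0L
  end_days <- as_day(persons$followup_end)
  dd <- as_day(persons$death_date)
  end_days <- ifelse(!is.na(dd), pmin(end_days, dd), end_days)

  for (i in seq_len(nrow(persons))) {
    pid <- persons$person_id[i]
    anchors <- anchors_by_person[[pid]]
    if (is.null(anchors)) next
    tl <- build_timeline(split_disp[[pid]], end_days[i], stockpile = stockpile)
    seg <- if (is.null(tl)) NULL else dose_segments(tl, cpz)
    for (a in anchors) {
      k <- k + 1L
      out_id[k] <- pid; out_anchor[k] <- a
      if (is.null(tl) || a <= tl$first_purchase) next
      lo <- max(a - lb_days, tl$first_purchase)
      if (a > lo) {
        out_pdc[k] <- min(1, interval_overlap_days(tl$covered, lo, a) / (a - lo))
        sg <- interval_clip_segments(seg, lo, a)
        out_med[k] <- weighted_day_median(sg$dose, sg$end - sg$start)
      }
      out_ty[k] <- days_to_years(
        interval_overlap_days(tl$covered, tl$first_purchase, a))
    }
  }
  keep <- seq_len(k)
  data.frame(person_id = out_id[keep], anchor = day_to_date(out_anchor[keep]),
             pdc_window = out_pdc[keep], median_cpz_window_mg = out_med[keep],
             ty_supply_to_anchor = out_ty[keep], stringsAsFactors = FALSE)
}
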