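# Case identification by the earliest qualifying event (first non-lithium
# antipsychotic purchase or first F20-F29 diagnosis) and greedy
# nearest-neighbour control matching on birth year with exact sex matching.

is_ssd_code <- function(icd10) grepl("^F2[0-9]", icd10)

#' Identify schizophrenia cases from diagnoses and dispensing
#'
#' Disease onset is the earlier of the first antipsychotic purchase (ATC
#' N05A*, lithium already excluded at validation) and the first schizophrenia
#' spectrum disorder diagnosis (ICD-10 F20-F29). Persons whose onset falls
#' outside the age window or into the registry buffer period are excluded
#' with reason codes rather than errors.
#'
#' @param persons validated persons data.frame.
#' @param dispensing validated dispensing data.frame.
#' @param diagnoses validated diagnoses data.frame.
#' @param min_age,max_age onset age window in years (defaults 15 and 40).
#' @param min_year onset must fall after this calendar year (default 2006,
#'   i.e. a two-year buffer after the 2004 start of electronic records).
#' @return list with `cases` (person_id, onset_date, onset_source,
#'   age_at_onset, first_purchase_date) and `excluded` (person_id, reason).
#' @export
identify_cases <- function(persons, dispensing, diagnoses,
                           min_age = 15, max_age = 40, min_year = 2006) {
  first_rx <- tapply(as_day(dispensing$purchase_date), dispensing$person_id, min)
  ssd <- diagnoses[is_ssd_code(diagnoses$icd10), , drop = FALSE]
  first_dx <- tapply(as_day(ssd$event_date), ssd$person_id, min)

  ids <- union(names(first_rx), names(first_dx))
  ids <- ids[ids %in% persons$person_id]
  if (!length(ids)) {
    return(list(cases = data.frame(person_id = character(0)),
                excluded = data.frame(person_id = character(0),
                                      reason = character(0))))
  }
  rx <- unname(first_rx[ids]); dx <- unname(first_dx[ids])
  onset <- pmin(rx, dx, na.rm = TRUE)
  source <- ifelse(!is.na(rx) & (is.na(dx) | rx <= dx), "prescription", "diagnosis")

  p <- persons[match(ids, persons$person_id), ]
  age <- days_to_years(onset - as_day(p$birth_date))
  onset_year <- as.integer(format(day_to_date(onset), "%Y"))

  in_age <- age >= min_age & age <= max_age
  in_year <- onset_year > min_year
  keep <- in_age & in_year
  excluded <- data.frame(
    person_id = ids[!keep],
    reason = ifelse(!in_age[!keep], "age_window", "year_window"),
    stringsAsFactors = FALSE)
  cases <- data.frame(
    person_id = ids[keep],
    onset_date = day_to_date(onset[keep]),
    onset_source = source[keep],
    age_at_onset = age[keep],
    first_purchase_date = day_to_date(rx[keep]),
    stringsAsFactors = FALSE)
  cases <- cases[order(cases$person_id), ]
  rownames(cases) <- NULL
  list(cases = cases, excluded = excluded)
}

#' Select birth-year and sex-matched controls
#'
#' Greedy nearest-neighbour matching without replacement: for each case, the
#' `k` not-yet-used candidates of identical sex with the smallest absolute
#' birth-year difference are taken. Candidates with any behavioural or mental
#' disorder diagnosis (ICD-10 F*) or any antipsychotic dispensing are removed
#' from the pool first. Cases are processed in order of ascending exact-year
#' candidate availability (scarcest first), then by person id; candidate ties
#' at equal distance are broken by a seeded shuffle fixed at pool
#' construction. Controls inherit the matched case's onset date as their
#' index date.
#'
#' @param cases case table from [identify_cases()].
#' @param persons validated persons data.frame (cases plus candidate pool;
#'   case rows are looked up for birth year and sex, all other rows form the
#'   candidate pool).
#' @param diagnoses,dispensing validated tables used to screen candidates.
#' @param k controls per case (default 4).
#' @param seed integer seed for the tie-breaking shuffle.
#' @return object of class `matched_cohort`: data.frame with columns
#'   `case_id`, `control_id`, `birth_year_distance`, `index_date`.
#' @export
match_controls <- function(cases, persons, diagnoses, dispensing,
                           k = 4L, seed = 1L) {
  stopifnot(k >= 1L, nrow(cases) > 0L)
  has_f <- unique(diagnoses$person_id[grepl("^F", diagnoses$icd10)])
  has_ap <- unique(dispensing$person_id)
  pool <- persons[!(persons$person_id %in% c(has_f, has_ap, cases$person_id)), ]
  pool_by <- as.integer(format(pool$birth_date, "%Y"))
  pool_sex <- pool$sex
  tiebreak <- with_seed(substream_seed(seed, "match_ties"),
                        stats::runif(nrow(pool)))
  available <- rep(TRUE, nrow(pool))

  cp <- persons[match(cases$person_id, persons$person_id), ]
  case_by <- as.integer(format(cp$birth_date, "%Y"))
  case_sex <- cp$sex

  # scarcest cases first: fewest available exact-year same-sex candidates
  scarcity <- vapply(seq_len(nrow(cases)), function(i) {
    sum(pool_sex == case_sex[i] & pool_by == case_by[i])
  }, numeric(1))
  case_order <- order(scarcity, cases$person_id)

  out <- vector("list", nrow(cases))
  for (i in case_order) {
    elig <- which(available & pool_sex == case_sex[i])
    if (length(elig) < k) {
      stop("control pool exhausted for case ", cases$person_id[i],
           ": need ", k, ", have ", length(elig), call. = FALSE)
    }
    dist <- abs(pool_by[elig] - case_by[i])
    pick <- elig[order(dist, tiebreak[elig])[seq_len(k)]]
    available[pick] <- FALSE
    out[[i]] <- data.frame(case_id = cases$person_id[i],
                           control_id = pool$person_id[pick],
                           birth_year_distance = abs(pool_by[pick] - case_by[i]),
                           index_date = cases$onset_date[i],
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out[order(seq_along(out))])
  res <- res[order(res$case_id), ]
  rownames(res) <- NULL
  class(res) <- c("matched_cohort", "data.frame")
  res
}

#' @export
print.matched_cohort <- function(x, ...) {
  cat("Matched cohort:", length(unique(x$case_id)), "cases,",
      nrow(x), "controls (",
      round(mean(x$birth_year_distance == 0) * 100, 1),
      "% exact birth-year matches)\n")
  invisible(x)
}

#' Total birth-year distance of a matching
#'
#' Convenience summary used to compare the greedy assignment with exhaustive
#' oracles on small pools.
#'
#' @param matched a [match_controls()] result.
#' @return sum of absolute birth-year differences over all matched pairs.
#' @export
matching_total_distance <- function(matched) sum(matched$birth_year_distance)
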