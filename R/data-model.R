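#' The twenty antipsychotic agents recognised in dispensing records
#'
#' Dispensing rows whose drug name is not on this list (or whose ATC code is
#' outside N05A, or is lithium N05AN) are rejected during validation.
#'
#' @return character vector of lowercase drug names.
#' @export
antipsychotic_drugs <- function() {
  c("quetiapine", "olanzapine", "aripiprazole", "clozapine", "risperidone",
    "haloperidol", "amisulpride", "sertindole", "flupentixol", "perphenazine",
    "ziprasidone", "levomepromazine", "zuclopenthixol", "chlorprothixene",
    "sulpiride", "cariprazine", "melperone", "chlorpromazine", "fluphenazine",
    "paliperidone")
}

#' Names of the fifteen polygenic score traits
#'
#' Schizophrenia plus fourteen cardiometabolic traits: coronary heart disease,
#' total/LDL/HDL/non-HDL cholesterol, triglycerides, C-reactive protein,
#' glycated haemoglobin, fasting and random glucose, type 2 diabetes, BMI and
#' systolic/diastolic blood pressure.
#'
#' @return character vector of length 15.
#' @export
prs_traits <- function() {
  c("SCZ", "CHD", "TC", "LDL", "HDL", "nonHDL", "TG", "CRP", "HbA1c",
    "FG", "RG", "T2D", "BMI", "SBP", "DBP")
}

pc_names <- function() paste0("PC", 1:10)

# Canonical column sets per table type.
canonical_schema <- function() {
  list(
    persons = c("person_id", "sex", "birth_date", "death_date", "followup_end"),
    dispensing = c("person_id", "purchase_date", "atc_code", "drug_name",
                   "daily_dose_mg", "days_supplied"),
    diagnoses = c("person_id", "event_date", "icd10"),
    measurements = c("person_id", "measure_date", "kind", "value"),
    prs = c("person_id", prs_traits(), pc_names())
  )
}

# Returns list(parsed = Date vector, bad = logical of unparseable non-missing)
parse_dates <- function(x) {
  if (inherits(x, "Date")) return(list(parsed = x, bad = rep(FALSE, length(x))))
  x <- as.character(x)
  missing <- is.na(x) | !nzchar(x) | x %in% c("NA", ".")
  parsed <- as.Date(rep(NA_character_, length(x)))
  parsed[!missing] <- as.Date(x[!missing], format = "%Y-%m-%d")
  list(parsed = parsed, bad = !missing & is.na(parsed))
}

read_delim_auto <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    colClasses = "character", quote = "\"", comment.char = "",
                    check.names = FALSE)
}

apply_schema <- function(df, type, schema_config = NULL) {
  canon <- canonical_schema()[[type]]
  mapping <- schema_config[[type]] %||% list()
  for (canon_name in names(mapping)) {
    file_name <- mapping[[canon_name]]
    if (file_name %in% names(df)) {
      names(df)[names(df) == file_name] <- canon_name
    }
  }
  required <- setdiff(canon, c("death_date"))
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("schema error in '", type, "' table: missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!"death_date" %in% names(df) && type == "persons") df$death_date <- NA
  df[, canon, drop = FALSE]
}

reject <- function(rows, reason) {
  if (!length(rows)) return(NULL)
  data.frame(line = rows, reason = reason, stringsAsFactors = FALSE)
}

#' Validate a persons table
#'
#' Enforces the person-level invariants: parseable ISO-8601 dates, birth before
#' end of follow-up and, for decedents, death on or before (and defining) the
#' end of follow-up.
#'
#' @param df data.frame with canonical persons columns.
#' @return list with elements `valid` (typed data.frame) and `rejected`
#'   (data.frame of line numbers and reason codes; zero rows when clean).
#' @export
validate_persons <- function(df) {
  n <- nrow(df)
  bd <- parse_dates(df$birth_date); dd <- parse_dates(df$death_date)
  fe <- parse_dates(df$followup_end)
  bad_date <- bd$bad | dd$bad | fe$bad
  bad_sex <- !(df$sex %in% c("female", "male"))
  birth <- bd$parsed; death <- dd$parsed; fend <- fe$parsed
  bad_order <- !bad_date & (is.na(birth) | is.na(fend) | birth >= fend)
  bad_death <- !bad_date & !is.na(death) & !is.na(fend) & death > fend
  bad <- bad_date | bad_sex | bad_order | bad_death
  rej <- rbind(reject(which(bad_date), "unparseable_date"),
               reject(which(bad_sex & !bad_date), "invalid_sex"),
               reject(which(bad_order & !bad_sex), "birth_after_followup"),
               reject(which(bad_death & !bad_order & !bad_sex), "death_after_followup"))
  valid <- data.frame(person_id = as.character(df$person_id)[!bad],
                      sex = df$sex[!bad],
                      birth_date = birth[!bad],
                      death_date = death[!bad],
                      followup_end = fend[!bad],
                      stringsAsFactors = FALSE)
  list(valid = valid, rejected = rej %||% reject(integer(0), character(0)) %||%
         data.frame(line = integer(0), reason = character(0)))
}

#' Validate a dispensing table
#'
#' Rejects rows outside ATC class N05A, lithium rows (N05AN), drugs not on the
#' recognised antipsychotic list, non-positive doses or supplies, and
#' unparseable dates.
#'
#' @inheritParams validate_persons
#' @return list(valid, rejected) as in [validate_persons()].
#' @export
validate_dispensing <- function(df) {
  pd <- parse_dates(df$purchase_date)
  dose <- suppressWarnings(as.numeric(df$daily_dose_mg))
  supp <- suppressWarnings(as.numeric(df$days_supplied))
  drug <- tolower(as.character(df$drug_name))
  atc <- toupper(as.character(df$atc_code))
  bad_date <- pd$bad | is.na(pd$parsed)
  bad_atc <- !startsWith(atc, "N05A")
  lithium <- startsWith(atc, "N05AN")
  bad_drug <- !(drug %in% antipsychotic_drugs())
  bad_dose <- is.na(dose) | dose <= 0
  bad_supp <- is.na(supp) | supp <= 0 | supp != round(supp)
  bad <- bad_date | bad_atc | lithium | bad_drug | bad_dose | bad_supp
  rej <- rbind(reject(which(bad_date), "unparseable_date"),
               reject(which(lithium & !bad_date), "lithium_excluded"),
               reject(which(bad_atc & !bad_date), "atc_not_antipsychotic"),
               reject(which(bad_drug & !bad_atc & !lithium & !bad_date), "unknown_drug"),
               reject(which(bad_dose & !bad_drug & !bad_atc & !lithium & !bad_date), "non-positive dose"),
               reject(which(bad_supp & !bad_dose & !bad_drug & !bad_atc & !lithium & !bad_date), "non-positive supply"))
  valid <- data.frame(person_id = as.character(df$person_id)[!bad],
                      purchase_date = pd$parsed[!bad],
                      atc_code = atc[!bad],
                      drug_name = drug[!bad],
                      daily_dose_mg = dose[!bad],
                      days_supplied = as.integer(supp[!bad]),
                      stringsAsFactors = FALSE)
  list(valid = valid,
       rejected = rej %||% data.frame(line = integer(0), reason = character(0)))
}

#' Validate a diagnosis-event table
#'
#' @inheritParams validate_persons
#' @return list(valid, rejected) as in [validate_persons()].
#' @export
validate_diagnoses <- function(df) {
  ed <- parse_dates(df$event_date)
  icd <- toupper(as.character(df$icd10))
  bad_date <- ed$bad | is.na(ed$parsed)
  bad_icd <- !grepl("^[A-Z][0-9]{2}(\\.[0-9]+)?$", icd)
  bad <- bad_date | bad_icd
  rej <- rbind(reject(which(bad_date), "unparseable_date"),
               reject(which(bad_icd & !bad_date), "invalid_icd10"))
  valid <- data.frame(person_id = as.character(df$person_id)[!bad],
                      event_date = ed$parsed[!bad],
                      icd10 = icd[!bad], stringsAsFactors = FALSE)
  list(valid = valid,
       rejected = rej %||% data.frame(line = integer(0), reason = character(0)))
}

#' Validate a measurements table (BMI and smoking)
#'
#' BMI values must be plausible (10--80 kg/m2); smoking values must be
#' ever/never.
#'
#' @inheritParams validate_persons
#' @return list(valid, rejected) as in [validate_persons()].
#' @export
validate_measurements <- function(df) {
  md <- parse_dates(df$measure_date)
  kind <- tolower(as.character(df$kind))
  val <- as.character(df$value)
  bad_date <- md$bad | is.na(md$parsed)
  bad_kind <- !(kind %in% c("bmi", "smoking"))
  num <- suppressWarnings(as.numeric(val))
  bad_bmi <- kind == "bmi" & (is.na(num) | num <= 10 | num >= 80)
  bad_smk <- kind == "smoking" & !(val %in% c("ever", "never"))
  bad <- bad_date | bad_kind | bad_bmi | bad_smk
  rej <- rbind(reject(which(bad_date), "unparseable_date"),
               reject(which(bad_kind & !bad_date), "unknown_kind"),
               reject(which(bad_bmi & !bad_kind & !bad_date), "bmi_out_of_range"),
               reject(which(bad_smk & !bad_kind & !bad_date), "invalid_smoking_value"))
  valid <- data.frame(person_id = as.character(df$person_id)[!bad],
                      measure_date = md$parsed[!bad],
                      kind = kind[!bad], value = val[!bad],
                      stringsAsFactors = FALSE)
  list(valid = valid,
       rejected = rej %||% data.frame(line = integer(0), reason = character(0)))
}

#' Validate a polygenic-score table
#'
#' Requires all 15 trait columns and 10 genotype principal components, numeric
#' and complete.
#'
#' @inheritParams validate_persons
#' @return list(valid, rejected) as in [validate_persons()].
#' @export
validate_prs <- function(df) {
  score_cols <- c(prs_traits(), pc_names())
  num <- df
  for (cc in score_cols) num[[cc]] <- suppressWarnings(as.numeric(df[[cc]]))
  bad <- rowSums(is.na(as.matrix(num[, score_cols]))) > 0
  rej <- reject(which(bad), "missing_or_nonnumeric_score")
  valid <- num[!bad, c("person_id", score_cols), drop = FALSE]
  valid$person_id <- as.character(valid$person_id)
  rownames(valid) <- NULL
  list(valid = valid,
       rejected = rej %||% data.frame(line = integer(0), reason = character(0)))
}

#' Read and validate the full set of cohort tables
#'
#' Reads CSV or TSV files (dialect sniffed from the header line), renames
#' columns through an optional schema mapping, validates every row against the
#' type invariants and returns typed collections plus a rejection report.
#' Validation is total: every input row is either accepted or listed in the
#' rejection report.
#'
#' @param paths named list/vector with elements `persons`, `dispensing`,
#'   `diagnoses`, `measurements`, `prs` (any subset).
#' @param schema_config optional nested list mapping canonical column names to
#'   the file's column names, e.g. `list(persons = list(person_id = "ID"))`.
#' @return list with one validated data.frame per supplied table plus
#'   `rejections`, a data.frame with columns `table`, `line`, `reason`.
#' @export
read_tables <- function(paths, schema_config = NULL) {
  out <- list()
  rejections <- data.frame(table = character(0), line = integer(0),
                           reason = character(0))
  validators <- list(persons = validate_persons,
                     dispensing = validate_dispensing,
                     diagnoses = validate_diagnoses,
                     measurements = validate_measurements,
                     prs = validate_prs)
  for (type in names(validators)) {
    if (is.null(paths[[type]])) next
    if (!file.exists(paths[[type]])) {
      stop("file not found for table '", type, "': ", paths[[type]], call. = FALSE)
    }
    raw <- read_delim_auto(paths[[type]])
    df <- apply_schema(raw, type, schema_config)
    v <- validators[[type]](df)
    out[[type]] <- v$valid
    if (nrow(v$rejected)) {
      rejections <- rbind(rejections,
                          cbind(table = type, v$rejected))
    }
  }
  out$rejections <- rejections
  out
}

#' Write a validated collection as tab-separated text
#'
#' Dates are serialised as ISO-8601 so that [read_tables()] round-trips the
#' collection unchanged.
#'
#' @param records data.frame to write.
#' @param path output file path (written as TSV).
#' @return invisibly, `path`.
#' @export
write_tables <- function(records, path) {
  df <- records
  for (cc in names(df)) {
    if (inherits(df[[cc]], "Date")) df[[cc]] <- format(df[[cc]], "%Y-%m-%d")
  }
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE,
                     na = "NA")
  invisible(path)
}

#' Reduce smoking measurements to one ever/never status per person
#'
#' Any recorded "ever" wins over any number of "never" records.
#'
#' @param measurements validated measurements data.frame.
#' @return data.frame with columns `person_id`, `smoking` ("ever"/"never").
#' @export
reduce_smoking <- function(measurements) {
  smk <- measurements[measurements$kind == "smoking", , drop = FALSE]
  if (!nrow(smk)) {
    return(data.frame(person_id = character(0), smoking = character(0)))
  }
  ever <- tapply(smk$value == "ever", smk$person_id, any)
  data.frame(person_id = names(ever),
             smoking = ifelse(ever, "ever", "never"),
             stringsAsFactors = FALSE, row.names = NULL)
}
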