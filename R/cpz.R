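#' Chlorpromazine dose-equivalence table
#'
#' Loads the shipped table of oral dose equivalents (mg of each agent with
#' potency comparable to 100 mg chlorpromazine, after published consensus
#' equivalence tables) and derives the multiplicative conversion factor
#' `mg chlorpromazine per mg of drug`. The table is data, not code: pass a
#' path to substitute institution-specific equivalents.
#'
#' @param path optional path to a TSV with columns `drug` and
#'   `cpz100_equiv_mg`; defaults to the table shipped with the package.
#' @return data.frame with columns `drug`, `cpz100_equiv_mg`, `factor`
#'   (chlorpromazine mg per drug mg); chlorpromazine's factor is exactly 1.
#' @export
cpz_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "cpz_equivalents.tsv", package = "apmets")
  }
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  stopifnot(all(c("drug", "cpz100_equiv_mg") %in% names(tab)),
            all(tab$cpz100_equiv_mg > 0))
  tab$drug <- tolower(tab$drug)
  tab$factor <- 100 / tab$cpz100_equiv_mg
  tab
}

cpz_factor <- function(drugs, cpz) {
  idx <- match(drugs, cpz$drug)
  if (anyNA(idx)) {
    stop("drug(s) missing from CPZ equivalence table: ",
         paste(unique(drugs[is.na(idx)]), collapse = ", "), call. = FALSE)
  }
  cpz$factor[idx]
}
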