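# Polygenic-score association: pairwise score correlations, covariate-adjusted
# marginal scans (logistic for case status, linear for continuous outcomes)
# and the forward-stepwise multivariate procedure that repeatedly admits the
# lowest-p candidate score.

#' Pearson correlation matrix of the polygenic scores
#'
#' @param prs validated polygenic-score data.frame (or any data.frame holding
#'   the trait columns).
#' @param traits trait columns to use, default all fifteen.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
prs_correlation <- function(prs, traits = prs_traits()) {
  m <- as.matrix(prs[, traits, drop = FALSE])
  if (nrow(m) < 3L) stop("need at least 3 persons", call. = FALSE)
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant score column(s): ",
         paste(traits[sds == 0], collapse = ", "), call. = FALSE)
  }
  stats::cor(m)
}

fit_one <- function(data, outcome, term, covariates, family) {
  # covariates first: an aliased candidate (not the covariate) is the term
  # that gets dropped and reported as a singular fit
  rhs <- paste(c(covariates, term), collapse = " + ")
  f <- stats::as.formula(paste(outcome, "~", rhs))
  fit <- tryCatch({
    if (family == "binomial") {
      stats::glm(f, data = data, family = stats::binomial())
    } else {
      stats::lm(f, data = data)
    }
  }, error = function(e) e, warning = function(w) w)
  if (inherits(fit, "condition")) {
    return(data.frame(term = term, estimate = NA_real_, se = NA_real_,
                      p = NA_real_, or = NA_real_, ci_lo = NA_real_,
                      ci_hi = NA_real_, status = conditionMessage(fit),
                      stringsAsFactors = FALSE))
  }
  co <- summary(fit)$coefficients
  if (!(term %in% rownames(co)) || anyNA(co[term, ])) {
    return(data.frame(term = term, estimate = NA_real_, se = NA_real_,
                      p = NA_real_, or = NA_real_, ci_lo = NA_real_,
                      ci_hi = NA_real_, status = "singular fit",
                      stringsAsFactors = FALSE))
  }
  est <- co[term, 1]; se <- co[term, 2]; p <- co[term, 4]
  is_bin <- family == "binomial"
  data.frame(term = term, estimate = est, se = se, p = p,
             or = if (is_bin) exp(est) else NA_real_,
             ci_lo = if (is_bin) exp(est - 1.96 * se) else est - 1.96 * se,
             ci_hi = if (is_bin) exp(est + 1.96 * se) else est + 1.96 * se,
             status = "ok", stringsAsFactors = FALSE)
}

#' Covariate-adjusted marginal scan over candidate polygenic scores
#'
#' Fits one regression per candidate score (logistic for a binary outcome,
#' linear otherwise), each adjusted for the baseline covariates, and reports
#' Wald estimates, standard errors, two-sided p-values and, for binary
#' outcomes, odds ratios with 95% confidence intervals. A candidate whose fit
#' fails (separation, singularity) is recorded with a status message and the
#' scan continues.
#'
#' @param data data.frame containing outcome, candidates and covariates.
#' @param outcome name of the outcome column (0/1 for binary).
#' @param candidates candidate score column names.
#' @param covariates baseline covariate column names (default sex, birth year
#'   and the 10 genotype principal components where present).
#' @param family "binomial" or "gaussian"; guessed from the outcome if NULL.
#' @return data.frame of per-candidate fits, ordered as `candidates`.
#' @export
marginal_scan <- function(data, outcome, candidates,
                          covariates = intersect(c("sex", "birth_year", pc_names()),
                                                 names(data)),
                          family = NULL) {
  if (is.null(family)) {
    y <- data[[outcome]]
    family <- if (all(y %in% c(0, 1, NA))) "binomial" else "gaussian"
  }
  out <- do.call(rbind, lapply(candidates, function(tr) {
    fit_one(data, outcome, tr, covariates, family)
  }))
  rownames(out) <- NULL
  out
}

#' Forward-stepwise polygenic-score selection
#'
#' Starting from the baseline covariate model, repeatedly refits every
#' remaining candidate against the current model and admits the one with the
#' lowest Wald p-value, as long as that p-value is below the entry threshold;
#' ties are broken by trait-name order. Stops when no candidate enters.
#'
#' @inheritParams marginal_scan
#' @param alpha entry threshold; defaults to the Bonferroni level
#'   `0.05 / length(candidates)`.
#' @return object of class `stepwise_result`: list with `trace` (step, term,
#'   p at entry), `included`, `final` (coefficient table of the final model),
#'   `marginal` (the initial scan) and the thresholds used. Each marginal row
#'   carries Bonferroni and nominal significance flags.
#' @export
forward_stepwise <- function(data, outcome, candidates,
                             covariates = intersect(c("sex", "birth_year", pc_names()),
                                                    names(data)),
                             alpha = 0.05 / length(candidates),
                             family = NULL) {
  if (is.null(family)) {
    y <- data[[outcome]]
    family <- if (all(y %in% c(0, 1, NA))) "binomial" else "gaussian"
  }
  marginal <- marginal_scan(data, outcome, candidates, covariates, family)
  marginal$sig_bonferroni <- !is.na(marginal$p) & marginal$p < alpha
  marginal$sig_nominal <- !is.na(marginal$p) & marginal$p < 0.05

  included <- character(0)
  remaining <- candidates
  trace <- data.frame(step = integer(0), term = character(0), p = numeric(0))
  repeat {
    if (!length(remaining)) break
    scan <- marginal_scan(data, outcome, remaining,
                          covariates = c(covariates, included), family = family)
    scan <- scan[order(scan$p, scan$term), ]
    best <- scan[!is.na(scan$p), ][1, ]
    if (!nrow(best) || is.na(best$p) || best$p >= alpha) break
    included <- c(included, best$term)
    remaining <- setdiff(remaining, best$term)
    trace <- rbind(trace, data.frame(step = length(included),
                                     term = best$term, p = best$p))
  }
  final <- marginal_scan(data, outcome,
                         if (length(included)) included else character(0),
                         covariates = covariates, family = family)
  if (length(included) > 1) {
    # refit jointly: each included term adjusted for the others + baseline
    final <- do.call(rbind, lapply(included, function(tr) {
      fit_one(data, outcome, tr, c(covariates, setdiff(included, tr)), family)
    }))
  }
  structure(list(trace = trace, included = included, final = final,
                 marginal = marginal, alpha = alpha, outcome = outcome,
                 family = family),
            class = "stepwise_result")
}

#' @export
print.stepwise_result <- function(x, ...) {
  cat("Forward-stepwise scan of", nrow(x$marginal), "candidate scores on '",
      x$outcome, "' (entry p <", signif(x$alpha, 3), ")\n", sep = " ")
  if (length(x$included)) {
    for (i in seq_len(nrow(x$trace))) {
      cat(sprintf("  step %d: + %s (p = %.3g)\n", x$trace$step[i],
                  x$trace$term[i], x$trace$p[i]))
    }
  } else {
    cat("  no score entered; final model = baseline covariates only\n")
  }
  invisible(x)
}
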