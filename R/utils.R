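#' @keywords internal
"_PACKAGE"

DAYS_PER_YEAR <- 365.25

#' Convert whole days to years
#'
#' Single package-wide convention: one year is 365.25 days.
#'
#' @param days numeric vector of day counts.
#' @return numeric vector of years.
#' @export
days_to_years <- function(days) days / DAYS_PER_YEAR

# Dates are handled internally as integer day numbers (days since 1970-01-01);
# all intervals are half-open [start, end) counted in whole days.
as_day <- function(x) {
  if (inherits(x, "Date")) return(as.integer(unclass(x)))
  if (is.character(x)) return(as.integer(unclass(as.Date(x))))
  as.integer(x)
}

day_to_date <- function(d) as.Date(d, origin = "1970-01-01")

#' Union of half-open integer intervals
#'
#' Merges overlapping or touching intervals [start, end) into a disjoint,
#' sorted set.
#'
#' @param start,end integer vectors of equal length; each interval must have
#'   `end > start`.
#' @return data.frame with columns `start`, `end`, disjoint and sorted.
#' @keywords internal
interval_union <- function(start, end) {
  stopifnot(length(start) == length(end))
  keep <- end > start
  start <- start[keep]; end <- end[keep]
  if (length(start) == 0L) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  out_s <- start[1]; out_e <- end[1]
  res_s <- integer(0); res_e <- integer(0)
  for (i in seq_along(start)[-1]) {
    if (start[i] <= out_e) {
      out_e <- max(out_e, end[i])
    } else {
      res_s <- c(res_s, out_s); res_e <- c(res_e, out_e)
      out_s <- start[i]; out_e <- end[i]
    }
  }
  data.frame(start = c(res_s, out_s), end = c(res_e, out_e))
}

# Total days of intervals intersected with window [lo, hi).
interval_overlap_days <- function(intervals, lo, hi) {
  if (nrow(intervals) == 0L || hi <= lo) return(0L)
  s <- pmax(intervals$start, lo)
  e <- pmin(intervals$end, hi)
  sum(pmax(e - s, 0L))
}

# Clip intervals to [lo, hi).
interval_clip <- function(intervals, lo, hi) {
  s <- pmax(intervals$start, lo)
  e <- pmin(intervals$end, hi)
  keep <- e > s
  data.frame(start = s[keep], end = e[keep])
}

# Deterministic substream seed derived from a root seed and a stage name, so
# that adding a downstream stage never perturbs draws of earlier stages.
substream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.double(seed) * 48271 + h * 7919) %% 2147483647)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
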