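#' Descriptive hydrochemistry summary
#'
#' Per-analyte mean, sample standard deviation (n - 1 denominator),
#' range, coefficient of variation and exceedance against the configured
#' drinking limit, computed on working values (below-detection cells are
#' substituted at MDL/2 first if they have not been already).
#'
#' @param table a [conc_table()].
#' @param water_type water types to include (default `"surface"`, the
#'   convention for reporting drinking-water statistics; use `NULL` for
#'   all samples).
#' @return A data frame with one row per analyte: `analyte`, `mean`,
#'   `sd`, `min`, `max`, `cv_percent` (100 * sd/mean, `NA` when the mean
#'   is zero), `exceed_count` and `exceed_percent` (`NA` where no limit
#'   is configured).
#' @export
#' @examples
#' fx <- make_worked_fixtures()
#' head(summarize_concentrations(fx$table))
summarize_concentrations <- function(table, water_type = "surface") {
  stopifnot(inherits(table, "conc_table"))
  tab <- filter_water_type(table, water_type)
  if (!tab$substituted) tab <- substitute_censored(tab)
  X <- tab$conc
  n <- nrow(X)
  if (n < 2) stop("need at least 2 samples for a summary")
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  cv <- ifelse(mu == 0, NA_real_, 100 * sdv / mu)
  lim <- tab$analytes$drinking_limit
  cnt <- vapply(seq_len(ncol(X)),
                function(j) if (is.na(lim[j])) NA_integer_
                            else sum(X[, j] > lim[j]),
                integer(1))
  data.frame(
    analyte = colnames(X),
    mean = mu, sd = sdv,
    min = apply(X, 2, min), max = apply(X, 2, max),
    cv_percent = cv,
    exceed_count = cnt,
    exceed_percent = 100 * cnt / n,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Exceedance of a drinking-water limit
#'
#' Counts samples whose working value strictly exceeds the limit
#' (equality is compliant). The percentage is kept at full precision;
#' round only at display time.
#'
#' @param table a [conc_table()].
#' @param analyte analyte name.
#' @param limit limit in ug/L; defaults to the configured drinking limit.
#' @param water_type water types to include (default `"surface"`).
#' @param strict if `FALSE`, count `>=` instead of `>`.
#' @return list with `count`, `n` and `percent`.
#' @export
exceedance <- function(table, analyte, limit = NULL,
                       water_type = "surface", strict = TRUE) {
  stopifnot(inherits(table, "conc_table"))
  tab <- filter_water_type(table, water_type)
  if (!tab$substituted) tab <- substitute_censored(tab)
  if (!analyte %in% colnames(tab$conc))
    stop("analyte '", analyte, "' not present in table")
  if (is.null(limit))
    limit <- tab$analytes$drinking_limit[tab$analytes$name == analyte]
  if (is.na(limit) || limit <= 0)
    stop("no positive limit available for '", analyte, "'")
  x <- tab$conc[, analyte]
  cnt <- if (strict) sum(x > limit) else sum(x >= limit)
  list(count = cnt, n = length(x), percent = 100 * cnt / length(x))
}

#' Rank analytes by a summary statistic
#'
#' Descending order by the chosen key; ties broken lexicographically by
#' analyte name so rankings are deterministic.
#'
#' @param summary output of [summarize_concentrations()].
#' @param key `"mean"` or `"cv_percent"`.
#' @return Character vector of analyte names, highest first.
#' @export
rank_analytes <- function(summary, key = c("mean", "cv_percent")) {
  key <- match.arg(key)
  stopifnot(nrow(summary) >= 1)
  ord <- order(-summary[[key]], summary$analyte)
  summary$analyte[ord]
}
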