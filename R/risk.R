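#' Exposure parameter sets
#'
#' One row per population group (`children`, `men`, `women`) with oral
#' ingestion rate `IR` (L/day), exposure frequency `EF` (days/year),
#' exposure duration `ED` (years), body weight `BW` (kg) and life
#' expectancy `LE` (years).
#'
#' @param group,IR,EF,ED,BW,LE vectors of equal length.
#' @return data frame of class `exposure_params`.
#' @export
exposure_params <- function(group, IR, EF, ED, BW, LE) {
  df <- data.frame(group = as.character(group), IR = IR, EF = EF,
                   ED = ED, BW = BW, LE = LE, stringsAsFactors = FALSE)
  with(df, stopifnot(all(IR > 0), all(EF > 0), all(EF <= 365),
                     all(ED > 0), all(BW > 0), all(LE > 0),
                     all(ED <= LE)))
  if (anyDuplicated(df$group)) stop("duplicate group names")
  class(df) <- c("exposure_params", "data.frame")
  df
}

#' Default exposure parameters
#'
#' Commonly used Chinese technical-guideline values for drinking-water
#' ingestion, shipped as editable defaults (site studies should supply
#' their own): children IR 1.0 L/d, BW 16 kg, ED 6 y; men IR 2.2 L/d,
#' BW 65 kg, ED 30 y; women IR 1.7 L/d, BW 56 kg, ED 30 y; EF 365 d/y
#' and LE 70 y throughout.
#'
#' @return An [exposure_params()] data frame with three rows.
#' @export
default_exposure <- function() {
  exposure_params(
    group = c("children", "men", "women"),
    IR = c(1.0, 2.2, 1.7),
    EF = c(365, 365, 365),
    ED = c(6, 30, 30),
    BW = c(16, 65, 56),
    LE = c(70, 70, 70)
  )
}

#' Read exposure parameters from YAML
#'
#' @param path YAML file with one entry per group carrying keys
#'   `group`, `IR`, `EF`, `ED`, `BW`, `LE`.
#' @return An [exposure_params()] data frame.
#' @export
read_exposure_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$groups)) raw <- raw$groups
  df <- do.call(rbind, lapply(raw, as.data.frame))
  exposure_params(df$group, df$IR, df$EF, df$ED, df$BW, df$LE)
}

#' Toxicity constants
#'
#' Oral reference doses (RfD, mg/(kg d)) for the non-carcinogenic
#' analytes and slope factors (SF, (kg d)/mg) for the carcinogens.
#'
#' @param rfd named numeric vector of reference doses, all positive.
#' @param sf named numeric vector of slope factors (may be empty).
#' @return list of class `toxicity_table` with elements `rfd` and `sf`.
#' @export
toxicity_table <- function(rfd, sf = numeric(0)) {
  stopifnot(all(rfd > 0), all(sf > 0),
            !is.null(names(rfd)), length(sf) == 0 || !is.null(names(sf)))
  structure(list(rfd = rfd, sf = sf), class = "toxicity_table")
}

#' Default toxicity constants
#'
#' Oral RfDs for the 15 assessed analytes -- Fe 0.7, Mn 0.14, Cu 0.04,
#' Zn 0.3, Al 1, As 0.0003, Se 0.005, Cd 0.0005, Li 0.002, B 0.2,
#' Ba 0.2, Sb 0.0004, Ni 0.02, Co 0.0003, Mo 0.005 mg/(kg d) -- and the
#' single slope factor, As 1.5 (kg d)/mg.
#'
#' @return A [toxicity_table()].
#' @export
default_toxicity <- function() {
  toxicity_table(
    rfd = c(Fe = 0.7, Mn = 0.14, Cu = 0.04, Zn = 0.3, Al = 1,
            As = 0.0003, Se = 0.005, Cd = 0.0005, Li = 0.002, B = 0.2,
            Ba = 0.2, Sb = 0.0004, Ni = 0.02, Co = 0.0003, Mo = 0.005),
    sf = c(As = 1.5)
  )
}

#' Read toxicity constants from YAML
#'
#' @param path YAML file with maps `rfd` and optionally `sf`.
#' @return A [toxicity_table()].
#' @export
read_toxicity_config <- function(path) {
  raw <- yaml::read_yaml(path)
  toxicity_table(unlist(raw$rfd),
                 if (is.null(raw$sf)) numeric(0) else unlist(raw$sf))
}

#' Chronic daily intake through drinking-water ingestion
#'
#' `CDI = (Cw * 1e-3 * IR * EF * ED) / (BW * AT)` in mg/(kg d), where
#' `Cw` is in ug/L (the 1e-3 converts to mg/L) and the averaging time
#' `AT` is `ED * 365` days for the non-carcinogenic horizon and
#' `LE * 365` days for the carcinogenic horizon.
#'
#' @param c_w concentration in ug/L (vectorized).
#' @param params a single-row subset of [exposure_params()] or a list
#'   with `IR`, `EF`, `ED`, `BW`, `LE`.
#' @param horizon `"noncarcinogenic"` or `"carcinogenic"`.
#' @return CDI in mg/(kg d).
#' @export
#' @examples
#' cdi(10, list(IR = 2, EF = 365, ED = 30, BW = 70, LE = 70))
cdi <- function(c_w, params,
                horizon = c("noncarcinogenic", "carcinogenic")) {
  horizon <- match.arg(horizon)
  stopifnot(all(c_w >= 0))
  at_years <- if (horizon == "carcinogenic") params$LE else params$ED
  if (params$BW <= 0 || at_years <= 0) stop("BW and AT must be positive")
  (c_w * 1e-3 * params$IR * params$EF * params$ED) /
    (params$BW * at_years * 365)
}

#' Hazard quotient and hazard index
#'
#' `HQ = CDI / RfD`; `HI = sum(HQ)` over the assessed analytes.
#'
#' @param cdi_value CDI in mg/(kg d).
#' @param rfd reference dose, mg/(kg d), positive.
#' @param hq numeric vector of hazard quotients.
#' @return Dimensionless HQ / HI.
#' @export
hazard_quotient <- function(cdi_value, rfd) {
  if (any(rfd <= 0)) stop("RfD must be positive")
  cdi_value / rfd
}

#' @rdname hazard_quotient
#' @export
hazard_index <- function(hq) {
  if (length(hq) == 0) {
    warning("empty HQ set; HI = 0")
    return(0)
  }
  sum(hq)
}

#' Cancer risk and cumulative cancer risk
#'
#' `CR = CDI * SF`; `CCR = sum(CR)` over the carcinogens.
#'
#' @param cdi_value CDI in mg/(kg d) (carcinogenic horizon).
#' @param sf slope factor, (kg d)/mg, positive.
#' @param cr numeric vector of cancer risks.
#' @return Dimensionless CR / CCR.
#' @export
cancer_risk <- function(cdi_value, sf) {
  if (any(sf <= 0)) stop("slope factor must be positive")
  cdi_value * sf
}

#' @rdname cancer_risk
#' @export
cumulative_cancer_risk <- function(cr) sum(cr)

#' Risk-level classification
#'
#' Non-carcinogenic: level I when `HI <= 1`, level II when `HI > 1`.
#' Carcinogenic bands are half-open at the lower edge:
#' level I `CR < 1e-6`; II `[1e-6, 1e-5)`; III `[1e-5, 1e-4)`;
#' IV `[1e-4, 1e-3)`; V `>= 1e-3`.
#'
#' @param hi,cr non-negative values (vectorized).
#' @return Character vector of levels (`"I"`..`"V"`).
#' @export
classify_hi <- function(hi) {
  if (any(hi < 0)) stop("HI must be non-negative")
  ifelse(hi > 1, "II", "I")
}

#' @rdname classify_hi
#' @export
classify_cr <- function(cr) {
  if (any(cr < 0)) stop("CR must be non-negative")
  breaks <- c(-Inf, 1e-6, 1e-5, 1e-4, 1e-3, Inf)
  c("I", "II", "III", "IV", "V")[
    findInterval(cr, breaks, left.open = FALSE)]
}

#' Deterministic health risk assessment
#'
#' Runs the full oral-ingestion risk chain for every sample and
#' population group: per-analyte CDI at both horizons, HQ, HI with its
#' I/II level, CR for the carcinogens, CCR with its I-V level, and
#' per-group summary fractions.
#'
#' @param table a [conc_table()]; working values (MDL/2 substituted) are
#'   used.
#' @param exposure an [exposure_params()] table (default
#'   [default_exposure()]).
#' @param tox a [toxicity_table()] (default [default_toxicity()]).
#' @param water_type water types to assess (default `"surface"`).
#' @return An object of class `risk_table`: `detail` (long data frame,
#'   one row per sample x group x assessed analyte, with `cdi_nc`,
#'   `hq`, `cdi_ca`, `cr`), `summary` (one row per sample x group with
#'   `hi`, `hi_level`, `ccr`, `cr_level`) and `fractions` (per group:
#'   percent of samples at HI level I and per CR level).
#' @export
#' @examples
#' fx <- make_worked_fixtures()
#' risk <- assess_risk(fx$table)
#' risk$fractions
assess_risk <- function(table, exposure = default_exposure(),
                        tox = default_toxicity(),
                        water_type = "surface") {
  stopifnot(inherits(table, "conc_table"),
            inherits(tox, "toxicity_table"))
  tab <- filter_water_type(table, water_type)
  if (!tab$substituted) tab <- substitute_censored(tab)
  X <- tab$conc
  n <- nrow(X)
  nc_analytes <- intersect(colnames(X), names(tox$rfd))
  if (!length(nc_analytes))
    stop("no assessed analyte has a configured RfD")
  ca_analytes <- intersect(colnames(X), names(tox$sf))

  detail <- list(); summ <- list()
  for (g in seq_len(nrow(exposure))) {
    par <- as.list(exposure[g, ])
    cdi_nc <- sapply(nc_analytes, function(a)
      cdi(X[, a], par, "noncarcinogenic"))
    hq <- sweep(cdi_nc, 2, tox$rfd[nc_analytes], "/")
    hi <- rowSums(hq)
    if (length(ca_analytes)) {
      cdi_ca <- sapply(ca_analytes, function(a)
        cdi(X[, a], par, "carcinogenic"))
      cdi_ca <- matrix(cdi_ca, n, length(ca_analytes),
                       dimnames = list(NULL, ca_analytes))
      cr <- sweep(cdi_ca, 2, tox$sf[ca_analytes], "*")
      ccr <- rowSums(cr)
    } else {
      cdi_ca <- cr <- matrix(numeric(0), n, 0)
      ccr <- rep(0, n)
    }
    detail[[par$group]] <- data.frame(
      sample = rep(tab$samples$id, length(nc_analytes)),
      group = par$group,
      analyte = rep(nc_analytes, each = n),
      cdi_nc = as.vector(cdi_nc),
      hq = as.vector(hq),
      cdi_ca = as.vector(vapply(nc_analytes, function(a)
        if (a %in% ca_analytes) cdi_ca[, a] else rep(NA_real_, n),
        numeric(n))),
      cr = as.vector(vapply(nc_analytes, function(a)
        if (a %in% ca_analytes) cr[, a] else rep(NA_real_, n),
        numeric(n))),
      stringsAsFactors = FALSE
    )
    summ[[par$group]] <- data.frame(
      sample = tab$samples$id, group = par$group,
      hi = hi, hi_level = classify_hi(hi),
      ccr = ccr, cr_level = classify_cr(ccr),
      stringsAsFactors = FALSE
    )
  }
  detail <- do.call(rbind, detail); rownames(detail) <- NULL
  summ <- do.call(rbind, summ); rownames(summ) <- NULL

  fractions <- do.call(rbind, lapply(split(summ, summ$group), function(d) {
    lev <- factor(d$cr_level, levels = c("I", "II", "III", "IV", "V"))
    pct <- as.data.frame.list(as.list(100 * table(lev) / nrow(d)))
    names(pct) <- paste0("cr_level_", levels(lev), "_percent")
    cbind(data.frame(group = d$group[1],
                     hi_below_1_percent = 100 * mean(d$hi <= 1),
                     stringsAsFactors = FALSE),
          pct)
  }))
  rownames(fractions) <- NULL
  structure(list(detail = detail, summary = summ, fractions = fractions,
                 exposure = exposure, tox = tox, n = n),
            class = "risk_table")
}

#' @export
print.risk_table <- function(x, ...) {
  cat(sprintf("<risk_table> %d samples x %d groups\n",
              x$n, nrow(x$exposure)))
  print(x$fractions, digits = 4)
  invisible(x)
}

#' Sensitivity of the hazard index to individual analytes
#'
#' Default score: an analyte's mean contribution share,
#' `mean(HQ_j) / mean(HI)`, which sums to 1 across analytes. The
#' alternative is the Spearman rank correlation between the analyte's
#' concentration-driven HQ and HI across samples. Ranked descending;
#' ties broken lexicographically.
#'
#' @param risk a [assess_risk()] result.
#' @param group population group to analyse (default `"children"`).
#' @param method `"contribution"` or `"spearman"`.
#' @return data frame `analyte`, `score`, `rank`, with the method as an
#'   attribute; scores are `NA` when HI is degenerate (constant zero).
#' @export
hi_sensitivity <- function(risk, group = "children",
                           method = c("contribution", "spearman")) {
  method <- match.arg(method)
  stopifnot(inherits(risk, "risk_table"))
  d <- risk$detail[risk$detail$group == group, ]
  if (!nrow(d)) stop("unknown group '", group, "'")
  s <- risk$summary[risk$summary$group == group, ]
  if (length(unique(s$sample)) < 2)
    stop("need at least 2 samples for a sensitivity ranking")
  hq_mat <- tapply(d$hq, list(d$sample, d$analyte), sum)
  hq_mat <- hq_mat[s$sample, , drop = FALSE]
  hi <- s$hi
  if (method == "contribution") {
    score <- if (mean(hi) == 0) rep(NA_real_, ncol(hq_mat))
             else colMeans(hq_mat) / mean(hi)
  } else {
    score <- if (stats::sd(hi) == 0) rep(NA_real_, ncol(hq_mat))
             else apply(hq_mat, 2, function(v)
               suppressWarnings(stats::cor(v, hi, method = "spearman")))
  }
  out <- data.frame(analyte = colnames(hq_mat), score = score,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$analyte), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "method") <- method
  out
}
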