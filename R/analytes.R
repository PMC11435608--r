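#' Analyte configuration
#'
#' An analyte configuration is a data frame with one row per measured
#' analyte and columns `name`, `mdl` (method detection limit, ug/L),
#' `error_fraction` (relative measurement error in (0, 1) used in the
#' above-detection uncertainty branch) and `drinking_limit` (regulatory
#' limit in ug/L, `NA` where no limit is configured).
#'
#' @param name character vector of analyte identifiers (e.g. `"Fe"`).
#' @param mdl positive method detection limits, ug/L.
#' @param error_fraction per-analyte error fractions, each in (0, 1).
#' @param drinking_limit positive limits in ug/L, or `NA` where none
#'   applies.
#'
#' @return A validated data frame of class `analyte_config`.
#' @export
#' @examples
#' analyte_config(c("Fe", "Hg"), mdl = c(10, 0.04),
#'                error_fraction = c(0.1, 0.15),
#'                drinking_limit = c(300, 1))
analyte_config <- function(name, mdl, error_fraction,
                           drinking_limit = NA_real_) {
  name <- as.character(name)
  cfg <- data.frame(
    name = name,
    mdl = as.numeric(mdl),
    error_fraction = as.numeric(error_fraction),
    drinking_limit = rep_len(as.numeric(drinking_limit), length(name)),
    stringsAsFactors = FALSE
  )
  validate_analyte_config(cfg)
}

validate_analyte_config <- function(cfg) {
  stopifnot(is.data.frame(cfg))
  need <- c("name", "mdl", "error_fraction")
  miss <- setdiff(need, names(cfg))
  if (length(miss))
    stop("analyte config missing column(s): ", paste(miss, collapse = ", "))
  if (!"drinking_limit" %in% names(cfg)) cfg$drinking_limit <- NA_real_
  if (anyDuplicated(cfg$name))
    stop("duplicate analyte name(s): ",
         paste(unique(cfg$name[duplicated(cfg$name)]), collapse = ", "))
  bad <- !is.finite(cfg$mdl) | cfg$mdl <= 0
  if (any(bad))
    stop("mdl must be positive for: ", paste(cfg$name[bad], collapse = ", "))
  bad <- !is.finite(cfg$error_fraction) |
    cfg$error_fraction <= 0 | cfg$error_fraction >= 1
  if (any(bad))
    stop("error_fraction must lie in (0, 1) for: ",
         paste(cfg$name[bad], collapse = ", "))
  bad <- !is.na(cfg$drinking_limit) & cfg$drinking_limit <= 0
  if (any(bad))
    stop("drinking_limit must be positive when present, offending: ",
         paste(cfg$name[bad], collapse = ", "))
  rownames(cfg) <- NULL
  class(cfg) <- c("analyte_config", "data.frame")
  cfg
}

#' Read an analyte configuration from a YAML file
#'
#' The file holds one entry per analyte with keys `name`, `mdl`,
#' `error_fraction` and optionally `drinking_limit` (see the bundled
#' `inst/extdata/analytes.yml` for the expected layout).
#'
#' @param path path to a YAML file.
#' @return An `analyte_config` data frame.
#' @export
read_analyte_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$analytes)) raw <- raw$analytes
  rows <- lapply(raw, function(a) {
    data.frame(
      name = as.character(a$name),
      mdl = as.numeric(a$mdl),
      error_fraction = as.numeric(a$error_fraction),
      drinking_limit = if (is.null(a$drinking_limit)) NA_real_
                       else as.numeric(a$drinking_limit),
      stringsAsFactors = FALSE
    )
  })
  validate_analyte_config(do.call(rbind, rows))
}

#' Default analyte panel
#'
#' The 17-element PTE panel of the study system (Fe, Mn, Cu, Zn, Al, Hg,
#' As, Se, Cd, Pb, Li, B, Ba, Sb, Ni, Co, Mo). The MDL and error-fraction
#' values are synthetic placeholders of realistic magnitude -- laboratory
#' reports should always supply their own -- while the bundled drinking
#' limits cover only Hg (1 ug/L), Cd (5 ug/L), As (10 ug/L) and Se
#' (10 ug/L); all other limits are left to the user's configuration.
#'
#' @return An `analyte_config` data frame with 17 rows.
#' @export
default_analytes <- function() {
  analyte_config(
    name = c("Fe", "Mn", "Cu", "Zn", "Al", "Hg", "As", "Se", "Cd",
             "Pb", "Li", "B", "Ba", "Sb", "Ni", "Co", "Mo"),
    mdl = c(10, 1, 0.5, 1, 10, 0.04, 0.3, 0.4, 0.05,
            0.09, 0.3, 5, 1, 0.15, 0.6, 0.03, 0.06),
    error_fraction = c(0.10, 0.10, 0.10, 0.10, 0.10, 0.15, 0.12, 0.12,
                       0.10, 0.12, 0.10, 0.10, 0.10, 0.15, 0.10, 0.10,
                       0.10),
    drinking_limit = c(NA, NA, NA, NA, NA, 1, 10, 10, 5,
                       NA, NA, NA, NA, NA, NA, NA, NA)
  )
}
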