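#' Concentration tables
#'
#' A `conc_table` couples an n x m sample-by-analyte concentration matrix
#' (ug/L) with per-sample metadata (id, water type, river) and the analyte
#' configuration (MDL, error fraction, drinking limit). Cells reported
#' only as "below detection" carry the analyte's MDL as their recorded
#' bound and are flagged in a parallel logical matrix; the matrix view is
#' dense. [substitute_censored()] replaces the bound with MDL/2 working
#' values ahead of statistics and factorization.
#'
#' @param conc numeric n x m matrix, non-negative, with column names
#'   matching `analytes$name`.
#' @param censored logical n x m matrix flagging below-detection cells
#'   (default: none).
#' @param samples data frame with columns `id`, `water_type` (one of
#'   `"surface"`, `"ground"`, `"mine"`) and optionally `river`.
#' @param analytes an [analyte_config()] covering every column of `conc`.
#'
#' @return An object of class `conc_table` with elements `conc`,
#'   `censored`, `samples`, `analytes` and a `substituted` flag.
#' @export
conc_table <- function(conc, analytes, samples = NULL, censored = NULL) {
  conc <- as.matrix(conc)
  storage.mode(conc) <- "double"
  n <- nrow(conc); m <- ncol(conc)
  analytes <- validate_analyte_config(as.data.frame(analytes))
  if (is.null(colnames(conc))) colnames(conc) <- analytes$name[seq_len(m)]
  unknown <- setdiff(colnames(conc), analytes$name)
  if (length(unknown))
    stop("unknown analyte column(s): ", paste(unknown, collapse = ", "))
  analytes <- analytes[match(colnames(conc), analytes$name), , drop = FALSE]
  rownames(analytes) <- NULL
  if (is.null(samples)) {
    samples <- data.frame(id = paste0("S", seq_len(n)),
                          water_type = "surface",
                          river = NA_character_,
                          stringsAsFactors = FALSE)
  }
  samples <- as.data.frame(samples)
  if (!"river" %in% names(samples)) samples$river <- NA_character_
  stopifnot(all(c("id", "water_type") %in% names(samples)),
            nrow(samples) == n)
  samples$id <- as.character(samples$id)
  if (anyDuplicated(samples$id))
    stop("duplicate sample id(s): ",
         paste(unique(samples$id[duplicated(samples$id)]), collapse = ", "))
  bad_wt <- !samples$water_type %in% c("surface", "ground", "mine")
  if (any(bad_wt))
    stop("water_type must be surface/ground/mine; offending sample(s): ",
         paste(samples$id[bad_wt], collapse = ", "))
  if (is.null(censored)) {
    censored <- matrix(FALSE, n, m)
  }
  censored <- as.matrix(censored)
  stopifnot(identical(dim(censored), dim(conc)))
  dimnames(censored) <- dimnames(conc)
  bad <- which(!is.finite(conc) | conc < 0, arr.ind = TRUE)
  if (nrow(bad))
    stop("negative or non-finite concentration at sample '",
         samples$id[bad[1, 1]], "', analyte '",
         colnames(conc)[bad[1, 2]], "'")
  rownames(conc) <- samples$id
  structure(list(conc = conc, censored = censored, samples = samples,
                 analytes = analytes, substituted = FALSE),
            class = "conc_table")
}

#' @export
print.conc_table <- function(x, ...) {
  cat(sprintf("<conc_table> %d samples x %d analytes (ug/L)\n",
              nrow(x$conc), ncol(x$conc)))
  cat("  water types:",
      paste(sprintf("%s=%d", names(table(x$samples$water_type)),
                    table(x$samples$water_type)), collapse = ", "), "\n")
  cat(sprintf("  censored cells: %d (%.1f%%)%s\n", sum(x$censored),
              100 * mean(x$censored),
              if (x$substituted) ", MDL/2 substituted" else ""))
  invisible(x)
}

#' @export
dim.conc_table <- function(x) dim(x$conc)

#' @export
as.matrix.conc_table <- function(x, ...) x$conc

#' Read a wide concentration CSV
#'
#' Expects metadata columns `id`, `water_type`, optionally `river`,
#' followed by one numeric column per analyte (ug/L). Below-detection
#' cells may be written `"<MDL"`, `"<value"` or left blank; they are
#' flagged censored and recorded at the analyte's MDL bound.
#'
#' @param path CSV path (UTF-8, "." decimal).
#' @param analytes an [analyte_config()] listing every analyte column.
#' @return A [conc_table()].
#' @export
read_concentrations <- function(path, analytes) {
  analytes <- validate_analyte_config(as.data.frame(analytes))
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        check.names = FALSE, colClasses = "character")
  meta_cols <- intersect(c("id", "water_type", "river"), names(df))
  if (!all(c("id", "water_type") %in% meta_cols))
    stop("CSV must contain 'id' and 'water_type' columns")
  value_cols <- setdiff(names(df), meta_cols)
  unknown <- setdiff(value_cols, analytes$name)
  if (length(unknown))
    stop("unknown analyte column(s): ", paste(unknown, collapse = ", "))
  n <- nrow(df); m <- length(value_cols)
  conc <- matrix(NA_real_, n, m, dimnames = list(NULL, value_cols))
  cens <- matrix(FALSE, n, m, dimnames = list(NULL, value_cols))
  for (j in value_cols) {
    raw <- trimws(df[[j]])
    mdl_j <- analytes$mdl[analytes$name == j]
    below <- raw == "" | raw == "<MDL" | grepl("^<", raw)
    cens[, j] <- below
    conc[below, j] <- mdl_j
    vals <- suppressWarnings(as.numeric(raw[!below]))
    if (anyNA(vals)) {
      i <- which(!below)[which(is.na(vals))[1]]
      stop("non-numeric concentration at sample '", df$id[i],
           "', analyte '", j, "'")
    }
    conc[!below, j] <- vals
  }
  samples <- df[meta_cols]
  conc_table(conc, analytes, samples = samples, censored = cens)
}

#' Substitute below-detection cells by MDL/2
#'
#' Every censored cell's working value becomes half the analyte's method
#' detection limit (standard receptor-modelling practice); censored flags
#' are preserved so uncertainty construction can still route those cells
#' through the below-detection branch. Idempotent, and never touches an
#' uncensored cell.
#'
#' @param table a [conc_table()].
#' @param fraction fraction of MDL used as the working value (default 0.5).
#' @return The table with substituted working values.
#' @export
substitute_censored <- function(table, fraction = 0.5) {
  stopifnot(inherits(table, "conc_table"), fraction > 0, fraction <= 1)
  if (any(table$censored)) {
    mdl_row <- table$analytes$mdl
    idx <- which(table$censored, arr.ind = TRUE)
    table$conc[idx] <- fraction * mdl_row[idx[, 2]]
  }
  table$substituted <- TRUE
  table
}

#' Subset a concentration table by water type
#'
#' @param table a [conc_table()].
#' @param water_type subset to keep, e.g. `"surface"`; `NULL` keeps all.
#' @return A [conc_table()] with the matching samples.
#' @export
filter_water_type <- function(table, water_type = NULL) {
  stopifnot(inherits(table, "conc_table"))
  if (is.null(water_type)) return(table)
  keep <- table$samples$water_type %in% water_type
  if (!any(keep)) stop("no samples of water_type ",
                       paste(water_type, collapse = "/"))
  table$conc <- table$conc[keep, , drop = FALSE]
  table$censored <- table$censored[keep, , drop = FALSE]
  table$samples <- table$samples[keep, , drop = FALSE]
  rownames(table$samples) <- NULL
  table
}

fmt_num <- function(x) {
  # %.17g round-trips IEEE doubles exactly through read.csv
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- ""
  out
}

#' Write tables and matrices to CSV
#'
#' Writes a [conc_table()] (censored cells as `"<MDL"`), a plain numeric
#' matrix, or any data frame. Numeric cells are written with 17
#' significant digits so that a write/read cycle reproduces them exactly.
#'
#' @param x object to write.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path) {
  if (inherits(x, "conc_table")) {
    cells <- matrix(fmt_num(x$conc), nrow(x$conc),
                    dimnames = dimnames(x$conc))
    cells[x$censored] <- "<MDL"
    df <- cbind(x$samples[intersect(c("id", "water_type", "river"),
                                    names(x$samples))],
                as.data.frame(cells, stringsAsFactors = FALSE))
  } else if (is.matrix(x)) {
    df <- as.data.frame(matrix(fmt_num(x), nrow(x), dimnames = dimnames(x)),
                        stringsAsFactors = FALSE)
    if (!is.null(rownames(x))) df <- cbind(row = rownames(x), df)
  } else {
    df <- as.data.frame(x)
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], fmt_num)
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
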