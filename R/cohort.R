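GENOTYPES <- c("Control", "Pten", "Rictor", "Tsc2")
ROIS <- c("genu", "midbody", "splenium", "fornix")

#' Construct a cohort object from a data frame
#'
#' A cohort is the tidy per-observation table shared by every analysis stage:
#' one row per mouse x ROI, joining the EM reference fractions (`fA_EM`,
#' `fM_EM`, both unitless volume fractions in \[0,1\]) with one or more
#' DWI-model axonal water fractions held in columns named `fAW_<MODEL>`.
#'
#' @param df data frame with columns `mouse_id`, `genotype`, `roi`, `fA_EM`,
#'   `fM_EM`, at least one `fAW_<MODEL>` column, and optionally `group`
#'   (integer 1/2).
#' @param provenance named list of free-form metadata (seed, preset, source
#'   file); stored as an attribute and written to the sidecar JSON.
#' @return An object of class `axon_cohort` (a data frame).
#' @export
#' @examples
#' df <- data.frame(
#'   mouse_id = c("m1", "m1"), genotype = "Control",
#'   roi = c("genu", "splenium"), fA_EM = c(0.35, 0.33),
#'   fM_EM = c(0.30, 0.31), fAW_WMTI = c(0.62, 0.60)
#' )
#' as_cohort(df)
as_cohort <- function(df, provenance = list()) {
  stopifnot(is.data.frame(df))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  diag <- validate_cohort(df)
  if (nrow(diag) > 0L) {
    stop("invalid cohort:\n", paste(utils::capture.output(print(diag)), collapse = "\n"),
         call. = FALSE)
  }
  structure(df, class = c("axon_cohort", "data.frame"),
            provenance = provenance)
}

#' Validate a cohort table
#'
#' Validation is total: every offending cell yields one located diagnostic
#' row rather than an opaque failure or a silent drop.
#'
#' @param df candidate data frame.
#' @return data frame with columns `row` (NA for table-level problems),
#'   `column`, `message`; zero rows when valid.
#' @export
validate_cohort <- function(df) {
  diag <- data.frame(row = integer(), column = character(),
                     message = character(), stringsAsFactors = FALSE)
  add <- function(row, column, message) {
    rbind(diag, data.frame(row = row, column = column, message = message,
                           stringsAsFactors = FALSE))
  }
  required <- c("mouse_id", "genotype", "roi", "fA_EM", "fM_EM")
  for (col in required) {
    if (!col %in% names(df)) diag <- add(NA_integer_, col, "missing required column")
  }
  faw_cols <- grep("^fAW_", names(df), value = TRUE)
  if (length(faw_cols) == 0L) {
    diag <- add(NA_integer_, "fAW_<MODEL>", "no DWI-model fAW column present")
  }
  if (nrow(diag) > 0L) return(diag)
  if (nrow(df) == 0L) return(add(NA_integer_, "", "cohort is empty"))

  frac_cols <- c("fA_EM", "fM_EM", faw_cols)
  for (col in frac_cols) {
    x <- df[[col]]
    if (!is.numeric(x)) {
      diag <- add(NA_integer_, col, "column is not numeric")
      next
    }
    bad <- which(!is.finite(x) | x < 0 | x > 1)
    for (i in bad) diag <- add(i, col, sprintf("fraction out of [0,1]: %s", format(x[i])))
  }
  if (is.numeric(df$fA_EM) && is.numeric(df$fM_EM)) {
    over <- which(is.finite(df$fA_EM) & is.finite(df$fM_EM) &
                    df$fA_EM + df$fM_EM > 1 + 1e-12)
    for (i in over) diag <- add(i, "fA_EM+fM_EM", "fA_EM + fM_EM exceeds 1")
  }
  badg <- which(!df$genotype %in% GENOTYPES)
  for (i in badg) diag <- add(i, "genotype", sprintf("unknown genotype '%s'", df$genotype[i]))
  badr <- which(!df$roi %in% ROIS)
  for (i in badr) diag <- add(i, "roi", sprintf("unknown ROI '%s'", df$roi[i]))
  key <- paste(df$mouse_id, df$roi, sep = "\r")
  dup <- which(duplicated(key))
  for (i in dup) diag <- add(i, "mouse_id,roi", "duplicate (mouse_id, roi) pair")
  if ("group" %in% names(df)) {
    badgr <- which(!is.na(df$group) & !df$group %in% c(1, 2))
    for (i in badgr) diag <- add(i, "group", "group label must be 1 or 2")
  }
  diag
}

#' Names of the DWI models carried by a cohort
#' @param cohort an `axon_cohort`.
#' @return character vector of model names (the `<MODEL>` part of the
#'   `fAW_<MODEL>` columns).
#' @export
dwi_models <- function(cohort) {
  sub("^fAW_", "", grep("^fAW_", names(cohort), value = TRUE))
}

#' Cohort provenance metadata
#' @param cohort an `axon_cohort`.
#' @return named list (possibly empty).
#' @export
provenance <- function(cohort) {
  attr(cohort, "provenance") %||% list()
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.axon_cohort <- function(x, ...) {
  cat(sprintf("axon_cohort: %d observations (%d mice x %d ROIs), models: %s\n",
              nrow(x), length(unique(x$mouse_id)), length(unique(x$roi)),
              paste(dwi_models(x), collapse = ", ")))
  NextMethod()
  invisible(x)
}

#' Read a cohort from a tidy CSV
#'
#' Expects the documented column layout (`mouse_id`, `genotype`, `roi`,
#' `fA_EM`, `fM_EM`, one or more `fAW_<MODEL>`, optional `group`). A sidecar
#' `<path>.json`, when present, is read back into the provenance attribute.
#'
#' @param path CSV file path.
#' @param keep_groups if `TRUE`, a `group` column in the file is trusted;
#'   otherwise it is dropped so that [assign_groups()] recomputes it from the
#'   data (the default, since groups are derived from the EM metric).
#' @return an `axon_cohort`.
#' @export
read_cohort <- function(path, keep_groups = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE),
    error = function(e) stop("cannot parse CSV '", path, "': ", conditionMessage(e),
                             call. = FALSE)
  )
  if (nrow(df) == 0L || ncol(df) <= 1L) {
    stop("schema error: '", path, "' has no usable rows/columns", call. = FALSE)
  }
  num_cols <- c("fA_EM", "fM_EM", grep("^fAW_", names(df), value = TRUE))
  for (col in intersect(num_cols, names(df))) {
    x <- df[[col]]
    if (!is.numeric(x)) {
      xs <- suppressWarnings(as.numeric(x))
      bad <- which(is.na(xs) & !is.na(x) & nzchar(trimws(x)))
      if (length(bad) > 0L) {
        stop(sprintf("parse error: non-numeric value in column '%s' at row(s) %s",
                     col, paste(bad, collapse = ", ")), call. = FALSE)
      }
      df[[col]] <- xs
    }
  }
  if (!keep_groups) df$group <- NULL
  prov <- list(source = path)
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    prov <- utils::modifyList(jsonlite::read_json(sidecar, simplifyVector = TRUE), prov)
  }
  as_cohort(df, provenance = prov)
}

#' Write a cohort to CSV (plus a provenance sidecar)
#'
#' Values are serialized with 17 significant digits so that
#' `read_cohort(write_cohort(c))` reproduces the cohort exactly.
#'
#' @param cohort an `axon_cohort`.
#' @param path output CSV path; provenance goes to `<path>.json`.
#' @param sidecar write the provenance sidecar (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, sidecar = TRUE) {
  stopifnot(inherits(cohort, "axon_cohort"))
  out <- as.data.frame(cohort)
  lead <- intersect(c("mouse_id", "genotype", "roi", "group", "fA_EM", "fM_EM"),
                    names(out))
  out <- out[, c(lead, setdiff(names(out), lead)), drop = FALSE]
  for (col in names(out)) {
    if (is.double(out[[col]])) out[[col]] <- sprintf("%.17g", out[[col]])
  }
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write '", path, "'", call. = FALSE)
  if (sidecar) {
    jsonlite::write_json(provenance(cohort), paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(path)
}
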