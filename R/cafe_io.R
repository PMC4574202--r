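#' Read a vial-level CAFE assay table
#'
#' Reads a tab- or comma-delimited file (dialect chosen by extension, or
#' forced via `sep`) with one row per vial.  Required columns: `line`,
#' `sex`, `replicate`, `total_ul`, `flies_alive`; an optional `batch`
#' column links vials to evaporation controls (a single `"global"` batch is
#' assumed when absent, matching a shared humid chamber).  Sex codes are
#' normalized to `F`/`M` via `sex_synonyms`.  Rows with no surviving flies
#' are quarantined (returned in `attr(, "quarantined")`) with a warning
#' rather than silently dropped.
#'
#' @param path path to the assay file.
#' @param sep field separator; default inferred from the file extension
#'   (`.csv` is comma, anything else tab).
#' @param sex_synonyms named character vector mapping raw sex codes to
#'   `"F"`/`"M"`.
#' @return data.frame of validated vial records; quarantined rows (if any)
#'   in `attr(, "quarantined")`.
#' @export
readAssayTable <- function(path, sep = NULL,
                           sex_synonyms = c(F = "F", female = "F", f = "F",
                                            M = "M", male = "M", m = "M")) {
  if (!file.exists(path)) stop("assay file not found: ", path)
  sep <- sep %||% if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  stopifnot_cols(df, c("line", "sex", "replicate", "total_ul",
                       "flies_alive"), "assay table")
  if (!"batch" %in% names(df)) df$batch <- "global"
  for (col in c("total_ul", "flies_alive", "replicate")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (length(bad))
      stop(sprintf("non-numeric '%s' value(s) at data row(s): %s",
                   col, paste(bad, collapse = ", ")), call. = FALSE)
    df[[col]] <- v
  }
  sx <- sex_synonyms[as.character(df$sex)]
  if (anyNA(sx))
    stop("unrecognized sex code(s): ",
         paste(unique(df$sex[is.na(sx)]), collapse = ", "))
  df$sex <- unname(sx)
  if (any(df$total_ul < 0, na.rm = TRUE))
    warning(sum(df$total_ul < 0),
            " vial(s) with negative total_ul retained (flagged after ",
            "adjustment); check capillary readings")
  dup <- duplicated(df[, c("line", "sex", "replicate")])
  if (any(dup))
    stop("replicate ids must be unique within line x sex; duplicated rows: ",
         paste(which(dup), collapse = ", "))
  dead <- df$flies_alive < 1
  quarantined <- df[dead, , drop = FALSE]
  if (nrow(quarantined)) {
    warning(sprintf("%d vial(s) with no surviving flies quarantined",
                    nrow(quarantined)))
    df <- df[!dead, , drop = FALSE]
  }
  rownames(df) <- NULL
  attr(df, "quarantined") <- quarantined
  df
}

#' Read an evaporation-control table
#'
#' Delimited file with columns `evap_ul` and optionally `batch`
#' (`"global"` assumed when absent).
#'
#' @inheritParams readAssayTable
#' @return data.frame with `batch` and `evap_ul`.
#' @export
readEvaporationControls <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("control file not found: ", path)
  sep <- sep %||% if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  stopifnot_cols(df, "evap_ul", "control table")
  if (!"batch" %in% names(df)) df$batch <- "global"
  df$evap_ul <- suppressWarnings(as.numeric(df$evap_ul))
  if (anyNA(df$evap_ul) || any(df$evap_ul < 0))
    stop("evap_ul must be numeric and >= 0")
  df[, c("batch", "evap_ul")]
}

#' Evaporation- and survivor-adjusted per-fly intake
#'
#' Adjusted intake per vial is
#' `(total_ul - mean(evap_ul of the vial's batch)) / flies_alive`.
#' Negative adjusted values (consumption below evaporation) are retained
#' but flagged, not floored, to avoid upward bias in low-consumption lines.
#'
#' @param records vial records (see [readAssayTable()]).
#' @param controls evaporation controls (batch, evap_ul); every batch in
#'   `records` must have at least one control.
#' @return `records` with columns `adjusted_ul` (uL/fly) and
#'   `flag_negative` appended.
#' @examples
#' rec <- data.frame(line = "l1", sex = "F", replicate = 1,
#'                   total_ul = 12, flies_alive = 8, batch = "b1")
#' ctl <- data.frame(batch = "b1", evap_ul = 2)
#' adjustConsumption(rec, ctl)$adjusted_ul  # (12 - 2) / 8 = 1.25
#' @export
adjustConsumption <- function(records, controls) {
  stopifnot_cols(records, c("line", "sex", "total_ul", "flies_alive"),
                 "vial records")
  if (!"batch" %in% names(records)) records$batch <- "global"
  if (!"batch" %in% names(controls)) controls$batch <- "global"
  stopifnot_cols(controls, "evap_ul", "controls")
  evap <- tapply(controls$evap_ul, controls$batch, mean)
  orphan <- setdiff(unique(records$batch), names(evap))
  if (length(orphan))
    stop("batch(es) without evaporation controls: ",
         paste(orphan, collapse = ", "))
  if (any(records$flies_alive < 1))
    stop("records with flies_alive < 1 cannot be adjusted; quarantine them first")
  records$adjusted_ul <- (records$total_ul -
                          as.vector(evap[records$batch])) /
    records$flies_alive
  records$flag_negative <- records$adjusted_ul < 0
  records
}

#' Per-line, per-sex phenotype summaries: mean, within-line SD, CV_E
#'
#' Collapses adjusted vials to a line phenotype table with, per line x sex:
#' replicate count, mean per-fly intake, the within-line standard deviation
#' (n - 1 denominator; `NA` with a single vial) and the coefficient of
#' environmental variation `CV_E = 100 * SD / mean` (percent; `NA` when the
#' mean is not positive).  Cells with fewer than `min_reps` vials are
#' flagged (`flag_low_reps`) for exclusion from CV_E analyses rather than
#' dropped.
#'
#' @param adjusted vial records carrying the value column (normally the
#'   output of [adjustConsumption()]).
#' @param min_reps minimum replicates for a trustworthy CV_E (default 3).
#' @param value name of the per-fly intake column.
#' @return data.frame (one row per line x sex): `line`, `sex`, `n`,
#'   `mean`, `sd`, `cv_e`, `flag_low_reps`.
#' @examples
#' v <- data.frame(line = "l1", sex = "F", adjusted_ul = c(1.5, 2, 2.5))
#' summarizeLines(v)  # mean 2, SD 0.5, CV_E 25
#' @export
summarizeLines <- function(adjusted, min_reps = 3L, value = "adjusted_ul") {
  stopifnot_cols(adjusted, c("line", "sex", value), "adjusted vials")
  key <- interaction(adjusted$line, adjusted$sex, drop = TRUE, sep = "\r")
  y <- adjusted[[value]]
  n <- as.vector(table(key))
  mu <- tapply(y, key, mean)
  sdv <- tapply(y, key, function(z) if (length(z) >= 2) sd(z) else NA_real_)
  parts <- do.call(rbind, strsplit(names(mu), "\r", fixed = TRUE))
  out <- data.frame(line = parts[, 1], sex = parts[, 2],
                    n = as.integer(table(key)[names(mu)]),
                    mean = unname(mu), sd = unname(sdv),
                    stringsAsFactors = FALSE)
  out$cv_e <- ifelse(!is.na(out$sd) & out$mean > 0,
                     100 * out$sd / out$mean, NA_real_)
  out$flag_low_reps <- out$n < min_reps
  out <- out[order(out$line, out$sex), ]
  rownames(out) <- NULL
  out
}
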