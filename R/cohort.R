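#' Compute the amyloid-beta 42/40 ratio
#'
#' The ratio of CSF amyloid-beta 1-42 to amyloid-beta 1-40 concentration is
#' the amyloidosis marker used throughout the package: it is more robust to
#' pre-analytical losses (tube adsorption) than Abeta42 alone, because the
#' two isoforms are absorbed similarly.
#'
#' @param abeta42 Abeta 1-42 concentration (pg/mL).
#' @param abeta40 Abeta 1-40 concentration (pg/mL); must be strictly positive.
#' @return The dimensionless ratio `abeta42 / abeta40`.
#' @examples
#' compute_ratio(642, 10000)
#' @export
compute_ratio <- function(abeta42, abeta40) {
  if (any(!is.finite(abeta40)) || any(abeta40 <= 0)) {
    stop("abeta40 must be strictly positive", call. = FALSE)
  }
  abeta42 / abeta40
}

required_cohort_columns <- c(
  "subject_id", "cohort", "diagnosis", "age", "sex",
  "abeta42", "abeta40", "ptau", "ttau"
)

#' Load a subject-level biomarker cohort from CSV
#'
#' Reads a comma-separated (UTF-8, `.` decimal, single header row) table of
#' subject-level CSF biomarker records and validates it. Required columns
#' (case-insensitive, any order): `subject_id`, `cohort`, `diagnosis`,
#' `age`, `sex`, `abeta42`, `abeta40`, `ptau`, `ttau`. An optional `stage`
#' column (`dementia`/`MCI`/`none`) is kept if present; unknown extra
#' columns are preserved. A `ratio` column (`abeta42/abeta40`) is computed
#' (or checked, if already present).
#'
#' Row-level invariants: all four concentrations strictly positive; age in
#' (18, 110); sex `F`/`M`; cohort 1 or 2. Diagnoses outside the controlled
#' vocabulary are mapped to `"other"` with a warning. Invalid rows abort
#' with the offending row number under `strict = TRUE`, and are dropped
#' with a message otherwise.
#'
#' @param path Path to the CSV file.
#' @param strict If `TRUE` (default), any invalid row is an error; if
#'   `FALSE`, invalid rows are dropped and their count reported.
#' @return A `cohort_table`: a `data.frame` with validated columns plus
#'   `ratio`, row order preserved; attribute `n_dropped` records drops.
#' @export
load_cohort_csv <- function(path, strict = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                  fileEncoding = "UTF-8")
  names(raw) <- tolower(trimws(names(raw)))
  missing <- setdiff(required_cohort_columns, names(raw))
  if (length(missing) > 0) {
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  as_cohort_table(raw, strict = strict)
}

#' Validate a data frame as a cohort table
#'
#' Applies the same validation as [load_cohort_csv()] to an in-memory data
#' frame. See that function for the contract.
#'
#' @param df A data frame holding the required columns.
#' @param strict Error on invalid rows (`TRUE`) or drop them (`FALSE`).
#' @return A validated `cohort_table`.
#' @export
as_cohort_table <- function(df, strict = TRUE) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  missing <- setdiff(required_cohort_columns, names(df))
  if (length(missing) > 0) {
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }

  num_cols <- c("age", "abeta42", "abeta40", "ptau", "ttau")
  for (cl in num_cols) {
    v <- df[[cl]]
    if (is.character(v)) {
      conv <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(conv) & !is.na(v) & trimws(v) != "")
      if (length(bad) > 0 && strict) {
        stop(sprintf("non-numeric value in column '%s' at row %d", cl, bad[1]),
             call. = FALSE)
      }
      df[[cl]] <- conv
    } else {
      df[[cl]] <- as.numeric(v)
    }
  }
  df$subject_id <- as.character(df$subject_id)
  df$cohort <- suppressWarnings(as.integer(df$cohort))
  df$sex <- toupper(trimws(as.character(df$sex)))
  df$diagnosis <- trimws(as.character(df$diagnosis))

  unknown <- !(df$diagnosis %in% DIAGNOSIS_VOCAB)
  if (any(unknown)) {
    warning(sum(unknown), " diagnosis value(s) outside the controlled ",
            "vocabulary mapped to 'other'", call. = FALSE)
    df$diagnosis[unknown] <- "other"
  }
  if ("stage" %in% names(df)) {
    df$stage <- trimws(as.character(df$stage))
    ok_stage <- df$stage %in% c("dementia", "MCI", "none") | is.na(df$stage)
    if (any(!ok_stage)) df$stage[!ok_stage] <- NA_character_
  }

  bad_row <- rep(FALSE, nrow(df))
  reasons <- character(nrow(df))
  flag <- function(cond, why) {
    cond[is.na(cond)] <- TRUE
    reasons[cond & !bad_row] <<- why
    bad_row <<- bad_row | cond
  }
  for (cl in c("abeta42", "abeta40", "ptau", "ttau")) {
    flag(!is.finite(df[[cl]]) | df[[cl]] <= 0,
         sprintf("non-positive or missing %s", cl))
  }
  flag(!is.finite(df$age) | df$age <= 18 | df$age >= 110, "age outside (18, 110)")
  flag(!(df$sex %in% c("F", "M")), "sex not F/M")
  flag(!(df$cohort %in% c(1L, 2L)), "cohort not 1/2")

  if (any(bad_row)) {
    if (strict) {
      i <- which(bad_row)[1]
      stop(sprintf("invalid record at row %d: %s", i, reasons[i]),
           call. = FALSE)
    }
    message("dropped ", sum(bad_row), " invalid row(s)")
  }
  n_dropped <- sum(bad_row)
  df <- df[!bad_row, , drop = FALSE]
  rownames(df) <- NULL

  if ("ratio" %in% names(df)) {
    df$ratio <- as.numeric(df$ratio)
    rel <- abs(df$ratio - df$abeta42 / df$abeta40) /
      pmax(abs(df$abeta42 / df$abeta40), .Machine$double.xmin)
    if (any(rel > 1e-12)) {
      stop("ratio column inconsistent with abeta42/abeta40", call. = FALSE)
    }
  } else {
    df$ratio <- compute_ratio(df$abeta42, df$abeta40)
  }

  class(df) <- c("cohort_table", "data.frame")
  attr(df, "n_dropped") <- n_dropped
  df
}

#' Write a cohort table to CSV
#'
#' Inverse of [load_cohort_csv()]: comma-separated, UTF-8, `.` decimal,
#' one header row; full double precision so that a write/read round trip
#' reproduces every numeric field to within 1e-9.
#'
#' @param table A `cohort_table`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(table, path) {
  df <- as.data.frame(table)
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(x) format(x, digits = 17, trim = TRUE))
  write.csv(df, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("<cohort_table> %d subjects (%d cohort-1, %d cohort-2), %d diagnoses\n",
              nrow(x), sum(x$cohort == 1), sum(x$cohort == 2),
              length(unique(x$diagnosis))))
  print(head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}
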