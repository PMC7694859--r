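# Cohort container and CSV / JSON input-output.

.COHORT_COLS <- c(
  "dog_id", "breed", "sex", "age_years", "bw_kg", "examiner_id",
  "sighthound", "health_class", "view",
  names(.MM_VARS), "fs_pct"
)

.SEX_LEVELS <- c("male", "female")
.HEALTH_LEVELS <- c("all_ok", "immaculate", "excluded")
.VIEW_LEVELS <- c("long_axis", "short_axis")

# tolerance (percentage points) for the FS = 100*(LVDd-LVDs)/LVDd
# consistency check; source FS values are machine-computed then rounded
.FS_TOL <- 0.5

#' Construct an echocardiographic cohort
#'
#' An \code{echo_cohort} is a data frame with one row per screened dog and a
#' fixed column set: identifiers (\code{dog_id}, \code{examiner_id}),
#' signalment (\code{breed}, \code{sex}, \code{age_years}, \code{bw_kg} in
#' kg, \code{sighthound}, \code{health_class}), the acquisition \code{view},
#' the six M-mode dimensions in cm (possibly \code{NA}) and fractional
#' shortening \code{fs_pct} in percent. A free-text \code{provenance}
#' attribute records where the rows came from (file, generator seed, ...).
#'
#' @param df Data frame with (at least) the required columns.
#' @param provenance Character scalar describing the origin of the data.
#' @param validate Check invariants (default \code{TRUE}).
#' @return An \code{echo_cohort}.
#' @export
as_echo_cohort <- function(df, provenance = "unspecified", validate = TRUE) {
  stopifnot(is.data.frame(df))
  missing_cols <- setdiff(.COHORT_COLS, names(df))
  if (length(missing_cols) > 0L) {
    stop("missing required cohort column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- as.data.frame(df)[, .COHORT_COLS]
  df$dog_id <- as.character(df$dog_id)
  df$breed <- as.character(df$breed)
  df$examiner_id <- as.character(df$examiner_id)
  df$sighthound <- as.logical(df$sighthound)
  num_cols <- c("age_years", "bw_kg", names(.MM_VARS), "fs_pct")
  for (cl in num_cols) df[[cl]] <- as.numeric(df[[cl]])
  rownames(df) <- NULL
  out <- structure(df, class = c("echo_cohort", "data.frame"),
                   provenance = provenance)
  if (validate) {
    problems <- cohort_problems(out)
    if (nrow(problems) > 0L) {
      stop("invalid cohort (", nrow(problems), " problem(s)); first: row ",
           problems$row[1], ", field '", problems$field[1], "': ",
           problems$message[1], call. = FALSE)
    }
  }
  out
}

#' @export
print.echo_cohort <- function(x, ...) {
  cat("<echo_cohort> ", nrow(x), " dogs, ",
      length(unique(x$breed)), " breeds, ",
      length(unique(x$examiner_id)), " examiners\n", sep = "")
  cat("  provenance: ", attr(x, "provenance"), "\n", sep = "")
  print(head(as.data.frame(x), 4L))
  if (nrow(x) > 4L) cat("  ... (", nrow(x) - 4L, " more rows)\n", sep = "")
  invisible(x)
}

# One row per invariant violation: row index, field, message.
cohort_problems <- function(df) {
  bad <- list()
  note <- function(rows, field, msg) {
    if (length(rows) > 0L) {
      bad[[length(bad) + 1L]] <<- data.frame(
        row = rows, field = field, message = msg, stringsAsFactors = FALSE)
    }
  }
  note(which(is.na(df$bw_kg) | df$bw_kg <= 0), "bw_kg",
       "body weight must be a positive number (kg)")
  note(which(!df$sex %in% .SEX_LEVELS), "sex",
       paste("must be one of:", paste(.SEX_LEVELS, collapse = ", ")))
  note(which(!df$health_class %in% .HEALTH_LEVELS), "health_class",
       paste("must be one of:", paste(.HEALTH_LEVELS, collapse = ", ")))
  note(which(!df$view %in% .VIEW_LEVELS), "view",
       paste("must be one of:", paste(.VIEW_LEVELS, collapse = ", ")))
  note(which(!is.na(df$age_years) & df$age_years < 0), "age_years",
       "age must be nonnegative")
  for (v in names(.MM_VARS)) {
    note(which(!is.na(df[[v]]) & df[[v]] <= 0), v,
         "dimension must be positive (cm) when present")
  }
  note(which(!is.na(df$fs_pct) & (df$fs_pct <= 0 | df$fs_pct >= 100)),
       "fs_pct", "fractional shortening must lie in (0, 100)")
  ok_fs <- !is.na(df$fs_pct) & !is.na(df$lvdd_cm) & !is.na(df$lvds_cm) &
    df$lvdd_cm > 0
  fs_calc <- 100 * (df$lvdd_cm - df$lvds_cm) / df$lvdd_cm
  note(which(ok_fs & abs(df$fs_pct - fs_calc) > .FS_TOL), "fs_pct",
       sprintf("inconsistent with 100*(LVDd-LVDs)/LVDd beyond %.1f points",
               .FS_TOL))
  dup <- duplicated(df$dog_id)
  note(which(dup), "dog_id", "duplicate dog_id within cohort")
  if (length(bad) == 0L) {
    return(data.frame(row = integer(), field = character(),
                      message = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, bad)
  out[order(out$row), , drop = FALSE]
}

#' Read a cohort from CSV
#'
#' Reads a one-row-per-dog CSV with the fixed \code{echo_cohort} column set
#' (missing measurements as empty cells). In strict mode any invariant
#' violation (nonpositive body weight, inconsistent FS, duplicate ids, ...)
#' aborts with the offending row and field; in lenient mode violating rows
#' are dropped and the number dropped is reported via \code{message()} and
#' stored in the \code{dropped} attribute.
#'
#' @param path CSV file path.
#' @param strict Abort on any invalid row (default \code{TRUE})?
#' @return An \code{echo_cohort}.
#' @seealso [write_cohort()], [as_echo_cohort()]
#' @export
read_cohort <- function(path, strict = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(.COHORT_COLS, names(df))
  if (length(missing_cols) > 0L) {
    stop("missing required column(s) in ", path, ": ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  num_cols <- c("age_years", "bw_kg", names(.MM_VARS), "fs_pct")
  for (cl in num_cols) {
    suppressWarnings(v <- as.numeric(df[[cl]]))
    newly_na <- which(is.na(v) & !is.na(df[[cl]]) &
                        !(trimws(as.character(df[[cl]])) %in% c("", "NA")))
    if (length(newly_na) > 0L && strict) {
      stop("non-numeric value in column '", cl, "' at row ", newly_na[1],
           call. = FALSE)
    }
    df[[cl]] <- v
  }
  cohort <- as_echo_cohort(df, provenance = paste0("file:", path),
                           validate = FALSE)
  problems <- cohort_problems(cohort)
  if (nrow(problems) > 0L) {
    if (strict) {
      stop("invalid cohort in ", path, ": row ", problems$row[1],
           ", field '", problems$field[1], "': ", problems$message[1],
           " (", nrow(problems), " problem(s) total)", call. = FALSE)
    }
    drop_rows <- unique(problems$row)
    message("read_cohort: dropped ", length(drop_rows),
            " invalid record(s) of ", nrow(cohort))
    cohort <- cohort[-drop_rows, , drop = FALSE]
    cohort <- as_echo_cohort(cohort, provenance = paste0("file:", path),
                             validate = TRUE)
    attr(cohort, "dropped") <- length(drop_rows)
  }
  cohort
}

#' Write a cohort to CSV
#'
#' @param cohort An \code{echo_cohort}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "echo_cohort"))
  write.csv(as.data.frame(cohort), path, row.names = FALSE, na = "")
  invisible(path)
}

# ---- JSON serialization of fitted objects and report tables ----

.SERIALIZABLE <- c("allometric_fit", "index_constants", "data.frame")

#' Serialize a fitted model or report table to JSON
#'
#' Self-describing JSON serialization for [fit_allometric()] fits,
#' [index_constants] objects and plain report data frames. All numeric
#' fields must be finite; [read_model()] restores the object with values at
#' full stored precision.
#'
#' @param x Object to serialize.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_model <- function(x, path) {
  kind <- class(x)[1]
  if (!kind %in% .SERIALIZABLE) {
    stop("cannot serialize objects of class ", kind, call. = FALSE)
  }
  payload <- if (is.data.frame(x)) as.list(as.data.frame(x)) else unclass(x)
  nums <- unlist(Filter(is.numeric, payload), use.names = FALSE)
  if (any(!is.finite(nums))) {
    stop("refusing to serialize non-finite numeric field in ", kind,
         call. = FALSE)
  }
  obj <- list(class = kind, fields = payload)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read back a model serialized by [write_model()]
#'
#' @param path JSON file path.
#' @return The restored object.
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  fields <- obj$fields
  switch(obj$class,
    data.frame = as.data.frame(fields, stringsAsFactors = FALSE),
    index_constants = new_index_constants(
      variable = fields$variable, exponent = fields$exponent,
      percentiles = fields$percentiles,
      constants = setNames(unlist(fields$constants),
                           names(fields$constants))),
    allometric_fit = structure(fields, class = "allometric_fit"),
    stop("unknown serialized class: ", obj$class, call. = FALSE)
  )
}
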