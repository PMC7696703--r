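#' Assemble and validate a sample table
#'
#' A `sample_table` couples a numeric intensity matrix (rows = samples,
#' columns = variables) with per-sample metadata describing the matched
#' case-control design: which subject and pair each sample belongs to,
#' whether the subject is a future case or its matched control, whether the
#' sample is the baseline, the repeated (later) sample, or the only sample of
#' a single-time-point design, and the sampling / diagnosis times in years.
#'
#' Validation enforces the design invariants the downstream modeling relies
#' on: unique variable names, complete (non-missing, finite) intensities,
#' metadata rows matching value rows one-to-one by sample id, and each pair
#' id mapping to exactly one case subject and one control subject.
#'
#' @param values numeric matrix of intensities; rownames are sample ids,
#'   colnames are variable ids.
#' @param meta data frame with columns `sample_id`, `subject_id`, `pair_id`,
#'   `group` (`"case"`/`"control"`), `timepoint`
#'   (`"baseline"`/`"repeated"`/`"single"`), `sampling_time` (years, numeric
#'   or ISO-8601 date), `diagnosis_time` (years or ISO-8601 date; `NA` for
#'   controls).
#' @return an object of class `sample_table` with elements `values`,
#'   `variable_ids` and `meta` (times coerced to numeric years).
#' @export
sample_table <- function(values, meta) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)

  required <- c("sample_id", "subject_id", "pair_id", "group", "timepoint",
                "sampling_time", "diagnosis_time")
  missing_cols <- setdiff(required, names(meta))
  if (length(missing_cols) > 0L) {
    stop("schema error: metadata is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }

  if (is.null(colnames(values))) {
    stop("schema error: values matrix must have variable names as colnames",
         call. = FALSE)
  }
  if (anyDuplicated(colnames(values))) {
    dup <- unique(colnames(values)[duplicated(colnames(values))])
    stop("schema error: duplicated variable name(s): ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  if (anyNA(values) || any(!is.finite(values))) {
    stop("missing or non-finite values in intensity matrix; ",
         "only variables detected in all samples are supported", call. = FALSE)
  }

  if (is.null(rownames(values))) rownames(values) <- as.character(meta$sample_id)
  meta$sample_id <- as.character(meta$sample_id)
  if (nrow(values) != nrow(meta)) {
    stop("schema error: ", nrow(values), " value rows but ", nrow(meta),
         " metadata rows", call. = FALSE)
  }
  if (!setequal(rownames(values), meta$sample_id) ||
      anyDuplicated(meta$sample_id)) {
    stop("schema error: metadata sample_id does not match value row names",
         call. = FALSE)
  }
  values <- values[meta$sample_id, , drop = FALSE]

  meta$subject_id <- as.character(meta$subject_id)
  meta$pair_id <- as.character(meta$pair_id)
  meta$group <- as.character(meta$group)
  meta$timepoint <- as.character(meta$timepoint)
  if (!all(meta$group %in% c("case", "control"))) {
    stop("schema error: group must be 'case' or 'control'", call. = FALSE)
  }
  if (!all(meta$timepoint %in% c("baseline", "repeated", "single"))) {
    stop("schema error: timepoint must be 'baseline', 'repeated' or 'single'",
         call. = FALSE)
  }
  meta$sampling_time <- as_years(meta$sampling_time)
  meta$diagnosis_time <- as_years(meta$diagnosis_time)

  # each pair: exactly one case subject and one control subject
  by_pair <- split(meta, meta$pair_id)
  bad <- vapply(by_pair, function(m) {
    cases <- unique(m$subject_id[m$group == "case"])
    ctrls <- unique(m$subject_id[m$group == "control"])
    length(cases) != 1L || length(ctrls) != 1L
  }, logical(1))
  if (any(bad)) {
    stop("pairing error: pair(s) without exactly one case and one control ",
         "subject: ", paste(names(by_pair)[bad], collapse = ", "),
         call. = FALSE)
  }

  structure(list(values = values,
                 variable_ids = colnames(values),
                 meta = meta),
            class = "sample_table")
}

# Times are continuous years. Dates (ISO-8601) are converted using the mean
# Gregorian year length so that differences of converted values are exact
# year spans.
as_years <- function(x) {
  if (inherits(x, "Date")) return(as.numeric(x) / 365.2425)
  if (is.character(x)) {
    out <- suppressWarnings(as.numeric(x))
    idx <- is.na(out) & !is.na(x) & nzchar(x)
    if (any(idx)) {
      d <- as.Date(x[idx], format = "%Y-%m-%d")
      if (anyNA(d)) {
        stop("schema error: time values must be numeric years or ISO-8601 ",
             "dates", call. = FALSE)
      }
      out[idx] <- as.numeric(d) / 365.2425
    }
    return(out)
  }
  as.numeric(x)
}

#' Read a cohort from a values file and a metadata file
#'
#' The values file is delimited text with the sample id in the first column
#' and one column per variable. The metadata file carries the columns
#' documented in [sample_table()]. Tab and comma delimiters are
#' auto-detected from the header line.
#'
#' @param values_path path to the delimited values matrix.
#' @param meta_path path to the delimited metadata table.
#' @return a validated [sample_table()].
#' @export
read_cohort <- function(values_path, meta_path) {
  vals <- read_delim_auto(values_path)
  meta <- read_delim_auto(meta_path)
  m <- as.matrix(vals[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(vals[[1L]])
  sample_table(m, meta)
}

#' Write a cohort to a values file and a metadata file
#'
#' Inverse of [read_cohort()]: values with the sample id as first column,
#' metadata as-is, both as TSV. Numeric values are written at full double
#' precision so a write/read round trip reproduces the matrix exactly.
#'
#' @param table a [sample_table()].
#' @param values_path,meta_path output paths.
#' @return invisibly, the input table.
#' @export
write_cohort <- function(table, values_path, meta_path) {
  stopifnot(inherits(table, "sample_table"))
  df <- data.frame(sample_id = rownames(table$values),
                   table$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, values_path)
  write_tsv(table$meta, meta_path)
  invisible(table)
}

read_delim_auto <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                    stringsAsFactors = FALSE, comment.char = "",
                    quote = "\"")
}

write_tsv <- function(df, path) {
  # format() at 17 significant digits keeps doubles round-trip exact
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(x) {
    ifelse(is.na(x), NA_character_,
           formatC(x, digits = 17, format = "g"))
  })
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' @export
print.sample_table <- function(x, ...) {
  cat("sample_table: ", nrow(x$values), " samples x ",
      ncol(x$values), " variables\n", sep = "")
  cat("  pairs: ", length(unique(x$meta$pair_id)),
      "; timepoints: ", paste(unique(x$meta$timepoint), collapse = "/"),
      "\n", sep = "")
  invisible(x)
}
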