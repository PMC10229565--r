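#' Read an IBI file
#'
#' Reads a one-column interval file: either a CSV with an `ibi_ms` header or a
#' headerless plain-text file with one RR interval (ms) per row. Subject, day
#' and session metadata come from the arguments or, when omitted, from a
#' filename of the form `<subject>_<day>_<session>.csv`.
#'
#' Non-numeric rows are rejected with the offending row number; nothing is
#' silently dropped.
#'
#' @param path file path.
#' @param subject_id,day_index,session optional metadata overriding the
#'   filename convention.
#' @return an [ibi_series()].
#' @export
read_ibi_file <- function(path, subject_id = NULL, day_index = NULL,
                          session = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) > 0 && identical(tolower(lines[1]), "ibi_ms")) {
    lines <- lines[-1]
  }
  if (length(lines) < 2) {
    stop("empty or near-empty IBI file (fewer than 2 intervals): ", path,
         call. = FALSE)
  }
  vals <- suppressWarnings(as.numeric(lines))
  if (anyNA(vals)) {
    bad <- which(is.na(vals))[1]
    stop(sprintf("non-numeric IBI value at row %d of %s: '%s'",
                 bad, path, lines[bad]), call. = FALSE)
  }
  meta <- parse_ibi_filename(path)
  ibi_series(vals,
             subject_id = subject_id %||% meta$subject_id,
             day_index  = day_index %||% meta$day_index,
             session    = session %||% meta$session)
}

parse_ibi_filename <- function(path) {
  stem <- sub("\\.[^.]*$", "", basename(path))
  parts <- strsplit(stem, "_", fixed = TRUE)[[1]]
  n <- length(parts)
  if (n >= 3 && grepl("^[0-9]+$", parts[n - 1]) &&
      parts[n] %in% c("morning", "evening")) {
    list(subject_id = paste(parts[1:(n - 2)], collapse = "_"),
         day_index = as.integer(parts[n - 1]), session = parts[n])
  } else {
    list(subject_id = stem, day_index = 0L, session = "morning")
  }
}

#' Write an IBI series to disk
#'
#' One-column CSV with header `ibi_ms`; the filename encodes the metadata as
#' `<subject>_<day>_<session>.csv` so that [read_ibi_file()] round-trips it.
#'
#' @param series an [ibi_series()].
#' @param dir output directory (created if missing).
#' @return the path written, invisibly.
#' @export
write_ibi_file <- function(series, dir) {
  stopifnot(inherits(series, "ibi_series"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  path <- file.path(dir, sprintf("%s_%d_%s.csv", series$subject_id,
                                 series$day_index, series$session))
  writeLines(c("ibi_ms", sprintf("%.17g", series$intervals)), path)
  invisible(path)
}

#' Read a weekly symptom file
#'
#' CSV with columns `week_index` and `scl90_dep`. Rows may be unordered;
#' the result is sorted by week. Duplicate weeks are an error; missing weeks
#' are permitted and stay as gaps.
#'
#' @param path file path.
#' @param subject_id optional subject id (default: file stem).
#' @return a [symptom_series()].
#' @export
read_symptom_file <- function(path, subject_id = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("week_index", "scl90_dep")
  if (!all(need %in% names(df))) {
    stop("symptom file must have columns week_index and scl90_dep: ", path,
         call. = FALSE)
  }
  symptom_series(df$week_index, df$scl90_dep,
                 subject_id = subject_id %||% sub("\\.[^.]*$", "", basename(path)))
}

#' @rdname read_symptom_file
#' @param series a [symptom_series()].
#' @param dir output directory.
#' @export
write_symptom_file <- function(series, dir) {
  stopifnot(inherits(series, "symptom_series"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  path <- file.path(dir, paste0(series$subject_id, "_scl90.csv"))
  utils::write.csv(
    data.frame(week_index = series$week_index, scl90_dep = series$score),
    path, row.names = FALSE)
  invisible(path)
}

#' Read a cohort manifest
#'
#' The manifest links interval files to subjects: CSV with columns
#' `subject_id`, `ibi_path`, `day_index`, `session`, plus optional `group`,
#' `symptom_path` and `clinical_override` columns. Paths are resolved
#' relative to the manifest's directory. Every referenced file must exist.
#'
#' @param path manifest CSV path.
#' @return a tibble with one row per assessment file and the per-subject
#'   columns carried along.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "ibi_path", "day_index", "session")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop("manifest is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  root <- dirname(path)
  resolve <- function(p) ifelse(file.exists(p), p, file.path(root, p))
  df$ibi_path <- resolve(df$ibi_path)
  gone <- !file.exists(df$ibi_path)
  if (any(gone)) {
    stop("manifest references missing IBI file(s): ",
         paste(utils::head(df$ibi_path[gone], 3), collapse = ", "),
         call. = FALSE)
  }
  if ("symptom_path" %in% names(df)) {
    df$symptom_path <- resolve(df$symptom_path)
    gone <- !is.na(df$symptom_path) & !file.exists(df$symptom_path)
    if (any(gone)) {
      stop("manifest references missing symptom file(s): ",
           paste(unique(df$symptom_path[gone]), collapse = ", "),
           call. = FALSE)
    }
  }
  tibble::as_tibble(df)
}

#' Write result tables plus run metadata
#'
#' Writes each table in `tables` as `<path_prefix><name>.csv` (stable column
#' order, no row names) and a `<path_prefix>run_metadata.json` recording the
#' configuration, seed and package version, so a run can be audited and
#' reproduced byte-for-byte.
#'
#' @param tables named list of data frames.
#' @param path_prefix output path prefix (directory part is created).
#' @param config list echoed into the metadata file.
#' @param seed the seed used for the run (recorded, not applied).
#' @return character vector of files written, invisibly.
#' @export
write_results <- function(tables, path_prefix, config = list(), seed = NULL) {
  stopifnot(is.list(tables), !is.null(names(tables)), all(nzchar(names(tables))))
  dir <- dirname(paste0(path_prefix, "x"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (nm in names(tables)) {
    p <- paste0(path_prefix, nm, ".csv")
    utils::write.csv(as.data.frame(tables[[nm]]), p, row.names = FALSE)
    paths <- c(paths, p)
  }
  meta <- list(
    package = "hrvtrans",
    version = as.character(utils::packageVersion("hrvtrans")),
    seed = seed,
    config = config,
    tables = names(tables)
  )
  mp <- paste0(path_prefix, "run_metadata.json")
  jsonlite::write_json(meta, mp, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(c(paths, mp))
}
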