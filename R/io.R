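# Readers/writers for the item-parameter, response and results formats.
# Comma-delimited, decimal point, UTF-8, mandatory header; numbers survive a
# round trip to at least 12 significant digits. The readers normalize the
# typographic minus sign (U+2212) to ASCII.

ITEM_COLS <- c("item_id", "a", "b", "c")

fmt_num <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) "" else format(v, digits = 15, scientific = FALSE,
                                 trim = TRUE)
  }, character(1))
}

normalize_minus <- function(x) gsub("−", "-", x)

parse_num <- function(x, col, path) {
  x <- normalize_minus(trimws(x))
  out <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & x != "" & is.na(out))
  if (length(bad))
    stop(sprintf("cannot parse column '%s' of %s as numeric (data row%s %s)",
                 col, path, if (length(bad) > 1) "s" else "",
                 paste(bad, collapse = ", ")), call. = FALSE)
  out
}

#' Write an item-parameter table to CSV or JSON
#'
#' Columns: `item_id`, `a`, `b`, `c`, and `anchor_block`/`forms` when
#' present. The format follows the file extension (`.json` for JSON,
#' anything else CSV). Round trips are lossless to 12 significant digits.
#'
#' @param items item-parameter data.frame, `item_bank` or
#'   `calibration_result`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_item_params <- function(items, path) {
  if (inherits(items, "item_bank")) items <- items$items
  if (inherits(items, "calibration_result")) items <- items$item_estimates
  if (!all(ITEM_COLS %in% names(items)))
    stop("schema error: need columns ", paste(ITEM_COLS, collapse = ", "),
         call. = FALSE)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(items, path, digits = NA, dataframe = "rows")
  } else {
    out <- items
    for (cl in c("a", "b", "c")) out[[cl]] <- fmt_num(out[[cl]])
    write.csv(out, path, row.names = FALSE, quote = FALSE,
              fileEncoding = "UTF-8")
  }
  invisible(path)
}

#' Read an item-parameter table from CSV or JSON
#'
#' @param path input path (CSV or JSON, by extension).
#' @return data.frame with at least `item_id`, `a`, `b`, `c`.
#' @export
read_item_params <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    df <- jsonlite::fromJSON(path)
  } else {
    df <- read.csv(path, colClasses = "character", fileEncoding = "UTF-8",
                   check.names = FALSE)
    missing <- setdiff(ITEM_COLS, names(df))
    if (length(missing))
      stop(sprintf("schema error in %s: missing column%s %s", path,
                   if (length(missing) > 1) "s" else "",
                   paste(missing, collapse = ", ")), call. = FALSE)
    for (cl in c("a", "b", "c")) df[[cl]] <- parse_num(df[[cl]], cl, path)
  }
  missing <- setdiff(ITEM_COLS, names(df))
  if (length(missing))
    stop(sprintf("schema error in %s: missing column%s %s", path,
                 if (length(missing) > 1) "s" else "",
                 paste(missing, collapse = ", ")), call. = FALSE)
  if (any(!is.finite(df$a)) || any(df$a <= 0))
    stop("invalid discriminations in ", path, call. = FALSE)
  df
}

#' Write / read a binary response matrix
#'
#' CSV with a `person_id` column followed by one 0/1 column per item.
#'
#' @param responses persons x items binary matrix with dimnames.
#' @param path file path.
#' @return `path` (writer, invisibly) or the matrix (reader).
#' @export
write_responses <- function(responses, path) {
  x <- as.matrix(responses)
  df <- data.frame(person_id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE,
            fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_responses
#' @export
read_responses <- function(path) {
  df <- read.csv(path, check.names = FALSE, fileEncoding = "UTF-8")
  if (!"person_id" %in% names(df))
    stop("schema error in ", path, ": missing column person_id",
         call. = FALSE)
  x <- as.matrix(df[, setdiff(names(df), "person_id"), drop = FALSE])
  if (any(!x %in% c(0, 1)))
    stop("non-binary responses in ", path, call. = FALSE)
  storage.mode(x) <- "integer"
  rownames(x) <- df$person_id
  x
}

#' Write / read long-format study records
#'
#' Plain CSV of the records table produced by [run_study()]; directly
#' consumable by external mixed-model tooling.
#'
#' @param records records data.frame.
#' @param path file path.
#' @return `path` (writer, invisibly) or the data.frame (reader).
#' @export
write_results <- function(records, path) {
  write.csv(records, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  read.csv(path, fileEncoding = "UTF-8")
}

#' Write per-person ability estimates
#'
#' CSV columns `person_id`, `form`, `theta_hat`.
#'
#' @param fit a `calibration_result`.
#' @param form form index recorded with each row.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_theta <- function(fit, form, path) {
  df <- data.frame(person_id = fit$theta$person_id, form = form,
                   theta_hat = fmt_num(fit$theta$theta_hat))
  write.csv(df, path, row.names = FALSE, quote = FALSE,
            fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a study configuration from JSON
#'
#' Keys mirror the arguments of [study_config()]; unknown keys are rejected
#' individually by name.
#'
#' @param path JSON file.
#' @param overrides named list applied on top of the file's values.
#' @return a `study_config`.
#' @export
read_study_config <- function(path, overrides = list()) {
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  raw <- modifyList(raw, overrides)
  allowed <- setdiff(names(formals(study_config)), "calib")
  unknown <- setdiff(names(raw), c(allowed, "calib"))
  if (length(unknown))
    stop("invalid config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  calib <- if (!is.null(raw$calib)) do.call(calib_control, as.list(raw$calib))
           else calib_control()
  raw$calib <- NULL
  do.call(study_config, c(raw, list(calib = calib)))
}
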