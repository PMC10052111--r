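# CSV reading and writing for measurement tables. One dialect everywhere:
# UTF-8, '.' decimal separator, the column set of measurements().

#' Read a measurement table from CSV
#'
#' Expects the package's measurement CSV dialect: header row with columns
#' `analyte, matrix, value, unit, loq, below_loq, sector, creatinine, date`
#' (the `unit` column is mandatory and must match the matrix). Malformed
#' rows are reported with their line numbers.
#'
#' @param path path to a CSV file.
#' @return a validated measurement table (see [measurements()]).
#' @export
read_measurements <- function(path) {
  if (!file.exists(path)) stop("measurement file not found: ", path)
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8",
                    na.strings = c("NA", "")),
    error = function(e) stop("cannot parse ", path, ": ", conditionMessage(e),
                             call. = FALSE)
  )
  missing_cols <- setdiff(MEASUREMENT_COLUMNS, names(df))
  if (length(missing_cols)) {
    stop(path, ": missing header column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  df <- df[MEASUREMENT_COLUMNS]
  df$below_loq <- as.logical(df$below_loq)
  for (col in c("value", "loq", "creatinine")) df[[col]] <- as.numeric(df[[col]])
  df$date <- as.character(df$date)
  # +1 for the header line when naming offending rows
  bad <- which(is.na(df$value) | is.na(df$loq) | is.na(df$below_loq))
  if (length(bad)) {
    stop(path, ": malformed row(s) at line(s) ",
         paste(bad + 1L, collapse = ", "),
         " (value, loq and below_loq must be present and numeric/logical)")
  }
  tryCatch(validate_measurements(df),
           error = function(e) stop(path, ": ", conditionMessage(e),
                                    call. = FALSE))
}

#' Write a measurement table to CSV
#'
#' Round-trip companion of [read_measurements()]:
#' `read_measurements(write_measurements(x, f))` reproduces `x`.
#'
#' @param df a measurement table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(df, path) {
  df <- validate_measurements(df)
  out <- as.data.frame(df)[MEASUREMENT_COLUMNS]
  out$below_loq <- ifelse(out$below_loq, "TRUE", "FALSE")
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8", na = "")
  invisible(path)
}
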