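.SAMPLE_NUMERIC <- c("d18O_W", "d2H_W", "d18O_M", "d2H_M", "temp_2wk")

#' Read milk sample records from a CSV file
#'
#' Reads a comma-separated table of sample records (header row, UTF-8).
#' Recognised columns: `shed_id`, `date` (`DD/MM/YYYY`), `t` (day number),
#' `d18O_W`, `d2H_W`, `d18O_M`, `d2H_M`, `temp_2wk`, `outdoor_summer`; other
#' columns are kept as-is. Missing values are empty fields. Unicode minus
#' signs (as often pasted from publications) are normalised to ASCII.
#' Where `t` is absent it is filled from the date on the non-leap calendar;
#' an explicit `t` is kept even when it disagrees with the date, since
#' published tables occasionally carry authoritative day numbers. Rows whose
#' date cannot be mapped (e.g. 29 February) are dropped with a warning that
#' reports their line numbers; the remaining rows are returned.
#'
#' @param path CSV file path.
#' @return Data frame of sample records; dropped-row messages are attached
#'   as attribute `row_errors`.
#' @export
read_samples <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character",
                         fileEncoding = "UTF-8", strip.white = TRUE)
  mandatory <- c("shed_id", "d18O_M")
  miss <- setdiff(mandatory, names(raw))
  if (length(miss)) {
    stop("schema error: missing mandatory column(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (!("t" %in% names(raw)) && !("date" %in% names(raw))) {
    stop("schema error: need a `t` or `date` column", call. = FALSE)
  }
  for (col in intersect(c(.SAMPLE_NUMERIC, "t"), names(raw))) {
    raw[[col]] <- as.numeric(gsub("−", "-", raw[[col]]))
  }
  if ("outdoor_summer" %in% names(raw)) {
    raw$outdoor_summer <- as.logical(raw$outdoor_summer)
  }
  if (!("t" %in% names(raw))) raw$t <- NA_real_
  row_errors <- character()
  if ("date" %in% names(raw)) {
    need_t <- which(is.na(raw$t) & nzchar(raw$date))
    drop <- integer()
    for (i in need_t) {
      ti <- tryCatch(day_number(raw$date[i]), error = function(e) e)
      if (inherits(ti, "error")) {
        # +1 for the header row
        row_errors <- c(row_errors,
                        sprintf("line %d: %s", i + 1L, conditionMessage(ti)))
        drop <- c(drop, i)
      } else {
        raw$t[i] <- ti
      }
    }
    if (length(drop)) {
      warning("dropped ", length(drop), " malformed row(s):\n  ",
              paste(row_errors, collapse = "\n  "), call. = FALSE)
      raw <- raw[-drop, , drop = FALSE]
      rownames(raw) <- NULL
    }
  }
  raw$t <- as.integer(raw$t)
  attr(raw, "row_errors") <- row_errors
  raw
}

#' Write sample records to CSV
#'
#' Inverse of [read_samples()]: comma-separated, header row, missing values
#' as empty fields, dates as `DD/MM/YYYY`, full numeric precision.
#'
#' @param records Data frame of sample records.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_samples <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, na = "",
                   fileEncoding = "UTF-8", quote = FALSE)
  invisible(path)
}

#' Write a verification report to CSV
#'
#' Writes the report produced by [verify_samples()] — the sample inputs, the
#' calculated seasonal values, the per-step differences (per mil) and the
#' pass/fail flags — as a delimited file that round-trips through
#' [read_report()] at full precision.
#'
#' @param results Data frame from [verify_samples()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path) {
  if (is.null(results) || nrow(results) == 0) {
    stop("no results to write", call. = FALSE)
  }
  utils::write.csv(results, path, row.names = FALSE, na = "",
                   fileEncoding = "UTF-8", quote = FALSE)
  invisible(path)
}

#' Read a verification report written by [write_report()]
#'
#' @param path CSV file path.
#' @return Data frame with the report columns restored to their types.
#' @export
read_report <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  out <- utils::read.csv(path, fileEncoding = "UTF-8", strip.white = TRUE)
  for (col in intersect(c("step1_pass", "step2_pass", "overall"),
                        names(out))) {
    out[[col]] <- as.logical(out[[col]])
  }
  out
}
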