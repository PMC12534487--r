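#' Read a submission table from CSV
#'
#' Reads timestamped 7-item Likert submissions. The CSV must have a header
#' row; the expected columns are `timestamp` plus the seven item names in
#' [swemwbs_items]. Deposited files with different headers are handled via
#' `column_map`, a named character vector mapping the canonical names to the
#' file's column names, e.g. `c(timestamp = "Submitted", relaxed = "Relax")`.
#'
#' No filtering is applied: rows arrive in file order, invalid codes intact.
#'
#' @param path Path to a CSV file.
#' @param column_map Optional named character vector (canonical -> file
#'   column). Unmapped canonical names are looked up verbatim.
#' @return A `submission_table`: a data.frame with a POSIXct `timestamp`
#'   column and the seven item columns, one row per submission.
#' @export
read_submissions <- function(path, column_map = NULL) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)

  wanted <- c("timestamp", swemwbs_items)
  names(wanted) <- wanted
  if (!is.null(column_map)) {
    bad <- setdiff(names(column_map), wanted)
    if (length(bad) > 0)
      stop("column_map has unknown canonical names: ", paste(bad, collapse = ", "),
           call. = FALSE)
    wanted[names(column_map)] <- column_map
  }
  missing_cols <- wanted[!wanted %in% names(raw)]
  if (length(missing_cols) > 0)
    stop("input is missing required column(s): ",
         paste(sprintf("'%s' (for %s)", missing_cols, names(missing_cols)),
               collapse = ", "),
         call. = FALSE)

  ts <- parse_timestamps(raw[[wanted[["timestamp"]]]])
  if (anyNA(ts)) {
    rows <- which(is.na(ts))
    stop("unparseable timestamp in row(s): ",
         paste(utils::head(rows, 20), collapse = ", "),
         if (length(rows) > 20) sprintf(" (and %d more)", length(rows) - 20) else "",
         call. = FALSE)
  }

  out <- data.frame(timestamp = ts)
  for (item in swemwbs_items) {
    v <- raw[[wanted[[item]]]]
    out[[item]] <- suppressWarnings(as.numeric(v))
  }
  class(out) <- c("submission_table", "data.frame")
  out
}

parse_timestamps <- function(x) {
  if (inherits(x, "POSIXct")) return(x)
  x <- as.character(x)
  fmts <- c("%Y-%m-%d %H:%M:%S", "%Y-%m-%d %H:%M", "%Y-%m-%dT%H:%M:%S",
            "%d/%m/%Y %H:%M")
  out <- as.POSIXct(rep(NA_character_, length(x)), tz = "UTC")
  for (f in fmts) {
    idx <- is.na(out)
    if (!any(idx)) break
    out[idx] <- as.POSIXct(x[idx], format = f, tz = "UTC")
  }
  out
}

#' Write a submission table to CSV
#'
#' Inverse of [read_submissions()]: canonical headers, minute-resolution
#' timestamps, one row per submission in table order.
#'
#' @param table A `submission_table`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_submissions <- function(table, path) {
  out <- as.data.frame(table)
  out$timestamp <- format(out$timestamp, "%Y-%m-%d %H:%M", tz = "UTC")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct an observation sequence
#'
#' A cleaned, chronologically ordered T x 7 matrix of Likert scores together
#' with its timestamps. Values are integers 1-5 before modelling but are
#' treated as real-valued by the Gaussian emission model.
#'
#' @param values Numeric T x d matrix.
#' @param timestamps POSIXct vector of length T, nondecreasing.
#' @param item_names Character vector of length d.
#' @return An `observation_sequence` object.
#' @export
observation_sequence <- function(values, timestamps,
                                 item_names = colnames(values)) {
  values <- as.matrix(values)
  if (nrow(values) < 1) stop("observation sequence must have T >= 1", call. = FALSE)
  if (length(timestamps) != nrow(values))
    stop("timestamps length must match rows of values", call. = FALSE)
  if (is.unsorted(as.numeric(timestamps)))
    stop("timestamps must be nondecreasing", call. = FALSE)
  if (is.null(item_names)) item_names <- paste0("item_", seq_len(ncol(values)))
  colnames(values) <- item_names
  structure(list(values = values, timestamps = timestamps,
                 item_names = item_names),
            class = "observation_sequence")
}

#' @export
print.observation_sequence <- function(x, ...) {
  cat(sprintf("observation_sequence: T = %d, %d items (%s)\n",
              nrow(x$values), length(x$item_names),
              paste(x$item_names, collapse = ", ")))
  cat(sprintf("  time span: %s .. %s\n",
              format(min(x$timestamps)), format(max(x$timestamps))))
  invisible(x)
}

#' Clean a submission table
#'
#' Applies the study's exclusion rule: any record carrying a code outside
#' {1, ..., 5} on any of the seven items (the deposited data contain rare 0
#' and -1 codes), or with a missing item, is dropped whole. Survivors are
#' sorted by timestamp; ties keep input order (stable sort).
#'
#' @param table A `submission_table`.
#' @return A list with components `sequence` (an [observation_sequence()])
#'   and `report`, a list of exclusion counts by reason (`invalid_code`,
#'   `missing`), the input/retained totals and the survivor fraction.
#' @export
clean_submissions <- function(table) {
  if (nrow(table) == 0) stop("submission table is empty", call. = FALSE)
  vals <- as.matrix(as.data.frame(table)[, swemwbs_items])
  storage.mode(vals) <- "double"

  has_missing <- apply(vals, 1, anyNA)
  ok_code <- !is.na(vals) & vals %in% c(1, 2, 3, 4, 5)
  has_invalid <- apply(!ok_code & !is.na(vals), 1, any)

  drop_missing <- has_missing
  drop_invalid <- has_invalid & !has_missing  # one reason per record
  keep <- !(drop_missing | drop_invalid)

  report <- list(
    n_input = nrow(table),
    excluded_invalid_code = sum(drop_invalid),
    excluded_missing = sum(drop_missing),
    n_retained = sum(keep),
    survivor_fraction = sum(keep) / nrow(table)
  )
  if (report$n_retained == 0)
    stop("no records survive cleaning", call. = FALSE)

  vals <- vals[keep, , drop = FALSE]
  ts <- table$timestamp[keep]
  ord <- order(as.numeric(ts))  # radix order: stable for ties
  seq <- observation_sequence(vals[ord, , drop = FALSE], ts[ord],
                              item_names = swemwbs_items)
  list(sequence = seq, report = report)
}

#' Assign morning/afternoon time bins
#'
#' Labels each observation by its clock time: `morning` for \[06:00, 12:00),
#' `afternoon` for \[12:00, 18:00), `excluded` otherwise (the installation
#' collected no valid evening data). Intervals are half-open, so 12:00 falls
#' in the afternoon.
#'
#' @param seq An [observation_sequence()].
#' @return A factor of length T with levels morning/afternoon/excluded.
#' @export
assign_time_bins <- function(seq) {
  lt <- as.POSIXlt(seq$timestamps, tz = "UTC")
  hours <- lt$hour + lt$min / 60 + lt$sec / 3600
  lab <- ifelse(hours >= 6 & hours < 12, "morning",
                ifelse(hours >= 12 & hours < 18, "afternoon", "excluded"))
  factor(lab, levels = c("morning", "afternoon", "excluded"))
}

#' Write a cleaned observation sequence to CSV
#'
#' @param seq An [observation_sequence()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_observations <- function(seq, path) {
  out <- data.frame(timestamp = format(seq$timestamps, "%Y-%m-%d %H:%M", tz = "UTC"))
  out <- cbind(out, as.data.frame(seq$values))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
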