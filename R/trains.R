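#' Discharge event tables
#'
#' `motorsync` represents discharge data as an *event tibble*: one row per
#' action potential, with a `time` column (seconds) and a `unit` column
#' (unit label). All analysis functions accept this layout, so readers,
#' simulators and analyses chain with the pipe.
#'
#' `as_event_tbl()` coerces and validates a data frame into this layout:
#' times must be finite, non-negative numbers, and within each unit they
#' must be unique (duplicate timestamps are physiologically impossible and
#' indicate an upstream decomposition fault, so they raise an error rather
#' than being deduplicated silently). Rows are sorted by unit appearance
#' order, then time, so row order in the source never affects results.
#'
#' @param x A data frame with columns `time` (numeric seconds) and `unit`.
#' @return A tibble with columns `time` and `unit`, sorted by time within
#'   unit, carrying a `units` attribute listing all unit labels (including
#'   units with zero discharges, which cannot own any rows).
#' @examples
#' as_event_tbl(data.frame(time = c(0.1, 0.035, 0.115), unit = c("u2", "u1", "u1")))
#' @export
as_event_tbl <- function(x) {
  if (!is.data.frame(x)) {
    stop("`x` must be a data frame with columns `time` and `unit`", call. = FALSE)
  }
  names(x)[match(c("time", "unit"), tolower(names(x)))] <- c("time", "unit")
  if (!all(c("time", "unit") %in% names(x))) {
    stop("event table must have columns `time` and `unit`", call. = FALSE)
  }
  units_attr <- attr(x, "units")
  x <- tibble::as_tibble(x[c("time", "unit")])
  x$unit <- as.character(x$unit)
  x$time <- as.double(x$time)
  bad <- which(!is.finite(x$time) | x$time < 0)
  if (length(bad) > 0) {
    stop(sprintf("non-finite or negative time at row %d (unit '%s')",
                 bad[1], x$unit[bad[1]]), call. = FALSE)
  }
  x$.row <- seq_len(nrow(x))
  unit_levels <- unique(x$unit)
  x <- x[order(match(x$unit, unit_levels), x$time), ]
  for (u in unit_levels) {
    tu <- x[x$unit == u, ]
    dup <- which(duplicated(tu$time))
    if (length(dup) > 0) {
      stop(sprintf("duplicate discharge time %.6g in unit '%s' (row %d)",
                   tu$time[dup[1]], u, tu$.row[dup[1]]), call. = FALSE)
    }
  }
  x$.row <- NULL
  attr(x, "units") <- unique(c(unit_levels, units_attr))
  x
}

#' List the unit labels in an event table
#'
#' @param events An event tibble (see [as_event_tbl()]).
#' @return Character vector of unit labels, including any units recorded as
#'   present but silent (zero discharges).
#' @export
unit_labels <- function(events) {
  u <- attr(events, "units")
  if (is.null(u)) unique(as.character(events$unit)) else u
}

# named list of sorted discharge-time vectors, one per unit
discharge_times <- function(events) {
  events <- as_event_tbl(events)
  lapply(stats::setNames(nm = unit_labels(events)),
         function(u) events$time[events$unit == u])
}

sniff_delim <- function(path) {
  header <- readLines(path, n = 1L)
  if (length(header) == 0) {
    stop(sprintf("'%s' is empty", path), call. = FALSE)
  }
  if (grepl("\t", header, fixed = TRUE)) "\t" else ","
}

#' Read discharge times from an event-list file
#'
#' An event list is a CSV or TSV file (delimiter sniffed from the header
#' row) with one row per discharge and header columns `time` (seconds) and
#' `unit` (label).
#'
#' @param path Path to the file.
#' @param units Optional character vector restricting (and checking) the
#'   unit labels to load; an unknown label is an error.
#' @return An event tibble (see [as_event_tbl()]).
#' @export
read_event_list <- function(path, units = NULL) {
  if (!file.exists(path)) stop(sprintf("no such file: '%s'", path), call. = FALSE)
  delim <- sniff_delim(path)
  x <- readr::read_delim(path, delim = delim, col_types = readr::cols(),
                         show_col_types = FALSE, progress = FALSE)
  if (nrow(x) == 0) stop(sprintf("'%s' contains no discharges", path), call. = FALSE)
  x <- as_event_tbl(x)
  if (!is.null(units)) {
    unknown <- setdiff(units, unit_labels(x))
    if (length(unknown) > 0) {
      stop(sprintf("unknown unit label(s): %s", paste(unknown, collapse = ", ")),
           call. = FALSE)
    }
    keep <- x$unit %in% units
    x <- x[keep, ]
    attr(x, "units") <- units
  }
  x
}

#' Read discharge times from a sampled indicator table
#'
#' The indicator layout is a regular time series: a `Time` column (seconds,
#' typically on a 1 kHz grid) plus one 0/1 column per unit, with 1 marking a
#' discharge at that sample. Times are taken verbatim; no resampling.
#'
#' @param path Path to a CSV/TSV indicator table.
#' @return An event tibble. Units whose column is all zero contribute no
#'   rows but are kept in `unit_labels()` and flagged with a warning.
#' @export
read_indicator_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: '%s'", path), call. = FALSE)
  delim <- sniff_delim(path)
  x <- readr::read_delim(path, delim = delim, col_types = readr::cols(),
                         show_col_types = FALSE, progress = FALSE)
  tcol <- which(tolower(names(x)) == "time")
  if (length(tcol) != 1) {
    stop(sprintf("'%s' must have exactly one Time column", path), call. = FALSE)
  }
  time <- as.double(x[[tcol]])
  unit_cols <- setdiff(seq_along(x), tcol)
  if (length(unit_cols) == 0) {
    stop(sprintf("'%s' has no unit columns", path), call. = FALSE)
  }
  pieces <- lapply(unit_cols, function(j) {
    v <- x[[j]]
    if (!all(v %in% c(0, 1))) {
      stop(sprintf("unit column '%s' contains non-binary values", names(x)[j]),
           call. = FALSE)
    }
    tibble::tibble(time = time[v == 1], unit = names(x)[j])
  })
  silent <- names(x)[unit_cols][vapply(pieces, nrow, 0L) == 0]
  if (length(silent) > 0) {
    warning(sprintf("unit(s) with no discharges: %s", paste(silent, collapse = ", ")),
            call. = FALSE)
  }
  out <- dplyr::bind_rows(pieces)
  attr(out, "units") <- names(x)[unit_cols]
  as_event_tbl(out)
}

#' Write an event table to an event-list CSV
#'
#' Output is sorted by unit then time and formatted deterministically, so
#' identical input always produces a byte-identical file.
#'
#' @param events An event tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_event_list <- function(events, path) {
  events <- as_event_tbl(events)
  readr::write_csv(events[c("time", "unit")], path, progress = FALSE)
  invisible(path)
}

#' Per-unit discharge characteristics
#'
#' Computes, for every unit in an event table, the discharge count, the
#' interspike intervals (ISIs, successive differences of the discharge
#' times) and their arithmetic mean. At least two discharges per unit are
#' required, since a single discharge has no ISI.
#'
#' @param events An event tibble.
#' @return A tibble with one row per unit: `unit`, `n_discharges`,
#'   `mean_isi` (s), and a list-column `isis` of the individual intervals.
#' @examples
#' events <- as_event_tbl(data.frame(
#'   time = c(0.035, 0.115, 0.183), unit = "motor_unit_1"))
#' unit_characteristics(events)
#' @export
unit_characteristics <- function(events) {
  trains <- discharge_times(as_event_tbl(events))
  short <- names(trains)[vapply(trains, length, 0L) < 2]
  if (length(short) > 0) {
    stop(sprintf("unit(s) with fewer than 2 discharges: %s",
                 paste(short, collapse = ", ")), call. = FALSE)
  }
  tibble::tibble(
    unit = names(trains),
    n_discharges = unname(vapply(trains, length, 0L)),
    mean_isi = unname(vapply(trains, function(t) mean(diff(t)), 0)),
    isis = unname(lapply(trains, diff))
  )
}
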