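#' Construct a spike train
#'
#' A spike train is a vector of spike times for one neuron, in seconds,
#' sorted non-decreasing. Duplicate times are kept: spike sorting can emit
#' coincident spikes and the downstream statistics tolerate ties.
#'
#' @param times numeric vector of spike times (seconds, finite, >= 0).
#'   Unsorted input is sorted with a warning.
#' @param neuron_id opaque identifier for the neuron.
#' @return an object of class `"spike_train"` with fields `times` and
#'   `neuron_id`.
#' @seealso [event_series()], [read_spike_times()]
#' @export
spike_train <- function(times, neuron_id = NA_character_) {
  times <- as.numeric(times)
  if (anyNA(times) || any(!is.finite(times))) {
    stop("spike times must be finite and non-missing")
  }
  if (any(times < 0)) {
    stop("spike times must be non-negative")
  }
  if (is.unsorted(times)) {
    warning("spike times were not sorted; sorting")
    times <- sort(times)
  }
  structure(list(times = times, neuron_id = as.character(neuron_id)[1L]),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("Spike train '%s': %d spikes", x$neuron_id, length(x$times)))
  if (length(x$times)) {
    cat(sprintf(" on [%.4g, %.4g] s", min(x$times), max(x$times)))
  }
  cat("\n")
  invisible(x)
}

#' Construct an event series
#'
#' Event (stimulus-onset) times in seconds, strictly increasing, with an
#' optional categorical label per event (e.g. grating direction).
#'
#' @param onsets numeric vector of event times, strictly increasing.
#' @param labels optional per-event labels; stored as character.
#' @return an object of class `"event_series"` with fields `onsets`,
#'   `labels` and `q` (the number of events).
#' @export
event_series <- function(onsets, labels = NULL) {
  onsets <- as.numeric(onsets)
  if (anyNA(onsets) || any(!is.finite(onsets))) {
    stop("event times must be finite and non-missing")
  }
  if (length(onsets) >= 2L && any(diff(onsets) <= 0)) {
    stop("event times must be strictly increasing")
  }
  if (!is.null(labels)) {
    if (length(labels) != length(onsets)) {
      stop("labels must have one entry per event")
    }
    labels <- as.character(labels)
  }
  structure(list(onsets = onsets, labels = labels, q = length(onsets)),
            class = "event_series")
}

#' @export
print.event_series <- function(x, ...) {
  cat(sprintf("Event series: %d events", x$q))
  if (x$q >= 2L) {
    cat(sprintf(", median onset-to-onset %.4g s", default_window(x)))
  }
  if (!is.null(x$labels)) {
    cat(sprintf(", %d label levels", length(unique(x$labels))))
  }
  cat("\n")
  invisible(x)
}

#' Default analysis-window length
#'
#' The default cut-off `tau` for the analysis window after each event is the
#' median onset-to-onset interval of the event series.
#'
#' @param events an [event_series()].
#' @return window duration in seconds.
#' @export
default_window <- function(events) {
  if (events$q < 2L) stop("need at least 2 events to derive a window")
  stats::median(diff(events$onsets))
}

# Resolve a tau argument: NULL means the median onset-to-onset default.
resolve_tau <- function(events, tau) {
  if (is.null(tau)) tau <- default_window(events)
  tau <- as.numeric(tau)[1L]
  if (!is.finite(tau) || tau <= 0) stop("window length tau must be > 0")
  tau
}

# -- file readers ------------------------------------------------------------

# Split the lines of a delimited text file into a character matrix, guessing
# the delimiter (comma, tab, or whitespace) from the first non-empty line.
parse_delim_lines <- function(lines) {
  delim <- if (grepl(",", lines[1L], fixed = TRUE)) "," else
    if (grepl("\t", lines[1L], fixed = TRUE)) "\t" else "[[:space:]]+"
  strsplit(trimws(lines), delim)
}

# as.numeric that reports the offending 1-based file line on failure.
numeric_or_stop <- function(x, line_numbers, path) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) & !(x %in% c("NA", "NaN")))
  if (length(bad)) {
    stop(sprintf("non-numeric value '%s' on line %d of '%s'",
                 x[bad[1L]], line_numbers[bad[1L]], path))
  }
  out
}

#' Read spike times from a text file
#'
#' Accepts either a single column of spike times (one per line, no header) or
#' a delimited table with header columns `neuron_id` and `time` holding
#' several neurons. Times are in seconds. Unsorted times are sorted with a
#' warning; grouping is stable so duplicate times are preserved.
#'
#' @param path path to the file.
#' @return a list of [spike_train()] objects, one per neuron (a single-column
#'   file yields one train with `neuron_id = "1"`).
#' @export
read_spike_times <- function(path) {
  if (!file.exists(path)) stop(sprintf("file '%s' does not exist", path))
  lines <- readLines(path)
  keep <- nzchar(trimws(lines))
  if (!any(keep)) stop(sprintf("file '%s' is empty", path))
  line_numbers <- which(keep)
  fields <- parse_delim_lines(lines[keep])
  ncols <- lengths(fields)
  header <- suppressWarnings(is.na(as.numeric(fields[[1L]][1L])))
  if (header) {
    nm <- tolower(fields[[1L]])
    it <- match("time", nm)
    if (is.na(it)) stop(sprintf("header of '%s' lacks a 'time' column", path))
    ii <- match("neuron_id", nm)
    fields <- fields[-1L]
    line_numbers <- line_numbers[-1L]
    if (any(lengths(fields) < max(it, ii, na.rm = TRUE))) {
      stop(sprintf("ragged rows in '%s'", path))
    }
    times <- numeric_or_stop(vapply(fields, `[[`, "", it), line_numbers, path)
    ids <- if (is.na(ii)) rep("1", length(times)) else
      vapply(fields, `[[`, "", ii)
  } else {
    if (any(ncols > 1L)) {
      # headerless two-column file: (id, time) rows
      times <- numeric_or_stop(vapply(fields, `[[`, "", 2L), line_numbers, path)
      ids <- vapply(fields, `[[`, "", 1L)
    } else {
      times <- numeric_or_stop(unlist(fields), line_numbers, path)
      ids <- rep("1", length(times))
    }
  }
  out <- lapply(split(times, factor(ids, levels = unique(ids))), function(tt) {
    if (is.unsorted(tt)) tt <- sort(tt)
    spike_train(tt)
  })
  for (id in names(out)) out[[id]]$neuron_id <- id
  unname(out)
}

#' Read event times from a text file
#'
#' Expects a delimited table with columns `time` and optionally `label`
#' (header optional if there is a single column). Onsets must be strictly
#' increasing and at least two events are required.
#'
#' @param path path to the file.
#' @return an [event_series()].
#' @export
read_event_times <- function(path) {
  if (!file.exists(path)) stop(sprintf("file '%s' does not exist", path))
  lines <- readLines(path)
  keep <- nzchar(trimws(lines))
  if (!any(keep)) stop(sprintf("file '%s' is empty", path))
  line_numbers <- which(keep)
  fields <- parse_delim_lines(lines[keep])
  header <- suppressWarnings(is.na(as.numeric(fields[[1L]][1L])))
  it <- 1L
  il <- if (lengths(fields)[1L] >= 2L) 2L else NA_integer_
  if (header) {
    nm <- tolower(fields[[1L]])
    it <- match("time", nm)
    if (is.na(it)) stop(sprintf("header of '%s' lacks a 'time' column", path))
    il <- match("label", nm)
    fields <- fields[-1L]
    line_numbers <- line_numbers[-1L]
  }
  times <- numeric_or_stop(vapply(fields, `[[`, "", it), line_numbers, path)
  labels <- if (!is.na(il)) vapply(fields, `[[`, "", il) else NULL
  if (length(times) < 2L) stop("insufficient events: need at least 2")
  if (any(diff(times) <= 0)) {
    stop(sprintf("event times in '%s' are not strictly increasing", path))
  }
  event_series(times, labels)
}

# -- result records ----------------------------------------------------------

#' Construct a result record
#'
#' A uniform container for the outcome of any of the statistical tests in
#' this package: a p-value, the test statistic, and named auxiliary fields
#' (latencies, the ZETA value, bin widths, flags, ...).
#'
#' @param neuron_id neuron identifier.
#' @param test name of the test.
#' @param p p-value in \[0, 1\] (or NA when undefined).
#' @param statistic test statistic (or NA when undefined).
#' @param ... further scalar auxiliary fields, keyed by name.
#' @return an object of class `"result_record"`.
#' @export
result_record <- function(neuron_id, test, p, statistic, ...) {
  if (!is.na(p) && (p < 0 || p > 1)) stop("p must lie in [0, 1]")
  structure(c(list(neuron_id = as.character(neuron_id)[1L],
                   test = as.character(test)[1L],
                   p = as.numeric(p)[1L],
                   statistic = as.numeric(statistic)[1L]),
              list(...)),
            class = "result_record")
}

#' @export
print.result_record <- function(x, ...) {
  cat(sprintf("%s [neuron %s]: p = %.4g, statistic = %.4g\n",
              x$test, x$neuron_id, x$p, x$statistic))
  extra <- setdiff(names(x), c("neuron_id", "test", "p", "statistic"))
  for (nm in extra) {
    val <- x[[nm]]
    if (is.numeric(val) && length(val) == 1L) {
      cat(sprintf("  %s = %.6g\n", nm, val))
    }
  }
  invisible(x)
}

records_to_frame <- function(records) {
  if (inherits(records, "result_record")) records <- list(records)
  if (is.data.frame(records)) return(records)
  if (!length(records)) {
    return(data.frame(neuron_id = character(), test = character(),
                      p = numeric(), statistic = numeric(),
                      stringsAsFactors = FALSE))
  }
  cols <- unique(unlist(lapply(records, names)))
  scalar <- vapply(cols, function(nm) {
    all(vapply(records, function(r)
      is.null(r[[nm]]) || (is.atomic(r[[nm]]) && length(r[[nm]]) == 1L),
      logical(1L)))
  }, logical(1L))
  cols <- cols[scalar]
  out <- lapply(cols, function(nm) {
    vals <- lapply(records, function(r) if (is.null(r[[nm]])) NA else r[[nm]])
    unlist(vals)
  })
  names(out) <- cols
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Write test results to disk
#'
#' Serializes a set of result records to JSON (extension `.json`) or TSV
#' (any other extension). Numeric fields round-trip at full double precision;
#' undefined statistics are stored as `null` (JSON) or `NA` (TSV).
#'
#' @param records a list of [result_record()]s or a data frame.
#' @param path output path; the extension selects the format.
#' @return the output path, invisibly.
#' @seealso [read_results()]
#' @export
write_results <- function(records, path) {
  df <- records_to_frame(records)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(df, path, dataframe = "rows", auto_unbox = FALSE,
                         digits = I(17), na = "null", pretty = TRUE)
  } else {
    out <- df
    for (nm in names(out)) {
      if (is.numeric(out[[nm]])) {
        out[[nm]] <- ifelse(is.na(out[[nm]]), "NA",
                            sprintf("%.17g", out[[nm]]))
      }
    }
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Read back results written by [write_results()]
#'
#' @param path path to a `.json` or `.tsv` results file.
#' @return a data frame with one row per record.
#' @export
read_results <- function(path) {
  if (!file.exists(path)) stop(sprintf("file '%s' does not exist", path))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    df <- jsonlite::fromJSON(path)
    if (!is.data.frame(df)) df <- as.data.frame(df, stringsAsFactors = FALSE)
  } else {
    df <- utils::read.table(path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
    for (nm in setdiff(names(df), c("neuron_id", "test"))) {
      suppressWarnings(num <- as.numeric(df[[nm]]))
      if (!any(is.na(num) & !(df[[nm]] %in% c("NA", NA)))) df[[nm]] <- num
    }
  }
  df
}
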