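# Reading AE hit tables, noise filtering, and window labelling.

#' Read an AE hit table
#'
#' Reads a tab-delimited AE export with one row per hit, a `TIME_S` column
#' (seconds since experiment start) and the 18 standard waveform-parameter
#' columns (`RISE`, `COUN`, `ENER`, `DURATION`, `AMP`, `AFRQ`, `RMS`, `ASL`,
#' `RFRQ`, `IFRQ`, `SIGSTRNGTH`, `ABSENERGY`, `FREQPP1`--`FREQPP4`, `FRQC`,
#' `PFRQ`). Column order in the file is irrelevant; unknown extra columns are
#' dropped with a warning.
#'
#' @param path File path.
#' @param sep Field separator (default tab).
#' @return Data frame with `TIME_S` followed by the 18 parameters in canonical
#'   order, rows in file order.
#' @export
read_ae_table <- function(path, sep = "\t") {
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character")
  needed <- c("TIME_S", AE_PARAMS)
  missing <- setdiff(needed, names(raw))
  if (length(missing))
    stop("format error: missing column(s) ", paste(missing, collapse = ", "),
         call. = FALSE)
  extra <- setdiff(names(raw), needed)
  if (length(extra))
    warning("ignoring unknown column(s): ", paste(extra, collapse = ", "))
  out <- raw[, needed, drop = FALSE]
  for (cn in needed) {
    v <- suppressWarnings(as.numeric(out[[cn]]))
    bad <- which(is.na(v) & !is.na(out[[cn]]) & out[[cn]] != "NA")
    if (length(bad))
      stop("non-numeric value in column ", cn, " at line ", bad[1] + 1L,
           " of ", path, call. = FALSE)
    out[[cn]] <- v
  }
  rownames(out) <- NULL
  out
}

#' Write an AE hit table
#'
#' Tab-delimited, one header row, `TIME_S` plus the 18 waveform parameters.
#'
#' @param signals AE signal data frame (as from [simulate_experiment()]).
#' @param path Destination path.
#' @export
write_ae_table <- function(signals, path) {
  cols <- c("TIME_S", AE_PARAMS)
  stopifnot(all(cols %in% names(signals)))
  utils::write.table(signals[, cols], path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read / write a window schedule table
#'
#' Columns `index`, `start_s`, `end_s`, `kind` and (optionally)
#' `embolism_count`; times in seconds from experiment start.
#'
#' @param path File path.
#' @return Schedule data frame.
#' @export
read_schedule <- function(path) {
  sch <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("index", "start_s", "end_s", "kind")
  missing <- setdiff(need, names(sch))
  if (length(missing))
    stop("format error: missing column(s) ", paste(missing, collapse = ", "),
         call. = FALSE)
  sch
}

#' @rdname read_schedule
#' @param schedule Schedule data frame.
#' @export
write_schedule <- function(schedule, path) {
  utils::write.table(schedule, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Discard sub-noise AE hits
#'
#' Retains signals whose peak amplitude lies strictly above the acquisition
#' noise floor ("above the noise level"), 28 dB by default. Order is
#' preserved; the filter is idempotent.
#'
#' @param signals AE signal data frame with an `AMP` column (dB).
#' @param threshold_db Noise floor in dB.
#' @return The retained rows.
#' @export
filter_noise <- function(signals, threshold_db = 28) {
  stopifnot("AMP" %in% names(signals))
  out <- signals[signals$AMP > threshold_db, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Group AE signals into labelled microCT windows
#'
#' Assigns every signal to the schedule window containing its timestamp, using
#' the half-open convention `[start_s, end_s)` so boundary hits belong to the
#' window that starts there. Each window carries its microCT embolism count -
#' the weak supervision used downstream. Signals falling in schedule gaps (or
#' before/after the schedule) are collected as orphans.
#'
#' @param signals AE signal data frame with `TIME_S`.
#' @param schedule Window schedule (`index`, `start_s`, `end_s`, `kind`),
#'   chronologically ordered and non-overlapping.
#' @param counts Per-window embolism counts; taken from a `embolism_count`
#'   column of `schedule` when omitted.
#' @return Object of class `ae_windows`: list with `windows` (schedule plus
#'   `embolism_count`, `n_signals`), `assignment` (window index per signal,
#'   `NA` for orphans), `orphans` (row indices), `signals` and `features`
#'   (the 6-column matrix from [extract_features()]).
#' @export
link_windows <- function(signals, schedule, counts = NULL) {
  stopifnot(all(c("start_s", "end_s") %in% names(schedule)))
  if (is.unsorted(schedule$start_s, strictly = FALSE) ||
      any(schedule$start_s >= schedule$end_s) ||
      any(utils::head(schedule$end_s, -1) > utils::tail(schedule$start_s, -1) + 1e-9))
    stop("schedule windows must be ordered and non-overlapping", call. = FALSE)
  if (is.null(counts)) {
    if (!"embolism_count" %in% names(schedule))
      stop("no counts given and schedule lacks an embolism_count column",
           call. = FALSE)
    counts <- schedule$embolism_count
  }
  if (length(counts) != nrow(schedule))
    stop("counts length (", length(counts), ") != number of windows (",
         nrow(schedule), ")", call. = FALSE)
  t <- signals$TIME_S
  idx <- findInterval(t, schedule$start_s)
  ## half-open [start, end): t == end falls into the following window
  inside <- idx >= 1L & t < schedule$end_s[pmax(idx, 1L)]
  assignment <- ifelse(inside, idx, NA_integer_)
  windows <- schedule
  windows$embolism_count <- as.integer(counts)
  windows$n_signals <- tabulate(assignment[!is.na(assignment)], nrow(schedule))
  structure(list(windows = windows, assignment = assignment,
                 orphans = which(is.na(assignment)),
                 signals = signals, features = extract_features(signals)),
            class = "ae_windows")
}

#' @export
print.ae_windows <- function(x, ...) {
  w <- x$windows
  cat(sprintf("AE windows: %d windows (%d scan, %d break), %d signals (%d orphans)\n",
              nrow(w), sum(w$kind == "scan"), sum(w$kind == "break"),
              nrow(x$signals), length(x$orphans)))
  cat(sprintf("  microCT events: %d total; windows with events: %d\n",
              sum(w$embolism_count), sum(w$embolism_count > 0)))
  invisible(x)
}

#' Merge consecutive non-event windows
#'
#' Windows in which microCT detected no embolism are fused with their
#' zero-count neighbours into single non-embolism datasets, while every
#' window with at least one event keeps its own identity - the construction
#' that turns a fine scan/break timeline into embolism and non-embolism
#' datasets. Merged windows get kind `"non-embolism"`; gaps between
#' non-adjacent windows are never bridged.
#'
#' @param schedule Schedule data frame with `embolism_count`.
#' @return A re-indexed schedule data frame.
#' @export
merge_nonevent_windows <- function(schedule) {
  stopifnot("embolism_count" %in% names(schedule))
  n <- nrow(schedule)
  if (n == 0L) return(schedule)
  adjacent <- c(FALSE, abs(utils::head(schedule$end_s, -1) -
                             utils::tail(schedule$start_s, -1)) < 1e-9)
  zero <- schedule$embolism_count == 0
  ## new group starts whenever the window has events, follows an event
  ## window, or is not contiguous with its predecessor
  new_group <- !zero | !c(FALSE, zero[-n]) | !adjacent
  grp <- cumsum(new_group)
  out <- do.call(rbind, lapply(split(seq_len(n), grp), function(ii) {
    data.frame(start_s = schedule$start_s[ii[1]],
               end_s = schedule$end_s[ii[length(ii)]],
               kind = if (length(ii) > 1L) "non-embolism"
               else schedule$kind[ii],
               embolism_count = sum(schedule$embolism_count[ii]))
  }))
  out <- data.frame(index = seq_len(nrow(out)), out, row.names = NULL)
  out
}

#' Extract the discriminant feature block
#'
#' Returns the six waveform parameters used for classification, in the fixed
#' order `AMP`, `COUN`, `DURATION`, `SIGSTRNGTH`, `ABSENERGY`, `FREQPP2`.
#'
#' @param signals AE signal data frame (one or more rows).
#' @return Numeric matrix with one row per signal and the six feature columns.
#' @export
extract_features <- function(signals) {
  stopifnot(all(AE_FEATURES %in% names(signals)))
  m <- as.matrix(signals[, AE_FEATURES, drop = FALSE])
  if (anyNA(m) || any(!is.finite(m)))
    stop("non-finite feature values", call. = FALSE)
  m
}
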