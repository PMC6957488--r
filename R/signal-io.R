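CHANNELS <- c("oxy_sat", "V1", "V2", "V3", "temperature")
CONDITIONS <- c("BC", "38", "40", "42", "44")

#' A single-channel recording
#'
#' One subject/condition/channel time series with its sampling rate and time
#' origin. Oxygen-saturation values are percentages and must lie in
#' \[0, 100\]; perfusion channels are in arbitrary perfusion units;
#' the temperature channel is the probe set-point trace in degrees Celsius.
#'
#' @param subject_id subject label.
#' @param group `"TS"` (thermal stimulation) or `"BC"` (blank control).
#' @param condition one of `"BC"`, `"38"`, `"40"`, `"42"`, `"44"`.
#' @param channel one of `"oxy_sat"`, `"V1"`, `"V2"`, `"V3"`, `"temperature"`.
#' @param values numeric vector of samples, all finite.
#' @param sampling_rate_hz sampling rate in Hz (default 3).
#' @param t0_s time of the first sample in seconds (default 0).
#' @return An object of class `signal_record`.
#' @export
signal_record <- function(subject_id, group, condition, channel, values,
                          sampling_rate_hz = 3, t0_s = 0) {
  group <- match.arg(as.character(group), c("TS", "BC"))
  condition <- match.arg(as.character(condition), CONDITIONS)
  channel <- match.arg(as.character(channel), CHANNELS)
  values <- as.numeric(values)
  stopifnot(is.finite(sampling_rate_hz), sampling_rate_hz > 0,
            is.finite(t0_s), length(values) >= 1L)
  if (!all(is.finite(values)))
    stop("non-finite values in record ", subject_id, "/", condition, "/",
         channel)
  if (channel == "oxy_sat" && (min(values) < 0 || max(values) > 100))
    stop("oxy_sat values must lie in [0, 100]")
  structure(list(subject_id = as.character(subject_id), group = group,
                 condition = condition, channel = channel,
                 sampling_rate_hz = sampling_rate_hz, t0_s = t0_s,
                 values = values),
            class = "signal_record")
}

#' @export
print.signal_record <- function(x, ...) {
  cat(sprintf("signal_record %s/%s/%s: %d samples at %g Hz from t = %g s\n",
              x$subject_id, x$condition, x$channel, length(x$values),
              x$sampling_rate_hz, x$t0_s))
  invisible(x)
}

rec_times <- function(rec) {
  rec$t0_s + (seq_along(rec$values) - 1) / rec$sampling_rate_hz
}

rec_key <- function(rec) paste(rec$subject_id, rec$condition, rec$channel,
                               sep = "/")

new_dataset <- function(records) {
  keys <- vapply(records, rec_key, character(1))
  if (anyDuplicated(keys))
    stop("duplicate (subject, condition, channel) records: ",
         paste(unique(keys[duplicated(keys)]), collapse = ", "))
  names(records) <- keys
  structure(records, class = "signal_dataset")
}

#' Look up one record in a dataset
#'
#' @param dataset a `signal_dataset`.
#' @param subject_id,condition,channel record coordinates.
#' @return The matching `signal_record`, or an error if absent.
#' @export
get_record <- function(dataset, subject_id, condition, channel) {
  key <- paste(subject_id, condition, channel, sep = "/")
  rec <- dataset[[key]]
  if (is.null(rec)) stop("no record ", key, " in dataset")
  rec
}

#' Index of a dataset's records
#'
#' @param dataset a `signal_dataset`.
#' @return A data.frame with one row per record: subject_id, group,
#'   condition, channel, n_samples, sampling_rate_hz.
#' @export
dataset_index <- function(dataset) {
  data.frame(
    subject_id = vapply(dataset, `[[`, character(1), "subject_id"),
    group = vapply(dataset, `[[`, character(1), "group"),
    condition = vapply(dataset, `[[`, character(1), "condition"),
    channel = vapply(dataset, `[[`, character(1), "channel"),
    n_samples = vapply(dataset, function(r) length(r$values), integer(1)),
    sampling_rate_hz = vapply(dataset, `[[`, numeric(1), "sampling_rate_hz"),
    row.names = NULL)
}

#' @export
print.signal_dataset <- function(x, ...) {
  idx <- dataset_index(x)
  cat(sprintf("signal_dataset: %d records, %d subjects, conditions: %s\n",
              nrow(idx), length(unique(idx$subject_id)),
              paste(sort(unique(idx$condition)), collapse = ", ")))
  invisible(x)
}

#' Protocol epoch boundaries
#'
#' Half-open, contiguous baseline / stimulation / post windows in seconds
#' from recording start. The default is the 30/30/30-minute protocol.
#'
#' @param baseline,stimulation,post `c(start_s, end_s)` pairs; each window is
#'   half-open `[start, end)` and the three must be contiguous.
#' @return An object of class `epoch_spec`.
#' @export
epoch_spec <- function(baseline = c(0, 1800),
                       stimulation = c(1800, 3600),
                       post = c(3600, 5400)) {
  w <- list(baseline = as.numeric(baseline),
            stimulation = as.numeric(stimulation),
            post = as.numeric(post))
  for (nm in names(w)) {
    if (length(w[[nm]]) != 2L || !all(is.finite(w[[nm]])) ||
        diff(w[[nm]]) <= 0)
      stop("epoch `", nm, "` must be a finite [start, end) of positive length")
  }
  if (w$baseline[2] != w$stimulation[1] || w$stimulation[2] != w$post[1])
    stop("epochs must be contiguous: baseline|stimulation|post")
  structure(w, class = "epoch_spec")
}

#' Extract one protocol epoch from a record
#'
#' Returns the sub-series whose sample times fall in the half-open window
#' `[start, end)` of the requested epoch. For grids aligned to the window the
#' result has exactly `window_s * rate` samples.
#'
#' @param rec a `signal_record`.
#' @param spec an [epoch_spec()].
#' @param which `"baseline"`, `"stimulation"` or `"post"`.
#' @return A `signal_record` restricted to the epoch (with updated `t0_s`).
#' @export
extract_epoch <- function(rec, spec, which = c("baseline", "stimulation",
                                               "post")) {
  which <- match.arg(which)
  stopifnot(inherits(rec, "signal_record"), inherits(spec, "epoch_spec"))
  win <- spec[[which]]
  times <- rec_times(rec)
  span <- c(times[1L], times[length(times)] + 1 / rec$sampling_rate_hz)
  if (win[1] < span[1] || win[2] > span[2])
    stop("epoch window [", win[1], ", ", win[2], ") outside recording span [",
         span[1], ", ", span[2], ")")
  sel <- times >= win[1] & times < win[2]
  if (!any(sel)) stop("epoch window contains no samples")
  out <- rec
  out$values <- rec$values[sel]
  out$t0_s <- times[sel][1L]
  out
}

# Concatenate one or more (contiguous, in protocol order) epoch extracts.
extract_epochs <- function(rec, spec, which) {
  segs <- lapply(which, function(w) extract_epoch(rec, spec, w))
  out <- segs[[1L]]
  if (length(segs) > 1L)
    out$values <- unlist(lapply(segs, `[[`, "values"), use.names = FALSE)
  out
}

#' Minute-averaged time course
#'
#' For each grid time point t (every `grid_step_s` seconds from the start of
#' the record) return the mean of the samples in the half-open one-minute
#' window `[t - 30, t + 30)`. Grid points whose window is not fully covered
#' by the recording are dropped, so at 3 Hz every reported mean uses exactly
#' 180 samples.
#'
#' @param rec a `signal_record` spanning at least 60 s.
#' @param grid_step_s spacing of the output grid in seconds (default 60).
#' @return A data.frame with columns `time_s` and `mean`.
#' @export
minute_average <- function(rec, grid_step_s = 60) {
  stopifnot(inherits(rec, "signal_record"),
            is.finite(grid_step_s), grid_step_s > 0)
  times <- rec_times(rec)
  n <- length(rec$values)
  dur <- n / rec$sampling_rate_hz
  if (dur < 60) stop("record shorter than one 60-s averaging window")
  t_end <- rec$t0_s + dur          # end of coverage (half-open)
  grid <- rec$t0_s + grid_step_s * seq(0, floor(dur / grid_step_s))
  grid <- grid[grid - 30 >= rec$t0_s & grid + 30 <= t_end]
  means <- vapply(grid, function(t0) {
    mean(rec$values[times >= t0 - 30 & times < t0 + 30])
  }, numeric(1))
  data.frame(time_s = grid, mean = means)
}

#' Read a long-format recordings CSV
#'
#' The canonical format is a UTF-8 CSV with header columns `subject_id`,
#' `group`, `condition`, `channel`, `time_s`, `value`, rows per channel in
#' nondecreasing time. The sampling rate is inferred from the median time
#' step; gaps larger than 1.5 times that step are rejected. In non-strict
#' mode a subject whose rows fail validation is skipped with a warning (all
#' its records are dropped); in strict mode any invalid row aborts the read.
#'
#' @param path path to the CSV file.
#' @param strict abort on the first invalid subject instead of skipping it.
#' @return A `signal_dataset`.
#' @export
read_dataset <- function(path, strict = FALSE) {
  dt <- data.table::fread(path, colClasses = list(
    character = c("subject_id", "group", "condition", "channel")))
  required <- c("subject_id", "group", "condition", "channel", "time_s",
                "value")
  missing_cols <- setdiff(required, names(dt))
  if (length(missing_cols))
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  if (!is.numeric(dt$time_s) || !is.numeric(dt$value))
    stop("columns time_s and value must be numeric")
  dt$..row <- seq_len(nrow(dt))

  parse_subject <- function(sub) {
    sdt <- dt[dt$subject_id == sub, ]
    recs <- list()
    for (grp in split(sdt, paste(sdt$condition, sdt$channel, sep = "/"))) {
      tms <- grp$time_s
      if (is.unsorted(tms, strictly = TRUE)) {
        bad <- grp$..row[which(diff(tms) <= 0)[1L] + 1L]
        stop("time not strictly increasing at row ", bad,
             " (subject ", sub, ")")
      }
      if (!all(is.finite(grp$value))) {
        bad <- grp$..row[which(!is.finite(grp$value))[1L]]
        stop("non-finite value at row ", bad, " (subject ", sub, ")")
      }
      steps <- diff(tms)
      med <- median(steps)
      if (length(steps) && any(steps > 1.5 * med)) {
        bad <- grp$..row[which(steps > 1.5 * med)[1L] + 1L]
        stop("time gap exceeding 1.5x the median step at row ", bad,
             " (subject ", sub, ")")
      }
      recs[[length(recs) + 1L]] <- signal_record(
        subject_id = sub, group = grp$group[1L],
        condition = grp$condition[1L], channel = grp$channel[1L],
        values = grp$value, sampling_rate_hz = 1 / med, t0_s = tms[1L])
    }
    recs
  }

  records <- list()
  for (sub in unique(dt$subject_id)) {
    if (strict) {
      records <- c(records, parse_subject(sub))
    } else {
      recs <- tryCatch(parse_subject(sub), error = function(e) {
        warning("skipping subject ", sub, ": ", conditionMessage(e),
                call. = FALSE)
        NULL
      })
      records <- c(records, recs)
    }
  }
  if (!length(records)) stop("no valid records in ", path)
  new_dataset(records)
}

#' Write a dataset to the canonical long CSV
#'
#' Numeric columns are rendered with `%.17g`, which guarantees that doubles
#' survive a write/read cycle bit-for-bit.
#'
#' @param dataset a `signal_dataset`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "signal_dataset"))
  tabs <- lapply(dataset, function(rec) {
    data.table::data.table(
      subject_id = rec$subject_id, group = rec$group,
      condition = rec$condition, channel = rec$channel,
      time_s = sprintf("%.17g", rec_times(rec)),
      value = sprintf("%.17g", rec$values))
  })
  data.table::fwrite(data.table::rbindlist(tabs), path, quote = FALSE)
  invisible(path)
}
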