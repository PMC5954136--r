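# Canonical long-format event schema shared by readers, writers and the
# generator. All times are seconds relative to the cue onset of the trial
# the event belongs to; inter-trial events (foot-shocks) carry negative
# times on the following trial.
.EVENT_COLUMNS <- c("subject_id", "session_index", "trial_index",
                    "trial_type", "cue_duration_s", "event_type", "t_s")

.TRIAL_TYPES <- c("bisection_forced", "bisection_free", "bisection_test",
                  "fi", "probe")

.EVENT_TYPES <- c("cue_on", "cue_off", "press_short_lever",
                  "press_long_lever", "press", "reinforcer", "shock")

.PRESS_EVENTS <- c("press_short_lever", "press_long_lever", "press")

#' Construct a trial table
#'
#' A trial table is the package's canonical in-memory representation of an
#' operant session: one row per trial, with press times held in a list
#' column. It is an ordinary `data.frame` with class `"trial_table"` so
#' all the usual subsetting idioms work.
#'
#' @param subject_id character subject identifiers.
#' @param session_index,trial_index positive integers.
#' @param trial_type one of `"bisection_forced"`, `"bisection_free"`,
#'   `"bisection_test"`, `"fi"`, `"probe"`.
#' @param cue_duration_s planned stimulus duration in seconds (for probe
#'   trials, the probe length).
#' @param press_times list of numeric vectors, press times in seconds from
#'   cue onset, nondecreasing within a trial.
#' @param chosen_lever `"short"`, `"long"` or `"none"` (bisection trials;
#'   `NA` for peak-interval trials).
#' @param response_latency_s seconds from lever presentation (cue offset)
#'   to the first press; `NA` when no response.
#' @param reinforced logical; probe trials are never reinforced.
#' @param shock_times list of numeric vectors of inter-trial shock times
#'   (negative, relative to this trial's cue onset).
#' @return A `trial_table` data frame.
#' @export
trial_table <- function(subject_id, session_index, trial_index, trial_type,
                        cue_duration_s, press_times,
                        chosen_lever = NA_character_,
                        response_latency_s = NA_real_,
                        reinforced = FALSE,
                        shock_times = NULL) {
  n <- length(trial_index)
  if (is.null(shock_times)) shock_times <- rep(list(numeric(0)), n)
  stopifnot(length(press_times) == n)
  df <- data.frame(
    subject_id = rep_len(as.character(subject_id), n),
    session_index = rep_len(as.integer(session_index), n),
    trial_index = as.integer(trial_index),
    trial_type = rep_len(as.character(trial_type), n),
    cue_duration_s = rep_len(as.numeric(cue_duration_s), n),
    chosen_lever = rep_len(as.character(chosen_lever), n),
    response_latency_s = rep_len(as.numeric(response_latency_s), n),
    reinforced = rep_len(as.logical(reinforced), n),
    stringsAsFactors = FALSE
  )
  df$press_times <- lapply(press_times, as.numeric)
  df$shock_times <- lapply(shock_times, as.numeric)
  bad <- setdiff(unique(df$trial_type), .TRIAL_TYPES)
  if (length(bad) > 0)
    stop("unknown trial_type: ", paste(bad, collapse = ", "))
  class(df) <- c("trial_table", "data.frame")
  df
}

#' @export
print.trial_table <- function(x, ...) {
  cat("Trial table:", nrow(x), "trials,",
      length(unique(x$subject_id)), "subject(s),",
      length(unique(paste(x$subject_id, x$session_index))), "session(s)\n")
  tt <- table(x$trial_type)
  cat("  trial types:",
      paste(sprintf("%s=%d", names(tt), as.integer(tt)), collapse = ", "),
      "\n")
  invisible(x)
}

#' Read an operant event log
#'
#' Parses a long-format CSV event log (one row per time-stamped event) into
#' a [trial_table()]. Choice, latency and reinforcement are derived from
#' the event stream: the chosen lever is the lever of the first press, the
#' response latency is measured from cue offset to the first press, and a
#' trial is reinforced when it contains a `reinforcer` event.
#'
#' Malformed rows (unknown event or trial type, unparsable time) are
#' dropped and collected into the `diagnostics` attribute rather than
#' aborting the whole read; structural violations (missing columns,
#' non-monotone event times within a trial) are errors.
#'
#' @param path path to a CSV file with columns
#'   `subject_id, session_index, trial_index, trial_type, cue_duration_s,
#'   event_type, t_s`.
#' @return A `trial_table` with a `diagnostics` attribute (data frame of
#'   dropped rows and the reason, zero rows for a clean file).
#' @seealso [write_events()], [validate_session()]
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ev <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(t_s = "character")[0])
  missing_cols <- setdiff(.EVENT_COLUMNS, names(ev))
  if (length(missing_cols) > 0)
    stop("event log is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  diagnostics <- data.frame(row = integer(0), reason = character(0),
                            stringsAsFactors = FALSE)
  if (nrow(ev) > 0) {
    ev$t_s <- suppressWarnings(as.numeric(ev$t_s))
    bad <- which(is.na(ev$t_s) | !(ev$event_type %in% .EVENT_TYPES) |
                   !(ev$trial_type %in% .TRIAL_TYPES))
    if (length(bad) > 0) {
      reason <- ifelse(is.na(ev$t_s[bad]), "unparsable t_s",
                       ifelse(!(ev$event_type[bad] %in% .EVENT_TYPES),
                              "unknown event_type", "unknown trial_type"))
      diagnostics <- data.frame(row = bad, reason = reason,
                                stringsAsFactors = FALSE)
      ev <- ev[-bad, , drop = FALSE]
    }
  }
  if (nrow(ev) == 0) {
    out <- trial_table(character(0), integer(0), integer(0), character(0),
                       numeric(0), list())
    attr(out, "diagnostics") <- diagnostics
    return(out)
  }
  key <- paste(ev$subject_id, ev$session_index, ev$trial_index, sep = "\r")
  # preserve file order of trials
  groups <- split(seq_len(nrow(ev)), factor(key, levels = unique(key)))
  rows <- lapply(groups, function(idx) {
    tr <- ev[idx, , drop = FALSE]
    ts_main <- tr$t_s[tr$event_type != "shock"]
    if (is.unsorted(ts_main))
      stop("non-monotone event times within trial ", tr$trial_index[1],
           " (subject ", tr$subject_id[1], ", session ",
           tr$session_index[1], ")")
    presses <- tr$t_s[tr$event_type %in% .PRESS_EVENTS]
    press_ev <- tr$event_type[tr$event_type %in% .PRESS_EVENTS]
    lever <- NA_character_
    if (tr$trial_type[1] %in% c("bisection_forced", "bisection_free",
                                "bisection_test")) {
      lever <- if (length(presses) == 0) "none"
               else if (press_ev[1] == "press_short_lever") "short"
               else "long"
    }
    latency <- if (length(presses) > 0 &&
                   startsWith(tr$trial_type[1], "bisection"))
      presses[1] - tr$cue_duration_s[1] else NA_real_
    list(subject_id = tr$subject_id[1],
         session_index = tr$session_index[1],
         trial_index = tr$trial_index[1],
         trial_type = tr$trial_type[1],
         cue_duration_s = tr$cue_duration_s[1],
         press_times = presses,
         chosen_lever = lever,
         response_latency_s = latency,
         reinforced = any(tr$event_type == "reinforcer"),
         shock_times = tr$t_s[tr$event_type == "shock"])
  })
  out <- trial_table(
    subject_id = vapply(rows, `[[`, character(1), "subject_id"),
    session_index = vapply(rows, `[[`, numeric(1), "session_index"),
    trial_index = vapply(rows, `[[`, numeric(1), "trial_index"),
    trial_type = vapply(rows, `[[`, character(1), "trial_type"),
    cue_duration_s = vapply(rows, `[[`, numeric(1), "cue_duration_s"),
    press_times = lapply(rows, `[[`, "press_times"),
    chosen_lever = vapply(rows, `[[`, character(1), "chosen_lever"),
    response_latency_s = vapply(rows, `[[`, numeric(1),
                                "response_latency_s"),
    reinforced = vapply(rows, `[[`, logical(1), "reinforced"),
    shock_times = lapply(rows, `[[`, "shock_times")
  )
  attr(out, "diagnostics") <- diagnostics
  out
}

#' Write an operant event log
#'
#' Serializes a [trial_table()] to the long-format CSV schema read by
#' [read_events()]. Each trial emits a `cue_on` row at t = 0, one row per
#' press (typed by lever for bisection trials), a `reinforcer` row at the
#' reinforcing press when applicable, a `cue_off` row, and `shock` rows
#' for any inter-trial shocks. `read_events(write_events(x))` reproduces
#' `x` field by field.
#'
#' @param trials a `trial_table`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_events <- function(trials, path) {
  stopifnot(inherits(trials, "trial_table"))
  chunks <- vector("list", nrow(trials))
  for (i in seq_len(nrow(trials))) {
    tr <- trials[i, ]
    presses <- trials$press_times[[i]]
    shocks <- trials$shock_times[[i]]
    press_type <- if (startsWith(tr$trial_type, "bisection")) {
      if (identical(tr$chosen_lever, "short")) "press_short_lever"
      else "press_long_lever"
    } else "press"
    ev_t <- c(0, presses)
    ev_e <- c("cue_on", rep(press_type, length(presses)))
    if (isTRUE(tr$reinforced) && length(presses) > 0) {
      # reinforcement is delivered at the reinforcing press: the first
      # press for bisection, the first press at/after the FI for FI trials
      t_r <- if (tr$trial_type == "fi") {
        cand <- presses[presses >= 30][1]
        if (is.na(cand)) presses[length(presses)] else cand
      } else presses[1]
      ev_t <- c(ev_t, t_r)
      ev_e <- c(ev_e, "reinforcer")
    }
    ev_t <- c(ev_t, tr$cue_duration_s)
    ev_e <- c(ev_e, "cue_off")
    ord <- order(ev_t, match(ev_e, .EVENT_TYPES))
    ev_t <- c(shocks, ev_t[ord])
    ev_e <- c(rep("shock", length(shocks)), ev_e[ord])
    chunks[[i]] <- data.frame(
      subject_id = tr$subject_id, session_index = tr$session_index,
      trial_index = tr$trial_index, trial_type = tr$trial_type,
      cue_duration_s = tr$cue_duration_s,
      event_type = ev_e, t_s = ev_t, stringsAsFactors = FALSE)
  }
  ev <- if (length(chunks) > 0) do.call(rbind, chunks)
  else stats::setNames(
    data.frame(character(0), integer(0), integer(0), character(0),
               numeric(0), character(0), numeric(0)), .EVENT_COLUMNS)
  utils::write.csv(ev, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Bin a trial's presses into fixed-width time bins
#'
#' Bins are half-open, zero-based from cue onset: bin k covers
#' `[k*w, (k+1)*w)`. Presses at `t < 0` or `t >= window_s` are excluded,
#' so the counts always sum to the number of in-window presses.
#'
#' @param trial a single-row `trial_table`, or a numeric vector of press
#'   times in seconds from cue onset.
#' @param bin_width_s positive bin width in seconds.
#' @param window_s analysis window in seconds (`>= bin_width_s`).
#' @return A `binned_trial` object: list with `counts` (length
#'   `ceiling(window_s / bin_width_s)`), `bin_width_s`, `window_s`.
#' @export
bin_trial <- function(trial, bin_width_s = 1, window_s = 90) {
  if (!is.numeric(bin_width_s) || bin_width_s <= 0)
    stop("bin_width_s must be a positive number of seconds")
  if (window_s < bin_width_s)
    stop("window_s must be at least one bin wide")
  t <- if (is.numeric(trial)) trial
  else if (inherits(trial, "trial_table")) {
    if (nrow(trial) != 1) stop("bin_trial() expects a single trial")
    trial$press_times[[1]]
  } else stop("trial must be press times or a single-row trial_table")
  n_bins <- ceiling(window_s / bin_width_s)
  t <- t[t >= 0 & t < window_s]
  counts <- tabulate(floor(t / bin_width_s) + 1L, nbins = n_bins)
  structure(list(counts = counts, bin_width_s = bin_width_s,
                 window_s = window_s),
            class = "binned_trial")
}

#' @export
print.binned_trial <- function(x, ...) {
  cat("Binned trial:", length(x$counts), "bins of", x$bin_width_s,
      "s,", sum(x$counts), "presses\n")
  invisible(x)
}

#' Bin every trial of a table into a trial-by-bin count matrix
#'
#' @inheritParams bin_trial
#' @param trials a `trial_table`.
#' @return Integer matrix, one row per trial, one column per bin.
#' @export
bin_trials <- function(trials, bin_width_s = 1, window_s = 90) {
  stopifnot(inherits(trials, "trial_table"))
  n_bins <- ceiling(window_s / bin_width_s)
  m <- t(vapply(trials$press_times, function(p)
    bin_trial(p, bin_width_s, window_s)$counts, integer(n_bins)))
  rownames(m) <- paste(trials$subject_id, trials$session_index,
                       trials$trial_index, sep = ".")
  m
}

#' Write a binned-count matrix with trial identifiers
#'
#' One row per trial, identifier columns followed by one column per bin.
#'
#' @inheritParams bin_trials
#' @param path output CSV path.
#' @export
write_binned_matrix <- function(trials, path, bin_width_s = 1,
                                window_s = 90) {
  m <- bin_trials(trials, bin_width_s, window_s)
  colnames(m) <- sprintf("bin_%03d", seq_len(ncol(m)) - 1L)
  out <- cbind(trials[, c("subject_id", "session_index", "trial_index",
                          "trial_type")],
               as.data.frame(m, row.names = FALSE))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Validate the internal consistency of a session's trials
#'
#' A diagnostic pass over a trial table: flags duplicated trial indices
#' within a subject-session, probe trials whose cue duration differs from
#' the probe window, reinforced probe trials, bisection trials whose
#' recorded choice disagrees with their press record, and negative cue
#' durations. A clean simulated session produces an empty report.
#'
#' @param trials a `trial_table`.
#' @param probe_window_s expected probe-trial duration (seconds).
#' @return Data frame with columns `severity` (`"error"`/`"warning"`),
#'   `subject_id`, `session_index`, `trial_index`, `message`; zero rows
#'   when nothing is wrong.
#' @export
validate_session <- function(trials, probe_window_s = 90) {
  stopifnot(inherits(trials, "trial_table"))
  findings <- list()
  note <- function(severity, tr, msg) {
    findings[[length(findings) + 1L]] <<- data.frame(
      severity = severity, subject_id = tr$subject_id,
      session_index = tr$session_index, trial_index = tr$trial_index,
      message = msg, stringsAsFactors = FALSE)
  }
  key <- paste(trials$subject_id, trials$session_index)
  for (k in unique(key)) {
    idx <- trials$trial_index[key == k]
    dup <- unique(idx[duplicated(idx)])
    for (d in dup)
      note("error", trials[key == k & trials$trial_index == d, ][1, ],
           "duplicated trial_index within session")
  }
  for (i in seq_len(nrow(trials))) {
    tr <- trials[i, ]
    if (tr$cue_duration_s < 0)
      note("error", tr, "negative cue duration")
    if (tr$trial_type == "probe") {
      if (tr$cue_duration_s != probe_window_s)
        note("warning", tr, sprintf(
          "probe trial with cue_duration_s %g (expected %g)",
          tr$cue_duration_s, probe_window_s))
      if (isTRUE(tr$reinforced))
        note("error", tr, "probe trial marked reinforced")
    }
    if (startsWith(tr$trial_type, "bisection")) {
      has_press <- length(trials$press_times[[i]]) > 0
      if (identical(tr$chosen_lever, "none") == has_press)
        note("error", tr,
             "chosen_lever inconsistent with press record")
    }
  }
  if (length(findings) == 0)
    data.frame(severity = character(0), subject_id = character(0),
               session_index = integer(0), trial_index = integer(0),
               message = character(0), stringsAsFactors = FALSE)
  else do.call(rbind, findings)
}

#' Vendor event-log converter (stub)
#'
#' Native operant-chamber formats (e.g. Graphic State exports) are not
#' parsed by this package. Convert vendor logs to the long-format CSV
#' schema documented in [read_events()] — one row per event with
#' columns `subject_id, session_index, trial_index, trial_type,
#' cue_duration_s, event_type, t_s` and times in seconds relative to
#' each trial's cue onset — with your lab's export tooling, then load
#' them with [read_events()].
#'
#' @param path vendor file path.
#' @return Never returns; raises an informative error.
#' @export
read_vendor_events <- function(path) {
  stop("native vendor formats are not supported; export to the ",
       "long-format CSV schema described in ?read_events")
}
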