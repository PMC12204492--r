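#' Session bundle: one animal-session of imaging data
#'
#' A `session_bundle` collects everything recorded in one active-avoidance
#' session for one animal: a fluorescence trace matrix (neurons x frames),
#' an optional neuropil matrix of the same shape, the trial event table,
#' an optional behavior track, per-neuron metadata, and an optional
#' dropped-frame mask.
#'
#' Timestamps are seconds from session start; frame indices are 1-based in R
#' but all windows are half-open `[start, end)` in seconds.
#'
#' @param traces numeric matrix, neurons x frames (arbitrary fluorescence
#'   units, or z-like units for synthetic sessions).
#' @param frame_rate_hz positive scalar; acquisition rate (5, 20 or 30 Hz).
#' @param events `event_table` (see [event_table()]).
#' @param neuropil optional matrix, same shape as `traces`.
#' @param behavior optional `behavior_track` (see [behavior_track()]).
#' @param neurons optional data.frame of per-neuron records with columns
#'   `neuron_id`, `ap_mm`, `ml_mm`, `dv_mm` and optional `subtype`.
#' @param animal_id,session_id identifier strings.
#' @param dropped_frame_mask optional logical vector of length `ncol(traces)`.
#' @return an object of class `session_bundle`.
#' @export
session_bundle <- function(traces, frame_rate_hz, events,
                           neuropil = NULL, behavior = NULL, neurons = NULL,
                           animal_id = "a1", session_id = "s1",
                           dropped_frame_mask = NULL) {
  traces <- as.matrix(traces)
  if (!is.numeric(traces)) stop("traces must be a numeric matrix")
  if (!is.numeric(frame_rate_hz) || length(frame_rate_hz) != 1L ||
      frame_rate_hz <= 0) {
    stop("frame_rate_hz must be a positive scalar")
  }
  if (!is.null(neuropil)) {
    neuropil <- as.matrix(neuropil)
    if (!identical(dim(neuropil), dim(traces))) {
      stop("neuropil: shape mismatch with traces")
    }
  }
  events <- validate_event_table(events)
  dur <- ncol(traces) / frame_rate_hz
  ev_times <- c(events$cs_onset_s, events$cs_offset_s,
                events$shock_onset_s, events$avrun_onset_s)
  ev_times <- ev_times[is.finite(ev_times)]
  if (length(ev_times) && (min(ev_times) < 0 || max(ev_times) > dur)) {
    stop("events: timestamps outside [0, frames/frame_rate] = [0, ",
         signif(dur, 6), "]")
  }
  if (is.null(neurons)) {
    neurons <- data.frame(neuron_id = sprintf("n%03d", seq_len(nrow(traces))),
                          ap_mm = NA_real_, ml_mm = NA_real_, dv_mm = NA_real_,
                          subtype = "none", stringsAsFactors = FALSE)
  }
  neurons <- validate_neuron_table(neurons, n = nrow(traces))
  if (!is.null(dropped_frame_mask)) {
    dropped_frame_mask <- as.logical(dropped_frame_mask)
    if (length(dropped_frame_mask) != ncol(traces)) {
      stop("dropped_frame_mask: length mismatch with frames")
    }
  }
  if (!is.null(behavior)) behavior <- validate_behavior_track(behavior)
  structure(list(traces = traces, neuropil = neuropil,
                 frame_rate_hz = frame_rate_hz, events = events,
                 behavior = behavior, neurons = neurons,
                 animal_id = as.character(animal_id),
                 session_id = as.character(session_id),
                 dropped_frame_mask = dropped_frame_mask,
                 z = NULL),
            class = "session_bundle")
}

#' @export
print.session_bundle <- function(x, ...) {
  cat("<session_bundle> ", x$animal_id, "/", x$session_id, ": ",
      nrow(x$traces), " neurons x ", ncol(x$traces), " frames @ ",
      x$frame_rate_hz, " Hz, ", nrow(x$events), " trials\n", sep = "")
  invisible(x)
}

#' Trial event table for a signaled active-avoidance session
#'
#' One row per trial. The conditioned stimulus (CS) is a 10-s tone; an
#' avoidance run within the tone terminates it (success), otherwise the
#' foot-shock is delivered at tone offset (failure).
#'
#' @param trial_index integer trial numbers.
#' @param cs_onset_s,cs_offset_s CS onset/offset, seconds from session start.
#' @param outcome character, "success" or "failure" per trial.
#' @param shock_onset_s shock onset (s); required (finite) on failure trials.
#' @param avrun_onset_s avoidance-run onset (s); `NA` when no run occurred.
#' @param cs_max_s maximum CS duration used to check the success invariant.
#' @return data.frame of class `event_table`.
#' @export
event_table <- function(trial_index, cs_onset_s, cs_offset_s, outcome,
                        shock_onset_s = NA_real_, avrun_onset_s = NA_real_,
                        cs_max_s = 10) {
  df <- data.frame(trial_index = as.integer(trial_index),
                   cs_onset_s = as.numeric(cs_onset_s),
                   cs_offset_s = as.numeric(cs_offset_s),
                   outcome = as.character(outcome),
                   shock_onset_s = as.numeric(shock_onset_s),
                   avrun_onset_s = as.numeric(avrun_onset_s),
                   stringsAsFactors = FALSE)
  attr(df, "cs_max_s") <- cs_max_s
  class(df) <- c("event_table", "data.frame")
  validate_event_table(df)
}

validate_event_table <- function(events) {
  if (!is.data.frame(events)) stop("events must be a data.frame event_table")
  need <- c("trial_index", "cs_onset_s", "cs_offset_s", "outcome")
  miss <- setdiff(need, names(events))
  if (length(miss)) stop("event table missing columns: ",
                         paste(miss, collapse = ", "))
  if (!"shock_onset_s" %in% names(events)) events$shock_onset_s <- NA_real_
  if (!"avrun_onset_s" %in% names(events)) events$avrun_onset_s <- NA_real_
  if (!all(events$outcome %in% c("success", "failure"))) {
    stop("outcome must be 'success' or 'failure'")
  }
  if (any(events$cs_offset_s <= events$cs_onset_s)) {
    stop("cs_offset_s must exceed cs_onset_s on every trial")
  }
  fail <- events$outcome == "failure"
  if (any(fail & !is.finite(events$shock_onset_s))) {
    stop("failure trials must carry shock_onset_s")
  }
  cs_max <- attr(events, "cs_max_s")
  if (is.null(cs_max)) cs_max <- 10
  succ <- events$outcome == "success"
  # success runs terminate the tone, so the CS cannot outlast its ceiling
  if (any(succ & (events$cs_offset_s - events$cs_onset_s) > cs_max + 1e-9)) {
    stop("success trials must have cs duration <= ", cs_max, " s")
  }
  if (!inherits(events, "event_table")) {
    class(events) <- c("event_table", "data.frame")
  }
  events
}

validate_neuron_table <- function(neurons, n) {
  subtypes <- c("Glp1r", "Chat", "Lhx2", "Met", "Tshz2", "Foxp2", "Calcr",
                "none")
  if (!is.data.frame(neurons)) stop("neurons must be a data.frame")
  if (nrow(neurons) != n) stop("neurons: row count differs from trace rows")
  if (!"neuron_id" %in% names(neurons)) {
    neurons$neuron_id <- sprintf("n%03d", seq_len(n))
  }
  for (cc in c("ap_mm", "ml_mm", "dv_mm")) {
    if (!cc %in% names(neurons)) neurons[[cc]] <- NA_real_
  }
  if (!"subtype" %in% names(neurons)) neurons$subtype <- "none"
  if (!all(neurons$subtype %in% subtypes)) {
    stop("subtype must be one of: ", paste(subtypes, collapse = ", "))
  }
  neurons
}

#' Behavior track (tracked body point at 30 Hz)
#'
#' @param xy numeric matrix, frames x 2, coordinates in cm.
#' @param frame_rate_hz sampling rate (default 30 Hz, the video rate).
#' @param bodypoint which tracked point the coordinates refer to.
#' @return object of class `behavior_track`.
#' @export
behavior_track <- function(xy, frame_rate_hz = 30, bodypoint = "center") {
  xy <- as.matrix(xy)
  validate_behavior_track(structure(list(xy = xy,
                                         frame_rate_hz = frame_rate_hz,
                                         bodypoint = bodypoint),
                                    class = "behavior_track"))
}

validate_behavior_track <- function(bt) {
  if (!inherits(bt, "behavior_track")) stop("not a behavior_track")
  if (ncol(bt$xy) != 2L) stop("behavior xy must have two columns")
  if (!all(is.finite(bt$xy))) stop("behavior coordinates must be finite")
  if (bt$frame_rate_hz <= 0) stop("behavior frame rate must be positive")
  bt
}

# lossless CSV: doubles serialized with 17 significant digits, which
# round-trips IEEE doubles exactly through text
fwrite_precise <- function(df, path) {
  df <- as.data.frame(df)
  for (cc in names(df)) {
    if (is.double(df[[cc]])) {
      v <- sprintf("%.17g", df[[cc]])
      v[is.na(df[[cc]])] <- NA_character_
      df[[cc]] <- v
    }
  }
  data.table::fwrite(df, path)
}

#' Write a session bundle to a directory of plain-text tables
#'
#' Matrices and tables go to CSV with doubles serialized at 17
#' significant digits (bit-exact on re-read); scalars go to a YAML
#' header. The inverse is [read_session_bundle()].
#'
#' @param bundle a `session_bundle`.
#' @param path directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
write_session_bundle <- function(bundle, path) {
  stopifnot(inherits(bundle, "session_bundle"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  hdr <- list(animal_id = bundle$animal_id, session_id = bundle$session_id,
              frame_rate_hz = bundle$frame_rate_hz,
              n_neurons = nrow(bundle$traces), n_frames = ncol(bundle$traces),
              has_neuropil = !is.null(bundle$neuropil),
              has_behavior = !is.null(bundle$behavior),
              has_dropped_mask = !is.null(bundle$dropped_frame_mask),
              behavior_frame_rate_hz =
                if (!is.null(bundle$behavior)) bundle$behavior$frame_rate_hz,
              behavior_bodypoint =
                if (!is.null(bundle$behavior)) bundle$behavior$bodypoint)
  hdr$cs_max_s <- attr(bundle$events, "cs_max_s") %||% 10
  yaml::write_yaml(hdr, file.path(path, "session.yaml"))
  fwrite_precise(as.data.frame(bundle$traces), file.path(path, "traces.csv"))
  if (!is.null(bundle$neuropil)) {
    fwrite_precise(as.data.frame(bundle$neuropil),
                   file.path(path, "neuropil.csv"))
  }
  fwrite_precise(as.data.frame(bundle$events), file.path(path, "events.csv"))
  fwrite_precise(bundle$neurons, file.path(path, "neurons.csv"))
  if (!is.null(bundle$behavior)) {
    fwrite_precise(as.data.frame(bundle$behavior$xy),
                   file.path(path, "behavior.csv"))
  }
  if (!is.null(bundle$dropped_frame_mask)) {
    data.table::fwrite(data.frame(dropped = bundle$dropped_frame_mask),
                       file.path(path, "dropped_frames.csv"))
  }
  invisible(path)
}

#' Read a session bundle written by [write_session_bundle()]
#'
#' @param path bundle directory.
#' @return a validated `session_bundle`.
#' @export
read_session_bundle <- function(path) {
  if (!dir.exists(path)) stop("no such bundle directory: ", path)
  hfile <- file.path(path, "session.yaml")
  tfile <- file.path(path, "traces.csv")
  efile <- file.path(path, "events.csv")
  if (!file.exists(tfile)) stop("format error: traces.csv missing in ", path)
  if (!file.exists(efile)) stop("format error: events.csv missing in ", path)
  hdr <- if (file.exists(hfile)) yaml::read_yaml(hfile) else list()
  traces <- as.matrix(data.table::fread(tfile))
  dimnames(traces) <- NULL
  events <- as.data.frame(data.table::fread(efile))
  attr(events, "cs_max_s") <- hdr$cs_max_s %||% 10
  neuropil <- NULL
  if (file.exists(file.path(path, "neuropil.csv"))) {
    neuropil <- as.matrix(data.table::fread(file.path(path, "neuropil.csv")))
    dimnames(neuropil) <- NULL
  }
  neurons <- NULL
  if (file.exists(file.path(path, "neurons.csv"))) {
    neurons <- as.data.frame(data.table::fread(file.path(path, "neurons.csv")))
  }
  behavior <- NULL
  if (file.exists(file.path(path, "behavior.csv"))) {
    xy <- as.matrix(data.table::fread(file.path(path, "behavior.csv")))
    dimnames(xy) <- NULL
    behavior <- behavior_track(
      xy,
      frame_rate_hz = hdr$behavior_frame_rate_hz %||% 30,
      bodypoint = hdr$behavior_bodypoint %||% "center")
  }
  mask <- NULL
  if (file.exists(file.path(path, "dropped_frames.csv"))) {
    mask <- data.table::fread(file.path(path, "dropped_frames.csv"))$dropped
  }
  session_bundle(traces, frame_rate_hz = hdr$frame_rate_hz %||% 5,
                 events = events, neuropil = neuropil, behavior = behavior,
                 neurons = neurons,
                 animal_id = hdr$animal_id %||% "a1",
                 session_id = hdr$session_id %||% "s1",
                 dropped_frame_mask = mask)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
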