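#' Fluorescence trace specification and generator
#'
#' Emulates a single-ROI calcium-imaging trial: a baseline fluorescence level
#' under exponential photobleaching, an odor-evoked response kernel switched on
#' at `onset_frame`, and additive Gaussian noise:
#' `F(t) = baseline * exp(-t / tau_bleach) * (1 + amplitude * k(t - t_onset)) + noise`,
#' where the kernel `k` is an exponential decay with unit peak at onset.
#' Defaults mirror a typical widefield acquisition: 40 frames at ~9 Hz with the
#' stimulus at frame 20.
#'
#' @param frame_rate acquisition rate in Hz (default 9).
#' @param n_frames trial length in frames (default 40).
#' @param onset_frame 1-based frame index of stimulus onset (default 20).
#' @param amplitude response amplitude in dF/F units (default 0.5).
#' @param baseline baseline fluorescence (arbitrary units, default 100).
#' @param tau_bleach bleach time constant in seconds (`Inf` = no bleach).
#' @param tau_response response decay time constant in seconds (default 1).
#' @param noise_sd additive Gaussian noise sd (fluorescence units).
#' @param seed integer seed (mandatory).
#' @return `trace_spec()` an `al_trace_spec`; `make_trace()` an
#'   `al_fluorescence_trace`.
#' @export
trace_spec <- function(frame_rate = 9, n_frames = 40L, onset_frame = 20L,
                       amplitude = 0.5, baseline = 100, tau_bleach = Inf,
                       tau_response = 1, noise_sd = 0, seed) {
  al_assert(!missing(seed), "al_spec_error", "trace_spec: seed is mandatory")
  al_assert(frame_rate > 0, "al_spec_error", "frame_rate must be positive")
  al_assert(onset_frame >= 1 && onset_frame <= n_frames, "al_spec_error",
            "onset_frame must lie within the trace")
  structure(list(frame_rate = frame_rate, n_frames = as.integer(n_frames),
                 onset_frame = as.integer(onset_frame), amplitude = amplitude,
                 baseline = baseline, tau_bleach = tau_bleach,
                 tau_response = tau_response, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "al_trace_spec")
}

#' @param spec an `al_trace_spec`.
#' @rdname trace_spec
#' @export
make_trace <- function(spec) {
  al_assert(inherits(spec, "al_trace_spec"), "al_spec_error",
            "make_trace expects a trace_spec()")
  t_s <- (seq_len(spec$n_frames) - 1) / spec$frame_rate
  t_onset <- (spec$onset_frame - 1) / spec$frame_rate
  kernel <- ifelse(t_s >= t_onset,
                   exp(-(t_s - t_onset) / spec$tau_response), 0)
  bleach <- if (is.finite(spec$tau_bleach)) exp(-t_s / spec$tau_bleach) else 1
  values <- spec$baseline * bleach * (1 + spec$amplitude * kernel)
  if (spec$noise_sd > 0) {
    values <- values + with_seed(spec$seed,
                                 stats::rnorm(spec$n_frames, 0, spec$noise_sd))
  }
  fluorescence_trace(values, spec$frame_rate, spec$onset_frame)
}

#' Construct a fluorescence trace
#'
#' @param values raw fluorescence per frame (finite, non-negative).
#' @param frame_rate Hz.
#' @param onset_frame 1-based stimulus onset frame; at least one second of
#'   frames must remain after onset.
#' @param metadata optional named list (glomerulus, animal, trial, ...).
#' @return an `al_fluorescence_trace`.
#' @export
fluorescence_trace <- function(values, frame_rate, onset_frame,
                               metadata = list()) {
  al_assert(all(is.finite(values)) && all(values >= 0), "al_input_error",
            "trace values must be finite and non-negative")
  al_assert(onset_frame >= 1 && onset_frame <= length(values),
            "al_input_error", "onset_frame must lie within the trace")
  al_assert(length(values) - onset_frame >= floor(frame_rate) - 1,
            "al_input_error",
            "trace must extend at least one second past onset")
  structure(list(values = as.numeric(values), frame_rate = frame_rate,
                 onset_frame = as.integer(onset_frame), metadata = metadata),
            class = "al_fluorescence_trace")
}

#' @export
print.al_fluorescence_trace <- function(x, ...) {
  cat(sprintf("<al_fluorescence_trace> %d frames @ %.3g Hz, onset frame %d\n",
              length(x$values), x$frame_rate, x$onset_frame))
  invisible(x)
}

#' Write / read traces as delimited text (one column per trial)
#'
#' @param traces list of `al_fluorescence_trace` sharing frame rate and onset.
#' @param path file path.
#' @return `read_traces()` a list of traces.
#' @export
write_traces <- function(traces, path) {
  fr <- unique(vapply(traces, `[[`, numeric(1), "frame_rate"))
  on <- unique(vapply(traces, `[[`, integer(1), "onset_frame"))
  al_assert(length(fr) == 1 && length(on) == 1, "al_input_error",
            "all traces in one file must share frame_rate and onset_frame")
  df <- as.data.frame(lapply(traces, `[[`, "values"))
  names(df) <- if (!is.null(names(traces))) names(traces) else
    sprintf("trial_%02d", seq_along(traces))
  write_tsv(df, path, comment = sprintf("frame_rate=%g onset_frame=%d", fr, on))
}

#' @rdname write_traces
#' @export
read_traces <- function(path) {
  al_assert(file.exists(path), "al_load_error", "missing file: %s", path)
  header <- readLines(path, n = 1L)
  al_assert(grepl("frame_rate=", header), "al_load_error",
            "%s: missing frame_rate/onset_frame comment header", path)
  fr <- as.numeric(sub(".*frame_rate=([0-9.eE+-]+).*", "\\1", header))
  on <- as.integer(sub(".*onset_frame=([0-9]+).*", "\\1", header))
  df <- read_tsv(path)
  lapply(stats::setNames(names(df), names(df)), function(nm) {
    fluorescence_trace(df[[nm]], fr, on, metadata = list(trial = nm))
  })
}
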