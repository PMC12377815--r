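# Experimental input-signal generators: stimulus trains, sinusoidal MTC
# length trajectories with concentric/eccentric phasing, isometric holds.
#
# The default sample rate is 2 kHz, matching the acquisition rate of the
# fibre-bundle experiments the fixtures emulate.

#' Stimulus train of block pulses
#'
#' Each stimulus pulse is represented as a block pulse of amplitude 1 and
#' (by default) 4 ms duration; within a train, pulses are delivered at a
#' fixed rate (inter-onset interval `1/rate`).
#'
#' @param n_pulses number of pulses (>= 1).
#' @param rate within-train pulse rate (Hz); default 100.
#' @param onset time of the first pulse onset (s).
#' @param width block pulse duration (s); default 0.004.
#' @param duration total signal duration (s).
#' @param sample_rate sampling rate (Hz); default 2000.
#' @return data.frame `(t, stim)` with attributes `pulse_times` (onsets),
#'   `pulse_width` and `sample_rate`; class `stimulus_train`.
#' @export
make_stimulus <- function(n_pulses, rate = 100, onset = 0.1, width = 0.004,
                          duration = NULL, sample_rate = 2000) {
  if (n_pulses < 1) stop("n_pulses must be >= 1", call. = FALSE)
  if (width <= 0) stop("width must be > 0", call. = FALSE)
  if (n_pulses > 1 && width * rate >= 1)
    stop("pulses overlap: need width * rate < 1", call. = FALSE)
  onsets <- onset + (seq_len(n_pulses) - 1L) / rate
  if (is.null(duration)) duration <- onsets[n_pulses] + width + 0.5
  if (duration < onsets[n_pulses] + width)
    stop("duration does not cover the train", call. = FALSE)
  t <- seq(0, duration, by = 1 / sample_rate)
  stim <- stim_signal(t, onsets, width)
  structure(data.frame(t = t, stim = stim),
            pulse_times = onsets, pulse_width = width,
            sample_rate = sample_rate,
            class = c("stimulus_train", "data.frame"))
}

#' Evaluate a block-pulse train at arbitrary times
#' @keywords internal
stim_signal <- function(t, onsets, width) {
  stim <- numeric(length(t))
  for (o in onsets) stim[t >= o & t < o + width] <- 1
  stim
}

#' Movement protocol description
#'
#' @param kind `"isometric"` or `"sinusoid"`.
#' @param amplitude movement amplitude (m); peak-to-centre.
#' @param frequency movement frequency (Hz).
#' @param offset_length MTC length about which the movement occurs (m).
#' @param stim_phase `"concentric"` or `"eccentric"`: whether the stimulus
#'   train spans the shortening or the lengthening half-cycle.
#' @param n_cycles number of movement cycles.
#' @param n_pulses,pulse_rate stimulus train description.
#' @param lead_in quiet time before movement/stimulation onset (s).
#' @param tail quiet time appended after the last cycle (s).
#' @param stim_phase_frac position of the train centre within the selected
#'   half-cycle, as a fraction: 0.5 (default) centres the train on the peak
#'   shortening (or lengthening) velocity. The experiments' exact phase is
#'   not documented; this default is a package choice, not a reported value.
#' @return list of class `movement_protocol`.
#' @export
movement_protocol <- function(kind = c("sinusoid", "isometric"),
                              amplitude = 0.25e-3, frequency = 2,
                              offset_length, stim_phase = c("concentric",
                                                            "eccentric"),
                              n_cycles = 2L, n_pulses = 5L, pulse_rate = 100,
                              lead_in = 0.1, tail = 0.4,
                              stim_phase_frac = 0.5) {
  kind <- match.arg(kind)
  stim_phase <- match.arg(stim_phase)
  if (amplitude < 0) stop("amplitude must be >= 0", call. = FALSE)
  if (kind == "sinusoid" && frequency <= 0)
    stop("frequency must be > 0", call. = FALSE)
  structure(list(kind = kind, amplitude = amplitude, frequency = frequency,
                 offset_length = offset_length, stim_phase = stim_phase,
                 n_cycles = as.integer(n_cycles),
                 n_pulses = as.integer(n_pulses), pulse_rate = pulse_rate,
                 lead_in = lead_in, tail = tail,
                 stim_phase_frac = stim_phase_frac),
            class = "movement_protocol")
}

#' MTC length trajectory and phased stimulus for a protocol
#'
#' For a sinusoid, `l_mtc(t) = offset + A sin(2 pi f (t - lead_in))` once
#' the movement starts; shortening occupies the half-cycle centred at
#' `lead_in + T/2` and lengthening the half-cycle centred at `lead_in + T`.
#' The stimulus train is centred (per `stim_phase_frac`) on the selected
#' half-cycle of the first movement cycle; concentric and eccentric
#' placement differ by exactly half a period. Isometric protocols return a
#' constant trace with the train starting after the lead-in.
#'
#' @param protocol `movement_protocol`.
#' @param sample_rate sampling rate (Hz); must be at least 20x the movement
#'   frequency. Default 2000.
#' @return `simulation_input` (see [simulation_input()]).
#' @export
make_length_trajectory <- function(protocol, sample_rate = 2000) {
  p <- protocol
  stopifnot(inherits(p, "movement_protocol"))
  if (p$kind == "sinusoid" && sample_rate < 20 * p$frequency)
    stop("sample_rate must be >= 20x movement frequency", call. = FALSE)
  span <- (p$n_pulses - 1L) / p$pulse_rate + 0.004
  if (p$kind == "isometric") {
    duration <- p$lead_in + span + p$tail
    t <- seq(0, duration, by = 1 / sample_rate)
    l <- rep(p$offset_length, length(t))
    onset <- p$lead_in
  } else {
    per <- 1 / p$frequency
    duration <- p$lead_in + p$n_cycles * per + p$tail
    t <- seq(0, duration, by = 1 / sample_rate)
    ph <- pmax(t - p$lead_in, 0)
    ph <- pmin(ph, p$n_cycles * per)
    l <- p$offset_length + p$amplitude * sin(2 * pi * p$frequency * ph)
    centre <- p$lead_in +
      if (p$stim_phase == "concentric") per / 2 else per
    onset <- centre + (p$stim_phase_frac - 0.5) * per / 2 - span / 2
  }
  onset <- round(onset * sample_rate) / sample_rate  # align to sample grid
  onsets <- onset + (seq_len(p$n_pulses) - 1L) / p$pulse_rate
  stim <- stim_signal(t, onsets, 0.004)
  simulation_input(t = t, l_mtc = l, stim = stim, sample_rate = sample_rate,
                   pulse_times = onsets, pulse_width = 0.004,
                   metadata = list(protocol = p))
}

#' Assemble a simulation input
#'
#' Paired MTC length and stimulation trajectories on a common uniform time
#' grid, defining one contraction/trial.
#'
#' @param t uniform time grid (s), starting at 0.
#' @param l_mtc MTC length samples (m).
#' @param stim binary stimulation samples.
#' @param sample_rate sampling rate (Hz).
#' @param pulse_times optional exact pulse onsets (s); if omitted they are
#'   reconstructed from rising edges of `stim`.
#' @param pulse_width block pulse duration (s).
#' @param metadata free-form condition labels.
#' @return list of class `simulation_input`.
#' @export
simulation_input <- function(t, l_mtc, stim, sample_rate = NULL,
                             pulse_times = NULL, pulse_width = 0.004,
                             metadata = list()) {
  if (length(t) != length(l_mtc) || length(t) != length(stim))
    stop("t, l_mtc and stim must have equal length", call. = FALSE)
  stopifnot_finite(t, "t"); stopifnot_finite(l_mtc, "l_mtc")
  if (is.null(sample_rate)) sample_rate <- 1 / stats::median(diff(t))
  if (sample_rate <= 0) stop("sample_rate must be > 0", call. = FALSE)
  if (is.null(pulse_times)) {
    up <- which(diff(c(0, stim)) > 0.5)
    pulse_times <- t[up]
  }
  structure(list(t = t, l_mtc = l_mtc, stim = stim,
                 sample_rate = sample_rate, pulse_times = pulse_times,
                 pulse_width = pulse_width, metadata = metadata),
            class = "simulation_input")
}

#' Write / read a trial as two-column CSV
#'
#' Columns `t`, `l_mtc`, `stim`; lengths may be declared in `m` or `mm`
#' via the `unit` argument and are converted at the boundary (SI
#' internally).
#'
#' @param input `simulation_input`.
#' @param path CSV path.
#' @param unit `"m"` (default) or `"mm"` for the length column.
#' @export
write_input_csv <- function(input, path, unit = c("m", "mm")) {
  unit <- match.arg(unit)
  fac <- if (unit == "mm") 1e3 else 1
  utils::write.csv(data.frame(t = input$t, l_mtc = input$l_mtc * fac,
                              stim = input$stim),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_input_csv
#' @param metadata metadata to attach to the read input.
#' @export
read_input_csv <- function(path, unit = c("m", "mm"), metadata = list()) {
  unit <- match.arg(unit)
  fac <- if (unit == "mm") 1e-3 else 1
  df <- utils::read.csv(path)
  simulation_input(t = df$t, l_mtc = df$l_mtc * fac, stim = df$stim,
                   metadata = metadata)
}
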