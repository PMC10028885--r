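#' Evoked-response component set
#'
#' Parameterizes the synthetic grand-average source waveforms: Gaussian
#' components (signed amplitude in nAm, peak latency and width in ms) on a
#' 500-Hz grid over the -50 to 450 ms epoch.  Defaults emulate the standard
#' auditory evoked morphology: a P1-like positivity at 50 ms and an N1-like
#' negativity at 100 ms in both conditions, plus a broad awareness-related
#' negativity peaking at 180 ms (support roughly 60-360 ms) present only in
#' the detected condition.  Amplitudes are plausible magnitudes for
#' source-localized auditory fields (tens of nAm); band-limited Gaussian
#' noise emulates the 0.15-15 Hz filtering of the empirical pipeline.
#'
#' @param p1,n1,aan Lists with `amp` (nAm), `lat` (ms), `width` (Gaussian
#'   sd, ms).
#' @param noise_amp Noise standard deviation before filtering, nAm.
#' @param fs Sampling rate, Hz.
#' @param band Band-pass edges, Hz.
#' @param seed Integer seed.
#' @return An `erf_component_set`.
#' @export
erf_component_set <- function(p1 = list(amp = 8, lat = 50, width = 12),
                              n1 = list(amp = -10, lat = 100, width = 16),
                              aan = list(amp = -12, lat = 180, width = 50),
                              noise_amp = 1, fs = 500, band = c(0.15, 15),
                              seed = 1) {
  for (cmp in list(p1, n1, aan))
    stopifnot(cmp$width > 0)
  stopifnot(fs > 2 * band[2])
  structure(list(p1 = p1, n1 = n1, aan = aan, noise_amp = noise_amp,
                 fs = fs, band = band, seed = as.integer(seed)),
            class = "erf_component_set")
}

.gauss_bump <- function(time, cmp) cmp$amp * exp(-(time - cmp$lat)^2 / (2 * cmp$width^2))

# zero-phase band-pass (2nd-order Butterworth, forward-backward)
.bandpass <- function(x, fs, band) {
  bf <- signal::butter(2, band / (fs / 2), type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

#' Generate synthetic target waveforms
#'
#' The undetected-condition waveform is P1 + N1 (+ filtered noise); the
#' detected-condition waveform adds the broad awareness negativity.  The
#' deterministic components are smooth and band-limited by construction;
#' the zero-phase band-pass is applied to the noise so that component peak
#' latencies are exact.
#'
#' @param spec An [erf_component_set()].
#' @return List with `undetected` and `detected` [target_waveform()]s.
#' @export
generate_targets <- function(spec = erf_component_set()) {
  stopifnot(inherits(spec, "erf_component_set"))
  step <- 1000 / spec$fs
  time <- seq(-50, 450 - step, by = step)
  undet <- .gauss_bump(time, spec$p1) + .gauss_bump(time, spec$n1)
  det <- undet + .gauss_bump(time, spec$aan)
  if (spec$noise_amp > 0) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(spec$seed)
    undet <- undet + .bandpass(stats::rnorm(length(time), 0, spec$noise_amp),
                               spec$fs, spec$band)
    det <- det + .bandpass(stats::rnorm(length(time), 0, spec$noise_amp),
                           spec$fs, spec$band)
  }
  list(undetected = target_waveform(time, undet, "undetected"),
       detected = target_waveform(time, det, "detected"))
}

#' Target waveform container
#'
#' @param time Uniform epoch time grid, ms.
#' @param amplitude Amplitude, nAm.
#' @param condition `"detected"`, `"undetected"` or `"difference"`.
#' @param provenance Free-form provenance note.
#' @return A `target_waveform` (data frame with `time`, `amplitude`).
#' @export
target_waveform <- function(time, amplitude, condition, provenance = "synthetic") {
  stopifnot(length(time) == length(amplitude), all(is.finite(amplitude)))
  if (length(time) > 2)
    stopifnot(diff(range(diff(time))) < 1e-9)
  structure(data.frame(time = time, amplitude = amplitude),
            condition = condition, provenance = provenance,
            class = c("target_waveform", "data.frame"))
}

#' Generate oddball stimulus timelines
#'
#' Each 5-s sequence holds ten 100-ms tones at a 500-ms onset asynchrony;
#' one uniformly placed tone is the deviant.  A synthetic button press time
#' is drawn for a `p_detect` fraction of sequences (uniform over
#' `press_range`); undetected sequences have no press.
#'
#' @param seed Integer seed.
#' @param n_sequences Number of sequences.
#' @param p_detect Probability a sequence is detected (has a press).
#' @param press_range Press-time range, s.
#' @return List of `oddball_timeline` objects: `onsets` (s),
#'   `tone_duration` (ms), `soa` (ms), `deviant_index`, `press_time`
#'   (s or `NA`).
#' @export
generate_oddball <- function(seed = 1, n_sequences = 1, p_detect = 0.7,
                             press_range = c(1, 5)) {
  stopifnot(n_sequences >= 1)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  lapply(seq_len(n_sequences), function(i) {
    press <- if (stats::runif(1) < p_detect)
      stats::runif(1, press_range[1], press_range[2]) else NA_real_
    structure(list(onsets = seq(0, by = 0.5, length.out = 10),
                   tone_duration = 100, soa = 500,
                   deviant_index = sample.int(10, 1),
                   sequence_length = 5, press_time = press),
              class = "oddball_timeline")
  })
}

#' Bin standard tones into detected and undetected
#'
#' Detection is press-relative: the two standard tones immediately
#' preceding the button press and all standard tones after it count as
#' detected; standards more than two tones before the press are
#' undetected.  The deviant tone is excluded from both bins.  With no
#' press, every standard is undetected; a press before the first tone
#' makes every standard detected.
#'
#' @param timeline An `oddball_timeline`.
#' @return List with `detected` and `undetected` onset vectors (s).
#' @export
bin_tones <- function(timeline) {
  std <- timeline$onsets[-timeline$deviant_index]
  if (is.na(timeline$press_time))
    return(list(detected = numeric(0), undetected = std))
  before <- std[std < timeline$press_time]
  after <- std[std >= timeline$press_time]
  last_two <- if (length(before) > 0)
    sort(utils::tail(sort(before), 2)) else numeric(0)
  list(detected = c(last_two, after),
       undetected = setdiff(before, last_two))
}

#' Epoch a continuous trace around stimulus onsets
#'
#' Extracts fixed-length segments on a regular post-onset grid.  Onsets
#' whose window exceeds the recording are dropped with a warning.
#'
#' @param time,amplitude Continuous recording (ms and any amplitude unit);
#'   `time` must be uniformly sampled.
#' @param onsets Stimulus onsets, ms.
#' @param window `c(t0, t1)` epoch window relative to onset, ms.
#' @param fs Epoch sampling rate, Hz.
#' @return List of data frames with `time` (epoch-relative, ms) and
#'   `amplitude`, one per retained onset.
#' @export
epoch_trace <- function(time, amplitude, onsets, window = c(-50, 450),
                        fs = 500) {
  step <- 1000 / fs
  rel <- seq(window[1], window[2] - step, by = step)
  out <- list()
  for (on in onsets) {
    tt <- on + rel
    if (tt[1] < min(time) || tt[length(tt)] > max(time)) {
      warning("onset at ", on, " ms too close to the recording edge; dropped")
      next
    }
    out[[length(out) + 1]] <-
      data.frame(time = rel,
                 amplitude = stats::approx(time, amplitude, xout = tt)$y)
  }
  out
}
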