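# F0 contours are sampled at <= 0.01 s spacing; start/end F0 are aggregated
# over the first/last 0.05 s of the call.
F0_MAX_SPACING <- 0.01
EDGE_WINDOW <- 0.05

#' Construct an F0 contour
#'
#' A fundamental-frequency contour: strictly increasing sample times (s)
#' with spacing at most 0.01 s, and a positive F0 (Hz) at each time.
#'
#' @param times_s Numeric vector of sample times, strictly increasing.
#' @param f0_hz Positive F0 values, same length.
#' @return An object of class \code{f0_contour}.
#' @export
f0_contour <- function(times_s, f0_hz) {
  if (length(times_s) < 2) stop("contour needs >= 2 samples", call. = FALSE)
  if (length(times_s) != length(f0_hz))
    stop("times_s and f0_hz lengths differ", call. = FALSE)
  dt <- diff(times_s)
  if (any(dt <= 0)) stop("contour times must strictly increase", call. = FALSE)
  if (any(dt > F0_MAX_SPACING + 1e-12))
    stop("contour spacing exceeds ", F0_MAX_SPACING, " s", call. = FALSE)
  if (any(f0_hz <= 0)) stop("F0 values must be positive", call. = FALSE)
  structure(list(times_s = as.numeric(times_s), f0_hz = as.numeric(f0_hz)),
            class = "f0_contour")
}

#' Construct a spectrum series
#'
#' Framewise spectra of a call: frame centre times, strictly increasing bin
#' frequencies (a 256-point analysis on 44.1 kHz audio gives 129 bins
#' ~172.3 Hz apart), an amplitude matrix (frames x bins) and a per-frame
#' total intensity in dB.
#'
#' @param frame_times_s Frame centre times (s), strictly increasing.
#' @param freqs_hz Bin frequencies (Hz), strictly increasing.
#' @param amplitude Matrix \code{length(frame_times_s) x length(freqs_hz)}.
#' @param intensity_db Per-frame intensity (dB); computed from
#'   \code{amplitude} when omitted.
#' @return An object of class \code{spectrum_series}.
#' @export
spectrum_series <- function(frame_times_s, freqs_hz, amplitude,
                            intensity_db = NULL) {
  amplitude <- as.matrix(amplitude)
  if (any(diff(frame_times_s) <= 0))
    stop("frame times must strictly increase", call. = FALSE)
  if (any(diff(freqs_hz) <= 0))
    stop("bin frequencies must strictly increase", call. = FALSE)
  if (nrow(amplitude) != length(frame_times_s) ||
      ncol(amplitude) != length(freqs_hz))
    stop("amplitude must be frames x bins", call. = FALSE)
  if (is.null(intensity_db)) {
    pow <- rowSums(amplitude^2)
    intensity_db <- 10 * log10(pmax(pow, .Machine$double.xmin))
  }
  structure(list(frame_times_s = as.numeric(frame_times_s),
                 freqs_hz = as.numeric(freqs_hz),
                 amplitude = amplitude,
                 intensity_db = as.numeric(intensity_db)),
            class = "spectrum_series")
}

#' Construct a call bout
#'
#' An ordered sequence of calls of the same type from the same caller,
#' each a list with elements \code{contour} (\code{\link{f0_contour}}, on an
#' absolute time axis) and optionally \code{spectra}
#' (\code{\link{spectrum_series}}). Calls must be time-ordered and
#' non-overlapping.
#'
#' @param calls List of calls as described above.
#' @return An object of class \code{call_bout}.
#' @export
call_bout <- function(calls) {
  if (length(calls) < 1) stop("bout needs >= 1 call", call. = FALSE)
  on <- vapply(calls, function(cl) cl$contour$times_s[1], 0)
  off <- vapply(calls, function(cl) max(cl$contour$times_s), 0)
  if (length(calls) > 1 && any(on[-1] <= off[-length(calls)]))
    stop("calls overlap or are out of order", call. = FALSE)
  structure(list(calls = calls, onsets_s = on, offsets_s = off),
            class = "call_bout")
}

#' Measure the acoustic variables of one call
#'
#' Computes the per-call acoustic variables from an F0 contour and (when
#' supplied) framewise spectra:
#' \itemize{
#'   \item duration: last minus first contour time;
#'   \item maximum F0: the highest contour value, its time being the
#'     earliest sample attaining it;
#'   \item start/end F0: the median of contour samples within the first/last
#'     0.05 s (median is robust to edge jitter); for calls shorter than
#'     0.1 s the windows are truncated at the call midpoint, with a warning;
#'   \item F0 drop: maximum minus end F0; slope steepness: drop divided by
#'     the time from the maximum to the call end (0 when the drop is 0 or
#'     the maximum falls at the end);
#'   \item peak frequency: the maximum-amplitude bin within the single frame
#'     nearest the time of maximum intensity; its time is that frame's
#'     centre;
#'   \item positions: event time as a proportion of call duration.
#' }
#' All times are reported relative to the call onset, so the measurement is
#' invariant to uniform time translation.
#'
#' @param contour An \code{\link{f0_contour}} spanning the call.
#' @param spectra A \code{\link{spectrum_series}} covering the contour's
#'   span, or \code{NULL} (peak-frequency fields are then \code{NA}).
#' @return Named list of the acoustic fields of a call record.
#' @export
measure_call <- function(contour, spectra = NULL) {
  stopifnot(inherits(contour, "f0_contour"))
  t0 <- contour$times_s[1]
  t <- contour$times_s - t0
  f0 <- contour$f0_hz
  duration <- t[length(t)]

  w <- EDGE_WINDOW
  if (duration < 2 * w) {
    warning(sprintf(
      "call of %.3f s is shorter than 0.1 s; start/end windows truncated at midpoint",
      duration))
    w <- duration / 2
  }
  f0_start <- stats::median(f0[t <= w + 1e-12])
  f0_end <- stats::median(f0[t >= duration - w - 1e-12])

  f0_max <- max(f0)
  t_f0max <- t[which.max(f0)]          # earliest sample attaining the max
  f0_drop <- f0_max - f0_end
  slope <- if (f0_drop == 0 || t_f0max >= duration) 0 else
    f0_drop / (duration - t_f0max)

  peak_freq <- t_peak <- pos_peak <- NA_real_
  if (!is.null(spectra)) {
    stopifnot(inherits(spectra, "spectrum_series"))
    i <- which.max(spectra$intensity_db)  # earliest frame on ties
    j <- which.max(spectra$amplitude[i, ])
    peak_freq <- spectra$freqs_hz[j]
    t_peak <- min(max(spectra$frame_times_s[i] - t0, 0), duration)
    pos_peak <- t_peak / duration
  }

  list(duration_s = duration,
       f0_start_hz = f0_start, f0_end_hz = f0_end, f0_max_hz = f0_max,
       f0_drop_hz = f0_drop, slope_steepness_hz_per_s = slope,
       peak_freq_hz = peak_freq,
       t_f0max_s = t_f0max, t_peakfreq_s = t_peak,
       pos_f0max = t_f0max / duration, pos_peakfreq = pos_peak)
}

#' Inter-call intervals of a bout
#'
#' The silent gap from the end of each call to the beginning of the next
#' within an unbroken same-type sequence. A single call yields an empty
#' vector.
#'
#' @param bout A \code{\link{call_bout}}.
#' @return Numeric vector of length (number of calls - 1), in seconds.
#' @export
inter_call_intervals <- function(bout) {
  stopifnot(inherits(bout, "call_bout"))
  n <- length(bout$calls)
  if (n == 1) return(numeric(0))
  gaps <- bout$onsets_s[-1] - bout$offsets_s[-n]
  if (any(gaps <= 0)) stop("calls overlap within bout", call. = FALSE)
  gaps
}
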