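#' Neuropil correction of a raw fluorescence trace
#'
#' Subtracts scaled neuropil fluorescence from the raw somatic trace,
#' `corrected = raw - coeff * neuropil`.
#'
#' @param raw,neuropil per-frame fluorescence vectors of equal length
#' @param coeff subtraction coefficient in [0, 1] (default 0.8)
#' @return corrected per-frame trace
#' @export
neuropil_correct <- function(raw, neuropil, coeff = 0.8) {
  if (length(raw) != length(neuropil))
    stop("raw and neuropil traces differ in length")
  stopifnot(coeff >= 0, coeff <= 1)
  raw - coeff * neuropil
}

#' Rolling-percentile delta-F/F
#'
#' The baseline at each frame is a low percentile (default 30th) of the
#' trace in a centered moving window (default 60 s), truncated at the
#' session edges; dF/F = (trace - baseline) / baseline.
#'
#' @param trace corrected fluorescence trace
#' @param frame_rate Hz
#' @param percentile baseline percentile (0-100)
#' @param window_s window length in seconds
#' @return per-frame dF/F
#' @export
compute_dff <- function(trace, frame_rate, percentile = 30, window_s = 60) {
  n <- length(trace)
  half <- floor(window_s * frame_rate / 2)
  if (2 * half + 1 < 2) stop("window too short for the frame rate")
  base <- vapply(seq_len(n), function(t) {
    lo <- max(1, t - half)
    hi <- min(n, t + half)
    stats::quantile(trace[lo:hi], percentile / 100, names = FALSE)
  }, numeric(1))
  bad <- which(base <= 0)
  if (length(bad))
    stop("nonpositive baseline at frame ", bad[1],
         "; dF/F undefined")
  (trace - base) / base
}

#' Temporal Gaussian smoothing of an activity trace
#'
#' Convolves with a normalized discrete Gaussian kernel (default s.d.
#' 0.5 s), truncated at 4 s.d. and renormalized at the session edges, so
#' constant traces are preserved and nonnegative input stays nonnegative.
#'
#' @param trace per-frame activity (vector) or cells x frames matrix
#'   (each row smoothed)
#' @param frame_rate Hz
#' @param kernel_sd_s kernel standard deviation in seconds
#' @return smoothed object of the same shape
#' @export
smooth_activity <- function(trace, frame_rate, kernel_sd_s = 0.5) {
  stopifnot(kernel_sd_s > 0)
  sd_f <- kernel_sd_s * frame_rate
  half <- ceiling(4 * sd_f)
  k <- exp(-(-half:half)^2 / (2 * sd_f^2))
  k <- k / sum(k)
  smooth1 <- function(x) {
    n <- length(x)
    # pad with zeros and renormalize by the smoothed all-ones trace so
    # edge frames keep their scale
    num <- stats::filter(c(numeric(half), x, numeric(half)), k, sides = 2)
    den <- stats::filter(c(numeric(half), rep(1, n), numeric(half)), k, sides = 2)
    as.numeric(num / den)[(half + 1):(half + n)]
  }
  if (is.null(dim(trace))) smooth1(trace)
  else t(apply(trace, 1, smooth1))
}

#' Synchronize behavioral streams to the imaging frame clock
#'
#' Continuous variables (position, speed) are linearly interpolated onto
#' the frame times; position is interpolated on unwrapped coordinates and
#' re-wrapped so no spurious mid-track values appear at the lap boundary.
#' Event streams (licks, rewards) are assigned to the nearest frame, with
#' multiple events in one frame interval collapsing to a single event on
#' that frame.
#'
#' @param t_native monotone increasing native timestamps (s)
#' @param frame_times monotone increasing imaging frame timestamps (s)
#' @param position native position samples (cm, wrapped), or NULL
#' @param speed native speed samples, or NULL
#' @param event_times numeric vector of event timestamps (s), or NULL
#' @param track_length cm, for unwrapping
#' @return list with per-frame `position`, `speed`, `event` (logical)
#' @export
sync_behavior <- function(t_native, frame_times, position = NULL,
                          speed = NULL, event_times = NULL,
                          track_length = 200) {
  if (is.unsorted(t_native, strictly = TRUE) ||
      is.unsorted(frame_times, strictly = TRUE))
    stop("timestamps must be strictly increasing")
  out <- list(position = NULL, speed = NULL, event = NULL)
  if (!is.null(position)) {
    # unwrap: accumulate laps where position drops by more than half a track
    d <- diff(position)
    laps <- cumsum(c(0, d < -track_length / 2))
    unwrapped <- position + laps * track_length
    interp <- stats::approx(t_native, unwrapped, xout = frame_times,
                            rule = 2)$y
    out$position <- wrap_pos(interp, track_length)
  }
  if (!is.null(speed)) {
    out$speed <- stats::approx(t_native, speed, xout = frame_times,
                               rule = 2)$y
  }
  if (!is.null(event_times)) {
    ev <- logical(length(frame_times))
    if (length(event_times)) {
      fi <- vapply(event_times,
                   function(tt) which.min(abs(frame_times - tt)),
                   integer(1))
      ev[unique(fi)] <- TRUE
    }
    out$event <- ev
  }
  out
}
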