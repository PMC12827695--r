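# Event detection on the RSS trace: troughs, peaks between consecutive
# troughs, peak amplitude and trough-to-trough duration (TTD).

#' Detect troughs in an RSS trace
#'
#' A trough is a frame whose value is strictly lower than both immediate
#' neighbors. Endpoints have only one neighbor and are never troughs;
#' plateaus (ties) yield no trough under the strict rule.
#'
#' @param rss An `rss_trace` (from [compute_rss()]) or numeric vector.
#' @return Integer vector of trough frames (1-based), strictly increasing.
#' @examples
#' detect_troughs(c(5, 3, 4, 2, 6, 1, 7))  # frames 2, 4, 6
#' @export
detect_troughs <- function(rss) {
  v <- if (inherits(rss, "rss_trace")) rss$values else as.numeric(rss)
  n <- length(v)
  if (n < 3L) stop_edgedyn("trough detection needs at least 3 frames, got %d", n)
  mid <- 2:(n - 1L)
  mid[v[mid] < v[mid - 1L] & v[mid] < v[mid + 1L]]
}

#' Detect peaks between consecutive troughs
#'
#' For each pair of adjacent troughs the peak is the frame of maximum value
#' strictly between them (open interval); ties resolve to the earliest
#' frame. With fewer than two troughs no peak is defined and an empty
#' result is returned with a warning (the subject is then excluded from
#' peak statistics).
#'
#' @param rss An `rss_trace` or numeric vector.
#' @param troughs Trough frames as returned by [detect_troughs()].
#' @return List with `frames` (integer) and `amplitudes` (numeric), one
#'   entry per consecutive trough pair.
#' @examples
#' v <- c(5, 3, 4, 2, 6, 1, 7)
#' detect_peaks(v, detect_troughs(v))
#' @export
detect_peaks <- function(rss, troughs) {
  v <- if (inherits(rss, "rss_trace")) rss$values else as.numeric(rss)
  troughs <- as.integer(troughs)
  if (length(troughs) < 2L) {
    warning("fewer than 2 troughs; no peaks defined", call. = FALSE)
    return(list(frames = integer(0), amplitudes = numeric(0)))
  }
  k <- length(troughs) - 1L
  frames <- integer(k)
  for (m in seq_len(k)) {
    lo <- troughs[m]; hi <- troughs[m + 1L]
    span <- (lo + 1L):(hi - 1L)           # TTD >= 2 guarantees non-empty
    frames[m] <- span[which.max(v[span])] # which.max takes earliest tie
  }
  list(frames = frames, amplitudes = v[frames])
}

#' Event profile of one subject's RSS trace
#'
#' Runs trough and peak detection and assembles per-subject dynamics
#' summaries: peak amplitudes (highest value between adjacent troughs) and
#' trough-to-trough durations in frames.
#'
#' @param rss An `rss_trace` or numeric vector.
#' @param tr_seconds Repetition time; taken from the trace when available.
#' @return Object of class `event_profile`: `trough_frames`, `peak_frames`,
#'   `peak_amplitudes`, `ttd_frames`, `mean_peak_amplitude`, `mean_ttd`
#'   (frames), `tr_seconds`. Means are `NA` when fewer than two troughs
#'   exist.
#' @examples
#' event_profile(c(5, 3, 4, 2, 6, 1, 7))
#' @export
event_profile <- function(rss, tr_seconds = NULL) {
  v <- if (inherits(rss, "rss_trace")) rss$values else as.numeric(rss)
  tr <- tr_seconds %||% (if (inherits(rss, "rss_trace")) rss$tr_seconds else NA_real_)
  troughs <- detect_troughs(v)
  peaks <- if (length(troughs) >= 2L) detect_peaks(v, troughs)
           else list(frames = integer(0), amplitudes = numeric(0))
  ttd <- if (length(troughs) >= 2L) diff(troughs) else integer(0)
  structure(list(
    trough_frames = troughs,
    peak_frames = peaks$frames,
    peak_amplitudes = peaks$amplitudes,
    ttd_frames = ttd,
    mean_peak_amplitude = if (length(peaks$amplitudes)) mean(peaks$amplitudes) else NA_real_,
    mean_ttd = if (length(ttd)) mean(ttd) else NA_real_,
    tr_seconds = tr), class = "event_profile")
}

#' @export
print.event_profile <- function(x, ...) {
  cat(sprintf(paste0("<event_profile> %d troughs, %d peaks; mean peak",
                     " amplitude %.4g, mean TTD %.4g frames\n"),
              length(x$trough_frames), length(x$peak_frames),
              x$mean_peak_amplitude, x$mean_ttd))
  invisible(x)
}

#' Summarize event dynamics
#'
#' Arithmetic means of peak amplitude and TTD from an event profile. TTD is
#' reported in frames by default; `units = "seconds"` multiplies by the
#' repetition time.
#'
#' @param profile An `event_profile`.
#' @param tr_seconds Repetition time in seconds; defaults to the profile's.
#' @param units `"frames"` (default) or `"seconds"` for the TTD mean.
#' @return Named list `mean_peak_amplitude`, `mean_ttd`, `units`,
#'   `n_peaks`, `n_ttd`. Values are `NA` for an empty profile.
#' @export
summarize_dynamics <- function(profile, tr_seconds = NULL,
                               units = c("frames", "seconds")) {
  stopifnot(inherits(profile, "event_profile"))
  units <- match.arg(units)
  tr <- tr_seconds %||% profile$tr_seconds
  ttd <- profile$mean_ttd
  if (units == "seconds") {
    if (is.null(tr) || is.na(tr))
      stop_edgedyn("tr_seconds required for units = 'seconds'")
    ttd <- ttd * tr
  }
  list(mean_peak_amplitude = profile$mean_peak_amplitude,
       mean_ttd = ttd, units = units,
       n_peaks = length(profile$peak_frames),
       n_ttd = length(profile$ttd_frames))
}

#' Per-subject dynamics table for a set of series
#'
#' Convenience wrapper: ETS -> RSS -> event profile for each subject,
#' returning one row per subject.
#'
#' @param series_list List of [roi_time_series()] objects.
#' @return data.frame with columns `subject_id`, `n_troughs`, `n_peaks`,
#'   `mean_peak_amplitude`, `mean_ttd_frames`, `mean_ttd_seconds`.
#' @export
dynamics_table <- function(series_list) {
  rows <- lapply(series_list, function(s) {
    prof <- event_profile(compute_rss(compute_ets(zscore_series(s))))
    data.frame(subject_id = s$subject_id,
               n_troughs = length(prof$trough_frames),
               n_peaks = length(prof$peak_frames),
               mean_peak_amplitude = prof$mean_peak_amplitude,
               mean_ttd_frames = prof$mean_ttd,
               mean_ttd_seconds = prof$mean_ttd * s$tr_seconds,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
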