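# Synthetic multi-site two-group cohort generator. BOLD series are white
# Gaussian noise plus community-structured co-fluctuation events whose rate
# and amplitude differ by group; per-site additive/multiplicative effects
# emulate scanner differences. Stands in for restricted clinical rs-fMRI.

#' Specification of a synthetic cohort
#'
#' Defaults describe the package's reference world: two balanced groups
#' ("SCD"-like with rarer, weaker co-fluctuation events; "HC"-like with more
#' frequent, stronger ones), 20 regions in 4 equal communities, 200 frames
#' at TR 3 s, unit noise, and mild two-site location/scale effects.
#'
#' @param n_per_group Subjects per group.
#' @param n_roi Number of regions.
#' @param n_frames Frames per subject (T, >= 20).
#' @param tr_seconds Repetition time in seconds.
#' @param n_communities Number of disjoint equal-size communities
#'   (loadings 1 inside, 0 outside).
#' @param event_rate_per_group Events per frame for (group1, group2); mean
#'   inter-event interval is 1/rate frames. Must lie in (0, 1).
#' @param event_amplitude_per_group Event amplitude added to member
#'   regions, per group.
#' @param noise_sd Baseline Gaussian noise SD.
#' @param n_sites Number of acquisition sites (round-robin assignment).
#' @param site_shift_sd SD of the per-ROI additive site shift.
#' @param site_scale_sd SD (log scale) of the per-ROI multiplicative site
#'   factor, exp(N(0, sd)).
#' @param interval_model `"geometric"` (memoryless renewal, default) or
#'   `"fixed"` (deterministic spacing round(1/rate), for exact tests).
#' @param event_duration Temporal extent of one event in frames (default
#'   5, i.e. ~15 s at TR 3 s): the amplitude is spread over a raised-cosine
#'   (Hann) envelope centred on the event frame, emulating the
#'   multi-second extent of hemodynamic co-fluctuation events without
#'   modelling an explicit HRF.
#' @param bandpass Length-2 passband in Hz applied to the baseline noise
#'   (not the events) by Fourier masking, emulating the slow spectral
#'   content of hemodynamically smoothed, band-pass-filtered BOLD; the
#'   gain is corrected so the filtered noise keeps marginal SD `noise_sd`.
#'   Default `c(0.01, 0.03)`. `NULL` leaves the noise white.
#' @param apoe_probs Multinomial probabilities of APOE e4 allele count
#'   (0, 1, 2).
#' @param mmse_slope Slope linking a subject's event amplitude to the MMSE
#'   mean (0 = uncorrelated).
#' @param group_labels Length-2 character vector of group names.
#' @param seed Integer seed; the whole cohort is a deterministic function
#'   of the spec.
#' @return Validated list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = 20L, n_roi = 20L, n_frames = 200L,
                        tr_seconds = 3.0, n_communities = 4L,
                        event_rate_per_group = c(0.12, 0.20),
                        event_amplitude_per_group = c(2, 3),
                        noise_sd = 1.0, n_sites = 2L,
                        site_shift_sd = 0.1, site_scale_sd = 0.1,
                        interval_model = c("geometric", "fixed"),
                        event_duration = 5L,
                        bandpass = c(0.01, 0.03),
                        apoe_probs = c(0.66, 0.30, 0.04),
                        mmse_slope = 0,
                        group_labels = c("SCD", "HC"),
                        seed = 1L) {
  spec <- list(
    n_per_group = check_count(n_per_group, "n_per_group"),
    n_roi = check_count(n_roi, "n_roi", 2L),
    n_frames = check_count(n_frames, "n_frames", 20L),
    tr_seconds = check_positive(tr_seconds, "tr_seconds"),
    n_communities = check_count(n_communities, "n_communities"),
    event_rate_per_group = as.numeric(event_rate_per_group),
    event_amplitude_per_group = as.numeric(event_amplitude_per_group),
    noise_sd = check_positive(noise_sd, "noise_sd", strict = FALSE),
    n_sites = check_count(n_sites, "n_sites"),
    site_shift_sd = check_positive(site_shift_sd, "site_shift_sd", strict = FALSE),
    site_scale_sd = check_positive(site_scale_sd, "site_scale_sd", strict = FALSE),
    interval_model = match.arg(interval_model),
    event_duration = check_count(event_duration, "event_duration"),
    bandpass = if (is.null(bandpass)) NULL else as.numeric(bandpass),
    apoe_probs = as.numeric(apoe_probs),
    mmse_slope = as.numeric(mmse_slope),
    group_labels = as.character(group_labels),
    seed = check_count(seed, "seed", min = 0L))
  if (spec$n_roi < spec$n_communities)
    stop_edgedyn("'n_roi' (%d) must be >= 'n_communities' (%d)",
                 spec$n_roi, spec$n_communities)
  if (length(spec$group_labels) != 2L || anyDuplicated(spec$group_labels))
    stop_edgedyn("'group_labels' must be 2 distinct labels")
  for (f in c("event_rate_per_group", "event_amplitude_per_group"))
    if (length(spec[[f]]) != 2L)
      stop_edgedyn("'%s' must have one value per group", f)
  if (any(spec$event_rate_per_group <= 0 | spec$event_rate_per_group >= 1))
    stop_edgedyn("'event_rate_per_group' values must lie in (0, 1)")
  if (any(spec$event_amplitude_per_group < 0))
    stop_edgedyn("'event_amplitude_per_group' values must be >= 0")
  if (!is.null(spec$bandpass) &&
      (length(spec$bandpass) != 2L || any(spec$bandpass <= 0) ||
       spec$bandpass[1L] >= spec$bandpass[2L]))
    stop_edgedyn("'bandpass' must be increasing positive frequencies (Hz) or NULL")
  if (length(spec$apoe_probs) != 3L || any(spec$apoe_probs < 0) ||
      abs(sum(spec$apoe_probs) - 1) > 1e-8)
    stop_edgedyn("'apoe_probs' must be 3 probabilities summing to 1")
  structure(spec, class = "cohort_spec")
}

# disjoint near-equal-size communities in contiguous blocks
community_assignment <- function(n_roi, n_communities) {
  sort(rep_len(seq_len(n_communities), n_roi))
}

# per-site ROI-wise additive shift and multiplicative scale
make_site_effects <- function(spec) {
  lapply(seq_len(spec$n_sites), function(s)
    list(shift = stats::rnorm(spec$n_roi, 0, spec$site_shift_sd),
         scale = exp(stats::rnorm(spec$n_roi, 0, spec$site_scale_sd))))
}

# Fourier band-pass by masking DFT bins outside [lo, hi] Hz (DC always
# removed), with gain correction so white-noise input keeps its marginal
# SD. Rows = regions, columns = frames.
bandpass_rows <- function(x, tr_seconds, band) {
  t_n <- ncol(x)
  freq <- (seq_len(t_n) - 1L) / (t_n * tr_seconds)
  freq <- pmin(freq, 1 / tr_seconds - freq)       # fold to [0, Nyquist]
  keep <- freq >= band[1L] & freq <= band[2L]
  if (!any(keep))
    stop_edgedyn("bandpass [%g, %g] Hz keeps no frequency bin at T=%d, TR=%g",
                 band[1L], band[2L], t_n, tr_seconds)
  gain <- 1 / sqrt(sum(keep) / t_n)
  t(apply(x, 1L, function(row) {
    f <- stats::fft(row)
    f[!keep] <- 0
    Re(stats::fft(f, inverse = TRUE)) / t_n * gain
  }))
}

sample_event_frames <- function(spec, rate) {
  if (spec$interval_model == "fixed") {
    step <- max(1L, as.integer(round(1 / rate)))
    frames <- seq.int(step, spec$n_frames, by = step)
  } else {
    # renewal process: intervals 1 + Geom(rate), mean 1/rate
    frames <- integer(0)
    t <- 0L
    repeat {
      t <- t + 1L + stats::rgeom(1L, rate)
      if (t > spec$n_frames) break
      frames <- c(frames, t)
    }
  }
  frames
}

#' Generate one synthetic subject
#'
#' Baseline N(0, noise_sd) noise in every region; at each event frame
#' (renewal process with group-specific mean inter-event interval 1/rate),
#' the group's event amplitude is added to all members of one randomly
#' chosen community. The site effect is then applied per region as
#' `scale * x + shift`. Consumes the current RNG stream; seed externally
#' or via [generate_cohort()].
#'
#' @param spec A [cohort_spec()].
#' @param group Group label (one of `spec$group_labels`).
#' @param site Site index in 1..n_sites.
#' @param site_effects Optional list from the cohort-level site draw; when
#'   `NULL`, fresh site effects are drawn.
#' @param subject_id Subject identifier.
#' @return List with `series` ([roi_time_series()]) and `truth` (list:
#'   `event_frames`, `event_amplitudes`, `event_communities`, `group`,
#'   `site`).
#' @export
generate_subject <- function(spec, group, site = 1L, site_effects = NULL,
                             subject_id = "subject") {
  stopifnot(inherits(spec, "cohort_spec"))
  gi <- match(group, spec$group_labels)
  if (is.na(gi)) stop_edgedyn("unknown group '%s'", group)
  site <- check_count(site, "site")
  if (site > spec$n_sites) stop_edgedyn("site %d > n_sites %d", site, spec$n_sites)
  if (is.null(site_effects)) site_effects <- make_site_effects(spec)
  rate <- spec$event_rate_per_group[gi]
  amp <- spec$event_amplitude_per_group[gi]
  comm <- community_assignment(spec$n_roi, spec$n_communities)
  x <- matrix(stats::rnorm(spec$n_roi * spec$n_frames, 0, spec$noise_sd),
              spec$n_roi, spec$n_frames)
  if (!is.null(spec$bandpass))
    x <- bandpass_rows(x, spec$tr_seconds, spec$bandpass)
  frames <- sample_event_frames(spec, rate)
  comms <- if (length(frames))
    sample.int(spec$n_communities, length(frames), replace = TRUE)
  else integer(0)
  # raised-cosine event envelope centred on the event frame
  w <- spec$event_duration
  off <- seq.int(-((w - 1L) %/% 2L), (w - 1L) - (w - 1L) %/% 2L)
  env <- 0.5 * (1 + cos(2 * pi * off / (w + 1L)))
  for (k in seq_along(frames)) {
    fr <- frames[k] + off
    ok <- fr >= 1L & fr <= spec$n_frames
    rows <- comm == comms[k]
    x[rows, fr[ok]] <- x[rows, fr[ok]] +
      amp * rep(env[ok], each = sum(rows))
  }
  se <- site_effects[[site]]
  x <- x * se$scale + se$shift
  series <- roi_time_series(x, subject_id = subject_id,
                            tr_seconds = spec$tr_seconds)
  list(series = series,
       truth = list(event_frames = frames,
                    event_amplitudes = rep(amp, length(frames)),
                    event_communities = comms,
                    group = spec$group_labels[gi], site = site))
}

#' Generate a full synthetic cohort
#'
#' Subjects (n_per_group per group, groups interleaved) are assigned
#' round-robin to sites. Metadata includes simulated APOE e4 allele counts
#' (multinomial) and MMSE / MoCA scores (Gaussian, truncated to plausible
#' ranges; MMSE mean optionally tied to the subject's event amplitude via
#' `mmse_slope`). Deterministic given the spec (including its seed).
#'
#' @param spec A [cohort_spec()].
#' @return Object of class `synthetic_cohort`: `series` (list of
#'   [roi_time_series()]), `metadata` (data.frame: subject_id, group, site,
#'   apoe4_count, mmse, moca), `truth` (per-subject event lists), `spec`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    site_effects <- make_site_effects(spec)
    n <- 2L * spec$n_per_group
    groups <- rep(spec$group_labels, spec$n_per_group)   # interleaved
    # round-robin to sites within each group, so no site is single-group
    sites <- integer(n)
    for (g in spec$group_labels)
      sites[groups == g] <- rep_len(seq_len(spec$n_sites), sum(groups == g))
    ids <- sprintf("sub-%03d", seq_len(n))
    series <- vector("list", n)
    truth <- vector("list", n)
    for (s in seq_len(n)) {
      subj <- generate_subject(spec, groups[s], sites[s], site_effects, ids[s])
      series[[s]] <- subj$series
      truth[[s]] <- subj$truth
    }
    names(series) <- names(truth) <- ids
    amp <- spec$event_amplitude_per_group[match(groups, spec$group_labels)]
    mmse <- stats::rnorm(n, 29.1 + spec$mmse_slope * (amp - mean(amp)), 1.1)
    mmse <- pmin(pmax(round(mmse), 24), 30)
    moca <- pmin(pmax(round(stats::rnorm(n, 26.3, 2.2)), 18), 30)
    apoe <- sample(0:2, n, replace = TRUE, prob = spec$apoe_probs)
    metadata <- data.frame(subject_id = ids, group = groups, site = sites,
                           apoe4_count = apoe, mmse = mmse, moca = moca,
                           stringsAsFactors = FALSE)
    structure(list(series = series, metadata = metadata, truth = truth,
                   spec = spec),
              class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d subjects (%s), %d ROIs x %d frames, %d site(s)\n",
              nrow(x$metadata),
              paste(sprintf("%d %s", table(x$metadata$group)[x$spec$group_labels],
                            x$spec$group_labels), collapse = " + "),
              x$spec$n_roi, x$spec$n_frames, x$spec$n_sites))
  invisible(x)
}
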