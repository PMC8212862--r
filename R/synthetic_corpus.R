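#' Rhythm specification for synthetic RR-interval generation
#'
#' Describes the beat-to-beat statistics of one synthetic recording. Three
#' rhythm kinds are supported: `"sinus"` (regular rhythm with small
#' respiratory-scale variability), `"af"` (atrial fibrillation: markedly
#' irregular RR intervals, optionally confined to one episode), and
#' `"ectopic-sinus"` (sinus rhythm interrupted by premature beats with
#' compensatory pauses).
#'
#' @param kind one of `"sinus"`, `"af"`, `"ectopic-sinus"`.
#' @param mean_rr mean RR interval in milliseconds (> 0).
#' @param rr_sd standard deviation of the RR intervals in milliseconds (>= 0).
#'   For `"af"` the effective sd is at least `0.15 * mean_rr`.
#' @param af_episode_onset,af_episode_offset optional episode bounds in
#'   seconds for an AF episode embedded in sinus rhythm. When omitted and
#'   `kind = "af"`, the whole recording is AF. An episode must last at least
#'   10 s, matching the rule by which a recording is labeled AF.
#' @param ectopy_rate per-beat probability of an ectopic (premature) beat,
#'   used when `kind = "ectopic-sinus"`.
#'
#' @return an object of class `rhythm_spec`.
#' @export
rhythm_spec <- function(kind = c("sinus", "af", "ectopic-sinus"),
                        mean_rr = 800, rr_sd = 30,
                        af_episode_onset = NULL, af_episode_offset = NULL,
                        ectopy_rate = 0) {
  kind <- match.arg(kind)
  assert_that(mean_rr > 0, "mean_rr must be positive")
  assert_that(rr_sd >= 0, "rr_sd must be non-negative")
  assert_that(ectopy_rate >= 0 && ectopy_rate <= 1,
              "ectopy_rate must be in [0, 1]")
  if (!is.null(af_episode_onset) || !is.null(af_episode_offset)) {
    assert_that(!is.null(af_episode_onset) && !is.null(af_episode_offset),
                "both af_episode_onset and af_episode_offset are required")
    assert_that(af_episode_offset - af_episode_onset >= 10,
                "an AF episode must last at least 10 s")
  }
  structure(list(kind = kind, mean_rr = mean_rr, rr_sd = rr_sd,
                 af_episode_onset = af_episode_onset,
                 af_episode_offset = af_episode_offset,
                 ectopy_rate = ectopy_rate),
            class = "rhythm_spec")
}

#' Transient-noise specification
#'
#' Rates and amplitude ranges of the three artifact families injected into
#' synthetic recordings: short biphasic spikes (electrode contact), baseline
#' steps with exponential recovery (electrode movement), and band-limited
#' 20--100 Hz bursts (muscle noise). Counts per recording are Poisson with the
#' given means.
#'
#' @param spike_rate,step_rate,burst_rate mean number of events per recording.
#' @param spike_amp_range spike amplitude as a multiple of the R-wave
#'   amplitude, `c(lo, hi)`.
#' @param step_amp_range baseline-step amplitude in millivolts, `c(lo, hi)`.
#' @param burst_amp_range burst peak amplitude as a multiple of the R-wave
#'   amplitude, `c(lo, hi)` with `lo >= 1` recommended so bursts defeat the
#'   QRS detector.
#' @param burst_duration_range burst duration in seconds, `c(lo, hi)`.
#'
#' @return an object of class `noise_spec`.
#' @export
noise_spec <- function(spike_rate = 2, step_rate = 0.5, burst_rate = 0.5,
                       spike_amp_range = c(1, 3),
                       step_amp_range = c(0.5, 2),
                       burst_amp_range = c(1, 2),
                       burst_duration_range = c(0.3, 1)) {
  assert_that(all(c(spike_rate, step_rate, burst_rate) >= 0),
              "artifact rates must be non-negative")
  for (r in list(spike_amp_range, step_amp_range, burst_amp_range,
                 burst_duration_range)) {
    assert_that(length(r) == 2 && all(r > 0) && r[1] <= r[2],
                "amplitude/duration ranges must be positive c(lo, hi)")
  }
  structure(list(spike_rate = spike_rate, step_rate = step_rate,
                 burst_rate = burst_rate, spike_amp_range = spike_amp_range,
                 step_amp_range = step_amp_range,
                 burst_amp_range = burst_amp_range,
                 burst_duration_range = burst_duration_range),
            class = "noise_spec")
}

# Exact truncated-normal sampler via inverse-CDF; degenerate sd gives the mean.
rtruncnorm <- function(n, mean, sd, lo, hi) {
  if (sd <= 0) return(rep(mean, n))
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

#' Generate a synthetic RR-interval beat-time series
#'
#' Draws successive RR intervals according to a [rhythm_spec()] and
#' accumulates them into strictly increasing beat times covering the
#' recording. Sinus intervals follow a normal law truncated to
#' `[0.5, 1.5] * mean_rr`; AF intervals follow a normal law with sd at least
#' `0.15 * mean_rr`, truncated to `[300, 1800]` ms. With probability
#' `ectopy_rate` a beat is replaced by a premature beat (interval scaled by
#' 0.6) followed by a compensatory pause (interval scaled by 1.4). When the
#' spec carries an AF episode, intervals inside the episode follow the AF law
#' and intervals outside follow the sinus law.
#'
#' @param spec a [rhythm_spec()].
#' @param duration recording duration in seconds (> 0).
#' @param seed integer seed; the output is a pure function of the arguments.
#'
#' @return numeric vector of beat times in milliseconds, strictly increasing,
#'   all within `[0, duration * 1000)`.
#' @export
gen_rr_series <- function(spec, duration = 30, seed = 1L) {
  assert_that(inherits(spec, "rhythm_spec"), "spec must be a rhythm_spec")
  assert_that(duration > 0, "duration must be positive")
  dur_ms <- duration * 1000
  ep <- if (!is.null(spec$af_episode_onset)) {
    c(spec$af_episode_onset, spec$af_episode_offset) * 1000
  } else NULL
  in_af <- function(t_ms) {
    if (spec$kind != "af") return(FALSE)
    if (is.null(ep)) return(TRUE)
    t_ms >= ep[1] && t_ms < ep[2]
  }
  with_seed(seed, {
    times <- numeric(0)
    t <- stats::runif(1, 0, spec$mean_rr)
    pending <- numeric(0)   # intervals already committed (ectopic couplets)
    while (t < dur_ms) {
      times <- c(times, t)
      if (length(pending) > 0) {
        iv <- pending[1]
        pending <- pending[-1]
      } else if (in_af(t)) {
        iv <- rtruncnorm(1, spec$mean_rr, max(spec$rr_sd, 0.15 * spec$mean_rr),
                         300, 1800)
      } else {
        iv <- rtruncnorm(1, spec$mean_rr, spec$rr_sd,
                         0.5 * spec$mean_rr, 1.5 * spec$mean_rr)
        if (spec$kind == "ectopic-sinus" && spec$ectopy_rate > 0 &&
            stats::runif(1) < spec$ectopy_rate) {
          pending <- 1.4 * iv
          iv <- 0.6 * iv
        }
      }
      t <- t + iv
    }
    times
  })
}

#' Default PQRST morphology
#'
#' Gaussian wave components used by [render_ecg()]: amplitude (mV), center
#' offset from the R peak (ms), and width (ms) for the P, Q, R, S and T
#' waves.
#'
#' @return named list of wave parameter vectors.
#' @export
default_morphology <- function() {
  list(P = c(amp = 0.12, mu = -180, sigma = 25),
       Q = c(amp = -0.10, mu = -25, sigma = 8),
       R = c(amp = 1.00, mu = 0, sigma = 12),
       S = c(amp = -0.15, mu = 25, sigma = 8),
       T = c(amp = 0.30, mu = 200, sigma = 60))
}

#' Render a synthetic single-lead ECG from beat times
#'
#' Renders each beat as a sum-of-Gaussians PQRST template, adds low-frequency
#' baseline wander (<= 0.15 Hz sinusoid) and white measurement noise, and,
#' within AF intervals, suppresses the P wave and adds a small 4--12 Hz
#' fibrillatory baseline. The recording-level rhythm label is AF if and only
#' if the summed AF-interval duration is at least 10 s.
#'
#' @param beat_times sorted beat times in milliseconds.
#' @param spec the [rhythm_spec()] used to generate the beats (supplies the
#'   AF intervals).
#' @param fs sampling rate in Hz (default 1000).
#' @param duration recording duration in seconds.
#' @param seed integer seed for wander, noise and fibrillatory phases.
#' @param subject_id,recording_id identifiers carried on the recording.
#' @param morphology optional template override, see `default_morphology`.
#' @param wander_amp baseline-wander amplitude in mV.
#' @param noise_sd white-noise standard deviation in mV (<= 0.02).
#'
#' @return a list with components `recording` (class `ecg_recording`:
#'   `subject_id`, `recording_id`, `fs`, `samples`, `duration`, `r_amp`) and
#'   `truth` (class `beat_truth`: `beat_times`, `rhythm_label`, `noise_times`,
#'   `af_intervals`).
#' @export
render_ecg <- function(beat_times, spec, fs = 1000, duration = 30, seed = 1L,
                       subject_id = "S0001", recording_id = "R0001",
                       morphology = default_morphology(),
                       wander_amp = 0.1, noise_sd = 0.01) {
  assert_that(!is.unsorted(beat_times, strictly = TRUE) || length(beat_times) < 2,
              "beat_times must be strictly increasing")
  assert_that(fs > 0, "fs must be positive")
  assert_that(noise_sd <= 0.02, "noise_sd must not exceed 0.02 mV")
  n <- round(fs * duration)
  t_ms <- (seq_len(n) - 1) / fs * 1000

  af_intervals <- if (spec$kind == "af") {
    if (is.null(spec$af_episode_onset)) list(c(0, duration)) else
      list(c(spec$af_episode_onset, min(spec$af_episode_offset, duration)))
  } else list()

  in_af <- rep(FALSE, n)
  for (iv in af_intervals) {
    in_af <- in_af | (t_ms >= iv[1] * 1000 & t_ms < iv[2] * 1000)
  }

  x <- with_seed(seed, {
    sig <- numeric(n)
    for (b in beat_times) {
      b_af <- length(af_intervals) > 0 &&
        any(vapply(af_intervals, function(iv)
          b >= iv[1] * 1000 && b < iv[2] * 1000, logical(1)))
      for (wname in names(morphology)) {
        if (wname == "P" && b_af) next
        w <- morphology[[wname]]
        lo <- max(1L, floor((b + w["mu"] - 4 * w["sigma"]) / 1000 * fs) + 1L)
        hi <- min(n, ceiling((b + w["mu"] + 4 * w["sigma"]) / 1000 * fs) + 1L)
        if (lo > hi) next
        idx <- lo:hi
        sig[idx] <- sig[idx] +
          w["amp"] * exp(-((t_ms[idx] - b - w["mu"])^2) / (2 * w["sigma"]^2))
      }
    }
    # fibrillatory baseline inside AF intervals
    if (any(in_af)) {
      f1 <- stats::runif(1, 4, 12); f2 <- stats::runif(1, 4, 12)
      p1 <- stats::runif(1, 0, 2 * pi); p2 <- stats::runif(1, 0, 2 * pi)
      fib <- 0.05 * sin(2 * pi * f1 * t_ms / 1000 + p1) +
             0.03 * sin(2 * pi * f2 * t_ms / 1000 + p2)
      sig[in_af] <- sig[in_af] + fib[in_af]
    }
    fw <- stats::runif(1, 0.05, 0.15)
    pw <- stats::runif(1, 0, 2 * pi)
    sig <- sig + wander_amp * sin(2 * pi * fw * t_ms / 1000 + pw)
    sig + stats::rnorm(n, 0, noise_sd)
  })

  af_total <- sum(vapply(af_intervals, function(iv) iv[2] - iv[1], numeric(1)))
  truth <- structure(list(beat_times = as.numeric(beat_times),
                          rhythm_label = if (af_total >= 10) "AF" else "non-AF",
                          noise_times = numeric(0),
                          af_intervals = af_intervals),
                     class = "beat_truth")
  rec <- structure(list(subject_id = subject_id, recording_id = recording_id,
                        fs = fs, samples = x, duration = duration,
                        r_amp = unname(morphology$R["amp"])),
                   class = "ecg_recording")
  list(recording = rec, truth = truth)
}

#' @export
print.ecg_recording <- function(x, ...) {
  cat(sprintf("<ecg_recording %s/%s: %.0f Hz, %.1f s, %d samples>\n",
              x$subject_id, x$recording_id, x$fs, x$duration,
              length(x$samples)))
  invisible(x)
}

#' Inject transient-noise artifacts into a rendered recording
#'
#' Adds Poisson-count spikes, baseline steps, and muscle-noise bursts to the
#' signal. Spikes are 10--50 ms biphasic deflections (signal altered only
#' within +/- 50 ms of the center); steps are baseline offsets decaying
#' exponentially with a 0.2--1 s time constant; bursts are band-limited
#' 20--100 Hz noise at or above the R-wave amplitude. True beat times are
#' never moved or deleted; `noise_times` records every artifact center.
#'
#' @param rec an `ecg_recording`.
#' @param truth the matching `beat_truth`.
#' @param noise a [noise_spec()].
#' @param seed integer seed.
#'
#' @return a list `(recording, truth)` with the noisy signal and updated
#'   `noise_times`.
#' @export
inject_transients <- function(rec, truth, noise, seed = 1L) {
  assert_that(inherits(noise, "noise_spec"), "noise must be a noise_spec")
  n <- length(rec$samples)
  fs <- rec$fs
  dur_ms <- rec$duration * 1000
  r_amp <- rec$r_amp %||% 1
  t_ms <- (seq_len(n) - 1) / fs * 1000

  out <- with_seed(seed, {
    x <- rec$samples
    centers <- numeric(0)
    n_spike <- stats::rpois(1, noise$spike_rate)
    n_step <- stats::rpois(1, noise$step_rate)
    n_burst <- stats::rpois(1, noise$burst_rate)

    if (n_spike > 0) {
      for (i in seq_len(n_spike)) {
        c0 <- stats::runif(1, 100, dur_ms - 100)
        w <- stats::runif(1, 10, 50)
        amp <- stats::runif(1, noise$spike_amp_range[1],
                            noise$spike_amp_range[2]) * r_amp
        sgn <- sample(c(-1, 1), 1)
        # strictly within +/- 50 ms of the center
        lo <- max(1L, ceiling((c0 - 50) * fs / 1000) + 1L)
        hi <- min(n, floor((c0 + 50) * fs / 1000) + 1L)
        idx <- lo:hi
        d <- t_ms[idx] - c0
        s <- exp(-((d + w / 4)^2) / (2 * (w / 6)^2)) -
             exp(-((d - w / 4)^2) / (2 * (w / 6)^2))
        x[idx] <- x[idx] + sgn * amp * s
        centers <- c(centers, c0)
      }
    }
    if (n_step > 0) {
      for (i in seq_len(n_step)) {
        c0 <- stats::runif(1, 100, dur_ms - 100)
        amp <- stats::runif(1, noise$step_amp_range[1], noise$step_amp_range[2]) *
          sample(c(-1, 1), 1)
        tau <- stats::runif(1, 0.2, 1) * 1000
        idx <- which(t_ms >= c0)
        x[idx] <- x[idx] + amp * exp(-(t_ms[idx] - c0) / tau)
        centers <- c(centers, c0)
      }
    }
    if (n_burst > 0) {
      bp <- signal::butter(2, c(20, 100) / (fs / 2), type = "pass")
      for (i in seq_len(n_burst)) {
        dur_b <- stats::runif(1, noise$burst_duration_range[1],
                              noise$burst_duration_range[2]) * 1000
        c0 <- stats::runif(1, dur_b / 2 + 100, dur_ms - dur_b / 2 - 100)
        amp <- stats::runif(1, noise$burst_amp_range[1],
                            noise$burst_amp_range[2]) * r_amp
        lo <- max(1L, floor((c0 - dur_b / 2) / 1000 * fs) + 1L)
        hi <- min(n, ceiling((c0 + dur_b / 2) / 1000 * fs) + 1L)
        idx <- lo:hi
        raw <- stats::rnorm(length(idx))
        b <- as.numeric(signal::filtfilt(bp, raw))
        b <- b / max(abs(b)) * amp
        x[idx] <- x[idx] + b
        centers <- c(centers, c0)
      }
    }
    list(x = x, centers = sort(centers))
  })

  rec$samples <- out$x
  truth$noise_times <- sort(c(truth$noise_times, out$centers))
  list(recording = rec, truth = truth)
}

#' Build a synthetic screening corpus
#'
#' Assembles a multi-subject corpus of rendered 30-s recordings with full
#' beat-level ground truth. `round(n_subjects * af_prevalence)` subjects are
#' designated AF; each AF subject receives at least `min_af_recordings`
#' AF-labeled recordings (fully-AF or containing one embedded episode of at
#' least 10 s). A fraction of non-AF subjects carries an ectopic-sinus rhythm
#' to emulate the non-AF irregular rhythms seen in screening. Every recording
#' receives transient noise per `noise`.
#'
#' @param n_subjects number of subjects (> 0).
#' @param recordings_per_subject recordings per subject.
#' @param af_prevalence fraction of subjects with AF, in `[0, 1]`.
#' @param noise a [noise_spec()] applied to every recording.
#' @param seed integer master seed.
#' @param duration,fs recording duration (s) and sampling rate (Hz).
#' @param min_af_recordings minimum number of AF recordings per AF subject.
#' @param af_recording_frac binomial fraction of an AF subject's recordings
#'   that are AF (floored at `min_af_recordings`).
#' @param ectopic_frac fraction of non-AF subjects with ectopic-sinus rhythm.
#' @param ectopy_rate per-beat ectopy probability for those subjects.
#'
#' @return an object of class `af_corpus`: `recordings` (list of
#'   `(recording, truth)` pairs), `subjects` (named list mapping subject id to
#'   recording ids), `af_subjects`, and the generating `seed`.
#' @export
build_corpus <- function(n_subjects, recordings_per_subject = 26,
                         af_prevalence = 0.024,
                         noise = noise_spec(), seed = 1L,
                         duration = 30, fs = 1000,
                         min_af_recordings = 1, af_recording_frac = 0.5,
                         ectopic_frac = 0.1, ectopy_rate = 0.1) {
  assert_that(n_subjects > 0, "n_subjects must be positive")
  assert_that(af_prevalence >= 0 && af_prevalence <= 1,
              "af_prevalence must be in [0, 1]")
  n_af <- round(n_subjects * af_prevalence)

  plan <- with_seed(seed, {
    af_ids <- sort(sample.int(n_subjects, n_af))
    mean_rr <- stats::runif(n_subjects, 700, 1000)
    ect <- stats::runif(n_subjects) < ectopic_frac
    list(af_ids = af_ids, mean_rr = mean_rr, ect = ect)
  })

  recordings <- vector("list", n_subjects * recordings_per_subject)
  subjects <- list()
  af_subjects <- character(0)
  k <- 0L
  for (s in seq_len(n_subjects)) {
    sid <- sprintf("S%04d", s)
    is_af_subject <- s %in% plan$af_ids
    rec_ids <- character(recordings_per_subject)
    sseed <- child_seed(seed, s * 1000L)
    af_recs <- integer(0)
    if (is_af_subject) {
      af_subjects <- c(af_subjects, sid)
      n_af_rec <- with_seed(sseed, {
        max(min_af_recordings,
            stats::rbinom(1, recordings_per_subject, af_recording_frac))
      })
      n_af_rec <- min(n_af_rec, recordings_per_subject)
      af_recs <- with_seed(sseed + 1L,
                           sort(sample.int(recordings_per_subject, n_af_rec)))
    }
    for (r in seq_len(recordings_per_subject)) {
      rid <- sprintf("%s-R%03d", sid, r)
      rec_ids[r] <- rid
      rseed <- child_seed(seed, s * 1000L + r)
      if (r %in% af_recs) {
        full <- with_seed(rseed + 7L, stats::runif(1) < 0.5)
        if (full || duration <= 20) {
          spec <- rhythm_spec("af", mean_rr = min(plan$mean_rr[s], 800),
                              rr_sd = 150)
        } else {
          ep <- with_seed(rseed + 8L, {
            len <- stats::runif(1, 10, min(20, duration))
            on <- stats::runif(1, 0, duration - len)
            c(on, on + len)
          })
          spec <- rhythm_spec("af", mean_rr = min(plan$mean_rr[s], 800),
                              rr_sd = 150,
                              af_episode_onset = ep[1],
                              af_episode_offset = ep[2])
        }
      } else if (plan$ect[s]) {
        spec <- rhythm_spec("ectopic-sinus", mean_rr = plan$mean_rr[s],
                            rr_sd = 30, ectopy_rate = ectopy_rate)
      } else {
        spec <- rhythm_spec("sinus", mean_rr = plan$mean_rr[s], rr_sd = 30)
      }
      beats <- gen_rr_series(spec, duration = duration, seed = rseed)
      rendered <- render_ecg(beats, spec, fs = fs, duration = duration,
                             seed = rseed + 1L, subject_id = sid,
                             recording_id = rid)
      noisy <- inject_transients(rendered$recording, rendered$truth, noise,
                                 seed = rseed + 2L)
      k <- k + 1L
      recordings[[k]] <- noisy
    }
    subjects[[sid]] <- rec_ids
  }
  structure(list(recordings = recordings, subjects = subjects,
                 af_subjects = af_subjects, seed = as.integer(seed)),
            class = "af_corpus")
}

#' @export
print.af_corpus <- function(x, ...) {
  cat(sprintf("<af_corpus: %d subjects, %d recordings, %d AF subjects>\n",
              length(x$subjects), length(x$recordings),
              length(x$af_subjects)))
  invisible(x)
}

#' Corpus manifest
#'
#' One row per recording: subject, recording, rhythm label, beat and noise
#' counts.
#'
#' @param corpus an `af_corpus`.
#' @return a data.frame with columns `subject_id`, `recording_id`,
#'   `rhythm_label`, `n_beats`, `n_noise_events`.
#' @export
corpus_manifest <- function(corpus) {
  assert_that(inherits(corpus, "af_corpus"), "corpus must be an af_corpus")
  do.call(rbind, lapply(corpus$recordings, function(r) {
    data.frame(subject_id = r$recording$subject_id,
               recording_id = r$recording$recording_id,
               rhythm_label = r$truth$rhythm_label,
               n_beats = length(r$truth$beat_times),
               n_noise_events = length(r$truth$noise_times),
               stringsAsFactors = FALSE)
  }))
}

#' Label detector events against beat-level ground truth
#'
#' A detection is labeled a true beat if it is the nearest detection, within
#' `tolerance`, to at least one true beat; every other detection is a false
#' detection. Each true beat therefore matches at most one detection.
#'
#' @param detection_times sorted detection times in milliseconds.
#' @param truth a `beat_truth`.
#' @param tolerance matching tolerance in milliseconds (default 75, half a
#'   conservative QRS refractory period).
#'
#' @return character vector in `{"true_beat", "false_detection"}`, aligned
#'   with `detection_times`.
#' @export
label_events <- function(detection_times, truth, tolerance = 75) {
  assert_that(tolerance >= 0, "tolerance must be non-negative")
  assert_that(!is.unsorted(detection_times),
              "detection_times must be sorted")
  labels <- rep("false_detection", length(detection_times))
  beats <- truth$beat_times
  if (length(detection_times) == 0 || length(beats) == 0) return(labels)
  for (b in beats) {
    d <- abs(detection_times - b)
    j <- which.min(d)
    if (d[j] <= tolerance) labels[j] <- "true_beat"
  }
  labels
}
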