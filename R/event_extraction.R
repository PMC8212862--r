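#' Reference QRS detector
#'
#' A deliberately simple energy-based QRS detector: band-pass the signal to
#' 5--40 Hz (zero-phase Butterworth), square it, threshold the envelope at an
#' adaptive multiple of the running median absolute amplitude, and enforce a
#' 250-ms refractory period (within the refractory window the larger peak
#' wins). Its simplicity is intentional: transient noise produces false
#' detections, which is precisely the failure mode the event-quality CNN is
#' trained to identify.
#'
#' @param rec an `ecg_recording` (fs >= 250 Hz).
#' @param factor adaptive-threshold multiple of the running median absolute
#'   band-passed amplitude.
#' @param refractory refractory period in milliseconds.
#' @param median_window width of the running-median window in seconds; kept
#'   long so that a transient burst cannot inflate its own threshold.
#'
#' @return sorted numeric vector of detection times in milliseconds.
#' @export
detect_qrs <- function(rec, factor = 5, refractory = 250, median_window = 8) {
  assert_that(inherits(rec, "ecg_recording"), "rec must be an ecg_recording")
  assert_that(rec$fs >= 250, "sampling rate must be at least 250 Hz")
  if (rec$duration < 1) {
    warning("recording shorter than 1 s: no detections")
    return(numeric(0))
  }
  fs <- rec$fs
  bp <- signal::butter(2, c(5, 40) / (fs / 2), type = "pass")
  xf <- as.numeric(signal::filtfilt(bp, rec$samples))
  e <- xf^2
  k <- min(2L * floor(median_window * fs / 2) + 1L,
           2L * floor((length(xf) - 1) / 2) + 1L)
  thr_amp <- factor * stats::runmed(abs(xf), k, endrule = "constant")
  thr <- thr_amp^2

  n <- length(e)
  is_peak <- c(FALSE, e[2:(n - 1)] > e[1:(n - 2)] & e[2:(n - 1)] >= e[3:n],
               FALSE) & (e > thr)
  cand <- which(is_peak)
  if (length(cand) == 0) return(numeric(0))
  ref_n <- refractory / 1000 * fs
  kept <- integer(0)
  for (i in cand) {
    if (length(kept) == 0 || i - kept[length(kept)] >= ref_n) {
      kept <- c(kept, i)
    } else if (e[i] > e[kept[length(kept)]]) {
      kept[length(kept)] <- i  # larger peak within refractory wins
    }
  }
  (kept - 1) / fs * 1000
}

#' Extract a raw 400-ms event segment
#'
#' Returns the samples on `[t - 150 ms, t + 250 ms)` around a detection time,
#' i.e. 400 samples at 1,000 Hz. Recordings at other sampling rates are
#' polyphase-resampled to 1,000 Hz first. Windows crossing a recording
#' boundary are edge-replicated to full length and flagged `padded`.
#'
#' @param rec an `ecg_recording`.
#' @param t detection time in milliseconds, in `[0, duration * 1000)`.
#'
#' @return list with `samples` (length 400) and `padded` (logical).
#' @export
extract_segment <- function(rec, t) {
  assert_that(inherits(rec, "ecg_recording"), "rec must be an ecg_recording")
  dur_ms <- rec$duration * 1000
  assert_that(t >= 0 && t < dur_ms, "t outside the recording")
  x <- resample_to_1000(rec)$samples
  n <- length(x)
  i0 <- round(t)                       # 0-based sample index at time t
  idx0 <- (i0 - 150):(i0 + 249)        # 0-based window indices
  padded <- any(idx0 < 0) || any(idx0 >= n)
  idx0 <- pmin(pmax(idx0, 0L), n - 1L) # edge replication
  list(samples = x[idx0 + 1L], padded = padded)
}

# Resample a recording to 1,000 Hz (polyphase); identity when already there.
resample_to_1000 <- function(rec) {
  if (rec$fs == 1000) return(rec)
  r <- 1000 / rec$fs
  fr <- as.integer(round(r * 1000))
  g <- gcd_int(fr, 1000L)
  p <- fr %/% g; q <- 1000L %/% g
  y <- as.numeric(signal::resample(rec$samples, p, q))
  target <- round(rec$duration * 1000)
  if (length(y) > target) y <- y[seq_len(target)]
  if (length(y) < target) y <- c(y, rep(y[length(y)], target - length(y)))
  rec$samples <- y
  rec$fs <- 1000
  rec
}

gcd_int <- function(a, b) if (b == 0L) a else gcd_int(b, a %% b)

#' Min-max normalization to [0, 1]
#'
#' `(x - min) / (max - min)`; a constant segment maps to 0.5 everywhere
#' (centered, avoiding division by zero). Idempotent.
#'
#' @param segment non-empty numeric vector.
#' @return numeric vector of the same length with values in `[0, 1]`.
#' @export
minmax_normalize <- function(segment) {
  assert_that(length(segment) > 0, "segment must be non-empty")
  lo <- min(segment); hi <- max(segment)
  if (hi == lo) return(rep(0.5, length(segment)))
  (segment - lo) / (hi - lo)
}

#' Build an event dataset from a corpus
#'
#' Runs the reference QRS detector on every recording, labels each detection
#' as true beat or false detection against the corpus ground truth, extracts
#' the normalized 400-ms segment for each event, and assigns subject-disjoint
#' train/validation/test splits whose event fractions approximate the targets
#' (no subject contributes to more than one split).
#'
#' @param corpus an `af_corpus` with at least 3 subjects.
#' @param fractions length-3 non-negative vector summing to 1:
#'   train/validation/test event fractions.
#' @param seed integer seed for the subject shuffle.
#' @param tolerance beat-matching tolerance in ms passed to [label_events()].
#'
#' @return an object of class `event_dataset`: `segments` (events x 400
#'   matrix, values in `[0, 1]`), `label` (0 = true beat, 1 = false
#'   detection), `time_ms`, `recording_id`, `subject_id`, `padded`, `split`,
#'   and counts `M`, `M0`, `M1`.
#' @export
build_event_dataset <- function(corpus, fractions = c(0.6, 0.2, 0.2),
                                seed = 1L, tolerance = 75) {
  assert_that(inherits(corpus, "af_corpus"), "corpus must be an af_corpus")
  assert_that(length(fractions) == 3 && all(fractions >= 0) &&
                abs(sum(fractions) - 1) < 1e-9,
              "fractions must be three non-negative numbers summing to 1")
  assert_that(length(corpus$subjects) >= 3,
              "need at least 3 subjects to form disjoint splits")

  seg_list <- list(); lab <- integer(0); tms <- numeric(0)
  rid <- character(0); sid <- character(0); pad <- logical(0)
  for (r in corpus$recordings) {
    det <- detect_qrs(r$recording)
    if (length(det) == 0) next
    labels <- label_events(det, r$truth, tolerance = tolerance)
    ext <- lapply(det, function(tt) extract_segment(r$recording, tt))
    segs <- t(vapply(ext, function(s) minmax_normalize(s$samples),
                     numeric(400)))
    pads <- vapply(ext, `[[`, logical(1), "padded")
    seg_list[[length(seg_list) + 1L]] <- segs
    lab <- c(lab, as.integer(labels == "false_detection"))
    tms <- c(tms, det)
    rid <- c(rid, rep(r$recording$recording_id, length(det)))
    sid <- c(sid, rep(r$recording$subject_id, length(det)))
    pad <- c(pad, pads)
  }
  segments <- do.call(rbind, seg_list)

  subj_ids <- names(corpus$subjects)
  ev_per_subj <- table(factor(sid, levels = subj_ids))
  order_subj <- with_seed(seed, sample(subj_ids))
  total <- sum(ev_per_subj)
  alloc <- c(train = 0, validation = 0, test = 0)
  targets <- fractions * total
  assign_split <- character(length(subj_ids))
  names(assign_split) <- order_subj
  for (s in order_subj) {
    deficit <- targets - alloc
    pick <- which.max(deficit)
    assign_split[s] <- c("train", "validation", "test")[pick]
    alloc[pick] <- alloc[pick] + ev_per_subj[[s]]
  }
  split <- factor(unname(assign_split[sid]),
                  levels = c("train", "validation", "test"))

  structure(list(segments = segments, label = lab, time_ms = tms,
                 recording_id = rid, subject_id = sid, padded = pad,
                 split = split,
                 M = length(lab), M0 = sum(lab == 0L), M1 = sum(lab == 1L)),
            class = "event_dataset")
}

#' @export
print.event_dataset <- function(x, ...) {
  cat(sprintf(paste0("<event_dataset: %d events (%d true beats, %d false",
                     " detections); train/val/test = %d/%d/%d>\n"),
              x$M, x$M0, x$M1,
              sum(x$split == "train"), sum(x$split == "validation"),
              sum(x$split == "test")))
  invisible(x)
}
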