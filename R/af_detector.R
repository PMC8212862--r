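#' RR-interval series from accepted detection times
#'
#' @param times sorted detection times in milliseconds, at least two, with no
#'   duplicates (a zero interval is rejected).
#' @return an object of class `rr_series`: `times`, `intervals` (successive
#'   differences, ms), `median_rr`.
#' @export
rr_intervals <- function(times) {
  assert_that(length(times) >= 2, "need at least two detection times")
  assert_that(!is.unsorted(times), "times must be sorted")
  iv <- diff(times)
  assert_that(all(iv > 0), "duplicate detection times give a zero interval")
  structure(list(times = as.numeric(times), intervals = as.numeric(iv),
                 median_rr = stats::median(iv)),
            class = "rr_series")
}

#' Detector parameters for the RR-irregularity AF detector
#'
#' @param N sliding-window length in RR intervals (>= 2; >= 3 for the
#'   irregularity fraction to be defined).
#' @param alpha dimensionless threshold constant: the per-window threshold is
#'   `gamma = alpha * median(window)`.
#' @param eta window-irregularity threshold in `(0, 1)`.
#' @param eta_d recording-decision threshold in `(0, 1]`; the default 1/3
#'   encodes the rule that a 30-s recording with at least 10 s of AF is
#'   labeled AF.
#' @return an object of class `detector_params`.
#' @export
detector_params <- function(N, alpha, eta, eta_d = 1 / 3) {
  assert_that(N >= 2, "N must be at least 2")
  assert_that(alpha > 0, "alpha must be positive")
  assert_that(eta > 0 && eta < 1, "eta must be in (0, 1)")
  assert_that(eta_d > 0 && eta_d <= 1, "eta_d must be in (0, 1]")
  structure(list(N = as.integer(N), alpha = alpha, eta = eta, eta_d = eta_d),
            class = "detector_params")
}

#' Shipped detector parameter presets
#'
#' Optimal operating points with and without event-level quality control:
#' `"without_qc"` is `N = 8, alpha = 0.07, eta = 0.55`; `"with_qc"` is
#' `N = 4, alpha = 0.04, eta = 0.65`.
#'
#' @param name `"with_qc"` or `"without_qc"`.
#' @return a [detector_params()] object.
#' @export
detector_preset <- function(name = c("with_qc", "without_qc")) {
  name <- match.arg(name)
  if (name == "with_qc") detector_params(4, 0.04, 0.65)
  else detector_params(8, 0.07, 0.55)
}

#' Per-window irregularity threshold
#'
#' `gamma = alpha * median(window)`.
#'
#' @param window numeric vector of N RR intervals (ms).
#' @param alpha threshold constant (dimensionless).
#' @return the threshold in milliseconds.
#' @export
gamma_threshold <- function(window, alpha) {
  alpha * stats::median(window)
}

#' Irregularity fraction of one RR-interval window
#'
#' The default (`variant = "discordant"`) counts interval pairs whose
#' absolute difference strictly exceeds `gamma`, normalized by
#' `(N - 1)(N - 2)`; a pair whose difference equals `gamma` exactly counts as
#' regular. The `"printed"` variant counts the complementary (concordant)
#' pairs with the same normalizer; the two variants sum to
#' `N(N - 1) / 2 / ((N - 1)(N - 2))` whenever no pair difference sits exactly
#' on `gamma`. Note the normalizer is not the pair count `N(N - 1)/2`, so the
#' maximum of the discordant fraction is `N / (2(N - 2))` and equals 1 only
#' at `N = 4`; the window threshold `eta` is calibrated jointly with this
#' normalizer.
#'
#' @param window numeric vector of N >= 3 RR intervals (ms).
#' @param gamma threshold in ms (>= 0).
#' @param variant `"discordant"` (default) or `"printed"`.
#' @return the irregularity fraction.
#' @export
irregularity_fraction <- function(window, gamma,
                                  variant = c("discordant", "printed")) {
  variant <- match.arg(variant)
  N <- length(window)
  assert_that(N >= 3, "window must hold at least 3 intervals")
  assert_that(gamma >= 0, "gamma must be non-negative")
  d <- abs(outer(window, window, "-"))
  diffs <- d[upper.tri(d)]
  count <- if (variant == "discordant") sum(diffs > gamma)
           else sum(diffs <= gamma)
  count / ((N - 1) * (N - 2))
}

#' Window irregularity flag
#'
#' `O = 1` when the irregularity fraction reaches the threshold
#' (`Lambda >= eta`, boundary inclusive), else 0.
#'
#' @param lambda irregularity fraction(s).
#' @param eta window threshold.
#' @return integer 0/1 vector.
#' @export
window_flag <- function(lambda, eta) {
  as.integer(lambda >= eta)
}

# Vectorized irregularity fractions for all stride-1 windows of N intervals.
# Returns gamma and lambda per window (window i starts at interval i).
lambda_series <- function(intervals, N, alpha,
                          variant = c("discordant", "printed")) {
  variant <- match.arg(variant)
  M <- length(intervals)
  nW <- M - N + 1L
  if (nW < 1L) return(list(gamma = numeric(0), lambda = numeric(0)))
  W <- stats::embed(intervals, N)  # row i = window starting at interval i
  med <- apply(W, 1, stats::median)
  gam <- alpha * med
  count <- numeric(nW)
  base <- seq_len(nW)
  for (a in 0:(N - 2)) {
    for (b in (a + 1):(N - 1)) {
      d <- abs(intervals[base + a] - intervals[base + b])
      count <- count + if (variant == "discordant") (d > gam) else (d <= gam)
    }
  }
  list(gamma = gam, lambda = count / ((N - 1) * (N - 2)))
}

#' Quality-control pruning of a detection series
#'
#' Applies the event-level quality-control rule before AF detection. Given
#' detection times and their event labels: (a) the recording's median RR
#' interval is computed over intervals between consecutive true-labeled
#' detections; (b) every *isolated* false detection (a run of exactly one)
#' whose flanking true detections span an interval deviating less than 15%
#' from that median is simply omitted — the two sub-intervals merge into one
#' normal RR interval; (c) every remaining false detection is deleted from
#' the series and its time is reported so that sliding windows spanning it
#' can be excluded from detection. Runs of two or more consecutive false
#' detections never merge.
#'
#' @param times sorted detection times in milliseconds.
#' @param labels character vector aligned with `times`, values
#'   `"true_beat"` / `"false_detection"`.
#' @return list with `times` (the accepted, true-labeled detection times),
#'   `excluded_times` (deleted false detections whose surrounding windows
#'   must not qualify), `merged_times` (false detections removed under the
#'   15% rule), `median_rr`, and `quality_flag` (`TRUE` when no true
#'   detections remain).
#' @export
qc_prune <- function(times, labels) {
  assert_that(length(times) == length(labels),
              "times and labels differ in length")
  assert_that(!is.unsorted(times), "times must be sorted")
  is_true <- labels == "true_beat"
  if (!any(is_true)) {
    return(list(times = numeric(0), excluded_times = as.numeric(times),
                merged_times = numeric(0), median_rr = NA_real_,
                quality_flag = TRUE))
  }
  true_times <- times[is_true]
  false_times <- times[!is_true]
  median_rr <- if (length(true_times) >= 2) stats::median(diff(true_times))
               else NA_real_

  merged <- numeric(0)
  excluded <- numeric(0)
  if (length(false_times) > 0) {
    for (ft_group in split(false_times,
                           findInterval(false_times, true_times))) {
      gap <- findInterval(ft_group[1], true_times)
      interior <- gap >= 1 && gap < length(true_times)
      if (interior && length(ft_group) == 1 && !is.na(median_rr)) {
        span <- true_times[gap + 1] - true_times[gap]
        if (abs(span - median_rr) / median_rr < 0.15) {
          merged <- c(merged, ft_group)
          next
        }
      }
      excluded <- c(excluded, ft_group)
    }
  }
  list(times = true_times, excluded_times = sort(excluded),
       merged_times = sort(merged), median_rr = median_rr,
       quality_flag = FALSE)
}

#' Recording-level AF decision
#'
#' Slides a window of `N` RR intervals (stride 1) over the series, computes
#' the irregularity fraction and flag for each window, and labels the
#' recording AF when the flagged fraction over qualifying windows reaches
#' `eta_d`. A window does not qualify when an excluded (quality-control
#' deleted) event time lies strictly inside its time span. With no
#' qualifying windows, or fewer intervals than `N`, the decision is non-AF
#' with `quality_flag` set.
#'
#' @param series an `rr_series` (see [rr_intervals()]) or a sorted numeric
#'   vector of accepted detection times in ms.
#' @param params a [detector_params()].
#' @param excluded_times times of deleted false detections (from
#'   [qc_prune()]); `NULL` disables window exclusion.
#' @param variant irregularity-fraction variant, see
#'   [irregularity_fraction()].
#' @return an object of class `af_decision`: `label` (`"AF"` / `"non-AF"`),
#'   `fraction`, `I` (number of qualifying windows), `quality_flag`, and a
#'   `windows` data.frame (`gamma`, `lambda`, `O`, `qualifies`).
#' @export
detect_af <- function(series, params, excluded_times = NULL,
                      variant = "discordant") {
  if (!inherits(series, "rr_series")) {
    if (length(series) < 2) {
      return(structure(list(label = "non-AF", fraction = 0, I = 0L,
                            quality_flag = TRUE,
                            windows = data.frame(gamma = numeric(0),
                                                 lambda = numeric(0),
                                                 O = integer(0),
                                                 qualifies = logical(0))),
                       class = "af_decision"))
    }
    series <- rr_intervals(series)
  }
  N <- params$N
  M <- length(series$intervals)
  nW <- M - N + 1L
  if (nW < 1L) {
    return(structure(list(label = "non-AF", fraction = 0, I = 0L,
                          quality_flag = TRUE,
                          windows = data.frame(gamma = numeric(0),
                                               lambda = numeric(0),
                                               O = integer(0),
                                               qualifies = logical(0))),
                     class = "af_decision"))
  }
  ls <- lambda_series(series$intervals, N, params$alpha, variant)
  O <- window_flag(ls$lambda, params$eta)
  qualifies <- rep(TRUE, nW)
  if (!is.null(excluded_times) && length(excluded_times) > 0) {
    t0 <- series$times[seq_len(nW)]
    t1 <- series$times[seq_len(nW) + N]
    for (ex in excluded_times) {
      qualifies <- qualifies & !(ex > t0 & ex < t1)
    }
  }
  I <- sum(qualifies)
  fraction <- if (I > 0) sum(O[qualifies]) / I else 0
  label <- if (I > 0 && fraction >= params$eta_d) "AF" else "non-AF"
  structure(list(label = label, fraction = fraction, I = as.integer(I),
                 quality_flag = I == 0L,
                 windows = data.frame(gamma = ls$gamma, lambda = ls$lambda,
                                      O = O, qualifies = qualifies)),
            class = "af_decision")
}

#' @export
print.af_decision <- function(x, ...) {
  cat(sprintf("<af_decision: %s (fraction %.3f over %d qualifying windows%s)>\n",
              x$label, x$fraction, x$I,
              if (x$quality_flag) ", quality flag" else ""))
  invisible(x)
}
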