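#' Confusion counts from predicted and true labels
#'
#' Standard 2x2 tally with a declared positive class. At the event level the
#' positive class is the false detection; at the recording level it is AF.
#'
#' @param predicted,truth equal-length label vectors.
#' @param positive the positive-class label.
#' @return an object of class `confusion_counts` with fields `TP`, `FP`,
#'   `TN`, `FN`.
#' @export
confusion <- function(predicted, truth, positive) {
  assert_that(length(predicted) == length(truth),
              "predicted and truth differ in length")
  p <- predicted == positive
  t <- truth == positive
  confusion_counts(TP = sum(p & t), FP = sum(p & !t),
                   TN = sum(!p & !t), FN = sum(!p & t))
}

#' @rdname confusion
#' @param TP,FP,TN,FN non-negative counts.
#' @export
confusion_counts <- function(TP, FP, TN, FN) {
  assert_that(all(c(TP, FP, TN, FN) >= 0), "counts must be non-negative")
  structure(list(TP = TP, FP = FP, TN = TN, FN = FN),
            class = "confusion_counts")
}

#' Performance metrics from confusion counts
#'
#' Sensitivity `Se = TP / (TP + FN)`, specificity `Sp = TN / (TN + FP)`,
#' accuracy, false positive rate `FPR = 1 - Sp`, positive predictive value
#' `PPV = TP / (TP + FP)`, and `F1 = 2 Se PPV / (Se + PPV)`. A metric whose
#' denominator is zero is reported as `NA` (not available), never silently 0.
#'
#' @param counts a `confusion_counts` object.
#' @return list of class `metric_set` with `Se`, `Sp`, `Acc`, `FPR`, `PPV`,
#'   `F1` as fractions in `[0, 1]` (or `NA`).
#' @export
metrics <- function(counts) {
  assert_that(inherits(counts, "confusion_counts"),
              "counts must be confusion_counts")
  rate <- function(num, den) if (den > 0) num / den else NA_real_
  with(counts, {
    se <- rate(TP, TP + FN)
    sp <- rate(TN, TN + FP)
    acc <- rate(TP + TN, TP + FP + TN + FN)
    fpr <- if (is.na(sp)) NA_real_ else 1 - sp
    ppv <- rate(TP, TP + FP)
    f1 <- if (!is.na(se) && !is.na(ppv) && se + ppv > 0)
      2 * se * ppv / (se + ppv) else NA_real_
    structure(list(Se = se, Sp = sp, Acc = acc, FPR = fpr, PPV = ppv,
                   F1 = f1), class = "metric_set")
  })
}

#' @export
print.metric_set <- function(x, ...) {
  cat(sprintf("Se %.1f%%  Sp %.1f%%  Acc %.1f%%  FPR %.1f%%  PPV %.1f%%  F1 %.1f%%\n",
              100 * x$Se, 100 * x$Sp, 100 * x$Acc, 100 * x$FPR, 100 * x$PPV,
              100 * x$F1))
  invisible(x)
}

#' Patient-level sensitivity
#'
#' A patient counts as detected when at least one of their recordings is
#' labeled AF; sensitivity is computed over AF patients only (the screening
#' question is whether every AF patient is found).
#'
#' @param subject_id subject of each recording decision.
#' @param predicted recording-level predicted labels (`"AF"` / `"non-AF"`).
#' @param af_subjects subject ids truly carrying AF.
#' @return sensitivity in `[0, 1]`, or `NA` when there are no AF patients.
#' @export
patient_sensitivity <- function(subject_id, predicted, af_subjects) {
  assert_that(length(subject_id) == length(predicted),
              "subject_id and predicted differ in length")
  if (length(af_subjects) == 0) return(NA_real_)
  detected <- unique(subject_id[predicted == "AF"])
  mean(af_subjects %in% detected)
}

#' Subject-level train/test split
#'
#' Assigns whole subjects to the training or test set. AF subjects are
#' divided as evenly as possible between the two sets (with an odd count the
#' extra AF subject alternates with the seed's parity); non-AF subjects are
#' split by `fraction`.
#'
#' @param corpus an `af_corpus`, or any list with `subjects` (named list) and
#'   `af_subjects` elements.
#' @param fraction fraction of subjects assigned to training.
#' @param seed integer seed.
#' @return an object of class `split_plan`: named character vector
#'   `assignment` (subject id to `"train"` / `"test"`) plus the `seed`.
#' @export
split_subjects <- function(corpus, fraction = 0.5, seed = 1L) {
  subj <- names(corpus$subjects)
  assert_that(length(subj) >= 2, "need at least two subjects")
  af <- intersect(subj, corpus$af_subjects)
  non_af <- setdiff(subj, af)
  with_seed(seed, {
    af_sh <- sample(af)
    non_sh <- sample(non_af)
    n_af_train <- length(af) %/% 2 +
      (if (length(af) %% 2 == 1 && seed %% 2 == 1) 1L else 0L)
    n_non_train <- round(fraction * length(non_af))
    assignment <- c(
      stats::setNames(rep(c("train", "test"),
                          c(n_af_train, length(af) - n_af_train)), af_sh),
      stats::setNames(rep(c("train", "test"),
                          c(n_non_train, length(non_af) - n_non_train)),
                      non_sh))
    structure(list(assignment = assignment[subj], seed = as.integer(seed)),
              class = "split_plan")
  })
}

#' Prepare per-recording detector inputs from a corpus
#'
#' Runs the reference QRS detector on every recording and, when a trained
#' event-quality model is supplied, classifies each event and applies the
#' quality-control pruning rule. The result is the flat per-recording input
#' the AF detector and the evaluation protocol consume.
#'
#' @param corpus an `af_corpus`.
#' @param model optional trained `qc_model`; `NULL` disables quality control.
#' @param theta decision threshold used with `model`.
#' @param oracle use the ground-truth event labels instead of the model
#'   (perfect-classifier analysis).
#' @param tolerance beat-matching tolerance (ms) for `oracle` labeling.
#' @return list of class `detector_inputs`: per recording `subject_id`,
#'   `recording_id`, `truth` label, `times` (accepted detection times),
#'   `excluded_times`, `quality_flag`.
#' @export
prepare_detector_inputs <- function(corpus, model = NULL, theta = 0.5,
                                    oracle = FALSE, tolerance = 75) {
  assert_that(inherits(corpus, "af_corpus"), "corpus must be an af_corpus")
  out <- lapply(corpus$recordings, function(r) {
    det <- detect_qrs(r$recording)
    entry <- list(subject_id = r$recording$subject_id,
                  recording_id = r$recording$recording_id,
                  truth = r$truth$rhythm_label)
    if (is.null(model) && !oracle) {
      entry$times <- det
      entry$excluded_times <- numeric(0)
      entry$quality_flag <- length(det) < 2
      return(entry)
    }
    labels <- if (oracle) {
      label_events(det, r$truth, tolerance = tolerance)
    } else {
      segs <- t(vapply(det, function(tt)
        minmax_normalize(extract_segment(r$recording, tt)$samples),
        numeric(400)))
      classify_events(model, segs, theta)$labels
    }
    pr <- qc_prune(det, labels)
    entry$times <- pr$times
    entry$excluded_times <- pr$excluded_times
    entry$quality_flag <- pr$quality_flag || length(pr$times) < 2
    entry
  })
  structure(list(recordings = out,
                 subjects = corpus$subjects,
                 af_subjects = corpus$af_subjects),
            class = "detector_inputs")
}

# Recording-level decisions for one parameter set over detector inputs.
decide_recordings <- function(inputs, params, variant = "discordant") {
  vapply(inputs$recordings, function(e) {
    if (length(e$times) < 2) return("non-AF")
    detect_af(e$times, params, excluded_times = e$excluded_times,
              variant = variant)$label
  }, character(1))
}

#' Constrained grid search over detector parameters
#'
#' Exhaustively evaluates every combination of the window length `N`, the
#' threshold constant `alpha`, and the window threshold `eta` on the training
#' recordings. Among combinations whose recording-level sensitivity meets
#' `se_min`, the one with the lowest false positive rate is returned (ties
#' broken toward smaller `N`, then smaller `alpha`, then smaller `eta`). If
#' no combination is feasible, the one with the highest sensitivity (then
#' lowest FPR) is returned with `feasible = FALSE`.
#'
#' @param inputs a `detector_inputs` object restricted to the training
#'   recordings (see [prepare_detector_inputs()] and [split_subjects()]);
#'   must contain both AF and non-AF recordings.
#' @param N_grid,alpha_grid,eta_grid the search grid (defaults: `4:8`,
#'   `0.03..0.12` step 0.01, `0.05..0.95` step 0.05 — 950 combinations).
#' @param se_min sensitivity constraint (default 0.99).
#' @param eta_d recording-decision threshold.
#' @param variant irregularity-fraction variant.
#' @return list of class `grid_search_result`: `params` (a
#'   [detector_params()]), `Se`, `FPR`, `feasible`, and `table` (all
#'   combinations with their training Se and FPR).
#' @export
grid_search <- function(inputs, N_grid = 4:8,
                        alpha_grid = seq(0.03, 0.12, by = 0.01),
                        eta_grid = seq(0.05, 0.95, by = 0.05),
                        se_min = 0.99, eta_d = 1 / 3,
                        variant = "discordant") {
  recs <- inputs$recordings
  assert_that(length(recs) > 0, "empty training set")
  truth <- vapply(recs, `[[`, character(1), "truth")
  is_af <- truth == "AF"
  assert_that(any(is_af) && any(!is_af),
              "training set needs both AF and non-AF recordings")

  n_combo <- length(N_grid) * length(alpha_grid) * length(eta_grid)
  tab <- data.frame(N = integer(n_combo), alpha = numeric(n_combo),
                    eta = numeric(n_combo), Se = numeric(n_combo),
                    FPR = numeric(n_combo))
  n_af <- sum(is_af); n_non <- sum(!is_af)
  row <- 0L
  for (N in N_grid) {
    norm <- (N - 1) * (N - 2)
    # per-recording precomputation shared across alpha and eta: window
    # medians, absolute pair differences, and the qualifying-window mask
    per_rec <- lapply(recs, function(e) {
      M <- length(e$times) - 1L
      if (M < N) return(NULL)
      iv <- diff(e$times)
      nW <- M - N + 1L
      W <- stats::embed(iv, N)
      med <- apply(W, 1, stats::median)
      pairs <- utils::combn(N, 2)
      D <- abs(W[, pairs[1, ], drop = FALSE] - W[, pairs[2, ], drop = FALSE])
      qual <- rep(TRUE, nW)
      if (length(e$excluded_times) > 0) {
        t0 <- e$times[seq_len(nW)]
        t1 <- e$times[seq_len(nW) + N]
        for (ex in e$excluded_times) qual <- qual & !(ex > t0 & ex < t1)
      }
      list(med = med, D = D, qual = qual, I = sum(qual))
    })
    for (alpha in alpha_grid) {
      lam <- lapply(per_rec, function(pr) {
        if (is.null(pr) || pr$I == 0) return(NULL)
        disc <- rowSums(if (variant == "discordant") pr$D > alpha * pr$med
                        else pr$D <= alpha * pr$med)
        (disc / norm)[pr$qual]
      })
      I_rec <- vapply(per_rec, function(pr)
        if (is.null(pr)) 0L else pr$I, integer(1))
      for (eta in eta_grid) {
        det <- mapply(function(l, I) {
          I > 0 && sum(l >= eta) / I >= eta_d
        }, lam, I_rec)
        row <- row + 1L
        tab[row, ] <- list(N, alpha, eta,
                           sum(det & is_af) / n_af,
                           sum(det & !is_af) / n_non)
      }
    }
  }

  feasible <- tab$Se >= se_min
  if (any(feasible)) {
    cand <- which(feasible)
    best <- cand[which.min(tab$FPR[cand])]   # first minimum = smallest N, alpha, eta
    feas <- TRUE
  } else {
    best <- order(-tab$Se, tab$FPR)[1]
    feas <- FALSE
  }
  structure(list(params = detector_params(tab$N[best], tab$alpha[best],
                                          tab$eta[best], eta_d),
                 Se = tab$Se[best], FPR = tab$FPR[best], feasible = feas,
                 table = tab),
            class = "grid_search_result")
}

#' @export
print.grid_search_result <- function(x, ...) {
  cat(sprintf("<grid_search: N=%d alpha=%.2f eta=%.2f (Se %.1f%%, FPR %.1f%%%s)>\n",
              x$params$N, x$params$alpha, x$params$eta, 100 * x$Se,
              100 * x$FPR, if (x$feasible) "" else ", infeasible"))
  invisible(x)
}

# Restrict detector inputs to the subjects assigned `keep` in a split plan.
subset_inputs <- function(inputs, plan, keep) {
  sel <- vapply(inputs$recordings, function(e)
    identical(unname(plan$assignment[e$subject_id]), keep), logical(1))
  subj_keep <- names(plan$assignment)[plan$assignment == keep]
  structure(list(recordings = inputs$recordings[sel],
                 subjects = inputs$subjects[names(inputs$subjects) %in% subj_keep],
                 af_subjects = intersect(inputs$af_subjects, subj_keep)),
            class = "detector_inputs")
}

#' Repeated subject-split evaluation of the AF detector
#'
#' For each repeat: draw a subject-level 50/50 split (AF subjects divided
#' equally), optimize the detector parameters on the training recordings
#' under the sensitivity constraint, and evaluate recording-level Se, FPR and
#' PPV plus patient-level sensitivity on the test recordings. Reports the
#' per-repeat rows and the mean and standard deviation across repeats.
#'
#' @param inputs a `detector_inputs` object for the whole corpus.
#' @param n_repeats number of random splits (default 10).
#' @param base_seed seed for the first split; repeat `k` uses
#'   `base_seed + k - 1`.
#' @param optimize run the grid search per split (otherwise `params` is used
#'   unchanged).
#' @param params fixed [detector_params()] when `optimize = FALSE`.
#' @param ... passed to [grid_search()].
#' @return list of class `repeated_eval`: `rows` (per-repeat data.frame with
#'   seed, N, alpha, eta, Se, FPR, PPV, patient_Se) and `summary` (mean and
#'   sd per metric).
#' @export
repeated_eval <- function(inputs, n_repeats = 10, base_seed = 1L,
                          optimize = TRUE, params = NULL, ...) {
  assert_that(n_repeats >= 1, "n_repeats must be at least 1")
  rows <- data.frame()
  for (k in seq_len(n_repeats)) {
    seed_k <- base_seed + k - 1L
    plan <- split_subjects(inputs, 0.5, seed_k)
    train <- subset_inputs(inputs, plan, "train")
    test <- subset_inputs(inputs, plan, "test")
    p <- if (optimize) grid_search(train, ...)$params else params
    pred <- decide_recordings(test, p)
    truth <- vapply(test$recordings, `[[`, character(1), "truth")
    m <- metrics(confusion(pred, truth, positive = "AF"))
    sid <- vapply(test$recordings, `[[`, character(1), "subject_id")
    pse <- patient_sensitivity(sid, pred, test$af_subjects)
    rows <- rbind(rows, data.frame(seed = seed_k, N = p$N, alpha = p$alpha,
                                   eta = p$eta, Se = m$Se, FPR = m$FPR,
                                   PPV = m$PPV, patient_Se = pse))
  }
  num <- rows[, c("Se", "FPR", "PPV", "patient_Se")]
  structure(list(rows = rows,
                 summary = data.frame(metric = names(num),
                                      mean = vapply(num, mean, numeric(1)),
                                      sd = vapply(num, stats::sd, numeric(1)))),
            class = "repeated_eval")
}

#' @export
print.repeated_eval <- function(x, ...) {
  cat(sprintf("<repeated_eval over %d splits>\n", nrow(x$rows)))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Reference recording-level operating figures from a published screening study
#'
#' Recording-level confusion counts and summary metrics reported by a large
#' handheld-ECG AF screening study for its irregular-rhythm review subset,
#' with and without event-level quality control. Shipped so the expert-review
#' worked examples can be recomputed; these figures describe that study's
#' data, not this package's synthetic corpora.
#'
#' @return nested list with `without_qc` and `with_qc`, each holding
#'   `counts` (a `confusion_counts`) and `ppv_pct`, `se_pct`, `fpr_pct`.
#' @export
screening_reference <- function() {
  list(without_qc = list(counts = confusion_counts(TP = 106, FP = 2405,
                                                   TN = 318, FN = 1),
                         se_pct = 99.0, fpr_pct = 87.5, ppv_pct = 4.6),
       with_qc = list(counts = confusion_counts(TP = 106, FP = 1807,
                                                TN = 916, FN = 1),
                      se_pct = 99.0, fpr_pct = 65.0, ppv_pct = 6.2))
}

#' Expert-review load from recording-level confusion counts
#'
#' Every detector-positive recording must be reviewed by an expert, so the
#' review load is `TP + FP`.
#'
#' @param counts a `confusion_counts` at the recording level.
#' @return integer number of recordings to review.
#' @export
review_load <- function(counts) {
  assert_that(inherits(counts, "confusion_counts"),
              "counts must be confusion_counts")
  counts$TP + counts$FP
}

#' Recordings reviewed per AF recording found
#'
#' The reciprocal of the positive predictive value, rounded to a whole
#' number of recordings: with PPV p, about `round(1/p)` detector-positive
#' recordings must be reviewed to find one AF recording.
#'
#' @param ppv positive predictive value as a fraction.
#' @return integer count.
#' @export
recordings_per_af <- function(ppv) {
  assert_that(ppv > 0 && ppv <= 1, "ppv must be in (0, 1]")
  round(1 / ppv)
}
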