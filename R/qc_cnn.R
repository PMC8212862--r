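#' Default event-quality CNN configuration
#'
#' The network that classifies each 400-sample event as a true heartbeat or a
#' false (noise) detection: three 1-D convolutional layers (16, 32, 64
#' filters, kernel 10, stride 2, no padding), average pooling (kernel 5,
#' stride 2) after the second and third convolutions, and three fully
#' connected layers (40, 40, 1 neurons) with dropout 0.5 / 0.25 after the
#' first two. The hidden activations are rectifiers; the output is a sigmoid
#' giving the probability that the event is a false detection. An L2 penalty
#' of 0.01 applies to the first convolutional layer's weights. With a
#' 400-sample input the temporal lengths through the network are
#' 196, 94, 45, 18, 7.
#'
#' @param input_length input segment length in samples (400 at 1,000 Hz).
#' @return an object of class `qc_model_config`.
#' @export
qc_model_config <- function(input_length = 400) {
  structure(list(
    input_length = input_length,
    conv_layers = list(list(filters = 16L, kernel = 10L, stride = 2L),
                       list(filters = 32L, kernel = 10L, stride = 2L),
                       list(filters = 64L, kernel = 10L, stride = 2L)),
    pool_kernel = 5L, pool_stride = 2L,
    fc_sizes = c(40L, 40L, 1L),
    dropout = c(0.5, 0.25),
    l2_conv1 = 0.01,
    activation = "relu", output_activation = "sigmoid",
    padding = "valid",
    init = "uniform fan-in scaling"
  ), class = "qc_model_config")
}

#' Training configuration for the event-quality CNN
#'
#' @param epochs maximum number of epochs.
#' @param batch_size minibatch size.
#' @param learning_rate Adam learning rate.
#' @param patience early-stopping patience: training stops once the
#'   validation loss has exceeded its best value for more than `patience`
#'   consecutive epochs (0 stops on the first increase). The parameters from
#'   the best-validation epoch are restored.
#' @param seed integer seed covering initialization, shuffling and dropout.
#' @return an object of class `train_config`.
#' @export
train_config <- function(epochs = 200, batch_size = 256,
                         learning_rate = 0.001, patience = 0, seed = 1L) {
  assert_that(epochs >= 1, "epochs must be at least 1")
  assert_that(batch_size >= 1, "batch_size must be at least 1")
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 optimizer = "adam",
                 patience = as.integer(patience), seed = as.integer(seed)),
            class = "train_config")
}

#' Output length of a valid (unpadded) 1-D convolution or pooling
#'
#' @param L_in input length (>= kernel).
#' @param kernel kernel size.
#' @param stride stride (>= 1).
#' @return `floor((L_in - kernel) / stride) + 1`.
#' @export
conv_output_length <- function(L_in, kernel, stride) {
  assert_that(L_in >= kernel, "input length must be at least the kernel size")
  assert_that(stride >= 1, "stride must be at least 1")
  as.integer((L_in - kernel) %/% stride + 1)
}

#' Per-layer trainable-parameter counts
#'
#' Convolutional layer: `filters * (kernel * in_channels) + filters`; fully
#' connected layer: `n_in * n_out + n_out`; pooling and dropout layers have
#' none. For the default configuration this gives 176; 5,152; 20,544;
#' 17,960; 1,640; 41.
#'
#' @param config a [qc_model_config()].
#' @return named integer vector (`conv1`..`conv3`, `fc1`..`fc3`) with a
#'   `total` attribute.
#' @export
layer_param_counts <- function(config = qc_model_config()) {
  s <- cnn_shapes(config)
  counts <- integer(0)
  Cin <- 1L
  for (i in seq_along(config$conv_layers)) {
    cl <- config$conv_layers[[i]]
    counts[paste0("conv", i)] <-
      as.integer(cl$filters * (cl$kernel * Cin) + cl$filters)
    Cin <- cl$filters
  }
  n_in <- s$flat
  for (i in seq_along(config$fc_sizes)) {
    n_out <- config$fc_sizes[i]
    counts[paste0("fc", i)] <- as.integer(n_in * n_out + n_out)
    n_in <- n_out
  }
  attr(counts, "total") <- sum(counts)
  counts
}

#' Class weights for imbalanced event training
#'
#' `w_j = (M / 2) / M_j` with `M = M_0 + M_1`, so that
#' `M_0 w_0 + M_1 w_1 = M`.
#'
#' @param M0 number of true beat detections (> 0).
#' @param M1 number of false detections (> 0).
#' @return list with `w0` and `w1`.
#' @export
class_weights <- function(M0, M1) {
  assert_that(M0 > 0 && M1 > 0, "both class counts must be positive")
  M <- M0 + M1
  list(w0 = M / (2 * M0), w1 = M / (2 * M1))
}

#' Weighted binary cross entropy
#'
#' `L = -(1/M) sum(w1 y log(p) + w0 (1 - y) log(1 - p))`, with predictions
#' clipped to `[eps, 1 - eps]` to keep the loss finite. With unit weights
#' this is the ordinary binary cross entropy.
#'
#' @param y 0/1 labels (1 = false detection).
#' @param p predicted probabilities in `[0, 1]`.
#' @param weights list with `w0`, `w1` (see [class_weights()]).
#' @param eps clipping constant.
#' @return scalar loss.
#' @export
weighted_bce <- function(y, p, weights = list(w0 = 1, w1 = 1), eps = 1e-7) {
  assert_that(length(y) == length(p), "labels and predictions differ in length")
  p <- pmin(pmax(p, eps), 1 - eps)
  -mean(weights$w1 * y * log(p) + weights$w0 * (1 - y) * log(1 - p))
}

# Early-stopping bookkeeping: given the validation-loss history, return the
# epoch at which training stops and the best epoch. Stops once the loss has
# exceeded its running best for more than `patience` consecutive epochs.
early_stop_epochs <- function(val_losses, patience = 0) {
  best <- Inf; best_epoch <- 0L; streak <- 0L
  for (e in seq_along(val_losses)) {
    if (val_losses[e] <= best) {
      best <- val_losses[e]; best_epoch <- e; streak <- 0L
    } else {
      streak <- streak + 1L
      if (streak > patience) {
        return(list(stop_epoch = e, best_epoch = best_epoch))
      }
    }
  }
  list(stop_epoch = length(val_losses), best_epoch = best_epoch)
}

#' Train the event-quality CNN
#'
#' Minimizes the weighted binary cross entropy (class weights from the
#' training-split counts via [class_weights()]) with Adam. The validation
#' loss is evaluated at the end of every epoch; training stops early once it
#' has exceeded its best value for more than `patience` consecutive epochs,
#' and the parameters from the best-validation epoch are returned. Fully
#' deterministic given `tconfig$seed`.
#'
#' @param dataset an `event_dataset` with non-empty train and validation
#'   splits containing both classes.
#' @param mconfig a [qc_model_config()].
#' @param tconfig a [train_config()].
#' @param verbose print per-epoch losses.
#'
#' @return an object of class `qc_model`: trained `params`, `config`,
#'   `weights` (the class weights used), and `history` (data.frame with
#'   `epoch`, `train_loss`, `val_loss`).
#' @export
train_qc <- function(dataset, mconfig = qc_model_config(),
                     tconfig = train_config(), verbose = FALSE) {
  assert_that(inherits(dataset, "event_dataset"),
              "dataset must be an event_dataset")
  tr <- dataset$split == "train"
  va <- dataset$split == "validation"
  assert_that(any(tr) && any(va),
              "dataset needs non-empty train and validation splits")
  Xtr <- dataset$segments[tr, , drop = FALSE]
  ytr <- dataset$label[tr]
  Xva <- dataset$segments[va, , drop = FALSE]
  yva <- dataset$label[va]
  assert_that(length(unique(ytr)) == 2, "training split needs both classes")

  w <- class_weights(sum(ytr == 0), sum(ytr == 1))
  params <- cnn_init(mconfig, tconfig$seed)
  state <- adam_init(params)
  n <- nrow(Xtr)

  best_loss <- Inf; best_params <- params; streak <- 0L
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0))

  with_seed(child_seed(tconfig$seed, 1L), {
    for (epoch in seq_len(tconfig$epochs)) {
      ord <- sample.int(n)
      starts <- seq(1, n, by = tconfig$batch_size)
      ep_loss <- 0
      for (s0 in starts) {
        idx <- ord[s0:min(s0 + tconfig$batch_size - 1, n)]
        Xb <- Xtr[idx, , drop = FALSE]
        yb <- ytr[idx]
        fw <- cnn_forward(params, Xb, mconfig, training = TRUE)
        loss <- weighted_bce(yb, fw$prob, w) +
          mconfig$l2_conv1 * sum(params$W_conv1^2)
        grads <- cnn_backward(params, fw$cache, yb, fw$prob, w, mconfig)
        up <- adam_step(params, grads, state, tconfig$learning_rate)
        params <- up$params; state <- up$state
        ep_loss <- ep_loss + loss * length(idx)
      }
      val_prob <- predict_prob(params, Xva, mconfig)
      val_loss <- weighted_bce(yva, val_prob, w)
      history[epoch, ] <- list(epoch, ep_loss / n, val_loss)
      if (verbose) {
        message(sprintf("epoch %3d  train %.4f  val %.4f", epoch,
                        ep_loss / n, val_loss))
      }
      if (val_loss <= best_loss) {
        best_loss <- val_loss; best_params <- params; streak <- 0L
      } else {
        streak <- streak + 1L
        if (streak > tconfig$patience) break
      }
    }
  })

  structure(list(params = best_params, config = mconfig, weights = w,
                 tconfig = tconfig, history = history),
            class = "qc_model")
}

# Batched forward pass without dropout.
predict_prob <- function(params, X, config, batch = 2048L) {
  n <- nrow(X)
  out <- numeric(n)
  for (s0 in seq(1, n, by = batch)) {
    idx <- s0:min(s0 + batch - 1, n)
    out[idx] <- cnn_forward(params, X[idx, , drop = FALSE], config)$prob
  }
  out
}

#' Predict false-detection probabilities
#'
#' @param object a trained `qc_model`.
#' @param newdata an `event_dataset`, or a numeric matrix of normalized
#'   400-sample segments (one row per event), or a single segment vector.
#' @param ... unused.
#' @return numeric vector of probabilities in `[0, 1]`.
#' @export
predict.qc_model <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "event_dataset")) newdata$segments
       else if (is.matrix(newdata)) newdata
       else matrix(newdata, nrow = 1)
  assert_that(ncol(X) == object$config$input_length,
              "segments have the wrong length")
  predict_prob(object$params, X, object$config)
}

#' @export
print.qc_model <- function(x, ...) {
  pc <- layer_param_counts(x$config)
  cat(sprintf("<qc_model: %d parameters, trained %d epochs, best val loss %.4f>\n",
              attr(pc, "total"), nrow(x$history), min(x$history$val_loss)))
  invisible(x)
}

#' Select the decision threshold by maximal F1 on validation events
#'
#' Sweeps the threshold over `{0.01, 0.02, ..., 0.99}`; for each value an
#' event is called a false detection when its probability strictly exceeds
#' the threshold, and the F1-score is computed with false detections as the
#' positive class. The smallest threshold attaining the maximal F1 is
#' returned.
#'
#' @param probabilities predicted probabilities on the validation split.
#' @param labels 0/1 validation labels (1 = false detection); both classes
#'   must be present.
#' @return list with `theta` (the threshold) and `f1` (the F1 attained).
#' @export
select_threshold <- function(probabilities, labels) {
  assert_that(length(probabilities) == length(labels),
              "probabilities and labels differ in length")
  assert_that(length(unique(labels)) == 2,
              "validation set must contain both classes")
  grid <- seq(0.01, 0.99, by = 0.01)
  f1s <- vapply(grid, function(th) {
    pred <- as.integer(probabilities > th)
    tp <- sum(pred == 1 & labels == 1)
    fp <- sum(pred == 1 & labels == 0)
    fn <- sum(pred == 0 & labels == 1)
    if (tp == 0) return(0)
    se <- tp / (tp + fn); ppv <- tp / (tp + fp)
    2 * se * ppv / (se + ppv)
  }, numeric(1))
  best <- which.max(f1s)   # which.max returns the first (smallest) maximizer
  list(theta = grid[best], f1 = f1s[best])
}

#' Classify events as true beats or false detections
#'
#' An event is labeled a false detection when its predicted probability
#' strictly exceeds the threshold.
#'
#' @param model a trained `qc_model`.
#' @param events segments (matrix or `event_dataset`) to classify.
#' @param theta decision threshold in `(0, 1)`.
#' @return list with `labels` (`"true_beat"` / `"false_detection"`) and
#'   `probabilities`.
#' @export
classify_events <- function(model, events, theta) {
  p <- predict(model, events)
  list(labels = ifelse(p > theta, "false_detection", "true_beat"),
       probabilities = p)
}
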