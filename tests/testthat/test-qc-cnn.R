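test_that("convolution output lengths match the architecture table", {
  expect_equal(conv_output_length(400, 10, 2), 196)
  expect_equal(conv_output_length(196, 10, 2), 94)
  expect_equal(conv_output_length(94, 5, 2), 45)
  expect_equal(conv_output_length(45, 10, 2), 18)
  expect_equal(conv_output_length(18, 5, 2), 7)
  for (s in 1:4) expect_equal(conv_output_length(13, 13, s), 1)
  expect_error(conv_output_length(5, 10, 2), "kernel")
})

test_that("per-layer parameter counts reproduce the reference architecture", {
  pc <- layer_param_counts(qc_model_config())
  expect_equal(unname(pc["conv1"]), 176)
  expect_equal(unname(pc["conv2"]), 5152)
  expect_equal(unname(pc["conv3"]), 20544)
  expect_equal(unname(pc["fc1"]), 17960)
  expect_equal(unname(pc["fc2"]), 1640)
  expect_equal(unname(pc["fc3"]), 41)
  s <- afqc:::cnn_shapes(qc_model_config())
  expect_equal(s$lengths, c(196, 94, 45, 18, 7))
  expect_equal(s$flat, 448)
})

test_that("class weights follow the balanced-reweighting identity", {
  w <- class_weights(100, 100)
  expect_equal(c(w$w0, w$w1), c(1, 1))
  w2 <- class_weights(34657, 10683)
  expect_equal(round(w2$w0, 4), 0.6541)
  expect_equal(round(w2$w1, 4), 2.1221)
  set.seed(3)
  for (i in 1:50) {
    M0 <- sample(1:1e5, 1); M1 <- sample(1:1e5, 1)
    w <- class_weights(M0, M1)
    expect_equal(M0 * w$w0 + M1 * w$w1, M0 + M1)
  }
  expect_error(class_weights(0, 5), "positive")
})

test_that("weighted cross entropy matches hand-worked values and reduces to BCE", {
  y <- c(0, 1, 1, 0)
  expect_lt(weighted_bce(y, y), 1e-6)
  expect_equal(weighted_bce(1, 0.5, list(w0 = 1, w1 = 2)), 2 * log(2))
  set.seed(4)
  for (i in 1:20) {
    yy <- rbinom(30, 1, 0.4)
    pp <- runif(30)
    expect_equal(weighted_bce(yy, pp), bce_brute(yy, pp))
  }
  expect_error(weighted_bce(c(0, 1), 0.5), "length")
})

test_that("threshold selection maximizes F1 and breaks ties low", {
  sel <- select_threshold(c(0.1, 0.2, 0.6, 0.9), c(0, 0, 1, 1))
  expect_equal(sel$theta, 0.20)
  expect_equal(sel$f1, 1)
  # wide perfect margin: every theta in [0.3, 0.69] ties at F1 = 1,
  # the smallest is returned
  sel2 <- select_threshold(c(0.1, 0.3, 0.7, 0.95), c(0, 0, 1, 1))
  expect_equal(sel2$theta, 0.30)
  expect_error(select_threshold(c(0.2, 0.8), c(1, 1)), "both classes")
})

test_that("event classification uses a strict threshold and is monotone", {
  run <- list(params = afqc:::cnn_init(qc_model_config(), 1L),
              config = qc_model_config())
  class(run) <- "qc_model"
  # strictness checked on raw probabilities via the same rule
  p <- c(0.80, 0.75, 0.20)
  lab <- ifelse(p > 0.75, "false_detection", "true_beat")
  expect_identical(lab, c("false_detection", "true_beat", "true_beat"))
  set.seed(9)
  probs <- runif(200)
  n_flagged <- vapply(seq(0.05, 0.95, by = 0.05),
                      function(th) sum(probs > th), integer(1))
  expect_true(all(diff(n_flagged) <= 0))
})

test_that("untrained network output stays in [0, 1] for extreme inputs", {
  cfg <- qc_model_config()
  params <- afqc:::cnn_init(cfg, 2L)
  X <- rbind(rep(0, 400), rep(1, 400),
             matrix(runif(2 * 400), 2, 400))
  p <- afqc:::predict_prob(params, X, cfg)
  expect_true(all(p >= 0 & p <= 1))
  expect_length(p, 4)
})

test_that("early stopping halts after the loss first exceeds its best", {
  # strictly increasing from epoch 2, patience 0: stop at 2, best at 1
  es <- afqc:::early_stop_epochs(c(0.5, 0.6, 0.7, 0.8), patience = 0)
  expect_equal(es$stop_epoch, 2)
  expect_equal(es$best_epoch, 1)
  # recovery within the patience window continues training
  es2 <- afqc:::early_stop_epochs(c(0.5, 0.6, 0.4, 0.45, 0.3), patience = 1)
  expect_equal(es2$stop_epoch, 5)
  expect_equal(es2$best_epoch, 5)
  es3 <- afqc:::early_stop_epochs(c(0.5, 0.6, 0.65, 0.7), patience = 1)
  expect_equal(es3$stop_epoch, 3)
  expect_equal(es3$best_epoch, 1)
})

test_that("training is deterministic given the seed and learns the tiny task", {
  ds <- tiny_event_dataset()
  tc <- train_config(epochs = 6, batch_size = 32, patience = 10, seed = 5L)
  m1 <- train_qc(ds, tconfig = tc)
  m2 <- train_qc(ds, tconfig = tc)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$params$W_conv2, m2$params$W_conv2)
  expect_lte(nrow(m1$history), 6)
  # the two synthetic segment classes are trivially separable
  te <- ds$split == "test"
  p <- predict(m1, ds$segments[te, , drop = FALSE])
  auc_ok <- mean(sample(p[ds$label[te] == 1], 500, replace = TRUE) >
                   sample(p[ds$label[te] == 0], 500, replace = TRUE))
  expect_gt(auc_ok, 0.9)
})

test_that("gradients agree with finite differences", {
  cfg <- qc_model_config()
  cfg$dropout <- c(0, 0)
  set.seed(11)
  params <- afqc:::cnn_init(cfg, 3L)
  X <- matrix(runif(4 * 400), 4, 400)
  y <- c(0, 1, 1, 0)
  w <- list(w0 = 0.8, w1 = 1.5)
  loss_at <- function(p) {
    f <- afqc:::cnn_forward(p, X, cfg)
    weighted_bce(y, f$prob, w) + cfg$l2_conv1 * sum(p$W_conv1^2)
  }
  fw <- afqc:::cnn_forward(params, X, cfg, training = TRUE)
  g <- afqc:::cnn_backward(params, fw$cache, y, fw$prob, w, cfg)
  for (nm in c("W_conv1", "W_conv2", "b_conv3", "W_fc1", "W_fc3")) {
    i <- sample(length(params[[nm]]), 1)
    p2 <- params
    p2[[nm]][i] <- p2[[nm]][i] + 1e-6
    up <- loss_at(p2)
    p2[[nm]][i] <- p2[[nm]][i] - 2e-6
    dn <- loss_at(p2)
    expect_equal(g[[nm]][i], (up - dn) / 2e-6, tolerance = 1e-4)
  }
})
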