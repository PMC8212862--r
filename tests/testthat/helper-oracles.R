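# Independent oracles, deliberately written without reusing package internals.

# Brute-force irregularity fraction: explicit double loop over all pairs.
lambda_brute <- function(window, gamma, discordant = TRUE) {
  N <- length(window)
  cnt <- 0L
  for (j in 1:(N - 1)) {
    for (k in (j + 1):N) {
      d <- abs(window[j] - window[k])
      hit <- if (discordant) d > gamma else d <= gamma
      if (hit) cnt <- cnt + 1L
    }
  }
  cnt / ((N - 1) * (N - 2))
}

# Hand-coded metric formulas for cross-checking metrics().
metrics_brute <- function(TP, FP, TN, FN) {
  list(Se = TP / (TP + FN), Sp = TN / (TN + FP),
       Acc = (TP + TN) / (TP + FP + TN + FN),
       FPR = FP / (TN + FP), PPV = TP / (TP + FP))
}

# Unweighted cross entropy as a plain per-sample loop.
bce_brute <- function(y, p, eps = 1e-7) {
  p <- pmin(pmax(p, eps), 1 - eps)
  total <- 0
  for (i in seq_along(y)) {
    total <- total + if (y[i] == 1) -log(p[i]) else -log(1 - p[i])
  }
  total / length(y)
}

# Exhaustive grid evaluation through the public single-recording decision
# path, independent of grid_search()'s vectorized internals.
grid_brute <- function(inputs, N_grid, alpha_grid, eta_grid, eta_d = 1 / 3) {
  truth <- vapply(inputs$recordings, `[[`, character(1), "truth")
  rows <- list()
  for (N in N_grid) for (alpha in alpha_grid) for (eta in eta_grid) {
    p <- detector_params(N, alpha, eta, eta_d)
    det <- vapply(inputs$recordings, function(e) {
      if (length(e$times) < 2) return(FALSE)
      detect_af(e$times, p, excluded_times = e$excluded_times)$label == "AF"
    }, logical(1))
    rows[[length(rows) + 1L]] <- data.frame(
      N = N, alpha = alpha, eta = eta,
      Se = mean(det[truth == "AF"]), FPR = mean(det[truth != "AF"]))
  }
  do.call(rbind, rows)
}
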