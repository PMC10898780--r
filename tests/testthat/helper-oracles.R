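# Straight-loop reference implementations, kept deliberately naive and
# independent of the vectorised package code paths.

loop_local_order <- function(phases, distances, lambda) {
  n <- nrow(phases)
  tt <- ncol(phases)
  R <- matrix(NA_real_, n, tt)
  for (i in seq_len(n)) {
    w <- numeric(n)
    for (p in seq_len(n)) w[p] <- exp(-lambda * distances[i, p])
    for (t in seq_len(tt)) {
      acc <- 0 + 0i
      for (p in seq_len(n)) acc <- acc + w[p] * exp(1i * phases[p, t])
      R[i, t] <- Mod(acc / sum(w))
    }
  }
  R
}

loop_pooled_sd <- function(R) {
  vals <- c()
  for (i in seq_len(nrow(R))) for (t in seq_len(ncol(R))) vals <- c(vals, R[i, t])
  m <- sum(vals) / length(vals)
  sqrt(sum((vals - m)^2) / length(vals))
}

loop_row_sd <- function(R) {
  out <- numeric(nrow(R))
  for (i in seq_len(nrow(R))) {
    v <- R[i, ]
    m <- sum(v) / length(v)
    out[i] <- sqrt(sum((v - m)^2) / length(v))
  }
  out
}

loop_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  sxy <- sum((x - mx) * (y - my))
  sxy / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# random phase matrix in (-pi, pi]
random_phases <- function(n, tt, seed) {
  set.seed(seed)
  matrix(runif(n * tt, -pi, pi), n, tt)
}

tiny_geometry <- function(n = 12, seed = 42) make_geometry(n, seed = seed)

quick_config <- function(omega, ...) {
  hopf_config(omega = omega, n_volumes = 60L, TR = 2, burn_in = 10, ...)
}

unwrap_phase <- function(theta) {
  d <- diff(theta)
  d <- atan2(sin(d), cos(d))
  theta[1] + c(0, cumsum(d))
}

random_omega <- function(n, seed = 9) {
  set.seed(seed)
  2 * pi * runif(n, 0.03, 0.07)
}
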