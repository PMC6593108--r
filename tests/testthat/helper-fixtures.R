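# shared fixtures: everything is generated in code at test time

# reduced-rate protocol for fast end-to-end runs (same schedule, 100 Hz)
small_protocol <- function(rate_hz = 100) session_protocol(rate_hz = rate_hz)

small_session <- function(seed = 42, noise_sd = 0.1, separation = 1,
                          rate_hz = 100) {
  m <- make_subject_model(separation, noise_sd, seed = seed)
  generate_session(small_protocol(rate_hz), m, seed = seed + 1)
}

# spherical 2-class Gaussian clouds
gaussian_fixture <- function(n_per_class, means, sd = 1, seed = 1) {
  set.seed(seed)
  d <- length(means[[1]])
  X <- do.call(rbind, lapply(means, function(mu) {
    matrix(stats::rnorm(n_per_class * d, sd = sd), ncol = d) +
      matrix(mu, n_per_class, d, byrow = TRUE)
  }))
  list(X = X, y = rep(paste0("C", seq_along(means)), each = n_per_class))
}

# concentric-ring binary problem: class 1 inside radius r1, class 0 outside
ring_fixture <- function(n_per_class = 100, r_inner = 1, r_outer = 2,
                         seed = 1) {
  set.seed(seed)
  ang <- stats::runif(2 * n_per_class, 0, 2 * pi)
  rad <- c(stats::runif(n_per_class, 0, r_inner * 0.9),
           stats::runif(n_per_class, r_outer * 0.9, r_outer * 1.3))
  list(X = cbind(rad * cos(ang), rad * sin(ang)),
       y = rep(c(1, 0), each = n_per_class))
}

# literal per-element transcription of the cross-entropy cost
cost_oracle <- function(theta, theta0, X, y) {
  m <- nrow(X)
  total <- 0
  for (i in seq_len(m)) {
    z <- sum(theta * X[i, ]) + theta0
    g <- 1 / (1 + exp(-z))
    g <- min(1 - 1e-12, max(1e-12, g))
    total <- total + y[i] * log(g) + (1 - y[i]) * log(1 - g)
  }
  -total / m
}

# literal matrix-inverse transcription of the binary discriminant equations
lda_binary_oracle <- function(X1, X2) {
  n1 <- nrow(X1); n2 <- nrow(X2)
  mu1 <- colMeans(X1); mu2 <- colMeans(X2)
  S1 <- matrix(0, ncol(X1), ncol(X1)); S2 <- S1
  for (i in seq_len(n1)) S1 <- S1 + tcrossprod(X1[i, ] - mu1)
  for (i in seq_len(n2)) S2 <- S2 + tcrossprod(X2[i, ] - mu2)
  Sigma <- (S1 + S2) / (n1 + n2 - 2)
  beta <- solve(Sigma) %*% (mu1 - mu2)
  beta0 <- -t(beta) %*% ((mu1 + mu2) / 2) + log((n1 / (n1 + n2)) / (n2 / (n1 + n2)))
  list(beta = drop(beta), beta0 = drop(beta0))
}

# literal per-class transcription of the one-vs-all discriminant scores
lda_ova_score_oracle <- function(model, x) {
  Sinv <- solve(model$sigma)
  vapply(model$units, function(u) {
    cb <- drop(Sinv %*% u$mu)
    sum(cb * x) - sum(cb * u$mu) / 2 + log(u$prior)
  }, numeric(1))
}

# term-by-term polynomial evaluation, coefficients highest degree first
polyval_oracle <- function(coeffs, v) {
  n <- length(coeffs) - 1
  sum(coeffs * v^(n:0))
}

# exact two-sided signed-rank p by enumeration of all sign assignments
wilcoxon_enum_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  vs <- vapply(0:(2^n - 1), function(mask) {
    sum(r[bitwAnd(mask, 2^(seq_len(n) - 1)) > 0])
  }, numeric(1))
  mu <- n * (n + 1) / 4
  mean(abs(vs - mu) >= abs(v_obs - mu) - 1e-12)
}
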