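# Independent brute-force oracles and tiny fixture builders used across
# the suite.  These deliberately mirror the definitions, not the package
# implementations.

# plain double-loop frequency-weighted mean of cosines
loop_ssim <- function(probe_vec, context_mat, weights) {
  num <- 0; den <- 0
  for (i in seq_len(nrow(context_mat))) {
    v <- context_mat[i, ]
    cs <- sum(probe_vec * v) /
      (sqrt(sum(probe_vec^2)) * sqrt(sum(v^2)))
    num <- num + cs * weights[i]
    den <- den + weights[i]
  }
  unname(num / den)
}

# naive O(N^2) sample entropy, templates 1..N-m for both lengths,
# ordered pairs, self-matches excluded, Chebyshev distance
naive_sampen <- function(x, m, r) {
  n <- length(x)
  nt <- n - m
  a <- 0L; b <- 0L
  for (i in seq_len(nt)) for (j in seq_len(nt)) {
    if (i == j) next
    dm <- max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)]))
    if (dm <= r) {
      b <- b + 1L
      dm1 <- max(dm, abs(x[i + m] - x[j + m]))
      if (dm1 <= r) a <- a + 1L
    }
  }
  -log(a / b)
}

# piecewise-linear evaluation by explicit segment search
manual_interp <- function(t, v, tout) {
  vapply(tout, function(tq) {
    if (tq <= t[1]) return(v[1])
    if (tq >= t[length(t)]) return(v[length(v)])
    j <- max(which(t <= tq))
    if (t[j] == tq) return(v[j])
    v[j] + (v[j + 1] - v[j]) * (tq - t[j]) / (t[j + 1] - t[j])
  }, numeric(1))
}

# small deterministic embedding space from explicit vectors
toy_space <- function(vecs) {
  m <- do.call(rbind, vecs)
  rownames(m) <- names(vecs)
  embedding_space(m)
}

# balanced Gaussian crossed-design data for model tests
sim_lmm_data <- function(n_p, n_i, beta = c(0, 0, 0, 0, 0, 0, 0, 0),
                         tau_p = 0.5, tau_i = 0.3, sigma = 1,
                         seed = 1) {
  set.seed(seed)
  d <- expand.grid(participant = factor(seq_len(n_p)),
                   item = factor(seq_len(n_i)))
  d$ssim <- stats::rnorm(n_i)[as.integer(d$item)]
  d$type2 <- factor(ifelse(as.integer(d$item) <= n_i / 2, "new", "old"),
                    levels = c("new", "old"))
  d$response <- factor(sample(c("new", "old"), nrow(d), replace = TRUE),
                       levels = c("new", "old"))
  X <- stats::model.matrix(~ ssim * type2 * response, d)
  d$dv <- as.vector(X %*% beta) +
    stats::rnorm(n_p, 0, tau_p)[as.integer(d$participant)] +
    stats::rnorm(n_i, 0, tau_i)[as.integer(d$item)] +
    stats::rnorm(nrow(d), 0, sigma)
  d
}
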