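# Random model/profile generators shared across property-style tests.

draw_model <- function(N = sample(1:10, 1)) {
  rmab(N = N,
       q_C = runif(1, 0.05, 0.95),
       q_I = runif(1, 0.05, 1),
       q_O = runif(1, 0.05, 1))
}

draw_profile <- function(model) {
  strategy_profile(model, runif(model$N, 0, 0.95))
}

# model inside the positive-social-learning regime (q_O - q_I) N > a + q_O
draw_regime_model <- function(N_range = 2:12) {
  repeat {
    N <- sample(N_range, 1)
    m <- rmab(N, runif(1, 0.05, 0.9), runif(1, 0.02, 0.6), runif(1, 0.3, 1))
    if ((m$q_O - m$q_I) * m$N > effective_rate(m) + m$q_O) return(m)
  }
}

# reference parameters used throughout (the package's worked example)
ref_model <- function() rmab(N = 10, q_C = 0.2, q_I = 0.3, q_O = 0.8)

# decode a state bitmask into per-agent 0/1 indicators
bit_ints <- function(state, N)
  as.integer(bitwAnd(state, 2L^(seq_len(N) - 1L)) > 0L)

# independent numeric maximizer of the common (diagonal) fitness w(r, r):
# golden-section bracket, then sign-bisection of the central-difference
# derivative, which pushes past golden section's sqrt(eps) resolution limit
diag_argmax <- function(m, h = 1e-5) {
  wd <- function(r) fitness_closed(m, r, r)
  g <- stats::optimize(wd, c(0, 1 - 1e-9), maximum = TRUE, tol = 1e-10)$maximum
  dw <- function(r) (wd(r + h) - wd(r - h)) / (2 * h)
  lo <- max(h, g - 1e-3); hi <- min(1 - h - 1e-9, g + 1e-3)
  if (dw(lo) <= 0 || dw(hi) >= 0) return(g)  # bracket failed; keep golden
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (dw(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
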