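test_that("N = 1 transition matrix matches the hand-evaluated two-state chain", {
  m <- rmab(1, 0.2, 0.3, 0.8)
  ch <- knowledge_chain(m, 0.5)
  # uninformed gains with prob (1 - q_C)(1 - r) q_I = 0.8 * 0.15
  expect_equal(ch$T[2, 1], 0.12)
  expect_equal(ch$T[1, 1], 0.88)
  expect_equal(ch$T[1, 2], 0.2)
  expect_equal(ch$T[2, 2], 0.8)
  expect_equal(steady_state(ch)[2], 0.375, tolerance = 1e-12)
})

test_that("transition matrix is a proper stochastic matrix with the reset floor", {
  set.seed(21)
  for (i in 1:10) {
    m <- draw_model(N = sample(1:6, 1))
    ch <- knowledge_chain(m, draw_profile(m))
    expect_true(all(ch$T >= 0))
    expect_equal(colSums(ch$T), rep(1, 2^m$N), tolerance = 1e-12)
    # reset term: every column puts at least q_C / N on the zero state
    expect_true(all(ch$T[1, ] >= m$q_C / m$N - 1e-14))
  }
})

test_that("transitions gain at most one bit and lose bits only via reset", {
  set.seed(22)
  m <- draw_model(N = 5)
  ch <- knowledge_chain(m, draw_profile(m))
  S <- 2^5
  bits <- ch$bits
  for (s in seq_len(S)) {
    dest <- which(ch$T[, s] > 0)
    for (d in dest) {
      if (d == 1L) next  # global reset
      gained <- sum(bits[d, ] & !bits[s, ])
      lost <- sum(bits[s, ] & !bits[d, ])
      expect_lte(gained, 1L)
      expect_equal(lost, 0L)
    }
  }
})

test_that("chain size cap and profile validation are enforced", {
  expect_error(knowledge_chain(rmab(20, 0.2, 0.3, 0.8), 0.5), "N <= 14")
  expect_error(knowledge_chain(ref_model(), rep(0.5, 3)), "length")
})

test_that("stationary distribution is stationary, normalized and unique", {
  set.seed(23)
  for (i in 1:10) {
    m <- draw_model(N = sample(1:6, 1))
    ch <- knowledge_chain(m, draw_profile(m))
    p <- steady_state(ch)
    expect_true(all(p >= 0))
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_lt(max(abs(as.numeric(ch$T %*% p) - p)), 1e-10)
  }
})

test_that("step_distribution preserves mass and fixes the stationary law", {
  m <- ref_model()
  ch <- knowledge_chain(m, 0.3)
  p <- steady_state(ch)
  expect_equal(step_distribution(ch, p), p, tolerance = 1e-12)
  q <- c(1, rep(0, 2^10 - 1))
  for (t in 1:1000) q <- step_distribution(ch, q)
  expect_lt(abs(sum(q) - 1), 1e-10)
  expect_error(step_distribution(ch, q[-1]), "length")
})

test_that("without individual learning the chain collapses to the empty state", {
  m <- rmab(4, 0.3, 1e-8, 0.8)
  p <- steady_state(knowledge_chain(m, 0))
  expect_gt(p[1], 1 - 1e-5)
})

test_that("chain marginals agree with closed-form fitness (homogeneous N = 2)", {
  set.seed(24)
  for (i in 1:50) {
    m <- draw_model(N = 2)
    r <- runif(1, 0, 0.95)
    w_chain <- marginal_fitness(knowledge_chain(m, r))
    expect_equal(unname(w_chain), rep(fitness_closed(m, r, r), 2),
                 tolerance = 1e-10)
  }
})

test_that("chain marginals agree with closed-form fitness (random profiles)", {
  set.seed(25)
  for (i in 1:40) {
    m <- draw_model(N = sample(1:7, 1))
    p <- draw_profile(m)
    expect_equal(marginal_fitness(knowledge_chain(m, p)), fitness(m, p),
                 tolerance = 1e-8)
  }
})

test_that("near-pure two-group profiles approach the group fitness values", {
  m <- rmab(6, 0.2, 0.3, 0.8)
  gf <- group_fitness(m, 3)
  w <- marginal_fitness(knowledge_chain(m, c(rep(0, 3), rep(1 - 1e-9, 3))))
  expect_equal(unname(w[1:3]), rep(gf$w_I, 3), tolerance = 1e-5)
  expect_equal(unname(w[4:6]), rep(gf$w_S, 3), tolerance = 1e-5)
})

test_that("spectral gap matches the 2x2 trace identity and stays below 1", {
  sg <- spectral_gap(knowledge_chain(rmab(1, 0.2, 0.3, 0.8), 0.5))
  # second eigenvalue = trace - 1 = 0.88 + 0.8 - 1
  expect_equal(sg$rho, 0.68, tolerance = 1e-12)
  expect_equal(sg$tau, -1 / log(0.68), tolerance = 1e-12)
  set.seed(26)
  for (i in 1:50) {
    m <- draw_model(N = sample(1:8, 1))
    sg <- spectral_gap(knowledge_chain(m, draw_profile(m)))
    expect_lt(sg$rho, 1)
    expect_gt(sg$tau, 0)
  }
})

test_that("late-time convergence rate tracks the subdominant eigenvalue", {
  m <- rmab(3, 0.2, 0.3, 0.8)
  ch <- knowledge_chain(m, 0.4)
  p_inf <- steady_state(ch)
  rho <- spectral_gap(ch)$rho
  q <- c(1, rep(0, 7))
  resid <- numeric(60)
  for (t in 1:60) {
    q <- step_distribution(ch, q)
    resid[t] <- max(abs(q - p_inf))
  }
  ratios <- resid[41:60] / resid[40:59]
  # the ratio approaches rho from above (a slowly decaying polynomial factor
  # remains when the subdominant eigenvalue is nearly defective)
  expect_true(all(ratios >= rho - 1e-6))
  expect_lt(abs(mean(ratios) - rho), 0.02)
  expect_true(all(diff(resid[40:60]) < 0))
})

test_that("steady-state table exposes bitmask, informed count and probability", {
  ch <- knowledge_chain(rmab(3, 0.2, 0.3, 0.8), 0.4)
  tab <- steady_state_table(ch)
  expect_equal(names(tab), c("state_bitmask", "N1", "probability"))
  expect_equal(tab$N1, c(0, 1, 1, 2, 1, 2, 2, 3))
  expect_equal(sum(tab$probability), 1, tolerance = 1e-12)
})
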