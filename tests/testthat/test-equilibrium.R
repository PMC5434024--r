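test_that("best response maximizes focal fitness (brute-force oracle)", {
  m <- ref_model()
  grid <- seq(0, 1, length.out = 4001)
  step <- grid[2] - grid[1]
  for (rbar in seq(0, 0.95, by = 0.05)) {
    w <- fitness_closed(m, grid, rbar)
    r0 <- grid[which.max(w)]
    br <- best_response(m, rbar)
    if (br < 1e-9 || br > 1 - 1e-9) {
      # clamped response: the grid argmax sits at the matching boundary
      expect_lt(abs(br - r0), step + 1e-9)
    } else {
      opt <- stats::optimize(function(r) fitness_closed(m, r, rbar),
                             lower = max(0, r0 - 2 * step),
                             upper = min(1, r0 + 2 * step),
                             maximum = TRUE, tol = 1e-12)$maximum
      expect_equal(br, opt, tolerance = 1e-6)
    }
  }
})

test_that("best response vanishes when copying pays less than searching", {
  m <- rmab(10, 0.2, 0.75, 0.5)
  expect_equal(best_response(m, seq(0, 0.9, by = 0.1)), rep(0, 10))
})

test_that("best response is non-increasing and vanishes above r*", {
  set.seed(31)
  for (i in 1:20) {
    m <- draw_regime_model()
    g <- seq(0, 0.999, length.out = 200)
    br <- best_response(m, g)
    expect_true(all(diff(br) <= 1e-12))
    r_hi <- auxiliary_points(m)$r_star_hi
    expect_equal(abs(unclamped_response(m, r_hi)), 0, tolerance = 1e-9)
    if (r_hi < 0.999)
      expect_equal(max(br[g >= r_hi + 1e-9]), 0)
  }
})

test_that("best response tends to zero as q_O approaches q_I from above", {
  vals <- vapply(10^-(1:6), function(eps) {
    m <- rmab(10, 0.2, 0.3, 0.3 + eps)
    max(best_response(m, seq(0, 0.9, by = 0.1)))
  }, numeric(1))
  expect_true(all(diff(vals) <= 0))
  expect_lt(vals[6], 1e-3)
})

test_that("response map fixes the Nash profile and respects symmetry", {
  m <- ref_model()
  r_N <- nash_closed(m)$r_Nash
  out <- response_map(m, rep(r_N, 10))
  expect_equal(out$r, rep(r_N, 10), tolerance = 1e-8)
  set.seed(32)
  p <- draw_profile(m)
  perm <- sample(10)
  expect_equal(response_map(m, p$r[perm])$r, response_map(m, p)$r[perm])
  m0 <- rmab(5, 0.2, 0.6, 0.4)
  expect_equal(response_map(m0, runif(5, 0, 0.9))$r, rep(0, 5))
})

test_that("closed-form Nash value matches both independent numeric solvers", {
  m <- ref_model()
  r_N <- nash_closed(m)$r_Nash
  expect_equal(r_N, 0.7088299, tolerance = 1e-6)
  expect_equal(nash_bisect(m), r_N, tolerance = 1e-8)
  expect_equal(nash_fixed_point(m), r_N, tolerance = 1e-8)
  # out-of-regime branch: (q_O - q_I) N = 0.5 <= a + q_O
  m2 <- rmab(10, 0.2, 0.75, 0.8)
  expect_false(nash_closed(m2)$regime)
  expect_equal(nash_closed(m2)$r_Nash, 0)
  expect_equal(nash_bisect(m2), 0, tolerance = 1e-8)
  expect_equal(nash_fixed_point(m2), 0, tolerance = 1e-8)
})

test_that("three Nash solvers agree across random regime parameters", {
  set.seed(33)
  for (i in 1:30) {
    m <- draw_regime_model()
    r_N <- nash_closed(m)$r_Nash
    expect_equal(nash_bisect(m), r_N, tolerance = 1e-8)
    expect_equal(nash_fixed_point(m), r_N, tolerance = 1e-8)
  }
})

test_that("Nash probability vanishes continuously at the regime boundary", {
  # walk q_I up to the boundary value ((N-1) q_O - a) / N
  m <- ref_model()
  q_star <- regime_boundary(m)
  qs <- q_star - c(0.1, 0.05, 0.02, 0.01, 0.005, 0.001, 1e-4, 1e-6)
  r_vals <- vapply(qs, function(q) nash_closed(rmab(10, 0.2, q, 0.8))$r_Nash,
                   numeric(1))
  expect_true(all(diff(r_vals) < 0))
  expect_lt(r_vals[length(r_vals)], 1e-3)
  expect_equal(nash_closed(rmab(10, 0.2, q_star + 1e-9, 0.8))$r_Nash, 0)
})

test_that("closed-form Pareto point matches golden-section maximization", {
  m <- ref_model()
  r_P <- pareto_closed(m)$r_Pareto
  opt <- stats::optimize(function(r) fitness_closed(m, r, r), c(0, 1 - 1e-9),
                         maximum = TRUE, tol = 1e-10)$maximum
  expect_equal(r_P, opt, tolerance = 1e-7)
  expect_equal(r_P, 0.4780494, tolerance = 1e-6)
  expect_equal(pareto_closed(rmab(10, 0.2, 0.75, 0.8))$r_Pareto, 0)
})

test_that("Pareto lies below Nash throughout the regime", {
  set.seed(34)
  for (i in 1:100) {
    m <- draw_regime_model()
    expect_lt(pareto_closed(m)$r_Pareto, nash_closed(m)$r_Nash)
  }
})

test_that("for N = 2 the diagonal Pareto point maximizes total fitness off-diagonal", {
  m <- rmab(2, 0.1, 0.1, 0.8)
  r_P <- pareto_closed(m)$r_Pareto
  g <- seq(0, 1 - 1e-9, length.out = 201)
  tot <- outer(g, g, function(r1, r2)
    fitness_closed(m, r1, r2) + fitness_closed(m, r2, r1))
  ix <- which(tot == max(tot), arr.ind = TRUE)[1, ]
  step <- g[2] - g[1]
  expect_lt(abs(g[ix[1]] - r_P), step + 1e-12)
  expect_lt(abs(g[ix[2]] - r_P), step + 1e-12)
})

test_that("auxiliary points satisfy the certified orderings and root identities", {
  m <- ref_model()
  aux <- auxiliary_points(m)
  expect_equal(aux$r_I, 1 - 1.0040816 / 5, tolerance = 1e-6)
  # the non-trivial diagonal point where the equilibrium gain vanishes
  expect_equal(fitness_closed(m, aux$r_I, aux$r_I),
               m$q_I / (effective_rate(m) + m$q_I), tolerance = 1e-12)
  expect_lt(aux$r_star_lo, aux$r_star_hi)
  expect_lt(aux$r_star_hi, 1)
  r_N <- nash_closed(m)$r_Nash
  r_P <- pareto_closed(m)$r_Pareto
  expect_equal(aux$k(1 / (1 - r_N)), 0, tolerance = 1e-8)
  expect_lt(aux$k(1), 0)
  expect_gt(aux$k(1 / (1 - aux$r_I)), 0)
  expect_lt(aux$k(1 / (1 - r_P)), 0)
  expect_true(r_P < r_N && r_N < aux$r_I)
  expect_false(auxiliary_points(rmab(10, 0.2, 0.8, 0.5))$defined)
})

test_that("auxiliary orderings hold across random regime parameters", {
  set.seed(35)
  for (i in 1:50) {
    m <- draw_regime_model()
    aux <- auxiliary_points(m)
    r_N <- nash_closed(m)$r_Nash
    expect_lt(aux$r_star_lo, aux$r_star_hi)
    expect_lt(aux$r_star_hi, 1)
    expect_equal(aux$k(1 / (1 - r_N)) /
                   max(1, abs(aux$k(0))), 0, tolerance = 1e-8)
    expect_lt(aux$k(1), 0)
  }
})

test_that("self-consistency map is increasing with derivative at most 1/2", {
  m <- ref_model()
  s <- m$N * nash_closed(m)$r_Nash
  sc <- self_consistency_map(m, s)
  grid <- seq(sc$lower, sc$upper, length.out = 2001)
  h <- 1e-7
  slope <- (vapply(grid + h, sc$g_free, numeric(1)) -
            vapply(grid - h, sc$g_free, numeric(1))) / (2 * h)
  expect_true(all(diff(vapply(grid, sc$g_free, numeric(1))) > 0))
  expect_lt(max(slope), 0.5 + 1e-3)
  # the maximum slope 1/2 is attained at the lower endpoint
  expect_equal(slope[1], 0.5, tolerance = 1e-3)
  expect_equal(grid[which.max(slope)], sc$lower, tolerance = 1e-3)
})

test_that("ESS certificate passes at reference parameters and centers at zero slack", {
  m <- ref_model()
  cert <- verify_ess(m, grid_size = 1001L)
  expect_true(cert$pass)
  expect_gt(min(cert$worst_slack), 1e-9)
  # at the equilibrium itself both inequalities are ties
  r_N <- cert$r_Nash
  expect_equal(fitness_closed(m, r_N, r_N) - fitness_closed(m, r_N, r_N), 0)
  # out-of-regime boundary case: no strictness claimed, only weak dominance
  m0 <- rmab(10, 0.2, 0.75, 0.8)
  g <- seq(0, 1 - 1e-9, length.out = 501)
  expect_true(all(fitness_closed(m0, 0, g) >= fitness_closed(m0, g, g) - 1e-12))
})

test_that("fitness ordering holds strictly in the regime and collapses outside", {
  m <- ref_model()
  ord <- fitness_ordering(m)
  expect_equal(ord$w_I, 0.59514, tolerance = 1e-4)
  expect_equal(ord$w_N, 0.63718, tolerance = 1e-4)
  expect_equal(ord$w_P, 0.66603, tolerance = 1e-4)
  expect_true(ord$w_P > ord$w_N && ord$w_N > ord$w_I)
  out <- fitness_ordering(rmab(10, 0.2, 0.75, 0.8))
  expect_equal(out$w_N, out$w_I, tolerance = 1e-14)
  expect_equal(out$w_P, out$w_I, tolerance = 1e-14)
})

test_that("w_N exceeds w_I exactly when the regime condition holds", {
  m <- ref_model()
  q_star <- regime_boundary(m)
  set.seed(36)
  for (dq in runif(40, -0.15, 0.15)) {
    q_I <- min(max(q_star + dq, 0.01), 0.99)
    mi <- rmab(10, 0.2, q_I, 0.8)
    ord <- fitness_ordering(mi)
    if (ord$regime) {
      expect_true(ord$w_P > ord$w_N && ord$w_N > ord$w_I)
    } else {
      expect_equal(ord$w_N, ord$w_I, tolerance = 1e-14)
      expect_equal(ord$w_P, ord$w_I, tolerance = 1e-14)
    }
  }
})

test_that("equilibrium object bundles all intermediates and serializes", {
  eq <- equilibrium(ref_model())
  expect_s3_class(eq, "rmab_equilibrium")
  expect_true(eq$regime)
  expect_equal(eq$r_Nash, 1 - eq$eta)
  js <- jsonlite::fromJSON(equilibrium_to_json(eq))
  expect_equal(js$r_Nash, eq$r_Nash)
  expect_equal(js$D1, eq$D1)
  expect_equal(js$params$a, effective_rate(eq$model))
  expect_output(print(eq), "r_Nash")
})
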