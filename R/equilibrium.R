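#' Best-response social-learning probability
#'
#' Given the mean strategy `rbar` of the other agents, the focal agent's
#' fitness `w(r, rbar)` has a unique maximum over `r`. The maximizer is
#' `f(rbar) = 0` when `q_O <= q_I` (copying is never worth it if it succeeds
#' less often than searching), and otherwise the clamp to `[0, 1]` of the
#' unconstrained response
#' \deqn{\bar f(r) = \frac{-\zeta + \sqrt{q_O (N-1)(1-r)}\,\sqrt{\zeta}}
#'   {q_O - q_I},\qquad \zeta = a + q_I + q_I (N-1)(1-r).}
#' `f` is non-increasing: the more the others copy, the less information is
#' produced and the less attractive copying becomes. It vanishes for
#' `rbar >= r*` (see [auxiliary_points()]) and tends to 0 as
#' `q_O` decreases to `q_I`.
#'
#' @param model an [rmab()] model.
#' @param rbar mean strategy of the other agents in `[0, 1]`; vectorized.
#' @return best-response probability(ies) in `[0, 1]`.
#' @export
best_response <- function(model, rbar) {
  stopifnot(inherits(model, "rmab"))
  if (model$q_O <= model$q_I) return(rep(0, length(rbar)))
  pmin(1, pmax(0, unclamped_response(model, rbar)))
}

#' Unclamped best-response curve
#'
#' The analytic stationary point `fbar(rbar)` underlying [best_response()];
#' it may be negative (no interior optimum: respond with \code{r = 0}) or exceed 1.
#' Defined only for `q_O > q_I`. The argument may lie outside `[0, 1]` as
#' long as it stays below 1, which the self-consistency analysis of
#' [self_consistency_map()] exploits.
#'
#' @param model an [rmab()] model with `q_O > q_I`.
#' @param rbar mean strategy; vectorized, `rbar <= 1`.
#' @return the unclamped response, any real value.
#' @export
unclamped_response <- function(model, rbar) {
  stopifnot(inherits(model, "rmab"))
  if (model$q_O <= model$q_I)
    stop("unclamped response is defined only for q_O > q_I", call. = FALSE)
  if (any(rbar > 1 + .rmab_tol))
    stop("'rbar' must be at most 1", call. = FALSE)
  a <- effective_rate(model)
  N <- model$N; q_I <- model$q_I; q_O <- model$q_O
  zeta <- a + q_I + q_I * (N - 1) * (1 - rbar)
  (-zeta + sqrt(q_O * (N - 1) * pmax(1 - rbar, 0)) * sqrt(zeta)) / (q_O - q_I)
}

#' Best-response map over strategy profiles
#'
#' Applies [best_response()] to each agent's leave-one-out mean, giving the
#' continuous self-map of the strategy cube whose unique fixed point is the
#' homogeneous Nash profile. Permuting agents permutes the image identically.
#'
#' @param model an [rmab()] model.
#' @param profile an `"rmab_profile"`, scalar or length-`N` vector.
#' @return an `"rmab_profile"` with each component replaced by the agent's
#'   best response. Components equal to 1 (possible only off-equilibrium) are
#'   nudged inside `[0, 1)` by the profile tolerance.
#' @export
response_map <- function(model, profile) {
  stopifnot(inherits(model, "rmab"))
  p <- if (inherits(profile, "rmab_profile")) profile else
    strategy_profile(model, profile)
  br <- best_response(model, p$rbar)
  strategy_profile(model, pmin(br, 1 - 2e-12))
}

# regime condition (q_O - q_I) N > a + q_O; boundary equality counts as FALSE,
# matching the closed forms' second branch
.in_regime <- function(model) {
  a <- effective_rate(model)
  (model$q_O - model$q_I) * model$N > a + model$q_O
}

#' Threshold of q_I below which equilibrium social learning is positive
#'
#' The regime condition `(q_O - q_I) N > a + q_O`, rearranged for the
#' individual-learning success probability, gives the threshold
#' `((N - 1) q_O - a) / N`: for `q_I` below it the Nash social-learning
#' probability is positive and the mixed equilibrium strictly beats pure
#' individual learning; at or above it the equilibrium is \code{r = 0}.
#'
#' @param model an [rmab()] model (its `q_I` is ignored).
#' @return the threshold value of `q_I`.
#' @export
regime_boundary <- function(model) {
  stopifnot(inherits(model, "rmab"))
  ((model$N - 1) * model$q_O - effective_rate(model)) / model$N
}

#' Closed-form Nash equilibrium social-learning probability
#'
#' The unique Nash equilibrium of the game is homogeneous, `r_n = r_Nash`
#' for all agents, with
#' \deqn{r_{\rm Nash} = 1 - \eta \quad\text{if } (q_O-q_I)N > a+q_O,
#'   \qquad r_{\rm Nash} = 0 \text{ otherwise},}
#' \deqn{\eta = \frac{2(a+q_O)^2}{(q_O-q_I N)(a+q_O) + (aN+q_O)(q_O-q_I)
#'   + \sqrt{D_1}}}
#' where `D_1` is the discriminant returned alongside. The corresponding
#' strategy is an evolutionarily stable strategy (see [verify_ess()]).
#'
#' @param model an [rmab()] model.
#' @return list with `r_Nash`, intermediates `eta` and `D1` (both `NA` in
#'   the zero branch), and logical `regime`.
#' @export
nash_closed <- function(model) {
  stopifnot(inherits(model, "rmab"))
  a <- effective_rate(model)
  N <- model$N; q_I <- model$q_I; q_O <- model$q_O
  if (!.in_regime(model))
    return(list(r_Nash = 0, eta = NA_real_, D1 = NA_real_, regime = FALSE))
  D1 <- (N - 1) * q_O *
    (-(4 * a * N + 3 * q_O * N + q_O) * q_I^2 +
       2 * (3 * a * q_O * N + 2 * q_O^2 * N - 2 * a^2 - 3 * a * q_O) * q_I +
       a * q_O * (a * N + 3 * a + 4 * q_O))
  if (D1 < 0)
    stop("negative discriminant D1 inside the positive-equilibrium regime; ",
         "this indicates a bug, not a parameter problem", call. = FALSE)
  eta <- 2 * (a + q_O)^2 /
    ((q_O - q_I * N) * (a + q_O) + (a * N + q_O) * (q_O - q_I) + sqrt(D1))
  list(r_Nash = 1 - eta, eta = eta, D1 = D1, regime = TRUE)
}

#' Nash equilibrium by bisection on r - f(r)
#'
#' Independent numeric solver: `h(r) = r - f(r)` is strictly increasing with
#' `h(0) <= 0 <= h(1)`, so its unique zero on `[0, 1)` is the equilibrium.
#' Bisection is unconditionally convergent here, which is why it is the
#' primary numeric cross-check of [nash_closed()].
#'
#' @param model an [rmab()] model.
#' @param tol bisection half-width tolerance (default `1e-10`).
#' @param max_iter iteration cap (default 200).
#' @return the equilibrium probability.
#' @export
nash_bisect <- function(model, tol = 1e-10, max_iter = 200L) {
  stopifnot(inherits(model, "rmab"), tol > 0)
  if (model$q_O <= model$q_I) return(0)
  h <- function(r) r - best_response(model, r)
  lo <- 0; hi <- 1 - 1e-14
  hlo <- h(lo); hhi <- h(hi)
  if (hlo > 0 || hhi < 0)
    stop("bisection bracket invalid: h(0) <= 0 <= h(1) failed", call. = FALSE)
  if (hlo == 0) return(0)
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    if (h(mid) <= 0) lo <- mid else hi <- mid
    if (hi - lo < tol) return((lo + hi) / 2)
  }
  stop("bisection did not reach tolerance within max_iter", call. = FALSE)
}

#' Nash equilibrium by damped fixed-point iteration
#'
#' Secondary numeric cross-check: iterates
#' \code{r <- (1 - lambda) * r + lambda * f(r)}, starting from
#' `lambda = 1/2` and halving `lambda` whenever the residual `|r - f(r)|`
#' fails to contract. The damping suppresses the oscillation of the raw map
#' \code{r <- f(r)} (`f` is decreasing); making it adaptive keeps the
#' iteration contractive even where `f` is steeper than -3, in which case a
#' fixed damping of 1/2 provably diverges. Because `f` is decreasing, the
#' residual bounds the distance to the root, so the stopping rule is safe.
#'
#' @param model an [rmab()] model.
#' @param tol stop when `|r - f(r)| < tol` (default `1e-10`).
#' @param max_iter iteration cap (default 500).
#' @param r0 starting point in `[0, 1)`.
#' @return the equilibrium probability.
#' @export
nash_fixed_point <- function(model, tol = 1e-10, max_iter = 500L, r0 = 0.5) {
  stopifnot(inherits(model, "rmab"), tol > 0)
  if (model$q_O <= model$q_I) return(0)
  r <- r0
  lambda <- 0.5
  err_prev <- Inf
  for (i in seq_len(max_iter)) {
    fr <- best_response(model, r)
    err <- abs(r - fr)
    if (err < tol) return(r)
    if (err > 0.9 * err_prev) lambda <- max(lambda / 2, 1e-3)
    err_prev <- err
    r <- (1 - lambda) * r + lambda * fr
  }
  stop("fixed-point iteration did not converge within max_iter", call. = FALSE)
}

#' Closed-form Pareto-optimal social-learning probability
#'
#' The total fitness `sum(w_n)` over the strategy cube is maximized at the
#' homogeneous profile `r_n = r_Pareto` with
#' \deqn{r_{\rm Pareto} = \frac{(a+q_I N)X - (a+q_I)Y}{q_I N X + (q_O-q_I)Y}
#'   \quad\text{if } (q_O-q_I)N > a+q_O, \qquad 0 \text{ otherwise},}
#' \deqn{X = \sqrt{(N-1)(a+q_O)(q_O-q_I)},\qquad Y = \sqrt{(a+Nq_I)N q_O}.}
#' In the positive regime `r_Pareto < r_Nash`: the selfish equilibrium
#' over-uses social learning relative to the common good.
#'
#' @param model an [rmab()] model.
#' @return list with `r_Pareto`, intermediates `X`, `Y` (`NA` in the zero
#'   branch) and logical `regime`.
#' @export
pareto_closed <- function(model) {
  stopifnot(inherits(model, "rmab"))
  a <- effective_rate(model)
  N <- model$N; q_I <- model$q_I; q_O <- model$q_O
  if (!.in_regime(model))
    return(list(r_Pareto = 0, X = NA_real_, Y = NA_real_, regime = FALSE))
  argX <- (N - 1) * (a + q_O) * (q_O - q_I)
  argY <- (a + N * q_I) * N * q_O
  if (argX < 0 || argY < 0)
    stop("negative radicand in Pareto closed form; this indicates a bug",
         call. = FALSE)
  X <- sqrt(argX); Y <- sqrt(argY)
  r_P <- ((a + q_I * N) * X - (a + q_I) * Y) / (q_I * N * X + (q_O - q_I) * Y)
  list(r_Pareto = r_P, X = X, Y = Y, regime = TRUE)
}

#' Auxiliary points and curves of the equilibrium analysis
#'
#' Computes the quantities used to certify uniqueness of the equilibrium and
#' the fitness ordering (all requiring `q_O > q_I`):
#' * `r_star_hi` (\eqn{r^*}): the zero of the unclamped response,
#'   `fbar(r*) = 0`; best responding to any `rbar >= r*` means not copying.
#'   \eqn{r^* = 1 - (a+q_I)/((N-1)(q_O-q_I))}.
#' * `r_star_lo` (\eqn{r_*}), with discriminant `D2`: below it the unclamped
#'   response exceeds 1 and clamps. Always `r_star_lo < r_star_hi < 1`.
#' * `k`: the quadratic in `u = 1/(1 - r)` whose larger root is
#'   `1/(1 - r_Nash)`,
#'   \deqn{k(u) = (a+q_O)^2 u^2 - \{(q_O-q_I N)(a+q_O)+(aN+q_O)(q_O-q_I)\}u
#'     + (q_O-q_I)(q_O-q_I N^2),}
#'   obtained by squaring the fixed-point condition \code{r = fbar(r)}; its
#'   discriminant equals the `D1` of [nash_closed()]. Sign checks of `k` at
#'   `1/(1-r_I)` and `1/(1-r_Pareto)` certify the ordering
#'   `r_Pareto < r_Nash < r_I`.
#' * `r_I`: the non-trivial diagonal point whose common fitness equals the
#'   pure individual learner's, `w(r_I, r_I) = q_I/(a+q_I)`;
#'   \eqn{r_I = 1 - (a+q_O)/((q_O-q_I)N)}. It lies in `(0, 1)` exactly in
#'   the positive regime.
#'
#' @param model an [rmab()] model with `q_O > q_I` (otherwise all fields are
#'   `NA` and `defined` is `FALSE`).
#' @return list with `r_star_hi`, `r_star_lo`, `D2`, `r_I`, the function
#'   `k(u)`, and logical `defined`.
#' @export
auxiliary_points <- function(model) {
  stopifnot(inherits(model, "rmab"))
  a <- effective_rate(model)
  N <- model$N; q_I <- model$q_I; q_O <- model$q_O
  if (q_O <= q_I || N < 2)
    return(list(r_star_hi = NA_real_, r_star_lo = NA_real_, D2 = NA_real_,
                r_I = NA_real_, k = NULL, defined = FALSE))
  r_hi <- 1 - (a + q_I) / ((N - 1) * (q_O - q_I))
  b2 <- q_O * (a - q_I) - 2 * a * q_I
  D2 <- b2^2 + 4 * q_I * (q_O - q_I) * (a + q_O)^2
  if (D2 < 0)
    stop("negative discriminant D2; this indicates a bug", call. = FALSE)
  r_lo <- 1 - (-b2 + sqrt(D2)) / (2 * (N - 1) * q_I * (q_O - q_I))
  kB <- (q_O - q_I * N) * (a + q_O) + (a * N + q_O) * (q_O - q_I)
  kC <- (q_O - q_I) * (q_O - q_I * N^2)
  k <- function(u) (a + q_O)^2 * u^2 - kB * u + kC
  list(r_star_hi = r_hi, r_star_lo = r_lo, D2 = D2,
       r_I = 1 - (a + q_O) / ((q_O - q_I) * N), k = k, defined = TRUE)
}

#' Self-consistency map for a candidate fixed-point sum
#'
#' At any fixed point of the best-response map with strategy sum `s`, every
#' component satisfies \code{r = g(r) = f((s - r)/(N - 1))}. On the interval
#' `[s - (N-1) r*, s - (N-1) r_*]` the map is clamp-free, strictly
#' increasing and concave, and its derivative attains its maximum value 1/2
#' at the left endpoint — which is what forces all components of a fixed
#' point to coincide.
#'
#' @param model an [rmab()] model with `q_O > q_I` and `N >= 2`.
#' @param s the candidate strategy sum (at the equilibrium, `s = N * r_Nash`).
#' @return list with the clamped map `g(r)`, the clamp-free analytic map
#'   `g_free(r)`, and the clamp-free interval endpoints `lower`, `upper`.
#' @export
self_consistency_map <- function(model, s) {
  stopifnot(inherits(model, "rmab"))
  aux <- auxiliary_points(model)
  if (!aux$defined)
    stop("self-consistency map requires q_O > q_I and N >= 2", call. = FALSE)
  N <- model$N
  g <- function(r) best_response(model, (s - r) / (N - 1))
  g_free <- function(r) unclamped_response(model, (s - r) / (N - 1))
  list(g = g, g_free = g_free,
       lower = s - (N - 1) * aux$r_star_hi,
       upper = s - (N - 1) * aux$r_star_lo)
}

#' Evolutionary-stability certificate for the Nash strategy
#'
#' Checks numerically, on a grid over `[0, 1)`, the two strict inequalities
#' that make the equilibrium an ESS in the sense of Thomas:
#' `w(r_Nash, r_Nash) > w(r, r_Nash)` (no unilateral deviation pays — Nash
#' in the strong sense) and `w(r_Nash, r) > w(r, r)` (a resident playing the
#' equilibrium strategy beats a population of deviants). Grid points within
#' two grid steps of `r_Nash` are excluded: at the equilibrium itself both
#' slacks vanish by definition.
#'
#' @param model an [rmab()] model.
#' @param grid_size number of grid points (default 1001).
#' @param margin strictness margin every slack must exceed (default `1e-9`).
#' @return object of class `"rmab_ess"`: grid size, margin, the worst slack
#'   of each inequality, the radius of the exclusion ball and logical `pass`.
#' @export
verify_ess <- function(model, grid_size = 1001L, margin = 1e-9) {
  stopifnot(inherits(model, "rmab"), grid_size >= 11L, margin > 0)
  r_N <- nash_closed(model)$r_Nash
  grid <- seq(0, 1 - 1e-9, length.out = grid_size)
  step <- grid[2] - grid[1]
  keep <- abs(grid - r_N) > 2 * step
  w_NN <- fitness_closed(model, r_N, r_N)
  slack_nash <- w_NN - fitness_closed(model, grid[keep], r_N)
  slack_thomas <- fitness_closed(model, r_N, grid[keep]) -
    fitness_closed(model, grid[keep], grid[keep])
  worst <- c(nash = min(slack_nash), thomas = min(slack_thomas))
  structure(list(r_Nash = r_N, grid_size = as.integer(grid_size),
                 margin = margin, exclusion_radius = 2 * step,
                 worst_slack = worst, pass = all(worst > margin)),
            class = "rmab_ess")
}

#' @export
print.rmab_ess <- function(x, ...) {
  cat(sprintf("ESS certificate at r_Nash = %.6f: %s\n", x$r_Nash,
              if (x$pass) "PASS" else "FAIL"))
  cat(sprintf("  grid %d points, margin %g, exclusion radius %g\n",
              x$grid_size, x$margin, x$exclusion_radius))
  cat(sprintf("  worst slack (Nash strong sense): %.3g\n", x$worst_slack["nash"]))
  cat(sprintf("  worst slack (Thomas ESS):        %.3g\n", x$worst_slack["thomas"]))
  invisible(x)
}

#' Steady-state fitness at the Pareto, Nash and individual-learning points
#'
#' Returns `w_I = q_I/(a+q_I)` (pure individual learning), the equilibrium
#' fitness `w_N = w(r_Nash, r_Nash)` and the Pareto fitness
#' `w_P = w(r_Pareto, r_Pareto)`. In the positive regime these are strictly
#' ordered `w_P > w_N > w_I` — the mixed equilibrium strictly beats pure
#' individual learning, which resolves Rogers' paradox — and outside it all
#' three coincide.
#'
#' @param model an [rmab()] model.
#' @return list with `w_P`, `w_N`, `w_I` and logical `regime`.
#' @export
fitness_ordering <- function(model) {
  stopifnot(inherits(model, "rmab"))
  r_N <- nash_closed(model)$r_Nash
  r_P <- pareto_closed(model)$r_Pareto
  list(w_P = fitness_closed(model, r_P, r_P),
       w_N = fitness_closed(model, r_N, r_N),
       w_I = model$q_I / (effective_rate(model) + model$q_I),
       regime = .in_regime(model))
}

#' Solve the full equilibrium problem
#'
#' One-stop solver bundling [nash_closed()], [pareto_closed()],
#' [auxiliary_points()] and [fitness_ordering()] into a single classed
#' result with all intermediates, for auditability.
#'
#' @param model an [rmab()] model.
#' @return object of class `"rmab_equilibrium"`: a list with `r_Nash`,
#'   `eta`, `D1`, `r_Pareto`, `X`, `Y`, `r_I`, `regime`, `w_I`, `w_N`,
#'   `w_P` and the model.
#' @examples
#' eq <- equilibrium(rmab(10, 0.2, 0.3, 0.8))
#' print(eq)
#' @export
equilibrium <- function(model) {
  stopifnot(inherits(model, "rmab"))
  ns <- nash_closed(model)
  ps <- pareto_closed(model)
  aux <- auxiliary_points(model)
  ord <- fitness_ordering(model)
  structure(list(r_Nash = ns$r_Nash, eta = ns$eta, D1 = ns$D1,
                 r_Pareto = ps$r_Pareto, X = ps$X, Y = ps$Y,
                 r_I = aux$r_I, regime = ns$regime,
                 w_I = ord$w_I, w_N = ord$w_N, w_P = ord$w_P,
                 model = model),
            class = "rmab_equilibrium")
}

#' @export
print.rmab_equilibrium <- function(x, ...) {
  m <- x$model
  cat("Equilibrium of the social-learning bandit game\n")
  cat(sprintf("  N = %d, q_C = %g, q_I = %g, q_O = %g (a = %.6g)\n",
              m$N, m$q_C, m$q_I, m$q_O, effective_rate(m)))
  cat(sprintf("  regime (q_O - q_I) N > a + q_O: %s\n",
              if (x$regime) "yes (positive social learning)" else
                "no (equilibrium is pure individual learning)"))
  cat(sprintf("  r_Nash   = %.6f    r_Pareto = %.6f\n", x$r_Nash, x$r_Pareto))
  if (x$regime) cat(sprintf("  r_I      = %.6f    (r_Pareto < r_Nash < r_I)\n", x$r_I))
  cat(sprintf("  w_I = %.6f   w_N = %.6f   w_P = %.6f\n", x$w_I, x$w_N, x$w_P))
  invisible(x)
}

#' @export
summary.rmab_equilibrium <- function(object, ...) {
  print(object)
  cat("\nIntermediates:\n")
  cat(sprintf("  eta = %s, D1 = %s, X = %s, Y = %s\n",
              format(object$eta), format(object$D1),
              format(object$X), format(object$Y)))
  invisible(object)
}

#' Serialize an equilibrium solution to JSON
#'
#' Emits every field of the solution (including intermediates `eta`, `D1`,
#' `X`, `Y`, `r_I` and the regime flag) so downstream consumers can audit
#' the computation.
#'
#' @param x an `"rmab_equilibrium"` from [equilibrium()].
#' @return a JSON string.
#' @export
equilibrium_to_json <- function(x) {
  stopifnot(inherits(x, "rmab_equilibrium"))
  m <- x$model
  jsonlite::toJSON(list(
    params = list(N = m$N, q_C = m$q_C, q_I = m$q_I, q_O = m$q_O,
                  a = effective_rate(m)),
    regime = x$regime,
    r_Nash = x$r_Nash, eta = x$eta, D1 = x$D1,
    r_Pareto = x$r_Pareto, X = x$X, Y = x$Y, r_I = x$r_I,
    w_I = x$w_I, w_N = x$w_N, w_P = x$w_P), auto_unbox = TRUE, digits = NA,
    na = "null")
}
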