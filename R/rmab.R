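#' Define a restless multi-armed bandit social-learning model
#'
#' Constructs the parameter object for a population of `N` agents facing a
#' restless bandit with a single good arm. In each turn one agent is chosen
#' uniformly at random; an informed agent exploits the good arm, while an
#' uninformed agent either searches at random (individual learning, success
#' probability `q_I`) or copies an informed agent (social learning, success
#' probability `q_O`, possible only while at least one agent is informed).
#' Independently, the good arm relocates with probability `q_C / N` per turn,
#' wiping everyone's knowledge.
#'
#' The effective environmental turnover rate is the derived quantity
#' `a = q_C / (1 - q_C / N)`; it is recomputed on demand by
#' [effective_rate()] and never stored, so it can not go stale.
#'
#' @param N integer number of agents, `N >= 1`.
#' @param q_C per-turn arm-change probability scale; requires `0 < q_C` and
#'   `q_C / N < 1`.
#' @param q_I individual-learning success probability in `(0, 1]`.
#' @param q_O social-learning (copy) success probability in `(0, 1]`.
#'
#' @return An object of class `"rmab"`: a list with elements `N`, `q_C`,
#'   `q_I`, `q_O`.
#'
#' @examples
#' m <- rmab(N = 10, q_C = 0.2, q_I = 0.3, q_O = 0.8)
#' effective_rate(m)
#' fitness(m, r = 0.5)
#' @seealso [strategy_profile()], [fitness()], [equilibrium()],
#'   [knowledge_chain()], [simulate.rmab()]
#' @export
rmab <- function(N, q_C, q_I, q_O) {
  if (length(N) != 1L || !is.finite(N) || N < 1 || N != as.integer(N))
    stop("'N' must be a single integer >= 1", call. = FALSE)
  N <- as.integer(N)
  chk_prob <- function(x, nm, closed_top) {
    if (length(x) != 1L || !is.finite(x))
      stop(sprintf("'%s' must be a single finite number", nm), call. = FALSE)
    if (x <= .rmab_tol)
      stop(sprintf("'%s' must be strictly positive", nm), call. = FALSE)
    if (closed_top && x > 1 + .rmab_tol)
      stop(sprintf("'%s' must be at most 1", nm), call. = FALSE)
  }
  chk_prob(q_C, "q_C", closed_top = FALSE)
  chk_prob(q_I, "q_I", closed_top = TRUE)
  chk_prob(q_O, "q_O", closed_top = TRUE)
  if (q_C / N >= 1 - .rmab_tol)
    stop("'q_C / N' must be < 1 so the effective rate a is finite", call. = FALSE)
  structure(list(N = N, q_C = q_C, q_I = q_I, q_O = q_O), class = "rmab")
}

# boundary tolerance for all probability validation in the package
.rmab_tol <- 1e-12

#' @export
print.rmab <- function(x, ...) {
  cat("Restless-bandit social-learning model\n")
  cat(sprintf("  N = %d agents, q_C = %g, q_I = %g, q_O = %g\n",
              x$N, x$q_C, x$q_I, x$q_O))
  cat(sprintf("  effective turnover rate a = %.6g\n", effective_rate(x)))
  invisible(x)
}

#' Effective environmental turnover rate
#'
#' Computes `a = q_C / (1 - q_C / N)`, the per-agent-action rate at which the
#' good arm relocates. It is strictly increasing in `q_C`, strictly
#' decreasing in `N`, and tends to `q_C` as `N` grows.
#'
#' @param model an [rmab()] model.
#' @return the positive scalar `a`.
#' @export
effective_rate <- function(model) {
  stopifnot(inherits(model, "rmab"))
  model$q_C / (1 - model$q_C / model$N)
}

#' Strategy profile of social-learning probabilities
#'
#' A strategy profile assigns to each agent `n` a probability `r_n` of
#' choosing social learning (copying) over individual learning when
#' uninformed. Profiles live in the half-open cube `[0, 1)^N`: `r_n = 1` is
#' excluded because a population of pure copiers with nobody searching has no
#' source of information and the steady state degenerates.
#'
#' @param model an [rmab()] model.
#' @param r either a single probability (recycled to all `N` agents,
#'   a homogeneous profile) or a length-`N` vector, each entry in `[0, 1)`.
#'
#' @return An object of class `"rmab_profile"`: a list with the per-agent
#'   vector `r`, the total `s = sum(r)` and the leave-one-out means
#'   `rbar[n] = (s - r[n]) / (N - 1)` (defined as 0 when `N = 1`, where no
#'   other agents exist and the mean field is vacuous).
#' @export
strategy_profile <- function(model, r) {
  stopifnot(inherits(model, "rmab"))
  N <- model$N
  if (length(r) == 1L) r <- rep(as.numeric(r), N)
  if (length(r) != N)
    stop(sprintf("'r' must have length 1 or N = %d", N), call. = FALSE)
  if (any(!is.finite(r)) || any(r < -.rmab_tol) || any(r >= 1 - .rmab_tol))
    stop("each strategy r_n must lie in [0, 1)", call. = FALSE)
  r <- pmin(pmax(r, 0), 1)
  s <- sum(r)
  rbar <- if (N == 1L) 0 else (s - r) / (N - 1)
  structure(list(r = r, s = s, rbar = rbar, N = N), class = "rmab_profile")
}

#' @export
print.rmab_profile <- function(x, ...) {
  cat(sprintf("Strategy profile for N = %d agents\n", x$N))
  if (length(unique(x$r)) == 1L) {
    cat(sprintf("  homogeneous r = %g\n", x$r[1]))
  } else {
    cat("  r =", format(x$r, digits = 5), "\n")
  }
  invisible(x)
}

#' Closed-form steady-state fitness of a focal agent
#'
#' Evaluates the steady-state probability `w(r, rbar)` that a focal agent
#' playing social-learning probability `r` knows the good arm, when the other
#' `N - 1` agents play mean strategy `rbar`:
#' \deqn{w(r,\bar r)=\frac{1}{a+q_I+(q_O-q_I)r}\left\{q_I+(q_O-q_I)r
#'   -\frac{a\,q_O\,r}{a+(N-1)q_I(1-\bar r)+q_I(1-r)}\right\}}
#' with `a` the [effective_rate()]. At \code{r = 0} this reduces to
#' `q_I / (a + q_I)` independently of `rbar` (a pure individual learner is
#' insensitive to what the others do), and at `N = 1` to
#' `(1 - r) q_I / (a + (1 - r) q_I)`.
#'
#' \code{r = 1} is accepted here (unlike in [strategy_profile()]) because the
#' two-group pure-strategy fitness of [group_fitness()] is the \code{r = 1} limit
#' of this function.
#'
#' @param model an [rmab()] model.
#' @param r focal agent's social-learning probability in `[0, 1]`; vectorized.
#' @param rbar mean strategy of the other agents in `[0, 1]`; vectorized.
#' @return fitness value(s) in `[0, 1]`.
#' @export
fitness_closed <- function(model, r, rbar) {
  stopifnot(inherits(model, "rmab"))
  if (any(r < -.rmab_tol) || any(r > 1 + .rmab_tol) ||
      any(rbar < -.rmab_tol) || any(rbar > 1 + .rmab_tol))
    stop("'r' and 'rbar' must lie in [0, 1]", call. = FALSE)
  a <- effective_rate(model)
  N <- model$N; q_I <- model$q_I; q_O <- model$q_O
  inner <- a + (N - 1) * q_I * (1 - rbar) + q_I * (1 - r)
  if (any(inner <= 0))
    stop("internal error: nonpositive inner denominator in fitness", call. = FALSE)
  (q_I + (q_O - q_I) * r - a * q_O * r / inner) / (a + q_I + (q_O - q_I) * r)
}

#' Per-agent steady-state fitness of a strategy profile
#'
#' The fitness of agent `n` is `w_n = w(r_n, rbar_n)` where `rbar_n` is the
#' leave-one-out mean of the others' strategies; see [fitness_closed()]. For
#' `N <= 14` the values can be cross-checked against the exact Markov chain
#' marginals of [marginal_fitness()].
#'
#' @param model an [rmab()] model.
#' @param r a strategy profile: an `"rmab_profile"`, a scalar (homogeneous
#'   profile) or a length-`N` vector.
#' @return named numeric vector of length `N` with entries in `[0, 1]`.
#' @export
fitness <- function(model, r) {
  stopifnot(inherits(model, "rmab"))
  p <- if (inherits(r, "rmab_profile")) r else strategy_profile(model, r)
  w <- fitness_closed(model, p$r, p$rbar)
  names(w) <- paste0("agent", seq_len(model$N))
  w
}

#' Pure-strategy group fitness: individual vs. social learners
#'
#' Splits the population into `N_I` pure individual learners (\code{r = 0}) and
#' `N - N_I` pure social learners (\code{r = 1}) and returns the steady-state
#' fitness of each group:
#' \deqn{w_I = \frac{q_I}{a+q_I},\qquad
#'   w_S = \frac{N_I\,q_I\,q_O}{(a+N_I q_I)(a+q_O)}.}
#' `w_S` is increasing in the number of individual learners: copiers are
#' information scroungers and do better the more producers there are. With
#' `N_I = 0` nobody ever finds the arm and `w_S = 0`; with `N_I = N` there
#' are no social learners and the reported `w_S` is vacuous (flagged).
#'
#' @param model an [rmab()] model.
#' @param N_I number of individual learners, `0 <= N_I <= N`.
#' @return list with `w_I`, `w_S`, `N_I`, `N_S` and logical `vacuous_w_S`.
#' @export
group_fitness <- function(model, N_I) {
  stopifnot(inherits(model, "rmab"))
  if (length(N_I) != 1L || N_I < 0 || N_I > model$N || N_I != as.integer(N_I))
    stop("'N_I' must be an integer in [0, N]", call. = FALSE)
  a <- effective_rate(model)
  q_I <- model$q_I; q_O <- model$q_O
  list(w_I = q_I / (a + q_I),
       w_S = N_I * q_I * q_O / ((a + N_I * q_I) * (a + q_O)),
       N_I = as.integer(N_I), N_S = model$N - as.integer(N_I),
       vacuous_w_S = N_I == model$N)
}

#' Large-population limits of the pure-strategy group fitness
#'
#' As `N` grows with the proportion of each group held fixed, the
#' individual-learner fitness tends to `q_I / (q_C + q_I)` and the
#' social-learner fitness to `q_O / (q_C + q_O)`. When `q_O > q_I` the
#' second limit exceeds the first, so in a large population a minority of
#' copiers outperforms the searchers they scrounge from.
#'
#' @param model an [rmab()] model.
#' @return named vector `c(w_I = ..., w_S = ...)` of the two limits.
#' @export
asymptotic_fitness <- function(model) {
  stopifnot(inherits(model, "rmab"))
  c(w_I = model$q_I / (model$q_C + model$q_I),
    w_S = model$q_O / (model$q_C + model$q_O))
}

#' Serialize a model (and optional profile) to JSON
#'
#' Writes the keys `N`, `q_C`, `q_I`, `q_O` and, when a profile is given,
#' `r` (a scalar for a homogeneous profile, otherwise a length-`N` array).
#'
#' @param model an [rmab()] model.
#' @param profile optional `"rmab_profile"` or `r` vector.
#' @return a JSON string.
#' @export
rmab_to_json <- function(model, profile = NULL) {
  stopifnot(inherits(model, "rmab"))
  x <- list(N = model$N, q_C = model$q_C, q_I = model$q_I, q_O = model$q_O)
  if (!is.null(profile)) {
    p <- if (inherits(profile, "rmab_profile")) profile else
      strategy_profile(model, profile)
    r <- p$r
    x$r <- if (length(unique(r)) == 1L) r[1] else r
  }
  jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
}

#' Deserialize a model (and optional profile) from JSON
#'
#' @param txt a JSON string or path to a JSON file with keys
#'   `N`, `q_C`, `q_I`, `q_O` and optionally `r`.
#' @return list with elements `model` (an `"rmab"`) and `profile`
#'   (an `"rmab_profile"` or `NULL`).
#' @export
rmab_from_json <- function(txt) {
  x <- jsonlite::fromJSON(txt)
  for (k in c("N", "q_C", "q_I", "q_O"))
    if (is.null(x[[k]])) stop(sprintf("missing key '%s'", k), call. = FALSE)
  model <- rmab(x$N, x$q_C, x$q_I, x$q_O)
  profile <- if (!is.null(x$r)) strategy_profile(model, x$r)
  list(model = model, profile = profile)
}
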