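#' Exact Markov chain over agent knowledge states
#'
#' Builds the dense transition matrix of the knowledge process. The state is
#' the vector of indicators "agent n knows the good arm", encoded as a
#' bitmask (agent n is bit n - 1), so there are `2^N` states. One turn is
#' the probability mixture
#' \deqn{T(\sigma'|\sigma) = \left(1-\frac{q_C}{N}\right)
#'   \left\{\left(1-\sum_n p_n(\sigma)\right)\delta_{\sigma',\sigma}
#'   + \sum_n p_n(\sigma)\,\delta_{\sigma',\sigma+e_n}\right\}
#'   + \frac{q_C}{N}\,\delta_{\sigma',\vec 0},}
#' \deqn{p_n(\sigma) = \frac{\delta_{\sigma_n,0}}{N}
#'   \left\{r_n (1-\delta_{N_1,0}) q_O + (1-r_n) q_I\right\}:}
#' either the arm relocates and all knowledge is lost (global reset to the
#' zero state), or one uniformly chosen agent may gain knowledge. At most
#' one bit is ever gained per turn and bits are only cleared by the reset,
#' so the chain is irreducible and aperiodic for valid parameters and has a
#' unique stationary distribution.
#'
#' Columns index the source state and rows the destination, so distributions
#' are column vectors evolved by `T %*% p` (see [step_distribution()]).
#'
#' @param model an [rmab()] model.
#' @param profile an `"rmab_profile"`, scalar or length-`N` vector.
#' @param max_N cap on `N` for the dense `2^N` matrix (default 14).
#' @return object of class `"rmab_chain"`: list with the `2^N x 2^N` matrix
#'   `T`, the `2^N x N` 0/1 matrix `bits` of state decodings, `model` and
#'   the profile.
#' @seealso [steady_state()], [marginal_fitness()], [spectral_gap()]
#' @export
knowledge_chain <- function(model, profile, max_N = 14L) {
  stopifnot(inherits(model, "rmab"))
  N <- model$N
  if (N > max_N)
    stop(sprintf("dense chain limited to N <= %d (2^N states); got N = %d",
                 max_N, N), call. = FALSE)
  p <- if (inherits(profile, "rmab_profile")) profile else
    strategy_profile(model, profile)
  S <- 2L^N
  bits <- .state_bits(N)
  N1 <- rowSums(bits)
  q_reset <- model$q_C / N
  Tm <- matrix(0, S, S)
  for (s in seq_len(S)) {
    sig <- bits[s, ]
    # per-agent one-turn knowledge-gain probabilities from this state
    pn <- ifelse(sig == 0L,
                 (p$r * (N1[s] > 0) * model$q_O + (1 - p$r) * model$q_I) / N,
                 0)
    Tm[s, s] <- Tm[s, s] + (1 - q_reset) * (1 - sum(pn))
    gain <- which(pn > 0)
    if (length(gain))
      Tm[cbind(s + 2L^(gain - 1L), s)] <- (1 - q_reset) * pn[gain]
    Tm[1L, s] <- Tm[1L, s] + q_reset
  }
  structure(list(T = Tm, bits = bits, N1 = N1, model = model, profile = p),
            class = "rmab_chain")
}

# decode states 0..2^N-1 into a 2^N x N 0/1 matrix (row s+1 = state s)
.state_bits <- function(N) {
  s <- 0:(2L^N - 1L)
  vapply(seq_len(N), function(n) as.integer(bitwAnd(s, 2L^(n - 1L)) > 0L),
         integer(length(s)))
}

#' @export
print.rmab_chain <- function(x, ...) {
  cat(sprintf("Knowledge-state Markov chain: N = %d agents, %d states\n",
              x$model$N, nrow(x$T)))
  invisible(x)
}

#' Advance a distribution by one turn
#'
#' Applies the Chapman-Kolmogorov update `p' = T p`. Mass and
#' nonnegativity are preserved exactly (up to floating point).
#'
#' @param chain an `"rmab_chain"` from [knowledge_chain()].
#' @param p a probability vector over the `2^N` states.
#' @return the distribution after one turn.
#' @export
step_distribution <- function(chain, p) {
  stopifnot(inherits(chain, "rmab_chain"))
  if (length(p) != nrow(chain$T))
    stop("distribution length does not match the number of states", call. = FALSE)
  if (any(p < -1e-12) || abs(sum(p) - 1) > 1e-8)
    stop("'p' is not a probability distribution", call. = FALSE)
  as.numeric(chain$T %*% p)
}

#' Stationary distribution of the knowledge chain
#'
#' Solves `T p = p`, `sum(p) = 1` by replacing one (redundant) balance row
#' of `T - I` with the normalization constraint; if the linear solve fails,
#' falls back to power iteration to tolerance `1e-12`. Uniqueness is
#' guaranteed by Perron-Frobenius: the chain is irreducible and primitive
#' for valid parameters.
#'
#' @param chain an `"rmab_chain"` from [knowledge_chain()].
#' @return the stationary probability vector over the `2^N` states.
#' @export
steady_state <- function(chain) {
  stopifnot(inherits(chain, "rmab_chain"))
  S <- nrow(chain$T)
  A <- chain$T - diag(S)
  A[S, ] <- 1
  b <- c(rep(0, S - 1L), 1)
  p <- tryCatch(solve(A, b), error = function(e) NULL)
  if (is.null(p) || any(!is.finite(p))) {
    # power-iteration fallback
    p <- rep(1 / S, S)
    for (i in seq_len(100000L)) {
      p2 <- as.numeric(chain$T %*% p)
      if (max(abs(p2 - p)) < 1e-12) { p <- p2; break }
      p <- p2
    }
  }
  p <- pmax(p, 0)
  p / sum(p)
}

#' Per-agent steady-state fitness from the exact chain
#'
#' The fitness of agent `n` is the stationary probability that bit `n` is
#' set, `w_n = sum_sigma P(sigma) sigma_n`. This is the brute-force oracle
#' the closed form [fitness()] is validated against.
#'
#' @param chain an `"rmab_chain"` from [knowledge_chain()].
#' @param steady optional precomputed stationary distribution.
#' @return named numeric vector of length `N`.
#' @export
marginal_fitness <- function(chain, steady = NULL) {
  stopifnot(inherits(chain, "rmab_chain"))
  if (is.null(steady)) steady <- steady_state(chain)
  w <- as.numeric(crossprod(chain$bits, steady))
  names(w) <- paste0("agent", seq_len(chain$model$N))
  w
}

#' Spectral gap and relaxation time
#'
#' Computes the modulus `rho` of the largest non-unit eigenvalue of the
#' transition matrix and the relaxation time `tau = -1 / log(rho)`.
#' Convergence to the stationary distribution is exponential,
#' `|P(t) - P| ~ rho^t`, so `tau` is the natural timescale after which the
#' steady-state fitness is an accurate description of the process (and the
#' burn-in scale for [simulate.rmab()]).
#'
#' @param chain an `"rmab_chain"` from [knowledge_chain()].
#' @return list with `rho` (in `(0, 1)`) and `tau`.
#' @export
spectral_gap <- function(chain) {
  stopifnot(inherits(chain, "rmab_chain"))
  ev <- eigen(chain$T, only.values = TRUE)$values
  if (sum(Mod(ev - 1) < 1e-8) != 1L)
    stop("unit eigenvalue is not simple within tolerance; ",
         "the chain appears reducible", call. = FALSE)
  rho <- max(Mod(ev[-which.min(Mod(ev - 1))]))
  if (rho >= 1)
    stop("subdominant eigenvalue modulus >= 1; the chain appears reducible",
         call. = FALSE)
  list(rho = rho, tau = -1 / log(rho))
}

#' Stationary distribution as a plain table
#'
#' One row per knowledge state with its bitmask encoding, informed count
#' `N1` and stationary probability — the CSV-friendly view of
#' [steady_state()].
#'
#' @param chain an `"rmab_chain"` from [knowledge_chain()].
#' @param steady optional precomputed stationary distribution.
#' @return data.frame with columns `state_bitmask`, `N1`, `probability`.
#' @export
steady_state_table <- function(chain, steady = NULL) {
  stopifnot(inherits(chain, "rmab_chain"))
  if (is.null(steady)) steady <- steady_state(chain)
  data.frame(state_bitmask = 0:(nrow(chain$T) - 1L),
             N1 = chain$N1,
             probability = steady)
}
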