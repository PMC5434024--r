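#' Simulate the knowledge process turn by turn
#'
#' Stochastic agent-based counterpart of the exact chain of
#' [knowledge_chain()]: each turn either resets all knowledge (probability
#' `q_C / N`, the arm relocated) or lets one uniformly chosen agent act —
#' exploit if informed, otherwise attempt copying with probability `r_n`
#' (succeeding with probability `q_O` only while at least one other agent
#' is informed) or random search (succeeding with probability `q_I`). The
#' reset and the agent action are mutually exclusive within a turn, matching
#' the transition-matrix mixture exactly, so long-run occupancies estimate
#' the same stationary law.
#'
#' All randomness comes from R's RNG in a fixed per-turn draw order
#' (reset, agent index, action choice, success), so a given `seed`
#' reproduces the trace exactly.
#'
#' @param object an [rmab()] model.
#' @param nsim number of independent traces (default 1). For `nsim > 1` a
#'   list of traces is returned, seeded `seed, seed + 1, ...`.
#' @param seed RNG seed; if `NULL` one is drawn and recorded in the trace.
#' @param r strategy profile (an `"rmab_profile"`, scalar or vector).
#' @param turns number of turns to simulate.
#' @param record_events if `TRUE`, also keep the per-turn event log
#'   (reset flag, chosen agent, action, success, informed count).
#' @param ... unused.
#' @return An object of class `"rmab_trace"` (or a list of them): the
#'   per-turn state bitmask vector `states`, the optional `events`
#'   data.frame, `seed`, `turns`, the model and the profile. Supports `N`
#'   up to 30 (bitmask storage).
#' @examples
#' m <- rmab(10, 0.2, 0.3, 0.8)
#' tr <- simulate(m, seed = 1, r = 0.5, turns = 20000)
#' estimate_fitness(tr, burn_in = 1000)
#' @export
simulate.rmab <- function(object, nsim = 1, seed = NULL, r, turns = 1e5,
                          record_events = FALSE, ...) {
  stopifnot(inherits(object, "rmab"))
  if (length(turns) != 1L || !is.finite(turns) || turns < 1)
    stop("'turns' must be a positive integer", call. = FALSE)
  turns <- as.integer(turns)
  p <- if (inherits(r, "rmab_profile")) r else strategy_profile(object, r)
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1L)
  if (nsim > 1) {
    return(lapply(seq_len(nsim) - 1L, function(k)
      simulate.rmab(object, nsim = 1, seed = seed + k, r = p, turns = turns,
                    record_events = record_events)))
  }
  set.seed(seed)
  out <- sim_rmab_cpp(object$N, object$q_C, object$q_I, object$q_O, p$r,
                      turns, record_events)
  events <- NULL
  if (record_events) {
    ev <- out$events
    events <- data.frame(turn = seq_len(turns), reset = ev[, 1],
                         agent = ev[, 2], action = c("none", "exploit",
                         "search", "copy")[ev[, 3] + 2L],
                         success = ev[, 4], N1 = ev[, 5])
  }
  structure(list(states = out$states, events = events, seed = seed,
                 turns = turns, model = object, profile = p),
            class = "rmab_trace")
}

#' @export
print.rmab_trace <- function(x, ...) {
  cat(sprintf("Simulation trace: N = %d, %d turns, seed %d\n",
              x$model$N, x$turns, x$seed))
  cat(sprintf("  final informed count N1 = %d\n",
              sum(.bit_set(x$states[x$turns], x$model$N))))
  invisible(x)
}

.bit_set <- function(state, N) as.integer(bitwAnd(state, 2L^(seq_len(N) - 1L)) > 0L)

#' Default burn-in length for a simulation
#'
#' The chain forgets its initial condition on the relaxation timescale
#' `tau` of [spectral_gap()]; discarding `20 * tau` turns makes the
#' residual initialization bias negligible next to sampling noise. Because
#' computing `tau` needs the full `2^N` eigenproblem, the default used by
#' [estimate_fitness()] is the cheap, deliberately generous surrogate
#' `max(100, ceiling(20 * N / q_C))` — an upper scale for the reset-driven
#' mixing time, itself at least `20 * tau` in practice. Set
#' `spectral = TRUE` (requires `N <= 14`) for the eigenvalue-based value.
#'
#' @param model an [rmab()] model.
#' @param r strategy profile (used only when `spectral = TRUE`).
#' @param spectral if `TRUE`, compute `ceiling(20 * tau)` exactly.
#' @return integer burn-in length in turns.
#' @export
default_burn_in <- function(model, r = 0, spectral = FALSE) {
  stopifnot(inherits(model, "rmab"))
  if (spectral) {
    tau <- spectral_gap(knowledge_chain(model, r))$tau
    return(max(1L, as.integer(ceiling(20 * tau))))
  }
  max(100L, as.integer(ceiling(20 * model$N / model$q_C)))
}

#' Estimate steady-state fitness from a simulation trace
#'
#' The fitness estimate for agent `n` is the fraction of post-burn-in turns
#' in which the agent was informed. Standard errors come from the method of
#' batch means: the retained turns are split into `n_batches` equal
#' consecutive batches (at least 20, so that the batch length exceeds the
#' autocorrelation time by a wide margin) and the SE is the standard
#' deviation of batch means divided by `sqrt(n_batches)`.
#'
#' @param trace an `"rmab_trace"` from [simulate.rmab()].
#' @param burn_in number of initial turns to discard; default
#'   [default_burn_in()] for the trace's model. Must leave at least
#'   `n_batches` turns.
#' @param n_batches number of batches (default 20, the minimum).
#' @return object of class `"rmab_fitness_estimate"`: per-agent estimates
#'   `w_hat`, standard errors `se` (0 is flagged degenerate), the
#'   `n_batches x N` batch-mean matrix, the number of retained turns
#'   `n_used`, and a variance-based effective sample size `ess` per agent
#'   (`NA` where the SE is degenerate).
#' @export
estimate_fitness <- function(trace, burn_in = NULL, n_batches = 20L) {
  stopifnot(inherits(trace, "rmab_trace"))
  if (n_batches < 20L)
    stop("'n_batches' must be at least 20 for a stable batch-means SE",
         call. = FALSE)
  if (is.null(burn_in)) burn_in <- default_burn_in(trace$model)
  if (burn_in >= trace$turns)
    stop("'burn_in' must be smaller than the number of turns", call. = FALSE)
  post <- trace$states[(burn_in + 1L):trace$turns]
  if (length(post) < n_batches)
    stop(sprintf("insufficient data: %d post-burn-in turns for %d batches",
                 length(post), n_batches), call. = FALSE)
  N <- trace$model$N
  batch_len <- length(post) %/% n_batches
  used <- post[(length(post) - n_batches * batch_len + 1L):length(post)]
  occ <- vapply(seq_len(N),
                function(n) as.numeric(bitwAnd(used, 2L^(n - 1L)) > 0L),
                numeric(length(used)))
  grp <- rep(seq_len(n_batches), each = batch_len)
  bm <- rowsum(occ, grp) / batch_len
  w_hat <- colMeans(bm)
  se <- apply(bm, 2, stats::sd) / sqrt(n_batches)
  names(w_hat) <- names(se) <- paste0("agent", seq_len(N))
  ess <- ifelse(se > 0, w_hat * (1 - w_hat) / se^2, NA_real_)
  structure(list(w_hat = w_hat, se = se, batch_means = bm,
                 n_used = length(used), n_batches = as.integer(n_batches),
                 burn_in = as.integer(burn_in),
                 degenerate = any(se == 0), seed = trace$seed),
            class = "rmab_fitness_estimate")
}

#' @export
print.rmab_fitness_estimate <- function(x, ...) {
  cat(sprintf("Fitness estimates from %d turns (%d batches, burn-in %d)\n",
              x$n_used, x$n_batches, x$burn_in))
  df <- data.frame(w_hat = round(x$w_hat, 5), se = signif(x$se, 3))
  print(df)
  if (x$degenerate)
    cat("note: at least one SE is exactly 0 (constant occupancy; degenerate)\n")
  invisible(x)
}

#' Export a simulation event log as a data.frame
#'
#' Requires the trace to have been recorded with `record_events = TRUE`.
#' Columns: `turn`, `reset`, `agent` (0 on reset turns), `action`
#' (`none`/`exploit`/`search`/`copy`), `success`, `N1` (informed count
#' after the turn) — ready for `write.csv`.
#'
#' @param trace an `"rmab_trace"`.
#' @return the event data.frame.
#' @export
trace_events <- function(trace) {
  stopifnot(inherits(trace, "rmab_trace"))
  if (is.null(trace$events))
    stop("trace was recorded without events; rerun simulate() with ",
         "record_events = TRUE", call. = FALSE)
  trace$events
}
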