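#' Validated run configuration for report commands
#'
#' Bundles model parameters, a profile specification and command options
#' into a single validated list, shared by the report functions and the
#' command-line interface. The profile may be given as a scalar, a
#' length-`N` vector `r`, or a two-group count `N_I` (that many pure
#' individual learners, the rest pure social learners).
#'
#' @param N,q_C,q_I,q_O model parameters; see [rmab()].
#' @param r strategy specification (scalar or length-`N`), or `NULL`.
#' @param N_I two-group split: number of individual learners, or `NULL`.
#' @param sweep optional list `list(param =, from =, to =, steps =)` with
#'   `param` one of `"q_I"`, `"q_O"`, `"q_C"`, `"r"`, `"N_I"`.
#' @param turns,burn_in simulation lengths (simulation commands only).
#' @param seed RNG seed or `NULL` (auto-seeded and recorded).
#' @return a validated list of class `"rmab_config"`.
#' @export
run_config <- function(N, q_C, q_I, q_O, r = NULL, N_I = NULL, sweep = NULL,
                       turns = 1e5, seed = NULL, burn_in = NULL) {
  model <- rmab(N, q_C, q_I, q_O)
  if (!is.null(r) && !is.null(N_I))
    stop("give either 'r' or 'N_I', not both", call. = FALSE)
  if (!is.null(r)) strategy_profile(model, r)  # validate early
  if (!is.null(N_I) && (N_I < 0 || N_I > N))
    stop("'N_I' must lie in [0, N]", call. = FALSE)
  if (!is.null(sweep)) {
    if (!all(c("param", "from", "to", "steps") %in% names(sweep)))
      stop("'sweep' needs fields param, from, to, steps", call. = FALSE)
    if (!sweep$param %in% c("q_I", "q_O", "q_C", "r", "N_I"))
      stop("unknown sweep parameter: ", sweep$param, call. = FALSE)
  }
  structure(list(model = model, r = r, N_I = N_I, sweep = sweep,
                 turns = turns, seed = seed, burn_in = burn_in),
            class = "rmab_config")
}

#' Read a run configuration from a JSON or YAML file
#'
#' The document may contain any of the [run_config()] fields; entries in
#' `overrides` (e.g. parsed command-line flags) replace file values.
#'
#' @param path path to a `.json`, `.yaml` or `.yml` file.
#' @param overrides named list of fields that win over the file.
#' @return a validated `"rmab_config"`.
#' @export
read_run_config <- function(path, overrides = list()) {
  ext <- tolower(tools::file_ext(path))
  x <- if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the 'yaml' package is required to read YAML configs", call. = FALSE)
    yaml::read_yaml(path)
  } else jsonlite::fromJSON(path)
  for (k in names(overrides)) if (!is.null(overrides[[k]])) x[[k]] <- overrides[[k]]
  do.call(run_config, x[intersect(names(x),
    c("N", "q_C", "q_I", "q_O", "r", "N_I", "sweep", "turns", "seed",
      "burn_in"))])
}

#' Per-agent fitness table: closed form, exact chain, simulation
#'
#' One row per agent with the closed-form fitness and, on request, the
#' exact Markov-chain marginal (`N <= 14`) and/or a seeded simulation
#' estimate with its batch-means SE, side by side.
#'
#' @param config an `"rmab_config"` with a profile (`r` or `N_I`; a
#'   two-group `N_I` spec uses \code{r = 0} and \code{r = 1} groups, the latter
#'   nudged just inside 1 for the chain/simulation columns).
#' @param exact add the exact-chain column (default `TRUE` when `N <= 10`).
#' @param simulate add simulation columns (default `FALSE`).
#' @return data.frame with columns `agent`, `r`, `w_closed` and optionally
#'   `w_exact`, `w_sim`, `se_sim`.
#' @export
fitness_table <- function(config, exact = config$model$N <= 10,
                          simulate = FALSE) {
  stopifnot(inherits(config, "rmab_config"))
  model <- config$model
  if (!is.null(config$N_I)) {
    gf <- group_fitness(model, config$N_I)
    r_vec <- c(rep(0, gf$N_I), rep(1, gf$N_S))
    w_closed <- c(rep(gf$w_I, gf$N_I), rep(gf$w_S, gf$N_S))
    r_eval <- pmin(r_vec, 1 - 1e-9)  # chain/simulator require r < 1
  } else {
    p <- strategy_profile(model, if (is.null(config$r)) 0 else config$r)
    r_vec <- r_eval <- p$r
    w_closed <- unname(fitness(model, p))
  }
  out <- data.frame(agent = seq_len(model$N), r = r_vec, w_closed = w_closed)
  if (exact)
    out$w_exact <- unname(marginal_fitness(knowledge_chain(model, r_eval)))
  if (simulate) {
    tr <- simulate.rmab(model, seed = config$seed, r = r_eval,
                        turns = config$turns)
    est <- estimate_fitness(tr, burn_in = config$burn_in)
    out$w_sim <- unname(est$w_hat)
    out$se_sim <- unname(est$se)
  }
  out
}

#' Two-group fitness against the population split
#'
#' Sweeps the number of individual learners `N_I` from 0 to `N` and tabulates
#' the pure-strategy group fitness of [group_fitness()]. As the share of
#' social learners grows, `w_S` falls from above `w_I` down to 0 — the
#' producer-scrounger pattern behind Rogers' paradox.
#'
#' @param model an [rmab()] model.
#' @return data.frame with columns `N_I`, `N_S`, `share_social`, `w_I`,
#'   `w_S`, `vacuous_w_S`.
#' @export
group_fitness_table <- function(model) {
  stopifnot(inherits(model, "rmab"))
  rows <- lapply(0:model$N, function(ni) {
    gf <- group_fitness(model, ni)
    data.frame(N_I = gf$N_I, N_S = gf$N_S,
               share_social = gf$N_S / model$N,
               w_I = gf$w_I, w_S = gf$w_S, vacuous_w_S = gf$vacuous_w_S)
  })
  do.call(rbind, rows)
}

#' Equilibrium fitness sweep over an environment parameter
#'
#' Tabulates `r_Nash`, `r_Pareto` and the fitness triple `w_I`, `w_N`,
#' `w_P` along a grid of one model parameter (default `q_I`). For a `q_I`
#' sweep the regime boundary `((N - 1) q_O - a) / N` is attached as the
#' attribute `"boundary"`: left of it the three fitnesses are strictly
#' ordered, right of it they coincide.
#'
#' @param model an [rmab()] model (its swept parameter is replaced).
#' @param values grid of parameter values.
#' @param param which parameter to sweep: `"q_I"`, `"q_O"` or `"q_C"`.
#' @return data.frame with one row per grid value.
#' @export
equilibrium_sweep <- function(model, values, param = "q_I") {
  stopifnot(inherits(model, "rmab"), param %in% c("q_I", "q_O", "q_C"))
  rows <- lapply(values, function(v) {
    pars <- list(N = model$N, q_C = model$q_C, q_I = model$q_I, q_O = model$q_O)
    pars[[param]] <- v
    eq <- equilibrium(do.call(rmab, pars))
    data.frame(value = v, regime = eq$regime, r_Nash = eq$r_Nash,
               r_Pareto = eq$r_Pareto, w_I = eq$w_I, w_N = eq$w_N,
               w_P = eq$w_P)
  })
  out <- do.call(rbind, rows)
  names(out)[1] <- param
  if (param == "q_I") attr(out, "boundary") <- regime_boundary(model)
  out
}

#' Best-response displacement field for two agents
#'
#' For `N = 2`, evaluates the displacement `(f(r_2) - r_1, f(r_1) - r_2)`
#' of the best-response map on a square grid — the vector field whose only
#' zero is the homogeneous Nash point.
#'
#' @param model an [rmab()] model with `N = 2`.
#' @param resolution grid points per axis (default 201).
#' @return data.frame with columns `r1`, `r2`, `u`, `v` (the two
#'   displacement components).
#' @export
best_response_field <- function(model, resolution = 201L) {
  stopifnot(inherits(model, "rmab"))
  if (model$N != 2L) stop("the displacement field is defined for N = 2",
                          call. = FALSE)
  g <- seq(0, 1 - 1e-9, length.out = resolution)
  br <- best_response(model, g)
  data.frame(r1 = rep(g, times = resolution),
             r2 = rep(g, each = resolution),
             u = rep(br, each = resolution) - rep(g, times = resolution),
             v = rep(br, times = resolution) - rep(g, each = resolution))
}

#' Count grid cells containing a fixed point of the response map
#'
#' A cell of the [best_response_field()] grid contains a fixed point when
#' both displacement components change sign across it (each component is
#' monotone in the coordinate it is differenced along, so a sign change
#' brackets a zero). For valid parameters exactly one cell qualifies — the
#' one containing the homogeneous Nash point.
#'
#' @param field data.frame from [best_response_field()].
#' @return data.frame of qualifying cells with the cell-corner coordinates.
#' @export
fixed_point_cells <- function(field) {
  g <- sort(unique(field$r1))
  n <- length(g)
  U <- matrix(field$u, n, n)  # rows r1, cols r2
  V <- matrix(field$v, n, n)
  su <- sign(U); sv <- sign(V)
  # sign change of u across r1 (rows), of v across r2 (cols), within a cell
  cu <- (su[-n, -n] * su[-1, -n] <= 0) | (su[-n, -1] * su[-1, -1] <= 0)
  cv <- (sv[-n, -n] * sv[-n, -1] <= 0) | (sv[-1, -n] * sv[-1, -1] <= 0)
  hit <- which(cu & cv, arr.ind = TRUE)
  data.frame(r1_lo = g[hit[, 1]], r1_hi = g[hit[, 1] + 1L],
             r2_lo = g[hit[, 2]], r2_hi = g[hit[, 2] + 1L])
}

#' Simulation report with closed-form reference
#'
#' Runs [simulate.rmab()] under the config's seed, estimates per-agent
#' fitness with batch-means SEs, and puts the closed-form value alongside.
#'
#' @param config an `"rmab_config"` with `r`, `turns` and optionally
#'   `seed`, `burn_in`.
#' @return list with the estimates data.frame (`agent`, `r`, `w_hat`, `se`,
#'   `w_closed`), the `seed` used and the `burn_in` applied.
#' @export
simulation_report <- function(config) {
  stopifnot(inherits(config, "rmab_config"))
  model <- config$model
  r <- if (is.null(config$r)) 0 else config$r
  tr <- simulate.rmab(model, seed = config$seed, r = r, turns = config$turns)
  est <- estimate_fitness(tr, burn_in = config$burn_in)
  df <- data.frame(agent = seq_len(model$N), r = tr$profile$r,
                   w_hat = unname(est$w_hat), se = unname(est$se),
                   w_closed = unname(fitness(model, tr$profile)))
  list(estimates = df, seed = tr$seed, burn_in = est$burn_in,
       turns = config$turns)
}
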