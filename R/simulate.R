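#' Single birth-death step of the Moran process
#'
#' One replacement event: a reproducer is drawn with probability
#' proportional to total strategy fitness, its offspring's strategy flips
#' with probability `mutation_rate`, and the offspring replaces an
#' individual drawn uniformly from the population. The state moves by at
#' most one.
#'
#' @param state current number of A-players, in `0..N`.
#' @param model a [moran_model()].
#' @param mutation_rate per-replacement flip probability in `[0, 1)`.
#' @return The next state.
#' @export
moran_step <- function(state, model, mutation_rate = 0) {
  stopifnot(inherits(model, "moran_model"))
  if (state < 0 || state > model$N)
    stop("state out of range 0..N", call. = FALSE)
  sp <- step_probabilities(model, mutation_rate)
  r <- stats::runif(1)
  state + (r < sp$p_up[state + 1]) -
    (r >= sp$p_up[state + 1] &
       r < sp$p_up[state + 1] + sp$p_down[state + 1])
}

#' Monte Carlo ensemble of Moran trajectories
#'
#' Runs independent replicates of the birth-death process from a common
#' start state, recording absorption outcomes and times. Replicates are
#' advanced in lockstep with precomputed one-step probabilities, so large
#' ensembles are cheap. With `mutation_rate = 0` runs end at the absorbing
#' boundaries; with mutation they run for exactly `max_steps` steps and are
#' reported as censored.
#'
#' @param model a [moran_model()].
#' @param start common start state (default 1, a single invader).
#' @param replicates number of independent runs.
#' @param max_steps step budget per run.
#' @param mutation_rate per-replacement flip probability.
#' @param seed optional integer seed; echoed in the result.
#' @param thin record every `thin`-th state when `record_paths = TRUE`
#'   (default `N`, about one generation).
#' @param record_paths keep thinned state paths (a `replicates x K` matrix).
#' @param conf_level confidence level of the binomial interval on the
#'   fixation fraction.
#' @return Object of class `trajectory_ensemble`: per-replicate `outcomes`
#'   data frame (`replicate`, `outcome`, `absorption_time`, `final_state`),
#'   counts, `fixation_fraction` of strategy A with `conf_int`, `seed`, and
#'   the run settings.
#' @export
run_ensemble <- function(model, start = 1, replicates = 1000,
                         max_steps = 1e6, mutation_rate = 0, seed = NULL,
                         thin = model$N, record_paths = FALSE,
                         conf_level = 0.99) {
  stopifnot(inherits(model, "moran_model"))
  if (replicates < 1 || max_steps < 1)
    stop("replicates and max_steps must be positive", call. = FALSE)
  if (start < 0 || start > model$N)
    stop("start out of range 0..N", call. = FALSE)
  if (mutation_rate < 0 || mutation_rate >= 1)
    stop("mutation_rate must be in [0, 1)", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  N <- model$N
  sp <- step_probabilities(model, mutation_rate)
  state <- rep.int(as.integer(start), replicates)
  alive <- rep.int(TRUE, replicates)
  t_abs <- rep.int(NA_integer_, replicates)
  absorbing <- mutation_rate == 0

  paths <- NULL
  if (record_paths) {
    K <- floor(max_steps / thin) + 1L
    paths <- matrix(NA_integer_, replicates, K)
    paths[, 1] <- state
  }

  step <- 0L
  if (absorbing) {
    alive <- state != 0L & state != N
    t_abs[!alive] <- 0L
  }
  while (any(alive) && step < max_steps) {
    step <- step + 1L
    idx <- which(alive)
    s <- state[idx]
    r <- stats::runif(length(idx))
    pu <- sp$p_up[s + 1L]
    pd <- sp$p_down[s + 1L]
    state[idx] <- s + (r < pu) - (r >= pu & r < pu + pd)
    if (absorbing) {
      hit <- idx[state[idx] == 0L | state[idx] == N]
      if (length(hit)) {
        alive[hit] <- FALSE
        t_abs[hit] <- step
      }
    }
    if (record_paths && step %% thin == 0L)
      paths[, step %/% thin + 1L] <- state
  }

  outcome <- rep.int("censored", replicates)
  outcome[!is.na(t_abs) & state == N] <- "fixed_A"
  outcome[!is.na(t_abs) & state == 0L] <- "fixed_B"
  n_A <- sum(outcome == "fixed_A")
  n_B <- sum(outcome == "fixed_B")
  frac <- if (n_A + n_B > 0) n_A / (n_A + n_B) else NA_real_
  ci <- if (n_A + n_B > 0)
    as.numeric(stats::binom.test(n_A, n_A + n_B,
                                 conf.level = conf_level)$conf.int)
  else c(NA_real_, NA_real_)

  structure(list(
    outcomes = data.frame(replicate = seq_len(replicates), outcome = outcome,
                          absorption_time = t_abs, final_state = state,
                          stringsAsFactors = FALSE),
    counts = c(fixed_A = n_A, fixed_B = n_B,
               censored = sum(outcome == "censored")),
    fixation_fraction = frac,
    conf_int = ci,
    conf_level = conf_level,
    paths = paths,
    seed = seed,
    settings = list(N = N, u = model$u, fitness_map = model$fitness_map,
                    start = start, replicates = replicates,
                    max_steps = max_steps, mutation_rate = mutation_rate,
                    thin = thin, labels = rownames(model$payoffs))
  ), class = "trajectory_ensemble")
}

#' @export
print.trajectory_ensemble <- function(x, ...) {
  s <- x$settings
  cat(sprintf("Moran ensemble: %d replicates from i = %d (N = %d, u = %g, mutation = %g)\n",
              s$replicates, s$start, s$N, s$u, s$mutation_rate))
  cat(sprintf("  fixed %s: %d   fixed %s: %d   censored: %d\n",
              s$labels[1], x$counts["fixed_A"], s$labels[2],
              x$counts["fixed_B"], x$counts["censored"]))
  if (!is.na(x$fixation_fraction))
    cat(sprintf("  fixation fraction of %s: %.4f (%g%% CI %.4f-%.4f)\n",
                s$labels[1], x$fixation_fraction, 100 * x$conf_level,
                x$conf_int[1], x$conf_int[2]))
  invisible(x)
}

#' Long-run state occupancy under mutation
#'
#' Simulates one long trajectory of the mutation-augmented chain, discards a
#' burn-in, and histograms the visited states; also computes the exact
#' stationary distribution by detailed balance
#' ([stationary_distribution()]) and the total-variation distance between
#' the two, as a chain-versus-closed-form cross-check.
#'
#' @param model a [moran_model()].
#' @param mutation_rate per-replacement flip probability, must be > 0.
#' @param steps chain length.
#' @param burn_in steps discarded before counting (default `steps %/% 10`).
#' @param start start state (default near `N/2`).
#' @param seed optional integer seed.
#' @return Object of class `stationary_estimate`: `empirical` and `exact`
#'   probability vectors over `0..N`, their `tv_distance`, and settings.
#' @export
empirical_stationary <- function(model, mutation_rate, steps = 1e6,
                                 burn_in = steps %/% 10,
                                 start = round(model$N / 2), seed = NULL) {
  stopifnot(inherits(model, "moran_model"))
  if (mutation_rate <= 0)
    stop("empirical_stationary requires mutation_rate > 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  N <- model$N
  sp <- step_probabilities(model, mutation_rate)
  up <- sp$p_up
  dn <- sp$p_down
  counts <- integer(N + 1)
  s <- as.integer(start)
  rv <- stats::runif(steps)
  for (t in seq_len(steps)) {
    r <- rv[t]
    if (r < up[s + 1L]) s <- s + 1L
    else if (r < up[s + 1L] + dn[s + 1L]) s <- s - 1L
    if (t > burn_in) counts[s + 1L] <- counts[s + 1L] + 1L
  }
  emp <- counts / sum(counts)
  names(emp) <- 0:N
  exact <- stationary_distribution(model, mutation_rate)
  structure(list(empirical = emp, exact = exact,
                 tv_distance = 0.5 * sum(abs(emp - exact)),
                 settings = list(N = N, u = model$u,
                                 mutation_rate = mutation_rate,
                                 steps = steps, burn_in = burn_in,
                                 start = start, seed = seed)),
            class = "stationary_estimate")
}

#' @export
print.stationary_estimate <- function(x, ...) {
  s <- x$settings
  cat(sprintf("Stationary occupancy (N = %d, u = %g, mutation = %g, %g steps)\n",
              s$N, s$u, s$mutation_rate, s$steps))
  cat(sprintf("  TV distance empirical vs detailed balance: %.4f\n",
              x$tv_distance))
  invisible(x)
}
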