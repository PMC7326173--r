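#' Frequency-dependent Moran model for a 2x2 game
#'
#' Couples a [payoff_matrix()] to a finite population of size `N`, a
#' selection strength `u`, and a payoff-to-fitness mapping. States of the
#' process are the integer counts `i = 0..N` of players using the first
#' (row) strategy, here called strategy A.
#'
#' Two fitness maps are supported. The linear map `f = 1 - u + u * U` is the
#' model's baseline; because it can turn negative for strongly negative
#' payoffs, fitness is clamped below at `fitness_floor` and every clamp is
#' counted (see [fitness()]). The exponential map `f = exp(u * U)` is always
#' positive and is the appropriate choice under stronger selection.
#'
#' @param payoffs a [payoff_matrix()].
#' @param N population size (>= 2).
#' @param u selection strength in `[0, 1)`; `u = 0` is neutral drift.
#' @param fitness_map `"linear"` or `"exponential"`.
#' @param fitness_floor positive lower clamp for linear fitness.
#' @return Object of class `moran_model`.
#' @examples
#' m <- moran_model(payoff_matrix(2, 1, 1, 2), N = 3, u = 0.5)
#' fixation_probability(m, 1)
#' @export
moran_model <- function(payoffs, N, u,
                        fitness_map = c("linear", "exponential"),
                        fitness_floor = 1e-9) {
  stopifnot(inherits(payoffs, "payoff_matrix"))
  if (!is.numeric(N) || length(N) != 1L || N < 2 || N != round(N))
    stop("invalid parameter `N`: must satisfy N >= 2 and integer", call. = FALSE)
  if (!is.numeric(u) || length(u) != 1L || u < 0 || u >= 1)
    stop("invalid parameter `u`: must satisfy 0 <= u < 1", call. = FALSE)
  if (!is.numeric(fitness_floor) || fitness_floor <= 0)
    stop("invalid parameter `fitness_floor`: must be > 0", call. = FALSE)
  structure(list(payoffs = payoffs, N = as.integer(N), u = u,
                 fitness_map = match.arg(fitness_map),
                 fitness_floor = fitness_floor),
            class = "moran_model")
}

#' @export
print.moran_model <- function(x, ...) {
  cat(sprintf("Moran model: %s vs %s, N = %d, u = %g, %s fitness\n",
              rownames(x$payoffs)[1], rownames(x$payoffs)[2],
              x$N, x$u, x$fitness_map))
  invisible(x)
}

#' Expected payoffs at state i
#'
#' With `i` A-players among `N`, each player samples an opponent uniformly
#' from the other `N - 1` (excluding itself):
#' `U_A = ((i-1) AA + (N-i) AB) / (N-1)` and
#' `U_B = (i BA + (N-i-1) BB) / (N-1)`.
#'
#' @param payoffs a [payoff_matrix()].
#' @param N population size.
#' @param i number of A-players; vectorised, each in `1..N-1`.
#' @return Matrix with columns `U_A`, `U_B`, one row per `i`.
#' @export
expected_payoffs <- function(payoffs, N, i) {
  stopifnot(inherits(payoffs, "payoff_matrix"))
  if (any(i < 1 | i > N - 1))
    stop("state i out of range: need 1 <= i <= N - 1", call. = FALSE)
  U_A <- ((i - 1) * payoffs[1, 1] + (N - i) * payoffs[1, 2]) / (N - 1)
  U_B <- (i * payoffs[2, 1] + (N - i - 1) * payoffs[2, 2]) / (N - 1)
  cbind(U_A = U_A, U_B = U_B)
}

#' Payoff-to-fitness mapping
#'
#' Linear: `max(1 - u + u * U, floor)`; exponential: `exp(u * U)`. The
#' linear map is the model's baseline but is only admissible while it stays
#' positive; clamped values are counted in the `"clamped"` attribute and
#' reported via [message()] when `options(greengame.verbose = TRUE)`.
#'
#' @param U expected payoff (vectorised).
#' @param u selection strength in `[0, 1)`.
#' @param map `"linear"` or `"exponential"`.
#' @param floor positive clamp for the linear map.
#' @return Positive fitness vector with attribute `clamped` (count).
#' @export
fitness <- function(U, u, map = c("linear", "exponential"), floor = 1e-9) {
  map <- match.arg(map)
  if (map == "exponential") {
    f <- exp(u * U)
    attr(f, "clamped") <- 0L
    return(f)
  }
  raw <- 1 - u + u * U
  n_clamped <- sum(raw < floor)
  if (n_clamped > 0L && isTRUE(getOption("greengame.verbose", FALSE)))
    message(sprintf("fitness: clamped %d negative linear value(s) to %g",
                    n_clamped, floor))
  f <- pmax(raw, floor)
  attr(f, "clamped") <- as.integer(n_clamped)
  f
}

# Fitness of both strategies at every interior state 1..N-1.
fitness_profile <- function(model) {
  i <- seq_len(model$N - 1)
  U <- expected_payoffs(model$payoffs, model$N, i)
  f_A <- fitness(U[, "U_A"], model$u, model$fitness_map, model$fitness_floor)
  f_B <- fitness(U[, "U_B"], model$u, model$fitness_map, model$fitness_floor)
  list(i = i, U_A = U[, "U_A"], U_B = U[, "U_B"],
       f_A = as.numeric(f_A), f_B = as.numeric(f_B),
       clamped = attr(f_A, "clamped") + attr(f_B, "clamped"))
}

# One-step up/down probabilities for every state 0..N, optionally with
# offspring mutation.  p_up[i+1] = P(i -> i+1), p_down[i+1] = P(i -> i-1).
step_probabilities <- function(model, mutation_rate = 0) {
  N <- model$N
  fp <- fitness_profile(model)
  i <- fp$i
  p_choose_A <- c(0, i * fp$f_A / (i * fp$f_A + (N - i) * fp$f_B), 1)
  if (mutation_rate > 0)
    p_choose_A <- p_choose_A * (1 - mutation_rate) +
      (1 - p_choose_A) * mutation_rate
  states <- 0:N
  list(p_up = p_choose_A * (N - states) / N,
       p_down = (1 - p_choose_A) * states / N,
       clamped = fp$clamped)
}

#' Transition matrix of the Moran process
#'
#' The tridiagonal `(N+1) x (N+1)` Markov matrix over states `i = 0..N`:
#' `P[i, i+1] = (i f_A / (i f_A + (N-i) f_B)) (N-i)/N`,
#' `P[i, i-1] = ((N-i) f_B / (i f_A + (N-i) f_B)) i/N`, and the diagonal
#' takes the remainder. Without mutation the boundary rows are absorbing.
#'
#' @param model a [moran_model()].
#' @param mutation_rate per-replacement probability that the offspring's
#'   strategy flips; 0 gives the absorbing chain of the analytic theory.
#' @return `(N+1) x (N+1)` matrix, rows/cols named `0..N`, with attribute
#'   `clamped` (number of clamped fitness values).
#' @export
transition_matrix <- function(model, mutation_rate = 0) {
  stopifnot(inherits(model, "moran_model"))
  N <- model$N
  sp <- step_probabilities(model, mutation_rate)
  P <- matrix(0, N + 1, N + 1, dimnames = list(0:N, 0:N))
  idx <- seq_len(N + 1)
  P[cbind(idx[-(N + 1)], idx[-(N + 1)] + 1L)] <- sp$p_up[-(N + 1)]
  P[cbind(idx[-1], idx[-1] - 1L)] <- sp$p_down[-1]
  diag(P) <- 1 - sp$p_up - sp$p_down
  attr(P, "clamped") <- sp$clamped
  P
}

#' Export a transition matrix
#'
#' Dense CSV or a sparse triplet text file (`row,col,value`, zero-based
#' state indices, nonzero entries only).
#'
#' @param P matrix from [transition_matrix()].
#' @param path output file.
#' @param format `"csv"` (dense) or `"triplet"` (sparse).
#' @return `path`, invisibly.
#' @export
write_transition_matrix <- function(P, path, format = c("csv", "triplet")) {
  format <- match.arg(format)
  if (format == "csv") {
    utils::write.csv(as.data.frame(P), path, row.names = TRUE)
  } else {
    nz <- which(P != 0, arr.ind = TRUE)
    df <- data.frame(row = nz[, 1] - 1L, col = nz[, 2] - 1L,
                     value = P[nz])
    df <- df[order(df$row, df$col), ]
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}

# Cumulative log of gamma_j = f_B(j)/f_A(j), j = 1..N-1, plus stable
# log-sum-exp partial sums used by the fixation formulas.
gamma_accumulate <- function(model) {
  fp <- fitness_profile(model)
  lg <- cumsum(log(fp$f_B) - log(fp$f_A))
  if (any(!is.finite(lg)))
    stop("degenerate model: non-finite fitness ratio after clamping",
         call. = FALSE)
  list(lg = lg, clamped = fp$clamped, fp = fp)
}

#' Fixation probabilities of strategy A from every start state
#'
#' The standard birth-death product formula with ratios
#' `gamma_j = f_B(j)/f_A(j)`:
#' `F_i = (1 + sum_{k=1}^{i-1} prod_{j<=k} gamma_j) /`
#' `(1 + sum_{k=1}^{N-1} prod_{j<=k} gamma_j)`, accumulated in log space so
#' strongly selected (or clamped) games cannot overflow.
#'
#' @param model a [moran_model()].
#' @return Numeric vector `F` of length `N + 1` over states `0..N`, with
#'   `F[1] = 0` and `F[N+1] = 1`.
#' @seealso [absorbing_solve()] for the independent linear-algebra oracle.
#' @export
fixation_vector <- function(model) {
  stopifnot(inherits(model, "moran_model"))
  N <- model$N
  ga <- gamma_accumulate(model)
  s <- c(0, ga$lg)                    # log prod_{j<=k} gamma_j, k = 0..N-1
  m <- max(s)
  cs <- cumsum(exp(s - m))            # partial sums, shifted by exp(-m)
  Fv <- c(0, cs[seq_len(N - 1)] / cs[N], 1)
  names(Fv) <- 0:N
  attr(Fv, "clamped") <- ga$clamped
  Fv
}

#' @rdname fixation_vector
#' @param start_i starting number of A-players, in `0..N`.
#' @export
fixation_probability <- function(model, start_i) {
  if (any(start_i < 0 | start_i > model$N))
    stop("start_i out of range 0..N", call. = FALSE)
  unname(fixation_vector(model)[start_i + 1])
}

#' Full fixation analysis of a 2x2 Moran game
#'
#' Computes the fixation-probability vector, its increments
#' `q_i = F_i - F_{i-1}`, the single-invader fixation probabilities
#' `Q_A` (one A among N-1 B) and `Q_B` (one B among N-1 A), and their ratio,
#' which by the birth-death identity equals `prod_i f_A(i)/f_B(i)` and is
#' also reported in log form.
#'
#' @param model a [moran_model()].
#' @return Object of class `fixation_result` with fields `F`, `q`, `Q_A`,
#'   `Q_B`, `ratio`, `log_ratio`, `clamped`, and a `model` echo.
#' @export
fixation_result <- function(model) {
  Fv <- fixation_vector(model)
  N <- model$N
  lg <- gamma_accumulate(model)$lg
  structure(list(
    F = as.numeric(Fv),
    q = diff(as.numeric(Fv)),
    Q_A = as.numeric(Fv[2]),
    Q_B = 1 - as.numeric(Fv[N]),
    ratio = exp(-lg[N - 1]),
    log_ratio = -lg[N - 1],
    clamped = attr(Fv, "clamped"),
    model = list(N = N, u = model$u, fitness_map = model$fitness_map,
                 fitness_floor = model$fitness_floor,
                 labels = rownames(model$payoffs),
                 payoffs = as.numeric(model$payoffs))
  ), class = "fixation_result")
}

#' @export
print.fixation_result <- function(x, ...) {
  lab <- x$model$labels
  cat(sprintf("Fixation analysis (%s vs %s, N = %d, u = %g)\n",
              lab[1], lab[2], x$model$N, x$model$u))
  cat(sprintf("  Q_%s = %.6g  Q_%s = %.6g  ratio = %.6g (log %.4g)\n",
              lab[1], x$Q_A, lab[2], x$Q_B, x$ratio, x$log_ratio))
  if (x$clamped > 0)
    cat(sprintf("  note: %d linear fitness value(s) clamped at the floor\n",
                x$clamped))
  invisible(x)
}

#' Ratio of single-invader fixation probabilities
#'
#' `Q_A / Q_B = prod_{i=1}^{N-1} f_A(i) / f_B(i)`, returned both raw and as
#' a log-ratio (the product of `N - 1` fitness ratios can overflow).
#' A value above 1 means strategy A invades B more readily than B invades A.
#'
#' @param model a [moran_model()].
#' @return List with `ratio` and `log_ratio`.
#' @export
fixation_ratio <- function(model) {
  stopifnot(inherits(model, "moran_model"))
  lg <- gamma_accumulate(model)$lg
  list(ratio = exp(-lg[model$N - 1]), log_ratio = -lg[model$N - 1])
}

#' First-order weak-selection approximation of the fixation ratio
#'
#' Taylor-expanding each linear-fitness ratio around `u = 0` and dropping
#' the higher-order remainder gives
#' `Q_A/Q_B ~ prod_{i=1}^{N-1} (1 + (U_A^i - U_B^i) u)`. The payoff
#' difference sequence and its sum (the derivative of the log-ratio at
#' `u = 0`) are returned so that monotonicity in `u`, `T` and `mu` can be
#' inspected directly. The truncation error is `O(u^2)`; a warning is issued
#' when the approximation strays more than 10% from the exact ratio.
#'
#' @param model a [moran_model()] with the linear fitness map.
#' @return Object of class `weak_selection_result`: `ratio_first_order`,
#'   `payoff_differences`, `first_order_coefficient` (sum of differences),
#'   `exact_ratio`, `rel_error`, `u`.
#' @export
weak_selection_ratio <- function(model) {
  stopifnot(inherits(model, "moran_model"))
  if (model$fitness_map != "linear")
    stop("weak-selection expansion is defined for the linear fitness map",
         call. = FALSE)
  fp <- fitness_profile(model)
  d <- fp$U_A - fp$U_B
  approx <- prod(1 + model$u * d)
  exact <- fixation_ratio(model)$ratio
  rel <- abs(exact - approx) / abs(exact)
  if (is.finite(rel) && rel > 0.1)
    warning(sprintf(paste0(
      "weak-selection approximation off by %.1f%%; u = %g is outside the ",
      "validity regime"), 100 * rel, model$u), call. = FALSE)
  structure(list(ratio_first_order = approx,
                 payoff_differences = d,
                 first_order_coefficient = sum(d),
                 exact_ratio = exact,
                 rel_error = rel,
                 u = model$u),
            class = "weak_selection_result")
}

#' @export
print.weak_selection_result <- function(x, ...) {
  cat(sprintf("Weak-selection fixation ratio (u = %g)\n", x$u))
  cat(sprintf("  first order: %.6g  exact: %.6g  rel. error: %.3g\n",
              x$ratio_first_order, x$exact_ratio, x$rel_error))
  cat(sprintf("  sum of payoff differences: %.6g\n", x$first_order_coefficient))
  invisible(x)
}

#' Payoff-difference profile and interior equilibria
#'
#' The deterministic skeleton of the process: the payoff difference
#' `d(i) = U_A^i - U_B^i` over the interior states, and every sign change,
#' located by linear interpolation between adjacent integer states. A root
#' where `d` passes from positive to negative attracts the deterministic
#' dynamic (stable); negative to positive repels it (unstable).
#'
#' @param model a [moran_model()] (selection strength is irrelevant here).
#' @return List of class `selection_gradient`: `i`, `x` (= i/N), `gradient`,
#'   and `roots`, a data frame with columns `i_root`, `x_root`, `stability`.
#' @export
selection_gradient <- function(model) {
  stopifnot(inherits(model, "moran_model"))
  N <- model$N
  i <- seq_len(N - 1)
  U <- expected_payoffs(model$payoffs, N, i)
  d <- U[, "U_A"] - U[, "U_B"]
  roots <- data.frame(i_root = numeric(0), x_root = numeric(0),
                      stability = character(0), stringsAsFactors = FALSE)
  if (N > 2) {
    for (j in seq_len(N - 2)) {
      if (d[j] == 0 || d[j] * d[j + 1] >= 0) {
        if (d[j] == 0 && d[j + 1] != 0) {
          roots <- rbind(roots, data.frame(
            i_root = i[j], x_root = i[j] / N,
            stability = if (d[j + 1] < 0) "stable" else "unstable"))
        }
        next
      }
      i_root <- i[j] + d[j] / (d[j] - d[j + 1])
      roots <- rbind(roots, data.frame(
        i_root = i_root, x_root = i_root / N,
        stability = if (d[j] > 0) "stable" else "unstable"))
    }
  }
  structure(list(i = i, x = i / N, gradient = unname(d), roots = roots),
            class = "selection_gradient")
}

#' Absorbing-chain oracle for fixation probabilities
#'
#' Solves the linear system `F_i = P[i,i+1] F_{i+1} + P[i,i-1] F_{i-1} +
#' P[i,i] F_i` with `F_0 = 0`, `F_N = 1` by direct dense linear algebra on
#' the interior states. Deliberately independent of the product formula in
#' [fixation_vector()]; the two must agree to near machine precision.
#'
#' @param model a [moran_model()].
#' @param oracle_bound refuse populations larger than this (dense solve).
#' @return Numeric vector of length `N + 1` over states `0..N`.
#' @export
absorbing_solve <- function(model, oracle_bound = 2000) {
  stopifnot(inherits(model, "moran_model"))
  N <- model$N
  if (N > oracle_bound)
    stop(sprintf("oracle limited to N <= %d (dense solve)", oracle_bound),
         call. = FALSE)
  sp <- step_probabilities(model, mutation_rate = 0)
  up <- sp$p_up[2:N]       # states 1..N-1
  dn <- sp$p_down[2:N]
  n <- N - 1
  A <- matrix(0, n, n)
  b <- numeric(n)
  for (k in seq_len(n)) {
    A[k, k] <- up[k] + dn[k]
    if (k > 1) A[k, k - 1] <- -dn[k]
    if (k < n) A[k, k + 1] <- -up[k]
  }
  b[n] <- up[n]
  Fint <- solve(A, b)
  out <- c(0, Fint, 1)
  names(out) <- 0:N
  out
}

#' Exact stationary distribution of the mutation-augmented chain
#'
#' With mutation the tridiagonal chain is irreducible and reversible; the
#' stationary distribution follows from detailed balance,
#' `pi_{i+1}/pi_i = P[i,i+1]/P[i+1,i]`, accumulated in log space.
#'
#' @param model a [moran_model()].
#' @param mutation_rate per-replacement mutation probability, must be > 0.
#' @return Probability vector over states `0..N`.
#' @export
stationary_distribution <- function(model, mutation_rate) {
  stopifnot(inherits(model, "moran_model"))
  if (!is.numeric(mutation_rate) || mutation_rate <= 0 || mutation_rate >= 1)
    stop("stationary distribution requires 0 < mutation_rate < 1 ",
         "(the absorbing chain has no interior stationary mass)", call. = FALSE)
  N <- model$N
  sp <- step_probabilities(model, mutation_rate)
  lr <- log(sp$p_up[1:N]) - log(sp$p_down[2:(N + 1)])
  lp <- c(0, cumsum(lr))
  lp <- lp - max(lp)
  p <- exp(lp) / sum(exp(lp))
  names(p) <- 0:N
  p
}
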