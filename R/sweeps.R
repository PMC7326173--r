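# Per-game metric bundle shared by the sweep functions.
game_metrics <- function(payoffs, N, u, fitness_map, fitness_floor) {
  model <- moran_model(payoffs, N = N, u = u, fitness_map = fitness_map,
                       fitness_floor = fitness_floor)
  fr <- fixation_result(model)
  fp <- fitness_profile(model)
  d <- fp$U_A - fp$U_B
  first_order <- if (fitness_map == "linear") prod(1 + u * d) else NA_real_
  sg <- selection_gradient(model)
  stable <- sg$roots[sg$roots$stability == "stable", , drop = FALSE]
  x_star <- if (nrow(stable)) stable$x_root[1]
            else if (nrow(sg$roots)) sg$roots$x_root[1] else NA_real_
  list(Q_A = fr$Q_A, n_Q_A = N * fr$Q_A, Q_B = fr$Q_B,
       log_ratio = fr$log_ratio, first_order_ratio = first_order,
       first_order_coefficient = sum(d), x_star = x_star,
       clamped = fr$clamped)
}

metric_value <- function(metrics, metric) {
  switch(metric,
         n_qa = metrics$n_Q_A,
         qa = metrics$Q_A,
         log_ratio = metrics$log_ratio,
         stop("unknown metric", call. = FALSE))
}

metric_baseline <- function(metric, N) {
  switch(metric, n_qa = 1, qa = 1 / N, log_ratio = 0)
}

#' Sweep the incentive strength and locate its threshold
#'
#' Builds the stage-1 innovate-vs-free-ride game at every incentive value in
#' `T_grid`, computes fixation metrics, and reports the smallest incentive
#' at which the chosen metric exceeds its neutral baseline (`N * Q_V` vs 1
#' by default), refined by bisection between the bracketing grid points.
#' The metric is monotone in the incentive under the linear map (the
#' incentive enters only the innovator payoffs), so the crossing is unique.
#'
#' @param params an [econ_params()] object.
#' @param T_grid strictly increasing vector of incentive values.
#' @param u selection strength.
#' @param fitness_map,fitness_floor passed to [moran_model()].
#' @param metric threshold metric: `"n_qa"` (N * Q_A vs 1, default), `"qa"`
#'   (Q_A vs 1/N) or `"log_ratio"` (log Q_A/Q_B vs 0).
#' @param refine bisection-refine the bracketed crossing.
#' @param refine_tol absolute tolerance on the incentive axis.
#' @return Object of class `sweep_result`: `grid` data frame (one row per
#'   incentive value), `threshold` (or `NA`), `status` (`"bracketed"`,
#'   `"above_everywhere"`, `"below_everywhere"`), `metric`, `baseline`,
#'   and a parameter echo. A warning of class `greengame_no_threshold` is
#'   signalled when the metric never crosses the baseline inside the grid.
#' @export
sweep_incentive <- function(params, T_grid, u = 0.5,
                            fitness_map = c("linear", "exponential"),
                            fitness_floor = 1e-9, metric = "n_qa",
                            refine = TRUE, refine_tol = 1e-3) {
  stopifnot(inherits(params, "econ_params"))
  fitness_map <- match.arg(fitness_map)
  if (length(T_grid) < 1 || any(diff(T_grid) <= 0))
    stop("T_grid must be nonempty and strictly increasing", call. = FALSE)
  N <- params$N
  rows <- lapply(T_grid, function(Tv) {
    m <- game_metrics(stage1_payoffs(params, T_incentive = Tv), N, u,
                      fitness_map, fitness_floor)
    data.frame(T_incentive = Tv, Q_A = m$Q_A, n_Q_A = m$n_Q_A,
               log_ratio = m$log_ratio, first_order_ratio = m$first_order_ratio,
               first_order_coefficient = m$first_order_coefficient,
               x_star = m$x_star, clamped = m$clamped)
  })
  grid <- do.call(rbind, rows)
  base <- metric_baseline(metric, N)
  vals <- vapply(seq_len(nrow(grid)), function(k)
    metric_value(as.list(grid[k, ]), metric), numeric(1))

  eval_T <- function(Tv) metric_value(
    game_metrics(stage1_payoffs(params, T_incentive = Tv), N, u,
                 fitness_map, fitness_floor), metric)

  threshold <- NA_real_
  status <- "below_everywhere"
  if (vals[1] >= base) {
    status <- "above_everywhere"
    threshold <- T_grid[1]
  } else {
    cross <- which(vals >= base)
    if (length(cross)) {
      j <- cross[1]
      lo <- T_grid[j - 1]; hi <- T_grid[j]
      if (refine) {
        while (hi - lo > refine_tol) {
          mid <- (lo + hi) / 2
          if (eval_T(mid) >= base) hi <- mid else lo <- mid
        }
      }
      threshold <- hi
      status <- "bracketed"
    }
  }
  if (status == "below_everywhere") {
    w <- simpleWarning(
      "no threshold: metric never crosses the neutral baseline within T_grid")
    class(w) <- c("greengame_no_threshold", class(w))
    warning(w)
  }
  structure(list(grid = grid, threshold = threshold, status = status,
                 metric = metric, baseline = base,
                 settings = list(u = u, fitness_map = fitness_map,
                                 fitness_floor = fitness_floor,
                                 refine_tol = refine_tol),
                 params = unclass(params)),
            class = "sweep_result")
}

#' Sweep the differential coefficient and incentive jointly
#'
#' Stage-2 lead-vs-follow metrics on the full `(mu, T)` grid, including the
#' interior-equilibrium location from the payoff-difference profile and the
#' incentive-response coefficient (see [incentive_response()]).
#'
#' @param params an [econ_params()] object.
#' @param mu_grid strictly increasing values in `[1, 2]`.
#' @param T_grid strictly increasing incentive values.
#' @inheritParams sweep_incentive
#' @return Object of class `sweep_result` whose `grid` has one row per
#'   `(mu, T)` combination.
#' @export
sweep_mu_T <- function(params, mu_grid, T_grid, u = 0.5,
                       fitness_map = c("linear", "exponential"),
                       fitness_floor = 1e-9, metric = "n_qa") {
  stopifnot(inherits(params, "econ_params"))
  fitness_map <- match.arg(fitness_map)
  if (any(diff(mu_grid) <= 0) || any(diff(T_grid) <= 0) ||
      !length(mu_grid) || !length(T_grid))
    stop("grids must be nonempty and strictly increasing", call. = FALSE)
  if (any(mu_grid < 1 | mu_grid > 2))
    stop("mu_grid must lie within [1, 2]", call. = FALSE)
  N <- params$N
  combos <- expand.grid(mu = mu_grid, T_incentive = T_grid,
                        KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(combos)), function(k) {
    muv <- combos$mu[k]; Tv <- combos$T_incentive[k]
    m <- game_metrics(stage2_payoffs(params, T_incentive = Tv, mu = muv),
                      N, u, fitness_map, fitness_floor)
    data.frame(mu = muv, T_incentive = Tv, Q_A = m$Q_A, n_Q_A = m$n_Q_A,
               log_ratio = m$log_ratio, first_order_ratio = m$first_order_ratio,
               first_order_coefficient = m$first_order_coefficient,
               incentive_response = incentive_response(params, mu = muv),
               x_star = m$x_star, clamped = m$clamped)
  })
  structure(list(grid = do.call(rbind, rows), threshold = NA_real_,
                 status = "grid", metric = metric,
                 baseline = metric_baseline(metric, N),
                 settings = list(u = u, fitness_map = fitness_map,
                                 fitness_floor = fitness_floor),
                 params = unclass(params)),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("Parameter sweep (%d grid points, metric %s vs baseline %g)\n",
              nrow(x$grid), x$metric, x$baseline))
  if (!is.na(x$threshold))
    cat(sprintf("  threshold: %.4g (%s)\n", x$threshold, x$status))
  else cat(sprintf("  status: %s\n", x$status))
  invisible(x)
}

#' @export
as.data.frame.sweep_result <- function(x, ...) x$grid

#' Incentive-response coefficient of the lead-vs-follow game
#'
#' The derivative with respect to the incentive strength of the first-order
#' invasion exponent `sum_i (U_L^i - U_F^i)`:
#' `P(C) * ((N-1) * mu - (N/2) * (2 - mu))`. Leaders gain `mu P(C)` per unit
#' of incentive in every state while followers gain `(2-mu) P(C)` weighted
#' by the leader frequency, so a higher differential coefficient `mu` makes
#' the invasion exponent respond more steeply to the incentive - this is the
#' common factor the grouped weak-selection form isolates.
#'
#' @param params an [econ_params()] object.
#' @param mu differential coefficient (defaults to `params$mu`).
#' @return Scalar coefficient (utility per unit incentive).
#' @export
incentive_response <- function(params, mu = params$mu) {
  stopifnot(inherits(params, "econ_params"))
  N <- params$N
  params$P_success * ((N - 1) * mu - (N / 2) * (2 - mu))
}

#' Interior equilibrium of a game as a function of the incentive
#'
#' Finds the incentive value whose stage-2 game has its interior equilibrium
#' at a target frequency, by root-finding on the equilibrium location. Used
#' to extract iso-equilibrium contours of the `(mu, T)` plane: parameter
#' pairs with equal equilibrium structure but different invasion speed.
#'
#' @param params an [econ_params()] object.
#' @param target_x target equilibrium frequency in (0, 1).
#' @param mu differential coefficient of the game.
#' @param T_range search interval for the incentive.
#' @return The matching incentive value, or `NA` if the target is not
#'   attained inside `T_range`.
#' @export
iso_equilibrium_T <- function(params, target_x, mu, T_range = c(1, 500)) {
  stopifnot(inherits(params, "econ_params"))
  locate <- function(Tv) {
    pm <- stage2_payoffs(params, T_incentive = Tv, mu = mu)
    sg <- selection_gradient(moran_model(pm, N = params$N, u = 0))
    st <- sg$roots[sg$roots$stability == "stable", , drop = FALSE]
    if (!nrow(st)) return(NA_real_)
    st$x_root[1]
  }
  f <- function(Tv) locate(Tv) - target_x
  lo <- f(T_range[1]); hi <- f(T_range[2])
  if (!is.finite(lo) || !is.finite(hi) || lo * hi > 0) return(NA_real_)
  stats::uniroot(f, T_range, tol = 1e-6)$root
}

#' Sequential two-stage analysis
#'
#' Stage 1 (innovate vs free-ride) is analysed first; conditional on
#' innovation fixating, stage 2 (lead vs follow) is analysed in the same
#' population. Stage 2 is marked unreached when innovation is strictly
#' dominated in stage 1. The end-to-end summary multiplies the two
#' single-invader fixation probabilities when stage 2 is reached and
#' reduces to the stage-1 probability otherwise.
#'
#' @param params an [econ_params()] object.
#' @param T_incentive,mu incentive parameters (default from `params`).
#' @param u selection strength used in both stages.
#' @param fitness_map,fitness_floor passed to [moran_model()].
#' @return Object of class `two_stage_report`: `stage1` and `stage2`
#'   [fixation_result()]s, the payoff matrices, `stage2_reached`, and
#'   `end_to_end`.
#' @export
two_stage_run <- function(params, T_incentive = params$T_incentive,
                          mu = params$mu, u = 0.1,
                          fitness_map = c("linear", "exponential"),
                          fitness_floor = 1e-9) {
  stopifnot(inherits(params, "econ_params"))
  fitness_map <- match.arg(fitness_map)
  pm1 <- stage1_payoffs(params, T_incentive = T_incentive)
  pm2 <- stage2_payoffs(params, T_incentive = T_incentive, mu = mu)
  m1 <- moran_model(pm1, N = params$N, u = u, fitness_map = fitness_map,
                    fitness_floor = fitness_floor)
  m2 <- moran_model(pm2, N = params$N, u = u, fitness_map = fitness_map,
                    fitness_floor = fitness_floor)
  f1 <- fixation_result(m1)
  dominated <- pm1["V", "V"] < pm1["D", "V"] && pm1["V", "D"] < pm1["D", "D"]
  reached <- !dominated
  f2 <- fixation_result(m2)
  structure(list(stage1 = f1, stage2 = f2,
                 payoffs = list(stage1 = pm1, stage2 = pm2),
                 stage2_reached = reached,
                 end_to_end = if (reached) f1$Q_A * f2$Q_A else f1$Q_A,
                 settings = list(T_incentive = T_incentive, mu = mu, u = u,
                                 fitness_map = fitness_map)),
            class = "two_stage_report")
}

#' @export
print.two_stage_report <- function(x, ...) {
  s <- x$settings
  cat(sprintf("Two-stage run (T = %g, mu = %g, u = %g)\n",
              s$T_incentive, s$mu, s$u))
  cat(sprintf("  stage 1 (V vs D): Q_V = %.6g\n", x$stage1$Q_A))
  if (x$stage2_reached)
    cat(sprintf("  stage 2 (L vs F): Q_L = %.6g\n", x$stage2$Q_A))
  else cat("  stage 2 not reached (innovation strictly dominated)\n")
  cat(sprintf("  end-to-end single-invader probability: %.6g\n", x$end_to_end))
  invisible(x)
}
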