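#' Economic scenario parameters for the innovation game
#'
#' Bundles the economic and policy quantities that generate the two payoff
#' matrices of the model: the cost structure of the market, the societal
#' reward from green technology and how it is shared, the R&D cost and its
#' success probability, the policy incentive, and the discounting horizon.
#'
#' The market story: non-innovators produce at marginal cost `C1 > 1`,
#' innovators at cost 1 and price `C1`, so innovation earns the margin
#' `(C1 - 1)/C1` on its share of the societal reward `R`. During the monopoly
#' period (`0` to `t1`) a single leading innovator captures share `a`; after
#' followers enter (`t1` to `t2`) the duopoly jointly captures share `b`,
#' split equally. If nobody innovates every participant bears the per-capita
#' ecological loss `-R_star`. Successful innovation (probability `P_success`)
#' additionally earns the policy incentive `T`, split unevenly between
#' leaders (`mu * T`) and followers (`(2 - mu) * T`) in the second stage.
#'
#' @param N population size (number of participants, >= 2).
#' @param C1 non-innovator marginal cost, must exceed the innovator cost 1.
#' @param a innovators' share of the societal reward during monopoly, in (0, 1).
#' @param b total share captured by the leader/follower duopoly; the printed
#'   model constraint `0 < a*b < 2*a` is enforced as written.
#' @param R total societal reward from green technology (utility units).
#' @param R_star per-capita loss borne when no one innovates (>= 0). The model
#'   text posits `R = N * R_star`; a violation is reported as a warning, not an
#'   error, because the published simulation scenario itself violates it.
#' @param C R&D input cost (> 0).
#' @param P_success probability that the R&D input succeeds, in (0, 1].
#' @param T_incentive policy incentive strength `T` (> 0).
#' @param mu differential coefficient in `[1, 2]`: leaders receive `mu * T`,
#'   followers `(2 - mu) * T`, so the mean incentive is always `T`.
#' @param r discount rate of future utility (> 0).
#' @param t1,t2 stage boundary times, `0 < t1 < t2` (the model sets `t0 = 0`).
#'
#' @return An object of class `econ_params` (a validated named list).
#' @seealso [innovation_rewards()], [stage1_payoffs()], [stage2_payoffs()]
#' @examples
#' p <- econ_params(N = 10, C1 = 2, a = 0.4, b = 0.7, R = 1000, R_star = 100,
#'                  C = 100, P_success = 0.4, T_incentive = 85, mu = 1.297,
#'                  r = 0.015, t1 = 100, t2 = 300)
#' innovation_rewards(p)
#' @export
econ_params <- function(N, C1, a, b, R, R_star, C, P_success, T_incentive,
                        mu = 1, r, t1, t2) {
  chk <- function(ok, field, constraint) {
    if (!isTRUE(ok)) {
      stop(sprintf("invalid parameter `%s`: must satisfy %s", field, constraint),
           call. = FALSE)
    }
  }
  num1 <- function(x, field) {
    chk(is.numeric(x) && length(x) == 1L && is.finite(x), field,
        "a single finite number")
    as.numeric(x)
  }
  N <- num1(N, "N"); C1 <- num1(C1, "C1"); a <- num1(a, "a"); b <- num1(b, "b")
  R <- num1(R, "R"); R_star <- num1(R_star, "R_star"); C <- num1(C, "C")
  P_success <- num1(P_success, "P_success")
  T_incentive <- num1(T_incentive, "T_incentive")
  mu <- num1(mu, "mu"); r <- num1(r, "r"); t1 <- num1(t1, "t1"); t2 <- num1(t2, "t2")

  chk(N >= 2 && N == round(N), "N", "N >= 2 and integer")
  chk(C1 > 1, "C1", "C1 > 1")
  chk(a > 0 && a < 1, "a", "0 < a < 1")
  chk(a * b > 0 && a * b < 2 * a, "b", "0 < a*b < 2*a")
  chk(R_star >= 0, "R_star", "R_star >= 0")
  chk(C > 0, "C", "C > 0")
  chk(P_success > 0 && P_success <= 1, "P_success", "0 < P_success <= 1")
  chk(T_incentive > 0, "T_incentive", "T_incentive > 0")
  chk(mu >= 1 && mu <= 2, "mu", "1 <= mu <= 2")
  chk(r > 0, "r", "r > 0")
  chk(t1 > 0 && t1 < t2, "t1", "0 < t1 < t2")

  out <- structure(
    list(N = as.integer(N), C1 = C1, a = a, b = b, R = R, R_star = R_star,
         C = C, P_success = P_success, T_incentive = T_incentive, mu = mu,
         r = r, t1 = t1, t2 = t2),
    class = "econ_params"
  )
  if (!isTRUE(all.equal(R, N * R_star))) {
    warning(sprintf(
      "R (%g) differs from N * R_star (%g); the model posits R = N * R_star",
      R, N * R_star), call. = FALSE)
  }
  out
}

#' @export
print.econ_params <- function(x, ...) {
  cat("Economic scenario (innovation game)\n")
  cat(sprintf("  population N = %d, incentive T = %g (mu = %g)\n",
              x$N, x$T_incentive, x$mu))
  cat(sprintf("  costs: C1 = %g, R&D C = %g with P(success) = %g\n",
              x$C1, x$C, x$P_success))
  cat(sprintf("  reward R = %g (shares a = %g, b = %g), loss R* = %g\n",
              x$R, x$a, x$b, x$R_star))
  cat(sprintf("  discounting: r = %g over 0 < %g < %g\n", x$r, x$t1, x$t2))
  invisible(x)
}

# Discounted time-span factors shared by every payoff formula:
#   full   = 1 - e^{-r t2}          (whole horizon)
#   first  = 1 - e^{-r t1}          (monopoly period)
#   second = e^{-r t1} - e^{-r t2}  (duopoly period)
discount_spans <- function(params) {
  r <- params$r
  list(full   = 1 - exp(-r * params$t2),
       first  = 1 - exp(-r * params$t1),
       second = exp(-r * params$t1) - exp(-r * params$t2))
}

#' Per-capita discounted market-reward terms
#'
#' The three building blocks of all payoff cells: the margin
#' `P(C) (C1-1) / (N r C1)` applied to the duopoly share `b R` over the whole
#' horizon, to the monopoly share `a R` over the first period, and to `b R`
#' over the second period.
#'
#' @param params an [econ_params()] object.
#' @return Named list with components `b_full`, `a_first`, `b_second`.
#' @export
market_share_terms <- function(params) {
  stopifnot(inherits(params, "econ_params"))
  sp <- discount_spans(params)
  k <- params$P_success * (params$C1 - 1) /
    (params$N * params$r * params$C1)
  list(b_full   = k * sp$full   * params$b * params$R,
       a_first  = k * sp$first  * params$a * params$R,
       b_second = k * sp$second * params$b * params$R)
}

#' Discounted innovation rewards and utilities
#'
#' Aggregate reward flows and total discounted utilities of the two innovator
#' roles: the monopoly-period flow `R1 = (C1-1) a R / C1`, the duopoly flows
#' `R1* = R2 = (C1-1) b R / (2 C1)` (the reward is split equally between
#' leader and follower), and the discounted totals
#' `V1 = R1/r (1 - e^{-r t1}) + R1*/r (e^{-r t1} - e^{-r t2})` for the leader
#' and `V2 = R2/r (e^{-r t1} - e^{-r t2})` for the follower.
#'
#' @param params an [econ_params()] object.
#' @return Object of class `reward_breakdown`: list with `R1`, `R1_star`,
#'   `R2`, `V1`, `V2`.
#' @export
innovation_rewards <- function(params) {
  stopifnot(inherits(params, "econ_params"))
  sp <- discount_spans(params)
  R1 <- (params$C1 - 1) * params$a * params$R / params$C1
  R2 <- (params$C1 - 1) * params$b * params$R / (2 * params$C1)
  V1 <- R1 / params$r * sp$first + R2 / params$r * sp$second
  V2 <- R2 / params$r * sp$second
  structure(list(R1 = R1, R1_star = R2, R2 = R2, V1 = V1, V2 = V2),
            class = "reward_breakdown")
}

#' @export
print.reward_breakdown <- function(x, ...) {
  cat("Discounted innovation rewards\n")
  cat(sprintf("  monopoly flow R1 = %g; duopoly flows R1* = R2 = %g\n",
              x$R1, x$R2))
  cat(sprintf("  leader utility V1 = %g; follower utility V2 = %g\n",
              x$V1, x$V2))
  invisible(x)
}
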