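# Shared fixtures: the baseline economic scenario and random bounded games.

baseline_params <- function(T_incentive = 85, mu = 1.297) {
  suppressWarnings(econ_params(
    N = 100, C1 = 2, a = 0.4, b = 0.7, R = 1000, R_star = 100, C = 100,
    P_success = 0.4, T_incentive = T_incentive, mu = mu,
    r = 0.015, t1 = 100, t2 = 300))
}

random_game <- function(lo = -2, hi = 2) {
  e <- stats::runif(4, lo, hi)
  payoff_matrix(e[1], e[2], e[3], e[4])
}

random_econ <- function() {
  a <- stats::runif(1, 0.1, 0.9)
  suppressWarnings(econ_params(
    N = sample(5:40, 1), C1 = stats::runif(1, 1.2, 3), a = a,
    b = stats::runif(1, 0.1, 1.5), R = stats::runif(1, 100, 2000),
    R_star = stats::runif(1, 0, 200), C = stats::runif(1, 10, 200),
    P_success = stats::runif(1, 0.1, 1), T_incentive = stats::runif(1, 1, 150),
    mu = stats::runif(1, 1, 2), r = stats::runif(1, 0.005, 0.1),
    t1 = stats::runif(1, 10, 100), t2 = stats::runif(1, 110, 400)))
}
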