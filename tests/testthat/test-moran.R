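test_that("expected payoffs are the exclusion-of-self convex combinations", {
  pm <- payoff_matrix(2, 1, 1, 2)
  U <- expected_payoffs(pm, N = 3, i = 1:2)
  expect_equal(unname(U[1, ]), c(1, 1.5))
  expect_equal(unname(U[2, ]), c(1.5, 1))

  cg <- payoff_matrix(0.7, 0.7, 0.7, 0.7)
  U <- expected_payoffs(cg, N = 12, i = 1:11)
  expect_equal(as.numeric(U), rep(0.7, 22))

  # at i = N-1 a lone free rider meets no other free rider
  pm1 <- stage1_payoffs(baseline_params())
  expect_identical(expected_payoffs(pm1, 100, 99)[, "U_B"][[1]], 0)
  expect_error(expected_payoffs(pm, 3, 3), "out of range")
})

test_that("fitness maps behave at the anchors and clamp negative values", {
  expect_equal(as.numeric(fitness(c(-5, 0, 7), u = 0)), c(1, 1, 1))
  expect_equal(as.numeric(fitness(1, u = 0.73)), 1)
  f <- fitness(-100, u = 0.5, floor = 1e-9)
  expect_identical(as.numeric(f), 1e-9)
  expect_identical(attr(f, "clamped"), 1L)
  expect_gt(as.numeric(fitness(-100, u = 0.9, map = "exponential")), 0)
})

test_that("transition matrices are stochastic, tridiagonal and absorbing", {
  set.seed(42)
  for (k in 1:200) {
    model <- moran_model(random_game(), N = sample(2:30, 1),
                         u = runif(1, 0, 0.9))
    P <- transition_matrix(model)
    N <- model$N
    expect_lt(max(abs(rowSums(P) - 1)), 1e-12)
    expect_true(all(P >= 0 & P <= 1))
    expect_identical(P[1, 1], 1)
    expect_identical(P[N + 1, N + 1], 1)
    expect_true(all(P[abs(row(P) - col(P)) > 1] == 0))
  }
})

test_that("transition probabilities match hand-computed cases", {
  # neutral symmetric random walk: P(i, i+1) = i(N-i)/N^2
  m <- moran_model(random_game(), N = 4, u = 0)
  P <- transition_matrix(m)
  expect_equal(P["2", "3"], 0.25)
  expect_equal(P["2", "1"], 0.25)
  expect_equal(P["2", "2"], 0.5)

  m <- moran_model(payoff_matrix(2, 1, 1, 2), N = 3, u = 0.5)
  P <- transition_matrix(m)
  expect_equal(P["1", "2"], (1 * 1.0 / (1.0 + 2 * 1.25)) * (2 / 3),
               tolerance = 1e-12)
  expect_equal(P["1", "0"], (2 * 1.25 / 3.5) * (1 / 3), tolerance = 1e-12)
})

test_that("neutral drift fixes a mutant with probability i/N", {
  for (N in c(2, 10, 100)) {
    m <- moran_model(random_game(), N = N, u = 0)
    Fv <- fixation_vector(m)
    expect_equal(as.numeric(Fv), (0:N) / N, tolerance = 1e-14)
    expect_equal(fixation_probability(m, 1), 1 / N, tolerance = 1e-14)
  }
})

test_that("product formula matches hand computation and is monotone", {
  m <- moran_model(payoff_matrix(2, 1, 1, 2), N = 3, u = 0.5)
  expect_equal(fixation_probability(m, 1), 1 / 3.25, tolerance = 1e-12)
  expect_equal(fixation_probability(m, 2), 1 - 1 / 3.25, tolerance = 1e-12)
  set.seed(7)
  for (k in 1:20) {
    m <- moran_model(random_game(), N = sample(3:40, 1), u = runif(1, 0, 0.3))
    Fv <- fixation_vector(m)
    expect_identical(Fv[[1]], 0)
    expect_identical(Fv[[m$N + 1]], 1)
    expect_true(all(diff(Fv) >= -1e-15))
    expect_equal(sum(diff(Fv)), 1, tolerance = 1e-12)
  }
})

test_that("frequency-independent selection recovers the geometric closed form", {
  set.seed(11)
  for (k in 1:20) {
    ab <- runif(2, -1.5, 1.5)
    pm <- payoff_matrix(ab[1], ab[1], ab[2], ab[2])
    N <- sample(3:60, 1)
    u <- runif(1, 0, 0.3)
    m <- moran_model(pm, N = N, u = u)
    gam <- (1 - u + u * ab[2]) / (1 - u + u * ab[1])
    expect_equal(fixation_probability(m, 1), (1 - gam) / (1 - gam^N),
                 tolerance = 1e-12)
  }
})

test_that("product formula agrees with the absorbing-chain oracle", {
  set.seed(99)
  for (k in 1:100) {
    m <- moran_model(random_game(), N = sample(3:50, 1), u = runif(1, 0, 0.1))
    expect_lt(max(abs(fixation_vector(m) - absorbing_solve(m))), 1e-10)
  }
  m <- moran_model(payoff_matrix(2, 1, 1, 2), N = 3, u = 0)
  expect_equal(as.numeric(absorbing_solve(m)), (0:3) / 3, tolerance = 1e-14)
})

test_that("the fixation ratio equals the product of fitness ratios", {
  m <- moran_model(payoff_matrix(2, 1, 1, 2), N = 3, u = 0.5)
  expect_equal(fixation_ratio(m)$ratio, 1, tolerance = 1e-12)
  expect_equal(fixation_ratio(moran_model(random_game(), 15, 0))$ratio, 1)
  set.seed(13)
  for (k in 1:30) {
    m <- moran_model(random_game(), N = sample(3:30, 1), u = runif(1, 0, 0.2))
    fr <- fixation_result(m)
    expect_equal(fr$ratio, fr$Q_A / fr$Q_B, tolerance = 1e-9)
  }
})

test_that("weak-selection expansion is first-order exact at u = 0", {
  pm <- stage1_payoffs(baseline_params())
  m0 <- moran_model(pm, N = 100, u = 0)
  expect_equal(weak_selection_ratio(m0)$ratio_first_order, 1)

  # derivative of the approximation at u = 0 equals the log-derivative of
  # the exact ratio, both by central finite differences
  set.seed(5)
  for (k in 1:10) {
    pm <- random_game()
    N <- sample(4:25, 1)
    h <- 1e-6
    appr <- function(u) weak_selection_ratio(
      moran_model(pm, N = N, u = u))$ratio_first_order
    exact <- function(u) fixation_ratio(moran_model(pm, N = N, u = u))$ratio
    d_appr <- (appr(h) - appr(0)) / h
    d_exact <- (log(exact(h)) - log(exact(0))) / h
    S <- weak_selection_ratio(moran_model(pm, N = N, u = 0))$first_order_coefficient
    expect_equal(d_appr, S, tolerance = 1e-4)
    expect_equal(d_exact, S, tolerance = 1e-4)
  }
  expect_error(weak_selection_ratio(
    moran_model(pm, N = 10, u = 0.1, fitness_map = "exponential")), "linear")
})

test_that("the mu-sensitivity of the lead-follow payoff difference matches the grouped common factor", {
  set.seed(17)
  for (k in 1:5) {
    p <- random_econ()
    N <- p$N
    h <- 1e-6
    d_at <- function(mu) {
      U <- expected_payoffs(stage2_payoffs(p, mu = mu), N, seq_len(N - 1))
      U[, "U_A"] - U[, "U_B"]
    }
    sens <- (d_at(1.5 + h) - d_at(1.5 - h)) / (2 * h)
    i <- seq_len(N - 1)
    expect_equal(sens,
                 p$P_success * p$T_incentive * (N - 1 + i) / (N - 1),
                 tolerance = 1e-4)
  }
})

test_that("selection gradient finds and classifies interior equilibria", {
  # strict dominance: positive gradient, no roots
  m <- moran_model(payoff_matrix(3, 2, 1, 0), N = 12, u = 0)
  sg <- selection_gradient(m)
  expect_true(all(sg$gradient > 0))
  expect_identical(nrow(sg$roots), 0L)

  # coordination game: single unstable interior root at the midpoint
  m <- moran_model(payoff_matrix(5, 0, 0, 5), N = 11, u = 0)
  sg <- selection_gradient(m)
  expect_identical(nrow(sg$roots), 1L)
  expect_gt(sg$roots$i_root, 5)
  expect_lt(sg$roots$i_root, 6)
  expect_identical(sg$roots$stability, "unstable")

  # baseline stage-2 game: one stable root (hawk-dove-like profile)
  m <- moran_model(stage2_payoffs(baseline_params()), N = 100, u = 0)
  sg <- selection_gradient(m)
  expect_identical(nrow(sg$roots), 1L)
  expect_identical(sg$roots$stability, "stable")
  expect_equal(sg$roots$x_root, 0.9231006, tolerance = 1e-6)
})

test_that("stationary distribution satisfies detailed balance and symmetry", {
  m <- moran_model(payoff_matrix(1, 1, 1, 1), N = 2, u = 0)
  p <- stationary_distribution(m, mutation_rate = 0.5)
  expect_equal(p[["0"]], p[["2"]])
  expect_equal(sum(p), 1, tolerance = 1e-12)
  expect_error(stationary_distribution(m, 0), "mutation_rate")

  # detailed balance holds on the full transition matrix
  m <- moran_model(random_game(), N = 15, u = 0.1)
  pi <- stationary_distribution(m, 0.05)
  P <- transition_matrix(m, mutation_rate = 0.05)
  lhs <- pi[1:15] * P[cbind(1:15, 2:16)]
  rhs <- pi[2:16] * P[cbind(2:16, 1:15)]
  expect_equal(unname(lhs), unname(rhs), tolerance = 1e-12)
  # and pi is a left eigenvector
  expect_equal(as.numeric(pi %*% P), as.numeric(pi), tolerance = 1e-12)
})

test_that("transition matrices export to dense CSV and sparse triplets", {
  m <- moran_model(payoff_matrix(2, 1, 1, 2), N = 4, u = 0.2)
  P <- transition_matrix(m)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_transition_matrix(P, f1, "csv")
  write_transition_matrix(P, f2, "triplet")
  dense <- read.csv(f1, row.names = 1)
  expect_equal(as.numeric(as.matrix(dense)), as.numeric(P))
  trip <- read.csv(f2)
  expect_identical(names(trip), c("row", "col", "value"))
  expect_equal(sum(trip$value), sum(P))
})
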