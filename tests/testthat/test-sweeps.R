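test_that("a pure incentive game is above baseline at every positive incentive", {
  p <- econ_params(N = 20, C1 = 2, a = 0.4, b = 0.7, R = 0, R_star = 0,
                   C = 1e-12, P_success = 0.4, T_incentive = 1,
                   r = 0.015, t1 = 100, t2 = 300)
  sw <- sweep_incentive(p, T_grid = c(1, 5, 10), u = 0.05)
  expect_identical(sw$status, "above_everywhere")
  expect_true(all(sw$grid$n_Q_A > 1))
  expect_identical(sw$threshold, 1)
})

test_that("the incentive threshold is bracketed and grid-stable", {
  p <- baseline_params()
  sw <- sweep_incentive(p, T_grid = seq(1, 150, by = 10), u = 0.1,
                        refine_tol = 1e-3)
  expect_identical(sw$status, "bracketed")
  expect_gt(sw$threshold, 0)
  # monotone metric: below baseline strictly before, at or above after
  eval_T <- function(Tv) {
    m <- moran_model(stage1_payoffs(p, T_incentive = Tv), N = p$N, u = 0.1)
    p$N * fixation_result(m)$Q_A
  }
  delta <- 5e-3
  expect_lt(eval_T(sw$threshold - delta), 1)
  expect_gte(eval_T(sw$threshold + delta), 1)
  # metric nondecreasing in the incentive along the grid
  expect_true(all(diff(sw$grid$n_Q_A) >= -1e-12))

  # halving the grid step moves the refined threshold by less than the
  # coarse step
  sw2 <- sweep_incentive(p, T_grid = seq(1, 150, by = 5), u = 0.1,
                         refine_tol = 1e-3)
  expect_lt(abs(sw2$threshold - sw$threshold), 10)
})

test_that("a never-crossing sweep signals no-threshold", {
  p <- baseline_params()
  # below the threshold region the metric stays under the neutral baseline
  expect_warning(
    sw <- sweep_incentive(p, T_grid = c(0.5, 1, 2), u = 0.1),
    class = "greengame_no_threshold")
  expect_identical(sw$status, "below_everywhere")
  expect_true(is.na(sw$threshold))
})

test_that("stage-2 metrics increase with the differential coefficient", {
  p <- baseline_params()
  sw <- sweep_mu_T(p, mu_grid = seq(1, 2, by = 0.1), T_grid = c(50, 85),
                   u = 0.05)
  for (Tv in c(50, 85)) {
    rows <- sw$grid[sw$grid$T_incentive == Tv, ]
    expect_true(all(diff(rows$Q_A) >= -1e-12))
    expect_true(all(diff(rows$incentive_response) > 0))
  }
  # mu = 1 row equals a direct equal-incentive stage-2 computation
  m_eq <- moran_model(stage2_payoffs(p, T_incentive = 50, mu = 1),
                      N = p$N, u = 0.05)
  direct <- fixation_result(m_eq)$Q_A
  expect_identical(sw$grid$Q_A[sw$grid$mu == 1 & sw$grid$T_incentive == 50],
                   direct)
})

test_that("iso-equilibrium contour extraction recovers a matching incentive", {
  p <- baseline_params()
  sg <- selection_gradient(moran_model(stage2_payoffs(p), N = p$N, u = 0))
  x_star <- sg$roots$x_root[1]
  T_match <- iso_equilibrium_T(p, target_x = x_star, mu = 1.085,
                               T_range = c(10, 400))
  expect_false(is.na(T_match))
  sg2 <- selection_gradient(moran_model(
    stage2_payoffs(p, T_incentive = T_match, mu = 1.085), N = p$N, u = 0))
  expect_equal(sg2$roots$x_root[1], x_star, tolerance = 0.005)
  # on the contour, the higher-mu game responds more steeply to incentive
  expect_gt(incentive_response(p, mu = 1.297), incentive_response(p, mu = 1.085))
})

test_that("the two-stage composition multiplies single-invader probabilities", {
  p <- baseline_params()
  ts <- two_stage_run(p, u = 0)
  expect_true(ts$stage2_reached)
  expect_equal(ts$end_to_end, (1 / p$N)^2, tolerance = 1e-12)

  ts <- two_stage_run(p, u = 0.05)
  m1 <- moran_model(stage1_payoffs(p), N = p$N, u = 0.05)
  m2 <- moran_model(stage2_payoffs(p), N = p$N, u = 0.05)
  expect_identical(ts$end_to_end,
                   fixation_result(m1)$Q_A * fixation_result(m2)$Q_A)

  # innovation strictly dominated: no market, no incentive worth the cost
  pd <- econ_params(N = 20, C1 = 2, a = 0.4, b = 0.7, R = 0, R_star = 0,
                    C = 50, P_success = 0.4, T_incentive = 1,
                    r = 0.015, t1 = 100, t2 = 300)
  tsd <- two_stage_run(pd, u = 0.1)
  expect_false(tsd$stage2_reached)
  expect_identical(tsd$end_to_end, tsd$stage1$Q_A)
})

test_that("sweep grids validate their inputs", {
  p <- baseline_params()
  expect_error(sweep_incentive(p, T_grid = c(5, 5)), "increasing")
  expect_error(sweep_mu_T(p, mu_grid = c(0.5, 1), T_grid = 85), "\\[1, 2\\]")
})
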