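# Shared noise-free synthetic run-1 data for the objective tests.
make_problem <- function(free = list(), noise = our_noise_model(0, 0,
                                                                interval_h = 0.2,
                                                                seed = 1),
                         weights = NULL) {
  p <- run_params(1); i <- run_init(1)
  g <- gen_our_profile(p, i, noise, duration = 24)
  calibration_problem(g$series, p, i, free = free, weights = weights)
}

test_that("objective is near zero at the truth on noise-free data", {
  prob <- make_problem(free = list(mu_H = c(0.52, 52)))
  loss <- calib_objective(c(mu_H = 5.2), prob)
  expect_lt(loss, 1e-6)
  expect_gt(calib_objective(c(mu_H = 5.2 * 1.5), prob), loss + 1e-3)
})

test_that("the loss is linear in the stream weights", {
  prob1 <- make_problem(free = list(mu_H = c(0.52, 52)),
                        weights = c(our = 1))
  prob2 <- make_problem(free = list(mu_H = c(0.52, 52)),
                        weights = c(our = 2))
  cand <- c(mu_H = 4)
  expect_equal(calib_objective(cand, prob2),
               2 * calib_objective(cand, prob1), tolerance = 1e-10)
})

test_that("objective is invariant to observation ordering", {
  p <- run_params(1); i <- run_init(1)
  g <- gen_our_profile(p, i, our_noise_model(0.01, 0.2, interval_h = 0.4,
                                             seed = 2), duration = 24)
  prob <- calibration_problem(g$series, p, i,
                              free = list(K_S = c(2.4, 240)))
  # same data, reversed order (our_series insists on increasing time, so
  # build the reversed stream directly)
  rev_series <- data.frame(time_h = rev(g$series$time_h),
                           our = rev(g$series$our))
  prob_rev <- calibration_problem(rev_series, p, i,
                                  free = list(K_S = c(2.4, 240)))
  cand <- c(K_S = 60)
  expect_equal(calib_objective(cand, prob),
               calib_objective(cand, prob_rev), tolerance = 1e-9)
})

test_that("impossible candidates are penalized, not fatal", {
  prob <- make_problem(free = list(bound_cod = c(0, 5000)))
  expect_warning(loss <- calib_objective(c(bound_cod = 4000), prob),
                 "penalized")
  expect_identical(loss, 1e12)
})

test_that("degenerate fits behave: no free parameters, collapsed bounds", {
  prob0 <- make_problem()
  res0 <- fit_kinetics(prob0, seed = 1)
  expect_length(res0$estimates, 0)
  expect_lt(res0$rss, 1e-6)

  probc <- make_problem(free = list(mu_H = c(4.4, 4.4)))
  resc <- fit_kinetics(probc, method = "local", seed = 1)
  expect_identical(unname(resc$estimates), 4.4)
})

test_that("single-parameter recovery from clean data", {
  prob <- make_problem(free = list(mu_H = c(0.52, 52)))
  res <- fit_kinetics(prob, n_starts = 6, seed = 11)
  expect_lt(abs(res$estimates[["mu_H"]] / 5.2 - 1), 0.02)
  expect_true(is.finite(res$se[["mu_H"]]))
})

test_that("three-parameter recovery on 1%-noise data (seeded experiment)", {
  p <- run_params(1); i <- run_init(1)
  # n = 200 observation points, 1% multiplicative noise
  g <- gen_our_profile(p, i, our_noise_model(0.01, 0,
                                             interval_h = 24 / 199,
                                             seed = 42), duration = 24)
  free <- list(mu_H = c(0.52, 52), K_S = c(2.4, 240), b_H = c(0.01, 1))
  prob <- calibration_problem(g$series, p, i, free = free)
  res <- fit_kinetics(prob, n_starts = 20, seed = 42)
  truth <- c(mu_H = 5.2, K_S = 24, b_H = 0.1)
  for (nm in names(truth))
    expect_lt(abs(res$estimates[[nm]] / truth[[nm]] - 1), 0.10)
})

test_that("fits are deterministic given the seed", {
  prob <- make_problem(free = list(mu_H = c(0.52, 52)))
  r1 <- fit_kinetics(prob, n_starts = 4, seed = 9)
  r2 <- fit_kinetics(prob, n_starts = 4, seed = 9)
  expect_identical(r1$estimates, r2$estimates)
  expect_identical(r1$rss, r2$rss)
})

test_that("storage fixed at zero yields no simulated PHA", {
  p <- run_params(4); i <- run_init(4)
  g <- gen_our_profile(p, i, our_noise_model(0.01, 0.2, interval_h = 0.4,
                                             seed = 3), duration = 24)
  prob <- calibration_problem(g$series, p, i,
                              free = list(mu_H = c(0.3, 30)))
  res <- fit_kinetics(prob, n_starts = 4, seed = 3)
  fitted <- sludgeresp:::.apply_candidate(res$estimates, prob)
  traj <- simulate_batch(fitted$init, fitted$params)
  expect_identical(max(traj$X_STO), 0)
})

test_that("run comparison tabulates fold changes", {
  vecs <- list(run1 = c(mu_H = 5.2, K_S = 24, b_H = 0.1, K_X = 0.15),
               run4 = c(mu_H = 3, K_S = 80, b_H = 0.27, K_X = 0.21))
  tab <- compare_runs(vecs, reference = "run1")
  expect_equal(tab$fold_run4[tab$parameter == "b_H"], 2.7)
  expect_equal(tab$fold_run4[tab$parameter == "K_X"], 1.4)
  expect_true(all(tab$fold_run1 == 1))

  same <- compare_runs(list(a = vecs$run1, b = vecs$run1))
  expect_true(all(same$fold_b == 1))

  expect_error(compare_runs(list(a = c(x = 1), b = c(y = 2))), "share")
  expect_error(compare_runs(list(a = c(x = 1))), "at least two")
})
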