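test_that("process rates follow the Monod/Contois forms at landmark states", {
  p <- run_params(1)
  st <- c(S_S = Inf, S_H1 = 0, S_H2 = 0, X_H = 1450, X_STO = 0)
  r <- process_rates(st, p)
  expect_equal(r[["rho_growth"]], 5.2 * 1450) # saturation limit

  st2 <- c(S_S = 24, S_H1 = 0, S_H2 = 0, X_H = 1450, X_STO = 0)
  r2 <- process_rates(st2, p)
  expect_equal(r2[["rho_growth"]], 5.2 * 0.5 * 1450) # S_S = K_S => 1/2

  p4 <- run_params(4) # storage fully suppressed
  expect_identical(p4$k_STO, 0)
  r4 <- process_rates(c(S_S = 500, S_H1 = 0, S_H2 = 0, X_H = 1000,
                        X_STO = 0), p4)
  expect_identical(r4[["rho_storage"]], 0)

  # Contois form: hydrolysis saturates in the ratio S_H1/X_H
  stc <- c(S_S = 0, S_H1 = 0.15 * 1450, S_H2 = 0, X_H = 1450, X_STO = 0)
  expect_equal(process_rates(stc, p)[["rho_hyd1"]], 5.2 * 0.5 * 1450)
})

test_that("process rates reject invalid states", {
  p <- run_params(1)
  expect_error(process_rates(c(S_S = -1, S_H1 = 0, S_H2 = 0, X_H = 10,
                               X_STO = 0), p), "negative")
  expect_error(process_rates(c(S_S = 0, S_H1 = 5, S_H2 = 0, X_H = 0,
                               X_STO = 0), p), "X_H = 0")
  # X_H = 0 with no hydrolysable substrate is fine (all rates zero)
  r <- process_rates(c(S_S = 10, S_H1 = 0, S_H2 = 0, X_H = 0, X_STO = 0),
                     p)
  expect_true(all(r == 0))
})

test_that("rates are monotone in their substrate and degree-1 in X_H", {
  p <- run_params(1)
  base <- c(S_S = 20, S_H1 = 100, S_H2 = 80, X_H = 1000, X_STO = 30)
  for (sub in c("S_S", "S_H1", "S_H2")) {
    lo <- base; hi <- base; hi[sub] <- hi[sub] * 2
    rho <- c(S_S = "rho_growth", S_H1 = "rho_hyd1", S_H2 = "rho_hyd2")[sub]
    expect_gte(process_rates(hi, p)[[rho]], process_rates(lo, p)[[rho]])
  }
  r1 <- process_rates(base, p)
  base2 <- base; base2["X_H"] <- 2 * base["X_H"]
  r2 <- process_rates(base2, p)
  for (rho in c("rho_growth", "rho_storage", "rho_decay"))
    expect_equal(r2[[rho]], 2 * r1[[rho]])
})

test_that("stoichiometric coefficients carry the yield structure", {
  p <- run_params(1) # Y_H = 0.6, Y_STO = 0.8, f_ES = 0.05, f_EX = 0.15
  m <- stoichiometry_matrix(p)
  expect_equal(m["growth", "S_O"], -0.4 / 0.6)
  expect_equal(m["growth", "S_S"], -1 / 0.6)
  expect_equal(m["storage", "S_O"], -0.2)
  expect_equal(m["storage", "X_STO"], 0.8)
  expect_equal(m["decay", "S_O"], -(1 - 0.2))
  expect_equal(unname(m["hyd1", c("S_H1", "S_S")]), c(-1, 1))
  expect_equal(unname(m["hyd2", c("S_H2", "S_S")]), c(-1, 1))
  expect_equal(m["growth_sto", "X_STO"], -1 / 0.6)
})

test_that("every process conserves COD (oxygen counted as negative COD)", {
  expect_equal(max(abs(cod_continuity(run_params(1)))), 0,
               tolerance = 1e-12)
  for (seed in 1:200) {
    res <- cod_continuity(random_params(seed))
    expect_lt(max(abs(res)), 1e-12)
  }
})

test_that("the RHS assembles matrix-times-rates with oxygen bookkeeping", {
  p <- run_params(1)
  # substrate-free limit: decay is the only active process
  st <- c(S_S = 0, S_H1 = 0, S_H2 = 0, X_H = 1450, X_STO = 0, X_P = 0,
          S_P = 0, O_cum = 0)
  d <- model_rhs(0, st, p)
  expect_equal(d[["X_H"]], -0.1 * 1450)
  expect_equal(d[["O_cum"]], (1 - 0.2) * 0.1 * 1450)
  expect_equal(d[["S_P"]], 0.05 * 0.1 * 1450)
  expect_equal(d[["S_S"]], 0)

  # storage-free parameters keep X_STO = 0 an invariant subspace
  p4 <- run_params(4)
  d4 <- model_rhs(0, random_state(3), p4)
  st0 <- random_state(4); st0["X_STO"] <- 0
  expect_equal(model_rhs(0, st0, p4)[["X_STO"]], 0)

  # COD continuity propagates: component derivatives + dO_cum/dt sum to 0
  for (seed in 1:50) {
    d <- model_rhs(0, random_state(seed), random_params(seed + 1000))
    expect_lt(abs(sum(d)), 1e-9 * max(abs(d), 1))
  }
})

test_that("compiled and R right-hand sides agree", {
  for (seed in 1:25) {
    p <- random_params(seed)
    st <- random_state(seed + 500)
    d_r <- model_rhs(0, st, p)
    d_cpp <- sludgeresp:::.batch_rhs_cpp(unname(st),
                                         sludgeresp:::.batch_par_vector(p))
    expect_equal(unname(d_r), d_cpp, tolerance = 1e-12)
  }
})

test_that("the optional oxygen switch scales every rate", {
  p <- run_params(1)
  st <- c(S_S = 30, S_H1 = 100, S_H2 = 50, X_H = 1000, X_STO = 20)
  r_inf <- process_rates(st, p)
  r_do <- process_rates(st, p, S_O = 3) # DO held above 3 mg/L
  sw <- 3 / (p$K_OH + 3)
  expect_equal(unname(r_do), unname(r_inf) * sw)
  expect_gt(sw, 0.996) # the switch is saturated in the aerated reactor
})

test_that("parameter validation names the offending field", {
  expect_error(model_params(mu_H = -1, K_S = 24, b_H = 0.1, k_h1 = 5.2,
                            K_X = 0.15, k_h2 = 0.56, K_XX = 0.05,
                            k_STO = 1.2, K_STO = 0.5, mu_STO = 0.8,
                            Y_H = 0.6, Y_STO = 0.8, f_ES = 0.05,
                            f_EX = 0.15), "mu_H")
  expect_error(model_params(mu_H = 5.2, K_S = 24, b_H = 0.1, k_h1 = 5.2,
                            K_X = 0.15, k_h2 = 0.56, K_XX = 0.05,
                            k_STO = 1.2, K_STO = 0.5, mu_STO = 0.8,
                            Y_H = 1.5, Y_STO = 0.8, f_ES = 0.05,
                            f_EX = 0.15), "Y_H")
  expect_error(model_params(mu_H = 5.2, K_S = 24, b_H = 0.1, k_h1 = 5.2,
                            K_X = 0.15, k_h2 = 0.56, K_XX = 0.05,
                            k_STO = 1.2, K_STO = 0.5, mu_STO = 0.8,
                            Y_H = 0.6, Y_STO = 0.8, f_ES = 0.5,
                            f_EX = 0.6), "f_ES")
})
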