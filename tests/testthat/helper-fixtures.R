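# Shared fixture builders. All randomness is locally seeded.

# A random valid parameter set for property-style tests.
random_params <- function(seed) {
  set.seed(seed)
  model_params(
    mu_H = runif(1, 0.5, 8), K_S = runif(1, 1, 100),
    b_H = runif(1, 0.01, 0.5), K_OH = 0.01,
    k_h1 = runif(1, 0.5, 8), K_X = runif(1, 0.01, 0.5),
    k_h2 = runif(1, 0.1, 2), K_XX = runif(1, 0.01, 0.3),
    k_STO = runif(1, 0, 2), K_STO = runif(1, 0.1, 5),
    mu_STO = runif(1, 0, 1),
    Y_H = runif(1, 0.3, 0.8), Y_STO = runif(1, 0.5, 1),
    f_ES = runif(1, 0, 0.1), f_EX = runif(1, 0, 0.3))
}

# A random nonnegative batch state (named, full layout).
random_state <- function(seed) {
  set.seed(seed)
  c(S_S = runif(1, 0, 100), S_H1 = runif(1, 0, 400),
    S_H2 = runif(1, 0, 300), X_H = runif(1, 100, 3000),
    X_STO = runif(1, 0, 150), X_P = runif(1, 0, 50),
    S_P = runif(1, 0, 40), O_cum = runif(1, 0, 300))
}

# Initial conditions with no substrate: pure endogenous decay.
decay_only_init <- function(X_H1 = 1450) {
  initial_conditions(S_S1 = 0, S_H1_0 = 0, S_H2_0 = 0, X_H1 = X_H1,
                     X_STO1 = 0, total_biomass = 2010)
}

# Random OTU count vector with a rare-heavy tail.
random_counts <- function(seed, S = 120, N = 2000) {
  set.seed(seed)
  p <- rgamma(S, shape = 0.3)
  as.integer(table(factor(sample.int(S, N, replace = TRUE, prob = p),
                          levels = seq_len(S))))
}

# Total COD + cumulative oxygen along a trajectory (conserved quantity).
traj_total_cod <- function(traj) {
  rowSums(traj[, c("S_S", "S_H1", "S_H2", "X_H", "X_STO", "X_P", "S_P",
                   "O_cum")])
}
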