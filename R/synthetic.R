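# Synthetic-data generators: noisy respirometric OUR profiles from known
# kinetics, and OTU count tables with controlled richness structure. Both
# are pure functions of (specification, seed).

#' Respirometer noise model
#'
#' Multiplicative plus additive Gaussian noise: a respirometer has roughly
#' constant relative error at high OUR and a floor of absolute noise near
#' the endogenous baseline.
#'
#' @param mult_sd standard deviation of the multiplicative component
#'   (fraction of the true OUR; default 0.01 = 1%)
#' @param add_sd standard deviation of the additive component
#'   (mg O2/L/h; default 0.5)
#' @param interval_h sampling interval (hours)
#' @param seed RNG seed
#' @return an `our_noise_model` list
#' @export
our_noise_model <- function(mult_sd = 0.01, add_sd = 0.5,
                            interval_h = 0.12, seed = 1) {
  if (mult_sd < 0 || add_sd < 0)
    stop("noise standard deviations must be >= 0", call. = FALSE)
  if (interval_h <= 0) stop("interval_h must be > 0", call. = FALSE)
  structure(list(mult_sd = mult_sd, add_sd = add_sd,
                 interval_h = interval_h, seed = as.integer(seed)),
            class = "our_noise_model")
}

#' Generate a noisy synthetic OUR profile from known kinetics
#'
#' Simulates the batch model and corrupts the OUR at the sampling grid with
#' `observed = true * (1 + eps_m) + eps_a`, clipped at zero. The noise-free
#' truth is returned alongside so recovery experiments can score estimates
#' against known generating values.
#'
#' @param params a [model_params()] object (ground-truth kinetics)
#' @param init an [initial_conditions()] object
#' @param noise an [our_noise_model()]
#' @param duration test length (hours)
#' @param ... passed to [simulate_batch()] (tolerances etc.)
#' @return list with `series` (an [our_series()], provenance "simulated"),
#'   `truth` (the noise-free `batch_trajectory` at the same grid), `params`,
#'   `init` and `noise`
#' @export
gen_our_profile <- function(params, init, noise = our_noise_model(),
                            duration = 24, ...) {
  times_h <- seq(0, duration, by = noise$interval_h)
  traj <- simulate_batch(init, params, times_h = times_h, ...)
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(.mix_seed(noise$seed, 101L))
  n <- nrow(traj)
  obs <- traj$our * (1 + stats::rnorm(n, 0, noise$mult_sd)) +
    stats::rnorm(n, 0, noise$add_sd)
  list(series = our_series(traj$time_h, pmax(obs, 0),
                           provenance = "simulated"),
       truth = traj, params = params, init = init, noise = noise)
}

#' Specification of a synthetic OTU community
#'
#' @param S_obs target observed richness of the generated sample
#' @param N total reads
#' @param F1 optional target singleton count (validity check only; the
#'   realized F1 follows from the abundance law and is reported, not
#'   force-matched)
#' @param law abundance law: `"log-series"` (default; heavy rare tail),
#'   `"geometric"` (rank-geometric) or `"dirichlet"` (symmetric Dirichlet
#'   relative abundances)
#' @param law_param law-specific shape parameter: log-series `x` (0 < x <
#'   1; default from the Fisher relation for the target `S_obs`, `N`),
#'   geometric decay `k` (default 0.05), Dirichlet concentration (default
#'   calibrated)
#' @param seed RNG seed
#' @return a `community_spec` list
#' @export
community_spec <- function(S_obs, N, F1 = NA, law = c("log-series",
                                                      "geometric",
                                                      "dirichlet"),
                           law_param = NULL, seed = 1) {
  law <- match.arg(law)
  if (S_obs < 1 || N < S_obs)
    stop("need 1 <= S_obs <= N", call. = FALSE)
  if (!is.na(F1) && F1 > S_obs)
    stop("unattainable spec: F1 > S_obs", call. = FALSE)
  structure(list(S_obs = as.integer(S_obs), N = as.integer(N),
                 F1 = if (is.na(F1)) NA_integer_ else as.integer(F1),
                 law = law, law_param = law_param,
                 seed = as.integer(seed)),
            class = "community_spec")
}

# Fisher log-series parameter x = N/(N + alpha) with alpha solving
# S = alpha * log(1 + N/alpha).
.fisher_x <- function(S, N) {
  f <- function(a) a * log(1 + N / a) - S
  alpha <- stats::uniroot(f, c(1e-3, 1e8), tol = 1e-10)$root
  N / (N + alpha)
}

# i.i.d. draws from the log-series distribution P(k) proportional to x^k/k
# by inversion over a truncated support (tail mass < 1e-12).
.rlogseries <- function(n, x) {
  kmax <- max(50L, ceiling(log(1e-15) / log(x)))
  k <- seq_len(kmax)
  p <- exp(k * log(x) - log(k))
  sample.int(kmax, n, replace = TRUE, prob = p)
}

# One multinomial community draw for a candidate law parameter.
.draw_community <- function(spec, par) {
  p <- switch(spec$law,
    "log-series" = {
      x <- if (is.null(spec$law_param)) .fisher_x(spec$S_obs, spec$N)
           else spec$law_param
      .rlogseries(round(par), x)          # par = species-pool size
    },
    "geometric" = {
      k <- if (is.null(spec$law_param)) 0.05 else spec$law_param
      if (k == 0) rep(1, round(par)) else (1 - k)^(seq_len(round(par)) - 1)
    },
    "dirichlet" = {
      pool <- max(2L * spec$S_obs, 4L)    # par = Dirichlet concentration
      g <- stats::rgamma(pool, shape = par, rate = 1)
      if (all(g == 0)) g <- rep(1, pool)
      g
    })
  counts <- stats::rmultinom(1, spec$N, prob = p / sum(p))[, 1]
  counts[counts > 0]
}

#' Generate an OTU count table with controlled richness
#'
#' Draws relative abundances from the chosen law and multinomial reads of
#' size `N`, then calibrates the free law parameter (species-pool size for
#' the log-series and geometric laws, concentration for the Dirichlet law)
#' by bisection (at most 50 iterations) until the realized richness lies
#' within +/-5% of the target `S_obs`. Deterministic given the spec seed.
#'
#' @param spec a [community_spec()]
#' @param sample_id row name for the generated sample
#' @return list with `otu` (a one-sample [otu_table()]), `abundances` (the
#'   observed per-OTU counts), and realized `S_obs`, `F1`, `F2`, `N`
#' @examples
#' g <- gen_otu_table(community_spec(S_obs = 288, N = 2977, seed = 7))
#' g$S_obs
#' @export
gen_otu_table <- function(spec, sample_id = "sample1") {
  stopifnot(inherits(spec, "community_spec"))
  old <- .save_seed(); on.exit(.restore_seed(old))
  target <- spec$S_obs
  tol <- 0.05 * target
  draw_at <- function(par) {
    # same sub-seed for every candidate: realized richness is then a
    # (noisy but reproducible) monotone function of the parameter
    set.seed(.mix_seed(spec$seed, 202L))
    .draw_community(spec, par)
  }
  if (spec$law == "dirichlet") {
    lo <- 1e-4; hi <- 100
  } else {
    # the pool must be large enough that N reads can realize the target
    # richness even when S_obs approaches N (birthday collisions)
    lo <- max(2, target)
    hi <- max(20 * target, min(5 * target^2, 2e6), target + 10)
  }
  counts <- NULL
  for (i in seq_len(50L)) {
    par <- (lo + hi) / 2
    counts <- draw_at(par)
    S <- length(counts)
    if (abs(S - target) <= tol) break
    if (S < target) lo <- par else hi <- par
  }
  S <- length(counts)
  if (abs(S - target) > tol)
    stop("could not calibrate the abundance law to the target richness (",
         "realized ", S, ", target ", target, ")", call. = FALSE)
  counts <- sort(counts, decreasing = TRUE)
  m <- matrix(counts, nrow = 1,
              dimnames = list(sample_id,
                              sprintf("Otu%04d", seq_along(counts))))
  list(otu = otu_table(m, level = NA_character_),
       abundances = counts,
       S_obs = S, F1 = sum(counts == 1), F2 = sum(counts == 2),
       N = sum(counts))
}
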