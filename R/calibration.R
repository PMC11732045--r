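# Reproducible bounded least-squares calibration of the batch model
# against OUR (and optionally soluble COD and PHA) time series, replacing
# eyeball curve fitting with a quantitative, seeded, multistart procedure.

.init_fields <- c("S_S1", "S_H1_0", "S_H2_0", "X_H1", "X_STO1",
                  "bound_cod")

#' Define a calibration problem
#'
#' Free parameters may be kinetic/stoichiometric constants (fields of
#' [model_params()]) or initial-condition fields (`X_H1`, `X_STO1`,
#' `S_S1`, `S_H1_0`, `S_H2_0`, `bound_cod`). Freeing `bound_cod` rescales
#' the three substrate fractions proportionally so the total dosed COD
#' (bioavailable + bound) stays fixed.
#'
#' @param our an [our_series()] (or data.frame with `time_h`, `our`);
#'   required
#' @param params baseline [model_params()]; fixed parameters keep these
#'   values
#' @param init baseline [initial_conditions()]
#' @param free named list of length-2 numeric bounds `c(lower, upper)` per
#'   free parameter; all bounds must be finite
#' @param cod optional soluble-COD series: data.frame `time_h`, `cod`
#'   (model counterpart `S_S + S_H1 + S_H2 + S_P`)
#' @param pha optional PHA series: data.frame `time_h`, `pha` (model
#'   counterpart `X_STO`)
#' @param weights optional named vector of stream weights (`our`, `cod`,
#'   `pha`) multiplying the per-point relative scaling; the relative
#'   scaling already makes streams of different magnitude comparable
#' @param rtol,atol integration tolerances used during fitting
#' @return a `calibration_problem` list
#' @export
calibration_problem <- function(our, params, init, free = list(),
                                cod = NULL, pha = NULL, weights = NULL,
                                rtol = 1e-7, atol = 1e-7) {
  validate_model_params(params)
  validate_initial_conditions(init)
  if (is.null(our$time_h) || is.null(our$our) || nrow(our) == 0L)
    stop("'our' must be a nonempty series with time_h and our columns",
         call. = FALSE)
  ok_names <- c(setdiff(names(params), "Y_SP"), .init_fields)
  for (nm in names(free)) {
    b <- free[[nm]]
    if (!nm %in% ok_names)
      stop("unknown free parameter '", nm, "'", call. = FALSE)
    if (length(b) != 2L || any(!is.finite(b)) || b[1] > b[2])
      stop("bounds for '", nm, "' must be finite c(lower, upper)",
           call. = FALSE)
  }
  streams <- list(our = data.frame(time_h = our$time_h, obs = our$our))
  if (!is.null(cod))
    streams$cod <- data.frame(time_h = cod$time_h, obs = cod$cod)
  if (!is.null(pha))
    streams$pha <- data.frame(time_h = pha$time_h, obs = pha$pha)
  w <- c(our = 1, cod = 1, pha = 1)[names(streams)]
  names(w) <- names(streams)
  if (!is.null(weights)) w[names(weights)] <- weights
  structure(list(streams = streams, params = params, init = init,
                 free = free, weights = w, rtol = rtol, atol = atol),
            class = "calibration_problem")
}

# Apply a named candidate vector to the baseline params/init pair.
.apply_candidate <- function(candidate, problem) {
  params <- problem$params
  init <- problem$init
  for (nm in names(candidate)) {
    v <- candidate[[nm]]
    if (nm %in% .init_fields) {
      if (nm == "bound_cod") {
        dosed <- init$S_S1 + init$S_H1_0 + init$S_H2_0 + init$bound_cod
        avail_old <- dosed - init$bound_cod
        avail_new <- dosed - v
        if (avail_new < 0 || avail_old <= 0)
          stop("bound_cod candidate exceeds the dosed COD", call. = FALSE)
        sc <- avail_new / avail_old
        init$S_S1 <- init$S_S1 * sc
        init$S_H1_0 <- init$S_H1_0 * sc
        init$S_H2_0 <- init$S_H2_0 * sc
        init$bound_cod <- v
      } else {
        init[[nm]] <- v
      }
    } else {
      params[[nm]] <- v
    }
  }
  validate_model_params(params)
  validate_initial_conditions(init)
  list(params = params, init = init)
}

# Weighted residual vector over all streams at a candidate. Residuals are
# scaled per point by the observation magnitude (floored at 10% of the
# stream mean): respirometer error is dominantly multiplicative, so this
# is the heteroscedasticity-consistent weighting, and it simultaneously
# normalizes streams of different magnitude (OUR ~ 1e2 vs PHA ~ 1e1).
# User stream weights multiply on top.
.calib_residuals <- function(candidate, problem) {
  pi <- .apply_candidate(candidate, problem)
  times <- sort(unique(c(0, unlist(lapply(problem$streams,
                                          `[[`, "time_h")))))
  traj <- simulate_batch(pi$init, pi$params, times_h = times,
                         rtol = problem$rtol, atol = problem$atol)
  model_of <- list(
    our = function(tr) tr$our,
    cod = function(tr) tr$S_S + tr$S_H1 + tr$S_H2 + tr$S_P,
    pha = function(tr) tr$X_STO)
  unlist(lapply(names(problem$streams), function(s) {
    d <- problem$streams[[s]]
    sim <- stats::approx(traj$time_h, model_of[[s]](traj), d$time_h)$y
    m <- mean(abs(d$obs))
    if (m == 0) m <- 1
    scale <- pmax(abs(d$obs), 0.1 * m)
    sqrt(problem$weights[[s]]) * (sim - d$obs) / scale
  }))
}

#' Calibration objective (weighted sum of squares)
#'
#' Sum over data streams of `weight * sum(((sim - obs)/scale_i)^2)` with
#' the per-point scale `max(|obs_i|, 0.1 mean|obs|)` (respirometer error
#' is dominantly relative), the model evaluated at the observation times.
#' A failed simulation
#' returns a large finite penalty (1e12) with a warning so optimizers can
#' continue past pathological candidates.
#'
#' @param candidate named numeric vector of values for the problem's free
#'   parameters
#' @param problem a [calibration_problem()]
#' @return scalar loss
#' @export
calib_objective <- function(candidate, problem) {
  r <- tryCatch(.calib_residuals(candidate, problem), error = function(e) {
    warning("simulation failed during calibration (", conditionMessage(e),
            "); penalized", call. = FALSE)
    NULL
  })
  if (is.null(r) || any(!is.finite(r))) return(1e12)
  sum(r^2)
}

#' Fit the batch model to respirometric data
#'
#' Bounded least squares via `nlminb` on the free parameters. With
#' `method = "multistart"`, `n_starts` starting points are drawn
#' log-uniformly within the bounds using the given seed, each polished
#' locally, and the best optimum returned; results are deterministic given
#' the seed. Approximate standard errors come from a forward-difference
#' Jacobian of the weighted residuals at the optimum.
#'
#' @param problem a [calibration_problem()]
#' @param method `"multistart"` (default) or `"local"` (start from the
#'   bound midpoint in log space)
#' @param n_starts number of multistart draws
#' @param seed RNG seed for the start draws
#' @return a `calibration_result` list: `estimates`, `se`, `rss`,
#'   `rss_stream`, `convergence` (per-start diagnostics), `n_obs`, `seed`
#' @export
fit_kinetics <- function(problem, method = c("multistart", "local"),
                         n_starts = 20, seed = 1) {
  method <- match.arg(method)
  stopifnot(inherits(problem, "calibration_problem"))
  free <- problem$free
  p <- length(free)
  nobs <- sum(vapply(problem$streams, nrow, integer(1)))

  if (p == 0L) {
    rss <- calib_objective(stats::setNames(numeric(0), character(0)),
                           problem)
    return(structure(list(estimates = numeric(0), se = numeric(0),
                          rss = rss, convergence = data.frame(),
                          n_obs = nobs, seed = as.integer(seed)),
                     class = "calibration_result"))
  }

  lower <- vapply(free, `[`, numeric(1), 1)
  upper <- vapply(free, `[`, numeric(1), 2)
  names(lower) <- names(upper) <- names(free)

  # dimensions with collapsed bounds are pinned, not optimized (finite
  # differencing at a zero-width box is ill-posed)
  pinned <- upper - lower <= 0
  if (all(pinned)) {
    est <- lower
    rss <- calib_objective(est, problem)
    return(structure(list(estimates = est,
                          se = stats::setNames(rep(NA_real_, p),
                                               names(free)),
                          rss = rss, convergence = data.frame(),
                          n_obs = nobs, seed = as.integer(seed)),
                     class = "calibration_result"))
  }

  # pinned dimensions stay at their bound; only the rest are optimized
  fidx <- which(!pinned)
  expand <- function(x) {
    full <- lower
    full[fidx] <- x
    full
  }
  obj <- function(x) calib_objective(expand(x), problem)
  lo_f <- lower[fidx]; up_f <- upper[fidx]

  # log-uniform draws need a positive floor when a lower bound is 0
  lo_pos <- pmax(lo_f, up_f * 1e-6)

  starts <- if (method == "local") {
    matrix(sqrt(lo_pos * up_f), nrow = 1)
  } else {
    old <- .save_seed(); on.exit(.restore_seed(old))
    set.seed(.mix_seed(seed, 303L))
    m <- vapply(seq_along(fidx), function(j) {
      exp(stats::runif(n_starts, log(lo_pos[j]), log(up_f[j])))
    }, numeric(n_starts))
    matrix(m, nrow = n_starts)
  }

  # L-BFGS-B with parameter-scaled finite-difference steps (~0.1% of the
  # parameter): steps this large stay above the adaptive integrator's
  # output noise, which defeats optimizers taking sqrt(eps)-sized steps.
  run_lbfgsb <- function(start) {
    tryCatch(
      stats::optim(start, obj, method = "L-BFGS-B", lower = lo_f,
                   upper = up_f,
                   control = list(parscale = pmax(abs(start), 1e-3),
                                  maxit = 200)),
      error = function(e) list(value = Inf, par = start,
                               convergence = -1L,
                               message = conditionMessage(e)))
  }
  fits <- lapply(seq_len(nrow(starts)),
                 function(i) run_lbfgsb(starts[i, ]))
  objs <- vapply(fits, `[[`, numeric(1), "value")
  if (all(!is.finite(objs)))
    stop("all optimization starts failed:\n",
         paste(vapply(fits, function(f) f$message %||% "unknown",
                      character(1)), collapse = "\n"), call. = FALSE)
  best <- fits[[which.min(objs)]]
  # one polish pass from the incumbent guards against premature stalls
  polish <- run_lbfgsb(best$par)
  if (polish$value <= best$value) best <- polish
  best$objective <- best$value
  est <- expand(pmin(pmax(best$par, lo_f), up_f))
  names(est) <- names(free)

  # approximate SEs from a forward-difference Jacobian at the optimum
  se <- rep(NA_real_, p)
  r0 <- tryCatch(.calib_residuals(est, problem), error = function(e) NULL)
  if (!is.null(r0) && nobs > p) {
    J <- matrix(NA_real_, length(r0), p)
    for (j in seq_len(p)) {
      h <- max(1e-6 * abs(est[j]), 1e-9)
      xj <- est; xj[j] <- xj[j] + h
      rj <- tryCatch(.calib_residuals(xj, problem),
                     error = function(e) NULL)
      if (is.null(rj)) { J <- NULL; break }
      J[, j] <- (rj - r0) / h
    }
    if (!is.null(J)) {
      s2 <- sum(r0^2) / (length(r0) - p)
      cov <- tryCatch(s2 * solve(crossprod(J)), error = function(e) NULL)
      if (!is.null(cov)) se <- sqrt(pmax(diag(cov), 0))
    }
  }
  conv <- data.frame(start = seq_len(nrow(starts)),
                     objective = objs,
                     converged = vapply(fits, function(f)
                       identical(f$convergence, 0L), logical(1)))
  structure(list(estimates = est,
                 se = stats::setNames(se, names(free)),
                 rss = best$objective, convergence = conv, n_obs = nobs,
                 seed = as.integer(seed)),
            class = "calibration_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.calibration_result <- function(x, ...) {
  cat("Calibration result (RSS =", signif(x$rss, 6), ")\n")
  if (length(x$estimates)) {
    print(data.frame(estimate = x$estimates, se = x$se))
  } else cat("  (no free parameters)\n")
  invisible(x)
}

#' Compare calibrated parameters across experimental runs
#'
#' Tabulates estimates and fold-changes relative to a reference run; used
#' to quantify kinetic shifts under antibiotic exposure (e.g. the rise in
#' the endogenous decay rate under chronic stress).
#'
#' @param results named list of `calibration_result` objects or plain
#'   named numeric parameter vectors
#' @param reference name or index of the reference run (default first)
#' @return data.frame: one row per shared parameter, one estimate column
#'   per run plus `fold_<run>` columns (run / reference)
#' @export
compare_runs <- function(results, reference = 1) {
  if (length(results) < 2L) stop("need at least two results", call. = FALSE)
  vecs <- lapply(results, function(r) {
    if (inherits(r, "calibration_result")) r$estimates else unlist(r)
  })
  if (is.null(names(vecs)))
    names(vecs) <- paste0("run", seq_along(vecs))
  shared <- Reduce(intersect, lapply(vecs, names))
  if (length(shared) == 0L)
    stop("results share no parameter names", call. = FALSE)
  ref <- vecs[[reference]][shared]
  out <- data.frame(parameter = shared)
  for (nm in names(vecs)) out[[nm]] <- unname(vecs[[nm]][shared])
  for (nm in names(vecs)) out[[paste0("fold_", nm)]] <-
    unname(vecs[[nm]][shared] / ref)
  out
}
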