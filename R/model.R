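#' Process rates of the six-process growth-and-storage model
#'
#' Evaluates the kinetic rate expressions: Monod growth on readily
#' biodegradable substrate, surface-saturation (Contois) hydrolysis of the
#' two hydrolysable fractions in the ratio `S_H/X_H`, Monod PHA storage,
#' first-order growth on stored PHA, and first-order endogenous decay. The
#' dissolved-oxygen switch `S_O/(K_OH + S_O)` multiplies every rate; with
#' DO held well above `K_OH` (the aerated respirometer) it is numerically 1,
#' which is the default (`S_O = Inf`).
#'
#' @param state named numeric vector or list with components `S_S`, `S_H1`,
#'   `S_H2`, `X_H`, `X_STO` (mg COD/L); extra components are ignored
#' @param params a [model_params()] object
#' @param S_O dissolved oxygen (mg O2/L) for the optional oxygen switch;
#'   `Inf` (default) evaluates the switch as exactly 1
#' @return named numeric vector of the six process rates in
#'   mg COD/(L day): `rho_growth`, `rho_hyd1`, `rho_hyd2`, `rho_storage`,
#'   `rho_growth_sto`, `rho_decay`
#' @export
process_rates <- function(state, params, S_O = Inf) {
  s <- as.list(state)
  for (f in c("S_S", "S_H1", "S_H2", "X_H", "X_STO")) {
    v <- s[[f]]
    if (is.null(v) || !is.finite(v) && !identical(v, Inf))
      stop("state component '", f, "' missing or not numeric", call. = FALSE)
    if (v < 0)
      stop("state component '", f, "' is negative", call. = FALSE)
  }
  if (s$X_H == 0 && (s$S_H1 > 0 || s$S_H2 > 0))
    stop("hydrolysis rate undefined: X_H = 0 with hydrolysable substrate ",
         "present (Contois ratio S_H/X_H)", call. = FALSE)

  monod <- function(x, k) {
    if (x <= 0) 0 else if (!is.finite(x)) 1 else x / (k + x)
  }
  sw <- if (is.finite(S_O)) S_O / (params$K_OH + S_O) else 1

  contois <- function(k_h, S_H, K) {
    if (s$X_H <= 0) return(0)
    r <- S_H / s$X_H
    k_h * monod(r, K) * sw * s$X_H
  }
  c(rho_growth     = params$mu_H * monod(s$S_S, params$K_S) * sw * s$X_H,
    rho_hyd1       = contois(params$k_h1, s$S_H1, params$K_X),
    rho_hyd2       = contois(params$k_h2, s$S_H2, params$K_XX),
    rho_storage    = params$k_STO * monod(s$S_S, params$K_STO) * sw * s$X_H,
    rho_growth_sto = params$mu_STO * s$X_STO * sw,
    rho_decay      = params$b_H * s$X_H * sw)
}

.component_names <- c("S_S", "S_H1", "S_H2", "X_H", "X_STO", "X_P", "S_P")
.process_names <- c("growth", "hyd1", "hyd2", "storage", "growth_sto",
                    "decay")

#' Stoichiometric matrix of the growth-and-storage model
#'
#' Returns the signed COD-unit stoichiometric coefficients of the six
#' processes over the seven model components plus an oxygen column `S_O`
#' (negative = oxygen consumed). Because every component is expressed as
#' COD, each row balances: the COD lost from substrates and biomass
#' reappears in products and consumed oxygen (see [cod_continuity()]).
#'
#' @param params a [model_params()] object
#' @return 6 x 8 numeric matrix, rows `growth`, `hyd1`, `hyd2`, `storage`,
#'   `growth_sto`, `decay`; columns `S_S`, `S_H1`, `S_H2`, `X_H`, `X_STO`,
#'   `X_P`, `S_P`, `S_O`
#' @export
stoichiometry_matrix <- function(params) {
  validate_model_params(params)
  Y_H <- params$Y_H; Y_STO <- params$Y_STO
  f_ES <- params$f_ES; f_EX <- params$f_EX
  f_E <- f_ES + f_EX
  m <- matrix(0, nrow = 6, ncol = 8,
              dimnames = list(.process_names, c(.component_names, "S_O")))
  m["growth", c("S_S", "X_H", "S_O")] <- c(-1 / Y_H, 1, -(1 - Y_H) / Y_H)
  m["hyd1", c("S_H1", "S_S")] <- c(-1, 1)
  m["hyd2", c("S_H2", "S_S")] <- c(-1, 1)
  m["storage", c("S_S", "X_STO", "S_O")] <- c(-1, Y_STO, -(1 - Y_STO))
  m["growth_sto", c("X_STO", "X_H", "S_O")] <-
    c(-1 / Y_H, 1, -(1 - Y_H) / Y_H)
  m["decay", c("X_H", "X_P", "S_P", "S_O")] <- c(-1, f_EX, f_ES, -(1 - f_E))
  m
}

#' COD continuity check of the stoichiometric matrix
#'
#' For each process, sums the COD coefficients counting consumed oxygen as
#' negative COD. A consistent ASM-type matrix yields zero for every row:
#' COD is conserved process by process.
#'
#' @param params a [model_params()] object
#' @return named numeric vector of per-process residuals; all should be 0
#'   within 1e-12
#' @export
cod_continuity <- function(params) {
  m <- stoichiometry_matrix(params)
  # oxygen has COD content -1: consumed O2 (negative coefficient) carries
  # away positive COD
  rowSums(m[, .component_names]) - m[, "S_O"]
}

#' Time derivative of the batch state
#'
#' Assembles the ODE right-hand side as the transpose of the stoichiometric
#' matrix applied to the process-rate vector. The cumulative-oxygen
#' component `O_cum` integrates the total oxygen consumption rate, so
#' `d O_cum/dt >= 0` and total COD + `O_cum` is invariant along
#' trajectories.
#'
#' @param t time (day); unused (the system is autonomous) but kept for a
#'   conventional ODE signature
#' @param state named numeric vector with components `S_S`, `S_H1`, `S_H2`,
#'   `X_H`, `X_STO`, `X_P`, `S_P`, `O_cum`
#' @param params a [model_params()] object
#' @inheritParams process_rates
#' @return named derivative vector (mg COD/L/day), same layout as `state`
#' @export
model_rhs <- function(t, state, params, S_O = Inf) {
  rho <- process_rates(state, params, S_O = S_O)
  m <- stoichiometry_matrix(params)
  d <- drop(rho %*% m)
  out <- c(d[.component_names], O_cum = -d[["S_O"]])
  names(out) <- c(.component_names, "O_cum")
  out
}
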