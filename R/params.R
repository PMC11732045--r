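#' Kinetic and stoichiometric parameters of the growth-and-storage model
#'
#' Builds a validated parameter set for the six-process activated sludge
#' model (heterotrophic growth on readily biodegradable COD, two
#' surface-saturation hydrolysis processes, PHA storage, growth on stored
#' PHA, and endogenous decay). All rates are per day and all concentrations
#' in COD units, the common currency of ASM-type models.
#'
#' @param mu_H maximum heterotrophic growth rate on `S_S` (1/day)
#' @param K_S half-saturation constant for growth (mg COD/L)
#' @param b_H endogenous decay rate (1/day)
#' @param K_OH oxygen half-saturation (mg O2/L); only used when a finite
#'   dissolved-oxygen level is supplied to the rate functions
#' @param k_h1 maximum hydrolysis rate of the readily hydrolysable fraction
#'   `S_H1` (1/day)
#' @param K_X hydrolysis half-saturation for `S_H1` (g COD/g cell COD)
#' @param k_h2 maximum hydrolysis rate of the slowly hydrolysable fraction
#'   `S_H2` (1/day)
#' @param K_XX hydrolysis half-saturation for `S_H2` (g COD/g cell COD)
#' @param k_STO maximum PHA storage rate (1/day)
#' @param K_STO half-saturation for storage (mg COD/L)
#' @param mu_STO maximum growth rate on stored PHA (1/day)
#' @param Y_H heterotrophic yield (g cell COD/g COD), in (0, 1)
#' @param Y_STO storage yield (g COD/g COD), in (0, 1]
#' @param f_ES fraction of decayed biomass released as soluble microbial
#'   product `S_P`
#' @param f_EX fraction of decayed biomass retained as inert particulate
#'   product `X_P`
#' @param Y_SP soluble-microbial-product yield on utilized COD
#'   (g COD/g COD); used only by the mass-balance accounting, not by the ODE
#' @return an object of class `model_params` (a named list)
#' @seealso [run_params()] for the bundled calibrated sets,
#'   [process_rates()], [stoichiometry_matrix()], [simulate_batch()]
#' @export
model_params <- function(mu_H, K_S, b_H, K_OH = 0.01, k_h1, K_X, k_h2, K_XX,
                         k_STO, K_STO, mu_STO, Y_H, Y_STO, f_ES, f_EX,
                         Y_SP = 0.06) {
  p <- list(mu_H = mu_H, K_S = K_S, b_H = b_H, K_OH = K_OH,
            k_h1 = k_h1, K_X = K_X, k_h2 = k_h2, K_XX = K_XX,
            k_STO = k_STO, K_STO = K_STO, mu_STO = mu_STO,
            Y_H = Y_H, Y_STO = Y_STO, f_ES = f_ES, f_EX = f_EX,
            Y_SP = Y_SP)
  p <- lapply(p, function(v) if (is.numeric(v)) as.numeric(v) else v)
  validate_model_params(p)
  structure(p, class = "model_params")
}

validate_model_params <- function(p) {
  num1 <- function(field) {
    v <- p[[field]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("parameter '", field, "' must be a single finite number",
           call. = FALSE)
    v
  }
  for (f in c("mu_H", "K_S", "b_H", "K_OH", "k_h1", "K_X", "k_h2", "K_XX",
              "k_STO", "K_STO", "mu_STO", "Y_SP")) {
    if (num1(f) < 0)
      stop("parameter '", f, "' must be >= 0", call. = FALSE)
  }
  if (num1("Y_H") <= 0 || p$Y_H >= 1)
    stop("parameter 'Y_H' must lie strictly in (0, 1)", call. = FALSE)
  if (num1("Y_STO") <= 0 || p$Y_STO > 1)
    stop("parameter 'Y_STO' must lie in (0, 1]", call. = FALSE)
  if (num1("f_ES") < 0 || num1("f_EX") < 0 || p$f_ES + p$f_EX >= 1)
    stop("fractions must satisfy f_ES >= 0, f_EX >= 0, f_ES + f_EX < 1",
         call. = FALSE)
  invisible(p)
}

#' @export
print.model_params <- function(x, ...) {
  cat("Growth-and-storage model parameters\n")
  v <- unlist(x)
  cat(sprintf("  %-6s = %g\n", names(v), v), sep = "")
  invisible(x)
}

# Parameter vector in the fixed order the compiled integrator expects.
# S_O = Inf encodes the saturated oxygen switch (DO held high, switch == 1).
.batch_par_vector <- function(params, S_O = Inf) {
  c(params$mu_H, params$K_S, params$b_H, params$K_OH, params$k_h1,
    params$K_X, params$k_h2, params$K_XX, params$k_STO, params$K_STO,
    params$mu_STO, params$Y_H, params$Y_STO, params$f_ES, params$f_EX, S_O)
}

#' Initial conditions for a batch respirometric test
#'
#' The dosed biodegradable substrate is split into readily biodegradable
#' (`S_S1`), readily hydrolysable (`S_H1_0`) and slowly hydrolysable
#' (`S_H2_0`) COD. `bound_cod` is the portion of the dose blocked from
#' microbial utilization by antibiotic-substrate binding; the three
#' fractions are the post-binding (bioavailable) amounts, so
#' `S_S1 + S_H1_0 + S_H2_0 + bound_cod` equals the total dosed
#' biodegradable COD.
#'
#' @param S_S1,S_H1_0,S_H2_0 initial bioavailable COD fractions (mg COD/L)
#' @param X_H1 initial active heterotrophic biomass (mg cell COD/L)
#' @param X_STO1 initial stored PHA (mg COD/L)
#' @param total_biomass total biomass COD (mg COD/L); must be >= `X_H1`
#' @param bound_cod COD blocked from utilization (mg COD/L)
#' @return an object of class `initial_conditions`
#' @export
initial_conditions <- function(S_S1, S_H1_0, S_H2_0, X_H1, X_STO1 = 0,
                               total_biomass = X_H1, bound_cod = 0) {
  ic <- list(S_S1 = S_S1, S_H1_0 = S_H1_0, S_H2_0 = S_H2_0, X_H1 = X_H1,
             X_STO1 = X_STO1, total_biomass = total_biomass,
             bound_cod = bound_cod)
  ic <- lapply(ic, function(v) if (is.numeric(v)) as.numeric(v) else v)
  validate_initial_conditions(ic)
  structure(ic, class = "initial_conditions")
}

validate_initial_conditions <- function(ic) {
  for (f in c("S_S1", "S_H1_0", "S_H2_0", "X_H1", "X_STO1",
              "total_biomass", "bound_cod")) {
    v <- ic[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0)
      stop("initial condition '", f, "' must be a single finite number >= 0",
           call. = FALSE)
  }
  if (ic$X_H1 > ic$total_biomass)
    stop("X_H1 exceeds total_biomass", call. = FALSE)
  invisible(ic)
}

#' Bundled calibrated parameter sets and initial states
#'
#' Calibrated kinetics and initial states for the four respirometric runs of
#' the sulfamethoxazole exposure experiment: run 1 (control, no antibiotic),
#' run 2 (acute, 50 mg/L SMX), run 4 (after 30 days chronic exposure) and
#' run 5 (intermittent, day 50). The antibiotic suppresses PHA storage
#' completely in runs 2, 4 and 5 (`k_STO = 0`), raises the growth
#' half-saturation `K_S`, and up to triples the endogenous decay rate `b_H`.
#'
#' @param run one of 1, 2, 4, 5
#' @return `run_params()`: a [model_params()] object; `run_init()`: an
#'   [initial_conditions()] object
#' @examples
#' p <- run_params(1)
#' p$mu_H  # 5.2 per day
#' @export
run_params <- function(run) {
  run <- match.arg(as.character(run), c("1", "2", "4", "5"))
  path <- system.file("extdata", paste0("params_run", run, ".json"),
                      package = "sludgeresp", mustWork = TRUE)
  load_params(path)
}

#' @rdname run_params
#' @export
run_init <- function(run) {
  run <- match.arg(as.character(run), c("1", "2", "4", "5"))
  path <- system.file("extdata", paste0("init_run", run, ".json"),
                      package = "sludgeresp", mustWork = TRUE)
  load_init(path)
}
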