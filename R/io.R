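# Configuration and tabular I/O. Config files are JSON (always) or YAML
# (when the yaml package is installed); keys mirror the model symbol names.

.read_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML config needs the 'yaml' package; ",
           "use JSON instead", call. = FALSE)
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}

.from_config <- function(cfg, constructor, required, optional, what) {
  unknown <- setdiff(names(cfg), c(required, optional))
  if (length(unknown))
    stop("unknown ", what, " key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  missing <- setdiff(required, names(cfg))
  if (length(missing))
    stop("missing required ", what, " key(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  do.call(constructor, cfg)
}

#' Load a model parameter set from a config file
#'
#' Reads a JSON (or YAML) file keyed by the kinetic symbol names (`mu_H`,
#' `K_S`, `b_H`, ...) and returns a validated [model_params()]. Unknown
#' keys are rejected by name; invariant violations name the offending
#' field.
#'
#' @param path config file path (.json, .yml or .yaml)
#' @return a [model_params()] object
#' @export
load_params <- function(path) {
  req <- c("mu_H", "K_S", "b_H", "k_h1", "K_X", "k_h2", "K_XX", "k_STO",
           "K_STO", "mu_STO", "Y_H", "Y_STO", "f_ES", "f_EX")
  .from_config(.read_config(path), model_params, req,
               optional = c("K_OH", "Y_SP"), what = "parameter")
}

#' Load batch initial conditions from a config file
#'
#' @param path config file path (.json, .yml or .yaml)
#' @return an [initial_conditions()] object
#' @export
load_init <- function(path) {
  req <- c("S_S1", "S_H1_0", "S_H2_0", "X_H1")
  .from_config(.read_config(path), initial_conditions, req,
               optional = c("X_STO1", "total_biomass", "bound_cod"),
               what = "initial-condition")
}

#' Read an OUR series from delimited text
#'
#' Two-column CSV with header `time_h,our_mg_L_h` (a plain `time_h,our`
#' header is also accepted).
#'
#' @param path file path
#' @param provenance provenance flag to attach (default "measured")
#' @return an [our_series()]
#' @export
read_our_csv <- function(path, provenance = "measured") {
  d <- utils::read.csv(path)
  if (ncol(d) < 2L) stop("need two columns: time and OUR", call. = FALSE)
  names(d)[1:2] <- c("time_h", "our")
  if (any(diff(d$time_h) <= 0))
    stop("time column must be strictly increasing", call. = FALSE)
  our_series(d$time_h, d$our, provenance = provenance)
}

#' Write an OUR series (or any tabular object) as CSV
#'
#' A round trip through [write_our_csv()]/[read_our_csv()] reproduces the
#' values to full double precision.
#'
#' @param series an [our_series()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_our_csv <- function(series, path) {
  d <- data.frame(time_h = format(series$time_h, digits = 17,
                                  scientific = FALSE, trim = TRUE),
                  our_mg_L_h = format(series$our, digits = 17,
                                      scientific = FALSE, trim = TRUE))
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a data.frame (trajectory, balance table, summary) as CSV
#'
#' @param obj a data.frame
#' @param path output path
#' @return `path`, invisibly
#' @export
write_table <- function(obj, path) {
  utils::write.csv(as.data.frame(obj), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
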