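#' Kinetic parameters of the three-state silencing model
#'
#' Bundle and validate the full parameter set of the coarse-grained
#' sRNA--mRNA--ribosome model. Rates are in molecules and minutes throughout;
#' `x`, `w`, `y`, `z` are dimensionless ratios describing the interaction
#' region of the target 5'UTR.
#'
#' @param alpha_m mRNA transcription rate (molecules/min, > 0).
#' @param alpha_s sRNA transcription rate (molecules/min, >= 0).
#' @param beta_m0 degradation rate of the naked mRNA (1/min, > 0).
#' @param beta_s sRNA degradation rate (1/min, > 0).
#' @param beta_p protein degradation/dilution rate (1/min, > 0).
#' @param k0 basal sRNA--mRNA interaction rate constant (1/(molecule*min), > 0).
#' @param gamma0 maximal translation rate (proteins per mRNA per min, > 0).
#' @param x ribosome--RBS binding affinity (dimensionless, >= 0).
#' @param w ratio of ribosome-bound to naked mRNA degradation rates (> 0);
#'   `w < 1` means bound ribosomes protect the mRNA.
#' @param y ratio of the sRNA--mRNA interaction rates with vs without a bound
#'   ribosome (> 0); `y < 1` is competition, `y > 1` recruitment.
#' @param z ratio of the sRNA--mRNA complex dissociation rate to the complex
#'   degradation rate (>= 0).
#' @return An object of class `kinetic_params` (a validated named list).
#' @seealso [preset_params()] for the two published parameter presets,
#'   [effective_rates()] for the coarse-grained rates.
#' @export
kinetic_params <- function(alpha_m = 1, alpha_s = 1, beta_m0 = 0.4,
                           beta_s = 0.1, beta_p = 1 / 60, k0 = 0.04,
                           gamma0 = 1, x = 1, w = 1, y = 1, z = 0.001) {
  p <- list(alpha_m = alpha_m, alpha_s = alpha_s, beta_m0 = beta_m0,
            beta_s = beta_s, beta_p = beta_p, k0 = k0, gamma0 = gamma0,
            x = x, w = w, y = y, z = z)
  validate_params(p)
  structure(p, class = "kinetic_params")
}

param_names <- function() {
  c("alpha_m", "alpha_s", "beta_m0", "beta_s", "beta_p", "k0", "gamma0",
    "x", "w", "y", "z")
}

validate_params <- function(p) {
  for (nm in param_names()) {
    v <- p[[nm]]
    if (is.null(v) || length(v) != 1L || !is.finite(v))
      stop("parameter '", nm, "' must be a single finite number", call. = FALSE)
  }
  strict_pos <- c("alpha_m", "beta_m0", "beta_s", "beta_p", "k0", "gamma0",
                  "w", "y")
  for (nm in strict_pos)
    if (p[[nm]] <= 0)
      stop("parameter '", nm, "' must be > 0 (got ", p[[nm]], ")",
           call. = FALSE)
  for (nm in c("alpha_s", "x", "z"))
    if (p[[nm]] < 0)
      stop("parameter '", nm, "' must be >= 0 (got ", p[[nm]], ")",
           call. = FALSE)
  invisible(p)
}

#' Published model parameter presets
#'
#' Two fixed parameter sets ship with the package, named after the model
#' figures they reproduce. They differ only in the naked-mRNA degradation
#' rate (`beta_m0` = 0.4 vs 0.42 1/min) and are deliberately kept separate.
#' The basal interaction rate is parameterized through the basal leakage rate
#' `lambda0 = beta_m0 * beta_s / k0`; both presets have `lambda0 = 1`.
#'
#' @param name `"fig2"` or `"fig5"`.
#' @param ... overrides for individual parameters (e.g. `y = 100`,
#'   `alpha_s = 2`, `x = 0.5`), passed to [kinetic_params()].
#' @return A `kinetic_params` object.
#' @export
preset_params <- function(name = c("fig2", "fig5"), ...) {
  name <- match.arg(name)
  base <- switch(name,
    fig2 = list(alpha_m = 1, alpha_s = 1, beta_m0 = 0.4, beta_s = 0.1,
                beta_p = 1 / 60, k0 = 0.04, gamma0 = 1, x = 1, w = 1,
                y = 1, z = 0.001),
    fig5 = list(alpha_m = 1, alpha_s = 1, beta_m0 = 0.42, beta_s = 0.1,
                beta_p = 1 / 60, k0 = 0.042, gamma0 = 1, x = 1, w = 1,
                y = 1, z = 0.001))
  dots <- list(...)
  bad <- setdiff(names(dots), param_names())
  if (length(bad) > 0)
    stop("unknown parameter override(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  base[names(dots)] <- dots
  do.call(kinetic_params, base)
}

#' Modify a parameter set
#'
#' @param params a `kinetic_params` object.
#' @param ... named parameter replacements.
#' @return A new validated `kinetic_params` object.
#' @export
update_params <- function(params, ...) {
  stopifnot(inherits(params, "kinetic_params"))
  dots <- list(...)
  bad <- setdiff(names(dots), param_names())
  if (length(bad) > 0)
    stop("unknown parameter(s): ", paste(bad, collapse = ", "), call. = FALSE)
  p <- unclass(params)
  p[names(dots)] <- dots
  do.call(kinetic_params, p)
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("Kinetic parameters (min^-1, molecules):\n")
  v <- unlist(unclass(x))
  print(v)
  er <- effective_rates(x)
  cat(sprintf("effective: beta_m=%.4g  k=%.4g  gamma=%.4g  lambda=%.4g  b=%.4g\n",
              er$beta_m, er$k, er$gamma, er$lam, er$b))
  invisible(x)
}

#' Read a parameter set from a flat key-value config file
#'
#' The format is one `key = value` pair per line, `#` comments allowed, keys
#' exactly the eleven model parameter names. Unknown keys are an error;
#' missing keys fall back to the defaults of [kinetic_params()].
#'
#' @param path file path.
#' @return A `kinetic_params` object.
#' @export
read_params <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "[=:]")
  if (any(lengths(kv) != 2L))
    stop("malformed config line(s) in ", path, call. = FALSE)
  keys <- trimws(vapply(kv, `[[`, "", 1L))
  vals <- suppressWarnings(as.numeric(trimws(vapply(kv, `[[`, "", 2L))))
  if (anyNA(vals))
    stop("non-numeric value(s) in ", path, call. = FALSE)
  bad <- setdiff(keys, param_names())
  if (length(bad) > 0)
    stop("unknown parameter key(s) in ", path, ": ",
         paste(bad, collapse = ", "), call. = FALSE)
  do.call(kinetic_params, as.list(stats::setNames(vals, keys)))
}

#' Write a parameter set as a flat key-value config file
#'
#' @param params a `kinetic_params` object.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "kinetic_params"))
  lines <- sprintf("%s = %.17g", param_names(),
                   unlist(unclass(params)[param_names()]))
  writeLines(lines, path)
  invisible(path)
}
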