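#' Jacobian of the mass-action system at a steady state
#'
#' Linearization of the (m, s, p) dynamics around the steady state:
#' \deqn{J = \begin{pmatrix} -\beta_m - ks & -km & 0\\
#'                           -ks & -\beta_s - km & 0\\
#'                           \gamma & 0 & -\beta_p \end{pmatrix}.}
#'
#' @param params a [kinetic_params()] object.
#' @param ss a [steady_state()]; computed if missing.
#' @return 3x3 matrix with dimnames `m`, `s`, `p`.
#' @export
jacobian_at <- function(params, ss = steady_state(params)) {
  er <- effective_rates(params)
  J <- matrix(c(-er$beta_m - er$k * ss$s, -er$k * ss$m, 0,
                -er$k * ss$s, -params$beta_s - er$k * ss$m, 0,
                er$gamma, 0, -params$beta_p),
              nrow = 3, byrow = TRUE,
              dimnames = list(c("m", "s", "p"), c("m", "s", "p")))
  J
}

#' Diffusion matrix of the linear noise approximation
#'
#' Built from the stoichiometry of the seven elementary reactions (mRNA and
#' sRNA birth and decay, codegradation, protein birth and decay):
#' \eqn{N = \sum_r a_r \nu_r \nu_r^T} evaluated at the steady state. The
#' codegradation channel (propensity \eqn{k s m}, stoichiometry
#' \eqn{(-1,-1,0)}) contributes the positive off-diagonal coupling
#' `N[m,s] = N[s,m] = k s m`; at steady state the diagonal entries reduce to
#' `2 alpha_m` and `2 alpha_s` by mass balance.
#'
#' @inheritParams jacobian_at
#' @return 3x3 symmetric matrix with dimnames `m`, `s`, `p`.
#' @export
diffusion_at <- function(params, ss = steady_state(params)) {
  er <- effective_rates(params)
  cod <- er$k * ss$s * ss$m
  N <- matrix(0, 3, 3, dimnames = list(c("m", "s", "p"), c("m", "s", "p")))
  N[1, 1] <- params$alpha_m + er$beta_m * ss$m + cod
  N[2, 2] <- params$alpha_s + params$beta_s * ss$s + cod
  N[1, 2] <- N[2, 1] <- cod
  N[3, 3] <- er$gamma * ss$m + params$beta_p * ss$p
  N
}

#' Stationary covariance from the fluctuation--dissipation relation
#'
#' Solves the Lyapunov equation \eqn{JC + CJ^T + N = 0} for the stationary
#' covariance `C` via the 9x9 Kronecker (vec) linear system. `J` must be
#' stable (all eigenvalues with negative real part), which holds at the
#' unique positive steady state of this model.
#'
#' @param J Jacobian (3x3), e.g. from [jacobian_at()].
#' @param N diffusion matrix (3x3), e.g. from [diffusion_at()].
#' @param ss optional [steady_state()]; if supplied, the noise summaries
#'   `eta_p` (protein CV^2), `eta_m` and the protein Fano factor are filled.
#' @return An object of class `covariance_result`: list with `C`, `J`, `N`,
#'   `eta_p`, `eta_m`, `fano_p`.
#' @export
solve_covariance <- function(J, N, ss = NULL) {
  stopifnot(is.matrix(J), all(dim(J) == c(3, 3)),
            is.matrix(N), all(dim(N) == c(3, 3)))
  ev <- eigen(J, only.values = TRUE)$values
  if (any(Re(ev) >= 0))
    stop("Jacobian is not stable; cannot solve the Lyapunov equation",
         call. = FALSE)
  I3 <- diag(3)
  A <- kronecker(I3, J) + kronecker(J, I3)
  C <- matrix(solve(A, -as.vector(N)), 3, 3, dimnames = dimnames(J))
  C <- (C + t(C)) / 2
  out <- list(C = C, J = J, N = N, eta_p = NA_real_, eta_m = NA_real_,
              fano_p = NA_real_)
  if (!is.null(ss)) {
    if (ss$p > 0) {
      out$eta_p <- C[3, 3] / ss$p^2
      out$fano_p <- C[3, 3] / ss$p
    }
    if (ss$m > 0) out$eta_m <- C[1, 1] / ss$m^2
  }
  structure(out, class = "covariance_result")
}

#' Protein noise for a parameter set
#'
#' Convenience wrapper: steady state, Jacobian, diffusion matrix and
#' Lyapunov solve in one call.
#'
#' @inheritParams jacobian_at
#' @return A `covariance_result` (see [solve_covariance()]).
#' @export
protein_noise <- function(params) {
  ss <- steady_state(params)
  solve_covariance(jacobian_at(params, ss), diffusion_at(params, ss), ss)
}

#' Intrinsic noise along a translational-activity axis
#'
#' Protein noise \eqn{\eta = \sigma_p^2/\langle p\rangle^2} from the linear
#' noise approximation, at each grid point, with the configured sRNA level
#' and with the sRNA off. Without sRNA the noise obeys the two-stage
#' closed form \eqn{\eta = (1 + b/(1+\beta_p/\beta_m))/\langle p\rangle},
#' which tends to \eqn{(1+b)/\langle p\rangle} for long-lived proteins.
#'
#' @inheritParams response_curve
#' @return A `data.frame` with columns `axis_kind`, `axis_value`, `x`,
#'   `p_on`, `p_off`, `eta_on`, `eta_off`.
#' @export
noise_curve <- function(params,
                        axis_kind = c("x", "translational_activity",
                                      "unregulated_expression"),
                        grid) {
  stopifnot(inherits(params, "kinetic_params"))
  axis_kind <- match.arg(axis_kind)
  if (length(grid) < 3L || any(diff(grid) <= 0))
    stop("grid must be strictly increasing with >= 3 points", call. = FALSE)
  xs <- switch(axis_kind,
    x = grid,
    translational_activity = {
      if (any(grid <= 0) || any(grid >= 1))
        stop("translational activity grid must lie in (0, 1)", call. = FALSE)
      grid / (1 - grid)
    },
    unregulated_expression = vapply(grid, invert_x_from_expression, 0,
                                    params = params))
  n <- length(grid)
  out <- data.frame(axis_kind = rep(axis_kind, n), axis_value = grid, x = xs,
                    p_on = NA_real_, p_off = NA_real_,
                    eta_on = NA_real_, eta_off = NA_real_)
  for (i in seq_len(n)) {
    p_on <- update_params(params, x = xs[i])
    p_off <- update_params(p_on, alpha_s = 0)
    for (tag in c("on", "off")) {
      pp <- if (tag == "on") p_on else p_off
      ss <- steady_state(pp)
      if (ss$p <= 0) next  # undefined noise at zero expression
      cv <- solve_covariance(jacobian_at(pp, ss), diffusion_at(pp, ss), ss)
      out[[paste0("p_", tag)]][i] <- ss$p
      out[[paste0("eta_", tag)]][i] <- cv$eta_p
    }
  }
  out
}

#' Detect an interior local maximum in a noisy profile
#'
#' Returns the index of an interior point that exceeds both neighbors by
#' more than `multiple` times the combined (quadrature) standard errors, or
#' `NULL` for monotone / flat-within-error profiles. When several points
#' qualify, the one with the largest value is returned.
#'
#' @param values numeric profile (>= 5 points).
#' @param errors standard errors (scalar or vector, >= 0; default 0).
#' @param multiple significance multiple of the combined errors (default 1).
#' @return Integer index, or `NULL` if no significant interior maximum.
#' @export
detect_local_maximum <- function(values, errors = 0, multiple = 1) {
  n <- length(values)
  if (n < 5L) stop("need >= 5 points", call. = FALSE)
  errors <- rep_len(errors, n)
  if (any(errors < 0)) stop("errors must be >= 0", call. = FALSE)
  cand <- integer(0)
  for (i in 2:(n - 1L)) {
    lhs <- values[i] - values[i - 1L] >
      multiple * sqrt(errors[i]^2 + errors[i - 1L]^2)
    rhs <- values[i] - values[i + 1L] >
      multiple * sqrt(errors[i]^2 + errors[i + 1L]^2)
    if (lhs && rhs) cand <- c(cand, i)
  }
  if (length(cand) == 0L) return(NULL)
  cand[which.max(values[cand])]
}

#' @export
print.covariance_result <- function(x, ...) {
  cat("Stationary covariance (linear noise approximation)\n")
  print(round(x$C, 6))
  cat(sprintf("eta_p = %.6g   eta_m = %.6g   Fano_p = %.6g\n",
              x$eta_p, x$eta_m, x$fano_p))
  invisible(x)
}

#' Serialize a covariance result to JSON
#'
#' Matrices are written row-major with named axes (m, s, p).
#'
#' @param cv a `covariance_result`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_covariance_json <- function(cv, path) {
  obj <- list(axes = c("m", "s", "p"),
              C = as.vector(t(cv$C)), J = as.vector(t(cv$J)),
              N = as.vector(t(cv$N)),
              eta_p = cv$eta_p, eta_m = cv$eta_m, fano_p = cv$fano_p)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
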