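#' Coarse-grained effective rates
#'
#' Collapse the three occupancy states of the target interaction region
#' (naked, ribosome-bound, sRNA-bound) into effective mass-action rates.
#' With ribosome--RBS affinity `x` the mRNA spends a fraction `x/(1+x)` of
#' its time ribosome-bound, giving
#' \deqn{\beta_m = \beta_{m0}\frac{1+wx}{1+x},\quad
#'       k = k_0\frac{1+xy}{(1+x)(1+z+xyz)},\quad
#'       \gamma = \gamma_0\frac{x}{1+x}.}
#' The leakage rate \eqn{\lambda = \beta_m \beta_s / k} compares RNA turnover
#' time scales (small \eqn{\lambda} = tight, threshold-like silencing), and
#' \eqn{b = \gamma/\beta_m} is the protein burst size.
#'
#' @param params a [kinetic_params()] object.
#' @return An object of class `effective_rates`: list with `beta_m`, `k`,
#'   `gamma`, `lam`, `b`.
#' @examples
#' effective_rates(preset_params("fig2", y = 100))
#' @export
effective_rates <- function(params) {
  stopifnot(inherits(params, "kinetic_params"))
  x <- params$x
  beta_m <- params$beta_m0 * (1 + params$w * x) / (1 + x)
  k <- params$k0 * (1 + x * params$y) /
    ((1 + x) * (1 + params$z + x * params$y * params$z))
  gamma <- params$gamma0 * x / (1 + x)
  structure(list(beta_m = beta_m, k = k, gamma = gamma,
                 lam = beta_m * params$beta_s / k, b = gamma / beta_m),
            class = "effective_rates")
}

new_steady_state <- function(m, s, p, params, er = effective_rates(params)) {
  res <- c(dm = params$alpha_m - er$beta_m * m - er$k * s * m,
           ds = params$alpha_s - params$beta_s * s - er$k * s * m,
           dp = er$gamma * m - params$beta_p * p)
  structure(list(m = m, s = s, p = p, residual_norm = max(abs(res))),
            class = "steady_state")
}

#' Steady state of the silencing model
#'
#' Mean steady-state molecule numbers of mRNA (`m`), sRNA (`s`) and protein
#' (`p`) obtained by setting the mass-action time derivatives to zero. The
#' closed form solves the quadratic in \eqn{\beta_m m},
#' \deqn{m = \frac{(\alpha_m-\alpha_s-\lambda)
#'   + \sqrt{(\alpha_m-\alpha_s-\lambda)^2 + 4\lambda\alpha_m}}{2\beta_m},}
#' the unique nonnegative root; then \eqn{s = (\beta_m m - \alpha_m +
#' \alpha_s)/\beta_s} and \eqn{p = \gamma m / \beta_p}. The numeric method is
#' an independent oracle: it eliminates `s` through the sRNA balance
#' (\eqn{s = \alpha_s/(\beta_s + km)}) and root-finds the reduced mRNA
#' equation with [stats::uniroot()].
#'
#' @param params a [kinetic_params()] object.
#' @param method `"closed_form"` (default) or `"numeric"`.
#' @param tol convergence tolerance for the numeric method.
#' @return An object of class `steady_state`: list with `m`, `s`, `p`,
#'   `residual_norm` (max absolute mass-action residual at the solution).
#' @examples
#' steady_state(preset_params("fig2", alpha_s = 2))
#' @export
steady_state <- function(params, method = c("closed_form", "numeric"),
                         tol = 1e-12) {
  stopifnot(inherits(params, "kinetic_params"))
  method <- match.arg(method)
  er <- effective_rates(params)
  if (method == "closed_form") {
    a <- params$alpha_m - params$alpha_s - er$lam
    u <- (a + sqrt(a * a + 4 * er$lam * params$alpha_m)) / 2
    m <- u / er$beta_m
    # sRNA balance form: algebraically equal to (u - alpha_m + alpha_s) /
    # beta_s at the root, but free of the catastrophic cancellation that
    # form suffers when lambda is tiny
    s <- params$alpha_s / (params$beta_s + er$k * m)
  } else {
    if (tol <= 0) stop("tol must be > 0", call. = FALSE)
    # reduced equation g(m) = alpha_m - beta_m m - k m s(m), s(m) from Eq for s
    g <- function(m) {
      s <- params$alpha_s / (params$beta_s + er$k * m)
      params$alpha_m - er$beta_m * m - er$k * s * m
    }
    hi <- params$alpha_m / er$beta_m          # g(hi) <= 0, g(0) = alpha_m > 0
    r <- stats::uniroot(g, lower = 0, upper = hi, tol = tol * hi,
                        extendInt = "no")
    m <- r$root
    s <- params$alpha_s / (params$beta_s + er$k * m)
  }
  s <- max(s, 0)
  ss <- new_steady_state(m, s, er$gamma * m / params$beta_p, params, er)
  if (method == "numeric" && ss$residual_norm > 1e3 * tol * params$alpha_m)
    stop("numeric steady state did not converge: residual ",
         format(ss$residual_norm), call. = FALSE)
  ss
}

#' Unregulated target expression
#'
#' Mean protein level in the absence of sRNA,
#' \eqn{p_{off} = \gamma(x)\,\alpha_m / (\beta_m(x)\,\beta_p)}. This is the
#' experimentally accessible "translational activity" axis (expression of the
#' reporter without sRNA induction).
#'
#' @inheritParams effective_rates
#' @return Mean protein count (molecules).
#' @export
unregulated_expression <- function(params) {
  er <- effective_rates(params)
  er$gamma * params$alpha_m / (er$beta_m * params$beta_p)
}

#' Silencing efficacy (fold repression)
#'
#' Ratio of target expression without and with the sRNA,
#' \eqn{p(\alpha_s{=}0)/p(\alpha_s)} (>= 1, larger = stronger silencing).
#' Translation and protein turnover cancel in the ratio, so efficacy equals
#' the mRNA ratio \eqn{m_{off}/m_{on}}. The reciprocal on/off convention
#' (repressed over unregulated, <= 1) is available via `as_ratio = TRUE`.
#'
#' @inheritParams effective_rates
#' @param as_ratio if `TRUE`, return the on/off expression ratio (<= 1)
#'   instead of fold repression.
#' @return Fold repression (or its reciprocal).
#' @export
efficacy <- function(params, as_ratio = FALSE) {
  stopifnot(inherits(params, "kinetic_params"))
  if (params$alpha_s <= 0)
    stop("efficacy requires alpha_s > 0", call. = FALSE)
  if (params$x <= 0)
    stop("undefined efficacy: unregulated expression is zero at x = 0",
         call. = FALSE)
  m_on <- steady_state(params)$m
  m_off <- steady_state(update_params(params, alpha_s = 0))$m
  if (as_ratio) m_on / m_off else m_off / m_on
}

#' Efficacy and expression response curves
#'
#' Sweep silencing efficacy and the regulated/unregulated expression levels
#' along one of four axes: the ribosome affinity `x`, the translational
#' activity \eqn{\gamma/\gamma_0 = x/(1+x)}, the unregulated expression level
#' (the experimentally plotted axis, default in the pipeline), or the sRNA
#' transcription rate `alpha_s`.
#'
#' @inheritParams effective_rates
#' @param axis_kind one of `"x"`, `"translational_activity"`,
#'   `"unregulated_expression"`, `"alpha_s"`.
#' @param grid strictly increasing numeric grid (>= 3 points) on the chosen
#'   axis.
#' @return A `data.frame` with columns `axis_kind`, `axis_value`, `x`,
#'   `expression_off`, `expression_on`, `efficacy`.
#' @export
response_curve <- function(params,
                           axis_kind = c("x", "translational_activity",
                                         "unregulated_expression", "alpha_s"),
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
                                    params = params),
    alpha_s = rep(params$x, length(grid)))
  n <- length(grid)
  out <- data.frame(axis_kind = rep(axis_kind, n), axis_value = grid,
                    x = xs, expression_off = NA_real_,
                    expression_on = NA_real_, efficacy = NA_real_)
  for (i in seq_len(n)) {
    pi_ <- if (axis_kind == "alpha_s")
      update_params(params, alpha_s = grid[i])
    else update_params(params, x = xs[i])
    out$expression_on[i] <- steady_state(pi_)$p
    out$expression_off[i] <- steady_state(update_params(pi_, alpha_s = 0))$p
    out$efficacy[i] <- out$expression_off[i] / out$expression_on[i]
  }
  out
}

#' Locate the efficacy optimum over ribosome affinity
#'
#' Grid pre-scan on log-spaced `x` followed by local refinement with
#' [stats::optimize()]. In the competition mode (`y/w < 1`) efficacy
#' decreases monotonically in `x`, so the maximum sits at the range boundary
#' and is flagged as such; in the recruitment mode (`y/w > 1`) an interior
#' maximum appears where the naked and ribosome-assisted sRNA-binding
#' channels balance.
#'
#' @inheritParams effective_rates
#' @param x_range length-2 positive range of ribosome affinities.
#' @param n_grid pre-scan grid size.
#' @return List with `x_opt`, `efficacy_opt`, `boundary` (`"none"`, `"lower"`
#'   or `"upper"`).
#' @export
find_max_efficacy <- function(params, x_range = c(1e-2, 1e2), n_grid = 200) {
  stopifnot(length(x_range) == 2L, all(x_range > 0), all(is.finite(x_range)),
            x_range[1] < x_range[2])
  lg <- seq(log(x_range[1]), log(x_range[2]), length.out = n_grid)
  f <- function(l) efficacy(update_params(params, x = exp(l)))
  vals <- vapply(lg, f, 0)
  i <- which.max(vals)
  if (i == 1L || i == n_grid) {
    return(list(x_opt = exp(lg[i]), efficacy_opt = vals[i],
                boundary = if (i == 1L) "lower" else "upper"))
  }
  opt <- stats::optimize(f, lower = lg[i - 1L], upper = lg[i + 1L],
                         maximum = TRUE, tol = 1e-10)
  list(x_opt = exp(opt$maximum), efficacy_opt = opt$objective,
       boundary = "none")
}

#' Classify the transcriptional regime
#'
#' The sRNA:mRNA transcription-rate ratio sets three regimes: `expressed`
#' (target transcribed much faster than the sRNA), `silenced` (sRNA in
#' excess) and `crossover` (comparable rates, where expression is
#' ultra-sensitive). Default thresholds 0.5 and 2 bracket the two published
#' regimes (ratio 1 = crossover, ratio 2 = silenced).
#'
#' @inheritParams effective_rates
#' @param t_lo,t_hi thresholds, `0 < t_lo < 1 < t_hi`.
#' @return List with `label` and `ratio`.
#' @export
classify_regime <- function(params, t_lo = 0.5, t_hi = 2) {
  stopifnot(t_lo > 0, t_lo < 1, t_hi > 1)
  r <- params$alpha_s / params$alpha_m
  label <- if (r < t_lo) "expressed" else if (r >= t_hi) "silenced" else
    "crossover"
  list(label = label, ratio = r)
}

#' Invert ribosome affinity from unregulated expression
#'
#' Solve `unregulated_expression(x) = expr_off` for `x`. The unregulated
#' level is \eqn{p(x) = A\,x/(1+wx)} with
#' \eqn{A = \gamma_0\alpha_m/(\beta_{m0}\beta_p)}, a saturating curve with
#' supremum \eqn{p_{max} = A/w}; the inverse is the closed form
#' \eqn{x = p/(A - w\,p)}. For `w = 1` this is \eqn{x = r/(1-r)} with
#' \eqn{r = p_{off}/p_{max}}.
#'
#' @inheritParams effective_rates
#' @param expr_off unregulated protein level, in `(0, p_max)`.
#' @return The ribosome affinity `x_hat`.
#' @export
invert_x_from_expression <- function(expr_off, params) {
  stopifnot(inherits(params, "kinetic_params"))
  A <- params$gamma0 * params$alpha_m / (params$beta_m0 * params$beta_p)
  p_max <- A / params$w
  if (expr_off <= 0) stop("expr_off must be > 0", call. = FALSE)
  if (expr_off >= p_max)
    stop("expr_off at or above the saturation level ", format(p_max),
         ": x is unbounded", call. = FALSE)
  expr_off / (A - params$w * expr_off)
}

#' Serialize a response curve to CSV
#'
#' @param curve a data.frame from [response_curve()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_response_curve <- function(curve, path) {
  utils::write.csv(curve[, c("axis_kind", "axis_value", "expression_off",
                             "expression_on", "efficacy")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
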