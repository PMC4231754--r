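#' Configuration for the exact stochastic simulator
#'
#' @param seed integer seed; every trajectory derives its own stream from it,
#'   so runs are bitwise reproducible.
#' @param t_burn_in burn-in time before sampling starts (min). Default
#'   `NULL`: ten relaxation times of the slowest linear mode,
#'   `10 / min(beta_p, beta_s, beta_m)`.
#' @param t_sample sampling duration per trajectory (min).
#' @param sample_interval spacing of recorded states (min). Default `NULL`:
#'   `max(1 / beta_m, 1)`, at least one effective mRNA lifetime to limit
#'   autocorrelation between samples.
#' @param n_trajectories number of independent trajectories (batch means over
#'   trajectories give the standard errors).
#' @return An `ssa_config` list.
#' @export
ssa_config <- function(seed = 1L, t_burn_in = NULL, t_sample = 2000,
                       sample_interval = NULL, n_trajectories = 16L) {
  stopifnot(t_sample > 0, n_trajectories >= 2L)
  structure(list(seed = as.integer(seed), t_burn_in = t_burn_in,
                 t_sample = t_sample, sample_interval = sample_interval,
                 n_trajectories = as.integer(n_trajectories)),
            class = "ssa_config")
}

#' Exact Gillespie simulation of the silencing system
#'
#' Direct-method stochastic simulation of the seven elementary reactions
#' implied by the mass-action model (mRNA/sRNA birth and decay,
#' codegradation, protein birth and decay), used as the independent oracle
#' for the linear noise approximation. States are sampled at fixed intervals
#' after burn-in; means, variances and CV^2 are estimated per trajectory and
#' combined by batch means, with standard errors from the between-trajectory
#' spread.
#'
#' @param params a [kinetic_params()] object.
#' @param config an [ssa_config()].
#' @param init optional integer initial state `c(m, s, p)`; default is the
#'   deterministic steady state, rounded.
#' @return An object of class `ssa_result`: list with `mean`, `se_mean`,
#'   `var`, `cv2`, `se_cv2` (each named over m, s, p), `per_trajectory`
#'   matrices, `event_count`, `n_samples_per_traj`, and the `config` (seed
#'   included).
#' @export
gillespie_simulate <- function(params, config = ssa_config(), init = NULL) {
  stopifnot(inherits(params, "kinetic_params"),
            inherits(config, "ssa_config"))
  er <- effective_rates(params)
  t_burn <- config$t_burn_in
  if (is.null(t_burn))
    t_burn <- 10 / min(params$beta_p, params$beta_s, er$beta_m)
  dt <- config$sample_interval
  if (is.null(dt)) dt <- max(1 / er$beta_m, 1)
  ss <- steady_state(params)
  if (is.null(init)) init <- as.integer(round(c(ss$m, ss$s, ss$p)))
  stopifnot(length(init) == 3L, all(init >= 0))
  rates <- c(alpha_m = params$alpha_m, beta_m = er$beta_m,
             alpha_s = params$alpha_s, beta_s = params$beta_s,
             k = er$k, gamma = er$gamma, beta_p = params$beta_p)
  raw <- ssa_run(rates, as.integer(init), t_burn, config$t_sample, dt,
                 config$n_trajectories, as.double(config$seed))
  nt <- config$n_trajectories
  agg <- function(M) {
    mu <- colMeans(M)
    se <- apply(M, 2, stats::sd) / sqrt(nt)
    list(mean = stats::setNames(mu, c("m", "s", "p")),
         se = stats::setNames(se, c("m", "s", "p")))
  }
  a_mean <- agg(raw$mean_traj); a_cv2 <- agg(raw$cv2_traj)
  structure(list(mean = a_mean$mean, se_mean = a_mean$se,
                 var = stats::setNames(colMeans(raw$var_traj),
                                       c("m", "s", "p")),
                 cv2 = a_cv2$mean, se_cv2 = a_cv2$se,
                 per_trajectory = list(mean = raw$mean_traj,
                                       var = raw$var_traj,
                                       cv2 = raw$cv2_traj),
                 event_count = raw$event_count,
                 n_samples_per_traj = raw$n_samples,
                 config = c(unclass(config),
                            list(t_burn_in_used = t_burn,
                                 sample_interval_used = dt))),
            class = "ssa_result")
}

#' @export
print.ssa_result <- function(x, ...) {
  cat(sprintf("SSA: %d trajectories, %d samples each, %.0f events\n",
              x$config$n_trajectories, x$n_samples_per_traj, x$event_count))
  tab <- rbind(mean = x$mean, se_mean = x$se_mean, cv2 = x$cv2,
               se_cv2 = x$se_cv2)
  print(round(tab, 5))
  invisible(x)
}

#' Serialize an SSA result to JSON
#'
#' @param res an `ssa_result`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ssa_json <- function(res, path) {
  obj <- list(axes = c("m", "s", "p"),
              mean = unname(res$mean), se_mean = unname(res$se_mean),
              var = unname(res$var), cv2 = unname(res$cv2),
              se_cv2 = unname(res$se_cv2),
              event_count = res$event_count,
              n_samples_per_traj = res$n_samples_per_traj,
              seed = res$config$seed)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
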