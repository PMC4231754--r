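# Estimators mirroring the measurement pipeline: GFP-vs-OD slopes with the
# published repeat-aggregation formulas, efficacy ratios, CV^2 noise with
# autofluorescence correction, efficiency-corrected ddCq quantification and
# exponential half-life fits.

#' Per-well expression slope
#'
#' 'GFP per cell' for one well: ordinary least-squares slope of total
#' fluorescence versus OD, restricted to the linear part of the curve. The
#' default window rule keeps reads whose OD lies in the central fraction of
#' the observed OD range (exponential phase) and whose fluorescence is below
#' the detector ceiling.
#'
#' @param t_min,od,fluor aligned time/OD/fluorescence vectors for one well.
#' @param od_window central OD fraction retained (default `c(0.2, 0.8)`,
#'   i.e. the central 60 percent of the OD range).
#' @param ceiling fluorescence detection ceiling; reads at or above it are
#'   dropped.
#' @param min_points minimum in-window reads for an unflagged fit.
#' @return List with `slope`, `se`, `n_used`, `flagged`.
#' @export
slope_expression <- function(t_min, od, fluor, od_window = c(0.2, 0.8),
                             ceiling = Inf, min_points = 4L) {
  stopifnot(length(od) == length(fluor))
  rng <- range(od)
  lo <- rng[1] + od_window[1] * diff(rng)
  hi <- rng[1] + od_window[2] * diff(rng)
  keep <- od >= lo & od <= hi & fluor < ceiling
  n <- sum(keep)
  if (n < 2L)
    return(list(slope = NA_real_, se = NA_real_, n_used = n, flagged = TRUE))
  # closed-form OLS (summary.lm warns on the exact-fit fixtures)
  xx <- od[keep]; yy <- fluor[keep]
  sxx <- sum((xx - mean(xx))^2)
  slope <- sum((xx - mean(xx)) * (yy - mean(yy))) / sxx
  rss <- sum((yy - mean(yy) - slope * (xx - mean(xx)))^2)
  list(slope = slope,
       se = if (n > 2L) sqrt(rss / (n - 2L) / sxx) else NA_real_,
       n_used = n, flagged = n < min_points)
}

#' Aggregate per-repeat expression with the published formulas
#'
#' Mean gene expression for a strain from its biological repeats:
#' \eqn{g = n^{-1}\sum_r g_r} and
#' \eqn{\sigma_g = n^{-1}\sqrt{\sum_r[(g_r-g)^2 + \sigma_{g_r}^2]}} --- the
#' published estimator, not the conventional standard error of the mean
#' (available via `conventional_sem = TRUE`, never the default). If an
#' autofluorescence estimate is supplied its mean is subtracted from every
#' repeat before averaging; negative corrected means are flagged, never
#' clipped.
#'
#' @param g_r per-repeat expression values (replicate-averaged slopes).
#' @param sigma_gr per-repeat standard errors (same length; default 0).
#' @param autofluor optional `expression_estimate` for the autofluorescence
#'   control, subtracted from each repeat.
#' @param conventional_sem use `sd(g_r)/sqrt(n)` instead of the published
#'   formula.
#' @return An `expression_estimate`: list with `g`, `sigma_g`, `n_repeats`,
#'   `g_r`, `sigma_gr`, `flagged`.
#' @export
aggregate_expression <- function(g_r, sigma_gr = 0, autofluor = NULL,
                                 conventional_sem = FALSE) {
  n <- length(g_r)
  stopifnot(n >= 1L)
  sigma_gr <- rep_len(sigma_gr, n)
  if (!is.null(autofluor)) g_r <- g_r - autofluor$g
  g <- mean(g_r)
  sigma_g <- if (conventional_sem) {
    if (n > 1L) stats::sd(g_r) / sqrt(n) else 0
  } else {
    sqrt(sum((g_r - g)^2 + sigma_gr^2)) / n
  }
  structure(list(g = g, sigma_g = sigma_g, n_repeats = n, g_r = g_r,
                 sigma_gr = sigma_gr, flagged = g <= 0),
            class = "expression_estimate")
}

#' Expression estimate for one strain from a plate dataset
#'
#' Applies [slope_expression()] well by well, averages technical replicates
#' within each biological repeat (`g_r`, with the replicate-spread standard
#' error), and combines repeats with [aggregate_expression()], subtracting
#' the autofluorescence strain's estimate.
#'
#' @param plate long-format plate data from [simulate_plate_reader()] (or
#'   the same CSV layout).
#' @param variant strain to estimate.
#' @param induction `"on"` or `"off"`.
#' @param autofluor_variant autofluorescence control strain (`NULL` to skip
#'   correction).
#' @param ... window options passed to [slope_expression()].
#' @return An `expression_estimate`.
#' @export
expression_from_plate <- function(plate, variant, induction = "off",
                                  autofluor_variant = "blank", ...) {
  af <- NULL
  if (!is.null(autofluor_variant) && autofluor_variant %in% plate$variant)
    af <- expression_from_plate(plate, autofluor_variant, "off",
                                autofluor_variant = NULL, ...)
  sub <- plate[plate$variant == variant & plate$induction == induction, ]
  if (nrow(sub) == 0L)
    stop("no wells for variant '", variant, "' (", induction, ")",
         call. = FALSE)
  reps <- sort(unique(sub$repeat_id))
  g_r <- sg_r <- numeric(length(reps))
  for (i in seq_along(reps)) {
    wr <- sub[sub$repeat_id == reps[i], ]
    slopes <- vapply(split(wr, wr$replicate), function(d)
      slope_expression(d$t_min, d$od, d$fluor, ...)$slope, 0)
    g_r[i] <- mean(slopes)
    sg_r[i] <- if (length(slopes) > 1L)
      stats::sd(slopes) / sqrt(length(slopes)) else 0
  }
  aggregate_expression(g_r, sg_r, autofluor = af)
}

#' Silencing efficacy from paired expression estimates
#'
#' Ratio of expression with and without the sRNA, with first-order
#' (delta-method) error propagation; `fold_repression` is the reciprocal.
#'
#' @param on,off `expression_estimate` objects for the induced and
#'   un-induced states.
#' @return An `efficacy_estimate`: list with `ratio`, `fold_repression`,
#'   `se`, `se_fold`, `flagged`.
#' @export
efficacy_estimate <- function(on, off) {
  if (off$g <= 0)
    return(structure(list(ratio = NA_real_, fold_repression = NA_real_,
                          se = NA_real_, se_fold = NA_real_, flagged = TRUE),
                     class = "efficacy_estimate"))
  ratio <- on$g / off$g
  rel <- sqrt((on$sigma_g / on$g)^2 + (off$sigma_g / off$g)^2)
  structure(list(ratio = ratio, fold_repression = 1 / ratio,
                 se = abs(ratio) * rel, se_fold = rel / abs(ratio),
                 flagged = on$g <= 0),
            class = "efficacy_estimate")
}

cv2_one_sample <- function(values, af_mean, af_var) {
  mu <- mean(values) - af_mean
  v <- stats::var(values) - af_var
  if (mu <= 0) return(c(eta = NA_real_, mean = mu))
  c(eta = v / mu^2, mean = mu)
}

#' CV^2 noise estimate from flow-cytometry data
#'
#' For each repeat, the mean and variance of the per-cell distribution are
#' corrected by subtracting the independently measured autofluorescence mean
#' and variance, and the noise \eqn{\eta_r} (CV^2 = variance over squared
#' mean) is averaged over replicate tubes with its replicate-spread standard
#' error. Repeats are then combined with the published formulas
#' \eqn{\eta = n^{-1}\sum_r \eta_r},
#' \eqn{\sigma_\eta = n^{-1}\sqrt{\sum_r[(\eta_r-\eta)^2 +
#' \sigma_{\eta_r}^2]}}; the corrected mean level is combined analogously.
#'
#' @param flow per-cell data from [simulate_flow_cytometry()] (one variant
#'   and induction state).
#' @param blank autofluorescence-only data from [simulate_flow_blank()].
#' @param min_cells minimum cells per replicate tube.
#' @return A `noise_estimate`: list with `eta`, `se_eta`, `mean_gfp`,
#'   `se_mean`, `n_repeats`, `flagged`.
#' @export
cv2_estimate <- function(flow, blank, min_cells = 1000L) {
  af_mean <- mean(blank$cell_fluor)
  af_var <- stats::var(blank$cell_fluor)
  reps <- sort(unique(flow$repeat_id))
  eta_r <- se_eta_r <- mu_r <- se_mu_r <- numeric(length(reps))
  for (i in seq_along(reps)) {
    wr <- flow[flow$repeat_id == reps[i], ]
    per <- vapply(split(wr$cell_fluor, wr$replicate), function(v) {
      if (length(v) < min_cells)
        stop("fewer than ", min_cells, " cells in a replicate", call. = FALSE)
      cv2_one_sample(v, af_mean, af_var)
    }, c(eta = 0, mean = 0))
    eta_r[i] <- mean(per["eta", ])
    mu_r[i] <- mean(per["mean", ])
    nrep <- ncol(per)
    se_eta_r[i] <- if (nrep > 1L) stats::sd(per["eta", ]) / sqrt(nrep) else 0
    se_mu_r[i] <- if (nrep > 1L) stats::sd(per["mean", ]) / sqrt(nrep) else 0
  }
  n <- length(reps)
  eta <- mean(eta_r); mu <- mean(mu_r)
  structure(list(
    eta = eta,
    se_eta = sqrt(sum((eta_r - eta)^2 + se_eta_r^2)) / n,
    mean_gfp = mu,
    se_mean = sqrt(sum((mu_r - mu)^2 + se_mu_r^2)) / n,
    n_repeats = n, flagged = !all(is.finite(eta_r)) || mu <= 0),
    class = "noise_estimate")
}

#' Efficiency-corrected relative quantification (ddCq)
#'
#' Relative target abundance against an internal reference gene,
#' \eqn{E_t^{\Delta Cq_t} / E_r^{\Delta Cq_r}} with
#' \eqn{\Delta Cq = Cq(\mathrm{ref\ point}) - Cq(\mathrm{sample})}.
#'
#' @param cq_target,cq_ref aligned Cq vectors (one value per sample, e.g.
#'   replicate-averaged).
#' @param ref_index index of the reference sample (default 1).
#' @param E_target,E_ref amplification efficiencies in (1, 2].
#' @return Vector of relative abundances (1 at the reference sample).
#' @export
ddcq_relative_quantity <- function(cq_target, cq_ref, ref_index = 1L,
                                   E_target = 2, E_ref = 2) {
  stopifnot(length(cq_target) == length(cq_ref),
            E_target > 1, E_target <= 2, E_ref > 1, E_ref <= 2)
  d_t <- cq_target[ref_index] - cq_target
  d_r <- cq_ref[ref_index] - cq_ref
  E_target^d_t / E_ref^d_r
}

#' Fit an exponential decay curve
#'
#' Nonlinear least squares of \eqn{f(t) = f_0 2^{-t/\tau_{1/2}}}, started
#' from the log-linear fit (which is exact for noiseless data).
#'
#' @param t_min times (min).
#' @param f relative abundances (> 0 required for the starting values).
#' @return List with `tau_half`, `f0`, `rss`.
#' @export
fit_exp_decay <- function(t_min, f) {
  stopifnot(length(t_min) == length(f), length(f) >= 3L)
  if (any(f <= 0))
    stop("nonpositive abundances cannot be fit", call. = FALSE)
  lf <- stats::lm(log2(f) ~ t_min)
  sl <- unname(stats::coef(lf)[2])
  if (sl >= 0) stop("abundances do not decay", call. = FALSE)
  start <- list(f0 = 2^unname(stats::coef(lf)[1]), tau = -1 / sl)
  # scaleOffset makes the relative-offset criterion valid at zero residual
  fit <- stats::nls(f ~ f0 * 2^(-t_min / tau), start = start,
                    control = stats::nls.control(maxiter = 200,
                                                 scaleOffset = 1))
  co <- stats::coef(fit)
  list(tau_half = unname(co["tau"]), f0 = unname(co["f0"]),
       rss = sum(stats::resid(fit)^2))
}

#' mRNA half-life from a rifampicin-chase qPCR series
#'
#' Replicate Cq values are averaged per time point; time points whose
#' replicate spread (max minus min target Cq) exceeds `snr_threshold` are
#' excluded as low signal-to-noise and logged. Relative abundances follow
#' from [ddcq_relative_quantity()] against the first retained time point,
#' and the half-life from [fit_exp_decay()].
#'
#' @param decay data from [simulate_decay_qpcr()] (or the same CSV layout).
#' @param E_target,E_ref amplification efficiencies.
#' @param snr_threshold replicate Cq spread above which a time point is
#'   excluded (cycles, default 1.0).
#' @return A `half_life_estimate`: list with `tau_half`, `f0`,
#'   `excluded_points` (data.frame `t_min`, `reason`), `fit_rss`,
#'   `n_points_used`.
#' @export
fit_half_life <- function(decay, E_target = 2, E_ref = 2,
                          snr_threshold = 1.0) {
  agg <- do.call(rbind, lapply(split(decay, decay$t_min), function(d)
    data.frame(t_min = d$t_min[1], cq_t = mean(d$cq_target),
               cq_r = mean(d$cq_ref),
               spread = diff(range(d$cq_target)))))
  agg <- agg[order(agg$t_min), ]
  drop <- agg$spread > snr_threshold
  excluded <- data.frame(t_min = agg$t_min[drop],
                         reason = rep("replicate Cq spread above threshold",
                                      sum(drop)))
  use <- agg[!drop, ]
  if (nrow(use) < 3L)
    stop("fewer than 3 usable time points after exclusions (",
         nrow(use), " left)", call. = FALSE)
  rel <- ddcq_relative_quantity(use$cq_t, use$cq_r, ref_index = 1L,
                                E_target = E_target, E_ref = E_ref)
  fit <- fit_exp_decay(use$t_min, rel)
  structure(list(tau_half = fit$tau_half, f0 = fit$f0,
                 excluded_points = excluded, fit_rss = fit$rss,
                 n_points_used = nrow(use)),
            class = "half_life_estimate")
}
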