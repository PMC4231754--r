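# Synthetic-data layer: emulate the three assay modalities (plate reader,
# flow cytometry, rifampicin-chase qPCR) with the statistical structure the
# estimators assume. All generators are pure functions of (config, seed) and
# carry their ground truth as a "truth" attribute.

#' Build an RBS-variant library
#'
#' A set of reporter variants sharing all kinetic parameters except the
#' ribosome--RBS affinity `x`, log-spaced over `x_span`, mirroring a
#' Shine--Dalgarno mutant library. With `w = 1` the unregulated expression
#' scales as `x/(1+x)`, so the span must reach well below `x = 0.01` for the
#' library to cover two orders of magnitude of expression; the default
#' (0.008--50) yields a ~120-fold range.
#'
#' @param base_params shared [kinetic_params()].
#' @param n_variants number of variants (>= 2).
#' @param x_span length-2 positive range `(x_lo, x_hi)`.
#' @return A `variant_library`: data.frame with columns `name`, `x_true` and
#'   the shared parameters as attribute `base_params`.
#' @export
make_variant_library <- function(base_params, n_variants = 10,
                                 x_span = c(0.008, 50)) {
  stopifnot(inherits(base_params, "kinetic_params"), n_variants >= 2,
            length(x_span) == 2, x_span[1] > 0, x_span[1] < x_span[2])
  x_true <- exp(seq(log(x_span[1]), log(x_span[2]),
                    length.out = n_variants))
  lib <- data.frame(name = sprintf("v%02d", seq_len(n_variants)),
                    x_true = x_true, stringsAsFactors = FALSE)
  attr(lib, "base_params") <- base_params
  class(lib) <- c("variant_library", "data.frame")
  lib
}

#' Kinetic parameters of one library variant
#'
#' @param library a [make_variant_library()] result.
#' @param name variant name.
#' @return The variant's `kinetic_params` (base parameters with its `x`).
#' @export
variant_params <- function(library, name) {
  i <- match(name, library$name)
  if (is.na(i)) stop("unknown variant: ", name, call. = FALSE)
  update_params(attr(library, "base_params"), x = library$x_true[i])
}

#' Generator settings for plate-reader time series
#'
#' @param doubling_time exponential-phase doubling time (min). Default 45,
#'   typical for E. coli in glucose minimal medium with casamino acids.
#' @param od0 OD at the first read.
#' @param t_max,dt time span and read interval (min); default reads every
#'   10 min for 2 h.
#' @param gain fluorescence units per protein molecule (arbitrary global
#'   scale; cancels in efficacy and CV^2).
#' @param autofluor_rate cellular autofluorescence (RFU per OD).
#' @param noise_sd relative technical noise on each fluorescence read.
#' @param ceiling detector saturation level (total RFU).
#' @param repeat_sdlog lognormal sd of the biological-repeat factor
#'   (extrinsic day-to-day variability).
#' @param n_repeats,n_replicates biological repeats and technical replicates
#'   (adjacent wells) per repeat.
#' @return A `plate_truth` list.
#' @export
plate_truth <- function(doubling_time = 45, od0 = 0.05, t_max = 120, dt = 10,
                        gain = 50, autofluor_rate = 150, noise_sd = 0.02,
                        ceiling = 1e5, repeat_sdlog = 0.1, n_repeats = 3,
                        n_replicates = 3) {
  structure(list(doubling_time = doubling_time, od0 = od0, t_max = t_max,
                 dt = dt, gain = gain, autofluor_rate = autofluor_rate,
                 noise_sd = noise_sd, ceiling = ceiling,
                 repeat_sdlog = repeat_sdlog, n_repeats = n_repeats,
                 n_replicates = n_replicates),
            class = "plate_truth")
}

#' Simulate plate-reader growth/fluorescence curves for a variant library
#'
#' OD grows exponentially from `od0`; total well fluorescence is
#' `(g_true * repeat_factor + autofluor_rate) * OD * (1 + noise)`, capped at
#' the detector ceiling. Induction-on wells express at the model's regulated
#' steady state, induction-off wells at the unregulated one. A reporter-free
#' `blank` strain (pure autofluorescence) is included for the correction.
#'
#' @param library a [make_variant_library()].
#' @param truth a [plate_truth()].
#' @param seed integer seed.
#' @return Long-format data.frame `(well, variant, induction, replicate,
#'   repeat_id, t_min, od, fluor)` with a `truth` attribute recording all
#'   generator ground truths.
#' @export
simulate_plate_reader <- function(library, truth = plate_truth(), seed = 1L) {
  stopifnot(inherits(library, "variant_library"),
            inherits(truth, "plate_truth"))
  tgrid <- seq(0, truth$t_max, by = truth$dt)
  od <- truth$od0 * 2^(tgrid / truth$doubling_time)
  variants <- c(library$name, "blank")
  g_true <- list()
  for (v in library$name) {
    pv <- variant_params(library, v)
    g_true[[v]] <- c(off = truth$gain * unregulated_expression(pv),
                     on = truth$gain * steady_state(pv)$p)
  }
  g_true[["blank"]] <- c(off = 0, on = 0)
  rows <- list(); ri <- 0L
  facs <- list(); fi <- 0L
  with_seed(seed, {
    for (v in variants) for (ind in c("off", "on")) {
      if (v == "blank" && ind == "on") next
      for (r in seq_len(truth$n_repeats)) {
        fac <- stats::rlnorm(1, meanlog = -truth$repeat_sdlog^2 / 2,
                             sdlog = truth$repeat_sdlog)
        fi <- fi + 1L
        facs[[fi]] <- data.frame(variant = v, induction = ind,
                                 repeat_id = r, factor = fac,
                                 stringsAsFactors = FALSE)
        slope <- g_true[[v]][[ind]] * fac + truth$autofluor_rate
        for (tech in seq_len(truth$n_replicates)) {
          eps <- stats::rnorm(length(tgrid), 0, truth$noise_sd)
          fl <- pmin(slope * od * (1 + eps), truth$ceiling)
          ri <- ri + 1L
          rows[[ri]] <- data.frame(
            well = sprintf("%s_%s_r%d_t%d", v, ind, r, tech),
            variant = v, induction = ind, replicate = tech, repeat_id = r,
            t_min = tgrid, od = od, fluor = fl, stringsAsFactors = FALSE)
        }
      }
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "truth") <- list(
    kind = "plate_reader", seed = seed, config = unclass(truth),
    base_params = unclass(attr(library, "base_params")),
    variants = data.frame(
      name = library$name, x_true = library$x_true,
      g_true_off = vapply(library$name, function(v) g_true[[v]][["off"]], 0),
      g_true_on = vapply(library$name, function(v) g_true[[v]][["on"]], 0)),
    repeat_factors = do.call(rbind, facs))
  out
}

#' Generator settings for flow-cytometry samples
#'
#' @param n_cells cells per sample (default 50 000).
#' @param eta_ext additive extrinsic CV^2 (default 0.05; the measured CV^2
#'   equals the intrinsic noise up to this additive constant).
#' @param gain fluorescence units per protein molecule.
#' @param autofluor_mean,autofluor_sd additive cellular autofluorescence.
#' @param n_repeats,n_replicates biological repeats and replicate tubes.
#' @return A `flow_truth` list.
#' @export
flow_truth <- function(n_cells = 50000, eta_ext = 0.05, gain = 50,
                       autofluor_mean = 100, autofluor_sd = 30,
                       n_repeats = 3, n_replicates = 3) {
  stopifnot(n_cells >= 2, eta_ext >= 0)
  structure(list(n_cells = n_cells, eta_ext = eta_ext, gain = gain,
                 autofluor_mean = autofluor_mean, autofluor_sd = autofluor_sd,
                 n_repeats = n_repeats, n_replicates = n_replicates),
            class = "flow_truth")
}

#' Simulate per-cell fluorescence for one variant and induction state
#'
#' Per-cell reporter levels are gamma-distributed with mean `gain * <p>`
#' (model steady state) and CV^2 equal to the model's intrinsic noise
#' `eta_p` plus the extrinsic constant `eta_ext`; Gaussian autofluorescence
#' is added on top (so raw values can dip below the reporter signal floor).
#' The gamma family matches burst-driven expression and is fully set by
#' mean + CV^2, which is all the downstream estimator uses.
#'
#' @param params the variant's [kinetic_params()].
#' @param induction `"on"` (sRNA induced) or `"off"` (`alpha_s = 0`).
#' @param truth a [flow_truth()].
#' @param seed integer seed.
#' @param variant_name label recorded in the output.
#' @return Data.frame `(variant, induction, repeat_id, replicate,
#'   cell_fluor)` with a `truth` attribute (intrinsic/extrinsic CV^2 and the
#'   target mean among them).
#' @export
simulate_flow_cytometry <- function(params, induction = c("on", "off"),
                                    truth = flow_truth(), seed = 1L,
                                    variant_name = "wt") {
  stopifnot(inherits(params, "kinetic_params"), inherits(truth, "flow_truth"))
  induction <- match.arg(induction)
  p_use <- if (induction == "off") update_params(params, alpha_s = 0) else
    params
  ss <- steady_state(p_use)
  if (ss$p <= 0)
    stop("zero expression: flow sample undefined at x = 0", call. = FALSE)
  cv <- solve_covariance(jacobian_at(p_use, ss), diffusion_at(p_use, ss), ss)
  cv2_tot <- cv$eta_p + truth$eta_ext
  if (cv2_tot <= 0) stop("target CV^2 must be > 0", call. = FALSE)
  mean_fl <- truth$gain * ss$p
  shape <- 1 / cv2_tot
  n <- truth$n_cells
  rows <- list(); ri <- 0L
  with_seed(seed, {
    for (r in seq_len(truth$n_repeats)) for (tech in
                                             seq_len(truth$n_replicates)) {
      sig <- stats::rgamma(n, shape = shape, scale = mean_fl / shape)
      af <- stats::rnorm(n, truth$autofluor_mean, truth$autofluor_sd)
      ri <- ri + 1L
      rows[[ri]] <- data.frame(variant = variant_name, induction = induction,
                               repeat_id = r, replicate = tech,
                               cell_fluor = sig + af,
                               stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "truth") <- list(kind = "flow", seed = seed,
                             config = unclass(truth), variant = variant_name,
                             induction = induction, p_mean = ss$p,
                             mean_fluor = mean_fl, eta_int = cv$eta_p,
                             eta_ext = truth$eta_ext, cv2_total = cv2_tot)
  out
}

#' Simulate an autofluorescence-only flow sample
#'
#' The un-induced control used for the noise correction: pure Gaussian
#' autofluorescence, same design as [simulate_flow_cytometry()].
#'
#' @inheritParams simulate_flow_cytometry
#' @return Data.frame in the same layout, `variant = "blank"`.
#' @export
simulate_flow_blank <- function(truth = flow_truth(), seed = 1L) {
  rows <- list(); ri <- 0L
  n <- truth$n_cells
  with_seed(seed, {
    for (r in seq_len(truth$n_repeats)) for (tech in
                                             seq_len(truth$n_replicates)) {
      ri <- ri + 1L
      rows[[ri]] <- data.frame(variant = "blank", induction = "off",
                               repeat_id = r, replicate = tech,
                               cell_fluor = stats::rnorm(
                                 n, truth$autofluor_mean, truth$autofluor_sd),
                               stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "truth") <- list(kind = "flow_blank", seed = seed,
                             config = unclass(truth))
  out
}

#' Simulate a rifampicin-chase RT-qPCR decay series
#'
#' After transcription shutoff the target abundance decays as
#' \eqn{f(t) = f_0 2^{-t/\tau_{1/2}}}; quantification cycles follow
#' \eqn{Cq(t) = Cq_0 + (t/\tau_{1/2}) \ln 2/\ln E + \epsilon} with
#' efficiency `E` and Gaussian cycle noise, while the 16S reference channel
#' stays flat. Default half-life 1.6 min (the measured average for the sodB
#' reporter library) and sampling at 1, 2, 3, 5 and 7 min.
#'
#' @param strain_truth list with `name`, `tau_half` (min), `cq0` (target Cq
#'   at t = 0), `cq_ref0` (reference Cq).
#' @param design list with `times` (min, strictly increasing, first at 1),
#'   `n_replicates` (2--3), `E_target`, `E_ref` in (1, 2], `cq_sd` (cycles).
#' @param seed integer seed.
#' @return Data.frame `(strain, t_min, replicate, cq_target, cq_ref)` with a
#'   `truth` attribute.
#' @export
simulate_decay_qpcr <- function(strain_truth = list(name = "wt",
                                                    tau_half = 1.6,
                                                    cq0 = 20, cq_ref0 = 12),
                                design = list(times = c(1, 2, 3, 5, 7),
                                              n_replicates = 3,
                                              E_target = 2, E_ref = 2,
                                              cq_sd = 0.1),
                                seed = 1L) {
  stopifnot(strain_truth$tau_half > 0, all(diff(design$times) > 0),
            design$E_target > 1, design$E_target <= 2,
            design$E_ref > 1, design$E_ref <= 2, design$cq_sd >= 0)
  tt <- design$times
  cq_t_true <- strain_truth$cq0 +
    (tt / strain_truth$tau_half) * log(2) / log(design$E_target)
  rows <- list()
  with_seed(seed, {
    for (j in seq_along(tt)) {
      nr <- design$n_replicates
      rows[[j]] <- data.frame(
        strain = strain_truth$name, t_min = tt[j], replicate = seq_len(nr),
        cq_target = cq_t_true[j] + stats::rnorm(nr, 0, design$cq_sd),
        cq_ref = strain_truth$cq_ref0 + stats::rnorm(nr, 0, design$cq_sd),
        stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "truth") <- list(kind = "decay_qpcr", seed = seed,
                             strain = strain_truth, design = design)
  out
}
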