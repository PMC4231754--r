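# Shared fixtures: random valid parameter sets and the exact-rate fixture
# whose effective rates are beta_m = 0.4, k = 0.04, lambda = 1 (x = 1,
# w = y = 1, z = 0 make Eqs for the effective rates collapse to the basal
# values).

random_params <- function(n, seed = 42) {
  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed); code
  }
  withr_seed(lapply(seq_len(n), function(i) kinetic_params(
    alpha_m = 10^runif(1, -1, 1), alpha_s = 10^runif(1, -2, 1),
    beta_m0 = 10^runif(1, -1.5, 0), beta_s = 10^runif(1, -2, 0),
    beta_p = 10^runif(1, -2.5, -0.5), k0 = 10^runif(1, -3, 0),
    gamma0 = 10^runif(1, -1, 1), x = 10^runif(1, -2, 2),
    w = 10^runif(1, -1, 1), y = 10^runif(1, -2, 2),
    z = 10^runif(1, -4, 0))))
}

exact_rate_params <- function(alpha_s = 2) {
  kinetic_params(alpha_m = 1, alpha_s = alpha_s, beta_m0 = 0.4, beta_s = 0.1,
                 beta_p = 1 / 60, k0 = 0.04, gamma0 = 1, x = 1, w = 1, y = 1,
                 z = 0)
}
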