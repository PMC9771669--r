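# Shared fixtures, built once per test run. Kept deliberately small: the
# full-scale study conditions live in test-acceptance.R.

# tiny constant-environment survey dataset with known truth
fix_const <- suppressWarnings(
  vb_generate_dataset("constant-env", seed = 42, n_t = 6, n_a = 4,
                      n_per_cell = 60)
)

# a well-formed parameter set on a small lattice
make_params <- function(n_t = 5, n_a = 4, env = "varying", groups = NULL,
                        r_b = 0.3, mu = 380, s2 = 1200) {
  grid <- vb_grid(0, n_t, 0, n_a)
  n_int <- if (env == "constant") 1L else n_t - 1L
  n_g <- if (is.null(groups)) 1L else groups$n_groups
  vb_params(
    grid, r_b,
    e_first_age = rep(120, n_t), v_first_age = rep(800, n_t),
    e_first_time = seq(190, by = 45, length.out = n_a - 1),
    v_first_time = rep(900, n_a - 1),
    mu_linf = matrix(mu, n_int, n_g),
    sigma2_linf2 = matrix(s2, n_int, n_g),
    env = env, groups = groups
  )
}

# random valid parameters for property-style loops
random_params <- function(env = "varying", n_t = 5, n_a = 4) {
  grid <- vb_grid(0, n_t, 0, n_a)
  n_int <- if (env == "constant") 1L else n_t - 1L
  vb_params(
    grid,
    r_b = runif(1, 0.1, 0.6),
    e_first_age = runif(n_t, 40, 150),
    v_first_age = runif(n_t, 50, 400),
    e_first_time = sort(runif(n_a - 1, 150, 500)),
    v_first_time = runif(n_a - 1, 500, 5000),
    mu_linf = matrix(runif(n_int, 300, 600), n_int, 1),
    sigma2_linf2 = matrix(runif(n_int, 500, 20000), n_int, 1),
    env = env
  )
}

# small observation table placed directly on a lattice
make_obs <- function(rows) {
  tibble::as_tibble(rows)
}
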