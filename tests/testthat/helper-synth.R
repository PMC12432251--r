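# shared fixture builders: everything is generated in code at test time

tiny_grid <- c(5L, 4L, 3L)

tiny_patterns <- function(seed = 1, alpha = 0.5, noise = 0, amp = 1,
                          grid = tiny_grid, drift = c(0, 0), rho = 1, ...) {
  simulate_patterns(
    synth_config(grid = grid, alpha = alpha, amp = amp, sigma_noise = noise,
                 sigma_drift = drift, rho_session = rho, ...),
    seed = seed)
}

tiny_dataset <- function(seed = 1, alpha = 0.5, noise = 0, amp = 1,
                         n_runs = 6L, n_sessions = 2L, grid = tiny_grid,
                         drift = c(0, 0), rho = 1, ...) {
  simulate_betas(tiny_patterns(seed, alpha, noise, amp, grid, drift, rho, ...),
                 n_runs = n_runs, n_sessions = n_sessions,
                 seed = seed + 1000L)
}

# four-condition dataset with well-separated condition patterns, ideal for
# multi-class decoding checks
separable_dataset <- function(seed = 1, grid = tiny_grid) {
  with_seed <- function(s, e) { set.seed(s); e }
  V <- prod(grid)
  set.seed(seed)
  conds <- c("SweT", "SavT", "SweO", "SavO")
  proto <- matrix(rnorm(4 * V, sd = 2), nrow = 4,
                  dimnames = list(conds, NULL))
  meta <- expand.grid(run = 1:6, session = 1:2, condition = conds,
                      stringsAsFactors = FALSE)
  meta$subject <- 1L
  vals <- proto[meta$condition, , drop = FALSE] +
    matrix(rnorm(nrow(meta) * V, sd = 0.05), nrow = nrow(meta))
  beta_dataset(vals, meta, grid)
}
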