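# shared test fixtures, built in code

# a spatially uniform constant-rate model; its symmetric steady state
# solves 1 - u - u^2 = 0, i.e. u* = (sqrt(5) - 1) / 2
constant_model <- function(a = 1, b = 1, th = 1, mobility = "none",
                           d_m = 1e-3, d_ns = 1e-3) {
  model_spec(a, b, a, b, th, d_m = d_m, d_ns = d_ns, mobility = mobility)
}

# pure-diffusion model (all reaction rates zero)
diffusion_model <- function(d = 1e-3, mobility = "both") {
  model_spec(0, 0, 0, 0, 0, d_m = d, d_ns = d, mobility = mobility)
}

# windowed Gaussian-mixture initial state pair on a grid
seeded_state <- function(grid, seed = 1, windowed = TRUE, amplitude = 6) {
  m <- gaussian_mixture_ic(grid, 3, amplitude, seed = seed)
  n <- gaussian_mixture_ic(grid, 3, amplitude, seed = seed + 1)
  if (windowed) {
    w <- consistency_window(grid)
    m <- apply_window(m, w)
    n <- apply_window(n, w)
  }
  state_pair(m, n, grid)
}

# max-norm difference between two trajectories, over all snapshots and
# both species
traj_max_diff <- function(a, b) {
  max(vapply(seq_along(a$states), function(i) {
    max(abs(a$states[[i]]$m - b$states[[i]]$m),
        abs(a$states[[i]]$n - b$states[[i]]$n))
  }, numeric(1)))
}
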