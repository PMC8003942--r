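#' Reference oncogene cluster-pattern table
#'
#' The packaged molecular-profiling table for non-small-cell lung cancer
#' oncogenes: 31 gene records, each with a cluster index (1--4) for the
#' non-treatment condition and the three long-exposure plasma-treatment
#' conditions (1 h, 2 h, 4 h post treatment), plus the id of the kinetic
#' model reported as its best or complete fit.  One record (`KRAS(2)`)
#' has no fitted model and carries `NA`.  The table ships as delimited
#' text in the package's pattern-table layout and is treated as
#' immutable reference data.
#'
#' @return A data frame with columns `gene_label`, `NT`, `LE1h`, `LE2h`,
#'   `LE4h`, `model`.
#' @export
table7_patterns <- function() {
  path <- system.file("extdata", "table7_patterns.tsv", package = "rdgep",
                      mustWork = TRUE)
  read_pattern_table(path)
}

#' Synthetic cluster pattern of a registry model
#'
#' Runs the full forward pipeline for one registry model -- seeded
#' Gaussian-mixture initial states (windowed for consistency under
#' Dirichlet conditions), reaction-diffusion integration, abundance
#' normalization, cluster assignment -- and returns the resulting
#' pattern.  Deterministic given `(model_id, config, seed)`.
#'
#' @param model_id registry model id (1--15).
#' @param config an [run_config()]; its seeds are superseded by `seed`
#'   when one is given.
#' @param seed integer seed for the initial states (the siRNA state uses
#'   `seed + 1`); `NULL` keeps the seeds in `config`.
#' @return An `rd_pattern` labelled `model_<id>`.
#' @export
synthetic_pattern <- function(model_id, config = run_config(), seed = NULL) {
  if (!is.null(seed)) {
    config$seed_m <- as.integer(seed)
    config$seed_n <- as.integer(seed) + 1L
  }
  config$model_id <- model_id
  traj <- .run_trajectory(config)
  cluster_pattern(traj,
                  condition_map = config$condition_map,
                  mode = config$normalization,
                  gene_label = paste0("model_", model_id))
}

#' Cluster-pattern library of the registry models
#'
#' [synthetic_pattern()] for every requested registry model under one
#' shared configuration and seed, giving the library that observed gene
#' patterns are matched against.
#'
#' @param model_ids which registry models to include.
#' @inheritParams synthetic_pattern
#' @return Named list of `rd_pattern`s (names are the model ids).
#' @export
pattern_library <- function(model_ids = 1:15, config = run_config(),
                            seed = NULL) {
  stats::setNames(
    lapply(model_ids, synthetic_pattern, config = config, seed = seed),
    as.character(model_ids))
}

#' Fine-step reference integration of the well-mixed system
#'
#' Classical 4th-order Runge-Kutta integration of the coupled reaction
#' ODEs at a small fixed step (default `1e-4`).  Intended as a numerical
#' reference for validating the production integrators; vectorised over
#' initial states and evaluation points, so a whole grid of well-mixed
#' cells can be integrated at once.
#'
#' @param model an `rd_model`.
#' @param m0,n0 initial concentrations (vectors are recycled to a common
#'   length).
#' @param t_end final time.
#' @param dt fixed step size.
#' @param x,y rate evaluation points (vectors recycled like `m0`).
#' @param times times at which to record the state (aligned to the
#'   nearest step); default `0:floor(t_end)` plus `t_end`.
#' @return A list with `times` and matrices `m`, `n` of dimension
#'   `length(times) x n_points`.
#' @export
reference_ode <- function(model, m0, n0, t_end, dt = 1e-4,
                          x = 0.5, y = 0.5, times = NULL) {
  stopifnot(inherits(model, "rd_model"))
  if (is.null(times)) times <- unique(c(0:floor(t_end), t_end))
  np <- max(length(m0), length(n0), length(x), length(y))
  m <- rep_len(as.numeric(m0), np)
  n <- rep_len(as.numeric(n0), np)
  x <- rep_len(as.numeric(x), np)
  y <- rep_len(as.numeric(y), np)

  evs <- lapply(model[c("alpha_m", "beta_m", "alpha_ns", "beta_ns", "theta")],
                .rate_evaluator, x = x, y = y)
  rhs <- function(t, m, n) {
    coupled <- evs$theta(t) * m * n
    list(dm = evs$alpha_m(t) - evs$beta_m(t) * m - coupled,
         dn = evs$alpha_ns(t) - evs$beta_ns(t) * n - coupled)
  }

  n_steps <- as.integer(ceiling(t_end / dt - 1e-9))
  k_rec <- pmin(pmax(as.integer(round(times / dt)), 0L), n_steps)
  mm <- matrix(NA_real_, length(times), np)
  nn <- matrix(NA_real_, length(times), np)
  record <- function(k, t, m, n) {
    for (i in which(k_rec == k)) {
      mm[i, ] <<- m
      nn[i, ] <<- n
    }
  }
  .step_loop(rhs, m, n, dt, n_steps, "rk4", record_at = k_rec, record = record)
  list(times = times, m = mm, n = nn)
}
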