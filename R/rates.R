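#' Rate function specifications
#'
#' A rate specification (`rd_rate`) is a deterministic scalar function of
#' time and, for the spatially varying "experimental" forms, of the spatial
#' coordinates `(x, y)`.  Rates parameterise transcription (production),
#' self-degradation, and coupled degradation in the two-species
#' mRNA--siRNA kinetic models.
#'
#' The built-in expression identifiers are:
#'
#' * `const` -- a constant; its value is given by `value`.
#' * `exp_t` -- \eqn{e^t}.
#' * `gauss_sharp` -- \eqn{e^{-100 (t-2)^2}}, a narrow pulse centred at t = 2.
#' * `gauss` -- \eqn{e^{-(t-2)^2}}, a broad pulse centred at t = 2.
#' * `cosh2` -- \eqn{e^{3-t} + e^{-1+t}}, a U-shaped rate with minimum at t = 2.
#' * `half_cosh2` -- \eqn{0.5 (e^{3-t} + e^{-1+t})}.
#' * `pulse` -- \eqn{e^{-(t-2)^2} / (0.05 + (t-2)^2)}, a sharp rational pulse
#'   peaking at 20 when t = 2.
#' * `exp_sin` -- \eqn{e^{t/2} |\sin(\pi t)|}, an amplitude-growing rectified
#'   oscillation vanishing at integer t.  The alternative reading
#'   \eqn{e^{t^2} |\sin(\pi t)|} is available as `exp_t2_sin`.
#' * `log1p` -- \eqn{\log(1 + t)} (natural logarithm).
#' * `log_pole` -- \eqn{1 / (\log 5 - \log(1 + t))}, singular at t = 4.
#'   When created through [rate_spec()] it carries a default cap equal to
#'   its value at \eqn{t = 4 - 10^{-2}} so that capped evaluation stays
#'   finite through the pole.
#' * `epigenetic` -- \eqn{1 + 1 / (2 - 0.1 t)}, an epigenetic modulation
#'   rate (present in the library, unused by the built-in models).
#' * `tanh_half` -- \eqn{0.5 [\tanh((xy - 0.5)/0.2) + 1]}, spatial.
#' * `tanh_one` -- \eqn{\tanh((xy - 0.5)/0.2) + 1}, spatial.
#' * `custom` -- a user closure `fn(t, x, y)`.
#'
#' Here `xy` denotes the product of the two spatial coordinates, and all
#' logarithms are natural.
#'
#' @param expression_id one of the identifiers above.
#' @param value constant value; required when `expression_id = "const"`.
#' @param cap optional maximum absolute value.  Capped evaluation returns
#'   `sign(v) * min(|v|, cap)`, which keeps singular-prone rates finite.
#' @param fn for `expression_id = "custom"`, a vectorised function
#'   `fn(t, x, y)`.
#' @param spatial for custom rates, whether `fn` depends on `(x, y)`.
#'
#' @return An object of class `rd_rate`.
#' @examples
#' r <- rate_spec("tanh_half")
#' rate_eval(r, t = 0, x = 0.5, y = 0.5)  # 0.07585818
#' @export
rate_spec <- function(expression_id, value = NULL, cap = NULL, fn = NULL,
                      spatial = FALSE) {
  ids <- names(.rate_table)
  if (!is.character(expression_id) || length(expression_id) != 1L ||
      !(expression_id %in% c(ids, "custom"))) {
    stop("unknown rate expression_id: ", deparse(expression_id),
         " (known: ", paste(c(ids, "custom"), collapse = ", "), ")",
         call. = FALSE)
  }
  if (expression_id == "const") {
    if (is.null(value) || !is.numeric(value) || length(value) != 1L ||
        !is.finite(value)) {
      stop("constant rate requires a single finite 'value'", call. = FALSE)
    }
  }
  if (expression_id == "custom") {
    if (!is.function(fn)) stop("custom rate requires 'fn'", call. = FALSE)
  }
  if (!is.null(cap) && (!is.numeric(cap) || cap <= 0)) {
    stop("'cap' must be a positive number", call. = FALSE)
  }
  if (is.null(cap) && expression_id == "log_pole") {
    # default cap: the rate's value just before its pole (t = 4 - 1e-2)
    cap <- 1 / (log(5) - log(1 + (4 - 1e-2)))
  }
  structure(
    list(kind = .rate_kind(expression_id),
         expression_id = expression_id,
         value = if (identical(expression_id, "const")) as.numeric(value) else NULL,
         cap = cap,
         fn = fn,
         spatial = if (identical(expression_id, "custom")) isTRUE(spatial)
                   else .rate_table[[expression_id]]$spatial),
    class = "rd_rate")
}

# expression table: evaluator f(t, x, y) plus metadata.  All evaluators are
# vectorised over their active argument.
.rate_table <- list(
  const       = list(kind = "constant", spatial = FALSE,
                     f = function(t, x, y, value) rep_len(value, length(t))),
  exp_t       = list(kind = "exponential", spatial = FALSE,
                     f = function(t, x, y, value) exp(t)),
  gauss_sharp = list(kind = "exponential", spatial = FALSE,
                     f = function(t, x, y, value) exp(-100 * (t - 2)^2)),
  gauss       = list(kind = "exponential", spatial = FALSE,
                     f = function(t, x, y, value) exp(-(t - 2)^2)),
  cosh2       = list(kind = "exponential", spatial = FALSE,
                     f = function(t, x, y, value) exp(3 - t) + exp(-1 + t)),
  half_cosh2  = list(kind = "exponential", spatial = FALSE,
                     f = function(t, x, y, value) 0.5 * (exp(3 - t) + exp(-1 + t))),
  pulse       = list(kind = "exponential", spatial = FALSE,
                     f = function(t, x, y, value) exp(-(t - 2)^2) / (0.05 + (t - 2)^2)),
  exp_sin     = list(kind = "exponential", spatial = FALSE,
                     f = function(t, x, y, value) exp(t / 2) * abs(sin(pi * t))),
  exp_t2_sin  = list(kind = "exponential", spatial = FALSE,
                     f = function(t, x, y, value) exp(t^2) * abs(sin(pi * t))),
  log1p       = list(kind = "log", spatial = FALSE,
                     f = function(t, x, y, value) log(1 + t)),
  log_pole    = list(kind = "log", spatial = FALSE,
                     f = function(t, x, y, value) 1 / (log(5) - log(1 + t))),
  epigenetic  = list(kind = "epigenetic", spatial = FALSE,
                     f = function(t, x, y, value) 1 + 1 / (2 - 0.1 * t)),
  tanh_half   = list(kind = "experimental", spatial = TRUE,
                     f = function(t, x, y, value) 0.5 * (tanh((x * y - 0.5) / 0.2) + 1)),
  tanh_one    = list(kind = "experimental", spatial = TRUE,
                     f = function(t, x, y, value) tanh((x * y - 0.5) / 0.2) + 1)
)

.rate_kind <- function(id) {
  if (id == "custom") "custom" else .rate_table[[id]]$kind
}

#' Evaluate a rate specification
#'
#' Evaluates the rate at time `t` and, for spatial rates, at coordinates
#' `(x, y)`.  Evaluation is deterministic.  Temporal rates ignore `(x, y)`
#' and are vectorised over `t`; spatial rates ignore `t` and are vectorised
#' over `x` and `y` (which may be arrays, in which case the result has
#' their shape).  If the rate carries a cap, the returned value is
#' `sign(v) * min(|v|, cap)`.
#'
#' @param rate an [rate_spec()] object.
#' @param t time, `t >= 0`.
#' @param x,y spatial coordinates; required for spatial rates.
#' @param apply_cap set to `FALSE` to inspect the raw, uncapped value.
#' @return Numeric vector/array of rate values.
#' @export
rate_eval <- function(rate, t, x = NULL, y = NULL, apply_cap = TRUE) {
  stopifnot(inherits(rate, "rd_rate"))
  if (any(t < 0)) stop("rate evaluation requires t >= 0", call. = FALSE)
  if (rate$spatial && (is.null(x) || is.null(y))) {
    stop("spatial rate '", rate$expression_id,
         "' requires coordinates x and y", call. = FALSE)
  }
  v <- if (rate$expression_id == "custom") {
    rate$fn(t, x, y)
  } else {
    .rate_table[[rate$expression_id]]$f(t, x, y, rate$value)
  }
  if (any(is.nan(v))) {
    stop("rate '", rate$expression_id, "' evaluated to NaN", call. = FALSE)
  }
  if (apply_cap && !is.null(rate$cap)) {
    v <- sign(v) * pmin(abs(v), rate$cap)
  } else if (any(!is.finite(v))) {
    stop("rate '", rate$expression_id,
         "' is singular at the evaluation point and has no cap",
         call. = FALSE)
  }
  v
}

#' @export
print.rd_rate <- function(x, ...) {
  cat("<rd_rate> ", x$expression_id,
      if (x$expression_id == "const") paste0(" = ", format(x$value)),
      if (x$spatial) "  [spatial]" else "  [temporal]",
      if (!is.null(x$cap)) paste0("  cap=", format(x$cap)),
      "\n", sep = "")
  invisible(x)
}

#' Diagnose a rate over a time horizon
#'
#' Samples the rate on a dense time grid over `[0, horizon]` and reports
#' extrema, sign changes, zeros, and proximity to singularities (values
#' that are non-finite or exceed `singular_threshold` in magnitude before
#' capping).  Spatial rates are sampled at a fixed evaluation point.
#'
#' @param rate an [rate_spec()] object.
#' @param horizon positive end of the sampled time interval.
#' @param n number of sample points.
#' @param x,y evaluation point for spatial rates (default domain centre).
#' @param singular_threshold magnitude above which a raw value is flagged
#'   as near-singular.
#' @return An `rd_rate_report` list with elements `max`, `min`, `t_max`,
#'   `n_sign_changes`, `zeros`, `singularities`, and `flags`.
#' @examples
#' rep6 <- validate_rate(rate_spec("log_pole"), horizon = 4)
#' rep6$singularities  # flags t = 4
#' @export
validate_rate <- function(rate, horizon, n = 4001L, x = 0.5, y = 0.5,
                          singular_threshold = 1e6) {
  stopifnot(inherits(rate, "rd_rate"))
  if (!is.numeric(horizon) || horizon <= 0) {
    stop("'horizon' must be > 0", call. = FALSE)
  }
  ts <- seq(0, horizon, length.out = n)
  raw <- vapply(ts, function(ti) {
    out <- tryCatch(
      rate_eval(rate, ti, x = x, y = y, apply_cap = FALSE),
      error = function(e) Inf)
    as.numeric(out)[1L]
  }, numeric(1))

  finite <- is.finite(raw)
  singular <- ts[!finite | abs(raw) > singular_threshold]
  vals <- raw[finite]
  tf <- ts[finite]
  zero_tol <- 1e-9
  near_zero <- abs(vals) < zero_tol
  sgn <- sign(vals)
  sgn_nz <- sgn[sgn != 0]
  n_sign_changes <- if (length(sgn_nz) > 1) sum(diff(sgn_nz) != 0) else 0L
  # zeros: grid points at (or bracketing) a zero of the rate
  crossing <- which(diff(sgn) != 0 & sgn[-length(sgn)] != 0 & sgn[-1] != 0)
  zeros <- sort(unique(c(tf[near_zero], tf[crossing])))

  flags <- character(0)
  if (length(singular)) {
    flags <- c(flags, paste0("near-singular around t = ",
                             paste(format(range(singular)), collapse = "..")))
  }
  if (n_sign_changes > 0) flags <- c(flags, "rate changes sign on the horizon")
  if (length(zeros)) flags <- c(flags, paste0(length(zeros), " zero(s) detected"))

  structure(
    list(expression_id = rate$expression_id,
         horizon = horizon,
         max = if (length(vals)) max(vals) else NA_real_,
         min = if (length(vals)) min(vals) else NA_real_,
         t_max = if (length(vals)) tf[which.max(vals)] else NA_real_,
         n_sign_changes = n_sign_changes,
         zeros = zeros,
         singularities = singular,
         flags = flags),
    class = "rd_rate_report")
}

#' @export
print.rd_rate_report <- function(x, ...) {
  cat("Rate diagnostic:", x$expression_id, "on [0,", format(x$horizon), "]\n")
  cat("  max ", format(x$max), " at t = ", format(x$t_max),
      ";  min ", format(x$min), "\n", sep = "")
  cat("  sign changes:", x$n_sign_changes, "\n")
  if (length(x$zeros)) {
    cat("  zeros near t =", paste(format(round(x$zeros, 4)), collapse = ", "), "\n")
  }
  if (length(x$singularities)) {
    cat("  SINGULARITY near t =",
        paste(format(round(range(x$singularities), 4)), collapse = ".."), "\n")
  }
  if (!length(x$flags)) cat("  no flags\n")
  invisible(x)
}
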