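#' Two-species kinetic model specification
#'
#' A model specification (`rd_model`) bundles the five rate functions of
#' the coupled mRNA--siRNA system -- mRNA production `alpha_m`, mRNA
#' self-degradation `beta_m`, siRNA production `alpha_ns`, siRNA
#' self-degradation `beta_ns`, and the coupled-degradation coefficient
#' `theta` multiplying the bilinear loss term `m * n` in both species'
#' equations -- together with the diffusion coefficients and the mobility
#' mode.
#'
#' The mobility mode selects which species carries a diffusion term:
#' `"none"` (reaction-only), `"ns_only"` (siRNA mobile), `"mi_only"`
#' (mRNA mobile), or `"both"`.
#'
#' @param alpha_m,beta_m,alpha_ns,beta_ns,theta rate functions, each an
#'   [rate_spec()] object or a single number (interpreted as a constant
#'   rate).
#' @param d_m,d_ns non-negative diffusion coefficients (length^2/time).
#' @param mobility one of `"none"`, `"ns_only"`, `"mi_only"`, `"both"`.
#' @param model_id optional integer identifier (1--15 for registry models).
#' @return An object of class `rd_model`.
#' @examples
#' # a symmetric constant-rate model with fixed point (sqrt(5)-1)/2
#' m <- model_spec(1, 1, 1, 1, 1, mobility = "none")
#' @export
model_spec <- function(alpha_m, beta_m, alpha_ns, beta_ns, theta,
                       d_m = 1e-3, d_ns = 1e-3,
                       mobility = c("both", "none", "ns_only", "mi_only"),
                       model_id = NA_integer_) {
  as_rate <- function(r, what) {
    if (inherits(r, "rd_rate")) return(r)
    if (is.numeric(r) && length(r) == 1L && is.finite(r)) {
      return(rate_spec("const", value = r))
    }
    stop("'", what, "' must be an rd_rate or a single number", call. = FALSE)
  }
  mobility <- match.arg(mobility)
  if (!is.numeric(d_m) || d_m < 0 || !is.numeric(d_ns) || d_ns < 0) {
    stop("diffusion coefficients must be >= 0", call. = FALSE)
  }
  structure(
    list(model_id = as.integer(model_id),
         alpha_m = as_rate(alpha_m, "alpha_m"),
         beta_m = as_rate(beta_m, "beta_m"),
         alpha_ns = as_rate(alpha_ns, "alpha_ns"),
         beta_ns = as_rate(beta_ns, "beta_ns"),
         theta = as_rate(theta, "theta"),
         d_m = as.numeric(d_m),
         d_ns = as.numeric(d_ns),
         mobility = mobility),
    class = "rd_model")
}

#' @export
print.rd_model <- function(x, ...) {
  fmt <- function(r) {
    if (r$expression_id == "const") format(r$value) else r$expression_id
  }
  cat("<rd_model>", if (!is.na(x$model_id)) paste("model", x$model_id) else "custom", "\n")
  cat("  alpha_m:  ", fmt(x$alpha_m), "\n")
  cat("  beta_m:   ", fmt(x$beta_m), "\n")
  cat("  alpha_ns: ", fmt(x$alpha_ns), "\n")
  cat("  beta_ns:  ", fmt(x$beta_ns), "\n")
  cat("  theta:    ", fmt(x$theta), "\n")
  cat("  D_m =", format(x$d_m), " D_ns =", format(x$d_ns),
      " mobility =", x$mobility, "\n")
  invisible(x)
}

# registry rows: (alpha_m, beta_m, alpha_ns, beta_ns, theta), each either an
# expression id or a numeric constant.  Several rows duplicate
# one another (1/7, 2/9, 4/10, 8/14, 12/15) and are reproduced verbatim;
# they form the pattern-equivalence classes documented in
# model_equivalence_classes().
.registry_rows <- list(
  list("half_cosh2", 1e-3, "exp_t", 10, 1),               # 1
  list("half_cosh2", 1e-3, "pulse", 1e-1, 1e-1),          # 2
  list("cosh2", "gauss", "tanh_half", 1e-2, "gauss"),     # 3
  list("tanh_half", "gauss_sharp", "pulse", 1e-2, "exp_sin"), # 4
  list("half_cosh2", "log1p", "exp_sin", "exp_sin", "log1p"), # 5
  list("pulse", 1e-2, "log_pole", 10, 1),                 # 6
  list("half_cosh2", 1e-3, "exp_t", 10, 1),               # 7
  list("half_cosh2", 1e-3, "pulse", 1e-3, 1),             # 8
  list("half_cosh2", 1e-3, "pulse", 1e-1, 1e-1),          # 9
  list("tanh_half", "gauss_sharp", "pulse", 1e-2, "exp_sin"), # 10
  list("pulse", "exp_sin", "exp_sin", "gauss", 1e-3),     # 11
  list("pulse", 1e-2, "cosh2", "pulse", "pulse"),         # 12
  list("pulse", 1, "tanh_half", 1e-3, 1e-1),              # 13
  list("half_cosh2", 1e-3, "pulse", 1e-3, 1),             # 14
  list("pulse", 1e-2, "cosh2", "pulse", "pulse")          # 15
)

#' Retrieve a registry model
#'
#' Returns one of the fifteen built-in two-species kinetic models.  All
#' registry models default to diffusion coefficients
#' `d_m = d_ns = 1e-3` on the unit domain with both species mobile.
#'
#' @param model_id integer in 1--15.
#' @param d_m,d_ns,mobility overrides for the diffusion setup.
#' @return An `rd_model`.
#' @examples
#' get_model(1)
#' @export
get_model <- function(model_id, d_m = 1e-3, d_ns = 1e-3, mobility = "both") {
  if (!is.numeric(model_id) || length(model_id) != 1L ||
      is.na(model_id) || model_id != as.integer(model_id) ||
      model_id < 1L || model_id > length(.registry_rows)) {
    stop("model_id must be an integer in 1..", length(.registry_rows),
         call. = FALSE)
  }
  row <- .registry_rows[[as.integer(model_id)]]
  as_r <- function(z) if (is.character(z)) rate_spec(z) else z
  model_spec(as_r(row[[1]]), as_r(row[[2]]), as_r(row[[3]]),
             as_r(row[[4]]), as_r(row[[5]]),
             d_m = d_m, d_ns = d_ns, mobility = mobility,
             model_id = as.integer(model_id))
}

#' List all registry models
#'
#' @inheritParams get_model
#' @return A list of 15 `rd_model` objects, named `"1"` ... `"15"`.
#' @export
model_registry <- function(d_m = 1e-3, d_ns = 1e-3, mobility = "both") {
  ids <- seq_along(.registry_rows)
  stats::setNames(
    lapply(ids, get_model, d_m = d_m, d_ns = d_ns, mobility = mobility),
    as.character(ids))
}

#' Registry models with identical rate definitions
#'
#' Several registry rows repeat the same five rate functions; such models
#' are indistinguishable dynamically and always yield identical cluster
#' patterns.  Pattern matching resolves ties by the lowest model id, so a
#' query pattern generated from one member of a class is reported under
#' the class's smallest id.
#'
#' @return A list of integer vectors, one per equivalence class of
#'   duplicated models (singleton classes omitted).
#' @export
model_equivalence_classes <- function() {
  key <- vapply(.registry_rows, function(r) {
    paste(vapply(r, function(z) if (is.character(z)) z else format(z, digits = 17),
                 character(1)), collapse = "|")
  }, character(1))
  classes <- split(seq_along(key), key)
  classes <- classes[vapply(classes, length, integer(1)) > 1L]
  classes <- lapply(classes, as.integer)
  unname(classes[order(vapply(classes, min, integer(1)))])
}

#' Write a model registry to a plain-text file
#'
#' One block per model, `key = value` lines.  Rates are stored by their
#' stable expression id; constants as `const <value>`, caps as a
#' `cap=<value>` suffix.  Custom closures are not serialisable.
#'
#' @param models list of `rd_model` objects (e.g. [model_registry()]).
#' @param path output file.
#' @export
write_model_registry <- function(models, path) {
  enc_rate <- function(r) {
    if (r$expression_id == "custom") {
      stop("custom rates cannot be serialised", call. = FALSE)
    }
    s <- r$expression_id
    if (s == "const") s <- paste(s, format(r$value, digits = 17))
    if (!is.null(r$cap)) s <- paste0(s, " cap=", format(r$cap, digits = 17))
    s
  }
  lines <- c("# rdgep model registry")
  for (m in models) {
    lines <- c(lines, "",
               paste0("[model ", m$model_id, "]"),
               paste("alpha_m =", enc_rate(m$alpha_m)),
               paste("beta_m =", enc_rate(m$beta_m)),
               paste("alpha_ns =", enc_rate(m$alpha_ns)),
               paste("beta_ns =", enc_rate(m$beta_ns)),
               paste("theta =", enc_rate(m$theta)),
               paste("d_m =", format(m$d_m, digits = 17)),
               paste("d_ns =", format(m$d_ns, digits = 17)),
               paste("mobility =", m$mobility))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a model registry written by [write_model_registry()]
#'
#' @param path input file.
#' @return A named list of `rd_model` objects.
#' @export
read_model_registry <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  dec_rate <- function(s) {
    toks <- strsplit(trimws(s), "\\s+")[[1]]
    id <- toks[1]
    value <- NULL
    cap <- NULL
    for (tok in toks[-1]) {
      if (startsWith(tok, "cap=")) {
        cap <- as.numeric(sub("^cap=", "", tok))
      } else {
        value <- as.numeric(tok)
      }
    }
    rate_spec(id, value = value, cap = cap)
  }
  out <- list()
  cur <- NULL
  cur_id <- NA_integer_
  flush <- function(cur, cur_id, out) {
    if (is.null(cur)) return(out)
    m <- model_spec(dec_rate(cur[["alpha_m"]]), dec_rate(cur[["beta_m"]]),
                    dec_rate(cur[["alpha_ns"]]), dec_rate(cur[["beta_ns"]]),
                    dec_rate(cur[["theta"]]),
                    d_m = as.numeric(cur[["d_m"]]),
                    d_ns = as.numeric(cur[["d_ns"]]),
                    mobility = cur[["mobility"]],
                    model_id = cur_id)
    out[[as.character(cur_id)]] <- m
    out
  }
  for (ln in lines) {
    if (grepl("^\\[model\\s+\\d+\\]$", ln)) {
      out <- flush(cur, cur_id, out)
      cur <- list()
      cur_id <- as.integer(gsub("\\D", "", ln))
    } else if (grepl("=", ln, fixed = TRUE)) {
      if (is.null(cur)) stop("malformed registry file: key outside a block",
                             call. = FALSE)
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      key <- trimws(kv[1])
      val <- trimws(paste(kv[-1], collapse = "="))
      cur[[key]] <- val
    } else {
      stop("malformed registry line: ", ln, call. = FALSE)
    }
  }
  flush(cur, cur_id, out)
}
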