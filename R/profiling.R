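#' Trapezoidal total abundance of a field
#'
#' Domain integral of the concentration field by tensor-product
#' trapezoidal quadrature; exact for fields linear along each axis.
#'
#' @param f field array.
#' @param grid the field's [make_grid()].
#' @return A scalar.
#' @examples
#' g <- make_grid(2, 21)
#' total_abundance(array(3, c(21, 21)), g)  # 3 on the unit square
#' @export
total_abundance <- function(f, grid) {
  stopifnot(inherits(grid, "rd_grid"))
  .check_field(f, grid)
  sum(f * .trapz_weights(grid))
}

#' Four-cluster normalized abundance scale
#'
#' The 0--12 normalized abundance axis is partitioned into four cluster
#' intervals with small gaps between consecutive clusters:
#' C1 `[0, 2.265458]`, C2 `[2.267602, 4.383277]`,
#' C3 `[4.383667, 7.001413]`, C4 `[7.002388, 12]`.
#' Cluster assignment is made total on `[0, 12]` by cutting each
#' inter-cluster gap at its midpoint; the three derived thresholds are
#' exposed as `gap_thresholds`.
#'
#' @param bounds optional 4 x 2 matrix of `(lower, upper)` interval
#'   bounds overriding the default scale.
#' @return An object of class `rd_scale` with elements `bounds`
#'   (4 x 2 matrix) and `gap_thresholds` (length 3).
#' @export
cluster_scale <- function(bounds = NULL) {
  if (is.null(bounds)) {
    bounds <- cbind(lower = c(0, 2.267602, 4.383667, 7.002388),
                    upper = c(2.265458, 4.383277, 7.001413, 12))
  } else {
    bounds <- as.matrix(bounds)
    if (nrow(bounds) != 4L || ncol(bounds) != 2L) {
      stop("'bounds' must be a 4 x 2 matrix", call. = FALSE)
    }
    colnames(bounds) <- c("lower", "upper")
  }
  if (any(diff(as.vector(t(bounds))) <= 0)) {
    stop("cluster intervals must be ordered and disjoint", call. = FALSE)
  }
  thr <- (bounds[1:3, 2] + bounds[2:4, 1]) / 2
  rownames(bounds) <- paste0("C", 1:4)
  structure(list(bounds = bounds, gap_thresholds = unname(thr)),
            class = "rd_scale")
}

#' @export
print.rd_scale <- function(x, ...) {
  cat("<rd_scale> four-cluster normalized abundance scale\n")
  print(x$bounds)
  cat("gap thresholds:", paste(format(x$gap_thresholds), collapse = ", "), "\n")
  invisible(x)
}

#' Normalize an abundance series
#'
#' `minmax12` maps the series affinely so its minimum lands on 0 and its
#' maximum on 12 (the span of the cluster scale); `identity` returns the
#' input unchanged for pre-scaled series.
#'
#' @param series non-empty numeric vector.
#' @param mode `"minmax12"` or `"identity"`.
#' @return Numeric vector of the same length.
#' @export
normalize_series <- function(series, mode = c("minmax12", "identity")) {
  mode <- match.arg(mode)
  if (!length(series)) stop("'series' must be non-empty", call. = FALSE)
  if (!all(is.finite(series))) stop("'series' must be finite", call. = FALSE)
  if (mode == "identity") return(series)
  rng <- range(series)
  if (rng[2] <= rng[1]) {
    stop("cannot min-max normalize a constant series", call. = FALSE)
  }
  (series - rng[1]) / (rng[2] - rng[1]) * 12
}

#' Assign normalized abundances to clusters
#'
#' Each value on the 0--12 normalized scale gets the index of the cluster
#' interval containing it; values falling inside an inter-cluster gap are
#' cut at the gap midpoint (the midpoint itself belongs to the upper
#' cluster).  Values outside `[0, 12]` are clamped; a warning is raised
#' if they lie more than `1e-6` outside.
#'
#' @param value numeric vector of normalized abundances.
#' @param scale an [cluster_scale()].
#' @return Integer vector of cluster indices in 1--4.
#' @examples
#' assign_cluster(c(3, 5), cluster_scale())  # 2, 3
#' @export
assign_cluster <- function(value, scale = cluster_scale()) {
  stopifnot(inherits(scale, "rd_scale"))
  if (any(is.na(value))) stop("cluster assignment of NA/NaN", call. = FALSE)
  lo <- scale$bounds[1, 1]
  hi <- scale$bounds[4, 2]
  if (any(value < lo - 1e-6) || any(value > hi + 1e-6)) {
    warning("values outside [", lo, ", ", hi, "] clamped", call. = FALSE)
  }
  value <- pmin(pmax(value, lo), hi)
  as.integer(findInterval(value, scale$gap_thresholds) + 1L)
}

#' Cluster pattern of a gene across conditions
#'
#' Constructs a pattern record: one cluster index (1--4) per condition.
#' The default conditions are the non-treatment state and the
#' long-exposure treatment states measured 1, 2, and 4 hours post
#' treatment (`NT`, `LE1h`, `LE2h`, `LE4h`).
#'
#' @param clusters integer vector of cluster indices, one per condition.
#' @param gene_label label of the gene (or synthetic source).
#' @param conditions condition names; default the four standard ones.
#' @return An object of class `rd_pattern`.
#' @export
pattern_record <- function(clusters, gene_label = NA_character_,
                           conditions = c("NT", "LE1h", "LE2h", "LE4h")) {
  clusters <- as.integer(clusters)
  if (length(clusters) != length(conditions)) {
    stop("one cluster index per condition required", call. = FALSE)
  }
  if (length(clusters) != 4L) {
    stop("a pattern record has exactly 4 conditions", call. = FALSE)
  }
  if (any(is.na(clusters)) || any(clusters < 1L) || any(clusters > 4L)) {
    stop("cluster indices must be in 1..4", call. = FALSE)
  }
  structure(list(gene_label = gene_label,
                 clusters = stats::setNames(clusters, conditions)),
            class = "rd_pattern")
}

#' @export
print.rd_pattern <- function(x, ...) {
  cat("<rd_pattern> ", if (is.na(x$gene_label)) "?" else x$gene_label, ": ",
      paste(names(x$clusters), x$clusters, sep = "=", collapse = " "),
      "\n", sep = "")
  invisible(x)
}

#' Extract the cluster pattern of a simulated trajectory
#'
#' Normalizes the total mRNA abundance series over the trajectory's
#' snapshot times, then assigns a cluster per condition according to the
#' condition-to-time mapping (default: `NT` at t = 0, `LE1h` at t = 1,
#' `LE2h` at t = 2, `LE4h` at t = 4).
#'
#' @param traj an `rd_trajectory` from [simulate_pde()].
#' @param scale an [cluster_scale()].
#' @param condition_map named numeric vector mapping condition names to
#'   snapshot times.
#' @param mode normalization mode, see [normalize_series()].
#' @param gene_label label for the resulting record.
#' @return An `rd_pattern`.
#' @export
cluster_pattern <- function(traj, scale = cluster_scale(),
                            condition_map = c(NT = 0, LE1h = 1,
                                              LE2h = 2, LE4h = 4),
                            mode = c("minmax12", "identity"),
                            gene_label = NA_character_) {
  stopifnot(inherits(traj, "rd_trajectory"))
  mode <- match.arg(mode)
  normed <- normalize_series(traj$abundance_m, mode)
  idx <- vapply(condition_map, function(tt) {
    i <- which(abs(traj$times - tt) < 1e-9)
    if (!length(i)) {
      stop("condition time t = ", tt, " is not among the trajectory's ",
           "snapshot times (", paste(traj$times, collapse = ", "), ")",
           call. = FALSE)
    }
    i[1]
  }, integer(1))
  pattern_record(assign_cluster(normed[idx], scale),
                 gene_label = gene_label,
                 conditions = names(condition_map))
}

#' Match a cluster pattern against a model pattern library
#'
#' The distance between two patterns is the L1 sum of absolute
#' differences of cluster indices over conditions.  The minimal-distance
#' model wins; ties are broken by the lowest model id.  A distance of 0
#' is a *complete* fit, any positive distance a *best* fit.  Models tied
#' with the winner or within distance + 1 are listed as runner-ups.
#'
#' @param pattern an `rd_pattern` (the gene's observed pattern).
#' @param library named list of `rd_pattern`s, one per model id (names
#'   are the ids), e.g. from [pattern_library()].
#' @return An `rd_match`: list with `gene_label`, `model_id`,
#'   `fit_kind` (`"complete"` or `"best"`), `distance`, `runner_ups`,
#'   and the full `distances` vector.
#' @export
match_models <- function(pattern, library) {
  stopifnot(inherits(pattern, "rd_pattern"))
  if (!length(library)) stop("empty pattern library", call. = FALSE)
  conds <- names(pattern$clusters)
  dists <- vapply(library, function(p) {
    stopifnot(inherits(p, "rd_pattern"))
    if (!identical(names(p$clusters), conds)) {
      stop("library pattern conditions do not match the query pattern",
           call. = FALSE)
    }
    sum(abs(p$clusters - pattern$clusters))
  }, numeric(1))
  ids <- as.integer(names(library))
  if (any(is.na(ids))) ids <- seq_along(library)
  ord <- order(dists, ids)
  best <- ord[1]
  best_dist <- dists[best]
  runner_ups <- ids[dists <= best_dist + 1 & ids != ids[best]]
  structure(list(gene_label = pattern$gene_label,
                 model_id = ids[best],
                 fit_kind = if (best_dist == 0) "complete" else "best",
                 distance = as.integer(best_dist),
                 runner_ups = sort(runner_ups),
                 distances = stats::setNames(as.integer(dists), ids)),
            class = "rd_match")
}

#' @export
print.rd_match <- function(x, ...) {
  cat("<rd_match> ", if (is.na(x$gene_label)) "?" else x$gene_label,
      " -> model ", x$model_id, " (", x$fit_kind, " fit, distance ",
      x$distance, ")\n", sep = "")
  if (length(x$runner_ups)) {
    cat("  runner-ups:", paste(x$runner_ups, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Read / write pattern tables
#'
#' Tab-separated tables with header columns `gene_label`, `NT`, `LE1h`,
#' `LE2h`, `LE4h`, and optionally `model` (the matched model id, `NA`
#' allowed).
#'
#' @param path file path.
#' @return A data frame ([read_pattern_table()]).
#' @export
read_pattern_table <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("gene_label", "NT", "LE1h", "LE2h", "LE4h")
  if (!all(need %in% names(df))) {
    stop("pattern table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  for (cn in c("NT", "LE1h", "LE2h", "LE4h")) {
    df[[cn]] <- as.integer(df[[cn]])
    if (any(is.na(df[[cn]])) || any(df[[cn]] < 1L) || any(df[[cn]] > 4L)) {
      stop("cluster indices in column ", cn, " must be in 1..4", call. = FALSE)
    }
  }
  if ("model" %in% names(df)) df$model <- as.integer(df$model)
  df
}

#' @rdname read_pattern_table
#' @param df data frame in the pattern-table layout.
#' @export
write_pattern_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Convert pattern-table rows to pattern records
#'
#' @param df a pattern-table data frame (see [read_pattern_table()]).
#' @return A list of `rd_pattern` objects.
#' @export
as_pattern_records <- function(df) {
  lapply(seq_len(nrow(df)), function(i) {
    pattern_record(unlist(df[i, c("NT", "LE1h", "LE2h", "LE4h")]),
                   gene_label = df$gene_label[i])
  })
}

#' Match every row of a pattern table against a model library
#'
#' @param df pattern-table data frame.
#' @param library model pattern library (see [match_models()]).
#' @return A data frame with one row per gene: `gene_label`, `model_id`,
#'   `fit_kind`, `distance`, `runner_ups` (comma-separated).
#' @export
match_pattern_table <- function(df, library) {
  recs <- as_pattern_records(df)
  rows <- lapply(recs, function(p) {
    mm <- match_models(p, library)
    data.frame(gene_label = mm$gene_label,
               model_id = mm$model_id,
               fit_kind = mm$fit_kind,
               distance = mm$distance,
               runner_ups = paste(mm$runner_ups, collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write a match report as JSON
#'
#' @param report data frame from [match_pattern_table()], or a single
#'   `rd_match`.
#' @param path output file.
#' @export
write_match_report <- function(report, path) {
  if (inherits(report, "rd_match")) {
    report <- report[c("gene_label", "model_id", "fit_kind", "distance",
                       "runner_ups")]
  }
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
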