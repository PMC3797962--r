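#' Flatten an episode or primitive rollout into a trajectory table
#'
#' Column schema: `step`, `time`, then per-dimension state columns
#' (`y_d`/`ydot_d` or `q_d`/`qd_d`), control/excitation columns, `phase`
#' and (walker) `impact`.
#'
#' @param x An `"episode_result"` or `"primitive_rollout"`.
#' @return A plain data frame with one row per recorded step.
#' @export
trajectory_frame <- function(x) {
  if (inherits(x, "primitive_rollout")) {
    D <- ncol(x$y)
    df <- data.frame(step = seq_along(x$time), time = x$time)
    for (d in seq_len(D)) df[[paste0("y_", d)]] <- x$y[, d]
    for (d in seq_len(D)) df[[paste0("ydot_", d)]] <- x$yd[, d]
    df$phase <- x$phase
    return(df)
  }
  stopifnot(inherits(x, "episode_result"))
  if (x$task_type == "pointmass") {
    T <- length(x$y)
    data.frame(step = seq_len(T), time = x$time,
               y_1 = x$y, ydot_1 = x$yd,
               u_1 = c(x$u, NA_real_), phase = x$phase)
  } else if (x$task_type == "walker") {
    T <- nrow(x$q)
    df <- data.frame(step = seq_len(T), time = x$time)
    for (d in 1:5) df[[paste0("q_", d)]] <- x$q[, d]
    for (d in 1:5) df[[paste0("qd_", d)]] <- x$qd[, d]
    for (d in 1:4) df[[paste0("u_", d)]] <- x$u[, d]
    df$phase <- x$phase
    df$impact <- as.numeric(x$impact)
    df
  } else {
    T <- nrow(x$q)
    df <- data.frame(step = seq_len(T), time = x$time)
    for (d in 1:2) df[[paste0("q_", d)]] <- x$q[, d]
    for (d in 1:2) df[[paste0("qd_", d)]] <- x$qd[, d]
    df$marker_x <- x$marker[, 1]; df$marker_y <- x$marker[, 2]
    for (d in seq_len(ncol(x$excitation))) {
      df[[paste0("excitation_", d)]] <- x$excitation[, d]
    }
    df$phase <- x$phase
    df
  }
}

#' Write a trajectory table to CSV
#'
#' Values are written with 17 significant digits so that a write/read
#' round trip is lossless for doubles.
#'
#' @param x An episode, primitive rollout, or trajectory data frame.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_trajectory_csv <- function(x, path) {
  df <- if (is.data.frame(x)) x else trajectory_frame(x)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(names(df), collapse = ","), con)
  if (nrow(df) > 0) {
    cols <- lapply(df, function(col) {
      out <- formatC(col, digits = 17, format = "g")
      out[is.na(col)] <- "NA"
      out
    })
    writeLines(do.call(paste, c(cols, sep = ",")), con)
  }
  invisible(path)
}

#' Read a trajectory table written by [write_trajectory_csv()]
#'
#' Malformed rows (wrong field count, non-numeric payload) raise an error
#' naming the offending line.
#'
#' @param path CSV file path.
#' @return Data frame with numeric columns.
#' @export
read_trajectory_csv <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0) stop("empty trajectory file: ", path)
  header <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
  n_col <- length(header)
  body <- lines[-1]
  out <- vector("list", n_col)
  parsed <- matrix(NA_real_, length(body), n_col)
  for (i in seq_along(body)) {
    fields <- strsplit(body[i], ",", fixed = TRUE)[[1]]
    if (length(fields) != n_col) {
      stop(sprintf("parse error at line %d of %s: expected %d fields, found %d",
                   i + 1L, path, n_col, length(fields)))
    }
    vals <- suppressWarnings(as.numeric(fields))
    bad <- is.na(vals) & fields != "NA"
    if (any(bad)) {
      stop(sprintf("parse error at line %d of %s: non-numeric field '%s'",
                   i + 1L, path, fields[which(bad)[1]]))
    }
    parsed[i, ] <- vals
  }
  df <- as.data.frame(parsed)
  names(df) <- header
  df
}

#' Write a learning curve to CSV
#'
#' Columns: `evaluation`, `best_cost`, `current_cost`.
#'
#' @param x A `"synergy_fit"` or its `curve` data frame.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_learning_curve_csv <- function(x, path) {
  curve <- if (inherits(x, "synergy_fit")) x$curve else x
  df <- data.frame(evaluation = curve$evaluation,
                   best_cost = curve$best_cost,
                   current_cost = curve$current_cost)
  write_trajectory_csv(df, path)
}

#' Serialize a learned policy (or any configuration list) to JSON
#'
#' The human-readable key-tree config format of the package; numbers are
#' written at full precision, so `read_config(write_config(x))` round
#' trips.
#'
#' @param x A plain (possibly nested) list of numerics/strings/logicals.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_config <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Save a learned policy for later reuse
#'
#' Stores the flat policy vector together with the layout description so
#' the fit can be reloaded (e.g. for frozen-synergy generalization runs).
#'
#' @param fit A `"synergy_fit"`.
#' @param path Output JSON path.
#' @return The path, invisibly.
#' @export
save_policy <- function(fit, path) {
  stopifnot(inherits(fit, "synergy_fit"))
  lay <- fit$layout
  write_config(list(
    layout = list(K = lay$K, M = lay$M, N = lay$N, D = lay$D,
                  scheme = lay$scheme, learn_shifts = lay$learn_shifts,
                  kind = lay$kind, free_shapes = lay$free_shapes),
    theta = fit$par, value = fit$value, seed = fit$seed,
    frozen_shapes = fit$frozen_shapes,
    shapes = lapply(fit$shapes, function(sh) list(
      kind = sh$kind, N = sh$N, D = sh$D,
      amplitudes = as.vector(sh$amplitudes), means = as.vector(sh$means),
      bandwidths = as.vector(sh$bandwidths)))), path)
}

#' Load a policy saved with [save_policy()]
#'
#' @param path JSON path.
#' @return List with `layout` ([parameter_layout()]), `theta`, `shapes`,
#'   `coeffs`.
#' @export
load_policy <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  lay <- cfg$layout
  layout <- parameter_layout(lay$K, lay$M, lay$N, lay$D, lay$scheme,
                             lay$learn_shifts, lay$kind, lay$free_shapes)
  shapes <- lapply(cfg$shapes, function(sh) {
    synergy_shape(sh$kind,
                  matrix(sh$amplitudes, sh$N, sh$D),
                  matrix(sh$means, sh$N, sh$D),
                  matrix(sh$bandwidths, sh$N, sh$D))
  })
  dec <- unpack_policy(as.numeric(cfg$theta), layout, shapes = shapes)
  list(layout = layout, theta = as.numeric(cfg$theta),
       shapes = dec$shapes, coeffs = dec$coeffs)
}
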