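# Plain-text interchange: marginal sample CSVs (x1, x2, ...), trajectory
# CSVs (path_id, step, t, then one column per state coordinate).

#' Write / read marginal samples as CSV
#'
#' Columns are named `x1`, `x2`, ... regardless of the originating system
#' (for Morris-Lecar marginals `x1` = v, `x2` = w).
#'
#' @param samples n x d matrix.
#' @param path File path.
#' @export
write_marginal_csv <- function(samples, path) {
  X <- as_sample_matrix(samples, "samples")
  colnames(X) <- paste0("x", seq_len(ncol(X)))
  utils::write.csv(as.data.frame(X), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_marginal_csv
#' @return A numeric matrix.
#' @export
read_marginal_csv <- function(path) {
  as_sample_matrix(utils::read.csv(path), "csv samples")
}

#' Write / read a trajectory ensemble as CSV
#'
#' Long format with columns `path_id`, `step`, `t`, then the state
#' coordinates (named by `state_names`, default `v`, `w` for 2-D and
#' `x1`, ... otherwise).
#'
#' @param ens A [trajectory_ensemble].
#' @param path File path.
#' @param state_names Optional column names for the state coordinates.
#' @export
write_trajectory_csv <- function(ens, path, state_names = NULL) {
  stopifnot(inherits(ens, "trajectory_ensemble"))
  dm <- dim(ens$states)
  if (is.null(state_names))
    state_names <- if (dm[3] == 2L) c("v", "w") else paste0("x", seq_len(dm[3]))
  df <- data.frame(path_id = rep(seq_len(dm[1]), times = dm[2]),
                   step = rep(seq_len(dm[2]) - 1L, each = dm[1]),
                   t = rep(ens$times, each = dm[1]))
  for (j in seq_len(dm[3])) df[[state_names[j]]] <- as.numeric(ens$states[, , j])
  df <- df[order(df$path_id, df$step), ]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @return A [trajectory_ensemble].
#' @export
read_trajectory_csv <- function(path) {
  df <- utils::read.csv(path)
  state_cols <- setdiff(names(df), c("path_id", "step", "t"))
  paths <- sort(unique(df$path_id))
  steps <- sort(unique(df$step))
  states <- array(NA_real_, c(length(paths), length(steps), length(state_cols)))
  df <- df[order(df$path_id, df$step), ]
  for (j in seq_along(state_cols))
    states[, , j] <- matrix(df[[state_cols[j]]], length(paths),
                            length(steps), byrow = TRUE)
  times <- df$t[df$path_id == paths[1]][order(df$step[df$path_id == paths[1]])]
  trajectory_ensemble(states, times)
}
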