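#' Snapshot dataset of high-dimensional states with derivatives
#'
#' @param X \eqn{m \times n} matrix of snapshots (rows are time samples).
#' @param dX Matching matrix of first time derivatives.
#' @param ddX Optional matching matrix of second time derivatives (required
#'   by second-order models).
#' @param times Optional length-m time stamps.
#' @param traj_id Optional length-m integer labels grouping rows into
#'   trajectories (used for trajectory-wise validation splits and simulation
#'   metrics).
#' @param metadata Optional list echoing the generator name and its config.
#' @return An object of class \code{snapshot_dataset}.
#' @export
snapshot_dataset <- function(X, dX, ddX = NULL, times = NULL, traj_id = NULL,
                             metadata = list()) {
  X <- as.matrix(X); dX <- as.matrix(dX)
  stopifnot(all(dim(dX) == dim(X)))
  if (!is.null(ddX)) {
    ddX <- as.matrix(ddX)
    stopifnot(all(dim(ddX) == dim(X)))
  }
  if (!is.null(times)) stopifnot(length(times) == nrow(X))
  if (!is.null(traj_id)) stopifnot(length(traj_id) == nrow(X))
  structure(list(X = X, dX = dX, ddX = ddX, times = times,
                 traj_id = traj_id, metadata = metadata),
            class = "snapshot_dataset")
}

#' @export
print.snapshot_dataset <- function(x, ...) {
  cat(sprintf("<snapshot_dataset> m = %d samples, n = %d dims%s%s\n",
              nrow(x$X), ncol(x$X),
              if (!is.null(x$ddX)) ", with ddX" else "",
              if (!is.null(x$traj_id))
                sprintf(", %d trajectories", length(unique(x$traj_id))) else ""))
  if (!is.null(x$metadata$generator)) {
    cat(sprintf("  generator: %s\n", x$metadata$generator))
  }
  invisible(x)
}

# row subset preserving all parallel fields
dataset_slice <- function(ds, idx) {
  snapshot_dataset(
    ds$X[idx, , drop = FALSE], ds$dX[idx, , drop = FALSE],
    if (!is.null(ds$ddX)) ds$ddX[idx, , drop = FALSE],
    if (!is.null(ds$times)) ds$times[idx],
    if (!is.null(ds$traj_id)) ds$traj_id[idx],
    ds$metadata
  )
}

# split row indices into train/validation; whole trajectories go to one side
# when trajectory labels exist (avoids temporal leakage)
dataset_split <- function(ds, validation_fraction) {
  m <- nrow(ds$X)
  if (validation_fraction <= 0) {
    return(list(train = seq_len(m), val = integer(0)))
  }
  if (!is.null(ds$traj_id)) {
    ids <- unique(ds$traj_id)
    n_val <- max(1L, floor(length(ids) * validation_fraction))
    val_ids <- sample(ids, n_val)
    val <- which(ds$traj_id %in% val_ids)
  } else {
    n_val <- max(1L, floor(m * validation_fraction))
    val <- sample.int(m, n_val)
  }
  list(train = setdiff(seq_len(m), val), val = sort(val))
}

#' Standardize a snapshot dataset feature-wise
#'
#' Centers each measurement coordinate and scales it to unit variance,
#' applying the same scale to the derivative matrices (derivatives are not
#' centered: d/dt of an affine map drops the offset). Standardizing the
#' inputs is the usual preprocessing for network training when raw features
#' span orders of magnitude; supply the \code{center}/\code{scale} of the
#' training set to transform a test set consistently.
#'
#' @param ds A \code{\link{snapshot_dataset}}.
#' @param center,scale Optional per-feature vectors (defaults: column means
#'   and standard deviations of \code{ds$X}; zero deviations become 1).
#' @return A \code{snapshot_dataset} whose metadata records \code{center}
#'   and \code{scale}.
#' @export
standardize_dataset <- function(ds, center = NULL, scale = NULL) {
  if (is.null(center)) center <- colMeans(ds$X)
  if (is.null(scale)) {
    scale <- apply(ds$X, 2, stats::sd)
    scale[scale == 0] <- 1
  }
  meta <- ds$metadata
  meta$center <- center
  meta$scale <- scale
  snapshot_dataset(
    sweep(sweep(ds$X, 2, center), 2, scale, "/"),
    sweep(ds$dX, 2, scale, "/"),
    if (!is.null(ds$ddX)) sweep(ds$ddX, 2, scale, "/"),
    ds$times, ds$traj_id, meta
  )
}
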