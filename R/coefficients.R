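#' Sparse coefficient matrix for latent dynamics
#'
#' Holds the \eqn{p \times d} coefficient matrix \eqn{\Xi = [\xi_1, \ldots,
#' \xi_d]} together with a binary mask of active entries. Masked-out entries
#' are exactly zero; the mask is what sequential thresholding prunes during
#' training.
#'
#' @param values Numeric \eqn{p \times d} matrix.
#' @param mask Binary matrix of the same shape; defaults to
#'   \code{values != 0}.
#' @param terms Optional character row labels (canonical term strings).
#' @return An object of class \code{coefficient_matrix}.
#' @export
coefficient_matrix <- function(values, mask = NULL, terms = NULL) {
  values <- as.matrix(values)
  if (is.null(mask)) mask <- (values != 0) * 1
  mask <- as.matrix(mask) * 1
  stopifnot(all(dim(mask) == dim(values)))
  values[mask == 0] <- 0
  if (!is.null(terms)) {
    stopifnot(length(terms) == nrow(values))
    rownames(values) <- rownames(mask) <- terms
  }
  colnames(values) <- colnames(mask) <- paste0("z", seq_len(ncol(values)))
  structure(list(values = values, mask = mask), class = "coefficient_matrix")
}

#' Number of active (unmasked) coefficients
#'
#' @param xi A \code{\link{coefficient_matrix}}.
#' @return Integer count of active entries, e.g. 7 for the Lorenz system.
#' @export
active_term_count <- function(xi) {
  as.integer(sum(xi$mask != 0))
}

#' @export
print.coefficient_matrix <- function(x, ...) {
  cat(sprintf("<coefficient_matrix> %d x %d, %d active terms\n",
              nrow(x$values), ncol(x$values), active_term_count(x)))
  act <- which(x$mask != 0, arr.ind = TRUE)
  if (nrow(act) > 0) {
    tn <- rownames(x$values)
    if (is.null(tn)) tn <- paste0("term", seq_len(nrow(x$values)))
    for (i in seq_len(nrow(act))) {
      cat(sprintf("  d%s/dt ~ %+.4g * %s\n", colnames(x$values)[act[i, 2]],
                  x$values[act[i, 1], act[i, 2]], tn[act[i, 1]]))
    }
  }
  invisible(x)
}

#' Tidy a coefficient matrix into a long table
#'
#' @param x A \code{\link{coefficient_matrix}}.
#' @param ... Unused.
#' @return A tibble with columns \code{term}, \code{coordinate},
#'   \code{value}, \code{active}.
#' @importFrom generics tidy
#' @export
tidy.coefficient_matrix <- function(x, ...) {
  tn <- rownames(x$values)
  if (is.null(tn)) tn <- paste0("term", seq_len(nrow(x$values)))
  tibble::tibble(
    term = rep(tn, times = ncol(x$values)),
    coordinate = rep(colnames(x$values), each = nrow(x$values)),
    value = as.vector(x$values),
    active = as.vector(x$mask) != 0
  )
}

#' Write / read a coefficient table as CSV
#'
#' Rows are labeled by canonical term strings, columns by latent coordinate;
#' a parallel set of \code{mask_*} columns records the active support.
#'
#' @param xi A \code{\link{coefficient_matrix}}.
#' @param path File path.
#' @return \code{write_coefficients} returns \code{path} invisibly;
#'   \code{read_coefficients} returns a \code{coefficient_matrix}.
#' @export
write_coefficients <- function(xi, path) {
  d <- ncol(xi$values)
  df <- data.frame(term = rownames(xi$values), check.names = FALSE)
  if (is.null(df$term)) df$term <- paste0("term", seq_len(nrow(xi$values)))
  for (j in seq_len(d)) df[[paste0("z", j)]] <- xi$values[, j]
  for (j in seq_len(d)) df[[paste0("mask_z", j)]] <- xi$mask[, j]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_coefficients
#' @export
read_coefficients <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  vcols <- grep("^z[0-9]+$", names(df), value = TRUE)
  mcols <- grep("^mask_z[0-9]+$", names(df), value = TRUE)
  coefficient_matrix(as.matrix(df[vcols]), as.matrix(df[mcols]),
                     terms = df$term)
}
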