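#' Plot a latent trajectory
#'
#' Coordinates against time, one facet per latent coordinate.
#'
#' @param object A \code{\link{latent_trajectory}}.
#' @param ... Unused.
#' @return A ggplot object.
#' @importFrom ggplot2 autoplot
#' @export
autoplot.latent_trajectory <- function(object, ...) {
  d <- ncol(object$z)
  df <- data.frame(
    time = rep(object$times, times = d),
    coordinate = rep(paste0("z", seq_len(d)), each = length(object$times)),
    value = as.vector(object$z)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~coordinate, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "time", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a coefficient matrix as a term-by-coordinate heat map
#'
#' @param object A \code{\link{coefficient_matrix}}.
#' @param ... Unused.
#' @return A ggplot object; inactive entries are blank.
#' @export
autoplot.coefficient_matrix <- function(object, ...) {
  df <- tidy(object)
  df$value[!df$active] <- NA
  df$term <- factor(df$term, levels = rev(unique(df$term)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$coordinate, y = .data$term,
                                   fill = .data$value)) +
    ggplot2::geom_tile(color = "grey80") +
    ggplot2::scale_fill_gradient2(na.value = "white") +
    ggplot2::labs(x = NULL, y = NULL, fill = "coef") +
    ggplot2::theme_minimal()
}

#' Plot training history
#'
#' Loss terms over epochs on a log scale, split by train/validation.
#'
#' @param object A \code{sindy_ae_model}.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sindy_ae_model <- function(object, ...) {
  h <- object$history
  if (is.null(h)) stop("model has no training history", call. = FALSE)
  long <- stats::reshape(
    h[, c("epoch", "split", "recon", "sindy_z", "sindy_x", "total")],
    direction = "long",
    varying = c("recon", "sindy_z", "sindy_x", "total"),
    v.names = "value", timevar = "term",
    times = c("recon", "sindy_z", "sindy_x", "total")
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value,
                                     color = .data$term,
                                     linetype = .data$split)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "epoch", y = "loss (log scale)") +
    ggplot2::theme_minimal()
}
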