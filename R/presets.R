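#' Shipped per-benchmark training configurations
#'
#' Tuned defaults for the three synthetic benchmarks and the linear toy
#' problem. These are package choices (library order, architecture, loss
#' weights, threshold schedule) selected so the discovered models printed by
#' the corresponding generators are representable; they are not published
#' hyperparameter values. The \code{scale} argument multiplies the epoch
#' budget: \code{scale = 1} is the package's full setting, smaller values
#' give proportionally shorter runs for quick experiments.
#'
#' @param benchmark One of \code{"linear_toy"}, \code{"lorenz"},
#'   \code{"rd"}, \code{"pendulum"}.
#' @param seed Base seed.
#' @param scale Epoch multiplier in (0, 1].
#' @return A \code{\link{training_config}}.
#' @export
preset_config <- function(benchmark = c("linear_toy", "lorenz", "rd",
                                        "pendulum"),
                          seed = 0L, scale = 1) {
  benchmark <- match.arg(benchmark)
  stopifnot(scale > 0, scale <= 1)
  ep <- function(e) max(1L, as.integer(round(e * scale)))
  switch(
    benchmark,
    linear_toy = training_config(
      epochs = ep(2000), batch_size = 256, learning_rate = 3e-3,
      threshold = 0.1, threshold_interval = 500, refinement_epochs = ep(200),
      seed = seed, validation_fraction = 0.2,
      weights = loss_weights(1e-2, 1e-3, 1e-4),
      spec = library_spec(2, poly_order = 2),
      hidden_widths = integer(0), activation = "linear",
      history_interval = 100
    ),
    lorenz = training_config(
      epochs = ep(10000), batch_size = 1024, learning_rate = 1e-3,
      threshold = 0.1, threshold_interval = 500,
      refinement_epochs = ep(1000), seed = seed,
      validation_fraction = 0.2,
      weights = loss_weights(5e-4, 5e-5, 1e-5),
      spec = library_spec(3, poly_order = 3),
      hidden_widths = c(64, 32), activation = "sigmoid",
      history_interval = 100
    ),
    rd = training_config(
      epochs = ep(3000), batch_size = 1024, learning_rate = 1e-3,
      threshold = 0.1, threshold_interval = 500, refinement_epochs = ep(500),
      seed = seed, validation_fraction = 0.2,
      weights = loss_weights(5e-4, 5e-5, 1e-5),
      spec = library_spec(2, poly_order = 3, include_sine = TRUE),
      hidden_widths = 128, activation = "sigmoid",
      history_interval = 100
    ),
    pendulum = training_config(
      epochs = ep(5000), batch_size = 1024, learning_rate = 1e-3,
      threshold = 0.1, threshold_interval = 500, refinement_epochs = ep(500),
      seed = seed, validation_fraction = 0.2,
      weights = loss_weights(5e-4, 5e-5, 1e-5),
      spec = library_spec(1, poly_order = 3, include_sine = TRUE,
                          model_order = 2),
      hidden_widths = c(128, 64), activation = "sigmoid",
      history_interval = 100
    )
  )
}
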