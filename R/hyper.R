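#' Hyperparameter search space for network tuning
#'
#' Five dimensions: learning rate on a log10 scale in [1e-5, 1e-2], batch
#' size in [16, 128] (snapped to {16, 32, 64, 128}), dropout in [0.2, 0.7],
#' kernel size in [3, 5] (snapped to {3, 5}), and epochs in [50, 200]
#' (rounded to an integer).
#'
#' @return A \code{\link{search_space}}.
#' @export
hyper_space <- function() {
  search_space(lower = c(1e-5, 16, 0.2, 3, 50),
               upper = c(1e-2, 128, 0.7, 5, 200),
               scale = c("log10", "linear", "linear", "linear", "linear"),
               names = c("learning_rate", "batch_size", "dropout",
                         "kernel_size", "epochs"))
}

#' Decode an optimizer position into hyperparameters
#'
#' @param position Numeric 5-vector on the search scale (learning rate as
#'   log10).
#' @param space The \code{\link{hyper_space}} (dimension names are taken
#'   from it).
#' @return Named list \code{learning_rate}, \code{batch_size},
#'   \code{dropout}, \code{kernel_size}, \code{epochs}.
#' @export
decode_position <- function(position, space = hyper_space()) {
  snap <- function(x, choices) choices[which.min(abs(choices - x))]
  list(
    learning_rate = 10^position[1],
    batch_size = as.integer(snap(position[2], c(16, 32, 64, 128))),
    dropout = min(0.7, max(0.2, position[3])),
    kernel_size = as.integer(snap(position[4], c(3, 5))),
    epochs = as.integer(round(min(200, max(50, position[5]))))
  )
}

#' Encode hyperparameters as an optimizer position
#'
#' Inverse of \code{\link{decode_position}} (learning rate to log10).
#'
#' @param theta Named list as returned by \code{\link{decode_position}}.
#' @return Numeric 5-vector on the search scale.
#' @export
encode_theta <- function(theta) {
  c(log10(theta$learning_rate), theta$batch_size, theta$dropout,
    theta$kernel_size, theta$epochs)
}
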