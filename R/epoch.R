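#' Construct an epoch of a multivariate time series
#'
#' An epoch is one stationary segment of a recording: a numeric matrix with
#' \code{T} rows (time) and \code{d} columns (components/channels). Epochs from
#' the same recording may have different \code{d}; all statistics in this
#' package are designed to remain comparable across such changes.
#'
#' @param values numeric matrix (or vector, treated as one column), rows are
#'   time points. All entries must be finite; \code{T >= 8} is required.
#' @param sampling_rate_hz optional positive sampling rate, used only to
#'   convert Hz band definitions to angular frequency.
#' @param epoch_index non-negative integer label for the epoch.
#' @param center if \code{TRUE} (default) column means are subtracted. All
#'   spectral estimation in this package operates on centered epochs.
#' @return An object of class \code{"epoch_series"} with elements
#'   \code{values}, \code{n_time}, \code{n_comp}, \code{sampling_rate_hz},
#'   \code{epoch_index}, \code{centered}.
#' @examples
#' e <- epoch_series(matrix(rnorm(256), 128, 2))
#' e$n_time; e$n_comp
#' @export
epoch_series <- function(values, sampling_rate_hz = NULL, epoch_index = 0L,
                         center = TRUE) {
  if (is.data.frame(values)) values <- as.matrix(values)
  if (!is.matrix(values)) values <- matrix(as.numeric(values), ncol = 1L)
  storage.mode(values) <- "double"
  bad <- which(!apply(values, 2L, function(x) all(is.finite(x))))
  if (length(bad) > 0L) {
    stop("non-finite values in column(s): ", paste(bad, collapse = ", "))
  }
  n_time <- nrow(values)
  n_comp <- ncol(values)
  if (n_time < 8L) stop("epoch too short: T = ", n_time, " (need T >= 8)")
  if (n_comp < 1L) stop("epoch must have at least one component")
  if (!is.null(sampling_rate_hz)) {
    stopifnot(is.numeric(sampling_rate_hz), length(sampling_rate_hz) == 1L,
              sampling_rate_hz > 0)
  }
  if (center) values <- sweep(values, 2L, colMeans(values))
  structure(
    list(values = values, n_time = n_time, n_comp = n_comp,
         sampling_rate_hz = sampling_rate_hz,
         epoch_index = as.integer(epoch_index), centered = center),
    class = "epoch_series"
  )
}

#' @export
print.epoch_series <- function(x, ...) {
  cat("Epoch series: T =", x$n_time, ", d =", x$n_comp,
      if (!is.null(x$sampling_rate_hz)) paste0(", fs = ", x$sampling_rate_hz, " Hz"),
      if (x$centered) "(centered)" else "(raw)", "\n")
  invisible(x)
}

#' Centre an epoch (subtract column means)
#'
#' @param epoch an \code{\link{epoch_series}}.
#' @return The epoch with per-column means removed.
#' @export
center_epoch <- function(epoch) {
  stopifnot(inherits(epoch, "epoch_series"))
  if (epoch$centered) return(epoch)
  epoch$values <- sweep(epoch$values, 2L, colMeans(epoch$values))
  epoch$centered <- TRUE
  epoch
}

#' Pre-whiten an epoch by the inverse square root of its lag-0 covariance
#'
#' Multiplies each observation by the symmetric inverse square root of the
#' sample lag-0 covariance matrix, so that the transformed epoch has identity
#' lag-0 covariance. Used to separate contemporaneous from lead-lag
#' cross-dependence before coherence analysis.
#'
#' @param epoch an \code{\link{epoch_series}}.
#' @return A pre-whitened \code{epoch_series} whose sample covariance is the
#'   identity (to numerical tolerance).
#' @export
prewhiten <- function(epoch) {
  stopifnot(inherits(epoch, "epoch_series"))
  epoch <- center_epoch(epoch)
  x <- epoch$values
  sigma <- crossprod(x) / nrow(x)
  eig <- eigen(sigma, symmetric = TRUE)
  if (min(eig$values) <= 1e-10 * max(eig$values)) {
    stop("lag-0 covariance is numerically singular; ",
         "reduce the number of components before pre-whitening")
  }
  root_inv <- eig$vectors %*% (t(eig$vectors) / sqrt(eig$values))
  epoch$values <- x %*% root_inv
  epoch
}
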