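#' Upper bound on the peak width parameter
#'
#' The admissible width of a Gaussian elution peak is limited so that the
#' whole peak fits inside the recorded time window: 99.73% of the mass of
#' a Gaussian lies within three standard deviations of its centre, so a
#' peak centred anywhere on the axis fits whenever
#' \code{6 * sigma < t}.  The bound returned is \code{t / 6}; admissible
#' integer widths are \code{1 .. ceiling(t / 6) - 1}.
#'
#' @param t number of elution time points (integer, >= 7).
#' @return the real bound \code{t / 6} (sigma must be strictly below it).
#' @export
sigma_upper_bound <- function(t) {
  t <- as.integer(t)
  if (is.na(t) || t < 7L)
    stop("time axis too short (t = ", t,
         "): no integer sigma satisfies sigma < t/6 with sigma >= 1")
  t / 6
}

#' Largest admissible integer sigma for a time axis of length t
#' @noRd
sigma_max <- function(t) {
  bound <- sigma_upper_bound(t)
  smax <- ceiling(bound) - 1L
  if (smax < 1L)
    stop("time axis too short (t = ", t, "): no admissible sigma")
  as.integer(smax)
}

#' Construct and validate a reference-curve parameter pair
#'
#' A candidate compound is described by theta = (mu, sigma): the integer
#' elution-time index of its peak maximum and its integer Gaussian width.
#'
#' @param mu peak centre, integer in \code{1..t}.
#' @param sigma peak width, integer in \code{1..ceiling(t/6)-1}.
#' @param t length of the elution time axis.
#' @return object of class \code{reference_params} (fields \code{mu},
#'   \code{sigma}).
#' @export
reference_params <- function(mu, sigma, t) {
  mu <- as.integer(mu); sigma <- as.integer(sigma); t <- as.integer(t)
  if (is.na(mu) || mu < 1L || mu > t)
    stop("mu = ", mu, " outside the time axis 1..", t)
  if (is.na(sigma) || sigma < 1L || sigma >= sigma_upper_bound(t))
    stop("sigma = ", sigma, " outside the admissible range 1..",
         sigma_max(t), " for t = ", t)
  structure(list(mu = mu, sigma = sigma), class = "reference_params")
}

#' @export
print.reference_params <- function(x, ...) {
  cat("(mu = ", x$mu, ", sigma = ", x$sigma, ")\n", sep = "")
  invisible(x)
}

#' Unit-maximum Gaussian reference curve
#'
#' Evaluates \code{exp(-(x - mu)^2 / (2 sigma^2))} for \code{x = 1..t}.
#' The usual Gaussian normalising factor is dropped so that the curve
#' peaks at exactly 1: amplitude information belongs to the spectra, not
#' to the elution profile template.  The curve is evaluated on the
#' truncated window \code{1..t} with no renormalisation; the width bound
#' of \code{\link{sigma_upper_bound}} guarantees at least 99.73% of the
#' mass can fit in the window.
#'
#' @param params a \code{reference_params}, or anything coercible by
#'   \code{reference_params(mu, sigma, t)} when given as a length-2
#'   numeric \code{c(mu, sigma)}.
#' @param t length of the elution time axis.
#' @return object of class \code{reference_curve}: fields \code{values}
#'   (length t, in (0, 1]) and \code{params}.
#' @export
gaussian_reference <- function(params, t) {
  if (!inherits(params, "reference_params")) {
    params <- reference_params(params[[1]], params[[2]], t)
  } else {
    # revalidate against this axis
    params <- reference_params(params$mu, params$sigma, t)
  }
  x <- seq_len(t)
  v <- exp(-(x - params$mu)^2 / (2 * params$sigma^2))
  structure(list(values = v, params = params), class = "reference_curve")
}

#' Full integer parameter grid for a time axis
#'
#' All integer (mu, sigma) pairs with \code{1 <= mu <= t} and
#' \code{1 <= sigma <= ceiling(t/6) - 1}.  This is the search domain of
#' the genetic algorithm and of exhaustive fitness evaluation.
#'
#' @param t length of the elution time axis.
#' @return data.frame with integer columns \code{mu}, \code{sigma}.
#' @export
parameter_grid <- function(t) {
  t <- as.integer(t)
  smax <- sigma_max(t)
  expand.grid(mu = seq_len(t), sigma = seq_len(smax),
              KEEP.OUT.ATTRS = FALSE)
}

#' Is an integer (mu, sigma) pair on the admissible grid?
#' @noRd
theta_on_grid <- function(mu, sigma, t) {
  mu >= 1 & mu <= t & sigma >= 1 & sigma <= sigma_max(t) &
    mu == round(mu) & sigma == round(sigma)
}
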