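#' Specification of a synthetic HPLC-DAD chromatogram
#'
#' Describes a bilinear mixture X = A S: each compound contributes a
#' rank-one term (spectrum times elution profile).  Elution profiles are
#' unit-maximum Gaussians with integer (mu, sigma); spectra are smooth
#' positive curves over the wavelength axis generated as small Gaussian
#' mixtures.  The defaults are the package's five-compound benchmark:
#' five Gaussian peaks at (50,21), (75,12), (90,10), (155,17), (175,9) on
#' a 241-point time axis with 101 wavelength channels and no noise, with
#' the last two peaks overlapping severely.
#'
#' @param thetas 2-column matrix or list of c(mu, sigma) pairs.
#' @param t time-axis length.
#' @param m number of wavelength channels (must exceed the number of
#'   compounds for the mixture to be separable).
#' @param noise_sd standard deviation of additive i.i.d. Gaussian noise
#'   (default 0: noiseless).
#' @param seed integer seed controlling the spectra and the noise.
#' @return list of class \code{simulation_spec}.
#' @export
simulation_spec <- function(thetas = rbind(c(50, 21), c(75, 12), c(90, 10),
                                           c(155, 17), c(175, 9)),
                            t = 241L, m = 101L, noise_sd = 0, seed = 7L) {
  t <- as.integer(t); m <- as.integer(m)
  thetas <- normalize_theta_list(thetas, t)
  key <- vapply(thetas, function(th) paste0(th$mu, "_", th$sigma), "")
  if (anyDuplicated(key)) stop("thetas must be pairwise distinct")
  if (m < length(thetas) + 1L)
    stop("need more wavelength channels than compounds (m >= n + 1)")
  stopifnot(noise_sd >= 0)
  structure(list(thetas = thetas, t = t, m = m,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "simulation_spec")
}

#' Elution peak matrix of a simulation
#'
#' @param spec a \code{\link{simulation_spec}}.
#' @return n x t matrix; row i is the unit-maximum Gaussian for theta i.
#' @export
make_peaks <- function(spec) {
  S <- do.call(rbind, lapply(spec$thetas, function(th)
    gaussian_reference(th, spec$t)$values))
  rownames(S) <- vapply(spec$thetas, function(th)
    paste0("(", th$mu, ",", th$sigma, ")"), "")
  S
}

#' Synthetic absorbance spectra of a simulation
#'
#' Each compound's spectrum is a sum of 2-3 Gaussian bands over the
#' wavelength axis with seeded random centres, widths and heights,
#' rescaled to unit maximum.  Draws are retried (up to 100 times) until
#' the spectra matrix has full column rank and no pair of columns
#' correlates above 0.95, so the bilinear mixture is well conditioned.
#'
#' @param spec a \code{\link{simulation_spec}}.
#' @return m x n nonnegative matrix with unit-maximum columns.
#' @export
make_spectra <- function(spec) {
  n <- length(spec$thetas)
  m <- spec$m
  wl <- seq_len(m)
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(spec$seed)
  for (attempt in seq_len(100L)) {
    A <- vapply(seq_len(n), function(j) {
      nb <- sample(2:3, 1)
      v <- rep(0, m)
      for (b in seq_len(nb)) {
        ctr <- runif(1, 0.1 * m, 0.9 * m)
        wid <- runif(1, 0.05 * m, 0.2 * m)
        ht <- runif(1, 0.3, 1)
        v <- v + ht * exp(-(wl - ctr)^2 / (2 * wid^2))
      }
      v / max(v)
    }, numeric(m))
    A <- matrix(A, nrow = m)
    ok_rank <- qr(A)$rank == n
    cors <- suppressWarnings(cor(A))
    ok_cor <- n == 1L || max(abs(cors[upper.tri(cors)])) < 0.95
    if (ok_rank && ok_cor) {
      colnames(A) <- rownames(make_peaks(spec))
      return(A)
    }
  }
  stop("could not generate well-conditioned spectra after 100 attempts")
}

#' Generate a synthetic chromatogram dataset
#'
#' Builds the bilinear mixture X = A S (+ optional i.i.d. Gaussian
#' noise).  At \code{noise_sd = 0} the product is exact: X equals A S to
#' machine precision and has rank equal to the number of compounds.
#'
#' @param spec a \code{\link{simulation_spec}}.
#' @return list with \code{X} (a \code{\link{chromatogram}}), \code{A}
#'   (m x n true spectra), \code{S} (n x t true peaks), \code{thetas}
#'   (list of true \code{reference_params}).
#' @export
make_dataset <- function(spec) {
  S <- make_peaks(spec)
  A <- make_spectra(spec)
  X <- A %*% S
  if (spec$noise_sd > 0) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(spec$seed + 1L)
    X <- X + matrix(rnorm(length(X), sd = spec$noise_sd),
                    nrow = nrow(X))
  }
  list(X = chromatogram(X), A = A, S = S, thetas = spec$thetas)
}

# Save/restore .Random.seed so generators with their own seed do not
# disturb the caller's RNG stream.
get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}
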