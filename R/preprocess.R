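#' Centre and whiten a chromatogram matrix
#'
#' Standard ICA preprocessing: subtract the per-wavelength mean, then
#' project onto the leading eigenvectors of the sample covariance and
#' rescale so the retained components have identity covariance.  The
#' covariance uses the population normalisation (divide by t), so the
#' expectation operators of the ICA contrast are plain sample means.
#'
#' All eigencomponents whose eigenvalue exceeds
#' \code{variance_tol * largest eigenvalue} are retained; by default
#' everything numerically nonzero is kept so that no small compound is
#' discarded by an eigenvalue cut-off.  For a noiseless bilinear mixture
#' of n compounds with more wavelengths than compounds, exactly n
#' components survive.
#'
#' @param X a \code{\link{chromatogram}} (or bare matrix, wavelength rows).
#' @param variance_tol relative eigenvalue threshold (default 1e-10).
#' @return object of class \code{whitened_data}: \code{X_tilde} (k x t,
#'   zero row means, identity covariance), \code{Dw} (k x m whitening
#'   matrix), \code{mean_vec}, \code{k}, \code{t}, and the augmented
#'   matrices \code{X_tilde_prime} (extra all-zeros row) and
#'   \code{X_tilde_dprime} (extra all-ones row) used to carry an additive
#'   offset through the ICA fit.
#' @export
center_whiten <- function(X, variance_tol = 1e-10) {
  X <- as_chromatogram(X)
  A <- X$absorbance
  m <- nrow(A); t <- ncol(A)
  mean_vec <- rowMeans(A)
  Ac <- A - mean_vec
  C <- tcrossprod(Ac) / t
  e <- eigen(C, symmetric = TRUE)
  lead <- e$values[1]
  if (!is.finite(lead) || lead <= 0)
    stop("constant input: the chromatogram has zero variance")
  keep <- which(e$values > variance_tol * lead)
  k <- length(keep)
  Dw <- diag(1 / sqrt(e$values[keep]), nrow = k) %*% t(e$vectors[, keep, drop = FALSE])
  X_tilde <- Dw %*% Ac
  structure(
    list(X_tilde = X_tilde,
         Dw = Dw,
         mean_vec = mean_vec,
         k = k,
         t = t,
         X_tilde_prime = rbind(X_tilde, 0),
         X_tilde_dprime = rbind(X_tilde, 1)),
    class = "whitened_data")
}

#' @export
print.whitened_data <- function(x, ...) {
  cat("<whitened_data> k = ", x$k, " components, t = ", x$t,
      " time points\n", sep = "")
  invisible(x)
}

#' Augmented unmixing weight
#'
#' A single-unit weight for the constrained ICA fit: a unit-norm
#' direction \code{b} in the whitened space, an additive offset \code{d}
#' (the constant difference between the whitened-domain output and the
#' raw-domain elution profile), and an amplitude \code{scale} mapping the
#' unit-variance whitened output onto the reference curve's units.
#'
#' @param b numeric vector, normalised to unit Euclidean norm.
#' @param d scalar offset.
#' @param scale scalar amplitude (default 1).
#' @return object of class \code{augmented_weight}.
#' @export
augmented_weight <- function(b, d = 0, scale = 1) {
  b <- as.numeric(b)
  nb <- sqrt(sum(b^2))
  if (nb == 0) stop("weight vector b must be nonzero")
  structure(list(b = b / nb, d = as.numeric(d), scale = as.numeric(scale)),
            class = "augmented_weight")
}

#' Raw-domain output of a weight on whitened data
#'
#' Maps a whitened-domain direction back to a calculated elution curve:
#' \code{y = scale * (b' X_tilde) + d}.  With \code{scale = 1} this is the
#' augmented product \code{[b', d] \%*\% X_tilde_dprime}, whose appended
#' all-ones row carries the offset; the all-zeros variant drops it.
#'
#' @param W a \code{\link{center_whiten}} result.
#' @param w an \code{\link{augmented_weight}}.
#' @return numeric vector of length t.
#' @export
raw_output <- function(W, w) {
  if (length(w$b) != W$k)
    stop("weight length ", length(w$b), " does not match k = ", W$k)
  drop(w$scale * crossprod(w$b, W$X_tilde)) + w$d
}
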