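#' Estimate compound spectra by pseudo-inverse
#'
#' Given the observed chromatogram X and the recovered elution peak
#' matrix S (one row per compound), the least-squares spectra are
#' \code{A = X \%*\% pinv(S)}: the bilinear model X = A S inverted with
#' the Moore-Penrose pseudo-inverse, ignoring noise.  Negative spectral
#' values are reported via an attribute rather than clipped — with real
#' data they flag model misfit, not a numerical problem.
#'
#' @param X a \code{\link{chromatogram}} (or bare m x t matrix).
#' @param S n x t matrix of recovered elution peaks, full row rank.
#' @return m x n spectra matrix; attribute \code{n_negative} counts
#'   negative entries.
#' @export
estimate_spectra <- function(X, S) {
  if (inherits(X, "chromatogram")) X <- X$absorbance
  S <- as.matrix(S)
  if (ncol(X) != ncol(S))
    stop("X has ", ncol(X), " time points but S has ", ncol(S))
  sv <- svd(S, nu = 0, nv = 0)$d
  if (length(sv) < nrow(S) || min(sv) < 1e-10 * max(sv))
    stop("collinear peaks: S is rank deficient, spectra are not identifiable")
  A <- X %*% MASS::ginv(S)
  nneg <- sum(A < 0)
  if (nneg > 0)
    message(nneg, " negative spectral value(s) in the estimate; ",
            "with real data this indicates reference-curve misfit or noise")
  attr(A, "n_negative") <- nneg
  A
}

#' Score a separation against simulation ground truth
#'
#' Matches recovered compounds to true ones by nearest (mu, sigma) in
#' Euclidean distance (greedy, smallest distance first), then reports
#' per-compound mean squared errors between unit-maximum-scaled
#' recovered and true elution curves, and between unit-maximum-scaled
#' recovered and true spectra.  Scaling both sides to unit maximum makes
#' the errors invariant to the arbitrary positive amplitude of a
#' recovered component.
#'
#' @param result a \code{\link{separate}} result (or any list with
#'   \code{thetas}, \code{peaks} (n x t), \code{spectra} (m x n)).
#' @param truth list with \code{thetas}, \code{S} (n0 x t true peaks),
#'   \code{A} (m x n0 true spectra), as returned by
#'   \code{\link{make_dataset}}.
#' @return object of class \code{evaluation_report}: data.frame
#'   \code{table} with one row per matched pair (recovered index, true
#'   index, theta distance, \code{curve_error}, \code{spectrum_error})
#'   plus \code{unmatched_true} and \code{unmatched_recovered} indices.
#' @export
evaluate_separation <- function(result, truth) {
  rec_th <- normalize_theta_matrix(result$thetas)
  true_th <- normalize_theta_matrix(truth$thetas)
  n_rec <- nrow(rec_th); n_true <- nrow(true_th)
  if (!is.null(result$peaks) && ncol(result$peaks) != ncol(truth$S))
    stop("peak matrices have different time axes")

  # greedy bipartite matching, smallest theta distance first
  d <- outer(seq_len(n_rec), seq_len(n_true), Vectorize(function(i, j)
    sqrt(sum((rec_th[i, ] - true_th[j, ])^2))))
  d <- matrix(d, n_rec, n_true)
  pairs <- list()
  dd <- d
  while (any(is.finite(dd))) {
    ij <- arrayInd(which.min(dd), dim(dd))
    pairs[[length(pairs) + 1L]] <- c(ij[1], ij[2], d[ij[1], ij[2]])
    dd[ij[1], ] <- Inf
    dd[, ij[2]] <- Inf
  }
  unit_scale <- function(v) {
    mx <- max(abs(v))
    if (mx == 0) v else v / mx
  }
  rows <- lapply(pairs, function(p) {
    i <- p[1]; j <- p[2]
    ce <- mean((unit_scale(result$peaks[i, ]) - unit_scale(truth$S[j, ]))^2)
    se <- mean((unit_scale(result$spectra[, i]) - unit_scale(truth$A[, j]))^2)
    data.frame(recovered = i, true = j, theta_dist = p[3],
               curve_error = ce, spectrum_error = se)
  })
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(recovered = integer(), true = integer(),
               theta_dist = numeric(), curve_error = numeric(),
               spectrum_error = numeric())
  structure(
    list(table = tab[order(tab$true), , drop = FALSE],
         unmatched_true = setdiff(seq_len(n_true), tab$true),
         unmatched_recovered = setdiff(seq_len(n_rec), tab$recovered)),
    class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report>\n")
  print(x$table, row.names = FALSE)
  if (length(x$unmatched_true))
    cat("unmatched true compounds:", x$unmatched_true, "\n")
  if (length(x$unmatched_recovered))
    cat("unmatched recovered compounds:", x$unmatched_recovered, "\n")
  invisible(x)
}

# thetas as list of reference_params / pairs -> 2-column matrix
normalize_theta_matrix <- function(thetas) {
  if (is.matrix(thetas)) return(thetas[, 1:2, drop = FALSE])
  do.call(rbind, lapply(thetas, function(th) {
    if (inherits(th, "reference_params")) c(th$mu, th$sigma)
    else c(th[[1]], th[[2]])
  }))
}
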