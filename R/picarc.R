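#' Options for the constrained single-unit ICA fit
#'
#' @param gamma weight of the measurement-operator penalty (the squared
#'   distance between the calculated curve and its reference) relative to
#'   the negentropy contrast.  The model itself carries no weight, but
#'   the two terms live on different scales; the default 10 keeps the
#'   reference constraint strictly dominant so that the extracted curve
#'   cannot drift out of the reference's basin (see the methods
#'   vignette).  \code{gamma = 0} maximises the contrast alone.
#' @param tol convergence tolerance on \code{|1 - |b_new . b||};
#'   default 1e-6.
#' @param max_iter iteration cap; default 200.
#' @param fitness_mode \code{"picarc"} (penalised negentropy ascent) or
#'   \code{"ls"} (closed-form least-squares projection, no negentropy
#'   term; used as an independent oracle).
#' @return list of class \code{fit_options}.
#' @export
fit_options <- function(gamma = 10, tol = 1e-6, max_iter = 200L,
                        fitness_mode = c("picarc", "ls")) {
  fitness_mode <- match.arg(fitness_mode)
  stopifnot(gamma >= 0, tol > 0, max_iter >= 1)
  structure(list(gamma = gamma, tol = tol,
                 max_iter = as.integer(max_iter),
                 fitness_mode = fitness_mode),
            class = "fit_options")
}

#' Quartic negentropy contrast
#'
#' The non-Gaussianity contrast used by the constrained fit:
#' \code{G(u) = u^4 / 4}, with first derivative \code{g(u) = u^3} and
#' second derivative \code{gprime(u) = 3 u^2}.
#'
#' @param u numeric vector.
#' @return list with components \code{G}, \code{g}, \code{gprime}.
#' @export
contrast_quartic <- function(u) {
  list(G = u^4 / 4, g = u^3, gprime = 3 * u^2)
}

#' Squared Euclidean distance between a calculated and a reference curve
#'
#' The measurement operator of the constrained model: the sum over time
#' points of the squared difference between the extracted elution curve
#' and the Gaussian reference.
#'
#' @param y numeric vector, or a fit's \code{curve}.
#' @param r numeric vector, or a \code{\link{gaussian_reference}} result.
#' @return nonnegative scalar.
#' @export
measure_distance <- function(y, r) {
  if (inherits(y, "calculated_curve")) y <- y$values
  if (inherits(r, "reference_curve")) r <- r$values
  if (length(y) != length(r))
    stop("curve lengths differ: ", length(y), " vs ", length(r))
  sum((y - r)^2)
}

# Optimal affine calibration of a unit-variance whitened output u onto a
# reference r: scale = <u, r - mean(r)> / t (the rows of X_tilde have
# exactly unit population variance), offset = mean(r) (the row means of
# X_tilde are exactly zero).
affine_calibrate <- function(u, r, t) {
  list(scale = sum(u * (r - mean(r))) / t, d = mean(r))
}

# Penalised objective, its state, and its gradient for one unit.
# J(b) = mean(G(b'Xt)) - gamma * sum((scale*u + d - r)^2), with the
# affine calibration (scale, d) always at its closed-form optimum, so
# the envelope theorem gives the gradient without differentiating them.
unit_state <- function(b, Xt, r, rc, dmean, t, gamma) {
  u <- drop(crossprod(b, Xt))
  sc <- sum(u * rc) / t
  e <- sc * u + dmean - r
  list(J = mean(u^4) / 4 - gamma * sum(e^2),
       u = u, scale = sc, e = e)
}

unit_gradient <- function(st, Xt, t, gamma) {
  drop(Xt %*% (st$u^3)) / t - 2 * gamma * st$scale * drop(Xt %*% st$e)
}

# One monotone ascent pass on the unit sphere: project the gradient onto
# the tangent space, backtrack the step until the objective improves.
# Returns the updated (b, state, alpha) plus the rotation |1-|b'.b|| and
# a flag saying whether any improving step existed.
ascend_unit <- function(b, st, alpha, Xt, r, rc, dmean, t, gamma) {
  grad <- unit_gradient(st, Xt, t, gamma)
  gt <- grad - sum(grad * b) * b
  if (sqrt(sum(gt^2)) < 1e-12)
    return(list(b = b, state = st, alpha = alpha, delta = 0,
                moved = FALSE))
  for (ls in seq_len(40L)) {
    bt <- b + alpha * gt
    bt <- bt / sqrt(sum(bt^2))
    stt <- unit_state(bt, Xt, r, rc, dmean, t, gamma)
    if (stt$J > st$J + 1e-14) {
      delta <- abs(1 - abs(sum(bt * b)))
      return(list(b = bt, state = stt, alpha = alpha * 1.5,
                  delta = delta, moved = TRUE))
    }
    alpha <- alpha / 2
  }
  list(b = b, state = st, alpha = alpha, delta = 0, moved = FALSE)
}

#' Fit one constrained ICA unit against a reference curve
#'
#' Extracts the single source whose elution profile best resembles the
#' given Gaussian reference.  The unit-norm direction \code{b} in the
#' whitened space maximises the penalised contrast
#' \code{mean(G(b'X)) - gamma * ||scale * b'X + d - r||^2}, where the
#' amplitude and offset mapping the unit-variance whitened output onto
#' the reference's units are always at their closed-form optimum.  The
#' maximisation runs as projected gradient ascent on the unit sphere with
#' a backtracking line search, so the objective increases monotonically
#' and the fit is deterministic.
#'
#' The starting direction is the least-squares projection
#' \code{b0 = X_tilde \%*\% (r - mean(r))}, normalised — the exact
#' minimiser of the reference distance — so the fitness surface over
#' theta is reproducible without random initialisation.  In
#' \code{fitness_mode = "ls"} the fit stops there and no negentropy
#' ascent is applied; this closed form serves as the independent oracle
#' for the default mode.
#'
#' @param W a \code{\link{center_whiten}} result.
#' @param r a \code{\link{gaussian_reference}} curve (or bare vector of
#'   length t, in which case \code{theta} bookkeeping is skipped).
#' @param opts a \code{\link{fit_options}} list.
#' @return object of class \code{single_unit_fit}: \code{weight}
#'   (an \code{\link{augmented_weight}}), \code{curve} (list with
#'   \code{values}, \code{source_theta}), \code{epsilon} (squared
#'   distance between curve and reference), \code{iterations},
#'   \code{converged}.
#' @export
fit_single_unit <- function(W, r, opts = fit_options()) {
  theta <- NULL
  if (inherits(r, "reference_curve")) {
    theta <- r$params
    r <- r$values
  }
  if (length(r) != W$t)
    stop("reference length ", length(r), " does not match t = ", W$t)
  t <- W$t
  Xt <- W$X_tilde
  rc <- r - mean(r)
  dmean <- mean(r)

  b <- drop(Xt %*% rc)
  nb <- sqrt(sum(b^2))
  if (nb < .Machine$double.eps)
    stop("reference curve is orthogonal to the data: cannot initialise")
  b <- b / nb

  iterations <- 0L
  converged <- TRUE
  if (opts$fitness_mode == "picarc") {
    st <- unit_state(b, Xt, r, rc, dmean, t, opts$gamma)
    alpha <- 1
    converged <- FALSE
    for (it in seq_len(opts$max_iter)) {
      step <- ascend_unit(b, st, alpha, Xt, r, rc, dmean, t, opts$gamma)
      iterations <- it
      b <- step$b; st <- step$state; alpha <- step$alpha
      if (!step$moved || step$delta < opts$tol) { converged <- TRUE; break }
    }
  }

  u <- drop(crossprod(b, Xt))
  cal <- affine_calibrate(u, r, t)
  # resolve the ICA sign indeterminacy: positive amplitude = positive peak
  if (cal$scale < 0) {
    b <- -b
    u <- -u
    cal$scale <- -cal$scale
  }
  y <- cal$scale * u + cal$d
  structure(
    list(weight = augmented_weight(b, d = cal$d, scale = cal$scale),
         curve = structure(list(values = y, source_theta = theta),
                           class = "calculated_curve"),
         epsilon = measure_distance(y, r),
         iterations = iterations,
         converged = converged),
    class = "single_unit_fit")
}

#' Memoising fitness cache
#'
#' The parameter grid is finite, so the fitness at each integer
#' (mu, sigma) pair is computed once and memoised.
#'
#' @return an environment usable as the \code{cache} argument of
#'   \code{\link{picarc_fitness}}.
#' @export
fitness_cache <- function() new.env(parent = emptyenv())

#' Fitness of a reference-curve parameter pair
#'
#' Evaluates the constrained-ICA fitness surface at one point of the
#' (mu, sigma) grid: fit a single unit against the Gaussian reference for
#' theta and return the squared distance between the extracted curve and
#' the reference.  Smaller is better; the surface's interior local minima
#' are the candidate compounds.
#'
#' @param theta a \code{\link{reference_params}} or \code{c(mu, sigma)}.
#' @param W a \code{\link{center_whiten}} result.
#' @param opts a \code{\link{fit_options}} list.
#' @param cache optional \code{\link{fitness_cache}} environment.
#' @return nonnegative scalar.
#' @export
picarc_fitness <- function(theta, W, opts = fit_options(), cache = NULL) {
  if (!inherits(theta, "reference_params"))
    theta <- reference_params(theta[[1]], theta[[2]], W$t)
  key <- paste0(theta$mu, "_", theta$sigma)
  if (!is.null(cache)) {
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
  }
  fit <- fit_single_unit(W, gaussian_reference(theta, W$t), opts)
  val <- fit$epsilon
  if (!is.null(cache)) cache[[key]] <- val
  val
}

#' Evaluate the fitness surface on the full parameter grid
#'
#' Brute-force evaluation of \code{\link{picarc_fitness}} at every
#' admissible integer (mu, sigma); used for oracle checks and for
#' locating local minima exhaustively on small instances.
#'
#' @inheritParams picarc_fitness
#' @return data.frame with columns \code{mu}, \code{sigma}, \code{fit}.
#' @export
fitness_surface <- function(W, opts = fit_options(), cache = NULL) {
  grid <- parameter_grid(W$t)
  grid$fit <- vapply(seq_len(nrow(grid)), function(i) {
    picarc_fitness(c(grid$mu[i], grid$sigma[i]), W, opts, cache)
  }, numeric(1))
  grid
}

#' Interior 8-neighbour local minima of a fitness surface
#'
#' A grid point is a local minimum when it is strictly interior (not on
#' any edge of the mu-sigma domain) and its fitness is no worse than all
#' eight neighbouring grid points.
#'
#' @param surface a \code{\link{fitness_surface}} data.frame.
#' @param t time-axis length the surface was computed for.
#' @return data.frame of the qualifying (mu, sigma, fit) rows.
#' @export
surface_local_minima <- function(surface, t) {
  smax <- sigma_max(t)
  F <- matrix(NA_real_, nrow = t, ncol = smax)
  F[cbind(surface$mu, surface$sigma)] <- surface$fit
  hits <- list()
  sig_range <- setdiff(seq_len(smax), c(1L, smax))
  for (mu in 2:(t - 1L)) {
    for (sg in sig_range) {
      v <- F[mu, sg]
      nb <- F[(mu - 1L):(mu + 1L), (sg - 1L):(sg + 1L)]
      if (!anyNA(nb) && v <= min(nb))
        hits[[length(hits) + 1L]] <- c(mu, sg, v)
    }
  }
  if (!length(hits))
    return(data.frame(mu = integer(), sigma = integer(), fit = numeric()))
  out <- do.call(rbind, hits)
  data.frame(mu = as.integer(out[, 1]), sigma = as.integer(out[, 2]),
             fit = out[, 3])
}

#' Jointly refine several units
#'
#' Final polishing step once the solution set of (mu, sigma) pairs is
#' known: every unit runs its constrained ascent in parallel, each
#' against its own reference.  Units are kept distinct by their distinct
#' references rather than by forced orthogonality: elution peaks overlap
#' in time, so their whitened-space directions are genuinely
#' non-orthogonal and symmetric decorrelation would distort the
#' recovered curves.  Classical fastICA-style symmetric decorrelation
#' (\code{B (B'B)^{-1/2}}) is available behind \code{decorrelate = TRUE}
#' for the unconstrained use case.
#'
#' @param thetas list of \code{\link{reference_params}} (or a 2-column
#'   matrix / list of c(mu, sigma)), pairwise distinct.
#' @param W a \code{\link{center_whiten}} result.
#' @param opts a \code{\link{fit_options}} list.
#' @param decorrelate apply symmetric decorrelation after every joint
#'   update (default FALSE).
#' @return list with \code{Y_star} (n x t matrix of recovered elution
#'   curves, rows ordered by ascending mu, each with a positive peak),
#'   \code{B} (k x n directions in the same order), \code{thetas}
#'   (reordered to match), \code{iterations}, \code{converged}.
#' @export
parallel_refine <- function(thetas, W, opts = fit_options(),
                            decorrelate = FALSE) {
  thetas <- normalize_theta_list(thetas, W$t)
  n <- length(thetas)
  if (n == 0L) stop("no reference parameters supplied")
  key <- vapply(thetas, function(th) paste0(th$mu, "_", th$sigma), "")
  if (anyDuplicated(key)) stop("reference parameters must be pairwise distinct")
  ord <- order(vapply(thetas, `[[`, 0L, "mu"),
               vapply(thetas, `[[`, 0L, "sigma"))
  thetas <- thetas[ord]

  t <- W$t
  Xt <- W$X_tilde
  R <- do.call(rbind, lapply(thetas, function(th)
    gaussian_reference(th, t)$values))
  Rc <- R - rowMeans(R)
  dmeans <- rowMeans(R)

  B <- vapply(seq_len(n), function(i) {
    b <- drop(Xt %*% Rc[i, ])
    b / sqrt(sum(b^2))
  }, numeric(W$k))
  B <- matrix(B, nrow = W$k)

  check_rank <- function(B) {
    M <- crossprod(B)
    e <- eigen(M, symmetric = TRUE, only.values = !decorrelate)
    if (min(e$values) < 1e-12 * max(e$values))
      stop("degenerate unit set: directions are collinear")
    e
  }
  sym_decorrelate <- function(B, e) {
    B %*% (e$vectors %*% diag(1 / sqrt(e$values), n) %*% t(e$vectors))
  }
  e <- check_rank(B)
  if (decorrelate) B <- sym_decorrelate(B, e)

  iterations <- 0L
  converged <- opts$fitness_mode == "ls"
  if (opts$fitness_mode == "picarc") {
    states <- lapply(seq_len(n), function(i)
      unit_state(B[, i], Xt, R[i, ], Rc[i, ], dmeans[i], t, opts$gamma))
    alphas <- rep(1, n)
    converged <- FALSE
    for (it in seq_len(opts$max_iter)) {
      B_old <- B
      moved_any <- FALSE
      for (i in seq_len(n)) {
        step <- ascend_unit(B[, i], states[[i]], alphas[i], Xt,
                            R[i, ], Rc[i, ], dmeans[i], t, opts$gamma)
        B[, i] <- step$b
        states[[i]] <- step$state
        alphas[i] <- step$alpha
        moved_any <- moved_any || step$moved
      }
      e <- check_rank(B)
      if (decorrelate) {
        B <- sym_decorrelate(B, e)
        states <- lapply(seq_len(n), function(i)
          unit_state(B[, i], Xt, R[i, ], Rc[i, ], dmeans[i], t, opts$gamma))
      }
      iterations <- it
      delta <- max(abs(1 - abs(colSums(B * B_old))))
      if (!moved_any || delta < opts$tol) { converged <- TRUE; break }
    }
  }

  U <- crossprod(B, Xt)
  Y <- matrix(0, n, t)
  for (i in seq_len(n)) {
    u <- U[i, ]
    cal <- affine_calibrate(u, R[i, ], t)
    if (cal$scale < 0) {
      B[, i] <- -B[, i]
      u <- -u
      cal$scale <- -cal$scale
    }
    Y[i, ] <- cal$scale * u + cal$d
  }
  rownames(Y) <- vapply(thetas, function(th)
    paste0("(", th$mu, ",", th$sigma, ")"), "")
  list(Y_star = Y, B = B, thetas = thetas,
       iterations = iterations, converged = converged)
}

# Accept a list of reference_params, a list of c(mu, sigma) pairs, or a
# 2-column matrix/data.frame; return a validated list of reference_params.
normalize_theta_list <- function(thetas, t) {
  if (inherits(thetas, "reference_params")) thetas <- list(thetas)
  if (is.matrix(thetas) || is.data.frame(thetas)) {
    thetas <- lapply(seq_len(nrow(thetas)), function(i)
      c(thetas[i, 1], thetas[i, 2]))
  }
  lapply(thetas, function(th) {
    if (inherits(th, "reference_params"))
      reference_params(th$mu, th$sigma, t)
    else
      reference_params(th[[1]], th[[2]], t)
  })
}
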