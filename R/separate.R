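#' Separate a chromatogram into compound peaks and spectra
#'
#' The full pipeline: run the multi-areas genetic algorithm to locate
#' the solution set of (mu, sigma) reference parameters, jointly refine
#' the constrained ICA units at those parameters to obtain the recovered
#' elution curves, and estimate the spectra by pseudo-inverse.  The
#' number of compounds is whatever the search finds — it is never an
#' input.
#'
#' @param X a \code{\link{chromatogram}} or bare matrix (wavelength rows).
#' @param config an \code{\link{mga_config}}.
#' @param fit_opts a \code{\link{fit_options}}.
#' @return object of class \code{separation_result}: \code{thetas} (list
#'   of \code{\link{reference_params}}, ascending mu), \code{peaks}
#'   (n x t), \code{spectra} (m x n), \code{fitness} (per-solution),
#'   \code{run_log} (per-generation area table), \code{generations},
#'   \code{converged}, \code{config}, \code{fit_opts}.
#' @examples
#' sim <- make_dataset(simulation_spec(thetas = rbind(c(30, 5)),
#'                                     t = 101, m = 21))
#' res <- separate(sim$X, mga_config(pop_size = 30, seed = 1))
#' res$thetas
#' @export
separate <- function(X, config = mga_config(), fit_opts = fit_options()) {
  X <- as_chromatogram(X)
  mres <- mga_run(X, config, fit_opts)
  n <- length(mres$solutions)
  if (n == 0L) {
    warning("no solutions found: every candidate area centre failed ",
            "the local-minimum screen")
    peaks <- matrix(numeric(0), 0L, n_time(X))
    spectra <- matrix(numeric(0), n_wavelength(X), 0L)
    fitness <- numeric(0)
    thetas <- list()
  } else {
    ref <- parallel_refine(mres$solutions, mres$W, fit_opts)
    thetas <- ref$thetas
    peaks <- ref$Y_star
    spectra <- estimate_spectra(X, peaks)
    fitness <- vapply(thetas, function(th)
      picarc_fitness(th, mres$W, fit_opts, mres$cache), numeric(1))
  }
  structure(
    list(thetas = thetas, peaks = peaks, spectra = spectra,
         fitness = fitness, run_log = mres$history,
         generations = mres$generations, converged = mres$converged,
         config = config, fit_opts = fit_opts),
    class = "separation_result")
}

#' @export
print.separation_result <- function(x, ...) {
  n <- length(x$thetas)
  cat("<separation_result> ", n, " compound(s) in ", x$generations,
      " generation(s)", if (!x$converged) " [not converged]", "\n",
      sep = "")
  if (n) {
    th <- normalize_theta_matrix(x$thetas)
    df <- data.frame(mu = th[, 1], sigma = th[, 2],
                     fitness = signif(x$fitness, 4))
    print(df, row.names = FALSE)
  }
  invisible(x)
}

#' Repeated separation with consensus over seeds
#'
#' Random initialisation occasionally sends a run to a spurious local
#' minimum; the standard remedy is to run several times and keep the
#' parameter pairs that recur.  Solutions from \code{n_runs} seeded runs
#' are pooled (grouped exactly by (mu, sigma)) and those appearing in at
#' least half the runs form the consensus set, which is then refined and
#' estimated once.
#'
#' @param X a \code{\link{chromatogram}} or bare matrix.
#' @param config an \code{\link{mga_config}}; run i uses seed
#'   \code{config$seed + i - 1}.
#' @param fit_opts a \code{\link{fit_options}}.
#' @param n_runs number of seeded runs (default 10).
#' @return list with \code{consensus} (a \code{separation_result} for
#'   the consensus thetas), \code{runs} (per-run solution tables),
#'   \code{counts} (how often each theta appeared).
#' @export
separate_consensus <- function(X, config = mga_config(),
                               fit_opts = fit_options(), n_runs = 10L) {
  X <- as_chromatogram(X)
  runs <- vector("list", n_runs)
  tally <- list()
  for (i in seq_len(n_runs)) {
    cfg_i <- config
    cfg_i$seed <- config$seed + i - 1L
    mres <- mga_run(X, cfg_i, fit_opts)
    th <- normalize_theta_matrix(mres$solutions)
    runs[[i]] <- th
    if (!is.null(th) && nrow(th))
      for (r in seq_len(nrow(th))) {
        key <- paste0(th[r, 1], "_", th[r, 2])
        tally[[key]] <- (if (is.null(tally[[key]])) 0L else tally[[key]]) + 1L
      }
  }
  counts <- data.frame(
    mu = as.integer(sub("_.*", "", names(tally))),
    sigma = as.integer(sub(".*_", "", names(tally))),
    runs = unlist(unname(tally)))
  counts <- counts[order(counts$mu, counts$sigma), , drop = FALSE]
  keep <- counts[counts$runs >= ceiling(n_runs / 2), c("mu", "sigma"),
                 drop = FALSE]
  if (!nrow(keep))
    stop("no consensus: no (mu, sigma) pair appeared in at least half ",
         "of the ", n_runs, " runs")
  W <- center_whiten(X)
  ref <- parallel_refine(as.matrix(keep), W, fit_opts)
  spectra <- estimate_spectra(X, ref$Y_star)
  cache <- fitness_cache()
  consensus <- structure(
    list(thetas = ref$thetas, peaks = ref$Y_star, spectra = spectra,
         fitness = vapply(ref$thetas, function(th)
           picarc_fitness(th, W, fit_opts, cache), numeric(1)),
         run_log = NULL, generations = NA_integer_, converged = TRUE,
         config = config, fit_opts = fit_opts),
    class = "separation_result")
  list(consensus = consensus, runs = runs, counts = counts)
}
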