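# Shared fixtures, memoised so expensive objects are built once per run.

.fixtures <- new.env(parent = emptyenv())

fx <- function(name, maker) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- maker()
  .fixtures[[name]]
}

five_truth <- function() {
  m <- rbind(c(50L, 21L), c(75L, 12L), c(90L, 10L), c(155L, 17L),
             c(175L, 9L))
  m[order(m[, 1]), ]
}

# five-compound noiseless benchmark with whitening + fitness cache
fx_five <- function() fx("five", function() {
  ds <- make_dataset(simulation_spec())
  ds$W <- center_whiten(ds$X)
  ds$cache <- fitness_cache()
  ds
})

# one-compound control
fx_one <- function() fx("one", function() {
  ds <- make_dataset(simulation_spec(thetas = rbind(c(30, 5)),
                                     t = 101, m = 21))
  ds$W <- center_whiten(ds$X)
  ds
})

# two-compound instance for exhaustive-grid comparisons
fx_two <- function() fx("two", function() {
  ds <- make_dataset(simulation_spec(thetas = rbind(c(30, 5), c(60, 8)),
                                     t = 101, m = 21, seed = 11))
  ds$W <- center_whiten(ds$X)
  ds
})

# ten default-configuration runs on the benchmark, seeds 1..10
fx_bench_runs <- function() fx("bench_runs", function() {
  ds <- fx_five()
  lapply(1:10, function(sd) {
    t0 <- proc.time()[["elapsed"]]
    res <- suppressWarnings(mga_run(ds$X, mga_config(seed = sd)))
    list(solutions = theta_matrix(res$solutions),
         generations = res$generations,
         converged = res$converged,
         elapsed = proc.time()[["elapsed"]] - t0)
  })
})

theta_matrix <- function(thetas) {
  if (!length(thetas)) return(matrix(integer(0), 0, 2))
  m <- do.call(rbind, lapply(thetas, function(th) c(th$mu, th$sigma)))
  m[order(m[, 1], m[, 2]), , drop = FALSE]
}

# a run is correct when it finds exactly the generating pairs, each
# within one grid step
is_correct_run <- function(sols, truth = five_truth()) {
  nrow(sols) == nrow(truth) && all(abs(sols - truth) <= 1)
}

make_chrom <- function(mu, sigma, t, fit) {
  picarc:::new_chromosome(mu, sigma, t, fit)
}

# independently coded greedy clustering (second implementation used as
# an oracle for separate_areas)
oracle_greedy_cluster <- function(df, r0) {
  # df: data.frame mu, sigma, fit
  df <- df[order(df$fit, df$mu, df$sigma), ]
  assigned <- rep(NA_integer_, nrow(df))
  k <- 0L
  while (anyNA(assigned)) {
    k <- k + 1L
    free <- which(is.na(assigned))
    c_ <- free[1]
    d <- sqrt((df$mu[free] - df$mu[c_])^2 + (df$sigma[free] - df$sigma[c_])^2)
    assigned[free[d <= r0]] <- k
  }
  split(df, assigned)
}

# transitive closure of an overlap relation, coded independently
oracle_overlap_groups <- function(centers, radii, factor) {
  n <- length(radii)
  g <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      d <- sqrt(sum((centers[[i]] - centers[[j]])^2))
      if (d < factor * (radii[i] + radii[j]) && g[i] != g[j]) {
        g[g == max(g[i], g[j])] <- min(g[i], g[j])
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  match(g, sort(unique(g)))
}
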