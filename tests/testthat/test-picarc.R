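test_that("the quartic contrast and its derivatives are consistent", {
  expect_identical(unlist(contrast_quartic(0)), c(G = 0, g = 0, gprime = 0))
  expect_identical(unlist(contrast_quartic(2)), c(G = 4, g = 8, gprime = 12))
  # g is the derivative of G (central-difference oracle)
  h <- 1e-6
  fd <- (contrast_quartic(1.3 + h)$G - contrast_quartic(1.3 - h)$G) / (2 * h)
  expect_equal(contrast_quartic(1.3)$g, fd, tolerance = 1e-6)
})

test_that("the measurement operator is the squared Euclidean distance", {
  expect_identical(measure_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_identical(measure_distance(c(1, 0, 0), c(0, 0, 1)), 2)
  set.seed(5)
  y <- rnorm(50); r <- rnorm(50)
  oracle <- 0
  for (j in seq_along(y)) oracle <- oracle + (y[j] - r[j])^2
  expect_equal(measure_distance(y, r), oracle, tolerance = 1e-12)
  expect_identical(measure_distance(y, r), measure_distance(r, y))
  expect_error(measure_distance(1:3, 1:4), "lengths differ")
})

test_that("a single unit recovers a lone compound exactly", {
  sim <- fx_one()
  fit <- fit_single_unit(sim$W, gaussian_reference(c(30, 5), 101))
  expect_lt(fit$epsilon, 1e-6)
  expect_gt(abs(cor(fit$curve$values, sim$S[1, ])), 0.9999)
  expect_true(fit$converged)
  # the deterministic start is already the optimum: no extra iterations
  expect_lte(fit$iterations, 2L)
  # unit norm after the fit
  expect_equal(sum(fit$weight$b^2), 1, tolerance = 1e-10)

  # a displaced reference fits strictly worse
  off <- fit_single_unit(sim$W, gaussian_reference(c(45, 5), 101))
  expect_gt(off$epsilon, fit$epsilon)
})

test_that("fitness is memoised, nonnegative and deterministic", {
  ds <- fx_five()
  cache <- fitness_cache()
  v1 <- picarc_fitness(c(90, 10), ds$W, cache = cache)
  v2 <- picarc_fitness(c(90, 10), ds$W, cache = cache)
  expect_identical(v1, v2)
  expect_identical(length(ls(cache)), 1L)
  # byte-identical without a cache too (deterministic init)
  expect_identical(v1, picarc_fitness(c(90, 10), ds$W))

  set.seed(8)
  g <- parameter_grid(241)
  pick <- g[sample(nrow(g), 20), ]
  for (i in seq_len(nrow(pick)))
    expect_gte(picarc_fitness(c(pick$mu[i], pick$sigma[i]), ds$W,
                              cache = ds$cache), 0)
})

test_that("every generating theta is a clear fitness minimum", {
  ds <- fx_five()
  for (i in seq_len(nrow(five_truth()))) {
    mu <- five_truth()[i, 1]; sg <- five_truth()[i, 2]
    f0 <- picarc_fitness(c(mu, sg), ds$W, cache = ds$cache)
    nb <- c(picarc_fitness(c(mu - 3, sg), ds$W, cache = ds$cache),
            picarc_fitness(c(mu + 3, sg), ds$W, cache = ds$cache),
            picarc_fitness(c(mu, sg - 3), ds$W, cache = ds$cache),
            picarc_fitness(c(mu, sg + 3), ds$W, cache = ds$cache))
    expect_lt(f0, min(nb))
  }
})

test_that("the least-squares surface has minima exactly at the truth", {
  ds <- fx_two()
  mins <- surface_local_minima(
    fitness_surface(ds$W, fit_options(fitness_mode = "ls")), 101)
  expect_equal(as.matrix(mins[order(mins$mu), c("mu", "sigma")]),
               matrix(c(30L, 60L, 5L, 8L), 2), ignore_attr = TRUE)
})

test_that("joint refinement recovers all generating curves", {
  ds <- fx_five()
  ref <- parallel_refine(five_truth(), ds$W)
  expect_identical(theta_matrix(ref$thetas), five_truth())
  for (i in 1:5) {
    expect_lt(mean((ref$Y_star[i, ] - ds$S[i, ])^2), 1e-4)
    expect_gt(max(ref$Y_star[i, ]), 0)
  }
  # refinement of a single unit reduces to the single-unit fit
  one <- parallel_refine(list(c(90, 10)), ds$W)
  single <- fit_single_unit(ds$W, gaussian_reference(c(90, 10), 241))
  expect_equal(drop(one$Y_star), single$curve$values, tolerance = 1e-8)
})

test_that("symmetric decorrelation orthogonalises the directions", {
  ds <- fx_five()
  ref <- parallel_refine(five_truth(), ds$W, decorrelate = TRUE)
  expect_lt(max(abs(crossprod(ref$B) - diag(5))), 1e-6)
})

test_that("degenerate unit sets are rejected", {
  ds <- fx_five()
  expect_error(parallel_refine(rbind(c(90, 10), c(90, 10)), ds$W),
               "distinct")
})
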