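test_that("the pseudo-inverse estimator inverts the bilinear model", {
  ds <- fx_five()
  A <- estimate_spectra(ds$X, ds$S)
  expect_lt(max(abs(A - ds$A)), 1e-8)

  # orthogonal peak rows: compare against explicit normal equations
  S <- rbind(c(1, 0, 0, 1, 0, 0, 1, 0), c(0, 1, 0, 0, 1, 0, 0, 1))
  A0 <- matrix(c(1, 2, 3, 4), 2, 2)
  X <- A0 %*% S
  oracle <- X %*% t(S) %*% solve(S %*% t(S))
  expect_equal(estimate_spectra(chromatogram(X), S), oracle,
               tolerance = 1e-10, ignore_attr = TRUE)

  # one compound: closed form X s' / ||s||^2
  s <- matrix(gaussian_reference(c(30, 5), 101)$values, 1)
  a0 <- matrix(c(0.3, 1, 0.7), 3)
  X1 <- a0 %*% s
  expect_equal(estimate_spectra(chromatogram(X1), s),
               X1 %*% t(s) / sum(s^2), tolerance = 1e-12,
               ignore_attr = TRUE)

  expect_error(estimate_spectra(ds$X, rbind(ds$S, ds$S[1, ])),
               "collinear")
})

test_that("evaluation matches compounds and is permutation-invariant", {
  ds <- fx_five()
  truth <- list(thetas = ds$thetas, S = ds$S, A = ds$A)
  ident <- list(thetas = ds$thetas, peaks = ds$S, spectra = ds$A)
  ev <- evaluate_separation(ident, truth)
  expect_identical(ev$table$recovered, ev$table$true)
  expect_true(all(ev$table$curve_error == 0))
  expect_true(all(ev$table$spectrum_error == 0))
  expect_identical(ev$unmatched_true, integer(0))

  perm <- c(3, 1, 5, 2, 4)
  shuffled <- list(thetas = ds$thetas[perm], peaks = ds$S[perm, ],
                   spectra = ds$A[, perm])
  ev2 <- evaluate_separation(shuffled, truth)
  expect_true(all(ev2$table$curve_error == 0))
  expect_identical(ev2$table$true, ev$table$true)

  # evaluation is invariant to positive rescaling of recovered curves
  scaled <- list(thetas = ds$thetas, peaks = 3.7 * ds$S,
                 spectra = 0.2 * ds$A)
  ev3 <- evaluate_separation(scaled, truth)
  expect_lt(max(ev3$table$curve_error), 1e-28)
})

test_that("a constant offset on a unit-scaled curve scores as its square", {
  t <- 101
  s <- gaussian_reference(c(30, 5), t)$values
  truth <- list(thetas = list(c(30, 5)), S = matrix(s, 1),
                A = matrix(c(1, 0.5), 2))
  # recovered curve carries a +0.01 constant offset; same spectrum
  result <- list(thetas = list(c(30, 5)),
                 peaks = matrix(s + 0.01, 1),
                 spectra = matrix(c(1, 0.5), 2))
  ev <- evaluate_separation(result, truth)
  # direct-arithmetic oracle (both curves unit-maximum-scaled)
  offset_mse <- mean(((s + 0.01) / max(s + 0.01) - s)^2)
  expect_equal(ev$table$curve_error, offset_mse, tolerance = 1e-12)
  # a ~0.01 pointwise discrepancy scores ~1e-4
  expect_lt(abs(log10(ev$table$curve_error) - (-4)), 1)
})
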