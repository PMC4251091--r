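test_that("whitening yields zero-mean, identity-covariance components", {
  set.seed(42)
  X <- matrix(rnorm(4 * 2000), 4, 2000)
  W <- center_whiten(X)
  expect_identical(W$k, 4L)
  expect_lt(max(abs(rowMeans(W$X_tilde))), 1e-10)

  # covariance recomputed with an explicit loop oracle
  k <- W$k; t <- W$t
  C <- matrix(0, k, k)
  for (i in seq_len(k)) for (j in seq_len(k))
    C[i, j] <- sum(W$X_tilde[i, ] * W$X_tilde[j, ]) / t
  expect_lt(max(abs(C - diag(k))), 0.1)
  expect_lt(max(abs(C - diag(k))), 1e-8)   # exact by construction

  # the whitening matrix inverts the covariance on the retained subspace
  Xc <- X - rowMeans(X)
  expect_lt(max(abs(W$Dw %*% (tcrossprod(Xc) / t) %*% t(W$Dw) - diag(k))),
            1e-8)
})

test_that("a noiseless n-compound mixture retains exactly n components", {
  two <- make_dataset(simulation_spec(thetas = rbind(c(20, 3), c(60, 6)),
                                      t = 101, m = 5, seed = 2))
  expect_identical(center_whiten(two$X)$k, 2L)
  expect_identical(fx_five()$W$k, 5L)
})

test_that("degenerate input is rejected", {
  expect_error(center_whiten(matrix(3.7, 4, 50)), "constant input")
})

test_that("augmented matrices carry the offset as the model requires", {
  W <- fx_one()$W
  expect_true(all(W$X_tilde_prime[W$k + 1L, ] == 0))
  expect_true(all(W$X_tilde_dprime[W$k + 1L, ] == 1))

  # y = b'X + d; the all-ones row carries d, the all-zeros row kills it
  set.seed(1)
  b <- rnorm(W$k); b <- b / sqrt(sum(b^2)); d <- 2.3
  w <- augmented_weight(b, d = d)
  y <- raw_output(W, w)
  expect_equal(y, drop(c(b, d) %*% W$X_tilde_dprime), tolerance = 1e-14)
  expect_equal(y - d, drop(c(b, d) %*% W$X_tilde_prime), tolerance = 1e-14)

  # d = 0 reduces to the plain projection; a coordinate weight reads a row
  expect_equal(raw_output(W, augmented_weight(b)),
               drop(crossprod(b, W$X_tilde)), tolerance = 1e-14)
  e1 <- augmented_weight(c(1, rep(0, W$k - 1L)), d = 5)
  expect_equal(raw_output(W, e1), W$X_tilde[1, ] + 5, tolerance = 1e-14)

  expect_error(raw_output(W, augmented_weight(rep(1, W$k + 2L))),
               "does not match")
})

test_that("weights are normalised to the unit sphere", {
  w <- augmented_weight(c(3, 4))
  expect_equal(sqrt(sum(w$b^2)), 1, tolerance = 1e-10)
  expect_equal(w$b, c(0.6, 0.8))
  expect_error(augmented_weight(c(0, 0)), "nonzero")
})
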