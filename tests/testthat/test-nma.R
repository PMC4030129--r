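test_that("a connected network has exactly six rigid-body modes", {
  net <- buildNetwork(makeHelix(20), cutoff = 8)
  modes <- computeModes(anmHessian(net))
  expect_equal(numZeroModes(modes), 6L)
  expect_false(modes@disconnected)
  # eigenvectors orthonormal
  g <- crossprod(modes@vectors)
  expect_lt(max(abs(g - diag(ncol(g)))), 1e-8)
  expect_true(all(modeValues(modes) > 0))
})

test_that("two disconnected fragments carry six zero modes each", {
  frag <- makeHelix(5)@coords
  both <- rbind(frag, sweep(frag, 2L, c(100, 0, 0), "+"))
  net <- suppressWarnings(buildNetwork(both, cutoff = 8))
  expect_warning(modes <- computeModes(anmHessian(net)), "disconnected")
  expect_equal(numZeroModes(modes), 12L)
  expect_true(modes@disconnected)
})

test_that("the dimer has a single internal mode of eigenvalue 2*gamma", {
  # hand result for the 6x6 two-bead Hessian: the stretch mode has
  # curvature 2*gamma in mass-unweighted coordinates
  for (g in c(1, 2.5)) {
    modes <- computeModes(anmHessian(dimerNet(3.8, gamma = g)))
    expect_equal(numZeroModes(modes), 5L)  # one spring constrains 1 of 6 dof
    expect_equal(modeValues(modes), 2 * g, tolerance = 1e-10)
  }
})

test_that("mode covariance matches the Hessian pseudoinverse", {
  net <- randomConnectedNet(12, seed = 4)
  modes <- computeModes(anmHessian(net))
  temp <- 298
  cc1 <- modeCovariance(modes, 1L, temp)
  expect_equal(sum(diag(cc1)), kB * temp / modeValues(modes)[1])
  expect_equal(qr(cc1, tol = 1e-10)$rank, 1L)
  # all nonzero modes vs pseudoinverse oracle
  ccAll <- modeCovariance(modes, temperature = temp)
  h <- anmHessian(net)
  e <- eigen(h, symmetric = TRUE)
  keep <- e$values > 1e-8 * max(e$values)
  pinv <- e$vectors[, keep] %*% (t(e$vectors[, keep]) / e$values[keep])
  expect_lt(max(abs(ccAll - kB * temp * pinv)) / max(abs(ccAll)), 1e-6)
  # linear in temperature
  expect_equal(modeCovariance(modes, 1:3, 2 * temp),
               2 * modeCovariance(modes, 1:3, temp))
  # requesting a zero mode is an error
  expect_error(modeCovariance(modes, 0L), "range")
})

test_that("NMA B-factors scale as 1/gamma and match the pseudoinverse", {
  net1 <- randomConnectedNet(10, seed = 5, gamma = 1)
  net3 <- buildNetwork(net1@refCoords, cutoff = 8, gamma = 3)
  m1 <- computeModes(anmHessian(net1))
  m3 <- computeModes(anmHessian(net3))
  b1 <- bfactors(nmaBfactors(m1))
  b3 <- bfactors(nmaBfactors(m3))
  expect_equal(b1 / 3, b3, tolerance = 1e-8)
  cc <- modeCovariance(m1, temperature = 298)
  msf <- vapply(seq_len(10), function(i) {
    ii <- (3 * (i - 1) + 1):(3 * i)
    sum(diag(cc[ii, ii]))
  }, 0)
  expect_equal(unname(b1), (8 * pi^2 / 3) * msf)
})

test_that("the inserted domain is the most flexible unit of the benchmark", {
  syn <- makeTwoDomainStructure(seed = 1)
  m <- syn$model
  net <- buildNetwork(m, cutoff = 10, weightExponent = 2.5)
  modes <- computeModes(anmHessian(net))
  b <- bfactors(nmaBfactors(modes, resid = residLabels(m)))
  expect_gt(mean(b[domainIndices(m, "insert")]),
            mean(b[domainIndices(m, "core")]))
})

test_that("the NMA cross-correlation map honors its contracts", {
  net <- randomConnectedNet(12, seed = 6)
  modes <- computeModes(anmHessian(net))
  d <- nmaDccm(modes, 1:3)
  m <- correlations(d)
  expect_equal(diag(m), rep(1, 12))
  expect_equal(m, t(m))
  expect_true(all(abs(m) <= 1 + 1e-12))
  # temperature cancels in the normalization
  expect_equal(correlations(nmaDccm(modes, 1:3, temperature = 100)), m)
  # uniform gamma rescaling cancels too
  netS <- buildNetwork(net@refCoords, cutoff = 8, gamma = 7)
  expect_equal(correlations(nmaDccm(computeModes(anmHessian(netS)), 1:3)), m,
               tolerance = 1e-6)
  # two-bead spring: the single internal (stretch) mode anticorrelates
  dd <- correlations(nmaDccm(computeModes(anmHessian(dimerNet(3.8))), 1L))
  expect_equal(dd[1L, 2L], -1)
})

test_that("core and inserted domain move in opposite directions", {
  syn <- makeTwoDomainStructure(seed = 1)
  m <- syn$model
  net <- buildNetwork(m, cutoff = 10, weightExponent = 2.5)
  d <- correlations(nmaDccm(computeModes(anmHessian(net)), 1:3))
  ci <- domainIndices(m, "core")
  ii <- domainIndices(m, "insert")
  expect_lt(mean(d[ci, ii]), 0)
})
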