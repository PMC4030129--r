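rigidTransform <- function(x, th, shift) {
  rot <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  sweep(x %*% rot, 2L, shift, "+")
}

test_that("superposition recovers rigid transforms exactly", {
  ref <- coords(makeHelix(12))
  frames <- lapply(1:5, function(i)
    rigidTransform(ref, th = 0.3 * i, shift = c(i, -i, 2 * i)))
  tr <- superpose(trajectory(frames), ref)
  expect_true(tr@superposed)
  for (f in 1:5)
    expect_lt(sqrt(mean((tr@xyz[f, ] - as.numeric(t(ref)))^2)), 1e-6)
  # idempotence on an aligned trajectory
  tr2 <- superpose(tr, ref)
  expect_lt(max(abs(tr2@xyz - tr@xyz)), 1e-8)
})

test_that("superposition agrees with an independent least-squares fit", {
  skip_if_not_installed("bio3d")
  ref <- coords(makeHelix(9))
  set.seed(31)
  frames <- lapply(1:4, function(i)
    rigidTransform(ref + matrix(rnorm(27, sd = 0.5), 9L, 3L), 0.9 * i,
                   c(3, 1, -2) * i))
  tr <- superpose(trajectory(frames), ref)
  fitted <- bio3d::fit.xyz(as.numeric(t(ref)),
                           do.call(rbind, lapply(frames, function(f)
                             as.numeric(t(f)))),
                           fixed.inds = 1:27, mobile.inds = 1:27)
  expect_lt(max(abs(tr@xyz - fitted)), 1e-6)
})

test_that("reflections are never applied as superpositions", {
  ref <- rbind(c(0, 0, 0), c(3.8, 0, 0), c(3.8, 3.8, 0), c(0, 0, 3.8))
  mirrored <- ref %*% diag(c(-1, 1, 1))
  tr <- superpose(trajectory(list(mirrored)), ref)
  # a proper rotation cannot undo a reflection of a chiral set
  rmsd <- sqrt(mean((tr@xyz[1L, ] - as.numeric(t(ref)))^2))
  expect_gt(rmsd, 0.5)
})

test_that("degenerate fit selections are rejected", {
  ref <- coords(makeHelix(10))
  tr <- trajectory(list(ref))
  expect_error(superpose(tr, ref, fitSelection = 1:2), "at least 3")
  collinear <- matrix(c(0, 0, 0, 1, 0, 0, 2, 0, 0), 3L, 3L, byrow = TRUE)
  tr2 <- trajectory(list(collinear))
  expect_error(superpose(tr2, collinear), "collinear")
})

test_that("covariance PCA conserves variance and demands superposition", {
  set.seed(41)
  frames <- lapply(1:50, function(i) matrix(rnorm(15), 5L, 3L))
  expect_error(covariancePCA(trajectory(frames)), "superpose")
  tr <- trajectory(frames, superposed = TRUE)
  pca <- covariancePCA(tr, burnInFraction = 0)
  xc <- sweep(tr@xyz, 2L, colMeans(tr@xyz))
  expect_equal(sum(modeValues(pca@modes)), mean(rowSums(xc^2)),
               tolerance = 1e-8)
  # projections of the mean are zero
  expect_lt(max(abs(colMeans(pca@projections))), 1e-10)
  # constant trajectory: all eigenvalues zero
  tr0 <- trajectory(lapply(1:12, function(i) coords(makeHelix(5))),
                    superposed = TRUE)
  expect_equal(max(covariancePCA(tr0, 0)@modes@values), 0)
})

test_that("burn-in drops the leading fraction of frames", {
  set.seed(42)
  frames <- lapply(1:30, function(i) matrix(rnorm(9), 3L, 3L))
  pca <- covariancePCA(trajectory(frames, superposed = TRUE),
                       burnInFraction = 1 / 6)
  expect_equal(pca@framesUsed, 6:30)
})

test_that("PCA of a thermal ensemble recovers the generating mode", {
  net <- buildNetwork(makeTwoDomainStructure(seed = 2)$model, cutoff = 8)
  modes <- computeModes(anmHessian(net))
  tr <- sampleAnmEnsemble(modes, net@refCoords, nFrames = 5000L,
                          kList = 1L, seed = 5)
  pca <- covariancePCA(tr, burnInFraction = 0)
  expect_gt(overlap(modeVector(modes, 1L), modeVector(pca@modes, 1L)), 0.99)
})

test_that("cluster selection prefers many conformations per unit spread", {
  # two separated clouds along a single coordinate: 600 broad, 300 tight
  set.seed(51)
  v <- c(1, rep(0, 14))
  z <- c(rnorm(600, -30, 6), rnorm(300, 30, 0.5))
  xyz <- outer(z, v)
  pca <- covariancePCA(trajectory(xyz, superposed = TRUE), 0)
  cl <- clusterSelect(pca, nComponents = 1L, gridBins = 20L)
  expect_gt(length(unique(cl@labels)), 1L)
  tightFrames <- which(cl@labels == cl@selected)
  expect_true(all(tightFrames > 600L))  # the tight cloud wins on density
  # unimodal cloud: one cluster holding nearly everything
  z1 <- rnorm(500)
  pca1 <- covariancePCA(trajectory(outer(z1, v), superposed = TRUE), 0)
  cl1 <- clusterSelect(pca1, nComponents = 1L)
  expect_gte(sum(cl1@labels == cl1@selected) / 500, 0.95)
})

test_that("cluster selection is invariant to frame order", {
  set.seed(52)
  v <- c(1, rep(0, 11))
  z <- c(rnorm(200, -10, 2), rnorm(100, 10, 0.4))
  xyz <- outer(z, v)
  perm <- sample(length(z))
  pcaA <- covariancePCA(trajectory(xyz, superposed = TRUE), 0)
  pcaB <- covariancePCA(trajectory(xyz[perm, ], superposed = TRUE), 0)
  clA <- clusterSelect(pcaA, 1L)
  clB <- clusterSelect(pcaB, 1L)
  selA <- which(clA@labels == clA@selected)
  selB <- perm[which(clB@labels == clB@selected)]
  expect_setequal(selA, selB)
})

test_that("identical frames collapse to one trivially selected bin", {
  frames <- lapply(1:15, function(i) coords(makeHelix(4)))
  pca <- covariancePCA(trajectory(frames, superposed = TRUE), 0)
  cl <- clusterSelect(pca)
  expect_equal(length(unique(cl@labels)), 1L)
  expect_equal(cl@selected, 1L)
})

test_that("clustering fewer than 10 frames is refused", {
  set.seed(53)
  frames <- lapply(1:8, function(i) matrix(rnorm(9), 3L, 3L))
  pca <- covariancePCA(trajectory(frames, superposed = TRUE), 0)
  expect_error(clusterSelect(pca), "fewer than 10")
})

test_that("trajectory DCCM: opposed motion, null noise, full-rank identity", {
  # two beads translated oppositely frame to frame
  set.seed(61)
  amp <- rnorm(200)
  frames <- lapply(amp, function(a)
    rbind(c(a, 0, 0), c(10 - a, 0, 0)))
  pca <- covariancePCA(trajectory(frames, superposed = TRUE), 0)
  d <- suppressWarnings(edaDccm(pca, 1L))
  expect_equal(correlations(d)[1L, 2L], -1)
  # independent beads: off-diagonals vanish with 1e4 frames
  set.seed(62)
  xyz <- matrix(rnorm(1e4 * 18), 1e4, 18L)
  pcaN <- covariancePCA(trajectory(xyz, superposed = TRUE), 0)
  dn <- correlations(edaDccm(pcaN, reconstruction = FALSE))
  offdiag <- dn[upper.tri(dn)]
  expect_lt(max(abs(offdiag)), 0.05)
  # full-rank reconstruction equals the raw-frame DCCM
  dr <- correlations(edaDccm(pcaN, modeList = 1:18, reconstruction = TRUE))
  expect_equal(dr, dn, tolerance = 1e-8)
})

test_that("trajectory B-factors are zero for a frozen chain and scale
           quadratically with amplitude", {
  tr0 <- trajectory(lapply(1:12, function(i) coords(makeHelix(6))),
                    superposed = TRUE)
  expect_equal(unname(bfactors(edaBfactors(tr0))), rep(0, 6))
  set.seed(63)
  dev <- matrix(rnorm(20 * 9), 20L, 9L)
  base <- as.numeric(t(coords(makeHelix(3))))
  tr1 <- trajectory(sweep(dev, 2L, base, "+"), superposed = TRUE)
  tr2 <- trajectory(sweep(2 * dev, 2L, base, "+"), superposed = TRUE)
  expect_equal(bfactors(edaBfactors(tr2)), 4 * bfactors(edaBfactors(tr1)))
})

test_that("ensemble B-factors agree with the generating normal modes", {
  net <- buildNetwork(makeTwoDomainStructure(seed = 2)$model, cutoff = 8)
  modes <- computeModes(anmHessian(net))
  tr <- sampleAnmEnsemble(modes, net@refCoords, nFrames = 5000L, seed = 6)
  bn <- bfactors(nmaBfactors(modes))
  bt <- bfactors(edaBfactors(tr))
  expect_gt(cor(bn, bt), 0.95)
})
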