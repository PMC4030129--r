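test_that("displacement overlap obeys its closed forms", {
  set.seed(71)
  v <- matrix(rnorm(30), 10L, 3L)
  expect_equal(overlap(v, v), 1)
  expect_equal(overlap(v, -v), 1)          # sign-invariant
  expect_equal(overlap(v, 3.7 * v), 1)     # scale-invariant
  a <- matrix(c(1, 0, 0), 1L, 3L)
  b <- matrix(c(0, 1, 0), 1L, 3L)
  expect_equal(overlap(a, b), 0)
  expect_equal(overlap(a, matrix(c(1, 1, 0) / sqrt(2), 1L, 3L)), 0.70711,
               tolerance = 1e-5)
  expect_error(overlap(v, 0 * v), "zero displacement")
  expect_error(overlap(v, matrix(rnorm(9), 3L, 3L)), "bead counts")
})

test_that("overlap matches the independent normal-mode implementation", {
  skip_if_not_installed("bio3d")
  set.seed(72)
  net <- randomConnectedNet(10, seed = 7)
  modes <- computeModes(anmHessian(net))
  dv <- rnorm(30)
  ref <- bio3d::overlap(modes@vectors, dv, nmodes = ncol(modes@vectors))
  mine <- vapply(seq_len(ncol(modes@vectors)), function(k)
    overlap(matrix(modes@vectors[, k], ncol = 3L, byrow = TRUE),
            matrix(dv, ncol = 3L, byrow = TRUE)), 0)
  # bio3d reports the squared normalized inner product
  expect_equal(mine^2, ref$overlap, tolerance = 1e-8)
})

test_that("a mode set against itself gives unit overlaps everywhere", {
  net <- randomConnectedNet(12, seed = 8)
  modes <- computeModes(anmHessian(net))
  tab <- modeOverlapTable(modes, modes, nModes = 3L,
                          domains = list(left = 1:6, right = 7:12))
  expect_equal(nrow(tab), 12L)  # 3 scopes x (3 modes + average)
  expect_equal(tab$overlap, rep(1, 12L), tolerance = 1e-10)
})

test_that("PCA of an ANM ensemble recovers the mode set index by index", {
  syn <- makeTwoDomainStructure(seed = 1)
  net <- buildNetwork(syn$model, cutoff = 8)
  modes <- computeModes(anmHessian(net))
  tr <- sampleAnmEnsemble(modes, net@refCoords, nFrames = 5000L, seed = 9)
  pca <- covariancePCA(tr, burnInFraction = 0)
  ii <- domainIndices(syn$model, "insert")
  tab <- modeOverlapTable(modes, pca@modes, nModes = 3L,
                          domains = list(insert = ii))
  diag3 <- tab$overlap[tab$scope == "full" & tab$mode != "Average"]
  expect_true(all(diag3 >= 0.9))
  insert3 <- tab$overlap[tab$scope == "insert" & tab$mode != "Average"]
  expect_true(all(insert3 >= 0.8))
  expect_equal(tab$overlap[tab$mode == "Average" & tab$scope == "full"],
               mean(diag3))
})

test_that("a rigid (zero-displacement) domain surfaces as NA, not a value", {
  vecs <- diag(12)  # 4 beads; mode 1 moves only bead 1's x
  modes <- new("ModeSet", values = rep(1, 12), vectors = vecs,
               nZero = 0L, source = "pca", disconnected = FALSE)
  expect_warning(
    tab <- modeOverlapTable(modes, modes, nModes = 1L,
                            domains = list(still = 3:4)),
    "zero displacement")
  expect_true(is.na(tab$overlap[tab$scope == "still" & tab$mode == "1"]))
})

test_that("z-scoring centers and scales with the population SD", {
  p <- new("BFactorProfile", values = c(1, 2, 3), normalization = "raw",
           source = "crystal", resid = c("1", "2", "3"))
  z <- normalizeBfactors(p)
  expect_equal(z@values, c(-1.2247449, 0, 1.2247449), tolerance = 1e-6)
  expect_equal(normalizeBfactors(z), z)  # idempotent
  flat <- new("BFactorProfile", values = rep(5, 4), normalization = "raw",
              source = "nma", resid = as.character(1:4))
  expect_error(normalizeBfactors(flat), "constant")
  # normalization preserves correlation between profiles
  set.seed(81)
  a <- new("BFactorProfile", values = runif(20, 1, 50),
           normalization = "raw", source = "nma",
           resid = as.character(1:20))
  b <- new("BFactorProfile", values = runif(20, 1, 50),
           normalization = "raw", source = "eda",
           resid = as.character(1:20))
  expect_equal(cor(normalizeBfactors(a)@values, normalizeBfactors(b)@values),
               cor(a@values, b@values))
})

test_that("B-factor differences are antisymmetric and alignment-checked", {
  mk <- function(v, resid = as.character(seq_along(v)))
    normalizeBfactors(new("BFactorProfile", values = v,
                          normalization = "raw", source = "eda",
                          resid = resid))
  a <- mk(c(1, 5, 2, 8))
  b <- mk(c(2, 3, 9, 1))
  expect_equal(unname(bfactorDelta(a, a)), rep(0, 4))
  expect_equal(bfactorDelta(a, b), -bfactorDelta(b, a))
  cRaw <- new("BFactorProfile", values = 1:4, normalization = "raw",
              source = "eda", resid = as.character(1:4))
  expect_error(bfactorDelta(a, cRaw), "normalize")
  d <- mk(c(1, 2, 3, 4), resid = c("1", "2", "3", "99"))
  expect_error(bfactorDelta(a, d), "99")
})

test_that("the composite DCCM pairs methods and summarizes blocks", {
  set.seed(82)
  base <- stats::cov2cor(crossprod(matrix(rnorm(400), 40L, 10L)))
  m1 <- new("DCCM", matrix = base, method = "eda", provenance = "x",
            zeroGuard = integer())
  half <- base * 0.5
  diag(half) <- 1
  m2 <- new("DCCM", matrix = half, method = "nma", provenance = "y",
            zeroGuard = integer())
  same <- dccmPairReport(m1, m1,
                         regions = list(ab = list(rows = 1:4, cols = 5:10)))
  expect_equal(same$composite, base)
  expect_equal(diff(same$blocks$meanCC), 0)
  rep2 <- dccmPairReport(m1, m2,
                         regions = list(ab = list(rows = 1:4, cols = 5:10)))
  expect_equal(rep2$blocks$meanAbsCC[2L] / rep2$blocks$meanAbsCC[1L], 0.5)
  # upper triangle from m1, lower from m2
  expect_equal(rep2$composite[1L, 2L], base[1L, 2L])
  expect_equal(rep2$composite[2L, 1L], half[2L, 1L])
})

test_that("both coarse-grained routes see the anticorrelated hinge", {
  syn <- makeTwoDomainStructure(seed = 1)
  m <- syn$model
  ci <- domainIndices(m, "core")
  ii <- domainIndices(m, "insert")
  netN <- buildNetwork(m, cutoff = 10, weightExponent = 2.5)
  dN <- nmaDccm(computeModes(anmHessian(netN)), 1:3)
  netC <- buildNetwork(m, cutoff = 8)
  modesC <- computeModes(anmHessian(netC))
  tr <- sampleAnmEnsemble(modesC, netC@refCoords, nFrames = 3000L, seed = 4)
  dE <- edaDccm(covariancePCA(tr, 0), 1:3, method = "eda")
  rep <- dccmPairReport(dE, dN, regions = list(
    coreXinsert = list(rows = ci, cols = ii)))
  expect_lt(rep$blocks$meanCC[1L], 0)
  expect_lt(rep$blocks$meanCC[2L], 0)
})
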