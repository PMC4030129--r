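# Synthetic structures and ensembles with known ground truth: a compact
# two-domain Calpha chain (flexible domain inserted into a rigid core via
# two linkers) and Gaussian thermal ensembles of a given elastic network.

# Evaluate expr with a reproducible RNG state, restoring the caller's
# stream afterwards so the generators are pure functions of their seed.
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else rm(".Random.seed", envir = globalenv())
  })
  force(expr)
}

.minDistTo <- function(placed, p) {
  if (!nrow(placed)) return(Inf)
  sqrt(min(rowSums(sweep(placed, 2L, p)^2)))
}

# Self-avoiding biased random walk of n beads confined to a sphere.
# biasFun(t, pos) may return a drift vector added to the random direction;
# acceptFun(cand) may impose an extra region constraint (e.g. a half-space).
.confinedWalk <- function(n, start, center, radius, bondLength, clash,
                          placed, biasFun = NULL, acceptFun = NULL,
                          maxTry = 120L) {
  walk <- matrix(NA_real_, n, 3L)
  walk[1L, ] <- start
  if (n == 1L) return(walk)
  for (t in 2:n) {
    ok <- FALSE
    for (trial in seq_len(maxTry)) {
      dir <- rnorm(3L)
      # soft confinement: pull back toward the sphere center when outside
      off <- walk[t - 1L, ] - center
      r <- sqrt(sum(off^2))
      if (r > 0.8 * radius) dir <- dir - 2.5 * (r / radius) * off / r
      if (!is.null(biasFun)) dir <- dir + biasFun(t, walk[t - 1L, ])
      dir <- dir / sqrt(sum(dir^2))
      cand <- walk[t - 1L, ] + bondLength * dir
      if (sqrt(sum((cand - center)^2)) > radius) next
      if (!is.null(acceptFun) && !acceptFun(cand)) next
      if (.minDistTo(placed, cand) < clash) next
      if (t > 2L &&
          .minDistTo(walk[seq_len(t - 2L), , drop = FALSE], cand) < clash)
        next
      walk[t, ] <- cand
      ok <- TRUE
      break
    }
    if (!ok) return(NULL)
  }
  walk
}

#' Synthetic two-domain Calpha structure
#'
#' Generates, deterministically per seed, a compact chain that emulates
#' the architecture of a flexible domain inserted into a rigid core: a
#' densely packed core (self-avoiding walk confined to a sphere), split
#' at its midpoint by an excursion — linker, loosely packed inserted
#' domain in a displaced sphere, linker — before the chain returns to the
#' core. Consecutive beads sit at the Calpha virtual-bond distance and
#' the chain is self-avoiding at the clash distance. Under a contact
#' cutoff of 8-10 A the inserted domain has strictly lower mean contact
#' degree than the core, which is what makes it the soft, mobile unit in
#' every downstream analysis.
#'
#' @param nCore beads in the rigid core.
#' @param nInsert beads in the inserted domain (0 gives a single-domain
#'   control).
#' @param linkerLength beads per linker (two linkers).
#' @param bondLength consecutive-bead distance, Angstrom.
#' @param compactness core packing scale: the core sphere radius is
#'   compactness * nCore^(1/3) Angstrom (the insert sphere is 80% more
#'   dilute).
#' @param clash self-avoidance distance, Angstrom.
#' @param seed RNG seed; the generator is a pure function of it.
#' @return list with `model` (a \linkS4class{CalphaModel}, domains
#'   tagged) and `domains` (list of \linkS4class{DomainDefinition}:
#'   "core" and, when present, "insert").
#' @export
makeTwoDomainStructure <- function(nCore = 60L, nInsert = 30L,
                                   linkerLength = 3L, bondLength = 3.8,
                                   compactness = 3.0, clash = 2.0,
                                   seed = 1L) {
  stopifnot(nCore >= 2L, nInsert >= 0L, linkerLength >= 1L,
            bondLength > clash, compactness > 0)
  .withSeed(seed, {
    coreR <- compactness * nCore^(1 / 3)
    res <- NULL
    for (attempt in seq_len(50L)) {
      res <- .tryTwoDomain(nCore, nInsert, linkerLength, bondLength,
                           compactness, clash, coreR)
      if (!is.null(res)) break
    }
    if (is.null(res))
      stop("could not generate a self-avoiding two-domain chain; ",
           "try a larger compactness")
    n <- nrow(res$coords)
    resname <- sample(names(.RESIDUE_MASS), n, replace = TRUE)
    model <- calphaModel(res$coords, resno = seq_len(n), resname = resname)
    model <- assignDomains(model, res$defs)
    list(model = model, domains = res$defs)
  })
}

.tryTwoDomain <- function(nCore, nInsert, linkerLength, bondLength,
                          compactness, clash, coreR) {
  core <- .confinedWalk(nCore, start = c(0, 0, 0), center = c(0, 0, 0),
                        radius = coreR, bondLength = bondLength,
                        clash = clash, placed = matrix(0, 0L, 3L))
  if (is.null(core)) return(NULL)
  if (nInsert == 0L) {
    defs <- list(domainDefinition("core", 1L, nCore))
    return(list(coords = core, defs = defs))
  }
  insR <- 1.8 * compactness * max(nInsert, 8L)^(1 / 3)
  # attach at the outermost bead of the middle third of the core chain, so
  # the excursion leaves from the core surface rather than its interior
  mid3 <- seq.int(max(2L, nCore %/% 3L), min(nCore - 1L, 2L * (nCore %/% 3L)))
  h <- mid3[which.max(rowSums(core[mid3, , drop = FALSE]^2))]
  a <- core[h, ]; b <- core[h + 1L, ]
  u <- a / sqrt(sum(a^2))
  # the inserted domain packs against a cap of the core surface (as
  # inserted editing/CP domains do) instead of dangling as a quasi-free
  # pendulum: its walk is confined to the half-space beyond the core and
  # to a sphere abutting the surface
  planeOff <- coreR
  center <- u * (planeOff + 0.55 * insR)
  inHalf <- function(p) sum(p * u) >= planeOff
  # first linker: biased walk from the attachment bead into the half-space
  l1bias <- function(t, pos) 2.2 * u
  walk1 <- .confinedWalk(linkerLength + 2L, start = a, center = center,
                         radius = planeOff + 2 * insR,
                         bondLength = bondLength, clash = clash,
                         placed = core, biasFun = l1bias)
  if (is.null(walk1)) return(NULL)
  start <- walk1[linkerLength + 2L, ]     # first insert bead
  linker1 <- walk1[2:(linkerLength + 1L), , drop = FALSE]
  if (!inHalf(start) || sqrt(sum((start - center)^2)) > insR) return(NULL)
  placed <- rbind(core, linker1)
  # return point for the second linker, above the core re-entry bead
  target <- b + u * bondLength * (linkerLength + 1) * 0.8
  span <- c(2.6, 4.4) * (linkerLength + 1)  # admissible |q - b|
  insert <- NULL
  for (tryIns in seq_len(60L)) {
    bias <- function(t, pos) {
      w <- max(0, (t - 0.55 * nInsert) / (0.45 * nInsert))
      dirv <- target - pos
      nv <- sqrt(sum(dirv^2))
      if (nv < 1e-9) return(c(0, 0, 0))
      1.8 * w * dirv / nv
    }
    cand <- .confinedWalk(nInsert, start = start, center = center,
                          radius = insR, bondLength = bondLength,
                          clash = clash, placed = placed, biasFun = bias,
                          acceptFun = inHalf)
    if (is.null(cand)) next
    endDist <- sqrt(sum((cand[nInsert, ] - b)^2))
    if (endDist < span[1L] || endDist > span[2L]) next
    insert <- cand
    break
  }
  if (is.null(insert)) return(NULL)
  q <- insert[nInsert, ]
  steps <- seq_len(linkerLength) / (linkerLength + 1)
  # interpolate, then jitter off the straight line: exactly collinear
  # contacts would give a bead a spurious zero-frequency direction
  axis <- (b - q) / sqrt(sum((b - q)^2))
  perp <- .orthobasis(axis)
  jit <- matrix(runif(2L * linkerLength, -0.6, 0.6), linkerLength, 2L)
  linker2 <- t(vapply(seq_len(linkerLength), function(k)
    q + (b - q) * steps[k] + perp %*% jit[k, ], numeric(3L)))
  placed <- rbind(placed, insert)
  for (k in seq_len(linkerLength))
    if (.minDistTo(placed, linker2[k, ]) < clash) return(NULL)
  coordsAll <- rbind(core[seq_len(h), , drop = FALSE], linker1, insert,
                     linker2, core[(h + 1L):nCore, , drop = FALSE])
  i1 <- h + linkerLength + 1L
  i2 <- h + linkerLength + nInsert
  nTot <- nrow(coordsAll)
  defs <- list(
    domainDefinition("core", c(1L, i2 + linkerLength + 1L), c(h, nTot)),
    domainDefinition("insert", i1, i2))
  list(coords = coordsAll, defs = defs)
}

#' Ideal helical Calpha trace
#'
#' A regular-geometry fixture: beads on an alpha-helical parametric curve
#' (default rise 1.5 A, radius 2.3 A, 100 degrees per residue), giving
#' the usual ~3.8 A consecutive spacing and a banded contact map under a
#' short cutoff.
#'
#' @param n number of beads.
#' @param rise rise per residue, Angstrom.
#' @param radius helix radius, Angstrom.
#' @param turn rotation per residue, degrees.
#' @return a \linkS4class{CalphaModel}.
#' @export
makeHelix <- function(n, rise = 1.5, radius = 2.3, turn = 100) {
  stopifnot(n >= 2L)
  th <- (seq_len(n) - 1L) * turn * pi / 180
  coords <- cbind(radius * cos(th), radius * sin(th),
                  rise * (seq_len(n) - 1L))
  calphaModel(coords)
}

#' Sample a Gaussian thermal ensemble of an elastic network
#'
#' Draws frames from the analytic thermal distribution of the selected
#' modes: frame = mean + sum_k sqrt(kB T / lambda_k) z_k v_k with z_k iid
#' standard normal. The sample covariance converges to
#' \code{\link{modeCovariance}} as the number of frames grows, so the
#' ensemble is a ground-truth input for essential-dynamics recovery
#' tests. Frames are generated about the mean (no rigid-body noise), so
#' the trajectory is born superposed.
#'
#' @param modes an ANM \linkS4class{ModeSet}.
#' @param meanCoords N x 3 mean structure (the network reference).
#' @param temperature K.
#' @param nFrames number of frames.
#' @param kList nonzero-mode indices (default all).
#' @param seed RNG seed.
#' @return a \linkS4class{Trajectory} with origin "ensemble_sample".
#' @export
sampleAnmEnsemble <- function(modes, meanCoords, temperature = 298,
                              nFrames = 1000L, kList = NULL, seed = 1L) {
  if (is(meanCoords, "CalphaModel")) meanCoords <- coords(meanCoords)
  meanCoords <- as.matrix(meanCoords)
  if (is.null(kList))
    kList <- seq_len(length(modes@values) - modes@nZero)
  cols <- .resolveModeCols(modes, kList)
  if (3L * nrow(meanCoords) != nrow(modes@vectors))
    stop("meanCoords does not match the mode dimension")
  amp <- sqrt(.KB_KCAL * temperature / modes@values[cols])
  v <- modes@vectors[, cols, drop = FALSE]
  .withSeed(seed, {
    z <- matrix(rnorm(nFrames * length(cols)), nFrames, length(cols))
    xyz <- sweep(z, 2L, amp, "*") %*% t(v)
    xyz <- sweep(xyz, 2L, .flatten(meanCoords), "+")
    trajectory(xyz, dt = 1, origin = "ensemble_sample", superposed = TRUE,
               meta = list(seed = seed, temperature = temperature,
                           kList = as.integer(kList)))
  })
}

# two unit vectors orthogonal to axis (columns of a 3 x 2 matrix)
.orthobasis <- function(axis) {
  ref <- if (abs(axis[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  p1 <- ref - sum(ref * axis) * axis
  p1 <- p1 / sqrt(sum(p1^2))
  p2 <- c(axis[2L] * p1[3L] - axis[3L] * p1[2L],
          axis[3L] * p1[1L] - axis[1L] * p1[3L],
          axis[1L] * p1[2L] - axis[2L] * p1[1L])
  cbind(p1, p2)
}
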