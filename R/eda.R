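# Essential dynamics: superposition, covariance PCA, PC-space cluster
# selection, and trajectory-derived DCCMs / B-factors.

.kabsch <- function(mobile, fixed) {
  # optimal proper rotation (det +1) minimizing RMSD after centering
  cm <- colMeans(mobile)
  cf <- colMeans(fixed)
  a <- sweep(mobile, 2L, cm)
  b <- sweep(fixed, 2L, cf)
  s <- svd(crossprod(a, b))   # 3x3
  d <- sign(det(s$u %*% t(s$v)))
  corr <- diag(c(1, 1, d))
  rot <- s$u %*% corr %*% t(s$v)
  list(rotation = rot, shiftMobile = cm, shiftFixed = cf)
}

#' Superpose trajectory frames onto a reference
#'
#' Removes overall translation and rotation: each frame is least-squares
#' fitted to the reference with the optimal proper rotation (Kabsch
#' algorithm; reflections are never applied). Fitting can be restricted
#' to a bead subset (e.g. a rigid core) while the transform is applied to
#' all beads.
#'
#' @param traj a \linkS4class{Trajectory}.
#' @param reference N x 3 reference coordinates (or a
#'   \linkS4class{CalphaModel}).
#' @param fitSelection optional bead indices to fit on (default all).
#' @return the superposed \linkS4class{Trajectory} (`superposed` flag set).
#' @export
superpose <- function(traj, reference, fitSelection = NULL) {
  if (is(reference, "CalphaModel")) reference <- coords(reference)
  reference <- as.matrix(reference)
  if (nrow(reference) != nBeads(traj))
    stop("reference bead count does not match the trajectory")
  if (is.null(fitSelection)) fitSelection <- seq_len(nBeads(traj))
  if (length(fitSelection) < 3L)
    stop("need at least 3 beads to define a superposition")
  sel <- as.integer(fitSelection)
  refSel <- reference[sel, , drop = FALSE]
  if (qr(sweep(refSel, 2L, colMeans(refSel)))$rank < 2L)
    stop("degenerate (collinear) fit selection")
  xyz <- traj@xyz
  for (f in seq_len(nrow(xyz))) {
    fr <- .unflatten(xyz[f, ])
    k <- .kabsch(fr[sel, , drop = FALSE], refSel)
    fitted <- sweep(sweep(fr, 2L, k$shiftMobile) %*% k$rotation, 2L,
                    k$shiftFixed, FUN = "+")
    xyz[f, ] <- .flatten(fitted)
  }
  out <- traj
  out@xyz <- xyz
  out@superposed <- TRUE
  out@velocities <- matrix(0, 0L, ncol(xyz))  # rotated velocities dropped
  out
}

#' Essential dynamics: PCA of the coordinate covariance
#'
#' Discards an initial burn-in fraction of frames (equilibration), then
#' eigendecomposes the covariance matrix of the 3N Cartesian coordinates
#' about their mean. Principal components are returned as a
#' \linkS4class{ModeSet} with source "pca" (eigenvalues descending, A^2);
#' projections are the centered frames on the eigenvectors. The
#' trajectory must be superposed first (or generated directly about a
#' mean, as thermal ensembles are).
#'
#' @param traj a superposed \linkS4class{Trajectory}.
#' @param burnInFraction fraction of leading frames to drop (default 1/6,
#'   the 5-of-30 convention scaled to any run length).
#' @param zeroTolRel relative threshold flagging negligible-variance PCs.
#' @return a \linkS4class{PCAResult}.
#' @export
covariancePCA <- function(traj, burnInFraction = 1 / 6, zeroTolRel = 1e-10) {
  if (!traj@superposed)
    stop("trajectory is not superposed: call superpose() first")
  if (burnInFraction < 0 || burnInFraction >= 1)
    stop("burnInFraction must be in [0, 1)")
  nf <- nFrames(traj)
  drop <- floor(nf * burnInFraction)
  keep <- seq.int(drop + 1L, nf)
  if (length(keep) < 2L)
    stop("need at least 2 frames after burn-in")
  x <- traj@xyz[keep, , drop = FALSE]
  mu <- colMeans(x)
  xc <- sweep(x, 2L, mu)
  cc <- crossprod(xc) / nrow(xc)   # population covariance (1/n)
  e <- eigen(cc, symmetric = TRUE) # descending
  vals <- pmax(e$values, 0)
  nZero <- sum(vals < zeroTolRel * max(vals, .Machine$double.eps))
  modes <- new("ModeSet", values = vals, vectors = e$vectors,
               nZero = as.integer(nZero), source = "pca",
               disconnected = FALSE)
  new("PCAResult", meanCoords = .unflatten(mu), modes = modes,
      projections = xc %*% e$vectors, framesUsed = as.integer(keep))
}

# connected components of occupied bins under face adjacency in k dims
.binClusters <- function(binIdx) {
  keys <- apply(binIdx, 1L, paste, collapse = ",")
  uk <- unique(keys)
  ub <- binIdx[match(uk, keys), , drop = FALSE]
  nb <- nrow(ub)
  lab <- integer(nb)
  cur <- 0L
  lookup <- setNames(seq_len(nb), uk)
  kdim <- ncol(ub)
  for (s in seq_len(nb)) {
    if (lab[s]) next
    cur <- cur + 1L
    queue <- s
    lab[s] <- cur
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      for (d in seq_len(kdim)) for (step in c(-1L, 1L)) {
        nbr <- ub[v, ]
        nbr[d] <- nbr[d] + step
        hit <- lookup[paste(nbr, collapse = ",")]
        if (!is.na(hit) && !lab[hit]) {
          lab[hit] <- cur
          queue <- c(queue, hit)
        }
      }
    }
  }
  lab[match(keys, uk)]
}

#' Select the densest conformational cluster in PC space
#'
#' Frames are histogram-binned in the leading principal components;
#' clusters are connected occupied bins (face adjacency). Each cluster is
#' scored by its number of conformations per unit fluctuation — frames
#' divided by the RMS spread of their projections — and the
#' highest-density cluster is selected (ties break to the lowest cluster
#' id). The spread is floored at half a bin width, so a cluster confined
#' to a single bin (in the limit, a single frame) cannot claim infinite
#' density; a fully degenerate trajectory still selects its one bin
#' trivially.
#'
#' @param pca a \linkS4class{PCAResult}.
#' @param nComponents number of leading PCs to bin (default 3).
#' @param gridBins bins per PC axis (default 20).
#' @return a \linkS4class{ClusterSelection}.
#' @export
clusterSelect <- function(pca, nComponents = 3L, gridBins = 20L) {
  proj <- pca@projections
  if (nrow(proj) < 10L)
    stop("fewer than 10 frames: clustering is meaningless")
  nComponents <- min(as.integer(nComponents), ncol(proj))
  p <- proj[, seq_len(nComponents), drop = FALSE]
  binIdx <- matrix(1L, nrow(p), nComponents)
  for (d in seq_len(nComponents)) {
    rng <- range(p[, d])
    if (diff(rng) > 0) {
      cut <- (p[, d] - rng[1L]) / diff(rng)
      binIdx[, d] <- pmin(as.integer(floor(cut * gridBins)) + 1L, gridBins)
    }
  }
  lab <- .binClusters(binIdx)
  ids <- sort(unique(lab))
  # a cluster occupying one bin cannot claim a spread below the bin scale;
  # without this floor a singleton frame would score infinite density
  widths <- apply(p, 2L, function(v) diff(range(v))) / gridBins
  floorSpread <- 0.5 * mean(widths)
  scores <- vapply(ids, function(id) {
    inC <- lab == id
    q <- p[inC, , drop = FALSE]
    ctr <- colMeans(q)
    spread <- max(sqrt(mean(rowSums(sweep(q, 2L, ctr)^2))), floorSpread)
    if (spread <= .Machine$double.eps) Inf else sum(inC) / spread
  }, 0)
  selected <- ids[which.max(scores)]  # which.max takes the first maximum
  new("ClusterSelection", labels = as.integer(lab),
      selected = as.integer(selected), scores = scores,
      framesUsed = pca@framesUsed)
}

.subsetRows <- function(pca, frameSubset) {
  if (is.null(frameSubset)) return(seq_len(nrow(pca@projections)))
  if (is(frameSubset, "ClusterSelection")) {
    if (!identical(frameSubset@framesUsed, pca@framesUsed))
      stop("cluster selection was computed on a different frame set")
    return(which(frameSubset@labels == frameSubset@selected))
  }
  as.integer(frameSubset)
}

#' Dynamic cross-correlation map from a trajectory
#'
#' Residue-pair fluctuation correlations (vector form of the
#' cross-correlation coefficient) from essential dynamics. By default the
#' covariance is reconstructed from the leading PCs (1-3), mirroring the
#' combined-modes convention of the normal-mode DCCM; set
#' `reconstruction = FALSE` to use the raw frame covariance. An optional
#' \linkS4class{ClusterSelection} restricts the analysis to the selected
#' cluster's frames.
#'
#' @param pca a \linkS4class{PCAResult}.
#' @param modeList PC indices for the reconstruction (default 1:3).
#' @param frameSubset optional \linkS4class{ClusterSelection} or frame
#'   index vector (into the PCA's frame set).
#' @param reconstruction use the rank-|modeList| PC reconstruction (TRUE)
#'   or the raw frame covariance (FALSE).
#' @param method tag stored in the result (default "eda").
#' @return a \linkS4class{DCCM}.
#' @export
edaDccm <- function(pca, modeList = 1:3, frameSubset = NULL,
                    reconstruction = TRUE, method = "eda") {
  rows <- .subsetRows(pca, frameSubset)
  xc <- pca@projections[rows, , drop = FALSE] %*% t(pca@modes@vectors)
  xc <- sweep(xc, 2L, colMeans(xc))
  if (reconstruction) {
    modeList <- as.integer(modeList)
    if (any(modeList < 1L) || any(modeList > ncol(pca@projections)))
      stop("PC index out of range")
    v <- pca@modes@vectors[, modeList, drop = FALSE]
    lam <- colMeans((xc %*% v)^2)          # subset variance along each PC
    cc <- v %*% (lam * t(v))
    prov <- sprintf("EDA PCs %s (reconstruction), %d frames",
                    paste(modeList, collapse = ","), length(rows))
  } else {
    cc <- crossprod(xc) / nrow(xc)
    prov <- sprintf("EDA raw covariance, %d frames", length(rows))
  }
  .dccmFromCovariance(cc, method, prov)
}

#' B-factor profile from a trajectory
#'
#' B_i = (8 pi^2 / 3) times the mean-square deviation of bead i from its
#' mean position over the analyzed frames.
#'
#' @param traj a superposed \linkS4class{Trajectory} or a
#'   \linkS4class{PCAResult}.
#' @param frameSubset optional \linkS4class{ClusterSelection} (PCAResult
#'   input) or frame index vector.
#' @param resid residue labels (default 1..N).
#' @param source tag for the profile (default "eda").
#' @return a \linkS4class{BFactorProfile} (raw, A^2).
#' @export
edaBfactors <- function(traj, frameSubset = NULL, resid = NULL,
                        source = "eda") {
  if (is(traj, "PCAResult")) {
    rows <- .subsetRows(traj, frameSubset)
    x <- traj@projections[rows, , drop = FALSE] %*% t(traj@modes@vectors)
  } else {
    if (!traj@superposed)
      stop("trajectory is not superposed: call superpose() first")
    rows <- if (is.null(frameSubset)) seq_len(nFrames(traj))
            else as.integer(frameSubset)
    x <- traj@xyz[rows, , drop = FALSE]
  }
  mu <- colMeans(x)
  dev2 <- sweep(x, 2L, mu)^2
  n <- ncol(x) %/% 3L
  msf <- vapply(seq_len(n), function(i) {
    cols <- (3L * (i - 1L) + 1L):(3L * i)
    mean(rowSums(dev2[, cols, drop = FALSE]))
  }, 0)
  b <- .B_FROM_MSF * msf
  if (is.null(resid)) resid <- as.character(seq_len(n))
  new("BFactorProfile", values = b, normalization = "raw", source = source,
      resid = as.character(resid))
}
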