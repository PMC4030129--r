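#' Build an elastic network from a Calpha model
#'
#' Two beads are in contact when their reference distance is below the
#' cutoff; every contact carries a harmonic spring. With distance-weight
#' exponent p the spring constant of a contact at reference distance r0 is
#' gamma * r0^(-p); p = 0 is the uniform-spring network used for
#' coarse-grained dynamics (cutoff 8 A, gamma 1 kcal mol^-1 A^-2), while
#' the ANM normal-mode parameterization uses cutoff 10 A with p = 2.5.
#'
#' @param model a \linkS4class{CalphaModel}, or an N x 3 coordinate matrix.
#' @param cutoff contact cutoff r_c, Angstrom (> 0).
#' @param gamma uniform spring constant, kcal mol^-1 A^-2.
#' @param weightExponent dimensionless distance-weight exponent p >= 0.
#' @return an \linkS4class{ElasticNetwork}. A disconnected contact graph
#'   gives a warning (and is recorded in the object), not an error.
#' @export
buildNetwork <- function(model, cutoff = 8, gamma = 1, weightExponent = 0) {
  if (cutoff <= 0) stop("cutoff must be positive")
  if (gamma <= 0) stop("gamma must be positive")
  if (weightExponent < 0) stop("weightExponent must be >= 0")
  if (is(model, "CalphaModel")) {
    xyz <- coords(model)
    m <- masses(model)
  } else {
    xyz <- as.matrix(model)
    m <- rep(.MASS_FALLBACK, nrow(xyz))
  }
  n <- nrow(xyz)
  if (n < 2L) stop("need at least 2 beads")
  d <- as.matrix(stats::dist(xyz))
  hit <- which(upper.tri(d) & d > 0 & d < cutoff, arr.ind = TRUE)
  edges <- cbind(i = as.integer(hit[, 1L]), j = as.integer(hit[, 2L]))
  ord <- order(edges[, 1L], edges[, 2L])
  edges <- edges[ord, , drop = FALSE]
  refDist <- d[edges]
  pairGamma <- gamma * refDist^(-weightExponent)
  connected <- .graphConnected(n, edges)
  if (!connected)
    warning("elastic network is disconnected at this cutoff")
  new("ElasticNetwork", refCoords = xyz, gamma = as.numeric(gamma),
      cutoff = as.numeric(cutoff), weightExponent = as.numeric(weightExponent),
      edges = edges, refDist = refDist, pairGamma = pairGamma,
      connected = connected, masses = m)
}

.graphConnected <- function(n, edges) {
  if (!nrow(edges)) return(n == 1L)
  seen <- logical(n)
  adj <- vector("list", n)
  for (k in seq_len(nrow(edges))) {
    i <- edges[k, 1L]; j <- edges[k, 2L]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  queue <- 1L
  seen[1L] <- TRUE
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    nb <- adj[[v]]
    fresh <- nb[!seen[nb]]
    seen[fresh] <- TRUE
    queue <- c(queue, fresh)
  }
  all(seen)
}

.checkCoords <- function(net, x) {
  x <- as.matrix(x)
  if (!identical(dim(x), dim(net@refCoords)))
    stop(sprintf("coordinate shape %d x %d does not match the network (%d x 3)",
                 nrow(x), ncol(x), nBeads(net)))
  x
}

#' Elastic-network potential energy
#'
#' Sum over unordered contact pairs of (k_ij / 2) (r_ij - r_ij0)^2, where
#' k_ij is the per-contact spring constant. Zero at the reference
#' structure and invariant under rigid rotation and translation.
#'
#' @param net an \linkS4class{ElasticNetwork}.
#' @param x N x 3 coordinates, Angstrom.
#' @return energy, kcal mol^-1.
#' @export
enmEnergy <- function(net, x) {
  x <- .checkCoords(net, x)
  if (!nrow(net@edges)) return(0)
  r <- .pairDist(x, net@edges[, 1L], net@edges[, 2L])
  sum(0.5 * net@pairGamma * (r - net@refDist)^2)
}

#' Elastic-network forces
#'
#' Analytic gradient of \code{\link{enmEnergy}}: F = -dE/dx. Total force
#' and total torque vanish (the potential depends only on internal
#' distances).
#'
#' @inheritParams enmEnergy
#' @return N x 3 forces, kcal mol^-1 A^-1.
#' @export
enmForces <- function(net, x) {
  x <- .checkCoords(net, x)
  f <- matrix(0, nrow(x), 3L)
  if (!nrow(net@edges)) return(f)
  i <- net@edges[, 1L]; j <- net@edges[, 2L]
  dvec <- x[j, , drop = FALSE] - x[i, , drop = FALSE]
  r <- sqrt(rowSums(dvec^2))
  if (any(r < 1e-10))
    stop("coincident bonded beads: singular geometry (r_ij = 0)")
  # force on i along +dvec with magnitude k (r - r0)
  scale <- net@pairGamma * (r - net@refDist) / r
  fi <- dvec * scale
  for (c in 1:3) {
    f[, c] <- f[, c] +
      tapply2(fi[, c], i, nrow(x)) - tapply2(fi[, c], j, nrow(x))
  }
  f
}

# fast grouped sum into a length-n vector
tapply2 <- function(v, idx, n) {
  out <- numeric(n)
  acc <- rowsum(v, idx)
  out[as.integer(rownames(acc))] <- acc
  out
}

#' Anisotropic-network-model Hessian
#'
#' The 3N x 3N second-derivative matrix of the network potential at the
#' reference structure: off-diagonal super-elements
#' H_ij = -(k_ij / r_ij0^2) (r_ij0 outer r_ij0) for contacts, diagonal
#' super-elements minus the sum of the row's off-diagonal blocks
#' (translational sum rule). Symmetric and positive semidefinite.
#'
#' @param net an \linkS4class{ElasticNetwork}.
#' @return a 3N x 3N numeric matrix, kcal mol^-1 A^-2.
#' @export
anmHessian <- function(net) {
  n <- nBeads(net)
  h <- matrix(0, 3L * n, 3L * n)
  if (nrow(net@edges)) {
    for (k in seq_len(nrow(net@edges))) {
      i <- net@edges[k, 1L]; j <- net@edges[k, 2L]
      dv <- net@refCoords[j, ] - net@refCoords[i, ]
      blk <- -(net@pairGamma[k] / net@refDist[k]^2) * tcrossprod(dv)
      ii <- (3L * (i - 1L) + 1L):(3L * i)
      jj <- (3L * (j - 1L) + 1L):(3L * j)
      h[ii, jj] <- h[ii, jj] + blk
      h[jj, ii] <- h[jj, ii] + blk
      h[ii, ii] <- h[ii, ii] - blk
      h[jj, jj] <- h[jj, jj] - blk
    }
  }
  h
}

#' Export a network's springs as an edge-list table
#'
#' @param net an \linkS4class{ElasticNetwork}.
#' @return data.frame with columns i, j, refDist, pairGamma.
#' @export
networkEdges <- function(net) {
  data.frame(i = net@edges[, 1L], j = net@edges[, 2L],
             refDist = net@refDist, pairGamma = net@pairGamma)
}
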