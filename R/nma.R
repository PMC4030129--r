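#' Normal modes of an ANM Hessian
#'
#' Dense symmetric eigendecomposition, eigenvalues ascending. Modes with
#' eigenvalue below `zeroTolRel` times the largest eigenvalue are flagged
#' as near-zero rigid-body modes; a connected network has exactly six
#' (three translations, three rotations). More than six indicates a
#' disconnected network and is recorded (with a warning), since each rigid
#' fragment contributes six.
#'
#' @param h 3N x 3N Hessian from \code{\link{anmHessian}}.
#' @param zeroTolRel relative zero-mode threshold (default 1e-8).
#' @return a \linkS4class{ModeSet} with source "anm". "Mode k" in all
#'   downstream functions means the k-th nonzero (internal) mode.
#' @export
computeModes <- function(h, zeroTolRel = 1e-8) {
  h <- as.matrix(h)
  if (nrow(h) != ncol(h) || nrow(h) %% 3L != 0L)
    stop("Hessian must be 3N x 3N")
  if (max(abs(h - t(h))) > 1e-8 * max(1, max(abs(h))))
    stop("Hessian must be symmetric")
  e <- eigen((h + t(h)) / 2, symmetric = TRUE)
  vals <- rev(e$values)
  vecs <- e$vectors[, rev(seq_len(ncol(e$vectors))), drop = FALSE]
  lmax <- max(vals)
  if (lmax <= 0) stop("Hessian has no positive eigenvalue")
  nZero <- sum(vals < zeroTolRel * lmax)
  vals[seq_len(nZero)] <- pmax(vals[seq_len(nZero)], 0)
  disconnected <- nZero > 6L
  if (disconnected)
    warning(sprintf(
      "%d near-zero modes: the network has %d disconnected rigid fragments",
      nZero, nZero %/% 6L))
  new("ModeSet", values = vals, vectors = vecs, nZero = as.integer(nZero),
      source = "anm", disconnected = disconnected)
}

.resolveModeCols <- function(modes, kList) {
  kList <- as.integer(kList)
  if (!length(kList)) stop("empty mode selection")
  if (modes@source == "anm") {
    cols <- modes@nZero + kList
    if (any(kList < 1L) ||
        any(cols > length(modes@values)))
      stop("mode index out of range (indices count nonzero modes)")
  } else {
    cols <- kList
    nAvail <- length(modes@values) - modes@nZero
    if (any(kList < 1L) || any(kList > nAvail))
      stop("PC index out of range")
  }
  if (any(modes@values[cols] <= 0))
    stop("zero mode requested: thermal amplitude is undefined")
  cols
}

#' Thermal covariance restricted to selected modes
#'
#' For an ANM mode set at temperature T, the positional covariance carried
#' by modes k in `kList` is C = kB T * sum_k lambda_k^-1 v_k v_k^T
#' (Angstrom^2); with all nonzero modes it equals kB T times the
#' pseudoinverse of the Hessian. Modes are thermally weighted (soft modes
#' dominate), which is what "thermal fluctuations" of an elastic network
#' mean.
#'
#' @param modes a \linkS4class{ModeSet} with source "anm".
#' @param kList indices of nonzero modes (1 = softest internal mode).
#' @param temperature K.
#' @return 3N x 3N covariance matrix, A^2; PSD of rank length(kList).
#' @export
modeCovariance <- function(modes, kList = NULL, temperature = 298) {
  if (modes@source != "anm")
    stop("modeCovariance expects ANM modes; PCA modes already carry variances")
  if (is.null(kList))
    kList <- seq_len(length(modes@values) - modes@nZero)
  cols <- .resolveModeCols(modes, kList)
  v <- modes@vectors[, cols, drop = FALSE]
  w <- .KB_KCAL * temperature / modes@values[cols]
  v %*% (w * t(v))
}

.bfactorsFromCovariance <- function(cc) {
  n <- nrow(cc) %/% 3L
  msf <- vapply(seq_len(n), function(i) {
    ii <- (3L * (i - 1L) + 1L):(3L * i)
    sum(diag(cc[ii, ii, drop = FALSE]))
  }, 0)
  .B_FROM_MSF * msf
}

#' B-factors from ANM normal modes
#'
#' B_i = (8 pi^2 / 3) <dr_i^2>, with the mean-square fluctuation taken
#' from the thermal mode covariance (all nonzero modes by default,
#' matching the convention of reporting thermal fluctuations over all
#' principal modes; pass `kList` to restrict).
#'
#' @inheritParams modeCovariance
#' @param resid residue labels for the profile (default 1..N).
#' @return a \linkS4class{BFactorProfile} (source "nma", raw A^2).
#' @export
nmaBfactors <- function(modes, temperature = 298, kList = NULL,
                        resid = NULL) {
  cc <- modeCovariance(modes, kList, temperature)
  b <- .bfactorsFromCovariance(cc)
  if (is.null(resid)) resid <- as.character(seq_along(b))
  new("BFactorProfile", values = b, normalization = "raw", source = "nma",
      resid = as.character(resid))
}

.dccmFromCovariance <- function(cc, method, provenance) {
  n <- nrow(cc) %/% 3L
  tr <- vapply(seq_len(n), function(i) {
    ii <- (3L * (i - 1L) + 1L):(3L * i)
    sum(diag(cc[ii, ii, drop = FALSE]))
  }, 0)
  m <- matrix(0, n, n)
  for (i in seq_len(n)) {
    ii <- (3L * (i - 1L) + 1L):(3L * i)
    for (j in i:n) {
      jj <- (3L * (j - 1L) + 1L):(3L * j)
      m[i, j] <- m[j, i] <- sum(diag(cc[ii, jj, drop = FALSE]))
    }
  }
  zero <- which(tr <= .Machine$double.eps * max(tr, 1))
  denom <- sqrt(outer(tr, tr))
  denom[denom == 0] <- Inf
  m <- m / denom
  if (length(zero)) {
    warning(sprintf(
      "%d bead(s) with zero fluctuation in the selected subspace; correlations zeroed",
      length(zero)))
    m[zero, ] <- 0
    m[, zero] <- 0
  }
  m <- pmin(pmax(m, -1), 1)
  m[cbind(seq_len(n), seq_len(n))] <- ifelse(seq_len(n) %in% zero, 0, 1)
  new("DCCM", matrix = m, method = method, provenance = provenance,
      zeroGuard = as.integer(zero))
}

#' Dynamic cross-correlation map from ANM modes
#'
#' Cross-correlation of residue fluctuations in the subspace of the
#' selected modes (combined modes 1-3 by default): the vector form
#' CC_ij = tr(C_ij) / sqrt(tr(C_ii) tr(C_jj)) of the per-coordinate
#' correlation coefficient. Positive values mark residues moving in the
#' same direction, negative values opposite directions. The normalization
#' cancels the temperature.
#'
#' @inheritParams modeCovariance
#' @param kList nonzero-mode indices (default 1:3).
#' @return a \linkS4class{DCCM} with method "nma".
#' @export
nmaDccm <- function(modes, kList = 1:3, temperature = 298) {
  cc <- modeCovariance(modes, kList, temperature)
  .dccmFromCovariance(cc, "nma",
                      sprintf("ANM modes %s", paste(kList, collapse = ",")))
}
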