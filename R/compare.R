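# Cross-method comparison: normalized displacement overlaps, B-factor
# tracks, and paired DCCM reports.

.asField <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) == 1L) x <- .unflatten(as.numeric(x))
  if (ncol(x) != 3L) stop("a displacement field must be N x 3 (or 3N)")
  if (!all(is.finite(x))) stop("displacement field must be finite")
  x
}

#' Overlap between two displacement fields
#'
#' The normalized absolute inner product of two per-residue displacement
#' fields (Marques-Sanejouand form):
#' O = |sum_i dr_i^a . dr_i^b| / sqrt(sum_i |dr_i^a|^2 sum_i |dr_i^b|^2),
#' with the per-bead product the 3-vector dot product. O = 1 means the
#' two methods predict identical displacement directions (up to sign and
#' overall amplitude); O = 0 means orthogonal fields.
#'
#' @param a,b N x 3 displacement fields (3N vectors accepted).
#' @param selection optional bead indices to restrict the comparison to
#'   (e.g. a single domain).
#' @return overlap in [0, 1].
#' @export
overlap <- function(a, b, selection = NULL) {
  a <- .asField(a); b <- .asField(b)
  if (nrow(a) != nrow(b))
    stop("displacement fields have different bead counts")
  if (!is.null(selection)) {
    a <- a[selection, , drop = FALSE]
    b <- b[selection, , drop = FALSE]
  }
  na2 <- sum(a^2); nb2 <- sum(b^2)
  if (na2 <= 0 || nb2 <= 0)
    stop("overlap undefined: zero displacement field on the selection")
  abs(sum(a * b)) / sqrt(na2 * nb2)
}

.modeField <- function(modes, k) {
  if (is(modes, "ModeSet")) modeVector(modes, k) else .asField(modes)
}

#' Mode-overlap table between two mode sets
#'
#' Index-paired overlaps (mode k of set A vs mode/PC k of set B) for the
#' leading modes, over the full protein and optionally restricted to
#' domains, plus a per-scope "Average" row (the mean of the per-mode
#' overlaps). Both sets must index the same beads in the same order.
#' Set `bestMatch = TRUE` to additionally report, for each A mode, the B
#' mode with maximal overlap — a diagnostic that is never silently
#' substituted for the index pairing.
#'
#' @param setA,setB \linkS4class{ModeSet}s (ANM modes and/or PCs).
#' @param nModes number of leading modes to pair (default 3).
#' @param domains optional named list of bead-index vectors (see
#'   \code{\link{domainIndices}}).
#' @param bestMatch also compute maximum-overlap pairing diagnostics.
#' @return data.frame with columns scope, mode, overlap (and, with
#'   `bestMatch`, bestModeB and bestOverlap). Domain rows where either
#'   field is numerically zero carry NA with a warning rather than a
#'   value.
#' @export
modeOverlapTable <- function(setA, setB, nModes = 3L, domains = NULL,
                             bestMatch = FALSE) {
  nModes <- as.integer(nModes)
  scopes <- c(list(full = NULL), domains)
  rows <- list()
  for (s in seq_along(scopes)) {
    scopeName <- names(scopes)[s]
    sel <- scopes[[s]]
    ov <- numeric(nModes)
    for (k in seq_len(nModes)) {
      ov[k] <- tryCatch(
        overlap(.modeField(setA, k), .modeField(setB, k), sel),
        error = function(e) {
          warning(sprintf("scope '%s', mode %d: %s", scopeName, k,
                          conditionMessage(e)))
          NA_real_
        })
    }
    df <- data.frame(scope = scopeName, mode = c(as.character(seq_len(nModes)),
                                                 "Average"),
                     overlap = c(ov, mean(ov)))
    if (bestMatch) {
      nB <- ncol(setB@vectors) - if (setB@source == "anm") setB@nZero else 0L
      nB <- min(nB, max(10L, nModes))
      bm <- t(vapply(seq_len(nModes), function(k) {
        o <- vapply(seq_len(nB), function(kk) {
          tryCatch(overlap(.modeField(setA, k), .modeField(setB, kk), sel),
                   error = function(e) NA_real_)
        }, 0)
        c(which.max(o), max(o, na.rm = TRUE))
      }, numeric(2L)))
      df$bestModeB <- c(bm[, 1L], NA)
      df$bestOverlap <- c(bm[, 2L], NA)
    }
    rows[[s]] <- df
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Normalize a B-factor profile
#'
#' Z-score by default (mean 0, population SD 1 over beads with defined
#' values), so profiles with different absolute scales — crystallographic,
#' normal-mode, trajectory-derived — can be overlaid. Min-max scaling to
#' [0, 1] is available as an option. Idempotent on already-normalized
#' input; normalization preserves Pearson correlations between profiles.
#'
#' @param p a \linkS4class{BFactorProfile}.
#' @param method "zscore" or "minmax".
#' @return the normalized \linkS4class{BFactorProfile}.
#' @export
normalizeBfactors <- function(p, method = c("zscore", "minmax")) {
  method <- match.arg(method)
  if (p@normalization == method) return(p)
  v <- p@values
  ok <- !is.na(v)
  if (method == "zscore") {
    s <- sqrt(mean((v[ok] - mean(v[ok]))^2))  # population SD
    if (s <= 0) stop("cannot z-score a constant B-factor profile")
    v[ok] <- (v[ok] - mean(v[ok])) / s
  } else {
    rng <- range(v[ok])
    if (diff(rng) <= 0) stop("cannot min-max scale a constant profile")
    v[ok] <- (v[ok] - rng[1L]) / diff(rng)
  }
  p@values <- v
  p@normalization <- method
  p
}

#' Difference between two normalized B-factor profiles
#'
#' Elementwise bound minus unbound, matched on residue labels; useful for
#' locating flexibility changes on ligand binding. Both profiles must be
#' normalized (same method) so the difference is scale-free.
#'
#' @param bound,unbound normalized \linkS4class{BFactorProfile}s over the
#'   same residue set.
#' @return named numeric vector of per-residue differences.
#' @export
bfactorDelta <- function(bound, unbound) {
  if (bound@normalization == "raw" || unbound@normalization == "raw")
    stop("normalize both profiles first (see normalizeBfactors)")
  if (bound@normalization != unbound@normalization)
    stop("profiles use different normalizations")
  miss <- c(setdiff(bound@resid, unbound@resid),
            setdiff(unbound@resid, bound@resid))
  if (length(miss))
    stop("profiles cover different residues; unmatched: ",
         paste(unique(miss), collapse = ", "))
  u <- unbound@values[match(bound@resid, unbound@resid)]
  setNames(bound@values - u, bound@resid)
}

#' Composite DCCM and per-block comparison of two methods
#'
#' Builds the customary paired map — method 1 above the diagonal, method
#' 2 below — and, for optional rectangular residue blocks (e.g. inserted
#' domain vs catalytic core), reports each method's mean correlation and
#' mean absolute correlation, quantifying where one method sees stronger
#' coupled motion than the other.
#'
#' @param m1,m2 \linkS4class{DCCM}s over the same beads.
#' @param regions optional named list; each element a list with integer
#'   bead-index vectors `rows` and `cols`.
#' @return list with `composite` (N x N matrix, m1 upper / m2 lower) and
#'   `blocks` (data.frame: region, method, meanCC, meanAbsCC).
#' @export
dccmPairReport <- function(m1, m2, regions = NULL) {
  a <- correlations(m1); b <- correlations(m2)
  if (!identical(dim(a), dim(b)))
    stop("the two DCCMs have different dimensions")
  comp <- a
  comp[lower.tri(comp)] <- b[lower.tri(b)]
  blocks <- NULL
  if (length(regions)) {
    rows <- lapply(seq_along(regions), function(r) {
      reg <- regions[[r]]
      sub1 <- a[reg$rows, reg$cols, drop = FALSE]
      sub2 <- b[reg$rows, reg$cols, drop = FALSE]
      data.frame(
        region = rep(names(regions)[r] %||% as.character(r), 2L),
        method = c(m1@method, m2@method),
        meanCC = c(mean(sub1), mean(sub2)),
        meanAbsCC = c(mean(abs(sub1)), mean(abs(sub2))))
    })
    blocks <- do.call(rbind, rows)
    rownames(blocks) <- NULL
  }
  list(composite = comp, blocks = blocks)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
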