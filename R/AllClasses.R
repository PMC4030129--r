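#' Calpha bead model of a protein
#'
#' One bead per residue: coordinates, residue mass, experimental B-factor
#' (when present in the source PDB) and an optional domain tag. Bead order
#' follows file order, which is robust to renumbered PDB files; `resid`
#' labels carry author numbering with any insertion code appended.
#'
#' @slot resno integer author residue numbers.
#' @slot insert character insertion codes ("" when absent).
#' @slot chain character chain identifiers.
#' @slot resname character three-letter residue names.
#' @slot coords numeric N x 3 matrix, Angstrom.
#' @slot mass numeric residue masses, amu.
#' @slot bfactorExp numeric crystallographic B-factors, A^2 (NA if absent).
#' @slot domain character domain tags (NA when untagged).
#' @slot chainBreak logical TRUE where bead i starts a new chain segment.
#'
#' @exportClass CalphaModel
setClass("CalphaModel",
  representation(
    resno = "integer", insert = "character", chain = "character",
    resname = "character", coords = "matrix", mass = "numeric",
    bfactorExp = "numeric", domain = "character", chainBreak = "logical"
  )
)

setValidity("CalphaModel", function(object) {
  n <- nrow(object@coords)
  msg <- character()
  if (n < 2L) msg <- c(msg, "a CalphaModel needs at least 2 beads")
  if (ncol(object@coords) != 3L) msg <- c(msg, "coords must be N x 3")
  if (!all(is.finite(object@coords))) msg <- c(msg, "coords must be finite")
  for (s in c("resno", "insert", "chain", "resname", "mass", "bfactorExp",
              "domain", "chainBreak")) {
    if (length(slot(object, s)) != n)
      msg <- c(msg, sprintf("slot '%s' must have length %d", s, n))
  }
  if (any(!is.na(object@mass) & object@mass <= 0))
    msg <- c(msg, "masses must be strictly positive")
  if (length(msg)) msg else TRUE
})

#' Domain definition as inclusive residue-number intervals
#'
#' @slot name character(1) domain label.
#' @slot ranges integer matrix with columns start, end (inclusive, author
#'   residue numbering).
#' @exportClass DomainDefinition
setClass("DomainDefinition",
  representation(name = "character", ranges = "matrix")
)

setValidity("DomainDefinition", function(object) {
  r <- object@ranges
  if (length(object@name) != 1L || !nzchar(object@name))
    return("name must be a single non-empty string")
  if (nrow(r) < 1L || ncol(r) != 2L)
    return("ranges must be a non-empty matrix with columns start, end")
  if (any(r[, 2L] < r[, 1L]))
    return("each range must have end >= start")
  TRUE
})

#' Calpha trajectory
#'
#' Ordered frames of Calpha coordinates. Coordinates are stored in the flat
#' xyz convention (frames x 3N, per-bead triples) used across trajectory
#' tooling. `origin` records how the frames were produced; `superposed`
#' records whether rigid-body motion has been removed (essential-dynamics
#' routines require it).
#'
#' @slot xyz numeric nFrames x 3N matrix, Angstrom.
#' @slot nBeads integer(1).
#' @slot dt numeric(1) ps between saved frames.
#' @slot origin character(1) one of "cgmd", "ensemble_sample", "external".
#' @slot superposed logical(1).
#' @slot velocities numeric matrix (nFrames x 3N, A/ps) or 0-row when absent.
#' @slot meta list of provenance (seed, parameters) for reproducibility.
#' @exportClass Trajectory
setClass("Trajectory",
  representation(
    xyz = "matrix", nBeads = "integer", dt = "numeric", origin = "character",
    superposed = "logical", velocities = "matrix", meta = "list"
  )
)

setValidity("Trajectory", function(object) {
  msg <- character()
  if (ncol(object@xyz) != 3L * object@nBeads)
    msg <- c(msg, "xyz must have 3 * nBeads columns")
  if (nrow(object@xyz) < 1L) msg <- c(msg, "at least one frame required")
  if (!(length(object@dt) == 1L && object@dt > 0))
    msg <- c(msg, "dt must be a single positive number (ps)")
  if (!object@origin %in% c("cgmd", "ensemble_sample", "external"))
    msg <- c(msg, "origin must be cgmd, ensemble_sample or external")
  if (nrow(object@velocities) &&
      !identical(dim(object@velocities), dim(object@xyz)))
    msg <- c(msg, "velocities, when present, must match xyz dimensions")
  if (length(msg)) msg else TRUE
})

#' Elastic network over a Calpha model
#'
#' Reference coordinates plus the binary contact map within a cutoff and a
#' per-contact spring constant. With distance-weight exponent p the spring
#' of a contact at reference distance r0 is gamma * r0^(-p); p = 0 gives the
#' uniform-spring network.
#'
#' @slot refCoords numeric N x 3, Angstrom.
#' @slot gamma numeric(1) kcal mol^-1 A^-2.
#' @slot cutoff numeric(1) Angstrom.
#' @slot weightExponent numeric(1) dimensionless p >= 0.
#' @slot edges integer E x 2 matrix of contacts (i < j, 1-based).
#' @slot refDist numeric E reference distances, Angstrom.
#' @slot pairGamma numeric E per-contact spring constants.
#' @slot connected logical(1) contact graph connectivity.
#' @slot masses numeric N bead masses, amu.
#' @exportClass ElasticNetwork
setClass("ElasticNetwork",
  representation(
    refCoords = "matrix", gamma = "numeric", cutoff = "numeric",
    weightExponent = "numeric", edges = "matrix", refDist = "numeric",
    pairGamma = "numeric", connected = "logical", masses = "numeric"
  )
)

setValidity("ElasticNetwork", function(object) {
  msg <- character()
  n <- nrow(object@refCoords)
  if (n < 2L) msg <- c(msg, "need at least 2 beads")
  if (object@cutoff <= 0) msg <- c(msg, "cutoff must be positive")
  if (object@weightExponent < 0) msg <- c(msg, "weightExponent must be >= 0")
  if (nrow(object@edges)) {
    if (any(object@edges[, 1L] >= object@edges[, 2L]))
      msg <- c(msg, "edges must be stored with i < j")
    if (any(object@pairGamma <= 0))
      msg <- c(msg, "pair spring constants must be positive")
    if (length(object@refDist) != nrow(object@edges) ||
        length(object@pairGamma) != nrow(object@edges))
      msg <- c(msg, "refDist/pairGamma must align with edges")
  }
  if (length(object@masses) != n)
    msg <- c(msg, "masses must have one entry per bead")
  if (length(msg)) msg else TRUE
})

#' Set of normal modes or principal components
#'
#' Eigenpairs of an ANM Hessian (source "anm": eigenvalues ascending,
#' kcal mol^-1 A^-2, six near-zero rigid-body modes first for a connected
#' network) or of a trajectory covariance matrix (source "pca": eigenvalues
#' descending, A^2). "Mode k" means the k-th internal (nonzero) mode for
#' ANM and the k-th principal component for PCA.
#'
#' @slot values numeric eigenvalues in the source's canonical order.
#' @slot vectors numeric 3N x K matrix of unit eigenvectors (columns).
#' @slot nZero integer(1) number of near-zero modes.
#' @slot source character(1) "anm" or "pca".
#' @slot disconnected logical(1) TRUE when more than 6 zero modes were found.
#' @exportClass ModeSet
setClass("ModeSet",
  representation(
    values = "numeric", vectors = "matrix", nZero = "integer",
    source = "character", disconnected = "logical"
  )
)

setValidity("ModeSet", function(object) {
  msg <- character()
  if (length(object@values) != ncol(object@vectors))
    msg <- c(msg, "one eigenvalue per eigenvector column")
  if (!object@source %in% c("anm", "pca"))
    msg <- c(msg, "source must be 'anm' or 'pca'")
  if (object@source == "anm" && is.unsorted(object@values, strictly = FALSE))
    msg <- c(msg, "ANM eigenvalues must be ascending")
  if (object@source == "pca" && is.unsorted(rev(object@values)))
    msg <- c(msg, "PCA eigenvalues must be descending")
  if (length(msg)) msg else TRUE
})

#' Result of essential-dynamics PCA on a trajectory
#'
#' @slot meanCoords numeric N x 3 mean structure, Angstrom.
#' @slot modes \linkS4class{ModeSet} with source "pca".
#' @slot projections numeric frames x K matrix of PC projections, Angstrom.
#' @slot framesUsed integer indices of trajectory frames kept after burn-in.
#' @exportClass PCAResult
setClass("PCAResult",
  representation(
    meanCoords = "matrix", modes = "ModeSet", projections = "matrix",
    framesUsed = "integer"
  )
)

#' PC-space cluster selection
#'
#' Frames are histogram-binned in the leading PCs; clusters are connected
#' occupied bins; the cluster with the greatest number of conformations per
#' unit fluctuation (frames / RMS projection spread) is selected.
#'
#' @slot labels integer cluster id per analyzed frame.
#' @slot selected integer(1) id of the selected cluster.
#' @slot scores numeric density score per cluster (frames * A^-1).
#' @slot framesUsed integer trajectory frame indices the labels refer to.
#' @exportClass ClusterSelection
setClass("ClusterSelection",
  representation(
    labels = "integer", selected = "integer", scores = "numeric",
    framesUsed = "integer"
  )
)

#' Per-residue B-factor profile
#'
#' @slot values numeric per-bead B, A^2 when raw, dimensionless when
#'   normalized.
#' @slot normalization character(1) "raw", "zscore" or "minmax".
#' @slot source character(1) e.g. "crystal", "nma", "eda", "ceda".
#' @slot resid character per-bead residue labels.
#' @exportClass BFactorProfile
setClass("BFactorProfile",
  representation(
    values = "numeric", normalization = "character", source = "character",
    resid = "character"
  )
)

setValidity("BFactorProfile", function(object) {
  ok <- is.finite(object@values) | is.na(object@values)
  if (!all(ok)) return("B-factors must be finite or NA")
  if (!object@normalization %in% c("raw", "zscore", "minmax"))
    return("normalization must be raw, zscore or minmax")
  if (length(object@resid) != length(object@values))
    return("resid labels must align with values")
  TRUE
})

#' Dynamic cross-correlation map
#'
#' Symmetric N x N matrix of normalized residue-pair fluctuation
#' correlations in [-1, 1]; unit diagonal except where a bead had zero
#' fluctuation in the analyzed subspace (0/0 guard, recorded in
#' `zeroGuard`).
#'
#' @slot matrix numeric N x N correlation matrix.
#' @slot method character(1) producing method tag ("nma", "eda", ...).
#' @slot provenance character free-form description (modes used, frames).
#' @slot zeroGuard integer indices of beads whose correlations were zeroed.
#' @exportClass DCCM
setClass("DCCM",
  representation(
    matrix = "matrix", method = "character", provenance = "character",
    zeroGuard = "integer"
  )
)

setValidity("DCCM", function(object) {
  m <- object@matrix
  if (nrow(m) != ncol(m)) return("DCCM must be square")
  if (max(abs(m - t(m))) > 1e-8) return("DCCM must be symmetric")
  if (any(abs(m) > 1 + 1e-8)) return("correlations must lie in [-1, 1]")
  free <- setdiff(seq_len(nrow(m)), object@zeroGuard)
  if (length(free) && max(abs(diag(m)[free] - 1)) > 1e-8)
    return("diagonal must be 1 away from zero-fluctuation beads")
  TRUE
})

#' Langevin simulation parameters
#'
#' @slot dt numeric(1) integration time step, ps.
#' @slot nSteps integer(1) number of steps.
#' @slot temperature numeric(1) K.
#' @slot friction numeric(1) ps^-1 (0 = deterministic velocity Verlet limit).
#' @slot saveEvery integer(1) save a frame every this many steps.
#' @slot seed integer(1) RNG seed, recorded in trajectory metadata.
#' @exportClass SimulationParams
setClass("SimulationParams",
  representation(
    dt = "numeric", nSteps = "integer", temperature = "numeric",
    friction = "numeric", saveEvery = "integer", seed = "integer"
  )
)

setValidity("SimulationParams", function(object) {
  msg <- character()
  if (object@dt <= 0) msg <- c(msg, "dt must be positive")
  if (object@nSteps < 1L) msg <- c(msg, "nSteps must be >= 1")
  if (object@temperature < 0) msg <- c(msg, "temperature must be >= 0")
  if (object@friction < 0) msg <- c(msg, "friction must be >= 0")
  if (object@saveEvery < 1L) msg <- c(msg, "saveEvery must be >= 1")
  if (length(msg)) msg else TRUE
})
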