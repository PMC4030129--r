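#' Construct a CalphaModel from coordinates
#'
#' Low-level constructor used by the PDB reader and the synthetic-structure
#' generator. Consecutive beads are expected to sit at Calpha virtual-bond
#' distance; gaps outside the sanity band that are not flagged as chain
#' breaks are auto-flagged with a warning rather than rejected, since real
#' PDB files contain unannotated breaks.
#'
#' @param coords numeric N x 3 matrix, Angstrom.
#' @param resno author residue numbers (default 1:N).
#' @param insert insertion codes (default "").
#' @param chain chain identifiers (default "A").
#' @param resname three-letter residue names (default "ALA"); sets masses
#'   via the built-in average-residue-mass table, 110 amu fallback.
#' @param mass explicit masses, amu; overrides `resname` lookup.
#' @param bfactorExp experimental B-factors, A^2 (default NA).
#' @param chainBreak logical; TRUE where a bead starts a new segment.
#' @param distanceBand length-2 sanity band for consecutive-bead distances,
#'   Angstrom.
#' @return a \linkS4class{CalphaModel}.
#' @export
calphaModel <- function(coords, resno = seq_len(nrow(coords)),
                        insert = "", chain = "A", resname = "ALA",
                        mass = NULL, bfactorExp = NA_real_,
                        chainBreak = NULL, distanceBand = c(2.5, 4.5)) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  n <- nrow(coords)
  resno <- as.integer(rep_len(resno, n))
  insert <- rep_len(as.character(insert), n)
  chain <- rep_len(as.character(chain), n)
  resname <- rep_len(as.character(resname), n)
  if (is.null(mass)) mass <- residueMass(resname)
  mass <- rep_len(as.numeric(mass), n)
  bfactorExp <- rep_len(as.numeric(bfactorExp), n)
  if (is.null(chainBreak)) {
    chainBreak <- c(TRUE, chain[-1L] != chain[-n])
  } else {
    chainBreak <- rep_len(as.logical(chainBreak), n)
    chainBreak[1L] <- TRUE
  }
  if (n >= 2L) {
    d <- .pairDist(coords, seq_len(n - 1L), 2:n)
    bad <- which((d < distanceBand[1L] | d > distanceBand[2L]) &
                   !chainBreak[-1L])
    if (length(bad)) {
      warning(sprintf(
        "%d consecutive-bead distance(s) outside [%g, %g] A (first at bead %d, %.2f A); flagging chain break(s)",
        length(bad), distanceBand[1L], distanceBand[2L], bad[1L], d[bad[1L]]))
      chainBreak[bad + 1L] <- TRUE
    }
  }
  new("CalphaModel", resno = resno, insert = insert, chain = chain,
      resname = resname, coords = coords, mass = mass,
      bfactorExp = bfactorExp, domain = rep(NA_character_, n),
      chainBreak = chainBreak)
}

#' Define a domain as residue-number intervals
#'
#' @param name domain label, e.g. "ED".
#' @param start,end inclusive interval bounds (vectors for multi-interval
#'   domains such as an aminoacylation core split around an insertion).
#' @return a \linkS4class{DomainDefinition}.
#' @examples
#' domainDefinition("ED", 224, 407)
#' domainDefinition("core", c(1, 408), c(223, 505))
#' @export
domainDefinition <- function(name, start, end) {
  new("DomainDefinition", name = as.character(name),
      ranges = cbind(start = as.integer(start), end = as.integer(end)))
}

#' Construct a Trajectory
#'
#' @param frames a list of N x 3 coordinate matrices, or an nFrames x 3N
#'   matrix in flat xyz order.
#' @param dt ps between saved frames.
#' @param origin one of "cgmd", "ensemble_sample", "external".
#' @param superposed has rigid-body motion been removed?
#' @param velocities optional nFrames x 3N matrix, A/ps.
#' @param meta provenance list (seed, parameters).
#' @return a \linkS4class{Trajectory}.
#' @export
trajectory <- function(frames, dt = 1, origin = "external",
                       superposed = FALSE, velocities = NULL, meta = list()) {
  if (is.list(frames)) {
    if (!length(frames)) stop("a trajectory needs at least one frame")
    nb <- nrow(frames[[1L]])
    bad <- which(vapply(frames, nrow, 0L) != nb)
    if (length(bad))
      stop(sprintf("frame %d has an inconsistent bead count", bad[1L]))
    xyz <- do.call(rbind, lapply(frames, .flatten))
  } else {
    xyz <- as.matrix(frames)
    if (ncol(xyz) %% 3L != 0L) stop("flat xyz must have 3N columns")
    nb <- ncol(xyz) %/% 3L
  }
  if (is.null(velocities)) velocities <- matrix(0, 0L, ncol(xyz))
  new("Trajectory", xyz = xyz, nBeads = as.integer(nb), dt = as.numeric(dt),
      origin = origin, superposed = superposed, velocities = velocities,
      meta = meta)
}

#' Read a Calpha model from a PDB file
#'
#' Parses ATOM records (via bio3d), keeps one CA bead per residue (the
#' alphabetically first alternate location when several are present),
#' captures the temperature-factor column as the experimental B-factor and
#' assigns residue masses from the built-in table. Residues without a CA
#' atom are skipped with a warning. HETATM, TER and header records are
#' ignored.
#'
#' @param path PDB file.
#' @param chain optional chain identifier filter.
#' @param distanceBand consecutive-bead sanity band passed to
#'   \code{\link{calphaModel}}.
#' @return a \linkS4class{CalphaModel}.
#' @export
readCalphaPDB <- function(path, chain = NULL, distanceBand = c(2.5, 4.5)) {
  if (!file.exists(path)) stop("no such file: ", path)
  pdb <- bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE)
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (!is.null(chain)) {
    at <- at[!is.na(at$chain) & at$chain == chain, , drop = FALSE]
    if (!nrow(at))
      stop(sprintf("no ATOM records for chain '%s'", chain))
  }
  if (!nrow(at) || !any(at$elety == "CA"))
    stop("no CA atoms found: not a Calpha-parseable PDB file")
  at$insert[is.na(at$insert)] <- ""
  at$chain[is.na(at$chain)] <- " "
  at$alt[is.na(at$alt)] <- ""
  reskey <- paste(at$chain, at$resno, at$insert, sep = "|")
  ca <- at[at$elety == "CA", , drop = FALSE]
  cakey <- paste(ca$chain, ca$resno, ca$insert, sep = "|")
  dup <- duplicated(paste(cakey, ca$alt, sep = "|"))
  if (any(dup)) {
    d <- ca[which(dup)[1L], ]
    stop(sprintf(
      "duplicate CA record for chain %s resid %s%s altloc '%s' (atom serial %s)",
      d$chain, d$resno, d$insert, d$alt, d$eleno))
  }
  # first altloc alphabetically per residue; "" (no altloc) sorts first
  ord <- order(match(cakey, unique(cakey)), ca$alt)
  ca <- ca[ord, , drop = FALSE]
  ca <- ca[!duplicated(paste(ca$chain, ca$resno, ca$insert, sep = "|")), ,
           drop = FALSE]
  missing <- setdiff(unique(reskey), cakey)
  if (length(missing))
    warning(sprintf("%d residue(s) without a CA atom skipped (%s)",
                    length(missing),
                    paste(utils::head(gsub("\\|", ":", missing), 3L),
                          collapse = ", ")))
  calphaModel(
    coords = cbind(ca$x, ca$y, ca$z), resno = ca$resno, insert = ca$insert,
    chain = ca$chain, resname = ca$resid, bfactorExp = ca$b,
    distanceBand = distanceBand)
}

#' Tag model beads with domain labels
#'
#' @param model a \linkS4class{CalphaModel}.
#' @param defs a \linkS4class{DomainDefinition} or list of them; an empty
#'   list leaves the model unchanged.
#' @return the model with its `domain` slot filled. Overlapping
#'   definitions (two domains claiming one residue) are an error.
#' @export
assignDomains <- function(model, defs) {
  if (is(defs, "DomainDefinition")) defs <- list(defs)
  if (!length(defs)) return(model)
  resno <- model@resno
  tags <- model@domain
  for (def in defs) {
    validObject(def)
    hit <- rep(FALSE, length(resno))
    for (k in seq_len(nrow(def@ranges)))
      hit <- hit | (resno >= def@ranges[k, 1L] & resno <= def@ranges[k, 2L])
    if (!any(hit))
      stop(sprintf("domain '%s' matches no residues in the model", def@name))
    clash <- hit & !is.na(tags) & tags != def@name
    if (any(clash))
      stop(sprintf(
        "residue %s claimed by both domain '%s' and domain '%s'",
        residLabels(model)[which(clash)[1L]], tags[which(clash)[1L]],
        def@name))
    tags[hit] <- def@name
  }
  model@domain <- tags
  model
}

#' Bead indices of a domain
#'
#' @param model a \linkS4class{CalphaModel} with domain tags (see
#'   \code{\link{assignDomains}}).
#' @param name domain label.
#' @return integer bead indices.
#' @export
domainIndices <- function(model, name) {
  idx <- which(!is.na(model@domain) & model@domain == name)
  if (!length(idx)) stop(sprintf("no beads tagged with domain '%s'", name))
  idx
}

# ---- trajectory I/O ---------------------------------------------------------

.writePdbFrame <- function(con, coords, model, serialOffset = 0L) {
  n <- nrow(coords)
  resno <- if (is.null(model)) seq_len(n) else model@resno
  chain <- if (is.null(model)) rep("A", n) else model@chain
  resnm <- if (is.null(model)) rep("ALA", n) else model@resname
  ins <- if (is.null(model)) rep("", n) else model@insert
  b <- if (is.null(model)) rep(0, n) else ifelse(is.na(model@bfactorExp), 0,
                                                 model@bfactorExp)
  lines <- sprintf(
    "ATOM  %5d  CA  %-4s%1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f           C",
    (seq_len(n) + serialOffset - 1L) %% 99999L + 1L,
    substr(resnm, 1L, 4L), substr(paste0(chain, " "), 1L, 1L),
    resno, substr(paste0(ins, " "), 1L, 1L),
    coords[, 1L], coords[, 2L], coords[, 3L], rep(1, n), b)
  writeLines(lines, con)
}

#' Write a trajectory to multi-model PDB or XYZ
#'
#' Multi-model PDB frames are bracketed by MODEL / ENDMDL records; the XYZ
#' dialect is the plain count / comment / `element x y z` format. The
#' round trip through \code{\link{readTrajectory}} preserves coordinates to
#' the fixed-width precision of the format (1e-3 A for PDB).
#'
#' @param traj a \linkS4class{Trajectory}.
#' @param model a \linkS4class{CalphaModel} supplying residue metadata for
#'   PDB output, or NULL for generic labels.
#' @param path output file.
#' @param format "pdb" or "xyz".
#' @return `path`, invisibly.
#' @export
writeTrajectory <- function(traj, model = NULL, path, format = c("pdb", "xyz")) {
  format <- match.arg(format)
  if (!nFrames(traj)) stop("cannot write an empty trajectory")
  if (!is.null(model) && nBeads(model) != nBeads(traj))
    stop(sprintf("bead-count mismatch: model has %d, trajectory has %d",
                 nBeads(model), nBeads(traj)))
  con <- file(path, "w")
  on.exit(close(con))
  if (format == "pdb") {
    for (f in seq_len(nFrames(traj))) {
      writeLines(sprintf("MODEL     %4d", f), con)
      .writePdbFrame(con, frameCoords(traj, f), model)
      writeLines("ENDMDL", con)
    }
    writeLines("END", con)
  } else {
    n <- nBeads(traj)
    elem <- if (is.null(model)) rep("C", n) else
      substr(model@resname, 1L, 1L)
    for (f in seq_len(nFrames(traj))) {
      writeLines(as.character(n), con)
      writeLines(sprintf("frame %d dt %g ps", f, traj@dt), con)
      xyzf <- frameCoords(traj, f)
      writeLines(sprintf("%-2s %12.6f %12.6f %12.6f", elem,
                         xyzf[, 1L], xyzf[, 2L], xyzf[, 3L]), con)
    }
  }
  invisible(path)
}

#' Read a trajectory from multi-model PDB or XYZ
#'
#' @param path input file.
#' @param format "pdb" or "xyz".
#' @param dt ps per saved frame to record in the result.
#' @return a \linkS4class{Trajectory} with origin "external".
#' @export
readTrajectory <- function(path, format = c("pdb", "xyz"), dt = 1) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "pdb") {
    pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
    sel <- which(pdb$atom$type == "ATOM" & pdb$atom$elety == "CA")
    if (!length(sel)) stop("no CA atoms found in trajectory PDB")
    cols <- as.integer(t(outer(3L * (sel - 1L), 1:3, "+")))
    xyz <- pdb$xyz[, cols, drop = FALSE]
    trajectory(xyz, dt = dt, origin = "external")
  } else {
    txt <- readLines(path)
    frames <- list()
    pos <- 1L
    f <- 0L
    while (pos <= length(txt)) {
      if (!nzchar(trimws(txt[pos]))) { pos <- pos + 1L; next }
      n <- suppressWarnings(as.integer(trimws(txt[pos])))
      f <- f + 1L
      if (is.na(n) || pos + 1L + n > length(txt))
        stop(sprintf("truncated or malformed XYZ at frame %d", f))
      block <- txt[(pos + 2L):(pos + 1L + n)]
      fields <- strsplit(trimws(block), "\\s+")
      if (any(vapply(fields, length, 0L) < 4L))
        stop(sprintf("malformed coordinate line in XYZ frame %d", f))
      m <- t(vapply(fields, function(x) as.numeric(x[2:4]), numeric(3L)))
      if (any(!is.finite(m)))
        stop(sprintf("non-numeric coordinates in XYZ frame %d", f))
      frames[[f]] <- m
      pos <- pos + 2L + n
    }
    if (!length(frames)) stop("no frames found in XYZ file")
    nb <- vapply(frames, nrow, 0L)
    if (any(nb != nb[1L]))
      stop(sprintf("frame %d has an inconsistent bead count",
                   which(nb != nb[1L])[1L]))
    trajectory(frames, dt = dt, origin = "external")
  }
}
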