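# Shared fixtures: handcrafted PDB text and small reference systems.

# A PDB ATOM line with explicit column control, independent of the
# package's writer.
pdbAtomLine <- function(serial, name, resname, chain, resno, x, y, z,
                        b = 10, alt = " ", icode = " ", occ = 1) {
  sprintf("ATOM  %5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f           C",
          serial, paste0(" ", name), alt, resname, chain, resno, icode,
          x, y, z, occ, b)
}

writeToyPdb <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(c("HEADER    TOY", lines, "TER", "END"), path)
  path
}

# three CA residues along x at bond distance, B-factors 11/22/33
toyPdb3 <- function() {
  writeToyPdb(c(
    pdbAtomLine(1, "CA", "ALA", "A", 1, 0.0, 0.0, 0.0, b = 11),
    pdbAtomLine(2, "CA", "GLY", "A", 2, 3.8, 0.0, 0.0, b = 22),
    pdbAtomLine(3, "CA", "LEU", "A", 3, 7.6, 0.0, 0.0, b = 33)))
}

# a dimer network with configurable bond length
dimerNet <- function(r0 = 3.8, gamma = 1, cutoff = r0 + 2) {
  buildNetwork(matrix(c(0, 0, 0, r0, 0, 0), 2L, 3L, byrow = TRUE),
               cutoff = cutoff, gamma = gamma)
}

# random compact connected structure: a seeded self-avoiding chain packed
# into a sphere (loose clouds leave dangling beads whose single or
# collinear contacts add spurious mechanical zero modes)
randomConnectedNet <- function(n, seed, cutoff = 8, ...) {
  xyz <- coords(makeTwoDomainStructure(nCore = n, nInsert = 0L,
                                       seed = seed)$model)
  net <- suppressWarnings(buildNetwork(xyz, cutoff = cutoff, ...))
  stopifnot(net@connected)
  net
}

# numerical gradient of enmEnergy by central differences
numericalForces <- function(net, x, h = 1e-5) {
  f <- matrix(0, nrow(x), 3L)
  for (i in seq_len(nrow(x))) for (d in 1:3) {
    xp <- x; xm <- x
    xp[i, d] <- xp[i, d] + h
    xm[i, d] <- xm[i, d] - h
    f[i, d] <- -(enmEnergy(net, xp) - enmEnergy(net, xm)) / (2 * h)
  }
  f
}

# numerical Hessian of enmEnergy by central differences on the gradient
numericalHessian <- function(net, h = 1e-5) {
  x <- net@refCoords
  n <- nrow(x)
  hess <- matrix(0, 3L * n, 3L * n)
  for (i in seq_len(n)) for (d in 1:3) {
    xp <- x; xm <- x
    xp[i, d] <- xp[i, d] + h
    xm[i, d] <- xm[i, d] - h
    gp <- -numericalForcesFlat(net, xp)
    gm <- -numericalForcesFlat(net, xm)
    hess[, 3L * (i - 1L) + d] <- (gp - gm) / (2 * h)
  }
  (hess + t(hess)) / 2
}

numericalForcesFlat <- function(net, x) as.numeric(t(enmForces(net, x)))

kB <- 0.0019872041
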