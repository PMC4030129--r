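test_that("a toy PDB parses into one bead per residue with B-factors", {
  m <- readCalphaPDB(toyPdb3())
  expect_s4_class(m, "CalphaModel")
  expect_equal(nBeads(m), 3L)
  expect_equal(unname(bfactors(m)), c(11, 22, 33))
  expect_equal(coords(m)[, 1], c(0, 3.8, 7.6))
  expect_equal(m@resname, c("ALA", "GLY", "LEU"))
  # masses from the residue table, not the fallback
  expect_equal(masses(m), c(71.08, 57.05, 113.16))
})

test_that("chain filtering on an absent chain is an explicit error", {
  expect_error(readCalphaPDB(toyPdb3(), chain = "B"), "chain 'B'")
})

test_that("residues without a CA atom are skipped with a warning", {
  p <- writeToyPdb(c(
    pdbAtomLine(1, "CA", "ALA", "A", 1, 0, 0, 0),
    pdbAtomLine(2, "N", "GLY", "A", 2, 3.0, 1.0, 0),
    pdbAtomLine(3, "CA", "LEU", "A", 3, 3.8, 0, 0),
    pdbAtomLine(4, "CA", "VAL", "A", 4, 7.6, 0, 0)))
  expect_warning(m <- readCalphaPDB(p), "without a CA")
  expect_equal(nBeads(m), 3L)
  expect_equal(m@resno, c(1L, 3L, 4L))
})

test_that("alternate locations pick the alphabetically first; duplicates error", {
  p <- writeToyPdb(c(
    pdbAtomLine(1, "CA", "ALA", "A", 1, 0, 0, 0, alt = "B", b = 1),
    pdbAtomLine(2, "CA", "ALA", "A", 1, 0.5, 0, 0, alt = "A", b = 2),
    pdbAtomLine(3, "CA", "GLY", "A", 2, 3.8, 0, 0)))
  m <- suppressWarnings(readCalphaPDB(p))
  expect_equal(nBeads(m), 2L)
  expect_equal(unname(bfactors(m))[1], 2)  # altloc A wins
  expect_equal(coords(m)[1, 1], 0.5)

  pdup <- writeToyPdb(c(
    pdbAtomLine(1, "CA", "ALA", "A", 1, 0, 0, 0),
    pdbAtomLine(2, "CA", "ALA", "A", 1, 0.1, 0, 0),
    pdbAtomLine(3, "CA", "GLY", "A", 2, 3.8, 0, 0)))
  expect_error(suppressWarnings(readCalphaPDB(pdup)), "duplicate CA")
})

test_that("a file without CA atoms fails to parse", {
  p <- writeToyPdb(pdbAtomLine(1, "N", "ALA", "A", 1, 0, 0, 0))
  expect_error(readCalphaPDB(p), "no CA atoms")
})

test_that("domain assignment tags residue ranges and rejects overlap", {
  m <- calphaModel(makeHelix(30)@coords, resno = 219 + seq_len(30))
  m2 <- assignDomains(m, domainDefinition("ED", 224, 240))
  expect_equal(sum(!is.na(domains(m2))), 17L)  # resids 224..240 inclusive
  expect_true(all(m2@resno[!is.na(domains(m2))] >= 224 &
                    m2@resno[!is.na(domains(m2))] <= 240))
  # empty definition list leaves the model untouched
  expect_identical(assignDomains(m, list()), m)
  # two domains claiming one residue
  expect_error(
    assignDomains(m2, domainDefinition("other", 240, 245)),
    "claimed by both")
})

test_that("multi-interval domains map each residue at most once", {
  m <- calphaModel(makeHelix(20)@coords, resno = 1:20)
  d <- domainDefinition("core", c(1, 15), c(5, 20))
  m2 <- assignDomains(m, d)
  expect_equal(which(!is.na(domains(m2))), c(1:5, 15:20))
  expect_equal(domainIndices(m2, "core"), c(1:5, 15:20))
})

test_that("trajectory round trip through multi-model PDB keeps 1e-3 A", {
  set.seed(11)
  frames <- lapply(1:4, function(i) matrix(runif(30, 0, 100), 10L, 3L))
  tr <- trajectory(frames, dt = 0.5)
  f <- tempfile(fileext = ".pdb")
  writeTrajectory(tr, NULL, f, format = "pdb")
  txt <- readLines(f)
  expect_equal(sum(grepl("^MODEL", txt)), 4L)
  expect_equal(sum(grepl("^ENDMDL", txt)), 4L)
  back <- readTrajectory(f, "pdb", dt = 0.5)
  expect_equal(nFrames(back), 4L)
  expect_equal(nBeads(back), 10L)
  expect_lt(max(abs(back@xyz - tr@xyz)), 1e-3)
})

test_that("trajectory round trip through XYZ is lossless to 1e-6", {
  set.seed(12)
  frames <- lapply(1:5, function(i) matrix(runif(30, 0, 100), 10L, 3L))
  tr <- trajectory(frames)
  f <- tempfile(fileext = ".xyz")
  writeTrajectory(tr, NULL, f, format = "xyz")
  back <- readTrajectory(f, "xyz")
  expect_equal(nFrames(back), 5L)
  expect_equal(nBeads(back), 10L)
  expect_lt(max(abs(back@xyz - tr@xyz)), 1e-6)
})

test_that("trajectory writing and reading reject malformed input", {
  expect_error(trajectory(list()), "at least one frame")
  set.seed(13)
  tr <- trajectory(list(matrix(runif(15), 5L, 3L)))
  model <- makeHelix(7)
  expect_error(writeTrajectory(tr, model, tempfile(), "pdb"),
               "bead-count mismatch")
  # truncated last XYZ frame names the offending frame
  f <- tempfile(fileext = ".xyz")
  writeTrajectory(trajectory(lapply(1:5, function(i)
    matrix(runif(9), 3L, 3L))), NULL, f, "xyz")
  txt <- readLines(f)
  writeLines(txt[1:(length(txt) - 2L)], f)
  expect_error(readTrajectory(f, "xyz"), "frame 5")
  # inconsistent bead count across frames
  expect_error(
    trajectory(list(matrix(0, 3L, 3L), matrix(0, 4L, 3L))),
    "frame 2")
})

test_that("implausible consecutive-bead distances are flagged, not fatal", {
  xyz <- rbind(c(0, 0, 0), c(3.8, 0, 0), c(20, 0, 0), c(23.8, 0, 0))
  expect_warning(m <- calphaModel(xyz), "chain break")
  expect_true(m@chainBreak[3L])
})
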