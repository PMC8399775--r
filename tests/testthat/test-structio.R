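test_that("PDB and PDBQT dialects parse handcrafted records to the same coordinates", {
  pdb <- tempfile(fileext = ".pdb")
  writeLines(c(
    atom_line(1, "N", "ALA", "A", 1, 1.234, -2.5, 0.001, element = "N"),
    atom_line(2, "CA", "ALA", "A", 1, 2.0, 0.0, 0.5, element = "C"),
    atom_line(3, "O", "ALA", "A", 1, -3.125, 4.75, 8.0, element = "O")), pdb)
  s <- readStructure(pdb, "pdb")
  expect_equal(nAtoms(s), 3L)
  expect_equal(atoms(s)$resseq, c(1L, 1L, 1L))
  expect_equal(atoms(s)$x, c(1.234, 2.0, -3.125))
  expect_equal(atoms(s)$element, c("N", "C", "O"))

  pdbqt <- tempfile(fileext = ".pdbqt")
  writeLines(c(
    atom_line(1, "N", "ALA", "A", 1, 1.234, -2.5, 0.001, extra = "    -0.350 N "),
    atom_line(2, "CA", "ALA", "A", 1, 2.0, 0.0, 0.5, extra = "     0.150 C "),
    atom_line(3, "O", "ALA", "A", 1, -3.125, 4.75, 8.0, extra = "    -0.271 OA")), pdbqt)
  q <- readStructure(pdbqt, "pdbqt")
  expect_equal(coords(q), coords(s))
  expect_equal(atoms(q)$charge, c(-0.350, 0.150, -0.271))
  expect_equal(atoms(q)$atom_type, c("N", "C", "OA"))
  expect_equal(atoms(q)$element, c("N", "C", "O"))  # OA maps to oxygen
})

test_that("parse errors name the offending line; empty files and insertion codes are rejected", {
  bad <- tempfile()
  writeLines(c(
    atom_line(1, "CA", "ALA", "A", 1, 0, 0, 0, element = "C"),
    sub("   0\\.000", "     abc", atom_line(2, "CB", "ALA", "A", 1, 0, 1, 1, element = "C"))),
    bad)
  expect_error(readStructure(bad), "line 2")

  empty <- tempfile(); writeLines(c("REMARK nothing here", ""), empty)
  expect_error(readStructure(empty), "no ATOM/HETATM")

  icode <- tempfile()
  line <- atom_line(1, "CA", "ALA", "A", 1, 0, 0, 0, element = "C")
  substr(line, 27, 27) <- "A"
  writeLines(line, icode)
  expect_error(readStructure(icode), "insertion code")
})

test_that("parser ignores trailing whitespace and blank lines", {
  f <- tempfile()
  writeLines(c("", paste0(atom_line(1, "CA", "ALA", "A", 1, 1, 2, 3, element = "C"), "   "),
               "", "TER", ""), f)
  s <- readStructure(f)
  expect_equal(unname(coords(s)[1, ]), c(1, 2, 3))
})

test_that("structures round-trip through PDB at format precision", {
  set.seed(11)
  df <- data.frame(serial = 1:20, name = paste0("C", 1:20), element = "C",
                   resname = "LIG", resseq = rep(1:4, each = 5), chain = "A",
                   x = round(runif(20, -50, 50), 3), y = round(runif(20, -50, 50), 3),
                   z = round(runif(20, -50, 50), 3))
  s <- new("Structure", atoms = df, label = "rt")
  f <- tempfile(fileext = ".pdb")
  writeStructure(s, f)
  s2 <- readStructure(f)
  expect_equal(coords(s2), coords(s), tolerance = 1e-9)
  expect_equal(atoms(s2)$resseq, df$resseq)
})

test_that("multi-model PDBQT pose bundles parse energies and enforce atom-count consistency", {
  two_model <- function(e1, e2, n2 = 2L) {
    c("MODEL 1",
      sprintf("REMARK VINA RESULT:    %6.1f      0.000      0.000", e1),
      atom_line(1, "C1", "LIG", "Z", 1, 0, 0, 0, extra = "     0.000 C "),
      atom_line(2, "N1", "LIG", "Z", 1, 1.4, 0, 0, extra = "    -0.300 NA"),
      "ENDMDL", "MODEL 2",
      sprintf("REMARK VINA RESULT:    %6.1f      0.000      0.000", e2),
      atom_line(1, "C1", "LIG", "Z", 1, 5, 5, 5, extra = "     0.000 C "),
      if (n2 == 2L) atom_line(2, "N1", "LIG", "Z", 1, 6.4, 5, 5, extra = "    -0.300 NA"),
      "ENDMDL")
  }
  f <- tempfile(fileext = ".pdbqt")
  writeLines(two_model(-5.1, -4.2), f)
  b <- readPoseBundle(f)
  expect_equal(nPoses(b), 2L)
  expect_equal(energies(b), c(-5.1, -4.2))
  expect_equal(atomMeta(b)$element, c("C", "N"))

  one <- tempfile(fileext = ".pdbqt")
  writeLines(two_model(-5.1, -4.2)[1:5], one)
  expect_equal(nPoses(readPoseBundle(one)), 1L)

  mism <- tempfile(fileext = ".pdbqt")
  writeLines(two_model(-5.1, -4.2, n2 = 1L), mism)
  expect_error(readPoseBundle(mism), "model 2 has 1 atoms")

  noE <- tempfile(fileext = ".pdbqt")
  writeLines(grep("REMARK", two_model(-5.1, -4.2), value = TRUE, invert = TRUE), noE)
  expect_error(readPoseBundle(noE), "energy REMARK")
  perm <- readPoseBundle(noE, permissive = TRUE)
  expect_true(all(is.nan(energies(perm))))
})

test_that("pose bundles round-trip: JSON exactly, PDBQT to the printed 3 decimals", {
  set.seed(7)
  cl <- lapply(1:10, function(i) matrix(rnorm(12 * 3, sd = 5), ncol = 3))
  b <- new("PoseBundle", ligandId = "lig1", coords = cl,
           energies = rnorm(10, -6, 1.5),
           atomMeta = data.frame(name = paste0("C", 1:12), element = "C"))
  fj <- tempfile(fileext = ".json")
  writePoseBundle(b, fj, "json")
  bj <- readPoseBundle(fj)
  expect_equal(bj@coords, lapply(b@coords, function(m) {
    dimnames(m) <- list(NULL, c("x", "y", "z")); m
  }), tolerance = 1e-12)
  expect_equal(energies(bj), energies(b), tolerance = 1e-12)

  fq <- tempfile(fileext = ".pdbqt")
  writePoseBundle(b, fq, "pdbqt")
  bq <- readPoseBundle(fq)
  for (i in 1:10)
    expect_equal(unname(poseCoords(bq, i)), unname(poseCoords(b, i)), tolerance = 1.1e-3)
  expect_equal(energies(bq), energies(b), tolerance = 1.1e-3)
})

test_that("fixed-column parsing agrees with an independent PDB reader", {
  r <- makeToyReceptor(seed = 3)
  f <- tempfile(fileext = ".pdb")
  writeStructure(r$structure, f)
  ours <- readStructure(f)
  ref <- bio3d::read.pdb(f)
  expect_equal(unname(coords(ours)),
               unname(matrix(ref$xyz, ncol = 3, byrow = TRUE)), tolerance = 1e-9)
  expect_equal(atoms(ours)$resseq, ref$atom$resno)
})

test_that("manifest bookkeeping: totals, small cases and malformed rows", {
  df <- data.frame(ligand_id = c(paste0("tp", 1:95), paste0("d", 1:3829)),
                   label = c(rep("TP", 95), rep("decoy", 3829)))
  f <- tempfile(fileext = ".csv")
  write.csv(df, f, row.names = FALSE)
  man <- readManifest(f)
  expect_equal(unname(labelCounts(man)), c(95L, 3829L, 3924L))

  small <- makeManifest(data.frame(ligand_id = letters[1:5],
                                   label = c("TP", "TP", "decoy", "decoy", "decoy")))
  expect_equal(unname(labelCounts(small)), c(2L, 3L, 5L))

  dup <- data.frame(ligand_id = c("a", "a"), label = c("TP", "decoy"))
  expect_error(makeManifest(dup), "duplicate ligand_id: a")
  expect_error(makeManifest(data.frame(ligand_id = "a", label = "maybe")),
               "unknown label")
  expect_error(makeManifest(data.frame(ligand_id = c("a", "b"), label = c("TP", ""))),
               "row\\(s\\): 2")
  expect_error(makeManifest(data.frame(ligand_id = "a", label = "TP", ec50_nM = 2.0)),
               "threshold")
})
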