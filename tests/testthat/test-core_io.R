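# Readers/writers and container invariants.

test_that("PDB reader transcribes atoms and box; missing CRYST1 errors", {
  pdb <- file.path(tempdir(), "w3.pdb")
  writeLines(c(
    "CRYST1   20.000   20.000   20.000  90.00  90.00  90.00 P 1",
    "ATOM      1  O   HOH A   1       1.000   2.000   3.000  1.00  0.00           O",
    "ATOM      2  H1  HOH A   1       1.800   2.000   3.000  1.00  0.00           H",
    "ATOM      3  H2  HOH A   1       0.700   2.700   3.400  1.00  0.00           H",
    "END"), pdb)
  rs <- readStructurePDB(pdb)
  expect_equal(nrow(rs$frame$coords), 3)
  expect_equal(rs$frame$box, c(20, 20, 20))
  expect_equal(rs$frame$coords[1, ], c(x = 1, y = 2, z = 3))
  expect_equal(atomTable(rs$topology)$molecule_kind[1], "water")

  noBox <- file.path(tempdir(), "nobox.pdb")
  writeLines(readLines(pdb)[-1], noBox)
  expect_error(readStructurePDB(noBox), "CRYST1")
  expect_equal(readStructurePDB(noBox, box = c(15, 15, 15))$frame$box,
               c(15, 15, 15))
})

test_that("synthetic structure survives a PDB round trip to 1e-3 A", {
  traj <- generateMembraneTrajectory(membraneSpec(
    n_lipids_per_leaflet = 6, n_frames = 2, n_drugs_adsorbed = 1,
    n_drugs_free = 1, n_waters = 10, seed = 11))
  f <- file.path(tempdir(), "bil.pdb")
  writeStructurePDB(topology(traj), getFrame(traj, 1), f)
  rs <- readStructurePDB(f)
  expect_lt(max(abs(rs$frame$coords - getFrame(traj, 1)$coords)), 1e-3)
  expect_equal(nrow(rs$frame$coords), nAtoms(traj))
  # atom ordering preserved: element sequence matches
  expect_equal(atomTable(rs$topology)$element,
               toupper(substr(atomTable(traj)$element, 1, 1)))
})

test_that("text trajectory round-trips and rejects empty/truncated files", {
  traj <- generateMembraneTrajectory(membraneSpec(
    n_lipids_per_leaflet = 5, n_frames = 5, n_drugs_adsorbed = 1,
    n_drugs_free = 1, n_waters = 5, seed = 3))
  f <- file.path(tempdir(), "t.trj")
  writeTrajectoryTRJ(traj, f)
  rt <- readTrajectoryTRJ(f, topology(traj))
  expect_equal(nFrames(rt), 5)
  expect_true(all(diff(frameTimes(rt)) > 0))
  expect_lt(max(abs(rt@coords - traj@coords)), 1e-3)
  expect_equal(rt@box, traj@box, tolerance = 1e-3)

  empty <- file.path(tempdir(), "empty.trj")
  writeLines(c("# memtraj-trj 1", paste("natoms", nAtoms(traj))), empty)
  expect_error(readTrajectoryTRJ(empty, topology(traj)), "no complete")

  lines <- readLines(f)
  trunc <- file.path(tempdir(), "trunc.trj")
  writeLines(lines[-length(lines)], trunc)
  expect_error(readTrajectoryTRJ(trunc, topology(traj)),
               "last complete frame is 4")
})

test_that("topology table round-trips; bad tables are rejected", {
  tab <- helperAtoms(2, element = c("P", "C"), mass = c(123, 14),
                     molecule_id = c(0L, 0L), molecule_kind = "lipid",
                     labels = c("P", "C2"))
  f <- file.path(tempdir(), "top.tsv")
  writeTopologyTable(Topology(tab), f)
  topo <- readTopologyTable(f)
  expect_s4_class(topo, "Topology")
  expect_equal(nAtoms(topo), 2)
  expect_equal(atomTable(topo)$labels, c("P", "C2"))

  dup <- tab; dup$index <- c(0L, 0L)
  fd <- file.path(tempdir(), "dup.tsv")
  utils::write.table(dup, fd, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  expect_error(readTopologyTable(fd), "duplicate")

  badKind <- tab; badKind$molecule_kind <- "protein"
  expect_error(Topology(badKind), "unknown molecule_kind")
  expect_error(Topology(transform(tab, mass = c(-1, 14))), "mass")

  # generator output satisfies every container invariant
  traj <- generateMembraneTrajectory(membraneSpec(
    n_lipids_per_leaflet = 4, n_frames = 3, n_waters = 5, seed = 2))
  expect_true(validObject(topology(traj)))
  expect_true(validObject(traj))
})

test_that("QM tables read back energies/charges and flag electron counts", {
  qf <- generateQMFixture(4, seed = 8)
  fe <- file.path(tempdir(), "e.tsv")
  fq <- file.path(tempdir(), "q.tsv")
  writeQMTables(qf$table, fe, fq)
  qm <- readQMTables(fe, fq)
  expect_s4_class(qm, "QMStateTable")
  expect_equal(qm@energies, qf$table@energies, tolerance = 1e-10)
  expect_equal(unname(qm@charges), unname(qf$table@charges),
               tolerance = 1e-10)

  # hand-written 2-atom table: E(N) lands in the energies map
  writeLines(c("state\tenergy_hartree", "Nminus1\t-99.5", "N\t-100.0",
               "Nplus1\t-100.1"), fe)
  expect_equal(readQMTables(fe)@energies[["N"]], -100.0)

  writeLines(c("state\tenergy_hartree", "N\t-100.0"), fe)
  expect_error(readQMTables(fe), "missing state")

  # charge sets two electrons apart -> warning with measured deviation
  bad <- data.frame(index = 0:1, element = "C", Z = 6,
                    q_Nminus1 = c(1, 1), q_N = c(0, 0),
                    q_Nplus1 = c(-1, -1))
  utils::write.table(bad, fq, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  expect_warning(readQMTables(chargesPath = fq), "one electron")
})
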