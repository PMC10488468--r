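# CHARMM-style pair energies, decomposition, complex extraction,
# supermolecular interaction energies.

.pairSystem <- function(r, q = c(0, 0), eps = c(0.1, 0.1),
                        rmh = c(2, 2)) {
  atoms <- helperAtoms(2, charge = q, epsilon = eps, rmin_half = rmh,
                       molecule_id = 0:1,
                       molecule_kind = c("drug", "lipid"),
                       labels = c("drug", "lipid"))
  makeTraj(atoms, rbind(c(0, 0, 0), c(r, 0, 0)), box = c(200, 200, 200))
}

test_that("LJ minimum and Coulomb closed forms are reproduced", {
  # neutral pair at r = rmin_ab: E_vdw = -eps_ab, E_elec = 0
  tr <- .pairSystem(4, eps = c(0.1, 0.1), rmh = c(2, 2))
  e <- pairEnergy(tr, 1, 1, 2)
  expect_equal(unname(e["vdw"]), -0.1, tolerance = 1e-12)
  expect_equal(unname(e["elec"]), 0)

  # +1/-1 at 3.320636 A (inside the unswitched region): -100 kcal/mol
  tr2 <- .pairSystem(3.320636, q = c(1, -1), eps = c(0, 0))
  e2 <- pairEnergy(tr2, 1, 1, 2)
  expect_equal(unname(e2["elec"]), -100.0, tolerance = 1e-9)
  expect_equal(unname(e2["vdw"]), 0)

  expect_error(pairEnergy(tr, 1, 1:2, 2), "disjoint")
  tr0 <- .pairSystem(0.0)
  expect_error(pairEnergy(tr0, 1, 1, 2), "zero interatomic")
})

test_that("pair energies match the fixture's closed-form reference", {
  ef <- generateEnergyFixture(100, seed = 17)
  a <- atomTable(ef$traj)
  for (p in seq_len(100)) {
    gA <- which(a$molecule_id == 2 * p - 2)
    gB <- which(a$molecule_id == 2 * p - 1)
    e <- pairEnergy(ef$traj, 1, gA, gB, cutoff = ef$cutoff,
                    switchStart = ef$switchStart)
    expect_equal(unname(e["elec"]), ef$reference$elec[p],
                 tolerance = 1e-8)
    expect_equal(unname(e["vdw"]), ef$reference$vdw[p],
                 tolerance = 1e-8)
  }
  # symmetry of the pair sum
  eAB <- pairEnergy(ef$traj, 1, "grpA", "grpB")
  eBA <- pairEnergy(ef$traj, 1, "grpB", "grpA")
  expect_equal(eAB, eBA, tolerance = 1e-10)
})

test_that("the switched potential is continuous across both radii", {
  rs <- sort(c(seq(9.9, 12.1, by = 1e-4), 10, 12))
  es <- vapply(rs, function(r) {
    sum(pairEnergy(.pairSystem(r, q = c(0.5, -0.5)), 1, 1, 2))
  }, numeric(1))
  jumps <- abs(diff(es))
  expect_lt(max(jumps), 1e-3)
  # identically zero beyond the cutoff
  expect_equal(sum(abs(pairEnergy(.pairSystem(12.0001), 1, 1, 2))), 0)
})

test_that("functional-group contributions are additive over a partition", {
  set.seed(41)
  nd <- 6; nl <- 10
  labs <- paste0("grp", c(1, 1, 2, 2, 3, 3))
  atoms <- rbind(
    helperAtoms(nd, charge = runif(nd, -0.4, 0.4),
                epsilon = runif(nd, 0.05, 0.2),
                rmin_half = runif(nd, 1.6, 2.2), molecule_id = 0L,
                molecule_kind = "drug",
                labels = paste("drug", labs, sep = ";")),
    helperAtoms(nl, charge = runif(nl, -0.4, 0.4),
                epsilon = runif(nl, 0.05, 0.2),
                rmin_half = runif(nl, 1.6, 2.2), molecule_id = 1L,
                molecule_kind = "lipid", labels = "lipid"))
  atoms$index <- seq_len(nd + nl) - 1L
  co <- rbind(matrix(runif(nd * 3, 0, 4), ncol = 3),
              matrix(runif(nl * 3, 2, 8), ncol = 3))
  traj <- makeTraj(atoms, co, box = c(100, 100, 100))

  whole <- pairEnergy(traj, 1, 1:nd, nd + seq_len(nl))
  parts <- lapply(paste0("grp", 1:3), function(g) {
    groupContribution(traj, g, target = "lipid", drugMolecules = 0L,
                      frames = 1L)
  })
  sumElec <- sum(vapply(parts, function(p) p$elec, numeric(1)))
  sumVdw <- sum(vapply(parts, function(p) p$vdw, numeric(1)))
  expect_equal(sumElec, unname(whole["elec"]), tolerance = 1e-6)
  expect_equal(sumVdw, unname(whole["vdw"]), tolerance = 1e-6)

  # a single-atom label equals that atom's own pair energy
  single <- atoms; single$labels[1] <- "drug;S_3prime"
  trajS <- makeTraj(single, co, box = c(100, 100, 100))
  gc1 <- groupContribution(trajS, "S_3prime", target = "lipid",
                           drugMolecules = 0L, frames = 1L)
  e1 <- pairEnergy(trajS, 1, 1L, nd + seq_len(nl))
  expect_equal(gc1$elec, unname(e1["elec"]), tolerance = 1e-10)
  expect_equal(gc1$vdw, unname(e1["vdw"]), tolerance = 1e-10)
  expect_error(groupContribution(trajS, "no_such", frames = 1L),
               "no atoms|matches no")
})

test_that("complex extraction applies the whole-lipid any-atom rule", {
  traj <- generateMembraneTrajectory(membraneSpec(
    n_lipids_per_leaflet = 8, n_frames = 3, n_drugs_adsorbed = 2,
    n_drugs_free = 1, n_waters = 10, seed = 19))
  a <- atomTable(traj)
  mid <- moleculeIds(traj, "drug")[1]
  cx <- extractComplex(traj, 2, mid, cutoff = 3)
  co <- getFrame(traj, 2)$coords
  box <- getFrame(traj, 2)$box
  drugRows <- which(a$molecule_id == mid)
  # brute-force recount of the inclusion set
  lipMols <- unique(a$molecule_id[a$molecule_kind == "lipid"])
  inc <- c()
  for (lm in lipMols) {
    rows <- which(a$molecule_id == lm)
    mind <- Inf
    for (i in rows) for (j in drugRows) {
      d <- co[i, ] - co[j, ]
      d <- d - box * round(d / box)
      mind <- min(mind, sqrt(sum(d^2)))
    }
    if (mind <= 3) inc <- c(inc, lm)
  }
  expect_equal(cx$lipidMolecules, sort(inc))
  # drug atoms first, lipids whole
  expect_equal(cx$atomRows[seq_along(drugRows)], drugRows)
  if (length(inc)) {
    expect_true(all(table(a$molecule_id[cx$atomRows][-seq_along(drugRows)])
                    == sum(a$molecule_id == inc[1])))
  }
  f <- file.path(tempdir(), "complex.pdb")
  writeComplexPDB(cx, traj, f)
  rs <- readStructurePDB(f)
  expect_equal(nrow(rs$frame$coords), length(cx$atomRows))
})

test_that("explicit near/far lipids are included/excluded", {
  atoms <- rbind(
    helperAtoms(1, molecule_id = 0L, molecule_kind = "drug",
                labels = "drug"),
    helperAtoms(2, molecule_id = 1L, molecule_kind = "lipid",
                labels = "lipid"),
    helperAtoms(2, molecule_id = 2L, molecule_kind = "lipid",
                labels = "lipid"))
  atoms$index <- 0:4
  co <- rbind(c(0, 0, 0),
              c(2.5, 0, 0), c(9, 0, 0),      # one atom at 2.5 A: in
              c(3.5, 4, 0), c(10, 4, 0))     # nearest 3.5 A: out
  traj <- makeTraj(atoms, co, box = c(100, 100, 100))
  cx <- extractComplex(traj, 1, 0, cutoff = 3)
  expect_equal(cx$lipidMolecules, 1L)
  expect_equal(cx$atomRows, c(1L, 2L, 3L))
})

test_that("supermolecular interaction is the fragment-energy difference", {
  expect_equal(supermolecularInteraction(-10, -4, -5), -1)
  # classical pairwise model: Delta E equals the direct cross pair energy
  ef <- generateEnergyFixture(20, seed = 29)
  gA <- selectAtoms(ef$traj, label = "grpA")
  gB <- selectAtoms(ef$traj, label = "grpB")
  eCross <- sum(pairEnergy(ef$traj, 1, gA, gB))
  eA <- sum(bruteInternalEnergy(ef$traj, 1, gA))
  eB <- sum(bruteInternalEnergy(ef$traj, 1, gB))
  eAll <- sum(bruteInternalEnergy(ef$traj, 1, c(gA, gB)))
  expect_equal(supermolecularInteraction(eAll, eA, eB), eCross,
               tolerance = 1e-8)
  # non-interacting fragments: Delta E = 0
  far <- .pairSystem(50)
  e <- sum(pairEnergy(far, 1, 1, 2))
  expect_equal(e, 0, tolerance = 1e-12)
})

test_that("drug-lipid decomposition matches per-frame recomputation", {
  traj <- generateMembraneTrajectory(membraneSpec(
    n_lipids_per_leaflet = 10, n_frames = 30, n_drugs_adsorbed = 2,
    n_drugs_free = 2, n_waters = 40, seed = 23))
  frames <- selectAnalysisFrames(traj)
  dec <- decomposeDrugLipid(traj, frames = frames, zThreshold = 24)
  # solution drugs sit farther than the cutoff from any lipid: zero energy
  sol <- dec$byMolecule[dec$byMolecule$location_class == "solution", ]
  expect_gt(nrow(sol), 0)
  expect_equal(max(abs(c(sol$elec_lipid, sol$vdw_lipid))), 0)
  # adsorbed class average equals the brute mean over its observations
  obs <- dec$observations
  ads <- obs[obs$location_class == "adsorbed", ]
  expect_equal(
    dec$byClass$elec[dec$byClass$location_class == "adsorbed" &
                       dec$byClass$target == "lipid"],
    mean(ads$elec_lipid), tolerance = 1e-12)
  # single static adsorbed drug: class average equals one pairEnergy call
  lipRows <- selectAtoms(traj, kind = "lipid")
  mid <- dec$byMolecule$molecule_id[
    dec$byMolecule$location_class == "adsorbed"][1]
  rows <- which(atomTable(traj)$molecule_id == mid)
  one <- decomposeDrugLipid(traj, drugMolecules = mid,
                            frames = frames[1], zThreshold = 24)
  eRef <- pairEnergy(traj, frames[1], rows, lipRows)
  expect_equal(one$byMolecule$elec_lipid, unname(eRef["elec"]),
               tolerance = 1e-10)
  expect_equal(one$byMolecule$vdw_lipid, unname(eRef["vdw"]),
               tolerance = 1e-10)
})
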