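# Structural metrics: APL, thicknesses, order parameters.

.flatBilayer <- function(zP = 19, zC2 = 15) {
  atoms <- helperAtoms(4, element = c("P", "C", "P", "C"),
                       mass = c(123, 14, 123, 14),
                       molecule_id = c(0L, 0L, 1L, 1L),
                       molecule_kind = "lipid",
                       labels = c("P", "C2", "P", "C2"))
  co <- rbind(c(0, 0, zP), c(0, 0, zC2), c(5, 5, -zP), c(5, 5, -zC2))
  makeTraj(atoms, co, box = c(80, 80, 100))
}

test_that("area per lipid is box area over leaflet count, frame-averaged", {
  atoms <- helperAtoms(2, element = "P", mass = 123,
                       molecule_id = 0:1, molecule_kind = "lipid",
                       labels = "P")
  co <- array(rep(rbind(c(0, 0, 19), c(0, 0, -19)), 3), c(2, 3, 3))
  box <- rbind(c(80, 80, 100), c(82, 82, 100), c(84, 84, 100))
  traj <- Trajectory(Topology(atoms, leafletCounts = c(upper = 100L,
                                                       lower = 100L)),
                     co, box = box, times = 0:2)
  expect_equal(areaPerLipid(traj, "upper")$apl,
               mean(c(80 * 80, 82 * 82, 84 * 84)) / 100)
  traj1 <- Trajectory(Topology(atoms, leafletCounts = c(upper = 100L,
                                                        lower = 100L)),
                      co[, , 1, drop = FALSE], box = c(80, 80, 100),
                      times = 0)
  expect_equal(areaPerLipid(traj1, "upper")$apl, 64.0)
})

test_that("synthetic APL is recovered exactly from the constructed box", {
  traj <- generateMembraneTrajectory(membraneSpec(
    n_lipids_per_leaflet = 12, apl = 67.3, n_frames = 4, n_waters = 5,
    seed = 2))
  expect_equal(areaPerLipid(traj, "upper")$apl, 67.3, tolerance = 1e-6)
  expect_equal(areaPerLipid(traj, "lower")$apl, 67.3, tolerance = 1e-6)
})

test_that("thickness metrics follow their leaflet-mean definitions", {
  traj <- .flatBilayer()
  expect_equal(bilayerThickness(traj)$thickness, 38.0)
  expect_equal(hydrophobicThickness(traj)$thickness, 30.0)
  # P sits outside C2, so bilayer > hydrophobic
  expect_gt(bilayerThickness(traj)$thickness,
            hydrophobicThickness(traj)$thickness)

  # single-leaflet system: contract violation
  atoms <- helperAtoms(2, element = "P", mass = 123, molecule_id = 0:1,
                       molecule_kind = "lipid", labels = "P")
  oneSide <- makeTraj(atoms, rbind(c(0, 0, 19), c(5, 5, 18)),
                      box = c(50, 50, 100))
  expect_error(bilayerThickness(oneSide), "both leaflets")
})

test_that("thickness metrics are invariant under translation and xy-rotation", {
  traj <- generateMembraneTrajectory(membraneSpec(
    n_lipids_per_leaflet = 10, n_frames = 5, n_waters = 10, seed = 8))
  t0 <- bilayerThickness(traj)$thickness
  shifted <- traj
  shifted@coords[, 3, ] <- shifted@coords[, 3, ] + 11
  expect_equal(bilayerThickness(shifted)$thickness, t0,
               tolerance = 1e-12)
  rot <- traj
  th <- 30 * pi / 180
  x <- rot@coords[, 1, ]; y <- rot@coords[, 2, ]
  rot@coords[, 1, ] <- cos(th) * x - sin(th) * y
  rot@coords[, 2, ] <- sin(th) * x + cos(th) * y
  expect_equal(bilayerThickness(rot)$thickness, t0, tolerance = 1e-9)
})

test_that("generator headgroup separation is recovered within noise", {
  spec <- membraneSpec(n_lipids_per_leaflet = 100, n_frames = 50,
                       headgroup_z_mean = 19, headgroup_z_sigma = 1,
                       n_waters = 20, seed = 4)
  traj <- generateMembraneTrajectory(spec)
  expect_equal(bilayerThickness(traj)$thickness, 38.0, tolerance = 0.2)
  expect_gt(bilayerThickness(traj)$thickness,
            hydrophobicThickness(traj)$thickness)
})

test_that("monolayer thickness uses P and terminal carbons in one leaflet", {
  atoms <- helperAtoms(4, element = c("P", "C", "P", "C"),
                       mass = c(123, 15, 123, 15),
                       molecule_id = c(0L, 0L, 1L, 1L),
                       molecule_kind = "lipid",
                       labels = c("P", "terminal_CH3", "P",
                                  "terminal_CH3"))
  co <- rbind(c(0, 0, 30), c(0, 0, 18), c(4, 4, -30), c(4, 4, -18))
  traj <- makeTraj(atoms, co, box = c(50, 50, 200),
                   geometry = "monolayer_pair")
  expect_equal(monolayerThickness(traj, "upper")$thickness, 12.0)
  expect_error(monolayerThickness(.flatBilayer()), "geometry")
})

test_that("tilted chains shorten the monolayer thickness as cos(tilt)", {
  t0 <- monolayerThickness(makeTiltedMonolayer(0), "upper")$thickness
  t60 <- monolayerThickness(makeTiltedMonolayer(60), "upper")$thickness
  expect_equal(t0, 8 * 1.25, tolerance = 1e-6)   # constructed extent
  expect_equal(t60 / t0, cos(60 * pi / 180), tolerance = 0.02)
})

test_that("order parameters hit the closed-form limits", {
  # all-trans chains along z: S_mol = 1 at every interior carbon
  up <- makeChainSystem(matrix(rep(c(0, 0, 1), 10), ncol = 3,
                               byrow = TRUE))
  opUp <- orderParameters(up, "sn1")
  expect_true(all(abs(opUp$s_mol - 1) < 1e-12))

  # magic angle: S_mol = 0
  ma <- 54.7356 * pi / 180
  magic <- makeChainSystem(matrix(rep(c(sin(ma), 0, cos(ma)), 10),
                                  ncol = 3, byrow = TRUE))
  expect_true(all(abs(orderParameters(magic, "sn1")$s_mol) < 1e-3))

  # isotropic orientations: S_mol = 0 +/- 0.02 at 1e4 samples
  set.seed(31)
  u <- matrix(rnorm(3e4), ncol = 3)
  iso <- makeChainSystem(u)
  expect_true(all(abs(orderParameters(iso, "sn1")$s_mol) < 0.02))

  # bounds invariant on synthetic data
  traj <- generateMembraneTrajectory(membraneSpec(
    n_lipids_per_leaflet = 10, n_frames = 5, chain_tilt_deg = 25,
    n_waters = 5, seed = 5))
  sm <- orderParameters(traj, "sn1")$s_mol
  expect_true(all(sm >= -0.5 - 1e-12 & sm <= 1 + 1e-12))

  expect_error(orderParameters(up, "sn9"), "no atoms")
  short <- makeChainSystem(matrix(c(0, 0, 1), ncol = 3), nBeads = 2)
  expect_error(orderParameters(short, "sn1"), "fewer than 3")
})
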