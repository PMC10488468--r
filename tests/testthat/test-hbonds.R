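# Geometric hydrogen-bond detection, statistics and lifetimes.

test_that("the distance/angle criterion accepts and rejects as specified", {
  fx <- generateHBondFixture(data.frame(
    distance = c(2.9, 3.1, 2.9), angle = c(10, 10, 25),
    donor_element = "O", acceptor_label = "PO4_O"))
  ev <- detectHBonds(fx)
  expect_equal(nrow(ev), 1)               # only (2.9 A, 10 deg) passes
  expect_equal(ev$distance, 2.9, tolerance = 1e-9)
  expect_equal(ev$angle, 10, tolerance = 1e-6)
  expect_equal(ev$drug_role, "donor")
  expect_equal(ev$partner_class, "lipid_PO4")
})

test_that("choline nitrogens are acceptors only in extended mode", {
  fx <- generateHBondFixture(data.frame(
    distance = c(2.5, 2.5), angle = c(5, 5), donor_element = "O",
    acceptor_label = c("choline_N", "water")))
  std <- detectHBonds(fx)
  expect_equal(std$partner_class, "water")  # choline triple invisible
  ext <- detectHBonds(fx, extendedAcceptors = TRUE)
  expect_setequal(ext$partner_class, c("lipid_choline_N", "water"))
})

test_that("event counts are monotone in both cutoffs", {
  fr <- randomHBFrame(101)
  n1 <- nrow(detectHBonds(fr, dCut = 3.0, aCut = 20))
  n2 <- nrow(detectHBonds(fr, dCut = 3.5, aCut = 20))
  n3 <- nrow(detectHBonds(fr, dCut = 3.5, aCut = 35))
  expect_lte(n1, n2)
  expect_lte(n2, n3)
})

test_that("detection is invariant under rigid rotation about z", {
  fr <- randomHBFrame(55, nDon = 10, nAcc = 40, nInert = 50)
  k0 <- eventKey(detectHBonds(fr))
  expect_gt(length(k0), 0)
  th <- 25 * pi / 180
  rot <- fr
  x <- rot@coords[, 1, ]; y <- rot@coords[, 2, ]
  rot@coords[, 1, ] <- cos(th) * x - sin(th) * y
  rot@coords[, 2, ] <- sin(th) * x + cos(th) * y
  expect_identical(eventKey(detectHBonds(rot)), k0)
  shifted <- fr
  shifted@coords <- shifted@coords + 2.5
  expect_identical(eventKey(detectHBonds(shifted)), k0)
})

test_that("per-frame statistics average constructed bond counts exactly", {
  # 4 triples; two inside the cutoffs, two outside
  fx <- generateHBondFixture(data.frame(
    distance = c(2.0, 2.2, 3.6, 3.8), angle = 5, donor_element = "O",
    acceptor_label = "PO4_O"))
  co1 <- getFrame(fx, 1)$coords
  co2 <- co1
  a <- atomTable(fx)
  # frame 2: pull the two far acceptors to 2.4 A from their donors
  for (i in 3:4) {
    don <- which(a$molecule_id == 2 * (i - 1))[1]
    acc <- which(a$molecule_id == 2 * i - 1)
    u <- (co1[acc, ] - co1[don, ])
    co2[acc, ] <- co1[don, ] + u / sqrt(sum(u^2)) * 2.4
  }
  coords <- array(c(co1, co2), c(nrow(co1), 3, 2))
  traj <- Trajectory(topology(fx), coords, box = fx@box[c(1, 1), ],
                     times = c(0, 0.05))
  st <- hbondStatistics(traj)
  expect_equal(st$totalPerFrame, 3.0)     # frames with 2 and 4 bonds
  expect_equal(st$nFrames, 2)
  expect_equal(sum(st$byClass$mean_count_per_frame), 3.0)
  expect_equal(unique(st$byClass$partner_class), "lipid_PO4")

  # static replication: 3 bonds in every one of 10 frames
  fx3 <- generateHBondFixture(data.frame(
    distance = c(2.0, 2.2, 2.4), angle = 5, donor_element = "O",
    acceptor_label = "PO4_O"))
  co <- array(rep(getFrame(fx3, 1)$coords, 10),
              c(nAtoms(fx3), 3, 10))
  traj10 <- Trajectory(topology(fx3), co,
                       box = fx3@box[rep(1, 10), ],
                       times = (0:9) * 0.05)
  expect_equal(hbondStatistics(traj10)$totalPerFrame, 3.0)
})

test_that("lifetimes follow run lengths with and without gap bridging", {
  fx <- generateHBondFixture(data.frame(
    distance = 2.5, angle = 5, donor_element = "O",
    acceptor_label = "PO4_O"))
  base <- getFrame(fx, 1)$coords
  mkTraj <- function(present) {
    nf <- length(present)
    co <- array(rep(base, nf), c(nrow(base), 3, nf))
    acc <- 3L
    for (f in which(!present)) co[acc, 1, f] <- base[acc, 1] + 10
    Trajectory(topology(fx), co, box = fx@box[rep(1, nf), ],
               times = (seq_len(nf) - 1) * 0.05)   # 50 ps stride
  }
  # present in all 10 frames: one instance of 500 ps
  lt <- hbondLifetimes(mkTraj(rep(TRUE, 10)))
  expect_equal(lt$meanLifetime_ps, 500)
  expect_equal(nrow(lt$instances), 1)

  # present frames 1-4 and 6-10: gap of one frame
  pattern <- c(rep(TRUE, 4), FALSE, rep(TRUE, 5))
  bridged <- hbondLifetimes(mkTraj(pattern), gapTolerance = 1)
  expect_equal(nrow(bridged$instances), 1)
  expect_equal(bridged$meanLifetime_ps, 500)   # bridged gap counts

  strict <- hbondLifetimes(mkTraj(pattern), gapTolerance = 0)
  expect_equal(nrow(strict$instances), 2)
  expect_equal(sort(strict$instances$lifetime_ps), c(200, 250))
  expect_equal(strict$meanLifetime_ps, 225)
})

test_that("the detector matches the scalar brute-force recount", {
  for (seed in c(7, 19, 23)) {
    fr <- randomHBFrame(seed)
    impl <- eventKey(detectHBonds(fr))
    oracle <- eventKey(bruteHBonds(fr))
    expect_identical(impl, oracle)
  }
  expect_error(detectHBonds(generateBrownianEnsemble(2, 1e-6,
                                                     nFrames = 2)),
               "donor_H")
})
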