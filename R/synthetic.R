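# Synthetic-data generators. Every analysis stage in the package has a
# recovery or oracle test against data produced here with known ground
# truth; the ground-truth numbers are computed from the construction by
# closed-form arithmetic, never by the analysis code under test.

#' Specification for a synthetic membrane trajectory
#'
#' Defaults emulate the simulated systems the package targets: a
#' two-leaflet POPC-like membrane of 100 lipids per leaflet at the
#' equilibrated area per lipid of 67.3 A^2, headgroup phosphorus bands at
#' +/-19 A (bilayer P-P thickness 38 A), 18 drug molecules split between a
#' membrane-adsorbed slow population and a free fast population whose
#' diffusion coefficients straddle the 2e-6 cm^2/s two-range boundary, and
#' frames saved every 50 ps.
#'
#' Lipids are coarse bead chains (choline, P, C2 and tail beads ending in a
#' terminal CH3) that diffuse laterally only; drugs are two-atom rigid
#' donor bodies performing 3D Brownian motion, confined by reflecting walls
#' to the headgroup band (adsorbed population) or the water slab (free
#' population).
#'
#' @param n_lipids_per_leaflet lipids per leaflet.
#' @param apl area per lipid, A^2 (fixes the lateral box).
#' @param headgroup_z_mean mean |z| of the P band, A.
#' @param headgroup_z_sigma standard deviation of per-lipid P heights, A.
#' @param tail_length tail beads per chain (beyond C2).
#' @param n_drugs_adsorbed,n_drugs_free population sizes.
#' @param D_adsorbed,D_free drug diffusion coefficients, cm^2/s
#'   (must satisfy \code{D_adsorbed < D_free}).
#' @param chain_tilt_deg uniform chain tilt from the membrane normal.
#' @param n_frames number of frames (>= 2).
#' @param dt frame spacing, ns.
#' @param seed RNG seed; identical specs give bit-identical trajectories.
#' @param geometry \code{"bilayer"} or \code{"monolayer_pair"}.
#' @param n_waters water beads placed uniformly in the aqueous region.
#' @param D_lipid lateral lipid diffusion coefficient, cm^2/s.
#' @return a validated spec (list of class \code{"MembraneSpec"}).
#' @export
membraneSpec <- function(n_lipids_per_leaflet = 100, apl = 67.3,
                         headgroup_z_mean = 19, headgroup_z_sigma = 1,
                         tail_length = 8, n_drugs_adsorbed = 9,
                         n_drugs_free = 9, D_adsorbed = 0.5e-6,
                         D_free = 5e-6, chain_tilt_deg = 0,
                         n_frames = 200, dt = 0.05, seed = 1,
                         geometry = c("bilayer", "monolayer_pair"),
                         n_waters = 400, D_lipid = 8e-8) {
  geometry <- match.arg(geometry)
  spec <- list(n_lipids_per_leaflet = as.integer(n_lipids_per_leaflet),
               apl = apl, headgroup_z_mean = headgroup_z_mean,
               headgroup_z_sigma = headgroup_z_sigma,
               tail_length = as.integer(tail_length),
               n_drugs_adsorbed = as.integer(n_drugs_adsorbed),
               n_drugs_free = as.integer(n_drugs_free),
               D_adsorbed = D_adsorbed, D_free = D_free,
               chain_tilt_deg = chain_tilt_deg,
               n_frames = as.integer(n_frames), dt = dt,
               seed = as.integer(seed), geometry = geometry,
               n_waters = as.integer(n_waters), D_lipid = D_lipid)
  if (spec$apl <= 0) .stopf("apl must be > 0")
  if (spec$n_frames < 2) .stopf("n_frames must be >= 2")
  if (!(spec$D_adsorbed < spec$D_free)) {
    .stopf("D_adsorbed (%g) must be smaller than D_free (%g)",
           spec$D_adsorbed, spec$D_free)
  }
  if (sqrt(spec$apl) < 4) {
    .stopf("box too small to host lipids at apl = %g A^2", spec$apl)
  }
  if (spec$geometry == "monolayer_pair" && spec$n_drugs_free > 0 &&
      spec$headgroup_z_mean < 24) {
    .stopf(paste("monolayer water slab too thin for free drugs;",
                 "need headgroup_z_mean >= 24 A"))
  }
  class(spec) <- "MembraneSpec"
  spec
}

.drugAtomRows <- function(kind = "drug") {
  # heavy donor bead + its hydrogen; rigid body, H at +x offset 1.0 A
  data.frame(
    element = c("O", "H"),
    mass = c(204, 1.008),
    charge = c(0.10, 0.05),
    epsilon = c(0.20, 0.046),
    rmin_half = c(2.0, 0.22),
    labels = c("drug;donor;acceptor", "drug;donor_H"),
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic membrane trajectory
#'
#' Builds the system described by a [membraneSpec()]: lipids on a lattice
#' of area \code{apl} each, per-lipid P heights drawn from
#' \code{Normal(+/-headgroup_z_mean, headgroup_z_sigma)}, mirrored across
#' the two leaflets and frozen (lipids diffuse laterally only), chains
#' tilted by
#' \code{chain_tilt_deg}, and Brownian drug molecules with per-axis step
#' variance \code{2 D dt}. Output coordinates are wrapped into the centred
#' primary cell in x and y (and z for bilayers); the unwrapped drug
#' centre-of-mass paths, the population labels and the per-lipid P heights
#' are retained as ground truth in \code{metadata(traj)$truth}.
#'
#' @param spec a [membraneSpec()].
#' @return a [Trajectory-class] with ground truth in its metadata.
#' @export
generateMembraneTrajectory <- function(spec) {
  stopifnot(inherits(spec, "MembraneSpec"))
  set.seed(spec$seed)
  n <- spec$n_lipids_per_leaflet
  nf <- spec$n_frames
  hz <- spec$headgroup_z_mean
  tiltRad <- spec$chain_tilt_deg * pi / 180
  bond <- 1.25
  Lx <- Ly <- sqrt(spec$apl * n)
  Lz <- if (spec$geometry == "bilayer") 2 * (hz + 51) else
    2 * (hz + 4 + spec$tail_length * bond + 15)

  nside <- ceiling(sqrt(n))
  lat <- (seq_len(n) - 1L)
  latx <- -Lx / 2 + ((lat %% nside) + 0.5) * Lx / nside
  laty <- -Ly / 2 + ((lat %/% nside) + 0.5) * Ly / nside

  # interior direction of the tails: toward z = 0 for a bilayer, away from
  # the water slab (at z = 0) for an opposed-monolayer pair
  tailDir <- function(s) if (spec$geometry == "bilayer") -s else s

  nb <- 3L + spec$tail_length            # beads per lipid
  atoms <- list(); base <- list()
  beadLip <- integer(0)
  lipZ <- numeric(0)
  molId <- 0L
  zPbase <- stats::rnorm(n, hz, spec$headgroup_z_sigma)
  for (s in c(1, -1)) {
    zP <- s * zPbase    # mirrored leaflets: rho(z) = rho(-z) for lipids
    lipZ <- c(lipZ, zP)
    d <- tailDir(s)
    zoff <- c(-3 * d, 0, 4 * d, 4 * d + seq_len(spec$tail_length) * bond *
                cos(tiltRad) * d)
    xoff <- c(0, 0, 0, seq_len(spec$tail_length) * bond * sin(tiltRad))
    lbl <- c("choline;choline_N", "P;PO4_O;acceptor", "C2;sn1",
             rep("sn1", spec$tail_length))
    mid <- ceiling(spec$tail_length / 2)
    lbl[3L + mid] <- paste0(lbl[3L + mid], ";double_bond")
    lbl[nb] <- paste0(lbl[nb], ";terminal_CH3")
    elem <- c("N", "P", "C", rep("C", spec$tail_length))
    mass <- c(87, 123, 14, rep(14, spec$tail_length - 1L), 15)
    chg <- c(0.25, -0.25, rep(0, spec$tail_length + 1L))
    eps <- c(0.15, 0.15, rep(0.10, spec$tail_length + 1L))
    rmh <- c(2.1, 2.1, rep(2.0, spec$tail_length + 1L))
    for (i in seq_len(n)) {
      atoms[[length(atoms) + 1L]] <- data.frame(
        element = elem, mass = mass, charge = chg, epsilon = eps,
        rmin_half = rmh, molecule_id = molId, molecule_kind = "lipid",
        labels = lbl, stringsAsFactors = FALSE)
      base[[length(base) + 1L]] <- cbind(latx[i] + xoff, laty[i],
                                         zP[i] + zoff)
      beadLip <- c(beadLip, rep(molId + 1L, nb))
      molId <- molId + 1L
    }
  }
  nLip <- molId

  # waters: static beads filling the aqueous region
  if (spec$n_waters > 0) {
    side <- sample(c(1, -1), spec$n_waters, replace = TRUE)
    wz <- if (spec$geometry == "bilayer") {
      side * stats::runif(spec$n_waters, hz + 6, Lz / 2 - 2)
    } else {
      stats::runif(spec$n_waters, -(hz - 8), hz - 8)
    }
    for (i in seq_len(spec$n_waters)) {
      atoms[[length(atoms) + 1L]] <- data.frame(
        element = "O", mass = 18.015, charge = 0, epsilon = 0.15,
        rmin_half = 1.77, molecule_id = molId, molecule_kind = "water",
        labels = "water;acceptor", stringsAsFactors = FALSE)
      base[[length(base) + 1L]] <- cbind(
        stats::runif(1, -Lx / 2, Lx / 2), stats::runif(1, -Ly / 2, Ly / 2),
        wz[i])
      molId <- molId + 1L
    }
  }
  nStaticAtoms <- sum(vapply(base, nrow, integer(1)))

  # drugs: adsorbed then free; reflecting z-walls keep each population in
  # its region over the analysed window
  nDrug <- spec$n_drugs_adsorbed + spec$n_drugs_free
  drugInfo <- NULL
  drugPaths <- NULL
  if (nDrug > 0) {
    pop <- rep(c("adsorbed", "solution"),
               c(spec$n_drugs_adsorbed, spec$n_drugs_free))
    Dd <- ifelse(pop == "adsorbed", spec$D_adsorbed, spec$D_free)
    sgn <- sample(c(1, -1), nDrug, replace = TRUE)
    drugPaths <- array(NA_real_, dim = c(nf, 3, nDrug))
    for (k in seq_len(nDrug)) {
      if (pop[k] == "adsorbed") {
        wall <- sort(sgn[k] * c(hz - 6, hz + 4))
      } else if (spec$geometry == "bilayer") {
        wall <- sort(sgn[k] * c(hz + 20, Lz / 2 - 3))
      } else {
        wall <- c(-(hz - 20), hz - 20)
      }
      sd3 <- sqrt(2 * (Dd[k] / .A2NS_TO_CM2S) * spec$dt)
      start <- c(stats::runif(1, -Lx / 2, Lx / 2),
                 stats::runif(1, -Ly / 2, Ly / 2),
                 stats::runif(1, wall[1], wall[2]))
      steps <- matrix(stats::rnorm(3 * (nf - 1), 0, sd3), ncol = 3)
      path <- rbind(start, sweep(.cumsumCols(steps), 2, start, "+"))
      path[, 3] <- .reflect(path[, 3], wall[1], wall[2])
      drugPaths[, , k] <- path
      ad <- .drugAtomRows()
      ad$molecule_id <- molId
      ad$molecule_kind <- "drug"
      atoms[[length(atoms) + 1L]] <- ad
      molId <- molId + 1L
    }
    drugInfo <- data.frame(molecule_id = nLip + spec$n_waters +
                             seq_len(nDrug) - 1L,
                           population = pop, D_cm2_s = Dd,
                           leaflet_sign = sgn)
  }

  atomDf <- do.call(rbind, atoms)
  atomDf$index <- seq_len(nrow(atomDf)) - 1L
  topo <- Topology(atomDf[, c("index", "element", "mass", "charge",
                              "epsilon", "rmin_half", "molecule_id",
                              "molecule_kind", "labels")],
                   geometry = spec$geometry,
                   leafletCounts = c(upper = n, lower = n))

  nat <- nrow(atomDf)
  coords <- array(NA_real_, dim = c(nat, 3, nf))
  baseM <- do.call(rbind, base)

  # lateral lipid random walks, applied rigidly to every bead of a lipid
  sdL <- sqrt(2 * (spec$D_lipid / .A2NS_TO_CM2S) * spec$dt)
  dispX <- rbind(0, .cumsumCols(matrix(stats::rnorm(nLip * (nf - 1), 0, sdL),
                                       ncol = nLip)))
  dispY <- rbind(0, .cumsumCols(matrix(stats::rnorm(nLip * (nf - 1), 0, sdL),
                                       ncol = nLip)))
  lipRows <- seq_len(sum(beadLip > 0))
  coords[lipRows, 1, ] <- baseM[lipRows, 1] + t(dispX[, beadLip])
  coords[lipRows, 2, ] <- baseM[lipRows, 2] + t(dispY[, beadLip])
  coords[lipRows, 3, ] <- baseM[lipRows, 3]

  watRows <- setdiff(seq_len(nStaticAtoms), lipRows)
  if (length(watRows)) {
    for (d in 1:3) coords[watRows, d, ] <- baseM[watRows, d]
  }

  if (nDrug > 0) {
    for (k in seq_len(nDrug)) {
      r0 <- nStaticAtoms + 2L * (k - 1L) + 1L
      coords[r0, , ] <- t(drugPaths[, , k])
      coords[r0 + 1L, , ] <- t(drugPaths[, , k] + rep(c(1, 0, 0),
                                                      each = nf))
    }
  }

  # wrap into the centred primary cell: x, y always; z only for bilayers
  coords[, 1, ] <- .wrapCentered(coords[, 1, ], Lx)
  coords[, 2, ] <- .wrapCentered(coords[, 2, ], Ly)
  if (spec$geometry == "bilayer") {
    coords[, 3, ] <- .wrapCentered(coords[, 3, ], Lz)
  }

  truth <- list(spec = spec, drugs = drugInfo, lipid_z = lipZ)
  if (nDrug > 0) {
    # drug centre of mass: rigid 2-atom body, constant offset from heavy atom
    mH <- .drugAtomRows()$mass
    comOff <- c(mH[2] / sum(mH), 0, 0)
    truth$unwrapped_com <- drugPaths +
      rep(rep(comOff, each = nf), times = nDrug)
  }
  Trajectory(topo, coords, box = c(Lx, Ly, Lz),
             times = (seq_len(nf) - 1L) * spec$dt,
             metadata = list(truth = truth))
}

#' Generate a free Brownian ensemble of single-bead molecules
#'
#' Pure, unconfined 3D Brownian motion in a periodic box: the reference
#' system for Einstein-relation diffusion estimation. Output coordinates
#' are wrapped; unwrapped paths are kept in \code{metadata(traj)$truth}.
#'
#' @param nMolecules number of molecules (one bead each).
#' @param D diffusion coefficient(s), cm^2/s; recycled over molecules.
#' @param nFrames frames; @param dt frame spacing, ns.
#' @param box length-3 box, A.
#' @param seed RNG seed.
#' @return a [Trajectory-class] with truth (unwrapped paths, D per
#'   molecule) in metadata.
#' @export
generateBrownianEnsemble <- function(nMolecules, D, nFrames = 1000,
                                     dt = 0.05, box = c(200, 200, 200),
                                     seed = 1) {
  set.seed(seed)
  D <- rep(D, length.out = nMolecules)
  atoms <- data.frame(
    index = seq_len(nMolecules) - 1L, element = "C", mass = 100,
    charge = 0, epsilon = 0.1, rmin_half = 2.0,
    molecule_id = seq_len(nMolecules) - 1L, molecule_kind = "drug",
    labels = "drug", stringsAsFactors = FALSE)
  coords <- array(NA_real_, dim = c(nMolecules, 3, nFrames))
  unwrapped <- array(NA_real_, dim = c(nFrames, 3, nMolecules))
  for (k in seq_len(nMolecules)) {
    sdk <- sqrt(2 * (D[k] / .A2NS_TO_CM2S) * dt)
    start <- stats::runif(3, -box / 4, box / 4)
    steps <- matrix(stats::rnorm(3 * (nFrames - 1), 0, sdk), ncol = 3)
    path <- rbind(start, sweep(.cumsumCols(steps), 2, start, "+"))
    unwrapped[, , k] <- path
    coords[k, , ] <- t(.wrapCentered(path, rep(box, each = nFrames)))
  }
  Trajectory(Topology(atoms), coords, box = box,
             times = (seq_len(nFrames) - 1L) * dt,
             metadata = list(truth = list(D_cm2_s = D,
                                          unwrapped_com = unwrapped)))
}

#' Construct isolated donor-H...acceptor triples with exact geometry
#'
#' Each case becomes one donor molecule (heavy donor + hydrogen at 1.0 A)
#' and one acceptor atom, with the requested donor-acceptor distance and
#' the requested angle between the donor-to-hydrogen and donor-to-acceptor
#' vectors; triples are separated by 20 A so they cannot interfere.
#' Acceptors labelled \code{"choline_N"} carry only that label (they are
#' found by the detector only in extended-acceptor mode); all others carry
#' \code{"acceptor"} plus the requested class label.
#'
#' @param cases data.frame with columns \code{distance} (A, > 0.5),
#'   \code{angle} (degrees), \code{donor_element} (\code{"O"}/\code{"N"}),
#'   \code{acceptor_label} (e.g. \code{"PO4_O"}, \code{"water"},
#'   \code{"choline_N"}).
#' @return a single-frame [Trajectory-class].
#' @export
generateHBondFixture <- function(cases) {
  stopifnot(all(c("distance", "angle", "donor_element",
                  "acceptor_label") %in% names(cases)))
  if (any(cases$distance <= 0.5)) .stopf("distances must exceed 0.5 A")
  nc <- nrow(cases)
  atoms <- list(); xyz <- list()
  mol <- 0L
  for (i in seq_len(nc)) {
    ox <- 20 * (i - 1)
    a <- cases$angle[i] * pi / 180
    dAcc <- cases$distance[i]
    accLab <- cases$acceptor_label[i]
    accKind <- if (accLab == "water") "water" else "lipid"
    accLabels <- if (accLab == "choline_N") "choline_N" else
      paste("acceptor", accLab, sep = ";")
    accElem <- if (grepl("N", accLab)) "N" else "O"
    atoms[[length(atoms) + 1L]] <- data.frame(
      element = c(cases$donor_element[i], "H"),
      mass = c(15.999, 1.008), charge = c(-0.5, 0.3),
      epsilon = c(0.15, 0.046), rmin_half = c(1.77, 0.22),
      molecule_id = mol, molecule_kind = "drug",
      labels = c("drug;donor", "drug;donor_H"), stringsAsFactors = FALSE)
    xyz[[length(xyz) + 1L]] <- rbind(c(ox, 0, 0),
                                     c(ox + cos(a), sin(a), 0))
    mol <- mol + 1L
    atoms[[length(atoms) + 1L]] <- data.frame(
      element = accElem, mass = 15.999, charge = -0.5, epsilon = 0.15,
      rmin_half = 1.77, molecule_id = mol, molecule_kind = accKind,
      labels = accLabels, stringsAsFactors = FALSE)
    xyz[[length(xyz) + 1L]] <- rbind(c(ox + dAcc, 0, 0))
    mol <- mol + 1L
  }
  atomDf <- do.call(rbind, atoms)
  atomDf$index <- seq_len(nrow(atomDf)) - 1L
  topo <- Topology(atomDf[, c("index", "element", "mass", "charge",
                              "epsilon", "rmin_half", "molecule_id",
                              "molecule_kind", "labels")])
  box <- c(20 * nc + 60, 60, 60)
  Trajectory(topo, do.call(rbind, xyz), box = box, times = 0,
             metadata = list(cases = cases))
}

#' Generate isolated charged Lennard-Jones pairs with closed-form energies
#'
#' Random charges, LJ parameters and separations (2.5-14 A, so some pairs
#' fall beyond the 12 A cutoff); pairs are 40 A apart so cross-pair terms
#' vanish. The reference table is computed by an independent scalar
#' formula (CHARMM combining rules, Coulomb constant 332.0636, switching
#' over 10-12 A), not by the energetics module.
#'
#' @param nPairs number of pairs (>= 1).
#' @param seed RNG seed.
#' @param cutoff,switchStart cutoff scheme used for the reference, A.
#' @return list: \code{traj} (single-frame [Trajectory-class]; pair member
#'   A is kind \code{"drug"}, label \code{"grpA"}; member B kind
#'   \code{"lipid"}, label \code{"grpB"}), \code{reference} (per-pair
#'   data.frame \code{pair}, \code{r}, \code{elec}, \code{vdw}, kcal/mol).
#' @export
generateEnergyFixture <- function(nPairs, seed = 1, cutoff = 12,
                                  switchStart = 10) {
  stopifnot(nPairs >= 1)
  set.seed(seed)
  atoms <- list(); xyz <- list(); ref <- list()
  ron2 <- switchStart^2; roff2 <- cutoff^2
  for (p in seq_len(nPairs)) {
    ox <- 40 * (p - 1)
    r <- stats::runif(1, 2.5, 14)
    u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
    q <- stats::runif(2, -0.7, 0.7)
    eps <- stats::runif(2, 0.05, 0.3)
    rmh <- stats::runif(2, 1.6, 2.4)
    atoms[[p]] <- data.frame(
      element = c("C", "C"), mass = c(12.011, 12.011), charge = q,
      epsilon = eps, rmin_half = rmh,
      molecule_id = c(2L * p - 2L, 2L * p - 1L),
      molecule_kind = c("drug", "lipid"),
      labels = c("drug;grpA", "lipid;grpB"), stringsAsFactors = FALSE)
    xyz[[p]] <- rbind(c(ox, 0, 0), c(ox, 0, 0) + r * u)
    # independent scalar reference
    if (r > cutoff) {
      ev <- c(0, 0)
    } else {
      sw <- if (r <= switchStart) 1 else
        (roff2 - r^2)^2 * (roff2 + 2 * r^2 - 3 * ron2) / (roff2 - ron2)^3
      rmin <- rmh[1] + rmh[2]
      epsab <- sqrt(eps[1] * eps[2])
      ev <- c(332.0636 * q[1] * q[2] / r * sw,
              epsab * ((rmin / r)^12 - 2 * (rmin / r)^6) * sw)
    }
    ref[[p]] <- data.frame(pair = p, r = r, elec = ev[1], vdw = ev[2])
  }
  atomDf <- do.call(rbind, atoms)
  atomDf$index <- seq_len(nrow(atomDf)) - 1L
  topo <- Topology(atomDf[, c("index", "element", "mass", "charge",
                              "epsilon", "rmin_half", "molecule_id",
                              "molecule_kind", "labels")])
  box <- c(40 * nPairs + 100, 200, 200)
  list(traj = Trajectory(topo, do.call(rbind, xyz), box = box, times = 0),
       reference = do.call(rbind, ref),
       cutoff = cutoff, switchStart = switchStart)
}

#' Generate a toy quantum-chemistry state table with known descriptors
#'
#' Energies are built from drawn ionization potential and electron
#' affinity; atomic charges are built from drawn per-atom Fukui weights
#' that sum exactly to one, so electron counts differ by exactly one
#' between adjacent states. The returned ground truth (I, A, mu, eta and
#' the three Fukui vectors) comes from the construction itself.
#'
#' @param nAtoms atoms in the toy molecule (>= 1).
#' @param seed RNG seed.
#' @param environment environment tag for the table.
#' @return list: \code{table} (a [QMStateTable-class]) and \code{truth}
#'   (list \code{I}, \code{A}, \code{mu}, \code{eta}, \code{f_n},
#'   \code{f_e}, \code{f_r}; atomic units).
#' @export
generateQMFixture <- function(nAtoms, seed = 1, environment = "vacuum") {
  stopifnot(nAtoms >= 1)
  set.seed(seed)
  z <- sample(c(1, 6, 7, 8, 16), nAtoms, replace = TRUE)
  elements <- c("1" = "H", "6" = "C", "7" = "N", "8" = "O",
                "16" = "S")[as.character(z)]
  ion <- stats::runif(1, 0.2, 0.5)
  aff <- stats::runif(1, 0.01, 0.15)
  eN <- -stats::runif(1, 50, 500)
  energies <- c(Nminus1 = eN + ion, N = eN, Nplus1 = eN - aff)
  # per-atom Fukui weights summing exactly to 1 (negatives allowed)
  fN <- stats::runif(nAtoms, -0.2, 1); fN <- fN / sum(fN)
  fE <- stats::runif(nAtoms, -0.2, 1); fE <- fE / sum(fE)
  qN <- stats::runif(nAtoms, -0.5, 0.5)
  popN <- z - qN
  popPlus <- popN + fN
  popMinus <- popN - fE
  charges <- cbind(Nminus1 = z - popMinus, N = qN, Nplus1 = z - popPlus)
  truth <- list(I = ion, A = aff, mu = -(ion + aff) / 2, eta = ion - aff,
                f_n = fN, f_e = fE, f_r = (fN + fE) / 2)
  list(table = QMStateTable("toy", energies = energies, charges = charges,
                            atomicNumbers = z, elements = elements,
                            environment = environment),
       truth = truth)
}
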