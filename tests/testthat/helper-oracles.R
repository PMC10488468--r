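# Shared fixture builders and independent (brute-force, scalar) oracles.
# Oracles deliberately avoid the vectorized code paths of the package.

helperAtoms <- function(n, element = "C", mass = 12, charge = 0,
                        epsilon = 0.1, rmin_half = 2,
                        molecule_id = seq_len(n) - 1L,
                        molecule_kind = "drug", labels = "") {
  data.frame(index = seq_len(n) - 1L, element = element, mass = mass,
             charge = charge, epsilon = epsilon, rmin_half = rmin_half,
             molecule_id = molecule_id, molecule_kind = molecule_kind,
             labels = labels, stringsAsFactors = FALSE)
}

makeTraj <- function(atoms, coords, box, times = NULL,
                     geometry = "bilayer", leafletCounts = integer(0)) {
  if (length(dim(coords)) == 2) coords <- array(coords, c(dim(coords), 1))
  if (is.null(times)) times <- (seq_len(dim(coords)[3]) - 1) * 0.05
  Trajectory(Topology(atoms, geometry = geometry,
                      leafletCounts = leafletCounts),
             coords, box = box, times = times)
}

# scalar double-loop hydrogen-bond recount (independent of detectHBonds)
bruteHBonds <- function(traj, frame = 1, dCut = 3, aCut = 20,
                        extended = FALSE) {
  a <- atomTable(traj)
  co <- traj@coords[, , frame]
  box <- traj@box[frame, ]
  splitLabs <- strsplit(a$labels, ";", fixed = TRUE)
  has <- function(i, l) l %in% splitLabs[[i]]
  hs <- which(vapply(seq_len(nrow(a)), has, logical(1), l = "donor_H"))
  accs <- which(vapply(seq_len(nrow(a)), function(i) {
    has(i, "acceptor") || (extended && has(i, "choline_N"))
  }, logical(1)))
  out <- NULL
  for (h in hs) {
    cand <- which(a$molecule_id == a$molecule_id[h] &
                    a$element %in% c("N", "O"))
    best <- NA; bestd <- Inf
    for (d in cand) {
      v <- co[d, ] - co[h, ]
      v <- v - box * round(v / box)
      if (sum(v^2) < bestd) { bestd <- sum(v^2); best <- d }
    }
    don <- best
    for (acc in accs) {
      if (a$molecule_id[acc] == a$molecule_id[don]) next
      da <- co[acc, ] - co[don, ]
      da <- da - box * round(da / box)
      r <- sqrt(sum(da^2))
      if (r >= dCut) next
      dh <- co[h, ] - co[don, ]
      dh <- dh - box * round(dh / box)
      cosang <- sum(dh * da) / sqrt(sum(dh^2) * sum(da^2))
      ang <- acos(min(1, max(-1, cosang))) * 180 / pi
      if (ang <= aCut) {
        out <- rbind(out, data.frame(donor = don, hydrogen = h,
                                     acceptor = acc))
      }
    }
  }
  out
}

# random labelled frame for detector stress tests: nDon donor molecules
# (heavy O + H at 1 A), nAcc acceptor atoms, nInert unlabelled atoms.
# Most donors get one acceptor planted near the hydrogen direction with
# distances/angles straddling the cutoffs, so every frame carries a mix
# of accepted and rejected candidate bonds.
randomHBFrame <- function(seed, nDon = 25, nAcc = 100, nInert = 350,
                          box = 30) {
  set.seed(seed)
  atoms <- list(); xyz <- list(); mol <- 0L
  planted <- list()
  for (k in seq_len(nDon)) {
    p <- runif(3, -box / 2, box / 2)
    u <- rnorm(3); u <- u / sqrt(sum(u^2))
    atoms[[length(atoms) + 1L]] <- helperAtoms(
      2, element = c("O", "H"), mass = c(16, 1), molecule_id = mol,
      molecule_kind = "drug", labels = c("drug;donor", "drug;donor_H"))
    xyz[[length(xyz) + 1L]] <- rbind(p, p + u)
    mol <- mol + 1L
    if (runif(1) < 0.7) {
      # acceptor at U(2, 3.6) A, tilted U(0, 35) deg off the D->H axis
      r <- runif(1, 2, 3.6)
      th <- runif(1, 0, 35) * pi / 180
      w <- rnorm(3); w <- w - sum(w * u) * u; w <- w / sqrt(sum(w^2))
      planted[[length(planted) + 1L]] <-
        p + r * (cos(th) * u + sin(th) * w)
    }
  }
  for (k in seq_len(nAcc)) {
    pos <- if (k <= length(planted)) planted[[k]] else
      runif(3, -box / 2, box / 2)
    atoms[[length(atoms) + 1L]] <- helperAtoms(
      1, element = "O", mass = 16, molecule_id = mol,
      molecule_kind = "lipid", labels = "acceptor;PO4_O")
    xyz[[length(xyz) + 1L]] <- matrix(pos, 1)
    mol <- mol + 1L
  }
  for (k in seq_len(nInert)) {
    atoms[[length(atoms) + 1L]] <- helperAtoms(
      1, element = "C", mass = 12, molecule_id = mol,
      molecule_kind = "water", labels = "")
    xyz[[length(xyz) + 1L]] <- matrix(runif(3, -box / 2, box / 2), 1)
    mol <- mol + 1L
  }
  atomDf <- do.call(rbind, atoms)
  atomDf$index <- seq_len(nrow(atomDf)) - 1L
  makeTraj(atomDf, do.call(rbind, xyz), box = c(box, box, box))
}

eventKey <- function(ev) {
  if (is.null(ev) || !nrow(ev)) return(character(0))
  sort(paste(ev$donor, ev$hydrogen, ev$acceptor, sep = "_"))
}

# O(n^2) scalar MSD oracle
bruteMSD <- function(path, dims = 1:3) {
  n <- nrow(path)
  msd <- numeric(n - 1)
  for (L in seq_len(n - 1)) {
    s <- 0
    for (t in seq_len(n - L)) {
      d <- path[t + L, dims] - path[t, dims]
      s <- s + sum(d^2)
    }
    msd[L] <- s / (n - L)
  }
  msd
}

# chains of nBeads along per-lipid direction vectors (rows of dirs)
makeChainSystem <- function(dirs, nBeads = 8, spacing = 1.5) {
  nLip <- nrow(dirs)
  atoms <- list(); xyz <- list()
  for (k in seq_len(nLip)) {
    u <- dirs[k, ] / sqrt(sum(dirs[k, ]^2))
    atoms[[k]] <- helperAtoms(nBeads, mass = 14, molecule_id = k - 1L,
                              molecule_kind = "lipid", labels = "sn1")
    origin <- c(((k - 1) %% 100) * 8, ((k - 1) %/% 100) * 8, 0)
    xyz[[k]] <- t(vapply(seq_len(nBeads) - 1L,
                         function(j) origin + j * spacing * u,
                         numeric(3)))
  }
  atomDf <- do.call(rbind, atoms)
  atomDf$index <- seq_len(nrow(atomDf)) - 1L
  makeTraj(atomDf, do.call(rbind, xyz), box = c(1e4, 1e4, 1e4))
}

# opposed monolayers whose full P-to-terminal extent lies along a tilted
# chain axis: thickness = (nBeads-1) * spacing * cos(tilt)
makeTiltedMonolayer <- function(tiltDeg, nPerLeaflet = 5, nBeads = 9,
                                spacing = 1.25) {
  t <- tiltDeg * pi / 180
  atoms <- list(); xyz <- list(); mol <- 0L
  for (s in c(1, -1)) {
    for (k in seq_len(nPerLeaflet)) {
      labs <- c("P", rep("sn1", nBeads - 1L))
      labs[nBeads] <- "sn1;terminal_CH3"
      atoms[[length(atoms) + 1L]] <- helperAtoms(
        nBeads, element = c("P", rep("C", nBeads - 1L)), mass = 14,
        molecule_id = mol, molecule_kind = "lipid", labels = labs)
      origin <- c(k * 10, 0, s * 30)
      u <- c(sin(t), 0, s * cos(t))   # tails outward from the water slab
      xyz[[length(xyz) + 1L]] <- t(vapply(seq_len(nBeads) - 1L,
                                          function(j) origin + j * spacing * u,
                                          numeric(3)))
      mol <- mol + 1L
    }
  }
  atomDf <- do.call(rbind, atoms)
  atomDf$index <- seq_len(nrow(atomDf)) - 1L
  makeTraj(atomDf, do.call(rbind, xyz), box = c(500, 500, 500),
           geometry = "monolayer_pair")
}

# total internal pairwise energy of an atom set (scalar reference)
bruteInternalEnergy <- function(traj, frame, rows, cutoff = 12,
                                switchStart = 10) {
  a <- atomTable(traj)
  co <- traj@coords[, , frame]
  box <- traj@box[frame, ]
  tot <- c(elec = 0, vdw = 0)
  for (i in seq_along(rows)) {
    for (j in seq_len(i - 1)) {
      p <- rows[i]; q <- rows[j]
      d <- co[p, ] - co[q, ]
      d <- d - box * round(d / box)
      r <- sqrt(sum(d^2))
      if (r > cutoff) next
      sw <- if (r <= switchStart) 1 else {
        (cutoff^2 - r^2)^2 * (cutoff^2 + 2 * r^2 - 3 * switchStart^2) /
          (cutoff^2 - switchStart^2)^3
      }
      rmin <- a$rmin_half[p] + a$rmin_half[q]
      tot["elec"] <- tot["elec"] +
        332.0636 * a$charge[p] * a$charge[q] / r * sw
      tot["vdw"] <- tot["vdw"] +
        sqrt(a$epsilon[p] * a$epsilon[q]) *
        ((rmin / r)^12 - 2 * (rmin / r)^6) * sw
    }
  }
  tot
}
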