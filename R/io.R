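# Readers and writers for the external formats: PDB structures (via bio3d),
# the package's plain-text trajectory format (.trj), TSV topology tables and
# TSV quantum-chemistry state tables. All other modules consume only the
# Topology / Trajectory / QMStateTable containers built here.

.ELEMENT_MASSES <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                     P = 30.973762, S = 32.06, Na = 22.98977, Cl = 35.45,
                     K = 39.0983)

.KIND_RESID <- c(lipid = "LIP", drug = "DRG", water = "WAT", ion = "ION")

.guessKind <- function(resid) {
  resid <- toupper(resid)
  ifelse(resid %in% c("TIP3", "HOH", "WAT", "SOL", "SPC"), "water",
    ifelse(resid %in% c("SOD", "NA", "CLA", "CL", "POT", "K", "ION"), "ion",
      ifelse(resid %in% c("POPC", "POPG", "POPE", "DPPC", "LIP"), "lipid",
             "drug")))
}

#' Read a PDB structure
#'
#' Parses atoms with \pkg{bio3d} and the orthorhombic box from the CRYST1
#' record. Returns a topology skeleton (element, a standard-mass guess,
#' molecule membership from residue numbers; charges and LJ parameters
#' zeroed — the TSV topology table is the authoritative source for those)
#' together with the coordinate frame.
#'
#' @param path PDB file path.
#' @param box optional length-3 box (Angstrom) overriding/replacing CRYST1.
#' @return list with \code{topology} ([Topology-class] skeleton) and
#'   \code{frame} (list \code{coords}, \code{box}, \code{time = 0}).
#' @export
readStructurePDB <- function(path, box = NULL) {
  if (!file.exists(path)) .stopf("no such file: %s", path)
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom
  if (is.null(box)) {
    cl <- grep("^CRYST1", readLines(path, warn = FALSE), value = TRUE)
    if (!length(cl)) {
      .stopf("PDB %s has no CRYST1 record and no box was supplied", path)
    }
    box <- as.numeric(c(substr(cl[1], 7, 15), substr(cl[1], 16, 24),
                        substr(cl[1], 25, 33)))
    if (anyNA(box)) .stopf("malformed CRYST1 record in %s: %s", path, cl[1])
  }
  elem <- at$elesy
  if (is.null(elem) || all(is.na(elem)) || all(elem == "")) {
    elem <- sub("^([A-Za-z]).*", "\\1", at$elety)
  }
  elem <- sub("^\\s+|\\s+$", "", elem)
  mass <- .ELEMENT_MASSES[elem]
  mass[is.na(mass)] <- 12.011
  ch <- ifelse(is.na(at$chain), "", at$chain)
  nr <- nrow(at)
  mol <- cumsum(c(TRUE, diff(at$resno) != 0 | ch[-1] != ch[-nr])) - 1L
  atoms <- data.frame(
    index = seq_len(nrow(at)) - 1L,
    element = elem,
    mass = unname(mass),
    charge = 0, epsilon = 0, rmin_half = 0,
    molecule_id = as.integer(mol),
    molecule_kind = .guessKind(at$resid),
    labels = at$elety,
    stringsAsFactors = FALSE
  )
  coords <- cbind(at$x, at$y, at$z)
  colnames(coords) <- c("x", "y", "z")
  list(topology = Topology(atoms),
       frame = list(coords = coords, box = as.numeric(box), time = 0))
}

#' Write one frame as a PDB file
#'
#' Emits a CRYST1 record for the orthorhombic box followed by ATOM records
#' (written with \pkg{bio3d}); coordinates are truncated to the PDB's
#' 0.001-Angstrom precision.
#'
#' @param topology a [Topology-class].
#' @param frame frame list (\code{coords}, \code{box}) as from [getFrame()].
#' @param path output file.
#' @param subset optional 1-based atom row positions to write (in order).
#' @return invisibly, the path.
#' @export
writeStructurePDB <- function(topology, frame, path, subset = NULL) {
  a <- atomTable(topology)
  co <- frame$coords
  if (is.null(subset)) subset <- seq_len(nrow(a))
  a <- a[subset, , drop = FALSE]
  co <- co[subset, , drop = FALSE]
  b <- frame$box
  cat(sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1\n",
              b[1], b[2], b[3], 90, 90, 90), file = path)
  elety <- toupper(substr(a$element, 1, 1))
  bio3d::write.pdb(file = path, xyz = as.numeric(t(co)),
                   resno = a$molecule_id + 1L,
                   resid = .KIND_RESID[a$molecule_kind],
                   eleno = seq_len(nrow(a)),
                   elety = elety, elesy = elety,
                   append = TRUE, end = TRUE)
  invisible(path)
}

# --- plain-text trajectory format ------------------------------------------
# Line 1: "# memtraj-trj 1"
# Line 2: "natoms <N>"
# Then per frame: "frame <time_ns> <Lx> <Ly> <Lz>" followed by N lines "x y z"
# Coordinates in Angstrom, written at 1e-4 A precision.

#' Write a Trajectory in the package's text frame-sequence format
#'
#' @param traj a [Trajectory-class].
#' @param path output file (conventionally \code{.trj}).
#' @return invisibly, the path.
#' @export
writeTrajectoryTRJ <- function(traj, path) {
  n <- nAtoms(traj)
  nf <- nFrames(traj)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c("# memtraj-trj 1", paste("natoms", n)), con)
  for (i in seq_len(nf)) {
    b <- traj@box[i, ]
    writeLines(sprintf("frame %.6f %.4f %.4f %.4f",
                       traj@times[i], b[1], b[2], b[3]), con)
    co <- traj@coords[, , i]
    writeLines(sprintf("%.4f %.4f %.4f", co[, 1], co[, 2], co[, 3]), con)
  }
  invisible(path)
}

#' Read a Trajectory from the package's text frame-sequence format
#'
#' @param path input \code{.trj} file.
#' @param topology a [Topology-class] with matching atom count.
#' @return a [Trajectory-class].
#' @export
readTrajectoryTRJ <- function(path, topology) {
  if (!file.exists(path)) .stopf("no such file: %s", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 2 || !startsWith(lines[1], "# memtraj-trj")) {
    .stopf("%s is not a memtraj-trj file (bad header line 1)", path)
  }
  n <- as.integer(sub("^natoms\\s+", "", lines[2]))
  if (is.na(n)) .stopf("malformed natoms record at line 2 of %s", path)
  if (n != nAtoms(topology)) {
    .stopf("trajectory atom count (%d) does not match topology (%d)",
           n, nAtoms(topology))
  }
  body <- lines[-(1:2)]
  per <- n + 1L
  nf <- length(body) %/% per
  if (nf < 1) .stopf("%s contains no complete frames", path)
  if (length(body) %% per != 0) {
    .stopf("truncated trajectory %s: last complete frame is %d", path, nf)
  }
  hdrIdx <- (seq_len(nf) - 1L) * per + 1L
  hdr <- body[hdrIdx]
  if (!all(startsWith(hdr, "frame "))) {
    bad <- which(!startsWith(hdr, "frame "))[1]
    .stopf("malformed frame header at line %d of %s",
           2L + hdrIdx[bad], path)
  }
  hnum <- matrix(scan(text = sub("^frame ", "", hdr), quiet = TRUE),
                 nrow = nf, byrow = TRUE)
  xyz <- scan(text = body[-hdrIdx], quiet = TRUE)
  if (length(xyz) != 3L * n * nf) {
    .stopf("coordinate record count mismatch in %s", path)
  }
  coords <- array(NA_real_, dim = c(n, 3, nf))
  m <- matrix(xyz, ncol = 3, byrow = TRUE)
  for (i in seq_len(nf)) {
    coords[, , i] <- m[((i - 1L) * n + 1L):(i * n), ]
  }
  Trajectory(topology, coords, box = hnum[, 2:4, drop = FALSE],
             times = hnum[, 1])
}

# --- topology TSV -----------------------------------------------------------

#' Read a topology table (TSV)
#'
#' Columns: \code{index} (0-based), \code{element}, \code{mass},
#' \code{charge}, \code{epsilon}, \code{rmin_half}, \code{molecule_id},
#' \code{molecule_kind}, \code{labels} (semicolon-separated). Optional
#' header comment \code{# geometry: bilayer|monolayer_pair}.
#'
#' @param path TSV file.
#' @param geometry overrides the geometry comment if given.
#' @return a validated [Topology-class].
#' @export
readTopologyTable <- function(path, geometry = NULL) {
  if (!file.exists(path)) .stopf("no such file: %s", path)
  first <- readLines(path, n = 1L)
  if (is.null(geometry)) {
    geometry <- if (grepl("^# geometry:", first)) {
      sub("^# geometry:\\s*", "", first)
    } else "bilayer"
  }
  tab <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE)
  if (anyDuplicated(tab$index)) {
    .stopf("duplicate atom index in %s: %s", path,
           paste(unique(tab$index[duplicated(tab$index)]), collapse = ", "))
  }
  tab <- tab[order(tab$index), , drop = FALSE]
  Topology(tab, geometry = geometry)
}

#' Write a topology table (TSV)
#'
#' @param topology a [Topology-class].
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeTopologyTable <- function(topology, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste0("# geometry: ", topology@geometry), con)
  utils::write.table(atomTable(topology), con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

# --- QM state tables --------------------------------------------------------

#' Read quantum-chemistry state tables (TSV)
#'
#' The energy table has columns \code{state} (\code{Nminus1}, \code{N},
#' \code{Nplus1}) and \code{energy_hartree}; the charges table has columns
#' \code{index}, \code{element}, \code{Z}, \code{q_Nminus1}, \code{q_N},
#' \code{q_Nplus1}. Adjacent charge states must differ by one electron in
#' total population \eqn{\sum_i (Z_i - q_i)}; deviations beyond
#' \code{electronTol} raise a warning reporting the measured deviation
#' (electrostatic-potential-fitted charges need not conserve populations
#' exactly).
#'
#' @param energyPath energies TSV, or NULL when only charges are needed.
#' @param chargesPath charges TSV, or NULL for global descriptors only.
#' @param molecule molecule name.
#' @param environment \code{"vacuum"} or \code{"water"}.
#' @param electronTol tolerance on the one-electron population steps.
#' @return a validated [QMStateTable-class].
#' @export
readQMTables <- function(energyPath = NULL, chargesPath = NULL,
                         molecule = "molecule", environment = "vacuum",
                         electronTol = 0.01) {
  energies <- c(Nminus1 = NA_real_, N = NA_real_, Nplus1 = NA_real_)
  if (!is.null(energyPath)) {
    et <- utils::read.delim(energyPath, stringsAsFactors = FALSE)
    miss <- setdiff(.QM_STATES, et$state)
    if (length(miss)) {
      .stopf("energy table %s missing state(s): %s", energyPath,
             paste(miss, collapse = ", "))
    }
    energies[et$state] <- et$energy_hartree
  }
  charges <- NULL
  z <- numeric(0)
  elements <- character(0)
  if (!is.null(chargesPath)) {
    ct <- utils::read.delim(chargesPath, stringsAsFactors = FALSE)
    need <- c("Z", "q_Nminus1", "q_N", "q_Nplus1")
    miss <- setdiff(need, names(ct))
    if (length(miss)) {
      .stopf("charges table %s missing column(s): %s", chargesPath,
             paste(miss, collapse = ", "))
    }
    charges <- cbind(Nminus1 = ct$q_Nminus1, N = ct$q_N, Nplus1 = ct$q_Nplus1)
    z <- ct$Z
    elements <- if (!is.null(ct$element)) ct$element else character(0)
    pops <- colSums(z - charges)
    dev <- max(abs(diff(pops) - 1))
    if (dev > electronTol) {
      .warnf(paste("adjacent charge states should differ by one electron;",
                   "measured deviation %.4g"), dev)
    }
  }
  QMStateTable(molecule, energies = energies, charges = charges,
               atomicNumbers = z, elements = elements,
               environment = environment)
}

#' Write quantum-chemistry state tables (TSV)
#'
#' @param qm a [QMStateTable-class].
#' @param energyPath output energies TSV (skipped when NULL).
#' @param chargesPath output charges TSV (skipped when NULL).
#' @return invisibly, NULL.
#' @export
writeQMTables <- function(qm, energyPath = NULL, chargesPath = NULL) {
  if (!is.null(energyPath)) {
    utils::write.table(
      data.frame(state = names(qm@energies), energy_hartree = qm@energies),
      energyPath, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(chargesPath) && nrow(qm@charges)) {
    el <- if (length(qm@elements)) qm@elements else
      rep(NA_character_, nrow(qm@charges))
    utils::write.table(
      data.frame(index = seq_len(nrow(qm@charges)) - 1L, element = el,
                 Z = qm@atomicNumbers,
                 q_Nminus1 = qm@charges[, "Nminus1"],
                 q_N = qm@charges[, "N"],
                 q_Nplus1 = qm@charges[, "Nplus1"]),
      chargesPath, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(NULL)
}
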