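# Classical interaction energies: CHARMM-style Lennard-Jones and Coulomb
# pair sums with switching, adsorbed/solution-resolved drug-lipid and
# drug-water decompositions, per-functional-group contributions, and
# supermolecular complex extraction.

.resolveGroup <- function(traj, group) {
  if (is.character(group) && length(group) == 1) {
    rows <- selectAtoms(traj, label = group)
    if (!length(rows)) rows <- selectAtoms(traj, kind = group)
    if (!length(rows)) .stopf("group '%s' matches no atoms", group)
    rows
  } else {
    as.integer(group)
  }
}

#' Pairwise interaction energy between two atom groups
#'
#' Sums over minimum-image pairs (a in A, b in B) within the cutoff:
#' \deqn{E_{vdw} = \sum \epsilon_{ab} [(r_{min,ab}/r)^{12} -
#'   2 (r_{min,ab}/r)^6] \, sw(r)}
#' \deqn{E_{elec} = \sum 332.0636 \, q_a q_b / r \, sw(r)}
#' with CHARMM combining rules (\eqn{\epsilon_{ab} =
#' \sqrt{\epsilon_a \epsilon_b}}, \eqn{r_{min,ab} = r_{min/2,a} +
#' r_{min/2,b}}) and the CHARMM switching polynomial sw(r), identically 1
#' below \code{switchStart} and 0 above \code{cutoff}. Electrostatics is
#' a cutoff approximation (no Ewald summation); see the package vignette.
#'
#' @param traj a [Trajectory-class].
#' @param frame frame number.
#' @param groupA,groupB disjoint atom selections: 1-based row positions,
#'   or a single label / molecule kind.
#' @param cutoff pair cutoff, A (default 12).
#' @param switchStart switching onset, A (default 10).
#' @return named numeric: \code{elec}, \code{vdw} (kcal/mol).
#' @export
pairEnergy <- function(traj, frame = 1L, groupA, groupB, cutoff = 12,
                       switchStart = 10) {
  a <- atomTable(traj)
  gA <- .resolveGroup(traj, groupA)
  gB <- .resolveGroup(traj, groupB)
  if (length(intersect(gA, gB))) .stopf("groups A and B must be disjoint")
  co <- traj@coords[, , frame, drop = TRUE]
  box <- traj@box[frame, ]
  dx <- minImage(outer(co[gA, 1], co[gB, 1], "-"), box[1])
  dy <- minImage(outer(co[gA, 2], co[gB, 2], "-"), box[2])
  dz <- minImage(outer(co[gA, 3], co[gB, 3], "-"), box[3])
  r <- sqrt(dx^2 + dy^2 + dz^2)
  if (any(r < 1e-12)) .stopf("zero interatomic distance in pair energy")
  within <- r <= cutoff
  if (!any(within)) return(c(elec = 0, vdw = 0))
  rw <- r[within]
  sw <- .switchFun(rw, switchStart, cutoff)
  qq <- outer(a$charge[gA], a$charge[gB])[within]
  epsab <- sqrt(outer(a$epsilon[gA], a$epsilon[gB]))[within]
  rmin <- outer(a$rmin_half[gA], a$rmin_half[gB], "+")[within]
  sr6 <- (rmin / rw)^6
  c(elec = sum(.COULOMB_K * qq / rw * sw),
    vdw = sum(epsab * (sr6^2 - 2 * sr6) * sw))
}

#' Select analysis frames
#'
#' Default protocol: the final sixth of the trajectory, thinned evenly to
#' at most \code{nMax} frames (the convention of extracting 100 frames
#' from the final 20 ns of a 120 ns run).
#'
#' @param traj a [Trajectory-class].
#' @param fraction trailing fraction to use (default 1/6).
#' @param nMax maximum frames after thinning (default 100).
#' @return integer frame numbers.
#' @export
selectAnalysisFrames <- function(traj, fraction = 1 / 6, nMax = 100) {
  nf <- nFrames(traj)
  idx <- seq.int(max(1L, nf - ceiling(fraction * nf) + 1L), nf)
  .thinIndices(idx, nMax)
}

#' Drug-lipid and drug-water energy decomposition by location class
#'
#' Over the selected frames, each drug molecule is classified per frame
#' as adsorbed or in solution (centre-of-mass distance from the bilayer
#' midplane against \code{zThreshold}), then its electrostatic and van
#' der Waals interaction energies with the lipid and water groups are
#' computed and averaged within each class (per molecule-frame
#' observation).
#'
#' @param traj a [Trajectory-class].
#' @param drugMolecules molecule ids (default: all drug molecules).
#' @param frames analysis frames (default [selectAnalysisFrames()]).
#' @param zThreshold adsorption cutoff, A (default [defaultZThreshold()]).
#' @param cutoff,switchStart energy cutoff scheme, A.
#' @return list: \code{byClass} (data.frame \code{location_class},
#'   \code{target}, \code{elec}, \code{vdw}, \code{n_obs}; kcal/mol per
#'   molecule-frame), \code{byMolecule} (per-molecule means and majority
#'   class).
#' @export
decomposeDrugLipid <- function(traj, drugMolecules = NULL, frames = NULL,
                               zThreshold = NULL, cutoff = 12,
                               switchStart = 10) {
  if (is.null(drugMolecules)) drugMolecules <- moleculeIds(traj, "drug")
  if (is.null(frames)) frames <- selectAnalysisFrames(traj)
  if (!length(frames)) .stopf("no frames selected")
  if (is.null(zThreshold)) zThreshold <- defaultZThreshold(traj)
  a <- atomTable(traj)
  lipRows <- selectAtoms(traj, kind = "lipid")
  watRows <- selectAtoms(traj, kind = "water")
  p <- selectAtoms(traj, label = "P")
  mono <- membraneGeometry(traj) == "monolayer_pair"

  obs <- list()
  for (f in frames) {
    z <- traj@coords[, 3, f]
    refZ <- if (mono) mean(abs(z[p])) else mean(z[p])
    for (mid in drugMolecules) {
      rows <- which(a$molecule_id == mid)
      m <- a$mass[rows]
      zc <- sum(z[rows] * m) / sum(m)
      dz <- if (mono) abs(abs(zc) - refZ) else
        abs(minImage(zc - refZ, traj@box[f, 3]))
      cls <- if (dz <= zThreshold) "adsorbed" else "solution"
      eL <- pairEnergy(traj, f, rows, lipRows, cutoff, switchStart)
      eW <- if (length(watRows)) {
        pairEnergy(traj, f, rows, watRows, cutoff, switchStart)
      } else c(elec = NA_real_, vdw = NA_real_)
      obs[[length(obs) + 1L]] <- data.frame(
        frame = f, molecule_id = mid, location_class = cls,
        elec_lipid = eL[["elec"]], vdw_lipid = eL[["vdw"]],
        elec_water = eW[["elec"]], vdw_water = eW[["vdw"]])
    }
  }
  obs <- do.call(rbind, obs)

  classAvg <- function(cls, col) {
    v <- obs[obs$location_class == cls, col]
    if (length(v)) mean(v) else NA_real_
  }
  byClass <- do.call(rbind, lapply(c("adsorbed", "solution"), function(cl) {
    data.frame(location_class = cl,
               target = c("lipid", "water"),
               elec = c(classAvg(cl, "elec_lipid"),
                        classAvg(cl, "elec_water")),
               vdw = c(classAvg(cl, "vdw_lipid"),
                       classAvg(cl, "vdw_water")),
               n_obs = sum(obs$location_class == cl))
  }))
  byMolecule <- do.call(rbind, lapply(drugMolecules, function(mid) {
    sub <- obs[obs$molecule_id == mid, , drop = FALSE]
    data.frame(molecule_id = mid,
               location_class = names(which.max(
                 table(sub$location_class))),
               elec_lipid = mean(sub$elec_lipid),
               vdw_lipid = mean(sub$vdw_lipid),
               elec_water = mean(sub$elec_water),
               vdw_water = mean(sub$vdw_water))
  }))
  list(byClass = byClass, byMolecule = byMolecule, observations = obs)
}

#' Functional-group contribution to a drug's interaction energy
#'
#' Restricts the drug side of [pairEnergy()] to the atoms carrying a
#' functional-group label (e.g. ribose oxygens, the 3'-position S or CH2
#' group) and averages over frames and molecules. When the labels
#' partition a molecule, group contributions sum exactly to the
#' whole-molecule energy (pairwise additivity).
#'
#' @param traj a [Trajectory-class].
#' @param groupLabel functional-group label on drug atoms.
#' @param target target selection (default all lipid atoms).
#' @param drugMolecules molecule ids (default all drugs).
#' @param frames analysis frames (default [selectAnalysisFrames()]).
#' @param cutoff,switchStart energy cutoff scheme, A.
#' @return data.frame: \code{group}, \code{elec}, \code{vdw} (kcal/mol,
#'   per molecule-frame), \code{n_obs}.
#' @export
groupContribution <- function(traj, groupLabel, target = "lipid",
                              drugMolecules = NULL, frames = NULL,
                              cutoff = 12, switchStart = 10) {
  if (is.null(drugMolecules)) drugMolecules <- moleculeIds(traj, "drug")
  if (is.null(frames)) frames <- selectAnalysisFrames(traj)
  a <- atomTable(traj)
  lab <- labelMask(traj, groupLabel)
  tRows <- .resolveGroup(traj, target)
  tot <- c(elec = 0, vdw = 0)
  nObs <- 0L
  for (f in frames) {
    for (mid in drugMolecules) {
      rows <- which(a$molecule_id == mid & lab)
      if (!length(rows)) next
      tot <- tot + pairEnergy(traj, f, rows, tRows, cutoff, switchStart)
      nObs <- nObs + 1L
    }
  }
  if (!nObs) .stopf("label '%s' matches no atoms in the drug molecules",
                    groupLabel)
  data.frame(group = groupLabel, elec = tot[["elec"]] / nObs,
             vdw = tot[["vdw"]] / nObs, n_obs = nObs)
}

#' Extract a drug-lipid supermolecular complex
#'
#' Cuts the drug molecule together with every lipid having at least one
#' atom within \code{cutoff} of any drug atom (whole-lipid inclusion),
#' ordered drug first, then lipids by molecule id — the geometry on which
#' supermolecular interaction energies are evaluated externally.
#'
#' @param traj a [Trajectory-class].
#' @param frame frame number.
#' @param drugMolecule drug molecule id.
#' @param cutoff contact cutoff, A (default 3).
#' @return list of class \code{"ExtractedComplex"}: \code{atomRows}
#'   (1-based, drug first), \code{lipidMolecules}, \code{frame},
#'   \code{drugMolecule}.
#' @export
extractComplex <- function(traj, frame = 1L, drugMolecule, cutoff = 3) {
  a <- atomTable(traj)
  drugRows <- which(a$molecule_id == drugMolecule)
  if (!length(drugRows)) .stopf("no molecule with id %s", drugMolecule)
  lipRows <- selectAtoms(traj, kind = "lipid")
  co <- traj@coords[, , frame, drop = TRUE]
  box <- traj@box[frame, ]
  keepMol <- integer(0)
  if (length(lipRows)) {
    dx <- minImage(outer(co[lipRows, 1], co[drugRows, 1], "-"), box[1])
    dy <- minImage(outer(co[lipRows, 2], co[drugRows, 2], "-"), box[2])
    dz <- minImage(outer(co[lipRows, 3], co[drugRows, 3], "-"), box[3])
    r2 <- dx^2 + dy^2 + dz^2
    touch <- apply(r2 <= cutoff^2, 1, any)
    keepMol <- sort(unique(a$molecule_id[lipRows[touch]]))
  }
  atomRows <- c(drugRows,
                which(a$molecule_id %in% keepMol & a$molecule_kind ==
                        "lipid"))
  structure(list(atomRows = atomRows, lipidMolecules = keepMol,
                 frame = frame, drugMolecule = drugMolecule),
            class = "ExtractedComplex")
}

#' Write an extracted complex as a PDB file
#'
#' @param complex an [extractComplex()] result.
#' @param traj the [Trajectory-class] it came from.
#' @param path output PDB path.
#' @return invisibly, the path.
#' @export
writeComplexPDB <- function(complex, traj, path) {
  fr <- getFrame(traj, complex$frame)
  writeStructurePDB(topology(traj), fr, path, subset = complex$atomRows)
}

#' Supermolecular interaction energy
#'
#' \eqn{\Delta E = E_{complex} - E_{drug} - E_{lipids}} from three
#' energies of the same Hamiltonian and units (externally computed QM
#' energies, or this package's classical pair energies as a
#' pairwise-additive stand-in, for which \eqn{\Delta E} equals the direct
#' drug-lipid pair energy identically).
#'
#' @param eComplex,eDrug,eLipids energies in one consistent unit.
#' @return the interaction energy, same unit.
#' @export
supermolecularInteraction <- function(eComplex, eDrug, eLipids) {
  stopifnot(is.numeric(eComplex), is.numeric(eDrug), is.numeric(eLipids))
  eComplex - eDrug - eLipids
}
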