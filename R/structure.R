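# Membrane structural metrics: area per lipid, bilayer / hydrophobic /
# monolayer thickness, and molecular chain order parameters S_mol.

#' Assign lipids to leaflets
#'
#' Leaflet membership is fixed from the first frame: per-lipid mean z
#' values split at the largest gap in their sorted sequence, lipids above
#' the gap forming the upper leaflet. Lipids diffuse laterally only, so
#' no flip-flop is expected and the assignment is not revisited.
#'
#' @param traj a [Trajectory-class].
#' @param minGap smallest z separation (A) accepted between the leaflets'
#'   mean-z clusters; below it the system is treated as single-leaflet.
#' @return named character vector over lipid molecule ids.
#' @export
leafletAssignment <- function(traj, minGap = 5) {
  a <- atomTable(traj)
  co <- traj@coords[, , 1, drop = TRUE]
  lip <- moleculeIds(traj, "lipid")
  if (!length(lip)) .stopf("no lipid molecules in topology")
  z <- vapply(lip, function(m) {
    mean(co[a$molecule_id == m, 3])
  }, numeric(1))
  # leaflets are separated by the largest gap in the sorted mean-z values;
  # a gap below minGap means both leaflets are not present
  zs <- sort(z)
  if (length(zs) < 2) .stopf("need lipids in both leaflets; found 1 lipid")
  gaps <- diff(zs)
  gi <- which.max(gaps)
  if (gaps[gi] < minGap) {
    .stopf(paste("cannot separate two leaflets (largest z gap %.2f A);",
                 "both leaflets must be populated"), gaps[gi])
  }
  cutZ <- (zs[gi] + zs[gi + 1]) / 2
  stats::setNames(ifelse(z >= cutZ, "upper", "lower"), lip)
}

#' Area per lipid
#'
#' Time average of \eqn{L_x L_y / n_{lipids}} for one leaflet.
#'
#' @param traj a [Trajectory-class].
#' @param leaflet \code{"upper"} or \code{"lower"}.
#' @return list with \code{apl} (A^2/lipid) and \code{sd} over frames.
#' @export
areaPerLipid <- function(traj, leaflet = "upper") {
  lc <- traj@topology@leafletCounts
  nLip <- if (length(lc) && leaflet %in% names(lc)) {
    lc[[leaflet]]
  } else {
    sum(leafletAssignment(traj) == leaflet)
  }
  if (!nLip) .stopf("leaflet '%s' contains no lipids", leaflet)
  perFrame <- traj@box[, 1] * traj@box[, 2] / nLip
  list(apl = mean(perFrame), sd = stats::sd(perFrame))
}

.leafletMeanZ <- function(traj, label, leafletOf) {
  a <- atomTable(traj)
  rows <- selectAtoms(traj, label = label)
  if (!length(rows)) .stopf("no atoms labelled '%s'", label)
  side <- leafletOf[as.character(a$molecule_id[rows])]
  if (anyNA(side)) .stopf("atoms labelled '%s' outside lipid molecules",
                          label)
  up <- rows[side == "upper"]
  lo <- rows[side == "lower"]
  if (!length(up) || !length(lo)) {
    .stopf("label '%s' must occur in both leaflets", label)
  }
  list(up = up, lo = lo)
}

.interLeafletDistance <- function(traj, label) {
  leafletOf <- leafletAssignment(traj)
  rows <- .leafletMeanZ(traj, label, leafletOf)
  perFrame <- vapply(seq_len(nFrames(traj)), function(f) {
    z <- traj@coords[, 3, f]
    abs(mean(z[rows$up]) - mean(z[rows$lo]))
  }, numeric(1))
  list(mean = mean(perFrame), sd = stats::sd(perFrame))
}

#' Bilayer thickness
#'
#' Average distance between the mean z of the phosphorus atoms of the two
#' leaflets, frame-averaged.
#'
#' @param traj a [Trajectory-class] with bilayer geometry.
#' @return list with \code{thickness} (A) and \code{sd} over frames.
#' @export
bilayerThickness <- function(traj) {
  d <- .interLeafletDistance(traj, "P")
  list(thickness = d$mean, sd = d$sd)
}

#' Hydrophobic thickness
#'
#' As [bilayerThickness()], using the C2 carbon atoms of opposite
#' leaflets.
#'
#' @param traj a [Trajectory-class].
#' @return list with \code{thickness} (A) and \code{sd} over frames.
#' @export
hydrophobicThickness <- function(traj) {
  d <- .interLeafletDistance(traj, "C2")
  list(thickness = d$mean, sd = d$sd)
}

#' Monolayer thickness
#'
#' For opposed-monolayer systems: distance between the mean z of the
#' P atoms and of the terminal chain carbons within one leaflet,
#' frame-averaged.
#'
#' @param traj a [Trajectory-class] with \code{monolayer_pair} geometry.
#' @param leaflet \code{"upper"} or \code{"lower"}.
#' @return list with \code{thickness} (A) and \code{sd} over frames.
#' @export
monolayerThickness <- function(traj, leaflet = "upper") {
  if (membraneGeometry(traj) != "monolayer_pair") {
    .stopf("monolayerThickness requires monolayer_pair geometry")
  }
  a <- atomTable(traj)
  leafletOf <- leafletAssignment(traj)
  pick <- function(label) {
    rows <- selectAtoms(traj, label = label)
    rows[leafletOf[as.character(a$molecule_id[rows])] == leaflet]
  }
  p <- pick("P")
  term <- pick("terminal_CH3")
  if (!length(p) || !length(term)) {
    .stopf("leaflet '%s' lacks P or terminal_CH3 atoms", leaflet)
  }
  perFrame <- vapply(seq_len(nFrames(traj)), function(f) {
    z <- traj@coords[, 3, f]
    abs(mean(z[p]) - mean(z[term]))
  }, numeric(1))
  list(thickness = mean(perFrame), sd = stats::sd(perFrame))
}

#' Chain order parameters S_mol
#'
#' For carbon n of each chain, \eqn{S_{mol}(n) = \langle (3\cos^2\theta_n
#' - 1)/2 \rangle} over lipids and frames, where \eqn{\theta_n} is the
#' angle between the vector from carbon n-1 to carbon n+1 and the membrane
#' normal (z). The molecular axis is the heavy-atom C(n-1) to C(n+1)
#' vector — the standard choice when no explicit hydrogens exist; because
#' the angle enters squared, leaflets contribute symmetrically without an
#' explicit sign flip. Chain membership comes from the chain label
#' (\code{"sn1"}/\code{"sn2"}); carbon order is atom order within each
#' molecule. Values lie in [-0.5, 1]: 1 for all-trans chains along z,
#' 0 for isotropic orientations.
#'
#' @param traj a [Trajectory-class].
#' @param chain chain label (default \code{"sn1"}).
#' @param frames frame subset (default all).
#' @return data.frame of class \code{"OrderProfile"}: \code{chain},
#'   \code{carbon} (interior carbon index, 2-based), \code{s_mol},
#'   \code{n_obs}.
#' @export
orderParameters <- function(traj, chain = "sn1", frames = NULL) {
  if (is.null(frames)) frames <- seq_len(nFrames(traj))
  a <- atomTable(traj)
  rows <- selectAtoms(traj, label = chain)
  if (!length(rows)) .stopf("no atoms labelled '%s'", chain)
  byMol <- split(rows, a$molecule_id[rows])
  len <- unique(vapply(byMol, length, integer(1)))
  if (length(len) != 1) .stopf("chains of unequal length for '%s'", chain)
  if (len < 3) .stopf("chain '%s' has fewer than 3 carbons", chain)

  nInt <- len - 2L
  sSum <- numeric(nInt)
  nObs <- 0L
  idx <- do.call(rbind, byMol)    # molecules x carbons (atom rows)
  for (f in frames) {
    co <- traj@coords[, , f, drop = TRUE]
    box <- traj@box[f, ]
    for (k in seq_len(nInt)) {
      v <- co[idx[, k + 2L], , drop = FALSE] - co[idx[, k], , drop = FALSE]
      v <- minImage(v, rep(box, each = nrow(v)))
      cos2 <- v[, 3]^2 / rowSums(v * v)
      sSum[k] <- sSum[k] + sum((3 * cos2 - 1) / 2)
    }
    nObs <- nObs + nrow(idx)
  }
  out <- data.frame(chain = chain, carbon = seq_len(nInt) + 1L,
                    s_mol = sSum / nObs, n_obs = nObs)
  class(out) <- c("OrderProfile", "data.frame")
  out
}

#' Structural summary report
#'
#' Convenience wrapper returning APL per leaflet plus the thickness
#' metrics applicable to the system geometry.
#'
#' @param traj a [Trajectory-class].
#' @return data.frame with columns \code{metric}, \code{value}, \code{sd}.
#' @export
structuralReport <- function(traj) {
  rows <- list()
  for (lf in c("upper", "lower")) {
    ap <- areaPerLipid(traj, lf)
    rows[[length(rows) + 1L]] <-
      data.frame(metric = paste0("apl_", lf), value = ap$apl, sd = ap$sd)
  }
  if (membraneGeometry(traj) == "bilayer") {
    bt <- bilayerThickness(traj)
    ht <- hydrophobicThickness(traj)
    rows[[length(rows) + 1L]] <- data.frame(metric = "bilayer_thickness",
                                            value = bt$thickness,
                                            sd = bt$sd)
    rows[[length(rows) + 1L]] <-
      data.frame(metric = "hydrophobic_thickness", value = ht$thickness,
                 sd = ht$sd)
  } else {
    for (lf in c("upper", "lower")) {
      mt <- monolayerThickness(traj, lf)
      rows[[length(rows) + 1L]] <-
        data.frame(metric = paste0("monolayer_thickness_", lf),
                   value = mt$thickness, sd = mt$sd)
    }
  }
  do.call(rbind, rows)
}
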