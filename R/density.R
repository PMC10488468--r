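# Partial mass-density profiles along the membrane normal (z) and
# detection of adsorption-mode maxima.

.referenceZ <- function(traj, reference, frame) {
  co <- traj@coords[, , frame, drop = TRUE]
  if (reference == "bilayer_midplane") {
    p <- selectAtoms(traj, label = "P")
    if (!length(p)) .stopf("no P-labelled atoms for bilayer_midplane")
    mean(co[p, 3])
  } else {
    w <- selectAtoms(traj, kind = "water")
    if (!length(w)) .stopf("no water atoms for water_slab_center")
    mean(co[w, 3])
  }
}

#' Compute a partial mass-density profile along z
#'
#' Per frame, the atoms of the selected group are shifted so that the
#' chosen reference (bilayer midplane = mean z of the P-labelled atoms;
#' water-slab centre for opposed monolayers) maps to z = 0, wrapped into
#' the centred primary cell, and histogrammed with their masses; frame
#' histograms are averaged. With \code{useCOM = TRUE} the group is binned
#' as per-molecule centres of mass carrying the molecular mass — the
#' convention used for drug molecules.
#'
#' Densities are mass per bin volume in kg/m^3 (1 amu/A^3 =
#' 1660.539 kg/m^3); the same normalization is used for every group, so
#' the integral \eqn{\sum \rho \Delta z \, L_x L_y} returns the group's
#' total mass exactly.
#'
#' @param traj a [Trajectory-class].
#' @param group group label (see [labelMask()]), or a molecule kind when
#'   \code{useCOM = TRUE} (e.g. \code{"drug"}).
#' @param binWidth bin width, A (default 0.5).
#' @param reference \code{"bilayer_midplane"} (default) or
#'   \code{"water_slab_center"}.
#' @param useCOM bin molecular centres of mass instead of atoms.
#' @param frames frame subset (default all).
#' @return data.frame of class \code{"DensityProfile"} with columns
#'   \code{z} (bin centres, A) and \code{rho} (kg/m^3); attributes
#'   \code{group}, \code{binWidth}, \code{nFrames}, \code{boxArea}
#'   (mean Lx*Ly, A^2), \code{groupMass} (amu).
#' @export
computeDensityProfile <- function(traj, group, binWidth = 0.5,
                                  reference = c("bilayer_midplane",
                                                "water_slab_center"),
                                  useCOM = FALSE, frames = NULL) {
  reference <- match.arg(reference)
  if (binWidth <= 0) .stopf("binWidth must be > 0")
  if (is.null(frames)) frames <- seq_len(nFrames(traj))
  a <- atomTable(traj)
  if (useCOM) {
    rows <- selectAtoms(traj, kind = group)
    if (!length(rows)) rows <- selectAtoms(traj, label = group)
  } else {
    rows <- selectAtoms(traj, label = group)
  }
  if (!length(rows)) .stopf("empty group '%s'", group)

  Lz <- max(traj@box[frames, 3])
  # odd bin count with the middle bin centred on the reference (z = 0)
  nh <- ceiling(Lz / (2 * binWidth))
  nBins <- 2L * nh + 1L
  breaks <- ((-nh):(nh + 1L) - 0.5) * binWidth
  centers <- ((-nh):nh) * binWidth

  acc <- numeric(nBins)
  areaSum <- 0
  for (f in frames) {
    refZ <- .referenceZ(traj, reference, f)
    z <- traj@coords[rows, 3, f] - refZ
    m <- a$mass[rows]
    if (useCOM) {
      mid <- a$molecule_id[rows]
      z <- minImage(z, traj@box[f, 3])   # make molecules whole around ref
      zc <- vapply(split(seq_along(z), mid),
                   function(i) sum(z[i] * m[i]) / sum(m[i]), numeric(1))
      m <- vapply(split(m, mid), sum, numeric(1))
      z <- zc
    }
    z <- .wrapCentered(z, nBins * binWidth)
    bin <- pmin(nBins, pmax(1L, floor((z - breaks[1]) / binWidth) + 1L))
    bs <- rowsum(m, bin)
    acc[as.integer(rownames(bs))] <- acc[as.integer(rownames(bs))] + bs[, 1]
    areaSum <- areaSum + prod(traj@box[f, 1:2])
  }
  area <- areaSum / length(frames)
  rho <- (acc / length(frames)) / (binWidth * area) * .AMU_A3_TO_KG_M3
  out <- data.frame(z = centers, rho = rho)
  attr(out, "group") <- group
  attr(out, "binWidth") <- binWidth
  attr(out, "nFrames") <- length(frames)
  attr(out, "boxArea") <- area
  attr(out, "groupMass") <- sum(acc) / length(frames)
  class(out) <- c("DensityProfile", "data.frame")
  out
}

#' Locate density-profile maxima (adsorption modes)
#'
#' Finds local maxima with topographic prominence at least
#' \code{minProminence} times the global maximum, sorted by |z|
#' ascending. When the P-profile peak position is supplied, each mode is
#' classified as \code{"into_headgroups"} (closer to the midplane than the
#' P peak) or \code{"surface"} (at or beyond it).
#'
#' @param profile a \code{"DensityProfile"} from [computeDensityProfile()].
#' @param minProminence prominence threshold as a fraction of max(rho).
#' @param pPeak |z| of the phosphate-density peak, or NULL.
#' @return data.frame with \code{z}, \code{height}, \code{prominence} and
#'   (when \code{pPeak} is given) \code{mode}; zero rows when the profile
#'   has no qualifying maxima.
#' @export
locateModes <- function(profile, minProminence = 0.05, pPeak = NULL) {
  rho <- profile$rho
  z <- profile$z
  n <- length(rho)
  if (!n || max(rho) <= 0) {
    return(data.frame(z = numeric(0), height = numeric(0),
                      prominence = numeric(0)))
  }
  lo <- min(rho)
  isMax <- which(vapply(seq_len(n), function(i) {
    l <- if (i > 1) rho[i - 1] else -Inf
    r <- if (i < n) rho[i + 1] else -Inf
    rho[i] > l && rho[i] >= r && rho[i] > 0 && rho[i] > lo
  }, logical(1)))
  if (!length(isMax)) {
    return(data.frame(z = numeric(0), height = numeric(0),
                      prominence = numeric(0)))
  }
  prom <- vapply(isMax, function(i) {
    h <- rho[i]
    # walk outwards to the nearest higher bin on each side; the saddle is
    # the minimum along the way; prominence = height - highest saddle
    saddle <- function(idx) {
      lo <- h
      for (j in idx) {
        if (rho[j] > h) return(lo)
        lo <- min(lo, rho[j])
      }
      min(lo, 0)  # reaches the profile edge: drop to baseline
    }
    sl <- saddle(rev(seq_len(i - 1)))
    sr <- saddle(seq(i + 1, n)[seq_len(max(0, n - i))])
    h - max(sl, sr)
  }, numeric(1))
  keep <- prom >= minProminence * max(rho)
  out <- data.frame(z = z[isMax][keep], height = rho[isMax][keep],
                    prominence = prom[keep])
  out <- out[order(abs(out$z)), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(pPeak) && nrow(out)) {
    out$mode <- ifelse(abs(out$z) < pPeak, "into_headgroups", "surface")
  }
  out
}
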