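# Mean squared displacement, Einstein-relation diffusion coefficients and
# drug localization (adsorbed vs in solution).

#' Unwrap a molecule's centre-of-mass path
#'
#' Reconstructs the continuous (periodic-image-free) path of a molecule's
#' centre of mass: minimum-image increments between consecutive frames are
#' accumulated per atom and mass-averaged. The first frame is left
#' unchanged. Fails if any per-axis frame-to-frame displacement reaches
#' half the box (the minimum-image increment would be ambiguous).
#'
#' @param traj a [Trajectory-class].
#' @param moleculeId molecule id (as in the topology table).
#' @return matrix \code{n_frames x 3} (A) with attribute \code{times}.
#' @export
unwrapMolecule <- function(traj, moleculeId) {
  a <- atomTable(traj)
  rows <- which(a$molecule_id == moleculeId)
  if (!length(rows)) .stopf("no molecule with id %s", moleculeId)
  nf <- nFrames(traj)
  m <- a$mass[rows]
  co <- traj@coords[rows, , , drop = FALSE]
  # per-atom unwrapped paths
  un <- co
  if (nf > 1) {
    for (f in 2:nf) {
      box <- traj@box[f, ]
      d <- co[, , f] - co[, , f - 1L]
      d <- matrix(d, ncol = 3)
      if (any(abs(d) >= matrix(box / 2, nrow(d), 3, byrow = TRUE))) {
        bad <- abs(minImage(d, rep(box, each = nrow(d))))
        if (any(bad >= box / 2 - 1e-9)) {
          .stopf(paste("frame %d: displacement >= box/2; trajectory",
                       "stride too coarse to unwrap"), f)
        }
      }
      un[, , f] <- un[, , f - 1L] + minImage(d, rep(box, each = nrow(d)))
    }
  }
  com <- t(vapply(seq_len(nf), function(f) {
    colSums(matrix(un[, , f], ncol = 3) * m) / sum(m)
  }, numeric(3)))
  attr(com, "times") <- traj@times
  com
}

#' Mean squared displacement of a path
#'
#' \eqn{MSD(\tau)} for lag times up to \code{maxLag}, averaged over all
#' valid time origins (or using only the first origin). Dimensionality is
#' selected through \code{dims}: \code{1:3} for 3D, \code{1:2} for lateral
#' (xy) MSD.
#'
#' @param path \code{n_frames x 3} unwrapped path (A), uniformly spaced in
#'   time; typically from [unwrapMolecule()].
#' @param times frame times (ns); default taken from the path attribute.
#' @param maxLag largest lag (ns); default half the path span.
#' @param allOrigins average over all time origins (default TRUE).
#' @param dims coordinate columns entering the MSD (default \code{1:3}).
#' @return data.frame with \code{lag} (ns), \code{msd} (A^2),
#'   \code{n_origins}.
#' @export
msdCurve <- function(path, times = attr(path, "times"), maxLag = NULL,
                     allOrigins = TRUE, dims = 1:3) {
  n <- nrow(path)
  if (n < 2) .stopf("path must contain at least 2 frames")
  if (is.null(times)) .stopf("frame times required")
  dt <- diff(times)
  if (max(abs(dt - dt[1])) > 1e-9 * max(dt)) {
    .stopf("msdCurve requires uniformly spaced frames")
  }
  dt <- dt[1]
  span <- times[n] - times[1]
  if (is.null(maxLag)) maxLag <- span / 2
  if (maxLag > span + 1e-12) .stopf("maxLag exceeds trajectory span")
  maxLagF <- max(1L, min(n - 1L, floor(maxLag / dt + 1e-9)))
  p <- path[, dims, drop = FALSE]
  lagF <- seq_len(maxLagF)
  msd <- numeric(maxLagF)
  nOrig <- integer(maxLagF)
  for (L in lagF) {
    if (allOrigins) {
      d <- p[(1L + L):n, , drop = FALSE] - p[seq_len(n - L), , drop = FALSE]
      msd[L] <- mean(rowSums(d * d))
      nOrig[L] <- n - L
    } else {
      d <- p[1L + L, ] - p[1L, ]
      msd[L] <- sum(d * d)
      nOrig[L] <- 1L
    }
  }
  data.frame(lag = lagF * dt, msd = msd, n_origins = nOrig)
}

#' Einstein-relation diffusion coefficient from an MSD curve
#'
#' Least-squares slope m of MSD vs lag over the fit window gives
#' \eqn{D = m / (2d)} with d the dimensionality; the slope (A^2/ns) is
#' converted to cm^2/s (1 A^2/ns = 1e-7 cm^2/s). The default window,
#' 10-50% of the largest lag, avoids both the short-lag ballistic/noise
#' region and the poorly averaged long-lag tail. A negative slope is
#' clipped to D = 0 with a warning.
#'
#' @param msd data.frame from [msdCurve()].
#' @param dimensionality 2 (lateral) or 3.
#' @param window length-2 lag window (ns); default
#'   \code{c(0.1, 0.5) * max(lag)}.
#' @return list: \code{D_cm2_s}, \code{slope_A2_ns}, \code{fit_r2},
#'   \code{window}, \code{dimensionality}.
#' @export
fitDiffusion <- function(msd, dimensionality = 3, window = NULL) {
  if (is.null(window)) window <- c(0.1, 0.5) * max(msd$lag)
  sel <- msd$lag >= window[1] & msd$lag <= window[2]
  if (sum(sel) < 2) .stopf("fit window contains fewer than 2 MSD points")
  fit <- stats::lm(msd ~ lag, data = msd[sel, ])
  slope <- unname(stats::coef(fit)[2])
  ss <- sum((msd$msd[sel] - mean(msd$msd[sel]))^2)
  r2 <- if (ss > 0) 1 - sum(stats::residuals(fit)^2) / ss else 1
  if (slope < 0) {
    .warnf("negative MSD slope (%.3g A^2/ns); clipping D to 0", slope)
    slope <- 0
  }
  list(D_cm2_s = slope / (2 * dimensionality) * .A2NS_TO_CM2S,
       slope_A2_ns = slope, fit_r2 = r2, window = window,
       dimensionality = dimensionality)
}

#' Default adsorption threshold from the phosphate density peak
#'
#' |z| of the highest-prominence P-density mode plus 5 A.
#'
#' @param traj a [Trajectory-class].
#' @return z threshold in A.
#' @export
defaultZThreshold <- function(traj) {
  prof <- computeDensityProfile(traj, "P")
  modes <- locateModes(prof, minProminence = 0.05)
  if (!nrow(modes)) .stopf("no P-density peak found")
  abs(modes$z[which.max(modes$height)]) + 5
}

#' Classify a drug molecule as membrane-adsorbed or in solution
#'
#' A molecule is \code{"adsorbed"} when its centre of mass satisfies
#' \eqn{|z - z_{ref}| \le} \code{zThreshold} in at least
#' \code{minFraction} of the analysed frames; the reference is the
#' bilayer midplane (mean z of P atoms, per frame) or the water-slab
#' centre for opposed monolayers.
#'
#' @param traj a [Trajectory-class].
#' @param moleculeId molecule id.
#' @param zThreshold distance cutoff from the membrane reference (A);
#'   default [defaultZThreshold()]. For monolayer-pair systems the
#'   adsorbed condition is |z| within \code{zThreshold} of the P band
#'   instead (the slab centre is water, not membrane).
#' @param minFraction minimum fraction of frames (default 0.5).
#' @param frames frame subset (default all).
#' @return \code{"adsorbed"} or \code{"solution"}.
#' @export
classifyLocation <- function(traj, moleculeId, zThreshold = NULL,
                             minFraction = 0.5, frames = NULL) {
  if (is.null(zThreshold)) zThreshold <- defaultZThreshold(traj)
  if (zThreshold <= 0) .stopf("zThreshold must be > 0")
  if (is.null(frames)) frames <- seq_len(nFrames(traj))
  a <- atomTable(traj)
  rows <- which(a$molecule_id == moleculeId)
  if (!length(rows)) .stopf("no molecule with id %s", moleculeId)
  m <- a$mass[rows]
  p <- selectAtoms(traj, label = "P")
  mono <- membraneGeometry(traj) == "monolayer_pair"
  inside <- vapply(frames, function(f) {
    z <- traj@coords[, 3, f]
    zc <- sum(z[rows] * m) / sum(m)
    if (mono) {
      pz <- mean(abs(z[p]))
      abs(abs(zc) - pz) <= zThreshold
    } else {
      refZ <- mean(z[p])
      dz <- abs(minImage(zc - refZ, traj@box[f, 3]))
      dz <= zThreshold
    }
  }, logical(1))
  if (mean(inside) >= minFraction) "adsorbed" else "solution"
}

#' Partition diffusion coefficients into slow and fast sets
#'
#' Splits at the two-range boundary near 2e-6 cm^2/s separating
#' membrane-penetrating (slow) from in-solution (fast) drug molecules;
#' ties (D equal to the threshold) go to the fast set.
#'
#' @param D named numeric vector of diffusion coefficients, cm^2/s.
#' @param threshold boundary (default \code{2e-6} cm^2/s).
#' @return list with \code{slow} and \code{fast} (names of \code{D},
#'   or indices when unnamed).
#' @export
partitionByD <- function(D, threshold = 2e-6) {
  ids <- if (is.null(names(D))) as.character(seq_along(D)) else names(D)
  list(slow = ids[D < threshold], fast = ids[D >= threshold])
}

#' Per-molecule diffusion coefficients for drug molecules
#'
#' Unwraps each drug molecule, restricts to the analysis segment (by
#' default the second half of the trajectory), computes the all-origin
#' MSD and fits the Einstein relation. Drug molecules exchange between
#' water and membrane, so the default MSD is 3D; pass \code{dims = 1:2}
#' for lateral-only estimates.
#'
#' @param traj a [Trajectory-class].
#' @param moleculeIds molecule ids (default: all drug molecules).
#' @param dims coordinates entering the MSD (default \code{1:3}).
#' @param segmentStart fraction of the trajectory discarded from the
#'   front (default 0.5).
#' @param maxLag,window passed to [msdCurve()] / [fitDiffusion()].
#' @return data.frame: \code{molecule_id}, \code{D_cm2_s}, \code{fit_r2}.
#' @export
diffusionCoefficients <- function(traj, moleculeIds = NULL, dims = 1:3,
                                  segmentStart = 0.5, maxLag = NULL,
                                  window = NULL) {
  if (is.null(moleculeIds)) {
    moleculeIds <- moleculeIds(traj, "drug")
  }
  nf <- nFrames(traj)
  f0 <- max(1L, floor(segmentStart * nf) + 1L)
  res <- lapply(moleculeIds, function(mid) {
    com <- unwrapMolecule(traj, mid)
    seg <- com[f0:nf, , drop = FALSE]
    attr(seg, "times") <- traj@times[f0:nf]
    fit <- fitDiffusion(msdCurve(seg, maxLag = maxLag, dims = dims),
                        dimensionality = length(dims), window = window)
    data.frame(molecule_id = mid, D_cm2_s = fit$D_cm2_s,
               fit_r2 = fit$fit_r2)
  })
  do.call(rbind, res)
}
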