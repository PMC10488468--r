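# Physical constants and small geometry helpers shared across modules.

# 1 amu / A^3 expressed in kg / m^3
.AMU_A3_TO_KG_M3 <- 1660.53906660

# 1 A^2 / ns expressed in cm^2 / s (applied exactly once, in fitDiffusion)
.A2NS_TO_CM2S <- 1e-7

# Coulomb constant, kcal * A / (mol * e^2), CHARMM convention
.COULOMB_K <- 332.0636

#' Minimum-image convention displacement
#'
#' Maps displacements into the primary periodic image, component-wise.
#'
#' @param d numeric vector/matrix of displacements in Angstrom.
#' @param L box length(s) in Angstrom; recycled against `d`.
#' @return displacement(s) folded into \code{[-L/2, L/2)}.
#' @keywords internal
minImage <- function(d, L) {
  d - L * round(d / L)
}

# wrap coordinates into the centred primary cell [-L/2, L/2)
.wrapCentered <- function(x, L) {
  x - L * floor(x / L + 0.5)
}

# reflect a coordinate into [lo, hi] (specular walls)
.reflect <- function(x, lo, hi) {
  w <- hi - lo
  stopifnot(w > 0)
  y <- (x - lo) %% (2 * w)
  y <- ifelse(y > w, 2 * w - y, y)
  lo + y
}

# r^2 and angle helpers ------------------------------------------------------

# angle in degrees between vectors u and v (rows of matrices or single vectors)
.vecAngleDeg <- function(u, v) {
  if (is.null(dim(u))) u <- matrix(u, nrow = 1)
  if (is.null(dim(v))) v <- matrix(v, nrow = 1)
  dot <- rowSums(u * v)
  nu <- sqrt(rowSums(u * u))
  nv <- sqrt(rowSums(v * v))
  cosang <- pmin(1, pmax(-1, dot / (nu * nv)))
  acos(cosang) * 180 / pi
}

# CHARMM switching polynomial on [switchStart, cutoff]; 1 below, 0 above.
.switchFun <- function(r, switchStart, cutoff) {
  stopifnot(cutoff > switchStart)
  ron2 <- switchStart^2
  roff2 <- cutoff^2
  sw <- rep(1, length(r))
  mid <- r > switchStart & r <= cutoff
  rr <- r[mid]^2
  sw[mid] <- (roff2 - rr)^2 * (roff2 + 2 * rr - 3 * ron2) / (roff2 - ron2)^3
  sw[r > cutoff] <- 0
  sw
}

# column-wise cumulative sums that stay a matrix for a single row
.cumsumCols <- function(m) {
  out <- apply(m, 2, cumsum)
  if (is.null(dim(out))) out <- matrix(out, nrow = 1)
  out
}

# evenly thin an index vector to at most n entries, keeping the last
.thinIndices <- function(idx, n) {
  if (length(idx) <= n) return(idx)
  sel <- unique(round(seq(1, length(idx), length.out = n)))
  idx[sel]
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
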