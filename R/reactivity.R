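# Conceptual-DFT reactivity descriptors from finite differences of
# fixed-geometry state energies and fitted atomic charges.

#' Ionization potential and electron affinity
#'
#' Finite differences of the three-state energies at fixed geometry:
#' \eqn{I = E(N-1) - E(N)}, \eqn{A = E(N) - E(N+1)}.
#'
#' @param qm a [QMStateTable-class] with all three energies.
#' @return named numeric: \code{I}, \code{A} (hartree).
#' @export
ionizationAndAffinity <- function(qm) {
  e <- qm@energies
  if (anyNA(e)) {
    .stopf("missing state energy: %s",
           paste(names(e)[is.na(e)], collapse = ", "))
  }
  c(I = unname(e["Nminus1"] - e["N"]), A = unname(e["N"] - e["Nplus1"]))
}

#' Chemical potential
#'
#' Finite-difference (parabolic) first derivative of energy with respect
#' to electron number: \eqn{\mu = -(I + A)/2}.
#'
#' @param I ionization potential (hartree).
#' @param A electron affinity (hartree).
#' @return mu in hartree.
#' @export
chemicalPotential <- function(I, A) {
  -(I + A) / 2
}

#' Chemical hardness
#'
#' Finite-difference second derivative: \eqn{\eta = I - A}. A negative
#' hardness (A > I) is unphysical input and is flagged with a warning.
#'
#' @inheritParams chemicalPotential
#' @return eta in hartree.
#' @export
hardness <- function(I, A) {
  eta <- I - A
  if (any(eta < 0)) .warnf("negative hardness (I < A): unphysical input")
  eta
}

#' Condensed Fukui indices from atomic charges
#'
#' Converts per-state charges to electron populations via
#' \eqn{N_i = Z_i - q_i} and takes finite differences:
#' \deqn{f^n_i = N_i(N+1) - N_i(N), \quad f^e_i = N_i(N) - N_i(N-1),
#'   \quad f^r_i = (f^n_i + f^e_i)/2.}
#' When the input charge sets change the total electron count by exactly
#' one between adjacent states, the index sums are normalized to unity:
#' \eqn{\sum_i f^n_i = \sum_i f^e_i = 1}. Sums deviating from 1 by more
#' than \code{sumTol} trigger a warning (electrostatic-fitting charge
#' schemes need not conserve populations exactly); no renormalization is
#' applied. Negative indices are legitimate: those atoms respond
#' opposite to the molecule as a whole.
#'
#' @param qm a [QMStateTable-class] with all three charge sets.
#' @param sumTol tolerance on the unit sums (default 1e-3).
#' @return data.frame of class \code{"FukuiIndices"}: \code{index}
#'   (0-based atom index), \code{element}, \code{f_n}, \code{f_e},
#'   \code{f_r}; attribute \code{sums} (named numeric with \code{f_n},
#'   \code{f_e}, \code{f_r} totals).
#' @export
fukuiIndices <- function(qm, sumTol = 1e-3) {
  ch <- qm@charges
  if (!nrow(ch)) .stopf("QMStateTable has no charge sets")
  z <- qm@atomicNumbers
  pops <- z - ch                      # populations per state, column-wise
  fn <- pops[, "Nplus1"] - pops[, "N"]
  fe <- pops[, "N"] - pops[, "Nminus1"]
  fr <- (fn + fe) / 2
  sums <- c(f_n = sum(fn), f_e = sum(fe), f_r = sum(fr))
  dev <- max(abs(sums[c("f_n", "f_e")] - 1))
  if (dev > sumTol) {
    .warnf("Fukui index sums deviate from unity by %.4g", dev)
  }
  el <- if (length(qm@elements)) qm@elements else
    rep(NA_character_, nrow(ch))
  out <- data.frame(index = seq_len(nrow(ch)) - 1L, element = el,
                    f_n = unname(fn), f_e = unname(fe), f_r = unname(fr))
  attr(out, "sums") <- sums
  class(out) <- c("FukuiIndices", "data.frame")
  out
}

#' Full reactivity descriptor set for one molecule/environment
#'
#' @param qm a [QMStateTable-class].
#' @return list of class \code{"ReactivityResult"}: \code{molecule},
#'   \code{environment}, \code{I}, \code{A}, \code{mu}, \code{eta}
#'   (hartree), \code{fukui} (when charges are present), \code{sums}.
#' @export
reactivityDescriptors <- function(qm) {
  ia <- ionizationAndAffinity(qm)
  fk <- if (nrow(qm@charges)) fukuiIndices(qm) else NULL
  structure(list(molecule = qm@molecule, environment = qm@environment,
                 I = ia[["I"]], A = ia[["A"]],
                 mu = chemicalPotential(ia[["I"]], ia[["A"]]),
                 eta = hardness(ia[["I"]], ia[["A"]]),
                 fukui = fk,
                 sums = if (!is.null(fk)) attr(fk, "sums") else NULL),
            class = "ReactivityResult")
}

#' Label atoms as soft or hard from radical Fukui indices
#'
#' Atoms with \eqn{f^r \ge} \code{threshold} times the maximum
#' \eqn{f^r} are labelled soft (locally polarizable, charge-transfer
#' active); the rest hard. Deterministic; the threshold is a display
#' convention, not a physical constant.
#'
#' @param fukui a \code{"FukuiIndices"} data.frame ([fukuiIndices()]).
#' @param threshold fraction of max f_r (default 0.5).
#' @return character vector (\code{"soft"}/\code{"hard"}) per atom.
#' @export
classifySoftHard <- function(fukui, threshold = 0.5) {
  fr <- fukui$f_r
  ifelse(fr >= threshold * max(fr), "soft", "hard")
}

#' Compare reactivity descriptors between environments
#'
#' Percentage changes of mu and eta from one environment (typically
#' vacuum) to another (typically aqueous continuum).
#'
#' @param ref,other [QMStateTable-class] objects for the two environments.
#' @return data.frame: \code{quantity}, \code{ref}, \code{other},
#'   \code{pct_change}.
#' @export
compareEnvironments <- function(ref, other) {
  a <- reactivityDescriptors(ref)
  b <- reactivityDescriptors(other)
  data.frame(
    quantity = c("mu", "eta"),
    ref = c(a$mu, a$eta),
    other = c(b$mu, b$eta),
    pct_change = c((b$mu - a$mu) / abs(a$mu) * 100,
                   (b$eta - a$eta) / abs(a$eta) * 100))
}
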