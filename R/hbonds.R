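# Geometric hydrogen-bond detection (donor-acceptor distance + angle
# criterion), role/partner-resolved statistics, and bond lifetimes.

.PARTNER_LABELS <- c(PO4_O = "lipid_PO4", ester_O = "lipid_ester",
                     glycerol_OH = "lipid_glycerol_OH",
                     hydroxyl = "lipid_glycerol_OH",
                     choline_N = "lipid_choline_N")

.partnerClass <- function(labels, kind) {
  for (l in strsplit(labels, ";", fixed = TRUE)[[1]]) {
    if (l %in% names(.PARTNER_LABELS)) return(unname(.PARTNER_LABELS[l]))
  }
  if (kind == "water") "water" else "other"
}

# donor hydrogens and their heavy donor atoms: each atom labelled donor_H
# is paired with the nearest N/O atom of the same molecule (frame 1)
.donorPairs <- function(traj) {
  a <- atomTable(traj)
  hRows <- selectAtoms(traj, label = "donor_H")
  if (!length(hRows)) {
    .stopf("topology has no donor_H labels; cannot detect hydrogen bonds")
  }
  co <- traj@coords[, , 1, drop = TRUE]
  box <- traj@box[1, ]
  heavy <- vapply(hRows, function(h) {
    cand <- which(a$molecule_id == a$molecule_id[h] &
                    a$element %in% c("N", "O"))
    if (!length(cand)) return(NA_integer_)
    d <- sweep(co[cand, , drop = FALSE], 2, co[h, ])
    d <- minImage(d, rep(box, each = length(cand)))
    cand[which.min(rowSums(d * d))]
  }, integer(1))
  if (anyNA(heavy)) {
    .stopf("donor_H atom without an N/O heavy atom in its molecule")
  }
  data.frame(hydrogen = hRows, donor = heavy)
}

.acceptorRows <- function(traj, extendedAcceptors) {
  acc <- selectAtoms(traj, label = "acceptor")
  if (extendedAcceptors) {
    acc <- sort(union(acc, selectAtoms(traj, label = "choline_N")))
  }
  acc
}

#' Detect hydrogen bonds in one frame
#'
#' Emits an event for every donor/hydrogen/acceptor triple whose
#' donor-acceptor (heavy-atom) minimum-image distance is below
#' \code{dCut} and whose angle between the donor-to-hydrogen and
#' donor-to-acceptor vectors (deviation from linearity) is at most
#' \code{aCut}. Donors and acceptors in the same molecule are skipped.
#' The choline N(CH3)3 nitrogen — not a standard hydrogen-bond acceptor —
#' participates only when \code{extendedAcceptors = TRUE} and is reported
#' under its own partner class.
#'
#' @param traj a [Trajectory-class] whose topology labels donor hydrogens
#'   (\code{"donor_H"}) and acceptors (\code{"acceptor"}; optionally
#'   \code{"choline_N"}).
#' @param frame frame number (default 1).
#' @param dCut donor-acceptor distance cutoff, A (default 3.0).
#' @param aCut angle cutoff, degrees (default 20).
#' @param extendedAcceptors include choline nitrogens as acceptors.
#' @return data.frame: \code{frame}, \code{donor}, \code{hydrogen},
#'   \code{acceptor} (1-based atom rows), \code{distance} (A),
#'   \code{angle} (degrees), \code{drug_role}
#'   (\code{donor}/\code{acceptor}/\code{none}), \code{partner_class}.
#' @export
detectHBonds <- function(traj, frame = 1L, dCut = 3.0, aCut = 20,
                         extendedAcceptors = FALSE) {
  a <- atomTable(traj)
  dp <- .donorPairs(traj)
  acc <- .acceptorRows(traj, extendedAcceptors)
  co <- traj@coords[, , frame, drop = TRUE]
  box <- traj@box[frame, ]
  empty <- data.frame(frame = integer(0), donor = integer(0),
                      hydrogen = integer(0), acceptor = integer(0),
                      distance = numeric(0), angle = numeric(0),
                      drug_role = character(0),
                      partner_class = character(0))
  if (!length(acc)) return(empty)

  events <- list()
  dxa <- outer(co[dp$donor, 1], co[acc, 1], "-")
  dya <- outer(co[dp$donor, 2], co[acc, 2], "-")
  dza <- outer(co[dp$donor, 3], co[acc, 3], "-")
  dxa <- minImage(dxa, box[1]); dya <- minImage(dya, box[2])
  dza <- minImage(dza, box[3])
  r <- sqrt(dxa^2 + dya^2 + dza^2)
  sameMol <- outer(a$molecule_id[dp$donor], a$molecule_id[acc], "==")
  hit <- which(r < dCut & !sameMol, arr.ind = TRUE)
  if (!nrow(hit)) return(empty)

  di <- dp$donor[hit[, 1]]
  hi <- dp$hydrogen[hit[, 1]]
  ai <- acc[hit[, 2]]
  vDH <- minImage(co[hi, , drop = FALSE] - co[di, , drop = FALSE],
                  rep(box, each = length(di)))
  vDA <- -cbind(dxa[hit], dya[hit], dza[hit])
  ang <- .vecAngleDeg(vDH, vDA)
  keep <- ang <= aCut
  if (!any(keep)) return(empty)
  di <- di[keep]; hi <- hi[keep]; ai <- ai[keep]
  rr <- r[hit][keep]; ang <- ang[keep]

  donorIsDrug <- a$molecule_kind[di] == "drug"
  accIsDrug <- a$molecule_kind[ai] == "drug"
  role <- ifelse(donorIsDrug, "donor", ifelse(accIsDrug, "acceptor",
                                              "none"))
  partner <- vapply(seq_along(di), function(i) {
    p <- if (donorIsDrug[i]) ai[i] else di[i]
    .partnerClass(a$labels[p], a$molecule_kind[p])
  }, character(1))
  data.frame(frame = frame, donor = di, hydrogen = hi, acceptor = ai,
             distance = rr, angle = ang, drug_role = role,
             partner_class = partner)
}

#' Hydrogen-bond statistics over a trajectory
#'
#' Per-frame detection cross-tabulated by drug role and partner class;
#' counts are means per frame for the whole system (all drug molecules
#' together, as conventionally tabulated) and per drug molecule.
#'
#' @param traj a [Trajectory-class].
#' @param frames frame subset (default all).
#' @inheritParams detectHBonds
#' @return list: \code{byClass} (data.frame \code{drug_role},
#'   \code{partner_class}, \code{mean_count_per_frame},
#'   \code{per_molecule}), \code{totalPerFrame}, \code{nFrames},
#'   \code{nDrugs}.
#' @export
hbondStatistics <- function(traj, frames = NULL, dCut = 3.0, aCut = 20,
                            extendedAcceptors = FALSE) {
  if (is.null(frames)) frames <- seq_len(nFrames(traj))
  nDrugs <- length(moleculeIds(traj, "drug"))
  ev <- lapply(frames, detectHBonds, traj = traj, dCut = dCut,
               aCut = aCut, extendedAcceptors = extendedAcceptors)
  ev <- do.call(rbind, ev)
  nf <- length(frames)
  if (!nrow(ev)) {
    byClass <- data.frame(drug_role = character(0),
                          partner_class = character(0),
                          mean_count_per_frame = numeric(0),
                          per_molecule = numeric(0))
  } else {
    tab <- as.data.frame(table(drug_role = ev$drug_role,
                               partner_class = ev$partner_class),
                         stringsAsFactors = FALSE)
    tab <- tab[tab$Freq > 0, , drop = FALSE]
    byClass <- data.frame(drug_role = tab$drug_role,
                          partner_class = tab$partner_class,
                          mean_count_per_frame = tab$Freq / nf,
                          per_molecule = if (nDrugs) {
                            tab$Freq / nf / nDrugs
                          } else NA_real_)
  }
  list(byClass = byClass, totalPerFrame = nrow(ev) / nf,
       nFrames = nf, nDrugs = nDrugs, events = ev)
}

#' Hydrogen-bond lifetimes
#'
#' A bond instance is a maximal run of frames in which the same
#' (donor, hydrogen, acceptor) triple is detected, allowing interruptions
#' of at most \code{gapTolerance} frames (bridged gaps count towards the
#' lifetime); lifetime = frames in the run times the frame stride.
#'
#' @param traj a [Trajectory-class] with at least 2 frames.
#' @param gapTolerance frames an instance may be interrupted (default 0).
#' @param frames frame subset (default all; must be consecutive).
#' @inheritParams detectHBonds
#' @return list: \code{byClass} (data.frame \code{partner_class},
#'   \code{drug_role}, \code{mean_lifetime_ps}, \code{n_instances}),
#'   \code{meanLifetime_ps}, \code{instances} (per-instance data.frame).
#' @export
hbondLifetimes <- function(traj, gapTolerance = 0L, frames = NULL,
                           dCut = 3.0, aCut = 20,
                           extendedAcceptors = FALSE) {
  if (nFrames(traj) < 2) .stopf("lifetimes require at least 2 frames")
  if (is.null(frames)) frames <- seq_len(nFrames(traj))
  stridePs <- mean(diff(frameTimes(traj)[frames])) * 1000
  ev <- do.call(rbind, lapply(frames, detectHBonds, traj = traj,
                              dCut = dCut, aCut = aCut,
                              extendedAcceptors = extendedAcceptors))
  if (is.null(ev) || !nrow(ev)) {
    return(list(byClass = data.frame(partner_class = character(0),
                                     drug_role = character(0),
                                     mean_lifetime_ps = numeric(0),
                                     n_instances = integer(0)),
                meanLifetime_ps = NA_real_,
                instances = data.frame()))
  }
  key <- paste(ev$donor, ev$hydrogen, ev$acceptor, sep = "_")
  inst <- list()
  for (k in unique(key)) {
    sub <- ev[key == k, , drop = FALSE]
    fs <- sort(match(sub$frame, frames))
    brk <- c(0L, which(diff(fs) > gapTolerance + 1L), length(fs))
    for (j in seq_len(length(brk) - 1L)) {
      run <- fs[(brk[j] + 1L):brk[j + 1L]]
      inst[[length(inst) + 1L]] <- data.frame(
        key = k, drug_role = sub$drug_role[1],
        partner_class = sub$partner_class[1],
        start_frame = frames[run[1]],
        n_frames = run[length(run)] - run[1] + 1L,
        lifetime_ps = (run[length(run)] - run[1] + 1L) * stridePs)
    }
  }
  inst <- do.call(rbind, inst)
  agg <- stats::aggregate(lifetime_ps ~ partner_class + drug_role, inst,
                          mean)
  cnt <- stats::aggregate(lifetime_ps ~ partner_class + drug_role, inst,
                          length)
  byClass <- data.frame(partner_class = agg$partner_class,
                        drug_role = agg$drug_role,
                        mean_lifetime_ps = agg$lifetime_ps,
                        n_instances = cnt$lifetime_ps)
  list(byClass = byClass, meanLifetime_ps = mean(inst$lifetime_ps),
       instances = inst)
}
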