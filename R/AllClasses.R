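#' @import methods
#' @importFrom S4Vectors metadata metadata<-
NULL

.MOLECULE_KINDS <- c("lipid", "drug", "water", "ion")

#' Topology: static per-atom metadata for a membrane system
#'
#' Holds the atom table shared by every analysis: element, mass, partial
#' charge, Lennard-Jones parameters, molecule membership and named
#' functional-group labels (e.g. \code{"P"}, \code{"choline"}, \code{"C2"},
#' \code{"terminal_CH3"}, \code{"donor_H"}, \code{"acceptor"}). Atom indices
#' in the \code{index} column are 0-based, matching the on-disk table
#' format; all R-level subscripts into the table are the usual 1-based row
#' positions.
#'
#' @slot atoms data.frame with columns \code{index}, \code{element},
#'   \code{mass} (amu), \code{charge} (e), \code{epsilon} (kcal/mol),
#'   \code{rmin_half} (Angstrom), \code{molecule_id}, \code{molecule_kind},
#'   \code{labels} (semicolon-separated group labels).
#' @slot geometry \code{"bilayer"} or \code{"monolayer_pair"}.
#' @slot leafletCounts named integer vector, lipids per leaflet
#'   (names \code{"upper"}, \code{"lower"}); may be empty, in which case
#'   leaflets are assigned geometrically from the first frame.
#'
#' @seealso [Trajectory-class], [readTopologyTable()]
#' @export
setClass("Topology",
  representation(
    atoms = "data.frame",
    geometry = "character",
    leafletCounts = "integer"
  ),
  prototype(
    geometry = "bilayer",
    leafletCounts = integer(0)
  )
)

setValidity("Topology", function(object) {
  a <- object@atoms
  need <- c("index", "element", "mass", "charge", "epsilon", "rmin_half",
            "molecule_id", "molecule_kind", "labels")
  miss <- setdiff(need, names(a))
  if (length(miss)) {
    return(paste("atoms table missing columns:", paste(miss, collapse = ", ")))
  }
  if (nrow(a)) {
    if (!identical(as.integer(a$index), seq_len(nrow(a)) - 1L)) {
      return("atom indices must be contiguous 0-based integers in row order")
    }
    if (any(a$mass <= 0)) return("all atom masses must be > 0")
    if (any(a$epsilon < 0)) return("lj epsilon must be >= 0")
    if (any(a$rmin_half < 0)) return("lj rmin_half must be >= 0")
    if (!all(a$molecule_kind %in% .MOLECULE_KINDS)) {
      bad <- setdiff(unique(a$molecule_kind), .MOLECULE_KINDS)
      return(paste("unknown molecule_kind:", paste(bad, collapse = ", ")))
    }
  }
  if (length(object@geometry) != 1 ||
      !object@geometry %in% c("bilayer", "monolayer_pair")) {
    return("geometry must be 'bilayer' or 'monolayer_pair'")
  }
  if (length(object@leafletCounts) &&
      object@geometry == "bilayer" && length(object@leafletCounts) != 2) {
    return("bilayer geometry requires exactly two leaflet ids")
  }
  TRUE
})

#' Construct a Topology
#'
#' @param atoms atom data.frame (see [Topology-class]).
#' @param geometry \code{"bilayer"} or \code{"monolayer_pair"}.
#' @param leafletCounts optional named integer vector of lipids per leaflet.
#' @return a validated [Topology-class] object.
#' @export
Topology <- function(atoms, geometry = "bilayer", leafletCounts = integer(0)) {
  atoms$index <- as.integer(atoms$index)
  atoms$molecule_id <- as.integer(atoms$molecule_id)
  atoms$labels <- as.character(atoms$labels)
  rownames(atoms) <- NULL
  new("Topology", atoms = atoms, geometry = geometry,
      leafletCounts = leafletCounts)
}

#' Trajectory: time-ordered coordinate frames over a Topology
#'
#' Coordinates are stored as an \code{n_atoms x 3 x n_frames} array in
#' Angstrom; boxes are orthorhombic, one \code{(Lx, Ly, Lz)} row per frame;
#' times are in ns and strictly increasing. Arbitrary provenance (for
#' synthetic data: the generating spec and ground-truth tables) lives in
#' \code{metadata()}.
#'
#' @slot topology a [Topology-class].
#' @slot coords numeric array, \code{n_atoms x 3 x n_frames}.
#' @slot box numeric matrix, \code{n_frames x 3}, Angstrom.
#' @slot times numeric vector, ns.
#' @slot metadata list.
#' @export
setClass("Trajectory",
  representation(
    topology = "Topology",
    coords = "array",
    box = "matrix",
    times = "numeric",
    metadata = "list"
  )
)

setValidity("Trajectory", function(object) {
  d <- dim(object@coords)
  if (length(d) != 3 || d[2] != 3) {
    return("coords must be an n_atoms x 3 x n_frames array")
  }
  if (d[1] != nrow(object@topology@atoms)) {
    return("coordinate count does not match topology atom count")
  }
  nf <- d[3]
  if (nf < 1) return("trajectory must contain at least one frame")
  if (nrow(object@box) != nf || ncol(object@box) != 3) {
    return("box must be an n_frames x 3 matrix")
  }
  if (any(object@box <= 0)) return("box lengths must be > 0")
  if (length(object@times) != nf) return("one time per frame required")
  if (nf > 1 && any(diff(object@times) <= 0)) {
    return("frame times must be strictly increasing")
  }
  TRUE
})

#' Construct a Trajectory
#'
#' @param topology a [Topology-class].
#' @param coords \code{n_atoms x 3 x n_frames} array (Angstrom).
#' @param box \code{n_frames x 3} matrix or length-3 vector (recycled).
#' @param times frame times in ns.
#' @param metadata optional provenance list.
#' @return a validated [Trajectory-class] object.
#' @export
Trajectory <- function(topology, coords, box, times, metadata = list()) {
  if (length(dim(coords)) == 2) {
    coords <- array(coords, dim = c(dim(coords), 1L))
  }
  nf <- dim(coords)[3]
  if (is.null(dim(box))) {
    box <- matrix(rep(as.numeric(box), each = nf), nrow = nf)
  }
  new("Trajectory", topology = topology, coords = coords, box = box,
      times = as.numeric(times), metadata = metadata)
}

#' QMStateTable: fixed-geometry energies and charges for three charge states
#'
#' Container for the quantum-chemistry numbers entering the conceptual-DFT
#' descriptors: total energies of the (N-1)-, N- and (N+1)-electron states
#' at the neutral geometry (hartree), and per-atom charges (e) fitted for
#' each state, together with atomic numbers so that charges convert to
#' electron populations via \eqn{N_i = Z_i - q_i}.
#'
#' @slot molecule molecule name.
#' @slot environment \code{"vacuum"} or \code{"water"}.
#' @slot energies named numeric, names \code{Nminus1}, \code{N},
#'   \code{Nplus1}; hartree. May contain NA when only charges are used.
#' @slot charges numeric matrix \code{n_atoms x 3}, columns
#'   \code{Nminus1}, \code{N}, \code{Nplus1}; e.
#' @slot atomicNumbers numeric vector of Z per atom.
#' @slot elements character vector of element symbols (may be empty).
#' @export
setClass("QMStateTable",
  representation(
    molecule = "character",
    environment = "character",
    energies = "numeric",
    charges = "matrix",
    atomicNumbers = "numeric",
    elements = "character"
  )
)

.QM_STATES <- c("Nminus1", "N", "Nplus1")

setValidity("QMStateTable", function(object) {
  if (!identical(names(object@energies), .QM_STATES)) {
    return("energies must be named Nminus1, N, Nplus1")
  }
  ch <- object@charges
  if (nrow(ch)) {
    if (!identical(colnames(ch), .QM_STATES)) {
      return("charge columns must be named Nminus1, N, Nplus1")
    }
    if (length(object@atomicNumbers) != nrow(ch)) {
      return("one atomic number per charge row required")
    }
  }
  if (!object@environment %in% c("vacuum", "water")) {
    return("environment must be 'vacuum' or 'water'")
  }
  TRUE
})

#' Construct a QMStateTable
#'
#' @param molecule molecule name.
#' @param energies named numeric vector (\code{Nminus1}, \code{N},
#'   \code{Nplus1}), hartree; NA entries allowed.
#' @param charges matrix \code{n_atoms x 3} with the same column names, or
#'   NULL when only global descriptors are needed.
#' @param atomicNumbers Z per atom (required with charges).
#' @param elements optional element symbols.
#' @param environment \code{"vacuum"} (default) or \code{"water"}.
#' @return a validated [QMStateTable-class] object.
#' @export
QMStateTable <- function(molecule, energies = c(Nminus1 = NA_real_,
                                                N = NA_real_,
                                                Nplus1 = NA_real_),
                         charges = NULL, atomicNumbers = numeric(0),
                         elements = character(0), environment = "vacuum") {
  energies <- energies[.QM_STATES]
  names(energies) <- .QM_STATES
  if (is.null(charges)) {
    charges <- matrix(numeric(0), nrow = 0, ncol = 3,
                      dimnames = list(NULL, .QM_STATES))
  } else {
    charges <- as.matrix(charges)
    colnames(charges) <- .QM_STATES
  }
  new("QMStateTable", molecule = molecule, environment = environment,
      energies = energies, charges = charges,
      atomicNumbers = as.numeric(atomicNumbers),
      elements = as.character(elements))
}
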