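# Generics, accessors and show methods for the core classes.

#' @rdname Topology-class
#' @param x,object a Topology or Trajectory.
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' @rdname Topology-class
#' @export
setGeneric("atomTable", function(x) standardGeneric("atomTable"))

#' @rdname Topology-class
#' @export
setGeneric("membraneGeometry", function(x) standardGeneric("membraneGeometry"))

#' @rdname Trajectory-class
#' @param x,object a Trajectory.
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname Trajectory-class
#' @export
setGeneric("frameTimes", function(x) standardGeneric("frameTimes"))

#' @rdname Trajectory-class
#' @export
setGeneric("boxDims", function(x) standardGeneric("boxDims"))

#' @rdname Trajectory-class
#' @export
setGeneric("topology", function(x) standardGeneric("topology"))

#' @export
#' @rdname Topology-class
setMethod("nAtoms", "Topology", function(x) nrow(x@atoms))

#' @export
#' @rdname Topology-class
setMethod("atomTable", "Topology", function(x) x@atoms)

#' @export
#' @rdname Topology-class
setMethod("membraneGeometry", "Topology", function(x) x@geometry)

#' @export
#' @rdname Trajectory-class
setMethod("nAtoms", "Trajectory", function(x) nrow(x@topology@atoms))

#' @export
#' @rdname Trajectory-class
setMethod("atomTable", "Trajectory", function(x) x@topology@atoms)

#' @export
#' @rdname Trajectory-class
setMethod("membraneGeometry", "Trajectory", function(x) x@topology@geometry)

#' @export
#' @rdname Trajectory-class
setMethod("nFrames", "Trajectory", function(x) dim(x@coords)[3])

#' @export
#' @rdname Trajectory-class
setMethod("frameTimes", "Trajectory", function(x) x@times)

#' @export
#' @rdname Trajectory-class
setMethod("boxDims", "Trajectory", function(x) x@box)

#' @export
#' @rdname Trajectory-class
setMethod("topology", "Trajectory", function(x) x@topology)

#' @importFrom S4Vectors metadata
#' @export
setMethod("metadata", "Trajectory", function(x, ...) x@metadata)

#' @importFrom S4Vectors metadata<-
#' @export
setReplaceMethod("metadata", "Trajectory", function(x, ..., value) {
  x@metadata <- value
  x
})

#' Extract one frame from a Trajectory
#'
#' @param traj a [Trajectory-class].
#' @param i frame number (1-based).
#' @return list with \code{coords} (\code{n_atoms x 3} matrix, Angstrom),
#'   \code{box} (length-3), \code{time} (ns).
#' @export
getFrame <- function(traj, i) {
  stopifnot(is(traj, "Trajectory"))
  i <- as.integer(i)
  if (i < 1L || i > nFrames(traj)) .stopf("frame %d out of range", i)
  list(coords = traj@coords[, , i, drop = TRUE],
       box = as.numeric(traj@box[i, ]),
       time = traj@times[i])
}

#' Logical mask of atoms carrying a group label
#'
#' Group labels are stored as a semicolon-separated string per atom;
#' this matches whole labels, not substrings.
#'
#' @param x a [Topology-class] or [Trajectory-class].
#' @param label label to match (e.g. \code{"P"}, \code{"terminal_CH3"}).
#' @return logical vector over atoms.
#' @export
labelMask <- function(x, label) {
  a <- atomTable(x)
  vapply(strsplit(a$labels, ";", fixed = TRUE),
         function(l) label %in% l, logical(1))
}

#' Atom row positions (1-based) for a selection
#'
#' @param x Topology or Trajectory.
#' @param label group label, or NULL.
#' @param kind molecule kind filter, or NULL.
#' @param moleculeId molecule id filter, or NULL.
#' @return integer vector of row positions into the atom table.
#' @export
selectAtoms <- function(x, label = NULL, kind = NULL, moleculeId = NULL) {
  a <- atomTable(x)
  keep <- rep(TRUE, nrow(a))
  if (!is.null(label)) keep <- keep & labelMask(x, label)
  if (!is.null(kind)) keep <- keep & a$molecule_kind %in% kind
  if (!is.null(moleculeId)) keep <- keep & a$molecule_id %in% moleculeId
  which(keep)
}

#' Molecule ids of a given kind
#' @param x Topology or Trajectory.
#' @param kind molecule kind (default \code{"drug"}).
#' @return sorted integer molecule ids.
#' @export
moleculeIds <- function(x, kind = "drug") {
  a <- atomTable(x)
  sort(unique(a$molecule_id[a$molecule_kind %in% kind]))
}

setMethod("show", "Topology", function(object) {
  a <- object@atoms
  cat("Topology:", nrow(a), "atoms,",
      length(unique(a$molecule_id)), "molecules;",
      "geometry:", object@geometry, "\n")
  if (nrow(a)) {
    kinds <- table(a$molecule_kind[!duplicated(a$molecule_id)])
    cat("  molecules by kind:",
        paste(names(kinds), kinds, sep = "=", collapse = ", "), "\n")
  }
})

setMethod("show", "Trajectory", function(object) {
  cat("Trajectory:", nAtoms(object), "atoms x", nFrames(object), "frames;",
      sprintf("t = %.4g..%.4g ns", object@times[1],
              object@times[nFrames(object)]), "\n")
  b <- object@box[1, ]
  cat(sprintf("  box (frame 1): %.2f x %.2f x %.2f A; geometry: %s\n",
              b[1], b[2], b[3], object@topology@geometry))
})

setMethod("show", "QMStateTable", function(object) {
  cat("QMStateTable:", object@molecule, sprintf("(%s)", object@environment),
      "\n  energies [hartree]:",
      paste(sprintf("%s=%.6g", names(object@energies), object@energies),
            collapse = ", "),
      "\n  charge sets:", nrow(object@charges), "atoms x 3 states\n")
})
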