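#' Accessors for BarrierScreen classes
#'
#' Slot access goes through accessors, not `@`.
#'
#' @param x an object of the documented class.
#' @name accessors
NULL

#' @rdname accessors
#' @return `atoms()`: the atom data.frame of a [ProteinStructure-class].
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))

#' @rdname accessors
#' @export
setMethod("atoms", "ProteinStructure", function(x) x@atoms)

#' @rdname accessors
#' @return `links()`: the two-column covalent-bond serial matrix.
#' @export
setGeneric("links", function(x) standardGeneric("links"))

#' @rdname accessors
#' @export
setMethod("links", "ProteinStructure", function(x) x@links)

#' @rdname accessors
#' @return `stateTag()`: the state tag ("ES", "GE" or "frame").
#' @export
setGeneric("stateTag", function(x) standardGeneric("stateTag"))

#' @rdname accessors
#' @export
setMethod("stateTag", "ProteinStructure", function(x) x@stateTag)

#' @rdname accessors
#' @return `nAtoms()`: number of atoms.
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' @rdname accessors
#' @export
setMethod("nAtoms", "ProteinStructure", function(x) nrow(x@atoms))

#' @rdname accessors
#' @return `energies()`: per-frame energies of a [ReactionProfile-class].
#' @export
setGeneric("energies", function(x) standardGeneric("energies"))

#' @rdname accessors
#' @export
setMethod("energies", "ReactionProfile", function(x) x@energies)

#' @rdname accessors
#' @return `x1Targets()`: per-frame reaction-coordinate targets.
#' @export
setGeneric("x1Targets", function(x) standardGeneric("x1Targets"))

#' @rdname accessors
#' @export
setMethod("x1Targets", "ReactionProfile", function(x) x@x1)

#' @rdname accessors
#' @export
setMethod("x1Targets", "FrameSet", function(x) x@x1Targets)

#' @rdname accessors
#' @return `frames()`: the list of frame structures of a [FrameSet-class].
#' @export
setGeneric("frames", function(x) standardGeneric("frames"))

#' @rdname accessors
#' @export
setMethod("frames", "FrameSet", function(x) x@frames)

#' @rdname accessors
#' @return `fixedSerials()`: frozen atom serials of a [ConstraintSet-class].
#' @export
setGeneric("fixedSerials", function(x) standardGeneric("fixedSerials"))

#' @rdname accessors
#' @export
setMethod("fixedSerials", "ConstraintSet", function(x) x@fixedSerials)

#' @rdname accessors
#' @return `barrierValue()`: the barrier height in kcal/mol (NA if invalid).
#' @export
setGeneric("barrierValue", function(x) standardGeneric("barrierValue"))

#' @rdname accessors
#' @export
setMethod("barrierValue", "BarrierResult",
          function(x) if (x@valid) x@barrier else NA_real_)
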