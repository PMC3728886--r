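#' @import methods
NULL

.BACKBONE_NAMES <- c("N", "CA", "C", "O", "OXT", "H", "HA", "H1", "H2", "H3")

.AA3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
          Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
          L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
          S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")
.AA1 <- setNames(names(.AA3), .AA3)

.atomColumns <- c("serial", "name", "altLoc", "resname", "chain", "resno",
                  "insert", "x", "y", "z", "element", "isSubstrate")

#' ProteinStructure: atoms, covalent-link registry and a state tag
#'
#' The central molecular container of the package. Atoms live in a
#' data.frame (one row per atom, in file/construction order) so that
#' standard data-frame tooling applies; the covalent-link registry holds
#' explicit inter-residue/substrate bonds (PDB CONECT records) as pairs of
#' atom serial numbers. `stateTag` marks which stationary point along the
#' reaction the structure represents: the enzyme-substrate complex
#' (`"ES"`), the covalent glycosyl-enzyme intermediate (`"GE"`), or an
#' interpolation `"frame"`.
#'
#' @slot atoms data.frame with columns serial, name, altLoc, resname,
#'   chain, resno, insert, x, y, z, element, isSubstrate.
#' @slot links integer matrix with two columns of atom serial numbers,
#'   one row per explicit covalent bond.
#' @slot stateTag character scalar, one of "ES", "GE", "frame".
#' @slot meta free-form list (mutant label, modelling status, ...).
#' @exportClass ProteinStructure
setClass("ProteinStructure",
         representation(atoms = "data.frame", links = "matrix",
                        stateTag = "character", meta = "list"))

setValidity("ProteinStructure", function(object) {
    a <- object@atoms
    if (nrow(a) == 0L) return("structure contains no atoms")
    missing <- setdiff(.atomColumns, colnames(a))
    if (length(missing))
        return(paste("missing atom columns:", paste(missing, collapse = ", ")))
    if (anyDuplicated(a$serial))
        return("atom serial numbers are not unique")
    if (!all(is.finite(c(a$x, a$y, a$z))))
        return("non-finite atom coordinates")
    if (any(!nzchar(a$element)))
        return("empty element symbols")
    if (!object@stateTag %in% c("ES", "GE", "frame"))
        return("stateTag must be one of 'ES', 'GE', 'frame'")
    ln <- object@links
    if (length(ln) && (ncol(ln) != 2L || !all(ln %in% a$serial)))
        return("link registry references unknown atom serials")
    TRUE
})

#' Construct a ProteinStructure
#'
#' @param atoms data.frame of atoms (see [ProteinStructure-class]); missing
#'   optional columns (altLoc, insert, element, isSubstrate) are filled with
#'   defaults.
#' @param links two-column matrix (or NULL) of bonded atom serial pairs.
#' @param stateTag "ES", "GE" or "frame".
#' @param meta free-form metadata list.
#' @return A [ProteinStructure-class] object.
#' @export
proteinStructure <- function(atoms, links = NULL, stateTag = "frame",
                             meta = list()) {
    atoms <- as.data.frame(atoms)
    if (is.null(atoms$altLoc)) atoms$altLoc <- ""
    if (is.null(atoms$insert)) atoms$insert <- ""
    if (is.null(atoms$isSubstrate)) atoms$isSubstrate <- FALSE
    if (is.null(atoms$element))
        atoms$element <- vapply(atoms$name, .elementFromName, character(1))
    if (is.null(atoms$serial)) atoms$serial <- seq_len(nrow(atoms))
    atoms$serial <- as.integer(atoms$serial)
    atoms$resno <- as.integer(atoms$resno)
    atoms <- atoms[, .atomColumns]
    rownames(atoms) <- NULL
    if (is.null(links)) links <- matrix(integer(0), ncol = 2)
    if (nrow(links))  # canonical bond orientation: low serial first
        links <- t(apply(links, 1L, sort))
    storage.mode(links) <- "integer"
    new("ProteinStructure", atoms = atoms, links = links,
        stateTag = stateTag, meta = meta)
}

.elementFromName <- function(name) {
    # first alphabetic character of the atom name; good enough for the
    # H/C/N/O/S/P set this package manipulates
    ch <- regmatches(name, regexpr("[A-Za-z]", name))
    if (!length(ch)) stop("cannot infer element from atom name '", name, "'")
    toupper(ch)
}

#' Formal-charge rules under a fixed protonation convention
#'
#' Standard protonation of ionizable residues: ASP/GLU carry -1, LYS/ARG
#' +1, HIS is neutral (epsilon tautomer), CYS/TYR/SER/THR neutral; chain
#' termini are zwitterionic (+1 amino, -1 carboxylate, net 0 per chain).
#' Hetero groups (substrates, cofactors) must be declared explicitly in
#' `hetero`, keyed by residue name.
#'
#' @slot charges named numeric, residue name -> formal charge.
#' @slot hetero named numeric, hetero residue name -> declared charge.
#' @slot zwitterionic logical, apply +1/-1 terminus charges per chain.
#' @exportClass ProtonationRules
setClass("ProtonationRules",
         representation(charges = "numeric", hetero = "numeric",
                        zwitterionic = "logical"))

setValidity("ProtonationRules", function(object) {
    need <- c("ASP", "GLU", "LYS", "ARG", "HIS", "CYS", "TYR")
    if (!all(need %in% names(object@charges)))
        return("rules must cover at least ASP, GLU, LYS, ARG, HIS, CYS, TYR")
    TRUE
})

#' Default protonation rules
#'
#' @param hetero named numeric of declared hetero-group charges, e.g.
#'   `c(XYB = -1)` for an anionic substrate.
#' @param zwitterionic treat chain termini as NH3+/COO- (net zero).
#' @return A [ProtonationRules-class] object covering the 20 canonical
#'   amino acids.
#' @export
defaultProtonationRules <- function(hetero = numeric(0), zwitterionic = TRUE) {
    ch <- setNames(numeric(20), unname(.AA3))
    ch[c("ASP", "GLU")] <- -1
    ch[c("LYS", "ARG")] <- +1
    new("ProtonationRules", charges = ch, hetero = hetero,
        zwitterionic = zwitterionic)
}

#' A single point mutation
#'
#' @slot chain chain identifier.
#' @slot seqNumber residue sequence number.
#' @slot wtAa,targetAa one-letter codes; must differ.
#' @slot label canonical label, e.g. "Q127W".
#' @exportClass MutationSpec
setClass("MutationSpec",
         representation(chain = "character", seqNumber = "integer",
                        wtAa = "character", targetAa = "character",
                        label = "character"))

setValidity("MutationSpec", function(object) {
    if (!object$targetAa %in% names(.AA3))
        return("targetAa must be a canonical one-letter amino-acid code")
    if (!object$wtAa %in% names(.AA3))
        return("wtAa must be a canonical one-letter amino-acid code")
    if (object$wtAa == object$targetAa)
        return("wtAa and targetAa must differ")
    expect <- paste0(object$wtAa, object$seqNumber, object$targetAa)
    if (object$label != expect)
        return(paste0("label must be '", expect, "'"))
    TRUE
})

setMethod("$", "MutationSpec", function(x, name) slot(x, name))

#' Construct a MutationSpec
#'
#' @param chain chain identifier.
#' @param seqNumber residue number.
#' @param wtAa wild-type one-letter code.
#' @param targetAa replacement one-letter code.
#' @return A [MutationSpec-class].
#' @export
mutationSpec <- function(chain, seqNumber, wtAa, targetAa) {
    new("MutationSpec", chain = as.character(chain),
        seqNumber = as.integer(seqNumber), wtAa = wtAa, targetAa = targetAa,
        label = paste0(wtAa, seqNumber, targetAa))
}

#' A double mutant: two single mutations at distinct positions
#'
#' Constituents are stored in canonical order by (chain, seqNumber).
#'
#' @slot first,second [MutationSpec-class] constituents.
#' @exportClass DoubleSpec
setClass("DoubleSpec",
         representation(first = "MutationSpec", second = "MutationSpec"))

setValidity("DoubleSpec", function(object) {
    a <- object@first; b <- object@second
    if (a@chain == b@chain && a@seqNumber == b@seqNumber)
        return("double mutant must combine two distinct positions")
    if (a@chain > b@chain ||
        (a@chain == b@chain && a@seqNumber > b@seqNumber))
        return("constituents must be ordered by (chain, seqNumber)")
    TRUE
})

#' Construct a DoubleSpec (canonically ordered)
#' @param first,second [MutationSpec-class] objects at distinct positions.
#' @return A [DoubleSpec-class].
#' @export
doubleSpec <- function(first, second) {
    swap <- first@chain > second@chain ||
        (first@chain == second@chain && first@seqNumber > second@seqNumber)
    if (swap) { tmp <- first; first <- second; second <- tmp }
    new("DoubleSpec", first = first, second = second)
}

#' The constrained reaction coordinate
#'
#' The single interatomic distance x1 that is frozen during frame
#' relaxation: for a retaining glycosidase, the nucleophile carboxylate
#' oxygen (O-epsilon) to anomeric carbon (C1) distance.
#'
#' @slot atomA,atomB atom selectors (`"chain:resno:name"`, see
#'   [resolveAtoms()]).
#' @slot value target distance in Angstrom (> 0).
#' @exportClass ReactionCoordinate
setClass("ReactionCoordinate",
         representation(atomA = "character", atomB = "character",
                        value = "numeric"))

setValidity("ReactionCoordinate", function(object) {
    if (length(object@value) && (!is.finite(object@value) || object@value <= 0))
        return("reaction-coordinate value must be a positive length")
    TRUE
})

#' Construct a ReactionCoordinate
#' @param atomA,atomB atom selectors (`"chain:resno:name"` or
#'   `"resname:name"` for substrate atoms).
#' @param value optional target distance in Angstrom.
#' @return A [ReactionCoordinate-class].
#' @export
reactionCoordinate <- function(atomA, atomB, value = numeric(0)) {
    new("ReactionCoordinate", atomA = atomA, atomB = atomB, value = value)
}

#' Cartesian constraint set K
#'
#' Atoms of all residues beyond `layerRadius` of the active center are
#' spatially frozen during optimization. The reaction-coordinate atoms are
#' never members of the fixed set. `originState` records which optimized
#' state the frozen coordinates were inherited from; constraints are only
#' meaningful on parts of the system already optimized in a preceding step.
#'
#' @slot fixedSerials integer vector of frozen atom serial numbers.
#' @slot layerRadius optimization-layer radius in Angstrom (Inf =
#'   unconstrained).
#' @slot originState state tag of the structure the frozen coordinates
#'   come from.
#' @exportClass ConstraintSet
setClass("ConstraintSet",
         representation(fixedSerials = "integer", layerRadius = "numeric",
                        originState = "character"))

#' An empty (unconstrained) constraint set
#' @return A [ConstraintSet-class] with no fixed atoms.
#' @export
unconstrained <- function() {
    new("ConstraintSet", fixedSerials = integer(0), layerRadius = Inf,
        originState = "frame")
}

#' An interpolation frame set
#'
#' Ordered frames along x1: frame 1 is the ES endpoint, the last frame the
#' GE endpoint, with `nIntermediate` linear blends in between, each with
#' its exact x1 target enforced.
#'
#' @slot frames list of [ProteinStructure-class] objects.
#' @slot x1Targets numeric vector of per-frame x1 targets (Angstrom).
#' @slot rc the [ReactionCoordinate-class].
#' @slot constraint the [ConstraintSet-class] applied during relaxation.
#' @exportClass FrameSet
setClass("FrameSet",
         representation(frames = "list", x1Targets = "numeric",
                        rc = "ReactionCoordinate", constraint = "ConstraintSet"))

setValidity("FrameSet", function(object) {
    if (length(object@frames) != length(object@x1Targets))
        return("one x1 target per frame required")
    TRUE
})

#' Energy-engine configuration
#'
#' @slot methodLabel Hamiltonian label written on the keyword line ("PM6").
#' @slot gnorm gradient-norm convergence threshold, kcal/(mol A).
#' @slot cutoff NDDO cutoff distance, Angstrom.
#' @slot eps relative dielectric constant of the continuum solvent.
#' @slot charge total system charge.
#' @slot reorthogonalize also record reorthogonalized single-point energies.
#' @slot walltimeLimit wall-clock limit per job, seconds (Inf = none).
#' @slot engine "surrogate" or "external".
#' @slot binary path of the external engine executable ("" = unset).
#' @slot extraKeywords free-form additional keywords.
#' @slot failurePatterns named character vector of regexes matched against
#'   engine output (names are statuses, e.g. LEWIS_FAILURE).
#' @exportClass EngineConfig
setClass("EngineConfig",
         representation(methodLabel = "character", gnorm = "numeric",
                        cutoff = "numeric", eps = "numeric",
                        charge = "integer", reorthogonalize = "logical",
                        walltimeLimit = "numeric", engine = "character",
                        binary = "character", extraKeywords = "character",
                        failurePatterns = "character"))

setValidity("EngineConfig", function(object) {
    if (object@gnorm <= 0) return("gnorm must be > 0")
    if (object@cutoff <= 0) return("cutoff must be > 0")
    if (object@eps < 1) return("eps must be >= 1")
    if (!object@engine %in% c("surrogate", "external"))
        return("engine must be 'surrogate' or 'external'")
    TRUE
})

#' Default failure patterns for the MOPAC-dialect output parser
#'
#' Engine message wording varies across versions, so the list is plain
#' data the caller can edit/extend.
#' @return named character vector (status -> regex).
#' @export
defaultFailurePatterns <- function() {
    c(LEWIS_FAILURE = "LEWIS STRUCTURE|UNABLE TO RESOLVE.*LEWIS|FAILED TO ACHIEVE A LEWIS",
      NOT_CONVERGED = "EXCESS NUMBER OF OPTIMIZATION CYCLES|GEOMETRY NOT OPTIMIZED",
      TIMEOUT = "RAN OUT OF TIME|WALL CLOCK LIMIT")
}

#' Construct an EngineConfig
#'
#' Defaults follow the production screening settings: PM6 with localized
#' orbitals, gnorm 1.0 kcal/(mol A), NDDO cutoff 15 A, COSMO water
#' (eps = 78).
#'
#' @param methodLabel Hamiltonian label.
#' @param gnorm gradient convergence threshold, kcal/(mol A).
#' @param cutoff NDDO cutoff, Angstrom.
#' @param eps relative dielectric constant.
#' @param charge total charge.
#' @param reorthogonalize record a second, reorthogonalized single-point
#'   energy per frame.
#' @param walltimeLimit seconds per engine job.
#' @param engine "surrogate" or "external".
#' @param binary external engine executable path.
#' @param extraKeywords extra keyword tokens appended to the keyword line.
#' @param failurePatterns status -> regex map for output classification.
#' @return An [EngineConfig-class].
#' @export
engineConfig <- function(methodLabel = "PM6", gnorm = 1.0, cutoff = 15,
                         eps = 78, charge = 0L, reorthogonalize = FALSE,
                         walltimeLimit = Inf, engine = "surrogate",
                         binary = "", extraKeywords = character(0),
                         failurePatterns = defaultFailurePatterns()) {
    new("EngineConfig", methodLabel = methodLabel, gnorm = gnorm,
        cutoff = cutoff, eps = eps, charge = as.integer(charge),
        reorthogonalize = reorthogonalize, walltimeLimit = walltimeLimit,
        engine = engine, binary = binary, extraKeywords = extraKeywords,
        failurePatterns = failurePatterns)
}

#' Result of one engine job
#'
#' @slot finalEnergy final heat of formation / energy, kcal/mol (NA unless
#'   converged).
#' @slot finalStructure optimized [ProteinStructure-class], or NULL.
#' @slot status one of CONVERGED, LEWIS_FAILURE, CHARGE_MISMATCH,
#'   NOT_CONVERGED, TIMEOUT.
#' @slot reportedCharge engine-reported total charge (NA if absent).
#' @slot wallTime seconds.
#' @exportClass EngineResult
setClass("EngineResult",
         representation(finalEnergy = "numeric", finalStructure = "ANY",
                        status = "character", reportedCharge = "numeric",
                        wallTime = "numeric"))

.ENGINE_STATUSES <- c("CONVERGED", "LEWIS_FAILURE", "CHARGE_MISMATCH",
                      "NOT_CONVERGED", "TIMEOUT")

setValidity("EngineResult", function(object) {
    if (!object@status %in% .ENGINE_STATUSES)
        return(paste("status must be one of:",
                     paste(.ENGINE_STATUSES, collapse = ", ")))
    if (object@status == "CONVERGED" &&
        (!is.finite(object@finalEnergy) || is.null(object@finalStructure)))
        return("CONVERGED requires a finite energy and a final structure")
    TRUE
})

#' Analytic surrogate energy surface
#'
#' A programmable stand-in for a quantum-chemical engine. The energy along
#' the reaction coordinate is a symmetric quartic double-well with exact
#' minima of zero at `x1ES` and `x1GE`, plus a flat-topped polynomial bump
#' `B * (1 - u^4)^3` (`u = (x1 - midpoint)/bumpWidth`, compactly supported
#' between the basins), so the analytic barrier is exactly
#' `wellHeight + B`. The bump height is set per mutant label as
#' `barrierWT + sum(offsets[constituent labels]) - wellHeight`, which makes
#' programmed single-mutant effects exactly additive in double mutants
#' unless a `pairDeviations` entry says otherwise. All non-reacting atoms
#' feel harmonic tethers to reference coordinates.
#'
#' @slot x1ES,x1GE basin positions along x1, Angstrom.
#' @slot wellHeight quartic double-well saddle height, kcal/mol.
#' @slot bumpWidth half-width of the bump support, Angstrom.
#' @slot barrierWT programmed wild-type barrier, kcal/mol.
#' @slot offsets named numeric: single-mutant label -> barrier offset.
#' @slot pairDeviations named numeric: double label "A-B" -> deviation from
#'   additivity.
#' @slot stiffness tether force constant, kcal/(mol A^2).
#' @slot reference tether reference coordinates (n x 3 matrix) or 0-row
#'   matrix to tether each job to its own starting coordinates.
#' @slot noiseSd per-frame energy noise SD, kcal/mol.
#' @slot noiseSeed base seed of the noise stream.
#' @exportClass SurrogateSurface
setClass("SurrogateSurface",
         representation(x1ES = "numeric", x1GE = "numeric",
                        wellHeight = "numeric", bumpWidth = "numeric",
                        barrierWT = "numeric", offsets = "numeric",
                        pairDeviations = "numeric", stiffness = "numeric",
                        reference = "matrix", noiseSd = "numeric",
                        noiseSeed = "integer"))

setValidity("SurrogateSurface", function(object) {
    if (object@x1ES == object@x1GE) return("x1ES and x1GE must differ")
    if (object@barrierWT < object@wellHeight)
        return("programmed WT barrier must be >= wellHeight")
    halfgap <- abs(object@x1ES - object@x1GE) / 2
    if (object@bumpWidth <= 0 || object@bumpWidth >= halfgap)
        return("bumpWidth must lie in (0, |x1ES - x1GE|/2)")
    if (object@noiseSd < 0) return("noiseSd must be >= 0")
    TRUE
})

#' A reaction profile: per-frame energies and engine statuses
#'
#' @slot label mutant label ("WT" for wild type).
#' @slot pathwayId endpoint-derivation pathway used (1-5).
#' @slot x1 per-frame reaction-coordinate targets, Angstrom.
#' @slot energies per-frame energies, kcal/mol (NA where not converged).
#' @slot statuses per-frame engine statuses.
#' @slot layerRadius optimization-layer radius, Angstrom.
#' @slot reorthoEnergies optional parallel reorthogonalized energies.
#' @exportClass ReactionProfile
setClass("ReactionProfile",
         representation(label = "character", pathwayId = "integer",
                        x1 = "numeric", energies = "numeric",
                        statuses = "character", layerRadius = "numeric",
                        reorthoEnergies = "numeric"))

setValidity("ReactionProfile", function(object) {
    n <- length(object@x1)
    if (length(object@energies) != n || length(object@statuses) != n)
        return("x1, energies and statuses must have equal length")
    bad <- object@statuses != "CONVERGED" & !is.na(object@energies)
    if (any(bad))
        return("energies must be NA for non-converged frames")
    TRUE
})

#' Construct a ReactionProfile
#' @param label mutant label.
#' @param x1 frame x1 targets.
#' @param energies frame energies (kcal/mol, NA if not converged).
#' @param statuses frame statuses (default CONVERGED where energy present).
#' @param pathwayId derivation pathway id.
#' @param layerRadius optimization layer radius.
#' @param reorthoEnergies optional reorthogonalized energies.
#' @return A [ReactionProfile-class].
#' @export
reactionProfile <- function(label, x1, energies, statuses = NULL,
                            pathwayId = 5L, layerRadius = Inf,
                            reorthoEnergies = numeric(0)) {
    if (is.null(statuses))
        statuses <- ifelse(is.na(energies), "NOT_CONVERGED", "CONVERGED")
    new("ReactionProfile", label = label, pathwayId = as.integer(pathwayId),
        x1 = as.numeric(x1), energies = as.numeric(energies),
        statuses = statuses, layerRadius = layerRadius,
        reorthoEnergies = reorthoEnergies)
}

#' Result of barrier extraction from a reaction profile
#'
#' @slot barrier kcal/mol (NA when invalid).
#' @slot argmax,argmin frame indices of the profile maximum and of the
#'   preceding minimum (argmin < argmax).
#' @slot valid logical.
#' @slot reason rejection reason: "", LAST_FRAME_MAX, NO_PRE_MAX or
#'   INCOMPLETE.
#' @exportClass BarrierResult
setClass("BarrierResult",
         representation(barrier = "numeric", argmax = "integer",
                        argmin = "integer", valid = "logical",
                        reason = "character"))

setValidity("BarrierResult", function(object) {
    if (object@valid) {
        if (!is.finite(object@barrier) || object@barrier <= 0)
            return("valid barrier must be finite and > 0")
        if (object@argmin >= object@argmax)
            return("argmin must precede argmax")
    } else if (!nzchar(object@reason)) {
        return("invalid result must carry a rejection reason")
    }
    TRUE
})

#' An endpoint-derivation pathway plan
#'
#' Ordered preparation steps for one of the five interpolation pathways:
#' 1-2 are wild-type-only, 3-5 mutant-capable.
#'
#' @slot pathwayId integer 1-5.
#' @slot steps ordered character vector of step names.
#' @slot constrained whether constraints K are applied.
#' @exportClass PathwayPlan
setClass("PathwayPlan",
         representation(pathwayId = "integer", steps = "character",
                        constrained = "logical"))

#' Transition-state-theory rate conversion record
#'
#' Binds a turnover number, a temperature and the activation free energy
#' obtained from the Eyring relation dG = R T ln(kB T / (h kcat)).
#'
#' @slot kcat turnover number, 1/s.
#' @slot temperature Kelvin.
#' @slot deltaG activation free energy, kcal/mol.
#' @exportClass RateConversion
setClass("RateConversion",
         representation(kcat = "numeric", temperature = "numeric",
                        deltaG = "numeric"))

setValidity("RateConversion", function(object) {
    dg <- eyringDG(object@kcat, object@temperature)
    if (abs(dg - object@deltaG) > 1e-9 * max(1, abs(dg)))
        return("deltaG inconsistent with kcat and temperature")
    TRUE
})

## ---- show methods -------------------------------------------------------

setMethod("show", "ProteinStructure", function(object) {
    a <- object@atoms
    cat("ProteinStructure [", object@stateTag, "]: ", nrow(a), " atoms, ",
        nrow(unique(a[, c("chain", "resno", "insert")])), " residues, ",
        sum(a$isSubstrate), " substrate atoms, ",
        nrow(object@links), " registered bonds\n", sep = "")
    lab <- object@meta$label
    if (!is.null(lab)) cat("  mutant label:", lab, "\n")
})

setMethod("show", "MutationSpec", function(object) {
    cat("MutationSpec ", object@label, " (chain ", object@chain, ")\n",
        sep = "")
})

setMethod("show", "DoubleSpec", function(object) {
    cat("DoubleSpec ", doubleLabel(object), "\n", sep = "")
})

setMethod("show", "ReactionProfile", function(object) {
    cat("ReactionProfile '", object@label, "' (pathway ", object@pathwayId,
        "): ", length(object@x1), " frames, x1 ",
        sprintf("%.3f", object@x1[1]), " -> ",
        sprintf("%.3f", object@x1[length(object@x1)]), " A, ",
        sum(object@statuses == "CONVERGED"), " converged\n", sep = "")
})

setMethod("show", "BarrierResult", function(object) {
    if (object@valid)
        cat(sprintf("BarrierResult: %.1f kcal/mol (frames %d -> %d)\n",
                    object@barrier, object@argmin, object@argmax))
    else
        cat("BarrierResult: invalid (", object@reason, ")\n", sep = "")
})

setMethod("show", "EngineResult", function(object) {
    cat("EngineResult:", object@status,
        if (is.finite(object@finalEnergy))
            sprintf("E = %.4f kcal/mol", object@finalEnergy) else "",
        "\n")
})

setMethod("show", "SurrogateSurface", function(object) {
    cat(sprintf(paste0("SurrogateSurface: basins at %.2f / %.2f A, ",
                       "WT barrier %.2f kcal/mol, %d mutant offsets\n"),
                object@x1ES, object@x1GE, object@barrierWT,
                length(object@offsets)))
})
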