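#' Derive the ES complex from a glycosyl-enzyme (GE) structure
#'
#' The covalent nucleophile-substrate bond (O-epsilon to C1) is removed
#' from the link registry, the glycosidic bond between C1 and the leaving
#' group's linking oxygen is formed, and the leaving-group fragment is
#' rigid-body translated so the new bond takes the standard glycosidic
#' C-O length. No other atom moves.
#'
#' @param ge a GE-state [ProteinStructure-class] whose link registry
#'   contains the O-epsilon - C1 bond.
#' @param rc the [ReactionCoordinate-class] (atomA = nucleophile oxygen,
#'   atomB = anomeric carbon C1).
#' @param leavingGroup residue name of the leaving-group fragment
#'   (present and not yet bonded to C1).
#' @param linkAtom atom name of the leaving group's phenolic oxygen.
#' @param bondLength glycosidic C-O bond length, Angstrom.
#' @return an ES-state [ProteinStructure-class].
#' @export
deriveESfromGE <- function(ge, rc, leavingGroup = "ONP", linkAtom = "O1",
                           bondLength = 1.43) {
    ia <- resolveAtoms(ge, rc@atomA)
    ib <- resolveAtoms(ge, rc@atomB)
    sa <- ge@atoms$serial[ia]
    sb <- ge@atoms$serial[ib]
    ln <- ge@links
    hit <- which((ln[, 1L] == sa & ln[, 2L] == sb) |
                 (ln[, 1L] == sb & ln[, 2L] == sa))
    if (!length(hit))
        stop("derivation error: no covalent nucleophile-C1 link in ",
             "the link registry (already an ES structure?)")
    lg <- which(ge@atoms$resname == leavingGroup)
    if (!length(lg))
        stop("derivation error: no '", leavingGroup, "' fragment present")
    io <- resolveAtoms(ge, paste(leavingGroup, linkAtom, sep = ":"))
    so <- ge@atoms$serial[io]
    if (any((ln[, 1L] == sb & ln[, 2L] == so) |
            (ln[, 1L] == so & ln[, 2L] == sb)))
        stop("derivation error: C1 already bonded to the leaving group")
    xyz <- .coords(ge)
    dir <- .unit(xyz[ib, ] - xyz[ia, ])
    newO <- xyz[ib, ] + bondLength * dir
    shift <- newO - xyz[io, ]
    xyz[lg, ] <- sweep(xyz[lg, , drop = FALSE], 2L, shift, "+")
    out <- .setCoords(ge, xyz)
    out@links <- rbind(ln[-hit, , drop = FALSE],
                       as.integer(c(min(sb, so), max(sb, so))))
    storage.mode(out@links) <- "integer"
    out@stateTag <- "ES"
    out
}

#' Assemble a mutant ES'' from a mutant GE and the wild-type ES'
#'
#' Implements the substrate-extraction step of the mutant-capable
#' derivation pathway: protein coordinates are taken from the (optimized)
#' mutant GE, substrate coordinates from the wild-type ES', and the link
#' registry becomes that of an ES state. The mutated side chain is thereby
#' identically oriented in the resulting ES and the GE it came from.
#'
#' @param mutGe mutant GE [ProteinStructure-class].
#' @param wtEsPrime wild-type ES' [ProteinStructure-class] with matching
#'   substrate atom naming.
#' @return the mutant ES'' [ProteinStructure-class].
#' @export
extractAndModifySubstrate <- function(mutGe, wtEsPrime) {
    ga <- mutGe@atoms
    ea <- wtEsPrime@atoms
    gSub <- which(ga$isSubstrate)
    eSub <- which(ea$isSubstrate)
    gKeys <- .atomKeys(mutGe)[gSub]
    eKeys <- .atomKeys(wtEsPrime)[eSub]
    hit <- match(gKeys, eKeys)
    if (anyNA(hit))
        stop("substrate correspondence error: atom(s) ",
             paste(gKeys[is.na(hit)], collapse = ", "),
             " missing from the ES' structure")
    out <- mutGe
    src <- eSub[hit]
    out@atoms$x[gSub] <- ea$x[src]
    out@atoms$y[gSub] <- ea$y[src]
    out@atoms$z[gSub] <- ea$z[src]
    # protein-internal bonds from the mutant, substrate-involving bonds
    # from the ES' state (mapped onto the mutant's serials by atom key)
    keyAll <- .atomKeys(mutGe)
    eKeyAll <- .atomKeys(wtEsPrime)
    isSubSerial <- ga$serial[gSub]
    gl <- mutGe@links
    protOnly <- gl[!(gl[, 1L] %in% isSubSerial | gl[, 2L] %in% isSubSerial), ,
                   drop = FALSE]
    el <- wtEsPrime@links
    eSubSerial <- ea$serial[eSub]
    subLinks <- el[el[, 1L] %in% eSubSerial | el[, 2L] %in% eSubSerial, ,
                   drop = FALSE]
    if (nrow(subLinks)) {
        mapSerial <- function(sr) {
            k <- eKeyAll[match(sr, ea$serial)]
            ga$serial[match(k, keyAll)]
        }
        subLinks <- cbind(mapSerial(subLinks[, 1L]), mapSerial(subLinks[, 2L]))
        if (anyNA(subLinks))
            stop("substrate correspondence error: bonded atom missing ",
                 "from the mutant structure")
    }
    out@links <- rbind(protOnly, subLinks)
    storage.mode(out@links) <- "integer"
    out@stateTag <- "ES"
    out
}

#' Build the Cartesian constraint set K
#'
#' All atoms of protein residues with no atom within `layerRadius` of the
#' active center are frozen; substrate atoms and the reaction-coordinate
#' atoms are never frozen (the latter are removed with a warning if their
#' residue falls outside the layer).
#'
#' @param s a [ProteinStructure-class], already optimized in the state the
#'   frozen coordinates are inherited from.
#' @param activeCenter atom selectors/serials of the active-center set
#'   (non-empty), typically the substrate atoms.
#' @param layerRadius optimization-layer radius, Angstrom (Inf =
#'   unconstrained).
#' @param rc optional [ReactionCoordinate-class] whose atoms are excluded
#'   from the fixed set.
#' @return A [ConstraintSet-class].
#' @export
buildConstraints <- function(s, activeCenter, layerRadius, rc = NULL) {
    if (!length(activeCenter)) stop("active center must be non-empty")
    if (layerRadius <= 0 && !is.infinite(layerRadius))
        stop("layerRadius must be positive or infinite")
    if (is.infinite(layerRadius))
        return(new("ConstraintSet", fixedSerials = integer(0),
                   layerRadius = Inf, originState = s@stateTag))
    inner <- residuesWithin(s, activeCenter, layerRadius)
    innerKeys <- paste(inner$chain, inner$resno, inner$insert, sep = ":")
    a <- s@atoms
    rkey <- .residueKeys(a)
    isSub <- as.logical(ave(a$isSubstrate, rkey, FUN = any))
    fixed <- a$serial[!isSub & !(rkey %in% innerKeys)]
    if (!is.null(rc)) {
        rcSerials <- a$serial[resolveAtoms(s, c(rc@atomA, rc@atomB))]
        drop <- intersect(fixed, rcSerials)
        if (length(drop)) {
            warning("reaction-coordinate atom(s) removed from the fixed set")
            fixed <- setdiff(fixed, drop)
        }
    }
    new("ConstraintSet", fixedSerials = as.integer(fixed),
        layerRadius = layerRadius, originState = s@stateTag)
}

#' Build interpolation frames between ES and GE endpoints
#'
#' Intermediate coordinates are linear blends
#' `c_k = (1 - t_k) c_ES + t_k c_GE` with `t_k = k/(n+1)`, giving
#' `nIntermediate + 2` frames whose x1 targets form an arithmetic
#' progression from x1(ES) to x1(GE). Each frame's x1 is enforced exactly
#' by rescaling the anomeric-carbon position along the nucleophile-carbon
#' axis. Atom correspondence between the endpoints is established by
#' (chain, resno, insertion, atom name) matching; any unmatched atom is an
#' error.
#'
#' @param es,ge endpoint [ProteinStructure-class] objects with identical
#'   atom sets.
#' @param rc the [ReactionCoordinate-class].
#' @param nIntermediate number of intermediate frames (default 10).
#' @param constraint [ConstraintSet-class] recorded for downstream
#'   relaxation (default unconstrained).
#' @return A [FrameSet-class] of `nIntermediate + 2` frames; frame 1 is
#'   the ES endpoint, the last frame the GE endpoint.
#' @export
makeFrames <- function(es, ge, rc, nIntermediate = 10L,
                       constraint = unconstrained()) {
    kE <- .atomKeys(es)
    kG <- .atomKeys(ge)
    if (nrow(es@atoms) != nrow(ge@atoms) || !setequal(kE, kG) ||
        anyDuplicated(kE))
        stop("endpoint correspondence error: atom sets do not match")
    ord <- match(kE, kG)
    geo <- ge
    geo@atoms <- ge@atoms[ord, , drop = FALSE]
    rownames(geo@atoms) <- NULL
    x1e <- measureX1(es, rc)
    x1g <- measureX1(geo, rc)
    if (isTRUE(all.equal(x1e, x1g, tolerance = 1e-12)))
        stop("degenerate path: x1 identical at both endpoints")
    ia <- resolveAtoms(es, rc@atomA)
    ib <- resolveAtoms(es, rc@atomB)
    ce <- .coords(es)
    cg <- .coords(geo)
    n <- as.integer(nIntermediate)
    tk <- seq(0L, n + 1L) / (n + 1)
    targets <- (1 - tk) * x1e + tk * x1g
    frames <- vector("list", n + 2L)
    for (k in seq_along(tk)) {
        xyz <- (1 - tk[k]) * ce + tk[k] * cg
        if (k > 1L && k < length(tk)) {
            # endpoints are kept bit-exact; intermediates get their x1
            # target enforced by rescaling the anomeric carbon position
            axis <- xyz[ib, ] - xyz[ia, ]
            xyz[ib, ] <- xyz[ia, ] + axis * (targets[k] / sqrt(sum(axis^2)))
        }
        f <- if (k == 1L) es else if (k == length(tk)) geo else es
        f <- .setCoords(f, xyz)
        f@stateTag <- if (k == 1L) "ES" else if (k == length(tk)) "GE"
                      else "frame"
        f@meta$frameIndex <- k - 1L
        frames[[k]] <- f
    }
    new("FrameSet", frames = frames, x1Targets = targets, rc = rc,
        constraint = constraint)
}

#' Close-contact validity check
#'
#' Fails iff any non-bonded atom pair sits closer than `dmin`; all
#' offending pairs are reported. Pairs within the same residue and pairs
#' in the link registry count as bonded and are exempt. Badly clashing
#' frames are the geometries an engine refuses to start on.
#'
#' @param f a [ProteinStructure-class] (e.g. one interpolation frame).
#' @param dmin minimum allowed non-bonded distance, Angstrom.
#' @return list with elements `pass` (logical) and `pairs` (data.frame
#'   serialA, serialB, dist).
#' @export
closeContactCheck <- function(f, dmin = 0.7) {
    stopifnot(dmin > 0)
    xyz <- .coords(f)
    n <- nrow(xyz)
    d <- as.matrix(stats::dist(xyz))
    diag(d) <- Inf
    rkey <- .residueKeys(f@atoms)
    d[outer(rkey, rkey, "==")] <- Inf
    if (nrow(f@links)) {
        i1 <- match(f@links[, 1L], f@atoms$serial)
        i2 <- match(f@links[, 2L], f@atoms$serial)
        d[cbind(i1, i2)] <- Inf
        d[cbind(i2, i1)] <- Inf
    }
    bad <- which(d < dmin & upper.tri(d), arr.ind = TRUE)
    pairs <- data.frame(serialA = f@atoms$serial[bad[, 1L]],
                        serialB = f@atoms$serial[bad[, 2L]],
                        dist = d[bad])
    list(pass = nrow(pairs) == 0L, pairs = pairs)
}

.PATHWAY_STEPS <- list(
    `1` = c("prepare WT GE from crystal model",
            "modify substrate (1) -> WT ES",
            "optimize WT GE (unconstrained)",
            "optimize WT ES (unconstrained)",
            "interpolate"),
    `2` = c("optimize WT GE",
            "modify substrate (2) -> WT ES'",
            "define constraints K",
            "apply constraints K",
            "optimize WT ES'",
            "interpolate"),
    `3` = c("mutate WT ES opt -> Mut ES",
            "mutate WT GE opt -> Mut GE",
            "optimize Mut ES",
            "optimize Mut GE",
            "interpolate"),
    `4` = c("mutate WT ES' opt -> Mut ES'",
            "mutate WT GE opt -> Mut GE",
            "optimize Mut ES'",
            "optimize Mut GE",
            "interpolate"),
    `5` = c("mutate WT GE opt -> Mut GE",
            "optimize Mut GE",
            "extract substrate",
            "modify substrate (3) -> Mut ES''",
            "optimize Mut ES''",
            "interpolate"))

#' Plan an endpoint-derivation pathway
#'
#' Pathways 1-2 prepare wild-type interpolations, 3-5 mutant
#' interpolations. Pathway 3 interpolates between two independently
#' mutated and optimized endpoints, so Cartesian constraints cannot be
#' meaningfully applied there: fixing atoms whose coordinates differ
#' slightly between the endpoints produces enormous energies; requesting
#' them is a configuration error.
#'
#' @param pathwayId integer 1-5.
#' @param mutation optional [MutationSpec-class]/[DoubleSpec-class];
#'   required for pathways 3-5, rejected for 1-2.
#' @param constrained apply the constraint set K.
#' @return A [PathwayPlan-class].
#' @export
planPathway <- function(pathwayId, mutation = NULL, constrained = FALSE) {
    pathwayId <- as.integer(pathwayId)
    if (!pathwayId %in% 1:5) stop("pathwayId must be 1..5")
    if (pathwayId %in% 1:2 && !is.null(mutation))
        stop("pathways 1-2 are wild-type-only")
    if (pathwayId %in% 3:5 && is.null(mutation))
        stop("pathways 3-5 require a mutation")
    if (pathwayId == 3L && constrained)
        stop("configuration error: constraints cannot be applied in ",
             "pathway 3")
    new("PathwayPlan", pathwayId = pathwayId,
        steps = .PATHWAY_STEPS[[as.character(pathwayId)]],
        constrained = constrained)
}
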