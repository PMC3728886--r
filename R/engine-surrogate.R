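#' Construct a surrogate energy surface
#'
#' See [SurrogateSurface-class] for the functional form. The analytic
#' barrier for a mutant label equals `barrierWT + sum(offsets)` exactly
#' (plus any programmed pair deviation for a double), with basin minima
#' of exactly zero at both endpoints.
#'
#' @param x1ES,x1GE basin positions, Angstrom.
#' @param barrierWT wild-type barrier, kcal/mol.
#' @param offsets named numeric of per-single-mutant barrier offsets.
#' @param pairDeviations named numeric of non-additive deviations per
#'   double label.
#' @param wellHeight double-well saddle height, kcal/mol.
#' @param bumpWidth bump support half-width, Angstrom.
#' @param stiffness tether force constant, kcal/(mol A^2).
#' @param reference optional tether reference coordinates (n x 3).
#' @param noiseSd per-frame energy noise SD, kcal/mol.
#' @param noiseSeed seed of the noise stream.
#' @return A [SurrogateSurface-class].
#' @export
surrogateSurface <- function(x1ES = 3.0, x1GE = 1.5, barrierWT = 18.5,
                             offsets = numeric(0),
                             pairDeviations = numeric(0),
                             wellHeight = 2.0, bumpWidth = 0.6,
                             stiffness = 10, reference = NULL,
                             noiseSd = 0, noiseSeed = 1L) {
    if (is.null(reference)) reference <- matrix(numeric(0), ncol = 3L)
    new("SurrogateSurface", x1ES = x1ES, x1GE = x1GE,
        wellHeight = wellHeight, bumpWidth = bumpWidth,
        barrierWT = barrierWT, offsets = offsets,
        pairDeviations = pairDeviations, stiffness = stiffness,
        reference = reference, noiseSd = noiseSd,
        noiseSeed = as.integer(noiseSeed))
}

#' Programmed barrier of a mutant label on a surrogate surface
#'
#' "WT" (or "") maps to the wild-type barrier; a double label "A-B" sums
#' the constituent offsets (exact additivity) plus any programmed pair
#' deviation.
#'
#' @param surf a [SurrogateSurface-class].
#' @param label mutant label.
#' @return barrier in kcal/mol.
#' @export
programmedBarrier <- function(surf, label = "WT") {
    if (is.null(label) || !nzchar(label) || identical(label, "WT"))
        return(surf@barrierWT)
    parts <- strsplit(label, "-", fixed = TRUE)[[1L]]
    miss <- setdiff(parts, names(surf@offsets))
    if (length(miss))
        stop("no programmed offset for mutant(s): ",
             paste(miss, collapse = ", "))
    b <- surf@barrierWT + sum(surf@offsets[parts])
    if (label %in% names(surf@pairDeviations))
        b <- b + surf@pairDeviations[[label]]
    b
}

# 1-D energy along the reaction coordinate: symmetric quartic double-well
# (exact zeros at both basins) + flat-topped compact bump of height
# barrier - wellHeight centered at the midpoint, so the analytic barrier
# equals the programmed value exactly
.surf1d <- function(surf, x, label = "WT") {
    half <- abs(surf@x1ES - surf@x1GE) / 2
    A <- surf@wellHeight / half^4
    quart <- A * ((x - surf@x1ES) * (x - surf@x1GE))^2
    B <- programmedBarrier(surf, label) - surf@wellHeight
    xm <- (surf@x1ES + surf@x1GE) / 2
    u <- (x - xm) / surf@bumpWidth
    q <- ifelse(abs(u) < 1, (1 - u^4)^3, 0)
    quart + B * q
}

.surf1dGrad <- function(surf, x, label = "WT") {
    half <- abs(surf@x1ES - surf@x1GE) / 2
    A <- surf@wellHeight / half^4
    p <- (x - surf@x1ES) * (x - surf@x1GE)
    dquart <- A * 2 * p * (2 * x - surf@x1ES - surf@x1GE)
    B <- programmedBarrier(surf, label) - surf@wellHeight
    xm <- (surf@x1ES + surf@x1GE) / 2
    u <- (x - xm) / surf@bumpWidth
    dq <- ifelse(abs(u) < 1,
                 3 * (1 - u^4)^2 * (-4 * u^3) / surf@bumpWidth, 0)
    dquart + B * dq
}

# total surrogate energy and gradient for a coordinate matrix
.surrogateEG <- function(surf, xyz, ia, ib, label, ref) {
    d <- xyz[ib, ] - xyz[ia, ]
    x1 <- sqrt(sum(d * d))
    e <- .surf1d(surf, x1, label)
    g <- matrix(0, nrow(xyz), 3L)
    de <- .surf1dGrad(surf, x1, label)
    u <- d / x1
    g[ib, ] <- de * u
    g[ia, ] <- -de * u
    teth <- seq_len(nrow(xyz))[-c(ia, ib)]
    dd <- xyz[teth, , drop = FALSE] - ref[teth, , drop = FALSE]
    e <- e + surf@stiffness / 2 * sum(dd * dd)
    g[teth, ] <- g[teth, ] + surf@stiffness * dd
    list(energy = e, grad = g)
}

#' Evaluate the surrogate energy of a structure
#'
#' @param s a [ProteinStructure-class].
#' @param surf a [SurrogateSurface-class].
#' @param rc the [ReactionCoordinate-class].
#' @param label mutant label ("WT" default).
#' @param reference optional tether reference coordinates; defaults to
#'   the surface's reference, or to the structure's own coordinates.
#' @return energy in kcal/mol.
#' @export
surrogateEnergy <- function(s, surf, rc, label = NULL, reference = NULL) {
    label <- .jobLabel(s, label)
    ia <- resolveAtoms(s, rc@atomA)
    ib <- resolveAtoms(s, rc@atomB)
    xyz <- .coords(s)
    ref <- .tetherReference(surf, xyz, reference)
    .surrogateEG(surf, xyz, ia, ib, label, ref)$energy
}

.jobLabel <- function(s, label) {
    if (!is.null(label) && nzchar(label)) return(label)
    if (!is.null(s@meta$label) && nzchar(s@meta$label)) return(s@meta$label)
    "WT"
}

.tetherReference <- function(surf, xyz, reference) {
    if (!is.null(reference)) return(reference)
    if (nrow(surf@reference) == nrow(xyz)) return(surf@reference)
    xyz
}

#' Deterministic local optimization on the surrogate surface
#'
#' Minimizes the surrogate energy over all unconstrained atoms by BFGS
#' descent with the analytic gradient. Constrained atoms (the set K plus
#' any serials in `alsoFix`, e.g. the frozen reaction-coordinate pair of
#' a frame job) are bit-unchanged. Convergence is declared when the
#' largest per-atom gradient norm falls below the configured gnorm.
#'
#' @param s a [ProteinStructure-class].
#' @param k a [ConstraintSet-class].
#' @param surf a [SurrogateSurface-class].
#' @param cfg an [EngineConfig-class].
#' @param rc the [ReactionCoordinate-class].
#' @param label mutant label (default: the structure's own).
#' @param alsoFix additional frozen serials.
#' @param reference tether reference override.
#' @return An [EngineResult-class] with the optimized structure.
#' @export
surrogateOptimize <- function(s, k, surf, cfg = engineConfig(), rc,
                              label = NULL, alsoFix = integer(0),
                              reference = NULL) {
    label <- .jobLabel(s, label)
    ia <- resolveAtoms(s, rc@atomA)
    ib <- resolveAtoms(s, rc@atomB)
    xyz0 <- .coords(s)
    ref <- .tetherReference(surf, xyz0, reference)
    fixedIdx <- which(s@atoms$serial %in% c(k@fixedSerials, alsoFix))
    freeIdx <- setdiff(seq_len(nrow(xyz0)), fixedIdx)
    t0 <- Sys.time()
    e0 <- .surrogateEG(surf, xyz0, ia, ib, label, ref)$energy
    if (!is.finite(e0)) stop("engine error: non-finite surrogate energy")
    if (!length(freeIdx)) {
        res <- new("EngineResult", finalEnergy = e0, finalStructure = s,
                   status = "CONVERGED", reportedCharge = NA_real_,
                   wallTime = as.numeric(difftime(Sys.time(), t0,
                                                  units = "secs")))
        return(res)
    }
    fn <- function(p) {
        xyz <- xyz0
        xyz[freeIdx, ] <- matrix(p, ncol = 3L)
        .surrogateEG(surf, xyz, ia, ib, label, ref)$energy
    }
    gr <- function(p) {
        xyz <- xyz0
        xyz[freeIdx, ] <- matrix(p, ncol = 3L)
        as.vector(.surrogateEG(surf, xyz, ia, ib, label, ref)$grad[freeIdx, ])
    }
    opt <- stats::optim(as.vector(xyz0[freeIdx, , drop = FALSE]), fn, gr,
                        method = "BFGS",
                        control = list(maxit = 1000, reltol = 1e-14))
    xyz <- xyz0
    xyz[freeIdx, ] <- matrix(opt$par, ncol = 3L)
    eg <- .surrogateEG(surf, xyz, ia, ib, label, ref)
    gnorms <- sqrt(rowSums(eg$grad[freeIdx, , drop = FALSE]^2))
    status <- if (max(gnorms) <= cfg@gnorm) "CONVERGED" else "NOT_CONVERGED"
    out <- .setCoords(s, xyz)
    new("EngineResult",
        finalEnergy = if (status == "CONVERGED") eg$energy else NA_real_,
        finalStructure = if (status == "CONVERGED") out else NULL,
        status = status, reportedCharge = NA_real_,
        wallTime = as.numeric(difftime(Sys.time(), t0, units = "secs")))
}
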