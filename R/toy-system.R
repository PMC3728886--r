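#' Specification of a deterministic toy enzyme-substrate system
#'
#' The toy system emulates the geometry the screening pipeline needs --
#' a two-fragment substrate (a sugar analog carrying the anomeric carbon
#' C1 and a leaving-group fragment with a phenolic oxygen O1), a
#' nucleophile carboxylate analog providing O-epsilon, and a shell of
#' mutable residues (full N/CA/C/O/CB backbones) at controlled radii so
#' that the 4 A active-site rule selects exactly `nActive` of them (plus
#' the nucleophile itself, which is always in contact with the
#' substrate). Chemical realism is deliberately sacrificed for verifiable
#' geometry. Positions listed in `clashPositions` are caged by blocker
#' pseudo-atoms placed on the chi1 circle of the residue, which makes any
#' rebuilt side chain beyond C-beta unbuildable there by construction.
#'
#' @param nResidues number of shell residues.
#' @param nActive shell residues placed inside the 4 A rule
#'   (`<= nResidues`).
#' @param seed integer; fixes all coordinates.
#' @param clashPositions integer indices (1-based, into the shell) of
#'   residues to cage.
#' @param x1ES,x1GE endpoint reaction-coordinate values, Angstrom.
#' @param wtBarrier programmed wild-type barrier, kcal/mol.
#' @param mutantOffsets named numeric of per-mutant barrier offsets
#'   (relative to WT) carried into the ground truth.
#' @param pairDeviations named numeric of programmed non-additivities.
#' @return a ToySystemSpec list.
#' @export
toySystemSpec <- function(nResidues = 8L, nActive = 3L, seed = 7L,
                          clashPositions = integer(0), x1ES = 3.0,
                          x1GE = 1.5, wtBarrier = 18.5,
                          mutantOffsets = numeric(0),
                          pairDeviations = numeric(0)) {
    stopifnot(nActive <= nResidues, nResidues >= 1L,
              all(clashPositions %in% seq_len(nResidues)))
    structure(list(nResidues = as.integer(nResidues),
                   nActive = as.integer(nActive), seed = as.integer(seed),
                   clashPositions = as.integer(clashPositions),
                   x1ES = x1ES, x1GE = x1GE, wtBarrier = wtBarrier,
                   mutantOffsets = mutantOffsets,
                   pairDeviations = pairDeviations),
              class = "ToySystemSpec")
}

# n unit directions spread over the band |x| < 0.45, avoiding the +-x
# reaction axis where nucleophile and leaving group sit
.shellDirections <- function(n) {
    i <- seq_len(n)
    dx <- if (n == 1L) 0 else -0.45 + 0.9 * (i - 0.5) / n
    r <- sqrt(1 - dx^2)
    phi <- i * 2.399963229728653
    cbind(dx, r * cos(phi), r * sin(phi), deparse.level = 0)
}

# radius R such that min distance from R*dir to the target points is m
.radiusFor <- function(dir, pts, m) {
    f <- function(R) min(sqrt(colSums((t(pts) - R * dir)^2))) - m
    stats::uniroot(f, c(0.5, 60))$root
}

.MUTABLE_CYCLE <- c("ALA", "SER", "VAL", "LEU", "THR", "ASN", "GLN",
                    "ILE", "MET", "PHE")

#' Generate a toy ES/GE endpoint pair with ground truth
#'
#' Returns correspondence-matched ES and GE structures differing along
#' the reaction coordinate (nucleophile analog and leaving-group
#' fragment shifted; everything else identical), the reaction coordinate,
#' and a ground-truth record for surface construction and assertions.
#' Generation is a pure function of the spec (including its seed).
#'
#' @param spec a [toySystemSpec()].
#' @return list with elements `es`, `ge` ([ProteinStructure-class]),
#'   `rc` ([ReactionCoordinate-class]) and `groundTruth` (list: wtBarrier,
#'   offsets, pairDeviations, activeKeys, mutablePositions, clashResnos,
#'   hetero charges, x1ES, x1GE).
#' @export
makeToySystem <- function(spec) {
    stopifnot(inherits(spec, "ToySystemSpec"))
    x1GE <- spec$x1GE
    rows <- list()
    addAtom <- function(name, resname, chain, resno, xyz, sub = FALSE) {
        rows[[length(rows) + 1L]] <<- data.frame(
            serial = length(rows) + 1L, name = name, altLoc = "",
            resname = resname, chain = chain, resno = as.integer(resno),
            insert = "", x = xyz[1L], y = xyz[2L], z = xyz[3L],
            element = .elementFromName(name), isSubstrate = sub,
            stringsAsFactors = FALSE)
    }
    ## the substrate is the moving partner (the protein, including the
    ## nucleophile analog, is identical in both endpoints): in the GE the
    ## anomeric carbon C1 sits x1GE from the static nucleophile oxygen
    ## OE1 at the origin, in the ES the sugar fragment is retracted along
    ## -x to x1ES
    addAtom("C1", "XYL", "X", 1L, c(-x1GE, 0, 0), TRUE)
    addAtom("O5", "XYL", "X", 1L, c(-x1GE - 0.55, 1.25, 0.15), TRUE)
    addAtom("C2", "XYL", "X", 1L, c(-x1GE - 0.70, -1.20, 0.30), TRUE)
    addAtom("O2", "XYL", "X", 1L, c(-x1GE - 1.85, -1.60, 0.45), TRUE)
    ## leaving-group fragment, unbound in the GE state
    addAtom("O1", "ONP", "X", 2L, c(-x1GE - 2.50, 0.05, 0.00), TRUE)
    addAtom("C7", "ONP", "X", 2L, c(-x1GE - 3.85, 0.30, 0.05), TRUE)
    addAtom("O7", "ONP", "X", 2L, c(-x1GE - 4.55, 1.35, 0.20), TRUE)
    ## nucleophile carboxylate analog, static on the +x side
    addAtom("OE1", "GLU", "A", 10L, c(0, 0, 0))
    addAtom("CD", "GLU", "A", 10L, c(1.25, 0.35, 0.00))
    addAtom("OE2", "GLU", "A", 10L, c(1.90, 1.35, 0.10))
    addAtom("CG", "GLU", "A", 10L, c(2.10, -0.85, -0.10))
    subPts <- do.call(rbind, lapply(rows[1:7], function(r)
        c(r$x, r$y, r$z)))
    ## mutable shell residues
    dirs <- .shellDirections(spec$nResidues)
    jit <- .withSeed(spec$seed,
                     matrix(stats::runif(spec$nResidues * 8L, -0.03, 0.03),
                            spec$nResidues))
    mutable <- list()
    cbPos <- vector("list", spec$nResidues)
    caPos <- vector("list", spec$nResidues)
    for (i in seq_len(spec$nResidues)) {
        d <- dirs[i, ]
        inner <- i <= spec$nActive
        targetMin <- if (inner) 3.5 else 6.0 + 0.5 * (i - spec$nActive)
        RN <- .radiusFor(d, subPts, targetMin)
        zref <- if (abs(d[3L]) < 0.9) c(0, 0, 1) else c(0, 1, 0)
        u <- .unit(.cross3(d, zref))
        v <- .cross3(d, u)
        rn <- .MUTABLE_CYCLE[(i - 1L) %% length(.MUTABLE_CYCLE) + 1L]
        resno <- 10L + i
        N <- RN * d
        # ideal local backbone: CA-N 1.45 A, N-CA-C 111 deg, C=O 1.23 A,
        # C-beta tetrahedral from N/CA/C
        e1 <- .unit(d + (0.55 + jit[i, 1L]) * u + jit[i, 2L] * v)
        w <- .unit(v - sum(v * e1) * e1 + jit[i, 3L] * u)
        CA <- N + 1.45 * e1
        C <- CA + 1.52 * (cos(69 * pi / 180) * e1 + sin(69 * pi / 180) * w)
        O <- C + 1.23 * (cos(55 * pi / 180) * e1 + sin(55 * pi / 180) * w)
        CB <- .placeCB(N, CA, C)
        addAtom("N", rn, "A", resno, N)
        addAtom("CA", rn, "A", resno, CA)
        addAtom("C", rn, "A", resno, C)
        addAtom("O", rn, "A", resno, O)
        addAtom("CB", rn, "A", resno, CB)
        mutable[[i]] <- data.frame(chain = "A", resno = resno, resname = rn,
                                   stringsAsFactors = FALSE)
        cbPos[[i]] <- CB; caPos[[i]] <- CA
    }
    ## blocker cages on the chi1 circle of programmed clash positions
    for (p in spec$clashPositions) {
        res <- mutable[[p]]
        nPos <- dirs[p, ] * .radiusFor(dirs[p, ], subPts,
                                       if (p <= spec$nActive) 3.5
                                       else 6.0 + 0.5 * (p - spec$nActive))
        for (j in seq_len(24L)) {
            chi <- -180 + (j - 1L) * 15
            pos <- .nerf(nPos, caPos[[p]], cbPos[[p]], 1.52, 114, chi)
            addAtom(sprintf("B%02d", j), "BLK", "Z", 900L + p, pos)
        }
    }
    atoms <- do.call(rbind, rows)
    serialOf <- function(resname, name)
        atoms$serial[atoms$resname == resname & atoms$name == name]
    links <- rbind(c(serialOf("XYL", "C1"), serialOf("XYL", "O5")),
                   c(serialOf("XYL", "C1"), serialOf("XYL", "C2")),
                   c(serialOf("XYL", "C2"), serialOf("XYL", "O2")),
                   c(serialOf("ONP", "O1"), serialOf("ONP", "C7")),
                   c(serialOf("ONP", "C7"), serialOf("ONP", "O7")),
                   c(serialOf("GLU", "OE1"), serialOf("XYL", "C1")),
                   c(serialOf("GLU", "OE1"), serialOf("GLU", "CD")),
                   c(serialOf("GLU", "CD"), serialOf("GLU", "OE2")),
                   c(serialOf("GLU", "CD"), serialOf("GLU", "CG")))
    ge <- proteinStructure(atoms, links = links, stateTag = "GE",
                           meta = list(label = "WT"))
    rc <- reactionCoordinate("A:10:OE1", "XYL:C1")
    ## ES endpoint: sugar fragment retracted along -x, leaving group
    ## re-bonded to C1
    esPre <- ge
    xyl <- which(esPre@atoms$resname == "XYL")
    esPre@atoms$x[xyl] <- esPre@atoms$x[xyl] - (spec$x1ES - spec$x1GE)
    es <- deriveESfromGE(esPre, rc)
    for (endpoint in list(es, ge)) {
        cc <- closeContactCheck(endpoint, 0.7)
        if (!cc$pass)
            stop("generation error: infeasible placement (close contacts ",
                 "in the ", endpoint@stateTag, " endpoint)")
    }
    gt <- list(wtBarrier = spec$wtBarrier, offsets = spec$mutantOffsets,
               pairDeviations = spec$pairDeviations,
               activeKeys = c("A:10",
                              paste0("A:", 10L + seq_len(spec$nActive))),
               mutablePositions = do.call(rbind, mutable),
               clashResnos = 10L + spec$clashPositions,
               hetero = c(XYL = 0, ONP = 0, BLK = 0),
               x1ES = spec$x1ES, x1GE = spec$x1GE)
    list(es = es, ge = ge, rc = rc, groundTruth = gt)
}

#' Build a surrogate surface from a ground-truth record
#'
#' With `noiseSd = 0`, the analytic x1 barrier of the surface equals the
#' programmed ground truth exactly for every mutant label; with noise,
#' converged frame energies are perturbed i.i.d. with the given SD under
#' the given seed (noise is applied to energies, never to coordinates,
#' which keeps the barrier-extraction statistics interpretable).
#'
#' @param gt ground-truth list from [makeToySystem()] (fields wtBarrier,
#'   offsets, pairDeviations, x1ES, x1GE).
#' @param noiseSd per-frame energy noise SD, kcal/mol (>= 0).
#' @param seed seed of the noise stream.
#' @return A [SurrogateSurface-class].
#' @export
makeSurface <- function(gt, noiseSd = 0, seed = 1L) {
    stopifnot(noiseSd >= 0)
    surrogateSurface(x1ES = gt$x1ES, x1GE = gt$x1GE,
                     barrierWT = gt$wtBarrier, offsets = gt$offsets,
                     pairDeviations = gt$pairDeviations,
                     noiseSd = noiseSd, noiseSeed = seed)
}
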