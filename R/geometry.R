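#' Euclidean distance between two atoms
#'
#' @param s a [ProteinStructure-class].
#' @param a,b atom selectors (see [resolveAtoms()]); must each resolve to
#'   exactly one atom.
#' @return distance in Angstrom.
#' @examples
#' ## 3-4-5 triangle
#' s <- proteinStructure(data.frame(
#'     name = c("C1", "C2"), resname = "LIG", chain = "S", resno = 1,
#'     x = c(0, 3), y = c(0, 4), z = 0, element = "C", isSubstrate = TRUE))
#' atomDistance(s, "LIG:C1", "LIG:C2")  # 5
#' @export
atomDistance <- function(s, a, b) {
    ia <- resolveAtoms(s, a)
    ib <- resolveAtoms(s, b)
    xyz <- .coords(s)
    sqrt(sum((xyz[ia, ] - xyz[ib, ])^2))
}

#' Measure the current reaction-coordinate value
#' @param s a [ProteinStructure-class].
#' @param rc a [ReactionCoordinate-class].
#' @return x1 in Angstrom.
#' @export
measureX1 <- function(s, rc) atomDistance(s, rc@atomA, rc@atomB)

#' Protein residues with any atom within a radius of a center atom set
#'
#' A residue is included iff the minimum distance between its atoms and
#' the center atoms is at most `r`. Substrate residues are never part of
#' the result.
#'
#' @param s a [ProteinStructure-class].
#' @param center atom selectors or serials defining the center set
#'   (non-empty).
#' @param r radius in Angstrom (> 0, or Inf).
#' @return data.frame with columns chain, resno, insert, resname, minDist,
#'   ordered by (chain, resno, insert).
#' @export
residuesWithin <- function(s, center, r) {
    if (!length(center)) stop("center atom set must be non-empty")
    if (r < 0) stop("radius must be non-negative")
    idx <- resolveAtoms(s, center, unique_ = FALSE)
    a <- s@atoms
    xyz <- .coords(s)
    cxyz <- xyz[idx, , drop = FALSE]
    rkey <- .residueKeys(a)
    sub <- tapply(a$isSubstrate, rkey, any)
    # min distance from each atom to the center set
    d2 <- vapply(seq_len(nrow(xyz)), function(i)
        min(colSums((t(cxyz) - xyz[i, ])^2)), numeric(1))
    minD <- tapply(sqrt(d2), rkey, min)
    first <- !duplicated(rkey)
    res <- data.frame(chain = a$chain[first], resno = a$resno[first],
                      insert = a$insert[first], resname = a$resname[first],
                      stringsAsFactors = FALSE)
    key <- rkey[first]
    res$minDist <- as.numeric(minD[key])
    res <- res[!as.logical(sub[key]) & res$minDist <= r, , drop = FALSE]
    res <- res[order(res$chain, res$resno, res$insert), , drop = FALSE]
    rownames(res) <- NULL
    res
}

#' Total formal charge under a protonation convention
#'
#' Sums per-residue contributions from the rules, zwitterionic terminus
#' contributions per protein chain, and declared hetero-group charges.
#' Residues covered neither by the amino-acid rules nor by the declared
#' hetero charges raise an error.
#'
#' @param s a [ProteinStructure-class].
#' @param rules a [ProtonationRules-class]
#'   (default [defaultProtonationRules()]).
#' @return integer total charge.
#' @export
formalCharge <- function(s, rules = defaultProtonationRules()) {
    a <- s@atoms
    rkey <- .residueKeys(a)
    first <- !duplicated(rkey)
    resname <- a$resname[first]
    chain <- a$chain[first]
    isSub <- as.logical(tapply(a$isSubstrate, rkey, any)[rkey[first]])
    total <- 0
    protChains <- character(0)
    for (i in seq_along(resname)) {
        rn <- resname[i]
        if (!isSub[i] && rn %in% names(rules@charges)) {
            total <- total + rules@charges[[rn]]
            protChains <- c(protChains, chain[i])
        } else if (rn %in% names(rules@hetero)) {
            total <- total + rules@hetero[[rn]]
        } else {
            stop("residue '", rn, "' not covered by protonation rules ",
                 "and no hetero charge declared")
        }
    }
    if (rules@zwitterionic) {
        # NH3+ amino and COO- carboxylate terminus on every protein chain
        for (ch in unique(protChains)) total <- total + 1 - 1
    }
    as.integer(round(total))
}
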