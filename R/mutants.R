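#' Detect the active site around the substrate
#'
#' The active site is every protein residue with at least one atom within
#' `r` Angstrom of any substrate-flagged atom. Catalytic residues are
#' included here; their exclusion happens at enumeration time.
#'
#' @param s a [ProteinStructure-class] with substrate-flagged atoms.
#' @param r cutoff radius, Angstrom (default 4.0).
#' @return data.frame of residues (chain, resno, insert, resname, minDist)
#'   sorted by sequence number.
#' @export
detectActiveSite <- function(s, r = 4.0) {
    subSerials <- s@atoms$serial[s@atoms$isSubstrate]
    if (!length(subSerials))
        stop("structure has no substrate-flagged atoms")
    if (r <= 0)
        return(residuesWithin(s, subSerials, 0)[0, , drop = FALSE])
    res <- residuesWithin(s, subSerials, r)
    res[order(res$resno, res$chain, res$insert), , drop = FALSE]
}

#' Enumerate all single mutants of a position list
#'
#' Every non-excluded position is mutated to each of the 19 other
#' canonical amino acids, giving `19 * (positions - exclusions)` specs in
#' deterministic order (position, then alphabetical target). Positions
#' whose residue name is not a canonical amino acid are skipped with a
#' warning.
#'
#' @param positions data.frame with columns chain, resno, resname (as
#'   returned by [detectActiveSite()]).
#' @param exclusions character vector of `"chain:resno"` keys for
#'   positions that must not be mutated (e.g. the catalytic residues).
#'   An exclusion that is not among the positions triggers a warning, not
#'   an error.
#' @return data.frame with columns label, chain, seqNumber, wtAa,
#'   targetAa, one row per [MutationSpec-class].
#' @export
enumerateSingleMutants <- function(positions, exclusions = character(0)) {
    if (!nrow(positions)) stop("positions must be non-empty")
    keys <- paste(positions$chain, positions$resno, sep = ":")
    unknown <- setdiff(exclusions, keys)
    if (length(unknown))
        warning("exclusions not among positions: ",
                paste(unknown, collapse = ", "))
    keep <- !(keys %in% exclusions)
    noncanon <- keep & !(positions$resname %in% .AA3)
    if (any(noncanon)) {
        warning("skipping non-canonical position(s): ",
                paste(keys[noncanon], collapse = ", "))
        keep <- keep & !noncanon
    }
    pos <- positions[keep, , drop = FALSE]
    pos <- pos[order(pos$chain, pos$resno), , drop = FALSE]
    out <- do.call(rbind, lapply(seq_len(nrow(pos)), function(i) {
        wt1 <- .AA1[[pos$resname[i]]]
        targets <- sort(setdiff(names(.AA3), wt1))
        data.frame(label = paste0(wt1, pos$resno[i], targets),
                   chain = pos$chain[i], seqNumber = pos$resno[i],
                   wtAa = wt1, targetAa = targets,
                   stringsAsFactors = FALSE)
    }))
    if (is.null(out))
        out <- data.frame(label = character(0), chain = character(0),
                          seqNumber = integer(0), wtAa = character(0),
                          targetAa = character(0))
    rownames(out) <- NULL
    out
}

#' Convert a spec table to a list of MutationSpec objects
#' @param tab data.frame as returned by [enumerateSingleMutants()].
#' @return list of [MutationSpec-class] objects.
#' @export
mutationSpecs <- function(tab) {
    lapply(seq_len(nrow(tab)), function(i)
        mutationSpec(tab$chain[i], tab$seqNumber[i], tab$wtAa[i],
                     tab$targetAa[i]))
}

#' Canonical label of a double mutant
#' @param d a [DoubleSpec-class].
#' @return label like "Q7W-Q127W".
#' @export
doubleLabel <- function(d) paste(d@first@label, d@second@label, sep = "-")

#' Best (lowest-barrier) single mutant per position
#'
#' @param records data.frame with at least label, chain, seqNumber, wtAa,
#'   targetAa and barrier columns; each barrier must be finite. Ties at a
#'   position are broken alphabetically by target amino acid.
#' @return data.frame of one winning spec row per position, ordered by
#'   (chain, seqNumber).
#' @export
bestPerPosition <- function(records) {
    if (!nrow(records)) return(records)
    if (!all(is.finite(records$barrier)))
        stop("all records must carry a finite barrier")
    records <- records[order(records$chain, records$seqNumber,
                             records$barrier, records$targetAa), ,
                       drop = FALSE]
    key <- paste(records$chain, records$seqNumber, sep = ":")
    out <- records[!duplicated(key), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Enumerate candidate double mutants from per-position winners
#'
#' All C(P, 2) unordered pairs of distinct positions, in canonical order.
#'
#' @param best data.frame of single-mutant specs, at most one per
#'   position (a duplicate position is an error).
#' @return list of [DoubleSpec-class] objects.
#' @export
enumerateDoubleMutants <- function(best) {
    key <- paste(best$chain, best$seqNumber, sep = ":")
    if (anyDuplicated(key))
        stop("input contains more than one spec for a position")
    if (nrow(best) < 2L) return(list())
    best <- best[order(best$chain, best$seqNumber), , drop = FALSE]
    specs <- mutationSpecs(best)
    out <- list()
    for (i in seq_len(length(specs) - 1L))
        for (j in seq((i + 1L), length(specs)))
            out[[length(out) + 1L]] <- doubleSpec(specs[[i]], specs[[j]])
    out
}
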