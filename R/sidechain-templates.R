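## Idealized side-chain internal-coordinate templates.
##
## Every canonical amino acid is described as a list of heavy atoms beyond
## C-beta, each placed by natural-extension (NeRF) from three previously
## placed atoms: (parent = bonded atom, angleRef, torsRef). Torsions are
## either a fixed value in degrees or a chi reference of the form "chi2" /
## "chi1+120" / "chi2+180"; bond lengths in Angstrom, angles in degrees.
## Values are generic ideal-geometry numbers (C-C 1.52, aromatic 1.39,
## C-O 1.43, C=O 1.25, C-N 1.47/1.33, C-S 1.81); side-chain construction
## resolves the chi angles by exhaustive grid search, so only topology and
## rough geometry matter here, not rotamer statistics.

.tplRow <- function(name, parent, angleRef, torsRef, bond, angle, torsion) {
    data.frame(name = name, parent = parent, angleRef = angleRef,
               torsRef = torsRef, bond = bond, angle = angle,
               torsion = as.character(torsion), stringsAsFactors = FALSE)
}

.SIDECHAIN_TEMPLATES <- local({
    r <- .tplRow
    list(
    GLY = r(character(0), character(0), character(0), character(0),
            numeric(0), numeric(0), character(0)),
    ALA = r(character(0), character(0), character(0), character(0),
            numeric(0), numeric(0), character(0)),
    SER = r("OG", "CB", "CA", "N", 1.42, 110.5, "chi1"),
    CYS = r("SG", "CB", "CA", "N", 1.81, 114.0, "chi1"),
    THR = rbind(r("OG1", "CB", "CA", "N", 1.43, 109.5, "chi1"),
                r("CG2", "CB", "CA", "N", 1.52, 110.5, "chi1-120")),
    VAL = rbind(r("CG1", "CB", "CA", "N", 1.52, 110.5, "chi1"),
                r("CG2", "CB", "CA", "N", 1.52, 110.5, "chi1+120")),
    LEU = rbind(r("CG",  "CB", "CA", "N", 1.53, 116.3, "chi1"),
                r("CD1", "CG", "CB", "CA", 1.52, 110.5, "chi2"),
                r("CD2", "CG", "CB", "CA", 1.52, 110.5, "chi2+120")),
    ILE = rbind(r("CG1", "CB", "CA", "N", 1.53, 110.4, "chi1"),
                r("CG2", "CB", "CA", "N", 1.52, 110.5, "chi1-120"),
                r("CD1", "CG1", "CB", "CA", 1.52, 113.0, "chi2")),
    MET = rbind(r("CG", "CB", "CA", "N", 1.52, 114.0, "chi1"),
                r("SD", "CG", "CB", "CA", 1.81, 112.7, "chi2"),
                r("CE", "SD", "CG", "CB", 1.79, 100.6, "chi3")),
    PRO = rbind(r("CG", "CB", "CA", "N", 1.50, 104.0, "30"),
                r("CD", "CG", "CB", "CA", 1.51, 105.0, "-35")),
    PHE = rbind(r("CG",  "CB", "CA", "N",   1.50, 113.8, "chi1"),
                r("CD1", "CG", "CB", "CA",  1.39, 120.0, "chi2"),
                r("CD2", "CG", "CB", "CA",  1.39, 120.0, "chi2+180"),
                r("CE1", "CD1", "CG", "CB", 1.39, 120.0, "180"),
                r("CE2", "CD2", "CG", "CB", 1.39, 120.0, "180"),
                r("CZ",  "CE1", "CD1", "CG", 1.39, 120.0, "0")),
    TYR = rbind(r("CG",  "CB", "CA", "N",   1.50, 113.8, "chi1"),
                r("CD1", "CG", "CB", "CA",  1.39, 120.0, "chi2"),
                r("CD2", "CG", "CB", "CA",  1.39, 120.0, "chi2+180"),
                r("CE1", "CD1", "CG", "CB", 1.39, 120.0, "180"),
                r("CE2", "CD2", "CG", "CB", 1.39, 120.0, "180"),
                r("CZ",  "CE1", "CD1", "CG", 1.39, 120.0, "0"),
                r("OH",  "CZ",  "CE1", "CD1", 1.38, 120.0, "180")),
    TRP = rbind(r("CG",  "CB", "CA", "N",   1.50, 113.8, "chi1"),
                r("CD1", "CG", "CB", "CA",  1.37, 127.0, "chi2"),
                r("CD2", "CG", "CB", "CA",  1.43, 126.6, "chi2+180"),
                r("NE1", "CD1", "CG", "CB", 1.38, 110.2, "180"),
                r("CE2", "CD2", "CG", "CB", 1.41, 107.2, "180"),
                r("CE3", "CD2", "CG", "CB", 1.40, 133.9, "0"),
                r("CZ2", "CE2", "CD2", "CG", 1.40, 122.4, "180"),
                r("CZ3", "CE3", "CD2", "CG", 1.39, 118.8, "180"),
                r("CH2", "CZ2", "CE2", "CD2", 1.37, 117.5, "180")),
    ASP = rbind(r("CG",  "CB", "CA", "N",  1.52, 113.0, "chi1"),
                r("OD1", "CG", "CB", "CA", 1.25, 118.5, "chi2"),
                r("OD2", "CG", "CB", "CA", 1.25, 118.5, "chi2+180")),
    ASN = rbind(r("CG",  "CB", "CA", "N",  1.52, 113.0, "chi1"),
                r("OD1", "CG", "CB", "CA", 1.23, 120.8, "chi2"),
                r("ND2", "CG", "CB", "CA", 1.33, 116.5, "chi2+180")),
    GLU = rbind(r("CG",  "CB", "CA", "N",  1.52, 114.0, "chi1"),
                r("CD",  "CG", "CB", "CA", 1.52, 113.0, "chi2"),
                r("OE1", "CD", "CG", "CB", 1.25, 118.5, "chi3"),
                r("OE2", "CD", "CG", "CB", 1.25, 118.5, "chi3+180")),
    GLN = rbind(r("CG",  "CB", "CA", "N",  1.52, 114.0, "chi1"),
                r("CD",  "CG", "CB", "CA", 1.52, 113.0, "chi2"),
                r("OE1", "CD", "CG", "CB", 1.23, 120.8, "chi3"),
                r("NE2", "CD", "CG", "CB", 1.33, 116.5, "chi3+180")),
    LYS = rbind(r("CG", "CB", "CA", "N",  1.52, 114.0, "chi1"),
                r("CD", "CG", "CB", "CA", 1.52, 111.3, "chi2"),
                r("CE", "CD", "CG", "CB", 1.52, 111.3, "chi3"),
                r("NZ", "CE", "CD", "CG", 1.47, 110.9, "chi4")),
    ARG = rbind(r("CG",  "CB", "CA", "N",  1.52, 114.0, "chi1"),
                r("CD",  "CG", "CB", "CA", 1.52, 111.3, "chi2"),
                r("NE",  "CD", "CG", "CB", 1.46, 112.0, "chi3"),
                r("CZ",  "NE", "CD", "CG", 1.33, 124.2, "chi4"),
                r("NH1", "CZ", "NE", "CD", 1.33, 120.0, "0"),
                r("NH2", "CZ", "NE", "CD", 1.33, 120.0, "180")),
    HIS = rbind(r("CG",  "CB", "CA", "N",   1.50, 113.8, "chi1"),
                r("ND1", "CG", "CB", "CA",  1.38, 122.7, "chi2"),
                r("CD2", "CG", "CB", "CA",  1.36, 131.0, "chi2+180"),
                r("CE1", "ND1", "CG", "CB", 1.32, 109.0, "180"),
                r("NE2", "CD2", "CG", "CB", 1.37, 107.0, "180"))
    )
})

#' Side-chain template for a canonical amino acid
#'
#' @param aa one- or three-letter amino-acid code.
#' @return data.frame of NeRF placement rows (name, parent, angleRef,
#'   torsRef, bond, angle, torsion); zero rows for glycine and alanine
#'   (glycine additionally has no C-beta).
#' @export
sideChainTemplate <- function(aa) {
    aa3 <- if (nchar(aa) == 1L) .AA3[[aa]] else toupper(aa)
    tpl <- .SIDECHAIN_TEMPLATES[[aa3]]
    if (is.null(tpl)) stop("no side-chain template for '", aa, "'")
    tpl
}

# number of searchable chi dihedrals in a template
.nChi <- function(tpl) {
    m <- regmatches(tpl$torsion, regexpr("chi[1-4]", tpl$torsion))
    if (!length(m)) 0L else max(as.integer(substring(m, 4L)))
}

# stage of each template row: the highest chi index it depends on
# (through its own torsion or through any ancestor row)
.tplStages <- function(tpl) {
    stage <- integer(nrow(tpl))
    for (i in seq_len(nrow(tpl))) {
        own <- regmatches(tpl$torsion[i], regexpr("chi[1-4]", tpl$torsion[i]))
        own <- if (length(own)) as.integer(substring(own, 4L)) else 0L
        anc <- match(c(tpl$parent[i], tpl$angleRef[i], tpl$torsRef[i]),
                     tpl$name)
        anc <- anc[!is.na(anc)]
        stage[i] <- max(own, if (length(anc)) stage[anc] else 0L)
    }
    stage
}

# hard-sphere van der Waals radii (Angstrom) by element
.VDW_RADII <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80,
                P = 1.80, F = 1.47, CL = 1.75, BR = 1.85)

.vdwRadius <- function(element) {
    r <- .VDW_RADII[toupper(element)]
    ifelse(is.na(r), 1.70, r)
}
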