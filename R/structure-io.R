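#' Read a PDB file into a ProteinStructure
#'
#' ATOM/HETATM records are parsed with bio3d; HETATM groups are flagged as
#' substrate atoms and CONECT records populate the covalent-link registry.
#' Alternate locations: altLoc 'A' or blank is kept, all others dropped
#' with a warning.
#'
#' @param path PDB file path.
#' @param stateTag state tag to assign ("ES", "GE" or "frame").
#' @return A [ProteinStructure-class].
#' @examples
#' pdb <- system.file("extdata", "toy_ge_synthetic.pdb",
#'                    package = "BarrierScreen")
#' if (nzchar(pdb)) readPDB(pdb, stateTag = "GE")
#' @export
readPDB <- function(path, stateTag = "frame") {
    if (!file.exists(path)) stop("cannot read PDB file: ", path)
    p <- suppressWarnings(bio3d::read.pdb(path, rm.alt = FALSE,
                                          verbose = FALSE))
    at <- p$atom
    if (is.null(at) || nrow(at) == 0L) stop("no atoms in PDB file: ", path)
    alt <- ifelse(is.na(at$alt), "", at$alt)
    keep <- alt %in% c("", "A")
    if (!all(keep)) {
        warning(sum(!keep), " alternate-location atoms dropped (kept 'A')")
        at <- at[keep, , drop = FALSE]
        alt <- alt[keep]
    }
    element <- ifelse(is.na(at$elesy) | !nzchar(trimws(at$elesy)),
                      vapply(at$elety, .elementFromName, character(1)),
                      trimws(at$elesy))
    atoms <- data.frame(serial = as.integer(at$eleno),
                        name = at$elety,
                        altLoc = alt,
                        resname = at$resid,
                        chain = ifelse(is.na(at$chain), "", at$chain),
                        resno = as.integer(at$resno),
                        insert = ifelse(is.na(at$insert), "", at$insert),
                        x = at$x, y = at$y, z = at$z,
                        element = element,
                        isSubstrate = at$type == "HETATM",
                        stringsAsFactors = FALSE)
    proteinStructure(atoms, links = .readConect(path, atoms$serial),
                     stateTag = stateTag)
}

# CONECT records: columns 7-31 hold up to one origin + four bonded serials
.readConect <- function(path, knownSerials) {
    lines <- grep("^CONECT", readLines(path, warn = FALSE), value = TRUE)
    if (!length(lines)) return(matrix(integer(0), ncol = 2))
    pairs <- do.call(rbind, lapply(lines, function(l) {
        f <- suppressWarnings(as.integer(
            sapply(seq(7, 27, by = 5), function(i) substr(l, i, i + 4))))
        f <- f[!is.na(f)]
        if (length(f) < 2L) return(NULL)
        cbind(f[1L], f[-1L])
    }))
    if (is.null(pairs)) return(matrix(integer(0), ncol = 2))
    pairs <- t(apply(pairs, 1L, sort))
    pairs <- unique(pairs)
    bad <- matrix(!(pairs %in% knownSerials), ncol = 2L)
    if (any(bad)) {
        warning("CONECT records referencing unknown serials dropped")
        pairs <- pairs[!(bad[, 1L] | bad[, 2L]), , drop = FALSE]
    }
    storage.mode(pairs) <- "integer"
    pairs
}

#' Write a ProteinStructure to a PDB file
#'
#' Coordinates are written with the standard %8.3f fields; the link
#' registry is emitted as CONECT records. `readPDB(writePDB(s))`
#' reproduces atom names, residue numbering and coordinates to 3 decimals.
#'
#' @param s a [ProteinStructure-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writePDB <- function(s, path) {
    stopifnot(is(s, "ProteinStructure"))
    a <- s@atoms
    ok <- tryCatch({
        bio3d::write.pdb(file = path,
                         xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                         type = ifelse(a$isSubstrate, "HETATM", "ATOM"),
                         eleno = a$serial, elety = a$name,
                         resid = a$resname, chain = a$chain,
                         resno = a$resno, insert = ifelse(nzchar(a$insert),
                                                          a$insert, NA),
                         alt = ifelse(nzchar(a$altLoc), a$altLoc, NA),
                         o = rep(1, nrow(a)), b = rep(0, nrow(a)),
                         elesy = a$element)
        TRUE
    }, error = function(e) {
        stop("cannot write PDB file '", path, "': ", conditionMessage(e))
    })
    if (nrow(s@links)) {
        lines <- readLines(path, warn = FALSE)
        conect <- sprintf("CONECT%5d%5d", s@links[, 1L], s@links[, 2L])
        endAt <- grep("^END", lines)
        if (length(endAt))
            lines <- append(lines, conect, after = min(endAt) - 1L)
        else lines <- c(lines, conect)
        writeLines(lines, path)
    }
    invisible(path)
}

#' Resolve atom selectors to row indices
#'
#' Selectors are either integer atom serial numbers, or strings of the
#' form `"chain:resno:name"` (protein atoms) or `"resname:name"` (hetero /
#' substrate atoms, addressed by residue name).
#'
#' @param s a [ProteinStructure-class].
#' @param sel selector vector.
#' @param unique_ require each selector to match exactly one atom.
#' @return integer row indices into `atoms(s)`.
#' @export
resolveAtoms <- function(s, sel, unique_ = TRUE) {
    a <- s@atoms
    if (is.numeric(sel)) {
        idx <- match(as.integer(sel), a$serial)
        if (anyNA(idx)) stop("unknown atom serial(s): ",
                             paste(sel[is.na(idx)], collapse = ", "))
        return(idx)
    }
    out <- integer(0)
    for (one in sel) {
        parts <- strsplit(one, ":", fixed = TRUE)[[1L]]
        hit <- if (length(parts) == 3L) {
            which(a$chain == parts[1L] & a$resno == as.integer(parts[2L]) &
                  a$name == parts[3L])
        } else if (length(parts) == 2L) {
            which(a$resname == parts[1L] & a$name == parts[2L])
        } else stop("malformed atom selector: '", one, "'")
        if (!length(hit)) stop("selector '", one, "' matches no atom")
        if (unique_ && length(hit) > 1L)
            stop("selector '", one, "' is ambiguous (", length(hit),
                 " matches)")
        out <- c(out, hit)
    }
    out
}

# per-atom identity keys used for ES/GE correspondence matching
.atomKeys <- function(s) {
    a <- s@atoms
    paste(a$chain, a$resno, a$insert, a$name, sep = ":")
}

# per-residue keys, in atom order
.residueKeys <- function(a) paste(a$chain, a$resno, a$insert, sep = ":")

.coords <- function(s) as.matrix(s@atoms[, c("x", "y", "z")])

.setCoords <- function(s, xyz) {
    s@atoms$x <- xyz[, 1L]; s@atoms$y <- xyz[, 2L]; s@atoms$z <- xyz[, 3L]
    s
}

#' Serialize a frame set as multi-model PDB plus JSON sidecar
#'
#' Frames are written as MODEL/ENDMDL blocks; the sidecar records per-frame
#' index, x1 target and the frozen-atom serials.
#'
#' @param fs a [FrameSet-class].
#' @param pdbPath multi-model PDB output path.
#' @param jsonPath sidecar path (default: `pdbPath` with .json).
#' @return `pdbPath`, invisibly.
#' @export
writeFrameSet <- function(fs, pdbPath,
                          jsonPath = sub("\\.pdb$", ".json", pdbPath)) {
    stopifnot(is(fs, "FrameSet"))
    con <- file(pdbPath, "w")
    on.exit(close(con))
    for (i in seq_along(fs@frames)) {
        tmp <- tempfile(fileext = ".pdb")
        writePDB(fs@frames[[i]], tmp)
        body <- readLines(tmp, warn = FALSE)
        unlink(tmp)
        body <- body[!grepl("^END$|^END ", body)]
        writeLines(c(sprintf("MODEL %8d", i), body, "ENDMDL"), con)
    }
    writeLines("END", con)
    jsonlite::write_json(
        list(frames = data.frame(index = seq_along(fs@frames) - 1L,
                                 x1_target = fs@x1Targets),
             fixed_serials = fs@constraint@fixedSerials,
             layer_radius = fs@constraint@layerRadius),
        jsonPath, auto_unbox = TRUE, digits = NA)
    invisible(pdbPath)
}
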