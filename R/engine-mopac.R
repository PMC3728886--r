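#' Write a MOPAC-dialect engine input deck
#'
#' Emits a deterministic text deck: one keyword line (method label,
#' MOZYME, GNORM, CUTOFF, EPS, CHARGE, CHARGES, any extra keywords), a
#' title line, a blank line, then one line per atom
#' `element x flag y flag z flag` with optimization flag 1 (free) or 0
#' (frozen). Atoms in the constraint set -- plus any serials in `alsoFix`,
#' used to freeze the two reaction-coordinate atoms during frame
#' relaxation -- get `0 0 0`.
#'
#' @param s a [ProteinStructure-class].
#' @param k a [ConstraintSet-class].
#' @param cfg an [EngineConfig-class].
#' @param alsoFix additional atom serials to freeze.
#' @return the deck as a single character string.
#' @export
writeEngineInput <- function(s, k, cfg, alsoFix = integer(0)) {
    a <- s@atoms
    fixed <- a$serial %in% c(k@fixedSerials, alsoFix)
    kw <- paste(c(cfg@methodLabel, "MOZYME",
                  sprintf("GNORM=%g", cfg@gnorm),
                  sprintf("CUTOFF=%g", cfg@cutoff),
                  sprintf("EPS=%g", cfg@eps),
                  sprintf("CHARGE=%d", cfg@charge),
                  "CHARGES", cfg@extraKeywords), collapse = " ")
    title <- paste0("BarrierScreen ", s@stateTag,
                    if (!is.null(s@meta$label)) paste0(" ", s@meta$label))
    flag <- ifelse(fixed, 0L, 1L)
    atomLines <- sprintf("%-2s %12.5f %d %12.5f %d %12.5f %d",
                         a$element, a$x, flag, a$y, flag, a$z, flag)
    paste(c(kw, title, "", atomLines), collapse = "\n")
}

#' Parse a MOPAC-dialect input deck back into atoms and flags
#'
#' Round-trip companion of [writeEngineInput()], used to audit that a
#' deck encodes exactly the intended geometry and constraint flags.
#'
#' @param text deck text (single string or vector of lines).
#' @return list with `keywords` (character), `atoms` (data.frame element,
#'   x, y, z) and `optimize` (logical per atom).
#' @export
parseEngineInput <- function(text) {
    lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n"))
    if (length(lines) < 4L) stop("truncated engine input")
    body <- lines[-(1:3)]
    body <- body[nzchar(trimws(body))]
    f <- strsplit(trimws(body), "\\s+")
    atoms <- data.frame(element = vapply(f, `[`, "", 1L),
                        x = as.numeric(vapply(f, `[`, "", 2L)),
                        y = as.numeric(vapply(f, `[`, "", 4L)),
                        z = as.numeric(vapply(f, `[`, "", 6L)))
    flags <- vapply(f, function(v) all(v[c(3L, 5L, 7L)] == "1"), logical(1))
    list(keywords = strsplit(trimws(lines[1L]), "\\s+")[[1L]],
         atoms = atoms, optimize = flags)
}

#' Parse MOPAC-dialect engine output
#'
#' Extracts the final heat of formation (kcal/mol), the final Cartesian
#' geometry when present, the engine-reported total charge, and
#' classifies failures by a configurable regex list (Lewis-structure
#' failure, non-convergence, timeout). A file with neither a final energy
#' nor a recognized failure message is a parse error that quotes a
#' diagnostic excerpt.
#'
#' @param text output text (single string or vector of lines).
#' @param patterns named regex vector (status -> pattern), default
#'   [defaultFailurePatterns()].
#' @param template optional [ProteinStructure-class] to carry the parsed
#'   final geometry (atom count must match).
#' @return An [EngineResult-class].
#' @export
parseEngineOutput <- function(text, patterns = defaultFailurePatterns(),
                              template = NULL) {
    lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n"))
    if (!length(lines) || !any(nzchar(lines)))
        stop("parse error: empty engine output")
    joined <- paste(lines, collapse = "\n")
    charge <- NA_real_
    m <- regmatches(joined,
                    regexpr("(COMPUTED )?CHARGE ON SYSTEM\\s*[=:]\\s*-?[0-9]+",
                            joined))
    if (length(m))
        charge <- as.numeric(sub(".*[=:]\\s*", "", m))
    for (st in names(patterns)) {
        if (grepl(patterns[[st]], joined, ignore.case = TRUE))
            return(new("EngineResult", finalEnergy = NA_real_,
                       finalStructure = NULL, status = st,
                       reportedCharge = charge, wallTime = NA_real_))
    }
    em <- regmatches(joined,
                     regexpr(paste0("FINAL HEAT OF FORMATION\\s*=\\s*",
                                    "-?[0-9]+\\.?[0-9]*([DE][+-][0-9]+)?",
                                    "\\s*KCAL"), joined))
    if (!length(em)) {
        excerpt <- paste(utils::tail(lines[nzchar(lines)], 3L),
                         collapse = " | ")
        stop("parse error: no final heat of formation and no recognized ",
             "failure message; file ends: ", excerpt)
    }
    energy <- as.numeric(sub("D", "E",
                             sub("\\s*KCAL.*$", "",
                                 sub(".*=\\s*", "", em)), fixed = TRUE))
    geom <- .parseCartesianBlock(lines)
    finalStructure <- geom
    if (!is.null(template)) {
        if (!is.null(geom) && nrow(geom) == nrow(template@atoms))
            finalStructure <- .setCoords(template, geom)
        else finalStructure <- template
    } else if (is.null(geom)) {
        # converged single point without a printed geometry block
        finalStructure <- NA
    }
    new("EngineResult", finalEnergy = energy,
        finalStructure = finalStructure, status = "CONVERGED",
        reportedCharge = charge, wallTime = .parseWallTime(joined))
}

.parseCartesianBlock <- function(lines) {
    start <- grep("CARTESIAN COORDINATES", lines)
    if (!length(start)) return(NULL)
    i <- start[length(start)] + 1L
    rows <- list()
    while (i <= length(lines)) {
        f <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
        if (length(f) >= 5L && !is.na(suppressWarnings(as.numeric(f[3L])))) {
            rows[[length(rows) + 1L]] <- as.numeric(f[3:5])
        } else if (length(rows)) break
        i <- i + 1L
    }
    if (!length(rows)) return(NULL)
    do.call(rbind, rows)
}

.parseWallTime <- function(joined) {
    m <- regmatches(joined,
                    regexpr("(TOTAL (CPU|JOB) TIME|WALL-CLOCK TIME)[^0-9]*[0-9.]+",
                            joined))
    if (!length(m)) return(NA_real_)
    as.numeric(regmatches(m, regexpr("[0-9.]+$", m)))
}

#' Compare the engine-reported total charge with the expected value
#'
#' An absent reported charge is logged and treated as a failure.
#'
#' @param expected expected total charge (from [formalCharge()] under
#'   standard protonation).
#' @param r an [EngineResult-class].
#' @return list with `pass` (logical), `result` (the [EngineResult-class],
#'   with status CHARGE_MISMATCH on failure) and `reason`.
#' @export
checkCharge <- function(expected, r) {
    if (is.na(r@reportedCharge)) {
        warning("engine did not report a total charge; treated as failure")
        r@status <- "CHARGE_MISMATCH"
        return(list(pass = FALSE, result = r,
                    reason = "reported charge absent"))
    }
    if (r@reportedCharge == expected)
        return(list(pass = TRUE, result = r, reason = ""))
    r@status <- "CHARGE_MISMATCH"
    list(pass = FALSE, result = r,
         reason = sprintf("expected %d, engine reported %d",
                          as.integer(expected),
                          as.integer(r@reportedCharge)))
}

#' Describe an engine job
#'
#' @param structure a [ProteinStructure-class].
#' @param constraint a [ConstraintSet-class].
#' @param config an [EngineConfig-class].
#' @param rc the [ReactionCoordinate-class] (required by the surrogate
#'   engine and for frame jobs).
#' @param surface a [SurrogateSurface-class] (surrogate engine only).
#' @param label mutant label evaluated on the surrogate surface.
#' @param fixRC freeze the two reaction-coordinate atoms (frame jobs).
#' @return a job list consumed by [runEngine()].
#' @export
engineJob <- function(structure, constraint = unconstrained(),
                      config = engineConfig(), rc = NULL, surface = NULL,
                      label = NULL, fixRC = FALSE) {
    list(structure = structure, constraint = constraint, config = config,
         rc = rc, surface = surface, label = label, fixRC = fixRC)
}

#' Run one engine job
#'
#' Dispatches on the configured engine. The surrogate engine optimizes on
#' the analytic surface in-process; the external engine writes the input
#' deck, executes the configured binary and parses its output, enforcing
#' the walltime limit. A missing external binary is a configuration
#' error, never a silent fallback.
#'
#' @param job an [engineJob()] list.
#' @return An [EngineResult-class].
#' @export
runEngine <- function(job) {
    cfg <- job$config
    if (cfg@walltimeLimit <= 0)
        return(new("EngineResult", finalEnergy = NA_real_,
                   finalStructure = NULL, status = "TIMEOUT",
                   reportedCharge = NA_real_, wallTime = 0))
    if (cfg@engine == "surrogate") {
        if (is.null(job$surface))
            stop("configuration error: surrogate engine requires a surface")
        alsoFix <- integer(0)
        if (isTRUE(job$fixRC)) {
            idx <- resolveAtoms(job$structure, c(job$rc@atomA, job$rc@atomB))
            alsoFix <- job$structure@atoms$serial[idx]
        }
        return(surrogateOptimize(job$structure, job$constraint, job$surface,
                                 cfg, rc = job$rc, label = job$label,
                                 alsoFix = alsoFix))
    }
    if (!nzchar(cfg@binary) || !file.exists(cfg@binary))
        stop("configuration error: external engine binary not configured ",
             "or not found ('", cfg@binary, "')")
    alsoFix <- integer(0)
    if (isTRUE(job$fixRC)) {
        idx <- resolveAtoms(job$structure, c(job$rc@atomA, job$rc@atomB))
        alsoFix <- job$structure@atoms$serial[idx]
    }
    deck <- writeEngineInput(job$structure, job$constraint, cfg, alsoFix)
    inp <- tempfile(fileext = ".mop")
    writeLines(deck, inp)
    t0 <- Sys.time()
    out <- tryCatch(
        system2(cfg@binary, args = inp, stdout = TRUE, stderr = TRUE,
                timeout = if (is.finite(cfg@walltimeLimit))
                    cfg@walltimeLimit else 0),
        warning = function(w) w, error = function(e) e)
    wall <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    if (inherits(out, "condition") || wall > cfg@walltimeLimit)
        return(new("EngineResult", finalEnergy = NA_real_,
                   finalStructure = NULL, status = "TIMEOUT",
                   reportedCharge = NA_real_, wallTime = wall))
    res <- parseEngineOutput(out, cfg@failurePatterns,
                             template = job$structure)
    res@wallTime <- wall
    if (res@status == "CONVERGED")
        res <- checkCharge(cfg@charge, res)$result
    res
}
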