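.labelHash <- function(label) {
    v <- utf8ToInt(label)
    as.integer(sum(v * seq_along(v)) %% 100003L)
}

# run expr under a temporary RNG state
.withSeed <- function(seed, expr) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
            else if (exists(".Random.seed", envir = globalenv(),
                            inherits = FALSE))
                rm(".Random.seed", envir = globalenv()))
    set.seed(seed)
    expr
}

#' Map a reaction profile between two endpoint structures
#'
#' Builds the interpolation frames, validates each against close
#' contacts, relaxes each frame with the configured engine (both
#' reaction-coordinate atoms frozen, plus the constraint set K) and
#' collects per-frame energies and statuses. With a surrogate surface
#' carrying `noiseSd > 0`, converged frame energies are perturbed by
#' seeded i.i.d. Gaussian noise; with `reorthogonalize = TRUE` a second,
#' independently perturbed energy set is recorded, standing in for
#' reorthogonalized single-point energies.
#'
#' @param es,ge endpoint [ProteinStructure-class] objects.
#' @param rc the [ReactionCoordinate-class].
#' @param surface a [SurrogateSurface-class] (surrogate engine).
#' @param cfg an [EngineConfig-class].
#' @param constraint a [ConstraintSet-class].
#' @param nIntermediate intermediate frame count (default 10).
#' @param dmin close-contact threshold, Angstrom.
#' @param label mutant label ("WT" for wild type).
#' @param pathwayId derivation pathway recorded on the profile.
#' @return A [ReactionProfile-class].
#' @export
runProfile <- function(es, ge, rc, surface = NULL, cfg = engineConfig(),
                       constraint = unconstrained(), nIntermediate = 10L,
                       dmin = 0.7, label = "WT", pathwayId = 5L) {
    fs <- makeFrames(es, ge, rc, nIntermediate, constraint)
    n <- length(fs@frames)
    energies <- rep(NA_real_, n)
    statuses <- character(n)
    for (i in seq_len(n)) {
        f <- fs@frames[[i]]
        cc <- closeContactCheck(f, dmin)
        if (!cc$pass) {
            statuses[i] <- "CLOSE_CONTACT"
            next
        }
        res <- runEngine(engineJob(f, constraint, cfg, rc = rc,
                                   surface = surface, label = label,
                                   fixRC = TRUE))
        statuses[i] <- res@status
        if (res@status == "CONVERGED") energies[i] <- res@finalEnergy
    }
    reortho <- numeric(0)
    if (!is.null(surface)) {
        conv <- statuses == "CONVERGED"
        if (cfg@reorthogonalize) {
            reortho <- energies
            if (surface@noiseSd > 0)
                reortho[conv] <- reortho[conv] +
                    .withSeed(surface@noiseSeed + .labelHash(label) + 500009L,
                              stats::rnorm(n, 0, surface@noiseSd))[conv]
        }
        if (surface@noiseSd > 0)
            energies[conv] <- energies[conv] +
                .withSeed(surface@noiseSeed + .labelHash(label),
                          stats::rnorm(n, 0, surface@noiseSd))[conv]
    } else if (cfg@reorthogonalize) {
        warning("reorthogonalized single points need a second engine pass; ",
                "recorded as NA")
        reortho <- rep(NA_real_, n)
    }
    reactionProfile(label, fs@x1Targets, energies, statuses,
                    pathwayId = pathwayId,
                    layerRadius = constraint@layerRadius,
                    reorthoEnergies = reortho)
}

.emptyRecords <- function() {
    data.frame(label = character(0), type = character(0),
               chain = character(0), seqNumber = integer(0),
               wtAa = character(0), targetAa = character(0),
               barrier = numeric(0), valid = logical(0),
               reason = character(0), ddE = numeric(0),
               barrierReortho = numeric(0), status = character(0),
               stringsAsFactors = FALSE)
}

.recordRow <- function(spec, barrier = NA_real_, valid = FALSE,
                       reason = "", ddE = NA_real_,
                       barrierReortho = NA_real_, status = "OK") {
    if (is(spec, "DoubleSpec")) {
        data.frame(label = doubleLabel(spec), type = "double",
                   chain = NA_character_, seqNumber = NA_integer_,
                   wtAa = NA_character_, targetAa = NA_character_,
                   barrier = barrier, valid = valid, reason = reason,
                   ddE = ddE, barrierReortho = barrierReortho,
                   status = status, stringsAsFactors = FALSE)
    } else {
        data.frame(label = spec@label, type = "single",
                   chain = spec@chain, seqNumber = spec@seqNumber,
                   wtAa = spec@wtAa, targetAa = spec@targetAa,
                   barrier = barrier, valid = valid, reason = reason,
                   ddE = ddE, barrierReortho = barrierReortho,
                   status = status, stringsAsFactors = FALSE)
    }
}

#' Screen a set of mutants end to end
#'
#' For each mutation spec, runs the default mutant derivation pathway
#' (pathway 5): build the side chain(s) on the optimized wild-type GE,
#' optimize the mutant GE, assemble the mutant ES'' from the wild-type
#' ES' substrate, optimize it, interpolate, relax every frame and extract
#' the barrier. Mutants failing any validity filter (unbuildable side
#' chain, engine failure, charge mismatch, close contacts, timeout,
#' invalid profile shape) are retained in the output with their rejection
#' reason; no attempt is made to repair them.
#'
#' @param es optimized wild-type ES' [ProteinStructure-class].
#' @param ge optimized wild-type GE [ProteinStructure-class].
#' @param rc the [ReactionCoordinate-class].
#' @param mutants list of [MutationSpec-class] / [DoubleSpec-class]
#'   objects (see [mutationSpecs()], [enumerateDoubleMutants()]).
#' @param surface a [SurrogateSurface-class] (surrogate engine) or NULL
#'   (external engine per `cfg`).
#' @param cfg an [EngineConfig-class].
#' @param nIntermediate intermediate frames per profile.
#' @param layerRadius optimization-layer radius, Angstrom (Inf =
#'   unconstrained; 10 is the production screening setting, after which
#'   top hits should be recomputed unconstrained).
#' @param dmin close-contact threshold, Angstrom.
#' @return list with `records` (one row per mutant plus the "WT" row),
#'   `profiles` (named [ReactionProfile-class] list), `wtBarrier`
#'   (kcal/mol) and `report` (rejected mutants and reasons).
#' @export
screenMutants <- function(es, ge, rc, mutants, surface = NULL,
                          cfg = engineConfig(), nIntermediate = 10L,
                          layerRadius = Inf, dmin = 0.7) {
    subSerials <- ge@atoms$serial[ge@atoms$isSubstrate]
    constraint <- if (is.finite(layerRadius))
        buildConstraints(ge, subSerials, layerRadius, rc = rc)
    else unconstrained()
    wtProfile <- runProfile(es, ge, rc, surface, cfg, constraint,
                            nIntermediate, dmin, label = "WT")
    wtBar <- extractBarrier(wtProfile)
    if (!wtBar@valid)
        stop("wild-type profile invalid (", wtBar@reason, "); aborting")
    records <- .emptyRecords()
    profiles <- list(WT = wtProfile)
    for (spec in mutants) {
        label <- if (is(spec, "DoubleSpec")) doubleLabel(spec)
                 else spec@label
        row <- tryCatch(
            .screenOne(spec, label, es, ge, rc, surface, cfg, constraint,
                       nIntermediate, dmin, wtBar, profiles),
            error = function(e)
                list(row = .recordRow(spec, reason = "DERIVATION_ERROR",
                                      status = conditionMessage(e)),
                     profile = NULL))
        if (!is.null(row$profile)) profiles[[label]] <- row$profile
        records <- rbind(records, row$row)
    }
    rownames(records) <- NULL
    report <- records[!records$valid, c("label", "type", "reason", "status"),
                      drop = FALSE]
    rownames(report) <- NULL
    list(records = records, profiles = profiles,
         wtBarrier = wtBar@barrier, report = report)
}

.screenOne <- function(spec, label, es, ge, rc, surface, cfg, constraint,
                       nIntermediate, dmin, wtBar, profiles) {
    mutGE <- buildSideChain(ge, spec)
    if (identical(mutGE@meta$modelStatus, "DISCARDED_MODELING"))
        return(list(row = .recordRow(spec, reason = "DISCARDED_MODELING",
                                     status = "DISCARDED_MODELING"),
                    profile = NULL))
    optGE <- runEngine(engineJob(mutGE, constraint, cfg, rc = rc,
                                 surface = surface, label = label))
    if (optGE@status != "CONVERGED")
        return(list(row = .recordRow(spec, reason = optGE@status,
                                     status = optGE@status), profile = NULL))
    mutES <- extractAndModifySubstrate(optGE@finalStructure, es)
    optES <- runEngine(engineJob(mutES, constraint, cfg, rc = rc,
                                 surface = surface, label = label))
    if (optES@status != "CONVERGED")
        return(list(row = .recordRow(spec, reason = optES@status,
                                     status = optES@status), profile = NULL))
    profile <- runProfile(optES@finalStructure, optGE@finalStructure, rc,
                          surface, cfg, constraint, nIntermediate, dmin,
                          label = label)
    br <- extractBarrier(profile)
    reBar <- NA_real_
    if (length(profile@reorthoEnergies)) {
        reRes <- tryCatch(
            extractBarrier(reactionProfile(label, profile@x1,
                                           profile@reorthoEnergies,
                                           profile@statuses)),
            error = function(e) NULL)
        if (!is.null(reRes) && reRes@valid) reBar <- reRes@barrier
    }
    if (!br@valid)
        return(list(row = .recordRow(spec, reason = br@reason,
                                     status = "PROFILE_INVALID",
                                     barrierReortho = reBar),
                    profile = profile))
    list(row = .recordRow(spec, barrier = br@barrier, valid = TRUE,
                          ddE = br@barrier - wtBar@barrier,
                          barrierReortho = reBar, status = "OK"),
         profile = profile)
}

#' Rank screened mutants by barrier
#'
#' Invalid records are excluded; ties break stably by label.
#'
#' @param records record data.frame from [screenMutants()].
#' @param topN number of rows to keep (default all).
#' @return ranked data.frame with a `rank` column; barriers are printed
#'   at 0.1 kcal/mol precision downstream, full precision retained here.
#' @export
rankMutants <- function(records, topN = Inf) {
    ok <- records[records$valid & is.finite(records$barrier), , drop = FALSE]
    ok <- ok[order(ok$barrier, ok$label), , drop = FALSE]
    if (is.finite(topN)) ok <- utils::head(ok, topN)
    if (nrow(ok)) ok$rank <- seq_len(nrow(ok))
    rownames(ok) <- NULL
    ok
}

#' Double-mutant additivity analysis
#'
#' For each valid double mutant with both constituent singles present,
#' the expected barrier under additivity is
#' `b1 + b2 - bWT`; residuals are observed minus expected. Doubles with a
#' missing constituent are excluded with a warning.
#'
#' @param records record data.frame from [screenMutants()] (singles and
#'   doubles).
#' @param wtBarrier wild-type barrier, kcal/mol.
#' @param displayCap histogram display cap, kcal/mol (default 30; only
#'   barriers below the cap enter the distribution summary).
#' @return list with `table` (label, observed, expected, residual) and
#'   `summary` (means of the single/double distributions below the cap,
#'   mean residual, counts).
#' @export
additivityAnalysis <- function(records, wtBarrier, displayCap = 30) {
    singles <- records[records$type == "single" & records$valid, ,
                       drop = FALSE]
    doubles <- records[records$type == "double" & records$valid, ,
                       drop = FALSE]
    sb <- stats::setNames(singles$barrier, singles$label)
    rows <- list()
    for (i in seq_len(nrow(doubles))) {
        parts <- strsplit(doubles$label[i], "-", fixed = TRUE)[[1L]]
        if (!all(parts %in% names(sb))) {
            warning("double ", doubles$label[i],
                    " excluded: constituent single(s) missing")
            next
        }
        expected <- sum(sb[parts]) - wtBarrier
        rows[[length(rows) + 1L]] <-
            data.frame(label = doubles$label[i],
                       observed = doubles$barrier[i], expected = expected,
                       residual = doubles$barrier[i] - expected,
                       stringsAsFactors = FALSE)
    }
    tab <- if (length(rows)) do.call(rbind, rows)
           else data.frame(label = character(0), observed = numeric(0),
                           expected = numeric(0), residual = numeric(0))
    sBelow <- singles$barrier[singles$barrier < displayCap]
    dBelow <- doubles$barrier[doubles$barrier < displayCap]
    list(table = tab,
         summary = list(meanSingle = mean(sBelow), meanDouble = mean(dBelow),
                        meanResidual = mean(tab$residual),
                        nSingle = length(sBelow), nDouble = length(dBelow),
                        displayCap = displayCap))
}

#' Histogram of single- and double-mutant barrier distributions
#'
#' @param records record data.frame from [screenMutants()].
#' @param displayCap only barriers below this value are shown, kcal/mol.
#' @param ... passed to [graphics::hist()].
#' @return invisibly, the list of the two hist objects.
#' @export
plotBarrierDistribution <- function(records, displayCap = 30, ...) {
    ok <- records[records$valid, , drop = FALSE]
    s <- ok$barrier[ok$type == "single" & ok$barrier < displayCap]
    d <- ok$barrier[ok$type == "double" & ok$barrier < displayCap]
    brk <- pretty(c(s, d), n = 20)
    hs <- graphics::hist(s, breaks = brk, plot = FALSE)
    hd <- graphics::hist(d, breaks = brk, plot = FALSE)
    graphics::plot(hs, col = grDevices::adjustcolor("steelblue", 0.5),
                   xlab = "barrier [kcal/mol]",
                   main = "Single vs double mutant barriers", ...)
    graphics::plot(hd, col = grDevices::adjustcolor("firebrick", 0.5),
                   add = TRUE)
    graphics::legend("topright", fill = c("steelblue", "firebrick"),
                     legend = c("single", "double"), bty = "n")
    invisible(list(single = hs, double = hd))
}

#' Qualitative agreement between raw and reorthogonalized barriers
#'
#' Each mutant is classified by the sign of its barrier change relative
#' to the wild type under both energy variants. Quadrants 1 (higher under
#' both) and 3 (lower under both) agree; quadrants 2 (higher raw, lower
#' reorthogonalized) and 4 (the converse) disagree. Only mutants with a
#' raw barrier below `cap` enter the statistic.
#'
#' @param records record data.frame with `barrier` and `barrierReortho`
#'   columns (valid rows only are used).
#' @param wtRaw,wtReortho wild-type reference barriers under the two
#'   variants.
#' @param cap barrier cap, kcal/mol (default 34).
#' @return list with `counts` (quadrants 1-4), `agreement` (percent,
#'   rounded to the nearest integer) and `n`.
#' @export
reorthoAgreement <- function(records, wtRaw, wtReortho = wtRaw, cap = 34) {
    ok <- records$valid & is.finite(records$barrier) &
        is.finite(records$barrierReortho) & records$barrier < cap
    dRaw <- records$barrier[ok] - wtRaw
    dRe <- records$barrierReortho[ok] - wtReortho
    counts <- c(sum(dRaw >= 0 & dRe >= 0), sum(dRaw >= 0 & dRe < 0),
                sum(dRaw < 0 & dRe < 0), sum(dRaw < 0 & dRe >= 0))
    list(counts = counts, agreement = agreementFromCounts(counts),
         n = sum(ok))
}

#' Agreement percentage from quadrant counts
#'
#' @param counts integer vector of quadrant counts (1-4); quadrants 1 and
#'   3 are the agreeing ones.
#' @return percent agreement, rounded to the nearest integer.
#' @examples
#' agreementFromCounts(c(90, 14, 45, 20))  # 80
#' @export
agreementFromCounts <- function(counts) {
    stopifnot(length(counts) == 4L, all(counts >= 0), sum(counts) > 0)
    round(100 * (counts[1L] + counts[3L]) / sum(counts))
}
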