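test_that("engine input decks are deterministic and carry the settings", {
    toy <- defaultToy()
    cfg <- engineConfig(gnorm = 1.0, cutoff = 15, eps = 78, charge = -9L)
    deck <- writeEngineInput(toy$ge, unconstrained(), cfg)
    kw <- strsplit(strsplit(deck, "\n")[[1]][1], " ")[[1]]
    expect_true(all(c("PM6", "MOZYME", "GNORM=1", "CUTOFF=15", "EPS=78",
                      "CHARGE=-9", "CHARGES") %in% kw))
    expect_identical(deck, writeEngineInput(toy$ge, unconstrained(), cfg))
    # unconstrained: every atom optimized
    parsed <- parseEngineInput(deck)
    expect_true(all(parsed$optimize))
    expect_equal(nrow(parsed$atoms), nAtoms(toy$ge))
})

test_that("constraint flags round-trip through the deck text", {
    toy <- defaultToy()
    a <- atoms(toy$ge)
    fixedS <- a$serial[4:6]
    k <- new("ConstraintSet", fixedSerials = as.integer(fixedS),
             layerRadius = 8, originState = "GE")
    deck <- writeEngineInput(toy$ge, k, engineConfig())
    parsed <- parseEngineInput(deck)
    expect_equal(sum(!parsed$optimize), 3L)
    expect_equal(which(!parsed$optimize), 4:6)
    expect_equal(sum(parsed$optimize), nAtoms(toy$ge) - 3L)
    # geometry recoverable at written precision
    expect_equal(parsed$atoms$x, a$x, tolerance = 1e-5)
    expect_equal(parsed$atoms$element, a$element)
    # frozen reaction-coordinate atoms via alsoFix
    rcIdx <- resolveAtoms(toy$ge, c(toy$rc@atomA, toy$rc@atomB))
    deck2 <- writeEngineInput(toy$ge, unconstrained(), engineConfig(),
                              alsoFix = a$serial[rcIdx])
    expect_equal(which(!parseEngineInput(deck2)$optimize), sort(rcIdx))
})

test_that("engine output parsing extracts energy, charge and geometry", {
    out <- c(" STARTING MOZYME CALCULATION",
             " COMPUTED CHARGE ON SYSTEM: -9",
             " CYCLE 57 GRADIENT NORM 0.854",
             " FINAL HEAT OF FORMATION = -4123.45678 KCAL/MOL",
             "",
             " CARTESIAN COORDINATES",
             "   1  C    0.1000   0.2000   0.3000",
             "   2  O    1.4000   0.2000   0.3000",
             "",
             " TOTAL JOB TIME: 123.4 SECONDS")
    r <- parseEngineOutput(out)
    expect_equal(r@status, "CONVERGED")
    expect_equal(r@finalEnergy, -4123.45678)
    expect_equal(r@reportedCharge, -9)
    expect_equal(r@finalStructure[2, 1], 1.4)
    expect_equal(r@wallTime, 123.4)
})

test_that("failure phrases classify the run and suppress the energy", {
    lewis <- c(" MOZYME SETUP", " UNABLE TO RESOLVE ALL LEWIS STRUCTURES",
               " JOB ABORTED")
    r <- parseEngineOutput(lewis)
    expect_equal(r@status, "LEWIS_FAILURE")
    expect_true(is.na(r@finalEnergy))
    r2 <- parseEngineOutput(c(" GEOMETRY NOT OPTIMIZED",
                              " EXCESS NUMBER OF OPTIMIZATION CYCLES"))
    expect_equal(r2@status, "NOT_CONVERGED")
    # truncated output is a parse error with an excerpt
    expect_error(parseEngineOutput(c(" STARTING", " CYCLE 1")),
                 "parse error")
})

test_that("charge checking passes on equality and fails otherwise", {
    mk <- function(ch) new("EngineResult", finalEnergy = -1,
                           finalStructure = NA, status = "CONVERGED",
                           reportedCharge = ch, wallTime = 1)
    expect_true(checkCharge(-9, mk(-9))$pass)
    bad <- checkCharge(-9, mk(-8))
    expect_false(bad$pass)
    expect_equal(bad$result@status, "CHARGE_MISMATCH")
    expect_warning(absent <- checkCharge(-9, mk(NA_real_)), "did not report")
    expect_false(absent$pass)
    expect_match(absent$reason, "absent")
})

test_that("runEngine dispatches, times out, and never falls back silently", {
    toy <- defaultToy()
    surf <- makeSurface(toy$groundTruth)
    ok <- runEngine(engineJob(toy$ge, config = engineConfig(),
                              rc = toy$rc, surface = surf))
    expect_equal(ok@status, "CONVERGED")
    expect_true(is.finite(ok@finalEnergy))
    to <- runEngine(engineJob(toy$ge,
                              config = engineConfig(walltimeLimit = 0),
                              rc = toy$rc, surface = surf))
    expect_equal(to@status, "TIMEOUT")
    expect_error(runEngine(engineJob(toy$ge,
                                     config = engineConfig(engine = "external"),
                                     rc = toy$rc)),
                 "configuration error")
    expect_error(runEngine(engineJob(toy$ge, config = engineConfig(),
                                     rc = toy$rc, surface = NULL)),
                 "configuration error")
})

test_that("engine configuration is validated", {
    expect_error(engineConfig(gnorm = 0), "gnorm")
    expect_error(engineConfig(eps = 0.5), "eps")
    expect_error(engineConfig(engine = "dft"), "surrogate")
})

test_that("surrogate optimization honors constraints bit-exactly", {
    toy <- defaultToy()
    surf <- makeSurface(toy$groundTruth)
    # all atoms constrained: energy of the input geometry, nothing moves
    allFix <- new("ConstraintSet",
                  fixedSerials = atoms(toy$ge)$serial,
                  layerRadius = 0.1, originState = "GE")
    r <- surrogateOptimize(toy$ge, allFix, surf, engineConfig(), rc = toy$rc)
    expect_identical(atoms(r@finalStructure)$x, atoms(toy$ge)$x)
    expect_equal(r@finalEnergy, surrogateEnergy(toy$ge, surf, toy$rc))
    # partially constrained start away from the tether reference:
    # frozen atoms never move, energy never increases
    s <- toy$ge
    free <- which(!s@atoms$isSubstrate & s@atoms$resno > 10)[1:6]
    ref <- as.matrix(atoms(s)[, c("x", "y", "z")])
    s@atoms$x[free] <- s@atoms$x[free] + 0.4
    k <- new("ConstraintSet",
             fixedSerials = atoms(s)$serial[-free], layerRadius = 5,
             originState = "GE")
    e0 <- surrogateEnergy(s, surf, toy$rc, reference = ref)
    r2 <- surrogateOptimize(s, k, surf, engineConfig(), rc = toy$rc,
                            reference = ref)
    expect_identical(atoms(r2@finalStructure)$x[-free], atoms(s)$x[-free])
    expect_lte(r2@finalEnergy, e0)
})

test_that("a single free atom descends to its tether reference", {
    toy <- defaultToy()
    surf <- makeSurface(toy$groundTruth)
    s <- toy$ge
    a <- atoms(s)
    free <- which(a$name == "CB" & a$resno == 11)
    ref <- as.matrix(a[, c("x", "y", "z")])
    s@atoms$x[free] <- s@atoms$x[free] + 0.8
    s@atoms$y[free] <- s@atoms$y[free] - 0.5
    k <- new("ConstraintSet", fixedSerials = a$serial[-free],
             layerRadius = 1, originState = "GE")
    r <- surrogateOptimize(s, k, surf, engineConfig(), rc = toy$rc,
                           reference = ref)
    expect_equal(r@status, "CONVERGED")
    got <- unlist(atoms(r@finalStructure)[free, c("x", "y", "z")])
    expect_equal(unname(got), unname(ref[free, ]), tolerance = 1e-4)
})

test_that("profile barriers converge to the analytic barrier with frame count", {
    toy <- defaultToy()
    surf <- makeSurface(toy$groundTruth)
    # dense 1-D grid oracle over x1
    x <- seq(toy$groundTruth$x1GE, toy$groundTruth$x1ES,
             length.out = 200001)
    e <- BarrierScreen:::.surf1d(surf, x)
    analytic <- max(e) - min(e)
    expect_equal(analytic, 18.5, tolerance = 1e-6)
    errs <- vapply(c(4L, 10L, 50L), function(n) {
        p <- runProfile(toy$es, toy$ge, toy$rc, surface = surf,
                        nIntermediate = n)
        abs(barrierValue(extractBarrier(p)) - analytic)
    }, numeric(1))
    expect_equal(errs, sort(errs, decreasing = TRUE))  # monotone decrease
    expect_lt(errs[2], 0.1)
    expect_lt(errs[3], 0.01)
    # the profile maximum is within one frame of the analytic barrier top
    p10 <- runProfile(toy$es, toy$ge, toy$rc, surface = surf)
    b10 <- extractBarrier(p10)
    xtop <- x[which.max(e)]
    expect_lte(abs(x1Targets(p10)[b10@argmax] - xtop), 1.5 / 11 + 1e-9)
})
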