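test_that("ES derivation swaps exactly one bond and moves only the leaving group", {
    toy <- defaultToy()
    ge <- toy$ge
    es <- deriveESfromGE(ge, toy$rc)
    expect_equal(stateTag(es), "ES")
    # bond bookkeeping: cardinality conserved, nucleophile link gone,
    # glycosidic link formed
    expect_equal(nrow(links(es)), nrow(links(ge)))
    a <- atoms(ge)
    sOE <- a$serial[a$name == "OE1"]
    sC1 <- a$serial[a$name == "C1"]
    sO1 <- a$serial[a$name == "O1"]
    key <- function(l) paste(l[, 1], l[, 2])
    expect_true(paste(min(sOE, sC1), max(sOE, sC1)) %in% key(links(ge)))
    expect_false(paste(min(sOE, sC1), max(sOE, sC1)) %in% key(links(es)))
    expect_true(paste(min(sC1, sO1), max(sC1, sO1)) %in% key(links(es)))
    # new glycosidic bond at the standard length
    expect_equal(atomDistance(es, "XYL:C1", "ONP:O1"), 1.43, tolerance = 1e-9)
    # locality: every non-leaving-group atom untouched
    moved <- atoms(es)$resname == "ONP"
    expect_identical(atoms(es)$x[!moved], a$x[!moved])
    expect_identical(atoms(es)$y[!moved], a$y[!moved])
    # applying twice is caught by the link guard
    expect_error(deriveESfromGE(es, toy$rc), "derivation error")
})

test_that("substrate extraction takes protein from GE and substrate from ES'", {
    toy <- defaultToy()
    # identity case: wild-type inputs reproduce the ES'
    idc <- extractAndModifySubstrate(toy$ge, toy$es)
    expect_equal(as.matrix(atoms(idc)[, c("x", "y", "z")]),
                 as.matrix(atoms(toy$es)[, c("x", "y", "z")]))
    # mutant case: coordinate-source bookkeeping
    mutGE <- buildSideChain(toy$ge, mutationSpec("A", 11, "A", "L"))
    mutES <- extractAndModifySubstrate(mutGE, toy$es)
    aG <- atoms(mutGE); aE <- atoms(toy$es); aM <- atoms(mutES)
    expect_identical(aM$x[!aM$isSubstrate], aG$x[!aG$isSubstrate])
    sub <- aM$isSubstrate
    keyM <- paste(aM$chain[sub], aM$resno[sub], aM$name[sub])
    keyE <- paste(aE$chain[aE$isSubstrate], aE$resno[aE$isSubstrate],
                  aE$name[aE$isSubstrate])
    expect_identical(aM$x[sub], aE$x[aE$isSubstrate][match(keyM, keyE)])
    expect_equal(stateTag(mutES), "ES")
    expect_equal(measureX1(mutES, toy$rc), measureX1(toy$es, toy$rc))
    # a missing substrate atom is a correspondence error
    broken <- toy$es
    broken@atoms <- broken@atoms[broken@atoms$name != "O5", ]
    expect_error(extractAndModifySubstrate(toy$ge, broken),
                 "correspondence")
})

test_that("constraint sets freeze exactly the residues beyond the layer", {
    toy <- defaultToy(nResidues = 8, nActive = 3)
    ge <- toy$ge
    subS <- atoms(ge)$serial[atoms(ge)$isSubstrate]
    expect_length(fixedSerials(buildConstraints(ge, subS, Inf)), 0L)
    k8 <- buildConstraints(ge, subS, 8)
    # distance audit: fixed atoms are exactly those of protein residues
    # whose minimum substrate distance exceeds 8 A
    inner <- residuesWithin(ge, subS, 8)
    innerKey <- paste(inner$chain, inner$resno)
    a <- atoms(ge)
    manual <- integer(0)
    for (i in seq_len(nrow(a))) {
        if (a$isSubstrate[i]) next
        rk <- paste(a$chain[i], a$resno[i])
        # BLK cages count as their own (hetero, non-substrate) residues
        if (any(a$isSubstrate[a$chain == a$chain[i] &
                              a$resno == a$resno[i]])) next
        if (!(rk %in% innerKey)) manual <- c(manual, a$serial[i])
    }
    expect_setequal(fixedSerials(k8), manual)
    # monotone: larger radius, smaller fixed set
    for (r in list(c(4, 6), c(6, 8), c(8, 12))) {
        f1 <- fixedSerials(buildConstraints(ge, subS, r[1]))
        f2 <- fixedSerials(buildConstraints(ge, subS, r[2]))
        expect_true(all(f2 %in% f1))
    }
    expect_error(buildConstraints(ge, integer(0), 8), "non-empty")
    # reaction-coordinate atoms are evicted from the fixed set
    expect_warning(
        kSmall <- buildConstraints(ge, "XYL:O2", 0.5, rc = toy$rc),
        "reaction-coordinate")
    rcSerials <- atoms(ge)$serial[resolveAtoms(ge, c(toy$rc@atomA,
                                                     toy$rc@atomB))]
    expect_false(any(rcSerials %in% fixedSerials(kSmall)))
})

test_that("frames interpolate linearly with exact x1 targets", {
    toy <- defaultToy()
    fs <- makeFrames(toy$es, toy$ge, toy$rc, nIntermediate = 10)
    expect_length(frames(fs), 12L)
    tg <- x1Targets(fs)
    # arithmetic progression 3.0 -> 1.5
    expect_equal(tg[1], 3.0)
    expect_equal(tg[12], 1.5)
    expect_equal(diff(tg), rep(-1.5 / 11, 11))
    expect_equal(tg[2], 3.0 - 1.5 / 11)  # 2.8636...
    for (i in seq_along(tg))
        expect_lt(abs(measureX1(frames(fs)[[i]], toy$rc) - tg[i]), 1e-6)
    # endpoints are the inputs, bit-exact
    expect_identical(atoms(frames(fs)[[1]])$x, atoms(toy$es)$x)
    expect_identical(atoms(frames(fs)[[12]])$x, atoms(toy$ge)$x)
    # intermediates lie on the ES->GE segment (before x1 enforcement the
    # blend is linear; atoms identical in both endpoints never move)
    ce <- as.matrix(atoms(toy$es)[, c("x", "y", "z")])
    cg <- as.matrix(atoms(toy$ge)[, c("x", "y", "z")])
    same <- rowSums(abs(ce - cg)) == 0
    for (i in c(3, 7)) {
        ci <- as.matrix(atoms(frames(fs)[[i]])[, c("x", "y", "z")])
        expect_equal(ci[same, ], ce[same, ])
    }
    # n = 0 gives exactly the endpoints
    expect_length(frames(makeFrames(toy$es, toy$ge, toy$rc, 0)), 2L)
})

test_that("frame construction validates correspondence and degeneracy", {
    toy <- defaultToy()
    broken <- toy$ge
    broken@atoms <- broken@atoms[-5, ]
    expect_error(makeFrames(toy$es, broken, toy$rc), "correspondence")
    expect_error(makeFrames(toy$ge, toy$ge, toy$rc), "degenerate")
})

test_that("two-atom toy: x1 sequence 3.0, 2.8636, ..., 1.5", {
    mk <- function(d) proteinStructure(data.frame(
        serial = 1:2, name = c("OE1", "C1"), resname = c("GLU", "XYL"),
        chain = c("A", "X"), resno = c(1L, 2L), x = c(0, d), y = 0, z = 0,
        element = c("O", "C"), isSubstrate = c(FALSE, TRUE)))
    rc <- reactionCoordinate("A:1:OE1", "XYL:C1")
    fs <- makeFrames(mk(3.0), mk(1.5), rc, 10)
    got <- vapply(frames(fs), measureX1, numeric(1), rc = rc)
    expect_equal(got, seq(3.0, 1.5, length.out = 12), tolerance = 1e-9)
})

test_that("close-contact check matches a brute-force scan", {
    two <- proteinStructure(data.frame(
        serial = 1:2, name = c("H1", "H2"), resname = c("AAA", "BBB"),
        chain = "A", resno = 1:2, x = c(0, 0.3), y = 0, z = 0,
        element = "H", isSubstrate = FALSE))
    r <- closeContactCheck(two, 0.7)
    expect_false(r$pass)
    expect_equal(nrow(r$pairs), 1L)
    # a registered bond at 1.0 A is exempt
    bonded <- proteinStructure(atoms(two), links = matrix(1:2, 1))
    bonded@atoms$x[2] <- 1.0
    expect_true(closeContactCheck(bonded, 1.2)$pass)
    # random fixture vs O(N^2) oracle
    set.seed(5)
    for (k in 1:5) {
        s <- randomStructure(40, seed = k)
        s@atoms$x <- s@atoms$x / 8; s@atoms$y <- s@atoms$y / 8
        s@atoms$z <- s@atoms$z / 8
        r <- closeContactCheck(s, 2.0)
        expect_equal(nrow(r$pairs), bruteCloseContact(s, 2.0))
    }
})

test_that("pathway plans follow the derivation graph", {
    m <- mutationSpec("A", 127, "Q", "W")
    p5 <- planPathway(5, m)
    expect_equal(p5@steps,
                 c("mutate WT GE opt -> Mut GE", "optimize Mut GE",
                   "extract substrate", "modify substrate (3) -> Mut ES''",
                   "optimize Mut ES''", "interpolate"))
    p2 <- planPathway(2)
    expect_true(any(grepl("modify substrate \\(2\\)", p2@steps)))
    expect_lt(grep("modify substrate", p2@steps),
              grep("optimize WT ES", p2@steps))
    expect_error(planPathway(3, m, constrained = TRUE), "configuration")
    expect_error(planPathway(1, m), "wild-type-only")
    expect_error(planPathway(4), "require a mutation")
    expect_error(planPathway(7), "1..5")
})

test_that("frame sets serialize to multi-model PDB with a JSON sidecar", {
    toy <- defaultToy()
    fs <- makeFrames(toy$es, toy$ge, toy$rc, 2)
    pdb <- tempfile(fileext = ".pdb")
    writeFrameSet(fs, pdb)
    lines <- readLines(pdb)
    expect_equal(sum(grepl("^MODEL", lines)), 4L)
    expect_equal(sum(grepl("^ENDMDL", lines)), 4L)
    side <- jsonlite::read_json(sub("\\.pdb$", ".json", pdb),
                                simplifyVector = TRUE)
    expect_equal(side$frames$x1_target, x1Targets(fs))
})
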