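positionsDF <- function(n, resname = "ALA") {
    data.frame(chain = "A", resno = seq_len(n) + 100L, resname = resname)
}

test_that("single-mutant enumeration yields 19 specs per open position", {
    one <- enumerateSingleMutants(positionsDF(1))
    expect_equal(nrow(one), 19L)
    expect_false(any(one$targetAa == one$wtAa))
    expect_equal(one$label, paste0(one$wtAa, one$seqNumber, one$targetAa))

    twenty <- enumerateSingleMutants(positionsDF(20),
                                     exclusions = c("A:101", "A:102"))
    expect_equal(nrow(twenty), 342L)

    expect_equal(nrow(enumerateSingleMutants(positionsDF(2),
                                             exclusions = c("A:101", "A:102"))),
                 0L)
    expect_warning(enumerateSingleMutants(positionsDF(3),
                                          exclusions = "B:999"),
                   "not among positions")
    # property: 19 * (#positions - #excluded), deterministic ordering
    set.seed(11)
    for (k in 1:5) {
        p <- sample(3:25, 1)
        nex <- sample(0:2, 1)
        ex <- if (nex > 0) paste0("A:", 100 + sample(p, nex))
              else character(0)
        a <- enumerateSingleMutants(positionsDF(p), ex)
        b <- enumerateSingleMutants(positionsDF(p), ex)
        expect_identical(a, b)
        expect_equal(nrow(a), 19L * (p - length(ex)))
    }
})

test_that("non-canonical positions are skipped with a warning", {
    pos <- rbind(positionsDF(2), data.frame(chain = "A", resno = 200L,
                                            resname = "BLK"))
    expect_warning(out <- enumerateSingleMutants(pos), "non-canonical")
    expect_equal(nrow(out), 38L)
})

test_that("bestPerPosition keeps the lowest barrier, ties alphabetical", {
    rec <- data.frame(label = c("Q127W", "Q127K"), chain = "A",
                      seqNumber = 127L, wtAa = "Q",
                      targetAa = c("W", "K"), barrier = c(6.9, 8.6))
    expect_equal(bestPerPosition(rec)$label, "Q127W")
    expect_equal(bestPerPosition(rec[1, ])$label, "Q127W")
    tie <- data.frame(label = c("Q127W", "Q127F"), chain = "A",
                      seqNumber = 127L, wtAa = "Q",
                      targetAa = c("W", "F"), barrier = c(5, 5))
    expect_equal(bestPerPosition(tie)$targetAa, "F")
    expect_error(bestPerPosition(transform(rec, barrier = c(1, NA))),
                 "finite")
    expect_equal(nrow(bestPerPosition(rec[0, ])), 0L)
})

test_that("double-mutant candidates are all pairs of distinct positions", {
    mk <- function(p) data.frame(label = paste0("A", 100 + seq_len(p), "W"),
                                 chain = "A", seqNumber = 100L + seq_len(p),
                                 wtAa = "A", targetAa = "W")
    expect_length(enumerateDoubleMutants(mk(3)), 3L)
    expect_length(enumerateDoubleMutants(mk(2)), 1L)
    # brute-force pairing oracle
    p <- 17
    got <- enumerateDoubleMutants(mk(p))
    oracle <- 0
    for (i in 1:(p - 1)) for (j in (i + 1):p) oracle <- oracle + 1
    expect_length(got, oracle)  # C(17,2) = 136
    expect_equal(oracle, 136)
    labs <- vapply(got, doubleLabel, character(1))
    expect_false(anyDuplicated(labs) > 0)
    dup <- rbind(mk(3), mk(3)[1, ])
    expect_error(enumerateDoubleMutants(dup), "more than one spec")
})

test_that("mutation specs are validated at construction", {
    expect_error(mutationSpec("A", 5, "A", "A"), "differ")
    expect_error(mutationSpec("A", 5, "A", "X"), "canonical")
    expect_equal(mutationSpec("A", 127, "Q", "W")$label, "Q127W")
    d <- doubleSpec(mutationSpec("A", 127, "Q", "W"),
                    mutationSpec("A", 7, "Q", "W"))
    expect_equal(doubleLabel(d), "Q7W-Q127W")  # canonical position order
})

test_that("side-chain building preserves everything outside the residue", {
    toy <- defaultToy()
    before <- atoms(toy$ge)
    m <- buildSideChain(toy$ge, mutationSpec("A", 12, "S", "W"))
    after <- atoms(m)
    keyB <- paste(before$chain, before$resno, before$name)
    keyA <- paste(after$chain, after$resno, after$name)
    outside <- before$resno != 12 | before$chain != "A"
    idx <- match(keyB[outside], keyA)
    expect_false(anyNA(idx))
    expect_identical(before$x[outside], after$x[idx])   # bit-exact
    expect_identical(before$y[outside], after$y[idx])
    expect_identical(before$z[outside], after$z[idx])
    # backbone + CB of the mutated residue bit-exact too
    bb <- before$resno == 12 & before$name %in% c("N", "CA", "C", "O", "CB")
    idx <- match(keyB[bb], keyA)
    expect_identical(before$x[bb], after$x[idx])
    # full tryptophan side chain present
    expect_setequal(after$name[after$resno == 12 & after$chain == "A"],
                    c("N", "CA", "C", "O", "CB", "CG", "CD1", "CD2",
                      "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2"))
    expect_equal(m@meta$modelStatus, "OK")
    expect_equal(m@meta$label, "S12W")
})

test_that("mutation to glycine leaves no side-chain atoms beyond C-beta", {
    toy <- defaultToy()
    g <- buildSideChain(toy$ge, mutationSpec("A", 13, "V", "G"))
    resAtoms <- atoms(g)$name[atoms(g)$resno == 13 & atoms(g)$chain == "A"]
    expect_setequal(resAtoms, c("N", "CA", "C", "O"))
})

test_that("the chi-grid search returns the grid minimum (exhaustive oracle)", {
    toy <- defaultToy()
    m <- buildSideChain(toy$ge, mutationSpec("A", 11, "A", "F"))
    expect_equal(m@meta$modelStatus, "OK")
    # independent oracle: enumerate the full 30-degree grid and rescore
    # each placement with a separately written clash loop
    a <- atoms(toy$ge)
    res <- a$resno == 11 & a$chain == "A"
    bb <- as.matrix(a[res & a$name %in% c("N", "CA", "C"), c("x", "y", "z")])
    rownames(bb) <- a$name[res & a$name %in% c("N", "CA", "C")]
    bb <- rbind(bb, CB = unlist(a[res & a$name == "CB", c("x", "y", "z")]))
    env <- a[!res, ]
    keep <- sqrt((env$x - bb["CA", 1])^2 + (env$y - bb["CA", 2])^2 +
                 (env$z - bb["CA", 3])^2) <= 12
    env <- env[keep, ]
    envXyz <- as.matrix(env[, c("x", "y", "z")])
    vdw <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20)
    envR <- unname(vdw[env$element]); envR[is.na(envR)] <- 1.7
    tpl <- sideChainTemplate("F")
    tplR <- unname(vdw[substr(tpl$name, 1, 1)]); tplR[is.na(tplR)] <- 1.7
    score <- function(chis) {
        xyz <- BarrierScreen:::.placeTemplate(tpl, bb, chis)
        s <- 0
        for (i in seq_len(nrow(xyz))) for (j in seq_len(nrow(envXyz))) {
            ov <- 0.8 * (tplR[i] + envR[j]) -
                sqrt(sum((xyz[i, ] - envXyz[j, ])^2))
            if (ov > 0) s <- s + ov^2
        }
        s
    }
    grid <- seq(-180, 150, by = 30)
    gmin <- Inf
    for (c1 in grid) for (c2 in grid)
        gmin <- min(gmin, score(c(c1, c2)))
    # the refined score can only improve on the grid minimum
    expect_lte(m@meta$clashScore, gmin + 1e-9)
    # in this open environment the placement is contact-free
    xyzNew <- as.matrix(atoms(m)[atoms(m)$resno == 11 &
                                 !(atoms(m)$name %in%
                                   c("N", "CA", "C", "O", "CB")),
                                 c("x", "y", "z")])
    for (i in seq_len(nrow(xyzNew)))
        expect_gte(min(sqrt(colSums((t(envXyz) - xyzNew[i, ])^2))), 1.5)
})

test_that("unresolvable backbone and wild-type mismatch are errors", {
    toy <- defaultToy()
    expect_error(buildSideChain(toy$ge, mutationSpec("A", 99, "A", "W")),
                 "no residue")
    expect_error(buildSideChain(toy$ge, mutationSpec("A", 11, "S", "W")),
                 "mismatch")
    # the nucleophile analog has no backbone
    expect_error(buildSideChain(toy$ge, mutationSpec("A", 10, "E", "W")),
                 "backbone")
})

test_that("a caged position flags the mutant instead of accepting it", {
    toy <- defaultToy(nResidues = 8, nActive = 3, clashPositions = 2L)
    for (target in c("K", "F", "P", "Y")) {
        m <- buildSideChain(toy$ge, mutationSpec("A", 12, "S", target))
        expect_equal(m@meta$modelStatus, "DISCARDED_MODELING")
    }
    open <- buildSideChain(toy$ge, mutationSpec("A", 11, "A", "K"))
    expect_equal(open@meta$modelStatus, "OK")
})
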