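# Fixtures are generated programmatically; nothing is read from disk
# except files the tests themselves write to tempdir().

# hand-written PDB text (fixed-width records) for parser tests
writePdbLines <- function(lines, path = tempfile(fileext = ".pdb")) {
    writeLines(lines, path)
    path
}

pdbAtomLine <- function(serial, name, resname, chain, resno, x, y, z,
                        type = "ATOM", insert = " ", element = NULL) {
    if (is.null(element)) element <- substr(gsub("[0-9]", "", name), 1, 1)
    sprintf("%-6s%5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            type, serial, name, " ", resname, chain, resno, insert,
            x, y, z, 1, 0, element)
}

# random synthetic structure built in code
randomStructure <- function(n, seed = 1) {
    set.seed(seed)
    nres <- ceiling(n / 5)
    resno <- rep(seq_len(nres), each = 5)[seq_len(n)]
    proteinStructure(data.frame(
        serial = seq_len(n),
        name = paste0("C", ((seq_len(n) - 1) %% 5) + 1),
        resname = "ALA", chain = "A", resno = resno,
        x = round(runif(n, -40, 40), 3), y = round(runif(n, -40, 40), 3),
        z = round(runif(n, -40, 40), 3),
        element = "C", isSubstrate = FALSE))
}

# independent two-pass barrier oracle: scan for the first global maximum,
# then scan the prefix for its minimum
bruteBarrier <- function(e) {
    amax <- 1
    for (i in seq_along(e)) if (e[i] > e[amax]) amax <- i
    if (amax == length(e)) return(list(valid = FALSE, reason = "LAST_FRAME_MAX"))
    if (amax == 1) return(list(valid = FALSE, reason = "NO_PRE_MAX"))
    amin <- 1
    for (i in seq_len(amax - 1)) if (e[i] < e[amin]) amin <- i
    list(valid = TRUE, barrier = e[amax] - e[amin], argmax = amax,
         argmin = amin)
}

# O(N^2) close-contact oracle (same-residue and linked pairs exempt)
bruteCloseContact <- function(s, dmin) {
    a <- atoms(s)
    xyz <- as.matrix(a[, c("x", "y", "z")])
    rkey <- paste(a$chain, a$resno, a$insert)
    linked <- apply(links(s), 1, function(p) paste(sort(p), collapse = "-"))
    bad <- 0
    for (i in seq_len(nrow(a) - 1)) for (j in (i + 1):nrow(a)) {
        if (rkey[i] == rkey[j]) next
        if (paste(sort(c(a$serial[i], a$serial[j])), collapse = "-") %in%
            linked) next
        if (sqrt(sum((xyz[i, ] - xyz[j, ])^2)) < dmin) bad <- bad + 1
    }
    bad
}

# default toy system shared across tests
defaultToy <- function(...) makeToySystem(toySystemSpec(...))
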