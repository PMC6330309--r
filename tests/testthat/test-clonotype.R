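test_that("CDR3 similarity is the normalised Levenshtein similarity", {
    expect_equal(cdr3Similarity("ARDYW", "ARDYW"), 1.0)
    expect_equal(cdr3Similarity("ARDYW", "ARDFW"), 0.8)
    expect_equal(cdr3Similarity("AR", "ARDYW"), 0.4)
    expect_error(cdr3Similarity("", "AR"), "non-empty")
    # symmetry and the identity <=> 1 property against an independent DP
    set.seed(5)
    a <- randomCdr3(60); b <- randomCdr3(60)
    sAB <- cdr3Similarity(a, b)
    expect_equal(sAB, cdr3Similarity(b, a))
    dp <- mapply(oracleLevenshtein, a, b)
    expect_equal(sAB, unname(1 - dp / pmax(nchar(a), nchar(b))))
    expect_identical(sAB == 1, a == b)
})

test_that("hamming mode requires equal lengths and counts substitutions", {
    expect_equal(cdr3Similarity("ARDYW", "ARDFW", method = "hamming"), 0.8)
    expect_error(cdr3Similarity("AR", "ARDYW", method = "hamming"),
                 "equal-length")
})

test_that("clustering handles the degenerate cases", {
    one <- clusterClonotypes(c(a = "ARDYW", b = "ARDYW", c = "ARDYW"))
    expect_identical(nFamilies(one), 1L)
    expect_identical(familyTable(one)$nMembers, 3L)

    two <- clusterClonotypes(c(a = "AAAAA", b = "WWWWW"))
    expect_identical(nFamilies(two), 2L)

    empty <- clusterClonotypes(character(0))
    expect_identical(nFamilies(empty), 0L)
})

test_that("clustering equals brute-force connected components", {
    set.seed(13)
    for (rep in 1:10) {
        n <- sample(20:60, 1)
        # mix of clustered (mutated copies) and random CDR3s to force edges
        seeds <- randomCdr3(max(2, n %/% 6))
        cdr3s <- vapply(seq_len(n), function(i) {
            s <- strsplit(sample(seeds, 1), "")[[1]]
            k <- sample(0:2, 1)
            if (k > 0) {
                pos <- sample(length(s), min(k, length(s)))
                s[pos] <- sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                                 length(pos), replace = TRUE)
            }
            paste(s, collapse = "")
        }, character(1))
        names(cdr3s) <- paste0("s", seq_len(n))
        fams <- clusterClonotypes(cdr3s)
        got <- integer(n); names(got) <- names(cdr3s)
        for (f in seq_along(familyMembers(fams)))
            got[familyMembers(fams)[[f]]] <- f
        expect_identical(canonicalPartition(unname(got)),
                         canonicalPartition(oracleComponents(unname(cdr3s))))
    }
})

test_that("clustering is invariant to input order and monotone in threshold", {
    set.seed(17)
    cdr3s <- stats::setNames(randomCdr3(40, c(6, 10)), paste0("s", 1:40))
    partitionOf <- function(tab) {
        p <- integer(length(cdr3s)); names(p) <- names(cdr3s)
        for (f in seq_along(familyMembers(tab)))
            p[familyMembers(tab)[[f]]] <- f
        p
    }
    base <- partitionOf(clusterClonotypes(cdr3s))
    perm <- sample(seq_along(cdr3s))
    shuf <- partitionOf(clusterClonotypes(cdr3s[perm]))
    expect_identical(canonicalPartition(unname(base)),
                     canonicalPartition(unname(shuf[names(base)])))

    nf <- vapply(c(0.5, 0.7, 0.8, 0.9, 1.0), function(th)
        nFamilies(clusterClonotypes(cdr3s, threshold = th)), integer(1))
    expect_true(all(diff(nf) >= 0))
})

test_that("ranking computes read fractions, dense ranks and tie order", {
    cd <- c(a1 = "ARDYW", a2 = "ARDYW", b1 = "GGGGG")
    rc <- c(a1 = 60L, a2 = 30L, b1 = 10L)
    fams <- clusterClonotypes(cd, readCount = rc)
    tab <- familyTable(fams)
    expect_equal(tab$readFraction, c(0.9, 0.1))
    expect_identical(tab$rank, 1:2)
    expect_identical(tab$representativeCdr3, c("ARDYW", "GGGGG"))
    expect_equal(sum(tab$readFraction), 1)

    # equal abundance: ranks assigned by lexicographic representative CDR3
    tie <- clusterClonotypes(c(x = "WWWWW", y = "AAAAA"),
                             readCount = c(x = 5L, y = 5L))
    expect_identical(familyTable(tie)$representativeCdr3,
                     c("AAAAA", "WWWWW"))

    expect_error(clusterClonotypes(c(a = "ARDYW"),
                                   readCount = c(a = 0L)), "positive")
})

test_that("rank order recovers planted clone sizes in simulation", {
    cfg <- defaultScenario(nAnimals = 1, nSequences = 400, nClones = 12,
                           cdr3MutRate = 0, shmRate = 0,
                           shmRateByCategory = numeric(0))
    sim <- simulateRepertoire(cfg)
    cd <- stats::setNames(sim$truth$junction, sim$truth$sequenceId)
    rc <- stats::setNames(sim$truth$readCount, sim$truth$sequenceId)
    fams <- clusterClonotypes(cd, readCount = rc)
    cloneReads <- tapply(sim$truth$readCount, sim$truth$cloneId, sum)
    memb <- familyMembers(fams)
    famClone <- vapply(memb, function(m)
        sim$truth$cloneId[match(m[1], sim$truth$sequenceId)], character(1))
    # every family maps to one planted clone and rank follows clone reads
    expect_true(all(vapply(seq_along(memb), function(f)
        all(sim$truth$cloneId[match(memb[[f]], sim$truth$sequenceId)] ==
            famClone[f]), logical(1))))
    expect_equal(unname(cloneReads[famClone]),
                 unname(cloneReads[famClone][order(-cloneReads[famClone])]))
})

test_that("candidate selection walks ranks, dedupes and spans families", {
    cd <- c(a1 = "AAAAA", a2 = "AAAAA", b1 = "DDDDD", c1 = "GGGGG")
    rc <- c(a1 = 50L, a2 = 40L, b1 = 20L, c1 = 5L)
    rep <- Repertoire(c(a1 = "MAAAAA", a2 = "MAAAAA", b1 = "MDDDDD",
                        c1 = "MGGGGG"), readCount = rc)
    fams <- clusterClonotypes(cd, readCount = rc)
    # duplicates at the full-sequence level collapse to one candidate
    expect_identical(selectCandidates(fams, rep, nPerFamily = 3,
                                      maxCandidates = 10),
                     c("a1", "b1", "c1"))
    # budget of one per family, max 2: top-2 families' representatives
    expect_identical(selectCandidates(fams, rep, nPerFamily = 1,
                                      maxCandidates = 2), c("a1", "b1"))

    # 120 singleton families, 3 per family, budget 300 -> spans >= 100
    set.seed(23)
    n <- 120
    cdr <- stats::setNames(
        vapply(1:n, function(i) strrep(LETTERS[c(1,4,5,6,7,9)][1 + i %% 6],
                                       6 + i %% 7), character(1)),
        paste0("f", 1:n))
    cdr[] <- paste0(cdr, randomCdr3(n, c(12, 18)))  # make them distinct
    big <- do.call(c, lapply(1:n, function(i)
        stats::setNames(rep(cdr[i], 3), paste0("f", i, "_m", 1:3))))
    seqs <- stats::setNames(paste0(randomCdr3(3 * n, c(30, 40))),
                            names(big))
    rp <- Repertoire(seqs)
    fams2 <- clusterClonotypes(big)
    sel <- selectCandidates(fams2, rp, nPerFamily = 3, maxCandidates = 300)
    expect_identical(length(sel), 300L)
    famOf <- sub("_m[0-9]$", "", sel)
    expect_gte(length(unique(famOf)), 100L)
})
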