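gl <- toyGermlineSet()

test_that("aligned-pair reconstruction matches the string-based alignment", {
    v <- as.character(aaSequences(gl)[["IGHV3-23*01"]])
    set.seed(11)
    cases <- c(
        v,                                              # identity
        paste0(substr(v, 1, 60), substr(v, 62, 96)),    # deletion
        paste0(substr(v, 1, 40), "QQ", substr(v, 41, 96)),  # insertion
        chartr("S", "T", v)                             # substitutions
    )
    for (q in cases) {
        al <- alignGermline(q, gl, "IGHV3-23*01")
        pa <- Biostrings::pairwiseAlignment(
            pattern = Biostrings::AAStringSet(q),
            subject = Biostrings::AAString(v), type = "local-global",
            substitutionMatrix = "BLOSUM62", gapOpening = 10,
            gapExtension = 1)
        ap <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
        as <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
        qpos <- cumsum(ap != "-") + IRanges::start(Biostrings::pattern(pa)) - 1L
        gpos <- cumsum(as != "-") + IRanges::start(Biostrings::subject(pa)) - 1L
        keep <- ap != "-" & as != "-"
        expect_identical(al$pairs,
                         cbind(query = qpos[keep], germline = gpos[keep]))
        expect_true(all(diff(al$pairs[, 1]) > 0))
        expect_true(all(diff(al$pairs[, 2]) > 0))
    }
})

test_that("V assignment returns the true gene, identity 1 for germline", {
    v <- as.character(aaSequences(gl)[["IGHV3-23*01"]])
    res <- assignVGene(c(q = paste0(v, "ARDY", "WGQGTLVTVSS")), gl)
    expect_identical(res$gene, "IGHV3-23*01")
    expect_equal(res$identity, 1)
    expect_true(res$passFilter)
})

test_that("short alignments fail the minimum-alignment filter", {
    res <- assignVGene(c(q = "EVQLL"), gl)   # 5 residues < default 7
    expect_false(res$passFilter)
    expect_lte(res$alignedLength, 5L)
    expect_true(assignVGene(c(q = "EVQLL"), gl, minAligned = 3L)$passFilter)
})

test_that("V origin recovery on mutated reads agrees with an edit-distance oracle", {
    set.seed(21)
    vGenes <- names(defaultScenario()@vWeights)
    for (i in 1:50) {
        v <- sample(vGenes, 1)
        L <- nchar(as.character(aaSequences(gl)[[v]]))
        nmut <- rbinom(1, L, 0.02)
        subs <- NULL
        if (nmut > 0) {
            pos <- sample(L, nmut)
            subs <- stats::setNames(sample(setdiff(strsplit(
                "ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X"), nmut), pos)
        }
        read <- buildRead(gl, v, "IGHJ4*01",
                          paste(sample(c("A","R","D","S","Y","G"), 10,
                                       TRUE), collapse = ""), subs)
        call <- assignVGene(c(r = read), gl)$gene
        expect_identical(call, v)
        expect_identical(call, oracleBestV(read, gl))
    }
})

test_that("region extraction recovers the planted junction and shifts with indels", {
    read <- buildRead(gl, "IGHV3-23*01", "IGHJ4*01", "ARDRSY")
    rep <- Repertoire(c(s = read))
    ann <- annotateRepertoire(rep, gl)
    expect_identical(unname(cdr3(ann)), "ARDRSY")
    expect_identical(ann@ann$fr4[1], "RGQGTLVTVSS")
    expect_identical(ann@ann$cdr1[1], "GFTFSSYA")
    expect_identical(ann@ann$cdr2[1], "ISGSGGST")
    expect_identical(unname(fr4Residue(ann)), "R")
    expect_identical(unname(shmCount(ann)), 0L)

    # a bare germline V (no J) is not annotatable
    bare <- annotateRepertoire(
        Repertoire(c(s = as.character(aaSequences(gl)[["IGHV3-23*01"]]))), gl)
    expect_false(bare@ann$annotatable[1])
    expect_true(is.na(cdr3(bare)[[1]]))

    # one-residue insertion inside FR3 shifts downstream boundaries by one
    ins <- paste0(substr(read, 1, 70), "P", substr(read, 71, nchar(read)))
    annIns <- annotateRepertoire(Repertoire(c(s = ins)), gl)
    expect_identical(nchar(annIns@ann$fr3[1]), 39L)
    expect_identical(unname(cdr3(annIns)), "ARDRSY")
    concat <- paste0(annIns@ann$fr1[1], annIns@ann$cdr1[1], annIns@ann$fr2[1],
                     annIns@ann$cdr2[1], annIns@ann$fr3[1], annIns@ann$cdr3[1],
                     annIns@ann$fr4[1])
    expect_true(grepl(concat, ins, fixed = TRUE))
})

test_that("SHM counts planted substitutions and excludes the junction", {
    # three substitutions planted in FR1, CDR1 and FR3
    read <- buildRead(gl, "IGHV3-23*01", "IGHJ4*01", "ARDRSY",
                      vSubs = c("3" = "K", "27" = "W", "80" = "H"))
    expect_identical(countVMismatches(read, gl), 3L)
    # differences confined to the CDR3 junction do not count
    readJ <- buildRead(gl, "IGHV3-23*01", "IGHJ4*01", "WWWWWWWW")
    expect_identical(countVMismatches(readJ, gl), 0L)
    # germline-identical implies v_identity exactly 1
    ann <- annotateRepertoire(Repertoire(c(a = readJ)), gl)
    expect_equal(ann@ann$vIdentity[1], 1)
})

test_that("SHM count is monotone under added substitutions", {
    set.seed(31)
    v <- "IGHV3-30*01"
    L <- nchar(as.character(aaSequences(gl)[[v]]))
    for (rep in 1:10) {
        pos <- sample(L, 6)
        alphabet <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
        base <- strsplit(as.character(aaSequences(gl)[[v]]), "")[[1]]
        subs <- vapply(pos, function(p) sample(setdiff(alphabet, base[p]), 1),
                       character(1))
        counts <- vapply(seq_along(pos), function(k) {
            read <- buildRead(gl, v, "IGHJ1*01", "ARDY",
                              stats::setNames(subs[1:k], pos[1:k]))
            countVMismatches(read, gl, gene = v)
        }, integer(1))
        expect_true(all(diff(counts) >= 0))
        expect_identical(counts[6], 6L)
    }
})

test_that("FR4 motif residue reflects germline variant and motif SHM", {
    wt <- buildRead(gl, "IGHV3-23*01", "IGHJ5*01", "ARDY")
    expect_identical(motifResidue(wt, gl), "W")
    rv <- buildRead(gl, "IGHV3-23*01", "IGHJ4*01", "ARDY")
    expect_identical(motifResidue(rv, gl), "R")
    # simulated SHM converting the motif residue to S
    mut <- sub("RGQGTLVTVSS$", "SGQGTLVTVSS", rv)
    expect_identical(motifResidue(mut, gl, jGene = "IGHJ4*01"), "S")
})

test_that("annotation is deterministic and order-invariant", {
    sim <- simulateRepertoire(defaultScenario(nAnimals = 1,
                                              nSequences = 40))
    ann1 <- annotateRepertoire(sim$repertoire, gl)
    ann2 <- annotateRepertoire(sim$repertoire, gl)
    expect_identical(as.data.frame(annotations(ann1)),
                     as.data.frame(annotations(ann2)))
    perm <- rev(seq_len(length(sim$repertoire)))
    annP <- annotateRepertoire(sim$repertoire[perm], gl)
    a <- as.data.frame(annotations(ann1))
    b <- as.data.frame(annotations(annP))
    expect_equal(a[order(a$sequenceId), ], b[order(b$sequenceId), ],
                 ignore_attr = TRUE)
})

test_that("mean SHM recovers the planted per-residue rate", {
    for (mu in c(0.01, 0.03)) {
        cfg <- defaultScenario(seed = 100 + round(1000 * mu),
                               nAnimals = 1, nSequences = 600,
                               shmRate = mu,
                               shmRateByCategory = numeric(0))
        sim <- simulateRepertoire(cfg)
        ann <- annotateRepertoire(sim$repertoire, gl)
        L <- vapply(vCall(ann), function(g)
            regionBounds(gl, g)["FR3", "end"], integer(1))
        rate <- unname(shmCount(ann)) / L
        se <- stats::sd(rate) / sqrt(length(rate))
        expect_lt(abs(mean(rate) - mu), 3 * se + 1e-12)
    }
})
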