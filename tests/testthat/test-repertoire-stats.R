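gl <- toyGermlineSet()

.mkAnnotated <- function(vGenes, jGene = "IGHJ4*01", animal = "a1") {
    set.seed(91)
    reads <- vapply(seq_along(vGenes), function(i)
        buildRead(gl, vGenes[i], jGene,
                  paste(sample(c("A","R","D","S","Y","G","T","N"), 10,
                               TRUE), collapse = "")), character(1))
    names(reads) <- paste0(animal, "_s", seq_along(reads))
    annotateRepertoire(Repertoire(reads, animalId = animal), gl)
}

test_that("V usage frequencies count sequences, normalise, and zero-fill", {
    ann <- .mkAnnotated(rep("IGHV3-23*01", 10))
    u <- vGeneUsage(ann)
    expect_equal(unname(u["IGHV3-23*01"]), 1)
    expect_equal(sum(u), 1)

    ann2 <- .mkAnnotated(c(rep("IGHV3-23*01", 3), "IGHV4-39*01"))
    u2 <- vGeneUsage(ann2, genes = germlineNames(gl))
    expect_equal(unname(u2["IGHV3-23*01"]), 0.75)
    expect_equal(unname(u2["IGHV4-39*01"]), 0.25)
    expect_equal(unname(u2["IGHV1-69*01"]), 0)
    expect_true(all(germlineNames(gl)[segmentType(gl) == "V"] %in%
                    names(u2)))

    # read weighting
    ann2@info$readCount <- c(10L, 1L, 1L, 28L)
    uw <- vGeneUsage(ann2, weightByReads = TRUE)
    expect_equal(unname(uw["IGHV4-39*01"]), 0.7)
})

test_that("usage averaging is the unweighted mean over samples", {
    p1 <- c(V1 = 1.0)
    p2 <- c(V1 = 0.5, V2 = 0.5)
    avg <- averageUsage(list(p1, p2))
    expect_equal(unname(avg["V1"]), 0.75)
    expect_equal(unname(avg["V2"]), 0.25)
    expect_equal(sum(avg), 1)
    expect_equal(averageUsage(list(p2)), p2[order(names(p2))])
})

test_that("detection limit is the decoy maximum and is monotone in samples", {
    decoys <- c("IGHV3-NL1*01", "IGHV1-45*01")
    p1 <- c("IGHV3-23*01" = 0.999, "IGHV3-NL1*01" = 0.001)
    p2 <- c("IGHV3-23*01" = 0.9965, "IGHV3-NL1*01" = 0.0035)
    p3 <- c("IGHV3-23*01" = 0.998, "IGHV1-45*01" = 0.002)
    expect_equal(detectionLimit(list(p1, p2, p3), decoys), 0.0035)
    expect_equal(detectionLimit(list(p1), decoys), 0.001)
    # never assigned -> floor at zero
    expect_equal(detectionLimit(list(c("IGHV3-23*01" = 1)), decoys), 0)
    expect_error(detectionLimit(list(p1), character(0)), "non-empty")
    # adding a sample can only raise or preserve the threshold
    expect_gte(detectionLimit(list(p1, p2), decoys),
               detectionLimit(list(p1), decoys))
})

test_that("ELISA calls normalise by mean background with boundary at 30", {
    m <- data.frame(
        supernatantId = c("b1", "b2", "s1", "s2", "s3"),
        antigen = "ag",
        signal = c(90, 110, 3000, 100, 2999.9),
        isBackground = c(TRUE, TRUE, FALSE, FALSE, FALSE))
    calls <- elisaCall(m)
    expect_equal(calls$ratio, c(30, 1, 29.999))
    expect_identical(calls$positive, c(TRUE, FALSE, FALSE))
    expect_error(elisaCall(m[!m$isBackground, ]), "background")
})

test_that("SHM distributions are percentages summing to 100 per category", {
    sim <- simulateRepertoire(defaultScenario(nAnimals = 1,
                                              nSequences = 120))
    ann <- annotateRepertoire(sim$repertoire, gl)
    labels <- stats::setNames(
        ifelse(sim$truth$lambdaBinding, "lambda_binding",
               "antigen_specific"), sim$truth$sequenceId)
    d <- shmDistribution(ann, labels)
    sums <- tapply(d$percent, d$category, sum)
    expect_true(all(abs(sums - 100) < 1e-6))
    expect_error(shmDistribution(ann, c(nosuch = "x")), "unknown")

    # degenerate: all germline -> 100% in bin 0
    reads <- c(g1 = buildRead(gl, "IGHV3-23*01", "IGHJ4*01", "ARDY"),
               g2 = buildRead(gl, "IGHV3-30*01", "IGHJ1*01", "GRDY"))
    annG <- annotateRepertoire(Repertoire(reads), gl)
    dG <- shmDistribution(annG, c(g1 = "cat", g2 = "cat"))
    expect_equal(dG$percent[dG$shm == 0], 100)
})

test_that("FR4/lambda cross-tab reproduces hand-computed percentages", {
    reads <- c(
        stats::setNames(vapply(1:11, function(i)
            buildRead(gl, "IGHV3-23*01", "IGHJ5*01",
                      paste0("ARD", strrep("Y", i))), character(1)),
            paste0("w", 1:11)),
        stats::setNames(vapply(1:19, function(i)
            buildRead(gl, "IGHV3-23*01", "IGHJ4*01",
                      paste0("GRD", strrep("S", i))), character(1)),
            paste0("r", 1:19)))
    ann <- annotateRepertoire(Repertoire(reads), gl)
    # counts: W-binder 8, R-binder 2, W-nonbinder 3, R-nonbinder 17
    lab <- c(rep(TRUE, 8), rep(FALSE, 3), rep(TRUE, 2), rep(FALSE, 17))
    names(lab) <- c(paste0("w", 1:11), paste0("r", 1:19))
    ct <- crosstabFR4(ann, lab)
    expect_identical(ct$counts["W", "lambda"], 8L)
    expect_identical(ct$counts["R_other", "nonLambda"], 17L)
    expect_equal(ct$pctLambdaW, 80)
    expect_equal(ct$pctNonLambdaR, 85)
    expect_identical(sum(ct$counts), 30L)

    # fully coupled labels give 100 / 100
    lab2 <- stats::setNames(grepl("^w", names(lab)), names(lab))
    ct2 <- crosstabFR4(ann, lab2)
    expect_equal(ct2$pctLambdaW, 100)
    expect_equal(ct2$pctNonLambdaR, 100)
})

test_that("campaign summaries count candidates and specific families", {
    cd <- c(s1 = "AAAAA", s2 = "AAAAA", s3 = "DDDDD", s4 = "GGGGG",
            s5 = "GGGGG", s6 = "TTTTT", s7 = "TTTTT", s8 = "SSSSS",
            s9 = "SSSSS", s10 = "YYYYY")
    fams <- clusterClonotypes(cd)
    pos <- stats::setNames(c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE,
                             FALSE, TRUE, FALSE, FALSE), names(cd))
    cs <- campaignSummary("toy", pos, fams)
    expect_identical(cs$totalScreened, 10L)
    expect_identical(cs$antigenSpecific, 4L)
    expect_equal(cs$percentSpecific, 40)
    expect_identical(cs$totalFamilies, 6L)
    expect_identical(cs$specificFamilies, 3L)
    expect_true(is.na(cs$lambdaPercent))
    cs2 <- campaignSummary("toy", pos, fams,
                           lambdaPositive = stats::setNames(
                               c(TRUE, rep(FALSE, 9)), names(cd)))
    expect_equal(cs2$lambdaPercent, 10)
})

test_that("cohort summaries reproduce the packaged campaign arithmetic", {
    tab <- campaignData()
    s <- summarizeCampaigns(tab)
    cs <- s$columnStats
    expect_equal(cs$mean[cs$column == "specificFamilies"], 24.8)
    expect_equal(cs$mean[cs$column == "totalFamilies"], 113.1)
    expect_equal(s$pooled$totalScreened, 2600)
    expect_equal(s$pooled$lambdaPositive, 122)
    expect_equal(s$pooled$lambdaScreened, 2426)
    # single row -> statistics equal that row
    one <- summarizeCampaigns(tab[1, ])
    expect_equal(one$columnStats$mean, one$columnStats$min)
    expect_equal(one$pooled$totalScreened, tab$totalScreened[1])
})
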