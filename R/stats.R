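#' @include clonotype.R
NULL

#' V-gene usage profile of a sample
#'
#' Fraction of pass-filter sequences (or of reads, when
#' \code{weightByReads = TRUE}) assigned to each V gene. Genes supplied via
#' \code{genes} but absent from the assignments get frequency 0, so decoy
#' genes always appear in the profile. Frequencies sum to 1.
#'
#' @param x an [AnnotatedRepertoire-class] with at least one pass-filter
#'   sequence.
#' @param weightByReads weight sequences by \code{readCount} instead of
#'   counting each unique sequence once (default \code{FALSE}: usage is
#'   molecule-level).
#' @param genes optional character vector fixing the profile's gene set
#'   (e.g. \code{germlineNames()} of the reference used).
#' @return named numeric vector of frequencies with attributes
#'   \code{sampleId} and \code{nSequences}.
#' @export
vGeneUsage <- function(x, weightByReads = FALSE, genes = NULL) {
    stopifnot(is(x, "AnnotatedRepertoire"))
    keep <- x@ann$passFilter
    if (!any(keep)) stop("sample has no pass-filter sequences")
    calls <- x@ann$vCall[keep]
    w <- if (weightByReads) as.numeric(x@info$readCount[keep])
         else rep(1, sum(keep))
    lev <- if (is.null(genes)) sort(unique(calls))
           else union(genes, unique(calls))
    freq <- vapply(split(w, factor(calls, levels = lev)), sum, numeric(1))
    freq <- freq / sum(freq)
    structure(freq,
              sampleId = paste(unique(x@info$animalId), collapse = "+"),
              nSequences = sum(keep))
}

#' Average usage profiles across samples
#'
#' Unweighted arithmetic mean of per-gene frequencies across animal
#' profiles (each animal counts equally regardless of sequencing depth).
#'
#' @param profiles list of profiles from [vGeneUsage()].
#' @return named numeric vector over the union of genes; sums to 1.
#' @export
averageUsage <- function(profiles) {
    stopifnot(length(profiles) >= 1)
    genes <- sort(unique(unlist(lapply(profiles, names))))
    m <- vapply(profiles, function(p) {
        v <- stats::setNames(numeric(length(genes)), genes)
        v[names(p)] <- p
        v
    }, numeric(length(genes)))
    rowMeans(matrix(m, nrow = length(genes), dimnames = list(genes)))
}

#' Usage limit of detection from decoy genes
#'
#' The limit of detection is the frequency below which spurious matches
#' occur: the maximum per-sample frequency attained by any decoy gene (a
#' gene present in the alignment reference but absent from the genome)
#' across all profiles. Genes should only be called "detected" above this
#' threshold. Adding samples can only raise or preserve the threshold.
#'
#' @param profiles list of profiles from [vGeneUsage()].
#' @param decoyGenes non-empty character vector of decoy gene names.
#' @return the frequency threshold (0 when no decoy is ever assigned).
#' @export
detectionLimit <- function(profiles, decoyGenes) {
    if (!length(decoyGenes)) stop("decoy gene set must be non-empty")
    hits <- unlist(lapply(profiles, function(p)
        p[intersect(names(p), decoyGenes)]))
    if (!length(hits)) 0 else max(0, hits)
}

#' Call ELISA positivity
#'
#' Normalises each supernatant's luminescence by the mean background
#' signal and calls a well positive when the ratio is at least 30-fold
#' over background (a ratio of exactly 30 is positive).
#'
#' @param measurements data.frame as from [readElisaCsv()] (columns
#'   \code{supernatantId}, \code{antigen}, \code{signal},
#'   \code{isBackground}); must contain at least one background well.
#' @param threshold fold-over-background required (default 30).
#' @return data.frame with one row per non-background supernatant:
#'   \code{supernatantId}, \code{antigen}, \code{ratio}, \code{positive}.
#' @examples
#' m <- data.frame(supernatantId = c("b1", "b2", "s1"),
#'                 antigen = "ag", signal = c(90, 110, 3000),
#'                 isBackground = c(TRUE, TRUE, FALSE))
#' elisaCall(m)  # ratio 30 -> positive
#' @export
elisaCall <- function(measurements, threshold = 30) {
    need <- c("supernatantId", "antigen", "signal", "isBackground")
    stopifnot(all(need %in% colnames(measurements)))
    out <- do.call(rbind, lapply(split(measurements, measurements$antigen),
        function(m) {
            bg <- m$signal[m$isBackground]
            if (!length(bg))
                stop("no background wells for antigen '", m$antigen[1], "'")
            s <- m[!m$isBackground, , drop = FALSE]
            data.frame(supernatantId = s$supernatantId,
                       antigen = s$antigen,
                       ratio = s$signal / mean(bg),
                       positive = s$signal / mean(bg) >= threshold,
                       stringsAsFactors = FALSE)
        }))
    rownames(out) <- NULL
    out
}

#' Somatic hypermutation distribution by category
#'
#' Bins sequences by their V-region mismatch count and converts bin counts
#' to percentages within each labelled category (e.g. antigen-specific
#' vs. lambda-binding). Percentages per category sum to 100.
#'
#' @param x an [AnnotatedRepertoire-class].
#' @param labels named character vector mapping sequence ids to category
#'   labels; every labelled id must be annotated in \code{x}.
#' @return data.frame with columns \code{category}, \code{shm} (mismatch
#'   bin), \code{count}, \code{percent}.
#' @export
shmDistribution <- function(x, labels) {
    stopifnot(is(x, "AnnotatedRepertoire"))
    unknown <- setdiff(names(labels), x@info$sequenceId)
    if (length(unknown))
        stop("label(s) for unknown sequence id: ",
             paste(utils::head(unknown, 3), collapse = ", "))
    shm <- shmCount(x)[names(labels)]
    if (anyNA(shm))
        stop("labelled sequences must all be annotated (non-NA shm count)")
    bins <- 0:max(shm)
    grp <- split(shm, unname(labels))
    out <- do.call(rbind, lapply(names(grp), function(cat) {
        s <- grp[[cat]]
        cnt <- vapply(bins, function(b) sum(s == b), integer(1))
        data.frame(category = cat, shm = bins, count = cnt,
                   percent = 100 * cnt / length(s),
                   stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
    out
}

#' Cross-tabulate the FR4 motif residue against lambda binding
#'
#' Builds the 2 x 2 table of (residue at the FR4 conserved-motif position:
#' wild-type W vs. R/other) against lambda-light-chain binding, and the two
#' headline percentages: the share of lambda binders carrying the wild-type
#' tryptophan and the share of non-binders carrying the engineered
#' arginine (or another substitution). Sequences with an unaligned motif
#' residue are excluded and reported via the \code{nExcluded} attribute.
#'
#' @param x an [AnnotatedRepertoire-class].
#' @param lambdaLabels named logical vector mapping sequence ids to lambda
#'   binding.
#' @return list with \code{counts} (2 x 2 integer matrix, rows
#'   \code{W} / \code{R_other}, columns \code{lambda} / \code{nonLambda}),
#'   \code{pctLambdaW}, \code{pctNonLambdaR}; attribute \code{nExcluded}.
#' @export
crosstabFR4 <- function(x, lambdaLabels) {
    stopifnot(is(x, "AnnotatedRepertoire"), is.logical(lambdaLabels))
    res <- fr4Residue(x)[names(lambdaLabels)]
    keep <- !is.na(res)
    res <- res[keep]; lab <- lambdaLabels[keep]
    counts <- matrix(c(
        sum(res == "W" & lab), sum(res != "W" & lab),
        sum(res == "W" & !lab), sum(res != "W" & !lab)),
        nrow = 2, dimnames = list(c("W", "R_other"),
                                  c("lambda", "nonLambda")))
    structure(list(
        counts = counts,
        pctLambdaW = 100 * counts["W", "lambda"] /
            max(sum(counts[, "lambda"]), 1L),
        pctNonLambdaR = 100 * counts["R_other", "nonLambda"] /
            max(sum(counts[, "nonLambda"]), 1L)),
        nExcluded = sum(!keep))
}

#' Summarise one discovery campaign
#'
#' Table-style per-antigen metrics for a screened candidate set: counts of
#' antigen-specific candidates, clonotype families screened, families with
#' at least one antigen-positive member, and (when a lambda assay was run)
#' the percentage of lambda-binding candidates.
#'
#' @param antigen antigen label.
#' @param antigenPositive named logical vector over the screened sequence
#'   ids (ELISA calls against the antigen).
#' @param families a [ClonotypeTable-class] clustering of the screened set.
#' @param lambdaPositive optional named logical vector of lambda ELISA
#'   calls; \code{NULL} (not tested) yields \code{NA} lambda percentage.
#' @return one-row data.frame with columns \code{antigen},
#'   \code{totalScreened}, \code{antigenSpecific}, \code{percentSpecific},
#'   \code{totalFamilies}, \code{specificFamilies}, \code{lambdaPercent}.
#' @export
campaignSummary <- function(antigen, antigenPositive, families,
                            lambdaPositive = NULL) {
    stopifnot(is.logical(antigenPositive), is(families, "ClonotypeTable"))
    total <- length(antigenPositive)
    pos <- sum(antigenPositive)
    specFam <- sum(vapply(families@members, function(m)
        any(antigenPositive[m] %in% TRUE), logical(1)))
    data.frame(
        antigen = antigen,
        totalScreened = total,
        antigenSpecific = pos,
        percentSpecific = 100 * pos / total,
        totalFamilies = nFamilies(families),
        specificFamilies = specFam,
        lambdaPercent = if (is.null(lambdaPositive)) NA_real_
                        else 100 * sum(lambdaPositive) / total,
        stringsAsFactors = FALSE
    )
}

#' Cohort statistics over campaign summaries
#'
#' Aggregates per-antigen campaign rows: unweighted mean/min/max of each
#' numeric column, pooled screening totals, and the pooled lambda-binding
#' percentage over campaigns with lambda data. Lambda-positive counts are
#' reconstructed from each row's percentage as
#' \code{round(lambdaPercent * totalScreened / 100)} when only percentages
#' are recorded.
#'
#' @param rows data.frame of campaign rows as from [campaignSummary()] (at
#'   least \code{totalScreened}, \code{antigenSpecific},
#'   \code{totalFamilies}, \code{specificFamilies}, \code{lambdaPercent}).
#' @return list with \code{columnStats} (data.frame: column, mean, min,
#'   max) and \code{pooled} (named list: \code{totalScreened},
#'   \code{antigenSpecific}, \code{percentSpecific},
#'   \code{lambdaScreened}, \code{lambdaPositive}, \code{lambdaPercent}).
#' @examples
#' summarizeCampaigns(campaignData())$columnStats
#' @export
summarizeCampaigns <- function(rows) {
    stopifnot(nrow(rows) >= 1)
    num <- c("totalScreened", "antigenSpecific", "percentSpecific",
             "totalFamilies", "specificFamilies", "lambdaPercent")
    num <- intersect(num, colnames(rows))
    columnStats <- data.frame(
        column = num,
        mean = vapply(num, function(cn) mean(rows[[cn]], na.rm = TRUE),
                      numeric(1)),
        min = vapply(num, function(cn) min(rows[[cn]], na.rm = TRUE),
                     numeric(1)),
        max = vapply(num, function(cn) max(rows[[cn]], na.rm = TRUE),
                     numeric(1)),
        row.names = NULL, stringsAsFactors = FALSE
    )
    hasL <- !is.na(rows$lambdaPercent)
    lamPos <- round(rows$lambdaPercent[hasL] *
                    rows$totalScreened[hasL] / 100)
    list(
        columnStats = columnStats,
        pooled = list(
            totalScreened = sum(rows$totalScreened),
            antigenSpecific = sum(rows$antigenSpecific),
            percentSpecific = 100 * sum(rows$antigenSpecific) /
                sum(rows$totalScreened),
            lambdaScreened = sum(rows$totalScreened[hasL]),
            lambdaPositive = sum(lamPos),
            lambdaPercent = if (any(hasL))
                100 * sum(lamPos) / sum(rows$totalScreened[hasL])
                else NA_real_
        )
    )
}

#' Packaged discovery-campaign summary data
#'
#' Per-antigen screening metrics from a published ten-antigen
#' heavy-chain-only antibody discovery programme in transgenic rats,
#' shipped as a plain CSV: candidates screened, antigen-specific counts,
#' clonotype families screened and antigen-specific families (CDR3
#' families at 80\% similarity), and the percentage of candidates binding
#' free lambda light chain (one campaign was not lambda-assayed).
#'
#' @return data.frame with one row per antigen and the columns of
#'   [campaignSummary()].
#' @export
campaignData <- function() {
    path <- system.file("extdata", "hcab_campaigns.csv",
                        package = "hcabrep", mustWork = TRUE)
    tab <- utils::read.csv(path, stringsAsFactors = FALSE)
    tab$percentSpecific <- 100 * tab$antigenSpecific / tab$totalScreened
    tab
}
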