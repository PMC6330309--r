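#' @include repertoire.R
NULL

#' CDR3 amino-acid similarity
#'
#' Normalised Levenshtein similarity between CDR3 strings:
#' \code{1 - editDistance(a, b) / max(nchar(a), nchar(b))}. Symmetric, 1
#' exactly for identical strings, and robust to junction length variation.
#' With \code{method = "hamming"} a same-length Hamming similarity is used
#' instead (error for unequal lengths).
#'
#' @param a,b character vectors of CDR3 amino-acid strings (recycled).
#' @param method \code{"levenshtein"} (default) or \code{"hamming"}.
#' @return numeric vector of similarities in \[0, 1\].
#' @examples
#' cdr3Similarity("ARDYW", "ARDFW")  # 0.8
#' @export
cdr3Similarity <- function(a, b, method = c("levenshtein", "hamming")) {
    method <- match.arg(method)
    if (any(!nzchar(a)) || any(!nzchar(b)) || anyNA(a) || anyNA(b))
        stop("CDR3 strings must be non-empty")
    n <- max(length(a), length(b))
    a <- rep_len(a, n); b <- rep_len(b, n)
    if (method == "hamming") {
        if (any(nchar(a) != nchar(b)))
            stop("hamming similarity requires equal-length CDR3s")
        d <- mapply(function(x, y)
            sum(strsplit(x, "")[[1]] != strsplit(y, "")[[1]]), a, b)
        return(unname(1 - d / nchar(a)))
    }
    d <- diag(utils::adist(a, b))
    unname(1 - d / pmax(nchar(a), nchar(b)))
}

.similarityMatrix <- function(cdr3s, method) {
    if (method == "hamming") {
        if (length(unique(nchar(cdr3s))) > 1)
            stop("hamming similarity requires equal-length CDR3s")
        n <- nchar(cdr3s[1])
        1 - utils::adist(cdr3s, costs = list(ins = n, del = n, sub = 1)) / n
    } else {
        1 - utils::adist(cdr3s) / outer(nchar(cdr3s), nchar(cdr3s), pmax)
    }
}

## Partition unique CDR3 strings at a similarity threshold.
.clusterCdr3 <- function(cdr3s, threshold, linkage, method) {
    if (length(cdr3s) == 1L) return(1L)
    sim <- .similarityMatrix(cdr3s, method)
    hc <- stats::hclust(stats::as.dist(1 - sim), method = linkage)
    ## cut so that pairs with similarity >= threshold (distance <=
    ## 1 - threshold) are merged; with single linkage this is exactly the
    ## connected components of the threshold graph
    stats::cutree(hc, h = (1 - threshold) + 1e-12)
}

#' Cluster sequences into clonotype families
#'
#' Groups annotated sequences into clonotype families: single-linkage
#' agglomerative clustering on CDR3 distance \code{1 - similarity}, cut at
#' \code{1 - threshold}, which is exactly the connected components of the
#' graph joining pairs with CDR3 similarity at or above the threshold
#' (default 0.8). The partition is invariant to input order. Families are
#' then ranked by read abundance (see [rankClonotypes()]).
#'
#' @param x an [AnnotatedRepertoire-class] (pass-filter, annotatable
#'   sequences are clustered), or a named character vector of CDR3 strings.
#' @param threshold similarity threshold in (0, 1\]; default 0.8.
#' @param linkage \code{"single"} (default; the 80\% rule then composes
#'   into families transitively) or \code{"complete"}.
#' @param method string similarity, \code{"levenshtein"} or
#'   \code{"hamming"}.
#' @param byVJ when \code{TRUE}, restrict families to sequences sharing the
#'   same V and J call (off by default).
#' @param readCount optional named read weights when \code{x} is a
#'   character vector.
#' @return A [ClonotypeTable-class].
#' @examples
#' fams <- clusterClonotypes(c(a = "ARDYW", b = "ARDFW", c = "GGGGGGGG"))
#' familyTable(fams)
#' @export
clusterClonotypes <- function(x, threshold = 0.8,
                              linkage = c("single", "complete"),
                              method = c("levenshtein", "hamming"),
                              byVJ = FALSE, readCount = NULL) {
    linkage <- match.arg(linkage)
    method <- match.arg(method)
    stopifnot(threshold > 0, threshold <= 1)
    if (is(x, "AnnotatedRepertoire")) {
        keep <- x@ann$passFilter & x@ann$annotatable
        ids <- x@info$sequenceId[keep]
        cd <- stats::setNames(x@ann$cdr3[keep], ids)
        rc <- readCounts(x)[ids]
        gate <- if (byVJ) paste(x@ann$vCall[keep], x@ann$jCall[keep])
                else rep("", sum(keep))
    } else {
        cd <- x
        if (is.null(names(cd)) && length(cd))
            names(cd) <- paste0("seq", seq_along(cd))
        ids <- names(cd)
        rc <- if (is.null(readCount))
            stats::setNames(rep(1L, length(cd)), ids) else readCount[ids]
        gate <- rep("", length(cd))
    }
    if (!length(cd))
        return(new("ClonotypeTable",
                   families = DataFrame(familyId = integer(),
                       rank = integer(), readFraction = numeric(),
                       nMembers = integer(),
                       representativeCdr3 = character()),
                   members = list(), threshold = threshold,
                   linkage = linkage))
    if (any(!nzchar(cd) | is.na(cd)))
        stop("all sequences must carry a non-empty CDR3")

    memb <- integer(length(cd))
    offset <- 0L
    for (g in unique(gate)) {
        sel <- which(gate == g)
        uniq <- sort(unique(cd[sel]))  # sort: order invariance
        cl <- .clusterCdr3(uniq, threshold, linkage, method)
        memb[sel] <- offset + cl[match(cd[sel], uniq)]
        offset <- offset + max(cl)
    }
    members <- split(ids, memb)
    fams <- lapply(members, identity)
    tab <- new("ClonotypeTable",
        families = DataFrame(
            familyId = seq_along(fams),
            rank = NA_integer_,
            readFraction = NA_real_,
            nMembers = unname(lengths(fams)),
            representativeCdr3 = NA_character_),
        members = unname(fams),
        threshold = threshold, linkage = linkage)
    rankClonotypes(tab, readCount = rc, cdr3 = cd)
}

#' Rank clonotype families by read abundance
#'
#' Assigns each family its fraction of total sample reads and a dense rank
#' (1 = most abundant; ties broken by lexicographic representative CDR3).
#' The representative CDR3 is the most abundant member's CDR3.
#'
#' @param x a [ClonotypeTable-class].
#' @param readCount named numeric of per-sequence read counts.
#' @param cdr3 named character of per-sequence CDR3s.
#' @return The [ClonotypeTable-class] with \code{rank},
#'   \code{readFraction} and \code{representativeCdr3} filled in, rows
#'   ordered by rank.
#' @export
rankClonotypes <- function(x, readCount, cdr3) {
    stopifnot(is(x, "ClonotypeTable"))
    total <- sum(readCount[unlist(x@members)])
    if (!isTRUE(total > 0)) stop("total read count must be positive")
    frac <- vapply(x@members, function(m) sum(readCount[m]) / total,
                   numeric(1))
    rep3 <- vapply(x@members, function(m) {
        rc <- readCount[m]
        cands <- cdr3[m[rc == max(rc)]]
        sort(cands)[1L]
    }, character(1))
    o <- order(-frac, rep3)
    fam <- x@families[o, , drop = FALSE]
    fam$rank <- seq_along(o)
    fam$readFraction <- frac[o]
    fam$representativeCdr3 <- rep3[o]
    fam$familyId <- seq_along(o)
    initialize(x, families = fam, members = x@members[o])
}

#' @describeIn ClonotypeTable the per-family summary table.
#' @param x a \code{ClonotypeTable}.
#' @export
setMethod("familyTable", "ClonotypeTable", function(x) x@families)

#' @describeIn ClonotypeTable list of member sequence ids per family, in
#'   rank order.
#' @export
setMethod("familyMembers", "ClonotypeTable", function(x) {
    stats::setNames(x@members, x@families$familyId)
})

#' @describeIn ClonotypeTable number of families.
#' @export
setMethod("nFamilies", "ClonotypeTable", function(x) nrow(x@families))

#' @export
setMethod("length", "ClonotypeTable", function(x) nrow(x@families))

#' @export
setMethod("show", "ClonotypeTable", function(object) {
    cat(sprintf(
        "ClonotypeTable: %d families over %d sequences (threshold %.2f, %s linkage)\n",
        nFamilies(object), sum(object@families$nMembers),
        object@threshold, object@linkage))
    if (nFamilies(object))
        cat(sprintf("  top family: %s (%.1f%% of reads, %d members)\n",
                    object@families$representativeCdr3[1],
                    100 * object@families$readFraction[1],
                    object@families$nMembers[1]))
})

#' Select screening candidates from ranked families
#'
#' Emulates abundance-prioritised candidate picking for a primary screen:
#' walk families in rank order, taking up to \code{nPerFamily} most
#' abundant distinct sequences from each, until \code{maxCandidates} have
#' been collected. Returned candidates are pairwise distinct at the
#' full-sequence level, so a family whose members are all copies of one
#' sequence contributes a single candidate.
#'
#' @param x a ranked [ClonotypeTable-class].
#' @param rep the [Repertoire-class] (or [AnnotatedRepertoire-class]) the
#'   families were built from.
#' @param nPerFamily maximum candidates drawn from one family.
#' @param maxCandidates total candidate budget.
#' @return character vector of selected sequence ids.
#' @export
selectCandidates <- function(x, rep, nPerFamily = 3L, maxCandidates = 300L) {
    stopifnot(is(x, "ClonotypeTable"), is(rep, "Repertoire"))
    rc <- readCounts(rep)
    seqs <- stats::setNames(as.character(aaSequences(rep)),
                            sequenceIds(rep))
    chosen <- character(0)
    seen <- character(0)
    for (m in x@members) {
        o <- m[order(-rc[m], m)]
        take <- 0L
        for (id in o) {
            if (take >= nPerFamily || length(chosen) >= maxCandidates) break
            if (seqs[[id]] %in% seen) next
            chosen <- c(chosen, id)
            seen <- c(seen, seqs[[id]])
            take <- take + 1L
        }
        if (length(chosen) >= maxCandidates) break
    }
    chosen
}
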