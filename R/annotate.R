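#' @include germline.R repertoire.R
#' @importFrom Biostrings pairwiseAlignment nmatch nmismatch mismatchTable
#'   pattern subject indel width
#' @importFrom IRanges start end
NULL

## Alignment scheme (fixed for reproducibility): BLOSUM62, affine gaps
## (open 10, extend 1), germline global / query local, so the full germline
## segment span is consumed and the query contributes a substring.
.GAP_OPEN <- 10
.GAP_EXT <- 1

.alignBatch <- function(queries, germSeq) {
    pa <- pairwiseAlignment(
        pattern = queries, subject = Biostrings::AAString(germSeq),
        type = "local-global", substitutionMatrix = "BLOSUM62",
        gapOpening = .GAP_OPEN, gapExtension = .GAP_EXT
    )
    list(
        score = Biostrings::score(pa),
        nmatch = nmatch(pa),
        nmismatch = nmismatch(pa),
        ps = start(pattern(pa)), pe = end(pattern(pa)),
        ss = start(subject(pa)), es = end(subject(pa)),
        pgS = as.list(start(indel(pattern(pa)))),
        pgW = as.list(width(indel(pattern(pa)))),
        sgS = as.list(start(indel(subject(pa)))),
        sgW = as.list(width(indel(subject(pa)))),
        mm = mismatchTable(pa)
    )
}

## Aligned (query, germline) position pairs of alignment i in a batch,
## reconstructed from the alignment-column coordinates of the gap ranges.
## Both coordinates 1-based; strictly increasing in both.
.alignPairs <- function(b, i) {
    ncolTotal <- (b$pe[i] - b$ps[i] + 1L) +
        sum(rep.int(1L, length(b$pgS[[i]])) * b$pgW[[i]])
    pgap <- sgap <- logical(ncolTotal)
    if (length(b$pgS[[i]]))
        pgap[unlist(Map(seq.int,
            b$pgS[[i]], b$pgS[[i]] + b$pgW[[i]] - 1L))] <- TRUE
    if (length(b$sgS[[i]]))
        sgap[unlist(Map(seq.int,
            b$sgS[[i]], b$sgS[[i]] + b$sgW[[i]] - 1L))] <- TRUE
    qpos <- b$ps[i] - 1L + cumsum(!pgap)
    gpos <- b$ss[i] - 1L + cumsum(!sgap)
    keep <- !pgap & !sgap
    cbind(query = qpos[keep], germline = gpos[keep])
}

## Query cut point (1-based) for a 0-based germline boundary b: position of
## the first aligned query residue at or beyond germline index b; one past
## the last aligned residue when b lies beyond the alignment.
.cutAt <- function(pairs, b) {
    hit <- pairs[, "germline"] >= b + 1L
    if (any(hit)) pairs[which(hit)[1L], "query"]
    else pairs[nrow(pairs), "query"] + 1L
}

## Germline span used for alignment. V genes align over their full span;
## J genes align over the FR4 span only (conserved motif onward), because
## the junction-proximal J residues lie inside CDR3, whose content is
## sample-dependent -- anchoring on FR4 keeps the motif projection and the
## CDR3/FR4 boundary register stable.
.alignSpan <- function(germline, gene) {
    i <- match(gene, germlineNames(germline))
    s <- as.character(germline@aa[[i]])
    if (germline@segment[i] == "J" && !is.na(germline@fr4Offset[i]))
        substr(s, germline@fr4Offset[i] + 1L, nchar(s))
    else s
}

.bestGene <- function(x, germline, segment, minAligned) {
    if (!is(x, "Repertoire")) x <- Repertoire(x)
    genes <- germlineNames(germline)[segmentType(germline) == segment]
    if (!length(genes))
        stop("reference contains no ", segment, " segments")
    queries <- aaSequences(x)
    n <- length(queries)
    score <- ident <- matrix(NA_real_, n, length(genes),
                             dimnames = list(NULL, genes))
    alen <- matrix(NA_integer_, n, length(genes))
    colnames(alen) <- genes
    for (g in genes) {
        b <- .alignBatch(queries, .alignSpan(germline, g))
        score[, g] <- b$score
        alen[, g] <- b$nmatch + b$nmismatch
        ident[, g] <- b$nmatch / pmax(b$nmatch + b$nmismatch, 1L)
    }
    ## best score; ties broken by higher identity, then gene name
    best <- character(n)
    for (i in seq_len(n)) {
        cand <- which(score[i, ] == max(score[i, ]))
        if (length(cand) > 1L)
            cand <- cand[ident[i, cand] == max(ident[i, cand])]
        best[i] <- sort(genes[cand])[1L]
    }
    bi <- cbind(seq_len(n), match(best, genes))
    DataFrame(
        sequenceId = sequenceIds(x),
        gene = best,
        score = score[bi],
        identity = ident[bi],
        alignedLength = alen[bi],
        passFilter = alen[bi] >= minAligned
    )
}

#' Assign germline V genes
#'
#' Aligns each repertoire sequence against every V-segment reference
#' (BLOSUM62, affine gaps, germline-global) and returns the highest-scoring
#' gene, with ties broken by higher identity and then lexicographic gene
#' name. Sequences whose alignment spans fewer than \code{minAligned}
#' residues fail the filter -- the amino-acid analogue (ceiling(20/3) = 7)
#' of discarding reads with under 20 nucleotides of Ig-locus alignment.
#'
#' @param x a [Repertoire-class] (or named character vector of sequences).
#' @param germline a [GermlineSet-class] containing V segments.
#' @param minAligned minimum aligned (non-gap) residues (default 7).
#' @return [S4Vectors::DataFrame] with columns \code{sequenceId},
#'   \code{gene}, \code{score}, \code{identity}, \code{alignedLength},
#'   \code{passFilter}.
#' @examples
#' gl <- toyGermlineSet()
#' v <- as.character(aaSequences(gl)[["IGHV3-23*01"]])
#' assignVGene(c(read1 = paste0(v, "ARDRSY", "RGQGTLVTVSS")), gl)
#' @export
assignVGene <- function(x, germline, minAligned = 7L) {
    .bestGene(x, germline, "V", minAligned)
}

#' Assign germline J genes
#'
#' Companion of [assignVGene()] for J segments; the same scoring scheme and
#' tie rules apply, but each J gene is aligned over its FR4 span only
#' (conserved W-G-x-G motif onward): the junction-proximal J residues lie
#' inside CDR3, whose content varies per rearrangement, so anchoring on FR4
#' keeps the motif projection stable.
#'
#' @inheritParams assignVGene
#' @return [S4Vectors::DataFrame] as for [assignVGene()].
#' @export
assignJGene <- function(x, germline, minAligned = 7L) {
    .bestGene(x, germline, "J", minAligned)
}

#' Align one query to one germline gene
#'
#' Single-pair version of the scheme used throughout annotation, returning
#' the matched position pairs; mainly useful for inspection and testing.
#'
#' @param query amino-acid string.
#' @param germline a [GermlineSet-class].
#' @param gene germline gene name.
#' @return list with \code{score}, \code{identity}, \code{alignedLength}
#'   and the strictly increasing \code{pairs} matrix of matched (query,
#'   germline) 1-based positions.
#' @export
alignGermline <- function(query, germline, gene) {
    i <- match(gene, germlineNames(germline))
    if (is.na(i)) stop("unknown gene: ", gene)
    b <- .alignBatch(Biostrings::AAStringSet(query),
                     as.character(germline@aa[[i]]))
    list(score = b$score[1], identity = b$nmatch[1] /
             max(b$nmatch[1] + b$nmismatch[1], 1L),
         alignedLength = b$nmatch[1] + b$nmismatch[1],
         pairs = .alignPairs(b, 1L))
}

#' Annotate a repertoire against a germline reference
#'
#' Full germline annotation: V and J gene assignment, projection of the
#' V-segment region boundaries and the J-segment FR4 motif onto the query
#' through the alignment, extraction of FR1..FR4 and CDR1..CDR3 substrings,
#' somatic-hypermutation counting (amino-acid substitutions over aligned
#' V-region positions, gaps excluded) and the residue observed at the FR4
#' conserved-motif position. CDR3 spans from the end of the projected FR3
#' to the start of the projected J motif region.
#'
#' Sequences failing the minimum-alignment filter keep their calls but are
#' flagged \code{passFilter = FALSE}; sequences whose CDR3 projection is
#' empty or inverted (e.g. a bare germline V with no J) are flagged
#' \code{annotatable = FALSE} with \code{NA} regions.
#'
#' @inheritParams assignVGene
#' @return An [AnnotatedRepertoire-class].
#' @examples
#' gl <- toyGermlineSet()
#' v <- as.character(aaSequences(gl)[["IGHV3-23*01"]])
#' rep <- Repertoire(c(s1 = paste0(v, "ARDRSY", "RGQGTLVTVSS")))
#' ann <- annotateRepertoire(rep, gl)
#' cdr3(ann)
#' @export
annotateRepertoire <- function(x, germline, minAligned = 7L) {
    stopifnot(is(x, "Repertoire"))
    vres <- assignVGene(x, germline, minAligned)
    jres <- assignJGene(x, germline, minAligned)
    n <- length(x)
    qchr <- as.character(x@aa)
    queries <- x@aa

    reg <- matrix(NA_character_, n, 7,
                  dimnames = list(NULL, c("fr1", "cdr1", "fr2", "cdr2",
                                          "fr3", "cdr3", "fr4")))
    shm <- rep(NA_integer_, n)
    fr4res <- rep(NA_character_, n)
    vEnd <- rep(NA_integer_, n)    # query cut at end of projected FR3
    jStart <- rep(NA_integer_, n)  # query cut at start of projected FR4
    jEnd <- rep(NA_integer_, n)

    for (g in unique(vres$gene)) {
        idx <- which(vres$gene == g)
        b <- .alignBatch(queries[idx], as.character(germline@aa[[g]]))
        bounds <- regionBounds(germline, g)
        cuts <- c(bounds[, "start"], bounds[5, "end"])
        mmBySeq <- split(b$mm$SubjectStart, factor(b$mm$PatternId,
                                                   levels = seq_along(idx)))
        for (k in seq_along(idx)) {
            i <- idx[k]
            pairs <- .alignPairs(b, k)
            q <- vapply(cuts, function(bb) .cutAt(pairs, bb), integer(1))
            if (is.unsorted(q)) next  # projection degenerate
            for (r in 1:5)
                reg[i, r] <- substr(qchr[i], q[r], q[r + 1] - 1L)
            vEnd[i] <- q[6]
            shm[i] <- sum(mmBySeq[[k]] <= bounds[5, "end"])
        }
    }

    for (g in unique(jres$gene)) {
        idx <- which(jres$gene == g)
        if (is.na(fr4MotifOffset(germline)[[g]]))
            stop("J gene '", g, "' has no fr4 motif offset")
        ## aligned over the FR4 span: germline position 1 is the motif
        b <- .alignBatch(queries[idx], .alignSpan(germline, g))
        for (k in seq_along(idx)) {
            i <- idx[k]
            pairs <- .alignPairs(b, k)
            jStart[i] <- pairs[1L, "query"]
            jEnd[i] <- pairs[nrow(pairs), "query"]
            exact <- pairs[, "germline"] == 1L
            if (any(exact))
                fr4res[i] <- substr(qchr[i], pairs[exact, "query"][1],
                                    pairs[exact, "query"][1])
        }
    }

    pass <- vres$passFilter & jres$passFilter
    annotatable <- pass & !is.na(vEnd) & !is.na(jStart) & jStart > vEnd
    ok <- which(annotatable)
    reg[ok, "cdr3"] <- substr(qchr[ok], vEnd[ok], jStart[ok] - 1L)
    reg[ok, "fr4"] <- substr(qchr[ok], jStart[ok], jEnd[ok])
    annotatable[ok] <- nzchar(reg[ok, "cdr3"])
    reg[!annotatable, ] <- NA_character_

    ann <- DataFrame(
        vCall = vres$gene, jCall = jres$gene,
        vScore = vres$score, vIdentity = vres$identity,
        alignedLength = vres$alignedLength,
        shmCount = shm, fr4Residue = fr4res,
        passFilter = pass, annotatable = annotatable,
        fr1 = as.vector(reg[, "fr1"]), cdr1 = as.vector(reg[, "cdr1"]),
        fr2 = as.vector(reg[, "fr2"]), cdr2 = as.vector(reg[, "cdr2"]),
        fr3 = as.vector(reg[, "fr3"]), cdr3 = as.vector(reg[, "cdr3"]),
        fr4 = as.vector(reg[, "fr4"])
    )
    new("AnnotatedRepertoire", aa = x@aa, info = x@info, ann = ann)
}

#' Count somatic hypermutation of one sequence
#'
#' Amino-acid substitutions between a query and its germline V gene over
#' aligned V-region positions (FR1 through FR3, including CDR1/CDR2);
#' alignment gaps and everything downstream of FR3 (the CDR3 junction) are
#' excluded. A germline-identical V region yields 0.
#'
#' @param query amino-acid string.
#' @param germline a [GermlineSet-class].
#' @param gene V gene to count against; defaults to the best-scoring V.
#' @return non-negative integer.
#' @export
countVMismatches <- function(query, germline, gene = NULL) {
    if (is.null(gene))
        gene <- assignVGene(c(q = unname(query)), germline)$gene[1]
    b <- .alignBatch(Biostrings::AAStringSet(query),
                     as.character(germline@aa[[gene]]))
    frEnd <- regionBounds(germline, gene)[5, "end"]
    sum(b$mm$SubjectStart <= frEnd)
}

#' Residue at the FR4 conserved-motif position
#'
#' Returns the query residue aligned to the J gene's conserved W-G-x-G
#' tryptophan position (the residue an engineered variant carries as
#' arginine; conventionally labelled Kabat position 101), or \code{NA} when
#' that germline position is unaligned.
#'
#' @param query amino-acid string.
#' @param germline a [GermlineSet-class].
#' @param jGene J gene to read against; defaults to the best-scoring J.
#' @return single residue character or \code{NA}.
#' @export
motifResidue <- function(query, germline, jGene = NULL) {
    if (is.null(jGene))
        jGene <- assignJGene(c(q = unname(query)), germline)$gene[1]
    off <- fr4MotifOffset(germline)[[jGene]]
    if (is.na(off)) stop("J gene '", jGene, "' has no fr4 motif offset")
    b <- .alignBatch(Biostrings::AAStringSet(unname(query)),
                     .alignSpan(germline, jGene))
    pairs <- .alignPairs(b, 1L)
    exact <- pairs[, "germline"] == 1L
    if (!any(exact)) return(NA_character_)
    substr(query, pairs[exact, "query"][1], pairs[exact, "query"][1])
}
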