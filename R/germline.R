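#' @include AllGenerics.R
NULL

#' Construct a germline gene set
#'
#' Low-level constructor; most users will call [readGermlineFasta()] or
#' [toyGermlineSet()].
#'
#' @param aa named character vector or [Biostrings::AAStringSet] of germline
#'   amino-acid sequences.
#' @param segment character vector of segment types (\code{"V"}, \code{"D"},
#'   \code{"J"}).
#' @param decoy logical vector flagging decoy V genes (absent from the
#'   genome, present in the alignment reference to measure the usage limit
#'   of detection). Default all \code{FALSE}.
#' @param regions named list of 5 x 2 integer matrices (rows FR1, CDR1,
#'   FR2, CDR2, FR3; columns start, end; 0-based half-open) for V genes,
#'   \code{NULL} entries for D/J genes.
#' @param fr4Offset integer vector of 0-based FR4 conserved-motif residue
#'   indices for J genes, \code{NA} otherwise.
#' @return A [GermlineSet-class] object.
#' @export
GermlineSet <- function(aa, segment, decoy = NULL, regions = NULL,
                        fr4Offset = NULL) {
    if (!is(aa, "AAStringSet"))
        aa <- Biostrings::AAStringSet(aa)
    n <- length(aa)
    if (is.null(decoy)) decoy <- rep(FALSE, n)
    if (is.null(regions)) regions <- rep(list(NULL), n)
    if (is.null(fr4Offset)) fr4Offset <- rep(NA_integer_, n)
    new("GermlineSet", aa = aa, segment = as.character(segment),
        decoy = as.logical(decoy), regions = regions,
        fr4Offset = as.integer(fr4Offset))
}

#' @describeIn GermlineSet gene identifiers.
#' @param x a \code{GermlineSet}.
#' @export
setMethod("germlineNames", "GermlineSet", function(x) names(x@aa))

#' @describeIn GermlineSet segment type per gene.
#' @export
setMethod("segmentType", "GermlineSet", function(x) {
    stats::setNames(x@segment, names(x@aa))
})

#' @describeIn GermlineSet decoy flags per gene.
#' @export
setMethod("isDecoy", "GermlineSet", function(x) {
    stats::setNames(x@decoy, names(x@aa))
})

#' @describeIn GermlineSet amino-acid sequences.
#' @export
setMethod("aaSequences", "GermlineSet", function(x) x@aa)

#' @describeIn GermlineSet region boundary matrix (0-based half-open) of one
#'   V gene.
#' @param gene gene identifier.
#' @export
setMethod("regionBounds", "GermlineSet", function(x, gene) {
    i <- match(gene, names(x@aa))
    if (is.na(i)) stop("unknown gene: ", gene)
    x@regions[[i]]
})

#' @describeIn GermlineSet FR4 conserved-motif offsets (0-based) per gene.
#' @export
setMethod("fr4MotifOffset", "GermlineSet", function(x) {
    stats::setNames(x@fr4Offset, names(x@aa))
})

#' @export
setMethod("length", "GermlineSet", function(x) length(x@aa))

#' @export
setMethod("[", "GermlineSet", function(x, i, j, ..., drop = TRUE) {
    if (is.character(i)) i <- match(i, names(x@aa))
    initialize(x, aa = x@aa[i], segment = x@segment[i], decoy = x@decoy[i],
               regions = x@regions[i], fr4Offset = x@fr4Offset[i])
})

#' @export
setMethod("show", "GermlineSet", function(object) {
    tab <- table(factor(object@segment, levels = c("V", "D", "J")))
    cat(sprintf("GermlineSet with %d genes (%d V, %d D, %d J; %d decoy)\n",
                length(object), tab[["V"]], tab[["D"]], tab[["J"]],
                sum(object@decoy)))
    nm <- germlineNames(object)
    cat("  ", paste(utils::head(nm, 8), collapse = " "),
        if (length(nm) > 8) "..." else "", "\n")
})

## ---- FASTA I/O ------------------------------------------------------------

## Header grammar (1-based inclusive coordinates at the file boundary):
##   >NAME segment=V decoy=false regions=FR1:1-25,CDR1:26-33,...
##   >NAME segment=J fr4_motif=5
.parseHeaderTokens <- function(desc) {
    toks <- strsplit(trimws(desc), "\\s+")[[1]]
    kv <- toks[grepl("=", toks, fixed = TRUE)]
    parts <- strsplit(kv, "=", fixed = TRUE)
    stats::setNames(vapply(parts, `[`, "", 2L), vapply(parts, `[`, "", 1L))
}

#' Read a germline reference FASTA
#'
#' Reads germline V/D/J amino-acid segments from a FASTA file whose headers
#' carry structured tokens: \code{segment=V|D|J}, optionally
#' \code{decoy=true|false}, for V genes
#' \code{regions=FR1:1-25,CDR1:26-33,...} (1-based inclusive in the file;
#' converted to 0-based half-open internally) and for J genes
#' \code{fr4_motif=<pos>} (1-based position of the conserved W-G-x-G
#' tryptophan, or of the engineered arginine variant).
#'
#' @param path path to the FASTA file.
#' @return A [GermlineSet-class].
#' @examples
#' fa <- system.file("extdata", "toy_germline.fasta", package = "hcabrep")
#' gl <- readGermlineFasta(fa)
#' gl
#' @export
readGermlineFasta <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path)
    set <- tryCatch(Biostrings::readAAStringSet(path),
        error = function(e) stop("malformed FASTA '", path, "': ",
                                 conditionMessage(e)))
    full <- names(set)
    nm <- sub("\\s.*$", "", full)
    if (anyDuplicated(nm))
        stop("duplicate gene name(s) in ", path, ": ",
             paste(unique(nm[duplicated(nm)]), collapse = ", "))
    segment <- character(length(set))
    decoy <- logical(length(set))
    regions <- vector("list", length(set))
    fr4 <- rep(NA_integer_, length(set))
    for (i in seq_along(set)) {
        kv <- .parseHeaderTokens(sub("^\\S+", "", full[i]))
        if (!"segment" %in% names(kv))
            stop("record '", nm[i], "': header lacks a segment= token")
        segment[i] <- kv[["segment"]]
        decoy[i] <- identical(tolower(kv["decoy"][[1]]), "true")
        if (segment[i] == "V") {
            if (!"regions" %in% names(kv))
                stop("V gene '", nm[i], "' lacks region boundaries")
            ent <- strsplit(strsplit(kv[["regions"]], ",")[[1]], "[:-]")
            m <- matrix(NA_integer_, 5, 2,
                        dimnames = list(V_REGIONS, c("start", "end")))
            for (e in ent) {
                if (length(e) != 3 || !e[1] %in% V_REGIONS)
                    stop("V gene '", nm[i], "': malformed regions token")
                m[e[1], ] <- c(as.integer(e[2]) - 1L, as.integer(e[3]))
            }
            if (anyNA(m))
                stop("V gene '", nm[i], "': incomplete region boundaries")
            regions[[i]] <- m
        }
        if (segment[i] == "J" && "fr4_motif" %in% names(kv))
            fr4[i] <- as.integer(kv[["fr4_motif"]]) - 1L
    }
    names(set) <- nm
    GermlineSet(set, segment, decoy, regions, fr4)
}

#' Write a germline reference FASTA
#'
#' Inverse of [readGermlineFasta()]; coordinates are written 1-based
#' inclusive.
#'
#' @param x a [GermlineSet-class].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeGermlineFasta <- function(x, path) {
    stopifnot(is(x, "GermlineSet"))
    nm <- germlineNames(x)
    hdr <- character(length(x))
    for (i in seq_along(nm)) {
        h <- sprintf("%s segment=%s decoy=%s", nm[i], x@segment[i],
                     tolower(as.character(x@decoy[i])))
        if (x@segment[i] == "V") {
            r <- x@regions[[i]]
            h <- paste0(h, " regions=", paste(sprintf("%s:%d-%d",
                rownames(r), r[, 1] + 1L, r[, 2]), collapse = ","))
        }
        if (!is.na(x@fr4Offset[i]))
            h <- paste0(h, sprintf(" fr4_motif=%d", x@fr4Offset[i] + 1L))
        hdr[i] <- h
    }
    out <- x@aa
    names(out) <- hdr
    Biostrings::writeXStringSet(out, path)
    invisible(path)
}

## ---- packaged synthetic toy reference -------------------------------------

## Synthetic IMGT-style toy reference. Gene names and overall architecture
## follow the human IGH locus; the sequences are hand-built variants of a
## canonical VH3 backbone and are NOT the true IMGT alleles. Region lengths:
## FR1 25, CDR1 7-10, FR2 17, CDR2 7-8, FR3 38. IGHJ4*01 carries the
## engineered arginine at the FR4 conserved-motif position; all other J
## genes carry the wild-type tryptophan.
.TOY_V <- list(
    "IGHV3-23*01" = c("EVQLLESGGGLVQPGGSLRLSCAAS", "GFTFSSYA",
                      "MSWVRQAPGKGLEWVSA", "ISGSGGST",
                      "YYADSVKGRFTISRDNSKNTLYLQMNSLRAEDTAVYYC"),
    "IGHV3-30*01" = c("QVQLVESGGGVVQPGRSLRLSCAAS", "GFTFSSYG",
                      "MHWVRQAPGKGLEWVAV", "ISYDGSNK",
                      "YYADSVKGRFTISRDNSKNTLYLQMNSLRAEDTAVYYC"),
    "IGHV3-7*01"  = c("EVQLVESGGGLVQPGGSLRLSCAAS", "GFTFSSYW",
                      "MSWVRQAPGKGLEWVAN", "IKQDGSEK",
                      "YYVDSVKGRFTISRDNAKNSLYLQMNSLRAEDTAVYYC"),
    "IGHV4-39*01" = c("QLQLQESGPGLVKPSETLSLTCTVS", "GGSISSSSYY",
                      "WSWIRQPPGKGLEWIGS", "IYYSGST",
                      "YYNPSLKSRVTISVDTSKNQFSLKLSSVTAADTAVYYC"),
    "IGHV4-34*01" = c("QVQLQQWGAGLLKPSETLSLTCAVY", "GGSFSGYY",
                      "WSWIRQPPGKGLEWIGE", "INHSGST",
                      "YYNPSLKSRVTISVDTSKNQFSLKLSSVTAADTAVYYC"),
    "IGHV1-69*01" = c("QVQLVQSGAEVKKPGSSVKVSCKAS", "GGTFSSYA",
                      "ISWVRQAPGQGLEWMGG", "IIPIFGTA",
                      "NYAQKFQGRVTITADESTSTAYMELSSLRSEDTAVYYC"),
    ## decoy V genes: absent from the simulated genomes, present in the
    ## alignment reference so spurious matches define the limit of detection
    "IGHV3-NL1*01" = c("EVQLLESGGGLVQPGGSLRLSCAAS", "GFTFSSYA",
                       "MSWVRQAPGKGLEWVSA", "ISGSGGGT",
                       "YYADSVKGRFTISRDNAKNTLYLQMNSLRAEDTALYYC"),
    "IGHV1-45*01"  = c("QMQLVQSGAEVKKPGASVKVSCKAS", "GYTFTSYA",
                       "ISWVRQAPGQGLEWMGW", "INAGNGNT",
                       "NYAQKFQGRVTITADESTNTAYMELSSLRSEDTAVYYC"),
    "IGHV4-28*01"  = c("QVQLQESGPGLVKPSGTLSLTCAVS", "GYSISSSNWW",
                       "GSWVRQPPGKGLEWIGE", "IYHSGST",
                       "NYNPSLKSRVTISVDKSKNQFSLKLSSVTAADTAVYYC")
)
.TOY_V_DECOY <- c("IGHV3-NL1*01", "IGHV1-45*01", "IGHV4-28*01")

.TOY_D <- c(
    "IGHD3-10*01" = "GYSSGWYG",
    "IGHD2-2*01"  = "DIVLMVYAI",
    "IGHD6-19*01" = "GIAVAGTG"
)

.TOY_J <- c(
    "IGHJ1*01" = "AEYFQHWGQGTLVTVSS",
    "IGHJ2*01" = "YWYFDLWGRGTLVTVSS",
    "IGHJ3*01" = "DAFDVWGQGTMVTVSS",
    "IGHJ4*01" = "YFDYRGQGTLVTVSS",   # engineered W->R at the motif position
    "IGHJ5*01" = "NWFDPWGQGTLVTVSS",
    "IGHJ6*01" = "YYYYYGMDVWGQGTTVTVSS"
)

#' Packaged synthetic toy germline reference
#'
#' A small synthetic IMGT-style amino-acid reference: 6 V genes, 3 D genes
#' and 6 J genes, plus (by default) 3 decoy V genes used to calibrate the
#' usage limit of detection. \code{IGHJ4*01} carries the engineered arginine
#' at the FR4 conserved-motif position (the residue conventionally labelled
#' Kabat 101); all other J genes carry the wild-type tryptophan. Sequences
#' are hand-built variants of a canonical VH3 backbone, not true IMGT
#' alleles.
#'
#' @param decoys logical; include the decoy V genes (default \code{TRUE}).
#' @return A [GermlineSet-class].
#' @examples
#' gl <- toyGermlineSet()
#' table(segmentType(gl))
#' @export
toyGermlineSet <- function(decoys = TRUE) {
    vnames <- names(.TOY_V)
    if (!decoys) vnames <- setdiff(vnames, .TOY_V_DECOY)
    vseq <- vapply(.TOY_V[vnames], paste, "", collapse = "")
    vreg <- lapply(.TOY_V[vnames], function(parts) {
        ends <- cumsum(nchar(parts))
        matrix(c(c(0L, ends[-5]), ends), ncol = 2,
               dimnames = list(V_REGIONS, c("start", "end")))
    })
    jmotif <- as.integer(regexpr("[WR]G.G", .TOY_J)) - 1L
    aa <- c(vseq, .TOY_D, .TOY_J)
    GermlineSet(
        aa = aa,
        segment = rep(c("V", "D", "J"),
                      c(length(vseq), length(.TOY_D), length(.TOY_J))),
        decoy = names(aa) %in% .TOY_V_DECOY,
        regions = c(vreg, rep(list(NULL), length(.TOY_D) + length(.TOY_J))),
        fr4Offset = c(rep(NA_integer_, length(vseq) + length(.TOY_D)), jmotif)
    )
}
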