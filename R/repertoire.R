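#' @include AllGenerics.R
NULL

#' Construct a repertoire
#'
#' @param aa named character vector or [Biostrings::AAStringSet] of VH
#'   amino-acid sequences; names are sequence ids.
#' @param animalId,strain character scalars or vectors (recycled).
#' @param readCount integer vector of read-abundance weights (default 1).
#' @return A [Repertoire-class].
#' @export
Repertoire <- function(aa, animalId = "animal1", strain = "synthetic",
                       readCount = 1L) {
    if (!is(aa, "AAStringSet")) aa <- Biostrings::AAStringSet(aa)
    n <- length(aa)
    info <- DataFrame(
        sequenceId = names(aa),
        animalId = rep_len(as.character(animalId), n),
        strain = rep_len(as.character(strain), n),
        readCount = rep_len(as.integer(readCount), n)
    )
    new("Repertoire", aa = aa, info = info)
}

#' @describeIn Repertoire sequence ids.
#' @param x a \code{Repertoire}.
#' @export
setMethod("sequenceIds", "Repertoire", function(x) x@info$sequenceId)

#' @describeIn Repertoire amino-acid sequences.
#' @export
setMethod("aaSequences", "Repertoire", function(x) x@aa)

#' @describeIn Repertoire read-abundance weights, named by sequence id.
#' @export
setMethod("readCounts", "Repertoire", function(x) {
    stats::setNames(x@info$readCount, x@info$sequenceId)
})

#' @describeIn Repertoire animal ids, named by sequence id.
#' @export
setMethod("animalIds", "Repertoire", function(x) {
    stats::setNames(x@info$animalId, x@info$sequenceId)
})

#' @export
setMethod("length", "Repertoire", function(x) length(x@aa))

#' @export
setMethod("[", "Repertoire", function(x, i, j, ..., drop = TRUE) {
    if (is.character(i)) i <- match(i, names(x@aa))
    initialize(x, aa = x@aa[i], info = x@info[i, , drop = FALSE])
})

#' @export
setMethod("show", "Repertoire", function(object) {
    cat(sprintf("%s with %d sequences from %d animal(s), %d total reads\n",
                class(object), length(object),
                length(unique(object@info$animalId)),
                sum(object@info$readCount)))
})

## ---- AnnotatedRepertoire accessors ----------------------------------------

#' @export
setMethod("[", "AnnotatedRepertoire", function(x, i, j, ..., drop = TRUE) {
    if (is.character(i)) i <- match(i, names(x@aa))
    initialize(x, aa = x@aa[i], info = x@info[i, , drop = FALSE],
               ann = x@ann[i, , drop = FALSE])
})

#' @describeIn AnnotatedRepertoire full annotation table (sample metadata
#'   plus germline annotations) as a [S4Vectors::DataFrame].
#' @param x an \code{AnnotatedRepertoire}.
#' @export
setMethod("annotations", "AnnotatedRepertoire", function(x) {
    cbind(x@info, x@ann)
})

#' @describeIn AnnotatedRepertoire V gene calls, named by sequence id.
#' @export
setMethod("vCall", "AnnotatedRepertoire", function(x) {
    stats::setNames(x@ann$vCall, x@info$sequenceId)
})

#' @describeIn AnnotatedRepertoire J gene calls.
#' @export
setMethod("jCall", "AnnotatedRepertoire", function(x) {
    stats::setNames(x@ann$jCall, x@info$sequenceId)
})

#' @describeIn AnnotatedRepertoire CDR3 amino-acid substrings.
#' @export
setMethod("cdr3", "AnnotatedRepertoire", function(x) {
    stats::setNames(x@ann$cdr3, x@info$sequenceId)
})

#' @describeIn AnnotatedRepertoire somatic hypermutation counts (amino-acid
#'   mismatches over the aligned V region, gaps excluded).
#' @export
setMethod("shmCount", "AnnotatedRepertoire", function(x) {
    stats::setNames(x@ann$shmCount, x@info$sequenceId)
})

#' @describeIn AnnotatedRepertoire residue observed at the J-encoded FR4
#'   conserved-motif position (\code{NA} when unaligned).
#' @export
setMethod("fr4Residue", "AnnotatedRepertoire", function(x) {
    stats::setNames(x@ann$fr4Residue, x@info$sequenceId)
})

#' @describeIn AnnotatedRepertoire minimum-alignment filter flags.
#' @export
setMethod("passFilter", "AnnotatedRepertoire", function(x) {
    stats::setNames(x@ann$passFilter, x@info$sequenceId)
})

#' @export
setMethod("show", "AnnotatedRepertoire", function(object) {
    callNextMethod()
    ok <- object@ann$passFilter & object@ann$annotatable
    cat(sprintf("  %d pass-filter and annotatable; V calls: %s\n",
                sum(ok),
                paste(utils::head(sort(unique(object@ann$vCall[ok])), 5),
                      collapse = " ")))
})

## ---- repertoire input ------------------------------------------------------

#' Read repertoire sequences
#'
#' Reads VH amino-acid sequences from FASTA or from an AIRR-style
#' rearrangement TSV. FASTA records get \code{readCount = 1}; the AIRR
#' dialect requires \code{sequence_id} and \code{sequence_aa} columns and
#' uses \code{duplicate_count} (when present) as the read weight. Input
#' order is preserved and no record is silently dropped: malformed rows
#' raise an error naming the offending line.
#'
#' @param path input file.
#' @param format \code{"fasta"} or \code{"airr_tsv"}.
#' @param animalId,strain sample labels applied when the file does not
#'   carry \code{animal_id} / \code{strain} columns.
#' @return A [Repertoire-class].
#' @export
readRepertoire <- function(path, format = c("fasta", "airr_tsv"),
                           animalId = "animal1", strain = "unknown") {
    format <- match.arg(format)
    if (!file.exists(path)) stop("no such file: ", path)
    if (format == "fasta") {
        set <- Biostrings::readAAStringSet(path)
        names(set) <- sub("\\s.*$", "", names(set))
        if (anyDuplicated(names(set)))
            stop("duplicate sequence id(s) in ", path)
        if (any(width(set) == 0))
            stop("empty sequence record in ", path, ": ",
                 names(set)[which(width(set) == 0)[1]])
        return(Repertoire(set, animalId = animalId, strain = strain))
    }
    tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                             check.names = FALSE)
    for (col in c("sequence_id", "sequence_aa"))
        if (!col %in% colnames(tab))
            stop("AIRR TSV ", path, " is missing required column '", col, "'")
    bad <- which(is.na(tab$sequence_aa) | tab$sequence_aa == "")
    if (length(bad))
        stop("empty sequence_aa at line ", bad[1] + 1L, " of ", path)
    rc <- if ("duplicate_count" %in% colnames(tab))
        as.integer(tab$duplicate_count) else 1L
    Repertoire(
        stats::setNames(tab$sequence_aa, tab$sequence_id),
        animalId = if ("animal_id" %in% colnames(tab)) tab$animal_id
                   else animalId,
        strain = if ("strain" %in% colnames(tab)) tab$strain else strain,
        readCount = rc
    )
}

## ---- annotated AIRR-style TSV ----------------------------------------------

.AIRR_OUT_COLS <- c(
    sequence_id = "sequenceId", animal_id = "animalId", strain = "strain",
    sequence_aa = NA, v_call = "vCall", j_call = "jCall",
    v_score = "vScore", v_identity = "vIdentity",
    aligned_length = "alignedLength", shm_count = "shmCount",
    fr4_motif_residue = "fr4Residue", pass_filter = "passFilter",
    annotatable = "annotatable",
    fr1_aa = "fr1", cdr1_aa = "cdr1", fr2_aa = "fr2", cdr2_aa = "cdr2",
    fr3_aa = "fr3", cdr3_aa = "cdr3", fr4_aa = "fr4",
    duplicate_count = "readCount"
)

#' Write an annotated repertoire as AIRR-style TSV
#'
#' The canonical annotated-output dialect: one row per sequence with
#' columns \code{sequence_id}, \code{animal_id}, \code{strain},
#' \code{sequence_aa}, \code{v_call}, \code{j_call}, \code{v_score},
#' \code{v_identity}, \code{aligned_length}, \code{shm_count},
#' \code{fr4_motif_residue}, \code{pass_filter}, \code{annotatable}, the
#' seven region substrings (\code{fr1_aa} .. \code{fr4_aa},
#' \code{cdr1_aa} .. \code{cdr3_aa}) and \code{duplicate_count}. Reading the
#' file back with [readAnnotatedTsv()] reproduces the object exactly.
#'
#' @param x an [AnnotatedRepertoire-class].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeAnnotatedTsv <- function(x, path) {
    stopifnot(is(x, "AnnotatedRepertoire"))
    full <- annotations(x)
    out <- data.frame(row.names = seq_len(length(x)))
    for (airr in names(.AIRR_OUT_COLS)) {
        col <- .AIRR_OUT_COLS[[airr]]
        vals <- if (is.na(col)) as.character(x@aa) else full[[col]]
        if (is.double(vals)) vals <- sprintf("%.17g", vals)
        out[[airr]] <- vals
    }
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
    invisible(path)
}

#' Read an annotated repertoire from AIRR-style TSV
#'
#' @param path a file written by [writeAnnotatedTsv()].
#' @return An [AnnotatedRepertoire-class].
#' @export
readAnnotatedTsv <- function(path) {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                             colClasses = "character", na.strings = "")
    miss <- setdiff(names(.AIRR_OUT_COLS), colnames(tab))
    if (length(miss))
        stop("annotated TSV ", path, " is missing column(s): ",
             paste(miss, collapse = ", "))
    aa <- Biostrings::AAStringSet(
        stats::setNames(tab$sequence_aa, tab$sequence_id))
    info <- DataFrame(
        sequenceId = tab$sequence_id,
        animalId = tab$animal_id,
        strain = tab$strain,
        readCount = as.integer(tab$duplicate_count)
    )
    chr <- function(v) { v[is.na(v)] <- NA_character_; as.character(v) }
    ann <- DataFrame(
        vCall = chr(tab$v_call), jCall = chr(tab$j_call),
        vScore = as.numeric(tab$v_score),
        vIdentity = as.numeric(tab$v_identity),
        alignedLength = as.integer(tab$aligned_length),
        shmCount = as.integer(tab$shm_count),
        fr4Residue = chr(tab$fr4_motif_residue),
        passFilter = as.logical(tab$pass_filter),
        annotatable = as.logical(tab$annotatable),
        fr1 = chr(tab$fr1_aa), cdr1 = chr(tab$cdr1_aa), fr2 = chr(tab$fr2_aa),
        cdr2 = chr(tab$cdr2_aa), fr3 = chr(tab$fr3_aa),
        cdr3 = chr(tab$cdr3_aa), fr4 = chr(tab$fr4_aa)
    )
    new("AnnotatedRepertoire", aa = aa, info = info, ann = ann)
}

#' Read ELISA plate measurements
#'
#' Reads a CSV with columns \code{supernatant_id}, \code{antigen},
#' \code{signal} and \code{is_background_control} (logical). Signals must
#' be positive.
#'
#' @param path CSV file path.
#' @return data.frame with columns \code{supernatantId}, \code{antigen},
#'   \code{signal}, \code{isBackground}.
#' @export
readElisaCsv <- function(path) {
    tab <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("supernatant_id", "antigen", "signal", "is_background_control")
    miss <- setdiff(need, colnames(tab))
    if (length(miss))
        stop("ELISA CSV ", path, " is missing column(s): ",
             paste(miss, collapse = ", "))
    if (any(!is.finite(tab$signal)) || any(tab$signal <= 0))
        stop("ELISA signals must be positive")
    data.frame(
        supernatantId = as.character(tab$supernatant_id),
        antigen = as.character(tab$antigen),
        signal = as.numeric(tab$signal),
        isBackground = as.logical(tab$is_background_control),
        stringsAsFactors = FALSE
    )
}
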