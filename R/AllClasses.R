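#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

AA_STANDARD <- c("A","C","D","E","F","G","H","I","K","L",
                 "M","N","P","Q","R","S","T","V","W","Y")

V_REGIONS <- c("FR1", "CDR1", "FR2", "CDR2", "FR3")

#' Germline gene reference set
#'
#' Holds a set of germline V, D and J segments at the amino-acid level.
#' V segments carry IMGT-style region boundaries (FR1, CDR1, FR2, CDR2, FR3)
#' as 0-based half-open intervals that tile a prefix of the sequence; J
#' segments carry the index of the conserved FR4 tryptophan of the W-G-x-G
#' motif (the residue an engineered J variant may carry as arginine).
#' V segments may additionally be flagged as decoys: genes deliberately
#' absent from the animal's genome, used to derive the usage limit of
#' detection.
#'
#' @slot aa [Biostrings::AAStringSet] of germline amino-acid sequences,
#'   named by gene identifier.
#' @slot segment character vector, one of \code{"V"}, \code{"D"}, \code{"J"}
#'   per gene.
#' @slot decoy logical vector; \code{TRUE} for decoy V genes.
#' @slot regions named list; for each V gene a 5 x 2 integer matrix with
#'   rows FR1..FR3 and columns \code{start}, \code{end} (0-based half-open);
#'   \code{NULL} for D and J genes.
#' @slot fr4Offset integer vector; for J genes the 0-based index of the
#'   conserved FR4 motif residue, \code{NA} otherwise.
#'
#' @seealso [readGermlineFasta()], [toyGermlineSet()]
#' @exportClass GermlineSet
setClass("GermlineSet",
    representation(
        aa = "AAStringSet",
        segment = "character",
        decoy = "logical",
        regions = "list",
        fr4Offset = "integer"
    )
)

setValidity("GermlineSet", function(object) {
    n <- length(object@aa)
    nm <- names(object@aa)
    msg <- character()
    if (is.null(nm) || anyNA(nm) || any(nm == ""))
        msg <- c(msg, "all germline genes must be named")
    if (anyDuplicated(nm))
        msg <- c(msg, sprintf("duplicate gene name(s): %s",
            paste(unique(nm[duplicated(nm)]), collapse = ", ")))
    if (length(object@segment) != n || length(object@decoy) != n ||
        length(object@regions) != n || length(object@fr4Offset) != n)
        return("slot lengths disagree")
    if (!all(object@segment %in% c("V", "D", "J")))
        msg <- c(msg, "segment must be one of V, D, J")
    seqs <- as.character(object@aa)
    bad <- vapply(strsplit(seqs, ""), function(x) !all(x %in% AA_STANDARD),
                  logical(1))
    if (any(bad))
        msg <- c(msg, sprintf(
            "germline sequence with non-standard residues: %s",
            paste(nm[bad], collapse = ", ")))
    for (i in seq_len(n)) {
        if (object@segment[i] == "V") {
            r <- object@regions[[i]]
            if (is.null(r) || !is.matrix(r) || nrow(r) != 5L ||
                !identical(rownames(r), V_REGIONS)) {
                msg <- c(msg, sprintf(
                    "V gene '%s' lacks FR1..FR3 region boundaries", nm[i]))
                next
            }
            if (r[1, 1] != 0L || any(r[, 2] <= r[, 1]) ||
                any(r[-1, 1] != r[-5, 2]))
                msg <- c(msg, sprintf(
                    "region intervals of '%s' must be ordered, disjoint and tile a prefix",
                    nm[i]))
            if (r[5, 2] > nchar(seqs[i]))
                msg <- c(msg, sprintf(
                    "region intervals of '%s' exceed the sequence", nm[i]))
        }
        if (object@segment[i] == "J" && !is.na(object@fr4Offset[i])) {
            off <- object@fr4Offset[i]
            res <- substr(seqs[i], off + 1L, off + 1L)
            if (off < 0L || off >= nchar(seqs[i]) || !(res %in% c("W", "R")))
                msg <- c(msg, sprintf(
                    "fr4 motif offset of '%s' must point at a germline W or R",
                    nm[i]))
        }
    }
    if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Repertoire of VH amino-acid sequences
#'
#' A set of heavy-chain variable-domain amino-acid sequences with sample
#' metadata and read-abundance weights.
#'
#' @slot aa [Biostrings::AAStringSet], named by \code{sequenceId}.
#' @slot info [S4Vectors::DataFrame] with columns \code{sequenceId},
#'   \code{animalId}, \code{strain}, \code{readCount}.
#'
#' @seealso [readRepertoire()], [annotateRepertoire()]
#' @exportClass Repertoire
setClass("Repertoire",
    representation(aa = "AAStringSet", info = "DataFrame")
)

setValidity("Repertoire", function(object) {
    need <- c("sequenceId", "animalId", "strain", "readCount")
    if (!all(need %in% colnames(object@info)))
        return(sprintf("info must have columns: %s",
                       paste(need, collapse = ", ")))
    if (nrow(object@info) != length(object@aa))
        return("info rows must match number of sequences")
    if (!identical(names(object@aa), as.character(object@info$sequenceId)))
        return("sequence names must equal info$sequenceId")
    if (anyDuplicated(object@info$sequenceId))
        return("sequence ids must be unique")
    if (any(object@info$readCount < 0))
        return("readCount must be >= 0")
    TRUE
})

#' Annotated repertoire
#'
#' A [Repertoire] after germline annotation: per sequence the V and J gene
#' call, V identity, framework/CDR region substrings, somatic hypermutation
#' count over the V region, the residue at the J-encoded FR4 conserved motif
#' position, and filter flags. Sequences whose germline alignment spans
#' fewer than the minimum number of residues have \code{passFilter = FALSE};
#' sequences where region projection fails (e.g. no J gene present) have
#' \code{annotatable = FALSE} and \code{NA} regions.
#'
#' @slot ann [S4Vectors::DataFrame] with columns \code{vCall}, \code{jCall},
#'   \code{vScore}, \code{vIdentity}, \code{alignedLength}, \code{shmCount},
#'   \code{fr4Residue}, \code{passFilter}, \code{annotatable} and the seven
#'   region substrings \code{fr1}..\code{fr4}, \code{cdr1}..\code{cdr3}.
#'
#' @exportClass AnnotatedRepertoire
setClass("AnnotatedRepertoire",
    contains = "Repertoire",
    representation(ann = "DataFrame")
)

ANN_COLS <- c("vCall", "jCall", "vScore", "vIdentity", "alignedLength",
              "shmCount", "fr4Residue", "passFilter", "annotatable",
              "fr1", "cdr1", "fr2", "cdr2", "fr3", "cdr3", "fr4")

setValidity("AnnotatedRepertoire", function(object) {
    if (!all(ANN_COLS %in% colnames(object@ann)))
        return(sprintf("ann must have columns: %s",
                       paste(ANN_COLS, collapse = ", ")))
    if (nrow(object@ann) != length(object@aa))
        return("ann rows must match number of sequences")
    ok <- which(object@ann$annotatable %in% TRUE)
    if (length(ok)) {
        concat <- paste0(object@ann$fr1[ok], object@ann$cdr1[ok],
                         object@ann$fr2[ok], object@ann$cdr2[ok],
                         object@ann$fr3[ok], object@ann$cdr3[ok],
                         object@ann$fr4[ok])
        hit <- mapply(grepl, concat, as.character(object@aa)[ok],
                      MoreArgs = list(fixed = TRUE))
        if (!all(hit))
            return("region concatenation must be a substring of sequence_aa")
    }
    TRUE
})

#' Clonotype family table
#'
#' The partition of an annotated repertoire into clonotype families:
#' clusters of sequences whose CDR3 amino-acid similarity is at least the
#' clustering threshold (single-linkage, so families are the connected
#' components of the similarity graph). Families are ranked by the fraction
#' of total sample reads they contain.
#'
#' @slot families [S4Vectors::DataFrame] with columns \code{familyId},
#'   \code{rank}, \code{readFraction}, \code{nMembers},
#'   \code{representativeCdr3}.
#' @slot members list of character vectors of member sequence ids, parallel
#'   to \code{families}.
#' @slot threshold numeric similarity threshold used.
#' @slot linkage character, \code{"single"} or \code{"complete"}.
#'
#' @seealso [clusterClonotypes()], [rankClonotypes()]
#' @exportClass ClonotypeTable
setClass("ClonotypeTable",
    representation(
        families = "DataFrame",
        members = "list",
        threshold = "numeric",
        linkage = "character"
    )
)

setValidity("ClonotypeTable", function(object) {
    fam <- object@families
    need <- c("familyId", "rank", "readFraction", "nMembers",
              "representativeCdr3")
    if (!all(need %in% colnames(fam)))
        return(sprintf("families must have columns: %s",
                       paste(need, collapse = ", ")))
    if (nrow(fam) != length(object@members))
        return("members list must parallel the family table")
    ids <- unlist(object@members, use.names = FALSE)
    if (anyDuplicated(ids))
        return("families must partition the sequences (duplicate member)")
    if (!all(fam$nMembers == lengths(object@members)))
        return("nMembers must equal length of member lists")
    if (nrow(fam) && !anyNA(fam$readFraction)) {
        if (abs(sum(fam$readFraction) - 1) > 1e-9)
            return("read fractions must sum to 1")
        o <- order(fam$rank)
        if (is.unsorted(-fam$readFraction[o]))
            return("rank ordering must be non-increasing in readFraction")
    }
    TRUE
})

#' Repertoire simulation configuration
#'
#' Parameters of the synthetic heavy-chain-only repertoire generator. The
#' generator emulates a multi-animal immunization campaign: biased V-gene
#' usage, clonal expansion with shared CDR3 junctions, per-residue somatic
#' hypermutation, a J-segment mixture in which one variant carries arginine
#' at the FR4 conserved-tryptophan position, lambda-light-chain-binding
#' labels statistically coupled to that residue, and ELISA signals with
#' separable positive/negative ranges.
#'
#' @slot seed integer RNG seed.
#' @slot nAnimals,nSequences integers; animals per cohort and sequences per
#'   animal.
#' @slot strain character label.
#' @slot vWeights named numeric; per-sequence V-gene usage probabilities
#'   (normalised).
#' @slot jWeights named numeric; J-gene usage probabilities.
#' @slot nClones integer; clonal families per animal.
#' @slot cloneSizeLaw character, \code{"geometric"} or \code{"zipf"}.
#' @slot cloneSizeParam numeric; geometric decay p or zipf exponent s.
#' @slot junctionLengthRange integer length-2; CDR3 junction length range.
#' @slot junctionAlphabet named numeric over the 20 residues; junction
#'   residue weights (normalised).
#' @slot cdr3MutRate numeric; per-position junction mutation probability
#'   within a clone.
#' @slot shmRate numeric; per-residue V-region substitution probability.
#' @slot shmRateByCategory named numeric; optional overrides for labels
#'   \code{"lambda_binding"} and/or \code{"antigen_specific"}.
#' @slot pLambdaGivenW,pLambdaGivenR numerics; lambda-binding probability
#'   given the realised FR4 motif residue (W vs. anything else).
#' @slot pCloneSpecific,pAntigenSpecific numerics; probability that a clone
#'   is antigen-reactive and the marginal per-sequence antigen-specific
#'   probability (members of reactive clones are positive with probability
#'   \code{pAntigenSpecific / pCloneSpecific}).
#' @slot elisa list with \code{backgroundMean}, \code{backgroundCv},
#'   \code{nBackground}, \code{positiveRange}, \code{negativeRange}.
#'
#' @seealso [simulationConfig()], [defaultScenario()], [simulateRepertoire()]
#' @exportClass SimulationConfig
setClass("SimulationConfig",
    representation(
        seed = "integer",
        nAnimals = "integer",
        nSequences = "integer",
        strain = "character",
        vWeights = "numeric",
        jWeights = "numeric",
        nClones = "integer",
        cloneSizeLaw = "character",
        cloneSizeParam = "numeric",
        junctionLengthRange = "integer",
        junctionAlphabet = "numeric",
        cdr3MutRate = "numeric",
        shmRate = "numeric",
        shmRateByCategory = "numeric",
        pLambdaGivenW = "numeric",
        pLambdaGivenR = "numeric",
        pCloneSpecific = "numeric",
        pAntigenSpecific = "numeric",
        elisa = "list"
    )
)

setValidity("SimulationConfig", function(object) {
    msg <- character()
    prob1 <- function(x) length(x) == 1 && !is.na(x) && x >= 0 && x <= 1
    for (s in c("cdr3MutRate", "shmRate", "pLambdaGivenW", "pLambdaGivenR",
                "pCloneSpecific", "pAntigenSpecific"))
        if (!prob1(slot(object, s)))
            msg <- c(msg, sprintf("%s must be a probability", s))
    if (length(object@shmRateByCategory)) {
        if (is.null(names(object@shmRateByCategory)) ||
            !all(names(object@shmRateByCategory) %in%
                 c("lambda_binding", "antigen_specific")) ||
            any(object@shmRateByCategory < 0) ||
            any(object@shmRateByCategory > 1))
            msg <- c(msg, "shmRateByCategory must be probabilities named lambda_binding/antigen_specific")
    }
    for (s in c("vWeights", "jWeights", "junctionAlphabet")) {
        w <- slot(object, s)
        if (is.null(names(w)) || any(w < 0) || abs(sum(w) - 1) > 1e-6)
            msg <- c(msg, sprintf("%s must be named, non-negative, sum 1", s))
    }
    if (!all(names(object@junctionAlphabet) %in% AA_STANDARD))
        msg <- c(msg, "junctionAlphabet must be over the 20 standard residues")
    if (object@pAntigenSpecific > object@pCloneSpecific)
        msg <- c(msg, "pAntigenSpecific (marginal) cannot exceed pCloneSpecific")
    if (length(object@junctionLengthRange) != 2 ||
        object@junctionLengthRange[1] < 1 ||
        diff(object@junctionLengthRange) < 0)
        msg <- c(msg, "junctionLengthRange must be an increasing length-2 range")
    if (!object@cloneSizeLaw %in% c("geometric", "zipf"))
        msg <- c(msg, "cloneSizeLaw must be 'geometric' or 'zipf'")
    e <- object@elisa
    need <- c("backgroundMean", "backgroundCv", "nBackground",
              "positiveRange", "negativeRange")
    if (!all(need %in% names(e))) {
        msg <- c(msg, sprintf("elisa must have elements: %s",
                              paste(need, collapse = ", ")))
    } else {
        if (any(e$positiveRange < 30))
            msg <- c(msg, "elisa positive ratio range must lie entirely >= 30")
        if (any(e$negativeRange >= 30))
            msg <- c(msg, "elisa negative ratio range must lie entirely < 30")
        if (e$backgroundMean <= 0)
            msg <- c(msg, "elisa background mean must be positive")
    }
    if (length(msg)) paste(msg, collapse = "; ") else TRUE
})
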