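#' @include germline.R repertoire.R
NULL

.withSeed <- function(seed, expr) {
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (is.null(old)) {
            if (exists(".Random.seed", envir = globalenv(),
                       inherits = FALSE))
                rm(".Random.seed", envir = globalenv())
        } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
    expr
}

## Junction residue alphabets. Within-class residue profiles are shared;
## the class totals differ between the heavy-chain-only ("hcab") and the
## light-chain-paired comparison ("h2l2") repertoires, planting CDR3 class
## shifts of -8.7 (hydrophobic), +5.0 (charged), +3.7 (polar uncharged)
## and 0.0 (special cases) percentage points.
.WITHIN_CLASS <- list(
    hydrophobic = c(A = .15, V = .15, I = .08, L = .14, M = .04, F = .14,
                    Y = .25, W = .05),
    special_cases = c(C = .06, G = .70, P = .24),
    charged = c(R = .30, H = .10, K = .15, D = .30, E = .15),
    polar_uncharged = c(S = .40, T = .25, N = .20, Q = .15)
)

.classAlphabet <- function(classTotals) {
    w <- unlist(lapply(names(classTotals), function(cl)
        classTotals[[cl]] * .WITHIN_CLASS[[cl]]))
    w / sum(w)
}

#' Junction residue alphabets used by the simulator
#'
#' @param which \code{"hcab"} (hydrophilic-enriched CDR3s of a
#'   heavy-chain-only repertoire) or \code{"h2l2"} (light-chain-paired
#'   comparison repertoire).
#' @return named numeric weights over the 20 residues (sum 1).
#' @export
junctionAlphabet <- function(which = c("hcab", "h2l2")) {
    which <- match.arg(which)
    totals <- switch(which,
        hcab = c(hydrophobic = .333, special_cases = .25, charged = .22,
                  polar_uncharged = .197),
        h2l2 = c(hydrophobic = .42, special_cases = .25, charged = .17,
                 polar_uncharged = .16))
    .classAlphabet(totals)
}

#' Build a simulation configuration
#'
#' All parameters of the repertoire generator with defaults describing the
#' study conditions the package's analyses target: a 10-animal cohort of
#' 2,000 sequences each, V usage biased toward VH3/VH4 genes, 80\% usage
#' of the arginine-variant J gene, lambda binding coupled to the FR4 motif
#' residue (P(lambda|W) = 0.23, P(lambda|R) = 0.007, reproducing ~5\%
#' lambda binders of which ~89\% carry W while ~84\% of non-binders carry
#' R), and category-dependent V-region hypermutation (1.45\% per residue
#' for lambda binders, 3.3\% for antigen-specific sequences, 2\%
#' otherwise, giving ~25\% vs. <5\% germline sequences).
#'
#' @param seed integer RNG seed.
#' @param nAnimals,nSequences cohort dimensions.
#' @param strain strain label.
#' @param vWeights,jWeights named usage weights (normalised internally).
#' @param nClones clonal families per animal.
#' @param cloneSizeLaw,cloneSizeParam clone-size law (\code{"geometric"}
#'   decay p or \code{"zipf"} exponent s) for the clone expansion weights.
#' @param junctionLengthRange CDR3 junction length range.
#' @param junctionAlphabet named residue weights for junction generation.
#' @param cdr3MutRate per-position junction mutation probability within a
#'   clone.
#' @param shmRate baseline per-residue V-region substitution probability.
#' @param shmRateByCategory named overrides (\code{lambda_binding},
#'   \code{antigen_specific}).
#' @param pLambdaGivenW,pLambdaGivenR lambda-binding probabilities given
#'   the realised FR4 motif residue.
#' @param pCloneSpecific probability a clone is antigen-reactive.
#' @param pAntigenSpecific marginal per-sequence antigen-specific
#'   probability.
#' @param elisa list of ELISA signal parameters (see
#'   [SimulationConfig-class]).
#' @return A [SimulationConfig-class].
#' @export
simulationConfig <- function(
    seed = 42L,
    nAnimals = 10L,
    nSequences = 2000L,
    strain = "HC27sim",
    vWeights = c("IGHV3-23*01" = .30, "IGHV3-30*01" = .20,
                 "IGHV4-39*01" = .20, "IGHV4-34*01" = .12,
                 "IGHV3-7*01" = .10, "IGHV1-69*01" = .08),
    jWeights = c("IGHJ4*01" = .80, "IGHJ1*01" = .04, "IGHJ2*01" = .04,
                 "IGHJ3*01" = .04, "IGHJ5*01" = .04, "IGHJ6*01" = .04),
    nClones = 50L,
    cloneSizeLaw = "geometric",
    cloneSizeParam = 0.08,
    junctionLengthRange = c(9L, 18L),
    junctionAlphabet = hcabrep::junctionAlphabet("hcab"),
    cdr3MutRate = 0.03,
    shmRate = 0.02,
    shmRateByCategory = c(lambda_binding = 0.0145,
                          antigen_specific = 0.033),
    pLambdaGivenW = 0.23,
    pLambdaGivenR = 0.007,
    pCloneSpecific = 0.30,
    pAntigenSpecific = 0.215,
    elisa = list(backgroundMean = 100, backgroundCv = 0.2,
                 nBackground = 16L, positiveRange = c(40, 400),
                 negativeRange = c(0.2, 5))) {
    jW <- jWeights[jWeights > 0]
    new("SimulationConfig",
        seed = as.integer(seed), nAnimals = as.integer(nAnimals),
        nSequences = as.integer(nSequences), strain = strain,
        vWeights = vWeights / sum(vWeights), jWeights = jW / sum(jW),
        nClones = as.integer(nClones), cloneSizeLaw = cloneSizeLaw,
        cloneSizeParam = cloneSizeParam,
        junctionLengthRange = as.integer(junctionLengthRange),
        junctionAlphabet = junctionAlphabet / sum(junctionAlphabet),
        cdr3MutRate = cdr3MutRate, shmRate = shmRate,
        shmRateByCategory = shmRateByCategory,
        pLambdaGivenW = pLambdaGivenW, pLambdaGivenR = pLambdaGivenR,
        pCloneSpecific = pCloneSpecific,
        pAntigenSpecific = pAntigenSpecific, elisa = elisa)
}

#' @rdname scenarios
#' @export
defaultScenario <- function(...) simulationConfig(...)

#' Packaged simulation scenarios
#'
#' \code{defaultScenario()}: the heavy-chain-only cohort described in
#' [simulationConfig()]. \code{h2l2Scenario()}: a smaller comparison
#' cohort emulating light-chain-paired antibodies (neutral junction
#' alphabet, wild-type J genes only, no lambda assay).
#' \code{nullCompositionScenario()}: the default cohort but with the
#' comparison junction alphabet, so contrasting it against
#' \code{h2l2Scenario()} data is a composition null.
#' \code{highShmScenario()}: uniformly elevated hypermutation (6\% per
#' residue, no category structure).
#'
#' @param ... overrides forwarded to [simulationConfig()].
#' @return A [SimulationConfig-class].
#' @name scenarios
#' @export
h2l2Scenario <- function(...) {
    preset <- list(
        seed = 43L, nAnimals = 5L, nSequences = 1000L, strain = "H2L2sim",
        jWeights = c("IGHJ1*01" = .2, "IGHJ2*01" = .2, "IGHJ3*01" = .2,
                     "IGHJ5*01" = .2, "IGHJ6*01" = .2),
        junctionAlphabet = junctionAlphabet("h2l2"),
        pLambdaGivenW = 0, pLambdaGivenR = 0,
        shmRateByCategory = c(antigen_specific = 0.033))
    do.call(simulationConfig, utils::modifyList(preset, list(...)))
}

#' @rdname scenarios
#' @export
nullCompositionScenario <- function(...) {
    preset <- list(seed = 44L,
                   junctionAlphabet = junctionAlphabet("h2l2"))
    do.call(simulationConfig, utils::modifyList(preset, list(...)))
}

#' @rdname scenarios
#' @export
highShmScenario <- function(...) {
    preset <- list(seed = 45L, shmRate = 0.06,
                   shmRateByCategory = numeric(0))
    do.call(simulationConfig, utils::modifyList(preset, list(...)))
}

#' Read a simulation configuration from YAML
#'
#' Reads a scenario file whose keys mirror the arguments of
#' [simulationConfig()]; packaged scenario files live under
#' \code{system.file("extdata", "scenarios", package = "hcabrep")}.
#'
#' @param path YAML file path.
#' @return A [SimulationConfig-class].
#' @export
readSimulationConfig <- function(path) {
    y <- yaml::read_yaml(path)
    for (k in c("vWeights", "jWeights", "junctionAlphabet",
                "shmRateByCategory"))
        if (!is.null(y[[k]])) y[[k]] <- unlist(y[[k]])
    if (is.null(y$shmRateByCategory)) y$shmRateByCategory <- numeric(0)
    if (!is.null(y$elisa)) {
        y$elisa$positiveRange <- as.numeric(unlist(y$elisa$positiveRange))
        y$elisa$negativeRange <- as.numeric(unlist(y$elisa$negativeRange))
    }
    unknown <- setdiff(names(y), names(formals(simulationConfig)))
    if (length(unknown))
        stop("unknown configuration key(s): ",
             paste(unknown, collapse = ", "))
    do.call(simulationConfig, y)
}

#' @export
setMethod("show", "SimulationConfig", function(object) {
    cat(sprintf(
        "SimulationConfig: %d animal(s) x %d sequences, %d clones/animal (seed %d)\n",
        object@nAnimals, object@nSequences, object@nClones, object@seed))
    cat(sprintf("  shm %.3f/res, cdr3 mut %.3f, J(R-variant) weight %.2f\n",
                object@shmRate, object@cdr3MutRate,
                sum(object@jWeights["IGHJ4*01"], na.rm = TRUE)))
})

.mutateString <- function(res, rate, replaceWeights = NULL) {
    hit <- which(stats::runif(length(res)) < rate)
    for (i in hit) {
        if (is.null(replaceWeights)) {
            res[i] <- sample(setdiff(AA_STANDARD, res[i]), 1L)
        } else {
            w <- replaceWeights
            w[res[i]] <- 0
            res[i] <- sample(names(w), 1L, prob = w)
        }
    }
    list(res = res, positions = hit)
}

#' Simulate a heavy-chain-only repertoire with ground truth
#'
#' Generates a multi-animal cohort under a [SimulationConfig-class]:
#' clonal families share a CDR3 junction (drawn from the configured
#' residue alphabet and mutated per member), V and J germline origins are
#' drawn per sequence from the usage weights, the V region accumulates
#' per-residue substitutions at a rate that may depend on the sequence's
#' binder category, and lambda-binding labels are drawn conditionally on
#' the realised FR4 motif residue. The output is bit-reproducible given
#' the configuration (per-animal sub-seeds are derived from the master
#' seed, so animals are generated order-independently).
#'
#' @param config a [SimulationConfig-class].
#' @param germline reference used for generation (default
#'   [toyGermlineSet()]; decoys are never drawn).
#' @return list with \code{repertoire} (a [Repertoire-class]) and
#'   \code{truth} (data.frame: \code{sequenceId}, \code{animalId},
#'   \code{cloneId}, \code{vOrigin}, \code{jOrigin}, \code{junction},
#'   \code{nShmV}, \code{shmPositions}, \code{fr4Residue},
#'   \code{lambdaBinding}, \code{antigenSpecific}, \code{readCount}).
#' @examples
#' sim <- simulateRepertoire(defaultScenario(nAnimals = 1, nSequences = 50))
#' sim$repertoire
#' @export
simulateRepertoire <- function(config, germline = toyGermlineSet()) {
    stopifnot(is(config, "SimulationConfig"))
    badV <- setdiff(names(config@vWeights), germlineNames(germline))
    badJ <- setdiff(names(config@jWeights), germlineNames(germline))
    if (length(badV) || length(badJ))
        stop("usage weights name genes absent from the reference: ",
             paste(c(badV, badJ), collapse = ", "))
    vSeqs <- lapply(names(config@vWeights), function(g)
        strsplit(as.character(germline@aa[[g]]), "")[[1]])
    names(vSeqs) <- names(config@vWeights)
    jOff <- fr4MotifOffset(germline)
    jFr4 <- lapply(names(config@jWeights), function(g) {
        s <- as.character(germline@aa[[g]])
        strsplit(substr(s, jOff[[g]] + 1L, nchar(s)), "")[[1]]
    })
    names(jFr4) <- names(config@jWeights)
    alpha <- config@junctionAlphabet
    byCat <- config@shmRateByCategory
    pMember <- if (config@pCloneSpecific > 0)
        config@pAntigenSpecific / config@pCloneSpecific else 0

    perAnimal <- lapply(seq_len(config@nAnimals), function(a) {
        .withSeed((config@seed * 1000L + a) %% .Machine$integer.max, {
            nC <- config@nClones; nS <- config@nSequences
            lens <- sample(seq(config@junctionLengthRange[1],
                               config@junctionLengthRange[2]),
                           nC, replace = TRUE)
            junctions <- lapply(lens, function(l)
                sample(names(alpha), l, replace = TRUE, prob = alpha))
            cloneSpecific <- stats::runif(nC) < config@pCloneSpecific
            w <- switch(config@cloneSizeLaw,
                geometric = (1 - config@cloneSizeParam)^(seq_len(nC) - 1),
                zipf = seq_len(nC)^(-config@cloneSizeParam))
            cloneOf <- sample.int(nC, nS, replace = TRUE, prob = w)
            vOrigin <- sample(names(config@vWeights), nS, replace = TRUE,
                              prob = config@vWeights)
            jOrigin <- sample(names(config@jWeights), nS, replace = TRUE,
                              prob = config@jWeights)
            seqs <- character(nS)
            junc <- character(nS)
            fr4r <- character(nS)
            lambda <- antigen <- logical(nS)
            nshm <- integer(nS)
            shmPos <- character(nS)
            for (i in seq_len(nS)) {
                jx <- .mutateString(junctions[[cloneOf[i]]],
                                    config@cdr3MutRate, alpha)$res
                fx <- .mutateString(jFr4[[jOrigin[i]]], config@shmRate)$res
                fr4r[i] <- fx[1]
                lambda[i] <- stats::runif(1) <
                    if (fx[1] == "W") config@pLambdaGivenW
                    else config@pLambdaGivenR
                antigen[i] <- cloneSpecific[cloneOf[i]] &&
                    stats::runif(1) < pMember
                rate <- config@shmRate
                if (lambda[i] && "lambda_binding" %in% names(byCat))
                    rate <- byCat[["lambda_binding"]]
                else if (antigen[i] && "antigen_specific" %in% names(byCat))
                    rate <- byCat[["antigen_specific"]]
                vx <- .mutateString(vSeqs[[vOrigin[i]]], rate)
                nshm[i] <- length(vx$positions)
                shmPos[i] <- paste(vx$positions, collapse = ",")
                junc[i] <- paste(jx, collapse = "")
                seqs[i] <- paste0(paste(vx$res, collapse = ""), junc[i],
                                  paste(fx, collapse = ""))
            }
            data.frame(
                sequenceId = sprintf("a%02d_s%05d", a, seq_len(nS)),
                animalId = sprintf("animal%02d", a),
                cloneId = sprintf("a%02d_c%03d", a, cloneOf),
                vOrigin = vOrigin, jOrigin = jOrigin,
                junction = junc, nShmV = nshm, shmPositions = shmPos,
                fr4Residue = fr4r, lambdaBinding = lambda,
                antigenSpecific = antigen,
                readCount = 1L + stats::rgeom(nS, 0.5),
                sequence = seqs, stringsAsFactors = FALSE)
        })
    })
    truth <- do.call(rbind, perAnimal)
    rep <- Repertoire(
        stats::setNames(truth$sequence, truth$sequenceId),
        animalId = truth$animalId, strain = config@strain,
        readCount = truth$readCount)
    truth$sequence <- NULL
    list(repertoire = rep, truth = truth)
}

#' Simulate ELISA measurements for simulated sequences
#'
#' Emits background wells and one well per supernatant; positive
#' supernatants (per the simulated labels) receive signal ratios drawn
#' from the configured positive range and negatives from the negative
#' range, relative to the realised mean background, so [elisaCall()] on
#' the output recovers the planted labels exactly (the two ranges are
#' disjoint around the 30-fold threshold by construction).
#'
#' @param truth ground-truth data.frame from [simulateRepertoire()].
#' @param config the [SimulationConfig-class] used.
#' @param assay \code{"antigen"} (uses the \code{antigenSpecific} label)
#'   or \code{"lambda"} (uses \code{lambdaBinding}).
#' @param ids optional subset of sequence ids to assay (e.g. a screening
#'   candidate set).
#' @param seed RNG seed for the signal draws (labels do not depend on it).
#' @return data.frame in the layout of [readElisaCsv()].
#' @export
simulateElisa <- function(truth, config, assay = c("antigen", "lambda"),
                          ids = NULL,
                          seed = config@seed + 777L) {
    assay <- match.arg(assay)
    if (is.null(ids)) ids <- truth$sequenceId
    rows <- truth[match(ids, truth$sequenceId), , drop = FALSE]
    if (anyNA(rows$sequenceId)) stop("unknown sequence id in 'ids'")
    lab <- if (assay == "antigen") rows$antigenSpecific
           else rows$lambdaBinding
    e <- config@elisa
    .withSeed(seed %% .Machine$integer.max, {
        bg <- stats::rlnorm(e$nBackground, log(e$backgroundMean),
                            e$backgroundCv)
        ratio <- ifelse(lab,
            stats::runif(length(lab), e$positiveRange[1],
                         e$positiveRange[2]),
            stats::runif(length(lab), e$negativeRange[1],
                         e$negativeRange[2]))
        rbind(
            data.frame(supernatantId = sprintf("bg%02d",
                           seq_len(e$nBackground)),
                       antigen = assay, signal = bg, isBackground = TRUE,
                       stringsAsFactors = FALSE),
            data.frame(supernatantId = rows$sequenceId, antigen = assay,
                       signal = ratio * mean(bg), isBackground = FALSE,
                       stringsAsFactors = FALSE))
    })
}
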