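#' @include repertoire.R
NULL

#' Amino-acid class scheme
#'
#' The four-way partition of the 20 standard residues used throughout the
#' CDR composition analysis: hydrophobic (A, V, I, L, M, F, Y, W), special
#' cases (C, G, P), charged (R, H, K, D, E) and polar uncharged (S, T, N,
#' Q).
#'
#' @return named character vector mapping each residue to its class.
#' @export
aminoClassScheme <- function() {
    c(A = "hydrophobic", V = "hydrophobic", I = "hydrophobic",
      L = "hydrophobic", M = "hydrophobic", F = "hydrophobic",
      Y = "hydrophobic", W = "hydrophobic",
      C = "special_cases", G = "special_cases", P = "special_cases",
      R = "charged", H = "charged", K = "charged", D = "charged",
      E = "charged",
      S = "polar_uncharged", T = "polar_uncharged", N = "polar_uncharged",
      Q = "polar_uncharged")
}

AA_CLASSES <- c("hydrophobic", "special_cases", "charged", "polar_uncharged")

#' Per-CDR amino-acid class frequencies
#'
#' For each antibody, counts the residues of each class within each of the
#' three CDRs and divides by the CDR length, giving 12 frequencies (3 CDRs
#' x 4 classes) in \[0, 1\]; within a CDR the four class frequencies sum
#' to 1. Antibodies with an empty or missing CDR are excluded and reported
#' via the \code{excluded} attribute.
#'
#' @param x an [AnnotatedRepertoire-class], or a data.frame/list with
#'   components \code{cdr1}, \code{cdr2}, \code{cdr3} (character vectors).
#' @param scheme residue-to-class map (default [aminoClassScheme()]).
#' @return numeric matrix, one row per retained antibody, 12 columns named
#'   \code{<CDR>.<class>}; attribute \code{excluded} lists dropped ids.
#' @export
cdrClassFrequencies <- function(x, scheme = aminoClassScheme()) {
    if (is(x, "AnnotatedRepertoire")) {
        cdrs <- list(CDR1 = x@ann$cdr1, CDR2 = x@ann$cdr2,
                     CDR3 = x@ann$cdr3)
        ids <- x@info$sequenceId
    } else {
        cdrs <- list(CDR1 = x$cdr1, CDR2 = x$cdr2, CDR3 = x$cdr3)
        ids <- if (!is.null(x$sequenceId)) x$sequenceId
               else paste0("seq", seq_along(cdrs$CDR1))
    }
    keep <- Reduce(`&`, lapply(cdrs, function(v) !is.na(v) & nzchar(v)))
    freq <- matrix(NA_real_, sum(keep), 12,
        dimnames = list(ids[keep],
            paste(rep(names(cdrs), each = 4), AA_CLASSES, sep = ".")))
    for (cdr in names(cdrs)) {
        sp <- strsplit(cdrs[[cdr]][keep], "")
        cls <- lapply(sp, function(r)
            factor(scheme[r], levels = AA_CLASSES))
        tab <- t(vapply(cls, function(f) as.integer(table(f)),
                        integer(4)))
        freq[, paste(cdr, AA_CLASSES, sep = ".")] <-
            tab / lengths(sp)
    }
    structure(freq, excluded = ids[!keep])
}

#' Mann-Whitney U test
#'
#' Two-sided Mann-Whitney-Wilcoxon test. For small samples (both groups at
#' most \code{exactMax}) the p-value is computed by full enumeration of
#' the permutation distribution of U (ties handled through mid-ranks, so
#' the exact path remains valid with tied data); otherwise the
#' tie-corrected normal approximation with continuity correction is used.
#' When all pooled values are identical the test is degenerate and p = 1
#' by convention.
#'
#' @param x,y numeric vectors.
#' @param exactMax largest per-group size for the exact enumeration
#'   (default 8).
#' @return list with \code{U} (statistic of the first group), \code{p},
#'   \code{method} (\code{"exact"}, \code{"normal"} or
#'   \code{"degenerate"}).
#' @examples
#' mannWhitneyU(c(0.2, 0.4), c(0.6, 0.8))$p  # 1/3 by enumeration
#' @export
mannWhitneyU <- function(x, y, exactMax = 8L) {
    stopifnot(length(x) >= 1, length(y) >= 1)
    n1 <- length(x); n2 <- length(y)
    r <- rank(c(x, y))
    U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
    if (length(unique(c(x, y))) == 1L)
        return(list(U = U, p = 1, method = "degenerate"))
    if (n1 <= exactMax && n2 <= exactMax) {
        combs <- utils::combn(n1 + n2, n1)
        Us <- colSums(matrix(r[combs], nrow = n1)) - n1 * (n1 + 1) / 2
        p <- min(1, 2 * min(mean(Us <= U), mean(Us >= U)))
        return(list(U = U, p = p, method = "exact"))
    }
    p <- stats::wilcox.test(x, y, alternative = "two.sided",
                            exact = FALSE, correct = TRUE)$p.value
    list(U = U, p = p, method = "normal")
}

#' Compare CDR class composition between two antibody groups
#'
#' For each of the 12 (CDR, class) cells, compares the per-antibody
#' frequency distributions of two groups by a two-sided Mann-Whitney U
#' test and reports the group-mean difference converted to percentage
#' points (\code{100 * (mean(A) - mean(B))}). Raw p-values are reported
#' (mirroring the convention of reporting unadjusted values for these 12
#' tests); a Bonferroni-adjusted column is emitted alongside for
#' transparency. Swapping groups negates the percent difference and leaves
#' p-values unchanged. With \code{location = "median"} the effect size
#' uses group medians instead of means.
#'
#' @param groupA,groupB frequency matrices from [cdrClassFrequencies()]
#'   (at least 2 rows each).
#' @param location \code{"mean"} (default) or \code{"median"}.
#' @return data.frame with one row per (CDR, class): \code{cdr},
#'   \code{class}, \code{meanA}, \code{meanB}, \code{percentDifference},
#'   \code{pValue}, \code{pBonferroni}, \code{nA}, \code{nB},
#'   \code{degenerate}.
#' @export
compareGroups <- function(groupA, groupB, location = c("mean", "median")) {
    location <- match.arg(location)
    stopifnot(nrow(groupA) >= 2, nrow(groupB) >= 2,
              identical(colnames(groupA), colnames(groupB)))
    loc <- if (location == "mean") mean else stats::median
    out <- lapply(colnames(groupA), function(cell) {
        a <- groupA[, cell]; b <- groupB[, cell]
        mw <- mannWhitneyU(a, b)
        parts <- strsplit(cell, ".", fixed = TRUE)[[1]]
        data.frame(
            cdr = parts[1], class = parts[2],
            meanA = loc(a), meanB = loc(b),
            percentDifference = 100 * (loc(a) - loc(b)),
            pValue = mw$p, nA = length(a), nB = length(b),
            degenerate = mw$method == "degenerate",
            stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, out)
    out$pBonferroni <- pmin(1, out$pValue * nrow(out))
    out[, c("cdr", "class", "meanA", "meanB", "percentDifference",
            "pValue", "pBonferroni", "nA", "nB", "degenerate")]
}

#' Kyte-Doolittle residue hydropathy scale
#'
#' The published 1982 per-residue hydropathy values.
#'
#' @return named numeric vector over the 20 standard residues.
#' @export
kdScale <- function() {
    c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
      G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
      P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)
}

#' Kyte-Doolittle hydropathy profile
#'
#' Sliding-window hydropathy over an amino-acid sequence (typically the
#' framework-1 to framework-4 span of a VH domain). The score at each
#' window centre is a weighted mean of the residue hydropathy values, with
#' weights decreasing linearly from 1 at the centre to \code{edgeWeight}
#' at both window ends (the "linear weight variation model";
#' \code{edgeWeight = 1} reduces to the unweighted sliding mean). Weights
#' are normalised to sum to 1, so a homopolymer profiles flat at the
#' residue's scale value for any edge weight.
#'
#' @param sequence amino-acid string, length at least \code{window}.
#' @param window odd window size (default 9).
#' @param edgeWeight relative weight at the window edges, in (0, 1\]
#'   (default 1).
#' @return numeric vector of length \code{nchar(sequence) - window + 1};
#'   names give the 1-based centre positions.
#' @examples
#' kyteDoolittleProfile(strrep("I", 12))  # flat at 4.5
#' @export
kyteDoolittleProfile <- function(sequence, window = 9L, edgeWeight = 1.0) {
    stopifnot(window %% 2 == 1, window >= 1,
              edgeWeight > 0, edgeWeight <= 1)
    res <- strsplit(sequence, "")[[1]]
    if (length(res) < window)
        stop("sequence shorter than the window (", length(res), " < ",
             window, ")")
    vals <- kdScale()[res]
    if (anyNA(vals))
        stop("non-standard residue in sequence: ",
             paste(unique(res[is.na(vals)]), collapse = ", "))
    h <- (window - 1) / 2
    w <- 1 - (1 - edgeWeight) * abs(seq(-h, h)) / max(h, 1)
    w <- w / sum(w)
    centers <- seq_len(length(res) - window + 1L) + h
    scores <- vapply(seq_along(centers), function(i)
        sum(w * vals[i:(i + window - 1L)]), numeric(1))
    stats::setNames(scores, centers)
}
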