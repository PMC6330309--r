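# Independent oracle implementations used to cross-check the package.

# Plain dynamic-programming Levenshtein distance (unit costs), written
# without adist so the package's similarity path has an independent check.
oracleLevenshtein <- function(a, b) {
    x <- strsplit(a, "")[[1]]
    y <- strsplit(b, "")[[1]]
    prev <- 0:length(y)
    for (i in seq_along(x)) {
        cur <- numeric(length(y) + 1)
        cur[1] <- i
        for (j in seq_along(y)) {
            cur[j + 1] <- min(prev[j + 1] + 1, cur[j] + 1,
                              prev[j] + (x[i] != y[j]))
        }
        prev <- cur
    }
    prev[length(y) + 1]
}

# Connected components of the CDR3 similarity-threshold graph by
# breadth-first search over the full pairwise matrix. The similarity
# primitive (normalised Levenshtein via adist) is itself validated against
# oracleLevenshtein in the clonotype tests; here the independence is in the
# component construction (BFS vs. hierarchical clustering with a cut).
oracleComponents <- function(cdr3s, threshold = 0.8) {
    n <- length(cdr3s)
    sim <- 1 - utils::adist(cdr3s) / outer(nchar(cdr3s), nchar(cdr3s), pmax)
    adj <- sim >= threshold
    comp <- rep(NA_integer_, n)
    k <- 0L
    for (s in seq_len(n)) {
        if (!is.na(comp[s])) next
        k <- k + 1L
        queue <- s
        while (length(queue)) {
            v <- queue[1]; queue <- queue[-1]
            if (!is.na(comp[v])) next
            comp[v] <- k
            queue <- c(queue, which(adj[v, ] & is.na(comp)))
        }
    }
    comp
}

# Exact two-sided Mann-Whitney p-value by enumerating group assignments
# and counting pairwise wins (+ half-ties) directly, without ranks.
oracleMannWhitney <- function(x, y) {
    n1 <- length(x); n2 <- length(y)
    pool <- c(x, y)
    uStat <- function(idx) {
        a <- pool[idx]; b <- pool[-idx]
        sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
    }
    U <- uStat(seq_len(n1))
    Us <- apply(utils::combn(n1 + n2, n1), 2, uStat)
    min(1, 2 * min(mean(Us <= U), mean(Us >= U)))
}

# Best V gene by global edit distance of the read against each V germline
# (junction/FR4 count as uniform extra edits for every gene, so the argmin
# identifies the origin); independent of the BLOSUM62 alignment route.
oracleBestV <- function(read, germline) {
    genes <- germlineNames(germline)[segmentType(germline) == "V"]
    d <- vapply(genes, function(g)
        oracleLevenshtein(read, as.character(aaSequences(germline)[[g]])),
        numeric(1))
    genes[which.min(d)]
}

adjustedRand <- function(a, b) mclust::adjustedRandIndex(a, b)

# Canonical form of a partition label vector (clusters renumbered by first
# appearance), so two partitions are identical iff their canonical forms are.
canonicalPartition <- function(p) {
    match(p, unique(p))
}

# Small deterministic repertoire built from the toy germline: reads are
# germline V + a fixed junction + the FR4 span of a chosen J gene, with
# optional planted substitutions.
buildRead <- function(germline, v, j, junction, vSubs = NULL) {
    vseq <- strsplit(as.character(aaSequences(germline)[[v]]), "")[[1]]
    if (!is.null(vSubs))
        vseq[as.integer(names(vSubs))] <- vSubs
    jseq <- as.character(aaSequences(germline)[[j]])
    fr4 <- substr(jseq, fr4MotifOffset(germline)[[j]] + 1L, nchar(jseq))
    paste0(paste(vseq, collapse = ""), junction, fr4)
}

randomCdr3 <- function(n, lenRange = c(8, 16)) {
    lens <- sample(seq(lenRange[1], lenRange[2]), n, replace = TRUE)
    vapply(lens, function(l)
        paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], l,
                     replace = TRUE), collapse = ""), character(1))
}
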