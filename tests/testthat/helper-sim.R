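# Shared fixtures and oracles, all built in code.

suppressPackageStartupMessages({
    library(GenomicRanges)
    library(SummarizedExperiment)
})

oneChrom <- function(len = 3e7) GenomeLayout(c(c1 = len))

# Match CO calls against simulated truth: a true CO is recovered when an
# unused call of the same sample/chromosome contains its position.
matchCoCalls <- function(cl, truth, sampleNames) {
    idx <- match(cl$sample, sampleNames)
    hit <- logical(nrow(truth))
    used <- rep(FALSE, nrow(cl))
    for (i in seq_len(nrow(truth))) {
        j <- which(idx == truth$gamete[i] & cl$chrom == truth$chrom[i] &
                   cl$left < truth$pos[i] & cl$right > truth$pos[i] & !used)
        if (length(j)) { hit[i] <- TRUE; used[j[1]] <- TRUE }
    }
    list(hit = hit, used = used)
}

# True COs with >= k informative (non-missing phase) markers on each side.
flankedTruth <- function(truth, pm, adm, k = 2) {
    ph <- phaseCalls(pm)
    pos <- start(rowRanges(adm))
    chr <- as.character(seqnames(rowRanges(adm)))
    vapply(seq_len(nrow(truth)), function(i) {
        s <- truth$gamete[i]
        sel <- chr == truth$chrom[i] & !is.na(ph[, s])
        obs <- pos[sel]
        sum(obs < truth$pos[i]) >= k && sum(obs > truth$pos[i]) >= k
    }, logical(1))
}

# Exhaustive agreement-maximizing phasing: choose per-sample groups h and
# per-marker labels lab (0/1) maximizing the number of observed genotype
# calls matching predicted(s, m) = 1 iff h[s] == lab[m].
bruteForcePhase <- function(G) {
    n <- nrow(G); M <- ncol(G)
    best <- NULL; bestScore <- -1
    for (code in 0:(2^(n - 1) - 1)) {
        h <- c(0L, as.integer(intToBits(code))[seq_len(n - 1)])
        lab <- integer(M); sc <- 0
        for (m in seq_len(M)) {
            agr0 <- sum(G[, m] == as.integer(h == 0L), na.rm = TRUE)
            agr1 <- sum(G[, m] == as.integer(h == 1L), na.rm = TRUE)
            lab[m] <- if (agr0 >= agr1) 0L else 1L
            sc <- sc + max(agr0, agr1)
        }
        if (sc > bestScore) {
            bestScore <- sc
            best <- list(h = h, lab = lab, score = sc)
        }
    }
    # markers whose optimal label is not unique under the optimal partition
    # (e.g. fully dropped-out columns): any tie-break is co-optimal
    h <- best$h
    best$tied <- vapply(seq_len(M), function(m) {
        sum(G[, m] == as.integer(h == 0L), na.rm = TRUE) ==
            sum(G[, m] == as.integer(h == 1L), na.rm = TRUE)
    }, logical(1))
    best
}

# Does a phasing solution equal the brute-force optimum up to a global
# swap?  Labels are compared only at markers whose optimal label is unique.
phasingMatchesOracle <- function(hPm, labPm, bf) {
    free <- bf$tied
    same <- all(hPm == bf$h) && all(labPm[!free] == bf$lab[!free])
    swap <- all(hPm == 1L - bf$h) && all(labPm[!free] == 1L - bf$lab[!free])
    same || swap
}

# Small fully observed phasing instance: true sample groups (>= 2 each),
# true marker labels, mutant-allele dropout at rate `dropout`.
phasingInstance <- function(seed, dropout = 0.08) {
    set.seed(seed)
    n <- sample(4:8, 1); M <- sample(6:10, 1)
    repeat {
        h <- rbinom(n, 1, 0.5)
        if (min(table(factor(h, levels = 0:1))) >= 2) break
    }
    lab <- rbinom(M, 1, 0.5)
    mut <- outer(h, lab, function(a, b) as.integer(a == b))
    G <- mut
    drop <- matrix(rbinom(n * M, 1, dropout) == 1, n, M)
    G[drop & mut == 1] <- 0L
    ms <- MarkerSet(rep("c1", M), seq_len(M) * 1000, "G", "A", "P1",
                    "unassigned")
    adm <- AlleleDepthMatrix(ms, matrix(6L, M, n) - 3L * t(G), 3L * t(G))
    list(G = G, adm = adm, h = h, lab = lab)
}

# Build a PhaseMatrix + AlleleDepthMatrix pair from explicit per-marker
# phase calls for a single sample, with read evidence consistent with each
# call (alt reads where the call matches the marker label, deep ref-only
# otherwise), unless overridden.
toyPhased <- function(calls, labels = NULL, alt = NULL, depth = NULL,
                      pos = NULL, support = NULL, prov = NULL) {
    M <- length(calls)
    if (is.null(labels)) labels <- rep("A", M)
    if (is.null(pos)) pos <- seq_len(M) * 1000
    if (is.null(alt))
        alt <- ifelse(!is.na(calls) & calls == labels, 3L, 0L)
    if (is.null(depth)) depth <- ifelse(alt > 0, 6L, 12L)
    if (is.null(support)) support <- ifelse(is.na(calls), NA_real_, 1)
    if (is.null(prov)) prov <- ifelse(is.na(calls), NA_character_,
                                      "observed")
    ms <- MarkerSet(rep("c1", M), pos, "G", "A", "P1", "unassigned")
    mk <- granges(ms); mcols(mk) <- mcols(ms); mk$phaseLabel <- labels
    pm <- new("PhaseMatrix", markers = mk,
              phase = matrix(calls, M, 1), support = matrix(support, M, 1),
              provenance = matrix(prov, M, 1), degraded = character())
    adm <- AlleleDepthMatrix(ms, matrix(as.integer(depth - alt), M, 1),
                             matrix(as.integer(alt), M, 1), "S1")
    list(pm = pm, adm = adm)
}
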