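## Sliding-window hierarchical-clustering phasing with voting-based
## imputation.  Each window of consecutive markers is clustered into two
## sample groups (the two locally inherited haplotypes); overlapping windows
## vote on every (sample, marker) phase call.

# Pairwise mismatch-fraction distance over co-observed markers.  G is a
# samples x w matrix with values 1 (mutant), 0 (wild-type), NA (missing).
# Pairs with fewer than minCoobs co-observed markers get the uninformative
# distance 0.5.
mismatchDistance <- function(G, minCoobs = 3) {
    M1 <- (G == 1); M1[is.na(M1)] <- FALSE
    M0 <- (G == 0); M0[is.na(M0)] <- FALSE
    obs <- (!is.na(G)) * 1
    mism <- M1 %*% t(M0) + M0 %*% t(M1)
    coobs <- obs %*% t(obs)
    D <- ifelse(coobs >= minCoobs, mism / pmax(coobs, 1), 0.5)
    list(D = D, mism = mism, coobs = coobs)
}

#' Cluster one marker window into two sample groups
#'
#' Hierarchical agglomerative clustering (average linkage) on the pairwise
#' mismatch fraction over co-observed markers, cut into exactly two groups,
#' followed by a greedy polish that moves single samples between the groups
#' while the total within-window agreement (with per-marker mutant labels
#' re-optimized) improves -- the tree cut occasionally misplaces a sample
#' whose allele dropouts leave it equidistant from both groups.
#' Per-sample confidence is the fraction of the sample's non-missing calls
#' matching its group's consensus.  A window in which all observed calls
#' agree (no variation) is degenerate: it forms a single group and later
#' abstains from voting.
#'
#' @param G integer matrix (samples x markers) with values 1 (mutant),
#'   0 (wild-type), NA (missing).
#' @param minCoobs minimum co-observed markers for an informative pairwise
#'   distance (pairs below it get distance 0.5).
#' @return list with `groups` (integer 1/2 per sample; NA for samples with
#'   no observed call), `confidence` (numeric per sample) and `degenerate`
#'   (logical).
#' @export
clusterWindow <- function(G, minCoobs = 3) {
    stopifnot2(is.matrix(G) && ncol(G) >= 2, "window needs >= 2 markers")
    nObs <- rowSums(!is.na(G))
    if (all(nObs == 0)) stop("all calls missing in window")
    if (sum(nObs > 0) < 2)
        stop("need at least 2 samples with observed calls")
    dd <- mismatchDistance(G, minCoobs)
    if (sum(dd$mism[dd$coobs >= 1]) == 0) {
        # no disagreement anywhere: single group
        grp <- ifelse(nObs > 0, 1L, NA_integer_)
        conf <- ifelse(nObs > 0, 1, NA_real_)
        return(list(groups = grp, confidence = conf, degenerate = TRUE))
    }
    hc <- stats::hclust(stats::as.dist(dd$D), method = "average")
    grp <- stats::cutree(hc, k = 2)
    grp[nObs == 0] <- NA_integer_
    # polish: greedily move single samples between the two groups while the
    # total agreement (with per-marker mutant labels re-optimized) improves;
    # the average-linkage tree occasionally misplaces a sample whose allele
    # dropouts make it equidistant from both groups
    S1 <- (G == 1); S1[is.na(S1)] <- FALSE
    S0 <- (G == 0); S0[is.na(S0)] <- FALSE
    D <- S1 - S0
    for (iter in seq_len(2L * nrow(G))) {
        in1 <- !is.na(grp) & grp == 1L
        in2 <- !is.na(grp) & grp == 2L
        a0 <- colSums(S1[in1, , drop = FALSE]) +
              colSums(S0[in2, , drop = FALSE])   # group 1 carries the mutant
        a1 <- colSums(S1[in2, , drop = FALSE]) +
              colSums(S0[in1, , drop = FALSE])   # group 2 carries it
        base <- sum(pmax(a0, a1))
        sgn <- ifelse(in1, 1, -1)
        A0 <- matrix(a0, nrow(G), ncol(G), byrow = TRUE) - sgn * D
        A1 <- matrix(a1, nrow(G), ncol(G), byrow = TRUE) + sgn * D
        deltas <- rowSums(pmax(A0, A1)) - base
        deltas[is.na(grp)] <- -Inf
        if (sum(in1) == 1) deltas[in1] <- -Inf   # keep both groups nonempty
        if (sum(in2) == 1) deltas[in2] <- -Inf
        b <- which.max(deltas)
        if (!is.finite(deltas[b]) || deltas[b] <= 0) break
        grp[b] <- 3L - grp[b]
    }
    conf <- rep(NA_real_, nrow(G))
    for (k in 1:2) {
        idx <- which(!is.na(grp) & grp == k)
        if (!length(idx)) next
        sub <- G[idx, , drop = FALSE]
        ones <- colSums(sub == 1, na.rm = TRUE)
        zeros <- colSums(sub == 0, na.rm = TRUE)
        cons <- ifelse(ones >= zeros, 1L, 0L)   # ties toward mutant
        match <- sweep(sub, 2, cons, "==")
        conf[idx] <- rowSums(match, na.rm = TRUE) / pmax(rowSums(!is.na(sub)), 1)
    }
    list(groups = grp, confidence = conf, degenerate = FALSE)
}

# Phase one chromosome; internal worker for phaseMarkers.
phaseChromosome <- function(G, window, step, supportTerminal,
                            supportInternal, terminalSpan, minCoobs) {
    M <- ncol(G); nS <- nrow(G)
    degraded <- M < window
    starts <- if (degraded) 1L else seq(1L, M - window + 1L, by = step)
    wlen <- if (degraded) M else window

    votesA <- matrix(0L, nS, M)
    votesT <- matrix(0L, nS, M)
    prevGroups <- NULL
    for (s in starts) {
        cols <- s:(s + wlen - 1L)
        sub <- G[, cols, drop = FALSE]
        if (sum(rowSums(!is.na(sub)) > 0) < 2) next
        cl <- tryCatch(clusterWindow(sub, minCoobs), error = function(e) NULL)
        if (is.null(cl) || cl$degenerate) next
        grp <- cl$groups                       # 1/2, NA for unobserved
        # orient against the previous informative window: majority of shared
        # samples keep their label; ties toward no change
        if (!is.null(prevGroups)) {
            both <- !is.na(grp) & !is.na(prevGroups)
            agree <- sum(grp[both] == prevGroups[both])
            if (agree < sum(both) - agree) grp <- 3L - grp
        }
        prevGroups <- grp
        idx <- which(!is.na(grp))
        votesT[idx, cols] <- votesT[idx, cols] + 1L
        isA <- idx[grp[idx] == 1L]
        votesA[isA, cols] <- votesA[isA, cols] + 1L
    }

    fracA <- ifelse(votesT > 0, votesA / votesT, NA_real_)
    voted <- ifelse(votesT == 0, NA_character_,
                    ifelse(fracA >= 0.5, "A", "B"))
    voteSupport <- ifelse(votesT == 0, NA_real_, pmax(fracA, 1 - fracA))

    # per-marker phase label: majority over observed mutant samples of their
    # voted phase
    label <- rep(NA_character_, M)
    for (m in seq_len(M)) {
        mut <- which(!is.na(G[, m]) & G[, m] == 1L & !is.na(voted[, m]))
        if (length(mut)) {
            nA <- sum(voted[mut, m] == "A")
            label[m] <- if (nA >= length(mut) - nA) "A" else "B"
        } else {
            wt <- which(!is.na(G[, m]) & G[, m] == 0L & !is.na(voted[, m]))
            if (length(wt)) {
                nA <- sum(voted[wt, m] == "A")
                # wild-type samples carry the other phase
                label[m] <- if (nA >= length(wt) - nA) "B" else "A"
            }
        }
    }
    label[is.na(label)] <- "A"

    # positional vote thresholds: ordinals terminalSpan[1]..[2] from either
    # end use the terminal support rate, the interior the internal rate;
    # ordinals below terminalSpan[1] rely on observed calls only
    ordinal <- pmin(seq_len(M), rev(seq_len(M)))
    thr <- rep(supportInternal, M)
    thr[ordinal >= terminalSpan[1] & ordinal <= terminalSpan[2]] <-
        supportTerminal
    obsOnly <- ordinal < terminalSpan[1]

    labM <- matrix(label, nS, M, byrow = TRUE)
    obsPhase <- ifelse(is.na(G), NA_character_,
                       ifelse(G == 1L, labM, otherPhase(labM)))
    # support rate of a call = fraction of covering-window votes for the
    # called phase; a call with no covering votes stands on its own (1)
    support <- ifelse(votesT == 0, 1,
                      ifelse(obsPhase == "A", fracA, 1 - fracA))
    phase <- obsPhase
    prov <- ifelse(is.na(obsPhase), NA_character_, "observed")

    # the vote decides wherever it clears the positional threshold (the
    # observed raw genotype is dropout-prone at low coverage: a heterozygous
    # mutant shows no alt read in a sizeable fraction of 5x sites); below
    # the threshold, and at the outermost markers, the observed call stands
    thrM <- matrix(thr, nS, M, byrow = TRUE)
    useVote <- !matrix(obsOnly, nS, M, byrow = TRUE) &
        !is.na(voted) & voteSupport >= thrM
    newProv <- ifelse(is.na(obsPhase), "imputed",
                      ifelse(obsPhase != voted, "corrected", "observed"))
    phase[useVote] <- voted[useVote]
    support[useVote] <- voteSupport[useVote]
    prov[useVote] <- newProv[useVote]

    list(phase = phase, support = support, prov = prov, label = label,
         degraded = degraded)
}

#' Phase markers by sliding-window clustering with voting
#'
#' Slides a window of `window` consecutive markers (step `step`) along each
#' chromosome, clusters the samples in every window into the two local
#' haplotype groups ([clusterWindow()]), orients the group labels
#' consistently along the chromosome by maximal sample-overlap with the
#' previous window, and decides each (sample, marker) phase call by majority
#' vote over the covering windows (degenerate windows abstain).  The support
#' rate of a call is its winning-vote fraction.
#'
#' The vote decides a call (imputing missing sites and correcting
#' contradicted observed ones) wherever its support reaches the positional
#' threshold: `supportTerminal` (default 0.9) for markers at ordinal
#' positions `terminalSpan` (default 5-9) from either chromosome end and
#' `supportInternal` (default 0.8) in between.  Markers at ordinals below
#' `terminalSpan[1]` rely on observed calls only (a handful of windows
#' cannot out-vote a genuine terminal phase switch), as do sites where the
#' vote falls below its threshold; there the observed raw genotype, read
#' through the marker's phase label, stands.
#'
#' Chromosomes with fewer markers than one window are phased in degraded
#' single-window mode and flagged.
#'
#' @param adm an [AlleleDepthMatrix-class] for one parent's marker set.
#' @param window,step window size and step in markers.
#' @param supportTerminal,supportInternal,terminalSpan see Details.
#' @param minCoobs passed to [clusterWindow()].
#' @return A [PhaseMatrix-class].
#' @export
phaseMarkers <- function(adm, window = 10L, step = 1L,
                         supportTerminal = 0.9, supportInternal = 0.8,
                         terminalSpan = c(5L, 9L), minCoobs = 3L) {
    stopifnot2(ncol(adm) >= 2, "need at least 2 samples")
    stopifnot2(window >= 2, "window must be >= 2")
    gr <- rowRanges(adm)
    G <- t(genotypeCalls(adm))        # samples x markers
    chrom <- as.character(seqnames(gr))
    M <- length(gr); nS <- ncol(adm)
    phase <- matrix(NA_character_, nS, M)
    support <- matrix(NA_real_, nS, M)
    prov <- matrix(NA_character_, nS, M)
    label <- rep(NA_character_, M)
    degraded <- character()
    for (ch in unique(chrom)) {
        idx <- which(chrom == ch)
        if (length(idx) < 2) { degraded <- c(degraded, ch); next }
        res <- phaseChromosome(G[, idx, drop = FALSE],
                               window, step, supportTerminal,
                               supportInternal, terminalSpan, minCoobs)
        phase[, idx] <- res$phase
        support[, idx] <- res$support
        prov[, idx] <- res$prov
        label[idx] <- res$label
        if (res$degraded) degraded <- c(degraded, ch)
    }
    mk <- granges(gr)
    mcols(mk) <- mcols(gr)
    mk$phaseLabel <- label
    new("PhaseMatrix", markers = mk,
        phase = t(phase), support = t(support), provenance = t(prov),
        degraded = degraded)
}
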