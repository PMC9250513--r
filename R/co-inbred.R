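## Crossover calling in inbred-line progeny: consistent phase switches along
## chromosomes, read-level border refinement, chromosome-terminus validation.

#' Validate a candidate crossover at a chromosome terminus
#'
#' A terminal phase switch supported by fewer than `minRun` markers is
#' accepted when the terminal marker of the new phase carries a
#' well-supported mutant allele (>= `wellSupportedAlt` alt reads) or when
#' the consecutive wild-type observation of the variant marker carries more
#' than `wtMinReads` reads (a deeply covered ref-only site at a marker of
#' the old phase is itself strong evidence for the new haplotype, since the
#' sample then demonstrably lacks the old phase's mutation).
#'
#' @param altReads alt reads at the terminal new-phase marker.
#' @param wtReads reads at the consecutive wild-type (ref-only) observation.
#' @param wellSupportedAlt alt-read threshold (default 3).
#' @param wtMinReads strictly-greater-than read threshold (default 10).
#' @return logical (vectorized): accept the candidate?
#' @examples
#' validateTerminalCO(4, 0)    # well-supported mutant allele
#' validateTerminalCO(1, 12)   # > 10 wild-type reads
#' validateTerminalCO(1, 5)    # fails both clauses
#' @export
validateTerminalCO <- function(altReads, wtReads, wellSupportedAlt = 3,
                               wtMinReads = 10) {
    altReads <- ifelse(is.na(altReads), 0, altReads)
    wtReads <- ifelse(is.na(wtReads), 0, wtReads)
    altReads >= wellSupportedAlt | wtReads > wtMinReads
}

# Evidence strength of phase P for one sample at a marker.  EMS markers are
# dominant-presence evidence: >= refineAlt alt reads at a P-labelled marker
# pin P (single alt reads can be sequencing errors); a ref-only observation
# at a marker of the other phase pins P only when its depth exceeds
# wtStrongDepth (dropout of the mutant allele is common at low coverage).
strongEvidence <- function(phaseP, label, altR, depthR, refineAlt,
                           wtStrongDepth) {
    (label == phaseP & altR >= refineAlt) |
        (label == otherPhase(phaseP) & altR == 0 & depthR > wtStrongDepth)
}

#' Call crossovers from phased inbred progeny
#'
#' A crossover is a consistent switch of marker phase along a chromosome: at
#' least `minRun` consecutive non-missing markers of the new phase.
#' Internal runs shorter than `minRun` are treated as noise and masked,
#' weakest first (by the run's direct read evidence), so that an isolated
#' miscall between two genuine runs is removed rather than a genuine
#' boundary marker.  Terminal runs shorter than `minRun` are validated by
#' [validateTerminalCO()].
#'
#' Interval borders are then refined by examining the read evidence across
#' the transition region: the right bound is the first marker carrying
#' strong evidence for the new phase (>= `refineAlt` alt reads at a marker
#' of that phase, or a ref-only observation deeper than `wtStrongDepth`
#' reads at a marker of the old phase), and the left bound the last marker
#' before it with strong evidence for the old phase.  Calls resting only on
#' shallow wild-type observations or on imputation do not pin bounds.
#'
#' @param pm a [PhaseMatrix-class] from [phaseMarkers()].
#' @param adm the matching [AlleleDepthMatrix-class] (same markers/samples).
#' @param parent parent id recorded in the calls (whose meiosis).
#' @param sex sex of that meiosis, from the cross direction.
#' @param minRun minimum consecutive markers of the new phase (default 2).
#' @param wellSupportedAlt,wtMinReads terminal-validation thresholds.
#' @param refineAlt alt reads required for strong mutant evidence in border
#'   refinement (default 2).
#' @param wtStrongDepth depth above which a ref-only observation is strong
#'   evidence (default 10).
#' @return A [CrossoverSet-class].
#' @export
callCrossovers <- function(pm, adm, parent = "P1", sex = "female",
                           minRun = 2L, wellSupportedAlt = 3,
                           wtMinReads = 10, refineAlt = 2,
                           wtStrongDepth = 10) {
    stopifnot2(nrow(phaseCalls(pm)) == nrow(adm),
               "PhaseMatrix and AlleleDepthMatrix must share markers")
    ph <- phaseCalls(pm)
    prov <- callProvenance(pm)
    label <- markerPhase(pm)
    altM <- altDepth(adm); depM <- totalDepth(adm)
    gr <- pm@markers
    chrom <- as.character(seqnames(gr)); posAll <- start(gr)
    samples <- colnames(ph)
    if (is.null(samples)) samples <- colnames(adm)
    calls <- list(); ci <- 0L
    for (ch in unique(chrom)) {
        cidx <- which(chrom == ch)
        pos <- posAll[cidx]
        lab <- label[cidx]
        for (s in seq_along(samples)) {
            p <- ph[cidx, s]
            obs <- which(!is.na(p))
            if (length(obs) < 2) next
            pseq <- p[obs]
            aR <- altM[cidx, s]; dR <- depM[cidx, s]
            pv <- prov[cidx, s]
            # direct read evidence carried by each call (0 for vote-derived
            # calls contradicting or lacking their own observation)
            callScore <- ifelse(pv[obs] != "observed", 0,
                         ifelse(lab[obs] == pseq, aR[obs],
                         ifelse(aR[obs] == 0 & dR[obs] > wtStrongDepth,
                                dR[obs], 0)))
            # weakest-first masking of internal short runs
            keep <- seq_along(pseq)
            repeat {
                r <- rle(pseq[keep])
                if (length(r$lengths) <= 1) break
                ends <- cumsum(r$lengths)
                startsR <- c(1, head(ends, -1) + 1)
                short <- which(r$lengths < minRun)
                internal <- short[short > 1 & short < length(r$lengths)]
                if (!length(internal)) break
                scores <- vapply(internal, function(k)
                    sum(callScore[keep[startsR[k]:ends[k]]]), numeric(1))
                k <- internal[which.min(scores)]
                keep <- keep[-(startsR[k]:ends[k])]
            }
            # a surviving run must carry strong read evidence for its own
            # phase somewhere: paired allele dropouts (or error reads) can
            # fabricate a minRun-long run of weak calls, but almost never a
            # strong one
            repeat {
                r <- rle(pseq[keep])
                if (length(r$lengths) <= 1) break
                ends <- cumsum(r$lengths)
                startsR <- c(1, head(ends, -1) + 1)
                strongRun <- vapply(seq_along(r$lengths), function(k) {
                    idx <- obs[keep[startsR[k]:ends[k]]]
                    any(strongEvidence(r$values[k], lab[idx], aR[idx],
                                       dR[idx], refineAlt, wtStrongDepth))
                }, logical(1))
                if (all(strongRun)) break
                weak <- which(!strongRun)
                scores <- vapply(weak, function(k)
                    sum(callScore[keep[startsR[k]:ends[k]]]), numeric(1))
                k <- weak[which.min(scores)]
                keep <- keep[-(startsR[k]:ends[k])]
            }
            if (length(keep) < 2) next
            r <- rle(pseq[keep])
            nr <- length(r$lengths)
            if (nr <= 1) next
            ends <- cumsum(r$lengths)
            startsR <- c(1, head(ends, -1) + 1)
            # validate short terminal runs: a run of the new phase N is
            # built from alt observations at N-labelled markers and
            # ref-only observations at markers of the old phase; accept on
            # a well-supported mutant allele or a deep (> wtMinReads)
            # consecutive wild-type observation
            runOK <- rep(TRUE, nr)
            for (k in unique(c(1, nr))) {
                if (r$lengths[k] >= minRun) next
                runIdx <- obs[keep[startsR[k]:ends[k]]]
                phN <- r$values[k]
                mutIdx <- runIdx[lab[runIdx] == phN & aR[runIdx] >= 1]
                wtIdx <- runIdx[lab[runIdx] == otherPhase(phN) &
                                aR[runIdx] == 0]
                maxAlt <- if (length(mutIdx)) max(aR[mutIdx]) else 0
                maxWt <- if (length(wtIdx)) max(dR[wtIdx]) else 0
                if (!validateTerminalCO(maxAlt, maxWt, wellSupportedAlt,
                                        wtMinReads))
                    runOK[k] <- FALSE
            }
            use <- which(runOK)
            if (length(use) < 2) next
            for (j in seq_len(length(use) - 1)) {
                k1 <- use[j]; k2 <- use[j + 1]
                if (r$values[k1] == r$values[k2]) next
                fromP <- r$values[k1]; toP <- r$values[k2]
                leftRun <- obs[keep[startsR[k1]:ends[k1]]]
                rightRun <- obs[keep[startsR[k2]:ends[k2]]]
                # refinement scans every marker (called or not) from the
                # start of the left run to the end of the right run
                region <- leftRun[1]:rightRun[length(rightRun)]
                strongNew <- strongEvidence(toP, lab[region], aR[region],
                                            dR[region], refineAlt,
                                            wtStrongDepth)
                strongOld <- strongEvidence(fromP, lab[region], aR[region],
                                            dR[region], refineAlt,
                                            wtStrongDepth)
                lpos <- NA_real_; rpos <- NA_real_
                if (any(strongNew) && any(strongOld)) {
                    # optimal cut: maximize strong-old markers before the
                    # cut plus strong-new markers after it (robust to a
                    # stray strong observation deep inside either run)
                    co <- cumsum(strongOld)
                    cn <- sum(strongNew) - cumsum(strongNew)
                    cut <- which.max(c(sum(strongNew), co + cn)) - 1L
                    liC <- which(strongOld & seq_along(region) <= cut)
                    riC <- which(strongNew & seq_along(region) > cut)
                    if (length(liC) && length(riC)) {
                        lpos <- pos[region[liC[length(liC)]]]
                        rpos <- pos[region[riC[1]]]
                    }
                }
                if (is.na(lpos) || !(lpos < rpos)) {
                    lpos <- pos[leftRun[length(leftRun)]]
                    rpos <- pos[rightRun[1]]
                }
                ci <- ci + 1L
                calls[[ci]] <- data.frame(
                    sample = samples[s], parent = parent, sex = sex,
                    chrom = ch, left = lpos, right = rpos,
                    from = fromP, to = toP, resolution = rpos - lpos,
                    stringsAsFactors = FALSE)
            }
        }
    }
    if (length(calls)) CrossoverSet(do.call(rbind, calls))
    else CrossoverSet()
}

#' Per-gamete crossover counts and group comparison
#'
#' Counts COs per sample (samples without calls count zero) and compares
#' groups (e.g. female vs male meiosis) with the two-sided Mann-Whitney
#' (Wilcoxon rank-sum) test.
#'
#' @param cos a [CrossoverSet-class] or data.frame of calls.
#' @param samples character vector of all sample ids (including samples with
#'   zero COs).
#' @param groups factor/character of the same length: group of each sample.
#' @return list with `perSample` (sample, group, n), `groupMeans`, and
#'   `tests` (data.frame of pairwise two-sided Mann-Whitney results).
#' @export
coCountSummary <- function(cos, samples, groups) {
    cl <- if (is(cos, "CrossoverSet")) coCalls(cos) else cos
    stopifnot2(length(samples) == length(groups),
               "samples and groups must have equal length")
    groups <- as.character(groups)
    glev <- unique(groups)
    if (length(glev) < 2) stop("need at least 2 groups")
    if (any(table(factor(groups, levels = glev)) == 0))
        stop("empty group")
    n <- as.integer(table(factor(cl$sample, levels = samples)))
    perSample <- data.frame(sample = samples, group = groups, n = n,
                            stringsAsFactors = FALSE)
    groupMeans <- tapply(perSample$n, perSample$group, mean)
    pairs <- utils::combn(glev, 2)
    tests <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(i) {
        a <- perSample$n[groups == pairs[1, i]]
        b <- perSample$n[groups == pairs[2, i]]
        wt <- suppressWarnings(wilcox.test(a, b, alternative = "two.sided"))
        p <- wt$p.value
        if (is.na(p)) p <- 1        # fully tied tiny groups
        data.frame(group1 = pairs[1, i], group2 = pairs[2, i],
                   mean1 = mean(a), mean2 = mean(b),
                   W = unname(wt$statistic), p = p,
                   stringsAsFactors = FALSE)
    }))
    list(perSample = perSample, groupMeans = groupMeans, tests = tests)
}
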