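## Crossover calling in hybrid BC1/F2 progeny from dense-SNP allele depths:
## sliding-window genotyping with an allelic-ratio homozygosity threshold,
## per-SNP breakpoint refinement, and sample-level QC.

#' Genotype sliding SNP windows from allele depths
#'
#' Windows of `winSnps` consecutive SNPs (step `stepSnps`) are genotyped
#' from the summed parent-1 (`ref`) and parent-2 (`alt`) read counts: a
#' window with fewer than `minReads` total reads is missing; otherwise the
#' allelic ratio max(reads)/total calls homozygosity for the majority
#' parent when it reaches `homRatio` (inclusive), heterozygosity below it.
#'
#' @param adm an [AlleleDepthMatrix-class] of dense SNPs (`ref` = parent-1
#'   reads, `alt` = parent-2 reads).
#' @param winSnps,stepSnps window size and step, in SNPs.
#' @param homRatio homozygosity threshold on the allelic ratio (default
#'   0.95, inclusive).
#' @param minReads minimum reads per window (default 10).
#' @return data.frame with one row per (sample, chromosome, window):
#'   `sample`, `chrom`, `win`, `startIdx`/`endIdx` (SNP ordinals within the
#'   chromosome), `start`/`end` (bp of the flanking SNPs), `p1`, `p2`,
#'   `ratio`, `call` in `hom_p1`/`het`/`hom_p2`/`missing`.
#' @export
genotypeWindows <- function(adm, winSnps = 50L, stepSnps = 25L,
                            homRatio = 0.95, minReads = 10L) {
    stopifnot2(winSnps >= 1, "winSnps must be >= 1")
    gr <- rowRanges(adm)
    chrom <- as.character(seqnames(gr))
    refM <- refDepth(adm); altM <- altDepth(adm)
    samples <- colnames(adm)
    out <- vector("list", length(unique(chrom)))
    oi <- 0L
    for (ch in unique(chrom)) {
        idx <- which(chrom == ch)
        n <- length(idx)
        w <- min(winSnps, n)
        starts <- seq(1L, max(1L, n - w + 1L), by = stepSnps)
        # anchor a final window at the chromosome end so terminal segments
        # shorter than one step are still covered by a full window
        starts <- unique(c(starts, max(1L, n - w + 1L)))
        endsW <- pmin(starts + w - 1L, n)
        pos <- start(gr)[idx]
        # window sums via cumulative sums per sample
        cr <- apply(refM[idx, , drop = FALSE], 2, cumsum)
        ca <- apply(altM[idx, , drop = FALSE], 2, cumsum)
        if (!is.matrix(cr)) { cr <- matrix(cr, nrow = 1); ca <- matrix(ca, nrow = 1) }
        cr <- rbind(0, cr); ca <- rbind(0, ca)
        p1 <- cr[endsW + 1L, , drop = FALSE] - cr[starts, , drop = FALSE]
        p2 <- ca[endsW + 1L, , drop = FALSE] - ca[starts, , drop = FALSE]
        tot <- p1 + p2
        ratio <- ifelse(tot > 0, pmax(p1, p2) / tot, NA_real_)
        call <- ifelse(tot < minReads, "missing",
                ifelse(ratio >= homRatio & p1 >= p2, "hom_p1",
                ifelse(ratio >= homRatio, "hom_p2", "het")))
        nw <- length(starts)
        oi <- oi + 1L
        out[[oi]] <- data.frame(
            sample = rep(samples, each = nw),
            chrom = ch, win = rep(seq_len(nw), times = length(samples)),
            startIdx = rep(starts, times = length(samples)),
            endIdx = rep(endsW, times = length(samples)),
            start = rep(pos[starts], times = length(samples)),
            end = rep(pos[endsW], times = length(samples)),
            p1 = as.vector(p1), p2 = as.vector(p2),
            ratio = as.vector(ratio), call = as.vector(call),
            stringsAsFactors = FALSE)
    }
    do.call(rbind, out[seq_len(oi)])
}

# Breakpoint refinement between state s1 (left) and s2 (right) on the SNP
# index range lo..hi (the span from the last window called s1 to the first
# window called s2).  The cut is located by a binomial likelihood
# changepoint over the parent-2 read counts (p = errorRate under hom-P1,
# 1/2 under het, 1 - errorRate under hom-P2).  Bounds are then set by
# read evidence scanned outward from the cut: on a heterozygous side, the
# first SNP with >= 2 reads of the allele the flanking homozygous state
# lacks (single reads can be sequencing errors); on a homozygous side, the
# third SNP consistent with homozygosity (reads of the parent allele and
# none of the other), because one or two such SNPs in a row can be
# heterozygous sites with allele dropout at ~5x coverage.
refineBreakpoint <- function(refR, altR, pos, lo, hi, s1, s2,
                             errorRate = 0.005) {
    region <- lo:hi
    len <- length(region)
    eps <- max(errorRate, 1e-6)
    pOf <- function(state) switch(state, hom_p1 = eps, het = 0.5,
                                  hom_p2 = 1 - eps)
    dep <- refR[region] + altR[region]
    ll1 <- stats::dbinom(altR[region], dep, pOf(s1), log = TRUE)
    ll2 <- stats::dbinom(altR[region], dep, pOf(s2), log = TRUE)
    g <- which.max(c(0, cumsum(ll1 - ll2))) - 1L   # cut after g SNPs
    boundFor <- function(state, otherState, side) {
        idx <- if (side < 0) rev(seq_len(g))
               else if (g < len) (g + 1L):len else integer()
        if (!length(idx)) return(NA_integer_)
        i <- region[idx]
        if (state == "het") {
            ex <- if (otherState == "hom_p1") altR else refR
            hit <- which(ex[i] >= 2)
            if (length(hit)) i[hit[1]] else NA_integer_
        } else {
            own <- if (state == "hom_p1") refR else altR
            oth <- if (state == "hom_p1") altR else refR
            hit <- which(own[i] >= 1 & oth[i] == 0)
            if (!length(hit)) return(NA_integer_)
            i[hit[min(3L, length(hit))]]
        }
    }
    li <- boundFor(s1, s2, -1L)
    ri <- boundFor(s2, s1, 1L)
    if (is.na(li) || is.na(ri) || pos[li] >= pos[ri]) return(NULL)
    c(li, ri)
}

# Likelihood test for a crossover within one window span of a chromosome
# terminus.  Window-level genotyping cannot see a terminal segment shorter
# than about half a window, so the terminal span is re-examined at SNP
# resolution: a terminal CO is accepted when the best changepoint into a
# design-legal neighbouring state improves the log-likelihood over the
# constant-state explanation by at least `tau`.  tau = 21 (about six
# average-depth informative SNPs) keeps the false-call probability per
# chromosome end far below 1e-4: faking it needs a run of allele-dropout
# SNPs whose total depth exceeds 30.
terminalRescue <- function(refR, altR, pos, s1, side, design,
                           errorRate = 0.005, tau = 21, span = 50L) {
    n <- length(pos)
    k <- min(span, n)
    region <- if (side == "left") seq_len(k) else (n - k + 1L):n
    cand <- switch(s1,
                   hom_p1 = "het", hom_p2 = "het",
                   het = if (design == "BC1") "hom_p1"
                         else c("hom_p1", "hom_p2"))
    eps <- max(errorRate, 1e-6)
    pOf <- function(state) switch(state, hom_p1 = eps, het = 0.5,
                                  hom_p2 = 1 - eps)
    dep <- refR[region] + altR[region]
    llS1 <- stats::dbinom(altR[region], dep, pOf(s1), log = TRUE)
    best <- NULL; bestGain <- tau
    for (s0 in cand) {
        d <- stats::dbinom(altR[region], dep, pOf(s0), log = TRUE) - llS1
        gain <- if (side == "left") max(cumsum(d))
                else max(rev(cumsum(rev(d))))
        if (gain >= bestGain) { bestGain <- gain; best <- s0 }
    }
    if (is.null(best)) return(NULL)
    lo <- region[1]; hi <- region[length(region)]
    bp <- if (side == "left")
        refineBreakpoint(refR, altR, pos, lo, hi, best, s1, errorRate)
    else refineBreakpoint(refR, altR, pos, lo, hi, s1, best, errorRate)
    if (is.null(bp)) return(NULL)
    list(from = if (side == "left") best else s1,
         to = if (side == "left") s1 else best,
         left = pos[bp[1]], right = pos[bp[2]])
}

legalTransitions <- function(design) {
    if (design == "BC1")
        list(c("hom_p1", "het"), c("het", "hom_p1"))
    else
        list(c("hom_p1", "het"), c("het", "hom_p1"),
             c("het", "hom_p2"), c("hom_p2", "het"))
}

#' Call crossovers in hybrid progeny from window genotypes
#'
#' A crossover is a sustained window-genotype transition (>= `minRunWins`
#' consecutive windows in each state) that is legal for the design: in BC1,
#' hom-P1 <-> het; in F2 additionally het <-> hom-P2.  Direct hom <-> hom
#' transitions (impossible in one meiosis) are flagged and excluded.  The
#' breakpoint is refined at SNP resolution by a binomial likelihood
#' changepoint, and the interval runs from the last SNP with error-robust
#' evidence for the left state to the first SNP with such evidence for the
#' right state (see the package vignette for the evidence rules); when no
#' refining SNPs are found the window-run boundaries are used.  Crossovers
#' closer to a chromosome end than window genotyping can resolve are
#' rescued by a terminal likelihood test.
#'
#' @param wins window genotypes from [genotypeWindows()].
#' @param adm the [AlleleDepthMatrix-class] the windows were computed from.
#' @param design "BC1" or "F2".
#' @param sex sex of the analysed meiosis (cross direction), recorded in
#'   the output.
#' @param minRunWins sustained-transition requirement (default 2 windows).
#' @return A [CrossoverSet-class]; impossible transitions appear in
#'   `coFlagged()`.
#' @export
callCrossoversHybrid <- function(wins, adm, design = c("BC1", "F2"),
                                 sex = "female", minRunWins = 2L,
                                 errorRate = 0.005) {
    design <- match.arg(design)
    legal <- legalTransitions(design)
    gr <- rowRanges(adm)
    chromAll <- as.character(seqnames(gr))
    refM <- refDepth(adm); altM <- altDepth(adm)
    calls <- list(); flagged <- list(); ci <- 0L; fi <- 0L
    for (ch in unique(wins$chrom)) {
        cidx <- which(chromAll == ch)
        pos <- start(gr)[cidx]
        wch <- wins[wins$chrom == ch, ]
        for (smp in unique(wch$sample)) {
            ws <- wch[wch$sample == smp, ]
            ws <- ws[order(ws$win), ]
            ok <- ws$call != "missing"
            if (sum(ok) < 2) next
            wsv <- ws[ok, ]
            r <- rle(wsv$call)
            # sustained states only: internal runs need minRunWins
            # windows; terminal runs may be single (a crossover close to a
            # chromosome end is seen by one window only, and a false
            # homozygosity call over a full window of summed reads is
            # essentially impossible)
            keepRun <- r$lengths >= minRunWins
            keepRun[c(1, length(keepRun))] <- TRUE
            if (sum(keepRun) < 2) next
            ends <- cumsum(r$lengths); startsR <- c(1, head(ends, -1) + 1)
            st <- r$values[keepRun]
            sIdx <- startsR[keepRun]; eIdx <- ends[keepRun]
            # merge consecutive identical surviving states
            j <- 1
            while (j < length(st)) {
                if (st[j] == st[j + 1]) {
                    eIdx[j] <- eIdx[j + 1]
                    st <- st[-(j + 1)]; sIdx <- sIdx[-(j + 1)]
                    eIdx <- eIdx[-(j + 1)]
                } else j <- j + 1
            }
            smpCol <- match(smp, colnames(adm))
            refR <- refM[cidx, smpCol]; altR <- altM[cidx, smpCol]
            # chromosome termini: rescue crossovers too close to an end
            # for window-level genotyping to see
            spanL <- wsv$endIdx[1]
            spanR <- length(pos) - wsv$startIdx[nrow(wsv)] + 1L
            if (length(st) == 1 || wsv$startIdx[eIdx[1]] > spanL) {
                tc <- terminalRescue(refR, altR, pos, st[1], "left",
                                     design, errorRate, span = spanL)
                if (!is.null(tc)) {
                    ci <- ci + 1L
                    calls[[ci]] <- data.frame(
                        sample = smp, parent = NA_character_, sex = sex,
                        chrom = ch, left = tc$left, right = tc$right,
                        from = tc$from, to = tc$to,
                        resolution = tc$right - tc$left,
                        stringsAsFactors = FALSE)
                }
            }
            nst <- length(st)
            if (nst == 1 ||
                wsv$endIdx[sIdx[nst]] < wsv$startIdx[nrow(wsv)]) {
                tc <- terminalRescue(refR, altR, pos, st[nst], "right",
                                     design, errorRate, span = spanR)
                if (!is.null(tc)) {
                    ci <- ci + 1L
                    calls[[ci]] <- data.frame(
                        sample = smp, parent = NA_character_, sex = sex,
                        chrom = ch, left = tc$left, right = tc$right,
                        from = tc$from, to = tc$to,
                        resolution = tc$right - tc$left,
                        stringsAsFactors = FALSE)
                }
            }
            if (length(st) < 2) next
            for (j in seq_len(length(st) - 1)) {
                s1 <- st[j]; s2 <- st[j + 1]
                isLegal <- any(vapply(legal, function(tr)
                    tr[1] == s1 && tr[2] == s2, logical(1)))
                lo <- wsv$startIdx[eIdx[j]]       # last window of left run
                hi <- wsv$endIdx[sIdx[j + 1]]     # first window of right run
                if (!isLegal) {
                    fi <- fi + 1L
                    flagged[[fi]] <- data.frame(
                        sample = smp, parent = NA_character_, sex = sex,
                        chrom = ch, left = pos[lo], right = pos[hi],
                        from = s1, to = s2, resolution = pos[hi] - pos[lo],
                        reason = "impossible_transition",
                        stringsAsFactors = FALSE)
                    next
                }
                bp <- refineBreakpoint(refR, altR, pos, lo, hi, s1, s2,
                                       errorRate)
                if (is.null(bp)) {
                    lpos <- wsv$end[eIdx[j]]
                    rpos <- wsv$start[sIdx[j + 1]]
                    if (!(lpos < rpos)) { lpos <- pos[lo]; rpos <- pos[hi] }
                } else {
                    lpos <- pos[bp[1]]; rpos <- pos[bp[2]]
                }
                ci <- ci + 1L
                calls[[ci]] <- data.frame(
                    sample = smp, parent = NA_character_, sex = sex,
                    chrom = ch, left = lpos, right = rpos,
                    from = s1, to = s2, resolution = rpos - lpos,
                    stringsAsFactors = FALSE)
            }
        }
    }
    CrossoverSet(
        if (ci) do.call(rbind, calls) else emptyCoFrame(),
        if (fi) do.call(rbind, flagged) else emptyCoFrame("reason"))
}

#' Sample-level QC for hybrid populations
#'
#' Drops samples whose fraction of missing windows exceeds `maxMissing`
#' (poor coverage) and BC1 samples whose fraction of hom-P2 windows exceeds
#' `contaminationMax` (a genotype impossible under the backcross design,
#' signalling contamination).
#'
#' @param wins window genotypes from [genotypeWindows()].
#' @param design "BC1" or "F2".
#' @param maxMissing maximum tolerated missing-window fraction (default 0.5).
#' @param contaminationMax maximum tolerated hom-P2 window fraction in BC1
#'   (default 0.05).
#' @return data.frame with `sample`, `fracMissing`, `fracHomP2`, `keep`,
#'   `reason` (`""`, `"coverage"` or `"contamination"`).
#' @export
qcSamples <- function(wins, design = c("BC1", "F2"), maxMissing = 0.5,
                      contaminationMax = 0.05) {
    design <- match.arg(design)
    sp <- split(wins$call, wins$sample)
    out <- do.call(rbind, lapply(names(sp), function(smp) {
        calls <- sp[[smp]]
        fm <- mean(calls == "missing")
        called <- calls[calls != "missing"]
        fh2 <- if (length(called)) mean(called == "hom_p2") else 0
        reason <- ""
        if (fm > maxMissing) reason <- "coverage"
        else if (design == "BC1" && fh2 > contaminationMax)
            reason <- "contamination"
        data.frame(sample = smp, fracMissing = fm, fracHomP2 = fh2,
                   keep = reason == "", reason = reason,
                   stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
    out
}
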