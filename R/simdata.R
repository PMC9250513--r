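## Forward simulator of the crossing designs: EMS marker sets, gamma-renewal
## meiosis with interference, and low-coverage allele-depth sampling.

#' Simulate an EMS marker set for one F1* parent
#'
#' Marker counts are allocated to chromosomes proportionally to length;
#' positions are uniform, sorted and unique within each chromosome.  Each
#' marker gets a true phase (A/B, fair coin) and an EMS-type substitution
#' (G->A or C->T with equal probability).
#'
#' @param layout a [GenomeLayout-class].
#' @param nMarkers total number of markers across the genome.
#' @param parentId label stored in the `parent` column.
#' @param seed RNG seed.
#' @return A [MarkerSet-class] with true `phase` labels.
#' @examples
#' ms <- simulateMarkerSet(GenomeLayout(c(chr1 = 1e6)), 100, "P1", seed = 7)
#' @export
simulateMarkerSet <- function(layout, nMarkers, parentId = "P1", seed = 1L) {
    sl <- chromLengths(layout)
    nMarkers <- as.integer(nMarkers)
    stopifnot2(nMarkers >= 0, "nMarkers must be >= 0")
    if (nMarkers == 0)
        return(MarkerSet(seqlengths = sl))
    withSeed(seed, {
        frac <- sl / sum(sl)
        n <- floor(nMarkers * frac)
        rem <- nMarkers - sum(n)
        if (rem > 0) {
            extra <- order(nMarkers * frac - n, decreasing = TRUE)[seq_len(rem)]
            n[extra] <- n[extra] + 1L
        }
        if (any(n > sl))
            stop("more markers requested than distinct positions available")
        chrom <- rep(names(sl), n)
        pos <- unlist(lapply(seq_along(sl), function(i) {
            sort(sample.int(sl[i], n[i]))
        }), use.names = FALSE)
        ref <- sample(c("G", "C"), sum(n), replace = TRUE)
        alt <- ifelse(ref == "G", "A", "T")
        phase <- sample(c("A", "B"), sum(n), replace = TRUE)
        MarkerSet(chrom, pos, ref, alt, parent = parentId, phase = phase,
                  seqlengths = sl)
    })
}

# CO positions on one bivalent from a stationary gamma renewal process on the
# genetic axis [0, lambda] (unit-mean inter-arrivals scaled by 1/lambda),
# started 20 mean inter-arrivals upstream for stationarity.
renewalEvents <- function(lambda, nu, burn = 20) {
    if (lambda <= 0) return(numeric())
    t <- -burn
    out <- numeric()
    repeat {
        draws <- rgamma(max(8L, ceiling(lambda)), shape = nu, rate = nu)
        pts <- t + cumsum(draws)
        t <- pts[length(pts)]
        out <- c(out, pts[pts > 0 & pts <= lambda])
        if (t > lambda) break
    }
    out
}

# Map genetic-axis fractions in [0,1] to bp through a piecewise-constant
# intensity track (GRanges with a numeric `score`); NULL means uniform.
geneticToBp <- function(u, chromLength, track = NULL) {
    if (is.null(track) || length(track) == 0)
        return(u * chromLength)
    s <- pmax(start(track) - 1, 0)
    e <- pmin(end(track), chromLength)
    w <- (e - s) * track$score
    cw <- cumsum(w) / sum(w)
    cw0 <- c(0, cw[-length(cw)])
    idx <- findInterval(u, cw0, rightmost.closed = FALSE)
    idx[idx < 1] <- 1L; idx[idx > length(w)] <- length(w)
    frac <- (u - cw0[idx]) / (cw[idx] - cw0[idx])
    s[idx] + frac * (e[idx] - s[idx])
}

#' Simulate meiosis: crossover placement with interference
#'
#' COs are placed on each bivalent by a stationary gamma renewal process
#' (shape `nu`; `nu = 1` is a Poisson process, larger `nu` gives
#' interference) scaled so the expected number of COs per bivalent equals
#' `intensity` for that chromosome.  Each bivalent CO is transmitted to the
#' sampled chromatid independently with probability 1/2, so the expected
#' transmitted count is `intensity / 2`.  With `obligateCo` the bivalent is
#' re-drawn (up to 10000 times) until it carries at least one CO.  COs whose
#' position falls inside a heterozygous inversion are discarded (after the
#' obligate-CO acceptance, so a fully inverted chromosome yields zero COs
#' rather than an infinite loop).
#'
#' @param layout a [GenomeLayout-class].
#' @param intensity expected COs per bivalent: a single number or a named
#'   per-chromosome vector.
#' @param nu gamma shape (> 0).
#' @param obligateCo logical.
#' @param hetInversions `GRanges` of heterozygous inversions (or NULL).
#' @param nGametes number of gametes to draw.
#' @param seed RNG seed.
#' @param intensityTrack optional `GRanges` with a `score` column giving a
#'   piecewise-constant relative CO intensity along each chromosome
#'   (uniform genetic map when NULL).
#' @return A [SimTruth-class].
#' @examples
#' tr <- simulateMeiosis(GenomeLayout(c(chr1 = 3e7)), intensity = 2,
#'                       nu = 1, nGametes = 10, seed = 1)
#' @export
simulateMeiosis <- function(layout, intensity, nu = 1, obligateCo = FALSE,
                            hetInversions = NULL, nGametes = 1L, seed = 1L,
                            intensityTrack = NULL) {
    stopifnot2(nu > 0, "nu must be > 0")
    stopifnot2(all(intensity >= 0), "intensity must be >= 0")
    sl <- chromLengths(layout)
    lam <- if (length(intensity) == 1) setNames(rep(intensity, length(sl)),
                                               names(sl))
           else intensity[names(sl)]
    withSeed(seed, {
        evG <- list(); evB <- list(); k <- 0L
        sp <- expand.grid(gamete = seq_len(nGametes), chrom = names(sl),
                          stringsAsFactors = FALSE)
        sp$phase <- sample(c("A", "B"), nrow(sp), replace = TRUE)
        for (chrom in names(sl)) {
            L <- sl[[chrom]]
            inv <- if (!is.null(hetInversions))
                hetInversions[as.character(seqnames(hetInversions)) == chrom]
            else NULL
            trk <- if (!is.null(intensityTrack))
                intensityTrack[as.character(seqnames(intensityTrack)) == chrom]
            else NULL
            for (g in seq_len(nGametes)) {
                tries <- 0L
                repeat {
                    ev <- renewalEvents(lam[[chrom]], nu)
                    tries <- tries + 1L
                    if (!obligateCo || length(ev) > 0 || lam[[chrom]] == 0)
                        break
                    if (tries >= 10000L)
                        stop("obligate CO: rejection cap reached on ", chrom)
                }
                if (length(ev)) {
                    pos <- geneticToBp(ev / lam[[chrom]], L, trk)
                    if (!is.null(inv) && length(inv)) {
                        drop <- rep(FALSE, length(pos))
                        for (i in seq_along(inv))
                            drop <- drop | (pos >= start(inv)[i] &
                                            pos <= end(inv)[i])
                        pos <- pos[!drop]
                    }
                    pos <- sort(pos)
                    if (length(pos)) {
                        k <- k + 1L
                        evB[[k]] <- data.frame(gamete = g, chrom = chrom,
                                               pos = pos)
                        keep <- runif(length(pos)) < 0.5
                        if (any(keep))
                            evG[[k]] <- data.frame(gamete = g, chrom = chrom,
                                                   pos = pos[keep])
                    }
                }
            }
        }
        bind <- function(x) if (length(x)) do.call(rbind, x)
                            else data.frame(gamete = integer(),
                                            chrom = character(),
                                            pos = numeric())
        new("SimTruth", events = bind(evG), bivalentEvents = bind(evB),
            startPhase = sp, nGametes = as.integer(nGametes))
    })
}

# Sample allele depths for a carrier indicator matrix (markers x samples):
# depth ~ Poisson(meanDepth); alt | depth ~ Binomial(depth, p) with p = 1/2
# for heterozygous carriers and p = errorRate otherwise.
sampleDepths <- function(carrier, meanDepth, errorRate, hetProb = 0.5) {
    n <- length(carrier)
    depth <- rpois(n, meanDepth)
    p <- ifelse(carrier, hetProb, errorRate)
    alt <- rbinom(n, depth, p)
    list(ref = matrix(depth - alt, nrow(carrier), ncol(carrier)),
         alt = matrix(alt, nrow(carrier), ncol(carrier)))
}

# Transmitted-haplotype phase for every (marker position, gamete) pair.
phaseMatrixFromTruth <- function(truth, markers) {
    chrom <- as.character(seqnames(markers))
    pos <- start(markers)
    out <- matrix(NA_character_, length(markers), truth@nGametes)
    ev <- truth@events
    sp <- truth@startPhase
    for (ch in unique(chrom)) {
        idx <- which(chrom == ch)
        for (g in seq_len(truth@nGametes)) {
            p0 <- sp$phase[sp$gamete == g & sp$chrom == ch]
            cop <- sort(ev$pos[ev$gamete == g & ev$chrom == ch])
            nf <- findInterval(pos[idx], cop)
            out[idx, g] <- ifelse(nf %% 2 == 0, p0, otherPhase(p0))
        }
    }
    out
}

#' Simulate an inbred F1 population (two F1* parents, EMS markers)
#'
#' Emulates the inbred-line design: two F1* parents, each heterozygous for a
#' private set of EMS markers split between two phases, are reciprocally
#' crossed; every F1 receives one recombinant haplotype from each parent
#' (parent 1 contributing the female meiosis, parent 2 the male).  Allele
#' depths at each parent's markers are sampled at low coverage: a sample
#' carrying the mutant phase is heterozygous (alt ~ Binomial(depth, 1/2));
#' otherwise alt reads arise only through sequencing error.
#'
#' @param cfg a [SimConfig-class].
#' @param layout a [GenomeLayout-class].
#' @return list with elements `markers` (list of two [MarkerSet-class]),
#'   `depths` (list of two [AlleleDepthMatrix-class]), `truth` (list of two
#'   [SimTruth-class], female/male) and `cfg`.
#' @export
simulateInbredPopulation <- function(cfg, layout) {
    validObject(cfg)
    seed <- cfg@seed
    ms1 <- simulateMarkerSet(layout, cfg@markerCount, "P1",
                             childSeed(seed, 1))
    ms2 <- simulateMarkerSet(layout, cfg@markerCount, "P2",
                             childSeed(seed, 2))
    trF <- simulateMeiosis(layout, cfg@intensity[["female"]], cfg@nu,
                           cfg@obligateCo, cfg@inversions, cfg@nSamples,
                           childSeed(seed, 3))
    trM <- simulateMeiosis(layout, cfg@intensity[["male"]], cfg@nu,
                           cfg@obligateCo, cfg@inversions, cfg@nSamples,
                           childSeed(seed, 4))
    sampleNames <- sprintf("F1_%03d", seq_len(cfg@nSamples))
    mkDepth <- function(ms, truth, k) {
        hap <- phaseMatrixFromTruth(truth, ms)
        carrier <- hap == matrix(ms$phase, length(ms), cfg@nSamples)
        withSeed(childSeed(seed, k), {
            d <- sampleDepths(carrier, cfg@meanDepth, cfg@errorRate)
            AlleleDepthMatrix(ms, d$ref, d$alt, sampleNames)
        })
    }
    list(markers = list(P1 = ms1, P2 = ms2),
         depths = list(P1 = mkDepth(ms1, trF, 5), P2 = mkDepth(ms2, trM, 6)),
         truth = list(female = trF, male = trM),
         cfg = cfg)
}

#' Simulate a hybrid BC1 or F2 population genotyped at dense SNPs
#'
#' BC1: each sample carries one fixed parent-1 (Col-like) haplotype from the
#' recurrent parent plus one recombinant F1 gamete, so every position is
#' hom-P1 or het.  F2: two independent recombinant gametes (one female, one
#' male meiosis).  Allele depths at the SNPs are sampled as in
#' [simulateInbredPopulation()]; the `ref` assay counts parent-1 (Col)
#' reads, `alt` parent-2 (Ler) reads.  Phase "A" of a gamete denotes the
#' parent-1 haplotype.
#'
#' @param cfg a [SimConfig-class] (`nSamples`, `meanDepth`, `errorRate`,
#'   `intensity`, `nu`, `obligateCo`, `inversions`, `seed` are used).
#' @param layout a [GenomeLayout-class].
#' @param snpDensity SNP markers per Mb (default 200, i.e. one per 5 kb).
#' @param design "BC1" or "F2".
#' @param sex which meiosis produced the transmitted gamete in BC1
#'   ("female": the F1 hybrid was the seed parent).
#' @return list with `snps` (GRanges), `depths` ([AlleleDepthMatrix-class]),
#'   `truth` (list of [SimTruth-class]; one gamete set for BC1, female+male
#'   for F2), `genotype` (integer matrix, copies of the parent-2 allele),
#'   `design`, `cfg`.
#' @export
simulateHybridPopulation <- function(cfg, layout, snpDensity = 200,
                                     design = c("BC1", "F2"),
                                     sex = c("female", "male")) {
    design <- match.arg(design)
    sex <- match.arg(sex)
    validObject(cfg)
    seed <- cfg@seed
    sl <- chromLengths(layout)
    snps <- withSeed(childSeed(seed, 11), {
        n <- pmax(2L, as.integer(round(sl / 1e6 * snpDensity)))
        GRanges(rep(names(sl), n), IRanges(unlist(lapply(
            seq_along(sl), function(i) sort(sample.int(sl[i], n[i]))),
            use.names = FALSE), width = 1L))
    })
    GenomeInfoDb::seqlevels(snps) <- names(sl)
    sampleNames <- sprintf("%s_%03d", design, seq_len(cfg@nSamples))
    gamete1 <- simulateMeiosis(layout, cfg@intensity[[sex]], cfg@nu,
                               cfg@obligateCo, cfg@inversions, cfg@nSamples,
                               childSeed(seed, 12))
    hap1 <- phaseMatrixFromTruth(gamete1, snps)  # "A" = P1/Col haplotype
    if (design == "BC1") {
        geno <- (hap1 == "B") + 0L               # copies of P2 allele: 0 or 1
        truth <- list(gamete = gamete1)
    } else {
        gamete2 <- simulateMeiosis(layout, cfg@intensity[["male"]], cfg@nu,
                                   cfg@obligateCo, cfg@inversions,
                                   cfg@nSamples, childSeed(seed, 13))
        hap2 <- phaseMatrixFromTruth(gamete2, snps)
        geno <- (hap1 == "B") + (hap2 == "B")
        truth <- list(female = gamete1, male = gamete2)
    }
    depths <- withSeed(childSeed(seed, 14), {
        n <- length(geno)
        depth <- rpois(n, cfg@meanDepth)
        p <- c(cfg@errorRate, 0.5, 1 - cfg@errorRate)[geno + 1L]
        alt <- rbinom(n, depth, p)
        AlleleDepthMatrix(snps,
                          matrix(depth - alt, nrow(geno), ncol(geno)),
                          matrix(alt, nrow(geno), ncol(geno)),
                          sampleNames)
    })
    list(snps = snps, depths = depths, truth = truth, genotype = geno,
         design = design, sex = sex, cfg = cfg)
}
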