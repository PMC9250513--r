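randomCos <- function(n, L = 3e7, nGametes = 500, seed = 2) {
    set.seed(seed)
    data.frame(sample = sample(seq_len(nGametes), n, replace = TRUE),
               chrom = "c1", mid = runif(n, 1, L - 1))
}

test_that("window counts conserve the total number of crossovers", {
    lay <- oneChrom()
    cos <- randomCos(800)
    trk <- coFrequencyTrack(cos, lay, nGametes = 500, win = 5e4,
                            step = 5e4, ci = NULL)
    expect_equal(sum(trk$count), 800L)
    expect_equal(trk$freq, trk$count / 500)
    # empty list: all-zero track with degenerate CI
    trk0 <- coFrequencyTrack(cos[0, ], lay, nGametes = 500, win = 5e4,
                             step = 5e4)
    expect_true(all(trk0$count == 0))
    expect_true(all(trk0$ciLow == 0 & trk0$ciHigh == 0))
    expect_error(coFrequencyTrack(cos, lay, 500, win = 2e6, step = 3e4),
                 "multiple")
})

test_that("a point mass hits exactly win/step sliding windows", {
    lay <- oneChrom()
    cos <- data.frame(sample = 1:10, chrom = "c1", mid = 1.5e7 + 25000)
    trk <- coFrequencyTrack(cos, lay, nGametes = 10, win = 2e6, step = 5e4,
                            ci = NULL)
    expect_equal(sum(trk$count > 0), 40L)            # 2 Mb / 50 kb
    expect_true(all(trk$count[trk$count > 0] == 10L))
})

test_that("bootstrap confidence bands bracket the truth at nominal rate", {
    lay <- oneChrom()
    tr <- simulateMeiosis(lay, intensity = 2, nu = 1, nGametes = 2000,
                          seed = 61)
    ev <- coTruth(tr)
    cos <- data.frame(sample = ev$gamete, chrom = ev$chrom, mid = ev$pos)
    trk <- coFrequencyTrack(cos, lay, nGametes = 2000, win = 2e6,
                            step = 5e4, ci = 0.90, nBoot = 400, seed = 7)
    trueFreq <- 1 * 2e6 / 3e7          # uniform landscape, 1 CO per gamete
    cover <- mean(trk$ciLow <= trueFreq & trk$ciHigh >= trueFreq)
    expect_gte(cover, 0.85)
    expect_true(all(trk$ciLow <= trk$freq & trk$freq <= trk$ciHigh))
})

test_that("normalization and smoothing identities hold", {
    lay <- oneChrom()
    cos <- randomCos(1200)
    trk <- coFrequencyTrack(cos, lay, nGametes = 500, win = 5e4,
                            step = 5e4, ci = NULL)
    sm <- normalizeAndSmooth(trk, k = 40)
    expect_equal(sum(sm$rel), 1)
    ok <- !is.na(sm$z)
    expect_lt(abs(mean(sm$z[ok])), 1e-12)
    expect_lt(abs(stats::sd(sm$z[ok]) - 1), 1e-12)
    # unit impulse away from the ends: mass preserved, spread 1/k over k
    trk2 <- trk
    trk2$count <- 0L; trk2$count[300] <- 10L
    sm2 <- normalizeAndSmooth(trk2, k = 40)
    expect_equal(sum(sm2$smoothed, na.rm = TRUE), 1)
    expect_equal(max(sm2$smoothed, na.rm = TRUE), 1 / 40)
    # constant input: smoothing is the identity on defined positions
    trk3 <- trk
    trk3$count <- rep(5L, length(trk3))
    sm3 <- suppressWarnings(normalizeAndSmooth(trk3, k = 40))
    ok3 <- !is.na(sm3$smoothed)
    expect_equal(sm3$smoothed[ok3], sm3$rel[ok3], tolerance = 1e-12)
    expect_true(all(sm3$z[ok3] == 0))  # sd 0 handled with a warning
    # ends where the centered window is incomplete are missing
    expect_true(all(is.na(sm$smoothed[1:19])))
})

test_that("a chromosome without crossovers warns and goes missing", {
    lay <- GenomeLayout(c(c1 = 1e6, c2 = 1e6))
    cos <- data.frame(sample = 1:5, chrom = "c1", mid = seq(1e5, 9e5, 2e5))
    trk <- coFrequencyTrack(cos, lay, nGametes = 5, win = 5e4, step = 5e4,
                            ci = NULL)
    # warns once about the empty chromosome and once about the z-score
    # scope losing variance with half the genome missing
    ws <- capture_warnings(sm <- normalizeAndSmooth(trk, k = 4))
    expect_true(any(grepl("zero COs", ws)))
    expect_true(all(is.na(sm$rel[as.character(seqnames(sm)) == "c2"])))
})

test_that("peak and valley detection finds constructed extrema", {
    lay <- oneChrom()
    cos <- randomCos(10)
    trk <- coFrequencyTrack(cos, lay, nGametes = 10, win = 5e4, step = 5e4,
                            ci = NULL)
    n <- length(trk)
    x <- seq_len(n)
    # single bump
    trk$smoothed <- stats::dnorm(x, 300, 40)
    pk <- detectPeaksValleys(trk, minProminence = 1e-4)
    pk <- pk[pk$type == "peak", ]
    expect_equal(nrow(pk), 1)
    expect_equal(pk$pos, (start(trk)[300] + end(trk)[300]) / 2)
    # two bumps plus sub-prominence noise
    set.seed(9)
    trk$smoothed <- stats::dnorm(x, 150, 30) + stats::dnorm(x, 420, 30) +
        rnorm(n, 0, 2e-4)
    pk2 <- detectPeaksValleys(trk, minProminence = 3e-3)
    expect_equal(nrow(pk2[pk2$type == "peak", ]), 2)
    # monotone track: no internal extrema
    trk$smoothed <- x / n
    expect_equal(nrow(detectPeaksValleys(trk, minProminence = 1e-6)), 0)
})

test_that("nlcor captures non-monotone structure that Spearman misses", {
    x <- seq(-1, 1, length.out = 500)
    expect_equal(nlcorCoefficient(x, 2 * x), 1)
    expect_equal(correlateTracks(x, 2 * x, method = "spearman"), 1)
    # symmetric V: Spearman blind, nlcor strong
    y <- abs(x - stats::median(x))
    expect_lt(abs(cor(x, y, method = "spearman")), 0.1)
    expect_gte(nlcorCoefficient(x, y), 0.8)
    # independent noise stays near zero for both
    set.seed(5)
    vals <- replicate(20, {
        a <- rnorm(1000); b <- rnorm(1000)
        c(nlcorCoefficient(a, b), abs(cor(a, b, method = "spearman")))
    })
    expect_gte(mean(vals[1, ] < 0.1), 0.95)
    expect_true(all(vals[2, ] < 0.1))
    expect_error(nlcorCoefficient(1:5, 1:5), "10")
    # invariance to x-translation and positive scaling
    expect_equal(nlcorCoefficient(10 + 3 * x, y), nlcorCoefficient(x, y))
    # at least as strong as |Pearson| on monotone linear data
    set.seed(6)
    a <- rnorm(300); b <- 2 * a + rnorm(300, 0, 0.4)
    expect_gte(nlcorCoefficient(a, b) + 0.05, abs(cor(a, b)))
})

test_that("track correlation respects compartment scopes", {
    lay <- arabidopsisLayout()
    tr <- simulateMeiosis(lay, intensity = 2, nu = 1, nGametes = 300,
                          seed = 71)
    ev <- coTruth(tr)
    cos <- data.frame(sample = ev$gamete, chrom = ev$chrom, mid = ev$pos)
    trk <- coFrequencyTrack(cos, lay, nGametes = 300, win = 5e4, step = 5e4,
                            ci = NULL)
    sm <- normalizeAndSmooth(trk, k = 40)
    full <- correlateTracks(sm, sm, method = "spearman")
    arms <- correlateTracks(sm, sm, method = "spearman", scope = "arms",
                            layout = lay)
    expect_equal(full, 1); expect_equal(arms, 1)
    expect_error(correlateTracks(sm, sm, scope = "arms"), "layout")
})

test_that("permutation overlap test reaches its floor and stays calibrated", {
    lay <- oneChrom()
    # complete depletion: regions cover half the genome, COs avoid them
    reg <- GRanges("c1", IRanges(1, 1.5e7))
    cos <- data.frame(sample = 1, chrom = "c1",
                      mid = runif(400, 1.6e7, 3e7 - 1))
    pt <- permutationOverlapTest(cos, reg, lay, nPerm = 4999, seed = 3)
    expect_equal(pt$observed, 0L)
    expect_equal(pt$pDeplete, 1 / 5000)
    expect_equal(pt$direction, "depleted")
    # regions covering everything: overlap certain, enrichment p = 1
    regAll <- GRanges("c1", IRanges(1, 3e7))
    ptAll <- permutationOverlapTest(cos, regAll, lay, nPerm = 499, seed = 3)
    expect_equal(ptAll$pEnrich, 1)
    expect_error(permutationOverlapTest(cos[0, ], reg, lay), "empty")
    expect_error(permutationOverlapTest(cos, reg, lay, nPerm = 10), "100")
    # null calibration: uniform COs vs a fixed region give uniform p
    set.seed(11)
    ps <- replicate(60, {
        cosN <- data.frame(sample = 1, chrom = "c1",
                           mid = runif(150, 1, 3e7))
        permutationOverlapTest(cosN, reg, lay, nPerm = 199,
                               seed = sample.int(1e6, 1))$pDeplete
    })
    expect_gt(suppressWarnings(stats::ks.test(ps, "punif")$p.value), 0.01)
})

test_that("adjacency mode tests the flanks, not the regions", {
    lay <- oneChrom()
    reg <- GRanges("c1", IRanges(1e7, 1.1e7))
    # all COs packed into the 50-kb flanks
    cos <- data.frame(sample = 1, chrom = "c1",
                      mid = c(runif(50, 1e7 - 4e4, 1e7 - 1),
                              runif(50, 1.1e7 + 1, 1.1e7 + 4e4)))
    pt <- permutationOverlapTest(cos, reg, lay, nPerm = 999, seed = 5,
                                 mode = "adjacency", flankWidth = 5e4)
    expect_equal(pt$observed, 100L)
    expect_equal(pt$pEnrich, 1 / 1000)
    expect_equal(pt$direction, "enriched")
})

test_that("coefficient of coincidence handles degenerate inputs", {
    ev <- data.frame(gamete = c(1, 2, 3), pos = c(1e6, 5e6, 9e6))
    out <- interferenceCoc(ev, nGametes = 100, chromLength = 1e7,
                           binWidth = 2e6)
    expect_true(all(out$coc$coc[!is.na(out$coc$coc)] == 0))
    expect_error(interferenceCoc(ev, 100, 1e7, binWidth = 0), "binWidth")
    expect_error(interferenceCoc(ev[1, , drop = FALSE], 100, 1e7, 2e6),
                 "2 COs")
    # spacing summary
    ev2 <- data.frame(gamete = c(1, 1, 1), pos = c(1e6, 2e6, 4e6))
    out2 <- interferenceCoc(ev2, 10, 1e7, 1e6)
    expect_equal(out2$spacing$mean, 1.5e6)
    expect_equal(out2$spacing$n, 2)
})
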