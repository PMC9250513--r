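test_that("simulated marker sets are sorted, unique, EMS-typed and reproducible", {
    lay <- GenomeLayout(c(chr1 = 1e6))
    ms <- simulateMarkerSet(lay, 100, "P1", seed = 7)
    expect_length(ms, 100)
    expect_false(is.unsorted(start(ms)))
    expect_false(anyDuplicated(start(ms)) > 0)
    expect_true(all(start(ms) >= 1 & start(ms) <= 1e6))
    expect_true(all(emsSubstitutionCheck(ms$ref, ms$alt)))
    expect_true(all(ms$phase %in% c("A", "B")))
    # determinism
    ms2 <- simulateMarkerSet(lay, 100, "P1", seed = 7)
    expect_identical(start(ms), start(ms2))
    expect_identical(ms$phase, ms2$phase)
    # empty set is valid
    expect_length(simulateMarkerSet(lay, 0, "P1", seed = 1), 0)
    # allocation proportional to length
    lay2 <- GenomeLayout(c(a = 3e6, b = 1e6))
    ms3 <- simulateMarkerSet(lay2, 400, "P1", seed = 2)
    expect_equal(sum(seqnames(ms3) == "a"), 300)
    expect_error(simulateMarkerSet(GenomeLayout(c(a = 10)), 50, "P1", 1),
                 "more markers")
})

test_that("meiosis simulation honours intensity, thinning and suppression", {
    lay <- oneChrom()
    expect_error(simulateMeiosis(lay, 1, nu = 0), "nu")
    # intensity 0: no COs at all
    tr0 <- simulateMeiosis(lay, 0, nGametes = 50, seed = 1)
    expect_equal(nrow(coTruth(tr0)), 0)
    # transmitted mean = lambda / 2 (thinning of the bivalent process)
    tr <- simulateMeiosis(lay, intensity = 2, nu = 1, nGametes = 10000,
                          seed = 3)
    m <- nrow(coTruth(tr)) / 10000
    se <- sqrt(1 / 10000)       # Poisson mean 1 per gamete
    expect_lt(abs(m - 1), 3 * se)
    # whole-chromosome heterozygous inversion suppresses everything
    inv <- GRanges("c1", IRanges(1, 3e7))
    trI <- simulateMeiosis(lay, 2, nu = 1, hetInversions = inv,
                           nGametes = 100, seed = 4)
    expect_equal(nrow(coTruth(trI)), 0)
    expect_equal(nrow(trI@bivalentEvents), 0)
    # obligate CO: every bivalent carries at least one
    trO <- simulateMeiosis(lay, 0.3, nu = 1, obligateCo = TRUE,
                           nGametes = 200, seed = 5)
    expect_equal(length(unique(trO@bivalentEvents$gamete)), 200)
    # determinism
    trA <- simulateMeiosis(lay, 2, nu = 5, nGametes = 20, seed = 9)
    trB <- simulateMeiosis(lay, 2, nu = 5, nGametes = 20, seed = 9)
    expect_identical(coTruth(trA), coTruth(trB))
})

test_that("gamma renewal interference has the expected spacing statistics", {
    lay <- oneChrom()
    # nu = 1: inter-CO distances on the bivalent consistent with exponential
    tr1 <- simulateMeiosis(lay, intensity = 12, nu = 1, nGametes = 600,
                           seed = 41)
    bv <- tr1@bivalentEvents
    sp <- unlist(lapply(split(bv$pos, bv$gamete),
                        function(p) if (length(p) > 1) diff(sort(p))
                                    else numeric()))
    set.seed(1)
    sp <- sample(sp, 5000)
    expect_gt(suppressWarnings(
        stats::ks.test(sp, "pexp", 1 / mean(sp))$p.value), 0.01)
    # nu = 10: spacing CV well below 1 (theory: 1/sqrt(10) ~ 0.32)
    tr10 <- simulateMeiosis(lay, intensity = 12, nu = 10, nGametes = 600,
                            seed = 43)
    bv10 <- tr10@bivalentEvents
    sp10 <- unlist(lapply(split(bv10$pos, bv10$gamete),
                          function(p) if (length(p) > 1) diff(sort(p))
                                      else numeric()))
    cv <- stats::sd(sp10) / mean(sp10)
    expect_lt(cv + 3 * cv / sqrt(2 * length(sp10)), 1)   # significantly < 1
    expect_lt(cv, 0.5)
})

test_that("inbred population read model is faithful to the design", {
    lay <- oneChrom()
    cfg <- SimConfig(nSamples = 120, markerCount = 200, seed = 5)
    pop <- simulateInbredPopulation(cfg, lay)
    adm <- pop$depths$P1
    expect_s4_class(adm, "AlleleDepthMatrix")
    expect_equal(dim(adm), c(200L, 120L))
    # grand mean depth within 2% of the Poisson mean
    expect_lt(abs(mean(totalDepth(adm)) - 5) / 5, 0.02)
    # error = 0: no alt signal at markers of the non-transmitted phase
    cfg0 <- SimConfig(nSamples = 40, markerCount = 100, errorRate = 0,
                      seed = 6)
    pop0 <- simulateInbredPopulation(cfg0, lay)
    ms <- pop0$markers$P1
    hap <- vapply(seq_len(40), function(g)
        truePhaseAt(pop0$truth$female, g, "c1", start(ms)),
        character(length(ms)))
    carrier <- hap == matrix(ms$phase, length(ms), 40)
    expect_true(all(altDepth(pop0$depths$P1)[!carrier] == 0))
    # carriers do show the mutant allele overall
    expect_gt(mean(altDepth(pop0$depths$P1)[carrier] > 0), 0.85)
    # determinism
    popB <- simulateInbredPopulation(cfg0, lay)
    expect_identical(altDepth(pop0$depths$P1), altDepth(popB$depths$P1))
})

test_that("transmitted haplotypes flip phase exactly at the simulated COs", {
    lay <- oneChrom()
    tr <- simulateMeiosis(lay, 3, nu = 1, nGametes = 30, seed = 8)
    ev <- coTruth(tr)
    for (g in unique(ev$gamete)) {
        cop <- sort(ev$pos[ev$gamete == g])
        before <- truePhaseAt(tr, g, "c1", cop - 0.5)
        after <- truePhaseAt(tr, g, "c1", cop + 0.5)
        expect_true(all(before != after))
    }
})

test_that("hybrid populations obey the BC1/F2 genotype structure", {
    lay <- GenomeLayout(c(c1 = 5e6))
    cfg <- SimConfig(nSamples = 30, errorRate = 0, seed = 11)
    bc <- simulateHybridPopulation(cfg, lay, snpDensity = 100,
                                   design = "BC1")
    expect_true(all(bc$genotype %in% 0:1))
    # hom-Col positions carry no Ler reads at error 0
    expect_true(all(altDepth(bc$depths)[bc$genotype == 0] == 0))
    f2 <- simulateHybridPopulation(cfg, lay, snpDensity = 100, design = "F2")
    expect_true(all(f2$genotype %in% 0:2))
    # zero-CO chromosomes are genotype-constant along their length
    cfg0 <- SimConfig(nSamples = 40, intensity = c(female = 0, male = 0),
                      obligateCo = FALSE, seed = 12)
    f20 <- simulateHybridPopulation(cfg0, lay, snpDensity = 100,
                                    design = "F2")
    perSample <- apply(f20$genotype, 2, function(v) length(unique(v)))
    expect_true(all(perSample == 1))
    expect_gt(length(unique(f20$genotype[1, ])), 1)
    # determinism
    bc2 <- simulateHybridPopulation(cfg, lay, snpDensity = 100,
                                    design = "BC1")
    expect_identical(altDepth(bc$depths), altDepth(bc2$depths))
    expect_error(simulateHybridPopulation(cfg, lay, design = "BC2"))
})
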