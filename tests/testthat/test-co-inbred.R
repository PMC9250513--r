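test_that("phase switches become crossovers with marker-position bounds", {
    # A A A B B: one CO between markers 3 and 4
    toy <- toyPhased(c("A", "A", "A", "B", "B"),
                     labels = c("A", "A", "A", "B", "B"))
    cos <- callCrossovers(toy$pm, toy$adm)
    expect_equal(length(cos), 1)
    cl <- coCalls(cos)
    expect_equal(cl$left, 3000)
    expect_equal(cl$right, 4000)
    expect_equal(cl$from, "A"); expect_equal(cl$to, "B")
    expect_equal(cl$resolution, 1000)
    # no switch, no CO
    toy2 <- toyPhased(rep("A", 5), labels = rep("A", 5))
    expect_equal(length(callCrossovers(toy2$pm, toy2$adm)), 0)
    # empty phase sequence
    toy3 <- toyPhased(rep(NA_character_, 5))
    expect_equal(length(callCrossovers(toy3$pm, toy3$adm)), 0)
})

test_that("isolated internal flips are masked as noise", {
    # A A B A A with weak evidence for the lone B: no CO
    toy <- toyPhased(c("A", "A", "B", "A", "A"),
                     labels = c("A", "A", "A", "A", "A"),
                     alt = c(3, 3, 0, 3, 3),
                     depth = c(6, 6, 4, 6, 6))
    expect_equal(length(callCrossovers(toy$pm, toy$adm)), 0)
})

test_that("a double crossover with strong evidence yields two calls", {
    toy <- toyPhased(c("A", "A", "B", "B", "A", "A"),
                     labels = c("A", "A", "B", "B", "A", "A"))
    cos <- callCrossovers(toy$pm, toy$adm)
    expect_equal(length(cos), 2)
    cl <- coCalls(cos)
    expect_equal(cl$from, c("A", "B"))
    expect_equal(cl$to, c("B", "A"))
    expect_equal(cl$left, c(2000, 4000))
    expect_equal(cl$right, c(3000, 5000))
})

test_that("terminal validation follows the printed read-support rule", {
    # pure rule
    expect_true(validateTerminalCO(4, 0))          # well-supported mutant
    expect_true(validateTerminalCO(3, 0))
    expect_false(validateTerminalCO(2, 10))        # 10 reads is not > 10
    expect_true(validateTerminalCO(1, 12))         # deep wild-type
    expect_true(validateTerminalCO(0, 11))
    expect_false(validateTerminalCO(1, 5))         # fails both clauses
    expect_false(validateTerminalCO(NA, NA))
    # integrated: terminal single-marker switch accepted on 4 alt reads
    toy <- toyPhased(c("A", "A", "A", "A", "B"),
                     labels = c("A", "A", "A", "A", "B"),
                     alt = c(3, 3, 3, 3, 4),
                     depth = c(6, 6, 6, 6, 8))
    cos <- callCrossovers(toy$pm, toy$adm)
    expect_equal(length(cos), 1)
    expect_equal(coCalls(cos)$left, 4000)
    # rejected on 1 alt read with shallow wild-type context
    toy2 <- toyPhased(c("A", "A", "A", "A", "B"),
                      labels = c("A", "A", "A", "A", "B"),
                      alt = c(3, 3, 3, 3, 1),
                      depth = c(6, 6, 6, 6, 5))
    expect_equal(length(callCrossovers(toy2$pm, toy2$adm)), 0)
    # accepted when the consecutive wild-type observation carries > 10
    # reads: a deep ref-only site at an old-phase marker demonstrates the
    # sample lacks the old phase there
    toy3 <- toyPhased(c("A", "A", "A", "A", "B"),
                      labels = c("A", "A", "A", "A", "A"),
                      alt = c(3, 3, 3, 3, 0),
                      depth = c(6, 6, 6, 6, 12))
    expect_equal(length(callCrossovers(toy3$pm, toy3$adm)), 1)
    toy4 <- toyPhased(c("A", "A", "A", "A", "B"),
                      labels = c("A", "A", "A", "A", "A"),
                      alt = c(3, 3, 3, 3, 0),
                      depth = c(6, 6, 6, 6, 9))
    expect_equal(length(callCrossovers(toy4$pm, toy4$adm)), 0)
})

test_that("call parity matches the endpoint phases on clean data", {
    lay <- oneChrom()
    cfg <- SimConfig(nSamples = 40, markerCount = 120, meanDepth = 30,
                     errorRate = 0, seed = 31)
    pop <- simulateInbredPopulation(cfg, lay)
    pm <- phaseMarkers(pop$depths$P1)
    cos <- callCrossovers(pm, pop$depths$P1)
    cl <- coCalls(cos)
    ph <- phaseCalls(pm)
    for (s in seq_len(40)) {
        v <- ph[, s]; v <- v[!is.na(v)]
        nCo <- sum(cl$sample == colnames(pop$depths$P1)[s])
        expect_equal(nCo %% 2, as.integer(v[1] != v[length(v)]))
    }
})

test_that("swapping phase labels leaves crossover calls unchanged", {
    lay <- oneChrom()
    cfg <- SimConfig(nSamples = 50, markerCount = 100, seed = 32)
    pop <- simulateInbredPopulation(cfg, lay)
    adm <- pop$depths$P1
    pm <- phaseMarkers(adm)
    cos <- coCalls(callCrossovers(pm, adm))
    # relabel A<->B everywhere in the PhaseMatrix
    flip <- function(x) ifelse(x == "A", "B", ifelse(x == "B", "A", x))
    pm2 <- pm
    pm2@phase <- matrix(flip(pm@phase), nrow(pm@phase))
    pm2@markers$phaseLabel <- flip(pm2@markers$phaseLabel)
    cos2 <- coCalls(callCrossovers(pm2, adm))
    expect_equal(cos$left, cos2$left)
    expect_equal(cos$right, cos2$right)
    expect_equal(cos$from, flip(cos2$from))
})

test_that("resolution shrinks as marker density grows", {
    lay <- oneChrom()
    med <- vapply(c(300L, 900L), function(n) {
        cfg <- SimConfig(nSamples = 80, markerCount = n, seed = 33)
        pop <- simulateInbredPopulation(cfg, lay)
        pm <- phaseMarkers(pop$depths$P1)
        cl <- coCalls(callCrossovers(pm, pop$depths$P1))
        # bounds are genuine marker positions
        expect_true(all(cl$left %in% start(pop$markers$P1)))
        expect_true(all(cl$right %in% start(pop$markers$P1)))
        median(cl$resolution)
    }, numeric(1))
    expect_lt(med[2], med[1])
})

test_that("per-gamete counts and Mann-Whitney comparison behave", {
    cl <- data.frame(sample = c("a", "a", "b"), chrom = "c1",
                     left = 1, right = 2, from = "A", to = "B")
    samples <- c("a", "b", "c", "d")
    groups <- c("f", "f", "m", "m")
    out <- coCountSummary(cl, samples, groups)
    expect_equal(out$perSample$n, c(2L, 1L, 0L, 0L))
    expect_equal(unname(out$groupMeans["f"]), 1.5)
    # identical groups: p in the tie region
    cl2 <- data.frame(sample = rep(c("a", "b", "c", "d"), each = 2),
                      chrom = "c1", left = 1, right = 2,
                      from = "A", to = "B")
    out2 <- coCountSummary(cl2, samples, groups)
    expect_gt(out2$tests$p, 0.99)
    expect_error(coCountSummary(cl, samples, rep("f", 4)), "2 groups")
    expect_error(coCountSummary(cl, samples[1:2], groups), "equal length")
})

test_that("heterochiasmy is detected from called crossovers", {
    lay <- oneChrom()
    cfgF <- SimConfig(nSamples = 150, markerCount = 150,
                      intensity = c(female = 1, male = 1), seed = 34)
    cfgM <- SimConfig(nSamples = 150, markerCount = 150,
                      intensity = c(female = 4, male = 4), seed = 35)
    popF <- simulateInbredPopulation(cfgF, lay)
    popM <- simulateInbredPopulation(cfgM, lay)
    cosF <- callCrossovers(phaseMarkers(popF$depths$P1), popF$depths$P1,
                           sex = "female")
    cosM <- callCrossovers(phaseMarkers(popM$depths$P1), popM$depths$P1,
                           sex = "male")
    clF <- coCalls(cosF); clF$sample <- paste0("F", clF$sample)
    clM <- coCalls(cosM); clM$sample <- paste0("M", clM$sample)
    samples <- c(paste0("F", colnames(popF$depths$P1)),
                 paste0("M", colnames(popM$depths$P1)))
    groups <- rep(c("female", "male"), each = 150)
    out <- coCountSummary(rbind(clF, clM), samples, groups)
    expect_gt(out$groupMeans["male"], out$groupMeans["female"])
    expect_lt(out$tests$p, 1e-6)
})
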