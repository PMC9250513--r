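## Megabase-scale recombination landscapes: windowed CO-frequency tracks
## with bootstrap confidence bands, per-chromosome normalization and
## moving-average smoothing, peak/valley detection, permutation overlap
## tests, and coefficient-of-coincidence interference summaries.

# CO interval midpoints as a data.frame(sample, chrom, mid).
coMidpoints <- function(cos, allowEmpty = FALSE) {
    cl <- if (is(cos, "CrossoverSet")) coCalls(cos) else cos
    if (!nrow(cl)) {
        if (allowEmpty)
            return(data.frame(sample = character(), chrom = character(),
                              mid = numeric()))
        stop("empty crossover list")
    }
    if (!is.null(cl$mid))
        data.frame(sample = cl$sample, chrom = cl$chrom, mid = cl$mid)
    else
        data.frame(sample = cl$sample, chrom = cl$chrom,
                   mid = (cl$left + cl$right) / 2)
}

#' Windowed crossover-frequency track with bootstrap confidence bands
#'
#' Assigns each CO to windows by its interval midpoint and reports per-window
#' frequency (COs per gamete).  With `win == step` the windows tile the
#' chromosome (the 50-kb grid used for normalization and smoothing); with
#' `win > step` they slide (the 2-Mb / 50-kb display track).  Confidence
#' bounds are percentile bootstrap over gametes.
#'
#' @param cos a [CrossoverSet-class] or data.frame with `sample`, `chrom`
#'   and either `mid` or `left`/`right` columns.
#' @param layout a [GenomeLayout-class].
#' @param nGametes total gametes screened (samples without COs included).
#' @param win,step window and step size in bp; `win` must be a multiple of
#'   `step`.
#' @param ci confidence level (default 0.90); `NULL` skips the bootstrap.
#' @param nBoot bootstrap replicates (default 1000).
#' @param seed RNG seed for the bootstrap.
#' @param cmPerMb also report cM/Mb (frequency x 100 / window Mb).
#' @return A [LandscapeTrack-class] with `count`, `freq`, and (with `ci`)
#'   `ciLow`/`ciHigh` columns.
#' @export
coFrequencyTrack <- function(cos, layout, nGametes, win = 2e6, step = 5e4,
                             ci = 0.90, nBoot = 1000L, seed = 1L,
                             cmPerMb = FALSE) {
    stopifnot2(nGametes > 0, "nGametes must be > 0")
    if (win %% step != 0) stop("win must be a multiple of step")
    mids <- coMidpoints(cos, allowEmpty = TRUE)
    gam <- factor(mids$sample)
    sl <- chromLengths(layout)
    trk <- list(); k <- 0L
    for (ch in names(sl)) {
        L <- sl[[ch]]
        starts <- if (win >= L) 0 else seq(0, L - win, by = step)
        ends <- pmin(starts + win, L)
        sel <- mids$chrom == ch
        m <- mids$mid[sel]
        cnt <- integer(length(starts))
        if (length(m)) {
            sm <- sort(m)
            cnt <- findInterval(ends, sm, left.open = FALSE) -
                   findInterval(starts, sm, left.open = FALSE)
        }
        gr <- GRanges(factor(rep(ch, length(starts)), levels = names(sl)),
                      IRanges(starts + 1, ends))
        gr$count <- cnt
        gr$freq <- cnt / nGametes
        if (cmPerMb) gr$cmMb <- gr$freq * 100 / (win / 1e6)
        if (!is.null(ci) && length(m)) {
            # per-gamete incidence: sparse (gamete x window) count matrix
            gIdx <- as.integer(gam[sel])
            wFirst <- pmax(1L, as.integer(ceiling((m - win) / step)) + 1L)
            wLast <- pmin(length(starts), as.integer(ceiling(m / step)))
            nw <- pmax(wLast - wFirst + 1L, 0L)
            rows <- rep(gIdx, nw)
            cols <- unlist(lapply(seq_along(m), function(i)
                if (nw[i] > 0) wFirst[i]:wLast[i] else integer()),
                use.names = FALSE)
            S <- Matrix::sparseMatrix(i = rows, j = cols, x = 1,
                                      dims = c(nGametes, length(starts)))
            W <- withSeed(seed, {
                matrix(rmultinom(nBoot, nGametes,
                                 rep(1 / nGametes, nGametes)),
                       nrow = nGametes)
            })
            boot <- as.matrix(Matrix::crossprod(S, W)) / nGametes
            a <- (1 - ci) / 2
            qs <- t(apply(boot, 1, quantile, probs = c(a, 1 - a),
                          names = FALSE))
            gr$ciLow <- qs[, 1]; gr$ciHigh <- qs[, 2]
        } else if (!is.null(ci)) {
            gr$ciLow <- 0; gr$ciHigh <- 0
        }
        k <- k + 1L; trk[[k]] <- gr
    }
    out <- do.call(c, trk)
    GenomeInfoDb::seqlevels(out) <- names(sl)
    new("LandscapeTrack", out, nGametes = as.numeric(nGametes),
        win = win, step = step)
}

#' Normalize, smooth and z-score a landscape track
#'
#' Per window: relative frequency = window count / total CO count of the
#' chromosome; then a centered moving average over `k` nearby windows
#' (`stats::filter`; positions whose window is incomplete at chromosome ends
#' are missing), then z-scoring over the stated scope (`base::scale`).
#'
#' @param track a [LandscapeTrack-class] on a tiling grid (win == step).
#' @param k smoothing span in windows (default 40, i.e. 2 Mb on a 50-kb
#'   grid).
#' @param scope z-score scope: `"genome"` (default) or `"chromosome"`.
#' @return the track with `rel`, `smoothed` and `z` columns added.
#' @export
normalizeAndSmooth <- function(track, k = 40L, scope = c("genome",
                                                         "chromosome")) {
    scope <- match.arg(scope)
    chrom <- as.character(seqnames(track))
    rel <- rep(NA_real_, length(track))
    sm <- rep(NA_real_, length(track))
    for (ch in unique(chrom)) {
        idx <- which(chrom == ch)
        tot <- sum(track$count[idx])
        if (tot == 0) {
            warning("chromosome ", ch, " has zero COs; ",
                    "relative frequencies set missing")
            next
        }
        rel[idx] <- track$count[idx] / tot
        sm[idx] <- as.numeric(stats::filter(rel[idx], rep(1 / k, k),
                                            sides = 2))
    }
    track$rel <- rel
    track$smoothed <- sm
    z <- rep(NA_real_, length(track))
    zscore <- function(v) {
        ok <- !is.na(v)
        if (!any(ok)) return(v)
        s <- stats::sd(v[ok])
        if (is.na(s) || s == 0) {
            warning("zero variance in z-score scope; z set to 0")
            v[ok] <- 0
            return(v)
        }
        v[ok] <- (v[ok] - mean(v[ok])) / s
        v
    }
    if (scope == "genome") z <- zscore(sm)
    else for (ch in unique(chrom)) {
        idx <- which(chrom == ch)
        z[idx] <- zscore(sm[idx])
    }
    track$z <- z
    track
}

#' Detect peaks and valleys in a smoothed track
#'
#' Local maxima/minima with topographic prominence >= `minProminence`,
#' computed per chromosome on the non-missing stretch of the chosen value
#' column, ranked by prominence.
#'
#' @param track a [LandscapeTrack-class] (or GRanges) with the value column.
#' @param minProminence minimum prominence (same units as the values).
#' @param value which column to scan (default `"smoothed"`).
#' @return data.frame with `chrom`, `pos` (window midpoint), `value`,
#'   `type` (`peak`/`valley`), `prominence`, sorted by decreasing
#'   prominence.
#' @export
detectPeaksValleys <- function(track, minProminence = 0, value = "smoothed") {
    v <- mcols(track)[[value]]
    if (is.null(v)) stop("no '", value, "' column in track")
    chrom <- as.character(seqnames(track))
    mid <- (start(track) + end(track)) / 2
    out <- list(); k <- 0L
    prominences <- function(x) {
        # prominence of each local max of x (NA elsewhere)
        n <- length(x)
        res <- rep(NA_real_, n)
        for (i in seq_len(n)) {
            if (i > 1 && x[i] <= x[i - 1]) next
            if (i < n && x[i] < x[i + 1]) next
            if (i == 1 || i == n) next       # no terminal extrema
            lo <- x[i]; hi <- x[i]
            minL <- x[i]
            j <- i - 1
            while (j >= 1 && x[j] <= x[i]) { minL <- min(minL, x[j]); j <- j - 1 }
            minR <- x[i]
            j <- i + 1
            while (j <= n && x[j] <= x[i]) { minR <- min(minR, x[j]); j <- j + 1 }
            base <- max(minL, minR)
            res[i] <- x[i] - base
        }
        res
    }
    for (ch in unique(chrom)) {
        idx <- which(chrom == ch)
        ok <- which(!is.na(v[idx]))
        if (length(ok) < 3) next
        x <- v[idx][ok]
        for (type in c("peak", "valley")) {
            xx <- if (type == "peak") x else -x
            pr <- prominences(xx)
            hit <- which(!is.na(pr) & pr >= minProminence)
            for (i in hit) {
                k <- k + 1L
                out[[k]] <- data.frame(
                    chrom = ch, pos = mid[idx][ok][i], value = x[i],
                    type = type, prominence = pr[i],
                    stringsAsFactors = FALSE)
            }
        }
    }
    if (!k) return(data.frame(chrom = character(), pos = numeric(),
                              value = numeric(), type = character(),
                              prominence = numeric()))
    res <- do.call(rbind, out)
    res[order(-res$prominence), , drop = FALSE]
}

#' Correlate two landscape tracks
#'
#' Pairs windows on identical grids (missing positions excluded pairwise),
#' optionally restricted to a compartment scope, and correlates by Spearman
#' rank correlation or by the segmented non-linear coefficient
#' ([nlcorCoefficient()]).
#'
#' @param x,y [LandscapeTrack-class] objects on identical grids, or numeric
#'   vectors.
#' @param method `"spearman"` or `"nlcor"`.
#' @param scope `"genome"`, `"arms"` or `"pericentromere"`; scopes other
#'   than genome require `layout`.
#' @param layout a [GenomeLayout-class] for compartment scopes.
#' @param value column to correlate when tracks are given (default
#'   `"smoothed"`).
#' @return the correlation coefficient (Spearman in [-1, 1]; nlcor in
#'   [0, 1]).
#' @export
correlateTracks <- function(x, y, method = c("spearman", "nlcor"),
                            scope = c("genome", "arms", "pericentromere"),
                            layout = NULL, value = "smoothed") {
    method <- match.arg(method)
    scope <- match.arg(scope)
    if (is(x, "GRanges")) {
        stopifnot2(length(x) == length(y), "tracks must share their grid")
        keep <- rep(TRUE, length(x))
        if (scope != "genome") {
            stopifnot2(!is.null(layout), "compartment scopes need a layout")
            comp <- chromosomeCompartments(layout)
            want <- if (scope == "arms") "arm" else "pericentromere"
            target <- comp[comp$compartment %in% want]
            keep <- overlapsAny(granges(x), target, type = "within")
        }
        vx <- mcols(x)[[value]][keep]
        vy <- mcols(y)[[value]][keep]
    } else {
        vx <- x; vy <- y
    }
    ok <- !is.na(vx) & !is.na(vy)
    if (sum(ok) < 10) stop("fewer than 10 paired points")
    if (method == "spearman") cor(vx[ok], vy[ok], method = "spearman")
    else nlcorCoefficient(vx[ok], vy[ok])
}

#' Permutation overlap test of crossovers against a region set
#'
#' Compares the observed number of CO midpoints inside `regions` (or, in
#' adjacency mode, inside flanks of width `flankWidth` on each side of the
#' regions) with a null distribution obtained by re-placing each CO
#' uniformly within its chromosome, preserving per-chromosome counts.  Both
#' one-sided empirical p-values are reported with the permutation floor
#' `1 / (nPerm + 1)`.
#'
#' @param cos a [CrossoverSet-class] or data.frame of calls.
#' @param regions `GRanges` region set.
#' @param layout a [GenomeLayout-class].
#' @param nPerm permutations (>= 100; default 4999).
#' @param seed RNG seed.
#' @param mode `"overlap"` or `"adjacency"`.
#' @param flankWidth flank width in bp for adjacency mode (default 50 kb).
#' @param mask optional `GRanges` excluded from random placement (e.g.
#'   centromeres).
#' @return list with `observed`, `expected`, `nullSd`, `pEnrich`,
#'   `pDeplete`, `direction`, `nPerm`, `mode`.
#' @export
permutationOverlapTest <- function(cos, regions, layout, nPerm = 4999L,
                                   seed = 1L, mode = c("overlap",
                                                       "adjacency"),
                                   flankWidth = 5e4, mask = NULL) {
    mode <- match.arg(mode)
    stopifnot2(nPerm >= 100, "nPerm must be >= 100")
    mids <- coMidpoints(cos)
    sl <- chromLengths(layout)
    if (mode == "adjacency") {
        left <- flank(regions, flankWidth, start = TRUE)
        right <- flank(regions, flankWidth, start = FALSE)
        target <- setdiff(reduce(c(left, right)), reduce(regions))
        target <- target[end(target) >= 1]
        start(target) <- pmax(start(target), 1)
        end(target) <- pmin(end(target), sl[as.character(seqnames(target))])
        target <- target[width(target) > 0]
    } else {
        target <- reduce(regions)
    }
    # flattened boundaries per chromosome for fast point-in-set counting
    insideCount <- function(pos, bnd) {
        if (!length(bnd)) return(0L)
        sum(findInterval(pos, bnd) %% 2L == 1L)
    }
    chroms <- unique(mids$chrom)
    obs <- 0L
    nullCounts <- matrix(0L, nPerm, 1)
    withSeed(seed, {
        for (ch in chroms) {
            tch <- target[as.character(seqnames(target)) == ch]
            bnd <- if (length(tch))
                as.numeric(t(cbind(start(tch) - 0.5, end(tch) + 0.5)))
            else numeric()
            pos <- mids$mid[mids$chrom == ch]
            obs <- obs + insideCount(pos, bnd)
            nco <- length(pos)
            L <- sl[[ch]]
            if (is.null(L)) stop("chromosome ", ch, " not in layout")
            allow <- NULL
            if (!is.null(mask)) {
                mch <- reduce(mask[as.character(seqnames(mask)) == ch])
                allow <- setdiff(GRanges(ch, IRanges(1, L)), mch)
            }
            u <- matrix(runif(nco * nPerm), nco, nPerm)
            if (is.null(allow)) {
                rnd <- u * L
            } else {
                w <- width(allow); cw <- cumsum(w)
                v <- u * cw[length(cw)]
                seg <- matrix(findInterval(v, c(0, cw[-length(cw)]),
                                           left.open = TRUE), nco, nPerm)
                seg[seg < 1] <- 1L
                rnd <- start(allow)[seg] - 1 + (v - c(0, cw)[seg])
            }
            nullCounts <- nullCounts +
                matrix(vapply(seq_len(nPerm), function(p)
                    insideCount(rnd[, p], bnd), integer(1)), nPerm, 1)
        }
    })
    nullv <- as.numeric(nullCounts)
    pEnrich <- (1 + sum(nullv >= obs)) / (nPerm + 1)
    pDeplete <- (1 + sum(nullv <= obs)) / (nPerm + 1)
    list(observed = obs, expected = mean(nullv), nullSd = stats::sd(nullv),
         pEnrich = pEnrich, pDeplete = pDeplete,
         direction = if (obs >= mean(nullv)) "enriched" else "depleted",
         nPerm = nPerm, mode = mode)
}

#' Coefficient-of-coincidence interference summary
#'
#' Partitions a chromosome into intervals of `binWidth` bp and, for every
#' pair separation d, compares the observed frequency of gametes with COs in
#' both intervals of a pair against the product of the single-interval
#' frequencies: CoC(d) = sum(observed double frequency) / sum(expected),
#' pooled over all interval pairs at that separation.  CoC near 1 indicates
#' no interference; CoC << 1 at short separations indicates interference.
#' Also summarises inter-CO distances (mean, CV).
#'
#' @param events data.frame with `gamete` and `pos` columns (COs of one
#'   chromosome), e.g. from [coTruth()] or CO-call midpoints.
#' @param nGametes total gametes screened.
#' @param chromLength chromosome length in bp.
#' @param binWidth interval width in bp (> 0).
#' @param maxSepFrac maximum pair separation as a fraction of the
#'   chromosome length (default 0.5; longer separations have too few
#'   interval pairs for a stable ratio).
#' @return list with `coc` (data.frame: separation, coc, nPairs) and
#'   `spacing` (list: mean, cv, n).
#' @export
interferenceCoc <- function(events, nGametes, chromLength, binWidth,
                            maxSepFrac = 0.5) {
    stopifnot2(binWidth > 0, "binWidth must be > 0")
    if (nrow(events) < 2) stop("need at least 2 COs")
    nb <- ceiling(chromLength / binWidth)
    bin <- pmin(nb, floor(events$pos / binWidth) + 1L)
    gam <- factor(events$gamete, levels = sort(unique(events$gamete)))
    # presence indicator gamete x bin
    ind <- matrix(0L, nlevels(gam), nb)
    ind[cbind(as.integer(gam), bin)] <- 1L
    f1 <- colSums(ind) / nGametes
    co <- crossprod(ind) / nGametes          # observed double frequencies
    maxSep <- floor(maxSepFrac * nb)
    seps <- seq_len(max(1L, maxSep))
    coc <- vapply(seps, function(d) {
        i <- seq_len(nb - d)
        num <- sum(co[cbind(i, i + d)])
        den <- sum(f1[i] * f1[i + d])
        if (den == 0) NA_real_ else num / den
    }, numeric(1))
    nPairs <- as.integer(nb - seps)
    # inter-CO spacing within gametes
    sp <- split(events$pos, events$gamete)
    dd <- unlist(lapply(sp, function(p) if (length(p) > 1) diff(sort(p))
                        else numeric()), use.names = FALSE)
    spacing <- list(mean = if (length(dd)) mean(dd) else NA_real_,
                    cv = if (length(dd) > 1)
                        stats::sd(dd) / mean(dd) else NA_real_,
                    n = length(dd))
    list(coc = data.frame(separation = seps * binWidth, coc = coc,
                          nPairs = nPairs),
         spacing = spacing)
}
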