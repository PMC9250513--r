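#' Segmented non-linear correlation coefficient
#'
#' Captures non-monotone dependence that a single rank or linear coefficient
#' misses: the points are ordered by x and split into s equal-size
#' contiguous segments for every s from 1 to `maxSegments`; within each
#' segment the Pearson correlation and its p-value are computed, p-values
#' are Benjamini-Hochberg adjusted across the segments of that
#' segmentation, and segments failing the screen (adjusted p >= `alpha`)
#' contribute zero.  The score of a segmentation is the segment-size
#' weighted mean of |r| over all segments; the reported coefficient is the
#' maximum score over the scanned segmentations, a value in [0, 1].
#'
#' A V-shaped relation, invisible to Spearman, scores ~1 here (each
#' monotone half is one near-perfectly linear segment); independent noise
#' scores near 0 because segments rarely pass the significance screen.
#'
#' @param x,y numeric vectors (pairwise complete; >= 10 points).
#' @param maxSegments maximum number of segments scanned (default
#'   `ceiling(n/20)`, so segments keep >= ~20 points).
#' @param alpha per-segmentation BH-adjusted significance screen (0.05).
#' @return list-free numeric scalar in [0, 1].
#' @examples
#' x <- seq(-1, 1, length.out = 200)
#' nlcorCoefficient(x, 2 * x)        # 1
#' nlcorCoefficient(x, abs(x))       # ~1, Spearman ~0
#' @export
nlcorCoefficient <- function(x, y, maxSegments = NULL, alpha = 0.05) {
    ok <- !is.na(x) & !is.na(y)
    x <- x[ok]; y <- y[ok]
    n <- length(x)
    if (n < 10) stop("fewer than 10 paired points")
    if (is.null(maxSegments)) maxSegments <- ceiling(n / 20)
    maxSegments <- max(1L, min(as.integer(maxSegments), floor(n / 5)))
    o <- order(x)
    x <- x[o]; y <- y[o]
    best <- 0
    for (s in seq_len(maxSegments)) {
        bounds <- floor(seq(0, n, length.out = s + 1))
        rs <- numeric(s); ps <- numeric(s); sizes <- integer(s)
        for (k in seq_len(s)) {
            idx <- (bounds[k] + 1):bounds[k + 1]
            sizes[k] <- length(idx)
            if (length(idx) < 3 || stats::sd(x[idx]) == 0 ||
                stats::sd(y[idx]) == 0) {
                rs[k] <- 0; ps[k] <- 1
                next
            }
            ct <- suppressWarnings(cor.test(x[idx], y[idx],
                                            method = "pearson"))
            rs[k] <- ct$estimate; ps[k] <- ct$p.value
        }
        padj <- p.adjust(ps, method = "BH")
        contrib <- ifelse(padj < alpha, abs(rs), 0)
        score <- sum(sizes * contrib) / n
        if (score > best) best <- score
    }
    best
}
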