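#' @import methods
#' @importFrom stats rpois rbinom rgamma runif rmultinom cor.test
#'   p.adjust wilcox.test ks.test setNames
NULL

# Evaluate expr under a fixed RNG seed without disturbing the caller's RNG
# stream.  All simulate*/bootstrap entry points funnel through this.
withSeed <- function(seed, expr) {
    if (!is.null(seed)) {
        has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
        if (has) old <- get(".Random.seed", envir = globalenv())
        set.seed(as.integer(seed))
        on.exit({
            if (has) assign(".Random.seed", old, envir = globalenv())
            else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
                rm(".Random.seed", envir = globalenv())
        })
    }
    force(expr)
}

# Derive a reproducible child seed from a parent seed, kept below 2^31.
childSeed <- function(seed, k) {
    if (is.null(seed)) return(NULL)
    as.integer((as.numeric(seed) * 48271 + 7919 * k) %% 2147483647L)
}

otherPhase <- function(p) ifelse(p == "A", "B", ifelse(p == "B", "A", NA))

stopifnot2 <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
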