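#' @import S4Vectors
#' @import IRanges
#' @import GenomicRanges
#' @importFrom GenomeInfoDb seqnames seqlengths seqlevels Seqinfo keepSeqlevels
#' @importFrom SummarizedExperiment SummarizedExperiment rowRanges assay assays
#'   colData
NULL

## ---------------------------------------------------------------------------
## GenomeLayout
## ---------------------------------------------------------------------------

#' Genome layout: chromosome lengths and (peri)centromere intervals
#'
#' The coordinate frame for all simulations and landscape tracks: chromosome
#' lengths plus one centromere and one pericentromere interval per
#' chromosome.  The centromere must be contained in the pericentromere; the
#' arm/pericentromere/centromere partition derived from these intervals is
#' the stratification used for compartment-restricted correlations.
#'
#' Intervals are held as `GRanges` (1-based, closed); BED input/output
#' converts to/from 0-based half-open coordinates.
#'
#' @slot seqlengths named numeric vector of chromosome lengths (bp).
#' @slot centromere,pericentromere `GRanges`, one range per chromosome.
#' @export
setClass("GenomeLayout", representation(
    seqlengths = "numeric",
    centromere = "GRanges",
    pericentromere = "GRanges"
))

setValidity("GenomeLayout", function(object) {
    sl <- object@seqlengths
    if (length(sl) == 0 || is.null(names(sl)) || any(!nzchar(names(sl))))
        return("seqlengths must be a named vector")
    if (anyDuplicated(names(sl))) return("duplicated chromosome names")
    if (any(!is.finite(sl)) || any(sl <= 0))
        return("chromosome lengths must be positive")
    for (slot in c("centromere", "pericentromere")) {
        gr <- slot(object, slot)
        if (length(gr) == 0) next
        cn <- as.character(seqnames(gr))
        if (!all(cn %in% names(sl)))
            return(sprintf("%s on unknown chromosome", slot))
        if (any(start(gr) < 1) || any(end(gr) > sl[cn]))
            return(sprintf("%s interval outside chromosome bounds", slot))
    }
    cen <- object@centromere
    per <- object@pericentromere
    if (length(cen) > 0) {
        if (length(per) == 0)
            return("centromere given without pericentromere")
        hit <- countOverlaps(cen, per, type = "within")
        if (any(hit == 0))
            return("each centromere must be contained in a pericentromere")
    }
    TRUE
})

#' @param chromLengths named numeric vector of chromosome lengths in bp.
#' @param centromere,pericentromere `GRanges` (or NULL) with one interval per
#'   chromosome; centromeres must lie within pericentromeres.
#' @return A `GenomeLayout` object.
#' @examples
#' GenomeLayout(c(chr1 = 1e6))
#' @rdname GenomeLayout-class
#' @export
GenomeLayout <- function(chromLengths, centromere = NULL,
                         pericentromere = NULL) {
    if (is.null(centromere)) centromere <- GRanges()
    if (is.null(pericentromere)) pericentromere <- GRanges()
    new("GenomeLayout", seqlengths = chromLengths,
        centromere = centromere, pericentromere = pericentromere)
}

#' @export
setMethod("show", "GenomeLayout", function(object) {
    cat("GenomeLayout with", length(object@seqlengths), "chromosome(s):\n")
    print(object@seqlengths)
    if (length(object@centromere))
        cat("centromere intervals:", length(object@centromere), "\n")
    if (length(object@pericentromere))
        cat("pericentromere intervals:", length(object@pericentromere), "\n")
})

#' @export
setGeneric("chromLengths", function(x) standardGeneric("chromLengths"))
#' @rdname GenomeLayout-class
#' @export
setMethod("chromLengths", "GenomeLayout", function(x) x@seqlengths)

#' @export
setGeneric("centromere", function(x) standardGeneric("centromere"))
#' @rdname GenomeLayout-class
#' @export
setMethod("centromere", "GenomeLayout", function(x) x@centromere)

#' @export
setGeneric("pericentromere", function(x) standardGeneric("pericentromere"))
#' @rdname GenomeLayout-class
#' @export
setMethod("pericentromere", "GenomeLayout", function(x) x@pericentromere)

#' Arm / pericentromere / centromere partition of a genome layout
#'
#' Splits every chromosome into `arm`, `pericentromere` (pericentromeric
#' interval minus the centromere core) and `centromere` classes.  The classes
#' partition each chromosome exactly once.
#'
#' @param layout a [GenomeLayout-class] object.
#' @return `GRanges` with a `compartment` metadata column.
#' @export
chromosomeCompartments <- function(layout) {
    sl <- chromLengths(layout)
    whole <- GRanges(names(sl), IRanges(1L, as.integer(sl)))
    GenomeInfoDb::seqlevels(whole) <- names(sl)
    cen <- layout@centromere
    per <- layout@pericentromere
    GenomeInfoDb::seqlevels(cen) <- names(sl)
    GenomeInfoDb::seqlevels(per) <- names(sl)
    arms <- setdiff(whole, per)
    periOnly <- setdiff(per, cen)
    out <- c(
        `names<-`(arms, NULL), `names<-`(periOnly, NULL),
        `names<-`(cen, NULL))
    out$compartment <- rep(c("arm", "pericentromere", "centromere"),
                           c(length(arms), length(periOnly), length(cen)))
    sort(out)
}

#' Approximate Arabidopsis thaliana (Col-0 reference) genome layout
#'
#' Chromosome lengths of the five A. thaliana nuclear chromosomes with
#' approximate centromere and pericentromere intervals (rounded to 0.1 Mb;
#' adequate for the megabase-scale compartment stratification used here, not
#' for base-pair-accurate annotation).
#'
#' @return A [GenomeLayout-class] object.
#' @examples
#' arabidopsisLayout()
#' @export
arabidopsisLayout <- function() {
    sl <- c(Chr1 = 30427671, Chr2 = 19698289, Chr3 = 23459830,
            Chr4 = 18585056, Chr5 = 26975502)
    cen <- GRanges(names(sl), IRanges(
        start = c(14500001, 3100001, 13500001, 3200001, 11500001),
        end   = c(15500000, 4100000, 14500000, 4200000, 12500000)))
    per <- GRanges(names(sl), IRanges(
        start = c(11500001, 1100001, 10300001, 1500001, 9000001),
        end   = c(17700000, 7100000, 17300000, 6300000, 16000000)))
    GenomeLayout(sl, centromere = cen, pericentromere = per)
}

## ---------------------------------------------------------------------------
## MarkerSet
## ---------------------------------------------------------------------------

#' Ordered set of EMS mutation markers
#'
#' A `GRanges`-based container of single-nucleotide EMS markers with `ref`,
#' `alt`, `parent` (which F1* carries the marker) and `phase`
#' (`"A"`/`"B"`/`"unassigned"`: which of the parent's two homologues carries
#' it) metadata columns.  Markers are kept sorted by (chromosome, position)
#' and unique within parent.
#'
#' @export
setClass("MarkerSet", contains = "GRanges")

setValidity("MarkerSet", function(object) {
    mc <- mcols(object)
    need <- c("ref", "alt", "parent", "phase")
    if (!all(need %in% colnames(mc)))
        return(paste("missing metadata columns:",
                     paste(setdiff(need, colnames(mc)), collapse = ", ")))
    if (length(object)) {
        if (any(width(object) != 1L)) return("markers must have width 1")
        if (any(mc$ref == mc$alt)) return("ref must differ from alt")
        if (!all(mc$phase %in% c("A", "B", "unassigned")))
            return("phase must be A, B or unassigned")
        if (is.unsorted(order(as.integer(factor(as.character(seqnames(object)),
            levels = seqlevels(object))), start(object))))
            return("markers must be sorted by (chrom, pos)")
        key <- paste(mc$parent, seqnames(object), start(object))
        if (anyDuplicated(key))
            return("duplicate marker positions within a parent")
    }
    TRUE
})

#' @param chrom,pos,ref,alt,parent,phase vectors describing the markers;
#'   `pos` is 1-based.
#' @param seqlengths optional named chromosome lengths.
#' @return A `MarkerSet`.
#' @rdname MarkerSet-class
#' @export
MarkerSet <- function(chrom = character(), pos = integer(),
                      ref = character(), alt = character(),
                      parent = "P1", phase = "unassigned",
                      seqlengths = NULL) {
    n <- length(pos)
    gr <- GRanges(chrom, IRanges(as.integer(pos), width = 1L),
                  ref = rep_len(as.character(ref), n),
                  alt = rep_len(as.character(alt), n),
                  parent = rep_len(as.character(parent), n),
                  phase = rep_len(as.character(phase), n))
    if (!is.null(seqlengths)) {
        GenomeInfoDb::seqlevels(gr) <- names(seqlengths)
        GenomeInfoDb::seqlengths(gr) <- seqlengths
    }
    gr <- sort(gr)
    new("MarkerSet", gr)
}

#' @export
setMethod("show", "MarkerSet", function(object) {
    cat("MarkerSet with", length(object), "markers,",
        length(unique(object$parent)), "parent(s)\n")
    if (length(object)) callNextMethod()
})

## ---------------------------------------------------------------------------
## AlleleDepthMatrix
## ---------------------------------------------------------------------------

#' Per-marker, per-sample allele read depths
#'
#' A `RangedSummarizedExperiment` with two assays, `ref` and `alt`, holding
#' reference- and alternative-allele read counts at each marker (rows) for
#' each sample (columns).  Rows carry the marker annotation (a
#' [MarkerSet-class]-style `GRanges`).  A total depth of zero means the site
#' is missing for that sample.
#'
#' @export
setClass("AlleleDepthMatrix",
         contains = "RangedSummarizedExperiment")

setValidity("AlleleDepthMatrix", function(object) {
    if (!all(c("ref", "alt") %in% names(assays(object))))
        return("assays 'ref' and 'alt' are required")
    r <- assay(object, "ref"); a <- assay(object, "alt")
    if (any(r < 0, na.rm = TRUE) || any(a < 0, na.rm = TRUE))
        return("read counts must be non-negative")
    TRUE
})

#' @param markers `GRanges`/[MarkerSet-class] of marker positions (rows).
#' @param ref,alt integer matrices (markers x samples) of read counts.
#' @param sampleNames optional column names.
#' @return An `AlleleDepthMatrix`.
#' @rdname AlleleDepthMatrix-class
#' @export
AlleleDepthMatrix <- function(markers, ref, alt, sampleNames = NULL) {
    if (!is.null(sampleNames)) colnames(ref) <- colnames(alt) <- sampleNames
    if (is.null(colnames(ref)))
        colnames(ref) <- colnames(alt) <- paste0("S", seq_len(ncol(ref)))
    se <- SummarizedExperiment(assays = list(ref = ref, alt = alt),
                               rowRanges = markers)
    new("AlleleDepthMatrix", se)
}

#' @export
setGeneric("refDepth", function(x) standardGeneric("refDepth"))
#' @rdname AlleleDepthMatrix-class
#' @export
setMethod("refDepth", "AlleleDepthMatrix",
          function(x) assay(x, "ref"))

#' @export
setGeneric("altDepth", function(x) standardGeneric("altDepth"))
#' @rdname AlleleDepthMatrix-class
#' @export
setMethod("altDepth", "AlleleDepthMatrix",
          function(x) assay(x, "alt"))

#' @export
setGeneric("totalDepth", function(x) standardGeneric("totalDepth"))
#' @rdname AlleleDepthMatrix-class
#' @export
setMethod("totalDepth", "AlleleDepthMatrix",
          function(x) assay(x, "ref") + assay(x, "alt"))

#' Derived genotype calls from allele depths
#'
#' For EMS markers the mutant allele is dominant-presence evidence: a site is
#' called `mutant` (1) when at least one alt read is seen, `wild-type` (0)
#' when only ref reads are seen, and missing (NA) with zero reads.
#'
#' @param x an [AlleleDepthMatrix-class].
#' @return integer matrix (markers x samples) with values 1, 0, NA.
#' @export
genotypeCalls <- function(x) {
    a <- altDepth(x); tot <- totalDepth(x)
    g <- ifelse(a >= 1L, 1L, 0L)
    g[tot == 0L] <- NA_integer_
    g
}

## ---------------------------------------------------------------------------
## PhaseMatrix
## ---------------------------------------------------------------------------

#' Phased genotype calls from sliding-window clustering
#'
#' Result of [phaseMarkers()]: per-(marker, sample) local phase calls
#' (`"A"`/`"B"`/NA) with voting support rates and provenance
#' (`observed`, `imputed`, `corrected`), plus the inferred per-marker phase
#' label (which homologue carries the mutant allele) and flags for
#' chromosomes phased in degraded single-window mode.
#'
#' @slot markers marker `GRanges` with a `phaseLabel` metadata column.
#' @slot phase,support,provenance matrices (markers x samples).
#' @slot degraded character vector of chromosomes with fewer markers than one
#'   window.
#' @export
setClass("PhaseMatrix", representation(
    markers = "GRanges",
    phase = "matrix",
    support = "matrix",
    provenance = "matrix",
    degraded = "character"
))

setValidity("PhaseMatrix", function(object) {
    d <- dim(object@phase)
    if (length(object@markers) != d[1]) return("markers/phase length mismatch")
    if (!identical(dim(object@support), d) ||
        !identical(dim(object@provenance), d))
        return("matrix dimensions differ")
    ok <- object@phase %in% c("A", "B") | is.na(object@phase)
    if (!all(ok)) return("phase values must be A, B or NA")
    nm <- !is.na(object@phase)
    if (any(is.na(object@support[nm])))
        return("support must be defined for every non-missing call")
    TRUE
})

#' @export
setMethod("show", "PhaseMatrix", function(object) {
    cat("PhaseMatrix:", nrow(object@phase), "markers x",
        ncol(object@phase), "samples\n")
    tab <- table(factor(object@provenance[!is.na(object@phase)],
                        levels = c("observed", "imputed", "corrected")))
    cat("calls:", sum(!is.na(object@phase)), "(",
        paste(names(tab), tab, collapse = ", "), ")\n")
    if (length(object@degraded))
        cat("degraded chromosomes:",
            paste(object@degraded, collapse = ", "), "\n")
})

#' @export
setGeneric("phaseCalls", function(x) standardGeneric("phaseCalls"))
#' @rdname PhaseMatrix-class
#' @export
setMethod("phaseCalls", "PhaseMatrix", function(x) x@phase)

#' @export
setGeneric("supportRates", function(x) standardGeneric("supportRates"))
#' @rdname PhaseMatrix-class
#' @export
setMethod("supportRates", "PhaseMatrix", function(x) x@support)

#' @export
setGeneric("callProvenance", function(x) standardGeneric("callProvenance"))
#' @rdname PhaseMatrix-class
#' @export
setMethod("callProvenance", "PhaseMatrix", function(x) x@provenance)

#' @export
setGeneric("markerPhase", function(x) standardGeneric("markerPhase"))
#' @rdname PhaseMatrix-class
#' @export
setMethod("markerPhase", "PhaseMatrix", function(x) x@markers$phaseLabel)

## ---------------------------------------------------------------------------
## CrossoverSet
## ---------------------------------------------------------------------------

#' A set of called crossover intervals
#'
#' One row per crossover: sample, parent whose meiosis produced it, sex of
#' that meiosis, chromosome, the flanking-marker interval (`left` = position
#' of the last marker supporting the preceding state, `right` = first marker
#' of the new state, both 1-based bp), the state transition and the
#' resolution (`right - left`).  Records rejected as biologically impossible
#' (e.g. adjacent hom/hom transitions in a backcross) are kept in `flagged`.
#'
#' @slot calls,flagged data.frames with columns sample, parent, sex, chrom,
#'   left, right, from, to, resolution (+ reason for flagged).
#' @export
setClass("CrossoverSet", representation(
    calls = "data.frame",
    flagged = "data.frame"
))

coColumns <- c("sample", "parent", "sex", "chrom", "left", "right",
               "from", "to", "resolution")

emptyCoFrame <- function(extra = character()) {
    cols <- c(coColumns, extra)
    out <- as.data.frame(setNames(rep(list(character()), length(cols)), cols),
                         stringsAsFactors = FALSE)
    out$left <- numeric(); out$right <- numeric(); out$resolution <- numeric()
    out
}

setValidity("CrossoverSet", function(object) {
    cl <- object@calls
    if (!all(coColumns %in% names(cl))) return("missing columns in calls")
    if (nrow(cl)) {
        if (any(cl$left >= cl$right)) return("left must be < right")
        if (any(cl$from == cl$to)) return("from must differ from to")
        if (any(cl$resolution != cl$right - cl$left))
            return("resolution must equal right - left")
    }
    TRUE
})

#' @param calls data.frame of crossover records.
#' @param flagged data.frame of excluded records (with a `reason` column).
#' @return A `CrossoverSet`.
#' @rdname CrossoverSet-class
#' @export
CrossoverSet <- function(calls = emptyCoFrame(),
                         flagged = emptyCoFrame("reason")) {
    if (nrow(calls)) calls$resolution <- calls$right - calls$left
    new("CrossoverSet", calls = calls, flagged = flagged)
}

#' @export
setGeneric("coCalls", function(x) standardGeneric("coCalls"))
#' @rdname CrossoverSet-class
#' @export
setMethod("coCalls", "CrossoverSet", function(x) x@calls)

#' @export
setGeneric("coFlagged", function(x) standardGeneric("coFlagged"))
#' @rdname CrossoverSet-class
#' @export
setMethod("coFlagged", "CrossoverSet", function(x) x@flagged)

#' @export
setMethod("length", "CrossoverSet", function(x) nrow(x@calls))

#' @export
setMethod("show", "CrossoverSet", function(object) {
    cat("CrossoverSet with", nrow(object@calls), "crossovers in",
        length(unique(object@calls$sample)), "sample(s)\n")
    if (nrow(object@flagged))
        cat("flagged records:", nrow(object@flagged), "\n")
    if (nrow(object@calls)) {
        cat("median resolution:",
            stats::median(object@calls$resolution), "bp\n")
    }
})

#' Convert crossover calls to GRanges intervals
#' @param x a [CrossoverSet-class].
#' @return `GRanges` of CO intervals with metadata columns.
#' @export
coIntervals <- function(x) {
    cl <- coCalls(x)
    if (!nrow(cl)) return(GRanges())
    GRanges(cl$chrom, IRanges(cl$left, cl$right),
            sample = cl$sample, parent = cl$parent, sex = cl$sex,
            from = cl$from, to = cl$to, resolution = cl$resolution)
}

#' Combine two CrossoverSets
#' @param x,y,... CrossoverSet objects.
#' @export
setMethod("c", "CrossoverSet", function(x, ...) {
    more <- list(...)
    calls <- do.call(rbind, c(list(coCalls(x)), lapply(more, coCalls)))
    flagged <- do.call(rbind, c(list(coFlagged(x)), lapply(more, coFlagged)))
    CrossoverSet(calls, flagged)
})

## ---------------------------------------------------------------------------
## LandscapeTrack
## ---------------------------------------------------------------------------

#' Windowed crossover-frequency landscape track
#'
#' A `GRanges`-based track of CO counts/frequencies in sliding (or tiling)
#' windows, optionally with bootstrap confidence bounds (`ciLow`, `ciHigh`),
#' per-chromosome-normalized relative frequency (`rel`), moving-average
#' smoothed values (`smoothed`) and z-scores (`z`).
#'
#' @slot nGametes number of gametes the frequencies are scaled by.
#' @slot win,step window and step size in bp.
#' @export
setClass("LandscapeTrack", contains = "GRanges",
         representation(nGametes = "numeric", win = "numeric",
                        step = "numeric"))

#' @export
setMethod("show", "LandscapeTrack", function(object) {
    cat(sprintf("LandscapeTrack: %d windows (win %g bp, step %g bp, %g gametes)\n",
                length(object), object@win, object@step, object@nGametes))
    if (length(object)) callNextMethod()
})

#' @export
setGeneric("nGametes", function(x) standardGeneric("nGametes"))
#' @rdname LandscapeTrack-class
#' @export
setMethod("nGametes", "LandscapeTrack", function(x) x@nGametes)

## ---------------------------------------------------------------------------
## SimConfig / SimTruth
## ---------------------------------------------------------------------------

#' Simulation configuration for the crossing designs
#'
#' Defaults emulate the study conditions of the motivating experimental
#' design: ~300 progeny per population, ~450 EMS markers per F1* parent
#' (~900 segregating per population), 5x mean sequencing depth with Poisson
#' dropout, 0.5% per-read error, female/male CO intensities per bivalent
#' scaled so a gamete carries ~5 COs genome-wide (female below male:
#' heterochiasmy), gamma-renewal interference and an obligate CO per
#' bivalent.
#'
#' @slot nSamples progeny count.
#' @slot markerCount EMS markers per F1* parent (genome-wide).
#' @slot meanDepth Poisson mean sequencing depth per site.
#' @slot errorRate per-read probability of observing the wrong allele.
#' @slot intensity named numeric `c(female=, male=)`: expected COs per
#'   bivalent per chromosome.
#' @slot nu gamma-renewal interference shape (1 = no interference).
#' @slot obligateCo force at least one CO per bivalent (rejection sampling).
#' @slot inversions `GRanges` of inversions suppressing COs when heterozygous.
#' @slot seed integer RNG seed; identical (config, seed) gives identical
#'   output.
#' @export
setClass("SimConfig", representation(
    nSamples = "integer", markerCount = "integer",
    meanDepth = "numeric", errorRate = "numeric",
    intensity = "numeric", nu = "numeric", obligateCo = "logical",
    inversions = "GRanges", seed = "integer"
))

setValidity("SimConfig", function(object) {
    if (object@nSamples < 1) return("nSamples must be >= 1")
    if (object@markerCount < 0) return("markerCount must be >= 0")
    if (object@meanDepth < 0) return("meanDepth must be >= 0")
    if (object@errorRate < 0 || object@errorRate > 1)
        return("errorRate must be in [0, 1]")
    if (any(object@intensity < 0)) return("intensity must be >= 0")
    if (!all(c("female", "male") %in% names(object@intensity)))
        return("intensity must have 'female' and 'male' entries")
    if (object@nu <= 0) return("nu must be > 0")
    TRUE
})

#' @param nSamples,markerCount,meanDepth,errorRate,intensity,nu,obligateCo,inversions,seed
#'   see slot documentation.
#' @return A `SimConfig`.
#' @rdname SimConfig-class
#' @export
SimConfig <- function(nSamples = 300L, markerCount = 450L, meanDepth = 5,
                      errorRate = 0.005,
                      intensity = c(female = 1.6, male = 2.45),
                      nu = 5, obligateCo = TRUE,
                      inversions = GRanges(), seed = 1L) {
    new("SimConfig", nSamples = as.integer(nSamples),
        markerCount = as.integer(markerCount), meanDepth = meanDepth,
        errorRate = errorRate, intensity = intensity, nu = nu,
        obligateCo = obligateCo, inversions = inversions,
        seed = as.integer(seed))
}

#' @export
setMethod("show", "SimConfig", function(object) {
    cat(sprintf(
        "SimConfig: %d samples, %d markers/parent, depth %g, error %g\n",
        object@nSamples, object@markerCount, object@meanDepth,
        object@errorRate))
    cat(sprintf("intensity/bivalent: female %g, male %g; nu %g; obligate %s\n",
                object@intensity["female"], object@intensity["male"],
                object@nu, object@obligateCo))
})

#' Ground truth of a simulated meiosis
#'
#' Per-gamete true crossover positions (exact bp, both at the bivalent level
#' and after transmission to the sampled chromatid) and the phase of the
#' transmitted haplotype at the left end of each chromosome.  The
#' transmitted haplotype phase flips exactly at the transmitted CO
#' positions.
#'
#' @slot events data.frame (gamete, chrom, pos): transmitted COs, strictly
#'   increasing within gamete x chromosome.
#' @slot bivalentEvents data.frame (gamete, chrom, pos): all COs formed on
#'   the bivalent.
#' @slot startPhase data.frame (gamete, chrom, phase in A/B).
#' @slot nGametes number of gametes simulated.
#' @export
setClass("SimTruth", representation(
    events = "data.frame", bivalentEvents = "data.frame",
    startPhase = "data.frame", nGametes = "integer"
))

setValidity("SimTruth", function(object) {
    ev <- object@events
    if (nrow(ev)) {
        o <- order(ev$gamete, ev$chrom, ev$pos)
        ev <- ev[o, ]
        same <- duplicated(ev[c("gamete", "chrom")])
        if (any(same & c(FALSE, diff(ev$pos) <= 0)[seq_len(nrow(ev))] &
                duplicated(paste(ev$gamete, ev$chrom))))
            return("CO positions must be strictly increasing within a gamete")
    }
    TRUE
})

#' @export
setMethod("show", "SimTruth", function(object) {
    cat(sprintf("SimTruth: %d gametes, %d transmitted COs (%d on bivalents)\n",
                object@nGametes, nrow(object@events),
                nrow(object@bivalentEvents)))
})

#' @export
setGeneric("coTruth", function(x) standardGeneric("coTruth"))
#' @rdname SimTruth-class
#' @export
setMethod("coTruth", "SimTruth", function(x) x@events)

#' True transmitted haplotype phase at given positions
#'
#' @param truth a [SimTruth-class].
#' @param gamete gamete index.
#' @param chrom chromosome name.
#' @param positions bp positions to query.
#' @return character vector of phases ("A"/"B"); the phase flips at each
#'   transmitted CO position.
#' @export
truePhaseAt <- function(truth, gamete, chrom, positions) {
    sp <- truth@startPhase
    p0 <- sp$phase[sp$gamete == gamete & sp$chrom == chrom]
    if (length(p0) != 1) stop("unknown gamete/chromosome")
    ev <- truth@events
    cop <- sort(ev$pos[ev$gamete == gamete & ev$chrom == chrom])
    nflips <- findInterval(positions, cop)
    ifelse(nflips %% 2 == 0, p0, otherPhase(p0))
}
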