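## Candidate-variant filtering into high-confidence EMS marker sets, and
## syntenic-block coordinate liftover between assemblies.

#' Is a substitution EMS-type (G->A / C->T)?
#'
#' EMS alkylates guanine, so induced mutations are overwhelmingly G:C -> A:T
#' transitions; on the reference strand this is a G->A or C->T substitution.
#'
#' @param ref,alt single-nucleotide alleles (vectorized).
#' @return logical vector.
#' @examples
#' emsSubstitutionCheck(c("G", "C", "A"), c("A", "T", "G"))
#' @export
emsSubstitutionCheck <- function(ref, alt) {
    ref <- toupper(as.character(ref)); alt <- toupper(as.character(alt))
    if (!all(ref %in% c("A", "C", "G", "T")) ||
        !all(alt %in% c("A", "C", "G", "T")))
        stop("alleles must be single A/C/G/T nucleotides")
    (ref == "G" & alt == "A") | (ref == "C" & alt == "T")
}

#' Filter candidate variants into a high-confidence EMS marker set
#'
#' Retains exactly the candidates that satisfy all of: (i) heterozygous call
#' with alternative-allele frequency in `[afLow, afHigh]` (inclusive) in the
#' F1* that carries them, (ii) present in exactly one of the two F1*
#' parents, (iii) EMS-type substitution (G->A / C->T), and (iv) position
#' outside all mask intervals (tandem repeats, structural variants:
#' non-allelic signal).
#'
#' @param variants data.frame with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt`, and per-parent columns `het_a`, `af_a`, `het_b`, `af_b`
#'   (heterozygous genotype call and alt-allele read frequency in each F1*).
#'   Presence of a marker in a parent means a heterozygous call with at
#'   least one alt read (`af > 0`) in that parent.
#' @param masks `GRanges` of masked intervals (or NULL).
#' @param afLow,afHigh inclusive allele-frequency window (default 0.4-0.6).
#' @param parentIds labels for the two parents.
#' @param seqlengths optional named chromosome lengths for the output.
#' @return A [MarkerSet-class], sorted; `phase` is `"unassigned"`.
#' @export
filterEmsMarkers <- function(variants, masks = NULL, afLow = 0.4,
                             afHigh = 0.6, parentIds = c("P1", "P2"),
                             seqlengths = NULL) {
    need <- c("chrom", "pos", "ref", "alt", "het_a", "af_a", "het_b", "af_b")
    stopifnot2(all(need %in% names(variants)),
               paste("variants must have columns:",
                     paste(need, collapse = ", ")))
    stopifnot2(all(variants$af_a >= 0 & variants$af_a <= 1 &
                   variants$af_b >= 0 & variants$af_b <= 1, na.rm = TRUE),
               "allele frequencies must lie in [0, 1]")
    presA <- variants$het_a & variants$af_a > 0
    presB <- variants$het_b & variants$af_b > 0
    oneParent <- xor(presA, presB)
    af <- ifelse(presA, variants$af_a, variants$af_b)
    inWindow <- oneParent & af >= afLow & af <= afHigh
    ems <- emsSubstitutionCheck(variants$ref, variants$alt)
    keep <- oneParent & inWindow & ems
    if (!is.null(masks) && length(masks) && any(keep)) {
        gr <- GRanges(variants$chrom[keep],
                      IRanges(variants$pos[keep], width = 1L))
        keep[keep] <- countOverlaps(gr, masks) == 0
    }
    v <- variants[keep, , drop = FALSE]
    if (anyDuplicated(paste(v$chrom, v$pos)))
        stop("duplicate positions after filtering: non-allelic signal")
    MarkerSet(v$chrom, v$pos, v$ref, v$alt,
              parent = ifelse(presA[keep], parentIds[1], parentIds[2]),
              phase = "unassigned", seqlengths = seqlengths)
}

#' Validate a syntenic block table
#'
#' @param blocks data.frame with columns `src_chrom`, `src_start`,
#'   `src_end`, `tgt_chrom`, `tgt_start`, `tgt_end`, `strand` (0-based
#'   half-open intervals, strand "+" or "-").
#' @return the blocks, invisibly, after validation.
#' @export
validateSynBlocks <- function(blocks) {
    need <- c("src_chrom", "src_start", "src_end", "tgt_chrom",
              "tgt_start", "tgt_end", "strand")
    stopifnot2(all(need %in% names(blocks)),
               paste("blocks must have columns:", paste(need, collapse = ", ")))
    stopifnot2(all(blocks$strand %in% c("+", "-")),
               "strand must be '+' or '-'")
    stopifnot2(all(blocks$src_end > blocks$src_start &
                   blocks$tgt_end > blocks$tgt_start),
               "blocks must have positive length")
    for (ch in unique(blocks$src_chrom)) {
        b <- blocks[blocks$src_chrom == ch, ]
        b <- b[order(b$src_start), ]
        if (nrow(b) > 1 && any(b$src_start[-1] < b$src_end[-nrow(b)]))
            stop("overlapping source blocks on ", ch)
    }
    invisible(blocks)
}

#' Transfer positions between assemblies through syntenic blocks
#'
#' A position inside a `+` block maps affinely
#' (`tgt_start + (pos - src_start)`); inside a `-` block it maps reflected
#' (`tgt_end - 1 - (pos - src_start)`), in 0-based terms.  Blocks whose
#' source and target lengths differ are scaled proportionally.  Positions
#' outside all blocks are unmapped (NA) rather than clamped.
#'
#' @param chrom,pos source chromosome and 1-based position (vectorized).
#' @param blocks syntenic block table (see [validateSynBlocks()]).
#' @return data.frame with `chrom` (target chromosome or NA), `pos`
#'   (1-based target position or NA) and `mapped` (logical).
#' @examples
#' b <- data.frame(src_chrom = "c1", src_start = 100, src_end = 200,
#'                 tgt_chrom = "c1", tgt_start = 1000, tgt_end = 1100,
#'                 strand = "+")
#' liftoverPositions("c1", 151, b)   # 0-based 150 -> 1050 -> 1-based 1051
#' @export
liftoverPositions <- function(chrom, pos, blocks) {
    validateSynBlocks(blocks)
    n <- length(pos)
    chrom <- rep_len(as.character(chrom), n)
    outChrom <- rep(NA_character_, n)
    outPos <- rep(NA_real_, n)
    p0 <- pos - 1                       # to 0-based
    for (i in seq_len(nrow(blocks))) {
        b <- blocks[i, ]
        hit <- chrom == b$src_chrom & p0 >= b$src_start & p0 < b$src_end
        if (!any(hit)) next
        off <- p0[hit] - b$src_start
        scale <- (b$tgt_end - b$tgt_start) / (b$src_end - b$src_start)
        offT <- if (scale == 1) off else floor(off * scale)
        outChrom[hit] <- b$tgt_chrom
        outPos[hit] <- if (b$strand == "+") b$tgt_start + offT
                       else b$tgt_end - 1 - offT
    }
    data.frame(chrom = outChrom, pos = outPos + 1, mapped = !is.na(outPos))
}

#' Invert a syntenic block table (swap source and target)
#'
#' Reflection is an involution, so "-" blocks keep their strand; useful for
#' round-trip checks.
#'
#' @param blocks syntenic block table.
#' @return the inverted table.
#' @export
invertSynBlocks <- function(blocks) {
    validateSynBlocks(blocks)
    data.frame(src_chrom = blocks$tgt_chrom, src_start = blocks$tgt_start,
               src_end = blocks$tgt_end, tgt_chrom = blocks$src_chrom,
               tgt_start = blocks$src_start, tgt_end = blocks$src_end,
               strand = blocks$strand)
}
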