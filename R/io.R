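## Readers and writers for the interchange formats: marker tables
## (TSV/VCF), allele-depth tables (TSV/VCF AD), regions (BED), syntenic
## blocks (TSV), CO tables (TSV/BED) and landscape tracks (bedGraph).

#' @importFrom data.table fread fwrite as.data.table
NULL

#' Write / read a marker set as TSV
#'
#' Columns: chrom, pos (1-based), ref, alt, parent, phase.
#' @param ms a [MarkerSet-class].
#' @param file path.
#' @export
writeMarkerTSV <- function(ms, file) {
    fwrite(data.table::data.table(
        chrom = as.character(seqnames(ms)), pos = start(ms),
        ref = ms$ref, alt = ms$alt, parent = ms$parent, phase = ms$phase),
        file, sep = "\t")
    invisible(file)
}

#' @param seqlengths optional named chromosome lengths.
#' @rdname writeMarkerTSV
#' @export
readMarkerTSV <- function(file, seqlengths = NULL) {
    d <- fread(file, sep = "\t", data.table = FALSE)
    MarkerSet(d$chrom, d$pos, d$ref, d$alt, d$parent, d$phase,
              seqlengths = seqlengths)
}

#' Write a marker set with allele depths as a minimal VCF
#'
#' CHROM/POS/REF/ALT plus one genotype column per sample carrying the AD
#' (ref,alt) field.  The complementary reader ([readAlleleDepthVCF()]) uses
#' VariantAnnotation.
#'
#' @param adm an [AlleleDepthMatrix-class].
#' @param file output path (plain text).
#' @export
writeAlleleDepthVCF <- function(adm, file) {
    gr <- rowRanges(adm)
    refM <- refDepth(adm); altM <- altDepth(adm)
    con <- file(file, "w")
    on.exit(close(con))
    writeLines(c("##fileformat=VCFv4.2",
                 "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
                 paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                         "FILTER", "INFO", "FORMAT", colnames(adm)),
                       collapse = "\t")), con)
    ad <- matrix(paste(refM, altM, sep = ","), nrow(adm), ncol(adm))
    ref <- if (!is.null(gr$ref)) gr$ref else "N"
    alt <- if (!is.null(gr$alt)) gr$alt else "N"
    lines <- apply(cbind(as.character(seqnames(gr)), start(gr), ".",
                         ref, alt, ".", "PASS", ".", "AD", ad),
                   1, paste, collapse = "\t")
    writeLines(lines, con)
    invisible(file)
}

#' Read per-sample allele depths from a VCF with an AD FORMAT field
#'
#' @param file VCF path.
#' @param genome genome tag passed to VariantAnnotation (default "unknown").
#' @return An [AlleleDepthMatrix-class].
#' @export
readAlleleDepthVCF <- function(file, genome = "unknown") {
    if (!requireNamespace("VariantAnnotation", quietly = TRUE))
        stop("VariantAnnotation is required to read VCF")
    vcf <- VariantAnnotation::readVcf(file, genome = genome)
    ad <- VariantAnnotation::geno(vcf)$AD
    getK <- function(k) {
        m <- apply(ad, c(1, 2), function(v) {
            v <- unlist(v)
            if (length(v) >= k && !is.na(v[k])) v[k] else 0L
        })
        matrix(as.integer(m), nrow(ad), ncol(ad),
               dimnames = dimnames(ad))
    }
    gr <- SummarizedExperiment::rowRanges(vcf)
    mk <- granges(gr)
    mk$ref <- as.character(gr$REF)
    mk$alt <- vapply(seq_along(gr), function(i)
        as.character(gr$ALT[[i]][1]), character(1))
    mk$parent <- "P1"; mk$phase <- "unassigned"
    AlleleDepthMatrix(mk, getK(1), getK(2), colnames(ad))
}

#' Write / read an allele-depth matrix as long-format TSV
#'
#' Columns: sample, chrom, pos, ref_count, alt_count.
#' @param adm an [AlleleDepthMatrix-class].
#' @param file path.
#' @export
writeAlleleDepthTSV <- function(adm, file) {
    gr <- rowRanges(adm)
    refM <- refDepth(adm); altM <- altDepth(adm)
    fwrite(data.table::data.table(
        sample = rep(colnames(adm), each = nrow(adm)),
        chrom = rep(as.character(seqnames(gr)), ncol(adm)),
        pos = rep(start(gr), ncol(adm)),
        ref_count = as.vector(refM), alt_count = as.vector(altM)),
        file, sep = "\t")
    invisible(file)
}

#' @param markers optional [MarkerSet-class] giving marker annotation.
#' @rdname writeAlleleDepthTSV
#' @export
readAlleleDepthTSV <- function(file, markers = NULL) {
    d <- fread(file, sep = "\t", data.table = FALSE)
    key <- paste(d$chrom, d$pos)
    ukey <- unique(key)
    samples <- unique(d$sample)
    ri <- match(key, ukey); ci <- match(d$sample, samples)
    refM <- matrix(0L, length(ukey), length(samples))
    altM <- matrix(0L, length(ukey), length(samples))
    refM[cbind(ri, ci)] <- d$ref_count
    altM[cbind(ri, ci)] <- d$alt_count
    first <- !duplicated(key)
    if (is.null(markers))
        markers <- GRanges(d$chrom[first],
                           IRanges(d$pos[first], width = 1L))
    o <- order(as.character(seqnames(markers)), start(markers))
    AlleleDepthMatrix(markers[o], refM[o, , drop = FALSE],
                      altM[o, , drop = FALSE], samples)
}

#' Read a BED file of regions (masks, inversions, non-syntenic blocks)
#'
#' @param file BED path (0-based half-open; converted to 1-based GRanges).
#' @return `GRanges`.
#' @export
readRegionsBED <- function(file) {
    if (requireNamespace("rtracklayer", quietly = TRUE))
        return(rtracklayer::import(file, format = "BED"))
    d <- fread(file, header = FALSE, data.table = FALSE)
    GRanges(d[[1]], IRanges(d[[2]] + 1L, d[[3]]))
}

#' Write regions as BED
#' @param gr `GRanges`.
#' @param file path.
#' @export
writeRegionsBED <- function(gr, file) {
    if (requireNamespace("rtracklayer", quietly = TRUE)) {
        rtracklayer::export(gr, file, format = "BED")
    } else {
        fwrite(data.table::data.table(
            chrom = as.character(seqnames(gr)), start = start(gr) - 1L,
            end = end(gr)), file, sep = "\t", col.names = FALSE)
    }
    invisible(file)
}

#' Read a syntenic-block table (7-column TSV)
#'
#' Columns: src_chrom, src_start, src_end, tgt_chrom, tgt_start, tgt_end,
#' strand; 0-based half-open.
#' @param file path.
#' @export
readSynBlocksTSV <- function(file) {
    d <- fread(file, sep = "\t", data.table = FALSE)
    if (!"src_chrom" %in% names(d))
        names(d) <- c("src_chrom", "src_start", "src_end", "tgt_chrom",
                      "tgt_start", "tgt_end", "strand")
    validateSynBlocks(d)
    d
}

#' Write / read crossover calls as TSV
#'
#' @param cos a [CrossoverSet-class].
#' @param file path.
#' @export
writeCoTSV <- function(cos, file) {
    fwrite(as.data.table(coCalls(cos)), file, sep = "\t")
    invisible(file)
}

#' @rdname writeCoTSV
#' @export
readCoTSV <- function(file) {
    CrossoverSet(fread(file, sep = "\t", data.table = FALSE))
}

#' Write crossover intervals as BED
#' @param cos a [CrossoverSet-class].
#' @param file path.
#' @export
writeCoBED <- function(cos, file) {
    cl <- coCalls(cos)
    fwrite(data.table::data.table(
        chrom = cl$chrom, start = as.integer(cl$left) - 1L,
        end = as.integer(cl$right),
        name = paste(cl$sample, cl$from, cl$to, sep = "|")),
        file, sep = "\t", col.names = FALSE)
    invisible(file)
}

#' Write a landscape track as bedGraph
#'
#' @param track a [LandscapeTrack-class].
#' @param file path.
#' @param value column to export (default `"freq"`).
#' @export
writeTrackBedGraph <- function(track, file, value = "freq") {
    v <- mcols(track)[[value]]
    stopifnot2(!is.null(v), paste("no column", value))
    fwrite(data.table::data.table(
        chrom = as.character(seqnames(track)), start = start(track) - 1L,
        end = end(track), value = v), file, sep = "\t", col.names = FALSE)
    invisible(file)
}
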