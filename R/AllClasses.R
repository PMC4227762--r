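#' Per-sample allele counts at SNP loci
#'
#' `AlleleCounts` is the central container of the package: read counts for the
#' reference and alternative allele of every catalogued SNP locus (rows) in
#' every sample (columns) of an enrichment-based methylation sequencing
#' experiment.  It extends [SummarizedExperiment::RangedSummarizedExperiment]
#' with two integer assays, `"ref"` and `"alt"`; the `rowRanges` carry the
#' locus metadata (`snp_id`, `ref`, `alt` alleles) and the `colData` a `sex`
#' column used for X-chromosome handling.
#'
#' A sample with `ref + alt == 0` at a locus is *uncovered* there: in
#' enrichment data an unmethylated sample yields no reads, so zero coverage is
#' an expected outcome, not a missing-data error.
#'
#' @param loci `GRanges` of width-1 SNP positions (1-based) with metadata
#'   columns `ref` and `alt` (single nucleotides, distinct) and optionally
#'   `snp_id`.  Alternatively a `data.frame` with columns `chrom`, `pos`,
#'   `ref`, `alt` and optionally `snp_id`.
#' @param ref,alt integer matrices (loci x samples) of reference- and
#'   alternative-allele read counts.  Column names are sample identifiers.
#' @param sex character vector of per-sample sex, values in
#'   `c("female", "male", "unknown")`; recycled default `"unknown"`.
#'
#' @return An `AlleleCounts` object.
#'
#' @examples
#' loci <- data.frame(chrom = "chr1", pos = c(100L, 200L),
#'                    ref = c("A", "C"), alt = c("G", "T"))
#' ref <- matrix(c(5L, 0L, 3L, 7L), 2, dimnames = list(NULL, c("s1", "s2")))
#' alt <- matrix(c(4L, 0L, 0L, 1L), 2, dimnames = list(NULL, c("s1", "s2")))
#' ac <- AlleleCounts(loci, ref, alt)
#' snpCoverage(ac)
#'
#' @aliases refCounts altCounts snpCoverage sampleSex snpLoci
#' @importFrom methods new validObject is setValidity slot
#' @importFrom S4Vectors DataFrame mcols mcols<-
#' @importFrom GenomicRanges GRanges seqnames start
#' @importFrom IRanges IRanges
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowRanges
#'   colData
#' @export
setClass("AlleleCounts", contains = "RangedSummarizedExperiment")

.NUCS <- c("A", "C", "G", "T")
.SEXES <- c("female", "male", "unknown")

.validAlleleCounts <- function(object) {
    msg <- character()
    if (!all(c("ref", "alt") %in% names(assays(object))))
        return("assays 'ref' and 'alt' are required")
    r <- assay(object, "ref")
    a <- assay(object, "alt")
    if (!is.numeric(r) || !is.numeric(a))
        msg <- c(msg, "count assays must be numeric")
    else if (any(r < 0) || any(a < 0) ||
             any(r != floor(r)) || any(a != floor(a)))
        msg <- c(msg, "counts must be non-negative integers")
    m <- mcols(rowRanges(object))
    if (!all(c("ref", "alt") %in% names(m))) {
        msg <- c(msg, "loci need 'ref' and 'alt' allele columns")
    } else {
        if (!all(m$ref %in% .NUCS) || !all(m$alt %in% .NUCS))
            msg <- c(msg, "alleles must be single nucleotides A/C/G/T")
        if (any(m$ref == m$alt))
            msg <- c(msg, "ref and alt allele must differ at every locus")
    }
    key <- paste(seqnames(object), start(object))
    if (anyDuplicated(key))
        msg <- c(msg, "duplicated (chrom, pos) locus")
    if (!"sex" %in% names(colData(object)))
        msg <- c(msg, "colData needs a 'sex' column")
    else if (!all(colData(object)$sex %in% .SEXES))
        msg <- c(msg, "sex must be one of female/male/unknown")
    if (length(msg)) msg else TRUE
}

setValidity("AlleleCounts", .validAlleleCounts)

.lociAsGRanges <- function(loci) {
    if (is(loci, "GRanges")) return(loci)
    stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(loci)))
    gr <- GRanges(loci$chrom, IRanges(loci$pos, width = 1L))
    mcols(gr)$snp_id <- if ("snp_id" %in% names(loci))
        as.character(loci$snp_id) else NA_character_
    mcols(gr)$ref <- as.character(loci$ref)
    mcols(gr)$alt <- as.character(loci$alt)
    gr
}

#' @rdname AlleleCounts-class
#' @export
AlleleCounts <- function(loci, ref, alt, sex = NULL) {
    gr <- .lociAsGRanges(loci)
    ref <- as.matrix(ref); alt <- as.matrix(alt)
    storage.mode(ref) <- "integer"; storage.mode(alt) <- "integer"
    if (is.null(sex)) sex <- rep("unknown", ncol(ref))
    cd <- DataFrame(sex = as.character(sex), row.names = colnames(ref))
    se <- SummarizedExperiment(assays = list(ref = ref, alt = alt),
                               rowRanges = gr, colData = cd)
    new("AlleleCounts", se)
}

#' @rdname AlleleCounts-class
#' @export
setMethod("refCounts", "AlleleCounts", function(x, ...) assay(x, "ref"))

#' @rdname AlleleCounts-class
#' @export
setMethod("altCounts", "AlleleCounts", function(x, ...) assay(x, "alt"))

#' @rdname AlleleCounts-class
#' @export
setMethod("snpCoverage", "AlleleCounts", function(x, ...) {
    assay(x, "ref") + assay(x, "alt")
})

#' @rdname AlleleCounts-class
#' @export
setMethod("sampleSex", "AlleleCounts", function(x, ...) {
    stats::setNames(colData(x)$sex, colnames(x))
})

#' @rdname AlleleCounts-class
#' @export
setMethod("snpLoci", "AlleleCounts", function(x, ...) rowRanges(x))

setMethod("show", "AlleleCounts", function(object) {
    cat("AlleleCounts:", nrow(object), "SNP loci x",
        ncol(object), "samples\n")
    cov <- snpCoverage(object)
    cat("  total reads:", sum(cov),
        " uncovered entries:", sum(cov == 0), "\n")
    cat("  samples:", paste(utils::head(colnames(object), 4), collapse = ", "),
        if (ncol(object) > 4) "..." else "", "\n")
})

#' Catalogue of known SNPs
#'
#' Lookup table of known single-nucleotide variant positions and their allowed
#' alleles, typically derived from a dbSNP-style VCF.  Multi-allelic entries
#' keep their full allele set; indel and multi-nucleotide records are skipped
#' at read time (the skip count is kept in `skipped`).
#'
#' @param chrom,pos,alleles parallel vectors: chromosome, 1-based position and
#'   a list of allowed-allele character vectors (each of length >= 2).
#' @param skipped integer count of non-SNV records dropped during parsing.
#'
#' @return A `SnpCatalogue`.
#' @aliases catalogueAlleles
#' @export
setClass("SnpCatalogue",
         representation(entries = "DataFrame", skipped = "integer"))

setValidity("SnpCatalogue", function(object) {
    e <- object@entries
    if (!all(c("chrom", "pos", "alleles") %in% names(e)))
        return("entries need chrom, pos, alleles")
    if (length(e$alleles) && any(lengths(e$alleles) < 2))
        return("every catalogue entry needs >= 2 alleles")
    if (anyDuplicated(paste(e$chrom, e$pos)))
        return("duplicated (chrom, pos) in catalogue")
    TRUE
})

#' @rdname SnpCatalogue-class
#' @export
SnpCatalogue <- function(chrom, pos, alleles, skipped = 0L) {
    e <- DataFrame(chrom = as.character(chrom), pos = as.integer(pos))
    e$alleles <- IRanges::CharacterList(alleles)
    new("SnpCatalogue", entries = e, skipped = as.integer(skipped))
}

#' @rdname SnpCatalogue-class
#' @export
setMethod("catalogueAlleles", "SnpCatalogue", function(x, chrom, pos) {
    i <- match(paste(chrom, pos), paste(x@entries$chrom, x@entries$pos))
    out <- as.list(x@entries$alleles[ifelse(is.na(i), 1L, i)])
    out[is.na(i)] <- list(character())
    if (length(chrom) == 1L) out[[1L]] else out
})

setMethod("length", "SnpCatalogue", function(x) nrow(x@entries))

setMethod("show", "SnpCatalogue", function(object) {
    cat("SnpCatalogue:", length(object), "SNV entries",
        sprintf("(%d non-SNV records skipped)\n", object@skipped))
})

#' Configuration of the two-stage permutation screen
#'
#' Holds the Monte-Carlo and significance settings of the heterozygote-deficit
#' screen.  Defaults follow the published operating point: a quick first pass
#' at `b1 = 1000` iterations, a `stage1Alpha = 0.005` gate, a refined second
#' pass at `b2 = 1e6` iterations for gated-in loci, and Benjamini-Hochberg
#' significance at `fdrQ = 0.1`.
#'
#' @param b1,b2 iteration counts of the two Monte-Carlo stages.
#' @param stage1Alpha stage-1 P-value gate for entering stage 2.
#' @param fdrQ false-discovery-rate level of the final significance call.
#' @param seed integer seed; per-locus substreams are derived from it so
#'   results do not depend on locus order.
#'
#' @return A `ScreenConfig`.
#' @export
setClass("ScreenConfig",
         representation(b1 = "numeric", stage1Alpha = "numeric",
                        b2 = "numeric", fdrQ = "numeric", seed = "integer"))

setValidity("ScreenConfig", function(object) {
    if (object@b1 < 1 || object@b2 < 1)
        return("iteration counts must be >= 1")
    if (object@stage1Alpha <= 0 || object@stage1Alpha > 1)
        return("stage1Alpha must lie in (0, 1]")
    if (object@fdrQ <= 0 || object@fdrQ >= 1)
        return("fdrQ must lie in (0, 1)")
    TRUE
})

#' @rdname ScreenConfig-class
#' @export
ScreenConfig <- function(b1 = 1000, stage1Alpha = 0.005, b2 = 1e6,
                         fdrQ = 0.1, seed = 1L) {
    new("ScreenConfig", b1 = b1, stage1Alpha = stage1Alpha, b2 = b2,
        fdrQ = fdrQ, seed = as.integer(seed))
}

setMethod("show", "ScreenConfig", function(object) {
    cat(sprintf(
        "ScreenConfig: B1=%g (gate %.3g), B2=%g, FDR q=%.3g, seed=%d\n",
        object@b1, object@stage1Alpha, object@b2, object@fdrQ, object@seed))
})
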