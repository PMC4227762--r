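## Readers/writers for every external table the pipeline touches.
## All internal coordinates are 1-based inclusive (dbSNP/VCF convention);
## BED input is converted on read by rtracklayer.

.ANN_CLASSES <- c("promoter", "exon", "intron")

.stopParse <- function(path, line, what) {
    stop(sprintf("parse error in '%s' (line %d): %s", path, line, what),
         call. = FALSE)
}

#' Read and write allele-count tables
#'
#' The canonical allele-count TSV has a `#`-prefixed header line with columns
#' `chrom`, `pos`, `snp_id`, `ref`, `alt`, then one `<sample>_ref` /
#' `<sample>_alt` column pair per sample.  A separate sample sheet
#' (`sample_id`, `sex`) supplies per-sample metadata; every sample column in
#' the count file must appear in the sheet.  Zero counts denote zero coverage
#' (uncovered sample).
#'
#' `writeAlleleCounts()` emits the same dialect deterministically, rows
#' ordered by (chrom, pos), so identical tables produce byte-identical files.
#'
#' @param path file path of the count table.
#' @param sample_sheet path of the sample-sheet TSV (`sample_id`, `sex`).
#' @param x an [AlleleCounts] object.
#'
#' @return `readAlleleCounts()` an [AlleleCounts]; `writeAlleleCounts()`
#'   invisibly `NULL`.
#' @export
readAlleleCounts <- function(path, sample_sheet) {
    lines <- readLines(path)
    if (!length(lines) || !startsWith(lines[1], "#"))
        .stopParse(path, 1L, "missing '#'-prefixed header")
    header <- strsplit(sub("^#", "", lines[1]), "\t", fixed = TRUE)[[1]]
    fixed <- c("chrom", "pos", "snp_id", "ref", "alt")
    if (!identical(header[seq_along(fixed)], fixed))
        .stopParse(path, 1L, "header must start with chrom/pos/snp_id/ref/alt")
    scols <- header[-seq_along(fixed)]
    if (length(scols) %% 2L != 0L)
        .stopParse(path, 1L, "unpaired sample columns")
    ids_ref <- sub("_ref$", "", scols[c(TRUE, FALSE)])
    ids_alt <- sub("_alt$", "", scols[c(FALSE, TRUE)])
    if (!identical(ids_ref, ids_alt) ||
        !all(endsWith(scols[c(TRUE, FALSE)], "_ref")) ||
        !all(endsWith(scols[c(FALSE, TRUE)], "_alt")))
        .stopParse(path, 1L, "sample columns must come as <id>_ref, <id>_alt")
    sheet <- readSampleSheet(sample_sheet)
    missing <- setdiff(ids_ref, sheet$sample_id)
    if (length(missing))
        stop(sprintf("samples absent from sample sheet: %s",
                     paste(missing, collapse = ", ")), call. = FALSE)

    body <- lines[-1]
    body <- body[nzchar(body)]
    if (!length(body)) {
        gr <- GRanges()
        mcols(gr)$snp_id <- character()
        mcols(gr)$ref <- character(); mcols(gr)$alt <- character()
        m <- matrix(integer(), 0L, length(ids_ref),
                    dimnames = list(NULL, ids_ref))
        return(AlleleCounts(gr, m, m,
                            sex = sheet$sex[match(ids_ref, sheet$sample_id)]))
    }
    df <- utils::read.delim(text = body, header = FALSE,
                            col.names = header, colClasses = "character")
    pos <- suppressWarnings(as.integer(df$pos))
    bad <- which(is.na(pos) | pos < 1L)
    if (length(bad))
        .stopParse(path, bad[1] + 1L, "invalid position")
    cnt <- as.matrix(df[, scols, drop = FALSE])
    suppressWarnings(storage.mode(cnt) <- "numeric")
    bad <- which(rowSums(is.na(cnt) | cnt < 0 | cnt != floor(cnt)) > 0)
    if (length(bad))
        .stopParse(path, bad[1] + 1L, "counts must be non-negative integers")
    key <- paste(df$chrom, pos)
    if (anyDuplicated(key))
        .stopParse(path, which(duplicated(key))[1] + 1L,
                   "duplicate (chrom, pos)")
    if (!all(df$ref %in% .NUCS) || !all(df$alt %in% .NUCS))
        .stopParse(path, which(!(df$ref %in% .NUCS & df$alt %in% .NUCS))[1] + 1L,
                   "alleles must be A/C/G/T")
    loci <- data.frame(chrom = df$chrom, pos = pos, snp_id = df$snp_id,
                       ref = df$ref, alt = df$alt)
    ref <- cnt[, c(TRUE, FALSE), drop = FALSE]
    alt <- cnt[, c(FALSE, TRUE), drop = FALSE]
    colnames(ref) <- colnames(alt) <- ids_ref
    AlleleCounts(loci, ref, alt,
                 sex = sheet$sex[match(ids_ref, sheet$sample_id)])
}

#' @rdname readAlleleCounts
#' @export
writeAlleleCounts <- function(x, path) {
    stopifnot(is(x, "AlleleCounts"))
    o <- order(as.character(seqnames(x)), start(x))
    x <- x[o, ]
    ids <- colnames(x)
    header <- paste0("#", paste(c("chrom", "pos", "snp_id", "ref", "alt",
                                  rbind(paste0(ids, "_ref"),
                                        paste0(ids, "_alt"))),
                                collapse = "\t"))
    m <- mcols(rowRanges(x))
    cnt <- matrix(0L, nrow(x), 2L * ncol(x))
    cnt[, c(TRUE, FALSE)] <- refCounts(x)
    cnt[, c(FALSE, TRUE)] <- altCounts(x)
    rows <- if (nrow(x)) {
        paste(as.character(seqnames(x)), start(x),
              ifelse(is.na(m$snp_id), ".", m$snp_id), m$ref, m$alt,
              apply(cnt, 1L, paste, collapse = "\t"), sep = "\t")
    } else character()
    writeLines(c(header, rows), path)
    invisible(NULL)
}

#' @rdname readAlleleCounts
#' @export
readSampleSheet <- function(path) {
    df <- utils::read.delim(path, comment.char = "",
                            colClasses = "character")
    if (!all(c("sample_id", "sex") %in% names(df)))
        .stopParse(path, 1L, "sample sheet needs sample_id and sex columns")
    if (anyDuplicated(df$sample_id))
        stop("duplicated sample_id in sample sheet", call. = FALSE)
    if (!all(df$sex %in% .SEXES))
        stop("sex must be one of female/male/unknown", call. = FALSE)
    df
}

#' @rdname readAlleleCounts
#' @export
writeSampleSheet <- function(x, path) {
    stopifnot(is(x, "AlleleCounts"))
    utils::write.table(
        data.frame(sample_id = colnames(x), sex = unname(sampleSex(x))),
        path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(NULL)
}

#' Read a known-SNV catalogue
#'
#' Accepts either a standard VCF (positions 1-based; parsed with
#' \pkg{vcfR}) or a 4-column TSV (`chrom`, `pos`, `ref`,
#' comma-separated `alts`).  Only single-nucleotide records are kept:
#' indels and multi-nucleotide variants are skipped and counted (see
#' `skipped` slot of the result).  Multi-allelic SNVs retain their full
#' allele set.
#'
#' @param path VCF or TSV file.
#' @return A [SnpCatalogue].
#' @export
readSnpCatalogue <- function(path) {
    first <- readLines(path, n = 1L)
    if (grepl("^##fileformat=VCF", first)) {
        v <- vcfR::read.vcfR(path, verbose = FALSE)
        fix <- vcfR::getFIX(v)
        if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                             dimnames = list(NULL, names(fix)))
        ref <- fix[, "REF"]; alt <- fix[, "ALT"]
        alts <- strsplit(ifelse(is.na(alt), "", alt), ",", fixed = TRUE)
        keep_alts <- lapply(alts, function(a) a[a %in% .NUCS])
        ok <- ref %in% .NUCS & lengths(keep_alts) >= 1L
        skipped <- sum(!ok)
        alleles <- mapply(function(r, a) unique(c(r, a)),
                          ref[ok], keep_alts[ok], SIMPLIFY = FALSE)
        SnpCatalogue(fix[ok, "CHROM"], as.integer(fix[ok, "POS"]),
                     alleles, skipped = skipped)
    } else {
        df <- utils::read.delim(path, comment.char = "#", header = FALSE,
                                col.names = c("chrom", "pos", "ref", "alts"),
                                colClasses = "character")
        alts <- strsplit(df$alts, ",", fixed = TRUE)
        keep_alts <- lapply(alts, function(a) a[a %in% .NUCS])
        ok <- df$ref %in% .NUCS & lengths(keep_alts) >= 1L
        alleles <- mapply(function(r, a) unique(c(r, a)),
                          df$ref[ok], keep_alts[ok], SIMPLIFY = FALSE)
        SnpCatalogue(df$chrom[ok], as.integer(df$pos[ok]), alleles,
                     skipped = sum(!ok))
    }
}

#' Read functional annotation intervals
#'
#' BED6+2 input: the six standard BED columns followed by a functional class
#' (`promoter`, `exon` or `intron`) and a feature identifier.  BED's 0-based
#' half-open coordinates are converted to the package's 1-based inclusive
#' convention.  Promoter intervals are expected to span the 2000 bp upstream
#' of a transcription start site, ending at it (strand-aware);
#' [makePromoters()] derives them from TSS positions.
#'
#' @param path BED6+2 file.
#' @return A `GRanges` with metadata columns `class` and `feature_id`.
#' @export
readAnnotationIntervals <- function(path) {
    gr <- rtracklayer::import(
        path, format = "BED",
        extraCols = c(class = "character", feature_id = "character"))
    if (!all(gr$class %in% .ANN_CLASSES))
        stop(sprintf("annotation class outside {%s}: %s",
                     paste(.ANN_CLASSES, collapse = ", "),
                     paste(unique(setdiff(gr$class, .ANN_CLASSES)),
                           collapse = ", ")), call. = FALSE)
    gr
}

#' @rdname readAnnotationIntervals
#' @param tss `GRanges` of width-1 transcription start sites with a valid
#'   strand (`+` or `-`) and a `feature_id` metadata column.
#' @param upstream promoter extent upstream of the TSS in bp.
#' @export
makePromoters <- function(tss, upstream = 2000L) {
    stopifnot(all(GenomicRanges::width(tss) == 1L),
              all(as.character(BiocGenerics::strand(tss)) %in% c("+", "-")))
    neg <- as.character(BiocGenerics::strand(tss)) == "-"
    s <- ifelse(neg, start(tss), pmax(1L, start(tss) - upstream))
    e <- ifelse(neg, start(tss) + upstream, start(tss))
    out <- GRanges(seqnames(tss), IRanges(s, e),
                   strand = BiocGenerics::strand(tss))
    mcols(out)$class <- "promoter"
    mcols(out)$feature_id <- mcols(tss)$feature_id
    out
}

#' Read per-allele bisulfite methylation calls
#'
#' TSV columns: `chrom`, `pos`, `sample_id`, `allele` (`ref`/`alt`), `meth`,
#' `unmeth` — summed CpG methylation calls of the bisulfite reads carrying
#' each SNP allele.  Rows with `meth + unmeth == 0` carry no information and
#' are dropped with a warning.
#'
#' @param path TSV file.
#' @return A `data.frame` with the validated columns.
#' @export
readMethylationCalls <- function(path) {
    df <- utils::read.delim(path, comment.char = "#",
                            colClasses = c(chrom = "character",
                                           sample_id = "character",
                                           allele = "character"))
    need <- c("chrom", "pos", "sample_id", "allele", "meth", "unmeth")
    if (!all(need %in% names(df)))
        .stopParse(path, 1L, "methylation table needs chrom/pos/sample_id/allele/meth/unmeth")
    if (!all(df$allele %in% c("ref", "alt")))
        stop("allele must be 'ref' or 'alt'", call. = FALSE)
    if (any(df$meth < 0 | df$unmeth < 0))
        stop("negative methylation-call counts", call. = FALSE)
    if (anyDuplicated(df[c("chrom", "pos", "sample_id", "allele")]))
        stop("duplicate (locus, sample, allele) row", call. = FALSE)
    empty <- df$meth + df$unmeth == 0
    if (any(empty)) {
        warning(sprintf("dropping %d rows with zero calls", sum(empty)))
        df <- df[!empty, , drop = FALSE]
    }
    df
}

#' Read per-site allele-specific-expression counts
#'
#' TSV columns: `chrom`, `pos`, `tissue`, `gene_ids` (comma-separated; empty
#' for intergenic sites), `ref_count`, `alt_count` — high-quality reference
#' and non-reference base counts at known variant sites in RNA-seq data.
#'
#' @param path TSV file.
#' @return A `data.frame`; `gene_ids` is a list column of character vectors.
#' @export
readAseCounts <- function(path) {
    df <- utils::read.delim(path, comment.char = "#",
                            colClasses = c(chrom = "character",
                                           tissue = "character",
                                           gene_ids = "character"))
    need <- c("chrom", "pos", "tissue", "gene_ids", "ref_count", "alt_count")
    if (!all(need %in% names(df)))
        .stopParse(path, 1L, "ASE table needs chrom/pos/tissue/gene_ids/ref_count/alt_count")
    if (any(df$ref_count < 0 | df$alt_count < 0))
        stop("negative ASE counts", call. = FALSE)
    df$gene_ids <- lapply(strsplit(df$gene_ids, ",", fixed = TRUE),
                          function(g) g[nzchar(g)])
    df
}
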