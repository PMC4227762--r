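## Functional classification with fractional multi-annotation weights and a
## chromosome-matched random-sampling enrichment test.

.FUN_CLASSES <- c("promoter", "exon", "intron", "intergenic")

#' Fractional functional classification of SNP loci
#'
#' Assigns each locus weights over `promoter`, `exon`, `intron` and
#' `intergenic` that always sum to one.  All annotation intervals overlapping
#' the position on either strand are collected; the weight 1/k is given to
#' each of the k *distinct* classes present (a position in an exon on the
#' sense strand and an intron on the antisense strand scores 0.5 exon +
#' 0.5 intron).  A position overlapping nothing is intergenic with weight 1.
#'
#' @param loci `GRanges` of SNP positions (strand ignored for overlap).
#' @param annotation `GRanges` from [readAnnotationIntervals()] with a
#'   `class` metadata column.
#' @return `classifyLoci()`: numeric matrix (loci x 4 classes);
#'   `classifySnp()`: named numeric vector for a single locus.
#' @export
classifyLoci <- function(loci, annotation) {
    w <- matrix(0, length(loci), length(.FUN_CLASSES),
                dimnames = list(NULL, .FUN_CLASSES))
    hits <- GenomicRanges::findOverlaps(loci, annotation,
                                        ignore.strand = TRUE)
    cls <- mcols(annotation)$class[S4Vectors::subjectHits(hits)]
    qh <- S4Vectors::queryHits(hits)
    for (cl in .ANN_CLASSES)
        w[unique(qh[cls == cl]), cl] <- 1
    k <- rowSums(w)
    none <- k == 0
    w[none, "intergenic"] <- 1
    w[!none, ] <- w[!none, , drop = FALSE] / k[!none]
    w
}

#' @rdname classifyLoci
#' @param chrom,pos single locus coordinates (alternative to `loci`).
#' @export
classifySnp <- function(chrom, pos, annotation) {
    gr <- GRanges(chrom, IRanges(pos, width = 1L))
    drop(classifyLoci(gr, annotation))
}

#' Chromosome-matched functional enrichment test
#'
#' Tests whether the significant loci are enriched or depleted in each
#' functional class relative to the filtered universe they came from.  Each
#' null draw samples, per chromosome and without replacement, as many loci
#' from the universe as there are significant loci on that chromosome, then
#' sums the fractional class weights of the sampled set.  Two-sided empirical
#' P-values double the smaller tail with the add-one correction and are
#' capped at 1.
#'
#' @param significant `GRanges` of significant loci (must be a subset of the
#'   universe).
#' @param universe `GRanges` of all filtered loci.
#' @param annotation annotation `GRanges`.
#' @param n_draws number of null samplings.
#' @param seed integer RNG seed.
#' @return A `DataFrame` with one row per class: `class`, `observed`,
#'   `null_mean`, `null_sd`, `p_two_sided`, and `n_draws` in its metadata.
#' @export
enrichmentTest <- function(significant, universe, annotation,
                           n_draws = 1000, seed = 1L) {
    key_u <- paste(seqnames(universe), start(universe))
    key_s <- paste(seqnames(significant), start(significant))
    if (!all(key_s %in% key_u))
        stop("significant loci must be a subset of the universe",
             call. = FALSE)
    w_u <- classifyLoci(universe, annotation)
    obs <- colSums(classifyLoci(significant, annotation))
    chr_u <- as.character(seqnames(universe))
    draw_n <- table(as.character(seqnames(significant)))
    if (!all(names(draw_n) %in% chr_u))
        stop("chromosome with significant loci but empty universe",
             call. = FALSE)
    idx_by_chr <- split(seq_along(chr_u), chr_u)
    set.seed(seed)
    null_sums <- matrix(0, n_draws, length(.FUN_CLASSES),
                        dimnames = list(NULL, .FUN_CLASSES))
    for (b in seq_len(n_draws)) {
        take <- unlist(lapply(names(draw_n), function(ch) {
            pool <- idx_by_chr[[ch]]
            if (length(pool) == 1L) pool
            else sample(pool, draw_n[[ch]], replace = FALSE)
        }), use.names = FALSE)
        null_sums[b, ] <- colSums(w_u[take, , drop = FALSE])
    }
    p <- vapply(.FUN_CLASSES, function(cl) {
        hi <- sum(null_sums[, cl] >= obs[[cl]]) + 1
        lo <- sum(null_sums[, cl] <= obs[[cl]]) + 1
        min(1, 2 * min(hi, lo) / (n_draws + 1))
    }, numeric(1))
    out <- DataFrame(class = .FUN_CLASSES, observed = unname(obs),
                     null_mean = colMeans(null_sums),
                     null_sd = apply(null_sums, 2, stats::sd),
                     p_two_sided = unname(p))
    S4Vectors::metadata(out) <- list(n_draws = n_draws)
    out
}
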