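## Bisulfite validation: per-heterozygote-sample Pearson chi-square on
## allele-partitioned methylation calls with a fixed-margin Monte-Carlo null,
## and a summed global statistic per locus.

.chisq2x2 <- function(k, r1, r2, c1, c2) {
    ## Pearson chi-square of the 2x2 table with margins (r1, r2) x (c1, c2)
    ## and top-left cell k, vectorised over k.
    n <- r1 + r2
    e11 <- r1 * c1 / n; e12 <- r1 * c2 / n
    e21 <- r2 * c1 / n; e22 <- r2 * c2 / n
    as.numeric((k - e11)^2 / e11 + (r1 - k - e12)^2 / e12 +
               (c1 - k - e21)^2 / e21 + (r2 - c1 + k - e22)^2 / e22)
}

#' Per-sample allele-by-methylation chi-square
#'
#' Pearson chi-square (no continuity correction) of the 2x2 table of
#' methylated/unmethylated CpG calls partitioned by SNP allele for one
#' heterozygous sample.  A large value means the methylation degree is
#' allele-dependent — the bisulfite signature of monoallelic methylation.
#' Tables with a zero row (an allele without calls) or zero column (all
#' calls methylated, or all unmethylated) are degenerate and excluded.
#'
#' @param tab 2x2 numeric matrix: rows = ref/alt allele, columns =
#'   methylated/unmethylated call counts.
#' @return The chi-square statistic, or `NA` for a degenerate table.
#' @export
sampleChisq <- function(tab) {
    stopifnot(identical(dim(tab), c(2L, 2L)), all(tab >= 0))
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) return(NA_real_)
    .chisq2x2(tab[1, 1], rowSums(tab)[1], rowSums(tab)[2],
              colSums(tab)[1], colSums(tab)[2])
}

#' Monte-Carlo P-value for one sample's chi-square
#'
#' Null replicates permute methylation-call labels among the table's calls
#' with both margins fixed (the conditional hypergeometric null, drawn with
#' `stats::r2dtable`); `P = (1 + #\{null chi2 >= observed\}) / (1 + B)`.
#'
#' @inheritParams sampleChisq
#' @param B number of permutation replicates.
#' @param seed optional integer seed.
#' @return List with `chi2` and `p` (`NA`s for a degenerate table).
#' @export
samplePvalue <- function(tab, B = 2000, seed = NULL) {
    chi2 <- sampleChisq(tab)
    if (is.na(chi2)) return(list(chi2 = NA_real_, p = NA_real_))
    if (!is.null(seed)) set.seed(seed)
    null_chi2 <- .nullChisqDraws(tab, B)
    list(chi2 = chi2, p = (1 + sum(null_chi2 >= chi2)) / (1 + B))
}

.nullChisqDraws <- function(tab, B) {
    k <- vapply(stats::r2dtable(B, rowSums(tab), colSums(tab)),
                function(m) m[1, 1], numeric(1))
    .chisq2x2(k, rowSums(tab)[1], rowSums(tab)[2],
              colSums(tab)[1], colSums(tab)[2])
}

#' Global bisulfite validation of candidate loci
#'
#' For every candidate locus, builds the per-sample 2x2 allele-by-methylation
#' tables from a methylation-call table, computes each usable sample's
#' chi-square and Monte-Carlo P-value, and sums the chi-squares into a global
#' locus statistic whose null replicates are sums of one permuted chi-square
#' per usable sample.  Samples that are uncovered, effectively homozygous
#' (calls for one allele only) or degenerate (a zero methylation-column
#' margin) are excluded with the corresponding reason.
#'
#' SNPs whose two alleles are C/T or G/A are flagged `ambiguous`: on one
#' bisulfite strand the conversion chemistry itself interconverts those
#' bases, so their allele partition deserves caution.  The test still runs.
#'
#' @param calls methylation-call `data.frame` from [readMethylationCalls()].
#' @param loci optional `GRanges` of candidate loci (with `ref`/`alt`
#'   metadata for the ambiguity flag); defaults to the loci present in
#'   `calls`.
#' @param samples optional character vector of all samples assayed; samples
#'   absent from `calls` at a locus are then reported as `uncovered`.
#' @param B permutation replicates per sample.
#' @param seed integer seed (per-locus substreams derived from it).
#' @return List of two `DataFrame`s: `per_locus` (`chrom`, `pos`,
#'   `n_usable`, `global_chi2`, `global_p`, `ambiguous`) and `per_sample`
#'   (`chrom`, `pos`, `sample_id`, `usable`, `reason`, `chi2`, `p`).
#' @export
validateWgbs <- function(calls, loci = NULL, samples = NULL, B = 2000,
                         seed = 1L) {
    if (is.null(loci)) {
        u <- unique(calls[c("chrom", "pos")])
        loci <- GRanges(u$chrom, IRanges(u$pos, width = 1L))
    }
    m <- mcols(loci)
    ambiguous <- if (all(c("ref", "alt") %in% names(m))) {
        pair <- paste(pmin(m$ref, m$alt), pmax(m$ref, m$alt))
        pair %in% c("C T", "A G")
    } else rep(NA, length(loci))

    per_locus <- vector("list", length(loci))
    per_sample <- vector("list", length(loci))
    for (i in seq_along(loci)) {
        ch <- as.character(seqnames(loci))[i]; po <- start(loci)[i]
        rows <- calls[calls$chrom == ch & calls$pos == po, , drop = FALSE]
        ids <- union(unique(rows$sample_id), samples)
        chi2 <- p <- stats::setNames(rep(NA_real_, length(ids)), ids)
        reason <- stats::setNames(rep(NA_character_, length(ids)), ids)
        nulls <- list()
        set.seed(.locusSeed(seed, ch, po, 3L))
        for (s in ids) {
            sr <- rows[rows$sample_id == s, , drop = FALSE]
            if (!nrow(sr)) { reason[s] <- "uncovered"; next }
            if (length(unique(sr$allele)) < 2L) {
                reason[s] <- "homozygous"; next
            }
            tab <- rbind(ref = c(sr$meth[sr$allele == "ref"],
                                 sr$unmeth[sr$allele == "ref"]),
                         alt = c(sr$meth[sr$allele == "alt"],
                                 sr$unmeth[sr$allele == "alt"]))
            colnames(tab) <- c("meth", "unmeth")
            if (any(colSums(tab) == 0) || any(rowSums(tab) == 0)) {
                reason[s] <- "degenerate_table"; next
            }
            chi2[s] <- sampleChisq(tab)
            null_s <- .nullChisqDraws(tab, B)
            p[s] <- (1 + sum(null_s >= chi2[s])) / (1 + B)
            nulls[[s]] <- null_s
        }
        usable <- !is.na(chi2)
        if (any(usable)) {
            global_chi2 <- sum(chi2[usable])
            global_null <- Reduce(`+`, nulls)
            global_p <- (1 + sum(global_null >= global_chi2)) / (1 + B)
        } else {
            global_chi2 <- NA_real_; global_p <- NA_real_
        }
        per_locus[[i]] <- DataFrame(chrom = ch, pos = po,
                                    n_usable = sum(usable),
                                    global_chi2 = global_chi2,
                                    global_p = global_p,
                                    ambiguous = ambiguous[i])
        per_sample[[i]] <- DataFrame(chrom = ch, pos = po, sample_id = ids,
                                     usable = usable, reason = unname(reason),
                                     chi2 = unname(chi2), p = unname(p))
    }
    list(per_locus = do.call(rbind, per_locus),
         per_sample = do.call(rbind, per_sample))
}
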