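## Genotype layer: SNP tracing against the catalogue, genotype calling,
## genotype-based allele-frequency estimation, MAF/coverage filtering and the
## iterative Bayesian sequencing-error correction.

GENOTYPES <- c("hom_ref", "hom_alt", "het", "missing")

.isChrX <- function(chrom) chrom %in% c("X", "chrX")

#' Restrict candidate mismatch positions to the known-SNV catalogue
#'
#' Keeps only loci that (i) are present in the catalogue, (ii) have both
#' observed alleles among the catalogue's allowed alleles and (iii) carry at
#' least one alternative-allele read in at least one sample — a position
#' nobody mismatches at carries no SNP evidence.
#'
#' @param x an [AlleleCounts] of candidate mismatch positions.
#' @param catalogue a [SnpCatalogue].
#' @return The retained subset of `x` (possibly zero loci).
#' @export
traceSnps <- function(x, catalogue) {
    stopifnot(is(x, "AlleleCounts"), is(catalogue, "SnpCatalogue"))
    if (!nrow(x)) return(x)
    chrom <- as.character(seqnames(x)); pos <- start(x)
    allowed <- catalogueAlleles(catalogue, chrom, pos)
    if (nrow(x) == 1L) allowed <- list(allowed)
    m <- mcols(rowRanges(x))
    compatible <- mapply(function(a, r, v) all(c(r, v) %in% a),
                         allowed, m$ref, m$alt)
    has_alt <- rowSums(altCounts(x)) > 0
    x[compatible & has_alt, ]
}

#' Call genotypes from allele counts
#'
#' Detection-based calls: a sample is heterozygous at a locus when both
#' alleles are observed at least once, homozygous when only one allele is
#' observed, and missing when uncovered.  In enrichment data a monoallelically
#' methylated heterozygote only exposes its methylated allele, so it is
#' (deliberately) called homozygous here — the deficit of `het` calls is the
#' screen's signal.
#'
#' @param x an [AlleleCounts].
#' @return A character matrix (loci x samples) with values
#'   `hom_ref`, `hom_alt`, `het`, `missing`.
#' @export
callGenotypes <- function(x) {
    stopifnot(is(x, "AlleleCounts"))
    r <- refCounts(x); a <- altCounts(x)
    g <- matrix("missing", nrow(r), ncol(r), dimnames = dimnames(r))
    g[r > 0 & a == 0] <- "hom_ref"
    g[r == 0 & a > 0] <- "hom_alt"
    g[r > 0 & a > 0] <- "het"
    g
}

#' Estimate allele frequencies from genotype calls
#'
#' The reference-allele frequency is computed from genotype counts, not from
#' read counts: `p_hat = (2 n_hom_ref + n_het) / (2 n_typed)`.  Counting
#' genotypes rather than allelic read abundances blunts reference-mapping
#' bias.  Loci with zero typed samples get `NA`.
#'
#' @param genotypes genotype matrix from [callGenotypes()].
#' @return Numeric vector of per-locus reference-allele frequencies.
#' @export
estimateAlleleFrequencies <- function(genotypes) {
    n_rr <- rowSums(genotypes == "hom_ref")
    n_het <- rowSums(genotypes == "het")
    n_typed <- rowSums(genotypes != "missing")
    p <- (2 * n_rr + n_het) / (2 * n_typed)
    p[n_typed == 0] <- NA_real_
    p
}

#' Per-locus summaries for the screen
#'
#' Collects, per locus, the genotype-based allele frequency, the number of
#' typed (covered) samples, the observed heterozygote count and the total
#' coverage — everything the coverage-conditioned null needs.
#'
#' @param x an [AlleleCounts].
#' @param genotypes optional genotype matrix; recomputed when absent.
#' @return A `DataFrame` with columns `chrom`, `pos`, `p_hat`, `n_typed`,
#'   `het_observed`, `total_coverage`.
#' @export
locusSummaries <- function(x, genotypes = callGenotypes(x)) {
    DataFrame(chrom = as.character(seqnames(x)), pos = start(x),
              p_hat = estimateAlleleFrequencies(genotypes),
              n_typed = as.integer(rowSums(genotypes != "missing")),
              het_observed = as.integer(rowSums(genotypes == "het")),
              total_coverage = as.integer(rowSums(snpCoverage(x))))
}

#' Filter loci on major-allele frequency and total coverage
#'
#' Retains loci whose major-allele frequency (from genotype-based estimates)
#' is below `maf_max` and whose total coverage across samples reaches the
#' chromosome-class threshold: `min_cov_autosome` for autosomes and the less
#' stringent `min_cov_x` for chromosome X, where only female samples carry
#' two X copies and contribute.  X-chromosome loci are evaluated — and their
#' counts interpreted downstream — on the female subset only; male columns
#' are zeroed there so later stages cannot pick them up.
#'
#' @param x an [AlleleCounts].
#' @param maf_max exclusive upper bound on the major-allele frequency.
#' @param min_cov_autosome,min_cov_x inclusive total-coverage thresholds.
#' @return The filtered [AlleleCounts].
#' @export
filterLoci <- function(x, maf_max = 0.90, min_cov_autosome = 350,
                       min_cov_x = 250) {
    stopifnot(is(x, "AlleleCounts"))
    if (!nrow(x)) return(x)
    chrx <- .isChrX(as.character(seqnames(x)))
    sex <- unname(sampleSex(x))
    if (any(chrx)) {
        if (!any(sex == "female"))
            stop("X-chromosome loci present but no female samples declared; ",
                 "sex metadata is required for X analysis", call. = FALSE)
        female <- sex == "female"
        r <- refCounts(x); a <- altCounts(x)
        r[chrx, !female] <- 0L
        a[chrx, !female] <- 0L
        x <- AlleleCounts(rowRanges(x), r, a, sex = sex)
    }
    g <- callGenotypes(x)
    p <- estimateAlleleFrequencies(g)
    maf <- pmax(p, 1 - p)
    cov <- rowSums(snpCoverage(x))
    thr <- ifelse(chrx, min_cov_x, min_cov_autosome)
    keep <- !is.na(maf) & maf < maf_max & cov >= thr
    x[keep, ]
}

#' Iterative Bayesian correction of sequencing errors
#'
#' A sample showing both alleles may be a genuine heterozygote or a homozygote
#' with miscalled reads.  For every mixed profile with `n = ref + alt` reads
#' the three genotype posteriors are compared:
#' \itemize{
#'   \item het: prior `2 p q`, likelihood `Binom(n, 1/2)` at the ref count;
#'   \item hom_ref: prior `p^2`, likelihood `Binom(n, epsilon)` at the alt
#'     count;
#'   \item hom_alt: prior `q^2`, likelihood `Binom(n, epsilon)` at the ref
#'     count,
#' }
#' with `p` the current genotype-based reference-allele frequency of the
#' locus and `epsilon` the per-read probability of miscalling towards the
#' other retained allele.  When a homozygous hypothesis has the strictly
#' largest posterior the minority-allele reads are removed (set to zero);
#' ties — including the degenerate `p` in `{0, 1}` case — keep the
#' heterozygote, which disfavours monoallelic calls.  Frequencies are
#' re-estimated from the corrected calls and the pass repeats, `rounds`
#' times in total.
#'
#' Correction never increases a count and never invents an allele; pure
#' homozygote profiles are fixed points.
#'
#' @param x an [AlleleCounts] (already filtered).
#' @param epsilon per-read sequencing-error rate towards the other allele.
#' @param rounds number of correction passes.
#' @return The corrected [AlleleCounts].
#' @export
correctSequencingErrors <- function(x, epsilon = 0.0025, rounds = 2L) {
    stopifnot(is(x, "AlleleCounts"), epsilon >= 0, epsilon < 0.5, rounds >= 1)
    r <- refCounts(x); a <- altCounts(x)
    for (round in seq_len(rounds)) {
        g <- matrix("missing", nrow(r), ncol(r))
        g[r > 0 & a == 0] <- "hom_ref"
        g[r == 0 & a > 0] <- "hom_alt"
        g[r > 0 & a > 0] <- "het"
        p <- estimateAlleleFrequencies(g)
        idx <- which(r > 0 & a > 0, arr.ind = TRUE)
        if (!nrow(idx)) break
        ri <- r[idx]; ai <- a[idx]; n <- ri + ai
        pl <- p[idx[, 1L]]; ql <- 1 - pl
        lp_het <- log(2 * pl * ql) + stats::dbinom(ri, n, 0.5, log = TRUE)
        lp_rr <- 2 * log(pl) + stats::dbinom(ai, n, epsilon, log = TRUE)
        lp_aa <- 2 * log(ql) + stats::dbinom(ri, n, epsilon, log = TRUE)
        to_rr <- lp_rr > lp_het & lp_rr >= lp_aa
        to_aa <- lp_aa > lp_het & lp_aa > lp_rr
        if (any(to_rr)) a[idx[to_rr, , drop = FALSE]] <- 0L
        if (any(to_aa)) r[idx[to_aa, , drop = FALSE]] <- 0L
    }
    AlleleCounts(rowRanges(x), r, a, sex = unname(sampleSex(x)))
}
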