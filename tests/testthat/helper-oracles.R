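## Independent oracles and small fixture builders shared across tests.
## Every oracle re-derives its quantity by enumeration or naive simulation,
## never by calling the code path it checks.

suppressMessages({
    library(GenomicRanges)
    library(IRanges)
    library(S4Vectors)
})

## Small AlleleCounts builder from parallel vectors/matrices.
makeAC <- function(chrom, pos, ref_allele, alt_allele, ref, alt,
                   sex = NULL, snp_id = NA) {
    loci <- data.frame(chrom = chrom, pos = pos,
                       snp_id = rep(snp_id, length.out = length(chrom)),
                       ref = ref_allele, alt = alt_allele)
    ref <- as.matrix(ref); alt <- as.matrix(alt)
    if (is.null(colnames(ref)))
        colnames(ref) <- colnames(alt) <- sprintf("s%d", seq_len(ncol(ref)))
    AlleleCounts(loci, ref, alt, sex = sex)
}

## Exact null distribution of the heterozygote-call count for one locus:
## enumerate genotype assignments and, for heterozygotes, the binomial read
## split; convolve per-sample call probabilities.
enumHetCallProb <- function(p, coverage) {
    if (coverage < 1) return(0)
    ## P(genotype het) * P(both alleles appear among `coverage` reads)
    p_both <- sum(vapply(0:coverage, function(k) {
        if (k > 0 && k < coverage) dbinom(k, coverage, 0.5) else 0
    }, numeric(1)))
    2 * p * (1 - p) * p_both
}

enumNullHetDist <- function(p, coverages) {
    coverages <- coverages[coverages > 0]
    pmf <- 1  # P(het count = 0) for zero samples
    for (cv in coverages) {
        q <- enumHetCallProb(p, cv)
        pmf <- c(pmf * (1 - q), 0) + c(0, pmf * q)
    }
    pmf  # index k+1 = P(het count = k)
}

exactHetDeficitP <- function(het_observed, p, coverages) {
    pmf <- enumNullHetDist(p, coverages)
    sum(pmf[seq_len(min(het_observed + 1, length(pmf)))])
}

## Naive null simulation: draw a genotype per sample, then individual reads.
naiveNullHetCounts <- function(p, coverages, B) {
    coverages <- coverages[coverages > 0]
    vapply(seq_len(B), function(b) {
        hets <- 0L
        for (cv in coverages) {
            g <- sample(c("RR", "RA", "AA"), 1,
                        prob = c(p^2, 2 * p * (1 - p), (1 - p)^2))
            if (g == "RA") {
                reads <- sample(c("R", "A"), cv, replace = TRUE)
                if (length(unique(reads)) == 2L) hets <- hets + 1L
            }
        }
        hets
    }, integer(1))
}

## Exact conditional P for a 2x2 table: hypergeometric enumeration of all
## tables with the observed margins.
exact2x2CondP <- function(tab) {
    r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
    c1 <- sum(tab[, 1]); c2 <- sum(tab[, 2])
    obs <- chisqStat2x2(tab)
    ks <- max(0, c1 - r2):min(r1, c1)
    w <- dhyper(ks, r1, r2, c1)
    stats <- vapply(ks, function(k)
        chisqStat2x2(rbind(c(k, r1 - k), c(c1 - k, r2 - (c1 - k)))),
        numeric(1))
    sum(w[stats >= obs - 1e-9])
}

chisqStat2x2 <- function(tab) {
    e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    sum((tab - e)^2 / e)
}

## Exact two-sided binomial P at 0.5 by direct summation of outcomes no more
## probable than the observed one.
exactBinomTwoSidedP <- function(k, n) {
    d <- dbinom(0:n, n, 0.5)
    sum(d[d <= d[k + 1] * (1 + 1e-7)])
}

## Row-scan re-implementation of the locus filter rules.
bruteFilterKeep <- function(ac, maf_max = 0.9, min_cov = 350,
                            min_cov_x = 250) {
    chrom <- as.character(GenomicRanges::seqnames(snpLoci(ac)))
    sex <- unname(sampleSex(ac))
    keep <- logical(nrow(ac))
    for (i in seq_len(nrow(ac))) {
        is_x <- chrom[i] %in% c("X", "chrX")
        use <- if (is_x) sex == "female" else rep(TRUE, ncol(ac))
        r <- refCounts(ac)[i, use]; a <- altCounts(ac)[i, use]
        n_rr <- sum(r > 0 & a == 0); n_aa <- sum(r == 0 & a > 0)
        n_het <- sum(r > 0 & a > 0); n_typed <- sum(r + a > 0)
        if (n_typed == 0) next
        p <- (2 * n_rr + n_het) / (2 * n_typed)
        maf <- max(p, 1 - p)
        cov <- sum(r) + sum(a)
        keep[i] <- maf < maf_max && cov >= (if (is_x) min_cov_x else min_cov)
    }
    keep
}
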