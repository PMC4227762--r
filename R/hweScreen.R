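## The detector: coverage-conditioned Hardy-Weinberg null for the
## heterozygote count, two-stage Monte-Carlo P-values, BH significance and
## the reference-bias QC.

## Deterministic per-locus seed so results are independent of processing
## order and safe to parallelise.  Plain 31-polynomial string hash folded
## into [1, 2^31 - 2].
.locusSeed <- function(seed, chrom, pos, salt = 0L) {
    h <- (as.double(seed) %% 2147483647) + 1
    for (ch in utf8ToInt(as.character(chrom)))
        h <- (h * 31 + ch) %% 2147483647
    h <- (h * 31 + as.double(pos)) %% 2147483647
    h <- (h * 31 + salt) %% 2147483647
    as.integer(h + 1)
}

#' Per-sample probability of a heterozygote call under the null
#'
#' Under Hardy-Weinberg equilibrium with reference-allele frequency `p_hat`,
#' a sample observed with coverage `c` is *called* heterozygous only if it is
#' heterozygous (probability `2 p q`) and both alleles appear among its `c`
#' reads, each read falling on either allele with probability 1/2 — i.e.
#' `2 p q (1 - 0.5^(c-1))`.  Homozygotes can never be called heterozygous.
#' A coverage-1 sample can never show two alleles, which is exactly the
#' low-coverage false-homozygote effect the coverage-conditioned null
#' accounts for.
#'
#' @param p_hat reference-allele frequency in (0, 1).
#' @param coverages integer vector of per-sample coverages (zeros allowed;
#'   they contribute probability 0).
#' @return Numeric vector of per-sample het-call probabilities.
#' @export
hetCallProbs <- function(p_hat, coverages) {
    pr <- 2 * p_hat * (1 - p_hat) * (1 - 0.5^(coverages - 1))
    pr[coverages < 1] <- 0
    pr
}

#' Simulate null heterozygote counts for one locus
#'
#' Draws `B` replicates of the number of heterozygote *calls* among the typed
#' samples under the HWE null with the observed per-sample coverages.  Each
#' sample contributes an independent Bernoulli with probability
#' [hetCallProbs()]; samples are grouped by coverage so a replicate costs one
#' binomial draw per distinct coverage value.  This is the exact marginal of
#' drawing a genotype from `(p^2, 2pq, q^2)` and then splitting the sample's
#' reads Bernoulli(1/2) between alleles.
#'
#' @inheritParams hetCallProbs
#' @param B number of null replicates.
#' @return Integer vector of length `B` of null heterozygote counts.
#' @export
simulateNullHetCounts <- function(p_hat, coverages, B) {
    coverages <- coverages[coverages > 0]
    counts <- integer(B)
    if (!length(coverages)) return(counts)
    tab <- table(coverages)
    cov_vals <- as.integer(names(tab))
    pr <- hetCallProbs(p_hat, cov_vals)
    for (i in seq_along(cov_vals))
        counts <- counts + stats::rbinom(B, as.integer(tab[[i]]), pr[i])
    counts
}

#' Monte-Carlo P-value for a heterozygote deficit
#'
#' One-sided (deficiency only) Monte-Carlo P-value with the add-one rule:
#' `P = (1 + #\{null het count <= observed\}) / (1 + B)`, so the smallest
#' attainable value is `1/(B+1)` and P is never zero.  Loci with `p_hat` of
#' `NA`, 0 or 1 are untestable (`NA`): with one allele fixed no heterozygote
#' is expected under the null at all.
#'
#' @inheritParams simulateNullHetCounts
#' @param het_observed observed number of heterozygote calls.
#' @param seed optional integer seed applied before drawing.
#' @return Monte-Carlo P-value in `(0, 1]`, or `NA` if untestable.
#' @export
hetDeficitPvalue <- function(het_observed, p_hat, coverages, B = 1000,
                             seed = NULL) {
    if (is.na(p_hat) || p_hat <= 0 || p_hat >= 1) return(NA_real_)
    if (!is.null(seed)) set.seed(seed)
    null_counts <- simulateNullHetCounts(p_hat, coverages, B)
    (1 + sum(null_counts <= het_observed)) / (1 + B)
}

#' Two-stage permutation screen for monoallelic methylation
#'
#' Runs the heterozygote-deficit test over every locus of a filtered,
#' error-corrected allele-count table.  Every testable locus first gets a
#' quick stage-1 P-value at `b1` iterations; only loci at or below the
#' `stage1Alpha` gate proceed to the refined stage-2 P-value at `b2`
#' iterations.  `p_final` is the stage-2 value where present, else the
#' stage-1 value.  Significance is a Benjamini-Hochberg call at `fdrQ`
#' across all tested loci.  Per-locus RNG substreams are derived from
#' `(seed, chrom, pos)`, so results are reproducible and independent of
#' locus order.  On chromosome X only female samples are used; samples with
#' zero coverage at a locus carry no genotype information and are excluded
#' from both the observed statistic and the null.
#'
#' @param x a filtered, corrected [AlleleCounts].
#' @param config a [ScreenConfig].
#' @return A `DataFrame` with one row per locus: `chrom`, `pos`, `snp_id`,
#'   `p_hat`, `n_typed`, `het_observed`, `p_stage1`, `p_stage2`, `p_final`,
#'   `significant`, plus the BH critical value in
#'   `S4Vectors::metadata()$bh_critical`.
#' @export
twoStageScreen <- function(x, config = ScreenConfig()) {
    stopifnot(is(x, "AlleleCounts"), is(config, "ScreenConfig"))
    sex <- unname(sampleSex(x))
    cov <- snpCoverage(x)
    g <- callGenotypes(x)
    chrom <- as.character(seqnames(x)); pos <- start(x)
    chrx <- .isChrX(chrom)
    if (any(chrx)) {
        ## male samples carry one X; they must not enter the diploid null
        male <- sex == "male"
        cov[chrx, male] <- 0L
        g[chrx, male] <- "missing"
    }
    p_hat <- estimateAlleleFrequencies(g)
    n_typed <- as.integer(rowSums(g != "missing"))
    het_obs <- as.integer(rowSums(g == "het"))

    n <- nrow(x)
    p1 <- p2 <- rep(NA_real_, n)
    for (i in seq_len(n)) {
        covi <- cov[i, ]
        p1[i] <- hetDeficitPvalue(het_obs[i], p_hat[i], covi, config@b1,
                                  seed = .locusSeed(config@seed, chrom[i],
                                                    pos[i], 1L))
        if (!is.na(p1[i]) && p1[i] <= config@stage1Alpha)
            p2[i] <- hetDeficitPvalue(het_obs[i], p_hat[i], covi, config@b2,
                                      seed = .locusSeed(config@seed, chrom[i],
                                                        pos[i], 2L))
    }
    p_final <- ifelse(is.na(p2), p1, p2)
    bh <- bhThreshold(p_final[!is.na(p_final)], config@fdrQ)
    signif <- !is.na(p_final) & p_final <= bh$critical & bh$critical > 0
    m <- mcols(rowRanges(x))
    out <- DataFrame(chrom = chrom, pos = pos, snp_id = m$snp_id,
                     p_hat = p_hat, n_typed = n_typed,
                     het_observed = het_obs, p_stage1 = p1, p_stage2 = p2,
                     p_final = p_final, significant = signif)
    S4Vectors::metadata(out) <- list(bh_critical = bh$critical,
                                     config = config)
    out
}

#' Benjamini-Hochberg threshold and significance flags
#'
#' Classic step-up procedure: with the `m` P-values sorted ascending,
#' `k* = max\{k : p_(k) <= k q / m\}`; the critical value is `k* q / m`
#' (0 when no rank qualifies) and every P-value at or below it is flagged.
#' Agrees with `stats::p.adjust(..., "BH") <= q` but also exposes the
#' critical value itself.
#'
#' @param p numeric vector of P-values.
#' @param q FDR level.
#' @return List with `critical` (the critical P-value), `n_significant` and
#'   `significant` (logical flags parallel to `p`).
#' @export
bhThreshold <- function(p, q = 0.1) {
    stopifnot(length(p) >= 1, all(p >= 0 & p <= 1, na.rm = TRUE))
    m <- length(p)
    ps <- sort(p)
    k <- which(ps <= seq_len(m) * q / m)
    crit <- if (length(k)) max(k) * q / m else 0
    flags <- p <= crit & crit > 0
    list(critical = crit, n_significant = sum(flags), significant = flags)
}

#' Reference-bias quality control
#'
#' At significant loci, compares the per-sample coverages of
#' homozygous-reference and homozygous-alternative calls with a two-sided
#' Wilcoxon rank-sum test.  Under reference-mapping bias the alternative
#' allele would be systematically under-covered; a large P-value is
#' reassuring.  Purely diagnostic — never used for filtering.
#'
#' @param results screen output of [twoStageScreen()].
#' @param x the [AlleleCounts] the screen ran on.
#' @param genotypes optional genotype matrix; recomputed when absent.
#' @return List with `assessable`, `p_value`, `n_hom_ref`, `n_hom_alt`.
#' @export
referenceBiasQc <- function(results, x, genotypes = callGenotypes(x)) {
    sig <- which(results$significant)
    if (!length(sig))
        return(list(assessable = FALSE, reason = "no significant loci",
                    p_value = NA_real_, n_hom_ref = 0L, n_hom_alt = 0L))
    cov <- snpCoverage(x)[sig, , drop = FALSE]
    g <- genotypes[sig, , drop = FALSE]
    cov_rr <- cov[g == "hom_ref"]
    cov_aa <- cov[g == "hom_alt"]
    if (!length(cov_rr) || !length(cov_aa))
        return(list(assessable = FALSE,
                    reason = "one homozygote class empty",
                    p_value = NA_real_,
                    n_hom_ref = length(cov_rr), n_hom_alt = length(cov_aa)))
    p <- suppressWarnings(
        stats::wilcox.test(cov_rr, cov_aa, alternative = "two.sided")$p.value)
    ## fully tied samples (zero rank variance) carry no evidence at all
    if (is.na(p)) p <- 1
    list(assessable = TRUE, p_value = min(1, p),
         n_hom_ref = length(cov_rr), n_hom_alt = length(cov_aa))
}
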