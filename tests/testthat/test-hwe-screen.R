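test_that("coverage-1 samples can never be called heterozygous", {
    expect_equal(hetCallProbs(0.5, c(1, 1, 1)), c(0, 0, 0))
    expect_true(all(simulateNullHetCounts(0.5, rep(1L, 20), 500) == 0L))
    ## a locus where everyone has coverage 1 always returns P = 1
    p <- hetDeficitPvalue(0, 0.5, rep(1L, 20), B = 500, seed = 1)
    expect_equal(p, 1)
})

test_that("per-sample het-call probability matches enumeration", {
    ## closed form at coverage 2 and p = 0.5: 2pq * (1 - 2 * 0.25) = 0.25
    expect_equal(enumHetCallProb(0.5, 2), 0.25)
    expect_equal(hetCallProbs(0.5, 2), 0.25)
    for (p in c(0.2, 0.5, 0.8)) for (cv in 1:6)
        expect_equal(hetCallProbs(p, cv), enumHetCallProb(p, cv))
    ## large coverage limit: 2pq
    expect_equal(hetCallProbs(0.5, 500), 0.5, tolerance = 1e-12)

    ## empirical frequency of a het call over many replicates
    set.seed(99)
    counts <- simulateNullHetCounts(0.5, 2L, 1e5)
    expect_lt(abs(mean(counts) - 0.25), 0.005)
})

test_that("grouped null sampler matches the naive genotype+read simulator", {
    covs <- c(2L, 3L, 3L, 5L, 8L)
    set.seed(21)
    naive <- naiveNullHetCounts(0.3, covs, 4000)
    set.seed(22)
    fast <- simulateNullHetCounts(0.3, covs, 4000)
    ## same distribution: pooled-SE mean check plus two-sample chi-square
    se <- sqrt(var(naive) / 4000 + var(fast) / 4000)
    expect_lt(abs(mean(naive) - mean(fast)), 3 * se)
    lv <- 0:length(covs)
    tab <- rbind(table(factor(naive, levels = lv)),
                 table(factor(fast, levels = lv)))
    tab <- tab[, colSums(tab) > 0, drop = FALSE]
    expect_gt(suppressWarnings(chisq.test(tab)$p.value), 0.001)
})

test_that("Monte-Carlo P matches exhaustive enumeration on tiny loci", {
    cases <- list(list(p = 0.5, covs = c(1L, 2L, 3L), obs = 0L),
                  list(p = 0.3, covs = c(2L, 2L, 3L, 3L), obs = 1L),
                  list(p = 0.7, covs = c(3L, 3L, 1L), obs = 0L))
    B <- 4e5
    for (cs in cases) {
        exact <- exactHetDeficitP(cs$obs, cs$p, cs$covs)
        mc <- hetDeficitPvalue(cs$obs, cs$p, cs$covs, B = B, seed = 5)
        se <- sqrt(exact * (1 - exact) / B)
        expect_lt(abs(mc - exact), 3 * se + 2 / B)
    }
})

test_that("P-value boundaries behave as specified", {
    ## everything heterozygous: P = 1 within 1/(B+1)
    p <- hetDeficitPvalue(10, 0.5, rep(20L, 10), B = 1000, seed = 2)
    expect_gte(p, 1 - 1 / 1001)
    ## strong deficit: minimum attainable P = 1/(B+1)
    p <- hetDeficitPvalue(0, 0.5, rep(30L, 100), B = 1000, seed = 3)
    expect_equal(p, 1 / 1001)
    ## untestable loci are NA
    expect_true(is.na(hetDeficitPvalue(0, 1, rep(10L, 5), B = 100)))
    expect_true(is.na(hetDeficitPvalue(0, NA, rep(10L, 5), B = 100)))
})

test_that("two-stage screen gates, refines and is order-invariant", {
    sim <- simulateMethylcap(simParams(n_samples = 80, n_loci = 40,
                                       frac_monoallelic = 0.25, seed = 31))
    cfg <- ScreenConfig(b1 = 400, b2 = 4000, seed = 17)
    res <- twoStageScreen(sim$counts, cfg)
    ## stage-2 entered iff stage-1 at or below the gate
    entered <- !is.na(res$p_stage2)
    expect_true(all(res$p_stage1[entered] <= cfg@stage1Alpha))
    expect_true(all(res$p_stage1[!entered & !is.na(res$p_stage1)] >
                    cfg@stage1Alpha))
    expect_equal(res$p_final, ifelse(entered, res$p_stage2, res$p_stage1))

    ## identical seed, permuted locus order: identical per-locus results
    perm <- sample(nrow(sim$counts))
    res2 <- twoStageScreen(sim$counts[perm, ], cfg)
    m <- match(paste(res$chrom, res$pos), paste(res2$chrom, res2$pos))
    expect_equal(res$p_stage1, res2$p_stage1[m])
    expect_equal(res$p_final, res2$p_final[m])
})

test_that("screen excludes male samples on chromosome X", {
    ## X locus: males carry huge discordant counts that would change the
    ## statistic if (wrongly) included
    ref <- rbind(c(20L, 10L, 0L, 500L))
    alt <- rbind(c(15L, 9L, 25L, 0L))
    colnames(ref) <- colnames(alt) <- c("f1", "f2", "f3", "m1")
    ac <- makeAC("chrX", 100L, "A", "G", ref, alt,
                 sex = c("female", "female", "female", "male"))
    res <- twoStageScreen(ac, ScreenConfig(b1 = 200, b2 = 200, seed = 1))
    expect_identical(res$n_typed, 3L)
    expect_identical(res$het_observed, 2L)
})

test_that("Benjamini-Hochberg threshold follows the step function", {
    bh <- bhThreshold(c(0.001, 0.02, 0.9), q = 0.1)
    expect_equal(bh$critical, 2 * 0.1 / 3)
    expect_identical(bh$significant, c(TRUE, TRUE, FALSE))
    bh1 <- bhThreshold(rep(1, 10), q = 0.1)
    expect_equal(bh1$critical, 0)
    expect_identical(bh1$n_significant, 0L)
    ## cross-check flags against stats::p.adjust on random P-values
    set.seed(8)
    p <- c(runif(50)^3, runif(50))
    bh2 <- bhThreshold(p, q = 0.1)
    expect_identical(bh2$significant,
                     p.adjust(p, method = "BH") <= 0.1)
})

test_that("reference-bias QC compares homozygote coverages", {
    mkres <- function() S4Vectors::DataFrame(significant = TRUE)
    ## identical coverage distributions: P near 1
    ref <- rbind(c(rep(10L, 10), rep(0L, 10)))
    alt <- rbind(c(rep(0L, 10), rep(10L, 10)))
    colnames(ref) <- colnames(alt) <- sprintf("s%d", 1:20)
    ac <- makeAC("chr1", 1L, "A", "G", ref, alt)
    qc <- referenceBiasQc(mkres(), ac)
    expect_true(qc$assessable)
    expect_gt(qc$p_value, 0.9)

    ## complete separation at n = 20 per class: tiny P
    ref2 <- rbind(c(rep(5L, 20), rep(0L, 20)))
    alt2 <- rbind(c(rep(0L, 20), rep(50L, 20)))
    colnames(ref2) <- colnames(alt2) <- sprintf("s%d", 1:40)
    ac2 <- makeAC("chr1", 1L, "A", "G", ref2, alt2)
    expect_lt(referenceBiasQc(mkres(), ac2)$p_value, 0.01)

    ## one observation per class: exact two-sided P = 1
    ref3 <- rbind(c(3L, 0L)); alt3 <- rbind(c(0L, 9L))
    colnames(ref3) <- colnames(alt3) <- c("s1", "s2")
    ac3 <- makeAC("chr1", 1L, "A", "G", ref3, alt3)
    expect_equal(referenceBiasQc(mkres(), ac3)$p_value, 1)

    ## one class empty: not assessable
    ref4 <- rbind(c(3L, 5L)); alt4 <- rbind(c(0L, 0L))
    colnames(ref4) <- colnames(alt4) <- c("s1", "s2")
    ac4 <- makeAC("chr1", 1L, "A", "G", ref4, alt4)
    expect_false(referenceBiasQc(mkres(), ac4)$assessable)
})

test_that("rejection rate rises with coverage and sample count", {
    ## 3x3 grid of simulator settings; monoallelic rejection rate at
    ## alpha 0.05 should be non-decreasing along both axes (0.02 slack)
    rate <- matrix(NA_real_, 3, 3)
    depths <- c(2, 4, 8); sizes <- c(30, 60, 120)
    for (i in 1:3) for (j in 1:3) {
        sim <- simulateMethylcap(simParams(
            n_samples = sizes[j], n_loci = 100, frac_monoallelic = 1,
            allele_freq = 0.5, depth_mean = depths[i],
            seed = 100 + 10 * i + j))
        res <- twoStageScreen(sim$counts,
                              ScreenConfig(b1 = 200, b2 = 200,
                                           seed = 50 + i + j))
        rate[i, j] <- mean(res$p_final <= 0.05, na.rm = TRUE)
    }
    expect_true(all(diff(rate) >= -0.02))       # over depth, per column
    expect_true(all(t(diff(t(rate))) >= -0.02)) # over samples, per row
})
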