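test_that("SNP tracing keeps catalogued, allele-compatible, mismatched loci", {
    cat <- SnpCatalogue(chrom = c("chr1", "chr1", "chr2"),
                        pos = c(100L, 200L, 300L),
                        alleles = list(c("A", "G"), c("C", "T"),
                                       c("A", "G", "T")))
    ac <- makeAC(chrom = c("chr1", "chr1", "chr1", "chr2"),
                 pos = c(100L, 200L, 250L, 300L),
                 ref_allele = c("A", "C", "A", "A"),
                 alt_allele = c("G", "T", "G", "C"),
                 ref = matrix(5L, 4, 2), alt = matrix(1L, 4, 2))
    out <- traceSnps(ac, cat)
    ## chr1:250 not in catalogue; chr2:300 observed alt C not allowed
    expect_identical(start(snpLoci(out)), c(100L, 200L))

    ## a catalogued locus with zero alt reads everywhere is dropped
    ac2 <- makeAC("chr1", 100L, "A", "G",
                  ref = matrix(c(5L, 9L), 1), alt = matrix(c(0L, 0L), 1))
    expect_identical(nrow(traceSnps(ac2, cat)), 0L)
})

test_that("tracing agrees with a brute-force rule scan on a random fixture", {
    set.seed(42)
    n <- 10L
    chrom <- "chr1"; pos <- seq_len(n) * 10L
    in_cat <- rep(c(TRUE, FALSE), length.out = n)
    refA <- sample(.nucs <- c("A", "C", "G", "T"), n, replace = TRUE)
    altA <- vapply(refA, function(r) sample(setdiff(.nucs, r), 1), "")
    cat_alleles <- lapply(seq_len(n), function(i) {
        if (runif(1) < 0.3) c(refA[i], sample(setdiff(.nucs, c(refA[i], altA[i])), 1))
        else c(refA[i], altA[i])
    })
    cat <- SnpCatalogue(rep(chrom, sum(in_cat)), pos[in_cat],
                        cat_alleles[in_cat])
    ref <- matrix(rpois(3 * n, 5), n); alt <- matrix(rpois(3 * n, 1), n)
    colnames(ref) <- colnames(alt) <- c("s1", "s2", "s3")
    ac <- makeAC(rep(chrom, n), pos, refA, altA, ref, alt)
    out <- traceSnps(ac, cat)
    expected <- vapply(seq_len(n), function(i) {
        in_cat[i] && all(c(refA[i], altA[i]) %in% cat_alleles[[i]]) &&
            sum(alt[i, ]) > 0
    }, logical(1))
    expect_identical(start(snpLoci(out)), pos[expected])
})

test_that("genotype calls follow the detection rule", {
    ac <- makeAC(rep("chr1", 3), c(1L, 2L, 3L), rep("A", 3), rep("G", 3),
                 ref = matrix(c(7L, 3L, 0L), 3),
                 alt = matrix(c(0L, 1L, 0L), 3))
    g <- callGenotypes(ac)
    expect_identical(unname(g[, 1]), c("hom_ref", "het", "missing"))
})

test_that("allele frequencies come from genotype counts", {
    g <- matrix(c(rep("hom_ref", 25), rep("het", 50), rep("hom_alt", 25)),
                nrow = 1)
    expect_equal(estimateAlleleFrequencies(g), 0.5)
    expect_equal(estimateAlleleFrequencies(matrix(rep("hom_ref", 100), 1)), 1)
    g3 <- matrix(c(rep("hom_ref", 30), rep("het", 40), rep("hom_alt", 10),
                   rep("missing", 5)), nrow = 1)
    expect_equal(estimateAlleleFrequencies(g3), 100 / 160)
    expect_true(is.na(estimateAlleleFrequencies(matrix("missing", 1, 3))))
})

test_that("frequency estimates recover the truth at HWE with high coverage", {
    sim <- simulateMethylcap(simParams(n_samples = 200, n_loci = 200,
                                       meth_prob = 1, depth_mean = 30,
                                       epsilon = 0, seed = 11))
    p_hat <- estimateAlleleFrequencies(callGenotypes(sim$counts))
    n2 <- 2 * ncol(sim$counts)
    se <- sqrt(p_hat * (1 - p_hat) / n2)
    covered <- abs(p_hat - sim$truth$loci$p) <= 1.96 * se
    expect_gte(mean(covered), 0.9)
})

test_that("locus filter applies MAF and chromosome-class coverage rules", {
    ## autosomal locus at coverage 349 (MAF fine) is dropped; 350 retained
    mk <- function(chrom, n_rr, n_het, n_aa, cov_each, sex = NULL) {
        n <- n_rr + n_het + n_aa
        ref <- matrix(0L, 1, n); alt <- matrix(0L, 1, n)
        ref[1, seq_len(n_rr)] <- cov_each
        if (n_het) {
            i <- n_rr + seq_len(n_het)
            ref[1, i] <- cov_each %/% 2L
            alt[1, i] <- cov_each - cov_each %/% 2L
        }
        if (n_aa) alt[1, n_rr + n_het + seq_len(n_aa)] <- cov_each
        colnames(ref) <- colnames(alt) <- sprintf("s%d", seq_len(n))
        makeAC(chrom, 1000L, "A", "G", ref, alt, sex = sex)
    }
    low <- mk("chr5", 10, 20, 10, 8L)    # coverage 320 < 350
    expect_identical(nrow(filterLoci(low)), 0L)
    ok <- mk("chr5", 10, 20, 10, 9L)     # coverage 360, MAF 0.5
    expect_identical(nrow(filterLoci(ok)), 1L)

    ## MAF 0.95 at ample coverage is dropped
    skewed <- mk("chr5", 18, 2, 0, 20L)  # p = 38/40 = 0.95
    expect_identical(nrow(filterLoci(skewed)), 0L)

    ## X locus: female-only coverage 250 suffices at the X threshold
    sexes <- c(rep("female", 25), rep("male", 5))
    xac <- mk("chrX", 10, 10, 10, 10L, sex = sexes)  # females cover 250
    expect_identical(nrow(filterLoci(xac)), 1L)
    expect_identical(nrow(filterLoci(xac, min_cov_x = 251)), 0L)

    ## X loci without any female samples is a configuration error
    xbad <- mk("chrX", 10, 10, 10, 10L, sex = rep("unknown", 30))
    expect_error(filterLoci(xbad), "sex")
})

test_that("filter agrees with a row-scan oracle and is idempotent", {
    set.seed(7)
    for (rep in 1:5) {
        n <- 5L; ns <- 5L
        ref <- matrix(rpois(n * ns, 30), n)
        alt <- matrix(rpois(n * ns, 10) * rbinom(n * ns, 1, 0.6), n)
        colnames(ref) <- colnames(alt) <- sprintf("s%d", 1:ns)
        ac <- makeAC(c("chr1", "chr2", "chrX", "chr3", "chrX"),
                     1:5 * 10L, rep("A", n), rep("G", n), ref, alt,
                     sex = c("female", "female", "male", "female",
                             "unknown"))
        keep <- bruteFilterKeep(ac, 0.9, 100, 60)
        got <- filterLoci(ac, 0.9, 100, 60)
        expect_identical(start(snpLoci(got)), (1:5 * 10L)[keep])
        again <- filterLoci(got, 0.9, 100, 60)
        expect_identical(unname(refCounts(again)), unname(refCounts(got)))
    }
})

test_that("Bayesian correction removes error-like minority reads only", {
    ## posterior oracle: evaluate the three hypotheses directly
    post <- function(r, a, p, eps = 0.0025) {
        n <- r + a
        c(het = 2 * p * (1 - p) * dbinom(r, n, 0.5),
          hom_ref = p^2 * dbinom(a, n, eps),
          hom_alt = (1 - p)^2 * dbinom(r, n, eps))
    }
    ## balanced profile: heterozygote wins by an astronomic margin
    pb <- post(50, 50, 0.5)
    expect_gt(pb["het"], 1e20 * max(pb["hom_ref"], pb["hom_alt"]))
    ## 200:1 profile: hom_ref wins
    ps <- post(200, 1, 0.5)
    expect_gt(ps["hom_ref"], ps["het"])

    ## build a table with p_hat = 0.5: the het caller sees (2*1+1)/(2*3)
    ac <- makeAC(rep("chr1", 2), c(1L, 2L), c("A", "A"), c("G", "G"),
                 ref = rbind(c(50L, 5L, 0L), c(200L, 5L, 0L)),
                 alt = rbind(c(50L, 0L, 5L), c(1L, 0L, 5L)))
    out <- correctSequencingErrors(ac, epsilon = 0.0025, rounds = 1L)
    expect_identical(unname(refCounts(out)[1, 1]), 50L)   # balanced kept
    expect_identical(unname(altCounts(out)[1, 1]), 50L)
    expect_identical(unname(altCounts(out)[2, 1]), 0L)    # minority deleted
    expect_identical(unname(refCounts(out)[2, 1]), 200L)

    ## pure homozygote profiles are fixed points
    expect_identical(unname(refCounts(out)[1, 2]), 5L)
    expect_identical(unname(altCounts(out)[1, 3]), 5L)
})

test_that("correction never increases counts nor invents alleles", {
    sim <- simulateMethylcap(simParams(n_samples = 40, n_loci = 30,
                                       frac_monoallelic = 0.3, seed = 13))
    cc <- correctSequencingErrors(sim$counts)
    expect_true(all(refCounts(cc) <= refCounts(sim$counts)))
    expect_true(all(altCounts(cc) <= altCounts(sim$counts)))
    expect_true(all(snpCoverage(cc) <= snpCoverage(sim$counts)))

    ## with epsilon = 0 a mixed profile can only be resolved towards het:
    ## the error likelihood of any minority read is exactly zero
    cc0 <- correctSequencingErrors(sim$counts, epsilon = 0)
    both <- refCounts(sim$counts) > 0 & altCounts(sim$counts) > 0
    expect_identical(refCounts(cc0)[both], refCounts(sim$counts)[both])
    expect_identical(altCounts(cc0)[both], altCounts(sim$counts)[both])
})
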