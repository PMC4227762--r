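## Synthetic-data generator: reproduces the statistical structure the screen
## assumes (HWE genotypes, methylation-dependent capture, per-sample coverage
## variation, per-read sequencing errors) with ground truth attached.

#' Simulation parameters
#'
#' Bundles the generator settings with validation.  Defaults describe a
#' desk-scale enrichment-sequencing cohort: 300 samples, 500 SNP loci,
#' allele frequencies uniform on \[0.1, 0.9\] (the post-MAF-filter regime), a
#' 0.8 per-sample probability that a locus is methylated at all (enrichment
#' dropout: unmethylated samples yield no reads), Poisson read depth with
#' mean 10 per methylated allele copy, and a 0.25% per-read error rate.
#'
#' @param n_samples,n_loci cohort dimensions.
#' @param frac_monoallelic fraction of loci carrying stable monoallelic
#'   methylation.
#' @param allele_freq single fixed reference-allele frequency, or a
#'   length-2 vector giving the bounds of a uniform law.
#' @param meth_prob per-sample probability that a locus is methylated at all.
#' @param depth_mean mean read depth per methylated allele copy.
#' @param depth_dispersion negative-binomial dispersion (variance
#'   `mu + dispersion * mu^2`); 0 gives Poisson depths.
#' @param epsilon per-read probability of being miscalled as the other
#'   allele.
#' @param x_fraction fraction of loci placed on chromosome X.
#' @param female_fraction fraction of female samples.
#' @param seed integer RNG seed.
#' @return A validated parameter list of class `SimParams`.
#' @export
simParams <- function(n_samples = 300, n_loci = 500, frac_monoallelic = 0,
                      allele_freq = c(0.1, 0.9), meth_prob = 0.8,
                      depth_mean = 10, depth_dispersion = 0,
                      epsilon = 0.0025, x_fraction = 0,
                      female_fraction = 0.64, seed = 1L) {
    stopifnot(n_samples >= 1, n_loci >= 1,
              frac_monoallelic >= 0, frac_monoallelic <= 1,
              all(allele_freq > 0), all(allele_freq < 1),
              length(allele_freq) %in% 1:2,
              meth_prob > 0, meth_prob <= 1,
              depth_mean > 0, depth_dispersion >= 0,
              epsilon >= 0, epsilon < 0.5,
              x_fraction >= 0, x_fraction <= 1,
              female_fraction >= 0, female_fraction <= 1)
    structure(list(n_samples = n_samples, n_loci = n_loci,
                   frac_monoallelic = frac_monoallelic,
                   allele_freq = allele_freq, meth_prob = meth_prob,
                   depth_mean = depth_mean,
                   depth_dispersion = depth_dispersion, epsilon = epsilon,
                   x_fraction = x_fraction,
                   female_fraction = female_fraction,
                   seed = as.integer(seed)),
              class = "SimParams")
}

.rdepth <- function(n, copies, mu, dispersion) {
    ## total reads over `copies` methylated allele copies; sums of Poissons /
    ## negative binomials stay in the family
    out <- integer(length(copies))
    pos <- copies > 0
    if (!any(pos)) return(out)
    if (dispersion == 0) {
        out[pos] <- stats::rpois(sum(pos), mu * copies[pos])
    } else {
        out[pos] <- stats::rnbinom(sum(pos), size = copies[pos] / dispersion,
                                   mu = mu * copies[pos])
    }
    out
}

#' Simulate enrichment-sequencing allele counts with ground truth
#'
#' Per locus, a reference-allele frequency is drawn and each sample receives
#' a Hardy-Weinberg genotype `(p^2, 2pq, q^2)`.  With probability
#' `meth_prob` the locus is methylated in a sample; at biallelic loci both
#' allele copies are then methylated, while at monoallelic loci exactly one
#' allele carries the mark — a random but *stable* choice per heterozygote
#' (the imprinting-like pattern the screen is designed to detect; homozygotes
#' have one methylated copy of their only allele).  Every methylated copy
#' emits reads from the depth law; every read is miscalled as the other
#' allele with probability `epsilon`.  Unmethylated samples emit nothing,
#' reproducing enrichment dropout.  Male samples get zero counts at
#' X-chromosome loci.
#'
#' @param params a [simParams()] list.
#' @return List with `counts` (an [AlleleCounts]) and `truth` (list:
#'   per-locus `DataFrame` `loci` with `monoallelic` flag and true `p`;
#'   `genotype` and `meth_allele` character matrices; `sex`).
#' @export
simulateMethylcap <- function(params = simParams()) {
    stopifnot(inherits(params, "SimParams"))
    set.seed(params$seed)
    nL <- params$n_loci; nS <- params$n_samples

    n_x <- round(params$x_fraction * nL)
    chrom <- c(sample(paste0("chr", 1:22), nL - n_x, replace = TRUE),
               rep("chrX", n_x))
    pos <- seq_len(nL) * 1000L
    alleles <- t(vapply(seq_len(nL), function(i) sample(.NUCS, 2),
                        character(2)))
    sex <- ifelse(stats::runif(nS) < params$female_fraction,
                  "female", "male")
    samples <- sprintf("s%03d", seq_len(nS))

    p <- if (length(params$allele_freq) == 1L)
        rep(params$allele_freq, nL)
    else stats::runif(nL, params$allele_freq[1], params$allele_freq[2])
    mono <- stats::runif(nL) < params$frac_monoallelic

    P <- matrix(p, nL, nS)
    u <- matrix(stats::runif(nL * nS), nL, nS)
    G <- (u > P^2) + (u > P^2 + 2 * P * (1 - P))   # 0 RR, 1 het, 2 AA
    M <- matrix(stats::runif(nL * nS) < params$meth_prob, nL, nS)

    ## methylated copies per allele
    mono_m <- matrix(mono, nL, nS)
    side <- matrix(stats::runif(nL * nS) < 0.5, nL, nS)  # het mark on ref?
    copies_ref <- ifelse(mono_m,
                         ifelse(G == 0, 1L, ifelse(G == 1 & side, 1L, 0L)),
                         ifelse(G == 0, 2L, ifelse(G == 1, 1L, 0L)))
    copies_alt <- ifelse(mono_m,
                         ifelse(G == 2, 1L, ifelse(G == 1 & !side, 1L, 0L)),
                         ifelse(G == 2, 2L, ifelse(G == 1, 1L, 0L)))
    copies_ref[!M] <- 0L; copies_alt[!M] <- 0L
    if (n_x > 0) {
        male <- sex == "male"
        copies_ref[chrom == "chrX", male] <- 0L
        copies_alt[chrom == "chrX", male] <- 0L
    }

    reads_ref <- .rdepth(nL * nS, copies_ref, params$depth_mean,
                         params$depth_dispersion)
    reads_alt <- .rdepth(nL * nS, copies_alt, params$depth_mean,
                         params$depth_dispersion)
    obs_ref <- stats::rbinom(nL * nS, reads_ref, 1 - params$epsilon) +
        stats::rbinom(nL * nS, reads_alt, params$epsilon)
    obs_alt <- reads_ref + reads_alt - obs_ref
    ref <- matrix(as.integer(obs_ref), nL, nS,
                  dimnames = list(NULL, samples))
    alt <- matrix(as.integer(obs_alt), nL, nS,
                  dimnames = list(NULL, samples))

    loci <- data.frame(chrom = chrom, pos = pos,
                       snp_id = sprintf("sim%05d", seq_len(nL)),
                       ref = alleles[, 1], alt = alleles[, 2])
    geno <- matrix(c("hom_ref", "het", "hom_alt")[G + 1L], nL, nS,
                   dimnames = list(NULL, samples))
    meth_allele <- matrix("none", nL, nS, dimnames = list(NULL, samples))
    meth_allele[M & copies_ref > 0 & copies_alt > 0] <- "both"
    meth_allele[M & copies_ref > 0 & copies_alt == 0] <- "ref"
    meth_allele[M & copies_ref == 0 & copies_alt > 0] <- "alt"

    truth <- list(loci = DataFrame(loci, monoallelic = mono, p = p),
                  genotype = geno, meth_allele = meth_allele, sex = sex,
                  params = params)
    list(counts = AlleleCounts(loci, ref, alt, sex = sex), truth = truth)
}

#' Simulate per-allele bisulfite methylation calls
#'
#' Emits the validation-side view of the same ground truth: for every
#' (locus, sample), per-allele CpG call totals whose methylated fraction is
#' `f_high` on the methylated allele and `f_low` on the unmethylated allele
#' of monoallelic heterozygotes, and a shared fraction `f_shared` on both
#' alleles elsewhere.  Call depths per allele follow the depth law;
#' zero-depth allele rows are omitted (uncovered downstream).
#'
#' @param truth the `truth` component of [simulateMethylcap()].
#' @param loci_idx indices of truth loci to emit (default all).
#' @param f_high,f_low methylated-call fractions on the methylated /
#'   unmethylated allele of a monoallelic heterozygote.
#' @param f_shared methylated-call fraction at biallelic loci (both alleles)
#'   and for homozygotes.
#' @param depth_mean,depth_dispersion call-depth law per allele; defaults
#'   from the truth's params.
#' @param seed integer seed.
#' @return A methylation-call `data.frame` as from [readMethylationCalls()].
#' @export
simulateWgbsCalls <- function(truth, loci_idx = NULL, f_high = 0.95,
                              f_low = 0.05, f_shared = 0.8,
                              depth_mean = truth$params$depth_mean,
                              depth_dispersion = truth$params$depth_dispersion,
                              seed = truth$params$seed + 1L) {
    set.seed(seed)
    if (is.null(loci_idx)) loci_idx <- seq_len(nrow(truth$loci))
    samples <- colnames(truth$genotype)
    out <- vector("list", length(loci_idx) * length(samples))
    k <- 0L
    for (i in loci_idx) {
        mono <- truth$loci$monoallelic[i]
        for (j in seq_along(samples)) {
            g <- truth$genotype[i, j]
            alleles <- switch(g, het = c("ref", "alt"),
                              hom_ref = "ref", hom_alt = "alt")
            if (mono && g == "het") {
                marked <- truth$meth_allele[i, j]
                if (marked == "none") marked <- sample(c("ref", "alt"), 1)
                f <- ifelse(alleles == marked, f_high, f_low)
            } else {
                f <- rep(f_shared, length(alleles))
            }
            depth <- .rdepth(length(alleles), rep(1L, length(alleles)),
                             depth_mean, depth_dispersion)
            meth <- stats::rbinom(length(alleles), depth, f)
            keep <- depth > 0
            if (!any(keep)) next
            k <- k + 1L
            out[[k]] <- data.frame(
                chrom = truth$loci$chrom[i], pos = truth$loci$pos[i],
                sample_id = samples[j], allele = alleles[keep],
                meth = meth[keep], unmeth = depth[keep] - meth[keep])
        }
    }
    do.call(rbind, out[seq_len(k)])
}

#' Simulate allele-specific-expression site counts
#'
#' Generates per-site RNA-seq allele counts for a set of genes in one or
#' more tissues.  ASE genes express the reference allele with fraction
#' `effect`; biallelically expressed genes with fraction 0.5.  Site depths
#' follow the depth law.
#'
#' @param n_genes,sites_per_gene,n_tissues layout of the simulated table.
#' @param frac_ase fraction of genes with allele-specific expression.
#' @param effect allelic fraction of the reference allele in ASE genes.
#' @param depth_mean,depth_dispersion per-site depth law.
#' @param seed integer seed.
#' @return List with `sites` (a `data.frame` as from [readAseCounts()]) and
#'   `truth` (`data.frame` of `gene_id`, `ase`).
#' @export
simulateAseCounts <- function(n_genes = 50, sites_per_gene = 3,
                              n_tissues = 1, frac_ase = 0.2, effect = 0.9,
                              depth_mean = 50, depth_dispersion = 0,
                              seed = 1L) {
    set.seed(seed)
    genes <- sprintf("g%04d", seq_len(n_genes))
    ase <- stats::runif(n_genes) < frac_ase
    n_sites <- n_genes * sites_per_gene * n_tissues
    gene_idx <- rep(rep(seq_len(n_genes), each = sites_per_gene), n_tissues)
    tissue <- rep(sprintf("t%02d", seq_len(n_tissues)),
                  each = n_genes * sites_per_gene)
    depth <- .rdepth(n_sites, rep(1L, n_sites), depth_mean,
                     depth_dispersion)
    frac <- ifelse(ase[gene_idx], effect, 0.5)
    ref_count <- stats::rbinom(n_sites, depth, frac)
    sites <- data.frame(
        chrom = "chr1",
        pos = seq_len(n_sites) * 100L,
        tissue = tissue,
        ref_count = ref_count, alt_count = depth - ref_count)
    sites$gene_ids <- as.list(genes[gene_idx])
    list(sites = sites,
         truth = data.frame(gene_id = genes, ase = ase))
}
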