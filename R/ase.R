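## Allele-specific expression validation from RNA-seq allele counts:
## per-site exact binomial tests, per-tissue FDR control and the
## two-significant-sites gene rule.

#' Exact binomial test for allelic imbalance at one site
#'
#' Two-sided exact binomial P-value under the null that both alleles are
#' equally expressed (success probability 1/2), using the minimum-likelihood
#' convention: the sum of the probabilities of all outcomes no more probable
#' than the observed one (this is `stats::binom.test`'s two-sided rule).
#' Sites with total depth below `min_depth` are not tested.
#'
#' @param ref_count,alt_count high-quality reference / alternative base
#'   counts (vectorised).
#' @param min_depth minimum raw read depth for a site to be testable.
#' @return Numeric vector of P-values, `NA` where the depth filter excludes
#'   the site.
#' @export
siteBinomialTest <- function(ref_count, alt_count, min_depth = 10) {
    n <- ref_count + alt_count
    mapply(function(r, tot) {
        if (tot < min_depth) return(NA_real_)
        stats::binom.test(r, tot, p = 0.5)$p.value
    }, ref_count, n)
}

#' Per-site ASE tests over an ASE count table
#'
#' @param sites ASE `data.frame` from [readAseCounts()].
#' @inheritParams siteBinomialTest
#' @return The input with added columns `depth`, `tested`, `reason`
#'   (`"low_depth"` for excluded sites) and `p`.
#' @export
aseSiteTests <- function(sites, min_depth = 10) {
    sites$depth <- sites$ref_count + sites$alt_count
    sites$p <- siteBinomialTest(sites$ref_count, sites$alt_count, min_depth)
    sites$tested <- !is.na(sites$p)
    sites$reason <- ifelse(sites$tested, NA_character_, "low_depth")
    sites
}

#' Gene-level ASE classification
#'
#' Benjamini-Hochberg control at `fdr_q` is applied per tissue across that
#' tissue's tested sites; a gene in a tissue is called `ASE` when at least
#' `min_sites` of its sites are significant, `BE` (biallelically expressed)
#' when at least `min_sites` sites were tested but fewer than `min_sites`
#' are significant, and `not_assessable` otherwise.  Sites annotated to
#' several genes count for each of them; intergenic sites count for none.
#'
#' @param site_results output of [aseSiteTests()].
#' @param fdr_q per-tissue FDR level.
#' @param min_sites minimum significant (and tested) site count.
#' @return A `data.frame` with one row per (gene, tissue): `gene_id`,
#'   `tissue`, `n_sites_tested`, `n_sites_significant`, `classification`.
#' @export
callGeneAse <- function(site_results, fdr_q = 0.01, min_sites = 2) {
    site_results$bh_significant <- FALSE
    for (ti in unique(site_results$tissue)) {
        sel <- site_results$tissue == ti & site_results$tested
        if (!any(sel)) next
        site_results$bh_significant[sel] <-
            stats::p.adjust(site_results$p[sel], method = "BH") <= fdr_q
    }
    tested <- site_results[site_results$tested, , drop = FALSE]
    long <- data.frame(
        gene_id = unlist(tested$gene_ids, use.names = FALSE),
        tissue = rep(tested$tissue, lengths(tested$gene_ids)),
        sig = rep(tested$bh_significant, lengths(tested$gene_ids)))
    if (!nrow(long))
        return(data.frame(gene_id = character(), tissue = character(),
                          n_sites_tested = integer(),
                          n_sites_significant = integer(),
                          classification = character()))
    agg <- stats::aggregate(sig ~ gene_id + tissue, long,
                            function(z) c(n = length(z), k = sum(z)))
    out <- data.frame(gene_id = agg$gene_id, tissue = agg$tissue,
                      n_sites_tested = agg$sig[, "n"],
                      n_sites_significant = agg$sig[, "k"])
    out$classification <- ifelse(
        out$n_sites_significant >= min_sites, "ASE",
        ifelse(out$n_sites_tested >= min_sites, "BE", "not_assessable"))
    out
}

#' Summarise gene-level ASE calls across tissues
#'
#' Collapses per-(gene, tissue) expression-type calls to per-gene categories:
#' a gene shows ASE when at least one tissue is called `ASE`; it is *mixed*
#' when it additionally shows `BE` in another tissue, and *exclusively ASE*
#' when no tissue shows `BE`.  `not_assessable` rows are ignored.
#'
#' @param calls a `data.frame` with columns `gene_id` and `classification`
#'   (values `ASE` / `BE`, one row per gene-tissue call), e.g. the output of
#'   [callGeneAse()].
#' @return List of counts: `n_genes_assessable`, `n_ase`, `n_mixed`,
#'   `n_exclusive_ase`, `n_be_only`.
#' @export
summarizeAseGeneTypes <- function(calls) {
    calls <- calls[calls$classification %in% c("ASE", "BE"), , drop = FALSE]
    has_ase <- tapply(calls$classification == "ASE", calls$gene_id, any)
    has_be <- tapply(calls$classification == "BE", calls$gene_id, any)
    list(n_genes_assessable = length(has_ase),
         n_ase = sum(has_ase),
         n_mixed = sum(has_ase & has_be),
         n_exclusive_ase = sum(has_ase & !has_be),
         n_be_only = sum(!has_ase & has_be))
}
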