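## Orchestration: a single entry point chaining trace -> filter -> correct ->
## screen -> FDR (-> enrichment), with a reproducible run manifest.

#' Pipeline run configuration
#'
#' Collects every stage's tunable with the published defaults: MAF cut-off
#' 0.9, total-coverage thresholds 350 (autosomes) / 250 (chromosome X),
#' sequencing-error rate 0.0025 with 2 correction rounds, two-stage screen
#' at 1000 / 1,000,000 iterations with a 0.005 gate, FDR 0.1, 2000
#' bisulfite permutations, ASE depth >= 10 (base quality >= 13 assumed
#' upstream), ASE FDR 0.01 with >= 2 significant sites per gene.
#' Serialisable to/from YAML.
#'
#' @param counts,sample_sheet,catalogue,annotation input file paths (the
#'   latter two optional depending on the stages run).
#' @param out_dir output directory for stage outputs and the manifest.
#' @param maf_max,min_cov_autosome,min_cov_x filter thresholds.
#' @param epsilon,rounds error-correction settings.
#' @param b1,stage1_alpha,b2,fdr_q screen settings.
#' @param enrichment_draws null samplings of the enrichment test.
#' @param seed integer seed for all stochastic stages.
#' @return A named list of class `RunConfig`.
#' @export
runConfig <- function(counts = NULL, sample_sheet = NULL, catalogue = NULL,
                      annotation = NULL, out_dir = ".",
                      maf_max = 0.90, min_cov_autosome = 350,
                      min_cov_x = 250, epsilon = 0.0025, rounds = 2L,
                      b1 = 1000, stage1_alpha = 0.005, b2 = 1e6,
                      fdr_q = 0.1, enrichment_draws = 1000, seed = 1L) {
    structure(list(counts = counts, sample_sheet = sample_sheet,
                   catalogue = catalogue, annotation = annotation,
                   out_dir = out_dir, maf_max = maf_max,
                   min_cov_autosome = min_cov_autosome,
                   min_cov_x = min_cov_x, epsilon = epsilon,
                   rounds = as.integer(rounds), b1 = b1,
                   stage1_alpha = stage1_alpha, b2 = b2, fdr_q = fdr_q,
                   enrichment_draws = enrichment_draws,
                   seed = as.integer(seed)),
              class = "RunConfig")
}

#' @rdname runConfig
#' @param path YAML file with `runConfig()` fields.
#' @export
readRunConfig <- function(path) {
    vals <- yaml::read_yaml(path)
    known <- names(formals(runConfig))
    unknown <- setdiff(names(vals), known)
    if (length(unknown))
        stop("unknown config fields: ", paste(unknown, collapse = ", "),
             call. = FALSE)
    do.call(runConfig, vals)
}

#' Write screen results as TSV
#'
#' @param results `DataFrame` from [twoStageScreen()].
#' @param path output file.
#' @export
writeScreenResults <- function(results, path) {
    utils::write.table(as.data.frame(results), path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    invisible(NULL)
}

#' Write a genotype matrix as TSV
#'
#' @param x the [AlleleCounts] the genotypes belong to.
#' @param genotypes matrix from [callGenotypes()].
#' @param path output file.
#' @export
writeGenotypes <- function(x, genotypes, path) {
    df <- data.frame(chrom = as.character(seqnames(x)), pos = start(x),
                     genotypes, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(NULL)
}

#' Run the full detection pipeline
#'
#' Executes SNP tracing, MAF/coverage filtering, iterative error correction
#' (with the filter re-applied afterwards, since corrected genotype
#' frequencies can cross the MAF cut-off), the two-stage heterozygote-deficit
#' screen with BH significance, and — when annotation is supplied — the
#' chromosome-matched enrichment test.  Stage outputs are persisted under
#' `out_dir` (`corrected_counts.tsv`, `genotypes.tsv`, `screen_results.tsv`,
#' optional `enrichment.tsv`) together with a YAML `manifest.yaml` recording
#' the configuration, seed, package version and per-stage record counts.
#'
#' @param config a [runConfig()] list (or path handled by
#'   [readRunConfig()]).
#' @return Invisibly, a list with the stage objects (`counts`, `screen`,
#'   `enrichment`, `qc`, `manifest`).
#' @export
runPipeline <- function(config) {
    if (is.character(config)) config <- readRunConfig(config)
    stopifnot(inherits(config, "RunConfig"))
    for (f in c("counts", "sample_sheet", "catalogue")) {
        if (is.null(config[[f]]) || !file.exists(config[[f]]))
            stop(sprintf("configuration error: input '%s' missing", f),
                 call. = FALSE)
    }
    if (!dir.exists(config$out_dir))
        dir.create(config$out_dir, recursive = TRUE)
    stage <- function(name, expr) {
        tryCatch(expr, error = function(e)
            stop(sprintf("pipeline stage '%s' failed: %s", name,
                         conditionMessage(e)), call. = FALSE))
    }
    ac <- stage("read", readAlleleCounts(config$counts, config$sample_sheet))
    cat0 <- stage("read", readSnpCatalogue(config$catalogue))
    n_input <- nrow(ac)
    traced <- stage("trace", traceSnps(ac, cat0))
    filtered <- stage("filter",
                      filterLoci(traced, config$maf_max,
                                 config$min_cov_autosome, config$min_cov_x))
    corrected <- stage("correct",
                       correctSequencingErrors(filtered, config$epsilon,
                                               config$rounds))
    corrected <- stage("refilter",
                       filterLoci(corrected, config$maf_max,
                                  config$min_cov_autosome, config$min_cov_x))
    cfg <- ScreenConfig(b1 = config$b1, stage1Alpha = config$stage1_alpha,
                        b2 = config$b2, fdrQ = config$fdr_q,
                        seed = config$seed)
    res <- stage("screen", twoStageScreen(corrected, cfg))
    qc <- referenceBiasQc(res, corrected)

    enr <- NULL
    if (!is.null(config$annotation)) {
        ann <- stage("annotation", readAnnotationIntervals(config$annotation))
        sig <- rowRanges(corrected)[res$significant]
        if (length(sig))
            enr <- stage("enrich",
                         enrichmentTest(sig, rowRanges(corrected), ann,
                                        n_draws = config$enrichment_draws,
                                        seed = config$seed))
    }

    writeAlleleCounts(corrected,
                      file.path(config$out_dir, "corrected_counts.tsv"))
    writeGenotypes(corrected, callGenotypes(corrected),
                   file.path(config$out_dir, "genotypes.tsv"))
    writeScreenResults(res, file.path(config$out_dir, "screen_results.tsv"))
    if (!is.null(enr))
        utils::write.table(as.data.frame(enr),
                           file.path(config$out_dir, "enrichment.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)

    manifest <- list(
        package_version = as.character(utils::packageVersion("MAMscreen")),
        config = unclass(config),
        stages = list(
            input_loci = n_input,
            traced = nrow(traced), trace_dropped = n_input - nrow(traced),
            filtered = nrow(filtered),
            filter_dropped = nrow(traced) - nrow(filtered),
            corrected = nrow(corrected),
            refilter_dropped = nrow(filtered) - nrow(corrected),
            tested = sum(!is.na(res$p_final)),
            stage2_entered = sum(!is.na(res$p_stage2)),
            significant = sum(res$significant),
            bh_critical = S4Vectors::metadata(res)$bh_critical),
        qc = list(reference_bias_p = qc$p_value,
                  assessable = qc$assessable))
    yaml::write_yaml(manifest, file.path(config$out_dir, "manifest.yaml"))
    invisible(list(counts = corrected, screen = res, enrichment = enr,
                   qc = qc, manifest = manifest))
}
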