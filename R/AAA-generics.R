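#' @rdname AlleleCounts-class
#' @export
setGeneric("refCounts", function(x, ...) standardGeneric("refCounts"))

#' @rdname AlleleCounts-class
#' @export
setGeneric("altCounts", function(x, ...) standardGeneric("altCounts"))

#' @rdname AlleleCounts-class
#' @export
setGeneric("snpCoverage", function(x, ...) standardGeneric("snpCoverage"))

#' @rdname AlleleCounts-class
#' @export
setGeneric("sampleSex", function(x, ...) standardGeneric("sampleSex"))

#' @rdname AlleleCounts-class
#' @export
setGeneric("snpLoci", function(x, ...) standardGeneric("snpLoci"))

#' @rdname SnpCatalogue-class
#' @export
setGeneric("catalogueAlleles", function(x, chrom, pos) {
    standardGeneric("catalogueAlleles")
})
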