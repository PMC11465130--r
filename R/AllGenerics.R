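#' @rdname ElementCatalog-accessors
#' @export
setGeneric("cgis", function(x) standardGeneric("cgis"))
#' @rdname ElementCatalog-accessors
#' @export
setGeneric("enhancers", function(x) standardGeneric("enhancers"))
#' @rdname ElementCatalog-accessors
#' @export
setGeneric("promoters2", function(x) standardGeneric("promoters2"))
#' @rdname ElementCatalog-accessors
#' @export
setGeneric("geneAnnotation", function(x) standardGeneric("geneAnnotation"))
#' @rdname ElementCatalog-accessors
#' @export
setGeneric("cgiClass", function(x) standardGeneric("cgiClass"))
#' @rdname ElementCatalog-accessors
#' @export
setGeneric("orphanCgis", function(x) standardGeneric("orphanCgis"))
#' @rdname ElementCatalog-accessors
#' @export
setGeneric("compositionTable", function(x) standardGeneric("compositionTable"))

#' @rdname RegionMethylation-accessors
#' @export
setGeneric("regionBeta", function(x) standardGeneric("regionBeta"))
#' @rdname RegionMethylation-accessors
#' @export
setGeneric("nProbes", function(x) standardGeneric("nProbes"))
#' @rdname RegionMethylation-accessors
#' @export
setGeneric("betaStates", function(x, ...) standardGeneric("betaStates"))

#' Accessors for ElementCatalog
#'
#' `cgis()`, `enhancers()`, `promoters2()` and `geneAnnotation()` return the
#' stored interval sets (`promoters2` is named to avoid masking
#' `GenomicRanges::promoters`). `cgiClass()` returns the primary class of
#' each CGI window, `orphanCgis()` the orphan subset, and
#' `compositionTable()` a class-composition summary including the secondary
#' genic annotation.
#'
#' @param x an `ElementCatalog`.
#' @name ElementCatalog-accessors
NULL

#' @rdname ElementCatalog-accessors
setMethod("cgis", "ElementCatalog", function(x) x@cgis)
#' @rdname ElementCatalog-accessors
setMethod("enhancers", "ElementCatalog", function(x) x@enhancers)
#' @rdname ElementCatalog-accessors
setMethod("promoters2", "ElementCatalog", function(x) x@promoters)
#' @rdname ElementCatalog-accessors
setMethod("geneAnnotation", "ElementCatalog", function(x) x@genes)
#' @rdname ElementCatalog-accessors
setMethod("cgiClass", "ElementCatalog", function(x) {
  stats::setNames(as.character(S4Vectors::mcols(x@cgis)$cgiClass),
                  names(x@cgis))
})
#' @rdname ElementCatalog-accessors
setMethod("orphanCgis", "ElementCatalog", function(x) {
  x@cgis[S4Vectors::mcols(x@cgis)$cgiClass == "orphan"]
})
#' @rdname ElementCatalog-accessors
setMethod("compositionTable", "ElementCatalog", function(x) {
  mc <- S4Vectors::mcols(x@cgis)
  cl <- factor(mc$cgiClass,
               levels = c("orphan", "promoter_overlap", "enhancer_overlap"))
  data.frame(class = levels(cl),
             n = as.integer(table(cl)),
             n_genic = as.integer(tapply(mc$genic, cl, sum, default = 0L)),
             row.names = NULL)
})

#' Accessors for RegionMethylation
#'
#' `regionBeta()` returns the region-by-sample mean beta matrix,
#' `nProbes()` the per-region probe counts, and `betaStates()` the
#' hypo/hemi/hyper state of every entry (see [classifyBetaState()]).
#'
#' @param x a `RegionMethylation`.
#' @param ... passed to [classifyBetaState()] (thresholds).
#' @name RegionMethylation-accessors
NULL

#' @rdname RegionMethylation-accessors
setMethod("regionBeta", "RegionMethylation", function(x)
  SummarizedExperiment::assay(x, "beta"))
#' @rdname RegionMethylation-accessors
setMethod("nProbes", "RegionMethylation", function(x)
  stats::setNames(SummarizedExperiment::rowData(x)$nProbes, rownames(x)))
#' @rdname RegionMethylation-accessors
setMethod("betaStates", "RegionMethylation", function(x, ...)
  classifyBetaState(SummarizedExperiment::assay(x, "beta"), ...))
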