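#' @import methods
#' @importClassesFrom GenomicRanges GRanges
#' @importFrom GenomicRanges GRanges seqnames strand findOverlaps countOverlaps reduce sort start end width
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors mcols mcols<- queryHits subjectHits DataFrame metadata metadata<-
NULL

setClassUnion("GRangesOrNULL", c("GRanges", "NULL"))

#' ElementCatalog: classified regulatory elements
#'
#' Holds the CGI windows (after 500 bp expansion and merging) together with
#' the promoters, enhancers and genes used to classify them. Each CGI window
#' carries exactly one primary class: `orphan` (overlapping neither a
#' promoter nor an enhancer), `promoter_overlap`, or `enhancer_overlap`.
#' Overlap with a gene body is recorded as a secondary logical annotation and
#' does not disqualify a window from orphan status.
#'
#' @slot cgis `GRanges` of CGI windows; metadata columns `cgiClass`
#'   (factor) and `genic` (logical).
#' @slot enhancers,promoters `GRanges` of the classifying elements.
#' @slot genes `GRanges` of TSS anchors (width 1, stranded) or gene bodies;
#'   may be empty.
#' @export
setClass("ElementCatalog",
  slots = c(cgis = "GRanges", enhancers = "GRanges",
            promoters = "GRanges", genes = "GRangesOrNULL"))

setValidity("ElementCatalog", function(object) {
  mc <- S4Vectors::mcols(object@cgis)
  if (length(object@cgis) > 0) {
    if (!all(c("cgiClass", "genic") %in% colnames(mc)))
      return("cgis must carry 'cgiClass' and 'genic' metadata columns")
    cl <- mc$cgiClass
    ok <- c("orphan", "promoter_overlap", "enhancer_overlap")
    if (!all(as.character(cl) %in% ok))
      return("cgiClass values must be orphan/promoter_overlap/enhancer_overlap")
    if (anyNA(cl)) return("every CGI window must have exactly one class")
  }
  TRUE
})

#' RegionMethylation: region-by-sample mean beta values
#'
#' A `RangedSummarizedExperiment` with a single assay `"beta"` holding
#' per-region, per-sample mean methylation in \[0, 1\], and a `rowData`
#' column `nProbes` giving the number of probes aggregated into each region.
#' Regions with zero probes carry `NA` beta values and are excluded from
#' downstream screening.
#'
#' @export
setClass("RegionMethylation",
  contains = "RangedSummarizedExperiment")

setValidity("RegionMethylation", function(object) {
  if (!"beta" %in% SummarizedExperiment::assayNames(object))
    return("assay 'beta' is required")
  b <- SummarizedExperiment::assay(object, "beta")
  if (any(b < 0 | b > 1, na.rm = TRUE))
    return("beta values must lie in [0, 1]")
  if (!"nProbes" %in% colnames(SummarizedExperiment::rowData(object)))
    return("rowData column 'nProbes' is required")
  TRUE
})

#' ModelSpec: one of the nine triplet regulatory structures
#'
#' A directed acyclic graph over the nodes O (oCGI methylation), E (enhancer
#' methylation) and G (gene expression), together with its joint-probability
#' factorization, dominance label and Markov-equivalence class.
#'
#' @slot id model identifier, e.g. `"oCGI_direct"`.
#' @slot edges two-column character matrix (`from`, `to`) over `O`, `E`, `G`.
#' @slot factorization human-readable factorization string.
#' @slot dominance `"oCGI"`, `"enhancer"` or `"co"`.
#' @slot equivClass Markov-equivalence class label (shared by structures
#'   with identical skeleton and v-structures).
#' @export
setClass("ModelSpec",
  slots = c(id = "character", edges = "matrix",
            factorization = "character", dominance = "character",
            equivClass = "character"))

setValidity("ModelSpec", function(object) {
  e <- object@edges
  if (ncol(e) != 2) return("edges must be a 2-column matrix")
  nodes <- c("O", "E", "G")
  if (nrow(e) > 0 && !all(e %in% nodes))
    return("edge endpoints must be O, E or G")
  if (nrow(e) > 0 && any(e[, 1] == e[, 2])) return("self-loops not allowed")
  # acyclicity on 3 nodes: no pair with edges both ways, no directed 3-cycle
  key <- function(a, b) paste(a, b)
  ek <- key(e[, 1], e[, 2])
  if (any(key(e[, 2], e[, 1]) %in% ek)) return("edges must form a DAG")
  if (all(c(key("O", "E"), key("E", "G"), key("G", "O")) %in% ek) ||
      all(c(key("O", "G"), key("G", "E"), key("E", "O")) %in% ek))
    return("edges must form a DAG")
  if (!object@dominance %in% c("oCGI", "enhancer", "co"))
    return("dominance must be oCGI, enhancer or co")
  TRUE
})

setMethod("show", "ElementCatalog", function(object) {
  cl <- table(S4Vectors::mcols(object@cgis)$cgiClass)
  cat("ElementCatalog with", length(object@cgis), "CGI windows\n")
  cat("  classes:", paste(names(cl), cl, sep = "=", collapse = ", "), "\n")
  cat("  genic overlap:", sum(S4Vectors::mcols(object@cgis)$genic), "\n")
  cat("  promoters:", length(object@promoters),
      " enhancers:", length(object@enhancers), "\n")
})

setMethod("show", "ModelSpec", function(object) {
  ed <- if (nrow(object@edges) == 0) "(no edges)" else
    paste(object@edges[, 1], "->", object@edges[, 2], collapse = ", ")
  cat("ModelSpec", object@id, "\n")
  cat("  ", object@factorization, "\n")
  cat("  edges:", ed, "\n")
  cat("  dominance:", object@dominance,
      " equivalence class:", object@equivClass, "\n")
})
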