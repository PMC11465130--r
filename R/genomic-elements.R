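#' Expand CpG islands to 500 bp windows and merge overlaps
#'
#' Each CGI is replaced by a 500 bp window (plus/minus 250 bp) centered on
#' its midpoint; windows that overlap are merged into their union. For CGIs
#' longer than 500 bp the literal window would truncate the island, so the
#' window is widened to the union of the original span and the centered
#' window (never discarding covered bases) and the result is flagged.
#' Windows whose lower edge would fall below position 0 are clamped at 0 and
#' flagged.
#'
#' The midpoint of an even-length CGI is `floor((start0 + end0) / 2)` in
#' 0-based coordinates.
#'
#' @param cgis `GRanges` of CpG islands.
#' @param flank expansion half-width in bp (default 250, giving 500 bp
#'   windows).
#' @return Sorted, non-overlapping `GRanges` with metadata columns
#'   `nSource` (CGIs merged into the window), `merged`, `clamped` and
#'   `longCgi`. Names are taken from the source CGI when unmerged, else
#'   `merged_<i>`.
#' @examples
#' expandAndMergeCgis(bedRanges("chr1", 1000, 1100))  # chr1:800-1300
#' @export
expandAndMergeCgis <- function(cgis, flank = 250L) {
  if (length(cgis) == 0) {
    out <- GenomicRanges::GRanges()
    S4Vectors::mcols(out) <- S4Vectors::DataFrame(
      nSource = integer(), merged = logical(),
      clamped = logical(), longCgi = logical())
    return(out)
  }
  if (any(GenomicRanges::width(cgis) < 1))
    stop("invalid interval: non-positive length CGI")
  ids <- .elementIds(cgis, "cgi")
  mid0 <- .midpoint0(cgis)
  winStart0 <- mid0 - flank
  winEnd0 <- mid0 + flank
  clamped <- winStart0 < 0
  winStart0[clamped] <- 0L
  longCgi <- GenomicRanges::width(cgis) > 2L * flank
  # never discard bases of a CGI longer than the window: take the union
  start0 <- pmin(winStart0, bedStart(cgis))
  end0 <- pmax(winEnd0, bedEnd(cgis))
  win <- bedRanges(as.character(GenomicRanges::seqnames(cgis)),
                   start0, end0, id = ids)
  red <- GenomicRanges::reduce(GenomicRanges::sort(win), with.revmap = TRUE)
  revmap <- S4Vectors::mcols(red)$revmap
  srt <- GenomicRanges::sort(win)  # revmap indexes the sorted input
  perm <- match(names(srt), ids)
  nSource <- lengths(revmap)
  S4Vectors::mcols(red) <- S4Vectors::DataFrame(
    nSource = nSource,
    merged = nSource > 1L,
    clamped = vapply(revmap, function(i) any(clamped[perm[i]]), logical(1)),
    longCgi = vapply(revmap, function(i) any(longCgi[perm[i]]), logical(1))
  )
  names(red) <- ifelse(nSource == 1L,
                       vapply(revmap, function(i) names(srt)[i[1]],
                              character(1)),
                       sprintf("merged_%d", seq_along(red)))
  red
}

#' Define promoter windows around transcription start sites
#'
#' The promoter is the region from `upstream` bp upstream to `downstream`
#' bp downstream of each TSS, oriented by strand (defaults 1500/500). The
#' TSS is the gene start for `+` genes and the gene end for `-` genes; for
#' width-1 TSS anchors both coincide. Windows extending below position 0
#' are clamped and flagged.
#'
#' @param genes stranded `GRanges` (gene bodies or width-1 TSS anchors)
#'   with a `gene_id` metadata column or names.
#' @param upstream,downstream window extents in bp.
#' @return `GRanges` of promoters with metadata columns `gene_id`, `tss0`
#'   (0-based TSS position) and `clamped`.
#' @examples
#' g <- bedRanges("chr1", 5000, 5001, strand = "+", id = "g1")
#' definePromoters(g)  # chr1:3500-5500
#' @export
definePromoters <- function(genes, upstream = 1500L, downstream = 500L) {
  if (length(genes) == 0) return(GenomicRanges::GRanges())
  str <- as.character(GenomicRanges::strand(genes))
  if (any(str == "*"))
    stop("cannot orient promoter: gene(s) with missing strand")
  ids <- if (!is.null(S4Vectors::mcols(genes)$gene_id))
    as.character(S4Vectors::mcols(genes)$gene_id) else .elementIds(genes, "gene")
  # TSS point t in 0-based coordinates: gene start for '+', gene end for '-';
  # width-1 anchors mark the TSS position directly on either strand
  isPoint <- GenomicRanges::width(genes) == 1L
  tss0 <- ifelse(isPoint | str == "+", bedStart(genes), bedEnd(genes))
  # promoter: '+': [t - upstream, t + downstream); '-': mirror image
  start0 <- ifelse(str == "+", tss0 - upstream, tss0 - downstream)
  end0 <- ifelse(str == "+", tss0 + downstream, tss0 + upstream)
  clamped <- start0 < 0
  start0[clamped] <- 0L
  out <- bedRanges(as.character(GenomicRanges::seqnames(genes)),
                   start0, end0, strand = str)
  S4Vectors::mcols(out) <- S4Vectors::DataFrame(
    gene_id = ids, tss0 = as.integer(tss0), clamped = clamped)
  names(out) <- sprintf("prom_%s_%d", ids, seq_along(out))
  out
}

#' Classify CGI windows into orphan / promoter-overlap / enhancer-overlap
#'
#' A window overlapping any promoter is classed `promoter_overlap`; else a
#' window overlapping any enhancer is `enhancer_overlap`; the remaining
#' windows are orphan CGIs (oCGIs). Overlap is evaluated under the half-open
#' convention, so an exactly abutting pair does not overlap. Overlap with a
#' gene body, when `genes` is supplied, is recorded as the secondary
#' `genic` annotation and never disqualifies a window from orphan status.
#'
#' @param cgiWindows `GRanges` of (expanded, merged) CGI windows.
#' @param promoters,enhancers `GRanges` of classifying elements.
#' @param genes optional `GRanges` of gene bodies for the genic annotation.
#' @return An [ElementCatalog-class].
#' @export
classifyCgis <- function(cgiWindows, promoters, enhancers, genes = NULL) {
  if (length(cgiWindows) > 0) {
    names(cgiWindows) <- .elementIds(cgiWindows, "cgi")
    inProm <- GenomicRanges::countOverlaps(cgiWindows, promoters) > 0
    inEnh <- GenomicRanges::countOverlaps(cgiWindows, enhancers) > 0
    cl <- ifelse(inProm, "promoter_overlap",
                 ifelse(inEnh, "enhancer_overlap", "orphan"))
    genic <- if (!is.null(genes) && length(genes) > 0)
      GenomicRanges::countOverlaps(cgiWindows, genes) > 0
    else rep(FALSE, length(cgiWindows))
    S4Vectors::mcols(cgiWindows)$cgiClass <-
      factor(cl, levels = c("orphan", "promoter_overlap", "enhancer_overlap"))
    S4Vectors::mcols(cgiWindows)$genic <- genic
  }
  methods::new("ElementCatalog", cgis = cgiWindows, enhancers = enhancers,
               promoters = promoters, genes = genes)
}

#' Write the classified-CGI BED and composition summary
#'
#' @param catalog an `ElementCatalog`.
#' @param bedPath output BED path (class in the name column as
#'   `<id>|<class>`); `NULL` to skip.
#' @param summaryPath output TSV path for the composition table; `NULL` to
#'   skip.
#' @return the composition table, invisibly.
#' @export
writeCatalog <- function(catalog, bedPath = NULL, summaryPath = NULL) {
  comp <- compositionTable(catalog)
  if (!is.null(bedPath)) {
    w <- cgis(catalog)
    writeBed(w, bedPath,
             name = paste(names(w), S4Vectors::mcols(w)$cgiClass, sep = "|"))
  }
  if (!is.null(summaryPath))
    utils::write.table(comp, summaryPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(comp)
}
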