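#' Assign elements or genes to topologically associating domains
#'
#' An element belongs to the TAD containing its anchor point: the interval
#' midpoint for regulatory elements (`anchor = "midpoint"`) or the TSS for
#' genes (`anchor = "tss"`, requiring a `tss0` metadata column or width-1
#' ranges). Elements whose anchor falls outside every TAD are left
#' unassigned (and are excluded from pairing). TADs must be non-overlapping
#' within each chromosome.
#'
#' @param elements `GRanges` with names (element ids).
#' @param tads `GRanges` of TADs with names (TAD ids).
#' @param anchor `"midpoint"` or `"tss"`.
#' @return data.frame with columns `id`, `tad` (`NA` if unassigned),
#'   `anchor0` (the 0-based anchor position) and `rule`.
#' @export
assignToTads <- function(elements, tads, anchor = c("midpoint", "tss")) {
  anchor <- match.arg(anchor)
  if (!GenomicRanges::isDisjoint(tads))
    stop("overlapping TADs in input")
  names(tads) <- .elementIds(tads, "tad")
  ids <- .elementIds(elements, "el")
  pos0 <- if (anchor == "midpoint") .midpoint0(elements)
  else if (!is.null(S4Vectors::mcols(elements)$tss0))
    S4Vectors::mcols(elements)$tss0
  else if (all(GenomicRanges::width(elements) == 1L)) bedStart(elements)
  else stop("tss anchor needs width-1 ranges or a 'tss0' metadata column")
  pts <- .pointRanges(as.character(GenomicRanges::seqnames(elements)), pos0)
  # suppress the harmless seqlevel-mismatch warning for chromosomes
  # lacking any TAD (those elements are simply unassigned)
  ov <- suppressWarnings(
    GenomicRanges::findOverlaps(pts, tads, type = "within",
                                select = "first"))
  data.frame(id = ids,
             tad = ifelse(is.na(ov), NA_character_, names(tads)[ov]),
             anchor0 = as.integer(pos0),
             rule = anchor,
             stringsAsFactors = FALSE)
}

#' Enumerate candidate element-gene pairs within shared TADs
#'
#' Forms the Cartesian products (oCGIs x genes) and (enhancers x genes)
#' restricted to pairs sharing a TAD. Each pair is annotated with the bp
#' distance between the element midpoint and the TSS, the number of
#' distinct TSS positions strictly between them (counted over all
#' annotated genes on the chromosome), and an adjacency flag
#' (`n_intervening == 0`).
#'
#' @param catalog an `ElementCatalog`; its orphan CGI windows and
#'   enhancers are paired. Genes must be TSS anchors (see
#'   [readGeneAnnotation()]).
#' @param tads `GRanges` of non-overlapping TADs with names.
#' @return data.frame with columns `element_id`, `element_kind`
#'   (`"oCGI"`/`"enhancer"`), `gene_id`, `tad_id`, `distance`,
#'   `n_intervening_genes`, `adjacent`.
#' @export
enumeratePairs <- function(catalog, tads) {
  genes <- geneAnnotation(catalog)
  if (is.null(genes) || length(genes) == 0)
    stop("catalog carries no gene annotation")
  names(tads) <- .elementIds(tads, "tad")
  oc <- orphanCgis(catalog)
  en <- enhancers(catalog)
  names(en) <- .elementIds(en, "enh")
  names(genes) <- .elementIds(genes, "gene")
  gAssign <- assignToTads(genes, tads, anchor = "tss")
  tssByChrom <- split(gAssign$anchor0,
                      as.character(GenomicRanges::seqnames(genes)))
  tssByChrom <- lapply(tssByChrom, function(v) sort(unique(v)))

  onePairSet <- function(els, kind) {
    if (length(els) == 0) return(NULL)
    eAssign <- assignToTads(els, tads, anchor = "midpoint")
    eChrom <- as.character(GenomicRanges::seqnames(els))
    rows <- list()
    for (tid in unique(stats::na.omit(eAssign$tad))) {
      ei <- which(eAssign$tad == tid)
      gi <- which(gAssign$tad == tid)
      if (length(ei) == 0 || length(gi) == 0) next
      grid <- expand.grid(e = ei, g = gi)
      mid0 <- eAssign$anchor0[grid$e]
      tss0 <- gAssign$anchor0[grid$g]
      lo <- pmin(mid0, tss0); hi <- pmax(mid0, tss0)
      nBetween <- mapply(function(ch, l, h) {
        u <- tssByChrom[[ch]]
        if (is.null(u)) 0L else sum(u > l & u < h)
      }, eChrom[grid$e], lo, hi)
      rows[[tid]] <- data.frame(
        element_id = eAssign$id[grid$e],
        element_kind = kind,
        gene_id = gAssign$id[grid$g],
        tad_id = tid,
        distance = as.integer(hi - lo),
        n_intervening_genes = as.integer(nBetween),
        stringsAsFactors = FALSE)
    }
    if (length(rows) == 0) NULL else do.call(rbind, rows)
  }
  out <- rbind(onePairSet(oc, "oCGI"), onePairSet(en, "enhancer"))
  if (is.null(out))
    out <- data.frame(element_id = character(), element_kind = character(),
                      gene_id = character(), tad_id = character(),
                      distance = integer(), n_intervening_genes = integer(),
                      stringsAsFactors = FALSE)
  out$adjacent <- out$n_intervening_genes == 0L
  rownames(out) <- NULL
  out[order(out$element_kind, out$element_id, out$gene_id), ]
}

#' Summarize the regulatory geometry of candidate pairs
#'
#' Per element kind: the distribution of targets per element, the fraction
#' of adjacent pairs (no intervening TSS), and a distance histogram whose
#' bins single out the long-range regimes above 500 kb and above 1 Mb.
#'
#' @param pairs a pair table from [enumeratePairs()] (optionally filtered
#'   to selected triplets).
#' @return list with `targetsPerElement` (data.frame kind/n_targets/
#'   n_elements), `adjacencyFraction` (named numeric) and
#'   `distanceHistogram` (data.frame kind/bin/count); empty structures for
#'   empty input.
#' @export
geometrySummary <- function(pairs) {
  bins <- c(0, 1e4, 5e4, 1e5, 5e5, 1e6, Inf)
  labs <- c("<=10kb", "10-50kb", "50-100kb", "100-500kb",
            ">500kb", ">1000kb")
  if (nrow(pairs) == 0)
    return(list(targetsPerElement = data.frame(kind = character(),
                                               n_targets = integer(),
                                               n_elements = integer()),
                adjacencyFraction = stats::setNames(numeric(), character()),
                distanceHistogram = data.frame(kind = character(),
                                               bin = character(),
                                               count = integer())))
  tpe <- do.call(rbind, lapply(split(pairs, pairs$element_kind), function(p) {
    tab <- table(table(p$element_id))
    data.frame(kind = p$element_kind[1],
               n_targets = as.integer(names(tab)),
               n_elements = as.integer(tab), stringsAsFactors = FALSE)
  }))
  rownames(tpe) <- NULL
  adj <- vapply(split(pairs, pairs$element_kind),
                function(p) mean(p$adjacent), numeric(1))
  dh <- do.call(rbind, lapply(split(pairs, pairs$element_kind), function(p) {
    ct <- table(cut(p$distance, breaks = bins, labels = labs,
                    right = TRUE, include.lowest = TRUE))
    data.frame(kind = p$element_kind[1], bin = names(ct),
               count = as.integer(ct), stringsAsFactors = FALSE)
  }))
  rownames(dh) <- NULL
  list(targetsPerElement = tpe, adjacencyFraction = adj,
       distanceHistogram = dh)
}
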