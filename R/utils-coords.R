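#' Construct a GRanges from BED-style (0-based, half-open) coordinates
#'
#' All file formats read and written by this package use the BED convention:
#' 0-based starts and exclusive ends. Internally intervals are held as
#' `GRanges` (1-based, closed); this helper performs the conversion so that
#' coordinates can be stated in BED terms throughout analyses and tests.
#'
#' @param chrom character vector of chromosome names.
#' @param start0 integer vector of 0-based inclusive starts.
#' @param end0 integer vector of exclusive ends (`end0 > start0`).
#' @param strand strand characters (`+`, `-`, `*` or `.`; `.` is mapped
#'   to `*`).
#' @param id optional element identifiers, stored as `names()`.
#' @return A `GRanges` object.
#' @examples
#' bedRanges("chr1", 1000, 1100)
#' @export
bedRanges <- function(chrom, start0, end0, strand = "*", id = NULL) {
  if (any(end0 <= start0))
    stop("invalid interval: end must exceed start (0-based half-open)")
  if (any(start0 < 0))
    stop("invalid interval: negative start coordinate")
  strand <- ifelse(strand == ".", "*", strand)
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = as.integer(start0) + 1L,
                              end = as.integer(end0)),
    strand = strand
  )
  if (!is.null(id)) names(gr) <- id
  gr
}

#' BED-style start coordinates of a GRanges
#' @param gr a `GRanges`.
#' @return integer vector of 0-based starts.
#' @export
bedStart <- function(gr) GenomicRanges::start(gr) - 1L

#' BED-style end coordinates of a GRanges
#' @param gr a `GRanges`.
#' @return integer vector of exclusive ends.
#' @export
bedEnd <- function(gr) GenomicRanges::end(gr)

# midpoint in BED coordinates: floor((start0 + end0) / 2)
.midpoint0 <- function(gr) {
  as.integer(floor((bedStart(gr) + bedEnd(gr)) / 2))
}

# point GRanges (width 1) at a 0-based position
.pointRanges <- function(chrom, pos0, id = NULL) {
  bedRanges(chrom, pos0, pos0 + 1L, id = id)
}

.elementIds <- function(gr, prefix) {
  if (!is.null(names(gr)) && !anyDuplicated(names(gr))) return(names(gr))
  sprintf("%s_%d", prefix, seq_along(gr))
}
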