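#' Read a BED3/BED6 file into GRanges
#'
#' Coordinates in the file are 0-based half-open and are converted to the
#' internal 1-based `GRanges` representation. Column 4, when present, becomes
#' `names()`; column 6 the strand.
#'
#' @param path path to a BED file (uncompressed, tab-separated).
#' @return A `GRanges`.
#' @export
readBed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(df) < 3) stop("BED file needs at least 3 columns: ", path)
  id <- if (ncol(df) >= 4) as.character(df[[4]]) else NULL
  strand <- if (ncol(df) >= 6) as.character(df[[6]]) else "*"
  bedRanges(df[[1]], df[[2]], df[[3]], strand = strand, id = id)
}

#' Write a GRanges as BED
#'
#' @param gr a `GRanges`; `names()` populate the name column, else the
#'   `name` argument.
#' @param path output path.
#' @param name optional character vector for the BED name column.
#' @export
writeBed <- function(gr, path, name = NULL) {
  nm <- if (!is.null(name)) name
        else if (!is.null(names(gr))) names(gr)
        else rep(".", length(gr))
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = bedStart(gr),
    end = bedEnd(gr),
    name = nm,
    score = 0L,
    strand = ifelse(as.character(GenomicRanges::strand(gr)) == "*", ".",
                    as.character(GenomicRanges::strand(gr)))
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a gene annotation table
#'
#' Expects a tab-separated file with columns `gene_id`, `chrom`, `tss`,
#' `strand`; `tss` is the 0-based transcription start site position. Returns
#' a width-1 `GRanges` anchored at each TSS, stranded, named by `gene_id`.
#' Alternative TSSs may repeat a `gene_id`.
#'
#' @param path path to the annotation TSV (header required).
#' @return A `GRanges` with metadata column `gene_id`.
#' @export
readGeneAnnotation <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "tss", "strand")
  if (!all(need %in% names(df)))
    stop("gene annotation needs columns: ", paste(need, collapse = ", "))
  gr <- .pointRanges(df$chrom, df$tss, id = df$gene_id)
  GenomicRanges::strand(gr) <- ifelse(df$strand == ".", "*", df$strand)
  S4Vectors::mcols(gr)$gene_id <- df$gene_id
  gr
}

#' Read a probe manifest
#'
#' Tab-separated columns `probe_id`, `chrom`, `pos` (0-based probe
#' position). Returns width-1 `GRanges` named by probe id.
#'
#' @param path path to the manifest TSV (header required).
#' @return A `GRanges`.
#' @export
readProbeManifest <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("probe_id", "chrom", "pos")
  if (!all(need %in% names(df)))
    stop("probe manifest needs columns: ", paste(need, collapse = ", "))
  .pointRanges(df$chrom, df$pos, id = df$probe_id)
}

#' Read a numeric matrix from TSV
#'
#' Rows are features (probes, regions or genes), columns samples; the first
#' column holds feature ids; `NA` marks missing values.
#'
#' @param path path to the TSV.
#' @return numeric matrix with dimnames.
#' @export
readMatrixTsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- as.character(df[[1]])
  m
}

#' Write a numeric matrix as TSV
#'
#' Inverse of [readMatrixTsv()]; numbers are formatted with full precision
#' (`%.12g`) so that a rewrite of unchanged data is byte-identical.
#'
#' @param m numeric matrix with dimnames.
#' @param path output path.
#' @param idColumn name of the leading id column.
#' @export
writeMatrixTsv <- function(m, path, idColumn = "id") {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste(c(idColumn, colnames(m)), collapse = "\t"), con)
  body <- vapply(seq_len(nrow(m)), function(i) {
    vals <- ifelse(is.na(m[i, ]), "NA", sprintf("%.12g", m[i, ]))
    paste(c(rownames(m)[i], vals), collapse = "\t")
  }, character(1))
  writeLines(body, con)
  invisible(path)
}

#' Read sample cluster labels
#'
#' Tab-separated columns `sample_id`, `cluster` (values `C1`/`C2`).
#'
#' @param path path to the labels TSV (header required).
#' @return named character vector, sample id -> cluster.
#' @export
readClusterLabels <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  stats::setNames(as.character(df$cluster), as.character(df$sample_id))
}
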