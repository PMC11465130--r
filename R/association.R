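# Discretize a numeric vector for MI estimation. Vectors with at most
# `bins` distinct values are treated as already discrete (codes by sorted
# value); otherwise equal-frequency binning via ranks (ties broken by input
# order for determinism). Returns integer codes in 1..levels.
.discretize <- function(x, bins = 3L, method = c("equalfreq", "state")) {
  method <- match.arg(method)
  if (method == "state") {
    st <- classifyBetaState(x)
    return(match(st, c("hypo", "hemi", "hyper")))
  }
  ux <- sort(unique(x))
  if (length(ux) <= bins) return(match(x, ux))
  r <- rank(x, ties.method = "first")
  as.integer(ceiling(r * bins / length(x)))
}

# plug-in MI (nats) from integer codes
.miFromCodes <- function(cx, cy) {
  n <- length(cx)
  nx <- max(cx); ny <- max(cy)
  joint <- tabulate((cx - 1L) * ny + cy, nbins = nx * ny) / n
  px <- rowSums(matrix(joint, nx, ny, byrow = TRUE))
  py <- colSums(matrix(joint, nx, ny, byrow = TRUE))
  pos <- joint > 0
  e <- outer(px, py)
  sum(joint[pos] * log(joint[pos] / t(e)[pos]))
}

#' Plug-in mutual information between two sample vectors
#'
#' Both vectors are discretized (equal-frequency binning into `bins`
#' levels by default; vectors with at most `bins` distinct values are used
#' as-is; methylation may alternatively use the hypo/hemi/hyper state
#' discretization) and the empirical mutual information is computed in
#' nats. MI is symmetric and non-negative; a vector that is constant after
#' discretization yields 0 with a warning.
#'
#' @param x,y numeric vectors of equal length (>= 3); pairs with missing
#'   entries are dropped.
#' @param bins number of discretization levels (default 3).
#' @param method discretization: `"equalfreq"` or `"state"` (beta-state
#'   thresholds; applies to both vectors).
#' @return mutual information in nats.
#' @examples
#' mutualInformation(c(0, 0, 1, 1), c(0, 0, 1, 1))  # ln 2
#' @export
mutualInformation <- function(x, y, bins = 3L,
                              method = c("equalfreq", "state")) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  keep <- !(is.na(x) | is.na(y))
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("need at least 3 paired non-missing observations")
  method <- match.arg(method)
  cx <- .discretize(x, bins, method)
  cy <- .discretize(y, bins, method)
  if (max(cx) == 1L || max(cy) == 1L) {
    warning("constant vector after discretization; MI is 0")
    return(0)
  }
  .miFromCodes(cx, cy)
}

#' Permutation p-value for a mutual-information association
#'
#' Permutes `y` against fixed `x` and reports
#' `p = (1 + #\{perm MI >= observed\}) / (nPerm + 1)`. Discretization happens
#' once; the permutation distribution is over the discretized codes, so the
#' test is exact for the plug-in estimator. Identical seeds give identical
#' p-values.
#'
#' @inheritParams mutualInformation
#' @param nPerm number of permutations (>= 99; default 999).
#' @param seed integer seed for the permutation stream; `NULL` continues
#'   the current RNG stream (used internally by [screenAssociations()]).
#' @return list with `mi` (observed, nats) and `p`.
#' @export
permutationPvalue <- function(x, y, nPerm = 999L, seed = NULL, bins = 3L,
                              method = c("equalfreq", "state")) {
  if (nPerm < 99) stop("nPerm must be at least 99")
  if (length(x) != length(y)) stop("x and y must have equal length")
  keep <- !(is.na(x) | is.na(y))
  x <- x[keep]; y <- y[keep]
  method <- match.arg(method)
  cx <- .discretize(x, bins, method)
  cy <- .discretize(y, bins, method)
  if (max(cx) == 1L || max(cy) == 1L) {
    warning("constant vector after discretization; MI is 0")
    return(list(mi = 0, p = 1))
  }
  if (!is.null(seed)) set.seed(seed)
  obs <- .miFromCodes(cx, cy)
  hits <- 0L
  for (i in seq_len(nPerm)) {
    if (.miFromCodes(cx, sample(cy)) >= obs - 1e-12) hits <- hits + 1L
  }
  list(mi = obs, p = (1 + hits) / (nPerm + 1))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment (monotone, capped at 1); the
#' module surface over `stats::p.adjust(method = "BH")`.
#'
#' @param p numeric vector of p-values in (0, 1].
#' @return adjusted p-values, same length and order.
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.04))  # 0.03 0.03 0.04
#' @export
bhAdjust <- function(p) {
  if (length(p) == 0) return(numeric())
  if (any(p <= 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in (0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Screen candidate pairs by mutual information
#'
#' For every candidate pair, the mutual information between the element's
#' region methylation and the gene's expression is computed across shared
#' samples, with a permutation p-value and a Benjamini-Hochberg adjusted
#' p-value. The oCGI-gene and enhancer-gene pair families are adjusted
#' separately, mirroring their use as separate screening criteria. One
#' seeded generator stream drives all permutations, so results are
#' reproducible for a fixed pair-table order.
#'
#' @param pairs pair table from [enumeratePairs()].
#' @param regionBeta a [RegionMethylation-class] or a regions-by-samples
#'   beta matrix covering the pair elements.
#' @param expr genes-by-samples expression matrix.
#' @param bins MI discretization levels (default 3).
#' @param nPerm permutations per pair (default 999).
#' @param seed mandatory integer seed.
#' @return `pairs` with columns `mi`, `p`, `adj_p`, `n_samples` appended.
#' @export
screenAssociations <- function(pairs, regionBeta, expr, bins = 3L,
                               nPerm = 999L, seed) {
  if (missing(seed)) stop("a seed is mandatory for the permutation screen")
  b <- if (methods::is(regionBeta, "RegionMethylation"))
    SummarizedExperiment::assay(regionBeta, "beta") else regionBeta
  samples <- intersect(colnames(b), colnames(expr))
  if (length(samples) < 3) stop("fewer than 3 shared samples")
  set.seed(seed)
  n <- nrow(pairs)
  mi <- p <- numeric(n)
  for (i in seq_len(n)) {
    x <- b[pairs$element_id[i], samples]
    y <- expr[pairs$gene_id[i], samples]
    r <- permutationPvalue(x, y, nPerm = nPerm, seed = NULL, bins = bins)
    mi[i] <- r$mi; p[i] <- r$p
  }
  out <- pairs
  out$mi <- mi
  out$p <- p
  out$adj_p <- NA_real_
  for (kind in unique(out$element_kind)) {
    idx <- out$element_kind == kind
    out$adj_p[idx] <- bhAdjust(out$p[idx])
  }
  out$n_samples <- length(samples)
  out
}

#' Assemble oCGI-enhancer-gene triplets from screened pairs
#'
#' For each gene and TAD, every combination of one passing oCGI-gene pair
#' and one passing enhancer-gene pair (adjusted p below `alpha`) becomes a
#' triplet; a gene lacking a passing pair of either kind yields none.
#'
#' @param associations screened pair table from [screenAssociations()].
#' @param alpha adjusted-p threshold (default 0.05).
#' @return data.frame with columns `ocgi_id`, `enhancer_id`, `gene_id`,
#'   `tad_id`, `mi_og`, `adj_p_og`, `mi_eg`, `adj_p_eg`.
#' @export
buildTriplets <- function(associations, alpha = 0.05) {
  pass <- associations[!is.na(associations$adj_p) &
                         associations$adj_p < alpha, ]
  oc <- pass[pass$element_kind == "oCGI", ]
  en <- pass[pass$element_kind == "enhancer", ]
  out <- merge(
    oc[, c("element_id", "gene_id", "tad_id", "mi", "adj_p")],
    en[, c("element_id", "gene_id", "tad_id", "mi", "adj_p")],
    by = c("gene_id", "tad_id"), suffixes = c("_og", "_eg"))
  out <- data.frame(ocgi_id = out$element_id_og,
                    enhancer_id = out$element_id_eg,
                    gene_id = out$gene_id, tad_id = out$tad_id,
                    mi_og = out$mi_og, adj_p_og = out$adj_p_og,
                    mi_eg = out$mi_eg, adj_p_eg = out$adj_p_eg,
                    stringsAsFactors = FALSE)
  out[order(out$tad_id, out$gene_id, out$ocgi_id, out$enhancer_id), ,
      drop = FALSE]
}
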