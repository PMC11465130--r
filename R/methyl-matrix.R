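#' Quality-control filter for a probe-level beta matrix
#'
#' Applies three filters in order, one pass each: (1) remove probes on the
#' SNP exclusion list; (2) remove probes observed (non-missing) in fewer
#' than `probeMinFrac` of samples; (3) remove samples observed in fewer
#' than `sampleMinFrac` of the remaining probes. "Observed" means a
#' non-missing beta value.
#'
#' @param beta numeric probes-by-samples matrix with dimnames; `NA` marks
#'   missing values; non-missing entries must lie in \[0, 1\].
#' @param snpProbes character vector of probe ids to exclude.
#' @param probeMinFrac,sampleMinFrac minimum observed fractions
#'   (default 0.2; the criterion fires on strictly-less-than).
#' @return list with `beta` (the filtered matrix) and `report`, a list
#'   counting removals per criterion plus the residual missing fraction.
#' @export
qcFilterBeta <- function(beta, snpProbes = character(),
                         probeMinFrac = 0.2, sampleMinFrac = 0.2) {
  stopifnot(is.matrix(beta), nrow(beta) > 0, ncol(beta) > 0)
  if (any(beta < 0 | beta > 1, na.rm = TRUE))
    stop("beta values outside [0, 1]")
  isSnp <- rownames(beta) %in% snpProbes
  m <- beta[!isSnp, , drop = FALSE]
  if (nrow(m) == 0) stop("all probes removed by QC (SNP exclusion)")
  probeFrac <- rowMeans(!is.na(m))
  lowProbe <- probeFrac < probeMinFrac
  m <- m[!lowProbe, , drop = FALSE]
  if (nrow(m) == 0) stop("all probes removed by QC (low observation)")
  sampleFrac <- colMeans(!is.na(m))
  lowSample <- sampleFrac < sampleMinFrac
  m <- m[, !lowSample, drop = FALSE]
  if (ncol(m) == 0) stop("all samples removed by QC")
  list(beta = m,
       report = list(
         nProbesIn = nrow(beta), nSamplesIn = ncol(beta),
         nSnpProbesRemoved = sum(isSnp),
         nLowObservationProbesRemoved = sum(lowProbe),
         nLowObservationSamplesRemoved = sum(lowSample),
         nProbesOut = nrow(m), nSamplesOut = ncol(m),
         missingFraction = mean(is.na(m))))
}

#' K-nearest-neighbour imputation of missing beta values
#'
#' Each missing entry is replaced by the mean beta of that sample over the
#' `k` probes (rows) nearest to the target probe, where distance is the
#' mean squared difference over jointly observed samples (Euclidean
#' distance scaled by the number of shared columns). Only probes observed
#' in the target sample can donate; ties in distance are broken by probe
#' row order. Probes missing in more than `rowmax` of samples are imputed
#' by their row mean instead (column mean if the row is fully missing).
#' Samples missing in more than `colmax` of probes are an error. Observed
#' entries are never altered.
#'
#' @param beta numeric probes-by-samples matrix, `NA` for missing.
#' @param k number of neighbour probes (default 10).
#' @param rowmax maximum missing fraction per probe for the KNN path
#'   (default 0.5).
#' @param colmax maximum tolerated missing fraction per sample
#'   (default 0.8).
#' @return the completed matrix.
#' @export
knnImputeBeta <- function(beta, k = 10L, rowmax = 0.5, colmax = 0.8) {
  stopifnot(is.matrix(beta))
  colMiss <- colMeans(is.na(beta))
  if (any(colMiss > colmax))
    stop("sample(s) exceed colmax missingness: ",
         paste(colnames(beta)[colMiss > colmax], collapse = ", "))
  if (!anyNA(beta)) return(beta)
  obs <- !is.na(beta)
  x0 <- beta
  x0[!obs] <- 0
  # pairwise sums of squared differences over jointly observed columns
  sq <- x0^2
  mObs <- obs * 1
  ss <- sq %*% t(mObs) + mObs %*% t(sq) - 2 * x0 %*% t(x0)
  shared <- mObs %*% t(mObs)
  d2 <- ss / shared          # mean squared difference; NaN when no overlap
  d2[shared == 0] <- Inf
  colMeansObs <- colSums(x0) / colSums(mObs)
  out <- beta
  rowMiss <- rowMeans(!obs)
  for (r in which(rowMiss > 0)) {
    missCols <- which(!obs[r, ])
    if (rowMiss[r] > rowmax) {
      # fallback: row mean, then column mean for fully missing rows
      rm <- mean(beta[r, ], na.rm = TRUE)
      out[r, missCols] <- if (is.nan(rm)) colMeansObs[missCols] else rm
      next
    }
    dr <- d2[r, ]
    dr[r] <- Inf
    ord <- order(dr, seq_along(dr))  # distance, then row order for ties
    for (cc in missCols) {
      donors <- ord[obs[ord, cc] & is.finite(dr[ord])]
      if (length(donors) == 0) {
        out[r, cc] <- colMeansObs[cc]
      } else {
        out[r, cc] <- mean(beta[donors[seq_len(min(k, length(donors)))], cc])
      }
    }
  }
  out
}

#' Aggregate probe-level beta values to region means
#'
#' Probes are assigned to regions by coordinate containment under the
#' half-open convention (a probe exactly at a region's end coordinate is
#' outside it). Per region and sample the arithmetic mean of contained
#' probes is taken. Regions containing zero probes are kept with `NA`
#' values and flagged for exclusion from downstream screening.
#'
#' @param beta numeric probes-by-samples matrix (complete; impute first).
#' @param probeRanges width-1 `GRanges` named by probe id covering
#'   `rownames(beta)`.
#' @param regions `GRanges` of target regions with unique names.
#' @return A [RegionMethylation-class].
#' @export
aggregateRegionBeta <- function(beta, probeRanges, regions) {
  stopifnot(is.matrix(beta))
  if (is.null(names(regions)) || anyDuplicated(names(regions)))
    stop("regions must carry unique names")
  pr <- probeRanges[rownames(beta)]
  ov <- GenomicRanges::findOverlaps(pr, regions, type = "within")
  n <- tabulate(S4Vectors::subjectHits(ov), nbins = length(regions))
  mean_ <- matrix(NA_real_, length(regions), ncol(beta),
                  dimnames = list(names(regions), colnames(beta)))
  if (length(ov) > 0) {
    grp <- S4Vectors::subjectHits(ov)
    sums <- rowsum(beta[S4Vectors::queryHits(ov), , drop = FALSE], grp)
    mean_[as.integer(rownames(sums)), ] <- sums / n[as.integer(rownames(sums))]
  }
  rr <- regions
  S4Vectors::mcols(rr)$nProbes <- n
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(beta = mean_), rowRanges = rr)
  methods::as(se, "RegionMethylation")
}

#' Classify beta values into methylation states
#'
#' Hypomethylated if beta < `hypo` (default 0.32), hypermethylated if
#' beta > `hyper` (default 0.79), hemimethylated otherwise (both
#' boundaries inclusive to hemi). The three states partition \[0, 1\]
#' exactly; values outside are an error, `NA` propagates.
#'
#' @param beta numeric vector or matrix of beta values.
#' @param hypo,hyper state thresholds.
#' @return character vector or matrix of `"hypo"`, `"hemi"`, `"hyper"`.
#' @examples
#' classifyBetaState(c(0.20, 0.50, 0.85))  # hypo hemi hyper
#' @export
classifyBetaState <- function(beta, hypo = 0.32, hyper = 0.79) {
  if (any(beta < 0 | beta > 1, na.rm = TRUE))
    stop("beta values must lie in [0, 1]")
  out <- ifelse(beta < hypo, "hypo", ifelse(beta > hyper, "hyper", "hemi"))
  if (is.matrix(beta)) dimnames(out) <- dimnames(beta)
  out
}
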