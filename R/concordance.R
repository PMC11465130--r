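#' Cluster-direction concordance filtering of called triplets
#'
#' A called triplet is labeled `C2_UP` when the mean methylation of its
#' dominant element(s) is strictly lower in cluster C2 than in C1 AND the
#' mean expression of its gene is strictly higher in C2; `C1_UP` by the
#' mirrored inequalities. The dominant element is the oCGI for
#' oCGI-dominated models, the enhancer for enhancer-dominated models, and
#' both for the co-dominated model (whose two elements must agree).
#' Expression is compared as per-cluster means of `log1p` expression (the
#' scale on which the models are fit; robust to the heavy right tail of
#' expression counts). Discordant triplets are dropped with a reason.
#' Per-cluster beta states are recorded as annotation.
#'
#' @param calls call table from [callTriplets()] (triplets with a selected
#'   model).
#' @param regionBeta a [RegionMethylation-class] or regions-by-samples
#'   beta matrix.
#' @param expr genes-by-samples expression matrix.
#' @param labels named character vector, sample id -> `"C1"`/`"C2"`; every
#'   analyzed sample must be labeled and both clusters non-empty.
#' @return list with `kept` (calls plus `direction`, per-cluster means and
#'   states) and `dropped` (calls plus `drop_reason`).
#' @export
concordanceFilter <- function(calls, regionBeta, expr, labels) {
  b <- if (methods::is(regionBeta, "RegionMethylation"))
    SummarizedExperiment::assay(regionBeta, "beta") else regionBeta
  samples <- intersect(colnames(b), colnames(expr))
  unlabeled <- setdiff(samples, names(labels))
  if (length(unlabeled) > 0)
    stop("missing cluster label for sample(s): ",
         paste(unlabeled, collapse = ", "))
  cl <- labels[samples]
  if (!all(c("C1", "C2") %in% cl)) stop("both clusters must be non-empty")
  s1 <- samples[cl == "C1"]; s2 <- samples[cl == "C2"]
  assigned <- calls[!is.na(calls$selected_model), , drop = FALSE]
  keptRows <- list(); dropRows <- list()
  for (i in seq_len(nrow(assigned))) {
    row <- assigned[i, , drop = FALSE]
    dom <- row$dominance
    els <- switch(dom,
                  oCGI = row$ocgi_id,
                  enhancer = row$enhancer_id,
                  co = c(row$ocgi_id, row$enhancer_id))
    b1 <- vapply(els, function(el) mean(b[el, s1]), numeric(1))
    b2 <- vapply(els, function(el) mean(b[el, s2]), numeric(1))
    g1 <- mean(log1p(expr[row$gene_id, s1]))
    g2 <- mean(log1p(expr[row$gene_id, s2]))
    lower2 <- b2 < b1; lower1 <- b1 < b2
    ann <- data.frame(
      beta_ocgi_C1 = mean(b[row$ocgi_id, s1]),
      beta_ocgi_C2 = mean(b[row$ocgi_id, s2]),
      beta_enh_C1 = mean(b[row$enhancer_id, s1]),
      beta_enh_C2 = mean(b[row$enhancer_id, s2]),
      log_expr_C1 = g1, log_expr_C2 = g2,
      state_ocgi_C1 = classifyBetaState(mean(b[row$ocgi_id, s1])),
      state_ocgi_C2 = classifyBetaState(mean(b[row$ocgi_id, s2])),
      state_enh_C1 = classifyBetaState(mean(b[row$enhancer_id, s1])),
      state_enh_C2 = classifyBetaState(mean(b[row$enhancer_id, s2])),
      stringsAsFactors = FALSE)
    if (all(lower2) && g2 > g1) {
      keptRows[[length(keptRows) + 1]] <-
        cbind(row, data.frame(direction = "C2_UP"), ann)
    } else if (all(lower1) && g1 > g2) {
      keptRows[[length(keptRows) + 1]] <-
        cbind(row, data.frame(direction = "C1_UP"), ann)
    } else {
      reason <- if (length(els) > 1 && any(lower2) && any(lower1))
        "dominant elements disagree" else "no direction"
      dropRows[[length(dropRows) + 1]] <-
        cbind(row, data.frame(drop_reason = reason), ann)
    }
  }
  empty <- assigned[0, , drop = FALSE]
  list(kept = if (length(keptRows)) do.call(rbind, keptRows) else
         cbind(empty, data.frame(direction = character())),
       dropped = if (length(dropRows)) do.call(rbind, dropRows) else
         cbind(empty, data.frame(drop_reason = character())))
}

#' Per-sample cis score over a direction-labeled gene set
#'
#' The cis score of a sample is the arithmetic mean of the expression of a
#' gene set (e.g. the genes upregulated in C2 among concordant triplet
#' targets). Samples are stratified into high/low groups at the cohort
#' median of the scores.
#'
#' @param expr genes-by-samples expression matrix.
#' @param geneSet character vector of gene ids (non-empty); genes absent
#'   from the matrix are skipped with a warning.
#' @return data.frame with columns `sample`, `score`, `group`
#'   (`"high"` if score > median, else `"low"`).
#' @export
cisScore <- function(expr, geneSet) {
  if (length(geneSet) == 0) stop("empty gene set")
  present <- intersect(geneSet, rownames(expr))
  absent <- setdiff(geneSet, present)
  if (length(present) == 0) stop("no gene of the set is in the matrix")
  if (length(absent) > 0)
    warning("skipping genes absent from the matrix: ",
            paste(absent, collapse = ", "))
  score <- colMeans(expr[present, , drop = FALSE])
  data.frame(sample = colnames(expr), score = as.numeric(score),
             group = ifelse(score > stats::median(score), "high", "low"),
             stringsAsFactors = FALSE, row.names = NULL)
}
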