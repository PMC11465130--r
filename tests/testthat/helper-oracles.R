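# Independent brute-force oracles used to cross-check the implementation.

# all-pairs half-open interval overlap: data.frames with chrom/start0/end0
overlapsAnyOracle <- function(q, s) {
  vapply(seq_len(nrow(q)), function(i) {
    any(s$chrom == q$chrom[i] &
          s$start0 < q$end0[i] & q$start0[i] < s$end0)
  }, logical(1))
}

# exhaustive-scan KNN imputation following the documented contract
knnImputeOracle <- function(m, k = 10, rowmax = 0.5, colmax = 0.8) {
  out <- m
  colMeansObs <- apply(m, 2, mean, na.rm = TRUE)
  for (r in seq_len(nrow(m))) {
    miss <- which(is.na(m[r, ]))
    if (length(miss) == 0) next
    if (mean(is.na(m[r, ])) > rowmax) {
      rm_ <- mean(m[r, ], na.rm = TRUE)
      out[r, miss] <- if (is.nan(rm_)) colMeansObs[miss] else rm_
      next
    }
    d <- rep(Inf, nrow(m))
    for (j in seq_len(nrow(m))) {
      if (j == r) next
      shared <- which(!is.na(m[r, ]) & !is.na(m[j, ]))
      if (length(shared) == 0) next
      d[j] <- mean((m[r, shared] - m[j, shared])^2)
    }
    for (cc in miss) {
      cand <- which(!is.na(m[, cc]) & is.finite(d))
      cand <- cand[order(d[cand], cand)]
      if (length(cand) == 0) out[r, cc] <- colMeansObs[cc]
      else out[r, cc] <- mean(m[cand[seq_len(min(k, length(cand)))], cc])
    }
  }
  out
}

# independent step-up BH reimplementation
bhOracle <- function(p) {
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(p[o] * m / seq(m, 1)))[ro]
}

# factorized-density product logL at MLE parameters (gaussian backend)
gaussLogLOracle <- function(o, e, g, parents) {
  dat <- list(O = o, E = e, G = g)
  total <- 0
  for (node in c("O", "E", "G")) {
    pa <- parents[[node]]
    df <- data.frame(y = dat[[node]])
    for (p in pa) df[[p]] <- dat[[p]]
    fit <- if (length(pa) == 0) lm(y ~ 1, data = df)
    else lm(stats::reformulate(pa, "y"), data = df)
    mu <- fitted(fit)
    s2 <- mean(residuals(fit)^2)
    total <- total + sum(dnorm(dat[[node]], mu, sqrt(s2), log = TRUE))
  }
  total
}
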