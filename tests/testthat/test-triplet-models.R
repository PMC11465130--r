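models <- enumerateModels()

edgeSet <- function(m) {
  if (nrow(m@edges) == 0) character()
  else sort(paste(m@edges[, 1], m@edges[, 2], sep = ">"))
}

test_that("nine structures with the printed factorizations and dominance split", {
  expect_length(models, 9)
  dom <- vapply(models, function(m) m@dominance, character(1))
  expect_equal(sum(dom == "oCGI"), 4L)
  expect_equal(sum(dom == "enhancer"), 4L)
  expect_equal(sum(dom == "co"), 1L)
  # edges follow the factorizations
  expect_equal(edgeSet(models$oCGI_direct), "O>G")       # P(O)P(G|O)P(E)
  expect_equal(edgeSet(models$oCGI_cascade), c("E>G", "O>E"))
  expect_equal(edgeSet(models$oCGI_coresponsive), c("O>E", "O>G"))
  expect_equal(edgeSet(models$oCGI_composite), c("E>G", "O>E", "O>G"))
  expect_equal(edgeSet(models$enhancer_direct), "E>G")
  expect_equal(edgeSet(models$enhancer_cascade), c("E>O", "O>G"))
  expect_equal(edgeSet(models$enhancer_coresponsive), c("E>G", "E>O"))
  expect_equal(edgeSet(models$enhancer_composite), c("E>G", "E>O", "O>G"))
  expect_equal(edgeSet(models$co_dominated), c("E>G", "O>G"))
  for (m in models) expect_true(validObject(m))
})

test_that("the nine structures collapse into the six expected equivalence classes", {
  cls <- vapply(models, function(m) m@equivClass, character(1))
  expect_length(unique(cls), 6)
  byClass <- lapply(split(names(cls), cls), sort)
  expect_true(any(vapply(byClass, identical,
                         logical(1), y = "oCGI_direct")))
  expect_true(any(vapply(byClass, identical,
                         logical(1), y = "enhancer_direct")))
  expect_true(any(vapply(byClass, identical,
                         logical(1), y = "co_dominated")))
  expect_true(any(vapply(byClass, identical, logical(1),
                         y = c("enhancer_coresponsive", "oCGI_cascade"))))
  expect_true(any(vapply(byClass, identical, logical(1),
                         y = c("enhancer_cascade", "oCGI_coresponsive"))))
  expect_true(any(vapply(byClass, identical, logical(1),
                         y = c("enhancer_composite", "oCGI_composite"))))
})

test_that("Markov-equivalent structures have equal maximized likelihood", {
  cls <- vapply(models, function(m) m@equivClass, character(1))
  set.seed(61)
  for (i in 1:20) {
    o <- runif(50); e <- runif(50); g <- rnorm(50)
    ll <- vapply(models, function(m)
      fitTripletModel(o, e, g, m)$logL, numeric(1))
    for (cl in unique(cls)) {
      lls <- ll[cls == cl]
      expect_lt(max(lls) - min(lls), 1e-8)
    }
  }
})

test_that("gaussian parameter counts and the AIC identity are exact", {
  o <- runif(30); e <- runif(30); g <- rnorm(30)
  ks <- vapply(models, function(m) fitTripletModel(o, e, g, m)$k, integer(1))
  expect_equal(unname(ks[c("oCGI_direct", "co_dominated", "oCGI_composite",
                           "enhancer_composite")]),
               c(7L, 8L, 9L, 9L))
  for (m in models) {
    f <- fitTripletModel(o, e, g, m)
    expect_identical(f$aic, 2 * f$k - 2 * f$logL)
  }
})

test_that("each model's logL equals the factorized density-product oracle", {
  set.seed(71)
  o <- runif(20); e <- runif(20); g <- rnorm(20)  # 20-sample fixture
  for (m in models) {
    parents <- list(
      O = m@edges[m@edges[, 2] == "O", 1],
      E = m@edges[m@edges[, 2] == "E", 1],
      G = m@edges[m@edges[, 2] == "G", 1])
    expect_equal(fitTripletModel(o, e, g, m)$logL,
                 gaussLogLOracle(o, e, g, parents), tolerance = 1e-10)
  }
})

test_that("the complete DAG attains the trivariate gaussian MLE likelihood", {
  set.seed(81)
  n <- 40
  o <- runif(n); e <- runif(n); g <- rnorm(n)
  X <- cbind(o, e, g)
  S <- crossprod(scale(X, scale = FALSE)) / n  # MLE covariance
  closedForm <- -n / 2 * (3 * log(2 * pi) + log(det(S)) + 3)
  expect_equal(fitTripletModel(o, e, g, models$oCGI_composite)$logL,
               closedForm, tolerance = 1e-8)
})

test_that("zero-variance nodes are rejected by name", {
  expect_error(
    fitTripletModel(rep(0.5, 20), runif(20), rnorm(20), models$co_dominated),
    "O")
})

test_that("the discrete backend smooths empty cells and counts parameters", {
  set.seed(91)
  o <- runif(30); e <- runif(30); g <- rnorm(30)
  f <- fitTripletModel(o, e, g, models$oCGI_direct, backend = "discrete")
  expect_true(is.finite(f$logL))
  # roots contribute (3-1), the single-parent child (3-1)*3
  expect_equal(f$k, 2L + 2L + 6L)
  fc <- fitTripletModel(o, e, g, models$co_dominated, backend = "discrete")
  expect_equal(fc$k, 2L + 2L + 2L * 9L)
  expect_identical(fc$aic, 2 * fc$k - 2 * fc$logL)
  # even degenerate all-hypo methylation keeps a finite likelihood
  oh <- rep(c(0.1, 0.2), 15)
  fd <- fitTripletModel(oh, e, g, models$co_dominated, backend = "discrete")
  expect_true(is.finite(fd$logL))
})

test_that("validity testing matches simulated ground truth", {
  set.seed(500)
  n <- 500
  # mutually independent: the direct model's edge shows no dependence
  o <- runif(n); e <- runif(n); g <- rnorm(n)
  v <- ciTests(o, e, g, models$oCGI_direct)
  expect_false(v$valid)
  edgeRow <- v$results[v$results$implied == "dependent", ][1, ]
  expect_gte(edgeRow$p, 0.05)

  # strong O -> G with E independent: the direct model is valid
  o2 <- runif(n); e2 <- runif(n)
  g2 <- 2 - 3 * o2 + rnorm(n, sd = 0.3)
  v2 <- ciTests(o2, e2, g2, models$oCGI_direct)
  expect_true(v2$valid)
  dep <- v2$results[v2$results$implied == "dependent", ]
  indep <- v2$results[v2$results$implied == "independent", ]
  expect_true(all(dep$p < 0.05))
  expect_true(all(indep$p >= 0.05))

  # perfectly correlated o == g: dependence p ~ 0
  x <- runif(50)
  v3 <- ciTests(x, runif(50), x, models$oCGI_direct)
  expect_lt(v3$results$p[v3$results$relation == "O ~ G" &
                           v3$results$conditioning == ""], 1e-10)
})

test_that("selection takes the smallest valid AIC and breaks class ties by MI", {
  set.seed(600)
  n <- 400
  e <- runif(n)
  g <- 3 - 2.5 * e + rnorm(n, sd = 0.4)   # enhancer-direct truth
  o <- runif(n)
  fits <- lapply(models, function(m) fitTripletModel(o, e, g, m))
  val <- lapply(models, function(m) ciTests(o, e, g, m))
  sel <- selectModel(fits, val, miOG = 0.01, miEG = 0.8)
  expect_equal(sel$selected, "enhancer_direct")
  expect_false(sel$tieBreak)

  # chain truth O -> E -> G: the two class members tie exactly; dominance
  # follows the larger element-gene MI
  o2 <- runif(n)
  e2 <- pmin(pmax(0.5 + 0.9 * (o2 - mean(o2)) + rnorm(n, sd = 0.05),
                  0.001), 0.999)
  g2 <- 3 - 3 * e2 + rnorm(n, sd = 0.3)
  fits2 <- lapply(models, function(m) fitTripletModel(o2, e2, g2, m))
  val2 <- lapply(models, function(m) ciTests(o2, e2, g2, m))
  selO <- selectModel(fits2, val2, miOG = 0.9, miEG = 0.2)
  selE <- selectModel(fits2, val2, miOG = 0.2, miEG = 0.9)
  expect_true(selO$tieBreak && selE$tieBreak)
  expect_equal(selO$selected, "oCGI_cascade")
  expect_equal(selE$selected, "enhancer_coresponsive")
  expect_equal(unname(selO$aic["oCGI_cascade"]),
               unname(selO$aic["enhancer_coresponsive"]))

  # nothing valid: unassigned with reason
  selNone <- selectModel(fits, lapply(val, function(v) {
    v$valid <- FALSE; v
  }), 0.5, 0.5)
  expect_true(is.na(selNone$selected))
  expect_match(selNone$reason, "no structure")
})

test_that("callTriplets returns per-model AICs and a selected structure", {
  cfg <- simulationConfig(seed = 5, nSamples = 120, nTads = 4,
                          direction = "C2_UP",
                          structures = "oCGI_cascade")
  b <- simulateBundle(cfg)
  win <- expandAndMergeCgis(b$cgis)
  cat <- classifyCgis(win, definePromoters(b$genes), b$enhancers)
  regions <- c(GenomicRanges::granges(orphanCgis(cat)),
               GenomicRanges::granges(b$enhancers))
  names(regions) <- c(names(orphanCgis(cat)), names(b$enhancers))
  rb <- aggregateRegionBeta(knnImputeBeta(b$beta), b$probes, regions)
  trip <- data.frame(ocgi_id = b$truth$ocgi_id,
                     enhancer_id = b$truth$enhancer_id,
                     gene_id = b$truth$gene_id, tad_id = b$truth$tad_id,
                     mi_og = 0.5, adj_p_og = 0.001,
                     mi_eg = 0.9, adj_p_eg = 0.001)
  calls <- callTriplets(trip, rb, b$expr)
  expect_equal(nrow(calls), 4)
  expect_true(all(paste0("aic_", names(models)) %in% colnames(calls)))
  expect_true(all(!is.na(calls$selected_model)))
  expect_true(all(calls$n_valid_models >= 1))
})
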