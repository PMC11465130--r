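# a one-chromosome catalog for pairing tests: elements/genes placed by hand
mkCatalog <- function(ocgiStarts, enhStarts, tssPos, elWidth = 500) {
  win <- bedRanges("chr1", ocgiStarts, ocgiStarts + elWidth,
                   id = sprintf("cgi_%d", seq_along(ocgiStarts)))
  S4Vectors::mcols(win)$cgiClass <-
    factor(rep("orphan", length(win)),
           levels = c("orphan", "promoter_overlap", "enhancer_overlap"))
  S4Vectors::mcols(win)$genic <- rep(FALSE, length(win))
  enh <- bedRanges("chr1", enhStarts, enhStarts + 400,
                   id = sprintf("enh_%d", seq_along(enhStarts)))
  genes <- bedRanges("chr1", tssPos, tssPos + 1, strand = "+",
                     id = sprintf("gene_%d", seq_along(tssPos)))
  S4Vectors::mcols(genes)$gene_id <- names(genes)
  new("ElementCatalog", cgis = win, enhancers = enh,
      promoters = GenomicRanges::GRanges(), genes = genes)
}

test_that("TAD assignment is by anchor containment with midpoint rule", {
  tads <- bedRanges("chr1", c(0, 10000), c(10000, 20000), id = c("A", "B"))
  # fully inside
  a <- assignToTads(bedRanges("chr1", 1000, 1500, id = "x"), tads)
  expect_equal(a$tad, "A")
  # spans the boundary, midpoint 9900 in A
  b <- assignToTads(bedRanges("chr1", 9500, 10300, id = "y"), tads)
  expect_equal(b$tad, "A")
  # midpoint beyond all TADs -> unassigned
  c_ <- assignToTads(bedRanges("chr1", 25000, 26000, id = "z"), tads)
  expect_true(is.na(c_$tad))
  # element on a chromosome without TADs
  d <- assignToTads(bedRanges("chr9", 100, 200, id = "w"), tads)
  expect_true(is.na(d$tad))
  # overlapping TADs are rejected
  expect_error(
    assignToTads(bedRanges("chr1", 1, 2),
                 bedRanges("chr1", c(0, 5000), c(10000, 15000))),
    "overlapping")
})

test_that("pair enumeration is the TAD-restricted product with geometry", {
  tads <- bedRanges("chr1", c(0, 1e6), c(1e6, 2e6), id = c("tadA", "tadB"))
  cat <- mkCatalog(ocgiStarts = 9750, enhStarts = 500000,
                   tssPos = c(20000, 300000, 600000))
  pairs <- enumeratePairs(cat, tads)
  # 1 oCGI x 3 genes + 1 enhancer x 3 genes, all in tadA
  expect_equal(nrow(pairs), 6)
  expect_true(all(pairs$tad_id == "tadA"))

  # oCGI midpoint 10000; target gene_3 at 600000: distance and intervening
  p3 <- pairs[pairs$element_kind == "oCGI" & pairs$gene_id == "gene_3", ]
  expect_equal(p3$distance, 590000L)
  expect_equal(p3$n_intervening_genes, 2L)
  expect_false(p3$adjacent)
  p1 <- pairs[pairs$element_kind == "oCGI" & pairs$gene_id == "gene_1", ]
  expect_equal(p1$n_intervening_genes, 0L)
  expect_true(p1$adjacent)
})

test_that("elements and genes in different TADs are never paired", {
  tads <- bedRanges("chr1", c(0, 1e5), c(1e5, 2e5), id = c("A", "B"))
  cat <- mkCatalog(ocgiStarts = 1000, enhStarts = 2000, tssPos = 150000)
  pairs <- enumeratePairs(cat, tads)
  expect_equal(nrow(pairs), 0)
})

test_that("pair counts match the brute-force double loop and ignore ordering", {
  set.seed(7)
  tads <- bedRanges("chr1", seq(0, 4e5, 1e5), seq(1e5, 5e5, 1e5),
                    id = sprintf("t%d", 1:5))
  cat <- mkCatalog(ocgiStarts = sample(0:490000, 8),
                   enhStarts = sample(0:490000, 6),
                   tssPos = sample(0:499000, 10))
  pairs <- enumeratePairs(cat, tads)

  bruteCount <- function(el, genes) {
    tadOf <- function(pos) {
      hit <- which(bedStart(tads) <= pos & pos < bedEnd(tads))
      if (length(hit)) names(tads)[hit] else NA
    }
    n <- 0
    for (i in seq_along(el)) {
      tm <- tadOf(floor((bedStart(el)[i] + bedEnd(el)[i]) / 2))
      for (j in seq_along(genes)) {
        tg <- tadOf(bedStart(genes)[j])
        if (!is.na(tm) && !is.na(tg) && tm == tg) n <- n + 1
      }
    }
    n
  }
  expected <- bruteCount(orphanCgis(cat), geneAnnotation(cat)) +
    bruteCount(enhancers(cat), geneAnnotation(cat))
  expect_equal(nrow(pairs), expected)

  # permuting the inputs leaves the sorted pair table unchanged
  cat2 <- mkCatalog(ocgiStarts = rev(bedStart(orphanCgis(cat))),
                    enhStarts = rev(bedStart(enhancers(cat))),
                    tssPos = rev(bedStart(geneAnnotation(cat))))
  # rebuild ids so reversed inputs name the same elements
  pairs2 <- enumeratePairs(cat2, tads)
  key <- function(p) sort(paste(p$distance, p$n_intervening_genes, p$element_kind))
  expect_equal(key(pairs2), key(pairs))
})

test_that("geometry summary bins long-range pairs and reports adjacency", {
  pairs <- data.frame(
    element_id = c("a", "a", "b"), element_kind = "oCGI",
    gene_id = c("g1", "g2", "g3"), tad_id = "t",
    distance = c(5000, 750000, 1200000),
    n_intervening_genes = c(0L, 3L, 5L),
    adjacent = c(TRUE, FALSE, FALSE))
  gs <- geometrySummary(pairs)
  dh <- gs$distanceHistogram
  expect_equal(dh$count[dh$bin == ">500kb"], 1L)
  expect_equal(dh$count[dh$bin == ">1000kb"], 1L)
  expect_equal(unname(gs$adjacencyFraction["oCGI"]), 1 / 3)
  tpe <- gs$targetsPerElement
  expect_equal(tpe$n_elements[tpe$n_targets == 2], 1L)  # element a
  expect_equal(tpe$n_elements[tpe$n_targets == 1], 1L)  # element b

  allAdj <- pairs; allAdj$adjacent <- TRUE
  expect_equal(unname(geometrySummary(allAdj)$adjacencyFraction["oCGI"]), 1)
  empty <- geometrySummary(pairs[0, ])
  expect_equal(nrow(empty$distanceHistogram), 0)
})

test_that("every emitted pair shares a TAD between element and gene", {
  cfg <- simulationConfig(seed = 3, nSamples = 20, nTads = 6,
                          genesPerTad = 2)
  b <- simulateBundle(cfg)
  win <- expandAndMergeCgis(b$cgis)
  cat <- classifyCgis(win, definePromoters(b$genes), b$enhancers, b$genes)
  pairs <- enumeratePairs(cat, b$tads)
  ea <- assignToTads(c(GenomicRanges::granges(orphanCgis(cat)),
                       GenomicRanges::granges(b$enhancers)),
                     b$tads)
  ga <- assignToTads(b$genes, b$tads, anchor = "tss")
  for (i in seq_len(nrow(pairs))) {
    expect_equal(ea$tad[ea$id == pairs$element_id[i]],
                 ga$tad[ga$id == pairs$gene_id[i]])
  }
  # 6 TADs x (1 oCGI + 1 enhancer) x 2 genes
  expect_equal(nrow(pairs), 24)
})
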