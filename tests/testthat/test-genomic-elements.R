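test_that("CGI expansion centers a 500 bp window on the midpoint", {
  w <- expandAndMergeCgis(bedRanges("chr1", 1000, 1100))
  expect_equal(bedStart(w), 800)
  expect_equal(bedEnd(w), 1300)
  expect_equal(GenomicRanges::width(w), 500)
  expect_false(S4Vectors::mcols(w)$merged)
})

test_that("overlapping windows merge into their union, chromosomes never merge", {
  w <- expandAndMergeCgis(bedRanges(c("chr1", "chr1"), c(1000, 1400),
                                    c(1100, 1500)))
  expect_length(w, 1)
  expect_equal(bedStart(w), 800)
  expect_equal(bedEnd(w), 1700)
  expect_true(S4Vectors::mcols(w)$merged)
  expect_equal(S4Vectors::mcols(w)$nSource, 2L)

  w2 <- expandAndMergeCgis(bedRanges(c("chr1", "chr2"), c(1000, 1000),
                                     c(1100, 1100)))
  expect_length(w2, 2)
})

test_that("windows below zero are clamped and flagged; long CGIs keep their span", {
  w <- expandAndMergeCgis(bedRanges("chr1", 50, 150))  # midpoint 100
  expect_equal(bedStart(w), 0)
  expect_equal(bedEnd(w), 350)
  expect_true(S4Vectors::mcols(w)$clamped)

  long <- expandAndMergeCgis(bedRanges("chr1", 1000, 2000))  # width 1000
  expect_equal(bedStart(long), 1000)  # union keeps all covered bases
  expect_equal(bedEnd(long), 2000)
  expect_true(S4Vectors::mcols(long)$longCgi)
})

test_that("expansion is idempotent and unmerged outputs are 500 bp", {
  set.seed(41)
  starts <- sort(sample(0:50000, 40))
  cgis <- bedRanges("chr1", starts,
                    starts + sample(80:600, 40, replace = TRUE))
  w1 <- expandAndMergeCgis(cgis)
  w2 <- expandAndMergeCgis(w1)
  expect_equal(bedStart(w2), bedStart(w1))
  expect_equal(bedEnd(w2), bedEnd(w1))
  plain <- !S4Vectors::mcols(w1)$merged & !S4Vectors::mcols(w1)$clamped &
    !S4Vectors::mcols(w1)$longCgi
  expect_true(all(GenomicRanges::width(w1)[plain] == 500))
  expect_true(GenomicRanges::isDisjoint(w1))
})

test_that("promoters extend 1500 bp upstream / 500 bp downstream by strand", {
  p <- definePromoters(bedRanges("chr1", 5000, 5001, strand = "+", id = "g"))
  expect_equal(bedStart(p), 3500)
  expect_equal(bedEnd(p), 5500)

  m <- definePromoters(bedRanges("chr1", 5000, 5001, strand = "-", id = "g"))
  expect_equal(bedStart(m), 4500)
  expect_equal(bedEnd(m), 6500)

  cl <- definePromoters(bedRanges("chr1", 1000, 1001, strand = "+"))
  expect_equal(bedStart(cl), 0)
  expect_equal(bedEnd(cl), 1500)
  expect_true(S4Vectors::mcols(cl)$clamped)

  expect_error(definePromoters(bedRanges("chr1", 5000, 5001, strand = "*")),
               "strand")
})

test_that("gene-body inputs anchor the promoter at the strand-aware TSS", {
  p <- definePromoters(bedRanges("chr1", 5000, 9000, strand = "+", id = "g"))
  expect_equal(c(bedStart(p), bedEnd(p)), c(3500, 5500))
  m <- definePromoters(bedRanges("chr1", 5000, 9000, strand = "-", id = "g"))
  expect_equal(c(bedStart(m), bedEnd(m)), c(8500, 10500))
})

test_that("CGI classification: promoter beats enhancer, abutting is no overlap", {
  win <- bedRanges("chr1", 800, 1300, id = "w1")
  promFar <- bedRanges("chr1", 5000, 7000)
  enhFar <- bedRanges("chr1", 100, 200)

  cat1 <- classifyCgis(win, bedRanges("chr1", 1200, 1400), enhFar)
  expect_equal(unname(cgiClass(cat1)), "promoter_overlap")
  expect_length(orphanCgis(cat1), 0)

  cat2 <- classifyCgis(win, promFar, enhFar)
  expect_equal(unname(cgiClass(cat2)), "orphan")

  # exactly abutting promoter (end == promoter start): half-open, no overlap
  cat3 <- classifyCgis(win, bedRanges("chr1", 1300, 1500), enhFar)
  expect_equal(unname(cgiClass(cat3)), "orphan")

  # enhancer overlap only
  cat4 <- classifyCgis(win, promFar, bedRanges("chr1", 1250, 1350))
  expect_equal(unname(cgiClass(cat4)), "enhancer_overlap")
})

test_that("genic overlap is secondary and does not disqualify orphans", {
  win <- bedRanges("chr1", 800, 1300, id = "w1")
  cat <- classifyCgis(win, bedRanges("chr1", 5000, 7000),
                      bedRanges("chr1", 100, 200),
                      genes = bedRanges("chr1", 900, 4000))
  expect_equal(unname(cgiClass(cat)), "orphan")
  expect_true(S4Vectors::mcols(cgis(cat))$genic)
  comp <- compositionTable(cat)
  expect_equal(comp$n_genic[comp$class == "orphan"], 1L)
})

test_that("classification partitions the windows and matches the all-pairs oracle", {
  set.seed(99)
  nw <- 60
  ws <- sort(sample(0:100000, nw))
  ps <- sample(0:100000, 20)
  es <- sample(0:100000, 20)
  win <- bedRanges("chr1", ws, ws + 500, id = sprintf("w%d", 1:nw))
  prom <- bedRanges("chr1", ps, ps + 2000)
  enh <- bedRanges("chr1", es, es + 400)
  cat <- classifyCgis(win, prom, enh)
  cls <- cgiClass(cat)
  expect_equal(length(cls), nw)  # every window classified exactly once
  expect_equal(sum(table(cls)), nw)

  qdf <- data.frame(chrom = "chr1", start0 = bedStart(win),
                    end0 = bedEnd(win))
  inProm <- overlapsAnyOracle(qdf, data.frame(chrom = "chr1",
                                              start0 = bedStart(prom),
                                              end0 = bedEnd(prom)))
  inEnh <- overlapsAnyOracle(qdf, data.frame(chrom = "chr1",
                                             start0 = bedStart(enh),
                                             end0 = bedEnd(enh)))
  expected <- ifelse(inProm, "promoter_overlap",
                     ifelse(inEnh, "enhancer_overlap", "orphan"))
  expect_equal(unname(cls), expected)
})

test_that("empty CGI input yields an empty catalog, not an error", {
  cat <- classifyCgis(GenomicRanges::GRanges(),
                      bedRanges("chr1", 1, 10), bedRanges("chr1", 20, 30))
  expect_s4_class(cat, "ElementCatalog")
  expect_length(cgis(cat), 0)
})

test_that("BED round-trip preserves 0-based half-open coordinates", {
  gr <- bedRanges(c("chr1", "chr2"), c(0, 999), c(500, 1500),
                  strand = c("+", "-"), id = c("a", "b"))
  f <- tempfile(fileext = ".bed")
  writeBed(gr, f)
  back <- readBed(f)
  expect_equal(bedStart(back), c(0, 999))
  expect_equal(bedEnd(back), c(500, 1500))
  expect_equal(names(back), c("a", "b"))
  expect_equal(as.character(GenomicRanges::strand(back)), c("+", "-"))
})
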