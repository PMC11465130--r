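#' Simulation configuration for synthetic triplet bundles
#'
#' Collects the generating conditions for the synthetic-data module:
#' sample size, cluster composition, edge effect sizes, the Beta
#' distributions anchoring the methylation states, noise levels,
#' missingness, and toy-genome geometry. Defaults describe a two-cluster
#' cohort of 300 samples with strong regulatory effects.
#'
#' Direction is simulated by drawing the structure's source element(s)
#' from different Beta distributions per cluster: for single-source
#' structures the source moves across states (hyper in the up-regulated
#' cluster's counterpart, hypo in it); for the co-dominated collider both
#' sources get only a mild within-hemi shift (`coShiftShapes`), because a
#' large shared cluster effect would destroy the marginal O/E independence
#' that identifies the collider.
#'
#' @param seed integer seed (mandatory for emission).
#' @param nSamples number of samples.
#' @param clusterFractions named fractions for C1/C2 (sum to 1).
#' @param direction intended direction, `"C2_UP"`, `"C1_UP"` or `"none"`
#'   (no cluster effect).
#' @param effectSize standardized magnitude of methylation-to-expression
#'   edges (applied with negative sign: methylation represses).
#' @param methylEdgeCoef beta-scale coefficient of
#'   methylation-to-methylation edges.
#' @param methylEdgeNoiseSd beta-scale noise sd of child methylation
#'   nodes (noise redrawn when a draw would leave \[0, 1\]).
#' @param exprBaseline mean log-scale expression.
#' @param exprNoiseSd log-scale expression noise sd.
#' @param betaShapes list of Beta shape pairs for `hypo`, `hemi`,
#'   `hyper` state draws.
#' @param coShiftShapes list of Beta shape pairs `up`/`down` for the mild
#'   co-dominated cluster shift.
#' @param spreadShapes Beta shape pair for unshifted root draws in
#'   no-cluster simulations (broad support so edges carry signal).
#' @param missingRate MCAR missingness rate of emitted probe values, in
#'   \[0, 0.5\].
#' @param probeNoiseSd logit-scale sd of probe values around regional
#'   means.
#' @param nTads number of TADs (one triplet each).
#' @param genesPerTad genes per TAD; the first is the triplet target,
#'   additional genes are unregulated decoys (independent expression).
#' @param probesPerElement probes emitted per element.
#' @param tadWidth TAD width in bp.
#' @param structures generating model ids, recycled over TADs.
#' @return a `simulationConfig` list.
#' @export
simulationConfig <- function(seed,
                             nSamples = 300L,
                             clusterFractions = c(C1 = 0.5, C2 = 0.5),
                             direction = "C2_UP",
                             effectSize = 1,
                             methylEdgeCoef = 0.9,
                             methylEdgeNoiseSd = 0.08,
                             exprBaseline = 4,
                             exprNoiseSd = 0.5,
                             betaShapes = list(hypo = c(2, 8),
                                               hemi = c(5, 5),
                                               hyper = c(8, 2)),
                             coShiftShapes = list(up = c(10.33, 9.67),
                                                  down = c(9.67, 10.33)),
                             spreadShapes = c(2, 2),
                             missingRate = 0.02,
                             probeNoiseSd = 0.15,
                             nTads = 100L,
                             genesPerTad = 1L,
                             probesPerElement = 3L,
                             tadWidth = 1e5,
                             structures = c("oCGI_cascade",
                                            "enhancer_cascade",
                                            "oCGI_composite",
                                            "co_dominated")) {
  stopifnot(abs(sum(clusterFractions) - 1) < 1e-9,
            missingRate >= 0, missingRate <= 0.5,
            is.finite(effectSize))
  cfg <- list(seed = as.integer(seed), nSamples = as.integer(nSamples),
              clusterFractions = clusterFractions, direction = direction,
              effectSize = effectSize, methylEdgeCoef = methylEdgeCoef,
              methylEdgeNoiseSd = methylEdgeNoiseSd,
              exprBaseline = exprBaseline,
              exprNoiseSd = exprNoiseSd, betaShapes = betaShapes,
              coShiftShapes = coShiftShapes, spreadShapes = spreadShapes,
              missingRate = missingRate, probeNoiseSd = probeNoiseSd,
              nTads = as.integer(nTads),
              genesPerTad = as.integer(genesPerTad),
              probesPerElement = as.integer(probesPerElement),
              tadWidth = tadWidth, structures = structures)
  class(cfg) <- "simulationConfig"
  cfg
}

.clampBeta <- function(b) pmin(pmax(b, 1e-6), 1 - 1e-6)

# derive a per-triplet substream seed below 2^31
.substreamSeed <- function(seed, i) {
  as.integer((as.numeric(seed) + 1000003 * i) %% 2147483647)
}

.clusterVector <- function(config) {
  n1 <- round(config$nSamples * config$clusterFractions[["C1"]])
  factor(c(rep("C1", n1), rep("C2", config$nSamples - n1)),
         levels = c("C1", "C2"))
}

#' Simulate one triplet under a regulatory structure
#'
#' Samples (O, E, G) forward along the structure's factorization: source
#' methylation nodes from Beta distributions (per cluster when a direction
#' is simulated), child methylation nodes through a linear link on the
#' beta scale (noise redrawn to keep values in \[0, 1\]), and log-scale
#' expression linearly on its standardized methylation parents (negative
#' coefficients: methylation represses) with Gaussian noise, mapped to the
#' natural scale as `expm1` so that the model backend's `log1p` recovers
#' the generating scale exactly. Uses the current RNG stream; bundle
#' emission derives a per-triplet substream from (seed, triplet index).
#'
#' @param model a [ModelSpec-class] or model id.
#' @param config a [simulationConfig()].
#' @param clusters optional factor of C1/C2 per sample; derived from the
#'   config fractions when `NULL`.
#' @return list with numeric vectors `o`, `e` (beta values), `g`
#'   (expression, natural scale), `clusters`, and `truth` (generating
#'   model, equivalence class, intended direction, edge coefficients).
#' @export
simulateTriplet <- function(model, config, clusters = NULL) {
  if (is.character(model)) model <- enumerateModels()[[model]]
  if (is.null(model)) stop("unknown model")
  if (is.null(clusters)) clusters <- .clusterVector(config)
  n <- length(clusters)
  edges <- model@edges
  methNodes <- c("O", "E")
  roots <- methNodes[!methNodes %in% edges[, 2]]
  deg <- vapply(methNodes, function(nd) sum(edges == nd), integer(1))
  sources <- if (model@id == "co_dominated") c("O", "E")
  else methNodes[deg > 0 & !methNodes %in% edges[, 2]]
  withClusters <- config$direction %in% c("C1_UP", "C2_UP") &&
    nlevels(droplevels(clusters)) == 2
  upCluster <- if (config$direction == "C2_UP") "C2" else "C1"

  drawRoot <- function(node) {
    if (!withClusters || !node %in% sources) {
      if (!node %in% sources && length(sources) > 0 && withClusters) {
        # isolated element in a direct model: hemi draw, no cluster effect
        sh <- config$betaShapes$hemi
      } else sh <- config$spreadShapes
      return(stats::rbeta(n, sh[1], sh[2]))
    }
    if (model@id == "co_dominated") {
      shUp <- config$coShiftShapes$down   # lower methylation when "up"
      shDown <- config$coShiftShapes$up
    } else {
      shUp <- config$betaShapes$hypo
      shDown <- config$betaShapes$hyper
    }
    b <- numeric(n)
    isUp <- clusters == upCluster
    b[isUp] <- stats::rbeta(sum(isUp), shUp[1], shUp[2])
    b[!isUp] <- stats::rbeta(sum(!isUp), shDown[1], shDown[2])
    b
  }

  vals <- list()
  coefs <- list()
  # topological order over O, E (G is always terminal)
  methOrder <- if (any(edges[, 2] %in% methNodes)) {
    child <- edges[edges[, 2] %in% methNodes, 2]
    c(setdiff(methNodes, child), child)
  } else methNodes
  for (node in methOrder) {
    pa <- .parentsOf(edges, node)
    if (length(pa) == 0) {
      vals[[node]] <- drawRoot(node)
    } else {
      mu <- 0.5 + config$methylEdgeCoef * (vals[[pa]] - mean(vals[[pa]]))
      b <- mu + stats::rnorm(n, 0, config$methylEdgeNoiseSd)
      for (tries in 1:50) {          # redraw noise for out-of-range values
        bad <- b <= 0 | b >= 1
        if (!any(bad)) break
        b[bad] <- mu[bad] + stats::rnorm(sum(bad), 0,
                                         config$methylEdgeNoiseSd)
      }
      vals[[node]] <- .clampBeta(b)
      coefs[[paste0(pa, "->", node)]] <- config$methylEdgeCoef
    }
  }
  paG <- .parentsOf(edges, "G")
  y <- rep(config$exprBaseline, n)
  for (p in paG) {
    bp <- vals[[p]]
    y <- y - config$effectSize * (bp - mean(bp)) / stats::sd(bp)
    coefs[[paste0(p, "->G")]] <- -config$effectSize
  }
  y <- y + stats::rnorm(n, 0, config$exprNoiseSd)
  list(o = vals$O, e = vals$E, g = expm1(pmax(y, 1e-6)),
       clusters = clusters,
       truth = list(model = model@id, equivClass = model@equivClass,
                    direction = if (withClusters) config$direction
                    else "none",
                    coefficients = coefs))
}

#' Simulate a full multi-TAD bundle in memory
#'
#' Lays out a toy genome of `nTads` adjacent TADs on `chr1`, each
#' containing one CpG island (away from any promoter or enhancer, so its
#' expanded window classifies as orphan), one enhancer and one gene; every
#' fifth TAD additionally carries a decoy CGI overlapping the promoter to
#' exercise classification. Each TAD's triplet is simulated under the
#' config's generating structures (recycled), probe-level beta values are
#' drawn around the regional means with logit-normal noise plus MCAR
#' missingness, and a ground-truth manifest records the generating model,
#' equivalence class and intended direction per triplet. Deterministic
#' given the seed (per-triplet substreams).
#'
#' @param config a [simulationConfig()].
#' @return list with `cgis`, `enhancers`, `tads`, `genes` (GRanges),
#'   `probes` (GRanges), `beta` (probes x samples with missingness),
#'   `expr`, `labels`, `snpProbes`, `truth` (data.frame) and `config`.
#' @export
simulateBundle <- function(config) {
  nT <- config$nTads
  w <- config$tadWidth
  off <- function(i, o) as.integer((i - 1) * w + o)
  clusters <- .clusterVector(config)
  samples <- sprintf("S%03d", seq_len(config$nSamples))
  models <- enumerateModels()
  structIds <- rep_len(config$structures, nT)

  tads <- bedRanges("chr1", off(seq_len(nT), 0), off(seq_len(nT), w),
                    id = sprintf("tad_%d", seq_len(nT)))
  cgis <- bedRanges("chr1", off(seq_len(nT), 10000),
                    off(seq_len(nT), 10300),
                    id = sprintf("cgi_%d", seq_len(nT)))
  decoyTads <- seq_len(nT)[seq_len(nT) %% 5L == 0L]
  if (length(decoyTads) > 0) {
    decoys <- bedRanges("chr1", off(decoyTads, 68600), off(decoyTads, 68800),
                        id = sprintf("cgi_decoy_%d", decoyTads))
    cgis <- c(cgis, decoys)
  }
  enh <- bedRanges("chr1", off(seq_len(nT), 40000), off(seq_len(nT), 40400),
                   id = sprintf("enh_%d", seq_len(nT)))
  nG <- config$genesPerTad
  tadOfGene <- rep(seq_len(nT), each = nG)
  gOff <- 70000 + (rep(seq_len(nG), nT) - 1) * 8000
  geneIds <- ifelse(rep(seq_len(nG), nT) == 1,
                    sprintf("gene_%d", tadOfGene),
                    sprintf("gene_%d_decoy%d", tadOfGene,
                            rep(seq_len(nG), nT) - 1))
  genes <- .pointRanges("chr1", off(tadOfGene, gOff), id = geneIds)
  GenomicRanges::strand(genes) <- "+"
  S4Vectors::mcols(genes)$gene_id <- names(genes)

  nP <- config$probesPerElement
  beta <- matrix(NA_real_, nrow = 2 * nT * nP, ncol = config$nSamples)
  colnames(beta) <- samples
  probeIds <- character(nrow(beta))
  probePos <- integer(nrow(beta))
  expr <- matrix(NA_real_, length(genes), config$nSamples,
                 dimnames = list(names(genes), samples))
  truth <- vector("list", nT)

  for (i in seq_len(nT)) {
    set.seed(.substreamSeed(config$seed, i))
    sim <- simulateTriplet(models[[structIds[i]]], config, clusters)
    expr[sprintf("gene_%d", i), ] <- sim$g
    if (nG > 1) {
      for (k in 2:nG)
        expr[sprintf("gene_%d_decoy%d", i, k - 1), ] <-
          expm1(stats::rnorm(config$nSamples, config$exprBaseline, 1))
    }
    regional <- list(o = sim$o, e = sim$e)
    anchors <- list(o = 10050L, e = 40050L)
    prefix <- list(o = sprintf("cgi_%d", i), e = sprintf("enh_%d", i))
    for (elk in c("o", "e")) {
      lb <- stats::qlogis(.clampBeta(regional[[elk]]))
      for (j in seq_len(nP)) {
        ridx <- (i - 1) * 2 * nP + (match(elk, c("o", "e")) - 1) * nP + j
        probeIds[ridx] <- sprintf("p_%s_%d", prefix[[elk]], j)
        probePos[ridx] <- off(i, anchors[[elk]] + (j - 1) * 60L)
        beta[ridx, ] <- stats::plogis(
          lb + stats::rnorm(config$nSamples, 0, config$probeNoiseSd))
      }
    }
    truth[[i]] <- data.frame(
      triplet_id = sprintf("triplet_%d", i),
      tad_id = sprintf("tad_%d", i),
      ocgi_id = sprintf("cgi_%d", i),
      enhancer_id = sprintf("enh_%d", i),
      gene_id = sprintf("gene_%d", i),
      model = sim$truth$model,
      equiv_class = sim$truth$equivClass,
      direction = sim$truth$direction,
      stringsAsFactors = FALSE)
  }
  rownames(beta) <- probeIds
  set.seed(.substreamSeed(config$seed, 0L))
  if (config$missingRate > 0) {
    mask <- stats::runif(length(beta)) < config$missingRate
    beta[mask] <- NA_real_
  }
  probes <- .pointRanges("chr1", probePos, id = probeIds)
  list(cgis = cgis, enhancers = enh, tads = tads, genes = genes,
       probes = probes, beta = beta, expr = expr,
       labels = stats::setNames(as.character(clusters), samples),
       snpProbes = character(),
       truth = do.call(rbind, truth), config = config)
}

#' Write a synthetic fixture bundle to disk
#'
#' Emits the bundle of [simulateBundle()] as plain-text files: BED for
#' CGIs, enhancers and TADs; TSV for gene annotation, probe manifest,
#' probe-level beta matrix (with missingness), expression and cluster
#' labels; a SNP-probe exclusion list; and the ground-truth manifest as
#' JSON. Byte-identical across runs with the same config.
#'
#' @param config a [simulationConfig()].
#' @param dir output directory (created if needed).
#' @return named character vector of written paths, invisibly.
#' @export
emitFixtureBundle <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  bundle <- simulateBundle(config)
  paths <- c(
    cgis = file.path(dir, "cgis.bed"),
    enhancers = file.path(dir, "enhancers.bed"),
    tads = file.path(dir, "tads.bed"),
    genes = file.path(dir, "genes.tsv"),
    probes = file.path(dir, "probes.tsv"),
    beta = file.path(dir, "beta.tsv"),
    expr = file.path(dir, "expression.tsv"),
    labels = file.path(dir, "labels.tsv"),
    snps = file.path(dir, "snp_probes.txt"),
    truth = file.path(dir, "truth.json"))
  writeBed(bundle$cgis, paths["cgis"])
  writeBed(bundle$enhancers, paths["enhancers"])
  writeBed(bundle$tads, paths["tads"])
  utils::write.table(
    data.frame(gene_id = names(bundle$genes),
               chrom = as.character(GenomicRanges::seqnames(bundle$genes)),
               tss = bedStart(bundle$genes),
               strand = as.character(GenomicRanges::strand(bundle$genes))),
    paths["genes"], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(probe_id = names(bundle$probes),
               chrom = as.character(GenomicRanges::seqnames(bundle$probes)),
               pos = bedStart(bundle$probes)),
    paths["probes"], sep = "\t", quote = FALSE, row.names = FALSE)
  writeMatrixTsv(bundle$beta, paths["beta"], idColumn = "probe_id")
  writeMatrixTsv(bundle$expr, paths["expr"], idColumn = "gene_id")
  utils::write.table(
    data.frame(sample_id = names(bundle$labels), cluster = bundle$labels),
    paths["labels"], sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(bundle$snpProbes, paths["snps"])
  jsonlite::write_json(
    list(seed = config$seed, n_samples = config$nSamples,
         structures = config$structures, direction = config$direction,
         triplets = bundle$truth),
    paths["truth"], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}
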