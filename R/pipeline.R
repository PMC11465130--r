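#' Read and validate a pipeline configuration
#'
#' The configuration (a YAML file or an R list) names the input files, the
#' output directory and the stage parameters. Required inputs: `cgis`,
#' `enhancers`, `tads`, `genes`, `beta`, `probes`, `expression`,
#' `labels`; optional: `snp_probes`. Parameters (with defaults): `k` 10,
#' `rowmax` 0.5, `colmax` 0.8, `bins` 3, `n_perm` 999, `alpha` 0.05,
#' `backend` "gaussian", `seed` (mandatory: the permutation screen is
#' seeded).
#'
#' @param config path to a YAML file or a named list.
#' @return validated config list.
#' @export
readPipelineConfig <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  need <- c("cgis", "enhancers", "tads", "genes", "beta", "probes",
            "expression", "labels")
  missingIn <- setdiff(need, names(config$inputs))
  if (length(missingIn) > 0)
    stop("config inputs missing: ", paste(missingIn, collapse = ", "))
  if (is.null(config$out_dir)) stop("config needs out_dir")
  defaults <- list(k = 10L, rowmax = 0.5, colmax = 0.8, bins = 3L,
                   n_perm = 999L, alpha = 0.05, backend = "gaussian")
  for (p in names(defaults))
    if (is.null(config$params[[p]])) config$params[[p]] <- defaults[[p]]
  if (is.null(config$params$seed))
    stop("config needs params$seed (permutation screen is seeded)")
  config
}

.provenancePath <- function(outDir, stage)
  file.path(outDir, sprintf("provenance_%s.json", stage))

.stageProvenance <- function(inputs, params) {
  sums <- vapply(inputs, function(f)
    unname(tools::md5sum(f)), character(1))
  list(inputs = as.list(sums), params = params,
       version = as.character(utils::packageVersion("tripletCis")))
}

.stageCached <- function(outDir, stage, prov, outputs) {
  pp <- .provenancePath(outDir, stage)
  if (!file.exists(pp) || !all(file.exists(outputs))) return(FALSE)
  old <- jsonlite::read_json(pp, simplifyVector = TRUE)
  identical(old$inputs, lapply(prov$inputs, identity)) &&
    identical(as.character(old$params), as.character(prov$params))
}

.writeProvenance <- function(outDir, stage, prov) {
  jsonlite::write_json(prov, .provenancePath(outDir, stage),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Run the full triplet cis-regulation pipeline
#'
#' Executes the stages elements, preprocess, pairs, screen, fit and score
#' in order over plain-file handoffs (TSV/BED/JSON) in `out_dir`. Each
#' stage writes its tables plus a provenance record (input checksums,
#' parameters, package version); a rerun with unchanged inputs and
#' parameters skips completed stages ("cached"). Stage progress is logged
#' to stderr. Two runs with identical config, inputs and seed produce
#' identical output files.
#'
#' @param config a config list or YAML path (see [readPipelineConfig()]).
#' @return invisible list: per-stage status (`"run"`/`"cached"`) and the
#'   paths of the final tables.
#' @export
runPipeline <- function(config) {
  cfg <- readPipelineConfig(config)
  outDir <- cfg$out_dir
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  inp <- cfg$inputs
  par <- cfg$params
  status <- list()
  log <- function(stage, msg) message(sprintf("[%s] %s", stage, msg))

  runStage <- function(stage, inFiles, params, outputs, fun) {
    prov <- .stageProvenance(inFiles, params)
    if (.stageCached(outDir, stage, prov, outputs)) {
      log(stage, "cached")
      status[[stage]] <<- "cached"
      return(invisible(NULL))
    }
    log(stage, "running")
    fun()
    .writeProvenance(outDir, stage, prov)
    status[[stage]] <<- "run"
  }

  p <- function(...) file.path(outDir, ...)

  # 1. elements: oCGI definition
  runStage("elements",
           c(inp$cgis, inp$enhancers, inp$genes), list(),
           c(p("classified_cgis.bed"), p("composition.tsv"),
             p("ocgi_windows.bed"), p("regions.bed")),
           function() {
    cgis <- readBed(inp$cgis)
    enh <- readBed(inp$enhancers)
    genes <- readGeneAnnotation(inp$genes)
    win <- expandAndMergeCgis(cgis)
    prom <- definePromoters(genes)
    cat <- classifyCgis(win, prom, enh)
    writeCatalog(cat, p("classified_cgis.bed"), p("composition.tsv"))
    writeBed(orphanCgis(cat), p("ocgi_windows.bed"))
    regions <- c(GenomicRanges::granges(orphanCgis(cat)),
                 GenomicRanges::granges(enh))
    names(regions) <- c(names(orphanCgis(cat)), .elementIds(enh, "enh"))
    writeBed(regions, p("regions.bed"))
  })

  # 2. preprocess: QC + imputation
  runStage("preprocess",
           c(inp$beta,
             if (!is.null(inp$snp_probes)) inp$snp_probes),
           par[c("k", "rowmax", "colmax")],
           c(p("beta_imputed.tsv"), p("qc_report.json")),
           function() {
    beta <- readMatrixTsv(inp$beta)
    snps <- if (!is.null(inp$snp_probes)) readLines(inp$snp_probes)
    else character()
    qc <- qcFilterBeta(beta, snps)
    imp <- knnImputeBeta(qc$beta, k = par$k, rowmax = par$rowmax,
                         colmax = par$colmax)
    writeMatrixTsv(imp, p("beta_imputed.tsv"), idColumn = "probe_id")
    jsonlite::write_json(qc$report, p("qc_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  })

  # 3. pairs: region aggregation + TAD-constrained pairing
  runStage("pairs",
           c(p("regions.bed"), p("ocgi_windows.bed"),
             p("beta_imputed.tsv"), inp$probes, inp$tads, inp$genes,
             inp$enhancers),
           list(),
           c(p("region_beta.tsv"), p("pairs.tsv")),
           function() {
    regions <- readBed(p("regions.bed"))
    probes <- readProbeManifest(inp$probes)
    imp <- readMatrixTsv(p("beta_imputed.tsv"))
    rb <- aggregateRegionBeta(imp, probes, regions)
    writeMatrixTsv(regionBeta(rb), p("region_beta.tsv"),
                   idColumn = "region_id")
    win <- readBed(p("ocgi_windows.bed"))
    mc <- S4Vectors::DataFrame(cgiClass = factor(
      rep("orphan", length(win)),
      levels = c("orphan", "promoter_overlap", "enhancer_overlap")),
      genic = rep(FALSE, length(win)))
    S4Vectors::mcols(win) <- mc
    cat <- methods::new("ElementCatalog", cgis = win,
                        enhancers = readBed(inp$enhancers),
                        promoters = GenomicRanges::GRanges(),
                        genes = readGeneAnnotation(inp$genes))
    pairs <- enumeratePairs(cat, readBed(inp$tads))
    utils::write.table(pairs, p("pairs.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  })

  # 4. screen: MI + permutation p + BH; triplet assembly
  runStage("screen",
           c(p("pairs.tsv"), p("region_beta.tsv"), inp$expression),
           par[c("bins", "n_perm", "alpha", "seed")],
           c(p("associations.tsv"), p("triplets.tsv")),
           function() {
    pairs <- utils::read.table(p("pairs.tsv"), sep = "\t", header = TRUE,
                               stringsAsFactors = FALSE)
    rb <- readMatrixTsv(p("region_beta.tsv"))
    expr <- readMatrixTsv(inp$expression)
    rb <- rb[stats::complete.cases(rb), , drop = FALSE]  # 0-probe regions
    pairs <- pairs[pairs$element_id %in% rownames(rb), , drop = FALSE]
    assoc <- screenAssociations(pairs, rb, expr, bins = par$bins,
                                nPerm = par$n_perm, seed = par$seed)
    utils::write.table(assoc, p("associations.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    trip <- buildTriplets(assoc, alpha = par$alpha)
    utils::write.table(trip, p("triplets.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  })

  # 5. fit: nine-model selection per triplet
  runStage("fit",
           c(p("triplets.tsv"), p("region_beta.tsv"), inp$expression),
           par[c("backend", "alpha")],
           p("triplet_calls.tsv"),
           function() {
    trip <- utils::read.table(p("triplets.tsv"), sep = "\t", header = TRUE,
                              stringsAsFactors = FALSE)
    rb <- readMatrixTsv(p("region_beta.tsv"))
    expr <- readMatrixTsv(inp$expression)
    calls <- callTriplets(trip, rb, expr, backend = par$backend,
                          alpha = par$alpha)
    utils::write.table(calls, p("triplet_calls.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  })

  # 6. score: concordance direction + cis scores
  runStage("score",
           c(p("triplet_calls.tsv"), p("region_beta.tsv"),
             inp$expression, inp$labels),
           list(),
           c(p("concordant_triplets.tsv"), p("cis_scores.tsv"),
             p("genes_C1_UP.txt"), p("genes_C2_UP.txt")),
           function() {
    calls <- utils::read.table(p("triplet_calls.tsv"), sep = "\t",
                               header = TRUE, stringsAsFactors = FALSE)
    rb <- readMatrixTsv(p("region_beta.tsv"))
    expr <- readMatrixTsv(inp$expression)
    labels <- readClusterLabels(inp$labels)
    conc <- concordanceFilter(calls, rb, expr, labels)
    utils::write.table(conc$kept, p("concordant_triplets.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    for (dir in c("C1_UP", "C2_UP")) {
      gs <- sort(unique(conc$kept$gene_id[conc$kept$direction == dir]))
      writeLines(gs, p(sprintf("genes_%s.txt", dir)))
    }
    c2 <- sort(unique(conc$kept$gene_id[conc$kept$direction == "C2_UP"]))
    scores <- if (length(c2) > 0) cisScore(expr, c2)
    else data.frame(sample = character(), score = numeric(),
                    group = character())
    utils::write.table(scores, p("cis_scores.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  })

  invisible(list(status = status,
                 outputs = list(calls = p("triplet_calls.tsv"),
                                concordant = p("concordant_triplets.tsv"),
                                scores = p("cis_scores.tsv"))))
}
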