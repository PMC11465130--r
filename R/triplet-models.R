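.NODES <- c("O", "E", "G")

.edgeMatrix <- function(...) {
  v <- c(...)
  if (length(v) == 0)
    return(matrix(character(), 0, 2,
                  dimnames = list(NULL, c("from", "to"))))
  matrix(v, ncol = 2, byrow = TRUE, dimnames = list(NULL, c("from", "to")))
}

.parentsOf <- function(edges, node) edges[edges[, 2] == node, 1]

# skeleton + v-structure signature; identical signature <=> same
# Markov-equivalence class
.equivSignature <- function(edges) {
  if (nrow(edges) == 0) return("skel:|v:")
  skel <- apply(edges, 1, function(e) paste(sort(e), collapse = "-"))
  vs <- character()
  for (z in .NODES) {
    pa <- .parentsOf(edges, z)
    if (length(pa) == 2) {
      adjacentParents <- paste(sort(pa), collapse = "-") %in% skel
      if (!adjacentParents)
        vs <- c(vs, paste0(sort(pa)[1], ">", z, "<", sort(pa)[2]))
    }
  }
  paste0("skel:", paste(sort(unique(skel)), collapse = ","),
         "|v:", paste(sort(vs), collapse = ","))
}

#' Enumerate the nine triplet regulatory model structures
#'
#' Returns the nine candidate Bayesian-network structures over the nodes O
#' (oCGI methylation), E (enhancer methylation) and G (gene expression):
#' four oCGI-dominated, four enhancer-dominated and one co-dominated, each
#' defined by its joint-probability factorization. Markov-equivalence
#' classes (identical skeleton and v-structures, hence identical maximized
#' likelihood) are annotated; the nine structures fall into six classes,
#' with the co-dominated collider `O -> G <- E` the only two-edge structure
#' identifiable on its own.
#'
#' @return named list of nine [ModelSpec-class] objects, in the order
#'   oCGI direct/cascade/co-responsive/composite, enhancer
#'   direct/cascade/co-responsive/composite, co-dominated.
#' @export
enumerateModels <- function() {
  def <- list(
    oCGI_direct = list(
      edges = .edgeMatrix("O", "G"),
      fact = "P(O,E,G) = P(O) * P(G|O) * P(E)", dom = "oCGI"),
    oCGI_cascade = list(
      edges = .edgeMatrix("O", "E", "E", "G"),
      fact = "P(O,E,G) = P(O) * P(E|O) * P(G|E)", dom = "oCGI"),
    oCGI_coresponsive = list(
      edges = .edgeMatrix("O", "E", "O", "G"),
      fact = "P(O,E,G) = P(O) * P(E|O) * P(G|O)", dom = "oCGI"),
    oCGI_composite = list(
      edges = .edgeMatrix("O", "E", "O", "G", "E", "G"),
      fact = "P(O,E,G) = P(O) * P(E|O) * P(G|O:E)", dom = "oCGI"),
    enhancer_direct = list(
      edges = .edgeMatrix("E", "G"),
      fact = "P(O,E,G) = P(O) * P(G|E) * P(E)", dom = "enhancer"),
    enhancer_cascade = list(
      edges = .edgeMatrix("E", "O", "O", "G"),
      fact = "P(O,E,G) = P(E) * P(O|E) * P(G|O)", dom = "enhancer"),
    enhancer_coresponsive = list(
      edges = .edgeMatrix("E", "O", "E", "G"),
      fact = "P(O,E,G) = P(E) * P(O|E) * P(G|E)", dom = "enhancer"),
    enhancer_composite = list(
      edges = .edgeMatrix("E", "O", "E", "G", "O", "G"),
      fact = "P(O,E,G) = P(E) * P(O|E) * P(G|O:E)", dom = "enhancer"),
    co_dominated = list(
      edges = .edgeMatrix("O", "G", "E", "G"),
      fact = "P(O,E,G) = P(O) * P(E) * P(G|O:E)", dom = "co")
  )
  sigs <- vapply(def, function(d) .equivSignature(d$edges), character(1))
  classIds <- paste0("EC", match(sigs, unique(sigs)))
  out <- mapply(function(nm, d, cls) {
    methods::new("ModelSpec", id = nm, edges = d$edges,
                 factorization = d$fact, dominance = d$dom,
                 equivClass = cls)
  }, names(def), def, classIds, SIMPLIFY = FALSE)
  out
}

# ---- Gaussian node fit: linear regression on parents with MLE variance ----
.gaussNodeFit <- function(y, X, node) {
  n <- length(y)
  if (stats::sd(y) == 0)
    stop("zero-variance node under gaussian backend: ", node)
  Xd <- if (is.null(X)) matrix(1, n, 1) else cbind(1, X)
  res <- stats::residuals(stats::lm.fit(Xd, y))
  sigma2 <- sum(res^2) / n
  if (sigma2 < 1e-12) sigma2 <- 1e-12  # guard degenerate perfect fits
  logL <- -n / 2 * (log(2 * pi * sigma2) + 1)
  list(logL = logL, k = ncol(Xd) + 1L, sigma2 = sigma2)
}

# discrete codes: beta states for methylation nodes, tertiles for expression
.discreteCodes <- function(dat) {
  list(O = .discretize(dat$O, method = "state"),
       E = .discretize(dat$E, method = "state"),
       G = .discretize(dat$G, 3L, method = "equalfreq"))
}

.discreteNodeFit <- function(cy, cpa, nLevels = 3L) {
  n <- length(cy)
  if (length(cpa) == 0) {
    counts <- tabulate(cy, nbins = nLevels)
    sm <- counts
    sm[sm == 0] <- 0.5                     # pseudo-count on empty cells only
    p <- sm / sum(sm)
    logL <- sum(counts[counts > 0] * log(p[counts > 0]))
    return(list(logL = logL, k = nLevels - 1L))
  }
  combo <- Reduce(function(a, b) (a - 1L) * nLevels + b, cpa)
  nCombo <- nLevels^length(cpa)
  counts <- matrix(0, nLevels, nCombo)
  for (i in seq_len(n)) counts[cy[i], combo[i]] <- counts[cy[i], combo[i]] + 1
  logL <- 0
  for (j in seq_len(nCombo)) {
    cj <- counts[, j]
    if (sum(cj) == 0) next
    sm <- cj
    sm[sm == 0] <- 0.5
    p <- sm / sum(sm)
    logL <- logL + sum(cj[cj > 0] * log(p[cj > 0]))
  }
  list(logL = logL, k = (nLevels - 1L) * nCombo)
}

#' Fit one regulatory model structure to a triplet
#'
#' Maximizes the likelihood of the model's factorization: under the
#' gaussian backend each node is regressed linearly on its parents with
#' MLE error variance (intended inputs: raw region beta for O and E,
#' log1p expression for G); under the discrete backend each node gets a
#' multinomial conditional table over beta states (O, E) and expression
#' tertiles (G), with 0.5 pseudo-counts on empty cells. Free parameters
#' per node: `#parents + 2` (gaussian: coefficients, intercept, variance)
#' or `(levels - 1) * prod(parent levels)` (discrete). `aic = 2k - 2 logL`.
#'
#' @param o,e,g aligned numeric sample vectors (length >= 10).
#' @param model a [ModelSpec-class].
#' @param backend `"gaussian"` or `"discrete"`.
#' @return list with `model`, `backend`, `logL`, `k`, `aic`, `dominance`,
#'   `equivClass`.
#' @export
fitTripletModel <- function(o, e, g, model,
                            backend = c("gaussian", "discrete")) {
  backend <- match.arg(backend)
  n <- length(o)
  if (length(e) != n || length(g) != n) stop("o, e, g must be aligned")
  if (n < 10) stop("need at least 10 samples")
  dat <- list(O = o, E = e, G = g)
  logL <- 0; k <- 0L
  if (backend == "gaussian") {
    for (node in .NODES) {
      pa <- .parentsOf(model@edges, node)
      X <- if (length(pa) == 0) NULL
      else do.call(cbind, dat[pa])
      f <- .gaussNodeFit(dat[[node]], X, node)
      logL <- logL + f$logL
      k <- k + length(pa) + 2L
    }
  } else {
    codes <- .discreteCodes(dat)
    for (node in .NODES) {
      pa <- .parentsOf(model@edges, node)
      f <- .discreteNodeFit(codes[[node]], codes[pa])
      logL <- logL + f$logL
      k <- k + f$k
    }
  }
  list(model = model@id, backend = backend, logL = logL, k = k,
       aic = 2 * k - 2 * logL, dominance = model@dominance,
       equivClass = model@equivClass)
}

# ---- conditional (in)dependence tests -------------------------------------

# Fisher z test of (partial) correlation; condSet a character subset of names(dat)
.gaussCorTest <- function(dat, x, y, condSet) {
  n <- length(dat[[x]])
  if (n < length(condSet) + 4)
    return(list(p = NA_real_, untestable = TRUE))
  r <- if (length(condSet) == 0) {
    stats::cor(dat[[x]], dat[[y]])
  } else {
    z <- dat[[condSet]]
    rxy <- stats::cor(dat[[x]], dat[[y]])
    rxz <- stats::cor(dat[[x]], z)
    ryz <- stats::cor(dat[[y]], z)
    (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
  }
  r <- max(min(r, 1 - 1e-12), -1 + 1e-12)
  zstat <- atanh(r) * sqrt(n - length(condSet) - 3)
  list(p = 2 * stats::pnorm(-abs(zstat)), untestable = FALSE)
}

# joint test of x independent of {y, z}: overall F of the regression
.gaussJointTest <- function(dat, x, others) {
  n <- length(dat[[x]])
  if (n < 5) return(list(p = NA_real_, untestable = TRUE))
  X <- cbind(1, do.call(cbind, dat[others]))
  res <- stats::residuals(stats::lm.fit(X, dat[[x]]))
  tss <- sum((dat[[x]] - mean(dat[[x]]))^2)
  rss <- sum(res^2)
  q <- length(others)
  f <- ((tss - rss) / q) / (rss / (n - q - 1))
  list(p = stats::pf(f, q, n - q - 1, lower.tail = FALSE),
       untestable = FALSE)
}

# G^2 test of independence between codes, optionally within strata of cond
.g2Test <- function(cx, cy, cond = NULL) {
  g2 <- 0; df <- 0
  strata <- if (is.null(cond)) list(seq_along(cx))
  else split(seq_along(cx), cond)
  for (idx in strata) {
    if (length(idx) < 2) next
    tab <- table(cx[idx], cy[idx])
    tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
    if (nrow(tab) < 2 || ncol(tab) < 2) next
    e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    pos <- tab > 0
    g2 <- g2 + 2 * sum(tab[pos] * log(tab[pos] / e[pos]))
    df <- df + (nrow(tab) - 1) * (ncol(tab) - 1)
  }
  if (df == 0) return(list(p = NA_real_, untestable = TRUE))
  list(p = stats::pchisq(g2, df, lower.tail = FALSE), untestable = FALSE)
}

# model-implied pairwise relations for validity testing
.impliedRelations <- function(edges) {
  skel <- if (nrow(edges) == 0) character()
  else apply(edges, 1, function(e) paste(sort(e), collapse = "-"))
  rels <- list()
  # adjacency in a DAG means no subset of the remaining nodes separates the
  # pair, so every edge must show dependence both marginally and given the
  # third node (the two possible conditioning sets on three nodes)
  for (i in seq_len(nrow(edges))) {
    z <- setdiff(.NODES, edges[i, ])
    for (cond in list(character(), z)) {
      rels[[length(rels) + 1]] <-
        list(x = edges[i, 1], y = edges[i, 2], cond = cond,
             implied = "dependent")
    }
  }
  deg <- vapply(.NODES, function(nd) sum(edges == nd), integer(1))
  isolated <- .NODES[deg == 0]
  if (length(isolated) == 1) {
    # both missing edges share the isolated node: the factorization's
    # independent factor is one joint statement, tested as such
    rels[[length(rels) + 1]] <-
      list(x = isolated, y = setdiff(.NODES, isolated),
           cond = character(), implied = "independent")
  } else if (length(isolated) == 0) {
    for (pr in list(c("E", "O"), c("G", "O"), c("E", "G"))) {
      if (paste(sort(pr), collapse = "-") %in% skel) next
      z <- setdiff(.NODES, pr)
      # separating set: empty when the third node is a collider between
      # the pair, else the third node (chain or fork)
      zIsCollider <- all(pr %in% .parentsOf(edges, z))
      rels[[length(rels) + 1]] <-
        list(x = pr[1], y = pr[2],
             cond = if (zIsCollider) character() else z,
             implied = "independent")
    }
  }
  rels
}

#' Validity tests for a model structure on triplet data
#'
#' Tests every pairwise relation the structure implies, with the
#' constraint-based reading of adjacency: an edge means no conditioning
#' set separates the pair, so each edge must show detectable dependence
#' both marginally and given the third node (every test at p < `alpha`),
#' while each implied (conditional) independence must survive
#' (p >= `alpha`) with its d-separating set as witness (empty for the
#' collider, the third node for chains and forks). For the two direct models the isolated node's
#' independent factor is tested as one joint statement against the other
#' two nodes. The gaussian backend uses Fisher-z (partial) correlation
#' tests and an overall F-test for the joint statement; the discrete
#' backend uses G^2 tests (stratified for conditioning). Relations that
#' cannot be tested at the available sample size are marked untestable and
#' do not invalidate the model.
#'
#' @inheritParams fitTripletModel
#' @param alpha test level (default 0.05).
#' @return list with `results` (data.frame: relation, conditioning,
#'   implied, p, ok, untestable) and `valid` (all testable relations ok).
#' @export
ciTests <- function(o, e, g, model, backend = c("gaussian", "discrete"),
                    alpha = 0.05) {
  backend <- match.arg(backend)
  dat <- list(O = o, E = e, G = g)
  codes <- if (backend == "discrete") .discreteCodes(dat) else NULL
  rels <- .impliedRelations(model@edges)
  rows <- lapply(rels, function(rl) {
    res <- if (backend == "gaussian") {
      if (length(rl$y) == 2) .gaussJointTest(dat, rl$x, rl$y)
      else .gaussCorTest(dat, rl$x, rl$y, rl$cond)
    } else {
      cy <- if (length(rl$y) == 2)
        (codes[[rl$y[1]]] - 1L) * 3L + codes[[rl$y[2]]]
      else codes[[rl$y]]
      cond <- if (length(rl$cond)) codes[[rl$cond]] else NULL
      .g2Test(codes[[rl$x]], cy, cond)
    }
    ok <- if (res$untestable) NA
    else if (rl$implied == "dependent") res$p < alpha
    else res$p >= alpha
    data.frame(relation = paste(rl$x, "~", paste(rl$y, collapse = ":")),
               conditioning = paste(rl$cond, collapse = ":"),
               implied = rl$implied, p = res$p,
               ok = ok, untestable = res$untestable,
               stringsAsFactors = FALSE)
  })
  results <- do.call(rbind, rows)
  list(results = results,
       valid = all(results$ok[!results$untestable]))
}

#' Select the regulatory model for a triplet
#'
#' Among fits whose structure passed validity testing, the model with the
#' smallest AIC is selected. When the minimum is attained by members of
#' one Markov-equivalence class (an AIC tie by construction), the tie is
#' broken by dominance: the oCGI-dominated member if `miOG >= miEG`, else
#' the enhancer-dominated member; the tie is annotated. If no fit is
#' valid, the triplet is left unassigned with a reason.
#'
#' @param fits list of nine fits from [fitTripletModel()].
#' @param validity list of nine results from [ciTests()], aligned with
#'   `fits`.
#' @param miOG,miEG mutual information of the oCGI-gene and enhancer-gene
#'   pairs, used only for tie-breaking.
#' @param tol AIC tie tolerance (default 1e-8).
#' @return list with `selected` (model id or `NA`), `aic` (named vector),
#'   `valid` (named logical), `tieBreak` (logical), `reason`.
#' @export
selectModel <- function(fits, validity, miOG, miEG, tol = 1e-8) {
  aic <- vapply(fits, function(f) f$aic, numeric(1))
  names(aic) <- vapply(fits, function(f) f$model, character(1))
  valid <- vapply(validity, function(v) v$valid, logical(1))
  names(valid) <- names(aic)
  if (!any(valid))
    return(list(selected = NA_character_, aic = aic, valid = valid,
                tieBreak = FALSE,
                reason = "no structure passes independence testing"))
  va <- aic[valid]
  cand <- names(va)[va <= min(va) + tol]
  tie <- length(cand) > 1
  sel <- if (!tie) cand else {
    doms <- vapply(fits[match(cand, names(aic))],
                   function(f) f$dominance, character(1))
    pick <- if (miOG >= miEG) which(doms == "oCGI") else
      which(doms == "enhancer")
    if (length(pick) == 0) pick <- 1L
    cand[pick[1]]
  }
  list(selected = sel, aic = aic, valid = valid, tieBreak = tie,
       reason = NA_character_)
}

#' Fit and select regulatory models for all triplets
#'
#' For each triplet, fits the nine candidate structures to (region beta of
#' the oCGI, region beta of the enhancer, log1p expression of the gene),
#' runs validity testing, and selects by smallest AIC with the
#' Markov-equivalence tie-break (see [selectModel()]).
#'
#' @param triplets triplet table from [buildTriplets()].
#' @param regionBeta a [RegionMethylation-class] or regions-by-samples beta
#'   matrix.
#' @param expr genes-by-samples expression matrix (natural scale; log1p is
#'   applied internally for the gaussian backend).
#' @param backend `"gaussian"` (default) or `"discrete"`.
#' @param alpha level for validity tests.
#' @return data.frame: the triplet columns, one `aic_<model>` column per
#'   structure, `selected_model`, `dominance`, `equiv_class`,
#'   `n_valid_models`, `tie_break`, `reason`.
#' @export
callTriplets <- function(triplets, regionBeta, expr,
                         backend = c("gaussian", "discrete"),
                         alpha = 0.05) {
  backend <- match.arg(backend)
  models <- enumerateModels()
  b <- if (methods::is(regionBeta, "RegionMethylation"))
    SummarizedExperiment::assay(regionBeta, "beta") else regionBeta
  samples <- intersect(colnames(b), colnames(expr))
  rows <- lapply(seq_len(nrow(triplets)), function(i) {
    o <- b[triplets$ocgi_id[i], samples]
    e <- b[triplets$enhancer_id[i], samples]
    g <- log1p(expr[triplets$gene_id[i], samples])
    fits <- lapply(models, function(m)
      fitTripletModel(o, e, g, m, backend = backend))
    validity <- lapply(models, function(m)
      ciTests(o, e, g, m, backend = backend, alpha = alpha))
    sel <- selectModel(fits, validity,
                       miOG = triplets$mi_og[i], miEG = triplets$mi_eg[i])
    aics <- as.list(sel$aic)
    names(aics) <- paste0("aic_", names(aics))
    dom <- if (is.na(sel$selected)) NA_character_
    else models[[sel$selected]]@dominance
    ecl <- if (is.na(sel$selected)) NA_character_
    else models[[sel$selected]]@equivClass
    cbind(triplets[i, , drop = FALSE],
          data.frame(aics,
                     selected_model = sel$selected,
                     dominance = dom, equiv_class = ecl,
                     n_valid_models = sum(sel$valid),
                     tie_break = sel$tieBreak, reason = sel$reason,
                     stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
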