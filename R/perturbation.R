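## Knockdown vectors X, perturbation probabilities, and the linear
## KO-indicator regression used for gene selection and network filtering.

#' Mean control expression at a time point
#'
#' The per-gene arithmetic mean over control cells sampled at time index
#' \code{t}; the wild-type reference against which knockdowns are expressed.
#'
#' @param dataset a [RengeExperiment-class].
#' @param t time index in \code{1..T}.
#' @return Named numeric vector of length G.
#' @export
controlBaseline <- function(dataset, t) {
  sel <- isControl(dataset) & timeIndex(dataset) == t
  if (!any(sel))
    .stopf("no control cells at time index %s", t)
  rowMeans(exprMatrix(dataset)[, sel, drop = FALSE])
}

#' Build per-cell knockdown vectors
#'
#' For a KO cell c targeting gene g at time t, the knockdown vector has a
#' single nonzero entry at g equal to \eqn{-p_c} times the mean control
#' expression of g at t (a complete knockout removes the gene's entire
#' baseline expression, attenuated by the perturbation probability).
#' Control rows are zero.
#'
#' @param dataset a [RengeExperiment-class] with \code{perturbProb} populated
#'   (defaults to 1).
#' @return A [KnockdownTable-class].
#' @export
buildKnockdownTable <- function(dataset) {
  G <- nrow(dataset)
  n <- ncol(dataset)
  X <- matrix(0, n, G, dimnames = list(cellIds(dataset), geneNames(dataset)))
  ko <- koGene(dataset)
  ti <- timeIndex(dataset)
  pp <- perturbProb(dataset)
  for (t in sort(unique(ti))) {
    base <- controlBaseline(dataset, t)
    sel <- which(ti == t & ko != CONTROL)
    for (c in sel) X[c, ko[c]] <- -pp[c] * base[ko[c]]
  }
  KnockdownTable(X, perturb_prob = pp)
}

#' Estimate per-cell perturbation probabilities
#'
#' Classifies, within each KO-gene stratum, cells whose transcriptome was
#' actually altered by the knockout from cells where editing failed. Each
#' cell is scored by the projection of its deviation from the time-matched
#' control baseline onto the stratum's mean deviation (the KO signature);
#' a two-component Gaussian mixture is fitted to the stratum's scores pooled
#' with control-cell scores, and \eqn{p_c} is the posterior probability that
#' the cell belongs to the higher-mean component. Deterministic given
#' \code{seed}. Strata with a single cell receive \eqn{p_c = 1} with a
#' warning; when the mixture degenerates to one component, all cells in the
#' stratum receive \eqn{p_c = 0.5}.
#'
#' @param dataset a [RengeExperiment-class].
#' @param seed integer seed.
#' @return A copy of \code{dataset} with \code{perturbProb} replaced for KO
#'   cells (control cells keep 1).
#' @export
estimatePerturbProb <- function(dataset, seed = 0L) {
  set.seed(as.integer(seed))
  E <- exprMatrix(dataset)
  ko <- koGene(dataset)
  ti <- timeIndex(dataset)
  pp <- perturbProb(dataset)
  bases <- lapply(sort(unique(ti)), function(t) controlBaseline(dataset, t))
  dev <- E - do.call(cbind, lapply(seq_len(ncol(E)),
                                   function(c) bases[[ti[c]]]))
  for (g in koGenes(dataset)) {
    cells_g <- which(ko == g)
    if (length(cells_g) == 1L) {
      .warnf("KO stratum '%s' has a single cell; perturb_prob set to 1", g)
      pp[cells_g] <- 1
      next
    }
    score <- rep(NA_real_, ncol(E))
    for (t in unique(ti[cells_g])) {
      sel <- cells_g[ti[cells_g] == t]
      mu <- rowMeans(dev[, sel, drop = FALSE])
      nrm <- sqrt(sum(mu^2))
      if (nrm < 1e-12) nrm <- 1
      others <- which(ko == CONTROL & ti == t)
      for (c in c(sel, others))
        score[c] <- sum(dev[, c] * mu) / nrm
    }
    pool <- which(!is.na(score))
    sc <- score[pool] - mean(score[pool])
    fitm <- tryCatch(
      mclust::Mclust(sc, G = 2, modelNames = c("E", "V"), verbose = FALSE),
      error = function(e) NULL)
    if (is.null(fitm) || length(unique(fitm$classification)) < 2) {
      pp[cells_g] <- 0.5
      next
    }
    hi <- which.max(fitm$parameters$mean)
    post <- fitm$z[, hi]
    names(post) <- as.character(pool)
    pp[cells_g] <- pmin(1, pmax(0, post[as.character(cells_g)]))
  }
  cd <- colData(dataset)
  cd$perturb_prob <- pp
  SummarizedExperiment::colData(dataset) <- cd
  dataset
}

## ---------------------------------------------------------------------------
## KO-indicator linear regression (MIMOSCA-style artifacts)
## ---------------------------------------------------------------------------

#' Per-gene linear regression of expression on KO indicators
#'
#' Fits, for every gene, ordinary least squares of its expression on one
#' indicator per KO gene (control cells have all indicators zero) plus an
#' intercept; with several time points and \code{t = NULL}, time-point
#' dummies are added as covariates. A ridge penalty of 1e-8 stabilizes
#' near-singular designs without changing well-posed coefficients.
#'
#' @param dataset a [RengeExperiment-class].
#' @param t a single time index, or \code{NULL} to use all cells.
#' @return A list of class \code{"PerturbRegression"} with \code{beta}
#'   (genes x KO genes: fitted expression change of each gene under each KO)
#'   and \code{intercepts}.
#' @export
fitPerturbRegression <- function(dataset, t = NULL) {
  keep <- if (is.null(t)) rep(TRUE, ncol(dataset)) else timeIndex(dataset) == t
  E <- exprMatrix(dataset)[, keep, drop = FALSE]
  ko <- koGene(dataset)[keep]
  kos <- intersect(geneNames(dataset), unique(ko[ko != CONTROL]))
  if (!length(kos)) .stopf("no KO cells in the selected stratum")
  D <- matrix(0, ncol(E), length(kos), dimnames = list(NULL, kos))
  for (g in kos) D[ko == g, g] <- 1
  covars <- matrix(1, ncol(E), 1, dimnames = list(NULL, "(Intercept)"))
  if (is.null(t)) {
    ti <- timeIndex(dataset)[keep]
    tt <- sort(unique(ti))
    if (length(tt) > 1)
      for (tp in tt[-1]) {
        cn <- paste0("time", tp)
        covars <- cbind(covars, as.numeric(ti == tp))
        colnames(covars)[ncol(covars)] <- cn
      }
  }
  Xd <- cbind(covars, D)
  dup <- which(duplicated(t(Xd)) & colnames(Xd) %in% kos)
  if (length(dup))
    .stopf("collinear KO strata: %s duplicates another design column",
           paste(colnames(Xd)[dup], collapse = ", "))
  XtX <- crossprod(Xd) + diag(1e-8, ncol(Xd))
  B <- solve(XtX, crossprod(Xd, t(E)))   # (covariates+KO) x genes
  beta <- t(B[kos, , drop = FALSE])      # genes x KO genes
  structure(list(beta = beta, intercepts = B["(Intercept)", ],
                 ko_genes = kos),
            class = "PerturbRegression")
}

#' Total expression variation per knockout
#'
#' The mean over KO genes of the summed absolute regression coefficients:
#' \eqn{\sum_{i,j} |\beta_{i,j}| / G_{ko}}. Networks in which single-gene
#' knockouts barely move the transcriptome score low and are poor inference
#' substrates.
#'
#' @param reg a \code{"PerturbRegression"} from [fitPerturbRegression()].
#' @return A single nonnegative number.
#' @export
mimoscaScore <- function(reg) {
  Gko <- ncol(reg$beta)
  if (is.null(Gko) || Gko == 0) .stopf("no KO genes in the regression")
  sum(abs(reg$beta)) / Gko
}

#' Rank genes by KO-induced expression variation
#'
#' Scores each gene by the summed absolute regression coefficients across
#' knockouts, \eqn{v_i = \sum_j |\beta_{i,j}|}; used to select responsive
#' non-KO genes into the network.
#'
#' @inheritParams mimoscaScore
#' @return Named numeric vector sorted in decreasing order.
#' @export
expressionVariationScores <- function(reg) {
  v <- rowSums(abs(reg$beta))
  sort(v, decreasing = TRUE)
}

#' @export
print.PerturbRegression <- function(x, ...) {
  cat("PerturbRegression:", nrow(x$beta), "genes x", ncol(x$beta),
      "KO indicators\n")
  invisible(x)
}
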