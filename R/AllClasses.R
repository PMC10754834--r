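#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#' @importFrom S4Vectors DataFrame metadata
NULL

## ---------------------------------------------------------------------------
## RengeExperiment: per-cell normalized expression + KO / time annotation
## ---------------------------------------------------------------------------

#' Container for a time-series single-cell CRISPR knockout screen
#'
#' A \code{RengeExperiment} extends
#' \linkS4class{SummarizedExperiment}: the \code{"expr"} assay holds
#' normalized expression with genes as rows and cells as columns, and the
#' column data carries, per cell, the sampling time (both the raw label and
#' a contiguous integer index \code{1..T}), the knockout (KO) target gene
#' (or the control sentinel \code{"control"}), and the perturbation
#' probability \eqn{p_c} (the probability that the detected gRNA actually
#' altered the transcriptome; defaults to 1 for KO cells).
#'
#' @section Invariants:
#' Every KO label is either \code{"control"} or one of the gene names; every
#' time index has at least one control cell; cell identifiers are unique.
#'
#' @export
setClass("RengeExperiment", contains = "SummarizedExperiment")

setValidity("RengeExperiment", function(object) {
  cd <- colData(object)
  msgs <- character(0)
  need <- c("ko_gene", "time_index", "time_label", "perturb_prob")
  miss <- setdiff(need, colnames(cd))
  if (length(miss))
    return(paste("missing colData column(s):", paste(miss, collapse = ", ")))
  if (!"expr" %in% SummarizedExperiment::assayNames(object))
    return("assay 'expr' is required")
  if (anyDuplicated(colnames(object)))
    msgs <- c(msgs, "duplicate cell identifiers")
  ko <- cd$ko_gene
  unknown <- setdiff(unique(ko[ko != CONTROL]), rownames(object))
  if (length(unknown))
    msgs <- c(msgs, paste("ko_gene label(s) not among gene names:",
                          paste(unknown, collapse = ", ")))
  ti <- cd$time_index
  if (length(ti) && (!is.numeric(ti) || any(ti < 1 | ti != round(ti))))
    msgs <- c(msgs, "time_index must be positive integers")
  if (length(ti)) {
    tt <- sort(unique(as.integer(ti)))
    if (!identical(tt, seq_along(tt)))
      msgs <- c(msgs, "time_index must be contiguous 1..T")
    no_ctrl <- tt[!tt %in% unique(as.integer(ti[ko == CONTROL]))]
    if (length(no_ctrl))
      msgs <- c(msgs, paste("no control cells at time index:",
                            paste(no_ctrl, collapse = ", ")))
  }
  pp <- cd$perturb_prob
  if (length(pp) && (any(!is.finite(pp)) || any(pp < 0 | pp > 1)))
    msgs <- c(msgs, "perturb_prob must lie in [0, 1]")
  if (length(msgs)) msgs else TRUE
})

#' Construct a RengeExperiment
#'
#' @param expr numeric matrix of normalized expression, cells x genes
#'   (the layout of a delimited input file); it is stored transposed,
#'   genes x cells, following Bioconductor convention.
#' @param time per-cell sampling time labels (numeric or character); they are
#'   rank-remapped to contiguous integer indices \code{1..T} and the raw label
#'   is kept in \code{timeLabel()}.
#' @param ko_gene per-cell KO target gene name, or the control sentinel
#'   (\code{"control"} / \code{"ctrl"}, case-insensitive).
#' @param perturb_prob optional per-cell perturbation probability in
#'   \code{[0,1]}; defaults to 1 everywhere.
#' @param cell_ids,gene_names identifiers; default to the dimnames of
#'   \code{expr}.
#' @return A \linkS4class{RengeExperiment}.
#' @examples
#' expr <- matrix(rpois(20, 5), nrow = 4,
#'                dimnames = list(paste0("c", 1:4), paste0("g", 1:5)))
#' re <- RengeExperiment(expr, time = c(1, 1, 2, 2),
#'                       ko_gene = c("control", "g1", "control", "g1"))
#' re
#' @export
RengeExperiment <- function(expr, time, ko_gene, perturb_prob = NULL,
                            cell_ids = rownames(expr),
                            gene_names = colnames(expr)) {
  expr <- as.matrix(expr)
  if (is.null(cell_ids)) cell_ids <- paste0("cell", seq_len(nrow(expr)))
  if (is.null(gene_names)) gene_names <- paste0("gene", seq_len(ncol(expr)))
  if (length(cell_ids) != nrow(expr))
    .stopf("cell axis mismatch: %d ids vs %d matrix rows",
           length(cell_ids), nrow(expr))
  if (length(gene_names) != ncol(expr))
    .stopf("gene axis mismatch: %d names vs %d matrix columns",
           length(gene_names), ncol(expr))
  ko_gene <- .normalizeKoLabels(ko_gene)
  tl <- as.character(time)
  lev <- sort(unique(time))
  ti <- match(time, lev)
  if (is.null(perturb_prob)) perturb_prob <- rep(1, nrow(expr))
  perturb_prob[ko_gene == CONTROL] <- 1
  m <- t(expr)
  dimnames(m) <- list(gene_names, cell_ids)
  se <- SummarizedExperiment(
    assays = list(expr = m),
    colData = DataFrame(ko_gene = ko_gene,
                        time_index = as.integer(ti),
                        time_label = tl,
                        perturb_prob = as.numeric(perturb_prob),
                        row.names = cell_ids))
  S4Vectors::metadata(se)$time_map <-
    data.frame(time_label = as.character(lev), time_index = seq_along(lev))
  new("RengeExperiment", se)
}

## ---------------------------------------------------------------------------
## GRNModel: the fitted parameter set
## ---------------------------------------------------------------------------

#' Fitted gene regulatory network model
#'
#' Holds the complete parameter set of the KO-propagation model: the signed
#' G x G coefficient matrix \code{A} (entry \code{A[i, j]} is the strength of
#' regulation of target \code{i} by regulator \code{j}; the diagonal absorbs
#' degradation/self-effects and is never exported as an edge), per-time
#' wild-type baselines \code{b} (G x T), the sigmoid time-order weight
#' parameters (per-KO-gene offset \code{alpha}, time slope \code{beta_w >= 0},
#' order decay \code{gamma_w >= 0}), the maximum propagation order \code{K},
#' and the regularization strengths.
#'
#' @export
setClass("GRNModel",
         representation(A = "matrix", b = "matrix", alpha = "numeric",
                        beta_w = "numeric", gamma_w = "numeric",
                        K = "integer", lambda1 = "numeric",
                        lambda2 = "numeric", converged = "logical",
                        value = "numeric", niter = "integer",
                        time_labels = "character"))

setValidity("GRNModel", function(object) {
  G <- nrow(object@A)
  if (ncol(object@A) != G) return("A must be square")
  if (nrow(object@b) != G) return("b must have one row per gene")
  if (object@beta_w < 0 || object@gamma_w < 0)
    return("beta_w and gamma_w must be nonnegative")
  if (object@K < 1L) return("K must be >= 1")
  if (object@lambda1 < 0 || object@lambda2 < 0)
    return("regularization strengths must be nonnegative")
  TRUE
})

#' @rdname GRNModel-class
#' @param A,b,alpha,beta_w,gamma_w,K,lambda1,lambda2 model parameters; see
#'   the class description.
#' @param converged,value,niter optimizer bookkeeping.
#' @param time_labels raw time labels corresponding to columns of \code{b}.
#' @export
GRNModel <- function(A, b, alpha = numeric(0), beta_w = 1, gamma_w = 1,
                     K = 1L, lambda1 = 0, lambda2 = 0, converged = TRUE,
                     value = NA_real_, niter = 0L,
                     time_labels = as.character(seq_len(ncol(b)))) {
  new("GRNModel", A = as.matrix(A), b = as.matrix(b),
      alpha = alpha, beta_w = as.numeric(beta_w), gamma_w = as.numeric(gamma_w),
      K = as.integer(K), lambda1 = as.numeric(lambda1),
      lambda2 = as.numeric(lambda2), converged = converged,
      value = as.numeric(value), niter = as.integer(niter),
      time_labels = time_labels)
}

## ---------------------------------------------------------------------------
## KnockdownTable: per-cell knockdown vectors X and perturbation probabilities
## ---------------------------------------------------------------------------

#' Per-cell knockdown vectors
#'
#' Each row of \code{X} (cells x genes) has at most one nonzero entry, at the
#' cell's KO gene, equal to minus the perturbation probability times the mean
#' control expression of that gene at the cell's sampling time. Control rows
#' are all zero.
#'
#' @export
setClass("KnockdownTable",
         representation(X = "matrix", perturb_prob = "numeric"))

setValidity("KnockdownTable", function(object) {
  nz <- rowSums(object@X != 0)
  if (any(nz > 1)) return("each knockdown row may carry at most one nonzero")
  if (any(object@X > 1e-12)) return("knockdown entries must be nonpositive")
  if (length(object@perturb_prob) != nrow(object@X))
    return("perturb_prob must have one entry per cell")
  TRUE
})

KnockdownTable <- function(X, perturb_prob = rep(1, nrow(X))) {
  new("KnockdownTable", X = as.matrix(X),
      perturb_prob = as.numeric(perturb_prob))
}

## ---------------------------------------------------------------------------
## BootstrapEnsemble
## ---------------------------------------------------------------------------

#' Bootstrap ensemble of network estimates
#'
#' \code{A_samples} is a G x G x N array of network matrices, each estimated
#' from a dataset resampled with replacement within every (KO gene, time)
#' stratum so that stratum sizes are preserved.
#'
#' @export
setClass("BootstrapEnsemble",
         representation(A_samples = "array", seed = "integer",
                        converged = "logical"))

BootstrapEnsemble <- function(A_samples, seed = NA_integer_,
                              converged = rep(TRUE, dim(A_samples)[3])) {
  new("BootstrapEnsemble", A_samples = A_samples,
      seed = as.integer(seed), converged = converged)
}

## ---------------------------------------------------------------------------
## TruthNetwork
## ---------------------------------------------------------------------------

#' Ground-truth regulatory network
#'
#' Scores are stored target x regulator (same orientation as a fitted
#' \code{A}); an edge regulator \code{j} -> target \code{i} is present when
#' \code{abs(scores)[i, j] > threshold} (for signed truth) or
#' \code{scores[i, j] > threshold} otherwise. Self-pairs are never edges.
#'
#' @export
setClass("TruthNetwork",
         representation(scores = "matrix", threshold = "numeric",
                        signed = "logical"))

TruthNetwork <- function(scores, threshold = 0, signed = any(scores < 0)) {
  new("TruthNetwork", scores = as.matrix(scores),
      threshold = as.numeric(threshold), signed = isTRUE(signed))
}
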