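## Accessor generics and show methods.

#' @importFrom SummarizedExperiment assayNames
NULL

#' Accessors for RengeExperiment and model objects
#'
#' @param x an object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("exprMatrix", function(x) standardGeneric("exprMatrix"))
#' @rdname accessors
#' @export
setMethod("exprMatrix", "RengeExperiment", function(x) assay(x, "expr"))

#' @rdname accessors
#' @export
setGeneric("geneNames", function(x) standardGeneric("geneNames"))
#' @rdname accessors
#' @export
setMethod("geneNames", "RengeExperiment", function(x) rownames(x))
#' @rdname accessors
#' @export
setMethod("geneNames", "GRNModel", function(x) rownames(x@A))

#' @rdname accessors
#' @export
setGeneric("cellIds", function(x) standardGeneric("cellIds"))
#' @rdname accessors
#' @export
setMethod("cellIds", "RengeExperiment", function(x) colnames(x))

#' @rdname accessors
#' @export
setGeneric("koGene", function(x) standardGeneric("koGene"))
#' @rdname accessors
#' @export
setMethod("koGene", "RengeExperiment",
          function(x) colData(x)$ko_gene)

#' @rdname accessors
#' @export
setGeneric("koGenes", function(x) standardGeneric("koGenes"))

#' @rdname accessors
#' @export
setMethod("koGenes", "RengeExperiment", function(x) {
  ko <- unique(koGene(x))
  intersect(geneNames(x), ko)   # gene order is the single source of truth
})
#' @rdname accessors
#' @export
setMethod("koGenes", "GRNModel", function(x) names(x@alpha))

#' @rdname accessors
#' @export
setGeneric("timeIndex", function(x) standardGeneric("timeIndex"))
#' @rdname accessors
#' @export
setMethod("timeIndex", "RengeExperiment",
          function(x) colData(x)$time_index)

#' @rdname accessors
#' @export
setGeneric("timeLabel", function(x) standardGeneric("timeLabel"))
#' @rdname accessors
#' @export
setMethod("timeLabel", "RengeExperiment",
          function(x) colData(x)$time_label)

#' @rdname accessors
#' @export
setGeneric("perturbProb", function(x) standardGeneric("perturbProb"))
#' @rdname accessors
#' @export
setMethod("perturbProb", "RengeExperiment",
          function(x) colData(x)$perturb_prob)
#' @rdname accessors
#' @export
setMethod("perturbProb", "KnockdownTable", function(x) x@perturb_prob)

#' @rdname accessors
#' @export
setGeneric("isControl", function(x) standardGeneric("isControl"))
#' @rdname accessors
#' @export
setMethod("isControl", "RengeExperiment",
          function(x) koGene(x) == CONTROL)

#' @rdname accessors
#' @export
setGeneric("nTimePoints", function(x) standardGeneric("nTimePoints"))
#' @rdname accessors
#' @export
setMethod("nTimePoints", "RengeExperiment",
          function(x) max(timeIndex(x)))
#' @rdname accessors
#' @export
setMethod("nTimePoints", "GRNModel", function(x) ncol(x@b))

#' @rdname accessors
#' @export
setGeneric("networkMatrix", function(x) standardGeneric("networkMatrix"))
#' @rdname accessors
#' @export
setMethod("networkMatrix", "GRNModel", function(x) x@A)

#' @rdname accessors
#' @export
setGeneric("baselines", function(x) standardGeneric("baselines"))
#' @rdname accessors
#' @export
setMethod("baselines", "GRNModel", function(x) x@b)

#' @rdname accessors
#' @export
setGeneric("weightParams", function(x) standardGeneric("weightParams"))
#' @rdname accessors
#' @export
setMethod("weightParams", "GRNModel",
          function(x) list(alpha = x@alpha, beta = x@beta_w, gamma = x@gamma_w))

#' @rdname accessors
#' @export
setGeneric("knockdownMatrix", function(x) standardGeneric("knockdownMatrix"))
#' @rdname accessors
#' @export
setMethod("knockdownMatrix", "KnockdownTable", function(x) x@X)

#' @rdname accessors
#' @export
setGeneric("nReplicates", function(x) standardGeneric("nReplicates"))
#' @rdname accessors
#' @export
setMethod("nReplicates", "BootstrapEnsemble",
          function(x) dim(x@A_samples)[3])

#' @rdname accessors
#' @export
setGeneric("truthScores", function(x) standardGeneric("truthScores"))
#' @rdname accessors
#' @export
setMethod("truthScores", "TruthNetwork", function(x) x@scores)

#' @rdname accessors
#' @param ... unused.
#' @export
setGeneric("truthEdges", function(x, ...) standardGeneric("truthEdges"))

#' @rdname accessors
#' @export
setMethod("truthEdges", "TruthNetwork", function(x, ...) {
  s <- if (x@signed) abs(x@scores) else x@scores
  e <- s > x@threshold
  diag(e) <- FALSE
  e
})

setMethod("show", "RengeExperiment", function(object) {
  cat("RengeExperiment:", nrow(object), "genes x", ncol(object), "cells\n")
  cat("  time points:", nTimePoints(object),
      " | KO genes:", length(koGenes(object)),
      " | control cells:", sum(isControl(object)), "\n")
  invisible(NULL)
})

setMethod("show", "GRNModel", function(object) {
  G <- nrow(object@A)
  offdiag <- object@A[row(object@A) != col(object@A)]
  cat("GRNModel:", G, "genes, K =", object@K,
      ", T =", ncol(object@b), "\n")
  cat(sprintf("  lambda1 = %.4g, lambda2 = %.4g | nonzero off-diagonal: %d/%d\n",
              object@lambda1, object@lambda2,
              sum(abs(offdiag) > 1e-8), length(offdiag)))
  cat(sprintf("  weights: beta = %.3g, gamma = %.3g, %d alpha | converged: %s\n",
              object@beta_w, object@gamma_w, length(object@alpha),
              object@converged))
  invisible(NULL)
})

setMethod("show", "KnockdownTable", function(object) {
  cat("KnockdownTable:", nrow(object@X), "cells x", ncol(object@X),
      "genes;", sum(rowSums(object@X != 0) > 0), "perturbed rows\n")
  invisible(NULL)
})

setMethod("show", "BootstrapEnsemble", function(object) {
  d <- dim(object@A_samples)
  cat("BootstrapEnsemble:", d[3], "replicates of a", d[1], "x", d[2],
      "network;", sum(object@converged), "converged\n")
  invisible(NULL)
})

setMethod("show", "TruthNetwork", function(object) {
  cat("TruthNetwork:", nrow(object@scores), "x", ncol(object@scores),
      "| threshold:", object@threshold,
      "| edges:", sum(truthEdges(object)), "\n")
  invisible(NULL)
})
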