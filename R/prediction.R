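## Predicting genome-wide expression changes after a knockout, and the
## leave-one-KO-out evaluation protocol.

#' Predict the expression change following a gene knockout
#'
#' Propagates a knockdown of gene \code{g} through the fitted network:
#' \deqn{\Delta E = \sum_{k=1}^K w(t,k,g) (M_g \odot A)^k X_g,}
#' the deviation from the wild-type baseline at time \code{t}. For a gene
#' never knocked out in training, \eqn{\alpha_g} defaults to the mean of the
#' fitted \eqn{\alpha} values. The change at gene \code{g} itself is zero
#' (masked row); the knockdown magnitude itself lives in \code{X_g}.
#'
#' @param model a [GRNModel-class].
#' @param g gene to knock out.
#' @param t time index.
#' @param magnitude knockdown entry of \code{X_g} (nonpositive); defaults to
#'   minus the model baseline of \code{g} at \code{t} (complete knockout).
#' @return Named vector of predicted expression changes (length G). Linear
#'   in \code{magnitude}.
#' @export
predictKoResponse <- function(model, g, t, magnitude = NULL) {
  genes <- geneNames(model)
  gi <- match(g, genes)
  if (is.na(gi)) .stopf("unknown gene '%s'", g)
  if (is.null(magnitude)) magnitude <- -model@b[gi, t]
  if (magnitude > 0) .stopf("knockdown magnitude must be nonpositive")
  x <- numeric(length(genes)); x[gi] <- magnitude
  rengeForward(model, g, t, x) - model@b[, t]
}

#' Leave-one-KO-out prediction benchmark
#'
#' Refits the model on every cell except those in which gene \code{j} was
#' knocked out (controls retained), predicts the expression change for the
#' KO of \code{j} at each time point, and reports the Pearson correlation
#' with the observed change (the stratum mean expression minus the
#' time-matched control baseline), over the other G - 1 genes.
#'
#' @param dataset a [RengeExperiment-class].
#' @param kd the matching [KnockdownTable-class].
#' @param j the held-out KO gene.
#' @param K,lambda1,lambda2 hyperparameters for the training fit.
#' @param seed integer seed.
#' @param ... passed to [rengeFit()].
#' @return A list with \code{correlations} (data.frame: time, cor, n_cells;
#'   \code{cor} is \code{NA} when the observed change has zero variance),
#'   \code{model} (the training fit), \code{predicted} and \code{observed}
#'   (G x T matrices of changes).
#' @export
leaveOneKoOut <- function(dataset, kd = buildKnockdownTable(dataset), j,
                          K = 2L, lambda1 = 0.01, lambda2 = 0.01,
                          seed = 0L, ...) {
  if (!j %in% koGenes(dataset))
    .stopf("'%s' is not a KO gene of this dataset", j)
  if (length(koGenes(dataset)) < 2L)
    .stopf("at least one other KO gene must remain for training")
  keep <- which(koGene(dataset) != j)
  ds_tr <- dataset[, keep]
  kd_tr <- KnockdownTable(knockdownMatrix(kd)[keep, , drop = FALSE],
                          perturbProb(kd)[keep])
  model <- rengeFit(ds_tr, kd_tr, K = K, lambda1 = lambda1,
                    lambda2 = lambda2, seed = seed, ...)
  genes <- geneNames(dataset)
  gi <- match(j, genes)
  Tn <- nTimePoints(dataset)
  E <- exprMatrix(dataset)
  ko <- koGene(dataset)
  ti <- timeIndex(dataset)
  pred <- obs <- matrix(NA_real_, length(genes), Tn,
                        dimnames = list(genes, NULL))
  res <- data.frame(time = seq_len(Tn), cor = NA_real_, n_cells = 0L)
  for (t in seq_len(Tn)) {
    base <- controlBaseline(dataset, t)
    pred[, t] <- predictKoResponse(model, j, t, magnitude = -base[gi])
    sel <- which(ko == j & ti == t)
    res$n_cells[t] <- length(sel)
    if (!length(sel)) next
    obs[, t] <- rowMeans(E[, sel, drop = FALSE]) - base
    po <- pred[-gi, t]; oo <- obs[-gi, t]
    if (stats::sd(oo) > 0 && stats::sd(po) > 0)
      res$cor[t] <- stats::cor(po, oo)
  }
  list(correlations = res, model = model, predicted = pred, observed = obs)
}
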