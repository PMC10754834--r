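## Cross-validated hyperparameter selection.

# Predicted expression for every cell of `dataset` under `model`, using the
# knockdown table for the per-cell knockdown scalar.
.predictCells <- function(model, dataset, kd) {
  E <- exprMatrix(dataset)
  X <- knockdownMatrix(kd)
  ko <- koGene(dataset)
  ti <- timeIndex(dataset)
  genes <- geneNames(dataset)
  P <- matrix(0, nrow(E), ncol(E), dimnames = dimnames(E))
  vcache <- list()
  for (c in seq_len(ncol(E))) {
    t <- ti[c]
    if (ko[c] == CONTROL) { P[, c] <- model@b[, t]; next }
    gi <- match(ko[c], genes)
    key <- paste0(ko[c], ".", t)
    if (is.null(vcache[[key]])) {
      e_g <- numeric(nrow(E)); e_g[gi] <- 1
      v <- rengeForward(model, ko[c], t, e_g) - model@b[, t]
      vcache[[key]] <- v
    }
    P[, c] <- model@b[, t] + X[c, gi] * vcache[[key]]
  }
  P
}

# Masked squared error of `model` on (dataset, kd): the KO gene's own
# coordinate is excluded per cell.
.maskedSqError <- function(model, dataset, kd) {
  P <- .predictCells(model, dataset, kd)
  R <- exprMatrix(dataset) - P
  ko <- koGene(dataset)
  genes <- geneNames(dataset)
  for (c in which(ko != CONTROL)) R[match(ko[c], genes), c] <- 0
  sum(R^2)
}

# Deterministic stratified fold assignment; cells within a stratum are
# ordered by id before shuffling so the split is permutation-invariant.
.foldAssignment <- function(dataset, folds, seed) {
  ko <- koGene(dataset)
  ti <- timeIndex(dataset)
  ids <- cellIds(dataset)
  fold <- rep(NA_integer_, length(ids))
  set.seed(as.integer(seed))
  small <- character(0)
  for (key in unique(paste(ko, ti, sep = "\r"))) {
    sel <- which(paste(ko, ti, sep = "\r") == key)
    sel <- sel[order(ids[sel])]
    if (length(sel) < folds) {
      small <- c(small, sub("\r", "@t", key))
      fold[sel] <- 0L          # kept entirely in training
      next
    }
    fold[sel] <- sample(rep_len(seq_len(folds), length(sel)))
  }
  if (length(small))
    .warnf("stratum smaller than %d folds kept entirely in training: %s",
           folds, paste(small, collapse = ", "))
  fold
}

#' Cross-validated loss of a hyperparameter setting
#'
#' Cells are partitioned into folds stratified by (KO gene, time); the model
#' is fitted on the training folds and scored by the masked squared error on
#' the held-out cells (mean per held-out cell, averaged over folds). Strata
#' smaller than the number of folds stay entirely in training, with a
#' warning. Deterministic given \code{seed}.
#'
#' @inheritParams rengeFit
#' @param folds number of folds (>= 2).
#' @param ... further arguments passed to [rengeFit()].
#' @return Mean held-out masked squared error per cell.
#' @export
rengeCvLoss <- function(dataset, kd = buildKnockdownTable(dataset), K = 2L,
                        lambda1 = 0.01, lambda2 = 0.01, folds = 5L,
                        seed = 0L, ...) {
  stopifnot(folds >= 2L)
  fold <- .foldAssignment(dataset, folds, seed)
  errs <- numeric(0)
  for (f in seq_len(folds)) {
    tr <- which(fold != f | fold == 0L)
    te <- which(fold == f)
    if (!length(te)) next
    ds_tr <- dataset[, tr]
    kd_tr <- KnockdownTable(knockdownMatrix(kd)[tr, , drop = FALSE],
                            perturbProb(kd)[tr])
    m <- rengeFit(ds_tr, kd_tr, K = K, lambda1 = lambda1, lambda2 = lambda2,
                  seed = seed, ...)
    ds_te <- dataset[, te]
    kd_te <- KnockdownTable(knockdownMatrix(kd)[te, , drop = FALSE],
                            perturbProb(kd)[te])
    errs <- c(errs, .maskedSqError(m, ds_te, kd_te) / length(te))
  }
  mean(errs)
}

#' Select hyperparameters by cross-validation
#'
#' Evaluates \code{budget} candidate settings — \code{K} uniform on
#' \code{1..K_max}, \eqn{\lambda_1, \lambda_2} log-uniform on
#' \code{lambda_range} — and returns the candidate minimizing the
#' cross-validation loss. The candidate stream is deterministic given
#' \code{seed}, and a larger budget extends the same stream, so the best
#' loss found never increases with budget.
#'
#' @inheritParams rengeCvLoss
#' @param budget number of candidate evaluations (>= 1).
#' @param K_max largest propagation order considered.
#' @param lambda_range range for both regularization strengths.
#' @return A list with \code{K}, \code{lambda1}, \code{lambda2},
#'   \code{cv_loss}, and the full \code{trials} table.
#' @export
selectHyperparameters <- function(dataset, kd = buildKnockdownTable(dataset),
                                  budget = 50L, folds = 5L, seed = 0L,
                                  K_max = 4L, lambda_range = c(1e-3, 1e2),
                                  ...) {
  stopifnot(budget >= 1L)
  lr <- log(lambda_range)
  Ks <- integer(budget); l1 <- numeric(budget); l2 <- numeric(budget)
  # candidates drawn one trial at a time so a larger budget extends the
  # same deterministic stream
  set.seed(as.integer(seed))
  for (i in seq_len(budget)) {
    Ks[i] <- sample.int(K_max, 1L)
    l1[i] <- exp(stats::runif(1, lr[1], lr[2]))
    l2[i] <- exp(stats::runif(1, lr[1], lr[2]))
  }
  cv <- numeric(budget)
  for (i in seq_len(budget)) {
    cv[i] <- suppressWarnings(
      rengeCvLoss(dataset, kd, K = Ks[i], lambda1 = l1[i], lambda2 = l2[i],
                  folds = folds, seed = seed, ...))
  }
  best <- which.min(cv)
  list(K = Ks[best], lambda1 = l1[best], lambda2 = l2[best],
       cv_loss = cv[best],
       trials = data.frame(K = Ks, lambda1 = l1, lambda2 = l2, cv_loss = cv))
}
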