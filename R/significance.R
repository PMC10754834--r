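## Bootstrap edge significance: stratified resampling, replicate refits,
## normal-approximation p-values and Benjamini-Hochberg q-values.

# Indices of a stratified resample with replacement (stratum sizes preserved).
.strataResampleIdx <- function(dataset) {
  ko <- koGene(dataset)
  ti <- timeIndex(dataset)
  idx <- integer(0)
  key <- paste(ko, ti, sep = "\r")
  for (k in unique(key)) {
    sel <- which(key == k)
    idx <- c(idx, sel[sample.int(length(sel), length(sel), replace = TRUE)])
  }
  idx
}

#' Resample cells within (KO gene, time) strata
#'
#' Draws, independently within every stratum, as many cells with replacement
#' as the stratum contains, so stratum sizes are preserved exactly.
#'
#' @param dataset a [RengeExperiment-class].
#' @param seed integer seed.
#' @return A resampled [RengeExperiment-class]; the drawn column indices are
#'   stored in \code{metadata(x)$boot_idx}.
#' @export
bootstrapResample <- function(dataset, seed = 0L) {
  set.seed(as.integer(seed))
  idx <- .strataResampleIdx(dataset)
  out <- dataset[, idx]
  colnames(out) <- make.unique(colnames(out))
  S4Vectors::metadata(out)$boot_idx <- idx
  out
}

#' Run the bootstrap ensemble
#'
#' Performs \code{N} resample-and-refit cycles at fixed hyperparameters
#' (selected once on the full data, never re-searched per replicate), with
#' per-replicate seeds derived deterministically from the master seed.
#' Non-convergent replicates are kept and flagged.
#'
#' @param dataset a [RengeExperiment-class].
#' @param kd the matching [KnockdownTable-class]; its rows are resampled
#'   alongside the cells (knockdown vectors are computed once, on the
#'   original data).
#' @param K,lambda1,lambda2 hyperparameters of the fit.
#' @param N number of replicates (default 30).
#' @param seed master seed.
#' @param freeze_w if \code{TRUE}, the weight parameters are frozen at the
#'   values of \code{ref_model} instead of re-estimated per replicate.
#' @param ref_model optional [GRNModel-class] supplying frozen weights and a
#'   warm start.
#' @param ... passed to [rengeFit()].
#' @return A [BootstrapEnsemble-class].
#' @export
runBootstrap <- function(dataset, kd = buildKnockdownTable(dataset),
                         K = 2L, lambda1 = 0.01, lambda2 = 0.01,
                         N = 30L, seed = 0L, freeze_w = FALSE,
                         ref_model = NULL, ...) {
  stopifnot(N >= 2L)
  G <- nrow(dataset)
  seeds <- .childSeeds(seed, N)
  A_samples <- array(NA_real_, c(G, G, N),
                     dimnames = list(geneNames(dataset), geneNames(dataset),
                                     NULL))
  converged <- logical(N)
  weights <- "estimate"
  if (freeze_w) {
    if (is.null(ref_model))
      .stopf("freeze_w = TRUE requires ref_model")
    wp <- weightParams(ref_model)
    weights <- list(alpha = wp$alpha, beta = wp$beta, gamma = wp$gamma)
  }
  X <- knockdownMatrix(kd)
  pp <- perturbProb(kd)
  for (l in seq_len(N)) {
    set.seed(seeds[l])
    idx <- .strataResampleIdx(dataset)
    ds_l <- dataset[, idx]
    colnames(ds_l) <- make.unique(colnames(ds_l))
    kd_l <- KnockdownTable(X[idx, , drop = FALSE], pp[idx])
    m <- suppressWarnings(
      rengeFit(ds_l, kd_l, K = K, lambda1 = lambda1, lambda2 = lambda2,
               seed = seeds[l], weights = weights, ...))
    A_samples[, , l] <- networkMatrix(m)
    converged[l] <- m@converged
  }
  if (any(!converged))
    .warnf("%d of %d bootstrap replicates did not converge",
           sum(!converged), N)
  BootstrapEnsemble(A_samples, seed = seed, converged = converged)
}

#' Edge p-values from a bootstrap ensemble
#'
#' For every off-diagonal coefficient, the bootstrap standard deviation
#' \code{s} (denominator N-1) defines the null \eqn{N(0, s^2)}; the
#' two-sided p-value is \eqn{p = 2(1 - \Phi(|A_{ij}| / s))}. Degenerate
#' cases: \code{s = 0} with a nonzero coefficient gives \code{p = 0} with a
#' warning, \code{s = 0} with a zero coefficient gives \code{p = 1}.
#' q-values control FDR by Benjamini-Hochberg over all off-diagonal tests.
#' Diagonal (self-regulation) entries are never tested or exported.
#'
#' @param ensemble a [BootstrapEnsemble-class].
#' @param A_hat the point estimate (G x G), e.g. \code{networkMatrix(fit)}.
#' @return An edge table (see [edgeTable()]) with p- and q-values.
#' @export
edgePvalues <- function(ensemble, A_hat) {
  stopifnot(nReplicates(ensemble) >= 2L)
  G <- nrow(A_hat)
  s <- apply(ensemble@A_samples, c(1, 2), stats::sd)
  z <- matrix(NA_real_, G, G)
  ok <- s > 0
  z[ok] <- A_hat[ok] / s[ok]
  p <- 2 * stats::pnorm(-abs(z))
  deg_nonzero <- !ok & A_hat != 0 & row(A_hat) != col(A_hat)
  if (any(deg_nonzero)) {
    .warnf("%d edge(s) with zero bootstrap variance and nonzero estimate; p set to 0",
           sum(deg_nonzero))
    p[deg_nonzero] <- 0
  }
  p[!ok & A_hat == 0] <- 1
  off <- row(p) != col(p)
  q <- matrix(NA_real_, G, G)
  q[off] <- stats::p.adjust(p[off], method = "BH")
  diag(p) <- NA_real_
  dimnames(p) <- dimnames(q) <- dimnames(A_hat)
  edgeTable(A_hat, p = p, q = q)
}
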