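## Parameter estimation: bound-constrained quasi-Newton (L-BFGS-B) on a
## smooth reparameterization. The L1 term is handled exactly by splitting
## A = A_pos - A_neg with A_pos, A_neg >= 0, so the penalty is linear in the
## optimization variables; the analytic gradient of the matrix-power terms is
## assembled from cached powers B^k e_g and transpose products.

# Build the smooth objective and its analytic gradient over the packed
# parameter vector. `weights` is "estimate", a list(alpha, beta, gamma) of
# frozen values, or a single numeric to pin w(t,k,g) to a constant.
.makeObjective <- function(dataset, kd, K, lambda1, lambda2,
                           weights = "estimate", estimate_baseline = TRUE,
                           init = NULL) {
  genes <- geneNames(dataset)
  G <- length(genes)
  Tn <- nTimePoints(dataset)
  kos <- koGenes(dataset)
  stats <- .strataStats(dataset, kd)
  b0 <- vapply(seq_len(Tn), function(t) controlBaseline(dataset, t),
               numeric(G))
  b0 <- matrix(b0, nrow = G)

  est_w <- identical(weights, "estimate")
  w_const <- if (is.numeric(weights) && length(weights) == 1L)
    as.numeric(weights) else NA_real_
  if (!est_w && is.na(w_const)) {
    a_fix <- weights$alpha
    if (length(a_fix) == 1L && is.null(names(a_fix)))
      a_fix <- stats::setNames(rep(a_fix, length(kos)), kos)
    a_fix <- stats::setNames(as.numeric(a_fix[kos]), kos)
    a_fix[is.na(a_fix)] <- 0
    beta_fix <- weights$beta
    gamma_fix <- weights$gamma
  } else {
    a_fix <- stats::setNames(rep(0, length(kos)), kos)
    beta_fix <- 1; gamma_fix <- 1
  }

  nA <- G * G
  idxP <- seq_len(nA)
  idxN <- nA + seq_len(nA)
  cur <- 2L * nA
  if (estimate_baseline) { idxB <- cur + seq_len(G * Tn); cur <- cur + G * Tn }
  else idxB <- integer(0)
  if (est_w) {
    idxAl <- cur + seq_along(kos); cur <- cur + length(kos)
    idxBe <- cur + 1L; idxGa <- cur + 2L; cur <- cur + 2L
  } else { idxAl <- integer(0); idxBe <- integer(0); idxGa <- integer(0) }

  npar <- cur
  par0 <- numeric(npar)
  if (estimate_baseline) par0[idxB] <- as.numeric(b0)
  if (est_w) { par0[idxAl] <- 0; par0[idxBe] <- 1; par0[idxGa] <- 1 }
  if (!is.null(init)) {
    if (!is.null(init$A)) {
      par0[idxP] <- pmax(as.numeric(init$A), 0)
      par0[idxN] <- pmax(-as.numeric(init$A), 0)
    }
    if (estimate_baseline && !is.null(init$b)) par0[idxB] <- as.numeric(init$b)
    if (est_w && !is.null(init$alpha)) par0[idxAl] <- init$alpha[kos]
    if (est_w && !is.null(init$beta)) par0[idxBe] <- init$beta
    if (est_w && !is.null(init$gamma)) par0[idxGa] <- init$gamma
  }
  lower <- rep(-Inf, npar); upper <- rep(Inf, npar)
  lower[c(idxP, idxN)] <- 0
  if (est_w) {
    lower[idxAl] <- -10; upper[idxAl] <- 10
    lower[c(idxBe, idxGa)] <- 0; upper[c(idxBe, idxGa)] <- 20
  }

  unpack <- function(par) {
    A <- matrix(par[idxP] - par[idxN], G, G, dimnames = list(genes, genes))
    b <- if (estimate_baseline)
      matrix(par[idxB], G, Tn) else b0
    rownames(b) <- genes
    if (est_w) {
      alpha <- stats::setNames(par[idxAl], kos)
      list(A = A, b = b, alpha = alpha, beta = par[idxBe], gamma = par[idxGa])
    } else {
      list(A = A, b = b, alpha = a_fix, beta = beta_fix, gamma = gamma_fix)
    }
  }

  # one shared forward/backward pass; fn and gr cache on the parameter vector
  evalBoth <- function(par) {
    pp <- unpack(par)
    A <- pp$A; b <- pp$b
    gA <- matrix(0, G, G)
    gb <- matrix(0, G, Tn)
    gAl <- stats::setNames(numeric(length(kos)), kos)
    gBe <- 0; gGa <- 0
    total <- 0
    for (st in stats) {
      bt <- b[, st$t]
      if (st$ko == CONTROL) {
        total <- total + st$sumE2 - 2 * sum(bt * st$sumE) + st$n * sum(bt^2)
        gb[, st$t] <- gb[, st$t] + 2 * (st$n * bt - st$sumE)
        next
      }
      gi <- st$g
      B <- .maskRow(A, gi)
      a_g <- if (est_w) pp$alpha[[st$ko]]
             else if (!is.na(w_const)) NA_real_
             else a_fix[[st$ko]]
      # forward: cache p_k = B^k e_g and weights
      pk <- vector("list", K + 1L)
      p <- numeric(G); p[gi] <- 1
      pk[[1L]] <- p
      w <- numeric(K)
      v <- numeric(G)
      for (k in seq_len(K)) {
        p <- as.numeric(B %*% p)
        pk[[k + 1L]] <- p
        w[k] <- if (!is.na(w_const)) w_const
                else .logistic(a_g + pp$beta * st$t - pp$gamma * k)
        v <- v + w[k] * p
      }
      bm <- bt; bm[gi] <- 0
      sEm <- st$sumE; sEm[gi] <- 0
      sSEm <- st$sumSE; sSEm[gi] <- 0
      total <- total + st$sumE2 -
        2 * sum(bm * sEm) - 2 * sum(v * sSEm) +
        st$n * sum(bm^2) + 2 * st$sum_s * sum(bm * v) +
        st$sum_s2 * sum(v^2)
      # baseline gradient (masked coordinate contributes nothing)
      gbt <- 2 * (st$n * bm - sEm + st$sum_s * v)
      gbt[gi] <- 0
      gb[, st$t] <- gb[, st$t] + gbt
      # rho = dL/dv
      rho <- 2 * (-sSEm + st$sum_s * bm + st$sum_s2 * v)
      # dL/dB = sum_k w_k sum_{j=0}^{k-1} (B^T)^j rho (B^{k-1-j} e_g)^T
      qj <- vector("list", K)
      q <- rho
      qj[[1L]] <- q
      if (K > 1L) for (j in 2:K) { q <- as.numeric(crossprod(B, q)); qj[[j]] <- q }
      dB <- matrix(0, G, G)
      for (k in seq_len(K)) {
        if (w[k] == 0) next
        for (j in 0:(k - 1L))
          dB <- dB + w[k] * tcrossprod(qj[[j + 1L]], pk[[k - j]])
      }
      dB[gi, ] <- 0                       # mask: row g of A is not a variable here
      gA <- gA + dB
      if (est_w) {
        for (k in seq_len(K)) {
          dwk <- sum(rho * pk[[k + 1L]])
          chain <- dwk * w[k] * (1 - w[k])
          gAl[st$ko] <- gAl[st$ko] + chain
          gBe <- gBe + chain * st$t
          gGa <- gGa - chain * k
        }
      }
    }
    # L2 penalty on powers of the (unmasked) A
    if (lambda2 > 0) {
      Apow <- vector("list", K + 1L)
      Apow[[1L]] <- diag(G)
      for (k in seq_len(K)) Apow[[k + 1L]] <- Apow[[k]] %*% A
      for (k in seq_len(K)) {
        total <- total + lambda2 * sum(Apow[[k + 1L]]^2)
        for (j in 0:(k - 1L))
          gA <- gA + 2 * lambda2 *
            t(Apow[[j + 1L]]) %*% Apow[[k + 1L]] %*% t(Apow[[k - j]])
      }
    }
    # L1 is linear in the split variables
    total <- total + lambda1 * sum(par[idxP] + par[idxN])
    grad <- numeric(npar)
    grad[idxP] <- as.numeric(gA) + lambda1
    grad[idxN] <- -as.numeric(gA) + lambda1
    if (estimate_baseline) grad[idxB] <- as.numeric(gb)
    if (est_w) { grad[idxAl] <- gAl; grad[idxBe] <- gBe; grad[idxGa] <- gGa }
    list(value = total, grad = grad)
  }

  cache <- new.env(parent = emptyenv())
  fn <- function(par) {
    res <- evalBoth(par)
    assign("par", par, envir = cache); assign("res", res, envir = cache)
    res$value
  }
  gr <- function(par) {
    if (exists("par", cache) && identical(get("par", cache), par))
      return(get("res", cache)$grad)
    evalBoth(par)$grad
  }
  list(fn = fn, gr = gr, par0 = par0, lower = lower, upper = upper,
       unpack = unpack, npar = npar, evalBoth = evalBoth)
}

#' Fit the network model
#'
#' Minimizes the objective of [rengeLoss()] jointly over the signed network
#' \code{A}, the per-time baselines, and the sigmoid weight parameters, using
#' bound-constrained L-BFGS-B. The L1 term is made smooth by the split
#' \code{A = A_pos - A_neg} with nonnegativity bounds; gradients of the
#' matrix-power terms are analytic. Initialization: \code{A = 0} (the
#' L1-preferred origin), baselines at the per-time control means (their
#' closed-form optimum under a zero network), \code{alpha = 0},
#' \code{beta = gamma = 1}.
#'
#' @param dataset a [RengeExperiment-class].
#' @param kd a [KnockdownTable-class]; computed via [buildKnockdownTable()]
#'   when omitted.
#' @param K maximum propagation order (1..4 is sensible for a handful of
#'   time points).
#' @param lambda1,lambda2 L1 / L2 regularization strengths.
#' @param seed integer; fitting is deterministic, the seed is recorded.
#' @param weights \code{"estimate"} (default), a list
#'   \code{list(alpha=, beta=, gamma=)} of frozen weight parameters, or a
#'   single number to pin \code{w(t,k,g)} to that constant.
#' @param estimate_baseline if \code{FALSE}, baselines stay fixed at the
#'   per-time control means.
#' @param init optional list of starting values (\code{A}, \code{b},
#'   \code{alpha}, \code{beta}, \code{gamma}).
#' @param maxit,factr L-BFGS-B controls.
#' @return A [GRNModel-class]; \code{converged} is \code{FALSE} (with a
#'   warning) if the iteration limit was hit.
#' @examples
#' sim <- simulateDataset(config = syntheticConfig(G = 6, n_ko = 3,
#'                        cells_per_stratum = 10, seed = 1))
#' fit <- rengeFit(sim$dataset, sim$kd, K = 2, lambda1 = 0.01, lambda2 = 0.01)
#' fit
#' @export
rengeFit <- function(dataset, kd = buildKnockdownTable(dataset), K = 2L,
                     lambda1 = 0.01, lambda2 = 0.01, seed = 0L,
                     weights = "estimate", estimate_baseline = TRUE,
                     init = NULL, maxit = 1000L, factr = 1e9) {
  if (!length(koGenes(dataset)))
    .stopf("at least one KO gene is required to fit a network")
  set.seed(as.integer(seed))
  obj <- .makeObjective(dataset, kd, K, lambda1, lambda2, weights,
                        estimate_baseline, init)
  opt <- stats::optim(obj$par0, fn = obj$fn, gr = obj$gr,
                      method = "L-BFGS-B",
                      lower = obj$lower, upper = obj$upper,
                      control = list(maxit = maxit, factr = factr))
  if (opt$convergence != 0)
    .warnf("L-BFGS-B did not converge (code %d): %s",
           opt$convergence, opt$message)
  pp <- obj$unpack(opt$par)
  GRNModel(A = pp$A, b = pp$b, alpha = pp$alpha, beta_w = pp$beta,
           gamma_w = pp$gamma, K = K, lambda1 = lambda1, lambda2 = lambda2,
           converged = opt$convergence == 0, value = opt$value,
           niter = as.integer(opt$counts[["function"]]),
           time_labels = .timeLabels(dataset))
}
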