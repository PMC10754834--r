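## The KO-propagation model: sigmoid time-order weights, masked matrix-power
## forward map, and the regularized least-squares objective.

#' Sigmoid time-order weight
#'
#' The strength at sampling time \code{t} of k-th order regulatory effects of
#' knocking out gene \code{g}:
#' \deqn{w(t, k, g) = 1 / (1 + \exp(-(\alpha_g + \beta t - \gamma k)))}
#' Monotonically increasing in \code{t} and decreasing in \code{k} (for
#' \eqn{\beta, \gamma > 0}): as time progresses, effects transmitted through
#' longer regulatory paths become more apparent. \eqn{\alpha_g} shifts how
#' quickly the KO of gene \code{g} takes effect.
#'
#' @param t time index.
#' @param k regulation order, \code{1..K}.
#' @param g KO gene name; genes without a fitted \eqn{\alpha} use the mean of
#'   the fitted values (0 when none were fitted).
#' @param model a [GRNModel-class].
#' @return Weight in (0, 1).
#' @export
rengeWeight <- function(t, k, g, model) {
  a <- .alphaFor(model, g)
  .logistic(a + model@beta_w * t - model@gamma_w * k)
}

.alphaFor <- function(model, g) {
  if (length(model@alpha) && g %in% names(model@alpha)) model@alpha[[g]]
  else if (length(model@alpha)) mean(model@alpha)
  else 0
}

# KO mask: row g of A is zeroed (a knocked-out gene is no longer regulated).
.maskRow <- function(A, g_idx) {
  if (length(g_idx)) A[g_idx, ] <- 0
  A
}

#' Forward propagation of a knockout through the network
#'
#' Computes the model's expected expression for a cell at time \code{t} in
#' which gene \code{g} was knocked out with knockdown vector \code{x}
#' (nonzero only at \code{g}):
#' \deqn{E = \sum_{k=1}^K w(t,k,g) (M_g \odot A)^k x + b_t,}
#' where \eqn{M_g} zeroes row \code{g} of \code{A}. For a control cell
#' (\code{g = "control"}, \code{x = 0}) the result is exactly \eqn{b_t}.
#' The component at the KO gene itself always equals \eqn{b_t[g]} (masked
#' row); the direct drop of the KO gene is carried by \code{x}, not by the
#' propagation.
#'
#' @param model a [GRNModel-class].
#' @param g KO gene name or \code{"control"}.
#' @param t time index.
#' @param x knockdown vector (length G); defaults to zero for control.
#' @return Expected expression vector of length G.
#' @export
rengeForward <- function(model, g, t, x = NULL) {
  b <- model@b[, t]
  if (identical(g, CONTROL)) return(b)
  genes <- geneNames(model)
  gi <- match(g, genes)
  if (is.na(gi)) .stopf("unknown KO gene '%s'", g)
  if (is.null(x)) x <- numeric(length(b))
  B <- .maskRow(model@A, gi)
  out <- b
  v <- x
  for (k in seq_len(model@K)) {
    v <- B %*% v
    out <- out + rengeWeight(t, k, g, model) * as.numeric(v)
  }
  names(out) <- genes
  out
}

#' Objective function of the model
#'
#' The fitting objective: the masked squared error between the data and the
#' forward model, plus L1 on \code{A} and L2 on every power \code{A^k},
#' \code{k = 1..K}:
#' \deqn{L = \sum_{t,c} \| m_{c,t} \odot (E_{c,t} - \hat E_{c,t}) \|_2^2
#'       + \lambda_1 \sum_{i,j} |A_{i,j}|
#'       + \lambda_2 \sum_{k=1}^K \sum_{i,j} (A^k)_{i,j}^2,}
#' where the mask \eqn{m_{c,t}} zeroes the KO gene's own coordinate (its
#' mRNA may persist after a functional knockout, so its residual is ignored).
#'
#' @param model a [GRNModel-class].
#' @param dataset a [RengeExperiment-class].
#' @param kd the matching [KnockdownTable-class].
#' @return The scalar objective value.
#' @export
rengeLoss <- function(model, dataset, kd) {
  st <- .strataStats(dataset, kd)
  fit <- .lossFromStats(model@A, model@b, model@alpha, model@beta_w,
                        model@gamma_w, model@K, st, geneNames(dataset))
  pen <- model@lambda1 * sum(abs(model@A)) +
    model@lambda2 * .powerPenalty(model@A, model@K)
  fit + pen
}

.powerPenalty <- function(A, K) {
  s <- 0
  Ak <- diag(nrow(A))
  for (k in seq_len(K)) {
    Ak <- Ak %*% A
    s <- s + sum(Ak^2)
  }
  s
}

## ---------------------------------------------------------------------------
## Sufficient statistics per (ko_gene, time) stratum.
##
## Within a stratum every cell's knockdown vector is s_c * e_g where s_c is
## the (signed, nonpositive) scalar entry; the model's prediction for the cell
## is b_t + s_c * v with v = sum_k w(t,k,g) B^k e_g. The per-cell squared
## error therefore collapses to moments (n, sum s, sum s^2, sum E, sum s*E,
## sum ||E||^2), making each objective evaluation O(strata * G + K * G^2)
## instead of O(cells * G).
## ---------------------------------------------------------------------------

.strataStats <- function(dataset, kd) {
  E <- exprMatrix(dataset)
  X <- knockdownMatrix(kd)
  ko <- koGene(dataset)
  ti <- timeIndex(dataset)
  genes <- geneNames(dataset)
  out <- list()
  for (t in sort(unique(ti))) {
    for (g in unique(ko[ti == t])) {
      sel <- which(ko == g & ti == t)
      Ecg <- E[, sel, drop = FALSE]
      if (g == CONTROL) {
        out[[length(out) + 1L]] <- list(
          g = NA_integer_, ko = CONTROL, t = t, n = length(sel),
          sumE = rowSums(Ecg), sumE2 = sum(Ecg^2),
          s = numeric(0), sum_s = 0, sum_s2 = 0, sumSE = NULL)
      } else {
        gi <- match(g, genes)
        s <- X[sel, gi]
        mrows <- Ecg[-gi, , drop = FALSE]
        out[[length(out) + 1L]] <- list(
          g = gi, ko = g, t = t, n = length(sel),
          sumE = rowSums(Ecg), sumE2 = sum(mrows^2),
          s = s, sum_s = sum(s), sum_s2 = sum(s^2),
          sumSE = as.numeric(Ecg %*% s))
      }
    }
  }
  out
}

# Masked squared-error part of the objective from sufficient statistics.
.lossFromStats <- function(A, b, alpha, beta_w, gamma_w, K, stats, genes) {
  total <- 0
  for (st in stats) {
    bt <- b[, st$t]
    if (st$ko == CONTROL) {
      total <- total + st$sumE2 - 2 * sum(bt * st$sumE) + st$n * sum(bt^2)
    } else {
      gi <- st$g
      B <- .maskRow(A, gi)
      a <- if (st$ko %in% names(alpha)) alpha[[st$ko]] else 0
      v <- numeric(nrow(A))
      pk <- numeric(nrow(A)); pk[gi] <- 1      # B^0 e_g
      for (k in seq_len(K)) {
        pk <- as.numeric(B %*% pk)
        w <- .logistic(a + beta_w * st$t - gamma_w * k)
        v <- v + w * pk
      }
      bm <- bt; bm[gi] <- 0
      sEm <- st$sumE; sEm[gi] <- 0
      sSEm <- st$sumSE; sSEm[gi] <- 0
      # v[gi] is structurally zero (masked row)
      total <- total + st$sumE2 -
        2 * sum(bm * sEm) - 2 * sum(v * sSEm) +
        st$n * sum(bm^2) + 2 * st$sum_s * sum(bm * v) +
        st$sum_s2 * sum(v^2)
    }
  }
  total
}
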