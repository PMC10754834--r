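## Synthetic ground-truth networks and simulated time-series KO screens,
## matched to the model class (with optional misspecification modes).

#' Configuration of the synthetic generator
#'
#' The defaults are the package's standard benchmark conditions: a 20-gene
#' network, 10 of which are knocked out, sampled at 4 time points with 30
#' cells per (KO, time) stratum; 12% edge density, 70% positive signs,
#' spectral radius capped at 0.8 (bounded matrix powers), Gaussian
#' observation noise with sd 0.1 on the normalized-expression scale, true
#' propagation order 2, and weight parameters alpha = 0, beta = 1,
#' gamma = 1.
#'
#' @param G number of genes.
#' @param n_ko number of KO genes (the first \code{n_ko} genes).
#' @param T_points number of time points.
#' @param cells_per_stratum cells per (KO-or-control, time) stratum.
#' @param edge_density Bernoulli probability of an off-diagonal edge.
#' @param sign_mix fraction of positive edges.
#' @param spectral_cap target spectral radius of the true network (< 1).
#' @param noise_sd observation noise standard deviation.
#' @param K_true true maximum propagation order.
#' @param alpha,beta,gamma true sigmoid weight parameters (alpha recycles
#'   over KO genes).
#' @param baseline_range wild-type expression baselines are drawn uniformly
#'   from this range.
#' @param squash \code{"none"} (linear, the model class) or \code{"tanh"}
#'   (each propagation step squashed through tanh; mild misspecification).
#' @param counts if \code{TRUE}, observations are negative-binomial counts
#'   around the model mean, then log1p-normalized (misspecification mode).
#' @param seed integer seed.
#' @return A list of class \code{"renge_config"}.
#' @export
syntheticConfig <- function(G = 20L, n_ko = 10L, T_points = 4L,
                            cells_per_stratum = 30L, edge_density = 0.12,
                            sign_mix = 0.7, spectral_cap = 0.8,
                            noise_sd = 0.1, K_true = 2L, alpha = 0,
                            beta = 1, gamma = 1, baseline_range = c(1, 3),
                            squash = c("none", "tanh"), counts = FALSE,
                            seed = 0L) {
  squash <- match.arg(squash)
  stopifnot(n_ko <= G, edge_density > 0 || edge_density == 0,
            edge_density < 1, spectral_cap < 1, noise_sd >= 0, K_true >= 1)
  structure(list(G = as.integer(G), n_ko = as.integer(n_ko),
                 T_points = as.integer(T_points),
                 cells_per_stratum = as.integer(cells_per_stratum),
                 edge_density = edge_density, sign_mix = sign_mix,
                 spectral_cap = spectral_cap, noise_sd = noise_sd,
                 K_true = as.integer(K_true), alpha = alpha, beta = beta,
                 gamma = gamma, baseline_range = baseline_range,
                 squash = squash, counts = counts, seed = as.integer(seed)),
            class = "renge_config")
}

#' Generate a sparse signed ground-truth network
#'
#' Off-diagonal support is Bernoulli(\code{edge_density}); magnitudes are
#' uniform on [0.3, 1] with signs Bernoulli(\code{sign_mix}); the matrix is
#' rescaled so its spectral radius equals \code{spectral_cap} (when the
#' radius is nonzero — strictly triangular support is nilpotent and left
#' unscaled); the diagonal is zero. Deterministic given \code{config$seed}.
#'
#' @param config a [syntheticConfig()].
#' @return A list with \code{A_true} (G x G signed matrix) and \code{truth}
#'   (a [TruthNetwork-class]).
#' @export
generateNetwork <- function(config) {
  set.seed(config$seed)
  G <- config$G
  genes <- sprintf("g%02d", seq_len(G))
  A <- matrix(0, G, G, dimnames = list(genes, genes))
  off <- which(.offDiag(A))
  sup <- off[stats::runif(length(off)) < config$edge_density]
  mag <- stats::runif(length(sup), 0.3, 1)
  sgn <- ifelse(stats::runif(length(sup)) < config$sign_mix, 1, -1)
  A[sup] <- mag * sgn
  rho <- max(Mod(eigen(A, only.values = TRUE)$values))
  if (rho > 1e-12) A <- A * (config$spectral_cap / rho)
  list(A_true = A, truth = TruthNetwork(A, threshold = 0, signed = TRUE))
}

# Deviation of the stratum mean from baseline: sum_k w(t,k,g) step_k with
# step_k = B step_{k-1} (optionally tanh-squashed per step), step_0 = x.
.simDeviation <- function(A, gi, t, x, K, w_fun, squash) {
  B <- .maskRow(A, gi)
  dev <- numeric(length(x))
  v <- x
  for (k in seq_len(K)) {
    v <- as.numeric(B %*% v)
    if (squash == "tanh") v <- tanh(v)
    dev <- dev + w_fun(t, k) * v
  }
  dev
}

#' Simulate a time-series KO screen from a true network
#'
#' Every (KO gene, time) stratum and every control stratum receives
#' \code{cells_per_stratum} cells. A stratum's mean expression is the
#' model's forward map: baseline plus the weighted masked matrix-power
#' propagation of the knockdown vector \eqn{X_g} (whose entry at g is minus
#' the gene's baseline: a complete knockout), and the KO gene's own
#' coordinate additionally carries the direct drop, landing near zero.
#' Cells are the stratum mean plus i.i.d. Gaussian noise (or
#' negative-binomial counts in \code{counts} mode). Deterministic given
#' \code{config$seed}.
#'
#' @param A_true true network; generated from \code{config} when omitted.
#' @param config a [syntheticConfig()].
#' @return A list with \code{dataset} ([RengeExperiment-class]),
#'   \code{kd} ([KnockdownTable-class]), \code{model} (the true
#'   [GRNModel-class]), and \code{truth} ([TruthNetwork-class]).
#' @export
simulateDataset <- function(A_true = NULL, config = syntheticConfig()) {
  if (is.null(A_true)) {
    net <- generateNetwork(config)
    A_true <- net$A_true
    truth <- net$truth
  } else {
    truth <- TruthNetwork(A_true, threshold = 0, signed = TRUE)
  }
  set.seed(config$seed + 1L)
  G <- config$G
  genes <- rownames(A_true)
  if (is.null(genes)) genes <- sprintf("g%02d", seq_len(G))
  kos <- genes[seq_len(config$n_ko)]
  Tn <- config$T_points
  base <- stats::runif(G, config$baseline_range[1], config$baseline_range[2])
  b <- matrix(base, G, Tn, dimnames = list(genes, NULL))
  alpha <- stats::setNames(rep_len(config$alpha, length(kos)), kos)
  model <- GRNModel(A = A_true, b = b, alpha = alpha,
                    beta_w = config$beta, gamma_w = config$gamma,
                    K = config$K_true, lambda1 = 0, lambda2 = 0)
  ncell <- (length(kos) + 1L) * Tn * config$cells_per_stratum
  expr <- matrix(NA_real_, ncell, G, dimnames = list(NULL, genes))
  ko_lab <- character(ncell); tvec <- integer(ncell); row <- 0L
  Xrows <- matrix(0, ncell, G, dimnames = list(NULL, genes))
  for (t in seq_len(Tn)) {
    for (g in c(CONTROL, kos)) {
      mu <- b[, t]
      xr <- numeric(G)
      if (g != CONTROL) {
        gi <- match(g, genes)
        xr[gi] <- -b[gi, t]
        w_fun <- function(tt, k)
          .logistic(alpha[[g]] + config$beta * tt - config$gamma * k)
        mu <- mu + .simDeviation(A_true, gi, t, xr, config$K_true,
                                 w_fun, config$squash)
        mu[gi] <- mu[gi] + xr[gi]   # direct drop of the KO gene itself
      }
      for (i in seq_len(config$cells_per_stratum)) {
        row <- row + 1L
        if (config$counts) {
          lam <- pmax(expm1(pmax(mu, 0)), 1e-6)
          expr[row, ] <- log1p(stats::rnbinom(G, mu = lam, size = 20))
        } else {
          expr[row, ] <- mu + stats::rnorm(G, sd = config$noise_sd)
        }
        ko_lab[row] <- g
        tvec[row] <- t
        Xrows[row, ] <- xr
      }
    }
  }
  ids <- sprintf("cell%05d", seq_len(ncell))
  rownames(expr) <- rownames(Xrows) <- ids
  ds <- RengeExperiment(expr, time = tvec, ko_gene = ko_lab,
                        cell_ids = ids, gene_names = genes)
  list(dataset = ds, kd = KnockdownTable(Xrows, rep(1, ncell)),
       model = model, truth = truth)
}

#' Benchmark sensitivity to the fraction of knocked-out genes
#'
#' For each ratio, a random subset M of the KO genes of size
#' \code{round(ratio * n_ko)} is selected; training is restricted to control
#' cells plus cells whose KO gene lies in M; the model is fitted and edge
#' recovery is scored by AUPRC ratios — overall, for edges whose regulator
#' is in M ("ko"), and for edges from never-knocked-out regulators
#' ("non_ko") — plus signed variants.
#'
#' @param config a [syntheticConfig()].
#' @param ratios fractions of KO genes to retain, in (0, 1].
#' @param seed seed governing subset choice (data come from
#'   \code{config$seed}).
#' @param K,lambda1,lambda2 fitting hyperparameters.
#' @param ... passed to [rengeFit()].
#' @return A data.frame with one row per ratio.
#' @export
koRatioSweep <- function(config = syntheticConfig(),
                         ratios = c(0.2, 0.6, 1.0), seed = 0L,
                         K = config$K_true, lambda1 = 0.01, lambda2 = 0.01,
                         ...) {
  stopifnot(all(ratios > 0 & ratios <= 1))
  sim <- simulateDataset(config = config)
  ds <- sim$dataset
  kd <- sim$kd
  kos <- koGenes(ds)
  truth <- sim$truth
  edges <- truthEdges(truth)
  set.seed(as.integer(seed))
  out <- data.frame()
  for (r in ratios) {
    m_size <- max(1L, round(r * length(kos)))
    M <- sort(sample(kos, m_size))
    keep <- which(koGene(ds) == CONTROL | koGene(ds) %in% M)
    ds_r <- ds[, keep]
    kd_r <- KnockdownTable(knockdownMatrix(kd)[keep, , drop = FALSE],
                           perturbProb(kd)[keep])
    fit <- rengeFit(ds_r, kd_r, K = K, lambda1 = lambda1, lambda2 = lambda2,
                    ...)
    A <- networkMatrix(fit)
    conf <- abs(A)
    in_M <- colnames(A) %in% M
    row_r <- data.frame(ratio = r, n_ko_used = m_size,
                        auprc_ratio = auprcRatio(conf, truth))
    row_r$auprc_ratio_ko <- .subsetAuprcRatio(conf, edges, in_M)
    row_r$auprc_ratio_non_ko <- .subsetAuprcRatio(conf, edges, !in_M)
    row_r$auprc_ratio_pos <- tryCatch(
      signedAuprcRatio(A, truth, "+"), error = function(e) NA_real_)
    row_r$auprc_ratio_neg <- tryCatch(
      signedAuprcRatio(A, truth, "-"), error = function(e) NA_real_)
    out <- rbind(out, row_r)
  }
  out
}

# AUPRC ratio restricted to edges whose regulator (column) is selected.
.subsetAuprcRatio <- function(conf, edges, col_sel) {
  if (!any(col_sel)) return(NA_real_)
  off <- .offDiag(edges) & matrix(col_sel, nrow(edges), ncol(edges),
                                  byrow = TRUE)
  y <- edges[off]
  if (!any(y) || all(y)) return(NA_real_)
  .auprc(conf[off], y) / mean(y)
}
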