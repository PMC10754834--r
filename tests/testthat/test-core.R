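toyModel <- function(A, b = matrix(0, nrow(A), 2), alpha = numeric(0),
                     beta_w = 0, gamma_w = 0, K = 1L, ...) {
  if (is.null(rownames(A))) {
    genes <- paste0("g", seq_len(nrow(A)))
    dimnames(A) <- list(genes, genes)
  }
  rownames(b) <- rownames(A)
  GRNModel(A = A, b = b, alpha = alpha, beta_w = beta_w, gamma_w = gamma_w,
           K = as.integer(K), ...)
}

test_that("sigmoid weights match the logistic and its limits", {
  m0 <- toyModel(diag(2) * 0, alpha = c(g1 = 0), beta_w = 0, gamma_w = 0)
  expect_equal(rengeWeight(3, 2, "g1", m0), 0.5)      # logistic at 0
  m1 <- toyModel(diag(2) * 0, alpha = c(g1 = 0), beta_w = 1, gamma_w = 1)
  expect_equal(rengeWeight(2, 1, "g1", m1), 1 / (1 + exp(-1)))
  mg <- toyModel(diag(2) * 0, alpha = c(g1 = 0), beta_w = 1, gamma_w = 700)
  expect_equal(rengeWeight(2, 1, "g1", mg), 0)        # overflow-safe limit
})

test_that("weights are increasing in t, decreasing in k, bounded in (0,1)", {
  m <- toyModel(diag(3) * 0, alpha = c(g1 = 0.3), beta_w = 0.8,
                gamma_w = 1.2)
  for (k in 1:4) {
    w <- sapply(1:6, function(t) rengeWeight(t, k, "g1", m))
    expect_true(all(diff(w) > 0))
    expect_true(all(w > 0 & w < 1))
  }
  for (t in 1:4) {
    w <- sapply(1:5, function(k) rengeWeight(t, k, "g1", m))
    expect_true(all(diff(w) < 0))
  }
  # gene without fitted alpha falls back to the mean alpha
  m2 <- toyModel(diag(2) * 0, alpha = c(g1 = 1, g2 = 3))
  expect_equal(rengeWeight(1, 1, "unseen", m2),
               renge:::.logistic(2))
})

test_that("forward propagation matches hand matrix-vector products", {
  A <- matrix(c(0, 0.5, 0, 0), 2, 2)   # A[2,1] = 0.5: g1 -> g2
  m <- toyModel(A, alpha = c(g1 = 20), beta_w = 0, gamma_w = 0, K = 1L)
  # alpha large -> w ~ 1
  out <- rengeForward(m, "g1", 1, c(-1, 0))
  expect_equal(unname(out), c(0, -0.5), tolerance = 1e-8)
  # nilpotent A: K = 2 adds nothing
  m2 <- toyModel(A, alpha = c(g1 = 20), beta_w = 0, gamma_w = 0, K = 2L)
  expect_equal(rengeForward(m2, "g1", 1, c(-1, 0)), out, tolerance = 1e-9)
  # control -> exactly the baseline
  b <- matrix(c(1, 2, 3, 4), 2, 2)
  mc <- toyModel(A, b = b, K = 2L)
  expect_equal(unname(rengeForward(mc, "control", 2)), c(3, 4))
})

test_that("the KO gene's own coordinate always equals the baseline", {
  set.seed(4)
  G <- 6
  A <- matrix(rnorm(G * G, sd = 0.4), G, G)
  b <- matrix(runif(G * 3, 1, 2), G, 3)
  genes <- paste0("g", 1:G)
  dimnames(A) <- list(genes, genes); rownames(b) <- genes
  for (K in c(1L, 3L)) {
    m <- GRNModel(A = A, b = b, alpha = c(g2 = 0.5), beta_w = 1, gamma_w = 1,
                  K = K)
    for (t in 1:3) {
      x <- numeric(G); x[2] <- -1.7
      expect_equal(rengeForward(m, "g2", t, x)[["g2"]], unname(b[2, t]))
    }
  }
})

test_that("objective value matches hand-computed penalty and zero cases", {
  # penalty only: A = [[0,1],[1,0]], K = 2 -> sum A^2 + sum (A^2)^2 = 2 + 2
  A <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_equal(renge:::.powerPenalty(A, 2L), 4)
  # control-only data equal to baselines, A = 0 -> loss 0
  E <- matrix(rep(c(1, 2), each = 4), 4, 2,
              dimnames = list(paste0("c", 1:4), c("g1", "g2")))
  ds <- RengeExperiment(E, time = rep(1:2, 2),
                        ko_gene = rep("control", 4))
  kd <- buildKnockdownTable(ds)
  m <- GRNModel(A = matrix(0, 2, 2, dimnames = list(c("g1", "g2"),
                                                    c("g1", "g2"))),
                b = matrix(c(1, 1, 1, 1), 2, 2), K = 1L)
  b0 <- vapply(1:2, function(t) controlBaseline(ds, t), numeric(2))
  m@b <- matrix(b0, 2, 2)
  expect_equal(rengeLoss(m, ds, kd), 0)
})

test_that("loss on a noiseless simulation is zero at the generating model", {
  sim <- makeSimDataset(G = 5, n_ko = 3, T_points = 3, n_per = 3,
                        noise_sd = 0, seed = 21, K_true = 2)
  expect_equal(rengeLoss(sim$model, sim$dataset, sim$kd), 0,
               tolerance = 1e-10)
})

test_that("analytic gradient matches central finite differences", {
  sim <- makeSimDataset(G = 5, n_ko = 3, T_points = 2, n_per = 4,
                        noise_sd = 0.2, seed = 13, K_true = 2)
  obj <- renge:::.makeObjective(sim$dataset, sim$kd, K = 3L,
                                lambda1 = 0.05, lambda2 = 0.3)
  set.seed(99)
  for (rep in 1:3) {
    par <- obj$par0 + abs(rnorm(obj$npar)) * 0.1
    gan <- obj$gr(par)
    idx <- sample(obj$npar, 20)
    eps <- 1e-6
    gfd <- vapply(idx, function(i) {
      p1 <- par; p2 <- par
      p1[i] <- p1[i] + eps; p2[i] <- p2[i] - eps
      (obj$fn(p1) - obj$fn(p2)) / (2 * eps)
    }, numeric(1))
    expect_lt(max(abs(gfd - gan[idx]) / pmax(abs(gfd), 1e-6)), 1e-5)
  }
})

test_that("zero-signal data with L1 gives an exactly zero off-diagonal network", {
  # KO cells identical to the control baseline: no knockout effect
  genes <- c("g1", "g2", "g3")
  E <- matrix(rep(c(1, 2, 3), each = 12), 12, 3,
              dimnames = list(paste0("c", 1:12), genes))
  ds <- RengeExperiment(E, time = rep(1:2, 6),
                        ko_gene = rep(c("control", "g1", "g2"), each = 4))
  fit <- rengeFit(ds, K = 1L, lambda1 = 0.5, lambda2 = 0)
  A <- networkMatrix(fit)
  expect_equal(max(abs(A[row(A) != col(A)])), 0)
})

test_that("doubling lambda1 does not increase the L1 norm of A", {
  sim <- makeSimDataset(G = 5, n_ko = 4, T_points = 2, n_per = 5,
                        noise_sd = 0.1, seed = 31)
  f1 <- rengeFit(sim$dataset, sim$kd, K = 1L, lambda1 = 0.05, lambda2 = 0.01)
  f2 <- rengeFit(sim$dataset, sim$kd, K = 1L, lambda1 = 0.1, lambda2 = 0.01)
  expect_lte(sum(abs(networkMatrix(f2))), sum(abs(networkMatrix(f1))) + 1e-6)
})

test_that("noiseless data with frozen weights recovers the true network", {
  cfg <- syntheticConfig(G = 4, n_ko = 4, cells_per_stratum = 5,
                         noise_sd = 0, edge_density = 0.3, seed = 7)
  sim <- simulateDataset(config = cfg)
  fit <- rengeFit(sim$dataset, sim$kd, K = 2L, lambda1 = 1e-6,
                  lambda2 = 1e-6, weights = list(alpha = 0, beta = 1,
                                                 gamma = 1))
  A <- networkMatrix(fit); At <- networkMatrix(sim$model)
  off <- row(A) != col(A)
  expect_lt(max(abs(A - At)[off]), 0.05)
})

test_that("fitting is deterministic given the seed", {
  sim <- makeSimDataset(G = 4, n_ko = 2, T_points = 2, n_per = 4,
                        noise_sd = 0.1, seed = 17)
  f1 <- rengeFit(sim$dataset, sim$kd, K = 1L, seed = 3)
  f2 <- rengeFit(sim$dataset, sim$kd, K = 1L, seed = 3)
  expect_identical(networkMatrix(f1), networkMatrix(f2))
})

test_that("the split fit equals an independent coordinate-descent lasso", {
  skip_if_not_installed("glmnet")
  set.seed(42)
  G <- 5; genes <- paste0("g", 1:G)
  A_true <- matrix(0, G, G, dimnames = list(genes, genes))
  A_true[2, 1] <- 0.6; A_true[3, 2] <- -0.5; A_true[5, 4] <- 0.4
  b <- runif(G, 1, 3)
  rows <- list(); ko <- character(0)
  for (g in c("control", genes)) for (i in 1:10) {
    x <- numeric(G)
    B <- A_true
    if (g != "control") {
      gi <- match(g, genes); x[gi] <- -b[gi]; B[gi, ] <- 0
    }
    mu <- b + as.numeric(B %*% x)
    if (g != "control") mu[match(g, genes)] <- 0
    rows[[length(rows) + 1]] <- mu + rnorm(G, sd = 0.15)
    ko <- c(ko, g)
  }
  E <- do.call(rbind, rows)
  dimnames(E) <- list(paste0("c", seq_len(nrow(E))), genes)
  ds <- RengeExperiment(E, time = rep(1, nrow(E)), ko_gene = ko)
  kd <- buildKnockdownTable(ds)
  lam1 <- 0.5
  fit <- rengeFit(ds, kd, K = 1L, lambda1 = lam1, lambda2 = 0, weights = 1,
                  estimate_baseline = FALSE, factr = 1e5, maxit = 5000)
  A <- networkMatrix(fit)
  X <- knockdownMatrix(kd); bse <- controlBaseline(ds, 1)
  Aor <- matrix(0, G, G)
  for (i in 1:G) {
    keep <- which(koGene(ds) != genes[i])
    g <- glmnet::glmnet(X[keep, , drop = FALSE], E[keep, i] - bse[i],
                        alpha = 1, lambda = lam1 / (2 * length(keep)),
                        standardize = FALSE, intercept = FALSE,
                        thresh = 1e-12)
    Aor[i, ] <- as.numeric(stats::coef(g))[-1]
  }
  expect_lt(max(abs(A - Aor)), 1e-3)
})

test_that("cross-validation is deterministic and permutation-invariant", {
  sim <- makeSimDataset(G = 4, n_ko = 2, T_points = 2, n_per = 6,
                        noise_sd = 0.1, seed = 23)
  ds <- sim$dataset; kd <- sim$kd
  cv1 <- rengeCvLoss(ds, kd, K = 1L, folds = 2, seed = 5, factr = 1e5)
  cv2 <- rengeCvLoss(ds, kd, K = 1L, folds = 2, seed = 5, factr = 1e5)
  expect_identical(cv1, cv2)
  perm <- sample(ncol(ds))
  kd_p <- KnockdownTable(knockdownMatrix(kd)[perm, , drop = FALSE],
                         perturbProb(kd)[perm])
  # fold membership is permutation-invariant (cells ordered by id within
  # strata); refits agree to optimizer tolerance, not to machine precision
  cv3 <- rengeCvLoss(ds[, perm], kd_p, K = 1L, folds = 2, seed = 5,
                     factr = 1e5)
  expect_equal(cv3, cv1, tolerance = 1e-2)
})

test_that("strata smaller than the fold count stay in training with a warning", {
  genes <- c("g1", "g2")
  E <- matrix(runif(20, 1, 2), 10, 2,
              dimnames = list(paste0("c", 1:10), genes))
  ds <- RengeExperiment(E, time = rep(1, 10),
                        ko_gene = c(rep("control", 6), rep("g1", 3), "g2"))
  expect_warning(rengeCvLoss(ds, K = 1L, folds = 2, seed = 1),
                 "entirely in training")
})

test_that("hyperparameter search returns the cv-argmin and improves with budget", {
  sim <- makeSimDataset(G = 4, n_ko = 2, T_points = 2, n_per = 6,
                        noise_sd = 0.1, seed = 29)
  h1 <- suppressWarnings(
    selectHyperparameters(sim$dataset, sim$kd, budget = 1, folds = 2,
                          seed = 8))
  expect_equal(nrow(h1$trials), 1L)
  expect_equal(h1$cv_loss, h1$trials$cv_loss[1])
  h3 <- suppressWarnings(
    selectHyperparameters(sim$dataset, sim$kd, budget = 3, folds = 2,
                          seed = 8))
  expect_equal(h3$cv_loss, min(h3$trials$cv_loss))
  # same seed stream prefix: a larger budget never worsens the best loss
  expect_lte(h3$cv_loss, h1$cv_loss + 1e-12)
  expect_equal(h3$trials$lambda1[1], h1$trials$lambda1[1])
})
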