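# Fixture builders shared across test files. Everything is generated in
# code; no data files.

# Small hand-specified dataset: G genes, one KO stratum per KO gene at each
# time, deterministic means from a supplied network, optional noise.
makeSimDataset <- function(G = 5, n_ko = G, T_points = 2, n_per = 6,
                           noise_sd = 0, seed = 1, edge_density = 0.25,
                           K_true = 1, beta = 1, gamma = 1,
                           cells_per_stratum = NULL) {
  cfg <- syntheticConfig(G = G, n_ko = n_ko, T_points = T_points,
                         cells_per_stratum = n_per, noise_sd = noise_sd,
                         edge_density = edge_density, K_true = K_true,
                         beta = beta, gamma = gamma, seed = seed)
  simulateDataset(config = cfg)
}

# Two-stratum single-time dataset with exact group means (for closed-form
# regression checks).
makeTwoGroupDataset <- function(ctrl_mean = 5, ko_mean = 3, n = 4) {
  genes <- c("gA", "gB")
  E <- rbind(
    matrix(rep(c(ctrl_mean, 2), each = n), n, 2),
    matrix(rep(c(ko_mean, 2), each = n), n, 2))
  colnames(E) <- genes
  rownames(E) <- paste0("c", seq_len(2 * n))
  RengeExperiment(E, time = rep(1, 2 * n),
                  ko_gene = rep(c("control", "gA"), each = n))
}

# Naive O(n^2) precision-recall area: for every distinct score threshold
# take predictions >= threshold, accumulate precision x recall increment.
# Independent re-derivation used as the AUPRC oracle.
bruteAuprc <- function(scores, labels) {
  th <- sort(unique(scores), decreasing = TRUE)
  P <- sum(labels)
  area <- 0; rec_prev <- 0
  for (s in th) {
    sel <- scores >= s
    prec <- sum(labels[sel]) / sum(sel)
    rec <- sum(labels[sel]) / P
    area <- area + prec * (rec - rec_prev)
    rec_prev <- rec
  }
  area
}

# Hand Benjamini-Hochberg step-up.
bhOracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  prev <- 1
  for (i in m:1) {
    val <- min(prev, p[o[i]] * m / i)
    q[o[i]] <- val
    prev <- val
  }
  q
}
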