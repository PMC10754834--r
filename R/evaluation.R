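## Benchmark statistics: AUPRC ratios, edge classification against a truth
## network, rank correlation of confidences, regulatory correlation, and
## degree summaries.

# Off-diagonal logical selector for a square matrix.
.offDiag <- function(M) row(M) != col(M)

# Area under the precision-recall curve, step-wise: scores are grouped into
# distinct-threshold steps (ties form a single step) and the area is the sum
# of precision x recall-increment over steps. No interpolation.
.auprc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  P <- sum(labels)
  if (P == 0) .stopf("no positive pairs in the truth")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(y); n <- seq_along(y)
  last <- !duplicated(grp, fromLast = TRUE)   # end of each tie block
  tp <- tp[last]; n <- n[last]
  prec <- tp / n
  rec <- tp / P
  sum(prec * diff(c(0, rec)))
}

#' AUPRC ratio of a scored prediction against a truth network
#'
#' The area under the precision-recall curve of the confidence scores versus
#' the true edge labels, divided by the AUPRC of a random predictor (the
#' positive prevalence), over off-diagonal pairs only (self-regulation is
#' never scored). A ratio of 1 is chance level.
#'
#' @param scores G x G confidence matrix, target x regulator (higher = more
#'   confident); the diagonal is ignored.
#' @param truth a [TruthNetwork-class] (or logical/0-1 matrix of edges).
#' @return The AUPRC ratio (>= 0).
#' @export
auprcRatio <- function(scores, truth) {
  lab <- if (is(truth, "TruthNetwork")) truthEdges(truth) else truth > 0
  off <- .offDiag(lab)
  y <- lab[off]
  if (!any(y)) .stopf("truth network has no edges")
  if (all(y)) .stopf("truth network has no non-edges")
  prev <- mean(y)
  .auprc(scores[off], y) / prev
}

#' Signed AUPRC ratio
#'
#' Evaluates recovery of positively (or negatively) signed regulation:
#' for \code{sign = "+"} the positives are the positive true edges,
#' confidences below zero are floored at 0, and the AUPRC ratio is computed
#' as in [auprcRatio()]; symmetric for \code{sign = "-"} (confidences
#' negated, negative true edges as positives).
#'
#' @param scores_signed G x G signed coefficient matrix.
#' @param truth a [TruthNetwork-class] carrying signed scores.
#' @param sign \code{"+"} or \code{"-"}.
#' @return The signed AUPRC ratio.
#' @export
signedAuprcRatio <- function(scores_signed, truth, sign = c("+", "-")) {
  sign <- match.arg(sign)
  if (!truth@signed) .stopf("truth network does not carry signs")
  edges <- truthEdges(truth)
  ts <- truthScores(truth)
  lab <- if (sign == "+") edges & ts > 0 else edges & ts < 0
  conf <- if (sign == "+") pmax(scores_signed, 0) else pmax(-scores_signed, 0)
  off <- .offDiag(lab)
  y <- lab[off]
  if (!any(y)) .stopf("no %s-signed true edges", sign)
  .auprc(conf[off], y) / mean(y)
}

#' Take the top-n edges of an edge table
#'
#' Ordered by descending absolute coefficient with the deterministic
#' lexicographic tie-break of [writeEdgeTable()].
#'
#' @param edges an edge table.
#' @param n number of edges to keep.
#' @export
topEdges <- function(edges, n) {
  utils::head(sortEdgeTable(edges), n)
}

#' Classify predicted edges by path length in the truth network
#'
#' An inferred regulation j -> i is \code{direct} when the shortest directed
#' path from j to i in the truth network has length 1, \code{indirect} when
#' it is longer, and \code{no_path} when i is unreachable from j. Typically
#' applied to the top-n predictions where n is the number of true edges.
#'
#' @param pred_top an edge table prefix (e.g. from [topEdges()]).
#' @param truth a [TruthNetwork-class].
#' @return \code{pred_top} with an added \code{class} column.
#' @export
classifyEdges <- function(pred_top, truth) {
  edges <- truthEdges(truth)
  genes <- rownames(edges)
  gr <- igraph::graph_from_adjacency_matrix(t(edges), mode = "directed")
  # t(): igraph adjacency [from, to]; ours is [target, regulator]
  D <- igraph::distances(gr, mode = "out")
  lab <- character(nrow(pred_top))
  for (r in seq_len(nrow(pred_top))) {
    from <- match(pred_top$regulator[r], genes)
    to <- match(pred_top$target[r], genes)
    if (is.na(from) || is.na(to)) { lab[r] <- "no_path"; next }
    d <- D[from, to]
    lab[r] <- if (!is.finite(d)) "no_path" else if (d == 1) "direct"
              else "indirect"
  }
  pred_top$class <- lab
  pred_top
}

#' Spearman correlation between prediction confidences and external scores
#'
#' Computed over the off-diagonal pairs shared between the two tables
#' (intersecting regulator and target sets), with average ranks for ties.
#' For bootstrap-tested networks the natural confidence is
#' \code{-log10(q_value)}.
#'
#' @param pred matrix of prediction confidences (target x regulator).
#' @param truth_scores matrix of external scores (target x regulator).
#' @return Spearman's rank correlation coefficient.
#' @export
confidenceRankCorrelation <- function(pred, truth_scores) {
  tg <- intersect(rownames(pred), rownames(truth_scores))
  rg <- intersect(colnames(pred), colnames(truth_scores))
  p <- pred[tg, rg, drop = FALSE]
  s <- truth_scores[tg, rg, drop = FALSE]
  off <- outer(tg, rg, FUN = "!=")
  ok <- off & is.finite(p) & is.finite(s)
  if (sum(ok) < 3) .stopf("fewer than 3 shared off-diagonal pairs")
  stats::cor(p[ok], s[ok], method = "spearman")
}

#' Regulatory correlation between outgoing profiles
#'
#' Entry (i, j) is the Spearman correlation between columns i and j of the
#' coefficient matrix — the two genes' outgoing regulatory profiles. Values
#' near 1 mean the genes regulate the same targets in the same direction
#' (a signature of, e.g., protein-complex partners); near -1, in opposite
#' directions. Constant columns yield \code{NA}.
#'
#' @param A G x G coefficient matrix (G >= 3).
#' @return Symmetric G x G matrix of rank correlations.
#' @export
regulatoryCorrelation <- function(A) {
  if (nrow(A) < 3) .stopf("at least 3 genes are required")
  suppressWarnings(stats::cor(A, method = "spearman"))
}

#' Out-degree summary of a significant network
#'
#' Filters edges at \code{q_value < fdr} and summarizes each regulator's
#' out-degree, either as counts split by coefficient sign or as the summed
#' absolute coefficient.
#'
#' @param edges an edge table with q-values.
#' @param fdr FDR threshold.
#' @param weight \code{"count"} or \code{"abs_sum"}.
#' @param genes optional gene universe to report (zero rows included).
#' @return A data.frame, one row per gene: \code{n_pos}, \code{n_neg} for
#'   counts, or \code{weighted_outdegree}.
#' @export
degreeSummary <- function(edges, fdr = 0.01, weight = c("count", "abs_sum"),
                          genes = NULL) {
  weight <- match.arg(weight)
  if (is.null(genes)) genes <- sort(unique(c(edges$regulator, edges$target)))
  sig <- edges[!is.na(edges$q_value) & edges$q_value < fdr, , drop = FALSE]
  if (weight == "count") {
    out <- data.frame(
      gene = genes,
      n_pos = vapply(genes, function(g)
        sum(sig$regulator == g & sig$coefficient > 0), integer(1)),
      n_neg = vapply(genes, function(g)
        sum(sig$regulator == g & sig$coefficient < 0), integer(1)),
      row.names = NULL)
  } else {
    out <- data.frame(
      gene = genes,
      weighted_outdegree = vapply(genes, function(g)
        sum(abs(sig$coefficient[sig$regulator == g])), numeric(1)),
      row.names = NULL)
  }
  out
}

#' Threshold an external score table into a truth network
#'
#' An edge is present when its score strictly exceeds the cutoff; raising
#' the cutoff yields nested (subset) networks.
#'
#' @param scores matrix of scores, target x regulator.
#' @param cutoff score threshold.
#' @return A [TruthNetwork-class].
#' @export
thresholdTruth <- function(scores, cutoff) {
  TruthNetwork(scores, threshold = cutoff, signed = FALSE)
}
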