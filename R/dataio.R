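## Reading expression matrices / metadata and writing results.

#' Read a normalized expression matrix
#'
#' Accepts either a dense delimited matrix (cells x genes; header row of gene
#' names, first column of cell identifiers; comma or tab auto-detected) or a
#' Matrix Market triplet file accompanied by gene and cell index files (one
#' identifier per line, or a delimited table whose first column is used).
#' For Matrix Market input the orientation is resolved against the index
#' files: genes x cells (the 10x convention) or cells x genes both work.
#'
#' Expression is expected to be already normalized (e.g. variance-stabilized);
#' a heuristic warns when the matrix looks like raw counts.
#'
#' @param matrix_path path to the matrix file (\code{.mtx} triggers Matrix
#'   Market parsing).
#' @param genes_path,cells_path index files; required for Matrix Market input.
#' @return A list with elements \code{expr} (genes x cells matrix),
#'   \code{genes}, \code{cells}, to be completed by [readMetadata()].
#' @seealso [readMetadata()]
#' @export
readExpression <- function(matrix_path, genes_path = NULL, cells_path = NULL) {
  if (grepl("\\.mtx$", matrix_path, ignore.case = TRUE)) {
    if (is.null(genes_path) || is.null(cells_path))
      .stopf("Matrix Market input requires genes_path and cells_path")
    m <- as.matrix(Matrix::readMM(matrix_path))
    genes <- .readIndexFile(genes_path)
    cells <- .readIndexFile(cells_path)
    if (nrow(m) == length(genes) && ncol(m) == length(cells)) {
      # genes x cells, keep
    } else if (nrow(m) == length(cells) && ncol(m) == length(genes)) {
      m <- t(m)
    } else {
      axis <- if (length(genes) %in% dim(m)) "cells" else "genes"
      .stopf("%s axis mismatch: matrix is %d x %d but %d genes / %d cells given",
             axis, nrow(m), ncol(m), length(genes), length(cells))
    }
    dimnames(m) <- list(genes, cells)
  } else {
    sep <- .detectSep(matrix_path)
    tab <- utils::read.table(matrix_path, header = TRUE, sep = sep,
                             check.names = FALSE, stringsAsFactors = FALSE)
    if (ncol(tab) > 1 && !is.numeric(tab[[1]])) {
      cells <- as.character(tab[[1]])
      tab <- tab[, -1, drop = FALSE]
    } else {
      cells <- rownames(tab)
    }
    m <- t(as.matrix(tab))   # file is cells x genes; store genes x cells
    colnames(m) <- cells
    genes <- rownames(m)
    if (!is.null(genes_path)) {
      g <- .readIndexFile(genes_path)
      if (length(g) != nrow(m))
        .stopf("gene axis mismatch: %d names but matrix has %d gene columns",
               length(g), nrow(m))
      genes <- rownames(m) <- g
    }
  }
  storage.mode(m) <- "double"
  if (all(m >= 0) && all(m == round(m)) && max(m) > 30)
    .warnf("expression matrix looks like raw counts; renge expects normalized expression")
  list(expr = m, genes = rownames(m), cells = colnames(m))
}

.readIndexFile <- function(path) {
  x <- readLines(path)
  x <- x[nzchar(trimws(x))]
  vapply(strsplit(x, "[\t,]"), `[[`, character(1), 1L)
}

#' Attach per-cell metadata to an expression matrix
#'
#' The metadata table must contain columns \code{cell_id}, \code{time} and
#' \code{ko_gene}, and may contain \code{perturb_prob}. KO labels equal
#' (case-insensitively) to \code{"control"} or \code{"ctrl"} mark control
#' cells. Time labels are rank-remapped to contiguous integers \code{1..T};
#' the mapping is kept in \code{metadata(x)$time_map}.
#'
#' @param meta_path path to a delimited metadata table.
#' @param dataset the partial dataset returned by [readExpression()].
#' @return A [RengeExperiment-class].
#' @export
readMetadata <- function(meta_path, dataset) {
  sep <- .detectSep(meta_path)
  meta <- utils::read.table(meta_path, header = TRUE, sep = sep,
                            check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("cell_id", "time", "ko_gene")
  miss <- setdiff(need, colnames(meta))
  if (length(miss))
    .stopf("metadata is missing column(s): %s", paste(miss, collapse = ", "))
  meta$cell_id <- as.character(meta$cell_id)
  idx <- match(dataset$cells, meta$cell_id)
  if (anyNA(idx))
    .stopf("cells present in expression but absent from metadata: %s",
           paste(utils::head(dataset$cells[is.na(idx)], 5), collapse = ", "))
  meta <- meta[idx, , drop = FALSE]
  ko <- .normalizeKoLabels(meta$ko_gene)
  unknown <- setdiff(unique(ko[ko != CONTROL]), dataset$genes)
  if (length(unknown))
    .stopf("ko_gene label(s) not among gene names: %s",
           paste(unknown, collapse = ", "))
  pp <- if ("perturb_prob" %in% colnames(meta))
    as.numeric(meta$perturb_prob) else rep(1, nrow(meta))
  pp[is.na(pp)] <- 1
  RengeExperiment(t(dataset$expr), time = meta$time, ko_gene = ko,
                  perturb_prob = pp, cell_ids = dataset$cells,
                  gene_names = dataset$genes)
}

#' Read expression and metadata in one step
#'
#' @inheritParams readExpression
#' @inheritParams readMetadata
#' @return A [RengeExperiment-class].
#' @export
readRengeExperiment <- function(matrix_path, meta_path,
                                genes_path = NULL, cells_path = NULL) {
  readMetadata(meta_path, readExpression(matrix_path, genes_path, cells_path))
}

## ---------------------------------------------------------------------------
## Edge tables
## ---------------------------------------------------------------------------

#' Flatten a network matrix into an edge table
#'
#' Produces one record per off-diagonal entry (self-regulation is never
#' exported), sorted by descending absolute coefficient with lexicographic
#' (regulator, target) tie-break.
#'
#' @param A G x G coefficient matrix, entry \code{[i, j]} = regulation of
#'   target \code{i} by regulator \code{j}.
#' @param p,q optional matrices of p- and q-values in the same orientation.
#' @param drop_zero drop records with zero coefficient and no p-value.
#' @return A \code{data.frame} with columns \code{regulator}, \code{target},
#'   \code{coefficient}, \code{p_value}, \code{q_value}.
#' @export
edgeTable <- function(A, p = NULL, q = NULL, drop_zero = FALSE) {
  genes <- rownames(A)
  if (is.null(genes)) genes <- paste0("g", seq_len(nrow(A)))
  off <- which(row(A) != col(A), arr.ind = TRUE)
  ed <- data.frame(
    regulator = genes[off[, "col"]],
    target = genes[off[, "row"]],
    coefficient = A[off],
    p_value = if (is.null(p)) NA_real_ else p[off],
    q_value = if (is.null(q)) NA_real_ else q[off],
    stringsAsFactors = FALSE)
  if (drop_zero)
    ed <- ed[ed$coefficient != 0 | !is.na(ed$p_value), , drop = FALSE]
  sortEdgeTable(ed)
}

#' @rdname edgeTable
#' @param edges an edge table.
#' @export
sortEdgeTable <- function(edges) {
  o <- order(-abs(edges$coefficient), edges$regulator, edges$target)
  ed <- edges[o, , drop = FALSE]
  rownames(ed) <- NULL
  ed
}

#' Write / read an edge table
#'
#' Tab-delimited with header \code{regulator/target/coefficient/p_value/
#' q_value}; rows ordered by descending absolute coefficient, ties broken
#' lexicographically by regulator then target.
#'
#' @param edges edge table as returned by [edgeTable()].
#' @param out_path,path file path.
#' @export
writeEdgeTable <- function(edges, out_path) {
  cols <- c("regulator", "target", "coefficient", "p_value", "q_value")
  for (cc in setdiff(cols, colnames(edges))) edges[[cc]] <- NA_real_
  edges <- sortEdgeTable(edges[, cols, drop = FALSE])
  utils::write.table(edges, out_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(out_path)
}

#' @rdname writeEdgeTable
#' @export
readEdgeTable <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE,
                    colClasses = c("character", "character", "numeric",
                                   "numeric", "numeric"))
}

## ---------------------------------------------------------------------------
## Model serialization (JSON)
## ---------------------------------------------------------------------------

#' Write / read a fitted model as JSON
#'
#' All parameters (A, per-time baselines, weight parameters, hyperparameters)
#' round-trip exactly through full-precision JSON.
#'
#' @param model a [GRNModel-class].
#' @param path file path.
#' @export
writeModel <- function(model, path) {
  obj <- list(
    genes = geneNames(model),
    A = unname(model@A),
    b = unname(model@b),
    time_labels = model@time_labels,
    alpha = as.list(model@alpha),
    beta = model@beta_w,
    gamma = model@gamma_w,
    K = model@K,
    lambda1 = model@lambda1,
    lambda2 = model@lambda2,
    converged = model@converged,
    value = model@value,
    niter = model@niter)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeModel
#' @export
readModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  genes <- obj$genes
  A <- matrix(unlist(obj$A), nrow = length(genes), byrow = TRUE,
              dimnames = list(genes, genes))
  if (is.matrix(obj$A)) A <- structure(obj$A, dimnames = list(genes, genes))
  b <- if (is.matrix(obj$b)) obj$b else
    matrix(unlist(obj$b), nrow = length(genes), byrow = TRUE)
  rownames(b) <- genes
  alpha <- unlist(obj$alpha)
  if (is.null(alpha)) alpha <- numeric(0)
  GRNModel(A = A, b = b, alpha = alpha, beta_w = obj$beta,
           gamma_w = obj$gamma, K = obj$K, lambda1 = obj$lambda1,
           lambda2 = obj$lambda2, converged = obj$converged,
           value = obj$value, niter = obj$niter,
           time_labels = as.character(obj$time_labels))
}

#' Write a RengeExperiment to delimited files
#'
#' Writes \code{expr.tsv} (cells x genes, first column \code{cell_id}) and
#' \code{meta.tsv} (\code{cell_id}, \code{time}, \code{ko_gene},
#' \code{perturb_prob}) into a directory.
#'
#' @param x a [RengeExperiment-class].
#' @param dir output directory (created if needed).
#' @export
writeRengeExperiment <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ex <- data.frame(cell_id = cellIds(x), t(exprMatrix(x)),
                   check.names = FALSE)
  utils::write.table(ex, file.path(dir, "expr.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  meta <- data.frame(cell_id = cellIds(x), time = timeLabel(x),
                     ko_gene = koGene(x), perturb_prob = perturbProb(x))
  utils::write.table(meta, file.path(dir, "meta.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
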