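# The four pairwise dissimilarity matrices the inference runs on: genetic
# (fractional allelic differences), Bray-Curtis, weighted UniFrac and body
# size (absolute standard-length difference).

#' Construct a labeled distance matrix
#'
#' A square, symmetric, zero-diagonal matrix of pairwise dissimilarities with
#' sample ids on both dimensions; the lingua franca of all inference in this
#' package.
#'
#' @param values square numeric matrix with identical row/col names.
#' @param metric metric label (`"genetic"`, `"braycurtis"`, `"wunifrac"`,
#'   `"size_L1"`, ...).
#' @param meta optional provenance list (marker subset, normalization mode).
#' @return an object of class `dist_matrix`.
#' @export
dist_matrix <- function(values, metric = "unknown", meta = list()) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop_gs("distance matrix must be square")
  if (is.null(rownames(values))) stop_gs("distance matrix needs sample ids")
  if (!identical(rownames(values), colnames(values)))
    stop_gs("row and column ids differ")
  if (max(abs(values - t(values))) > 1e-12)
    stop_gs("distance matrix is not symmetric")
  if (max(abs(diag(values))) > 1e-12) stop_gs("nonzero diagonal")
  if (any(values < -1e-12)) stop_gs("negative dissimilarities")
  values <- (values + t(values)) / 2
  diag(values) <- 0
  structure(values, metric = metric, meta = meta,
            class = c("dist_matrix", "matrix"))
}

#' @export
print.dist_matrix <- function(x, ...) {
  cat(sprintf("dist_matrix (%s): %d samples\n", attr(x, "metric"), nrow(x)))
  invisible(x)
}

# Subset a dist_matrix to (ordered) ids.
dist_subset <- function(d, ids) {
  dist_matrix(unclass(d)[ids, ids, drop = FALSE],
              metric = attr(d, "metric"), meta = attr(d, "meta"))
}

#' Genetic dissimilarity as the fraction of allelic differences
#'
#' For individuals i and j, `d(i,j) = sum_m |g_im - g_jm| / (2 * n_m(i,j))`
#' where the sum runs over markers non-missing in both individuals
#' (pairwise deletion) and `n_m(i,j)` counts those markers. Values lie in
#' \[0, 1\]: 0 for identical genotypes, 1 when every compared allele differs.
#'
#' @param G a [genotype_matrix()].
#' @param markers optional character vector of marker ids (e.g. one window);
#'   default all markers.
#' @return a `dist_matrix` with metric `"genetic"`.
#' @export
genetic_dissimilarity <- function(G, markers = NULL) {
  stopifnot(inherits(G, "genotype_matrix"))
  X <- G$dosages
  if (!is.null(markers)) {
    miss <- setdiff(markers, colnames(X))
    if (length(miss)) stop_gs("unknown marker(s): %s",
                              paste(miss, collapse = ", "))
    X <- X[, markers, drop = FALSE]
  }
  if (nrow(X) < 2L) stop_gs("need at least 2 samples")
  # decompose |a-b| over dosage classes: pairs (0,1),(1,2) differ by 1 allele,
  # (0,2) by 2; NA contributes to neither numerator nor denominator.
  I0 <- (!is.na(X) & X == 0L) + 0
  I1 <- (!is.na(X) & X == 1L) + 0
  I2 <- (!is.na(X) & X == 2L) + 0
  M <- I0 + I1 + I2
  num <- tcrossprod(I0, I1) + tcrossprod(I1, I0) +
    tcrossprod(I1, I2) + tcrossprod(I2, I1) +
    2 * (tcrossprod(I0, I2) + tcrossprod(I2, I0))
  shared <- tcrossprod(M)
  off <- shared == 0 & upper.tri(shared)
  if (any(off)) {
    idx <- which(off, arr.ind = TRUE)[1L, ]
    stop_gs("no shared non-missing markers for pair (%s, %s)",
            rownames(X)[idx[1L]], rownames(X)[idx[2L]])
  }
  d <- num / (2 * shared)
  diag(d) <- 0
  dist_matrix(d, metric = "genetic",
              meta = list(markers = if (is.null(markers)) "all" else markers))
}

#' Bray-Curtis dissimilarity
#'
#' `d(i,j) = sum_k |x_ik - x_jk| / sum_k (x_ik + x_jk)`; requires
#' non-negative abundances. Note log-CPM values can go negative for very deep
#' libraries, in which case this errors rather than returning a value outside
#' \[0, 1\].
#'
#' @param X a `normalized_matrix`, [community_matrix()] or plain non-negative
#'   matrix (samples x ASVs).
#' @return a `dist_matrix` with metric `"braycurtis"`.
#' @export
bray_curtis <- function(X) {
  mode <- if (inherits(X, "normalized_matrix")) attr(X, "norm_mode") else "raw"
  if (inherits(X, "community_matrix")) X <- X$counts
  X <- unclass(as.matrix(X))
  if (any(X < 0))
    stop_gs(paste("Bray-Curtis requires non-negative abundances;",
                  "input has negative values (log-CPM can be negative for",
                  "very deep libraries -- use counts or relative abundances,",
                  "or shift the normalization)"))
  man <- as.matrix(stats::dist(X, method = "manhattan"))
  s <- rowSums(X)
  denom <- outer(s, s, "+")
  zero <- denom == 0 & upper.tri(denom)
  if (any(zero)) {
    idx <- which(zero, arr.ind = TRUE)[1L, ]
    stop_gs("pair (%s, %s) has zero total abundance",
            rownames(X)[idx[1L]], rownames(X)[idx[2L]])
  }
  d <- man / denom
  diag(d) <- 0
  dist_matrix(d, metric = "braycurtis", meta = list(input = mode))
}

#' Weighted UniFrac dissimilarity
#'
#' Abundances are converted to per-sample proportions; for each branch `b` of
#' the rooted tree with length `l_b`, let `P_ib` be the proportion of sample
#' i's abundance on tips descending from `b`. Raw weighted UniFrac is
#' `sum_b l_b |P_ib - P_jb|`; the normalized variant divides by
#' `sum_t d_t (P_it + P_jt)` with `d_t` the root-to-tip distance, bounding
#' the result by 1.
#'
#' @param X a `normalized_matrix`, [community_matrix()] or plain non-negative
#'   matrix (samples x ASVs); columns must match tree tips.
#' @param tree rooted `phylo` with branch lengths; tips not present in `X`
#'   are pruned with a warning, ASVs missing from the tree are an error.
#' @param normalized divide by the abundance-weighted root-to-tip sum
#'   (default `TRUE`).
#' @return a `dist_matrix` with metric `"wunifrac"`.
#' @export
weighted_unifrac <- function(X, tree, normalized = TRUE) {
  mode <- if (inherits(X, "normalized_matrix")) attr(X, "norm_mode") else "raw"
  if (inherits(X, "community_matrix")) X <- X$counts
  X <- unclass(as.matrix(X))
  if (any(X < 0)) stop_gs("weighted UniFrac requires non-negative abundances")
  missing_tips <- setdiff(colnames(X), tree$tip.label)
  if (length(missing_tips))
    stop_gs("ASV(s) absent from tree: %s", paste(missing_tips, collapse = ", "))
  extra <- setdiff(tree$tip.label, colnames(X))
  if (length(extra)) {
    warn_gs("pruning %d tree tip(s) absent from the table", length(extra))
    tree <- ape::drop.tip(tree, extra)
  }
  P <- X / rowSums(X)
  P <- P[, tree$tip.label, drop = FALSE]

  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  # single post-order pass accumulating descendant tip mass per node
  M <- matrix(0, nrow(P), nnode)
  M[, seq_len(ntip)] <- P
  edge <- tree$edge[ape::postorder(tree), , drop = FALSE]
  for (e in seq_len(nrow(edge)))
    M[, edge[e, 1L]] <- M[, edge[e, 1L]] + M[, edge[e, 2L]]
  # branch b <-> edge leading to its child node; root edge excluded
  B <- M[, tree$edge[, 2L], drop = FALSE]
  Bw <- sweep(B, 2L, tree$edge.length, "*")
  raw <- as.matrix(stats::dist(Bw, method = "manhattan"))
  if (normalized) {
    depth <- ape::node.depth.edgelength(tree)[seq_len(ntip)]
    q <- as.vector(P %*% depth)
    denom <- outer(q, q, "+")
    denom[denom == 0] <- 1  # two all-zero-depth samples: distance already 0
    d <- raw / denom
  } else {
    d <- raw
  }
  rownames(d) <- colnames(d) <- rownames(X)
  diag(d) <- 0
  dist_matrix(d, metric = "wunifrac",
              meta = list(input = mode, normalized = normalized))
}

#' Body-size dissimilarity
#'
#' Absolute difference in standard length (mm) between two fish.
#'
#' @param meta a `sample_table` with `standard_length_mm` for every sample.
#' @return a `dist_matrix` with metric `"size_L1"`.
#' @export
size_dissimilarity <- function(meta) {
  sl <- meta$standard_length_mm
  if (is.null(sl) || anyNA(sl)) stop_gs("standard_length_mm missing")
  d <- abs(outer(sl, sl, "-"))
  rownames(d) <- colnames(d) <- meta$sample_id
  dist_matrix(d, metric = "size_L1")
}
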