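# Distance-matrix multivariate statistics implemented from first principles:
# principal coordinates analysis, PERMANOVA with sequential sums of squares,
# a beta-dispersion (distance-to-centroid) permutation test, and the
# Benjamini-Hochberg step-up FDR adjustment.

#' Principal coordinates analysis (classical scaling)
#'
#' Double-centers `-D^2/2` and eigendecomposes. Coordinates are eigenvectors
#' scaled by the square root of their (positive) eigenvalues; negative
#' eigenvalues — which arise for semi-metric dissimilarities such as
#' Bray-Curtis — are retained in the report but receive no correction.
#' The proportion of variation per axis is its eigenvalue over the sum of
#' positive eigenvalues.
#'
#' @param D a `dist_matrix`.
#' @param k number of axes to return (default 2); truncated with a warning
#'   if it exceeds the number of positive eigenvalues.
#' @return an object of class `pcoa_ordination`: list with `coordinates`
#'   (n x k), `eigenvalues` (all, descending) and `proportion` (per
#'   returned axis).
#' @export
pcoa <- function(D, k = 2L) {
  stopifnot(inherits(D, "dist_matrix"))
  n <- nrow(D)
  if (n < 3L) stop_gs("need at least 3 samples")
  G <- gower_center(unclass(D))
  e <- eigen(G, symmetric = TRUE)
  lambda <- e$values
  tol <- max(abs(lambda)) * 1e-9
  npos <- sum(lambda > tol)
  if (k > npos) {
    warn_gs("k = %d exceeds the %d positive eigenvalue(s); truncating", k,
            npos)
    k <- npos
  }
  coords <- e$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(lambda[seq_len(k)]), k)
  rownames(coords) <- rownames(D)
  colnames(coords) <- paste0("PCo", seq_len(k))
  structure(list(coordinates = coords,
                 eigenvalues = lambda,
                 proportion = lambda[seq_len(k)] / sum(lambda[lambda > tol])),
            class = "pcoa_ordination")
}

#' @export
print.pcoa_ordination <- function(x, ...) {
  cat(sprintf("PCoA: %d axes returned; variation explained: %s\n",
              ncol(x$coordinates),
              paste(sprintf("%.2f%%", 100 * x$proportion), collapse = ", ")))
  invisible(x)
}

# Gower-centered inner-product matrix of a distance matrix.
gower_center <- function(D) {
  A <- -0.5 * D^2
  n <- nrow(A)
  J <- diag(n) - matrix(1 / n, n, n)
  J %*% A %*% J
}

#' PERMANOVA: permutational multivariate analysis of variance
#'
#' Partitions the total sum of squares of a distance matrix among ordered
#' model terms (sequential decomposition, so term order matters) using
#' projection matrices of nested model matrices on the Gower-centered
#' inner-product matrix. The pseudo-F for each term is
#' `(SS_term/df_term) / (SS_resid/df_resid)`; p-values come from free
#' permutation of sample labels, recomputing every term,
#' `(1 + #\{F_perm >= F\}) / (n_perm + 1)`.
#'
#' Factors, continuous covariates (single-df terms) and interactions are all
#' supported through a model formula, e.g.
#' `~ population * standard_length_mm + tank * population`.
#'
#' @param D a `dist_matrix`.
#' @param meta a `sample_table` (matched to `D` by `sample_id`).
#' @param formula right-hand-side model formula over columns of `meta`.
#' @param n_perm number of permutations (default 999).
#' @param seed master seed.
#' @return a data frame (class `permanova_table`) with one row per term plus
#'   `Residual` and `Total` rows: `Df`, `SumOfSqs`, `R2`, `F`, `p_value`.
#' @export
permanova <- function(D, meta, formula, n_perm = 999L, seed = 1L) {
  stopifnot(inherits(D, "dist_matrix"))
  ids <- align_ids(rownames(D), meta$sample_id)
  D <- dist_subset(D, ids)
  meta <- meta[match(ids, meta$sample_id), , drop = FALSE]
  n <- nrow(D)
  trm <- terms(formula)
  labels <- attr(trm, "term.labels")
  if (!length(labels)) labels <- character()
  G <- gower_center(unclass(D))
  ss_total <- sum(diag(G))

  # nested model matrices and their hat matrices
  hats <- list(matrix(1 / n, n, n))  # intercept-only projection
  ranks <- 1L
  for (kk in seq_along(labels)) {
    X <- model.matrix(stats::reformulate(labels[seq_len(kk)]),
                      data = as.data.frame(meta))
    qrX <- qr(X)
    if (qrX$rank <= ranks[kk])
      stop_gs("term '%s' is aliased (adds no model degrees of freedom)",
              labels[kk])
    Q <- qr.Q(qrX)[, seq_len(qrX$rank), drop = FALSE]
    hats[[kk + 1L]] <- tcrossprod(Q)
    ranks <- c(ranks, qrX$rank)
  }
  dfs <- diff(ranks)
  df_res <- n - ranks[length(ranks)]
  if (df_res <= 0) stop_gs("no residual degrees of freedom")

  ss_fun <- function(Gp) {
    tr <- vapply(hats, function(H) sum(H * Gp), 1)
    ss_terms <- diff(tr)
    ss_res <- sum(diag(Gp)) - tr[length(tr)]
    f <- (ss_terms / dfs) / (ss_res / df_res)
    list(ss = ss_terms, ss_res = ss_res, f = f)
  }
  obs <- ss_fun(G)

  p <- rep(NA_real_, length(labels))
  if (length(labels) && n_perm > 0) {
    perms <- perm_matrix(n, n_perm, derive_seed(seed, 0L))
    count <- numeric(length(labels))
    for (i in seq_len(n_perm)) {
      pr <- perms[i, ]
      fp <- ss_fun(G[pr, pr])$f
      count <- count + (fp >= obs$f - 1e-12)
    }
    p <- (1 + count) / (n_perm + 1)
  }

  out <- data.frame(
    term = c(labels, "Residual", "Total"),
    Df = c(dfs, df_res, n - 1L),
    SumOfSqs = c(obs$ss, obs$ss_res, ss_total),
    R2 = c(obs$ss, obs$ss_res, ss_total) / ss_total,
    F = c(obs$f, NA, NA),
    p_value = c(p, NA, NA))
  structure(out, n_perm = n_perm, seed = seed,
            class = c("permanova_table", "data.frame"))
}

#' Beta-dispersion (multivariate homogeneity of group dispersions)
#'
#' Embeds the samples by PCoA on all axes, computes each sample's distance
#' to its group centroid — combining positive- and negative-eigenvalue axes
#' as `sqrt(max(0, d+^2 - d-^2))` — and tests equality of mean dispersion
#' across groups with a one-way ANOVA F whose null distribution is obtained
#' by permuting group labels.
#'
#' @param D a `dist_matrix`.
#' @param groups factor (or vector) of group labels, aligned with `D`'s
#'   samples, or the name of a column of `meta`.
#' @param meta optional `sample_table` used to look up `groups` by name.
#' @param n_perm permutations (default 999).
#' @param seed master seed.
#' @return an object of class `dispersion_result`: per-group mean distance
#'   to centroid, `F`, degrees of freedom, permutation `p_value` and the
#'   per-sample `distances`.
#' @export
beta_dispersion <- function(D, groups, meta = NULL, n_perm = 999L, seed = 1L) {
  stopifnot(inherits(D, "dist_matrix"))
  if (is.character(groups) && length(groups) == 1L && !is.null(meta)) {
    ids <- align_ids(rownames(D), meta$sample_id)
    D <- dist_subset(D, ids)
    groups <- meta[[groups]][match(ids, meta$sample_id)]
  }
  g <- factor(groups)
  n <- nrow(D)
  if (length(g) != n) stop_gs("groups must match the distance matrix samples")
  if (nlevels(g) < 2L) stop_gs("need at least 2 groups")
  if (any(table(g) < 2L))
    stop_gs("singleton group(s): %s",
            paste(levels(g)[table(g) < 2L], collapse = ", "))

  G <- gower_center(unclass(D))
  e <- eigen(G, symmetric = TRUE)
  tol <- max(abs(e$values)) * 1e-9
  pos <- e$values > tol
  neg <- e$values < -tol
  Cp <- e$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(e$values[pos]), sum(pos))
  Cn <- e$vectors[, neg, drop = FALSE] %*%
    diag(sqrt(-e$values[neg]), sum(neg))
  z <- numeric(n)
  for (lev in levels(g)) {
    m <- g == lev
    cp <- colMeans(Cp[m, , drop = FALSE])
    d2p <- rowSums(sweep(Cp[m, , drop = FALSE], 2L, cp)^2)
    d2n <- if (ncol(Cn)) {
      cn <- colMeans(Cn[m, , drop = FALSE])
      rowSums(sweep(Cn[m, , drop = FALSE], 2L, cn)^2)
    } else 0
    z[m] <- sqrt(pmax(0, d2p - d2n))
  }
  if (all(z < 1e-12)) stop_gs("zero variance: all dispersions are 0")

  f_stat <- function(zv, gv) {
    grand <- mean(zv)
    gm <- tapply(zv, gv, mean)
    ng <- tabulate(gv)
    ssb <- sum(ng * (gm - grand)^2)
    ssw <- sum((zv - gm[gv])^2)
    dfb <- nlevels(gv) - 1L
    dfw <- length(zv) - nlevels(gv)
    (ssb / dfb) / (ssw / dfw)
  }
  F_obs <- f_stat(z, g)
  perms <- perm_matrix(n, n_perm, derive_seed(seed, 0L))
  F_perm <- vapply(seq_len(n_perm), function(i) f_stat(z[perms[i, ]], g), 1)
  p <- perm_pvalue(F_perm, F_obs, n_perm)

  structure(list(group_means = tapply(z, g, mean), distances = setNames(z,
                 rownames(D)), F = F_obs,
                 df = c(nlevels(g) - 1L, n - nlevels(g)), p_value = p,
                 n_permutations = n_perm, seed = seed),
            class = "dispersion_result")
}

#' @export
print.dispersion_result <- function(x, ...) {
  cat(sprintf("Beta-dispersion: F(%d,%d) = %.3f, p = %.4g\n",
              x$df[1L], x$df[2L], x$F, x$p_value))
  print(round(x$group_means, 4))
  invisible(x)
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' `q_(i) = min_(j >= i) m p_(j) / j`, capped at 1, returned in input order.
#' Missing values pass through as missing (the adjustment is computed on the
#' observed p-values only).
#'
#' @param p_values numeric vector of p-values in \[0, 1\] (NA allowed).
#' @return vector of adjusted q-values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  ok <- !is.na(p_values)
  p <- p_values[ok]
  if (any(p < 0 | p > 1)) stop_gs("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(p_values))
  m <- length(p)
  if (m) {
    o <- order(p, decreasing = TRUE)
    q <- pmin(1, cummin(m / seq(m, 1) * p[o]))
    out[ok][o] <- q
  }
  out
}
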