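# Mantel and first-order partial Mantel correlation between distance
# matrices, with one-tailed (upper) permutation inference. Tests are
# directional because the working hypothesis is a positive association
# between genetic and community dissimilarity.

# Align two or more dist_matrix objects on their common (sorted) sample ids.
align_dists <- function(...) {
  ds <- list(...)
  ids <- do.call(align_ids, c(lapply(ds, rownames), list(what = "samples")))
  lapply(ds, dist_subset, ids = ids)
}

# Pearson correlation pieces over the strict upper triangle that are
# invariant under simultaneous row/column permutation of the matrix.
tri_moments <- function(A) {
  n <- nrow(A)
  L <- n * (n - 1) / 2
  s <- sum(A) / 2
  s2 <- sum(A^2) / 2
  list(L = L, s = s, s2 = s2, css = L * s2 - s^2)
}

# Correlation of permuted-A triangle with fixed vector v from the cross sum.
r_from_cross <- function(cross, momA, v_sum, v_css) {
  (momA$L * cross - momA$s * v_sum) / sqrt(momA$css * v_css)
}

perm_matrix <- function(n, n_perm, seed) {
  with_seed(seed, {
    m <- matrix(0L, n_perm, n)
    for (i in seq_len(n_perm)) m[i, ] <- sample.int(n)
    m
  })
}

mantel_result <- function(r, p, n_perm, method, control_metric, seed,
                          null_r) {
  structure(list(r = r, p_value = p, n_permutations = n_perm,
                 method = method, control_metric = control_metric,
                 seed = seed, null_r = null_r),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("%s Mantel test%s: r = %.4f, p = %.4g (%d permutations)\n",
              if (x$method == "simple") "Simple" else "Partial",
              if (is.null(x$control_metric)) ""
              else sprintf(" (control: %s)", x$control_metric),
              x$r, x$p_value, x$n_permutations))
  invisible(x)
}

perm_pvalue <- function(null_stats, observed, n_perm) {
  eps <- 1e-12 * max(1, abs(observed))
  (1 + sum(null_stats >= observed - eps)) / (n_perm + 1)
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation of the strict upper-triangle vectors, with a
#' one-tailed (upper) permutation p-value obtained by randomly relabeling
#' rows and columns of `A` simultaneously:
#' `p = (1 + #\{r_perm >= r_obs\}) / (n_perm + 1)`, so the smallest
#' achievable p is `1/(n_perm + 1)` (0.001 at the default 999).
#'
#' @param A,B `dist_matrix` objects; aligned on their common sample ids.
#' @param n_perm number of permutations (default 999).
#' @param seed master seed; the permutation stream is derived from
#'   `(seed, stream)` via [derive_seed()].
#' @param stream stream counter for reproducible parallel use (default 0).
#' @return a `mantel_result` with elements `r`, `p_value`,
#'   `n_permutations`, `method`, `seed` and the permutation null `null_r`.
#' @export
mantel_test <- function(A, B, n_perm = 999L, seed = 1L, stream = 0L) {
  al <- align_dists(A, B)
  A <- al[[1L]]; B <- al[[2L]]
  n <- nrow(A)
  if (n < 4L) stop_gs("need at least 4 shared samples (have %d)", n)
  a <- ut(A); b <- ut(B)
  if (var(a) == 0 || var(b) == 0) stop_gs("degenerate distance matrix")
  r_obs <- cor(a, b)
  momA <- tri_moments(unclass(A))
  b_sum <- sum(b); b_css <- momA$L * sum(b^2) - b_sum^2
  perms <- perm_matrix(n, n_perm, derive_seed(seed, stream))
  S <- tri_cross_sums(unclass(A), cbind(b), perms)
  r_perm <- r_from_cross(S[, 1L], momA, b_sum, b_css)
  p <- perm_pvalue(r_perm, r_obs, n_perm)
  mantel_result(r_obs, p, n_perm, "simple", NULL, seed, r_perm)
}

# First-order partial correlation from the three pairwise correlations.
partial_r <- function(r_ab, r_ac, r_bc) {
  (r_ab - r_ac * r_bc) / sqrt((1 - r_ac^2) * (1 - r_bc^2))
}

#' Partial Mantel test controlling for a third distance matrix
#'
#' First-order partial correlation
#' `r_AB.C = (r_AB - r_AC r_BC) / sqrt((1 - r_AC^2)(1 - r_BC^2))` on the
#' upper-triangle vectors; the permutation scheme relabels `A` only and
#' recomputes the partial statistic each time. One-tailed (upper) p as in
#' [mantel_test()].
#'
#' @param A,B,C `dist_matrix` objects (C is the control), aligned on common
#'   sample ids.
#' @inheritParams mantel_test
#' @return a `mantel_result` with `method = "partial"`.
#' @export
partial_mantel <- function(A, B, C, n_perm = 999L, seed = 1L, stream = 0L) {
  al <- align_dists(A, B, C)
  A <- al[[1L]]; B <- al[[2L]]; C <- al[[3L]]
  n <- nrow(A)
  if (n < 5L) stop_gs("need at least 5 shared samples (have %d)", n)
  a <- ut(A); b <- ut(B); cc <- ut(C)
  if (var(a) == 0 || var(b) == 0 || var(cc) == 0)
    stop_gs("degenerate distance matrix")
  r_ab <- cor(a, b); r_ac <- cor(a, cc); r_bc <- cor(b, cc)
  if (abs(r_ac) >= 1 - 1e-12 || abs(r_bc) >= 1 - 1e-12)
    stop_gs("control matrix collinear with input")
  r_obs <- partial_r(r_ab, r_ac, r_bc)
  momA <- tri_moments(unclass(A))
  b_sum <- sum(b); b_css <- momA$L * sum(b^2) - b_sum^2
  c_sum <- sum(cc); c_css <- momA$L * sum(cc^2) - c_sum^2
  perms <- perm_matrix(n, n_perm, derive_seed(seed, stream))
  S <- tri_cross_sums(unclass(A), cbind(b, cc), perms)
  r_ab_p <- r_from_cross(S[, 1L], momA, b_sum, b_css)
  r_ac_p <- r_from_cross(S[, 2L], momA, c_sum, c_css)
  r_perm <- partial_r(r_ab_p, r_ac_p, r_bc)
  p <- perm_pvalue(r_perm, r_obs, n_perm)
  mantel_result(r_obs, p, n_perm, "partial",
                attr(C, "metric") %||% "control", seed, r_perm)
}
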