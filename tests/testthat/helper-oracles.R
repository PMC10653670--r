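# Shared fixture builders and independent oracles used across the suite.
# Oracles are deliberately written by a different route than the package
# implementation (brute-force enumeration, residual regression, classical
# ANOVA) so that agreement is informative.

# Distance matrix from a point configuration (rows = samples).
dist_from_points <- function(X, ids = NULL, metric = "euclidean") {
  if (is.null(ids)) ids <- sprintf("s%02d", seq_len(nrow(X)))
  d <- as.matrix(stats::dist(X))
  dimnames(d) <- list(ids, ids)
  dist_matrix(d, metric = metric)
}

random_dist <- function(n, seed, dim = 3L) {
  set.seed(seed)
  dist_from_points(matrix(rnorm(n * dim), n))
}

# Brute-force Mantel r: Pearson correlation of the off-diagonal vectors,
# assembled element by element.
mantel_oracle <- function(A, B) {
  n <- nrow(A)
  av <- c(); bv <- c()
  for (i in seq_len(n)) for (j in seq_len(n)) if (i < j) {
    av <- c(av, A[i, j]); bv <- c(bv, B[i, j])
  }
  stats::cor(av, bv)
}

# Partial Mantel via the residual-correlation identity: regress the A- and
# B-vectors each on the C-vector by least squares and correlate residuals.
partial_mantel_oracle <- function(A, B, C) {
  av <- A[upper.tri(A)]; bv <- B[upper.tri(B)]; cv <- C[upper.tri(C)]
  ra <- stats::residuals(stats::lm(av ~ cv))
  rb <- stats::residuals(stats::lm(bv ~ cv))
  stats::cor(ra, rb)
}

# Branch-enumeration weighted UniFrac oracle: finds every branch's
# descendant tip set by its own recursion over the edge table (no reuse of
# the package's post-order accumulation), then sums l_b |P_ib - P_jb|.
wunifrac_oracle <- function(P, tree, normalized = TRUE) {
  tips <- tree$tip.label
  P <- P / rowSums(P)
  P <- P[, tips, drop = FALSE]
  descendants <- function(node) {
    if (node <= length(tips)) return(node)
    kids <- tree$edge[tree$edge[, 1L] == node, 2L]
    unlist(lapply(kids, descendants))
  }
  n <- nrow(P)
  d <- matrix(0, n, n, dimnames = list(rownames(P), rownames(P)))
  depth <- ape::node.depth.edgelength(tree)[seq_along(tips)]
  for (i in seq_len(n)) for (j in seq_len(n)) if (i < j) {
    tot <- 0
    for (e in seq_len(nrow(tree$edge))) {
      tipset <- descendants(tree$edge[e, 2L])
      tipset <- tipset[tipset <= length(tips)]
      pi_b <- sum(P[i, tipset]); pj_b <- sum(P[j, tipset])
      tot <- tot + tree$edge.length[e] * abs(pi_b - pj_b)
    }
    if (normalized) {
      den <- sum(depth * (P[i, ] + P[j, ]))
      tot <- if (den > 0) tot / den else 0
    }
    d[i, j] <- d[j, i] <- tot
  }
  d
}

# Classical one-way ANOVA F on a numeric response, via stats::aov.
anova_f_oracle <- function(y, g) {
  fit <- stats::aov(y ~ factor(g))
  summary(fit)[[1L]][["F value"]][1L]
}

# Orthogonal-Procrustes error between two configurations (rotation,
# reflection and translation allowed).
procrustes_error <- function(X, Y) {
  Xc <- scale(X, scale = FALSE); Yc <- scale(Y, scale = FALSE)
  if (ncol(Yc) < ncol(Xc))
    Yc <- cbind(Yc, matrix(0, nrow(Yc), ncol(Xc) - ncol(Yc)))
  if (ncol(Xc) < ncol(Yc))
    Xc <- cbind(Xc, matrix(0, nrow(Xc), ncol(Yc) - ncol(Xc)))
  s <- svd(crossprod(Yc, Xc))
  R <- s$u %*% t(s$v)
  max(abs(Yc %*% R - Xc))
}

# Tiny community fixture with guaranteed positive totals.
toy_counts <- function(n = 6L, k = 8L, seed = 1L, depth = 5000L) {
  set.seed(seed)
  m <- matrix(rpois(n * k, depth / k), n, k,
              dimnames = list(sprintf("s%02d", 1:n), sprintf("asv%03d", 1:k)))
  community_matrix(m)
}

# Minimal genotype fixture: n samples x given dosage matrix on one or more
# chromosomes (markers evenly spaced).
toy_genotypes <- function(dosages, chromosomes = NULL) {
  m <- ncol(dosages)
  if (is.null(colnames(dosages)))
    colnames(dosages) <- sprintf("m%03d", seq_len(m))
  if (is.null(rownames(dosages)))
    rownames(dosages) <- sprintf("s%02d", seq_len(nrow(dosages)))
  if (is.null(chromosomes)) chromosomes <- rep(1L, m)
  map <- data.frame(marker_id = colnames(dosages), chromosome = chromosomes,
                    position_bp = as.integer(stats::ave(
                      seq_len(m), chromosomes, FUN = function(ix)
                        seq_along(ix) * 1000L)))
  genotype_matrix(dosages, map)
}

toy_meta <- function(n = 8L, seed = 1L) {
  set.seed(seed)
  pops <- rep(c("Bt", "RS", "Hy"), length.out = n)
  sample_table(data.frame(
    sample_id = sprintf("s%02d", 1:n),
    population = pops,
    family = paste0(pops, 1L),
    tank = rep(c(1L, 2L), length.out = n),
    standard_length_mm = runif(n, 15, 20),
    sex = "unknown"))
}

# Hand-built scan_table for peak-calling tests: windows indexed 1..n on one
# chromosome, size 5, start_bp = idx * 1000.
toy_scan <- function(p, r = rep(0.5, length(p)), metric = "braycurtis",
                     chromosome = 1L, n_perm = 999L, size = 5L) {
  idx <- seq_along(p)
  s <- data.frame(chromosome = chromosome,
                  start_bp = idx * 1000L,
                  end_bp = idx * 1000L + (size - 1L) * 1000L,
                  markers = sprintf("w%d", idx),
                  mantel_r = r, p_value = p,
                  q_value = bh_adjust(p), n_perm = n_perm)
  structure(s, metric = metric, control = "genomewide", size = size,
            step = 1L, chrom_index = idx,
            class = c("scan_table", "data.frame"))
}
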