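# Sliding-window genome scan: per window of consecutive markers, a partial
# Mantel test of window genetic dissimilarity against community dissimilarity
# controlling for genome-wide relatedness (and optionally size), plus lowess
# p-value smoothing for display and cross-metric peak calling.

#' Build sliding marker windows along each chromosome
#'
#' Maximally overlapping windows of `size` consecutive markers (in map
#' order), advancing by `step` markers; chromosomes holding fewer than
#' `size` markers are skipped with a warning. A chromosome with `m` markers
#' yields `m - size + 1` windows at `step = 1`.
#'
#' @param G a [genotype_matrix()].
#' @param size markers per window (default 5).
#' @param step markers to advance between windows (default 1).
#' @return a data frame (class `window_set`) with one row per window:
#'   `window`, `chromosome`, `start_bp`, `end_bp`, `markers`
#'   (comma-separated marker ids); marker-id vectors in the
#'   `"marker_list"` attribute.
#' @export
make_windows <- function(G, size = 5L, step = 1L) {
  stopifnot(inherits(G, "genotype_matrix"))
  if (size < 2L) stop_gs("window size must be >= 2")
  if (step < 1L) stop_gs("step must be >= 1")
  map <- G$map
  out <- list(); marker_list <- list()
  skipped <- integer()
  for (chr in unique(map$chromosome)) {
    sub <- map[map$chromosome == chr, , drop = FALSE]
    m <- nrow(sub)
    if (m < size) { skipped <- c(skipped, chr); next }
    starts <- seq(1L, m - size + 1L, by = step)
    for (k in starts) {
      ids <- sub$marker_id[k:(k + size - 1L)]
      out[[length(out) + 1L]] <- data.frame(
        chromosome = chr,
        start_bp = sub$position_bp[k],
        end_bp = sub$position_bp[k + size - 1L],
        markers = paste(ids, collapse = ","),
        chrom_index = k)
      marker_list[[length(marker_list) + 1L]] <- ids
    }
  }
  if (length(skipped))
    warn_gs("chromosome(s) with fewer than %d markers skipped: %s", size,
            paste(skipped, collapse = ", "))
  if (!length(out)) {
    w <- data.frame(window = integer(), chromosome = integer(),
                    start_bp = integer(), end_bp = integer(),
                    markers = character(), chrom_index = integer())
  } else {
    w <- do.call(rbind, out)
    w <- cbind(window = seq_len(nrow(w)), w)
  }
  structure(w, marker_list = marker_list, size = as.integer(size),
            step = as.integer(step), class = c("window_set", "data.frame"))
}

# Sequential partial correlation: residualize on controls in order using the
# recursive first-order formula.
partial_r_seq <- function(r_ab, r_ac, r_bc) {
  # r_ac, r_bc: vectors of correlations of a and b with controls c1, c2, ...;
  # r_cc: handled by caller for >1 control via explicit recursion.
  partial_r(r_ab, r_ac, r_bc)
}

#' Genome scan of window-genetic vs community dissimilarity
#'
#' For every sliding window, computes the genetic dissimilarity restricted to
#' the window's markers and runs a partial Mantel test against the community
#' distance matrix. The control is the genome-wide genetic dissimilarity
#' (`"genomewide"`, the default, absorbing overall relatedness), body-size
#' dissimilarity (`"size"`), or both applied sequentially
#' (`"both-sequential"`: residualize on genome-wide relatedness, then size).
#'
#' Each window draws its permutations from a seed derived from
#' `(seed, window ordinal)`, so adding chromosomes or parallelizing does not
#' change any window's null. Windows whose markers are monomorphic in the
#' sample (zero variance in the window distances) are flagged with missing
#' `mantel_r`/`p_value` rather than failing the scan. Raw permutation
#' p-values are reported alongside Benjamini-Hochberg adjusted `q_value`s.
#'
#' @param G a [genotype_matrix()].
#' @param D_comm community `dist_matrix` (Bray-Curtis or weighted UniFrac).
#' @param control `"genomewide"`, `"size"` or `"both-sequential"`.
#' @param meta `sample_table`, required when size enters the control.
#' @param n_perm permutations per window (default 999).
#' @param seed master seed.
#' @param window_size,step passed to [make_windows()].
#' @return a data frame (class `scan_table`) with columns `chromosome`,
#'   `start_bp`, `end_bp`, `markers`, `mantel_r`, `p_value`, `q_value`,
#'   `n_perm`; metric/control labels and window geometry in attributes.
#' @export
scan_genome <- function(G, D_comm, control = c("genomewide", "size",
                                               "both-sequential"),
                        meta = NULL, n_perm = 999L, seed = 1L,
                        window_size = 5L, step = 1L) {
  control <- match.arg(control)
  stopifnot(inherits(G, "genotype_matrix"), inherits(D_comm, "dist_matrix"))
  if (control %in% c("size", "both-sequential") && is.null(meta))
    stop_gs("control '%s' needs sample metadata with standard lengths",
            control)

  controls <- list()
  if (control %in% c("genomewide", "both-sequential"))
    controls <- c(controls, list(genetic_dissimilarity(G)))
  if (control %in% c("size", "both-sequential"))
    controls <- c(controls, list(size_dissimilarity(meta)))

  ids <- do.call(align_ids,
                 c(list(sample_ids(G), rownames(D_comm)),
                   lapply(controls, rownames), list(what = "samples")))
  if (length(ids) < 5L) stop_gs("fewer than 5 shared samples")
  keep <- match(ids, sample_ids(G))
  G_al <- G
  G_al$dosages <- G$dosages[keep, , drop = FALSE]
  D_comm <- dist_subset(D_comm, ids)
  controls <- lapply(controls, dist_subset, ids = ids)

  windows <- make_windows(G_al, size = window_size, step = step)
  marker_list <- attr(windows, "marker_list")
  if (!nrow(windows)) stop_gs("no windows (all chromosomes too short)")

  b <- ut(D_comm)
  cs <- lapply(controls, ut)
  n <- length(ids)
  L <- n * (n - 1) / 2
  b_sum <- sum(b); b_css <- L * sum(b^2) - b_sum^2
  c_sum <- lapply(cs, sum)
  c_css <- lapply(cs, function(v) L * sum(v^2) - sum(v)^2)
  if (var(b) == 0 || any(vapply(cs, var, 1) == 0))
    stop_gs("degenerate community or control distance matrix")
  r_bc <- vapply(cs, function(v) cor(b, v), 1)
  r_cc <- if (length(cs) == 2L) cor(cs[[1L]], cs[[2L]]) else NA_real_
  V <- do.call(cbind, c(list(b), cs))

  stat_seq <- function(r_ab, r_ac) {
    # r_ac: per-control correlations of the (possibly permuted) window
    # distances with the controls; recycled formula for 1 or 2 controls.
    if (length(cs) == 1L) return(partial_r(r_ab, r_ac[[1L]], r_bc[1L]))
    r_ab_1 <- partial_r(r_ab, r_ac[[1L]], r_bc[1L])
    r_ac2_1 <- partial_r(r_ac[[2L]], r_ac[[1L]], r_cc)
    r_bc2_1 <- partial_r(r_bc[2L], r_bc[1L], r_cc)
    partial_r(r_ab_1, r_ac2_1, r_bc2_1)
  }

  rs <- ps <- rep(NA_real_, nrow(windows))
  for (w in seq_len(nrow(windows))) {
    D_win <- tryCatch(genetic_dissimilarity(G_al, marker_list[[w]]),
                      error = function(e) NULL)
    if (is.null(D_win)) next
    a <- ut(D_win)
    if (var(a) == 0) next  # monomorphic window: flagged, not fatal
    r_ab <- cor(a, b)
    r_ac <- lapply(cs, function(v) cor(a, v))
    if (any(abs(unlist(r_ac)) >= 1 - 1e-12)) next
    r_obs <- stat_seq(r_ab, r_ac)
    perms <- perm_matrix(n, n_perm, derive_seed(seed, windows$window[w]))
    momA <- tri_moments(unclass(D_win))
    S <- tri_cross_sums(unclass(D_win), V, perms)
    r_ab_p <- r_from_cross(S[, 1L], momA, b_sum, b_css)
    r_ac_p <- lapply(seq_along(cs), function(k)
      r_from_cross(S[, k + 1L], momA, c_sum[[k]], c_css[[k]]))
    r_perm <- stat_seq(r_ab_p, r_ac_p)
    rs[w] <- r_obs
    ps[w] <- perm_pvalue(r_perm, r_obs, n_perm)
  }

  res <- data.frame(chromosome = windows$chromosome,
                    start_bp = windows$start_bp,
                    end_bp = windows$end_bp,
                    markers = windows$markers,
                    mantel_r = rs, p_value = ps,
                    q_value = bh_adjust(ps),
                    n_perm = n_perm)
  structure(res, metric = attr(D_comm, "metric"), control = control,
            seed = seed, size = attr(windows, "size"),
            step = attr(windows, "step"),
            chrom_index = windows$chrom_index,
            class = c("scan_table", "data.frame"))
}

#' Lowess-smoothed p-values along the genome (display only)
#'
#' Smooths `log10(p)` against window genomic midpoint per chromosome with a
#' locally weighted linear smoother using fraction `span` of the points per
#' local fit; the output is clipped to the achievable p range
#' `[1/(n_perm+1), 1]`. Intended for plotting; peak calling always uses the
#' raw per-window p-values.
#'
#' @param scan a `scan_table`.
#' @param span fraction of points per local fit, in (0, 1] (default 0.05).
#' @return numeric vector of smoothed p-values, one per scan row (NA where
#'   the window was degenerate).
#' @export
smooth_pvalues <- function(scan, span = 0.05) {
  stopifnot(inherits(scan, "scan_table"))
  if (!nrow(scan)) stop_gs("empty scan")
  if (span <= 0 || span > 1) stop_gs("span must be in (0, 1]")
  out <- rep(NA_real_, nrow(scan))
  mid <- (scan$start_bp + scan$end_bp) / 2
  p_floor <- 1 / (scan$n_perm[1L] + 1)
  for (chr in unique(scan$chromosome)) {
    sel <- which(scan$chromosome == chr & !is.na(scan$p_value))
    if (!length(sel)) next
    if (length(sel) == 1L) { out[sel] <- scan$p_value[sel]; next }
    sm <- lowess(mid[sel], log10(scan$p_value[sel]), f = span)
    # lowess returns values sorted by x; map back to row order
    ord <- order(mid[sel])
    fitted <- numeric(length(sel))
    fitted[ord] <- sm$y
    out[sel] <- pmin(1, pmax(p_floor, 10^fitted))
  }
  out
}

# Merge significant window (chromosome) index runs into blocks: two windows
# belong to one block when they overlap or abut in marker index, i.e. their
# start indices differ by at most `size`.
blocks_from_windows <- function(chrom, idx, start_bp, end_bp, size) {
  out <- list()
  for (ch in unique(chrom)) {
    sel <- chrom == ch
    k <- sort(idx[sel])
    sb <- start_bp[sel][order(idx[sel])]
    eb <- end_bp[sel][order(idx[sel])]
    grp <- cumsum(c(1L, diff(k) > size))
    for (g in unique(grp)) {
      m <- grp == g
      out[[length(out) + 1L]] <- data.frame(
        chromosome = ch, start_bp = min(sb[m]), end_bp = max(eb[m]),
        n_windows = sum(m))
    }
  }
  if (!length(out)) data.frame(chromosome = integer(), start_bp = integer(),
                               end_bp = integer(), n_windows = integer())
  else do.call(rbind, out)
}

# Intersect two sets of intervals (data frames with start_bp/end_bp) on one
# chromosome; intervals are 1-based inclusive bp ranges.
intersect_intervals <- function(x, y) {
  out <- list()
  for (i in seq_len(nrow(x))) for (j in seq_len(nrow(y))) {
    s <- max(x$start_bp[i], y$start_bp[j])
    e <- min(x$end_bp[i], y$end_bp[j])
    if (s <= e) out[[length(out) + 1L]] <- data.frame(start_bp = s, end_bp = e)
  }
  if (!length(out)) data.frame(start_bp = integer(), end_bp = integer())
  else do.call(rbind, out)
}

merge_intervals <- function(x) {
  if (!nrow(x)) return(x)
  x <- x[order(x$start_bp, x$end_bp), , drop = FALSE]
  keep <- list(x[1L, , drop = FALSE])
  for (i in seq_len(nrow(x))[-1L]) {
    last <- keep[[length(keep)]]
    if (x$start_bp[i] <= last$end_bp) {
      keep[[length(keep)]]$end_bp <- max(last$end_bp, x$end_bp[i])
    } else keep[[length(keep) + 1L]] <- x[i, , drop = FALSE]
  }
  do.call(rbind, keep)
}

#' Call cross-metric peaks from one or more genome scans
#'
#' Per scan, windows with `p <= alpha` and `mantel_r > 0` are merged into
#' blocks when they overlap or abut in marker index. With
#' `require_all = TRUE` (default) a peak is a genomic region where blocks
#' from *every* scan overlap on the bp axis — windows consistently
#' significant across community-dissimilarity metrics; the reported interval
#' is `[min start_bp, max end_bp]` over the significant windows touching the
#' intersection. With `require_all = FALSE` the union of blocks is reported.
#'
#' @param scans a single `scan_table` or a list of them (same window set).
#' @param alpha significance threshold on the raw permutation p (default
#'   0.001, the smallest p achievable at 999 permutations).
#' @param require_all require support from every scan (default `TRUE`).
#' @return a data frame (class `peak_set`) with columns `chromosome`,
#'   `start_bp`, `end_bp`, `n_windows`, `metrics`.
#' @export
call_peaks <- function(scans, alpha = 0.001, require_all = TRUE) {
  if (inherits(scans, "scan_table")) scans <- list(scans)
  stopifnot(length(scans) >= 1L,
            all(vapply(scans, inherits, TRUE, "scan_table")))
  key <- function(s) paste(s$chromosome, s$start_bp, s$end_bp)
  for (s in scans[-1L]) if (!identical(key(s), key(scans[[1L]])))
    stop_gs("mismatched window sets across scans")
  empty <- data.frame(chromosome = integer(), start_bp = integer(),
                      end_bp = integer(), n_windows = integer(),
                      metrics = character())
  class(empty) <- c("peak_set", "data.frame")
  p_floor <- 1 / (scans[[1L]]$n_perm[1L] + 1)
  if (alpha < p_floor) {
    warn_gs("alpha = %g is below the achievable minimum p = %g; no peaks",
            alpha, p_floor)
    return(empty)
  }

  metric_of <- function(s) attr(s, "metric") %||% "unknown"
  size <- attr(scans[[1L]], "size") %||% 5L
  sig_rows <- lapply(scans, function(s) {
    sel <- !is.na(s$p_value) & s$p_value <= alpha & !is.na(s$mantel_r) &
      s$mantel_r > 0
    data.frame(chromosome = s$chromosome[sel], start_bp = s$start_bp[sel],
               end_bp = s$end_bp[sel],
               idx = (attr(s, "chrom_index") %||%
                        stats::ave(s$start_bp, s$chromosome,
                                   FUN = seq_along))[sel])
  })
  blocks <- lapply(sig_rows, function(sr)
    blocks_from_windows(sr$chromosome, sr$idx, sr$start_bp, sr$end_bp, size))
  if (any(vapply(blocks, nrow, 1L) == 0L) && require_all) return(empty)

  all_sig <- do.call(rbind, sig_rows)
  peaks <- list()
  for (ch in sort(unique(unlist(lapply(blocks, function(b) b$chromosome))))) {
    per_scan <- lapply(blocks, function(b)
      b[b$chromosome == ch, c("start_bp", "end_bp"), drop = FALSE])
    if (require_all) {
      core <- Reduce(intersect_intervals, per_scan)
    } else {
      core <- do.call(rbind, per_scan)
    }
    if (!nrow(core)) next
    core <- merge_intervals(core)
    for (i in seq_len(nrow(core))) {
      touching <- all_sig$chromosome == ch &
        all_sig$start_bp <= core$end_bp[i] & all_sig$end_bp >= core$start_bp[i]
      tw <- unique(all_sig[touching, c("start_bp", "end_bp")])
      support <- vapply(seq_along(scans), function(k) {
        sr <- sig_rows[[k]]
        any(sr$chromosome == ch & sr$start_bp <= core$end_bp[i] &
              sr$end_bp >= core$start_bp[i])
      }, TRUE)
      peaks[[length(peaks) + 1L]] <- data.frame(
        chromosome = ch, start_bp = min(tw$start_bp), end_bp = max(tw$end_bp),
        n_windows = nrow(tw),
        metrics = paste(sort(vapply(scans[support], metric_of, "")),
                        collapse = ","))
    }
  }
  if (!length(peaks)) return(empty)
  out <- do.call(rbind, peaks)
  # expansion to [min start, max end] can make neighbors overlap: merge them
  merged <- list()
  for (ch in unique(out$chromosome)) {
    sub <- out[out$chromosome == ch, , drop = FALSE]
    sub <- sub[order(sub$start_bp), , drop = FALSE]
    cur <- sub[1L, , drop = FALSE]
    for (i in seq_len(nrow(sub))[-1L]) {
      if (sub$start_bp[i] <= cur$end_bp) {
        cur$end_bp <- max(cur$end_bp, sub$end_bp[i])
        cur$n_windows <- cur$n_windows + sub$n_windows[i]
        cur$metrics <- paste(sort(unique(unlist(strsplit(
          c(cur$metrics, sub$metrics[i]), ",")))), collapse = ",")
      } else {
        merged[[length(merged) + 1L]] <- cur
        cur <- sub[i, , drop = FALSE]
      }
    }
    merged[[length(merged) + 1L]] <- cur
  }
  out <- do.call(rbind, merged)
  rownames(out) <- NULL
  class(out) <- c("peak_set", "data.frame")
  out
}
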