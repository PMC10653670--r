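# Library/ASV filtering and depth normalization for ASV count tables.
# Pipeline default order: depth filter first, then ASV prevalence (computed
# on the surviving libraries), then log-CPM or relative-abundance
# normalization.

#' Drop low-depth libraries
#'
#' Retains exactly the samples whose total ASV count is at least `min_total`
#' (libraries with *fewer* than `min_total` counts are excluded). The removed
#' sample ids are messaged.
#'
#' @param counts a [community_matrix()].
#' @param min_total minimum library size to keep (default 40000).
#' @return a filtered [community_matrix()].
#' @export
filter_libraries <- function(counts, min_total = 40000L) {
  stopifnot(inherits(counts, "community_matrix"), min_total >= 0)
  keep <- counts$totals >= min_total
  if (!any(keep)) stop_gs("empty dataset after filtering (min_total = %s)",
                          min_total)
  if (any(!keep))
    message(sprintf("filter_libraries: removed %d sample(s): %s", sum(!keep),
                    paste(rownames(counts$counts)[!keep], collapse = ", ")))
  community_matrix(counts$counts[keep, , drop = FALSE])
}

#' Drop rare and excluded ASVs
#'
#' Removes ASVs present (nonzero) in fewer than `min_libraries` samples, then
#' any ASV named in `exclude_ids` (e.g. known reagent contaminants).
#'
#' @param counts a [community_matrix()].
#' @param min_libraries minimum number of libraries an ASV must occur in
#'   (default 2, i.e. singleton-library ASVs are dropped).
#' @param exclude_ids character vector of ASV ids to remove regardless of
#'   prevalence; ids absent from the table produce a warning, not an error.
#' @return a filtered [community_matrix()].
#' @export
filter_asvs <- function(counts, min_libraries = 2L, exclude_ids = character()) {
  stopifnot(inherits(counts, "community_matrix"), min_libraries >= 1)
  prev <- colSums(counts$counts > 0L)
  drop_rare <- prev < min_libraries
  absent <- setdiff(exclude_ids, colnames(counts$counts))
  if (length(absent))
    warn_gs("exclude_ids not present in table: %s",
            paste(absent, collapse = ", "))
  drop_excl <- colnames(counts$counts) %in% exclude_ids
  keep <- !(drop_rare | drop_excl)
  if (!any(keep)) stop_gs("empty dataset after ASV filtering")
  if (any(drop_rare))
    message(sprintf("filter_asvs: dropped %d ASV(s) below prevalence %d",
                    sum(drop_rare), min_libraries))
  if (any(drop_excl))
    message(sprintf("filter_asvs: excluded %d listed ASV(s): %s",
                    sum(drop_excl),
                    paste(colnames(counts$counts)[drop_excl], collapse = ", ")))
  community_matrix(counts$counts[, keep, drop = FALSE])
}

new_normalized_matrix <- function(values, mode, params = list()) {
  structure(values, norm_mode = mode, norm_params = params,
            class = c("normalized_matrix", class(values)))
}

#' Log2 counts-per-million normalization with library-scaled prior
#'
#' Computes `log2((c_ij + p_i) / (L_i + 2 p_i) * 1e6)` where `L_i` is the
#' library size of sample `i` and the prior is scaled per library,
#' `p_i = prior_count * L_i / mean(L)`. This library-proportional prior keeps
#' the zero-count baseline comparable across libraries of unequal depth
#' (a plain constant prior would re-rank zeros across libraries).
#'
#' @param counts a [community_matrix()] with all totals > 0.
#' @param prior_count prior count added before the log (default 0.5).
#' @return a `normalized_matrix` (samples x ASVs) with mode `"logcpm"`.
#' @export
cpm_log_normalize <- function(counts, prior_count = 0.5) {
  stopifnot(inherits(counts, "community_matrix"))
  L <- counts$totals
  if (any(L <= 0)) stop_gs("library total 0 for sample(s): %s",
                           paste(names(L)[L <= 0], collapse = ", "))
  p <- prior_count * L / mean(L)
  vals <- log2((counts$counts + p) / (L + 2 * p) * 1e6)
  new_normalized_matrix(vals, "logcpm",
                        list(prior_count = prior_count, scale = 1e6))
}

#' Relative abundance (per-sample proportions)
#'
#' @param counts a [community_matrix()] with all totals > 0.
#' @return a `normalized_matrix` with mode `"relabund"`; rows sum to 1.
#' @export
relative_abundance <- function(counts) {
  stopifnot(inherits(counts, "community_matrix"))
  L <- counts$totals
  if (any(L <= 0)) stop_gs("library total 0 for sample(s): %s",
                           paste(names(L)[L <= 0], collapse = ", "))
  new_normalized_matrix(counts$counts / L, "relabund", list())
}
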