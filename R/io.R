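# Readers, writers and validated containers for every external format the
# pipeline touches: genotype dosage tables (+ marker map), VCF, ASV count
# tables, sample metadata, newick trees and tabular results.

#' Construct a validated genotype matrix
#'
#' Stores biallelic genotypes as ALT/minor-allele dosages (0, 1, 2 or `NA`)
#' together with a marker map (chromosome, 1-based bp position). Markers are
#' re-sorted by (chromosome, position); the permutation applied is recorded
#' in the `"marker_order"` attribute.
#'
#' @param dosages integer matrix, samples x markers, values in `{0,1,2,NA}`,
#'   with sample ids as rownames and marker ids as colnames.
#' @param map data frame with columns `marker_id`, `chromosome`,
#'   `position_bp` (one row per marker).
#' @param n_chromosomes number of chromosomes the map may reference
#'   (stickleback has 21).
#' @return an object of class `genotype_matrix`: a list with elements
#'   `dosages` and `map`.
#' @export
genotype_matrix <- function(dosages, map, n_chromosomes = 21L) {
  dosages <- as.matrix(dosages)
  if (is.null(rownames(dosages)) || is.null(colnames(dosages)))
    stop_gs("dosage matrix needs sample rownames and marker colnames")
  if (anyDuplicated(rownames(dosages)))
    stop_gs("duplicate sample ids: %s",
            paste(unique(rownames(dosages)[duplicated(rownames(dosages))]),
                  collapse = ", "))
  if (anyDuplicated(colnames(dosages)))
    stop_gs("duplicate marker ids: %s",
            paste(unique(colnames(dosages)[duplicated(colnames(dosages))]),
                  collapse = ", "))
  vals <- dosages[!is.na(dosages)]
  if (length(vals) && !all(vals %in% c(0, 1, 2)))
    stop_gs("dosages must be 0, 1, 2 or NA; found %s",
            paste(unique(vals[!vals %in% c(0, 1, 2)]), collapse = ", "))
  storage.mode(dosages) <- "integer"

  req <- c("marker_id", "chromosome", "position_bp")
  if (!all(req %in% names(map)))
    stop_gs("marker map needs columns %s", paste(req, collapse = ", "))
  map <- as.data.frame(map)[, req]
  if (!setequal(map$marker_id, colnames(dosages)))
    stop_gs("marker map ids do not match dosage matrix columns")
  bad <- !(map$chromosome %in% seq_len(n_chromosomes))
  if (any(bad))
    stop_gs("marker(s) on unknown chromosome (map declares %d): %s",
            n_chromosomes,
            paste(map$marker_id[bad], collapse = ", "))
  if (any(map$position_bp < 0))
    stop_gs("negative position_bp for marker(s): %s",
            paste(map$marker_id[map$position_bp < 0], collapse = ", "))
  map$chromosome <- as.integer(map$chromosome)
  map$position_bp <- as.integer(map$position_bp)

  ord <- order(map$chromosome, map$position_bp, map$marker_id)
  map <- map[ord, , drop = FALSE]
  rownames(map) <- NULL
  perm <- match(map$marker_id, colnames(dosages))
  dosages <- dosages[, perm, drop = FALSE]

  structure(list(dosages = dosages, map = map),
            marker_order = perm,
            n_chromosomes = as.integer(n_chromosomes),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d markers on %d chromosome(s)\n",
              nrow(x$dosages), ncol(x$dosages),
              length(unique(x$map$chromosome))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

sample_ids <- function(x) UseMethod("sample_ids")
#' @export
sample_ids.genotype_matrix <- function(x) rownames(x$dosages)
#' @export
sample_ids.community_matrix <- function(x) rownames(x$counts)
#' @export
sample_ids.data.frame <- function(x) x$sample_id
#' @export
sample_ids.default <- function(x) rownames(x)

#' Construct a validated community (ASV count) matrix
#'
#' @param counts non-negative integer matrix, samples x ASVs, with sample ids
#'   as rownames and ASV ids as colnames.
#' @return an object of class `community_matrix`: list with `counts` and
#'   per-sample `totals` (row sums).
#' @export
community_matrix <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) == 0L) stop_gs("no samples in count table")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop_gs("count matrix needs sample rownames and ASV colnames")
  if (anyDuplicated(colnames(counts)))
    stop_gs("duplicate ASV ids")
  if (anyDuplicated(rownames(counts)))
    stop_gs("duplicate sample ids")
  bad <- which(is.na(counts) | counts < 0 | counts != round(counts),
               arr.ind = TRUE)
  if (nrow(bad))
    stop_gs("counts must be non-negative integers; offending cell (%s, %s) = %s",
            rownames(counts)[bad[1L, 1L]], colnames(counts)[bad[1L, 2L]],
            counts[bad[1L, , drop = FALSE]])
  storage.mode(counts) <- "integer"
  structure(list(counts = counts, totals = rowSums(counts)),
            class = "community_matrix")
}

#' @export
print.community_matrix <- function(x, ...) {
  cat(sprintf("community_matrix: %d samples x %d ASVs, median depth %s\n",
              nrow(x$counts), ncol(x$counts),
              format(stats::median(x$totals), big.mark = ",")))
  invisible(x)
}

#' @export
dim.community_matrix <- function(x) dim(x$counts)

#' Validate a sample metadata table
#'
#' Required columns: `sample_id`, `population` (one of Bt, RS, Hy), `family`,
#' `tank` (1 or 2), `standard_length_mm` (positive). Optional `sex`
#' (F, M or unknown; filled with "unknown" when absent).
#'
#' @param df data frame of per-fish metadata.
#' @param strict when `TRUE` (default) malformed labels (e.g. `"BT "`) are an
#'   error; when `FALSE` population labels are whitespace-trimmed and
#'   case-normalized before validation.
#' @return the validated data frame (class `sample_table`), rows ordered by
#'   `sample_id`.
#' @export
sample_table <- function(df, strict = TRUE) {
  req <- c("sample_id", "population", "family", "tank", "standard_length_mm")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop_gs("metadata missing column(s): %s",
                            paste(miss, collapse = ", "))
  df <- as.data.frame(df)
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id)) stop_gs("duplicate sample_id in metadata")
  pops <- c("Bt", "RS", "Hy")
  df$population <- as.character(df$population)
  if (!strict) {
    key <- tolower(trimws(df$population))
    df$population <- pops[match(key, tolower(pops))]
  }
  bad <- !(df$population %in% pops)
  if (any(bad))
    stop_gs("unknown population label(s): %s",
            paste(unique(df$population[bad]), collapse = ", "))
  if (!all(df$tank %in% c(1, 2)))
    stop_gs("tank must be 1 or 2; found %s",
            paste(unique(df$tank[!df$tank %in% c(1, 2)]), collapse = ", "))
  df$tank <- as.integer(df$tank)
  sl <- df$standard_length_mm
  if (any(is.na(sl)) || any(sl <= 0))
    stop_gs("standard_length_mm must be positive and non-missing")
  if (is.null(df$sex)) df$sex <- "unknown"
  df$sex <- as.character(df$sex)
  if (!all(df$sex %in% c("F", "M", "unknown")))
    stop_gs("sex must be F, M or unknown")
  # one family, one population
  fam_pop <- unique(df[, c("family", "population")])
  if (anyDuplicated(fam_pop$family))
    stop_gs("family assigned to more than one population: %s",
            paste(fam_pop$family[duplicated(fam_pop$family)], collapse = ", "))
  df <- df[order(df$sample_id), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("sample_table", "data.frame")
  df
}

#' Read a genotype dosage table (TSV) or VCF
#'
#' The TSV dialect has one header row of marker ids, a first column of sample
#' ids and cells in `{0,1,2,NA}`, with a companion map file giving
#' `marker_id`, `chromosome`, `position_bp` per marker. VCF input must contain
#' biallelic SNP records; the GT field is converted to ALT-allele dosage
#' (`0/1` -> 1, `1|1` -> 2, `./.` -> `NA`).
#'
#' @param path genotype TSV or VCF file.
#' @param format `"tsv"` or `"vcf"`.
#' @param map_path marker-map TSV (required for `format = "tsv"`).
#' @param n_chromosomes passed to [genotype_matrix()].
#' @return a [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("tsv", "vcf"), map_path = NULL,
                           n_chromosomes = 21L) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_gs("file not found: %s", path)
  if (format == "tsv") {
    if (is.null(map_path)) stop_gs("map_path is required for TSV genotypes")
    tab <- read.delim(path, check.names = FALSE, row.names = 1L)
    m <- as.matrix(tab)
    bad <- m[!is.na(m) & !(m %in% c(0, 1, 2))]
    if (length(bad))
      stop_gs("dosage outside {0,1,2}: %s", paste(unique(bad), collapse = ", "))
    map <- read.delim(map_path, check.names = FALSE)
    genotype_matrix(m, map, n_chromosomes = n_chromosomes)
  } else {
    read_genotypes_vcf(path, n_chromosomes)
  }
}

read_genotypes_vcf <- function(path, n_chromosomes = 21L) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop_gs("reading VCF requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  bi <- vcfR::is.biallelic(v)
  if (!all(bi)) {
    ids <- vcfR::getID(v)
    if (all(is.na(ids))) ids <- paste0(vcfR::getCHROM(v), ":", vcfR::getPOS(v))
    stop_gs("non-biallelic VCF record(s): %s",
            paste(ids[!bi], collapse = ", "))
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  dos <- apply(gt, c(1, 2), function(g) {
    if (is.na(g) || g %in% c("./.", ".|.", ".")) return(NA_integer_)
    alleles <- strsplit(g, "[/|]")[[1L]]
    if (any(alleles == ".")) return(NA_integer_)
    sum(as.integer(alleles) > 0L)
  })
  ids <- vcfR::getID(v)
  chrom <- vcfR::getCHROM(v)
  pos <- vcfR::getPOS(v)
  if (any(is.na(ids)))
    ids[is.na(ids)] <- paste0(chrom[is.na(ids)], ":", pos[is.na(ids)])
  rownames(dos) <- ids
  # chromosome labels may carry a prefix like "chr" or "group"
  chr_num <- suppressWarnings(as.integer(gsub("[^0-9]", "", chrom)))
  if (any(is.na(chr_num)))
    stop_gs("cannot parse chromosome label(s): %s",
            paste(unique(chrom[is.na(chr_num)]), collapse = ", "))
  map <- data.frame(marker_id = ids, chromosome = chr_num, position_bp = pos)
  genotype_matrix(t(dos), map, n_chromosomes = n_chromosomes)
}

#' Read an ASV count table (samples x ASVs, TSV)
#'
#' @param path TSV with sample ids in the first column, ASV ids in the header
#'   and non-negative integer cells.
#' @return a [community_matrix()].
#' @export
read_counts <- function(path) {
  if (!file.exists(path)) stop_gs("file not found: %s", path)
  tab <- read.delim(path, check.names = FALSE, row.names = 1L)
  if (nrow(tab) == 0L) stop_gs("no samples in count table %s", path)
  community_matrix(as.matrix(tab))
}

#' Read a sample metadata table (TSV)
#'
#' @inheritParams sample_table
#' @param path metadata TSV.
#' @return a validated `sample_table`.
#' @export
read_metadata <- function(path, strict = TRUE) {
  if (!file.exists(path)) stop_gs("file not found: %s", path)
  sample_table(read.delim(path, check.names = FALSE), strict = strict)
}

#' Read a rooted phylogenetic tree (newick)
#'
#' Unrooted input is midpoint-rooted with a warning; missing branch lengths
#' are set to zero with a warning.
#'
#' @param path newick file.
#' @return an [ape::read.tree()] `phylo` object, rooted.
#' @export
read_tree <- function(path) {
  if (!file.exists(path)) stop_gs("file not found: %s", path)
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop_gs("could not parse newick in %s", path)
  if (anyDuplicated(tr$tip.label))
    stop_gs("duplicated tip label(s): %s",
            paste(unique(tr$tip.label[duplicated(tr$tip.label)]),
                  collapse = ", "))
  if (is.null(tr$edge.length)) {
    warn_gs("tree has no branch lengths; treating all as 0")
    tr$edge.length <- rep(0, nrow(tr$edge))
  }
  if (anyNA(tr$edge.length)) {
    warn_gs("missing branch length(s) treated as 0")
    tr$edge.length[is.na(tr$edge.length)] <- 0
  }
  if (any(tr$edge.length < 0)) stop_gs("negative branch length in %s", path)
  if (!ape::is.rooted(tr)) {
    warn_gs("input tree is unrooted; midpoint-rooting")
    tr <- phangorn::midpoint(tr)
  }
  tr
}

#' Write a tabular result as TSV at full floating precision
#'
#' Doubles are written with 17 significant digits so that write -> read
#' round-trips bit-identically; column order is preserved deterministically.
#'
#' @param result a data frame (scan tables, peak sets, PERMANOVA tables, ...)
#'   or a labeled matrix (e.g. a distance matrix).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_table <- function(result, path) {
  if (inherits(result, "dist_matrix") || is.matrix(result)) {
    df <- as.data.frame(apply(unclass(result), 2L, format_full))
    if (!is.null(rownames(result))) {
      df <- cbind(sample_id = rownames(result), df)
      names(df)[-1L] <- colnames(result)
    }
  } else {
    df <- as.data.frame(result)
    for (j in seq_along(df)) if (is.double(df[[j]]))
      df[[j]] <- format_full(df[[j]])
  }
  ok <- tryCatch({
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop_gs("cannot write %s: %s", path, conditionMessage(ok))
  invisible(path)
}

#' Read back a square distance matrix written by [write_table()]
#'
#' @param path TSV with a `sample_id` column and one column per sample.
#' @param metric metric label to attach.
#' @return a `dist_matrix`.
#' @export
read_dist <- function(path, metric = "unknown") {
  tab <- read.delim(path, check.names = FALSE, row.names = 1L)
  m <- as.matrix(tab)
  dist_matrix(m, metric = metric)
}
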