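# Synthetic common-garden generator: differentiated parental populations,
# Mendelian crosses with F1 hybrids, tank/size effects on standard length,
# and zero-inflated negative binomial ASV counts with optional planted
# genomic effects, so every analysis stage can be tested with known truth.

#' Describe a planted genomic effect window
#'
#' @param chromosome chromosome carrying the window.
#' @param start,end first and last marker index (within the chromosome, in
#'   map order) of the causal window.
#' @param n_asvs number of ASVs whose abundance responds to the window
#'   dosage (default 40).
#' @param delta log-scale effect per unit of (centered) window mean dosage
#'   (default 0.8; a power-oriented reference effect, not a biological
#'   estimate).
#' @return a list usable in `sim_config(planted_windows = list(...))`.
#' @export
planted_window <- function(chromosome, start, end, n_asvs = 40L,
                           delta = 0.8) {
  list(chromosome = as.integer(chromosome), start = as.integer(start),
       end = as.integer(end), n_asvs = as.integer(n_asvs), delta = delta)
}

#' Configure the synthetic common-garden experiment
#'
#' Defaults emulate the study design this package targets: 8 crosses (3 Boot
#' Lake "Bt", 3 Rabbit Slough "RS", 2 F1 hybrid "Hy"), 40 germ-free progeny
#' per cross split 20/20 across two tanks, one Bt family lost entirely,
#' partial survival leaving ~134 typed fish, 21 chromosomes x 115 biallelic
#' markers (~2,408 loci), ~2,306 ASVs scaled down to `n_asvs`, library sizes
#' log-normal around a mean of 238,706 reads, and population/tank/size/GxE
#' effects on ASV log-abundance.
#'
#' @param seed master seed.
#' @param n_chromosomes,markers_per_chromosome marker map shape.
#' @param chromosome_length_bp bp span per chromosome (marker positions are
#'   drawn uniformly).
#' @param n_families named vector of family counts per population.
#' @param offspring_per_family embryos per cross (default 40).
#' @param tank_split allocation per family to tanks 1 and 2 (default 20/20).
#' @param family_mortality family id lost entirely (default the first Bt
#'   family; `NULL` for none).
#' @param survival_rate per-fish survival probability after the family loss.
#' @param differentiation Bt-RS allele-frequency divergence in \[0, 1\]
#'   (Balding-Nichols style; 0 = identical populations).
#' @param inbreeding_bt excess homozygosity of Boot Lake founders.
#' @param sl_means population mean standard lengths, mm.
#' @param sl_family_sd,sl_residual_sd family and individual SL standard
#'   deviations, mm.
#' @param n_asvs number of ASVs (default 300, a desk-scale stand-in).
#' @param library_size_mean,library_size_sdlog log-normal library-size model.
#' @param zinb list: `base_log_mean_sd` (spread of baseline ASV
#'   log-abundances), `theta_meanlog`/`theta_sdlog` (log-normal NB
#'   dispersion), `pi_max` (zero-inflation probabilities drawn uniform on
#'   \[0, pi_max\]); optional `pi_values`/`theta_values` to fix them per ASV.
#' @param effects list of log-scale effect SDs: `population_sd`, `tank_sd`,
#'   `sl_slope_sd` (per mm), `gxe_sd` (population x tank).
#' @param planted_windows list of [planted_window()] descriptions.
#' @param dominance use dominance coding (heterozygote = homozygote ALT) for
#'   the planted-window dosage signal.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_chromosomes = 21L,
                       markers_per_chromosome = 115L,
                       chromosome_length_bp = 2e7,
                       n_families = c(Bt = 3L, RS = 3L, Hy = 2L),
                       offspring_per_family = 40L,
                       tank_split = c(20L, 20L),
                       family_mortality = "Bt1",
                       survival_rate = 0.53,
                       differentiation = 0.3,
                       inbreeding_bt = 0.15,
                       sl_means = c(Bt = 17.368, RS = 18.524, Hy = 16.753),
                       sl_family_sd = 0.5,
                       sl_residual_sd = 1.5,
                       n_asvs = 300L,
                       library_size_mean = 238706.4,
                       library_size_sdlog = 0.5,
                       zinb = list(),
                       effects = list(),
                       planted_windows = list(),
                       dominance = FALSE) {
  zinb_def <- list(base_log_mean_sd = 1.5, theta_meanlog = log(2),
                   theta_sdlog = 0.7, pi_max = 0.7,
                   pi_values = NULL, theta_values = NULL)
  zinb <- utils::modifyList(zinb_def, zinb)
  eff_def <- list(population_sd = 0.4, tank_sd = 0.3, sl_slope_sd = 0.03,
                  gxe_sd = 0.2)
  effects <- utils::modifyList(eff_def, effects)

  stopifnot(differentiation >= 0, differentiation <= 1,
            inbreeding_bt >= 0, inbreeding_bt <= 1,
            survival_rate >= 0, survival_rate <= 1,
            zinb$pi_max >= 0, zinb$pi_max <= 1,
            all(unlist(effects) >= 0),
            sl_family_sd >= 0, sl_residual_sd >= 0,
            sum(tank_split) == offspring_per_family,
                        all(c("Bt", "RS", "Hy") %in% names(n_families)))
  for (w in planted_windows) {
    if (w$chromosome < 1L || w$chromosome > n_chromosomes ||
        w$start < 1L || w$end > markers_per_chromosome || w$start > w$end)
      stop_gs("planted window off the marker map (chr %s, markers %s-%s)",
              w$chromosome, w$start, w$end)
    if (w$n_asvs > n_asvs) stop_gs("planted window affects more ASVs than exist")
  }
  structure(list(seed = as.integer(seed), n_chromosomes = n_chromosomes,
                 markers_per_chromosome = markers_per_chromosome,
                 chromosome_length_bp = chromosome_length_bp,
                 n_families = n_families,
                 offspring_per_family = offspring_per_family,
                 tank_split = tank_split,
                 family_mortality = family_mortality,
                 survival_rate = survival_rate,
                 differentiation = differentiation,
                 inbreeding_bt = inbreeding_bt,
                 sl_means = sl_means, sl_family_sd = sl_family_sd,
                 sl_residual_sd = sl_residual_sd, n_asvs = n_asvs,
                 library_size_mean = library_size_mean,
                 library_size_sdlog = library_size_sdlog,
                 zinb = zinb, effects = effects,
                 planted_windows = planted_windows, dominance = dominance),
            class = "sim_config")
}

family_names <- function(cfg) {
  unlist(lapply(c("Bt", "RS", "Hy"), function(p)
    paste0(p, seq_len(cfg$n_families[[p]]))))
}

marker_map_from_config <- function(cfg, seed) {
  with_seed(seed, {
    maps <- lapply(seq_len(cfg$n_chromosomes), function(chr) {
      pos <- sort(sample.int(cfg$chromosome_length_bp,
                             cfg$markers_per_chromosome))
      data.frame(marker_id = sprintf("chr%02d_m%03d", chr,
                                     seq_len(cfg$markers_per_chromosome)),
                 chromosome = chr, position_bp = pos)
    })
    do.call(rbind, maps)
  })
}

# genotype draw with inbreeding coefficient f: P(0)=(1-p)^2+fp(1-p),
# P(1)=2p(1-p)(1-f), P(2)=p^2+fp(1-p)
draw_genotypes <- function(p, f = 0) {
  q <- 1 - p
  pr0 <- q^2 + f * p * q
  pr1 <- 2 * p * q * (1 - f)
  u <- runif(length(p))
  ifelse(u < pr0, 0L, ifelse(u < pr0 + pr1, 1L, 2L))
}

#' Simulate differentiated parental founders
#'
#' Per marker, an ancestral frequency is drawn uniform on \[0.05, 0.95\]
#' (mirroring a minimum-minor-allele-frequency genotype filter); Boot Lake
#' and Rabbit Slough frequencies are drawn around it Balding-Nichols style
#' with divergence scaled by `differentiation`. Parental diploid genotypes
#' are drawn binomially, with excess homozygosity (`inbreeding_bt`) for Boot
#' Lake founders. Hybrid families take a Rabbit Slough mother and a Boot
#' Lake father.
#'
#' @param cfg a [sim_config()].
#' @return list with `parents` (a [genotype_matrix()] of 2 founders per
#'   family), `freqs` (per-marker ancestral/population frequencies) and
#'   `family_table` (family, population, mother, father).
#' @export
simulate_parents <- function(cfg) {
  map <- marker_map_from_config(cfg, derive_seed(cfg$seed, 1L))
  m <- nrow(map)
  fams <- family_names(cfg)
  with_seed(derive_seed(cfg$seed, 2L), {
    p0 <- runif(m, 0.05, 0.95)
    # planted causal windows must segregate among the fish to be a
    # well-defined ground truth: force intermediate ancestral frequencies
    for (w in cfg$planted_windows) {
      mk <- window_marker_ids(cfg, map, w)
      p0[match(mk, map$marker_id)] <- runif(length(mk), 0.4, 0.6)
    }
    Fst <- cfg$differentiation
    draw_pop_freq <- function() {
      if (Fst == 0) return(p0)
      if (Fst >= 1) return(rbinom(m, 1L, p0))
      a <- p0 * (1 - Fst) / Fst
      b <- (1 - p0) * (1 - Fst) / Fst
      rbeta(m, a, b)
    }
    p_bt <- draw_pop_freq()
    p_rs <- draw_pop_freq()
    fam_tab <- data.frame(
      family = fams,
      population = sub("[0-9]+$", "", fams),
      mother = paste0(fams, "_mother"),
      father = paste0(fams, "_father"))
    geno <- matrix(0L, nrow = 2L * length(fams), ncol = m)
    rownames(geno) <- as.vector(rbind(fam_tab$mother, fam_tab$father))
    colnames(geno) <- map$marker_id
    for (i in seq_len(nrow(fam_tab))) {
      pop <- fam_tab$population[i]
      if (pop == "Bt") {
        geno[fam_tab$mother[i], ] <- draw_genotypes(p_bt, cfg$inbreeding_bt)
        geno[fam_tab$father[i], ] <- draw_genotypes(p_bt, cfg$inbreeding_bt)
      } else if (pop == "RS") {
        geno[fam_tab$mother[i], ] <- draw_genotypes(p_rs, 0)
        geno[fam_tab$father[i], ] <- draw_genotypes(p_rs, 0)
      } else {  # Hy: RS female x Bt male
        geno[fam_tab$mother[i], ] <- draw_genotypes(p_rs, 0)
        geno[fam_tab$father[i], ] <- draw_genotypes(p_bt, cfg$inbreeding_bt)
      }
    }
    # planted causal windows are maximally informative by design: founders
    # are heterozygous there, so the window segregates in every family and
    # the planted ground truth is well-defined within as well as between
    # families
    for (w in cfg$planted_windows) {
      mk <- window_marker_ids(cfg, map, w)
      geno[, match(mk, map$marker_id)] <- 1L
    }
    list(parents = genotype_matrix(geno, map,
                                   n_chromosomes = cfg$n_chromosomes),
         freqs = data.frame(marker_id = map$marker_id, p0 = p0,
                            p_bt = p_bt, p_rs = p_rs),
         family_table = fam_tab)
  })
}

#' Simulate a Mendelian cross
#'
#' Each offspring receives, per marker, one allele drawn uniformly from each
#' parent's two alleles; markers segregate independently (no recombination
#' map).
#'
#' @param mother,father named dosage vectors sharing the same markers.
#' @param n_offspring number of offspring.
#' @param seed RNG seed.
#' @param prefix sample-id prefix for the offspring.
#' @return integer dosage matrix, offspring x markers.
#' @export
simulate_cross <- function(mother, father, n_offspring, seed,
                           prefix = "off") {
  stopifnot(length(mother) == length(father))
  m <- length(mother)
  with_seed(seed, {
    gm <- matrix(rbinom(n_offspring * m, 1L, rep(mother / 2,
                                                 each = n_offspring)),
                 n_offspring, m)
    gf <- matrix(rbinom(n_offspring * m, 1L, rep(father / 2,
                                                 each = n_offspring)),
                 n_offspring, m)
    off <- gm + gf
    rownames(off) <- sprintf("%s_%02d", prefix, seq_len(n_offspring))
    colnames(off) <- names(mother)
    off
  })
}

#' Simulate standard lengths, tank assignment and survival
#'
#' `SL = population mean + family effect + individual noise`; each family's
#' offspring are allocated to the two tanks per `tank_split`; the
#' `family_mortality` family is removed entirely and the rest thinned by
#' `survival_rate`.
#'
#' @param offspring_meta data frame with `sample_id`, `family`, `population`
#'   for every embryo.
#' @param cfg a [sim_config()].
#' @param seed RNG seed.
#' @return a validated `sample_table` of survivors.
#' @export
simulate_phenotypes <- function(offspring_meta, cfg, seed) {
  with_seed(seed, {
    fams <- unique(offspring_meta$family)
    fam_eff <- setNames(rnorm(length(fams), 0, cfg$sl_family_sd), fams)
    df <- offspring_meta
    df$standard_length_mm <- cfg$sl_means[df$population] +
      fam_eff[df$family] +
      rnorm(nrow(df), 0, cfg$sl_residual_sd)
    df$standard_length_mm <- pmax(df$standard_length_mm, 1)
    df$tank <- unlist(lapply(fams, function(f) {
      k <- sum(df$family == f)
      rep(c(1L, 2L), times = c(min(cfg$tank_split[1L], k),
                               max(0L, k - cfg$tank_split[1L])))
    }))
    df$sex <- sample(c("F", "M"), nrow(df), replace = TRUE)
    if (!is.null(cfg$family_mortality))
      df <- df[!(df$family %in% cfg$family_mortality), , drop = FALSE]
    keep <- runif(nrow(df)) < cfg$survival_rate
    df <- df[keep, , drop = FALSE]
    sample_table(df)
  })
}

#' Simulate a random ASV phylogeny
#'
#' Coalescent-style topology with exponentially distributed branch lengths;
#' tips named `asv0001`, `asv0002`, ...
#'
#' @param n_asvs number of tips (at least 2).
#' @param seed RNG seed.
#' @return a rooted `phylo`.
#' @export
simulate_tree <- function(n_asvs, seed = 1L) {
  if (n_asvs < 2L) stop_gs("need at least 2 ASVs")
  with_seed(seed, ape::rcoal(n_asvs,
                             tip.label = sprintf("asv%04d",
                                                 seq_len(n_asvs))))
}

window_marker_ids <- function(cfg, map, w) {
  sub <- map[map$chromosome == w$chromosome, , drop = FALSE]
  sub$marker_id[w$start:w$end]
}

#' Simulate zero-inflated negative binomial ASV counts
#'
#' Per ASV k and fish i the log relative abundance is
#' `mu_ik = beta0_k + pop_k(pop_i) + tank_k(tank_i) + gamma_k SL_i +
#' gxe_k(pop_i, tank_i) + sum_w delta_w s_iw` where `s_iw` is fish i's
#' centered mean dosage across planted window w's markers. Counts are drawn
#' `ZINB(mean = softmax-scaled exp(mu) x library size, dispersion theta_k,
#' zero-inflation pi_k)`, with the per-sample expected total matching the
#' drawn library size.
#'
#' @param meta a `sample_table` of survivors.
#' @param offspring a [genotype_matrix()] aligned with `meta`.
#' @param cfg a [sim_config()].
#' @param seed RNG seed.
#' @return list with `counts` (a [community_matrix()]) and `truth` (class
#'   `sim_truth`: every drawn coefficient, the planted windows and their
#'   affected ASVs, dispersions, zero-inflation and library sizes).
#' @export
simulate_counts <- function(meta, offspring, cfg, seed = NULL) {
  seed <- seed %||% derive_seed(cfg$seed, 5L)
  ids <- meta$sample_id
  stopifnot(all(ids %in% sample_ids(offspring)))
  K <- cfg$n_asvs
  n <- length(ids)
  with_seed(seed, {
    beta0 <- rnorm(K, 0, cfg$zinb$base_log_mean_sd)
    beta0 <- beta0 + log(1e6 / sum(exp(beta0)))
    pops <- c("Bt", "RS", "Hy")
    pop_eff <- matrix(rnorm(3 * K, 0, cfg$effects$population_sd), 3, K,
                      dimnames = list(pops, NULL))
    tank_eff <- rnorm(K, 0, cfg$effects$tank_sd)       # tank 2 vs tank 1
    gamma <- rnorm(K, 0, cfg$effects$sl_slope_sd)      # per mm of SL
    gxe_eff <- matrix(rnorm(3 * K, 0, cfg$effects$gxe_sd), 3, K,
                      dimnames = list(pops, NULL))     # extra pop effect, tank 2
    theta <- cfg$zinb$theta_values %||%
      exp(rnorm(K, cfg$zinb$theta_meanlog, cfg$zinb$theta_sdlog))
    pi_k <- cfg$zinb$pi_values %||% runif(K, 0, cfg$zinb$pi_max)
    L <- exp(rnorm(n, log(cfg$library_size_mean) -
                     cfg$library_size_sdlog^2 / 2, cfg$library_size_sdlog))

    sl_c <- meta$standard_length_mm - mean(meta$standard_length_mm)
    mu <- matrix(beta0, n, K, byrow = TRUE) +
      pop_eff[meta$population, , drop = FALSE] +
      outer(meta$tank == 2L, tank_eff) +
      outer(sl_c, gamma) +
      gxe_eff[meta$population, , drop = FALSE] * (meta$tank == 2L)

    planted <- list()
    for (w in cfg$planted_windows) {
      mk <- window_marker_ids(cfg, offspring$map, w)
      dos <- offspring$dosages[ids, mk, drop = FALSE]
      if (cfg$dominance) dos <- pmin(dos, 1L)
      s <- rowMeans(dos, na.rm = TRUE)
      s <- s - mean(s)
      affected <- sample.int(K, w$n_asvs)
      mu[, affected] <- mu[, affected] + w$delta * s
      planted[[length(planted) + 1L]] <-
        c(w, list(marker_ids = mk, affected_asvs = affected))
    }

    wgt <- sweep(exp(mu), 2L, 1 - pi_k, "*")
    mean_mat <- exp(mu) * (L / rowSums(wgt))
    zero <- matrix(runif(n * K) < rep(pi_k, each = n), n, K)
    counts <- matrix(rnbinom(n * K, size = rep(theta, each = n),
                             mu = as.vector(mean_mat)), n, K)
    counts[zero] <- 0L
    rownames(counts) <- ids
    colnames(counts) <- sprintf("asv%04d", seq_len(K))

    truth <- structure(list(beta0 = beta0, pop_effects = pop_eff,
                            tank_effects = tank_eff, sl_slopes = gamma,
                            gxe_effects = gxe_eff, theta = theta, pi = pi_k,
                            library_sizes = setNames(L, ids),
                            planted = planted, seed = seed),
                       class = "sim_truth")
    list(counts = community_matrix(counts), truth = truth)
  })
}

#' Reference configuration for genome-scan parameter recovery
#'
#' A scaled-down, low-noise configuration used to measure whether the
#' sliding-window scan localizes a known planted effect: 8 chromosomes x 50
#' markers, ~120-130 surviving fish, 300 ASVs, background design effects
#' (population/tank/size/GxE) switched off, mild zero-inflation
#' (pi ~ U(0, 0.1)) and moderate overdispersion (theta ~ logN(log 20, 0.3)),
#' and one planted window of 5 markers on chromosome 3 with log-scale effect
#' `delta` on 150 of the 300 ASVs. With `delta = 0` the scan sees pure count
#' noise and should call no peaks.
#'
#' @param seed master seed.
#' @param delta planted effect size (reference value 3; 0 for the null arm).
#' @return a [sim_config()].
#' @export
sim_config_scan_reference <- function(seed = 1L, delta = 3) {
  sim_config(seed = seed, n_chromosomes = 8L, markers_per_chromosome = 50L,
             n_asvs = 300L, survival_rate = 0.45,
             zinb = list(pi_max = 0.1, theta_meanlog = log(20),
                         theta_sdlog = 0.3),
             effects = list(population_sd = 0, tank_sd = 0, sl_slope_sd = 0,
                            gxe_sd = 0),
             planted_windows = if (delta > 0)
               list(planted_window(3L, 20L, 24L, n_asvs = 150L,
                                   delta = delta))
             else list())
}

#' Simulate a complete common-garden dataset
#'
#' Runs founders -> Mendelian crosses -> phenotypes/survival -> ASV tree ->
#' ZINB counts, returning all containers plus the ground-truth record, and
#' optionally writing the standard-format files (`genotypes.tsv`,
#' `marker_map.tsv`, `counts.tsv`, `meta.tsv`, `tree.nwk`, `truth.yaml`).
#'
#' @param cfg a [sim_config()].
#' @param out_dir optional directory to write files into.
#' @return list with `genotypes`, `counts`, `meta`, `tree`, `truth`,
#'   `parents` and (if written) `files`.
#' @export
simulate_dataset <- function(cfg, out_dir = NULL) {
  par <- simulate_parents(cfg)
  fams <- par$family_table
  off_list <- lapply(seq_len(nrow(fams)), function(i) {
    simulate_cross(par$parents$dosages[fams$mother[i], ],
                   par$parents$dosages[fams$father[i], ],
                   cfg$offspring_per_family,
                   derive_seed(cfg$seed, 10L + i),
                   prefix = fams$family[i])
  })
  off <- do.call(rbind, off_list)
  off_meta <- data.frame(
    sample_id = rownames(off),
    family = rep(fams$family, each = cfg$offspring_per_family),
    population = rep(fams$population, each = cfg$offspring_per_family))
  meta <- simulate_phenotypes(off_meta, cfg, derive_seed(cfg$seed, 3L))
  G <- genotype_matrix(off[meta$sample_id, , drop = FALSE],
                       par$parents$map, n_chromosomes = cfg$n_chromosomes)
  tree <- simulate_tree(cfg$n_asvs, derive_seed(cfg$seed, 4L))
  cn <- simulate_counts(meta, G, cfg)
  out <- list(genotypes = G, counts = cn$counts, meta = meta, tree = tree,
              truth = cn$truth, parents = par)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    fp <- function(x) file.path(out_dir, x)
    gdf <- data.frame(sample_id = rownames(G$dosages), G$dosages,
                      check.names = FALSE)
    write_table(gdf, fp("genotypes.tsv"))
    write_table(G$map, fp("marker_map.tsv"))
    cdf <- data.frame(sample_id = rownames(cn$counts$counts),
                      cn$counts$counts, check.names = FALSE)
    write_table(cdf, fp("counts.tsv"))
    write_table(as.data.frame(meta), fp("meta.tsv"))
    ape::write.tree(tree, fp("tree.nwk"))
    truth_list <- cn$truth
    truth_list$pop_effects <- as.data.frame(truth_list$pop_effects)
    truth_list$gxe_effects <- as.data.frame(truth_list$gxe_effects)
    yaml::write_yaml(lapply(unclass(truth_list), function(x)
      if (is.numeric(x)) unname(x) else x), fp("truth.yaml"),
      precision = 15L)
    out$files <- vapply(c("genotypes.tsv", "marker_map.tsv", "counts.tsv",
                          "meta.tsv", "tree.nwk", "truth.yaml"), fp, "")
  }
  out
}
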