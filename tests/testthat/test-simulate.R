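test_that("population differentiation scales with the divergence knob", {
  base <- function(diff, seed = 60) {
    cfg <- sim_config(seed = seed, n_chromosomes = 10L,
                      markers_per_chromosome = 200L,
                      differentiation = diff)
    par <- simulate_parents(cfg)
    mean(abs(par$freqs$p_bt - par$freqs$p_rs))
  }
  gaps <- vapply(c(0, 0.25, 0.5, 1), base, 1)
  expect_identical(gaps[1L], 0)
  expect_true(all(diff(gaps) > 0))
})

test_that("parent simulation is seed-stable and respects the MAF floor", {
  cfg <- sim_config(seed = 42, n_chromosomes = 2L,
                    markers_per_chromosome = 30L)
  p1 <- simulate_parents(cfg)
  p2 <- simulate_parents(cfg)
  expect_identical(p1$parents$dosages, p2$parents$dosages)
  expect_true(all(p1$freqs$p0 >= 0.05 & p1$freqs$p0 <= 0.95))
  expect_identical(nrow(p1$family_table), 8L)
  expect_identical(p1$family_table$population,
                   rep(c("Bt", "RS", "Hy"), times = c(3L, 3L, 2L)))
})

test_that("Mendelian crosses transmit one allele per parent", {
  m <- setNames(rep(2L, 50), sprintf("m%02d", 1:50))   # AA
  f <- setNames(rep(0L, 50), sprintf("m%02d", 1:50))   # aa
  off <- simulate_cross(m, f, 20L, seed = 1)
  expect_true(all(off == 1L))
  # Aa x Aa segregates 1:2:1
  het <- setNames(rep(1L, 40), sprintf("m%02d", 1:40))
  off2 <- simulate_cross(het, het, 100L, seed = 2)
  tab <- table(factor(off2, levels = 0:2))
  expect_gt(stats::chisq.test(tab, p = c(0.25, 0.5, 0.25))$p.value, 0.01)
})

test_that("offspring resemble their parents more than the other population", {
  cfg <- sim_config(seed = 8, n_chromosomes = 4L,
                    markers_per_chromosome = 60L, differentiation = 0.3)
  par <- simulate_parents(cfg)
  fam <- par$family_table
  bt <- fam[fam$population == "Bt", ][1L, ]
  rs <- fam[fam$population == "RS", ][1L, ]
  off <- simulate_cross(par$parents$dosages[bt$mother, ],
                        par$parents$dosages[bt$father, ], 10L, seed = 3,
                        prefix = "btoff")
  all_dos <- rbind(off, par$parents$dosages[c(bt$mother, rs$mother), ])
  D <- genetic_dissimilarity(genotype_matrix(all_dos, par$parents$map,
                                             cfg$n_chromosomes))
  d_parent <- mean(D[rownames(off), bt$mother])
  d_other <- mean(D[rownames(off), rs$mother])
  expect_lt(d_parent, d_other)
})

test_that("phenotypes recover configured SL structure", {
  cfg0 <- sim_config(seed = 4, sl_family_sd = 0, sl_residual_sd = 0,
                     survival_rate = 1, family_mortality = NULL)
  om <- data.frame(sample_id = sprintf("Bt1_%02d", 1:40),
                   family = "Bt1", population = "Bt")
  ph <- simulate_phenotypes(om, cfg0, seed = 1)
  expect_true(all(ph$standard_length_mm == 17.368))
  expect_identical(as.integer(table(ph$tank)), c(20L, 20L))
  # default config: population means recovered within 3 standard errors
  d <- simulate_dataset(sim_config(seed = 10))
  for (pop in c("Bt", "RS", "Hy")) {
    sl <- d$meta$standard_length_mm[d$meta$population == pop]
    se <- sd(sl) / sqrt(length(sl))
    expect_lt(abs(mean(sl) - sim_config()$sl_means[[pop]]), 3 * se)
  }
})

test_that("whole-family mortality removes exactly that family", {
  d <- simulate_dataset(sim_config(seed = 11))
  expect_false("Bt1" %in% d$meta$family)
  expect_identical(length(unique(d$meta$family)), 7L)
})

test_that("simulated trees have the requested tips and are seed-stable", {
  t2 <- simulate_tree(2L, seed = 1)
  expect_identical(ape::Ntip(t2), 2L)
  t40a <- simulate_tree(40L, seed = 9)
  t40b <- simulate_tree(40L, seed = 9)
  expect_identical(ape::write.tree(t40a), ape::write.tree(t40b))
  expect_identical(ape::Ntip(t40a), 40L)
  expect_true(ape::is.rooted(t40a))
  expect_error(simulate_tree(1L), "at least 2")
})

test_that("zero-inflation and null-effect behavior of the count model", {
  cfg <- sim_config(seed = 13, n_chromosomes = 2L,
                    markers_per_chromosome = 10L, n_asvs = 20L,
                    survival_rate = 0.3,
                    zinb = list(pi_values = c(1, rep(0, 19L))),
                    effects = list(population_sd = 0, tank_sd = 0,
                                   sl_slope_sd = 0, gxe_sd = 0))
  d <- simulate_dataset(cfg)
  expect_true(all(d$counts$counts[, 1L] == 0L))
  # with all effects off, per-population mean library composition is flat:
  # compare mean log1p counts of an abundant ASV between populations
  k <- which.max(colSums(d$counts$counts))
  y <- log1p(d$counts$counts[, k])
  pops <- d$meta$population[match(rownames(d$counts$counts),
                                  d$meta$sample_id)]
  fit <- stats::aov(y ~ pops)
  expect_gt(summary(fit)[[1L]][["Pr(>F)"]][1L], 0.001)
})

test_that("planted windows must lie on the marker map", {
  expect_error(sim_config(planted_windows = list(
    planted_window(25L, 1L, 5L))), "off the marker map")
  expect_error(sim_config(n_chromosomes = 4L, markers_per_chromosome = 10L,
                          planted_windows = list(
                            planted_window(2L, 8L, 12L))),
               "off the marker map")
})

test_that("the default design reproduces the study shape", {
  d <- simulate_dataset(sim_config(seed = 17))
  expect_identical(length(unique(d$meta$family)), 7L)
  expect_identical(sort(unique(d$meta$tank)), c(1L, 2L))
  expect_gte(nrow(d$meta), 120L)
  expect_lte(nrow(d$meta), 160L)
  expect_identical(ncol(d$genotypes$dosages), 21L * 115L)
  expect_identical(ncol(d$counts$counts), 300L)
  # library sizes near the configured mean
  expect_lt(abs(mean(d$counts$totals) - 238706.4) /
              238706.4, 0.25)
  # the zero-fraction spectrum spans the 5%-80% window used for
  # model-selection in differential-abundance work
  zf <- colMeans(d$counts$counts == 0L)
  expect_gt(sum(zf >= 0.05 & zf <= 0.8), 50L)
})

test_that("dataset writing is byte-identical under one seed", {
  cfg <- sim_config(seed = 19, n_chromosomes = 2L,
                    markers_per_chromosome = 8L, n_asvs = 12L,
                    survival_rate = 0.2)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulate_dataset(cfg, out_dir = d1)
  simulate_dataset(cfg, out_dir = d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  # truth coefficients round-trip through the yaml file
  tr <- yaml::read_yaml(file.path(d1, "truth.yaml"))
  d <- simulate_dataset(cfg)
  expect_equal(unlist(tr$beta0), unname(d$truth$beta0), tolerance = 1e-9)
  expect_equal(unlist(tr$theta), unname(d$truth$theta), tolerance = 1e-9)
})

test_that("every emitted file reads back into a validated container", {
  cfg <- sim_config(seed = 23, n_chromosomes = 2L,
                    markers_per_chromosome = 8L, n_asvs = 12L,
                    survival_rate = 0.25)
  out <- withr::local_tempdir()
  d <- simulate_dataset(cfg, out_dir = out)
  G <- read_genotypes(file.path(out, "genotypes.tsv"), "tsv",
                      file.path(out, "marker_map.tsv"),
                      n_chromosomes = 2L)
  expect_identical(G$dosages, d$genotypes$dosages)
  cm <- read_counts(file.path(out, "counts.tsv"))
  expect_identical(cm$counts, d$counts$counts)
  meta <- read_metadata(file.path(out, "meta.tsv"))
  expect_identical(meta$sample_id, d$meta$sample_id)
  tr <- read_tree(file.path(out, "tree.nwk"))
  expect_identical(sort(tr$tip.label), sort(d$tree$tip.label))
})

test_that("the heritability knob moves genome-wide association as designed", {
  # planted effect on 5 of 40 markers, no design effects: genome-wide
  # size-controlled association is positive; with no planted effect it is
  # centered on zero
  base_cfg <- function(s, delta) {
    sim_config(seed = s, n_chromosomes = 2L, markers_per_chromosome = 20L,
               n_asvs = 200L, survival_rate = 0.45,
               zinb = list(pi_max = 0.1, theta_meanlog = log(20),
                           theta_sdlog = 0.3),
               effects = list(population_sd = 0, tank_sd = 0,
                              sl_slope_sd = 0, gxe_sd = 0),
               planted_windows = if (delta > 0)
                 list(planted_window(1L, 8L, 12L, n_asvs = 100L,
                                     delta = delta)) else list())
  }
  gw_r <- function(cfg) {
    d <- simulate_dataset(cfg)
    Dbc <- bray_curtis(cpm_log_normalize(d$counts))
    partial_mantel(genetic_dissimilarity(d$genotypes), Dbc,
                   size_dissimilarity(d$meta), n_perm = 9, seed = 1)$r
  }
  with_effect <- vapply(1:10, function(s) gw_r(base_cfg(80 + s, 3)), 1)
  expect_gte(sum(with_effect > 0), 9L)
  null_r <- vapply(1:10, function(s) gw_r(base_cfg(80 + s, 0)), 1)
  expect_lt(abs(mean(null_r)), 0.05)
})

test_that("population-by-tank interactions are detectable at the reference
           effect size", {
  # gxe_sd = 0.4 is the documented power-reference value for the
  # interaction test (the study-shaped default is 0.2)
  p <- vapply(1:10, function(s) {
    d <- simulate_dataset(sim_config(seed = 960 + s, n_asvs = 150L,
                                     effects = list(gxe_sd = 0.4)))
    Dbc <- bray_curtis(cpm_log_normalize(d$counts))
    tab <- permanova(Dbc, d$meta,
                     ~ population + tank + standard_length_mm +
                       population:tank, n_perm = 99, seed = s)
    tab$p_value[4L]
  }, 1)
  expect_gte(mean(p <= 0.05), 0.8)
})
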