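test_that("the generator is fully determined by its seed", {
  cfg <- sim_config(n_genes = 60, n_metabolites = 20, n_modules = 3,
                    replicates = 3, seed = 11)
  a <- simulate_counts(cfg)
  b <- simulate_counts(cfg)
  expect_identical(unclass(a$counts), unclass(b$counts))
  ma <- simulate_metabolites(cfg, a$truth)
  mb <- simulate_metabolites(cfg, b$truth)
  expect_identical(unclass(ma$metabolites), unclass(mb$metabolites))
  expect_identical(simulate_phenotypes(cfg, a$truth),
                   simulate_phenotypes(cfg, b$truth))
  # a different seed changes the data
  cfg2 <- sim_config(n_genes = 60, n_metabolites = 20, n_modules = 3,
                     replicates = 3, seed = 12)
  expect_false(identical(unclass(simulate_counts(cfg2)$counts),
                         unclass(a$counts)))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_genes = 10, gene_module_fraction = 1.5),
               "module sizes")
  expect_error(sim_config(n_modules = 2, module_trajectories =
                            list(c(0, 1, 1, 1, 1))),
               "one trajectory per module")
  expect_error(sim_config(module_trajectories = rep(list(c(1, 1, 1, 1, 1)),
                                                    5)),
               "reference-group")
  expect_error(sim_config(phenotype_couplings = list(
    list(name = "x", module = 9, sign = 1, noise_sd = 0))),
    "unknown module")
})

test_that("module assignment partitions the planted fraction exactly once", {
  cfg <- sim_config(n_genes = 103, n_metabolites = 31, n_modules = 4,
                    gene_module_fraction = 0.5,
                    metabolite_module_fraction = 0.6,
                    module_trajectories = default_trajectories(4),
                    seed = 3)
  truth <- sim_ground_truth(cfg)
  expect_length(truth$gene_modules, 103)
  expect_equal(sum(truth$gene_modules > 0), floor(103 * 0.5))
  expect_equal(sum(truth$metabolite_modules > 0), floor(31 * 0.6))
  expect_false(anyDuplicated(names(truth$gene_modules)) > 0)
})

test_that("planted group means follow exp(loading x trajectory)", {
  # near-Poisson counts, flat library sizes, many replicates: the empirical
  # group-mean log2 ratio vs control converges to loading * effect / ln 2
  cfg <- sim_config(n_genes = 40, n_metabolites = 5, n_modules = 1,
                    groups = c("control", "treated"), replicates = 400,
                    module_trajectories = list(c(0, 2)),
                    gene_module_fraction = 0.5,
                    nb_dispersion = 1e-4, baseline_logmean = 6,
                    baseline_logmean_sd = 0.2,
                    library_size_range = c(1, 1),
                    phenotype_couplings = list(), seed = 5)
  sim <- simulate_counts(cfg)
  cnt <- unclass(sim$counts)
  trt <- sim$design$sample[sim$design$group == "treated"]
  ctl <- sim$design$sample[sim$design$group == "control"]
  ratio <- log2(rowMeans(cnt[, trt]) / rowMeans(cnt[, ctl]))
  planted <- sim$truth$gene_modules > 0
  expect_equal(ratio[planted],
               2 * sim$truth$loadings[planted] / log(2),
               tolerance = 0.02, ignore_attr = TRUE)
  expect_equal(unname(ratio[!planted]), rep(0, sum(!planted)),
               tolerance = 0.05)
})

test_that("under the all-null configuration no signal is planted", {
  cfg <- sim_config(n_genes = 500, n_metabolites = 10, n_modules = 0,
                    gene_module_fraction = 0,
                    metabolite_module_fraction = 0,
                    phenotype_couplings = list(), seed = 21)
  sim <- simulate_counts(cfg)
  de <- de_test(sim$counts, sim$design, "d14")
  expect_lt(mean(de$pvalue < 0.05), 0.05 + 2 * sqrt(0.05 * 0.95 / 500))
  expect_equal(mean(de$padj < 0.05), 0)
})

test_that("metabolite missingness is abundance-dependent and quantifiable", {
  cfg0 <- sim_config(n_genes = 20, n_metabolites = 100, n_modules = 2,
                     missing_threshold_quantile = 0, seed = 9)
  m0 <- simulate_metabolites(cfg0)
  expect_false(anyNA(unclass(m0$metabolites)))

  # certain censoring below the median removes ~half the entries
  cfg1 <- sim_config(n_genes = 20, n_metabolites = 100, n_modules = 2,
                     missing_threshold_quantile = 0.5, missing_prob = 1,
                     seed = 9)
  m1 <- simulate_metabolites(cfg1)
  frac <- mean(is.na(unclass(m1$metabolites)))
  expect_equal(frac, 0.5, tolerance = 0.02)
  # the censored entries are exactly the low-abundance ones
  expect_true(max(unclass(m1$complete)[is.na(unclass(m1$metabolites))]) <=
                min(unclass(m1$complete)[!is.na(unclass(m1$metabolites))]))
})

test_that("noise-free metabolites are constant within groups", {
  cfg <- sim_config(n_genes = 20, n_metabolites = 10, n_modules = 2,
                    metabolite_noise_sd = 0, missing_threshold_quantile = 0,
                    seed = 2)
  m <- simulate_metabolites(cfg)
  d <- sim_design(cfg)
  vals <- unclass(m$metabolites)
  for (g in cfg$groups) {
    sub <- vals[, d$sample[d$group == g], drop = FALSE]
    expect_true(all(apply(sub, 1, function(r) diff(range(r)) == 0)))
  }
})

test_that("phenotypes track their module trajectory exactly at zero noise", {
  cfg <- sim_config(n_genes = 20, n_metabolites = 5, n_modules = 2,
                    replicates = 3,
                    phenotype_couplings = list(
                      list(name = "pos", module = 1, sign = 1,
                           noise_sd = 0),
                      list(name = "neg", module = 1, sign = -1,
                           noise_sd = 0)),
                    seed = 4)
  truth <- sim_ground_truth(cfg)
  ph <- simulate_phenotypes(cfg, truth)
  d <- sim_design(cfg)
  expected <- truth$trajectories[1, match(d$group, cfg$groups)]
  expect_equal(unname(unclass(ph)["pos", ]), unname(expected))
  expect_equal(unclass(ph)["neg", ], -unclass(ph)["pos", ],
               ignore_attr = TRUE)
  # rank correlation with a noiseless module profile is perfect
  gene_means <- expected  # same group profile as a zero-noise module gene
  expect_equal(abs(cor(unclass(ph)["pos", ], gene_means,
                       method = "spearman")), 1)
})

test_that("cohort tables realise the requested sign concordance", {
  feats <- sprintf("g%04d", 1:1200)
  mouse <- toy_diff(feats, lfc = rep(c(2, -2), 600),
                    padj = rep(0.01, 1200))
  map <- simulate_ortholog_map(feats)
  expect_error(simulate_cohort_tables(mouse, map[0, ], 0.5), "empty")

  for (cf in c(0, 1)) {
    co <- simulate_cohort_tables(mouse, map, cf, seed = 8)
    tr <- same_trend_fraction(mouse, co$cohort_a, map)
    expect_equal(tr$pct, 100 * cf)
  }
  co <- simulate_cohort_tables(mouse, map, 0.75, seed = 8)
  tr <- same_trend_fraction(mouse, co$cohort_a, map)
  expect_equal(tr$pct / 100, 0.75,
               tolerance = 3 * sqrt(0.75 * 0.25 / 1200) / 0.75)
})
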