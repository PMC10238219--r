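test_that("size factors follow the median-of-ratios convention", {
  m <- matrix(c(10, 20, 30, 10, 20, 30), ncol = 2,
              dimnames = list(paste0("g", 1:3), c("s1", "s2")))
  expect_equal(size_factors(m), c(s1 = 1, s2 = 1))

  m2 <- m
  m2[, 2] <- 2 * m2[, 1]
  expect_equal(size_factors(m2), c(s1 = 1 / sqrt(2), s2 = sqrt(2)))

  # all-zero gene rows do not enter the median
  m3 <- rbind(m2, g4 = c(0, 0))
  expect_equal(size_factors(m3), size_factors(m2))

  m4 <- matrix(c(0, 1, 1, 0), 2, dimnames = list(c("a", "b"),
                                                 c("s1", "s2")))
  expect_error(size_factors(m4), "no gene")
})

test_that("the Welch statistic matches its closed form", {
  w <- fibronet:::welch_rows(matrix(c(4, 5, 6), 1),
                             matrix(c(1, 2, 3), 1))
  expect_equal(w$t, -3.674, tolerance = 1e-3)
  expect_equal(w$df, 4)
  # zero-variance conventions
  z <- fibronet:::welch_rows(matrix(c(1, 1), 1), matrix(c(1, 1), 1))
  expect_equal(z$p, 1)
  z2 <- fibronet:::welch_rows(matrix(c(1, 1), 1), matrix(c(2, 2), 1))
  expect_equal(z2$p, 0)
})

test_that("de_test reports effects on the log2(normalised + 1) scale", {
  cnt <- matrix(c(rep(10, 3), rep(40, 3)), nrow = 1,
                dimnames = list("gA", paste0("s", 1:6)))
  cnt <- rbind(gA = cnt[1, ], gB = c(5, 6, 7, 5, 6, 7))
  d <- study_design(paste0("s", 1:6), rep(c("ctl", "trt"), each = 3),
                    reference = "ctl")
  res <- de_test(omics_matrix(cnt, "counts"), d, "trt",
                 sf = setNames(rep(1, 6), colnames(cnt)))
  expect_equal(res$log2fc[res$feature == "gA"], log2(41) - log2(11))
  expect_equal(res$log2fc[res$feature == "gB"], 0)
  expect_equal(res$pvalue[res$feature == "gB"], 1)
  expect_error(de_test(omics_matrix(cnt, "counts"), d, "nope"),
               "absent from design")
})

test_that("de_test is invariant to sample column order", {
  fx <- sim_fixture()
  a <- de_test(fx$counts, fx$design, "d14")
  shuffled <- fx$counts[, rev(colnames(fx$counts))]
  b <- de_test(omics_matrix(unclass(shuffled), "counts"), fx$design, "d14")
  expect_equal(a, b)
})

test_that("BH adjustment equals the brute-force step-up rule", {
  expect_equal(bh_adjust(0.04), 0.04)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(0.5, -0.1)), "\\[0, 1\\]")
  set.seed(42)
  for (i in 1:25) {
    p <- runif(sample(1:60, 1))^sample(1:3, 1)
    expect_equal(bh_adjust(p), bh_stepup_oracle(p))
  }
})

test_that("consistent DEG sets demand direction at every time point", {
  tabs <- list(
    toy_diff(c("up", "part", "mixed", "dn"), c(1, 1, 1, -1),
             c(0.01, 0.01, 0.01, 0.01)),
    toy_diff(c("up", "part", "mixed", "dn"), c(1, 1, 1, -1),
             c(0.01, 0.2, 0.01, 0.01)),
    toy_diff(c("up", "part", "mixed", "dn"), c(1, 1, -1, -1),
             c(0.01, 0.01, 0.01, 0.01)),
    toy_diff(c("up", "part", "mixed", "dn"), c(1, 1, -1, -1),
             c(0.01, 0.01, 0.01, 0.01)))
  sets <- consistent_deg_sets(tabs)
  expect_equal(sets$deg0, "up")
  expect_equal(sets$deg1, "dn")
  expect_error(consistent_deg_sets(tabs[1]), "two time points")
  # a gene absent from one table is excluded with a warning
  tabs2 <- tabs
  tabs2[[2]] <- tabs2[[2]][-1, ]
  expect_warning(sets2 <- consistent_deg_sets(tabs2), "excluded")
  expect_length(sets2$deg0, 0)
})

test_that("recurrent DM sets use the at-least-two rule with no conflicts", {
  tabs <- list(
    toy_diff(c("m1", "m2", "m3"), c(1, 1, 1), c(0.01, 0.01, 0.01)),
    toy_diff(c("m1", "m2", "m3"), c(1, 1, -1), c(0.01, 0.2, 0.01)),
    toy_diff(c("m1", "m2", "m3"), c(-1, 1, 1), c(0.2, 0.2, 0.01)))
  sets <- recurrent_dm_sets(tabs)
  expect_equal(sets$dm0, "m1")          # up at 2 time points, never down
  expect_length(sets$dm1, 0)
  # m2: up at only 1 -> excluded; m3: up at 2 but down at 1 -> conflict
  expect_false("m2" %in% sets$dm0)
  expect_false("m3" %in% sets$dm0)
})

test_that("trajectories are group medians of per-feature z-scores", {
  d <- toy_design(2, c("g1", "g2", "g3"))
  m <- rbind(flat = rep(5, 6),
             rising = c(1, 1, 2, 2, 3, 3),
             other = c(2, 4, 1, 3, 6, 8))
  colnames(m) <- d$sample
  expect_warning(tr <- trajectories(m, d), "zero-variance")
  expect_equal(unname(tr["flat", ]), c(0, 0, 0))
  expect_true(all(diff(tr["rising", ]) > 0))
  # set trajectory = median over member features, checked by brute force
  tr2 <- suppressWarnings(
    trajectories(m, d, feature_sets = list(all = rownames(m))))
  manual <- apply(suppressWarnings(trajectories(m, d)), 2, median)
  expect_equal(unname(tr2["all", ]), unname(manual))
})

test_that("PCA view filters by TPM and explains variance coherently", {
  d <- toy_design(2, c("a", "b"))
  set.seed(1)
  tpm <- matrix(rexp(40, 0.1), nrow = 10,
                dimnames = list(paste0("g", 1:10), d$sample))
  tpm[1, ] <- 0.1  # filtered out at tpm_min = 5
  pv <- pca_view(omics_matrix(tpm, "TPM"), d)
  expect_lte(sum(pv$explained), 1)
  expect_lt(pv$n_genes, 10)

  # duplicated samples land on identical coordinates
  tpm2 <- tpm
  tpm2[, 2] <- tpm2[, 1]
  pv2 <- pca_view(omics_matrix(tpm2, "TPM"), d)
  expect_equal(pv2$coords[1, ], pv2$coords[2, ])

  # an input of rank 1 on the log2(TPM+1) scale concentrates all variance
  # on component 1
  a <- seq(1, 3, length.out = 10)
  b <- 0:3
  r1 <- 2^outer(a, b, "+") - 1
  dimnames(r1) <- dimnames(tpm)
  pv3 <- pca_view(omics_matrix(r1, "TPM"), d, tpm_min = 0)
  expect_gt(pv3$explained[1], 0.99)
  expect_error(pca_view(omics_matrix(tpm * 0, "TPM"), d), "fewer than 2")
})
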