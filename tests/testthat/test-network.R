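make_pairs <- function(mat, kinds = NULL) spearman_all_pairs(mat, kinds)

test_that("Spearman rho and its rank+Pearson oracle agree to 1e-12", {
  x <- c(1, 2, 3, 5); y <- c(2, 1, 4, 3)
  m <- rbind(x = x, y = y, z = rev(x))
  colnames(m) <- paste0("s", 1:4)
  pr <- make_pairs(m)
  expect_equal(pr$rho[pr$a == "x" & pr$b == "y"], 0.6)
  expect_equal(pr$rho[pr$a == "x" & pr$b == "z"], -1)
  expect_equal(pr$p[pr$a == "x" & pr$b == "z"], 0)

  set.seed(99)
  for (i in 1:100) {
    n <- sample(5:12, 1)
    a <- sample(1:5, n, replace = TRUE) + runif(n) * (i %% 2) # ties if even
    b <- rnorm(n)
    m <- rbind(a = a, b = b)
    colnames(m) <- paste0("s", 1:n)
    pr <- make_pairs(m)
    expect_equal(pr$rho, spearman_oracle(a, b), tolerance = 1e-12)
  }
})

test_that("degenerate correlation inputs are handled explicitly", {
  m <- rbind(a = c(1, 2, 3, 4), b = c(4, 3, 2, 1), flat = rep(1, 4))
  colnames(m) <- paste0("s", 1:4)
  expect_warning(pr <- make_pairs(m), "zero-variance")
  expect_false("flat" %in% c(pr$a, pr$b))
  expect_error(spearman_all_pairs(m[, 1:3]), "4 samples")
  m[1, 1] <- NA
  expect_error(spearman_all_pairs(m), "complete")
})

test_that("GCN keeps ceil(top_fraction x m) significant positive pairs", {
  pairs <- data.frame(
    a = paste0("g", 1:10), b = paste0("h", 1:10),
    rho = c(seq(0.95, 0.6, length.out = 8), -0.9, 0.9),
    p = c(rep(1e-6, 8), 1e-6, 0.9), stringsAsFactors = FALSE)
  net <- build_gcn(pairs, fdr = 0.05, top_fraction = 0.25)
  # 8 significant positive pairs -> ceil(0.25 * 8) = 2 kept, highest rho
  expect_equal(nrow(net$edges), 2)
  expect_equal(net$edges$rho, c(0.95, 0.9), tolerance = 1e-9)

  neg <- pairs; neg$rho <- -abs(neg$rho)
  expect_warning(net0 <- build_gcn(neg), "no edges")
  expect_equal(nrow(net0$edges), 0)

  # the exact counting rule holds on randomised inputs
  set.seed(7)
  for (i in 1:20) {
    k <- sample(10:200, 1)
    pr <- data.frame(a = sprintf("a%03d", 1:k), b = sprintf("b%03d", 1:k),
                     rho = runif(k, -1, 1), p = runif(k)^3,
                     stringsAsFactors = FALSE)
    padj <- bh_adjust(pr$p)
    m <- sum(padj <= 0.05 & pr$rho > 0)
    net <- suppressWarnings(build_gcn(pr))
    expect_equal(nrow(net$edges), if (m) ceiling(0.25 * m) else 0)
  }
})

test_that("rho ties at the GCN cutoff break deterministically", {
  pairs <- data.frame(a = c("a", "a", "b", "c"),
                      b = c("b", "c", "c", "d"),
                      rho = c(0.9, 0.8, 0.8, 0.8),
                      p = rep(1e-6, 4), stringsAsFactors = FALSE)
  net1 <- build_gcn(pairs, top_fraction = 0.5)    # keeps 2 of 4
  net2 <- build_gcn(pairs[sample(4), ], top_fraction = 0.5)
  expect_equal(net1$edges[order(net1$edges$from, net1$edges$to), ],
               net2$edges[order(net2$edges$from, net2$edges$to), ],
               ignore_attr = TRUE)
  # lexicographically smallest tied pair wins
  expect_setequal(paste(net1$edges$from, net1$edges$to),
                  c("a b", "a c"))
})

test_that("MCN keeps both correlation signs at the FDR filter", {
  pairs <- data.frame(a = c("m1", "m2"), b = c("m2", "m3"),
                      rho = c(-0.95, 0.9), p = c(1e-6, 1e-6),
                      stringsAsFactors = FALSE)
  mcn <- build_mcn(pairs)
  expect_equal(nrow(mcn$edges), 2)   # the negative pair is retained
  gcn <- build_gcn(pairs, top_fraction = 1)
  expect_false(any(gcn$edges$rho < 0))

  # edge count equals the brute-force significant-pair count
  set.seed(3)
  pr <- data.frame(a = sprintf("x%03d", 1:150), b = sprintf("y%03d", 1:150),
                   rho = runif(150, -1, 1), p = runif(150)^2,
                   stringsAsFactors = FALSE)
  expect_equal(nrow(build_mcn(pr)$edges), sum(bh_adjust(pr$p) <= 0.05))
})

test_that("phenotype rows join the correlation pass with their own rules", {
  d <- toy_design(3, c("g1", "g2", "g3", "g4"))
  set.seed(5)
  m <- matrix(rnorm(48), 4, 12, dimnames = list(paste0("g", 1:4), d$sample))
  ph <- rbind(mirror = m[1, ], anti = -m[2, ])
  expect_error(attach_phenotypes(m, ph[, 1:6, drop = FALSE]),
               "do not match")
  aug <- attach_phenotypes(m, ph, base_kind = "gene")
  pr <- spearman_all_pairs(aug)
  net <- build_gcn(pr)
  k <- setNames(net$nodes$kind, net$nodes$node)
  expect_equal(unname(k[c("mirror", "anti")]), rep("phenotype", 2))
  e <- net$edges
  expect_equal(e$rho[(e$from == "g1" & e$to == "mirror") |
                       (e$from == "mirror" & e$to == "g1")], 1)
  # the perfectly anti-correlated phenotype keeps its negative edge
  expect_equal(e$rho[(e$from == "g2" & e$to == "anti") |
                       (e$from == "anti" & e$to == "g2")], -1)
})

test_that("pure-noise phenotypes gain no edges beyond the type-I rate", {
  d <- toy_design(5, c("a", "b", "c", "d", "e"))
  set.seed(17)
  m <- matrix(rnorm(30 * 25), 30, 25,
              dimnames = list(sprintf("g%02d", 1:30), d$sample))
  ph <- matrix(rnorm(25), 1, 25, dimnames = list("noise", d$sample))
  net <- suppressWarnings(
    build_gcn(spearman_all_pairs(attach_phenotypes(m, ph,
                                                   base_kind = "gene"))))
  e <- net$edges
  expect_equal(sum(e$from == "noise" | e$to == "noise"), 0)
})

test_that("Leiden partitions are size-labelled and deterministic", {
  tri2 <- toy_network(c("a", "b", "c", "x", "y", "z", "p"),
                      c("b", "c", "a", "y", "z", "x", "q"))
  part <- leiden_partition(tri2, seed = 0)
  expect_equal(sort(unique(part$label)), 0:2)
  sizes <- attr(part, "sizes")
  expect_true(all(diff(sizes) <= 0))
  # disconnected triangles never merge
  lab <- setNames(part$label, part$node)
  expect_length(unique(lab[c("a", "b", "c")]), 1)
  expect_length(unique(lab[c("x", "y", "z")]), 1)
  expect_false(lab[["a"]] == lab[["x"]])

  # planted cliques in a ring are recovered, identically across runs
  cl <- function(i) sprintf("c%d_%d", i, 1:5)
  from <- to <- character(0)
  for (i in 1:4) {
    v <- cl(i)
    cmb <- combn(v, 2)
    from <- c(from, cmb[1, ]); to <- c(to, cmb[2, ])
  }
  for (i in 1:4) {  # single bridges between consecutive cliques
    from <- c(from, cl(i)[1]); to <- c(to, cl(i %% 4 + 1)[2])
  }
  ring <- toy_network(from, to)
  p1 <- leiden_partition(ring, seed = 1)
  p2 <- leiden_partition(ring, seed = 1)
  expect_identical(p1, p2)
  lab <- setNames(p1$label, p1$node)
  for (i in 1:4) expect_length(unique(lab[cl(i)]), 1)
  expect_length(unique(vapply(1:4, function(i) lab[[cl(i)[1]]], 0L)), 4)
})

test_that("clustering coefficients match triangle enumeration", {
  tri <- toy_network(c("a", "b", "c"), c("b", "c", "a"))
  expect_equal(unname(local_cc(tri, c("a", "b", "c"))), rep(1, 3))
  star <- toy_network(rep("hub", 3), c("l1", "l2", "l3"))
  expect_equal(unname(local_cc(star, c("hub", "l1"))), c(0, 0))
  expect_error(local_cc(star, "nope"), "unknown node")
  # 4-cycle plus one diagonal: per-node 2/3, 1, 2/3, 1 -> mean 5/6
  g <- toy_network(c("A", "B", "C", "D", "A"),
                   c("B", "C", "D", "A", "C"))
  cc <- local_cc(g, c("A", "B", "C", "D"))
  expect_equal(unname(cc), c(2 / 3, 1, 2 / 3, 1))
  part <- data.frame(node = c("A", "B", "C", "D"), label = 0L)
  expect_equal(unname(subnetwork_avg_cc(g, part)), 5 / 6)
})

test_that("phenotype centrality counts only omics neighbours", {
  kinds <- c(p1 = "phenotype", p2 = "phenotype", g1 = "gene", g2 = "gene",
             g3 = "gene", m1 = "metabolite")
  net <- toy_network(c("p1", "p1", "p1", "p1", "p2"),
                     c("g1", "g2", "g3", "p2", "p1"),
                     kinds = kinds)
  net$edges <- net$edges[!duplicated(paste(pmin(net$edges$from,
                                                net$edges$to),
                                           pmax(net$edges$from,
                                                net$edges$to))), ]
  cent <- phenotype_centrality(net)
  expect_equal(cent[["p1"]], 3)   # the phenotype-phenotype edge is excluded
  expect_equal(cent[["p2"]], 0)
  gonly <- toy_network("g1", "g2")
  expect_warning(out <- phenotype_centrality(gonly), "no phenotype")
  expect_length(out, 0)
})

test_that("top correlates rank by absolute rho with stable ties", {
  kinds <- c(p = "phenotype", a = "gene", b = "gene", c = "gene")
  net <- toy_network(rep("p", 3), c("a", "b", "c"),
                     rho = c(0.9, -0.95, 0.9), kinds = kinds)
  tc <- top_correlates(net, "p", k = 10)
  expect_equal(tc$node, c("b", "a", "c"))   # |−0.95| first, ties lexicographic
  expect_equal(tc$rho[1], -0.95)
  expect_equal(nrow(top_correlates(net, "p", k = 2)), 2)
  expect_error(top_correlates(net, "p", k = 0), "positive")
  expect_error(top_correlates(net, "zz"), "not in network")
})

test_that("composition statistics report rounded percentage shares", {
  single <- data.frame(node = letters[1:4], label = 0L)
  cs <- composition_stats(single)
  expect_equal(cs$table$pct, 100)
  # union shares from explicit size vectors
  cs2 <- composition_stats(c(4177, 3524, 3019, 2206, 765),
                           union = c(1, 2))
  expect_equal(cs2$union$size, 6543)
  expect_gte(cs2$union$pct, 47.79)
  expect_lte(cs2$union$pct, 47.80)
  expect_error(composition_stats(c(10, 5), union = 7), "not in partition")
})

test_that("partition labels are invariant to node permutation", {
  set.seed(12)
  base <- igraph::sample_gnp(40, 0.2)
  el <- igraph::as_edgelist(base)
  ids <- sprintf("n%02d", 1:40)
  net1 <- toy_network(ids[el[, 1]], ids[el[, 2]])
  perm <- sample(40)
  net2 <- toy_network(ids[perm[el[, 1]]], ids[perm[el[, 2]]])
  p1 <- leiden_partition(net1, seed = 4)
  p2 <- leiden_partition(net2, seed = 4)
  lab1 <- setNames(p1$label, p1$node)
  lab2 <- setNames(p2$label, p2$node)
  # same grouping structure once names are mapped through the permutation
  mapped <- lab2[ids[perm[match(names(lab1), ids)]]]
  m1 <- outer(lab1, lab1, "==")
  m2 <- outer(mapped, mapped, "==")
  expect_equal(unname(m1), unname(m2))
})
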