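# Independent brute-force oracles used across the suite.

# Step-up BH, written directly from the definition.
bh_stepup_oracle <- function(p) {
  n <- length(p)
  ord <- order(p, decreasing = TRUE)
  adj <- numeric(n)
  running <- Inf
  for (i in seq_along(ord)) {
    rank <- n - i + 1
    running <- min(running, p[ord[i]] * n / rank)
    adj[ord[i]] <- min(running, 1)
  }
  adj
}

# Upper-tail hypergeometric P(X >= k) by complete enumeration of the
# probability mass function (for small populations).
hyper_upper_oracle <- function(k, K, N, n) {
  js <- max(0, n - (N - K)):min(K, n)
  probs <- choose(K, js) * choose(N - K, n - js) / choose(N, n)
  sum(probs[js >= k])
}

# Spearman rho per pair: average-rank transform then Pearson.
spearman_oracle <- function(x, y) {
  stats::cor(rank(x), rank(y))
}

toy_design <- function(n_per = 3, groups = c("control", "d7", "d14")) {
  study_design(paste0(rep(groups, each = n_per), "_", seq_len(n_per)),
               rep(groups, each = n_per), reference = groups[1],
               group_levels = groups)
}

# Differential table with prescribed signs/significance for rule tests.
toy_diff <- function(features, lfc, padj, contrast = "t") {
  data.frame(feature = features, log2fc = lfc, pvalue = pmin(padj, 1) / 2,
             padj = padj, contrast = contrast, stringsAsFactors = FALSE)
}

# Edge-list network builder for graph-statistic tests.
toy_network <- function(from, to, rho = rep(0.9, length(from)),
                        kinds = NULL) {
  edges <- data.frame(from = from, to = to, rho = rho,
                      p = rep(1e-6, length(from)),
                      padj = rep(1e-5, length(from)),
                      stringsAsFactors = FALSE)
  net <- fibronet:::new_corr_network(edges, kinds)
  net
}
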