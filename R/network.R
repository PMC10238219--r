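#' All-pairs Spearman correlation
#'
#' Computes Spearman's rho (average ranks for ties) and a two-sided p-value
#' from the t approximation for every unordered pair of features. Features
#' with zero variance are dropped with a warning, since their rank
#' correlation is undefined.
#'
#' @param mat complete numeric matrix (features x samples), >= 4 samples.
#' @param kinds optional named character vector giving each feature's node
#'   kind (`"gene"`, `"metabolite"`, `"phenotype"`); defaults to the
#'   `node_kinds` attribute set by [attach_phenotypes()], else `"gene"`.
#' @return data frame with columns `a`, `b` (feature IDs, `a < b`
#'   lexicographically within the matrix row order), `rho`, `p`, plus a
#'   `node_kinds` attribute.
#' @export
spearman_all_pairs <- function(mat, kinds = NULL) {
  if (is.null(kinds)) kinds <- attr(mat, "node_kinds")
  mat <- as_plain_matrix(mat)
  if (ncol(mat) < 4) stop("need at least 4 samples for correlation")
  if (anyNA(mat)) stop("matrix must be complete; impute metabolites first")
  sds <- apply(mat, 1, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " zero-variance features excluded from pairs")
    mat <- mat[sds > 0, , drop = FALSE]
  }
  if (is.null(kinds))
    kinds <- stats::setNames(rep("gene", nrow(mat)), rownames(mat))
  kinds <- kinds[rownames(mat)]
  n <- ncol(mat)
  rho <- stats::cor(t(mat), method = "spearman")
  idx <- which(upper.tri(rho), arr.ind = TRUE)
  r <- rho[idx]
  r_c <- pmin(pmax(r, -1), 1)
  tstat <- r_c * sqrt((n - 2) / pmax(1 - r_c^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), n - 2)
  p[abs(r_c) >= 1] <- 0
  out <- data.frame(a = rownames(rho)[idx[, 1]], b = rownames(rho)[idx[, 2]],
                    rho = r, p = p, stringsAsFactors = FALSE)
  attr(out, "node_kinds") <- kinds
  out
}

pair_kind <- function(pairs, kinds) {
  if (is.null(kinds))
    return(rep(FALSE, nrow(pairs)))
  kinds[pairs$a] == "phenotype" | kinds[pairs$b] == "phenotype"
}

new_corr_network <- function(edges, kinds) {
  nodes <- unique(c(edges$from, edges$to))
  kind <- if (is.null(kinds)) rep("gene", length(nodes)) else
    unname(kinds[nodes])
  kind[is.na(kind)] <- "gene"
  structure(list(
    edges = edges,
    nodes = data.frame(node = nodes, kind = kind, stringsAsFactors = FALSE)),
    class = "corr_network")
}

#' @export
print.corr_network <- function(x, ...) {
  kt <- table(x$nodes$kind)
  cat(sprintf("corr_network: %d nodes (%s), %d edges\n", nrow(x$nodes),
              paste(sprintf("%s %d", names(kt), kt), collapse = ", "),
              nrow(x$edges)))
  invisible(x)
}

network_graph <- function(network) {
  igraph::graph_from_data_frame(
    network$edges[, c("from", "to")], directed = FALSE,
    vertices = network$nodes$node)
}

# Shared edge-selection core. BH is applied over all supplied pairs (one
# family per correlation run). Phenotype-involving pairs can bypass the
# positivity and top-fraction filters.
filter_pairs <- function(pairs, kinds, fdr, top_fraction, positive_only,
                         phenotype_fdr_only) {
  padj <- bh_adjust(pairs$p)
  pheno <- pair_kind(pairs, kinds)
  keep <- padj <= fdr
  core <- keep & !pheno
  if (positive_only) core <- core & pairs$rho > 0
  core_idx <- which(core)
  if (!is.na(top_fraction) && length(core_idx)) {
    id <- paste(pairs$a, pairs$b, sep = "\r")
    ord <- core_idx[order(-pairs$rho[core_idx], id[core_idx])]
    core_idx <- ord[seq_len(ceiling(top_fraction * length(ord)))]
  }
  pheno_idx <- if (phenotype_fdr_only) which(keep & pheno) else integer(0)
  sel <- sort(c(core_idx, pheno_idx))
  edges <- data.frame(from = pairs$a[sel], to = pairs$b[sel],
                      rho = pairs$rho[sel], p = pairs$p[sel],
                      padj = padj[sel], stringsAsFactors = FALSE)
  if (!nrow(edges)) warning("no edges survive the filters; empty network")
  new_corr_network(edges, kinds)
}

#' Build the gene co-expression network
#'
#' Keeps gene-gene pairs with BH-adjusted p <= `fdr` and rho > 0, then
#' retains the top `top_fraction` most positively correlated of them
#' (first `ceiling(top_fraction * m)` after sorting by decreasing rho, ties
#' broken by lexicographic pair ID). Pairs involving a phenotype node pass
#' the FDR filter only (both signs) by default.
#'
#' @param pairs output of [spearman_all_pairs()].
#' @param fdr adjusted-p threshold for edges.
#' @param top_fraction fraction of significant positive pairs kept.
#' @param phenotype_fdr_only exempt phenotype edges from the positivity and
#'   top-fraction filters.
#' @return a `corr_network` (edge list + node table).
#' @export
build_gcn <- function(pairs, fdr = 0.05, top_fraction = 0.25,
                      phenotype_fdr_only = TRUE) {
  filter_pairs(pairs, attr(pairs, "node_kinds"), fdr, top_fraction,
               positive_only = TRUE, phenotype_fdr_only = phenotype_fdr_only)
}

#' Build the metabolite correlation network
#'
#' Keeps all pairs with BH-adjusted p <= `fdr`; both correlation signs are
#' retained unless `positive_only`.
#'
#' @inheritParams build_gcn
#' @param positive_only drop negative-rho edges.
#' @return a `corr_network`.
#' @export
build_mcn <- function(pairs, fdr = 0.05, positive_only = FALSE) {
  filter_pairs(pairs, attr(pairs, "node_kinds"), fdr, top_fraction = NA,
               positive_only = positive_only, phenotype_fdr_only = TRUE)
}

#' Append phenotype rows to an omics matrix
#'
#' Phenotype variables become extra rows so that feature-phenotype Spearman
#' correlations are computed in the same pass; the returned matrix carries a
#' `node_kinds` attribute used by the network builders to treat phenotype
#' edges separately.
#'
#' @param mat feature matrix (features x samples).
#' @param phenotypes phenotype matrix (phenotypes x samples), same samples.
#' @param base_kind node kind of the feature rows; defaults to
#'   `"metabolite"` for relative-peak-area matrices and `"gene"` otherwise.
#' @return numeric matrix with `node_kinds` attribute.
#' @export
attach_phenotypes <- function(mat, phenotypes, base_kind = NULL) {
  if (!setequal(colnames(mat), colnames(phenotypes)))
    stop("phenotype samples do not match matrix samples")
  if (is.null(base_kind))
    base_kind <- switch(value_kind(mat), relative_peak_area = "metabolite",
                        "gene")
  m <- rbind(as_plain_matrix(mat),
             as_plain_matrix(phenotypes)[, colnames(mat), drop = FALSE])
  kinds <- stats::setNames(
    c(rep(base_kind, nrow(mat)), rep("phenotype", nrow(phenotypes))),
    rownames(m))
  attr(m, "node_kinds") <- kinds
  m
}

#' Leiden subnetwork detection
#'
#' Runs the Leiden algorithm (modularity objective) on the network, then
#' relabels communities 0..K-1 in decreasing size order so that label 0 is
#' the largest subnetwork. Size ties are broken by the lexicographically
#' smallest member node. Deterministic for a given seed.
#'
#' @param network a `corr_network`.
#' @param resolution Leiden resolution parameter.
#' @param seed RNG seed.
#' @param weighted use `|rho|` edge weights instead of an unweighted graph.
#' @return a `subnet_partition` data frame (`node`, `label`) with attribute
#'   `sizes` (named by label, decreasing).
#' @export
leiden_partition <- function(network, resolution = 1.0, seed = 0,
                             weighted = FALSE) {
  if (!nrow(network$edges)) stop("cannot partition an empty network")
  g <- network_graph(network)
  w <- if (weighted) abs(network$edges$rho) else NULL
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  comm <- igraph::cluster_leiden(g, objective_function = "modularity",
                                 weights = w, resolution = resolution,
                                 n_iterations = 5)
  memb <- igraph::membership(comm)
  groups <- split(names(memb), memb)
  first <- vapply(groups, function(v) min(v), "")
  ord <- order(-lengths(groups), first)
  label <- integer(length(memb))
  names(label) <- names(memb)
  for (i in seq_along(ord)) label[groups[[ord[i]]]] <- i - 1L
  part <- data.frame(node = names(label), label = unname(label),
                     stringsAsFactors = FALSE)
  sizes <- table(part$label)
  structure(part,
            sizes = stats::setNames(as.integer(sizes), names(sizes)),
            class = c("subnet_partition", "data.frame"))
}

#' @export
print.subnet_partition <- function(x, ...) {
  s <- attr(x, "sizes")
  cat("subnet_partition:", length(s), "subnetworks;",
      paste(sprintf("S-%s=%d", names(s), s), collapse = ", "), "\n")
  invisible(x)
}

#' Local clustering coefficient
#'
#' `2 * triangles / (deg * (deg - 1))`; nodes of degree < 2 score 0.
#'
#' @param network a `corr_network`.
#' @param node node ID(s).
#' @return numeric vector in \[0, 1\].
#' @export
local_cc <- function(network, node) {
  unknown <- setdiff(node, network$nodes$node)
  if (length(unknown))
    stop("unknown node(s): ", paste(unknown, collapse = ", "))
  g <- network_graph(network)
  out <- igraph::transitivity(g, type = "localundirected", vids = node,
                              isolates = "zero")
  stats::setNames(out, node)
}

#' Average clustering coefficient per subnetwork
#'
#' Averages members' local clustering coefficients. By default coefficients
#' are computed on the full network's edges; `induced = TRUE` restricts to
#' each subnetwork's induced subgraph.
#'
#' @param network a `corr_network`.
#' @param partition a [leiden_partition()] result.
#' @param induced compute on induced subgraphs instead of the full network.
#' @return named numeric vector (one value per subnetwork label).
#' @export
subnetwork_avg_cc <- function(network, partition, induced = FALSE) {
  labels <- sort(unique(partition$label))
  if (!induced) {
    cc <- local_cc(network, partition$node)
    return(vapply(labels, function(l)
      mean(cc[partition$node[partition$label == l]]), 0))
  }
  g <- network_graph(network)
  vapply(labels, function(l) {
    sub <- igraph::induced_subgraph(g,
                                    partition$node[partition$label == l])
    mean(igraph::transitivity(sub, type = "localundirected",
                              isolates = "zero"))
  }, 0)
}

#' Phenotype-node centrality
#'
#' For each phenotype node, the number of adjacent gene/metabolite nodes
#' (phenotype-phenotype edges excluded).
#'
#' @param network a `corr_network` with phenotype nodes.
#' @return named integer vector (possibly empty, with a warning).
#' @export
phenotype_centrality <- function(network) {
  ph <- network$nodes$node[network$nodes$kind == "phenotype"]
  if (!length(ph)) {
    warning("no phenotype nodes in the network")
    return(stats::setNames(integer(0), character(0)))
  }
  kind <- stats::setNames(network$nodes$kind, network$nodes$node)
  e <- network$edges
  counts <- stats::setNames(integer(length(ph)), ph)
  for (p in ph) {
    nb <- c(e$to[e$from == p], e$from[e$to == p])
    counts[p] <- sum(kind[nb] != "phenotype")
  }
  counts
}

#' Top correlated neighbours of a phenotype node
#'
#' Adjacent nodes ranked by decreasing `|rho|` (ties broken
#' lexicographically); the signed rho is returned.
#'
#' @param network a `corr_network`.
#' @param phenotype phenotype node ID.
#' @param k number of correlates to return.
#' @return data frame (`node`, `rho`) with at most `k` rows.
#' @export
top_correlates <- function(network, phenotype, k = 10) {
  if (k <= 0) stop("k must be positive")
  if (!phenotype %in% network$nodes$node)
    stop("phenotype node '", phenotype, "' not in network")
  e <- network$edges
  hit <- e$from == phenotype | e$to == phenotype
  nb <- ifelse(e$from[hit] == phenotype, e$to[hit], e$from[hit])
  rho <- e$rho[hit]
  ord <- order(-abs(rho), nb)
  take <- utils::head(ord, k)
  data.frame(node = nb[take], rho = rho[take], stringsAsFactors = FALSE)
}

#' Subnetwork composition statistics
#'
#' Per-subnetwork node counts and percentage shares (two decimals) of the
#' whole network, plus the share excluding phenotype nodes and, optionally,
#' the pooled share of a union of subnetworks.
#'
#' @param partition a [leiden_partition()] result, or a named/unnamed
#'   numeric vector of subnetwork sizes (taken as labels 0, 1, ... in order
#'   if unnamed).
#' @param node_kinds optional named character vector of node kinds (used to
#'   exclude phenotype nodes from the denominator); only available when
#'   `partition` is a real partition.
#' @param union optional integer vector of labels to pool.
#' @return list with `table` (label, size, pct, pct_excl_phenotype) and, if
#'   requested, `union` (`labels`, `size`, `pct`).
#' @export
composition_stats <- function(partition, node_kinds = NULL, union = NULL) {
  if (is.numeric(partition) && is.null(dim(partition))) {
    sizes <- as.integer(partition)
    labels <- if (is.null(names(partition)))
      seq_along(sizes) - 1L else as.integer(names(partition))
    pheno_per_label <- rep(0L, length(sizes))
    n_pheno <- 0L
  } else {
    tab <- table(partition$label)
    labels <- as.integer(names(tab))
    sizes <- as.integer(tab)
    if (!is.null(node_kinds)) {
      is_ph <- node_kinds[partition$node] == "phenotype"
      pheno_per_label <- vapply(labels, function(l)
        sum(is_ph[partition$label == l], na.rm = TRUE), 0L)
      n_pheno <- sum(is_ph, na.rm = TRUE)
    } else {
      pheno_per_label <- rep(0L, length(labels))
      n_pheno <- 0L
    }
  }
  total <- sum(sizes)
  total_np <- total - n_pheno
  tab <- data.frame(
    label = labels, size = sizes,
    pct = round(100 * sizes / total, 2),
    pct_excl_phenotype = round(100 * (sizes - pheno_per_label) / total_np, 2))
  out <- list(table = tab)
  if (!is.null(union)) {
    miss <- setdiff(union, labels)
    if (length(miss))
      stop("union labels not in partition: ", paste(miss, collapse = ", "))
    usize <- sum(sizes[labels %in% union])
    out$union <- list(labels = union, size = usize,
                      pct = round(100 * usize / total, 2))
  }
  out
}
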