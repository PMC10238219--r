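#' Hypergeometric over-representation analysis
#'
#' Upper-tail hypergeometric test `P(X >= k)` of a query feature set against
#' each set of a library, with population size = universe size, successes =
#' set members in the universe, draws = query size. P-values are BH-adjusted
#' across the library's sets. Query and sets are intersected with the
#' universe first.
#'
#' @param query character vector of feature IDs.
#' @param library named list of character vectors (e.g. from [read_gmt()]).
#' @param universe character vector of all eligible feature IDs.
#' @param fdr threshold recorded in the `significant` column.
#' @return data frame: `set`, `overlap`, `query_size`, `set_size`,
#'   `universe_size`, `pvalue`, `padj`, `significant`, `members`
#'   (comma-separated overlap IDs).
#' @export
hypergeom_ora <- function(query, library, universe, fdr = 0.05) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  query <- intersect(unique(query), universe)
  sets <- lapply(library, function(s) intersect(unique(s), universe))
  n <- length(query)
  N <- length(universe)
  res <- lapply(names(sets), function(nm) {
    K <- length(sets[[nm]])
    hits <- intersect(query, sets[[nm]])
    k <- length(hits)
    p <- if (n == 0 || K == 0) 1 else
      stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, overlap = k, query_size = n, set_size = K,
               universe_size = N, pvalue = p,
               members = paste(sort(hits), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(set = character(0), overlap = integer(0),
                      query_size = integer(0), set_size = integer(0),
                      universe_size = integer(0), pvalue = numeric(0),
                      members = character(0), stringsAsFactors = FALSE)
  out$padj <- if (nrow(out)) bh_adjust(out$pvalue) else numeric(0)
  out$significant <- out$padj <= fdr
  out[, c("set", "overlap", "query_size", "set_size", "universe_size",
          "pvalue", "padj", "significant", "members")]
}

feature_map_to_library <- function(map) {
  split(map$feature, map$target)
}

#' Metabolic-subsystem profiles of subnetworks
#'
#' For each subnetwork of a partition, over-representation of metabolic
#' subsystems among its members. The universe defaults to all partitioned
#' features (the network's nodes of that omics type); BH adjustment is
#' applied within each subnetwork across subsystems.
#'
#' @param partition a [leiden_partition()] result (one omics type; drop
#'   phenotype nodes first if present).
#' @param subsystem_map feature map data frame (`feature`, `target` =
#'   subsystem).
#' @param universe optional universe override.
#' @param fdr significance threshold.
#' @return data frame: `subnetwork` plus the [hypergeom_ora()] columns.
#' @export
subsystem_profiles <- function(partition, subsystem_map, universe = NULL,
                               fdr = 0.05) {
  if (is.null(universe)) universe <- partition$node
  lib <- feature_map_to_library(subsystem_map)
  if (length(intersect(subsystem_map$feature, universe)) <
      0.01 * length(universe))
    warning("subsystem map covers less than 1% of the universe")
  labels <- sort(unique(partition$label))
  out <- do.call(rbind, lapply(labels, function(l) {
    ora <- hypergeom_ora(partition$node[partition$label == l], lib,
                         universe, fdr)
    cbind(subnetwork = l, ora)
  }))
  rownames(out) <- NULL
  out
}

#' Bridge gene and metabolite subnetworks via shared subsystems
#'
#' Emits one bridge edge (GCN subnetwork, MCN subnetwork, subsystem) for
#' every subsystem significantly over-represented (adjusted p <= `fdr`) on
#' both the gene side and the metabolite side.
#'
#' @param gcn_profiles [subsystem_profiles()] of the gene partition.
#' @param mcn_profiles [subsystem_profiles()] of the metabolite partition.
#' @param fdr adjusted-p threshold applied on both sides.
#' @return data frame: `gcn_label`, `mcn_label`, `subsystem`, `padj_gene`,
#'   `padj_metab`.
#' @export
bridge_networks <- function(gcn_profiles, mcn_profiles, fdr = 0.05) {
  if (!length(intersect(gcn_profiles$set, mcn_profiles$set)))
    stop("gene and metabolite profiles share no subsystem vocabulary")
  g <- gcn_profiles[gcn_profiles$padj <= fdr, , drop = FALSE]
  m <- mcn_profiles[mcn_profiles$padj <= fdr, , drop = FALSE]
  out <- merge(
    data.frame(gcn_label = g$subnetwork, subsystem = g$set,
               padj_gene = g$padj, stringsAsFactors = FALSE),
    data.frame(mcn_label = m$subnetwork, subsystem = m$set,
               padj_metab = m$padj, stringsAsFactors = FALSE),
    by = "subsystem")
  out <- out[order(out$gcn_label, out$mcn_label, out$subsystem), ,
             drop = FALSE]
  rownames(out) <- NULL
  out[, c("gcn_label", "mcn_label", "subsystem", "padj_gene", "padj_metab")]
}

#' Associate gene tracks with subnetworks
#'
#' Hypergeometric over-representation of each externally supplied gene
#' track (temporal trajectory groups with shared regulators) in each
#' subnetwork; BH adjustment spans the whole track-by-subnetwork matrix.
#' Tracks with no gene in the universe are skipped with a warning.
#'
#' @param tracks feature map (`feature` = gene, `target` = track label) or
#'   named list of gene vectors.
#' @param partition gene partition.
#' @param universe optional universe override (default: partitioned genes).
#' @param fdr significance threshold.
#' @return data frame: `track`, `subnetwork`, `overlap`, `track_size`,
#'   `subnetwork_size`, `universe_size`, `pvalue`, `padj`, `significant`.
#' @export
track_association <- function(tracks, partition, universe = NULL,
                              fdr = 0.05) {
  if (is.data.frame(tracks)) tracks <- feature_map_to_library(tracks)
  if (is.null(universe)) universe <- partition$node
  universe <- unique(universe)
  tracks <- lapply(tracks, intersect, universe)
  empty <- !lengths(tracks)
  if (any(empty)) {
    warning("tracks with no genes in the universe skipped: ",
            paste(names(tracks)[empty], collapse = ", "))
    tracks <- tracks[!empty]
  }
  labels <- sort(unique(partition$label))
  N <- length(universe)
  rows <- list()
  for (tr in names(tracks)) {
    q <- tracks[[tr]]
    for (l in labels) {
      members <- intersect(partition$node[partition$label == l], universe)
      k <- length(intersect(q, members))
      p <- if (!length(q) || !length(members)) 1 else
        stats::phyper(k - 1, length(members), N - length(members),
                      length(q), lower.tail = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        track = tr, subnetwork = l, overlap = k, track_size = length(q),
        subnetwork_size = length(members), universe_size = N, pvalue = p,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$padj <- bh_adjust(out$pvalue)
  out$significant <- out$padj <= fdr
  out
}
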