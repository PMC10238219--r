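#' Read a feature-by-sample abundance table
#'
#' Expects UTF-8 TSV with a header row of sample IDs and the feature ID in
#' the first column. Empty cells become `NA` and are only accepted for value
#' kinds that allow missingness (`relative_peak_area`, `phenotype`).
#'
#' @param path TSV file path.
#' @inheritParams omics_matrix
#' @return an [omics_matrix()].
#' @export
read_omics_matrix <- function(path, kind) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = "", colClasses = NA)
  if (ncol(df) < 2)
    stop("matrix file needs a feature-ID column plus >=1 sample column: ",
         path)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    stop("duplicated feature IDs in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  vals <- df[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    if (!is.numeric(vals[[j]])) {
      suppressWarnings(num <- as.numeric(vals[[j]]))
      bad <- which(is.na(num) & !is.na(vals[[j]]))
      if (length(bad))
        stop("non-numeric cell at row '", ids[bad[1]], "', column '",
             colnames(vals)[j], "' in ", path)
      vals[[j]] <- num
    }
  }
  m <- as.matrix(vals)
  storage.mode(m) <- "double"
  rownames(m) <- ids
  omics_matrix(m, kind)
}

#' Write an omics matrix as TSV
#'
#' Missing values are written as empty cells; the first column is named
#' `feature`.
#'
#' @param mat matrix (features x samples) with dimnames.
#' @param path output path.
#' @export
write_omics_matrix <- function(mat, path) {
  df <- data.frame(feature = rownames(mat), as.data.frame(as_plain_matrix(mat)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Read a study design table
#'
#' Two-column TSV (`sample`, `group`).
#'
#' @param path TSV path.
#' @param reference reference group label.
#' @param group_levels optional ordered group labels.
#' @return a [study_design()].
#' @export
read_design <- function(path, reference, group_levels = NULL) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("sample", "group") %in% colnames(df)))
    stop("design file must have columns 'sample' and 'group': ", path)
  if (is.null(group_levels)) group_levels <- unique(df$group)
  study_design(df$sample, df$group, reference, group_levels)
}

#' @rdname read_design
#' @param design a [study_design()].
#' @export
write_design <- function(design, path) {
  utils::write.table(design[, c("sample", "group")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene-set library in GMT format
#'
#' One set per line: name, description, then tab-separated member IDs.
#' Members are de-duplicated within a set.
#'
#' @param path GMT file path.
#' @return named list of character vectors; set descriptions in attribute
#'   `descriptions`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    warning("empty GMT file: ", path)
    return(structure(list(), descriptions = character(0)))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(fields, length, 0L) < 3)
  if (length(short))
    stop("GMT line ", short[1], " has fewer than 3 fields in ", path)
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[[`, "", 1L)
  structure(sets,
            descriptions = stats::setNames(vapply(fields, `[[`, "", 2L),
                                           names(sets)))
}

#' Read a feature mapping table
#'
#' Two-column TSV mapping feature IDs to target IDs (metabolic subsystems,
#' orthologs, or gene tracks). One feature may map to several targets;
#' exact duplicate rows are dropped.
#'
#' @param path TSV path with a header.
#' @return data frame with columns `feature`, `target`.
#' @export
read_feature_map <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2)
    stop("feature map needs two columns: ", path)
  df <- df[, 1:2]
  colnames(df) <- c("feature", "target")
  df <- unique(df)
  rownames(df) <- NULL
  df
}

#' @rdname read_feature_map
#' @param map data frame with columns `feature`, `target`.
#' @export
write_feature_map <- function(map, path) {
  utils::write.table(map, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a differential table
#'
#' TSV with columns `feature`, `log2fc`, `pvalue`, `padj`, `contrast`.
#'
#' @param path TSV path.
#' @return a differential table data frame.
#' @export
read_differential <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("feature", "log2fc", "pvalue", "padj", "contrast")
  if (!all(need %in% colnames(df)))
    stop("differential table must have columns ",
         paste(need, collapse = ", "), ": ", path)
  df[, need]
}

#' @rdname read_differential
#' @param table differential table data frame.
#' @export
write_differential <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a correlation network and its partition
#'
#' Produces `<prefix>_edges.tsv` (source, target, rho, p, fdr),
#' `<prefix>_nodes.tsv` (node, kind, subnetwork, degree, local_cc) and
#' optionally `<prefix>.graphml`.
#'
#' @param network a [corr_network] object.
#' @param partition optional [leiden_partition()] result; nodes absent from
#'   the network raise an error.
#' @param path_prefix output path prefix.
#' @param graphml also write GraphML via igraph.
#' @return invisibly, the written file paths.
#' @export
write_network <- function(network, partition = NULL, path_prefix,
                          graphml = FALSE) {
  stopifnot(inherits(network, "corr_network"))
  edges <- network$edges
  nodes <- network$nodes
  labels <- rep(NA_integer_, nrow(nodes))
  if (!is.null(partition)) {
    extra <- setdiff(partition$node, nodes$node)
    if (length(extra))
      stop("partition nodes absent from network: ",
           paste(utils::head(extra, 5), collapse = ", "))
    labels <- partition$label[match(nodes$node, partition$node)]
  }
  g <- network_graph(network)
  deg <- igraph::degree(g)[nodes$node]
  lcc <- igraph::transitivity(g, type = "localundirected", vids = nodes$node,
                              isolates = "zero")
  edge_path <- paste0(path_prefix, "_edges.tsv")
  node_path <- paste0(path_prefix, "_nodes.tsv")
  utils::write.table(
    data.frame(source = edges$from, target = edges$to, rho = edges$rho,
               p = edges$p, fdr = edges$padj),
    edge_path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(node = nodes$node, kind = nodes$kind, subnetwork = labels,
               degree = as.integer(deg), local_cc = lcc),
    node_path, sep = "\t", quote = FALSE, row.names = FALSE)
  out <- c(edge_path, node_path)
  if (graphml) {
    gm <- paste0(path_prefix, ".graphml")
    igraph::write_graph(g, gm, format = "graphml")
    out <- c(out, gm)
  }
  invisible(out)
}

#' Read a network edge list written by [write_network()]
#'
#' @param path `_edges.tsv` path.
#' @return data frame with columns `from`, `to`, `rho`, `p`, `padj`.
#' @export
read_network_edges <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  data.frame(from = df$source, to = df$target, rho = df$rho, p = df$p,
             padj = df$fdr, stringsAsFactors = FALSE)
}

run_config_defaults <- function() {
  list(fdr = 0.05, top_fraction = 0.25, resolution = 1.0, seed = 0L,
       alpha = 0.05, min_present = 2L, knn_k = 3L)
}

#' Read a pipeline run configuration
#'
#' YAML (`.yml`/`.yaml`) or JSON file with any subset of the keys `fdr`,
#' `top_fraction`, `resolution`, `seed`, `alpha`, `min_present`, `knn_k`.
#' Missing keys take the defaults (fdr 0.05, top_fraction 0.25, resolution 1,
#' seed 0, alpha 0.05, min_present 2, knn_k 3); unknown keys are an error.
#'
#' @param path config file path, or `NULL` for all defaults.
#' @return named list of validated settings.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- run_config_defaults()
  if (!is.null(path)) {
    user <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
      yaml::read_yaml(path)
    else
      jsonlite::read_json(path, simplifyVector = TRUE)
    if (is.null(user)) user <- list()
    unknown <- setdiff(names(user), names(cfg))
    if (length(unknown))
      stop("unknown config keys: ", paste(unknown, collapse = ", "))
    cfg[names(user)] <- user
  }
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  stop_if <- function(bad, msg) if (bad) stop(msg, call. = FALSE)
  stop_if(cfg$fdr <= 0 || cfg$fdr > 1, "fdr must be in (0, 1]")
  stop_if(cfg$alpha <= 0 || cfg$alpha > 1, "alpha must be in (0, 1]")
  stop_if(cfg$top_fraction <= 0 || cfg$top_fraction > 1,
          "top_fraction must be in (0, 1]")
  stop_if(cfg$resolution <= 0, "resolution must be positive")
  stop_if(cfg$min_present < 1, "min_present must be >= 1")
  stop_if(cfg$knn_k < 1, "knn_k must be >= 1")
  cfg$seed <- as.integer(cfg$seed)
  cfg$min_present <- as.integer(cfg$min_present)
  cfg$knn_k <- as.integer(cfg$knn_k)
  cfg
}
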