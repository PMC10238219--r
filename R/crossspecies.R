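#' One-to-one ortholog filtering
#'
#' Removes every row participating in a many-to-many relation so that each
#' mouse ID and each human ID appears at most once.
#'
#' @param map data frame with columns `feature` (mouse) and `target`
#'   (human), e.g. from [read_feature_map()].
#' @return filtered map with an attribute `n_removed`.
#' @export
filter_one_to_one <- function(map) {
  map <- unique(map[, c("feature", "target")])
  keep <- !(map$feature %in% map$feature[duplicated(map$feature)]) &
    !(map$target %in% map$target[duplicated(map$target)])
  out <- map[keep, , drop = FALSE]
  if (!nrow(out)) stop("no one-to-one ortholog pairs remain")
  rownames(out) <- NULL
  structure(out, n_removed = sum(!keep))
}

#' Overlap of a mouse gene set with a human cohort
#'
#' Counts set members whose ortholog is significant (adjusted p < `alpha`)
#' in the cohort differential table, and the percentage of the set size
#' (two decimals). Unmapped members stay in the denominator by default.
#'
#' @param gene_set character vector of mouse gene IDs.
#' @param cohort human differential table.
#' @param map one-to-one ortholog map (`feature` = mouse, `target` = human).
#' @param alpha significance threshold.
#' @param count_unmapped keep unmapped members in the denominator.
#' @return list with `overlap` (count), `pct`, `n_set` (denominator).
#' @export
overlap_with_cohort <- function(gene_set, cohort, map, alpha = 0.05,
                                count_unmapped = TRUE) {
  gene_set <- unique(gene_set)
  human <- map$target[match(gene_set, map$feature)]
  mapped <- !is.na(human)
  sig_ids <- cohort$feature[cohort$padj < alpha]
  overlap <- sum(human[mapped] %in% sig_ids)
  denom <- if (count_unmapped) length(gene_set) else sum(mapped)
  pct <- if (denom) round(100 * overlap / denom, 2) else 0
  list(overlap = overlap, pct = pct, n_set = denom)
}

#' Same-trend fraction between two differential tables
#'
#' Over genes significant in both species (the default denominator), the
#' percentage whose fold-change signs agree.
#'
#' @param mouse mouse differential table.
#' @param cohort human differential table.
#' @param map one-to-one ortholog map.
#' @param alpha significance threshold applied to both tables.
#' @param denominator `"both"` (jointly significant genes) or `"mouse"`
#'   (all significant mouse genes with a mapped ortholog).
#' @return list with `pct`, `n_joint`, and the per-gene data frame `table`
#'   (`mouse_id`, `human_id`, `mouse_sign`, `cohort_sign`, `same_trend`).
#' @export
same_trend_fraction <- function(mouse, cohort, map, alpha = 0.05,
                                denominator = c("both", "mouse")) {
  denominator <- match.arg(denominator)
  m_sig <- mouse[mouse$padj < alpha, , drop = FALSE]
  human <- map$target[match(m_sig$feature, map$feature)]
  ok <- !is.na(human)
  m_sig <- m_sig[ok, , drop = FALSE]
  human <- human[ok]
  c_idx <- match(human, cohort$feature)
  c_sig <- !is.na(c_idx) & cohort$padj[c_idx] < alpha
  tab <- data.frame(
    mouse_id = m_sig$feature, human_id = human,
    mouse_sign = sign(m_sig$log2fc),
    cohort_sign = ifelse(c_sig, sign(cohort$log2fc[c_idx]), NA),
    stringsAsFactors = FALSE)
  tab$same_trend <- !is.na(tab$cohort_sign) &
    tab$mouse_sign == tab$cohort_sign
  n_joint <- sum(c_sig)
  denom <- if (denominator == "both") n_joint else nrow(tab)
  if (denominator == "both" && n_joint == 0)
    stop("no genes significant in both tables; same-trend undefined")
  list(pct = round(100 * sum(tab$same_trend) / denom, 2),
       n_joint = n_joint, table = tab)
}

#' Multi-cohort validated gene set
#'
#' Genes significant with the same fold-change sign in the mouse table and
#' in both human cohorts. If a partition is given, the subnetwork
#' composition of the validated set is reported as well.
#'
#' @param mouse mouse differential table (e.g. the day-14 contrast).
#' @param cohort_a,cohort_b human differential tables.
#' @param map one-to-one ortholog map.
#' @param alpha significance threshold.
#' @param partition optional gene partition for composition reporting.
#' @return list with `genes` (mouse IDs), `n`, and optionally `composition`
#'   (counts and percentage of the validated set per subnetwork label).
#' @export
validated_set <- function(mouse, cohort_a, cohort_b, map, alpha = 0.05,
                          partition = NULL) {
  m_sig <- mouse[mouse$padj < alpha, , drop = FALSE]
  human <- map$target[match(m_sig$feature, map$feature)]
  ok <- !is.na(human)
  m_sig <- m_sig[ok, , drop = FALSE]
  human <- human[ok]
  sig_sign <- function(tab, ids) {
    idx <- match(ids, tab$feature)
    s <- ifelse(!is.na(idx) & tab$padj[idx] < alpha,
                sign(tab$log2fc[idx]), NA)
    s
  }
  sa <- sig_sign(cohort_a, human)
  sb <- sig_sign(cohort_b, human)
  ms <- sign(m_sig$log2fc)
  keep <- !is.na(sa) & !is.na(sb) & sa == ms & sb == ms
  genes <- m_sig$feature[keep]
  out <- list(genes = genes, n = length(genes))
  if (!is.null(partition)) {
    lab <- partition$label[match(genes, partition$node)]
    tab <- table(factor(lab, levels = sort(unique(partition$label))))
    out$composition <- data.frame(
      label = as.integer(names(tab)), n = as.integer(tab),
      pct = round(100 * as.integer(tab) / max(length(genes), 1L), 2))
  }
  out
}
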