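#' Perturbation reversal analysis of subnetworks
#'
#' Tests whether a perturbation (e.g. a receptor knockout) reverses the
#' disease-induced dysregulation of each subnetwork. A gene is "reversed"
#' when it is significant in both the disease contrast (disease vs control)
#' and the perturbation contrast (perturbed-disease vs disease) with
#' opposite fold-change signs (with `require_significance = FALSE`,
#' opposite point estimates with a significant disease effect suffice).
#' Per subnetwork the report gives the reversed fraction among
#' disease-dysregulated members and a hypergeometric enrichment of
#' perturbation-affected genes, BH-adjusted across subnetworks. A
#' subnetwork is called `reversed-up`/`reversed-down` when its adjusted
#' enrichment p <= `fdr` and the median perturbation fold change among its
#' dysregulated members opposes the median disease sign; the direction
#' reported is the perturbation direction.
#'
#' @param disease differential table, disease vs control.
#' @param perturbation differential table, perturbed-disease vs disease.
#' @param partition gene partition ([leiden_partition()] result or data
#'   frame with `node`, `label`).
#' @param alpha per-gene significance threshold.
#' @param fdr subnetwork-level adjusted-p threshold.
#' @param require_significance require perturbation significance for the
#'   per-gene "reversed" flag.
#' @return data frame, one row per subnetwork: `label`, `n_genes`,
#'   `n_dysregulated`, `n_reversed`, `reversed_fraction`,
#'   `n_perturbation_affected`, `pvalue`, `padj`, `median_disease_sign`,
#'   `median_perturbation_lfc`, `call`.
#' @export
reversal_analysis <- function(disease, perturbation, partition,
                              alpha = 0.05, fdr = 0.05,
                              require_significance = TRUE) {
  univ <- intersect(partition$node,
                    intersect(disease$feature, perturbation$feature))
  if (length(univ) < length(partition$node))
    warning("restricting to ", length(univ),
            " genes present in the partition and both tables")
  d_idx <- match(univ, disease$feature)
  p_idx <- match(univ, perturbation$feature)
  d_sig <- disease$padj[d_idx] < alpha
  d_sign <- sign(disease$log2fc[d_idx])
  p_sig <- perturbation$padj[p_idx] < alpha
  p_lfc <- perturbation$log2fc[p_idx]
  opposite <- d_sign * sign(p_lfc) < 0
  reversed <- d_sig & opposite &
    (if (require_significance) p_sig else TRUE)
  affected <- if (require_significance) p_sig else sign(p_lfc) != 0
  labels <- sort(unique(partition$label))
  lab <- partition$label[match(univ, partition$node)]
  N <- length(univ)
  K <- sum(affected)
  rows <- lapply(labels, function(l) {
    in_l <- lab == l
    n <- sum(in_l)
    dys <- in_l & d_sig
    k <- sum(in_l & affected)
    p <- if (n == 0) 1 else
      stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    med_d <- if (any(dys)) stats::median(d_sign[dys]) else 0
    med_p <- if (any(dys)) stats::median(p_lfc[dys]) else 0
    data.frame(label = l, n_genes = n, n_dysregulated = sum(dys),
               n_reversed = sum(in_l & reversed),
               reversed_fraction = if (sum(dys)) sum(in_l & reversed) /
                 sum(dys) else 0,
               n_perturbation_affected = k, pvalue = p,
               median_disease_sign = med_d,
               median_perturbation_lfc = med_p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$padj <- bh_adjust(out$pvalue)
  opposes <- out$median_disease_sign * sign(out$median_perturbation_lfc) < 0
  out$call <- ifelse(out$padj <= fdr & opposes,
                     ifelse(out$median_perturbation_lfc > 0, "reversed-up",
                            "reversed-down"),
                     "unchanged")
  out[, c("label", "n_genes", "n_dysregulated", "n_reversed",
          "reversed_fraction", "n_perturbation_affected", "pvalue", "padj",
          "median_disease_sign", "median_perturbation_lfc", "call")]
}

#' Per-gene reversal report for a gene panel
#'
#' For each gene of a panel (e.g. validated track target genes), the
#' disease and perturbation effects and whether the perturbation
#' significantly attenuated (opposed) the disease effect.
#'
#' @param panel character vector of gene IDs.
#' @param disease differential table, disease vs control.
#' @param perturbation differential table, perturbed-disease vs disease.
#' @param alpha significance threshold.
#' @return data frame: `feature`, `disease_lfc`, `disease_padj`,
#'   `perturbation_lfc`, `perturbation_padj`, `attenuated`, `missing`.
#' @export
gene_panel_report <- function(panel, disease, perturbation, alpha = 0.05) {
  d_idx <- match(panel, disease$feature)
  p_idx <- match(panel, perturbation$feature)
  missing <- is.na(d_idx) | is.na(p_idx)
  d_lfc <- disease$log2fc[d_idx]
  d_padj <- disease$padj[d_idx]
  p_lfc <- perturbation$log2fc[p_idx]
  p_padj <- perturbation$padj[p_idx]
  attenuated <- !missing & d_padj < alpha & p_padj < alpha &
    sign(d_lfc) * sign(p_lfc) < 0
  data.frame(feature = panel, disease_lfc = d_lfc, disease_padj = d_padj,
             perturbation_lfc = p_lfc, perturbation_padj = p_padj,
             attenuated = attenuated, missing = missing,
             stringsAsFactors = FALSE)
}
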