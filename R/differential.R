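#' Median-of-ratios size factors
#'
#' Per-sample normalisation factors: for each sample, the median over
#' reference genes (genes positive in every sample) of the ratio between the
#' sample's count and the gene's geometric mean across samples.
#'
#' @param counts counts matrix (genes x samples).
#' @return named numeric vector of positive size factors, one per sample.
#' @export
size_factors <- function(counts) {
  counts <- as_plain_matrix(counts)
  ref <- rowSums(counts > 0) == ncol(counts)
  if (!any(ref))
    stop("no gene has positive counts in every sample; cannot normalise")
  logc <- log(counts[ref, , drop = FALSE])
  geo <- rowMeans(logc)
  apply(exp(logc - geo), 2, stats::median)
}

# Vectorised Welch t-test over matrix rows. Zero-variance rows follow the
# equal-mean p = 1 / unequal-mean p = 0 convention.
welch_rows <- function(x, y) {
  n1 <- ncol(x); n2 <- ncol(y)
  m1 <- rowMeans(x); m2 <- rowMeans(y)
  v1 <- apply(x, 1, stats::var); v2 <- apply(y, 1, stats::var)
  se2 <- v1 / n1 + v2 / n2
  t <- (m2 - m1) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(t), df)
  degen <- se2 == 0
  p[degen] <- ifelse(m1[degen] == m2[degen], 1, 0)
  list(estimate = m2 - m1, t = t, df = df, p = p)
}

# Pooled-variance (Student) t-test over matrix rows, same conventions.
pooled_rows <- function(x, y) {
  n1 <- ncol(x); n2 <- ncol(y)
  m1 <- rowMeans(x); m2 <- rowMeans(y)
  v1 <- apply(x, 1, stats::var); v2 <- apply(y, 1, stats::var)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  t <- (m2 - m1) / se
  p <- 2 * stats::pt(-abs(t), n1 + n2 - 2)
  degen <- se == 0
  p[degen] <- ifelse(m1[degen] == m2[degen], 1, 0)
  list(t = t, df = n1 + n2 - 2, p = p)
}

new_differential_table <- function(feature, log2fc, pvalue, padj, contrast) {
  data.frame(feature = feature, log2fc = log2fc, pvalue = pvalue,
             padj = padj, contrast = contrast, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Differential expression test for one contrast
#'
#' Default time-course test: counts are normalised by median-of-ratios size
#' factors, transformed to `log2(count / sf + 1)`, and each gene is compared
#' between the contrast group and the reference with a Welch t-test. Effects
#' are mean differences on that log2 scale; p-values are BH-adjusted across
#' all tested genes.
#'
#' @param counts counts [omics_matrix()] (genes x samples).
#' @param design a [study_design()].
#' @param contrast group label tested against the design's reference.
#' @param sf optional pre-computed size factors (named by sample); defaults
#'   to [size_factors()] on the full matrix.
#' @return differential table with columns `feature`, `log2fc`, `pvalue`,
#'   `padj`, `contrast` (one row per gene).
#' @export
de_test <- function(counts, design, contrast, sf = NULL) {
  check_design_matches(counts, design)
  if (!contrast %in% design$group)
    stop("contrast group '", contrast, "' absent from design")
  ref <- design_reference(design)
  if (is.null(sf)) sf <- size_factors(counts)
  y <- log2(sweep(as_plain_matrix(counts), 2, sf[colnames(counts)], "/") + 1)
  s_ref <- intersect(colnames(y), design_samples(design, ref))
  s_trt <- intersect(colnames(y), design_samples(design, contrast))
  if (length(s_ref) < 2 || length(s_trt) < 2)
    stop("need >=2 samples on each side of the contrast")
  w <- welch_rows(y[, s_ref, drop = FALSE], y[, s_trt, drop = FALSE])
  new_differential_table(rownames(y), w$estimate, w$p, bh_adjust(w$p),
                         paste0(contrast, "_vs_", ref))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment with monotonicity enforcement, order-preserving.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values in input order.
#' @export
bh_adjust <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Consistent differentially expressed gene sets
#'
#' DEG-0: genes significantly up (adjusted p < alpha, log2fc > 0) at every
#' time point; DEG-1: significantly down at every time point. Genes missing
#' from any table are excluded with a warning.
#'
#' @param tables list of differential tables, one per time point.
#' @param alpha adjusted-p significance threshold.
#' @return list with character vectors `deg0` and `deg1`.
#' @export
consistent_deg_sets <- function(tables, alpha = 0.05) {
  if (length(tables) < 2)
    stop("need differential tables for at least two time points")
  common <- Reduce(intersect, lapply(tables, `[[`, "feature"))
  n_all <- length(unique(unlist(lapply(tables, `[[`, "feature"))))
  if (length(common) < n_all)
    warning(n_all - length(common),
            " features absent from some time point were excluded")
  up <- down <- rep(TRUE, length(common))
  for (tab in tables) {
    idx <- match(common, tab$feature)
    sig <- tab$padj[idx] < alpha
    up <- up & sig & tab$log2fc[idx] > 0
    down <- down & sig & tab$log2fc[idx] < 0
  }
  list(deg0 = common[up], deg1 = common[down])
}

#' Recurrently differential metabolite sets
#'
#' DM-0: metabolites significantly up (adjusted p < alpha, effect > 0) at a
#' minimum number of time points and never significantly down; DM-1 the
#' mirror image. A metabolite significant in both directions at different
#' time points is excluded from both sets.
#'
#' @inheritParams consistent_deg_sets
#' @param min_timepoints minimum number of significant time points.
#' @return list with character vectors `dm0` and `dm1`.
#' @export
recurrent_dm_sets <- function(tables, alpha = 0.05, min_timepoints = 2) {
  if (length(tables) < 2)
    stop("need differential tables for at least two time points")
  feats <- unique(unlist(lapply(tables, `[[`, "feature")))
  n_up <- n_down <- stats::setNames(integer(length(feats)), feats)
  for (tab in tables) {
    sig <- tab$padj < alpha
    n_up[tab$feature] <- n_up[tab$feature] + (sig & tab$log2fc > 0)
    n_down[tab$feature] <- n_down[tab$feature] + (sig & tab$log2fc < 0)
  }
  list(dm0 = feats[n_up >= min_timepoints & n_down == 0],
       dm1 = feats[n_down >= min_timepoints & n_up == 0])
}

#' Group-median trajectories of z-scored features
#'
#' Each feature is z-scored across all samples, then summarised by the
#' per-group median. For a feature set, the set trajectory is the median of
#' its members' group medians.
#'
#' @param mat complete numeric matrix (features x samples).
#' @param design a [study_design()].
#' @param feature_sets optional named list of feature ID vectors.
#' @return matrix of group medians (features or sets x groups), groups in
#'   design order.
#' @export
trajectories <- function(mat, design, feature_sets = NULL) {
  check_design_matches(mat, design)
  mat <- as_plain_matrix(mat)
  if (anyNA(mat)) stop("trajectories need a complete matrix; impute first")
  sds <- apply(mat, 1, stats::sd)
  if (any(sds == 0))
    warning(sum(sds == 0), " zero-variance features given all-zero z-scores")
  z <- (mat - rowMeans(mat)) / ifelse(sds == 0, 1, sds)
  z[sds == 0, ] <- 0
  groups <- design_levels(design)
  med <- sapply(groups, function(g) {
    cols <- intersect(colnames(z), design_samples(design, g))
    apply(z[, cols, drop = FALSE], 1, stats::median)
  })
  med <- matrix(med, nrow = nrow(z),
                dimnames = list(rownames(z), groups))
  if (is.null(feature_sets)) return(med)
  out <- t(sapply(feature_sets, function(members) {
    members <- intersect(members, rownames(med))
    if (!length(members)) return(rep(NA_real_, length(groups)))
    apply(med[members, , drop = FALSE], 2, stats::median)
  }))
  colnames(out) <- groups
  out
}

#' PCA view of samples
#'
#' Keeps genes whose maximum TPM exceeds `tpm_min`, transforms to
#' `log2(TPM + 1)`, centres each gene, and returns sample coordinates on the
#' two leading principal components with explained-variance fractions.
#'
#' @param tpm TPM matrix (genes x samples).
#' @param design a [study_design()] (carried through to the output).
#' @param tpm_min expression filter threshold.
#' @return list with `coords` (samples x 2), `explained` (length-2 fractions
#'   of total variance), `n_genes` retained.
#' @export
pca_view <- function(tpm, design, tpm_min = 5) {
  check_design_matches(tpm, design)
  tpm <- as_plain_matrix(tpm)
  keep <- apply(tpm, 1, max) > tpm_min
  if (sum(keep) < 2)
    stop("fewer than 2 genes pass the TPM filter")
  x <- log2(tpm[keep, , drop = FALSE] + 1)
  xc <- x - rowMeans(x)
  pc <- stats::prcomp(t(xc), center = FALSE, scale. = FALSE)
  vars <- pc$sdev^2
  k <- min(2L, ncol(pc$x))
  coords <- pc$x[, seq_len(k), drop = FALSE]
  if (k < 2) coords <- cbind(coords, PC2 = 0)
  list(coords = coords,
       explained = (vars / sum(vars))[1:2],
       n_genes = sum(keep),
       group = design$group[match(rownames(coords), design$sample)])
}
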