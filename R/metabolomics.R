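#' Detection-limit missingness filter
#'
#' Keeps a metabolite only if every group has at least `min_present`
#' non-missing samples, mirroring the removal of metabolites with too few
#' detected values per time point.
#'
#' @param mat metabolite matrix (features x samples), `NA` = not detected.
#' @param design a [study_design()].
#' @param min_present minimum observed samples required per group.
#' @return list with `matrix` (kept rows) and `removed` (dropped feature
#'   IDs).
#' @export
metabolite_missing_filter <- function(mat, design, min_present = 2) {
  check_design_matches(mat, design, min_per_group = min_present)
  groups <- design_levels(design)
  ok <- rep(TRUE, nrow(mat))
  for (g in groups) {
    cols <- intersect(colnames(mat), design_samples(design, g))
    ok <- ok & rowSums(!is.na(mat[, cols, drop = FALSE])) >= min_present
  }
  kept <- mat[ok, , drop = FALSE]
  list(matrix = kept, removed = rownames(mat)[!ok])
}

#' Per-group k-nearest-neighbour imputation
#'
#' Within each design group independently, a missing value is replaced by
#' the mean of that metabolite in the `k` nearest samples of the same group.
#' Distances are Euclidean over the metabolites observed in both samples;
#' only samples with the target metabolite observed are eligible neighbours,
#' and `k` is capped at the number available. Observed values are never
#' changed.
#'
#' @param mat filtered metabolite matrix ([metabolite_missing_filter()]
#'   applied first: every metabolite needs >=1 observed value per group).
#' @param design a [study_design()].
#' @param k number of neighbours to average.
#' @return complete matrix of the same shape.
#' @export
knn_impute <- function(mat, design, k = 3) {
  check_design_matches(mat, design)
  out <- as_plain_matrix(mat)
  for (g in design_levels(design)) {
    cols <- intersect(colnames(out), design_samples(design, g))
    sub <- out[, cols, drop = FALSE]
    if (!anyNA(sub)) next
    d <- matrix(NA_real_, length(cols), length(cols),
                dimnames = list(cols, cols))
    for (i in seq_along(cols)) for (j in seq_along(cols)) {
      if (i == j) next
      both <- !is.na(sub[, i]) & !is.na(sub[, j])
      if (!any(both)) next
      d[i, j] <- sqrt(sum((sub[both, i] - sub[both, j])^2))
    }
    for (f in which(rowSums(is.na(sub)) > 0)) {
      obs <- which(!is.na(sub[f, ]))
      if (!length(obs))
        stop("metabolite '", rownames(sub)[f], "' has no observed value in ",
             "group '", g, "'; apply the missingness filter first")
      for (s in which(is.na(sub[f, ]))) {
        cand <- obs[!is.na(d[s, obs])]
        if (!length(cand)) cand <- obs  # no co-observed features: group mean
        ord <- cand[order(d[s, cand], cand)]
        use <- ord[seq_len(min(k, length(ord)))]
        sub[f, s] <- mean(sub[f, use])
      }
    }
    out[, cols] <- sub
  }
  out
}

#' Differential metabolite test for one contrast
#'
#' Equal-variance two-sample (Student) t-test on relative peak areas per
#' metabolite; the reported effect is the log2 ratio of group means.
#' P-values are BH-adjusted across tested metabolites.
#'
#' @param mat imputed (complete) metabolite matrix.
#' @param design a [study_design()].
#' @param contrast group label tested against the design's reference.
#' @return differential table (`feature`, `log2fc`, `pvalue`, `padj`,
#'   `contrast`).
#' @export
dm_test <- function(mat, design, contrast) {
  check_design_matches(mat, design)
  if (!contrast %in% design$group)
    stop("contrast group '", contrast, "' absent from design")
  if (anyNA(mat)) stop("dm_test needs an imputed (complete) matrix")
  mat <- as_plain_matrix(mat)
  ref <- design_reference(design)
  s_ref <- intersect(colnames(mat), design_samples(design, ref))
  s_trt <- intersect(colnames(mat), design_samples(design, contrast))
  if (length(s_ref) < 2 || length(s_trt) < 2)
    stop("need >=2 samples on each side of the contrast")
  x <- mat[, s_ref, drop = FALSE]
  y <- mat[, s_trt, drop = FALSE]
  res <- pooled_rows(x, y)
  effect <- log2(rowMeans(y) / rowMeans(x))
  new_differential_table(rownames(mat), effect, res$p, bh_adjust(res$p),
                         paste0(contrast, "_vs_", ref))
}

#' Relative peak area
#'
#' Normalises a metabolite peak area by the internal-standard peak area and
#' the sample amount.
#'
#' @param metabolite_area raw peak area.
#' @param internal_standard_area internal-standard peak area (> 0).
#' @param sample_amount sample amount (> 0).
#' @return relative peak area.
#' @export
relative_peak_area <- function(metabolite_area, internal_standard_area,
                               sample_amount) {
  if (any(internal_standard_area <= 0))
    stop("internal_standard_area must be positive")
  if (any(sample_amount <= 0))
    stop("sample_amount must be positive")
  metabolite_area / (internal_standard_area * sample_amount)
}

#' Mass error in parts per million
#'
#' `(measured - theoretical) / measured * 1e6`.
#'
#' @param measured_mz measured m/z (> 0).
#' @param theoretical_mz theoretical m/z.
#' @return signed mass error in ppm.
#' @export
mass_error_ppm <- function(measured_mz, theoretical_mz) {
  if (any(measured_mz <= 0)) stop("measured_mz must be positive")
  (measured_mz - theoretical_mz) / measured_mz * 1e6
}

#' Annotation tolerance checks
#'
#' Mass tolerance is ±10 ppm for capillary-electrophoresis (CE) mode and
#' ±25 ppm for liquid-chromatography (LC) mode; time tolerance is ±0.5 min
#' on migration time (MT) and ±0.3 min on retention time (RT).
#'
#' @param ppm signed mass error in ppm.
#' @param mode `"CE"` or `"LC"`.
#' @return logical: within tolerance.
#' @export
ppm_within_tolerance <- function(ppm, mode = c("CE", "LC")) {
  mode <- match.arg(mode)
  abs(ppm) <= if (mode == "CE") 10 else 25
}

#' @rdname ppm_within_tolerance
#' @param delta_min signed time difference in minutes.
#' @param time_mode `"MT"` (migration time) or `"RT"` (retention time).
#' @export
time_within_tolerance <- function(delta_min, time_mode = c("MT", "RT")) {
  time_mode <- match.arg(time_mode)
  abs(delta_min) <= if (time_mode == "MT") 0.5 else 0.3
}
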