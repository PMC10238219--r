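#' Omics abundance matrix
#'
#' A feature-by-sample numeric matrix carrying a value kind. Counts must be
#' non-negative integers and complete; TPM and relative peak areas must be
#' non-negative; metabolite and phenotype tables may contain missing values
#' (encoded as `NA`).
#'
#' @param values numeric matrix with unique, non-empty feature rownames and
#'   sample colnames.
#' @param kind one of `"counts"`, `"TPM"`, `"relative_peak_area"`,
#'   `"phenotype"`.
#' @return an `omics_matrix`: the validated matrix with a `value_kind`
#'   attribute.
#' @export
omics_matrix <- function(values,
                         kind = c("counts", "TPM", "relative_peak_area",
                                  "phenotype")) {
  kind <- match.arg(kind)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("matrix must have feature rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicated feature IDs: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicated sample IDs: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "))
  if (kind == "counts") {
    if (anyNA(values))
      stop("counts may not contain missing values")
    if (any(values < 0) || any(values != round(values)))
      stop("counts must be non-negative integers")
  } else if (kind %in% c("TPM", "relative_peak_area")) {
    if (any(values < 0, na.rm = TRUE))
      stop(kind, " values must be non-negative")
    if (kind == "TPM" && anyNA(values))
      stop("TPM may not contain missing values")
  }
  structure(values, value_kind = kind, class = c("omics_matrix", "matrix",
                                                 "array"))
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf("omics_matrix [%s]: %d features x %d samples, %d missing\n",
              attr(x, "value_kind"), nrow(x), ncol(x), sum(is.na(x))))
  invisible(x)
}

value_kind <- function(x) attr(x, "value_kind") %||% "unknown"

`%||%` <- function(a, b) if (is.null(a)) b else a

# strip class/attr for numeric work
as_plain_matrix <- function(x) {
  attr(x, "value_kind") <- NULL
  class(x) <- c("matrix", "array")
  x
}

#' Study design: sample-to-group assignment
#'
#' @param samples character vector of sample IDs.
#' @param groups character vector (same length) of group labels, e.g.
#'   `"control"`, `"d7"`, ... .
#' @param reference the reference (control) group label.
#' @param group_levels optional ordered group labels; defaults to order of
#'   first appearance.
#' @return a `study_design` data frame with columns `sample`, `group` and
#'   attributes `reference`, `group_levels`.
#' @export
study_design <- function(samples, groups, reference,
                         group_levels = unique(groups)) {
  if (length(samples) != length(groups))
    stop("'samples' and 'groups' must have equal length")
  if (anyDuplicated(samples))
    stop("duplicated sample IDs in design")
  if (!reference %in% group_levels)
    stop("reference group '", reference, "' not among group levels")
  if (!all(groups %in% group_levels))
    stop("groups outside 'group_levels': ",
         paste(setdiff(groups, group_levels), collapse = ", "))
  structure(
    data.frame(sample = as.character(samples), group = as.character(groups),
               stringsAsFactors = FALSE),
    reference = reference,
    group_levels = group_levels,
    class = c("study_design", "data.frame"))
}

design_reference <- function(design) attr(design, "reference")
design_levels <- function(design) attr(design, "group_levels")

# samples of one group, in design order
design_samples <- function(design, group) {
  design$sample[design$group == group]
}

check_design_matches <- function(mat, design, min_per_group = NULL) {
  missing <- setdiff(colnames(mat), design$sample)
  if (length(missing))
    stop("samples absent from design: ", paste(missing, collapse = ", "))
  if (!is.null(min_per_group)) {
    tab <- table(design$group[design$sample %in% colnames(mat)])
    bad <- names(tab)[tab < min_per_group]
    if (length(bad))
      stop("groups with fewer than ", min_per_group, " samples: ",
           paste(bad, collapse = ", "))
  }
  invisible(TRUE)
}
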