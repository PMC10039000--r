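#' Construct an expression matrix
#'
#' A light container for a gene-by-sample matrix of non-negative bulk RNA-seq
#' abundances with a declared unit (FPKM or TPM).
#'
#' @param values Numeric matrix, genes in rows (rownames = gene symbols),
#'   samples in columns (colnames = sample ids).
#' @param unit `"FPKM"` or `"TPM"`.
#' @return Object of class `expr_matrix` with fields `values` and `unit`.
#' @export
expr_matrix <- function(values, unit = c("FPKM", "TPM")) {
  unit <- match.arg(unit)
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("expression matrix needs gene rownames and sample colnames")
  }
  if (any(values < 0) || any(!is.finite(values))) {
    stop("expression values must be finite and non-negative")
  }
  structure(list(values = values, unit = unit), class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d genes x %d samples [%s]\n",
              nrow(x$values), ncol(x$values), x$unit))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Read a gene-by-sample expression TSV
#'
#' @param path TSV whose first column holds gene symbols and remaining
#'   columns one sample each.
#' @param unit Unit of the stored values (`"FPKM"` or `"TPM"`).
#' @return An [expr_matrix()].
#' @export
read_expression_matrix <- function(path, unit = c("FPKM", "TPM")) {
  stopifnot(file.exists(path))
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  genes <- df[[1]]
  if (any(duplicated(genes))) stop("duplicated gene symbols in expression matrix")
  m <- as.matrix(df[-1])
  rownames(m) <- genes
  expr_matrix(m, unit = match.arg(unit))
}

#' Read a sample sheet
#'
#' @param path TSV with columns `sample_id` and `cancer_type`.
#' @return Data frame with those two columns.
#' @export
read_sample_sheet <- function(path) {
  stopifnot(file.exists(path))
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "cancer_type") %in% names(df))) {
    stop("sample sheet needs columns 'sample_id' and 'cancer_type'")
  }
  df[c("sample_id", "cancer_type")]
}

#' Convert FPKM to TPM
#'
#' Rescales each sample column so it sums to one million:
#' `tpm(g, s) = fpkm(g, s) * 1e6 / sum_g' fpkm(g', s)`. The conversion is
#' exact when the matrix holds all genes used in the original FPKM
#' normalization; it is idempotent on already-TPM-scaled columns.
#'
#' @param x An [expr_matrix()] with unit FPKM.
#' @return An [expr_matrix()] with unit TPM.
#' @export
fpkm_to_tpm <- function(x) {
  stopifnot(inherits(x, "expr_matrix"))
  if (x$unit != "FPKM") stop("input unit must be FPKM")
  totals <- colSums(x$values)
  if (any(totals <= 0)) {
    stop("all-zero expression column(s): ",
         paste(colnames(x$values)[totals <= 0], collapse = ", "))
  }
  tpm <- sweep(x$values, 2, totals, "/") * 1e6
  expr_matrix(tpm, unit = "TPM")
}

#' Per-group median expression
#'
#' Median TPM of each gene within each sample group (typically cancer type,
#' or cancer type by genotype). For even group sizes the median is the
#' midpoint of the two central order statistics.
#'
#' @param x An [expr_matrix()] (any unit; medians are unit-preserving).
#' @param groups Named character vector mapping sample id to group label;
#'   samples absent from `groups` are dropped.
#' @return Numeric gene-by-group matrix of medians.
#' @export
group_median <- function(x, groups) {
  stopifnot(inherits(x, "expr_matrix"))
  groups <- groups[names(groups) %in% colnames(x$values)]
  lv <- unique(groups)
  if (length(lv) == 0) stop("no samples matched to any group")
  out <- vapply(lv, function(g) {
    cols <- names(groups)[groups == g]
    if (length(cols) == 0) stop("empty group: ", g)
    apply(x$values[, cols, drop = FALSE], 1, median)
  }, numeric(nrow(x$values)))
  out <- matrix(out, nrow = nrow(x$values))
  dimnames(out) <- list(rownames(x$values), lv)
  out
}

#' Filter genes expressed below a TPM floor in most groups
#'
#' A candidate gene is excluded when its median expression falls below
#' `tpm_floor` in strictly more than half of the groups (cancer types): with
#' `unit_count` types, exclusion requires `count(median < tpm_floor) >
#' unit_count / 2`. Candidates missing from the median table are reported,
#' not silently dropped.
#'
#' @param median_table Gene-by-group median matrix from [group_median()].
#' @param candidate_genes Character vector of genes to consider.
#' @param tpm_floor Expression threshold (default 1.0 TPM).
#' @param unit_count Number of groups forming the denominator (defaults to
#'   `ncol(median_table)`).
#' @return List with character vectors `kept`, `excluded`, `missing`.
#' @export
filter_low_expression_genes <- function(median_table, candidate_genes,
                                        tpm_floor = 1.0,
                                        unit_count = ncol(median_table)) {
  stopifnot(tpm_floor > 0, unit_count >= 1)
  present <- candidate_genes[candidate_genes %in% rownames(median_table)]
  missing <- setdiff(candidate_genes, present)
  n_low <- rowSums(median_table[present, , drop = FALSE] < tpm_floor)
  excluded <- present[n_low > unit_count / 2]
  list(kept = setdiff(present, excluded), excluded = excluded, missing = missing)
}
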