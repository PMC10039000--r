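#' Published cohort-A cancer-type summary
#'
#' Characteristics of the 21 TCGA cancer types forming cohort A in the
#' published cross-cancer study: histological class, developmental origin,
#' TP53 mutation rate (% of cases), GOF mutation rate (% of mutations), and
#' the cluster (A1/A2) each type fell into. These printed summary values are
#' the inputs for re-running the cluster-contrast statistics without access
#' to the underlying per-patient data.
#'
#' @return Data frame with columns `cancer_type`, `histology`, `origin`,
#'   `pct_tp53_mutant`, `pct_gof`, `cluster`.
#' @export
cohortA_summary <- function() {
  path <- system.file("extdata", "cohortA_summary.tsv", package = "p53cc",
                      mustWork = TRUE)
  read.delim(path, stringsAsFactors = FALSE)
}

#' Published MKI67 significance counts by cluster
#'
#' Per-cluster tally of cancer types with / without a significant MKI67
#' expression difference between TP53 mutant and wild-type groups, as
#' reported for cohort A (cluster A1: 12 of 17; cluster A2: 1 of 4).
#'
#' @return 2x2 integer matrix, rows = clusters, columns = significant /
#'   not significant.
#' @export
mki67_cluster_counts <- function() {
  path <- system.file("extdata", "mki67_cluster_counts.tsv",
                      package = "p53cc", mustWork = TRUE)
  df <- read.delim(path, stringsAsFactors = FALSE)
  m <- as.matrix(df[, c("significant", "not_significant")])
  rownames(m) <- df$cluster
  m
}
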