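#' Extract genes discriminating two clusters of ratio profiles
#'
#' For each gene, compares its log2 expression ratios across the profiles of
#' cluster 1 versus cluster 2 with a Wilcoxon rank-sum test and keeps genes
#' with `P < alpha`. No multiple-testing correction is applied by default
#' (set `adjust = "BH"` for a Benjamini-Hochberg variant, in which case the
#' adjusted P is thresholded).
#'
#' @param rm Gene-by-profile `ratio_matrix`.
#' @param clusters Named cluster assignment from [cut_k()] with exactly two
#'   distinct labels.
#' @param alpha Significance level (default 0.05).
#' @param mode Wilcoxon mode, `"exact"` (default) or `"normal"`.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return Data frame (`gene`, `statistic`, `p_value`, `significant`),
#'   ordered by P-value; the extracted genes are the rows with
#'   `significant == TRUE`.
#' @export
extract_discriminant_genes <- function(rm, clusters, alpha = 0.05,
                                       mode = c("exact", "normal"),
                                       adjust = c("none", "BH")) {
  mode <- match.arg(mode)
  adjust <- match.arg(adjust)
  labs <- unique(clusters)
  if (length(labs) != 2) stop("exactly two clusters are required")
  c1 <- names(clusters)[clusters == labs[1]]
  c2 <- names(clusters)[clusters == labs[2]]
  stopifnot(all(c(c1, c2) %in% colnames(rm)))
  res <- lapply(rownames(rm), function(g) {
    tr <- wilcoxon_rank_sum(rm[g, c1], rm[g, c2], mode = mode, alpha = alpha)
    data.frame(gene = g, statistic = tr$statistic, p_value = tr$p_value)
  })
  out <- do.call(rbind, res)
  p_use <- if (adjust == "BH") stats::p.adjust(out$p_value, "BH") else out$p_value
  out$significant <- p_use < alpha
  out[order(out$p_value), , drop = FALSE]
}

#' Tally extracted genes by pathway category
#'
#' @param extracted Character vector of extracted gene symbols.
#' @param map A `pathway_map` covering, at least, all extracted genes plus
#'   the background gene set being tallied.
#' @param genes Optional character vector restricting the background to the
#'   analyzed (kept) genes; defaults to all genes in `map`.
#' @return Data frame with one row per category plus a `Total` row:
#'   `category`, `n_genes`, `n_extracted`, `percent` (one decimal).
#' @export
category_tally <- function(extracted, map, genes = map$gene) {
  unmapped <- setdiff(extracted, map$gene)
  if (length(unmapped) > 0) {
    stop("extracted gene(s) not in pathway map: ", paste(unmapped, collapse = ", "))
  }
  if (!all(extracted %in% genes)) {
    stop("extracted gene(s) outside the analyzed gene set")
  }
  map <- map[map$gene %in% genes, , drop = FALSE]
  cats <- pathway_categories()
  n_genes <- vapply(cats, function(cl) sum(map$category == cl), 0L)
  n_ext <- vapply(cats, function(cl)
    sum(map$category == cl & map$gene %in% extracted), 0L)
  out <- data.frame(category = c(cats, "Total"),
                    n_genes = c(n_genes, sum(n_genes)),
                    n_extracted = c(n_ext, sum(n_ext)),
                    stringsAsFactors = FALSE)
  out$percent <- ifelse(out$n_genes > 0,
                        round(100 * out$n_extracted / out$n_genes, 1), NA_real_)
  rownames(out) <- NULL
  out
}

#' Per-cancer-type mutant vs wild-type tests over a gene set
#'
#' For each cancer type, compares the expression values of every gene in
#' `gene_set` between the TP53 mutant and wild-type samples with a Wilcoxon
#' rank-sum test and counts the genes with `P < alpha`. Cancer types with an
#' empty group are skipped with a warning.
#'
#' @param tpm An [expr_matrix()] in TPM.
#' @param genotypes A `p53_genotypes` table.
#' @param gene_set Non-empty character vector of genes.
#' @param types Cancer types to test (default: all in `genotypes`).
#' @param alpha Significance level (default 0.05).
#' @param mode Wilcoxon mode (default `"normal"`: per-type groups are large).
#' @return Data frame (`cancer_type`, `n_tested`, `n_significant`); per-gene
#'   P-values are kept in attribute `details`.
#' @export
per_type_gene_tests <- function(tpm, genotypes, gene_set,
                                types = sort(unique(genotypes$cancer_type)),
                                alpha = 0.05, mode = c("normal", "exact")) {
  mode <- match.arg(mode)
  stopifnot(inherits(tpm, "expr_matrix"), length(gene_set) >= 1)
  absent <- setdiff(gene_set, rownames(tpm$values))
  if (length(absent) > 0) stop("gene(s) missing from expression matrix: ",
                               paste(absent, collapse = ", "))
  details <- list(); rows <- list()
  for (ct in types) {
    mt <- genotypes$sample_id[genotypes$cancer_type == ct &
                                genotypes$genotype == "mutant"]
    wt <- genotypes$sample_id[genotypes$cancer_type == ct &
                                genotypes$genotype == "wildtype"]
    mt <- intersect(mt, colnames(tpm$values))
    wt <- intersect(wt, colnames(tpm$values))
    if (length(mt) == 0 || length(wt) == 0) {
      warning("skipping ", ct, ": empty mutant or wild-type group")
      next
    }
    p <- vapply(gene_set, function(g)
      wilcoxon_rank_sum(tpm$values[g, mt], tpm$values[g, wt],
                        mode = mode)$p_value, numeric(1))
    details[[ct]] <- data.frame(cancer_type = ct, gene = gene_set,
                                p_value = unname(p))
    rows[[ct]] <- data.frame(cancer_type = ct, n_tested = length(gene_set),
                             n_significant = sum(p < alpha))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "details") <- do.call(rbind, details)
  out
}

#' Compare per-type significant-gene counts between two clusters
#'
#' Second-stage contrast: the per-cancer-type counts from
#' [per_type_gene_tests()] are compared between cluster-1 and cluster-2
#' cancer types with a Wilcoxon rank-sum test.
#'
#' @param counts Output of [per_type_gene_tests()].
#' @param clusters Named cluster assignment over cancer types (two labels).
#' @param mode Wilcoxon mode (default `"exact"`; groups are small).
#' @return A `p53cc_test`.
#' @export
compare_counts_between_clusters <- function(counts, clusters,
                                            mode = c("exact", "normal")) {
  mode <- match.arg(mode)
  labs <- unique(clusters)
  if (length(labs) != 2) stop("exactly two clusters are required")
  x <- counts$n_significant[counts$cancer_type %in%
                              names(clusters)[clusters == labs[1]]]
  y <- counts$n_significant[counts$cancer_type %in%
                              names(clusters)[clusters == labs[2]]]
  wilcoxon_rank_sum(x, y, mode = mode)
}

#' Proliferation-marker contrast between clusters
#'
#' Tests, per cancer type, whether the expression of a marker gene (MKI67 by
#' default) differs between TP53 mutant and wild-type samples; then forms
#' the 2x2 contingency of cluster membership against per-type significance
#' and applies Fisher's exact test.
#'
#' @param tpm An [expr_matrix()] in TPM.
#' @param genotypes A `p53_genotypes` table.
#' @param clusters Named cluster assignment over cancer types (two labels,
#'   `A1` listed first by [cut_k()]).
#' @param alpha Significance level (default 0.05).
#' @param gene Marker gene symbol (default `"MKI67"`).
#' @param mode Wilcoxon mode for the per-type tests (default `"normal"`).
#' @return List with `per_type` (data frame: `cancer_type`, `cluster`,
#'   `p_value`, `significant`, `direction`), `table` (2x2 contingency,
#'   rows = clusters, columns = significant yes/no) and `fisher`
#'   (a `p53cc_test`).
#' @export
mki67_contrast <- function(tpm, genotypes, clusters, alpha = 0.05,
                           gene = "MKI67", mode = c("normal", "exact")) {
  mode <- match.arg(mode)
  if (!gene %in% rownames(tpm$values)) {
    stop("marker gene ", gene, " missing from expression matrix")
  }
  types <- names(clusters)
  rows <- lapply(types, function(ct) {
    mt <- intersect(genotypes$sample_id[genotypes$cancer_type == ct &
                                          genotypes$genotype == "mutant"],
                    colnames(tpm$values))
    wt <- intersect(genotypes$sample_id[genotypes$cancer_type == ct &
                                          genotypes$genotype == "wildtype"],
                    colnames(tpm$values))
    if (length(mt) == 0 || length(wt) == 0) {
      stop("empty mutant or wild-type group for ", ct)
    }
    tr <- wilcoxon_rank_sum(tpm$values[gene, mt], tpm$values[gene, wt],
                            mode = mode)
    data.frame(cancer_type = ct, cluster = unname(clusters[ct]),
               p_value = tr$p_value, significant = tr$p_value < alpha,
               direction = ifelse(median(tpm$values[gene, mt]) >=
                                    median(tpm$values[gene, wt]), "up", "down"),
               stringsAsFactors = FALSE)
  })
  per_type <- do.call(rbind, rows)
  labs <- sort(unique(per_type$cluster))
  tab <- matrix(0L, 2, 2, dimnames = list(labs, c("significant", "not_significant")))
  for (cl in labs) {
    sel <- per_type$cluster == cl
    tab[cl, ] <- c(sum(per_type$significant[sel]), sum(!per_type$significant[sel]))
  }
  fis <- if (any(colSums(tab) == 0)) {
    warning("degenerate contingency column; Fisher P = 1")
    new_test_result("fisher_2x2", NA_real_, 1, sum(tab[1, ]), sum(tab[2, ]), alpha)
  } else {
    fisher_2x2(tab, alpha)
  }
  list(per_type = per_type, table = tab, fisher = fis)
}
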