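#' Pipeline parameters
#'
#' One place for every tunable threshold of the analysis, with the study
#' defaults: variant allele-frequency threshold 0.20 (strict), p21-activity
#' loss cutoff 75% of wild-type, expression floor 1.0 TPM, ratio floor 0.01
#' TPM, minimum group size 10, significance level 0.05, k = 2 clusters,
#' exact Wilcoxon for small profile contrasts.
#'
#' @param af_threshold Allele-frequency threshold for recognizing mutations.
#' @param p21_loss_threshold Percent-of-wild-type p21 activity at or below
#'   which a missense variant counts as transactivation-deficient.
#' @param tpm_floor Low-expression filter threshold (TPM).
#' @param ratio_floor Median floor applied inside the log2 ratio (TPM).
#' @param min_group Minimum mutant/wild-type (and GOF/non-GOF) group size.
#' @param alpha Significance level.
#' @param k Number of clusters cut from the cohort-A dendrogram.
#' @param wilcoxon_mode `"exact"` or `"normal"` for profile-level contrasts.
#' @param other_class Genotype consequence of class-`other` variants
#'   (`"excluded"` or `"wildtype"`).
#' @param missing_reference Missense without reference record: `"error"` or
#'   `"retain"`.
#' @return Named list of parameters.
#' @export
pipeline_params <- function(af_threshold = 0.2, p21_loss_threshold = 75,
                            tpm_floor = 1.0, ratio_floor = 0.01,
                            min_group = 10, alpha = 0.05, k = 2,
                            wilcoxon_mode = c("exact", "normal"),
                            other_class = c("excluded", "wildtype"),
                            missing_reference = c("error", "retain")) {
  stopifnot(af_threshold > 0, tpm_floor > 0, ratio_floor > 0,
            min_group >= 1, alpha > 0, alpha < 1, k >= 1)
  list(af_threshold = af_threshold,
       p21_loss_threshold = p21_loss_threshold,
       tpm_floor = tpm_floor, ratio_floor = ratio_floor,
       min_group = min_group, alpha = alpha, k = k,
       wilcoxon_mode = match.arg(wilcoxon_mode),
       other_class = match.arg(other_class),
       missing_reference = match.arg(missing_reference))
}

#' Run the full cross-cancer analysis in memory
#'
#' Executes the whole workflow: sample genotyping, TPM conversion, cohort
#' construction, per-cohort low-expression gene filtering, log2 median-ratio
#' matrices (cohort A: mutant/wild-type per cancer type; cohort B: GOF and
#' non-GOF vs wild-type per cancer type), complete-linkage clustering with
#' Pearson correlation distance and a k-cut of the cohort-A tree, the
#' GOF/non-GOF sibling-pair summary on the cohort-B tree, discriminant-gene
#' extraction with pathway-category tallies, per-type cell-cycle gene tests
#' with the between-cluster second-stage contrast, and the MKI67 contrast.
#'
#' @param expression An [expr_matrix()] (FPKM or TPM).
#' @param sample_sheet Data frame (`sample_id`, `cancer_type`).
#' @param variants Variant table (see [as_variant_table()]).
#' @param ta A `ta_table`.
#' @param pathway_map A `pathway_map`.
#' @param params Parameter list from [pipeline_params()].
#' @return List of class `p53cc_result` with elements `genotypes`,
#'   `cohorts`, `filter_A`, `filter_B`, `ratio_A`, `ratio_B`, `tree_A`,
#'   `tree_B`, `clusters`, `siblings`, `discriminant`, `tally`,
#'   `cellcycle_counts`, `cellcycle_cluster_test`, `mki67`, `summary`.
#' @export
run_analysis <- function(expression, sample_sheet, variants, ta, pathway_map,
                         params = pipeline_params()) {
  genotypes <- genotype_samples(variants, sample_sheet, ta,
                                af_threshold = params$af_threshold,
                                other_class = params$other_class,
                                missing_reference = params$missing_reference)
  tpm <- if (expression$unit == "FPKM") fpkm_to_tpm(expression) else expression
  cohorts <- build_cohorts(genotypes, min_group = params$min_group)
  if (!any(cohorts$in_cohort_A)) stop("cohort A is empty")

  keep <- genotypes$genotype != "excluded"
  filt <- function(in_cohort) {
    types <- cohorts$cancer_type[in_cohort]
    sel <- keep & genotypes$cancer_type %in% types
    grp <- setNames(genotypes$cancer_type[sel], genotypes$sample_id[sel])
    med <- group_median(tpm, grp)
    filter_low_expression_genes(med, pathway_map$gene,
                                tpm_floor = params$tpm_floor,
                                unit_count = length(types))
  }
  filter_A <- filt(cohorts$in_cohort_A)
  ratio_A <- log2_ratio_matrix(tpm, genotypes[keep, ], cohorts, filter_A$kept,
                               mode = "A", floor_tpm = params$ratio_floor)
  tree_A <- complete_linkage(pearson_distance_matrix(ratio_A))
  clusters <- cut_k(tree_A, params$k)

  filter_B <- NULL; ratio_B <- NULL; tree_B <- NULL; siblings <- NULL
  if (any(cohorts$in_cohort_B)) {
    filter_B <- filt(cohorts$in_cohort_B)
    ratio_B <- log2_ratio_matrix(tpm, genotypes[keep, ], cohorts,
                                 filter_B$kept, mode = "B",
                                 floor_tpm = params$ratio_floor)
    tree_B <- complete_linkage(pearson_distance_matrix(ratio_B))
    btypes <- cohorts$cancer_type[cohorts$in_cohort_B]
    pairing <- setNames(c(paste0(btypes, ":nonGOF"), paste0(btypes, ":GOF")),
                        c(paste0(btypes, ":GOF"), paste0(btypes, ":nonGOF")))
    siblings <- sibling_pairs(tree_B, pairing)
  }

  discriminant <- extract_discriminant_genes(ratio_A, clusters,
                                             alpha = params$alpha,
                                             mode = params$wilcoxon_mode)
  extracted <- discriminant$gene[discriminant$significant]
  tally <- category_tally(extracted, pathway_map, genes = filter_A$kept)

  cc_genes <- intersect(
    pathway_map$gene[pathway_map$category == "cell_cycle"], filter_A$kept)
  a_types <- cohorts$cancer_type[cohorts$in_cohort_A]
  cellcycle_counts <- per_type_gene_tests(tpm, genotypes[keep, ], cc_genes,
                                          types = a_types,
                                          alpha = params$alpha)
  cellcycle_cluster_test <-
    compare_counts_between_clusters(cellcycle_counts, clusters,
                                    mode = params$wilcoxon_mode)

  mki67 <- if ("MKI67" %in% rownames(tpm$values)) {
    mki67_contrast(tpm, genotypes[keep, ], clusters, alpha = params$alpha)
  }

  summary <- list(
    n_samples = nrow(genotypes),
    n_mutant = sum(genotypes$genotype == "mutant"),
    n_wildtype = sum(genotypes$genotype == "wildtype"),
    n_excluded = sum(genotypes$genotype == "excluded"),
    cohort_A_types = sum(cohorts$in_cohort_A),
    cohort_B_types = sum(cohorts$in_cohort_B),
    candidate_genes = nrow(pathway_map),
    kept_genes = length(filter_A$kept),
    excluded_genes = filter_A$excluded,
    ratio_A_dim = dim(ratio_A),
    ratio_B_dim = if (!is.null(ratio_B)) dim(ratio_B),
    cluster_sizes = as.integer(table(clusters)[unique(sort(clusters))]),
    n_discriminant = length(extracted),
    sibling_pairs = if (!is.null(siblings)) siblings$count,
    sibling_total = if (!is.null(siblings)) siblings$total,
    mki67_fisher_p = if (!is.null(mki67)) mki67$fisher$p_value
  )

  structure(list(genotypes = genotypes, cohorts = cohorts,
                 filter_A = filter_A, filter_B = filter_B,
                 ratio_A = ratio_A, ratio_B = ratio_B,
                 tree_A = tree_A, tree_B = tree_B,
                 clusters = clusters, siblings = siblings,
                 discriminant = discriminant, tally = tally,
                 cellcycle_counts = cellcycle_counts,
                 cellcycle_cluster_test = cellcycle_cluster_test,
                 mki67 = mki67, summary = summary, params = params),
            class = "p53cc_result")
}

#' @export
print.p53cc_result <- function(x, ...) {
  s <- x$summary
  cat("p53cc analysis\n")
  cat(sprintf("  samples: %d (%d mutant / %d wild-type / %d excluded)\n",
              s$n_samples, s$n_mutant, s$n_wildtype, s$n_excluded))
  cat(sprintf("  cohort A: %d types, cohort B: %d types\n",
              s$cohort_A_types, s$cohort_B_types))
  cat(sprintf("  genes: %d candidates -> %d kept\n",
              s$candidate_genes, s$kept_genes))
  cat(sprintf("  k=%d cut sizes: %s\n", x$params$k,
              paste(s$cluster_sizes, collapse = "/")))
  cat(sprintf("  discriminant genes: %d\n", s$n_discriminant))
  if (!is.null(s$sibling_pairs)) {
    cat(sprintf("  GOF/non-GOF sibling pairs: %d/%d\n",
                s$sibling_pairs, s$sibling_total))
  }
  invisible(x)
}

#' Run the pipeline from input files and write a report bundle
#'
#' File-based front end of [run_analysis()]: reads the four inputs, runs the
#' analysis, and writes all intermediate tables (genotypes, cohort table,
#' ratio matrices, cluster labels, discriminant genes, category tally,
#' per-type counts, MKI67 contrast), Newick dendrograms, a JSON summary and
#' a run log of flooring/exclusion events into `out_dir`.
#'
#' @param expression_path Gene-by-sample TSV.
#' @param sample_sheet_path TSV (`sample_id`, `cancer_type`).
#' @param variants_path MAF-like TSV (see [read_maf()]).
#' @param ta_path Transactivation TSV (see [load_transactivation_table()]).
#' @param pathway_map_path Two-column TSV (gene, category).
#' @param out_dir Output directory (created).
#' @param unit Unit of the expression file (default `"FPKM"`).
#' @param params Parameter list from [pipeline_params()].
#' @return The `p53cc_result`, invisibly.
#' @export
run_pipeline <- function(expression_path, sample_sheet_path, variants_path,
                         ta_path, pathway_map_path, out_dir,
                         unit = "FPKM", params = pipeline_params()) {
  expression <- read_expression_matrix(expression_path, unit = unit)
  sheet <- read_sample_sheet(sample_sheet_path)
  variants <- read_maf(variants_path)
  ta <- load_transactivation_table(ta_path,
                                   p21_loss_threshold = params$p21_loss_threshold)
  map <- load_pathway_map(pathway_map_path)
  res <- run_analysis(expression, sheet, variants, ta, map, params)

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name) {
    write.table(df, file.path(out_dir, name), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  wt(as.data.frame(res$genotypes), "genotypes.tsv")
  wt(as.data.frame(res$cohorts), "cohorts.tsv")
  write_ratio_matrix(res$ratio_A, file.path(out_dir, "ratio_cohortA.tsv"))
  if (!is.null(res$ratio_B)) {
    write_ratio_matrix(res$ratio_B, file.path(out_dir, "ratio_cohortB.tsv"))
  }
  wt(data.frame(profile = names(res$clusters),
                cluster = unname(res$clusters)), "clusters_cohortA.tsv")
  wt(res$discriminant, "discriminant_genes.tsv")
  wt(res$tally, "category_tally.tsv")
  wt(res$cellcycle_counts, "cellcycle_counts.tsv")
  if (!is.null(res$mki67)) wt(res$mki67$per_type, "mki67_per_type.tsv")
  export_newick(res$tree_A, file.path(out_dir, "dendrogram_cohortA.nwk"))
  if (!is.null(res$tree_B)) {
    export_newick(res$tree_B, file.path(out_dir, "dendrogram_cohortB.nwk"))
  }
  jsonlite::write_json(res$summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  log_lines <- c(
    sprintf("excluded samples: %d", res$summary$n_excluded),
    sprintf("genes excluded by expression filter (cohort A): %s",
            paste(res$filter_A$excluded, collapse = ", ")),
    sprintf("floored ratio cells (cohort A): %d",
            nrow(attr(res$ratio_A, "floored"))),
    if (!is.null(res$ratio_B)) {
      sprintf("floored ratio cells (cohort B): %d",
              nrow(attr(res$ratio_B, "floored")))
    })
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(res)
}
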