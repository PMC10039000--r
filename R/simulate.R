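#' Synthetic p53 pathway gene-category map
#'
#' A synthetic stand-in for the published p53-signaling-pathway gene list:
#' 67 genuine p53-pathway gene symbols assigned to the eight functional
#' categories with the published kept-category sizes (14, 9, 23, 4, 4, 2, 6,
#' 1) plus the four low-expression genes (RPRM, TP53AIP1, ADGRB1, IGF1) that
#' the expression filter is expected to remove.
#'
#' @return A `pathway_map` data frame of 67 genes.
#' @export
synthetic_pathway_map <- function() {
  sets <- list(
    cell_cycle = c("CDK1", "CDK2", "CDK4", "CDK6", "CCNB1", "CCNB2", "CCND1",
                   "CCND2", "CCND3", "CCNE1", "CCNE2", "GTSE1", "GADD45A",
                   "SFN", "RPRM"),
    upstream = c("ATM", "ATR", "CHEK1", "CHEK2", "CDKN2A", "GORAB", "TP53",
                 "MDM4", "USP7"),
    apoptosis = c("BAX", "BBC3", "PMAIP1", "BID", "TNFRSF10A", "TNFRSF10B",
                  "FAS", "APAF1", "CASP3", "CASP8", "CASP9", "CYCS", "PIDD1",
                  "PERP", "ZMAT3", "SIVA1", "SHISA5", "TP73", "AIFM2", "EI24",
                  "TP53I3", "BCL2", "BCL2L1", "TP53AIP1"),
    dna_repair = c("DDB2", "RRM2B", "SESN1", "SESN2"),
    angiogenesis_metastasis = c("SERPINB5", "THBS1", "CD82", "SERPINE1",
                                "ADGRB1"),
    igf1_mtor = c("PTEN", "IGFBP3", "IGF1"),
    negative_feedback = c("MDM2", "CCNG1", "CCNG2", "PPM1D", "RFWD2", "SIAH1"),
    exosome = c("STEAP3")
  )
  as_pathway_map(data.frame(
    gene = unlist(sets, use.names = FALSE),
    category = rep(names(sets), lengths(sets)),
    stringsAsFactors = FALSE
  ))
}

#' Genes planted as low-expressed by the generator
#' @return Character vector of the four planted-low gene symbols.
#' @export
planted_low_genes <- function() c("ADGRB1", "IGF1", "RPRM", "TP53AIP1")

#' Synthetic transactivation reference table
#'
#' Builds a per-variant activity table: variants with lost p21
#' transactivation (uniform 0-50% of wild-type) and variants with retained
#' activity (85-130%). The seven non-p21 targets follow the p21 activity
#' linearly with Gaussian noise, mimicking the strong cross-target
#' correlation of measured mutant p53 activities. GOF variants are a flagged
#' subset of the lost-activity missense variants, placed preferentially at
#' hotspot residues. Consumes the current RNG stream.
#'
#' @param n_reduced Number of lost-activity variants (default 30).
#' @param n_retained Number of retained-activity variants (default 10).
#' @param n_gof Number of GOF-flagged variants among the reduced ones
#'   (default 12).
#' @param slope,noise_sd Linear coefficient and noise of non-p21 activities
#'   given p21 activity.
#' @param p21_loss_threshold Passed to [as_ta_table()].
#' @return A `ta_table`.
#' @export
synthetic_transactivation_table <- function(n_reduced = 30, n_retained = 10,
                                            n_gof = 12, slope = 0.9,
                                            noise_sd = 8,
                                            p21_loss_threshold = 75) {
  stopifnot(n_gof <= n_reduced)
  n <- n_reduced + n_retained
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N", "P",
          "Q", "R", "S", "T", "V", "W", "Y")
  hot <- default_hotspots()
  pos <- c(rep(hot, length.out = min(n_gof, length(hot) * 3)),
           sample(setdiff(100:300, hot),
                  n - min(n_gof, length(hot) * 3), replace = FALSE))
  pc <- paste0(sample(aa, n, replace = TRUE), pos, sample(aa, n, replace = TRUE))
  while (any(duplicated(pc))) {
    d <- duplicated(pc)
    pc[d] <- paste0(sample(aa, sum(d), TRUE), pos[d], sample(aa, sum(d), TRUE))
  }
  p21 <- c(runif(n_reduced, 0, 50), runif(n_retained, 85, 130))
  df <- data.frame(protein_change = pc, p21 = p21, stringsAsFactors = FALSE)
  for (tg in setdiff(ta_targets(), "p21")) {
    df[[tg]] <- pmax(0, slope * p21 + rnorm(n, 0, noise_sd))
  }
  df$gof <- c(rep(TRUE, n_gof), rep(FALSE, n - n_gof))
  as_ta_table(df, p21_loss_threshold = p21_loss_threshold)
}

#' Synthetic cohort configuration
#'
#' Captures the study-shaped conditions under which TCGA-like inputs are
#' generated. Defaults emulate the published cohort geometry: 21 cancer
#' types of which 17 belong to planted cluster 1, a 37.2% GOF share among
#' mutants, and mutation-class frequencies matching the reported
#' missense/nonsense/frameshift mix.
#'
#' @param seed Integer RNG seed.
#' @param n_types Number of cancer types (default 21).
#' @param cluster1_fraction Fraction of types in planted cluster 1
#'   (default 17/21).
#' @param samples_per_type Samples per cancer type (default 120).
#' @param mutant_fraction Fraction of samples that are TP53 mutant
#'   (default 0.5).
#' @param gof_fraction Fraction of mutants carrying a GOF variant
#'   (default 0.372).
#' @param class_probs Probabilities of (reduced-activity missense, nonsense,
#'   frameshift) for non-GOF mutants; GOF mutants are always missense.
#' @param excluded_fraction Fraction of samples planted with only a
#'   retained-activity missense, hence genotype `excluded` (default 0.02).
#' @param subthreshold_fraction Fraction of wild-type samples planted with a
#'   sub-threshold variant that must be ignored (default 0.05).
#' @param n_background_genes Non-pathway genes besides MKI67 (default 432,
#'   for 500 genes in total).
#' @param mutant_effect_fold Fold change applied to cell-cycle genes and
#'   MKI67 in mutant samples of cluster-1 types (default 2).
#' @param cluster2_effect_fold Same for cluster-2 types; the default
#'   `mutant_effect_fold^(-1/2)` plants a weaker, opposite-direction
#'   response so both clusters have a coherent (and distinguishable)
#'   signature while the cluster-1 response stays the larger in magnitude.
#'   Equal to 1 (no signal anywhere) when `mutant_effect_fold = 1`.
#' @param type_effect_sd SD (log2) of the per-type mutant response component
#'   shared by GOF and non-GOF mutants of a type (default 0.3).
#' @param noise_sd Per-observation log2 noise SD (default 0.5).
#' @param af_range Allele-frequency interval for planted mutations
#'   (default c(0.25, 0.6), clear of the 0.20 recognition boundary).
#' @param low_gene_log2 Baseline log2 abundance of the planted-low genes
#'   (default -6, well below the 1.0 TPM filter floor).
#' @param design Optional explicit per-type design data frame
#'   (`cancer_type`, `cluster`, `n_gof`, `n_nongof`, `n_wildtype`)
#'   overriding the size/fraction fields.
#' @return List of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1, n_types = 21,
                             cluster1_fraction = 17 / 21,
                             samples_per_type = 120,
                             mutant_fraction = 0.5,
                             gof_fraction = 0.372,
                             class_probs = c(missense = 0.551,
                                             nonsense = 0.229,
                                             frameshift = 0.220),
                             excluded_fraction = 0.02,
                             subthreshold_fraction = 0.05,
                             n_background_genes = 432,
                             mutant_effect_fold = 2,
                             cluster2_effect_fold = mutant_effect_fold^(-1 / 2),
                             type_effect_sd = 0.3,
                             noise_sd = 0.5,
                             af_range = c(0.25, 0.6),
                             low_gene_log2 = -6,
                             design = NULL) {
  cfg <- list(seed = seed, n_types = n_types,
              cluster1_fraction = cluster1_fraction,
              samples_per_type = samples_per_type,
              mutant_fraction = mutant_fraction,
              gof_fraction = gof_fraction,
              class_probs = class_probs / sum(class_probs),
              excluded_fraction = excluded_fraction,
              subthreshold_fraction = subthreshold_fraction,
              n_background_genes = n_background_genes,
              mutant_effect_fold = mutant_effect_fold,
              cluster2_effect_fold = cluster2_effect_fold,
              type_effect_sd = type_effect_sd,
              noise_sd = noise_sd,
              af_range = af_range,
              low_gene_log2 = low_gene_log2,
              design = design)
  fr <- c(cluster1_fraction, mutant_fraction, gof_fraction,
          excluded_fraction, subthreshold_fraction)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]")
  if (mutant_effect_fold <= 0 || cluster2_effect_fold <= 0) {
    stop("effect folds must be positive")
  }
  if (is.null(design) && mutant_fraction * samples_per_type < 1) {
    stop("infeasible config: fewer than one mutant sample per type")
  }
  class(cfg) <- "synthetic_config"
  cfg
}

# per-type sample-count design derived from the config fractions
.default_design <- function(cfg) {
  n1 <- round(cfg$n_types * cfg$cluster1_fraction)
  n_mut <- round(cfg$mutant_fraction * cfg$samples_per_type)
  n_gof <- round(cfg$gof_fraction * n_mut)
  data.frame(
    cancer_type = sprintf("T%02d", seq_len(cfg$n_types)),
    cluster = rep(c(1L, 2L), c(n1, cfg$n_types - n1)),
    n_gof = n_gof,
    n_nongof = n_mut - n_gof,
    n_wildtype = cfg$samples_per_type - n_mut,
    stringsAsFactors = FALSE
  )
}

#' Generate a TCGA-shaped synthetic cohort
#'
#' Produces every input the pipeline consumes - FPKM expression matrix,
#' sample sheet, variant table, transactivation reference, pathway map -
#' plus the planted truth, fully reproducible from the config seed.
#'
#' Expression is log-normal: `2^(baseline_g + effects + N(0, noise_sd))`.
#' Mutant samples of cluster-1 types multiply cell-cycle genes and MKI67 by
#' `mutant_effect_fold`; mutants of cluster-2 types by
#' `cluster2_effect_fold`; every mutant additionally carries its cancer
#' type's own response component (SD `type_effect_sd` per pathway gene),
#' shared by GOF and non-GOF mutants so that subtype profiles of one type
#' stay each other's nearest neighbours. Mutant samples carry one qualifying
#' variant drawn from the reference (GOF catalog variants for planted GOF
#' mutants) with allele frequency uniform on `af_range`; planted `excluded`
#' samples carry only a retained-activity missense; a fraction of wild-type
#' samples carry an ignorable sub-threshold variant.
#'
#' @param cfg A [synthetic_config()].
#' @return List with `expression` (FPKM [expr_matrix()]), `sample_sheet`,
#'   `variants`, `ta` (a `ta_table`), `pathway_map`, and `truth` (list:
#'   `genotypes` data frame with planted `genotype`/`subtype`/`hotspot`,
#'   `clusters` named vector of planted cluster labels per type, `config`).
#' @export
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(cfg$seed)
  design <- if (is.null(cfg$design)) .default_design(cfg) else cfg$design
  need <- c("cancer_type", "cluster", "n_gof", "n_nongof", "n_wildtype")
  stopifnot(all(need %in% names(design)))
  if (any(design$n_gof + design$n_nongof < 1)) {
    stop("infeasible design: a type has no mutant samples")
  }

  ta <- synthetic_transactivation_table()
  map <- synthetic_pathway_map()
  low <- planted_low_genes()
  pathway <- map$gene
  background <- sprintf("BG%04d", seq_len(cfg$n_background_genes))
  genes <- c(pathway, "MKI67", background)
  cc_genes <- c(map$gene[map$category == "cell_cycle"], "MKI67")

  baseline <- c(runif(length(pathway), 3, 9),      # pathway genes
                6,                                  # MKI67
                rnorm(length(background), 5, 2))
  names(baseline) <- genes
  baseline[low] <- cfg$low_gene_log2

  reduced <- ta$protein_change[ta$functional_class == "non_functional"]
  gof_pool <- ta$protein_change[ta$gof]
  nongof_pool <- setdiff(reduced, gof_pool)
  retained_pool <- ta$protein_change[ta$functional_class == "functional"]
  nonsense_pool <- paste0("R", c(196, 213, 306, 342), "*")
  frameshift_pool <- paste0(c("P", "K", "E", "S"), c(58, 120, 224, 261), "fs")

  samples <- list(); variants <- list(); truth_rows <- list()
  expr_cols <- list()
  e_log2 <- setNames(rep(0, length(genes)), genes)

  for (t in seq_len(nrow(design))) {
    ct <- design$cancer_type[t]
    fold <- if (design$cluster[t] == 1) cfg$mutant_effect_fold else
      cfg$cluster2_effect_fold
    cluster_eff <- e_log2
    cluster_eff[cc_genes] <- log2(fold)
    type_eff <- e_log2
    type_eff[c(pathway, "MKI67")] <- rnorm(length(pathway) + 1, 0,
                                           cfg$type_effect_sd)

    n_mut <- design$n_gof[t] + design$n_nongof[t]
    n_wt <- design$n_wildtype[t]
    n_exc <- round(cfg$excluded_fraction * (n_mut + n_wt))
    status <- c(rep("gof", design$n_gof[t]), rep("non_gof", design$n_nongof[t]),
                rep("excluded", n_exc), rep("wildtype", n_wt))
    ids <- sprintf("%s-S%03d", ct, seq_along(status))

    for (i in seq_along(status)) {
      st <- status[i]
      is_mut <- st %in% c("gof", "non_gof")
      mu <- baseline
      if (is_mut) mu <- mu + cluster_eff + type_eff
      expr_cols[[ids[i]]] <- 2^(mu + rnorm(length(genes), 0, cfg$noise_sd))

      pc <- NULL; vclass <- NULL; af <- NULL
      if (st == "gof") {
        pc <- sample(gof_pool, 1); vclass <- "missense"
      } else if (st == "non_gof") {
        vclass <- sample(names(cfg$class_probs), 1, prob = cfg$class_probs)
        pc <- switch(vclass,
                     missense = sample(nongof_pool, 1),
                     nonsense = sample(nonsense_pool, 1),
                     frameshift = sample(frameshift_pool, 1))
      } else if (st == "excluded") {
        pc <- sample(retained_pool, 1); vclass <- "missense"
      } else if (runif(1) < cfg$subthreshold_fraction) {
        pc <- sample(reduced, 1); vclass <- "missense"
        af <- runif(1, 0.02, 0.15)
      }
      if (!is.null(pc)) {
        if (is.null(af)) af <- runif(1, cfg$af_range[1], cfg$af_range[2])
        variants[[length(variants) + 1]] <- data.frame(
          sample_id = ids[i], cancer_type = ct, gene = "TP53",
          protein_change = pc, variant_class = vclass,
          allele_frequency = af, stringsAsFactors = FALSE)
      }
      truth_rows[[length(truth_rows) + 1]] <- data.frame(
        sample_id = ids[i], cancer_type = ct,
        genotype = if (is_mut) "mutant" else st,
        subtype = if (is_mut) st else "na",
        hotspot = is_mut && !is.null(pc) && vclass == "missense" &&
          protein_change_position(pc) %in% default_hotspots(),
        stringsAsFactors = FALSE)
    }
    samples[[ct]] <- data.frame(sample_id = ids, cancer_type = ct,
                                stringsAsFactors = FALSE)
  }

  values <- do.call(cbind, expr_cols)
  rownames(values) <- genes
  truth_geno <- do.call(rbind, truth_rows)
  clusters <- setNames(paste0("A", design$cluster), design$cancer_type)
  list(
    expression = expr_matrix(values, "FPKM"),
    sample_sheet = do.call(rbind, c(samples, make.row.names = FALSE)),
    variants = do.call(rbind, variants),
    ta = ta,
    pathway_map = map,
    truth = list(genotypes = truth_geno, clusters = clusters, config = cfg)
  )
}

#' Study-shaped synthetic fixture
#'
#' A cohort with the published geometry: the 21 cohort-A cancer-type codes,
#' 17 of them in planted cluster 1 (the published cluster-A1 membership), 17
#' types with enough GOF and non-GOF cases to enter cohort B (all but ACC,
#' KICH, MESO, UCEC), 67 candidate pathway genes of which 4 are planted
#' below the expression floor. Group sizes are 20 GOF + 20 non-GOF + 40
#' wild-type for cohort-B types and 4 GOF + 16 non-GOF + 40 wild-type for
#' the rest, large enough for stable medians and small enough for fast runs.
#'
#' @param seed Integer RNG seed (default 1).
#' @param ... Further arguments passed to [synthetic_config()].
#' @return The [generate_cohort()] bundle.
#' @export
paper_shaped_fixture <- function(seed = 1, ...) {
  a1 <- c("ACC", "BLCA", "BRCA", "ESCA", "GBM", "KICH", "LGG", "LIHC",
          "LUAD", "LUSC", "MESO", "OV", "PAAD", "PRAD", "SARC", "STAD",
          "UCEC")
  a2 <- c("CESC", "COAD", "HNSC", "READ")
  types <- c(a1, a2)
  not_b <- c("ACC", "KICH", "MESO", "UCEC")
  design <- data.frame(
    cancer_type = types,
    cluster = rep(c(1L, 2L), c(length(a1), length(a2))),
    n_gof = ifelse(types %in% not_b, 4L, 20L),
    n_nongof = ifelse(types %in% not_b, 16L, 20L),
    n_wildtype = 40L,
    stringsAsFactors = FALSE
  )
  cfg <- synthetic_config(seed = seed, design = design, ...)
  generate_cohort(cfg)
}

#' Write a synthetic cohort bundle to disk
#'
#' Writes the TSV inputs the pipeline reads plus the planted truth as JSON.
#'
#' @param bundle Output of [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ev <- bundle$expression$values
  write.table(data.frame(gene = rownames(ev), ev, check.names = FALSE),
              file.path(dir, "expression_fpkm.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(bundle$sample_sheet, file.path(dir, "sample_sheet.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(bundle$variants, file.path(dir, "variants.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(as.data.frame(bundle$ta), file.path(dir, "transactivation.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(as.data.frame(bundle$pathway_map),
              file.path(dir, "pathway_map.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(genotypes = bundle$truth$genotypes,
                            clusters = as.list(bundle$truth$clusters)),
                       file.path(dir, "truth.json"), auto_unbox = TRUE)
  invisible(dir)
}
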