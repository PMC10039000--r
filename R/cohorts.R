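#' Build the analysis cohorts from sample genotypes
#'
#' Cancer types enter cohort A when they hold at least `min_group` TP53
#' mutant and at least `min_group` wild-type cases; cohort B additionally
#' requires at least `min_group` GOF and `min_group` non-GOF mutant cases.
#' Excluded-genotype samples count nowhere.
#'
#' @param genotypes A `p53_genotypes` table from [genotype_samples()].
#' @param min_group Minimum group size (default 10).
#' @return Data frame of class `cohort_table` with one row per cancer type:
#'   `cancer_type`, `n_mutant`, `n_wildtype`, `n_gof`, `n_nongof`,
#'   `in_cohort_A`, `in_cohort_B`.
#' @export
build_cohorts <- function(genotypes, min_group = 10) {
  stopifnot(min_group >= 1)
  if (any(is.na(genotypes$cancer_type) | genotypes$cancer_type == "")) {
    stop("unknown (empty) cancer type label in genotypes")
  }
  types <- sort(unique(genotypes$cancer_type))
  cnt <- function(cond) {
    vapply(types, function(ct) sum(cond & genotypes$cancer_type == ct), 0L)
  }
  out <- data.frame(
    cancer_type = types,
    n_mutant = cnt(genotypes$genotype == "mutant"),
    n_wildtype = cnt(genotypes$genotype == "wildtype"),
    n_gof = cnt(genotypes$genotype == "mutant" & genotypes$subtype == "gof"),
    n_nongof = cnt(genotypes$genotype == "mutant" & genotypes$subtype == "non_gof"),
    stringsAsFactors = FALSE
  )
  out$in_cohort_A <- out$n_mutant >= min_group & out$n_wildtype >= min_group
  out$in_cohort_B <- out$in_cohort_A & out$n_gof >= min_group &
    out$n_nongof >= min_group
  rownames(out) <- NULL
  class(out) <- c("cohort_table", "data.frame")
  out
}

#' Log2 median expression-ratio matrix
#'
#' For every profile the value of a gene is
#' `log2(max(median_mt, floor_tpm) / max(median_wt, floor_tpm))`, where the
#' medians are taken over the mutant (mode A) or GOF / non-GOF mutant
#' (mode B) samples versus the wild-type samples of one cancer type. Mode A
#' yields one profile per cohort-A cancer type; mode B yields two profiles
#' per cohort-B cancer type, named `<TYPE>:GOF` and `<TYPE>:nonGOF`, both
#' sharing the type's full wild-type denominator. Flooring keeps every cell
#' finite; floored cells are recorded in attribute `floored`.
#'
#' @param tpm An [expr_matrix()] in TPM.
#' @param genotypes A `p53_genotypes` table.
#' @param cohorts A `cohort_table` from [build_cohorts()].
#' @param genes Character vector of (kept) genes forming the rows.
#' @param mode `"A"` (mutant vs wild-type) or `"B"` (subtype vs wild-type).
#' @param floor_tpm Lower bound applied to both medians before the ratio
#'   (default 0.01 TPM).
#' @return Numeric gene-by-profile matrix of class `ratio_matrix`, with
#'   attributes `mode` and `floored` (data frame of floored gene/profile
#'   cells).
#' @export
log2_ratio_matrix <- function(tpm, genotypes, cohorts, genes,
                              mode = c("A", "B"), floor_tpm = 0.01) {
  mode <- match.arg(mode)
  stopifnot(inherits(tpm, "expr_matrix"), floor_tpm > 0)
  if (tpm$unit != "TPM") stop("ratio matrix requires TPM input")
  absent <- setdiff(genes, rownames(tpm$values))
  if (length(absent) > 0) {
    stop("gene(s) absent from expression matrix: ", paste(absent, collapse = ", "))
  }
  types <- cohorts$cancer_type[if (mode == "A") cohorts$in_cohort_A else
    cohorts$in_cohort_B]
  if (length(types) == 0) stop("no cancer types in cohort ", mode)

  med_of <- function(ct, which_geno, which_sub = NULL) {
    keep <- genotypes$cancer_type == ct & genotypes$genotype == which_geno
    if (!is.null(which_sub)) keep <- keep & genotypes$subtype == which_sub
    ids <- genotypes$sample_id[keep]
    ids <- ids[ids %in% colnames(tpm$values)]
    if (length(ids) == 0) stop("no expression samples for ", ct, " ",
                               which_geno, if (!is.null(which_sub)) paste0("/", which_sub))
    apply(tpm$values[genes, ids, drop = FALSE], 1, median)
  }

  profiles <- list()
  for (ct in types) {
    wt <- pmax(med_of(ct, "wildtype"), floor_tpm)
    if (mode == "A") {
      mt <- pmax(med_of(ct, "mutant"), floor_tpm)
      profiles[[ct]] <- log2(mt / wt)
    } else {
      gof <- pmax(med_of(ct, "mutant", "gof"), floor_tpm)
      ngof <- pmax(med_of(ct, "mutant", "non_gof"), floor_tpm)
      profiles[[paste0(ct, ":GOF")]] <- log2(gof / wt)
      profiles[[paste0(ct, ":nonGOF")]] <- log2(ngof / wt)
    }
  }
  rm <- do.call(cbind, profiles)
  rownames(rm) <- genes

  # record flooring events for the run log
  floored <- data.frame(gene = character(0), profile = character(0))
  for (ct in types) {
    groups <- if (mode == "A") list(c(ct, "mutant")) else
      list(c(paste0(ct, ":GOF"), "gof"), c(paste0(ct, ":nonGOF"), "non_gof"))
    wt_raw <- med_of(ct, "wildtype")
    for (g in groups) {
      raw <- if (mode == "A") med_of(ct, "mutant") else med_of(ct, "mutant", g[2])
      hit <- raw < floor_tpm | wt_raw < floor_tpm
      if (any(hit)) {
        floored <- rbind(floored, data.frame(gene = genes[hit], profile = g[1]))
      }
    }
  }
  structure(rm, mode = mode, floored = floored,
            class = c("ratio_matrix", class(rm)))
}

#' Write a ratio matrix as TSV
#'
#' @param rm A `ratio_matrix`.
#' @param path Output path; first column `gene`, then one column per profile.
#' @export
write_ratio_matrix <- function(rm, path) {
  df <- data.frame(gene = rownames(rm), as.data.frame(unclass(rm)),
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
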