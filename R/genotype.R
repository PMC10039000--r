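#' Read a MAF-like variant table
#'
#' Accepts the usual MAF column names (`Tumor_Sample_Barcode`, `Hugo_Symbol`,
#' `HGVSp_Short`, `Variant_Classification`, `t_alt_count`/`t_ref_count`) or the
#' plain names this package writes (`sample_id`, `gene`, `protein_change`,
#' `variant_class`, `allele_frequency`), plus a `cancer_type` column. The
#' allele frequency is computed as `t_alt/(t_alt + t_ref)` when not given
#' directly. Variant classifications are collapsed to
#' missense / nonsense / frameshift / other.
#'
#' @param path Path to a TSV.
#' @return Data frame with columns `sample_id`, `cancer_type`, `gene`,
#'   `protein_change`, `variant_class`, `allele_frequency`.
#' @export
read_maf <- function(path) {
  stopifnot(file.exists(path))
  raw <- read.delim(path, stringsAsFactors = FALSE)
  pick <- function(...) {
    for (nm in c(...)) if (nm %in% names(raw)) return(raw[[nm]])
    NULL
  }
  out <- data.frame(
    sample_id = pick("sample_id", "Tumor_Sample_Barcode"),
    cancer_type = pick("cancer_type", "Cancer_Type"),
    gene = pick("gene", "Hugo_Symbol"),
    protein_change = pick("protein_change", "HGVSp_Short"),
    variant_class = pick("variant_class", "Variant_Classification"),
    stringsAsFactors = FALSE
  )
  af <- pick("allele_frequency", "AF")
  if (is.null(af)) {
    alt <- pick("t_alt_count"); ref <- pick("t_ref_count")
    if (is.null(alt) || is.null(ref)) {
      stop("need allele_frequency or t_alt_count/t_ref_count columns")
    }
    af <- alt / (alt + ref)
  }
  out$allele_frequency <- as.numeric(af)
  as_variant_table(out)
}

# MAF Variant_Classification -> the four classes used here
.collapse_variant_class <- function(x) {
  x <- as.character(x)
  out <- rep("other", length(x))
  out[x %in% c("missense", "Missense_Mutation")] <- "missense"
  out[x %in% c("nonsense", "Nonsense_Mutation")] <- "nonsense"
  out[x %in% c("frameshift", "Frame_Shift_Del", "Frame_Shift_Ins")] <- "frameshift"
  out
}

#' Validate a variant table
#'
#' @param df Data frame with columns `sample_id`, `cancer_type`, `gene`,
#'   `protein_change`, `variant_class`, `allele_frequency`.
#' @return The validated data.frame, protein changes normalized and variant
#'   classes collapsed to missense / nonsense / frameshift / other.
#' @export
as_variant_table <- function(df) {
  need <- c("sample_id", "cancer_type", "gene", "protein_change",
            "variant_class", "allele_frequency")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    stop("variant table missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (any(df$gene == "" | is.na(df$gene))) stop("empty gene symbol in variant table")
  af <- df$allele_frequency
  if (any(is.na(af)) || any(af < 0 | af > 1)) {
    stop("allele_frequency must lie in [0, 1]")
  }
  df$protein_change <- normalize_protein_change(df$protein_change)
  df$variant_class <- .collapse_variant_class(df$variant_class)
  df[need]
}

#' Classify one TP53 variant against the transactivation reference
#'
#' Implements the recognition rule for TP53 variants:
#' * allele frequency at or below `af_threshold` (strictly greater is
#'   required), or variant class `other` -> `ignored`;
#' * nonsense or frameshift above threshold -> `qualifying_mutation`,
#'   irrespective of the activity table;
#' * missense above threshold with a reference record showing lost p21
#'   transactivation (`non_functional`) -> `qualifying_mutation`;
#' * missense above threshold with retained activity ->
#'   `retained_activity_missense`.
#'
#' @param variant_class One of missense / nonsense / frameshift / other
#'   (vectorized).
#' @param protein_change Normalized protein change (vectorized).
#' @param allele_frequency Variant allele frequency in `[0, 1]` (vectorized).
#' @param ta A `ta_table` used to look up missense activity.
#' @param af_threshold Allele-frequency threshold (default 0.20; the
#'   comparison is strict, a variant at exactly the threshold is ignored).
#' @param missing_reference What to do with an above-threshold missense with
#'   no reference record: `"error"` (default) or `"retain"` (treat as
#'   retained-activity missense).
#' @return Character vector in
#'   `{qualifying_mutation, retained_activity_missense, ignored}`.
#' @export
recognize_variant <- function(variant_class, protein_change, allele_frequency,
                              ta, af_threshold = 0.2,
                              missing_reference = c("error", "retain")) {
  missing_reference <- match.arg(missing_reference)
  stopifnot(af_threshold > 0, af_threshold < 1)
  n <- length(variant_class)
  out <- rep("ignored", n)
  above <- allele_frequency > af_threshold
  out[above & variant_class %in% c("nonsense", "frameshift")] <- "qualifying_mutation"
  mis <- which(above & variant_class == "missense")
  if (length(mis) > 0) {
    idx <- match(protein_change[mis], ta$protein_change)
    absent <- is.na(idx)
    if (any(absent) && missing_reference == "error") {
      stop("missense variant(s) without transactivation reference: ",
           paste(unique(protein_change[mis][absent]), collapse = ", "))
    }
    cls <- rep("retained_activity_missense", length(mis))
    cls[!absent & ta$functional_class[idx] == "non_functional"] <- "qualifying_mutation"
    out[mis] <- cls
  }
  out
}

#' Assign each sample a TP53 genotype
#'
#' Every sample in `sample_sheet` receives one of three genotypes:
#' * `mutant` if it carries at least one qualifying TP53 mutation
#'   (see [recognize_variant()]);
#' * `excluded` if its only recognized TP53 variants are retained-activity
#'   missense mutations (or, by default, class-`other` variants above the
#'   allele-frequency threshold);
#' * `wildtype` if it has no TP53 variants above threshold.
#'
#' Mutant samples get a subtype: `gof` when any qualifying variant's protein
#' change is flagged gain-of-function in the reference catalog, otherwise
#' `non_gof`; and a hotspot flag when any qualifying missense falls on a
#' hotspot residue.
#'
#' @param variants Variant table (see [as_variant_table()]); genes other than
#'   TP53 are ignored.
#' @param sample_sheet Data frame (`sample_id`, `cancer_type`) listing every
#'   sample in the cohort, including samples without any variant row.
#' @param ta A `ta_table`.
#' @inheritParams recognize_variant
#' @param hotspots Integer residue positions counted as hotspots.
#' @param other_class Genotype consequence of an above-threshold class-`other`
#'   variant (splice, in-frame indel): `"excluded"` (default) or `"wildtype"`.
#' @return Data frame of class `p53_genotypes` with columns `sample_id`,
#'   `cancer_type`, `genotype`, `subtype` (`gof`/`non_gof`/`na`), `hotspot`,
#'   `n_qualifying`; the qualifying variant rows are kept in attribute
#'   `qualifying_variants`.
#' @export
genotype_samples <- function(variants, sample_sheet, ta,
                             af_threshold = 0.2,
                             hotspots = default_hotspots(),
                             other_class = c("excluded", "wildtype"),
                             missing_reference = c("error", "retain")) {
  other_class <- match.arg(other_class)
  missing_reference <- match.arg(missing_reference)
  variants <- as_variant_table(variants)
  stopifnot(all(c("sample_id", "cancer_type") %in% names(sample_sheet)))
  if (any(duplicated(sample_sheet$sample_id))) {
    dup <- unique(sample_sheet$sample_id[duplicated(sample_sheet$sample_id)])
    stop("duplicated sample_id in sample sheet: ", paste(dup, collapse = ", "))
  }
  # a sample must not carry conflicting cancer-type labels
  chk <- unique(variants[c("sample_id", "cancer_type")])
  if (any(duplicated(chk$sample_id))) {
    stop("conflicting cancer_type labels within sample(s): ",
         paste(unique(chk$sample_id[duplicated(chk$sample_id)]), collapse = ", "))
  }
  sheet_type <- setNames(sample_sheet$cancer_type, sample_sheet$sample_id)
  known <- variants$sample_id %in% sample_sheet$sample_id
  if (!all(known)) {
    stop("variant rows for sample(s) absent from the sample sheet: ",
         paste(unique(variants$sample_id[!known]), collapse = ", "))
  }
  mismatch <- sheet_type[variants$sample_id] != variants$cancer_type
  if (any(mismatch)) {
    stop("cancer_type in variant table disagrees with sample sheet for: ",
         paste(unique(variants$sample_id[mismatch]), collapse = ", "))
  }

  tp53 <- variants[variants$gene == "TP53", , drop = FALSE]
  tp53$status <- recognize_variant(tp53$variant_class, tp53$protein_change,
                                   tp53$allele_frequency, ta,
                                   af_threshold = af_threshold,
                                   missing_reference = missing_reference)
  above <- tp53$allele_frequency > af_threshold

  qual <- tp53[tp53$status == "qualifying_mutation", , drop = FALSE]
  qual$gof <- qual$protein_change %in% ta$protein_change[isTRUE_v(ta$gof)]
  qual$hotspot <- qual$variant_class == "missense" &
    protein_change_position(qual$protein_change) %in% hotspots

  has_qual <- unique(qual$sample_id)
  has_retained <- unique(tp53$sample_id[tp53$status == "retained_activity_missense"])
  has_other <- unique(tp53$sample_id[above & tp53$variant_class == "other"])

  ids <- sample_sheet$sample_id
  genotype <- rep("wildtype", length(ids))
  if (other_class == "excluded") genotype[ids %in% has_other] <- "excluded"
  genotype[ids %in% has_retained] <- "excluded"
  genotype[ids %in% has_qual] <- "mutant"

  gof_samples <- unique(qual$sample_id[qual$gof])
  hot_samples <- unique(qual$sample_id[qual$hotspot])
  subtype <- ifelse(genotype == "mutant",
                    ifelse(ids %in% gof_samples, "gof", "non_gof"), "na")
  hotspot <- genotype == "mutant" & ids %in% hot_samples
  nq <- table(factor(qual$sample_id, levels = ids))

  out <- data.frame(sample_id = ids,
                    cancer_type = sample_sheet$cancer_type,
                    genotype = genotype, subtype = subtype,
                    hotspot = hotspot,
                    n_qualifying = as.integer(nq),
                    stringsAsFactors = FALSE)
  attr(out, "qualifying_variants") <-
    qual[c("sample_id", "cancer_type", "protein_change", "variant_class",
           "allele_frequency", "gof", "hotspot")]
  class(out) <- c("p53_genotypes", "data.frame")
  out
}

# logical vector with NA -> FALSE
isTRUE_v <- function(x) !is.na(x) & x

#' Genotype and mutation-class summary counts
#'
#' Tallies sample genotypes and qualifying-mutation classes, overall or per
#' cancer type. Percentage shares are per qualifying mutation (variant class,
#' GOF/non-GOF and hotspot shares all use the number of qualifying mutations
#' as denominator; GOF vs non-GOF is compared across all mutation variants,
#' not mutant cases). Shares are `NA` when their denominator is zero.
#'
#' @param genotypes A `p53_genotypes` table from [genotype_samples()].
#' @param by Either `"overall"` (default) or `"cancer_type"`.
#' @return Data frame of sample counts (`n_samples`, `n_mutant`,
#'   `n_wildtype`, `n_excluded`, `n_gof_cases`, `n_nongof_cases`), qualifying
#'   mutation counts (`n_missense`, `n_nonsense`, `n_frameshift`, `n_gof`,
#'   `n_nongof`, `n_hotspot`) and shares in percent (`pct_missense`,
#'   `pct_nonsense`, `pct_frameshift`, `pct_gof`, `pct_nongof`,
#'   `pct_hotspot`), rounded to one decimal.
#' @export
genotype_counts <- function(genotypes, by = c("overall", "cancer_type")) {
  by <- match.arg(by)
  stopifnot(nrow(genotypes) > 0)
  qual <- attr(genotypes, "qualifying_variants")
  groups <- if (by == "overall") list(all = genotypes) else
    split(as.data.frame(genotypes), genotypes$cancer_type)
  one <- function(g) {
    q <- qual[qual$sample_id %in% g$sample_id, , drop = FALSE]
    n_q <- nrow(q)
    pct <- function(num, den) if (den > 0) round(100 * num / den, 1) else NA_real_
    data.frame(
      n_samples = nrow(g),
      n_mutant = sum(g$genotype == "mutant"),
      n_wildtype = sum(g$genotype == "wildtype"),
      n_excluded = sum(g$genotype == "excluded"),
      n_gof_cases = sum(g$genotype == "mutant" & g$subtype == "gof"),
      n_nongof_cases = sum(g$genotype == "mutant" & g$subtype == "non_gof"),
      n_missense = sum(q$variant_class == "missense"),
      n_nonsense = sum(q$variant_class == "nonsense"),
      n_frameshift = sum(q$variant_class == "frameshift"),
      n_gof = sum(q$gof),
      n_nongof = sum(!q$gof),
      n_hotspot = sum(q$hotspot),
      pct_missense = pct(sum(q$variant_class == "missense"), n_q),
      pct_nonsense = pct(sum(q$variant_class == "nonsense"), n_q),
      pct_frameshift = pct(sum(q$variant_class == "frameshift"), n_q),
      pct_gof = pct(sum(q$gof), n_q),
      pct_nongof = pct(sum(!q$gof), n_q),
      pct_hotspot = pct(sum(q$hotspot), n_q)
    )
  }
  out <- do.call(rbind, lapply(groups, one))
  out <- cbind(data.frame(group = names(groups), stringsAsFactors = FALSE), out)
  rownames(out) <- NULL
  out
}
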