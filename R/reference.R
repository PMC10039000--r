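#' Promoter targets of the transactivation reference
#'
#' The eight p53 target promoters on which mutant p53 transcriptional activity
#' is reported, as percent of wild-type activity.
#'
#' @return Character vector of the eight target names.
#' @export
ta_targets <- function() {
  c("p21", "MDM2", "BAX", "14-3-3s", "AIP1", "GADD45", "NOXA", "p53R2")
}

#' Pathway category labels
#'
#' The eight functional categories into which p53-signaling-pathway genes are
#' classified: one upstream category and seven downstream functional
#' categories.
#'
#' @return Character vector of the eight category labels.
#' @export
pathway_categories <- function() {
  c("cell_cycle", "upstream", "apoptosis", "dna_repair",
    "angiogenesis_metastasis", "igf1_mtor", "negative_feedback", "exosome")
}

#' Default TP53 hotspot residues
#'
#' Codon positions of the six classical TP53 mutational hotspots
#' (R175, G245, R248, R249, R273, R282).
#'
#' @return Integer vector of residue positions.
#' @export
default_hotspots <- function() {
  c(175L, 245L, 248L, 249L, 273L, 282L)
}

#' Normalize a protein-change string
#'
#' Strips an HGVS "p." prefix and upper-cases simple substitution strings so
#' that database dialects ("p.R175H", "r175h") compare equal. Frameshift
#' notations (e.g. "E224Kfs*5") keep their suffix verbatim after the prefix is
#' removed.
#'
#' @param x Character vector of protein changes.
#' @return Normalized character vector.
#' @export
normalize_protein_change <- function(x) {
  x <- sub("^p\\.", "", trimws(as.character(x)))
  simple <- grepl("^[A-Za-z][0-9]+[A-Za-z*]$", x)
  x[simple] <- toupper(x[simple])
  x
}

#' Residue position of a protein change
#'
#' @param x Character vector of (normalized) protein changes.
#' @return Integer vector of residue positions (NA where none can be parsed).
#' @export
protein_change_position <- function(x) {
  m <- regmatches(x, regexpr("^[A-Za-z]([0-9]+)", x))
  pos <- rep(NA_integer_, length(x))
  has <- lengths(regmatches(x, gregexpr("^[A-Za-z][0-9]+", x))) > 0
  pos[has] <- as.integer(sub("^[A-Za-z]", "", m))
  pos
}

#' Load a transactivation reference table
#'
#' Reads a TSV of per-variant mutant p53 transcriptional activities
#' (percent of wild-type) on the eight target promoters, with a
#' gain-of-function flag. A `functional_class` column
#' (functional / partially_functional / non_functional / unknown) is used if
#' present; otherwise the class is derived from the p21 activity column:
#' `non_functional` when p21 activity is at or below `p21_loss_threshold`
#' (percent of wild-type), `functional` above it, `unknown` when missing.
#'
#' @param path Path to a TSV with header columns `protein_change`, the eight
#'   targets of [ta_targets()] (`14-3-3s` may be written `X14.3.3s` by R's
#'   column mangling; both are accepted), and logical `gof`.
#' @param p21_loss_threshold Percent-of-wild-type p21 activity at or below
#'   which a missense variant is considered to have lost transactivation
#'   (default 75, just under the wild-type range).
#' @return A data.frame of class `ta_table`: one row per variant, columns
#'   `protein_change`, the eight activities, `gof`, `functional_class`.
#'   The threshold used is kept as attribute `p21_loss_threshold`.
#' @export
load_transactivation_table <- function(path, p21_loss_threshold = 75) {
  stopifnot(file.exists(path))
  raw <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  names(raw)[names(raw) %in% c("X14.3.3s", "14.3.3s", "X14_3_3s")] <- "14-3-3s"
  as_ta_table(raw, p21_loss_threshold = p21_loss_threshold)
}

#' Build a transactivation table from a data.frame
#'
#' @param df Data frame with the columns described in
#'   [load_transactivation_table()].
#' @inheritParams load_transactivation_table
#' @return A validated `ta_table` data.frame.
#' @export
as_ta_table <- function(df, p21_loss_threshold = 75) {
  targets <- ta_targets()
  missing_cols <- setdiff(c("protein_change", targets, "gof"), names(df))
  if (length(missing_cols) > 0) {
    stop("transactivation table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  df$protein_change <- normalize_protein_change(df$protein_change)
  bad <- !grepl("^[A-Z][0-9]+[A-Z*]$", df$protein_change)
  if (any(bad)) {
    stop("malformed protein change in transactivation table row(s) ",
         paste(which(bad), collapse = ", "), ": ",
         paste(unique(df$protein_change[bad]), collapse = ", "))
  }
  dup <- duplicated(df$protein_change)
  if (any(dup)) {
    stop("duplicate protein_change in transactivation table: ",
         paste(unique(df$protein_change[dup]), collapse = ", "))
  }
  for (tg in targets) {
    df[[tg]] <- as.numeric(df[[tg]])
    if (any(df[[tg]] < 0, na.rm = TRUE)) {
      stop("negative activity values for target ", tg)
    }
  }
  df$gof <- as.logical(df$gof)
  if (is.null(df$functional_class)) {
    df$functional_class <- ifelse(
      is.na(df$p21), "unknown",
      ifelse(df$p21 <= p21_loss_threshold, "non_functional", "functional"))
  } else {
    ok <- df$functional_class %in%
      c("functional", "partially_functional", "non_functional", "unknown")
    if (!all(ok)) stop("invalid functional_class value(s)")
  }
  df <- df[c("protein_change", targets, "gof", "functional_class")]
  attr(df, "p21_loss_threshold") <- p21_loss_threshold
  class(df) <- c("ta_table", "data.frame")
  df
}

#' Cross-target activity correlations
#'
#' Pearson correlation of the activity of mutant p53 on a reference target
#' (p21 by default) with its activity on each other target, across variants.
#' Missing activities are excluded pairwise; the two-sided P-value comes from
#' the usual t-transform of r.
#'
#' @param ta A `ta_table`.
#' @param reference_target Name of the reference target (default "p21").
#' @return Data frame with columns `target`, `r`, `p_value`, `n`.
#' @export
activity_correlations <- function(ta, reference_target = "p21") {
  targets <- ta_targets()
  if (!reference_target %in% targets) {
    stop("unknown reference target: ", reference_target)
  }
  others <- setdiff(targets, reference_target)
  x <- ta[[reference_target]]
  res <- lapply(others, function(tg) {
    y <- ta[[tg]]
    keep <- !is.na(x) & !is.na(y)
    if (sum(keep) < 3) stop("fewer than 3 complete pairs for target ", tg)
    if (stats::sd(x[keep]) == 0 || stats::sd(y[keep]) == 0) {
      stop("correlation undefined (zero variance) for target ", tg)
    }
    ct <- cor.test(x[keep], y[keep], method = "pearson")
    data.frame(target = tg, r = unname(ct$estimate),
               p_value = ct$p.value, n = sum(keep))
  })
  do.call(rbind, res)
}

#' Load a pathway gene-category map
#'
#' @param path Two-column TSV (`gene`, `category`) assigning each
#'   p53-signaling-pathway gene to exactly one of the eight categories of
#'   [pathway_categories()].
#' @return Data frame of class `pathway_map` with columns `gene`, `category`.
#' @export
load_pathway_map <- function(path) {
  stopifnot(file.exists(path))
  df <- read.delim(path, stringsAsFactors = FALSE)
  as_pathway_map(df)
}

#' Validate a pathway gene-category map
#'
#' @param df Data frame with columns `gene` and `category`.
#' @return Validated `pathway_map` data.frame.
#' @export
as_pathway_map <- function(df) {
  if (!all(c("gene", "category") %in% names(df))) {
    stop("pathway map needs columns 'gene' and 'category'")
  }
  if (any(df$gene == "" | is.na(df$gene))) stop("empty gene symbol in pathway map")
  bad <- !df$category %in% pathway_categories()
  if (any(bad)) {
    stop("unknown pathway categories: ",
         paste(unique(df$category[bad]), collapse = ", "))
  }
  if (any(duplicated(df$gene))) {
    stop("gene(s) mapped to more than one category: ",
         paste(unique(df$gene[duplicated(df$gene)]), collapse = ", "))
  }
  df <- df[c("gene", "category")]
  class(df) <- c("pathway_map", "data.frame")
  df
}
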