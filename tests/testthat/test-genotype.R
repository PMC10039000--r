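test_that("variant recognition applies the strict AF threshold and activity rule", {
  ta <- tiny_ta()
  rec <- function(...) recognize_variant(..., ta = ta)
  expect_equal(rec("missense", "R175H", 0.45), "qualifying_mutation")
  expect_equal(rec("nonsense", "R196*", 0.35), "qualifying_mutation")
  expect_equal(rec("frameshift", "E224fs", 0.35), "qualifying_mutation")
  expect_equal(rec("missense", "R175H", 0.15), "ignored")
  expect_equal(rec("missense", "R175H", 0.20), "ignored")   # boundary is strict
  expect_equal(rec("missense", "P72R", 0.45), "retained_activity_missense")
  expect_equal(rec("other", "X100Y", 0.45), "ignored")
  expect_error(rec("missense", "Q999Q", 0.45), "without transactivation")
  expect_equal(recognize_variant("missense", "Q999Q", 0.45, ta,
                                 missing_reference = "retain"),
               "retained_activity_missense")
})

test_that("samples partition into mutant / wildtype / excluded with subtype flags", {
  ta <- tiny_ta()
  sheet <- sheet_of(paste0("S", 1:6), "AA")
  vars <- rbind(
    vrow("S2", pc = "R273H", af = 0.5),                     # GOF hotspot
    vrow("S3", pc = "P72R", af = 0.5),                      # retained only
    vrow("S4", pc = "Y220C", af = 0.5),                     # non-GOF, non-hotspot
    vrow("S5", pc = "R175H", af = 0.1),                     # sub-threshold
    vrow("S6", pc = "X100Y", vclass = "other", af = 0.5))   # splice-like
  g <- genotype_samples(vars, sheet, ta)
  expect_setequal(g$genotype, c("wildtype", "mutant", "excluded"))
  gl <- setNames(g$genotype, g$sample_id)
  expect_equal(unname(gl[c("S1", "S2", "S3", "S4", "S5", "S6")]),
               c("wildtype", "mutant", "excluded", "mutant", "wildtype",
                 "excluded"))
  expect_equal(g$subtype[g$sample_id == "S2"], "gof")
  expect_true(g$hotspot[g$sample_id == "S2"])
  expect_equal(g$subtype[g$sample_id == "S4"], "non_gof")
  expect_false(g$hotspot[g$sample_id == "S4"])
  expect_true(all(g$subtype[g$genotype != "mutant"] == "na"))
  # class-`other` variants can be routed to wildtype instead
  g2 <- genotype_samples(vars, sheet, ta, other_class = "wildtype")
  expect_equal(g2$genotype[g2$sample_id == "S6"], "wildtype")
})

test_that("conflicting cancer-type labels within a sample are an input error", {
  ta <- tiny_ta()
  vars <- rbind(vrow("S1", type = "AA"), vrow("S1", type = "BB"))
  expect_error(genotype_samples(vars, sheet_of("S1", "AA"), ta), "conflicting")
})

test_that("raising the AF threshold never promotes a sample to mutant", {
  ta <- tiny_ta()
  set.seed(11)
  n <- 120
  sheet <- sheet_of(paste0("S", 1:n), "AA")
  vars <- do.call(rbind, lapply(1:n, function(i) {
    vrow(paste0("S", i),
         pc = sample(c("R175H", "R273H", "Y220C", "P72R", "R196*"), 1),
         vclass = sample(c("missense", "missense", "nonsense"), 1),
         af = runif(1))
  }))
  vars$variant_class[!grepl("\\*$", vars$protein_change) &
                       vars$variant_class == "nonsense"] <- "missense"
  vars$variant_class[grepl("\\*$", vars$protein_change)] <- "nonsense"
  thresholds <- c(0.1, 0.3, 0.5, 0.7)
  muts <- lapply(thresholds, function(t) {
    g <- genotype_samples(vars, sheet, ta, af_threshold = t)
    g$sample_id[g$genotype == "mutant"]
  })
  for (i in seq_along(thresholds)[-1]) {
    expect_true(all(muts[[i]] %in% muts[[i - 1]]))
  }
})

test_that("planted genotypes are recovered exactly off the AF boundary", {
  b <- generate_cohort(synthetic_config(seed = 5, n_types = 4,
                                        samples_per_type = 40))
  g <- genotype_samples(b$variants, b$sample_sheet, b$ta)
  truth <- b$truth$genotypes
  m <- merge(as.data.frame(g), truth, by = c("sample_id", "cancer_type"))
  expect_equal(nrow(m), nrow(truth))
  expect_equal(m$genotype.x, m$genotype.y)
  expect_equal(m$subtype.x, m$subtype.y)
  expect_equal(m$hotspot.x, m$hotspot.y)
})

test_that("mutation-class and GOF shares use qualifying-mutation denominators", {
  ta <- tiny_ta()
  counts <- c(missense = 2257L, nonsense = 452L, frameshift = 433L)
  n_gof <- 1169L
  n <- sum(counts)
  pcs <- character(n); cls <- character(n)
  cls[1:counts[1]] <- "missense"
  pcs[1:n_gof] <- "R175H"                                   # GOF catalog
  pcs[(n_gof + 1):counts[1]] <- "Y220C"                     # reduced, non-GOF
  cls[(counts[1] + 1):(counts[1] + counts[2])] <- "nonsense"
  pcs[(counts[1] + 1):(counts[1] + counts[2])] <- "R196*"
  cls[(counts[1] + counts[2] + 1):n] <- "frameshift"
  pcs[(counts[1] + counts[2] + 1):n] <- "E224fs"
  ids <- sprintf("S%04d", seq_len(n))
  vars <- data.frame(sample_id = ids, cancer_type = "AA", gene = "TP53",
                     protein_change = pcs, variant_class = cls,
                     allele_frequency = 0.5, stringsAsFactors = FALSE)
  g <- genotype_samples(vars, sheet_of(ids, "AA"), ta)
  gc <- genotype_counts(g)
  expect_equal(gc$pct_missense, 71.8)
  expect_equal(gc$pct_nonsense, 14.4)
  expect_equal(gc$pct_frameshift, 13.8)
  expect_equal(gc$pct_gof, 37.2)
  expect_equal(gc$pct_gof + gc$pct_nongof, 100)
})

test_that("all-wildtype cohorts report undefined shares", {
  ta <- tiny_ta()
  g <- genotype_samples(vrow("S1", af = 0.05), sheet_of(c("S1", "S2"), "AA"), ta)
  gc <- genotype_counts(g)
  expect_equal(gc$n_mutant, 0)
  expect_true(is.na(gc$pct_missense))
  expect_true(is.na(gc$pct_gof))
})

test_that("MAF column dialects are accepted and AF derived from read counts", {
  path <- tempfile(fileext = ".tsv")
  df <- data.frame(Tumor_Sample_Barcode = c("S1", "S2"),
                   cancer_type = "AA", Hugo_Symbol = "TP53",
                   HGVSp_Short = c("p.R175H", "p.R196*"),
                   Variant_Classification = c("Missense_Mutation",
                                              "Nonsense_Mutation"),
                   t_alt_count = c(30, 10), t_ref_count = c(70, 90))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  v <- read_maf(path)
  expect_equal(v$protein_change, c("R175H", "R196*"))
  expect_equal(v$variant_class, c("missense", "nonsense"))
  expect_equal(v$allele_frequency, c(0.3, 0.1))
})
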