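test_that("exact rank-sum p-values match small enumerations", {
  expect_equal(wilcoxon_rank_sum(c(1, 2), c(1, 2), mode = "exact")$p_value, 1)
  expect_equal(wilcoxon_rank_sum(c(1, 2), c(3, 4), mode = "exact")$p_value,
               1 / 3, tolerance = 1e-12)
  expect_error(wilcoxon_rank_sum(numeric(0), 1), "non-empty")
})

test_that("exact mode agrees with wilcox.test (no ties) and enumeration (ties)", {
  set.seed(31)
  for (i in 1:20) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    x <- rnorm(n1); y <- rnorm(n2)     # continuous, tie-free
    mine <- wilcoxon_rank_sum(x, y, mode = "exact")$p_value
    ref <- wilcox.test(x, y, exact = TRUE)$p.value
    expect_equal(mine, ref, tolerance = 1e-10)
  }
  for (i in 1:20) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    x <- sample(1:4, n1, replace = TRUE)   # heavy ties
    y <- sample(1:4, n2, replace = TRUE)
    mine <- wilcoxon_rank_sum(x, y, mode = "exact")$p_value
    expect_equal(mine, oracle_wilcoxon_exact(x, y), tolerance = 1e-10)
  }
})

test_that("exact p is symmetric under swapping the two groups", {
  set.seed(32)
  for (i in 1:10) {
    x <- sample(1:6, sample(2:5, 1), replace = TRUE)
    y <- sample(1:6, sample(2:5, 1), replace = TRUE)
    expect_equal(wilcoxon_rank_sum(x, y, mode = "exact")$p_value,
                 wilcoxon_rank_sum(y, x, mode = "exact")$p_value)
  }
})

test_that("normal mode matches the closed-form z without continuity correction", {
  set.seed(33)
  x <- rnorm(9); y <- rnorm(5)
  mine <- wilcoxon_rank_sum(x, y, mode = "normal")
  ref <- wilcox.test(x, y, exact = FALSE, correct = FALSE)$p.value
  expect_equal(mine$p_value, ref, tolerance = 1e-10)
  W <- sum(rank(c(x, y))[1:9])
  z <- (W - 9 * 15 / 2) / sqrt(9 * 5 * 15 / 12)
  expect_equal(mine$p_value, 2 * pnorm(-abs(z)))
})

test_that("2x2 Fisher matches the brute-force hypergeometric oracle", {
  expect_equal(fisher_2x2(rbind(c(1, 1), c(1, 1)))$p_value, 1)
  expect_equal(fisher_2x2(rbind(c(5, 0), c(0, 5)))$p_value, 2 / 252,
               tolerance = 1e-12)
  expect_warning(p0 <- fisher_2x2(rbind(c(0, 0), c(3, 4)))$p_value, "zero margin")
  expect_equal(p0, 1)
  set.seed(41)
  for (i in 1:40) {
    tab <- matrix(sample(0:6, 4, replace = TRUE), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(fisher_2x2(tab)$p_value, oracle_fisher_2x2(tab),
                 tolerance = 1e-9)
  }
})

test_that("r x c Fisher matches full enumeration and its pmf sums to one", {
  tab <- rbind(c(3, 7, 7), c(1, 1, 2))      # origins-by-cluster shape
  en <- oracle_rxc_tables(rowSums(tab), colSums(tab))
  expect_equal(sum(en$prob), 1, tolerance = 1e-12)
  expect_equal(fisher_rxc(tab)$p_value, oracle_fisher_rxc(tab),
               tolerance = 1e-9)
  set.seed(42)
  for (i in 1:10) {
    tab_i <- matrix(sample(0:4, 6, replace = TRUE), 2)
    if (any(rowSums(tab_i) == 0) || any(colSums(tab_i) == 0)) next
    en_i <- oracle_rxc_tables(rowSums(tab_i), colSums(tab_i))
    expect_equal(sum(en_i$prob), 1, tolerance = 1e-12)
    expect_equal(fisher_rxc(tab_i)$p_value, oracle_fisher_rxc(tab_i),
                 tolerance = 1e-9)
  }
  # consistency with the 2x2 route and degenerate single-row input
  t22 <- rbind(c(3, 1), c(2, 4))
  expect_equal(fisher_rxc(t22)$p_value, fisher_2x2(t22)$p_value)
  expect_equal(fisher_rxc(matrix(c(3, 4, 5), 1))$p_value, 1)
})

test_that("discriminant extraction keeps shifted genes and drops flat ones", {
  set.seed(51)
  profiles <- c(paste0("P", 1:8), paste0("Q", 1:4))
  clusters <- setNames(rep(c("A1", "A2"), c(8, 4)), profiles)
  rm_ <- rbind(flat = rep(1, 12),
               shifted = c(rnorm(8, 0, 0.2), rnorm(4, 2, 0.2)),
               noise = rnorm(12))
  colnames(rm_) <- profiles
  res <- extract_discriminant_genes(rm_, clusters)
  expect_false(res$significant[res$gene == "flat"])
  expect_equal(res$p_value[res$gene == "flat"], 1)
  expect_true(res$significant[res$gene == "shifted"])
})

test_that("category tallies report published-style percentages", {
  map <- synthetic_pathway_map()
  kept <- setdiff(map$gene, planted_low_genes())
  cc <- map$gene[map$category == "cell_cycle" & map$gene %in% kept]
  tally <- category_tally(cc[1:6], map, genes = kept)
  expect_equal(tally$percent[tally$category == "cell_cycle"], 42.9)
  expect_equal(tally$n_genes[tally$category == "Total"], 63)
  expect_equal(tally$n_extracted[tally$category == "Total"], 6)
  empty <- category_tally(character(0), map, genes = kept)
  expect_true(all(empty$n_extracted == 0))
  full <- category_tally(cc, map, genes = kept)
  expect_equal(full$percent[full$category == "cell_cycle"], 100)
  expect_error(category_tally("NOT_A_GENE", map), "not in pathway map")
})

test_that("per-type gene tests count planted effects where they were planted", {
  set.seed(52)
  types <- c("AA", "BB")
  ids <- unlist(lapply(types, function(ct) sprintf("%s-%02d", ct, 1:40)))
  g <- data.frame(sample_id = ids, cancer_type = rep(types, each = 40),
                  genotype = rep(rep(c("mutant", "wildtype"), each = 20), 2),
                  subtype = "na", hotspot = FALSE, n_qualifying = 0L,
                  stringsAsFactors = FALSE)
  class(g) <- c("p53_genotypes", "data.frame")
  vals <- matrix(2^rnorm(3 * 80, 5, 0.3), nrow = 3,
                 dimnames = list(c("g1", "g2", "MKI67"), ids))
  up <- g$sample_id[g$cancer_type == "AA" & g$genotype == "mutant"]
  vals[c("g1", "MKI67"), up] <- vals[c("g1", "MKI67"), up] * 4
  tpm <- expr_matrix(vals, "TPM")
  counts <- per_type_gene_tests(tpm, g, c("g1", "g2"))
  expect_equal(counts$n_significant[counts$cancer_type == "AA"], 1)
  expect_equal(counts$n_significant[counts$cancer_type == "BB"], 0)
  clusters <- c(AA = "A1", BB = "A2")
  mk <- mki67_contrast(tpm, g, clusters)
  expect_true(mk$per_type$significant[mk$per_type$cancer_type == "AA"])
  expect_equal(mk$per_type$direction[mk$per_type$cancer_type == "AA"], "up")
  expect_equal(mk$table["A1", "significant"], 1)
  expect_error(mki67_contrast(tpm, g, clusters, gene = "ABSENT"), "missing")
  # identical groups on a single gene yield a zero count
  flat <- expr_matrix(matrix(5, 1, 80, dimnames = list("g1", ids)), "TPM")
  c0 <- per_type_gene_tests(flat, g, "g1")
  expect_equal(c0$n_significant, c(0, 0))
})
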