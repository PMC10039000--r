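test_that("Pearson distance matches hand-computed correlations", {
  m <- cbind(a = c(1, 2, 3), b = c(1, 2, 4), c = c(3, 2, 1), d = c(2, 4, 6))
  d <- pearson_distance_matrix(m)
  expect_equal(diag(d), c(a = 0, b = 0, c = 0, d = 0))
  expect_equal(d["a", "c"], 2)                       # perfect anticorrelation
  expect_equal(d["a", "d"], 0, tolerance = 1e-12)    # scaled copy
  expect_equal(d["a", "b"], 1 - 0.9819805, tolerance = 1e-6)
  expect_equal(d, t(d))
  m0 <- cbind(a = c(1, 2, 3), flat = c(5, 5, 5))
  expect_error(pearson_distance_matrix(m0), "flat")
})

test_that("complete linkage follows the max-linkage trace on three points", {
  d <- matrix(c(0, 1, 2, 1, 0, 3, 2, 3, 0), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  hc <- complete_linkage(d)
  expect_s3_class(hc, "hclust")
  expect_equal(hc$height, c(1, 3))                   # {a,b} at 1, +c at max
  expect_equal(sort(hc$labels[-hc$merge[1, ]]), c("a", "b"))
})

test_that("identical profiles merge at height zero", {
  m <- matrix(rep(c(1, 2, 3), 4), nrow = 3,
              dimnames = list(NULL, paste0("p", 1:4)))
  hc <- complete_linkage(pearson_distance_matrix(m + 0))
  expect_equal(hc$height, rep(0, 3))
})

test_that("agglomeration agrees with hclust on random distinct-distance matrices", {
  set.seed(21)
  for (rep_i in 1:25) {
    n <- sample(4:7, 1)
    pts <- matrix(rnorm(2 * n), n)
    d <- as.matrix(dist(pts))
    dimnames(d) <- list(letters[1:n], letters[1:n])
    mine <- complete_linkage(d)
    ref <- hclust(as.dist(d), method = "complete")
    expect_equal(mine$height, ref$height, tolerance = 1e-12)
    for (k in 2:(n - 1)) {
      mine_cut <- cut_k(mine, k)
      ref_cut <- cutree(ref, k)
      names(ref_cut) <- letters[1:n]
      ref_lab <- setNames(as.character(ref_cut), names(ref_cut))
      expect_equal(partition_signature(mine_cut), partition_signature(ref_lab))
    }
  }
})

test_that("result is invariant to input profile order", {
  set.seed(8)
  m <- matrix(rnorm(60), nrow = 10,
              dimnames = list(NULL, paste0("p", 1:6)))
  d <- pearson_distance_matrix(m)
  hc1 <- complete_linkage(d)
  perm <- sample(6)
  hc2 <- complete_linkage(d[perm, perm])
  expect_equal(hc1$height, hc2$height)
  for (k in 2:5) {
    expect_equal(partition_signature(cut_k(hc1, k)),
                 partition_signature(cut_k(hc2, k)))
  }
})

test_that("k-cut spans singletons to one cluster and recovers planted blobs", {
  set.seed(4)
  blob <- function(center, n, prefix) {
    m <- matrix(rnorm(20 * n, rep(center, n), 0.05), nrow = 20)
    colnames(m) <- paste0(prefix, 1:n)
    m
  }
  c1 <- sin(1:20); c2 <- cos(1:20)
  m <- cbind(blob(c1, 4, "x"), blob(c2, 3, "y"))
  hc <- complete_linkage(pearson_distance_matrix(m))
  expect_equal(unname(cut_k(hc, 1)), rep("A1", 7), ignore_attr = TRUE)
  expect_equal(length(unique(cut_k(hc, 7))), 7)
  cl <- cut_k(hc, 2)
  expect_equal(unname(cl[paste0("x", 1:4)]), rep("A1", 4))  # larger first
  expect_equal(unname(cl[paste0("y", 1:3)]), rep("A2", 3))
  expect_error(cut_k(hc, 0), "out of range")
  expect_error(cut_k(hc, 8), "out of range")
  # two tight blobs far apart: last merge dwarfs earlier ones
  expect_gt(hc$height[6], 10 * max(hc$height[1:5]))
})

test_that("sibling pairs count partners merged while both are singletons", {
  set.seed(15)
  base <- matrix(rnorm(40 * 4), nrow = 40,
                 dimnames = list(NULL, paste0("T", 1:4)))
  m <- cbind(base, base + rnorm(160, 0, 0.01))
  colnames(m) <- c(paste0("T", 1:4, ":GOF"), paste0("T", 1:4, ":nonGOF"))
  pairing <- setNames(c(paste0("T", 1:4, ":nonGOF"), paste0("T", 1:4, ":GOF")),
                      c(paste0("T", 1:4, ":GOF"), paste0("T", 1:4, ":nonGOF")))
  hc <- complete_linkage(pearson_distance_matrix(m))
  sp <- sibling_pairs(hc, pairing)
  expect_equal(sp$count, 4)
  expect_equal(sp$total, 4)
  # corrupt one GOF profile toward another type: that pair is lost
  m2 <- m
  m2[, "T1:GOF"] <- m[, "T2:GOF"] + rnorm(40, 0, 0.001)
  hc2 <- complete_linkage(pearson_distance_matrix(m2))
  sp2 <- sibling_pairs(hc2, pairing)
  expect_false(sp2$pairs$sibling[sp2$pairs$member1 == "T1:GOF"])
  expect_error(sibling_pairs(hc, c(`T1:GOF` = "nope")), "absent")
  bad <- setNames(c("T2:GOF", "T3:GOF"), c("T1:GOF", "T2:GOF"))
  expect_error(sibling_pairs(hc, bad), "involution")
})

test_that("dendrograms export as readable Newick", {
  d <- as.matrix(dist(matrix(rnorm(10), 5)))
  dimnames(d) <- list(letters[1:5], letters[1:5])
  hc <- complete_linkage(d)
  path <- tempfile(fileext = ".nwk")
  export_newick(hc, path)
  phy <- ape::read.tree(path)
  expect_setequal(phy$tip.label, letters[1:5])
})
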