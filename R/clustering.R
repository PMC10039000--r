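#' Pearson correlation distance between profiles
#'
#' Distance between two profiles (columns) is `1 - r`, with `r` the Pearson
#' correlation across genes (centered by default; set `centered = FALSE` for
#' the uncentered cosine-style variant). Ranges over `[0, 2]`: identical
#' shapes are at 0, perfectly anticorrelated ones at 2.
#'
#' @param rm Gene-by-profile numeric matrix (e.g. a `ratio_matrix`).
#' @param centered Use centered Pearson correlation (default TRUE).
#' @return Symmetric profile-by-profile distance matrix with zero diagonal.
#' @export
pearson_distance_matrix <- function(rm, centered = TRUE) {
  m <- unclass(rm)
  if (ncol(m) < 2 || nrow(m) < 2) stop("need at least 2 profiles and 2 genes")
  if (centered) {
    sds <- apply(m, 2, stats::sd)
    if (any(sds == 0)) {
      stop("zero-variance profile(s): ",
           paste(colnames(m)[sds == 0], collapse = ", "))
    }
    r <- cor(m)
  } else {
    nrm <- sqrt(colSums(m^2))
    if (any(nrm == 0)) {
      stop("zero-variance profile(s): ",
           paste(colnames(m)[nrm == 0], collapse = ", "))
    }
    r <- crossprod(m) / outer(nrm, nrm)
  }
  d <- 1 - r
  diag(d) <- 0
  d
}

#' Complete-linkage agglomerative clustering
#'
#' Agglomerates profiles using the maximum pairwise distance between
#' clusters. Ties in the minimum inter-cluster distance are broken
#' deterministically by the lexicographically smallest pair of cluster
#' representatives (a cluster is represented by its alphabetically first
#' member id), so the result does not depend on input column order.
#'
#' @param d Symmetric distance matrix with labelled rows/columns (as from
#'   [pearson_distance_matrix()]), or a `dist` object.
#' @return An object of class `hclust` (fields `merge`, `height`, `order`,
#'   `labels`, `method = "complete"`), so that `stats::cutree`,
#'   `plot()` and `ape::as.phylo()` all apply.
#' @export
complete_linkage <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  if (is.null(rownames(d))) {
    rownames(d) <- colnames(d) <- paste0("P", seq_len(nrow(d)))
  }
  if (max(abs(d - t(d))) > 1e-12) stop("distance matrix is not symmetric")
  labels <- rownames(d)
  n <- length(labels)
  if (n < 2) stop("need at least two profiles")

  members <- as.list(seq_len(n))      # leaf indices per active cluster
  ids <- -seq_len(n)                  # hclust merge codes
  reps <- labels                      # lexicographic representative
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)

  for (step in seq_len(n - 1)) {
    k <- length(members)
    best <- NULL
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        dij <- max(d[members[[i]], members[[j]]])
        key <- sort(c(reps[i], reps[j]))
        if (is.null(best) || dij < best$d - 1e-15 ||
            (abs(dij - best$d) <= 1e-15 &&
             (key[1] < best$key[1] ||
              (key[1] == best$key[1] && key[2] < best$key[2])))) {
          best <- list(i = i, j = j, d = dij, key = key)
        }
      }
    }
    i <- best$i; j <- best$j
    merge[step, ] <- sort(c(ids[i], ids[j]))
    height[step] <- best$d
    members[[i]] <- c(members[[i]], members[[j]])
    reps[i] <- min(reps[i], reps[j])
    ids[i] <- step
    members[[j]] <- NULL
    ids <- ids[-j]
    reps <- reps[-j]
  }

  hc <- list(merge = merge, height = height,
             order = integer(n), labels = labels,
             method = "complete", call = match.call(),
             dist.method = "pearson")
  class(hc) <- "hclust"
  hc$order <- .hclust_leaf_order(merge, n)
  hc
}

# depth-first leaf ordering consistent with the merge tree
.hclust_leaf_order <- function(merge, n) {
  leaves_of <- function(node) {
    if (node < 0) return(-node)
    c(leaves_of(merge[node, 1]), leaves_of(merge[node, 2]))
  }
  leaves_of(n - 1L)
}

#' Cut a dendrogram into k clusters
#'
#' Keeps the first `n - k` merges (equivalently removes the `k - 1` highest
#' ones) and labels the connected components `A1`, `A2`, ... in decreasing
#' size order (ties broken by the alphabetically first member).
#'
#' @param hc An `hclust` tree, e.g. from [complete_linkage()].
#' @param k Number of clusters, `1 <= k <= n`.
#' @return Named character vector mapping profile id to cluster label, with
#'   attribute `k`.
#' @export
cut_k <- function(hc, k) {
  n <- length(hc$labels)
  if (k < 1 || k > n) stop("k out of range [1, ", n, "]")
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  node_root <- integer(n - 1)
  n_keep <- n - k
  for (s in seq_len(n - 1)) {
    a <- hc$merge[s, 1]; b <- hc$merge[s, 2]
    ra <- if (a < 0) find(-a) else find(node_root[a])
    rb <- if (b < 0) find(-b) else find(node_root[b])
    if (s <= n_keep) parent[rb] <- ra
    node_root[s] <- ra
  }
  comp <- vapply(seq_len(n), find, 1L)
  groups <- split(hc$labels, comp)
  ord <- order(-lengths(groups),
               vapply(groups, function(g) min(g), character(1)))
  groups <- groups[ord]
  out <- character(n)
  names(out) <- hc$labels
  for (i in seq_along(groups)) out[groups[[i]]] <- paste0("A", i)
  attr(out, "k") <- k
  out
}

#' Count partner profiles merged as first neighbours
#'
#' Given an involution pairing profiles (e.g. `TYPE:GOF` with
#' `TYPE:nonGOF`), counts the pairs whose two members are joined by a merge
#' while both are still singletons - i.e. each partner's nearest neighbour in
#' the agglomeration is the other.
#'
#' @param hc An `hclust` tree.
#' @param pairing Named character vector, `pairing[x] == y` and
#'   `pairing[y] == x` for every paired profile.
#' @return List with `count`, `total` (number of pairs) and data frame
#'   `pairs` (`member1`, `member2`, `sibling` flag).
#' @export
sibling_pairs <- function(hc, pairing) {
  labs <- hc$labels
  if (!all(names(pairing) %in% labs) || !all(pairing %in% labs)) {
    stop("pairing refers to profile(s) absent from the tree")
  }
  if (!identical(unname(pairing[pairing[names(pairing)]]), names(pairing))) {
    stop("pairing is not an involution")
  }
  sib <- character(0)
  for (s in seq_len(nrow(hc$merge))) {
    a <- hc$merge[s, 1]; b <- hc$merge[s, 2]
    if (a < 0 && b < 0) {
      la <- labs[-a]; lb <- labs[-b]
      if (!is.na(pairing[la]) && identical(unname(pairing[la]), lb)) {
        sib <- c(sib, la, lb)
      }
    }
  }
  first <- names(pairing)[names(pairing) < pairing]
  pairs <- data.frame(member1 = first, member2 = unname(pairing[first]),
                      sibling = first %in% sib, stringsAsFactors = FALSE)
  list(count = sum(pairs$sibling), total = nrow(pairs), pairs = pairs)
}

#' Export a dendrogram as Newick
#'
#' @param hc An `hclust` tree.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
export_newick <- function(hc, path) {
  phy <- ape::as.phylo(hc)
  ape::write.tree(phy, file = path)
  invisible(path)
}
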