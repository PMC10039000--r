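# Independent brute-force oracles and small fixture builders used across
# the suite. These recompute results from first principles and must stay
# independent of the package's implementation paths.

# exact two-sided Fisher p for a 2x2 table by hypergeometric enumeration
oracle_fisher_2x2 <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); c2 <- sum(tab[, 2])
  a_range <- max(0, r1 - c2):min(r1, c1)
  probs <- dhyper(a_range, c1, c2, r1)
  p_obs <- dhyper(tab[1, 1], c1, c2, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# all r x c tables with the observed margins, with their multivariate
# hypergeometric probabilities
oracle_rxc_tables <- function(rs, cs) {
  r <- length(rs); cc <- length(cs)
  fill <- function(row_left, col_left, acc) {
    if (length(row_left) == 1) {
      if (all(col_left >= 0)) return(list(rbind(acc, col_left)))
      return(list())
    }
    cells <- function(left, cols, row) {
      if (length(cols) == 1) {
        if (left <= cols) return(list(left))
        return(list())
      }
      out <- list()
      for (v in 0:min(left, cols[1])) {
        for (rest in cells(left - v, cols[-1], row)) {
          out[[length(out) + 1]] <- c(v, rest)
        }
      }
      out
    }
    out <- list()
    for (row in cells(row_left[1], col_left, NULL)) {
      out <- c(out, fill(row_left[-1], col_left - row, rbind(acc, row)))
    }
    out
  }
  tabs <- fill(rs, cs, NULL)
  n <- sum(rs)
  logp <- vapply(tabs, function(tb) {
    sum(lgamma(rs + 1)) + sum(lgamma(cs + 1)) - lgamma(n + 1) -
      sum(lgamma(tb + 1))
  }, numeric(1))
  list(tables = tabs, prob = exp(logp))
}

oracle_fisher_rxc <- function(tab) {
  en <- oracle_rxc_tables(rowSums(tab), colSums(tab))
  p_obs <- exp(sum(lgamma(rowSums(tab) + 1)) + sum(lgamma(colSums(tab) + 1)) -
                 lgamma(sum(tab) + 1) - sum(lgamma(tab + 1)))
  sum(en$prob[en$prob <= p_obs * (1 + 1e-7)])
}

# exact two-sided rank-sum p by full enumeration of group assignments
oracle_wilcoxon_exact <- function(x, y) {
  r <- rank(c(x, y))
  N <- length(r); m <- min(length(x), length(y))
  w_obs <- if (length(x) <= length(y)) sum(r[seq_along(x)]) else
    sum(r[(length(x) + 1):N])
  ws <- combn(N, m, function(ix) sum(r[ix]))
  lo <- mean(ws <= w_obs + 1e-9); hi <- mean(ws >= w_obs - 1e-9)
  min(1, 2 * min(lo, hi))
}

# tiny transactivation table with known classes
tiny_ta <- function() {
  df <- data.frame(
    protein_change = c("R175H", "R248Q", "R273H", "G245S", "Y220C", "P72R",
                       "N235S"),
    p21 = c(5, 2, 8, 20, 30, 110, 95),
    gof = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
  for (tg in setdiff(ta_targets(), "p21")) df[[tg]] <- df$p21 * 0.9 + 3
  as_ta_table(df)
}

# variant-row builder
vrow <- function(sample_id, type = "AA", pc = "R175H",
                 vclass = "missense", af = 0.5) {
  data.frame(sample_id = sample_id, cancer_type = type, gene = "TP53",
             protein_change = pc, variant_class = vclass,
             allele_frequency = af, stringsAsFactors = FALSE)
}

sheet_of <- function(ids, types) {
  data.frame(sample_id = ids, cancer_type = types, stringsAsFactors = FALSE)
}

# canonical partition signature, label-invariant
partition_signature <- function(labels) {
  grp <- split(names(labels), labels)
  grp <- lapply(grp, sort)
  unname(grp[order(vapply(grp, `[`, "", 1))])
}
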