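## Independent oracles used across the test files. Each is a deliberately
## naive re-derivation (brute force or textbook formula) of a quantity the
## package computes by a different route.

## AUC by exhaustive pair enumeration (ties count 1/2).
oracle_auc <- function(score, y) {
  pos <- score[y == 1]
  neg <- score[y == 0]
  tot <- 0
  for (p in pos) for (n in neg)
    tot <- tot + (p > n) + 0.5 * (p == n)
  tot / (length(pos) * length(neg))
}

## Benjamini-Hochberg by the textbook step-up rule.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(o)]
}

## Chi-square p-value by Monte-Carlo permutation of the underlying
## individual-level labels.
oracle_chisq_perm <- function(tab, n_perm = 4000, seed = 1) {
  set.seed(seed)
  rows <- rep(seq_len(nrow(tab)), rowSums(tab))
  cols <- rep.int(rep(seq_len(ncol(tab)), nrow(tab)), as.vector(t(tab)))
  stat <- function(r, co) {
    t2 <- table(factor(r, seq_len(nrow(tab))), factor(co, seq_len(ncol(tab))))
    e <- outer(rowSums(t2), colSums(t2)) / sum(t2)
    sum((t2 - e)^2 / e)
  }
  s0 <- stat(rows, cols)
  hits <- 0
  for (i in seq_len(n_perm))
    if (stat(rows, sample(cols)) >= s0 - 1e-12) hits <- hits + 1
  (hits + 1) / (n_perm + 1)
}

## Two-regulator loop enumeration by brute force over all triples.
oracle_loops <- function(edges, deg_set) {
  kinds <- list(c("TF", "miRNA"), c("TF", "lncRNA"), c("miRNA", "lncRNA"))
  has_edge <- function(a, b)
    any(edges$regulator == a & edges$target == b) ||
    any(edges$regulator == b & edges$target == a)
  cls <- function(r) edges$class[match(r, edges$regulator)]
  regs <- unique(edges$regulator)
  found <- character()
  for (g in intersect(unique(edges$target), deg_set))
    for (a in regs) for (b in regs) {
      if (a >= b) next
      if (!any(vapply(kinds, function(k)
        setequal(c(cls(a), cls(b)), k), logical(1)))) next
      if (!any(edges$regulator == a & edges$target == g)) next
      if (!any(edges$regulator == b & edges$target == g)) next
      if (!has_edge(a, b)) next
      found <- c(found, paste(a, b, g))
    }
  sort(unique(found))
}

## Canonical key of a find_loops() result for comparison with the oracle.
loop_keys <- function(loops) {
  if (!nrow(loops)) return(character())
  sort(paste(pmin(loops$regulator_a, loops$regulator_b),
             pmax(loops$regulator_a, loops$regulator_b), loops$target))
}

## ssGSEA enrichment score of one sample by the literal running sum.
oracle_ssgsea <- function(x, inset, weight) {
  r <- unname(rank(x, ties.method = "average"))
  ord <- order(r, decreasing = TRUE)
  w <- abs(r[ord])^weight
  es <- 0
  cum_in <- cum_out <- 0
  tot_in <- sum(w[inset[ord]])
  tot_out <- sum(!inset)
  for (i in seq_along(x)) {
    if (inset[ord][i]) cum_in <- cum_in + w[i] else cum_out <- cum_out + 1
    es <- es + (cum_in / tot_in - cum_out / tot_out)
  }
  es
}

## A small random edge table for network tests.
random_edges <- function(n_nodes = 30, n_edges = 80, seed = 1) {
  set.seed(seed)
  nodes <- sprintf("n%02d", seq_len(n_nodes))
  cls <- sample(c("TF", "miRNA", "lncRNA"), n_nodes, TRUE)
  names(cls) <- nodes
  e <- data.frame(regulator = sample(nodes, n_edges, TRUE),
                  target = sample(nodes, n_edges, TRUE),
                  stringsAsFactors = FALSE)
  e <- e[e$regulator != e$target, ]
  e <- e[!duplicated(e), ]
  e$class <- unname(cls[e$regulator])
  e$rho <- round(runif(nrow(e), -1, 1), 3)
  e[, c("regulator", "class", "target", "rho")]
}

## Small cohort configuration used when the full default is unnecessarily
## expensive for a unit test.
small_config <- function(seed = 1, ...) {
  cohort_config(n_aging_tumor = 60L, n_aging_normal = 15L,
                n_young_tumor = 80L, n_young_normal = 20L,
                n_genes = 300L, seed = seed, ...)
}
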