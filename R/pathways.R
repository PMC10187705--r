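## Gene-set analyses: over-representation, per-sample agglomerate z-scores,
## condition-associated pathway selection, aging-specificity filtering and
## single-sample enrichment (ssGSEA).

#' Read a GMT gene-set file
#'
#' Tab-separated: set name, description, then member genes.
#'
#' @param path file path.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(strsplit(lines, "\t"), function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(strsplit(lines, "\t"), `[`, character(1), 1L)
  if (anyDuplicated(names(sets))) stop("duplicate set names", call. = FALSE)
  if (any(lengths(sets) == 0)) stop("empty gene set", call. = FALSE)
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @param description per-set description column (recycled).
#' @return invisibly, the path.
#' @export
write_gmt <- function(sets, path, description = "na") {
  description <- rep_len(description, length(sets))
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], description[i], sets[[i]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Hypergeometric over-representation analysis
#'
#' For each set, the upper-tail hypergeometric probability of the observed
#' overlap with the query gene set given the universe, with fold enrichment
#' observed/expected and BH adjustment across sets. Sets with no member in
#' the universe are skipped.
#'
#' @param deg_set query genes (must be a subset of the universe).
#' @param collection named list of gene sets.
#' @param universe background genes.
#' @return data frame: set, n_set, n_overlap, fold, p.value, padj.
#' @export
ora_enrichment <- function(deg_set, collection, universe) {
  if (!length(deg_set)) stop("empty query gene set", call. = FALSE)
  if (!all(deg_set %in% universe))
    stop("query genes must be a subset of the universe", call. = FALSE)
  deg_set <- unique(deg_set)
  universe <- unique(universe)
  N <- length(universe)
  k <- length(deg_set)
  rows <- lapply(names(collection), function(nm) {
    s <- intersect(collection[[nm]], universe)
    if (!length(s)) return(NULL)
    ov <- length(intersect(deg_set, s))
    p <- stats::phyper(ov - 1, length(s), N - length(s), k,
                       lower.tail = FALSE)
    data.frame(set = nm, n_set = length(s), n_overlap = ov,
               fold = ov / (k * length(s) / N), p.value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no set overlaps the universe", call. = FALSE)
  out$padj <- bh_adjust(out$p.value)
  rownames(out) <- NULL
  out
}

#' Per-sample agglomerate z-score of a gene set
#'
#' Each member gene is z-standardized across samples; the agglomerate
#' score of a sample is the mean z-score over the set's genes present in
#' the matrix. Training-sample scores therefore average zero per gene and
#' in column mean.
#'
#' @param expr gene x sample expression matrix.
#' @param set character vector of member genes (>= 1 present).
#' @return named per-sample numeric score.
#' @export
agglomerate_zscore <- function(expr, set) {
  g <- intersect(set, rownames(expr))
  if (!length(g)) stop("gene set does not overlap the matrix",
                       call. = FALSE)
  z <- t(scale(t(expr[g, , drop = FALSE])))
  colMeans(z, na.rm = TRUE)
}

#' Agglomerate z-scores for a gene-set collection
#'
#' @param expr gene x sample matrix.
#' @param collection named list of gene sets.
#' @return pathway x sample matrix (sets with no overlap are dropped with
#'   a warning).
#' @export
pathway_score_matrix <- function(expr, collection) {
  keep <- vapply(collection, function(s)
    length(intersect(s, rownames(expr))) > 0, logical(1))
  if (any(!keep))
    warning("dropping set(s) with no overlap: ",
            paste(names(collection)[!keep], collapse = ", "))
  collection <- collection[keep]
  t(vapply(collection, function(s) agglomerate_zscore(expr, s),
           numeric(ncol(expr))))
}

#' Select pathways associated with a binary condition
#'
#' Per pathway, a logistic regression of the condition on the pathway
#' score (plus optional covariates); Wald p-values BH-adjusted across
#' pathways; pathways with adjusted p < \code{alpha} are selected, with the
#' enrichment direction given by the sign of the fitted slope.
#'
#' @param scores pathway x sample matrix.
#' @param condition two-level per-sample factor.
#' @param covariates optional per-sample data frame.
#' @param alpha selection threshold.
#' @return data frame: pathway, beta, direction, p.value, padj, selected.
#' @export
select_condition_pathways <- function(scores, condition, covariates = NULL,
                                      alpha = 0.05) {
  cf <- droplevels(as.factor(condition))
  if (nlevels(cf) != 2)
    stop("condition must have two levels present", call. = FALSE)
  beta <- p <- rep(NA_real_, nrow(scores))
  for (i in seq_len(nrow(scores))) {
    df <- data.frame(y = cf, x = scores[i, ])
    if (!is.null(covariates)) df <- cbind(df, covariates)
    fit <- suppressWarnings(stats::glm(y ~ ., data = df,
                                       family = stats::binomial()))
    co <- summary(fit)$coefficients
    if ("x" %in% rownames(co)) {
      beta[i] <- co["x", 1]
      p[i] <- co["x", 4]
    }
  }
  padj <- bh_adjust(p)
  data.frame(pathway = rownames(scores), beta = beta,
             direction = sign(beta), p.value = p, padj = padj,
             selected = !is.na(padj) & padj < alpha,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Remove pathways shared with the other age cohort
#'
#' A pathway selected in the cohort of interest is removed when it is also
#' selected in the other cohort with the same enrichment direction and its
#' scores do not differ between the cohorts (Kruskal-Wallis p >=
#' \code{alpha}). Pathways unique to the cohort, with opposite direction,
#' or significantly different between cohorts are kept.
#'
#' @param selected_aging,selected_young [select_condition_pathways()]
#'   outputs for the two cohorts.
#' @param scores pathway x sample score matrix spanning both cohorts.
#' @param age_group per-sample cohort labels aligned to \code{scores}.
#' @param alpha Kruskal threshold.
#' @return the retained subset of \code{selected_aging} rows (selected
#'   pathways only).
#' @export
aging_specificity_filter <- function(selected_aging, selected_young, scores,
                                     age_group, alpha = 0.05) {
  sa <- selected_aging[selected_aging$selected, ]
  sy <- selected_young[selected_young$selected, ]
  drop <- vapply(seq_len(nrow(sa)), function(i) {
    pw <- sa$pathway[i]
    j <- match(pw, sy$pathway)
    if (is.na(j)) return(FALSE)
    if (sa$direction[i] != sy$direction[j]) return(FALSE)
    if (!pw %in% rownames(scores)) return(FALSE)
    kt <- kruskal_test(scores[pw, ], age_group)
    kt$p.value >= alpha
  }, logical(1))
  out <- sa[!drop, ]
  rownames(out) <- NULL
  out
}

## Enrichment statistic for one sample: weighted difference between the
## in-set and out-of-set running cumulative distributions, summed over all
## ranks (Barbie-style single-sample GSEA). `r` are the per-gene ranks of
## expression (largest expression = largest rank), `inset` a logical.
ssgsea_es_sample <- function(r, inset, weight) {
  ord <- order(r, decreasing = TRUE)
  inset <- inset[ord]
  w <- abs(r[ord])^weight
  w_in <- w * inset
  p_in <- cumsum(w_in) / sum(w_in)
  p_out <- cumsum(!inset) / sum(!inset)
  sum(p_in - p_out)
}

#' Single-sample gene-set enrichment scores (ssGSEA)
#'
#' Per sample, genes are ranked by expression; the enrichment score is the
#' sum over ranks of the difference between the weighted in-set and the
#' unweighted out-of-set cumulative distributions, with rank weights raised
#' to \code{weight} (0 gives a purely rank-order statistic invariant to
#' monotone transforms of the sample's expression). Scores are then
#' linearly rescaled to \[0,1\] per pathway across samples (the normalized
#' enrichment score); set \code{rescale = FALSE} for raw enrichment scores.
#'
#' @param expr gene x sample matrix.
#' @param collection named list of gene sets (each must overlap the matrix
#'   in >= 2 genes).
#' @param weight rank-weight exponent (default 0.25).
#' @param rescale rescale per pathway to \[0,1\] across samples.
#' @return pathway x sample numeric matrix.
#' @export
ssgsea_nes <- function(expr, collection, weight = 0.25, rescale = TRUE) {
  if (!is.list(collection)) collection <- list(set = collection)
  ranks <- apply(expr, 2, rank, ties.method = "average")
  es <- matrix(NA_real_, length(collection), ncol(expr),
               dimnames = list(names(collection), colnames(expr)))
  for (k in seq_along(collection)) {
    inset <- rownames(expr) %in% collection[[k]]
    if (sum(inset) < 2)
      stop("set '", names(collection)[k],
           "' overlaps the matrix in fewer than 2 genes", call. = FALSE)
    if (all(inset))
      stop("set '", names(collection)[k],
           "' covers the whole matrix; enrichment undefined", call. = FALSE)
    for (s in seq_len(ncol(expr)))
      es[k, s] <- ssgsea_es_sample(ranks[, s], inset, weight)
  }
  if (rescale) {
    rng <- apply(es, 1, range)
    span <- rng[2, ] - rng[1, ]
    es <- (es - rng[1, ]) / ifelse(span > 0, span, 1)
    es[span == 0, ] <- 0.5
  }
  es
}

#' Compare enrichment scores between sample groups
#'
#' Per pathway, a Kruskal-Wallis rank test of the scores across groups
#' (equivalent to a Wilcoxon test for two groups), BH-adjusted. Groups
#' with fewer than 3 samples are flagged.
#'
#' @param nes pathway x sample score matrix.
#' @param groups per-sample labels (>= 2 levels present).
#' @return data frame: pathway, statistic, p.value, padj, flag.
#' @export
compare_nes <- function(nes, groups) {
  g <- droplevels(as.factor(groups))
  if (nlevels(g) < 2) stop("need at least two groups", call. = FALSE)
  small <- any(table(g) < 3)
  stat <- p <- rep(NA_real_, nrow(nes))
  for (i in seq_len(nrow(nes))) {
    kt <- kruskal_test(nes[i, ], g)
    stat[i] <- kt$statistic
    p[i] <- kt$p.value
  }
  data.frame(pathway = rownames(nes), statistic = stat, p.value = p,
             padj = bh_adjust(p),
             flag = if (small) "small_group" else "ok",
             row.names = NULL, stringsAsFactors = FALSE)
}
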