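## Correlation-filtered regulatory networks: edge filtering by Spearman
## correlation, enumeration of two-regulator/one-target loops, and
## activator/inhibitor classification of miRNA interactions by binding
## site and correlation sign.

#' Filter candidate edges by expression correlation
#'
#' Computes the Spearman correlation between the two endpoints of every
#' candidate edge and keeps edges with |rho| strictly greater than the
#' threshold (0.5 for tumor networks; 0.3 is conventional for quieter
#' normal-tissue networks). Edges with an endpoint missing from the
#' expression matrix are dropped with a warning.
#'
#' @param expr gene x sample matrix containing regulators and targets.
#' @param edges data frame with columns regulator, class (TF / miRNA /
#'   lncRNA / protein), target, and optionally site (for miRNA edges:
#'   promoter / 5UTR / CDS / 3UTR / none).
#' @param threshold strict absolute-correlation cut-off.
#' @return the retained edges with an added \code{rho} column.
#' @export
correlation_filter <- function(expr, edges, threshold = 0.5) {
  need <- c("regulator", "class", "target")
  if (!all(need %in% names(edges)))
    stop("edges must have regulator/class/target columns", call. = FALSE)
  quant <- edges$regulator %in% rownames(expr) &
    edges$target %in% rownames(expr)
  if (any(!quant))
    warning(sum(!quant), " edge(s) dropped: endpoint not quantified")
  edges <- edges[quant, , drop = FALSE]
  edges$rho <- vapply(seq_len(nrow(edges)), function(i)
    spearman_cor(expr[edges$regulator[i], ], expr[edges$target[i], ])$rho,
    numeric(1))
  out <- edges[abs(edges$rho) > threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}

.loop_kinds <- list(c("TF", "miRNA"), c("TF", "lncRNA"),
                    c("miRNA", "lncRNA"))

#' Enumerate two-regulator regulatory loops over a target gene set
#'
#' A loop is a triad of a target gene in \code{deg_set} and two regulators
#' of complementary classes (TF/miRNA, TF/lncRNA or miRNA/lncRNA) such
#' that both regulators have a retained edge to the target and a retained
#' edge (in either direction) connects the two regulators. Loops are
#' deduplicated on the unordered regulator pair and target.
#'
#' @param edges filtered edges (from [correlation_filter()]), including
#'   regulator class.
#' @param deg_set target genes of interest.
#' @return data frame: regulator_a, class_a, regulator_b, class_b, target,
#'   kind, rho_a (a-target), rho_b (b-target), rho_ab (regulator pair).
#' @export
find_loops <- function(edges, deg_set) {
  empty <- data.frame(regulator_a = character(), class_a = character(),
                      regulator_b = character(), class_b = character(),
                      target = character(), kind = character(),
                      rho_a = numeric(), rho_b = numeric(),
                      rho_ab = numeric(), stringsAsFactors = FALSE)
  if (!nrow(edges)) return(empty)
  if (!"rho" %in% names(edges)) edges$rho <- NA_real_
  pair_key <- paste(pmin(edges$regulator, edges$target),
                    pmax(edges$regulator, edges$target))
  pair_rho <- setNames(edges$rho, pair_key)
  rows <- list()
  tmask <- edges$target %in% deg_set
  for (g in unique(edges$target[tmask])) {
    inc <- edges[edges$target == g, , drop = FALSE]
    if (nrow(inc) < 2) next
    for (i in seq_len(nrow(inc) - 1)) {
      for (j in (i + 1):nrow(inc)) {
        cls <- c(inc$class[i], inc$class[j])
        kind_i <- which(vapply(.loop_kinds, function(k) setequal(cls, k),
                               logical(1)))
        if (!length(kind_i)) next
        key <- paste(pmin(inc$regulator[i], inc$regulator[j]),
                     pmax(inc$regulator[i], inc$regulator[j]))
        if (!key %in% names(pair_rho)) next
        ord <- order(match(cls, .loop_kinds[[kind_i]]))
        ii <- c(i, j)[ord]
        rows[[length(rows) + 1L]] <- data.frame(
          regulator_a = inc$regulator[ii[1]], class_a = inc$class[ii[1]],
          regulator_b = inc$regulator[ii[2]], class_b = inc$class[ii[2]],
          target = g,
          kind = paste(c(.loop_kinds[[kind_i]], "DEG"), collapse = "/"),
          rho_a = inc$rho[ii[1]], rho_b = inc$rho[ii[2]],
          rho_ab = unname(pair_rho[key]), stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out <- out[!duplicated(out[, c("regulator_a", "regulator_b", "target")]), ]
  rownames(out) <- NULL
  out
}

#' Loops present in one network but not another
#'
#' Set difference of two [find_loops()] results on the unordered regulator
#' pair and target (e.g. loops unique to the aging cohort).
#'
#' @param loops_a,loops_b loop tables.
#' @return the rows of \code{loops_a} absent from \code{loops_b}.
#' @export
loop_difference <- function(loops_a, loops_b) {
  key <- function(l) paste(pmin(l$regulator_a, l$regulator_b),
                           pmax(l$regulator_a, l$regulator_b), l$target)
  out <- loops_a[!key(loops_a) %in% key(loops_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify miRNA regulatory mode from binding site and correlation
#'
#' A miRNA is called an activator for a promoter interaction with positive
#' correlation, an inhibitor for a 3'UTR, CDS or 5'UTR interaction with
#' negative correlation, and unclassified otherwise (including a promoter
#' interaction with negative correlation).
#'
#' @param site binding-site class: promoter / 5UTR / CDS / 3UTR / none.
#' @param rho correlation between the miRNA and its target.
#' @return character vector: activator / inhibitor / unclassified.
#' @export
classify_mirna_mode <- function(site, rho) {
  ifelse(site == "promoter" & rho > 0, "activator",
         ifelse(site %in% c("3UTR", "CDS", "5UTR") & rho < 0, "inhibitor",
                "unclassified"))
}
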