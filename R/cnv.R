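## Gene-level copy-number analysis: shallow gain/loss calls on the segment-
## mean scale, per-group alteration frequencies, differential alteration
## between groups, and linkage of copy number to expression.

#' Call gains and losses from a gene-level copy-number matrix
#'
#' Strict thresholds on the segment-mean (log2-ratio-like) scale: a gain
#' when the value exceeds \code{gain_thr}, a loss when below
#' \code{loss_thr}; values exactly at a threshold are neutral. The default
#' thresholds (0.3 / -0.3) call shallow alterations; deep alterations are
#' the same caller at (1 / -1).
#'
#' @param cnv gene x sample numeric matrix.
#' @param gain_thr,loss_thr thresholds (gain_thr > 0 > loss_thr).
#' @return integer gene x sample matrix coded -1 (loss), 0 (neutral),
#'   1 (gain), class \code{alteration_calls}, with the thresholds attached.
#' @export
call_alterations <- function(cnv, gain_thr = 0.3, loss_thr = -0.3) {
  if (!(gain_thr > 0 && loss_thr < 0))
    stop("need gain_thr > 0 > loss_thr", call. = FALSE)
  calls <- matrix(0L, nrow(cnv), ncol(cnv), dimnames = dimnames(cnv))
  calls[cnv > gain_thr] <- 1L
  calls[cnv < loss_thr] <- -1L
  structure(calls, thresholds = c(gain = gain_thr, loss = loss_thr),
            class = c("alteration_calls", class(calls)))
}

#' Per-group gain/loss frequencies
#'
#' Frequency = altered samples / group size; an alteration is retained as
#' relevant when its frequency strictly exceeds
#' \code{relevance_threshold} (default 2\%).
#'
#' @param calls an [call_alterations()] matrix.
#' @param groups per-sample group labels covering all columns.
#' @param relevance_threshold strict frequency cut-off.
#' @return long data frame: gene, group, n_gain, n_loss, n_total,
#'   freq_gain, freq_loss, retained_gain, retained_loss.
#' @export
alteration_frequency <- function(calls, groups,
                                 relevance_threshold = 0.02) {
  groups <- droplevels(as.factor(groups))
  if (length(groups) != ncol(calls))
    stop("group labels must cover all samples", call. = FALSE)
  out <- do.call(rbind, lapply(levels(groups), function(g) {
    j <- groups == g
    ng <- rowSums(calls[, j, drop = FALSE] == 1L)
    nl <- rowSums(calls[, j, drop = FALSE] == -1L)
    nt <- sum(j)
    data.frame(gene = rownames(calls), group = g, n_gain = ng, n_loss = nl,
               n_total = nt, freq_gain = ng / nt, freq_loss = nl / nt,
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  out$retained_gain <- out$freq_gain > relevance_threshold
  out$retained_loss <- out$freq_loss > relevance_threshold
  out
}

#' Differential alteration between two sample groups
#'
#' Per gene, a Pearson chi-square test (no continuity correction) on the
#' 2x2 table of altered vs unaltered samples by group, BH-adjusted across
#' testable genes. Genes with a degenerate margin (altered in no sample or
#' in every sample, or alteration confined by the group split) are skipped
#' with a flag.
#'
#' @param calls an [call_alterations()] matrix.
#' @param groups two-level per-sample labels.
#' @param type count "any" alteration (default), only "gain", or only
#'   "loss".
#' @return data frame: gene, statistic, p.value, padj, flag.
#' @export
differential_alteration <- function(calls, groups,
                                    type = c("any", "gain", "loss")) {
  type <- match.arg(type)
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) != 2) stop("need exactly two groups", call. = FALSE)
  altered <- switch(type, any = calls != 0L, gain = calls == 1L,
                    loss = calls == -1L)
  ng <- nrow(calls)
  stat <- p <- rep(NA_real_, ng)
  flag <- rep("ok", ng)
  for (g in seq_len(ng)) {
    tab <- table(factor(altered[g, ], levels = c(FALSE, TRUE)), groups)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
      flag[g] <- "degenerate"
      next
    }
    ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    stat[g] <- unname(ht$statistic)
    p[g] <- ht$p.value
  }
  data.frame(gene = rownames(calls), statistic = stat, p.value = p,
             padj = bh_adjust(p), flag = flag, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Genes whose expression tracks their copy-number alteration
#'
#' A gene is linked to a gain when its copy number and expression are
#' positively Spearman-correlated (BH-adjusted p < \code{alpha}), the gain
#' frequency strictly exceeds \code{freq_thr}, and the gene is
#' significantly upregulated in the accompanying differential-expression
#' result (log2fc > \code{lfc_thr}, padj < \code{alpha}). The loss rule is
#' mirrored (positive correlation, loss frequency, log2fc < -lfc_thr).
#'
#' @param cnv,expr aligned gene x sample matrices (same dimnames).
#' @param de DEResult on the same genes.
#' @param gain_thr,loss_thr call thresholds.
#' @param freq_thr strict frequency threshold.
#' @param alpha significance threshold.
#' @param lfc_thr fold-change threshold (strict).
#' @return list: gains, losses (character gene vectors), table (per-gene
#'   details).
#' @export
cnv_expression_link <- function(cnv, expr, de, gain_thr = 0.3,
                                loss_thr = -0.3, freq_thr = 0.02,
                                alpha = 0.05, lfc_thr = 1) {
  if (!identical(dimnames(cnv), dimnames(expr)))
    stop("cnv and expression matrices are misaligned", call. = FALSE)
  if (!identical(rownames(cnv), de$gene))
    stop("DE result does not match the matrices", call. = FALSE)
  calls <- call_alterations(cnv, gain_thr, loss_thr)
  n <- ncol(cnv)
  freq_gain <- rowSums(calls == 1L) / n
  freq_loss <- rowSums(calls == -1L) / n
  rho <- p <- rep(NA_real_, nrow(cnv))
  for (g in seq_len(nrow(cnv))) {
    if (stats::sd(cnv[g, ]) == 0 || stats::sd(expr[g, ]) == 0) next
    sc <- spearman_cor(cnv[g, ], expr[g, ])
    rho[g] <- sc$rho
    p[g] <- sc$p.value
  }
  padj <- bh_adjust(p)
  corr_ok <- !is.na(rho) & rho > 0 & !is.na(padj) & padj < alpha
  de_up <- !is.na(de$padj) & de$padj < alpha & !is.na(de$log2fc) &
    de$log2fc > lfc_thr
  de_dn <- !is.na(de$padj) & de$padj < alpha & !is.na(de$log2fc) &
    de$log2fc < -lfc_thr
  gains <- rownames(cnv)[corr_ok & freq_gain > freq_thr & de_up]
  losses <- rownames(cnv)[corr_ok & freq_loss > freq_thr & de_dn]
  list(gains = gains, losses = losses,
       table = data.frame(gene = rownames(cnv), rho = rho, padj = padj,
                          freq_gain = freq_gain, freq_loss = freq_loss,
                          row.names = NULL, stringsAsFactors = FALSE))
}
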