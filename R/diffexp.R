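## Negative-binomial GLM likelihood-ratio differential expression.
##
## A deliberately simple, documented engine: per-gene NB GLM with log link
## and a library-size offset, fixed per-gene dispersion estimated by method
## of moments with a floor and shrinkage toward a mean-binned trend, and a
## chi-square likelihood-ratio test between nested designs. No independent
## filtering, no fold-change shrinkage.

#' Method-of-moments negative-binomial dispersion estimates
#'
#' Per-gene dispersion (the NB "alpha", variance = mu + alpha mu^2)
#' estimated on size-factor-normalized counts within each level of
#' \code{groups} (so planted group differences do not inflate the
#' estimate), pooled across levels by residual degrees of freedom, floored,
#' and shrunk toward the median dispersion of genes in the same
#' mean-expression decile.
#'
#' @param counts gene x sample integer matrix.
#' @param groups factor splitting samples (defaults to one group).
#' @param floor minimum dispersion.
#' @param shrink_weight weight on the decile trend (0 = pure per-gene).
#' @param cap maximum dispersion.
#' @return numeric vector of per-gene dispersions.
#' @export
estimate_dispersions <- function(counts, groups = NULL, floor = 1e-4,
                                 shrink_weight = 0.25, cap = 10) {
  q <- sweep(counts, 2, estimate_size_factors(counts), "/")
  if (is.null(groups)) groups <- factor(rep("all", ncol(counts)))
  groups <- droplevels(as.factor(groups))
  num <- den <- numeric(nrow(counts))
  mu_all <- rowMeans(q)
  for (g in levels(groups)) {
    j <- groups == g
    if (sum(j) < 2) next
    m <- rowMeans(q[, j, drop = FALSE])
    v <- apply(q[, j, drop = FALSE], 1, stats::var)
    w <- sum(j) - 1
    d <- (v - m) / pmax(m, 1e-8)^2
    num <- num + w * pmax(d, 0)
    den <- den + w
  }
  disp <- pmin(pmax(ifelse(den > 0, num / den, floor), floor), cap)
  ## decile trend on the overall mean
  br <- unique(stats::quantile(mu_all, probs = seq(0, 1, 0.1), na.rm = TRUE))
  if (length(br) > 2) {
    bin <- cut(mu_all, breaks = br, include.lowest = TRUE)
    trend <- stats::ave(disp, bin, FUN = stats::median)
    disp <- (1 - shrink_weight) * disp + shrink_weight * trend
  }
  pmin(pmax(disp, floor), cap)
}

## IRLS fit of an NB GLM with log link, offset and fixed dispersion.
## Returns coefficients, log-likelihood and a convergence flag.
nb_irls <- function(y, X, offset, theta, maxit = 50L, tol = 1e-8) {
  beta <- tryCatch(stats::lm.fit(X, log(y + 0.5) - offset)$coefficients,
                   error = function(e) rep(0, ncol(X)))
  beta[!is.finite(beta)] <- 0
  ll_old <- -Inf
  ok <- FALSE
  for (it in seq_len(maxit)) {
    eta <- pmin(pmax(drop(X %*% beta) + offset, -30), 30)
    mu <- exp(eta)
    w <- mu / (1 + mu / theta)
    z <- (eta - offset) + (y - mu) / mu
    fit <- tryCatch(stats::lm.wfit(X, z, w), error = function(e) NULL)
    if (is.null(fit) || anyNA(fit$coefficients)) {
      ok <- FALSE
      break
    }
    beta <- fit$coefficients
    eta <- pmin(pmax(drop(X %*% beta) + offset, -30), 30)
    mu <- exp(eta)
    ll <- sum(stats::dnbinom(y, size = theta, mu = mu, log = TRUE))
    if (is.finite(ll) && abs(ll - ll_old) < tol * (abs(ll_old) + 1)) {
      ok <- TRUE
      ll_old <- ll
      break
    }
    ll_old <- ll
    ok <- it < maxit  # reaching maxit without the tolerance -> not converged
  }
  list(coefficients = beta, loglik = ll_old, converged = ok && is.finite(ll_old))
}

#' Differential expression by negative-binomial GLM likelihood-ratio test
#'
#' Fits, per gene, an NB GLM of counts on a two-level contrast plus
#' adjustment covariates (full design) and on the covariates alone (reduced
#' design), with a log library-size offset and fixed method-of-moments
#' dispersion, and tests the contrast with a likelihood-ratio chi-square.
#' Genes with total count below \code{min_count} are flagged
#' \code{low_count} and not tested.
#'
#' @param counts gene x sample integer matrix.
#' @param coldata per-sample data frame aligned to \code{counts} columns.
#' @param contrast name of the two-level factor column tested.
#' @param covariates character vector of adjustment columns (may be empty).
#' @param ref reference level of the contrast (defaults to its first level).
#' @param min_count minimum total count per gene to be tested.
#' @param dispersion optional per-gene dispersion vector; estimated when
#'   NULL.
#' @param size_factors optional per-sample normalization factors; defaults
#'   to total counts scaled to geometric mean 1.
#' @return a \code{DEResult} data frame: gene, base_mean, log2fc (contrast
#'   non-reference vs reference level), lrt_stat, pvalue, padj (BH), flag
#'   (ok / low_count / fit_failed).
#' @export
nb_glm_lrt <- function(counts, coldata, contrast, covariates = character(),
                       ref = NULL, min_count = 10, dispersion = NULL,
                       size_factors = NULL) {
  if (ncol(counts) != nrow(coldata))
    stop("counts columns and coldata rows must align", call. = FALSE)
  y_fac <- droplevels(as.factor(coldata[[contrast]]))
  if (nlevels(y_fac) != 2)
    stop("contrast must have exactly two levels present", call. = FALSE)
  if (!is.null(ref)) y_fac <- stats::relevel(y_fac, ref = ref)
  if (min(table(y_fac)) < 2)
    stop("need at least 2 samples per contrast level", call. = FALSE)
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("gene%04d", seq_len(nrow(counts)))
  df <- data.frame(..y = y_fac)
  for (v in covariates) {
    cv <- coldata[[v]]
    df[[v]] <- if (is.numeric(cv)) cv else droplevels(as.factor(cv))
  }
  f_full <- stats::as.formula(paste("~ ..y",
                                    if (length(covariates))
                                      paste("+", paste(covariates,
                                                       collapse = " + "))
                                    else ""))
  f_red <- stats::as.formula(if (length(covariates))
    paste("~", paste(covariates, collapse = " + ")) else "~ 1")
  X_full <- stats::model.matrix(f_full, df)
  X_red <- stats::model.matrix(f_red, df)
  if (qr(X_full)$rank < ncol(X_full))
    stop("full design is rank deficient (covariates collinear with contrast)",
         call. = FALSE)
  df_lrt <- ncol(X_full) - ncol(X_red)
  fc_col <- 2L  # coefficient of the contrast non-reference level

  if (is.null(size_factors)) size_factors <- estimate_size_factors(counts)
  offset <- log(size_factors) - mean(log(size_factors))
  if (is.null(dispersion))
    dispersion <- estimate_dispersions(counts, groups = y_fac)
  dispersion <- rep_len(dispersion, nrow(counts))

  ng <- nrow(counts)
  base_mean <- rowMeans(sweep(counts, 2, size_factors, "/"))
  log2fc <- lrt <- pval <- rep(NA_real_, ng)
  flag <- rep("ok", ng)
  testable <- rowSums(counts) >= min_count
  flag[!testable] <- "low_count"
  for (g in which(testable)) {
    yg <- counts[g, ]
    th <- 1 / dispersion[g]
    ff <- nb_irls(yg, X_full, offset, th)
    fr <- nb_irls(yg, X_red, offset, th)
    if (!ff$converged || !fr$converged) {
      flag[g] <- "fit_failed"
      next
    }
    log2fc[g] <- ff$coefficients[fc_col] / log(2)
    lrt[g] <- max(0, 2 * (ff$loglik - fr$loglik))
    pval[g] <- stats::pchisq(lrt[g], df = df_lrt, lower.tail = FALSE)
  }
  padj <- bh_adjust(pval)
  res <- data.frame(gene = rownames(counts), base_mean = base_mean,
                    log2fc = log2fc, lrt_stat = lrt, pvalue = pval,
                    padj = padj, flag = flag, stringsAsFactors = FALSE,
                    row.names = NULL)
  attr(res, "contrast") <- c(variable = contrast,
                             level = levels(y_fac)[2],
                             reference = levels(y_fac)[1])
  attr(res, "covariates") <- covariates
  class(res) <- c("DEResult", "data.frame")
  res
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment via [stats::p.adjust()]. NAs are
#' passed through and do not count toward the number of tests.
#'
#' @param pvalues numeric vector in \[0,1\] (NAs allowed).
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  px <- pvalues[!is.na(pvalues)]
  if (length(px) && (any(px < 0) || any(px > 1)))
    stop("p-values must lie in [0,1]", call. = FALSE)
  stats::p.adjust(pvalues, method = "BH")
}

#' Threshold a DE result into a directed gene set
#'
#' Keeps genes with \code{padj < alpha} and \code{|log2fc| >= lfc_min}
#' (the fold-change threshold is inclusive).
#'
#' @param de a \code{DEResult}.
#' @param alpha adjusted-p threshold (strict).
#' @param lfc_min absolute log2 fold-change threshold (inclusive).
#' @return data frame gene / log2fc / padj / direction ("up" or "down").
#' @export
select_degs <- function(de, alpha = 0.05, lfc_min = 1) {
  stopifnot(alpha > 0, lfc_min > 0)
  keep <- !is.na(de$padj) & de$padj < alpha &
    !is.na(de$log2fc) & abs(de$log2fc) >= lfc_min
  out <- de[keep, c("gene", "log2fc", "padj")]
  out$direction <- ifelse(out$log2fc > 0, "up", "down")
  rownames(out) <- NULL
  out
}

#' Cohort-specific differentially expressed genes
#'
#' Genes selected (significant and large fold change) in the tumor-vs-normal
#' comparison of one age cohort but selected in neither the other cohort's
#' tumor-vs-normal comparison nor the aging-vs-young comparison of normal
#' tissue. Non-selection means failing either the adjusted-p or the
#' fold-change threshold.
#'
#' @param own_tvn DEResult for the cohort of interest (tumor vs normal).
#' @param other_tvn DEResult for the other age cohort (tumor vs normal).
#' @param normal_ovy DEResult for aging vs young in normal tissue.
#' @param alpha,lfc_min thresholds passed to [select_degs()].
#' @return character vector of cohort-specific genes.
#' @export
cohort_specific_sets <- function(own_tvn, other_tvn, normal_ovy,
                                 alpha = 0.05, lfc_min = 1) {
  u <- own_tvn$gene
  if (!identical(u, other_tvn$gene) || !identical(u, normal_ovy$gene))
    stop("DE results must share one gene universe", call. = FALSE)
  own <- select_degs(own_tvn, alpha, lfc_min)$gene
  other <- select_degs(other_tvn, alpha, lfc_min)$gene
  nor <- select_degs(normal_ovy, alpha, lfc_min)$gene
  setdiff(own, union(other, nor))
}

#' Log2 size-factor-normalized expression
#'
#' log2(normalized count + 1), the expression scale used for association
#' models, scoring and correlation analyses downstream.
#'
#' @param counts gene x sample matrix.
#' @param size_factors optional; defaults to total counts scaled to
#'   geometric mean 1.
#' @return gene x sample numeric matrix.
#' @export
normalized_log2 <- function(counts, size_factors = NULL) {
  if (is.null(size_factors)) size_factors <- estimate_size_factors(counts)
  log2(sweep(counts, 2, size_factors, "/") + 1)
}

#' Median-of-ratios library size factors
#'
#' Per-sample normalization factors computed as the median, over genes with
#' strictly positive counts in every sample, of the ratio of the sample's
#' count to the gene's geometric mean, scaled so the factors have geometric
#' mean 1. Unlike total-count normalization this estimator is robust to
#' asymmetric differential expression: a minority of strongly up-regulated
#' genes does not drag the factors of the affected samples upwards and so
#' does not induce spurious apparent down-regulation of the unchanged
#' majority. Falls back to total counts when no gene is positive everywhere.
#'
#' @param counts gene x sample matrix of non-negative counts.
#' @return named per-sample numeric vector with geometric mean 1.
#' @export
estimate_size_factors <- function(counts) {
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  pos <- rowSums(counts > 0) == ncol(counts)
  if (any(pos)) {
    lc <- log(counts[pos, , drop = FALSE])
    ratios <- lc - rowMeans(lc)
    sf <- exp(apply(ratios, 2, stats::median))
  } else {
    sf <- colSums(counts)
    if (all(sf == 0)) stop("all-zero count matrix", call. = FALSE)
    sf <- sf / exp(mean(log(pmax(sf, 1))))
  }
  sf <- sf / exp(mean(log(sf)))
  setNames(sf, colnames(counts))
}
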