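## Composite scoring: beta-weighted risk scores and the eigenvalue-weighted
## PCA aggressiveness score, plus cluster stratification by its sign.

#' Two-class linear discriminant direction
#'
#' Closed-form Fisher discriminant: beta = Sw^-1 (mu_2 - mu_1) with the
#' pooled within-class covariance Sw stabilized by a small ridge
#' (\code{ridge} times the mean diagonal). Deterministic; the direction is
#' oriented so the second factor level (the "positive" class) has the
#' higher mean score.
#'
#' @param x sample x gene matrix.
#' @param y two-level factor (or coercible); second level is the positive
#'   class.
#' @param ridge ridge fraction added to the diagonal of Sw.
#' @return list of class \code{risk_model}: coefficients (named per gene),
#'   levels, prior means.
#' @export
fit_lda <- function(x, y, ridge = 1e-6) {
  x <- as.matrix(x)
  y <- droplevels(as.factor(y))
  if (nlevels(y) != 2) stop("y must have exactly two classes", call. = FALSE)
  i1 <- y == levels(y)[1]
  m1 <- colMeans(x[i1, , drop = FALSE])
  m2 <- colMeans(x[!i1, , drop = FALSE])
  c1 <- stats::cov(x[i1, , drop = FALSE])
  c2 <- stats::cov(x[!i1, , drop = FALSE])
  n1 <- sum(i1); n2 <- sum(!i1)
  sw <- ((n1 - 1) * c1 + (n2 - 1) * c2) / (n1 + n2 - 2)
  lam <- ridge * mean(diag(sw))
  if (!is.finite(lam) || lam <= 0) lam <- ridge
  beta <- drop(solve(sw + diag(lam, ncol(x)), m2 - m1))
  names(beta) <- colnames(x)
  structure(list(coefficients = beta, levels = levels(y),
                 means = rbind(m1, m2), kind = "lda"),
            class = "risk_model")
}

#' Proportional-hazards risk coefficients for a gene panel
#'
#' Per-gene coefficients from a multivariable Cox fit of the survival
#' endpoint on the panel expression.
#'
#' @param x sample x gene matrix.
#' @param time,event survival outcome.
#' @return \code{risk_model} with Cox coefficients.
#' @export
fit_cox_risk <- function(x, time, event) {
  if (sum(event, na.rm = TRUE) == 0)
    stop("no events: cannot fit a proportional-hazards risk model",
         call. = FALSE)
  df <- as.data.frame(x)
  fit <- survival::coxph(survival::Surv(time, event) ~ ., data = df)
  beta <- stats::coef(fit)
  names(beta) <- colnames(x)
  structure(list(coefficients = beta, kind = "cox"), class = "risk_model")
}

#' Beta-weighted risk score
#'
#' Per-sample score sum_i x_i * beta_i over the model's genes; linear in
#' both the expression values and the coefficients.
#'
#' @param expr sample x gene matrix (genes must include the model's genes).
#' @param model a \code{risk_model} or a named coefficient vector.
#' @return named numeric per-sample score.
#' @export
risk_score <- function(expr, model) {
  beta <- if (inherits(model, "risk_model")) model$coefficients else model
  miss <- setdiff(names(beta), colnames(expr))
  if (length(miss))
    stop("expression matrix lacks model genes: ",
         paste(miss, collapse = ", "), call. = FALSE)
  drop(as.matrix(expr[, names(beta), drop = FALSE]) %*% beta)
}

#' Fit the eigenvalue-weighted PCA aggressiveness score model
#'
#' Genes are standardized to z-scores; the correlation matrix is
#' eigen-decomposed and only components with eigenvalue E > 1 are kept
#' (Kaiser rule). Each kept component is oriented so its loading sum is
#' positive, making higher scores correspond to higher panel expression.
#' The per-gene weight is W_i = sum_j L_ij * E_j over the kept components
#' (optionally the first component only), and the sample score is
#' sum_i z_i W_i / sum_i W_i, so training scores have mean zero.
#'
#' @param expr sample x gene matrix (raw or log scale; >= 2 genes, >= 3
#'   samples, no zero-variance gene).
#' @param components "all_selected" (default) or "pc1".
#' @return list of class \code{pca_aging_model}: center, scale, loadings,
#'   eigenvalues, selected component indices, weights.
#' @export
fit_pca_aging <- function(expr, components = c("all_selected", "pc1")) {
  components <- match.arg(components)
  expr <- as.matrix(expr)
  if (ncol(expr) < 2 || nrow(expr) < 3)
    stop("need at least 2 genes and 3 samples", call. = FALSE)
  ctr <- colMeans(expr)
  sdv <- apply(expr, 2, stats::sd)
  if (any(sdv == 0))
    stop("zero-variance gene(s): ",
         paste(colnames(expr)[sdv == 0], collapse = ", "), call. = FALSE)
  z <- scale(expr, center = ctr, scale = sdv)
  ee <- eigen(stats::cor(expr), symmetric = TRUE)
  L <- ee$vectors
  E <- pmax(ee$values, 0)
  flip <- colSums(L) < 0
  L[, flip] <- -L[, flip]
  sel <- which(E > 1)
  if (!length(sel))
    stop("degenerate panel: no component has eigenvalue > 1", call. = FALSE)
  if (components == "pc1") sel <- sel[1]
  W <- drop(L[, sel, drop = FALSE] %*% E[sel])
  if (abs(sum(W)) < 1e-12)
    stop("weight sum is zero; score undefined", call. = FALSE)
  rownames(L) <- colnames(expr)
  structure(list(center = ctr, scale = sdv, loadings = L, eigenvalues = E,
                 selected = sel, weights = setNames(W, colnames(expr))),
            class = "pca_aging_model")
}

#' Compute the PCA aggressiveness score for samples
#'
#' Standardizes with the training means/SDs and evaluates
#' sum_i z_i W_i / sum_i W_i per sample.
#'
#' @param expr sample x gene matrix on the scale the model was fitted on.
#' @param model a [fit_pca_aging()] model.
#' @return named numeric per-sample score.
#' @export
pca_aging_score <- function(expr, model) {
  stopifnot(inherits(model, "pca_aging_model"))
  g <- names(model$weights)
  miss <- setdiff(g, colnames(expr))
  if (length(miss))
    stop("expression matrix lacks panel genes: ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (abs(sum(model$weights)) < 1e-12)
    stop("weight sum is zero; score undefined", call. = FALSE)
  z <- scale(as.matrix(expr[, g, drop = FALSE]), center = model$center[g],
             scale = model$scale[g])
  drop(z %*% model$weights) / sum(model$weights)
}

#' Stratify samples into aggressiveness clusters by score sign
#'
#' Scores above zero (the training mean) label the more aggressive cluster
#' (MAAC in aging mode, MAYC in young mode); scores at or below zero label
#' the less aggressive cluster (LAAC / LAYC). The tie at exactly zero goes
#' to the less aggressive cluster.
#'
#' @param scores finite numeric scores.
#' @param mode "aging" or "young".
#' @return data frame: sample (names of \code{scores} or index), score,
#'   cluster (factor, less-aggressive level first).
#' @export
stratify <- function(scores, mode = c("aging", "young")) {
  mode <- match.arg(mode)
  if (any(!is.finite(scores))) stop("scores must be finite", call. = FALSE)
  labs <- if (mode == "aging") c("LAAC", "MAAC") else c("LAYC", "MAYC")
  cluster <- factor(ifelse(scores > 0, labs[2], labs[1]), levels = labs)
  data.frame(sample = if (is.null(names(scores)))
    as.character(seq_along(scores)) else names(scores),
    score = as.numeric(scores), cluster = cluster,
    stringsAsFactors = FALSE, row.names = NULL)
}
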