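## Four-step selection of cohort-specific, aging-dependent aggressiveness
## markers, plus internal validation within the aging tumor cohort.

#' Define a clinical aggressiveness parameter
#'
#' Describes how to derive a two-level factor (non-aggressive reference,
#' aggressive level) from a clinical table column.
#'
#' @param name label of the parameter.
#' @param variable clinical column used.
#' @param kind "binary" (factor column), "threshold" (continuous, aggressive
#'   when >= \code{cutoff}), "mean_split" (continuous, dichotomized at the
#'   cohort mean) or "level_set" (factor, aggressive when the value is in
#'   \code{aggressive_levels}).
#' @param aggressive_level label of the aggressive level of the derived
#'   factor.
#' @param aggressive_levels for "level_set": variable levels coding
#'   aggressive.
#' @param baseline_levels for "level_set": levels coding non-aggressive
#'   (others become NA, e.g. comparing tall-cell vs follicular while
#'   dropping classical).
#' @param cutoff threshold for "threshold".
#' @param low_is_aggressive for "mean_split": TRUE when values below the
#'   mean code the aggressive phenotype (e.g. differentiation score).
#' @return object of class \code{parameter_definition}.
#' @export
parameter_definition <- function(name, variable,
                                 kind = c("binary", "threshold",
                                          "mean_split", "level_set"),
                                 aggressive_level = NULL,
                                 aggressive_levels = NULL,
                                 baseline_levels = NULL,
                                 cutoff = NULL,
                                 low_is_aggressive = FALSE) {
  kind <- match.arg(kind)
  structure(list(name = name, variable = variable, kind = kind,
                 aggressive_level = aggressive_level,
                 aggressive_levels = aggressive_levels,
                 baseline_levels = baseline_levels, cutoff = cutoff,
                 low_is_aggressive = low_is_aggressive),
            class = "parameter_definition")
}

#' Derive the two-level aggressiveness factor for a parameter
#'
#' @param clinical per-sample clinical data frame.
#' @param def a [parameter_definition()].
#' @return factor with levels c(non-aggressive, aggressive); NA where the
#'   parameter is undefined for a sample.
#' @export
parameter_factor <- function(clinical, def) {
  if (!def$variable %in% names(clinical))
    stop("missing parameter column: ", def$variable, call. = FALSE)
  x <- clinical[[def$variable]]
  out <- switch(def$kind,
    binary = {
      f <- as.factor(x)
      agg <- f == def$aggressive_level
      ifelse(is.na(f), NA, ifelse(agg, "aggressive", "baseline"))
    },
    level_set = {
      f <- as.character(x)
      base <- def$baseline_levels
      if (is.null(base)) base <- setdiff(unique(stats::na.omit(f)),
                                         def$aggressive_levels)
      ifelse(is.na(f), NA,
             ifelse(f %in% def$aggressive_levels, "aggressive",
                    ifelse(f %in% base, "baseline", NA)))
    },
    threshold = ifelse(is.na(x), NA,
                       ifelse(x >= def$cutoff, "aggressive", "baseline")),
    mean_split = {
      m <- mean(x, na.rm = TRUE)
      hi <- x > m
      if (def$low_is_aggressive) hi <- !hi
      ifelse(is.na(x), NA, ifelse(hi, "aggressive", "baseline"))
    })
  factor(out, levels = c("baseline", "aggressive"))
}

#' The four named aggressiveness parameters
#'
#' Lymph-node metastasis (N1 vs N0), extrathyroidal extension (present or
#' gross vs absent), tumor size (>= 1 cm vs < 1 cm) and aggressive
#' histological type (classical/tall-cell vs follicular papillary thyroid
#' carcinoma).
#'
#' @return named list of [parameter_definition()] objects.
#' @export
default_aggressiveness_parameters <- function() {
  list(
    LNM = parameter_definition("LNM", "LNM", "binary",
                               aggressive_level = "N1"),
    ETE = parameter_definition("ETE", "ETE", "level_set",
                               aggressive_levels = c("present", "gross")),
    size_1cm = parameter_definition("size_1cm", "tumor_size_cm", "threshold",
                                    cutoff = 1),
    histotype = parameter_definition("histotype", "histotype", "level_set",
                                     aggressive_levels = c("CPTC", "TPTC"),
                                     baseline_levels = "FPTC"))
}

#' Internal-validation parameter set
#'
#' The wider panel of aggressive-phenotype codings used for internal
#' validation within the aging tumor cohort: lymph-node metastasis, two
#' codings of extrathyroidal extension, two histotype codings, two tumor
#' size cut-offs, mean-dichotomized differentiation score (low =
#' aggressive), BRAF and TERT promoter mutation status.
#'
#' @return named list of [parameter_definition()] objects.
#' @export
validation_parameters <- function() {
  c(default_aggressiveness_parameters()[c("LNM", "ETE", "histotype")],
    list(
      ETE_gross = parameter_definition("ETE_gross", "ETE", "level_set",
                                       aggressive_levels = "gross",
                                       baseline_levels = c("absent",
                                                           "present")),
      hist_tall = parameter_definition("hist_tall", "histotype", "level_set",
                                       aggressive_levels = "TPTC",
                                       baseline_levels = c("FPTC", "CPTC")),
      size_1cm = parameter_definition("size_1cm", "tumor_size_cm",
                                      "threshold", cutoff = 1),
      size_2cm = parameter_definition("size_2cm", "tumor_size_cm",
                                      "threshold", cutoff = 2),
      differentiation = parameter_definition("differentiation",
                                             "differentiation_score",
                                             "mean_split",
                                             low_is_aggressive = TRUE),
      BRAF = parameter_definition("BRAF", "BRAF", "binary",
                                  aggressive_level = "MUT"),
      TERT = parameter_definition("TERT", "TERT", "binary",
                                  aggressive_level = "MUT")))
}

#' Gene-by-parameter association matrix from NB-GLM tests
#'
#' For each parameter, runs the negative-binomial likelihood-ratio test of
#' counts on the derived aggressive/non-aggressive factor, adjusted for the
#' given covariates, across the supplied samples. Returns aligned matrices
#' of BH-adjusted p-values and log2 fold changes, plus the signed transform
#' t = sign(log2fc) * |log2(padj)|.
#'
#' @param counts gene x sample matrix (already restricted to the genes of
#'   interest).
#' @param clinical aligned clinical table.
#' @param params list of [parameter_definition()]s.
#' @param covariates adjustment columns (e.g. gender and race, optionally
#'   age group).
#' @param ... passed to [nb_glm_lrt()].
#' @return list of class \code{assoc_matrix}: padj, log2fc, t (gene x
#'   parameter matrices), covariates.
#' @export
build_association_matrix <- function(counts, clinical, params,
                                     covariates = c("gender", "race"), ...) {
  pn <- names(params)
  padj <- lfc <- matrix(NA_real_, nrow(counts), length(params),
                        dimnames = list(rownames(counts), pn))
  for (k in seq_along(params)) {
    y <- parameter_factor(clinical, params[[k]])
    keep <- !is.na(y)
    cd <- clinical[keep, , drop = FALSE]
    cd$..param <- droplevels(y[keep])
    de <- nb_glm_lrt(counts[, keep, drop = FALSE], cd, contrast = "..param",
                     covariates = covariates, ref = "baseline", ...)
    padj[, k] <- de$padj
    lfc[, k] <- de$log2fc
  }
  tmat <- sign(lfc) * abs(log2(pmax(padj, 1e-300)))
  structure(list(padj = padj, log2fc = lfc, t = tmat,
                 covariates = covariates),
            class = "assoc_matrix")
}

#' Selection step: minimum number of significant parameter associations
#'
#' Keeps genes significantly associated (adjusted p < \code{alpha}) with at
#' least \code{k_min} of the named aggressiveness parameters.
#'
#' @param assoc an [build_association_matrix()] result (gender/race
#'   adjusted).
#' @param params parameter names to count over (default: all columns).
#' @param k_min minimum number of significant parameters (1..4, default 2).
#' @param alpha significance threshold.
#' @return character vector of retained genes.
#' @export
step2_min_parameter_hits <- function(assoc, params = colnames(assoc$padj),
                                     k_min = 2, alpha = 0.05) {
  if (!all(params %in% colnames(assoc$padj)))
    stop("missing parameter column(s): ",
         paste(setdiff(params, colnames(assoc$padj)), collapse = ", "),
         call. = FALSE)
  stopifnot(k_min >= 1, k_min <= length(params))
  hits <- rowSums(assoc$padj[, params, drop = FALSE] < alpha, na.rm = TRUE)
  rownames(assoc$padj)[hits >= k_min]
}

#' Selection step: directional concordance with the cancer contrast
#'
#' Keeps genes whose cancer-contrast fold change has the same sign as every
#' one of their significant parameter associations (genes up in tumors must
#' be positively associated with the aggressive levels, genes down
#' negatively). Genes with no significant association are dropped. A
#' hierarchical clustering of the signed transformed adjusted p-values
#' (Euclidean distance, average linkage) is attached for reporting; the
#' filter itself does not depend on it.
#'
#' @param assoc gender/race-adjusted [build_association_matrix()] result.
#' @param cancer_de DEResult of the cohort's tumor-vs-normal contrast.
#' @param genes genes entering the step (default: all in \code{assoc}).
#' @param alpha significance threshold for "significant association".
#' @return character vector of retained genes, with attribute
#'   \code{clustering} (an hclust object, or NULL for < 3 genes).
#' @export
step3_directional_concordance <- function(assoc, cancer_de,
                                          genes = rownames(assoc$padj),
                                          alpha = 0.05) {
  de_lfc <- setNames(cancer_de$log2fc, cancer_de$gene)[genes]
  keep <- vapply(genes, function(g) {
    sig <- which(!is.na(assoc$padj[g, ]) & assoc$padj[g, ] < alpha)
    if (!length(sig) || is.na(de_lfc[g])) return(FALSE)
    signs <- sign(assoc$log2fc[g, sig])
    all(signs == sign(de_lfc[g]))
  }, logical(1))
  out <- genes[keep]
  cl <- NULL
  if (length(genes) >= 3) {
    tm <- assoc$t[genes, , drop = FALSE]
    tm[is.na(tm)] <- 0
    cl <- stats::hclust(stats::dist(tm), method = "average")
  }
  attr(out, "clustering") <- cl
  out
}

#' Selection step: aging dependence of the parameter associations
#'
#' A gene is aging-dependent for a parameter when the gender/race-adjusted
#' association is significant while the age/gender/race-adjusted one is not
#' (mode "nonsig"), or is weaker than the gender/race one (mode "weaker":
#' non-significant or larger adjusted p). A gene is retained when at least
#' one parameter qualifies.
#'
#' @param padj_gr,padj_agr aligned gene x parameter matrices of adjusted
#'   p-values under the two adjustment modes.
#' @param alpha significance threshold.
#' @param mode "nonsig" (default) or "weaker".
#' @return character vector of retained genes with attribute
#'   \code{qualifying} (logical gene x parameter matrix).
#' @export
step4_aging_dependence <- function(padj_gr, padj_agr, alpha = 0.05,
                                   mode = c("nonsig", "weaker")) {
  mode <- match.arg(mode)
  if (!identical(dim(padj_gr), dim(padj_agr)) ||
      !identical(dimnames(padj_gr), dimnames(padj_agr)))
    stop("adjusted p-value matrices are misaligned", call. = FALSE)
  dep <- if (mode == "nonsig") padj_agr > alpha
         else padj_agr > alpha | padj_agr > padj_gr
  q <- !is.na(padj_gr) & padj_gr < alpha & !is.na(dep) & dep
  out <- rownames(padj_gr)[rowSums(q) >= 1]
  if (is.null(out)) out <- character(0)
  attr(out, "qualifying") <- q
  out
}

#' Internal validation of a candidate panel within the aging tumor cohort
#'
#' Within aging tumors only, tests each candidate gene's standardized log2
#' expression against a wide set of aggressive-phenotype parameters:
#' logistic regression (adjusted for the covariates) for the binary
#' parameters, proportional-hazards regression for the survival endpoints.
#' P-values are BH-adjusted across genes within each parameter. A gene is
#' retained with at least one significant association. Survival endpoints
#' with zero events are skipped with a warning, and the gene is judged on
#' the remaining parameters.
#'
#' @param expr gene x sample log2 normalized expression (aging tumors).
#' @param clinical aligned clinical table (aging tumors).
#' @param survival long survival table (sample / endpoint / time / event).
#' @param panel candidate gene ids.
#' @param covariates adjustment columns.
#' @param alpha significance threshold on adjusted p.
#' @return list of class \code{signature_panel}: genes (validated),
#'   candidate, hits (logical gene x parameter matrix), padj matrix.
#' @export
internal_validation <- function(expr, clinical, survival, panel,
                                covariates = c("gender", "race"),
                                alpha = 0.05) {
  if (!nrow(clinical)) stop("cohort lacks aging tumors", call. = FALSE)
  panel <- intersect(panel, rownames(expr))
  defs <- validation_parameters()
  endpoints <- intersect(c("DFS", "PFI", "OS", "DSS"),
                         unique(survival$endpoint))
  pn <- c(names(defs), endpoints)
  pmat <- matrix(NA_real_, length(panel), length(pn),
                 dimnames = list(panel, pn))
  if (!length(panel))
    return(structure(list(genes = character(), candidate = panel,
                          hits = pmat > 0, padj = pmat),
                     class = "signature_panel"))
  cov_df <- clinical[, covariates, drop = FALSE]
  z <- t(scale(t(expr[panel, clinical$sample, drop = FALSE])))
  for (d in names(defs)) {
    y <- parameter_factor(clinical, defs[[d]])
    if (nlevels(droplevels(y[!is.na(y)])) < 2) next
    for (g in panel) {
      df <- cbind(data.frame(y = y, x = z[g, ]), cov_df)
      fit <- suppressWarnings(
        tryCatch(stats::glm(y ~ ., data = df, family = stats::binomial()),
                 error = function(e) NULL))
      if (!is.null(fit) && "x" %in% rownames(summary(fit)$coefficients))
        pmat[g, d] <- summary(fit)$coefficients["x", 4]
    }
  }
  for (ep in endpoints) {
    sv <- survival[survival$endpoint == ep, ]
    sv <- sv[match(clinical$sample, sv$sample), ]
    if (sum(sv$event, na.rm = TRUE) == 0) {
      warning("no events for endpoint ", ep, " in the aging cohort; skipped")
      next
    }
    for (g in panel) {
      df <- cbind(data.frame(time = sv$time, event = sv$event, x = z[g, ]),
                  cov_df)
      fit <- suppressWarnings(tryCatch(
        survival::coxph(survival::Surv(time, event) ~ ., data = df),
        error = function(e) NULL))
      if (!is.null(fit) && "x" %in% rownames(summary(fit)$coefficients))
        pmat[g, ep] <- summary(fit)$coefficients["x", 5]
    }
  }
  padj <- apply(pmat, 2, bh_adjust)
  if (is.null(dim(padj))) padj <- matrix(padj, nrow = length(panel),
                                         dimnames = dimnames(pmat))
  hits <- !is.na(padj) & padj < alpha
  structure(list(genes = panel[rowSums(hits) >= 1], candidate = panel,
                 hits = hits, padj = padj),
            class = "signature_panel")
}

#' Run the full signature-selection pipeline on a cohort
#'
#' Chains the selection stages: (1) cohort-specific differential expression
#' (tumor vs normal in the cohort of interest, excluding genes selected in
#' the other age cohort or in the normal-tissue age contrast); (2) at least
#' \code{k_min} significant associations with the four named aggressiveness
#' parameters across all tumors, adjusted for gender and race; (3)
#' directional concordance with the cancer contrast; (4) aging dependence
#' (association lost after additionally adjusting for age group); then
#' internal validation within the cohort's own tumors. The "young" mode is
#' fully symmetric and selects markers dependent on age below the cut-off.
#'
#' @param cohort list with counts, clinical, survival (as produced by
#'   [generate_cohort()]).
#' @param mode "aging" or "young": which cohort's panel to select.
#' @param alpha significance threshold used throughout.
#' @param lfc_min fold-change threshold for the cohort-specific step.
#' @param k_min minimum parameter hits in step 2.
#' @param aging_dependence_mode passed to [step4_aging_dependence()].
#' @param min_count low-count filter for the DE engine.
#' @return list of class \code{signature_pipeline}: panel (validated gene
#'   ids), provenance data frame with per-step survival flags, per-step
#'   counts, the validation object and the intermediate DE results.
#' @export
run_signature_pipeline <- function(cohort, mode = c("aging", "young"),
                                   alpha = 0.05, lfc_min = 1, k_min = 2,
                                   aging_dependence_mode = "nonsig",
                                   min_count = 10) {
  mode <- match.arg(mode)
  cl <- cohort$clinical
  counts <- cohort$counts
  if (!any(cl$age_group == "aging") || !any(cl$age_group == "young"))
    stop("cohort must contain both age groups", call. = FALSE)
  if (!any(cl$tissue == "tumor") || !any(cl$tissue == "normal"))
    stop("cohort must contain tumor and normal samples", call. = FALSE)
  own <- if (mode == "aging") "aging" else "young"
  other <- if (mode == "aging") "young" else "aging"

  tvn <- function(group) {
    j <- cl$age_group == group
    nb_glm_lrt(counts[, j, drop = FALSE], cl[j, , drop = FALSE],
               contrast = "tissue", covariates = c("gender", "race"),
               ref = "normal", min_count = min_count)
  }
  de_own <- tvn(own)
  de_other <- tvn(other)
  jn <- cl$tissue == "normal"
  de_norm <- nb_glm_lrt(counts[, jn, drop = FALSE], cl[jn, , drop = FALSE],
                        contrast = "age_group", covariates = c("gender",
                                                               "race"),
                        ref = "young", min_count = min_count)
  step1 <- cohort_specific_sets(de_own, de_other, de_norm, alpha, lfc_min)

  jt <- cl$tissue == "tumor"
  cl_t <- cl[jt, , drop = FALSE]
  params <- default_aggressiveness_parameters()
  if (length(step1)) {
    cnt_t <- counts[step1, jt, drop = FALSE]
    assoc_gr <- build_association_matrix(cnt_t, cl_t, params,
                                         covariates = c("gender", "race"),
                                         min_count = min_count)
    assoc_agr <- build_association_matrix(cnt_t, cl_t, params,
                                          covariates = c("age_group",
                                                         "gender", "race"),
                                          min_count = min_count)
    step2 <- step2_min_parameter_hits(assoc_gr, k_min = k_min, alpha = alpha)
    step3 <- step3_directional_concordance(assoc_gr, de_own, genes = step2,
                                           alpha = alpha)
    step4 <- step4_aging_dependence(assoc_gr$padj[step3, , drop = FALSE],
                                    assoc_agr$padj[step3, , drop = FALSE],
                                    alpha = alpha,
                                    mode = aging_dependence_mode)
  } else {
    assoc_gr <- assoc_agr <- NULL
    step2 <- step3 <- step4 <- character()
  }

  jv <- cl$tissue == "tumor" & cl$age_group == own
  expr <- normalized_log2(counts)
  val <- internal_validation(expr[, jv, drop = FALSE],
                             cl[jv, , drop = FALSE],
                             cohort$survival, step4, alpha = alpha)

  genes <- de_own$gene
  prov <- data.frame(gene = genes,
                     step1 = genes %in% step1,
                     step2 = genes %in% step2,
                     step3 = genes %in% step3,
                     step4 = genes %in% step4,
                     validated = genes %in% val$genes)
  structure(list(panel = val$genes, mode = mode, provenance = prov,
                 counts = c(step1 = length(step1), step2 = length(step2),
                            step3 = length(step3), step4 = length(step4),
                            validated = length(val$genes)),
                 validation = val,
                 de = list(own = de_own, other = de_other,
                           normal = de_norm),
                 assoc = list(gr = assoc_gr, agr = assoc_agr)),
            class = "signature_pipeline")
}
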