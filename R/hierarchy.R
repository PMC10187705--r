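## Cluster-by-parameter contingency analysis and the aggressiveness
## hierarchy: chi-square association of clinical parameters with the four
## score-derived clusters, enrichment-direction calls from Pearson
## residuals, and the per-cluster aggressiveness ratio.

#' Bundled reference cluster-by-parameter summary
#'
#' Published distribution of 15 clinical-parameter splits across the four
#' aggressiveness clusters (LAYC, MAYC, LAAC, MAAC) of 481 TCGA papillary
#' thyroid carcinoma samples, together with the per-cluster sample counts
#' and the published enrichment tallies. Shipped as plain TSV in
#' \code{extdata}; used as a worked reference for the hierarchy functions.
#'
#' @return list: \code{tables} (named list of level x cluster count
#'   matrices, each with the aggressive level in attribute
#'   \code{aggressive_level}), \code{summary} (data frame: cluster,
#'   n_samples, n_aggressive_enrichments, n_non_aggressive_enrichments).
#' @export
thyroid_cluster_reference <- function() {
  cf <- system.file("extdata", "cluster_clinical_counts.tsv",
                    package = "agesig", mustWork = TRUE)
  sf <- system.file("extdata", "cluster_summary.tsv", package = "agesig",
                    mustWork = TRUE)
  counts <- utils::read.delim(cf, stringsAsFactors = FALSE)
  summary <- utils::read.delim(sf, stringsAsFactors = FALSE)
  clusters <- c("LAYC", "MAYC", "LAAC", "MAAC")
  tables <- lapply(split(counts, counts$parameter), function(d) {
    m <- as.matrix(d[, clusters])
    rownames(m) <- d$level
    attr(m, "aggressive_level") <- d$level[d$aggressive == "yes"]
    m
  })
  list(tables = tables[unique(counts$parameter)], summary = summary)
}

#' Cluster-by-parameter contingency tables with chi-square tests
#'
#' Builds one level x cluster table per clinical parameter and tests the
#' association with a Pearson chi-square (no continuity correction).
#'
#' @param clinical per-sample clinical table.
#' @param clusters per-sample cluster labels (no empty cluster).
#' @param parameter_defs named list of [parameter_definition()]s.
#' @return named list; per parameter: table, test ([chisq_test()] result),
#'   aggressive_level.
#' @export
cluster_parameter_tables <- function(clinical, clusters, parameter_defs) {
  cl <- droplevels(as.factor(clusters))
  if (any(table(cl) == 0) || nlevels(cl) < 2)
    stop("clusters must be non-empty", call. = FALSE)
  out <- lapply(parameter_defs, function(def) {
    y <- parameter_factor(clinical, def)
    tab <- table(y, cl)
    tab <- tab[rowSums(tab) > 0, , drop = FALSE]
    list(table = unclass(as.matrix(tab)), test = chisq_test(tab),
         aggressive_level = "aggressive")
  })
  names(out) <- names(parameter_defs)
  out
}

#' Enrichment-direction calls per cluster and parameter
#'
#' For parameters with a significant cluster association (chi-square p <
#' \code{alpha}), a cluster is called "aggressive" when its Pearson
#' residual (O - E)/sqrt(E) in the aggressive level strictly exceeds
#' \code{residual_thr}, "non-aggressive" when a non-aggressive level's
#' residual does, and "none" otherwise. Non-significant parameters produce
#' no calls.
#'
#' @param tables list as from [cluster_parameter_tables()], or a named list
#'   of count matrices each carrying an \code{aggressive_level} attribute.
#' @param residual_thr strict residual threshold (2 is the conventional
#'   post-hoc cut-off).
#' @param alpha parameter-significance threshold.
#' @return data frame: parameter, cluster, observed, expected, residual,
#'   call, parameter_p.
#' @export
enrichment_directions <- function(tables, residual_thr = 2, alpha = 0.05) {
  norm <- lapply(names(tables), function(nm) {
    el <- tables[[nm]]
    if (is.matrix(el))
      el <- list(table = el, test = chisq_test(el),
                 aggressive_level = attr(el, "aggressive_level"))
    el$parameter <- nm
    el
  })
  rows <- lapply(norm, function(el) {
    res <- el$test$residuals
    agg_rows <- rownames(el$table) %in% el$aggressive_level
    sig <- el$test$p.value < alpha
    do.call(rbind, lapply(colnames(el$table), function(cl) {
      r_agg <- max(res[agg_rows, cl])
      r_non <- max(res[!agg_rows, cl])
      call <- if (!sig) "none"
      else if (r_agg > residual_thr) "aggressive"
      else if (r_non > residual_thr) "non-aggressive"
      else "none"
      data.frame(parameter = el$parameter, cluster = cl,
                 observed = sum(el$table[agg_rows, cl]),
                 expected = sum(el$test$expected[agg_rows, cl]),
                 residual = r_agg, call = call,
                 parameter_p = el$test$p.value,
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Aggressiveness ratio of a cluster
#'
#' (aggressive enrichments - non-aggressive enrichments) divided by the
#' number of significant parameters, rounded for reporting.
#'
#' @param n_agg,n_non enrichment counts (their sum cannot exceed
#'   \code{n_params}).
#' @param n_params number of significant parameters (> 0).
#' @param digits reporting precision (NULL for full precision).
#' @return numeric ratio in \[-1, 1\].
#' @export
aggressiveness_ratio <- function(n_agg, n_non, n_params, digits = 2) {
  if (any(n_params <= 0)) stop("n_params must be positive", call. = FALSE)
  if (any(n_agg + n_non > n_params))
    stop("enrichment counts exceed the number of parameters",
         call. = FALSE)
  r <- (n_agg - n_non) / n_params
  if (!is.null(digits)) r <- round(r, digits)
  r
}

#' Summarize enrichment calls into a per-cluster hierarchy
#'
#' @param enrich [enrichment_directions()] output.
#' @param n_params number of significant parameters; by default counted
#'   from the calls table.
#' @param digits ratio reporting precision.
#' @return data frame of class \code{hierarchy_result}: cluster,
#'   n_aggressive, n_non_aggressive, ratio.
#' @export
hierarchy_result <- function(enrich, n_params = NULL, digits = 2) {
  if (is.null(n_params))
    n_params <- length(unique(enrich$parameter[enrich$parameter_p < 0.05]))
  ag <- tapply(enrich$call == "aggressive", enrich$cluster, sum)
  no <- tapply(enrich$call == "non-aggressive", enrich$cluster, sum)
  out <- data.frame(cluster = names(ag), n_aggressive = as.integer(ag),
                    n_non_aggressive = as.integer(no),
                    ratio = aggressiveness_ratio(as.integer(ag),
                                                 as.integer(no), n_params,
                                                 digits),
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("hierarchy_result", "data.frame")
  out
}

#' Rank clusters from most to least aggressive
#'
#' Descending aggressiveness ratio; ties broken by the aggressive
#' enrichment count, then alphabetically (flagged).
#'
#' @param hier a [hierarchy_result()] data frame.
#' @return character vector of cluster labels, most aggressive first, with
#'   logical attribute \code{ties}.
#' @export
rank_clusters <- function(hier) {
  ord <- order(-hier$ratio, -hier$n_aggressive, hier$cluster)
  out <- hier$cluster[ord]
  attr(out, "ties") <- anyDuplicated(hier[, c("ratio", "n_aggressive")]) > 0
  out
}
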