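#' Configuration for a synthetic multi-omics tumor cohort
#'
#' Builds a validated configuration object for [generate_cohort()]. The
#' defaults emulate a papillary thyroid carcinoma study cohort: 160 tumors
#' from patients aged 55 and over with 19 paired normals, 321 tumors from
#' patients under 55 with 38 paired normals, and 1000 genes of which a
#' stated fraction belongs to each planted expression class.
#'
#' Planted gene classes (fractions of \code{n_genes}, remainder is null):
#' \describe{
#'   \item{shared_cancer}{log2 effect \code{lfc_cancer} in all tumors.}
#'   \item{aging_cancer_specific}{effect \code{lfc_cancer} only in tumors of
#'     the aging (>= 55) group.}
#'   \item{young_cancer_specific}{effect only in tumors of the young group.}
#'   \item{aging_dependent_aggressive}{aging-specific cancer effect plus a
#'     shift of \code{lfc_aggressive} per unit of the latent aggressiveness
#'     score, applied in aging tumor samples only.}
#'   \item{age_independent_aggressive}{aging-specific cancer effect plus the
#'     latent-aggressiveness shift in every tumor sample regardless of age.}
#'   \item{cnv_driven}{aging-specific cancer effect; counts additionally
#'     scale multiplicatively with \code{2^cnv} for the planted amplified
#'     segment (a chromosome-1q-like gain carried by a fraction of aging
#'     tumors).}
#' }
#'
#' The latent aggressiveness score is Gaussian per sample with a higher mean
#' in aging tumors than young tumors, so clinical aggressiveness parameters
#' (which are Bernoulli draws with log-odds slope \code{clinical_coupling}
#' on the latent score) are enriched in the aging group, as observed in
#' thyroid carcinoma cohorts.
#'
#' @param n_aging_tumor,n_aging_normal,n_young_tumor,n_young_normal sample
#'   counts per age group and tissue (all must be positive).
#' @param n_genes number of genes.
#' @param class_fractions named numeric vector of planted class fractions;
#'   must lie in \[0,1\] and sum to at most 1.
#' @param lfc_cancer planted tumor-vs-normal log2 fold change.
#' @param lfc_aggressive planted log2 shift per unit latent aggressiveness.
#' @param nb_dispersion negative-binomial dispersion (1/size), constant
#'   across genes.
#' @param libsize_range interval for the uniform library-size multiplier.
#' @param clinical_coupling log-odds slope linking the latent aggressiveness
#'   score to the binary clinical parameters.
#' @param latent_mean_aging,latent_mean_young,latent_sd parameters of the
#'   per-sample latent aggressiveness distribution by age group.
#' @param cnv_segment list with elements \code{gain} (segment-mean magnitude
#'   of the planted amplification) and \code{carrier_fraction} (fraction of
#'   aging tumors carrying it, in \[0,1\]).
#' @param surv_baseline_hazard baseline exponential event hazard (per year).
#' @param surv_cluster_hr hazard ratio applied to samples with positive
#'   latent aggressiveness.
#' @param censor_rate expected fraction of administratively censored samples.
#' @param young_zero_event_os force zero overall/disease-specific survival
#'   events in the young group (the degenerate stratum seen in thyroid
#'   cancer cohorts, where Cox models cannot be fit for young patients).
#' @param seed integer RNG seed; the generator is fully deterministic given
#'   the configuration.
#' @return object of class \code{cohort_config}.
#' @seealso [generate_cohort()], [generate_survival()]
#' @export
cohort_config <- function(n_aging_tumor = 160L,
                          n_aging_normal = 19L,
                          n_young_tumor = 321L,
                          n_young_normal = 38L,
                          n_genes = 1000L,
                          class_fractions = c(shared_cancer = 0.05,
                                              aging_cancer_specific = 0.06,
                                              young_cancer_specific = 0.03,
                                              aging_dependent_aggressive = 0.03,
                                              age_independent_aggressive = 0.03,
                                              cnv_driven = 0.02),
                          lfc_cancer = 2,
                          lfc_aggressive = 0.6,
                          nb_dispersion = 0.1,
                          libsize_range = c(0.7, 1.4),
                          clinical_coupling = 1.2,
                          latent_mean_aging = 1.5,
                          latent_mean_young = -0.75,
                          latent_sd = 1,
                          cnv_segment = list(gain = 0.6, carrier_fraction = 0.3),
                          surv_baseline_hazard = 0.05,
                          surv_cluster_hr = 3,
                          censor_rate = 0.7,
                          young_zero_event_os = TRUE,
                          seed = 1L) {
  sizes <- c(n_aging_tumor, n_aging_normal, n_young_tumor, n_young_normal)
  if (any(!is.finite(sizes)) || any(sizes <= 0))
    stop("all sample counts must be positive", call. = FALSE)
  if (n_genes <= 0) stop("n_genes must be positive", call. = FALSE)
  known <- c("shared_cancer", "aging_cancer_specific", "young_cancer_specific",
             "aging_dependent_aggressive", "age_independent_aggressive",
             "cnv_driven")
  if (is.null(names(class_fractions)) ||
      !all(names(class_fractions) %in% known))
    stop("class_fractions must be named with known gene classes",
         call. = FALSE)
  fr <- setNames(numeric(length(known)), known)
  fr[names(class_fractions)] <- class_fractions
  if (any(fr < 0) || any(fr > 1) || sum(fr) > 1)
    stop("class fractions must lie in [0,1] and sum to at most 1",
         call. = FALSE)
  if (nb_dispersion <= 0) stop("nb_dispersion must be > 0", call. = FALSE)
  if (length(libsize_range) != 2L || diff(libsize_range) < 0 ||
      libsize_range[1] <= 0)
    stop("libsize_range must be an increasing positive interval",
         call. = FALSE)
  if (cnv_segment$carrier_fraction < 0 || cnv_segment$carrier_fraction > 1)
    stop("carrier_fraction must lie in [0,1]", call. = FALSE)
  if (surv_baseline_hazard < 0) stop("negative hazard", call. = FALSE)
  if (surv_cluster_hr <= 0) stop("surv_cluster_hr must be > 0", call. = FALSE)
  if (censor_rate < 0 || censor_rate > 1)
    stop("censor_rate must lie in [0,1]", call. = FALSE)
  structure(list(n_aging_tumor = as.integer(n_aging_tumor),
                 n_aging_normal = as.integer(n_aging_normal),
                 n_young_tumor = as.integer(n_young_tumor),
                 n_young_normal = as.integer(n_young_normal),
                 n_genes = as.integer(n_genes),
                 class_fractions = fr,
                 lfc_cancer = lfc_cancer,
                 lfc_aggressive = lfc_aggressive,
                 nb_dispersion = nb_dispersion,
                 libsize_range = libsize_range,
                 clinical_coupling = clinical_coupling,
                 latent_mean_aging = latent_mean_aging,
                 latent_mean_young = latent_mean_young,
                 latent_sd = latent_sd,
                 cnv_segment = cnv_segment,
                 surv_baseline_hazard = surv_baseline_hazard,
                 surv_cluster_hr = surv_cluster_hr,
                 censor_rate = censor_rate,
                 young_zero_event_os = young_zero_event_os,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# marginal prevalence targets for the binary clinical parameters, matching
# a typical papillary thyroid carcinoma cohort (used to set intercepts)
.clinical_prevalence <- c(LNM = 0.50, ETE = 0.28, ETE_gross = 0.12,
                          hist_aggressive = 0.79, hist_tall = 0.10,
                          BRAF = 0.70, TERT = 0.08)

.immune_cells <- c("B_naive", "B_memory", "Plasma", "T_CD8", "T_CD4_naive",
                   "T_CD4_mem_rest", "T_CD4_mem_act", "T_fh", "T_reg",
                   "T_gd", "NK_rest", "NK_act", "Monocyte", "Macro_M0",
                   "Macro_M1", "Macro_M2", "DC_rest", "DC_act", "Mast_rest",
                   "Mast_act", "Eosinophil", "Neutrophil")

#' Generate a synthetic multi-omics cohort with planted ground truth
#'
#' Draws an expression count matrix (negative binomial with a log-linear
#' mean model and library-size multipliers), a gene-level copy-number
#' matrix with a planted amplified segment, a per-sample clinical table with
#' aggressiveness parameters coupled to a latent aggressiveness score, and
#' right-censored survival endpoints with cluster-dependent hazards.
#' Fully deterministic given \code{config$seed}.
#'
#' @param config a [cohort_config()] object.
#' @return list with elements \code{cohort} (list: \code{counts} gene x
#'   sample integer matrix, \code{cnv} gene x sample segment-mean matrix,
#'   \code{clinical} per-sample data frame, \code{survival} long data frame
#'   with columns sample/endpoint/time/event) and \code{truth} (list:
#'   \code{gene_class} per-gene factor, \code{latent_aggressiveness}
#'   per-sample numeric, \code{cnv_carriers} sample ids).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  ng <- config$n_genes

  grp <- rep(c("aging_tumor", "aging_normal", "young_tumor", "young_normal"),
             c(config$n_aging_tumor, config$n_aging_normal,
               config$n_young_tumor, config$n_young_normal))
  ns <- length(grp)
  sample_id <- sprintf("S%04d", seq_len(ns))
  age_group <- ifelse(grepl("^aging", grp), "aging", "young")
  tissue <- ifelse(grepl("tumor$", grp), "tumor", "normal")
  is_tumor <- tissue == "tumor"
  is_aging <- age_group == "aging"

  ## gene classes occupy disjoint contiguous blocks; remainder is null
  n_class <- round(config$class_fractions * ng)
  gene_class <- rep("null", ng)
  at <- 1L
  for (cl in names(n_class)) {
    if (n_class[[cl]] > 0) {
      gene_class[at:(at + n_class[[cl]] - 1L)] <- cl
      at <- at + n_class[[cl]]
    }
  }
  gene_id <- sprintf("G%04d", seq_len(ng))

  ## covariates
  age_years <- ifelse(is_aging, runif(ns, 55, 85), runif(ns, 20, 54))
  gender <- factor(sample(c("female", "male"), ns, TRUE, c(0.73, 0.27)),
                   levels = c("female", "male"))
  race <- factor(sample(c("white", "black", "asian"), ns, TRUE,
                        c(0.80, 0.10, 0.10)),
                 levels = c("white", "black", "asian"))

  ## latent aggressiveness: higher in aging tumors, fixed at 0 in normals
  latent <- numeric(ns)
  latent[is_tumor] <- rnorm(sum(is_tumor),
                            ifelse(is_aging[is_tumor],
                                   config$latent_mean_aging,
                                   config$latent_mean_young),
                            config$latent_sd)

  ## copy number: Gaussian segment-mean noise plus a planted amplified
  ## segment spanning the cnv_driven gene block, carried by a random subset
  ## of aging tumors
  cnv <- matrix(rnorm(ng * ns, 0, 0.03), ng, ns,
                dimnames = list(gene_id, sample_id))
  seg_genes <- which(gene_class == "cnv_driven")
  aging_tumor_idx <- which(is_tumor & is_aging)
  n_carrier <- round(config$cnv_segment$carrier_fraction *
                       length(aging_tumor_idx))
  carriers <- sort(sample(aging_tumor_idx, n_carrier))
  if (length(seg_genes) && length(carriers))
    cnv[seg_genes, carriers] <- cnv[seg_genes, carriers] +
      config$cnv_segment$gain

  ## expression mean model on the log2 scale
  base_log2 <- rnorm(ng, mean = 7, sd = 1.8)
  libsize <- runif(ns, config$libsize_range[1], config$libsize_range[2])
  eff <- matrix(0, ng, ns)
  add_fx <- function(genes, samples, value) {
    if (length(genes) && length(samples))
      eff[genes, samples] <<- eff[genes, samples] + value
  }
  tum <- which(is_tumor)
  agt <- which(is_tumor & is_aging)
  ygt <- which(is_tumor & !is_aging)
  add_fx(which(gene_class == "shared_cancer"), tum, config$lfc_cancer)
  for (cl in c("aging_cancer_specific", "aging_dependent_aggressive",
               "age_independent_aggressive", "cnv_driven"))
    add_fx(which(gene_class == cl), agt, config$lfc_cancer)
  add_fx(which(gene_class == "young_cancer_specific"), ygt,
         config$lfc_cancer)
  gad <- which(gene_class == "aging_dependent_aggressive")
  if (length(gad))
    eff[gad, agt] <- eff[gad, agt] +
      config$lfc_aggressive * rep(latent[agt], each = length(gad))
  gai <- which(gene_class == "age_independent_aggressive")
  if (length(gai))
    eff[gai, tum] <- eff[gai, tum] +
      config$lfc_aggressive * rep(latent[tum], each = length(gai))
  if (length(seg_genes))
    eff[seg_genes, ] <- eff[seg_genes, ] + cnv[seg_genes, , drop = FALSE]
  ## mild sex effect on a random 5% of genes so covariate adjustment matters
  sex_genes <- sample.int(ng, max(1L, round(0.05 * ng)))
  add_fx(sex_genes, which(gender == "male"), 0.25)

  log2mu <- base_log2 + eff + rep(log2(libsize), each = ng)
  mu <- 2^pmin(log2mu, 31)
  counts <- matrix(rnbinom(ng * ns, mu = mu, size = 1 / config$nb_dispersion),
                   ng, ns, dimnames = list(gene_id, sample_id))

  ## clinical aggressiveness parameters (tumors only)
  cc <- config$clinical_coupling
  prev <- .clinical_prevalence
  draw <- function(target, slope) {
    p <- stats::plogis(stats::qlogis(target) + slope * latent)
    out <- rbinom(ns, 1, p)
    out[!is_tumor] <- NA_integer_
    out
  }
  lnm <- draw(prev["LNM"], cc)
  ete_any <- draw(prev["ETE"], cc)
  ete_gross <- draw(prev["ETE_gross"], 0.8 * cc)   # gross given present
  hist_agg <- draw(prev["hist_aggressive"], cc)
  hist_tall <- draw(prev["hist_tall"], 0.8 * cc)   # tall given aggressive
  braf <- draw(prev["BRAF"], cc)
  tert <- draw(prev["TERT"], cc)
  ete <- ifelse(ete_any == 1L, ifelse(ete_gross == 1L, "gross", "present"),
                "absent")
  histotype <- ifelse(hist_agg == 1L, ifelse(hist_tall == 1L, "TPTC", "CPTC"),
                      "FPTC")
  ## tumor size is deliberately uncoupled from the latent score: in thyroid
  ## carcinoma cohorts the 1 cm size split shows no cluster association
  tumor_size_cm <- exp(rnorm(ns, log(1.6), 0.45))
  tumor_size_cm[!is_tumor] <- NA_real_
  differentiation <- rnorm(ns, 0, 1) - 0.8 * latent
  differentiation[!is_tumor] <- NA_real_

  ## immune fractions: Dirichlet draw, 22 cell phenotypes summing to 1
  alpha <- c(3, 2, 1, 6, 2, 4, 2, 3, 2, 1, 2, 1, 3, 4, 2, 4, 2, 1, 2, 1, 1, 1)
  gm <- matrix(rgamma(ns * 22L, shape = rep(alpha, each = ns)), ns, 22L)
  imm <- gm / rowSums(gm)
  colnames(imm) <- paste0("imm_", .immune_cells)

  clinical <- data.frame(sample = sample_id,
                         age_years = age_years,
                         age_group = factor(age_group,
                                            levels = c("young", "aging")),
                         tissue = factor(tissue,
                                         levels = c("normal", "tumor")),
                         gender = gender, race = race,
                         LNM = factor(ifelse(is.na(lnm), NA,
                                             ifelse(lnm == 1L, "N1", "N0")),
                                      levels = c("N0", "N1")),
                         ETE = factor(ifelse(is_tumor, ete, NA),
                                      levels = c("absent", "present",
                                                 "gross")),
                         tumor_size_cm = tumor_size_cm,
                         histotype = factor(ifelse(is_tumor, histotype, NA),
                                            levels = c("FPTC", "CPTC",
                                                       "TPTC")),
                         BRAF = factor(ifelse(is.na(braf), NA,
                                              ifelse(braf == 1L, "MUT",
                                                     "WT")),
                                       levels = c("WT", "MUT")),
                         TERT = factor(ifelse(is.na(tert), NA,
                                              ifelse(tert == 1L, "MUT",
                                                     "WT")),
                                       levels = c("WT", "MUT")),
                         differentiation_score = differentiation,
                         stringsAsFactors = FALSE)
  clinical <- cbind(clinical, as.data.frame(imm))

  surv <- generate_survival(latent, config, age_group = age_group,
                            sample_id = sample_id, tumor = is_tumor)

  cohort <- list(counts = counts, cnv = cnv, clinical = clinical,
                 survival = surv)
  truth <- list(gene_class = factor(gene_class,
                                    levels = c("null", names(n_class)),
                                    labels = c("null", names(n_class))),
                latent_aggressiveness = setNames(latent, sample_id),
                cnv_carriers = sample_id[carriers])
  names(truth$gene_class) <- gene_id
  list(cohort = cohort, truth = truth)
}

#' Generate right-censored survival endpoints from a latent score
#'
#' Event times are exponential with hazard
#' \code{surv_baseline_hazard * surv_cluster_hr^(latent > 0)}. Censoring is
#' independent per subject: a censoring time is drawn from an exponential
#' whose rate is set so the expected censored fraction equals
#' \code{censor_rate} (censoring independent of the event time given the
#' hazard group, so proportional-hazards estimates remain unbiased).
#' Endpoints DFS and PFI use the baseline hazard; OS and DSS use 0.4 times
#' the baseline; when \code{young_zero_event_os} is set, OS/DSS events in
#' young samples are suppressed (administratively censored), reproducing
#' the degenerate young stratum in which survival models cannot be fit.
#'
#' @param latent per-sample latent aggressiveness score (finite).
#' @param config a [cohort_config()] (hazard, HR, censoring fields used).
#' @param age_group optional per-sample "young"/"aging" labels (needed for
#'   the zero-event young stratum rule).
#' @param sample_id optional sample identifiers.
#' @param tumor optional logical; non-tumor samples get NA rows.
#' @return long data frame: sample, endpoint (DFS/PFI/OS/DSS), time, event.
#' @export
generate_survival <- function(latent, config, age_group = NULL,
                              sample_id = NULL, tumor = NULL) {
  if (any(!is.finite(latent))) stop("latent scores must be finite",
                                    call. = FALSE)
  if (config$surv_baseline_hazard < 0) stop("negative hazard", call. = FALSE)
  ns <- length(latent)
  if (is.null(sample_id)) sample_id <- sprintf("S%04d", seq_len(ns))
  if (is.null(tumor)) tumor <- rep(TRUE, ns)
  cr <- config$censor_rate
  hr_mult <- ifelse(latent > 0, config$surv_cluster_hr, 1)
  one_endpoint <- function(base_mult, zero_young = FALSE) {
    h <- config$surv_baseline_hazard * base_mult * hr_mult
    h <- pmax(h, 1e-12)
    tt <- rexp(ns, rate = h)
    if (cr >= 1) {
      time <- tt
      event <- rep(0L, ns)
    } else {
      c_rate <- h * cr / (1 - cr)
      cens <- if (cr <= 0) rep(Inf, ns) else rexp(ns, rate = c_rate)
      event <- as.integer(tt <= cens)
      time <- pmin(tt, cens)
    }
    if (zero_young && !is.null(age_group)) {
      yy <- age_group == "young"
      event[yy] <- 0L
    }
    time <- pmax(time, 1e-6)
    time[!tumor] <- NA_real_
    event[!tumor] <- NA_integer_
    data.frame(sample = sample_id, time = time, event = event,
               stringsAsFactors = FALSE)
  }
  out <- rbind(cbind(endpoint = "DFS", one_endpoint(1)),
               cbind(endpoint = "PFI", one_endpoint(1)),
               cbind(endpoint = "OS",
                     one_endpoint(0.4, config$young_zero_event_os)),
               cbind(endpoint = "DSS",
                     one_endpoint(0.4, config$young_zero_event_os)))
  out[, c("sample", "endpoint", "time", "event")]
}

#' Write a synthetic cohort to TSV files
#'
#' Writes counts.tsv, cnv.tsv, clinical.tsv, survival.tsv and truth.tsv
#' into \code{dir}.
#'
#' @param sim result of [generate_cohort()].
#' @param dir output directory (created if absent).
#' @return invisibly, the directory.
#' @export
write_cohort <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wm <- function(m, f) utils::write.table(
    data.frame(gene = rownames(m), m, check.names = FALSE),
    file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  wm(sim$cohort$counts, "counts.tsv")
  wm(sim$cohort$cnv, "cnv.tsv")
  utils::write.table(sim$cohort$clinical, file.path(dir, "clinical.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$cohort$survival, file.path(dir, "survival.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- data.frame(gene = names(sim$truth$gene_class),
                      gene_class = as.character(sim$truth$gene_class))
  utils::write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir directory containing the TSV files.
#' @return list with counts, cnv, clinical, survival (and truth when
#'   present).
#' @export
read_cohort <- function(dir) {
  rm_ <- function(f) {
    d <- utils::read.delim(file.path(dir, f), check.names = FALSE)
    m <- as.matrix(d[, -1, drop = FALSE])
    rownames(m) <- d[[1]]
    m
  }
  out <- list(counts = rm_("counts.tsv"), cnv = rm_("cnv.tsv"),
              clinical = utils::read.delim(file.path(dir, "clinical.tsv")),
              survival = utils::read.delim(file.path(dir, "survival.tsv")))
  out$clinical$age_group <- factor(out$clinical$age_group,
                                   levels = c("young", "aging"))
  out$clinical$tissue <- factor(out$clinical$tissue,
                                levels = c("normal", "tumor"))
  tf <- file.path(dir, "truth.tsv")
  if (file.exists(tf)) out$truth <- utils::read.delim(tf)
  out
}
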