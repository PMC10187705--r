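make_clinical <- function() {
  data.frame(sample = c("s1", "s2", "s3", "s4", "s5", "s6"),
             LNM = factor(c("N0", "N1", "N1", "N0", NA, "N1"),
                          levels = c("N0", "N1")),
             ETE = factor(c("absent", "present", "gross", "absent",
                            "present", "absent"),
                          levels = c("absent", "present", "gross")),
             tumor_size_cm = c(0.5, 1.0, 2.4, 0.9, 1.1, NA),
             histotype = factor(c("FPTC", "CPTC", "TPTC", "FPTC", "CPTC",
                                  "CPTC"),
                                levels = c("FPTC", "CPTC", "TPTC")),
             differentiation_score = c(2, -1, -2, 1, 0.5, -0.5),
             stringsAsFactors = FALSE)
}

test_that("parameter_factor derives the documented codings", {
  cl <- make_clinical()
  defs <- default_aggressiveness_parameters()
  lnm <- parameter_factor(cl, defs$LNM)
  expect_identical(as.character(lnm),
                   c("baseline", "aggressive", "aggressive", "baseline", NA,
                     "aggressive"))
  ete <- parameter_factor(cl, defs$ETE)
  expect_identical(as.character(ete),
                   c("baseline", "aggressive", "aggressive", "baseline",
                     "aggressive", "baseline"))
  ## threshold is inclusive at the cut-off (1.0 cm counts as aggressive)
  sz <- parameter_factor(cl, defs$size_1cm)
  expect_identical(as.character(sz),
                   c("baseline", "aggressive", "aggressive", "baseline",
                     "aggressive", NA))
  hist <- parameter_factor(cl, defs$histotype)
  expect_identical(as.character(hist),
                   c("baseline", "aggressive", "aggressive", "baseline",
                     "aggressive", "aggressive"))
  ## level_set drops values outside aggressive+baseline levels
  tall <- parameter_factor(cl, validation_parameters()$hist_tall)
  expect_identical(as.character(tall),
                   c("baseline", "baseline", "aggressive", "baseline",
                     "baseline", "baseline"))
  ## mean-split with low = aggressive
  dif <- parameter_factor(cl, validation_parameters()$differentiation)
  expect_identical(as.character(dif)[c(1, 3)], c("baseline", "aggressive"))
  expect_error(parameter_factor(cl[, -2], defs$LNM), "missing parameter")
})

test_that("step 2 counts significant parameters with a strict threshold", {
  padj <- rbind(g1 = c(0.01, 0.02, 0.5, 0.9),
                g2 = c(0.01, 0.5, 0.6, 0.9),
                g3 = c(NA, NA, NA, NA),
                g4 = c(0.05, 0.04, 0.3, 0.04))
  colnames(padj) <- c("LNM", "ETE", "size_1cm", "histotype")
  assoc <- structure(list(padj = padj, log2fc = sign(padj),
                          t = padj, covariates = c("gender", "race")),
                     class = "assoc_matrix")
  ## g1 two hits kept, g2 one hit dropped, g3 all-NA dropped,
  ## g4: 0.05 is not < 0.05, still two hits from the other columns
  expect_identical(step2_min_parameter_hits(assoc), c("g1", "g4"))
  expect_identical(step2_min_parameter_hits(assoc, k_min = 1),
                   c("g1", "g2", "g4"))
  expect_error(step2_min_parameter_hits(assoc, params = c("LNM", "bogus")),
               "missing parameter")
})

test_that("step 3 requires unanimous sign agreement with the cancer effect", {
  padj <- rbind(g_up = c(0.01, 0.01, 0.5, 0.5),
                g_mix = c(0.01, 0.01, 0.5, 0.5),
                g_down = c(0.01, 0.01, 0.5, 0.5),
                g_none = c(0.5, 0.6, 0.5, 0.5))
  lfc <- rbind(g_up = c(1, 2, -1, -1),      # non-significant signs ignored
               g_mix = c(1, -2, 1, 1),       # one significant discordance
               g_down = c(-1, -2, 1, 1),
               g_none = c(1, 1, 1, 1))
  colnames(padj) <- colnames(lfc) <- c("LNM", "ETE", "size_1cm", "histotype")
  assoc <- structure(list(padj = padj, log2fc = lfc,
                          t = sign(lfc) * abs(log2(padj)),
                          covariates = c("gender", "race")),
                     class = "assoc_matrix")
  de <- data.frame(gene = rownames(padj), base_mean = 10,
                   log2fc = c(2, 2, -2, 2), lrt_stat = 1,
                   pvalue = 0.001, padj = 0.001, flag = "ok")
  out <- step3_directional_concordance(assoc, de)
  expect_identical(as.character(out), c("g_up", "g_down"))
  ## vacuous concordance (no significant association) is disallowed
  expect_false("g_none" %in% out)
  expect_s3_class(attr(out, "clustering"), "hclust")
})

test_that("step 4 applies the aging-dependence rule and is order-invariant", {
  gr <- rbind(gene_a = c(0.01, 0.5), gene_b = c(0.01, 0.5),
              gene_c = c(0.20, 0.5))
  agr <- rbind(gene_a = c(0.20, 0.5), gene_b = c(0.01, 0.5),
               gene_c = c(0.20, 0.5))
  colnames(gr) <- colnames(agr) <- c("LNM", "ETE")
  out <- step4_aging_dependence(gr, agr)
  ## significant then lost -> retained; age-robust -> dropped;
  ## never significant -> dropped
  expect_identical(as.character(out), "gene_a")
  q <- attr(out, "qualifying")
  expect_true(q["gene_a", "LNM"])
  expect_false(any(q[c("gene_b", "gene_c"), ]))
  ## permuting gene order permutes nothing but the order
  perm <- c(3, 1, 2)
  out_p <- step4_aging_dependence(gr[perm, ], agr[perm, ])
  expect_setequal(as.character(out_p), as.character(out))
  expect_error(step4_aging_dependence(gr, agr[c(2, 1, 3), ]), "misaligned")
})

test_that("step 4 'weaker' mode also accepts attenuated associations", {
  gr <- rbind(g = c(0.001))
  agr <- rbind(g = c(0.01))  # still significant but weaker
  colnames(gr) <- colnames(agr) <- "LNM"
  expect_length(step4_aging_dependence(gr, agr, mode = "nonsig"), 0)
  expect_identical(as.character(step4_aging_dependence(gr, agr,
                                                       mode = "weaker")),
                   "g")
})

test_that("internal validation flags associated genes and skips dead strata", {
  set.seed(51)
  n <- 120
  clin <- data.frame(sample = sprintf("t%03d", 1:n),
                     gender = factor(sample(c("f", "m"), n, TRUE)),
                     race = factor(sample(c("w", "b"), n, TRUE)))
  latent <- rnorm(n)
  clin$LNM <- factor(ifelse(stats::rbinom(n, 1, stats::plogis(1.5 * latent)),
                            "N1", "N0"), levels = c("N0", "N1"))
  clin$ETE <- factor("absent", levels = c("absent", "present", "gross"))
  clin$histotype <- factor(sample(c("FPTC", "CPTC"), n, TRUE),
                           levels = c("FPTC", "CPTC", "TPTC"))
  clin$tumor_size_cm <- runif(n, 0.4, 3)
  clin$differentiation_score <- rnorm(n)
  clin$BRAF <- factor(sample(c("WT", "MUT"), n, TRUE),
                      levels = c("WT", "MUT"))
  clin$TERT <- factor(sample(c("WT", "MUT"), n, TRUE),
                      levels = c("WT", "MUT"))
  expr <- rbind(linked = 8 + latent + rnorm(n, 0, 0.3),
                noise = rnorm(n, 8, 1))
  colnames(expr) <- clin$sample
  tt <- rexp(n, 0.05 * ifelse(latent > 0, 3, 1))
  surv <- rbind(
    data.frame(sample = clin$sample, endpoint = "DFS", time = tt,
               event = 1L),
    data.frame(sample = clin$sample, endpoint = "OS", time = tt,
               event = 0L))  # zero events: must be skipped with a warning
  expect_warning(
    val <- internal_validation(expr, clin, surv, c("linked", "noise")),
    "OS")
  expect_true("linked" %in% val$genes)
  expect_false("noise" %in% val$genes)
  expect_true(all(is.na(val$padj[, "OS"])))
  ## the latent-linked gene shows both the clinical and the survival signal
  expect_lt(val$padj["linked", "LNM"], 0.05)
  expect_lt(val$padj["linked", "DFS"], 0.05)
  expect_error(internal_validation(expr, clin[0, ], surv, "linked"),
               "aging tumors")
})

test_that("pipeline recovers planted aging-dependent markers on one seed", {
  sim <- generate_cohort(cohort_config(seed = 101))
  pip <- run_signature_pipeline(sim$cohort, mode = "aging")
  cls <- sim$truth$gene_class
  planted <- names(cls)[cls == "aging_dependent_aggressive"]
  confound <- names(cls)[cls == "age_independent_aggressive"]
  expect_gte(mean(planted %in% pip$panel), 0.7)
  expect_lte(mean(cls[pip$panel] %in%
                    c("age_independent_aggressive", "null")), 0.2)
  expect_gte(mean(!confound %in% pip$panel), 0.8)
})

test_that("pipeline output is a monotone filtration with valid provenance", {
  sim <- generate_cohort(small_config(seed = 102))
  pip <- run_signature_pipeline(sim$cohort, mode = "aging")
  ct <- pip$counts
  expect_true(all(diff(ct) <= 0))
  pr <- pip$provenance
  ## each step's survivors are a subset of the previous step's
  expect_true(all(pr$step2 <= pr$step1))
  expect_true(all(pr$step3 <= pr$step2))
  expect_true(all(pr$step4 <= pr$step3))
  expect_true(all(pr$validated <= pr$step4))
  expect_setequal(pip$panel, pr$gene[pr$validated])
})

test_that("pipeline stays near-empty on cohorts without planted signal", {
  sizes <- integer(3)
  for (s in 1:3) {
    cfg <- small_config(seed = 200 + s,
                        class_fractions = c(shared_cancer = 0))
    sim <- generate_cohort(cfg)
    pip <- run_signature_pipeline(sim$cohort, mode = "aging")
    sizes[s] <- length(pip$panel)
  }
  expect_lte(mean(sizes), 2)
})

test_that("pipeline validates cohort composition", {
  sim <- generate_cohort(small_config(seed = 103))
  keep <- sim$cohort$clinical$age_group == "young"
  broken <- list(counts = sim$cohort$counts[, keep],
                 cnv = sim$cohort$cnv[, keep],
                 clinical = sim$cohort$clinical[keep, ],
                 survival = sim$cohort$survival)
  expect_error(run_signature_pipeline(broken, mode = "aging"),
               "age groups")
})

test_that("young mode selects the symmetric young-dependent panel", {
  sim <- generate_cohort(cohort_config(seed = 104))
  pip <- run_signature_pipeline(sim$cohort, mode = "young")
  cls <- sim$truth$gene_class
  ## the young panel must not contain aging-specific material
  expect_false(any(cls[pip$panel] %in%
                     c("aging_cancer_specific",
                       "aging_dependent_aggressive")))
})
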