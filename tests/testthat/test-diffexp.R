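test_that("bh_adjust matches the textbook step-up rule and p.adjust", {
  p <- c(0.01, 0.04, 0.03, 0.005)
  expect_equal(bh_adjust(p), c(0.02, 0.04, 0.04, 0.02))
  expect_equal(bh_adjust(p), oracle_bh(p))
  set.seed(1)
  q <- runif(200)
  expect_equal(bh_adjust(q), oracle_bh(q))
  expect_equal(bh_adjust(q), stats::p.adjust(q, "BH"))
})

test_that("bh_adjust passes NAs through and validates its input", {
  p <- c(0.01, NA, 0.04, 0.03, NA, 0.005)
  out <- bh_adjust(p)
  expect_identical(is.na(out), is.na(p))
  expect_equal(out[!is.na(out)], c(0.02, 0.04, 0.04, 0.02))
  expect_error(bh_adjust(c(0.5, 1.2)), "0")
  expect_error(bh_adjust(c(-0.1, 0.5)), "0")
})

test_that("median-of-ratios size factors recover pure library-size scaling", {
  set.seed(21)
  truth <- exp(rnorm(12, 0, 0.3))
  truth <- truth / exp(mean(log(truth)))
  mu <- 2^rnorm(400, 8, 1.5)
  counts <- matrix(rnbinom(400 * 12, mu = mu %o% truth, size = 20), 400, 12,
                   dimnames = list(NULL, sprintf("s%02d", 1:12)))
  sf <- estimate_size_factors(counts)
  expect_equal(exp(mean(log(sf))), 1, tolerance = 1e-12)
  expect_equal(unname(sf), truth, tolerance = 0.05)
  expect_named(sf, colnames(counts))
})

test_that("size factors resist one-sided differential expression", {
  ## 20% of genes 4x up in half the samples must not inflate those samples'
  ## factors (the failure mode of total-count normalization)
  set.seed(22)
  mu <- 2^rnorm(500, 8, 1.5)
  m <- mu %o% rep(1, 20)
  m[1:100, 11:20] <- m[1:100, 11:20] * 4
  counts <- matrix(rnbinom(500 * 20, mu = m, size = 20), 500, 20)
  sf <- estimate_size_factors(counts)
  sf_shift <- abs(mean(log(sf[11:20])) - mean(log(sf[1:10])))
  tot <- colSums(counts)
  tot_shift <- mean(log(tot[11:20])) - mean(log(tot[1:10]))
  ## the median's residual contamination is bounded and well under the
  ## planted-effect scale, while total counts absorb a large shift
  expect_lt(sf_shift, 0.2)
  expect_gt(tot_shift, 0.3)
  expect_lt(sf_shift, tot_shift / 2)
})

test_that("size factors fall back to totals and validate counts", {
  counts <- rbind(c(0, 4, 8), c(6, 0, 12), c(3, 2, 0))
  expect_silent(sf <- estimate_size_factors(counts))
  expect_equal(exp(mean(log(sf))), 1, tolerance = 1e-12)
  expect_error(estimate_size_factors(matrix(-1, 2, 2)), "non-negative")
  expect_error(estimate_size_factors(matrix(0, 2, 2)), "all-zero")
})

test_that("NB GLM matches the glm oracle with fixed dispersion", {
  set.seed(31)
  n <- 80
  grp <- factor(rep(c("a", "b"), each = n / 2))
  sex <- factor(sample(c("f", "m"), n, TRUE))
  off <- log(runif(n, 0.8, 1.25))
  mu <- exp(5 + 0.9 * (grp == "b") + 0.3 * (sex == "m") + off)
  y <- rnbinom(n, mu = mu, size = 10)
  counts <- matrix(y, 1, n, dimnames = list("g1", sprintf("s%02d", 1:n)))
  cd <- data.frame(grp = grp, sex = sex)
  de <- nb_glm_lrt(counts, cd, contrast = "grp", covariates = "sex",
                   ref = "a", dispersion = 0.1, size_factors = exp(off))
  fit_full <- stats::glm(y ~ grp + sex + offset(off - mean(off)),
                         family = MASS::negative.binomial(10))
  fit_red <- stats::glm(y ~ sex + offset(off - mean(off)),
                        family = MASS::negative.binomial(10))
  expect_equal(de$log2fc, unname(coef(fit_full)["grpb"]) / log(2),
               tolerance = 1e-5)
  expect_equal(de$lrt_stat,
               2 * (as.numeric(logLik(fit_full)) -
                      as.numeric(logLik(fit_red))),
               tolerance = 1e-5)
  expect_equal(de$pvalue, pchisq(de$lrt_stat, 1, lower.tail = FALSE))
  expect_identical(de$flag, "ok")
})

test_that("dispersion estimation is group-aware and near the truth", {
  set.seed(32)
  n <- 120
  grp <- factor(rep(c("a", "b"), each = n / 2))
  mu <- 2^rnorm(300, 8, 1)
  m <- mu %o% rep(1, n)
  m[1:60, grp == "b"] <- m[1:60, grp == "b"] * 6  # strong group difference
  counts <- matrix(rnbinom(300 * n, mu = m, size = 1 / 0.15), 300, n)
  d <- estimate_dispersions(counts, grp)
  expect_equal(median(d), 0.15, tolerance = 0.05)
  ## planted group differences must not inflate the estimates
  expect_lt(median(d[1:60]) / median(d[61:300]), 1.5)
  d1 <- estimate_dispersions(counts)  # group-blind: inflated for DE genes
  expect_gt(median(d1[1:60]) / median(d1[61:300]), 3)
})

test_that("nb_glm_lrt flags low-count genes and validates the design", {
  set.seed(33)
  counts <- matrix(rnbinom(40, mu = 50, size = 10), 2, 20,
                   dimnames = list(c("g1", "g2"), sprintf("s%02d", 1:20)))
  counts[2, ] <- c(rep(0L, 19), 3L)
  cd <- data.frame(grp = factor(rep(c("a", "b"), each = 10)))
  de <- nb_glm_lrt(counts, cd, "grp", min_count = 10)
  expect_identical(de$flag, c("ok", "low_count"))
  expect_true(is.na(de$pvalue[2]))
  ## padj computed over tested genes only
  expect_equal(de$padj[1], de$pvalue[1])
  expect_error(nb_glm_lrt(counts, data.frame(grp = factor(rep("a", 20))),
                          "grp"),
               "two levels")
  expect_error(nb_glm_lrt(counts[, 1:3],
                          data.frame(grp = factor(c("a", "a", "b"))), "grp"),
               "at least 2")
  expect_error(nb_glm_lrt(counts, cbind(cd, dup = cd$grp), "grp",
                          covariates = "dup"),
               "rank deficient")
  expect_error(nb_glm_lrt(counts, cd[1:5, , drop = FALSE], "grp"), "align")
})

test_that("LRT p-values are calibrated on null data", {
  set.seed(34)
  ng <- 400; n <- 60
  mu <- 2^rnorm(ng, 7, 1.5)
  ls <- runif(n, 0.7, 1.4)
  counts <- matrix(rnbinom(ng * n, mu = mu %o% ls, size = 10), ng, n)
  cd <- data.frame(grp = factor(rep(c("a", "b"), each = n / 2)))
  de <- nb_glm_lrt(counts, cd, "grp")
  t1 <- mean(de$pvalue < 0.05, na.rm = TRUE)
  expect_gt(t1, 0.01)
  expect_lt(t1, 0.12)
})

test_that("select_degs applies strict padj and inclusive lfc thresholds", {
  de <- data.frame(gene = c("a", "b", "c", "d", "e"),
                   base_mean = 100, log2fc = c(1.5, 1, -2, 0.5, 3),
                   lrt_stat = 1,
                   pvalue = c(0.001, 0.002, 0.003, 0.001, 0.2),
                   padj = c(0.01, 0.05, 0.049, 0.01, 0.5),
                   flag = "ok")
  sel <- select_degs(de, alpha = 0.05, lfc_min = 1)
  ## b: padj exactly at alpha -> excluded; c: |lfc| at threshold kept via
  ## inclusive rule; d: small fold change excluded; e: not significant
  expect_identical(sel$gene, c("a", "c"))
  expect_identical(sel$direction, c("up", "down"))
  sel2 <- select_degs(transform(de, padj = c(0.01, 0.0499, 0.049, 0.01, 0.5)),
                      lfc_min = 1)
  expect_true("b" %in% sel2$gene)
})

test_that("cohort-specific sets exclude genes shared with other contrasts", {
  mk <- function(padj, lfc) data.frame(
    gene = c("g1", "g2", "g3", "g4"), base_mean = 10, log2fc = lfc,
    lrt_stat = 1, pvalue = padj, padj = padj, flag = "ok")
  own <- mk(c(0.01, 0.01, 0.01, 0.4), c(2, 2, 2, 2))
  other <- mk(c(0.4, 0.01, 0.4, 0.4), c(0, 2, 0, 0))   # g2 shared
  norm <- mk(c(0.4, 0.4, 0.01, 0.4), c(0, 0, 2, 0))    # g3 age-driven
  out <- cohort_specific_sets(own, other, norm)
  expect_identical(out, "g1")
  expect_error(cohort_specific_sets(own[1:3, ], other, norm), "universe")
})

test_that("normalized_log2 computes log2 of normalized counts plus one", {
  counts <- matrix(c(0, 3, 7, 15), 2, 2)
  out <- normalized_log2(counts, size_factors = c(1, 2))
  expect_equal(out, log2(matrix(c(0, 3, 3.5, 7.5), 2, 2) + 1))
})
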