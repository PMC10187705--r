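test_that("GMT round trip preserves the collection", {
  sets <- list(alpha = c("g1", "g2", "g3"), beta = c("g2", "g4"))
  f <- tempfile(fileext = ".gmt")
  write_gmt(sets, f, description = c("first", "second"))
  back <- read_gmt(f)
  expect_identical(back, sets)
  writeLines(c("dup\tna\tg1", "dup\tna\tg2"), f)
  expect_error(read_gmt(f), "duplicate")
  writeLines("empty\tna", f)
  expect_error(read_gmt(f), "empty gene set")
  unlink(f)
})

test_that("ORA matches exact enumeration on a small universe", {
  universe <- paste0("g", 1:20)
  deg <- paste0("g", 1:6)
  sets <- list(hit = paste0("g", c(1:4, 15)),     # overlap 4 of 5
               cold = paste0("g", 10:14),          # overlap 0
               outside = paste0("x", 1:3))         # no universe overlap
  out <- ora_enrichment(deg, sets[1:2], universe)
  ## exact hypergeometric tail by direct combinatorics
  exact_p <- function(k, m) {
    sum(sapply(k:min(m, 6), function(i)
      choose(m, i) * choose(20 - m, 6 - i))) / choose(20, 6)
  }
  expect_equal(out$p.value[out$set == "hit"], exact_p(4, 5),
               tolerance = 1e-12)
  expect_equal(out$p.value[out$set == "cold"], exact_p(0, 5),
               tolerance = 1e-12)
  expect_equal(out$fold[out$set == "hit"], 4 / (6 * 5 / 20))
  expect_equal(out$padj, bh_adjust(out$p.value))
  ## sets with no universe overlap are skipped
  out2 <- ora_enrichment(deg, sets, universe)
  expect_false("outside" %in% out2$set)
  expect_error(ora_enrichment(character(), sets, universe), "empty query")
  expect_error(ora_enrichment(c(deg, "zz"), sets, universe), "subset")
})

test_that("agglomerate z-scores average member genes on the z scale", {
  set.seed(91)
  expr <- matrix(rnorm(40, 10, 3), 4, 10,
                 dimnames = list(paste0("g", 1:4), paste0("s", 1:10)))
  sc <- agglomerate_zscore(expr, c("g1", "g3", "missing"))
  z1 <- (expr["g1", ] - mean(expr["g1", ])) / sd(expr["g1", ])
  z3 <- (expr["g3", ] - mean(expr["g3", ])) / sd(expr["g3", ])
  expect_equal(sc, (z1 + z3) / 2)
  expect_equal(mean(sc), 0, tolerance = 1e-12)
  expect_error(agglomerate_zscore(expr, "absent"), "overlap")
  expect_warning(
    m <- pathway_score_matrix(expr, list(a = c("g1", "g3"), b = "absent")),
    "no overlap")
  expect_identical(rownames(m), "a")
})

test_that("condition-associated pathways are selected with directions", {
  set.seed(92)
  n <- 120
  cond <- factor(rep(c("ctl", "case"), each = n / 2),
                 levels = c("ctl", "case"))
  scores <- rbind(up = rnorm(n, ifelse(cond == "case", 1, 0), 0.7),
                  down = rnorm(n, ifelse(cond == "case", -1, 0), 0.7),
                  flat = rnorm(n))
  colnames(scores) <- paste0("s", 1:n)
  out <- select_condition_pathways(scores, cond)
  expect_true(out$selected[out$pathway == "up"])
  expect_true(out$selected[out$pathway == "down"])
  expect_false(out$selected[out$pathway == "flat"])
  expect_equal(out$direction[out$pathway == "up"], 1)
  expect_equal(out$direction[out$pathway == "down"], -1)
  expect_error(select_condition_pathways(scores, rep("one", n)),
               "two levels")
})

test_that("aging-specificity filter removes shared same-direction pathways", {
  set.seed(93)
  n <- 100
  age <- rep(c("aging", "young"), each = n / 2)
  mk <- function(pw, dir, sel) data.frame(pathway = pw, beta = dir,
                                          direction = dir, p.value = 0.001,
                                          padj = if (sel) 0.001 else 0.5,
                                          selected = sel)
  sa <- rbind(mk("shared_same", 1, TRUE), mk("own_only", 1, TRUE),
              mk("shared_opposite", 1, TRUE), mk("shared_shifted", 1, TRUE))
  sy <- rbind(mk("shared_same", 1, TRUE), mk("shared_opposite", -1, TRUE),
              mk("shared_shifted", 1, TRUE))
  scores <- rbind(shared_same = rnorm(n),
                  own_only = rnorm(n),
                  shared_opposite = rnorm(n),
                  shared_shifted = rnorm(n) + 2 * (age == "aging"))
  out <- aging_specificity_filter(sa, sy, scores, age)
  ## shared with same direction and indistinguishable scores -> removed;
  ## unique, opposite-direction, or cohort-shifted pathways survive
  expect_setequal(out$pathway,
                  c("own_only", "shared_opposite", "shared_shifted"))
})

test_that("ssGSEA matches the literal running-sum oracle", {
  set.seed(94)
  expr <- matrix(rnorm(15 * 4, 8, 2), 15, 4,
                 dimnames = list(paste0("g", 1:15), paste0("s", 1:4)))
  set <- paste0("g", c(2, 5, 9, 11, 14))
  es <- ssgsea_nes(expr, list(path = set), weight = 0.25, rescale = FALSE)
  inset <- rownames(expr) %in% set
  for (j in 1:4)
    expect_equal(es["path", j], oracle_ssgsea(expr[, j], inset, 0.25),
                 label = paste("sample", j))
})

test_that("weight zero makes ssGSEA invariant to monotone transforms", {
  set.seed(95)
  expr <- matrix(rexp(20 * 3) + 0.1, 20, 3,
                 dimnames = list(paste0("g", 1:20), paste0("s", 1:3)))
  set <- paste0("g", c(1, 4, 7, 12))
  e1 <- ssgsea_nes(expr, list(p = set), weight = 0, rescale = FALSE)
  e2 <- ssgsea_nes(log(expr), list(p = set), weight = 0, rescale = FALSE)
  e3 <- ssgsea_nes(expr^3, list(p = set), weight = 0, rescale = FALSE)
  expect_equal(e1, e2)
  expect_equal(e1, e3)
})

test_that("ssGSEA rescaling and validation behave as documented", {
  set.seed(96)
  expr <- matrix(rnorm(30 * 6), 30, 6,
                 dimnames = list(paste0("g", 1:30), paste0("s", 1:6)))
  sets <- list(a = paste0("g", 1:5), b = paste0("g", 20:26))
  nes <- ssgsea_nes(expr, sets)
  expect_true(all(nes >= 0 & nes <= 1))
  expect_equal(unname(apply(nes, 1, min)), c(0, 0))
  expect_equal(unname(apply(nes, 1, max)), c(1, 1))
  expect_error(ssgsea_nes(expr, list(tiny = "g1")), "fewer than 2")
  expect_error(ssgsea_nes(expr, list(all = rownames(expr))),
               "whole matrix")
})

test_that("compare_nes flags small groups and detects planted shifts", {
  set.seed(97)
  nes <- rbind(shift = c(rnorm(10, 0.2, 0.05), rnorm(10, 0.8, 0.05)),
               flat = runif(20))
  colnames(nes) <- paste0("s", 1:20)
  g <- rep(c("a", "b"), each = 10)
  out <- compare_nes(nes, g)
  expect_lt(out$padj[out$pathway == "shift"], 0.05)
  expect_gt(out$padj[out$pathway == "flat"], 0.05)
  expect_identical(unique(out$flag), "ok")
  out2 <- compare_nes(nes[, 1:12], rep(c("a", "b"), c(10, 2)))
  expect_identical(unique(out2$flag), "small_group")
  expect_error(compare_nes(nes, rep("a", 20)), "two groups")
})

test_that("planted aging pathway signal survives the full scoring chain", {
  sim <- generate_cohort(cohort_config(seed = 108))
  cl <- sim$cohort$clinical
  cls <- sim$truth$gene_class
  expr <- normalized_log2(sim$cohort$counts)
  tum <- cl$tissue == "tumor"
  collection <- list(
    aging_program = names(cls)[cls == "aging_cancer_specific"][1:20],
    background = names(cls)[cls == "null"][1:20])
  nes <- ssgsea_nes(expr[, tum], collection)
  cmp <- compare_nes(nes, cl$age_group[tum])
  expect_lt(cmp$padj[cmp$pathway == "aging_program"], 0.05)
  ## on the raw enrichment-score scale the planted program shifts far more
  ## than a null set of the same size (ranks are relative, so null sets are
  ## displaced a little in the opposite direction; the per-pathway [0,1]
  ## rescaling would hide that scale difference)
  es <- ssgsea_nes(expr[, tum], collection, rescale = FALSE)
  shift <- function(pw) abs(
    median(es[pw, cl$age_group[tum] == "aging"]) -
      median(es[pw, cl$age_group[tum] == "young"]))
  expect_gt(shift("aging_program"), 3 * shift("background"))
})
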