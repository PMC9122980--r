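test_that("auroc handles perfect, inverted and mixed rankings", {
  expect_equal(auroc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(auroc(c(0.9, 0.8, 0.2, 0.1), c(0, 0, 1, 1)), 0)
  # 4 positive-negative pairs, 3 concordant
  expect_equal(auroc(c(0.9, 0.6, 0.4, 0.2), c(1, 0, 1, 0)), 0.75)
  expect_error(auroc(c(1, 2), c(1, 1)), "single class")
})

test_that("auroc equals brute-force pair enumeration exactly", {
  set.seed(101)
  for (i in 1:1000) {
    n <- sample(4:50, 1)
    # discrete scores exercise the tie handling
    scores <- sample(0:9, n, replace = TRUE) / 10
    labels <- c(0, 1, rbinom(n - 2, 1, 0.5))  # both classes guaranteed
    expect_identical(auroc(scores, labels), auroc_bruteforce(scores, labels))
  }
})

test_that("auroc agrees with an established ROC implementation", {
  set.seed(7)
  scores <- rnorm(60)
  labels <- rbinom(60, 1, 0.4)
  expect_equal(auroc(scores, labels),
               as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                              direction = "<"))))
})

test_that("PEP is the best Spearman correlation to another reference gene", {
  set.seed(55)
  r1 <- c(0, 1, 2, 3, 4, 5)
  r2 <- c(5, 1, 4, 0, 3, 2)
  vals <- cbind(R1 = r1, R2 = r2,
                twin = 2 * r1,             # monotone in R1 -> PEP 1
                anti = 5 - r1,             # inverse of R1
                mixed = c(1, 0, 3, 2, 5, 4))
  expr <- toy_expr(vals)
  pep <- pep_scores(expr, reference = c("R1", "R2"))
  peps <- setNames(pep$pep, pep$gene)
  expect_equal(peps[["twin"]], 1)
  expect_equal(peps[["anti"]], max(spearman_manual(vals[, "anti"], r2), -1))
  # rank-based oracle: max of the two hand-computed coefficients
  expect_equal(peps[["mixed"]],
               max(spearman_manual(vals[, "mixed"], r1),
                   spearman_manual(vals[, "mixed"], r2)))
  # reference gene scored against the *other* references only
  expect_equal(peps[["R1"]], spearman_manual(r1, r2))
})

test_that("PEP of an exact negation of the only reference is -1", {
  x <- c(1, 0, 1, 1, 0, 0)
  expr <- toy_expr(cbind(R1 = x, neg = 1 - x))
  pep <- pep_scores(expr, reference = "R1")
  expect_equal(pep$pep[pep$gene == "neg"], -1)
  # a constant gene has no defined correlation
  expr2 <- toy_expr(cbind(R1 = x, flat = rep(2, 6)))
  expect_true(is.na(pep_scores(expr2, reference = "R1")$pep[2]))
})

test_that("PEP is invariant under strictly monotone transforms", {
  set.seed(77)
  v <- rexp(30)
  r <- rexp(30)
  expr_a <- toy_expr(cbind(R1 = r, g = v))
  expr_b <- toy_expr(cbind(R1 = r^2, g = log1p(3 * v)))
  pa <- pep_scores(expr_a, reference = "R1")
  pb <- pep_scores(expr_b, reference = "R1")
  expect_equal(pa$pep[pa$gene == "g"], pb$pep[pb$gene == "g"])
})

test_that("pep_threshold finds the persistent crossing point", {
  mk_report <- function(aurocs, genes) {
    validation_report(data.frame(gene = genes, auroc = aurocs), character(0))
  }
  genes <- paste0("G", 1:10)
  pep <- data.frame(gene = genes, pep = seq(0.05, 0.5, length.out = 10))

  # all perfect: threshold is the smallest PEP observed
  thr <- pep_threshold(pep, mk_report(rep(1, 10), genes), bins = 5)
  expect_equal(thr, 0.05)

  # never above 0.5: fallback with warning
  expect_warning(
    thr2 <- pep_threshold(pep, mk_report(rep(0.5, 10), genes), bins = 5),
    "never")
  expect_equal(thr2, 0.13)

  # crossing halfway: low-PEP bins at 0.4, high-PEP bins at 0.9
  thr3 <- pep_threshold(pep, mk_report(c(rep(0.4, 4), rep(0.9, 6)), genes),
                        bins = 5)
  expect_equal(thr3, pep$pep[5])

  expect_error(pep_threshold(pep[1:2, ], mk_report(rep(1, 2), genes[1:2])),
               "fewer than 3")
  expect_warning(
    thr4 <- pep_threshold(pep[1:2, ], mk_report(rep(1, 2), genes[1:2]),
                          allow_default_on_few = TRUE),
    "fewer than 3")
  expect_equal(thr4, 0.13)
})

test_that("pseudobulk correlation matches the direct Pearson formula", {
  expr <- toy_expr(rbind(c(1, 0, 4, 2), c(3, 1, 0, 2)),
                   genes = c("a", "b", "c", "d"))
  pooled <- colSums(expr$values)
  expect_equal(pseudobulk_correlation(expr, pooled), 1)

  # bulk whose log profile is c - log(pooled) on 3 genes: perfect inverse
  sub <- pooled[c("a", "b", "c")]
  bulk_anti <- 2^(10 - log2(sub + 1)) - 1
  expect_equal(pseudobulk_correlation(expr, bulk_anti), -1)

  # direct-formula oracle on an arbitrary bulk vector
  bulk2 <- c(a = 2, b = 9, c = 1, d = 5)
  lx <- log2(pooled + 1); ly <- log2(bulk2 + 1)
  manual <- sum((lx - mean(lx)) * (ly - mean(ly))) /
    sqrt(sum((lx - mean(lx))^2) * sum((ly - mean(ly))^2))
  expect_equal(pseudobulk_correlation(expr, bulk2), manual)

  expect_error(pseudobulk_correlation(expr, c(a = 1, b = 2)), "3 shared")
})

test_that("leave-one-out validation honors exclusions and degenerate truths", {
  scene <- small_scene()
  res <- scene$res
  rep0 <- loocv_reference_genes(res$expr, res$map)
  expect_true(all(rep0$per_gene$auroc >= 0 & rep0$per_gene$auroc <= 1,
                  na.rm = TRUE))
  expect_equal(rep0$average_auroc, mean(rep0$per_gene$auroc, na.rm = TRUE))

  excl <- res$map$ref_genes[1:2]
  rep1 <- loocv_reference_genes(res$expr, res$map, exclude = excl,
                                source_genes = res$source_genes)
  kept <- !(rep1$per_gene$gene %in% excl) & !is.na(rep1$per_gene$auroc)
  expect_equal(rep1$average_auroc, mean(rep1$per_gene$auroc[kept]))
  # per-gene values identical whatever the exclusion list
  expect_equal(rep1$per_gene$auroc, rep0$per_gene$auroc, tolerance = 1e-8)
})

test_that("sequential elimination starts at the LOOCV baseline", {
  scene <- small_scene()
  res <- scene$res
  base <- loocv_reference_genes(res$expr, res$map,
                                source_genes = res$source_genes)
  traj <- sequential_elimination(res$expr, res$map, order = "desc",
                                 steps = 1, source_genes = res$source_genes)
  expect_equal(traj$mean_auroc[1], base$average_auroc, tolerance = 1e-8)
  expect_equal(attr(traj, "per_gene")[, 1],
               setNames(base$per_gene$auroc, base$per_gene$gene),
               tolerance = 1e-8)
  expect_error(sequential_elimination(res$expr,
                 subset_spatial_map(res$map, genes = 1:2)), "at least 3")
})
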