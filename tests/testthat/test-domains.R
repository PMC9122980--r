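mk_atlas <- function(values) reconstructed_atlas(as.matrix(values))

test_that("domain gene selection applies both strict predicates", {
  vals <- cbind(lowvar = rnorm(50, sd = 1), mid = rnorm(50, sd = 2),
                high = rnorm(50, sd = sqrt(10)))
  vals <- abs(vals)
  # force the sample variances to known values
  vals <- sweep(vals, 2, apply(vals, 2, sd), "/")
  vals <- sweep(vals, 2, sqrt(c(1, 4, 10)), "*")
  atlas <- mk_atlas(vals)
  pep <- data.frame(gene = colnames(vals), pep = c(0.9, 0.05, 0.9))
  expect_equal(select_domain_genes(atlas, pep), "high")

  # constant gene never selected; boundary PEP excluded (strict inequality)
  atlas2 <- mk_atlas(cbind(const = rep(5, 10), big = c(rep(0, 5), rep(10, 5))))
  pep2 <- data.frame(gene = c("const", "big"), pep = c(0.9, 0.13))
  expect_error(select_domain_genes(atlas2, pep2), "no genes pass")
  pep3 <- data.frame(gene = c("const", "big"), pep = c(0.9, 0.14))
  expect_equal(select_domain_genes(atlas2, pep3), "big")
})

test_that("standardize_log composes log2(x+1) with population scaling", {
  atlas <- mk_atlas(cbind(g = c(0, 1, 3)))
  out <- standardize_log(atlas)
  expect_equal(unname(out[, 1]), c(-1.2247449, 0, 1.2247449),
               tolerance = 1e-6)
  # constant gene: zeros
  atlas2 <- mk_atlas(cbind(g = rep(4, 5)))
  expect_equal(unname(standardize_log(atlas2)[, 1]), rep(0, 5))
  # mean 0 / population variance 1 for non-constant genes
  set.seed(3)
  atlas3 <- mk_atlas(matrix(rexp(60), 20, 3))
  s <- standardize_log(atlas3)
  expect_equal(unname(colMeans(s)), rep(0, 3), tolerance = 1e-12)
  expect_equal(unname(colMeans(s^2)), rep(1, 3), tolerance = 1e-12)
})

test_that("hierarchical domain clustering recovers separated blobs", {
  set.seed(12)
  blob1 <- matrix(rnorm(40 * 3, mean = 0), 40, 3)
  blob2 <- matrix(rnorm(30 * 3, mean = 20), 30, 3)
  std <- rbind(blob1, blob2)
  rownames(std) <- paste0("c", 1:70)
  dom <- cluster_domains(std, k = 2)
  expect_equal(unname(dom$labels[1:40]), rep(1, 40))  # larger blob -> label 1
  expect_equal(unname(dom$labels[41:70]), rep(2, 30))

  # degenerate cuts
  expect_equal(unique(unname(cluster_domains(std, k = 1)$labels)), 1)
  expect_equal(sort(unname(cluster_domains(std[1:5, ], k = 5)$labels)), 1:5)
  expect_error(cluster_domains(std[1:4, ], k = 9), "exceeds")
})

test_that("domain partition is invariant to cell order", {
  set.seed(19)
  std <- matrix(rnorm(60 * 4), 60, 4)
  rownames(std) <- paste0("c", 1:60)
  perm <- sample(60)
  d1 <- cluster_domains(std, k = 5)
  d2 <- cluster_domains(std[perm, ], k = 5)
  # same partition up to relabeling: compare co-membership on pairs
  same1 <- outer(d1$labels, d1$labels, "==")
  l2 <- d2$labels[rownames(std)]
  same2 <- outer(l2, l2, "==")
  expect_equal(same1, same2)
})

test_that("domain means average the untransformed atlas", {
  atlas <- mk_atlas(cbind(g = c(1, 3, 5), h = rep(2, 3)))
  assign <- structure(list(labels = setNames(c(1L, 1L, 2L), atlas$cell_ids),
                           k = 2L, linkage = "average", genes = "g"),
                      class = "domain_assignment")
  tab <- domain_means(atlas, assign)
  expect_equal(unname(tab$means[, "g"]), c(2, 5))   # {(1,3)}, {(5)}
  expect_equal(unname(tab$means[, "h"]), c(2, 2))   # constant gene
  expect_equal(unname(tab$counts), c(2L, 1L))
  # conservation: count-weighted domain means give the global mean
  expect_equal(sum(tab$means[, "g"] * tab$counts) / sum(tab$counts),
               mean(atlas$values[, "g"]))
})

test_that("homeotic domain expression averages over positive-call cells", {
  map <- toy_map()  # G1 positive in cells a, c
  atlas <- reconstructed_atlas(
    cbind(gX = c(2, 9, 4, 9), gY = c(0, 1, 0, 2)),
    cell_ids = map$cell_ids)
  m <- homeotic_domain_expression(atlas, map, "G1")
  expect_equal(unname(m["gX"]), 3)       # mean(2, 4)
  expect_equal(unname(m["gY"]), 0)       # expressed only outside the domain
  # pair: both genes must be positive (G1 & G3 -> cell a only)
  m2 <- homeotic_domain_expression(atlas, map, c("G1", "G3"))
  expect_equal(unname(m2["gX"]), 2)
  # domain = all cells equals the global mean
  mall <- homeotic_domain_expression(atlas, map, "G2")  # G2: b, c, d
  expect_equal(unname(mall["gX"]), mean(c(9, 4, 9)))
  expect_error(homeotic_domain_expression(atlas, map, "NOPE"),
               "not reference genes")
  # fold change with pseudocount 1: means (3, 1) -> log2(4/2) = 1
  expect_equal(unname(domain_log2fc(c(g = 3), c(g = 1))), 1)
})

test_that("temporal fold-change uses strict thresholds and shared labels", {
  mk_tab <- function(m) structure(list(means = m, counts = c(domain1 = 2L)),
                                  class = "domain_expression_table")
  A <- mk_tab(matrix(c(3, 7, 1), 1, 3,
                     dimnames = list("domain1", c("a", "b", "c"))))
  B <- mk_tab(matrix(c(1, 1, 7), 1, 3,
                     dimnames = list("domain1", c("a", "b", "c"))))
  out <- temporal_fold_change(A, B)
  # a: log2(4/2) = 1 is NOT > 1 (strict); b: log2(8/2) = 2 -> up; c: down
  expect_equal(out$domain1$up, "b")
  expect_equal(out$domain1$down, "c")
  # identical tables give empty lists
  none <- temporal_fold_change(A, A)
  expect_equal(none$domain1$up, character(0))
  expect_equal(none$domain1$down, character(0))
  B2 <- mk_tab(matrix(1, 1, 3, dimnames = list("domainX", c("a", "b", "c"))))
  expect_error(temporal_fold_change(A, B2), "label mismatch")
})

test_that("signature relative expression subtracts background medians", {
  em <- cbind(s1 = c(5, 5, 5, 3, 3, 3, 1), s2 = c(2, 4, 6, 1, 3, 5, 0))
  rownames(em) <- paste0("g", 1:7)
  # list == background -> 0 per sample
  expect_equal(unname(signature_relative_expression(paste0("g", 1:7), em,
                                                    paste0("g", 1:7))),
               c(0, 0))
  # medians 5 vs 3 -> +2 (odd-sized lists)
  out <- signature_relative_expression(paste0("g", 1:3), em,
                                       paste0("g", 4:6))
  expect_equal(unname(out["s1"]), 2)
  # even-sized list: midpoint convention
  out2 <- signature_relative_expression(c("g1", "g2"), em, c("g4", "g7"))
  expect_equal(unname(out2["s2"]), mean(c(2, 4)) - mean(c(1, 0)))
  expect_error(signature_relative_expression("zz", em, "g1"), "intersection")
})

test_that("relative expression centers each gene across groups", {
  m <- rbind(a = c(2, 4, 6), b = c(5, 5, 5))
  out <- relative_expression(m)
  expect_equal(unname(out["a", ]), c(-2, 0, 2))
  expect_equal(unname(out["b", ]), c(0, 0, 0))
  expect_true(all(abs(rowMeans(out)) < 1e-12))
  expect_error(relative_expression(cbind(c(1, 2))), "2 groups")
})
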