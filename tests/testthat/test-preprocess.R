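test_that("cells expressing no reference gene are removed", {
  map <- spatial_map(c("c1", "c2", "c3"),
                     rbind(c(0,0,0), c(1,0,0), c(2,0,0)),
                     c("G1", "G2"),
                     rbind(c(1,0), c(0,0), c(0,1)))
  out <- filter_cells_no_reference(map)
  expect_equal(out$map$cell_ids, c("c1", "c3"))
  expect_equal(out$report$items_removed, 1)
  expect_equal(out$report$item_ids, "c2")

  # identity case: nothing to remove
  out2 <- filter_cells_no_reference(out$map)
  expect_equal(out2$report$items_removed, 0)
  expect_equal(out2$map$cell_ids, out$map$cell_ids)
})

test_that("uninformative reference genes are dropped", {
  map <- spatial_map(c("c1", "c2"), rbind(c(0,0,0), c(1,0,0)),
                     c("CONST", "KEEP", "ABSENT"),
                     rbind(c(1, 1, 0), c(1, 0, 1)))
  expr <- toy_expr(rbind(c(1, 2), c(0, 1), c(3, 0)),
                   genes = c("CONST", "KEEP"))
  out <- filter_uninformative_reference_genes(map, expr)
  expect_equal(out$map$ref_genes, "KEEP")
  expect_setequal(out$report$item_ids, c("CONST", "ABSENT"))

  # alternative reading: constantness judged on binarized nuclei
  expr2 <- toy_expr(rbind(c(1, 0), c(2, 1), c(3, 0)),
                    genes = c("CONST", "KEEP"))
  out2 <- filter_uninformative_reference_genes(map, expr2, scope = "nuclei")
  expect_setequal(out2$report$item_ids, c("CONST", "KEEP", "ABSENT")[c(1, 3)])
})

test_that("sparse cells and rare combinations are removed simultaneously", {
  # 6 cells sharing one pattern with >= 3 genes: each has 5 others -> kept
  patt <- matrix(rep(c(1, 1, 1, 0), 6), nrow = 6, byrow = TRUE)
  lone <- c(1, 0, 1, 1)      # unique pattern -> 0 others -> removed
  two  <- c(1, 1, 0, 0)      # only 2 genes -> removed
  m <- rbind(patt, lone, two)
  map <- spatial_map(paste0("c", 1:8), cbind(1:8, 0, 0),
                     paste0("G", 1:4), m)
  out <- filter_sparse_and_rare_combination_cells(map)
  expect_equal(out$map$cell_ids, paste0("c", 1:6))
  expect_setequal(out$report$item_ids, c("c7", "c8"))
})

test_that("rare-combination boundary: four other cells keep, three remove", {
  keep5 <- matrix(rep(c(1, 1, 1, 0), 5), nrow = 5, byrow = TRUE)  # 4 others
  drop4 <- matrix(rep(c(0, 1, 1, 1), 4), nrow = 4, byrow = TRUE)  # 3 others
  map <- spatial_map(paste0("c", 1:9), cbind(1:9, 0, 0),
                     paste0("G", 1:4), rbind(keep5, drop4))
  out <- filter_sparse_and_rare_combination_cells(map)
  expect_equal(out$map$cell_ids, paste0("c", 1:5))
  expect_equal(out$report$items_removed, 4)
})

test_that("low-prevalence gene filter honors the threshold and exceptions", {
  n <- 40
  vals <- cbind(rare = c(rep(1, 29), rep(0, n - 29)),
                boundary = c(rep(1, 30), rep(0, n - 30)),
                protected = c(rep(1, 29), rep(0, n - 29)),
                common = rep(1, n))
  expr <- toy_expr(vals)
  out <- filter_low_prevalence_genes(expr, min_cells = 30,
                                     always_keep = "protected")
  expect_equal(out$report$item_ids, "rare")
  expect_setequal(out$expr$genes, c("boundary", "protected", "common"))
})

test_that("nuclei expressing no reference gene are removed", {
  ref_block <- rbind(c(1, 0), c(0, 0), c(0, 2), c(0, 0), c(3, 0))
  expr <- toy_expr(cbind(ref_block, other = c(0, 5, 0, 2, 0)),
                   genes = c("R1", "R2", "other"))
  map <- spatial_map(c("c1", "c2"), rbind(c(0,0,0), c(1,0,0)),
                     c("R1", "R2"), rbind(c(1, 0), c(0, 1)))
  out <- filter_nuclei_no_reference(expr, map)
  expect_equal(out$report$items_removed, 2)
  expect_equal(length(out$expr$barcodes), 3)

  all_zero <- toy_expr(cbind(R1 = c(0, 0), R2 = c(0, 0)))
  expect_error(filter_nuclei_no_reference(all_zero, map), "empty result")
})

test_that("reference-correlated gene selection matches a rank-by-hand oracle", {
  set.seed(42)
  n <- 6
  r1 <- c(0, 1, 2, 3, 4, 5)
  vals <- cbind(R1 = r1,
                same = r1 * 2,            # correlation exactly 1
                close = r1 + abs(rnorm(n, 0, 0.1)),
                anti = rev(r1),
                noise = runif(n),
                flat = rep(1, n))         # undefined correlation
  expr <- toy_expr(vals)
  map <- spatial_map("c1", cbind(0, 0, 0), "R1", cbind(1))

  sel <- select_reference_correlated_genes(expr, map, top_n = 2)
  # oracle: rank by explicit Pearson correlation with R1
  cors <- sapply(colnames(vals)[-6], function(g) cor(vals[, g], r1))
  oracle_top2 <- names(sort(cors, decreasing = TRUE))[1:2]
  expect_setequal(sel, union("R1", oracle_top2)[1:2])

  # self-similarity: a gene identical to the reference is always selected
  expect_true("same" %in% select_reference_correlated_genes(expr, map, top_n = 1) ||
                "R1" %in% select_reference_correlated_genes(expr, map, top_n = 1))

  # saturation: top_n >= n_genes returns all genes with defined correlation
  sel_all <- select_reference_correlated_genes(expr, map, top_n = 100)
  expect_setequal(sel_all, setdiff(colnames(vals), "flat"))

  expect_error(select_reference_correlated_genes(
    subset_expression(expr, genes = c("same", "close")), map), "absent")
})

test_that("all filters are idempotent", {
  gen <- make_meristem_map(n_cells = 80, n_ref_genes = 6, seed = 3)
  sim <- simulate_nuclei(gen$map, gen$truth, n_nuclei = 120,
                         n_probe_genes = 10, dropout = 0.5, seed = 3)
  # spatial-map filters
  f1 <- filter_cells_no_reference(gen$map)
  expect_equal(filter_cells_no_reference(f1$map)$map$cell_ids,
               f1$map$cell_ids)
  f2 <- filter_uninformative_reference_genes(f1$map, sim$expr)
  expect_equal(filter_uninformative_reference_genes(f2$map, sim$expr)$map$ref_genes,
               f2$map$ref_genes)
  f3 <- filter_sparse_and_rare_combination_cells(f2$map)
  expect_equal(filter_sparse_and_rare_combination_cells(f3$map)$map$cell_ids,
               f3$map$cell_ids)
  # expression filters
  f4 <- filter_low_prevalence_genes(sim$expr, min_cells = 10)
  expect_equal(filter_low_prevalence_genes(f4$expr, min_cells = 10)$expr$genes,
               f4$expr$genes)
  f5 <- filter_nuclei_no_reference(f4$expr, f3$map)
  expect_equal(filter_nuclei_no_reference(f5$expr, f3$map)$expr$barcodes,
               f5$expr$barcodes)
})
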