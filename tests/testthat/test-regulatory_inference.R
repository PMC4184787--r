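test_that("model construction enforces the partition and association invariants", {
  t2 <- data.frame(gene_id = c("a", "b", "b"), module_id = c("M1", "M1", "M2"))
  r2 <- data.frame(regulator_id = "R1", module_id = c("M1", "M2"), weight = 1)
  expect_error(regulatory_model(t2, r2), "b")

  t3 <- data.frame(gene_id = c("a", "b"), module_id = c("M1", "M2"))
  r3 <- data.frame(regulator_id = "R1", module_id = "M1", weight = 1)
  expect_error(regulatory_model(t3, r3), "M2")

  r4 <- data.frame(regulator_id = "R1", module_id = c("M1", "M3"), weight = 1)
  expect_error(regulatory_model(t3, r4), "M3")
})

test_that("model files round-trip", {
  mod <- two_regulator_model()
  tp <- withr::local_tempfile(fileext = ".tsv")
  rp <- withr::local_tempfile(fileext = ".tsv")
  write_regulatory_model(mod, tp, rp)
  back <- load_regulatory_model(tp, rp)
  expect_equal(back$targets, mod$targets)
  expect_equal(back$regulators, mod$regulators)
})

test_that("permutation bin enrichment matches the exact hypergeometric tail", {
  # modules of sizes 2, 1, 1; the list is both genes of the first module
  mod <- regulatory_model(
    data.frame(gene_id = c("a", "b", "c", "d"),
               module_id = c("M1", "M1", "M2", "M3")),
    data.frame(regulator_id = "R1", module_id = c("M1", "M2", "M3"),
               weight = 1))
  res <- module_bin_enrichment(c("a", "b"), mod, n_perm = 10000, seed = 2)
  p_exact <- phyper(1, 2, 2, 2, lower.tail = FALSE)  # 1/6
  mc_se <- sqrt(p_exact * (1 - p_exact) / 10000)
  expect_lt(abs(res$p[res$module_id == "M1"] - p_exact), 3 * mc_se + 1e-4)
  expect_equal(res$observed[res$module_id == "M1"], 2L)
  expect_equal(res$expected[res$module_id == "M1"], 1)
})

test_that("a saturated gene list is never enriched", {
  mod <- two_regulator_model()
  res <- module_bin_enrichment(mod$targets$gene_id, mod, n_perm = 500, seed = 1)
  expect_equal(res$observed, res$size)
  expect_true(all(res$p == 1))
  expect_false(any(res$enriched))
  expect_error(module_bin_enrichment(c("zz"), mod, 100), "X = 0")
})

test_that("genes outside the model are dropped and counted", {
  mod <- two_regulator_model()
  res <- module_bin_enrichment(c("g01", "g02", "nope"), mod,
                               n_perm = 200, seed = 1)
  expect_equal(attr(res, "X"), 2L)
  expect_equal(attr(res, "n_dropped"), 1L)
})

test_that("pair enrichment reproduces the hand-computed 2x2 chi-square", {
  mod <- two_regulator_model()
  # 8 genes from the R1 module, 2 from the R2 module -> table [[8,2],[2,8]]
  genes <- c(sprintf("g%02d", 1:8), "g11", "g12")
  res <- pair_enrichment(genes, mod)
  r1 <- res[res$regulator_id == "R1", ]
  expect_equal(r1$observed, 8)
  expect_equal(r1$statistic, 7.2)
  expect_equal(r1$p, pchisq(7.2, 1, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(r1$p, stats::chisq.test(matrix(c(8, 2, 2, 8), 2),
                                       correct = FALSE)$p.value,
               tolerance = 1e-12)
  expect_equal(r1$method, "chisq")

  # proportional list: statistic ~ 0, p ~ 1
  prop <- pair_enrichment(c(sprintf("g%02d", 1:5), sprintf("g%02d", 11:15)),
                          mod)
  expect_equal(prop$statistic, c(0, 0))
  expect_equal(prop$p, c(1, 1))
})

test_that("pair totals are conserved across regulator tables", {
  set.seed(55)
  for (rep in 1:5) {
    sim <- simulate_model(simulation_design(n_genes = 150, n_modules = 8,
                                            n_regulators = 6,
                                            genes_per_archetype = 5,
                                            n_specific_genes = 5,
                                            modules_per_regulator = 3,
                                            seed = rep))
    mod <- sim$model
    genes <- sample(mod$targets$gene_id, 30)
    res <- pair_enrichment(genes, mod)
    # each listed gene generates one pair per regulator of its module
    n_regs <- table(mod$regulators$module_id)
    expected_total <- sum(n_regs[mod$targets$module_id[
      mod$targets$gene_id %in% genes]])
    expect_equal(attr(res, "total_pairs"), as.numeric(expected_total))
    expect_equal(sum(res$observed), as.numeric(expected_total))
  }
})

test_that("regulator selection is the conjunction of the two analyses", {
  mod <- two_regulator_model()
  pair_res <- list(up = data.frame(regulator_id = c("R1", "R2"),
                                   enriched = c(TRUE, TRUE)))
  module_res <- list(up = data.frame(module_id = c("M1", "M2"),
                                     enriched = c(TRUE, FALSE)))
  # R2 passes the pair test but its only module is not enriched
  expect_equal(select_regulators(pair_res, module_res, mod), "R1")
  # R2's module enriched but pair test not passed
  pair_res$up$enriched <- c(TRUE, FALSE)
  module_res$up$enriched <- c(TRUE, TRUE)
  expect_equal(select_regulators(pair_res, module_res, mod), "R1")
  # conjunction satisfied in different pools still counts
  pair_res <- list(up = data.frame(regulator_id = "R2", enriched = TRUE))
  module_res <- list(down = data.frame(module_id = "M2", enriched = TRUE))
  expect_equal(select_regulators(pair_res, module_res, mod), "R2")
})

test_that("the regulator x cluster matrix flags empty clusters and finds signal", {
  mod <- two_regulator_model()
  clusters <- list(c1 = sprintf("g%02d", 1:10),   # all of R1's targets
                   c2 = c("x1", "x2"),            # no model targets
                   c3 = c(sprintf("g%02d", c(1:3, 11:13))))  # balanced
  pm <- regulator_cluster_matrix(clusters, c("R1", "R2"), mod)
  expect_lt(pm$p["R1", "c1"], 0.01)
  expect_equal(unname(pm$p[, "c2"]), c(1, 1))
  expect_equal(pm$empty_clusters, "c2")
  expect_equal(unname(pm$p["R1", "c3"]), 1)

  # clusters sampled uniformly from targets: p-values are not extreme
  set.seed(33)
  sim <- simulate_model(simulation_design(n_genes = 400, n_modules = 10,
                                          n_regulators = 8, concentration = 0,
                                          genes_per_archetype = 20,
                                          seed = 12))
  cl <- lapply(1:20, function(i) sample(sim$model$targets$gene_id, 40))
  names(cl) <- paste0("k", 1:20)
  regs <- unique(sim$model$regulators$regulator_id)
  pmat <- regulator_cluster_matrix(cl, regs, sim$model)$p
  expect_gt(mean(pmat), 0.2)   # roughly uniform, far from all-significant
  expect_lt(mean(pmat < 0.05), 0.15)
})

test_that("hierarchical clustering of the P matrix separates planted blocks", {
  p <- matrix(0.5, 6, 6, dimnames = list(paste0("R", 1:6), paste0("c", 1:6)))
  p[1:3, 1:3] <- 1e-6
  p[4:6, 4:6] <- 1e-4
  hc <- hcluster_matrix(p)
  ro <- hc$row_order
  expect_setequal(ro[1:3], if (ro[1] %in% 1:3) 1:3 else 4:6)
  co <- hc$col_order
  expect_setequal(co[1:3], if (co[1] %in% 1:3) 1:3 else 4:6)

  # 2x2: one merge on each axis
  hc2 <- hcluster_matrix(matrix(c(0.1, 0.2, 0.3, 0.4), 2,
                                dimnames = list(c("a", "b"), c("x", "y"))))
  expect_equal(nrow(hc2$row_tree$merge), 1)
  expect_equal(nrow(hc2$col_tree$merge), 1)

  # permuting rows permutes the tree but not its topology
  perm <- c(4, 1, 6, 2, 5, 3)
  hp <- hcluster_matrix(p[perm, ])
  d0 <- stats::cophenetic(hc$row_tree)
  dp <- stats::cophenetic(hp$row_tree)
  m0 <- as.matrix(d0)[order(rownames(p)), order(rownames(p))]
  mp <- as.matrix(dp)[order(rownames(p)[perm]), order(rownames(p)[perm])]
  expect_equal(m0, mp)

  flat <- hcluster_matrix(matrix(0.5, 3, 3,
                                 dimnames = list(1:3, 1:3)))
  expect_true(flat$degenerate)
  expect_error(hcluster_matrix(p[1, , drop = FALSE]), ">= 2")
})

test_that("BH adjustment equals the brute-force step-up oracle", {
  set.seed(71)
  for (n in c(1, 2, 5, 8, 13, 20)) {
    p <- runif(n)
    expect_equal(p.adjust(p, "BH"), bh_oracle(p), tolerance = 1e-12)
  }
})

test_that("null regulator selection is rare", {
  set.seed(61)
  sim <- simulate_model(simulation_design(n_genes = 400, n_modules = 10,
                                          n_regulators = 8, concentration = 0,
                                          genes_per_archetype = 20,
                                          seed = 21))
  mod <- sim$model
  n_sel <- 0
  n_lists <- 30
  for (i in 1:n_lists) {
    genes <- sample(mod$targets$gene_id, 50)
    pr <- pair_enrichment(genes, mod, q_cutoff = 0.01)
    mr <- module_bin_enrichment(genes, mod, n_perm = 400, seed = i)
    n_sel <- n_sel + length(select_regulators(list(pr), list(mr), mod))
  }
  expect_lte(n_sel / (n_lists * 8), 0.01 + 3 * sqrt(0.01 * 0.99 / (n_lists * 8)))
})
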