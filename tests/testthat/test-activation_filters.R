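conds4 <- c("BL", "SF", "UA", "TG")

test_that("the composite filter is the intersection of its four criteria", {
  cm <- mean_matrix(c(500, 500, 500, 500,     # flat: fails ANOVA and fold
                      100, 100, 100, 300,     # clean responder: passes all
                       50,  90,  60, 100),    # below threshold everywhere
                    c("flat", "responder", "dim"), conds4)
  m <- condition_matrix(cm, conds4, jitter = 0.05)
  res <- variation_filter(m, conds4)

  flat <- res[res$gene_id == "flat", ]
  expect_false(flat$pass_anova)
  expect_false(flat$pass_fold)
  resp <- res[res$gene_id == "responder", ]
  expect_true(all(unlist(resp[c("pass_presence", "pass_anova",
                                "pass_fold", "pass_cv")])))
  expect_true(resp$pass)
  expect_false(res$pass_presence[res$gene_id == "dim"])

  expect_equal(res$pass,
               res$pass_presence & res$pass_anova & res$pass_fold & res$pass_cv)
})

test_that("the row-wise ANOVA agrees with the per-gene stats oracle", {
  set.seed(21)
  cm <- matrix(runif(8 * 4, 100, 1000), 8, 4,
               dimnames = list(paste0("g", 1:8), conds4))
  m <- condition_matrix(cm, conds4, jitter = 0.08)
  res <- variation_filter(m, conds4)
  for (i in 1:8) {
    y <- log2(m$values[i, ])
    ow <- stats::oneway.test(y ~ factor(m$popmap$condition, levels = conds4),
                             var.equal = TRUE)
    expect_equal(res$anova_p[i], ow$p.value, tolerance = 1e-10)
  }
  expect_equal(res$anova_q, p.adjust(res$anova_p, "BH"))
})

test_that("filter diagnostics match direct computation", {
  cm <- mean_matrix(c(100, 100, 100, 300), "resp", conds4)
  m <- condition_matrix(cm, conds4, jitter = 0.05)
  res <- variation_filter(m, conds4)
  expect_equal(res$max_mean, 300)
  expect_equal(res$max_fold, 3)
  # per-condition CV of replicates (jitter 0.05 -> sd/mean = 0.05)
  expect_equal(res$max_cv, 0.05, tolerance = 1e-12)
  # a condition with one replicate is unusable
  one_rep <- m$values[, -(1:2), drop = FALSE]
  pm <- m$popmap[-(1:2), ]
  expect_error(variation_filter(expression_matrix(one_rep, pm), conds4),
               "single replicate")
})

test_that("fold changes vs reference equal a loop oracle", {
  expect_equal(unname(fold_vs_reference(
    mean_matrix(c(120, 240), "g", c("BL", "TG")), "TG", "BL")[1, 1]), 2)
  set.seed(31)
  means <- matrix(runif(6 * 4, 10, 1000), 6, 4,
                  dimnames = list(paste0("g", 1:6), conds4))
  fc <- fold_vs_reference(means, c("SF", "UA", "TG"), "BL")
  for (i in 1:6) for (cc in c("SF", "UA", "TG"))
    expect_equal(fc[i, cc], means[i, cc] / means[i, "BL"])
  expect_equal(unname(fold_vs_reference(means, "BL", "BL")[, 1]),
               rep(1, 6), ignore_attr = TRUE)
})

test_that("condition correlation recovers exact and simulated relationships", {
  set.seed(8)
  a <- 2^rnorm(50)
  # suppressWarnings: lm warns about the (intended) perfect fits
  self <- suppressWarnings(condition_correlation(a, a))
  expect_equal(self$r, 1)
  expect_equal(self$slope, 1)
  sq <- suppressWarnings(condition_correlation(a, a^2))
  expect_equal(sq$r, 1)
  expect_equal(sq$slope, 2)

  # bivariate log-normal with known correlation 0.8
  set.seed(123)
  n <- 200
  z1 <- rnorm(n)
  z2 <- 0.8 * z1 + sqrt(1 - 0.8^2) * rnorm(n)
  est <- condition_correlation(2^z1, 2^z2)
  expect_lt(abs(est$r - 0.8), 0.1)
  expect_true(est$slope_ci[1] < est$slope && est$slope < est$slope_ci[2])

  expect_error(condition_correlation(a, rep(1, 50)), "variance")
  expect_error(condition_correlation(a[1:2], a[1:2]), "n >= 3")
})

test_that("Venn counts match the exhaustive classification oracle", {
  conds <- c("SF", "TG", "UA")
  fc0 <- matrix(1, 4, 3, dimnames = list(paste0("g", 1:4), conds))
  expect_true(all(venn_counts(fc0) == 0))

  one <- matrix(c(2.5, 1.7, 1.2), 1, 3, dimnames = list("g", conds))
  strict <- venn_counts(one, mode = "strict")
  expect_equal(unname(strict["SF"]), 1L)
  expect_equal(sum(strict), 1L)
  relaxed <- venn_counts(one, mode = "relaxed")
  expect_equal(unname(relaxed["SF&TG"]), 1L)
  expect_equal(sum(relaxed), 1L)

  set.seed(77)
  fc <- matrix(2^runif(300 * 3, -2.5, 2.5), 300, 3,
               dimnames = list(sprintf("g%03d", 1:300), conds))
  for (mode in c("strict", "relaxed")) for (dir in c("up", "down")) {
    got <- venn_counts(fc, direction = dir, mode = mode)
    expect_equal(got, venn_oracle(fc, 2, 1.5, dir, mode))
    # regions sum to the genes passing strict in >= 1 condition
    s <- if (dir == "up") fc > 2 else fc < 0.5
    expect_equal(sum(got), sum(rowSums(s) >= 1))
  }
  # relaxed shared regions dominate strict shared regions
  for (dir in c("up", "down")) {
    st <- venn_counts(fc, direction = dir, mode = "strict")
    rx <- venn_counts(fc, direction = dir, mode = "relaxed")
    shared <- grep("&", names(st), value = TRUE)
    expect_gte(sum(rx[shared]), sum(st[shared]))
  }
  expect_error(venn_counts(fc[, 1:2]), "3 conditions")
})

test_that("condition-specific genes require the fold against every comparator", {
  means <- mean_matrix(c(800, 300, 200, 100,
                         400, 400, 400, 400,
                         500, 300, 200, 100),
                       c("sf_only", "flat", "sf_short"),
                       c("SF", "TG", "UA", "BL"))
  got <- condition_specific_genes(means, "SF", c("TG", "UA"), "BL", 2)
  expect_setequal(got, "sf_only")  # 500 < 2 * 300 excludes sf_short
  expect_error(condition_specific_genes(means, "SF", c("SF", "UA"), "BL"),
               "must not appear")
})

test_that("planted condition-specific archetypes are recovered at zero noise", {
  sim <- simulate_expression(simulation_design(n_genes = 400, noise_cv = 0,
                                               genes_per_archetype = 10,
                                               n_non_nf = 4, seed = 17))
  means <- population_means(sim$matrix)
  sf_truth <- sim$truth$gene_id[sim$truth$role == "sf_up"]
  got <- condition_specific_genes(means, "SF", c("TG", "UA"), "BL", 2)
  expect_setequal(got, sf_truth)
})

test_that("category-count comparison matches exact enumeration", {
  expect_equal(category_count_compare(5, 50, 5, 50)$p, 1)

  # two-sided Fisher p for [[10,0],[0,10]] by hypergeometric enumeration
  probs <- dhyper(0:10, 10, 10, 10)
  p_exact <- sum(probs[probs <= dhyper(10, 10, 10, 10) * (1 + 1e-7)])
  got <- category_count_compare(10, 10, 0, 10)
  expect_equal(got$p, p_exact, tolerance = 1e-10)
  expect_equal(got$method, "fisher")

  # chi-square and Fisher agree in direction on balanced large tables
  set.seed(14)
  for (rep in 1:20) {
    k1 <- rbinom(1, 200, 0.3); k2 <- rbinom(1, 200, 0.5)
    pf <- category_count_compare(k1, 200, k2, 200, "fisher")$p
    pc <- category_count_compare(k1, 200, k2, 200, "chisq")$p
    expect_equal(pf < 0.05, pc < 0.05)
  }
  expect_error(category_count_compare(10, 5, 1, 10), "exceed")
})
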