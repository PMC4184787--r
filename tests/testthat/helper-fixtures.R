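# Fixtures and independent oracles used across the test files. Everything
# is built in code; no binary data.

# small expression matrix: 2 populations x 2 replicates each
tiny_matrix <- function() {
  vals <- matrix(c(100, 140, 10, 12,
                   200, 220, 300, 330),
                 nrow = 2, byrow = TRUE,
                 dimnames = list(c("g1", "g2"),
                                 c("P1_r1", "P1_r2", "P2_r1", "P2_r2")))
  popmap <- data.frame(
    sample_id = colnames(vals),
    population_id = c("P1", "P1", "P2", "P2"),
    class = c("neutrophil", "neutrophil", "non_neutrophil", "non_neutrophil"),
    condition = c("BL", "BL", NA, NA))
  expression_matrix(vals, popmap)
}

# genes x populations mean matrix with named rows/columns
mean_matrix <- function(values, genes, pops) {
  matrix(values, nrow = length(genes), byrow = TRUE,
         dimnames = list(genes, pops))
}

# model: two modules, one regulator each, 10 genes per module
two_regulator_model <- function() {
  regulatory_model(
    targets = data.frame(
      gene_id = sprintf("g%02d", 1:20),
      module_id = rep(c("M1", "M2"), each = 10)),
    regulators = data.frame(
      regulator_id = rep(c("R1", "R2"), each = 1),
      module_id = c("M1", "M2"),
      weight = c(1, 1)))
}

# brute-force BH step-up: the textbook definition, independent of p.adjust
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- numeric(n)
  prev <- 1
  for (i in n:1) {
    prev <- min(prev, p[o[i]] * n / i)
    q[o[i]] <- prev
  }
  q
}

# exhaustive per-gene Venn classification, mirroring the stated rule
venn_oracle <- function(fc, strict, relaxed, direction, mode) {
  conds <- colnames(fc)
  regions <- c(conds,
               paste(conds[1], conds[2], sep = "&"),
               paste(conds[1], conds[3], sep = "&"),
               paste(conds[2], conds[3], sep = "&"),
               paste(conds, collapse = "&"))
  counts <- setNames(integer(7), regions)
  for (i in seq_len(nrow(fc))) {
    x <- fc[i, ]
    s <- if (direction == "up") x > strict else x < 1 / strict
    r <- if (direction == "up") x > relaxed else x < 1 / relaxed
    if (!any(s)) next
    member <- if (mode == "strict") s else r
    counts[paste(conds[member], collapse = "&")] <-
      counts[paste(conds[member], collapse = "&")] + 1L
  }
  counts
}

# replicate-level matrix with given condition means (3 reps, exact means)
condition_matrix <- function(cond_means, conditions, jitter = 0) {
  n_rep <- 3
  genes <- rownames(cond_means)
  vals <- do.call(cbind, lapply(seq_along(conditions), function(j) {
    base <- matrix(cond_means[, j], nrow(cond_means), n_rep)
    # mean-preserving replicate offsets
    off <- jitter * cond_means[, j] %o% c(-1, 0, 1)
    base + off
  }))
  dimnames(vals) <- list(genes,
                         paste0(rep(conditions, each = n_rep), "_r",
                                rep(1:n_rep, length(conditions))))
  popmap <- data.frame(
    sample_id = colnames(vals),
    population_id = rep(conditions, each = n_rep),
    class = "neutrophil",
    condition = rep(conditions, each = n_rep))
  expression_matrix(vals, popmap)
}

adjusted_rand <- function(a, b) mclust::adjustedRandIndex(a, b)
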