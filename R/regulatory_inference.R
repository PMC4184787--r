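# Regulatory-model enrichment: a permutation null over coarse-module bins,
# regulator-target-pair over-representation by chi-square, dual-criterion
# regulator selection, the regulator x cluster P-value matrix, and its
# hierarchical clustering.

#' Construct a regulatory model
#'
#' A coarse-module regulatory model: every target gene belongs to exactly
#' one module, and each module is associated with one or more candidate
#' regulators, with regression-derived weights that are comparable only
#' within a module (the weights define associations and are carried through
#' for reporting; no test statistic uses them).
#'
#' @param targets `data.frame` with columns `gene_id`, `module_id`.
#' @param regulators `data.frame` with columns `regulator_id`, `module_id`,
#'   `weight`.
#' @return Object of class `RegulatoryModel`.
#' @export
regulatory_model <- function(targets, regulators) {
  targets <- as.data.frame(targets, stringsAsFactors = FALSE)
  regulators <- as.data.frame(regulators, stringsAsFactors = FALSE)
  stopifnot(all(c("gene_id", "module_id") %in% names(targets)),
            all(c("regulator_id", "module_id", "weight") %in% names(regulators)))
  if (anyDuplicated(targets$gene_id))
    stop("a target gene is assigned to more than one module: ",
         paste(unique(targets$gene_id[duplicated(targets$gene_id)]),
               collapse = ", "))
  mods <- unique(targets$module_id)
  orphan <- setdiff(unique(regulators$module_id), mods)
  if (length(orphan))
    stop("regulator association(s) reference module(s) with no targets: ",
         paste(orphan, collapse = ", "))
  bare <- setdiff(mods, unique(regulators$module_id))
  if (length(bare))
    stop("module(s) with no associated regulator: ",
         paste(bare, collapse = ", "))
  structure(list(targets = targets, regulators = regulators),
            class = "RegulatoryModel")
}

#' @export
print.RegulatoryModel <- function(x, ...) {
  cat(sprintf("RegulatoryModel: %d targets in %d modules, %d regulators (%d associations)\n",
              nrow(x$targets), length(unique(x$targets$module_id)),
              length(unique(x$regulators$regulator_id)), nrow(x$regulators)))
  invisible(x)
}

#' Read a regulatory model from its two tab-delimited files
#'
#' @param targets_path Tab-delimited file with columns `gene_id`,
#'   `module_id`.
#' @param regulators_path Tab-delimited file with columns `regulator_id`,
#'   `module_id`, `weight`.
#' @return A [regulatory_model()].
#' @export
load_regulatory_model <- function(targets_path, regulators_path) {
  targets <- utils::read.delim(targets_path, stringsAsFactors = FALSE,
                               colClasses = "character")
  regulators <- utils::read.delim(regulators_path, stringsAsFactors = FALSE)
  regulators$weight <- as.numeric(regulators$weight)
  regulatory_model(targets, regulators)
}

#' Write a regulatory model to its two tab-delimited files
#'
#' @param model A `RegulatoryModel`.
#' @param targets_path,regulators_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_regulatory_model <- function(model, targets_path, regulators_path) {
  stopifnot(inherits(model, "RegulatoryModel"))
  utils::write.table(model$targets, targets_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(model$regulators, regulators_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(c(targets_path, regulators_path))
}

#' Permutation enrichment of a gene list over coarse-module bins
#'
#' Let X be the number of unique listed genes that are model targets. Each
#' permutation draws X genes without replacement from all model targets and
#' tabulates per-module hits; the per-module p-value is the smoothed upper
#' tail `(1 + #{perm count >= observed}) / (n_perm + 1)`, BH-adjusted across
#' modules. Genes absent from the model are dropped (their number is
#' reported). The null is hypergeometric because a fixed set of distinct
#' genes is distributed over bins.
#'
#' The `p_fuzzy` column holds randomized ("fuzzy") p-values —
#' `(#{> obs} + U * (1 + #{= obs})) / (n_perm + 1)`, U ~ Uniform(0,1) —
#' which are exactly uniform under the null despite the discreteness of the
#' counts. They are a calibration diagnostic only; inference uses `p`/`q`.
#'
#' @param genes Character vector of gene identifiers.
#' @param model A `RegulatoryModel`.
#' @param n_perm Number of permutations (default 10000).
#' @param seed Integer seed.
#' @param q_cutoff BH Q threshold for the `enriched` flag (default 0.05).
#' @return `data.frame` of class `EnrichmentResult`, one row per module:
#'   `module_id`, `size`, `observed`, `expected`, `p`, `p_fuzzy`, `q`,
#'   `enriched`. Attributes `X` (list size used) and `n_dropped`.
#' @export
module_bin_enrichment <- function(genes, model, n_perm = 10000, seed = 1L,
                                  q_cutoff = 0.05) {
  stopifnot(inherits(model, "RegulatoryModel"))
  genes <- unique(genes)
  idx <- match(genes, model$targets$gene_id)
  n_dropped <- sum(is.na(idx))
  idx <- idx[!is.na(idx)]
  X <- length(idx)
  if (X == 0) stop("no listed gene is a model target (X = 0)")
  mod_f <- factor(model$targets$module_id,
                  levels = unique(model$targets$module_id))
  n_mod <- nlevels(mod_f)
  n_targets <- nrow(model$targets)
  observed <- tabulate(mod_f[idx], nbins = n_mod)
  sizes <- tabulate(mod_f, nbins = n_mod)

  ge <- integer(n_mod)  # permutations with count >= observed
  gt <- integer(n_mod)  # permutations with count >  observed
  u <- NULL
  withr::with_seed(seed, {
    mod_int <- as.integer(mod_f)
    for (b in seq_len(n_perm)) {
      cnt <- tabulate(mod_int[sample.int(n_targets, X)], nbins = n_mod)
      ge <- ge + (cnt >= observed)
      gt <- gt + (cnt > observed)
    }
    u <- stats::runif(n_mod)
  })
  p <- (1 + ge) / (n_perm + 1)
  p_fuzzy <- (gt + u * (1 + ge - gt)) / (n_perm + 1)
  q <- stats::p.adjust(p, method = "BH")
  out <- data.frame(module_id = levels(mod_f), size = sizes,
                    observed = observed,
                    expected = X * sizes / n_targets,
                    p = p, p_fuzzy = p_fuzzy, q = q,
                    enriched = q < q_cutoff & observed > X * sizes / n_targets,
                    row.names = NULL)
  attr(out, "X") <- X
  attr(out, "n_dropped") <- n_dropped
  class(out) <- c("EnrichmentResult", class(out))
  out
}

# number of regulator-target pairs each gene set generates, per regulator
pair_counts <- function(gene_idx, model, reg_levels) {
  mods <- model$targets$module_id[gene_idx]
  mod_tab <- table(mods)
  assoc <- model$regulators[model$regulators$module_id %in% names(mod_tab), ]
  mult <- as.numeric(mod_tab[assoc$module_id])
  counts <- tapply(mult, factor(assoc$regulator_id, levels = reg_levels), sum)
  counts[is.na(counts)] <- 0
  as.numeric(counts)
}

pearson_chisq_2x2 <- function(a, b, c, d) {
  n <- a + b + c + d
  denom <- (a + b) * (c + d) * (a + c) * (b + d)
  if (denom == 0) return(list(stat = 0, p = 1))
  stat <- (a * d - b * c)^2 * n / denom
  list(stat = stat, p = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Regulator-target-pair over-representation
#'
#' Each listed gene contributes one pair to regulator R for every
#' association of R with that gene's module. For each regulator the 2x2
#' table contrasts pairs for R versus pairs for all other regulators, in the
#' list versus in the remainder of the model, and is tested by Pearson
#' chi-square without continuity correction (Fisher's exact test when any
#' expected cell is below 5). BH adjustment is applied across regulators.
#'
#' @param genes Character vector of gene identifiers.
#' @param model A `RegulatoryModel`.
#' @param q_cutoff BH Q threshold for the `enriched` flag (default 0.01);
#'   the flag additionally requires over-representation
#'   (observed > expected).
#' @return `data.frame` of class `EnrichmentResult`, one row per regulator:
#'   `regulator_id`, `observed`, `max_pairs`, `expected`, `statistic`, `p`,
#'   `q`, `method`, `enriched`. Attribute `total_pairs` gives the pairs
#'   generated by the list.
#' @export
pair_enrichment <- function(genes, model, q_cutoff = 0.01) {
  stopifnot(inherits(model, "RegulatoryModel"))
  genes <- unique(genes)
  idx <- which(model$targets$gene_id %in% genes)
  if (length(idx) == 0) stop("no listed gene is a model target")
  reg_levels <- unique(model$regulators$regulator_id)
  in_list <- pair_counts(idx, model, reg_levels)
  in_model <- pair_counts(seq_len(nrow(model$targets)), model, reg_levels)
  if (any(in_model == 0))
    stop("regulator(s) with zero pairs in the model: ",
         paste(reg_levels[in_model == 0], collapse = ", "))
  t_list <- sum(in_list)
  t_model <- sum(in_model)
  res <- lapply(seq_along(reg_levels), function(i) {
    a <- in_list[i]; b <- t_list - a
    c <- in_model[i] - a; d <- (t_model - in_model[i]) - b
    tab <- matrix(c(a, b, c, d), 2, byrow = TRUE)
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    cs <- pearson_chisq_2x2(a, b, c, d)
    if (any(expected < 5)) {
      p <- stats::fisher.test(round(tab))$p.value
      method <- "fisher"
    } else {
      p <- cs$p
      method <- "chisq"
    }
    data.frame(regulator_id = reg_levels[i], observed = a,
               max_pairs = in_model[i],
               expected = t_list * in_model[i] / t_model,
               statistic = cs$stat, p = p, method = method)
  })
  out <- do.call(rbind, res)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out$enriched <- out$q < q_cutoff & out$observed > out$expected
  attr(out, "total_pairs") <- t_list
  class(out) <- c("EnrichmentResult", class(out))
  out
}

#' Dual-criterion regulator selection
#'
#' A regulator is selected when it is over-represented in the
#' regulator-target-pair test of at least one cluster pool AND is associated
#' with at least one coarse module significantly enriched in some pool.
#'
#' @param pool_pair_results Named list of [pair_enrichment()] results, one
#'   per cluster pool.
#' @param pool_module_results Named list of [module_bin_enrichment()]
#'   results, one per pool.
#' @param model The `RegulatoryModel` (supplies regulator-module
#'   associations).
#' @return Character vector of selected regulator identifiers (sorted).
#' @export
select_regulators <- function(pool_pair_results, pool_module_results, model) {
  stopifnot(inherits(model, "RegulatoryModel"))
  pair_hits <- unique(unlist(lapply(pool_pair_results, function(r)
    r$regulator_id[r$enriched])))
  enriched_modules <- unique(unlist(lapply(pool_module_results, function(r)
    r$module_id[r$enriched])))
  module_hits <- unique(
    model$regulators$regulator_id[model$regulators$module_id %in%
                                    enriched_modules])
  sort(intersect(pair_hits, module_hits))
}

#' Regulator x cluster matrix of pair-enrichment P-values
#'
#' Entry (R, c) is the raw chi-square (or Fisher fallback) p-value of the
#' regulator-target-pair test for cluster c's genes and regulator R.
#' Clusters with no model-target gene get a row of 1s and are flagged.
#'
#' @param cluster_genes Named list mapping cluster id to its gene
#'   identifiers.
#' @param regulators Character vector of regulators (matrix rows).
#' @param model A `RegulatoryModel`.
#' @return List with `p` (regulators x clusters matrix) and
#'   `empty_clusters` (character vector of flagged cluster ids).
#' @export
regulator_cluster_matrix <- function(cluster_genes, regulators, model) {
  if (!length(cluster_genes) || !length(regulators))
    stop("need a non-empty cluster list and regulator set")
  p <- matrix(1, nrow = length(regulators), ncol = length(cluster_genes),
              dimnames = list(regulators, names(cluster_genes)))
  empty <- character(0)
  for (cl in names(cluster_genes)) {
    gs <- cluster_genes[[cl]]
    if (!any(gs %in% model$targets$gene_id)) {
      empty <- c(empty, cl)
      next
    }
    res <- pair_enrichment(gs, model)
    p[, cl] <- res$p[match(regulators, res$regulator_id)]
  }
  list(p = p, empty_clusters = empty)
}

#' Hierarchical clustering of a P-value matrix
#'
#' Rows (regulators) and columns (clusters) are clustered agglomeratively on
#' their `-log10(p)` vectors with Euclidean distance and average linkage.
#' P-values are floored at `p_floor` before the log. An all-equal matrix is
#' ordered as given and flagged degenerate.
#'
#' @param p_matrix Numeric matrix of p-values (>= 2 rows and columns).
#' @param p_floor Smallest p used in the transform (default 1e-300).
#' @return List with `row_order`, `col_order` (leaf orders), `row_tree`,
#'   `col_tree` (`hclust` objects), and `degenerate`.
#' @export
hcluster_matrix <- function(p_matrix, p_floor = 1e-300) {
  if (nrow(p_matrix) < 2 || ncol(p_matrix) < 2)
    stop("matrix must have >= 2 rows and >= 2 columns")
  nl <- -log10(pmax(p_matrix, p_floor))
  degenerate <- max(nl) - min(nl) == 0
  row_tree <- stats::hclust(stats::dist(nl), method = "average")
  col_tree <- stats::hclust(stats::dist(t(nl)), method = "average")
  list(row_order = row_tree$order, col_order = col_tree$order,
       row_tree = row_tree, col_tree = col_tree, degenerate = degenerate)
}
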