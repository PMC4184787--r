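# Data model and I/O for normalized expression matrices with a
# sample -> population map. Intensities are stored on the linear scale;
# log2 is applied only where a downstream method calls for it.

#' Construct an ExpressionMatrix
#'
#' Bundles a genes x samples matrix of normalized, linear-scale intensities
#' with a sample-to-population map. All downstream analyses consume this
#' container.
#'
#' @param values Numeric matrix, genes in rows, samples in columns. Row names
#'   are gene identifiers, column names are sample identifiers. All values
#'   must be non-negative and non-missing.
#' @param popmap `data.frame` with columns `sample_id`, `population_id`,
#'   `class` (one of `"neutrophil"`, `"non_neutrophil"`) and `condition`
#'   (e.g. BM, BL, SF, UA, TG; may be `NA` for comparator populations).
#'   Every column of `values` must appear exactly once in `sample_id`.
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `values` and `popmap` (rows ordered as the matrix columns).
#' @export
expression_matrix <- function(values, popmap) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have gene row names and sample column names")
  dup <- rownames(values)[duplicated(rownames(values))]
  if (length(dup))
    stop("duplicated gene identifier(s): ", paste(unique(dup), collapse = ", "))
  dup <- colnames(values)[duplicated(colnames(values))]
  if (length(dup))
    stop("duplicated sample identifier(s): ", paste(unique(dup), collapse = ", "))
  if (anyNA(values)) stop("missing values are not allowed")
  if (any(values < 0)) stop("negative intensities are not allowed")

  popmap <- as.data.frame(popmap, stringsAsFactors = FALSE)
  req <- c("sample_id", "population_id", "class", "condition")
  miss <- setdiff(req, names(popmap))
  if (length(miss))
    stop("population map lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(popmap$sample_id))
    stop("duplicated sample_id in population map")
  unmapped <- setdiff(colnames(values), popmap$sample_id)
  if (length(unmapped))
    stop("sample(s) missing from population map: ",
         paste(unmapped, collapse = ", "))
  bad <- setdiff(unique(popmap$class), c("neutrophil", "non_neutrophil"))
  if (length(bad))
    stop("unknown population class: ", paste(bad, collapse = ", "))
  popmap <- popmap[match(colnames(values), popmap$sample_id), req]
  rownames(popmap) <- NULL
  structure(list(values = values, popmap = popmap), class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples, %d populations\n",
              nrow(x$values), ncol(x$values),
              length(unique(x$popmap$population_id))))
  invisible(x)
}

#' Analysis configuration
#'
#' Collects the constants used across the pipeline: the presence threshold
#' associated with reliable protein detection on this platform, the
#' activation-filter cutoffs, the clustering and enrichment parameters, and
#' the heat-map display span.
#'
#' @param presence_threshold Intensity above which a gene is considered
#'   reliably expressed (default 120).
#' @param anova_p Per-gene one-way ANOVA p-value cutoff (default 0.01).
#' @param min_fold Minimum pairwise fold difference between condition means
#'   (default 2).
#' @param relaxed_fold Relaxed fold cutoff used for shared Venn regions
#'   (default 1.5).
#' @param max_cv Maximum within-condition coefficient of variation of
#'   replicate intensities (default 0.5).
#' @param k_clusters Number of K-means clusters (default 32).
#' @param n_modules Number of coarse modules in the regulatory model
#'   (default 81).
#' @param n_permutations Permutations for the module-bin null (default 10000).
#' @param q_module BH Q cutoff for module enrichment (default 0.05).
#' @param q_pair BH Q cutoff for regulator-pair enrichment (default 0.01).
#' @param heatmap_fold_span Fold range spanned by the full heat-map color
#'   gradient (default 8).
#' @param seed Integer seed for all stochastic steps.
#' @return A list of class `AnalysisConfig`.
#' @export
analysis_config <- function(presence_threshold = 120, anova_p = 0.01,
                            min_fold = 2, relaxed_fold = 1.5, max_cv = 0.5,
                            k_clusters = 32, n_modules = 81,
                            n_permutations = 10000, q_module = 0.05,
                            q_pair = 0.01, heatmap_fold_span = 8, seed = 1L) {
  cfg <- list(presence_threshold = presence_threshold, anova_p = anova_p,
              min_fold = min_fold, relaxed_fold = relaxed_fold,
              max_cv = max_cv, k_clusters = as.integer(k_clusters),
              n_modules = as.integer(n_modules),
              n_permutations = as.integer(n_permutations),
              q_module = q_module, q_pair = q_pair,
              heatmap_fold_span = heatmap_fold_span, seed = as.integer(seed))
  thr <- c("presence_threshold", "min_fold", "relaxed_fold", "max_cv",
           "heatmap_fold_span")
  if (any(unlist(cfg[thr]) <= 0)) stop("thresholds must be > 0")
  pr <- c("anova_p", "q_module", "q_pair")
  if (any(unlist(cfg[pr]) <= 0 | unlist(cfg[pr]) >= 1))
    stop("probability cutoffs must lie in (0, 1)")
  if (cfg$k_clusters < 1 || cfg$n_modules < 1 || cfg$n_permutations < 0)
    stop("counts must be positive")
  class(cfg) <- "AnalysisConfig"
  cfg
}

#' Read an expression matrix and population map from disk
#'
#' The matrix file is tab-delimited with a header row of sample identifiers
#' and first column `gene_id`; the population map is a CSV with columns
#' `sample_id`, `population_id`, `class`, `condition`.
#'
#' @param matrix_path Path to the tab-delimited expression file.
#' @param popmap_path Path to the population-map CSV.
#' @return A validated [expression_matrix()].
#' @export
load_expression <- function(matrix_path, popmap_path) {
  hdr <- strsplit(readLines(matrix_path, n = 1), "\t", fixed = TRUE)[[1]]
  if (hdr[1] != "gene_id")
    stop("expression file must start with a 'gene_id' header column")
  tab <- utils::read.delim(matrix_path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character")
  genes <- tab[[1]]
  dup <- genes[duplicated(genes)]
  if (length(dup))
    stop("duplicated gene identifier(s): ", paste(unique(dup), collapse = ", "))
  vals <- as.matrix(tab[, -1, drop = FALSE])
  suppressWarnings(storage <- matrix(as.numeric(vals), nrow = nrow(vals)))
  if (anyNA(storage)) {
    bad <- which(is.na(storage), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric value for gene '%s', sample '%s'",
                 genes[bad[1]], colnames(vals)[bad[2]]))
  }
  dimnames(storage) <- list(genes, colnames(vals))
  popmap <- utils::read.csv(popmap_path, stringsAsFactors = FALSE,
                            colClasses = "character")
  expression_matrix(storage, popmap)
}

#' Write an expression matrix and population map to disk
#'
#' Inverse of [load_expression()]; the text dialect (UTF-8, tab-delimited,
#' `.` decimal separator, 15 significant digits) round-trips values exactly
#' for doubles that are exactly representable, and bit-identically after one
#' write/read cycle in all cases used here.
#'
#' @param m An `ExpressionMatrix`.
#' @param matrix_path,popmap_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_expression <- function(m, matrix_path, popmap_path) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  tab <- data.frame(gene_id = rownames(m$values),
                    format(m$values, digits = 17, trim = TRUE,
                           scientific = FALSE),
                    check.names = FALSE)
  utils::write.table(tab, matrix_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  utils::write.csv(m$popmap, popmap_path, row.names = FALSE, quote = FALSE)
  invisible(c(matrix_path, popmap_path))
}

#' Per-gene per-population mean expression
#'
#' Means over replicate samples of each population are the analysis currency
#' of every screen in this package.
#'
#' @param m An `ExpressionMatrix`.
#' @return Numeric matrix, genes x populations, linear scale. Column order
#'   follows first appearance in the population map.
#' @export
population_means <- function(m) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  pops <- unique(m$popmap$population_id)
  out <- vapply(pops, function(p) {
    cols <- m$popmap$population_id == p
    rowMeans(m$values[, cols, drop = FALSE])
  }, numeric(nrow(m$values)))
  out <- matrix(out, nrow = nrow(m$values),
                dimnames = list(rownames(m$values), pops))
  out
}

#' Summarize per-gene expression over a set of populations
#'
#' Produces the summary columns of a lineage-specificity report: median,
#' range, and the number of populations in the set whose mean exceeds a
#' presence threshold (strict inequality).
#'
#' @param means Genes x populations mean matrix from [population_means()].
#' @param popset Character vector of population columns to summarize.
#' @param threshold Presence threshold (default 120).
#' @return `data.frame` with columns `gene_id`, `median`, `min`, `max`,
#'   `count_above`.
#' @export
summarize_populations <- function(means, popset, threshold = 120) {
  if (length(popset) == 0) stop("popset must be non-empty")
  miss <- setdiff(popset, colnames(means))
  if (length(miss))
    stop("unknown population(s): ", paste(miss, collapse = ", "))
  sub <- means[, popset, drop = FALSE]
  data.frame(
    gene_id = rownames(means),
    median = apply(sub, 1, stats::median),
    min = apply(sub, 1, min),
    max = apply(sub, 1, max),
    count_above = as.integer(rowSums(sub > threshold)),
    row.names = NULL
  )
}

#' Log2-transform and mean-center population means
#'
#' Per gene, each mean is log2-transformed and the mean of the log2 values
#' over `popset` is subtracted, so that row means are exactly zero. Used for
#' heat-map display and pattern comparison; intensities must be positive (on
#' this platform normalized values are bounded well above zero, so a
#' non-positive value is a data error rather than a censored count).
#'
#' @param means Genes x populations mean matrix.
#' @param popset Populations to center across (default: all columns).
#' @return Genes x `popset` matrix of centered log2 values.
#' @export
log2_mean_center <- function(means, popset = colnames(means)) {
  sub <- means[, popset, drop = FALSE]
  if (any(sub <= 0)) stop("all means must be > 0 for log transformation")
  lg <- log2(sub)
  lg - rowMeans(lg)
}
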