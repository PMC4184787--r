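# Lineage-specificity screens over population means: genes reliably
# expressed in every neutrophil population but no comparator population
# (presence criterion), genes whose minimum neutrophil mean clears a fold
# multiple of the maximum comparator mean (fold criterion), the combined
# report, and the symmetric under-expression screen.

check_popsets <- function(means, nf_pops, non_nf_pops) {
  if (!length(nf_pops) || !length(non_nf_pops))
    stop("both population sets must be non-empty")
  if (length(intersect(nf_pops, non_nf_pops)))
    stop("population sets overlap: ",
         paste(intersect(nf_pops, non_nf_pops), collapse = ", "))
  miss <- setdiff(c(nf_pops, non_nf_pops), colnames(means))
  if (length(miss))
    stop("unknown population(s): ", paste(miss, collapse = ", "))
}

#' Presence criterion of the lineage-specificity screen
#'
#' Genes with mean expression strictly above `threshold` in every neutrophil
#' population and at or below it in every non-neutrophil population.
#'
#' @param means Genes x populations mean matrix.
#' @param nf_pops,non_nf_pops Disjoint population sets.
#' @param threshold Presence threshold (default 120).
#' @return Character vector of gene identifiers.
#' @export
presence_criterion <- function(means, nf_pops, non_nf_pops, threshold = 120) {
  check_popsets(means, nf_pops, non_nf_pops)
  nf <- means[, nf_pops, drop = FALSE]
  non <- means[, non_nf_pops, drop = FALSE]
  keep <- rowSums(nf > threshold) == length(nf_pops) &
    rowSums(non > threshold) == 0
  rownames(means)[keep]
}

#' Fold criterion of the lineage-specificity screen
#'
#' Genes whose minimum neutrophil-population mean is at least `min_fold`
#' times the maximum non-neutrophil mean.
#'
#' @inheritParams presence_criterion
#' @param min_fold Fold multiple (default 2); the comparison is `>=`. A gene
#'   absent everywhere (minimum neutrophil mean 0) never qualifies.
#' @return Character vector of gene identifiers.
#' @export
fold_criterion <- function(means, nf_pops, non_nf_pops, min_fold = 2) {
  check_popsets(means, nf_pops, non_nf_pops)
  min_nf <- apply(means[, nf_pops, drop = FALSE], 1, min)
  max_non <- apply(means[, non_nf_pops, drop = FALSE], 1, max)
  rownames(means)[min_nf > 0 & min_nf >= min_fold * max_non]
}

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Combined specificity report
#'
#' For every gene passing either criterion: the per-neutrophil-population
#' means, neutrophil median/range, non-neutrophil median/range and presence
#' count, the min-NF / max-non-NF ratio (with its half-away-from-zero
#' integer rounding, the convention under which a ratio of 11.87 is reported
#' as 12-fold), and the two criterion flags.
#'
#' @inheritParams presence_criterion
#' @param cfg An [analysis_config()]; supplies `presence_threshold` and
#'   `min_fold`.
#' @return `data.frame`, one row per gene in the union of the two criteria.
#' @export
specificity_report <- function(means, nf_pops, non_nf_pops,
                               cfg = analysis_config()) {
  thr <- cfg$presence_threshold
  pres <- presence_criterion(means, nf_pops, non_nf_pops, thr)
  fold <- fold_criterion(means, nf_pops, non_nf_pops, cfg$min_fold)
  genes <- rownames(means)[rownames(means) %in% union(pres, fold)]
  nf_sum <- summarize_populations(means[genes, , drop = FALSE], nf_pops, thr)
  non_sum <- summarize_populations(means[genes, , drop = FALSE], non_nf_pops, thr)
  ratio <- nf_sum$min / non_sum$max
  out <- data.frame(
    gene_id = genes,
    means[genes, nf_pops, drop = FALSE],
    nf_median = nf_sum$median, nf_min = nf_sum$min, nf_max = nf_sum$max,
    non_nf_median = non_sum$median, non_nf_min = non_sum$min,
    non_nf_max = non_sum$max, non_nf_above = non_sum$count_above,
    fold_ratio = ratio, fold_ratio_rounded = round_half_away(ratio),
    pass_presence = genes %in% pres, pass_fold = genes %in% fold,
    row.names = NULL, check.names = FALSE
  )
  out[order(out$gene_id), , drop = FALSE]
}

#' Specificity screen from a printed summary table
#'
#' Applies both criteria when only summary statistics of the comparator
#' populations are available: per-neutrophil-population means, the maximum
#' non-neutrophil mean, and the count of non-neutrophil populations above
#' the presence threshold (as in a published screen summary table).
#'
#' @param tab `data.frame` with per-NF-population mean columns named in
#'   `nf_cols`, a `non_nf_above` count column and a `non_nf_max` column;
#'   gene identifiers in `gene_id`.
#' @param nf_cols Names of the neutrophil mean columns.
#' @param threshold Presence threshold (default 120).
#' @param min_fold Fold multiple for the second criterion (default 2).
#' @return `tab` with logical columns `pass_presence`, `pass_fold`,
#'   `pass_both` appended.
#' @export
specificity_from_summary <- function(tab, nf_cols,
                                     threshold = 120, min_fold = 2) {
  nf <- as.matrix(tab[, nf_cols, drop = FALSE])
  tab$pass_presence <- rowSums(nf > threshold) == length(nf_cols) &
    tab$non_nf_above == 0
  tab$pass_fold <- apply(nf, 1, min) >= min_fold * tab$non_nf_max
  tab$pass_both <- tab$pass_presence & tab$pass_fold
  tab
}

#' Under-expression screen
#'
#' Mirror of the two specificity criteria with the roles of the neutrophil
#' and non-neutrophil sets swapped: (i) genes expressed above the threshold
#' in every non-neutrophil population and in no neutrophil population;
#' (ii) genes whose minimum non-neutrophil mean is strictly more than
#' `min_fold` times the maximum neutrophil mean (the fold direction is
#' strict here, unlike the `>=` of the over-expression screen).
#'
#' @inheritParams specificity_report
#' @return `data.frame` with one row per gene in the union, flags
#'   `pass_fold` and `pass_presence`, and attribute `counts` giving the two
#'   criterion counts, their intersection, and the union size.
#' @export
under_expression_screen <- function(means, nf_pops, non_nf_pops,
                                    cfg = analysis_config()) {
  check_popsets(means, nf_pops, non_nf_pops)
  thr <- cfg$presence_threshold
  nf <- means[, nf_pops, drop = FALSE]
  non <- means[, non_nf_pops, drop = FALSE]
  pass_presence <- rowSums(non > thr) == length(non_nf_pops) &
    rowSums(nf > thr) == 0
  pass_fold <- apply(non, 1, min) > cfg$min_fold * apply(nf, 1, max)
  keep <- pass_presence | pass_fold
  out <- data.frame(gene_id = rownames(means)[keep],
                    pass_fold = pass_fold[keep],
                    pass_presence = pass_presence[keep], row.names = NULL)
  attr(out, "counts") <- c(fold = sum(pass_fold),
                           presence = sum(pass_presence),
                           both = sum(pass_fold & pass_presence),
                           union = sum(keep))
  out
}

#' Collapse probe-level flags to gene level
#'
#' A gene is flagged if any of its probes is flagged (logical OR), matching
#' the probe-then-gene convention of array-based screens.
#'
#' @param probe_ids Character vector of probe identifiers.
#' @param gene_ids Parallel vector of gene symbols.
#' @param flags Parallel logical vector.
#' @return `data.frame` with one row per gene and its OR-combined flag.
#' @export
collapse_probes <- function(probe_ids, gene_ids, flags) {
  stopifnot(length(probe_ids) == length(gene_ids),
            length(gene_ids) == length(flags))
  agg <- tapply(flags, gene_ids, any)
  data.frame(gene_id = names(agg), flag = as.logical(agg), row.names = NULL)
}
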